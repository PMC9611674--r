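#' Create a twin runtime
#'
#' The runtime owns the broker-side plumbing: a registry of model
#' handlers (one per model type) and of the per-shipment wrapper
#' instances they spawn. Handlers subscribe to the `Model_Config` topic;
#' when an announcement carries their own model name they create a
#' wrapper instance wired to the announced topics and subscribe it to its
#' input topic from offset 0, so instances created late still replay the
#' full history.
#'
#' @param broker A [broker_new()] broker.
#' @param params Named list of per-model parameter lists (usually the
#'   `models:` section of the configuration file).
#' @param max_fill Gap-filling limit passed to every instance.
#' @return Environment of class `twin_runtime`.
#' @export
twin_runtime <- function(broker, params = list(), max_fill = 48L) {
  rt <- new.env(parent = emptyenv())
  rt$broker <- broker
  rt$params <- params
  rt$max_fill <- as.integer(max_fill)
  rt$handlers <- list()
  rt$instances <- new.env(parent = emptyenv())
  class(rt) <- "twin_runtime"
  rt
}

#' @export
print.twin_runtime <- function(x, ...) {
  cat(sprintf("<twin_runtime: %d handler(s), %d instance(s)>\n",
              length(x$handlers), length(ls(x$instances))))
  invisible(x)
}

#' Register a model handler
#'
#' @param rt A [twin_runtime()].
#' @param model_name Model type the handler serves (matched against the
#'   `model_name` field of `Model_Config` announcements).
#' @param factory Function `(params)` returning a fresh specific wrapper
#'   for one shipment.
#' @return The handler (list with `model_name`, `factory`), invisibly.
#' @export
register_handler <- function(rt, model_name, factory) {
  stopifnot(inherits(rt, "twin_runtime"), is.function(factory))
  handler <- list(model_name = model_name, factory = factory)
  rt$handlers[[model_name]] <- handler
  broker_subscribe(rt$broker, "Model_Config",
                   function(msg, offset) handle_config_message(msg, handler, rt),
                   from_offset = 0L)
  invisible(handler)
}

#' React to a Model_Config announcement
#'
#' Name filtering and idempotence live here: announcements for other
#' model types return `NULL`, and a duplicate announcement for an already
#' instantiated (shipment, model) pair is ignored, which makes handler
#' processing safe under at-least-once delivery.
#'
#' @param msg A `MODEL_CONFIG` [twin_message] from the `Model_Config` topic.
#' @param handler A handler as registered by [register_handler()].
#' @param rt The owning [twin_runtime()].
#' @return The new [wrapper_instance()], or `NULL` if the announcement
#'   was filtered or a duplicate.
#' @export
handle_config_message <- function(msg, handler, rt) {
  if (msg$kind != "MODEL_CONFIG") return(NULL)
  p <- msg$payload
  if (!identical(p$model_name, handler$model_name)) return(NULL)
  key <- paste(p$shipment_id, p$model_name, sep = "::")
  if (!is.null(get0(key, envir = rt$instances, inherits = FALSE))) {
    return(NULL)
  }
  lct <- as.list(stats::setNames(as.character(p$lifecycle_commands),
                                 as.character(p$lifecycle_events)))
  binding <- new_model_binding(p$cargo_type, p$model_name,
                               p$topic_in, p$topic_out, lct)
  wrapper <- handler$factory(rt$params[[p$model_name]])
  inst <- wrapper_instance(binding, wrapper, rt$broker,
                           max_fill = rt$max_fill)
  inst$shipment_id <- p$shipment_id
  assign(key, inst, envir = rt$instances)
  broker_subscribe(rt$broker, binding$topic_in,
                   function(m, offset) dispatch(inst, m),
                   from_offset = 0L)
  inst
}

#' Start handlers for a set of model types
#'
#' Convenience wrapper over [register_handler()] using a factory map,
#' e.g. [banana_factories()].
#'
#' @param rt A [twin_runtime()].
#' @param model_names Model types to serve.
#' @param factories Named list of wrapper factories.
#' @return The runtime, invisibly.
#' @export
start_handlers <- function(rt, model_names, factories = banana_factories()) {
  missing <- setdiff(model_names, names(factories))
  if (length(missing)) {
    stop(twin_error(sprintf("no wrapper factory for model type(s): %s",
                            paste(missing, collapse = ", ")),
                    "twin_wiring_error"))
  }
  for (nm in model_names) register_handler(rt, nm, factories[[nm]])
  invisible(rt)
}

#' Wrapper instances of a runtime
#' @param rt A [twin_runtime()].
#' @return Named list of [wrapper_instance()] (key `shipment::model`).
#' @export
runtime_instances <- function(rt) {
  keys <- sort(ls(rt$instances))
  stats::setNames(lapply(keys, function(k) get(k, envir = rt$instances)), keys)
}

#' Collected log records of all instances
#' @param rt A [twin_runtime()].
#' @return data.frame (see [instance_log()]).
#' @export
runtime_log <- function(rt) {
  logs <- lapply(runtime_instances(rt), instance_log)
  if (!length(logs)) return(instance_log(wrapper_instance(
    new_model_binding("", "", "A", "B", list()), NULL, NULL)))
  do.call(rbind, logs)
}
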