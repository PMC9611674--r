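#' Model commands driven by life-cycle events
#'
#' Closed command vocabulary for the wrapper phase machine. Transport
#' events are translated per model into one of these commands by the
#' `LifeCycleTranslate` table of the cargo-type configuration.
#' @export
MODEL_COMMANDS <- c("Start_Collect", "Stop_Collect", "Start_Model", "Stop_Model")

#' Sensor topic for a shipment
#'
#' First topic of every shipment's enriched-stream chain; sensor readings,
#' life-cycle events and prediction queries are all published here.
#'
#' @param shipment_id Shipment identifier (`[A-Za-z0-9]+`).
#' @return Topic name string.
#' @export
sensor_topic <- function(shipment_id) {
  paste0("Transports_Shipment_", shipment_id, "_Sensors")
}

new_model_binding <- function(cargo_type, model_name, topic_in, topic_out,
                              lifecycle_translate) {
  structure(list(cargo_type = cargo_type, model_name = model_name,
                 topic_in = topic_in, topic_out = topic_out,
                 lifecycle_translate = lifecycle_translate),
            class = "model_binding")
}

#' @export
print.model_binding <- function(x, ...) {
  cat(sprintf("<model_binding %s [%s]>\n  %s -> %s\n",
              x$model_name, x$cargo_type, x$topic_in, x$topic_out))
  if (length(x$lifecycle_translate)) {
    cat(paste0("  ", names(x$lifecycle_translate), ": ",
               unlist(x$lifecycle_translate), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Parse a cargo-type configuration
#'
#' The configuration is a YAML document with one section per cargo type;
#' each section maps model names to their stream wiring:
#'
#' ```yaml
#' Bananas:
#'   RipeningModel:
#'     Topic_In: Transports_Shipment_#ID_CoolPara
#'     Topic_Out: Transports_Shipment_#ID_RipePara
#'     LifeCycleTranslate:
#'       Start_Transport: Start_Collect
#'       Arrive_Transport: Stop_Collect
#'       Start_Ripening: Start_Model
#' ```
#'
#' Topic patterns may contain the literal token `#ID`, replaced by the
#' shipment number at instantiation time. A reserved top-level section
#' `models:` carries model parameters and is returned in the `params`
#' attribute rather than as a cargo type. Document order of the model
#' entries defines the chain order.
#'
#' @param text Configuration document as a single string, or a character
#'   vector of lines.
#' @return Named list: cargo type -> list of `model_binding` (document
#'   order), with attribute `params` holding the `models:` section.
#' @export
parse_config <- function(text) {
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  doc <- tryCatch(yaml::yaml.load(text),
                  error = function(e) stop(twin_error(
                    sprintf("configuration is not valid YAML: %s",
                            conditionMessage(e)), "twin_config_error")))
  if (is.null(doc)) doc <- list()
  if (!is.list(doc)) {
    stop(twin_error("configuration must be a mapping of cargo types",
                    "twin_config_error"))
  }
  params <- doc[["models"]]
  doc[["models"]] <- NULL
  schemas <- list()
  for (cargo in names(doc)) {
    section <- doc[[cargo]]
    bindings <- list()
    if (is.null(section)) section <- list()
    for (model_name in names(section)) {
      entry <- section[[model_name]]
      for (key in c("Topic_In", "Topic_Out")) {
        if (is.null(entry[[key]])) {
          stop(twin_error(sprintf("%s/%s: missing %s", cargo, model_name, key),
                          "twin_config_error"))
        }
      }
      lct <- entry[["LifeCycleTranslate"]]
      if (is.null(lct)) lct <- list()
      bad <- setdiff(unlist(lct), MODEL_COMMANDS)
      if (length(bad)) {
        stop(twin_error(sprintf(
          "%s/%s: unknown model command(s) in LifeCycleTranslate: %s",
          cargo, model_name, paste(bad, collapse = ", ")),
          "twin_config_error"))
      }
      if (identical(entry[["Topic_In"]], entry[["Topic_Out"]])) {
        stop(twin_error(sprintf("%s/%s: Topic_In equals Topic_Out",
                                cargo, model_name), "twin_config_error"))
      }
      bindings[[model_name]] <- new_model_binding(
        cargo, model_name, entry[["Topic_In"]], entry[["Topic_Out"]],
        as.list(lct))
    }
    schemas[[cargo]] <- bindings
  }
  attr(schemas, "params") <- if (is.null(params)) list() else params
  schemas
}

#' Read a configuration file
#' @param path Path to a YAML configuration file.
#' @return See [parse_config()].
#' @export
read_config <- function(path) {
  parse_config(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

#' Serialize a parsed configuration back to YAML
#' @param schemas A parsed configuration ([parse_config()]).
#' @return A single YAML string that parses to an equal schema map.
#' @export
format_config <- function(schemas) {
  doc <- lapply(schemas, function(bindings) {
    lapply(bindings, function(b) {
      list(Topic_In = b$topic_in, Topic_Out = b$topic_out,
           LifeCycleTranslate = b$lifecycle_translate)
    })
  })
  params <- attr(schemas, "params")
  if (length(params)) doc$models <- params
  yaml::as.yaml(doc)
}

substitute_id <- function(pattern, shipment_id) {
  gsub("#ID", shipment_id, pattern, fixed = TRUE)
}

#' Instantiate a shipment plan from a cargo-type schema
#'
#' Replaces every `#ID` token in the topic patterns with the shipment
#' number and verifies that the bindings form a connected linear chain:
#' the first model reads the shipment sensor topic, and every subsequent
#' model reads either the sensor topic or the output of an earlier model.
#' Instantiation is idempotent: an already-concrete schema passes through
#' unchanged.
#'
#' @param cargo_type Cargo type present in `schemas`.
#' @param shipment_id Shipment identifier (`[A-Za-z0-9]+`).
#' @param schemas Parsed configuration ([parse_config()]).
#' @return Object of class `shipment_plan`: list with `shipment_id`,
#'   `cargo_type` and `bindings` (concrete `model_binding`s, chain order).
#' @export
instantiate_plan <- function(cargo_type, shipment_id, schemas) {
  if (!grepl("^[A-Za-z0-9]+$", shipment_id)) {
    stop(twin_error(sprintf("invalid shipment_id: %s", shipment_id),
                    "twin_config_error"))
  }
  if (!cargo_type %in% names(schemas)) {
    stop(twin_error(sprintf("unknown cargo type: %s", cargo_type),
                    "twin_lookup_error"))
  }
  produced <- sensor_topic(shipment_id)
  bindings <- lapply(schemas[[cargo_type]], function(b) {
    b$topic_in <- substitute_id(b$topic_in, shipment_id)
    b$topic_out <- substitute_id(b$topic_out, shipment_id)
    b
  })
  for (b in bindings) {
    if (!b$topic_in %in% produced) {
      stop(twin_error(sprintf(
        "%s: input topic %s is neither the sensor topic nor produced upstream",
        b$model_name, b$topic_in), "twin_wiring_error"))
    }
    produced <- c(produced, b$topic_out)
  }
  structure(list(shipment_id = shipment_id, cargo_type = cargo_type,
                 bindings = bindings),
            class = "shipment_plan")
}

#' @export
print.shipment_plan <- function(x, ...) {
  cat(sprintf("<shipment_plan %s [%s]>\n", x$shipment_id, x$cargo_type))
  cat(sprintf("  %s\n", sensor_topic(x$shipment_id)))
  for (b in x$bindings) cat(sprintf("    -> %s -> %s\n", b$model_name, b$topic_out))
  invisible(x)
}

#' Announce a shipment plan on the Model_Config topic
#'
#' Publishes one `MODEL_CONFIG` message per binding to the well-known
#' `Model_Config` topic. Model handlers subscribe there and instantiate a
#' wrapper when they see their own model name; announcements for other
#' model types are ignored, and duplicate announcements for the same
#' (shipment, model) pair are suppressed by the handlers.
#'
#' @param plan A [instantiate_plan()] plan.
#' @param broker A broker.
#' @param timestamp Logical time of the announcement (hours), default 0.
#' @return Integer vector of publish offsets, invisibly.
#' @export
announce_plan <- function(plan, broker, timestamp = 0) {
  stopifnot(inherits(plan, "shipment_plan"))
  offs <- vapply(plan$bindings, function(b) {
    payload <- list(
      model_name = b$model_name,
      cargo_type = b$cargo_type,
      shipment_id = plan$shipment_id,
      topic_in = b$topic_in,
      topic_out = b$topic_out,
      lifecycle_events = as.character(names(b$lifecycle_translate)),
      lifecycle_commands = as.character(unlist(b$lifecycle_translate))
    )
    broker_publish(broker, "Model_Config",
                   twin_message("Model_Config", timestamp, plan$shipment_id,
                                "MODEL_CONFIG", payload))
  }, numeric(1))
  invisible(offs)
}

#' Translate a transport event into a model command
#'
#' Looks the event up in the binding's `LifeCycleTranslate` table. Events a
#' model does not subscribe to yield `NULL` and are silently ignored by
#' the wrapper.
#'
#' @param event_name Transport event name (e.g. `"Start_Transport"`).
#' @param binding A `model_binding`.
#' @return One of [MODEL_COMMANDS], or `NULL` for unmapped events.
#' @export
translate_event <- function(event_name, binding) {
  cmd <- binding$lifecycle_translate[[event_name]]
  if (is.null(cmd)) NULL else cmd
}
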