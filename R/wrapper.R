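#' Wrapper life-cycle phases
#'
#' A wrapper instance moves along
#' `WAITING -> COLLECTING -> ARMED -> ACTIVE -> STOPPED`, with the
#' shortcuts `WAITING -> ACTIVE` (collector phase omitted) and
#' `COLLECTING -> STOPPED`. Transitions are driven exclusively by the
#' model commands produced by [translate_event()].
#' @export
WRAPPER_PHASES <- c("WAITING", "COLLECTING", "ARMED", "ACTIVE", "STOPPED")

# legal (phase, command) -> new phase
.transitions <- list(
  Start_Collect = c(WAITING = "COLLECTING"),
  Stop_Collect  = c(COLLECTING = "ARMED"),
  Start_Model   = c(WAITING = "ACTIVE", ARMED = "ACTIVE"),
  Stop_Model    = c(ACTIVE = "STOPPED", COLLECTING = "STOPPED")
)

## ---- specific-wrapper contract ------------------------------------------

#' Specific-wrapper contract
#'
#' Each model type implements this small S3 contract on top of the generic
#' wrapper: `sw_collect()` is called once per input message while the
#' instance is in the COLLECTING phase, `sw_step()` once per (real or
#' gap-filled) sample in the ACTIVE phase, and `sw_predict()` for query
#' events. `sw_step()`/`sw_predict()` return a named list of result fields
#' (enriched into the stream under the wrapper's `field_prefix`
#' namespace), or `NULL` when the output is postponed, e.g. until enough
#' samples have accumulated.
#'
#' A wrapper object is an environment with fields `field_prefix`,
#' `required_fields`, `nominal_interval` (hours), `interval_tolerance`
#' (fraction) and `state`.
#'
#' @param w The specific wrapper.
#' @param payload Input payload field map.
#' @param t Logical timestamp, hours.
#' @param dt Hours since the previous processed sample (`NA` for the first).
#' @param horizon Prediction horizon, whole hours.
#' @param overrides Query payload carrying optional what-if overrides.
#' @return `sw_collect()`: ignored. `sw_step()`, `sw_predict()`: named
#'   list of result fields or `NULL`.
#' @name specific_wrapper
NULL

#' @rdname specific_wrapper
#' @export
sw_collect <- function(w, payload, t) UseMethod("sw_collect")
#' @rdname specific_wrapper
#' @export
sw_collect.default <- function(w, payload, t) NULL
#' @rdname specific_wrapper
#' @export
sw_step <- function(w, payload, t, dt) UseMethod("sw_step")
#' @rdname specific_wrapper
#' @export
sw_step.default <- function(w, payload, t, dt) NULL
#' @rdname specific_wrapper
#' @export
sw_predict <- function(w, payload, t, horizon, overrides = list()) {
  UseMethod("sw_predict")
}
#' @rdname specific_wrapper
#' @export
sw_predict.default <- function(w, payload, t, horizon, overrides = list()) NULL

new_specific_wrapper <- function(class, field_prefix, required_fields,
                                 nominal_interval = 1,
                                 interval_tolerance = 0.1) {
  w <- new.env(parent = emptyenv())
  w$field_prefix <- field_prefix
  w$required_fields <- required_fields
  w$nominal_interval <- nominal_interval
  w$interval_tolerance <- interval_tolerance
  w$state <- new.env(parent = emptyenv())
  class(w) <- c(class, "specific_wrapper")
  w
}

## ---- wrapper instance ----------------------------------------------------

#' Create a per-shipment wrapper instance
#'
#' The generic wrapper: holds the phase machine, the gap-filling state and
#' the instrumented call log, and owns one specific wrapper. Instances are
#' normally created by a model handler reacting to a `Model_Config`
#' announcement ([handle_config_message()]), not directly.
#'
#' @param binding Concrete `model_binding` (after `#ID` substitution).
#' @param wrapper A specific wrapper (see [specific_wrapper]).
#' @param broker Broker the instance publishes to.
#' @param max_fill Maximum number of gap-filled ticks per gap before the
#'   gap is declared a data outage (default 48).
#' @return Environment of class `wrapper_instance`.
#' @export
wrapper_instance <- function(binding, wrapper, broker, max_fill = 48L) {
  inst <- new.env(parent = emptyenv())
  inst$binding <- binding
  inst$shipment_id <- NA_character_
  inst$wrapper <- wrapper
  inst$broker <- broker
  inst$phase <- "WAITING"
  inst$collected <- 0L
  inst$last_payload <- NULL
  inst$last_timestamp <- NULL
  inst$max_fill <- as.integer(max_fill)
  inst$log <- list()
  inst$call_log <- list()
  class(inst) <- "wrapper_instance"
  inst
}

#' @export
print.wrapper_instance <- function(x, ...) {
  cat(sprintf("<wrapper_instance %s/%s phase=%s>\n",
              x$shipment_id, x$binding$model_name, x$phase))
  invisible(x)
}

log_instance <- function(inst, level, event, detail = "", t = NA_real_) {
  inst$log[[length(inst$log) + 1L]] <- list(
    level = level, event = event, detail = detail, t = t,
    model = inst$binding$model_name, shipment = inst$shipment_id,
    phase = inst$phase)
  invisible(inst)
}

record_call <- function(inst, fn, t) {
  inst$call_log[[length(inst$call_log) + 1L]] <-
    list(fn = fn, phase = inst$phase, t = t)
  invisible(inst)
}

#' Instance log as a data frame
#' @param inst A [wrapper_instance()].
#' @return data.frame with columns level, event, detail, t, model,
#'   shipment, phase.
#' @export
instance_log <- function(inst) {
  if (!length(inst$log)) {
    return(data.frame(level = character(0), event = character(0),
                      detail = character(0), t = numeric(0),
                      model = character(0), shipment = character(0),
                      phase = character(0)))
  }
  do.call(rbind, lapply(inst$log, function(r) {
    data.frame(level = r$level, event = r$event, detail = r$detail,
               t = r$t, model = r$model, shipment = r$shipment,
               phase = r$phase)
  }))
}

apply_command <- function(inst, cmd, t) {
  target <- .transitions[[cmd]][inst$phase]
  if (is.null(target) || is.na(target)) {
    log_instance(inst, "warning", "illegal_command",
                 sprintf("%s in phase %s ignored", cmd, inst$phase), t)
    return(invisible(FALSE))
  }
  log_instance(inst, "info", "phase_transition",
               sprintf("%s: %s -> %s", cmd, inst$phase, target), t)
  inst$phase <- unname(target)
  invisible(TRUE)
}

## ---- enrichment ----------------------------------------------------------

#' Enrich a message with model results
#'
#' Copies the input message to the output topic unchanged and appends the
#' model's result fields, namespaced as `<model_name>.<field>` so chained
#' models can never collide. With a `NULL` result the output payload is an
#' exact copy: every model forwards its full input stream, which is what
#' turns the model chain into a chain of enriched topics.
#'
#' @param input_msg A [twin_message].
#' @param model_name Namespace for the result fields.
#' @param result Named list of result fields, or `NULL`.
#' @param topic_out Topic for the enriched message.
#' @return A new [twin_message] on `topic_out` with the same timestamp,
#'   shipment and kind.
#' @export
enrich <- function(input_msg, model_name, result, topic_out) {
  payload <- input_msg$payload
  if (!is.null(result) && length(result)) {
    names(result) <- paste(model_name, names(result), sep = ".")
    payload[names(result)] <- result
  }
  twin_message(topic_out, input_msg$timestamp, input_msg$shipment_id,
               input_msg$kind, payload)
}

## ---- sampling checks and gap filling ------------------------------------

#' Classify the sampling interval of an incoming sample
#'
#' Compares the time since the previously processed sample with the
#' nominal sampling interval: within the tolerance band the sample is
#' `OK`; a longer interval is a `GAP` (triggering gap filling); a
#' non-advancing timestamp -- or an interval shorter than the lower
#' tolerance bound, i.e. an over-sampled near-duplicate -- is `REJECT`
#' and the sample is dropped from model processing (but still forwarded
#' downstream).
#'
#' @param last_t Timestamp of the previous processed sample, hours.
#' @param t Timestamp of the incoming sample, hours.
#' @param nominal Nominal sampling interval, hours.
#' @param tol Tolerance as a fraction of `nominal` (default 0.1).
#' @return `"OK"`, `"GAP"` or `"REJECT"`.
#' @export
check_interval <- function(last_t, t, nominal, tol = 0.1) {
  dt <- t - last_t
  if (dt <= 0) return("REJECT")
  if (abs(dt - nominal) <= tol * nominal) return("OK")
  if (dt > (1 + tol) * nominal) return("GAP")
  "REJECT"
}

# nominal ticks strictly between last_t and t
gap_ticks <- function(last_t, t, nominal) {
  eps <- 1e-9 * max(1, abs(t))
  ticks <- seq(last_t + nominal, by = nominal,
               length.out = max(0L, floor((t - last_t) / nominal - eps)))
  ticks[ticks < t - eps]
}

# run the model over a gap: feed the last known payload at each missing
# nominal tick. Returns TRUE if filled, FALSE on data outage.
fill_gap <- function(inst, t) {
  w <- inst$wrapper
  ticks <- gap_ticks(inst$last_timestamp, t, w$nominal_interval)
  if (length(ticks) > inst$max_fill) {
    log_instance(inst, "error", "data_outage",
                 sprintf("gap of %.1f h exceeds max_fill=%d ticks; state kept",
                         t - inst$last_timestamp, inst$max_fill), t)
    return(FALSE)
  }
  for (tick in ticks) {
    record_call(inst, "step", tick)
    try_model(inst, sw_step(w, inst$last_payload, tick, w$nominal_interval),
              tick)
    inst$last_timestamp <- tick
  }
  TRUE
}

# evaluate a model call, turning twin_error conditions into log records
try_model <- function(inst, expr, t) {
  tryCatch(expr, twin_error = function(e) {
    log_instance(inst, "error", "model_error", conditionMessage(e), t)
    NULL
  })
}

## ---- dispatch ------------------------------------------------------------

#' Dispatch one input message through a wrapper instance
#'
#' The heart of the generic wrapper. Life-cycle events are translated to
#' model commands and drive the phase machine; sensor samples are
#' collected, stepped or passed through depending on the phase; queries
#' trigger the prediction path. Every input message produces exactly one
#' output message on the instance's output topic (stream continuity), so
#' downstream models always see the full stream, whatever this model's
#' phase.
#'
#' @param inst A [wrapper_instance()].
#' @param msg Incoming [twin_message] from `binding$topic_in`.
#' @return The published output message, invisibly.
#' @export
dispatch <- function(inst, msg) {
  w <- inst$wrapper
  out <- switch(
    msg$kind,
    LIFECYCLE = {
      ev <- msg$payload[["event"]]
      cmd <- if (is.null(ev)) NULL else translate_event(ev, inst$binding)
      if (!is.null(cmd)) apply_command(inst, cmd, msg$timestamp)
      enrich(msg, w$field_prefix, NULL, inst$binding$topic_out)
    },
    QUERY = {
      if (inst$phase == "ACTIVE") {
        run_query(inst, msg)
      } else {
        log_instance(inst, "info", "query_ignored",
                     sprintf("query in phase %s forwarded untouched", inst$phase),
                     msg$timestamp)
        enrich(msg, w$field_prefix, NULL, inst$binding$topic_out)
      }
    },
    MODEL_CONFIG = enrich(msg, w$field_prefix, NULL, inst$binding$topic_out),
    { # SENSOR and RESULT share the sample path
      dispatch_sample(inst, msg)
    })
  broker_publish(inst$broker, inst$binding$topic_out, out)
  invisible(out)
}

dispatch_sample <- function(inst, msg) {
  w <- inst$wrapper
  t <- msg$timestamp
  if (inst$phase == "COLLECTING") {
    record_call(inst, "collect", t)
    try_model(inst, sw_collect(w, msg$payload, t), t)
    inst$collected <- inst$collected + 1L
    return(enrich(msg, w$field_prefix, NULL, inst$binding$topic_out))
  }
  if (inst$phase != "ACTIVE") {
    return(enrich(msg, w$field_prefix, NULL, inst$binding$topic_out))
  }
  if (msg$kind == "SENSOR" &&
      length(setdiff(w$required_fields, names(msg$payload)))) {
    log_instance(inst, "warning", "missing_fields",
                 paste(setdiff(w$required_fields, names(msg$payload)),
                       collapse = ", "), t)
    return(enrich(msg, w$field_prefix, NULL, inst$binding$topic_out))
  }
  result <- NULL
  if (is.null(inst$last_timestamp)) {
    record_call(inst, "step", t)
    result <- try_model(inst, sw_step(w, msg$payload, t, NA_real_), t)
    inst$last_payload <- msg$payload
    inst$last_timestamp <- t
  } else {
    cls <- check_interval(inst$last_timestamp, t, w$nominal_interval,
                          w$interval_tolerance)
    if (cls == "REJECT") {
      log_instance(inst, "warning", "sample_rejected",
                   sprintf("dt=%.3f h outside band around nominal %.3f h",
                           t - inst$last_timestamp, w$nominal_interval), t)
      return(enrich(msg, w$field_prefix, NULL, inst$binding$topic_out))
    }
    stepped <- TRUE
    if (cls == "GAP") stepped <- fill_gap(inst, t)
    if (stepped) {
      record_call(inst, "step", t)
      result <- try_model(inst,
                          sw_step(w, msg$payload, t, t - inst$last_timestamp),
                          t)
    }
    inst$last_payload <- msg$payload
    inst$last_timestamp <- t
  }
  if (!is.null(result) && !is.null(attr(result, "notice"))) {
    log_instance(inst, "info", "model_notice", attr(result, "notice"), t)
    attr(result, "notice") <- NULL
  }
  enrich(msg, w$field_prefix, result, inst$binding$topic_out)
}

#' Answer a prediction query
#'
#' Computes the prediction horizon as the hours between the query
#' timestamp and the `arrival_time` carried in the query payload, invokes
#' the specific wrapper's `sw_predict()` and enriches the query message
#' with the result (typically an hourly prediction array plus a query id).
#' A query without `arrival_time` is answered with an error field instead.
#'
#' @param inst An ACTIVE [wrapper_instance()].
#' @param msg A `QUERY` [twin_message].
#' @return The enriched output message (not yet published).
#' @export
run_query <- function(inst, msg) {
  w <- inst$wrapper
  arr <- msg$payload[["arrival_time"]]
  if (is.null(arr) || !is.finite(arr)) {
    log_instance(inst, "warning", "query_error", "missing arrival_time",
                 msg$timestamp)
    return(enrich(msg, w$field_prefix, list(error = "missing arrival_time"),
                  inst$binding$topic_out))
  }
  horizon <- max(0L, as.integer(round(arr - msg$timestamp)))
  record_call(inst, "predict", msg$timestamp)
  result <- try_model(inst,
                      sw_predict(w, msg$payload, msg$timestamp, horizon,
                                 overrides = msg$payload),
                      msg$timestamp)
  if (!is.null(result) && !is.null(attr(result, "notice"))) {
    log_instance(inst, "info", "model_notice", attr(result, "notice"),
                 msg$timestamp)
    attr(result, "notice") <- NULL
  }
  enrich(msg, w$field_prefix, result, inst$binding$topic_out)
}
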