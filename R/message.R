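#' Message kinds understood by the runtime
#'
#' Every event flowing through the platform is one of these kinds:
#' `SENSOR` readings, `LIFECYCLE` transport events, `QUERY` prediction
#' requests, `MODEL_CONFIG` instantiation announcements and generic
#' `RESULT` messages.
#'
#' @export
MESSAGE_KINDS <- c("SENSOR", "LIFECYCLE", "QUERY", "MODEL_CONFIG", "RESULT")

#' Construct a twin message
#'
#' A message is the unit of all communication in the platform: a
#' time-stamped, topic-addressed field map. Timestamps are logical time in
#' hours since scenario start, decoupled from wall-clock playback speed.
#'
#' @param topic Topic name, matching `[A-Za-z0-9_]+`.
#' @param timestamp Hours since scenario start (non-negative real).
#' @param shipment_id Shipment identifier; may be `""` only for
#'   `MODEL_CONFIG` messages.
#' @param kind One of [MESSAGE_KINDS].
#' @param payload Named list mapping field names to scalars, strings or
#'   numeric vectors.
#' @return An object of class `twin_message`.
#' @examples
#' m <- twin_message("Transports_Shipment_4711_Sensors", 12, "4711",
#'                   "SENSOR", list(T_Box = 18.4, T_Supply = 13.2))
#' @export
twin_message <- function(topic, timestamp, shipment_id, kind, payload = list()) {
  check_topic_name(topic)
  if (!is.numeric(timestamp) || length(timestamp) != 1L || is.na(timestamp) ||
      timestamp < 0) {
    stop(twin_error("timestamp must be a single non-negative number",
                    "twin_message_error"))
  }
  kind <- match.arg(kind, MESSAGE_KINDS)
  if (!is.character(shipment_id) || length(shipment_id) != 1L ||
      (!nzchar(shipment_id) && kind != "MODEL_CONFIG")) {
    stop(twin_error("shipment_id must be a non-empty string", "twin_message_error"))
  }
  payload <- as_payload(payload)
  structure(
    list(topic = topic, timestamp = as.numeric(timestamp),
         shipment_id = shipment_id, kind = kind, payload = payload),
    class = "twin_message"
  )
}

#' @export
print.twin_message <- function(x, ...) {
  cat(sprintf("<twin_message %s @ %.3f h | %s | %s>\n",
              x$kind, x$timestamp, x$shipment_id, x$topic))
  if (length(x$payload)) {
    flds <- vapply(x$payload, function(v) {
      if (length(v) > 1L) sprintf("[%d values]", length(v)) else format(v)
    }, character(1))
    cat(paste0("  ", names(x$payload), " = ", flds, collapse = "\n"), "\n")
  }
  invisible(x)
}

# coerce and validate a payload field map
as_payload <- function(payload) {
  if (is.null(payload)) payload <- list()
  if (!is.list(payload)) stop(twin_error("payload must be a named list",
                                         "twin_codec_error"))
  if (length(payload) && (is.null(names(payload)) || any(!nzchar(names(payload))))) {
    stop(twin_error("all payload fields must be named", "twin_codec_error"))
  }
  ok <- vapply(payload, function(v) {
    is.numeric(v) || is.character(v) || is.logical(v)
  }, logical(1))
  if (length(payload) && !all(ok)) {
    stop(twin_error(
      sprintf("payload fields must be scalars, strings or numeric arrays: %s",
              paste(names(payload)[!ok], collapse = ", ")),
      "twin_codec_error"))
  }
  payload[] <- lapply(payload, function(v) if (is.integer(v)) as.numeric(v) else v)
  payload
}

check_topic_name <- function(topic) {
  if (!is.character(topic) || length(topic) != 1L ||
      !grepl("^[A-Za-z0-9_]+$", topic)) {
    stop(twin_error(sprintf("invalid topic name: %s",
                            paste(format(topic), collapse = " ")),
                    "twin_topic_error"))
  }
  invisible(topic)
}

# condition constructor shared across the package
twin_error <- function(msg, class) {
  structure(class = c(class, "twin_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Encode a message as JSON
#'
#' Wire format: one JSON object with keys `topic`, `timestamp`,
#' `shipment_id`, `kind` and a nested `payload` object. Numbers are written
#' at full precision so that decode(encode(m)) reproduces `m` to better
#' than 12 significant digits (in practice bit-exactly).
#'
#' @param msg A [twin_message].
#' @return A single JSON string (no trailing newline).
#' @export
encode_message <- function(msg) {
  stopifnot(inherits(msg, "twin_message"))
  env <- list(topic = msg$topic, timestamp = msg$timestamp,
              shipment_id = msg$shipment_id, kind = msg$kind,
              payload = msg$payload)
  as.character(jsonlite::toJSON(env, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

#' Decode a JSON message
#'
#' Inverse of [encode_message()]. Unknown top-level keys are preserved by
#' folding them into the payload, so messages from richer producers survive
#' a round trip.
#'
#' @param text A single JSON string.
#' @param context Optional string (e.g. `"topic@offset"`) included in parse
#'   errors to locate the offending record.
#' @return A [twin_message].
#' @export
decode_message <- function(text, context = NULL) {
  obj <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE),
    error = function(e) {
      stop(twin_error(sprintf("malformed JSON%s: %s",
                              if (is.null(context)) "" else paste0(" at ", context),
                              conditionMessage(e)),
                      "twin_codec_error"))
    })
  required <- c("topic", "timestamp", "shipment_id", "kind")
  missing <- setdiff(required, names(obj))
  if (length(missing)) {
    stop(twin_error(sprintf("message missing envelope field(s): %s%s",
                            paste(missing, collapse = ", "),
                            if (is.null(context)) "" else paste0(" at ", context)),
                    "twin_schema_error"))
  }
  payload <- obj$payload
  if (is.null(payload)) payload <- list()
  extra <- setdiff(names(obj), c(required, "payload"))
  for (k in extra) payload[[k]] <- obj[[k]]
  payload[] <- lapply(payload, function(v) {
    if (is.list(v) && length(v) == 0L) numeric(0) else unlist(v)
  })
  twin_message(obj$topic, obj$timestamp, obj$shipment_id, obj$kind, payload)
}
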