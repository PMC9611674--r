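#' Create an in-memory broker
#'
#' The broker is an ordered, append-only topic log with publish/subscribe
#' semantics: late subscribers replay history from any offset, and every
#' subscriber of a topic receives its entries in offset order (per-topic
#' FIFO). It is the reference implementation of the streaming-platform
#' seam; adapters to external log-based brokers can implement the same
#' `publish`/`subscribe` contract.
#'
#' Delivery is synchronous and depth-first: publishing a message invokes
#' all current handlers before `broker_publish()` returns. Because handlers
#' may themselves publish (the enriched-stream chain), delivery recurses
#' along the chain; R's single-threaded evaluation serializes all handler
#' invocations, which satisfies the per-instance serialization contract.
#'
#' @return An environment of class `twin_broker`.
#' @export
broker_new <- function() {
  b <- new.env(parent = emptyenv())
  b$topics <- new.env(parent = emptyenv())
  class(b) <- "twin_broker"
  b
}

#' @export
print.twin_broker <- function(x, ...) {
  tps <- broker_topics(x)
  cat(sprintf("<twin_broker: %d topic(s)>\n", length(tps)))
  for (t in tps) cat(sprintf("  %-45s %d message(s)\n", t, topic_length(x, t)))
  invisible(x)
}

topic_env <- function(broker, topic, create = FALSE) {
  check_topic_name(topic)
  tl <- get0(topic, envir = broker$topics, inherits = FALSE)
  if (is.null(tl) && create) {
    tl <- new.env(parent = emptyenv())
    tl$entries <- list()
    tl$subscribers <- list()
    assign(topic, tl, envir = broker$topics)
  }
  tl
}

#' Publish a message to a topic
#'
#' Appends the message to the topic log and synchronously delivers it, in
#' offset order, to every attached subscriber.
#'
#' @param broker A [broker_new()] broker.
#' @param topic Topic name (`[A-Za-z0-9_]+`); created on first publish.
#' @param msg A [twin_message()]. Its `topic` field is rewritten to `topic`
#'   if it differs.
#' @return The zero-based offset at which the message was appended
#'   (invisibly a number, returned visibly).
#' @export
broker_publish <- function(broker, topic, msg) {
  stopifnot(inherits(broker, "twin_broker"), inherits(msg, "twin_message"))
  tl <- topic_env(broker, topic, create = TRUE)
  if (!identical(msg$topic, topic)) msg$topic <- topic
  # codec totality check at the boundary: a message we cannot serialize is
  # rejected before it enters the log
  as_payload(msg$payload)
  offset <- length(tl$entries)
  tl$entries[[offset + 1L]] <- msg
  for (sub in tl$subscribers) sub$handler(msg, offset)
  offset
}

#' Subscribe to a topic
#'
#' Attaches `handler` to the topic. History from `from_offset` onward is
#' replayed immediately (log semantics, not ephemeral pub/sub), then the
#' handler is invoked once per future publish, in offset order. Handlers
#' receive `(msg, offset)`; delivery is at-least-once with in-order replay,
#' so handlers should be idempotent per (topic, offset).
#'
#' @param broker A broker.
#' @param topic Topic name; created if absent.
#' @param handler Function of `(msg, offset)`.
#' @param from_offset First offset to deliver; must not exceed the current
#'   log length.
#' @return A subscription handle (list with `topic` and `id`), invisibly.
#' @export
broker_subscribe <- function(broker, topic, handler, from_offset = 0L) {
  stopifnot(inherits(broker, "twin_broker"), is.function(handler))
  tl <- topic_env(broker, topic, create = TRUE)
  n <- length(tl$entries)
  if (from_offset < 0 || from_offset > n) {
    stop(twin_error(sprintf(
      "from_offset %d out of range for topic %s (length %d)",
      from_offset, topic, n), "twin_range_error"))
  }
  id <- length(tl$subscribers) + 1L
  tl$subscribers[[id]] <- list(handler = handler)
  if (from_offset < n) {
    for (i in seq.int(from_offset + 1L, n)) handler(tl$entries[[i]], i - 1L)
  }
  invisible(list(topic = topic, id = id))
}

#' List topics present on a broker
#' @param broker A broker.
#' @return Character vector of topic names (sorted).
#' @export
broker_topics <- function(broker) sort(ls(broker$topics))

#' Number of messages in a topic
#' @param broker A broker.
#' @param topic Topic name.
#' @return Non-negative integer; 0 for unknown topics.
#' @export
topic_length <- function(broker, topic) {
  tl <- topic_env(broker, topic)
  if (is.null(tl)) 0L else length(tl$entries)
}

#' Messages of a topic
#' @param broker A broker.
#' @param topic Topic name.
#' @return List of [twin_message] in offset order (possibly empty).
#' @export
topic_messages <- function(broker, topic) {
  tl <- topic_env(broker, topic)
  if (is.null(tl)) list() else tl$entries
}

#' Dump a topic as JSON-lines
#'
#' One [encode_message()] JSON object per line; the on-disk format used by
#' [export_run()]. Replaying a dump through [decode_message()] reproduces
#' the topic byte-identically.
#'
#' @param broker A broker.
#' @param topic Topic name.
#' @return Character vector, one JSON line per message.
#' @export
topic_jsonl <- function(broker, topic) {
  vapply(topic_messages(broker, topic), encode_message, character(1))
}
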