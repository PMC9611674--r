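#' Wall-clock latency instrumentation
#'
#' Latency is the wall-clock time between publishing a sensor message and
#' reading the final model result at the end of the enriched chain.
#' Messages are matched by a correlation id carried in the payload
#' (`corr_id`, attached by [play()]); an id that never reaches the final
#' topic is counted as lost. Logical (scenario) time plays no role here:
#' latency is a property of the playback run, not of the models.
#'
#' @return `latency_tracker()`: an environment collecting publish and
#'   arrival times.
#' @export
latency_tracker <- function() {
  tr <- new.env(parent = emptyenv())
  tr$published <- new.env(parent = emptyenv())
  tr$received <- new.env(parent = emptyenv())
  tr$meta <- new.env(parent = emptyenv())
  class(tr) <- "latency_tracker"
  tr
}

now_ms <- function() as.numeric(Sys.time()) * 1000

#' @rdname latency_tracker
#' @param tr A `latency_tracker`.
#' @param key Correlation id.
#' @param shipment,model Labels attached to the record.
#' @export
latency_mark_publish <- function(tr, key, shipment = "", model = "") {
  assign(key, now_ms(), envir = tr$published)
  assign(key, c(shipment = shipment, model = model), envir = tr$meta)
  invisible(tr)
}

#' @rdname latency_tracker
#' @export
latency_mark_final <- function(tr, key, shipment = "", model = "") {
  if (is.null(get0(key, envir = tr$received, inherits = FALSE))) {
    assign(key, now_ms(), envir = tr$received)
    md <- get0(key, envir = tr$meta, inherits = FALSE)
    if (!is.null(md) && nzchar(model)) {
      md["model"] <- model
      assign(key, md, envir = tr$meta)
    }
  }
  invisible(tr)
}

#' Summarize end-to-end latencies
#'
#' @param tr A [latency_tracker()].
#' @return List with `records` (data.frame: key, shipment, model,
#'   latency_ms) and `summary` (data.frame: shipment, model, n, mean_ms,
#'   max_ms, lost).
#' @export
measure_latency <- function(tr) {
  keys <- ls(tr$published)
  if (!length(keys)) {
    rec <- data.frame(key = character(0), shipment = character(0),
                      model = character(0), latency_ms = numeric(0))
    smry <- data.frame(shipment = character(0), model = character(0),
                       n = integer(0), mean_ms = numeric(0),
                       max_ms = numeric(0), lost = integer(0))
    return(list(records = rec, summary = smry))
  }
  rec <- do.call(rbind, lapply(keys, function(k) {
    pub <- get(k, envir = tr$published)
    fin <- get0(k, envir = tr$received, inherits = FALSE)
    md <- get0(k, envir = tr$meta, inherits = FALSE)
    data.frame(key = k,
               shipment = if (is.null(md)) "" else unname(md["shipment"]),
               model = if (is.null(md)) "" else unname(md["model"]),
               latency_ms = if (is.null(fin)) NA_real_ else fin - pub)
  }))
  smry <- do.call(rbind, lapply(split(rec, rec$shipment), function(g) {
    ok <- g$latency_ms[!is.na(g$latency_ms)]
    data.frame(shipment = g$shipment[1],
               model = g$model[which(nzchar(g$model))[1]],
               n = length(ok),
               mean_ms = if (length(ok)) mean(ok) else NA_real_,
               max_ms = if (length(ok)) max(ok) else NA_real_,
               lost = sum(is.na(g$latency_ms)))
  }))
  rownames(smry) <- NULL
  list(records = rec, summary = smry)
}
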