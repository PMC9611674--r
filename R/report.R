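#' Framework invariants of a finished run
#'
#' Three structural properties hold for every run of the wrapper
#' framework, whatever the models compute:
#'
#' * **stream continuity** -- every instance publishes exactly one output
#'   message per input message, so all topics of a shipment's chain have
#'   equal length;
#' * **enrichment conservation** -- the input payload of every message is
#'   a subset of the corresponding output payload, values unchanged
#'   (models only ever append namespaced fields);
#' * **phase legality** -- `step()` is only ever invoked in the ACTIVE
#'   phase and `collect()` only in COLLECTING, verified against the
#'   instrumented call log.
#'
#' `check_run()` evaluates all three over a runtime after playback.
#'
#' @param rt A [twin_runtime()] after a run.
#' @return List with logical flags `continuity`, `enrichment`,
#'   `phase_legality`, `ok`, and a `detail` data.frame per instance.
#' @export
check_run <- function(rt) {
  insts <- runtime_instances(rt)
  detail <- do.call(rbind, lapply(names(insts), function(key) {
    inst <- insts[[key]]
    n_in <- topic_length(rt$broker, inst$binding$topic_in)
    n_out <- topic_length(rt$broker, inst$binding$topic_out)
    enr <- check_enrichment_instance(rt$broker, inst)
    calls <- inst$call_log
    bad_calls <- sum(vapply(calls, function(cl) {
      (cl$fn == "step" && cl$phase != "ACTIVE") ||
        (cl$fn == "collect" && cl$phase != "COLLECTING") ||
        (cl$fn == "predict" && cl$phase != "ACTIVE")
    }, logical(1)))
    data.frame(instance = key, n_in = n_in, n_out = n_out,
               continuity = n_in == n_out, enrichment = enr,
               illegal_calls = bad_calls)
  }))
  if (is.null(detail)) {
    detail <- data.frame(instance = character(0), n_in = integer(0),
                         n_out = integer(0), continuity = logical(0),
                         enrichment = logical(0), illegal_calls = integer(0))
  }
  res <- list(continuity = all(detail$continuity),
              enrichment = all(detail$enrichment),
              phase_legality = all(detail$illegal_calls == 0L),
              detail = detail)
  res$ok <- res$continuity && res$enrichment && res$phase_legality
  res
}

# input payload must be a subset of the output payload, values unchanged
check_enrichment_instance <- function(broker, inst) {
  ins <- topic_messages(broker, inst$binding$topic_in)
  outs <- topic_messages(broker, inst$binding$topic_out)
  n <- min(length(ins), length(outs))
  for (i in seq_len(n)) {
    pin <- ins[[i]]$payload
    pout <- outs[[i]]$payload
    if (length(setdiff(names(pin), names(pout)))) return(FALSE)
    for (k in names(pin)) {
      if (!identical(pin[[k]], pout[[k]])) return(FALSE)
    }
  }
  TRUE
}
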