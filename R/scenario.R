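#' Specify a synthetic banana-chain scenario
#'
#' The generator emulates the four phases of the banana cool chain:
#' *Packing* (boxes loaded warm, no cooling), *Transport* (cooling toward
#' the supply-air setpoint during the ocean voyage), *Harbor* (cooling
#' interrupted, slow drift toward ambient) and *Ripening* (cooling
#' resumed while starch-to-sugar conversion releases heat). The defaults
#' describe a plausible reference voyage -- loading at 26 degrees C, a
#' 13.2 degrees C setpoint, a 14-day transport, a 12-hour harbor gap and
#' 4 days of ripening at 0.3 K/h heat release -- and are synthetic study
#' conditions, not measurements (the setpoint range 13.0-14.4 degrees C
#' is the one used in practice for bananas).
#'
#' @param shipment_ids Character vector of shipment numbers
#'   (`[A-Za-z0-9]+`).
#' @param t_packing,t_transport,t_harbor,t_ripening Phase start hours
#'   (strictly increasing).
#' @param t_end End of the scenario, hours.
#' @param T_load Initial box temperature at packing, degrees C.
#' @param setpoint Supply-air setpoint during cooling, degrees C (the
#'   customary banana range is 13.0-14.4).
#' @param true_k_M Cooling-efficiency constant used to generate the box
#'   temperature, 1/h.
#' @param ripening_q Heat-release rate during ripening, K/h.
#' @param ambient Ambient temperature during packing/harbor, degrees C.
#' @param harbor_k Relaxation rate toward ambient while cooling is off, 1/h.
#' @param supply_noise,box_noise Gaussian noise standard deviations on the
#'   published supply and box temperatures, K.
#' @param sampling Sampling interval, hours.
#' @param queries List of queries, each a list with `at` (hour) and
#'   optional override fields `setpoint` or `setpoint_delta` (degrees C).
#'   Queries are typically scheduled 1.5-4 days after transport start,
#'   once enough data for the parameter estimate has accumulated.
#' @param seed Integer seed fixing all noise draws.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(shipment_ids = "4711",
                          t_packing = 0, t_transport = 6, t_harbor = 342,
                          t_ripening = 354, t_end = 450,
                          T_load = 26, setpoint = 13.2, true_k_M = 0.05,
                          ripening_q = 0.3, ambient = 18, harbor_k = 0.02,
                          supply_noise = 0.05, box_noise = 0.05,
                          sampling = 1, queries = list(), seed = 1L) {
  starts <- c(t_packing, t_transport, t_harbor, t_ripening, t_end)
  if (any(diff(starts) <= 0)) {
    stop(twin_error("phase start hours must be strictly increasing",
                    "twin_scenario_error"))
  }
  if (!all(grepl("^[A-Za-z0-9]+$", shipment_ids))) {
    stop(twin_error("shipment ids must match [A-Za-z0-9]+",
                    "twin_scenario_error"))
  }
  structure(list(shipment_ids = shipment_ids, t_packing = t_packing,
                 t_transport = t_transport, t_harbor = t_harbor,
                 t_ripening = t_ripening, t_end = t_end, T_load = T_load,
                 setpoint = setpoint, true_k_M = true_k_M,
                 ripening_q = ripening_q, ambient = ambient,
                 harbor_k = harbor_k, supply_noise = supply_noise,
                 box_noise = box_noise, sampling = sampling,
                 queries = queries, seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Read a scenario specification from YAML
#' @param path Path to a YAML file whose keys are [scenario_spec()]
#'   arguments.
#' @return A `scenario_spec`.
#' @export
read_scenario <- function(path) {
  doc <- yaml::yaml.load_file(path)
  if (is.null(doc)) doc <- list()
  known <- names(formals(scenario_spec))
  unknown <- setdiff(names(doc), known)
  if (length(unknown)) {
    stop(twin_error(sprintf("unknown scenario key(s): %s",
                            paste(unknown, collapse = ", ")),
                    "twin_scenario_error"))
  }
  do.call(scenario_spec, doc)
}

scenario_phase <- function(spec, t) {
  if (t >= spec$t_ripening) "Ripening"
  else if (t >= spec$t_harbor) "Harbor"
  else if (t >= spec$t_transport) "Transport"
  else "Packing"
}

#' Build the message list of a scenario
#'
#' Simulates the box temperature with [cool_step()] under the true
#' parameters (relaxation toward ambient while cooling is off during
#' packing and harbor handling) and produces, per shipment, the full
#' ordered event list: one `SENSOR` message per sampling interval
#' (payload `T_Box`, `T_Supply`), `LIFECYCLE` messages
#' (`Start_Transport`, `Arrive_Transport`, `Start_Ripening`,
#' `Stop_Ripening`) at the phase boundaries, and `QUERY` messages at the
#' scheduled hours with `arrival_time` set to the harbor arrival. At
#' equal timestamps life-cycle events precede the sensor sample and
#' queries follow it. All noise is drawn from `spec$seed`, so the same
#' spec always yields a byte-identical message list; the caller's RNG
#' state is left untouched.
#'
#' @param spec A [scenario_spec()].
#' @return List of [twin_message], globally ordered by timestamp (ties
#'   broken by shipment order and event priority), each addressed to its
#'   shipment's [sensor_topic()].
#' @export
build_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  msgs <- list()
  for (si in seq_along(spec$shipment_ids)) {
    sid <- spec$shipment_ids[si]
    topic <- sensor_topic(sid)
    times <- seq(spec$t_packing, spec$t_end, by = spec$sampling)
    n <- length(times)
    supply <- numeric(n)
    box <- numeric(n)
    T_true <- spec$T_load
    for (i in seq_len(n)) {
      t <- times[i]
      phase <- scenario_phase(spec, t)
      cooling_on <- phase %in% c("Transport", "Ripening")
      supply[i] <- if (cooling_on) {
        spec$setpoint + spec$supply_noise * stats::rnorm(1)
      } else {
        spec$ambient + spec$supply_noise * stats::rnorm(1)
      }
      box[i] <- T_true + spec$box_noise * stats::rnorm(1)
      # advance the true state over [t, t + sampling) using this phase
      if (i < n) {
        if (cooling_on) {
          q <- if (phase == "Ripening") spec$ripening_q else 0
          # the published sample is the state the next step builds on:
          # sensor noise acts as a small process disturbance, so the
          # measured series itself obeys the model recursion and noiseless
          # runs are exactly identifiable
          T_true <- cool_step(box[i], supply[i], spec$true_k_M, q,
                              spec$sampling)
        } else if (phase == "Harbor") {
          T_true <- box[i] + spec$sampling * spec$harbor_k *
            (spec$ambient - box[i])
        } else {
          T_true <- box[i]
        }
      }
    }
    ship <- list()
    add <- function(m, prio) {
      m$.prio <- prio
      ship[[length(ship) + 1L]] <<- m
    }
    events <- c(Start_Transport = spec$t_transport,
                Arrive_Transport = spec$t_harbor,
                Start_Ripening = spec$t_ripening,
                Stop_Ripening = spec$t_end)
    for (ev in names(events)) {
      add(twin_message(topic, events[[ev]], sid, "LIFECYCLE",
                       list(event = ev)), 0L)
    }
    for (i in seq_len(n)) {
      add(twin_message(topic, times[i], sid, "SENSOR",
                       list(T_Box = box[i], T_Supply = supply[i])), 1L)
    }
    for (qi in seq_along(spec$queries)) {
      qry <- spec$queries[[qi]]
      payload <- list(arrival_time = spec$t_harbor,
                      query_id = sprintf("%s_q%02d", sid, qi))
      for (k in intersect(names(qry), c("setpoint", "setpoint_delta",
                                        "arrival_time"))) {
        payload[[k]] <- qry[[k]]
      }
      add(twin_message(topic, qry[["at"]], sid, "QUERY", payload), 2L)
    }
    ord <- order(vapply(ship, function(m) m$timestamp, numeric(1)),
                 vapply(ship, function(m) m$.prio, integer(1)))
    ship <- lapply(ship[ord], function(m) { m$.prio <- NULL; m })
    msgs[[si]] <- ship
  }
  # global interleave: timestamp, then shipment order
  flat <- do.call(c, msgs)
  ship_idx <- rep(seq_along(msgs), lengths(msgs))
  within_idx <- unlist(lapply(lengths(msgs), seq_len))
  ord <- order(vapply(flat, function(m) m$timestamp, numeric(1)),
               ship_idx, within_idx)
  flat[ord]
}

#' Play a scenario into a broker
#'
#' Publishes every message to its topic in list order. The default
#' `"fast"` mode runs as fast as possible and is fully deterministic;
#' `"wallclock"` mode paces publishes so that each shipment emits
#' `speed` messages per second (hourly samples played back strongly
#' accelerated). A `corr_id` payload field is attached to every message
#' for end-to-end latency correlation; pass `final_topics` to have
#' arrivals recorded at the end of each shipment's chain.
#'
#' @param messages List of [twin_message] (from [build_scenario()]).
#' @param broker A broker.
#' @param speed Messages per second per shipment (wallclock mode).
#' @param mode `"fast"` (as fast as possible) or `"wallclock"`.
#' @param final_topics Named character vector: shipment id -> final topic
#'   of its chain (optional; enables latency measurement).
#' @return Playback report: list with `published` (count), `topics`
#'   (data.frame topic/count), and `latency` (see [measure_latency()]).
#' @export
play <- function(messages, broker, speed = 10, mode = c("fast", "wallclock"),
                 final_topics = NULL) {
  mode <- match.arg(mode)
  tracker <- latency_tracker()
  if (!is.null(final_topics)) {
    for (sid in names(final_topics)) {
      local({
        topic <- final_topics[[sid]]
        broker_subscribe(broker, topic, function(m, offset) {
          cid <- m$payload[["corr_id"]]
          if (!is.null(cid)) latency_mark_final(tracker, cid, m$shipment_id,
                                                model = topic)
        })
      })
    }
  }
  n_ship <- max(1L, length(unique(vapply(messages, function(m) m$shipment_id,
                                         character(1)))))
  pace <- 1 / (speed * n_ship)
  for (i in seq_along(messages)) {
    m <- messages[[i]]
    m$payload$corr_id <- sprintf("c%06d", i)
    latency_mark_publish(tracker, m$payload$corr_id, m$shipment_id)
    if (mode == "wallclock") Sys.sleep(pace)
    broker_publish(broker, m$topic, m)
  }
  topics <- broker_topics(broker)
  list(published = length(messages),
       topics = data.frame(topic = topics,
                           count = vapply(topics, topic_length,
                                          numeric(1), broker = broker),
                           row.names = NULL),
       latency = measure_latency(tracker))
}

#' Export topics of a finished run
#'
#' Writes every topic as JSON-lines (`<topic>.jsonl`, one
#' [encode_message()] object per line) and as a tidy CSV (`<topic>.csv`,
#' one row per message, one column per payload field; array-valued fields
#' are serialized as JSON strings in their cell).
#'
#' @param broker A broker.
#' @param topics Topic names to export (default: all).
#' @param path Output directory (created if missing).
#' @return Character vector of written file paths, invisibly.
#' @export
export_run <- function(broker, topics = broker_topics(broker), path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (topic in topics) {
    msgs <- topic_messages(broker, topic)
    jl <- file.path(path, paste0(topic, ".jsonl"))
    writeLines(vapply(msgs, encode_message, character(1)), jl)
    cols <- unique(unlist(lapply(msgs, function(m) names(m$payload))))
    rows <- lapply(msgs, function(m) {
      base <- list(timestamp = m$timestamp, shipment_id = m$shipment_id,
                   kind = m$kind)
      for (k in cols) {
        v <- m$payload[[k]]
        base[[k]] <- if (is.null(v)) NA
        else if (length(v) != 1L) as.character(jsonlite::toJSON(v, digits = NA))
        else v
      }
      as.data.frame(base, check.names = FALSE, stringsAsFactors = FALSE)
    })
    df <- if (length(rows)) do.call(rbind, rows)
    else data.frame(timestamp = numeric(0), shipment_id = character(0),
                    kind = character(0))
    cs <- file.path(path, paste0(topic, ".csv"))
    utils::write.csv(df, cs, row.names = FALSE)
    written <- c(written, jl, cs)
  }
  invisible(written)
}
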