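# shared fixtures: scenario specs and small oracles, all built in code

banana_config_path <- function() {
  system.file("extdata", "banana_config.yaml", package = "cooltwin")
}

ripening_snippet_path <- function() {
  system.file("extdata", "ripening_snippet.yaml", package = "cooltwin")
}

# reference voyage, optionally noise-free
reference_spec <- function(noise = 0.05, queries = list(), seed = 1L,
                           shipment_ids = "4711") {
  scenario_spec(shipment_ids = shipment_ids,
                t_packing = 0, t_transport = 6, t_harbor = 342,
                t_ripening = 354, t_end = 450,
                T_load = 26, setpoint = 13.2, true_k_M = 0.05,
                ripening_q = 0.3, supply_noise = noise, box_noise = noise,
                queries = queries, seed = seed)
}

# compressed voyage: ~100 messages per shipment (load-test shape)
small_spec <- function(shipment_ids = sprintf("S%02d", 1:10), noise = 0.05,
                       queries = list(), seed = 7L) {
  scenario_spec(shipment_ids = shipment_ids,
                t_packing = 0, t_transport = 4, t_harbor = 72,
                t_ripening = 78, t_end = 96,
                T_load = 26, setpoint = 13.2, true_k_M = 0.05,
                ripening_q = 0.3, supply_noise = noise, box_noise = noise,
                queries = queries, seed = seed)
}

run_spec <- function(spec, config = banana_config_path(),
                     cargo_type = "Bananas") {
  schemas <- read_config(config)
  broker <- broker_new()
  rt <- twin_runtime(broker, params = attr(schemas, "params"))
  start_handlers(rt, unique(unlist(lapply(schemas, names))))
  for (sid in spec$shipment_ids) {
    announce_plan(instantiate_plan(cargo_type, sid, schemas), broker)
  }
  report <- play(build_scenario(spec), broker)
  list(broker = broker, runtime = rt, report = report, spec = spec)
}

final_topic <- function(sid) paste0("Transports_Shipment_", sid, "_GreenLife")

# hindsight green-life reference: stream the measured box temperatures
# through the same accumulator the wrapper uses (first sample anchors)
gl_hindsight <- function(msgs, sid, t_from, t_to, p = green_life_params()) {
  st <- green_life_state(p)
  last_t <- NULL
  for (m in msgs) {
    if (m$kind != "SENSOR" || m$shipment_id != sid) next
    if (m$timestamp < t_from || m$timestamp > t_to) next
    dt <- if (is.null(last_t)) 0 else m$timestamp - last_t
    st <- green_life_update(st, m$payload$T_Box, dt)
    last_t <- m$timestamp
  }
  st
}

# last value of an enriched field among SENSOR messages at or before t
stream_field_at <- function(msgs, field, t = Inf) {
  val <- NULL
  for (m in msgs) {
    if (m$kind == "SENSOR" && m$timestamp <= t && !is.null(m$payload[[field]])) {
      val <- m$payload[[field]]
    }
  }
  val
}

query_answers <- function(broker, sid) {
  Filter(function(m) m$kind == "QUERY",
         topic_messages(broker, final_topic(sid)))
}
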