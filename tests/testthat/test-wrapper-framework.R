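# standalone instance on a fresh broker, dispatched to directly
make_instance <- function(wrapper, lct = c(Start_Transport = "Start_Collect",
                                           Arrive_Transport = "Stop_Collect",
                                           Start_Ripening = "Start_Model",
                                           Stop_Ripening = "Stop_Model"),
                          sid = "T1", max_fill = 48L) {
  lines <- c("X:", "  M:",
             "    Topic_In: Transports_Shipment_#ID_Sensors",
             "    Topic_Out: Transports_Shipment_#ID_Out",
             "    LifeCycleTranslate:",
             sprintf("      %s: %s", names(lct), lct))
  plan <- instantiate_plan("X", sid, parse_config(lines))
  broker <- broker_new()
  inst <- wrapper_instance(plan$bindings$M, wrapper, broker,
                           max_fill = max_fill)
  inst$shipment_id <- sid
  inst
}

sensor <- function(t, T_Box = 20, T_Supply = 13.2, sid = "T1", extra = list()) {
  twin_message(sensor_topic(sid), t, sid, "SENSOR",
               c(list(T_Box = T_Box, T_Supply = T_Supply), extra))
}

lifecycle <- function(t, event, sid = "T1") {
  twin_message(sensor_topic(sid), t, sid, "LIFECYCLE", list(event = event))
}

step_count <- function(inst) {
  sum(vapply(inst$call_log, function(cl) cl$fn == "step", logical(1)))
}

test_that("handlers filter announcements by model name and deduplicate", {
  broker <- broker_new()
  rt <- twin_runtime(broker)
  register_handler(rt, "RipeningModel", ripe_heat_wrapper)
  ann <- function(model) {
    twin_message("Model_Config", 0, "9", "MODEL_CONFIG",
                 list(model_name = model, cargo_type = "Bananas",
                      shipment_id = "9",
                      topic_in = "Transports_Shipment_9_CoolPara",
                      topic_out = "Transports_Shipment_9_RipePara",
                      lifecycle_events = "Start_Ripening",
                      lifecycle_commands = "Start_Model"))
  }
  broker_publish(broker, "Model_Config", ann("GreenLifeModel"))
  expect_length(runtime_instances(rt), 0)
  broker_publish(broker, "Model_Config", ann("RipeningModel"))
  insts <- runtime_instances(rt)
  expect_length(insts, 1)
  expect_equal(insts[[1]]$phase, "WAITING")
  broker_publish(broker, "Model_Config", ann("RipeningModel"))
  expect_length(runtime_instances(rt), 1)
  # unknown model types without a factory are a wiring error
  expect_error(start_handlers(rt, "UnheardOfModel"),
               class = "twin_wiring_error")
})

test_that("life-cycle commands drive the phase machine, illegal ones are logged", {
  inst <- make_instance(ripe_heat_wrapper())
  expect_equal(inst$phase, "WAITING")
  # Stop_Collect is illegal in WAITING: logged, state unchanged
  dispatch(inst, lifecycle(1, "Arrive_Transport"))
  expect_equal(inst$phase, "WAITING")
  expect_true(any(instance_log(inst)$event == "illegal_command"))

  dispatch(inst, lifecycle(2, "Start_Transport"))
  expect_equal(inst$phase, "COLLECTING")
  dispatch(inst, lifecycle(3, "Arrive_Transport"))
  expect_equal(inst$phase, "ARMED")
  dispatch(inst, lifecycle(4, "Start_Ripening"))
  expect_equal(inst$phase, "ACTIVE")
  dispatch(inst, lifecycle(5, "Stop_Ripening"))
  expect_equal(inst$phase, "STOPPED")

  # shortcut WAITING -> ACTIVE (collector phase omitted)
  inst2 <- make_instance(green_life_wrapper(),
                         lct = c(Start_Transport = "Start_Model"))
  dispatch(inst2, lifecycle(0, "Start_Transport"))
  expect_equal(inst2$phase, "ACTIVE")
  # shortcut COLLECTING -> STOPPED
  inst3 <- make_instance(ripe_heat_wrapper())
  dispatch(inst3, lifecycle(0, "Start_Transport"))
  dispatch(inst3, lifecycle(1, "Stop_Ripening"))
  expect_equal(inst3$phase, "STOPPED")
  # unmapped events are silently ignored
  inst4 <- make_instance(ripe_heat_wrapper())
  dispatch(inst4, lifecycle(0, "Door_Opened"))
  expect_equal(inst4$phase, "WAITING")
  expect_false(any(instance_log(inst4)$event == "illegal_command"))
})

test_that("non-active instances forward every message as a pure copy", {
  inst <- make_instance(green_life_wrapper(),
                        lct = c(Start_Transport = "Start_Model"))
  msg <- sensor(1, extra = list(note = "raw"))
  dispatch(inst, msg)
  out <- topic_messages(inst$broker, inst$binding$topic_out)
  expect_length(out, 1)
  expect_identical(out[[1]]$payload, msg$payload)
  expect_equal(out[[1]]$timestamp, msg$timestamp)
  expect_equal(step_count(inst), 0)
})

test_that("collecting instances count every sample and start the model armed", {
  inst <- make_instance(ripe_heat_wrapper())
  dispatch(inst, lifecycle(0, "Start_Transport"))
  for (t in 1:72) {
    dispatch(inst, sensor(t, extra = list(`CoolIdent.k_M` = 0.05)))
  }
  expect_equal(inst$collected, 72L)
  n_collect <- sum(vapply(inst$call_log, function(cl) cl$fn == "collect",
                          logical(1)))
  expect_equal(n_collect, 72L)
  dispatch(inst, lifecycle(73, "Arrive_Transport"))
  dispatch(inst, lifecycle(74, "Start_Ripening"))
  expect_equal(inst$phase, "ACTIVE")
  # every input so far produced exactly one output (stream continuity)
  expect_equal(topic_length(inst$broker, inst$binding$topic_out), 75L)
})

test_that("enrichment appends namespaced fields and conserves the input", {
  inst <- make_instance(green_life_wrapper(),
                        lct = c(Start_Transport = "Start_Model"))
  dispatch(inst, lifecycle(0, "Start_Transport"))
  msg <- sensor(1, T_Box = 14.0)
  dispatch(inst, msg)
  out <- topic_messages(inst$broker, inst$binding$topic_out)[[2]]
  expect_true(all(names(msg$payload) %in% names(out$payload)))
  expect_identical(out$payload$T_Box, msg$payload$T_Box)
  expect_true("GreenLife.remaining" %in% names(out$payload))
})

test_that("interval classification is total over OK, GAP and REJECT", {
  expect_equal(check_interval(10, 11, 1, 0.1), "OK")
  expect_equal(check_interval(10, 11.05, 1, 0.1), "OK")
  expect_equal(check_interval(10, 13, 1, 0.1), "GAP")
  expect_equal(check_interval(10, 10, 1, 0.1), "REJECT")
  expect_equal(check_interval(10, 9.5, 1, 0.1), "REJECT")
  expect_equal(check_interval(10, 10.5, 1, 0.1), "REJECT")
})

test_that("gaps are filled with the last known sample, up to max_fill", {
  inst <- make_instance(green_life_wrapper(),
                        lct = c(Start_Transport = "Start_Model"))
  dispatch(inst, lifecycle(0, "Start_Transport"))
  dispatch(inst, sensor(0, T_Box = 13))
  dispatch(inst, sensor(1, T_Box = 13))
  expect_equal(step_count(inst), 2)
  # a 3 h jump at nominal 1 h: two synthetic steps plus the real one
  dispatch(inst, sensor(4, T_Box = 13))
  expect_equal(step_count(inst), 5)
  # gap of exactly one nominal interval: no synthetic steps
  dispatch(inst, sensor(5, T_Box = 13))
  expect_equal(step_count(inst), 6)
  # 13 degrees C is the reference: 5 integrated hours consume 5/24 days
  expect_equal(inst$wrapper$state$gl$D, 5 / 24, tolerance = 1e-12)

  # a 200 h outage exceeds max_fill = 48: error logged, state kept
  dispatch(inst, sensor(205, T_Box = 13))
  expect_equal(step_count(inst), 6)
  expect_true(any(instance_log(inst)$event == "data_outage"))
  expect_equal(inst$wrapper$state$gl$D, 5 / 24, tolerance = 1e-12)
  # processing resumes on the next in-interval sample
  dispatch(inst, sensor(206, T_Box = 13))
  expect_equal(step_count(inst), 7)
  expect_equal(inst$wrapper$state$gl$D, 6 / 24, tolerance = 1e-12)
})

test_that("rejected samples are forwarded but not processed", {
  inst <- make_instance(green_life_wrapper(),
                        lct = c(Start_Transport = "Start_Model"))
  dispatch(inst, lifecycle(0, "Start_Transport"))
  dispatch(inst, sensor(1, T_Box = 13))
  dispatch(inst, sensor(1, T_Box = 99))    # duplicate timestamp
  expect_equal(step_count(inst), 1)
  expect_true(any(instance_log(inst)$event == "sample_rejected"))
  # stream continuity holds regardless
  expect_equal(topic_length(inst$broker, inst$binding$topic_out), 3L)
})

test_that("queries are answered in ACTIVE with an hourly array until arrival", {
  inst <- make_instance(cool_predict_wrapper(),
                        lct = c(Start_Transport = "Start_Model"))
  q <- function(t, arrival) {
    twin_message(sensor_topic("T1"), t, "T1", "QUERY",
                 c(list(arrival_time = arrival, `CoolIdent.k_M` = 0.05)))
  }
  # query in a non-active phase is forwarded untouched, with a notice
  dispatch(inst, q(10, 336))
  out <- topic_messages(inst$broker, inst$binding$topic_out)
  expect_false("CoolPredict.prediction" %in% names(out[[1]]$payload))
  expect_true(any(instance_log(inst)$event == "query_ignored"))

  dispatch(inst, lifecycle(20, "Start_Transport"))
  for (t in 21:72) dispatch(inst, sensor(t, T_Box = 20 - 0.1 * t))
  dispatch(inst, q(72, 336))
  out <- topic_messages(inst$broker, inst$binding$topic_out)
  ans <- out[[length(out)]]$payload
  expect_length(ans[["CoolPredict.prediction"]], 264)   # 336 - 72 hours

  # horizon 0: empty array, no error
  dispatch(inst, q(73, 73))
  out <- topic_messages(inst$broker, inst$binding$topic_out)
  expect_length(out[[length(out)]]$payload[["CoolPredict.prediction"]], 0)

  # missing arrival time: error field on the output topic
  bad <- twin_message(sensor_topic("T1"), 74, "T1", "QUERY", list())
  dispatch(inst, bad)
  out <- topic_messages(inst$broker, inst$binding$topic_out)
  expect_equal(out[[length(out)]]$payload[["CoolPredict.error"]],
               "missing arrival_time")
})

test_that("latency tracking pairs publishes with finals and counts losses", {
  tr <- latency_tracker()
  for (i in 1:100) {
    latency_mark_publish(tr, sprintf("c%03d", i), shipment = "S1")
  }
  for (i in 1:99) {
    latency_mark_final(tr, sprintf("c%03d", i), model = "chain_end")
  }
  res <- measure_latency(tr)
  expect_equal(nrow(res$records), 100)
  expect_equal(res$summary$n, 99)
  expect_equal(res$summary$lost, 1)
  ok <- res$records$latency_ms[!is.na(res$records$latency_ms)]
  expect_equal(res$summary$mean_ms, mean(ok))
  expect_true(all(ok >= 0))
})
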