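#' Specific wrappers of the banana cool chain
#'
#' The default model chain for cargo type `Bananas` consists of four
#' models, each behind its own wrapper, chained through enriched topics:
#'
#' 1. **CoolIdentModel** (`CoolIdent.*`) estimates the cooling-efficiency
#'    constant `k_M` from consecutive box/supply temperature pairs while
#'    cooling is running; adds `CoolIdent.k_M` and `CoolIdent.stable`.
#' 2. **RipeningModel** (`RipeHeat.*`) collects the `k_M` estimates during
#'    transport and, once ripening starts, observes the hidden
#'    ripening-heat rate; adds `RipeHeat.q` (smoothed, clipped at 0) and
#'    `RipeHeat.q_raw`.
#' 3. **CoolPredictModel** (`CoolPredict.*`) answers prediction queries
#'    with an hourly temperature array until the estimated arrival,
#'    assuming the supply air stays at the average of the recent readings
#'    (plus a second array for what-if setpoint overrides).
#' 4. **GreenLifeModel** (`GreenLife.*`) integrates the Q10 green-life
#'    dose over the measured box temperature and, on queries, combines the
#'    accumulated dose with the predicted temperature array.
#'
#' `banana_factories()` returns the factory map used by
#' [start_handlers()]; each factory takes the model's entry of the
#' configuration's `models:` section (or `NULL` for all defaults).
#'
#' @param params Named list of model parameters (see the individual
#'   factories for recognized keys), or `NULL`.
#' @return A specific wrapper ([specific_wrapper]); for
#'   `banana_factories()`, a named list of factories.
#' @name banana_wrappers
NULL

pget <- function(params, key, default) {
  v <- params[[key]]
  if (is.null(v)) default else v
}

#' @rdname banana_wrappers
#' @export
banana_factories <- function() {
  list(CoolIdentModel = cool_ident_wrapper,
       RipeningModel = ripe_heat_wrapper,
       CoolPredictModel = cool_predict_wrapper,
       GreenLifeModel = green_life_wrapper)
}

## ---- CoolIdent -----------------------------------------------------------

#' @rdname banana_wrappers
#' @export
cool_ident_wrapper <- function(params = NULL) {
  w <- new_specific_wrapper("cool_ident_wrapper", "CoolIdent",
                            required_fields = c("T_Box", "T_Supply"),
                            nominal_interval = pget(params, "nominal_interval", 1),
                            interval_tolerance = pget(params, "interval_tolerance", 0.1))
  w$state$est <- km_state(stable_hours = pget(params, "stable_hours", 72),
                          spread_tol = pget(params, "spread_tol", 0.02),
                          window = pget(params, "window", 24))
  w$state$prev <- NULL
  w
}

#' @export
sw_step.cool_ident_wrapper <- function(w, payload, t, dt) {
  cur <- list(t = t, T_Box = payload$T_Box, T_Supply = payload$T_Supply)
  if (!is.null(w$state$prev)) {
    w$state$est <- km_update(w$state$est, w$state$prev, cur)
  }
  w$state$prev <- cur
  est <- w$state$est
  if (is.na(est$k_hat)) return(NULL)   # output postponed until identifiable
  list(k_M = est$k_hat, stable = est$stable)
}

#' @export
sw_predict.cool_ident_wrapper <- function(w, payload, t, horizon,
                                          overrides = list()) {
  # a query reads the interim estimate; a later query reads a better one
  est <- w$state$est
  if (is.na(est$k_hat)) return(NULL)
  list(k_M = est$k_hat, stable = est$stable)
}

## ---- RipeHeat ------------------------------------------------------------

#' @rdname banana_wrappers
#' @export
ripe_heat_wrapper <- function(params = NULL) {
  w <- new_specific_wrapper("ripe_heat_wrapper", "RipeHeat",
                            required_fields = c("T_Box", "T_Supply"),
                            nominal_interval = pget(params, "nominal_interval", 1),
                            interval_tolerance = pget(params, "interval_tolerance", 0.1))
  w$state$k <- NULL
  w$state$n_collected <- 0L
  w$state$prev <- NULL
  w$state$raw <- numeric(0)
  w$state$smooth_window <- pget(params, "smooth_window", 5L)
  w
}

#' @export
sw_collect.ripe_heat_wrapper <- function(w, payload, t) {
  k <- payload[["CoolIdent.k_M"]]
  if (!is.null(k)) {
    w$state$k <- k
    w$state$n_collected <- w$state$n_collected + 1L
  }
  NULL
}

#' @export
sw_step.ripe_heat_wrapper <- function(w, payload, t, dt) {
  if (is.null(w$state$k)) {
    # fall back to the live stream value if the collector phase was skipped
    k <- payload[["CoolIdent.k_M"]]
    if (is.null(k)) {
      stop(twin_error(
        "no k_M available: RipeningModel must run downstream of CoolIdent",
        "twin_wiring_error"))
    }
    w$state$k <- k
  }
  cur <- list(t = t, T_Box = payload$T_Box, T_Supply = payload$T_Supply)
  if (is.null(w$state$prev)) {
    w$state$prev <- cur
    return(NULL)
  }
  raw <- ripening_heat(w$state$k, w$state$prev, cur)
  w$state$prev <- cur
  w$state$raw <- c(w$state$raw, raw)
  win <- w$state$smooth_window
  smoothed <- mean(utils::tail(w$state$raw, win))
  result <- list(q = max(0, smoothed), q_raw = raw)
  if (smoothed < 0) {
    attr(result, "notice") <- sprintf(
      "smoothed ripening heat %.4f K/h clipped to 0", smoothed)
  }
  result
}

## ---- CoolPredict ---------------------------------------------------------

#' @rdname banana_wrappers
#' @export
cool_predict_wrapper <- function(params = NULL) {
  w <- new_specific_wrapper("cool_predict_wrapper", "CoolPredict",
                            required_fields = c("T_Box", "T_Supply"),
                            nominal_interval = pget(params, "nominal_interval", 1),
                            interval_tolerance = pget(params, "interval_tolerance", 0.1))
  w$state$last_T_Box <- NULL
  w$state$supply_hist <- numeric(0)
  w$state$supply_window <- pget(params, "supply_window", 24L)
  w$state$chilling_floor <- pget(params, "chilling_floor", 12.5)
  w$state$last_k <- NULL
  w$state$query_count <- 0L
  w
}

#' @export
sw_step.cool_predict_wrapper <- function(w, payload, t, dt) {
  w$state$last_T_Box <- payload$T_Box
  w$state$supply_hist <- utils::tail(c(w$state$supply_hist, payload$T_Supply),
                                     w$state$supply_window)
  k <- payload[["CoolIdent.k_M"]]
  if (!is.null(k)) w$state$last_k <- k
  NULL   # per-sample pass-through; output only on queries
}

#' @export
sw_predict.cool_predict_wrapper <- function(w, payload, t, horizon,
                                            overrides = list()) {
  k <- payload[["CoolIdent.k_M"]]
  if (is.null(k)) k <- w$state$last_k
  if (is.null(k)) return(list(error = "no cooling estimate available yet"))
  if (is.null(w$state$last_T_Box)) {
    return(list(error = "no box temperature observed yet"))
  }
  if (!length(w$state$supply_hist)) {
    return(list(error = "no supply temperature observed yet"))
  }
  supply_base <- mean(w$state$supply_hist)
  w$state$query_count <- w$state$query_count + 1L
  query_id <- payload[["query_id"]]
  if (is.null(query_id)) query_id <- sprintf("q%03d", w$state$query_count)
  result <- list(
    prediction = predict_temperature(w$state$last_T_Box, supply_base, k, horizon),
    supply_assumed = supply_base,
    query_id = query_id)
  supply_mod <- overrides[["setpoint"]]
  if (is.null(supply_mod) && !is.null(overrides[["setpoint_delta"]])) {
    supply_mod <- supply_base + overrides[["setpoint_delta"]]
  }
  if (!is.null(supply_mod)) {
    result$prediction_whatif <-
      predict_temperature(w$state$last_T_Box, supply_mod, k, horizon)
    result$supply_whatif <- supply_mod
    result$chilling_warning <- supply_mod < w$state$chilling_floor
    if (result$chilling_warning) {
      attr(result, "notice") <- sprintf(
        "what-if setpoint %.1f below chilling floor %.1f degC",
        supply_mod, w$state$chilling_floor)
    }
  }
  result
}

## ---- GreenLife -----------------------------------------------------------

#' @rdname banana_wrappers
#' @export
green_life_wrapper <- function(params = NULL) {
  w <- new_specific_wrapper("green_life_wrapper", "GreenLife",
                            required_fields = "T_Box",
                            nominal_interval = pget(params, "nominal_interval", 1),
                            interval_tolerance = pget(params, "interval_tolerance", 0.1))
  p <- green_life_params(GL0 = pget(params, "GL0", 28),
                         Q10 = pget(params, "Q10", 3),
                         T_ref = pget(params, "T_ref", 13))
  w$state$gl <- green_life_state(p)
  w
}

#' @export
sw_step.green_life_wrapper <- function(w, payload, t, dt) {
  if (is.na(dt)) dt <- 0   # first sample anchors the integral
  w$state$gl <- green_life_update(w$state$gl, payload$T_Box, dt)
  list(remaining = w$state$gl$remaining)
}

#' @export
sw_predict.green_life_wrapper <- function(w, payload, t, horizon,
                                          overrides = list()) {
  gl <- w$state$gl
  result <- list(remaining = gl$remaining)
  fut <- payload[["CoolPredict.prediction"]]
  if (is.null(fut)) return(result)
  base <- green_life_predict(gl$D, fut, gl$params)
  result$prediction <- base$remaining
  if (!is.na(base$exhausted_at)) result$exhausted_at <- t + base$exhausted_at
  fut2 <- payload[["CoolPredict.prediction_whatif"]]
  if (!is.null(fut2)) {
    mod <- green_life_predict(gl$D, fut2, gl$params)
    result$prediction_whatif <- mod$remaining
    result$whatif_delta_days <- mod$remaining - base$remaining
  }
  result
}
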