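#' One explicit-Euler step of the first-order cooling model
#'
#' The box temperature relaxes toward the supply-air temperature with rate
#' constant `k_M` (the cooling-efficiency parameter) while internal heat
#' production raises it at rate `q`:
#'
#'   T' = T + dt * ( -k_M * (T - T_Supply) + q )
#'
#' Heat capacity is absorbed into `q` (units K/h), so the model carries no
#' separate capacity parameter. The explicit scheme is contractive only
#' for `dt * k_M < 1`, which is enforced.
#'
#' @param T_box Current box temperature, degrees C.
#' @param T_supply Supply-air temperature over the step, degrees C.
#' @param k_M Cooling-efficiency rate constant, 1/h (>= 0).
#' @param q Heat-production rate expressed as temperature rise, K/h.
#' @param dt Step length, hours (> 0).
#' @return Box temperature after `dt` hours.
#' @examples
#' cool_step(25, 13.2, k_M = 0.05, q = 0, dt = 1)  # 24.41
#' @export
cool_step <- function(T_box, T_supply, k_M, q = 0, dt = 1) {
  if (dt <= 0) stop(twin_error("dt must be positive", "twin_model_error"))
  if (k_M < 0) stop(twin_error("k_M must be non-negative", "twin_model_error"))
  if (dt * k_M >= 1) {
    stop(twin_error(sprintf("explicit scheme unstable: dt*k_M = %.3f >= 1",
                            dt * k_M), "twin_stability_error"))
  }
  T_box + dt * (-k_M * (T_box - T_supply) + q)
}

#' Fresh cooling-parameter estimator state
#'
#' Running-sum state for the regression-through-origin estimate of `k_M`
#' from consecutive (T_Box, T_Supply) samples during the cooling phase.
#'
#' @param stable_hours Hours of data required before the estimate may be
#'   declared stable (default 72 h, i.e. three days of cooling).
#' @param spread_tol Maximum relative spread of the estimate over the
#'   stability window for the stable flag (default 2 %).
#' @param window Stability window, hours (default 24).
#' @return Object of class `km_state`.
#' @export
km_state <- function(stable_hours = 72, spread_tol = 0.02, window = 24) {
  structure(list(n = 0L, Sxx = 0, Sxy = 0, k_hat = NA_real_,
                 history = list(t = numeric(0), k = numeric(0)),
                 start_t = NA_real_, elapsed = 0, stable = FALSE,
                 stable_hours = stable_hours, spread_tol = spread_tol,
                 window = window),
            class = "km_state")
}

#' Update the cooling-parameter estimate with one sample pair
#'
#' During cooling (heat production assumed zero) the Euler model gives
#' `(T_i - T_{i+1})/dt = k_M * (T_i - T_Supply_i)`, a line through the
#' origin. The estimator accumulates `Sxx = sum x^2` and `Sxy = sum x*y`
#' with `x = T_i - T_Supply_i` and `y = (T_i - T_{i+1})/dt`, giving
#' `k_hat = Sxy/Sxx`. The estimate is flagged stable once at least
#' `stable_hours` of data have elapsed *and* the relative spread of the
#' estimate over the trailing window falls below `spread_tol`.
#'
#' @param state A [km_state()].
#' @param prev,cur Consecutive samples: lists with `t` (hours), `T_Box`
#'   and `T_Supply` (degrees C); `cur$t > prev$t`.
#' @return The updated `km_state`.
#' @export
km_update <- function(state, prev, cur) {
  stopifnot(inherits(state, "km_state"))
  dt <- cur$t - prev$t
  if (!is.finite(dt) || dt <= 0) {
    stop(twin_error("samples must advance in time", "twin_model_error"))
  }
  x <- prev$T_Box - prev$T_Supply
  y <- (prev$T_Box - cur$T_Box) / dt
  state$n <- state$n + 1L
  if (is.na(state$start_t)) state$start_t <- prev$t
  state$elapsed <- cur$t - state$start_t
  if (x != 0) {
    state$Sxx <- state$Sxx + x * x
    state$Sxy <- state$Sxy + x * y
  }
  if (state$Sxx > 0) {
    state$k_hat <- state$Sxy / state$Sxx
  } else if (state$n >= 24L) {
    stop(twin_error(
      "no thermal excitation: T_Box identical to T_Supply in all samples",
      "twin_identifiability_error"))
  }
  if (!is.na(state$k_hat)) {
    state$history$t <- c(state$history$t, cur$t)
    state$history$k <- c(state$history$k, state$k_hat)
    keep <- state$history$t >= cur$t - state$window
    state$history$t <- state$history$t[keep]
    state$history$k <- state$history$k[keep]
    spread_ok <- FALSE
    if (length(state$history$k) >= 2L) {
      ks <- state$history$k
      ref <- max(abs(mean(ks)), .Machine$double.eps)
      spread_ok <- (max(ks) - min(ks)) / ref < state$spread_tol
    }
    state$stable <- state$elapsed >= state$stable_hours && spread_ok
  }
  state
}

#' Predict the future box temperature under constant supply air
#'
#' Iterates the cooling model with zero heat production from the current
#' box temperature, holding the supply air constant, and returns one value
#' per hour: element `i` is the predicted temperature `i` hours from now.
#'
#' @param T_now Current box temperature, degrees C.
#' @param T_supply_const Assumed constant supply-air temperature, degrees C.
#' @param k_hat Estimated cooling-efficiency constant, 1/h.
#' @param horizon Prediction horizon in whole hours (>= 0).
#' @return Numeric vector of length `horizon`.
#' @export
predict_temperature <- function(T_now, T_supply_const, k_hat, horizon) {
  if (length(horizon) != 1L || is.na(horizon) || horizon < 0) {
    stop(twin_error("horizon must be a non-negative number of hours",
                    "twin_range_error"))
  }
  horizon <- as.integer(horizon)
  out <- numeric(horizon)
  T_cur <- T_now
  for (i in seq_len(horizon)) {
    T_cur <- cool_step(T_cur, T_supply_const, k_hat, q = 0, dt = 1)
    out[i] <- T_cur
  }
  out
}

#' Observe the ripening heat from one sample pair
#'
#' Algebraic inversion of the cooling model: given the (previously
#' estimated) `k_M`, the heat-production rate that explains the observed
#' temperature change is
#'
#'   q_hat = (T_cur - T_prev)/dt + k_M * (T_prev - T_Supply_prev)
#'
#' This raw value inverts [cool_step()] exactly; smoothing and clipping of
#' the reported value happen in the wrapper.
#'
#' @param k_hat Cooling-efficiency constant, 1/h.
#' @param prev,cur Consecutive samples (lists with `t`, `T_Box`,
#'   `T_Supply`); `cur$t > prev$t`.
#' @return Raw heat-production rate `q_hat`, K/h.
#' @export
ripening_heat <- function(k_hat, prev, cur) {
  dt <- cur$t - prev$t
  if (!is.finite(dt) || dt <= 0) {
    stop(twin_error("samples must advance in time", "twin_model_error"))
  }
  (cur$T_Box - prev$T_Box) / dt + k_hat * (prev$T_Box - prev$T_Supply)
}

#' Centered moving average
#'
#' Window is truncated symmetrically at the series ends so the result has
#' the same length as the input.
#'
#' @param x Numeric vector.
#' @param window Odd window length (default 5).
#' @return Numeric vector, `length(x)`.
#' @export
smooth_centered <- function(x, window = 5L) {
  n <- length(x)
  if (n == 0L) return(x)
  half <- (as.integer(window) - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Green-life model parameters
#'
#' The green-life model tracks the remaining days until spontaneous
#' ripening starts, under a Q10 rate law: storage at the reference
#' temperature consumes green life in real time, and every 10 K above the
#' reference multiplies consumption by `Q10`.
#'
#' Defaults (`GL0 = 28` d, `Q10 = 3`, `T_ref = 13` degrees C) are
#' configuration values chosen as plausible for bananas, not measured
#' constants; they can be overridden via the `models:` section of the
#' configuration file.
#'
#' @param GL0 Green-life budget at the reference temperature, days (> 0).
#' @param Q10 Rate-acceleration factor per 10 K (> 1).
#' @param T_ref Reference temperature, degrees C.
#' @return Object of class `green_life_params`.
#' @export
green_life_params <- function(GL0 = 28, Q10 = 3, T_ref = 13) {
  if (GL0 <= 0) stop(twin_error("GL0 must be positive", "twin_model_error"))
  if (Q10 <= 1) stop(twin_error("Q10 must exceed 1", "twin_model_error"))
  structure(list(GL0 = GL0, Q10 = Q10, T_ref = T_ref),
            class = "green_life_params")
}

#' Green-life consumption rate at a temperature
#'
#' `r = Q10^((T - T_ref)/10)`, in days of green life consumed per day of
#' storage; `r(T_ref) = 1` and `r(T + 10) = Q10 * r(T)`.
#'
#' @param T Box temperature, degrees C (vectorized).
#' @param p A [green_life_params()].
#' @return Consumption rate(s), dimensionless.
#' @export
green_life_rate <- function(T, p) {
  p$Q10^((T - p$T_ref) / 10)
}

#' Fresh green-life accumulator state
#' @param p A [green_life_params()].
#' @return Object of class `green_life_state` with dose `D = 0` and
#'   `remaining = GL0`.
#' @export
green_life_state <- function(p = green_life_params()) {
  structure(list(D = 0, remaining = p$GL0, params = p),
            class = "green_life_state")
}

#' Accumulate green-life dose over one interval
#'
#' Adds `r(T) * dt/24` days to the accumulated dose `D`; the remaining
#' green life is `GL0 - D` and may go negative (budget exhausted).
#'
#' @param state A [green_life_state()].
#' @param T Box temperature over the interval, degrees C.
#' @param dt Interval length, hours (>= 0).
#' @return Updated state.
#' @export
green_life_update <- function(state, T, dt) {
  stopifnot(inherits(state, "green_life_state"))
  if (dt < 0) stop(twin_error("dt must be non-negative", "twin_model_error"))
  state$D <- state$D + green_life_rate(T, state$params) * dt / 24
  state$remaining <- state$params$GL0 - state$D
  state
}

#' Integrate green life over a future temperature trajectory
#'
#' Continues the dose integral from an already-accumulated dose over an
#' hourly temperature array (typically the output of
#' [predict_temperature()], or the measured series for a hindsight
#' reference). If the remaining green life crosses zero inside the
#' horizon, the crossing time is located by linear interpolation within
#' the hour.
#'
#' @param D0 Dose accumulated so far, days-at-reference.
#' @param future_T Numeric vector of hourly box temperatures, degrees C.
#' @param p A [green_life_params()].
#' @return List with `remaining` (days at the end of the horizon),
#'   `exhausted_at` (hours from now to the zero crossing, `NA` if not
#'   crossed) and `series` (remaining green life after each hour).
#' @export
green_life_predict <- function(D0, future_T, p = green_life_params()) {
  n <- length(future_T)
  remaining <- p$GL0 - D0
  series <- numeric(n)
  exhausted_at <- NA_real_
  for (i in seq_len(n)) {
    prev_rem <- remaining
    remaining <- remaining - green_life_rate(future_T[i], p) / 24
    series[i] <- remaining
    if (is.na(exhausted_at) && prev_rem > 0 && remaining <= 0) {
      exhausted_at <- (i - 1) + prev_rem / (prev_rem - remaining)
    }
  }
  list(remaining = remaining, exhausted_at = exhausted_at, series = series)
}

#' Compare baseline and what-if setpoint predictions
#'
#' Runs the temperature prediction twice -- once with the baseline supply
#' temperature (by convention the average of the recently observed supply
#' readings) and once with an operator override -- feeds both trajectories
#' into the green-life integral and reports both outcomes and their
#' difference. Overrides below the chilling floor are computed but
#' flagged, since bananas suffer chilling injuries at low temperatures.
#'
#' @param T_now Current box temperature, degrees C.
#' @param supply_baseline Baseline constant supply temperature, degrees C.
#' @param supply_override What-if supply temperature, degrees C.
#' @param k_hat Estimated cooling constant, 1/h.
#' @param horizon Prediction horizon, whole hours.
#' @param D0 Green-life dose accumulated so far, days.
#' @param p A [green_life_params()].
#' @param chilling_floor Warn below this supply temperature (default
#'   12.5 degrees C).
#' @return List with `baseline` and `modified` (each a
#'   [green_life_predict()] result plus the temperature array), the
#'   green-life `delta_days` (modified minus baseline) and
#'   `chilling_warning`.
#' @export
what_if <- function(T_now, supply_baseline, supply_override, k_hat, horizon,
                    D0, p = green_life_params(), chilling_floor = 12.5) {
  T_base <- predict_temperature(T_now, supply_baseline, k_hat, horizon)
  T_mod <- predict_temperature(T_now, supply_override, k_hat, horizon)
  gl_base <- green_life_predict(D0, T_base, p)
  gl_mod <- green_life_predict(D0, T_mod, p)
  gl_base$temperature <- T_base
  gl_mod$temperature <- T_mod
  list(baseline = gl_base, modified = gl_mod,
       delta_days = gl_mod$remaining - gl_base$remaining,
       chilling_warning = supply_override < chilling_floor)
}
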