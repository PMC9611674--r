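# simulate the cooling model and return the sample list
simulate_cooling <- function(k, dt, n, T0 = 25, Ts = 13.2,
                             q = function(i) 0, supply = function(i) Ts) {
  samples <- vector("list", n + 1)
  T_cur <- T0
  for (i in 0:n) {
    samples[[i + 1]] <- list(t = i * dt, T_Box = T_cur, T_Supply = supply(i))
    if (i < n) T_cur <- cool_step(T_cur, supply(i), k, q(i), dt)
  }
  samples
}

estimate_k <- function(samples, ...) {
  st <- km_state(...)
  for (i in seq_len(length(samples) - 1)) {
    st <- km_update(st, samples[[i]], samples[[i + 1]])
  }
  st
}

test_that("cool_step contracts toward the supply air", {
  expect_equal(cool_step(13.2, 13.2, 0.05, 0, 1), 13.2)      # fixed point
  expect_equal(cool_step(25, 13.2, 0.05, 0, 1), 25 - 0.05 * 11.8)  # = 24.41
  # contraction for q = 0
  expect_lt(abs(cool_step(25, 13.2, 0.3, 0, 1) - 13.2), abs(25 - 13.2))
  expect_error(cool_step(25, 13.2, 0.5, 0, 3), class = "twin_stability_error")
  expect_error(cool_step(25, 13.2, 0.05, 0, 0), class = "twin_model_error")
})

test_that("fine Euler steps converge to the closed-form exponential", {
  k <- 0.5; dt <- 0.01; T0 <- 25; Ts <- 13.2
  T_cur <- T0
  for (i in 1:240) T_cur <- cool_step(T_cur, Ts, k, 0, dt)
  expect_equal(T_cur, Ts + (T0 - Ts) * exp(-k * 2.4), tolerance = 1e-3)
})

test_that("noiseless simulate-then-estimate recovers k_M exactly", {
  st <- estimate_k(simulate_cooling(0.05, 1, 72))
  expect_equal(st$k_hat, 0.05, tolerance = 1e-9)

  # independent oracle: grid search over k minimizing the summed squared
  # one-step residuals of the same data
  samples <- simulate_cooling(0.05, 1, 72)
  sse <- function(k) {
    sum(vapply(seq_len(length(samples) - 1), function(i) {
      pred <- cool_step(samples[[i]]$T_Box, samples[[i]]$T_Supply, k, 0, 1)
      (pred - samples[[i + 1]]$T_Box)^2
    }, numeric(1)))
  }
  grid <- seq(0.02, 0.08, by = 1e-4)
  expect_equal(grid[which.min(vapply(grid, sse, numeric(1)))], 0.05,
               tolerance = 1e-3)
})

test_that("k_M recovery holds across the parameter range (property sweep)", {
  ks <- seq(0.01, 0.2, length.out = 10)
  for (k in ks) {
    for (dt in c(0.5, 1)) {
      st <- estimate_k(simulate_cooling(k, dt, ceiling(72 / dt)))
      expect_equal(st$k_hat, k, tolerance = 1e-9,
                   label = sprintf("k_hat (k=%.3f, dt=%.1f)", k, dt))
    }
  }
})

test_that("samples without thermal excitation carry no information", {
  st <- km_state()
  prev <- list(t = 0, T_Box = 13.2, T_Supply = 13.2)
  cur <- list(t = 1, T_Box = 13.2, T_Supply = 13.2)
  st2 <- km_update(st, prev, cur)
  expect_equal(st2$n, 1L)
  expect_equal(st2$Sxx, 0)
  expect_true(is.na(st2$k_hat))
  # 24+ uninformative samples raise an identifiability error
  expect_error({
    for (i in 1:30) {
      st <- km_update(st, list(t = i - 1, T_Box = 13.2, T_Supply = 13.2),
                      list(t = i, T_Box = 13.2, T_Supply = 13.2))
    }
  }, class = "twin_identifiability_error")
})

test_that("the estimate is never declared stable before three days", {
  st <- estimate_k(simulate_cooling(0.05, 1, 48))
  expect_equal(st$elapsed, 48)
  expect_false(st$stable)
  st <- estimate_k(simulate_cooling(0.05, 1, 80))
  expect_true(st$stable)
})

test_that("temperature prediction relaxes monotonically to the setpoint", {
  expect_length(predict_temperature(20, 13.2, 0.05, 0), 0)
  expect_equal(predict_temperature(13.2, 13.2, 0.05, 24), rep(13.2, 24))
  pred <- predict_temperature(20, 13.2, 0.05, 264)
  expect_length(pred, 264)
  expect_true(all(diff(pred) < 0))
  # closed-form damping bound: (1-k)^264 < e^{-0.05*264}, so well under 0.01
  expect_lt(abs(pred[264] - 13.2), 0.01)
  expect_error(predict_temperature(20, 13.2, 0.05, -3),
               class = "twin_range_error")
})

test_that("the ripening-heat observer inverts the cooling model exactly", {
  # steady state: no heat
  expect_equal(ripening_heat(0.05, list(t = 0, T_Box = 13.2, T_Supply = 13.2),
                             list(t = 1, T_Box = 13.2, T_Supply = 13.2)), 0)
  # constant q
  samples <- simulate_cooling(0.05, 1, 96, q = function(i) 0.5)
  for (i in seq_len(96)) {
    expect_equal(ripening_heat(0.05, samples[[i]], samples[[i + 1]]), 0.5,
                 tolerance = 1e-9)
  }
  # a step change in q is reproduced sample-wise
  qfun <- function(i) 0.2 + 0.3 * (i >= 10)
  samples <- simulate_cooling(0.05, 1, 48, q = qfun)
  qhat <- vapply(seq_len(48), function(i) {
    ripening_heat(0.05, samples[[i]], samples[[i + 1]])
  }, numeric(1))
  expect_equal(qhat, vapply(0:47, qfun, numeric(1)), tolerance = 1e-12)
})

test_that("observer exactness holds for arbitrary seeded q sequences", {
  set.seed(4242)
  for (rep in 1:5) {
    k <- runif(1, 0.01, 0.2)
    qs <- pmax(0, stats::rnorm(72, 0.3, 0.2))
    supply <- function(i) 13.2 + 0.5 * sin(i / 5)
    samples <- simulate_cooling(k, 1, 72, q = function(i) qs[i + 1],
                                supply = supply)
    qhat <- vapply(seq_len(72), function(i) {
      ripening_heat(k, samples[[i]], samples[[i + 1]])
    }, numeric(1))
    expect_equal(qhat, qs, tolerance = 1e-9)
  }
})

test_that("green-life rate law is normalized and Q10-multiplicative", {
  p <- green_life_params(GL0 = 28, Q10 = 3, T_ref = 13)
  expect_equal(green_life_rate(13, p), 1)
  expect_equal(green_life_rate(23, p), 3)
  expect_equal(green_life_rate(18, p), sqrt(3), tolerance = 1e-7)
  grid <- seq(-5, 45, by = 2.5)
  expect_equal(green_life_rate(grid + 10, p) / green_life_rate(grid, p),
               rep(3, length(grid)), tolerance = 1e-12)
})

test_that("green-life dose integrates, splits and exhausts correctly", {
  p <- green_life_params()
  st <- green_life_state(p)
  for (h in 1:24) st <- green_life_update(st, 13, 1)
  expect_equal(st$remaining, p$GL0 - 1, tolerance = 1e-12)
  expect_equal(green_life_update(st, 30, 0)$remaining, st$remaining)

  # 48 h at T_ref + 10 with Q10 = 3 consumes 6 days
  st2 <- green_life_state(p)
  for (h in 1:48) st2 <- green_life_update(st2, 23, 1)
  expect_equal(st2$D, 6, tolerance = 1e-12)

  # additivity: one pass equals any split
  set.seed(99)
  temps <- runif(100, 12, 30)
  one <- green_life_predict(0, temps, p)$remaining
  for (cut in c(1, 37, 99)) {
    d_head <- p$GL0 - green_life_predict(0, temps[1:cut], p)$remaining
    split <- green_life_predict(d_head, temps[(cut + 1):100], p)$remaining
    expect_equal(split, one, tolerance = 1e-12)
  }

  # empty future: unchanged
  expect_equal(green_life_predict(3, numeric(0), p)$remaining, p$GL0 - 3)

  # exhaustion time by linear interpolation within the hour
  res <- green_life_predict(p$GL0 - 2 / 24 - 0.5 / 24, rep(13, 5), p)
  expect_equal(res$exhausted_at, 2.5, tolerance = 1e-9)
  expect_lt(res$remaining, 0)
})

test_that("what-if comparisons are monotone and flag chilling risk", {
  p <- green_life_params()
  base <- what_if(14, 13.2, 13.2, 0.05, 192, D0 = 8, p = p)
  expect_equal(base$delta_days, 0)
  expect_false(base$chilling_warning)

  lower <- what_if(14, 13.2, 12.7, 0.05, 192, D0 = 8, p = p)
  expect_gt(lower$delta_days, 0)
  expect_true(all(lower$modified$temperature <= lower$baseline$temperature))

  chill <- what_if(14, 13.2, 12.0, 0.05, 192, D0 = 8, p = p)
  expect_true(chill$chilling_warning)
  expect_gt(chill$delta_days, lower$delta_days)
})
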