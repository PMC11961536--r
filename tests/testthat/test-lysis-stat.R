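make_series <- function(time, value) {
  qcmdlysis:::spread_series(time, value)
}

test_that("delta_d_spread is the pointwise DeltaD3 - DeltaD11 difference", {
  exp <- toy_experiment()          # dD_n = (12 - n) * t / 400
  sp <- delta_d_spread(exp)
  grid <- experiment_time(exp)
  expect_equal(sp$value, 9 * grid / 400 - 1 * grid / 400)
  expect_false(sp$normalized)

  # equal overtones give an identically zero spread
  tr <- lapply(c(3L, 11L), function(n)
    overtone_trace(n, grid, 0 * grid, 5 + 0 * grid))
  e2 <- qcmd_experiment(tr, exp$schedule)
  expect_equal(delta_d_spread(e2)$value, rep(0, length(grid)))

  # missing overtone 11 is an explicit error
  e3 <- qcmd_experiment(list(exp$traces[["3"]], exp$traces[["5"]]),
                        exp$schedule)
  expect_error(delta_d_spread(e3), "overtone absent")
})

test_that("noise-free growth gives a strictly increasing spread while the film grows", {
  p <- quiet_params("control")
  e <- simulate_experiment(p)
  sp <- delta_d_spread(e)
  w <- phase_window(p$schedule, "growth_static")
  idx <- sp$time > w["start"] + 1 & sp$time < w["end"]
  expect_true(all(diff(sp$value[idx]) > 0))
})

test_that("normalization pins the pre-injection maximum at 1 and is scale invariant", {
  t <- seq(0, 300, by = 1)
  v <- sin(t / 50) + 1.2
  s <- make_series(t, v)
  n1 <- normalize_spread(s, t_ref = 185)
  expect_equal(max(n1$value[n1$time < 185]), 1)
  expect_true(n1$normalized)
  expect_equal(n1$t_ref, 185)

  # positive rescaling of the raw series changes nothing
  for (c in c(0.2, 3, 1e4)) {
    nc <- normalize_spread(make_series(t, c * v), t_ref = 185)
    expect_equal(nc$value, n1$value)
  }

  # idempotence
  n2 <- normalize_spread(n1, t_ref = 185)
  expect_equal(n2, n1)

  # degenerate baselines are refused
  expect_error(normalize_spread(make_series(t, 0 * t), 185),
               "degenerate baseline")
  expect_error(normalize_spread(make_series(t, -1 + 0 * t), 185),
               "degenerate baseline")
  expect_error(normalize_spread(s, t_ref = -5), "no samples before")
})

test_that("second derivative is exact on polynomials and converges on sines", {
  # quadratic: constant second derivative 2a, exact everywhere after smoothing
  t <- seq(0, 50, by = 0.5)
  a <- 0.37; b <- -2; cc <- 5
  q <- make_series(t, a * t^2 + b * t + cc)
  d2 <- second_derivative(q, halfwidth = 5)
  expect_equal(d2$value, rep(2 * a, length(d2$value)))

  # linear series: identically zero
  lin <- make_series(t, 3 * t - 7)
  expect_equal(second_derivative(lin, halfwidth = 3)$value,
               rep(0, length(t) - 6))

  # sine: approaches -omega^2 sin(omega t) as the grid refines (no smoothing,
  # so the finite-difference error is the only error)
  omega <- 0.2
  err <- vapply(c(0.5, 0.25, 0.125), function(dt) {
    tt <- seq(0, 100, by = dt)
    d2s <- second_derivative(make_series(tt, sin(omega * tt)), halfwidth = 0)
    max(abs(d2s$value[-c(1, length(d2s$value))] +
              omega^2 * sin(omega * tt[-c(1, length(tt))])))
  }, numeric(1))
  expect_lt(err[1], omega^2 * 0.005)
  # second-order convergence: error shrinks ~4x per halving
  expect_lt(err[2], err[1] / 3)
  expect_lt(err[3], err[2] / 3)

  # windowing and sample guards
  expect_error(second_derivative(q, window = c(0, 3), halfwidth = 2),
               "too few samples")
})

test_that("drop fraction and fixed-time readout behave as defined", {
  sch <- default_schedule()
  t <- seq(0, 400, by = 0.5)

  const <- qcmdlysis:::spread_series(t, rep(1, length(t)), normalized = TRUE,
                                     t_ref = 185)
  expect_equal(drop_fraction(const, sch), 0)

  # pre-injection value 1, post-injection minimum 0.2 -> drop 0.8
  v <- ifelse(t < 185, 1, ifelse(t < 230, 1 - 0.8 * (t - 185) / 45, 0.2))
  dropped <- qcmdlysis:::spread_series(t, v, normalized = TRUE, t_ref = 185)
  expect_equal(drop_fraction(dropped, sch), 0.8)

  # rising series gives a negative (unclamped) drop
  rising <- qcmdlysis:::spread_series(
    t, ifelse(t < 185, 1, 1 + 0.002 * (t - 185)),
    normalized = TRUE, t_ref = 185)
  expect_lt(drop_fraction(rising, sch), 0)

  # readout: exact at grid points, linear between them
  s <- make_series(c(0, 10, 20), c(0.1, 0.2, 0.4))
  expect_equal(readout_at(s, 10), 0.2)
  expect_equal(readout_at(s, 15), 0.3)
  expect_error(readout_at(s, 25), "outside the series span")
})

test_that("classification calls lysis by derivative sign with a non-lytic tie-break", {
  sch <- default_schedule()
  t <- seq(0, 400, by = 0.5)

  # exactly constant post-flush series: derivative 0 -> non_lytic
  flat <- qcmdlysis:::spread_series(t, rep(1, length(t)), normalized = TRUE,
                                    t_ref = 185)
  call <- classify_lysis(flat, sch)
  expect_identical(call$label, "non_lytic")
  expect_equal(call$derivative_sum, 0)
  expect_equal(call$derivative_mean, 0)

  # convex post-flush recovery -> lytic; concave saturation -> non_lytic
  conv <- ifelse(t < 220, 1, 0.2 + 0.8 * ((t - 220) / 180)^2)
  expect_identical(
    classify_lysis(qcmdlysis:::spread_series(t, conv, normalized = TRUE,
                                             t_ref = 185), sch)$label,
    "lytic")
  conc <- 1 + 0.5 * sqrt(pmax(t - 220, 0) / 180)
  expect_identical(
    classify_lysis(qcmdlysis:::spread_series(t, conc, normalized = TRUE,
                                             t_ref = 185), sch)$label,
    "non_lytic")

  # un-normalized input is refused
  expect_error(classify_lysis(make_series(t, rep(1, length(t))), sch),
               "normalized")
})

test_that("classification is invariant under positive rescaling of the raw spread", {
  e <- simulate_experiment(sim_params("infectious", seed = 31))
  sp <- delta_d_spread(e)
  inj <- phase_window(e$schedule, "second_injection")
  base <- classify_lysis(normalize_spread(sp, inj["start"]), e$schedule)
  for (c in c(0.1, 7)) {
    scaled <- qcmdlysis:::spread_series(sp$time, c * sp$value)
    cl <- classify_lysis(normalize_spread(scaled, inj["start"]), e$schedule)
    expect_identical(cl$label, base$label)
    expect_equal(cl$derivative_mean, base$derivative_mean)
    expect_equal(cl$drop_fraction, base$drop_fraction)
  }
})

test_that("Welch comparison matches a brute-force evaluation of the formulas", {
  a <- c(1.1, 2.3, 3.1, 2.2)
  b <- c(11.0, 12.4, 13.1)
  gc <- group_compare(a, b)
  # brute-force Welch statistic, df and two-tailed p
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t_oracle <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_oracle <- (va + vb)^2 /
    (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p_oracle <- 2 * pt(-abs(t_oracle), df_oracle)
  expect_equal(gc$t_statistic, t_oracle)
  expect_equal(gc$degrees_of_freedom, df_oracle)
  expect_equal(gc$p_value, p_oracle)
  expect_identical(gc$stars, "***")

  # identical groups: t = 0, p = 1, ns
  same <- group_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_identical(same$stars, "ns")

  # shifted copy with equal spread: large |t|, ***
  sh <- group_compare(c(1, 2, 3), c(11, 12, 13))
  expect_lt(sh$p_value, 0.001)
  expect_identical(sh$stars, "***")

  expect_error(group_compare(1, c(1, 2)), "at least 2")
})

test_that("star mapping follows the conventional thresholds", {
  set.seed(4)
  x <- rnorm(6)
  # weak shift: not significant; strong shift: significant
  expect_identical(group_compare(x, x + 0.01)$stars, "ns")
  expect_identical(group_compare(x, x + 100)$stars, "***")
})
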