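test_that("infection fraction follows the Poisson encounter model", {
  expect_equal(infection_fraction(8e7, 4e-7, 0), 0)
  expect_equal(infection_fraction(1e12, 1, 1e6), 1)
  # k_i * titer * exposure = ln 2 gives exactly one half
  expect_equal(infection_fraction(log(2) / (4e-7 * 20), 4e-7, 20), 0.5)
  # monotone in each argument
  expect_true(all(diff(infection_fraction(10^(2:6), 4e-7, 20)) > 0))
  expect_true(all(diff(infection_fraction(2e6, 4e-7, seq(0, 60, 5))) >= 0))
  expect_error(infection_fraction(-1, 1, 1), "non-negative")
})

test_that("latent film trajectories respect the state bounds", {
  set.seed(3)
  cases <- list(
    quiet_params("control"),
    quiet_params("infectious", titer = 8e7),
    quiet_params("infectious", titer = 4e5),
    quiet_params("non_infectious"),
    quiet_params("infectious", titer = 2e6, collapse_time = 3,
                 s_debris = 0.1, h_debris = 20),
    quiet_params("control", growth_rate = 0.05, h_cap = 120)
  )
  for (p in cases) {
    tr <- film_trajectory(p)
    expect_true(all(tr$h >= 0))
    expect_true(all(tr$m >= 0))
    expect_true(all(tr$theta >= -1e-12 & tr$theta <= 1 + 1e-12))
    expect_true(all(tr$s >= 0 & tr$s <= 1))
    expect_true(all(diff(tr$m) >= -1e-9))
  }
})

test_that("control trajectory keeps a live film that grows during static phases", {
  tr <- film_trajectory(quiet_params("control"))
  expect_true(all(tr$s == 1))
  sch <- quiet_params("control")$schedule
  for (ph in c("growth_static", "post_static")) {
    w <- phase_window(sch, ph)
    idx <- tr$time >= w["start"] & tr$time < w["end"]
    expect_true(all(diff(tr$h[idx]) >= 0))
  }
})

test_that("high-titer infection collapses the film to debris; low titer regrows", {
  p_hi <- quiet_params("infectious", titer = 8e7)
  tr_hi <- film_trajectory(p_hi)
  tail_idx <- tr_hi$time > 300
  # near-total lysis: thickness near the debris value, softness near s_debris
  expect_equal(mean(tr_hi$h[tail_idx]), p_hi$h_debris, tolerance = 0.15)
  expect_equal(mean(tr_hi$s[tail_idx]), p_hi$s_debris, tolerance = 0.1)

  tr_lo <- film_trajectory(quiet_params("infectious", titer = 4e5))
  # survivors regrow: thickness rises again well after the collapse
  h250 <- tr_lo$h[which.min(abs(tr_lo$time - 250))]
  h400 <- tr_lo$h[length(tr_lo$h)]
  expect_gt(h400, h250 + 20)
  expect_lt(tr_lo$p, 1)
  expect_gt(tr_lo$p, 0.9)
})

test_that("simulation is deterministic under a fixed seed", {
  p <- sim_params("infectious", seed = 77)
  e1 <- simulate_experiment(p)
  e2 <- simulate_experiment(p)
  expect_identical(e1, e2)
  p2 <- sim_params("infectious", seed = 78)
  expect_false(identical(simulate_experiment(p2), e1))

  d <- list(sim_params("control"), sim_params("infectious"))
  pan1 <- simulate_panel(d, master_seed = 5)
  pan2 <- simulate_panel(d, master_seed = 5)
  expect_identical(pan1, pan2)
  pan3 <- simulate_panel(d, master_seed = 6)
  expect_false(identical(pan1, pan3))
  # different master seeds differ in noise but share the schedule
  expect_identical(pan1[[1]]$schedule, pan3[[1]]$schedule)
})

test_that("simulate_experiment does not disturb the global RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(simulate_experiment(sim_params("control", seed = 9)))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("noise-free simulator output equals kernels composed with the trajectory", {
  p <- quiet_params("infectious", titer = 2e6)
  e <- simulate_experiment(p)
  tr <- film_trajectory(p)
  film <- film_state(tr$h, tr$s, tr$m, tr$theta, p$resonance_sign)
  for (n in c(3, 7, 11)) {
    expect_equal(get_overtone_series(e, n, "dissipation"),
                 dissipation_kernel(film, n, p$f0, p$liquid, p$amplitude_D))
    expect_equal(get_overtone_series(e, n, "frequency"),
                 frequency_kernel(film, n, p$f0, p$amplitude_f))
  }
  # the spread statistic therefore matches the closed-form kernel difference
  sp <- delta_d_spread(e)
  oracle <- dissipation_kernel(film, 3, p$f0, p$liquid, p$amplitude_D) -
    dissipation_kernel(film, 11, p$f0, p$liquid, p$amplitude_D)
  expect_equal(sp$value, oracle)
})

test_that("panel bookkeeping: labels, sizes and sensor variability", {
  expect_error(simulate_panel(list()), "non-empty")
  pan <- simulate_panel(list(sim_params("control")), master_seed = 2)
  expect_length(pan, 1L)
  expect_identical(pan[[1]]$label, "control")

  design <- standard_panel_design()  # 2 controls, 3 titers, 1 non-infectious
  expect_length(design, 6L)
  pan <- simulate_panel(design, master_seed = 11)
  expect_identical(vapply(pan, `[[`, character(1), "label"),
                   c(rep("control", 2), rep("infectious", 3),
                     "non_infectious"))
})
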