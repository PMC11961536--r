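test_that("penetration depth reproduces the quoted aqueous-medium values", {
  # ~140 nm at n = 3 and ~70 nm at n = 11 for a 5 MHz sensor in water (25 C)
  expect_equal(penetration_depth(3), 140, tolerance = 0.05)
  expect_equal(penetration_depth(11), 70, tolerance = 0.05)
  # direct numeric evaluation of the closed form as oracle
  expect_equal(penetration_depth(3),
               sqrt(8.9e-4 / (pi * 3 * 5e6 * 997)) * 1e9)
  expect_error(penetration_depth(0), "n >= 1")
  expect_error(liquid_properties(-1, 1000), "positive")
})

test_that("penetration depth scales as 1/sqrt(n) for all overtone pairs", {
  ns <- c(1, 3, 5, 7, 9, 11, 13)
  liq <- water_properties("37C")
  for (a in ns) for (b in ns) {
    expect_equal(penetration_depth(a, 5e6, liq) / penetration_depth(b, 5e6, liq),
                 sqrt(b / a))
  }
  expect_equal(penetration_depth(3) / penetration_depth(11), sqrt(11 / 3))
  # strictly decreasing in n
  expect_true(all(diff(penetration_depth(ns)) < 0))
})

test_that("Sauerbrey constant and mass match brute-force arithmetic", {
  C_oracle <- sqrt(2648 * 2.947e10) / (2 * 5e6^2) * 1e8  # ng cm^-2 Hz^-1
  expect_equal(sauerbrey_constant(), C_oracle)
  expect_equal(C_oracle, 17.7, tolerance = 0.01)
  expect_equal(sauerbrey_mass(0, 3), 0)
  expect_equal(sauerbrey_mass(-30, 3), C_oracle * 30 / 3)
  expect_equal(sauerbrey_mass(-30, 3), 177, tolerance = 0.01)
  # linearity and sign opposition
  for (a in c(-2, 0.5, 3)) {
    expect_equal(sauerbrey_mass(a * -7, 5), a * sauerbrey_mass(-7, 5))
  }
  expect_true(sauerbrey_mass(-10, 3) > 0)
  expect_true(sauerbrey_mass(10, 3) < 0)
})

test_that("dissipation kernel obeys its limits", {
  # zero-thickness film dissipates nothing
  f0film <- film_state(thickness = 0, softness = 1, coverage = 1)
  for (n in c(3, 5, 7, 9, 11)) {
    expect_equal(dissipation_kernel(f0film, n, amplitude = 10), 0)
  }
  # saturation: h -> Inf at n = 3 gives A_D * s * theta
  thick <- film_state(thickness = 1e9, softness = 0.5, coverage = 0.8)
  expect_equal(dissipation_kernel(thick, 3, amplitude = 10), 10 * 0.5 * 0.8)
  # h = delta_3 at n = 3 gives A_D * (1 - exp(-1))
  d3 <- penetration_depth(3)
  at_d3 <- film_state(thickness = d3, softness = 1, coverage = 1)
  expect_equal(dissipation_kernel(at_d3, 3, amplitude = 1), 1 - exp(-1))
})

test_that("dissipation kernel is monotone in h, s, theta and decreasing in n", {
  for (fs in random_film_states(25, seed = 11)) {
    base <- vapply(c(3, 5, 7, 9, 11), function(n)
      dissipation_kernel(fs, n), numeric(1))
    expect_true(all(diff(base) <= 0))       # non-increasing in n
    expect_true(all(base >= 0))
    up_h <- film_state(fs$thickness * 1.3, fs$softness, fs$rigid_mass,
                       fs$coverage, fs$resonance_sign)
    up_s <- film_state(fs$thickness, min(1, fs$softness * 1.1),
                       fs$rigid_mass, fs$coverage, fs$resonance_sign)
    up_t <- film_state(fs$thickness, fs$softness, fs$rigid_mass,
                       min(1, fs$coverage * 1.1), fs$resonance_sign)
    expect_gt(dissipation_kernel(up_h, 5), dissipation_kernel(fs, 5))
    expect_gt(dissipation_kernel(up_s, 5), dissipation_kernel(fs, 5))
    expect_gt(dissipation_kernel(up_t, 5), dissipation_kernel(fs, 5))
  }
})

test_that("kernel-implied overtone spread is non-negative and grows with thickness", {
  hs <- seq(0, 500, by = 10)
  fs <- film_state(thickness = hs, softness = 0.7, coverage = 0.9)
  spread <- dissipation_kernel(fs, 3) - dissipation_kernel(fs, 11)
  expect_true(all(spread >= 0))
  expect_true(all(diff(spread) > 0))
  # matches the closed form directly
  d3 <- penetration_depth(3); d11 <- penetration_depth(11)
  oracle <- 250 * 0.7 * 0.9 *
    (d3 * (1 - exp(-hs / d3)) - d11 * (1 - exp(-hs / d11))) / d3
  expect_equal(spread, oracle)
})

test_that("frequency kernel combines Sauerbrey and coupled-resonance loads", {
  empty <- film_state()
  expect_equal(frequency_kernel(empty, 3), 0)
  # theta = 0 reduces to pure Sauerbrey with opposite-sign mass response
  rigid <- film_state(rigid_mass = 100, coverage = 0)
  expect_equal(frequency_kernel(rigid, 3),
               -3 * 100 / sauerbrey_constant())
  # chi = +1, m = 0, theta > 0 gives a positive shift (bacterial adhesion)
  bact <- film_state(thickness = 100, coverage = 0.5, resonance_sign = 1)
  expect_gt(frequency_kernel(bact, 3), 0)
  neg <- film_state(thickness = 100, coverage = 0.5, resonance_sign = -1)
  expect_lt(frequency_kernel(neg, 3), 0)
})
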