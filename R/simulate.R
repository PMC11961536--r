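#' Simulation parameters for a synthetic QCM-D phage assay
#'
#' Generative parameters for one simulated experiment. The defaults encode
#' the standard assay: a bacterial film adsorbs under flow, grows
#' logistically during the static phases, and at the second injection is
#' exposed to phage at a given titer. Infectious phage lyse an infected
#' fraction of the film after a latency (T7-like, 17 min), collapsing it to
#' thin, stiff envelope debris; survivors regrow. Non-infectious phage (and
#' plain-medium controls) leave growth intact.
#'
#' Two defaults are calibrations against the magnitudes the assay is
#' designed around rather than free choices: `phage_mass_amplitude` is
#' computed (when `NULL`) so that the noise-free third-overtone frequency
#' step across the injection window is -60 Hz at the reference titer
#' 8e7 PFU/mL, and the debris geometry (`h_debris`, `s_debris`) is set so
#' the normalized overtone-spread statistic drops by about 80% upon lysis.
#'
#' @param scenario `"control"` (plain medium, titer forced to 0),
#'   `"infectious"` or `"non_infectious"`.
#' @param titer Phage titer in PFU/mL. Defaults: 0 (control), 8e7
#'   (infectious, T7-like), 2e8 (non-infectious, phi29-like).
#' @param schedule A [phase_schedule()]; default [default_schedule()] (for a
#'   control the second injection is plain medium).
#' @param adsorption_rate Bacterial adsorption rate k_a during the bacteria
#'   injection, 1/min.
#' @param coverage_max Saturating fractional coverage reached by adsorption.
#' @param h_adsorb Effective film thickness at full adsorption, nm.
#' @param growth_rate Logistic growth rate r of film thickness during static
#'   phases, 1/min.
#' @param h_cap Logistic carrying thickness, nm.
#' @param latency Lytic latency tau after the start of phage exposure, min.
#' @param infection_rate_constant k_i of the Poisson encounter model, in
#'   mL/(PFU min); see [infection_fraction()].
#' @param collapse_time Exponential time constant of the post-lysis film
#'   collapse, min.
#' @param h_debris Effective thickness of fully collapsed envelope debris, nm.
#' @param s_debris Softness of the debris film, in [0, 1].
#' @param phage_adsorption_rate Rate constant k_m for phage mass uptake
#'   during the injection, mL/(PFU min).
#' @param phage_mass_amplitude Saturating rigid phage mass, ng/cm^2;
#'   `NULL` (default) triggers the -60 Hz calibration described above.
#' @param survivor_regrowth_boost Multiplier on `growth_rate` for the
#'   surviving fraction after lysis.
#' @param flush_loss Fractional loss of coverage/thickness over each flow
#'   phase (material sheared off by the pump).
#' @param phage_shock Extra transient fractional thickness loss over a
#'   phage-bearing injection (osmotic/crowding perturbation; recovered by
#'   regrowth in non-lytic scenarios).
#' @param amplitude_D,amplitude_f Kernel amplitudes passed to
#'   [dissipation_kernel()] and [frequency_kernel()].
#' @param sensor_sensitivity Multiplicative sensor factor lambda applied to
#'   both channels (drawn lognormally across replicates by
#'   [simulate_panel()]).
#' @param resonance_sign Coupled-resonance sign chi, +1 or -1.
#' @param noise_sd_f,noise_sd_D Gaussian measurement noise SDs (Hz and 1e-6
#'   units respectively).
#' @param dt Acquisition grid step, min.
#' @param f0 Fundamental frequency, Hz.
#' @param liquid Bulk [liquid_properties()].
#' @param seed Integer RNG seed for this experiment.
#' @return An object of class `"sim_params"`.
#' @export
sim_params <- function(scenario = c("control", "infectious", "non_infectious"),
                       titer = NULL,
                       schedule = NULL,
                       adsorption_rate = 0.15,
                       coverage_max = 0.8,
                       h_adsorb = 60,
                       growth_rate = 0.02,
                       h_cap = 250,
                       latency = 17,
                       infection_rate_constant = 4e-7,
                       collapse_time = 12,
                       h_debris = 95,
                       s_debris = 0.42,
                       phage_adsorption_rate = 1e-8,
                       phage_mass_amplitude = NULL,
                       survivor_regrowth_boost = 2,
                       flush_loss = 0.02,
                       phage_shock = 0.06,
                       amplitude_D = 250,
                       amplitude_f = 30,
                       sensor_sensitivity = 1,
                       resonance_sign = 1,
                       noise_sd_f = 0.5,
                       noise_sd_D = 0.05,
                       dt = 0.5,
                       f0 = 5e6,
                       liquid = water_properties(),
                       seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(titer)) {
    titer <- switch(scenario, control = 0, infectious = 8e7,
                    non_infectious = 2e8)
  }
  if (scenario == "control") titer <- 0
  if (is.null(schedule)) {
    schedule <- default_schedule(
      second_medium = if (scenario == "control") "medium" else "phage_in_medium")
  }
  stopifnot(inherits(schedule, "phase_schedule"))
  num_nonneg <- c(titer = titer, adsorption_rate = adsorption_rate,
                  h_adsorb = h_adsorb, growth_rate = growth_rate,
                  h_cap = h_cap, latency = latency,
                  infection_rate_constant = infection_rate_constant,
                  collapse_time = collapse_time, h_debris = h_debris,
                  phage_adsorption_rate = phage_adsorption_rate,
                  survivor_regrowth_boost = survivor_regrowth_boost,
                  amplitude_D = amplitude_D, amplitude_f = amplitude_f,
                  noise_sd_f = noise_sd_f, noise_sd_D = noise_sd_D)
  if (any(num_nonneg < 0)) {
    bad <- names(num_nonneg)[num_nonneg < 0]
    stop("sim_params fields must be >= 0: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (s_debris < 0 || s_debris > 1 || coverage_max < 0 || coverage_max > 1 ||
      flush_loss < 0 || flush_loss >= 1 || phage_shock < 0 || phage_shock >= 1) {
    stop("s_debris, coverage_max in [0,1]; flush_loss, phage_shock in [0,1)",
         call. = FALSE)
  }
  if (!resonance_sign %in% c(-1, 1)) {
    stop("resonance_sign must be +1 or -1", call. = FALSE)
  }
  if (dt <= 0 || sensor_sensitivity <= 0 || collapse_time <= 0) {
    stop("dt, sensor_sensitivity and collapse_time must be > 0", call. = FALSE)
  }
  if (is.null(phage_mass_amplitude)) {
    # calibrate: mass term of the n=3 frequency kernel reaches -60 Hz at the
    # end of a 8e7 PFU/mL injection of the scheduled duration
    inj <- phase_window(schedule, "second_injection")
    dur <- unname(inj["end"] - inj["start"])
    sat <- 1 - exp(-phage_adsorption_rate * 8e7 * dur)
    phage_mass_amplitude <- (60 * sauerbrey_constant(f0) / 3) / sat
  }
  structure(list(scenario = scenario, titer = titer, schedule = schedule,
                 adsorption_rate = adsorption_rate,
                 coverage_max = coverage_max, h_adsorb = h_adsorb,
                 growth_rate = growth_rate, h_cap = h_cap, latency = latency,
                 infection_rate_constant = infection_rate_constant,
                 collapse_time = collapse_time, h_debris = h_debris,
                 s_debris = s_debris,
                 phage_adsorption_rate = phage_adsorption_rate,
                 phage_mass_amplitude = phage_mass_amplitude,
                 survivor_regrowth_boost = survivor_regrowth_boost,
                 flush_loss = flush_loss, phage_shock = phage_shock,
                 amplitude_D = amplitude_D, amplitude_f = amplitude_f,
                 sensor_sensitivity = sensor_sensitivity,
                 resonance_sign = resonance_sign,
                 noise_sd_f = noise_sd_f, noise_sd_D = noise_sd_D,
                 dt = dt, f0 = f0, liquid = liquid, seed = as.integer(seed)),
            class = "sim_params")
}

#' Fraction of surface bacteria infected during phage exposure
#'
#' Poisson encounter model: p = 1 - exp(-k_i * titer * exposure). At high
#' titer essentially the whole film is infected within one exposure window;
#' at low titer a surviving fraction remains, which (once free phage are
#' flushed out) escapes infection and regrows.
#'
#' @param titer Phage titer, PFU/mL.
#' @param k_i Infection rate constant, mL/(PFU min).
#' @param exposure Exposure duration, min.
#' @return Infected fraction in [0, 1]; monotone in every argument.
#' @export
infection_fraction <- function(titer, k_i, exposure) {
  if (any(titer < 0) || any(k_i < 0) || any(exposure < 0)) {
    stop("infection_fraction requires non-negative arguments", call. = FALSE)
  }
  1 - exp(-k_i * titer * exposure)
}

#' Noise-free latent film trajectory
#'
#' Integrates the surface-film state on a uniform grid: coverage rises as a
#' saturating exponential during the bacterial injection; each flow phase
#' shears off a small multiplicative fraction; film thickness grows
#' logistically during static phases; rigid phage mass accumulates during a
#' phage-bearing second injection. For an infectious scenario, one latency
#' after exposure begins, an infected fraction p (from
#' [infection_fraction()] over the injection window) of the live film is
#' converted to debris that relaxes exponentially (time constant
#' `collapse_time`) toward the debris thickness, while the surviving live
#' film resumes logistic growth at a boosted rate. Softness is the
#' thickness-weighted mix of live (1) and debris (`s_debris`) material.
#'
#' @param params A [sim_params()].
#' @return An object of class `"film_trajectory"`: list with `time`, `h`,
#'   `s`, `m`, `theta`, the live/debris components `h_live`/`h_dead`, the
#'   infected fraction `p` and the lysis onset time `t_lysis` (NA when no
#'   lysis occurs).
#' @export
film_trajectory <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  sch <- params$schedule
  need <- c("bacteria_injection", "second_injection", "flush_2")
  if (!all(need %in% sch$name)) {
    stop("schedule error: phases required for simulation are missing: ",
         paste(setdiff(need, sch$name), collapse = ", "), call. = FALSE)
  }
  t0 <- min(sch$start); t_end <- max(sch$end)
  time <- seq(t0, t_end, by = params$dt)
  nt <- length(time)
  inj <- phase_window(sch, "second_injection")
  inj_dur <- unname(inj["end"] - inj["start"])

  lytic <- params$scenario == "infectious" && params$titer > 0
  p <- if (lytic) {
    infection_fraction(params$titer, params$infection_rate_constant, inj_dur)
  } else 0
  t_lysis <- if (lytic) unname(inj["start"]) + params$latency else NA_real_

  theta <- h_live <- h_dead <- m <- numeric(nt)
  th <- hl <- hd <- mm <- 0
  lysed <- FALSE
  theta[1L] <- h_live[1L] <- h_dead[1L] <- m[1L] <- 0

  # phase index of each grid point under the half-open convention
  phase_of <- function(t) {
    i <- findInterval(t, sch$start)
    i[i < 1L] <- 1L
    sch$name[pmin(i, nrow(sch))]
  }
  phases <- phase_of(time)
  dt <- params$dt

  for (i in seq_len(nt - 1L)) {
    ph <- phases[i]
    row <- sch[sch$name == ph, ]
    dur <- row$end - row$start
    flowing <- row$flow_rate > 0
    phage_on <- ph == "second_injection" && params$titer > 0

    if (ph == "bacteria_injection") {
      th <- params$coverage_max -
        (params$coverage_max - th) * exp(-params$adsorption_rate * dt)
      hl <- params$h_adsorb * th / max(params$coverage_max, 1e-12)
    } else if (flowing) {
      fac <- (1 - params$flush_loss)^(dt / dur)
      th <- th * fac
      hl <- hl * fac
      hd <- hd * fac
      if (phage_on) {
        shock <- (1 - params$phage_shock)^(dt / dur)
        hl <- hl * shock
      }
    } else {
      # static phase: logistic thickness growth of the live film
      r_eff <- params$growth_rate * if (lysed) params$survivor_regrowth_boost else 1
      hl <- hl + r_eff * hl * (1 - (hl + hd) / params$h_cap) * dt
    }

    if (phage_on) {
      mm <- params$phage_mass_amplitude *
        (1 - exp(-params$phage_adsorption_rate * params$titer *
                   (time[i + 1L] - unname(inj["start"]))))
    }

    if (lytic && !lysed && time[i + 1L] >= t_lysis) {
      hd <- hd + hl * p
      hl <- hl * (1 - p)
      lysed <- TRUE
    }
    if (lysed) {
      target <- params$h_debris * p
      hd <- target + (hd - target) * exp(-dt / params$collapse_time)
    }

    theta[i + 1L] <- th
    h_live[i + 1L] <- hl
    h_dead[i + 1L] <- hd
    m[i + 1L] <- mm
  }

  h <- h_live + h_dead
  s <- ifelse(h > 0, (h_live + params$s_debris * h_dead) / h, 1)
  structure(list(time = time, h = h, s = s, m = m, theta = theta,
                 h_live = h_live, h_dead = h_dead, p = p, t_lysis = t_lysis),
            class = "film_trajectory")
}

#' Simulate one multi-overtone QCM-D experiment
#'
#' Composes [film_trajectory()] with the acoustic kernels for overtones
#' 3, 5, 7, 9, 11, scales both channels by the sensor sensitivity and adds
#' independent Gaussian measurement noise per channel and overtone. The
#' global RNG state is preserved; an identical `params` (including its seed)
#' always yields a bit-identical experiment. With both noise SDs zero the
#' output equals the kernels applied to the latent trajectory exactly.
#'
#' @param params A [sim_params()].
#' @return A [qcmd_experiment()] with the scenario recorded in `label`.
#' @export
simulate_experiment <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  traj <- film_trajectory(params)
  nt <- length(traj$time)
  film <- film_state(thickness = traj$h, softness = traj$s,
                     rigid_mass = traj$m, coverage = traj$theta,
                     resonance_sign = params$resonance_sign)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(params$seed)
  lam <- params$sensor_sensitivity
  traces <- lapply(c(3L, 5L, 7L, 9L, 11L), function(n) {
    df <- lam * frequency_kernel(film, n, params$f0, params$amplitude_f)
    dD <- lam * dissipation_kernel(film, n, params$f0, params$liquid,
                                   params$amplitude_D)
    if (params$noise_sd_f > 0) df <- df + stats::rnorm(nt, 0, params$noise_sd_f)
    if (params$noise_sd_D > 0) dD <- dD + stats::rnorm(nt, 0, params$noise_sd_D)
    overtone_trace(n, traj$time, df, dD)
  })
  qcmd_experiment(traces, params$schedule,
                  sensor_id = sprintf("sim-%s-%d", params$scenario, params$seed),
                  fundamental_frequency = params$f0, label = params$scenario)
}

#' Simulate a replicate panel with per-sensor variability
#'
#' Runs [simulate_experiment()] for each design entry with a per-replicate
#' seed derived deterministically from `master_seed`. To emulate
#' sensor-to-sensor variability, each replicate's sensitivity lambda is drawn
#' lognormal(0, 0.15^2) and its coupled-resonance sign chi is +1 or -1 with
#' equal probability (disable with `draw_sensor_effects = FALSE` to honour
#' the per-entry values).
#'
#' @param design Non-empty list of [sim_params()] objects.
#' @param master_seed Integer master seed.
#' @param draw_sensor_effects Draw lambda and chi per replicate (default
#'   TRUE).
#' @return List of [qcmd_experiment()] objects (ground truth in each
#'   experiment's `label`).
#' @export
simulate_panel <- function(design, master_seed = 1L,
                           draw_sensor_effects = TRUE) {
  if (!is.list(design) || length(design) == 0L ||
      !all(vapply(design, inherits, logical(1), "sim_params"))) {
    stop("design must be a non-empty list of sim_params objects",
         call. = FALSE)
  }
  n <- length(design)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(master_seed))
  seeds <- sample.int(2147483646L, n)
  lambdas <- stats::rlnorm(n, 0, 0.15)
  chis <- sample(c(-1, 1), n, replace = TRUE)
  lapply(seq_len(n), function(i) {
    p <- design[[i]]
    p$seed <- seeds[i]
    if (draw_sensor_effects) {
      p$sensor_sensitivity <- lambdas[i]
      p$resonance_sign <- chis[i]
    }
    simulate_experiment(p)
  })
}

#' Standard screening panel design
#'
#' The default replicate collection the pipeline is exercised on: bacteria-
#' only controls, infectious (T7-like) arms at titers spanning 8e7 down to
#' 4e5 PFU/mL, and a non-infectious (phi29-like) arm at 2e8 PFU/mL.
#'
#' @param n_control Number of plain-medium control replicates.
#' @param infectious_titers Titers (PFU/mL), one infectious replicate each;
#'   recycled if `n_infectious` exceeds its length.
#' @param n_infectious Total infectious replicates.
#' @param n_non_infectious Number of non-infectious replicates.
#' @param ... Common overrides passed to every [sim_params()] call.
#' @return A list of [sim_params()] suitable for [simulate_panel()].
#' @export
standard_panel_design <- function(n_control = 2,
                                  infectious_titers = c(8e7, 2e6, 4e5),
                                  n_infectious = length(infectious_titers),
                                  n_non_infectious = 1, ...) {
  titers <- rep_len(infectious_titers, n_infectious)
  c(
    lapply(seq_len(n_control), function(i) sim_params("control", ...)),
    lapply(titers, function(tt) sim_params("infectious", titer = tt, ...)),
    lapply(seq_len(n_non_infectious),
           function(i) sim_params("non_infectious", ...))
  )
}
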