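#' Liquid properties for shear-wave calculations
#'
#' Bundle of dynamic viscosity and density used by [penetration_depth()] and
#' the dissipation kernel.
#'
#' @param viscosity Dynamic viscosity in Pa s. Must be > 0.
#' @param density Density in kg/m^3. Must be > 0.
#' @return An object of class `"liquid_properties"`.
#' @seealso [water_properties()] for the shipped presets.
#' @export
liquid_properties <- function(viscosity, density) {
  stopifnot(is.numeric(viscosity), length(viscosity) == 1L,
            is.numeric(density), length(density) == 1L)
  if (viscosity <= 0 || density <= 0) {
    stop("liquid viscosity and density must be strictly positive", call. = FALSE)
  }
  structure(list(viscosity = viscosity, density = density),
            class = "liquid_properties")
}

#' Water property presets
#'
#' Two presets for aqueous media: water at 25 C (eta = 8.9e-4 Pa s,
#' rho = 997 kg/m^3) and water at 37 C (eta = 6.92e-4 Pa s,
#' rho = 993.3 kg/m^3). The 25 C preset is the package default; it reproduces
#' the conventional ~140 nm / ~70 nm penetration depths quoted for the third
#' and eleventh overtones of a 5 MHz sensor in an aqueous medium. The 37 C
#' preset (assay temperature for E. coli work) gives ~122 nm / ~64 nm instead.
#'
#' @param temperature `"25C"` (default) or `"37C"`.
#' @return A [liquid_properties()] object.
#' @export
water_properties <- function(temperature = c("25C", "37C")) {
  temperature <- match.arg(temperature)
  switch(temperature,
         "25C" = liquid_properties(viscosity = 8.9e-4, density = 997),
         "37C" = liquid_properties(viscosity = 6.92e-4, density = 993.3))
}

#' Acoustic shear-wave penetration depth
#'
#' Decay length of the thickness-shear wave launched by a quartz resonator
#' into a Newtonian liquid at overtone n of fundamental frequency f0:
#'
#'   delta_n = sqrt(eta / (pi * n * f0 * rho))
#'
#' The depth falls as 1/sqrt(n): higher overtones probe a thinner region
#' above the sensor, which is what makes the spread between dissipation
#' overtones sensitive to the effective thickness of a bacterial film.
#'
#' @param n Overtone number (odd positive integer for real sensors; any
#'   value >= 1 is accepted). May be a vector.
#' @param f0 Fundamental resonance frequency in Hz (default 5 MHz).
#' @param liquid A [liquid_properties()] object. Default: water at 25 C.
#' @return Penetration depth(s) in nm.
#' @examples
#' penetration_depth(3)   # ~138 nm
#' penetration_depth(11)  # ~72 nm
#' @export
penetration_depth <- function(n, f0 = 5e6, liquid = water_properties()) {
  stopifnot(inherits(liquid, "liquid_properties"))
  if (any(n < 1) || f0 <= 0) {
    stop("penetration_depth requires n >= 1 and f0 > 0", call. = FALSE)
  }
  sqrt(liquid$viscosity / (pi * n * f0 * liquid$density)) * 1e9
}

#' Sauerbrey mass sensitivity constant
#'
#' C = sqrt(rho_q * mu_q) / (2 * f0^2), converted to ng cm^-2 Hz^-1.
#' For AT-cut quartz at 5 MHz this is the familiar ~17.7 ng cm^-2 Hz^-1.
#'
#' @param f0 Fundamental frequency in Hz.
#' @param rho_q Quartz density, kg/m^3.
#' @param mu_q Quartz shear modulus, Pa.
#' @return Mass sensitivity in ng cm^-2 Hz^-1.
#' @export
sauerbrey_constant <- function(f0 = 5e6, rho_q = 2648, mu_q = 2.947e10) {
  if (f0 <= 0) stop("f0 must be positive", call. = FALSE)
  # kg m^-2 Hz^-1 -> ng cm^-2 Hz^-1 is a factor 1e8
  sqrt(rho_q * mu_q) / (2 * f0^2) * 1e8
}

#' Sauerbrey areal mass from a frequency shift
#'
#' Rigid-film limit: Delta m = -C * Delta f_n / n. The sign convention means
#' mass uptake (negative Delta f) gives a positive mass change. Only valid
#' for thin rigid films; adhering bacteria violate it (see
#' [frequency_kernel()] for the coupled-resonance term).
#'
#' @param delta_f Frequency shift(s) at overtone `n`, in Hz (raw, not divided
#'   by overtone number).
#' @param n Overtone number.
#' @param f0 Fundamental frequency in Hz.
#' @return Areal mass change(s) in ng/cm^2.
#' @export
sauerbrey_mass <- function(delta_f, n, f0 = 5e6) {
  if (any(n < 1)) stop("overtone number must be >= 1", call. = FALSE)
  -sauerbrey_constant(f0) * delta_f / n
}

#' Effective film state above the sensor
#'
#' Latent surface state consumed by the dissipation and frequency kernels.
#' Fields may be equal-length vectors (a trajectory sampled on a grid) or
#' scalars.
#'
#' @param thickness Effective film thickness h in nm (>= 0). For a bacterial
#'   lawn this is an acoustically effective thickness, not the cell diameter.
#' @param softness Dimensionless softness s in [0, 1]; 1 for live,
#'   water-filled cells, small for collapsed envelope debris.
#' @param rigid_mass Rigidly coupled areal mass m in ng/cm^2 (>= 0), e.g.
#'   adsorbed phage particles.
#' @param coverage Fractional surface coverage theta in [0, 1].
#' @param resonance_sign Sensor-specific sign chi of the coupled-resonance
#'   frequency response, +1 or -1.
#' @return An object of class `"film_state"`.
#' @export
film_state <- function(thickness = 0, softness = 1, rigid_mass = 0,
                       coverage = 0, resonance_sign = 1) {
  lens <- c(length(thickness), length(softness), length(rigid_mass),
            length(coverage))
  nmax <- max(lens)
  if (!all(lens %in% c(1L, nmax))) {
    stop("film_state fields must be scalars or equal-length vectors",
         call. = FALSE)
  }
  if (any(thickness < 0) || any(rigid_mass < 0) ||
      any(softness < 0) || any(softness > 1) ||
      any(coverage < 0) || any(coverage > 1) ||
      !all(resonance_sign %in% c(-1, 1))) {
    stop("invalid film_state: need h >= 0, m >= 0, s and theta in [0, 1], chi in {-1, +1}",
         call. = FALSE)
  }
  structure(list(thickness = thickness, softness = softness,
                 rigid_mass = rigid_mass, coverage = coverage,
                 resonance_sign = resonance_sign),
            class = "film_state")
}

#' Overtone-dependent dissipation kernel
#'
#' Phenomenological closed-form mapping from film state to the dissipation
#' shift at overtone n:
#'
#'   DeltaD_n = A_D * s * theta * delta_n * (1 - exp(-h / delta_n)) / delta_3
#'
#' The bracket is the "sensed thickness": the part of the film lying within
#' one penetration depth of the sensor. Because delta_n shrinks with n, a
#' thick soft film loads the low overtones more than the high ones, so the
#' overtone spread DeltaD_3 - DeltaD_11 grows monotonically with film
#' thickness — the physical basis of the lysis statistic. This is a declared
#' surrogate for full continuum (Voigt-type) viscoelastic modelling: it
#' reproduces the qualitative overtone ordering while staying closed-form.
#'
#' @param film A [film_state()] (fields may be vectors).
#' @param n Overtone number.
#' @param f0 Fundamental frequency, Hz.
#' @param liquid [liquid_properties()] of the bulk medium.
#' @param amplitude A_D, the saturation dissipation amplitude in 1e-6 units
#'   for a fully soft, fully covering, infinitely thick film at n = 3.
#' @return DeltaD_n in 1e-6 units (same length as the film trajectory).
#' @export
dissipation_kernel <- function(film, n, f0 = 5e6,
                               liquid = water_properties(), amplitude = 250) {
  stopifnot(inherits(film, "film_state"))
  if (amplitude < 0) stop("dissipation amplitude must be >= 0", call. = FALSE)
  delta_n <- penetration_depth(n, f0, liquid)
  delta_3 <- penetration_depth(3, f0, liquid)
  sensed <- delta_n * (1 - exp(-film$thickness / delta_n))
  amplitude * film$softness * film$coverage * sensed / delta_3
}

#' Overtone-dependent frequency kernel
#'
#' Two additive loads:
#'
#'   Deltaf_n = -(n / C) * m + chi * A_f * theta * n / 3
#'
#' The first term is Sauerbrey loading by the rigidly coupled mass m (e.g.
#' adsorbed phage). The second is a coupled-resonance term for discrete
#' adhering bacteria, linear in coverage with a per-sensor sign chi: bacteria
#' behave as coupled resonators rather than a rigid layer, which is why
#' positive frequency shifts are routinely seen during bacterial adhesion
#' and why Deltaf alone is an unreliable cell count.
#'
#' @param film A [film_state()].
#' @param n Overtone number.
#' @param f0 Fundamental frequency, Hz.
#' @param amplitude A_f, coupled-resonance amplitude in Hz at n = 3 and full
#'   coverage.
#' @return Deltaf_n in Hz (raw, not overtone-normalized).
#' @export
frequency_kernel <- function(film, n, f0 = 5e6, amplitude = 30) {
  stopifnot(inherits(film, "film_state"))
  C <- sauerbrey_constant(f0)
  -(n / C) * film$rigid_mass +
    film$resonance_sign * amplitude * film$coverage * n / 3
}
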