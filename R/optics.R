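# Graaff power-law approximation to Mie scattering and its analytic
# sensitivities. All closed forms; lengths are handled in cm internally,
# with radii in um and wavelengths in um at this API.

GRAAFF_PREFACTOR <- 3.28
GRAAFF_SIZE_EXP <- 0.37
GRAAFF_INDEX_EXP <- 2.09
UM_PER_CM <- 1e4

#' Mie size parameter and Graaff-regime flag
#'
#' Computes the size parameter `x = 2*pi*a / lambda` for a spherical scatterer
#' and flags whether it falls in the regime `5 < x < 50` for which the Graaff
#' power-law cross-section was originally derived. Sub-micron lipid droplets
#' probed at 1000-1700 nm sit at `x ~ 2-3`, outside that window; the flag
#' reports this but the model functions still evaluate (see Details).
#'
#' @details The power-law form is routinely applied to Intralipid-like media
#'   below the nominal regime; out-of-regime use is therefore reported as a
#'   flag, never an error.
#'
#' @param radius_um Particle radius in micrometres (> 0), vectorised.
#' @param wavelength_um Wavelength in micrometres (> 0), vectorised.
#' @return A tibble with columns `radius_um`, `wavelength_um`,
#'   `size_parameter`, and logical `graaff_regime`.
#' @export
#' @examples
#' size_parameter(0.5, 1.0)
size_parameter <- function(radius_um, wavelength_um) {
  stop_if_not_positive(radius_um, "radius_um")
  stop_if_not_positive(wavelength_um, "wavelength_um")
  x <- 2 * pi * radius_um / wavelength_um
  tibble::tibble(
    radius_um = radius_um + 0 * x,
    wavelength_um = wavelength_um + 0 * x,
    size_parameter = x,
    graaff_regime = x > 5 & x < 50
  )
}

check_relative_index <- function(m) {
  if (any(!is.finite(m)) || any(m < 1)) {
    abort("relative refractive index `m` must be >= 1 (scattering model holds for m > 1).",
      class = "turbispec_out_of_model"
    )
  }
  invisible(m)
}

#' Reduced scattering cross-section of a single sphere (Graaff approximation)
#'
#' `sigma_s' = 3.28 * pi * a^2 * (2*pi*a/lambda)^0.37 * (m - 1)^2.09`, the
#' anisotropy-corrected scattering cross-section of a sphere of radius `a` and
#' relative refractive index `m = n_in / n_ex`. Returns square micrometres.
#' At `m = 1` the particle is index-matched and the cross-section is exactly 0.
#'
#' @inheritParams size_parameter
#' @param m Relative refractive index `n_in / n_ex` (>= 1), vectorised.
#' @return Reduced scattering cross-section(s) in um^2.
#' @export
#' @examples
#' reduced_scattering_cross_section(0.5, 1.0, 1.468 / 1.327)
reduced_scattering_cross_section <- function(radius_um, wavelength_um, m) {
  stop_if_not_positive(radius_um, "radius_um")
  stop_if_not_positive(wavelength_um, "wavelength_um")
  check_relative_index(m)
  x <- 2 * pi * radius_um / wavelength_um
  GRAAFF_PREFACTOR * pi * radius_um^2 * x^GRAAFF_SIZE_EXP * (m - 1)^GRAAFF_INDEX_EXP
}

#' Reduced scattering coefficient of a monodisperse sphere suspension
#'
#' `mu_s' = 2.46 * (phi / a) * (2*pi*a/lambda)^0.37 * (m - 1)^2.09` in cm^-1,
#' i.e. the single-sphere cross-section scaled by the number density
#' `3*phi / (4*pi*a^3)` of a suspension with volume fraction `phi`. The two
#' routes agree to machine precision and the cross-section route is kept as an
#' internal consistency check in the test-suite.
#'
#' @inheritParams reduced_scattering_cross_section
#' @param phi Scatterer volume fraction, in (0, 1), vectorised.
#' @return Reduced scattering coefficient(s) in cm^-1.
#' @export
#' @examples
#' # a 3% Intralipid-like suspension at 1 um
#' reduced_scattering_coefficient(0.03237, 0.5, 1.0, 1.468 / 1.327)
reduced_scattering_coefficient <- function(phi, radius_um, wavelength_um, m) {
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi >= 1)) {
    abort("`phi` must be a volume fraction in [0, 1).", class = "turbispec_invalid_argument")
  }
  stop_if_not_positive(radius_um, "radius_um")
  stop_if_not_positive(wavelength_um, "wavelength_um")
  check_relative_index(m)
  x <- 2 * pi * radius_um / wavelength_um
  2.46 * (phi / (radius_um / UM_PER_CM)) * x^GRAAFF_SIZE_EXP * (m - 1)^GRAAFF_INDEX_EXP
}

#' Analytic sensitivities of the reduced scattering coefficient
#'
#' Closed-form derivatives of `mu_s'` with respect to the background
#' refractive index `n_ex` (how dissolved glucose or salt acts), the scatterer
#' volume fraction `phi` (particle density), and the particle radius `a`
#' (particle size):
#'
#' * `dmus_dnex = -2.09 * mu_s' * n_in / n_ex^2 / (m - 1)` (cm^-1 per RIU)
#' * `dmus_dphi =  mu_s' / phi` (cm^-1 per unit volume fraction)
#' * `dmus_da_per_um = -0.63 * mu_s' / a` (cm^-1 per um)
#'
#' For a relatively refracting particle (`m > 1`) raising the background index
#' lowers scattering, adding particles raises it, and growing the (already
#' large, `x > 1`) particles at fixed volume fraction lowers it.
#'
#' @inheritParams reduced_scattering_coefficient
#' @param n_in Refractive index inside the particles (> 1).
#' @param n_ex Background (solution) refractive index (> 1); must not exceed
#'   `n_in`.
#' @return A tibble with columns `wavelength_um`, `mus_prime`, `dmus_dnex`,
#'   `dmus_dphi`, `dmus_da_per_um`.
#' @export
#' @examples
#' scattering_sensitivities(0.03237, 0.5, 1.0, n_in = 1.468, n_ex = 1.327)
scattering_sensitivities <- function(phi, radius_um, wavelength_um, n_in, n_ex) {
  stop_if_not_positive(n_in - 1, "n_in - 1")
  stop_if_not_positive(n_ex - 1, "n_ex - 1")
  m <- n_in / n_ex
  if (any(m <= 1)) {
    abort("sensitivities require m = n_in/n_ex > 1.", class = "turbispec_out_of_model")
  }
  mus <- reduced_scattering_coefficient(phi, radius_um, wavelength_um, m)
  tibble::tibble(
    wavelength_um = wavelength_um + 0 * mus,
    mus_prime = mus,
    dmus_dnex = -GRAAFF_INDEX_EXP * mus * n_in / n_ex^2 / (m - 1),
    dmus_dphi = mus / phi,
    dmus_da_per_um = -GRAAFF_SIZE_EXP_COMPLEMENT * mus / radius_um
  )
}

# 1 - 0.37: the radius exponent of mu_s' ~ phi * a^-0.63 * lambda^-0.37
GRAAFF_SIZE_EXP_COMPLEMENT <- 1 - GRAAFF_SIZE_EXP

#' Perturbations of different factors matched in |delta mu_s'|
#'
#' Given a target change of the reduced scattering coefficient at one
#' wavelength, returns the first-order magnitude of each physical factor —
#' glucose (mM), NaCl (mM), scatterer volume fraction, particle radius — that
#' alone produces that `|delta mu_s'|`. Solutes act through the background
#' refractive index at their molar refraction increments (`dn_ex/dC`); density
#' and size act directly.
#'
#' The sign column reports the direction of the factor change that reproduces
#' the *sign* of `target_dmus`: a positive `delta mu_s'` needs more particles
#' (`+phi`), smaller particles (`-a`), or a lower background index, i.e. a
#' *decrease* of solute concentration.
#'
#' @param target_dmus Target change in `mu_s'` (cm^-1), any sign; 0 gives all
#'   magnitudes 0.
#' @inheritParams scattering_sensitivities
#' @param dn_per_mM Named numeric: refractive-index increment (RIU per mM) of
#'   each solute. Defaults to aqueous glucose (`2.5e-5`) and NaCl
#'   (`0.98e-5`).
#' @return A tibble with columns `factor`, `magnitude`, `unit`, `amount_sign`.
#' @export
#' @examples
#' sens <- scattering_sensitivities(0.03237, 0.5, 1.0, 1.468, 1.327)
#' equivalent_perturbations(sens$dmus_dphi * 1.37e-5, 0.03237, 0.5, 1.0, 1.468, 1.327)
equivalent_perturbations <- function(target_dmus, phi, radius_um, wavelength_um,
                                     n_in, n_ex,
                                     dn_per_mM = c(glucose = 2.5e-5, nacl = 0.98e-5)) {
  stopifnot(is.finite(target_dmus), length(target_dmus) == 1)
  s <- scattering_sensitivities(phi, radius_um, wavelength_um, n_in, n_ex)
  sens <- c(
    vapply(dn_per_mM, function(dn) s$dmus_dnex * dn, numeric(1)),
    particle_density = s$dmus_dphi,
    particle_size = s$dmus_da_per_um
  )
  if (any(sens == 0)) {
    abort("a requested factor has zero scattering sensitivity (degenerate configuration).",
      class = "turbispec_degenerate_configuration"
    )
  }
  units <- c(rep("mM", length(dn_per_mM)), "volume fraction", "um")
  tibble::tibble(
    factor = names(sens),
    magnitude = unname(abs(target_dmus / sens)),
    unit = units,
    amount_sign = if (target_dmus == 0) rep(0, length(sens)) else sign(target_dmus) * sign(unname(sens))
  )
}
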