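# Semi-infinite diffusion-theory reflectance (two-dipole Green's function
# with extrapolated boundary) and the absorbance -> differential absorbance
# -> effective-attenuation-coefficient chain.

#' Diffusion-theory state of a homogeneous semi-infinite medium
#'
#' Derived quantities of the diffusion approximation:
#' `mu_eff = sqrt(3 * mu_a * (mu_a + mu_s'))` (the effective attenuation
#' coefficient, EAC), diffusion length `D = 1 / (3 * (mu_a + mu_s'))`,
#' isotropic-source depth `z0 = 1 / mu_s'` and extrapolated-boundary mirror
#' offset `zb = 2 * D`. All in cm / cm^-1.
#'
#' @param mu_a Absorption coefficient(s), cm^-1, > 0.
#' @param mu_s_prime Reduced scattering coefficient(s), cm^-1, > 0.
#' @return A `diffusion_state` tibble with columns `mu_a`, `mu_s_prime`,
#'   `mu_eff`, `D`, `z0`, `zb`.
#' @export
#' @examples
#' diffusion_state(1, 9) # mu_eff = sqrt(30)
diffusion_state <- function(mu_a, mu_s_prime) {
  stop_if_not_positive(mu_a, "mu_a")
  stop_if_not_positive(mu_s_prime, "mu_s_prime")
  mu_t <- mu_a + mu_s_prime
  out <- tibble::tibble(
    mu_a = mu_a + 0 * mu_t,
    mu_s_prime = mu_s_prime + 0 * mu_t,
    mu_eff = sqrt(3 * mu_a * mu_t),
    D = 1 / (3 * mu_t),
    z0 = 1 / (mu_s_prime + 0 * mu_t),
    zb = 2 / (3 * mu_t)
  )
  class(out) <- c("diffusion_state", class(out))
  out
}

#' Is the diffusion approximation trustworthy here?
#'
#' The closed form degrades when the detector sits within a few transport mean
#' free paths of the source or when absorption rivals scattering (e.g. the
#' 1450 nm water band). Flags points with separation at least `3 * z0` and
#' `mu_a <= mu_s'`.
#'
#' @param state A [diffusion_state()].
#' @param r_cm Source-detector separation(s), cm.
#' @return Logical vector.
#' @export
diffusion_regime_ok <- function(state, r_cm) {
  r_cm >= 3 * state$z0 & state$mu_a <= state$mu_s_prime
}

#' Diffuse reflectance of a semi-infinite medium (two-dipole closed form)
#'
#' Radially resolved diffuse reflectance per unit area,
#' `I(r)/I0 = (1/4pi) * sum` over the real source at depth `z0` and its
#' mirror image at `-(z0 + 2*zb)`, each contributing
#' `z * (mu_eff + 1/rho) * exp(-mu_eff * rho) / rho^2` with
#' `rho = sqrt(r^2 + z^2)`. Strictly positive for any positive separation;
#' the returned quantity is a ratio to the incident power, per cm^2.
#'
#' A warning (class `turbispec_regime_warning`) is emitted when any requested
#' point falls outside [diffusion_regime_ok()]; the value is still returned.
#'
#' @inheritParams diffusion_regime_ok
#' @param quiet Suppress the regime warning.
#' @return Numeric reflectance ratio(s), cm^-2.
#' @export
#' @examples
#' s <- diffusion_state(0.1, 10)
#' reflectance(s, c(0.08, 0.2))
reflectance <- function(state, r_cm, quiet = FALSE) {
  stopifnot(inherits(state, "diffusion_state"))
  stop_if_not_positive(r_cm, "r_cm")
  if (!quiet && !all(diffusion_regime_ok(state, r_cm))) {
    warn("some points lie outside the diffusion-approximation comfort zone (r < 3*z0 or mu_a > mu_s').",
      class = "turbispec_regime_warning"
    )
  }
  z0 <- state$z0
  zpos <- z0 + 2 * state$zb
  mu <- state$mu_eff
  r1 <- sqrt(r_cm^2 + z0^2)
  r2 <- sqrt(r_cm^2 + zpos^2)
  (z0 * (mu + 1 / r1) * exp(-mu * r1) / r1^2 +
    zpos * (mu + 1 / r2) * exp(-mu * r2) / r2^2) / (4 * pi)
}

#' Natural-log absorbance of an intensity ratio
#'
#' `A = -ln(I/I0)`. Note the natural logarithm: this package's absorbance
#' units are `ln`-based throughout, not the base-10 convention common on
#' bench spectrometers (divide by `ln(10) ~ 2.3026` to convert).
#'
#' @param intensity_ratio Positive ratio(s) `I/I0`.
#' @return Absorbance(s), a.u.
#' @export
absorbance <- function(intensity_ratio) {
  stop_if_not_positive(intensity_ratio, "intensity_ratio")
  -log(intensity_ratio)
}

#' Construct absorbance records
#'
#' @param wavelength_nm,sds_cm,A Equal-length vectors: wavelength (nm),
#'   source-detector separation (cm, > 0) and natural-log absorbance.
#' @return An `absorbance_record` tibble.
#' @export
absorbance_record <- function(wavelength_nm, sds_cm, A) {
  stop_if_not_positive(sds_cm, "sds_cm")
  stopifnot(all(is.finite(A)))
  out <- tibble::tibble(wavelength_nm = wavelength_nm, sds_cm = sds_cm, A = A)
  class(out) <- c("absorbance_record", class(out))
  out
}

#' Differential absorbance between two separations
#'
#' `AD = A(r_far) - A(r_near) = ln[I(r_near) / I(r_far)]` with
#' `r_far > r_near`, computed per wavelength. Differencing two separations
#' cancels source power and detector gain; `AD` is positive for a decaying
#' radial profile and grows roughly like `mu_eff * (r_far - r_near)`.
#'
#' @param rec_far,rec_near [absorbance_record()]s on the same wavelength grid
#'   with `rec_far$sds_cm > rec_near$sds_cm` row-wise.
#' @return A `differential_absorbance` tibble with columns `wavelength_nm`,
#'   `r_near_cm`, `r_far_cm`, `AD`.
#' @export
differential_absorbance <- function(rec_far, rec_near) {
  stopifnot(inherits(rec_far, "absorbance_record"), inherits(rec_near, "absorbance_record"))
  if (!isTRUE(all.equal(rec_far$wavelength_nm, rec_near$wavelength_nm))) {
    abort("records must share one wavelength grid.", class = "turbispec_invalid_argument")
  }
  if (any(rec_far$sds_cm <= rec_near$sds_cm)) {
    abort("`rec_far` must be at the larger separation.", class = "turbispec_invalid_argument")
  }
  out <- tibble::tibble(
    wavelength_nm = rec_far$wavelength_nm,
    r_near_cm = rec_near$sds_cm,
    r_far_cm = rec_far$sds_cm,
    AD = rec_far$A - rec_near$A
  )
  class(out) <- c("differential_absorbance", class(out))
  out
}

#' Change of the effective attenuation coefficient from differential absorbance
#'
#' The working approximation of the whole analysis: between two states of the
#' medium, `delta mu_eff ~ [AD_perturbed - AD_baseline] / (r_far - r_near)`.
#' The geometric (non-exponential) factors of the dipole solution are nearly
#' state-independent and cancel in the double difference, so what remains is
#' the change in the exponential decay rate.
#'
#' @param ad_perturbed,ad_baseline [differential_absorbance()] tibbles on the
#'   same wavelength grid and separation pair.
#' @return A tibble with columns `wavelength_nm`, `r_near_cm`, `r_far_cm`,
#'   `delta_mu_eff` (cm^-1).
#' @export
eac_change <- function(ad_perturbed, ad_baseline) {
  stopifnot(
    inherits(ad_perturbed, "differential_absorbance"),
    inherits(ad_baseline, "differential_absorbance")
  )
  same <- isTRUE(all.equal(ad_perturbed$wavelength_nm, ad_baseline$wavelength_nm)) &&
    isTRUE(all.equal(ad_perturbed$r_near_cm, ad_baseline$r_near_cm)) &&
    isTRUE(all.equal(ad_perturbed$r_far_cm, ad_baseline$r_far_cm))
  if (!same) {
    abort("differential absorbances must share wavelengths and separation pair.",
      class = "turbispec_invalid_argument"
    )
  }
  if (any(ad_perturbed$r_far_cm == ad_perturbed$r_near_cm)) {
    abort("separations must differ.", class = "turbispec_invalid_argument")
  }
  tibble::tibble(
    wavelength_nm = ad_perturbed$wavelength_nm,
    r_near_cm = ad_perturbed$r_near_cm,
    r_far_cm = ad_perturbed$r_far_cm,
    delta_mu_eff = (ad_perturbed$AD - ad_baseline$AD) /
      (ad_perturbed$r_far_cm - ad_perturbed$r_near_cm)
  )
}
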