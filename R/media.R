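# Synthetic-medium stage: builds the Intralipid-like phantom spectra the
# analysis assumes, the factor perturbations, and instrument-like absorbance
# noise. The packaged water absorption table is a synthetic smooth curve
# anchored at literature-scale values, not a measured dataset; every curve
# here is overridable through the dispersion config.

INTRALIPID_PHI_3PCT <- 0.03237
GLUCOSE_DN_PER_MM <- 2.5e-5
NACL_DN_PER_MM <- 0.98e-5
GLUCOSE_EPS_PLATEAU <- 0.00065 # cm^-1 per mM on 1500-1600 nm

the_water_table <- new.env(parent = emptyenv())

water_absorption_table <- function() {
  if (is.null(the_water_table$tab)) {
    path <- system.file("extdata", "water_absorption_synthetic.csv", package = "turbispec")
    the_water_table$tab <- read.csv(path)
  }
  the_water_table$tab
}

#' Pure-water NIR absorption coefficient (packaged synthetic table)
#'
#' Linear interpolation of the packaged 10 nm-grid table spanning
#' 1000-1700 nm. The table is a smooth synthetic emulation of the pure-water
#' spectrum — 0.36 cm^-1 at 1000 nm, the strong band peaking near 1450 nm at
#' ~29.5 cm^-1, falling to ~6.7 cm^-1 by 1600 nm — not a literature data set.
#'
#' @param wavelength_nm Wavelengths in nm, within the table support.
#' @return Absorption coefficient(s) in cm^-1.
#' @export
water_absorption <- function(wavelength_nm) {
  tab <- water_absorption_table()
  rng <- range(tab$wavelength_nm)
  if (any(wavelength_nm < rng[1] | wavelength_nm > rng[2])) {
    abort(sprintf("wavelength outside the packaged water table support [%d, %d] nm.", rng[1], rng[2]),
      class = "turbispec_range_error"
    )
  }
  stats::approx(tab$wavelength_nm, tab$mua_per_cm, xout = wavelength_nm)$y
}

#' Default dispersion and anisotropy configuration
#'
#' The spectra the medium builder needs but that are not part of the scatterer
#' geometry: background (water) refractive-index dispersion as a packaged
#' three-coefficient empirical fit `n_ex = A + B/lambda^2 + C*lambda^2`
#' (lambda in um, ~1.32-1.33 over the band), particle interior index as a
#' constant soybean-oil offset `n_in = n_ex + 0.14`, the water volume fraction
#' weighting the background absorption, and a linear-in-wavelength anisotropy
#' model `g = clamp(1.1 - 0.58*lambda_um, 0.2, 0.9)` typical of Intralipid.
#' Every element may be overridden.
#'
#' @return A named list understood by [intralipid_medium()].
#' @export
default_dispersion <- function() {
  list(
    n_ex_coef = c(A = 1.3253, B = 0.0060, C = -0.0047),
    n_in_offset = 0.14,
    water_fraction = 0.97,
    g_intercept = 1.1,
    g_slope_per_um = -0.58,
    g_min = 0.2,
    g_max = 0.9
  )
}

n_ex_of <- function(wavelength_um, disp) {
  co <- disp$n_ex_coef
  unname(co["A"] + co["B"] / wavelength_um^2 + co["C"] * wavelength_um^2)
}

g_of <- function(wavelength_um, disp) {
  pmin(pmax(disp$g_intercept + disp$g_slope_per_um * wavelength_um, disp$g_min), disp$g_max)
}

#' Build an Intralipid-like medium spectrum
#'
#' Constructs the per-wavelength optical state of a diluted Intralipid
#' suspension: scatterer volume fraction scales linearly with the nominal
#' concentration (`phi = 0.03237` at 3%), `mu_s'` follows the Graaff power
#' law with the configured dispersion, `mu_a` is the water-fraction-weighted
#' background absorption, and `mu_s = mu_s' / (1 - g)`.
#'
#' @param concentration_pct Nominal Intralipid concentration in percent
#'   (3 by default; 0 gives a non-scattering water background).
#' @param wavelength_nm Wavelength grid in nm within the packaged table
#'   support (default 1000-1660 nm, 10 nm steps).
#' @param radius_um Scatterer (oil droplet) radius in um; default 0.5.
#' @param dispersion Configuration list, see [default_dispersion()].
#' @return A `medium_spectrum` tibble with columns `wavelength_nm`, `n_ex`,
#'   `n_in`, `mu_a`, `mu_s_prime`, `g`, `mu_s`; the scatterer geometry is
#'   carried in attributes.
#' @export
#' @examples
#' m <- intralipid_medium(3)
#' dplyr::filter(m, wavelength_nm == 1000)
intralipid_medium <- function(concentration_pct = 3,
                              wavelength_nm = seq(1000, 1660, by = 10),
                              radius_um = 0.5,
                              dispersion = default_dispersion()) {
  if (!is.numeric(concentration_pct) || concentration_pct < 0) {
    abort("`concentration_pct` must be >= 0.", class = "turbispec_invalid_argument")
  }
  wl_um <- wavelength_nm / 1000
  phi <- INTRALIPID_PHI_3PCT * concentration_pct / 3
  n_ex <- n_ex_of(wl_um, dispersion)
  n_in <- n_ex + dispersion$n_in_offset
  g <- g_of(wl_um, dispersion)
  mus_prime <- reduced_scattering_coefficient(phi, radius_um, wl_um, n_in / n_ex)
  mu_a <- dispersion$water_fraction * water_absorption(wavelength_nm)
  out <- tibble::tibble(
    wavelength_nm = wavelength_nm,
    n_ex = n_ex,
    n_in = n_in,
    mu_a = mu_a,
    mu_s_prime = mus_prime,
    g = g,
    mu_s = mus_prime / (1 - g)
  )
  structure(out,
    class = c("medium_spectrum", class(out)),
    scatterer = list(radius_um = radius_um, phi = phi),
    concentration_pct = concentration_pct,
    dispersion = dispersion
  )
}

#' Glucose molar absorption template
#'
#' Per-mM absorption increment of aqueous glucose: zero at and below 1400 nm,
#' rising linearly to 0.00065 cm^-1/mM at 1500 nm, flat across 1500-1600 nm,
#' and held at the plateau to 1700 nm. Only the plateau value and the
#' near-zero short-wave behaviour are physically anchored; the ramp is the
#' package's declared interpolation between them.
#'
#' @param wavelength_nm Wavelengths in nm.
#' @return Absorption increments in cm^-1 per mM.
#' @export
glucose_absorption_template <- function(wavelength_nm) {
  ramp <- pmin(pmax((wavelength_nm - 1400) / 100, 0), 1)
  GLUCOSE_EPS_PLATEAU * ramp
}

#' Specify a single-factor perturbation of the medium
#'
#' The four factors of the analysis plus a convenience alias:
#' * `"glucose"` (mM): raises `n_ex` by 2.5e-5 RIU/mM and adds the molar
#'   absorption template — the only factor with an absorption channel;
#' * `"nacl"` (mM): raises `n_ex` by 0.98e-5 RIU/mM, no absorption;
#' * `"particle_density"` (delta volume fraction): changes `phi` only;
#' * `"particle_size"` (delta radius, nm): changes the droplet radius only;
#' * `"intralipid_concentration"` (delta %): `dphi = 0.03237 * dpct / 3`.
#'
#' @param kind One of the factor names above.
#' @param amount Magnitude in the factor's unit (may be negative).
#' @return A `perturbation_spec` object.
#' @export
#' @examples
#' perturbation("glucose", 100)
#' perturbation("particle_size", -0.336) # shrink radius by 0.336 nm
perturbation <- function(kind = c(
                           "glucose", "nacl", "particle_density",
                           "particle_size", "intralipid_concentration"
                         ),
                         amount) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(amount), length(amount) == 1, is.finite(amount))
  p <- list(
    kind = kind, amount = amount,
    dnex = 0, dphi = 0, da_um = 0,
    dmua_per_unit = function(wavelength_nm) rep(0, length(wavelength_nm))
  )
  if (kind == "glucose") {
    p$dnex <- GLUCOSE_DN_PER_MM * amount
    p$dmua_per_unit <- glucose_absorption_template
  } else if (kind == "nacl") {
    p$dnex <- NACL_DN_PER_MM * amount
  } else if (kind == "particle_density") {
    p$dphi <- amount
  } else if (kind == "particle_size") {
    p$da_um <- amount / 1000 # amount given in nm
  } else if (kind == "intralipid_concentration") {
    p$dphi <- INTRALIPID_PHI_3PCT * amount / 3
  }
  structure(p, class = "perturbation_spec")
}

#' @export
print.perturbation_spec <- function(x, ...) {
  cat(sprintf(
    "<perturbation_spec> %s, amount %g (dnex %g, dphi %g, da %g um)\n",
    x$kind, x$amount, x$dnex, x$dphi, x$da_um
  ))
  invisible(x)
}

#' Apply a perturbation to a medium spectrum
#'
#' Shifts the background index, volume fraction and/or radius and *recomputes*
#' `mu_s'` exactly from the Graaff power law (no first-order shortcut), and
#' adds the factor's absorption increment to `mu_a`. The `mask` argument
#' supports the decomposition of glucose into its scattering and absorption
#' channels: `"scattering_only"` suppresses the `mu_a` change,
#' `"absorption_only"` suppresses the scattering-side changes.
#'
#' @param medium A `medium_spectrum` from [intralipid_medium()].
#' @param p A `perturbation_spec` from [perturbation()].
#' @param mask `"both"` (default), `"scattering_only"`, or
#'   `"absorption_only"`.
#' @return A perturbed `medium_spectrum` of the same shape.
#' @export
#' @examples
#' m <- intralipid_medium(3)
#' g100 <- apply_perturbation(m, perturbation("glucose", 100))
apply_perturbation <- function(medium, p,
                               mask = c("both", "scattering_only", "absorption_only")) {
  mask <- match.arg(mask)
  stopifnot(inherits(medium, "medium_spectrum"), inherits(p, "perturbation_spec"))
  sc <- attr(medium, "scatterer")
  disp <- attr(medium, "dispersion")
  out <- medium
  if (mask %in% c("both", "scattering_only")) {
    n_ex <- medium$n_ex + p$dnex
    phi <- sc$phi + p$dphi
    radius_um <- sc$radius_um + p$da_um
    if (phi < 0 || phi >= 1 || radius_um <= 0 || any(medium$n_in / n_ex <= 1)) {
      abort("perturbed medium is unphysical (phi, radius or relative index out of range).",
        class = "turbispec_unphysical_state"
      )
    }
    wl_um <- medium$wavelength_nm / 1000
    out$n_ex <- n_ex
    out$mu_s_prime <- reduced_scattering_coefficient(phi, radius_um, wl_um, medium$n_in / n_ex)
    out$mu_s <- out$mu_s_prime / (1 - out$g)
    attr(out, "scatterer") <- list(radius_um = radius_um, phi = phi)
  }
  if (mask %in% c("both", "absorption_only")) {
    out$mu_a <- medium$mu_a + p$amount * p$dmua_per_unit(medium$wavelength_nm)
  }
  attr(out, "dispersion") <- disp
  out
}

#' Instrument absorbance-noise model
#'
#' Per-wavelength short-term absorbance fluctuation amplitudes (standard
#' deviations, natural-log absorbance units) as observed at a reference
#' (farthest) source-detector separation within 1 min, with a single
#' multiplicative factor (<= 1) applied at closer separations. Defaults are
#' the six instrument wavelengths with amplitudes 0.001, 0.002, 0.002, 0.004,
#' 0.002, 0.003 a.u. at 2.3 mm.
#'
#' @param sd_au Named numeric of absorbance sds; names are wavelengths in nm.
#' @param reference_sds_cm Separation at which `sd_au` applies (cm).
#' @param closer_sds_factor Multiplier for separations below the reference.
#' @return A `noise_model` object.
#' @export
noise_model <- function(sd_au = c(
                          "1050" = 0.001, "1219" = 0.002, "1314" = 0.002,
                          "1409" = 0.004, "1550" = 0.002, "1609" = 0.003
                        ),
                        reference_sds_cm = 0.23,
                        closer_sds_factor = 0.8) {
  stopifnot(all(sd_au >= 0), closer_sds_factor > 0, closer_sds_factor <= 1)
  structure(
    list(
      wavelength_nm = as.numeric(names(sd_au)),
      sd_au = unname(sd_au),
      reference_sds_cm = reference_sds_cm,
      closer_sds_factor = closer_sds_factor
    ),
    class = "noise_model"
  )
}

noise_sd_at <- function(nm, wavelength_nm, sds_cm) {
  idx <- match(wavelength_nm, nm$wavelength_nm)
  if (anyNA(idx)) {
    abort("noise model has no amplitude for a requested wavelength.",
      class = "turbispec_invalid_argument"
    )
  }
  nm$sd_au[idx] * ifelse(sds_cm < nm$reference_sds_cm, nm$closer_sds_factor, 1)
}

#' Draw reproducible measurement-noise realisations
#'
#' Zero-mean Gaussian additive absorbance noise with the model's
#' per-wavelength standard deviation at the given separation. The draw is a
#' pure function of `(model, n_repeats, seed, sds_cm)`; the caller's RNG
#' state is left untouched.
#'
#' @param nm A [noise_model()].
#' @param n_repeats Number of repeated measurements to draw.
#' @param seed Integer seed (required; there is no default randomness).
#' @param sds_cm Separation of the measurement (cm); default the reference.
#' @return A tibble with columns `wavelength_nm`, `repeat_id`, `noise_au`.
#' @export
sample_measurement_noise <- function(nm, n_repeats, seed, sds_cm = nm$reference_sds_cm) {
  stopifnot(inherits(nm, "noise_model"), n_repeats >= 1, is.numeric(seed))
  sds <- noise_sd_at(nm, nm$wavelength_nm, sds_cm)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  draws <- matrix(rnorm(length(sds) * n_repeats, mean = 0, sd = rep(sds, n_repeats)),
    nrow = length(sds)
  )
  tidyr::expand_grid(repeat_id = seq_len(n_repeats), wavelength_nm = nm$wavelength_nm) |>
    dplyr::mutate(noise_au = as.vector(draws))
}
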