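# broom-style accessors and ggplot2 methods for the package's result types

#' @export
print.medium_spectrum <- function(x, ...) {
  sc <- attr(x, "scatterer")
  cat(sprintf(
    "<medium_spectrum> %g%% suspension, radius %g um, phi %.5g, %d wavelengths (%g-%g nm)\n",
    attr(x, "concentration_pct"), sc$radius_um, sc$phi, nrow(x),
    min(x$wavelength_nm), max(x$wavelength_nm)
  ))
  NextMethod()
}

#' @export
print.eac_spectrum <- function(x, ...) {
  cat(sprintf(
    "<eac_spectrum> %s %g, engine %s, mask %s, SDS pair %g/%g cm\n",
    attr(x, "factor_kind"), attr(x, "factor_amount"), attr(x, "engine"),
    attr(x, "mask"), attr(x, "sds_pair")[1], attr(x, "sds_pair")[2]
  ))
  NextMethod()
}

#' Tidy an EAC difference spectrum
#'
#' @param x An `eac_spectrum`.
#' @param ... Unused.
#' @return A plain tibble with the spectrum plus its factor, engine, mask and
#'   separation-pair metadata as columns.
#' @exportS3Method generics::tidy
tidy.eac_spectrum <- function(x, ...) {
  tibble::tibble(
    factor = attr(x, "factor_kind"),
    amount = attr(x, "factor_amount"),
    engine = attr(x, "engine"),
    mask = attr(x, "mask"),
    r_near_cm = attr(x, "sds_pair")[1],
    r_far_cm = attr(x, "sds_pair")[2],
    wavelength_nm = x$wavelength_nm,
    delta_mu_eff = x$delta_mu_eff,
    stderr = x$stderr,
    regime_ok = x$regime_ok
  )
}

#' One-row summary of an EAC difference spectrum
#'
#' @inheritParams tidy.eac_spectrum
#' @return A one-row tibble with the run metadata and the discriminating
#'   features from [extract_features()].
#' @exportS3Method generics::glance
glance.eac_spectrum <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      factor = attr(x, "factor_kind"),
      amount = attr(x, "factor_amount"),
      engine = attr(x, "engine"),
      mask = attr(x, "mask"),
      n_wavelengths = nrow(x),
      n_regime_ok = sum(x$regime_ok)
    ),
    extract_features(x)
  )
}

#' Tidy a Monte Carlo result into its ring profile
#'
#' @param x An `mc_result`.
#' @param ... Unused.
#' @return Tibble `r_center_cm`, `reflectance_per_cm2`, `stderr`.
#' @exportS3Method generics::tidy
tidy.mc_result <- function(x, ...) x$rings

#' One-row summary of a Monte Carlo run
#'
#' @inheritParams tidy.mc_result
#' @return One-row tibble with the energy ledger and configuration scalars.
#' @exportS3Method generics::glance
glance.mc_result <- function(x, ...) {
  tibble::tibble(
    n_photons = x$config$n_photons,
    seed = x$config$seed,
    specular_reflectance = x$specular_reflectance,
    total_diffuse_reflectance = x$total_diffuse_reflectance,
    absorbed_fraction = x$absorbed_fraction,
    conservation_residual = x$conservation_residual
  )
}

#' Plot a medium spectrum
#'
#' Faceted view of the optical properties over wavelength.
#'
#' @param object A `medium_spectrum`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.medium_spectrum <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("mu_a", "mu_s_prime", "g", "n_ex"),
    names_to = "property", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$wavelength_nm, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~property, scales = "free_y") +
    ggplot2::labs(
      x = "wavelength (nm)", y = NULL,
      title = sprintf("%g%% suspension optical properties", attr(object, "concentration_pct"))
    )
}

#' Plot an EAC difference spectrum
#'
#' @param object An `eac_spectrum`.
#' @param ... Unused.
#' @return A ggplot object; MC spectra carry +-2 SE ribbons.
#' @exportS3Method ggplot2::autoplot
autoplot.eac_spectrum <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$wavelength_nm, y = .data$delta_mu_eff)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "wavelength (nm)", y = expression(Delta * mu[eff] ~ (cm^-1)),
      title = sprintf(
        "%s %g (%s engine, %s)", d$factor[1], d$amount[1],
        d$engine[1], d$mask[1]
      )
    )
  if (any(is.finite(d$stderr))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$delta_mu_eff - 2 * .data$stderr,
        ymax = .data$delta_mu_eff + 2 * .data$stderr
      ),
      alpha = 0.2
    )
  }
  p
}

#' Plot a Monte Carlo radial reflectance profile
#'
#' @param object An `mc_result`.
#' @param ... Unused.
#' @return A ggplot object (log10 reflectance vs radius).
#' @exportS3Method ggplot2::autoplot
autoplot.mc_result <- function(object, ...) {
  d <- dplyr::filter(object$rings, .data$reflectance_per_cm2 > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r_center_cm, y = .data$reflectance_per_cm2)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(.data$reflectance_per_cm2 - 2 * .data$stderr, .Machine$double.xmin),
      ymax = .data$reflectance_per_cm2 + 2 * .data$stderr
    ), size = 0.2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "r (cm)", y = expression(R(r) ~ (cm^-2)),
      title = sprintf("MC diffuse reflectance, %g photons", object$config$n_photons)
    )
}

#' Overlay several EAC difference spectra
#'
#' @param spectra Named list of `eac_spectrum` objects.
#' @param normalize Rescale all spectra to coincide at `lambda0_nm` first.
#' @param lambda0_nm Reference wavelength used when `normalize = TRUE`.
#' @return A ggplot object.
#' @export
plot_eac_spectra <- function(spectra, normalize = FALSE, lambda0_nm = 1000) {
  if (normalize) spectra <- normalize_at_reference(spectra, lambda0_nm)$spectra
  d <- purrr::imap(spectra, function(s, nm) dplyr::mutate(tidy(s), label = nm)) |>
    dplyr::bind_rows()
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$wavelength_nm, y = .data$delta_mu_eff, colour = .data$label
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "wavelength (nm)", y = expression(Delta * mu[eff] ~ (cm^-1)),
      colour = NULL
    )
}
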