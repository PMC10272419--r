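# R surface of the photon Monte Carlo engine: configuration, single runs,
# correlated-sampling paired runs, and the mapping from annular tallies to
# source-detector-separation absorbance records.

#' Monte Carlo run configuration
#'
#' Desk-scale defaults: 1e6 photons, 0.005 cm radial bins out to 0.5 cm
#' (covering all separations used in the analysis), MCML-conventional Russian
#' roulette (threshold 1e-4, survival chance 1/10), ambient index 1.0.
#' Differential signals of a few-mM solute are unresolvable at this photon
#' budget; the pipeline therefore simulates amplified perturbations on common
#' random numbers (see [paired_delta()]) exactly as the original analysis
#' scaled its own runs.
#'
#' @param n_photons Photon packets per run.
#' @param seed Integer seed; every source of randomness in a run derives from
#'   it.
#' @param radial_bin_dr Annulus width, cm.
#' @param n_radial_bins Number of annuli.
#' @param weight_threshold Roulette trigger weight, in (0, 1).
#' @param roulette_survival_inverse Integer `m`: survive with chance `1/m`,
#'   weight multiplied by `m`.
#' @param ambient_index Refractive index above the surface.
#' @param n_batches Photon batches used for standard errors.
#' @return An `mc_config` object.
#' @export
mc_config <- function(n_photons = 1e6, seed = 1L, radial_bin_dr = 0.005,
                      n_radial_bins = 100, weight_threshold = 1e-4,
                      roulette_survival_inverse = 10L, ambient_index = 1.0,
                      n_batches = 20L) {
  stopifnot(
    n_photons >= 1, radial_bin_dr > 0, n_radial_bins >= 1,
    weight_threshold > 0, weight_threshold < 1,
    roulette_survival_inverse >= 2, ambient_index > 0,
    n_batches >= 2, n_photons >= n_batches
  )
  structure(
    list(
      n_photons = n_photons, seed = as.integer(seed),
      radial_bin_dr = radial_bin_dr, n_radial_bins = as.integer(n_radial_bins),
      weight_threshold = weight_threshold,
      roulette_survival_inverse = as.integer(roulette_survival_inverse),
      ambient_index = ambient_index, n_batches = as.integer(n_batches)
    ),
    class = "mc_config"
  )
}

#' Run the photon Monte Carlo for one optical state
#'
#' Pencil beam at normal incidence on a semi-infinite homogeneous medium.
#' Specular reflection is taken at the index step on entry; inside, photon
#' packets hop with transport step `-ln(xi)/(mu_a + mu_s)`, deposit the
#' absorbed weight fraction at each interaction (implicit capture), deflect by
#' the Henyey-Greenstein phase function, split their weight by the Fresnel
#' coefficients at each surface encounter (the escaping fraction is tallied in
#' the annulus of its exit radius), and undergo Russian roulette at low
#' weight. Runs are bit-reproducible for a fixed seed.
#'
#' @param cfg An [mc_config()].
#' @param mu_a,mu_s Absorption and scattering coefficients, cm^-1
#'   (`mu_a + mu_s > 0`).
#' @param g Henyey-Greenstein anisotropy, in `[0, 1)`.
#' @param n_medium Refractive index of the medium.
#' @return An `mc_result`: list with `rings` (tibble `r_center_cm`,
#'   `reflectance_per_cm2`, `stderr`), scalar `specular_reflectance`,
#'   `absorbed_fraction`, `total_diffuse_reflectance`,
#'   `conservation_residual`, and the per-batch raw tallies used by
#'   [paired_delta()].
#' @export
#' @examples
#' res <- run_mc(mc_config(n_photons = 2e4, seed = 7), mu_a = 0.1, mu_s = 50, g = 0.8, n_medium = 1)
#' res$conservation_residual
run_mc <- function(cfg, mu_a, mu_s, g, n_medium) {
  stopifnot(inherits(cfg, "mc_config"))
  raw <- mc_run_cpp(
    cfg$n_photons, cfg$seed, cfg$radial_bin_dr, cfg$n_radial_bins,
    cfg$weight_threshold, cfg$roulette_survival_inverse,
    cfg$ambient_index, n_medium, mu_a, mu_s, g, cfg$n_batches
  )
  r_edges <- cfg$radial_bin_dr * seq(0, cfg$n_radial_bins)
  area <- pi * diff(r_edges^2)
  r_center <- (r_edges[-1] + r_edges[-length(r_edges)]) / 2
  # per-batch reflectance estimates -> mean and its standard error
  per_batch <- sweep(raw$ring_weight, 1, raw$batch_n, "/")
  per_batch <- sweep(per_batch, 2, area, "/")
  refl <- colSums(raw$ring_weight) / cfg$n_photons / area
  se <- apply(per_batch, 2, stats::sd) / sqrt(cfg$n_batches)
  structure(
    list(
      rings = tibble::tibble(
        r_center_cm = r_center,
        reflectance_per_cm2 = refl,
        stderr = se
      ),
      specular_reflectance = raw$specular,
      absorbed_fraction = raw$absorbed,
      total_diffuse_reflectance = raw$diffuse,
      overflow_reflectance = raw$overflow,
      conservation_residual = raw$specular + raw$absorbed + raw$diffuse - 1,
      batch_ring_weight = raw$ring_weight,
      batch_n = raw$batch_n,
      ring_area_cm2 = area,
      config = cfg,
      optical = list(mu_a = mu_a, mu_s = mu_s, g = g, n_medium = n_medium)
    ),
    class = "mc_result"
  )
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(
    "<mc_result> %g photons, seed %d | specular %.4f, diffuse %.4f, absorbed %.4f (residual %.2e)\n",
    x$config$n_photons, x$config$seed, x$specular_reflectance,
    x$total_diffuse_reflectance, x$absorbed_fraction, x$conservation_residual
  ))
  invisible(x)
}

#' Correlated-sampling difference of two media
#'
#' Runs baseline and perturbed optical states on identical per-photon random
#' streams (same config, same seed) and returns the per-annulus change in
#' natural-log absorbance, `delta A = -ln R_perturbed + ln R_baseline`, with a
#' bootstrap-over-photon-batches standard error. Common random numbers make
#' the difference of a null perturbation exactly zero and shrink the variance
#' of small differences by orders of magnitude relative to independent runs.
#'
#' @param cfg An [mc_config()]; applied identically to both states.
#' @param baseline,perturbed Lists with elements `mu_a`, `mu_s`, `g`,
#'   `n_medium` (e.g. one wavelength row of a `medium_spectrum`).
#' @param n_boot Bootstrap resamples of the photon batches.
#' @return A tibble `r_center_cm`, `delta_A`, `stderr` (rows with empty
#'   tallies carry `NA`).
#' @export
paired_delta <- function(cfg, baseline, perturbed, n_boot = 200L) {
  res_b <- run_mc(cfg, baseline$mu_a, baseline$mu_s, baseline$g, baseline$n_medium)
  res_p <- run_mc(cfg, perturbed$mu_a, perturbed$mu_s, perturbed$g, perturbed$n_medium)
  wb <- colSums(res_b$batch_ring_weight)
  wp <- colSums(res_p$batch_ring_weight)
  ok <- wb > 0 & wp > 0
  delta <- ifelse(ok, -log(wp) + log(wb), NA_real_)

  nb <- cfg$n_batches
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(derive_seed(cfg$seed, "paired-bootstrap"))
  boot <- matrix(NA_real_, n_boot, cfg$n_radial_bins)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nb, nb, replace = TRUE)
    sb <- colSums(res_b$batch_ring_weight[idx, , drop = FALSE])
    sp <- colSums(res_p$batch_ring_weight[idx, , drop = FALSE])
    pos <- sb > 0 & sp > 0
    boot[b, pos] <- -log(sp[pos]) + log(sb[pos])
  }
  se <- apply(boot, 2, stats::sd, na.rm = TRUE)
  se[!ok] <- NA_real_
  tibble::tibble(
    r_center_cm = res_b$rings$r_center_cm,
    delta_A = delta,
    stderr = se
  )
}

#' Absorbance records at chosen separations from an MC result
#'
#' Converts the annular reflectance profile to natural-log absorbance at given
#' source-detector separations. Each separation is read from the annulus
#' containing it, optionally averaging a small window of adjacent annuli to
#' trade radial resolution for statistical error.
#'
#' @param result An `mc_result`.
#' @param sds_cm Separations, cm, within the tallied radial range.
#' @param wavelength_nm Wavelength label attached to the records.
#' @param window Odd number of annuli averaged around the containing one.
#' @return An [absorbance_record()] tibble with an extra `stderr` column
#'   (standard error of `A`, from the ring standard errors).
#' @export
annuli_to_sds <- function(result, sds_cm, wavelength_nm = NA_real_, window = 1L) {
  stopifnot(inherits(result, "mc_result"), window >= 1, window %% 2 == 1)
  dr <- result$config$radial_bin_dr
  nb <- result$config$n_radial_bins
  if (any(sds_cm <= 0 | sds_cm >= nb * dr)) {
    abort("a separation lies outside the tallied radial grid.", class = "turbispec_range_error")
  }
  half <- (window - 1L) / 2L
  vals <- vapply(sds_cm, function(r) {
    bin <- min(nb, floor(r / dr) + 1L)
    lo <- max(1L, bin - half)
    hi <- min(nb, bin + half)
    w <- sum(result$batch_ring_weight[, lo:hi])
    if (w <= 0) {
      abort(sprintf("no photons tallied near r = %g cm: insufficient statistics.", r),
        class = "turbispec_insufficient_statistics"
      )
    }
    refl <- w / result$config$n_photons / sum(result$ring_area_cm2[lo:hi])
    # propagate ring standard errors through the window mean
    se_num <- sqrt(sum((result$rings$stderr[lo:hi] * result$ring_area_cm2[lo:hi])^2)) /
      sum(result$ring_area_cm2[lo:hi])
    c(refl, se_num / refl)
  }, numeric(2))
  rec <- absorbance_record(
    wavelength_nm = rep(wavelength_nm, length(sds_cm)),
    sds_cm = sds_cm,
    A = -log(vals[1, ])
  )
  rec$stderr <- vals[2, ]
  rec
}
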