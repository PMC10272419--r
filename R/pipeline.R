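# Orchestration: factor perturbation -> absorbance at a separation pair ->
# EAC difference spectrum, for the deterministic diffusion engine and the
# Monte Carlo engine; 1000 nm normalisation across factors; the synthetic
# four-separation instrument experiment; spectral-feature extraction.

new_eac_spectrum <- function(tbl, kind, amount, engine, sds_pair, mask) {
  structure(tbl,
    class = c("eac_spectrum", class(tbl)),
    factor_kind = kind, factor_amount = amount, engine = engine,
    sds_pair = sds_pair, mask = mask
  )
}

#' Diffusion-theory absorbance of a medium at given separations
#'
#' Evaluates the two-dipole closed form per wavelength and separation and
#' returns natural-log absorbances together with the per-point regime flag.
#'
#' @param medium A `medium_spectrum`.
#' @param sds_cm Separations, cm.
#' @return An [absorbance_record()] with extra column `regime_ok`.
#' @export
diffusion_absorbance <- function(medium, sds_cm) {
  state <- diffusion_state(medium$mu_a, medium$mu_s_prime)
  recs <- purrr::map(sds_cm, function(r) {
    rec <- absorbance_record(
      wavelength_nm = medium$wavelength_nm,
      sds_cm = rep(r, nrow(medium)),
      A = absorbance(reflectance(state, r, quiet = TRUE))
    )
    rec$regime_ok <- diffusion_regime_ok(state, r)
    rec
  })
  out <- dplyr::bind_rows(recs)
  class(out) <- c("absorbance_record", setdiff(class(out), "absorbance_record"))
  out
}

ad_from_records <- function(rec, r_near, r_far) {
  differential_absorbance(
    rec[rec$sds_cm == r_far, ],
    rec[rec$sds_cm == r_near, ]
  )
}

#' EAC difference spectrum of one perturbing factor
#'
#' The central computation: build the perturbed medium (optionally masking its
#' absorption or scattering channel), obtain baseline and perturbed
#' absorbances at the two separations with the chosen engine, difference them
#' (differential absorbance), and divide by the separation gap to get
#' `delta mu_eff` per wavelength.
#'
#' The diffusion engine is deterministic; the Monte Carlo engine runs both
#' states on common random numbers per wavelength and reports bootstrap
#' standard errors. The `regime_ok` column flags wavelengths where the
#' diffusion closed form is trustworthy at both separations.
#'
#' @param medium Baseline `medium_spectrum`.
#' @param p A [perturbation()].
#' @param engine `"diffusion"` or `"mc"`.
#' @param sds_pair Numeric length-2, near and far separation in cm (default
#'   `c(0.08, 0.2)`).
#' @param mask Passed to [apply_perturbation()].
#' @param mc_cfg An [mc_config()] (MC engine only).
#' @param window Annulus averaging window for the MC engine, odd.
#' @return An `eac_spectrum` tibble: `wavelength_nm`, `delta_mu_eff`,
#'   `stderr` (NA for diffusion), `regime_ok`.
#' @export
#' @examples
#' m <- intralipid_medium(3)
#' eac <- run_group(m, perturbation("glucose", 100))
#' head(tidy(eac))
run_group <- function(medium, p, engine = c("diffusion", "mc"),
                      sds_pair = c(0.08, 0.2),
                      mask = c("both", "scattering_only", "absorption_only"),
                      mc_cfg = NULL, window = 3L) {
  engine <- match.arg(engine)
  mask <- match.arg(mask)
  stopifnot(length(sds_pair) == 2, sds_pair[2] > sds_pair[1])
  perturbed <- apply_perturbation(medium, p, mask)
  r_near <- sds_pair[1]
  r_far <- sds_pair[2]

  if (engine == "diffusion") {
    rec_b <- diffusion_absorbance(medium, sds_pair)
    rec_p <- diffusion_absorbance(perturbed, sds_pair)
    eac <- eac_change(
      ad_from_records(rec_p, r_near, r_far),
      ad_from_records(rec_b, r_near, r_far)
    )
    out <- tibble::tibble(
      wavelength_nm = eac$wavelength_nm,
      delta_mu_eff = eac$delta_mu_eff,
      stderr = NA_real_,
      regime_ok = tapply(rec_b$regime_ok, rec_b$wavelength_nm, all)[
        as.character(eac$wavelength_nm)
      ] |> unname()
    )
  } else {
    if (is.null(mc_cfg)) mc_cfg <- mc_config()
    state <- diffusion_state(medium$mu_a, medium$mu_s_prime)
    rows <- purrr::map(seq_len(nrow(medium)), function(i) {
      cfg_i <- mc_cfg
      cfg_i$seed <- derive_seed(mc_cfg$seed, paste0("wl", medium$wavelength_nm[i]))
      pd <- paired_delta(
        cfg_i,
        baseline = as.list(medium[i, c("mu_a", "mu_s", "g")]) |>
          c(n_medium = medium$n_ex[i]),
        perturbed = as.list(perturbed[i, c("mu_a", "mu_s", "g")]) |>
          c(n_medium = perturbed$n_ex[i])
      )
      da <- delta_a_at(pd, c(r_near, r_far), mc_cfg$radial_bin_dr, window)
      tibble::tibble(
        wavelength_nm = medium$wavelength_nm[i],
        delta_mu_eff = (da$delta_A[2] - da$delta_A[1]) / (r_far - r_near),
        stderr = sqrt(da$stderr[1]^2 + da$stderr[2]^2) / (r_far - r_near),
        regime_ok = all(diffusion_regime_ok(state[i, ], c(r_near, r_far)))
      )
    })
    out <- dplyr::bind_rows(rows)
  }
  new_eac_spectrum(out, p$kind, p$amount, engine, sds_pair, mask)
}

# window-averaged delta-A of a paired_delta table at given radii
delta_a_at <- function(pd, sds_cm, dr, window) {
  half <- (window - 1L) / 2L
  nb <- nrow(pd)
  res <- vapply(sds_cm, function(r) {
    bin <- min(nb, floor(r / dr) + 1L)
    lo <- max(1L, bin - half)
    hi <- min(nb, bin + half)
    v <- pd$delta_A[lo:hi]
    s <- pd$stderr[lo:hi]
    keep <- is.finite(v)
    if (!any(keep)) {
      abort(sprintf("no usable annuli near r = %g cm: insufficient statistics.", r),
        class = "turbispec_insufficient_statistics"
      )
    }
    c(mean(v[keep]), sqrt(sum(s[keep]^2)) / sum(keep))
  }, numeric(2))
  list(delta_A = res[1, ], stderr = res[2, ])
}

#' Rescale factor spectra to coincide at a reference wavelength
#'
#' Multiplies each spectrum by the scalar that makes its `delta mu_eff` at the
#' reference wavelength equal the reference factor's, and reports the implied
#' equivalent amount of each factor (e.g. how many mM of NaCl mimic 1 mM of
#' glucose at 1000 nm, where glucose has no absorption channel and all factors
#' act through scattering alone).
#'
#' @param spectra Named list of `eac_spectrum` objects on one wavelength grid.
#' @param lambda0_nm Reference wavelength (must be on the grid); default 1000.
#' @param reference Name or index of the reference spectrum.
#' @return A list with `spectra` (the rescaled list) and `equivalents`, a
#'   tibble `factor`, `amount`, `scale`, `equivalent_amount`.
#' @export
normalize_at_reference <- function(spectra, lambda0_nm = 1000, reference = 1L) {
  stopifnot(length(spectra) >= 1)
  ref <- spectra[[reference]]
  val0 <- function(s) {
    v <- s$delta_mu_eff[s$wavelength_nm == lambda0_nm]
    if (length(v) != 1 || !is.finite(v) || v == 0) {
      abort("each spectrum must be non-zero at the reference wavelength.",
        class = "turbispec_invalid_argument"
      )
    }
    v
  }
  v_ref <- val0(ref)
  scales <- purrr::map_dbl(spectra, function(s) v_ref / val0(s))
  scaled <- purrr::imap(spectra, function(s, nm) {
    k <- scales[[nm]]
    s$delta_mu_eff <- s$delta_mu_eff * k
    s$stderr <- s$stderr * abs(k)
    s
  })
  list(
    spectra = scaled,
    equivalents = tibble::tibble(
      factor = unname(purrr::map_chr(spectra, attr, "factor_kind")),
      amount = unname(purrr::map_dbl(spectra, attr, "factor_amount")),
      scale = unname(scales),
      equivalent_amount = unname(purrr::map_dbl(spectra, attr, "factor_amount") * scales)
    )
  )
}

#' Synthetic four-separation instrument experiment
#'
#' Emulates the bench measurement: diffusion-theory absorbances of baseline
#' and perturbed media at the four detector-ring separations and the six
#' instrument wavelengths, plus additive per-wavelength absorbance noise, then
#' EAC difference spectra from each adjacent separation pair.
#'
#' @param medium Baseline `medium_spectrum`; its scatterer geometry,
#'   concentration and dispersion configuration are re-evaluated at the
#'   instrument wavelengths (which need not lie on its grid).
#' @param perturbations Named list of [perturbation()]s.
#' @param sds_cm The four separations, cm (default 0.125, 0.17, 0.20, 0.23).
#' @param wavelengths_nm Instrument wavelengths (default the six-diode set).
#' @param noise A [noise_model()], or `NULL` for a noise-free experiment.
#' @param seed Integer seed for the noise draws.
#' @return A tibble `factor`, `pair`, `r_near_cm`, `r_far_cm`,
#'   `wavelength_nm`, `delta_mu_eff`, of class `synth_experiment`.
#' @export
synth_experiment <- function(medium, perturbations,
                             sds_cm = c(0.125, 0.17, 0.20, 0.23),
                             wavelengths_nm = c(1050, 1219, 1314, 1409, 1550, 1609),
                             noise = noise_model(), seed = 1L) {
  stopifnot(length(sds_cm) >= 2)
  sds_cm <- sort(sds_cm)
  # re-evaluate the same medium on the instrument wavelength grid
  sub <- intralipid_medium(
    concentration_pct = attr(medium, "concentration_pct"),
    wavelength_nm = sort(wavelengths_nm),
    radius_um = attr(medium, "scatterer")$radius_um,
    dispersion = attr(medium, "dispersion")
  )

  measure <- function(state_medium, label) {
    rec <- diffusion_absorbance(state_medium, sds_cm)
    if (!is.null(noise)) {
      noise_draws <- purrr::map(seq_along(sds_cm), function(j) {
        draws <- sample_measurement_noise(
          noise,
          n_repeats = 1,
          seed = derive_seed(seed, paste0("noise-", label, "-sds", j)),
          sds_cm = sds_cm[j]
        )
        draws$noise_au[match(sub$wavelength_nm, draws$wavelength_nm)]
      })
      rec$A <- rec$A + unlist(noise_draws)
    }
    rec
  }

  rec_base <- measure(sub, "baseline")
  rows <- purrr::imap(perturbations, function(p, nm) {
    rec_p <- measure(apply_perturbation(sub, p), nm)
    pairs <- purrr::map(seq_len(length(sds_cm) - 1), function(k) {
      eac <- eac_change(
        ad_from_records(rec_p, sds_cm[k], sds_cm[k + 1]),
        ad_from_records(rec_base, sds_cm[k], sds_cm[k + 1])
      )
      tibble::tibble(
        factor = nm,
        pair = sprintf("%.3g/%.3g cm", sds_cm[k], sds_cm[k + 1]),
        r_near_cm = sds_cm[k], r_far_cm = sds_cm[k + 1],
        wavelength_nm = eac$wavelength_nm,
        delta_mu_eff = eac$delta_mu_eff
      )
    })
    dplyr::bind_rows(pairs)
  })
  out <- dplyr::bind_rows(rows)
  structure(out,
    class = c("synth_experiment", class(out)),
    seed = seed, sds_cm = sds_cm
  )
}

#' Discriminating spectral features of an EAC difference spectrum
#'
#' The two features that separate glucose from its scattering confounders:
#' the wavelength of the largest `|delta mu_eff|` in the long-wave band
#' (1400-1700 nm, glucose's absorption shifts it to shorter wavelengths than
#' the pure-scattering factors), and the short-band variation — range over
#' mean magnitude of `delta mu_eff` across 1000-1300 nm. Discrete argmax on
#' the sampled grid; ties break toward the shorter wavelength.
#'
#' @param s An `eac_spectrum`.
#' @param short_band,peak_band Band edges in nm.
#' @return A one-row tibble: `peak_wavelength_nm`, `peak_value`,
#'   `shortband_variation`, `monotone_direction`.
#' @export
extract_features <- function(s, short_band = c(1000, 1300), peak_band = c(1400, 1700)) {
  stopifnot(inherits(s, "eac_spectrum"))
  in_peak <- s$wavelength_nm >= peak_band[1] & s$wavelength_nm <= peak_band[2]
  in_short <- s$wavelength_nm >= short_band[1] & s$wavelength_nm <= short_band[2]
  if (sum(in_peak) < 1 || sum(in_short) < 2) {
    abort("wavelength grid too narrow for the requested feature bands.",
      class = "turbispec_invalid_argument"
    )
  }
  wl <- s$wavelength_nm[in_peak]
  v <- abs(s$delta_mu_eff[in_peak])
  peak_wl <- wl[which.max(v)] # which.max returns the first (shortest) maximum
  sh <- s$delta_mu_eff[in_short]
  d <- diff(sh)
  direction <- if (all(d > 0)) "increasing" else if (all(d < 0)) "decreasing" else "nonmonotone"
  tibble::tibble(
    peak_wavelength_nm = peak_wl,
    peak_value = s$delta_mu_eff[in_peak][which.max(v)],
    shortband_variation = (max(sh) - min(sh)) / mean(abs(sh)),
    monotone_direction = direction
  )
}
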