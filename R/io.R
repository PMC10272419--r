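# Configuration loading/validation, spectrum CSV round-tripping at full float
# precision, and the per-run provenance log.

run_config_defaults <- function() {
  list(
    seed = 1L,
    output_dir = NA_character_,
    medium = list(
      concentration_pct = 3, radius_um = 0.5,
      wavelength_min_nm = 1000, wavelength_max_nm = 1660, wavelength_step_nm = 10
    ),
    perturbations = list(list(kind = "glucose", amount = 100, mask = "both")),
    engine = list(name = "diffusion", sds_near_cm = 0.08, sds_far_cm = 0.2),
    mc = list(
      n_photons = 1e6, radial_bin_dr = 0.005, n_radial_bins = 100,
      weight_threshold = 1e-4, roulette_survival_inverse = 10,
      ambient_index = 1.0, n_batches = 20
    ),
    experiment = list(
      sds_cm = c(0.125, 0.17, 0.2, 0.23),
      wavelengths_nm = c(1050, 1219, 1314, 1409, 1550, 1609),
      noise_sd_au = c(0.001, 0.002, 0.002, 0.004, 0.002, 0.003),
      closer_sds_factor = 0.8
    )
  )
}

merge_known <- function(defaults, user, path, problems) {
  unknown <- setdiff(names(user), names(defaults))
  for (k in unknown) problems$bad <- c(problems$bad, paste0(path, k))
  for (k in intersect(names(user), names(defaults))) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) && k != "perturbations") {
      defaults[[k]] <- merge_known(
        defaults[[k]], as.list(user[[k]]),
        paste0(path, k, "."), problems
      )
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

validate_run_config <- function(cfg) {
  bad <- character()
  chk <- function(ok, field) if (!isTRUE(ok)) bad <<- c(bad, field)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed")
  chk(cfg$medium$concentration_pct >= 0, "medium.concentration_pct")
  chk(cfg$medium$radius_um > 0, "medium.radius_um")
  chk(cfg$medium$wavelength_min_nm < cfg$medium$wavelength_max_nm, "medium.wavelength_min_nm")
  chk(cfg$medium$wavelength_step_nm > 0, "medium.wavelength_step_nm")
  chk(cfg$engine$name %in% c("diffusion", "mc"), "engine.name")
  chk(cfg$engine$sds_far_cm > cfg$engine$sds_near_cm, "engine.sds_far_cm")
  chk(cfg$mc$n_photons >= 1, "mc.n_photons")
  chk(cfg$mc$radial_bin_dr > 0, "mc.radial_bin_dr")
  chk(cfg$mc$n_radial_bins >= 1, "mc.n_radial_bins")
  chk(cfg$mc$weight_threshold > 0 && cfg$mc$weight_threshold < 1, "mc.weight_threshold")
  chk(cfg$mc$roulette_survival_inverse >= 2, "mc.roulette_survival_inverse")
  chk(all(diff(cfg$experiment$sds_cm) > 0), "experiment.sds_cm")
  chk(
    length(cfg$experiment$noise_sd_au) == length(cfg$experiment$wavelengths_nm) &&
      all(cfg$experiment$noise_sd_au >= 0),
    "experiment.noise_sd_au"
  )
  for (i in seq_along(cfg$perturbations)) {
    p <- cfg$perturbations[[i]]
    ok <- is.list(p) && !is.null(p$kind) &&
      p$kind %in% c(
        "glucose", "nacl", "particle_density", "particle_size",
        "intralipid_concentration"
      ) &&
      is.numeric(p$amount)
    chk(ok, sprintf("perturbations[%d]", i))
  }
  bad
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, fills every omitted field with the documented default,
#' rejects unknown keys, and validates field values; all offending keys are
#' reported together. An empty file yields the full default configuration.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path), class = "turbispec_io_error")
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  problems <- new.env()
  problems$bad <- character()
  cfg <- merge_known(run_config_defaults(), user, "", problems)
  bad_values <- validate_run_config(cfg)
  all_bad <- c(
    if (length(problems$bad)) paste0("unknown key: ", problems$bad),
    if (length(bad_values)) paste0("invalid value: ", bad_values)
  )
  if (length(all_bad)) {
    abort(paste0(
      "configuration problems:\n",
      paste0("  - ", all_bad, collapse = "\n")
    ), class = "turbispec_config_error")
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#'
#' Inverse of [load_config()]; `load_config(write_config(cfg, path))` gives a
#' configuration equal to `cfg`.
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

spectrum_meta <- function(x) {
  if (inherits(x, "eac_spectrum")) {
    list(
      type = "eac_spectrum", factor_kind = attr(x, "factor_kind"),
      factor_amount = attr(x, "factor_amount"), engine = attr(x, "engine"),
      sds_pair = attr(x, "sds_pair"), mask = attr(x, "mask")
    )
  } else if (inherits(x, "medium_spectrum")) {
    list(
      type = "medium_spectrum", scatterer = attr(x, "scatterer"),
      concentration_pct = attr(x, "concentration_pct")
    )
  } else if (inherits(x, "absorbance_record")) {
    list(type = "absorbance_record")
  } else {
    list(type = "tibble")
  }
}

expected_columns <- list(
  eac_spectrum = c("wavelength_nm", "delta_mu_eff"),
  medium_spectrum = c("wavelength_nm", "n_ex", "n_in", "mu_a", "mu_s_prime", "g", "mu_s"),
  absorbance_record = c("wavelength_nm", "sds_cm", "A"),
  tibble = character()
)

#' Write a spectrum table to CSV at full float precision
#'
#' Comma-separated, dot decimal, UTF-8, one header row. Numeric columns are
#' written with 17 significant digits so the decimal representation
#' round-trips the IEEE double exactly; the object's class and metadata are
#' kept in a `#`-prefixed JSON comment line and restored by
#' [read_spectrum_csv()].
#'
#' @param x A `medium_spectrum`, `eac_spectrum`, [absorbance_record()] or
#'   plain tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(x, path) {
  meta <- spectrum_meta(x)
  df <- as.data.frame(x)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# turbispec ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectrum table written by [write_spectrum_csv()]
#'
#' Restores the table, its class and its metadata attributes, and validates
#' the column set for typed spectra; malformed numeric cells are reported
#' with their line number.
#'
#' @param path Path to a CSV written by [write_spectrum_csv()].
#' @return The restored tibble.
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "turbispec_io_error")
  }
  first <- readLines(path, n = 1)
  meta <- list(type = "tibble")
  if (startsWith(first, "# turbispec ")) {
    meta <- jsonlite::fromJSON(sub("^# turbispec ", "", first))
  }
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- expected_columns[[meta$type]]
  if (!all(need %in% names(df))) {
    abort(sprintf(
      "format error: %s file must have columns {%s}, found {%s}.",
      meta$type, paste(need, collapse = ", "), paste(names(df), collapse = ", ")
    ), class = "turbispec_format_error")
  }
  for (j in intersect(names(df), c(
    need, "stderr", "r_near_cm", "r_far_cm",
    "delta_mu_eff", "noise_au"
  ))) {
    if (is.integer(df[[j]])) df[[j]] <- as.double(df[[j]])
    if (is.character(df[[j]]) && nrow(df) > 0) {
      conv <- suppressWarnings(as.numeric(df[[j]]))
      bad <- which(is.na(conv) & !is.na(df[[j]]))
      if (length(bad)) {
        abort(sprintf(
          "format error in %s: column '%s' not numeric at data line %d.",
          path, j, bad[1]
        ), class = "turbispec_format_error")
      }
      df[[j]] <- conv
    }
  }
  out <- tibble::as_tibble(df)
  if (meta$type == "eac_spectrum") {
    out <- new_eac_spectrum(
      out, meta$factor_kind, meta$factor_amount, meta$engine,
      as.numeric(meta$sds_pair), meta$mask
    )
  } else if (meta$type == "medium_spectrum") {
    out <- structure(out,
      class = c("medium_spectrum", class(out)),
      scatterer = meta$scatterer, concentration_pct = meta$concentration_pct
    )
  } else if (meta$type == "absorbance_record") {
    class(out) <- c("absorbance_record", class(out))
  }
  out
}

#' Write a provenance log for a run
#'
#' JSON sidecar with the seed(s), package version, configuration echo and any
#' regime-warning summary — enough to reproduce deterministic outputs
#' bit-for-bit.
#'
#' @param dir Output directory (created if missing).
#' @param config A `run_config` (or any list) to echo.
#' @param seeds Named integer vector of the seeds actually used.
#' @param regime_warnings Character vector of regime-warning summaries.
#' @return Path of the written log, invisibly.
#' @export
write_run_log <- function(dir, config, seeds = c(global = config$seed),
                          regime_warnings = character()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "run_log.json")
  jsonlite::write_json(
    list(
      package_version = as.character(packageVersion("turbispec")),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
      seeds = as.list(seeds),
      regime_warnings = regime_warnings,
      config = unclass(config)
    ),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
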