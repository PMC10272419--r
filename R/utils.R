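# shared validators and the per-stage seed derivation

stop_if_not_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be finite and > 0.", name), class = "turbispec_invalid_argument")
  }
  invisible(x)
}

#' Derive a reproducible per-stage sub-seed from one global seed
#'
#' Each stochastic stage of a run (measurement noise, Monte Carlo transport,
#' bootstrap resampling) draws its own seed from the single user-supplied run
#' seed, so stages can be re-run independently yet reproducibly. The derivation
#' is a fixed integer hash of the global seed and the stage label; it has no
#' tunable state.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label, e.g. `"noise"`, `"mc"`.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "mc")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage), length(stage) == 1)
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h %% 2147483646 + 1)
}
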