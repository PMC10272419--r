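# Independent oracles shared across the suite.

# Direct evaluation of the reduced-scattering power law (duplicated on purpose:
# the tests must not trust the package's own kernel when checking derivatives).
mus_direct <- function(phi, a_um, lambda_um, n_in, n_ex) {
  m <- n_in / n_ex
  2.46 * (phi / (a_um * 1e-4)) * (2 * pi * a_um / lambda_um)^0.37 * (m - 1)^2.09
}

# Central finite difference of f at x with relative step h.
central_fd <- function(f, x, h = 1e-6) {
  dx <- h * abs(x)
  (f(x + dx) - f(x - dx)) / (2 * dx)
}

# Random optical-parameter draws in the Graaff sweep box.
draw_sweep <- function(n, seed = 421) {
  set.seed(seed)
  tibble::tibble(
    a_um = runif(n, 0.2, 2),
    phi = runif(n, 0.005, 0.1),
    m = runif(n, 1.02, 1.3),
    lambda_um = runif(n, 1.0, 1.7),
    n_ex = runif(n, 1.31, 1.34)
  ) |>
    dplyr::mutate(n_in = m * n_ex)
}

# Differential absorbance of a diffusion state straight from the closed form,
# bypassing the package's absorbance/differencing helpers.
ad_direct <- function(mu_a, mu_s_prime, r_near, r_far) {
  st <- diffusion_state(mu_a, mu_s_prime)
  log(reflectance(st, r_near, quiet = TRUE) / reflectance(st, r_far, quiet = TRUE))
}

# Default instrument-like medium reused across pipeline tests.
default_medium <- function(...) intralipid_medium(3, ...)
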