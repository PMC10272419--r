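test_that("size parameter and regime flag follow the definition", {
  cases <- tibble::tribble(
    ~a, ~lambda, ~x, ~flag,
    0.5, 1.0, pi, FALSE, # Intralipid droplets sit below the nominal regime
    1.0, 1.0, 2 * pi, TRUE,
    0.5, 1.609, 2 * pi * 0.5 / 1.609, FALSE # 1.9528
  )
  res <- size_parameter(cases$a, cases$lambda)
  expect_equal(res$size_parameter, cases$x, tolerance = 1e-12)
  expect_equal(res$graaff_regime, cases$flag)
  expect_equal(res$size_parameter[3], 1.95251, tolerance = 1e-5)
  expect_error(size_parameter(-0.5, 1), class = "turbispec_invalid_argument")
  expect_error(size_parameter(0.5, 0), class = "turbispec_invalid_argument")
})

test_that("reduced scattering cross-section matches the power law", {
  # index-matched particle scatters nothing
  expect_identical(reduced_scattering_cross_section(0.7, 1.3, 1), 0)
  # frozen value from independent term-by-term log-space evaluation:
  # exp(log(3.28) + log(pi) + 2 log(0.5) + 0.37 log(pi) + 2.09 log(0.10625))
  expect_equal(reduced_scattering_cross_section(0.5, 1.0, 1.10625),
    0.03630251,
    tolerance = 1e-6
  )
  # doubling the radius at fixed lambda multiplies by 2^2.37
  s1 <- reduced_scattering_cross_section(0.4, 1.2, 1.1)
  s2 <- reduced_scattering_cross_section(0.8, 1.2, 1.1)
  expect_equal(s2 / s1, 2^2.37, tolerance = 1e-12)
  expect_error(reduced_scattering_cross_section(0.5, 1, 0.98), class = "turbispec_out_of_model")
})

test_that("coefficient and cross-section routes agree to machine precision", {
  sw <- draw_sweep(1000)
  mus <- reduced_scattering_coefficient(sw$phi, sw$a_um, sw$lambda_um, sw$m)
  sigma_cm2 <- reduced_scattering_cross_section(sw$a_um, sw$lambda_um, sw$m) * 1e-8
  via_sigma <- 3 * sw$phi / (4 * pi * (sw$a_um * 1e-4)^3) * sigma_cm2
  expect_lt(max(abs(mus - via_sigma) / via_sigma), 1e-12)
})

test_that("Intralipid-like state reproduces the reference coefficient", {
  # oracle: Eq.-style cross-section scaled by number density (helper route)
  mus <- reduced_scattering_coefficient(0.03237, 0.5, 1.0, 1.468 / 1.327)
  expect_equal(mus, 22.445, tolerance = 1e-4)
  expect_equal(mus, 22.5, tolerance = 0.01) # the quoted round value
  # linear in phi, zero at the matched index
  expect_equal(
    reduced_scattering_coefficient(0.03237 / 2, 0.5, 1.0, 1.1),
    reduced_scattering_coefficient(0.03237, 0.5, 1.0, 1.1) / 2,
    tolerance = 1e-14
  )
  expect_identical(reduced_scattering_coefficient(0.03237, 0.5, 1.0, 1), 0)
})

test_that("mu_s' is decreasing in wavelength and increasing in relative index", {
  lam <- seq(1.0, 1.7, by = 0.05)
  mus_l <- reduced_scattering_coefficient(0.03, 0.5, lam, 1.11)
  expect_true(all(diff(mus_l) < 0))
  ms <- seq(1.02, 1.3, by = 0.02)
  mus_m <- reduced_scattering_coefficient(0.03, 0.5, 1.3, ms)
  expect_true(all(diff(mus_m) > 0))
})

test_that("analytic sensitivities match central finite differences", {
  sw <- draw_sweep(1000)
  s <- scattering_sensitivities(sw$phi, sw$a_um, sw$lambda_um, sw$n_in, sw$n_ex)
  fd_nex <- mapply(function(phi, a, l, ni, ne) {
    central_fd(function(x) mus_direct(phi, a, l, ni, x), ne)
  }, sw$phi, sw$a_um, sw$lambda_um, sw$n_in, sw$n_ex)
  fd_phi <- mapply(function(phi, a, l, ni, ne) {
    central_fd(function(x) mus_direct(x, a, l, ni, ne), phi)
  }, sw$phi, sw$a_um, sw$lambda_um, sw$n_in, sw$n_ex)
  fd_a <- mapply(function(phi, a, l, ni, ne) {
    central_fd(function(x) mus_direct(phi, x, l, ni, ne), a)
  }, sw$phi, sw$a_um, sw$lambda_um, sw$n_in, sw$n_ex)
  expect_lt(max(abs(s$dmus_dnex - fd_nex) / abs(fd_nex)), 1e-6)
  expect_lt(max(abs(s$dmus_dphi - fd_phi) / abs(fd_phi)), 1e-6)
  expect_lt(max(abs(s$dmus_da_per_um - fd_a) / abs(fd_a)), 1e-6)
  # signs for a relatively refracting particle
  expect_true(all(s$dmus_dnex < 0))
  expect_true(all(s$dmus_dphi > 0))
  expect_true(all(s$dmus_da_per_um < 0))
})

test_that("sensitivity worked example reproduces the reference state", {
  s <- scattering_sensitivities(0.03237, 0.5, 1.0, 1.468, 1.327)
  expect_equal(s$dmus_dphi, 693.4, tolerance = 1e-3)
  expect_equal(s$dmus_da_per_um, -28.28, tolerance = 1e-3)
  expect_equal(s$dmus_dnex, -368.0, tolerance = 1e-3)
  # per-mM glucose scattering sensitivity at dn/dC = 2.5e-5 RIU/mM
  expect_equal(s$dmus_dnex * 2.5e-5, -0.0092, tolerance = 0.01)
})

test_that("matched perturbations reproduce the density/size equivalence", {
  s <- scattering_sensitivities(0.03237, 0.5, 1.0, 1.468, 1.327)
  target <- s$dmus_dphi * 1.37e-5
  eq <- equivalent_perturbations(target, 0.03237, 0.5, 1.0, 1.468, 1.327)
  da_nm <- eq$magnitude[eq$factor == "particle_size"] * 1000
  expect_equal(da_nm, 0.336, tolerance = 1e-3)
  # converse: a 0.336 nm radius shrink is matched by dphi = 1.370e-5
  target2 <- abs(s$dmus_da_per_um) * 0.336e-3
  eq2 <- equivalent_perturbations(target2, 0.03237, 0.5, 1.0, 1.468, 1.327)
  expect_equal(eq2$magnitude[eq2$factor == "particle_density"], 1.370e-5, tolerance = 1e-3)
  # zero target degenerates to zero magnitudes
  eq0 <- equivalent_perturbations(0, 0.03237, 0.5, 1.0, 1.468, 1.327)
  expect_true(all(eq0$magnitude == 0))
  # signs: positive delta mu_s' needs +phi, -a, -solute
  expect_equal(
    eq$amount_sign[match(
      c("glucose", "nacl", "particle_density", "particle_size"),
      eq$factor
    )],
    c(-1, -1, 1, -1)
  )
})

test_that("the matched pair is scale-free and index independent", {
  sw <- draw_sweep(50, seed = 99)
  for (i in seq_len(nrow(sw))) {
    s <- scattering_sensitivities(sw$phi[i], sw$a_um[i], sw$lambda_um[i], sw$n_in[i], sw$n_ex[i])
    eq <- equivalent_perturbations(0.123, sw$phi[i], sw$a_um[i], sw$lambda_um[i], sw$n_in[i], sw$n_ex[i])
    dphi <- eq$magnitude[eq$factor == "particle_density"]
    da <- eq$magnitude[eq$factor == "particle_size"]
    # |da|/a = (dphi/phi) / 0.63 exactly, whatever the indices or wavelength
    expect_equal(da / sw$a_um[i], (dphi / sw$phi[i]) / 0.63, tolerance = 1e-12)
  }
})
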