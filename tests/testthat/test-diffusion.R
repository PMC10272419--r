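test_that("diffusion state derives its lengths from the coefficients", {
  st <- diffusion_state(1, 9)
  expect_equal(st$mu_eff, sqrt(30), tolerance = 1e-12)
  expect_equal(st$D, 1 / 30, tolerance = 1e-12)
  expect_equal(st$z0, 1 / 9, tolerance = 1e-12)
  expect_equal(st$zb, 2 * st$D, tolerance = 1e-12)
  expect_equal(diffusion_state(0.5, 10)$z0, 0.1, tolerance = 1e-12)
  # mu_eff vanishes with absorption
  expect_lt(diffusion_state(1e-12, 10)$mu_eff, 1e-5)
  expect_error(diffusion_state(0, 10), class = "turbispec_invalid_argument")
  expect_error(diffusion_state(1, -1), class = "turbispec_invalid_argument")
})

test_that("reflectance is positive and decays at the effective attenuation rate", {
  st <- diffusion_state(0.1, 10)
  r <- seq(0.05, 3, by = 0.05)
  I <- reflectance(st, r, quiet = TRUE)
  expect_true(all(I > 0))
  # asymptotically ln(r^2 I) falls with slope -mu_eff
  r1 <- 30 / st$mu_eff
  r2 <- 40 / st$mu_eff
  slope <- (log(r2^2 * reflectance(st, r2, quiet = TRUE)) -
    log(r1^2 * reflectance(st, r1, quiet = TRUE))) / (r2 - r1)
  expect_equal(slope, -st$mu_eff, tolerance = 0.02)
  expect_error(reflectance(st, 0), class = "turbispec_invalid_argument")
})

test_that("regime warning flags close detectors and strong absorption", {
  st <- diffusion_state(0.1, 10) # z0 = 0.1 cm
  expect_warning(reflectance(st, 0.05), class = "turbispec_regime_warning")
  expect_no_warning(reflectance(st, 0.5))
  expect_no_warning(reflectance(st, 0.05, quiet = TRUE))
  bad <- diffusion_state(30, 20) # 1450 nm-like: mu_a > mu_s'
  expect_warning(reflectance(bad, 0.5), class = "turbispec_regime_warning")
  expect_identical(diffusion_regime_ok(st, c(0.05, 0.5)), c(FALSE, TRUE))
})

test_that("absorbance is the natural logarithm of the intensity ratio", {
  expect_identical(absorbance(1), 0)
  expect_equal(absorbance(exp(-1)), 1, tolerance = 1e-15)
  expect_equal(absorbance(0.01), 4.6052, tolerance = 1e-4)
  expect_error(absorbance(0), class = "turbispec_invalid_argument")
  expect_error(absorbance(-2), class = "turbispec_invalid_argument")
})

test_that("differential absorbance composes with the reflectance closed form", {
  st <- diffusion_state(0.1, 10)
  wl <- c(1050, 1219)
  far <- absorbance_record(wl, rep(0.2, 2), absorbance(reflectance(st[c(1, 1), ], 0.2, quiet = TRUE)))
  near <- absorbance_record(wl, rep(0.08, 2), absorbance(reflectance(st[c(1, 1), ], 0.08, quiet = TRUE)))
  ad <- differential_absorbance(far, near)
  # oracle: AD = ln[I(r_near)/I(r_far)] straight from the closed form
  expect_equal(ad$AD, rep(ad_direct(0.1, 10, 0.08, 0.2), 2), tolerance = 1e-12)
  expect_true(all(ad$AD > 0))
  # identical records difference to zero
  expect_identical(differential_absorbance(
    absorbance_record(wl, c(0.3, 0.3), c(1, 2)) |> (\(x) {
      x$sds_cm <- x$sds_cm + 1e-9
      x
    })(),
    absorbance_record(wl, c(0.3, 0.3), c(1, 2))
  )$AD, c(0, 0))
  expect_error(differential_absorbance(near, far), class = "turbispec_invalid_argument")
  expect_error(
    differential_absorbance(
      absorbance_record(1050, 0.2, 1),
      absorbance_record(1219, 0.08, 1)
    ),
    class = "turbispec_invalid_argument"
  )
})

test_that("differential absorbance grows with absorption", {
  mu_as <- seq(0.05, 2, by = 0.05)
  ads <- vapply(mu_as, function(ma) ad_direct(ma, 15, 0.08, 0.2), numeric(1))
  expect_true(all(diff(ads) > 0))
})

test_that("eac_change recovers the closed-form change where geometry cancels", {
  # strongly scattering state at the analysis separations: z0 << r_near and
  # mu_eff * (r_far - r_near) of order one
  mk_ad <- function(mu_a, mus, r_near, r_far) {
    st <- diffusion_state(mu_a, mus)
    differential_absorbance(
      absorbance_record(1000, r_far, absorbance(reflectance(st, r_far, quiet = TRUE))),
      absorbance_record(1000, r_near, absorbance(reflectance(st, r_near, quiet = TRUE)))
    )
  }
  base <- mk_ad(0.5, 100, 0.08, 0.2)
  pert <- mk_ad(0.5, 99, 0.08, 0.2)
  est <- eac_change(pert, base)$delta_mu_eff
  truth <- diffusion_state(0.5, 99)$mu_eff - diffusion_state(0.5, 100)$mu_eff
  expect_lt(abs(est - truth) / abs(truth), 0.15)
  expect_lt(est, 0) # glucose-like: lower mu_s' lowers mu_eff
  # equal differential absorbances give exactly zero
  expect_identical(eac_change(base, base)$delta_mu_eff, 0)
})

test_that("composition identity holds across the far-field validity regime", {
  # sweep states and pick separations satisfying r_near >= 5*max(z0, 1/mu_eff)
  # and mu_eff*(r_far - r_near) in [0.3, 3]
  set.seed(11)
  for (i in 1:25) {
    mu_a <- runif(1, 0.2, 2)
    mus <- runif(1, 8, 60)
    st <- diffusion_state(mu_a, mus)
    r_near <- 5.5 * max(st$z0, 1 / st$mu_eff)
    r_far <- r_near + runif(1, 0.5, 2.5) / st$mu_eff
    pert_mus <- mus * (1 - 1e-3)
    ad_b <- ad_direct(mu_a, mus, r_near, r_far)
    ad_p <- ad_direct(mu_a, pert_mus, r_near, r_far)
    est <- (ad_p - ad_b) / (r_far - r_near)
    truth <- diffusion_state(mu_a, pert_mus)$mu_eff - st$mu_eff
    expect_lt(abs(est - truth) / abs(truth), 0.15)
  }
})

test_that("absorbance change is monotone in separation for a fixed perturbation", {
  rs <- seq(0.08, 0.3, by = 0.02)
  da <- vapply(rs, function(r) {
    log(reflectance(diffusion_state(0.35, 22), r, quiet = TRUE) /
      reflectance(diffusion_state(0.35, 21.8), r, quiet = TRUE))
  }, numeric(1))
  expect_true(all(diff(da) > 0) || all(diff(da) < 0))
})
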