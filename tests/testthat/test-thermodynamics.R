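test_that("build_isosteres reproduces a Clausius-Clapeyron construction", {
  qst <- 3000
  ds_prof <- ds_profile_from_dent(dent_ref_params, qst)
  xe_grid <- seq(0.04, 0.20, length.out = 8)
  ds <- generate_clausius_consistent(function(x) rep(qst, length(x)), ds_prof,
                                     xe_grid = xe_grid)
  fits <- lapply(sorption_groups(ds), fit_isotherm, model_id = "dent",
                 n_starts = 6)
  iso <- build_isosteres(fits, xe_grid)
  # inversion must reproduce the constructed aw at every (xe, T) cell
  for (i in seq_len(nrow(iso))) {
    truth <- ds$aw[abs(ds$xe - iso$xe[i]) < 1e-12 & ds$T == iso$T[i]]
    expect_equal(iso$aw[i], truth, tolerance = 1e-7)
  }
  expect_length(attr(iso, "dropped"), 0)

  # moisture beyond every curve's image is dropped with a reason
  iso2 <- build_isosteres(fits, c(xe_grid, 5))
  expect_length(attr(iso2, "dropped"), 1)
  expect_false(5 %in% iso2$xe)

  expect_error(build_isosteres(fits[1:2], xe_grid),
               class = "sorptherm_validation_error")
})

test_that("identical isotherms at all temperatures give zero isostere slope", {
  g <- lapply(c(298.15, 308.15, 318.15), function(Tv)
    fit_isotherm(noiseless_group("gab", T_K = Tv), "gab", n_starts = 4))
  iso <- build_isosteres(g, c(0.03, 0.06, 0.1))
  for (xe in unique(iso$xe)) {
    sl <- iso[iso$xe == xe, ]
    est <- fit_isostere(sl$ln_aw, sl$inv_T)
    expect_lt(abs(est$qst), 1e-4)
  }
})

test_that("fit_isostere recovers an exact linear law and validates input", {
  qst <- 3000; dS <- 5
  invT <- 1 / c(298.15, 308.15, 318.15)
  lnaw <- -qst / R_GAS * invT + dS / R_GAS
  est <- fit_isostere(lnaw, invT)
  expect_equal(est$qst, 3000, tolerance = 1e-9)
  expect_equal(est$dS, 5, tolerance = 1e-9)
  expect_equal(est$r2, 1, tolerance = 1e-12)

  expect_error(fit_isostere(lnaw[1:2], invT[1:2]),
               class = "sorptherm_validation_error")
  expect_error(fit_isostere(c(-1, -1, -1), rep(1 / 300, 3)),
               class = "sorptherm_validation_error")

  # zero slope: qst = 0 and dS = R * intercept
  est0 <- fit_isostere(rep(-0.7, 3), invT)
  expect_equal(est0$qst, 0, tolerance = 1e-10)
  expect_equal(est0$dS, R_GAS * -0.7, tolerance = 1e-10)
})

test_that("latent heat follows the linear correlation", {
  expect_equal(latent_heat(298.15), 8.314 * (6687 - 5.31 * 298.15),
               tolerance = 1e-12)
  expect_gt(latent_heat(298.15), latent_heat(318.15))
  expect_equal(suppressWarnings(latent_heat(6687 / 5.31)), 0,
               tolerance = 1e-9)
  expect_warning(latent_heat(200), class = "sorptherm_range_warning")
})

test_that("integral heat is net heat plus latent heat", {
  Th <- harmonic_mean_temperature(c(298.15, 308.15, 318.15))
  expect_equal(integral_heat(0, Th), latent_heat(Th))
  expect_equal(integral_heat(500, 307.8), 500 + latent_heat(307.8))
  # linearity in qst
  expect_equal(integral_heat(200, Th) + integral_heat(300, Th) - latent_heat(Th),
               integral_heat(500, Th))
})

test_that("harmonic mean temperature matches direct arithmetic and HM <= AM", {
  expect_equal(harmonic_mean_temperature(c(298, 308, 318)),
               3 / (1 / 298 + 1 / 308 + 1 / 318), tolerance = 1e-12)
  withr::with_seed(5, {
    for (i in 1:20) {
      temps <- runif(4, 250, 400)
      expect_lte(harmonic_mean_temperature(temps), mean(temps))
    }
  })
  expect_equal(harmonic_mean_temperature(rep(300, 3)), 300)
})

test_that("Gibbs energy follows -RT ln(aw)", {
  expect_equal(gibbs_energy(298.15, 1), 0)
  expect_equal(gibbs_energy(298.15, 0.5), 8.314 * 298.15 * log(2),
               tolerance = 1e-12)
  expect_equal(gibbs_energy(298.15, 0.25), 2 * gibbs_energy(298.15, 0.5),
               tolerance = 1e-12)
  aw <- seq(0.05, 0.99, length.out = 50)
  dg <- gibbs_energy(308.15, aw)
  expect_true(all(dg > 0))
  expect_true(all(diff(dg) < 0))
  expect_error(gibbs_energy(298.15, 0), class = "sorptherm_domain_error")
})

test_that("trend fitting recovers published functional forms exactly", {
  x <- seq(0.02, 0.3, length.out = 12)
  # power law with the published integral-heat coefficients
  pw <- fit_trend(x, 41.16 * x^(-0.014), "power")
  expect_equal(unname(pw$coefficients["a"]), 41.16, tolerance = 1e-8)
  expect_equal(unname(pw$coefficients["b"]), -0.014, tolerance = 1e-6)
  expect_equal(pw$r2, 1, tolerance = 1e-12)
  # logarithmic with the published desorption-entropy coefficients
  lg <- fit_trend(x, -1.54 * log(x) - 3.12, "log")
  expect_equal(unname(lg$coefficients["a"]), -1.54, tolerance = 1e-12)
  expect_equal(unname(lg$coefficients["c"]), -3.12, tolerance = 1e-12)
  # exponential with the published desorption Gibbs coefficients
  ex <- fit_trend(x, 5.04 * exp(-11.8 * x), "exp")
  expect_equal(unname(ex$coefficients["a"]), 5.04, tolerance = 1e-7)
  expect_equal(unname(ex$coefficients["b"]), -11.8, tolerance = 1e-6)
  # constant response: power exponent collapses to ~0
  ct <- fit_trend(x, rep(2.5, 12), "power")
  expect_lt(abs(ct$coefficients["b"]), 1e-6)
  expect_error(fit_trend(c(-1, 1, 2), c(1, 2, 3), "log"),
               class = "sorptherm_validation_error")
  expect_error(fit_trend(x[1:2], x[1:2], "linear"),
               class = "sorptherm_validation_error")
})

test_that("compensation recovers an exact isokinetic line and verdicts", {
  dS <- seq(-8, 6, length.out = 10)
  dH <- 400 * dS + 300
  comp <- compensation(dH, dS, c(298, 308, 318))
  expect_equal(comp$T_beta, 400, tolerance = 1e-9)
  expect_equal(comp$dG_beta, 300, tolerance = 1e-9)
  expect_equal(comp$r2, 1, tolerance = 1e-12)
  expect_equal(comp$T_h, 3 / sum(1 / c(298, 308, 318)), tolerance = 1e-12)
  expect_identical(comp$verdict, "enthalpy_driven")

  cold <- compensation(150 * dS + 100, dS, c(298, 308, 318))
  expect_identical(cold$verdict, "entropy_driven")

  noisy <- withr::with_seed(3, compensation(400 * dS + rnorm(10, 0, 5000),
                                            dS, c(298, 308, 318)))
  expect_identical(noisy$verdict, "indeterminate")

  expect_error(compensation(dH, rep(1, 10), c(298, 308, 318)),
               class = "sorptherm_validation_error")
  expect_error(compensation(dH[1:2], dS[1:2], c(298, 308)),
               class = "sorptherm_validation_error")
})

test_that("compensation slope equals the covariance/variance closed form", {
  withr::with_seed(9, {
    dS <- rnorm(12, 0, 4)
    dH <- 350 * dS + 500 + rnorm(12, 0, 200)
    comp <- compensation(dH, dS, c(298, 308, 318))
    expect_equal(comp$T_beta, stats::cov(dH, dS) / stats::var(dS),
                 tolerance = 1e-10)
  })
})

test_that("thermo_profile assembles a coherent branch profile", {
  # constant heat with a Dent-induced entropy profile: every temperature's
  # curve is an exact Dent isotherm, so the pipeline is exact end to end
  qst <- 3000
  ds_prof <- ds_profile_from_dent(dent_ref_params, qst)
  ds <- generate_clausius_consistent(function(x) rep(qst, length(x)), ds_prof,
                                     xe_grid = seq(0.04, 0.18, length.out = 10))
  fits <- lapply(sorption_groups(ds), fit_isotherm, model_id = "dent",
                 n_starts = 6)
  tp <- thermo_profile(fits, xe_grid = seq(0.05, 0.16, length.out = 8))
  expect_s3_class(tp, "thermo_profile")
  expect_equal(tp$profile$qst, rep(qst, nrow(tp$profile)), tolerance = 1e-5)
  expect_equal(tp$profile$dS, ds_prof(tp$profile$xe), tolerance = 1e-4)
  expect_equal(tp$profile$Qst - tp$profile$qst,
               rep(latent_heat(tp$T_h), nrow(tp$profile)), tolerance = 1e-9)
  expect_true(all(tp$gibbs$dG > 0))
  expect_true(all(c("Qst_power", "dS_log") %in% names(tp$trends)))
  expect_s3_class(tp$compensation, "compensation_result")
})

test_that("a declining heat profile is recovered with its sign and shape", {
  # varying qst: the scaled curves are no longer exactly Dent, so the fit
  # carries model-form error; sign and monotone shape must still come through
  qst_prof <- function(x) 6000 * x^(-0.25)
  ds_prof <- ds_profile_from_dent(dent_ref_params, qst_prof)
  ds <- generate_clausius_consistent(qst_prof, ds_prof,
                                     xe_grid = seq(0.04, 0.18, length.out = 10))
  fits <- lapply(sorption_groups(ds), fit_isotherm, model_id = "dent",
                 n_starts = 6)
  tp <- thermo_profile(fits, xe_grid = seq(0.05, 0.16, length.out = 8))
  expect_true(all(tp$profile$qst > 0))
  expect_true(all(diff(tp$profile$qst) < 0))
  expect_true(all(tp$profile$r2 > 0.99))
})
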