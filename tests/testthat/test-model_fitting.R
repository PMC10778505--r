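test_that("goodness_of_fit reproduces hand-computed statistics", {
  perfect <- goodness_of_fit(c(0.01, 0.05, 0.10), c(0.01, 0.05, 0.10))
  expect_equal(perfect$sse_eq13, 0)
  expect_equal(perfect$e_percent, 0)
  expect_equal(perfect$r2_standard, 1)
  expect_equal(perfect$r2_regression, 1)

  s <- goodness_of_fit(c(0.02, 0.04, 0.06), c(0.03, 0.04, 0.05))
  expect_equal(s$sse_eq13, (1e-4 + 0 + 1e-4) / 3, tolerance = 1e-12)
  expect_equal(s$e_percent, (100 / 3) * (0.5 + 0 + 1 / 6), tolerance = 1e-10)
  expect_equal(s$n_points, 3L)
  expect_false(s$e_percent_flagged)

  obs <- c(0.02, 0.05, 0.11)
  const <- goodness_of_fit(obs, rep(mean(obs), 3))
  expect_equal(const$r2_standard, 0)
  expect_equal(const$r2_regression, 0)

  expect_error(goodness_of_fit(1:3, 1:2), class = "sorptherm_validation_error")
})

test_that("goodness_of_fit flags near-zero observations and is permutation invariant", {
  obs <- c(1e-9, 0.04, 0.06)
  s <- goodness_of_fit(obs, c(0.01, 0.04, 0.05))
  expect_true(s$e_percent_flagged)
  # E% over the admissible subset only
  expect_equal(s$e_percent, 100 * mean(c(0, 0.01 / 0.06)), tolerance = 1e-10)

  set.seed(7)
  o <- runif(12, 0.01, 0.3); p <- o + rnorm(12, 0, 0.01)
  idx <- sample(12)
  a <- goodness_of_fit(o, p); b <- goodness_of_fit(o[idx], p[idx])
  expect_equal(a$sse_eq13, b$sse_eq13)
  expect_equal(a$e_percent, b$e_percent)
  expect_equal(a$r2_standard, b$r2_standard)
})

test_that("fit_isotherm recovers published GAB ground truth from noiseless data", {
  g <- noiseless_group("gab", c(0.06, 13.83, 0.89), T_K = 318.15,
                       branch = "desorption")
  fit <- fit_isotherm(g, "gab", n_starts = 8)
  expect_true(fit$converged)
  expect_equal(unname(fit$params), c(0.06, 13.83, 0.89), tolerance = 1e-4)
  expect_gt(fit$stats$r2_standard, 1 - 1e-10)
})

test_that("fit_isotherm validates inputs and is deterministic", {
  g2 <- sorption_dataset("adsorption", rep(298.15, 2), c(0.2, 0.6),
                         c(0.01, 0.05))
  expect_error(fit_isotherm(g2, "peleg"),
               class = "sorptherm_validation_error")
  g3 <- sorption_dataset("adsorption", rep(298.15, 4), c(0.2, 0.2, 0.6, 0.6),
                         c(0.01, 0.011, 0.05, 0.052))
  expect_error(fit_isotherm(g3, "gab"), "distinct aw",
               class = "sorptherm_validation_error")
  # non-temperature models refuse multi-temperature slices
  multi <- noiseless_multiT_group("gab")
  expect_error(fit_isotherm(multi, "gab"),
               class = "sorptherm_validation_error")

  scen <- sorption_scenario(seed = 11)
  g <- sorption_group(generate_sorption(scen), "adsorption", 308.15)
  f1 <- fit_isotherm(g, "oswin", n_starts = 8, seed = 99)
  f2 <- fit_isotherm(g, "oswin", n_starts = 8, seed = 99)
  expect_identical(f1, f2)
})

test_that("fits survive realistic measurement noise", {
  # 30-point GAB data with 0.002 g/g noise keeps conventional R2 >= 0.97
  aw <- seq(0.09, 0.83, length.out = 30)
  for (seed in 1:20) {
    xe_true <- st_evaluate("gab", c(0.06, 13.83, 0.89), aw)
    xe <- withr::with_seed(seed, pmax(xe_true + rnorm(30, 0, 0.002), 0))
    g <- sorption_dataset("desorption", rep(308.15, 30), aw, xe)
    fit <- fit_isotherm(g, "gab", n_starts = 6, seed = 1)
    expect_gt(fit$stats$r2_standard, 0.97)
  }
})

test_that("BET aw cut is honoured", {
  g <- noiseless_group("bet", c(0.05, 5))
  fit <- fit_isotherm(g, "bet", n_starts = 4, bet_max_aw = 0.5)
  expect_lte(fit$stats$n_points, sum(g$aw <= 0.5))
})

make_fake_fit <- function(model_id, branch, T_K, r2, sse, e) {
  structure(list(
    model_id = model_id, branch = branch, T = T_K,
    params = stats::setNames(
      rep(0.1, length(st_models()[[model_id]]$param_names)),
      st_models()[[model_id]]$param_names),
    stats = structure(list(r2_regression = r2, r2_standard = r2,
                           sse_eq13 = sse, e_percent = e,
                           e_percent_flagged = FALSE, n_points = 15L),
                      class = "fit_statistics"),
    converged = TRUE, n_starts_used = 1L, sse_raw = sse * 15, seed = 1L
  ), class = "isotherm_fit")
}

test_that("rank_models applies the published selection rule to printed criteria", {
  # published adsorption criteria rows (R2, SSE, E%) per temperature
  printed <- list(
    peleg      = list(r2 = c(0.990, 0.999, 0.994), sse = c(3.64e-5, 3.03e-6, 2.68e-5), e = c(0.16, 0.03, 0.11)),
    gab        = list(r2 = c(0.979, 0.999, 0.989), sse = c(7.44e-5, 4.23e-6, 5.30e-5), e = c(0.42, 0.03, 0.11)),
    bet        = list(r2 = c(0.977, 0.998, 0.979), sse = c(8.01e-5, 5.56e-6, 9.70e-5), e = c(0.67, 0.14, 0.22)),
    halsey     = list(r2 = c(0.970, 0.999, 0.984), sse = c(1.03e-4, 4.40e-6, 7.68e-5), e = c(0.71, 0.03, 0.13)),
    oswin      = list(r2 = c(0.977, 0.998, 0.980), sse = c(8.14e-5, 6.43e-6, 9.49e-5), e = c(0.41, 0.05, 0.20)),
    smith      = list(r2 = c(0.875, 0.868, 0.856), sse = c(4.36e-4, 4.82e-4, 6.78e-4), e = c(2.74, 1.19, 1.05)),
    adam_shove = list(r2 = c(0.991, 0.987, 0.962), sse = c(3.27e-5, 4.67e-5, 1.77e-4), e = c(0.22, 0.20, 0.41)),
    mod_oswin  = list(r2 = c(0.977, 0.999, 0.982), sse = c(8.14e-5, 6.55e-5, 1.41e-1), e = c(0.41, 0.07, 100.89)),
    mod_halsey = list(r2 = c(0.970, 0.999, 0.990), sse = c(1.03e-4, 1.46e-5, 7.00e-3), e = c(0.71, 0.07, 38.42))
  )
  temps <- c(298.15, 308.15, 318.15)
  fits <- list()
  for (m in names(printed)) {
    for (i in 1:3) {
      fits[[length(fits) + 1L]] <- make_fake_fit(
        m, "adsorption", temps[i], printed[[m]]$r2[i],
        printed[[m]]$sse[i], printed[[m]]$e[i])
    }
  }
  rk <- rank_models(fits)
  # the stated rule: smith fails R2, the modified models fail E%; among the
  # passing models Peleg has the smallest total SSE
  expect_false(rk$no_model_passed)
  expect_identical(rk$best_model_id, "peleg")
  passing <- rk$table$model_id[rk$table$passes_criteria]
  expect_setequal(passing, c("peleg", "gab", "bet", "halsey", "oswin",
                             "adam_shove"))
  expect_false("smith" %in% passing)
  tot <- tapply(vapply(fits, function(f) f$stats$sse_eq13, numeric(1)),
                vapply(fits, function(f) f$model_id, character(1)), sum)
  expect_equal(rk$table$total_sse[1], unname(min(tot[passing])))
})

test_that("rank_models filter precedence and tie-breaks", {
  fits <- c(
    lapply(298:300 + 0.15, function(Tv)
      make_fake_fit("gab", "adsorption", Tv, r2 = 0.95, sse = 5e-4, e = 1)),
    lapply(298:300 + 0.15, function(Tv)
      make_fake_fit("smith", "adsorption", Tv, r2 = 0.85, sse = 1e-6, e = 0.1))
  )
  rk <- rank_models(fits)
  expect_identical(rk$best_model_id, "gab")  # failing model never wins on SSE

  fits <- c(
    lapply(298:300 + 0.15, function(Tv)
      make_fake_fit("peleg", "adsorption", Tv, r2 = 0.99, sse = 1e-5, e = 0.5)),
    lapply(298:300 + 0.15, function(Tv)
      make_fake_fit("bet", "adsorption", Tv, r2 = 0.99, sse = 1e-5, e = 0.5))
  )
  rk <- rank_models(fits)
  expect_identical(rk$best_model_id, "bet")  # identical stats: fewer params

  fits <- lapply(298:300 + 0.15, function(Tv)
    make_fake_fit("smith", "adsorption", Tv, r2 = 0.80, sse = 1e-5, e = 0.5))
  rk <- rank_models(fits)
  expect_true(rk$no_model_passed)
  expect_identical(rk$best_model_id, "smith")
})
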