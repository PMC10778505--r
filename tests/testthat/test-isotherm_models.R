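test_that("registry exposes ten stable model specs", {
  reg <- st_models()
  expect_length(reg, 10)
  expect_named(reg, c("peleg", "gab", "bet", "halsey", "oswin", "smith",
                      "adam_shove", "mod_oswin", "mod_halsey", "dent"))
  expect_equal(reg$peleg$param_names, c("C1", "C2", "C3", "C4"))
  expect_true(reg$mod_oswin$uses_temperature)
  expect_true(reg$mod_halsey$uses_temperature)
  expect_false(any(vapply(reg[c("peleg", "gab", "bet", "halsey", "oswin",
                                "smith", "adam_shove", "dent")],
                          function(s) s$uses_temperature, logical(1))))
  counts <- vapply(reg, function(s) length(s$param_names), integer(1))
  expect_equal(unname(counts), c(4L, 3L, 2L, 2L, 2L, 2L, 4L, 3L, 3L, 3L))
})

test_that("model evaluation matches the algebra at hand-checked points", {
  # published adsorption 25 degC Peleg constants; both power terms share the
  # exponent so the curve is (C1 + C3) * aw^4.91
  expect_equal(st_evaluate("peleg", c(0.43, 4.91, 0.02, 4.91), 0.5),
               0.45 * 0.5^4.91, tolerance = 1e-12)
  expect_equal(st_evaluate("gab", c(0.06, 13.83, 0.89), 0), 0)
  expect_equal(st_evaluate("smith", c(0.04, 0.09), 0), 0.04)
  expect_equal(st_evaluate("adam_shove", c(0.05, -0.18, 0.93, -0.63), 0), 0.05)
  expect_equal(st_evaluate("halsey", c(0.01, 1.8), 0), 0)
  # modified Oswin consumes temperature in Celsius
  expect_equal(st_evaluate("mod_oswin", c(0.02, 0.003, 0.45), 0.5, T_C = 35),
               (0.02 + 0.003 * 35) * 1^0.45, tolerance = 1e-12)
  expect_error(st_evaluate("mod_oswin", c(0.02, 0.003, 0.45), 0.5),
               class = "sorptherm_validation_error")
  expect_error(st_evaluate("gab", c(0.06, 13.83, 0.89), 1.0),
               class = "sorptherm_domain_error")
  expect_error(st_evaluate("gab", c(0.06, 13.83), 0.5),
               class = "sorptherm_validation_error")
  # pole inside (0, 0.999): GAB with K large enough that 1 - K*aw vanishes
  expect_error(st_evaluate("gab", c(0.06, 13.83, 2), 0.5),
               class = "sorptherm_domain_error")
})

test_that("GAB with K = 1 collapses onto BET", {
  aw <- seq(0.05, 0.45, length.out = 50)
  expect_equal(st_evaluate("gab", c(0.05, 7, 1), aw),
               st_evaluate("bet", c(0.05, 7), aw), tolerance = 1e-12)
})

test_that("monotone models are strictly increasing on a 200-point grid", {
  aw <- seq(0.01, 0.95, length.out = 200)
  for (m in c("gab", "bet", "oswin", "halsey", "smith", "dent")) {
    xe <- st_evaluate(m, truth_params[[m]], aw)
    expect_true(all(diff(xe) > 0), label = sprintf("monotone %s", m))
    expect_true(all(xe >= 0), label = sprintf("nonnegative %s", m))
  }
})

test_that("inversion round-trips every registered model", {
  for (m in names(truth_params)) {
    T_C <- if (st_models()[[m]]$uses_temperature) 35 else NULL
    xe <- st_evaluate(m, truth_params[[m]], 0.4, T_C = T_C)
    aw <- st_invert(m, truth_params[[m]], xe, T_C = T_C)
    expect_equal(aw, 0.4, tolerance = 1e-8, label = sprintf("invert %s", m))
  }
})

test_that("Oswin inversion matches its closed form", {
  p <- c(K = 0.10, n = 0.41)
  for (xe in c(0.02, 0.08, 0.2)) {
    y <- (xe / p[["K"]])^(1 / p[["n"]])
    expect_equal(st_invert("oswin", p, xe), y / (1 + y), tolerance = 1e-10)
  }
})

test_that("inversion rejects bad targets and non-monotone brackets", {
  expect_error(st_invert("gab", truth_params$gab, -1),
               class = "sorptherm_range_error")
  expect_error(st_invert("gab", truth_params$gab, 100),
               class = "sorptherm_range_error")
  # downward-opening cubic is non-monotone on the full bracket
  expect_error(st_invert("adam_shove", c(0, 1, 0, -1.2), 0.1),
               class = "sorptherm_inversion_error")
})
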