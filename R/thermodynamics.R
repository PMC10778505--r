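#' Build Clausius-Clapeyron isosteres from fitted isotherms
#'
#' For each moisture content on `xe_grid`, inverts the per-temperature
#' fitted isotherms to the water activity holding that moisture, producing
#' the isostere table `ln(aw)` versus `1/T` at constant moisture. Requires
#' fits at three or more temperatures. Grid values that cannot be inverted
#' at every temperature (outside a curve's image) are dropped and recorded
#' in the `dropped` attribute with a reason.
#'
#' @param fits list of `isotherm_fit`, one per temperature, same branch
#' @param xe_grid moisture contents (g/g dry basis)
#' @param aw_bracket inversion bracket passed to [st_invert()]
#' @return data frame `(xe, T, aw, ln_aw, inv_T)` with attribute `dropped`
#' @export
build_isosteres <- function(fits, xe_grid, aw_bracket = c(1e-6, AW_MAX)) {
  temps <- vapply(fits, function(f) f$T[1], numeric(1))
  branches <- unique(vapply(fits, function(f) f$branch, character(1)))
  if (length(unique(round(temps, 6))) < 3) {
    st_stop("sorptherm_validation_error",
            "isosteres need fits at >= 3 distinct temperatures (got %d)",
            length(unique(round(temps, 6))))
  }
  if (length(branches) != 1) {
    st_stop("sorptherm_validation_error",
            "isostere fits must come from one branch (got: %s)",
            paste(branches, collapse = ", "))
  }
  rows <- list()
  dropped <- character(0)
  for (xe in xe_grid) {
    aw <- rep(NA_real_, length(fits))
    reason <- NULL
    for (i in seq_along(fits)) {
      f <- fits[[i]]
      aw_i <- tryCatch(
        st_invert(f$model_id, f$params, xe,
                  T_C = kelvin_to_celsius(f$T[1]), bracket = aw_bracket),
        error = function(e) {
          reason <<- conditionMessage(e)
          NA_real_
        }
      )
      aw[i] <- aw_i
    }
    if (any(is.na(aw))) {
      dropped <- c(dropped, sprintf("xe = %s: %s", format(xe), reason))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      xe = xe, T = temps, aw = aw, ln_aw = log(aw), inv_T = 1 / temps
    )
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(xe = numeric(0), T = numeric(0), aw = numeric(0),
               ln_aw = numeric(0), inv_T = numeric(0))
  attr(out, "dropped") <- dropped
  attr(out, "branch") <- branches
  out
}

#' Fit one isostere: ln(aw) against 1/T
#'
#' Ordinary least squares of `ln(aw)` on `1/T`. The slope equals `-qst/R`
#' (Clausius-Clapeyron) and the intercept equals `dS/R`, so the net
#' isosteric heat and the differential entropy fall out directly.
#'
#' @param ln_aw log water activities at one moisture content
#' @param inv_T reciprocal absolute temperatures (1/K), `>= 3` distinct
#' @return list `(qst, dS, r2)`: net isosteric heat (J/mol), differential
#'   entropy (J/mol/K), and the standard R-squared of the line
#' @export
fit_isostere <- function(ln_aw, inv_T) {
  if (length(ln_aw) != length(inv_T) || length(ln_aw) < 3) {
    st_stop("sorptherm_validation_error",
            "isostere regression needs >= 3 (ln aw, 1/T) pairs")
  }
  if (length(unique(inv_T)) < 2) {
    st_stop("sorptherm_validation_error",
            "degenerate isostere: all temperatures identical")
  }
  fit <- stats::lm(ln_aw ~ inv_T)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  sstot <- sum((ln_aw - mean(ln_aw))^2)
  r2 <- if (sstot > 0) 1 - sum(stats::resid(fit)^2) / sstot else 1
  list(qst = -slope * R_GAS, dS = intercept * R_GAS, r2 = r2)
}

#' Latent heat of vaporization of pure water
#'
#' Linear correlation `lambda = R * (6687 - 5.31 * T)` with `T` in Kelvin,
#' returning J/mol. Warns (but still evaluates) outside 250-400 K.
#'
#' @param T_K absolute temperature(s), K
#' @return latent heat(s), J/mol
#' @export
#' @examples
#' latent_heat(298.15)   # ~ 4.24e4 J/mol
latent_heat <- function(T_K) {
  if (any(T_K < 250 | T_K > 400)) {
    st_warn("sorptherm_range_warning",
            "temperature outside 250-400 K; latent-heat correlation extrapolated")
  }
  R_GAS * (6687 - 5.31 * T_K)
}

#' Integral isosteric heat of sorption
#'
#' `Qst = qst + lambda(T_ref)`: the net isosteric heat plus the latent heat
#' of pure water at a reference temperature (default: supply the harmonic
#' mean of the experiment temperatures).
#'
#' @param qst net isosteric heat(s), J/mol
#' @param T_ref reference temperature, K
#' @return integral isosteric heat(s), J/mol
#' @export
integral_heat <- function(qst, T_ref) {
  qst + latent_heat(T_ref)
}

#' Harmonic mean temperature
#'
#' `Th = n / sum(1/T_i)` over the experiment temperatures.
#'
#' @param temps absolute temperatures, K
#' @return harmonic mean temperature, K
#' @export
#' @examples
#' harmonic_mean_temperature(celsius_to_kelvin(c(25, 35, 45)))
harmonic_mean_temperature <- function(temps) {
  if (length(temps) < 1 || any(temps <= 0)) {
    st_stop("sorptherm_validation_error",
            "temperatures must be positive (K)")
  }
  length(temps) / sum(1 / temps)
}

#' Gibbs free energy of sorption
#'
#' `dG = -R * T * ln(aw)` (J/mol); positive for `aw < 1`, i.e. sorption at
#' sub-saturation humidity is non-spontaneous.
#'
#' @param T_K absolute temperature(s), K
#' @param aw water activity(ies), `0 < aw <= 1`
#' @return Gibbs free energy(ies), J/mol
#' @export
gibbs_energy <- function(T_K, aw) {
  if (any(aw <= 0)) {
    st_stop("sorptherm_domain_error", "aw must be > 0 for gibbs_energy")
  }
  if (any(aw > 1)) {
    st_stop("sorptherm_domain_error", "aw must be <= 1 for gibbs_energy")
  }
  -R_GAS * T_K * log(aw)
}

#' Fit a trend curve to a thermodynamic profile
#'
#' Families follow the forms conventionally reported for sorption
#' thermodynamics: power `y = a*x^b` and exponential `y = a*exp(b*x)` are
#' fitted by nonlinear least squares in original space (not log-linearized);
#' logarithmic `y = a*ln(x) + c` and `linear y = a*x + c` by ordinary least
#' squares.
#'
#' @param x predictor (moisture content); must be `> 0` for power/log
#' @param y response
#' @param family one of `"power"`, `"log"`, `"exp"`, `"linear"`
#' @return an object of class `trend_fit`: list with `family`,
#'   `coefficients` (named), `r2`
#' @export
fit_trend <- function(x, y, family = c("power", "log", "exp", "linear")) {
  family <- match.arg(family)
  if (length(x) != length(y) || length(x) < 3) {
    st_stop("sorptherm_validation_error",
            "trend fitting needs >= 3 (x, y) pairs of equal length")
  }
  if (family %in% c("power", "log") && any(x <= 0)) {
    st_stop("sorptherm_validation_error",
            "family '%s' requires x > 0", family)
  }
  r2_of <- function(pred) {
    sstot <- sum((y - mean(y))^2)
    if (sstot > 0) 1 - sum((y - pred)^2) / sstot else 1
  }
  if (family == "log") {
    fit <- stats::lm(y ~ log(x))
    co <- c(a = unname(stats::coef(fit)[2]), c = unname(stats::coef(fit)[1]))
    pred <- co["a"] * log(x) + co["c"]
  } else if (family == "linear") {
    fit <- stats::lm(y ~ x)
    co <- c(a = unname(stats::coef(fit)[2]), c = unname(stats::coef(fit)[1]))
    pred <- co["a"] * x + co["c"]
  } else if (family == "power") {
    # init from log-log regression when possible
    init <- if (all(y > 0)) {
      lf <- stats::lm(log(y) ~ log(x))
      c(exp(unname(stats::coef(lf)[1])), unname(stats::coef(lf)[2]))
    } else c(mean(y), 0)
    res_fun <- function(p) y - p[1] * x^p[2]
    best <- st_lm_fit(res_fun, init, lower = c(-1e8, -100), upper = c(1e8, 100))
    co <- c(a = best$par[1], b = best$par[2])
    pred <- co["a"] * x^co["b"]
  } else { # exp
    init <- if (all(y > 0)) {
      lf <- stats::lm(log(y) ~ x)
      c(exp(unname(stats::coef(lf)[1])), unname(stats::coef(lf)[2]))
    } else c(mean(y), 0)
    res_fun <- function(p) y - p[1] * exp(p[2] * x)
    best <- st_lm_fit(res_fun, init, lower = c(-1e8, -200), upper = c(1e8, 200))
    co <- c(a = best$par[1], b = best$par[2])
    pred <- co["a"] * exp(co["b"] * x)
  }
  out <- list(family = family, coefficients = co, r2 = r2_of(pred))
  class(out) <- "trend_fit"
  out
}

#' @export
print.trend_fit <- function(x, ...) {
  form <- switch(x$family,
    power = sprintf("y = %.4g * x^%.4g", x$coefficients["a"], x$coefficients["b"]),
    exp = sprintf("y = %.4g * exp(%.4g x)", x$coefficients["a"], x$coefficients["b"]),
    log = sprintf("y = %.4g * ln(x) + %.4g", x$coefficients["a"], x$coefficients["c"]),
    linear = sprintf("y = %.4g * x + %.4g", x$coefficients["a"], x$coefficients["c"])
  )
  cat(sprintf("<trend_fit> %s: %s (R2 = %.4f)\n", x$family, form, x$r2))
  invisible(x)
}

#' Enthalpy-entropy compensation and the isokinetic temperature
#'
#' Ordinary least squares of differential enthalpy on differential entropy,
#' `dH = dG_beta + T_beta * dS`. The slope is the isokinetic temperature
#' `T_beta` (K) and the intercept the Gibbs energy at `T_beta`. The verdict
#' compares `T_beta` with the harmonic mean temperature `Th`: enthalpy-driven
#' when `T_beta > Th`, entropy-driven when `T_beta < Th`, indeterminate when
#' the compensation line is weak (`r2 < r2_min`).
#'
#' @param dH differential enthalpies (net isosteric heats), J/mol
#' @param dS differential entropies, J/mol/K
#' @param temps experiment temperatures, K (for `Th`)
#' @param r2_min minimum compensation-line R-squared for a verdict
#' @return an object of class `compensation_result`: list with `T_beta`,
#'   `dG_beta`, `r2`, `T_h`, `verdict`
#' @export
compensation <- function(dH, dS, temps, r2_min = 0.9) {
  if (length(dH) != length(dS) || length(dH) < 3) {
    st_stop("sorptherm_validation_error",
            "compensation needs >= 3 (dH, dS) pairs of equal length")
  }
  if (stats::var(dS) == 0) {
    st_stop("sorptherm_validation_error",
            "zero-variance dS: compensation slope undefined")
  }
  fit <- stats::lm(dH ~ dS)
  T_beta <- unname(stats::coef(fit)[2])
  dG_beta <- unname(stats::coef(fit)[1])
  sstot <- sum((dH - mean(dH))^2)
  r2 <- if (sstot > 0) 1 - sum(stats::resid(fit)^2) / sstot else 1
  T_h <- harmonic_mean_temperature(temps)
  verdict <- if (r2 < r2_min) "indeterminate"
             else if (T_beta > T_h) "enthalpy_driven"
             else if (T_beta < T_h) "entropy_driven"
             else "indeterminate"
  out <- list(T_beta = T_beta, dG_beta = dG_beta, r2 = r2, T_h = T_h,
              verdict = verdict)
  class(out) <- "compensation_result"
  out
}

#' @export
print.compensation_result <- function(x, ...) {
  cat(sprintf(
    "<compensation> T_beta = %.2f K, dG_beta = %.1f J/mol, R2 = %.4f | Th = %.1f K -> %s\n",
    x$T_beta, x$dG_beta, x$r2, x$T_h, x$verdict))
  invisible(x)
}

# default moisture grid: the common invertible support of all fits
default_xe_grid <- function(fits, n = 12, aw_bracket = c(1e-6, AW_MAX)) {
  lims <- vapply(fits, function(f) {
    aw <- c(max(aw_bracket[1], 0.02), min(aw_bracket[2], 0.95))
    range(predict(f, aw))
  }, numeric(2))
  lo <- max(lims[1, ])
  hi <- min(lims[2, ])
  if (!(hi > lo)) {
    st_stop("sorptherm_validation_error",
            "fitted isotherms share no common moisture support")
  }
  span <- hi - lo
  seq(lo + 0.02 * span, hi - 0.02 * span, length.out = n)
}

#' Full thermodynamic profile for one branch
#'
#' Orchestrates isostere construction, per-moisture Clausius-Clapeyron
#' regression, integral heats, Gibbs energies, trend fits and the
#' compensation analysis for one branch.
#'
#' @param fits list of `isotherm_fit`, one per temperature, same branch
#' @param xe_grid moisture grid (default: 12 values across the common
#'   invertible support of the fits)
#' @param aw_bracket inversion bracket
#' @param use_integral_heat if `TRUE`, run the compensation on `Qst` instead
#'   of the net heat `qst`
#' @return an object of class `thermo_profile`: list with `branch`,
#'   `isosteres` (table), `profile` (data frame `xe, qst, Qst, dS, r2`),
#'   `gibbs` (data frame `xe, T, aw, dG`), `T_h`, `lambda_ref`,
#'   `trends` (list of [fit_trend()] results: `Qst_power`, `dS_log`, and per
#'   branch `dG_power`/`dG_exp` pooled and per temperature), `compensation`
#' @export
thermo_profile <- function(fits, xe_grid = NULL,
                           aw_bracket = c(1e-6, AW_MAX),
                           use_integral_heat = FALSE) {
  if (is.null(xe_grid)) xe_grid <- default_xe_grid(fits, aw_bracket = aw_bracket)
  iso <- build_isosteres(fits, xe_grid, aw_bracket = aw_bracket)
  branch <- attr(iso, "branch")
  temps <- sort(unique(iso$T))
  T_h <- harmonic_mean_temperature(vapply(fits, function(f) f$T[1], numeric(1)))
  lambda_ref <- latent_heat(T_h)
  xe_kept <- unique(iso$xe)
  prof <- do.call(rbind, lapply(xe_kept, function(xe) {
    sl <- iso[iso$xe == xe, ]
    est <- fit_isostere(sl$ln_aw, sl$inv_T)
    data.frame(xe = xe, qst = est$qst, Qst = integral_heat(est$qst, T_h),
               dS = est$dS, r2 = est$r2)
  }))
  gibbs <- data.frame(
    xe = iso$xe, T = iso$T, aw = iso$aw,
    dG = gibbs_energy(iso$T, iso$aw)
  )
  # trend fits reported on the kJ/mol scale customary for these profiles
  trends <- list(
    Qst_power = fit_trend(prof$xe, prof$Qst / 1000, "power"),
    dS_log = fit_trend(prof$xe, prof$dS, "log")
  )
  dg_family <- if (branch == "adsorption") "power" else "exp"
  trends[[paste0("dG_", dg_family, "_pooled")]] <-
    fit_trend(gibbs$xe, gibbs$dG / 1000, dg_family)
  for (Tv in temps) {
    gi <- gibbs[gibbs$T == Tv, ]
    trends[[sprintf("dG_%s_%gK", dg_family, round(Tv, 2))]] <-
      fit_trend(gi$xe, gi$dG / 1000, dg_family)
  }
  dH <- if (use_integral_heat) prof$Qst else prof$qst
  comp <- compensation(dH, prof$dS, vapply(fits, function(f) f$T[1], numeric(1)))
  out <- list(
    branch = branch, isosteres = iso, profile = prof, gibbs = gibbs,
    T_h = T_h, lambda_ref = lambda_ref, trends = trends, compensation = comp,
    use_integral_heat = use_integral_heat
  )
  class(out) <- "thermo_profile"
  out
}

#' @export
print.thermo_profile <- function(x, ...) {
  cat(sprintf("<thermo_profile> %s | %d moisture levels | Th = %.1f K\n",
              x$branch, nrow(x$profile), x$T_h))
  print(utils::head(x$profile), digits = 4)
  print(x$compensation)
  invisible(x)
}
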