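#' Fit the Dent model with the monolayer anchored to the BET value
#'
#' The Dent isotherm `Xe = Xm*b0*aw / ((1-b*aw)*(1-b*aw+b0*aw))` is fitted
#' with `Xm` held fixed at the BET monolayer moisture content and `(b, b0)`
#' free, by least squares on moisture-space residuals (consistent with the
#' other model fits, rather than the classical `aw/Xe` quadratic
#' linearization). This anchored fit is the basis of the closed-form
#' spreading pressure.
#'
#' @param group a `sorption_dataset` slice (one branch, one temperature)
#' @param xm_anchor BET monolayer moisture content (g/g dry basis, `> 0`)
#' @param n_starts,seed multi-start control as in [fit_isotherm()]
#' @return an object of class `dent_fit`: list with `b`, `b0`, `Xm_anchor`,
#'   `r2`, `branch`, `T` (K), `pole_warning` (TRUE when `b * max(aw) >= 1`)
#' @export
fit_dent <- function(group, xm_anchor, n_starts = 16L, seed = 20231226L) {
  if (!is.finite(xm_anchor) || xm_anchor <= 0) {
    st_stop("sorptherm_validation_error",
            "xm_anchor must be > 0 (got %s)", format(xm_anchor))
  }
  validate_sorption_dataset(group)
  if (nrow(group) < 3) {
    st_stop("sorptherm_validation_error",
            "at least 3 points required to fit the Dent constants")
  }
  temps <- sorption_temperatures(group)
  if (length(temps) != 1 || length(unique(group$branch)) != 1) {
    st_stop("sorptherm_validation_error",
            "fit_dent expects one branch at one temperature")
  }
  aw <- group$aw
  obs <- group$xe
  dent_fun <- st_models()$dent$fun
  residual_fun <- function(p) obs - dent_fun(aw, c(xm_anchor, p[1], p[2]), NULL)
  lower <- c(0, 1e-6)
  upper <- c(0.9999, 1e6)
  init <- c(0.3, 10)
  starts <- with_seed(seed, {
    s <- list(init)
    if (n_starts > 1) {
      for (i in 2:n_starts) {
        mult <- exp(stats::runif(2, log(0.1), log(10)))
        s[[i]] <- pmin(pmax(init * mult, lower), upper)
      }
    }
    s
  })
  best <- NULL
  for (p0 in starts) {
    fit <- st_lm_fit(residual_fun, p0, lower, upper)
    if (is.null(best) || fit$sse < best$sse) best <- fit
  }
  pred <- dent_fun(aw, c(xm_anchor, best$par), NULL)
  stats <- goodness_of_fit(obs, pred)
  pole <- best$par[1] * max(aw) >= 1
  if (pole) {
    st_warn("sorptherm_pole_warning",
            "Dent pole inside data range: b * max(aw) = %.4f >= 1",
            best$par[1] * max(aw))
  }
  out <- list(
    b = best$par[1], b0 = best$par[2], Xm_anchor = xm_anchor,
    r2 = stats$r2_standard, stats = stats,
    branch = unique(group$branch), T = temps, pole_warning = pole
  )
  class(out) <- "dent_fit"
  out
}

#' @export
print.dent_fit <- function(x, ...) {
  cat(sprintf(
    "<dent_fit> %s | T = %s K | Xm (BET anchor) = %.5g | b = %.5g, b0 = %.5g | R2 = %.4f\n",
    x$branch, format(x$T), x$Xm_anchor, x$b, x$b0, x$r2))
  invisible(x)
}

#' Spreading pressure of the sorbed water film, closed form
#'
#' For a Dent isotherm the surface excess free energy (spreading pressure)
#' integrates in closed form:
#' `phi = (KB*T/Am) * ln((1 + b0*aw - b*aw) / (1 - b*aw))` (J/m^2),
#' with `KB` the Boltzmann constant and `Am` the area of one sorbed water
#' molecule.
#'
#' @param dent a `dent_fit` (or any list with `b`, `b0`, `T` in K)
#' @param aw water activities; requires `b * aw < 1`
#' @param dimensionless if `TRUE`, return `phi * Am / (KB * T)` instead of
#'   J/m^2
#' @return spreading pressure(s)
#' @export
phi_closed <- function(dent, aw, dimensionless = FALSE) {
  if (any(dent$b * aw >= 1)) {
    st_stop("sorptherm_domain_error",
            "phi undefined: b * aw >= 1 (pole of the Dent film)")
  }
  if (any(aw < 0)) {
    st_stop("sorptherm_domain_error", "aw must be >= 0")
  }
  core <- log((1 + dent$b0 * aw - dent$b * aw) / (1 - dent$b * aw))
  if (dimensionless) core else KB * dent$T[1] / AM_WATER * core
}

#' Spreading pressure by direct numerical integration
#'
#' Integrates `(KB*T/Am) * integral_0^aw theta(a)/a da` with
#' `theta = Xe/Xm` the Dent moisture ratio, by adaptive quadrature. The
#' integrand `theta(a)/a = b0 / ((1-b*a)*(1-b*a+b0*a))` has the finite limit
#' `b0` at `a = 0`, which is used explicitly, so there is no singularity at
#' the lower bound. Serves as the independent check on [phi_closed()].
#'
#' @param dent a `dent_fit` (or list with `b`, `b0`, `T`)
#' @param aw_upper upper integration limit; requires `b * aw_upper < 1`
#' @param tol relative quadrature tolerance
#' @param dimensionless as in [phi_closed()]
#' @return spreading pressure (scalar)
#' @export
phi_numeric <- function(dent, aw_upper, tol = 1e-10, dimensionless = FALSE) {
  if (dent$b * aw_upper >= 1) {
    st_stop("sorptherm_domain_error",
            "phi undefined: b * aw_upper >= 1 (pole of the Dent film)")
  }
  if (aw_upper < 0) st_stop("sorptherm_domain_error", "aw_upper must be >= 0")
  if (aw_upper == 0) return(0)
  integrand <- function(a) {
    out <- dent$b0 / ((1 - dent$b * a) * (1 - dent$b * a + dent$b0 * a))
    out[a == 0] <- dent$b0   # analytic limit of theta(a)/a
    out
  }
  q <- tryCatch(
    stats::integrate(integrand, 0, aw_upper, rel.tol = tol,
                     subdivisions = 500L),
    error = function(e) {
      st_stop("sorptherm_numeric_error", "quadrature failed: %s",
              conditionMessage(e))
    }
  )
  if (dimensionless) q$value else KB * dent$T[1] / AM_WATER * q$value
}

#' Spreading-pressure curve on a water-activity grid
#'
#' @param dent a `dent_fit`
#' @param aw_grid water activities (default 0.05 to 0.80 step 0.05)
#' @param dimensionless as in [phi_closed()]
#' @return data frame `(branch, T, aw, phi)`
#' @export
spreading_pressure_curve <- function(dent, aw_grid = seq(0.05, 0.80, by = 0.05),
                                     dimensionless = FALSE) {
  data.frame(
    branch = dent$branch,
    T = dent$T[1],
    aw = aw_grid,
    phi = phi_closed(dent, aw_grid, dimensionless = dimensionless)
  )
}
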