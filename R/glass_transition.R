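#' Gordon-Taylor glass-transition temperature of a water-solids mixture
#'
#' `Tg = ((1-xw)*Tgs + k*xw*Tgw) / ((1-xw) + k*xw)` with `xw` the wet-basis
#' water mass fraction, `Tgs` the glass transition of the anhydrous solids
#' and `Tgw` that of pure water (-135 deg C). The ratio form is affine
#' invariant, so with `Tgs`/`Tgw` in deg C the result is in deg C.
#'
#' @param fit a `gt_fit` (or list with `Tgs`, `k`, `Tgw`, all deg C)
#' @param xw water mass fraction(s) in `[0, 1]`
#' @return glass-transition temperature(s), deg C
#' @export
#' @examples
#' gordon_taylor(list(Tgs = 3.4, k = 0.33, Tgw = -135), xw = 0.074)
gordon_taylor <- function(fit, xw) {
  if (any(!is.finite(xw) | xw < 0 | xw > 1)) {
    st_stop("sorptherm_domain_error", "xw must lie in [0, 1]")
  }
  ((1 - xw) * fit$Tgs + fit$k * xw * fit$Tgw) / ((1 - xw) + fit$k * xw)
}

#' Fit the Gordon-Taylor model to (moisture, Tg) data
#'
#' Nonlinear least squares over `(Tgs, k)` with the water glass transition
#' `Tgw` held fixed (default -135 deg C, the accepted value for amorphous
#' water).
#'
#' @param data a data frame with columns `xw` (wet-basis mass fraction) and
#'   `tg_c` (glass-transition midpoint, deg C), e.g. from [read_tg_csv()]
#' @param tgw_fixed fixed water glass-transition temperature, deg C
#' @return an object of class `gt_fit`: list with `Tgs`, `k`, `Tgw`, `r2`,
#'   `n_points`
#' @export
fit_gordon_taylor <- function(data, tgw_fixed = -135) {
  if (!all(c("xw", "tg_c") %in% names(data))) {
    st_stop("sorptherm_format_error", "data must have columns xw, tg_c")
  }
  xw <- as.numeric(data$xw)
  tg <- as.numeric(data$tg_c)
  if (length(xw) < 3) {
    st_stop("sorptherm_validation_error",
            "Gordon-Taylor fitting needs >= 3 points (got %d)", length(xw))
  }
  if (length(unique(xw)) < 2) {
    st_stop("sorptherm_validation_error",
            "Gordon-Taylor fitting needs >= 2 distinct moisture levels")
  }
  if (any(xw < 0 | xw > 1)) {
    st_stop("sorptherm_validation_error", "xw must lie in [0, 1]")
  }
  res_fun <- function(p) {
    tg - gordon_taylor(list(Tgs = p[1], k = p[2], Tgw = tgw_fixed), xw)
  }
  # Tgs init: Tg extrapolated to xw = 0 (max observed Tg is a fair start)
  init <- c(max(tg), 0.5)
  best <- st_lm_fit(res_fun, init, lower = c(tgw_fixed + 1e-6, 1e-6),
                    upper = c(500, 100))
  pred <- gordon_taylor(list(Tgs = best$par[1], k = best$par[2],
                             Tgw = tgw_fixed), xw)
  sstot <- sum((tg - mean(tg))^2)
  r2 <- if (sstot > 0) 1 - sum((tg - pred)^2) / sstot else 1
  out <- list(Tgs = best$par[1], k = best$par[2], Tgw = tgw_fixed,
              r2 = r2, n_points = length(xw))
  class(out) <- "gt_fit"
  out
}

#' @export
print.gt_fit <- function(x, ...) {
  cat(sprintf(
    "<gt_fit> Tgs = %.2f degC, k = %.3f (Tgw fixed at %.0f degC), R2 = %.4f, n = %d\n",
    x$Tgs, x$k, x$Tgw, x$r2, x$n_points))
  invisible(x)
}

#' Critical moisture content for glassy storage
#'
#' Solves `gordon_taylor(xw) = storage_T` in closed form:
#' `xw = (Tgs - T) / ((Tgs - T) + k*(T - Tgw))`. Below this water mass
#' fraction the material at `storage_T` remains glassy. Outside the
#' solvable range the boundary value is returned with an explanatory flag:
#' `xw = 0` when storage is warmer than `Tgs` (rubbery even when dry),
#' `xw = 1` when storage is at or below `Tgw`.
#'
#' @param fit a `gt_fit`
#' @param storage_T storage temperature, deg C
#' @return list with `xw` (wet basis), `x_db` (dry basis, g/g), `flag`
#'   (`"ok"`, `"rubbery_even_dry"` or `"glassy_at_any_moisture"`)
#' @export
critical_moisture <- function(fit, storage_T) {
  if (storage_T > fit$Tgs) {
    return(list(xw = 0, x_db = 0, flag = "rubbery_even_dry"))
  }
  if (storage_T <= fit$Tgw) {
    return(list(xw = 1, x_db = Inf, flag = "glassy_at_any_moisture"))
  }
  xw <- (fit$Tgs - storage_T) /
    ((fit$Tgs - storage_T) + fit$k * (storage_T - fit$Tgw))
  list(xw = xw, x_db = wet_to_db_fraction(xw), flag = "ok")
}

#' Critical water activity at a storage temperature
#'
#' Converts the critical wet-basis moisture to dry basis and inverts the
#' adsorption-branch isotherm fitted at the storage temperature, giving the
#' relative humidity below which the powder stays glassy.
#'
#' @param xw_critical critical water mass fraction (wet basis)
#' @param isotherm_fit an `isotherm_fit` for the storage temperature
#' @return water activity
#' @export
critical_aw <- function(xw_critical, isotherm_fit) {
  if (xw_critical <= 0) return(0)
  x_db <- wet_to_db_fraction(xw_critical)
  st_invert(isotherm_fit$model_id, isotherm_fit$params, x_db,
            T_C = kelvin_to_celsius(isotherm_fit$T[1]))
}
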