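#' Declare a synthetic sorption scenario
#'
#' The scenario states the world the generator draws from: a ground-truth
#' isotherm model with per-temperature parameters, the measurement grid, the
#' additive moisture noise, and hysteresis expressed as a multiplicative
#' offset on the desorption equilibrium surface. Defaults emulate a dynamic
#' vapor sorption experiment on a protein powder: three temperatures
#' (25/35/45 deg C), water activities 0.09-0.83 in 15 steps, duplicate runs,
#' additive Gaussian noise of 0.002 g/g, and published per-temperature GAB
#' ground truth for the desorption surface.
#'
#' @param model_id ground-truth model id
#' @param params named list mapping temperature (K, as character or numeric
#'   match) to a parameter vector, or a single vector reused at all
#'   temperatures
#' @param temperatures absolute temperatures, K (>= 3 distinct for
#'   thermodynamic use)
#' @param aw_grid water-activity grid
#' @param noise_sd additive Gaussian noise on moisture, g/g
#' @param hysteresis_offset multiplicative factor `>= 1` applied to the
#'   desorption surface
#' @param n_replicates replicate observations per grid point
#' @param seed integer seed
#' @return an object of class `sorption_scenario`
#' @export
sorption_scenario <- function(model_id = "gab",
                              params = list(`298.15` = c(0.71, 3.08, 0.11),
                                            `308.15` = c(0.07, 10.32, 0.77),
                                            `318.15` = c(0.06, 13.83, 0.89)),
                              temperatures = c(298.15, 308.15, 318.15),
                              aw_grid = seq(0.09, 0.83, length.out = 15),
                              noise_sd = 0.002,
                              hysteresis_offset = 1.3,
                              n_replicates = 2L,
                              seed = 20231226L) {
  if (noise_sd < 0) {
    st_stop("sorptherm_validation_error", "noise_sd must be >= 0")
  }
  if (hysteresis_offset < 1) {
    st_stop("sorptherm_validation_error", "hysteresis_offset must be >= 1")
  }
  if (length(unique(temperatures)) != length(temperatures)) {
    st_stop("sorptherm_validation_error", "temperatures must be distinct")
  }
  if (!is.list(params)) {
    params <- stats::setNames(rep(list(params), length(temperatures)),
                              as.character(temperatures))
  }
  missing_T <- setdiff(as.character(temperatures), names(params))
  if (length(missing_T) > 0) {
    st_stop("sorptherm_validation_error",
            "no ground-truth parameters for T = %s K",
            paste(missing_T, collapse = ", "))
  }
  out <- list(model_id = model_id, params = params,
              temperatures = temperatures, aw_grid = aw_grid,
              noise_sd = noise_sd, hysteresis_offset = hysteresis_offset,
              n_replicates = as.integer(n_replicates),
              seed = as.integer(seed))
  class(out) <- "sorption_scenario"
  out
}

#' Generate a synthetic sorption dataset
#'
#' Adsorption points are the ground-truth model curve plus Gaussian noise
#' (clipped at zero moisture); desorption points are the curve scaled by the
#' hysteresis offset plus noise, so the desorption branch lies uniformly
#' above adsorption, as observed in hysteresis loops. Each grid point is
#' replicated `n_replicates` times. Fully reproducible from the scenario
#' seed.
#'
#' @param scenario a [sorption_scenario()]
#' @return a `sorption_dataset`
#' @export
generate_sorption <- function(scenario) {
  stopifnot(inherits(scenario, "sorption_scenario"))
  with_seed(scenario$seed, {
    rows <- list()
    for (Tv in scenario$temperatures) {
      p <- scenario$params[[as.character(Tv)]]
      mu <- tryCatch(
        st_evaluate(scenario$model_id, p, scenario$aw_grid,
                    T_C = kelvin_to_celsius(Tv)),
        error = function(e) {
          st_stop("sorptherm_scenario_error",
                  "ground-truth model pole inside aw grid at T = %s K: %s",
                  format(Tv), conditionMessage(e))
        }
      )
      if (any(!is.finite(mu) | mu < 0)) {
        st_stop("sorptherm_scenario_error",
                "ground-truth model pole inside aw grid at T = %s K (negative or non-finite moisture)",
                format(Tv))
      }
      for (rep_i in seq_len(scenario$n_replicates)) {
        for (br in c("adsorption", "desorption")) {
          base <- if (br == "desorption") scenario$hysteresis_offset * mu else mu
          xe <- base + stats::rnorm(length(base), 0, scenario$noise_sd)
          xe <- pmax(xe, 0)
          rows[[length(rows) + 1L]] <- data.frame(
            branch = br, T = Tv, aw = scenario$aw_grid, xe = xe,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    ds <- do.call(rbind, rows)
    class(ds) <- c("sorption_dataset", "data.frame")
    attr(ds, "label") <- sprintf("synthetic %s scenario (seed %d)",
                                 scenario$model_id, scenario$seed)
    validate_sorption_dataset(ds)
    ds
  })
}

#' Generate a Clausius-Clapeyron-consistent sorption dataset
#'
#' Builds equilibrium points whose water activity at moisture `Xe` and
#' temperature `T` is exactly `aw = exp(-qst(Xe)/(R*T) + dS(Xe)/R)`, so the
#' dataset's true net isosteric heat and differential entropy profiles are
#' `qst_profile` and `dS_profile` by construction. Used as the end-to-end
#' oracle for the isostere pipeline.
#'
#' Note: both profiles constant in `Xe` yields a degenerate world (water
#' activity then does not depend on moisture, so the per-temperature
#' "isotherm" is a vertical line no model can fit). At least one profile
#' must vary with `Xe` for the fitting route to be exercised; a convenient
#' exact construction takes `dS(Xe)` from a reference isotherm (see
#' [ds_profile_from_dent()]).
#'
#' @param qst_profile function of `Xe` returning J/mol
#' @param dS_profile function of `Xe` returning J/mol/K
#' @param temperatures absolute temperatures, K
#' @param xe_grid moisture grid, g/g dry basis
#' @param branch branch label for the emitted points
#' @param noise_sd optional additive Gaussian noise on moisture, g/g
#' @param seed seed for the noise (ignored when `noise_sd = 0`)
#' @return a `sorption_dataset`
#' @export
generate_clausius_consistent <- function(qst_profile, dS_profile,
                                         temperatures = c(298.15, 308.15, 318.15),
                                         xe_grid = seq(0.04, 0.24, length.out = 12),
                                         branch = "adsorption",
                                         noise_sd = 0, seed = 20231226L) {
  rows <- list()
  for (Tv in temperatures) {
    q <- qst_profile(xe_grid)
    s <- dS_profile(xe_grid)
    aw <- exp(-q / (R_GAS * Tv) + s / R_GAS)
    bad <- which(!(aw > 0 & aw < 1))
    if (length(bad) > 0) {
      st_stop("sorptherm_scenario_error",
              "aw = %s outside (0, 1) at Xe = %s, T = %s K",
              format(aw[bad[1]]), format(xe_grid[bad[1]]), format(Tv))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      branch = branch, T = Tv, aw = aw, xe = xe_grid,
      stringsAsFactors = FALSE
    )
  }
  ds <- do.call(rbind, rows)
  if (noise_sd > 0) {
    ds$xe <- with_seed(seed, pmax(ds$xe + stats::rnorm(nrow(ds), 0, noise_sd), 0))
  }
  class(ds) <- c("sorption_dataset", "data.frame")
  attr(ds, "label") <- "Clausius-Clapeyron-consistent synthetic dataset"
  validate_sorption_dataset(ds)
  ds
}

#' Entropy profile induced by a Dent reference isotherm
#'
#' Returns the `dS(Xe)` profile for which
#' `aw(Xe, T) = exp(-qst/(R*T) + dS(Xe)/R)` reproduces a given Dent curve at
#' the reference temperature: `dS(Xe) = R*ln(aw_ref(Xe)) + qst/T_ref`. Since
#' the Dent family is closed under scaling of `aw`, every other temperature's
#' curve is then also an exact Dent isotherm, which makes the construction an
#' exact oracle for the fit-invert-regress pipeline.
#'
#' @param dent_params Dent parameters `c(Xm, b, b0)` of the reference curve
#' @param qst net isosteric heat: a constant (J/mol) or a function of `Xe`
#' @param T_ref reference temperature, K
#' @return function of `Xe` returning J/mol/K
#' @export
ds_profile_from_dent <- function(dent_params, qst, T_ref = 308.15) {
  force(dent_params); force(qst); force(T_ref)
  qfun <- if (is.function(qst)) qst else function(xe) rep(qst, length(xe))
  function(xe) {
    aw_ref <- vapply(xe, function(x) st_invert("dent", dent_params, x),
                     numeric(1))
    R_GAS * log(aw_ref) + qfun(xe) / T_ref
  }
}

#' Declare a synthetic glass-transition scenario
#'
#' Defaults state the published fish-gelatin world: `Tgs = 3.4` deg C,
#' `k = 0.33`, `Tgw = -135` deg C, ten moisture levels, 1 deg C of Gaussian
#' measurement noise on `Tg` (typical midpoint repeatability of a DSC scan).
#'
#' @param Tgs,k,Tgw ground-truth Gordon-Taylor parameters, deg C
#' @param xw_grid wet-basis water mass fractions
#' @param noise_sd Gaussian noise on `Tg`, deg C
#' @param seed integer seed
#' @return an object of class `tg_scenario`
#' @export
tg_scenario <- function(Tgs = 3.4, k = 0.33, Tgw = -135,
                        xw_grid = seq(0.02, 0.30, length.out = 10),
                        noise_sd = 1, seed = 20231226L) {
  if (k <= 0 || Tgw >= Tgs) {
    st_stop("sorptherm_validation_error",
            "scenario requires k > 0 and Tgw < Tgs")
  }
  out <- list(Tgs = Tgs, k = k, Tgw = Tgw, xw_grid = xw_grid,
              noise_sd = noise_sd, seed = as.integer(seed))
  class(out) <- "tg_scenario"
  out
}

#' Generate synthetic glass-transition data
#'
#' @param scenario a [tg_scenario()]
#' @return a `tg_dataset` data frame with columns `xw`, `tg_c`
#' @export
generate_tg <- function(scenario) {
  stopifnot(inherits(scenario, "tg_scenario"))
  tg_true <- gordon_taylor(scenario, scenario$xw_grid)
  tg <- with_seed(scenario$seed,
                  tg_true + stats::rnorm(length(tg_true), 0, scenario$noise_sd))
  out <- data.frame(xw = scenario$xw_grid, tg_c = tg)
  class(out) <- c("tg_dataset", "data.frame")
  out
}
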