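#' Analysis configuration
#'
#' Collects every tunable of the full pipeline with its default. A single
#' seed governs all stochastic stages (multi-start perturbations, synthetic
#' noise) through per-stage derived substreams.
#'
#' @param input path to a sorption CSV or a `sorption_dataset`
#' @param tg_input optional path to a Tg CSV or a `tg_dataset`
#' @param temperature_unit unit of the CSV temperature column
#' @param models model ids to fit (default all ten)
#' @param seed master integer seed
#' @param n_starts multi-start count per fit
#' @param bet_max_aw optional water-activity cut for the BET fit (classical
#'   rigor restricts to `<= 0.5`; default fits the full measured range)
#' @param isostere_model `"auto"` (best-ranked model per branch) or a model id
#' @param xe_grid `NULL` for the automatic common-support grid, or numeric
#' @param aw_grid_spread water-activity grid for spreading-pressure curves
#' @param use_integral_heat run compensation on `Qst` instead of `qst`
#' @param tgw fixed water glass-transition temperature, deg C
#' @param storage_temp storage temperature for the critical-moisture block,
#'   deg C
#' @param storage_threshold_db advisory dry-basis moisture threshold (g/g)
#'   echoed in the storage block (default 0.08 g/g)
#' @return an object of class `analysis_config`
#' @export
analysis_config <- function(input = NULL, tg_input = NULL,
                            temperature_unit = "C",
                            models = names(st_models()),
                            seed = 20231226L, n_starts = 32L,
                            bet_max_aw = NULL,
                            isostere_model = "auto",
                            xe_grid = NULL,
                            aw_grid_spread = seq(0.05, 0.80, by = 0.05),
                            use_integral_heat = FALSE,
                            tgw = -135,
                            storage_temp = 25,
                            storage_threshold_db = 0.08) {
  out <- list(input = input, tg_input = tg_input,
              temperature_unit = temperature_unit, models = models,
              seed = as.integer(seed), n_starts = as.integer(n_starts),
              bet_max_aw = bet_max_aw, isostere_model = isostere_model,
              xe_grid = xe_grid, aw_grid_spread = aw_grid_spread,
              use_integral_heat = use_integral_heat, tgw = tgw,
              storage_temp = storage_temp,
              storage_threshold_db = storage_threshold_db)
  class(out) <- "analysis_config"
  out
}

# stable short hash of the configuration for provenance
config_hash <- function(config) {
  txt <- paste(deparse(config[order(names(unclass(config)))]), collapse = "")
  v <- utf8ToInt(txt)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2^31
  sprintf("%08x", h)
}

# parameter matrix in the published layout: model x parameter, one column
# per branch x temperature
parameters_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    data.frame(
      model_id = f$model_id, branch = f$branch, T = f$T[1],
      parameter = names(f$params), value = unname(f$params),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# criteria matrix mirroring the published fitting-criteria layout
criteria_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    data.frame(
      model_id = f$model_id, branch = f$branch, T = f$T[1],
      sse_eq13 = f$stats$sse_eq13,
      r2_standard = f$stats$r2_standard,
      r2_regression = f$stats$r2_regression,
      e_percent = f$stats$e_percent,
      n_points = f$stats$n_points,
      converged = f$converged,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Hysteresis report from fitted isotherms
#'
#' For every temperature at which both branches are fitted, evaluates the
#' fitted curves on a common water-activity grid and reports the difference
#' `Xe(desorption) - Xe(adsorption)` together with the loop area (trapezoidal
#' integral of the difference over `aw`).
#'
#' @param fits list of `isotherm_fit` containing, per temperature, one
#'   adsorption and one desorption fit
#' @param aw_grid common evaluation grid
#' @return list with `table` (`T, aw, delta_xe`) and `areas` (`T, area`);
#'   temperatures missing a branch are skipped with a warning
#' @export
hysteresis_report <- function(fits, aw_grid = seq(0.10, 0.80, length.out = 15)) {
  temps <- sort(unique(vapply(fits, function(f) f$T[1], numeric(1))))
  tab <- list()
  areas <- list()
  for (Tv in temps) {
    fa <- Filter(function(f) f$T[1] == Tv && f$branch == "adsorption", fits)
    fd <- Filter(function(f) f$T[1] == Tv && f$branch == "desorption", fits)
    if (length(fa) == 0 || length(fd) == 0) {
      st_warn("sorptherm_stage_warning",
              "hysteresis at T = %s K skipped: missing branch", format(Tv))
      next
    }
    delta <- predict(fd[[1]], aw_grid) - predict(fa[[1]], aw_grid)
    tab[[length(tab) + 1L]] <- data.frame(T = Tv, aw = aw_grid,
                                          delta_xe = delta)
    area <- sum(diff(aw_grid) * (utils::head(delta, -1) + utils::tail(delta, -1)) / 2)
    areas[[length(areas) + 1L]] <- data.frame(T = Tv, area = area)
  }
  list(
    table = if (length(tab) > 0) do.call(rbind, tab) else NULL,
    areas = if (length(areas) > 0) do.call(rbind, areas) else NULL
  )
}

#' Run the full sorption analysis pipeline
#'
#' Stages, in order: read/validate data; fit all models per branch and
#' temperature; rank per branch; Dent fits anchored on the BET monolayer and
#' spreading-pressure curves; isostere thermodynamics (requires three or
#' more temperatures) with trend fits and compensation; hysteresis report;
#' Gordon-Taylor fit and critical storage conditions when Tg data are given.
#' A failed or inapplicable stage degrades to a recorded warning instead of
#' aborting the report.
#'
#' @param config an [analysis_config()]
#' @return an object of class `analysis_report`
#' @export
run_pipeline <- function(config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  warnings_log <- character(0)
  note <- function(fmt, ...) {
    warnings_log <<- c(warnings_log, sprintf(fmt, ...))
  }

  ds <- config$input
  if (is.character(ds)) {
    ds <- read_sorption_csv(ds, temperature_unit = config$temperature_unit)
  }
  validate_sorption_dataset(ds)

  fit_seed <- derive_seed(config$seed, "fit")
  fits <- fit_all_isotherms(ds, models = config$models,
                            n_starts = config$n_starts, seed = fit_seed,
                            bet_max_aw = config$bet_max_aw)

  branches <- unique(ds$branch)
  rankings <- list()
  for (br in branches) {
    rankings[[br]] <- rank_models(Filter(function(f) f$branch == br, fits))
    if (rankings[[br]]$no_model_passed) {
      note("branch %s: no model met the selection criteria", br)
    }
  }

  # Dent fits anchored on the per-group BET monolayer
  dent_seed <- derive_seed(config$seed, "dent")
  dent_fits <- list()
  spread <- list()
  for (f in Filter(function(f) f$model_id == "bet", fits)) {
    g <- sorption_group(ds, f$branch, f$T[1])
    df <- tryCatch(
      withCallingHandlers(
        fit_dent(g, xm_anchor = unname(f$params["Xm"]), seed = dent_seed),
        sorptherm_pole_warning = function(w) {
          note("%s", conditionMessage(w))
          invokeRestart("muffleWarning")
        }),
      error = function(e) {
        note("Dent fit failed (%s, %s K): %s", f$branch, format(f$T[1]),
             conditionMessage(e))
        NULL
      })
    if (!is.null(df)) {
      dent_fits[[length(dent_fits) + 1L]] <- df
      spread[[length(spread) + 1L]] <-
        spreading_pressure_curve(df, aw_grid = config$aw_grid_spread)
    }
  }
  spread_tab <- if (length(spread) > 0) do.call(rbind, spread) else NULL

  # thermodynamics per branch (needs >= 3 temperatures)
  thermo <- list()
  for (br in branches) {
    br_fits <- Filter(function(f) f$branch == br, fits)
    temps <- unique(vapply(br_fits, function(f) f$T[1], numeric(1)))
    if (length(temps) < 3) {
      note("branch %s: thermodynamics skipped (%d temperature(s) < 3)",
           br, length(temps))
      next
    }
    model_id <- if (identical(config$isostere_model, "auto")) {
      rankings[[br]]$best_model_id
    } else config$isostere_model
    sel <- Filter(function(f) f$model_id == model_id, br_fits)
    thermo[[br]] <- tryCatch(
      thermo_profile(sel, xe_grid = config$xe_grid,
                     use_integral_heat = config$use_integral_heat),
      error = function(e) {
        note("branch %s: thermodynamics failed: %s", br, conditionMessage(e))
        NULL
      })
    if (!is.null(thermo[[br]]) &&
        length(attr(thermo[[br]]$isosteres, "dropped")) > 0) {
      for (msg in attr(thermo[[br]]$isosteres, "dropped")) {
        note("branch %s isostere: dropped %s", br, msg)
      }
    }
  }

  best_fits <- list()
  for (br in branches) {
    for (Tv in sorption_temperatures(ds, br)) {
      cand <- Filter(function(f) {
        f$branch == br && f$T[1] == Tv &&
          f$model_id == rankings[[br]]$best_model_id
      }, fits)
      if (length(cand) > 0) best_fits[[length(best_fits) + 1L]] <- cand[[1]]
    }
  }
  hyst <- withCallingHandlers(
    hysteresis_report(best_fits),
    sorptherm_stage_warning = function(w) {
      note("%s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  # glass transition / storage block
  tg_block <- NULL
  if (!is.null(config$tg_input)) {
    tg <- config$tg_input
    if (is.character(tg)) tg <- read_tg_csv(tg)
    tg_block <- tryCatch({
      gt <- fit_gordon_taylor(tg, tgw_fixed = config$tgw)
      crit <- critical_moisture(gt, config$storage_temp)
      aw_crit <- NA_real_
      if (crit$flag == "ok" && "adsorption" %in% branches) {
        storage_T_K <- celsius_to_kelvin(config$storage_temp)
        ads_T <- sorption_temperatures(ds, "adsorption")
        nearest <- ads_T[which.min(abs(ads_T - storage_T_K))]
        iso <- Filter(function(f) {
          f$branch == "adsorption" && f$T[1] == nearest &&
            f$model_id == rankings[["adsorption"]]$best_model_id
        }, fits)
        if (length(iso) > 0) {
          aw_crit <- tryCatch(critical_aw(crit$xw, iso[[1]]),
                              error = function(e) {
                                note("critical aw not computed: %s",
                                     conditionMessage(e))
                                NA_real_
                              })
        }
      }
      list(fit = gt, storage_temp = config$storage_temp,
           critical = crit, critical_aw = aw_crit,
           threshold_db = config$storage_threshold_db,
           below_threshold = is.finite(crit$x_db) &&
             crit$x_db <= config$storage_threshold_db)
    }, error = function(e) {
      note("glass-transition stage failed: %s", conditionMessage(e))
      NULL
    })
  }

  out <- list(
    rankings = rankings,
    parameters = parameters_table(fits),
    criteria = criteria_table(fits),
    fits = fits,
    dent_fits = dent_fits,
    spreading = spread_tab,
    thermo = thermo,
    hysteresis = hyst,
    glass_transition = tg_block,
    warnings = warnings_log,
    provenance = list(
      seed = config$seed,
      config_hash = config_hash(config),
      package_version = as.character(utils::packageVersion("sorptherm"))
    )
  )
  class(out) <- "analysis_report"
  out
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  for (br in names(x$rankings)) {
    cat(sprintf("  %s: best model = %s\n", br, x$rankings[[br]]$best_model_id))
  }
  for (br in names(x$thermo)) {
    if (!is.null(x$thermo[[br]])) {
      cat(sprintf("  %s compensation: T_beta = %.1f K vs Th = %.1f K (%s)\n",
                  br, x$thermo[[br]]$compensation$T_beta,
                  x$thermo[[br]]$compensation$T_h,
                  x$thermo[[br]]$compensation$verdict))
    }
  }
  if (!is.null(x$glass_transition)) {
    cat(sprintf("  Gordon-Taylor: Tgs = %.2f degC, k = %.3f\n",
                x$glass_transition$fit$Tgs, x$glass_transition$fit$k))
  }
  if (length(x$warnings) > 0) {
    cat(sprintf("  %d warning(s) logged\n", length(x$warnings)))
  }
  invisible(x)
}

# serialize an analysis report to plain lists (for JSON round-tripping)
report_to_list <- function(report) {
  unclass_deep <- function(x) {
    if (is.data.frame(x)) return(lapply(unclass(x), unname))
    if (is.list(x)) return(lapply(x, unclass_deep))
    x
  }
  unclass_deep(unclass(report))
}

#' Write an analysis report to disk
#'
#' Emits tidy CSVs (`parameters.csv`, `criteria.csv`, `spread.csv`,
#' `profile_<branch>.csv`, `gibbs_<branch>.csv`, `hysteresis.csv`) plus a
#' JSON document (`report.json`) mirroring the parameter/criteria table
#' layout with the compensation, glass-transition and provenance blocks.
#' Output is deterministic for a given report.
#'
#' @param report an `analysis_report`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$parameters, file.path(dir, "parameters.csv"),
                   row.names = FALSE)
  utils::write.csv(report$criteria, file.path(dir, "criteria.csv"),
                   row.names = FALSE)
  if (!is.null(report$spreading)) {
    utils::write.csv(report$spreading, file.path(dir, "spread.csv"),
                     row.names = FALSE)
  }
  for (br in names(report$thermo)) {
    tp <- report$thermo[[br]]
    if (is.null(tp)) next
    utils::write.csv(tp$profile, file.path(dir, sprintf("profile_%s.csv", br)),
                     row.names = FALSE)
    utils::write.csv(tp$gibbs, file.path(dir, sprintf("gibbs_%s.csv", br)),
                     row.names = FALSE)
  }
  if (!is.null(report$hysteresis$table)) {
    utils::write.csv(report$hysteresis$table,
                     file.path(dir, "hysteresis.csv"), row.names = FALSE)
  }
  json <- jsonlite::toJSON(report_to_list(report), auto_unbox = TRUE,
                           digits = NA, null = "null", pretty = TRUE)
  writeLines(json, file.path(dir, "report.json"))
  invisible(dir)
}
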