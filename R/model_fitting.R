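#' Goodness-of-fit statistics for sorption model predictions
#'
#' Computes the three selection statistics conventional in sorption-isotherm
#' work, in both printed and standard form:
#' \itemize{
#'   \item `sse_eq13` — mean squared error `(1/N) * sum((obs - pred)^2)`.
#'     Note the `1/N`: this is the per-point convention used with the
#'     published selection thresholds, not a raw sum of squares.
#'   \item `e_percent` — mean relative percent error
#'     `(100/N) * sum(|obs - pred| / obs)`, computed over observations above
#'     a floor `eps` (division by near-zero moisture is excluded and
#'     flagged).
#'   \item `r2_regression` — regression-sum-of-squares ratio
#'     `sum((pred - mean(obs))^2) / sum((obs - mean(obs))^2)`, the form that
#'     accompanies the printed tables.
#'   \item `r2_standard` — the conventional `1 - SSres/SStot`; this is the
#'     variant the model-selection threshold (`>= 0.90`) is applied to.
#' }
#'
#' @param observed observed moisture contents (g/g dry basis)
#' @param predicted predicted moisture contents, same length
#' @param eps floor below which observations are excluded from `e_percent`
#' @return an object of class `fit_statistics`: list with `r2_regression`,
#'   `r2_standard`, `sse_eq13`, `e_percent`, `e_percent_flagged`, `n_points`
#' @export
#' @examples
#' goodness_of_fit(c(0.02, 0.04, 0.06), c(0.03, 0.04, 0.05))
goodness_of_fit <- function(observed, predicted, eps = 1e-6) {
  if (length(observed) != length(predicted)) {
    st_stop("sorptherm_validation_error",
            "observed (%d) and predicted (%d) lengths differ",
            length(observed), length(predicted))
  }
  if (length(observed) < 2) {
    st_stop("sorptherm_validation_error",
            "at least 2 points required for fit statistics")
  }
  n <- length(observed)
  res <- observed - predicted
  sse_eq13 <- sum(res^2) / n
  sstot <- sum((observed - mean(observed))^2)
  r2_regression <- if (sstot > 0) {
    sum((predicted - mean(observed))^2) / sstot
  } else NA_real_
  r2_standard <- if (sstot > 0) 1 - sum(res^2) / sstot else NA_real_
  admissible <- observed > eps
  e_percent <- if (any(admissible)) {
    100 * mean(abs(res[admissible]) / observed[admissible])
  } else NA_real_
  out <- list(
    r2_regression = r2_regression,
    r2_standard = r2_standard,
    sse_eq13 = sse_eq13,
    e_percent = e_percent,
    e_percent_flagged = !all(admissible),
    n_points = n
  )
  class(out) <- "fit_statistics"
  out
}

#' @export
print.fit_statistics <- function(x, ...) {
  cat(sprintf(
    "fit statistics (n = %d): R2 = %.4f (regression form %.4f), SSE = %.3e, E%% = %.2f%s\n",
    x$n_points, x$r2_standard, x$r2_regression, x$sse_eq13, x$e_percent,
    if (isTRUE(x$e_percent_flagged)) " [near-zero observations excluded]" else ""
  ))
  invisible(x)
}

#' Fit one isotherm model to one (branch, temperature) slice
#'
#' Nonlinear least squares on moisture-space residuals with deterministic
#' multi-start: the registry default initialization plus log-uniform
#' perturbations (multipliers in `[0.1, 10]`) drawn from `seed`. The best
#' converged start is kept, so the result is reproducible bit-for-bit for a
#' given seed.
#'
#' Temperature-dependent models (`mod_oswin`, `mod_halsey`) may be fitted to
#' a slice spanning several temperatures, since the temperature enters the
#' model per point; their `(A, B)` pair is only separately identifiable from
#' such multi-temperature data. All other models require a single
#' temperature.
#'
#' @param group a `sorption_dataset` slice for one branch (one temperature,
#'   except for temperature-dependent models)
#' @param model_id model id from [st_models()]
#' @param n_starts number of multi-start initializations (default 32)
#' @param seed integer seed for the start perturbations
#' @param bet_max_aw optional upper water-activity cut applied to the data
#'   before fitting (classically 0.5 for BET); default `NULL` fits the full
#'   measured range
#' @return an object of class `isotherm_fit`: list with `model_id`, `branch`,
#'   `T` (K), `params` (named), `stats` ([goodness_of_fit()] result),
#'   `converged`, `n_starts_used`, `sse_raw`
#' @export
fit_isotherm <- function(group, model_id, n_starts = 32L, seed = 20231226L,
                         bet_max_aw = NULL) {
  spec <- st_model_spec(model_id)
  validate_sorption_dataset(group)
  if (length(unique(group$branch)) != 1) {
    st_stop("sorptherm_validation_error",
            "fit_isotherm expects a single-branch slice")
  }
  temps <- sorption_temperatures(group)
  if (!spec$uses_temperature && length(temps) != 1) {
    st_stop("sorptherm_validation_error",
            "model '%s' must be fitted per temperature; slice has %d",
            model_id, length(temps))
  }
  if (!is.null(bet_max_aw)) {
    group <- group[group$aw <= bet_max_aw, , drop = FALSE]
  }
  np <- length(spec$param_names)
  if (nrow(group) < max(3L, np)) {
    st_stop("sorptherm_validation_error",
            "underdetermined: %d points for %d-parameter model '%s' (need >= %d)",
            nrow(group), np, model_id, max(3L, np))
  }
  if (length(unique(group$aw)) < 3) {
    st_stop("sorptherm_validation_error",
            "at least 3 distinct aw values required (got %d)",
            length(unique(group$aw)))
  }
  aw <- group$aw
  obs <- group$xe
  T_C <- kelvin_to_celsius(group$T)
  residual_fun <- function(p) obs - spec$fun(aw, p, T_C)

  starts <- with_seed(seed, {
    s <- vector("list", n_starts)
    s[[1]] <- spec$init
    if (n_starts > 1) {
      for (i in 2:n_starts) {
        mult <- exp(stats::runif(np, log(0.1), log(10)))
        s[[i]] <- pmin(pmax(spec$init * mult, spec$lower), spec$upper)
      }
    }
    s
  })

  best <- NULL
  for (p0 in starts) {
    fit <- st_lm_fit(residual_fun, p0, spec$lower, spec$upper)
    if (is.null(best) || fit$sse < best$sse) best <- fit
  }
  if (!is.finite(best$sse)) {
    st_stop("sorptherm_convergence_error",
            "no start converged for model '%s' (best residual norm Inf)",
            model_id)
  }
  pred <- spec$fun(aw, best$par, T_C)
  out <- list(
    model_id = model_id,
    branch = unique(group$branch),
    T = temps,
    params = stats::setNames(best$par, spec$param_names),
    stats = goodness_of_fit(obs, pred),
    converged = best$converged,
    n_starts_used = as.integer(n_starts),
    sse_raw = best$sse,
    seed = as.integer(seed)
  )
  class(out) <- "isotherm_fit"
  out
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf("<isotherm_fit> %s | %s | T = %s K\n", x$model_id, x$branch,
              paste(format(x$T), collapse = ", ")))
  cat("  params:", paste(sprintf("%s = %.6g", names(x$params), x$params),
                         collapse = ", "), "\n")
  print(x$stats)
  invisible(x)
}

#' Predict from a fitted isotherm
#' @param object an `isotherm_fit`
#' @param aw water activities
#' @param T_C temperature (deg C) for temperature-dependent models; defaults
#'   to the fit's own temperature
#' @param ... unused
#' @return predicted moisture contents (g/g dry basis)
#' @export
predict.isotherm_fit <- function(object, aw, T_C = NULL, ...) {
  if (is.null(T_C)) T_C <- kelvin_to_celsius(object$T[1])
  st_evaluate(object$model_id, object$params, aw, T_C = T_C)
}

#' Fit every registered model to every (branch, temperature) group
#'
#' @param ds a `sorption_dataset`
#' @param models model ids (default: all ten)
#' @param n_starts,seed,bet_max_aw passed to [fit_isotherm()]
#' @return list of `isotherm_fit`, one per model x branch x temperature
#'   (temperature-dependent models are still fitted per temperature here,
#'   matching the published per-temperature parameter tables)
#' @export
fit_all_isotherms <- function(ds, models = names(st_models()),
                              n_starts = 32L, seed = 20231226L,
                              bet_max_aw = NULL) {
  groups <- sorption_groups(ds)
  fits <- list()
  for (g in groups) {
    for (m in models) {
      cut <- if (identical(m, "bet")) bet_max_aw else NULL
      fits[[length(fits) + 1L]] <-
        fit_isotherm(g, m, n_starts = n_starts, seed = seed, bet_max_aw = cut)
    }
  }
  fits
}

#' Rank fitted models for one branch by the published selection criteria
#'
#' A model passes when `r2_standard >= 0.90` and `e_percent < 10` at every
#' temperature. Passing models are ordered by total `sse_eq13` across
#' temperatures (ascending), ties broken by mean E percent, then by fewer
#' parameters. If no model passes, the best model is chosen by total SSE and
#' flagged with a warning field.
#'
#' @param fits list of `isotherm_fit` objects for a single branch
#' @param r2_min,e_max the selection thresholds
#' @return an object of class `model_ranking`: list with `branch`, `table`
#'   (one row per model: mean R2, mean E percent, total SSE, passes),
#'   `best_model_id`, `no_model_passed`
#' @export
rank_models <- function(fits, r2_min = 0.90, e_max = 10) {
  branches <- unique(vapply(fits, function(f) f$branch, character(1)))
  if (length(branches) != 1) {
    st_stop("sorptherm_validation_error",
            "rank_models expects fits for exactly one branch (got: %s)",
            paste(branches, collapse = ", "))
  }
  ids <- unique(vapply(fits, function(f) f$model_id, character(1)))
  reg <- st_models()
  rows <- lapply(ids, function(id) {
    fs <- Filter(function(f) f$model_id == id, fits)
    r2 <- vapply(fs, function(f) f$stats$r2_standard, numeric(1))
    ep <- vapply(fs, function(f) f$stats$e_percent, numeric(1))
    sse <- vapply(fs, function(f) f$stats$sse_eq13, numeric(1))
    data.frame(
      model_id = id,
      n_params = length(reg[[id]]$param_names),
      n_temperatures = length(fs),
      mean_r2 = mean(r2),
      mean_e_percent = mean(ep),
      total_sse = sum(sse),
      passes_criteria = all(r2 >= r2_min) && all(ep < e_max),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  ord <- order(!tab$passes_criteria, tab$total_sse, tab$mean_e_percent,
               tab$n_params)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  no_pass <- !any(tab$passes_criteria)
  out <- list(
    branch = branches,
    table = tab,
    best_model_id = tab$model_id[1],
    no_model_passed = no_pass
  )
  class(out) <- "model_ranking"
  out
}

#' @export
print.model_ranking <- function(x, ...) {
  cat(sprintf("<model_ranking> branch = %s, best = %s%s\n", x$branch,
              x$best_model_id,
              if (x$no_model_passed) " (no model met the criteria)" else ""))
  print(x$table, digits = 4)
  invisible(x)
}
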