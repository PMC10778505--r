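#' Registry of sorption isotherm models
#'
#' Ten classical water-sorption models, each mapping water activity `aw`
#' (and, for the two "modified" models, temperature) to equilibrium moisture
#' content `Xe` in g water / g dry matter:
#'
#' \describe{
#'   \item{peleg}{`Xe = C1*aw^C2 + C3*aw^C4`}
#'   \item{gab}{`Xe = Xm*C*K*aw / ((1-K*aw)*(1-K*aw+C*K*aw))`}
#'   \item{bet}{`Xe = Xm*C*aw / ((1-aw)*(1+(C-1)*aw))`}
#'   \item{halsey}{`Xe = (A / (-ln aw))^(1/B)`, `A > 0`}
#'   \item{oswin}{`Xe = K*(aw/(1-aw))^n`}
#'   \item{smith}{`Xe = A - B*ln(1-aw)`}
#'   \item{adam_shove}{`Xe = A + B*aw + C*aw^2 + D*aw^3`}
#'   \item{mod_oswin}{`Xe = (A + B*T)*(aw/(1-aw))^C`, `T` in deg C}
#'   \item{mod_halsey}{`Xe = (-exp(A + B*T)/ln aw)^(1/C)`, `T` in deg C}
#'   \item{dent}{`Xe = Xm*b0*aw / ((1-b*aw)*(1-b*aw+b0*aw))`}
#' }
#'
#' The temperature unit inside the two modified models is degrees Celsius:
#' with published fish-gelatin parameters the pre-factor `A + B*T` is only
#' positive when `T` is in Celsius, and the choice is recorded in the
#' registry metadata (`temperature_unit`).
#'
#' @return a named list of model specs; each spec has elements `model_id`,
#'   `name`, `param_names`, `uses_temperature`, `temperature_unit`, `lower`,
#'   `upper`, `init` and the evaluation function `fun(aw, p, T_C)`.
#' @export
#' @examples
#' names(st_models())
#' st_models()$gab$param_names
st_models <- function() {
  spec <- function(model_id, name, param_names, fun,
                   lower, upper, init, uses_temperature = FALSE) {
    list(model_id = model_id, name = name, param_names = param_names,
         uses_temperature = uses_temperature,
         temperature_unit = if (uses_temperature) "C" else NA_character_,
         lower = stats::setNames(lower, param_names),
         upper = stats::setNames(upper, param_names),
         init = stats::setNames(init, param_names),
         fun = fun)
  }
  list(
    peleg = spec(
      "peleg", "Peleg", c("C1", "C2", "C3", "C4"),
      function(aw, p, T_C) p[1] * aw^p[2] + p[3] * aw^p[4],
      lower = c(1e-8, 0.01, 1e-8, 0.01), upper = c(1e3, 80, 1e3, 80),
      init = c(0.3, 5, 0.05, 1.2)
    ),
    gab = spec(
      "gab", "GAB", c("Xm", "C", "K"),
      function(aw, p, T_C) {
        d1 <- 1 - p[3] * aw
        d2 <- 1 - p[3] * aw + p[2] * p[3] * aw
        if (any(abs(d1) < 1e-12) || any(abs(d2) < 1e-12)) {
          st_stop("sorptherm_domain_error",
                  "GAB pole: denominator vanishes at aw = %s",
                  format(aw[which.min(pmin(abs(d1), abs(d2)))]))
        }
        p[1] * p[2] * p[3] * aw / (d1 * d2)
      },
      lower = c(1e-4, 1e-4, 1e-3), upper = c(10, 1e9, 2),
      init = c(0.05, 10, 0.8)
    ),
    bet = spec(
      "bet", "BET", c("Xm", "C"),
      function(aw, p, T_C) {
        d <- (1 - aw) * (1 + (p[2] - 1) * aw)
        if (any(abs(d) < 1e-12)) {
          st_stop("sorptherm_domain_error",
                  "BET pole: denominator vanishes at aw = %s",
                  format(aw[which.min(abs(d))]))
        }
        p[1] * p[2] * aw / d
      },
      lower = c(1e-4, 1e-6), upper = c(10, 1e12),
      init = c(0.05, 10)
    ),
    halsey = spec(
      "halsey", "Halsey", c("A", "B"),
      function(aw, p, T_C) {
        out <- numeric(length(aw))
        pos <- aw > 0
        out[pos] <- (p[1] / (-log(aw[pos])))^(1 / p[2])
        out
      },
      lower = c(1e-6, 0.01), upper = c(100, 50),
      init = c(0.05, 1.2)
    ),
    oswin = spec(
      "oswin", "Oswin", c("K", "n"),
      function(aw, p, T_C) p[1] * (aw / (1 - aw))^p[2],
      lower = c(1e-6, 0.01), upper = c(100, 20),
      init = c(0.05, 0.7)
    ),
    smith = spec(
      "smith", "Smith", c("A", "B"),
      function(aw, p, T_C) p[1] - p[2] * log(1 - aw),
      lower = c(-10, -10), upper = c(10, 10),
      init = c(0.01, 0.1)
    ),
    adam_shove = spec(
      "adam_shove", "Adam-Shove", c("A", "B", "C", "D"),
      function(aw, p, T_C) p[1] + p[2] * aw + p[3] * aw^2 + p[4] * aw^3,
      lower = c(-100, -100, -100, -100), upper = c(100, 100, 100, 100),
      init = c(0.02, 0.1, 0.1, 0.1)
    ),
    mod_oswin = spec(
      "mod_oswin", "Modified Oswin", c("A", "B", "C"),
      function(aw, p, T_C) (p[1] + p[2] * T_C) * (aw / (1 - aw))^p[3],
      lower = c(-100, -10, 0.01), upper = c(100, 10, 20),
      init = c(0.05, 1e-3, 0.7), uses_temperature = TRUE
    ),
    mod_halsey = spec(
      "mod_halsey", "Modified Halsey", c("A", "B", "C"),
      function(aw, p, T_C) {
        out <- numeric(length(aw))
        pos <- aw > 0
        out[pos] <- (-exp(p[1] + p[2] * T_C) / log(aw[pos]))^(1 / p[3])
        out
      },
      lower = c(-500, -50, 0.01), upper = c(500, 50, 20),
      init = c(-3, 0.01, 1.2), uses_temperature = TRUE
    ),
    dent = spec(
      "dent", "Dent", c("Xm", "b", "b0"),
      function(aw, p, T_C) {
        d1 <- 1 - p[2] * aw
        d2 <- 1 - p[2] * aw + p[3] * aw
        if (any(abs(d1) < 1e-12) || any(abs(d2) < 1e-12)) {
          st_stop("sorptherm_domain_error",
                  "Dent pole: denominator vanishes at aw = %s",
                  format(aw[which.min(pmin(abs(d1), abs(d2)))]))
        }
        p[1] * p[3] * aw / (d1 * d2)
      },
      lower = c(1e-4, 0, 1e-6), upper = c(10, 0.9999, 1e6),
      init = c(0.05, 0.3, 10)
    )
  )
}

# internal: fetch one spec or fail with the known ids
st_model_spec <- function(model_id) {
  reg <- st_models()
  if (!model_id %in% names(reg)) {
    st_stop("sorptherm_validation_error", "unknown model '%s' (known: %s)",
            model_id, paste(names(reg), collapse = ", "))
  }
  reg[[model_id]]
}

# maximum water activity at which singular models are evaluated
AW_MAX <- 0.999

#' Evaluate a sorption isotherm model
#'
#' @param model_id one of the ids in [st_models()]
#' @param params numeric parameter vector in registry order (may be named)
#' @param aw water activities, each in `[0, 1)`; values above 0.999 are
#'   rejected because several models are singular at `aw = 1`
#' @param T_C temperature in degrees Celsius; required (scalar or per-point)
#'   for `mod_oswin` and `mod_halsey`, ignored otherwise
#' @return predicted equilibrium moisture content(s), g/g dry basis
#' @export
#' @examples
#' st_evaluate("gab", c(Xm = 0.06, C = 13.83, K = 0.89), aw = c(0.2, 0.5))
st_evaluate <- function(model_id, params, aw, T_C = NULL) {
  spec <- st_model_spec(model_id)
  params <- as.numeric(params)
  if (length(params) != length(spec$param_names)) {
    st_stop("sorptherm_validation_error",
            "model '%s' takes %d parameters (%s), got %d", model_id,
            length(spec$param_names), paste(spec$param_names, collapse = ", "),
            length(params))
  }
  if (any(!is.finite(aw) | aw < 0 | aw > AW_MAX)) {
    st_stop("sorptherm_domain_error",
            "aw must lie in [0, %s] for model evaluation", format(AW_MAX))
  }
  if (spec$uses_temperature) {
    if (is.null(T_C)) {
      st_stop("sorptherm_validation_error",
              "model '%s' requires a temperature (deg C)", model_id)
    }
    T_C <- rep_len(as.numeric(T_C), length(aw))
  }
  spec$fun(aw, params, T_C)
}

#' Invert a sorption isotherm model
#'
#' Finds the water activity at which the model predicts a target moisture
#' content, by Brent root bracketing (derivative-free). The model must be
#' strictly monotone on the bracket; this is checked by sampling.
#'
#' @param model_id model id
#' @param params parameter vector
#' @param xe_target target moisture content (g/g dry basis, `>= 0`)
#' @param T_C temperature in degrees Celsius for temperature-dependent models
#' @param bracket water-activity search interval, default `c(1e-6, 0.999)`
#' @param tol absolute tolerance on the moisture residual, relative to
#'   `max(1, xe_target)`
#' @return the water activity solving `Xe(aw) = xe_target`
#' @export
#' @examples
#' p <- c(Xm = 0.06, C = 13.83, K = 0.89)
#' aw <- st_invert("gab", p, st_evaluate("gab", p, 0.4))
st_invert <- function(model_id, params, xe_target, T_C = NULL,
                      bracket = c(1e-6, AW_MAX), tol = 1e-10) {
  if (!is.finite(xe_target) || xe_target < 0) {
    st_stop("sorptherm_range_error",
            "xe_target must be a nonnegative number (got %s)",
            format(xe_target))
  }
  f <- function(aw) st_evaluate(model_id, params, aw, T_C = T_C)
  grid <- seq(bracket[1], bracket[2], length.out = 64)
  vals <- f(grid)
  d <- diff(vals)
  if (!(all(d > 0) || all(d < 0))) {
    st_stop("sorptherm_inversion_error",
            "model '%s' is not strictly monotone on [%s, %s]; narrow the bracket",
            model_id, format(bracket[1]), format(bracket[2]))
  }
  lo <- min(vals[1], vals[length(vals)])
  hi <- max(vals[1], vals[length(vals)])
  if (xe_target < lo || xe_target > hi) {
    st_stop("sorptherm_range_error",
            "xe_target = %s outside the model image [%s, %s] on the bracket",
            format(xe_target), format(lo), format(hi))
  }
  root <- stats::uniroot(function(aw) f(aw) - xe_target,
                         interval = bracket, tol = .Machine$double.eps^0.75,
                         maxiter = 2000)$root
  # polish by bisection until the moisture residual meets the contract
  target_tol <- tol * max(1, xe_target)
  if (abs(f(root) - xe_target) > target_tol) {
    a <- bracket[1]; b <- bracket[2]
    fa <- f(a) - xe_target
    for (i in 1:200) {
      m <- (a + b) / 2
      fm <- f(m) - xe_target
      if (abs(fm) <= target_tol) { root <- m; break }
      if (sign(fm) == sign(fa)) { a <- m; fa <- fm } else b <- m
    }
  }
  root
}
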