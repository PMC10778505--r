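# Levenberg-Marquardt least squares with box-projected parameters.
#
# Used by every nonlinear fit in the package (isotherm fitting, Dent
# anchoring, Gordon-Taylor, trend curves). minpack-style libraries are not
# assumed; this keeps convergence behaviour identical and deterministic
# across modules, and reaches machine-precision residuals on noiseless data,
# which base nls() refuses (zero-residual convergence failure).

# residual_fun(p) -> numeric residual vector; returns NULL-safe Inf on error
st_lm_residual_safe <- function(residual_fun, p) {
  r <- tryCatch(residual_fun(p), error = function(e) NULL)
  if (is.null(r) || any(!is.finite(r))) return(NULL)
  r
}

st_lm_fit <- function(residual_fun, p0, lower, upper,
                      max_iter = 250L, ftol = 1e-15, gtol = 1e-14) {
  p <- pmin(pmax(as.numeric(p0), lower), upper)
  np <- length(p)
  r <- st_lm_residual_safe(residual_fun, p)
  if (is.null(r)) {
    return(list(par = p, sse = Inf, converged = FALSE, iterations = 0L))
  }
  sse <- sum(r^2)
  lambda <- 1e-3
  converged <- FALSE
  it <- 0L
  jac <- function(p, r0) {
    J <- matrix(0, nrow = length(r0), ncol = np)
    for (j in seq_len(np)) {
      h <- max(abs(p[j]) * 1e-7, 1e-10)
      pp <- p; pm <- p
      pp[j] <- min(p[j] + h, upper[j])
      pm[j] <- max(p[j] - h, lower[j])
      dh <- pp[j] - pm[j]
      if (dh == 0) next
      rp <- st_lm_residual_safe(residual_fun, pp)
      rm <- st_lm_residual_safe(residual_fun, pm)
      if (is.null(rp) || is.null(rm)) return(NULL)
      J[, j] <- (rp - rm) / dh
    }
    J
  }
  while (it < max_iter) {
    it <- it + 1L
    J <- jac(p, r)
    if (is.null(J)) break
    g <- crossprod(J, r)                      # gradient of 0.5*sse
    if (max(abs(g)) < gtol * max(1, sse)) { converged <- TRUE; break }
    A <- crossprod(J)
    dA <- diag(A)
    dA[dA < 1e-300] <- 1e-300
    improved <- FALSE
    for (k in 1:25) {
      M <- A + lambda * diag(dA, nrow = np)
      delta <- tryCatch(solve(M, -g), error = function(e) NULL)
      if (!is.null(delta)) {
        p_new <- pmin(pmax(p + as.numeric(delta), lower), upper)
        r_new <- st_lm_residual_safe(residual_fun, p_new)
        if (!is.null(r_new)) {
          sse_new <- sum(r_new^2)
          if (sse_new < sse) {
            rel <- (sse - sse_new) / max(sse, 1e-300)
            p <- p_new; r <- r_new; sse <- sse_new
            lambda <- max(lambda / 3, 1e-12)
            improved <- TRUE
            if (rel < ftol || sse < 1e-300) converged <- TRUE
            break
          }
        }
      }
      lambda <- lambda * 5
      if (lambda > 1e12) break
    }
    if (!improved || converged) {
      if (!improved && lambda > 1e12) converged <- TRUE  # stalled at optimum
      break
    }
  }
  list(par = p, sse = sse, converged = converged || sse < 1e-280,
       iterations = it)
}

# run code under a temporary RNG state derived from `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a bounded sub-seed for a named pipeline stage
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
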