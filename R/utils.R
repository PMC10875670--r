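# Internal helpers shared across modules.

stop_monofilm <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "monofilm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so generators never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_monofilm("`seed` must be a single integer", "monofilm_domain_error")
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Savitzky-Golay-style local polynomial fit on a possibly non-uniform grid.
# For each point the `window` nearest neighbours (kept contiguous, shifted at
# the edges) are fit with a degree-`order` polynomial centred on that point;
# returns the fitted value (deriv = 0) or first derivative (deriv = 1).
local_poly <- function(x, y, window = 11L, order = 3L, deriv = 0L) {
  n <- length(x)
  window <- as.integer(window)
  order <- as.integer(order)
  if (window %% 2L == 0L) window <- window + 1L
  if (n < window) {
    stop_monofilm(
      sprintf("need at least %d points for smoothing window %d", window, window),
      "monofilm_config_error"
    )
  }
  if (order >= window) {
    stop_monofilm("polynomial order must be below the window size",
                  "monofilm_config_error")
  }
  h <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- min(max(1L, i - h), n - window + 1L)
    idx <- lo:(lo + window - 1L)
    dx <- x[idx] - x[i]
    X <- outer(dx, 0:order, `^`)
    beta <- qr.coef(qr(X), y[idx])
    beta[is.na(beta)] <- 0
    out[i] <- if (deriv == 0L) beta[[1L]] else beta[[2L]]
  }
  out
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

# Uniform pi grid for Eq-1-style integrals: 0, dpi, 2 dpi, ..., pi_target,
# with the endpoint appended when pi_target is not a multiple of dpi.
pressure_grid <- function(pi_target, dpi) {
  if (!is.finite(dpi) || dpi <= 0) {
    stop_monofilm("`dpi` must be a positive pressure step",
                  "monofilm_domain_error")
  }
  grid <- seq(0, pi_target, by = dpi)
  if (tail(grid, 1L) < pi_target - 1e-12) grid <- c(grid, pi_target)
  grid
}

fmt_num <- function(x) formatC(x, digits = 17, format = "g", width = -1)
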