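# Internal helpers: classed errors, seeded RNG scope, truncated normal draws.

stop_aorta <- function(class, message, ...) {
  stop(structure(
    class = c(class, "aortamech_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' @noRd
stop_invalid_geometry <- function(message) {
  stop_aorta("aortamech_invalid_geometry", message)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. All stochastic operations in the package funnel through this so
# results are reproducible given (seed) and independent of global state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Derive a reproducible child seed from a parent seed and a label, so that
# per-specimen / per-field streams do not collide. Kept below 2^31 - 1.
derive_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  parts <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(parts)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  as.integer(h + 1)
}

# Normal draw truncated to mean +/- 3 SD and to strictly positive values,
# by resampling. Degenerate SD = 0 returns the mean.
rtruncnorm_pos <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  lo <- max(mean - 3 * sd, .Machine$double.eps)
  hi <- mean + 3 * sd
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi & draw > 0
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# Linear interpolation of y at x0 on a discretely sampled curve; for
# duplicated x the last occurrence wins (monotone ramps make this safe).
interp_last <- function(x, y, x0) {
  keep <- !duplicated(x, fromLast = TRUE)
  stats::approx(x[keep], y[keep], xout = x0, rule = 1)$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
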