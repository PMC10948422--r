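# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)

#' @noRd
assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(sprintf("`%s` must be a single finite number", name))
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_domain(sprintf("`%s` = %g is outside its admissible range", name, x))
  invisible(x)
}

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, stable
logdiffexp <- function(a, b) {
  if (b > a) stop_domain("logdiffexp requires a >= b")
  if (b == a) return(-Inf)
  a + log1p(-exp(b - a))
}

# interpolated weighted median of values b with non-negative weights w
# (cumulative weights centred at cumsum(w) - w/2, linear interpolation at 0.5)
weighted_median_interp <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  cs <- cumsum(w) - w / 2
  if (cs[1L] >= 0.5) return(b[1L])
  k <- length(b)
  if (cs[k] <= 0.5) return(b[k])
  i <- max(which(cs < 0.5))
  b[i] + (b[i + 1L] - b[i]) * (0.5 - cs[i]) / (cs[i + 1L] - cs[i])
}

two_sided_normal_p <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmin(pmax(p, .Machine$double.xmin), 1)
}

# deterministic sub-seed derivation: keep results < 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% 2147483647L
}
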