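# Causal-effect estimators for harmonized exposure/outcome effect pairs.
#
# All estimators operate on Wald ratios r_j = beta_Yj / beta_Xj with
# first-order standard errors se(r_j) = |se_Yj / beta_Xj| and inverse-
# variance weights w_j = 1 / se(r_j)^2.

Z975 <- 1.959964

new_mr_estimate <- function(method, beta, se, pvalue, n_snps, ...) {
  structure(list(method = method, beta = beta, se = se, pvalue = pvalue,
                 n_snps = as.integer(n_snps), ...),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4g (se %.4g), p = %.3g, nsnp = %d\n",
              x$method, x$beta, x$se, x$pvalue, x$n_snps))
  if (!is.null(x$or_value))
    cat(sprintf("  OR = %.4f (95%% CI %.4f-%.4f)\n",
                x$or_value, x$or_lci, x$or_uci))
  invisible(x)
}

# ratios and weights for a harmonized set
wald_ratios <- function(hset) {
  bx <- hset$beta_exposure
  if (any(bx == 0))
    stop_domain("Wald ratio undefined: exposure beta of 0 for ",
                paste(hset$variant_id[bx == 0], collapse = ", "))
  r <- hset$beta_outcome / bx
  se_r <- abs(hset$se_outcome / bx)
  list(ratio = r, se = se_r, w = 1 / se_r^2, variant_id = hset$variant_id)
}

#' Single-instrument Wald ratio estimate
#'
#' The causal estimate from one variant: `beta_Y / beta_X`, with the
#' first-order (delta-method) standard error `|se_Y / beta_X|` and a
#' two-sided normal p-value.
#'
#' @param beta_x,se_x Exposure association and its standard error.
#' @param beta_y,se_y Outcome association and its standard error.
#' @return An `mr_estimate`.
#' @export
#' @examples
#' wald_ratio(0.2, 0.01, 0.05, 0.02)
wald_ratio <- function(beta_x, se_x, beta_y, se_y) {
  if (beta_x == 0) stop_domain("Wald ratio undefined for beta_x = 0")
  if (se_y <= 0) stop_domain("se_y must be positive")
  beta <- beta_y / beta_x
  se <- abs(se_y / beta_x)
  new_mr_estimate("wald_ratio", beta, se, two_sided_normal_p(beta / se), 1L)
}

#' Inverse-variance weighted causal estimate
#'
#' The weighted average of per-variant Wald ratios with inverse-variance
#' weights; equivalent to weighted regression of outcome on exposure effects
#' through the origin. The default multiplicative random-effects mode
#' inflates the fixed-effect standard error by `sqrt(Q / (k - 1))` when
#' Cochran's Q exceeds its degrees of freedom; `mode = "fixed"` keeps the
#' fixed-effect standard error.
#'
#' @param hset A `harmonized_set`. A single pair degrades to the Wald ratio
#'   (with a message).
#' @param mode `"random_multiplicative"` (default) or `"fixed"`.
#' @return An `mr_estimate` (method `"ivw"`) carrying `q_stat` and `q_df`.
#' @export
mr_ivw <- function(hset, mode = c("random_multiplicative", "fixed")) {
  mode <- match.arg(mode)
  k <- nrow(hset)
  if (k == 0) stop_domain("empty harmonized set")
  if (k == 1) {
    message("single instrument: IVW degrades to the Wald ratio")
    est <- wald_ratio(hset$beta_exposure, hset$se_exposure,
                      hset$beta_outcome, hset$se_outcome)
    est$method <- "ivw"
    est$q_stat <- 0; est$q_df <- 0L
    return(est)
  }
  wr <- wald_ratios(hset)
  beta <- sum(wr$w * wr$ratio) / sum(wr$w)
  se_fixed <- sqrt(1 / sum(wr$w))
  q <- sum(wr$w * (wr$ratio - beta)^2)
  se <- if (mode == "random_multiplicative" && q > (k - 1))
    se_fixed * sqrt(q / (k - 1)) else se_fixed
  new_mr_estimate("ivw", beta, se, two_sided_normal_p(beta / se), k,
                  q_stat = q, q_df = k - 1L, mode = mode)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with an
#' unconstrained intercept and weights `1/se_Y^2`. Exposure effects are
#' orientation-standardized first (each pair is sign-flipped so that
#' `beta_X >= 0`), which the intercept's interpretation as average
#' directional pleiotropy requires. Slope and intercept are reported with
#' standard errors from the weighted fit and two-sided p-values on the t
#' distribution with `k - 2` degrees of freedom. The `I2_GX` statistic
#' (heterogeneity of the exposure associations relative to their precision)
#' quantifies regression-dilution risk under the "NO Measurement Error"
#' assumption; values below 0.9 flag likely attenuation of the Egger slope
#' toward the null, reported in `nome_warning`.
#'
#' @param hset A `harmonized_set` with at least 3 pairs.
#' @return A list of class `mr_egger` with elements `slope` and `intercept`
#'   (both `mr_estimate`), `i2_gx`, and `nome_warning`.
#' @export
mr_egger <- function(hset) {
  k <- nrow(hset)
  if (k < 3) stop_domain("MR-Egger requires at least 3 instruments")
  flip <- ifelse(hset$beta_exposure < 0, -1, 1)
  bx <- hset$beta_exposure * flip
  by <- hset$beta_outcome * flip
  w <- 1 / hset$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  cf <- summary(fit)$coefficients
  t_p <- function(est, se) 2 * stats::pt(-abs(est / se), df = k - 2)
  slope <- new_mr_estimate("egger_slope", cf["bx", 1], cf["bx", 2],
                           t_p(cf["bx", 1], cf["bx", 2]), k)
  intercept <- new_mr_estimate("egger_intercept", cf["(Intercept)", 1],
                               cf["(Intercept)", 2],
                               t_p(cf["(Intercept)", 1], cf["(Intercept)", 2]),
                               k)
  wx <- 1 / hset$se_exposure^2
  bx_bar <- sum(wx * bx) / sum(wx)
  q_gx <- sum((bx - bx_bar)^2 * wx)
  i2_gx <- if (q_gx > 0) max(0, (q_gx - (k - 1)) / q_gx) else 0
  structure(list(slope = slope, intercept = intercept, i2_gx = i2_gx,
                 nome_warning = i2_gx < 0.9),
            class = "mr_egger")
}

#' @export
print.mr_egger <- function(x, ...) {
  print(x$slope); print(x$intercept)
  cat(sprintf("I2_GX = %.4f%s\n", x$i2_gx,
              if (x$nome_warning) "  [NOME violation: attenuation bias likely]" else ""))
  invisible(x)
}

# shared parametric-bootstrap machinery: resample each ratio from
# Normal(r_j, se_j) and recompute the point estimator
boot_se <- function(wr, estimator, n_boot, seed) {
  if (is.null(seed)) stop_domain("a seed is required for bootstrap standard errors")
  k <- length(wr$ratio)
  est <- numeric(n_boot)
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    r_star <- stats::rnorm(k, wr$ratio, wr$se)
    est[b] <- estimator(r_star)
  }
  stats::sd(est)
}

#' Weighted and simple median causal estimates
#'
#' The weighted median is the inverse-variance-weighted median of the Wald
#' ratios: ratios are sorted, weights normalized, and the ratio at centred
#' cumulative weight 0.5 is linearly interpolated. It is consistent when at
#' least half the total weight comes from valid instruments. The simple
#' median uses equal weights. Standard errors come from a seeded parametric
#' bootstrap (each ratio resampled from `Normal(r_j, se_j)`).
#'
#' @param hset A `harmonized_set` with at least 3 pairs.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed (required).
#' @param weights `"ivw"` (weighted median) or `"equal"` (simple median).
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(hset, n_boot = 1000, seed = NULL,
                               weights = c("ivw", "equal")) {
  weights <- match.arg(weights)
  k <- nrow(hset)
  if (k < 3) stop_domain("median estimators require at least 3 instruments")
  wr <- wald_ratios(hset)
  w <- if (weights == "ivw") wr$w else rep(1, k)
  beta <- weighted_median_interp(wr$ratio, w)
  se <- boot_se(wr, function(r) weighted_median_interp(r, w), n_boot, seed)
  method <- if (weights == "ivw") "weighted_median" else "simple_median"
  new_mr_estimate(method, beta, se, two_sided_normal_p(beta / se), k)
}

#' @rdname mr_weighted_median
#' @export
mr_simple_median <- function(hset, n_boot = 1000, seed = NULL) {
  mr_weighted_median(hset, n_boot = n_boot, seed = seed, weights = "equal")
}

# weighted Gaussian KDE maximizer over ratios; bandwidth = phi * modified
# Silverman rule (0.9 * min(sd, mad) * k^(-1/5))
kde_mode <- function(r, w, phi) {
  k <- length(r)
  s <- 0.9 * min(stats::sd(r), stats::mad(r)) * k^(-1 / 5)
  if (!is.finite(s) || s <= 0) return(r[which.max(w)])
  h <- phi * s
  wn <- w / sum(w)
  f <- function(x) vapply(x, function(xi)
    sum(wn * stats::dnorm((xi - r) / h)), numeric(1))
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 512L)
  fg <- f(grid)
  i <- which.max(fg)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-10)$maximum
}

#' Weighted mode causal estimate
#'
#' The mode-based estimate: the maximizer of an inverse-variance-weighted
#' Gaussian kernel density over the Wald ratios. It is consistent when the
#' largest homogeneous cluster of instruments is valid, even if they carry
#' less than half the weight. The bandwidth is `bandwidth_phi` times a
#' modified Silverman rule over the ratios; standard errors come from a
#' seeded parametric bootstrap.
#'
#' @param hset A `harmonized_set` with at least 3 pairs.
#' @param bandwidth_phi Bandwidth multiplier (default 1).
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed (required).
#' @return An `mr_estimate` (method `"weighted_mode"`).
#' @export
mr_weighted_mode <- function(hset, bandwidth_phi = 1, n_boot = 1000,
                             seed = NULL) {
  k <- nrow(hset)
  if (k < 3) stop_domain("the mode estimator requires at least 3 instruments")
  assert_scalar_num(bandwidth_phi, "bandwidth_phi", 0, Inf, TRUE)
  wr <- wald_ratios(hset)
  beta <- kde_mode(wr$ratio, wr$w, bandwidth_phi)
  se <- boot_se(wr, function(r) kde_mode(r, wr$w, bandwidth_phi), n_boot, seed)
  new_mr_estimate("weighted_mode", beta, se, two_sided_normal_p(beta / se), k)
}

#' Odds-ratio transform of a log-scale estimate
#'
#' `OR = exp(beta)` with 95% bounds `exp(beta +/- 1.959964 se)`, the
#' reporting convention for binary outcomes.
#'
#' @param beta,se Estimate on the log-odds scale and its standard error.
#' @return List with `or_value`, `or_lci`, `or_uci`.
#' @export
#' @examples
#' to_odds_ratio(log(0.0714), 0.7766)
to_odds_ratio <- function(beta, se) {
  if (se <= 0) stop_domain("se must be positive")
  list(or_value = exp(beta), or_lci = exp(beta - Z975 * se),
       or_uci = exp(beta + Z975 * se))
}

#' Two-sided Wald p-value implied by an odds ratio and its 95% CI
#'
#' Inverts the reporting convention: the log-scale standard error is
#' recovered from the CI width, `se = (ln UCI - ln LCI) / (2 * 1.959964)`,
#' and the two-sided normal p-value of `z = ln(OR)/se` is returned. Used to
#' check published tables for internal consistency.
#'
#' @param or_value,or_lci,or_uci Odds ratio and its 95% bounds
#'   (`0 < lci <= or <= uci`, strictly ordered unless all equal 1).
#' @return The implied two-sided p-value.
#' @export
#' @examples
#' wald_p_from_or_ci(0.0714, 0.0156, 0.3277)
wald_p_from_or_ci <- function(or_value, or_lci, or_uci) {
  if (!(or_lci > 0 && or_lci <= or_value && or_value <= or_uci) ||
      or_lci == or_uci)
    stop_domain("require 0 < or_lci <= or_value <= or_uci with lci < uci")
  se <- (log(or_uci) - log(or_lci)) / (2 * Z975)
  two_sided_normal_p(log(or_value) / se)
}
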