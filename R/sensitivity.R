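#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum_j w_j (r_j - beta_IVW_fixed)^2` over the Wald ratios with
#' inverse-variance weights, compared to the upper tail of the chi-square
#' distribution on `k - 1` degrees of freedom. `p < 0.05` conventionally
#' signals heterogeneity among the per-variant causal estimates.
#'
#' @param hset A `harmonized_set` with at least 2 pairs.
#' @return List with `q_stat`, `q_df`, `q_pvalue`.
#' @export
cochran_q <- function(hset) {
  k <- nrow(hset)
  if (k < 2) stop_domain("Cochran's Q requires at least 2 instruments")
  wr <- wald_ratios(hset)
  beta_fixed <- sum(wr$w * wr$ratio) / sum(wr$w)
  q <- sum(wr$w * (wr$ratio - beta_fixed)^2)
  list(q_stat = q, q_df = k - 1L,
       q_pvalue = stats::pchisq(q, df = k - 1, lower.tail = FALSE))
}

#' MR-PRESSO global pleiotropy test with outlier correction
#'
#' Simulation-based residual-sum-of-squares test for horizontal pleiotropy,
#' applicable when at least half the instruments are valid. The observed
#' statistic is `RSS = sum_j w_j (beta_Yj - b_(-j) beta_Xj)^2` where
#' `b_(-j)` is the leave-one-out IVW slope and `w_j = 1/se_Yj^2` puts each
#' residual on its sampling scale. The null distribution is built from
#' `n_sim` seeded parametric simulations drawing
#' `beta_Yj* ~ Normal(b_(-j) beta_Xj, se_Yj)` and recomputing RSS the same
#' way (leave-one-out slopes recomputed on the simulated data); the global
#' p-value is the continuity-corrected exceedance fraction
#' `(1 + #\{RSS* >= RSS\}) / (n_sim + 1)`, so it is never exactly zero.
#' Per-variant observed squared residuals are compared to their simulated
#' distributions, Bonferroni-corrected by the instrument count, and variants
#' below `outlier_alpha` are flagged; the corrected estimate is the IVW
#' recomputed without them.
#'
#' @param hset A `harmonized_set` with at least 4 pairs.
#' @param n_sim Number of simulated null datasets.
#' @param seed Integer seed (required; the test is simulation-based).
#' @param outlier_alpha Significance level applied to the Bonferroni-
#'   corrected per-variant p-values.
#' @param ivw_mode Mode for the outlier-corrected IVW.
#' @return An object of class `mr_presso`: `global_p`, `outliers`
#'   (variant IDs), `corrected` (an `mr_estimate`, or the uncorrected IVW
#'   when nothing is flagged), `per_snp` (data.frame of per-variant
#'   residuals and p-values), `n_sim`, `seed`.
#' @export
mr_presso <- function(hset, n_sim = 1000, seed = NULL, outlier_alpha = 0.05,
                      ivw_mode = c("random_multiplicative", "fixed")) {
  ivw_mode <- match.arg(ivw_mode)
  k <- nrow(hset)
  if (k < 4) stop_domain("MR-PRESSO requires at least 4 instruments")
  if (is.null(seed)) stop_domain("a seed is required for MR-PRESSO")
  assert_scalar_num(n_sim, "n_sim", 1, Inf)
  bx <- hset$beta_exposure; by <- hset$beta_outcome; sy <- hset$se_outcome
  w <- 1 / sy^2
  bxw <- bx * w
  s1 <- sum(by * bxw); s2 <- sum(bx * bxw)
  denom <- s2 - bx * bxw
  slope_loo <- (s1 - by * bxw) / denom
  resid_obs <- (by - slope_loo * bx)^2 * w
  rss_obs <- sum(resid_obs)

  set.seed(seed)
  mu <- slope_loo * bx
  by_star <- matrix(stats::rnorm(n_sim * k, mean = rep(mu, each = n_sim),
                                 sd = rep(sy, each = n_sim)),
                    nrow = n_sim, ncol = k)
  s1_star <- drop(by_star %*% bxw)
  slope_star <- (matrix(s1_star, n_sim, k) -
                   by_star * matrix(bxw, n_sim, k, byrow = TRUE)) /
    matrix(denom, n_sim, k, byrow = TRUE)
  resid_star <- (by_star - slope_star * matrix(bx, n_sim, k, byrow = TRUE))^2 *
    matrix(w, n_sim, k, byrow = TRUE)
  rss_star <- rowSums(resid_star)

  global_p <- (1 + sum(rss_star >= rss_obs)) / (n_sim + 1)
  p_raw <- (1 + colSums(resid_star >= matrix(resid_obs, n_sim, k, byrow = TRUE))) /
    (n_sim + 1)
  p_bonf <- pmin(1, p_raw * k)
  outlier <- p_bonf < outlier_alpha
  per_snp <- data.frame(variant_id = hset$variant_id, residual = resid_obs,
                        p_raw = p_raw, p_bonferroni = p_bonf,
                        outlier = outlier, stringsAsFactors = FALSE)
  outliers <- hset$variant_id[outlier]
  if (length(outliers) > k / 2)
    warning("more than 50% of instruments flagged as outliers; the MR-PRESSO validity assumption (>=50% valid instruments) is violated",
            call. = FALSE)
  corrected <- if (length(outliers) > 0 && (k - length(outliers)) >= 2) {
    mr_ivw(exclude_pairs(hset, outliers, "presso_outlier"), mode = ivw_mode)
  } else {
    mr_ivw(hset, mode = ivw_mode)
  }
  structure(list(global_p = global_p, outliers = outliers,
                 corrected = corrected, per_snp = per_snp,
                 rss_obs = rss_obs, n_sim = as.integer(n_sim), seed = seed),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO global p = %.4g (%d simulations)\n", x$global_p,
              x$n_sim))
  if (length(x$outliers) > 0) {
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
    cat("  corrected "); print(x$corrected)
  } else cat("  no outliers flagged\n")
  invisible(x)
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate with each instrument removed in turn, to
#' expose single variants driving the pooled estimate.
#'
#' @param hset A `harmonized_set` with at least 2 pairs.
#' @param ivw_mode IVW mode, matching the main analysis.
#' @return data.frame with one row per left-out variant: `variant_id`,
#'   `beta`, `se`, `pvalue`.
#' @export
leave_one_out <- function(hset, ivw_mode = c("random_multiplicative", "fixed")) {
  ivw_mode <- match.arg(ivw_mode)
  k <- nrow(hset)
  if (k < 2) stop_domain("leave-one-out requires at least 2 instruments")
  rows <- lapply(seq_len(k), function(j) {
    sub <- as_harmonized_set(as.data.frame(hset)[-j, , drop = FALSE],
                             attr(hset, "exposure_name"),
                             attr(hset, "outcome_name"))
    est <- suppressMessages(mr_ivw(sub, mode = ivw_mode))
    data.frame(variant_id = hset$variant_id[j], beta = est$beta, se = est$se,
               pvalue = est$pvalue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full sensitivity report for one exposure-outcome pair
#'
#' Bundles every diagnostic: Cochran's Q, the Egger intercept test and
#' `I2_GX`, MR-PRESSO (when at least 4 instruments are available), and the
#' leave-one-out table.
#'
#' @param hset A `harmonized_set`.
#' @param n_sim,seed,outlier_alpha Passed to [mr_presso()].
#' @param ivw_mode IVW mode used throughout.
#' @return An object of class `sensitivity_report`.
#' @export
sensitivity_report <- function(hset, n_sim = 1000, seed = NULL,
                               outlier_alpha = 0.05,
                               ivw_mode = c("random_multiplicative", "fixed")) {
  ivw_mode <- match.arg(ivw_mode)
  k <- nrow(hset)
  q <- if (k >= 2) cochran_q(hset) else NULL
  egger <- if (k >= 3) mr_egger(hset) else NULL
  presso <- if (k >= 4) mr_presso(hset, n_sim = n_sim, seed = seed,
                                  outlier_alpha = outlier_alpha,
                                  ivw_mode = ivw_mode) else NULL
  loo <- if (k >= 2) leave_one_out(hset, ivw_mode = ivw_mode) else NULL
  structure(list(q_stat = q$q_stat, q_df = q$q_df, q_pvalue = q$q_pvalue,
                 egger_intercept = egger$intercept, i2_gx = egger$i2_gx,
                 presso_global_p = presso$global_p,
                 presso_outliers = presso$outliers %||% character(),
                 presso_corrected = presso$corrected,
                 loo_table = loo, n_snps = k),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Sensitivity report (%d instruments)\n", x$n_snps))
  if (!is.null(x$q_stat))
    cat(sprintf("  Cochran's Q = %.4g on %d df, p = %.3g\n", x$q_stat,
                x$q_df, x$q_pvalue))
  if (!is.null(x$egger_intercept))
    cat(sprintf("  Egger intercept = %.4g (p = %.3g), I2_GX = %.3f\n",
                x$egger_intercept$beta, x$egger_intercept$pvalue, x$i2_gx))
  if (!is.null(x$presso_global_p))
    cat(sprintf("  MR-PRESSO global p = %.4g, %d outlier(s)\n",
                x$presso_global_p, length(x$presso_outliers)))
  invisible(x)
}

#' Write a sensitivity report as JSON (and the leave-one-out table as TSV)
#'
#' @param report A `sensitivity_report`.
#' @param json_path Output JSON path.
#' @param loo_tsv_path Optional TSV path for the leave-one-out table.
#' @return Invisibly, `report`.
#' @export
write_sensitivity_report <- function(report, json_path, loo_tsv_path = NULL) {
  payload <- list(
    n_snps = report$n_snps,
    q_stat = report$q_stat, q_df = report$q_df, q_pvalue = report$q_pvalue,
    egger_intercept = if (!is.null(report$egger_intercept))
      list(beta = report$egger_intercept$beta, se = report$egger_intercept$se,
           pvalue = report$egger_intercept$pvalue),
    i2_gx = report$i2_gx,
    presso_global_p = report$presso_global_p,
    presso_outliers = report$presso_outliers,
    presso_corrected = if (!is.null(report$presso_corrected))
      list(beta = report$presso_corrected$beta,
           se = report$presso_corrected$se,
           pvalue = report$presso_corrected$pvalue,
           n_snps = report$presso_corrected$n_snps),
    loo_table = report$loo_table
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!is.null(loo_tsv_path) && !is.null(report$loo_table))
    utils::write.table(report$loo_table, loo_tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(report)
}
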