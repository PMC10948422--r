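#' Colocalization priors
#'
#' Per-variant prior probabilities for the enumeration of single-causal-
#' variant hypotheses: `p1` that a variant is associated with trait 1 only,
#' `p2` with trait 2 only, `p12` with both. Defaults 1e-4, 1e-4, 1e-5.
#'
#' @param p1,p2,p12 Prior probabilities.
#' @return A list of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  assert_scalar_num(p1, "p1", 0, 1, TRUE, TRUE)
  assert_scalar_num(p2, "p2", 0, 1, TRUE, TRUE)
  assert_scalar_num(p12, "p12", 0, 1, TRUE, TRUE)
  if (p12 > p1 || p12 > p2)
    stop_domain("p12 must not exceed p1 or p2")
  if (p1 + p2 + p12 >= 1)
    stop_domain("p1 + p2 + p12 must be below 1")
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

#' Extract the variants of a region around a lead variant
#'
#' All records on the lead's chromosome within `window_bp` of its position,
#' bounds inclusive.
#'
#' @param records Summary-statistic data.frame with `variant_id`, `chrom`,
#'   `pos`.
#' @param lead Lead variant ID (must be present).
#' @param window_bp Region half-width in base pairs (default 500 kb).
#' @return The subset of `records` in the region.
#' @export
extract_region <- function(records, lead, window_bp = 500000) {
  i <- match(lead, records$variant_id)
  if (is.na(i)) stop_domain("lead variant ", lead, " not found in records")
  keep <- records$chrom == records$chrom[i] &
    abs(records$pos - records$pos[i]) <= window_bp
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Wakefield approximate log Bayes factor
#'
#' Closed-form log Bayes factor for a variant's association given its
#' estimate and standard error, under a normal effect prior with standard
#' deviation `prior_sd`: with `z = beta/se`, `V = se^2`, `W = prior_sd^2`,
#' `log ABF = 0.5 log(V/(V+W)) + 0.5 z^2 W/(V+W)`.
#'
#' @param beta,se Association estimate and standard error (`se > 0`).
#' @param prior_sd Prior effect-size standard deviation (0.15 is the
#'   conventional default for quantitative traits, 0.2 on the log-OR scale
#'   for case-control traits).
#' @return Log Bayes factor(s).
#' @export
#' @examples
#' wakefield_log_abf(0.1, 0.02, 0.15)
wakefield_log_abf <- function(beta, se, prior_sd = 0.15) {
  if (any(se <= 0)) stop_domain("se must be positive")
  if (any(prior_sd <= 0)) stop_domain("prior_sd must be positive")
  z <- beta / se
  v <- se^2
  w <- prior_sd^2
  r <- w / (v + w)
  0.5 * log1p(-r) + 0.5 * z^2 * r
}

#' Bayesian colocalization of two traits in one region
#'
#' Enumerates the five single-causal-variant hypotheses over the variants
#' shared by the two regions — H0 no association, H1/H2 association with one
#' trait only, H3 two distinct causal variants, H4 one shared causal
#' variant — weighting per-variant Wakefield approximate Bayes factors by
#' the priors and normalizing. All sums are computed in log space
#' (log-sum-exp), so large regions with strong signals are handled without
#' overflow. Regions are matched by variant ID; the caller is responsible
#' for coherent effect-allele orientation across the two traits (see
#' [harmonize()]), although the posteriors depend on the betas only through
#' `z^2` and are therefore orientation-invariant.
#'
#' @param region1,region2 data.frames with `variant_id`, `beta`, `se`
#'   (columns named `beta`/`se`, or a single-trait slice of a summary-stat
#'   table).
#' @param priors A [coloc_priors()].
#' @param prior_sd1,prior_sd2 Effect-size prior standard deviations for the
#'   two traits.
#' @param window_bp Recorded region half-width (metadata only).
#' @return An object of class `coloc_result`: posteriors `pph0`..`pph4`,
#'   `n_snps`, `priors`, `classification` (`"strong"`, `"moderate"`, or
#'   `"none"`), `lead_variant` (the variant with the largest joint ABF), and
#'   `window_bp`.
#' @export
coloc_abf <- function(region1, region2, priors = coloc_priors(),
                      prior_sd1 = 0.15, prior_sd2 = 0.2,
                      window_bp = 500000) {
  shared <- intersect(region1$variant_id, region2$variant_id)
  if (length(shared) == 0)
    stop_domain("regions share no variant IDs")
  i1 <- match(shared, region1$variant_id)
  i2 <- match(shared, region2$variant_id)
  labf1 <- wakefield_log_abf(region1$beta[i1], region1$se[i1], prior_sd1)
  labf2 <- wakefield_log_abf(region2$beta[i2], region2$se[i2], prior_sd2)
  bad <- !is.finite(labf1) | !is.finite(labf2)
  if (any(bad))
    stop_domain("non-finite Bayes factor for variant(s): ",
                paste(shared[bad], collapse = ", "))
  l1 <- logsumexp(labf1)              # sum_i ABF1_i
  l2 <- logsumexp(labf2)              # sum_j ABF2_j
  l12 <- logsumexp(labf1 + labf2)     # sum_i ABF1_i ABF2_i
  lsum <- l1 + l2                     # sum_{i,j} ABF1_i ABF2_j
  lh <- c(h0 = 0,
          h1 = log(priors$p1) + l1,
          h2 = log(priors$p2) + l2,
          h3 = log(priors$p1) + log(priors$p2) + logdiffexp(lsum, l12),
          h4 = log(priors$p12) + l12)
  pp <- exp(lh - logsumexp(lh))
  lead <- shared[which.max(labf1 + labf2)]
  structure(list(pph0 = pp[["h0"]], pph1 = pp[["h1"]], pph2 = pp[["h2"]],
                 pph3 = pp[["h3"]], pph4 = pp[["h4"]],
                 n_snps = length(shared), priors = priors,
                 classification = classify_coloc(pp[["h4"]]),
                 lead_variant = lead, window_bp = window_bp),
            class = "coloc_result")
}

#' Qualitative colocalization classification
#'
#' `"strong"` for PPH4 of at least 0.75, `"moderate"` for PPH4 strictly
#' between 0.5 and 0.75, otherwise `"none"`.
#'
#' @param pph4 Posterior probability of a shared causal variant, in `[0,1]`.
#' @return Character scalar.
#' @export
#' @examples
#' classify_coloc(0.7894)
classify_coloc <- function(pph4) {
  assert_scalar_num(pph4, "pph4", 0, 1)
  if (pph4 >= 0.75) "strong" else if (pph4 > 0.5) "moderate" else "none"
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalization over %d shared variant(s) (window +/- %g kb)\n",
              x$n_snps, x$window_bp / 1000))
  cat(sprintf("  PPH0 = %.4f  PPH1 = %.4f  PPH2 = %.4f  PPH3 = %.4f  PPH4 = %.4f\n",
              x$pph0, x$pph1, x$pph2, x$pph3, x$pph4))
  cat(sprintf("  classification: %s (lead %s)\n", x$classification,
              x$lead_variant))
  invisible(x)
}

#' Reconstruct beta and se from p-value, allele frequency, and sample size
#'
#' Fallback constructor for summary files lacking standard errors: the
#' standard error is approximated from the allele-frequency variance,
#' `se = 1/sqrt(2 f (1-f) n)` for a quantitative trait and
#' `se = 1/sqrt(2 f (1-f) n phi (1-phi))` for a case-control trait with case
#' fraction `phi`, and the effect magnitude recovered as `|z| * se` with `z`
#' from the two-sided p-value. The sign of the effect is not recoverable
#' from a p-value; `sign` defaults to +1. Colocalization depends only on
#' `z^2`, so the sign does not affect posteriors.
#'
#' @param pvalue Two-sided p-value(s).
#' @param eaf Effect-allele frequency.
#' @param n Sample size.
#' @param case_fraction Case fraction for case-control traits; `NULL` for
#'   quantitative.
#' @param sign Effect sign(s), +1 or -1.
#' @return data.frame with `beta`, `se`.
#' @export
beta_se_from_p <- function(pvalue, eaf, n, case_fraction = NULL, sign = 1) {
  if (any(pvalue <= 0 | pvalue > 1)) stop_domain("p-values must lie in (0,1]")
  if (any(eaf <= 0 | eaf >= 1)) stop_domain("eaf must lie strictly in (0,1)")
  scale <- 2 * eaf * (1 - eaf) * n
  if (!is.null(case_fraction)) {
    assert_scalar_num(case_fraction, "case_fraction", 0, 1, TRUE, TRUE)
    scale <- scale * case_fraction * (1 - case_fraction)
  }
  se <- 1 / sqrt(scale)
  z <- stats::qnorm(pvalue / 2, lower.tail = FALSE)
  data.frame(beta = sign * z * se, se = se)
}
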