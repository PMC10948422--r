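#' Configuration for the paired GWAS simulator
#'
#' Describes the generating model for a pair of GWAS summary-statistic sets
#' linked by a true causal effect `theta` of the exposure on the outcome.
#' Per variant `j`: the allele frequency is uniform on `maf_range`; the true
#' exposure effect `b_j` follows a spike-and-slab (zero with probability
#' `1 - pi_causal`, otherwise `Normal(0, effect_sd)`); the observed exposure
#' effect is `Normal(b_j, se_Xj)` with `se_Xj = 1/sqrt(2 f(1-f) N_X)`
#' (standardized-trait scaling); a direct (pleiotropic) effect `alpha_j` on
#' the outcome is 0, `Normal(0, pleiotropy_sd)` (balanced), or
#' `Normal(pleiotropy_mean, pleiotropy_sd)` (directional); and the observed
#' outcome effect is `Normal(theta b_j + alpha_j, se_Yj)`, where for a
#' binary outcome `se_Yj = 1/sqrt(2 f(1-f) N_Y phi(1-phi))` on the log-OR
#' scale with case fraction `phi`.
#'
#' @param n_snps Number of variants emitted.
#' @param n_exposure,n_outcome GWAS sample sizes (defaults: 23,909 for the
#'   quantitative exposure, 80,610 for the case-control outcome).
#' @param theta True causal effect of exposure on outcome.
#' @param pleiotropy_mode `"none"`, `"balanced"`, or `"directional"`.
#' @param pleiotropy_sd,pleiotropy_mean Spread and mean of the direct
#'   effects `alpha_j`.
#' @param pi_causal Fraction of variants with a nonzero true exposure
#'   effect.
#' @param effect_sd Slab standard deviation of the true exposure effects.
#' @param maf_range Allele-frequency interval within `(0, 0.5)`.
#' @param ld_block_size,ld_rho LD-block structure: variants per block and
#'   within-block correlation of the observed exposure effects (exercised
#'   only when `dense = TRUE`).
#' @param dense If `FALSE` (default) each emitted variant is its own LD
#'   block (mutually independent instruments); if `TRUE` full blocks are
#'   emitted with correlated noise, to stress the clumping stage.
#' @param binary_outcome Case-control outcome scaling of `se_Y`.
#' @param case_fraction Case fraction of the outcome GWAS.
#' @param seed Integer seed; every draw flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 50,
                       n_exposure = 23909, n_outcome = 80610,
                       theta = 0,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_sd = 0.05, pleiotropy_mean = 0.05,
                       pi_causal = 0.3, effect_sd = 0.1,
                       maf_range = c(0.05, 0.45),
                       ld_block_size = 5, ld_rho = 0.5, dense = FALSE,
                       binary_outcome = TRUE,
                       case_fraction = 20806 / 80610,
                       seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  assert_scalar_num(n_snps, "n_snps", 1, Inf)
  assert_scalar_num(n_exposure, "n_exposure", 2, Inf, TRUE)
  assert_scalar_num(n_outcome, "n_outcome", 2, Inf, TRUE)
  assert_scalar_num(pi_causal, "pi_causal", 0, 1)
  assert_scalar_num(effect_sd, "effect_sd", 0, Inf, TRUE)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] >= 0.5 ||
      maf_range[1] > maf_range[2])
    stop_domain("maf_range must be an interval within (0, 0.5)")
  assert_scalar_num(ld_rho, "ld_rho", -1, 1, TRUE, TRUE)
  assert_scalar_num(case_fraction, "case_fraction", 0, 1, TRUE, TRUE)
  assert_scalar_num(seed, "seed")
  structure(list(n_snps = as.integer(n_snps), n_exposure = n_exposure,
                 n_outcome = n_outcome, theta = theta,
                 pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_sd = pleiotropy_sd,
                 pleiotropy_mean = pleiotropy_mean,
                 pi_causal = pi_causal, effect_sd = effect_sd,
                 maf_range = maf_range, ld_block_size = as.integer(ld_block_size),
                 ld_rho = ld_rho, dense = dense,
                 binary_outcome = binary_outcome,
                 case_fraction = case_fraction, seed = as.integer(seed)),
            class = "sim_config")
}

# non-palindromic ordered allele pairs
ALLELE_PAIRS <- matrix(c("A", "G", "A", "C", "G", "A", "C", "A",
                         "T", "G", "T", "C", "G", "T", "C", "T"),
                       ncol = 2, byrow = TRUE)

#' Simulate a paired exposure/outcome GWAS with known ground truth
#'
#' Draws summary statistics under the model described in [sim_config()] and
#' emits two valid summary-statistic tables plus the truth record. The
#' outcome table's allele orientation is randomly swapped per variant (beta
#' negated, frequency complemented) so that [harmonize()] is exercised on
#' realistic input. With `pleiotropy_mode = "none"` the instruments satisfy
#' the instrumental-variable assumptions exactly; the other modes violate
#' the exclusion restriction in a controlled way.
#'
#' @param config A [sim_config()].
#' @return List with `exposure` and `outcome` (summary-stat data.frames in
#'   the format of [read_sumstats()]) and `truth` (list with `theta`, `b`,
#'   `alpha`, `maf`, `causal`, `seed`).
#' @export
simulate_gwas_pair <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  k <- config$n_snps
  maf <- stats::runif(k, config$maf_range[1], config$maf_range[2])
  causal <- stats::runif(k) < config$pi_causal
  b <- ifelse(causal, stats::rnorm(k, 0, config$effect_sd), 0)
  se_x <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exposure)
  phi_term <- if (config$binary_outcome)
    config$case_fraction * (1 - config$case_fraction) else 1
  se_y <- 1 / sqrt(2 * maf * (1 - maf) * config$n_outcome * phi_term)

  noise_x <- stats::rnorm(k)
  noise_y <- stats::rnorm(k)
  if (config$dense && config$ld_block_size > 1) {
    # within-block exchangeable correlation of the sampling noise
    rho <- config$ld_rho
    block <- rep(seq_len(ceiling(k / config$ld_block_size)),
                 each = config$ld_block_size)[seq_len(k)]
    shared_x <- stats::rnorm(max(block))[block]
    shared_y <- stats::rnorm(max(block))[block]
    noise_x <- sqrt(abs(rho)) * sign(rho) * shared_x + sqrt(1 - abs(rho)) * noise_x
    noise_y <- sqrt(abs(rho)) * sign(rho) * shared_y + sqrt(1 - abs(rho)) * noise_y
  }
  beta_x <- b + se_x * noise_x
  # Directional pleiotropy is oriented with respect to the exposure-
  # increasing allele (the orientation MR-Egger regresses in); on an
  # arbitrary allele coding a fixed-sign direct effect would average out.
  alpha <- switch(config$pleiotropy_mode,
                  none = rep(0, k),
                  balanced = stats::rnorm(k, 0, config$pleiotropy_sd),
                  directional = ifelse(b < 0, -1, 1) *
                    stats::rnorm(k, config$pleiotropy_mean,
                                 config$pleiotropy_sd))
  beta_y <- config$theta * b + alpha + se_y * noise_y

  pair_idx <- sample.int(nrow(ALLELE_PAIRS), k, replace = TRUE)
  ea <- ALLELE_PAIRS[pair_idx, 1]
  oa <- ALLELE_PAIRS[pair_idx, 2]
  ids <- paste0("rs", seq_len(k))
  pos <- 10000L * seq_len(k)

  exposure <- data.frame(
    variant_id = ids, chrom = "1", pos = pos,
    effect_allele = ea, other_allele = oa,
    eaf = maf, beta = beta_x, se = se_x,
    pvalue = two_sided_normal_p(beta_x / se_x), n = config$n_exposure,
    stringsAsFactors = FALSE)

  swap <- stats::runif(k) < 0.5
  outcome <- data.frame(
    variant_id = ids, chrom = "1", pos = pos,
    effect_allele = ifelse(swap, oa, ea),
    other_allele = ifelse(swap, ea, oa),
    eaf = ifelse(swap, 1 - maf, maf),
    beta = ifelse(swap, -beta_y, beta_y), se = se_y,
    pvalue = two_sided_normal_p(beta_y / se_y), n = config$n_outcome,
    stringsAsFactors = FALSE)

  list(exposure = exposure, outcome = outcome,
       truth = list(theta = config$theta, b = b, alpha = alpha, maf = maf,
                    causal = causal, seed = config$seed))
}

#' Simulate a colocalization region with a known causal configuration
#'
#' Generates z-scores for two traits over one region under exchangeable LD
#' with correlation `ld_rho`: the causal variant carries `effect_z`, every
#' other variant inherits `r * effect_z` through LD, and multivariate-normal
#' noise with the same correlation is added. Under `"shared"` both traits
#' have the same causal variant; under `"distinct"` two different variants;
#' under `"null"` neither trait has a signal. Betas and standard errors are
#' reconstructed from the z-scores with allele-frequency scaling.
#'
#' @param scenario `"shared"`, `"distinct"`, or `"null"`.
#' @param n_variants Number of region variants (at least 3).
#' @param ld_rho Pairwise LD correlation within the region.
#' @param n1,n2 Sample sizes of the two traits.
#' @param effect_z Causal-variant z-score magnitude.
#' @param seed Integer seed.
#' @param maf Common allele frequency used for the se reconstruction.
#' @return List with `region1`, `region2` (data.frames of `variant_id`,
#'   `chrom`, `pos`, `beta`, `se`) and `truth` (causal indices).
#' @export
simulate_coloc_region <- function(scenario = c("shared", "distinct", "null"),
                                  n_variants = 50, ld_rho = 0.3,
                                  n1 = 23909, n2 = 80610, effect_z = 8,
                                  seed = 1L, maf = 0.25) {
  scenario <- match.arg(scenario)
  if (n_variants < 3) stop_domain("a region needs at least 3 variants")
  assert_scalar_num(ld_rho, "ld_rho", 0, 1, FALSE, TRUE)
  set.seed(seed)
  m <- n_variants
  # exchangeable correlation: R = (1-rho) I + rho J; draw via shared factor
  draw_mvn <- function() {
    shared <- stats::rnorm(1)
    sqrt(ld_rho) * shared + sqrt(1 - ld_rho) * stats::rnorm(m)
  }
  r_to <- function(causal) {
    r <- rep(ld_rho, m); r[causal] <- 1; r
  }
  c1 <- c2 <- NA_integer_
  mu1 <- mu2 <- rep(0, m)
  if (scenario == "shared") {
    c1 <- c2 <- sample.int(m, 1)
    mu1 <- r_to(c1) * effect_z
    mu2 <- r_to(c2) * effect_z
  } else if (scenario == "distinct") {
    picks <- sample.int(m, 2)
    c1 <- picks[1]; c2 <- picks[2]
    mu1 <- r_to(c1) * effect_z
    mu2 <- r_to(c2) * effect_z
  }
  z1 <- mu1 + draw_mvn()
  z2 <- mu2 + draw_mvn()
  se1 <- rep(1 / sqrt(2 * maf * (1 - maf) * n1), m)
  se2 <- rep(1 / sqrt(2 * maf * (1 - maf) * n2), m)
  ids <- paste0("rs", seq_len(m))
  pos <- 10000L * seq_len(m)
  list(region1 = data.frame(variant_id = ids, chrom = "1", pos = pos,
                            beta = z1 * se1, se = se1, stringsAsFactors = FALSE),
       region2 = data.frame(variant_id = ids, chrom = "1", pos = pos,
                            beta = z2 * se2, se = se2, stringsAsFactors = FALSE),
       truth = list(scenario = scenario, causal1 = c1, causal2 = c2,
                    seed = seed))
}

#' Block-diagonal LD reference fixture
#'
#' Builds an [ld_reference()] with within-block off-diagonal r-squared
#' `rho^2`, zero across blocks, unit diagonal, and variants placed 10 kb
#' apart on one chromosome. Construction is deterministic.
#'
#' @param n_snps Total variants.
#' @param block_size Variants per block (last block may be smaller).
#' @param rho Within-block correlation (so r-squared is `rho^2`).
#' @return An `ld_reference` whose variant IDs are `rs1 ... rsN`.
#' @export
#' @examples
#' make_ld_fixture(6, 3, 0.9)
make_ld_fixture <- function(n_snps, block_size, rho) {
  if (block_size > n_snps) stop_domain("block_size must not exceed n_snps")
  assert_scalar_num(rho, "rho", -1, 1)
  block <- rep(seq_len(ceiling(n_snps / block_size)),
               each = block_size)[seq_len(n_snps)]
  r2 <- outer(block, block, function(a, b) ifelse(a == b, rho^2, 0))
  diag(r2) <- 1
  ids <- paste0("rs", seq_len(n_snps))
  dimnames(r2) <- list(ids, ids)
  positions <- data.frame(variant_id = ids, chrom = "1",
                          pos = 10000L * seq_len(n_snps),
                          stringsAsFactors = FALSE)
  ld_reference(r2, positions)
}
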