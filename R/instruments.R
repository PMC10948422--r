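#' Instrument-selection configuration
#'
#' Bundles the thresholds used when selecting genetic instruments from an
#' exposure GWAS. Two named presets are provided matching the two analysis
#' directions: `"forward"` (brain-structure exposures: p < 5e-6, clumping
#' r-squared 0.001 within 10 Mb) and `"reverse"` (disease exposure:
#' p < 5e-8, r-squared 0.001 within 250 kb). Both presets share the
#' minor-allele-frequency floor 0.01, the instrument-strength floor F >= 10,
#' and removal of instruments associated with the outcome at p < 0.05.
#'
#' @param preset `"forward"` or `"reverse"`, or `NULL` to take the defaults
#'   of the individual arguments.
#' @param p_threshold Genome-wide significance cutoff for candidates.
#' @param r2_threshold LD r-squared above which two candidates within the
#'   window are dependent.
#' @param window_bp Clumping window: distance from the index variant within
#'   which r-squared is checked (inclusive).
#' @param maf_min Minor-allele-frequency floor.
#' @param f_min Single-SNP F-statistic floor.
#' @param outcome_p_exclude Instruments with outcome p below this are
#'   excluded as outcome-associated.
#' @param r2_formula Per-SNP variance-explained formula: `"z"` for
#'   z-score based `z^2/(z^2 + n - 2)` or `"maf_beta"` for
#'   `2 MAF (1-MAF) beta^2`.
#' @return A list of class `selection_config`.
#' @export
#' @examples
#' selection_config("forward")
selection_config <- function(preset = NULL,
                             p_threshold = 5e-6,
                             r2_threshold = 0.001,
                             window_bp = 1e7,
                             maf_min = 0.01,
                             f_min = 10,
                             outcome_p_exclude = 0.05,
                             r2_formula = c("z", "maf_beta")) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("forward", "reverse"))
    if (preset == "forward") {
      if (missing(p_threshold)) p_threshold <- 5e-6
      if (missing(window_bp)) window_bp <- 1e7
    } else {
      if (missing(p_threshold)) p_threshold <- 5e-8
      if (missing(window_bp)) window_bp <- 250000
    }
  }
  assert_scalar_num(p_threshold, "p_threshold", 0, 1, TRUE, TRUE)
  assert_scalar_num(r2_threshold, "r2_threshold", 0, 1)
  assert_scalar_num(window_bp, "window_bp", 0, Inf, TRUE)
  assert_scalar_num(maf_min, "maf_min", 0, 0.5, FALSE, TRUE)
  assert_scalar_num(f_min, "f_min", 0, Inf)
  assert_scalar_num(outcome_p_exclude, "outcome_p_exclude", 0, 1)
  structure(list(p_threshold = p_threshold, r2_threshold = r2_threshold,
                 window_bp = window_bp, maf_min = maf_min, f_min = f_min,
                 outcome_p_exclude = outcome_p_exclude,
                 r2_formula = match.arg(r2_formula)),
            class = "selection_config")
}

#' Construct an LD reference from an r-squared matrix
#'
#' @param r2 Square symmetric matrix of pairwise LD r-squared values with
#'   unit diagonal; dimnames give variant IDs.
#' @param positions data.frame with columns `variant_id`, `chrom`, `pos`
#'   covering all matrix variants.
#' @return A list of class `ld_reference` with elements `variant_ids`,
#'   `r2`, `positions`.
#' @export
ld_reference <- function(r2, positions) {
  if (!is.matrix(r2) || nrow(r2) != ncol(r2))
    stop_domain("r2 must be a square matrix")
  ids <- rownames(r2) %||% colnames(r2)
  if (is.null(ids)) stop_domain("r2 must carry variant IDs as dimnames")
  if (max(abs(r2 - t(r2))) > 1e-8) stop_domain("r2 must be symmetric")
  if (max(abs(diag(r2) - 1)) > 1e-8) stop_domain("r2 must have unit diagonal")
  if (any(r2 < -1e-12 | r2 > 1 + 1e-12)) stop_domain("r2 values must lie in [0,1]")
  miss <- setdiff(ids, positions$variant_id)
  if (length(miss) > 0)
    stop_domain("positions missing for: ", paste(utils::head(miss, 5), collapse = ", "))
  pos <- positions[match(ids, positions$variant_id), , drop = FALSE]
  rownames(pos) <- NULL
  structure(list(variant_ids = ids, r2 = r2, positions = pos),
            class = "ld_reference")
}

#' Read an LD reference from TSV files
#'
#' The matrix file is a square r-squared matrix with a variant-ID header row
#' and first column; the positions file has columns `variant_id`, `chrom`,
#' `pos`.
#'
#' @param r2_path,positions_path File paths.
#' @return An `ld_reference`.
#' @export
read_ld_reference <- function(r2_path, positions_path) {
  m <- utils::read.table(r2_path, header = TRUE, sep = "\t", row.names = 1,
                         check.names = FALSE)
  m <- as.matrix(m)
  pos <- utils::read.table(positions_path, header = TRUE, sep = "\t",
                           colClasses = c("character", "character", "integer"),
                           col.names = c("variant_id", "chrom", "pos"))
  ld_reference(m, pos)
}

#' Compute an LD reference from a dosage matrix
#'
#' r-squared is the squared Pearson correlation of dosages across samples.
#'
#' @param dosage Numeric matrix, variants in rows (rownames are variant IDs),
#'   samples in columns.
#' @param positions data.frame of `variant_id`, `chrom`, `pos`.
#' @return An `ld_reference`.
#' @export
ld_from_dosage <- function(dosage, positions) {
  r <- stats::cor(t(dosage))
  r2 <- r * r
  diag(r2) <- 1
  ld_reference(r2, positions)
}

#' Greedy LD clumping of candidate instruments
#'
#' Selects an approximately independent set of variants: candidates are
#' ranked by ascending p-value (ties broken by variant ID), the best
#' remaining candidate is kept, and every remaining candidate on the same
#' chromosome within `window_bp` of it with r-squared above `r2_threshold`
#' is discarded; this repeats until no candidates remain.
#'
#' @param candidates Summary-statistic data.frame (rows below the selection
#'   p-threshold).
#' @param ld An [ld_reference()] covering the candidates.
#' @param config A [selection_config()].
#' @param missing_ld Policy for candidates absent from the LD reference:
#'   `"drop"` (default, with a warning) or `"error"`.
#' @return The retained subset of `candidates`, sorted by `(chrom, pos)`.
#' @export
ld_clump <- function(candidates, ld, config = selection_config(),
                     missing_ld = c("drop", "error")) {
  missing_ld <- match.arg(missing_ld)
  if (nrow(candidates) == 0) return(candidates)
  absent <- setdiff(candidates$variant_id, ld$variant_ids)
  if (length(absent) > 0) {
    if (missing_ld == "error")
      stop_domain("candidates absent from LD reference: ",
                  paste(utils::head(absent, 5), collapse = ", "))
    warning(sprintf("%d candidate(s) absent from LD reference dropped", length(absent)),
            call. = FALSE)
    candidates <- candidates[!(candidates$variant_id %in% absent), , drop = FALSE]
  }
  if (nrow(candidates) <= 1) return(candidates)
  ord <- order(candidates$pvalue, candidates$variant_id)
  cand <- candidates[ord, , drop = FALSE]
  alive <- rep(TRUE, nrow(cand))
  kept <- logical(nrow(cand))
  li <- match(cand$variant_id, ld$variant_ids)
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    kept[i] <- TRUE
    alive[i] <- FALSE
    rest <- which(alive)
    if (length(rest) == 0) break
    same_chr <- cand$chrom[rest] == cand$chrom[i]
    in_window <- abs(cand$pos[rest] - cand$pos[i]) <= config$window_bp
    r2v <- ld$r2[li[i], li[rest]]
    conflict <- same_chr & in_window & (r2v > config$r2_threshold)
    alive[rest[conflict]] <- FALSE
  }
  out <- cand[kept, , drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-SNP variance explained on the exposure
#'
#' Approximates the fraction of exposure variance explained by one variant
#' from summary data: `z^2 / (z^2 + n - 2)` with `z = beta/se` (default), or
#' `2 MAF (1 - MAF) beta^2` for standardized traits when selected in the
#' configuration. Summing over the instrument set gives the total R-squared
#' consumed by [compute_f_statistic()].
#'
#' @param beta,se,n Per-variant effect, standard error, sample size.
#' @param eaf Effect-allele frequency (needed by the `"maf_beta"` formula).
#' @param formula `"z"` or `"maf_beta"`.
#' @return Variance-explained fraction(s) in `[0, 1)`.
#' @export
snp_variance_explained <- function(beta, se, n, eaf = NULL,
                                   formula = c("z", "maf_beta")) {
  formula <- match.arg(formula)
  if (formula == "z") {
    if (any(se <= 0) || any(n <= 2))
      stop_domain("snp_variance_explained requires se > 0 and n > 2")
    z <- beta / se
    z^2 / (z^2 + n - 2)
  } else {
    if (is.null(eaf) || any(eaf <= 0) || any(eaf >= 1))
      stop_domain("maf_beta formula requires eaf strictly inside (0,1)")
    maf <- pmin(eaf, 1 - eaf)
    2 * maf * (1 - maf) * beta^2
  }
}

#' Instrument-strength F-statistic
#'
#' `F = R^2 (N - 1 - k) / ((1 - R^2) k)` where `R^2` is the total variance
#' of the exposure explained by the `k` instruments and `N` the exposure
#' GWAS sample size. Values below 10 conventionally indicate weak
#' instruments.
#'
#' @param r2_total Total variance explained, in `[0, 1)`.
#' @param n Exposure GWAS sample size.
#' @param k Number of instruments.
#' @return A list of class `f_statistic` with `r2_total`, `n`, `k`, `f`.
#' @export
#' @examples
#' compute_f_statistic(0.05, 1000, 10)
compute_f_statistic <- function(r2_total, n, k) {
  assert_scalar_num(r2_total, "r2_total", 0, 1, FALSE, TRUE)
  assert_scalar_num(k, "k", 1, Inf)
  if (n <= k + 1) stop_domain("F-statistic requires n > k + 1")
  f <- r2_total * (n - 1 - k) / ((1 - r2_total) * k)
  structure(list(r2_total = r2_total, n = n, k = k, f = f),
            class = "f_statistic")
}

#' @export
print.f_statistic <- function(x, ...) {
  cat(sprintf("F = %.4g (R2 = %.4g, N = %g, k = %d)%s\n", x$f, x$r2_total,
              x$n, as.integer(x$k), if (x$f < 10) "  [weak: F < 10]" else ""))
  invisible(x)
}

#' Read a confounder blocklist
#'
#' Plain-text file with one variant ID per line; `#` starts a comment and
#' anything after the first whitespace on a line is treated as annotation.
#'
#' @param path File path.
#' @return Character vector of variant IDs.
#' @export
read_blocklist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "[[:space:]]+"), `[[`, character(1), 1L)
}

#' Post-harmonization instrument exclusions
#'
#' Moves harmonized pairs to the exclusions table when (i) the instrument is
#' associated with the outcome (outcome p below `config$outcome_p_exclude`,
#' reason `outcome_associated`), (ii) the variant appears on the confounder
#' blocklist (reason `confounder`), or (iii) its single-SNP F-statistic falls
#' below `config$f_min` (reason `weak_instrument`).
#'
#' @param hset A `harmonized_set`.
#' @param confounder_blocklist Character vector of variant IDs.
#' @param config A [selection_config()].
#' @return The filtered `harmonized_set`.
#' @export
apply_exclusions <- function(hset, confounder_blocklist = character(),
                             config = selection_config()) {
  if (nrow(hset) == 0) stop_domain("harmonized set is empty")
  d <- as.data.frame(hset)
  out_assoc <- !is.na(d$pvalue_outcome) &
    d$pvalue_outcome < config$outcome_p_exclude
  hset <- exclude_pairs(hset, d$variant_id[out_assoc], "outcome_associated")

  d <- as.data.frame(hset)
  conf <- d$variant_id %in% confounder_blocklist
  hset <- exclude_pairs(hset, d$variant_id[conf], "confounder")

  d <- as.data.frame(hset)
  if (nrow(d) > 0 && all(is.finite(d$n_exposure))) {
    r2 <- snp_variance_explained(d$beta_exposure, d$se_exposure, d$n_exposure,
                                 eaf = d$eaf_exposure,
                                 formula = config$r2_formula)
    fstat <- vapply(seq_along(r2), function(i)
      compute_f_statistic(r2[i], d$n_exposure[i], 1)$f, numeric(1))
    weak <- fstat < config$f_min
    hset <- exclude_pairs(hset, d$variant_id[weak], "weak_instrument")
  }
  if (nrow(hset) == 0)
    stop_domain(sprintf("all instruments excluded for %s -> %s",
                        attr(hset, "exposure_name"), attr(hset, "outcome_name")))
  hset
}
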