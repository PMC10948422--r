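#' Benjamini-Hochberg step-up adjustment with an explicit family size
#'
#' Step-up adjusted values `a_(i) = m p_(i) / i` over the ascending-sorted
#' p-values, made monotone non-decreasing from the largest rank downwards
#' and capped at 1, returned in the original order. Unlike
#' `stats::p.adjust`, the family size `m` may exceed the number of supplied
#' p-values — needed when adjusting the top-ranked results of a larger
#' test family whose remaining p-values are not at hand.
#'
#' @param pvalues Numeric vector of p-values in `(0, 1]`.
#' @param m Family size (defaults to `length(pvalues)`; must be at least
#'   that).
#' @return Adjusted values in the original order.
#' @export
#' @examples
#' bh_adjust(c(0.0007, 0.0029, 0.008), m = 34)
bh_adjust <- function(pvalues, m = length(pvalues)) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues) | pvalues <= 0 | pvalues > 1))
    stop_domain("p-values must lie in (0, 1]")
  if (m < length(pvalues)) stop_domain("m must be at least length(pvalues)")
  o <- order(pvalues)
  k <- length(pvalues)
  adj <- m * pvalues[o] / seq_len(k)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(k)
  out[o] <- adj
  out
}

#' Significance tier of one result
#'
#' `"significant"` when the FDR-adjusted IVW p is below `fdr_threshold`
#' (default 0.1); `"nominal"` when the raw IVW p is below `nominal_p`
#' (default 0.05) but the adjusted p is not; otherwise `"null"`.
#'
#' @param pvalue Raw IVW p-value.
#' @param p_fdr BH-adjusted p-value.
#' @param fdr_threshold,nominal_p Tier cutoffs.
#' @return Character vector of tiers.
#' @export
classify_tier <- function(pvalue, p_fdr, fdr_threshold = 0.1,
                          nominal_p = 0.05) {
  ifelse(p_fdr < fdr_threshold, "significant",
         ifelse(pvalue < nominal_p, "nominal", "null"))
}

printed_decimals <- function(p) {
  s <- format(p, scientific = FALSE, trim = TRUE)
  ifelse(grepl("\\.", s), nchar(sub("^[^.]*\\.", "", s)), 0L)
}

#' Internal-consistency check of published result rows
#'
#' For each row of a printed results table, recomputes the two-sided Wald
#' p-value implied by the reported numbers — from `(OR, LCI, UCI)` via
#' [wald_p_from_or_ci()] when odds-ratio columns are present, otherwise
#' from `(beta, se)` — and flags rows whose implied and printed p-values
#' disagree by more than one unit in the last printed decimal place.
#'
#' @param table data.frame with a `pvalue` column and either
#'   `or`, `or_lci`, `or_uci` columns or `beta`, `se` columns. Extra columns
#'   are carried through.
#' @return The input with `implied_p` and `discrepancy` columns appended.
#' @export
consistency_check <- function(table) {
  has_or <- all(c("or", "or_lci", "or_uci") %in% names(table))
  has_beta <- all(c("beta", "se") %in% names(table))
  if (!has_or && !has_beta)
    stop_domain("table needs either (or, or_lci, or_uci) or (beta, se) columns")
  implied <- if (has_or) {
    vapply(seq_len(nrow(table)), function(i)
      wald_p_from_or_ci(table$or[i], table$or_lci[i], table$or_uci[i]),
      numeric(1))
  } else {
    two_sided_normal_p(table$beta / table$se)
  }
  tol <- 10^(-printed_decimals(table$pvalue))
  table$implied_p <- implied
  table$discrepancy <- abs(implied - table$pvalue) > tol
  table
}

# digest of an arbitrary R object via its deparsed form
manifest_digest <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(obj), f)
  unname(tools::md5sum(f))
}

resolve_records <- function(x, column_map = default_column_map()) {
  if (is.character(x)) read_sumstats(x, column_map) else x
}

# per-exposure seed derived from the run seed and the phenotype label,
# so run output is invariant to exposure ordering
label_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_len(nchar(label))) %% 100000L
  derive_seed(seed, h)
}

#' Run the bidirectional MR pipeline over many exposures
#'
#' For each exposure: restrict to genome-wide-significant, common variants;
#' LD-clump; harmonize against the outcome; apply outcome-association,
#' confounder-blocklist, and weak-instrument exclusions; purge MR-PRESSO
#' outliers (when at least four instruments remain) and re-estimate; fit all
#' requested estimators; and run the sensitivity suite. After all exposures,
#' BH-FDR is applied to the IVW p-values within the declared family and
#' significance tiers assigned. The run is fully determined by its inputs
#' and `seed`: per-exposure sub-seeds derive from the phenotype label, so
#' the output is invariant to the order of `exposures`.
#'
#' @param exposures Named list of exposure summary-statistic data.frames (or
#'   file paths); names are the phenotype labels.
#' @param outcome Outcome summary-statistic data.frame or file path.
#' @param ld An [ld_reference()] covering the exposure candidates.
#' @param blocklist Character vector of confounder-associated variant IDs
#'   (or a path readable by [read_blocklist()]).
#' @param config A [selection_config()]; use the `"forward"` or `"reverse"`
#'   preset to match the analysis direction.
#' @param direction Label recorded on every row.
#' @param outcome_name Outcome label.
#' @param fdr_family_size BH family size `m`; defaults to the number of
#'   exposures.
#' @param fdr_threshold,nominal_p Tier cutoffs (defaults 0.1 and 0.05).
#' @param binary_outcome,methods Passed to [mr_fit()].
#' @param n_boot,n_sim_presso Replication settings.
#' @param seed Master integer seed.
#' @return data.frame with one row per exposure and method: `exposure`,
#'   `outcome`, `direction`, `method`, `n_snps`, `beta`, `se`, `pvalue`,
#'   odds-ratio columns when binary, and on every row the exposure-level
#'   `p_fdr` (BH-adjusted IVW p) and `tier`. Attributes: `sensitivity`
#'   (named list of [sensitivity_report()]s), `fits` (named list of
#'   [mr_fit()] objects), and `manifest` (config digest, seeds, version,
#'   timestamp, per-stage record counts).
#' @export
run_bidirectional <- function(exposures, outcome, ld,
                              blocklist = character(),
                              config = selection_config("forward"),
                              direction = "forward",
                              outcome_name = "outcome",
                              fdr_family_size = NULL,
                              fdr_threshold = 0.1, nominal_p = 0.05,
                              binary_outcome = TRUE,
                              methods = c("ivw", "egger", "weighted_median",
                                          "simple_median", "weighted_mode"),
                              n_boot = 1000, n_sim_presso = 1000,
                              seed = 1L) {
  if (is.null(names(exposures)) || any(!nzchar(names(exposures))))
    stop_domain("exposures must be a named list (names are phenotype labels)")
  if (is.character(blocklist) && length(blocklist) == 1 &&
      file.exists(blocklist))
    blocklist <- read_blocklist(blocklist)
  outcome_records <- resolve_records(outcome)

  labels <- names(exposures)
  per_exposure <- stats::setNames(vector("list", length(labels)), labels)
  sens_list <- stats::setNames(vector("list", length(labels)), labels)
  fit_list <- stats::setNames(vector("list", length(labels)), labels)
  counts <- stats::setNames(vector("list", length(labels)), labels)

  for (label in labels) {
    res <- tryCatch({
      records <- resolve_records(exposures[[label]])
      maf <- pmin(records$eaf, 1 - records$eaf)
      candidates <- records[records$pvalue < config$p_threshold &
                              maf >= config$maf_min, , drop = FALSE]
      if (nrow(candidates) == 0)
        stop_domain("no candidates pass the significance and MAF filters")
      clumped <- ld_clump(candidates, ld, config)
      hset <- harmonize(clumped, outcome_records, exposure_name = label,
                        outcome_name = outcome_name)
      hset <- apply_exclusions(hset, blocklist, config)
      exp_seed <- label_seed(seed, label)
      if (nrow(hset) >= 4) {
        presso <- mr_presso(hset, n_sim = n_sim_presso,
                            seed = derive_seed(exp_seed, 1L))
        if (length(presso$outliers) > 0 &&
            nrow(hset) - length(presso$outliers) >= 2)
          hset <- exclude_pairs(hset, presso$outliers, "presso_outlier")
      }
      fit <- suppressMessages(
        mr_fit(hset, methods = methods, binary_outcome = binary_outcome,
               n_boot = n_boot, seed = derive_seed(exp_seed, 2L)))
      sens <- sensitivity_report(hset, n_sim = n_sim_presso,
                                 seed = derive_seed(exp_seed, 3L))
      list(fit = fit, sens = sens,
           counts = list(input = nrow(records), candidates = nrow(candidates),
                         clumped = nrow(clumped), instruments = nrow(hset)))
    }, error = function(e) {
      stop_domain(sprintf("[%s] %s", label, conditionMessage(e)))
    })
    fit_list[[label]] <- res$fit
    sens_list[[label]] <- res$sens
    counts[[label]] <- res$counts
    est <- res$fit$estimates
    est <- cbind(data.frame(exposure = label, outcome = outcome_name,
                            direction = direction,
                            stringsAsFactors = FALSE), est)
    per_exposure[[label]] <- est
  }

  result <- do.call(rbind, per_exposure[order(labels)])
  rownames(result) <- NULL

  ivw_p <- vapply(labels, function(l) {
    e <- fit_list[[l]]$estimates
    e$pvalue[e$method == "ivw"][1]
  }, numeric(1))
  m <- fdr_family_size %||% length(labels)
  p_fdr <- stats::setNames(bh_adjust(ivw_p, m = m), labels)
  tier <- stats::setNames(
    classify_tier(ivw_p, p_fdr, fdr_threshold, nominal_p), labels)
  result$p_fdr <- unname(p_fdr[result$exposure])
  result$tier <- unname(tier[result$exposure])

  manifest <- list(
    config_digest = manifest_digest(list(config = unclass(config),
                                         exposures = labels,
                                         outcome = outcome_name,
                                         direction = direction,
                                         fdr_family_size = m,
                                         seed = seed,
                                         n_boot = n_boot,
                                         n_sim_presso = n_sim_presso)),
    seeds = c(list(master = seed),
              stats::setNames(lapply(labels, label_seed, seed = seed), labels)),
    version = as.character(utils::packageVersion("mrcoloc")),
    timestamp = format(Sys.time(), tz = "UTC"),
    counts = counts)
  attr(result, "sensitivity") <- sens_list
  attr(result, "fits") <- fit_list
  attr(result, "manifest") <- manifest
  result
}

#' Write a pipeline result table and its run manifest
#'
#' @param result Output of [run_bidirectional()].
#' @param tsv_path Output TSV for the wide result table.
#' @param manifest_path Optional JSON path for the run manifest.
#' @return Invisibly, `result`.
#' @export
write_run_result <- function(result, tsv_path, manifest_path = NULL) {
  utils::write.table(as.data.frame(result), tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(manifest_path))
    jsonlite::write_json(attr(result, "manifest"), manifest_path,
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(result)
}

#' Run the pipeline from a YAML configuration file
#'
#' A thin file-driven wrapper over [run_bidirectional()] so a whole analysis
#' is an auditable artifact. The configuration lists the exposure files
#' (a mapping of label to path), the outcome file, the LD reference files,
#' an optional blocklist path, the direction preset, FDR settings, and
#' seeds. Outputs (result TSV and manifest JSON) are written next to
#' `out_prefix`.
#'
#' @param config_path YAML file path.
#' @param out_prefix Output path prefix; writes `<prefix>_results.tsv` and
#'   `<prefix>_manifest.json`.
#' @return The [run_bidirectional()] result, invisibly.
#' @export
run_from_config <- function(config_path, out_prefix) {
  cfg <- yaml::read_yaml(config_path)
  sel <- selection_config(preset = cfg$preset %||% "forward")
  ld <- read_ld_reference(cfg$ld$r2, cfg$ld$positions)
  result <- run_bidirectional(
    exposures = cfg$exposures,
    outcome = cfg$outcome,
    ld = ld,
    blocklist = cfg$blocklist %||% character(),
    config = sel,
    direction = cfg$direction %||% cfg$preset %||% "forward",
    outcome_name = cfg$outcome_name %||% "outcome",
    fdr_family_size = cfg$fdr_family_size,
    binary_outcome = cfg$binary_outcome %||% TRUE,
    n_boot = cfg$n_boot %||% 1000,
    n_sim_presso = cfg$n_sim_presso %||% 1000,
    seed = cfg$seed %||% 1L)
  write_run_result(result, paste0(out_prefix, "_results.tsv"),
                   paste0(out_prefix, "_manifest.json"))
  invisible(result)
}
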