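#' Default column mapping for GWAS summary-statistic tables
#'
#' Canonical field names used throughout the package mapped to the
#' conventional header names of two-sample MR summary files: `SNP`, `CHR`,
#' `BP`, `A1` (effect allele), `A2` (other allele), `EAF`, `BETA`, `SE`,
#' `P`, `N`. Pass a modified copy to [read_sumstats()] for files using a
#' different header dialect.
#'
#' @return Named character vector mapping canonical names to header names.
#' @export
#' @examples
#' default_column_map()
default_column_map <- function() {
  c(variant_id = "SNP", chrom = "CHR", pos = "BP",
    effect_allele = "A1", other_allele = "A2",
    eaf = "EAF", beta = "BETA", se = "SE", pvalue = "P", n = "N")
}

VALID_BASES <- c("A", "C", "G", "T")

# row-level validation; returns character vector of reasons ("" when valid)
validate_sumstats_rows <- function(d) {
  reason <- character(nrow(d))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    ifelse(reason == "" & cond, why, reason)
  }
  reason <- bad(!(d$effect_allele %in% VALID_BASES) |
                !(d$other_allele %in% VALID_BASES),
                "allele not a single base (indel/multi-allelic rejected)")
  reason <- bad(d$effect_allele == d$other_allele, "identical alleles")
  reason <- bad(!is.finite(d$se) | d$se <= 0, "se <= 0")
  reason <- bad(!is.finite(d$eaf) | d$eaf < 0 | d$eaf > 1, "eaf outside [0,1]")
  reason <- bad(!is.finite(d$beta), "non-finite beta")
  reason <- bad(!is.finite(d$pvalue) | d$pvalue <= 0 | d$pvalue > 1,
                "p outside (0,1]")
  reason <- bad(!is.finite(d$pos) | d$pos < 1, "pos < 1")
  reason <- bad(!is.finite(d$n) | d$n <= 0, "n <= 0")
  reason
}

#' Read a GWAS summary-statistic table
#'
#' Reads a tab-separated table (optionally gzip-compressed) of per-variant
#' association summaries, validates each row, and returns the valid records
#' sorted by chromosome and position. Rows failing validation (non-positive
#' standard error, allele frequency outside `[0,1]`, indel or multi-allelic
#' alleles, out-of-range p-value, and similar) are skipped, counted, and
#' reported with their line numbers via the `"skipped"` attribute and a
#' warning.
#'
#' @param path Path to a TSV file (a `.gz` suffix is read transparently).
#' @param column_map Named character vector mapping the canonical field names
#'   (see [default_column_map()]) to the file's header names.
#' @return A `data.frame` with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`,
#'   sorted by `(chrom, pos)`, with attributes `skipped` (a data.frame of
#'   `line`, `variant_id`, `reason`) and `n_skipped`.
#' @export
read_sumstats <- function(path, column_map = default_column_map()) {
  if (!file.exists(path)) stop_domain("summary-statistic file not found: ", path)
  needed <- default_column_map()
  if (!all(names(needed) %in% names(column_map)))
    stop_domain("column_map must name all of: ",
                paste(names(needed), collapse = ", "))
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "")
  missing_cols <- setdiff(unname(column_map[names(needed)]), names(raw))
  if (length(missing_cols) > 0)
    stop_domain("columns missing from ", path, ": ",
                paste(missing_cols, collapse = ", "))
  d <- data.frame(
    variant_id    = raw[[column_map[["variant_id"]]]],
    chrom         = raw[[column_map[["chrom"]]]],
    pos           = suppressWarnings(as.integer(raw[[column_map[["pos"]]]])),
    effect_allele = toupper(raw[[column_map[["effect_allele"]]]]),
    other_allele  = toupper(raw[[column_map[["other_allele"]]]]),
    eaf           = suppressWarnings(as.numeric(raw[[column_map[["eaf"]]]])),
    beta          = suppressWarnings(as.numeric(raw[[column_map[["beta"]]]])),
    se            = suppressWarnings(as.numeric(raw[[column_map[["se"]]]])),
    pvalue        = suppressWarnings(as.numeric(raw[[column_map[["pvalue"]]]])),
    n             = suppressWarnings(as.numeric(raw[[column_map[["n"]]]])),
    stringsAsFactors = FALSE
  )
  reason <- validate_sumstats_rows(d)
  bad <- reason != ""
  skipped <- data.frame(line = which(bad) + 1L,  # +1 for the header line
                        variant_id = d$variant_id[bad],
                        reason = reason[bad],
                        stringsAsFactors = FALSE)
  if (nrow(skipped) > 0)
    warning(sprintf("%d row(s) of %s skipped by validation (lines %s)",
                    nrow(skipped), basename(path),
                    paste(utils::head(skipped$line, 10L), collapse = ", ")),
            call. = FALSE)
  d <- d[!bad, , drop = FALSE]
  d <- d[order(d$chrom, d$pos, d$variant_id), , drop = FALSE]
  rownames(d) <- NULL
  attr(d, "skipped") <- skipped
  attr(d, "n_skipped") <- nrow(skipped)
  d
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "G" & a2 == "C") | (a1 == "C" & a2 == "G")
}

new_harmonized_set <- function(pairs, exclusions, exposure_name, outcome_name) {
  structure(pairs,
            exclusions = exclusions,
            exposure_name = exposure_name,
            outcome_name = outcome_name,
            class = c("harmonized_set", "data.frame"))
}

#' Harmonize exposure and outcome summary statistics
#'
#' Pairs variants present in both studies so that exposure and outcome
#' effects refer to the same effect allele. When the outcome's alleles are
#' swapped relative to the exposure, the outcome beta is negated and its
#' effect-allele frequency replaced by `1 - eaf`. Palindromic variants
#' (A/T or G/C) are excluded by default because strand orientation is
#' ambiguous between studies; variants whose allele sets match neither
#' directly nor after swapping are excluded as incompatible; variants absent
#' from the outcome are excluded as missing. Matching is by variant ID only;
#' position disagreements between the studies are reported as warnings.
#'
#' @param exposure,outcome Summary-statistic data.frames as returned by
#'   [read_sumstats()].
#' @param exposure_name,outcome_name Labels used in reports and error
#'   messages.
#' @param palindromic_rescue If `TRUE`, palindromic variants whose allele
#'   frequencies are concordant and clearly away from 0.5 in both studies
#'   (|eaf - 0.5| > `eaf_margin`) are retained instead of dropped. Off by
#'   default (the stricter convention).
#' @param eaf_margin Minimum distance of both allele frequencies from 0.5
#'   for a palindromic rescue.
#' @return A `harmonized_set`: a data.frame of paired effects
#'   (`variant_id`, `chrom`, `pos`, `beta_exposure`, `se_exposure`,
#'   `pvalue_exposure`, `eaf_exposure`, `n_exposure`, and the corresponding
#'   `_outcome` columns) with an `exclusions` attribute recording
#'   `(variant_id, reason)` for every exposure variant not paired.
#' @export
harmonize <- function(exposure, outcome,
                      exposure_name = "exposure", outcome_name = "outcome",
                      palindromic_rescue = FALSE, eaf_margin = 0.08) {
  if (anyDuplicated(exposure$variant_id) || anyDuplicated(outcome$variant_id))
    stop_domain("duplicate variant IDs within a study are not supported")
  idx <- match(exposure$variant_id, outcome$variant_id)
  exc <- list()
  keep <- logical(nrow(exposure))
  beta_o <- se_o <- p_o <- eaf_o <- n_o <- numeric(nrow(exposure))

  for (i in seq_len(nrow(exposure))) {
    j <- idx[i]
    if (is.na(j)) {
      exc[[length(exc) + 1L]] <- c(exposure$variant_id[i], "missing_in_outcome")
      next
    }
    e1 <- exposure$effect_allele[i]; e2 <- exposure$other_allele[i]
    o1 <- outcome$effect_allele[j];  o2 <- outcome$other_allele[j]
    pal <- is_palindromic(e1, e2)
    direct <- (e1 == o1 && e2 == o2)
    swapped <- (e1 == o2 && e2 == o1)
    if (pal) {
      rescued <- FALSE
      if (palindromic_rescue) {
        fe <- exposure$eaf[i]; fo <- outcome$eaf[j]
        if (abs(fe - 0.5) > eaf_margin && abs(fo - 0.5) > eaf_margin) {
          # infer orientation from frequency concordance
          same_orientation <- (fe - 0.5) * (fo - 0.5) > 0
          keep[i] <- TRUE; rescued <- TRUE
          if (same_orientation) {
            beta_o[i] <- outcome$beta[j]; eaf_o[i] <- outcome$eaf[j]
          } else {
            beta_o[i] <- -outcome$beta[j]; eaf_o[i] <- 1 - outcome$eaf[j]
          }
          se_o[i] <- outcome$se[j]; p_o[i] <- outcome$pvalue[j]
          n_o[i] <- outcome$n[j]
        }
      }
      if (!rescued)
        exc[[length(exc) + 1L]] <- c(exposure$variant_id[i], "palindromic")
      next
    }
    if (direct || swapped) {
      keep[i] <- TRUE
      sgn <- if (direct) 1 else -1
      beta_o[i] <- sgn * outcome$beta[j]
      eaf_o[i] <- if (direct) outcome$eaf[j] else 1 - outcome$eaf[j]
      se_o[i] <- outcome$se[j]; p_o[i] <- outcome$pvalue[j]
      n_o[i] <- outcome$n[j]
    } else {
      exc[[length(exc) + 1L]] <- c(exposure$variant_id[i], "incompatible_alleles")
    }
  }

  shared <- !is.na(idx)
  if (any(shared)) {
    pos_mismatch <- exposure$pos[shared] != outcome$pos[idx[shared]]
    if (any(pos_mismatch, na.rm = TRUE))
      warning(sprintf("%d shared variant(s) disagree on position between %s and %s (IDs matched anyway)",
                      sum(pos_mismatch, na.rm = TRUE), exposure_name, outcome_name),
              call. = FALSE)
  }

  exclusions <- if (length(exc) > 0) {
    m <- do.call(rbind, exc)
    data.frame(variant_id = m[, 1L], reason = m[, 2L], stringsAsFactors = FALSE)
  } else {
    data.frame(variant_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  }

  if (!any(keep))
    stop_domain(sprintf("no harmonizable variants shared between %s and %s",
                        exposure_name, outcome_name))

  pairs <- data.frame(
    variant_id = exposure$variant_id[keep],
    chrom = exposure$chrom[keep],
    pos = exposure$pos[keep],
    beta_exposure = exposure$beta[keep],
    se_exposure = exposure$se[keep],
    pvalue_exposure = exposure$pvalue[keep],
    eaf_exposure = exposure$eaf[keep],
    n_exposure = exposure$n[keep],
    beta_outcome = beta_o[keep],
    se_outcome = se_o[keep],
    pvalue_outcome = p_o[keep],
    eaf_outcome = eaf_o[keep],
    n_outcome = n_o[keep],
    stringsAsFactors = FALSE
  )
  rownames(pairs) <- NULL
  new_harmonized_set(pairs, exclusions, exposure_name, outcome_name)
}

#' Construct a harmonized set from already-oriented effect pairs
#'
#' Convenience constructor for data whose exposure and outcome effects are
#' already expressed for the same effect allele (for example simulated data
#' or a table exported by another tool).
#'
#' @param pairs A data.frame with at least `variant_id`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`; missing auxiliary columns
#'   are filled with `NA`.
#' @param exposure_name,outcome_name Labels.
#' @param exclusions Optional data.frame of `(variant_id, reason)`.
#' @return A `harmonized_set`.
#' @export
as_harmonized_set <- function(pairs, exposure_name = "exposure",
                              outcome_name = "outcome",
                              exclusions = NULL) {
  required <- c("variant_id", "beta_exposure", "se_exposure",
                "beta_outcome", "se_outcome")
  miss <- setdiff(required, names(pairs))
  if (length(miss) > 0)
    stop_domain("pairs lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(pairs) < 1) stop_domain("a harmonized set needs at least one pair")
  if (any(pairs$se_exposure <= 0) || any(pairs$se_outcome <= 0))
    stop_domain("standard errors must be positive")
  optional <- c("chrom", "pos", "pvalue_exposure", "eaf_exposure", "n_exposure",
                "pvalue_outcome", "eaf_outcome", "n_outcome")
  for (col in setdiff(optional, names(pairs))) pairs[[col]] <- NA
  exclusions <- exclusions %||%
    data.frame(variant_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  pairs <- as.data.frame(pairs)[, c("variant_id", "chrom", "pos",
                                    "beta_exposure", "se_exposure",
                                    "pvalue_exposure", "eaf_exposure",
                                    "n_exposure", "beta_outcome", "se_outcome",
                                    "pvalue_outcome", "eaf_outcome",
                                    "n_outcome")]
  rownames(pairs) <- NULL
  new_harmonized_set(pairs, exclusions, exposure_name, outcome_name)
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %s -> %s\n", attr(x, "exposure_name"),
              attr(x, "outcome_name")))
  cat(sprintf("  %d paired variant(s), %d exclusion(s)\n",
              nrow(x), nrow(attr(x, "exclusions"))))
  ex <- attr(x, "exclusions")
  if (nrow(ex) > 0) {
    tab <- table(ex$reason)
    cat("  exclusions:", paste(sprintf("%s=%d", names(tab), tab),
                               collapse = ", "), "\n")
  }
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more row(s)\n")
  invisible(x)
}

# move pairs to the exclusions table with a reason code
exclude_pairs <- function(hset, drop_ids, reason) {
  if (length(drop_ids) == 0) return(hset)
  ex <- attr(hset, "exclusions")
  ex <- rbind(ex, data.frame(variant_id = drop_ids, reason = reason,
                             stringsAsFactors = FALSE))
  pairs <- as.data.frame(hset)[!(hset$variant_id %in% drop_ids), , drop = FALSE]
  rownames(pairs) <- NULL
  new_harmonized_set(pairs, ex, attr(hset, "exposure_name"),
                     attr(hset, "outcome_name"))
}

#' Write a harmonized set to TSV files
#'
#' Writes the paired effects (columns suffixed `.exposure` / `.outcome`) and
#' the exclusions table as two tab-separated files.
#'
#' @param hset A `harmonized_set`.
#' @param pairs_path,exclusions_path Output file paths.
#' @return Invisibly, `hset`.
#' @export
write_harmonized_set <- function(hset, pairs_path, exclusions_path = NULL) {
  d <- as.data.frame(hset)
  names(d) <- sub("_exposure$", ".exposure", names(d))
  names(d) <- sub("_outcome$", ".outcome", names(d))
  utils::write.table(d, pairs_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(exclusions_path))
    utils::write.table(attr(hset, "exclusions"), exclusions_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(hset)
}
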