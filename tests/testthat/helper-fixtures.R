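# in-code fixtures shared by the unit tests

# minimal summary-stat data.frame in canonical internal layout
make_records <- function(ids, beta, se,
                         ea = "A", oa = "G",
                         chrom = "1", pos = 10000L * seq_along(ids),
                         eaf = 0.3, pvalue = NULL, n = 10000) {
  if (is.null(pvalue)) pvalue <- 2 * pnorm(-abs(beta / se))
  data.frame(variant_id = ids, chrom = chrom, pos = pos,
             effect_allele = rep_len(ea, length(ids)),
             other_allele = rep_len(oa, length(ids)),
             eaf = rep_len(eaf, length(ids)), beta = beta, se = se,
             pvalue = pvalue, n = rep_len(n, length(ids)),
             stringsAsFactors = FALSE)
}

# harmonized set straight from effect pairs
make_hset <- function(bx, sx, by, sy, ids = paste0("rs", seq_along(bx)), ...) {
  as_harmonized_set(data.frame(variant_id = ids,
                               beta_exposure = bx, se_exposure = sx,
                               beta_outcome = by, se_outcome = sy, ...),
                    "exposure", "outcome")
}

# write a canonical-header TSV and return its path
write_sumstats_tsv <- function(records, path = tempfile(fileext = ".tsv"),
                               header = c(SNP = "variant_id", CHR = "chrom",
                                          BP = "pos", A1 = "effect_allele",
                                          A2 = "other_allele", EAF = "eaf",
                                          BETA = "beta", SE = "se",
                                          P = "pvalue", N = "n")) {
  d <- records[, unname(header)]
  names(d) <- names(header)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# brute-force clumping validity check: every kept pair independent, every
# dropped candidate conflicts with a better-ranked kept one
check_clump_brute_force <- function(kept, candidates, ld, config) {
  ki <- match(kept$variant_id, ld$variant_ids)
  for (a in seq_len(nrow(kept))) for (b in seq_len(nrow(kept))) {
    if (a == b) next
    same <- kept$chrom[a] == kept$chrom[b] &&
      abs(kept$pos[a] - kept$pos[b]) <= config$window_bp
    if (same && ld$r2[ki[a], ki[b]] > config$r2_threshold) return(FALSE)
  }
  dropped <- candidates[!(candidates$variant_id %in% kept$variant_id), ,
                        drop = FALSE]
  for (d in seq_len(nrow(dropped))) {
    di <- match(dropped$variant_id[d], ld$variant_ids)
    conflict <- FALSE
    for (a in seq_len(nrow(kept))) {
      better <- kept$pvalue[a] < dropped$pvalue[d] ||
        (kept$pvalue[a] == dropped$pvalue[d] &&
           kept$variant_id[a] < dropped$variant_id[d])
      same <- kept$chrom[a] == dropped$chrom[d] &&
        abs(kept$pos[a] - dropped$pos[d]) <= config$window_bp
      if (better && same && ld$r2[ki[a], di] > config$r2_threshold)
        conflict <- TRUE
    }
    if (!conflict) return(FALSE)
  }
  TRUE
}

# multi-exposure pipeline inputs: one simulated study per label (variant IDs
# prefixed by label), a pooled outcome table, and an identity LD reference
make_multi_exposure_inputs <- function(thetas, n_snps = 60, seed = 1) {
  exposures <- list()
  outcome_parts <- list()
  ids_all <- character()
  pos_all <- integer()
  for (i in seq_along(thetas)) {
    label <- names(thetas)[i]
    sim <- simulate_gwas_pair(sim_config(n_snps = n_snps, theta = thetas[[i]],
                                         pi_causal = 0.5,
                                         seed = seed + 1000L * i))
    rename <- function(d) {
      d$variant_id <- paste0(label, "_", d$variant_id)
      d$pos <- d$pos + 1000000L * i
      d
    }
    exposures[[label]] <- rename(sim$exposure)
    outcome_parts[[label]] <- rename(sim$outcome)
    ids_all <- c(ids_all, exposures[[label]]$variant_id)
    pos_all <- c(pos_all, exposures[[label]]$pos)
  }
  r2 <- diag(length(ids_all))
  dimnames(r2) <- list(ids_all, ids_all)
  ld <- ld_reference(r2, data.frame(variant_id = ids_all, chrom = "1",
                                    pos = pos_all, stringsAsFactors = FALSE))
  list(exposures = exposures, outcome = do.call(rbind, outcome_parts), ld = ld)
}

# exhaustive enumeration of single-causal configurations for small regions:
# independent oracle for coloc_abf (plain arithmetic, no log-space tricks)
coloc_enumerate <- function(abf1, abf2, p1, p2, p12) {
  m <- length(abf1)
  s <- c(h0 = 1, h1 = 0, h2 = 0, h3 = 0, h4 = 0)
  for (i in seq_len(m)) s["h1"] <- s["h1"] + p1 * abf1[i]
  for (j in seq_len(m)) s["h2"] <- s["h2"] + p2 * abf2[j]
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    s["h3"] <- s["h3"] + p1 * p2 * abf1[i] * abf2[j]
  }
  for (i in seq_len(m)) s["h4"] <- s["h4"] + p12 * abf1[i] * abf2[i]
  s / sum(s)
}
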