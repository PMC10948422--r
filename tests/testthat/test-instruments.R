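# instrument selection: clumping, strength filters, exclusions

test_that("a single candidate clumps to itself", {
  cand <- make_records("rs1", beta = 0.1, se = 0.01)
  ld <- make_ld_fixture(1, 1, 0)
  expect_equal(ld_clump(cand, ld)$variant_id, "rs1")
})

test_that("correlated nearby candidates collapse to the best p-value", {
  cand <- make_records(c("rs1", "rs2"), beta = c(0.12, 0.10),
                       se = c(0.01, 0.01), pos = c(100000L, 150000L),
                       pvalue = c(1e-9, 1e-7))
  r2 <- matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(c("rs1", "rs2"),
                                                     c("rs1", "rs2")))
  ld <- ld_reference(r2, data.frame(variant_id = c("rs1", "rs2"),
                                    chrom = "1", pos = c(100000L, 150000L)))
  kept <- ld_clump(cand, ld)
  expect_equal(kept$variant_id, "rs1")
})

test_that("clumping a 5-candidate fixture matches the brute-force checker", {
  ids <- paste0("rs", 1:5)
  r2 <- matrix(c(1.00, 0.50, 0.00, 0.00, 0.00,
                 0.50, 1.00, 0.30, 0.00, 0.00,
                 0.00, 0.30, 1.00, 0.00, 0.90,
                 0.00, 0.00, 0.00, 1.00, 0.00,
                 0.00, 0.00, 0.90, 0.00, 1.00),
               5, 5, dimnames = list(ids, ids))
  pos <- data.frame(variant_id = ids, chrom = "1",
                    pos = c(1e5, 1.5e5, 2e5, 9e6, 2.5e5))
  ld <- ld_reference(r2, pos)
  cand <- make_records(ids, beta = rep(0.1, 5), se = rep(0.01, 5),
                       pos = pos$pos,
                       pvalue = c(1e-7, 1e-9, 1e-8, 1e-6, 1e-10))
  cfg <- selection_config(r2_threshold = 0.2, window_bp = 1e6)
  kept <- ld_clump(cand, ld, cfg)
  expect_true(check_clump_brute_force(kept, cand, ld, cfg))
  # rs5 (best p) knocks out rs3; rs2 knocks out rs1; rs4 independent
  expect_setequal(kept$variant_id, c("rs2", "rs4", "rs5"))
})

test_that("clumping is invariant to candidate order", {
  set.seed(42)
  n <- 30
  ld <- make_ld_fixture(n, 5, 0.7)
  cand <- make_records(paste0("rs", 1:n), beta = rnorm(n, 0, 0.1),
                       se = rep(0.01, n), pos = ld$positions$pos,
                       pvalue = runif(n, 1e-12, 1e-6))
  cfg <- selection_config(r2_threshold = 0.3, window_bp = 1e6)
  kept1 <- ld_clump(cand, ld, cfg)
  perm <- cand[sample(n), , drop = FALSE]
  kept2 <- ld_clump(perm, ld, cfg)
  expect_equal(kept1$variant_id, kept2$variant_id)
  expect_true(check_clump_brute_force(kept1, cand, ld, cfg))
})

test_that("candidates absent from the LD reference follow the chosen policy", {
  cand <- make_records(c("rs1", "rs_unknown"), beta = c(0.1, 0.1),
                       se = c(0.01, 0.01))
  ld <- make_ld_fixture(1, 1, 0)
  expect_warning(kept <- ld_clump(cand, ld), "absent")
  expect_equal(kept$variant_id, "rs1")
  expect_error(ld_clump(cand, ld, missing_ld = "error"), "absent")
})

test_that("the F-statistic matches its closed form and domain", {
  expect_equal(compute_f_statistic(0, 100, 5)$f, 0)
  expect_equal(compute_f_statistic(0.05, 1000, 10)$f,
               0.05 * 989 / (0.95 * 10))
  expect_equal(compute_f_statistic(0.05, 1000, 10)$f, 5.205263, tolerance = 1e-6)
  expect_equal(compute_f_statistic(0.01, 23909, 100)$f,
               0.01 * (23909 - 101) / (0.99 * 100))
  expect_equal(compute_f_statistic(0.01, 23909, 100)$f, 2.40485, tolerance = 1e-5)
  expect_error(compute_f_statistic(0.05, 11, 10), "n > k")
  expect_error(compute_f_statistic(1, 1000, 10), "range")
})

test_that("F is strictly increasing in variance explained and sample size", {
  r2 <- seq(0.001, 0.2, length.out = 20)
  f <- vapply(r2, function(x) compute_f_statistic(x, 5000, 10)$f, numeric(1))
  expect_true(all(diff(f) > 0))
  ns <- seq(100, 10000, length.out = 20)
  f <- vapply(ns, function(n) compute_f_statistic(0.05, n, 10)$f, numeric(1))
  expect_true(all(diff(f) > 0))
})

test_that("per-SNP variance explained follows the z-based map", {
  expect_equal(snp_variance_explained(0, 0.01, 1000), 0)
  expect_equal(snp_variance_explained(0.1, 0.02, 10000), 25 / (25 + 9998))
  # monotone in |z| at fixed n
  z <- seq(0.5, 10, length.out = 25)
  r2 <- vapply(z, function(zi) snp_variance_explained(zi * 0.01, 0.01, 5000),
               numeric(1))
  expect_true(all(diff(r2) > 0))
  # alternative frequency-based formula
  expect_equal(snp_variance_explained(0.1, 0.02, 10000, eaf = 0.3,
                                      formula = "maf_beta"),
               2 * 0.3 * 0.7 * 0.01)
})

test_that("exclusion rules move pairs to the right reason codes", {
  h <- make_hset(bx = c(0.10, 0.10, 0.10, 0.002),
                 sx = c(0.01, 0.01, 0.01, 0.010),
                 by = c(0.05, 0.05, 0.05, 0.010),
                 sy = rep(0.02, 4),
                 pvalue_outcome = c(0.5, 0.04, 0.5, 0.5),
                 n_exposure = rep(10000, 4))
  out <- apply_exclusions(h, confounder_blocklist = "rs3",
                          config = selection_config())
  ex <- attr(out, "exclusions")
  expect_equal(ex$reason[ex$variant_id == "rs2"], "outcome_associated")
  expect_equal(ex$reason[ex$variant_id == "rs3"], "confounder")
  # rs4: z = 0.2, single-SNP F far below 10
  expect_equal(ex$reason[ex$variant_id == "rs4"], "weak_instrument")
  expect_equal(out$variant_id, "rs1")
})

test_that("a single-SNP F just below 10 is excluded as weak", {
  # pick z so that F = z^2/(z^2+n-2)*(n-2)/1 = z^2 -> F = 9.9 (n large)
  n <- 100000
  z <- sqrt(9.9 * (n - 2) / (n - 2 - 9.9 + 0.0))  # ~ sqrt(9.9)
  h <- make_hset(bx = c(z * 0.01, 0.1), sx = c(0.01, 0.01),
                 by = c(0.01, 0.02), sy = c(0.02, 0.02),
                 pvalue_outcome = c(0.5, 0.5), n_exposure = c(n, n))
  out <- apply_exclusions(h, config = selection_config())
  ex <- attr(out, "exclusions")
  expect_equal(ex$reason[ex$variant_id == "rs1"], "weak_instrument")
  expect_equal(out$variant_id, "rs2")
})

test_that("excluding every instrument raises an explicit empty-set error", {
  h <- make_hset(0.1, 0.01, 0.05, 0.02, pvalue_outcome = 0.001,
                 n_exposure = 10000)
  expect_error(apply_exclusions(h, config = selection_config()),
               "all instruments excluded")
})

test_that("selection presets carry the per-direction defaults", {
  fwd <- selection_config("forward")
  expect_equal(fwd$p_threshold, 5e-6)
  expect_equal(fwd$window_bp, 1e7)
  rev <- selection_config("reverse")
  expect_equal(rev$p_threshold, 5e-8)
  expect_equal(rev$window_bp, 250000)
  for (cfg in list(fwd, rev)) {
    expect_equal(cfg$r2_threshold, 0.001)
    expect_equal(cfg$maf_min, 0.01)
    expect_equal(cfg$f_min, 10)
    expect_equal(cfg$outcome_p_exclude, 0.05)
  }
})

test_that("LD references validate symmetry, diagonal, and positions", {
  r2 <- matrix(c(1, 0.5, 0.4, 1), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  pos <- data.frame(variant_id = c("a", "b"), chrom = "1", pos = c(1L, 2L))
  expect_error(ld_reference(r2, pos), "symmetric")
  r2ok <- matrix(c(1, 0.5, 0.5, 1), 2,
                 dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(ld_reference(r2ok, pos[1, , drop = FALSE]), "positions")
  expect_s3_class(ld_reference(r2ok, pos), "ld_reference")
})

test_that("dosage matrices convert to squared-correlation LD", {
  set.seed(9)
  g <- matrix(rbinom(300, 2, 0.4), nrow = 3,
              dimnames = list(c("a", "b", "c"), NULL))
  pos <- data.frame(variant_id = c("a", "b", "c"), chrom = "1", pos = 1:3)
  ld <- ld_from_dosage(g, pos)
  expect_equal(ld$r2["a", "b"], cor(g["a", ], g["b", ])^2)
  expect_equal(diag(ld$r2), c(a = 1, b = 1, c = 1))
})

test_that("blocklists read variant IDs and ignore comments", {
  path <- tempfile()
  writeLines(c("# confounder-associated variants", "rs10  smoking",
               "", "rs20"), path)
  expect_equal(read_blocklist(path), c("rs10", "rs20"))
})
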