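# reading, validation, and allele harmonization

test_that("a well-formed table reads to one record per row, sorted", {
  rec <- make_records(c("rs3", "rs1", "rs2"), beta = c(0.1, 0.2, -0.1),
                      se = c(0.01, 0.02, 0.03), pos = c(30L, 10L, 20L))
  path <- write_sumstats_tsv(rec)
  got <- read_sumstats(path)
  expect_equal(nrow(got), 3)
  expect_equal(attr(got, "n_skipped"), 0)
  expect_equal(got$variant_id, c("rs1", "rs2", "rs3"))
  expect_equal(got$beta, c(0.2, -0.1, 0.1))
})

test_that("invalid rows are skipped, counted, and reported with line numbers", {
  rec <- make_records(paste0("rs", 1:4), beta = rep(0.1, 4), se = rep(0.01, 4))
  rec$se[2] <- 0              # invalid
  rec$eaf[4] <- 1.2           # invalid
  path <- write_sumstats_tsv(rec)
  expect_warning(got <- read_sumstats(path), "2 row")
  expect_equal(nrow(got), 2)
  skipped <- attr(got, "skipped")
  expect_equal(sort(skipped$line), c(3L, 5L))  # header is line 1
  expect_true(any(grepl("se", skipped$reason)))
  expect_true(any(grepl("eaf", skipped$reason)))
})

test_that("indels and multi-allelic rows are rejected at read time", {
  rec <- make_records(c("rs1", "rs2"), beta = c(0.1, 0.1), se = c(0.01, 0.01))
  rec$effect_allele[2] <- "AT"
  path <- write_sumstats_tsv(rec)
  expect_warning(got <- read_sumstats(path), "skipped")
  expect_equal(got$variant_id, "rs1")
})

test_that("shuffled column order with a matching map reads identically", {
  rec <- make_records(c("rs1", "rs2", "rs3"), beta = c(0.1, 0.2, -0.1),
                      se = c(0.01, 0.02, 0.03))
  p1 <- write_sumstats_tsv(rec)
  shuffled <- c(N = "n", P = "pvalue", SE = "se", BETA = "beta", EAF = "eaf",
                A2 = "other_allele", A1 = "effect_allele", BP = "pos",
                CHR = "chrom", SNP = "variant_id")
  p2 <- write_sumstats_tsv(rec, header = shuffled)
  a <- read_sumstats(p1)
  b <- read_sumstats(p2)
  attributes(a) <- attributes(a)[c("names", "class", "row.names")]
  attributes(b) <- attributes(b)[c("names", "class", "row.names")]
  expect_identical(a, b)
})

test_that("a missing mapped column is a configuration error", {
  rec <- make_records("rs1", beta = 0.1, se = 0.01)
  path <- write_sumstats_tsv(rec)
  bad_map <- default_column_map()
  bad_map[["se"]] <- "STDERR"
  expect_error(read_sumstats(path, bad_map), "STDERR")
})

test_that("harmonization pairs, flips, and excludes per the allele rules", {
  exposure <- make_records(c("rs1", "rs2", "rs3", "rs4"),
                           beta = c(0.10, 0.10, 0.10, 0.10),
                           se = rep(0.02, 4),
                           ea = c("A", "A", "A", "A"),
                           oa = c("G", "G", "T", "G"))
  outcome <- make_records(c("rs1", "rs2", "rs3", "rs5"),
                          beta = c(-0.05, -0.05, 0.02, 0.01),
                          se = rep(0.01, 4),
                          ea = c("A", "G", "A", "A"),
                          oa = c("G", "A", "T", "G"),
                          eaf = c(0.3, 0.3, 0.3, 0.3))
  h <- harmonize(exposure, outcome)
  # rs1: identical orientation, untouched
  expect_equal(h$beta_outcome[h$variant_id == "rs1"], -0.05)
  expect_equal(h$eaf_outcome[h$variant_id == "rs1"], 0.3)
  # rs2: swapped alleles force sign and frequency flip
  expect_equal(h$beta_outcome[h$variant_id == "rs2"], 0.05)
  expect_equal(h$eaf_outcome[h$variant_id == "rs2"], 0.7)
  ex <- attr(h, "exclusions")
  expect_equal(ex$reason[ex$variant_id == "rs3"], "palindromic")
  expect_equal(ex$reason[ex$variant_id == "rs4"], "missing_in_outcome")
})

test_that("incompatible allele sets are excluded with their reason", {
  exposure <- make_records("rs1", beta = 0.1, se = 0.02, ea = "A", oa = "G")
  outcome <- make_records(c("rs1", "rs9"), beta = c(0.1, 0.2),
                          se = c(0.02, 0.02), ea = c("A", "A"),
                          oa = c("C", "G"))
  # rs9 keeps the intersection non-empty is false: rs9 absent from exposure,
  # so only rs1 is shared and it is incompatible -> empty-set error
  expect_error(harmonize(exposure, outcome, "expA", "outB"),
               "expA.*outB|no harmonizable")
})

test_that("harmonization is idempotent on an already-harmonized pair", {
  exposure <- make_records(c("rs1", "rs2"), beta = c(0.1, -0.2),
                           se = c(0.02, 0.03), ea = "A", oa = "G")
  outcome <- make_records(c("rs1", "rs2"), beta = c(0.05, 0.07),
                          se = c(0.01, 0.01), ea = "A", oa = "G")
  h1 <- harmonize(exposure, outcome)
  # rebuild record sets from the harmonized pairs and harmonize again
  exposure2 <- make_records(h1$variant_id, beta = h1$beta_exposure,
                            se = h1$se_exposure, ea = "A", oa = "G",
                            eaf = h1$eaf_exposure)
  outcome2 <- make_records(h1$variant_id, beta = h1$beta_outcome,
                           se = h1$se_outcome, ea = "A", oa = "G",
                           eaf = h1$eaf_outcome)
  h2 <- harmonize(exposure2, outcome2)
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_equal(h2$beta_exposure, h1$beta_exposure)
  expect_equal(nrow(attr(h2, "exclusions")), 0)
})

test_that("flipping every outcome record leaves the harmonized pairs invariant", {
  set.seed(11)
  n <- 12
  exposure <- make_records(paste0("rs", 1:n), beta = rnorm(n, 0, 0.1),
                           se = runif(n, 0.005, 0.02), ea = "A", oa = "G")
  outcome <- make_records(paste0("rs", 1:n), beta = rnorm(n, 0, 0.05),
                          se = runif(n, 0.005, 0.02), ea = "A", oa = "G",
                          eaf = runif(n, 0.1, 0.9))
  flipped <- outcome
  flipped$effect_allele <- outcome$other_allele
  flipped$other_allele <- outcome$effect_allele
  flipped$beta <- -outcome$beta
  flipped$eaf <- 1 - outcome$eaf
  h1 <- harmonize(exposure, outcome)
  h2 <- harmonize(exposure, flipped)
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_equal(h2$eaf_outcome, h1$eaf_outcome)
})

test_that("pairs plus stage exclusions partition the exposure variants", {
  set.seed(4)
  n <- 20
  ea <- sample(c("A", "A", "A", "C"), n, replace = TRUE)
  oa <- ifelse(ea == "A", sample(c("G", "T"), n, replace = TRUE), "G")
  exposure <- make_records(paste0("rs", 1:n), beta = rnorm(n, 0, 0.1),
                           se = runif(n, 0.005, 0.02), ea = ea, oa = oa)
  keep_out <- sample(n, 15)
  outcome <- make_records(paste0("rs", keep_out), beta = rnorm(15, 0, 0.05),
                          se = runif(15, 0.005, 0.02), ea = ea[keep_out],
                          oa = oa[keep_out], pos = 10000L * keep_out)
  h <- harmonize(exposure, outcome)
  ex <- attr(h, "exclusions")
  expect_equal(nrow(h) + nrow(ex), n)
  expect_equal(sum(ex$reason == "missing_in_outcome"), n - 15)
})

test_that("palindromic rescue mode keeps frequency-concordant A/T pairs", {
  exposure <- make_records("rs1", beta = 0.1, se = 0.02, ea = "A", oa = "T",
                           eaf = 0.2)
  outcome <- make_records("rs1", beta = 0.04, se = 0.01, ea = "A", oa = "T",
                          eaf = 0.22)
  expect_error(harmonize(exposure, outcome), "no harmonizable")
  h <- harmonize(exposure, outcome, palindromic_rescue = TRUE)
  expect_equal(h$beta_outcome, 0.04)
  # discordant frequencies imply the strands differ: effect flips
  outcome$eaf <- 0.78
  h2 <- harmonize(exposure, outcome, palindromic_rescue = TRUE)
  expect_equal(h2$beta_outcome, -0.04)
})

test_that("harmonized sets round-trip through the TSV writer", {
  h <- make_hset(c(0.1, 0.2), c(0.01, 0.01), c(0.05, 0.04), c(0.02, 0.02))
  pairs <- tempfile(fileext = ".tsv")
  excl <- tempfile(fileext = ".tsv")
  write_harmonized_set(h, pairs, excl)
  got <- read.table(pairs, header = TRUE, sep = "\t")
  expect_equal(got$beta.exposure, h$beta_exposure)
  expect_true(file.exists(excl))
})
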