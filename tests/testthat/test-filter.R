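test_that("VAF is the alt fraction of site depth, exact to rounding", {
  expect_identical(computeVaf(10, 500), 0.02)
  expect_identical(computeVaf(0, 100), 0)
  expect_identical(computeVaf(35, 100), 0.35)
  expect_error(computeVaf(1, 0), "positive")
  expect_error(computeVaf(10, 5), "altDepth")
  set.seed(1)
  d <- sample(1:5000, 500, replace = TRUE)
  a <- vapply(d, function(x) sample(0:x, 1), integer(1))
  expect_true(all(abs(computeVaf(a, d) * d - a) <= 1e-9 * d))
})

test_that("homopolymer detection agrees with exhaustive run scanning", {
  expect_true(hasHomopolymer("TGAAAA", "CGTACG"))
  expect_false(hasHomopolymer("ACGTAC", "GTACGT"))
  expect_error(hasHomopolymer("ACG", "GTACGT"), "at least 6")
  # N never extends a run
  expect_false(hasHomopolymer("AANAAN", "CGTACG"))
  # all 4^6 possible upstream windows vs. the brute-force oracle
  combos <- expand.grid(rep(list(c("A", "C", "G", "T")), 6),
                        stringsAsFactors = FALSE)
  ups <- apply(combos, 1, paste, collapse = "")
  got <- hasHomopolymer(ups, rep("ACGTAC", length(ups)))
  want <- vapply(ups, function(u) bruteWindowRun(u, 6, TRUE) >= 4,
                 logical(1), USE.NAMES = FALSE)
  expect_identical(got, want)
  # only the window adjacent to the variant counts
  expect_false(hasHomopolymer("AAAAGC", "ACGTAC", window = 4))
  expect_true(hasHomopolymer("GCAAAA", "ACGTAC", window = 4))
})

test_that("population filter applies strict bounds with COSMIC relaxation", {
  cfg <- chipFilterConfig("panel")
  expect_false(passesPopulationFilter(2e-5, 0, cfg))
  expect_true(passesPopulationFilter(5e-4, 12, cfg))
  expect_true(passesPopulationFilter(0, 0, cfg))
  # bounds are strict
  expect_false(passesPopulationFilter(1e-5, 0, cfg))
  expect_false(passesPopulationFilter(1e-3, 12, cfg))
  expect_true(passesPopulationFilter(9.9e-6, 0, cfg))
})

test_that("cohort recurrence is a strict fraction over processed samples", {
  expect_false(cohortRecurrencePass(5, 100))
  expect_true(cohortRecurrencePass(4, 100))
  expect_false(cohortRecurrencePass(1, 1))
  expect_error(cohortRecurrencePass(1, 0), ">= 1")
})

test_that("protein-altering check includes exonic splicing and fails closed", {
  expect_true(isProteinAltering("missense"))
  expect_false(isProteinAltering("synonymous"))
  expect_true(isProteinAltering("splice_region_exonic"))
  expect_false(isProteinAltering("splice_region_intronic"))
  expect_warning(got <- isProteinAltering("mystery_term"), "failed closed")
  expect_false(got)
})

test_that("each cascade criterion fails exactly the record built to fail it", {
  recs <- rbind(
    makeRecord(pos = 1L),                                   # passes all
    makeRecord(pos = 2L, alt_depth = 11L, alt_fwd = 6L,
               alt_rev = 5L),                               # VAF 0.018
    makeRecord(pos = 3L, total_depth = 500L, alt_depth = 50L,
               alt_fwd = 25L, alt_rev = 25L),               # depth not >500
    makeRecord(pos = 4L, alt_fwd = 57L, alt_rev = 3L),      # strand bias
    makeRecord(pos = 5L, gnomad_af = 2e-5),                 # population
    makeRecord(pos = 6L, context_up = "ACTTTTGA"),          # homopolymer
    makeRecord(pos = 7L, consequence = "synonymous"))       # not altering
  cs <- suppressMessages(applyFilterCascade(recs, chipFilterConfig("panel"),
                                            nSamples = 100))
  calls <- chipCalls(cs)
  expect_identical(calls$passed, c(TRUE, rep(FALSE, 6)))
  flags <- paste0("flag_", criterionNames())
  failedPer <- lapply(2:7, function(i)
    criterionNames()[!unlist(calls[i, flags])])
  expect_identical(failedPer,
                   list("vaf_range", "depth", "strand_pairs", "population",
                        "homopolymer", "protein_altering"))
  # the recurrence criterion needs the whole run: the same variant carried
  # by 6 of 100 samples fails, by 4 of 100 passes
  recur <- do.call(rbind, lapply(1:6, function(i)
    makeRecord(pos = 50L, sample_id = sprintf("R%02d", i))))
  rare <- do.call(rbind, lapply(1:4, function(i)
    makeRecord(pos = 60L, sample_id = sprintf("R%02d", i))))
  calls2 <- chipCalls(suppressMessages(applyFilterCascade(
    rbind(recur, rare), chipFilterConfig("panel"), nSamples = 100)))
  expect_identical(calls2$flag_cohort_recurrence, rep(c(FALSE, TRUE), c(6, 4)))
})

test_that("VAF window endpoints are inclusive; depth bound is strict", {
  recs <- rbind(
    makeRecord(pos = 1L, alt_depth = 12L, alt_fwd = 6L, alt_rev = 6L),
    makeRecord(pos = 2L, alt_depth = 210L, alt_fwd = 105L,
               alt_rev = 105L),
    makeRecord(pos = 3L, total_depth = 501L, alt_depth = 50L,
               alt_fwd = 25L, alt_rev = 25L))
  cs <- suppressMessages(applyFilterCascade(recs, chipFilterConfig("panel"),
                                            nSamples = 100))
  calls <- chipCalls(cs)
  expect_identical(calls$vaf[1:2], c(0.02, 0.35))
  expect_true(all(calls$flag_vaf_range))
  expect_true(calls$flag_depth[3])
})

test_that("WES mode relaxes the depth and strand thresholds", {
  rec <- makeRecord(total_depth = 80L, alt_depth = 8L, alt_fwd = 4L,
                    alt_rev = 4L)
  panel <- chipCalls(suppressMessages(
    applyFilterCascade(rec, chipFilterConfig("panel"), 100)))
  wes <- chipCalls(suppressMessages(
    applyFilterCascade(rec, chipFilterConfig("wes"), 100)))
  expect_false(panel$passed)
  expect_true(wes$passed)
})

test_that("cascade flags equal independent per-criterion oracles on a batch", {
  sim <- suppressMessages(simulateCohort(cohortSimConfig(nSamples = 30,
                                                         seed = 9)))
  recs <- sim$variants
  cs <- suppressMessages(applyFilterCascade(recs, chipFilterConfig("panel"),
                                            nSamples = 30))
  calls <- chipCalls(cs)
  want <- oracleFlags(recs, 30)
  for (f in names(want)) expect_identical(calls[[f]], want[[f]], info = f)
})

test_that("the cascade is order-independent and never short-circuits", {
  sim <- suppressMessages(simulateCohort(cohortSimConfig(nSamples = 20,
                                                         seed = 4)))
  recs <- sim$variants
  perm <- sample(nrow(recs))
  a <- chipCalls(suppressMessages(
    applyFilterCascade(recs, chipFilterConfig("panel"), 20)))
  b <- chipCalls(suppressMessages(
    applyFilterCascade(recs[perm, ], chipFilterConfig("panel"), 20)))
  rownames(b) <- NULL
  expect_equal(b, {x <- a[perm, ]; rownames(x) <- NULL; x})
  # every flag is populated even for records failing an earlier criterion
  expect_false(anyNA(a[paste0("flag_", criterionNames())]))
})

test_that("loosening any single threshold never shrinks the passing set", {
  sim <- suppressMessages(simulateCohort(cohortSimConfig(nSamples = 40,
                                                         seed = 8)))
  recs <- sim$variants
  base <- chipFilterConfig("panel")
  passSet <- function(cfg) {
    calls <- chipCalls(suppressMessages(
      applyFilterCascade(recs, cfg, 40)))
    which(calls$passed)
  }
  p0 <- passSet(base)
  looser <- list(
    chipFilterConfig("panel", vafMin = 0.01),
    chipFilterConfig("panel", vafMax = 0.5),
    chipFilterConfig("panel", minDepth = 400),
    chipFilterConfig("panel", minStrandPairs = 2),
    chipFilterConfig("panel", gnomadMax = 1e-4),
    chipFilterConfig("panel", cohortRecurrenceMax = 0.2),
    chipFilterConfig("panel", homopolymerMinRun = 6))
  for (cfg in looser) expect_true(all(p0 %in% passSet(cfg)))
})

test_that("duplicate sample/variant records collapse to the deepest one", {
  recs <- rbind(makeRecord(alt_depth = 50L, alt_fwd = 25L, alt_rev = 25L),
                makeRecord(alt_depth = 70L, alt_fwd = 35L, alt_rev = 35L),
                makeRecord(pos = 2000L))
  cs <- suppressMessages(applyFilterCascade(recs, chipFilterConfig("panel"),
                                            100))
  calls <- chipCalls(cs)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$alt_depth[calls$pos == 1000L], 70L)
})

test_that("classification separates recurrent drivers from other passers", {
  cat <- readDriverCatalog()
  expect_identical(classifyCall("DNMT3A", "p.Arg882His", cat), "CHIP_PD")
  # recurrence of exactly 10 is not 'more than 10'
  expect_identical(classifyCall("KRAS", "p.Gly12Asp", cat), "CHIP")
  expect_identical(classifyCall("NOVEL1", "p.Ala5Gly", cat), "CHIP")
  expect_error(classifyCall("DNMT3A", "p.Arg882His", cat, passed = FALSE),
               "passing")
  cs <- suppressMessages(applyFilterCascade(
    rbind(makeRecord(hgvs_p = "p.Arg882His"),
          makeRecord(pos = 2000L, gene = "TET2", hgvs_p = "p.Gln910Ter",
                     consequence = "stop_gained"),
          makeRecord(pos = 3000L, gnomad_af = 0.5)),
    chipFilterConfig("panel"), 100))
  cs <- classifyChip(cs, cat)
  calls <- chipCalls(cs)
  expect_identical(calls$classification, c("CHIP_PD", "CHIP", "none"))
  expect_identical(calls$needs_review, calls$passed)
})
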