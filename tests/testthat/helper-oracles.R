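# Independent oracles and fixture builders, deliberately written as plain
# brute-force code so they share nothing with the implementation paths.

# AUC by exhaustive pair counting: wins + half ties over all cross pairs
bruteAuc <- function(x, y) {
  wins <- 0
  ties <- 0
  for (xi in x) for (yi in y) {
    if (xi > yi) wins <- wins + 1 else if (xi == yi) ties <- ties + 1
  }
  (wins + 0.5 * ties) / (length(x) * length(y))
}

# longest identical-base run (ACGT only) in the examined window of a context
bruteWindowRun <- function(context, window, fromEnd) {
  chars <- strsplit(context, "")[[1]]
  n <- length(chars)
  win <- if (fromEnd) chars[(n - window + 1):n] else chars[1:window]
  best <- 0
  run <- 0
  prev <- ""
  for (ch in win) {
    if (ch %in% c("A", "C", "G", "T") && ch == prev) run <- run + 1
    else if (ch %in% c("A", "C", "G", "T")) run <- 1
    else run <- 0
    prev <- if (ch %in% c("A", "C", "G", "T")) ch else ""
    best <- max(best, run)
  }
  best
}

# Poisson-binomial pmf by exhaustive enumeration over all 2^n outcomes
brutePoissonBinomial <- function(probs) {
  n <- length(probs)
  pmf <- numeric(n + 1)
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    pr <- prod(ifelse(bits == 1, probs, 1 - probs))
    pmf[sum(bits) + 1] <- pmf[sum(bits) + 1] + pr
  }
  pmf
}

# exclusive detection by exhaustive enumeration over both groups
bruteExclusiveDetection <- function(pa, pb) {
  pmfA <- brutePoissonBinomial(pa)
  pmfB <- brutePoissonBinomial(pb)
  (1 - pmfA[1]) * pmfB[1] + pmfA[1] * (1 - pmfB[1])
}

# two-sided exact 2x2 p by direct enumeration with the minimum-likelihood
# rule, using factorials only
brute2x2P <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- a + b + c + d
  tabProb <- function(k) {
    exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(N, c1))
  }
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(ks, tabProb, numeric(1))
  pObs <- tabProb(a)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# a variant record passing every panel criterion, fields overridable
makeRecord <- function(..., pos = 1000L) {
  rec <- data.frame(
    chrom = "chr1", pos = as.integer(pos), ref = "A", alt = "T",
    sample_id = "S1", total_depth = 600L, alt_depth = 60L,
    alt_fwd = 30L, alt_rev = 30L, gene = "DNMT3A",
    consequence = "missense", hgvs_p = "p.Ala100Thr",
    gnomad_af = 0, cosmic_count = 0L,
    context_up = "ACGTACGT", context_down = "GTCAGTCA",
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

# bind several records with distinct positions/samples
makeRecords <- function(n, sample_ids = "S1") {
  do.call(rbind, lapply(seq_len(n), function(i)
    makeRecord(pos = 1000L + i,
               sample_id = rep(sample_ids, length.out = n)[i])))
}

# plain-text single-sample VCF fixture written in code
writeTextVcf <- function(path, bodyLines,
                         formats = c("DP", "AD", "ADF", "ADR"),
                         sample = "S1") {
  fmtMeta <- vapply(formats, function(f) sprintf(
    "##FORMAT=<ID=%s,Number=%s,Type=Integer,Description=\"x\">",
    f, if (f == "DP") "1" else "R"), character(1))
  infoMeta <- vapply(
    c("GENE", "CSQT", "HGVSP", "CTXU", "CTXD"),
    function(f) sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"x\">", f),
    character(1))
  infoMeta <- c(infoMeta,
    "##INFO=<ID=GNOMAD_AF,Number=1,Type=Float,Description=\"x\">",
    "##INFO=<ID=COSMIC_CNT,Number=1,Type=Integer,Description=\"x\">")
  writeLines(c("##fileformat=VCFv4.2", fmtMeta, infoMeta,
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", sample),
                     collapse = "\t"),
               bodyLines), path)
  path
}

# recompute all seven criterion flags for a record batch with plain code,
# independently of the cascade
oracleFlags <- function(records, nSamples,
                        minDepth = 500, minPairs = 4) {
  key <- paste(records$chrom, records$pos, records$ref, records$alt)
  carriers <- vapply(key, function(k)
    length(unique(records$sample_id[key == k])), integer(1))
  vaf <- records$alt_depth / records$total_depth
  hp <- mapply(function(u, d)
    bruteWindowRun(u, 6, TRUE) >= 4 || bruteWindowRun(d, 6, FALSE) >= 4,
    records$context_up, records$context_down)
  altering <- c("missense", "stop_gained", "stop_lost", "start_lost",
                "frameshift", "inframe_insertion", "inframe_deletion",
                "splice_region_exonic")
  data.frame(
    flag_vaf_range = vaf >= 0.02 & vaf <= 0.35,
    flag_depth = records$total_depth > minDepth,
    flag_strand_pairs = records$alt_fwd >= minPairs &
      records$alt_rev >= minPairs,
    flag_population = records$gnomad_af < 1e-5 |
      (records$cosmic_count > 0 & records$gnomad_af < 1e-3),
    flag_cohort_recurrence = carriers / nSamples < 0.05,
    flag_homopolymer = !hp,
    flag_protein_altering = records$consequence %in% altering,
    row.names = NULL)
}

# recovery harness used by the filter tests and the acceptance suite:
# clone VAFs in [0.03, 0.30] at constant 600x depth
recoveryConfig <- function(nSamples = 300, seed = 11) {
  cohortSimConfig(nSamples = nSamples, vafRange = c(0.03, 0.30),
                  depthMean = 600, depthSize = Inf, seed = seed)
}

matchTruth <- function(sim, calls) {
  key <- paste(calls$sample_id, calls$chrom, calls$pos, calls$ref,
               calls$alt, sep = ":")
  match(paste(sim$truth$sample_id, sim$truth$key, sep = ":"), key)
}
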