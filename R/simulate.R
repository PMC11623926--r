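#' Default relative clone frequencies per CHIP gene
#'
#' DNMT3A, TET2 and PPM1D dominate, as in typical blood cohorts; the
#' frequencies sum to 1.
#'
#' @return Named numeric vector.
#' @export
defaultGeneFreq <- function() {
  c(DNMT3A = 0.30, TET2 = 0.15, PPM1D = 0.15, ASXL1 = 0.08, TP53 = 0.07,
    JAK2 = 0.05, SF3B1 = 0.05, SRSF2 = 0.05, GNB1 = 0.04, CBL = 0.03,
    KRAS = 0.03)
}

#' Configuration of the synthetic cohort generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' an age-dependent CHIP incidence (logistic in age, defaults tuned so the
#' simulated prevalence at the cohort mean age of 64 is about 44%),
#' gene-specific clone frequencies, log-normal clone VAFs truncated to the
#' calling window, binomial read sampling at panel (~600x) or WES (~80x)
#' site depths, and four planted artifact classes each carrying the
#' signature that trips exactly one filter criterion: `homopolymer`
#' (homopolymer context), `high_gnomad` (gnomAD frequency 10x the
#' threshold, no COSMIC membership), `recurrent` (the identical variant
#' planted in a fixed fraction of samples above the recurrence bound) and
#' `germline` (true VAF near 0.5, caught by the VAF ceiling). A fifth
#' class, `strand_bias` (strand split Binomial(alt, 0.95)), is available
#' but off by default.
#'
#' @param nSamples Number of samples.
#' @param mode `"panel"` or `"wes"`; sets the depth model default.
#' @param ageMean,ageSd Cohort age distribution (defaults 64 and 8 years).
#' @param incidenceIntercept,incidenceSlope Logistic age-incidence curve
#'   `P(CHIP | age) = plogis(intercept + slope * age)`.
#' @param geneFreq Named clone-frequency vector summing to 1.
#' @param vafMeanlog,vafSdlog Log-normal true-VAF parameters.
#' @param vafRange Truncation window for true clone VAFs.
#' @param depthMean Mean site depth (default 600 panel, 80 WES).
#' @param depthSize Negative-binomial size of the depth model; `Inf` for
#'   constant depth.
#' @param cloneLambda Poisson mean for extra clones per positive sample
#'   (clone count is `1 + Poisson(cloneLambda)`, truncated at 4).
#' @param hotspotFrac Fraction of DNMT3A clones placed at the p.Arg882His
#'   hotspot (default 0.10).
#' @param artifactRates Named rates: `homopolymer`, `high_gnomad` and
#'   `germline` are Poisson means per sample; `recurrent` is the fraction
#'   of samples carrying the shared artifact variant; `strand_bias` a
#'   Poisson mean (default 0).
#' @param seed Integer seed; the generator is a pure function of
#'   (config, seed).
#' @return A list of class `CohortSimConfig`.
#' @export
cohortSimConfig <- function(nSamples = 100, mode = c("panel", "wes"),
                            ageMean = 64, ageSd = 8,
                            incidenceIntercept = -5.36,
                            incidenceSlope = 0.08,
                            geneFreq = defaultGeneFreq(),
                            vafMeanlog = log(0.08), vafSdlog = 0.7,
                            vafRange = c(0.02, 0.35),
                            depthMean = NULL, depthSize = 80,
                            cloneLambda = 0.4, hotspotFrac = 0.10,
                            artifactRates = c(homopolymer = 0.4,
                                              high_gnomad = 0.4,
                                              recurrent = 0.08,
                                              germline = 0.3,
                                              strand_bias = 0),
                            seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(depthMean)) depthMean <- if (mode == "panel") 600 else 80
  if (abs(sum(geneFreq) - 1) > 1e-8)
    .stopf("invalid geneFreq: frequencies must sum to 1")
  if (any(artifactRates < 0) || artifactRates[["recurrent"]] > 1)
    .stopf("invalid artifactRates: rates must be non-negative, recurrent in [0,1]")
  if (!(vafRange[1] >= 0 && vafRange[1] < vafRange[2] && vafRange[2] <= 1))
    .stopf("invalid vafRange")
  if (nSamples < 1) .stopf("invalid nSamples")
  structure(list(nSamples = as.integer(nSamples), mode = mode,
                 ageMean = ageMean, ageSd = ageSd,
                 incidenceIntercept = incidenceIntercept,
                 incidenceSlope = incidenceSlope, geneFreq = geneFreq,
                 vafMeanlog = vafMeanlog, vafSdlog = vafSdlog,
                 vafRange = vafRange, depthMean = depthMean,
                 depthSize = depthSize, cloneLambda = cloneLambda,
                 hotspotFrac = hotspotFrac, artifactRates = artifactRates,
                 seed = as.integer(seed)),
            class = "CohortSimConfig")
}

#' Binomial read sampling for one variant site
#'
#' Alt-supporting depth is Binomial(depth, vaf); the strand split of the
#' alt reads is Binomial(altDepth, strandProb). Sequencing error and
#' mapping bias are deliberately not modelled: the filter-cascade tests
#' need controlled signatures. Uses the current RNG state; seed upstream.
#'
#' @param trueVaf True variant allele fraction in `[0, 1]`.
#' @param depth Site depth (>= 1).
#' @param strandProb Forward-strand probability (0.5 for unbiased reads).
#' @return List with `alt_depth`, `alt_fwd`, `alt_rev`.
#' @export
simulateReads <- function(trueVaf, depth, strandProb = 0.5) {
  stopifnot(trueVaf >= 0, trueVaf <= 1, depth >= 1)
  altDepth <- stats::rbinom(1, depth, trueVaf)
  altFwd <- stats::rbinom(1, altDepth, strandProb)
  list(alt_depth = altDepth, alt_fwd = altFwd, alt_rev = altDepth - altFwd)
}

.BASES <- c("A", "C", "G", "T")

# random flanking context of given length with no homopolymer run >= minRun
.cleanContext <- function(len, minRun) {
  repeat {
    s <- paste(sample(.BASES, len, replace = TRUE), collapse = "")
    r <- rle(strsplit(s, "")[[1]])
    if (max(r$lengths) < minRun) return(s)
  }
}

# context carrying a planted homopolymer run inside the examined window:
# adjacent to the variant, i.e. at the end of the upstream context or the
# start of the downstream context
.homopolymerContext <- function(len, run = 5, atStart = FALSE) {
  base <- sample(.BASES, 1)
  rest <- sample(setdiff(.BASES, base), len - run, replace = TRUE)
  parts <- if (atStart) c(rep(base, run), rest) else c(rest, rep(base, run))
  paste(parts, collapse = "")
}

.drawDepth <- function(n, cfg) {
  if (is.infinite(cfg$depthSize)) rep(as.integer(cfg$depthMean), n)
  else pmax(1L, stats::rnbinom(n, mu = cfg$depthMean, size = cfg$depthSize))
}

.drawTrueVaf <- function(n, cfg) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rlnorm(1, cfg$vafMeanlog, cfg$vafSdlog)
      if (v >= cfg$vafRange[1] && v <= cfg$vafRange[2]) break
    }
    out[i] <- v
  }
  out
}

.randomAa <- function(n) {
  aa <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
          "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
          "Tyr", "Val")
  paste0("p.", sample(aa, n, TRUE), sample(100:900, n, TRUE),
         sample(aa, n, TRUE))
}

.newVariantRow <- function(sampleId, gene, trueVaf, cfg, consequence,
                           hgvsP, gnomadAf = 0, cosmicCount = 0L,
                           contextUp = NULL, contextDown = NULL,
                           strandProb = 0.5, chrom = NULL, pos = NULL,
                           ref = NULL, alt = NULL) {
  depth <- .drawDepth(1, cfg)
  reads <- simulateReads(trueVaf, depth, strandProb)
  minRun <- 4
  if (is.null(contextUp)) contextUp <- .cleanContext(8, minRun)
  if (is.null(contextDown)) contextDown <- .cleanContext(8, minRun)
  if (is.null(chrom)) chrom <- paste0("chr", sample(1:22, 1))
  if (is.null(pos)) pos <- sample.int(2e8, 1)
  if (is.null(ref)) ref <- sample(.BASES, 1)
  if (is.null(alt)) alt <- sample(setdiff(.BASES, ref), 1)
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             sample_id = sampleId, total_depth = depth,
             alt_depth = reads$alt_depth, alt_fwd = reads$alt_fwd,
             alt_rev = reads$alt_rev, gene = gene,
             consequence = consequence, hgvs_p = hgvsP,
             gnomad_af = gnomadAf, cosmic_count = cosmicCount,
             context_up = contextUp, context_down = contextDown,
             stringsAsFactors = FALSE)
}

#' Simulate an annotated-variant cohort with ground truth
#'
#' Ages are drawn from the configured normal distribution; CHIP carriage by
#' the logistic age-incidence curve; clone genes by the clone-frequency
#' table (a configurable fraction of DNMT3A clones at the p.Arg882His
#' hotspot); clone VAFs log-normal truncated to the configured window;
#' reads by binomial sampling at the configured depth model. Artifacts are
#' planted per class with the signature that trips exactly one filter
#' criterion (see [cohortSimConfig()]). Every emitted record has exactly
#' one truth row. The output is a pure function of the config (which
#' carries the seed).
#'
#' @param cfg A config from [cohortSimConfig()].
#' @return List of class `chipCohortSim`: `variants` (records as in
#'   [readVariantVcf()]), `samples` (cohort table), `truth` (per record:
#'   `sample_id`, `key`, `class`, `true_vaf`) and `config`.
#' @export
simulateCohort <- function(cfg = cohortSimConfig()) {
  stopifnot(inherits(cfg, "CohortSimConfig"))
  set.seed(cfg$seed)
  n <- cfg$nSamples
  ids <- sprintf("S%04d", seq_len(n))
  age <- round(pmax(30, stats::rnorm(n, cfg$ageMean, cfg$ageSd)))
  samples <- data.frame(
    sample_id = ids, age = age,
    sex = sample(c("male", "female"), n, TRUE, prob = c(0.9, 0.1)),
    pathology = sample(c("LUAD", "LUSC", "other"), n, TRUE,
                       prob = c(0.50, 0.43, 0.07)),
    smoking = sample(c("never", "ever", "current"), n, TRUE,
                     prob = c(0.09, 0.54, 0.37)),
    timepoint = "pre",
    response = sample(c("responder", "non-responder", "unknown"), n, TRUE,
                      prob = c(0.35, 0.55, 0.10)),
    stringsAsFactors = FALSE)

  hasChip <- stats::rbinom(n, 1, stats::plogis(
    cfg$incidenceIntercept + cfg$incidenceSlope * age)) == 1

  rows <- list(); truth <- list(); k <- 0L
  addRow <- function(row, class, trueVaf) {
    k <<- k + 1L
    rows[[k]] <<- row
    truth[[k]] <<- data.frame(
      sample_id = row$sample_id,
      key = .variantKey(row$chrom, row$pos, row$ref, row$alt),
      class = class, true_vaf = trueVaf, stringsAsFactors = FALSE)
  }

  consTerms <- c("missense", "stop_gained", "frameshift")
  consProb <- c(0.7, 0.2, 0.1)
  for (i in seq_len(n)) {
    if (!hasChip[i]) next
    nClones <- min(1L + stats::rpois(1, cfg$cloneLambda), 4L)
    genes <- sample(names(cfg$geneFreq), nClones, TRUE, prob = cfg$geneFreq)
    vafs <- .drawTrueVaf(nClones, cfg)
    for (ci in seq_len(nClones)) {
      hotspot <- genes[ci] == "DNMT3A" &&
        stats::runif(1) < cfg$hotspotFrac
      row <- .newVariantRow(
        ids[i], genes[ci], vafs[ci], cfg,
        consequence = if (hotspot) "missense"
                      else sample(consTerms, 1, prob = consProb),
        hgvsP = if (hotspot) "p.Arg882His" else .randomAa(1),
        cosmicCount = if (hotspot) 500L else sample(c(0L, 3L, 25L), 1,
                                                    prob = c(0.5, 0.3, 0.2)))
      addRow(row, "true_chip", vafs[ci])
    }
  }

  rates <- cfg$artifactRates
  # homopolymer-context artifacts: clean otherwise, planted run trips the flag
  for (i in seq_len(n)) {
    for (j in seq_len(stats::rpois(1, rates[["homopolymer"]]))) {
      v <- .drawTrueVaf(1, cfg)
      side <- sample(c("up", "down"), 1)
      row <- .newVariantRow(
        ids[i], "HPART", v, cfg, "missense", .randomAa(1),
        contextUp = if (side == "up") .homopolymerContext(8) else NULL,
        contextDown = if (side == "down") .homopolymerContext(8, atStart = TRUE)
                      else NULL)
      addRow(row, "artifact:homopolymer", v)
    }
    # germline leakage: true VAF near 0.5, caught by the VAF ceiling
    for (j in seq_len(stats::rpois(1, rates[["germline"]]))) {
      v <- stats::runif(1, 0.45, 0.55)
      addRow(.newVariantRow(ids[i], "GLART", v, cfg, "missense",
                            .randomAa(1)), "germline", v)
    }
    # common germline polymorphism leaking through: gnomAD 10x threshold
    for (j in seq_len(stats::rpois(1, rates[["high_gnomad"]]))) {
      v <- .drawTrueVaf(1, cfg)
      addRow(.newVariantRow(ids[i], "GNART", v, cfg, "missense",
                            .randomAa(1), gnomadAf = 1e-4),
             "artifact:high_gnomad", v)
    }
    for (j in seq_len(stats::rpois(1, rates[["strand_bias"]]))) {
      v <- .drawTrueVaf(1, cfg)
      addRow(.newVariantRow(ids[i], "SBART", v, cfg, "missense",
                            .randomAa(1), strandProb = 0.95),
             "artifact:strand_bias", v)
    }
  }
  # recurrent panel noise: one fixed variant in a fixed fraction of samples
  if (rates[["recurrent"]] > 0) {
    nCarry <- max(1L, round(rates[["recurrent"]] * n))
    carriers <- sample(ids, nCarry)
    for (sid in carriers) {
      v <- .drawTrueVaf(1, cfg)
      addRow(.newVariantRow(sid, "RCART", v, cfg, "missense",
                            "p.Gly12Asp", chrom = "chr7", pos = 55242464L,
                            ref = "C", alt = "T"),
             "artifact:recurrent", v)
    }
  }

  variants <- if (k) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(nrow = 0, ncol = length(.recordColumns))),
                    .recordColumns)
  rownames(variants) <- NULL
  truthDf <- if (k) do.call(rbind, truth) else
    data.frame(sample_id = character(), key = character(),
               class = character(), true_vaf = numeric())
  rownames(truthDf) <- NULL
  .chLog("simulated cohort: ", n, " samples, ", sum(hasChip),
         " CHIP-positive, ", nrow(variants), " variant records")
  structure(list(variants = variants, samples = samples, truth = truthDf,
                 config = cfg), class = "chipCohortSim")
}

#' @export
print.chipCohortSim <- function(x, ...) {
  cat("Synthetic CHIP cohort:", nrow(x$samples), "samples,",
      nrow(x$variants), "variant records\n")
  print(table(x$truth$class))
  invisible(x)
}

#' Write per-sample VCFs and the cohort/truth tables of a simulated cohort
#'
#' Emits one VCF per sample (FILTER `.`; the cascade has not run), plus
#' `cohort.tsv` and `truth.tsv`, in the formats the pipeline reads.
#'
#' @param sim Output of [simulateCohort()].
#' @param dir Output directory (created if needed).
#' @param keys Key mapping from [vcfFieldKeys()].
#' @return Character vector of the VCF paths, invisibly non-VCF outputs
#'   alongside.
#' @export
writeCohortVcfs <- function(sim, dir, keys = vcfFieldKeys()) {
  stopifnot(inherits(sim, "chipCohortSim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (sid in sim$samples$sample_id) {
    recs <- sim$variants[sim$variants$sample_id == sid, , drop = FALSE]
    if (!nrow(recs)) next
    p <- file.path(dir, paste0(sid, ".vcf.gz"))
    .writeRecordsVcf(recs, rep(".", nrow(recs)), rep("none", nrow(recs)),
                     p, keys)
    paths <- c(paths, p)
  }
  utils::write.table(sim$samples, file.path(dir, "cohort.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .chLog("wrote ", length(paths), " per-sample VCFs to ", dir)
  invisible(paths)
}

#' Simulate a cell-by-gene count matrix with a planted pathway effect
#'
#' Counts are negative binomial with log-normal gene-level means and a
#' small log-normal cluster effect. In the designated target (myeloid-like)
#' cluster, cells of the high-burden group have the planted-set means
#' multiplied by `effectMultiplier`; all other clusters are unaffected, so
#' a null comparison is available in any non-target cluster (and everywhere
#' when `effectMultiplier = 1`).
#'
#' @param nCellsPerCluster Cells per (cluster, group) combination.
#' @param clusters Cluster labels; the first is the target unless
#'   `targetCluster` is given.
#' @param nGenes Gene universe size (genes named `gene1..geneN`).
#' @param plantedSet Genes carrying the effect; must be in the universe.
#' @param effectMultiplier Mean multiplier in the target cluster's
#'   high-burden cells (>= 1; 1 gives the null scenario).
#' @param groups Group labels (first = affected group).
#' @param nSamplesPerGroup Samples per group; cells are split evenly.
#' @param targetCluster Cluster receiving the effect.
#' @param dispersion Negative-binomial size parameter.
#' @param seed Integer seed.
#' @return A [SingleCellExperiment::SingleCellExperiment] with a `counts`
#'   assay and colData columns `cluster`, `sample`, `group`.
#' @export
simulateExpression <- function(nCellsPerCluster = 400,
                               clusters = c("myeloid", "tcell", "nk"),
                               nGenes = 600,
                               plantedSet = paste0("gene", 1:30),
                               effectMultiplier = 3,
                               groups = c("high_burden", "negative"),
                               nSamplesPerGroup = 4,
                               targetCluster = clusters[1],
                               dispersion = 2, seed = 1L) {
  genes <- paste0("gene", seq_len(nGenes))
  if (!all(plantedSet %in% genes))
    .stopf("planted genes outside the gene universe: %s",
           paste(setdiff(plantedSet, genes), collapse = ", "))
  if (effectMultiplier < 1) .stopf("effectMultiplier must be >= 1")
  set.seed(seed)
  geneMean <- stats::rlnorm(nGenes, meanlog = log(0.8), sdlog = 1)
  clusterFold <- matrix(stats::rlnorm(nGenes * length(clusters), 0, 0.2),
                        nGenes, length(clusters),
                        dimnames = list(genes, clusters))
  sampleIds <- paste0(rep(groups, each = nSamplesPerGroup), "_",
                      rep(seq_len(nSamplesPerGroup), length(groups)))
  sampleGroup <- rep(groups, each = nSamplesPerGroup)

  nCellsTotal <- nCellsPerCluster * length(clusters) * length(groups)
  counts <- matrix(0L, nGenes, nCellsTotal, dimnames = list(genes, NULL))
  meta <- data.frame(cluster = character(nCellsTotal),
                     sample = character(nCellsTotal),
                     group = character(nCellsTotal),
                     stringsAsFactors = FALSE)
  planted <- genes %in% plantedSet
  col <- 0L
  for (cl in clusters) {
    for (gi in seq_along(groups)) {
      mu <- geneMean * clusterFold[, cl]
      if (cl == targetCluster && gi == 1L)
        mu[planted] <- mu[planted] * effectMultiplier
      cellSamples <- sample(sampleIds[sampleGroup == groups[gi]],
                            nCellsPerCluster, TRUE)
      for (ci in seq_len(nCellsPerCluster)) {
        col <- col + 1L
        counts[, col] <- stats::rnbinom(nGenes, mu = mu, size = dispersion)
        meta$cluster[col] <- cl
        meta$sample[col] <- cellSamples[ci]
        meta$group[col] <- groups[gi]
      }
    }
  }
  colnames(counts) <- sprintf("cell%05d", seq_len(nCellsTotal))
  rownames(meta) <- colnames(counts)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(meta))
}
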