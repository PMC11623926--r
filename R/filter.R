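#' Variant allele frequency
#'
#' VAF is the fraction of reads at the site supporting the alternate
#' allele, `alt_depth / total_depth`; the 2-35% calling window presupposes
#' this definition.
#'
#' @param altDepth,totalDepth Non-negative integer read counts,
#'   `altDepth <= totalDepth`, `totalDepth > 0`. Vectorised.
#' @return Numeric fraction(s) in `[0, 1]`.
#' @examples
#' computeVaf(10, 500)  # 0.02, the lower calling bound
#' @export
computeVaf <- function(altDepth, totalDepth) {
  if (any(totalDepth <= 0)) .stopf("totalDepth must be positive")
  if (any(altDepth < 0) || any(altDepth > totalDepth))
    .stopf("need 0 <= altDepth <= totalDepth")
  altDepth / totalDepth
}

.maxRun <- function(s, window, fromEnd) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  win <- if (fromEnd) chars[seq.int(n - window + 1L, n)] else chars[seq_len(window)]
  win[!win %in% c("A", "C", "G", "T")] <- NA  # N never extends a run
  r <- rle(win)
  runs <- r$lengths[!is.na(r$values)]
  if (length(runs)) max(runs) else 0L
}

#' Homopolymer signature in the reference context of a variant
#'
#' Sequencing artifacts concentrate next to runs of identical bases; a
#' candidate variant is flagged when a run of at least `minRun` identical
#' bases (A/C/G/T only; N breaks a run) occurs within the `window` bases
#' immediately adjacent to the variant on either side. The run length
#' defining a homopolymer is conventional rather than fixed by the filter
#' description; 4 is the default and is configurable.
#'
#' @param contextUp Reference bases immediately 5' of the variant (the last
#'   `window` bases are examined). Vectorised.
#' @param contextDown Reference bases immediately 3' (the first `window`
#'   bases are examined).
#' @param window Bases examined on each side (default 6).
#' @param minRun Minimum identical-base run length (default 4).
#' @return Logical vector: `TRUE` when a homopolymer signature is present.
#' @examples
#' hasHomopolymer("TGAAAA", "CGTACG")  # TRUE: run of 4 A's upstream
#' hasHomopolymer("ACGTAC", "GTACGT")  # FALSE
#' @export
hasHomopolymer <- function(contextUp, contextDown, window = 6, minRun = 4) {
  if (any(nchar(contextUp) < window) || any(nchar(contextDown) < window))
    .stopf("context strings must be at least %d bases", window)
  up <- vapply(contextUp, .maxRun, integer(1), window = window,
               fromEnd = TRUE, USE.NAMES = FALSE)
  dn <- vapply(contextDown, .maxRun, integer(1), window = window,
               fromEnd = FALSE, USE.NAMES = FALSE)
  up >= minRun | dn >= minRun
}

#' Population-frequency (germline) filter
#'
#' A candidate passes when its global gnomAD allele frequency is strictly
#' below `gnomadMax` (default 1e-5), or strictly below `gnomadMaxCosmic`
#' (default 1e-3) when the variant is present in COSMIC — known somatic
#' hotspots are allowed a laxer germline bound.
#'
#' @param gnomadAf gnomAD allele frequency in `[0, 1]`; 0 when absent.
#'   Vectorised.
#' @param cosmicCount COSMIC recurrence count; 0 when absent.
#' @param config A [ChipFilterConfig-class].
#' @return Logical vector.
#' @export
passesPopulationFilter <- function(gnomadAf, cosmicCount,
                                   config = chipFilterConfig("panel")) {
  if (any(gnomadAf < 0 | gnomadAf > 1)) .stopf("gnomadAf must be in [0,1]")
  gnomadAf < config@gnomadMax |
    (cosmicCount > 0 & gnomadAf < config@gnomadMaxCosmic)
}

#' Cohort-recurrence (panel-of-normals-like) filter
#'
#' The identical variant (chrom:pos:ref:alt) recurring across unrelated
#' samples at low VAF indicates an artifact or germline leakage; a candidate
#' passes when the fraction of processed samples carrying it is strictly
#' below `cohortRecurrenceMax` (default 5%). The fraction must be computed
#' over all samples processed in the run.
#'
#' @param carriers Number of samples carrying the identical variant.
#'   Vectorised.
#' @param nSamples Total number of processed samples (>= 1).
#' @param config A [ChipFilterConfig-class].
#' @return Logical vector.
#' @examples
#' cohortRecurrencePass(4, 100)  # TRUE  (4% < 5%)
#' cohortRecurrencePass(5, 100)  # FALSE (5% is not < 5%)
#' @export
cohortRecurrencePass <- function(carriers, nSamples,
                                 config = chipFilterConfig("panel")) {
  if (nSamples < 1) .stopf("nSamples must be >= 1")
  carriers / nSamples < config@cohortRecurrenceMax
}

#' Protein-altering consequence check
#'
#' CHIP calls are restricted to variants altering the protein sequence,
#' including exonic splicing variants. Terms outside the controlled
#' vocabulary fail closed with a warning.
#'
#' @param consequence Consequence term(s).
#' @param config A [ChipFilterConfig-class] carrying the accepted terms.
#' @return Logical vector.
#' @export
isProteinAltering <- function(consequence,
                              config = chipFilterConfig("panel")) {
  known <- c(config@proteinAlteringTerms, .nonAlteringTerms)
  unknown <- !(consequence %in% known) & !is.na(consequence)
  if (any(unknown))
    warning("unknown consequence term(s) failed closed: ",
            paste(unique(consequence[unknown]), collapse = ", "),
            call. = FALSE)
  consequence %in% config@proteinAlteringTerms
}

#' Apply the stepwise CHIP filter cascade
#'
#' Evaluates all seven criteria for every record — VAF window (inclusive
#' endpoints), site depth (strict), per-strand read-pair support,
#' gnomAD/COSMIC population filter (strict), cohort recurrence (strict),
#' homopolymer context and protein-altering consequence — without
#' short-circuiting, so every rejection is auditable. Records must come
#' from all processed samples of a run together, because the recurrence
#' criterion counts carriers across the whole run. Identical
#' (sample, chrom, pos, ref, alt) duplicates are collapsed to the record
#' with the highest alt depth, with a logged count. All passing calls are
#' marked as needing manual review (the stand-in for IGV inspection).
#'
#' @param records `data.frame` of variant records (see [readVariantVcf()]).
#' @param config A [ChipFilterConfig-class].
#' @param nSamples Number of processed samples for the recurrence
#'   denominator; defaults to the number of distinct `sample_id` values in
#'   `records`. Supply explicitly when some processed samples yielded no
#'   candidate variants.
#' @return A [ChipCallSet-class]; classification is `"none"` until
#'   [classifyChip()] is applied.
#' @export
applyFilterCascade <- function(records, config = chipFilterConfig("panel"),
                               nSamples = NULL) {
  if (is.null(records)) records <- makeEmptyRecords()
  if (is.null(nSamples)) nSamples <- length(unique(records$sample_id))
  nSamples <- as.integer(max(nSamples, 1L))
  if (nrow(records) == 0) {
    records <- makeEmptyRecords()
    empty <- records
    empty$vaf <- numeric(0)
    for (f in criterionNames()) empty[[paste0("flag_", f)]] <- logical(0)
    empty$passed <- logical(0)
    empty$classification <- character(0)
    empty$needs_review <- logical(0)
    return(new("ChipCallSet", calls = empty, config = config,
               nSamples = nSamples))
  }
  miss <- setdiff(.recordColumns, names(records))
  if (length(miss))
    .stopf("records missing columns: %s", paste(miss, collapse = ", "))

  # collapse duplicate (sample, variant) records, keeping highest alt depth
  dupKey <- paste(records$sample_id,
                  .variantKey(records$chrom, records$pos, records$ref,
                              records$alt))
  if (anyDuplicated(dupKey)) {
    origIdx <- seq_len(nrow(records))
    ord <- order(dupKey, -records$alt_depth)
    keep <- ord[!duplicated(dupKey[ord])]
    .chLog("collapsed ", nrow(records) - length(keep),
           " duplicate sample/variant records")
    records <- records[sort(keep), , drop = FALSE]
  }
  rownames(records) <- NULL

  vaf <- computeVaf(records$alt_depth, records$total_depth)
  key <- .variantKey(records$chrom, records$pos, records$ref, records$alt)
  carriersByKey <- tapply(records$sample_id, key,
                          function(s) length(unique(s)))
  carriers <- as.integer(carriersByKey[key])

  calls <- records
  calls$vaf <- vaf
  calls$flag_vaf_range <- vaf >= config@vafMin & vaf <= config@vafMax
  calls$flag_depth <- records$total_depth > config@minDepth
  calls$flag_strand_pairs <- records$alt_fwd >= config@minStrandPairs &
    records$alt_rev >= config@minStrandPairs
  calls$flag_population <- passesPopulationFilter(records$gnomad_af,
                                                  records$cosmic_count, config)
  calls$flag_cohort_recurrence <- cohortRecurrencePass(carriers, nSamples,
                                                       config)
  calls$flag_homopolymer <- !hasHomopolymer(records$context_up,
                                            records$context_down,
                                            config@homopolymerWindow,
                                            config@homopolymerMinRun)
  calls$flag_protein_altering <- isProteinAltering(records$consequence, config)
  calls$passed <- Reduce(`&`, calls[paste0("flag_", criterionNames())])
  calls$classification <- "none"
  calls$needs_review <- calls$passed
  .chLog(nrow(calls), " records evaluated, ", sum(calls$passed),
         " passed all criteria")
  new("ChipCallSet", calls = calls, config = config, nSamples = nSamples)
}

.catalogMatches <- function(gene, hgvsP, catalog) {
  rows <- catalog[catalog$gene == toupper(gene %||% ""), , drop = FALSE]
  if (!nrow(rows)) return(rows)
  pat <- rows$hgvs_p_pattern
  hit <- vapply(seq_len(nrow(rows)), function(i) {
    if (is.na(pat[i]) || !nzchar(pat[i])) return(TRUE)  # gene-level entry
    if (is.na(hgvsP) || !nzchar(hgvsP)) return(FALSE)
    grepl(pat[i], hgvsP)
  }, logical(1))
  rows[hit, , drop = FALSE]
}

#' Classify one passing variant as CHIP or CHIP-PD
#'
#' A passing call is CHIP with putative drivers (CHIP-PD) when a matching
#' catalog entry has been reported strictly more than 10 times, or when it
#' matches an entry of the predefined hotspot list; otherwise it is CHIP.
#'
#' @param gene Gene symbol (may be `NA`).
#' @param hgvsP HGVS protein change string (may be `NA`).
#' @param catalog Driver catalog from [readDriverCatalog()].
#' @param passed Must be `TRUE`: classification is defined only for calls
#'   that survived the cascade.
#' @return `"CHIP_PD"` or `"CHIP"`.
#' @examples
#' cat <- readDriverCatalog()
#' classifyCall("DNMT3A", "p.Arg882His", cat)  # hotspot -> CHIP_PD
#' @export
classifyCall <- function(gene, hgvsP, catalog = readDriverCatalog(),
                         passed = TRUE) {
  if (!isTRUE(passed))
    .stopf("classification is defined only for passing calls")
  m <- .catalogMatches(gene, hgvsP, catalog)
  if (nrow(m) && any(m$recurrence_count > 10L | m$predefined)) "CHIP_PD"
  else "CHIP"
}

#' @describeIn classifyChip Classify all passing calls of a
#'   [ChipCallSet-class]; non-passing records keep classification `"none"`.
#' @export
setMethod("classifyChip", "ChipCallSet", function(x, catalog) {
  calls <- x@calls
  idx <- which(calls$passed)
  calls$classification[idx] <- vapply(idx, function(i)
    classifyCall(calls$gene[i], calls$hgvs_p[i], catalog), character(1))
  initialize(x, calls = calls)
})
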