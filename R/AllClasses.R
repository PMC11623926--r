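#' @import methods
NULL

#' Names of the filter-cascade criteria, in evaluation order
#'
#' Each criterion corresponds to one logical flag column (`flag_<name>`) in a
#' [ChipCallSet]. A variant passes the cascade only if every flag is `TRUE`.
#'
#' @return Character vector of criterion names.
#' @export
criterionNames <- function() {
  c("vaf_range", "depth", "strand_pairs", "population",
    "cohort_recurrence", "homopolymer", "protein_altering")
}

#' Consequence terms counted as protein-altering by default
#'
#' The CHIP definition restricts calls to variants that alter the protein
#' sequence, including exonic splicing variants; synonymous and non-coding
#' consequences are excluded.
#'
#' @return Character vector of consequence terms.
#' @export
proteinAlteringTerms <- function() {
  c("missense", "stop_gained", "stop_lost", "start_lost", "frameshift",
    "inframe_insertion", "inframe_deletion", "splice_region_exonic")
}

# consequence terms we recognise but treat as non-altering
.nonAlteringTerms <- c(
  "synonymous", "intronic", "intergenic", "utr_5", "utr_3",
  "upstream", "downstream", "non_coding", "splice_region_intronic"
)

#' Configuration of the CHIP filter cascade
#'
#' Thresholds of the stepwise somatic-variant filter. Defaults follow the
#' panel (discovery, ~600x) and whole-exome (replication, ~80x) settings:
#' VAF window 2-35% (endpoints inclusive), site depth strictly greater than
#' 500x (panel) or 40x (WES), at least 4 (panel) or 2 (WES) alt-supporting
#' read pairs in each of the forward and reverse directions, gnomAD allele
#' frequency strictly below 1e-5 (relaxed to 1e-3 for COSMIC variants),
#' identical-variant recurrence strictly below 5% of processed samples, and
#' no homopolymer run within 6 bp up- or downstream. The minimum run length
#' defining a homopolymer is not pinned by the filter definition; the
#' conventional value 4 is the default and is configurable.
#'
#' @slot mode `"panel"` or `"wes"`.
#' @slot vafMin,vafMax Inclusive VAF window bounds.
#' @slot minDepth Site depth must strictly exceed this.
#' @slot minStrandPairs Minimum alt-supporting read pairs per direction.
#' @slot gnomadMax Strict gnomAD frequency bound for non-COSMIC variants.
#' @slot gnomadMaxCosmic Strict bound when the variant is in COSMIC.
#' @slot cohortRecurrenceMax Strict bound on the fraction of processed
#'   samples carrying the identical variant.
#' @slot homopolymerWindow Bases examined on each side of the variant.
#' @slot homopolymerMinRun Minimum identical-base run length flagged.
#' @slot proteinAlteringTerms Consequence terms counted as protein-altering.
#'
#' @seealso [chipFilterConfig()], [applyFilterCascade()]
#' @export
setClass("ChipFilterConfig",
  representation(
    mode = "character",
    vafMin = "numeric",
    vafMax = "numeric",
    minDepth = "numeric",
    minStrandPairs = "numeric",
    gnomadMax = "numeric",
    gnomadMaxCosmic = "numeric",
    cohortRecurrenceMax = "numeric",
    homopolymerWindow = "numeric",
    homopolymerMinRun = "numeric",
    proteinAlteringTerms = "character"
  )
)

setValidity("ChipFilterConfig", function(object) {
  msg <- character()
  if (!object@mode %in% c("panel", "wes"))
    msg <- c(msg, "mode must be 'panel' or 'wes'")
  if (!(object@vafMin >= 0 && object@vafMin < object@vafMax &&
        object@vafMax <= 1))
    msg <- c(msg, "need 0 <= vafMin < vafMax <= 1")
  counts <- c(object@minDepth, object@minStrandPairs,
              object@homopolymerWindow, object@homopolymerMinRun)
  if (any(counts < 0)) msg <- c(msg, "count thresholds must be >= 0")
  if (!(object@gnomadMax <= object@gnomadMaxCosmic))
    msg <- c(msg, "gnomadMax must not exceed gnomadMaxCosmic")
  if (object@cohortRecurrenceMax < 0 || object@cohortRecurrenceMax > 1)
    msg <- c(msg, "cohortRecurrenceMax must be in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Create a filter-cascade configuration
#'
#' @param mode `"panel"` (targeted, ~600x) or `"wes"` (~80x); sets the
#'   depth and strand-pair defaults (panel: depth > 500, >= 4 pairs per
#'   strand; WES: depth > 40, >= 2 pairs per strand).
#' @param vafMin,vafMax Inclusive VAF window (default 0.02-0.35).
#' @param minDepth,minStrandPairs Override the mode defaults.
#' @param gnomadMax,gnomadMaxCosmic Strict population-frequency bounds
#'   (defaults 1e-5 and 1e-3).
#' @param cohortRecurrenceMax Strict cohort-recurrence bound (default 0.05).
#' @param homopolymerWindow,homopolymerMinRun Homopolymer filter window
#'   (default 6 bp) and minimum run length (default 4).
#' @param proteinAlteringTerms Consequence terms counted as protein-altering.
#'
#' @return A [ChipFilterConfig-class] object.
#' @examples
#' chipFilterConfig("panel")
#' chipFilterConfig("wes")
#' @export
chipFilterConfig <- function(mode = c("panel", "wes"),
                             vafMin = 0.02, vafMax = 0.35,
                             minDepth = NULL, minStrandPairs = NULL,
                             gnomadMax = 1e-5, gnomadMaxCosmic = 1e-3,
                             cohortRecurrenceMax = 0.05,
                             homopolymerWindow = 6, homopolymerMinRun = 4,
                             proteinAlteringTerms = CHIPburden::proteinAlteringTerms()) {
  mode <- match.arg(mode)
  if (is.null(minDepth)) minDepth <- if (mode == "panel") 500 else 40
  if (is.null(minStrandPairs)) minStrandPairs <- if (mode == "panel") 4 else 2
  new("ChipFilterConfig",
      mode = mode, vafMin = vafMin, vafMax = vafMax,
      minDepth = minDepth, minStrandPairs = minStrandPairs,
      gnomadMax = gnomadMax, gnomadMaxCosmic = gnomadMaxCosmic,
      cohortRecurrenceMax = cohortRecurrenceMax,
      homopolymerWindow = homopolymerWindow,
      homopolymerMinRun = homopolymerMinRun,
      proteinAlteringTerms = proteinAlteringTerms)
}

# columns every variant-record data.frame must carry
.recordColumns <- c(
  "chrom", "pos", "ref", "alt", "sample_id",
  "total_depth", "alt_depth", "alt_fwd", "alt_rev",
  "gene", "consequence", "hgvs_p", "gnomad_af", "cosmic_count",
  "context_up", "context_down"
)

#' Audited CHIP calls from the filter cascade
#'
#' Holds one row per candidate variant with its VAF, one logical pass flag
#' per filter criterion, the overall pass indicator, the CHIP / CHIP-PD
#' classification and a manual-review flag. Flags are never short-circuited:
#' every criterion is evaluated for every record so rejections are fully
#' auditable.
#'
#' @slot calls `data.frame` with the raw record fields, `vaf`, one
#'   `flag_<criterion>` column per [criterionNames()] entry, `passed`,
#'   `classification` (`"CHIP"`, `"CHIP_PD"` or `"none"`) and
#'   `needs_review`.
#' @slot config The [ChipFilterConfig-class] used.
#' @slot nSamples Number of processed samples the cohort-recurrence
#'   criterion was computed over.
#'
#' @seealso [applyFilterCascade()], [chipCalls()], [passingCalls()]
#' @export
setClass("ChipCallSet",
  representation(
    calls = "data.frame",
    config = "ChipFilterConfig",
    nSamples = "integer"
  )
)

setValidity("ChipCallSet", function(object) {
  msg <- character()
  calls <- object@calls
  flagCols <- paste0("flag_", criterionNames())
  need <- c(.recordColumns, "vaf", flagCols, "passed", "classification",
            "needs_review")
  miss <- setdiff(need, names(calls))
  if (length(miss))
    return(paste("calls is missing columns:", paste(miss, collapse = ", ")))
  if (nrow(calls)) {
    allPass <- Reduce(`&`, calls[flagCols])
    if (!identical(unname(allPass), unname(calls$passed)))
      msg <- c(msg, "passed must equal the conjunction of all criterion flags")
    if (any(calls$classification != "none" & !calls$passed))
      msg <- c(msg, "only passing calls may be classified")
    if (!all(calls$classification %in% c("CHIP", "CHIP_PD", "none")))
      msg <- c(msg, "classification must be CHIP, CHIP_PD or none")
    bad <- abs(calls$vaf - calls$alt_depth / calls$total_depth) > 1e-12
    if (any(bad)) msg <- c(msg, "vaf must equal alt_depth / total_depth")
  }
  if (object@nSamples < 1L) msg <- c(msg, "nSamples must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn ChipCallSet-class Compact summary of calls, pass counts and
#'   classifications.
#' @param object A `ChipCallSet`.
#' @export
setMethod("show", "ChipCallSet", function(object) {
  calls <- object@calls
  cat("ChipCallSet with", nrow(calls), "candidate variants in",
      length(unique(calls$sample_id)), "samples",
      sprintf("(cohort size %d, mode %s)\n", object@nSamples,
              object@config@mode))
  cat("  passing:", sum(calls$passed),
      " CHIP:", sum(calls$classification == "CHIP"),
      " CHIP-PD:", sum(calls$classification == "CHIP_PD"), "\n")
  if (nrow(calls)) {
    fails <- vapply(paste0("flag_", criterionNames()),
                    function(f) sum(!calls[[f]]), integer(1))
    names(fails) <- criterionNames()
    cat("  failures per criterion:\n")
    for (nm in names(fails)) cat(sprintf("    %-18s %d\n", nm, fails[[nm]]))
  }
  invisible(object)
})
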