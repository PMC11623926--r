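# stage logging goes to stderr so piped outputs stay clean
.chLog <- function(...) message("[CHIPburden] ", ...)

# variant identity key used by the recurrence filter and timepoint joins
.variantKey <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' An empty variant-record table with the expected columns
#'
#' Useful as the degenerate input of [applyFilterCascade()] and for
#' building record tables programmatically.
#'
#' @return Zero-row `data.frame` with all record columns, correctly typed.
#' @export
makeEmptyRecords <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), sample_id = character(),
             total_depth = integer(), alt_depth = integer(),
             alt_fwd = integer(), alt_rev = integer(), gene = character(),
             consequence = character(), hgvs_p = character(),
             gnomad_af = numeric(), cosmic_count = integer(),
             context_up = character(), context_down = character(),
             stringsAsFactors = FALSE)
}
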