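#' Accessors for ChipCallSet objects
#'
#' `chipCalls()` returns the full audited call table (one row per candidate
#' variant, with per-criterion flags); `passingCalls()` returns only the
#' rows that survived every criterion; `filterConfig()` returns the
#' [ChipFilterConfig-class] the cascade was run with; `cohortSize()` the
#' number of processed samples the recurrence criterion used.
#'
#' @param x A [ChipCallSet-class].
#' @return `chipCalls()` and `passingCalls()` return a `data.frame`;
#'   `filterConfig()` a `ChipFilterConfig`; `cohortSize()` an integer.
#' @name ChipCallSet-accessors
NULL

#' @rdname ChipCallSet-accessors
#' @export
setGeneric("chipCalls", function(x) standardGeneric("chipCalls"))

#' @rdname ChipCallSet-accessors
#' @export
setGeneric("passingCalls", function(x) standardGeneric("passingCalls"))

#' @rdname ChipCallSet-accessors
#' @export
setGeneric("filterConfig", function(x) standardGeneric("filterConfig"))

#' @rdname ChipCallSet-accessors
#' @export
setGeneric("cohortSize", function(x) standardGeneric("cohortSize"))

#' @rdname ChipCallSet-accessors
#' @export
setMethod("chipCalls", "ChipCallSet", function(x) x@calls)

#' @rdname ChipCallSet-accessors
#' @export
setMethod("passingCalls", "ChipCallSet",
          function(x) x@calls[x@calls$passed, , drop = FALSE])

#' @rdname ChipCallSet-accessors
#' @export
setMethod("filterConfig", "ChipCallSet", function(x) x@config)

#' @rdname ChipCallSet-accessors
#' @export
setMethod("cohortSize", "ChipCallSet", function(x) x@nSamples)

#' Classify passing calls as CHIP or CHIP with putative drivers
#'
#' @param x Object holding passing calls (a [ChipCallSet-class]).
#' @param catalog Driver catalog `data.frame`, see [readDriverCatalog()].
#' @return Object of the same class with `classification` filled in.
#' @seealso [classifyCall()] for the single-variant rule.
#' @export
setGeneric("classifyChip", function(x, catalog) standardGeneric("classifyChip"))
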