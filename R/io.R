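#' VCF key mapping for variant evidence and annotation fields
#'
#' Somatic callers differ in how they encode per-sample strand counts and
#' annotation; the mapping from the fields this package needs to concrete
#' FORMAT/INFO keys therefore lives in a configuration object rather than in
#' code. Defaults match the files written by [writeChipVcf()] and the
#' synthetic-cohort generator: FORMAT `DP` (site depth), `AD` (per-allele
#' depths, ref first), `ADF`/`ADR` (per-allele forward / reverse supporting
#' read pairs, ref first); INFO `GENE`, `CSQT` (consequence), `HGVSP`,
#' `GNOMAD_AF`, `COSMIC_CNT`, `CTXU`/`CTXD` (reference context 5' / 3' of
#' the variant) and `CHIPCLASS` (classification written for passing calls).
#'
#' @param dp,ad,adf,adr FORMAT key names.
#' @param gene,consequence,hgvsP,gnomadAf,cosmicCount,contextUp,contextDown,classification
#'   INFO key names.
#' @return A named list of key names.
#' @export
vcfFieldKeys <- function(dp = "DP", ad = "AD", adf = "ADF", adr = "ADR",
                         gene = "GENE", consequence = "CSQT",
                         hgvsP = "HGVSP", gnomadAf = "GNOMAD_AF",
                         cosmicCount = "COSMIC_CNT",
                         contextUp = "CTXU", contextDown = "CTXD",
                         classification = "CHIPCLASS") {
  list(dp = dp, ad = ad, adf = adf, adr = adr, gene = gene,
       consequence = consequence, hgvsP = hgvsP, gnomadAf = gnomadAf,
       cosmicCount = cosmicCount, contextUp = contextUp,
       contextDown = contextDown, classification = classification)
}

# exact textual representation of a double, so VCF round-trips bit-exactly
.num2str <- function(x) {
  ifelse(is.na(x), NA_character_,
         ifelse(x == round(x) & abs(x) < 1e15,
                sprintf("%.0f", x), sprintf("%.17g", x)))
}

.splitNth <- function(x, i) {
  vapply(seq_along(x), function(j) {
    if (is.na(x[j])) return(NA_character_)
    parts <- strsplit(x[j], ",", fixed = TRUE)[[1]]
    if (length(parts) >= i[j]) parts[i[j]] else NA_character_
  }, character(1))
}

#' Read annotated somatic variant calls from a VCF file
#'
#' Reads a VCF 4.2 file carrying the per-sample depth/strand evidence and
#' the annotation INFO fields named in `keys`, and normalises it to one
#' record per (sample, alt allele). Multi-allelic sites are decomposed;
#' spanning-deletion alleles (`*`) are dropped with a logged count; missing
#' gnomAD frequency is treated as 0 (absent from gnomAD) and missing COSMIC
#' count as 0.
#'
#' @param path VCF file (plain or gzipped).
#' @param keys Key mapping from [vcfFieldKeys()].
#' @return `data.frame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `sample_id`, `total_depth`, `alt_depth`, `alt_fwd`, `alt_rev`, `gene`,
#'   `consequence`, `hgvs_p`, `gnomad_af`, `cosmic_count`, `context_up`,
#'   `context_down`, plus `filter` (the FILTER column) and `classification`
#'   when present.
#' @examples
#' sim <- simulateCohort(cohortSimConfig(nSamples = 4, seed = 1))
#' d <- tempfile(); dir.create(d)
#' files <- writeCohortVcfs(sim, d)
#' head(readVariantVcf(files[1]))
#' @export
readVariantVcf <- function(path, keys = vcfFieldKeys()) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE)
  meta <- v@meta
  if (!any(grepl("^##fileformat=VCF", meta)))
    .stopf("malformed VCF header in %s: missing ##fileformat line", path)
  for (k in c("dp", "ad", "adf", "adr")) {
    id <- keys[[k]]
    if (!any(grepl(paste0("^##FORMAT=<ID=", id, "[,>]"), meta)))
      .stopf("VCF schema error in %s: required FORMAT field '%s' not declared",
             path, id)
  }
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  nVar <- nrow(fix)
  if (nVar == 0) return(makeEmptyRecords())
  samples <- colnames(v@gt)[-1]
  getFmt <- function(key) {
    m <- vcfR::extract.gt(v, element = key)
    if (is.null(m)) matrix(NA_character_, nVar, length(samples)) else m
  }
  dpM <- getFmt(keys$dp); adM <- getFmt(keys$ad)
  adfM <- getFmt(keys$adf); adrM <- getFmt(keys$adr)
  infoGet <- function(key) {
    val <- vcfR::extract.info(v, element = key)
    if (is.null(val)) rep(NA_character_, nVar) else val
  }
  gene <- infoGet(keys$gene); csq <- infoGet(keys$consequence)
  hgvs <- infoGet(keys$hgvsP); gaf <- infoGet(keys$gnomadAf)
  cos <- infoGet(keys$cosmicCount)
  ctxu <- infoGet(keys$contextUp); ctxd <- infoGet(keys$contextDown)
  clas <- infoGet(keys$classification)

  rows <- vector("list", nVar * max(1L, length(samples)))
  nStar <- 0L; ri <- 0L
  for (i in seq_len(nVar)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (s in seq_along(samples)) {
      dp <- dpM[i, s]
      if (is.na(dp)) next  # this sample does not carry the record
      for (ai in seq_along(alts)) {
        if (alts[ai] == "*") { nStar <- nStar + 1L; next }
        pick <- function(m) .splitNth(m[i, s], ai + 1L)
        gafI <- if (grepl(",", gaf[i] %||% "")) .splitNth(gaf[i], ai) else gaf[i]
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
          ref = fix[i, "REF"], alt = alts[ai], sample_id = samples[s],
          total_depth = as.integer(dp),
          alt_depth = as.integer(pick(adM)),
          alt_fwd = as.integer(pick(adfM)),
          alt_rev = as.integer(pick(adrM)),
          gene = gene[i], consequence = csq[i], hgvs_p = hgvs[i],
          gnomad_af = if (is.na(gafI)) 0 else as.numeric(gafI),
          cosmic_count = if (is.na(cos[i])) 0L else as.integer(cos[i]),
          context_up = ctxu[i], context_down = ctxd[i],
          filter = fix[i, "FILTER"],
          classification = if (is.na(clas[i])) "none" else clas[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (nStar > 0) .chLog("dropped ", nStar, " spanning-deletion (*) allele records")
  out <- do.call(rbind, rows[seq_len(ri)])
  if (is.null(out)) return(makeEmptyRecords())
  rownames(out) <- NULL
  .chLog("read ", nrow(out), " variant records from ", basename(path))
  out
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

.vcfMeta <- function(keys, samplesPresent) {
  c("##fileformat=VCFv4.2",
    sprintf("##FORMAT=<ID=%s,Number=1,Type=Integer,Description=\"Total read depth at site\">", keys$dp),
    sprintf("##FORMAT=<ID=%s,Number=R,Type=Integer,Description=\"Per-allele read depth\">", keys$ad),
    sprintf("##FORMAT=<ID=%s,Number=R,Type=Integer,Description=\"Per-allele forward-strand supporting read pairs\">", keys$adf),
    sprintf("##FORMAT=<ID=%s,Number=R,Type=Integer,Description=\"Per-allele reverse-strand supporting read pairs\">", keys$adr),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Gene symbol\">", keys$gene),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Protein consequence term\">", keys$consequence),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"HGVS protein change\">", keys$hgvsP),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"gnomAD global allele frequency (0 when absent)\">", keys$gnomadAf),
    sprintf("##INFO=<ID=%s,Number=1,Type=Integer,Description=\"COSMIC recurrence count (0 when absent)\">", keys$cosmicCount),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Reference bases 5-prime of the variant\">", keys$contextUp),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Reference bases 3-prime of the variant\">", keys$contextDown),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"CHIP classification of a passing call\">", keys$classification),
    "##FILTER=<ID=PASS,Description=\"Passed all CHIP filter criteria\">",
    vapply(criterionNames(), function(f)
      sprintf("##FILTER=<ID=%s,Description=\"Failed the %s criterion\">", f, f),
      character(1)))
}

.buildInfo <- function(rec, keys, classification = NULL) {
  parts <- character(0)
  addIf <- function(parts, key, val) {
    if (is.null(val) || is.na(val)) parts else c(parts, paste0(key, "=", val))
  }
  parts <- addIf(parts, keys$gene, rec$gene)
  parts <- addIf(parts, keys$consequence, rec$consequence)
  parts <- addIf(parts, keys$hgvsP, rec$hgvs_p)
  parts <- addIf(parts, keys$gnomadAf, .num2str(rec$gnomad_af))
  parts <- addIf(parts, keys$cosmicCount, rec$cosmic_count)
  parts <- addIf(parts, keys$contextUp, rec$context_up)
  parts <- addIf(parts, keys$contextDown, rec$context_down)
  if (!is.null(classification) && classification != "none")
    parts <- c(parts, paste0(keys$classification, "=", classification))
  if (!length(parts)) "." else paste(parts, collapse = ";")
}

# Shared VCF writer: records df + per-record FILTER strings (or ".")
.writeRecordsVcf <- function(records, filters, classifications, path,
                             keys = vcfFieldKeys()) {
  samples <- unique(records$sample_id)
  n <- nrow(records)
  meta <- .vcfMeta(keys, samples)
  if (n == 0) {
    con <- gzfile(path, "w")
    on.exit(close(con))
    writeLines(c(meta, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                               "FILTER", "INFO", "FORMAT",
                               if (length(samples)) samples else "SAMPLE"),
                             collapse = "\t")), con)
    return(invisible(path))
  }
  info <- vapply(seq_len(n), function(i)
    .buildInfo(records[i, ], keys, classifications[i]), character(1))
  fix <- cbind(CHROM = as.character(records$chrom),
               POS = as.character(records$pos),
               ID = ".", REF = records$ref, ALT = records$alt,
               QUAL = NA_character_, FILTER = filters, INFO = info)
  fmt <- paste(keys$dp, keys$ad, keys$adf, keys$adr, sep = ":")
  gt <- matrix(NA_character_, n, length(samples) + 1L,
               dimnames = list(NULL, c("FORMAT", samples)))
  gt[, "FORMAT"] <- fmt
  refDepth <- records$total_depth - records$alt_depth
  # ref-allele strand components are not tracked; written as 0 placeholders
  cell <- sprintf("%d:%d,%d:0,%d:0,%d",
                  records$total_depth, refDepth, records$alt_depth,
                  records$alt_fwd, records$alt_rev)
  for (i in seq_len(n)) gt[i, records$sample_id[i]] <- cell[i]
  v <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                    meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Write audited CHIP calls to a VCF file
#'
#' Produces a VCF 4.2 file (gzipped) with `PASS` in the FILTER column for
#' calls surviving every criterion and the semicolon-joined names of the
#' failing criteria otherwise; the CHIP / CHIP-PD classification of passing
#' calls is written as an INFO field. The file round-trips through
#' [readVariantVcf()] with all depth and annotation fields preserved.
#'
#' @param x A [ChipCallSet-class].
#' @param path Output path (conventionally `.vcf.gz`).
#' @param keys Key mapping from [vcfFieldKeys()].
#' @return The path, invisibly.
#' @export
writeChipVcf <- function(x, path, keys = vcfFieldKeys()) {
  stopifnot(is(x, "ChipCallSet"))
  calls <- chipCalls(x)
  flagCols <- paste0("flag_", criterionNames())
  filters <- vapply(seq_len(nrow(calls)), function(i) {
    failed <- criterionNames()[!unlist(calls[i, flagCols])]
    if (!length(failed)) "PASS" else paste(failed, collapse = ";")
  }, character(1))
  .writeRecordsVcf(calls, filters, calls$classification, path, keys)
  .chLog("wrote ", nrow(calls), " calls (", sum(calls$passed), " PASS) to ",
         basename(path))
  invisible(path)
}

#' Read the cohort metadata table
#'
#' Tab-separated with header; required columns `sample_id`, `age`, `sex`,
#' `pathology` (LUAD / LUSC / other), `smoking` (never / ever / current),
#' `timepoint` (pre / post) and `response` (responder / non-responder /
#' unknown). Unknown response values are tolerated and mapped to
#' `"unknown"`; duplicated sample ids and non-numeric ages are errors.
#'
#' @param path TSV file path.
#' @return `data.frame`, one row per sample.
#' @export
readCohortTable <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "age", "sex", "pathology", "smoking",
            "timepoint", "response")
  miss <- setdiff(need, names(d))
  if (length(miss))
    .stopf("cohort table missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(d$sample_id))
    .stopf("duplicated sample_id in cohort table: %s",
           paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "))
  age <- suppressWarnings(as.numeric(d$age))
  if (anyNA(age)) .stopf("non-numeric age for sample(s): %s",
                         paste(d$sample_id[is.na(age)], collapse = ", "))
  if (any(age <= 0)) .stopf("age must be positive")
  d$age <- age
  chk <- function(col, allowed) {
    bad <- setdiff(unique(d[[col]]), allowed)
    if (length(bad)) .stopf("invalid %s value(s): %s", col,
                            paste(bad, collapse = ", "))
  }
  chk("pathology", c("LUAD", "LUSC", "other"))
  chk("smoking", c("never", "ever", "current"))
  chk("timepoint", c("pre", "post"))
  d$response[!d$response %in% c("responder", "non-responder")] <- "unknown"
  d
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Members are de-duplicated preserving order. Lines with fewer than three
#' fields are a format error.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(setNames(list(), character(0)))
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      .stopf("GMT format error at line %d: fewer than 3 fields", i)
    list(name = f[1], members = unique(f[-(1:2)]))
  })
  setNames(lapply(sets, `[[`, "members"), vapply(sets, `[[`, "", "name"))
}

#' Read a CHIP driver catalog
#'
#' Tab-separated with columns `gene`, `hgvs_p_pattern` (regular expression
#' matched against the call's HGVS.p; empty for gene-level entries),
#' `recurrence_count` (number of reports in the curation) and `predefined`
#' (`yes`/`no`: membership in the curated hotspot list). Gene symbols are
#' upper-cased. A passing variant is classified CHIP-PD when a matching
#' entry has `recurrence_count` strictly greater than 10, or when it matches
#' a `predefined` entry.
#'
#' @param path TSV file path; defaults to the catalog shipped with the
#'   package (a synthetic seed list of canonical CHIP drivers, meant to be
#'   edited or replaced).
#' @return `data.frame` with the four columns above (`predefined` logical).
#' @export
readDriverCatalog <- function(path = system.file("extdata", "chip_drivers.tsv",
                                                 package = "CHIPburden")) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = character(0))
  need <- c("gene", "hgvs_p_pattern", "recurrence_count", "predefined")
  miss <- setdiff(need, names(d))
  if (length(miss))
    .stopf("driver catalog missing columns: %s", paste(miss, collapse = ", "))
  d$gene <- toupper(d$gene)
  d$recurrence_count <- as.integer(d$recurrence_count)
  if (any(is.na(d$recurrence_count) | d$recurrence_count < 0))
    .stopf("recurrence_count must be a non-negative integer")
  d$predefined <- tolower(as.character(d$predefined)) %in% c("yes", "true", "1")
  d
}
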