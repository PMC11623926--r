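#' Wilcoxon rank-sum AUC for one gene
#'
#' Rank-sum statistic with midranks for ties; the AUC `u / (n1 * n2)` is
#' the probability that a random observation from group 1 exceeds one from
#' group 2, ties counted one half. The p-value uses the exact rank-sum
#' distribution when there are no ties and at most 50 observations, and a
#' tie-corrected normal approximation with continuity correction otherwise.
#'
#' @param valuesGroup1,valuesGroup2 Non-empty numeric vectors.
#' @return List with `auc`, `u` and `p`.
#' @examples
#' wilcoxonAuc(c(5, 6, 7), c(1, 2, 3))$auc  # 1: perfect separation
#' @export
wilcoxonAuc <- function(valuesGroup1, valuesGroup2) {
  n1 <- length(valuesGroup1); n2 <- length(valuesGroup2)
  if (n1 == 0 || n2 == 0) .stopf("both groups must be non-empty")
  r <- rank(c(valuesGroup1, valuesGroup2))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n2)
  N <- n1 + n2
  tiesTab <- table(r)
  hasTies <- any(tiesTab > 1)
  if (!hasTies && N <= 50) {
    p <- if (u > n1 * n2 / 2) 1 - stats::pwilcox(u - 1, n1, n2)
         else stats::pwilcox(u, n1, n2)
    p <- min(1, 2 * p)
  } else {
    mu <- n1 * n2 / 2
    tieTerm <- sum(tiesTab^3 - tiesTab) / (N * (N - 1))
    sigma2 <- (n1 * n2 / 12) * ((N + 1) - tieTerm)
    if (sigma2 <= 0) {
      p <- 1  # all observations tied
    } else {
      z <- u - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(auc = auc, u = u, p = p)
}

.getExprInput <- function(x, assayName) {
  if (is(x, "SummarizedExperiment")) {
    mat <- SummarizedExperiment::assay(x, assayName)
    meta <- as.data.frame(SummarizedExperiment::colData(x))
  } else if (is.list(x) && all(c("counts", "metadata") %in% names(x))) {
    mat <- x$counts
    meta <- x$metadata
  } else .stopf("expression input must be a SummarizedExperiment or a list with counts and metadata")
  need <- c("cluster", "sample", "group")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    .stopf("cell metadata missing columns: %s", paste(miss, collapse = ", "))
  list(mat = as.matrix(mat), meta = meta)
}

#' AUC-rank differential expression within one cluster
#'
#' For each gene, computes the Wilcoxon rank-sum AUC of group A cells
#' versus group B cells within a cluster. Genes detected (count > 0) in
#' fewer than `minFrac` of the cells of both groups are dropped with a
#' logged count. The ranking metric is the centred AUC (`auc - 0.5`), which
#' is antisymmetric under group swap; the output is sorted by it,
#' descending, with deterministic ties broken by gene name.
#'
#' @param x A [SingleCellExperiment::SingleCellExperiment] (or any
#'   `SummarizedExperiment`) whose `colData` has `cluster`, `sample` and
#'   `group` columns, or a `list(counts =, metadata =)`.
#' @param cluster Cluster label to analyse.
#' @param groupA,groupB Group labels compared (A versus B).
#' @param minFrac Minimum detected fraction (default 0.05).
#' @param assayName Assay holding the expression values.
#' @return `data.frame` with `gene`, `auc`, `u`, `p`, `rank_score`, sorted;
#'   or `NULL` with a warning when the cluster lacks one of the groups.
#' @export
rankGenes <- function(x, cluster, groupA, groupB, minFrac = 0.05,
                      assayName = "counts") {
  inp <- .getExprInput(x, assayName)
  inCl <- inp$meta$cluster == cluster
  selA <- inCl & inp$meta$group == groupA
  selB <- inCl & inp$meta$group == groupB
  if (!any(selA) || !any(selB)) {
    warning(sprintf("cluster '%s' lacks cells of group '%s'; skipped",
                    cluster, if (!any(selA)) groupA else groupB),
            call. = FALSE)
    return(NULL)
  }
  mA <- inp$mat[, selA, drop = FALSE]
  mB <- inp$mat[, selB, drop = FALSE]
  fracA <- rowMeans(mA > 0)
  fracB <- rowMeans(mB > 0)
  keep <- fracA >= minFrac | fracB >= minFrac
  if (any(!keep))
    .chLog("dropped ", sum(!keep), " genes detected in < ", minFrac,
           " of cells in both groups")
  mA <- mA[keep, , drop = FALSE]
  mB <- mB[keep, , drop = FALSE]
  res <- lapply(seq_len(nrow(mA)), function(i)
    wilcoxonAuc(mA[i, ], mB[i, ]))
  out <- data.frame(
    gene = rownames(mA),
    auc = vapply(res, `[[`, numeric(1), "auc"),
    u = vapply(res, `[[`, numeric(1), "u"),
    p = vapply(res, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE)
  out$rank_score <- out$auc - 0.5
  out <- out[order(-out$rank_score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ES from in-set positions only; extrema of the weighted KS running sum
# occur immediately after an in-set increment or immediately before one.
.gseaEsFast <- function(stats, positions, weightExponent = 1) {
  N <- length(stats)
  K <- length(positions)
  w <- abs(stats[positions])^weightExponent
  sumW <- sum(w)
  if (sumW == 0) w[] <- 1 / K else w <- w / sumW
  cw <- cumsum(w)
  j <- seq_len(K)
  dec <- (positions - j) / (N - K)
  top <- cw - dec
  bottom <- c(0, cw[-K]) - dec
  maxP <- max(top)
  minP <- min(bottom)
  if (maxP >= -minP) maxP else minP
}

#' GSEA enrichment score on a ranked gene list
#'
#' Weighted Kolmogorov-Smirnov running statistic: walking the ranking from
#' the top, in-set genes increment the running sum by
#' `|rank_score|^weightExponent` normalised by the in-set total, out-of-set
#' genes decrement it by `1 / (N - K)`. The enrichment score is the
#' extremum of the larger excursion, and the leading edge contains the
#' in-set genes up to (positive ES) or after (negative ES) the extremum.
#'
#' @param ranked `data.frame` from [rankGenes()] (columns `gene`,
#'   `rank_score`, sorted), or a named, descending-sorted numeric vector of
#'   rank scores.
#' @param geneSet Character vector of gene names.
#' @param weightExponent Weighting exponent (default 1).
#' @param minSetSize Minimum in-ranking overlap required (default 5).
#' @return List with `es`, `running_sum` (full-length), `leading_edge` and
#'   `n_overlap`; or `NULL` with a warning when the overlap is below
#'   `minSetSize`. Genes absent from the ranking are dropped from the set
#'   with a logged count.
#' @export
gseaEs <- function(ranked, geneSet, weightExponent = 1, minSetSize = 5) {
  if (is.data.frame(ranked)) {
    stats <- ranked$rank_score
    names(stats) <- ranked$gene
  } else stats <- ranked
  inSet <- names(stats) %in% geneSet
  nDropped <- length(unique(geneSet)) - sum(inSet)
  if (nDropped > 0)
    .chLog("dropped ", nDropped, " set genes absent from the ranking")
  K <- sum(inSet)
  N <- length(stats)
  if (K < minSetSize) {
    warning(sprintf("overlap %d below minimum set size %d; skipped", K,
                    minSetSize), call. = FALSE)
    return(NULL)
  }
  if (K == N) .stopf("gene set covers the whole ranking")
  w <- abs(stats)^weightExponent
  sumW <- sum(w[inSet])
  inc <- if (sumW == 0) as.numeric(inSet) / K else ifelse(inSet, w / sumW, 0)
  running <- cumsum(ifelse(inSet, inc, -1 / (N - K)))
  maxP <- max(running)
  minP <- min(c(0, running))
  es <- if (maxP >= -minP) maxP else minP
  pos <- which(inSet)
  leading <- if (es >= 0) names(stats)[pos[pos <= which.max(running)]]
             else names(stats)[pos[pos >= which.min(running)]]
  list(es = es, running_sum = running, leading_edge = leading,
       n_overlap = K)
}

#' Preranked GSEA with a gene-label permutation null
#'
#' For each gene set, the observed enrichment score is compared with a null
#' built by repeatedly drawing random gene positions of the same set size
#' from the ranking (the preranked-GSEA convention). The normalised score
#' divides the observed ES by the mean absolute null ES of matching sign;
#' the permutation p-value is `(1 + b) / (1 + m)` where `b` counts nulls at
#' least as extreme among the `m` of matching sign. P-values are
#' Benjamini-Hochberg adjusted across all sets tested in the call. Fully
#' reproducible for a given seed.
#'
#' @param ranked Ranking from [rankGenes()] (or named sorted vector).
#' @param geneSets Named list of gene sets (e.g. from [readGmt()]).
#' @param nPerm Number of permutations (>= 100; default 1000).
#' @param seed Integer seed for the permutation generator.
#' @param weightExponent,minSetSize Passed to the ES computation.
#' @return `data.frame` with one row per tested set: `pathway`,
#'   `n_overlap`, `es`, `nes`, `p_perm`, `padj`, `leading_edge`
#'   (semicolon-joined), `flag` (`"p_floored"` when no null of matching
#'   sign was seen, `"skipped_small_overlap"` for sets below the size
#'   minimum, otherwise `""`).
#' @export
gseaPermutation <- function(ranked, geneSets, nPerm = 1000, seed = NULL,
                            weightExponent = 1, minSetSize = 5) {
  if (nPerm < 100) .stopf("nPerm must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(ranked)) {
    stats <- ranked$rank_score
    names(stats) <- ranked$gene
  } else stats <- ranked
  N <- length(stats)
  rows <- lapply(names(geneSets), function(nm) {
    obs <- withCallingHandlers(
      gseaEs(stats, geneSets[[nm]], weightExponent, minSetSize),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(obs))
      return(data.frame(pathway = nm, n_overlap = sum(names(stats) %in% geneSets[[nm]]),
                        es = NA_real_, nes = NA_real_, p_perm = NA_real_,
                        padj = NA_real_, leading_edge = "",
                        flag = "skipped_small_overlap",
                        stringsAsFactors = FALSE))
    K <- obs$n_overlap
    nullEs <- vapply(seq_len(nPerm), function(i)
      .gseaEsFast(stats, sort.int(sample.int(N, K)), weightExponent),
      numeric(1))
    sameSign <- if (obs$es >= 0) nullEs[nullEs >= 0] else nullEs[nullEs < 0]
    m <- length(sameSign)
    flag <- ""
    if (m == 0) {
      p <- 1 / (1 + nPerm)
      nes <- NA_real_
      flag <- "p_floored"
    } else {
      b <- if (obs$es >= 0) sum(sameSign >= obs$es) else sum(sameSign <= obs$es)
      p <- (1 + b) / (1 + m)
      nes <- obs$es / mean(abs(sameSign))
    }
    data.frame(pathway = nm, n_overlap = K, es = obs$es, nes = nes,
               p_perm = p, padj = NA_real_,
               leading_edge = paste(obs$leading_edge, collapse = ";"),
               flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tested <- !is.na(out$p_perm)
  out$padj[tested] <- bhAdjust(out$p_perm[tested])
  out
}
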