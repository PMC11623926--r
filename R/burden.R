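#' Stratify samples by CHIP burden
#'
#' A sample is `negative` when it has no passing CHIP call, `high_burden`
#' when its largest clone has VAF strictly greater than 10% (a VAF of 10%
#' in a heterozygous mutation corresponds to roughly 20% of blood cells),
#' and `chip` otherwise.
#'
#' @param x A [ChipCallSet-class] with classifications, or a `data.frame`
#'   of passing calls with `sample_id`, `vaf` and `classification`.
#' @param sampleIds Sample ids to profile, including samples with no calls;
#'   defaults to the samples present in `x`.
#' @param highBurdenVaf Strict VAF boundary for the high-burden category
#'   (default 0.10).
#' @return `data.frame` with `sample_id`, `n_chip` (passing calls),
#'   `n_chip_pd`, `max_vaf` (`NA` for negatives) and `category`.
#' @export
classifyBurden <- function(x, sampleIds = NULL, highBurdenVaf = 0.10) {
  calls <- if (is(x, "ChipCallSet")) passingCalls(x) else x
  if (is.null(sampleIds)) sampleIds <- unique(calls$sample_id)
  prof <- data.frame(sample_id = sampleIds, n_chip = 0L, n_chip_pd = 0L,
                     max_vaf = NA_real_, category = "negative",
                     stringsAsFactors = FALSE)
  if (nrow(calls)) {
    byS <- split(calls, calls$sample_id)
    idx <- match(names(byS), prof$sample_id)
    bad <- names(byS)[is.na(idx)]
    if (length(bad))
      .stopf("calls for samples absent from sampleIds: %s",
             paste(bad, collapse = ", "))
    prof$n_chip[idx] <- vapply(byS, nrow, integer(1))
    prof$n_chip_pd[idx] <- vapply(byS, function(d)
      sum(d$classification == "CHIP_PD"), integer(1))
    prof$max_vaf[idx] <- vapply(byS, function(d) max(d$vaf), numeric(1))
    prof$category[idx] <- ifelse(prof$max_vaf[idx] > highBurdenVaf,
                                 "high_burden", "chip")
  }
  prof
}

#' Carrier counts per stratum of a clinical covariate
#'
#' Counts CHIP carriers (burden category other than `negative`) and totals
#' within each level of a cohort covariate (e.g. pathology, timepoint,
#' response). Strata with zero samples are omitted with a log line.
#'
#' @param profiles Burden profiles from [classifyBurden()].
#' @param cohort Cohort table from [readCohortTable()] (or equivalent).
#' @param stratifyBy Name of the covariate column in `cohort`.
#' @return `data.frame` with `stratum`, `carriers`, `total`, `prevalence`.
#' @export
prevalenceTable <- function(profiles, cohort, stratifyBy) {
  if (!stratifyBy %in% names(cohort))
    .stopf("no column '%s' in cohort table", stratifyBy)
  idx <- match(profiles$sample_id, cohort$sample_id)
  if (anyNA(idx))
    .stopf("sample ids missing from cohort table: %s",
           paste(profiles$sample_id[is.na(idx)], collapse = ", "))
  stratum <- cohort[[stratifyBy]][idx]
  carrier <- profiles$category != "negative"
  levs <- unique(cohort[[stratifyBy]])
  empty <- setdiff(levs, unique(stratum))
  if (length(empty))
    .chLog("omitting empty strata for ", stratifyBy, ": ",
           paste(empty, collapse = ", "))
  agg <- data.frame(
    stratum = sort(unique(stratum)),
    stringsAsFactors = FALSE)
  agg$carriers <- vapply(agg$stratum, function(s)
    sum(carrier[stratum == s]), integer(1))
  agg$total <- vapply(agg$stratum, function(s)
    sum(stratum == s), integer(1))
  agg$prevalence <- agg$carriers / agg$total
  agg
}

#' Conditional exact test on a 2x2 table
#'
#' Exact test for association in a 2x2 contingency table, conditioning on
#' both margins: the two-sided p-value sums the hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (minimum-likelihood rule).
#' This is the construction used for the cohort's categorical prevalence
#' comparisons.
#'
#' @param a,b Carriers and non-carriers in group 1.
#' @param c,d Carriers and non-carriers in group 2.
#' @return List with `odds_ratio` (`(a*d)/(b*c)`, `Inf`/0 flagged),
#'   `p_value`, `or_infinite`, `or_zero` and `method`.
#' @examples
#' exact2x2Test(5, 5, 5, 5)$p_value   # 1: perfect symmetry
#' exact2x2Test(8, 35, 2, 48)
#' @export
exact2x2Test <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    .stopf("table entries must be non-negative integers")
  if (sum(counts) == 0) .stopf("all-zero table")
  orInf <- b == 0 || c == 0
  orZero <- (a == 0 || d == 0) && !orInf
  oddsRatio <- if (orInf && (a == 0 || d == 0)) NaN
               else if (orInf) Inf
               else (a * d) / (b * c)
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  pObs <- stats::dhyper(a, r1, r2, c1)
  # relative tolerance guards against ties broken by floating-point noise
  p <- min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
  list(odds_ratio = oddsRatio, p_value = p,
       or_infinite = orInf, or_zero = orZero,
       method = "conditional-exact-2x2")
}

#' Age-adjusted logistic regression
#'
#' Maximum-likelihood logistic fit of a binary outcome on a group indicator
#' and age, by iteratively reweighted least squares: convergence when the
#' largest coefficient change is below 1e-8, at most 100 iterations.
#' Complete or quasi-complete separation is detected and reported as a
#' flagged result rather than an error.
#'
#' @param outcome Binary vector (0/1 or logical).
#' @param group Binary group indicator (0/1, logical or two-level factor).
#' @param age Numeric ages, no missing values.
#' @return List with `coefficients` (`data.frame` of `term`, `estimate`,
#'   `se`, `z`, `p`), `converged`, `separation`, `iterations`.
#' @export
ageAdjustedLogistic <- function(outcome, group, age) {
  y <- as.numeric(outcome)
  if (is.factor(group)) group <- as.integer(group) - 1L
  g <- as.numeric(group)
  if (anyNA(c(y, g, age))) .stopf("missing values are not allowed")
  if (length(unique(y)) < 2) .stopf("outcome is constant")
  if (min(table(y)) < 2) .stopf("need at least 2 samples per outcome class")
  X <- cbind(intercept = 1, group = g, age = as.numeric(age))
  beta <- rep(0, ncol(X))
  converged <- FALSE
  it <- 0L
  for (it in seq_len(100L)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    betaNew <- tryCatch(solve(XtW %*% X, XtW %*% z),
                        error = function(e) NULL)
    if (is.null(betaNew)) break
    delta <- max(abs(betaNew - beta))
    beta <- drop(betaNew)
    if (delta < 1e-8) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  # diverging coefficients with fitted values pinned at 0/1 indicate
  # separation along some covariate combination
  separation <- !converged || max(abs(beta[-1])) > 15 ||
    all(abs(mu - y) < 1e-6)
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- t(X * w) %*% X
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e)
    rep(NA_real_, ncol(X)))
  zstat <- beta / se
  coefs <- data.frame(term = colnames(X), estimate = beta, se = se,
                      z = zstat, p = 2 * stats::pnorm(-abs(zstat)),
                      stringsAsFactors = FALSE, row.names = NULL)
  list(coefficients = coefs, converged = converged,
       separation = separation, iterations = it)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment: sorted ascending p-values are scaled by `n / rank`
#' and made monotone from the largest down, capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs not allowed).
#' @return Adjusted p-values in the original order.
#' @export
bhAdjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) .stopf("p-values must be in [0,1]")
  n <- length(p)
  if (n <= 1) return(p)
  o <- order(p)
  scaled <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

#' Pre/post-treatment VAF concordance of traced variants
#'
#' Inner-joins calls from two timepoints on (sample, chrom, pos, ref, alt)
#' and reports Pearson and Spearman correlations of the matched VAFs,
#' together with the variants detected at only one timepoint. Variants
#' present at one timepoint only are reported as gained/lost, never imputed
#' with pseudo-VAFs.
#'
#' @param preCalls,postCalls [ChipCallSet-class] objects or `data.frame`s
#'   of passing calls with `sample_id`, `chrom`, `pos`, `ref`, `alt`, `vaf`.
#' @return List with `matched` (`data.frame` of key, `vaf_pre`,
#'   `vaf_post`), `gained`, `lost` (keys), `pearson`, `spearman` (`NA` when
#'   fewer than 3 matched pairs) and `n_matched`.
#' @export
vafConcordance <- function(preCalls, postCalls) {
  getCalls <- function(x) if (is(x, "ChipCallSet")) passingCalls(x) else x
  pre <- getCalls(preCalls); post <- getCalls(postCalls)
  keyOf <- function(d) paste(d$sample_id,
                             .variantKey(d$chrom, d$pos, d$ref, d$alt))
  kPre <- keyOf(pre); kPost <- keyOf(post)
  common <- intersect(kPre, kPost)
  matched <- data.frame(
    key = common,
    vaf_pre = pre$vaf[match(common, kPre)],
    vaf_post = post$vaf[match(common, kPost)],
    stringsAsFactors = FALSE)
  enough <- nrow(matched) >= 3
  list(matched = matched,
       gained = setdiff(kPost, kPre),
       lost = setdiff(kPre, kPost),
       pearson = if (enough) stats::cor(matched$vaf_pre, matched$vaf_post)
                 else NA_real_,
       spearman = if (enough) stats::cor(matched$vaf_pre, matched$vaf_post,
                                         method = "spearman")
                  else NA_real_,
       n_matched = nrow(matched))
}
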