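#' Exclusive-detection power
#'
#' Probability that a specific variant is seen at least once among `n`
#' gene-level carriers when each carrier harbours it independently with
#' probability `p`: `1 - (1 - p)^n`. This is the conditional form of the
#' exclusive-detection model — the variant is assumed totally absent in the
#' comparison group — and is evaluated stably via `log1p` for small `p`.
#'
#' @param n Number of carriers (>= 0). Vectorised.
#' @param p Per-carrier variant frequency in `[0, 1]`.
#' @return Detection probability in `[0, 1]`.
#' @examples
#' detectionPower(16, 0.10)  # 0.815: 16 carriers give power >= 0.8
#' detectionPower(15, 0.10)  # 0.794: 15 do not
#' @export
detectionPower <- function(n, p) {
  if (any(n < 0)) .stopf("n must be >= 0")
  if (any(p < 0 | p > 1)) .stopf("p must be in [0,1]")
  out <- -expm1(n * log1p(-p))
  out[n == 0] <- 0
  out[p == 1 & n >= 1] <- 1
  out
}

#' Minimum carrier count reaching a target detection power
#'
#' Smallest `n` with `detectionPower(n, p) >= target`, computed in closed
#' form as `ceil(log(1 - target) / log(1 - p))` and then verified by direct
#' evaluation at `n` and `n - 1`.
#'
#' @param p Per-carrier variant frequency in `(0, 1]`.
#' @param target Target power in `(0, 1)`.
#' @return Integer carrier count.
#' @examples
#' minGroupSize(0.10, 0.8)  # 16
#' @export
minGroupSize <- function(p, target) {
  if (p <= 0) .stopf("unattainable: p must be positive")
  if (p > 1) .stopf("p must be in (0,1]")
  if (target <= 0 || target >= 1) .stopf("target must be in (0,1)")
  if (p == 1) return(1L)
  n <- as.integer(ceiling(log1p(-target) / log1p(-p)))
  # closed form can be off by one at representation boundaries; verify
  while (detectionPower(n, p) < target) n <- n + 1L
  while (n > 1L && detectionPower(n - 1L, p) >= target) n <- n - 1L
  n
}

#' Cohort size required to accrue a minimum number of gene-level carriers
#'
#' Smallest number of CHIP-positive samples `m` with
#' `m * genePrevalence >= minCarriers`. When the prevalence is supplied as
#' a count ratio `numerator / denominator`, the result is computed in exact
#' integer arithmetic (`ceil(minCarriers * denominator / numerator)`),
#' avoiding floating-point ceiling artifacts.
#'
#' @param minCarriers Required carriers (>= 1), e.g. from [minGroupSize()].
#' @param genePrevalence Gene-level CHIP prevalence among CHIP-positive
#'   samples, as a fraction; ignored when counts are given.
#' @param numerator,denominator Optional integer counts defining the
#'   prevalence exactly (e.g. 8 carriers of 50 CHIP samples).
#' @return Integer cohort size.
#' @examples
#' requiredCohortSize(16, numerator = 8, denominator = 50)  # 100
#' @export
requiredCohortSize <- function(minCarriers, genePrevalence = NULL,
                               numerator = NULL, denominator = NULL) {
  if (minCarriers < 1) .stopf("minCarriers must be >= 1")
  if (!is.null(numerator)) {
    if (is.null(denominator)) .stopf("denominator required with numerator")
    if (numerator <= 0) .stopf("unattainable: prevalence is zero")
    q <- minCarriers * denominator
    return(as.integer((q + numerator - 1) %/% numerator))
  }
  if (is.null(genePrevalence) || genePrevalence <= 0)
    .stopf("unattainable: prevalence is zero")
  m <- ceiling(minCarriers / genePrevalence)
  # guard against floating division landing one above an exact multiple
  if ((m - 1) * genePrevalence >= minCarriers) m <- m - 1
  as.integer(m)
}

#' Exact Poisson-binomial probability mass function
#'
#' Distribution of the number of carriers among samples with heterogeneous
#' carriage probabilities, computed exactly by iterative convolution
#' (dynamic programming). The equal-probability case reduces to the
#' binomial distribution.
#'
#' @param probs Per-sample carriage probabilities in `[0, 1]`.
#' @return Numeric vector of length `length(probs) + 1`: `P(K = 0..n)`.
#'   For an empty input, `1` (the point mass at zero).
#' @export
poissonBinomialPmf <- function(probs) {
  if (any(probs < 0 | probs > 1)) .stopf("probabilities must be in [0,1]")
  pmf <- 1
  for (p in probs) pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  pmf
}

# P(no carrier in a group), stably on the log scale
.probNone <- function(probs) {
  if (!length(probs)) return(1)
  if (any(probs == 1)) return(0)
  exp(sum(log1p(-probs)))
}

#' Probability of exclusive detection in one of two groups
#'
#' Probability that at least one carrier is observed in exactly one of two
#' groups: `P(>=1 in A) * P(0 in B) + P(0 in A) * P(>=1 in B)`, with the
#' zero-carrier probabilities computed stably as products of `1 - p_i`.
#' This is the unconditional form of the exclusive-detection model; the
#' headline minimum sizes use the conditional form [detectionPower()].
#'
#' @param probsA,probsB Per-sample carriage probabilities of each group.
#' @return Probability in `[0, 1]`.
#' @export
exclusiveDetectionProb <- function(probsA, probsB) {
  if (any(c(probsA, probsB) < 0 | c(probsA, probsB) > 1))
    .stopf("probabilities must be in [0,1]")
  qA <- .probNone(probsA)
  qB <- .probNone(probsB)
  (1 - qA) * qB + qA * (1 - qB)
}

#' Detection-power curve over carrier counts
#'
#' @param p Per-carrier variant frequency.
#' @param nMax Largest carrier count tabulated.
#' @return `data.frame` with `n` and `power`, suitable for TSV export.
#' @export
powerCurve <- function(p, nMax = 50) {
  data.frame(n = 0:nMax, power = detectionPower(0:nMax, p))
}
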