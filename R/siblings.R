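#' Mean phenotype Z-score of siblings of tail probands
#'
#' Among pairs whose proband lies beyond the tail cutoff, the mean sibling
#' Z-score with a normal-approximation 95% confidence interval. Under an
#' additive polygenic model siblings regress toward the mean by the factor
#' r (the sibling correlation); excess regression in one tail signals
#' non-additive or non-genetic factors there.
#'
#' @param pairs Data frame with `proband_z` and `sibling_z` (families with
#'   several siblings should be averaged to one row beforehand).
#' @param tail `"short"` (proband Z < -cutoff) or `"tall"` (Z > cutoff).
#' @param cutoff Positive |Z| cutoff (default 2.81, the ~0.25% tails).
#' @return List with `mean`, `ci` (length-2), `n`, and the selected
#'   sibling scores in `sib_z`.
#' @export
sibling_mean_z <- function(pairs, tail = c("short", "tall"), cutoff = 2.81) {
  tail <- match.arg(tail)
  stopifnot(cutoff > 0)
  keep <- if (tail == "short") pairs$proband_z < -cutoff
  else pairs$proband_z > cutoff
  sib <- pairs$sibling_z[keep & !is.na(pairs$sibling_z)]
  if (length(sib) < 2L) stop("fewer than 2 probands in the ", tail, " tail")
  m <- mean(sib)
  se <- stats::sd(sib) / sqrt(length(sib))
  list(mean = m, ci = m + c(-1.96, 1.96) * se, n = length(sib), sib_z = sib)
}

#' Differential regression-to-the-mean test between tails
#'
#' Welch t-test comparing the tall-tail sibling Z-scores against the
#' sign-reversed short-tail sibling Z-scores. Under a symmetric additive
#' model the two have equal means, so rejection indicates tail-asymmetric
#' regression to the mean.
#'
#' @param short_sib_z,tall_sib_z Sibling Z-scores for probands in each tail.
#' @return List with `t`, `df`, two-sided `p`.
#' @export
tail_regression_test <- function(short_sib_z, tall_sib_z) {
  short_sib_z <- short_sib_z[!is.na(short_sib_z)]
  tall_sib_z <- tall_sib_z[!is.na(tall_sib_z)]
  if (length(short_sib_z) < 2L || length(tall_sib_z) < 2L)
    stop("both tails need at least 2 sibling scores")
  ht <- stats::t.test(tall_sib_z, -short_sib_z)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Additive-model expectation for the sibling mean
#'
#' Under a standard bivariate normal with correlation `r`, the expected
#' sibling Z given a proband beyond the cutoff is the correlation times
#' the truncated standard-normal mean, `phi(c) / (1 - Phi(c)) * r` for the
#' upper tail and its negative for the lower tail.
#'
#' @param r Sibling correlation in (-1, 1).
#' @param cutoff Positive |Z| cutoff.
#' @param tail `"short"` or `"tall"`.
#' @return Expected mean sibling Z.
#' @examples
#' expected_sib_mean_additive(0.466, 2.81, "short")  # about -1.45
#' @export
expected_sib_mean_additive <- function(r, cutoff,
                                       tail = c("short", "tall")) {
  tail <- match.arg(tail)
  stopifnot(r > -1, r < 1, cutoff > 0)
  m <- r * stats::dnorm(cutoff) / stats::pnorm(cutoff, lower.tail = FALSE)
  if (tail == "short") -m else m
}
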