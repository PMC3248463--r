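#' Tail design for extreme-vs-extreme case-control sampling
#'
#' Defines the Z-score cutoffs bounding the case (upper, "tall") tail and
#' the control (lower, "short") tail. The default `+/-2.326` marks the
#' approximate 1% tails of a standard normal.
#'
#' @param case_cutoff Lower bound of the upper (case) tail, Z units.
#' @param control_cutoff Upper bound of the lower (control) tail, Z units;
#'   typically `-case_cutoff`.
#' @return A list of class `tail_design`.
#' @export
tail_design <- function(case_cutoff = 2.326, control_cutoff = -case_cutoff) {
  stopifnot(is.finite(case_cutoff), is.finite(control_cutoff))
  if (case_cutoff <= control_cutoff)
    stop("case_cutoff must exceed control_cutoff")
  structure(list(case_cutoff = case_cutoff, control_cutoff = control_cutoff),
            class = "tail_design")
}

#' Conditional allele-level moments of the standardized trait
#'
#' Under the single-SNP normal decomposition of a standardized trait, the
#' trait of a random allele copy is normal with mean `beta * p` for the
#' trait-increasing allele, `-beta * (1 - p)` for the decreasing allele,
#' and common variance `1 - beta^2 * p * (1 - p)`. The frequency-weighted
#' mixture of the two means is exactly zero.
#'
#' @param beta Per-allele effect in SD units, oriented so positive means
#'   trait-increasing.
#' @param freq Frequency of the trait-increasing allele, in (0, 1).
#' @return List with `m_increasing`, `m_decreasing`, `v`.
#' @export
allele_height_moments <- function(beta, freq) {
  stopifnot(freq > 0, freq < 1)
  v <- 1 - beta^2 * freq * (1 - freq)
  if (any(v <= 0)) stop("beta^2 * p * (1 - p) >= 1: inadmissible variance")
  list(m_increasing = beta * freq,
       m_decreasing = -beta * (1 - freq),
       v = v)
}

#' Odds of the trait-increasing allele in a distribution tail
#'
#' The odds of observing the increasing versus the decreasing allele among
#' individuals beyond a Z cutoff, computed as the ratio of the per-allele
#' mixture probabilities
#' `p * P(X > c | m_inc, v)  /  (1 - p) * P(X > c | m_dec, v)`
#' (upper tail; the lower tail uses `P(X < c)`). Tail probabilities use
#' complementary-CDF routines so extreme cutoffs do not cancel.
#'
#' @param beta,freq As in [allele_height_moments()].
#' @param cutoff Z cutoff defining the tail.
#' @param tail `"upper"` or `"lower"`.
#' @return Dimensionless odds.
#' @export
tail_allele_odds <- function(beta, freq, cutoff, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  mom <- allele_height_moments(beta, freq)
  s <- sqrt(mom$v)
  upper <- tail == "upper"
  p_inc <- stats::pnorm(cutoff, mom$m_increasing, s, lower.tail = !upper)
  p_dec <- stats::pnorm(cutoff, mom$m_decreasing, s, lower.tail = !upper)
  if (any(p_inc == 0) || any(p_dec == 0))
    stop("tail probability underflow at cutoff ", cutoff,
         "; choose a less extreme tail design")
  (freq * p_inc) / ((1 - freq) * p_dec)
}

#' Expected odds ratio for a tail-ascertained allelic test
#'
#' The allelic odds ratio predicted between the upper-tail cases and
#' lower-tail controls from a SNP's population effect size and frequency
#' under the normal polygenic model: the ratio of [tail_allele_odds()] in
#' the case tail over the control tail. The approximate standard error of
#' its log is obtained by recomputing the OR at `beta +/- 1.96 * se_beta`
#' and taking `(log OR_hi - log OR_lo) / (2 * 1.96)`.
#'
#' @param beta,se_beta,freq Per-SNP effect, its SE and effect-allele
#'   frequency; vectors are accepted and recycled together.
#' @param design A [tail_design()].
#' @return Data frame with `or_expected` and `se_log_expected`.
#' @examples
#' expected_odds_ratio(0.05, 0.007, 0.3)
#' @export
expected_odds_ratio <- function(beta, se_beta, freq, design = tail_design()) {
  n <- max(length(beta), length(se_beta), length(freq))
  beta <- rep_len(beta, n); se_beta <- rep_len(se_beta, n)
  freq <- rep_len(freq, n)
  or_at <- function(b) {
    vapply(seq_len(n), function(i) {
      tail_allele_odds(b[i], freq[i], design$case_cutoff, "upper") /
        tail_allele_odds(b[i], freq[i], design$control_cutoff, "lower")
    }, numeric(1))
  }
  or <- or_at(beta)
  se_log <- ifelse(
    se_beta == 0, 0,
    (log(or_at(beta + 1.96 * se_beta)) - log(or_at(beta - 1.96 * se_beta))) /
      (2 * 1.96))
  data.frame(or_expected = or, se_log_expected = se_log)
}

#' Z-test of observed versus expected odds ratio
#'
#' Compares an observed allelic OR with its model-expected value on the log
#' scale, combining the two standard errors in quadrature:
#' `z = (log or_obs - log or_exp) / sqrt(se_obs^2 + se_exp^2)`.
#'
#' @param or_obs,se_log_obs Observed OR and SE of its log.
#' @param or_expected,se_log_expected Expected OR and SE of its log, e.g.
#'   from [expected_odds_ratio()].
#' @return Data frame with `z` and two-sided `p`.
#' @export
observed_vs_expected_ztest <- function(or_obs, se_log_obs,
                                       or_expected, se_log_expected) {
  if (any(or_obs <= 0) || any(or_expected <= 0))
    stop("odds ratios must be positive")
  s2 <- se_log_obs^2 + se_log_expected^2
  if (any(s2 == 0)) stop("both standard errors are zero")
  z <- (log(or_obs) - log(or_expected)) / sqrt(s2)
  data.frame(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Expected direction of effect
#'
#' Sign of the published effect size, used to score agreement between
#' observed and published directions; zero effects carry no direction and
#' are returned as `NA` (excluded from sign tests).
#'
#' @param beta Numeric effect sizes.
#' @return Integer vector in `{-1, 1, NA}`.
#' @export
expected_direction <- function(beta) {
  out <- sign(beta)
  out[out == 0] <- NA_integer_
  as.integer(out)
}

#' Population sample size with power equivalent to a tail-ascertained design
#'
#' For a variant explaining a fraction `variance_explained` of the trait
#' variance, computes the noncentrality of the allele-frequency contrast
#' between two extreme groups drawn from symmetric Z bands, and returns the
#' randomly sampled population size whose quantitative-trait test has the
#' same noncentrality. The per-tail allele-frequency shift is
#' `beta * p * (1 - p) * E[Z | Z in band]` with `beta` solved from
#' `2 p (1 - p) beta^2 = variance_explained`, and the contrast variance is
#' `p (1 - p) * (1 / (2 n_short) + 1 / (2 n_tall))`; the equivalent
#' population N is the noncentrality divided by `variance_explained`.
#'
#' @param band_inner,band_outer Absolute Z limits of the ascertainment band
#'   (e.g. 2.326 and 2.81 for the ~1% to 0.25% tails).
#' @param n_short,n_tall Group sizes in the lower and upper band.
#' @param variance_explained Fraction of trait variance, in (0, 1).
#' @param freq Reference allele frequency (default 0.3, typical of common
#'   trait-associated variants).
#' @return Equivalent population sample size (individuals).
#' @examples
#' equivalent_population_n(2.326, 2.81, 461, 462, 0.001)  # ~5.9e3
#' @export
equivalent_population_n <- function(band_inner, band_outer, n_short, n_tall,
                                    variance_explained, freq = 0.3) {
  stopifnot(n_short > 0, n_tall > 0,
            variance_explained > 0, variance_explained < 1)
  mass <- stats::pnorm(band_outer) - stats::pnorm(band_inner)
  if (band_outer <= band_inner || mass <= 0) stop("empty tail band")
  band_mean <- (stats::dnorm(band_inner) - stats::dnorm(band_outer)) / mass
  pq <- freq * (1 - freq)
  beta <- sqrt(variance_explained / (2 * pq))
  freq_contrast <- 2 * beta * pq * band_mean  # tall minus short band shift
  contrast_var <- pq * (1 / (2 * n_short) + 1 / (2 * n_tall))
  ncp <- freq_contrast^2 / contrast_var
  ncp / variance_explained
}
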