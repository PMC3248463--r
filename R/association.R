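#' Stratified allele-count tables for one SNP
#'
#' Builds, per stratum, the 2x2 table of effect/other allele counts in the
#' tall (case) and short (control) groups. Missing dosages are excluded;
#' a stratum missing either group is dropped with a warning.
#'
#' @param dosage Effect-allele dosages (0/1/2/NA) for one SNP.
#' @param group Factor or character with levels among `tall`, `short`
#'   (other labels, e.g. `middle`, are ignored).
#' @param stratum Stratum labels (single stratum if `NULL`).
#' @return List of 2x2 matrices (rows `tall`, `short`; columns `effect`,
#'   `other`), class `allele_tables`.
#' @export
allele_tables <- function(dosage, group, stratum = NULL) {
  if (is.null(stratum)) stratum <- rep("all", length(dosage))
  keep <- !is.na(dosage) & group %in% c("tall", "short")
  if (!any(keep)) stop("no non-missing dosages in the tall/short groups")
  dosage <- dosage[keep]; group <- as.character(group)[keep]
  stratum <- as.character(stratum)[keep]
  out <- list()
  for (s in unique(stratum)) {
    i <- which(stratum == s)
    if (length(unique(group[i])) < 2L) {
      warning("stratum '", s, "' lacks one group; dropped")
      next
    }
    tab <- t(vapply(c("tall", "short"), function(g) {
      d <- dosage[i[group[i] == g]]
      c(effect = sum(d), other = 2 * length(d) - sum(d))
    }, numeric(2)))
    out[[s]] <- tab
  }
  if (!length(out)) stop("no stratum retained both groups")
  structure(out, class = "allele_tables")
}

#' Cochran-Mantel-Haenszel test on stratified allele tables
#'
#' The Mantel-Haenszel common odds ratio across strata, its log-scale
#' standard error by the Robins-Breslow-Greenland formula, and the 1-df
#' CMH chi-square p-value (no continuity correction). When a stratum table
#' contains a zero cell, the Haldane-Anscombe 0.5 correction is applied to
#' that stratum only for the OR/SE computation (flagged in the output);
#' the chi-square uses the raw counts.
#'
#' @param tables An [allele_tables()] list, or a single 2x2 matrix.
#' @return Data frame of class `assoc_result` with `or_obs`, `se_log_obs`,
#'   `p`, `direction`, and attribute `zero_cell_corrected`.
#' @export
cmh_test <- function(tables) {
  if (is.matrix(tables)) tables <- list(tables)
  tabs <- lapply(tables, function(t) matrix(as.numeric(t), 2, 2))
  margins_ok <- vapply(tabs, function(t) sum(t[1, ]) > 0 && sum(t[2, ]) > 0 &&
                         sum(t[, 1]) + sum(t[, 2]) > 0, logical(1))
  if (!any(margins_ok)) stop("all strata degenerate")
  tabs <- tabs[margins_ok]

  corrected <- vapply(tabs, function(t) any(t == 0), logical(1))
  ctabs <- lapply(tabs, function(t) if (any(t == 0)) t + 0.5 else t)

  # MH common OR and RBG variance on (possibly corrected) tables
  R <- vapply(ctabs, function(t) t[1, 1] * t[2, 2] / sum(t), numeric(1))
  S <- vapply(ctabs, function(t) t[1, 2] * t[2, 1] / sum(t), numeric(1))
  P <- vapply(ctabs, function(t) (t[1, 1] + t[2, 2]) / sum(t), numeric(1))
  Q <- vapply(ctabs, function(t) (t[1, 2] + t[2, 1]) / sum(t), numeric(1))
  or <- sum(R) / sum(S)
  var_log <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)

  # CMH chi-square on the raw counts
  num <- sum(vapply(tabs, function(t)
    t[1, 1] - sum(t[1, ]) * sum(t[, 1]) / sum(t), numeric(1)))
  den <- sum(vapply(tabs, function(t) {
    n <- sum(t)
    sum(t[1, ]) * sum(t[2, ]) * sum(t[, 1]) * sum(t[, 2]) / (n^2 * (n - 1))
  }, numeric(1)))
  stat <- if (den > 0) num^2 / den else 0
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)

  out <- data.frame(or_obs = or, se_log_obs = sqrt(var_log), p = p,
                    direction = expected_direction(log(or)))
  attr(out, "zero_cell_corrected") <- any(corrected)
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Logistic regression association for one SNP
#'
#' Fits a binomial log-odds model of case status on effect-allele dosage
#' (intercept + dosage) by iteratively reweighted least squares and returns
#' the per-allele odds ratio `exp(slope)` with its Wald standard error and
#' p-value. Complete separation is flagged and no estimate is returned.
#'
#' @param dosage Effect-allele dosages (0/1/2/NA).
#' @param case_status Logical or 0/1; `TRUE`/1 for cases (tall group).
#' @return Data frame of class `assoc_result` with `or_obs`, `se_log_obs`,
#'   `p`, `direction`; all `NA` with attribute `separated = TRUE` when the
#'   fit separates.
#' @export
logistic_assoc <- function(dosage, case_status) {
  keep <- !is.na(dosage) & !is.na(case_status)
  d <- dosage[keep]; y <- as.integer(case_status[keep])
  if (length(unique(y)) < 2L) stop("both case and control statuses required")
  if (stats::var(d) == 0) stop("dosage has zero variance")
  fit <- suppressWarnings(
    stats::glm(y ~ d, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  co <- summary(fit)$coefficients
  separated <- !fit$converged || abs(co["d", "Estimate"]) > 15 ||
    co["d", "Std. Error"] > 100
  if (separated) {
    out <- data.frame(or_obs = NA_real_, se_log_obs = NA_real_,
                      p = NA_real_, direction = NA_integer_)
  } else {
    out <- data.frame(or_obs = exp(co["d", "Estimate"]),
                      se_log_obs = co["d", "Std. Error"],
                      p = co["d", "Pr(>|z|)"],
                      direction = expected_direction(co["d", "Estimate"]))
  }
  attr(out, "separated") <- separated
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Fixed-effect inverse-variance meta-analysis of odds ratios
#'
#' Pools log odds ratios with weights `1 / SE^2`:
#' pooled log OR `= sum(w * logOR) / sum(w)`, `SE = 1 / sqrt(sum(w))`.
#'
#' @param log_or Numeric vector of per-study log odds ratios.
#' @param se_log Matching standard errors (positive).
#' @return Data frame of class `assoc_result` with `or_obs`, `se_log_obs`,
#'   `p` (two-sided Wald), `direction`.
#' @export
inverse_variance_meta <- function(log_or, se_log) {
  keep <- is.finite(log_or) & is.finite(se_log)
  log_or <- log_or[keep]; se_log <- se_log[keep]
  if (!length(log_or)) stop("no estimates with finite standard error")
  if (any(se_log <= 0)) stop("standard errors must be positive")
  w <- 1 / se_log^2
  est <- sum(w * log_or) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- est / se
  out <- data.frame(or_obs = exp(est), se_log_obs = se,
                    p = 2 * stats::pnorm(-abs(z)),
                    direction = expected_direction(est))
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Per-SNP association scan over a cohort
#'
#' Runs [cmh_test()] (stratified) or [logistic_assoc()] for every panel SNP
#' against the tall-vs-short contrast of a cohort.
#'
#' @param cohort A [sim_cohort] or any list with elements `dosages`,
#'   `group`, `stratum`.
#' @param panel The matching [snp_panel()].
#' @param method `"cmh"` (stratified allele-level) or `"logistic"`.
#' @return Data frame, one row per SNP: `snp_id`, `or_obs`, `se_log_obs`,
#'   `p`, `direction`.
#' @export
assoc_scan <- function(cohort, panel, method = c("cmh", "logistic")) {
  method <- match.arg(method)
  res <- lapply(seq_len(nrow(panel)), function(j) {
    d <- cohort$dosages[, j]
    r <- tryCatch(
      if (method == "cmh")
        cmh_test(allele_tables(d, cohort$group, cohort$stratum))
      else
        logistic_assoc(d, cohort$group == "tall"),
      error = function(e) data.frame(or_obs = NA_real_, se_log_obs = NA_real_,
                                     p = NA_real_, direction = NA_integer_))
    as.data.frame(r)
  })
  cbind(snp_id = panel$snp_id, do.call(rbind, res))
}

#' Direction-consistency sign test
#'
#' Counts SNPs whose observed direction of effect matches the published
#' direction and tests the count against chance (one-sided exact binomial
#' at probability 0.5). Pairs with an undefined sign are excluded.
#'
#' @param observed,expected Sign vectors in `{-1, 1, NA}`.
#' @return List with `k` matches, `n` informative pairs, and one-sided `p`.
#' @export
direction_consistency_test <- function(observed, expected) {
  keep <- !is.na(observed) & !is.na(expected)
  if (!any(keep)) stop("no informative sign pairs")
  k <- sum(observed[keep] == expected[keep])
  n <- sum(keep)
  p <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  list(k = k, n = n, p = p)
}

#' Enrichment of nominally significant associations
#'
#' Compares the number of tests below `alpha` with the count expected by
#' chance (`n * alpha`) using the exact binomial upper tail. Following the
#' aggregate-replication logic, callers typically pass p-values already
#' filtered to the direction-consistent SNPs; the filter is the caller's
#' explicit choice, not implicit here.
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param alpha Nominal significance level (default 0.05).
#' @return List with `observed`, `expected`, `n` and binomial tail `p`.
#' @examples
#' nominal_enrichment_test(rep(c(0.01, 0.5), c(49, 92)))  # 49 of 141
#' @export
nominal_enrichment_test <- function(p_values, alpha = 0.05) {
  p_values <- p_values[!is.na(p_values)]
  if (!length(p_values)) stop("no p-values supplied")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  n <- length(p_values)
  obs <- sum(p_values < alpha)
  list(observed = obs, expected = n * alpha, n = n,
       p = stats::pbinom(obs - 1, n, alpha, lower.tail = FALSE))
}
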