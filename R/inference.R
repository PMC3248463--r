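#' Null distribution of the group mean weighted allele score
#'
#' Runs the full generative pipeline per replicate — simulate genotypes,
#' form Z-scores (optionally with rare variants), ascertain under the
#' scheme, apply missingness, compute the mean WAS per group — and returns
#' the replicate mean and variance of the group mean WAS. These moments
#' define the Normal(mu_simulation, sigma^2_simulation) reference used by
#' [mean_was_pvalue()].
#'
#' @param panel A [snp_panel()].
#' @param scheme An ascertainment scheme.
#' @param rare_model Optional [rare_variant_model()].
#' @param missing_rates Optional per-SNP missing rates mirrored into every
#'   replicate.
#' @param n_replicates Number of replicates (>= 2; >= 100 recommended for
#'   inference).
#' @return Object of class `was_null`: data frame with one row per group
#'   (`group`, `mu`, `sigma2`, `n_replicates`) carrying the replicate
#'   draws in attribute `draws` (replicates x groups matrix).
#' @export
null_mean_was_distribution <- function(panel, scheme, rare_model = NULL,
                                       missing_rates = NULL,
                                       n_replicates = 1000) {
  stopifnot(n_replicates >= 2)
  if (was_variance(panel) <= 0) stop("panel has no WAS variance")
  draws <- NULL
  for (i in seq_len(n_replicates)) {
    co <- tryCatch(
      simulate_cohort(panel, scheme, rare_model, missing_rates),
      error = function(e)
        stop("replicate ", i, ": ", conditionMessage(e), call. = FALSE))
    w <- compute_was(co$dosages, panel)$score
    m <- tapply(w, co$group, mean, na.rm = TRUE)
    if (is.null(draws))
      draws <- matrix(NA_real_, n_replicates, length(m),
                      dimnames = list(NULL, names(m)))
    draws[i, names(m)] <- m
  }
  out <- data.frame(group = colnames(draws),
                    mu = colMeans(draws),
                    sigma2 = apply(draws, 2, stats::var),
                    n_replicates = n_replicates,
                    row.names = NULL)
  attr(out, "draws") <- draws
  class(out) <- c("was_null", "data.frame")
  out
}

#' Two-sided p-value of an observed mean WAS against the simulated null
#'
#' Evaluates the observed group mean score against
#' Normal(mu_simulation, sigma^2_simulation):
#' `p = 2 * min(Phi(t), 1 - Phi(t))` with
#' `t = (observed - mu) / sqrt(sigma2)`, capped at 1.
#'
#' @param observed_mean Observed group mean WAS.
#' @param null A [null_mean_was_distribution()] result or any list with
#'   `mu` and `sigma2`; when it has several groups, give `group`.
#' @param group Group label to select from a multi-group null.
#' @return Two-sided p-value.
#' @export
mean_was_pvalue <- function(observed_mean, null, group = NULL) {
  mu <- null$mu; sigma2 <- null$sigma2
  if (!is.null(group)) {
    i <- match(group, null$group)
    if (is.na(i)) stop("group '", group, "' not in null distribution")
    mu <- mu[i]; sigma2 <- sigma2[i]
  }
  if (length(mu) != 1L) stop("ambiguous null: specify group")
  if (!is.finite(sigma2) || sigma2 <= 0) stop("null sigma2 must be positive")
  t <- (observed_mean - mu) / sqrt(sigma2)
  min(1, 2 * min(stats::pnorm(t), stats::pnorm(t, lower.tail = FALSE)))
}

#' Welch t-test of tall versus short weighted allele scores
#'
#' Two-tailed two-sample t-test of the per-individual scores in the tall
#' group against the short group.
#'
#' @param was_tall,was_short Numeric score vectors (NA dropped).
#' @return List with `t`, `df` and two-sided `p`.
#' @export
tall_short_was_ttest <- function(was_tall, was_short) {
  was_tall <- was_tall[!is.na(was_tall)]
  was_short <- was_short[!is.na(was_short)]
  if (length(was_tall) < 2L || length(was_short) < 2L)
    stop("both groups need at least 2 scores")
  ht <- stats::t.test(was_tall, was_short)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Fit the observed-versus-null mean WAS comparison
#'
#' The package's central fit: given an ascertained cohort and the panel
#' that generated its scores, simulate the null distribution of the group
#' mean WAS under the matching ascertainment scheme (mirroring the
#' cohort's per-SNP missing rates) and evaluate the observed group means
#' against it. Under the purely polygenic additive model the observed
#' means sit inside the null; an upward shift of the short-group mean
#' signals that factors other than the panel's common variants shorten
#' those individuals.
#'
#' @param cohort A [sim_cohort] or compatible list (`dosages`, `z`,
#'   `group`, `stratum`).
#' @param panel The [snp_panel()].
#' @param scheme The ascertainment scheme the cohort was drawn under.
#' @param rare_model Optional [rare_variant_model()] for the null.
#' @param n_replicates Null replicates (default 1000; 10000 for
#'   publication-grade p-values).
#' @param mirror_missingness Mirror the cohort's observed per-SNP missing
#'   rates into the null replicates (default TRUE).
#' @param seed Optional seed for the null simulation.
#' @return Object of class `was_tail_test` with per-group observed means,
#'   null moments and two-sided p-values, plus the tall-vs-short Welch
#'   t-test of individual scores.
#' @examples
#' pan <- synthetic_panel(n_snps = 40, seed = 2)
#' sch <- threshold_scheme(pool_size = 4000, n_short = 40, n_tall = 40)
#' co <- simulate_cohort(pan, sch, seed = 5)
#' fit <- was_tail_test(co, pan, sch, n_replicates = 200, seed = 9)
#' fit
#' @export
was_tail_test <- function(cohort, panel, scheme, rare_model = NULL,
                          n_replicates = 1000, mirror_missingness = TRUE,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- compute_was(cohort$dosages, panel)$score
  obs <- tapply(w, cohort$group, mean, na.rm = TRUE)
  n_obs <- table(cohort$group)
  rates <- if (mirror_missingness) colMeans(is.na(cohort$dosages)) else NULL
  if (!is.null(rates) && all(rates == 0)) rates <- NULL
  null <- null_mean_was_distribution(panel, scheme, rare_model, rates,
                                     n_replicates)
  groups <- intersect(null$group, names(obs))
  res <- data.frame(
    group = groups,
    n = as.integer(n_obs[groups]),
    observed_mean = as.numeric(obs[groups]),
    mu_sim = null$mu[match(groups, null$group)],
    sigma2_sim = null$sigma2[match(groups, null$group)],
    row.names = NULL)
  res$p <- vapply(seq_len(nrow(res)), function(i)
    mean_was_pvalue(res$observed_mean[i],
                    list(mu = res$mu_sim[i], sigma2 = res$sigma2_sim[i])),
    numeric(1))
  tt <- if (all(c("tall", "short") %in% cohort$group))
    tall_short_was_ttest(w[cohort$group == "tall"],
                         w[cohort$group == "short"]) else NULL
  structure(list(table = res, null = null, ttest = tt, scores = w,
                 group = cohort$group, panel = panel, scheme = scheme,
                 rare_model = rare_model, missing_rates = rates,
                 n_replicates = n_replicates, seed = seed),
            class = "was_tail_test")
}

#' @export
print.was_tail_test <- function(x, digits = 4, ...) {
  cat("Observed vs simulated mean weighted allele score\n")
  cat("  null replicates:", x$n_replicates,
      if (!is.null(x$rare_model)) " (rare-variant scenario)" else "", "\n")
  tab <- x$table
  tab$sd_sim <- sqrt(tab$sigma2_sim)
  print(format(tab[c("group", "n", "observed_mean", "mu_sim", "sd_sim", "p")],
               digits = digits), row.names = FALSE)
  if (!is.null(x$ttest))
    cat(sprintf("Tall vs short WAS: Welch t = %.2f, p = %.3g\n",
                x$ttest$t, x$ttest$p))
  invisible(x)
}

#' @export
summary.was_tail_test <- function(object, ...) {
  cat("Polygenic tail fit:", nrow(object$panel), "SNPs;",
      length(object$scores), "individuals\n")
  print(object)
  draws <- attr(object$null, "draws")
  for (g in object$table$group) {
    sw <- stats::shapiro.test(draws[, g][seq_len(min(5000, nrow(draws)))])
    cat(sprintf("  normality of null mean WAS (%s): Shapiro W = %.3f, p = %.3g\n",
                g, sw$statistic, sw$p.value))
  }
  invisible(object)
}

#' @export
plot.was_tail_test <- function(x, groups = c("short", "tall"), ...) {
  draws <- attr(x$null, "draws")
  groups <- intersect(groups, x$table$group)
  old <- graphics::par(mfrow = c(1, length(groups)))
  on.exit(graphics::par(old))
  for (g in groups) {
    i <- match(g, x$table$group)
    graphics::hist(draws[, g], breaks = 30, main = paste(g, "extremes"),
                   xlab = "simulated mean WAS", col = "grey85", border = "white",
                   xlim = range(draws[, g], x$table$observed_mean[i]))
    graphics::abline(v = x$table$observed_mean[i], col = "red", lwd = 2)
    graphics::mtext(sprintf("observed (p = %.3g)", x$table$p[i]),
                    col = "red", cex = 0.8)
  }
  invisible(x)
}

#' Draw further null replicate means from a fitted tail test
#'
#' Re-runs the fitted null generating process (same panel, scheme, rare
#' model and mirrored missingness) for `nsim` additional replicates.
#'
#' @param object A [was_tail_test()] fit.
#' @param nsim Number of replicates.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Matrix of replicate group mean scores.
#' @export
simulate.was_tail_test <- function(object, nsim = 100, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  null <- null_mean_was_distribution(object$panel, object$scheme,
                                     object$rare_model, object$missing_rates,
                                     nsim)
  attr(null, "draws")
}

#' Band stratum of a threshold-ascertained cohort
#'
#' Defines a symmetric |Z| band stratum: the short tail is
#' `(-outer, -inner)` and the tall tail `(inner, outer)`. With
#' `outer = Inf` this is a plain more-extreme cutoff (e.g. inner 2.57 for
#' the 0.5% tails, 2.81 for 0.25%); finite `outer` gives the
#' extremes-minus-most-extreme "doughnut".
#'
#' @param label Stratum label.
#' @param inner,outer Absolute Z limits, `0 <= inner < outer`.
#' @return List of class `c("band_stratum", "stratum_spec")`.
#' @export
band_stratum <- function(label, inner, outer = Inf) {
  stopifnot(inner >= 0, outer > inner)
  structure(list(label = label, inner = inner, outer = outer),
            class = c("band_stratum", "stratum_spec"))
}

#' Quota stratum of a quota-ascertained cohort
#'
#' Restratifies by per-subpopulation extreme counts (floor of the expected
#' number in the stratum), optionally excluding the most extreme
#' individuals first (doughnut strata).
#'
#' @param label Stratum label.
#' @param quota_short,quota_tall Per-subpopulation counts per tail.
#' @param exclude_short,exclude_tall Per-subpopulation counts of most
#'   extreme individuals to exclude first.
#' @return List of class `c("quota_stratum", "stratum_spec")`.
#' @export
quota_stratum <- function(label, quota_short, quota_tall,
                          exclude_short = 0, exclude_tall = 0) {
  structure(list(label = label, quota_short = quota_short,
                 quota_tall = quota_tall, exclude_short = exclude_short,
                 exclude_tall = exclude_tall),
            class = c("quota_stratum", "stratum_spec"))
}

subset_cohort <- function(cohort, keep) {
  list(dosages = cohort$dosages[keep, , drop = FALSE],
       z = cohort$z[keep], group = cohort$group[keep],
       stratum = cohort$stratum[keep])
}

stratum_select <- function(cohort, stratum) {
  g <- cohort$group; z <- cohort$z
  if (inherits(stratum, "band_stratum")) {
    keep <- (g == "short" & z < -stratum$inner & z > -stratum$outer) |
      (g == "tall" & z > stratum$inner & z < stratum$outer)
    return(which(keep))
  }
  # quota stratum: per subpopulation, most extreme counts per tail
  keep <- integer(0)
  subs <- sort(unique(cohort$stratum[g != "middle"]))
  qs <- rep_len(stratum$quota_short, length(subs))
  qt <- rep_len(stratum$quota_tall, length(subs))
  es <- rep_len(stratum$exclude_short, length(subs))
  et <- rep_len(stratum$exclude_tall, length(subs))
  for (k in seq_along(subs)) {
    i_s <- which(g == "short" & cohort$stratum == subs[k])
    i_t <- which(g == "tall" & cohort$stratum == subs[k])
    ns <- min(qs[k], max(0, length(i_s) - es[k]))
    nt <- min(qt[k], max(0, length(i_t) - et[k]))
    if (ns > 0) keep <- c(keep, i_s[order(z[i_s])][es[k] + seq_len(ns)])
    if (nt > 0) keep <- c(keep, i_t[order(-z[i_t])][et[k] + seq_len(nt)])
  }
  keep
}

stratum_scheme <- function(stratum, base_scheme, n_short, n_tall) {
  if (inherits(stratum, "band_stratum")) {
    threshold_scheme(cutoff_short = -stratum$inner,
                     cutoff_tall = stratum$inner,
                     n_short = n_short, n_tall = n_tall,
                     pool_size = pool_size_of(base_scheme),
                     outer_short = -stratum$outer,
                     outer_tall = stratum$outer)
  } else {
    quota_scheme(subpop_sizes = base_scheme$subpop_sizes,
                 quota_short = stratum$quota_short,
                 quota_tall = stratum$quota_tall,
                 final_short = n_short, final_tall = n_tall,
                 exclude_short = stratum$exclude_short,
                 exclude_tall = stratum$exclude_tall)
  }
}

#' Stratified observed-versus-null tail analysis
#'
#' For each stratum, re-selects the observed individuals (Z band for
#' threshold designs, per-subpopulation quota with the floor rule for
#' quota designs), re-simulates the null with matched group sizes under a
#' stratum-matched scheme, and reports the observed mean WAS, null
#' moments and two-sided p per tail — the progressive-stratification
#' table showing where the polygenic model breaks down.
#'
#' @param cohort The observed (or simulated) cohort.
#' @param strata List of [band_stratum()] / [quota_stratum()] specs.
#' @param panel,scheme,rare_model,n_replicates Passed to the null
#'   simulation for each stratum.
#' @param mirror_missingness Mirror observed missing rates (default TRUE).
#' @param seed Optional seed.
#' @return Data frame: one row per stratum x group with sizes, observed
#'   mean, null `mu`/`sigma2` and `p` (NA rows for empty strata).
#' @export
stratified_tail_analysis <- function(cohort, strata, panel, scheme,
                                     rare_model = NULL, n_replicates = 500,
                                     mirror_missingness = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (st in strata) {
    keep <- stratum_select(cohort, st)
    sub <- subset_cohort(cohort, keep)
    ns <- sum(sub$group == "short"); nt <- sum(sub$group == "tall")
    if (ns == 0 || nt == 0) {
      out[[st$label]] <- data.frame(
        stratum = st$label, group = c("short", "tall"), n = c(ns, nt),
        observed_mean = NA_real_, mu_sim = NA_real_, sigma2_sim = NA_real_,
        p = NA_real_)
      next
    }
    sch <- stratum_scheme(st, scheme, ns, nt)
    fit <- was_tail_test(sub, panel, sch, rare_model, n_replicates,
                         mirror_missingness)
    tab <- fit$table
    out[[st$label]] <- cbind(stratum = st$label,
                             tab[c("group", "n", "observed_mean",
                                   "mu_sim", "sigma2_sim", "p")])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rare-variant scenario comparison
#'
#' Rebuilds the null distribution of the group mean WAS under each
#' candidate rare-variant scenario and evaluates the observed group means
#' against it, flagging scenarios consistent (p > 0.05) with the data.
#' Planted height-decreasing rare variants shift the simulated short-group
#' mean WAS upward (the rare allele, not the common panel, explains part
#' of the shortness), so an observed cohort is consistent only with
#' scenarios of comparable aggregate rare-variant effect.
#'
#' @param cohort Observed cohort.
#' @param scenarios Named list of [rare_variant_model()]s; `NULL` elements
#'   denote the pure polygenic null.
#' @param panel,scheme,n_replicates,mirror_missingness,seed As in
#'   [was_tail_test()].
#' @return Data frame: scenario x group rows with observed mean, null
#'   moments, `p` and `consistent`.
#' @export
scenario_comparison <- function(cohort, scenarios, panel, scheme,
                                n_replicates = 500,
                                mirror_missingness = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(scenarios)) || any(!nzchar(names(scenarios))))
    names(scenarios) <- paste0("scenario", seq_along(scenarios))
  out <- list()
  for (nm in names(scenarios)) {
    fit <- was_tail_test(cohort, panel, scheme, scenarios[[nm]],
                         n_replicates, mirror_missingness)
    tab <- fit$table
    out[[nm]] <- cbind(scenario = nm,
                       tab[c("group", "n", "observed_mean",
                             "mu_sim", "sigma2_sim", "p")],
                       consistent = tab$p > 0.05)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
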