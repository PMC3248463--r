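#' Rare-variant extension of the polygenic model
#'
#' Specifies `n` additional independent variants of frequency `F` and
#' per-allele effect `B` (SD units) added to the generative Z-score model.
#' Their score is centered by `alpha_rv = sum(B * 2 * F)` so the expected
#' Z-score stays 0, and the residual variance is reduced by
#' `var = sum(B^2 * 2 * F * (1 - F))` so the marginal Z variance stays 1.
#' The rare variants affect the simulated phenotype only; the weighted
#' allele score is still computed from the common panel alone.
#'
#' @param n Number of variants (used to recycle scalar `B`, `F`).
#' @param B Per-allele effect size(s), SD units (negative = trait-decreasing).
#' @param F Allele frequency(ies), in (0, 1).
#' @return List of class `rare_variant_model` with `B`, `F`, `alpha_rv`,
#'   `variance`.
#' @examples
#' rare_variant_model(1, B = -2, F = 0.005)
#' rare_variant_model(10, B = -1, F = 0.005)
#' @export
rare_variant_model <- function(n = length(B), B, F) {
  B <- rep_len(as.numeric(B), n)
  F <- rep_len(as.numeric(F), n)
  stopifnot(n >= 1, all(F > 0), all(F < 1))
  structure(list(B = B, F = F,
                 alpha_rv = sum(B * 2 * F),
                 variance = sum(B^2 * 2 * F * (1 - F))),
            class = "rare_variant_model")
}

#' Quota-based ascertainment scheme
#'
#' Mimics extreme-sample selection from several subpopulations: from each
#' subpopulation the most extreme `quota` individuals per tail are taken,
#' the tails are pooled across subpopulations, and individuals are randomly
#' dropped to exact final group sizes. Defaults follow a four-subpopulation
#' survey design (geography x gender strata of 4271/6582/5025/7610
#' individuals, ~50 per tail each, final 181 short and 192 tall).
#'
#' @param subpop_sizes Integer vector of subpopulation sample sizes.
#' @param quota_short,quota_tall Per-subpopulation quotas per tail
#'   (recycled to the number of subpopulations).
#' @param final_short,final_tall Exact final group sizes after pooling
#'   (`NULL` keeps all quota-selected individuals).
#' @param exclude_short,exclude_tall Per-subpopulation counts of the most
#'   extreme individuals to exclude before applying quotas (0 = none);
#'   supports "doughnut" strata that drop the most extreme individuals.
#' @return List of class `c("quota_scheme", "ascertainment_scheme")`.
#' @export
quota_scheme <- function(subpop_sizes = c(4271, 6582, 5025, 7610),
                         quota_short = 50, quota_tall = 50,
                         final_short = 181, final_tall = 192,
                         exclude_short = 0, exclude_tall = 0) {
  k <- length(subpop_sizes)
  quota_short <- rep_len(quota_short, k); quota_tall <- rep_len(quota_tall, k)
  exclude_short <- rep_len(exclude_short, k)
  exclude_tall <- rep_len(exclude_tall, k)
  if (any(quota_short + exclude_short > subpop_sizes) ||
      any(quota_tall + exclude_tall > subpop_sizes))
    stop("quota exceeds subpopulation size")
  structure(list(subpop_sizes = subpop_sizes,
                 quota_short = quota_short, quota_tall = quota_tall,
                 final_short = final_short, final_tall = final_tall,
                 exclude_short = exclude_short, exclude_tall = exclude_tall),
            class = c("quota_scheme", "ascertainment_scheme"))
}

#' Threshold-based ascertainment scheme
#'
#' Mimics selection of all individuals beyond symmetric Z cutoffs followed
#' by random subsampling to target group sizes. Defaults follow a
#' single-population survey design (50,000 genotyped individuals, cutoffs
#' -2.14/+2.14, 385 short and 456 tall extremes). An optional outer bound
#' restricts selection to a Z band (e.g. the ~1.5%-to-0.25% "doughnut"
#' 2.14 < |Z| < 2.81), and an optional middle group of `n_middle`
#' individuals with |Z| below `middle_limit` can be drawn.
#'
#' @param cutoff_short,cutoff_tall Inner Z cutoffs (short tail selects
#'   `Z < cutoff_short`, tall selects `Z > cutoff_tall`).
#' @param n_short,n_tall Target group sizes after subsampling (`NULL`
#'   keeps all selected).
#' @param pool_size Number of individuals simulated per replicate.
#' @param outer_short,outer_tall Optional outer |Z| bounds making each tail
#'   a band (`-Inf`/`Inf` = unbounded).
#' @param n_middle,middle_limit Optional middle-group draw.
#' @return List of class `c("threshold_scheme", "ascertainment_scheme")`.
#' @export
threshold_scheme <- function(cutoff_short = -2.14, cutoff_tall = 2.14,
                             n_short = 385, n_tall = 456,
                             pool_size = 50000,
                             outer_short = -Inf, outer_tall = Inf,
                             n_middle = 0, middle_limit = 2) {
  stopifnot(is.finite(cutoff_short), is.finite(cutoff_tall),
            cutoff_short < cutoff_tall,
            outer_short <= cutoff_short, outer_tall >= cutoff_tall)
  structure(list(cutoff_short = cutoff_short, cutoff_tall = cutoff_tall,
                 n_short = n_short, n_tall = n_tall, pool_size = pool_size,
                 outer_short = outer_short, outer_tall = outer_tall,
                 n_middle = n_middle, middle_limit = middle_limit),
            class = c("threshold_scheme", "ascertainment_scheme"))
}

pool_size_of <- function(scheme) {
  if (inherits(scheme, "quota_scheme")) sum(scheme$subpop_sizes)
  else scheme$pool_size
}

#' Simulate effect-allele dosages at panel frequencies
#'
#' Independent biallelic SNPs without linkage disequilibrium: each dosage
#' is drawn Binomial(2, eaf_j). Uses the current RNG state.
#'
#' @param panel A [snp_panel()].
#' @param n Number of individuals.
#' @return Integer matrix, `n` x `nrow(panel)`, columns named by snp_id.
#' @export
simulate_genotypes <- function(panel, n) {
  stopifnot(n >= 1)
  m <- nrow(panel)
  d <- matrix(stats::rbinom(n * m, 2L, rep(panel$eaf, each = n)), n, m)
  colnames(d) <- panel$snp_id
  d
}

#' Simulate phenotype Z-scores under the polygenic (+ rare-variant) model
#'
#' The null model takes `Z = WAS + N(0, sigma^2_remaining)` with
#' `sigma^2_remaining = 1 - var(WAS)`, so Z is marginally standard normal.
#' With a [rare_variant_model()], a centered rare-variant score
#' `sum(B * dosage_rv) - alpha_rv` is added and the residual variance is
#' reduced by the rare-variant variance.
#'
#' @param dosages Dosage matrix from [simulate_genotypes()].
#' @param panel The matching [snp_panel()].
#' @param rare_model Optional [rare_variant_model()].
#' @return List with `z`, `was` (the common-panel score), and
#'   `rare_score` (0 when no rare model).
#' @export
simulate_zscores <- function(dosages, panel, rare_model = NULL) {
  n <- nrow(dosages)
  was <- as.vector(dosages %*% panel$beta) - was_alpha(panel)
  rare <- 0
  sigma2 <- 1 - was_variance(panel)
  if (!is.null(rare_model)) {
    sigma2 <- sigma2 - rare_model$variance
    if (sigma2 <= 0)
      stop("rare-variant variance exhausts the residual variance budget")
    k <- length(rare_model$B)
    drv <- matrix(stats::rbinom(n * k, 2L, rep(rare_model$F, each = n)), n, k)
    rare <- as.vector(drv %*% rare_model$B) - rare_model$alpha_rv
  }
  z <- was + rare + stats::rnorm(n, 0, sqrt(sigma2))
  list(z = z, was = was, rare_score = rare)
}

#' Quota ascertainment of simulated extremes
#'
#' Assigns individuals to subpopulations, takes the most extreme `quota`
#' per tail within each (after skipping any `exclude` most extreme), pools
#' the tails and randomly drops to the exact final sizes. Rank ties are
#' broken by seeded uniform jitter.
#'
#' @param z Z-score vector for the whole pool.
#' @param scheme A [quota_scheme()]; `sum(subpop_sizes)` must not exceed
#'   `length(z)`.
#' @return List with integer `index` into `z`, `group` (`short`/`tall`)
#'   and `stratum` (subpopulation label) for the selected individuals.
#' @export
ascertain_quota <- function(z, scheme) {
  n <- length(z)
  sizes <- scheme$subpop_sizes
  if (sum(sizes) > n) stop("pool smaller than total subpopulation size")
  assign_idx <- sample.int(n, sum(sizes))
  subpop <- rep(seq_along(sizes), sizes)
  idx_s <- integer(0); idx_t <- integer(0)
  str_s <- integer(0); str_t <- integer(0)
  for (s in seq_along(sizes)) {
    i <- assign_idx[subpop == s]
    ord <- order(z[i], stats::runif(length(i)))
    ns <- scheme$quota_short[s]; nt <- scheme$quota_tall[s]
    es <- scheme$exclude_short[s]; et <- scheme$exclude_tall[s]
    sel_s <- if (ns > 0) i[ord][es + seq_len(ns)] else integer(0)
    sel_t <- if (nt > 0) i[rev(ord)][et + seq_len(nt)] else integer(0)
    idx_s <- c(idx_s, sel_s); str_s <- c(str_s, rep(s, ns))
    idx_t <- c(idx_t, sel_t); str_t <- c(str_t, rep(s, nt))
  }
  drop_to <- function(idx, str, final) {
    if (is.null(final)) return(list(idx = idx, str = str))
    if (final > length(idx)) stop("final group size exceeds pooled quota")
    keep <- sort(sample.int(length(idx), final))
    list(idx = idx[keep], str = str[keep])
  }
  s <- drop_to(idx_s, str_s, scheme$final_short)
  t <- drop_to(idx_t, str_t, scheme$final_tall)
  list(index = c(s$idx, t$idx),
       group = rep(c("short", "tall"), c(length(s$idx), length(t$idx))),
       stratum = paste0("subpop", c(s$str, t$str)))
}

#' Threshold ascertainment of simulated extremes
#'
#' Selects all individuals beyond the scheme's Z cutoffs (within the outer
#' band bounds if set), then randomly subsamples each tail to its target
#' size; optionally draws a middle group from `|Z| < middle_limit`.
#'
#' @param z Z-score vector for the whole pool.
#' @param scheme A [threshold_scheme()].
#' @return List with `index`, `group` (`short`/`tall`/`middle`) and
#'   `stratum` (`"all"`).
#' @export
ascertain_threshold <- function(z, scheme) {
  short_all <- which(z < scheme$cutoff_short & z > scheme$outer_short)
  tall_all <- which(z > scheme$cutoff_tall & z < scheme$outer_tall)
  pick <- function(idx, target, tail) {
    if (is.null(target)) return(idx)
    if (length(idx) < target)
      stop("insufficient ", tail, " extremes: ", length(idx),
           " available, ", target, " requested (increase the pool)")
    sort(sample(idx, target))
  }
  idx_s <- pick(short_all, scheme$n_short, "short")
  idx_t <- pick(tall_all, scheme$n_tall, "tall")
  idx_m <- integer(0)
  if (scheme$n_middle > 0) {
    mid <- which(abs(z) < scheme$middle_limit)
    idx_m <- pick(mid, scheme$n_middle, "middle")
  }
  list(index = c(idx_s, idx_t, idx_m),
       group = rep(c("short", "tall", "middle"),
                   c(length(idx_s), length(idx_t), length(idx_m))),
       stratum = rep("all", length(idx_s) + length(idx_t) + length(idx_m)))
}

#' Apply per-SNP random missingness to a dosage matrix
#'
#' Each cell is set missing independently with its SNP's rate, emulating
#' genotyping dropout. Missingness is independent of the dosage value.
#'
#' @param dosages Dosage matrix.
#' @param rates Per-SNP missing rates in `[0, 1)`, recycled across SNPs.
#' @return The matrix with `NA` in dropped cells.
#' @export
apply_missingness <- function(dosages, rates) {
  rates <- rep_len(rates, ncol(dosages))
  if (any(rates < 0 | rates >= 1)) stop("missing rates must lie in [0, 1)")
  if (all(rates == 0)) return(dosages)
  n <- nrow(dosages)
  drop <- matrix(stats::runif(n * ncol(dosages)) <
                   rep(rates, each = n), n, ncol(dosages))
  dosages[drop] <- NA
  dosages
}

#' Simulate an ascertained cohort
#'
#' One end-to-end replicate of the generative pipeline: draw panel dosages
#' for the scheme's pool, form Z-scores under the polygenic model (with an
#' optional rare-variant extension), ascertain extremes under the scheme,
#' and apply per-SNP missingness to the selected individuals.
#'
#' @param panel A [snp_panel()].
#' @param scheme A [quota_scheme()] or [threshold_scheme()].
#' @param rare_model Optional [rare_variant_model()].
#' @param missing_rates Optional per-SNP missing rates.
#' @param seed Optional integer seed set before simulation and recorded in
#'   the result.
#' @return List of class `sim_cohort`: `dosages` (selected individuals x
#'   SNPs, with missingness applied), `z`, `group`, `stratum`, `seed`.
#' @examples
#' pan <- synthetic_panel(n_snps = 20, seed = 1)
#' co <- simulate_cohort(pan, threshold_scheme(pool_size = 2000,
#'                       n_short = 20, n_tall = 20), seed = 7)
#' table(co$group)
#' @export
simulate_cohort <- function(panel, scheme, rare_model = NULL,
                            missing_rates = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- simulate_genotypes(panel, pool_size_of(scheme))
  sim <- simulate_zscores(d, panel, rare_model)
  sel <- if (inherits(scheme, "quota_scheme")) ascertain_quota(sim$z, scheme)
  else ascertain_threshold(sim$z, scheme)
  dos <- d[sel$index, , drop = FALSE]
  if (!is.null(missing_rates)) dos <- apply_missingness(dos, missing_rates)
  structure(list(dosages = dos, z = sim$z[sel$index], group = sel$group,
                 stratum = sel$stratum, seed = seed, panel_ids = panel$snp_id),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated ascertained cohort:",
      nrow(x$dosages), "individuals x", ncol(x$dosages), "SNPs\n")
  print(table(group = x$group, stratum = x$stratum))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing dosage rate: %.3f%%", 100 * miss))
  if (!is.null(x$seed)) cat("  (seed ", x$seed, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Simulate sibling pairs of phenotype Z-scores
#'
#' Draws pairs from a standard bivariate normal with correlation `r`
#' (both marginals standard normal), the additive expectation for full
#' siblings when `r` is the phenotypic sibling correlation.
#'
#' @param n_pairs Number of pairs.
#' @param r Sibling correlation, in (-1, 1).
#' @return Data frame with `proband_z` and `sibling_z`.
#' @export
simulate_sibling_pairs <- function(n_pairs, r) {
  stopifnot(n_pairs >= 1, r > -1, r < 1)
  z1 <- stats::rnorm(n_pairs)
  z2 <- r * z1 + stats::rnorm(n_pairs, 0, sqrt(1 - r^2))
  data.frame(proband_z = z1, sibling_z = z2)
}

#' Synthetic SNP effect panel
#'
#' Generates a panel emulating GWAS-discovered common height variants:
#' exponentially decaying effect sizes of a few hundredths of an SD with a
#' random sign mix, and intermediate allele frequencies. The defaults (160
#' SNPs, mean |beta| 0.028 SD) make the panel explain about 10% of the
#' trait variance, the level reported for common-variant height panels.
#' This synthetic panel is the bundled stand-in for a real
#' summary-statistic panel (whose values are not redistributable).
#'
#' @param n_snps Number of SNPs (default 160, the scale of a genotyped
#'   common-variant height panel).
#' @param mean_abs_beta Mean absolute effect size, SD units.
#' @param freq_range Range of effect-allele frequencies.
#' @param seed Optional seed.
#' @return A [snp_panel()].
#' @export
synthetic_panel <- function(n_snps = 160, mean_abs_beta = 0.028,
                            freq_range = c(0.1, 0.9), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  beta <- stats::rexp(n_snps, 1 / mean_abs_beta) *
    sample(c(-1, 1), n_snps, replace = TRUE)
  beta <- pmax(pmin(beta, 0.25), -0.25)
  eaf <- stats::runif(n_snps, freq_range[1], freq_range[2])
  snp_panel(sprintf("snp%03d", seq_len(n_snps)),
            effect_allele = sample(c("A", "C", "G", "T"), n_snps, TRUE),
            other_allele = "X",  # placeholder replaced below
            beta = beta, se = abs(beta) / 4 + 0.004, eaf = eaf) -> dummy
  # pick a distinct other allele per SNP
  dummy$other_allele <- vapply(dummy$effect_allele, function(a)
    sample(setdiff(c("A", "C", "G", "T"), a), 1), character(1))
  validate_snp_panel(dummy)
}
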