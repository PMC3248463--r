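test_that("simulated dosages have binomial moments at panel frequencies", {
  set.seed(21)
  pan <- snp_panel(c("a", "b", "c"), "A", "G", beta = 0.02, se = 0.005,
                   eaf = c(0.5, 0.1, 0.999))
  d <- simulate_genotypes(pan, 1e5)
  expect_equal(colMeans(d), 2 * pan$eaf, tolerance = 0.02,
               ignore_attr = TRUE)
  expect_equal(apply(d, 2, var), 2 * pan$eaf * (1 - pan$eaf),
               tolerance = 0.05, ignore_attr = TRUE)
  expect_true(all(d[, 3] >= 1))  # near-fixed allele is almost surely dosage 2
  expect_true(all(d %in% 0:2))
})

test_that("Z-scores are marginally standard normal under the null model", {
  set.seed(22)
  pan <- uniform_panel(n = 50)
  d <- simulate_genotypes(pan, 2e5)
  sim <- simulate_zscores(d, pan)
  expect_equal(var(sim$z), 1, tolerance = 0.02)
  expect_lt(abs(mean(sim$z)), 0.01)
  expect_equal(var(sim$was), was_variance(pan), tolerance = 0.05)
})

test_that("rare carriers are shifted by the rare effect size", {
  set.seed(23)
  pan <- uniform_panel(n = 20)
  rv <- rare_variant_model(1, B = -2, F = 0.005)
  expect_equal(rv$alpha_rv, -2 * 2 * 0.005)
  expect_equal(rv$variance, 4 * 2 * 0.005 * 0.995)
  d <- simulate_genotypes(pan, 4e5)
  sim <- simulate_zscores(d, pan, rv)
  expect_equal(var(sim$z), 1, tolerance = 0.02)
  carrier <- sim$rare_score < -1  # at least one copy of the rare allele
  expect_equal(mean(sim$z[carrier]) - mean(sim$z[!carrier]), -2,
               tolerance = 0.05)
  # an overloaded rare model exhausts the variance budget
  expect_error(simulate_zscores(d[1:10, ], pan,
                                rare_variant_model(100, B = -5, F = 0.2)),
               "variance budget")
})

test_that("quota ascertainment takes the most extreme per subpopulation", {
  set.seed(24)
  z <- rnorm(500)
  sch <- quota_scheme(subpop_sizes = c(100, 150), quota_short = c(5, 8),
                      quota_tall = c(6, 7), final_short = 10, final_tall = 11)
  sel <- ascertain_quota(z, sch)
  expect_equal(sum(sel$group == "short"), 10)
  expect_equal(sum(sel$group == "tall"), 11)
  expect_lt(max(z[sel$index[sel$group == "short"]]),
            min(z[sel$index[sel$group == "tall"]]))
  # quota = subpopulation size selects everyone
  sch_all <- quota_scheme(subpop_sizes = 20, quota_short = 10,
                          quota_tall = 10, final_short = NULL,
                          final_tall = NULL)
  sel_all <- ascertain_quota(rnorm(20), sch_all)
  expect_equal(sort(sel_all$index), 1:20)
  # order statistic: selected shorts are more extreme than unselected
  sch1 <- quota_scheme(subpop_sizes = 500, quota_short = 20, quota_tall = 20,
                       final_short = NULL, final_tall = NULL)
  s1 <- ascertain_quota(z, sch1)
  shorts <- s1$index[s1$group == "short"]
  expect_lt(max(z[shorts]), min(z[-s1$index]))
  expect_error(quota_scheme(subpop_sizes = 10, quota_short = 11), "exceeds")
})

test_that("stratum quotas follow the survey counts before dropping", {
  # the published 0.5% stratum counts per subpopulation sum to 116 per tail
  set.seed(25)
  sch <- quota_scheme(quota_short = c(21, 32, 25, 38),
                      quota_tall = c(21, 32, 25, 38),
                      final_short = NULL, final_tall = NULL)
  sel <- ascertain_quota(rnorm(sum(sch$subpop_sizes)), sch)
  expect_equal(sum(sel$group == "short"), 116)
  expect_equal(sum(sel$group == "tall"), 116)
})

test_that("threshold ascertainment selects beyond cutoffs then subsamples", {
  set.seed(26)
  z <- rnorm(50000)
  sch <- threshold_scheme(pool_size = 50000)
  sel <- ascertain_threshold(z, sch)
  expect_equal(sum(sel$group == "short"), 385)
  expect_equal(sum(sel$group == "tall"), 456)
  expect_true(all(z[sel$index[sel$group == "short"]] < -2.14))
  expect_true(all(z[sel$index[sel$group == "tall"]] > 2.14))
  # tail-mass oracle: about 50000 * (1 - Phi(2.14)) = 810 available per tail
  expect_equal(sum(z > 2.14), 50000 * pnorm(2.14, lower.tail = FALSE),
               tolerance = 0.12)
  # cutoff 0 with no targets partitions the cohort into the two tails
  sel0 <- ascertain_threshold(z, threshold_scheme(
    cutoff_short = -1e-12, cutoff_tall = 1e-12, n_short = NULL,
    n_tall = NULL, pool_size = 50000))
  expect_equal(length(sel0$index), 50000)
  expect_error(
    ascertain_threshold(z, threshold_scheme(cutoff_short = -6,
                                            cutoff_tall = 6,
                                            pool_size = 50000)),
    "insufficient")
  # band (doughnut) selection respects the outer bound
  selb <- ascertain_threshold(z, threshold_scheme(
    n_short = 50, n_tall = 50, pool_size = 50000,
    outer_short = -2.81, outer_tall = 2.81))
  expect_true(all(abs(z[selb$index]) < 2.81 & abs(z[selb$index]) > 2.14))
})

test_that("missingness hits cells at the nominal rate, independent of dosage", {
  set.seed(27)
  pan <- uniform_panel(n = 10)
  d <- simulate_genotypes(pan, 2e4)
  expect_identical(apply_missingness(d, 0), d)
  dm <- apply_missingness(d, 0.02)
  expect_equal(mean(is.na(dm)), 0.02, tolerance = 0.05)
  # independence of dropout and dosage value
  chi <- chisq.test(table(missing = is.na(dm[, 1]), dosage = d[, 1]))
  expect_gt(chi$p.value, 0.01)
  expect_error(apply_missingness(d, 1), "\\[0, 1\\)")
})

test_that("sibling pairs follow the bivariate normal with correlation r", {
  set.seed(28)
  p0 <- simulate_sibling_pairs(5e4, 0)
  expect_lt(abs(cor(p0$proband_z, p0$sibling_z)), 0.015)
  pr <- simulate_sibling_pairs(1e5, 0.466)
  expect_equal(cor(pr$proband_z, pr$sibling_z), 0.466, tolerance = 0.02)
  expect_equal(var(pr$sibling_z), 1, tolerance = 0.02)
  # E[sibling | proband = z] is r * z: binned regression slope
  expect_equal(unname(coef(lm(sibling_z ~ proband_z, pr))[2]), 0.466,
               tolerance = 0.02)
})

test_that("end-to-end simulated cohorts separate tall and short scores", {
  # quota-ascertained null cohorts show the mean-WAS separation
  pan <- synthetic_panel(n_snps = 80, mean_abs_beta = 0.05, seed = 31)
  sch <- quota_scheme(subpop_sizes = c(500, 500, 500, 500),
                      quota_short = 10, quota_tall = 10,
                      final_short = 35, final_tall = 38)
  seps <- vapply(1:20, function(i) {
    co <- simulate_cohort(pan, sch, seed = 100 + i)
    w <- compute_was(co$dosages, pan)$score
    mean(w[co$group == "tall"]) - mean(w[co$group == "short"])
  }, numeric(1))
  expect_true(all(seps > 0))
})

test_that("extra null-like common SNPs leave the original-panel score null", {
  pan <- uniform_panel(n = 60, beta = 0.05, eaf = 0.3)
  extra <- snp_panel(sprintf("x%03d", 1:180), "A", "G", beta = -0.05,
                     se = 0.007, eaf = 0.3)
  aug <- as_snp_panel(rbind(as.data.frame(pan),
                                  as.data.frame(extra)))
  sch <- threshold_scheme(pool_size = 8000, n_short = 80, n_tall = 80)
  set.seed(41)
  base <- null_mean_was_distribution(pan, sch, n_replicates = 150)
  set.seed(41)
  # same ascertainment with the extra variants in the generative model,
  # scoring only the original panel columns
  draws <- replicate(150, {
    co <- simulate_cohort(aug, sch)
    w <- compute_was(co$dosages[, seq_len(nrow(pan)), drop = FALSE], pan)
    tapply(w$score, co$group, mean)
  })
  mu_short <- mean(draws["short", ])
  i <- match("short", base$group)
  expect_equal(mu_short, base$mu[i],
               tolerance = 3 * sqrt(2 * base$sigma2[i] / 150) /
                 abs(base$mu[i]))
})
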