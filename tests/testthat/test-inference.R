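test_that("mean-WAS p-value evaluates the simulated normal reference", {
  null <- list(mu = 0.1, sigma2 = 0.04)
  expect_equal(mean_was_pvalue(0.1, null), 1)
  expect_equal(mean_was_pvalue(0.1 + 1.96 * 0.2, null), 0.05,
               tolerance = 1e-3)
  expect_equal(mean_was_pvalue(0.1 - 1.96 * 0.2, null),
               mean_was_pvalue(0.1 + 1.96 * 0.2, null))
  expect_error(mean_was_pvalue(0, list(mu = 0, sigma2 = 0)), "positive")
})

test_that("tall-vs-short t-test matches the Welch formula on a toy", {
  a <- c(0.1, 0.2, 0.4); b <- c(-0.1, 0.0, -0.3)
  got <- tall_short_was_ttest(a, b)
  se <- sqrt(var(a) / 3 + var(b) / 3)
  expect_equal(got$t, (mean(a) - mean(b)) / se)
  df <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(got$df, df)
  same <- tall_short_was_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("the null distribution shows selection-induced score shifts", {
  pan <- synthetic_panel(n_snps = 60, mean_abs_beta = 0.05, seed = 51)
  sch <- threshold_scheme(pool_size = 6000, n_short = 50, n_tall = 50)
  set.seed(52)
  null <- null_mean_was_distribution(pan, sch, n_replicates = 120)
  mu_s <- null$mu[null$group == "short"]
  mu_t <- null$mu[null$group == "tall"]
  expect_lt(mu_s, 0)
  expect_gt(mu_t, 0)
  expect_true(all(null$sigma2 > 0))
  draws <- attr(null, "draws")
  expect_equal(dim(draws), c(120, 2))
  # planted height-decreasing rare variants pull the short-group score
  # null upward (the rare allele explains part of the shortness)
  set.seed(52)
  null_rv <- null_mean_was_distribution(
    pan, sch, rare_model = rare_variant_model(1, B = -2, F = 0.005),
    n_replicates = 120)
  expect_gt(null_rv$mu[null_rv$group == "short"], mu_s)
  # tall side is essentially unaffected by a height-decreasing variant
  expect_equal(null_rv$mu[null_rv$group == "tall"], mu_t,
               tolerance = 0.25)
})

test_that("replicate mean scores pass normality at survey-style group sizes", {
  pan <- synthetic_panel(n_snps = 60, mean_abs_beta = 0.05, seed = 53)
  sch <- threshold_scheme(pool_size = 6000, n_short = 50, n_tall = 50)
  set.seed(54)
  null <- null_mean_was_distribution(pan, sch, n_replicates = 200)
  draws <- attr(null, "draws")
  expect_gt(shapiro.test(draws[, "short"])$p.value, 0.01)
  expect_gt(shapiro.test(draws[, "tall"])$p.value, 0.01)
})

test_that("the tail-test fit is calibrated under its own null", {
  pan <- synthetic_panel(n_snps = 50, mean_abs_beta = 0.05, seed = 55)
  sch <- threshold_scheme(pool_size = 6000, n_short = 40, n_tall = 40)
  co <- simulate_cohort(pan, sch, seed = 56)
  fit <- was_tail_test(co, pan, sch, n_replicates = 150, seed = 57)
  expect_s3_class(fit, "was_tail_test")
  expect_setequal(fit$table$group, c("short", "tall"))
  expect_true(all(fit$table$p >= 0 & fit$table$p <= 1))
  expect_lt(fit$ttest$p, 1e-6)  # tall and short scores separate strongly
  expect_output(print(fit), "Observed vs simulated")
  # missingness mirroring: the null replicates see the cohort's rates
  co_miss <- simulate_cohort(pan, sch, missing_rates = 0.05, seed = 58)
  fit_miss <- was_tail_test(co_miss, pan, sch, n_replicates = 50, seed = 59)
  expect_equal(mean(fit_miss$missing_rates), 0.05, tolerance = 0.25)
})

test_that("a full-cohort stratum reproduces the unstratified analysis", {
  pan <- synthetic_panel(n_snps = 50, mean_abs_beta = 0.05, seed = 61)
  sch <- threshold_scheme(pool_size = 20000, n_short = 60, n_tall = 60)
  co <- simulate_cohort(pan, sch, seed = 62)
  full <- band_stratum("all", inner = 2.14)
  strat <- stratified_tail_analysis(co, list(full), pan, sch,
                                    n_replicates = 100, seed = 63)
  expect_equal(strat$n[strat$group == "short"], 60)
  expect_equal(strat$n[strat$group == "tall"], 60)
  w <- compute_was(co$dosages, pan)$score
  expect_equal(strat$observed_mean[strat$group == "short"],
               mean(w[co$group == "short"]))
  # a more extreme band keeps only its members, a doughnut drops them
  inner <- band_stratum("extreme", inner = 2.81)
  ring <- band_stratum("ring", inner = 2.14, outer = 2.81)
  st2 <- stratified_tail_analysis(co, list(inner, ring), pan, sch,
                                  n_replicates = 50, seed = 64)
  n_inner <- st2$n[st2$stratum == "extreme"]
  n_ring <- st2$n[st2$stratum == "ring"]
  expect_equal(n_inner + n_ring, c(60, 60))
  expect_equal(sum(abs(co$z) > 2.81), sum(n_inner))
})

test_that("scenario comparison accepts the generating model, rejects others", {
  pan <- synthetic_panel(n_snps = 50, mean_abs_beta = 0.05, seed = 71)
  sch <- threshold_scheme(pool_size = 8000, n_short = 60, n_tall = 60)
  co <- simulate_cohort(pan, sch, seed = 72)  # pure polygenic cohort
  res <- scenario_comparison(
    co, list(null = NULL, big = rare_variant_model(1, B = -4, F = 0.005)),
    pan, sch, n_replicates = 150, seed = 73)
  expect_true(res$consistent[res$scenario == "null" & res$group == "short"])
  expect_false(res$consistent[res$scenario == "big" & res$group == "short"])
  # against the overly strong scenario the observed short mean sits BELOW
  # the scenario null mean (opposite-direction rejection)
  expect_lt(res$observed_mean[res$scenario == "big" & res$group == "short"],
            res$mu_sim[res$scenario == "big" & res$group == "short"])
})

test_that("rare-effect severity moves only the short-tail p-value", {
  pan <- synthetic_panel(n_snps = 50, mean_abs_beta = 0.05, seed = 81)
  sch <- threshold_scheme(pool_size = 8000, n_short = 60, n_tall = 60)
  set.seed(82)
  null <- null_mean_was_distribution(pan, sch, n_replicates = 200)
  models <- list(rare_variant_model(1, B = -1, F = 0.005),
                 rare_variant_model(1, B = -2, F = 0.005),
                 rare_variant_model(1, B = -4, F = 0.005))
  # paired seeds: same cohort seed under increasingly severe rare models
  ps <- t(vapply(models, function(m) {
    co <- simulate_cohort(pan, sch, rare_model = m, seed = 83)
    w <- compute_was(co$dosages, pan)$score
    c(short = mean_was_pvalue(mean(w[co$group == "short"]), null, "short"),
      tall = mean_was_pvalue(mean(w[co$group == "tall"]), null, "tall"))
  }, numeric(2)))
  expect_true(all(diff(log(ps[, "short"])) < 0))  # monotone more extreme
  expect_true(all(ps[, "tall"] > 0.01))
})
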