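test_that("ranked-pair randomization pairs by thickness and balances arms", {
  res <- rank_pair_randomize(c(22, 10, 20, 12), seed = 1)
  # thickest two form pair 1, thinnest two pair 2
  expect_equal(res$pair[res$value %in% c(22, 20)], c(1L, 1L))
  expect_equal(res$pair[res$value %in% c(12, 10)], c(2L, 2L))
  # one biofilm per arm within every pair
  for (p in unique(res$pair)) {
    expect_setequal(res$arm[res$pair == p], c("enzyme", "control"))
  }
  expect_error(rank_pair_randomize(c(1, 2, 3), seed = 1),
               class = "biofilmq_pairing_error")
})

test_that("randomization balance holds for arbitrary inputs", {
  for (s in 1:20) {
    n <- 2 * sample(2:6, 1)
    vals <- withr::with_seed(s, runif(n, 5, 50))
    res <- rank_pair_randomize(vals, seed = s)
    expect_equal(sum(res$arm == "enzyme"), n / 2)
    expect_equal(sum(res$arm == "control"), n / 2)
  }
})

test_that("outlier rules match brute-force reimplementations", {
  withr::with_seed(71, {
    for (i in 1:20) {
      n <- sample(10:200, 1)
      x <- rnorm(n, sd = sample(c(1, 10), 1))
      if (i %% 3 == 0) x[1] <- x[1] + 50
      rep_out <- detect_outliers_consensus(x, methods = c("zscore", "iqr",
                                                          "eti"))
      expect_equal(unname(rep_out$flags[, "zscore"]), oracle_zscore_flags(x))
      expect_equal(unname(rep_out$flags[, "iqr"]), oracle_iqr_flags(x))
      expect_equal(unname(rep_out$flags[, "eti"]), oracle_eti_flags(x))
      expect_equal(rep_out$consensus, oracle_consensus(rep_out$flags))
    }
  })
})

test_that("consensus voting applies the at-least-half rule", {
  x <- rep(1, 10)
  rep_out <- detect_outliers_consensus(x, methods = c("zscore", "iqr", "eti"))
  expect_false(any(rep_out$flags[, "zscore"]))
  expect_false(any(rep_out$flags[, "iqr"]))
  expect_false(any(rep_out$consensus))

  # all four methods on a positive (gamma-modelled) outcome with one
  # grossly aberrant record
  planted <- withr::with_seed(72, c(rgamma(99, shape = 8, rate = 8 / 20), 400))
  sim_tab <- data.frame(outcome = planted,
                        treatment = factor(rep(c("control", "enzyme"), 50),
                                           levels = c("control", "enzyme")))
  rep4 <- detect_outliers_consensus(planted,
                                    data = sim_tab,
                                    formula = outcome ~ 1)
  expect_equal(ncol(rep4$flags), 4L)
  expect_true(rep4$consensus[100])
  expect_equal(rep4$consensus, oracle_consensus(rep4$flags))

  expect_warning(
    detect_outliers_consensus(planted, methods = c("zscore", "cooks")),
    "cooks method skipped")
})

test_that("gamma GLM with a group-only design reproduces group means", {
  tab <- data.frame(
    participant = c("a", "a", "b", "b"),
    treatment = factor(c("control", "control", "enzyme", "enzyme"),
                       levels = c("control", "enzyme")),
    outcome = c(2, 2, 4, 4))
  fit <- suppressWarnings(fit_gamma_log(tab))
  expect_equal(unname(coef(fit)), c(log(2), log(2)))
  mu <- predict(fit, newdata = data.frame(
    treatment = factor(c("control", "enzyme"),
                       levels = c("control", "enzyme"))), type = "response")
  expect_equal(unname(mu), c(2, 4))

  expect_error(fit_gamma_log(data.frame(treatment = tab$treatment,
                                        outcome = c(-1, 2, 3, 4))),
               class = "biofilmq_domain_error")
})

test_that("gamma GLM recovers the planted effect ratio at large n", {
  sim <- gen_trial_dataset(n_participants = 500, n_per_arm = 10,
                           effect_ratio = 1.2, seed = 7)
  fit <- fit_gamma_log(sim$table)
  expect_lt(abs(exp(coef(fit)[["treatmentenzyme"]]) - 1.2), 0.03)
})

test_that("linear model reports exact mean pH differences", {
  tab <- data.frame(
    treatment = factor(rep(c("control", "enzyme"), each = 3),
                       levels = c("control", "enzyme")),
    outcome = c(6, 6, 6, 5.9, 5.9, 5.9))
  fit <- fit_linear(tab)
  expect_equal(unname(coef(fit)[2]), -0.1)

  same <- data.frame(treatment = tab$treatment, outcome = rep(6, 6))
  expect_equal(unname(coef(fit_linear(same))[2]), 0)
})

test_that("cluster bootstrap is reproducible and order-invariant", {
  sim <- gen_trial_dataset(n_participants = 8, n_per_arm = 4, seed = 13)
  b1 <- cluster_bootstrap(sim$table, B = 200, seed = 99)
  b2 <- cluster_bootstrap(sim$table, B = 200, seed = 99)
  expect_identical(b1$ci, b2$ci)
  expect_identical(b1$replicates, b2$replicates)

  # permuting records within clusters leaves estimates unchanged
  perm <- withr::with_seed(1, {
    idx <- unlist(lapply(split(seq_len(nrow(sim$table)),
                               sim$table$participant), sample))
    sim$table[idx, ]
  })
  b3 <- cluster_bootstrap(perm, B = 200, seed = 99)
  expect_equal(b3$coef, b1$coef)
  expect_equal(b3$ci, b1$ci)
})

test_that("singleton clusters reduce to ordinary case resampling", {
  sim <- gen_trial_dataset(n_participants = 15, n_per_arm = 1, seed = 17)
  tab <- sim$table
  # one record per cluster, labels sorting in row order
  tab$participant <- sprintf("R%02d", seq_len(nrow(tab)))
  b <- cluster_bootstrap(tab, B = 300, seed = 5)

  # independent plain case-resampling bootstrap with the same RNG stream
  fit0 <- suppressWarnings(glm(outcome ~ treatment,
                               family = Gamma(link = "log"), data = tab))
  oracle <- withr::with_seed(5L, {
    sapply(seq_len(300), function(i) {
      rows <- sample.int(nrow(tab), replace = TRUE)
      suppressWarnings(coef(glm(outcome ~ treatment,
                                family = Gamma(link = "log"),
                                data = tab[rows, ])))[2]
    })
  })
  # clusters are split() in participant order "1","10","11",... -> map back
  expect_equal(sort(b$replicates[, 2]), sort(unname(oracle)),
               tolerance = 1e-8)
})

test_that("bootstrap aborts when too many replicates fail", {
  tab <- data.frame(
    participant = rep(c("a", "b"), each = 4),
    treatment = factor(rep(c("control", "enzyme"), each = 4),
                       levels = c("control", "enzyme")),
    outcome = c(2, 3, 2.5, 3.5, 4, 5, 4.5, 5.5))
  # resamples drawing the same participant twice have one arm only
  expect_error(cluster_bootstrap(tab, B = 200, seed = 3),
               class = "biofilmq_unstable_bootstrap_error")
})

test_that("effect report exponentiates the model and its percentile bounds", {
  sim <- gen_trial_dataset(n_participants = 10, n_per_arm = 5,
                           effect_ratio = 1.3, seed = 23)
  b <- cluster_bootstrap(sim$table, formula = outcome ~ treatment + pre_value,
                         B = 300, seed = 7)
  est <- effect_report(b)
  expect_equal(est$ratio_of_means, exp(b$coef[["treatmentenzyme"]]))
  qs <- quantile(b$replicates[, "treatmentenzyme"], c(0.025, 0.975),
                 names = FALSE)
  expect_equal(c(est$ci_low, est$ci_high), exp(qs))
  expect_true(est$ci_low <= est$ratio_of_means &&
                est$ratio_of_means <= est$ci_high)
  expect_equal(names(est$adjusted_predictions), c("control", "enzyme"))
  # adjusted predictions at the mean pre-treatment covariate
  mu <- predict(b$fit, newdata = data.frame(
    treatment = factor(c("control", "enzyme"),
                       levels = c("control", "enzyme")),
    pre_value = mean(sim$table$pre_value)), type = "response")
  expect_equal(unname(est$adjusted_predictions), unname(mu))
})
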