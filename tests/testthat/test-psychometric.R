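test_that("the IRLS fit matches the established GLM fitter on random instances", {
  withr::with_seed(202, {
    for (i in 1:15) {
      inst <- random_instance()
      ref <- stats::glm(cbind(n_positive, n_trials - n_positive) ~ magnitude,
                        family = stats::binomial(), data = inst$data)
      expect_equal(unname(coef(inst$fit)), unname(coef(ref)),
                   tolerance = 1e-6)
      expect_equal(inst$fit$aic, AIC(ref), tolerance = 1e-8)
      expect_equal(inst$fit$residual_deviance, deviance(ref),
                   tolerance = 1e-6)
      expect_equal(unname(vcov(inst$fit)), unname(vcov(ref)),
                   tolerance = 1e-4)
    }
  })
})

test_that("the IRLS optimum dominates a dense likelihood grid search", {
  withr::with_seed(303, {
    for (i in 1:8) {
      inst <- random_instance()
      oracle <- grid_search_loglik(inst$data)
      expect_gte(inst$fit$log_likelihood, oracle$max_loglik - 1e-6)
    }
  })
})

test_that("AIC identity and deviance bookkeeping hold on every fit", {
  withr::with_seed(404, {
    for (i in 1:10) {
      inst <- random_instance()
      fit <- inst$fit
      expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$log_likelihood)
      expect_gte(fit$residual_deviance, 0)
      expect_gte(fit$deviance, fit$residual_deviance - 1e-8)
    }
  })
})

test_that("the intercept-only null fit recovers the logit of the pooled rate", {
  d <- tibble::tibble(magnitude = c(30, 70), n_positive = c(5, 5),
                      n_trials = c(10, 10))
  fit <- fit_logit_glm(d, terms = "1")
  expect_equal(unname(coef(fit)), 0, tolerance = 1e-8)  # logit(0.5)
})

test_that("simulated-truth coefficients are recovered within 3 SE at large n", {
  withr::with_seed(505, {
    mags <- seq(10, 90, by = 10)
    b0 <- -4; b1 <- 0.08; n <- 400
    y <- rbinom(length(mags), n, plogis(b0 + b1 * mags))
    fit <- fit_logit_glm(tibble::tibble(magnitude = mags, n_positive = y,
                                        n_trials = n))
    se <- sqrt(diag(fit$covariance))
    expect_lt(abs(coef(fit)[1] - b0), 3 * se[1])
    expect_lt(abs(coef(fit)[2] - b1), 3 * se[2])
  })
})

test_that("prediction is the inverse-logit line and is monotone for positive slopes", {
  fit <- make_fit(-3, 0.06)
  expect_equal(predict_response(fit, 50), 0.5)  # -3 + 0.06*50 = 0
  expect_equal(predict_response(fit, 0), plogis(-3))
  grid <- predict_curve(fit, seq(0, 100, 5))
  expect_true(all(diff(grid$probability) > 0))
  expect_gt(predict_response(fit, 1e4), 1 - 1e-10)  # logistic limit
})

test_that("rank-deficient designs and unknown factor levels are rejected", {
  d <- tibble::tibble(magnitude = c(20, 50, 80), n_positive = c(1, 2, 3),
                      n_trials = 4, dup = c(20, 50, 80))
  expect_error(fit_logit_glm(d, c("magnitude", "dup")), "singular")

  coh <- simulate_cohort(truth_params("g", "mouse", n_animals = 3,
                                      covariates = list(sex = "male")),
                         seed = 1)
  freq <- response_frequencies(coh$trials)
  fit <- fit_logit_glm(freq, c("magnitude", "animal_id"))
  expect_error(predict_response(fit, 50, list(animal_id = "nope")),
               "unknown level")
})

test_that("C50 is the closed-form threshold with delta-method uncertainty", {
  fit <- make_fit(-3, 0.06)
  est <- c50(fit)
  expect_true(est$valid)
  expect_equal(est$c50, 50)  # -beta0/beta1
  expect_equal(predict_response(fit, est$c50), 0.5, tolerance = 1e-9)
  expect_true(est$ci_low <= est$c50 && est$c50 <= est$ci_high)

  # delta-method SE against the explicit gradient formula
  g <- c(-1 / 0.06, -50 / 0.06)
  expect_equal(est$se, sqrt(drop(t(g) %*% fit$covariance %*% g)))

  expect_false(c50(make_fit(2, -0.05))$valid)  # non-positive slope
})

test_that("bootstrap and delta C50 intervals agree at well-behaved designs", {
  withr::with_seed(606, {
    mags <- seq(10, 90, by = 10)
    y <- rbinom(length(mags), 60, plogis(-4 + 0.08 * mags))
    d <- tibble::tibble(magnitude = mags, n_positive = y, n_trials = 60)
    fit <- fit_logit_glm(d)
    del <- c50(fit)
    boo <- c50(fit, method = "bootstrap", n_boot = 200, seed = 10)
    expect_true(boo$valid)
    expect_equal(boo$c50, del$c50)
    expect_equal(boo$se, del$se, tolerance = 0.35)
    # determinism under the explicit seed
    expect_identical(boo, c50(fit, method = "bootstrap", n_boot = 200,
                              seed = 10))
  })
})

test_that("per-animal C50s sit inside the monotone frequency bracket", {
  d <- tibble::tibble(
    animal_id = "A1", species = "rat", sex = "male", age = "young",
    zt_window = "ZT4-6", treatment = "none", genotype = "control",
    level_id = paste0("L", 1:5), magnitude = c(20, 40, 60, 80, 100),
    n_positive = c(0L, 1L, 2L, 4L, 4L), n_trials = 4L,
    frequency = c(0, 0.25, 0.5, 1, 1))
  est <- per_animal_c50(d, method = "independent")
  expect_true(est$valid)
  expect_gt(est$c50, 40)  # inside the rising part of the staircase
  expect_lt(est$c50, 80)

  # identical animals give identical estimates
  d2 <- dplyr::mutate(d, animal_id = "A2")
  both <- per_animal_c50(dplyr::bind_rows(d, d2), method = "independent")
  expect_equal(both$c50[1], both$c50[2])
})

test_that("degenerate animals are flagged, never given numeric thresholds", {
  zero <- tibble::tibble(
    animal_id = "Z1", species = "mouse", sex = "male", age = "young",
    zt_window = "ZT4-6", treatment = "none", genotype = "TKO",
    level_id = paste0("L", 1:6), magnitude = c(15, 30, 45, 60, 75, 90),
    n_positive = 0L, n_trials = 4L, frequency = 0)
  for (m in c("shared_slope", "independent")) {
    est <- per_animal_c50(zero, method = m)
    expect_false(est$valid)
    expect_equal(est$reason, "no responses")
    expect_true(is.na(est$c50))
  }
  allr <- dplyr::mutate(zero, animal_id = "S1", n_positive = 4L,
                        frequency = 1)
  expect_equal(per_animal_c50(allr)$reason, "all responses")
})

test_that("shared-slope and independent per-animal routes agree in ranking", {
  coh <- simulate_cohort(truth_params("g", "mouse", n_animals = 6,
                                      animal_c50_sd = 8), seed = 21)
  freq <- response_frequencies(coh$trials)
  sh <- per_animal_c50(freq, method = "shared_slope")
  ind <- per_animal_c50(freq, method = "independent")
  keep <- sh$valid & ind$valid
  expect_gt(sum(keep), 3)
  expect_gt(cor(sh$c50[keep], ind$c50[keep], method = "spearman"), 0.7)
})

test_that("forward AIC keeps a real group effect and skips absent ones", {
  mk <- function(delta, seed, sd = 0) {
    # zero between-animal spread so the binomial fit is correctly
    # specified and the null retention rate is the chi-square one
    a <- truth_params("ctrl", "mouse", true_c50 = 50, n_animals = 7,
                      animal_c50_sd = sd, covariates = list(sex = "male"))
    b <- truth_params("shift", "mouse", true_c50 = 50 + delta, n_animals = 7,
                      animal_c50_sd = sd, covariates = list(sex = "female"))
    coh <- simulate_cohort(list(a, b), seed = seed)
    response_frequencies(coh$trials)
  }
  # strong true sex-linked shift: retained
  sel <- stepwise_aic(mk(15, 31), candidates = "sex")
  expect_true("sex" %in% sel$best_terms)
  expect_lt(sel$best_fit$aic, sel$base_fit$aic)
  expect_equal(nrow(sel$trace), 2)
  expect_lt(sel$anova_vs_base$p_value, 0.05)

  # no effect: base model retained in most replicates
  kept <- vapply(1:10, function(s) {
    "sex" %in% stepwise_aic(mk(0, 100 + s), candidates = "sex")$best_terms
  }, logical(1))
  expect_lt(mean(kept), 0.5)

  # empty candidate list returns the base model unchanged
  sel0 <- stepwise_aic(mk(0, 1))
  expect_equal(sel0$best_terms, "magnitude")
  expect_null(sel0$anova_vs_base)
})

test_that("a collinear candidate is rejected through singular-design handling", {
  freq <- response_frequencies(
    simulate_cohort(truth_params("g", "mouse", n_animals = 5),
                    seed = 4)$trials)
  freq$magnitude_copy <- freq$magnitude
  sel <- stepwise_aic(freq, candidates = "magnitude_copy")
  expect_equal(sel$best_terms, "magnitude")
  expect_true(all(is.na(
    sel$trace$aic[sel$trace$candidate == "magnitude_copy"])))
})

test_that("likelihood-ratio model comparison matches the deviance ANOVA", {
  coh <- simulate_cohort(list(
    truth_params("a", "mouse", true_c50 = 45, n_animals = 5,
                 covariates = list(sex = "male")),
    truth_params("b", "mouse", true_c50 = 60, n_animals = 5,
                 covariates = list(sex = "female"))), seed = 17)
  freq <- response_frequencies(coh$trials)
  f0 <- fit_logit_glm(freq, "magnitude")
  f1 <- fit_logit_glm(freq, c("magnitude", "sex"))
  lr <- lr_test(f0, f1)

  g0 <- stats::glm(cbind(n_positive, n_trials - n_positive) ~ magnitude,
                   stats::binomial(), freq)
  g1 <- stats::update(g0, . ~ . + sex)
  ref <- stats::anova(g0, g1, test = "Chisq")
  expect_equal(lr$statistic, ref$Deviance[2], tolerance = 1e-6)
  expect_equal(lr$p_value, ref$`Pr(>Chi)`[2], tolerance = 1e-6)
  expect_equal(lr$df, ref$Df[2])
})

test_that("pairwise contrasts match the reference multiple-comparison machinery", {
  coh <- simulate_cohort(list(
    truth_params("g1", "mouse", true_c50 = 40, n_animals = 5,
                 covariates = list(genotype = "g1")),
    truth_params("g2", "mouse", true_c50 = 50, n_animals = 5,
                 covariates = list(genotype = "g2")),
    truth_params("g3", "mouse", true_c50 = 62, n_animals = 5,
                 covariates = list(genotype = "g3"))), seed = 23)
  freq <- response_frequencies(coh$trials)
  fit <- fit_logit_glm(freq, c("magnitude", "genotype"))
  withr::with_seed(1, {
    ours <- tukey_contrasts(fit, "genotype")
  })
  expect_equal(nrow(ours), 3)  # three pairwise level contrasts

  ref_fit <- stats::glm(
    cbind(n_positive, n_trials - n_positive) ~ magnitude + genotype,
    stats::binomial(), dplyr::mutate(freq, genotype = factor(genotype)))
  ref <- summary(multcomp::glht(ref_fit,
                                linfct = multcomp::mcp(genotype = "Tukey")))
  expect_equal(unname(ours$estimate), unname(ref$test$coefficients),
               tolerance = 1e-5)
  expect_equal(unname(ours$std_error), unname(ref$test$sigma),
               tolerance = 1e-5)
  # single-step adjusted p-values agree to quasi-Monte-Carlo accuracy
  expect_equal(unname(ours$adjusted_p), as.numeric(ref$test$pvalues),
               tolerance = 2e-3, ignore_attr = TRUE)
  expect_equal(ours$odds_ratio, exp(ours$estimate))
})

test_that("contrast families of size one reduce to the plain Wald test", {
  coh <- simulate_cohort(list(
    truth_params("a", "mouse", true_c50 = 45, n_animals = 5,
                 covariates = list(sex = "male")),
    truth_params("b", "mouse", true_c50 = 55, n_animals = 5,
                 covariates = list(sex = "female"))), seed = 29)
  fit <- fit_logit_glm(response_frequencies(coh$trials),
                       c("magnitude", "sex"))
  ct <- tukey_contrasts(fit, "sex")
  expect_equal(nrow(ct), 1)
  expect_equal(ct$adjusted_p, ct$p_value)  # family of size 1
  expect_error(tukey_contrasts(fit, "age"), "not in the fitted model")
})

test_that("identical simulated groups produce near-zero contrasts", {
  coh <- simulate_cohort(list(
    truth_params("a", "mouse", true_c50 = 50, n_animals = 7,
                 covariates = list(sex = "male")),
    truth_params("b", "mouse", true_c50 = 50, n_animals = 7,
                 covariates = list(sex = "female"))), seed = 37)
  fit <- fit_logit_glm(response_frequencies(coh$trials),
                       c("magnitude", "sex"))
  ct <- tukey_contrasts(fit, "sex")
  expect_lt(abs(ct$estimate), 3 * ct$std_error)
})

test_that("Bartlett pre-test matches the textbook closed form, then t", {
  a <- c(44, 50, 56); b <- c(40, 52, 58)
  cmp <- compare_c50_groups(a, b)
  # closed-form Bartlett statistic computed by hand for the worked set
  k <- 2; n <- c(3, 3); v <- c(var(a), var(b)); N <- sum(n)
  sp2 <- sum((n - 1) * v) / (N - k)
  stat <- ((N - k) * log(sp2) - sum((n - 1) * log(v))) /
    (1 + (sum(1 / (n - 1)) - 1 / (N - k)) / (3 * (k - 1)))
  expect_equal(cmp$bartlett_statistic, stat, tolerance = 1e-10)
  expect_equal(cmp$bartlett_statistic,
               unname(stats::bartlett.test(list(a, b))$statistic))
  expect_false(cmp$welch_fallback)

  ident <- compare_c50_groups(c(40, 50, 60, 70), c(40, 50, 60, 70))
  expect_equal(ident$t_statistic, 0)
  expect_equal(ident$p_value, 1)
})

test_that("heteroscedastic groups trigger the flagged Welch fallback", {
  withr::with_seed(71, {
    a <- rnorm(10, 50, 0.5)
    b <- rnorm(10, 50, 20)
  })
  cmp <- compare_c50_groups(a, b)
  expect_true(cmp$welch_fallback)
  expect_equal(cmp$test, "Welch t")
})

test_that("invalid estimates are excluded with a count, small groups rejected", {
  good <- tibble::tibble(c50 = c(45, 50, 55), valid = TRUE)
  mixed <- tibble::tibble(c50 = c(40, 52, 58, NA), valid = c(TRUE, TRUE,
                                                             TRUE, FALSE))
  cmp <- compare_c50_groups(good, mixed)
  expect_equal(cmp$n_excluded, 1)
  expect_equal(cmp$n_b, 3)
  expect_error(
    compare_c50_groups(good, tibble::tibble(c50 = 50, valid = TRUE)),
    "at least 2")
})

test_that("the comparison detects a true 10%-contrast C50 shift with high power", {
  withr::with_seed(83, {
    reject <- vapply(1:500, function(i) {
      a <- rnorm(7, 50, 4)
      b <- rnorm(7, 60, 4)
      compare_c50_groups(a, b)$p_value < 0.05
    }, logical(1))
  })
  expect_gt(mean(reject), 0.9)
})
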