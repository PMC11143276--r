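# Shared fixtures, all generated in code.

# five-level calibration table with a dark-disk gradient (background fixed)
make_calibration <- function() {
  data.frame(level_id = paste0("L", 1:5),
             Id = c(39, 30, 20, 10, 0), Ib = 39)
}

# hand-assembled psychometric fit with known coefficients, for closed-form
# checks of prediction/C50 algebra (magnitude-only model)
make_fit <- function(beta0, beta1, cov = diag(c(0.25, 1e-4))) {
  dimnames(cov) <- list(c("(Intercept)", "magnitude"),
                        c("(Intercept)", "magnitude"))
  structure(
    list(coefficients = c("(Intercept)" = beta0, magnitude = beta1),
         covariance = cov,
         log_likelihood = NA_real_, aic = NA_real_,
         deviance = NA_real_, residual_deviance = NA_real_,
         n_params = 2L, n_obs = 0L, n_trials_total = 0L,
         converged = TRUE, separation_flag = FALSE,
         fitted = numeric(0),
         terms_chr = "magnitude",
         formula = stats::reformulate("magnitude"),
         xlevels = list(),
         control = irls_control(),
         data = tibble::tibble()),
    class = "ltcv_fit")
}

# random small grouped-binomial instance guaranteed non-degenerate; used
# for oracle comparisons against stats::glm and grid search
random_instance <- function() {
  repeat {
    mags <- sort(sample(seq(10, 100, by = 10), sample(3:5, 1)))
    n <- sample(3:8, length(mags), replace = TRUE)
    b0 <- stats::runif(1, -4, 1)
    b1 <- stats::runif(1, 0.01, 0.12)
    y <- stats::rbinom(length(mags), n, stats::plogis(b0 + b1 * mags))
    if (sum(y) == 0 || sum(y) == sum(n)) next
    d <- tibble::tibble(magnitude = mags, n_positive = y, n_trials = n)
    fit <- tryCatch(fit_logit_glm(d), error = function(e) NULL)
    if (is.null(fit) || !fit$converged || fit$separation_flag) next
    return(list(data = d, fit = fit))
  }
}

# independent grid-search oracle for the 2-parameter binomial logit
# likelihood: iterative zooming around the grid argmax, pure likelihood
# evaluations only
grid_search_loglik <- function(data, n_grid = 21, n_zoom = 8,
                               b0_range = c(-15, 10), b1_range = c(-0.5, 0.5)) {
  ll <- function(b0, b1) {
    p <- stats::plogis(b0 + b1 * data$magnitude)
    sum(stats::dbinom(data$n_positive, data$n_trials, p, log = TRUE))
  }
  for (z in seq_len(n_zoom)) {
    b0s <- seq(b0_range[1], b0_range[2], length.out = n_grid)
    b1s <- seq(b1_range[1], b1_range[2], length.out = n_grid)
    vals <- outer(b0s, b1s, Vectorize(ll))
    idx <- arrayInd(which.max(vals), dim(vals))
    step0 <- diff(b0_range) / (n_grid - 1)
    step1 <- diff(b1_range) / (n_grid - 1)
    b0_range <- b0s[idx[1]] + c(-2, 2) * step0
    b1_range <- b1s[idx[2]] + c(-2, 2) * step1
  }
  list(max_loglik = max(vals),
       b0 = b0s[idx[1]], b1 = b1s[idx[2]])
}

# minimal observer-score table: one rat, `n_trials` presentations, three
# observers all scoring the supplied labels (a list, one vector per trial)
make_scores <- function(labels_per_trial, species = "rat",
                        magnitude = 60) {
  n <- length(labels_per_trial)
  do.call(rbind, lapply(seq_len(n), function(i) {
    labs <- labels_per_trial[[i]]
    tibble::tibble(
      animal_id = "A1", species = species, sex = "male", age = "young",
      zt_window = "ZT4-6", treatment = "none", genotype = "control",
      level_id = "L1", magnitude = magnitude, trial_index = i,
      observer_id = sprintf("obs%d", seq_along(labs)),
      response_type = labs)
  }))
}
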