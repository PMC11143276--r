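#' C50: the contrast eliciting a 50% response probability
#'
#' The contrast-sensitivity index of the assay: the contrast magnitude at
#' which the fitted psychometric curve crosses probability 0.5. For a
#' logit-linear model this is where the linear predictor is zero, i.e.
#' `c50 = -eta0 / slope` with `eta0` the predictor at magnitude 0 for the
#' requested covariate profile and `slope` its derivative in magnitude
#' (profile-specific when magnitude interactions are present). The default
#' confidence interval is by the delta method on the coefficient
#' covariance; a parametric bootstrap (refitting on binomial resamples of
#' the fitted probabilities) is available.
#'
#' The estimate is flagged invalid (`valid = FALSE`, with a reason) when
#' the magnitude slope is non-positive, the fit did not converge, or the
#' fit is separated — e.g. cohorts that never respond at any contrast have
#' no defined threshold.
#'
#' @param fit An `ltcv_fit` from [fit_logit_glm()].
#' @param covariates Named list fixing the covariate profile.
#' @param conf_level Confidence level for the interval.
#' @param method `"delta"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap replicates (bootstrap method only).
#' @param seed Seed for the bootstrap resamples.
#' @param subject Label for the estimate (e.g. animal or group id).
#' @return One-row tibble: `subject`, `c50`, `ci_low`, `ci_high`,
#'   `se`, `method`, `valid`, `reason`.
#' @examples
#' freq <- tibble::tibble(magnitude = rep(c(20, 50, 80), each = 2),
#'                        n_positive = c(0, 1, 2, 2, 4, 4), n_trials = 4)
#' c50(fit_logit_glm(freq))
#' @export
c50 <- function(fit, covariates = list(), conf_level = 0.95,
                method = c("delta", "bootstrap"), n_boot = 999L,
                seed = 1L, subject = "group") {
  stopifnot(inherits(fit, "ltcv_fit"))
  method <- match.arg(method)

  invalid <- function(reason) tibble::tibble(
    subject = subject, c50 = NA_real_, ci_low = NA_real_,
    ci_high = NA_real_, se = NA_real_, method = method,
    valid = FALSE, reason = reason)

  if (!fit$converged) return(invalid("fit did not converge"))
  if (fit$separation_flag) return(invalid("separation"))

  x0 <- drop(design_row(fit, 0, covariates))
  x1 <- drop(design_row(fit, 1, covariates))
  s_vec <- x1 - x0                       # picks out slope terms in magnitude
  beta <- fit$coefficients
  slope <- sum(s_vec * beta)
  if (!is.finite(slope) || slope <= 0) return(invalid("non-positive slope"))

  eta0 <- sum(x0 * beta)
  est <- -eta0 / slope

  if (method == "delta") {
    grad <- (-x0 - est * s_vec) / slope
    se <- sqrt(drop(t(grad) %*% fit$covariance %*% grad))
    zq <- stats::qnorm(1 - (1 - conf_level) / 2)
    lo <- est - zq * se
    hi <- est + zq * se
  } else {
    boot <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_boot), function(b) {
        d <- fit$data
        d$n_positive <- stats::rbinom(length(fit$fitted), d$n_trials,
                                      fit$fitted)
        bf <- tryCatch(fit_logit_glm(d, fit$terms_chr, fit$control),
                       error = function(e) NULL)
        if (is.null(bf)) return(NA_real_)
        r <- c50(bf, covariates, method = "delta", subject = subject)
        if (r$valid) r$c50 else NA_real_
      }, numeric(1))
    })
    boot <- boot[is.finite(boot)]
    if (length(boot) < n_boot / 2) return(invalid("bootstrap degenerate"))
    se <- stats::sd(boot)
    qs <- stats::quantile(boot, c((1 - conf_level) / 2,
                                  1 - (1 - conf_level) / 2), names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }

  tibble::tibble(subject = subject, c50 = est, ci_low = lo, ci_high = hi,
                 se = se, method = method, valid = TRUE, reason = NA_character_)
}

#' Per-animal C50 estimates
#'
#' Predicts each animal's C50 from the psychometric model. The default
#' route fits one GLM to the whole cohort with a shared magnitude slope and
#' a per-animal intercept, then inverts each animal's curve — sessions of a
#' handful of contrast levels and a few repetitions are too thin for stable
#' per-animal slopes. `method = "independent"` instead fits each animal its
#' own magnitude-only model. Animals whose response vector is all-zero or
#' all-one are flagged invalid (no threshold is identifiable) and excluded
#' from the shared fit.
#'
#' @param freq Frequency tibble from [response_frequencies()].
#' @param method `"shared_slope"` (default) or `"independent"`.
#' @param conf_level Confidence level for the per-animal intervals.
#' @param control An [irls_control()] list.
#' @return Tibble of C50 estimates, one row per animal (`subject` =
#'   `animal_id`), with `valid`/`reason` flags.
#' @export
per_animal_c50 <- function(freq, method = c("shared_slope", "independent"),
                           conf_level = 0.95, control = irls_control()) {
  method <- match.arg(method)
  freq <- tibble::as_tibble(freq)
  animals <- unique(freq$animal_id)

  degen_reason <- function(d) {
    if (sum(d$n_positive) == 0) return("no responses")
    if (sum(d$n_positive) == sum(d$n_trials)) return("all responses")
    if (length(unique(d$magnitude)) < 2) return("single contrast level")
    NA_character_
  }
  reasons <- vapply(animals, function(a) {
    degen_reason(freq[freq$animal_id == a, ])
  }, character(1), USE.NAMES = FALSE)

  invalid_row <- function(a, reason) tibble::tibble(
    subject = a, c50 = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    se = NA_real_, method = "delta", valid = FALSE, reason = reason)

  if (method == "shared_slope") {
    usable <- animals[is.na(reasons)]
    rows <- vector("list", length(animals))
    shared_fit <- NULL
    if (length(usable) >= 1) {
      sub <- freq[freq$animal_id %in% usable, ]
      terms <- if (length(usable) > 1) c("magnitude", "animal_id") else "magnitude"
      shared_fit <- tryCatch(fit_logit_glm(sub, terms, control),
                             error = function(e) NULL)
    }
    for (i in seq_along(animals)) {
      a <- animals[i]
      if (!is.na(reasons[i])) {
        rows[[i]] <- invalid_row(a, reasons[i])
      } else if (is.null(shared_fit)) {
        rows[[i]] <- invalid_row(a, "cohort fit failed")
      } else {
        cov <- if (length(usable) > 1) list(animal_id = a) else list()
        rows[[i]] <- c50(shared_fit, cov, conf_level, subject = a)
      }
    }
    dplyr::bind_rows(rows)
  } else {
    dplyr::bind_rows(lapply(seq_along(animals), function(i) {
      a <- animals[i]
      if (!is.na(reasons[i])) return(invalid_row(a, reasons[i]))
      f <- tryCatch(
        fit_logit_glm(freq[freq$animal_id == a, ], "magnitude", control),
        error = function(e) NULL)
      if (is.null(f)) return(invalid_row(a, "fit failed"))
      c50(f, conf_level = conf_level, subject = a)
    }))
  }
}

#' Compare C50 between two groups
#'
#' Two-sample comparison of per-animal C50 values: Bartlett's test checks
#' homoscedasticity first; if equal variances are not rejected at `alpha`,
#' a pooled-variance two-sample t-test is used, otherwise the Welch test is
#' substituted and flagged explicitly (`welch_fallback = TRUE`). Invalid
#' C50 estimates are excluded and counted.
#'
#' @param a,b C50 tibbles from [per_animal_c50()] (or bare numeric
#'   vectors).
#' @param alpha Significance level for the Bartlett pre-test.
#' @return An object of class `ltcv_c50_comparison`: Bartlett statistic and
#'   p-value, test used, t statistic, df, p-value, group means and sizes,
#'   and the number of excluded (invalid) estimates.
#' @export
compare_c50_groups <- function(a, b, alpha = 0.05) {
  pull_valid <- function(x) {
    if (is.numeric(x)) return(list(v = x[is.finite(x)],
                                   excl = sum(!is.finite(x))))
    stopifnot(all(c("c50", "valid") %in% names(x)))
    list(v = x$c50[x$valid], excl = sum(!x$valid))
  }
  ga <- pull_valid(a); gb <- pull_valid(b)
  if (length(ga$v) < 2 || length(gb$v) < 2) {
    stop("need at least 2 valid C50 estimates per group", call. = FALSE)
  }
  bart <- stats::bartlett.test(list(ga$v, gb$v))
  homoscedastic <- bart$p.value > alpha
  tt <- stats::t.test(ga$v, gb$v, var.equal = homoscedastic)
  structure(
    list(bartlett_statistic = unname(bart$statistic),
         bartlett_p = bart$p.value,
         homoscedastic = homoscedastic,
         welch_fallback = !homoscedastic,
         test = if (homoscedastic) "pooled-variance t" else "Welch t",
         t_statistic = unname(tt$statistic),
         df = unname(tt$parameter),
         p_value = tt$p.value,
         mean_a = mean(ga$v), mean_b = mean(gb$v),
         n_a = length(ga$v), n_b = length(gb$v),
         n_excluded = ga$excl + gb$excl,
         alpha = alpha),
    class = "ltcv_c50_comparison"
  )
}

#' @export
print.ltcv_c50_comparison <- function(x, ...) {
  cat("<ltcv_c50_comparison>\n")
  cat(sprintf("  Bartlett K^2 = %.3f, p = %.4g (%s)\n",
              x$bartlett_statistic, x$bartlett_p,
              if (x$homoscedastic) "homoscedastic" else "heteroscedastic"))
  if (x$welch_fallback) cat("  NOTE: Welch fallback in use\n")
  cat(sprintf("  %s: t = %.3f, df = %.2f, p = %.4g\n",
              x$test, x$t_statistic, x$df, x$p_value))
  cat(sprintf("  mean C50: %.2f (n=%d) vs %.2f (n=%d); %d invalid excluded\n",
              x$mean_a, x$n_a, x$mean_b, x$n_b, x$n_excluded))
  invisible(x)
}
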