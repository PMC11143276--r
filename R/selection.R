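#' Bottom-up model construction by AIC
#'
#' Greedy forward selection for the psychometric model: starting from the
#' magnitude-only base model, candidate fixed effects are tried one at a
#' time and the best candidate is kept only if it strictly lowers the AIC;
#' selection stops when no remaining candidate improves. Every candidate's
#' AIC and residual deviance are recorded in the trace, and the final model
#' is compared to the base by a likelihood-ratio (deviance ANOVA)
#' chi-square test.
#'
#' @param data Frequency tibble from [response_frequencies()].
#' @param candidates Ordered character vector of candidate terms (factors
#'   such as `"sex"`, `"age"`, `"zt_window"`, `"treatment"`, `"genotype"`,
#'   or interactions like `"magnitude:sex"`).
#' @param control An [irls_control()] list.
#' @return An object of class `ltcv_selection`: `best_fit` (`ltcv_fit`),
#'   `best_terms`, `trace` (tibble of step, candidate, aic,
#'   residual_deviance, kept), and `anova_vs_base` (NULL when nothing was
#'   added).
#' @export
stepwise_aic <- function(data, candidates = character(),
                         control = irls_control()) {
  base_fit <- fit_logit_glm(data, "magnitude", control)
  current <- base_fit
  terms <- "magnitude"
  remaining <- setdiff(candidates, terms)
  trace <- list(tibble::tibble(
    step = 0L, candidate = "magnitude (base)", aic = base_fit$aic,
    residual_deviance = base_fit$residual_deviance, kept = TRUE))
  step <- 0L

  repeat {
    if (!length(remaining)) break
    step <- step + 1L
    cand_fits <- lapply(remaining, function(term) {
      tryCatch(fit_logit_glm(data, c(terms, term), control),
               error = function(e) NULL)
    })
    aics <- vapply(cand_fits, function(f) if (is.null(f)) NA_real_ else f$aic,
                   numeric(1))
    devs <- vapply(cand_fits,
                   function(f) if (is.null(f)) NA_real_ else f$residual_deviance,
                   numeric(1))
    best <- if (all(is.na(aics))) NA_integer_ else which.min(aics)
    keep <- !is.na(best) && aics[best] < current$aic
    trace[[length(trace) + 1L]] <- tibble::tibble(
      step = step, candidate = remaining, aic = aics,
      residual_deviance = devs,
      kept = keep & seq_along(remaining) == best)
    if (!keep) break
    terms <- c(terms, remaining[best])
    current <- cand_fits[[best]]
    remaining <- remaining[-best]
  }

  structure(
    list(best_fit = current, best_terms = terms,
         base_fit = base_fit,
         trace = dplyr::bind_rows(trace),
         anova_vs_base = if (length(terms) > 1) lr_test(base_fit, current)),
    class = "ltcv_selection"
  )
}

#' @export
print.ltcv_selection <- function(x, ...) {
  cat("<ltcv_selection> forward AIC model construction\n")
  cat("  kept terms:", paste(x$best_terms, collapse = " + "), "\n")
  cat(sprintf("  base AIC %.2f -> best AIC %.2f\n",
              x$base_fit$aic, x$best_fit$aic))
  if (!is.null(x$anova_vs_base)) {
    cat(sprintf("  LR vs base: chi^2 = %.3f (df %d), p = %.4g\n",
                x$anova_vs_base$statistic, x$anova_vs_base$df,
                x$anova_vs_base$p_value))
  }
  invisible(x)
}
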