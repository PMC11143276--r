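#' Tukey-style pairwise contrasts for a fitted factor
#'
#' All pairwise differences between the levels of a factor in the fitted
#' psychometric model, on the logit scale, with standard errors from the
#' coefficient covariance. Family-wise adjustment is single-step: each
#' adjusted p-value is the probability that the maximum absolute component
#' of a multivariate normal with the contrasts' correlation exceeds the
#' observed statistic (the Tukey-type adjustment for GLM contrasts), with a
#' Bonferroni option as fallback. Odds ratios `exp(estimate)` with
#' family-wise 95% confidence intervals are reported alongside.
#'
#' @param fit An `ltcv_fit` whose terms include `factor`.
#' @param factor Name of a factor term with >= 2 levels.
#' @param adjust `"single-step"` (default), `"bonferroni"`, or `"none"`.
#' @param conf_level Confidence level for the (family-wise, when adjusted)
#'   intervals.
#' @return Tibble with one row per level pair: `contrast`, `estimate`
#'   (logit difference), `std_error`, `statistic`, `p_value` (unadjusted),
#'   `adjusted_p`, `odds_ratio`, `or_low`, `or_high`.
#' @export
tukey_contrasts <- function(fit, factor,
                            adjust = c("single-step", "bonferroni", "none"),
                            conf_level = 0.95) {
  stopifnot(inherits(fit, "ltcv_fit"))
  adjust <- match.arg(adjust)
  levels <- fit$xlevels[[factor]]
  if (is.null(levels)) {
    stop("factor '", factor, "' is not in the fitted model", call. = FALSE)
  }
  if (length(levels) < 2) {
    stop("factor '", factor, "' needs >= 2 levels", call. = FALSE)
  }

  beta <- fit$coefficients
  # coefficient positions of the non-reference level offsets (treatment
  # coding): reference level has a zero row
  coef_of <- function(lv) {
    nm <- paste0(factor, lv)
    row <- stats::setNames(rep(0, length(beta)), names(beta))
    if (nm %in% names(beta)) row[nm] <- 1
    row
  }
  pairs <- utils::combn(levels, 2, simplify = FALSE)
  K <- do.call(rbind, lapply(pairs, function(p) coef_of(p[2]) - coef_of(p[1])))
  rownames(K) <- vapply(pairs, function(p) paste(p[2], "-", p[1]),
                        character(1))

  est <- drop(K %*% beta)
  V <- K %*% fit$covariance %*% t(K)
  se <- sqrt(diag(V))
  z <- est / se
  p_raw <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  m <- length(est)

  if (adjust == "single-step" && m > 1) {
    R <- stats::cov2cor(V)
    p_adj <- vapply(abs(z), function(zi) {
      1 - mvtnorm::pmvnorm(lower = rep(-zi, m), upper = rep(zi, m),
                           corr = R, keepAttr = FALSE)
    }, numeric(1))
    p_adj <- pmin(pmax(p_adj, 0), 1)
    crit <- mvtnorm::qmvnorm(conf_level, tail = "both.tails", corr = R)$quantile
  } else if (adjust == "bonferroni" && m > 1) {
    p_adj <- pmin(p_raw * m, 1)
    crit <- stats::qnorm(1 - (1 - conf_level) / (2 * m))
  } else {
    p_adj <- p_raw
    crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  }

  tibble::tibble(
    contrast = rownames(K),
    estimate = est, std_error = se, statistic = z,
    p_value = p_raw, adjusted_p = p_adj,
    odds_ratio = exp(est),
    or_low = exp(est - crit * se),
    or_high = exp(est + crit * se)
  )
}
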