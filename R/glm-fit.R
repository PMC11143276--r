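#' IRLS control parameters
#'
#' @param tol Convergence tolerance on the relative change of the
#'   coefficient vector between iterations.
#' @param max_iter Maximum IRLS iterations.
#' @param mu_clamp Fitted probabilities are clamped to
#'   `[mu_clamp, 1 - mu_clamp]`; a fit whose working probabilities pin to
#'   the clamp bound at convergence is flagged as (quasi-)separated.
#' @return A list of control parameters.
#' @export
irls_control <- function(tol = 1e-8, max_iter = 100L, mu_clamp = 1e-10) {
  stopifnot(tol > 0, max_iter >= 1, mu_clamp > 0, mu_clamp < 0.5)
  list(tol = tol, max_iter = as.integer(max_iter), mu_clamp = mu_clamp)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# binomial log-likelihood with counts, including the combinatorial constant
# so that AIC matches the usual definition for grouped binomial data
binom_loglik <- function(y, n, mu) {
  sum(stats::dbinom(y, n, mu, log = TRUE))
}

#' Fit the binomial logit psychometric model
#'
#' Maximum-likelihood fit of a binomial generalized linear model with a
#' logit link by iteratively reweighted least squares (IRLS), written out in
#' full: at each iteration the working response
#' `z = eta + (y/n - mu) / (mu (1 - mu))` is regressed onto the design with
#' weights `n mu (1 - mu)` until the coefficient vector stabilizes. The
#' response is the per-animal per-contrast pair (`n_positive`, `n_trials`);
#' contrast `magnitude` (percent, uncentered) is always the first covariate,
#' so the C50 read off the fit is directly on the contrast axis.
#'
#' @param data Frequency tibble from [response_frequencies()] (columns
#'   `n_positive`, `n_trials`, plus every covariate named in `terms`).
#' @param terms Character vector of model terms; must include
#'   `"magnitude"`. Interactions use formula syntax, e.g. `"magnitude:sex"`.
#' @param control An [irls_control()] list.
#' @return An object of class `ltcv_fit`: coefficients, covariance
#'   (inverse observed Fisher information from the final IRLS weights),
#'   `log_likelihood`, `aic`, `deviance` (null), `residual_deviance`,
#'   `n_params`, `converged`, `separation_flag`, plus the terms/levels
#'   needed for prediction.
#' @examples
#' freq <- tibble::tibble(magnitude = rep(c(20, 50, 80), each = 2),
#'                        n_positive = c(0, 1, 2, 3, 4, 4), n_trials = 4)
#' fit <- fit_logit_glm(freq)
#' coef(fit)
#' @export
fit_logit_glm <- function(data, terms = "magnitude",
                          control = irls_control()) {
  data <- tibble::as_tibble(data)
  # magnitude anchors every candidate model; "1" requests the intercept-only
  # null fit (used for deviance baselines and degenerate checks)
  if (!"magnitude" %in% terms && !identical(terms, "1")) {
    stop("the contrast magnitude term must be present in every model",
         call. = FALSE)
  }
  for (col in c("n_positive", "n_trials")) {
    if (!col %in% names(data)) {
      stop("data must carry ", col, call. = FALSE)
    }
  }

  formula <- stats::reformulate(terms)
  vars <- all.vars(formula)
  data <- dplyr::mutate(data, dplyr::across(
    dplyr::all_of(vars) & dplyr::where(is.character), as.factor))
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(formula, mf)
  y <- data$n_positive
  n <- data$n_trials
  if (any(n <= 0) || any(y < 0) || any(y > n)) {
    stop("need 0 <= n_positive <= n_trials with n_trials > 0", call. = FALSE)
  }
  if (qr(X)$rank < ncol(X)) {
    stop("singular design: model terms are collinear", call. = FALSE)
  }

  p <- ncol(X)
  eps <- control$mu_clamp
  # initialize from the empirical proportions, shrunk away from 0/1
  mu <- (y + 0.5) / (n + 1)
  eta <- logit(mu)
  beta <- rep(0, p)
  converged <- FALSE

  for (iter in seq_len(control$max_iter)) {
    mu <- pmin(pmax(inv_logit(eta), eps), 1 - eps)
    w <- n * mu * (1 - mu)
    z <- eta + (y / n - mu) / (mu * (1 - mu))
    fit_wls <- stats::lm.wfit(X, z, w)
    beta_new <- fit_wls$coefficients
    if (anyNA(beta_new)) {
      stop("singular design in IRLS step", call. = FALSE)
    }
    delta <- max(abs(beta_new - beta)) / max(1, max(abs(beta_new)))
    beta <- beta_new
    eta <- drop(X %*% beta)
    if (iter > 1 && delta < control$tol) {
      converged <- TRUE
      break
    }
  }

  mu_raw <- inv_logit(eta)
  mu <- pmin(pmax(mu_raw, eps), 1 - eps)
  separation <- any(mu_raw <= eps | mu_raw >= 1 - eps)
  w <- n * mu * (1 - mu)
  XtWX <- crossprod(X * sqrt(w))
  covariance <- tryCatch(solve(XtWX), error = function(e) {
    matrix(NA_real_, p, p, dimnames = dimnames(XtWX))
  })
  dimnames(covariance) <- list(colnames(X), colnames(X))

  ll <- binom_loglik(y, n, mu)
  ll_sat <- binom_loglik(y, n, pmin(pmax(y / n, eps), 1 - eps))
  mu_null <- sum(y) / sum(n)
  null_dev <- 2 * (ll_sat - binom_loglik(y, n, rep(mu_null, length(y))))

  structure(
    list(coefficients = stats::setNames(beta, colnames(X)),
         covariance = covariance,
         log_likelihood = ll,
         aic = 2 * p - 2 * ll,
         deviance = null_dev,
         residual_deviance = 2 * (ll_sat - ll),
         n_params = p,
         n_obs = length(y),
         n_trials_total = sum(n),
         converged = converged,
         separation_flag = separation,
         fitted = mu_raw,
         terms_chr = terms,
         formula = formula,
         xlevels = stats::.getXlevels(stats::terms(mf), mf),
         control = control,
         data = data),
    class = "ltcv_fit"
  )
}

#' @export
coef.ltcv_fit <- function(object, ...) object$coefficients

#' @export
vcov.ltcv_fit <- function(object, ...) object$covariance

#' @export
logLik.ltcv_fit <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_params, class = "logLik")
}

#' @export
print.ltcv_fit <- function(x, ...) {
  cat("<ltcv_fit> binomial logit psychometric model\n")
  cat("  terms:", paste(x$terms_chr, collapse = " + "), "\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  logLik %.3f  AIC %.2f  resid. deviance %.2f on %d obs\n",
              x$log_likelihood, x$aic, x$residual_deviance, x$n_obs))
  if (!x$converged) cat("  WARNING: IRLS did not converge\n")
  if (x$separation_flag) cat("  WARNING: (quasi-)separation detected\n")
  invisible(x)
}

# design row(s) for a covariate profile at given magnitudes
design_row <- function(fit, magnitude, covariates = list()) {
  nd <- tibble::as_tibble(c(list(magnitude = magnitude), covariates))
  vars <- setdiff(all.vars(fit$formula), "magnitude")
  miss <- setdiff(vars, names(nd))
  if (length(miss)) {
    stop("prediction needs covariate(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (v in names(fit$xlevels)) {
    if (!all(nd[[v]] %in% fit$xlevels[[v]])) {
      stop("unknown level for factor ", v, call. = FALSE)
    }
    nd[[v]] <- factor(nd[[v]], levels = fit$xlevels[[v]])
  }
  stats::model.matrix(fit$formula, nd, xlev = fit$xlevels)
}

#' Predicted response probability
#'
#' Inverse-logit of the fitted linear predictor at a given contrast
#' magnitude and covariate profile; the psychometric curve is strictly
#' increasing in magnitude whenever the magnitude slope is positive.
#'
#' @param fit An `ltcv_fit`.
#' @param magnitude Contrast magnitude(s), percent.
#' @param covariates Named list of covariate values (factor levels must
#'   have been observed in the fit).
#' @return Probabilities in (0, 1).
#' @export
predict_response <- function(fit, magnitude, covariates = list()) {
  X <- design_row(fit, magnitude, covariates)
  unname(drop(inv_logit(X %*% fit$coefficients)))
}

#' Predicted psychometric curve on a magnitude grid
#'
#' Convenience wrapper emitting the (magnitude, probability) pairs of the
#' group prediction curve, e.g. for external plotting.
#'
#' @inheritParams predict_response
#' @param grid Magnitude grid (percent).
#' @return Tibble with `magnitude` and `probability`.
#' @export
predict_curve <- function(fit, grid = seq(0, 100, by = 1),
                          covariates = list()) {
  tibble::tibble(magnitude = grid,
                 probability = predict_response(fit, grid, covariates))
}

#' Likelihood-ratio comparison of two nested fits
#'
#' Deviance ANOVA for the binomial GLM: twice the log-likelihood difference
#' referred to a chi-square with as many degrees of freedom as the
#' difference in parameter count.
#'
#' @param fit0 Reduced model (`ltcv_fit`).
#' @param fit1 Full model (`ltcv_fit`), nested above `fit0`.
#' @return Tibble with `statistic`, `df`, `p_value`, and the two AICs.
#' @export
lr_test <- function(fit0, fit1) {
  stopifnot(inherits(fit0, "ltcv_fit"), inherits(fit1, "ltcv_fit"))
  if (fit1$n_params <= fit0$n_params) {
    stop("fit1 must have more parameters than fit0", call. = FALSE)
  }
  stat <- 2 * (fit1$log_likelihood - fit0$log_likelihood)
  df <- fit1$n_params - fit0$n_params
  tibble::tibble(
    statistic = stat, df = df,
    p_value = stats::pchisq(stat, df, lower.tail = FALSE),
    aic_reduced = fit0$aic, aic_full = fit1$aic
  )
}
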