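# Logistic-regression engine: single fits, all-subsets search, AICc
# ranking, delta-AICc < 2 candidate sets, coefficient averaging, and
# diagnostics. Fitting itself is ordinary IRLS via stats::glm with a tight
# convergence tolerance; everything above the single fit is implemented
# here.

.WALD_Z <- 1.96

#' Fit a logistic regression (binomial error, logit link)
#'
#' Maximum likelihood by iteratively reweighted least squares
#' (`stats::glm`), with convergence tolerance `1e-10` and up to 100
#' iterations. Standard errors come from the inverse observed information.
#' Non-convergence and (quasi-)complete separation are reported as flags on
#' the result, not as errors, so the all-subsets search can drop such
#' models from ranking.
#'
#' @param X data frame (or matrix) of numeric predictors; may have zero
#'   columns for an intercept-only model.
#' @param y binary 0/1 response, `length(y) == nrow(X)`.
#' @return object of class `logistic_fit`: `predictors`, `coefficients`,
#'   `se`, `loglik`, `k` (parameters incl. intercept), `n`, `fitted`,
#'   `converged`, `separation`, and the underlying `glm` object.
#' @export
fit_logistic <- function(X, y) {
  X <- as.data.frame(X)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  k <- ncol(X) + 1L
  if (length(y) <= k) stop("need n > number of parameters")
  dat <- cbind(.y = y, X)
  form <- if (ncol(X) == 0) .y ~ 1 else
    stats::reformulate(sprintf("`%s`", names(X)), response = ".y")
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = dat,
        control = glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (anyNA(coef(fit)))
    stop("design matrix is rank deficient; drop aliased predictors")
  # huge coefficients with huge SEs are the quasi-separation signature
  se <- sqrt(diag(vcov(fit)))
  if (any(abs(coef(fit)) > 1e2 & se > 1e2)) separation <- TRUE
  structure(list(predictors = names(X),
                 coefficients = coef(fit),
                 se = se,
                 loglik = as.numeric(logLik(fit)),
                 k = k, n = length(y),
                 fitted = fitted(fit),
                 converged = fit$converged,
                 separation = separation,
                 glm = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic_fit: %d predictor(s), n = %d, logLik = %.3f%s\n",
              length(x$predictors), x$n, x$loglik,
              if (x$separation) " [separation]" else
                if (!x$converged) " [not converged]" else ""))
  print(data.frame(estimate = x$coefficients, se = x$se))
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2*loglik + 2k + 2k(k+1)/(n - k - 1)`. Always exceeds AIC and
#' converges to it as `n` grows at fixed `k`.
#'
#' @param loglik maximised log-likelihood.
#' @param k number of estimated parameters (slopes + intercept).
#' @param n number of observations; requires `n - k - 1 > 0`.
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) stop("AICc undefined: need n > k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit every predictor subset and rank by AICc
#'
#' Enumerates all `2^p` subsets of the supplied predictors (including the
#' intercept-only model) in binary-counting order on the input column
#' order, fits each by [fit_logistic()], and computes AICc, delta AICc
#' relative to the best model, and Akaike weights
#' `w_i = exp(-delta_i/2) / sum(exp(-delta_j/2))` over all successfully
#' fitted models. Models that fail to converge or show separation are
#' recorded but excluded from ranking and weights. Ties in AICc keep the
#' enumeration order.
#'
#' @param X data frame of predictors (columns are candidate terms).
#' @param y binary response.
#' @param max_predictors guard against combinatorial blow-up; raising it
#'   past 20 must be explicit.
#' @return object of class `candidate_models`: `table` (one row per model:
#'   `model`, `terms`, `k`, `loglik`, `aicc`, `delta`, `weight`, `ok`) and
#'   `fits` (list of `logistic_fit`).
#' @export
all_subsets <- function(X, y, max_predictors = 20) {
  X <- as.data.frame(X)
  p <- ncol(X)
  if (p > max_predictors)
    stop("2^", p, " subsets requested; raise max_predictors to confirm")
  n_models <- 2^p
  fits <- vector("list", n_models)
  rows <- vector("list", n_models)
  for (m in seq_len(n_models) - 1L) {
    idx <- which(bitwAnd(m, bitwShiftL(1L, seq_len(p) - 1L)) > 0)
    fit <- fit_logistic(X[, idx, drop = FALSE], y)
    ok <- fit$converged && !fit$separation
    fits[[m + 1L]] <- fit
    rows[[m + 1L]] <- data.frame(
      model = m + 1L,
      terms = paste(names(X)[idx], collapse = "+"),
      k = fit$k, loglik = fit$loglik,
      aicc = aicc(fit$loglik, fit$k, fit$n),
      ok = ok, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$delta <- NA_real_
  tab$weight <- NA_real_
  usable <- which(tab$ok)
  if (length(usable) == 0) stop("no model converged cleanly")
  best <- min(tab$aicc[usable])
  tab$delta[usable] <- tab$aicc[usable] - best
  ew <- exp(-tab$delta[usable] / 2)
  tab$weight[usable] <- ew / sum(ew)
  tab <- tab[, c("model", "terms", "k", "loglik", "aicc", "delta",
                 "weight", "ok")]
  n_dropped <- sum(!tab$ok)
  if (n_dropped > 0)
    message(n_dropped, " model(s) excluded from ranking ",
            "(non-convergence or separation)")
  structure(list(table = tab, fits = fits, predictors = names(X)),
            class = "candidate_models")
}

#' @export
print.candidate_models <- function(x, n = 10, ...) {
  cat("candidate_models:", nrow(x$table), "models over",
      length(x$predictors), "predictors\n")
  ord <- order(x$table$delta, x$table$model)
  print(utils::head(x$table[ord, ], n), row.names = FALSE)
  invisible(x)
}

#' Retain the models within a delta-AICc band
#'
#' Keeps models with `delta < delta_max` (strict inequality; the best model
#' always qualifies at `delta = 0`) and renormalises their Akaike weights to
#' sum to one within the retained set.
#'
#' @param models a `candidate_models` object from [all_subsets()].
#' @param delta_max band width; default 2.
#' @return a `candidate_models` object restricted to the band, ordered by
#'   delta (enumeration order within ties).
#' @export
candidate_set <- function(models, delta_max = 2) {
  stopifnot(inherits(models, "candidate_models"))
  tab <- models$table
  keep <- which(tab$ok & tab$delta < delta_max)
  keep <- keep[order(tab$delta[keep], tab$model[keep])]
  tab <- tab[keep, , drop = FALSE]
  tab$weight <- tab$weight / sum(tab$weight)
  structure(list(table = tab, fits = models$fits[keep],
                 predictors = models$predictors,
                 delta_max = delta_max),
            class = "candidate_models")
}

#' Average coefficients over a candidate model set
#'
#' Weighted averaging of coefficients over the retained models, in both
#' standard variants. The *full* average treats a term as zero in models
#' that exclude it (`sum w_i * b_i` over all models); the *conditional*
#' average renormalises over the containing models only. The unconditional
#' standard error per term is `sum w_i * sqrt(var_i + (b_i - bbar)^2)`,
#' with zero-variance, zero-estimate pseudo-entries included for the full
#' variant. Relative importance is the summed weight of models containing
#' the term. A term is flagged significant when 0 lies outside
#' `estimate +/- 1.96 * SE` of the headline variant.
#'
#' @param candidates a `candidate_models` object (typically from
#'   [candidate_set()]); weights must sum to 1.
#' @param headline which variant drives the significance flag
#'   (`"full"`, the default, or `"conditional"`).
#' @return object of class `averaged_model`: `terms` (data frame with
#'   `term`, `estimate_full`, `se_full`, `estimate_cond`, `se_cond`,
#'   `importance`, `significant`), plus member fits and weights.
#' @export
model_average <- function(candidates, headline = c("full", "conditional")) {
  stopifnot(inherits(candidates, "candidate_models"))
  headline <- match.arg(headline)
  tab <- candidates$table
  fits <- candidates$fits
  w <- tab$weight
  stopifnot(length(fits) >= 1, abs(sum(w) - 1) < 1e-8)
  all_terms <- unique(unlist(lapply(fits, function(f)
    names(f$coefficients))))
  out <- lapply(all_terms, function(tm) {
    b <- vapply(fits, function(f)
      if (tm %in% names(f$coefficients)) f$coefficients[[tm]] else 0,
      numeric(1))
    v <- vapply(fits, function(f)
      if (tm %in% names(f$coefficients)) f$se[[tm]]^2 else 0, numeric(1))
    has <- vapply(fits, function(f) tm %in% names(f$coefficients),
                  logical(1))
    est_full <- sum(w * b)
    se_full <- sum(w * sqrt(v + (b - est_full)^2))
    wc <- w[has] / sum(w[has])
    est_cond <- sum(wc * b[has])
    se_cond <- sum(wc * sqrt(v[has] + (b[has] - est_cond)^2))
    data.frame(term = tm, estimate_full = est_full, se_full = se_full,
               estimate_cond = est_cond, se_cond = se_cond,
               importance = sum(w[has]), stringsAsFactors = FALSE)
  })
  terms <- do.call(rbind, out)
  est <- if (headline == "full") terms$estimate_full else terms$estimate_cond
  se <- if (headline == "full") terms$se_full else terms$se_cond
  terms$significant <- abs(est) - .WALD_Z * se > 0
  structure(list(terms = terms, fits = fits, weights = w,
                 headline = headline),
            class = "averaged_model")
}

#' @export
print.averaged_model <- function(x, ...) {
  cat(sprintf("averaged_model over %d member model(s), headline = %s\n",
              length(x$fits), x$headline))
  print(x$terms, row.names = FALSE)
  invisible(x)
}

#' Predict occurrence probabilities from an averaged model
#'
#' The default (`type = "probability"`) averages the member models'
#' predicted probabilities with their Akaike weights,
#' `sum_i w_i * plogis(X b_i)` — well defined for the logit link. The
#' alternative (`type = "coefficient"`) applies the inverse link to the
#' linear predictor built from the full-averaged coefficients.
#'
#' @param avg an `averaged_model`.
#' @param X data frame of predictors covering every averaged term.
#' @param type prediction mode, see above.
#' @return vector of probabilities in `(0, 1)`.
#' @export
predict_average <- function(avg, X, type = c("probability", "coefficient")) {
  stopifnot(inherits(avg, "averaged_model"))
  type <- match.arg(type)
  X <- as.data.frame(X)
  needed <- setdiff(avg$terms$term, "(Intercept)")
  missing <- setdiff(needed, names(X))
  if (length(missing) > 0)
    stop("missing predictor column(s): ", paste(missing, collapse = ", "))
  if (type == "probability") {
    probs <- vapply(avg$fits, function(f)
      as.numeric(predict(f$glm, newdata = X, type = "response")),
      numeric(nrow(X)))
    probs <- matrix(probs, nrow = nrow(X))
    as.numeric(probs %*% avg$weights)
  } else {
    b <- setNames(avg$terms$estimate_full, avg$terms$term)
    eta <- rep(b[["(Intercept)"]], nrow(X))
    for (tm in needed) eta <- eta + b[[tm]] * X[[tm]]
    plogis(eta)
  }
}

#' Cook's distance for a logistic fit
#'
#' One-step approximation
#' `D_i = r_i^2 * h_i / (k * (1 - h_i)^2)` with Pearson residuals `r_i` and
#' hat values `h_i` from the final IRLS weighted design (the standard GLM
#' case-deletion approximation, as computed by `stats::cooks.distance`).
#' Observations above the threshold are reported for analyst-confirmed
#' exclusion, not dropped automatically.
#'
#' @param fit a converged `logistic_fit`.
#' @param threshold flag level; default 0.9 ("close to 1").
#' @return list: `d` (per-observation distances) and `flagged` (indices
#'   with `d > threshold`).
#' @export
cooks_distance_fit <- function(fit, threshold = 0.9) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!fit$converged) stop("Cook's distance requires a converged fit")
  d <- as.numeric(cooks.distance(fit$glm))
  list(d = d, flagged = which(d > threshold))
}

#' Likelihood-ratio pseudo-R-squared
#'
#' Cox–Snell: `1 - exp(-(2/n) * (l1 - l0))`; Nagelkerke rescales by the
#' maximum attainable value `1 - exp((2/n) * l0)` so a perfect model scores
#' 1. Both are computed; choose the headline via `variant`.
#'
#' @param fit fitted model (`logistic_fit`).
#' @param null_fit intercept-only `logistic_fit` on the same response.
#' @param variant `"both"` (default, returns a named list),
#'   `"coxsnell"`, or `"nagelkerke"`.
#' @return named list or single numeric.
#' @export
pseudo_r2 <- function(fit, null_fit,
                      variant = c("both", "coxsnell", "nagelkerke")) {
  variant <- match.arg(variant)
  stopifnot(inherits(fit, "logistic_fit"), inherits(null_fit, "logistic_fit"),
            fit$n == null_fit$n, length(null_fit$predictors) == 0)
  n <- fit$n
  if (fit$loglik < null_fit$loglik)
    warning("model fits worse than the null; pseudo-R2 is negative")
  cs <- 1 - exp(-(2 / n) * (fit$loglik - null_fit$loglik))
  nk <- cs / (1 - exp((2 / n) * null_fit$loglik))
  switch(variant,
         both = list(coxsnell = cs, nagelkerke = nk),
         coxsnell = cs,
         nagelkerke = nk)
}
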