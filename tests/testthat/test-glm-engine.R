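# Logistic engine: closed-form fits, AICc, subset search, weights,
# averaging formulas, diagnostics, pseudo-R2.

# minimal stand-in for a fitted model, for unit tests of the averaging
# arithmetic (model_average only touches $coefficients and $se)
fake_fit <- function(coefs, ses) {
  structure(list(coefficients = coefs, se = ses), class = "logistic_fit")
}
fake_candidates <- function(fits, weights) {
  structure(list(table = data.frame(model = seq_along(fits),
                                    weight = weights,
                                    delta = rep(0, length(fits)),
                                    ok = TRUE),
                 fits = fits, predictors = character(0)),
            class = "candidate_models")
}

test_that("intercept-only and 2x2 fits match their closed forms", {
  y <- c(rep(1, 75), rep(0, 100))
  fit0 <- fit_logistic(data.frame(row.names = seq_along(y)), y)
  expect_equal(unname(fit0$coefficients), log(75 / 100), tolerance = 1e-8)
  expect_equal(fit0$k, 1L)
  expect_true(all(fit0$fitted > 0 & fit0$fitted < 1))

  # single binary predictor: slope is the log odds ratio log(ad/bc)
  x <- c(rep(1, 50), rep(0, 50))
  y2 <- c(rep(1, 30), rep(0, 20), rep(1, 10), rep(0, 40))
  fit <- fit_logistic(data.frame(x = x), y2)
  expect_equal(unname(fit$coefficients["x"]), log((30 * 40) / (20 * 10)),
               tolerance = 1e-7)
  expect_equal(unname(fit$coefficients["(Intercept)"]), log(10 / 40),
               tolerance = 1e-7)
  expect_lte(fit$loglik, 0)
})

test_that("complete separation is flagged, not fatal", {
  x <- c(-(5:1), 1:5) / 5
  y <- as.integer(x > 0)
  fit <- fit_logistic(data.frame(x = x), y)
  expect_true(fit$separation)
})

test_that("IRLS estimates match a generic likelihood optimizer", {
  for (s in 1:5) {
    set.seed(100 + s)
    n <- 80
    X <- data.frame(a = rnorm(n), b = runif(n))
    y <- rbinom(n, 1, plogis(-0.3 + 0.8 * X$a - 1.2 * X$b))
    fit <- fit_logistic(X, y)
    Xmat <- cbind(1, as.matrix(X))
    opt <- optim(c(0, 0, 0), neg_loglik, Xmat = Xmat, y = y,
                 method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 500))
    expect_equal(unname(fit$coefficients), opt$par, tolerance = 1e-6)
    expect_equal(fit$loglik, -opt$value, tolerance = 1e-8)
  }
})

test_that("AICc formula, boundary, and large-n limit", {
  expect_equal(aicc(-10, 2, 100), 24 + 12 / 97)
  # correction term at k = 1, n = 3 is 2*1*2/1 = 4
  expect_equal(aicc(-10, 1, 3) - (-2 * -10 + 2 * 1), 4)
  expect_error(aicc(-10, 2, 3), "n > k \\+ 1")
  corr <- vapply(c(10, 50, 200, 1000), function(n)
    aicc(-10, 3, n) - (-2 * -10 + 6), numeric(1))
  expect_true(all(diff(corr) < 0))  # decreases towards AIC
  expect_true(all(corr > 0))        # AICc always exceeds AIC
})

test_that("all_subsets enumerates every subset and matches brute force", {
  set.seed(31)
  n <- 120
  X <- data.frame(x1 = rnorm(n), x2 = runif(n), x3 = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.5 + 1.5 * X$x1))
  ms <- all_subsets(X, y)
  expect_identical(nrow(ms$table), 8L)
  sets <- lapply(strsplit(ms$table$terms, "\\+"), function(s)
    sort(s[nzchar(s)]))
  want <- lapply(list(character(0), "x1", "x2", "x3", c("x1", "x2"),
                      c("x1", "x3"), c("x2", "x3"),
                      c("x1", "x2", "x3")), sort)
  expect_true(all(want %in% sets) && length(sets) == length(want))

  # model-by-model brute force over explicit subsets
  for (i in seq_len(nrow(ms$table))) {
    terms <- strsplit(ms$table$terms[i], "\\+")[[1]]
    terms <- terms[nzchar(terms)]
    ref <- fit_logistic(X[, terms, drop = FALSE], y)
    expect_equal(ms$table$loglik[i], ref$loglik, tolerance = 1e-10)
    expect_equal(ms$table$aicc[i], aicc(ref$loglik, ref$k, ref$n))
  }

  # best model: delta 0, largest weight; weights sum to one
  best <- which.min(ms$table$aicc)
  expect_equal(ms$table$delta[best], 0)
  expect_equal(max(ms$table$weight), ms$table$weight[best])
  expect_equal(sum(ms$table$weight), 1)
  # the informative predictor is in the top-ranked model
  expect_match(ms$table$terms[best], "x1")

  expect_error(all_subsets(as.data.frame(matrix(rnorm(n * 21), n)), y),
               "max_predictors")
})

test_that("Akaike weights are invariant to a constant AICc shift", {
  a <- c(100, 101.3, 104)
  w1 <- exp(-(a - min(a)) / 2); w1 <- w1 / sum(w1)
  a2 <- a + 57.3
  w2 <- exp(-(a2 - min(a2)) / 2); w2 <- w2 / sum(w2)
  expect_equal(w1, w2)
})

test_that("candidate_set applies the strict delta band and renormalizes", {
  set.seed(32)
  n <- 150
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y <- rbinom(n, 1, plogis(X$x1))
  ms <- all_subsets(X, y)
  cs <- candidate_set(ms, delta_max = 2)
  expect_true(all(cs$table$delta < 2))
  expect_equal(sum(cs$table$weight), 1)
  expect_equal(cs$table$delta[1], 0)

  # strict boundary: a model at exactly delta = delta_max is excluded
  d2 <- sort(ms$table$delta)[2]
  cs2 <- candidate_set(ms, delta_max = d2)
  expect_identical(nrow(cs2$table), 1L)
  expect_equal(cs2$table$weight, 1)

  # two models at delta {0, 1}: renormalized weights follow exp(-delta/2)
  csb <- candidate_set(ms, delta_max = Inf)
  w <- exp(-csb$table$delta / 2) / sum(exp(-csb$table$delta / 2))
  expect_equal(csb$table$weight, w)
  expect_equal(
    exp(0) / (exp(0) + exp(-0.5)), 0.62245933, tolerance = 1e-7)
})

test_that("model averaging follows the full and conditional formulas", {
  # one candidate: averaged model identical to it in both variants
  f <- fake_fit(c(`(Intercept)` = -1, a = 2), c(`(Intercept)` = 0.5, a = 0.3))
  avg1 <- model_average(fake_candidates(list(f), 1))
  expect_equal(avg1$terms$estimate_full, c(-1, 2))
  expect_equal(avg1$terms$estimate_cond, c(-1, 2))
  expect_equal(avg1$terms$se_full, c(0.5, 0.3))
  expect_equal(avg1$terms$se_cond, c(0.5, 0.3))
  expect_equal(avg1$terms$importance, c(1, 1))

  # equal weights, term in both with beta 1 and 3, SE 0:
  # average 2, unconditional SE = 0.5*|1-2| + 0.5*|3-2| = 1
  f1 <- fake_fit(c(a = 1), c(a = 0))
  f2 <- fake_fit(c(a = 3), c(a = 0))
  avg2 <- model_average(fake_candidates(list(f1, f2), c(0.5, 0.5)))
  expect_equal(avg2$terms$estimate_full, 2)
  expect_equal(avg2$terms$se_full, 1)

  # term in only one of two equal-weight models (beta = 2 there):
  # conditional 2, full 1; importance 0.5
  f3 <- fake_fit(c(`(Intercept)` = 0, a = 2),
                 c(`(Intercept)` = 0.1, a = 0.2))
  f4 <- fake_fit(c(`(Intercept)` = 0), c(`(Intercept)` = 0.1))
  avg3 <- model_average(fake_candidates(list(f3, f4), c(0.5, 0.5)))
  row_a <- avg3$terms[avg3$terms$term == "a", ]
  expect_equal(row_a$estimate_cond, 2)
  expect_equal(row_a$estimate_full, 1)
  expect_equal(row_a$importance, 0.5)
  # full-variant SE includes the zero pseudo-entry:
  # 0.5*sqrt(0.04 + 1) + 0.5*sqrt(0 + 1)
  expect_equal(row_a$se_full, 0.5 * sqrt(0.04 + 1) + 0.5)
})

test_that("averaged predictions combine members by weight and stay in (0,1)", {
  set.seed(33)
  n <- 200
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y <- rbinom(n, 1, plogis(0.8 * X$x1))
  cs <- candidate_set(all_subsets(X, y), delta_max = Inf)
  avg <- model_average(cs)
  p <- predict_average(avg, X)
  # equals the weighted member predictions, by construction
  member_p <- vapply(cs$fits, function(f)
    as.numeric(predict(f$glm, newdata = X, type = "response")),
    numeric(n))
  expect_equal(p, as.numeric(member_p %*% cs$table$weight))
  expect_true(all(p > 0 & p < 1))

  # single-member set: predictions are that model's own fitted values
  cs1 <- candidate_set(all_subsets(X, y), delta_max = 1e-9)
  avg1 <- model_average(cs1)
  expect_equal(predict_average(avg1, X), unname(cs1$fits[[1]]$fitted))

  # coefficient mode agrees with the inverse link of the averaged terms
  b <- setNames(avg$terms$estimate_full, avg$terms$term)
  eta <- b[["(Intercept)"]] + b[["x1"]] * X$x1 + b[["x2"]] * X$x2
  expect_equal(predict_average(avg, X, type = "coefficient"),
               unname(plogis(eta)))
  expect_error(predict_average(avg, X["x1"]), "missing predictor")
})

test_that("Cook's distance is symmetric on balanced designs and finds outliers", {
  # perfectly balanced duplicated design: all distances equal
  X <- data.frame(x = rep(c(0, 1), each = 20))
  y <- rep(c(0, 1, 0, 1), each = 10)
  fit <- fit_logistic(X, y)
  d <- cooks_distance_fit(fit)$d
  expect_true(all(d >= 0))
  expect_equal(length(unique(round(d, 12))), 1L)

  # one gross outlier dominates
  set.seed(34)
  x2 <- c(rnorm(40), 8)
  y2 <- c(rbinom(40, 1, plogis(2 * x2[1:40])), 0)
  fit2 <- fit_logistic(data.frame(x = x2), y2)
  d2 <- cooks_distance_fit(fit2)$d
  expect_identical(which.max(d2), 41L)
})

test_that("pseudo-R2 variants match the likelihood-ratio formulas", {
  null_fit <- structure(list(loglik = -121.3, n = 175,
                             predictors = character(0)),
                        class = "logistic_fit")
  fit <- structure(list(loglik = -90, n = 175, predictors = "x"),
                   class = "logistic_fit")
  r2 <- pseudo_r2(fit, null_fit)
  expect_equal(r2$coxsnell, 1 - exp(-2 * 31.3 / 175))
  expect_equal(r2$coxsnell, 0.30073, tolerance = 1e-4)
  expect_gte(r2$nagelkerke, r2$coxsnell)

  # model identical to the null scores zero in both variants
  same <- pseudo_r2(structure(list(loglik = -121.3, n = 175,
                                   predictors = "x"),
                              class = "logistic_fit"), null_fit)
  expect_equal(same$coxsnell, 0)
  expect_equal(same$nagelkerke, 0)

  # worse than the null: negative with a warning
  expect_warning(
    worse <- pseudo_r2(structure(list(loglik = -130, n = 175,
                                      predictors = "x"),
                                 class = "logistic_fit"), null_fit),
    "negative")
  expect_lt(worse$coxsnell, 0)
})
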