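# Fixtures built in code: small site tables, occurrence matrices, and
# logistic toy data used across the test files.

# n sites on a rough Connecticut-like grid with iid covariates; cheap to
# build at any n (no spatial field, no distance matrix)
make_sites <- function(n, seed = 1) {
  set.seed(seed)
  site_table(data.frame(
    site_id = sprintf("S%04d", seq_len(n)),
    latitude = runif(n, 41, 42),
    longitude = runif(n, -73.5, -72),
    totalP = runif(n, 0.005, 0.1),
    cond = runif(n, 20, 400),
    secchi = runif(n, 0.5, 6),
    pH = runif(n, 5.5, 8.5),
    stringsAsFactors = FALSE))
}

# occurrence matrix from a named list group -> list(taxon = occupied site
# indices), over n sites
make_occ <- function(n, taxa_sites, groups) {
  taxa <- names(taxa_sites)
  pres <- matrix(0L, n, length(taxa),
                 dimnames = list(sprintf("S%04d", seq_len(n)), taxa))
  for (tx in taxa) pres[taxa_sites[[tx]], tx] <- 1L
  occurrence_matrix(pres, setNames(groups, taxa))
}

# Bernoulli response from a logistic model on one iid uniform covariate
make_logistic_toy <- function(n, b0, b1, seed = 1) {
  set.seed(seed)
  x <- runif(n)
  p <- plogis(b0 + b1 * x)
  list(X = data.frame(x = x), y = rbinom(n, 1, p), p = p)
}

# negative Bernoulli log-likelihood minimised by the generic-optimizer
# oracle used against the IRLS path
neg_loglik <- function(beta, Xmat, y) {
  eta <- as.numeric(Xmat %*% beta)
  -sum(y * eta - log1p(exp(eta)))
}

# benchmark confusion matrices for the four focal responses of a
# 176-water-body survey (rows predicted, columns observed)
benchmark_confusions <- function() {
  list(
    lemna     = threshold_evaluation(tn = 83, fn = 36, fp = 17, tp = 39),
    spirodela = threshold_evaluation(tn = 99, fn = 45, fp = 11, tp = 20),
    wolffia   = threshold_evaluation(tn = 115, fn = 37, fp = 6, tp = 17),
    group     = threshold_evaluation(tn = 75, fn = 29, fp = 20, tp = 51))
}
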