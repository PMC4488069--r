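# Species-pool permutation null model.
#
# Question: is the observed fraction of water bodies lacking the focal
# functional group different from what random community assembly predicts,
# given only the size of the group's species pool? Each iteration draws S
# occupancy frequencies with replacement from the occupancies of the whole
# regional flora, assigns each pseudo-species to that many sites uniformly
# at random, and records the fraction of sites left empty of the group.
# The exact conditional expectation prod(1 - k_i/n) provides an analytic
# oracle for the assignment step.

#' Observed fraction of sites lacking a functional group
#'
#' @param occ an [occurrence_matrix()].
#' @param group functional-group label. An unknown label is an error unless
#'   `strict = FALSE`, in which case a group with zero member taxa is
#'   vacuously absent everywhere (returns 1).
#' @param strict error on labels not present in the matrix (default).
#' @return proportion of sites where every member taxon is absent.
#' @export
observed_empty_proportion <- function(occ, group, strict = TRUE) {
  stopifnot(inherits(occ, "occurrence_matrix"))
  if (strict && !group %in% occ$group_of)
    stop("unknown group label: ", group)
  members <- occ$taxa[occ$group_of == group]
  if (length(members) == 0) return(1)
  mean(rowSums(occ$presence[, members, drop = FALSE]) == 0)
}

#' Exact expected empty fraction at fixed occupancies
#'
#' With each of `S` species placed independently and uniformly on `k_i` of
#' `n` sites, a given site escapes species `i` with probability
#' `1 - k_i/n`, so the expected fraction of sites with no species is
#' `prod_i (1 - k_i/n)` — the exact expectation of the Monte-Carlo
#' statistic conditional on the drawn frequencies.
#'
#' @param frequencies integer occupancies `k_1..k_S`, each in `[0, n_sites]`.
#' @param n_sites number of sites.
#' @return expected empty proportion.
#' @export
expected_empty_exact <- function(frequencies, n_sites) {
  if (any(frequencies < 0 | frequencies > n_sites))
    stop("occupancy outside [0, n_sites]")
  prod(1 - frequencies / n_sites)
}

#' Percentile confidence interval from Monte-Carlo samples
#'
#' Empirical percentiles at `(1 - level)/2` and `1 - (1 - level)/2`, with
#' linear interpolation between order statistics.
#'
#' @param samples numeric vector, length >= 2.
#' @param level coverage in `(0, 1)`; default 0.95.
#' @return named vector `c(lo, hi)`.
#' @export
empirical_ci <- function(samples, level = 0.95) {
  if (length(samples) < 2) stop("need at least two samples")
  stopifnot(level > 0, level < 1)
  q <- quantile(samples, c((1 - level) / 2, 1 - (1 - level) / 2),
                names = FALSE, type = 7)
  c(lo = q[1], hi = q[2])
}

#' Species-pool permutation null model for group prevalence
#'
#' Per iteration: draw `S` occupancy frequencies with replacement from
#' `freq_pool` (the occupancies of *all* taxa in the regional flora, focal
#' group included), assign each pseudo-species to that many distinct sites
#' uniformly at random (independently across species — random assembly, no
#' environmental filtering or interactions), and record the fraction of
#' sites holding zero pseudo-species. Summaries are the mean, a percentile
#' confidence interval, and — when an observed proportion is supplied — a
#' two-sided empirical p-value `2 * min(tail proportions)` (add-one
#' corrected, capped at 1).
#'
#' @param freq_pool integer occupancy frequencies of the whole species
#'   pool, each in `[0, n_sites]`.
#' @param S species-pool size of the focal group (pseudo-species per
#'   iteration).
#' @param n_sites number of sites.
#' @param B number of Monte-Carlo iterations; default 2000.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param observed observed empty proportion to compare against, or `NULL`.
#' @param level confidence level for the percentile interval.
#' @return object of class `null_model_result`: `S`, `B`, `samples`
#'   (per-iteration empty proportions), `mean`, `ci` (`lo`, `hi`, `level`),
#'   `observed`, `p_value`, `seed`.
#' @export
permutation_null <- function(freq_pool, S, n_sites, B = 2000, seed = NULL,
                             observed = NULL, level = 0.95) {
  if (length(freq_pool) == 0) stop("empty frequency pool")
  if (any(freq_pool < 0 | freq_pool > n_sites))
    stop("pool occupancy outside [0, n_sites]")
  stopifnot(S >= 1, B >= 1)
  if (!is.null(seed)) set.seed(seed)
  samples <- vapply(seq_len(B), function(b) {
    ks <- freq_pool[sample.int(length(freq_pool), S, replace = TRUE)]
    occupied <- logical(n_sites)
    for (k in ks) if (k > 0) occupied[sample.int(n_sites, k)] <- TRUE
    mean(!occupied)
  }, numeric(1))
  p_value <- NULL
  if (!is.null(observed)) {
    lo_tail <- (sum(samples <= observed) + 1) / (B + 1)
    hi_tail <- (sum(samples >= observed) + 1) / (B + 1)
    p_value <- min(1, 2 * min(lo_tail, hi_tail))
  }
  structure(list(S = S, B = B, samples = samples,
                 mean = mean(samples),
                 ci = c(empirical_ci(samples, level), level = level),
                 observed = observed, p_value = p_value, seed = seed),
            class = "null_model_result")
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf(
    "null_model_result: S = %d, B = %d\nmean empty = %.3f  %d%% CI [%.3f, %.3f]\n",
    x$S, x$B, x$mean, round(100 * x$ci[["level"]]),
    x$ci[["lo"]], x$ci[["hi"]]))
  if (!is.null(x$observed))
    cat(sprintf("observed = %.3f  two-sided p = %.4f\n",
                x$observed, x$p_value))
  invisible(x)
}

#' Run the null model across several pool sizes
#'
#' @param freq_pool,n_sites,B,seed,observed,level as in
#'   [permutation_null()].
#' @param pool_sizes vector of `S` values; default `c(1, 6, 12, 24)`.
#' @return list of `null_model_result`, named by pool size, plus a summary
#'   data frame in attribute `"summary"`.
#' @export
null_model_curve <- function(freq_pool, n_sites, pool_sizes = c(1, 6, 12, 24),
                             B = 2000, seed = NULL, observed = NULL,
                             level = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(pool_sizes, function(S)
    permutation_null(freq_pool, S, n_sites, B = B, seed = NULL,
                     observed = observed, level = level))
  names(res) <- as.character(pool_sizes)
  attr(res, "summary") <- data.frame(
    S = pool_sizes,
    mean = vapply(res, function(r) r$mean, numeric(1)),
    lo = vapply(res, function(r) r$ci[["lo"]], numeric(1)),
    hi = vapply(res, function(r) r$ci[["hi"]], numeric(1)),
    row.names = NULL)
  res
}
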