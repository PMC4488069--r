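# Correlation-matrix PCA of site environmental conditions: the dominant
# axes of variation in local water-body conditions, for descriptive maps
# and tables of loadings and explained variance.

#' Principal component analysis of site conditions (correlation matrix)
#'
#' Variables are centred and scaled (unit variance) before the
#' eigendecomposition, so the analysis is invariant to affine rescaling of
#' any input variable. Components are ordered by eigenvalue. Sign
#' convention: within each component the loading of largest magnitude is
#' made positive (signs are otherwise arbitrary up to reflection).
#'
#' @param sites a [site_table()] or data frame.
#' @param variables character vector of (numeric, non-constant) columns to
#'   analyse; at least two, and fewer than the number of complete rows.
#' @return object of class `pca_result`: `variables`, `loadings`
#'   (variables x components, orthonormal columns), `proportion`
#'   (variance explained per component; non-negative, non-increasing, sums
#'   to 1), `sdev`, `scores` (per-site, rows dropped for missing values
#'   are reported via attribute `"dropped"`).
#' @export
pca_correlation <- function(sites, variables) {
  df <- as.data.frame(sites)
  missing <- setdiff(variables, names(df))
  if (length(missing) > 0)
    stop("unknown variable(s): ", paste(missing, collapse = ", "))
  if (length(variables) < 2) stop("need at least two variables")
  x <- df[, variables, drop = FALSE]
  complete <- complete.cases(x)
  dropped <- which(!complete)
  if (length(dropped) > 0)
    message(length(dropped), " site(s) with missing values dropped from PCA")
  x <- x[complete, , drop = FALSE]
  if (nrow(x) <= length(variables))
    stop("need more complete sites than variables")
  for (v in variables)
    if (sd(x[[v]]) == 0) stop("constant variable: ", v)
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  # reflect components so the largest-magnitude loading is positive
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  rotation <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  if (!is.null(df$site_id)) rownames(scores) <- df$site_id[complete]
  prop <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(variables = variables, loadings = rotation,
                 proportion = prop, sdev = pc$sdev, scores = scores,
                 dropped = dropped),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, n_components = 4, ...) {
  k <- min(n_components, ncol(x$loadings))
  cat("pca_result (correlation matrix),", length(x$variables), "variables\n")
  tab <- rbind(x$loadings[, seq_len(k), drop = FALSE],
               `Proportion of Variance` = x$proportion[seq_len(k)])
  print(round(tab, 3))
  invisible(x)
}
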