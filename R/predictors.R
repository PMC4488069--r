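# Derived predictors fed into the occurrence models: shoreline development
# index, unit-interval rescaling, great-circle distances, neighbour counts,
# distance to nearest occupied water body, and a collinearity screen.

.EARTH_RADIUS_KM <- 6371.0088

#' Shoreline development index
#'
#' Ratio of a water body's shoreline length to the circumference of a circle
#' with the same surface area: `L / (2 * sqrt(pi * A))` with `A` in square
#' metres. Equals 1 for a perfect circle and grows with shoreline
#' convolution; it is scale invariant (scaling `L` by `c` and `A` by `c^2`
#' leaves it unchanged).
#'
#' @param shore_length_m shoreline length in metres.
#' @param area_ha surface area in hectares (converted internally to m^2).
#' @return dimensionless index, >= 1 for simple closed shorelines.
#' @export
shoreline_development_index <- function(shore_length_m, area_ha) {
  if (any(shore_length_m <= 0) || any(area_ha <= 0))
    stop("shore length and area must be positive")
  area_m2 <- area_ha * 1e4
  shore_length_m / (2 * sqrt(pi * area_m2))
}

#' Rescale a predictor to span the unit interval
#'
#' Affine map sending the minimum to 0 and the maximum to 1, so model
#' coefficients are comparable across predictors measured on different
#' scales. Idempotent: rescaling twice equals rescaling once.
#'
#' @param values numeric vector with at least two finite values and
#'   `max > min`.
#' @return rescaled vector in `[0, 1]`.
#' @export
rescale_unit_interval <- function(values) {
  finite <- values[is.finite(values)]
  if (length(finite) < 2)
    stop("need at least two finite values")
  rng <- range(finite)
  if (rng[1] == rng[2])
    stop("constant predictor has no spread; drop it before rescaling")
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Great-circle distance between two points, in km
#'
#' Haversine distance on a sphere of radius 6371.0088 km.
#'
#' @param a,b numeric vectors `c(latitude, longitude)` in decimal degrees.
#' @return distance in km.
#' @export
haversine_km <- function(a, b) {
  stopifnot(length(a) == 2, length(b) == 2)
  if (abs(a[1]) > 90 || abs(b[1]) > 90) stop("latitude outside [-90, 90]")
  if (abs(a[2]) > 180 || abs(b[2]) > 180) stop("longitude outside [-180, 180]")
  # geosphere expects (lon, lat) and a radius in metres
  geosphere::distHaversine(c(a[2], a[1]), c(b[2], b[1]),
                           r = .EARTH_RADIUS_KM * 1000) / 1000
}

# all pairwise great-circle distances between sites, km
.site_distance_matrix <- function(sites) {
  p <- cbind(sites$longitude, sites$latitude)
  d <- geosphere::distm(p, fun = function(x, y)
    geosphere::distHaversine(x, y, r = .EARTH_RADIUS_KM * 1000)) / 1000
  dimnames(d) <- list(sites$site_id, sites$site_id)
  d
}

#' Number of neighbouring water bodies within a radius
#'
#' Counts sites whose great-circle distance from the focal site is at most
#' `radius_km` (closed ball); the focal site itself is never counted.
#'
#' @param sites a [site_table()].
#' @param focal a `site_id` present in `sites`.
#' @param radius_km non-negative radius in km.
#' @return integer count.
#' @export
count_neighbors_within <- function(sites, focal, radius_km) {
  stopifnot(inherits(sites, "site_table"), radius_km >= 0)
  i <- match(focal, sites$site_id)
  if (is.na(i)) stop("unknown focal site: ", focal)
  d <- vapply(seq_len(nrow(sites)), function(j)
    haversine_km(c(sites$latitude[i], sites$longitude[i]),
                 c(sites$latitude[j], sites$longitude[j])), numeric(1))
  sum(d[-i] <= radius_km)
}

#' Distance to the nearest other water body occupied by a taxon
#'
#' Minimum great-circle distance from the focal site to any *other* site
#' where the taxon is present; the focal site is excluded even when itself
#' occupied. Returns `NA` (with a warning) when no other site is occupied —
#' never zero.
#'
#' @param sites a [site_table()].
#' @param occ an aligned [occurrence_matrix()].
#' @param taxon taxon label.
#' @param focal focal `site_id`.
#' @return distance in km, or `NA_real_`.
#' @export
distance_to_nearest_occupied <- function(sites, occ, taxon, focal) {
  stopifnot(inherits(sites, "site_table"), inherits(occ, "occurrence_matrix"))
  if (!taxon %in% occ$taxa) stop("unknown taxon: ", taxon)
  i <- match(focal, sites$site_id)
  if (is.na(i)) stop("unknown focal site: ", focal)
  occupied <- which(occ$presence[, taxon] == 1)
  occupied <- setdiff(occupied, i)
  if (length(occupied) == 0) {
    warning("no other site occupied by '", taxon, "'; returning NA")
    return(NA_real_)
  }
  min(vapply(occupied, function(j)
    haversine_km(c(sites$latitude[i], sites$longitude[i]),
                 c(sites$latitude[j], sites$longitude[j])), numeric(1)))
}

#' Screen predictors for collinearity
#'
#' Pearson product-moment correlations between all numeric predictor pairs
#' (for a 0/1 predictor this is the point-biserial correlation). Pairs with
#' `|r| >= threshold` are flagged, sorted by `|r|` descending. The screen is
#' advisory: it reports, the analyst decides which member of a flagged pair
#' to drop.
#'
#' @param sites a [site_table()] (or plain data frame of predictors).
#' @param threshold flag threshold in `(0, 1)`; default 0.7.
#' @param variables columns to screen; default all numeric columns except
#'   `site_id`.
#' @return data frame `var1, var2, r` of flagged pairs (may have zero rows);
#'   the full correlation matrix is attached as attribute `"correlations"`.
#' @export
collinearity_screen <- function(sites, threshold = 0.7, variables = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  df <- as.data.frame(sites)
  if (is.null(variables)) {
    variables <- names(df)[vapply(df, is.numeric, logical(1))]
    variables <- setdiff(variables, "site_id")
  }
  if (nrow(df) < 3) stop("need at least 3 sites")
  unknown <- setdiff(variables, names(df))
  if (length(unknown) > 0)
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  keep <- character(0)
  for (v in variables) {
    if (sd(df[[v]], na.rm = TRUE) == 0 || all(is.na(df[[v]]))) {
      warning("constant column '", v, "' excluded from collinearity screen")
    } else keep <- c(keep, v)
  }
  cm <- cor(df[, keep, drop = FALSE], use = "pairwise.complete.obs")
  pairs <- which(upper.tri(cm) & abs(cm) >= threshold, arr.ind = TRUE)
  out <- data.frame(var1 = keep[pairs[, 1]], var2 = keep[pairs[, 2]],
                    r = cm[pairs], stringsAsFactors = FALSE)
  out <- out[order(-abs(out$r)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "correlations") <- cm
  out
}
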