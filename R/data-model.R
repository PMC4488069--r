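# Core domain containers: per-site covariate table, site x taxon
# presence/absence matrix, and response definitions.

# Table-1 style covariate codes and their validation classes.
.count_covariates  <- c("nonFP", "lakes1km", "lakes10km")
.binary_covariates <- c("boatlaunch")
.nonneg_covariates <- c("size", "shoreline", "depth", "totalP", "cond",
                        "alk", "secchi", "distLM", "distSP", "distW")

#' Construct and validate a site covariate table
#'
#' A `site_table` is a data frame with one row per surveyed water body,
#' holding a unique `site_id`, decimal-degree coordinates, and any subset of
#' the standard covariate columns: `size` (surface area, ha), `shoreline`
#' (shoreline development index, dimensionless), `depth` (maximum depth, m),
#' `totalP` (total phosphorus, mg/L), `pH`, `cond` (conductivity, uS/cm),
#' `alk` (alkalinity, mg/L), `secchi` (Secchi depth, m), `nonFP` (richness of
#' non-floating plants), `lakes1km`/`lakes10km` (neighbouring water bodies
#' within 1 and 10 km), `distLM`/`distSP`/`distW` (km to the nearest water
#' body occupied by each focal taxon), and `boatlaunch` (0/1).
#'
#' @param df data frame with at least `site_id`, `latitude`, `longitude`.
#' @return the validated data frame with class `site_table`.
#' @export
site_table <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("site_id", "latitude", "longitude")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("site table lacks required column(s): ", paste(missing, collapse = ", "))
  df$site_id <- as.character(df$site_id)
  dup <- unique(df$site_id[duplicated(df$site_id)])
  if (length(dup) > 0)
    stop("duplicate site_id(s): ", paste(dup, collapse = ", "))
  if (any(df$latitude < -90 | df$latitude > 90, na.rm = TRUE))
    stop("latitude outside [-90, 90]")
  if (any(df$longitude < -180 | df$longitude > 180, na.rm = TRUE))
    stop("longitude outside [-180, 180]")
  for (v in intersect(.count_covariates, names(df))) {
    x <- df[[v]]
    if (any(x < 0 | x != round(x), na.rm = TRUE))
      stop("covariate '", v, "' must hold non-negative integer counts")
  }
  for (v in intersect(.binary_covariates, names(df))) {
    if (!all(df[[v]] %in% c(0, 1, NA)))
      stop("covariate '", v, "' must be 0/1")
  }
  for (v in intersect(.nonneg_covariates, names(df))) {
    if (any(df[[v]] < 0, na.rm = TRUE))
      stop("covariate '", v, "' must be non-negative")
  }
  if ("pH" %in% names(df) && any(df$pH < 0 | df$pH > 14, na.rm = TRUE))
    stop("pH outside [0, 14]")
  class(df) <- unique(c("site_table", class(df)))
  df
}

#' Construct and validate a site-by-taxon occurrence matrix
#'
#' Rows are sites (in the same order as a companion [site_table()]), columns
#' are taxa, entries are 0/1 presence. Each taxon carries exactly one
#' functional-group label (e.g. `"floating"` for free-floating plants,
#' `"other"` for the rest of the flora).
#'
#' @param presence numeric or integer matrix of 0/1 with rownames = site ids
#'   and colnames = taxon labels.
#' @param group_of named character vector mapping every taxon to its
#'   functional group.
#' @return an object of class `occurrence_matrix` with elements `sites`,
#'   `taxa`, `presence`, `group_of`.
#' @export
occurrence_matrix <- function(presence, group_of) {
  stopifnot(is.matrix(presence))
  if (is.null(rownames(presence)) || is.null(colnames(presence)))
    stop("presence matrix needs site rownames and taxon colnames")
  bad <- which(!(presence %in% c(0, 1)), arr.ind = FALSE)
  if (length(bad) > 0) {
    ij <- arrayInd(bad[1], dim(presence))
    stop(sprintf("occurrence value '%s' outside {0,1} at site '%s', taxon '%s'",
                 presence[bad[1]], rownames(presence)[ij[1]],
                 colnames(presence)[ij[2]]))
  }
  taxa <- colnames(presence)
  if (is.null(names(group_of)) || !setequal(names(group_of), taxa) ||
      length(group_of) != length(taxa))
    stop("group_of must assign exactly one group label to every taxon")
  storage.mode(presence) <- "integer"
  structure(list(sites = rownames(presence), taxa = taxa,
                 presence = presence,
                 group_of = group_of[taxa]),
            class = "occurrence_matrix")
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat("occurrence_matrix:", length(x$sites), "sites x", length(x$taxa),
      "taxa\n")
  tab <- table(x$group_of)
  cat("groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Per-taxon occupancy frequencies
#'
#' Number of sites in which each taxon was recorded present (the frequencies
#' `k_i` resampled by the species-pool null model).
#'
#' @param occ an [occurrence_matrix()].
#' @return named integer vector, one entry per taxon.
#' @export
occupancy_frequencies <- function(occ) {
  stopifnot(inherits(occ, "occurrence_matrix"))
  f <- colSums(occ$presence)
  setNames(as.integer(f), names(f))
}

#' Define a model response: one taxon or a whole functional group
#'
#' @param name label used in outputs.
#' @param taxon single taxon whose presence is the response, or `NULL`.
#' @param group functional-group label; the response is presence of *any*
#'   member taxon. Exactly one of `taxon`/`group` must be given.
#' @return object of class `response_spec`.
#' @export
response_spec <- function(name, taxon = NULL, group = NULL) {
  if (is.null(taxon) == is.null(group))
    stop("give exactly one of 'taxon' or 'group'")
  structure(list(name = name, taxon = taxon, group = group),
            class = "response_spec")
}

#' Extract the 0/1 response vector defined by a response_spec
#'
#' @param spec a [response_spec()].
#' @param occ an [occurrence_matrix()].
#' @return integer vector of length `n_sites`.
#' @export
response_vector <- function(spec, occ) {
  stopifnot(inherits(spec, "response_spec"), inherits(occ, "occurrence_matrix"))
  if (!is.null(spec$taxon)) {
    if (!spec$taxon %in% occ$taxa)
      stop("unknown taxon: ", spec$taxon)
    return(as.integer(occ$presence[, spec$taxon]))
  }
  members <- occ$taxa[occ$group_of == spec$group]
  if (length(members) == 0 && !spec$group %in% occ$group_of)
    stop("unknown group label: ", spec$group)
  as.integer(rowSums(occ$presence[, members, drop = FALSE]) > 0)
}
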