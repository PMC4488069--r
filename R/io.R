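# Delimited-text input/output for survey data.
#
# Three plain CSV files describe a survey:
#   sites.csv       one row per water body: site_id, latitude, longitude,
#                   covariate columns (Table-1 style codes)
#   occurrence.csv  one row per water body: site_id then one 0/1 column per
#                   taxon
#   taxa.csv        two columns: taxon, group
# Writers emit RFC-4180-style CSV, '.' decimal separator, fixed column order,
# so that read -> write is the identity on canonical files.

.canonical_site_columns <- c("site_id", "latitude", "longitude",
                             "size", "shoreline", "depth", "totalP", "pH",
                             "cond", "alk", "secchi", "nonFP",
                             "lakes1km", "lakes10km",
                             "distLM", "distSP", "distW", "boatlaunch")

.canonical_order <- function(cols) {
  known <- intersect(.canonical_site_columns, cols)
  c(known, sort(setdiff(cols, known)))
}

# deterministic, locale-independent cell formatting ('.' decimal separator)
.format_cells <- function(df) {
  as.data.frame(lapply(df, function(x) {
    if (is.numeric(x)) {
      out <- vapply(x, function(v) {
        if (is.na(v)) "NA" else as.character(v)
      }, character(1))
      out
    } else as.character(x)
  }), stringsAsFactors = FALSE, check.names = FALSE)
}

.write_canonical_csv <- function(df, path) {
  cells <- .format_cells(df)
  needs_quote <- function(s) grepl('[",\n\r]', s)
  quote_cell <- function(s) {
    ifelse(needs_quote(s), paste0('"', gsub('"', '""', s), '"'), s)
  }
  lines <- c(paste(quote_cell(names(cells)), collapse = ","),
             apply(as.matrix(cells), 1L,
                   function(r) paste(quote_cell(r), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a survey from delimited text
#'
#' Reads the sites, occurrence, and taxon-group CSV files, validates them,
#' and returns aligned objects (occurrence rows reordered to the site-table
#' order). Reading a file produced by [write_survey()] and writing it again
#' reproduces the file byte for byte.
#'
#' @param site_path path to the sites CSV (must contain a `site_id` column).
#' @param occurrence_path path to the occurrence CSV (`site_id` plus one 0/1
#'   column per taxon).
#' @param taxa_path path to the taxon-group CSV (`taxon,group`).
#' @return list with elements `sites` (a [site_table()]) and `occ`
#'   (an [occurrence_matrix()]).
#' @export
read_survey <- function(site_path, occurrence_path, taxa_path) {
  for (p in c(site_path, occurrence_path, taxa_path))
    if (!file.exists(p)) stop("file not found: ", p)
  sites_df <- read.csv(site_path, stringsAsFactors = FALSE,
                       check.names = FALSE)
  if (!"site_id" %in% names(sites_df))
    stop("sites file lacks a 'site_id' column: ", site_path)
  sites <- site_table(sites_df)

  occ_df <- read.csv(occurrence_path, stringsAsFactors = FALSE,
                     check.names = FALSE, colClasses = "character")
  if (!"site_id" %in% names(occ_df))
    stop("occurrence file lacks a 'site_id' column: ", occurrence_path)
  taxa <- setdiff(names(occ_df), "site_id")
  vals <- as.matrix(occ_df[, taxa, drop = FALSE])
  bad <- which(!(vals %in% c("0", "1")))
  if (length(bad) > 0) {
    ij <- arrayInd(bad[1], dim(vals))
    stop(sprintf(
      "occurrence value '%s' (site '%s', taxon '%s') does not parse to 0/1",
      vals[bad[1]], occ_df$site_id[ij[1]], taxa[ij[2]]))
  }
  pres <- matrix(as.integer(vals), nrow = nrow(vals),
                 dimnames = list(occ_df$site_id, taxa))

  only_sites <- setdiff(sites$site_id, occ_df$site_id)
  only_occ <- setdiff(occ_df$site_id, sites$site_id)
  if (length(only_sites) > 0 || length(only_occ) > 0)
    stop("site(s) present in one file only: ",
         paste(c(only_sites, only_occ), collapse = ", "))
  pres <- pres[sites$site_id, , drop = FALSE]

  taxa_df <- read.csv(taxa_path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "group") %in% names(taxa_df)))
    stop("taxa file needs columns taxon,group: ", taxa_path)
  group_of <- setNames(taxa_df$group, taxa_df$taxon)

  list(sites = sites, occ = occurrence_matrix(pres, group_of))
}

#' Write a survey as delimited text
#'
#' Inverse of [read_survey()]; emits the canonical column order so that the
#' round trip is the identity.
#'
#' @param sites a [site_table()].
#' @param occ an [occurrence_matrix()] aligned with `sites`.
#' @param site_path,occurrence_path,taxa_path output paths.
#' @return invisibly, the three paths.
#' @export
write_survey <- function(sites, occ, site_path, occurrence_path, taxa_path) {
  stopifnot(inherits(sites, "site_table"), inherits(occ, "occurrence_matrix"))
  if (!identical(sites$site_id, occ$sites))
    stop("sites and occurrence matrix are not aligned")
  sdf <- as.data.frame(sites)[, .canonical_order(names(sites))]
  .write_canonical_csv(sdf, site_path)
  odf <- data.frame(site_id = occ$sites, occ$presence,
                    check.names = FALSE, stringsAsFactors = FALSE)
  .write_canonical_csv(odf, occurrence_path)
  tdf <- data.frame(taxon = occ$taxa, group = unname(occ$group_of[occ$taxa]),
                    stringsAsFactors = FALSE)
  .write_canonical_csv(tdf, taxa_path)
  invisible(c(site_path, occurrence_path, taxa_path))
}
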