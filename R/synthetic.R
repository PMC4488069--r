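# Synthetic survey generator.
#
# Emulates the statistical structure of a regional lake/pond macrophyte
# survey: a right-skewed occupancy-frequency distribution across taxa,
# spatially autocorrelated site covariates (exponential-covariance Gaussian
# process over great-circle distances), focal-group presences driven by a
# known logistic model on unit-scaled covariates (positive nutrient and
# conductivity effects, negative water-clarity effect), and all remaining
# taxa assigned to sites at random. Ground truth (coefficients and
# per-site probabilities) is returned for recovery tests.

#' Configuration for the synthetic survey generator
#'
#' Defaults emulate a 176-water-body, 124-taxon regional survey with a
#' 6-member free-floating functional group. Occupied-site counts follow a
#' log-normal distribution rounded to integers and truncated to
#' `[1, n_sites]`; the default location/scale give a mean occupancy of about
#' 19 of 176 sites. Continuous covariates are Gaussian-process fields with
#' correlation `exp(-d / rho_km)` over between-site distance `d`, mixed with
#' a fraction `noise_frac` of independent noise.
#'
#' @param n_sites number of water bodies.
#' @param n_taxa total number of taxa (group members included).
#' @param group_size number of focal-group member taxa.
#' @param occ_meanlog,occ_sdlog log-normal location and scale of
#'   occupied-site counts before rounding/truncation.
#' @param bbox survey bounding box,
#'   `c(lat_min, lat_max, lon_min, lon_max)` in decimal degrees.
#' @param rho_km spatial autocorrelation range of covariate fields (km);
#'   `0` gives spatially independent covariates.
#' @param noise_frac fraction of covariate variance that is independent
#'   site-level noise, in `[0, 1]`.
#' @param beta named logistic coefficients on unit-interval-rescaled
#'   covariates for group members; must contain `intercept`.
#' @param member_offsets per-member additive intercept offsets creating
#'   common and rare group members; length `group_size`.
#' @param boatlaunch_prob Bernoulli probability of a boat launch.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_sites = 176,
                         n_taxa = 124,
                         group_size = 6,
                         occ_meanlog = 2.415,
                         occ_sdlog = 1.1,
                         bbox = c(lat_min = 41.0, lat_max = 42.05,
                                  lon_min = -73.7, lon_max = -71.8),
                         rho_km = 30,
                         noise_frac = 0.3,
                         beta = c(intercept = -2.5, totalP = 4,
                                  cond = 4, secchi = -4),
                         member_offsets = c(0, -1, -1.6, -4, -4.5, -5),
                         boatlaunch_prob = 0.4) {
  stopifnot(n_sites >= 2, group_size >= 1, group_size <= n_taxa,
            rho_km >= 0, noise_frac >= 0, noise_frac <= 1,
            length(member_offsets) == group_size,
            "intercept" %in% names(beta))
  if (bbox["lat_max"] <= bbox["lat_min"] ||
      bbox["lon_max"] <= bbox["lon_min"])
    stop("degenerate bounding box")
  structure(list(n_sites = n_sites, n_taxa = n_taxa,
                 group_size = group_size,
                 occ_meanlog = occ_meanlog, occ_sdlog = occ_sdlog,
                 bbox = bbox, rho_km = rho_km, noise_frac = noise_frac,
                 beta = beta, member_offsets = member_offsets,
                 boatlaunch_prob = boatlaunch_prob),
            class = "synth_config")
}

# one or more standard-normal Gaussian-process draws with covariance
# exp(-d/rho) over the site distance matrix; rho = 0 -> iid
.gp_field <- function(dmat, rho_km, n_draws = 1) {
  n <- nrow(dmat)
  z <- matrix(rnorm(n * n_draws), n, n_draws)
  if (rho_km <= 0) return(z)
  sigma <- exp(-dmat / rho_km)
  diag(sigma) <- diag(sigma) + 1e-8
  t(chol(sigma)) %*% z
}

# spatially structured field mixed with independent noise, unit variance
.mixed_field <- function(spatial_z, noise_frac) {
  n <- nrow(spatial_z)
  sqrt(1 - noise_frac) * spatial_z +
    sqrt(noise_frac) * matrix(rnorm(length(spatial_z)), n, ncol(spatial_z))
}

#' Generate a synthetic site covariate table
#'
#' Coordinates are uniform in the bounding box. Each continuous covariate is
#' an exponential-covariance Gaussian-process field over between-site
#' great-circle distances, mixed with independent noise by `noise_frac`,
#' then shifted and scaled to a plausible range for its variable (floors keep
#' physical quantities positive). Alkalinity shares latent structure with
#' conductivity and pH, and maximum depth with surface area and Secchi
#' depth, so the collinearity screen has realistic targets. Neighbour counts
#' (`lakes1km`, `lakes10km`) are computed from the generated coordinates;
#' `boatlaunch` is Bernoulli.
#'
#' @param config a [synth_config()].
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return a [site_table()].
#' @export
generate_sites <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_sites
  b <- config$bbox
  lat <- runif(n, b["lat_min"], b["lat_max"])
  lon <- runif(n, b["lon_min"], b["lon_max"])
  ids <- sprintf("WB%03d", seq_len(n))
  base <- site_table(data.frame(site_id = ids, latitude = lat,
                                longitude = lon,
                                stringsAsFactors = FALSE))
  dmat <- .site_distance_matrix(base)

  # independent latent spatial fields, one per continuous covariate
  fields <- .gp_field(dmat, config$rho_km, n_draws = 8)
  colnames(fields) <- c("size", "shoreline", "totalP", "pH", "cond",
                        "secchi", "alk_own", "depth_own")
  z <- .mixed_field(fields, config$noise_frac)
  # alkalinity tracks conductivity and pH; depth tracks size and clarity
  z_alk <- 0.8 * z[, "cond"] + 0.4 * z[, "pH"] +
    sqrt(1 - 0.8^2 - 0.4^2) * z[, "alk_own"]
  z_depth <- 0.6 * z[, "size"] + 0.6 * z[, "secchi"] +
    sqrt(1 - 2 * 0.6^2) * z[, "depth_own"]
  z_nonFP <- .mixed_field(.gp_field(dmat, config$rho_km), config$noise_frac)

  affine <- function(zv, mu, sigma, lo = -Inf, hi = Inf)
    pmin(pmax(mu + sigma * zv, lo), hi)
  df <- data.frame(
    site_id = ids, latitude = lat, longitude = lon,
    size      = affine(z[, "size"], 25, 20, lo = 0.5),
    shoreline = affine(z[, "shoreline"], 1.6, 0.4, lo = 1),
    depth     = affine(z_depth, 5, 3, lo = 0.5),
    totalP    = affine(z[, "totalP"], 0.03, 0.02, lo = 0.001),
    pH        = affine(z[, "pH"], 6.8, 0.6, lo = 4, hi = 10),
    cond      = affine(z[, "cond"], 150, 80, lo = 5),
    alk       = affine(z_alk, 40, 25, lo = 1),
    secchi    = affine(z[, "secchi"], 3, 1.2, lo = 0.2),
    nonFP     = pmax(0, round(12 + 5 * z_nonFP[, 1])),
    lakes1km  = vapply(seq_len(n), function(i)
      sum(dmat[i, -i] <= 1), numeric(1)),
    lakes10km = vapply(seq_len(n), function(i)
      sum(dmat[i, -i] <= 10), numeric(1)),
    boatlaunch = rbinom(n, 1, config$boatlaunch_prob),
    stringsAsFactors = FALSE)
  site_table(df)
}

#' Sample right-skewed occupancy frequencies
#'
#' Draws occupied-site counts from a log-normal distribution, rounded to the
#' nearest integer and truncated (by rejection) to `[1, n_sites]`. With the
#' default parameters the distribution is strongly right skewed: most taxa
#' occupy few sites, a few occupy many.
#'
#' @param config a [synth_config()].
#' @param n number of counts to draw.
#' @param seed integer seed, or `NULL`.
#' @return integer vector of length `n` with values in `[1, n_sites]`.
#' @export
sample_occupancy_frequencies <- function(config, n, seed = NULL) {
  stopifnot(inherits(config, "synth_config"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- integer(0)
  while (length(out) < n) {
    k <- round(rlnorm(2 * (n - length(out)) + 10,
                      config$occ_meanlog, config$occ_sdlog))
    out <- c(out, k[k >= 1 & k <= config$n_sites])
  }
  as.integer(out[seq_len(n)])
}

#' Exact mean of the rounded, truncated occupancy distribution
#'
#' Analytic counterpart of [sample_occupancy_frequencies()]: the mean of the
#' integer distribution `P(k) proportional to
#' plnorm(k + 0.5) - plnorm(k - 0.5)` over `k = 1, ..., n_sites`.
#'
#' @param config a [synth_config()].
#' @return list with `mean` and `var` of the count distribution.
#' @export
occupancy_distribution_moments <- function(config) {
  k <- seq_len(config$n_sites)
  p <- plnorm(k + 0.5, config$occ_meanlog, config$occ_sdlog) -
    plnorm(k - 0.5, config$occ_meanlog, config$occ_sdlog)
  p <- p / sum(p)
  m <- sum(k * p)
  list(mean = m, var = sum((k - m)^2 * p))
}

#' Assemble a community by random placement at fixed occupancies
#'
#' Each taxon `i` with occupancy `k_i` is assigned to exactly `k_i` distinct
#' sites chosen uniformly at random without replacement, independently
#' across taxa — the random-assembly assumption of the species-pool null
#' model.
#'
#' @param frequencies integer occupancies, one per taxon, each in
#'   `[0, n_sites]`.
#' @param n_sites number of sites.
#' @param seed integer seed, or `NULL`.
#' @param site_ids,taxon_names optional dimension labels.
#' @return an [occurrence_matrix()] with all taxa labelled `"other"`.
#' @export
assemble_random_community <- function(frequencies, n_sites, seed = NULL,
                                      site_ids = NULL, taxon_names = NULL) {
  if (any(frequencies < 0 | frequencies > n_sites))
    stop("occupancy outside [0, n_sites]")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(site_ids)) site_ids <- sprintf("WB%03d", seq_len(n_sites))
  if (is.null(taxon_names))
    taxon_names <- sprintf("taxon_%03d", seq_along(frequencies))
  pres <- matrix(0L, n_sites, length(frequencies),
                 dimnames = list(site_ids, taxon_names))
  for (j in seq_along(frequencies)) {
    k <- frequencies[j]
    if (k > 0) pres[sample.int(n_sites, k), j] <- 1L
  }
  occurrence_matrix(pres, setNames(rep("other", length(taxon_names)),
                                   taxon_names))
}

#' Generate focal-group presences from a known logistic model
#'
#' Computes `p_i = plogis(b0 + sum_j beta_j * x_ij)` on covariates rescaled
#' to the unit interval, then draws `presence_i ~ Bernoulli(p_i)`. Both the
#' presences and the true probabilities are returned so parameter-recovery
#' tests can compare against ground truth.
#'
#' @param sites a [site_table()].
#' @param beta named coefficients including an `intercept` element; other
#'   names must be covariate columns of `sites`.
#' @param seed integer seed, or `NULL`.
#' @return list with `presence` (0/1 integer vector), `prob` (true
#'   probabilities), and `linear` (linear predictor).
#' @export
generate_group_presence <- function(sites, beta, seed = NULL) {
  stopifnot(inherits(sites, "site_table"), "intercept" %in% names(beta))
  if (!is.null(seed)) set.seed(seed)
  covars <- setdiff(names(beta), "intercept")
  unknown <- setdiff(covars, names(sites))
  if (length(unknown) > 0)
    stop("unknown covariate(s) in beta: ", paste(unknown, collapse = ", "))
  eta <- rep(beta[["intercept"]], nrow(sites))
  for (v in covars)
    eta <- eta + beta[[v]] * rescale_unit_interval(sites[[v]])
  p <- plogis(eta)
  list(presence = rbinom(length(p), 1, p), prob = p, linear = eta)
}

#' Simulate a complete survey with known ground truth
#'
#' Orchestrates the generator: sites with spatially autocorrelated
#' covariates; `group_size` focal-group member taxa whose presences follow
#' the configured logistic model (with per-member intercept offsets creating
#' common and rare members); remaining taxa placed at random with
#' log-normal occupancies; and the derived distance predictors (`distLM`,
#' `distSP`, `distW`: km to the nearest other water body occupied by each of
#' the three most common group members) appended to the site table. A single
#' root seed streams all randomness.
#'
#' @param config a [synth_config()].
#' @param seed integer root seed.
#' @return list with `sites` (a [site_table()] including derived
#'   predictors), `occ` (an [occurrence_matrix()] with group labels
#'   `"floating"`/`"other"`), and `truth` (list: `beta`, `member_offsets`,
#'   `prob` matrix of true per-member probabilities, `member_taxa`).
#' @export
simulate_survey <- function(config = synth_config(), seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  sites <- generate_sites(config, seed = NULL)
  S <- config$group_size

  # focal-group members: shared slopes, member-specific intercept offsets
  member_taxa <- sprintf("float_sp%d", seq_len(S))
  prob <- matrix(NA_real_, config$n_sites, S,
                 dimnames = list(sites$site_id, member_taxa))
  pres_grp <- matrix(0L, config$n_sites, S,
                     dimnames = list(sites$site_id, member_taxa))
  for (m in seq_len(S)) {
    bm <- config$beta
    bm[["intercept"]] <- bm[["intercept"]] + config$member_offsets[m]
    g <- generate_group_presence(sites, bm, seed = NULL)
    prob[, m] <- g$prob
    pres_grp[, m] <- g$presence
  }

  # background flora: random assembly at log-normal occupancies
  n_other <- config$n_taxa - S
  freqs <- sample_occupancy_frequencies(config, n_other, seed = NULL)
  other <- assemble_random_community(freqs, config$n_sites, seed = NULL,
                                     site_ids = sites$site_id)
  pres <- cbind(pres_grp, other$presence)
  group_of <- setNames(c(rep("floating", S), rep("other", n_other)),
                       colnames(pres))
  occ <- occurrence_matrix(pres, group_of)

  # derived distance predictors for the three most common group members
  common3 <- member_taxa[order(colSums(pres_grp), decreasing = TRUE)][1:3]
  dmat <- .site_distance_matrix(sites)
  dist_to <- function(taxon) {
    occupied <- which(occ$presence[, taxon] == 1)
    vapply(seq_len(nrow(sites)), function(i) {
      others <- setdiff(occupied, i)
      if (length(others) == 0) NA_real_ else min(dmat[i, others])
    }, numeric(1))
  }
  sites$distLM <- dist_to(common3[1])
  sites$distSP <- dist_to(common3[2])
  sites$distW  <- dist_to(common3[3])
  sites <- site_table(as.data.frame(sites))

  list(sites = sites, occ = occ,
       truth = list(beta = config$beta,
                    member_offsets = config$member_offsets,
                    prob = prob, member_taxa = member_taxa,
                    focal3 = common3, seed = seed))
}
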