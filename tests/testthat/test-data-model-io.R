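# Domain containers, delimited-text round trips, and derived predictors.

test_that("site_table validates ids, coordinates, and covariate ranges", {
  df <- data.frame(site_id = c("a", "b"), latitude = c(41, 42),
                   longitude = c(-72, -73))
  expect_s3_class(site_table(df), "site_table")
  expect_error(site_table(df[, c("site_id", "latitude")]), "longitude")
  expect_error(site_table(transform(df, site_id = c("a", "a"))),
               "duplicate site_id.*a")
  expect_error(site_table(transform(df, latitude = c(41, 95))), "latitude")
  expect_error(site_table(transform(df, boatlaunch = c(0, 2))), "boatlaunch")
  expect_error(site_table(transform(df, pH = c(7, 15))), "pH")
  expect_error(site_table(transform(df, lakes1km = c(1.5, 2))), "counts")
  expect_error(site_table(transform(df, secchi = c(-1, 2))), "secchi")
})

test_that("occurrence_matrix rejects non-binary cells and unlabeled taxa", {
  pres <- matrix(c(1, 0, 0, 1), 2, 2,
                 dimnames = list(c("a", "b"), c("t1", "t2")))
  occ <- occurrence_matrix(pres, c(t1 = "floating", t2 = "other"))
  expect_identical(unname(occupancy_frequencies(occ)), c(1L, 1L))
  pres_bad <- pres; pres_bad[2, 1] <- 2
  expect_error(occurrence_matrix(pres_bad, c(t1 = "x", t2 = "x")),
               "site 'b', taxon 't1'")
  expect_error(occurrence_matrix(pres, c(t1 = "floating")), "every taxon")
})

test_that("survey files round-trip bit-identically through read/write", {
  sim <- simulate_survey(synth_config(n_sites = 25, n_taxa = 12), seed = 11)
  d1 <- withr::local_tempdir()
  paths1 <- file.path(d1, c("sites.csv", "occ.csv", "taxa.csv"))
  write_survey(sim$sites, sim$occ, paths1[1], paths1[2], paths1[3])
  dat <- read_survey(paths1[1], paths1[2], paths1[3])
  expect_identical(dat$occ$presence, sim$occ$presence)
  paths2 <- file.path(d1, c("sites2.csv", "occ2.csv", "taxa2.csv"))
  write_survey(dat$sites, dat$occ, paths2[1], paths2[2], paths2[3])
  for (i in 1:3)
    expect_identical(readLines(paths2[i]), readLines(paths1[i]))
})

test_that("read_survey reports malformed files precisely", {
  d <- withr::local_tempdir()
  sim <- simulate_survey(synth_config(n_sites = 6, n_taxa = 10), seed = 2)
  paths <- file.path(d, c("sites.csv", "occ.csv", "taxa.csv"))
  write_survey(sim$sites, sim$occ, paths[1], paths[2], paths[3])

  # duplicated site_id, named in the error
  sites_lines <- readLines(paths[1])
  writeLines(c(sites_lines, sites_lines[2]), file.path(d, "dup.csv"))
  expect_error(read_survey(file.path(d, "dup.csv"), paths[2], paths[3]),
               "duplicate site_id.*WB001")

  # occurrence cell outside {0,1}, with site and taxon reported
  occ_lines <- readLines(paths[2])
  occ_lines[2] <- sub("^(WB001,)[01]", "\\12", occ_lines[2])
  writeLines(occ_lines, file.path(d, "occ_bad.csv"))
  expect_error(read_survey(paths[1], file.path(d, "occ_bad.csv"), paths[3]),
               "'2'.*WB001")

  # site present in one file only
  writeLines(sites_lines[-2], file.path(d, "short.csv"))
  expect_error(read_survey(file.path(d, "short.csv"), paths[2], paths[3]),
               "one file only.*WB001")
  expect_error(read_survey("nope.csv", paths[2], paths[3]), "not found")
})

test_that("shoreline development index: circle identity, closed forms, scaling", {
  # circle of radius 100 m: L = 2*pi*100, A = pi*100^2 m^2 = pi ha
  expect_equal(shoreline_development_index(2 * pi * 100, pi), 1)
  # square of side 200 m: L = 800 m, A = 4 ha -> 2/sqrt(pi)
  expect_equal(shoreline_development_index(800, 4), 2 / sqrt(pi))
  # scale invariance: L -> cL, A -> c^2 A
  for (c_ in c(0.5, 3, 10))
    expect_equal(shoreline_development_index(800 * c_, 4 * c_^2),
                 2 / sqrt(pi))
  expect_error(shoreline_development_index(0, 4), "positive")
  expect_error(shoreline_development_index(800, -1), "positive")
})

test_that("rescale_unit_interval is affine, idempotent, and rejects constants", {
  expect_equal(rescale_unit_interval(c(2, 4, 6)), c(0, 0.5, 1))
  v <- c(0, 0.25, 0.9, 1)
  expect_equal(rescale_unit_interval(v), v)
  r <- rescale_unit_interval(rnorm(50))
  expect_equal(rescale_unit_interval(r), r)
  expect_error(rescale_unit_interval(c(5, 5, 5)), "constant")
  expect_error(rescale_unit_interval(3), "two finite")
})

test_that("haversine distance: zero, one-degree closed form, symmetry", {
  expect_equal(haversine_km(c(41, -72.5), c(41, -72.5)), 0)
  # one degree of latitude on a 6371.0088 km sphere: pi/180 * R
  expect_equal(haversine_km(c(41, -72.5), c(42, -72.5)),
               pi / 180 * 6371.0088, tolerance = 1e-6)
  set.seed(4)
  for (i in 1:10) {
    a <- c(runif(1, -80, 80), runif(1, -170, 170))
    b <- c(runif(1, -80, 80), runif(1, -170, 170))
    expect_equal(haversine_km(a, b), haversine_km(b, a))
  }
  expect_error(haversine_km(c(91, 0), c(0, 0)), "latitude")
})

test_that("neighbour counts match a brute-force pairwise oracle", {
  one <- site_table(data.frame(site_id = "x", latitude = 41, longitude = -72))
  expect_identical(count_neighbors_within(one, "x", 100), 0L)
  sites <- make_sites(20, seed = 9)
  expect_identical(count_neighbors_within(sites, "S0001", 0), 0L)
  expect_error(count_neighbors_within(sites, "nope", 1), "unknown focal")

  # oracle: explicit double loop over pairs
  radius <- 5
  d <- outer(seq_len(20), seq_len(20), Vectorize(function(i, j)
    haversine_km(c(sites$latitude[i], sites$longitude[i]),
                 c(sites$latitude[j], sites$longitude[j]))))
  counts <- vapply(sites$site_id, function(id)
    count_neighbors_within(sites, id, radius), integer(1))
  brute <- vapply(seq_len(20), function(i)
    sum(d[i, -i] <= radius), numeric(1))
  expect_identical(unname(counts), as.integer(brute))
  # summed over all foci = twice the unordered pairs within radius
  expect_identical(sum(counts),
                   2L * sum(d[upper.tri(d)] <= radius))
})

test_that("distance to nearest occupied excludes self and flags isolates", {
  sites <- make_sites(5, seed = 3)
  occ <- make_occ(5, list(t1 = c(1, 3), t2 = 2), c("floating", "other"))
  # exactly one other occupied site: equals the direct distance call
  expect_equal(
    distance_to_nearest_occupied(sites, occ, "t1", "S0002"),
    min(haversine_km(c(sites$latitude[2], sites$longitude[2]),
                     c(sites$latitude[1], sites$longitude[1])),
        haversine_km(c(sites$latitude[2], sites$longitude[2]),
                     c(sites$latitude[3], sites$longitude[3]))))
  # focal itself occupied: self ignored, nearest other returned
  expect_equal(distance_to_nearest_occupied(sites, occ, "t1", "S0001"),
               haversine_km(c(sites$latitude[1], sites$longitude[1]),
                            c(sites$latitude[3], sites$longitude[3])))
  # taxon absent everywhere else: missing value, not zero
  expect_warning(
    d <- distance_to_nearest_occupied(sites, occ, "t2", "S0002"), "NA")
  expect_true(is.na(d))
  expect_error(distance_to_nearest_occupied(sites, occ, "zz", "S0001"),
               "unknown taxon")
})

test_that("collinearity screen flags duplicates, handles binaries and noise", {
  sites <- make_sites(40, seed = 5)
  df <- as.data.frame(sites)
  df$totalP2 <- df$totalP
  dup <- collinearity_screen(site_table(df), threshold = 0.7)
  expect_true(any(dup$var1 == "totalP" & dup$var2 == "totalP2" &
                    abs(dup$r - 1) < 1e-12))
  # flagged pairs sorted by |r| descending
  expect_true(all(diff(abs(dup$r)) <= 1e-12))

  # point-biserial equals Pearson on the 0/1 coding
  set.seed(6)
  df$flag <- rbinom(40, 1, 0.5)
  cm <- attr(collinearity_screen(site_table(df), 0.7), "correlations")
  expect_equal(cm["flag", "totalP"], cor(df$flag, df$totalP))

  # independent columns at n = 1000 stay unflagged at threshold 0.7
  set.seed(7)
  big <- site_table(data.frame(site_id = as.character(1:1000),
                               latitude = 41.5, longitude = -72.5,
                               a = rnorm(1000), b = rnorm(1000),
                               c = rnorm(1000)))
  out <- collinearity_screen(big, 0.7, variables = c("a", "b", "c"))
  expect_identical(nrow(out), 0L)
  expect_true(all(abs(attr(out, "correlations")[upper.tri(diag(3))]) < 0.2))

  # constant column excluded with a warning
  df$const <- 1
  expect_warning(collinearity_screen(site_table(df), 0.7), "constant")
})
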