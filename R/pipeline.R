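# Config-driven orchestration of the full analysis: load or simulate a
# survey, derive and rescale predictors, screen collinearity, run the
# all-subsets search and delta-AICc < 2 averaging per response, evaluate
# classifications at optimal thresholds, run the species-pool null model,
# and the environmental PCA. Every random stage draws a child seed derived
# from one root seed; outputs are CSV tables plus a JSON summary stamped
# with the seed and a config hash.

#' Assemble a pipeline configuration
#'
#' @param input `NULL` to simulate a survey, or a list with paths
#'   `sites`, `occurrence`, `taxa` for [read_survey()].
#' @param synthetic a [synth_config()] used when `input` is `NULL`.
#' @param group focal functional-group label.
#' @param responses `"auto"` (the group plus its three most common member
#'   taxa) or a list of [response_spec()].
#' @param predictors predictor columns for the occurrence models; `NULL`
#'   selects all standard covariate columns present in the site table
#'   (plus latitude/longitude), minus `exclude_predictors`.
#' @param exclude_predictors predictors dropped before modelling (the
#'   collinearity screen is advisory; exclusions are an explicit choice).
#'   Default drops alkalinity and maximum depth, which track conductivity/pH
#'   and Secchi depth/size.
#' @param response_dist named map from response name to its
#'   distance-to-nearest-occupied column, added to that response's
#'   predictor set only; `"auto"` matches taxon responses to
#'   `distLM`/`distSP`/`distW` in occupancy order.
#' @param delta_max AICc band for the candidate set.
#' @param threshold_step grid step for [optimal_threshold()].
#' @param collinearity_threshold flag level for [collinearity_screen()].
#' @param null_pool_sizes,null_B species-pool sizes and iteration count for
#'   the permutation null model.
#' @param averaging headline averaging variant (`"full"` or
#'   `"conditional"`).
#' @param pseudo_r2_variant `"coxsnell"` or `"nagelkerke"` headline.
#' @param cooks_threshold flag level for Cook's distance on the best model.
#' @param max_predictors guard forwarded to [all_subsets()].
#' @param pca_variables variables for [pca_correlation()]; `NULL` selects
#'   the standard local-condition set present in the data.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL,
                            synthetic = synth_config(),
                            group = "floating",
                            responses = "auto",
                            predictors = NULL,
                            exclude_predictors = c("alk", "depth"),
                            response_dist = "auto",
                            delta_max = 2,
                            threshold_step = 0.005,
                            collinearity_threshold = 0.7,
                            null_pool_sizes = c(1, 6, 12, 24),
                            null_B = 2000,
                            averaging = "full",
                            pseudo_r2_variant = "coxsnell",
                            cooks_threshold = 0.9,
                            max_predictors = 20,
                            pca_variables = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected. The `synthetic` section is forwarded to
#' [synth_config()]; `responses` entries are forwarded to
#' [response_spec()].
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$synthetic))
    raw$synthetic <- do.call(synth_config, raw$synthetic)
  if (is.list(raw$responses))
    raw$responses <- lapply(raw$responses, function(r)
      do.call(response_spec, r))
  do.call(pipeline_config, raw)
}

# deterministic 31-bit polynomial hash of the deparsed config, for provenance
.config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# child seeds derived from one root seed, kept under 2^31
.child_seed <- function(seed, stage) {
  (seed * 7 + match(stage, c("simulate", "null", "fit")) * 104729) %%
    2147483647
}

.pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes: load or simulate -> predictor rescaling and missing-value
#' handling -> collinearity report -> per response: all-subsets search,
#' delta-AICc < 2 averaging, averaged predictions, optimal-threshold
#' evaluation, pseudo-R-squared, Cook's-distance report -> species-pool
#' null model -> environmental PCA. Writes CSV tables and a JSON summary
#' under `out_dir` and returns the results invisibly.
#'
#' @param config a [pipeline_config()].
#' @param seed root integer seed; child seeds for the simulation, the
#'   model fitting, and the null model are derived from it.
#' @param out_dir output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @return (invisibly) list with `sites`, `occ`, `screen`, `fits` (per
#'   response: candidate table, averaged model, evaluation, pseudo-R2,
#'   Cook's flags), `null`, `pca`, `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  # --- data -----------------------------------------------------------
  truth <- NULL
  if (is.null(config$input)) {
    sim <- .pipeline_stage("simulate",
      simulate_survey(config$synthetic, seed = .child_seed(seed, "simulate")))
    sites <- sim$sites; occ <- sim$occ; truth <- sim$truth
  } else {
    dat <- .pipeline_stage("load",
      read_survey(config$input$sites, config$input$occurrence,
                  config$input$taxa))
    sites <- dat$sites; occ <- dat$occ
  }

  # --- responses and predictors --------------------------------------
  members <- occ$taxa[occ$group_of == config$group]
  responses <- config$responses
  if (identical(responses, "auto")) {
    common <- members[order(colSums(occ$presence[, members, drop = FALSE]),
                            decreasing = TRUE)]
    common <- utils::head(common, 3)
    responses <- c(list(response_spec(config$group, group = config$group)),
                   lapply(common, function(tx) response_spec(tx, taxon = tx)))
  }
  dist_cols <- c("distLM", "distSP", "distW")
  predictors <- config$predictors
  if (is.null(predictors)) {
    std <- setdiff(.canonical_site_columns, c("site_id", dist_cols))
    predictors <- intersect(std, names(sites))
  }
  predictors <- setdiff(predictors, config$exclude_predictors)
  response_dist <- config$response_dist
  if (identical(response_dist, "auto")) {
    taxon_resps <- Filter(function(r) !is.null(r$taxon), responses)
    taxon_names <- vapply(taxon_resps, function(r) r$name, character(1))
    response_dist <- setNames(
      intersect(dist_cols, names(sites))[seq_along(taxon_names)],
      taxon_names)
  }

  # --- rescale, screen ------------------------------------------------
  screen <- .pipeline_stage("screen",
    collinearity_screen(sites, config$collinearity_threshold,
                        variables = c(predictors,
                                      intersect(dist_cols, names(sites)))))
  all_pred_cols <- unique(c(predictors,
                            unlist(response_dist, use.names = FALSE)))
  prep <- .pipeline_stage("predictors", {
    unknown <- setdiff(all_pred_cols, names(sites))
    if (length(unknown) > 0)
      stop("unknown predictor column(s): ", paste(unknown, collapse = ", "))
    ok <- complete.cases(as.data.frame(sites)[, all_pred_cols,
                                              drop = FALSE])
    if (sum(!ok) > 0)
      message(sum(!ok), " site(s) dropped for missing predictor values")
    list(complete = ok,
         X = as.data.frame(lapply(
           as.data.frame(sites)[ok, all_pred_cols, drop = FALSE],
           rescale_unit_interval)))
  })
  complete <- prep$complete
  X_all <- prep$X
  n_dropped <- sum(!complete)

  # --- per-response modelling ----------------------------------------
  set.seed(.child_seed(seed, "fit"))
  fit_one <- function(resp) {
    y <- response_vector(resp, occ)[complete]
    cols <- predictors
    if (resp$name %in% names(response_dist))
      cols <- c(cols, response_dist[[resp$name]])
    X <- X_all[, cols, drop = FALSE]
    models <- all_subsets(X, y, max_predictors = config$max_predictors)
    cand <- candidate_set(models, config$delta_max)
    avg <- model_average(cand, headline = config$averaging)
    prob <- predict_average(avg, X)
    eval <- evaluate_predictions(y, prob, step = config$threshold_step)
    best_fit <- cand$fits[[1]]
    null_fit <- fit_logistic(X[, 0, drop = FALSE], y)
    r2 <- pseudo_r2(best_fit, null_fit, variant = "both")
    cooks <- cooks_distance_fit(best_fit, config$cooks_threshold)
    list(response = resp$name, y = y, models = models, candidates = cand,
         averaged = avg, prob = prob, evaluation = eval, pseudo_r2 = r2,
         cooks_flagged = cooks$flagged)
  }
  fits <- lapply(responses, function(r)
    .pipeline_stage(paste0("fit:", r$name), fit_one(r)))
  names(fits) <- vapply(responses, function(r) r$name, character(1))

  # --- null model and PCA --------------------------------------------
  null <- .pipeline_stage("nullmodel", {
    pool <- occupancy_frequencies(occ)
    obs <- observed_empty_proportion(occ, config$group)
    null_model_curve(pool, length(occ$sites),
                     pool_sizes = config$null_pool_sizes,
                     B = config$null_B, seed = .child_seed(seed, "null"),
                     observed = obs)
  })
  pca_vars <- config$pca_variables
  if (is.null(pca_vars))
    pca_vars <- intersect(c("size", "shoreline", "depth", "nonFP",
                            "totalP", "pH", "cond", "alk", "secchi"),
                          names(sites))
  pca <- .pipeline_stage("pca", pca_correlation(sites, pca_vars))

  # --- summary and outputs -------------------------------------------
  summary <- list(
    seed = seed, config_hash = .config_hash(config),
    n_sites = length(occ$sites), n_taxa = length(occ$taxa),
    n_sites_modelled = sum(complete), n_sites_dropped = n_dropped,
    group = config$group,
    observed_empty_proportion = observed_empty_proportion(occ, config$group),
    responses = lapply(fits, function(f) list(
      n_candidate_models = nrow(f$candidates$table),
      threshold = f$evaluation$threshold,
      pcc = percent_correct(f$evaluation),
      kappa = f$evaluation$kappa,
      pseudo_r2 = f$pseudo_r2,
      significant_terms = f$averaged$terms$term[f$averaged$terms$significant],
      cooks_flagged = f$cooks_flagged)),
    null = lapply(null, function(r)
      list(S = r$S, mean = r$mean, lo = r$ci[["lo"]], hi = r$ci[["hi"]],
           p = r$p_value)),
    pca_proportion = pca$proportion)

  result <- list(sites = sites, occ = occ, truth = truth, screen = screen,
                 fits = fits, null = null, pca = pca, summary = summary)
  if (!is.null(out_dir)) .write_pipeline_outputs(result, config, out_dir)
  invisible(result)
}

# CSV + JSON artifacts; every table carries the seed/config hash via
# summary.json next to it
.write_pipeline_outputs <- function(result, config, out_dir) {
  p <- function(...) file.path(out_dir, ...)
  s <- result$screen
  .write_canonical_csv(
    if (nrow(s) > 0) s else
      data.frame(var1 = character(0), var2 = character(0), r = numeric(0)),
    p("collinearity.csv"))
  for (nm in names(result$fits)) {
    f <- result$fits[[nm]]
    .write_canonical_csv(f$candidates$table[, c("model", "terms", "k",
                                                "loglik", "aicc", "delta",
                                                "weight")],
                         p(sprintf("models_%s.csv", nm)))
    .write_canonical_csv(f$averaged$terms, p(sprintf("averaged_%s.csv", nm)))
  }
  eval_tab <- do.call(rbind, lapply(result$fits, function(f) {
    e <- f$evaluation
    data.frame(response = f$response, threshold = e$threshold,
               tn = e$tn, fn = e$fn, fp = e$fp, tp = e$tp,
               sensitivity = e$sensitivity, specificity = e$specificity,
               pcc = percent_correct(e), kappa = e$kappa,
               kappa_se = e$kappa_se,
               pseudo_r2_coxsnell = f$pseudo_r2$coxsnell,
               pseudo_r2_nagelkerke = f$pseudo_r2$nagelkerke,
               stringsAsFactors = FALSE)
  }))
  .write_canonical_csv(eval_tab, p("evaluation.csv"))
  .write_canonical_csv(attr(result$null, "summary"), p("nullmodel.csv"))
  samp <- do.call(rbind, lapply(result$null, function(r)
    data.frame(S = r$S, iteration = seq_along(r$samples),
               empty_proportion = r$samples)))
  .write_canonical_csv(samp, p("nullmodel_samples.csv"))
  load_tab <- data.frame(variable = rownames(result$pca$loadings),
                         result$pca$loadings, check.names = FALSE)
  .write_canonical_csv(load_tab, p("pca_loadings.csv"))
  .write_canonical_csv(
    data.frame(site_id = rownames(result$pca$scores), result$pca$scores,
               check.names = FALSE),
    p("pca_scores.csv"))
  jsonlite::write_json(result$summary, p("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
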