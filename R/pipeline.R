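#' Pipeline configuration
#'
#' Assembles and validates the settings for [run_pipeline()]: the input data,
#' column roles, kernel settings per stage, forest hyperparameters,
#' evaluation settings, output directory and master seed. Every stochastic
#' stage derives its stream from the single `seed`.
#'
#' @param input Path to a CSV/GeoJSON areal table, or a data frame.
#' @param outcome Outcome column name.
#' @param predictors Predictor column names (`NULL` = all other numerics).
#' @param id,coords Id and coordinate column names.
#' @param out_dir Output directory (created if missing).
#' @param seed Master integer seed.
#' @param gistar_k Gi* neighborhood size (k-NN; default 8).
#' @param lmi_k LMI neighborhood size (default 8).
#' @param lmi_n_perm LMI conditional permutations (default 999).
#' @param lmi_alpha LMI significance level (default 0.05).
#' @param gwcor_k GW correlation adaptive bandwidth (neighbor count).
#' @param gwols_bandwidth GW-OLS adaptive bandwidth; `NULL` selects by AICc.
#' @param rf_grid Data frame of RGS candidates (`NULL` = small default grid).
#' @param rgs_k_folds,rgs_tolerance,rgs_rounds Random-grid-search settings.
#' @param gwrf_k GW-RF calibration-set size (`NULL` = `max(30, n/5)` capped
#'   at n).
#' @param n_test Held-out test size for the model comparison
#'   (default `round(n / 5)`).
#' @param lonlat Declare the coordinates as longitude/latitude; they are
#'   then projected to planar km by an equirectangular projection about the
#'   data centroid, with a warning.
#' @param continue_on_error Downgrade stage failures to warnings.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, outcome, predictors = NULL, id = "id",
                            coords = c("x", "y"), out_dir = "gwareal_out",
                            seed = 1, gistar_k = 8, lmi_k = 8,
                            lmi_n_perm = 999, lmi_alpha = 0.05,
                            gwcor_k = 30, gwols_bandwidth = NULL,
                            rf_grid = NULL, rgs_k_folds = 5,
                            rgs_tolerance = 0.001, rgs_rounds = 2,
                            gwrf_k = NULL, n_test = NULL, lonlat = FALSE,
                            continue_on_error = FALSE) {
  structure(list(input = input, outcome = outcome, predictors = predictors,
                 id = id, coords = coords, out_dir = out_dir, seed = seed,
                 gistar_k = gistar_k, lmi_k = lmi_k,
                 lmi_n_perm = lmi_n_perm, lmi_alpha = lmi_alpha,
                 gwcor_k = gwcor_k, gwols_bandwidth = gwols_bandwidth,
                 rf_grid = rf_grid, rgs_k_folds = rgs_k_folds,
                 rgs_tolerance = rgs_tolerance, rgs_rounds = rgs_rounds,
                 gwrf_k = gwrf_k, n_test = n_test, lonlat = lonlat,
                 continue_on_error = continue_on_error),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$rf_grid)) vals$rf_grid <- dplyr::bind_rows(vals$rf_grid)
  if (!is.null(vals$coords)) vals$coords <- unlist(vals$coords)
  if (!is.null(vals$predictors)) vals$predictors <- unlist(vals$predictors)
  do.call(pipeline_config, vals)
}

log_stage <- function(stage, expr, continue_on_error = FALSE) {
  t0 <- Sys.time()
  inform(paste0("[gwareal] stage: ", stage))
  res <- tryCatch(expr, error = function(e) {
    msg <- paste0("Stage '", stage, "' failed: ", conditionMessage(e))
    if (continue_on_error) {
      warn(msg)
      return(structure(list(message = msg), class = "gw_stage_failure"))
    }
    gw_abort(msg, "gwareal_error_stage")
  })
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  list(result = res, seconds = elapsed)
}

# Equirectangular projection about the data centroid (planar units: km),
# applied when the user declares the coordinates are longitude/latitude.
# All analyses require planar coordinates; proper projection upstream is
# preferred and this fallback warns accordingly.
project_lonlat <- function(frame) {
  warn(paste0("Coordinates declared as longitude/latitude: applying an ",
              "equirectangular projection about the data centroid ",
              "(approximate; project upstream for production use)."))
  roles <- gw_roles(frame)
  coords <- area_coords(frame)
  r_earth <- 6371
  lat0 <- mean(coords[, 2]) * pi / 180
  frame[[roles$coords[1]]] <- r_earth * coords[, 1] * pi / 180 * cos(lat0)
  frame[[roles$coords[2]]] <- r_earth * coords[, 2] * pi / 180
  frame
}

#' Run the full geographically weighted analysis pipeline
#'
#' Executes the package's analysis sequence on one areal table — hotspots
#' (Gi* on the outcome), bivariate local Moran's I of the outcome against
#' each predictor, GW correlation of the outcome against each predictor,
#' GW-OLS (with AICc bandwidth selection unless fixed), global RF with
#' random grid search, GW-RF, and the four-model comparison — writing each
#' stage's tables as CSV/JSON under `config$out_dir` together with a run
#' manifest (config, config hash, seed, package version, stage timings).
#' All numeric CSV output is written at 10 significant digits, so reruns
#' with an identical config are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  if (is.null(seed)) abort_config("A seed is mandatory.")
  frame <- if (is.data.frame(config$input)) {
    as_area_frame(config$input, outcome = config$outcome,
                  predictors = config$predictors, id = config$id,
                  coords = config$coords)
  } else {
    read_area_table(config$input, outcome = config$outcome,
                    predictors = config$predictors, id = config$id,
                    coords = config$coords)
  }
  if (isTRUE(config$lonlat)) frame <- project_lonlat(frame)
  preds <- predictor_names(frame)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  coe <- config$continue_on_error
  timings <- list()
  results <- list()
  n <- nrow(frame)

  st <- log_stage("hotspots", {
    hs <- getis_ord_gi_star(frame, k = config$gistar_k)
    write_result_csv(hs, file.path(out_dir, "hotspots.csv"))
    hs
  }, coe)
  timings$hotspots <- st$seconds; results$hotspots <- st$result

  st <- log_stage("bivariate_lmi", {
    W <- build_weight_matrix(frame, "knn_binary", k = config$lmi_k,
                             row_standardize = TRUE)
    lmi <- purrr::map_dfr(preds, function(pn) {
      dplyr::mutate(
        bivariate_local_moran(frame, outcome_name(frame), pn, W = W,
                              n_perm = config$lmi_n_perm,
                              alpha = config$lmi_alpha,
                              seed = hash_seed(seed, 21)),
        predictor = pn)
    })
    write_result_csv(lmi, file.path(out_dir, "bivariate_lmi.csv"))
    lmi
  }, coe)
  timings$bivariate_lmi <- st$seconds; results$lmi <- st$result

  st <- log_stage("gw_correlation", {
    kern <- kernel_spec("bisquare", adaptive = TRUE,
                        bandwidth = min(config$gwcor_k, n))
    gwc <- purrr::map_dfr(preds, function(pn) {
      dplyr::mutate(gw_correlation(frame, pn, outcome_name(frame), kern),
                    predictor = pn)
    })
    write_result_csv(gwc, file.path(out_dir, "gw_correlation.csv"))
    gwc
  }, coe)
  timings$gw_correlation <- st$seconds; results$gw_correlation <- st$result

  st <- log_stage("gw_ols", {
    kern <- kernel_spec("bisquare", adaptive = TRUE,
                        bandwidth = config$gwols_bandwidth)
    fit <- fit_gwols(frame, kern)
    write_result_csv(fit$local, file.path(out_dir, "gwols_local.csv"))
    vifs <- if (length(preds) >= 2) local_vif(frame, fit$kernel) else NULL
    if (!is.null(vifs)) {
      write_result_csv(vifs, file.path(out_dir, "gwols_vif.csv"))
    }
    jsonlite::write_json(
      c(as.list(glance(fit)),
        list(selected_bandwidth = fit$kernel$bandwidth)),
      file.path(out_dir, "gwols_summary.json"),
      auto_unbox = TRUE, digits = NA)
    fit
  }, coe)
  timings$gw_ols <- st$seconds; results$gwols <- st$result

  st <- log_stage("global_rf", {
    grid <- config$rf_grid %||%
      expand.grid(ntree = c(200, 500), mtry = unique(pmin(c(2, 3), length(preds))))
    rgs <- random_grid_search(frame, grid, k_folds = config$rgs_k_folds,
                              stopping_tolerance = config$rgs_tolerance,
                              stopping_rounds = config$rgs_rounds,
                              seed = hash_seed(seed, 31))
    params <- rgs$best
    params$seed <- hash_seed(seed, 32)
    fit <- fit_global_rf(frame, params)
    write_result_csv(fit$importance,
                     file.path(out_dir, "global_rf_importance.csv"))
    write_result_csv(rgs$trace, file.path(out_dir, "rgs_trace.csv"))
    list(fit = fit, rgs = rgs)
  }, coe)
  timings$global_rf <- st$seconds; results$global_rf <- st$result

  st <- log_stage("gw_rf", {
    params <- if (!inherits(results$global_rf, "gw_stage_failure")) {
      results$global_rf$rgs$best
    } else rf_params()
    k <- config$gwrf_k %||% min(n, max(30, round(n / 5)))
    fit <- fit_gwrf(frame, k_neighbors = k, params = params,
                    seed = hash_seed(seed, 41), keep_forests = FALSE)
    write_result_csv(fit$local, file.path(out_dir, "gwrf_local.csv"))
    write_result_csv(local_importance_ranking(fit),
                     file.path(out_dir, "gwrf_rank_summary.csv"))
    write_result_csv(gwrf_summary(fit),
                     file.path(out_dir, "gwrf_summary.csv"))
    fit
  }, coe)
  timings$gw_rf <- st$seconds; results$gwrf <- st$result

  st <- log_stage("evaluation", {
    n_test <- config$n_test %||% round(n / 5)
    split <- train_test_split(frame, n_test, seed = hash_seed(seed, 51))
    control <- list(
      rf_params = if (!inherits(results$global_rf, "gw_stage_failure")) {
        results$global_rf$rgs$best
      } else rf_params(),
      gwols_kernel = if (!inherits(results$gwols, "gw_stage_failure")) {
        results$gwols$kernel
      } else NULL,
      gwrf_k = min(nrow(split$train),
                   config$gwrf_k %||% max(30, round(n / 5))))
    report <- compare_models(frame, split = split, control = control,
                             seed = hash_seed(seed, 52))
    write_result_csv(report$scores, file.path(out_dir, "evaluation_scores.csv"))
    write_result_csv(report$predictions,
                     file.path(out_dir, "evaluation_predictions.csv"))
    jsonlite::write_json(report$scores, file.path(out_dir, "evaluation_scores.json"),
                         dataframe = "rows", digits = NA)
    report
  }, coe)
  timings$evaluation <- st$seconds; results$evaluation <- st$result

  cfg_for_hash <- config
  cfg_for_hash$input <- if (is.data.frame(config$input)) "inline" else config$input
  manifest <- list(
    package = "gwareal",
    version = as.character(utils::packageVersion("gwareal")),
    seed = seed,
    config = cfg_for_hash[setdiff(names(cfg_for_hash), "rf_grid")],
    config_hash = rlang::hash(cfg_for_hash),
    n_units = n,
    timings_seconds = timings,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(results = results, manifest = manifest, out_dir = out_dir))
}
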