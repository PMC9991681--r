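#' Pipeline configuration
#'
#' One configuration object for the end-to-end analysis: synthetic-city
#' generation (or CSV inputs), store scoring, exposure derivation, multiple
#' imputation, association models, and the spatial risk surface. All module
#' seeds are derived deterministically from the single global seed, so one
#' integer reproduces the whole run.
#'
#' @param city a [city_config()], or `NULL` to read `patients`, `stores`,
#'   `tracts` CSV paths from `inputs`.
#' @param inputs optional named list of CSV paths (`patients`, `stores`,
#'   `tracts`) when `city` is `NULL`.
#' @param radii exposure radii in miles.
#' @param horizon AUC horizon in miles.
#' @param mechanism missingness mechanism applied to the generated cohort.
#' @param imputation list of [impute_covariates()] settings (`m`, `maxit`,
#'   `base_learner`, `ntree`).
#' @param vehicle_threshold fixed stratum threshold in percent, or `NULL` for
#'   the tract third quartile.
#' @param spatial list of [risk_config()] settings (grid, permutations,
#'   alpha).
#' @param out_dir output directory for the report bundle.
#' @param seed global integer seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(city = city_config(), inputs = NULL,
                            radii = c(0.5, 1, 2), horizon = 10,
                            mechanism = "MCAR",
                            imputation = list(m = 5L, maxit = 10L,
                                              base_learner = "random_forest",
                                              ntree = 100L),
                            vehicle_threshold = NULL,
                            spatial = list(grid_nx = 64L, grid_ny = 64L,
                                           n_permutations = 199L, alpha = 0.05),
                            out_dir = "results/pipeline", seed = 1L) {
  if (is.null(city) && (is.null(inputs) ||
                        !all(c("patients", "stores", "tracts") %in% names(inputs)))) {
    stop("either a city config or patients/stores/tracts input paths are required",
         call. = FALSE)
  }
  structure(list(city = city, inputs = inputs, radii = radii, horizon = horizon,
                 mechanism = mechanism, imputation = imputation,
                 vehicle_threshold = vehicle_threshold, spatial = spatial,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Named deterministic substream seeds below 2^31.
.derive_seeds <- function(seed, names) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max, length(names)), names)
}

.config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(lapply(rapply(unclass(config), unname, how = "replace"),
                          identity), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Stages run in order: generate (or load) the city, score stores, derive
#' exposures, inject missingness and impute, fit the association models
#' (descriptives, store-tract correlations, pooled exposure models with
#' effect modification), and map the spatial relative risk with significance
#' contours. Every stage writes its artifacts under `out_dir`, and a manifest
#' records the seed and a hash of the configuration. Reruns with the same
#' config are identical.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages?
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- .derive_seeds(config$seed,
                         c("city", "missingness", "imputation", "spatial"))

  # -- stage: generate or load ----------------------------------------------
  if (!is.null(config$city)) {
    cc <- config$city
    cc$seed <- unname(seeds["city"])
    city <- generate_city(cc)
    say("generated city: %d patients, %d stores, %d tracts",
        nrow(city$patients), nrow(city$stores), nrow(city$tracts))
  } else {
    city <- structure(list(
      patients = .read_checked(config$inputs$patients,
                               c("id", "x", "y", "food_insecure", "tract_id")),
      stores = .read_checked(config$inputs$stores, c("id", "x", "y")),
      tracts = .read_checked(config$inputs$tracts,
                             c("tract_id", "pct_no_vehicle")),
      config = NULL), class = "food_city")
    say("loaded city from CSV inputs")
  }
  write_city_ok <- !is.null(city$config)
  if (write_city_ok) write_city(city, config$out_dir)

  # -- stage: score ----------------------------------------------------------
  stores <- if (all(c("availability", "price", "quality", "total") %in%
                    names(city$stores))) {
    city$stores
  } else {
    score_stores(city$stores)
  }
  utils::write.csv(stores, file.path(config$out_dir, "stores_scored.csv"),
                   row.names = FALSE)

  # -- stage: expose ---------------------------------------------------------
  exposures <- compute_exposures(city$patients, stores, config$radii,
                                 config$horizon)
  utils::write.csv(exposures, file.path(config$out_dir, "exposures.csv"),
                   row.names = FALSE)
  say("exposures computed for %d patients over radii {%s}",
      nrow(exposures), paste(config$radii, collapse = ", "))

  # -- stage: impute ---------------------------------------------------------
  strata <- vehicle_strata(city$tracts, config$vehicle_threshold)
  observed <- if (!is.null(city$config) && length(city$config$missing_rates)) {
    inject_missingness(city$patients, city$config$missing_rates,
                       config$mechanism, seed = unname(seeds["missingness"]))
  } else {
    city$patients
  }
  utils::write.csv(observed, file.path(config$out_dir, "patients_observed.csv"),
                   row.names = FALSE)
  model_tab <- attach_tract_covariates(observed, city$tracts, strata)
  pres <- exposures[, grep("^present_", names(exposures)), drop = FALSE]
  imp_in <- cbind(model_tab[, setdiff(names(model_tab),
                                      c("id", "x", "y", "tract_id"))], pres)
  stack <- impute_covariates(imp_in, m = config$imputation$m,
                             maxit = config$imputation$maxit,
                             base_learner = config$imputation$base_learner,
                             ntree = config$imputation$ntree,
                             seed = unname(seeds["imputation"]))
  write_imputed_stack(stack, file.path(config$out_dir, "imputations"))
  say("imputed %d cells over %d variables (m = %d)",
      sum(stack$missing_pattern), sum(stack$missing_pattern > 0), stack$m)

  # -- stage: associate ------------------------------------------------------
  table1 <- compare_groups(model_tab, "food_insecure",
                           continuous = c("age", "bmi", "median_income",
                                          "pct_below_poverty", "unemployment_rate",
                                          "uninsured_rate", "pct_no_vehicle",
                                          "pct_public_assistance"),
                           categorical = c("sex", "race", "marital_status"))
  utils::write.csv(table1, file.path(config$out_dir, "table1_descriptives.csv"),
                   row.names = FALSE)
  store_tracts <- merge(stores[, c("id", "total", "tract_id")], city$tracts,
                        by = "tract_id", sort = FALSE)
  correlations <- correlate_stores(
    store_tracts$total,
    store_tracts[, c("median_income", "pct_below_poverty", "unemployment_rate",
                     "uninsured_rate", "pct_no_vehicle", "pct_public_assistance")])
  utils::write.csv(correlations, file.path(config$out_dir, "store_correlations.csv"),
                   row.names = FALSE)
  models <- .association_suite(stack, exposures, strata, config$radii)
  utils::write.csv(models, file.path(config$out_dir, "models.csv"),
                   row.names = FALSE)
  jsonlite::write_json(models, file.path(config$out_dir, "models.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", dataframe = "rows")
  say("fitted %d pooled association models", nrow(models))

  # -- stage: map ------------------------------------------------------------
  sp <- config$spatial
  rc <- risk_config(bounds = .city_bounds(city),
                    grid_nx = sp$grid_nx, grid_ny = sp$grid_ny,
                    n_permutations = sp$n_permutations, alpha = sp$alpha,
                    seed = unname(seeds["spatial"]))
  cases <- city$patients[city$patients$food_insecure == 1, ]
  controls <- city$patients[city$patients$food_insecure == 0, ]
  surface <- log_relative_risk(cases, controls, rc)
  contours <- tolerance_contours(surface)
  write_risk_surface(surface, file.path(config$out_dir, "risk_surface.csv"),
                     contours)
  contours_to_geojson(contours, file.path(config$out_dir, "risk_contours.geojson"))
  plot_risk_surface(surface, contours, file.path(config$out_dir, "risk_surface.png"))
  say("risk surface mapped: %d significant cells, %d contour lines",
      sum(contours$significant), length(contours$contours))

  manifest <- list(seed = config$seed, substream_seeds = as.list(seeds),
                   config_hash = .config_hash(config),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   stages = c("generate", "score", "expose", "impute",
                              "associate", "map"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(city = city, stores = stores, exposures = exposures,
                 stack = stack, table1 = table1, correlations = correlations,
                 models = models, surface = surface, contours = contours,
                 strata = strata, manifest = manifest))
}

.city_bounds <- function(city) {
  if (!is.null(city$config)) return(city$config$bounds)
  with(city$patients,
       c(xmin = min(x), ymin = min(y), xmax = max(x), ymax = max(y)))
}

.read_checked <- function(path, required) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing required columns %s (line 1)", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df
}

# Fit the full model grid: continuous outcomes (max/mean of total,
# availability, price per radius; AUC) with linear models, presence
# indicators (0.5 and 1 mile) with logistic models; each unadjusted,
# adjusted, and with vehicle effect modification.
.association_suite <- function(stack, exposures, strata, radii) {
  rows <- list()
  add <- function(fit, stratum = "all", interaction_p = NA_real_) {
    rows[[length(rows) + 1]] <<- data.frame(
      outcome = fit$outcome, family = fit$family,
      adjusted = fit$adjusted, stratum = stratum,
      estimate = fit$estimate, ci_low = fit$ci[1], ci_high = fit$ci[2],
      p_value = fit$p_value, interaction_p = interaction_p,
      n = fit$n, excluded_n = fit$excluded_n)
  }
  cont <- unlist(lapply(radii, function(r) {
    lab <- .radius_label(r)
    paste0(c("max_nems_", "mean_nems_", "max_avail_", "mean_avail_",
             "max_price_", "mean_price_"), lab)
  }))
  cont <- c(cont, "auc")
  for (oc in cont) {
    add(fit_exposure_model(stack, oc, "linear", exposures, adjusted = FALSE))
    add(fit_exposure_model(stack, oc, "linear", exposures, adjusted = TRUE))
    em <- effect_modification(stack, oc, "linear", exposures,
                              threshold = strata$threshold)
    add(em$high, "vehicle_high", em$interaction$p_value)
    add(em$low, "vehicle_low", em$interaction$p_value)
  }
  for (r in setdiff(radii, 2)) {
    oc <- paste0("present_", .radius_label(r))
    add(fit_exposure_model(stack, oc, "logistic", exposures, adjusted = FALSE))
    add(fit_exposure_model(stack, oc, "logistic", exposures, adjusted = TRUE))
    em <- effect_modification(stack, oc, "logistic", exposures,
                              threshold = strata$threshold)
    add(em$high, "vehicle_high", em$interaction$p_value)
    add(em$low, "vehicle_low", em$interaction$p_value)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
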