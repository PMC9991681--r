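#' Synthetic city configuration
#'
#' Describes the synthetic study region: a planar rectangle (miles) tiled by a
#' regular grid of census-tract analogues, a screened patient cohort with a
#' spatially structured food-insecurity outcome, and a set of full-line
#' grocery stores carrying NEMS-S item responses.
#'
#' Defaults emulate the study conditions the analysis assumes: 1100 patients
#' with ~31% food-insecurity prevalence, 75 stores whose total NEMS-S scores
#' target mean 27, sd 5, range 16--35, and tract covariates (income, poverty,
#' unemployment, uninsured, vehicle non-availability, public assistance) that
#' are spatially smooth and track the insecurity hotspots in the directions
#' reported for disadvantaged urban areas (lower income, higher poverty /
#' unemployment / no-vehicle / assistance rates).
#'
#' The insecurity outcome is generated from a logistic model:
#' `logit(p_i) = logit(baseline) + centred(hotspot bumps + covariate terms)`,
#' where the hotspot term is a sum of Gaussian bumps
#' `bump * exp(-d^2 / (2 r^2))` and covariate terms use the named log-odds
#' coefficients in `covariate_effects` (age per year, centred; `married`
#' indicator; `bmi` per unit, centred). Centring the linear predictor keeps
#' the marginal prevalence near `baseline_prevalence`.
#'
#' @param seed integer seed; identical configs give byte-identical cities.
#' @param bounds named numeric `c(xmin, ymin, xmax, ymax)` in miles.
#' @param n_patients,n_stores cohort and store counts.
#' @param baseline_prevalence target marginal insecurity prevalence.
#' @param hotspots list of `list(center = c(x, y), radius, bump)` giving
#'   Gaussian log-odds bumps; `list()` for a spatially homogeneous outcome.
#' @param n_tracts_x,n_tracts_y tract grid dimensions.
#' @param covariate_effects named numeric log-odds coefficients; recognised
#'   names are `age`, `married`, `bmi`. Zero-length for no covariate effects.
#' @param missing_rates named per-covariate missingness probabilities applied
#'   by [inject_missingness()] (the generator itself emits complete data).
#' @param store_score_mean,store_score_sd,store_score_min,store_score_max
#'   targets for the truncated-normal total NEMS-S distribution of stores.
#' @return a `city_config` list.
#' @export
city_config <- function(seed = 1L,
                        bounds = c(xmin = 0, ymin = 0, xmax = 12, ymax = 10),
                        n_patients = 1100L,
                        n_stores = 75L,
                        baseline_prevalence = 0.31,
                        hotspots = list(
                          list(center = c(6, 5), radius = 1.5, bump = 0.9),
                          list(center = c(3, 7.5), radius = 1.2, bump = 0.7),
                          list(center = c(9, 3), radius = 1.0, bump = 0.5)),
                        n_tracts_x = 12L, n_tracts_y = 10L,
                        covariate_effects = c(age = -0.02, married = -0.5, bmi = 0.01),
                        missing_rates = c(marital_status = 0.20, bmi = 0.15, race = 0.10),
                        store_score_mean = 27, store_score_sd = 5,
                        store_score_min = 16, store_score_max = 35) {
  stopifnot(length(bounds) == 4)
  names(bounds) <- c("xmin", "ymin", "xmax", "ymax")
  if (bounds["xmax"] <= bounds["xmin"] || bounds["ymax"] <= bounds["ymin"]) {
    stop("bounds are degenerate", call. = FALSE)
  }
  if (n_patients < 1 || n_stores < 1) stop("need at least one patient and store", call. = FALSE)
  if (baseline_prevalence < 0 || baseline_prevalence > 1) {
    stop("baseline_prevalence must be a probability", call. = FALSE)
  }
  if (length(missing_rates) && any(missing_rates < 0 | missing_rates > 1)) {
    stop("missing_rates must be probabilities", call. = FALSE)
  }
  if (store_score_min > store_score_max) {
    stop("infeasible store score targets: min > max", call. = FALSE)
  }
  if (store_score_min < -9 || store_score_max > 54) {
    stop("store score targets outside the attainable NEMS-S range [-9, 54]", call. = FALSE)
  }
  for (h in hotspots) {
    stopifnot(length(h$center) == 2, h$radius > 0)
  }
  structure(list(seed = as.integer(seed), bounds = bounds,
                 n_patients = as.integer(n_patients),
                 n_stores = as.integer(n_stores),
                 baseline_prevalence = baseline_prevalence,
                 hotspots = hotspots,
                 n_tracts_x = as.integer(n_tracts_x),
                 n_tracts_y = as.integer(n_tracts_y),
                 covariate_effects = covariate_effects,
                 missing_rates = missing_rates,
                 store_score_mean = store_score_mean,
                 store_score_sd = store_score_sd,
                 store_score_min = store_score_min,
                 store_score_max = store_score_max),
            class = "city_config")
}

# Summed Gaussian hotspot log-odds bump at points (x, y).
.hotspot_intensity <- function(x, y, hotspots) {
  eta <- numeric(length(x))
  for (h in hotspots) {
    d2 <- (x - h$center[1])^2 + (y - h$center[2])^2
    eta <- eta + h$bump * exp(-d2 / (2 * h$radius^2))
  }
  eta
}

# Map points into tract ids on the regular grid ("tx_ty", 1-based).
.tract_of <- function(x, y, config) {
  b <- config$bounds
  tx <- pmin(pmax(1L, ceiling((x - b["xmin"]) / (b["xmax"] - b["xmin"]) * config$n_tracts_x)),
             config$n_tracts_x)
  ty <- pmin(pmax(1L, ceiling((y - b["ymin"]) / (b["ymax"] - b["ymin"]) * config$n_tracts_y)),
             config$n_tracts_y)
  sprintf("T%02d_%02d", tx, ty)
}

# Low-frequency random surface in [-1, 1]-ish, for spatially smooth noise.
.smooth_field <- function(x, y, bounds, phase) {
  w <- bounds["xmax"] - bounds["xmin"]
  h <- bounds["ymax"] - bounds["ymin"]
  sin(2 * pi * (x - bounds["xmin"]) / w + phase[1]) *
    cos(2 * pi * (y - bounds["ymin"]) / h + phase[2])
}

.generate_tracts <- function(config) {
  b <- config$bounds
  dx <- (b["xmax"] - b["xmin"]) / config$n_tracts_x
  dy <- (b["ymax"] - b["ymin"]) / config$n_tracts_y
  g <- expand.grid(tx = seq_len(config$n_tracts_x), ty = seq_len(config$n_tracts_y))
  cx <- b["xmin"] + (g$tx - 0.5) * dx
  cy <- b["ymin"] + (g$ty - 0.5) * dy
  hs <- .hotspot_intensity(cx, cy, config$hotspots)
  hn <- if (max(hs) > 0) hs / max(hs) else hs  # normalized 0..1 intensity
  n <- nrow(g)
  ph <- matrix(stats::runif(12, 0, 2 * pi), ncol = 2)
  sm <- function(k) .smooth_field(cx, cy, b, ph[k, ])
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  data.frame(
    tract_id = sprintf("T%02d_%02d", g$tx, g$ty),
    xmin = b["xmin"] + (g$tx - 1) * dx, xmax = b["xmin"] + g$tx * dx,
    ymin = b["ymin"] + (g$ty - 1) * dy, ymax = b["ymin"] + g$ty * dy,
    center_x = cx, center_y = cy,
    median_income = clamp(28000 - 9000 * hn + 5000 * sm(1) + stats::rnorm(n, 0, 2500),
                          8000, 120000),
    pct_below_poverty = clamp(38 + 14 * hn + 7 * sm(2) + stats::rnorm(n, 0, 4), 0, 100),
    unemployment_rate = clamp(12 + 8 * hn + 4 * sm(3) + stats::rnorm(n, 0, 2.5), 0, 100),
    uninsured_rate = clamp(12 + 5 * hn + 3 * sm(4) + stats::rnorm(n, 0, 2), 0, 100),
    pct_no_vehicle = clamp(12 + 9 * hn + 4 * sm(5) + stats::rnorm(n, 0, 3), 0, 100),
    pct_public_assistance = clamp(34 + 13 * hn + 6 * sm(6) + stats::rnorm(n, 0, 4), 0, 100),
    stringsAsFactors = FALSE)
}

.generate_patients <- function(config, tracts) {
  n <- config$n_patients
  b <- config$bounds
  x <- stats::runif(n, b["xmin"], b["xmax"])
  y <- stats::runif(n, b["ymin"], b["ymax"])
  age <- round(pmin(pmax(stats::rnorm(n, 50, 16), 18), 95))
  sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.6, 0.4))
  race <- sample(c("black", "white", "other"), n, replace = TRUE,
                 prob = c(0.75, 0.15, 0.10))
  marital <- sample(c("married", "single", "widowed_divorced"), n, replace = TRUE,
                    prob = c(0.25, 0.55, 0.20))
  bmi <- round(pmin(pmax(stats::rnorm(n, 30.5, 7), 15), 60), 1)

  eff <- config$covariate_effects
  eta <- .hotspot_intensity(x, y, config$hotspots)
  if ("age" %in% names(eff)) eta <- eta + eff[["age"]] * (age - mean(age))
  if ("married" %in% names(eff)) eta <- eta + eff[["married"]] * (marital == "married")
  if ("bmi" %in% names(eff)) eta <- eta + eff[["bmi"]] * (bmi - mean(bmi))
  lp <- stats::qlogis(config$baseline_prevalence) + eta - mean(eta)
  fi <- stats::rbinom(n, 1L, stats::plogis(lp))

  data.frame(id = sprintf("P%04d", seq_len(n)), x = x, y = y,
             food_insecure = fi, age = age, sex = sex, race = race,
             marital_status = marital, bmi = bmi,
             tract_id = .tract_of(x, y, config),
             stringsAsFactors = FALSE)
}

# Draw item responses whose scored total exactly hits `target`: sample items,
# then nudge random items one step toward the target until the scorer agrees.
.items_for_total <- function(target, quality) {
  av <- sample(0:6, 5, replace = TRUE, prob = c(1, 1, 2, 3, 4, 4, 3))
  pr <- sample(-1:2, 9, replace = TRUE, prob = c(1, 3, 4, 2))
  total <- sum(av) + sum(pr) + quality
  while (total != target) {
    step <- sign(target - total)
    k <- sample.int(14, 1)
    if (k <= 5) {
      v <- av[k] + step
      if (v >= 0 && v <= 6) { av[k] <- v; total <- total + step }
    } else {
      v <- pr[k - 5] + step
      if (v >= -1 && v <= 2) { pr[k - 5] <- v; total <- total + step }
    }
  }
  list(av = av, pr = pr)
}

# Parent (mu, sigma) of a normal whose [lo, hi]-truncation has the requested
# mean and sd. Truncation shrinks spread, so the parent sigma is inflated.
.trunc_norm_params <- function(mean, sd, lo, hi) {
  moments <- function(mu, s) {
    a <- (lo - mu) / s; b <- (hi - mu) / s
    z <- stats::pnorm(b) - stats::pnorm(a)
    da <- stats::dnorm(a); db <- stats::dnorm(b)
    m <- mu + s * (da - db) / z
    v <- s^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
    c(m, sqrt(max(v, 0)))
  }
  obj <- function(par) {
    mo <- moments(par[1], exp(par[2]))
    (mo[1] - mean)^2 + (mo[2] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj)
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

.generate_stores <- function(config) {
  n <- config$n_stores
  b <- config$bounds
  x <- stats::runif(n, b["xmin"], b["xmax"])
  y <- stats::runif(n, b["ymin"], b["ymax"])
  # truncated-normal total targets, parent moments solved so the truncated
  # distribution hits the configured mean/sd
  if (config$store_score_min == config$store_score_max) {
    targets <- rep.int(as.integer(config$store_score_min), n)
  } else {
    pp <- .trunc_norm_params(config$store_score_mean, config$store_score_sd,
                             config$store_score_min, config$store_score_max)
    targets <- integer(n)
    for (i in seq_len(n)) {
      repeat {
        t <- round(stats::rnorm(1, pp["mu"], pp["sigma"]))
        if (t >= config$store_score_min && t <= config$store_score_max) break
      }
      targets[i] <- t
    }
  }
  # most stores rate top produce quality
  quality <- ifelse(stats::runif(n) < 72 / 75, 6L, sample(4:5, n, replace = TRUE))
  av <- matrix(0L, n, 5, dimnames = list(NULL, paste0("av_", 1:5)))
  pr <- matrix(0L, n, 9, dimnames = list(NULL, paste0("pr_", 1:9)))
  for (i in seq_len(n)) {
    it <- .items_for_total(targets[i], quality[i])
    av[i, ] <- it$av
    pr[i, ] <- it$pr
  }
  st <- data.frame(id = sprintf("S%03d", seq_len(n)), x = x, y = y,
                   av, pr, quality_item = quality,
                   tract_id = .tract_of(x, y, config),
                   stringsAsFactors = FALSE)
  score_stores(st)
}

#' Generate a synthetic city
#'
#' Deterministically (given the config seed) generates tract, patient, and
#' store tables with the structure described in [city_config()]. Store scores
#' are always derived by [score_stores()] from the sampled item responses, so
#' the scoring module is the single source of score truth.
#'
#' @param config a [city_config()].
#' @return a `food_city` list with elements `patients`, `stores`, `tracts`,
#'   `config`.
#' @export
generate_city <- function(config = city_config()) {
  stopifnot(inherits(config, "city_config"))
  set.seed(config$seed)
  tracts <- .generate_tracts(config)
  patients <- .generate_patients(config, tracts)
  stores <- .generate_stores(config)
  structure(list(patients = patients, stores = stores, tracts = tracts,
                 config = config),
            class = "food_city")
}

#' @export
print.food_city <- function(x, ...) {
  cat(sprintf("<food_city> %d patients (%.1f%% food insecure), %d stores, %d tracts\n",
              nrow(x$patients), 100 * mean(x$patients$food_insecure),
              nrow(x$stores), nrow(x$tracts)))
  invisible(x)
}

#' Mask covariate values to emulate EMR missingness
#'
#' Masks covariate cells under MCAR (completely at random) or MAR-on-age
#' (missingness probability increasing in age, rescaled to hit the marginal
#' rate). The outcome, coordinates, id, and tract link can never be masked.
#'
#' @param patients patient table.
#' @param missing_rates named per-covariate missingness probabilities.
#' @param mechanism `"MCAR"` or `"MAR-on-age"`.
#' @param seed integer seed.
#' @return the patient table with `NA`s injected.
#' @export
inject_missingness <- function(patients, missing_rates,
                               mechanism = c("MCAR", "MAR-on-age"), seed = 1L) {
  mechanism <- match.arg(mechanism)
  protected <- c("id", "x", "y", "food_insecure", "tract_id")
  if (any(names(missing_rates) %in% protected)) {
    stop("cannot mask outcome, coordinates, id or tract link", call. = FALSE)
  }
  if (length(missing_rates) && (any(missing_rates < 0 | missing_rates > 1))) {
    stop("missing_rates must be probabilities", call. = FALSE)
  }
  unknown <- setdiff(names(missing_rates), names(patients))
  if (length(unknown)) stop("unknown covariates: ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  set.seed(seed)
  n <- nrow(patients)
  w <- if (mechanism == "MAR-on-age") {
    stats::plogis(scale(patients$age)[, 1])
  } else {
    rep(1, n)
  }
  for (v in names(missing_rates)) {
    r <- missing_rates[[v]]
    if (r == 0) next
    p <- pmin(r * w / mean(w), 0.99)
    patients[[v]][stats::runif(n) < p] <- NA
  }
  patients
}

#' Write city tables to a directory
#'
#' Writes `patients.csv`, `stores.csv`, `tracts.csv` (headered UTF-8 CSV) and
#' `city_config.yaml` into `dir`.
#'
#' @param city a `food_city`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_city <- function(city, dir) {
  stopifnot(inherits(city, "food_city"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(city$patients, file.path(dir, "patients.csv"), row.names = FALSE)
  utils::write.csv(city$stores, file.path(dir, "stores.csv"), row.names = FALSE)
  utils::write.csv(city$tracts, file.path(dir, "tracts.csv"), row.names = FALSE)
  cfg <- city$config
  cfg_list <- lapply(unclass(cfg), function(x) if (is.numeric(x)) unname(x) else x)
  cfg_list$bounds <- as.list(cfg$bounds)
  cfg_list$covariate_effects <- as.list(cfg$covariate_effects)
  cfg_list$missing_rates <- as.list(cfg$missing_rates)
  yaml::write_yaml(cfg_list, file.path(dir, "city_config.yaml"))
  invisible(dir)
}

#' Write a point table as GeoJSON
#'
#' Emits a GeoJSON FeatureCollection of Point features; all non-coordinate
#' columns become feature properties. Coordinates are the planar mile frame
#' (no CRS is claimed).
#'
#' @param points data frame with `x` and `y` columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
points_to_geojson <- function(points, path) {
  stopifnot(all(c("x", "y") %in% names(points)))
  props <- points[, setdiff(names(points), c("x", "y")), drop = FALSE]
  features <- lapply(seq_len(nrow(points)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(points$x[i], points$y[i])),
         properties = as.list(props[i, , drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
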