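#' Compare groups on descriptive covariates
#'
#' Classic "Table 1" comparisons: Welch two-sample t-tests for continuous
#' covariates and chi-squared tests for categorical covariates, against a
#' binary grouping variable (here food insecurity). Continuity correction for
#' 2x2 tables is off by default.
#'
#' @param data data frame.
#' @param group name of the binary grouping column.
#' @param continuous,categorical character vectors of covariate names.
#' @param correct logical; Yates continuity correction for 2x2 chi-squared.
#' @return data frame with one row per covariate: test type, statistic, df,
#'   p-value, and per-group summaries (`mean (sd)` or modal `level: %`).
#' @export
compare_groups <- function(data, group, continuous = character(0),
                           categorical = character(0), correct = FALSE) {
  g <- data[[group]]
  lev <- sort(unique(g))
  if (length(lev) != 2) stop("grouping variable must be binary", call. = FALSE)
  rows <- list()
  for (v in continuous) {
    x0 <- data[[v]][g == lev[1]]
    x1 <- data[[v]][g == lev[2]]
    summ <- function(x) sprintf("%.1f (%.1f)", mean(x, na.rm = TRUE),
                                stats::sd(x, na.rm = TRUE))
    if (stats::sd(c(x0, x1), na.rm = TRUE) == 0 || anyNA(c(stats::sd(x0, na.rm = TRUE)))) {
      rows[[v]] <- data.frame(variable = v, type = "continuous",
                              statistic = NA_real_, df = NA_real_,
                              p_value = NA_real_, group0 = summ(x0),
                              group1 = summ(x1), note = "zero variance, test skipped")
      next
    }
    tt <- stats::t.test(x1, x0)
    rows[[v]] <- data.frame(variable = v, type = "continuous",
                            statistic = unname(tt$statistic),
                            df = unname(tt$parameter), p_value = tt$p.value,
                            group0 = summ(x0), group1 = summ(x1), note = "")
  }
  for (v in categorical) {
    tab <- table(data[[v]], g)
    topshare <- function(col) {
      p <- prop.table(tab[, col])
      sprintf("%s: %.0f%%", names(which.max(p)), 100 * max(p))
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    rows[[v]] <- data.frame(variable = v, type = "categorical",
                            statistic = unname(ct$statistic),
                            df = unname(ct$parameter), p_value = ct$p.value,
                            group0 = topshare(1), group1 = topshare(2), note = "")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(out)[names(out) == "group0"] <- paste0(group, "_", lev[1])
  names(out)[names(out) == "group1"] <- paste0(group, "_", lev[2])
  out
}

#' Correlate store scores with area covariates
#'
#' Pearson correlations (with two-sided t-based p-values) between a store
#' score and the covariates of the tract each store sits in.
#'
#' @param scores numeric store scores.
#' @param covariates data frame of tract covariates, one row per store.
#' @return data frame with `covariate`, `r`, `p_value`, `n`, `note`.
#' @export
correlate_stores <- function(scores, covariates) {
  if (length(scores) < 3) stop("need at least 3 stores", call. = FALSE)
  rows <- lapply(names(covariates), function(v) {
    x <- covariates[[v]]
    if (stats::sd(x, na.rm = TRUE) == 0) {
      return(data.frame(covariate = v, r = NA_real_, p_value = NA_real_,
                        n = sum(!is.na(x)), note = "constant covariate"))
    }
    ct <- stats::cor.test(scores, x, method = "pearson")
    data.frame(covariate = v, r = unname(ct$estimate), p_value = ct$p.value,
               n = sum(stats::complete.cases(scores, x)), note = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Vehicle-availability strata
#'
#' Classifies tracts as high vehicle non-availability when the percentage of
#' households without a vehicle meets the threshold (closed comparison,
#' `>=`). By default the threshold is the third quartile of the tract
#' distribution; pass `threshold` (e.g. 17) to fix it.
#'
#' @param tracts tract table with `pct_no_vehicle`.
#' @param threshold percentage threshold, or `NULL` to use the third quartile.
#' @return a `vehicle_strata` list: `threshold`, `auto`, and `high`, a logical
#'   vector named by `tract_id`.
#' @export
vehicle_strata <- function(tracts, threshold = NULL) {
  auto <- is.null(threshold)
  if (auto) threshold <- unname(stats::quantile(tracts$pct_no_vehicle, 0.75))
  high <- tracts$pct_no_vehicle >= threshold
  names(high) <- tracts$tract_id
  structure(list(threshold = threshold, auto = auto, high = high),
            class = "vehicle_strata")
}

#' Attach tract covariates (and vehicle stratum) to patients
#'
#' @param patients patient table with `tract_id`.
#' @param tracts tract table.
#' @param strata optional [vehicle_strata()]; adds a `vehicle_high` column.
#' @return patient table with tract covariate columns appended.
#' @export
attach_tract_covariates <- function(patients, tracts, strata = NULL) {
  keep <- c("tract_id", "median_income", "pct_below_poverty", "unemployment_rate",
            "uninsured_rate", "pct_no_vehicle", "pct_public_assistance")
  out <- merge(patients, tracts[, keep], by = "tract_id", sort = FALSE)
  out <- out[match(patients$id, out$id), ]
  rownames(out) <- NULL
  if (!is.null(strata)) out$vehicle_high <- unname(strata$high[out$tract_id])
  out
}

.default_adjustment <- c("age", "marital_status", "median_income",
                         "pct_below_poverty", "unemployment_rate",
                         "pct_no_vehicle", "pct_public_assistance")

.model_frames <- function(stack, exposures = NULL) {
  frames <- if (inherits(stack, "imputed_stack")) stack$imputations else list(stack)
  if (!is.null(exposures)) {
    frames <- lapply(frames, function(f) {
      stopifnot(nrow(f) == nrow(exposures))
      cbind(f, exposures[, setdiff(names(exposures), names(f)), drop = FALSE])
    })
  }
  frames
}

.fit_one <- function(formula, data, family) {
  sep <- FALSE
  fit <- withCallingHandlers(
    if (family == "logistic") {
      stats::glm(formula, data = data, family = stats::binomial())
    } else {
      stats::lm(formula, data = data)
    },
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  attr(fit, "separation") <- sep
  fit
}

#' Pooled exposure-insecurity model
#'
#' Regresses an exposure outcome on food-insecurity status, optionally
#' adjusted for the descriptive covariate set, fitting each completed table
#' of an imputed stack and pooling the food-insecurity coefficient by Rubin's
#' rules. Linear models report the mean difference in the exposure comparing
#' food insecure with food secure patients; logistic models (for presence
#' indicators) report the odds ratio.
#'
#' Rows with a missing outcome (patients with no store within the radius) are
#' excluded from continuous models; their count is returned. The 2-mile
#' presence indicator is refused for logistic models by default because too
#' few patients lack a store at that range for a stable fit; override with
#' `allow_2mi = TRUE`.
#'
#' @param stack an `imputed_stack` or a single complete data frame.
#' @param outcome name of the exposure outcome column.
#' @param family `"linear"` or `"logistic"`.
#' @param exposures optional data frame of exposure columns to bind onto each
#'   completed table (same row order).
#' @param adjusted include the adjustment covariates?
#' @param adjustment adjustment covariate names.
#' @param predictor name of the exposure-group column (binary).
#' @param allow_2mi allow a 2-mile logistic presence model.
#' @return a `fit_result` list: `estimate` (mean difference or OR), `coef`,
#'   `se`, `ci`, `p_value`, `n`, `excluded_n`, `family`, `pooled`, `m`,
#'   `separation`.
#' @export
fit_exposure_model <- function(stack, outcome, family = c("linear", "logistic"),
                               exposures = NULL, adjusted = TRUE,
                               adjustment = .default_adjustment,
                               predictor = "food_insecure",
                               allow_2mi = FALSE) {
  family <- match.arg(family)
  if (family == "logistic" && grepl("(^|_)2mi$", outcome) && !allow_2mi) {
    stop("2-mile presence model refused by default (too few patients lack a ",
         "store at 2 miles); set allow_2mi = TRUE to override", call. = FALSE)
  }
  frames <- .model_frames(stack, exposures)
  rhs <- if (adjusted) paste(c(predictor, adjustment), collapse = " + ") else predictor
  fml <- stats::as.formula(paste0("`", outcome, "` ~ ", rhs))
  keep <- !is.na(frames[[1]][[outcome]])
  fits <- lapply(frames, function(f) .fit_one(fml, f[keep, , drop = FALSE], family))
  sep <- any(vapply(fits, function(f) isTRUE(attr(f, "separation")), logical(1)))
  if (length(fits) >= 2) {
    po <- pool_fits(fits, predictor)
    coef <- po$estimate; se <- po$se; ci <- po$ci; p <- po$p_value
    pooled <- TRUE
  } else {
    sm <- summary(fits[[1]])$coefficients
    coef <- sm[predictor, 1]; se <- sm[predictor, 2]
    q <- stats::qt(0.975, stats::df.residual(fits[[1]]))
    ci <- coef + c(-1, 1) * q * se
    p <- sm[predictor, 4]
    pooled <- FALSE
  }
  est <- if (family == "logistic") exp(coef) else coef
  structure(list(outcome = outcome, family = family, predictor = predictor,
                 estimate = est, coef = coef, se = se,
                 ci = if (family == "logistic") exp(ci) else ci,
                 p_value = p, n = sum(keep), excluded_n = sum(!keep),
                 adjusted = adjusted, pooled = pooled, m = length(fits),
                 separation = sep),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  lab <- if (x$family == "logistic") "OR" else "mean difference"
  cat(sprintf("%s [%s, %s]: %s = %.3f (95%% CI %.3f to %.3f), p = %.3g, n = %d%s\n",
              x$outcome, x$family, if (x$adjusted) "adjusted" else "unadjusted",
              lab, x$estimate, x$ci[1], x$ci[2], x$p_value, x$n,
              if (x$separation) " [separation warning]" else ""))
  invisible(x)
}

#' Effect modification by vehicle availability
#'
#' Tests whether the exposure-insecurity association differs between areas of
#' high and low vehicle non-availability: the interaction p-value comes from
#' a product term `predictor x modifier` in the full model, and
#' stratum-specific estimates come from subgroup refits (which drop the
#' vehicle-availability rate from the adjustment set, since stratification
#' already conditions on it).
#'
#' @inheritParams fit_exposure_model
#' @param modifier name of the logical stratum column (e.g. `vehicle_high`
#'   from [attach_tract_covariates()]).
#' @param threshold stratum threshold, echoed in error messages and output.
#' @return list with `interaction` (a `pooled_estimate`-like summary of the
#'   product term), `high`, `low` (stratum `fit_result`s) and `threshold`.
#' @export
effect_modification <- function(stack, outcome, family = c("linear", "logistic"),
                                exposures = NULL, modifier = "vehicle_high",
                                adjustment = setdiff(.default_adjustment, "pct_no_vehicle"),
                                predictor = "food_insecure",
                                threshold = NA_real_, allow_2mi = FALSE) {
  family <- match.arg(family)
  frames <- .model_frames(stack, exposures)
  mod <- frames[[1]][[modifier]]
  if (is.null(mod)) stop("modifier column ", modifier, " not found", call. = FALSE)
  if (length(unique(mod)) < 2) {
    stop("modifier is constant; cannot stratify at threshold ", threshold, call. = FALSE)
  }
  if (!any(mod) || all(mod)) {
    stop("empty vehicle stratum at threshold ", threshold, call. = FALSE)
  }
  term <- paste0(predictor, ":", modifier, "TRUE")
  rhs <- paste(c(paste0(predictor, " * ", modifier), adjustment), collapse = " + ")
  fml <- stats::as.formula(paste0("`", outcome, "` ~ ", rhs))
  keep <- !is.na(frames[[1]][[outcome]])
  fits <- lapply(frames, function(f) {
    f[[modifier]] <- factor(f[[modifier]], levels = c(FALSE, TRUE))
    .fit_one(fml, f[keep, , drop = FALSE], family)
  })
  interaction <- if (length(fits) >= 2) {
    pool_fits(fits, term)
  } else {
    sm <- summary(fits[[1]])$coefficients
    list(estimate = sm[term, 1], se = sm[term, 2], p_value = sm[term, 4],
         m = 1L)
  }
  sub <- function(high) {
    sel <- lapply(frames, function(f) f[f[[modifier]] == high, , drop = FALSE])
    st <- if (length(sel) >= 2) {
      structure(list(imputations = sel, m = length(sel)), class = "imputed_stack")
    } else {
      sel[[1]]
    }
    fit_exposure_model(st, outcome, family, exposures = NULL, adjusted = TRUE,
                       adjustment = adjustment, predictor = predictor,
                       allow_2mi = allow_2mi)
  }
  list(interaction = interaction, high = sub(TRUE), low = sub(FALSE),
       threshold = threshold, outcome = outcome, family = family)
}
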