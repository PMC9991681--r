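#' Chained-equation multiple imputation
#'
#' Fills missing covariate cells by fully conditional specification: each
#' incomplete variable is regressed in turn on all other variables of the
#' working (currently completed) table, and its missing cells are replaced by
#' draws from the fitted model. `m` independent chains give `m` completed
#' tables. The default base learner is a random forest whose imputations are
#' drawn from terminal-node donors (an observed value co-landing in the same
#' leaf of a randomly chosen tree), which propagates predictive uncertainty
#' rather than imputing conditional means.
#'
#' The table passed in should contain only modeling variables (outcome,
#' covariates, presence indicators); fully observed variables act as
#' predictors only and are never altered.
#'
#' @param data data frame of modeling variables; missingness only in
#'   covariates to be imputed.
#' @param m number of imputations (>= 2).
#' @param maxit chained-equation cycles per imputation.
#' @param base_learner `"random_forest"`, `"normal_linear"`, or
#'   `"predictive_mean_matching"`.
#' @param ntree trees per forest (random forest learner only).
#' @param seed integer seed; the whole stack is reproducible from it.
#' @return an `imputed_stack`: list with `imputations` (list of `m` completed
#'   data frames), `diagnostics` (chain means per variable and iteration),
#'   `missing_pattern`, and the call configuration.
#' @export
impute_covariates <- function(data, m = 5L, maxit = 10L,
                              base_learner = c("random_forest", "normal_linear",
                                               "predictive_mean_matching"),
                              ntree = 100L, seed = 1L) {
  base_learner <- match.arg(base_learner)
  if (m < 2) stop("m must be at least 2", call. = FALSE)
  stopifnot(is.data.frame(data), nrow(data) > 0)

  num <- vapply(data, is.numeric, logical(1))
  for (v in names(data)[num]) {
    if (any(!is.finite(data[[v]]) & !is.na(data[[v]]))) {
      stop("non-finite values in ", v, call. = FALSE)
    }
  }
  was_char <- vapply(data, is.character, logical(1))
  was_lgl <- vapply(data, is.logical, logical(1))
  work0 <- data
  for (v in names(data)[was_char]) work0[[v]] <- factor(work0[[v]])
  for (v in names(data)[was_lgl]) work0[[v]] <- factor(work0[[v]], c(FALSE, TRUE))

  miss <- vapply(work0, function(x) sum(is.na(x)), integer(1))
  if (all(miss == 0)) {
    stack <- replicate(m, data, simplify = FALSE)
    return(structure(list(imputations = stack, diagnostics = NULL,
                          missing_pattern = miss, m = m, maxit = maxit,
                          base_learner = base_learner, seed = seed),
                     class = "imputed_stack"))
  }
  if (any(miss == nrow(work0))) {
    stop("variable with 100% missingness: ",
         paste(names(miss)[miss == nrow(work0)], collapse = ", "), call. = FALSE)
  }
  if (!any(miss == 0)) stop("need at least one fully observed variable", call. = FALSE)

  targets <- names(miss)[miss > 0]
  targets <- targets[order(miss[targets])]  # least missing first
  ry <- lapply(work0[targets], function(x) !is.na(x))

  set.seed(seed)
  diag_arr <- array(NA_real_, dim = c(m, maxit, length(targets)),
                    dimnames = list(NULL, NULL, targets))
  stack <- vector("list", m)
  for (chain in seq_len(m)) {
    work <- work0
    for (v in targets) {  # init: random draws from the observed margin
      nmis <- sum(!ry[[v]])
      work[[v]][!ry[[v]]] <- sample(work0[[v]][ry[[v]]], nmis, replace = TRUE)
    }
    for (it in seq_len(maxit)) {
      for (v in targets) {
        obs <- ry[[v]]
        x <- work[, setdiff(names(work), v), drop = FALSE]
        y <- work0[[v]]
        imp <- switch(base_learner,
          random_forest = .impute_rf(x, y, obs, ntree),
          normal_linear = .impute_norm(x, y, obs),
          predictive_mean_matching = .impute_pmm(x, y, obs))
        work[[v]][!obs] <- imp
        diag_arr[chain, it, v] <- if (is.numeric(work[[v]])) {
          mean(work[[v]][!obs])
        } else {
          max(prop.table(table(work[[v]][!obs])))
        }
      }
    }
    for (v in names(data)[was_char]) work[[v]] <- as.character(work[[v]])
    for (v in names(data)[was_lgl]) work[[v]] <- work[[v]] == "TRUE"
    stack[[chain]] <- work
  }
  structure(list(imputations = stack, diagnostics = diag_arr,
                 missing_pattern = miss, m = m, maxit = maxit,
                 base_learner = base_learner, seed = seed),
            class = "imputed_stack")
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat(sprintf("<imputed_stack> m = %d (%s), %d cells imputed over %d variables\n",
              x$m, x$base_learner, sum(x$missing_pattern),
              sum(x$missing_pattern > 0)))
  invisible(x)
}

# Random-forest imputation with terminal-node donor draws: for each missing
# row pick a random tree, collect observed training rows in the same leaf,
# and draw one of their responses.
.impute_rf <- function(x, y, obs, ntree) {
  xobs <- x[obs, , drop = FALSE]  # keep full level sets for predict()
  yobs <- if (is.factor(y)) droplevels(y[obs]) else y[obs]
  rf <- randomForest::randomForest(x = xobs, y = yobs, ntree = ntree)
  nodes_obs <- attr(stats::predict(rf, xobs, nodes = TRUE), "nodes")
  nodes_mis <- attr(stats::predict(rf, x[!obs, , drop = FALSE], nodes = TRUE), "nodes")
  nmis <- sum(!obs)
  out <- yobs[rep.int(1L, nmis)]  # typed container
  for (i in seq_len(nmis)) {
    tr <- sample.int(ntree, 1L)
    donors <- yobs[nodes_obs[, tr] == nodes_mis[i, tr]]
    if (!length(donors)) donors <- yobs
    out[i] <- donors[sample.int(length(donors), 1L)]
  }
  out
}

# Gaussian linear imputation: fitted mean plus a residual-scale noise draw.
.impute_norm <- function(x, y, obs) {
  if (!is.numeric(y)) return(.impute_pmm(x, y, obs))
  df <- cbind(.y = y, x)
  fit <- stats::lm(.y ~ ., data = df[obs, , drop = FALSE])
  pred <- stats::predict(fit, newdata = df[!obs, , drop = FALSE])
  pred + stats::rnorm(length(pred), 0, summary(fit)$sigma)
}

# Predictive mean matching: draw among the 5 observed rows whose fitted
# values are nearest the missing row's fitted value.
.impute_pmm <- function(x, y, obs, k = 5L) {
  ynum <- if (is.numeric(y)) y else as.integer(y)
  df <- cbind(.y = ynum, x)
  fit <- stats::lm(.y ~ ., data = df[obs, , drop = FALSE])
  fo <- stats::fitted(fit)
  fm <- stats::predict(fit, newdata = df[!obs, , drop = FALSE])
  yobs <- y[obs]
  vapply(seq_along(fm), function(i) {
    nb <- order(abs(fo - fm[i]))[seq_len(min(k, length(fo)))]
    j <- nb[sample.int(length(nb), 1L)]
    yobs[j]
  }, yobs[1L])
}

#' Rubin's-rules pooling
#'
#' Combines per-imputation estimates and squared standard errors: the pooled
#' estimate is the mean of the estimates; total variance is
#' `T = W + (1 + 1/m) B` with `W` the mean within-imputation variance and `B`
#' the between-imputation sample variance. Degrees of freedom use the
#' Barnard-Rubin small-sample adjustment when the complete-data degrees of
#' freedom `dfcom` are finite.
#'
#' @param estimates numeric vector of per-imputation point estimates.
#' @param variances matching squared standard errors.
#' @param dfcom complete-data residual degrees of freedom (`Inf` for the
#'   large-sample rule).
#' @param conf_level confidence level for the interval.
#' @return a `pooled_estimate` list: `estimate`, `within`, `between`, `total`,
#'   `se`, `df`, `ci`, `p_value`, `m`, `riv`, `fmi`.
#' @export
pool_estimates <- function(estimates, variances, dfcom = Inf, conf_level = 0.95) {
  m <- length(estimates)
  if (m < 2) stop("pooling needs m >= 2 imputations", call. = FALSE)
  if (length(variances) != m) stop("estimates and variances must match", call. = FALSE)
  qbar <- mean(estimates)
  w <- mean(variances)
  b <- stats::var(estimates)
  total <- w + (1 + 1 / m) * b
  riv <- if (w > 0) (1 + 1 / m) * b / w else Inf
  lambda <- riv / (1 + riv)
  df_old <- if (lambda > .Machine$double.eps) (m - 1) / lambda^2 else Inf
  df <- if (is.finite(dfcom)) {
    df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
    1 / (1 / df_old + 1 / df_obs)
  } else {
    df_old
  }
  se <- sqrt(total)
  alpha <- 1 - conf_level
  q <- if (is.finite(df)) stats::qt(1 - alpha / 2, df) else stats::qnorm(1 - alpha / 2)
  p <- if (se > 0) {
    2 * stats::pt(-abs(qbar) / se, df = if (is.finite(df)) df else 1e8)
  } else {
    as.numeric(qbar == 0)
  }
  structure(list(estimate = qbar, within = w, between = b, total = total,
                 se = se, df = df, ci = c(qbar - q * se, qbar + q * se),
                 p_value = p, m = m, riv = riv,
                 fmi = (riv + 2 / (df + 3)) / (1 + riv)),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("pooled estimate %.4g (se %.4g, 95%% CI %.4g to %.4g, p = %.3g, m = %d)\n",
              x$estimate, x$se, x$ci[1], x$ci[2], x$p_value, x$m))
  invisible(x)
}

#' Pool one coefficient across fitted models
#'
#' @param fits list of `lm`/`glm` fits, one per imputation.
#' @param term coefficient name to pool.
#' @param ... passed to [pool_estimates()].
#' @return a `pooled_estimate`.
#' @export
pool_fits <- function(fits, term, ...) {
  est <- vapply(fits, function(f) stats::coef(f)[[term]], numeric(1))
  va <- vapply(fits, function(f) stats::vcov(f)[term, term], numeric(1))
  dfcom <- min(vapply(fits, stats::df.residual, numeric(1)))
  pool_estimates(est, va, dfcom = dfcom, ...)
}

#' Write an imputed stack to disk
#'
#' Serializes the `m` completed tables as `imputation_<k>.csv` plus a JSON
#' sidecar with seed, configuration, and convergence diagnostics.
#'
#' @param stack an `imputed_stack`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_imputed_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "imputed_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(stack$imputations)) {
    utils::write.csv(stack$imputations[[k]],
                     file.path(dir, sprintf("imputation_%d.csv", k)),
                     row.names = FALSE)
  }
  meta <- list(m = stack$m, maxit = stack$maxit, base_learner = stack$base_learner,
               seed = stack$seed, missing_pattern = as.list(stack$missing_pattern),
               chain_means = stack$diagnostics)
  jsonlite::write_json(meta, file.path(dir, "imputation_meta.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
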