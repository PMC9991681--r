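#!/usr/bin/env Rscript
# Stage 5: descriptive comparisons and pooled exposure models.
#
# (a) Table-1-style comparison of food insecure vs secure patients (Welch
#     t-tests, chi-squared without continuity correction);
# (b) Pearson correlations between store NEMS-S totals and tract covariates;
# (c) pooled linear models for each continuous exposure and pooled logistic
#     models for 0.5- and 1-mile presence (2-mile presence excluded: almost
#     no patient lacks a store at that range), unadjusted and adjusted,
#     with vehicle-availability effect modification (tract third-quartile
#     threshold, closed comparison).

suppressMessages(library(foodaccess))

patients <- read.csv("results/patients_observed.csv", stringsAsFactors = FALSE)
tracts <- read.csv("results/city/tracts.csv", stringsAsFactors = FALSE)
stores <- read.csv("results/stores_scored.csv", stringsAsFactors = FALSE)
exposures <- read.csv("results/exposures.csv", stringsAsFactors = FALSE)

strata <- vehicle_strata(tracts)
cat(sprintf("high no-vehicle stratum: tracts with >= %.1f%% carless households\n",
            strata$threshold))
tab <- attach_tract_covariates(patients, tracts, strata)

table1 <- compare_groups(
  tab, "food_insecure",
  continuous = c("age", "bmi", "median_income", "pct_below_poverty",
                 "unemployment_rate", "uninsured_rate", "pct_no_vehicle",
                 "pct_public_assistance"),
  categorical = c("sex", "race", "marital_status"))
write.csv(table1, "results/table1_descriptives.csv", row.names = FALSE)
cat("\ndescriptive comparisons significant at 0.05:\n")
print(table1[!is.na(table1$p_value) & table1$p_value < 0.05,
             c("variable", "statistic", "p_value")], row.names = FALSE)

st <- merge(stores[, c("id", "total", "tract_id")], tracts, by = "tract_id")
correlations <- correlate_stores(
  st$total, st[, c("median_income", "pct_below_poverty", "unemployment_rate",
                   "uninsured_rate", "pct_no_vehicle", "pct_public_assistance")])
write.csv(correlations, "results/store_correlations.csv", row.names = FALSE)
cat("\nstore NEMS-S vs tract covariates (Pearson):\n")
print(correlations[, c("covariate", "r", "p_value")], row.names = FALSE)

# rebuild the imputation stack from its serialized artifacts
m <- length(list.files("results/imputations", pattern = "^imputation_[0-9]+\\.csv$"))
frames <- lapply(seq_len(m), function(k) {
  read.csv(sprintf("results/imputations/imputation_%d.csv", k),
           stringsAsFactors = FALSE)
})
stack <- structure(list(imputations = frames, m = m), class = "imputed_stack")

models <- local({
  rows <- list()
  add <- function(fit, stratum = "all", ip = NA_real_) {
    rows[[length(rows) + 1]] <<- data.frame(
      outcome = fit$outcome, family = fit$family, adjusted = fit$adjusted,
      stratum = stratum, estimate = fit$estimate, ci_low = fit$ci[1],
      ci_high = fit$ci[2], p_value = fit$p_value, interaction_p = ip,
      n = fit$n, excluded_n = fit$excluded_n)
  }
  cont <- c(paste0(rep(c("max_nems_", "mean_nems_", "max_avail_", "mean_avail_",
                         "max_price_", "mean_price_"), 3),
                   rep(c("0.5mi", "1mi", "2mi"), each = 6)), "auc")
  for (oc in cont) {
    add(fit_exposure_model(stack, oc, "linear", exposures, adjusted = FALSE))
    add(fit_exposure_model(stack, oc, "linear", exposures, adjusted = TRUE))
    em <- effect_modification(stack, oc, "linear", exposures,
                              threshold = strata$threshold)
    add(em$high, "vehicle_high", em$interaction$p_value)
    add(em$low, "vehicle_low", em$interaction$p_value)
  }
  for (oc in c("present_0.5mi", "present_1mi")) {
    add(fit_exposure_model(stack, oc, "logistic", exposures, adjusted = FALSE))
    add(fit_exposure_model(stack, oc, "logistic", exposures, adjusted = TRUE))
    em <- effect_modification(stack, oc, "logistic", exposures,
                              threshold = strata$threshold)
    add(em$high, "vehicle_high", em$interaction$p_value)
    add(em$low, "vehicle_low", em$interaction$p_value)
  }
  do.call(rbind, rows)
})
write.csv(models, "results/models.csv", row.names = FALSE)
cat(sprintf("\nfitted %d pooled models; adjusted all-patient estimates:\n",
            nrow(models)))
main <- models[models$adjusted & models$stratum == "all" &
                 models$outcome %in% c("max_nems_2mi", "mean_nems_1mi", "auc",
                                       "present_0.5mi", "present_1mi"), ]
print(main[, c("outcome", "family", "estimate", "ci_low", "ci_high", "p_value")],
      row.names = FALSE, digits = 3)
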