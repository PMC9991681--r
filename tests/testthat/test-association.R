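test_that("group comparisons match hand-computed statistics", {
  # identical groups: t = 0, p = 1
  df <- data.frame(g = rep(0:1, each = 4), v = rep(c(1, 2, 3, 4), 2))
  cg <- compare_groups(df, "g", continuous = "v")
  expect_equal(cg$statistic, 0)
  expect_equal(cg$p_value, 1)
  # 2x2 chi-squared without continuity correction:
  # counts (10, 20 / 30, 40) -> N(ad-bc)^2 / (r1 r2 c1 c2) = 0.79365
  df2 <- data.frame(g = rep(c(0, 0, 1, 1), c(10, 20, 30, 40)),
                    v = rep(c("a", "b", "a", "b"), c(10, 20, 30, 40)))
  cg2 <- compare_groups(df2, "g", categorical = "v")
  expect_equal(cg2$statistic, 100 * (10 * 40 - 20 * 30)^2 / (30 * 70 * 40 * 60),
               tolerance = 1e-10)
  expect_equal(cg2$statistic, 0.7936508, tolerance = 1e-6)
  # zero-variance variable is flagged, not tested
  df3 <- data.frame(g = rep(0:1, 5), v = rep(7, 10))
  cg3 <- compare_groups(df3, "g", continuous = "v")
  expect_true(is.na(cg3$p_value))
  expect_match(cg3$note, "zero variance")
  expect_error(compare_groups(data.frame(g = 1, v = 1), "g", "v"), "binary")
})

test_that("t-test and chi-squared reject at their nominal rate under the null", {
  set.seed(101)
  rej_t <- rej_c <- logical(400)
  for (i in seq_len(400)) {
    df <- data.frame(g = rep(0:1, each = 50), v = rnorm(100),
                     k = sample(c("a", "b"), 100, TRUE))
    cg <- compare_groups(df, "g", continuous = "v", categorical = "k")
    rej_t[i] <- cg$p_value[1] < 0.05
    rej_c[i] <- cg$p_value[2] < 0.05
  }
  expect_lt(abs(mean(rej_t) - 0.05), 0.03)
  expect_lt(abs(mean(rej_c) - 0.05), 0.03)
})

test_that("store-tract correlations match the closed form", {
  expect_equal(correlate_stores(1:5, data.frame(v = 2 * (1:5) + 3))$r, 1)
  r <- correlate_stores(c(1, 2, 3), data.frame(v = c(2, 1, 3)))
  expect_equal(r$r, 0.5)   # hand: cov 0.5, sds 1 and 1
  cs <- correlate_stores(rnorm(10), data.frame(v = rep(1, 10)))
  expect_true(is.na(cs$r))
  expect_match(cs$note, "constant")
  expect_error(correlate_stores(1:2, data.frame(v = 1:2)), "at least 3")
  # null calibration: mean r over independent draws is near zero
  set.seed(55)
  rs <- replicate(400, correlate_stores(rnorm(75), data.frame(v = rnorm(75)))$r)
  expect_lt(abs(mean(rs)), 0.02)
})

test_that("vehicle strata default to the tract third quartile with a closed rule", {
  tr <- data.frame(tract_id = paste0("t", 1:8),
                   pct_no_vehicle = c(5, 8, 10, 12, 14, 17, 20, 30))
  vs <- vehicle_strata(tr)
  expect_equal(vs$threshold, unname(quantile(tr$pct_no_vehicle, 0.75)))
  expect_true(vs$auto)
  fixed <- vehicle_strata(tr, threshold = 17)
  expect_false(fixed$auto)
  expect_identical(unname(fixed$high), tr$pct_no_vehicle >= 17)  # closed comparison
  expect_true(fixed$high[["t6"]])
})

test_that("a saturated logistic fit reproduces the 2x2 cross-product odds ratio", {
  a <- 20; b <- 35; c <- 15; d <- 50
  df <- expand_2x2(a, b, c, d)
  names(df) <- c("food_insecure", "present_1mi")
  fit <- fit_exposure_model(df, "present_1mi", "logistic", adjusted = FALSE)
  expect_equal(fit$estimate, (a * d) / (b * c), tolerance = 1e-8)
  expect_false(fit$pooled)
  expect_true(fit$ci[1] < fit$estimate && fit$estimate < fit$ci[2])
})

test_that("the 2-mile logistic presence model is refused by default", {
  df <- expand_2x2(20, 35, 15, 50)
  names(df) <- c("food_insecure", "present_2mi")
  expect_error(fit_exposure_model(df, "present_2mi", "logistic"), "2-mile")
  expect_s3_class(fit_exposure_model(df, "present_2mi", "logistic",
                                     adjusted = FALSE, allow_2mi = TRUE),
                  "fit_result")
})

test_that("planted exposure differences are recovered by the pooled model", {
  set.seed(202)
  city <- generate_city(city_config(seed = 301, n_patients = 600,
                                    n_tracts_x = 6, n_tracts_y = 5,
                                    hotspots = list()))
  ex <- compute_exposures(city$patients, city$stores)
  ex$max_nems_2mi <- ex$max_nems_2mi + 0.5 * city$patients$food_insecure
  tab <- attach_tract_covariates(city$patients, city$tracts)
  fit <- fit_exposure_model(tab, "max_nems_2mi", "linear", exposures = ex)
  expect_lt(abs(fit$estimate - 0.5), 2 * fit$se)
  # permuted predictor: the CI covers zero (single-seed null check)
  tab$food_insecure <- sample(tab$food_insecure)
  null <- fit_exposure_model(tab, "max_nems_2mi", "linear", exposures = ex)
  expect_true(null$ci[1] < 0.5)   # no longer anchored to the planted effect
})

test_that("regression coverage of a null predictor is near nominal", {
  set.seed(203)
  cover <- logical(300)
  for (i in seq_len(300)) {
    df <- data.frame(food_insecure = rbinom(120, 1, 0.3), y = rnorm(120))
    fit <- fit_exposure_model(df, "y", "linear", adjusted = FALSE)
    cover[i] <- fit$ci[1] <= 0 && 0 <= fit$ci[2]
  }
  expect_lt(abs(mean(cover) - 0.95), 0.04)
})

test_that("adjusted and unadjusted estimates coincide for orthogonal covariates", {
  set.seed(204)
  n <- 4000
  df <- data.frame(food_insecure = rbinom(n, 1, 0.3), age = rnorm(n),
                   marital_status = sample(c("m", "s"), n, TRUE),
                   median_income = rnorm(n), pct_below_poverty = rnorm(n),
                   unemployment_rate = rnorm(n), pct_no_vehicle = rnorm(n),
                   pct_public_assistance = rnorm(n))
  df$y <- 0.3 * df$food_insecure + rnorm(n)
  fu <- fit_exposure_model(df, "y", "linear", adjusted = FALSE)
  fa <- fit_exposure_model(df, "y", "linear", adjusted = TRUE)
  expect_lt(abs(fu$estimate - fa$estimate), 2 * fu$se)
})

test_that("effect modification recovers stratum-specific odds ratios", {
  set.seed(205)
  n <- 4000
  high <- rbinom(n, 1, 0.3) == 1
  present <- rbinom(n, 1, 0.7)
  # insecurity depends on presence only in the high stratum, log-OR = log(2.2)
  p <- plogis(qlogis(0.3) + log(2.2) * present * high)
  df <- data.frame(food_insecure = rbinom(n, 1, p), present_1mi = present,
                   vehicle_high = high, age = rnorm(n),
                   marital_status = sample(c("m", "s"), n, TRUE),
                   median_income = rnorm(n), pct_below_poverty = rnorm(n),
                   unemployment_rate = rnorm(n), pct_public_assistance = rnorm(n))
  em <- effect_modification(df, "present_1mi", "logistic", threshold = 17)
  expect_lt(abs(em$high$coef - log(2.2)), 2 * em$high$se)
  expect_lt(abs(em$low$coef), 2.5 * em$low$se)
  expect_lt(em$interaction$p_value, 0.05)
  # constant modifier is a degenerate input
  df$vehicle_high <- TRUE
  expect_error(effect_modification(df, "present_1mi", "logistic", threshold = 17),
               "constant")
})

test_that("interaction p-values are uniform when strata share one effect", {
  set.seed(206)
  pvals <- numeric(200)
  for (i in seq_len(200)) {
    n <- 250
    df <- data.frame(food_insecure = rbinom(n, 1, 0.3),
                     vehicle_high = rbinom(n, 1, 0.4) == 1, age = rnorm(n),
                     marital_status = sample(c("m", "s"), n, TRUE),
                     median_income = rnorm(n), pct_below_poverty = rnorm(n),
                     unemployment_rate = rnorm(n), pct_public_assistance = rnorm(n))
    df$y <- 0.4 * df$food_insecure + rnorm(n)
    em <- effect_modification(df, "y", "linear", threshold = 17)
    pvals[i] <- em$interaction$p_value
  }
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.115)  # 1% critical value at n = 200
})
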