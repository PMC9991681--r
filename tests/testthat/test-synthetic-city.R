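test_that("identical configs generate identical cities", {
  c1 <- generate_city(small_city_config(seed = 9))
  c2 <- generate_city(small_city_config(seed = 9))
  expect_identical(c1, c2)
  c3 <- generate_city(small_city_config(seed = 10))
  expect_false(identical(c1$patients, c3$patients))
})

test_that("configuration invariants are enforced", {
  expect_error(city_config(baseline_prevalence = 1.5), "probability")
  expect_error(city_config(store_score_min = 40, store_score_max = 30), "infeasible")
  expect_error(city_config(bounds = c(0, 0, 0, 10)), "degenerate")
  expect_error(city_config(n_patients = 0), "at least one")
  expect_error(city_config(missing_rates = c(bmi = 2)), "probabilities")
})

test_that("cohort structure matches the configured study conditions", {
  city <- generate_city(city_config(seed = 5))
  expect_equal(nrow(city$patients), 1100)
  expect_equal(nrow(city$stores), 75)
  b <- city$config$bounds
  expect_true(all(city$patients$x >= b["xmin"] & city$patients$x <= b["xmax"]))
  expect_true(all(city$patients$food_insecure %in% c(0, 1)))
  expect_true(all(city$stores$total >= 16 & city$stores$total <= 35))
  expect_true(abs(mean(city$stores$total) - 27) < 2)
  expect_true(abs(sd(city$stores$total) - 5) < 1.5)
  # store scores are exactly what the scorer derives from the items
  expect_identical(city$stores$total, score_stores(city$stores)$total)
  # every patient and store maps to an existing tract
  expect_true(all(city$patients$tract_id %in% city$tracts$tract_id))
  expect_true(all(city$stores$tract_id %in% city$tracts$tract_id))
  expect_true(all(city$tracts$pct_no_vehicle >= 0 & city$tracts$pct_no_vehicle <= 100))
})

test_that("prevalence is near target and homogeneous without hotspots or effects", {
  prevs <- pvals <- numeric(25)
  for (i in seq_len(25)) {
    city <- generate_city(city_config(
      seed = 100 + i, hotspots = list(), covariate_effects = numeric(0),
      n_tracts_x = 4, n_tracts_y = 4))
    prevs[i] <- mean(city$patients$food_insecure)
    pvals[i] <- chisq.test(table(city$patients$tract_id,
                                 city$patients$food_insecure))$p.value
  }
  expect_lt(abs(mean(prevs) - 0.31), 0.02)
  # homogeneity test rejects at roughly its nominal 5% rate
  expect_lte(mean(pvals < 0.05), 0.2)
  # with hotspots, insecurity correlates with the hotspot intensity field
  hot <- generate_city(city_config(seed = 1))
  eta <- sapply(seq_len(nrow(hot$patients)), function(i) {
    sum(sapply(hot$config$hotspots, function(hs) {
      d2 <- (hot$patients$x[i] - hs$center[1])^2 +
        (hot$patients$y[i] - hs$center[2])^2
      hs$bump * exp(-d2 / (2 * hs$radius^2))
    }))
  })
  expect_lt(cor.test(eta, hot$patients$food_insecure)$p.value, 0.05)
})

test_that("tract covariates track hotspot intensity in the expected directions", {
  city <- generate_city(city_config(seed = 3))
  h <- sapply(seq_len(nrow(city$tracts)), function(i) {
    sum(sapply(city$config$hotspots, function(hs) {
      d2 <- (city$tracts$center_x[i] - hs$center[1])^2 +
        (city$tracts$center_y[i] - hs$center[2])^2
      hs$bump * exp(-d2 / (2 * hs$radius^2))
    }))
  })
  expect_lt(cor(h, city$tracts$median_income), 0)
  expect_gt(cor(h, city$tracts$pct_below_poverty), 0)
  expect_gt(cor(h, city$tracts$pct_no_vehicle), 0)
})

test_that("missingness injection hits its rates and protects the outcome", {
  city <- generate_city(small_city_config(seed = 2, n_patients = 1000))
  # zero rates: identity
  expect_identical(inject_missingness(city$patients, c(bmi = 0)), city$patients)
  # MCAR rate 0.5: masked count within binomial range
  m1 <- inject_missingness(city$patients, c(marital_status = 0.5), "MCAR", seed = 4)
  expect_true(sum(is.na(m1$marital_status)) >= 450 &&
                sum(is.na(m1$marital_status)) <= 550)
  expect_identical(m1$food_insecure, city$patients$food_insecure)
  # MAR-on-age: missingness indicator positively correlates with age
  m2 <- inject_missingness(city$patients, c(bmi = 0.3), "MAR-on-age", seed = 5)
  expect_gt(cor(is.na(m2$bmi), city$patients$age), 0)
  expect_lt(abs(mean(is.na(m2$bmi)) - 0.3), 0.06)
  # the outcome and coordinates can never be masked
  expect_error(inject_missingness(city$patients, c(food_insecure = 0.1)), "outcome")
  expect_error(inject_missingness(city$patients, c(x = 0.1)), "outcome|coordinates")
})

test_that("writers emit readable CSV, YAML and GeoJSON", {
  city <- generate_city(small_city_config(seed = 6, n_patients = 40, n_stores = 8))
  dir <- withr::local_tempdir()
  write_city(city, dir)
  pat <- read.csv(file.path(dir, "patients.csv"))
  expect_equal(nrow(pat), 40)
  expect_true(all(c("id", "x", "y", "food_insecure", "tract_id") %in% names(pat)))
  cfg <- yaml::read_yaml(file.path(dir, "city_config.yaml"))
  expect_equal(cfg$n_patients, 40)
  gj <- file.path(dir, "stores.geojson")
  points_to_geojson(city$stores, gj)
  parsed <- jsonlite::read_json(gj)
  expect_equal(parsed$type, "FeatureCollection")
  expect_length(parsed$features, 8)
  expect_equal(parsed$features[[1]]$geometry$type, "Point")
})
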