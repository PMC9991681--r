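risk_bounds <- c(xmin = 0, ymin = 0, xmax = 10, ymax = 10)

test_that("the pilot density is a normalized Gaussian KDE", {
  cfg <- risk_config(risk_bounds, grid_nx = 32, grid_ny = 32)
  set.seed(31)
  pts <- data.frame(x = rnorm(200, 5, 1), y = rnorm(200, 5, 1))
  pd <- pilot_density(pts, 0.8, cfg)
  expect_true(all(pd$z >= 0))
  expect_equal(sum(pd$z) * pd$cell_area, 1, tolerance = 1e-9)
  # unimodal cloud: argmax near the centroid
  am <- which(pd$z == max(pd$z), arr.ind = TRUE)[1, ]
  expect_lt(abs(pd$x[am[1]] - mean(pts$x)), 0.5)
  expect_lt(abs(pd$y[am[2]] - mean(pts$y)), 0.5)
  # unnormalized values match the closed-form Gaussian mixture
  tri <- data.frame(x = c(2, 5, 8, 1, 9, 5, 3, 6, 4, 7),
                    y = c(2, 5, 8, 9, 1, 2, 7, 4, 5, 6))
  raw <- pilot_density(tri, 1, cfg, normalize = FALSE)
  i <- 10; j <- 20
  expected <- mean(exp(-((raw$x[i] - tri$x)^2 + (raw$y[j] - tri$y)^2) / 2) / (2 * pi))
  expect_equal(raw$z[i, j], expected, tolerance = 1e-12)
  expect_error(pilot_density(tri, 0, cfg), "positive")
  expect_error(pilot_density(tri[1:3, ], 1, cfg), "at least 10")
})

test_that("Abramson bandwidths follow the inverse-square-root rescaling", {
  # uniform pilot: every bandwidth equals h0
  expect_equal(adaptive_bandwidths(rep(0.3, 8), 0.5), rep(0.5, 8))
  # pilot values 1 and 4: bandwidth ratio 2
  h <- adaptive_bandwidths(c(1, 4), 0.5)
  expect_equal(h[1] / h[2], 2)
  # geometric mean of h/h0 over the pooled points is one by construction
  set.seed(32)
  pv <- rexp(50) + 0.01
  h2 <- adaptive_bandwidths(pv, 0.7, pv)
  expect_equal(exp(mean(log(h2 / 0.7))), 1, tolerance = 1e-10)
  expect_error(adaptive_bandwidths(c(1, 0), 0.5), "larger pilot")
})

test_that("risk surface configuration is validated", {
  expect_error(risk_config(risk_bounds, grid_nx = 16), "32")
  expect_error(risk_config(risk_bounds, n_permutations = 50), "99")
  expect_error(risk_config(risk_bounds, alpha = 1.2), "alpha")
})

test_that("identical case and control point sets give exactly zero log risk", {
  cfg <- risk_config(risk_bounds, grid_nx = 32, grid_ny = 32)
  set.seed(33)
  pts <- data.frame(x = runif(60, 0, 10), y = runif(60, 0, 10))
  s <- log_relative_risk(pts, pts, cfg)
  expect_true(all(s$rho == 0))
  expect_equal(sum(s$f) * s$cell_area, 1, tolerance = 1e-9)
  expect_equal(sum(s$g) * s$cell_area, 1, tolerance = 1e-9)
})

test_that("swapping case and control labels negates the surface", {
  cfg <- risk_config(risk_bounds, grid_nx = 32, grid_ny = 32)
  set.seed(34)
  a <- data.frame(x = runif(80, 0, 10), y = runif(80, 0, 10))
  b <- data.frame(x = rnorm(70, 6, 2), y = rnorm(70, 5, 2))
  b <- b[b$x > 0 & b$x < 10 & b$y > 0 & b$y < 10, ]
  s1 <- log_relative_risk(a, b, cfg)
  s2 <- log_relative_risk(b, a, cfg)
  expect_equal(s2$rho, -s1$rho, tolerance = 1e-9)
  # densities are invariant to point ordering
  perm <- sample(nrow(a))
  s3 <- log_relative_risk(a[perm, ], b, cfg)
  expect_equal(s3$rho, s1$rho, tolerance = 1e-9)
})

test_that("the null surface is flat and a planted hotspot is recovered", {
  cfg <- risk_config(risk_bounds, grid_nx = 32, grid_ny = 32)
  flat <- sapply(1:5, function(seed) {
    set.seed(seed)
    cases <- data.frame(x = runif(300, 0, 10), y = runif(300, 0, 10))
    controls <- data.frame(x = runif(300, 0, 10), y = runif(300, 0, 10))
    mean(abs(log_relative_risk(cases, controls, cfg)$rho))
  })
  expect_lt(mean(flat), 0.25)
  set.seed(35)
  cases <- data.frame(x = runif(300, 0, 10), y = runif(300, 0, 10))
  controls <- data.frame(x = runif(300, 0, 10), y = runif(300, 0, 10))
  # cases oversampled 3x inside a disc: argmax falls inside in most reps
  hits <- 0
  for (r in 1:100) {
    set.seed(400 + r)
    cs <- sample_disc_bump(300, risk_bounds, c(5, 5), 1.5, rr = 3)
    ct <- data.frame(x = runif(300, 0, 10), y = runif(300, 0, 10))
    s <- log_relative_risk(cs, ct, cfg)
    am <- which(s$rho == max(s$rho), arr.ind = TRUE)[1, ]
    d <- sqrt((s$x[am[1]] - 5)^2 + (s$y[am[2]] - 5)^2)
    hits <- hits + (d <= 1.5)
  }
  expect_gte(hits / 100, 0.85)
  expect_error(log_relative_risk(cases[1:5, ], controls, cfg), "at least 10")
  far <- data.frame(x = rep(50, 20), y = rep(50, 20))
  expect_error(log_relative_risk(far, controls, cfg), "outside")
})

test_that("permutation p-values are reproducible and contours track alpha", {
  cfg <- risk_config(risk_bounds, grid_nx = 32, grid_ny = 32,
                     n_permutations = 99, seed = 12)
  set.seed(36)
  cs <- sample_disc_bump(250, risk_bounds, c(5, 5), 1.5, rr = 3)
  ct <- data.frame(x = runif(250, 0, 10), y = runif(250, 0, 10))
  s <- log_relative_risk(cs, ct, cfg)
  t1 <- tolerance_contours(s)
  t2 <- tolerance_contours(s)
  expect_identical(t1$p, t2$p)           # fixed seed, identical draw
  expect_true(all(t1$p >= 1 / 100 & t1$p <= 1))
  # significant cells are exactly the sub-alpha, unfloored cells
  expect_identical(t1$significant, t1$p < 0.05 & !s$floored)
  # hotspot detected: some significant cell inside the true disc
  sig <- which(t1$significant, arr.ind = TRUE)
  d <- sqrt((s$x[sig[, 1]] - 5)^2 + (s$y[sig[, 2]] - 5)^2)
  expect_true(any(d <= 1.5))
  expect_gt(length(t1$contours), 0)
  # significance regions shrink as alpha drops, vanishing in the limit
  tiny <- tolerance_contours(s, alpha = 1 / 100)
  expect_true(all(which(tiny$significant) %in% which(t1$significant)))
  expect_equal(sum(tolerance_contours(s, alpha = 1e-6)$significant), 0)
  expect_error(tolerance_contours(s, n_permutations = 9), "99")
})

test_that("fixed-bandwidth density agrees with an independent KDE implementation", {
  skip_if_not_installed("MASS")
  set.seed(37)
  pts <- data.frame(x = runif(150, 2, 8), y = runif(150, 2, 8))
  cfg <- risk_config(risk_bounds, grid_nx = 40, grid_ny = 40)
  h <- 0.9
  pd <- pilot_density(pts, h, cfg, normalize = FALSE)
  # MASS::kde2d parameterizes bandwidth as full width ~ 4*sd of the kernel
  kk <- MASS::kde2d(pts$x, pts$y, h = 4 * h, n = 40,
                    lims = c(0.125, 9.875, 0.125, 9.875))
  expect_equal(max(abs(pd$z - kk$z)), 0, tolerance = 1e-6)
})
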