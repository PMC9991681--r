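# Shared fixture builders; everything is generated in code at test time.

# Small, fast city for structural tests.
small_city_config <- function(seed = 1, n_patients = 250, n_stores = 30, ...) {
  city_config(seed = seed, n_patients = n_patients, n_stores = n_stores,
              n_tracts_x = 6, n_tracts_y = 5, ...)
}

# Point pattern with a multiplicative risk bump inside a disc: density is
# proportional to `rr` inside the disc and 1 outside (rejection sampling).
sample_disc_bump <- function(n, bounds, center, radius, rr = 3) {
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- 2 * (n - nrow(out)) + 20
    x <- runif(m, bounds["xmin"], bounds["xmax"])
    y <- runif(m, bounds["ymin"], bounds["ymax"])
    inside <- (x - center[1])^2 + (y - center[2])^2 <= radius^2
    keep <- runif(m) < ifelse(inside, 1, 1 / rr)
    out <- rbind(out, cbind(x[keep], y[keep]))
  }
  data.frame(x = out[seq_len(n), 1], y = out[seq_len(n), 2])
}

# Fine-grid trapezoid integration of an access curve, the independent oracle
# for the exact step integral. The grid must be fine relative to the curve's
# jumps: the trapezoid discretization error is bounded by delta/2 times the
# total jump height (at most the maximum score), so delta = 1e-5 keeps the
# oracle's own error below 3e-4 for NEMS-scale curves.
trapezoid_auc <- function(curve, horizon, delta = 1e-5) {
  grid <- seq(0, horizon, by = delta)
  k <- findInterval(grid, curve$breakpoints)
  v <- c(0, curve$values)[k + 1]
  sum((v[-1] + v[-length(v)]) / 2) * delta
}

# Long-format table from a 2x2 count matrix (rows: predictor, cols: outcome).
expand_2x2 <- function(a, b, c, d) {
  data.frame(
    exposure = rep(c(1, 1, 0, 0), times = c(a, b, c, d)),
    outcome = rep(c(1, 0, 1, 0), times = c(a, b, c, d)))
}
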