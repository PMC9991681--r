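#' Spatial risk configuration
#'
#' Settings for the kernel relative-risk surface: evaluation grid, pilot
#' bandwidth rule, adaptive smoothing, permutation count and significance
#' level. Densities use a bivariate Gaussian kernel; each estimated density
#' is renormalised to integrate to one over the study window.
#'
#' @param bounds named `c(xmin, ymin, xmax, ymax)` study window (miles).
#' @param grid_nx,grid_ny evaluation grid dimensions (>= 32 each).
#' @param pilot `"silverman_pooled"` (Silverman's rule on the pooled sample,
#'   per-axis, geometric-mean combined) or a fixed numeric bandwidth.
#' @param h0 global bandwidth for the adaptive rescaling; `NULL` uses the
#'   pilot bandwidth.
#' @param adaptive use Abramson adaptive bandwidths with the shared pooled
#'   pilot (the symmetric contract)? Fixed-bandwidth estimation otherwise.
#' @param edge_correction reserved flag; the implementation renormalises mass
#'   over the window, and no per-point boundary kernel correction is applied.
#' @param n_permutations label permutations for tolerance contours (>= 99).
#' @param alpha significance level in (0, 1).
#' @param floor_factor density floor, as a fraction of the larger density
#'   maximum, applied before taking logs.
#' @param seed integer seed for the permutation draw.
#' @return a `risk_config` list.
#' @export
risk_config <- function(bounds, grid_nx = 64L, grid_ny = 64L,
                        pilot = "silverman_pooled", h0 = NULL, adaptive = TRUE,
                        edge_correction = FALSE, n_permutations = 999L,
                        alpha = 0.05, floor_factor = 1e-12, seed = 1L) {
  stopifnot(length(bounds) == 4)
  names(bounds) <- c("xmin", "ymin", "xmax", "ymax")
  if (grid_nx < 32 || grid_ny < 32) stop("grid must be at least 32 x 32", call. = FALSE)
  if (n_permutations < 99) stop("need at least 99 permutations", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  structure(list(bounds = bounds, grid_nx = as.integer(grid_nx),
                 grid_ny = as.integer(grid_ny), pilot = pilot, h0 = h0,
                 adaptive = isTRUE(adaptive), edge_correction = isTRUE(edge_correction),
                 n_permutations = as.integer(n_permutations), alpha = alpha,
                 floor_factor = floor_factor, seed = as.integer(seed)),
            class = "risk_config")
}

# Gaussian mixture value of the KDE at arbitrary evaluation points.
# h is scalar or per-data-point vector. Returns mean of kernels (mass 1/n each).
.kde_at <- function(points, eval_x, eval_y, h) {
  n <- nrow(points)
  h <- rep_len(h, n)
  out <- numeric(length(eval_x))
  for (j in seq_len(n)) {
    d2 <- (eval_x - points$x[j])^2 + (eval_y - points$y[j])^2
    out <- out + exp(-d2 / (2 * h[j]^2)) / (2 * pi * h[j]^2)
  }
  out / n
}

# Separable kernel factor matrices for fast grid evaluation: the density on
# the grid restricted to data columns S is (A[, S] %*% t(By[, S])) / |S| with
# A = Bx * coef. Per-point bandwidths supported.
.kernel_factors <- function(points, gx, gy, h) {
  n <- nrow(points)
  h <- rep_len(h, n)
  bx <- exp(-outer(gx, points$x, "-")^2 / (2 * rep(h^2, each = length(gx))))
  by <- exp(-outer(gy, points$y, "-")^2 / (2 * rep(h^2, each = length(gy))))
  coef <- 1 / (2 * pi * h^2)
  list(ax = sweep(bx, 2, coef, "*"), by = by)
}

.grid_density <- function(kf, idx, cell_area, normalize = TRUE) {
  z <- (kf$ax[, idx, drop = FALSE] %*% t(kf$by[, idx, drop = FALSE])) / length(idx)
  if (normalize) z <- z / (sum(z) * cell_area)
  z
}

#' Silverman pilot bandwidth
#'
#' Bivariate normal-reference rule: per axis,
#' `h_d = min(sd, IQR/1.34) * n^(-1/6)` (the d = 2 normal-scale bandwidth),
#' combined by geometric mean into one scalar.
#'
#' @param points data frame with `x`, `y`.
#' @return scalar bandwidth in miles.
#' @export
silverman_bandwidth <- function(points) {
  n <- nrow(points)
  one <- function(v) min(stats::sd(v), stats::IQR(v) / 1.34) * n^(-1 / 6)
  sqrt(one(points$x) * one(points$y))
}

#' Fixed-bandwidth pilot density
#'
#' Bivariate Gaussian kernel density on the evaluation grid, renormalised to
#' unit mass over the window.
#'
#' @param points data frame with `x`, `y` (>= 10 rows).
#' @param bandwidth positive scalar bandwidth (miles).
#' @param config a [risk_config()] providing window and grid.
#' @param normalize renormalise over the window (default)?
#' @return list with grid vectors `x`, `y`, density matrix `z`
#'   (`grid_nx x grid_ny`), and `cell_area`.
#' @export
pilot_density <- function(points, bandwidth, config, normalize = TRUE) {
  if (nrow(points) < 10) stop("need at least 10 points", call. = FALSE)
  if (!is.numeric(bandwidth) || bandwidth <= 0) stop("bandwidth must be positive", call. = FALSE)
  g <- .risk_grid(config)
  kf <- .kernel_factors(points, g$x, g$y, bandwidth)
  z <- .grid_density(kf, seq_len(nrow(points)), g$cell_area, normalize)
  list(x = g$x, y = g$y, z = z, cell_area = g$cell_area, bandwidth = bandwidth)
}

.risk_grid <- function(config) {
  b <- config$bounds
  dx <- (b["xmax"] - b["xmin"]) / config$grid_nx
  dy <- (b["ymax"] - b["ymin"]) / config$grid_ny
  list(x = unname(b["xmin"] + (seq_len(config$grid_nx) - 0.5) * dx),
       y = unname(b["ymin"] + (seq_len(config$grid_ny) - 0.5) * dy),
       cell_area = unname(dx * dy))
}

#' Abramson adaptive bandwidths
#'
#' Rescales a global bandwidth by the inverse square root of the pilot
#' density: `h_i = h0 * pilot_i^(-1/2) / gamma`, with `gamma` the geometric
#' mean of `pilot_j^(-1/2)` over the pooled sample, so that the geometric
#' mean of `h_i / h0` over the pooled points is exactly one. Cases and
#' controls must share the same pooled pilot and the same `gamma` (the
#' "symmetric" contract), which stabilises the density ratio.
#'
#' @param pilot_values pilot density at the points being rescaled.
#' @param h0 global bandwidth.
#' @param pooled_pilot_values pilot density at the pooled case+control points
#'   (defaults to `pilot_values`).
#' @return per-point bandwidth vector.
#' @export
adaptive_bandwidths <- function(pilot_values, h0, pooled_pilot_values = pilot_values) {
  if (any(pilot_values <= 0) || any(pooled_pilot_values <= 0)) {
    stop("pilot density is zero at a data point; use a larger pilot bandwidth",
         call. = FALSE)
  }
  gamma <- exp(mean(-0.5 * log(pooled_pilot_values)))
  h0 * pilot_values^(-0.5) / gamma
}

#' Spatial log relative-risk surface
#'
#' Estimates the log ratio of the case spatial density to the control spatial
#' density on a grid, using the symmetric adaptive method: one pilot density
#' is fitted to the pooled case+control points, Abramson bandwidths are
#' derived from it with a shared normalisation, and both densities are built
#' with those bandwidths and renormalised over the window. A density floor
#' (a tiny fraction of the larger density's maximum, applied to both
#' densities) keeps the log ratio finite; floored cells are flagged and
#' excluded from contouring.
#'
#' @param cases,controls data frames with `x`, `y` (>= 10 rows each, inside
#'   the window).
#' @param config a [risk_config()].
#' @return a `risk_surface`: grid vectors `x`, `y`; matrices `f` (cases), `g`
#'   (controls), `rho` (log relative risk), `floored` (logical); bandwidth
#'   metadata; and the inputs needed by [tolerance_contours()].
#' @export
log_relative_risk <- function(cases, controls, config) {
  stopifnot(inherits(config, "risk_config"))
  b <- config$bounds
  inside <- function(p) p$x >= b["xmin"] & p$x <= b["xmax"] &
    p$y >= b["ymin"] & p$y <= b["ymax"]
  if (!any(inside(cases))) stop("all cases fall outside the window", call. = FALSE)
  if (nrow(cases) < 10 || nrow(controls) < 10) {
    stop("need at least 10 cases and 10 controls", call. = FALSE)
  }
  pooled <- rbind(cases[, c("x", "y")], controls[, c("x", "y")])
  n_case <- nrow(cases)
  hp <- if (identical(config$pilot, "silverman_pooled")) {
    silverman_bandwidth(pooled)
  } else {
    as.numeric(config$pilot)
  }
  h0 <- if (is.null(config$h0)) hp else config$h0
  h <- if (config$adaptive) {
    pv <- .kde_at(pooled, pooled$x, pooled$y, hp)
    adaptive_bandwidths(pv, h0, pv)
  } else {
    rep(h0, nrow(pooled))
  }
  g <- .risk_grid(config)
  kf <- .kernel_factors(pooled, g$x, g$y, h)
  case_idx <- seq_len(n_case)
  f <- .grid_density(kf, case_idx, g$cell_area)
  gg <- .grid_density(kf, setdiff(seq_len(nrow(pooled)), case_idx), g$cell_area)
  floor <- config$floor_factor * max(max(f), max(gg))
  floored <- f < floor | gg < floor
  rho <- log(pmax(f, floor)) - log(pmax(gg, floor))
  structure(list(x = g$x, y = g$y, f = f, g = gg, rho = rho,
                 floored = floored, cell_area = g$cell_area,
                 pilot_bandwidth = hp, h0 = h0, bandwidths = h,
                 n_case = n_case, n_control = nrow(controls),
                 kernel_factors = kf, config = config),
            class = "risk_surface")
}

#' @export
print.risk_surface <- function(x, ...) {
  cat(sprintf("<risk_surface> %d x %d grid, %d cases / %d controls, rho in [%.2f, %.2f]\n",
              length(x$x), length(x$y), x$n_case, x$n_control,
              min(x$rho), max(x$rho)))
  invisible(x)
}

#' Permutation tolerance contours
#'
#' Per-cell upper-tail p-values for elevated risk by random relabelling of
#' case/control status: labels are permuted, both densities and the log
#' relative risk are recomputed per permutation (bandwidths are unchanged --
#' under the symmetric contract they depend only on the pooled points), and
#' each cell's p-value is `(1 + #{rho_perm >= rho_obs}) / (B + 1)`. Contours
#' trace the `p = alpha` level set by marching squares with sub-cell linear
#' interpolation (`grDevices::contourLines`). Floored cells are excluded.
#'
#' @param surface a [log_relative_risk()] surface.
#' @param n_permutations,alpha,seed override the surface config.
#' @return list with `p` (matrix), `significant` (logical matrix, `p < alpha`
#'   and not floored), `contours` (list of `x`/`y` polylines), `alpha`,
#'   `n_permutations`.
#' @export
tolerance_contours <- function(surface, n_permutations = NULL, alpha = NULL,
                               seed = NULL) {
  stopifnot(inherits(surface, "risk_surface"))
  cfg <- surface$config
  B <- if (is.null(n_permutations)) cfg$n_permutations else as.integer(n_permutations)
  alpha <- if (is.null(alpha)) cfg$alpha else alpha
  seed <- if (is.null(seed)) cfg$seed else seed
  if (B < 99) stop("need at least 99 permutations", call. = FALSE)
  n <- surface$n_case + surface$n_control
  kf <- surface$kernel_factors
  set.seed(seed)
  exceed <- matrix(0L, nrow(surface$rho), ncol(surface$rho))
  floor <- cfg$floor_factor
  for (b in seq_len(B)) {
    idx <- sample.int(n, surface$n_case)
    f <- .grid_density(kf, idx, surface$cell_area)
    g <- .grid_density(kf, setdiff(seq_len(n), idx), surface$cell_area)
    fl <- floor * max(max(f), max(g))
    rho_b <- log(pmax(f, fl)) - log(pmax(g, fl))
    exceed <- exceed + (rho_b >= surface$rho)
  }
  p <- (1 + exceed) / (B + 1)
  p_for_contour <- p
  p_for_contour[surface$floored] <- 1
  contours <- grDevices::contourLines(surface$x, surface$y, p_for_contour,
                                      levels = alpha)
  list(p = p, significant = p < alpha & !surface$floored,
       contours = contours, alpha = alpha, n_permutations = B)
}

#' Write a risk surface as CSV
#'
#' Long-format grid raster: `x`, `y`, `f`, `g`, `rho`, and `p` if contours
#' have been computed.
#'
#' @param surface a `risk_surface`.
#' @param path output CSV path.
#' @param contours optional [tolerance_contours()] result.
#' @return `path`, invisibly.
#' @export
write_risk_surface <- function(surface, path, contours = NULL) {
  grid <- expand.grid(x = surface$x, y = surface$y)
  out <- data.frame(grid, f = as.vector(surface$f), g = as.vector(surface$g),
                    rho = as.vector(surface$rho))
  if (!is.null(contours)) out$p <- as.vector(contours$p)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write tolerance contours as GeoJSON LineStrings
#'
#' @param contours a [tolerance_contours()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
contours_to_geojson <- function(contours, path) {
  features <- lapply(contours$contours, function(cl) {
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = mapply(c, cl$x, cl$y, SIMPLIFY = FALSE)),
         properties = list(level = cl$level))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Heatmap of a risk surface
#'
#' Writes a PNG heatmap of the log relative-risk surface with significance
#' contours overlaid, mirroring the usual display of such surfaces on the
#' log scale.
#'
#' @param surface a `risk_surface`.
#' @param contours optional [tolerance_contours()] result.
#' @param path output PNG path.
#' @param width,height device size in pixels.
#' @return `path`, invisibly (or `NULL` if no PNG device is available).
#' @export
plot_risk_surface <- function(surface, contours = NULL, path, width = 800,
                              height = 700) {
  ok <- tryCatch({
    grDevices::png(path, width = width, height = height)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) return(invisible(NULL))
  on.exit(grDevices::dev.off())
  pal <- grDevices::hcl.colors(64, "RdYlBu", rev = TRUE)
  graphics::image(surface$x, surface$y, surface$rho, col = pal,
                  xlab = "x (miles)", ylab = "y (miles)",
                  main = "Spatial log relative risk of food insecurity")
  if (!is.null(contours)) {
    for (cl in contours$contours) graphics::lines(cl$x, cl$y, lwd = 2)
  }
  invisible(path)
}
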