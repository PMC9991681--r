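#' Patient-store distance matrix
#'
#' Computes all pairwise patient-to-store distances in a common planar frame
#' (miles). The Euclidean metric is exact straight-line distance; the network
#' metric snaps each point to its nearest vertex of a weighted road graph and
#' returns shortest-path lengths.
#'
#' @param patients data frame with `x`, `y` (and optionally `id`).
#' @param stores data frame with `x`, `y` (and optionally `id`).
#' @param metric `"euclidean"` or `"network"`.
#' @param road_graph an `igraph` with vertex attributes `x`, `y` and edge
#'   attribute `weight`; required when `metric = "network"`.
#' @return numeric matrix `n_patients x n_stores` with a `metric` attribute.
#' @export
distance_matrix <- function(patients, stores,
                            metric = c("euclidean", "network"),
                            road_graph = NULL) {
  metric <- match.arg(metric)
  px <- patients$x; py <- patients$y
  sx <- stores$x; sy <- stores$y
  if (metric == "euclidean") {
    dm <- sqrt(outer(px, sx, "-")^2 + outer(py, sy, "-")^2)
  } else {
    if (is.null(road_graph)) stop("network metric requires road_graph", call. = FALSE)
    vx <- igraph::vertex_attr(road_graph, "x")
    vy <- igraph::vertex_attr(road_graph, "y")
    snap <- function(x, y) {
      vapply(seq_along(x), function(i) which.min((vx - x[i])^2 + (vy - y[i])^2),
             integer(1))
    }
    pv <- snap(px, py)
    sv <- snap(sx, sy)
    d <- igraph::distances(road_graph, v = unique(pv), to = unique(sv))
    dm <- d[match(pv, unique(pv)), match(sv, unique(sv)), drop = FALSE]
    if (any(!is.finite(dm))) {
      bad <- which(!is.finite(dm), arr.ind = TRUE)[1, ]
      stop(sprintf("no path between patient %d and store %d on road graph",
                   bad[1], bad[2]), call. = FALSE)
    }
  }
  dimnames(dm) <- list(patients$id, stores$id)
  attr(dm, "metric") <- metric
  dm
}

.radius_label <- function(r) paste0(sub("0+$", "", sub("\\.$", "", format(r))), "mi")

#' Radius exposure summaries
#'
#' For each patient and each radius, summarises the scores of stores lying in
#' the closed ball of that radius (distance <= r): the maximum ("healthiest")
#' score, the mean ("typical") score, and a presence flag. Patients with no
#' store in the ball get `NA` summaries (not zero) and `present = FALSE`.
#'
#' @param dm distance matrix from [distance_matrix()].
#' @param scores numeric store score vector (length = columns of `dm`).
#' @param radii positive sorted radii in miles.
#' @param prefix name stem for the summary columns (e.g. `"nems"`).
#' @return data frame with `present_<r>`, `max_<prefix>_<r>`,
#'   `mean_<prefix>_<r>` columns per radius.
#' @export
radius_summaries <- function(dm, scores, radii = c(0.5, 1, 2), prefix = "nems") {
  stopifnot(length(scores) == ncol(dm) || ncol(dm) == 0)
  if (any(radii <= 0) || is.unsorted(radii)) stop("radii must be positive and sorted", call. = FALSE)
  out <- data.frame(row.names = seq_len(nrow(dm)))
  for (r in radii) {
    lab <- .radius_label(r)
    inball <- dm <= r
    present <- if (ncol(dm)) rowSums(inball) > 0 else rep(FALSE, nrow(dm))
    mx <- mn <- rep(NA_real_, nrow(dm))
    idx <- which(present)
    for (i in idx) {
      s <- scores[inball[i, ]]
      mx[i] <- max(s)
      mn[i] <- mean(s)
    }
    out[[paste0("present_", lab)]] <- present
    out[[paste0("max_", prefix, "_", lab)]] <- mx
    out[[paste0("mean_", prefix, "_", lab)]] <- mn
  }
  out
}

#' Best-available-score access curve
#'
#' The step function giving, at each travel distance, the best (maximum)
#' store score reachable within that distance. Breakpoints are the sorted
#' distinct store distances; tied distances collapse to one breakpoint
#' carrying their maximum score; the curve is 0 before the first breakpoint.
#'
#' @param distances the patient's store distances (a row of the distance
#'   matrix).
#' @param scores matching store scores.
#' @return an `access_curve` list with `breakpoints` and `values`.
#' @export
access_curve <- function(distances, scores) {
  stopifnot(length(distances) == length(scores))
  ok <- is.finite(distances)
  distances <- distances[ok]; scores <- scores[ok]
  if (!length(distances)) {
    return(structure(list(breakpoints = numeric(0), values = numeric(0)),
                     class = "access_curve"))
  }
  bp <- sort(unique(distances))
  at <- vapply(bp, function(d) max(scores[distances == d]), numeric(1))
  structure(list(breakpoints = bp, values = cummax(at)), class = "access_curve")
}

#' Evaluate an access curve at a distance
#'
#' @param curve an [access_curve()].
#' @param r distance in miles.
#' @return curve value at `r` (0 before the first breakpoint).
#' @export
access_curve_value <- function(curve, r) {
  k <- findInterval(r, curve$breakpoints)
  if (k == 0) 0 else curve$values[k]
}

#' Accessibility AUC
#'
#' Integrates the access curve over `[0, horizon]`. Because the curve is
#' piecewise constant, the integral is computed exactly as a sum of step
#' areas -- the refinement limit of the trapezoid rule on this curve. Larger
#' values mean high-scoring stores are reachable at shorter distances.
#'
#' @param curve an [access_curve()].
#' @param horizon integration horizon in miles (> 0); stores at or beyond the
#'   horizon contribute nothing.
#' @return the AUC in score-miles.
#' @export
access_auc <- function(curve, horizon = 10) {
  if (!is.numeric(horizon) || length(horizon) != 1 || horizon <= 0) {
    stop("horizon must be a positive number of miles", call. = FALSE)
  }
  keep <- curve$breakpoints < horizon
  b <- curve$breakpoints[keep]
  v <- curve$values[keep]
  if (!length(b)) return(0)
  sum(v * diff(c(b, horizon)))
}

#' Per-patient exposure set
#'
#' Computes the full exposure table: presence flags and max/mean summaries of
#' total NEMS-S, availability, and price scores within each radius, plus the
#' accessibility AUC of the total-score access curve.
#'
#' @param patients patient table with `id`, `x`, `y`.
#' @param stores scored store table (from [score_stores()] or
#'   [generate_city()]).
#' @param radii radii in miles.
#' @param horizon AUC integration horizon in miles.
#' @param metric,road_graph passed to [distance_matrix()].
#' @return data frame, one row per patient, with `id` plus exposure columns.
#' @export
compute_exposures <- function(patients, stores, radii = c(0.5, 1, 2),
                              horizon = 10, metric = "euclidean",
                              road_graph = NULL) {
  stopifnot(all(c("total", "availability", "price") %in% names(stores)))
  dm <- distance_matrix(patients, stores, metric, road_graph)
  out <- cbind(
    data.frame(id = patients$id, stringsAsFactors = FALSE),
    radius_summaries(dm, stores$total, radii, "nems"))
  av <- radius_summaries(dm, stores$availability, radii, "avail")
  pr <- radius_summaries(dm, stores$price, radii, "price")
  out <- cbind(out,
               av[, grep("^(max|mean)_", names(av)), drop = FALSE],
               pr[, grep("^(max|mean)_", names(pr)), drop = FALSE])
  out$auc <- vapply(seq_len(nrow(dm)), function(i) {
    access_auc(access_curve(dm[i, ], stores$total), horizon)
  }, numeric(1))
  out
}

#' Rectangular-grid road graph
#'
#' Builds a lattice road graph over the bounding rectangle with the given
#' spacing; edge weights are Euclidean segment lengths. Useful as a sanity
#' fixture where network and straight-line distances coincide for collinear
#' points.
#'
#' @param bounds named `c(xmin, ymin, xmax, ymax)`.
#' @param spacing node spacing in miles.
#' @return an `igraph` with `x`, `y` vertex attributes and `weight` edges.
#' @export
grid_road_graph <- function(bounds, spacing = 1) {
  xs <- seq(bounds["xmin"], bounds["xmax"], by = spacing)
  ys <- seq(bounds["ymin"], bounds["ymax"], by = spacing)
  nodes <- expand.grid(x = xs, y = ys)
  nx <- length(xs)
  id <- function(ix, iy) (iy - 1L) * nx + ix
  from <- to <- integer(0)
  for (iy in seq_along(ys)) {
    for (ix in seq_along(xs)) {
      if (ix < nx) { from <- c(from, id(ix, iy)); to <- c(to, id(ix + 1L, iy)) }
      if (iy < length(ys)) { from <- c(from, id(ix, iy)); to <- c(to, id(ix, iy + 1L)) }
    }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::vertex_attr(g, "x") <- nodes$x
  igraph::vertex_attr(g, "y") <- nodes$y
  w <- sqrt((nodes$x[from] - nodes$x[to])^2 + (nodes$y[from] - nodes$y[to])^2)
  igraph::edge_attr(g, "weight") <- w
  g
}
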