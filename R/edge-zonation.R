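# Convex-hull tissue boundary, shortest centroid-to-edge distances, and
# per-type zonation summaries.

#' Build the tissue boundary as the convex hull of cell centroids
#'
#' Encloses all centroids of a section with the smallest convex polygon.
#' Hull vertices are a subset of the input centroids; collinear vertices
#' lying on a hull edge are dropped so the ring is strictly convex.
#'
#' @param cells cell table with `x_um`, `y_um` columns (or a 2-column
#'   numeric matrix of coordinates).
#' @return a `boundary_polygon`: numeric matrix of vertices (x, y), open
#'   ring, counterclockwise orientation.
#' @export
build_boundary <- function(cells) {
  xy <- if (is.matrix(cells)) cells else {
    check_cell_table(cells, need_volume = FALSE)
    cbind(cells$x_um, cells$y_um)
  }
  if (nrow(unique(xy)) < 3L)
    stop_input("need at least 3 distinct points to build a boundary")
  # chull returns hull indices in clockwise order; reverse for CCW
  h <- rev(grDevices::chull(xy[, 1], xy[, 2]))
  verts <- xy[h, , drop = FALSE]
  verts <- drop_collinear(verts)
  if (nrow(verts) < 3L)
    stop_input("degenerate geometry: all points are collinear")
  as_boundary_polygon(verts)
}

#' Construct a boundary polygon from explicit vertices
#'
#' @param verts numeric matrix/data.frame of (x, y) vertices, open or
#'   closed ring, any orientation (reoriented to counterclockwise).
#' @return a `boundary_polygon` object.
#' @export
as_boundary_polygon <- function(verts) {
  verts <- as.matrix(verts)[, 1:2, drop = FALSE]
  storage.mode(verts) <- "double"
  if (nrow(verts) > 1L && all(verts[1, ] == verts[nrow(verts), ]))
    verts <- verts[-nrow(verts), , drop = FALSE]
  if (nrow(verts) < 3L)
    stop_input("polygon needs at least 3 vertices, got %d", nrow(verts))
  if (signed_area(verts) < 0) verts <- verts[nrow(verts):1, , drop = FALSE]
  if (!is_convex(verts))
    stop_input("polygon vertices are not convex")
  colnames(verts) <- c("x", "y")
  structure(verts, class = c("boundary_polygon", "matrix", "array"))
}

signed_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

cross2 <- function(o, a, b) {
  (a[, 1] - o[, 1]) * (b[, 2] - o[, 2]) - (a[, 2] - o[, 2]) * (b[, 1] - o[, 1])
}

is_convex <- function(v, tol = 1e-9) {
  n <- nrow(v)
  i <- seq_len(n); j <- c(2:n, 1); k <- c(3:n, 1, 2)
  cr <- cross2(v[i, , drop = FALSE], v[j, , drop = FALSE], v[k, , drop = FALSE])
  scale <- max(abs(v)) ^ 2 + 1
  all(cr >= -tol * scale)
}

drop_collinear <- function(v, tol = 1e-9) {
  repeat {
    n <- nrow(v)
    if (n < 3L) return(v)
    i <- seq_len(n); j <- c(2:n, 1); k <- c(3:n, 1, 2)
    cr <- cross2(v[i, , drop = FALSE], v[j, , drop = FALSE],
                 v[k, , drop = FALSE])
    scale <- max(abs(v)) ^ 2 + 1
    flat <- which(abs(cr) <= tol * scale)
    if (!length(flat)) return(v)
    v <- v[-((flat[1] %% n) + 1L), , drop = FALSE]
  }
}

#' Shortest distance from points to a polygon boundary
#'
#' For each query point, the minimum Euclidean distance to any boundary
#' segment of the polygon ring. Points on the ring get distance 0; interior
#' and exterior points both get positive distances (exterior points trigger
#' a warning, since a hull built from the cells themselves never produces
#' them).
#'
#' @param points numeric matrix (n x 2) of query points, or a length-2
#'   vector for a single point.
#' @param polygon a `boundary_polygon`.
#' @return numeric vector of distances (micrometres), all >= 0.
#' @export
distance_to_edge <- function(points, polygon) {
  if (!inherits(polygon, "boundary_polygon"))
    polygon <- as_boundary_polygon(polygon)
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L)
  n <- nrow(polygon)
  j <- c(2:n, 1)
  ax <- polygon[, 1]; ay <- polygon[, 2]
  bx <- polygon[j, 1]; by <- polygon[j, 2]
  ex <- bx - ax; ey <- by - ay
  len2 <- ex^2 + ey^2
  d <- vapply(seq_len(nrow(points)), function(i) {
    px <- points[i, 1]; py <- points[i, 2]
    t <- pmin(1, pmax(0, ((px - ax) * ex + (py - ay) * ey) / len2))
    min(sqrt((ax + t * ex - px)^2 + (ay + t * ey - py)^2))
  }, numeric(1))
  if (any(d > 0 & !point_in_polygon(points, polygon)))
    warning("some query points lie outside the boundary polygon")
  d
}

#' Test whether points lie inside or on a convex polygon
#'
#' @param points n x 2 matrix of query points.
#' @param polygon a `boundary_polygon` (counterclockwise).
#' @param tol absolute tolerance on the edge orientation test.
#' @return logical vector.
#' @export
point_in_polygon <- function(points, polygon, tol = 1e-9) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  points <- as.matrix(points)
  n <- nrow(polygon)
  j <- c(2:n, 1)
  scale <- max(abs(polygon)) ^ 2 + 1
  inside <- rep(TRUE, nrow(points))
  for (e in seq_len(n)) {
    cr <- (polygon[j[e], 1] - polygon[e, 1]) * (points[, 2] - polygon[e, 2]) -
          (polygon[j[e], 2] - polygon[e, 2]) * (points[, 1] - polygon[e, 1])
    inside <- inside & (cr >= -tol * scale)
  }
  inside
}

#' Per-type zonation summary of edge distances
#'
#' Aggregates per-cell edge distances by cell type: mean, median, quartiles
#' and n, ranked by mean distance ascending (most peripheral types first).
#'
#' @param distances numeric vector of per-cell edge distances.
#' @param labels cell-type labels aligned with `distances`.
#' @return `data.frame` with one row per type: `cell_type`, `n`, `mean`,
#'   `median`, `q1`, `q3`, `rank` (1 = closest to the edge), sorted by rank.
#' @export
edge_summary <- function(distances, labels) {
  stopifnot(length(distances) == length(labels))
  if (anyNA(labels)) stop_input("missing cell-type labels")
  labels <- as.character(labels)
  keep <- !is.na(distances)
  if (!all(keep)) {
    warning(sprintf("%d cells with missing distances dropped", sum(!keep)))
    distances <- distances[keep]; labels <- labels[keep]
  }
  types <- sort(unique(labels))
  out <- do.call(rbind, lapply(types, function(tp) {
    d <- distances[labels == tp]
    data.frame(cell_type = tp, n = length(d), mean = mean(d),
               median = stats::median(d),
               q1 = unname(stats::quantile(d, 0.25)),
               q3 = unname(stats::quantile(d, 0.75)))
  }))
  out <- out[order(out$mean, out$cell_type), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
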