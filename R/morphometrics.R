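# Cell-shape morphometrics: 14 descriptors from polygon outlines --------
#
# Conventions: coordinates in um with x = anterior-posterior (AP) axis and
# y = dorsoventral (DV) axis; angles measured counterclockwise from +AP in
# [0, 180) degrees. Moments are polygon-exact (integrals over the polygon
# interior), not rasterized.

#' Construct a cell polygon
#'
#' @param vertices Two-column numeric matrix (or data.frame) of ordered
#'   `(x, y)` vertices in um; `x` is the AP axis, `y` the DV axis. At least
#'   3 vertices, simple (non-self-intersecting), nonzero area. Vertex
#'   order may be clockwise or counterclockwise.
#' @param cell_id,embryo_id,genotype,row_label Metadata; `row_label` is one
#'   of `"DME"` (leading edge), `"row2"`, `"other"`.
#' @return A `cell_polygon` object.
#' @export
cell_polygon <- function(vertices, cell_id = "cell_1", embryo_id = "embryo_1",
                         genotype = "wild_type",
                         row_label = c("other", "DME", "row2")) {
  row_label <- match.arg(row_label)
  v <- as.matrix(vertices)
  stop_if_not(is.numeric(v) && ncol(v) == 2L && nrow(v) >= 3L &&
                all(is.finite(v)),
              "`vertices` must be a finite 2-column matrix with >= 3 rows")
  # drop an explicitly closed last vertex
  if (nrow(v) > 3L && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  colnames(v) <- c("x", "y")
  a <- polygon_area_signed(v)
  stop_if_not(abs(a) > .Machine$double.eps, "polygon has zero area")
  stop_if_not(is_simple_polygon(v), "polygon is self-intersecting")
  if (a < 0) v <- v[nrow(v):1, , drop = FALSE]  # enforce CCW
  structure(list(cell_id = cell_id, embryo_id = embryo_id,
                 genotype = genotype, row_label = row_label, vertices = v),
            class = "cell_polygon")
}

#' @export
print.cell_polygon <- function(x, ...) {
  cat(sprintf("<cell_polygon> %s (%s, %s, %s): %d vertices, area %.2f um^2\n",
              x$cell_id, x$embryo_id, x$genotype, x$row_label,
              nrow(x$vertices), polygon_area_signed(x$vertices)))
  invisible(x)
}

# Shoelace signed area (CCW positive).
polygon_area_signed <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Proper segment-intersection test between all non-adjacent edge pairs.
# Touching at shared endpoints (adjacent edges) is allowed; collinear
# extra vertices on an edge are allowed.
is_simple_polygon <- function(v) {
  n <- nrow(v)
  p1 <- v; p2 <- v[c(2:n, 1), , drop = FALSE]
  seg_intersect <- function(a1, a2, b1, b2) {
    d1 <- cross2(b2 - b1, a1 - b1); d2 <- cross2(b2 - b1, a2 - b1)
    d3 <- cross2(a2 - a1, b1 - a1); d4 <- cross2(a2 - a1, b2 - a1)
    if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
        ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    on_seg <- function(p, q, r) {  # r collinear with pq: is r within box?
      min(p[1], q[1]) <= r[1] && r[1] <= max(p[1], q[1]) &&
        min(p[2], q[2]) <= r[2] && r[2] <= max(p[2], q[2])
    }
    (d1 == 0 && on_seg(b1, b2, a1)) || (d2 == 0 && on_seg(b1, b2, a2)) ||
      (d3 == 0 && on_seg(a1, a2, b1)) || (d4 == 0 && on_seg(a1, a2, b2))
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (they share a vertex)
      if (j == i + 1L || (i == 1L && j == n)) next
      if (seg_intersect(p1[i, ], p2[i, ], p1[j, ], p2[j, ])) return(FALSE)
    }
  }
  TRUE
}

cross2 <- function(u, w) u[1] * w[2] - u[2] * w[1]

# Polygon-exact centroid and second central moments (per unit area):
# returns list(area, centroid, cov) where cov is the 2x2 covariance of the
# uniform distribution over the polygon interior. Standard Green's-theorem
# vertex formulas; requires CCW orientation.
polygon_moments <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  cx <- sum((x + xn) * cr) / (6 * A)
  cy <- sum((y + yn) * cr) / (6 * A)
  # raw second moments about the origin
  Ixx <- sum((x^2 + x * xn + xn^2) * cr) / 12
  Iyy <- sum((y^2 + y * yn + yn^2) * cr) / 12
  Ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  cov <- matrix(c(Ixx / A - cx^2, Ixy / A - cx * cy,
                  Ixy / A - cx * cy, Iyy / A - cy^2), 2, 2)
  list(area = A, centroid = c(cx, cy), cov = cov)
}

# Rotating calipers on the convex hull: maximum Feret diameter (longest
# vertex-vertex distance) with its angle, and the minimum Feret diameter
# (smallest width across parallel supporting lines, attained perpendicular
# to a hull edge).
feret_diameters <- function(v) {
  h <- grDevices::chull(v)            # hull vertex indices (clockwise)
  hv <- v[h, , drop = FALSE]
  m <- nrow(hv)
  if (m == 1L) return(list(feret = 0, min_feret = 0, feret_angle = 0))
  if (m == 2L) {
    d <- hv[2, ] - hv[1, ]
    ang <- (atan2(d[2], d[1]) * 180 / pi) %% 180
    return(list(feret = sqrt(sum(d^2)), min_feret = 0, feret_angle = ang))
  }
  # max Feret: all hull vertex pairs (m is small for cell outlines)
  best <- c(0, 1L, 2L)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    d2 <- sum((hv[i, ] - hv[j, ])^2)
    if (d2 > best[1]) best <- c(d2, i, j)
  }
  d <- hv[best[3], ] - hv[best[2], ]
  feret <- sqrt(best[1])
  feret_angle <- (atan2(d[2], d[1]) * 180 / pi) %% 180
  # min Feret: for each hull edge, the max distance of hull vertices to it
  min_feret <- Inf
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    e <- hv[j, ] - hv[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    nrm <- c(-e[2], e[1]) / len
    width <- max(abs((sweep(hv, 2, hv[i, ]) %*% nrm)))
    if (width < min_feret) min_feret <- width
  }
  list(feret = feret, min_feret = min_feret, feret_angle = feret_angle)
}

#' Compute the 14 cell-shape descriptors of a polygon
#'
#' Descriptors follow the conventions of standard particle analysis on 2D
#' outlines, computed polygon-exactly (no rasterization):
#' \describe{
#'   \item{height, width}{axis-aligned bounding-box extents along the DV
#'     (y) and AP (x) axes, um.}
#'   \item{area}{shoelace area, um^2.}
#'   \item{perimeter}{edge-length sum, um.}
#'   \item{ellipse_major, ellipse_minor}{axes of the equivalent ellipse:
#'     the ellipse with the polygon's second central moments, uniformly
#'     rescaled so its area equals the polygon area, um.}
#'   \item{aspect_ratio}{major/minor (equals the square root of the
#'     covariance eigenvalue ratio).}
#'   \item{angle}{major-axis orientation, degrees CCW from +AP in
#'     \[0, 180).}
#'   \item{circularity}{`4 * pi * area / perimeter^2`.}
#'   \item{roundness}{`4 * area / (pi * ellipse_major^2)`.}
#'   \item{feret, min_feret, feret_angle}{maximum caliper diameter, its
#'     orientation, and the minimum caliper width (rotating calipers on
#'     the convex hull).}
#'   \item{solidity}{area / convex-hull area.}
#' }
#'
#' @param cell A [cell_polygon()] (or a bare 2-column vertex matrix).
#' @return A `shape_descriptors` object (named list of the 14 values, in
#'   the standard order; `as.data.frame()` gives a one-row table).
#' @examples
#' rect <- cell_polygon(cbind(c(0, 10, 10, 0), c(0, 0, 30, 30)))
#' unlist(shape_descriptors(rect))
#' @export
shape_descriptors <- function(cell) {
  if (!inherits(cell, "cell_polygon")) cell <- cell_polygon(cell)
  v <- cell$vertices
  mom <- polygon_moments(v)
  area <- mom$area
  per <- sum(sqrt(rowSums((v[c(2:nrow(v), 1), ] - v)^2)))
  width <- diff(range(v[, 1]))
  height <- diff(range(v[, 2]))

  eg <- eigen(mom$cov, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  # moment ellipse semi-axes 2*sqrt(lambda), rescaled to preserve area
  a0 <- 2 * sqrt(lam[1]); b0 <- 2 * sqrt(lam[2])
  s <- if (a0 > 0 && b0 > 0) sqrt(area / (pi * a0 * b0)) else 0
  major <- 2 * a0 * s; minor <- 2 * b0 * s
  aspect <- if (lam[2] > 0) sqrt(lam[1] / lam[2]) else Inf
  ax <- eg$vectors[, 1]
  angle <- (atan2(ax[2], ax[1]) * 180 / pi) %% 180

  fer <- feret_diameters(v)
  hull <- v[grDevices::chull(v), , drop = FALSE]
  hull_area <- abs(polygon_area_signed(hull))

  structure(list(
    height = height, width = width, area = area,
    aspect_ratio = aspect,
    circularity = 4 * pi * area / per^2,
    roundness = 4 * area / (pi * major^2),
    ellipse_major = major, ellipse_minor = minor,
    perimeter = per, angle = angle,
    feret = fer$feret, min_feret = fer$min_feret,
    feret_angle = fer$feret_angle,
    solidity = area / hull_area
  ), class = "shape_descriptors")
}

#' @export
print.shape_descriptors <- function(x, digits = 4, ...) {
  cat("<shape_descriptors>\n")
  print(round(unlist(unclass(x)), digits))
  invisible(x)
}

#' @export
as.data.frame.shape_descriptors <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' Names of the 14 shape descriptors, in standard order
#' @return Character vector of length 14.
#' @export
descriptor_names <- function() {
  c("height", "width", "area", "aspect_ratio", "circularity", "roundness",
    "ellipse_major", "ellipse_minor", "perimeter", "angle", "feret",
    "min_feret", "feret_angle", "solidity")
}

#' Build a morphometrics table from cell polygons
#'
#' One row per cell: the 14 descriptors in standard order, preceded by the
#' identity and group labels.
#'
#' @param cells List of [cell_polygon()] objects with unique `cell_id`s.
#' @return A data.frame with columns `cell_id`, `embryo_id`, `genotype`,
#'   `row_label`, then the 14 descriptor columns.
#' @export
build_table <- function(cells) {
  stop_if_not(length(cells) >= 1L, "`cells` must be a non-empty list")
  ids <- vapply(cells, function(cl) cl$cell_id, character(1))
  stop_if_not(!anyDuplicated(ids), "duplicate cell_id in `cells`")
  rows <- lapply(cells, function(cl) {
    d <- as.data.frame(shape_descriptors(cl))
    cbind(data.frame(cell_id = cl$cell_id, embryo_id = cl$embryo_id,
                     genotype = cl$genotype, row_label = cl$row_label,
                     stringsAsFactors = FALSE), d)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
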