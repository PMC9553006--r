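# Per-cell normalized fluorescence intensity and bootstrap test ---------

roi_mask <- function(roi, shape) {
  ny <- shape[1]; nx <- shape[2]
  if (is.numeric(roi) && is.null(dim(roi)) && length(roi) == 4L) {
    # rectangle: c(xmin, xmax, ymin, ymax), 1-based pixel indices, inclusive
    stop_if_not(all(roi == round(roi)), "rectangle ROI must be integer pixels")
    stop_if_not(roi[1] >= 1 && roi[2] <= nx && roi[3] >= 1 && roi[4] <= ny &&
                  roi[1] <= roi[2] && roi[3] <= roi[4],
                "ROI outside image bounds")
    m <- matrix(FALSE, ny, nx)
    m[roi[3]:roi[4], roi[1]:roi[2]] <- TRUE
    m
  } else if (is.matrix(roi) && ncol(roi) == 2L) {
    # polygon ROI in pixel coordinates (x, y)
    stop_if_not(all(roi[, 1] >= 0.5) && all(roi[, 1] <= nx + 0.5) &&
                  all(roi[, 2] >= 0.5) && all(roi[, 2] <= ny + 0.5),
                "ROI outside image bounds")
    gx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    gy <- matrix(seq_len(ny), ny, nx)
    inside <- matrix(FALSE, ny, nx)
    n <- nrow(roi); j <- n
    for (i in seq_len(n)) {
      cond <- (roi[i, 2] > gy) != (roi[j, 2] > gy)
      xint <- (roi[j, 1] - roi[i, 1]) * (gy - roi[i, 2]) /
        (roi[j, 2] - roi[i, 2]) + roi[i, 1]
      flip <- cond & (gx < xint)
      inside[flip] <- !inside[flip]
      j <- i
    }
    inside
  } else {
    stop("`roi` must be c(xmin, xmax, ymin, ymax) or a 2-column polygon matrix",
         call. = FALSE)
  }
}

#' Summed raw integrated density over an ROI and slice set
#'
#' The raw integrated density of a slice is the sum of all pixel values in
#' the region of interest; this returns the summation over the selected
#' slices.
#'
#' @param stack A `zstack_image` (from [render_junction_stack()] or
#'   [read_zstack()]).
#' @param roi Region of interest: a rectangle `c(xmin, xmax, ymin, ymax)`
#'   in 1-based pixel indices (inclusive), or a 2-column polygon matrix in
#'   pixel coordinates. `NULL` uses the full frame.
#' @param slices Slice indices to sum over (default: all; the study used
#'   nine selected slices per series).
#' @return Summed raw integrated density (counts).
#' @export
integrated_density <- function(stack, roi = NULL, slices = NULL) {
  d <- dim(stack$voxels)
  if (is.null(slices)) slices <- seq_len(d[1])
  stop_if_not(length(slices) >= 1L, "empty slice set")
  stop_if_not(all(slices == round(slices)) && all(slices >= 1) &&
                all(slices <= d[1]), "invalid slice indices")
  if (is.null(roi)) roi <- c(1, d[3], 1, d[2])
  m <- roi_mask(roi, d[2:3])
  sum(vapply(slices, function(s) sum(stack$voxels[s, , ][m]), numeric(1)))
}

#' Normalize summed integrated density by cell count
#'
#' @param total Summed raw integrated density, counts.
#' @param n_cells Number of cells covered by the ROI (>= 1).
#' @return Normalized intensity, counts/cell.
#' @export
normalize_per_cell <- function(total, n_cells) {
  check_number(total, "total", lower = 0)
  stop_if_not(is.numeric(n_cells) && length(n_cells) == 1L && n_cells >= 1,
              "`n_cells` must be >= 1")
  total / n_cells
}

#' Measure normalized per-cell intensity across embryos
#'
#' Applies [integrated_density()] and [normalize_per_cell()] to a list of
#' stacks. The study required the cropped ROI area to be the same for all
#' compared z-series; unequal ROI areas raise an error unless
#' `allow_unequal_roi = TRUE`.
#'
#' @param stacks List of `zstack_image` objects.
#' @param rois A single ROI (recycled) or list of ROIs, see
#'   [integrated_density()].
#' @param n_cells Integer vector: cells covered by each embryo's ROI.
#' @param slices Slice indices (default all).
#' @param allow_unequal_roi Permit differing ROI areas (default FALSE).
#' @return A data.frame: `embryo_id`, `genotype`, `raw_integrated_density_sum`,
#'   `n_cells`, `normalized`.
#' @export
measure_intensity <- function(stacks, rois = NULL, n_cells, slices = NULL,
                              allow_unequal_roi = FALSE) {
  stop_if_not(length(stacks) >= 1L, "`stacks` must be non-empty")
  stop_if_not(length(n_cells) == length(stacks),
              "`n_cells` must have one entry per stack")
  if (!is.list(rois) || is.matrix(rois)) rois <- rep(list(rois), length(stacks))
  stop_if_not(length(rois) == length(stacks),
              "`rois` must be a single ROI or one per stack")
  areas <- vapply(seq_along(stacks), function(i) {
    d <- dim(stacks[[i]]$voxels)
    roi <- rois[[i]]
    if (is.null(roi)) roi <- c(1, d[3], 1, d[2])
    sum(roi_mask(roi, d[2:3]))
  }, numeric(1))
  if (!allow_unequal_roi && length(unique(areas)) > 1L)
    stop("ROI areas differ across embryos; the comparison assumes equal ",
         "areas (set allow_unequal_roi = TRUE to override)", call. = FALSE)
  rows <- lapply(seq_along(stacks), function(i) {
    tot <- integrated_density(stacks[[i]], rois[[i]], slices)
    data.frame(embryo_id = stacks[[i]]$embryo_id,
               genotype = stacks[[i]]$genotype,
               raw_integrated_density_sum = tot,
               n_cells = n_cells[i],
               normalized = normalize_per_cell(tot, n_cells[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bootstrap test for a difference in group means
#'
#' Two-sample bootstrap test of `|mean(A) - mean(B)|`. The null
#' distribution is built by centering each group at its own mean, pooling
#' the centered values, and resampling (with replacement) groups of sizes
#' `nA` and `nB` from the pool `B` times; the p value is
#' `(1 + #\{T* >= T\}) / (B + 1)`.
#'
#' Centering a group at its mean shrinks its spread (n-1 degrees of
#' freedom in n residuals); by default the centered residuals are rescaled
#' by `sqrt(n / (n - 1))` so the pooled null sample keeps the groups'
#' variance. `center = "plain"` disables the rescale.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 3.
#' @param B Number of bootstrap resamples (default 10000).
#' @param seed Integer seed; the result is reproducible given
#'   `(group_a, group_b, B, seed)`.
#' @param center `"unbiased"` (variance-preserving rescale, default) or
#'   `"plain"` mean-centering.
#' @return A `bootstrap_test` object: `statistic_observed` (absolute mean
#'   difference), `mean_a`, `mean_b`, `B`, `p_value` (>= 1/(B+1)), `seed`.
#' @examples
#' set.seed(1)
#' bootstrap_compare(rnorm(8, 10), rnorm(8, 12), B = 1999, seed = 7)
#' @export
bootstrap_compare <- function(group_a, group_b, B = 10000, seed = 1,
                              center = c("unbiased", "plain")) {
  center <- match.arg(center)
  stop_if_not(is.numeric(group_a) && length(group_a) >= 3L,
              "`group_a` needs n >= 3")
  stop_if_not(is.numeric(group_b) && length(group_b) >= 3L,
              "`group_b` needs n >= 3")
  stop_if_not(B >= 1, "`B` must be >= 1")
  na <- length(group_a); nb <- length(group_b)
  t_obs <- abs(mean(group_a) - mean(group_b))
  fa <- if (center == "unbiased") sqrt(na / (na - 1)) else 1
  fb <- if (center == "unbiased") sqrt(nb / (nb - 1)) else 1
  pooled <- c((group_a - mean(group_a)) * fa,
              (group_b - mean(group_b)) * fb)
  t_null <- with_seed(seed, {
    vapply(seq_len(B), function(i) {
      abs(mean(sample(pooled, na, replace = TRUE)) -
            mean(sample(pooled, nb, replace = TRUE)))
    }, numeric(1))
  })
  p <- (1 + sum(t_null >= t_obs)) / (B + 1)
  structure(list(statistic_observed = t_obs,
                 mean_a = mean(group_a), mean_b = mean(group_b),
                 n_a = na, n_b = nb, B = as.integer(B),
                 p_value = p, seed = as.integer(seed)),
            class = "bootstrap_test")
}

#' @export
print.bootstrap_test <- function(x, ...) {
  cat("<bootstrap_test>\n")
  cat(sprintf("  group means: %.4g vs %.4g (n = %d, %d)\n",
              x$mean_a, x$mean_b, x$n_a, x$n_b))
  cat(sprintf("  |mean difference| = %.4g, B = %d, p = %.4g\n",
              x$statistic_observed, x$B, x$p_value))
  invisible(x)
}
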