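# Synthetic junctional fluorescence z-stacks ----------------------------

#' Parameters for the z-stack renderer
#'
#' @param image_shape Image size in pixels, `c(ny, nx)`.
#' @param n_slices Number of z slices (default 9, the number of slices
#'   analyzed per z-series).
#' @param pixel_size Lateral calibration, um/px.
#' @param z_step Axial step, um (default 0.3).
#' @param junction_intensity Ridge intensity added at cell boundaries,
#'   counts.
#' @param junction_width Ridge width, px.
#' @param background Background level, counts.
#' @param noise_model `"none"`, `"gaussian"` (additive, SD `noise_scale`)
#'   or `"poisson"` (counts drawn with the noiseless image as mean).
#' @param noise_scale SD of Gaussian noise, counts.
#' @param intensity_decay Per-slice multiplier on the junction intensity
#'   (slice s uses `junction_intensity * intensity_decay^(s-1)`). The
#'   "mutant" preset value 0.885 makes the slice-averaged junctional
#'   signal ~0.6x the wild-type level, emulating fading junctional
#'   E-cadherin; 1 (default) is the "wild-type" mode.
#' @return A `stack_params` object.
#' @seealso [render_junction_stack()]
#' @export
stack_params <- function(image_shape = c(200, 336), n_slices = 9,
                         pixel_size = 0.2, z_step = 0.3,
                         junction_intensity = 100, junction_width = 3,
                         background = 10,
                         noise_model = c("none", "gaussian", "poisson"),
                         noise_scale = 2, intensity_decay = 1) {
  noise_model <- match.arg(noise_model)
  stop_if_not(is.numeric(image_shape) && length(image_shape) == 2L &&
                all(image_shape >= 1), "`image_shape` must be (ny, nx) >= 1")
  stop_if_not(n_slices >= 1, "`n_slices` must be >= 1")
  check_number(pixel_size, "pixel_size", lower = .Machine$double.eps)
  check_number(z_step, "z_step", lower = .Machine$double.eps)
  check_number(junction_intensity, "junction_intensity", lower = 0)
  check_number(junction_width, "junction_width", lower = .Machine$double.eps)
  check_number(background, "background", lower = 0)
  check_number(noise_scale, "noise_scale", lower = 0)
  check_number(intensity_decay, "intensity_decay",
               lower = .Machine$double.eps, upper = 1)
  structure(list(image_shape = as.integer(image_shape),
                 n_slices = as.integer(n_slices),
                 pixel_size = pixel_size, z_step = z_step,
                 junction_intensity = junction_intensity,
                 junction_width = junction_width, background = background,
                 noise_model = noise_model, noise_scale = noise_scale,
                 intensity_decay = intensity_decay),
            class = "stack_params")
}

# Pixel-center coordinates (um) of column/row j: (j - 0.5) * pixel_size.
# Mask of pixels within `width_px / 2` pixels of any polygon edge.
junction_mask <- function(cells, shape, pixel_size, width_px) {
  ny <- shape[1]; nx <- shape[2]
  mask <- matrix(FALSE, ny, nx)
  half_w <- width_px * pixel_size / 2
  for (cl in cells) {
    v <- cl$vertices
    n <- nrow(v)
    for (e in seq_len(n)) {
      p1 <- v[e, ]; p2 <- v[if (e == n) 1L else e + 1L, ]
      xr <- range(p1[1], p2[1]) + c(-half_w, half_w)
      yr <- range(p1[2], p2[2]) + c(-half_w, half_w)
      jx <- max(1L, ceiling(xr[1] / pixel_size)):min(nx, ceiling(xr[2] / pixel_size + 0.5))
      jy <- max(1L, ceiling(yr[1] / pixel_size)):min(ny, ceiling(yr[2] / pixel_size + 0.5))
      if (!length(jx) || !length(jy)) next
      px <- (jx - 0.5) * pixel_size
      py <- (jy - 0.5) * pixel_size
      d <- p2 - p1
      len2 <- sum(d^2)
      gx <- matrix(px, length(jy), length(jx), byrow = TRUE)
      gy <- matrix(py, length(jy), length(jx))
      if (len2 == 0) {
        dist2 <- (gx - p1[1])^2 + (gy - p1[2])^2
      } else {
        tt <- pmin(pmax(((gx - p1[1]) * d[1] + (gy - p1[2]) * d[2]) / len2, 0), 1)
        dist2 <- (gx - (p1[1] + tt * d[1]))^2 + (gy - (p1[2] + tt * d[2]))^2
      }
      hit <- dist2 <= half_w^2
      mask[jy, jx] <- mask[jy, jx] | hit
    }
  }
  mask
}

# Even-odd point-in-polygon for a grid window (vectorized ray casting).
label_mask <- function(cells, shape, pixel_size) {
  ny <- shape[1]; nx <- shape[2]
  lab <- matrix(0L, ny, nx)
  for (ci in seq_along(cells)) {
    v <- cells[[ci]]$vertices
    xr <- range(v[, 1]); yr <- range(v[, 2])
    jx <- max(1L, ceiling(xr[1] / pixel_size)):min(nx, ceiling(xr[2] / pixel_size + 0.5))
    jy <- max(1L, ceiling(yr[1] / pixel_size)):min(ny, ceiling(yr[2] / pixel_size + 0.5))
    if (!length(jx) || !length(jy)) next
    px <- (jx - 0.5) * pixel_size
    py <- (jy - 0.5) * pixel_size
    gx <- matrix(px, length(jy), length(jx), byrow = TRUE)
    gy <- matrix(py, length(jy), length(jx))
    inside <- matrix(FALSE, length(jy), length(jx))
    n <- nrow(v)
    j <- n
    for (i in seq_len(n)) {
      cond <- (v[i, 2] > gy) != (v[j, 2] > gy)
      xint <- (v[j, 1] - v[i, 1]) * (gy - v[i, 2]) / (v[j, 2] - v[i, 2]) + v[i, 1]
      flip <- cond & (gx < xint)
      inside[flip] <- !inside[flip]
      j <- i
    }
    sub <- lab[jy, jx]
    sub[inside & sub == 0L] <- ci
    lab[jy, jx] <- sub
  }
  lab
}

#' Render a junctional-fluorescence z-stack from a cell mesh
#'
#' Each z slice draws the cell boundaries as ridges of width
#' `junction_width` px and intensity `junction_intensity *
#' intensity_decay^(s-1)` over a constant background, with optional
#' Gaussian or Poisson noise. A paired integer label image (ground-truth
#' cell segmentation, identical across slices) is returned.
#'
#' @param cells List of [cell_polygon()]s; must fit inside the image.
#' @param params A [stack_params()] object.
#' @param seed Integer seed (used when noise is on).
#' @param embryo_id,genotype Metadata stored on the stack.
#' @return A `zstack_image` object: list with `voxels` (z x y x x array,
#'   counts), `labels` (y x x integer matrix, 0 = background),
#'   `pixel_size`, `z_step`, `embryo_id`, `genotype`, `n_cells`.
#' @examples
#' ep <- simulate_epithelium(epithelium_params(n_rows = 2, n_cols = 3), seed = 1)
#' st <- render_junction_stack(ep$cells,
#'   stack_params(image_shape = c(140, 110), background = 0), seed = 1)
#' dim(st$voxels)
#' @export
render_junction_stack <- function(cells, params, seed = 1,
                                  embryo_id = "embryo_1",
                                  genotype = "wild_type") {
  stop_if_not(inherits(params, "stack_params"),
              "`params` must be a stack_params object")
  stop_if_not(length(cells) == 0 || all(vapply(cells, inherits, logical(1),
                                               "cell_polygon")),
              "`cells` must be cell_polygon objects")
  p <- params
  if (length(cells)) {
    allv <- do.call(rbind, lapply(cells, function(cl) cl$vertices))
    lim <- p$image_shape[c(2, 1)] * p$pixel_size
    stop_if_not(all(allv >= 0) && all(allv[, 1] <= lim[1]) &&
                  all(allv[, 2] <= lim[2]),
                "cells fall outside the image bounds")
  }
  mask <- if (length(cells))
    junction_mask(cells, p$image_shape, p$pixel_size, p$junction_width)
  else matrix(FALSE, p$image_shape[1], p$image_shape[2])
  labels <- if (length(cells)) label_mask(cells, p$image_shape, p$pixel_size)
  else matrix(0L, p$image_shape[1], p$image_shape[2])

  voxels <- with_seed(seed, {
    arr <- array(0, dim = c(p$n_slices, p$image_shape))
    for (s in seq_len(p$n_slices)) {
      img <- matrix(p$background, p$image_shape[1], p$image_shape[2])
      img <- img + mask * (p$junction_intensity * p$intensity_decay^(s - 1))
      img <- switch(p$noise_model,
        none = img,
        gaussian = pmax(img + stats::rnorm(length(img), 0, p$noise_scale), 0),
        poisson = matrix(stats::rpois(length(img), img),
                         p$image_shape[1], p$image_shape[2]))
      arr[s, , ] <- img
    }
    arr
  })
  structure(list(voxels = voxels, labels = labels,
                 pixel_size = p$pixel_size, z_step = p$z_step,
                 embryo_id = embryo_id, genotype = genotype,
                 n_cells = length(cells)),
            class = "zstack_image")
}

#' @export
print.zstack_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<zstack_image> %s (%s): %d slices of %d x %d px (%.3g um/px, dz %.2g um), %d cells\n",
    x$embryo_id, x$genotype, d[1], d[2], d[3], x$pixel_size, x$z_step,
    x$n_cells))
  invisible(x)
}
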