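# Synthetic epithelial cell meshes --------------------------------------

#' Parameters for the epithelium mesh generator
#'
#' The generator emulates the dorsolateral epidermis during closure: a
#' brick-like mesh of dorsoventrally elongated cells (height along DV >
#' width along AP), with a configurable fraction of "failed elongation"
#' defect cells that are shorter (height shrunk) and wider, as seen in
#' septate-junction mutants.
#'
#' @param n_rows,n_cols Cell counts (>= 1); rows run along the AP axis.
#'   The topmost row is labelled `DME` (leading edge), the next `row2`;
#'   the basal row absorbs the mesh-closing residual (see
#'   [simulate_epithelium()]), so `n_rows = 3` by default.
#' @param mean_height,mean_width Mean cell extents, um. Defaults 12 x 6
#'   (elongated, aspect ~2).
#' @param height_cv,width_cv Lognormal coefficients of variation of the
#'   per-cell dimension draws.
#' @param defect_fraction Fraction of cells carrying the defect factors.
#' @param defect_height_factor,defect_width_factor Multipliers applied to
#'   a defect cell's drawn height/width (defaults 0.5 and 2: rounder,
#'   wider cells of similar area).
#' @param boundary_jitter SD (um) of positional jitter on shared cell
#'   boundaries.
#' @return An `epithelium_params` object.
#' @seealso [simulate_epithelium()]
#' @export
epithelium_params <- function(n_rows = 3, n_cols = 10,
                              mean_height = 12, mean_width = 6,
                              height_cv = 0.2, width_cv = 0.2,
                              defect_fraction = 0,
                              defect_height_factor = 0.5,
                              defect_width_factor = 2,
                              boundary_jitter = 0.3) {
  stop_if_not(n_rows >= 1 && n_cols >= 1, "cell counts must be >= 1")
  check_number(mean_height, "mean_height", lower = .Machine$double.eps)
  check_number(mean_width, "mean_width", lower = .Machine$double.eps)
  check_number(height_cv, "height_cv", lower = 0)
  check_number(width_cv, "width_cv", lower = 0)
  check_probability(defect_fraction, "defect_fraction")
  check_number(defect_height_factor, "defect_height_factor",
               lower = .Machine$double.eps)
  check_number(defect_width_factor, "defect_width_factor",
               lower = .Machine$double.eps)
  check_number(boundary_jitter, "boundary_jitter", lower = 0)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 mean_height = mean_height, mean_width = mean_width,
                 height_cv = height_cv, width_cv = width_cv,
                 defect_fraction = defect_fraction,
                 defect_height_factor = defect_height_factor,
                 defect_width_factor = defect_width_factor,
                 boundary_jitter = boundary_jitter),
            class = "epithelium_params")
}

rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate an epithelial cell mesh
#'
#' Build a brick-like mesh of simple rectilinear polygons that tiles the
#' rectangle `[0, n_cols * mean_width] x [0, n_rows * mean_height]`
#' exactly. Rows are laid top-down from the leading edge: each row draws
#' per-cell widths (rescaled to the common row span, with brick-offset
#' jittered cuts) and per-cell heights; a cell's flat bottom edge sits at
#' the area-weighted mean of its jagged top boundary minus its drawn
#' height, so the drawn height is exactly the realized mean height. The
#' basal row closes the mesh at y = 0 and therefore absorbs the residual
#' (its drawn heights are not honored); statistics on realized heights
#' should use the non-basal rows. Defect cells (a fixed
#' `round(defect_fraction * n)` subset, drawn uniformly) have height
#' multiplied by `defect_height_factor` and width by
#' `defect_width_factor`. Degenerate geometry is prevented by clamping
#' each bottom edge strictly below its top boundary; the polygon
#' constructor rejects any remaining zero-area or self-intersecting cell.
#'
#' @param params An [epithelium_params()] object.
#' @param seed Integer seed.
#' @param embryo_id,genotype Metadata attached to the cells.
#' @return An `epithelium_sim` object: list with `cells` (list of
#'   [cell_polygon()]; the topmost row labelled `DME`, the next `row2`),
#'   `defect` (named logical ground-truth vector), `basal` (named logical:
#'   cells of the absorbing basal row), `width`, `height` (the tiled
#'   rectangle), and `params`.
#' @examples
#' ep <- simulate_epithelium(epithelium_params(defect_fraction = 0.3), seed = 1)
#' table(sapply(ep$cells, function(cl) cl$row_label))
#' @export
simulate_epithelium <- function(params, seed, embryo_id = "embryo_1",
                                genotype = "wild_type") {
  stop_if_not(inherits(params, "epithelium_params"),
              "`params` must be an epithelium_params object")
  p <- params
  with_seed(seed, {
    n_cells <- p$n_rows * p$n_cols
    W <- p$n_cols * p$mean_width
    H <- p$n_rows * p$mean_height
    n_defect <- round(p$defect_fraction * n_cells)
    defect_idx <- if (n_defect > 0) sort(sample.int(n_cells, n_defect)) else integer(0)
    defect <- seq_len(n_cells) %in% defect_idx
    dim(defect) <- c(p$n_cols, p$n_rows)  # [col, row]; row n_rows = top

    # --- per-row x-cuts (jittered, strictly increasing) and drawn heights
    cuts <- vector("list", p$n_rows)
    heights <- matrix(0, p$n_cols, p$n_rows)
    for (r in seq_len(p$n_rows)) {
      w <- rlnorm_mean_cv(p$n_cols, p$mean_width, p$width_cv)
      w[defect[, r]] <- w[defect[, r]] * p$defect_width_factor
      w <- w * W / sum(w)
      ct <- cumsum(c(0, w))
      if (p$boundary_jitter > 0 && p$n_cols > 1) {
        for (k in 2:p$n_cols) {
          gap <- 0.45 * min(ct[k] - ct[k - 1], ct[k + 1] - ct[k])
          ct[k] <- ct[k] + max(-gap, min(gap, stats::rnorm(1, 0, p$boundary_jitter)))
        }
      }
      cuts[[r]] <- ct
      h <- rlnorm_mean_cv(p$n_cols, p$mean_height, p$height_cv)
      h[defect[, r]] <- h[defect[, r]] * p$defect_height_factor
      heights[, r] <- h
    }

    # --- piecewise-constant boundaries on the global knot set, top-down:
    # bound[, r] is the lower boundary of row r; bound[, n_rows + 1] = H.
    knots <- sort(unique(round(unlist(cuts), 9)))
    nk <- length(knots) - 1L
    mids <- (knots[-1] + knots[-length(knots)]) / 2
    widths_k <- diff(knots)
    bound <- matrix(0, nk, p$n_rows + 1L)
    bound[, p$n_rows + 1L] <- H
    bottoms <- matrix(0, p$n_cols, p$n_rows)   # flat bottom y per cell
    for (r in p$n_rows:1) {
      ct <- cuts[[r]]
      cell_of <- findInterval(mids, ct, rightmost.closed = TRUE)
      for (cidx in seq_len(p$n_cols)) {
        span <- cell_of == cidx
        top_vals <- bound[span, r + 1L]
        t_mean <- sum(top_vals * widths_k[span]) / sum(widths_k[span])
        y_b <- if (r == 1L) 0 else t_mean - heights[cidx, r]
        # keep the bottom strictly below the top boundary everywhere, and
        # leave room for the rows still to be laid below
        y_b <- min(y_b, min(top_vals) - 0.05 * heights[cidx, r])
        y_b <- max(y_b, if (r == 1L) 0 else (r - 1L) * 0.05 * p$mean_height)
        if (r == 1L) y_b <- 0
        bottoms[cidx, r] <- y_b
        bound[span, r] <- y_b
      }
    }

    # --- assemble polygons: flat bottom, jagged top
    cells <- vector("list", n_cells)
    defect_out <- logical(n_cells)
    basal_out <- logical(n_cells)
    idx <- 0L
    for (r in seq_len(p$n_rows)) {
      ct <- cuts[[r]]
      cell_of <- findInterval(mids, ct, rightmost.closed = TRUE)
      row_label <- if (r == p$n_rows) "DME"
                   else if (r == p$n_rows - 1L) "row2" else "other"
      for (cidx in seq_len(p$n_cols)) {
        idx <- idx + 1L
        span_idx <- which(cell_of == cidx)
        xs <- c(knots[span_idx], knots[span_idx[length(span_idx)] + 1L])
        xs[1] <- ct[cidx]; xs[length(xs)] <- ct[cidx + 1L]
        y_b <- bottoms[cidx, r]
        verts <- list(c(xs[1], y_b), c(xs[length(xs)], y_b))
        for (m in rev(seq_along(span_idx))) {     # top: right -> left
          i <- span_idx[m]
          verts[[length(verts) + 1L]] <- c(xs[m + 1L], bound[i, r + 1L])
          verts[[length(verts) + 1L]] <- c(xs[m], bound[i, r + 1L])
        }
        verts <- do.call(rbind, verts)
        keep <- c(TRUE, rowSums(abs(diff(verts))) > 1e-9)
        verts <- verts[keep, , drop = FALSE]
        if (all(abs(verts[1, ] - verts[nrow(verts), ]) < 1e-9))
          verts <- verts[-nrow(verts), , drop = FALSE]
        cid <- sprintf("%s_r%d_c%d", embryo_id, r, cidx)
        cells[[idx]] <- cell_polygon(verts, cell_id = cid,
                                     embryo_id = embryo_id,
                                     genotype = genotype,
                                     row_label = row_label)
        defect_out[idx] <- defect[cidx, r]
        basal_out[idx] <- r == 1L && p$n_rows > 1L
      }
    }
    ids <- vapply(cells, function(cl) cl$cell_id, character(1))
    names(defect_out) <- ids
    names(basal_out) <- ids
    structure(list(cells = cells, defect = defect_out, basal = basal_out,
                   width = W, height = H, params = p),
              class = "epithelium_sim")
  })
}

#' @export
print.epithelium_sim <- function(x, ...) {
  cat(sprintf(
    "<epithelium_sim> %d x %d cells tiling %.1f x %.1f um (%d defect)\n",
    x$params$n_rows, x$params$n_cols, x$width, x$height, sum(x$defect)))
  invisible(x)
}
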