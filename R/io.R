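# Shared I/O: unit-headed CSV tables, polygon JSON, TIFF stacks ---------
#
# Column headers carry units (t_min, length_um, t_s, distance_um) so that
# unit drift is caught at the schema check, not downstream.

read_checked_csv <- function(path, required) {
  stop_if_not(file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_if_not(nrow(df) > 0, sprintf("empty input: %s", path))
  missing <- setdiff(required, names(df))
  stop_if_not(length(missing) == 0,
              sprintf("%s: missing column(s) %s (units are part of the name)",
                      path, paste(missing, collapse = ", ")))
  df
}

check_numeric_col <- function(df, col, path) {
  x <- df[[col]]
  bad <- which(!is.finite(suppressWarnings(as.numeric(x))))
  stop_if_not(length(bad) == 0,
              sprintf("%s: malformed values in '%s' at data row(s) %s",
                      path, col, paste(utils::head(bad, 5), collapse = ", ")))
  as.numeric(x)
}

#' Read closure trajectories from CSV
#'
#' Expected columns: `embryo_id`, `genotype`, `t_min`, `length_um`, and
#' optionally `tear_flag` (0/1) and `tear_side`. One trajectory per
#' `embryo_id`; times must be strictly increasing within an embryo.
#'
#' @param path CSV file path.
#' @return List of `dc_trajectory` objects.
#' @export
read_trajectories <- function(path) {
  df <- read_checked_csv(path, c("embryo_id", "genotype", "t_min", "length_um"))
  df$t_min <- check_numeric_col(df, "t_min", path)
  df$length_um <- check_numeric_col(df, "length_um", path)
  stop_if_not(all(df$length_um >= 0), sprintf("%s: negative lengths", path))
  lapply(split(df, df$embryo_id), function(sub) {
    sub <- sub[order(sub$t_min), ]
    stop_if_not(all(diff(sub$t_min) > 0),
                sprintf("%s: duplicate times for embryo %s", path,
                        sub$embryo_id[1]))
    torn <- "tear_flag" %in% names(sub) && any(sub$tear_flag == 1)
    structure(list(
      embryo_id = sub$embryo_id[1], genotype = sub$genotype[1],
      times = sub$t_min, lengths = sub$length_um,
      true_lengths = NULL, t0_index = NA_integer_, late_start = NA,
      outcome = if (torn) "torn" else "unset",
      event_time = if (torn) sub$t_min[which(sub$tear_flag == 1)[1]] else NA_real_,
      tear_side = if (torn && "tear_side" %in% names(sub))
        sub$tear_side[which(sub$tear_flag == 1)[1]] else NA_character_
    ), class = "dc_trajectory")
  })
}

#' Write closure trajectories to CSV
#'
#' Inverse of [read_trajectories()]; the round trip preserves times,
#' lengths and tear annotations.
#'
#' @param trajs List of `dc_trajectory` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  rows <- lapply(trajs, function(tr) {
    n <- length(tr$times)
    tear_flag <- integer(n)
    tear_side <- rep("", n)
    if (identical(tr$outcome, "torn") && !is.na(tr$event_time)) {
      i <- which(tr$times == tr$event_time)[1]
      if (!is.na(i)) {
        tear_flag[i] <- 1L
        tear_side[i] <- if (is.na(tr$tear_side)) "" else tr$tear_side
      }
    }
    data.frame(embryo_id = tr$embryo_id, genotype = tr$genotype,
               t_min = tr$times, length_um = tr$lengths,
               tear_flag = tear_flag, tear_side = tear_side,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read post-ablation recoil series from CSV
#'
#' Expected columns: `series_id`, `genotype`, `location`, `phase`, `t_s`,
#' `distance_um`, `pre_cut` (0/1; exactly one pre-cut row per series).
#'
#' @param path CSV file path.
#' @return List of `recoil_series` objects.
#' @export
read_recoil_series <- function(path) {
  df <- read_checked_csv(path, c("series_id", "genotype", "location",
                                 "phase", "t_s", "distance_um", "pre_cut"))
  df$t_s <- check_numeric_col(df, "t_s", path)
  df$distance_um <- check_numeric_col(df, "distance_um", path)
  lapply(split(df, df$series_id), function(sub) {
    sub <- sub[order(sub$t_s), ]
    out <- structure(list(
      series_id = sub$series_id[1], genotype = sub$genotype[1],
      location = sub$location[1], phase = sub$phase[1],
      times = sub$t_s, distances = sub$distance_um,
      pre_cut = sub$pre_cut == 1
    ), class = "recoil_series")
    check_recoil_series(out)
    out
  })
}

#' Write recoil series to CSV
#' @param series List of `recoil_series` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recoil_series <- function(series, path) {
  rows <- lapply(series, function(s) {
    data.frame(series_id = s$series_id, genotype = s$genotype,
               location = s$location, phase = s$phase,
               t_s = s$times, distance_um = s$distances,
               pre_cut = as.integer(s$pre_cut), stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read / write cell polygons as JSON
#'
#' Polygons are stored as a JSON array of objects with `cell_id`,
#' `embryo_id`, `genotype`, `row_label` and `vertices` (an array of
#' `[x, y]` pairs in um).
#'
#' @param cells List of [cell_polygon()] objects.
#' @param path JSON file path.
#' @return `write_cell_polygons()`: `path`, invisibly;
#'   `read_cell_polygons()`: list of `cell_polygon` objects.
#' @export
write_cell_polygons <- function(cells, path) {
  payload <- lapply(cells, function(cl) {
    list(cell_id = cl$cell_id, embryo_id = cl$embryo_id,
         genotype = cl$genotype, row_label = cl$row_label,
         vertices = unname(apply(cl$vertices, 1, function(v) c(v[1], v[2]),
                                 simplify = FALSE)))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cell_polygons
#' @export
read_cell_polygons <- function(path) {
  stop_if_not(file.exists(path), sprintf("file not found: %s", path))
  payload <- jsonlite::read_json(path)
  lapply(payload, function(cl) {
    v <- do.call(rbind, lapply(cl$vertices, unlist))
    cell_polygon(v, cell_id = cl$cell_id, embryo_id = cl$embryo_id,
                 genotype = cl$genotype, row_label = cl$row_label)
  })
}

#' Read / write z-stacks as multi-page TIFF with a JSON sidecar
#'
#' The voxel array is written as a 32-bit float multi-page TIFF scaled to
#' `[0, 1]`; the sidecar JSON (`<path>.json`) records the scale factor and
#' the spatial calibration (`pixel_size`, `z_step`), plus metadata.
#' Ground-truth labels, when present, are stored in the sidecar.
#'
#' @param stack A `zstack_image`.
#' @param path TIFF file path (sidecar written next to it).
#' @return `write_zstack()`: `path`, invisibly; `read_zstack()`: a
#'   `zstack_image`.
#' @export
write_zstack <- function(stack, path) {
  d <- dim(stack$voxels)
  scale <- max(stack$voxels, 1)
  pages <- lapply(seq_len(d[1]), function(s) stack$voxels[s, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  sidecar <- list(pixel_size_um = stack$pixel_size,
                  z_step_um = stack$z_step,
                  intensity_scale = scale,
                  embryo_id = stack$embryo_id,
                  genotype = stack$genotype,
                  n_cells = stack$n_cells,
                  labels = if (!is.null(stack$labels))
                    apply(stack$labels, 1, as.integer, simplify = FALSE))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_zstack
#' @export
read_zstack <- function(path) {
  stop_if_not(file.exists(path), sprintf("file not found: %s", path))
  sidecar_path <- paste0(path, ".json")
  stop_if_not(file.exists(sidecar_path),
              sprintf("calibration sidecar not found: %s", sidecar_path))
  meta <- jsonlite::read_json(sidecar_path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  voxels <- array(0, dim = c(length(pages), dim(pages[[1]])))
  for (s in seq_along(pages)) voxels[s, , ] <- pages[[s]] * meta$intensity_scale
  labels <- if (!is.null(meta$labels))
    do.call(rbind, lapply(meta$labels, unlist)) else NULL
  structure(list(voxels = voxels, labels = labels,
                 pixel_size = meta$pixel_size_um, z_step = meta$z_step_um,
                 embryo_id = meta$embryo_id, genotype = meta$genotype,
                 n_cells = meta$n_cells),
            class = "zstack_image")
}
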