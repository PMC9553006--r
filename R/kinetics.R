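# Closure kinetics: alignment, two-phase rate estimation, outcomes ------

#' Dorsal-hole length from canthus coordinates
#'
#' The hole length is the Euclidean distance between the anterior and
#' posterior canthi (the corners of the eye-shaped dorsal hole), in um.
#'
#' @param anterior_canthus,posterior_canthus Numeric `(x, y)` pairs, um.
#' @return Length in um.
#' @examples
#' measure_hole_length(c(0, 0), c(190, 0))
#' @export
measure_hole_length <- function(anterior_canthus, posterior_canthus) {
  stop_if_not(is.numeric(anterior_canthus) && length(anterior_canthus) == 2L &&
                all(is.finite(anterior_canthus)),
              "`anterior_canthus` must be a finite (x, y) pair")
  stop_if_not(is.numeric(posterior_canthus) && length(posterior_canthus) == 2L &&
                all(is.finite(posterior_canthus)),
              "`posterior_canthus` must be a finite (x, y) pair")
  sqrt(sum((anterior_canthus - posterior_canthus)^2))
}

#' Align a trajectory to the closure clock
#'
#' Set t = 0 at the first frame whose length falls inside the alignment
#' window (220-230 um by default). If no frame lands inside but the series
#' crosses the window between frames, the first frame below the window top
#' is used. Trajectories already below the window at their first frame are
#' flagged `late_start` (imaging began too late) and are excluded from rate
#' summaries downstream.
#'
#' @param traj A `dc_trajectory` (or compatible list with `times`,
#'   `lengths`).
#' @param window Length pair (um), default `c(220, 230)`.
#' @return The trajectory with `t0_index` set, `times` shifted so the
#'   alignment frame is 0, and `late_start` set.
#' @export
align_trajectory <- function(traj, window = c(220, 230)) {
  stop_if_not(length(traj$lengths) >= 1L, "trajectory has no frames")
  stop_if_not(is.numeric(window) && length(window) == 2L &&
                window[1] < window[2], "`window` must be an increasing pair")
  L <- traj$lengths
  if (L[1] < window[1]) {
    traj$late_start <- TRUE
    traj$t0_index <- NA_integer_
    return(traj)
  }
  inside <- which(L >= window[1] & L <= window[2])
  i0 <- if (length(inside)) inside[1] else {
    below <- which(L < window[2])
    stop_if_not(length(below) > 0,
                "trajectory never reaches the alignment window")
    below[1]
  }
  traj$t0_index <- as.integer(i0)
  traj$times <- traj$times - traj$times[i0]
  traj$late_start <- FALSE
  traj
}

#' Two-phase closure-rate estimation
#'
#' Estimate the early and late dorsal-hole shortening rates with the
#' endpoint estimator: the early rate spans the last frame with length
#' above the alignment-window bottom (220 um) to the first frame with
#' length below the changepoint `L_c` (190 um); the late rate spans that
#' frame to the last frame before closure. Rates are reported as positive
#' shortening rates in um/min. A regression variant (`method =
#' "regression"`, least-squares slope over the same windows) is provided
#' for cross-checking.
#'
#' @param traj An aligned `dc_trajectory` (see [align_trajectory()]);
#'   unaligned trajectories are aligned with the default window first.
#' @param L_c Changepoint length, um (default 190).
#' @param window Alignment window used for the early-phase start, um.
#' @param close_threshold Length (um) at or below which the hole counts as
#'   closed; the late window ends at the frame before the first such frame.
#' @param method `"endpoint"` (default) or `"regression"`.
#' @return A `phase_fit` object with `r_early`, `r_late` (NA when the
#'   trajectory never drops below `L_c` or a phase has fewer than 2
#'   frames), the index windows, and frame counts. `coef()` returns the
#'   two rates.
#' @examples
#' tr <- simulate_closure_trajectory(
#'   closure_preset("wild_type", noise_sigma = 0,
#'                  L_start_range = c(230, 230)), seed = 1)
#' fit_phase_rates(align_trajectory(tr))
#' @export
fit_phase_rates <- function(traj, L_c = 190, window = c(220, 230),
                            close_threshold = 5, method = c("endpoint", "regression")) {
  method <- match.arg(method)
  if (is.na(traj$t0_index) && !isTRUE(traj$late_start))
    traj <- align_trajectory(traj, window)
  stop_if_not(!isTRUE(traj$late_start),
              "late-start trajectory: imaging began below the alignment window")
  L <- traj$lengths; tt <- traj$times
  n <- length(L)
  check_number(L_c, "L_c", lower = 0)

  above <- which(L > window[1])
  a <- if (length(above)) above[length(above)] else 1L
  belowc <- which(L < L_c)
  b <- if (length(belowc)) belowc[1] else n
  r_late <- NA_real_

  closed_at <- which(L <= close_threshold)
  cc <- if (length(closed_at)) max(closed_at[1] - 1L, 1L) else n

  rate <- function(i, j) {
    if (j <= i || tt[j] == tt[i]) return(NA_real_)
    if (method == "endpoint") {
      (L[i] - L[j]) / (tt[j] - tt[i])
    } else {
      idx <- i:j
      -unname(stats::coef(stats::lm(L[idx] ~ tt[idx]))[2])
    }
  }

  r_early <- rate(a, b)
  if (is.na(r_early))
    warning("fewer than 2 frames in the early phase; early rate unset")
  if (length(belowc)) {
    r_late <- rate(b, cc)
    if (is.na(r_late))
      warning("fewer than 2 frames in the late phase; late rate unset")
  }

  structure(list(
    embryo_id = traj$embryo_id,
    genotype = traj$genotype,
    r_early = r_early, r_late = r_late, L_c = L_c,
    early_window = c(a, b), late_window = c(b, cc),
    n_early = b - a + 1L, n_late = cc - b + 1L,
    method = method
  ), class = "phase_fit")
}

#' @export
print.phase_fit <- function(x, ...) {
  cat("<phase_fit>", if (!is.null(x$embryo_id)) x$embryo_id else "", "\n")
  cat(sprintf("  early rate: %s um/min (frames %d-%d)\n",
              format(x$r_early, digits = 4), x$early_window[1], x$early_window[2]))
  cat(sprintf("  late rate:  %s um/min (frames %d-%d)\n",
              format(x$r_late, digits = 4), x$late_window[1], x$late_window[2]))
  cat(sprintf("  changepoint: %g um, method: %s\n", x$L_c, x$method))
  invisible(x)
}

#' @export
coef.phase_fit <- function(object, ...) {
  c(r_early = object$r_early, r_late = object$r_late)
}

#' Classify the outcome of a closure trajectory
#'
#' Tear annotations (ground truth from the generator, or manual) are
#' honored first. Otherwise the embryo is `closed` when the minimum length
#' is at or below `close_threshold`, `arrested` when the mean shortening
#' rate over the final `arrest_window` minutes falls below `arrest_rate`
#' while the hole is still open, and `in_progress` otherwise.
#'
#' @param traj A `dc_trajectory`.
#' @param close_threshold Closure length threshold, um (default 5).
#' @param arrest_rate Shortening-rate threshold, um/min (default 0.05).
#' @param arrest_window Averaging window for the arrest test, min
#'   (default 60).
#' @return One of `"torn"`, `"closed"`, `"arrested"`, `"in_progress"`.
#' @export
classify_outcome <- function(traj, close_threshold = 5,
                             arrest_rate = 0.05, arrest_window = 60) {
  if (identical(traj$outcome, "torn")) return("torn")
  L <- traj$lengths; tt <- traj$times
  if (min(L) <= close_threshold) return("closed")
  in_win <- tt >= (tt[length(tt)] - arrest_window)
  if (sum(in_win) >= 2L) {
    i <- which(in_win)[1]; j <- length(tt)
    mean_rate <- (L[i] - L[j]) / (tt[j] - tt[i])
    if (mean_rate < arrest_rate) return("arrested")
  }
  "in_progress"
}

#' Summarize a cohort of closure trajectories
#'
#' Per-genotype outcome frequencies and mean +/- SD early/late closure
#' rates. Following the study's inclusion rules, rate averages use only
#' embryos whose imaging began above the alignment window (no `late_start`
#' flag), and late rates average only over embryos that closed.
#'
#' @param trajs List of `dc_trajectory` objects.
#' @param L_c,window,close_threshold Passed to [fit_phase_rates()].
#' @param ... Passed to [classify_outcome()].
#' @return A data.frame with one row per genotype: `n`, outcome frequencies
#'   (`f_closed`, `f_arrested`, `f_torn`, `f_in_progress`, as proportions),
#'   `n_rate`, `mean_r_early`, `sd_r_early`, `n_closed`, `mean_r_late`,
#'   `sd_r_late`.
#' @export
summarize_cohort <- function(trajs, L_c = 190, window = c(220, 230),
                             close_threshold = 5, ...) {
  stop_if_not(length(trajs) >= 1L, "empty cohort")
  genos <- vapply(trajs, function(tr) tr$genotype, character(1))
  rows <- lapply(unique(genos), function(g) {
    sub <- trajs[genos == g]
    outcomes <- vapply(sub, classify_outcome,
                       close_threshold = close_threshold, ..., FUN.VALUE = character(1))
    n <- length(sub)
    fits <- lapply(sub, function(tr) {
      tr <- align_trajectory(tr, window)
      if (isTRUE(tr$late_start)) return(NULL)
      suppressWarnings(
        fit_phase_rates(tr, L_c = L_c, window = window,
                        close_threshold = close_threshold))
    })
    ok <- !vapply(fits, is.null, logical(1))
    r_early <- vapply(fits[ok], function(f) f$r_early, numeric(1))
    r_early <- r_early[!is.na(r_early)]
    closed <- ok & outcomes == "closed"
    r_late <- vapply(fits[closed], function(f) f$r_late, numeric(1))
    r_late <- r_late[!is.na(r_late)]
    data.frame(
      genotype = g, n = n,
      f_closed = mean(outcomes == "closed"),
      f_arrested = mean(outcomes == "arrested"),
      f_torn = mean(outcomes == "torn"),
      f_in_progress = mean(outcomes == "in_progress"),
      n_rate = length(r_early),
      mean_r_early = if (length(r_early)) mean(r_early) else NA_real_,
      sd_r_early = if (length(r_early) > 1) stats::sd(r_early) else NA_real_,
      n_closed = sum(outcomes == "closed"),
      mean_r_late = if (length(r_late)) mean(r_late) else NA_real_,
      sd_r_late = if (length(r_late) > 1) stats::sd(r_late) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
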