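# Laser-ablation mechanics: recoil velocity and Kelvin-Voigt fits -------

#' Parameters for the recoil-series generator
#'
#' @param D Asymptotic distance retracted, um (> 0).
#' @param tau Relaxation time, s (> 0).
#' @param sample_interval Sampling interval after the cut, s (default 3).
#' @param duration Total post-cut observation time, s (default 60).
#' @param noise_sigma SD (um) of additive Gaussian noise on distances.
#' @param L0 Pre-cut vertex-to-vertex distance, um.
#' @return An `ablation_params` object.
#' @seealso [simulate_recoil()], [fit_kelvin_voigt()]
#' @export
ablation_params <- function(D = 3, tau = 20, sample_interval = 3,
                            duration = 60, noise_sigma = 0, L0 = 4) {
  check_number(D, "D", lower = .Machine$double.eps)
  check_number(tau, "tau", lower = .Machine$double.eps)
  stop_if_not(sample_interval > 0, "`sample_interval` must be positive")
  stop_if_not(duration >= sample_interval,
              "`duration` must be >= `sample_interval`")
  check_number(noise_sigma, "noise_sigma", lower = 0)
  check_number(L0, "L0", lower = .Machine$double.eps)
  structure(list(D = D, tau = tau, sample_interval = sample_interval,
                 duration = duration, noise_sigma = noise_sigma, L0 = L0),
            class = "ablation_params")
}

#' Simulate a post-ablation recoil series
#'
#' Vertex-to-vertex distance after a junction cut follows the Kelvin-Voigt
#' (spring-dashpot) retraction `deltaL(t) = D * (1 - exp(-t / tau))`; the
#' series samples `L0 + deltaL(t_k) + noise` at `t_k = k * sample_interval`
#' up to `duration`, preceded by the pre-cut distance `L0` at `t = 0`
#' (flagged `pre_cut`).
#'
#' @param params An [ablation_params()] object.
#' @param seed Integer seed (used only when `noise_sigma > 0`).
#' @param series_id,genotype,location,phase Metadata stored on the series;
#'   `location` is one of `"dorsal_epidermis"`, `"lateral_epidermis"`,
#'   `"cable"`; `phase` is `"early"` (hole > 190 um) or `"late"`.
#' @return A `recoil_series` object: list with `times` (s; first entry
#'   pre-cut), `distances` (um), `pre_cut` (logical vector), and metadata.
#' @examples
#' rs <- simulate_recoil(ablation_params(D = 3, tau = 20), seed = 1)
#' rs$distances[2] - rs$distances[1]  # first-frame displacement
#' @export
simulate_recoil <- function(params, seed = 1, series_id = "cut_1",
                            genotype = "wild_type",
                            location = c("dorsal_epidermis",
                                         "lateral_epidermis", "cable"),
                            phase = c("early", "late")) {
  stop_if_not(inherits(params, "ablation_params"),
              "`params` must be an ablation_params object")
  location <- match.arg(location)
  phase <- match.arg(phase)
  p <- params
  tk <- seq(p$sample_interval, p$duration, by = p$sample_interval)
  dL <- p$D * (1 - exp(-tk / p$tau))
  noise <- if (p$noise_sigma > 0)
    with_seed(seed, stats::rnorm(length(tk), 0, p$noise_sigma)) else 0
  structure(list(
    series_id = series_id, genotype = genotype,
    location = location, phase = phase,
    times = c(0, tk),
    distances = c(p$L0, p$L0 + dL + noise),
    pre_cut = c(TRUE, rep(FALSE, length(tk)))
  ), class = "recoil_series")
}

#' @export
print.recoil_series <- function(x, ...) {
  cat(sprintf("<recoil_series> %s (%s, %s, %s): %d frames, L0 = %.2f um\n",
              x$series_id, x$genotype, x$location, x$phase,
              length(x$times), x$distances[x$pre_cut][1]))
  invisible(x)
}

check_recoil_series <- function(series) {
  stop_if_not(sum(series$pre_cut) == 1L,
              "series must have exactly one pre-cut entry")
  stop_if_not(which(series$pre_cut) == 1L,
              "the pre-cut entry must come first")
  stop_if_not(all(diff(series$times) > 0), "times must be increasing")
  stop_if_not(all(series$distances > 0), "distances must be positive")
}

#' Initial recoil velocity after junction ablation
#'
#' The recoil velocity — a proxy for the relative tension borne by the cut
#' junction — is the displacement of the flanking tricellular vertices over
#' the first frame after cutting: `v = (L(first post-cut) - L(pre-cut)) /
#' dt`, where `dt` is the interval between those two frames.
#'
#' @param series A `recoil_series`.
#' @param dt Interval (s) between the pre-cut and first post-cut frame;
#'   defaults to the series' own time difference.
#' @return A `recoil_velocity` object: list with `v` (um/s) and `dt_used`.
#' @export
recoil_velocity <- function(series, dt = NULL) {
  check_recoil_series(series)
  stop_if_not(length(series$times) >= 2L, "need at least one post-cut frame")
  if (is.null(dt)) dt <- series$times[2] - series$times[1]
  stop_if_not(dt > 0, "`dt` must be positive")
  structure(list(v = (series$distances[2] - series$distances[1]) / dt,
                 dt_used = dt, series_id = series$series_id),
            class = "recoil_velocity")
}

#' @export
print.recoil_velocity <- function(x, ...) {
  cat(sprintf("<recoil_velocity> %s: v = %.4f um/s (dt = %g s)\n",
              x$series_id, x$v, x$dt_used))
  invisible(x)
}

#' Fit the Kelvin-Voigt retraction model to a recoil series
#'
#' Nonlinear least squares of the post-cut displacement `deltaL(t) = L(t) -
#' L(pre-cut)` against `D * (1 - exp(-t / tau))` (no offset: `deltaL(0) = 0`
#' is enforced, since `D` is the asymptotic distance retracted). `tau`, the
#' relaxation time, estimates the viscosity-to-elasticity ratio of the
#' tissue. Levenberg-Marquardt fits are started from `D0 =` last observed
#' displacement and `tau0` in `{5, 15, 45}` s; the converged fit with the
#' lowest SSE is returned.
#'
#' @param series A `recoil_series` with at least 4 post-cut frames.
#' @param tau_starts Relaxation-time starting values, s.
#' @return A `kv_fit` object with `D_hat` (um), `tau_hat` (s), `sse`
#'   (um^2), `converged`, `n_points`. `coef()` returns the estimates;
#'   `predict()` evaluates the fitted displacement at new times;
#'   `residuals()` returns observed minus fitted displacement.
#' @examples
#' rs <- simulate_recoil(ablation_params(D = 3, tau = 20), seed = 1)
#' coef(fit_kelvin_voigt(rs))
#' @export
fit_kelvin_voigt <- function(series, tau_starts = c(5, 15, 45)) {
  check_recoil_series(series)
  post <- !series$pre_cut
  stop_if_not(sum(post) >= 4L, "need at least 4 post-cut frames")
  t_post <- series$times[post] - series$times[series$pre_cut]
  dL <- series$distances[post] - series$distances[series$pre_cut]
  dat <- data.frame(t = t_post, dL = dL)
  D0 <- max(dL[length(dL)], .Machine$double.eps)

  best <- NULL
  for (tau0 in tau_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(dL ~ D * (1 - exp(-t / tau)), data = dat,
                        start = list(D = D0, tau = tau0),
                        lower = c(D = 1e-9, tau = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(fit = fit, sse = sse)
  }

  if (is.null(best)) {
    out <- list(series_id = series$series_id, D_hat = NA_real_,
                tau_hat = NA_real_, sse = NA_real_, converged = FALSE,
                n_points = sum(post), t = t_post, dL = dL)
  } else {
    cf <- stats::coef(best$fit)
    out <- list(series_id = series$series_id,
                D_hat = unname(cf["D"]), tau_hat = unname(cf["tau"]),
                sse = best$sse, converged = TRUE,
                n_points = sum(post), t = t_post, dL = dL)
  }
  structure(out, class = "kv_fit")
}

#' @export
print.kv_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<kv_fit>", x$series_id, ": did not converge\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<kv_fit> %s: D = %.4g um, tau = %.4g s (SSE %.3g um^2, n = %d)\n",
    x$series_id, x$D_hat, x$tau_hat, x$sse, x$n_points))
  invisible(x)
}

#' @export
coef.kv_fit <- function(object, ...) {
  c(D = object$D_hat, tau = object$tau_hat)
}

#' @export
predict.kv_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$t
  object$D_hat * (1 - exp(-times / object$tau_hat))
}

#' @export
residuals.kv_fit <- function(object, ...) {
  object$dL - predict(object)
}

#' Compare recoil mechanics across groups
#'
#' Pairwise two-sided Welch t-tests of a mechanical readout (recoil
#' velocity or relaxation time) between genotypes, within each
#' location-by-phase stratum.
#'
#' @param values Numeric readout per cut.
#' @param group Grouping factor (e.g. genotype), same length.
#' @param strata Optional data.frame / list of stratifying variables
#'   (e.g. location, phase), same length.
#' @param min_n Minimum group size (default 3).
#' @return A data.frame with one row per contrast: stratum labels, the two
#'   group names, per-group mean, SD, n, the mean difference, and the Welch
#'   `p` value.
#' @export
compare_mechanics <- function(values, group, strata = NULL, min_n = 3L) {
  stop_if_not(is.numeric(values) && length(values) == length(group),
              "`values` and `group` must have equal length")
  group <- as.character(group)
  if (is.null(strata)) {
    strata_id <- rep("all", length(values))
    strata <- data.frame(stratum = strata_id, stringsAsFactors = FALSE)
  } else {
    strata <- as.data.frame(strata, stringsAsFactors = FALSE)
    stop_if_not(nrow(strata) == length(values),
                "`strata` must have one row per value")
    strata_id <- do.call(paste, c(strata, sep = ":"))
  }
  rows <- list()
  for (s in unique(strata_id)) {
    idx <- strata_id == s
    gs <- sort(unique(group[idx]))
    stop_if_not(length(gs) >= 1L, "no groups in stratum")
    if (length(gs) < 2L) next
    for (i in seq_len(length(gs) - 1L)) for (j in (i + 1L):length(gs)) {
      x <- values[idx & group == gs[i]]
      y <- values[idx & group == gs[j]]
      stop_if_not(length(x) >= min_n && length(y) >= min_n,
                  sprintf("groups '%s'/'%s' need >= %d values each",
                          gs[i], gs[j], min_n))
      diff_xy <- mean(x) - mean(y)
      p <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        if (diff_xy == 0) 1 else 0
      } else {
        stats::t.test(x, y, var.equal = FALSE)$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, group1 = gs[i], group2 = gs[j],
        mean1 = mean(x), sd1 = stats::sd(x), n1 = length(x),
        mean2 = mean(y), sd2 = stats::sd(y), n2 = length(y),
        difference = diff_xy, p = p, stringsAsFactors = FALSE)
    }
  }
  stop_if_not(length(rows) > 0, "need at least 2 groups to compare")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
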