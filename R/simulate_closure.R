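# Synthetic closure trajectories ----------------------------------------

# Truncated-normal draw by rejection; falls back to runif bounds midpoint
# cap after many rejections (only reachable with pathological params).
rtrunc_norm <- function(mean, sd, lower, upper) {
  if (sd == 0) return(min(max(mean, lower), upper))
  for (i in 1:1000) {
    x <- stats::rnorm(1L, mean, sd)
    if (x > lower && x < upper) return(x)
  }
  stats::runif(1L, lower, upper)
}

#' Simulate one dorsal-hole closure trajectory
#'
#' Generate a synthetic time series of dorsal-hole length, emulating the
#' live-imaging measurements: the hole shortens at the early rate while its
#' current length exceeds `L_inflection`, then at the late rate (two-phase
#' kinetics), with additive Gaussian measurement noise on the recorded
#' lengths. The trajectory ends at closure (length reaches 0, clamped), at
#' a tear event (drawn with probability `p_tear` at a truncated-normal
#' length, with anterior/posterior side drawn by `p_anterior_tear`), at an
#' arrest (shortening stops), or at `max_time`. Ground truth (outcome,
#' event time, tear side, noiseless lengths) is recorded.
#'
#' The generator is a pure function of `(params, seed)`: the caller's RNG
#' state is left untouched.
#'
#' @param params A [closure_params()] object.
#' @param seed Integer seed.
#' @param embryo_id Identifier stored on the trajectory.
#' @return A `dc_trajectory` object: list with `embryo_id`, `genotype`,
#'   `times` (min), `lengths` (um, noisy, clamped at 0), `true_lengths`,
#'   `t0_index` (unset until [align_trajectory()]), `outcome` (one of
#'   `"closed"`, `"arrested"`, `"torn"`, `"in_progress"`), `event_time`
#'   (min or `NA`) and `tear_side` (`"anterior"`, `"posterior"` or `NA`).
#' @examples
#' wt <- closure_preset("wild_type", noise_sigma = 0)
#' tr <- simulate_closure_trajectory(wt, seed = 1)
#' plot(tr$times, tr$lengths, type = "b",
#'      xlab = "time (min)", ylab = "hole length (um)")
#' @export
simulate_closure_trajectory <- function(params, seed, embryo_id = "embryo_1") {
  stop_if_not(inherits(params, "closure_params"),
              "`params` must be a closure_params object")
  with_seed(seed, {
    p <- params
    L_start <- stats::runif(1L, p$L_start_range[1], p$L_start_range[2])

    # event draws (fixed draw order for reproducibility)
    tears <- stats::runif(1L) < p$p_tear
    tear_length <- if (tears)
      rtrunc_norm(p$tear_length_mean, p$tear_length_sd, 0, L_start) else NA_real_
    tear_side <- if (tears) {
      if (stats::runif(1L) < p$p_anterior_tear) "anterior" else "posterior"
    } else NA_character_
    arrests <- stats::runif(1L) < p$p_arrest
    arrest_length <- if (arrests)
      rtrunc_norm(p$arrest_length_mean, p$arrest_length_sd,
                  0, p$L_inflection) else NA_real_

    r_late_eff <- if (p$enter_fast_phase) p$r_late else p$r_early

    n_max <- floor(p$max_time / p$frame_interval) + 1L
    times <- numeric(n_max); truth <- numeric(n_max)
    outcome <- "in_progress"; event_time <- NA_real_
    L <- L_start; arrested_now <- FALSE
    k <- 0L
    while (k < n_max) {
      k <- k + 1L
      times[k] <- (k - 1L) * p$frame_interval
      truth[k] <- max(L, 0)
      if (tears && L <= tear_length) {
        outcome <- "torn"; event_time <- times[k]; break
      }
      if (L <= 0) {
        outcome <- "closed"; event_time <- times[k]; break
      }
      if (arrests && !arrested_now && L <= arrest_length) {
        arrested_now <- TRUE; event_time <- times[k]
      }
      r <- if (arrested_now) 0 else if (L > p$L_inflection) p$r_early else r_late_eff
      L <- L - r * p$frame_interval
    }
    times <- times[seq_len(k)]; truth <- truth[seq_len(k)]
    if (outcome == "in_progress" && (arrested_now || p$r_early == 0))
      outcome <- "arrested"

    lengths <- pmax(truth + stats::rnorm(k, 0, p$noise_sigma), 0)

    structure(list(
      embryo_id = embryo_id,
      genotype = p$genotype_label,
      times = times,
      lengths = lengths,
      true_lengths = truth,
      t0_index = NA_integer_,
      late_start = NA,
      outcome = outcome,
      event_time = event_time,
      tear_side = tear_side
    ), class = "dc_trajectory")
  })
}

#' Simulate a cohort of closure trajectories
#'
#' Generate `n` independent trajectories from one parameter set. Per-embryo
#' seeds are derived deterministically from the master seed, so the cohort
#' is reproducible bit-for-bit given `(params, n, seed)`.
#'
#' @param params A [closure_params()] object.
#' @param n Number of embryos (>= 1).
#' @param seed Master integer seed.
#' @return List of `dc_trajectory` objects with ids `<genotype>_001`, ...
#' @examples
#' coh <- simulate_cohort(closure_preset("wild_type"), n = 5, seed = 42)
#' sapply(coh, function(tr) tr$outcome)
#' @export
simulate_cohort <- function(params, n, seed) {
  stop_if_not(is.numeric(n) && length(n) == 1L && n >= 1,
              "`n` must be >= 1")
  n <- as.integer(n)
  seeds <- derive_seeds(seed, n)
  lapply(seq_len(n), function(i) {
    simulate_closure_trajectory(
      params, seed = seeds[i],
      embryo_id = sprintf("%s_%03d", params$genotype_label, i))
  })
}

#' @export
print.dc_trajectory <- function(x, ...) {
  cat(sprintf("<dc_trajectory> %s (%s): %d frames, %.1f-%.1f um, outcome %s\n",
              x$embryo_id, x$genotype, length(x$times),
              max(x$lengths), min(x$lengths), x$outcome))
  if (!is.na(x$event_time))
    cat(sprintf("  event at t = %g min%s\n", x$event_time,
                if (!is.na(x$tear_side)) paste0(" (", x$tear_side, " tear)") else ""))
  invisible(x)
}

#' Draw binomially distributed cuticle-defect counts
#'
#' Emulates scoring of cuticle preparations: each of `n` embryos shows the
#' dorsal-open phenotype independently with probability `p_defect`.
#'
#' @param p_defect Defect probability in \[0, 1\].
#' @param n Number of embryos scored.
#' @param seed Integer seed.
#' @return Integer count of defective embryos.
#' @export
simulate_cuticle_counts <- function(p_defect, n, seed) {
  check_probability(p_defect, "p_defect")
  stop_if_not(is.numeric(n) && length(n) == 1L && n >= 1, "`n` must be >= 1")
  with_seed(seed, stats::rbinom(1L, as.integer(n), p_defect))
}
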