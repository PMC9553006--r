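#' Parameters for the closure-trajectory generator
#'
#' Bundle the kinetic and event parameters that define how a synthetic
#' dorsal-hole length trajectory is generated. The model is a two-phase
#' shortening process: the hole shortens at `r_early` um/min while longer
#' than `L_inflection` and at `r_late` um/min below it (the fast phase;
#' disabled when `enter_fast_phase = FALSE`, emulating mutants that never
#' accelerate). Trajectories can end by closure (length reaches 0), by a
#' tear between epidermis and amnioserosa (probability `p_tear`, at a
#' length drawn from a truncated normal), or by arrest (probability
#' `p_arrest`, shortening stops at a drawn length).
#'
#' @param genotype_label Character label attached to generated trajectories.
#' @param r_early,r_late Shortening rates, um/min (non-negative). `r_late`
#'   is ignored when `enter_fast_phase = FALSE`.
#' @param L_inflection Length (um) at which the fast phase begins; the rate
#'   applied over a frame interval is `r_early` while the current length
#'   exceeds this threshold, `r_late` otherwise. Default 190.
#' @param L_start_range Length-pair (um); the starting hole length is drawn
#'   uniformly from this interval. Default `c(220, 230)`.
#' @param frame_interval Time between frames, minutes. Default 10.
#' @param noise_sigma SD (um) of additive Gaussian measurement noise on the
#'   recorded lengths (the underlying process is noiseless). Default 2.
#' @param p_tear Probability that the embryo tears during closure.
#' @param tear_length_mean,tear_length_sd Mean/SD (um) of the hole length at
#'   which a tear triggers, truncated to (0, starting length).
#' @param p_anterior_tear Probability a tear occurs on the anterior half.
#' @param p_arrest Probability the embryo arrests before closing.
#' @param arrest_length_mean,arrest_length_sd Mean/SD (um) of the length at
#'   which shortening stops, truncated to (0, `L_inflection`).
#' @param enter_fast_phase Logical; when `FALSE` the late rate equals
#'   `r_early` (the embryo never accelerates).
#' @param max_time Maximum imaging time, minutes; trajectories that neither
#'   close nor tear are truncated here. Default 720.
#'
#' @return An object of class `closure_params` (a validated list).
#' @seealso [closure_preset()] for published genotype presets,
#'   [simulate_closure_trajectory()], [simulate_cohort()].
#' @export
closure_params <- function(genotype_label = "custom",
                           r_early = 0.64,
                           r_late = 1.88,
                           L_inflection = 190,
                           L_start_range = c(220, 230),
                           frame_interval = 10,
                           noise_sigma = 2,
                           p_tear = 0,
                           tear_length_mean = 120,
                           tear_length_sd = 30,
                           p_anterior_tear = 0.7,
                           p_arrest = 0,
                           arrest_length_mean = 120,
                           arrest_length_sd = 30,
                           enter_fast_phase = TRUE,
                           max_time = 720) {
  check_number(r_early, "r_early", lower = 0)
  check_number(r_late, "r_late", lower = 0)
  stop_if_not(is.numeric(L_start_range) && length(L_start_range) == 2L &&
                all(is.finite(L_start_range)) && L_start_range[1] > 0 &&
                L_start_range[1] <= L_start_range[2],
              "`L_start_range` must be an increasing positive length pair")
  check_number(L_inflection, "L_inflection",
               lower = .Machine$double.eps, upper = max(L_start_range))
  stop_if_not(frame_interval > 0, "`frame_interval` must be positive")
  check_number(noise_sigma, "noise_sigma", lower = 0)
  check_probability(p_tear, "p_tear")
  check_probability(p_anterior_tear, "p_anterior_tear")
  check_probability(p_arrest, "p_arrest")
  check_number(tear_length_mean, "tear_length_mean", lower = 0)
  check_number(tear_length_sd, "tear_length_sd", lower = 0)
  check_number(arrest_length_mean, "arrest_length_mean", lower = 0)
  check_number(arrest_length_sd, "arrest_length_sd", lower = 0)
  stop_if_not(isTRUE(enter_fast_phase) || isFALSE(enter_fast_phase),
              "`enter_fast_phase` must be TRUE or FALSE")
  check_number(max_time, "max_time", lower = frame_interval)

  structure(list(
    genotype_label = as.character(genotype_label),
    r_early = r_early, r_late = r_late,
    L_inflection = L_inflection, L_start_range = L_start_range,
    frame_interval = frame_interval, noise_sigma = noise_sigma,
    p_tear = p_tear, tear_length_mean = tear_length_mean,
    tear_length_sd = tear_length_sd, p_anterior_tear = p_anterior_tear,
    p_arrest = p_arrest, arrest_length_mean = arrest_length_mean,
    arrest_length_sd = arrest_length_sd,
    enter_fast_phase = enter_fast_phase, max_time = max_time
  ), class = "closure_params")
}

#' Published genotype presets for closure kinetics
#'
#' Load one of the genotype presets shipped with the package
#' (`wild_type`, `cora4`, `Mcr1`, `NrxIV4304`). Presets carry the published
#' early/late shortening rates and tearing penetrance for each genotype;
#' parameters the source data do not constrain are documented in the preset
#' file (`system.file("extdata", "genotype_presets.yaml", package =
#' "dcquant")`). Any preset field can be overridden through `...`.
#'
#' @param name Preset name; see Details. `closure_preset()` with no
#'   arguments lists available presets.
#' @param ... Overrides passed on to [closure_params()] (e.g.
#'   `noise_sigma = 0`, `L_start_range = c(230, 230)`).
#' @return A `closure_params` object, or a character vector of preset names
#'   when `name` is missing.
#' @examples
#' closure_preset()
#' wt <- closure_preset("wild_type", noise_sigma = 0)
#' @export
closure_preset <- function(name, ...) {
  path <- system.file("extdata", "genotype_presets.yaml", package = "dcquant")
  presets <- yaml::read_yaml(path)
  if (missing(name)) return(names(presets))
  stop_if_not(name %in% names(presets),
              sprintf("unknown preset '%s'; available: %s", name,
                      paste(names(presets), collapse = ", ")))
  args <- utils::modifyList(presets[[name]], list(...))
  do.call(closure_params, args)
}
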