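# End-to-end demo pipeline ----------------------------------------------

#' Default pipeline configuration
#'
#' Nested list of per-stage parameters consumed by [run_pipeline()]. Any
#' subset can be overridden; unknown keys are rejected.
#'
#' @param seed Master seed; every stage derives its own seed from it.
#' @return A `run_config` list.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    kinetics = list(genotypes = c("wild_type", "cora4", "Mcr1", "NrxIV4304"),
                    n_embryos = 12L),
    ablation = list(groups = list(
      wild_type = list(D = 3, tau = 20),
      mutant = list(D = 3, tau = 20)),
      n_cuts = 8L, noise_sigma = 0.05),
    shapes = list(n_rows = 3L, n_cols = 10L,
                  defect_fraction_mutant = 0.3, n_embryos = 3L),
    intensity = list(n_embryos = 8L, mutant_decay = 0.885, B = 2000L,
                     image_shape = c(120L, 200L)),
    stats = list(p_defect = c(0.567, 0.701), n_scored = c(356L, 398L))
  ), class = "run_config")
}

check_config <- function(config) {
  ref <- default_config()
  stop_if_not(is.list(config), "`config` must be a list")
  unknown <- setdiff(names(config), names(ref))
  stop_if_not(length(unknown) == 0,
              sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  for (stage in setdiff(names(config), "seed")) {
    bad <- setdiff(names(config[[stage]]), names(ref[[stage]]))
    stop_if_not(length(bad) == 0,
                sprintf("unknown config key(s) in '%s': %s", stage,
                        paste(bad, collapse = ", ")))
  }
  invisible(config)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Run the full demonstration pipeline
#'
#' Executes all six stages on synthetic data — simulate, kinetics,
#' ablation, shapes, intensity, stats — writing per-stage CSV/JSON outputs
#' and a machine-readable `summary.json` (carrying the config hash, seed
#' and per-stage key results) into `out_dir`. Fully deterministic given
#' `(config, seed)`.
#'
#' @param config A [default_config()]-style list (partial overrides are
#'   merged over the defaults).
#' @param out_dir Output directory (created if needed).
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("dcq_")) {
  config <- utils::modifyList(default_config(), check_config(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 6L)
  hash <- config_hash(config)
  summary <- list(config_hash = hash, seed = config$seed, stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  # --- simulate + kinetics
  cohorts <- stage("simulate", {
    ck <- config$kinetics
    unlist(lapply(seq_along(ck$genotypes), function(i) {
      simulate_cohort(closure_preset(ck$genotypes[i]), ck$n_embryos,
                      seed = seeds[1] + i)
    }), recursive = FALSE)
  })
  write_trajectories(cohorts, file.path(out_dir, "trajectories.csv"))
  summary$stages$simulate <- list(n_trajectories = length(cohorts))

  kin <- stage("kinetics", summarize_cohort(cohorts))
  utils::write.csv(kin, file.path(out_dir, "kinetics_summary.csv"),
                   row.names = FALSE)
  summary$stages$kinetics <- list(
    genotypes = kin$genotype, mean_r_early = kin$mean_r_early,
    mean_r_late = kin$mean_r_late, f_torn = kin$f_torn)

  # --- ablation
  abl <- stage("ablation", {
    ca <- config$ablation
    series <- list(); gidx <- 0L
    for (g in names(ca$groups)) {
      gidx <- gidx + 1L
      pars <- ablation_params(D = ca$groups[[g]]$D, tau = ca$groups[[g]]$tau,
                              noise_sigma = ca$noise_sigma)
      for (i in seq_len(ca$n_cuts)) {
        series[[length(series) + 1L]] <- simulate_recoil(
          pars, seed = seeds[2] + gidx * 1000L + i,
          series_id = sprintf("%s_cut%02d", g, i), genotype = g)
      }
    }
    fits <- lapply(series, fit_kelvin_voigt)
    vel <- vapply(series, function(s) recoil_velocity(s)$v, numeric(1))
    tab <- data.frame(
      series_id = vapply(series, function(s) s$series_id, character(1)),
      genotype = vapply(series, function(s) s$genotype, character(1)),
      recoil_velocity_um_s = vel,
      D_um = vapply(fits, function(f) f$D_hat, numeric(1)),
      tau_s = vapply(fits, function(f) f$tau_hat, numeric(1)),
      stringsAsFactors = FALSE)
    cmp <- compare_mechanics(tab$tau_s, tab$genotype)
    list(series = series, tab = tab, cmp = cmp)
  })
  write_recoil_series(abl$series, file.path(out_dir, "recoil_series.csv"))
  utils::write.csv(abl$tab, file.path(out_dir, "ablation_fits.csv"),
                   row.names = FALSE)
  utils::write.csv(abl$cmp, file.path(out_dir, "ablation_comparison.csv"),
                   row.names = FALSE)
  summary$stages$ablation <- list(
    mean_tau_s = mean(abl$tab$tau_s), welch_p = abl$cmp$p[1])

  # --- shapes
  shp <- stage("shapes", {
    cs <- config$shapes
    cells <- list()
    for (i in seq_len(cs$n_embryos)) {
      wt <- simulate_epithelium(
        epithelium_params(n_rows = cs$n_rows, n_cols = cs$n_cols),
        seed = seeds[3] + i, embryo_id = sprintf("wt_%d", i),
        genotype = "wild_type")
      mut <- simulate_epithelium(
        epithelium_params(n_rows = cs$n_rows, n_cols = cs$n_cols,
                          defect_fraction = cs$defect_fraction_mutant),
        seed = seeds[3] + 100L + i, embryo_id = sprintf("mut_%d", i),
        genotype = "mutant")
      cells <- c(cells, wt$cells, mut$cells)
    }
    tab <- build_table(cells)
    pca <- run_pca(tab)
    cmp <- compare_descriptors(tab, "genotype")
    list(cells = cells, tab = tab, pca = pca, cmp = cmp)
  })
  write_cell_polygons(shp$cells, file.path(out_dir, "cell_polygons.json"))
  utils::write.csv(shp$tab, file.path(out_dir, "shape_descriptors.csv"),
                   row.names = FALSE)
  utils::write.csv(shp$cmp, file.path(out_dir, "shape_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(pc = seq_along(shp$pca$variance_fraction),
               variance_fraction = shp$pca$variance_fraction),
    file.path(out_dir, "pca_variance.csv"), row.names = FALSE)
  summary$stages$shapes <- list(
    n_cells = nrow(shp$tab),
    pc1_variance_fraction = shp$pca$variance_fraction[1],
    n_significant = sum(shp$cmp$significant))

  # --- intensity
  intens <- stage("intensity", {
    ci <- config$intensity
    render_group <- function(genotype, decay, seed0) {
      lapply(seq_len(ci$n_embryos), function(i) {
        ep <- simulate_epithelium(
          epithelium_params(n_rows = 2L, n_cols = 5L),
          seed = seed0 + i, embryo_id = sprintf("%s_%d", genotype, i),
          genotype = genotype)
        render_junction_stack(
          ep$cells,
          stack_params(image_shape = ci$image_shape, intensity_decay = decay,
                       noise_model = "gaussian"),
          seed = seed0 + 500L + i,
          embryo_id = sprintf("%s_%d", genotype, i), genotype = genotype)
      })
    }
    wt <- render_group("wild_type", 1, seeds[4])
    mut <- render_group("mutant", ci$mutant_decay, seeds[4] + 10000L)
    meas <- measure_intensity(c(wt, mut),
                              n_cells = rep(10L, 2L * ci$n_embryos))
    bt <- bootstrap_compare(meas$normalized[meas$genotype == "wild_type"],
                            meas$normalized[meas$genotype == "mutant"],
                            B = ci$B, seed = seeds[4] + 99L)
    list(meas = meas, bt = bt)
  })
  utils::write.csv(intens$meas, file.path(out_dir, "intensity_measurements.csv"),
                   row.names = FALSE)
  summary$stages$intensity <- list(
    mean_normalized = tapply(intens$meas$normalized, intens$meas$genotype, mean),
    bootstrap_p = intens$bt$p_value)

  # --- stats
  sts <- stage("stats", {
    cs <- config$stats
    k1 <- simulate_cuticle_counts(cs$p_defect[1], cs$n_scored[1], seeds[5])
    k2 <- simulate_cuticle_counts(cs$p_defect[2], cs$n_scored[2], seeds[5] + 1L)
    tb <- two_by_two(k1, cs$n_scored[1] - k1, k2, cs$n_scored[2] - k2)
    pen <- penetrance(k1, cs$n_scored[1])
    list(tb = tb, pen = pen)
  })
  jsonlite::write_json(
    list(p1_percent = sts$tb$p1, p2_percent = sts$tb$p2,
         exact_p = sts$tb$exact_p, asymptotic_p = sts$tb$asymptotic_p,
         odds_ratio = sts$tb$odds_ratio),
    file.path(out_dir, "phenotype_stats.json"), auto_unbox = TRUE, digits = NA)
  summary$stages$stats <- list(
    p1_percent = sts$tb$p1, p2_percent = sts$tb$p2,
    exact_p = sts$tb$exact_p)

  summary$n_stages <- length(summary$stages)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
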