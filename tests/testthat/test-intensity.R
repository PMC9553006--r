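# Stack rendering, integrated density, normalization, bootstrap test

test_that("stacks render ridges whose sum matches the boundary pixel count", {
  # no cells, zero background: all-zero stack
  p0 <- stack_params(image_shape = c(50, 50), background = 0)
  st0 <- render_junction_stack(list(), p0, seed = 1)
  expect_true(all(st0$voxels == 0))
  expect_equal(integrated_density(st0), 0)

  # one rectangular cell, noise off: sum = boundary pixels x intensity x slices
  cell <- cell_polygon(cbind(c(2, 8, 8, 2), c(2, 2, 9, 9)))
  p1 <- stack_params(image_shape = c(60, 60), pixel_size = 0.2,
                     background = 0, junction_intensity = 100)
  st1 <- render_junction_stack(list(cell), p1, seed = 1)
  mask <- dcquant:::junction_mask(list(cell), c(60, 60), 0.2, 3)
  expect_equal(sum(st1$voxels), sum(mask) * 100 * 9)
  expect_gt(sum(mask), 0)

  # determinism with noise on
  pn <- stack_params(image_shape = c(50, 50), noise_model = "poisson")
  a <- render_junction_stack(list(cell), pn, seed = 5)
  b <- render_junction_stack(list(cell), pn, seed = 5)
  expect_identical(a$voxels, b$voxels)

  # cells outside the image bounds are rejected
  expect_error(render_junction_stack(
    list(cell_polygon(cbind(c(0, 100, 100), c(0, 0, 100)))), p1, seed = 1),
    "bounds")
})

test_that("integrated density sums the ROI and is additive", {
  st <- list(voxels = array(1, dim = c(9, 100, 100)), pixel_size = 0.2,
             z_step = 0.3, embryo_id = "e", genotype = "g")
  class(st) <- "zstack_image"
  expect_equal(integrated_density(st), 90000)
  expect_equal(integrated_density(st, roi = c(1, 10, 1, 10), slices = 1), 100)

  # additive over disjoint ROIs and disjoint slice sets
  left <- integrated_density(st, roi = c(1, 50, 1, 100))
  right <- integrated_density(st, roi = c(51, 100, 1, 100))
  expect_equal(left + right, integrated_density(st))
  s14 <- integrated_density(st, slices = 1:4)
  s59 <- integrated_density(st, slices = 5:9)
  expect_equal(s14 + s59, integrated_density(st))

  expect_error(integrated_density(st, roi = c(0, 10, 1, 10)), "bounds")
  expect_error(integrated_density(st, slices = integer(0)), "empty")
})

test_that("per-cell normalization divides by the cell count", {
  expect_equal(normalize_per_cell(90000, 5), 18000)
  expect_equal(normalize_per_cell(123, 1), 123)
  # equal sums, cell counts 10 vs 20: normalized ratio 2
  expect_equal(normalize_per_cell(6000, 10) / normalize_per_cell(6000, 20), 2)
  expect_error(normalize_per_cell(10, 0), ">= 1")
})

test_that("measure_intensity enforces equal ROI areas", {
  st <- function(id) {
    x <- list(voxels = array(1, dim = c(3, 20, 20)), pixel_size = 0.2,
              z_step = 0.3, embryo_id = id, genotype = "g")
    class(x) <- "zstack_image"
    x
  }
  stacks <- list(st("a"), st("b"))
  rois <- list(c(1, 10, 1, 10), c(1, 5, 1, 5))
  expect_error(measure_intensity(stacks, rois, n_cells = c(4, 4)),
               "ROI areas differ")
  m <- measure_intensity(stacks, rois, n_cells = c(4, 4),
                         allow_unequal_roi = TRUE)
  expect_equal(m$normalized, c(300 / 4, 75 / 4))
})

test_that("the bootstrap test is exact on ties, reproducible and powered", {
  const <- rep(3, 6)
  bt <- bootstrap_compare(const, const, B = 999, seed = 1)
  expect_equal(bt$statistic_observed, 0)
  expect_equal(bt$p_value, 1)

  x <- rnorm(8); y <- rnorm(8)
  expect_identical(bootstrap_compare(x, y, B = 999, seed = 3)$p_value,
                   bootstrap_compare(x, y, B = 999, seed = 3)$p_value)
  expect_gte(bt$p_value, 1 / 1000)

  set.seed(8)
  sep <- bootstrap_compare(rnorm(8, 0, 1), rnorm(8, 5, 1), B = 1999, seed = 4)
  expect_lte(sep$p_value, 0.01)

  expect_error(bootstrap_compare(1:2, 1:5), "n >= 3")
})

test_that("bootstrap p decreases along a mean-shift family", {
  set.seed(15)
  base <- rnorm(10)
  # same dispersion, growing mean separation, identical resampling seed:
  # the null distribution is fixed, so p must be non-increasing
  ps <- vapply(c(0, 0.5, 1, 2, 4), function(shift)
    bootstrap_compare(base, base + shift, B = 1999, seed = 9)$p_value,
    numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("mutant-mode stacks show reduced normalized intensity end to end", {
  render_group <- function(genotype, decay, seed0, n = 6) {
    lapply(seq_len(n), function(i) {
      ep <- simulate_epithelium(epithelium_params(n_rows = 2, n_cols = 4),
                                seed = seed0 + i, genotype = genotype,
                                embryo_id = sprintf("%s_%d", genotype, i))
      render_junction_stack(
        ep$cells, stack_params(image_shape = c(135, 135),
                               intensity_decay = decay,
                               noise_model = "gaussian"),
        seed = seed0 + 100 + i, genotype = genotype,
        embryo_id = sprintf("%s_%d", genotype, i))
    })
  }
  wt <- render_group("wild_type", 1, 1000)
  mut <- render_group("mutant", 0.885, 2000)
  m <- measure_intensity(c(wt, mut), n_cells = rep(8L, 12))
  a <- m$normalized[m$genotype == "wild_type"]
  b <- m$normalized[m$genotype == "mutant"]
  expect_gt(mean(a), mean(b))
  bt <- bootstrap_compare(a, b, B = 1999, seed = 5)
  expect_lt(bt$p_value, 0.05)
})
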