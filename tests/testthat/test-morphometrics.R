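# Shape descriptors: closed forms, invariances, raster oracle

test_that("an axis-aligned 10 x 30 rectangle reproduces all closed forms", {
  rect <- cell_polygon(cbind(c(0, 10, 10, 0), c(0, 0, 30, 30)))
  d <- shape_descriptors(rect)
  expect_equal(d$height, 30)
  expect_equal(d$width, 10)
  expect_equal(d$area, 300)
  expect_equal(d$perimeter, 80)
  expect_equal(d$circularity, 4 * pi * 300 / 80^2, tolerance = 1e-12)
  expect_equal(d$aspect_ratio, 3, tolerance = 1e-12)
  expect_equal(d$feret, sqrt(1000), tolerance = 1e-12)
  expect_equal(d$min_feret, 10, tolerance = 1e-12)
  expect_equal(d$solidity, 1, tolerance = 1e-12)
  expect_equal(d$angle, 90)
  # equivalent ellipse: same moments, rescaled to area 300
  expect_equal(d$ellipse_major / d$ellipse_minor, 3, tolerance = 1e-12)
  expect_equal(pi * d$ellipse_major * d$ellipse_minor / 4, 300,
               tolerance = 1e-9)
  expect_equal(d$roundness, 4 * 300 / (pi * d$ellipse_major^2),
               tolerance = 1e-12)
})

test_that("a 360-gon behaves like a circle", {
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  d <- shape_descriptors(cell_polygon(cbind(5 * cos(th), 5 * sin(th))))
  expect_equal(d$circularity, 1, tolerance = 1e-3)
  expect_equal(d$roundness, 1, tolerance = 1e-3)
  expect_equal(d$aspect_ratio, 1, tolerance = 1e-3)
  expect_equal(d$solidity, 1, tolerance = 1e-3)
  expect_equal(d$feret, 10, tolerance = 1e-3)
  expect_equal(d$min_feret, 10, tolerance = 1e-3)
})

test_that("descriptors scale, rotate and reflect as geometry dictates", {
  set.seed(5)
  v <- random_star_polygon(14)
  d0 <- shape_descriptors(cell_polygon(v))

  d2 <- shape_descriptors(cell_polygon(v * 2.5))
  for (nm in c("height", "width", "perimeter", "feret", "min_feret",
               "ellipse_major", "ellipse_minor"))
    expect_equal(d2[[nm]], 2.5 * d0[[nm]], tolerance = 1e-9)
  expect_equal(d2$area, 2.5^2 * d0$area, tolerance = 1e-9)
  for (nm in c("circularity", "roundness", "aspect_ratio", "solidity",
               "angle", "feret_angle"))
    expect_equal(d2[[nm]], d0[[nm]], tolerance = 1e-9)

  ang <- 35 * pi / 180
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  d3 <- shape_descriptors(cell_polygon(v %*% t(R)))
  for (nm in c("area", "perimeter", "feret", "min_feret", "aspect_ratio",
               "circularity", "roundness", "solidity"))
    expect_equal(d3[[nm]], d0[[nm]], tolerance = 1e-9)
  expect_equal((d3$angle - d0$angle) %% 180, 35, tolerance = 1e-6)
})

test_that("polygon-exact moments match the raster oracle on random shapes", {
  set.seed(42)
  for (i in 1:20) {
    v <- random_star_polygon(n = sample(6:16, 1))
    d <- shape_descriptors(cell_polygon(v))
    ref <- raster_moments(v, resolution = 500)
    axes <- ellipse_axes_from_cov(ref$cov, ref$area)
    expect_equal(d$area, ref$area, tolerance = 0.01)
    expect_equal(d$ellipse_major, unname(axes["major"]), tolerance = 0.01)
    expect_equal(d$ellipse_minor, unname(axes["minor"]), tolerance = 0.01)
  }
})

test_that("degenerate polygons are rejected", {
  expect_error(cell_polygon(cbind(c(0, 1, 2), c(0, 1, 2))), "zero area")
  bowtie <- cbind(c(0, 4, 4, 2, 0), c(0, 0, 3, -1, 3))  # nonzero net area
  expect_error(cell_polygon(bowtie), "self-intersecting")
  expect_error(cell_polygon(cbind(0, 1)), "3 rows")
})

test_that("the morphometrics table keeps labels, order and uniqueness", {
  sq <- function(id) cell_polygon(cbind(c(0, 5, 5, 0), c(0, 0, 5, 5)),
                                  cell_id = id, genotype = "wt")
  tab <- build_table(list(sq("a"), sq("b")))
  expect_equal(nrow(tab), 2)
  expect_identical(names(tab)[5:18], descriptor_names())
  expect_equal(unlist(tab[1, 5:18]), unlist(tab[2, 5:18]))
  expect_error(build_table(list()), "non-empty")
  expect_error(build_table(list(sq("a"), sq("a"))), "duplicate")
})
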