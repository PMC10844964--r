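test_that("signed distance matches closed forms on a circular nest", {
  g <- geometry_discs("s1", c(1000, 1000), cbind(500, 500), 100)
  cells <- make_cells(c(500, 650, 500, 100), c(500, 500, 620, 500),
                      id = c("center", "out50", "out20", "far"))
  d <- signed_distance(cells, g)
  expect_equal(unname(d), c(-100, 50, 20, 300), tolerance = 1e-9)
})

test_that("signed distance via polygon half-plane matches |x - 500|", {
  # tumor occupies x < 500; other polygon edges pushed far away
  poly <- rbind(c(-5000, -5000), c(500, -5000), c(500, 6000), c(-5000, 6000))
  g <- geometry_polygons("s1", c(1000, 1000), list(poly))
  set.seed(2)
  x <- runif(200, 200, 800); y <- runif(200, 300, 700)
  d <- signed_distance(make_cells(x, y), g)
  expect_equal(unname(d), ifelse(x < 500, -(500 - x), x - 500),
               tolerance = 1e-9)
})

test_that("polygon distances match a dense boundary-sampling oracle", {
  set.seed(8)
  ang <- seq(0, 2 * pi, length.out = 13)[-13]
  poly <- cbind(900 + (150 + runif(12, -60, 60)) * cos(ang),
                1100 + (150 + runif(12, -60, 60)) * sin(ang))
  g <- geometry_polygons("s1", c(2000, 2000), list(poly))
  x <- runif(100, 500, 1400); y <- runif(100, 700, 1500)
  d <- signed_distance(make_cells(x, y), g)
  expect_equal(abs(unname(d)), oracle_poly_distance(x, y, poly),
               tolerance = 0.2)
})

test_that("mask-based signed distance agrees with the closed form", {
  g <- geometry_discs("s1", c(1000, 1000), cbind(500, 500), 200)
  gm <- rasterize_geometry(g, res = 2)
  set.seed(4)
  cells <- make_cells(runif(300, 10, 990), runif(300, 10, 990))
  dm <- signed_distance(cells, gm)
  dc <- signed_distance(cells, g)
  expect_lt(max(abs(dm - dc)), 3)          # raster tolerance ~1.5 px
  expect_gt(mean(sign(dm) == sign(dc)), 0.99)
})

test_that("geometry error paths and frame flagging", {
  g0 <- geometry_discs("s1", c(1000, 1000), cbind(500, 500), 100)
  g0$discs <- g0$discs[0, ]
  expect_error(signed_distance(make_cells(1, 1), g0), "no boundary")
  g <- geometry_discs("s2", c(1000, 1000), cbind(500, 500), 100)
  bad <- make_cells(1, 1, sample_id = "other")
  expect_error(signed_distance(bad, g), "sample_id")
  out <- make_cells(c(500, 2000), c(500, 500), sample_id = "s2")
  expect_warning(d <- signed_distance(out, g), "outside")
  expect_true(is.na(d[2]) && !is.na(d[1]))
})

test_that("band areas: half-plane rectangle and out-of-frame bands", {
  # 1 x 1 mm frame, tumor occupies x < 500 um (mask representation)
  mask <- matrix(1L, 250, 250)
  mask[, 1:125] <- 2L
  g <- geometry_mask("s1", mask, 4)
  a <- band_areas(g, c(0, 100), res = 4)
  expect_equal(a, 0.1, tolerance = 0.02)
  expect_equal(band_areas(g, c(2000, 2100), res = 4), 0)
})

test_that("band areas match analytic annuli on a disc", {
  g <- geometry_discs("s1", c(2000, 2000), cbind(1000, 1000), 100)
  expect_equal(band_areas(g, c(-100, 0), method = "raster"),
               pi * 100^2 / 1e6, tolerance = 0.02)
  edges <- seq(-100, 200, by = 25)
  a_r <- band_areas(g, edges, method = "raster")
  a_a <- band_areas(g, edges, method = "analytic")
  expect_equal(a_r, a_a, tolerance = 0.02)
  # auto picks the analytic path when clearance allows
  expect_identical(band_areas(g, edges), a_a)
  expect_error(band_areas(g, edges, res = 10), "resolution")
})

test_that("compartment areas and mask round trip", {
  g <- geometry_discs("s1", c(3000, 3000), cbind(1500, 1500), 300)
  ca <- compartment_areas(g)
  expect_equal(unname(ca["EPI_TUMOR"]), pi * 0.09, tolerance = 1e-9)
  expect_equal(sum(ca), 9)
  gm <- rasterize_geometry(g, 2)
  expect_equal(unname(compartment_areas(gm)["EPI_TUMOR"]), pi * 0.09,
               tolerance = 0.01)
  f <- tempfile(fileext = ".csv")
  write_geometry_mask(gm, f)
  back <- read_geometry_mask(f, "s1", 2)
  expect_identical(back$mask, gm$mask)

  gp <- geometry_polygons("s1", c(1000, 1000),
                          list(rbind(c(100, 100), c(400, 120), c(350, 420),
                                     c(120, 380))))
  fp <- tempfile(fileext = ".geojson")
  write_geometry_polygons(gp, fp)
  backp <- read_geometry_polygons(fp, "s1")
  expect_equal(backp$polygons[[1]], gp$polygons[[1]], tolerance = 1e-12)
  expect_equal(backp$frame_um, gp$frame_um)
})
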