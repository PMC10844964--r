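test_that("geometry generation is deterministic and respects clearance", {
  cfg <- synthetic_config(seed = 5)
  g1 <- generate_geometry(cfg, "S1")
  g2 <- generate_geometry(cfg, "S1")
  expect_identical(g1, g2)
  d <- g1$discs
  ext <- cfg$nest_clearance_um
  expect_true(all(d$cx - d$r - ext >= 0 &
                    d$cx + d$r + ext <= g1$frame_um[1]))
  # a central 300 um disc has area pi * 0.09 mm2
  gd <- geometry_discs("S1", c(3000, 3000), cbind(1500, 1500), 300)
  expect_equal(unname(compartment_areas(gd)["EPI_TUMOR"]), pi * 0.09,
               tolerance = 1e-12)
})

test_that("zero nests produce an all-stroma geometry with no boundary", {
  cfg <- synthetic_config(seed = 5, n_nests = 0)
  g <- generate_geometry(cfg, "S1")
  expect_error(signed_distance(make_cells(10, 10, sample_id = "S1"), g),
               "no boundary")
  expect_error(band_areas(g, c(0, 100)), "no boundary")
})

test_that("impossible nest requests fail with guidance", {
  cfg <- synthetic_config(seed = 5, n_nests = 3,
                          nest_radius_um = c(900, 1000))
  expect_error(generate_geometry(cfg), "fewer or smaller nests")
})

test_that("uniform subset counts follow the Poisson expectation", {
  g <- geometry_discs("S1", c(3000, 3000), cbind(1500, 1500), 300)
  stroma_mm2 <- 9 - pi * 0.09
  cfg <- synthetic_config(
    seed = 610,
    subsets = list(U = list(model = "uniform", lambda = 100,
                            compartment = "stroma")),
    markers = "CD68")
  sc <- sample_cells(cfg, g)
  expected <- 100 * stroma_mm2
  expect_lt(abs(nrow(sc$cells) - expected), 3 * sqrt(expected))
  expect_true(all(sc$truth$true_d >= 0))
  # lambda = 0 yields no cells of that label
  cfg0 <- synthetic_config(
    seed = 611,
    subsets = list(U = list(model = "uniform", lambda = 0,
                            compartment = "stroma"),
                   V = list(model = "uniform", lambda = 50,
                            compartment = "stroma")),
    markers = "CD68")
  sc0 <- sample_cells(cfg0, g)
  expect_false("U" %in% sc0$truth$true_type)
  expect_true("V" %in% sc0$truth$true_type)
})

test_that("all-zero intensities warn and return an empty cohort", {
  g <- geometry_discs("S1", c(3000, 3000), cbind(1500, 1500), 300)
  cfg <- synthetic_config(
    seed = 612,
    subsets = list(U = list(model = "uniform", lambda = 0,
                            compartment = "stroma")),
    markers = "CD68")
  expect_warning(sc <- sample_cells(cfg, g), "empty cohort")
  expect_equal(nrow(sc$cells), 0)
})

test_that("emitted tables are byte-identical across reruns of one config", {
  cfg <- synthetic_config(seed = 99, survival = list(n_patients = 3))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  c1 <- generate_cohort(cfg); c2 <- generate_cohort(cfg)
  write_cell_table(c1$cells, f1); write_cell_table(c2$cells, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$band_density, c2$band_density)
})

test_that("ground truth is consistent with the pipeline's spatial calls", {
  cfg <- synthetic_config(seed = 120, survival = list(n_patients = 2))
  coh <- generate_cohort(cfg)
  s <- names(coh$geoms)[1]
  cells_s <- coh$cells[coh$cells$sample_id == s, ]
  truth_s <- coh$truth[coh$truth$sample_id == s, ]
  # closed-form path agrees exactly
  d <- signed_distance(cells_s, coh$geoms[[s]])
  expect_equal(unname(d), truth_s$true_d, tolerance = 1e-9)
  # raster path agrees in sign for cells >= 1 um from the boundary
  gm <- rasterize_geometry(coh$geoms[[s]], 2)
  dm <- signed_distance(cells_s, gm)
  off <- abs(truth_s$true_d) >= 1
  expect_gte(mean(sign(dm[off]) == sign(truth_s$true_d[off])), 0.999)
  # tissue class matches the sign of the true distance
  expect_identical(as.character(cells_s$tissue_class),
                   ifelse(truth_s$true_d < 0, "EPI_TUMOR", "STROMA"))
})

test_that("marker intensities reflect the configured components", {
  cfg <- synthetic_config(seed = 130)
  g <- generate_geometry(cfg, "S1")
  sc <- sample_cells(cfg, g)
  tumor <- sc$truth$true_type == "Tumor"
  expect_gt(median(log10(sc$cells$CK[tumor])), 2)
  expect_lt(median(log10(sc$cells$CK[!tumor])), 1.5)
  # checkpoint hi cells have hi-component intensities
  hi <- sc$truth$true_PDL1_hi
  expect_gt(median(log10(sc$cells$PDL1[hi])),
            median(log10(sc$cells$PDL1[!hi])) + 1)
  expect_true(all(sc$cells$confidence >= 0 & sc$cells$confidence <= 1))
})

test_that("survival sampler honours its contracts", {
  cfg <- synthetic_config(seed = 140,
                          survival = list(censor_rate = 0, n_patients = 40))
  dens <- setNames(rlnorm(40, log(50), 0.5), sprintf("P%03d", 1:40))
  cl <- sample_survival(cfg, dens)
  expect_true(all(cl$event))           # no censoring -> all events
  expect_true(all(cl$time_months > 0))
  cfg2 <- synthetic_config(seed = 140, survival = list(h0 = 0))
  expect_error(sample_survival(cfg2, dens), "h0")
  # beta = 0: linear predictor is flat
  cfg3 <- synthetic_config(seed = 141,
                           survival = list(beta = 0, n_patients = 40))
  cl3 <- sample_survival(cfg3, dens)
  expect_true(all(cl3$lp == 0))
})

test_that("boundary_exp profiles decay with the configured length", {
  cfg <- synthetic_config(
    seed = 150,
    subsets = list(M = list(model = "boundary_exp", lambda0 = 2000,
                            tau = 50, side = "stroma")),
    markers = "CD68")
  cells <- NULL; geoms <- list()
  for (k in 1:6) {
    sid <- paste0("S", k)
    g <- generate_geometry(cfg, sid, seed = cfg$seed + k)
    geoms[[sid]] <- g
    sc <- sample_cells(cfg, g, seed = cfg$seed + 100 + k)
    cells <- rbind(cells, sc$cells)
  }
  attr(cells, "markers") <- "CD68"
  prof <- density_profile(cells, geoms)
  st <- prof$centers > 0 & prof$centers < 250 & prof$mean_density > 0
  fit <- stats::lm(log(prof$mean_density[st]) ~ prof$centers[st])
  tau_hat <- -1 / unname(stats::coef(fit)[2])
  expect_lt(abs(tau_hat - 50) / 50, 0.25)
})
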