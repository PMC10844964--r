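test_that("gmm2 threshold lands at the equal-posterior crossing", {
  set.seed(42)
  n <- 10000
  comp <- rbinom(n, 1, 0.5)
  x <- 10^rnorm(n, ifelse(comp == 1, 2.5, 1.0), 0.2)
  fit <- fit_marker_threshold(x, marker = "CD68")
  expect_s3_class(fit, "threshold_fit")
  expect_gte(fit$threshold, 10^1.6)
  expect_lte(fit$threshold, 10^1.9)
  expect_false(fit$diagnostics$fallback)
  # oracle: numeric root of the equal-posterior equation of the TRUE mixture
  g <- function(t) dnorm(t, 1.0, 0.2) - dnorm(t, 2.5, 0.2)
  t_true <- uniroot(g, c(1.0, 2.5))$root
  expect_equal(log10(fit$threshold + 1), t_true, tolerance = 0.05)
})

test_that("fixed method ignores the data", {
  expect_equal(fit_marker_threshold(c(1, 2, 3), method = "fixed",
                                    params = list(value = 7))$threshold, 7)
})

test_that("degenerate single cluster falls back to mean + k SD", {
  set.seed(5)
  x <- 10^rnorm(1000, 1.0, 0.05)
  fit <- fit_marker_threshold(x, marker = "CD68")
  expect_equal(fit$method, "mean_sd")
  expect_true(isTRUE(fit$diagnostics$fallback))
  l <- log10(x + 1)
  expect_equal(fit$threshold, 10^(mean(l) + 2 * sd(l)) - 1, tolerance = 1e-8)
  expect_error(fit_marker_threshold(rep(3, 100)), "all intensities equal")
  expect_error(fit_marker_threshold(1:20, method = "gmm2"), ">= 50")
})

test_that("CD68/CD163 classification follows the strict-hi rule", {
  cells <- make_cells(1:3, 1:3, CD68 = c(100, 50, 10), CD163 = c(5, 60, 60))
  lab <- classify_cd68_cd163(cells, 50, 50)
  expect_equal(as.character(lab),
               c("CD68hiCD163lo", "CD68loCD163hi", "CD68loCD163hi"))
  # exactly at threshold is lo
  at <- make_cells(1, 1, CD68 = 50, CD163 = 50)
  expect_equal(as.character(classify_cd68_cd163(at, 50, 50)),
               "CD68loCD163lo")
  expect_error(classify_cd68_cd163(make_cells(1, 1, CD68 = 1), 1, 1),
               "CD163")
})

test_that("classification counts match a brute-force tally and partition", {
  set.seed(9)
  n <- 10000
  cells <- make_cells(runif(n), runif(n),
                      CD68 = rlnorm(n, 3, 1), CD163 = rlnorm(n, 3, 1))
  t68 <- 20; t163 <- 35
  lab <- classify_cd68_cd163(cells, t68, t163)
  # independent vectorized double-comparison oracle
  tally <- c(
    CD68hiCD163lo = sum(cells$CD68 > t68 & !(cells$CD163 > t163)),
    CD68hiCD163hi = sum(cells$CD68 > t68 & cells$CD163 > t163),
    CD68loCD163hi = sum(!(cells$CD68 > t68) & cells$CD163 > t163),
    CD68loCD163lo = sum(!(cells$CD68 > t68) & !(cells$CD163 > t163)))
  expect_equal(as.vector(table(lab)[names(tally)]), unname(tally))
  expect_equal(sum(table(lab)), n)  # partition
  # monotonicity: raising the CD68 threshold never increases CD68hi counts
  for (thr in c(25, 40, 80)) {
    lab2 <- classify_cd68_cd163(cells, thr, t163)
    expect_lte(sum(grepl("^CD68hi", lab2)), sum(cells$CD68 > 25))
  }
  n_hi <- vapply(c(10, 20, 40, 80),
                 function(thr) sum(grepl("^CD68hi",
                                         classify_cd68_cd163(cells, thr,
                                                             t163))), 0)
  expect_true(all(diff(n_hi) <= 0))
})

test_that("checkpoint classification implements the threshold-0 split", {
  cells <- make_cells(1:3, 1:3, PDL1 = c(0, 0.8, 5))
  cls <- classify_checkpoint(cells, "PDL1", 0)
  expect_equal(as.character(cls), c("lo", "hi", "hi"))
  cls2 <- classify_checkpoint(cells, "PDL1", 5)
  expect_equal(as.character(cls2), c("lo", "lo", "lo"))
  expect_error(classify_checkpoint(cells, "PD1", 0), "PD1")
})

test_that("mixture thresholds recover ground-truth components", {
  set.seed(77)
  n <- 4000
  comp <- rbinom(n, 1, 0.4) == 1
  x <- 10^rnorm(n, ifelse(comp, 2.2, 1.0), 0.2)  # 6 SD apart
  fit <- fit_marker_threshold(x, marker = "m")
  mis <- mean((x > fit$threshold) != comp)
  expect_lt(mis, 0.05)
})

test_that("threshold fits serialize to JSON", {
  set.seed(1)
  x <- c(10^rnorm(200, 1, 0.2), 10^rnorm(200, 2.5, 0.2))
  fits <- list(fit_marker_threshold(x, marker = "CD68"),
               fit_marker_threshold(3 * x, marker = "CD163"))
  f <- tempfile(fileext = ".json")
  write_threshold_fits(fits, f)
  back <- jsonlite::read_json(f)
  expect_named(back, c("CD68", "CD163"))
  expect_equal(back$CD68$threshold, fits[[1]]$threshold, tolerance = 1e-12)
})
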