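test_that("exact Wilcoxon on the canonical fixtures", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p_raw, 0.1)          # 2 of the 20 rank assignments
  expect_equal(w$method, "exact")
  # identical multisets are perfectly exchangeable
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_raw, 1)
  # Bonferroni arithmetic
  w2 <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), family_size = 4)
  expect_equal(w2$p_adjusted, min(1, w2$p_raw * 4))
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "empty group")
})

test_that("exact Wilcoxon agrees with the subset-enumeration oracle", {
  set.seed(51)
  for (i in 1:8) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- round(runif(na, 0, 10), 1)
    b <- round(runif(nb, 0, 10), 1)
    expect_equal(wilcoxon_rank_sum(a, b)$p_raw, oracle_wilcoxon_p(a, b),
                 info = sprintf("case %d", i))
  }
})

test_that("large-sample Wilcoxon tracks the reference implementation", {
  set.seed(52)
  a <- rnorm(30); b <- rnorm(25, 0.5)
  w <- wilcoxon_rank_sum(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(w$p_raw, ref$p.value, tolerance = 1e-10)
  expect_equal(unname(w$statistic), unname(ref$statistic))
  # with ties
  a2 <- sample(1:5, 40, TRUE); b2 <- sample(2:6, 35, TRUE)
  ref2 <- suppressWarnings(stats::wilcox.test(a2, b2, exact = FALSE,
                                              correct = TRUE))
  expect_equal(wilcoxon_rank_sum(a2, b2)$p_raw, ref2$p.value,
               tolerance = 1e-10)
})

test_that("Bonferroni adjustment is monotone and capped", {
  ws <- lapply(c(1, 5, 50), function(fs)
    wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), family_size = fs))
  adj <- vapply(ws, `[[`, 0, "p_adjusted")
  expect_true(all(diff(adj) >= 0))
  expect_lte(max(adj), 1)
})

test_that("Spearman rho and exact permutation p", {
  expect_equal(spearman_cor(1:6, (1:6) * 2 + 3)$rho, 1)
  expect_equal(spearman_cor(1:6, rev(1:6))$rho, -1)
  s <- spearman_cor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(s$rho, 0.8)
  expect_equal(s$method, "exact_permutation")
  o <- oracle_spearman(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(s$p, o$p)
  expect_true(spearman_cor(rep(1, 10), 1:10)$flagged)
})

test_that("correlation screen handles missingness and flags", {
  set.seed(61)
  X <- cbind(f1 = rnorm(20), f2 = rnorm(20), f3 = rep(1, 20))
  X[1:3, 1] <- NA
  Y <- cbind(event = rbinom(20, 1, 0.5), time = rexp(20))
  rownames(X) <- rownames(Y) <- sprintf("P%02d", 1:20)
  sc <- spearman_screen(X, Y)
  expect_equal(nrow(sc), 6)
  expect_equal(sc$n[sc$feature == "f1"], c(17L, 17L))
  expect_true(all(sc$flagged[sc$feature == "f3"]))
  ok <- !is.na(sc$p)
  expect_true(all(sc$p_adjusted[ok] >= sc$p[ok]))
  expect_lte(max(sc$p_adjusted, na.rm = TRUE), 1)
})

test_that("median and threshold splits follow the tie rules", {
  ms <- median_split(c(A = 1, B = 2, C = 3, D = 4))
  expect_equal(ms$cutoff, 2.5)
  expect_setequal(ms$hi, c("C", "D"))
  expect_setequal(ms$lo, c("A", "B"))
  ms3 <- median_split(c(A = 1, B = 2, C = 3))
  expect_equal(ms3$hi, "C")          # tie at the median goes lo
  expect_setequal(ms3$lo, c("A", "B"))
  ts <- threshold_split(c(A = 0, B = 0, C = 1.7))
  expect_equal(ts$hi, "C")
  expect_setequal(ts$lo, c("A", "B"))
  deg <- median_split(c(A = 2, B = 2, C = 2))
  expect_true(deg$degenerate)
  expect_error(median_split(c(A = 1)), ">= 2")
})

test_that("log-rank fixtures: identical groups and hand-computed tables", {
  surv <- data.frame(patient_id = sprintf("P%d", 1:6),
                     time_months = c(2, 4, 6, 1, 3, 5),
                     event = rep(TRUE, 6))
  lr <- km_logrank(surv, sprintf("P%d", 1:3), sprintf("P%d", 4:6))
  expect_equal(lr$chi2, oracle_logrank_chi2(c(2, 4, 6), rep(TRUE, 3),
                                            c(1, 3, 5), rep(TRUE, 3)),
               tolerance = 1e-12)
  # independent reference: survival package
  sd <- survival::survdiff(survival::Surv(time_months, event) ~ grp,
                           data = cbind(surv, grp = rep(1:2, each = 3)))
  expect_equal(lr$chi2, sd$chisq, tolerance = 1e-9)

  # identical groups: observed equals expected
  surv2 <- data.frame(patient_id = sprintf("Q%d", 1:8),
                      time_months = rep(c(1, 2, 3, 4), 2),
                      event = rep(c(TRUE, TRUE, FALSE, TRUE), 2))
  lr2 <- km_logrank(surv2, sprintf("Q%d", 1:4), sprintf("Q%d", 5:8))
  expect_equal(lr2$chi2, 0)
  expect_equal(lr2$p, 1)
})

test_that("log-rank is invariant under swapping group labels", {
  set.seed(71)
  surv <- data.frame(patient_id = sprintf("P%02d", 1:30),
                     time_months = rexp(30, 0.05),
                     event = runif(30) < 0.7)
  hi <- sprintf("P%02d", 1:14); lo <- sprintf("P%02d", 15:30)
  a <- km_logrank(surv, hi, lo)
  b <- km_logrank(surv, lo, hi)
  expect_equal(a$chi2, b$chi2, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_equal(a$km$hi, b$km$lo)
  # matches the reference implementation on censored data too
  sd <- survival::survdiff(survival::Surv(time_months, event) ~ g,
                           data = cbind(surv, g = rep(1:2, c(14, 16))))
  expect_equal(a$chi2, sd$chisq, tolerance = 1e-9)
})

test_that("KM without censoring equals the empirical survival function", {
  t <- c(3, 1, 4, 1, 5, 9, 2, 6)
  km <- km_curve(t, rep(TRUE, 8))
  emp <- vapply(km$time, function(tt) mean(t > tt), 0)
  expect_equal(km$surv, emp, tolerance = 1e-12)
  # no events at all -> undefined p
  surv <- data.frame(patient_id = c("a", "b", "c", "d"),
                     time_months = 1:4, event = FALSE)
  lr <- km_logrank(surv, c("a", "b"), c("c", "d"))
  expect_true(is.na(lr$p))
})
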