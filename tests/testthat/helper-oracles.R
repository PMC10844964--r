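# Independent brute-force / closed-form oracles used across the suite.
# These deliberately avoid the package's own code paths.

# quick standardized cell table
make_cells <- function(x, y, sample_id = "s1", id = NULL, tissue = "STROMA",
                       conf = 1, area = NA_real_, ...) {
  n <- length(x)
  cells <- data.frame(sample_id = rep_len(sample_id, n),
                      cell_id = id %||% sprintf("c%04d", seq_len(n)),
                      x_um = x, y_um = y,
                      tissue_class = factor(rep_len(tissue, n),
                                            levels = c("EPI_TUMOR", "STROMA",
                                                       "OTHER")),
                      confidence = rep_len(conf, n),
                      phenotype = rep_len(NA_character_, n),
                      cell_area_um2 = rep_len(area, n),
                      stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) cells[[nm]] <- extra[[nm]]
  cells
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive nearest-neighbour distances (double loop)
oracle_nn <- function(xf, yf, xt, yt, excl = rep(0L, length(xf))) {
  sapply(seq_along(xf), function(i) {
    d <- sqrt((xt - xf[i])^2 + (yt - yf[i])^2)
    if (excl[i] > 0) d <- d[-excl[i]]
    min(d)
  })
}

# exhaustive pairwise contact counts
oracle_contacts <- function(xr, yr, rr, xp, yp, rp, slack,
                            excl = rep(0L, length(xr))) {
  sapply(seq_along(xr), function(i) {
    d <- sqrt((xp - xr[i])^2 + (yp - yr[i])^2)
    hit <- d <= rr[i] + rp + slack
    if (excl[i] > 0) hit[excl[i]] <- FALSE
    sum(hit)
  })
}

# distance to a polygon boundary by dense resampling of its edges
oracle_poly_distance <- function(x, y, poly, step = 0.05) {
  m <- nrow(poly)
  pts <- do.call(rbind, lapply(seq_len(m), function(e) {
    a <- poly[e, ]
    b <- poly[if (e == m) 1 else e + 1, ]
    len <- sqrt(sum((b - a)^2))
    t <- seq(0, 1, length.out = max(2, ceiling(len / step) + 1))
    cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }))
  out <- numeric(length(x))
  for (start in seq(1, length(x), by = 50)) {
    idx <- start:min(start + 49, length(x))
    d2 <- outer(x[idx], pts[, 1], "-")^2 + outer(y[idx], pts[, 2], "-")^2
    out[idx] <- sqrt(apply(d2, 1, min))
  }
  out
}

# exact two-sided Wilcoxon p by enumerating which observations form group A;
# U computed by direct pairwise comparison (independent of rank arithmetic)
oracle_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(ia) {
    av <- pooled[ia]; bv <- pooled[-ia]
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  u_obs <- u_of(seq_len(na))
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2, u_of)
  mu <- na * length(b) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# exact Spearman permutation p via the no-ties d^2 formula
oracle_spearman <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_of <- function(r2) 1 - 6 * sum((rx - r2)^2) / (n * (n^2 - 1))
  rho <- rho_of(ry)
  perm_idx <- function(n) {
    if (n == 1) return(matrix(1L, 1, 1))
    sub <- perm_idx(n - 1)
    do.call(rbind, lapply(seq_len(n), function(k) {
      cbind(k, sub + (sub >= k))
    }))
  }
  perms <- perm_idx(n)
  rhos <- apply(perms, 1, function(p) rho_of(ry[p]))
  list(rho = rho, p = mean(abs(rhos) >= abs(rho) - 1e-9))
}

# log-rank chi-square from explicit 2x2 tables at each event time
oracle_logrank_chi2 <- function(t1, e1, t2, e2) {
  time <- c(t1, t2); ev <- c(e1, e2)
  g <- rep(1:2, c(length(t1), length(t2)))
  o <- e <- v <- 0
  for (tt in sort(unique(time[ev]))) {
    n <- sum(time >= tt)
    n1 <- sum(time >= tt & g == 1)
    d <- sum(time == tt & ev)
    d1 <- sum(time == tt & ev & g == 1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

write_tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
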