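#' Two-sample Wilcoxon rank-sum test with Bonferroni correction
#'
#' Two-sided rank-sum (Mann-Whitney) comparison of two groups, as used for
#' all pairwise group comparisons in this package.  For small samples
#' (`n_a + n_b <= 12`) the null distribution of the U statistic is obtained
#' by exact enumeration of all rank assignments (midranks make the
#' enumeration valid under ties); larger samples use the normal
#' approximation with tie-corrected variance and continuity correction.
#' The Bonferroni-adjusted p-value is `min(1, p_raw * family_size)`.
#'
#' @param a,b Numeric vectors (both nonempty).
#' @param family_size Number of tests in the comparison family.
#' @param exact_max Largest combined sample size for exact enumeration.
#' @return Object of class `group_comparison`: `statistic` (U), `p_raw`,
#'   `p_adjusted`, `family_size`, `method`.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_raw  # 0.1
wilcoxon_rank_sum <- function(a, b, family_size = 1, exact_max = 12) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("empty group", call. = FALSE)
  stopifnot(family_size >= 1)
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (n <= exact_max) {
    sums <- combn_rank_sums(r, na)
    us <- sums - na * (na + 1) / 2
    mu <- na * nb / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact"
  } else {
    mu <- na * nb / 2
    ties <- table(r)
    sigma2 <- na * nb / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approx"
  }
  structure(list(statistic = u, p_raw = p,
                 p_adjusted = min(1, p * family_size),
                 family_size = family_size, n = c(na, nb), method = method),
            class = "group_comparison")
}

# sums of all size-na subsets of the (mid)rank vector r
combn_rank_sums <- function(r, na) {
  combos <- utils::combn(length(r), na)
  colSums(matrix(r[combos], nrow = na))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> U=%.1f p=%.4g adj=%.4g (%s, family %d)\n",
              x$statistic, x$p_raw, x$p_adjusted, x$method, x$family_size))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Spearman correlation
# ---------------------------------------------------------------------------

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rho from Pearson correlation of midranks.  For `n <= exact_max`
#' (default 9) the two-sided p-value is computed by full enumeration of all
#' `n!` permutations; above, by the t approximation.  Constant input yields
#' `rho = NA` with `flagged = TRUE` rather than an error.
#'
#' @param x,y Numeric vectors; incomplete pairs dropped.
#' @param exact_max Largest n for exact permutation enumeration.
#' @return List with `rho`, `p`, `n`, `method`, `flagged`.
#' @export
spearman_cor <- function(x, y, exact_max = 9) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) return(list(rho = NA_real_, p = NA_real_, n = n,
                         method = "none", flagged = TRUE))
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "constant",
                flagged = TRUE))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= exact_max) {
    perms <- all_perms(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rhos <- as.vector(matrix(ryc[perms], nrow = nrow(perms)) %*% rxc) / denom
    p <- mean(abs(rhos) >= abs(rho) - 1e-9)
    method <- "exact_permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * pt(-abs(tstat), df = n - 2))
    method <- "t_approx"
  }
  list(rho = rho, p = p, n = n, method = method, flagged = FALSE)
}

# all permutations of 1..n as an (n! x n) matrix
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

#' Correlation screen of spatial covariates against outcomes
#'
#' Spearman-correlates each column of a patient x feature matrix (e.g.
#' distance-binned densities) with each column of a patient x outcome
#' matrix (e.g. event indicator, follow-up months, progression flags),
#' with pairwise-complete handling of missing values and Bonferroni
#' adjustment over all computed entries.  Entries with a constant column
#' or fewer than 3 complete pairs are flagged, not errors.
#'
#' @param features Numeric matrix, patients in rows (rownames = ids).
#' @param outcomes Numeric matrix, same rows.
#' @param alpha Significance level for the `significant` flag (raw p).
#' @return `data.frame` with one row per feature x outcome pair: `rho`,
#'   `p`, `p_adjusted`, `n`, `significant`, `flagged`.
#' @export
spearman_screen <- function(features, outcomes, alpha = 0.05) {
  features <- as.matrix(features); outcomes <- as.matrix(outcomes)
  stopifnot(nrow(features) == nrow(outcomes))
  fn <- colnames(features) %||% paste0("f", seq_len(ncol(features)))
  on <- colnames(outcomes) %||% paste0("o", seq_len(ncol(outcomes)))
  grid <- expand.grid(feature = fn, outcome = on,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    spearman_cor(features[, grid$feature[i]], outcomes[, grid$outcome[i]])
  })
  grid$rho <- vapply(res, `[[`, 0, "rho")
  grid$p <- vapply(res, `[[`, 0, "p")
  grid$n <- vapply(res, `[[`, 0L, "n")
  grid$flagged <- vapply(res, `[[`, TRUE, "flagged")
  fam <- sum(!is.na(grid$p))
  grid$p_adjusted <- pmin(1, grid$p * max(fam, 1))
  grid$significant <- !is.na(grid$p) & grid$p < alpha
  grid
}

# ---------------------------------------------------------------------------
# Survival
# ---------------------------------------------------------------------------

#' Split patients at the median of a covariate
#'
#' `hi` = strictly greater than the sample median, `lo` = less than or
#' equal (ties at the median go to `lo`).  If all values are identical the
#' split is degenerate (`hi` empty) and flagged.
#'
#' @param values Named numeric vector (names = patient ids); `NA` dropped.
#' @return List with `hi`, `lo` (character ids), `cutoff`, `degenerate`.
#' @export
#' @examples
#' median_split(c(A = 1, B = 2, C = 3, D = 4))  # hi = C, D
median_split <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need >= 2 patients with values",
                               call. = FALSE)
  med <- median(values)
  hi <- names(values)[values > med]
  lo <- names(values)[values <= med]
  list(hi = hi, lo = lo, cutoff = med, degenerate = length(hi) == 0)
}

#' Split patients at a fixed covariate threshold
#'
#' `hi` strictly above the threshold.  With the default `threshold = 0`
#' this separates "no expression" from "any expression" patients.
#'
#' @param values Named numeric vector.
#' @param threshold Cut point (default 0).
#' @return As [median_split()].
#' @export
threshold_split <- function(values, threshold = 0) {
  values <- values[!is.na(values)]
  hi <- names(values)[values > threshold]
  lo <- names(values)[values <= threshold]
  list(hi = hi, lo = lo, cutoff = threshold, degenerate = length(hi) == 0)
}

#' Kaplan-Meier curve
#'
#' Product-limit estimate with the standard tie convention (deaths precede
#' censorings at equal times, censored subjects count as at risk at their
#' own time).  Without censoring the curve equals the empirical survival
#' function.
#'
#' @param time Positive follow-up times.
#' @param event Logical/0-1 event indicators.
#' @return `data.frame` with one row per distinct event time: `time`,
#'   `n_risk`, `n_event`, `surv`.
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) == length(event), all(time > 0))
  event <- as.logical(event)
  et <- sort(unique(time[event]))
  n_risk <- vapply(et, function(t) sum(time >= t), 0)
  n_event <- vapply(et, function(t) sum(time == t & event), 0)
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = et, n_risk = n_risk, n_event = n_event, surv = surv)
}

#' Two-group log-rank test with Kaplan-Meier curves
#'
#' Mantel-Cox log-rank chi-square (1 df) comparing survival between a
#' high-covariate and a low-covariate patient group, plus the per-group
#' Kaplan-Meier step functions.  With no events in either group the
#' p-value is flagged undefined (`NA`).
#'
#' @param survival Clinical table with `patient_id`, `time_months`, `event`
#'   (see [read_clinical_table()]).
#' @param hi_ids,lo_ids Character vectors of patient ids (both nonempty,
#'   disjoint).
#' @return Object of class `survival_split`: `chi2`, `p`, `observed`,
#'   `expected` (length-2, hi then lo), `km` (list of two curves),
#'   `hi_ids`, `lo_ids`.
#' @export
km_logrank <- function(survival, hi_ids, lo_ids) {
  stopifnot(length(hi_ids) > 0, length(lo_ids) > 0,
            !anyDuplicated(c(hi_ids, lo_ids)))
  rows <- function(ids) survival[survival$patient_id %in% ids, , drop = FALSE]
  hi <- rows(hi_ids); lo <- rows(lo_ids)
  if (!nrow(hi) || !nrow(lo)) stop("empty group after matching ids",
                                   call. = FALSE)
  time <- c(hi$time_months, lo$time_months)
  event <- as.logical(c(hi$event, lo$event))
  grp <- rep(c(1L, 2L), c(nrow(hi), nrow(lo)))
  et <- sort(unique(time[event]))
  o1 <- e1 <- v <- 0
  for (t in et) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & grp == 1L)
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & grp == 1L)
    o1 <- o1 + d1
    e1 <- e1 + n1 * d / n
    if (n > 1) v <- v + n1 * (n - n1) * d * (n - d) / (n^2 * (n - 1))
  }
  if (length(et) == 0 || v <= 0) {
    chi2 <- if (length(et) == 0) NA_real_ else 0
    p <- NA_real_
    if (!is.na(chi2) && o1 == e1) p <- 1
  } else {
    chi2 <- (o1 - e1)^2 / v
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(list(chi2 = chi2, p = p,
                 observed = c(hi = o1, lo = sum(event) - o1),
                 expected = c(hi = e1, lo = sum(event) - e1),
                 km = list(hi = km_curve(hi$time_months, hi$event),
                           lo = km_curve(lo$time_months, lo$event)),
                 hi_ids = hi$patient_id, lo_ids = lo$patient_id),
            class = "survival_split")
}

#' @export
print.survival_split <- function(x, ...) {
  cat(sprintf("<survival_split> n_hi=%d n_lo=%d chi2=%.3f p=%.4g\n",
              length(x$hi_ids), length(x$lo_ids), x$chi2, x$p))
  invisible(x)
}

#' Restricted mean survival time of a KM curve
#'
#' Area under the Kaplan-Meier step function up to `tmax`; a simple scalar
#' summary used to order two survival curves.
#'
#' @param km A curve from [km_curve()].
#' @param tmax Upper integration limit.
#' @return Numeric RMST.
#' @export
km_rmst <- function(km, tmax) {
  times <- c(0, km$time[km$time <= tmax], tmax)
  surv <- c(1, km$surv[km$time <= tmax])
  sum(surv * diff(times))
}
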