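#' Fit a hi/lo threshold for one marker
#'
#' Derives an intensity cutoff separating "lo" from "hi" cells from the
#' distribution of per-cell mean intensities.  Marker intensities in
#' multiplexed IHC are typically bimodal on a log scale (a negative bulk and
#' a positive tail), so the default method fits a two-component Gaussian
#' mixture to `log10(intensity + eps)` by EM and places the threshold at the
#' equal-posterior crossing between the two component means, back-transformed
#' to intensity units.  If the fitted components are closer than
#' `min_sep` pooled standard deviations the mixture is considered degenerate
#' and the method falls back to `mean + k * SD` on the log scale; the
#' fallback is recorded in the diagnostics.
#'
#' @param x Numeric vector of nonnegative intensities.
#' @param method `"gmm2"` (two-component log-Gaussian mixture, default),
#'   `"mean_sd"` (log-scale mean + k SD) or `"fixed"`.
#' @param params List of tuning parameters: `eps` (offset before log,
#'   default 1), `k` (default 2), `min_sep` (default 0.5), `value` (for
#'   `"fixed"`), `max_iter`, `tol`.
#' @param marker Marker name recorded in the fit.
#' @return An object of class `threshold_fit`: list with `marker`, `method`
#'   (the method actually used), `threshold` (intensity units) and
#'   `diagnostics` (log-scale component means/SDs/weights, fallback flag).
#' @export
#' @examples
#' set.seed(1)
#' x <- c(10^rnorm(500, 1, 0.2), 10^rnorm(500, 2.5, 0.2))
#' fit_marker_threshold(x, marker = "CD68")$threshold
fit_marker_threshold <- function(x, method = c("gmm2", "mean_sd", "fixed"),
                                 params = list(), marker = "marker") {
  method <- match.arg(method)
  eps <- params$eps %||% 1
  k <- params$k %||% 2
  min_sep <- params$min_sep %||% 0.5
  if (method == "fixed") {
    if (is.null(params$value)) stop("fixed method requires params$value")
    return(structure(list(marker = marker, method = "fixed",
                          threshold = params$value,
                          diagnostics = list()),
                     class = "threshold_fit"))
  }
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("no finite intensities for marker ", marker)
  if (all(x == x[1])) stop("all intensities equal for marker ", marker)
  if (method == "gmm2" && length(x) < 50) {
    stop("gmm2 requires >= 50 values (marker ", marker, ")")
  }
  l <- log10(x + eps)
  clamp <- function(thr) min(max(thr, min(x)), max(x))

  mean_sd_fit <- function(extra = list()) {
    t_log <- mean(l) + k * sd(l)
    structure(list(marker = marker, method = "mean_sd",
                   threshold = clamp(10^t_log - eps),
                   diagnostics = c(list(log_mean = mean(l), log_sd = sd(l),
                                        k = k), extra)),
              class = "threshold_fit")
  }
  if (method == "mean_sd") return(mean_sd_fit())

  em <- fit_gmm2_em(l, max_iter = params$max_iter %||% 500,
                    tol = params$tol %||% 1e-10)
  pooled_sd <- sqrt(em$w[1] * em$s[1]^2 + em$w[2] * em$s[2]^2)
  if (!em$converged || (em$m[2] - em$m[1]) < min_sep * pooled_sd) {
    return(mean_sd_fit(list(fallback = TRUE,
                            gmm_mean_lo = em$m[1], gmm_mean_hi = em$m[2],
                            gmm_sd_lo = em$s[1], gmm_sd_hi = em$s[2],
                            gmm_weight_lo = em$w[1])))
  }
  t_log <- gmm2_crossing(em$w, em$m, em$s)
  structure(list(marker = marker, method = "gmm2",
                 threshold = clamp(10^t_log - eps),
                 diagnostics = list(mean_lo = em$m[1], mean_hi = em$m[2],
                                    sd_lo = em$s[1], sd_hi = em$s[2],
                                    weight_lo = em$w[1], weight_hi = em$w[2],
                                    log_threshold = t_log,
                                    loglik = em$loglik,
                                    iterations = em$iter,
                                    fallback = FALSE)),
            class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf("<threshold_fit> %s: %.4g (%s)\n",
              x$marker, x$threshold, x$method))
  invisible(x)
}

# Two-component univariate Gaussian mixture by EM, components ordered by mean.
fit_gmm2_em <- function(l, max_iter = 500, tol = 1e-10) {
  n <- length(l)
  med <- median(l)
  lo <- l[l <= med]; hi <- l[l > med]
  if (!length(hi)) hi <- max(l)
  m <- c(mean(lo), mean(hi))
  s <- pmax(c(sd(lo), sd(hi)), 1e-3)
  s[is.na(s)] <- max(sd(l) / 2, 1e-3)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(l, m[1], s[1])
    d2 <- w[2] * dnorm(l, m[2], s[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r2 <- d2 / tot
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
    n2 <- sum(r2); n1 <- n - n2
    if (n1 < 1e-8 || n2 < 1e-8) break
    m <- c(sum((1 - r2) * l) / n1, sum(r2 * l) / n2)
    s <- sqrt(pmax(c(sum((1 - r2) * (l - m[1])^2) / n1,
                     sum(r2 * (l - m[2])^2) / n2), 1e-6))
    w <- c(n1, n2) / n
    if (m[1] > m[2]) {  # keep components ordered
      m <- rev(m); s <- rev(s); w <- rev(w); r2 <- 1 - r2
    }
  }
  list(m = m, s = s, w = w, loglik = ll_old, converged = converged,
       iter = iter)
}

# Equal-posterior crossing of two Gaussian components between their means.
gmm2_crossing <- function(w, m, s) {
  g <- function(t) {
    (log(w[1]) + dnorm(t, m[1], s[1], log = TRUE)) -
      (log(w[2]) + dnorm(t, m[2], s[2], log = TRUE))
  }
  if (g(m[1]) > 0 && g(m[2]) < 0) {
    return(uniroot(g, c(m[1], m[2]), tol = 1e-12)$root)
  }
  # no sign change between the means (extreme weights): weighted midpoint
  (s[2] * m[1] + s[1] * m[2]) / (s[1] + s[2])
}

SUBSET_LEVELS <- c("CD68hiCD163lo", "CD68hiCD163hi",
                   "CD68loCD163hi", "CD68loCD163lo")

threshold_value <- function(thr) {
  if (inherits(thr, "threshold_fit")) thr$threshold else as.numeric(thr)
}

#' Classify cells into CD68/CD163 subsets
#'
#' Assigns each cell one of the four macrophage-associated subset labels
#' `CD68hiCD163lo`, `CD68hiCD163hi`, `CD68loCD163hi` or `CD68loCD163lo`.
#' "hi" means the cell's mean intensity is strictly greater than the marker
#' threshold; a cell exactly at the threshold is "lo".  The four labels
#' always partition the input.
#'
#' @param cells Standardized cell table with `CD68` and `CD163` columns
#'   (names configurable via `markers`).
#' @param cd68_threshold,cd163_threshold Numeric thresholds or
#'   [fit_marker_threshold()] fits.
#' @param markers Length-2 character vector naming the two intensity
#'   columns.
#' @return Factor of subset labels with levels in the order above.
#' @export
classify_cd68_cd163 <- function(cells, cd68_threshold, cd163_threshold,
                                markers = c("CD68", "CD163")) {
  for (m in markers) {
    if (!m %in% names(cells)) stop("missing marker column: ", m,
                                   call. = FALSE)
  }
  t68 <- threshold_value(cd68_threshold)
  t163 <- threshold_value(cd163_threshold)
  hi68 <- cells[[markers[1]]] > t68
  hi163 <- cells[[markers[2]]] > t163
  lab <- ifelse(hi68,
                ifelse(hi163, "CD68hiCD163hi", "CD68hiCD163lo"),
                ifelse(hi163, "CD68loCD163hi", "CD68loCD163lo"))
  factor(lab, levels = SUBSET_LEVELS)
}

#' Classify cells as hi/lo for one checkpoint marker
#'
#' `hi` iff intensity strictly exceeds the threshold.  With `threshold = 0`
#' this implements the "any expression vs no expression" split: cells with
#' zero intensity are `lo`, any positive intensity is `hi`.
#'
#' @param cells Standardized cell table.
#' @param marker Marker column name (e.g. `"PD-L1"`).
#' @param threshold Numeric threshold or [fit_marker_threshold()] fit.
#' @return Factor with levels `c("hi", "lo")`.
#' @export
classify_checkpoint <- function(cells, marker, threshold) {
  if (!marker %in% names(cells)) {
    stop("missing marker column: ", marker, call. = FALSE)
  }
  thr <- threshold_value(threshold)
  factor(ifelse(cells[[marker]] > thr, "hi", "lo"), levels = c("hi", "lo"))
}

#' Serialize threshold fits to a JSON sidecar
#'
#' @param fits List of `threshold_fit` objects.
#' @param path Output path.
#' @export
write_threshold_fits <- function(fits, path) {
  payload <- lapply(fits, function(f) {
    list(marker = f$marker, method = f$method, threshold = f$threshold,
         diagnostics = f$diagnostics)
  })
  names(payload) <- vapply(fits, function(f) f$marker, "")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
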