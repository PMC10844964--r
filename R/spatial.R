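cell_key <- function(cells) {
  if ("sample_id" %in% names(cells)) {
    paste(cells$sample_id, cells$cell_id, sep = "\r")
  } else {
    as.character(cells$cell_id)
  }
}

#' Nearest-distance statistics between two cell sets
#'
#' For every cell in `from_cells`, the Euclidean distance (µm) to the
#' nearest cell in `to_cells`; a to-cell with the same identifier as the
#' from-cell (same cell present in both sets) is excluded, so a set matched
#' against itself yields nearest non-self distances.  The mean of the
#' per-cell distances is the mean nearest distance (MND) commonly reported
#' for a subset relative to tumor cells.
#'
#' @param from_cells,to_cells Standardized cell tables.
#' @param method `"grid"` (accelerated, default) or `"brute"` (exact
#'   O(n²) reference path).
#' @return Object of class `nearest_distance_result`: list with `per_cell`
#'   (named numeric), `mnd`, `n_from`, `n_to`.
#' @export
#' @examples
#' f <- data.frame(cell_id = "a", x_um = 0, y_um = 0)
#' t <- data.frame(cell_id = c("b", "c"), x_um = c(3, 6), y_um = c(4, 8))
#' nearest_distance(f, t)$mnd  # 5
nearest_distance <- function(from_cells, to_cells,
                             method = c("grid", "brute")) {
  method <- match.arg(method)
  if (is.null(to_cells) || nrow(to_cells) == 0) {
    stop("no reference cells", call. = FALSE)
  }
  nf <- nrow(from_cells)
  if (nf == 0) {
    return(structure(list(per_cell = setNames(numeric(0), character(0)),
                          mnd = NaN, n_from = 0L, n_to = nrow(to_cells)),
                     class = "nearest_distance_result"))
  }
  kf <- cell_key(from_cells)
  kt <- cell_key(to_cells)
  excl <- match(kf, kt)
  excl[is.na(excl)] <- 0L
  d <- if (method == "grid") {
    nn_dist_grid(from_cells$x_um, from_cells$y_um,
                 to_cells$x_um, to_cells$y_um, as.integer(excl))
  } else {
    nn_brute(from_cells$x_um, from_cells$y_um,
             to_cells$x_um, to_cells$y_um, excl)
  }
  d[!is.finite(d)] <- NA_real_
  structure(list(per_cell = setNames(d, from_cells$cell_id),
                 mnd = mean(d, na.rm = TRUE),
                 n_from = nf, n_to = nrow(to_cells)),
            class = "nearest_distance_result")
}

nn_brute <- function(xf, yf, xt, yt, excl) {
  vapply(seq_along(xf), function(i) {
    d2 <- (xt - xf[i])^2 + (yt - yf[i])^2
    if (excl[i] > 0) d2[excl[i]] <- Inf
    sqrt(min(d2))
  }, 0)
}

#' @export
print.nearest_distance_result <- function(x, ...) {
  cat(sprintf("<nearest_distance_result> n_from=%d n_to=%d MND=%.2f um\n",
              x$n_from, x$n_to, x$mnd))
  invisible(x)
}

#' Count cell-cell contacts under a centroid+radius rule
#'
#' Two cells are in contact when their centroid distance is at most the sum
#' of their effective radii plus `slack`.  Radii derive from the segmented
#' cell area (`r = sqrt(area / pi)`) where available, else `default_radius`.
#' This approximates mask-level touching detection, which needs the
#' segmentation masks that tabular exports do not carry.
#'
#' @param ref_cells Reference cells (e.g. PD-1 hi T cells).
#' @param partner_cells Candidate partner cells.
#' @param partner_labels Either a column name in `partner_cells` or a vector
#'   of labels (one per partner cell) defining partner classes.
#' @param slack Extra tolerance in µm (default 1; must be >= 0).
#' @param default_radius Radius (µm) used when `cell_area_um2` is absent.
#' @param method `"grid"` or `"brute"`.
#' @return Object of class `contact_result`: list with `per_reference_cell`
#'   (integer matrix, reference cells x partner labels), `contact_fraction`
#'   (named, fraction of reference cells with >= 1 contact of that label),
#'   `total_pairs` (named pair counts) and the rule parameters.
#' @export
count_contacts <- function(ref_cells, partner_cells, partner_labels,
                           slack = 1, default_radius = 5,
                           method = c("grid", "brute")) {
  method <- match.arg(method)
  if (slack < 0) stop("negative slack", call. = FALSE)
  labels <- if (is.character(partner_labels) && length(partner_labels) == 1 &&
                partner_labels %in% names(partner_cells)) {
    as.character(partner_cells[[partner_labels]])
  } else {
    as.character(partner_labels)
  }
  stopifnot(length(labels) == nrow(partner_cells))
  radius_of <- function(cells) {
    a <- cells$cell_area_um2
    if (is.null(a)) a <- rep(NA_real_, nrow(cells))
    ifelse(is.finite(a) & a > 0, sqrt(a / pi), default_radius)
  }
  rr <- radius_of(ref_cells)
  kref <- cell_key(ref_cells)
  ulab <- sort(unique(labels))
  counts <- matrix(0L, nrow(ref_cells), length(ulab),
                   dimnames = list(ref_cells$cell_id, ulab))
  for (lab in ulab) {
    part <- partner_cells[labels == lab, , drop = FALSE]
    rp <- radius_of(part)
    excl <- match(kref, cell_key(part))
    excl[is.na(excl)] <- 0L
    counts[, lab] <- if (method == "grid") {
      radius_count_grid(ref_cells$x_um, ref_cells$y_um, rr,
                        part$x_um, part$y_um, rp, slack, as.integer(excl))
    } else {
      contacts_brute(ref_cells$x_um, ref_cells$y_um, rr,
                     part$x_um, part$y_um, rp, slack, excl)
    }
  }
  frac <- if (nrow(counts) > 0) colMeans(counts >= 1L) else
    setNames(rep(NaN, length(ulab)), ulab)
  structure(list(per_reference_cell = counts,
                 contact_fraction = frac,
                 total_pairs = colSums(counts),
                 rule = list(type = "CENTROID_RADIUS", slack = slack,
                             default_radius = default_radius)),
            class = "contact_result")
}

contacts_brute <- function(xr, yr, rr, xp, yp, rp, slack, excl) {
  vapply(seq_along(xr), function(i) {
    d2 <- (xp - xr[i])^2 + (yp - yr[i])^2
    thr <- (rr[i] + rp + slack)^2
    hit <- d2 <= thr
    if (excl[i] > 0) hit[excl[i]] <- FALSE
    sum(hit)
  }, 0L)
}

#' @export
print.contact_result <- function(x, ...) {
  cat("<contact_result>", nrow(x$per_reference_cell), "reference cells;",
      "contact fractions:\n")
  print(round(x$contact_fraction, 3))
  invisible(x)
}
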