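#' Tissue geometry constructors
#'
#' A `tissue_geometry` describes, for one sample, where the epithelium/tumor
#' compartment lies inside a rectangular sample frame.  Three representations
#' are supported:
#'
#' * `geometry_discs()`: tumor nests as non-overlapping discs inside the
#'   frame.  Signed distances and band areas have closed forms, which the
#'   synthetic generator exploits.
#' * `geometry_polygons()`: nests as simple closed polygons (µm vertices).
#' * `geometry_mask()`: a label raster with integer codes
#'   `0 = outside sample`, `1 = stroma`, `2 = epithelium/tumor`, with a
#'   µm-per-pixel scale.  Rows index y, columns index x; the centre of pixel
#'   `[i, j]` is at `((j - 0.5), (i - 0.5)) * um_per_px`.
#'
#' @param sample_id Sample identifier.
#' @param frame_um Numeric length-2, frame width and height in µm.
#' @param centers Matrix (n x 2) of disc centres in µm.
#' @param radii Disc radii in µm.
#' @param polygons List of n x 2 vertex matrices (closed implicitly).
#' @param mask Integer matrix of labels 0/1/2.
#' @param um_per_px Micrometres per pixel.
#' @return An object of class `tissue_geometry`.
#' @name tissue_geometry
NULL

#' @rdname tissue_geometry
#' @export
geometry_discs <- function(sample_id, frame_um, centers, radii) {
  centers <- matrix(as.numeric(centers), ncol = 2)
  radii <- as.numeric(radii)
  stopifnot(length(frame_um) == 2, all(frame_um > 0),
            nrow(centers) == length(radii), all(radii > 0))
  if (nrow(centers) > 1) {
    dd <- as.matrix(dist(centers))
    sep <- outer(radii, radii, "+")
    diag(dd) <- Inf
    if (any(dd < sep)) warning("overlapping discs: distances near buried ",
                               "boundary arcs will be underestimated")
  }
  structure(list(sample_id = sample_id, type = "discs",
                 frame_um = as.numeric(frame_um),
                 discs = data.frame(cx = centers[, 1], cy = centers[, 2],
                                    r = radii)),
            class = "tissue_geometry")
}

#' @rdname tissue_geometry
#' @export
geometry_polygons <- function(sample_id, frame_um, polygons) {
  polygons <- lapply(polygons, function(p) {
    p <- matrix(as.numeric(p), ncol = 2)
    if (nrow(p) >= 2 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), ]
    if (nrow(p) < 3) stop("polygon needs >= 3 vertices")
    if (any(!is.finite(p))) stop("non-finite polygon vertex")
    p
  })
  structure(list(sample_id = sample_id, type = "polygons",
                 frame_um = as.numeric(frame_um), polygons = polygons),
            class = "tissue_geometry")
}

#' @rdname tissue_geometry
#' @export
geometry_mask <- function(sample_id, mask, um_per_px) {
  mask <- matrix(as.integer(mask), nrow = nrow(mask))
  stopifnot(um_per_px > 0, all(mask %in% 0:2))
  structure(list(sample_id = sample_id, type = "mask", mask = mask,
                 um_per_px = um_per_px,
                 frame_um = c(ncol(mask), nrow(mask)) * um_per_px),
            class = "tissue_geometry")
}

#' @export
print.tissue_geometry <- function(x, ...) {
  cat(sprintf("<tissue_geometry> %s (%s), frame %.0f x %.0f um\n",
              x$sample_id %||% "?", x$type, x$frame_um[1], x$frame_um[2]))
  invisible(x)
}

has_tumor_region <- function(geom) {
  switch(geom$type,
         discs = nrow(geom$discs) > 0,
         polygons = length(geom$polygons) > 0,
         mask = any(geom$mask == 2L))
}

#' Read/write geometry files
#'
#' Masks are stored as headerless CSV integer grids (one row per raster
#' row, codes 0/1/2) with the µm-per-pixel scale supplied by the caller;
#' polygon geometries as GeoJSON `MultiPolygon`/`Polygon` features in µm
#' coordinates with a `frame_um` property.  (Binary TIFF/PNG label masks
#' are not supported in this text-only build; convert to CSV grids.)
#'
#' @param path File path.
#' @param sample_id Sample identifier to attach.
#' @param um_per_px Micrometres per pixel (mask only).
#' @return A `tissue_geometry`.
#' @export
read_geometry_mask <- function(path, sample_id, um_per_px) {
  m <- as.matrix(read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  geometry_mask(sample_id, m, um_per_px)
}

#' @rdname read_geometry_mask
#' @export
write_geometry_mask <- function(geom, path) {
  stopifnot(geom$type == "mask")
  write.table(geom$mask, path, sep = ",", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname read_geometry_mask
#' @export
read_geometry_polygons <- function(path, sample_id) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  frame_um <- unlist(gj$properties$frame_um)
  polys <- lapply(gj$geometry$coordinates, function(ring) {
    do.call(rbind, lapply(ring[[1]], function(pt) unlist(pt)))
  })
  geometry_polygons(sample_id, frame_um, polys)
}

#' @rdname read_geometry_mask
#' @export
write_geometry_polygons <- function(geom, path) {
  stopifnot(geom$type == "polygons")
  coords <- lapply(geom$polygons, function(p) {
    p <- rbind(p, p[1, ])
    list(lapply(seq_len(nrow(p)), function(i) as.numeric(p[i, ])))
  })
  gj <- list(type = "Feature",
             properties = list(frame_um = geom$frame_um),
             geometry = list(type = "MultiPolygon", coordinates = coords))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Signed distances
# ---------------------------------------------------------------------------

# closed-form signed distance to a union of (disjoint) discs
sd_discs <- function(x, y, discs) {
  n <- length(x)
  if (nrow(discs) == 0) stop("no boundary", call. = FALSE)
  vals <- matrix(0, n, nrow(discs))
  for (k in seq_len(nrow(discs))) {
    vals[, k] <- sqrt((x - discs$cx[k])^2 + (y - discs$cy[k])^2) - discs$r[k]
  }
  inside <- rowSums(vals < 0) > 0
  minabs <- apply(abs(vals), 1, min)
  ifelse(inside, -minabs, minabs)
}

# min distance from points to a polyline segment set, plus even-odd parity
sd_polygons <- function(x, y, polygons) {
  n <- length(x)
  best <- rep(Inf, n)
  crossings <- integer(n)
  for (p in polygons) {
    m <- nrow(p)
    for (e in seq_len(m)) {
      a <- p[e, ]
      b <- p[if (e == m) 1 else e + 1, ]
      vx <- b[1] - a[1]; vy <- b[2] - a[2]
      len2 <- vx * vx + vy * vy
      t <- if (len2 > 0) {
        pmin(1, pmax(0, ((x - a[1]) * vx + (y - a[2]) * vy) / len2))
      } else 0
      dx <- x - (a[1] + t * vx)
      dy <- y - (a[2] + t * vy)
      best <- pmin(best, dx * dx + dy * dy)
      # even-odd ray casting (ray towards +x), half-open rule on y
      cond <- (a[2] > y) != (b[2] > y)
      if (any(cond)) {
        xint <- a[1] + (y - a[2]) / (b[2] - a[2]) * vx
        crossings <- crossings + as.integer(cond & x < xint)
      }
    }
  }
  ifelse(crossings %% 2 == 1, -sqrt(best), sqrt(best))
}

# signed-distance field (µm) of a label mask; NA where mask == 0
signed_field_mask <- function(mask, um_per_px) {
  tumor <- mask == 2L
  stroma <- mask == 1L
  if (!any(tumor)) stop("no boundary", call. = FALSE)
  d_to_tumor <- sqrt(edt_sq(tumor))
  d_to_stroma <- sqrt(edt_sq(stroma))
  # pixel-centre distances overestimate distance to the interface by ~0.5 px
  f <- ifelse(tumor, -pmax(d_to_stroma - 0.5, 0),
              pmax(d_to_tumor - 0.5, 0)) * um_per_px
  f[mask == 0L] <- NA_real_
  f
}

#' Signed distance of cells to the epithelium/tumor-stroma boundary
#'
#' For each cell, the Euclidean distance (µm) to the interface between the
#' epithelium/tumor compartment and the stroma, negative for cells inside
#' the epithelium/tumor, positive in the stroma.  Cells outside the sample
#' frame (or, for masks, on out-of-sample pixels) get `NA` and are excluded
#' from downstream profiles.
#'
#' @param cells Standardized cell table (single sample).
#' @param geom A [tissue_geometry] for the same sample.
#' @return Named numeric vector of signed distances (names = `cell_id`).
#' @export
#' @examples
#' g <- geometry_discs("s1", c(1000, 1000), cbind(500, 500), 100)
#' cells <- data.frame(sample_id = "s1", cell_id = c("a", "b"),
#'                     x_um = c(500, 650), y_um = c(500, 500))
#' signed_distance(cells, g)  # -100, +50
signed_distance <- function(cells, geom) {
  stopifnot(inherits(geom, "tissue_geometry"))
  if (!has_tumor_region(geom)) stop("no boundary", call. = FALSE)
  if (!is.null(geom$sample_id) && "sample_id" %in% names(cells)) {
    ids <- unique(cells$sample_id)
    if (length(ids) > 1 || (length(ids) == 1 && ids != geom$sample_id)) {
      stop("cells and geometry disagree on sample_id", call. = FALSE)
    }
  }
  x <- cells$x_um; y <- cells$y_um
  out_of_frame <- x < 0 | x > geom$frame_um[1] | y < 0 | y > geom$frame_um[2]
  d <- switch(geom$type,
    discs = sd_discs(x, y, geom$discs),
    polygons = sd_polygons(x, y, geom$polygons),
    mask = {
      f <- signed_field_mask(geom$mask, geom$um_per_px)
      i <- pmin(pmax(ceiling(y / geom$um_per_px), 1L), nrow(geom$mask))
      j <- pmin(pmax(ceiling(x / geom$um_per_px), 1L), ncol(geom$mask))
      f[cbind(i, j)]
    })
  d[out_of_frame] <- NA_real_
  if (any(out_of_frame)) {
    warning(sum(out_of_frame), " cell(s) outside the sample frame excluded")
  }
  setNames(d, cells$cell_id)
}

# ---------------------------------------------------------------------------
# Rasterization and band areas
# ---------------------------------------------------------------------------

#' Rasterize a geometry to a label mask
#'
#' @param geom A [tissue_geometry].
#' @param res Raster resolution in µm per pixel.
#' @return A `tissue_geometry` of type `"mask"`.
#' @export
rasterize_geometry <- function(geom, res = 2) {
  if (geom$type == "mask") return(geom)
  nxp <- max(1L, as.integer(round(geom$frame_um[1] / res)))
  nyp <- max(1L, as.integer(round(geom$frame_um[2] / res)))
  xc <- (seq_len(nxp) - 0.5) * res
  yc <- (seq_len(nyp) - 0.5) * res
  mask <- matrix(1L, nyp, nxp)
  if (geom$type == "discs") {
    for (k in seq_len(nrow(geom$discs))) {
      dx2 <- (xc - geom$discs$cx[k])^2
      dy2 <- (yc - geom$discs$cy[k])^2
      mask[outer(dy2, dx2, "+") < geom$discs$r[k]^2] <- 2L
    }
  } else {
    for (i in seq_len(nyp)) {  # scanline fill, even-odd rule
      yrow <- yc[i]
      xs <- numeric(0)
      for (p in geom$polygons) {
        m <- nrow(p)
        a <- p
        b <- p[c(2:m, 1), , drop = FALSE]
        cond <- (a[, 2] > yrow) != (b[, 2] > yrow)
        if (any(cond)) {
          xs <- c(xs, a[cond, 1] + (yrow - a[cond, 2]) /
                    (b[cond, 2] - a[cond, 2]) * (b[cond, 1] - a[cond, 1]))
        }
      }
      if (length(xs)) {
        mask[i, findInterval(xc, sort(xs)) %% 2 == 1] <- 2L
      }
    }
  }
  geometry_mask(geom$sample_id, mask, res)
}

# per-pixel signed distance values for a raster of an analytic geometry
raster_signed_values <- function(geom, res) {
  if (geom$type == "discs") {
    nxp <- max(1L, as.integer(round(geom$frame_um[1] / res)))
    nyp <- max(1L, as.integer(round(geom$frame_um[2] / res)))
    xc <- rep((seq_len(nxp) - 0.5) * res, each = nyp)
    yc <- rep((seq_len(nyp) - 0.5) * res, times = nxp)
    sd_discs(xc, yc, geom$discs)
  } else if (geom$type == "polygons") {
    rg <- rasterize_geometry(geom, res)
    as.vector(signed_field_mask(rg$mask, res))
  } else {
    as.vector(signed_field_mask(geom$mask, geom$um_per_px))
  }
}

#' Areas of signed-distance bands
#'
#' Computes, for each bin of a signed-distance axis, the area (mm²) of the
#' part of the sample frame whose signed boundary distance falls in that
#' bin.  Disc geometries with enough clearance from the frame edges and
#' from each other are computed analytically (exact annulus areas);
#' otherwise the geometry is rasterized at `res` µm/pixel and an exact
#' Euclidean distance transform is applied inside and outside the tumor
#' compartment.  Bins are left-closed (`[a, b)`).
#'
#' @param geom A [tissue_geometry].
#' @param bin_edges Sorted numeric vector of signed-distance bin edges (µm).
#' @param res Raster resolution (µm per pixel, default 2).
#' @param method `"auto"`, `"analytic"` (discs only) or `"raster"`.
#' @return Numeric vector of band areas in mm², length
#'   `length(bin_edges) - 1`.
#' @export
band_areas <- function(geom, bin_edges, res = 2,
                       method = c("auto", "analytic", "raster")) {
  method <- match.arg(method)
  stopifnot(!is.unsorted(bin_edges), length(bin_edges) >= 2)
  if (res > min(diff(bin_edges)) / 4) {
    stop("raster resolution coarser than bin width / 4", call. = FALSE)
  }
  if (!has_tumor_region(geom)) stop("no boundary", call. = FALSE)
  if (method == "analytic" ||
      (method == "auto" && geom$type == "discs" &&
       discs_have_clearance(geom, max(abs(bin_edges))))) {
    return(band_areas_analytic(geom, bin_edges))
  }
  vals <- raster_signed_values(geom, res)
  vals <- vals[is.finite(vals)]
  bin <- findInterval(vals, bin_edges, left.open = FALSE)
  bin[vals >= bin_edges[length(bin_edges)]] <- 0L  # beyond last edge
  counts <- tabulate(bin, nbins = length(bin_edges) - 1)
  px_mm2 <- (if (geom$type == "mask") geom$um_per_px else res)^2 / 1e6
  counts * px_mm2
}

# TRUE if every disc (inflated by `extent`) stays inside the frame and the
# inflated annuli of distinct discs cannot overlap
discs_have_clearance <- function(geom, extent) {
  d <- geom$discs
  ok_frame <- all(d$cx - d$r - extent >= 0, d$cy - d$r - extent >= 0,
                  d$cx + d$r + extent <= geom$frame_um[1],
                  d$cy + d$r + extent <= geom$frame_um[2])
  if (!ok_frame) return(FALSE)
  if (nrow(d) > 1) {
    dd <- as.matrix(dist(cbind(d$cx, d$cy)))
    need <- outer(d$r, d$r, "+") + 2 * extent
    diag(dd) <- Inf
    if (any(dd < need)) return(FALSE)
  }
  TRUE
}

band_areas_analytic <- function(geom, bin_edges) {
  nb <- length(bin_edges) - 1
  areas <- numeric(nb)
  for (k in seq_len(nrow(geom$discs))) {
    r <- geom$discs$r[k]
    ro <- pmax(r + bin_edges, 0)   # radius at each signed offset
    areas <- areas + pi * (ro[-1]^2 - ro[-length(ro)]^2)
  }
  areas / 1e6
}

#' Compartment areas of a geometry
#'
#' @param geom A [tissue_geometry].
#' @param res Raster resolution for polygon geometries (µm/px).
#' @return Named numeric: areas (mm²) of `EPI_TUMOR` and `STROMA`.
#' @export
compartment_areas <- function(geom, res = 2) {
  frame_mm2 <- prod(geom$frame_um) / 1e6
  if (geom$type == "discs") {
    tumor <- sum(pi * geom$discs$r^2) / 1e6
    return(c(EPI_TUMOR = tumor, STROMA = frame_mm2 - tumor))
  }
  if (geom$type == "polygons") {
    tumor <- sum(vapply(geom$polygons, shoelace_area, 0)) / 1e6
    return(c(EPI_TUMOR = tumor, STROMA = frame_mm2 - tumor))
  }
  px_mm2 <- geom$um_per_px^2 / 1e6
  c(EPI_TUMOR = sum(geom$mask == 2L) * px_mm2,
    STROMA = sum(geom$mask == 1L) * px_mm2)
}

shoelace_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}
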