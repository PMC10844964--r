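#' Configuration of a synthetic cohort
#'
#' Defines the stated world for the generator: a rectangular sample frame
#' (default 3 x 3 mm, the size of a typical multispectral imaging region)
#' containing non-overlapping disc-shaped tumor nests, per-subset spatial
#' intensity models, bimodal (hi/lo) log-normal marker intensities,
#' distance-dependent checkpoint (PD-L1/PD-1) positivity, Beta-distributed
#' phenotype confidences, and exponential survival whose hazard depends on
#' each patient's realized cell density in one signed-distance band.
#'
#' Spatial models per subset are either
#' `list(model = "boundary_exp", lambda0 = <cells/mm2 at the boundary>,
#' tau = <decay length um>, side = "both"|"stroma"|"tumor")` — intensity
#' `lambda0 * exp(-|d|/tau)` restricted to the given side — or
#' `list(model = "uniform", lambda = <cells/mm2>,
#' compartment = "stroma"|"tumor"|"both")`.
#'
#' @param seed Base RNG seed.
#' @param frame_mm Frame width/height in mm.
#' @param n_nests Number of tumor nests per sample.
#' @param nest_radius_um Length-2 range of nest radii (µm).
#' @param nest_clearance_um Minimum distance kept between a nest boundary
#'   and the frame edge, and half the minimum boundary-to-boundary nest
#'   separation; defaults to `max(abs(range_um))` so that distance bands
#'   never clip the frame or each other (keeps band areas analytic).
#' @param subsets Named list of spatial models (see above).  Defaults model
#'   the canonical patterns: two boundary-accumulating macrophage-like
#'   subsets, one stroma-uniform subset, boundary-accumulating T cells,
#'   tumor-filling tumor cells and stroma-uniform leukocytes.
#' @param markers Marker panel to emit.
#' @param intensity Per-marker log10 component means/SDs,
#'   `list(mean_lo, mean_hi, sd)`.
#' @param checkpoint Positivity model per checkpoint marker:
#'   `list(p_by_type = c(type = pmax), tau = <um>)`; the probability that a
#'   cell of that type is "hi" is `pmax * exp(-max(d, 0)/tau)` (full `pmax`
#'   inside the tumor, decaying into the stroma).
#' @param confidence_shape Beta shape parameters for phenotype confidence.
#' @param bin_width,range_um Profiling grid the survival band refers to.
#' @param survival List: `h0` baseline hazard (1/month), `beta` log-hazard
#'   effect per SD of band density, `censor_rate` (probability a patient is
#'   censored uniformly before the event), `n_patients`, `band_center` (µm),
#'   `target_subset`, `target_checkpoint` (marker whose "hi" cells define
#'   the covariate, or `NA`).
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             frame_mm = c(3, 3),
                             n_nests = 1,
                             nest_radius_um = c(250, 350),
                             nest_clearance_um = NULL,
                             subsets = NULL,
                             markers = c("CK", "CD45", "CD68", "CD163",
                                         "CD3", "PDL1", "PD1"),
                             intensity = NULL,
                             checkpoint = NULL,
                             confidence_shape = c(8, 2),
                             bin_width = 25,
                             range_um = c(-512.5, 512.5),
                             survival = NULL) {
  subsets <- subsets %||% list(
    CD68hiCD163lo = list(model = "boundary_exp", lambda0 = 150, tau = 75,
                         side = "both"),
    CD68hiCD163hi = list(model = "boundary_exp", lambda0 = 120, tau = 100,
                         side = "both"),
    CD68loCD163hi = list(model = "uniform", lambda = 80,
                         compartment = "stroma"),
    Tcell = list(model = "boundary_exp", lambda0 = 400, tau = 150,
                 side = "both"),
    Tumor = list(model = "uniform", lambda = 1500, compartment = "tumor"),
    Leukocyte = list(model = "uniform", lambda = 500,
                     compartment = "stroma"))
  intensity <- intensity %||% setNames(
    rep(list(list(mean_lo = 1.0, mean_hi = 2.5, sd = 0.2)), length(markers)),
    markers)
  checkpoint <- checkpoint %||% list(
    PDL1 = list(p_by_type = c(CD68hiCD163lo = 0.45, CD68hiCD163hi = 0.6,
                              CD68loCD163hi = 0.25, Tcell = 0.5,
                              Tumor = 0.4, Leukocyte = 0.1), tau = 100),
    PD1 = list(p_by_type = c(CD68hiCD163lo = 0.2, CD68hiCD163hi = 0.25,
                             CD68loCD163hi = 0.1, Tcell = 0.55,
                             Tumor = 0.15, Leukocyte = 0.1), tau = 100))
  survival <- utils::modifyList(
    list(h0 = 0.02, beta = -0.7, censor_rate = 0.3, n_patients = 60,
         band_center = 75, target_subset = "CD68hiCD163hi",
         target_checkpoint = "PDL1", patient_sd = 0.3),
    survival %||% list())
  nest_clearance_um <- nest_clearance_um %||% max(abs(range_um))
  cfg <- list(seed = as.integer(seed), frame_mm = frame_mm,
              n_nests = n_nests, nest_radius_um = nest_radius_um,
              nest_clearance_um = nest_clearance_um, subsets = subsets,
              markers = markers, intensity = intensity,
              checkpoint = checkpoint, confidence_shape = confidence_shape,
              bin_width = bin_width, range_um = range_um,
              survival = survival)
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic_config> seed=%d frame=%gx%g mm, %d nest(s), %d subset model(s)\n",
              x$seed, x$frame_mm[1], x$frame_mm[2], x$n_nests,
              length(x$subsets)))
  invisible(x)
}

#' Generate a nest-in-stroma tissue geometry
#'
#' Places `n_nests` non-overlapping discs in the frame by rejection
#' sampling, keeping `nest_clearance_um` between every nest boundary and
#' the frame edge and `2 * nest_clearance_um` between nest boundaries (so
#' signed-distance bands up to the clearance stay exact under the analytic
#' band-area path).  Zero nests yield an all-stroma geometry for which
#' downstream distance calls raise the "no boundary" error.
#'
#' @param cfg A [synthetic_config()].
#' @param sample_id Sample id for the geometry.
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return A [tissue_geometry] of type `"discs"`.
#' @export
generate_geometry <- function(cfg, sample_id = "S1", seed = cfg$seed) {
  frame_um <- cfg$frame_mm * 1000
  with_seed(seed, {
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    attempts <- 0
    while (length(radii) < cfg$n_nests) {
      attempts <- attempts + 1
      if (attempts > 10000) {
        stop("could not place ", cfg$n_nests, " nests in 10000 attempts; ",
             "use fewer or smaller nests", call. = FALSE)
      }
      r <- runif(1, cfg$nest_radius_um[1], cfg$nest_radius_um[2])
      margin <- r + cfg$nest_clearance_um
      if (2 * margin >= min(frame_um)) {
        stop("nest radius plus clearance exceeds frame; use fewer or ",
             "smaller nests", call. = FALSE)
      }
      cx <- runif(1, margin, frame_um[1] - margin)
      cy <- runif(1, margin, frame_um[2] - margin)
      if (nrow(centers)) {
        dd <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
        if (any(dd < radii + r + 2 * cfg$nest_clearance_um)) next
      }
      centers <- rbind(centers, c(cx, cy))
      radii <- c(radii, r)
    }
    if (length(radii) == 0) {
      structure(list(sample_id = sample_id, type = "discs",
                     frame_um = frame_um,
                     discs = data.frame(cx = numeric(0), cy = numeric(0),
                                        r = numeric(0))),
                class = "tissue_geometry")
    } else {
      geometry_discs(sample_id, frame_um, centers, radii)
    }
  })
}

# hi/lo marker membership of each generated cell type
type_hi_markers <- function(type) {
  switch(type,
         CD68hiCD163lo = c("CD68", "CD45"),
         CD68hiCD163hi = c("CD68", "CD163", "CD45"),
         CD68loCD163hi = c("CD163", "CD45"),
         Tcell = c("CD3", "CD45"),
         Tumor = "CK",
         Leukocyte = "CD45",
         character(0))
}

# platform-style phenotype label (whole-slide workflow granularity)
type_phenotype <- function(type) {
  switch(type,
         CD68hiCD163lo = , CD68hiCD163hi = , CD68loCD163hi = "CD68CD163",
         Tcell = "Tcell", Tumor = "Tumor", Leukocyte = "Leukocyte", type)
}

#' Sample a synthetic cell table on a geometry
#'
#' Draws each configured subset from an inhomogeneous Poisson process by
#' thinning: candidate points uniform over the frame at the model's maximum
#' intensity, retained with probability `lambda(d)/lambda_max` where `d` is
#' the cell's true signed boundary distance.  Marker intensities are drawn
#' from the subset's "hi" log-normal component for its defining markers and
#' from the "lo" component otherwise; PD-L1/PD-1 "hi" status is drawn from
#' the distance-dependent checkpoint model and then expressed through the
#' corresponding intensity component.  Confidence is Beta-distributed.
#'
#' @param cfg A [synthetic_config()].
#' @param geom Geometry from [generate_geometry()].
#' @param seed RNG seed (defaults to `cfg$seed + 1`).
#' @return List with `cells` (standardized cell table, marker attribute
#'   set) and `truth` (per-cell ground truth: true type, compartment,
#'   signed distance, checkpoint states).
#' @export
sample_cells <- function(cfg, geom, seed = cfg$seed + 1) {
  frame_um <- geom$frame_um
  frame_mm2 <- prod(frame_um) / 1e6
  with_seed(seed, {
    recs <- list()
    for (type in names(cfg$subsets)) {
      mod <- cfg$subsets[[type]]
      lmax <- if (mod$model == "boundary_exp") mod$lambda0 else mod$lambda
      if (lmax <= 0) next
      m <- stats::rpois(1, lmax * frame_mm2)
      if (m == 0) next
      x <- runif(m, 0, frame_um[1])
      y <- runif(m, 0, frame_um[2])
      d <- sd_discs_or_na(x, y, geom)
      keep <- if (mod$model == "boundary_exp") {
        p <- exp(-abs(d) / mod$tau)
        side_ok <- switch(mod$side %||% "both",
                          both = TRUE, stroma = d >= 0, tumor = d < 0)
        runif(m) < p & side_ok
      } else {
        comp_ok <- switch(mod$compartment %||% "both",
                          both = TRUE, stroma = d >= 0, tumor = d < 0)
        rep(TRUE, m) & comp_ok
      }
      keep[is.na(keep)] <- FALSE
      if (!any(keep)) next
      recs[[type]] <- data.frame(true_type = type, x_um = x[keep],
                                 y_um = y[keep], true_d = d[keep],
                                 stringsAsFactors = FALSE)
    }
    if (!length(recs)) {
      warning("all subset intensities zero: empty cohort")
      empty <- empty_cells(cfg, geom$sample_id)
      return(list(cells = empty, truth = empty_truth()))
    }
    pts <- do.call(rbind, recs)
    n <- nrow(pts)
    ord <- order(pts$true_type, pts$x_um, pts$y_um,
                 method = "radix")  # locale-independent, seed-stable order
    pts <- pts[ord, , drop = FALSE]
    cells <- data.frame(
      sample_id = geom$sample_id,
      cell_id = sprintf("%s_c%06d", geom$sample_id, seq_len(n)),
      x_um = pts$x_um, y_um = pts$y_um,
      tissue_class = factor(ifelse(pts$true_d < 0, "EPI_TUMOR", "STROMA"),
                            levels = TISSUE_LEVELS),
      confidence = rbeta(n, cfg$confidence_shape[1], cfg$confidence_shape[2]),
      phenotype = vapply(pts$true_type, type_phenotype, ""),
      cell_area_um2 = rlnorm(n, log(80), 0.25),
      stringsAsFactors = FALSE)
    truth <- data.frame(cell_id = cells$cell_id, true_type = pts$true_type,
                        true_compartment = as.character(cells$tissue_class),
                        true_d = pts$true_d, stringsAsFactors = FALSE)
    # checkpoint hi/lo states
    chk_state <- list()
    for (mk in names(cfg$checkpoint)) {
      mod <- cfg$checkpoint[[mk]]
      pmaxv <- mod$p_by_type[pts$true_type]
      pmaxv[is.na(pmaxv)] <- 0
      p <- pmaxv * exp(-pmax(pts$true_d, 0) / mod$tau)
      chk_state[[mk]] <- runif(n) < p
      truth[[paste0("true_", mk, "_hi")]] <- chk_state[[mk]]
    }
    for (mk in cfg$markers) {
      im <- cfg$intensity[[mk]]
      hi <- if (mk %in% names(chk_state)) chk_state[[mk]] else
        vapply(pts$true_type, function(tt) mk %in% type_hi_markers(tt), TRUE)
      mu <- ifelse(hi, im$mean_hi, im$mean_lo)
      cells[[mk]] <- 10^rnorm(n, mu, im$sd)
      truth[[paste0("true_", mk, "_hi")]] <- hi
    }
    attr(cells, "markers") <- cfg$markers
    rownames(cells) <- rownames(truth) <- NULL
    list(cells = cells, truth = truth)
  })
}

sd_discs_or_na <- function(x, y, geom) {
  if (!has_tumor_region(geom)) return(rep(NA_real_, length(x)))
  sd_discs(x, y, geom$discs)
}

empty_cells <- function(cfg, sample_id) {
  cells <- data.frame(sample_id = character(0), cell_id = character(0),
                      x_um = numeric(0), y_um = numeric(0),
                      tissue_class = factor(character(0),
                                            levels = TISSUE_LEVELS),
                      confidence = numeric(0), phenotype = character(0),
                      cell_area_um2 = numeric(0), stringsAsFactors = FALSE)
  for (mk in cfg$markers) cells[[mk]] <- numeric(0)
  attr(cells, "markers") <- cfg$markers
  cells
}

empty_truth <- function() {
  data.frame(cell_id = character(0), true_type = character(0),
             true_compartment = character(0), true_d = numeric(0),
             stringsAsFactors = FALSE)
}

#' Sample survival times given band densities
#'
#' Exponential survival times with hazard `h0 * exp(beta * z)` where `z` is
#' the standardized band density; each patient is independently censored
#' with probability `censor_rate`, at a time uniform on `(0, T)`.
#'
#' @param cfg A [synthetic_config()].
#' @param band_density_by_patient Named numeric vector of band densities.
#' @param seed RNG seed (defaults to `cfg$seed + 2`).
#' @return Clinical table (`patient_id`, `time_months`, `event`) plus the
#'   true linear predictor as column `lp`.
#' @export
sample_survival <- function(cfg, band_density_by_patient,
                            seed = cfg$seed + 2) {
  sv <- cfg$survival
  if (sv$h0 <= 0) stop("h0 must be positive", call. = FALSE)
  v <- band_density_by_patient
  stopifnot(length(v) >= 2)
  z <- if (sd(v) > 0) (v - mean(v)) / sd(v) else rep(0, length(v))
  with_seed(seed, {
    n <- length(v)
    lp <- sv$beta * z
    t_event <- rexp(n, rate = sv$h0 * exp(lp))
    censored <- runif(n) < sv$censor_rate
    time <- ifelse(censored, runif(n) * t_event, t_event)
    data.frame(patient_id = names(v) %||% paste0("P", seq_len(n)),
               time_months = pmax(time, 1e-6), event = !censored,
               lp = lp, stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic cohort
#'
#' One sample per patient: geometry, cells and ground truth, the patient's
#' true density of the survival target subset (e.g. PD-L1 hi
#' CD68hiCD163hi cells) in the configured signed-distance band, and
#' survival times driven by that density.  Fully deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `cells` (all samples), `geoms` (named list),
#'   `truth`, `clinical`, `band_density`, `sample_to_patient`.
#' @export
generate_cohort <- function(cfg) {
  n <- cfg$survival$n_patients
  stopifnot(n >= 2)
  patients <- sprintf("P%03d", seq_len(n))
  geoms <- list()
  cells_list <- truth_list <- vector("list", n)
  band_density <- setNames(numeric(n), patients)
  edges <- c(cfg$survival$band_center - cfg$bin_width / 2,
             cfg$survival$band_center + cfg$bin_width / 2)
  # patient-level abundance heterogeneity shared across that patient's
  # subsets (log-normal multiplier on all spatial intensities)
  mult <- with_seed(cfg$seed + 13L,
                    rlnorm(n, 0, cfg$survival$patient_sd %||% 0.3))
  for (i in seq_len(n)) {
    sid <- paste0(patients[i], "_s1")
    cfg_i <- cfg
    cfg_i$subsets <- lapply(cfg$subsets, function(mod) {
      if (mod$model == "boundary_exp") mod$lambda0 <- mod$lambda0 * mult[i]
      else mod$lambda <- mod$lambda * mult[i]
      mod
    })
    g <- generate_geometry(cfg, sid, seed = cfg$seed + 7919L * i)
    geoms[[sid]] <- g
    sc <- sample_cells(cfg_i, g, seed = cfg$seed + 7919L * i + 1L)
    cells_list[[i]] <- sc$cells
    truth_list[[i]] <- cbind(sample_id = sid, sc$truth,
                             stringsAsFactors = FALSE)
    tr <- sc$truth
    sel <- tr$true_type == cfg$survival$target_subset
    if (!is.na(cfg$survival$target_checkpoint %||% NA)) {
      sel <- sel & tr[[paste0("true_", cfg$survival$target_checkpoint,
                              "_hi")]]
    }
    in_band <- sel & tr$true_d >= edges[1] & tr$true_d < edges[2]
    area <- band_areas(g, edges, method = "analytic")
    band_density[i] <- if (area > 0) sum(in_band) / area else NA_real_
  }
  clinical <- sample_survival(cfg, band_density, seed = cfg$seed + 3L)
  clinical$sample_ids <- as.list(paste0(clinical$patient_id, "_s1"))
  cells <- do.call(rbind, cells_list)
  attr(cells, "markers") <- cfg$markers
  list(cells = cells, geoms = geoms, truth = do.call(rbind, truth_list),
       clinical = clinical, band_density = band_density,
       sample_to_patient = setNames(patients, paste0(patients, "_s1")))
}
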