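#' Pipeline run configuration
#'
#' Bundles everything one analysis run needs: either a synthetic-cohort
#' configuration or paths to cell/geometry/clinical tables, the marker
#' panel, threshold methods, the profiling grid, the contact rule and the
#' distance bands tested for survival association.  Bands must sit on bin
#' centres of the configured grid; this is validated before any
#' computation.
#'
#' @param synthetic A [synthetic_config()], or `NULL` when reading tables.
#' @param cell_table,clinical_table Input paths (ignored for synthetic
#'   runs).  Geometry masks are read per sample as
#'   `<geometry_dir>/<sample_id>.csv` at `um_per_px`.
#' @param geometry_dir,um_per_px Mask locations and scale.
#' @param dialect [cell_dialect()] for the cell table.
#' @param min_conf Confidence filter cutoff.
#' @param threshold_methods Named list mapping marker to
#'   [fit_marker_threshold()] method.
#' @param bin_width,range_um Profiling grid (µm).
#' @param bands Signed band centres (µm) screened for survival association.
#' @param contact_slack,default_radius Contact rule parameters (µm).
#' @param alpha Significance level.
#' @param seed RNG seed for the run.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            cell_table = NULL, clinical_table = NULL,
                            geometry_dir = NULL, um_per_px = 2,
                            dialect = cell_dialect(),
                            min_conf = 0.5,
                            threshold_methods = list(CD68 = "gmm2",
                                                     CD163 = "gmm2",
                                                     PDL1 = "gmm2",
                                                     PD1 = "gmm2"),
                            bin_width = 25, range_um = c(-512.5, 512.5),
                            bands = c(-25, 25, 75),
                            contact_slack = 1, default_radius = 5,
                            alpha = 0.05, seed = 1L) {
  edges <- seq(range_um[1], range_um[2], by = bin_width)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  off <- vapply(bands, function(b) min(abs(centers - b)), 0)
  if (any(off > 1e-9)) {
    stop("band(s) not on the bin grid: ",
         paste(bands[off > 1e-9], collapse = ", "),
         "; available centers include ",
         paste(head(centers[centers >= 0], 6), collapse = ", "),
         call. = FALSE)
  }
  structure(list(synthetic = synthetic, cell_table = cell_table,
                 clinical_table = clinical_table,
                 geometry_dir = geometry_dir, um_per_px = um_per_px,
                 dialect = dialect, min_conf = min_conf,
                 threshold_methods = threshold_methods,
                 bin_width = bin_width, range_um = range_um, bands = bands,
                 contact_slack = contact_slack,
                 default_radius = default_radius, alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Per-compartment cell densities and relative densities
#'
#' Counts cells of each class in the epithelium/tumor and stroma
#' compartments of one sample, divides by the compartment areas (cells per
#' mm²), and expresses each class as a percentage of all counted cells in
#' that compartment.  Cells with tissue class `OTHER` are excluded.  A
#' zero-area compartment yields `NA` densities.
#'
#' @param cells Standardized cell table for one sample, with a `class`
#'   column (or supply `classes`).
#' @param geom The sample's [tissue_geometry].
#' @param classes Optional vector of class labels, one per cell.
#' @return `data.frame`: class, compartment, n, area_mm2, density_mm2,
#'   relative_pct.
#' @export
summarize_compartments <- function(cells, geom, classes = cells$class) {
  stopifnot(length(classes) == nrow(cells))
  areas <- compartment_areas(geom)
  keep <- cells$tissue_class %in% c("EPI_TUMOR", "STROMA")
  cells <- cells[keep, , drop = FALSE]
  classes <- factor(classes[keep])
  out <- expand.grid(class = levels(classes),
                     compartment = c("EPI_TUMOR", "STROMA"),
                     stringsAsFactors = FALSE)
  out$n <- mapply(function(cl, cp) {
    sum(classes == cl & cells$tissue_class == cp)
  }, out$class, out$compartment)
  out$area_mm2 <- areas[out$compartment]
  out$density_mm2 <- ifelse(out$area_mm2 > 0, out$n / out$area_mm2,
                            NA_real_)
  tot <- tapply(out$n, out$compartment, sum)
  out$relative_pct <- ifelse(tot[out$compartment] > 0,
                             100 * out$n / tot[out$compartment], NA_real_)
  rownames(out) <- NULL
  out
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes input loading (or synthetic generation), the confidence
#' filter, cohort-level threshold fitting, CD68/CD163 and checkpoint
#' classification, per-sample compartment summaries, distance profiles,
#' nearest-distance tables, checkpoint proportions, PD-1 hi T-cell contact
#' counts, and — when clinical data are present — the distance-band
#' correlation screen and median-split Kaplan-Meier/log-rank analyses at
#' the configured bands.  All tables are written as CSV under `out_dir`
#' together with a JSON manifest (config hash, seed, thresholds, row
#' counts per stage).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), msg))
  }
  counts <- list()

  # --- input ---------------------------------------------------------------
  inp <- stage("input", {
    if (!is.null(config$synthetic)) {
      generate_cohort(config$synthetic)
    } else {
      cells <- read_cell_table(config$cell_table, config$dialect)
      sids <- unique(cells$sample_id)
      geoms <- setNames(lapply(sids, function(s) {
        read_geometry_mask(file.path(config$geometry_dir,
                                     paste0(s, ".csv")),
                           s, config$um_per_px)
      }), sids)
      clinical <- if (!is.null(config$clinical_table)) {
        read_clinical_table(config$clinical_table)
      }
      s2p <- if (!is.null(clinical)) {
        setNames(rep(clinical$patient_id,
                     lengths(clinical$sample_ids)),
                 unlist(clinical$sample_ids))
      } else setNames(sids, sids)
      list(cells = cells, geoms = geoms, clinical = clinical,
           sample_to_patient = s2p)
    }
  })
  cells <- inp$cells
  markers <- attr(cells, "markers") %||% config$synthetic$markers
  counts$cells_raw <- nrow(cells)
  say("input: %d cells, %d samples", nrow(cells), length(inp$geoms))

  # --- confidence filter ---------------------------------------------------
  cells <- stage("confidence_filter",
                 filter_by_confidence(cells, config$min_conf))
  counts$cells_confident <- nrow(cells)
  say("confidence filter (> %.2f): %d cells retained", config$min_conf,
      nrow(cells))

  # --- thresholds (cohort-pooled) ------------------------------------------
  fits <- stage("thresholds", {
    fit_for <- intersect(names(config$threshold_methods), markers)
    setNames(lapply(fit_for, function(mk) {
      fit_marker_threshold(cells[[mk]],
                           method = config$threshold_methods[[mk]],
                           marker = mk)
    }), fit_for)
  })
  write_threshold_fits(fits, file.path(out_dir, "thresholds.json"))
  say("thresholds: %s",
      paste(sprintf("%s=%.3g", names(fits),
                    vapply(fits, `[[`, 0, "threshold")), collapse = ", "))

  # --- classification ------------------------------------------------------
  cells <- stage("classification", {
    is_mac <- !is.na(cells$phenotype) & cells$phenotype == "CD68CD163"
    cls <- ifelse(is.na(cells$phenotype), NA_character_, cells$phenotype)
    if (all(c("CD68", "CD163") %in% names(fits))) {
      sub <- classify_cd68_cd163(cells, fits$CD68, fits$CD163)
      cls[is_mac] <- as.character(sub[is_mac])
    }
    cells$class <- cls
    for (mk in intersect(c("PDL1", "PD1"), names(fits))) {
      cells[[paste0(mk, "_class")]] <-
        classify_checkpoint(cells, mk, fits[[mk]])
    }
    cells
  })

  # --- per-sample spatial analyses -----------------------------------------
  sids <- names(inp$geoms)
  comp <- stage("compartments", {
    do.call(rbind, lapply(sids, function(s) {
      cs <- cells[cells$sample_id == s, , drop = FALSE]
      if (!nrow(cs)) return(NULL)
      cbind(sample_id = s, summarize_compartments(cs, inp$geoms[[s]]))
    }))
  })
  write.csv(comp, file.path(out_dir, "compartment_summary.csv"),
            row.names = FALSE)

  subset_defs <- stage("subset_definitions", {
    defs <- list()
    for (cl in intersect(SUBSET_LEVELS, unique(cells$class))) {
      defs[[cl]] <- cells$class == cl
    }
    defs[["Tcell"]] <- cells$class == "Tcell"
    if ("PDL1_class" %in% names(cells)) {
      for (cl in intersect(c(SUBSET_LEVELS, "Tcell"), unique(cells$class))) {
        defs[[paste0(cl, "_PDL1hi")]] <-
          cells$class == cl & cells$PDL1_class == "hi"
      }
      defs[["Tumor_PDL1lo"]] <- cells$class == "Tumor" &
        cells$PDL1_class == "lo"
    }
    if ("PD1_class" %in% names(cells)) {
      defs[["Tcell_PD1hi"]] <- cells$class == "Tcell" &
        cells$PD1_class == "hi"
    }
    Filter(function(sel) any(sel), defs)
  })

  profiles <- stage("profiles", {
    setNames(lapply(names(subset_defs), function(nm) {
      density_profile(cells[subset_defs[[nm]], , drop = FALSE], inp$geoms,
                      bin_width = config$bin_width,
                      range_um = config$range_um)
    }), names(subset_defs))
  })
  prof_tab <- do.call(rbind, lapply(names(profiles), function(nm) {
    cbind(subset = nm, profile_table(profiles[[nm]]))
  }))
  write.csv(prof_tab, file.path(out_dir, "profiles.csv"), row.names = FALSE)
  say("profiles: %d subset(s) x %d bins", length(profiles),
      length(profiles[[1]]$centers))

  mnd <- stage("nearest_distance", {
    tumor <- cells[cells$class == "Tumor", , drop = FALSE]
    do.call(rbind, lapply(sids, function(s) {
      tu <- tumor[tumor$sample_id == s, , drop = FALSE]
      if (!nrow(tu)) return(NULL)
      do.call(rbind, lapply(names(subset_defs), function(nm) {
        fr <- cells[subset_defs[[nm]] & cells$sample_id == s, ,
                    drop = FALSE]
        if (!nrow(fr)) return(NULL)
        nd <- nearest_distance(fr, tu)
        data.frame(sample_id = s, subset = nm, n = nd$n_from,
                   mnd_um = nd$mnd)
      }))
    }))
  })
  write.csv(mnd, file.path(out_dir, "mnd.csv"), row.names = FALSE)

  chk <- stage("checkpoint_proportions", {
    out <- NULL
    for (mk in intersect(c("PDL1", "PD1"), sub("_class", "",
                         grep("_class$", names(cells), value = TRUE)))) {
      cl_col <- cells[[paste0(mk, "_class")]]
      hi_total <- sum(cl_col == "hi")
      for (cl in unique(cells$class[!is.na(cells$class)])) {
        sel <- !is.na(cells$class) & cells$class == cl
        out <- rbind(out, data.frame(
          marker = mk, class = cl, n = sum(sel),
          pct_hi_within_class = 100 * mean(cl_col[sel] == "hi"),
          pct_of_all_hi = if (hi_total > 0) {
            100 * sum(cl_col[sel] == "hi") / hi_total
          } else NA_real_))
      }
    }
    out
  })
  write.csv(chk, file.path(out_dir, "checkpoint_proportions.csv"),
            row.names = FALSE)

  contacts <- stage("contacts", {
    if (!all(c("PD1_class", "PDL1_class") %in% names(cells))) return(NULL)
    refs <- cells[cells$class == "Tcell" & cells$PD1_class == "hi", ,
                  drop = FALSE]
    partners <- cells[cells$PDL1_class == "hi" & !is.na(cells$class), ,
                      drop = FALSE]
    do.call(rbind, lapply(sids, function(s) {
      r <- refs[refs$sample_id == s, , drop = FALSE]
      p <- partners[partners$sample_id == s, , drop = FALSE]
      if (!nrow(r) || !nrow(p)) return(NULL)
      cr <- count_contacts(r, p, p$class, slack = config$contact_slack,
                           default_radius = config$default_radius)
      data.frame(sample_id = s, partner_class = names(cr$contact_fraction),
                 n_ref = nrow(r),
                 contact_fraction = unname(cr$contact_fraction),
                 total_pairs = unname(cr$total_pairs))
    }))
  })
  if (!is.null(contacts)) {
    write.csv(contacts, file.path(out_dir, "contacts.csv"),
              row.names = FALSE)
  }

  # --- survival association ------------------------------------------------
  surv_out <- NULL
  if (!is.null(inp$clinical)) {
    surv_out <- stage("survival", {
      s2p <- inp$sample_to_patient
      pts <- unique(unname(s2p))
      pat_profiles <- function(sel) {
        setNames(lapply(pts, function(p) {
          smp <- names(s2p)[s2p == p]
          density_profile(cells[sel & cells$sample_id %in% smp, ,
                                drop = FALSE],
                          inp$geoms[smp],
                          bin_width = config$bin_width,
                          range_um = config$range_um)
        }), pts)
      }
      targets <- intersect(c("CD68hiCD163hi_PDL1hi", "Tcell_PD1hi",
                             "Tumor_PDL1lo"), names(subset_defs))
      feats <- list()
      for (tg in targets) {
        pp <- pat_profiles(subset_defs[[tg]])
        for (b in config$bands) {
          feats[[paste0(tg, "@", b)]] <- band_covariate(pp, b)
        }
      }
      fmat <- do.call(cbind, feats)
      rownames(fmat) <- pts
      cl <- inp$clinical
      omat <- cbind(event = as.numeric(cl$event),
                    time_months = cl$time_months)
      rownames(omat) <- cl$patient_id
      omat <- omat[pts, , drop = FALSE]
      screen <- spearman_screen(fmat, omat, alpha = config$alpha)
      splits <- do.call(rbind, lapply(colnames(fmat), function(f) {
        v <- fmat[, f]
        if (sum(!is.na(v)) < 2) return(NULL)
        ms <- median_split(v)
        if (ms$degenerate || !length(ms$hi) || !length(ms$lo)) return(NULL)
        lr <- km_logrank(cl, ms$hi, ms$lo)
        data.frame(covariate = f, cutoff = ms$cutoff,
                   n_hi = length(ms$hi), n_lo = length(ms$lo),
                   chi2 = lr$chi2, p = lr$p)
      }))
      list(screen = screen, splits = splits, features = fmat)
    })
    write.csv(surv_out$screen, file.path(out_dir, "correlation_screen.csv"),
              row.names = FALSE)
    if (!is.null(surv_out$splits)) {
      write.csv(surv_out$splits, file.path(out_dir, "survival_splits.csv"),
                row.names = FALSE)
    }
    say("survival: %d covariate(s) screened", ncol(surv_out$features))
  }

  write_cell_table(cells, file.path(out_dir, "cells_classified.csv"))
  counts$cells_classified <- nrow(cells)

  cfg_json <- jsonlite::serializeJSON(config)
  manifest <- list(
    package = "spatTME",
    version = as.character(utils::packageVersion("spatTME")),
    seed = config$seed,
    config_sha = unname(substr(tools::md5sum(
      textConnection_write(cfg_json, out_dir)), 1, 32)),
    thresholds = setNames(lapply(fits, function(f) {
      list(method = f$method, threshold = f$threshold)
    }), names(fits)),
    row_counts = counts,
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(cells = cells, thresholds = fits, profiles = profiles,
                 compartments = comp, mnd = mnd, checkpoint = chk,
                 contacts = contacts, survival = surv_out,
                 manifest = manifest))
}

# write the serialized config next to outputs and hash the file
textConnection_write <- function(txt, out_dir) {
  p <- file.path(out_dir, "config.json")
  writeLines(txt, p)
  p
}
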