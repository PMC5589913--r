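#' Read a multi-page TIFF stack
#'
#' @param path TIFF file path.
#' @return list of numeric matrices, one per frame, in page order.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop_invalid(paste("no such file:", path), "io_error")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    storage.mode(p) <- "double"
    p
  })
}

#' Write a stack of matrices as a multi-page TIFF
#'
#' Label images are written as 16-bit integers; intensity images are
#' rescaled to [0, 1] 16-bit.
#'
#' @param stack list of matrices (all same size and type).
#' @param path output path.
#' @param labels TRUE for integer label movies.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, labels = FALSE) {
  if (labels) {
    mx <- max(1, max(unlist(lapply(stack, max))))
    if (mx > 65535) stop_invalid("too many labels for 16-bit TIFF", "io_error")
    pages <- lapply(stack, function(m) m / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16, reduce = FALSE)
  } else {
    lo <- min(unlist(lapply(stack, min))); hi <- max(unlist(lapply(stack, max)))
    pages <- lapply(stack, function(m) (m - lo) / max(hi - lo, 1e-12))
    tiff::writeTIFF(pages, path, bits.per.sample = 16, reduce = FALSE)
  }
  invisible(path)
}

# read a label movie written by write_stack(labels = TRUE); readTIFF with
# as.is = TRUE already returns raw 16-bit sample values
read_label_stack <- function(path) {
  lapply(read_stack(path), function(p) {
    m <- round(p)
    storage.mode(m) <- "integer"
    m
  })
}

#' Serialize tracked-tissue measurements to CSV tables
#'
#' Writes `cells.csv` (frame, cell_id, centroid, areas, perimeter, border
#' flag, neighbor list), `interfaces.csv` (frame, interface id, cell pair,
#' vertices, lengths, angle, class) and `vertices.csv` (frame, vertex id,
#' position) under `dir`.
#'
#' @param tracked a [tracked_tissue].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_tissue_tables <- function(tracked, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells <- do.call(rbind, lapply(tracked$frames, function(f) {
    if (!nrow(f$cells)) return(NULL)
    d <- f$cells
    data.frame(frame = f$frame_index, cell_id = d$cell_id,
               centroid_r = d$centroid_r, centroid_c = d$centroid_c,
               area_px = d$area_px, area_um2 = d$area_um2,
               perimeter_um = d$perimeter_um,
               touches_border = d$touches_border,
               neighbors = vapply(d$neighbors, paste, "", collapse = ";"))
  }))
  ints <- do.call(rbind, lapply(tracked$frames, function(f) {
    if (!nrow(f$interfaces)) return(NULL)
    d <- f$interfaces
    data.frame(frame = f$frame_index, interface_id = d$interface_id,
               cell_a = d$cell_a, cell_b = d$cell_b,
               vertex_1 = d$vertex_1, vertex_2 = d$vertex_2,
               length_px = d$length_px, length_um = d$length_um,
               angle_deg = d$angle_deg, class = d$class)
  }))
  verts <- do.call(rbind, lapply(tracked$frames, function(f) {
    if (!nrow(f$vertices)) return(NULL)
    data.frame(frame = f$frame_index, vertex_id = f$vertices$vertex_id,
               r = f$vertices$r, c = f$vertices$c)
  }))
  paths <- c(cells = file.path(dir, "cells.csv"),
             interfaces = file.path(dir, "interfaces.csv"),
             vertices = file.path(dir, "vertices.csv"))
  utils::write.csv(cells, paths["cells"], row.names = FALSE)
  utils::write.csv(ints, paths["interfaces"], row.names = FALSE)
  utils::write.csv(verts, paths["vertices"], row.names = FALSE)
  paths
}

#' Read a pipeline configuration from YAML
#'
#' The configuration mirrors the pipeline stages: `metadata` (pixel_size,
#' frame_interval), `inputs` (membrane / compartment stack paths, or a
#' `synthetic` block of [synth_tissue] / [synth_spot_movie] parameters),
#' `segmentation`, `detection`, `steps`, `association` parameter blocks,
#' `output_dir`, and `seed`.
#'
#' @param path YAML file.
#' @return config list (validated lightly; stage functions do the rest).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_invalid(paste("no such config:", path), "config_error")
  cfg <- yaml::read_yaml(path)
  for (p in c(cfg$inputs$membrane, cfg$inputs$compartments)) {
    if (!is.null(p) && !file.exists(p))
      stop_invalid(paste("input path does not exist:", p), "config_error")
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates segment -> track -> detect -> link -> associate -> steps ->
#' oscillate on a pair of movies (membrane + compartment channel), or on a
#' synthetic movie generated in place when the config carries a `synthetic`
#' block. All stage outputs are written as CSV under `output_dir`, and a
#' machine-readable JSON summary of the headline metrics (density profile,
#' polarity fractions, mean lifetimes by class, step metrics, oscillation
#' amplitude) is produced. Deterministic given the config seed.
#'
#' @param config list (see [read_pipeline_config]) or YAML path.
#' @return the summary list, invisibly; side effect: files under
#'   `config$output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out_dir <- config$output_dir %||% "pipeline_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  meta <- imaging_metadata(
    pixel_size = config$metadata$pixel_size %||% 0.164,
    frame_interval = config$metadata$frame_interval %||% 1)

  ## ---- inputs ----
  if (!is.null(config$synthetic)) {
    sy <- config$synthetic
    tis <- synth_tissue(mode = sy$mode %||% "control",
                        n_rows = sy$n_rows %||% 4, n_cols = sy$n_cols %||% 4,
                        n_frames = sy$n_frames %||% 120,
                        amplitude_pct = sy$amplitude_pct %||% 0,
                        n_steps = sy$n_steps %||% 3,
                        meta = meta, seed = seed)
    labels <- tis$labels
    spots <- synth_spot_movie(n_spots = sy$n_spots %||% 30,
                              n_frames = length(labels), lattice = tis,
                              polarity_fraction = sy$polarity_fraction %||% 0.57,
                              snr = sy$snr %||% 10,
                              frame_interval = meta$frame_interval,
                              seed = seed + 1)
    spot_stack <- spots$stack
  } else {
    membrane <- read_stack(config$inputs$membrane)
    spot_stack <- if (!is.null(config$inputs$compartments))
      read_stack(config$inputs$compartments) else NULL
    labels <- NULL
  }

  ## ---- segment + track ----
  if (is.null(labels)) {
    par_seg <- do.call(segmentation_params,
                       config$segmentation %||% list())
    frames <- lapply(seq_along(membrane), function(t)
      segment_frame(membrane[[t]], par_seg, meta, frame_index = t))
  } else {
    frames <- lapply(seq_along(labels), function(t)
      frame_from_labels(labels[[t]], meta, frame_index = t))
  }
  tracked <- track_cells(frames)
  write_tissue_tables(tracked, out_dir)
  classes <- classify_interfaces(tracked)

  ## ---- detect + link + associate ----
  assoc_summary <- NULL
  if (!is.null(spot_stack)) {
    det_par <- config$detection %||% list()
    det_args <- c(list(spot_stack),
                  det_par[intersect(names(det_par),
                                    c("J", "scales", "k_sigma",
                                      "user_threshold", "min_area"))])
    dets <- do.call(detect_particles_stack, det_args)
    trks <- link_tracks(dets,
                        max_link_dist = det_par$max_link_dist %||% 5,
                        frame_interval = meta$frame_interval)
    utils::write.csv(trks$detections, file.path(out_dir, "detections.csv"),
                     row.names = FALSE)
    utils::write.csv(trks$tracks, file.path(out_dir, "tracks.csv"),
                     row.names = FALSE)
    assoc <- associate_tracks(trks, tracked$frames)
    if (!is.null(assoc) && nrow(assoc)) {
      utils::write.csv(assoc, file.path(out_dir, "associations.csv"),
                       row.names = FALSE)
      dens <- density_profile(tracked$frames, assoc)
      utils::write.csv(dens$profile, file.path(out_dir, "density.csv"),
                       row.names = FALSE)
      lifetimes <- track_lifetimes(trks$tracks, length(tracked$frames),
                                   meta$frame_interval)
      cls_of <- classes$class[match(assoc$interface_id, classes$interface_id)]
      life_s <- assoc$lifetime_frames * meta$frame_interval
      assoc_summary <- list(
        fraction_vertical = dens$fraction_vertical,
        fraction_horizontal = dens$fraction_horizontal,
        mean_lifetime_AP_s = mean(life_s[cls_of %in% "AP"]),
        mean_lifetime_transverse_s = mean(life_s[cls_of %in% "transverse"]),
        mean_lifetime_all_s = lifetimes$mean_lifetime_s,
        n_tracks = nrow(trks$tracks))
    }
  }

  ## ---- steps on interface-length trajectories ----
  step_summary <- NULL
  len <- tracked$length_series
  min_len <- 21
  usable <- which(colSums(!is.na(len)) >= min_len)
  if (length(usable)) {
    anns <- list()
    for (j in usable) {
      x <- len[, j]
      ok <- which(!is.na(x))
      x <- x[min(ok):max(ok)]
      if (length(x) < min_len || anyNA(x)) next
      g <- rolling_gamma(x, windows = c(21, 41, 61, 81)[c(21, 41, 61, 81) <= length(x)])
      anns[[length(anns) + 1]] <- detect_steps(x, g,
                                               frame_interval = meta$frame_interval)
    }
    if (length(anns)) {
      sm <- step_metrics(anns)
      utils::write.csv(sm$per_interface, file.path(out_dir, "steps.csv"),
                       row.names = FALSE)
      step_summary <- sm$summary
    }
  }

  ## ---- oscillation amplitudes ----
  osc <- oscillation_amplitudes(tracked$area_series, meta$frame_interval)
  utils::write.csv(osc, file.path(out_dir, "oscillations.csv"), row.names = FALSE)

  summary <- list(
    config_seed = seed,
    n_frames = length(tracked$frames),
    n_cells = ncol(tracked$area_series),
    n_interfaces = ncol(tracked$length_series),
    association = assoc_summary,
    steps = step_summary,
    mean_amplitude_pct = mean(osc$mean_amplitude_pct, na.rm = TRUE))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
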