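#' Read and validate a run configuration
#'
#' Loads a YAML configuration and merges it over the package defaults,
#' which equal the published analysis parameters: 6-voxel radius exclusion,
#' particle area 60 to 1,000,000 um^2 and circularity 0.20 to 1.00, fill
#' cutoffs of 10,000 and 200 um^2, 75\% minimum fill, a 10 x 10 chunk grid
#' with a 7-voxel halo, and automatic histogram thresholds.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides named list applied on top of the file.
#' @return an object of class `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    seed = 1L,
    radius_threshold_vox = 6,
    chunk_grid = c(10L, 10L),
    chunk_halo = 7L,
    n_rays = 360L,
    particle_area_um2 = c(60, 1e6),
    particle_circularity = c(0.20, 1.00),
    fill_cutoffs_um2 = c(10000, 200),
    min_fill_pct = 75,
    thresholds = list(auto = TRUE, tissue = NULL, microfil = NULL),
    whole = list(stack_dir = NULL, cord_point = NULL, out_dir = "whole_out"),
    block = list(blocks_csv = NULL, out_dir = "block_out"),
    histology = list(manifest_csv = NULL, out_dir = "histology_out"),
    stats = list(blocks_density_csv = NULL, histology_blocks_csv = NULL,
                 out_dir = "stats_out")
  )
  cfg <- defaults
  merge_in <- function(cfg, upd) {
    for (nm in names(upd)) {
      if (is.list(upd[[nm]]) && is.list(cfg[[nm]])) {
        cfg[[nm]] <- merge_in(cfg[[nm]], upd[[nm]])
      } else {
        cfg[[nm]] <- upd[[nm]]
      }
    }
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) config_error(paste0("config file not found: ", path))
    cfg <- merge_in(cfg, yaml::read_yaml(path))
    cfg$config_path <- path
  }
  cfg <- merge_in(cfg, overrides)
  if (cfg$radius_threshold_vox <= 0) config_error("radius_threshold_vox must be positive")
  if (cfg$min_fill_pct < 0 || cfg$min_fill_pct > 100) {
    config_error("min_fill_pct must lie in [0, 100]")
  }
  structure(cfg, class = "run_config")
}

resolve_thresholds <- function(config, volume) {
  th <- config$thresholds
  if (isTRUE(th$auto)) return(find_thresholds(volume))
  if (is.null(th$tissue) || is.null(th$microfil)) {
    config_error("manual thresholds require both thresholds.tissue and thresholds.microfil")
  }
  threshold_pair(th$tissue, th$microfil)
}

write_provenance <- function(out_dir, config, extra = list()) {
  cfg <- unclass(config)
  hash_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, hash_file)
  prov <- c(list(
    package = "placvasc",
    version = as.character(utils::packageVersion("placvasc")),
    config_md5 = unname(tools::md5sum(hash_file)),
    seed = cfg$seed
  ), extra)
  unlink(hash_file)
  yaml::write_yaml(prov, file.path(out_dir, "provenance.yaml"))
  invisible(prov)
}

#' Run the whole-placenta analysis track
#'
#' Reads the slice stack, finds thresholds, segments tissue and vessels,
#' builds the cord-centred geometry from a maximum intensity projection,
#' skeletonises the vessel mask, measures radii, removes vessels thicker
#' than the radius threshold, and writes the per-chunk density map, the
#' 100-bin radial density profile and the skeleton table as CSV. Reruns
#' with the same configuration are bit-reproducible.
#'
#' @param config a [read_run_config()] result; needs `whole$stack_dir` and
#'   `whole$cord_point`.
#' @return list of result objects (profile, density map, skeleton,
#'   thresholds, geometry), invisibly; files in `whole$out_dir`.
#' @export
run_whole <- function(config) {
  if (is.null(config$whole$stack_dir)) config_error("whole.stack_dir is not set")
  if (is.null(config$whole$cord_point)) config_error("whole.cord_point is not set")
  volume <- read_stack(config$whole$stack_dir)
  thresholds <- resolve_thresholds(config, volume)
  seg <- segment_volume(volume, thresholds)
  mip <- max_intensity_projection(volume)
  planar_mask <- mip >= thresholds$tissue_threshold
  geometry <- compute_distance_map(planar_mask,
                                   as.numeric(config$whole$cord_point),
                                   n_rays = config$n_rays)
  skel <- skeletonise(seg$vessel_mask)
  skel <- measure_radius(skel, seg$vessel_mask, volume$voxel_size_um)
  filtered <- exclude_large_vessels(seg$vessel_mask, skel,
                                    config$radius_threshold_vox)
  regions <- chunk_region_labels(dim(volume$voxels), config$chunk_grid)
  dmap <- density_map(filtered, seg$tissue_mask, regions)
  profile <- radial_profile(filtered, seg$tissue_mask, geometry)

  out_dir <- config$whole$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(profile, file.path(out_dir, "profile.csv"), row.names = FALSE)
  write.csv(dmap, file.path(out_dir, "density_map.csv"), row.names = FALSE)
  write.csv(skeleton_to_df(skel), file.path(out_dir, "skeleton.csv"),
            row.names = FALSE)
  write_provenance(out_dir, config, list(
    tissue_threshold = thresholds$tissue_threshold,
    microfil_threshold = thresholds$microfil_threshold,
    global_density_pct = global_density(filtered, seg$tissue_mask)))
  invisible(list(profile = profile, density_map = dmap, skeleton = skel,
                 thresholds = thresholds, geometry = geometry,
                 filtered_vessel_mask = filtered))
}

#' Run the block micro-CT analysis track
#'
#' For each row of the block manifest (`placenta_id, block_id, stack_dir,
#' d_block_mm, d_edge_mm`), reads the block stack, computes the basal-third
#' vascular density and the normalised block location, and writes
#' `blocks_density.csv`.
#'
#' @param config a [read_run_config()] result; needs `block$blocks_csv`.
#' @return the block table, invisibly; file in `block$out_dir`.
#' @export
run_block <- function(config) {
  if (is.null(config$block$blocks_csv)) config_error("block.blocks_csv is not set")
  manifest <- read.csv(config$block$blocks_csv, stringsAsFactors = FALSE)
  if (nrow(manifest) == 0L) data_error("block manifest is empty")
  need <- c("placenta_id", "block_id", "stack_dir", "d_block_mm", "d_edge_mm")
  if (!all(need %in% names(manifest))) {
    data_error(paste("block manifest needs columns:", paste(need, collapse = ", ")))
  }
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    vol <- read_stack(r$stack_dir)
    th <- if (isTRUE(config$thresholds$auto)) NULL else resolve_thresholds(config, vol)
    bd <- block_density(vol, th)
    data.frame(placenta_id = r$placenta_id, block_id = r$block_id,
               normalised_location = normalise_block_location(r$d_block_mm, r$d_edge_mm),
               vessel_volume_vox = bd$vessel_volume_vox,
               tissue_plus_vessel_volume_vox = bd$tissue_volume_vox,
               density_pct = bd$density_pct)
  })
  out <- do.call(rbind, rows)
  out_dir <- config$block$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(out, file.path(out_dir, "blocks_density.csv"), row.names = FALSE)
  write_provenance(out_dir, config)
  invisible(out)
}

#' Run the histology analysis track
#'
#' For each micrograph in the manifest (`placenta_id, block_id, slide,
#' position, path, um_per_px`; position is `chorionic` or `basal`),
#' classifies pixels and runs the particle analysis, then aggregates per
#' block: vascular fill at the > 10,000 um^2 cutoff over all micrographs,
#' villous vascular fill at the > 200 um^2 cutoff over basal micrographs
#' only (the region analysed at the block imaging scale), the histological
#' vascular density, and the fill-based inclusion flag. Writes
#' `particles.csv` and `histology_blocks.csv`.
#'
#' @param config a [read_run_config()] result; needs `histology$manifest_csv`.
#' @return the per-block table, invisibly.
#' @export
run_histology <- function(config) {
  if (is.null(config$histology$manifest_csv)) {
    config_error("histology.manifest_csv is not set")
  }
  manifest <- read.csv(config$histology$manifest_csv, stringsAsFactors = FALSE)
  if (nrow(manifest) == 0L) data_error("histology manifest is empty")
  need <- c("placenta_id", "block_id", "slide", "position", "path", "um_per_px")
  if (!all(need %in% names(manifest))) {
    data_error(paste("histology manifest needs columns:", paste(need, collapse = ", ")))
  }
  classifier <- default_pixel_classifier()
  all_particles <- list()
  per_micrograph <- list()
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    img <- load_rgb_image(r$path)
    res <- analyse_micrograph(img, r$um_per_px, classifier = classifier,
                              area_range_um2 = config$particle_area_um2,
                              circ_range = config$particle_circularity)
    p <- res$particles
    if (nrow(p)) {
      p$placenta_id <- r$placenta_id
      p$block_id <- r$block_id
      p$slide <- r$slide
      p$position <- r$position
      all_particles[[i]] <- p
    }
    per_micrograph[[i]] <- data.frame(
      placenta_id = r$placenta_id, block_id = r$block_id,
      position = r$position, villous_area_um2 = res$villous_area_um2,
      idx = i)
  }
  particles <- do.call(rbind, all_particles)
  mg <- do.call(rbind, per_micrograph)

  block_key <- unique(mg[, c("placenta_id", "block_id")])
  cut_hi <- config$fill_cutoffs_um2[1]
  cut_lo <- config$fill_cutoffs_um2[2]
  rows <- lapply(seq_len(nrow(block_key)), function(k) {
    pid <- block_key$placenta_id[k]; bid <- block_key$block_id[k]
    pb <- particles[particles$placenta_id == pid & particles$block_id == bid, , drop = FALSE]
    basal <- pb[pb$position == "basal", , drop = FALSE]
    villous <- sum(mg$villous_area_um2[mg$placenta_id == pid & mg$block_id == bid])
    data.frame(
      placenta_id = pid, block_id = bid,
      fill_10000 = vascular_fill(pb, cut_hi),
      fill_200 = vascular_fill(basal, cut_lo),
      density_pct = if (villous > 0) vascular_density_histology(pb, villous) else NA_real_,
      villous_area_um2 = villous)
  })
  blocks <- do.call(rbind, rows)
  blocks$included <- !is.na(blocks$fill_200) & blocks$fill_200 >= config$min_fill_pct

  out_dir <- config$histology$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(particles)) {
    write.csv(particles, file.path(out_dir, "particles.csv"), row.names = FALSE)
  }
  write.csv(blocks, file.path(out_dir, "histology_blocks.csv"), row.names = FALSE)
  write_provenance(out_dir, config,
                   list(n_blocks = nrow(blocks),
                        n_excluded = sum(!blocks$included)))
  invisible(blocks)
}

#' Run the statistical analysis track
#'
#' Consumes the block-density and/or histology tables, applies the
#' inclusion rule to the histology blocks, and reports the Spearman
#' correlation of density against normalised location and the
#' Kruskal-Wallis/Dunn comparison of density across placentas.
#'
#' @param config a [read_run_config()] result; needs at least one of
#'   `stats$blocks_density_csv`, `stats$histology_blocks_csv`.
#' @return list of result objects, invisibly; `report.yaml` on disk.
#' @export
run_stats <- function(config) {
  bd_csv <- config$stats$blocks_density_csv
  hb_csv <- config$stats$histology_blocks_csv
  if (is.null(bd_csv) && is.null(hb_csv)) {
    config_error("stats needs blocks_density_csv and/or histology_blocks_csv")
  }
  report <- list()
  results <- list()
  if (!is.null(bd_csv)) {
    bd <- read.csv(bd_csv, stringsAsFactors = FALSE)
    if (nrow(bd) == 0L) data_error("blocks_density table is empty")
    corr <- spearman_correlation(bd$normalised_location, bd$density_pct)
    results$block_correlation <- corr
    report$block <- list(
      n_blocks = nrow(bd),
      density_summary = summarise_values(bd$density_pct),
      location_correlation = list(r_s = corr$r_s, p = corr$p, n = corr$n))
    if (length(unique(bd$placenta_id)) >= 2L &&
        all(table(bd$placenta_id) >= 2L)) {
      kw <- kruskal_wallis_dunn(bd$density_pct, bd$placenta_id)
      results$block_groups <- kw
      report$block$kruskal_wallis <- list(H = kw$H, df = kw$df, p = kw$p)
    }
  }
  if (!is.null(hb_csv)) {
    hb <- read.csv(hb_csv, stringsAsFactors = FALSE)
    if (nrow(hb) == 0L) data_error("histology_blocks table is empty")
    included <- apply_inclusion_rule(hb, config$min_fill_pct)
    report$histology <- list(
      n_blocks = nrow(hb),
      n_excluded = attr(included, "n_excluded"),
      density_summary = summarise_values(hb$density_pct))
    if ("normalised_location" %in% names(included) && nrow(included) >= 3L) {
      corr <- spearman_correlation(included$normalised_location,
                                   included$density_pct)
      results$histology_correlation <- corr
      report$histology$location_correlation <-
        list(r_s = corr$r_s, p = corr$p, n = corr$n)
    }
    if (length(unique(hb$placenta_id)) >= 2L && all(table(hb$placenta_id) >= 2L)) {
      kw <- kruskal_wallis_dunn(hb$density_pct, hb$placenta_id)
      results$histology_groups <- kw
      report$histology$kruskal_wallis <- list(H = kw$H, df = kw$df, p = kw$p)
    }
    results$included_histology_blocks <- included
  }
  out_dir <- config$stats$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(report, file.path(out_dir, "report.yaml"))
  write_provenance(out_dir, config)
  results$report <- report
  invisible(results)
}

#' Load an RGB image from TIFF or PNG
#'
#' @param path image file.
#' @return H x W x 3 array in \[0, 1\].
#' @export
load_rgb_image <- function(path) {
  if (!file.exists(path)) data_error(paste0("image not found: ", path))
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 2L) data_error("micrograph must be RGB, got greyscale")
  img[, , 1:3, drop = FALSE]
}

#' Save an RGB image as TIFF
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_rgb_image <- function(image, path) {
  tiff::writeTIFF(image, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}
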