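#' Pipeline stages
#'
#' The screen pipeline is composable from four stages, each of which reads
#' the previous stage's serialized outputs from the run directory, so any
#' stage can be re-run standalone with identical results (images and label
#' maps round-trip losslessly through 16-bit TIFF):
#'
#' * `stage_simulate()` — render the layout into per-field channel TIFFs
#'   plus plate map and ground-truth CSVs;
#' * `stage_segment()` — nucleus + cytoplasm label maps for every field,
#'   written as label TIFFs;
#' * `stage_measure()` — per-cell records, plate-context pyknosis flags and
#'   per-well summaries (`cells.csv`, `wells.csv`);
#' * `stage_analyze()` — normalization, Z-scores, hit calls, top-k ranking,
#'   clustering, heat map (`zscore.csv`, `hits.csv`, `top_hits.csv`,
#'   `dendrogram.nwk`, `heatmap.png`).
#'
#' @param layout A `plate_layout` data frame.
#' @param config Full configuration list ([default_config()]).
#' @param seed Run seed.
#' @param run_dir Run directory.
#' @return The run directory, invisibly.
#' @name pipeline-stages
NULL

#' @rdname pipeline-stages
#' @export
stage_simulate <- function(layout, config, seed, run_dir) {
  dir.create(file.path(run_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  sim <- simulate_plate(layout, config = config, seed = seed,
                        out_dir = file.path(run_dir, "images"))
  write_plate_map(layout, file.path(run_dir, "plate_map.csv"))
  write.csv(sim$cells, file.path(run_dir, "truth_cells.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(sim$well_classes, file.path(run_dir, "truth_wells.csv"),
            row.names = FALSE, quote = FALSE)
  cfg <- config; cfg$seed <- seed
  write_config(cfg, file.path(run_dir, "config_echo.yaml"))
  invisible(run_dir)
}

segment_field <- function(field, config) {
  nuclei <- segment_nuclei(field$channels$nuclear_dye, config$segmentation)
  cytoplasm <- segment_cytoplasm(field$channels$cyto_dye, nuclei,
                                 config$segmentation)
  list(nuclei = nuclei, cytoplasm = cytoplasm)
}

write_label_tiff <- function(labels, path) {
  if (max(labels) > 65535) stop("label overflow for 16-bit export")
  tiff::writeTIFF(unclass(labels) / 65535, path, bits.per.sample = 16L,
                  compression = "none")
}

read_label_tiff <- function(path, kind) {
  label_map(round(tiff::readTIFF(path) * 65535), kind)
}

#' @rdname pipeline-stages
#' @export
stage_segment <- function(run_dir, config = NULL) {
  if (is.null(config)) config <- read_run_config(run_dir)
  layout <- read_plate_map(file.path(run_dir, "plate_map.csv"))
  dir.create(file.path(run_dir, "labels"), showWarnings = FALSE)
  fpw <- config$generator$fields_per_well
  for (w in seq_len(nrow(layout))) {
    row <- layout[w, ]
    for (f in seq_len(fpw) - 1L) {
      field <- read_field_tiffs(file.path(run_dir, "images"), row$plate_id,
                                row$well_id, f,
                                channels = config$generator$channels,
                                pixel_size_um = config$generator$pixel_size_um)
      seg <- segment_field(field, config)
      base <- sprintf("%s_%s_f%d", row$plate_id, row$well_id, f)
      write_label_tiff(seg$nuclei,
                       file.path(run_dir, "labels",
                                 paste0(base, "_nuclei.tif")))
      write_label_tiff(seg$cytoplasm,
                       file.path(run_dir, "labels",
                                 paste0(base, "_cytoplasm.tif")))
    }
  }
  invisible(run_dir)
}

#' @rdname pipeline-stages
#' @export
stage_measure <- function(run_dir, config = NULL) {
  if (is.null(config)) config <- read_run_config(run_dir)
  layout <- read_plate_map(file.path(run_dir, "plate_map.csv"))
  fpw <- config$generator$fields_per_well
  records <- vector("list", nrow(layout))
  for (w in seq_len(nrow(layout))) {
    row <- layout[w, ]
    recs <- vector("list", fpw)
    for (f in seq_len(fpw) - 1L) {
      field <- read_field_tiffs(file.path(run_dir, "images"), row$plate_id,
                                row$well_id, f,
                                channels = config$generator$channels,
                                pixel_size_um = config$generator$pixel_size_um)
      base <- sprintf("%s_%s_f%d", row$plate_id, row$well_id, f)
      nuclei <- read_label_tiff(file.path(run_dir, "labels",
                                          paste0(base, "_nuclei.tif")),
                                "nucleus")
      cytoplasm <- read_label_tiff(file.path(run_dir, "labels",
                                             paste0(base, "_cytoplasm.tif")),
                                   "cytoplasm")
      recs[[f + 1L]] <- measure_cells(field, nuclei, cytoplasm,
                                      config$features)
    }
    recs <- do.call(rbind, recs)
    if (nrow(recs) > 0) recs$plate_id <- row$plate_id
    records[[w]] <- recs
  }
  cells <- do.call(rbind, records)
  finalize_measurements(cells, layout, config, run_dir)
}

# Pyknosis flags from plate-level control context, then well summaries.
finalize_measurements <- function(cells, layout, config, run_dir) {
  feat <- config$features
  for (p in unique(layout$plate_id)) {
    ctrl_wells <- layout$well_id[layout$plate_id == p &
                                   layout$role == "negative_control"]
    on_plate <- cells$plate_id == p
    ctx <- control_context(cells[on_plate & cells$well_id %in% ctrl_wells, ])
    cells$pyknotic[on_plate] <- pyknosis_flag(cells[on_plate, ], ctx,
                                              alpha = feat$pyknosis_alpha,
                                              beta = feat$pyknosis_beta)
  }
  wells <- do.call(rbind, lapply(seq_len(nrow(layout)), function(w) {
    row <- layout[w, ]
    recs <- cells[cells$plate_id == row$plate_id &
                    cells$well_id == row$well_id, ]
    summarize_well(recs, row, min_cells = feat$min_cells_per_well)
  }))
  if (!is.null(run_dir)) {
    write.csv(cells, file.path(run_dir, "cells.csv"), row.names = FALSE,
              quote = FALSE)
    write.csv(wells, file.path(run_dir, "wells.csv"), row.names = FALSE,
              quote = FALSE)
  }
  list(cells = cells, wells = wells)
}

#' @rdname pipeline-stages
#' @export
stage_analyze <- function(run_dir, config = NULL) {
  if (is.null(config)) config <- read_run_config(run_dir)
  wells <- read.csv(file.path(run_dir, "wells.csv"),
                    stringsAsFactors = FALSE)
  wells$biotin <- as.logical(wells$biotin)
  analyze_wells(wells, config, run_dir)
}

analyze_wells <- function(wells, config, run_dir) {
  an <- config$analysis
  sm <- screen_matrix(wells, an$features)
  sm <- normalize_intraplate(sm)
  sm <- zscore(sm, population = an$z_population)
  hits <- call_hits(sm, thresholds = list(t_hit = an$t_hit,
                                          t_null = an$t_null,
                                          t_tox = an$t_tox))
  top <- rank_top_k(hits, an$top_k)

  cl <- NULL
  active <- hits[hits$class != "inactive", , drop = FALSE]
  if (nrow(active) >= 2) {
    prof <- as.matrix(active[, c("z_cyto_plus", "z_cyto_minus",
                                 "z_nuc_plus", "z_nuc_minus",
                                 "pyknosis_z_plus")])
    rownames(prof) <- paste0(active$compound_id, "@",
                             active$concentration_uM)
    ok <- apply(prof, 1, function(x) all(is.finite(x)) && sd(x) > 0)
    if (sum(ok) >= 2) cl <- cluster_profiles(prof[ok, , drop = FALSE])
  }

  if (!is.null(run_dir)) {
    zs <- cbind(sm$meta, as.data.frame(sm$values))
    write.csv(zs, file.path(run_dir, "zscore.csv"), row.names = FALSE,
              quote = FALSE)
    write.csv(hits, file.path(run_dir, "hits.csv"), row.names = FALSE,
              quote = FALSE)
    write.csv(top, file.path(run_dir, "top_hits.csv"), row.names = FALSE,
              quote = FALSE)
    if (!is.null(cl)) {
      write_dendrogram_newick(cl, file.path(run_dir, "dendrogram.nwk"))
      prof <- as.matrix(active[, c("z_cyto_plus", "z_cyto_minus",
                                   "z_nuc_plus", "z_nuc_minus",
                                   "pyknosis_z_plus")])
      rownames(prof) <- paste0(active$compound_id, "@",
                               active$concentration_uM)
      ok <- rownames(prof) %in% cl$labels
      plot_heatmap(prof[ok, , drop = FALSE], cl,
                   file.path(run_dir, "heatmap.png"))
    }
  }
  list(matrix = sm, hits = hits, top = top, cluster = cl)
}

read_run_config <- function(run_dir) {
  p <- file.path(run_dir, "config_echo.yaml")
  if (!file.exists(p)) stop("no config_echo.yaml in ", run_dir)
  cfg <- yaml::read_yaml(p)
  seed <- cfg$seed; cfg$seed <- NULL
  cfg <- merge_config(default_config(), cfg)
  cfg$generator$field_shape <- as.integer(cfg$generator$field_shape)
  cfg$seed <- seed
  cfg
}

#' Run the full screen pipeline
#'
#' Simulate, segment, measure and analyze a layout in one call. With
#' `save_images = TRUE` the four stages run against the run directory
#' exactly as the standalone stage functions would; the default streams
#' fields through memory (identical results — the on-disk path is a
#' lossless round trip) and only writes the tables, which keeps a full
#' 384-well x 4-field run within desk-scale memory. A structured log
#' (`run_log.txt`) records the seed, a configuration digest and per-stage
#' counts; all CSV outputs are bit-identical across reruns of the same
#' config + seed.
#'
#' @param layout A `plate_layout` data frame (see [build_layout()]).
#' @param config Full configuration list.
#' @param seed Run seed.
#' @param run_dir Output directory (created if needed).
#' @param save_images Write field and label TIFFs and run the staged
#'   pipeline?
#' @return List with `cells`, `wells`, `matrix`, `hits`, `top`, `cluster`,
#'   `truth` (ground-truth tables), invisibly also written to `run_dir`.
#' @export
run_screen <- function(layout, config = default_config(), seed = 1,
                       run_dir, save_images = FALSE) {
  validate_config(config)
  validate_layout(layout)
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[3]

  if (save_images) {
    stage_simulate(layout, config, seed, run_dir)
    stage_segment(run_dir, config)
    mm <- stage_measure(run_dir, config)
    truth <- list(
      cells = read.csv(file.path(run_dir, "truth_cells.csv"),
                       stringsAsFactors = FALSE),
      wells = read.csv(file.path(run_dir, "truth_wells.csv"),
                       stringsAsFactors = FALSE))
  } else {
    g <- config$generator
    plates <- unique(layout$plate_id)
    n_fields <- g$fields_per_well
    records <- vector("list", nrow(layout))
    truth_cells <- vector("list", nrow(layout))
    for (w in seq_len(nrow(layout))) {
      row <- layout[w, ]
      p_idx <- match(row$plate_id, plates)
      mix <- phenotype_mixture(row$class, row$biotin, row$effect)
      iscale <- if (row$class == "nonspecific_loss") 1 - row$effect else 1
      recs <- vector("list", n_fields)
      tc <- vector("list", n_fields)
      for (f in seq_len(n_fields) - 1L) {
        fs <- field_seed(seed, p_idx, row$well_id, f)
        cells <- sample_cell_population(mix, g$cells_per_field,
                                        g$field_shape, seed = fs,
                                        tolerance_px = g$placement_tolerance_px,
                                        max_attempts = g$max_place_attempts)
        field <- render_field(cells, g, seed = fs + 1L,
                              intensity_scale = iscale,
                              well_id = row$well_id, field_index = f)
        seg <- segment_field(field, config)
        recs[[f + 1L]] <- measure_cells(field, seg$nuclei, seg$cytoplasm,
                                        config$features)
        tc[[f + 1L]] <- if (nrow(cells) > 0)
          cbind(plate_id = row$plate_id, well_id = row$well_id,
                field_index = f, cells, stringsAsFactors = FALSE)
      }
      recs <- do.call(rbind, recs)
      if (nrow(recs) > 0) recs$plate_id <- row$plate_id
      records[[w]] <- recs
      truth_cells[[w]] <- do.call(rbind, tc)
    }
    cells_df <- do.call(rbind, records)
    write_plate_map(layout, file.path(run_dir, "plate_map.csv"))
    truth <- list(cells = do.call(rbind, truth_cells),
                  wells = data.frame(plate_id = layout$plate_id,
                                     well_id = layout$well_id,
                                     class = layout$class,
                                     effect = layout$effect,
                                     biotin = layout$biotin,
                                     stringsAsFactors = FALSE))
    write.csv(truth$cells, file.path(run_dir, "truth_cells.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(truth$wells, file.path(run_dir, "truth_wells.csv"),
              row.names = FALSE, quote = FALSE)
    cfg <- config; cfg$seed <- seed
    write_config(cfg, file.path(run_dir, "config_echo.yaml"))
    mm <- finalize_measurements(cells_df, layout, config, run_dir)
  }

  # analyze from the serialized well table, so streaming and staged runs
  # agree bit for bit (the CSV is the interface between the stages)
  res <- stage_analyze(run_dir, config)

  log_lines <- c(
    "rushscreen run log",
    paste0("seed: ", seed),
    paste0("config_md5: ",
           unname(tools::md5sum(file.path(run_dir, "config_echo.yaml")))),
    paste0("plates: ", length(unique(layout$plate_id))),
    paste0("wells: ", nrow(layout)),
    paste0("fields_per_well: ", config$generator$fields_per_well),
    paste0("cells_measured: ", nrow(mm$cells)),
    paste0("wells_low_count: ", sum(mm$wells$low_count)),
    paste0("hits_by_class: ",
           paste(names(table(res$hits$class)), table(res$hits$class),
                 sep = "=", collapse = " ")),
    paste0("elapsed_s: ", round(proc.time()[3] - t0, 1))
  )
  writeLines(log_lines, file.path(run_dir, "run_log.txt"))

  invisible(list(cells = mm$cells, wells = mm$wells, matrix = res$matrix,
                 hits = res$hits, top = res$top, cluster = res$cluster,
                 truth = truth))
}
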