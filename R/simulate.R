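#' Sample a cell population for one field
#'
#' Draws `n_cells` cell specifications: centers placed by rejection sampling
#' so that no two nuclei overlap by more than `tolerance_px` (center
#' distance >= r_i + r_j - tolerance), phenotypes assigned by the mixture
#' weights, nucleus radii drawn from a truncated normal with the phenotype's
#' mean and CV (pyknotic radii additionally shrunk by the phenotype's shrink
#' factor). Deterministic given the seed.
#'
#' @param phenotype_mix Named numeric vector of mixture weights (names from
#'   the phenotype set), summing to 1.
#' @param n_cells Number of cells (>= 0).
#' @param field_shape Integer vector `c(rows, cols)` in pixels.
#' @param seed Integer seed.
#' @param phenotypes Named list of [phenotype_spec()] objects.
#' @param tolerance_px Allowed nucleus-nucleus overlap, pixels.
#' @param max_attempts Rejection-sampling attempts per cell before a
#'   placement error is raised.
#' @return Data frame (one row per cell): `x` (column), `y` (row),
#'   `phenotype`, `nucleus_radius`. This table is also the per-cell ground
#'   truth for the field.
#' @export
#' @examples
#' cells <- sample_cell_population(c(punctate_retained = 1), 20,
#'                                 c(256L, 256L), seed = 1)
#' nrow(cells)
sample_cell_population <- function(phenotype_mix, n_cells,
                                   field_shape = c(768L, 768L), seed = 1,
                                   phenotypes = default_phenotypes(),
                                   tolerance_px = 0, max_attempts = 500L) {
  stopifnot(n_cells >= 0, all(phenotype_mix >= 0))
  if (abs(sum(phenotype_mix) - 1) > 1e-8)
    stop("phenotype_mix weights must sum to 1")
  bad <- setdiff(names(phenotype_mix), names(phenotypes))
  if (length(bad) > 0)
    stop("unknown phenotype(s) in mix: ", paste(bad, collapse = ", "))
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      phenotype = character(0), nucleus_radius = numeric(0),
                      stringsAsFactors = FALSE)
  if (n_cells == 0) return(empty)

  withr::with_seed(seed, {
    phen <- sample(names(phenotype_mix), n_cells, replace = TRUE,
                   prob = phenotype_mix)
    radius <- vapply(phen, function(ph) {
      sp <- phenotypes[[ph]]
      r <- rnorm(1, sp$nucleus_radius_mean,
                 sp$nucleus_radius_cv * sp$nucleus_radius_mean)
      r <- min(max(r, sp$nucleus_radius_mean * 0.55),
               sp$nucleus_radius_mean * 1.45)
      r * sp$pyknotic_shrink_factor
    }, numeric(1))

    nr <- field_shape[1]; nc <- field_shape[2]
    margin <- 2
    xs <- numeric(n_cells); ys <- numeric(n_cells)
    for (i in seq_len(n_cells)) {
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        cx <- runif(1, 1 + margin, nc - margin)
        cy <- runif(1, 1 + margin, nr - margin)
        if (i == 1) { ok <- TRUE } else {
          j <- seq_len(i - 1)
          d <- sqrt((xs[j] - cx)^2 + (ys[j] - cy)^2)
          ok <- all(d >= radius[j] + radius[i] - tolerance_px)
        }
        if (ok) { xs[i] <- cx; ys[i] <- cy; placed <- TRUE; break }
      }
      if (!placed)
        stop("placement error: could not place cell ", i, " of ", n_cells,
             " in a ", nr, "x", nc, " field at overlap tolerance ",
             tolerance_px, " px")
    }
    data.frame(x = xs, y = ys, phenotype = unname(phen),
               nucleus_radius = unname(radius), stringsAsFactors = FALSE)
  })
}

# Anti-aliased disk coverage on a local window: w in [0,1] is the pixel
# coverage of the disk, rows/cols are the window indices in the field.
disk_patch <- function(cx, cy, r, nr, nc) {
  i0 <- max(1L, as.integer(floor(cy - r - 1)))
  i1 <- min(nr, as.integer(ceiling(cy + r + 1)))
  j0 <- max(1L, as.integer(floor(cx - r - 1)))
  j1 <- min(nc, as.integer(ceiling(cx + r + 1)))
  if (i0 > i1 || j0 > j1) return(NULL)
  ii <- i0:i1; jj <- j0:j1
  d <- sqrt(outer((ii - cy)^2, (jj - cx)^2, "+"))
  w <- pmin(pmax(r + 0.5 - d, 0), 1)
  list(ii = ii, jj = jj, w = w)
}

#' Render one multichannel field image
#'
#' Draws each cell into the configured channels: the nuclear dye as a soft
#' (anti-aliased) disk at the nucleus (pyknotic nuclei are shrunk and
#' brightened by `pyknotic_dye_gain`); the cytoplasmic dye as the larger
#' concentric cell-body disk; the reporter by splitting each cell's total
#' reporter between nucleus and cytoplasmic annulus according to its
#' phenotype's `cytoplasmic_reporter_fraction`, with the nuclear pool drawn
#' as Gaussian puncta (punctate phenotype) or uniformly (all others). An
#' optional `hook` channel renders puncta at the same punctum positions for
#' every non-pyknotic cell. Per-cell total reporter is log-normal
#' (`reporter_cv`) around `nuclear_reporter_mean x nucleus area` and is
#' renormalized over in-field pixels, so with noise and background disabled
#' the rendered per-cell integral equals the drawn total exactly (up to
#' 16-bit quantization). Additive background plus mean-dependent camera
#' noise (variance = `noise_gain` x mean + `read_noise_sd`^2) is applied
#' last and the result quantized to integer counts in [0, 65535].
#'
#' @param cells Cell specification table from [sample_cell_population()].
#' @param config Generator configuration (the `generator` element of
#'   [default_config()]).
#' @param seed Integer seed (noise and per-cell intensity draws).
#' @param intensity_scale Scalar multiplier on all reporter totals (used to
#'   model nonspecific signal loss / quenching).
#' @param well_id,field_index Identifiers stored in the result.
#' @param phenotypes Named list of [phenotype_spec()] objects to render
#'   from (defaults to [default_phenotypes()]).
#' @return A `field_image` object: list with `channels` (named list of
#'   matrices), `pixel_size_um`, `well_id`, `field_index`, `rng_seed`.
#' @export
render_field <- function(cells, config = default_config()$generator,
                         seed = 1, intensity_scale = 1,
                         well_id = "A01", field_index = 0L,
                         phenotypes = default_phenotypes()) {
  known <- c("nuclear_dye", "cyto_dye", "reporter", "hook")
  bad <- setdiff(config$channels, known)
  if (length(bad) > 0)
    stop("unknown channel name(s) in config: ", paste(bad, collapse = ", "))
  channels <- config$channels
  if (isTRUE(config$include_hook) && !("hook" %in% channels))
    channels <- c(channels, "hook")
  nr <- config$field_shape[1]; nc <- config$field_shape[2]

  # Local matrices with inline indexed assignment keep the per-cell patch
  # additions in place (no full-matrix copies inside the cell loop).
  ch_nuc <- matrix(0, nr, nc)
  ch_cyt <- matrix(0, nr, nc)
  ch_rep <- matrix(0, nr, nc)
  want_hook <- "hook" %in% channels
  ch_hook <- if (want_hook) matrix(0, nr, nc) else NULL

  # Gaussian punctum mixture on a nucleus window, masked by coverage.
  puncta_weights <- function(p, cx, cy, r_nuc, n_puncta, sigma) {
    pw <- matrix(0, nrow(p$w), ncol(p$w))
    ang <- runif(n_puncta, 0, 2 * pi)
    rad <- sqrt(runif(n_puncta)) * 0.7 * r_nuc
    px <- cx + rad * cos(ang); py <- cy + rad * sin(ang)
    for (q in seq_len(n_puncta)) {
      pw <- pw + exp(-0.5 * outer((p$ii - py[q])^2, (p$jj - px[q])^2, "+") /
                       sigma^2)
    }
    pw * p$w
  }

  withr::with_seed(seed, {
    n <- nrow(cells)
    if (n > 0) for (k in seq_len(n)) {
      sp <- phenotypes[[cells$phenotype[k]]]
      cx <- cells$x[k]; cy <- cells$y[k]
      r_nuc <- cells$nucleus_radius[k]
      r_body <- (r_nuc / sp$pyknotic_shrink_factor) * config$cell_body_scale

      nucp <- disk_patch(cx, cy, r_nuc, nr, nc)
      bodyp <- disk_patch(cx, cy, r_body, nr, nc)
      if (is.null(nucp) || is.null(bodyp))
        stop("cell center outside the field: (", cx, ", ", cy, ")")

      dye_gain <- if (sp$name == "pyknotic") config$pyknotic_dye_gain else 1
      ch_nuc[nucp$ii, nucp$jj] <- ch_nuc[nucp$ii, nucp$jj] +
        nucp$w * config$nuc_dye_mean * dye_gain
      ch_cyt[bodyp$ii, bodyp$jj] <- ch_cyt[bodyp$ii, bodyp$jj] +
        bodyp$w * config$cyto_dye_mean

      # reporter: split total between nucleus and cytoplasmic annulus
      total <- sp$nuclear_reporter_mean * pi * r_nuc^2 *
        rlnorm(1, -0.5 * log(1 + config$reporter_cv^2),
               sqrt(log(1 + config$reporter_cv^2))) * intensity_scale
      f_cyto <- sp$cytoplasmic_reporter_fraction

      if (sp$n_puncta > 0) {
        pw <- puncta_weights(nucp, cx, cy, r_nuc, sp$n_puncta,
                             sp$punctum_sigma)
        # 85% of the nuclear pool in puncta, the rest diffuse
        nw <- 0.85 * pw / sum(pw) + 0.15 * nucp$w / sum(nucp$w)
        if (want_hook)
          ch_hook[nucp$ii, nucp$jj] <- ch_hook[nucp$ii, nucp$jj] +
            pw / max(pw) * config$hook_punctum_intensity
      } else {
        nw <- nucp$w / sum(nucp$w)
        if (want_hook && sp$name != "pyknotic") {
          # the hook stays punctate even when the reporter is diffuse
          pw <- puncta_weights(nucp, cx, cy, r_nuc, 8L, 2.0)
          ch_hook[nucp$ii, nucp$jj] <- ch_hook[nucp$ii, nucp$jj] +
            pw / max(pw) * config$hook_punctum_intensity
        }
      }
      ch_rep[nucp$ii, nucp$jj] <- ch_rep[nucp$ii, nucp$jj] +
        (1 - f_cyto) * total * nw

      # cytoplasmic pool: uniform over the annulus (body minus nucleus)
      if (f_cyto > 0) {
        ann <- bodyp$w
        ri <- match(nucp$ii, bodyp$ii); rj <- match(nucp$jj, bodyp$jj)
        ann[ri, rj] <- pmax(ann[ri, rj] - nucp$w, 0)
        s <- sum(ann)
        if (s > 0)
          ch_rep[bodyp$ii, bodyp$jj] <- ch_rep[bodyp$ii, bodyp$jj] +
            f_cyto * total * ann / s
      }
    }

    img <- list(nuclear_dye = ch_nuc, cyto_dye = ch_cyt, reporter = ch_rep)
    if (want_hook) img$hook <- ch_hook
    img <- img[channels]

    # background + mean-dependent camera noise, 16-bit quantization
    # (fused compiled pass; noise drawn from the session RNG stream)
    for (ch in channels) {
      img[[ch]] <- .camera_noise_cpp(img[[ch]], config$background,
                                     config$noise_gain,
                                     config$read_noise_sd,
                                     isTRUE(config$noise_enabled))
    }
    img
  }) -> img

  structure(list(channels = img, pixel_size_um = config$pixel_size_um,
                 well_id = well_id, field_index = as.integer(field_index),
                 rng_seed = as.integer(seed)),
            class = "field_image")
}

#' Per-field seed from the run seed (counter-based)
#'
#' Every field's RNG stream is derived from the run seed and the field's
#' coordinates, so any single field can be re-rendered in isolation:
#' `seed_f = (seed * 2654435 + plate_index * 1000003 + well_index * 1009 +
#' field_index) mod (2^31 - 1)`, where `well_index` is the row-major well
#' position (1..384).
#'
#' @param seed Run seed.
#' @param plate_index 1-based plate number.
#' @param well_id Well identifier, e.g. `"B07"`.
#' @param field_index 0-based field number.
#' @return Integer seed.
#' @export
field_seed <- function(seed, plate_index, well_id, field_index) {
  row <- match(substr(well_id, 1, 1), LETTERS[1:16])
  col <- as.integer(substr(well_id, 2, 3))
  widx <- (row - 1L) * 24L + col
  as.integer((as.numeric(seed) %% 65536 * 2654435 +
                plate_index * 1000003 + widx * 1009 + field_index) %%
               2147483647)
}

#' Simulate a full plate (or several) from a layout
#'
#' For each well of the layout, derives the phenotype mixture from the
#' compound's ground-truth class, the release-cue (biotin) condition and the
#' effect size (see [phenotype_mixture()]); nonspecific-loss compounds
#' additionally scale all reporter totals by `1 - effect` in both
#' conditions. Renders `fields_per_well` fields per well with per-field
#' seeds from [field_seed()].
#'
#' @param layout A `plate_layout` data frame (see [build_layout()]).
#' @param fields_per_well Fields per well (>= 1).
#' @param config Full configuration list ([default_config()]).
#' @param seed Run seed.
#' @param out_dir If non-`NULL`, fields are written as one 16-bit grayscale
#'   TIFF per channel (named `{plate}_{well}_f{field}_{channel}.tif`) and
#'   dropped from memory; otherwise all `field_image` objects are returned
#'   (only sensible for small layouts).
#' @return List with `cells` (per-cell ground truth: `plate_id`, `well_id`,
#'   `field_index`, `x`, `y`, `phenotype`, `nucleus_radius`),
#'   `well_classes` (per-well truth: `plate_id`, `well_id`, `class`,
#'   `effect`, `biotin`), and `fields` (list of `field_image`, or `NULL`
#'   when `out_dir` is used).
#' @export
simulate_plate <- function(layout, fields_per_well = NULL,
                           config = default_config(), seed = 1,
                           out_dir = NULL) {
  validate_config(config)
  validate_layout(layout)
  g <- config$generator
  if (is.null(fields_per_well)) fields_per_well <- g$fields_per_well
  stopifnot(fields_per_well >= 1)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  plates <- unique(layout$plate_id)
  fields <- if (is.null(out_dir)) list() else NULL
  cells_gt <- vector("list", nrow(layout) * fields_per_well)
  gi <- 0L
  for (w in seq_len(nrow(layout))) {
    row <- layout[w, ]
    p_idx <- match(row$plate_id, plates)
    mix <- phenotype_mixture(row$class, row$biotin, row$effect)
    iscale <- if (row$class == "nonspecific_loss") 1 - row$effect else 1
    for (f in seq_len(fields_per_well) - 1L) {
      fs <- field_seed(seed, p_idx, row$well_id, f)
      cells <- sample_cell_population(mix, g$cells_per_field, g$field_shape,
                                      seed = fs,
                                      tolerance_px = g$placement_tolerance_px,
                                      max_attempts = g$max_place_attempts)
      fld <- render_field(cells, g, seed = fs + 1L,
                          intensity_scale = iscale,
                          well_id = row$well_id, field_index = f)
      gi <- gi + 1L
      cells_gt[[gi]] <- if (nrow(cells) > 0)
        cbind(plate_id = row$plate_id, well_id = row$well_id,
              field_index = f, cells, stringsAsFactors = FALSE)
      if (is.null(out_dir)) {
        fields[[paste0(row$plate_id, "_", row$well_id, "_f", f)]] <- fld
      } else {
        write_field_tiffs(fld, out_dir, row$plate_id)
      }
    }
  }
  cells_gt <- do.call(rbind, cells_gt[seq_len(gi)])
  well_classes <- data.frame(plate_id = layout$plate_id,
                             well_id = layout$well_id,
                             class = layout$class, effect = layout$effect,
                             biotin = layout$biotin,
                             stringsAsFactors = FALSE)
  list(cells = cells_gt, well_classes = well_classes, fields = fields)
}
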