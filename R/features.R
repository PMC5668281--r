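#' Granularity of a signal within a mask
#'
#' Scores how punctate (versus diffuse) a fluorescence signal is: the white
#' top-hat of the raster (structuring element: disk of the given radius) is
#' summed over the mask and divided by the raw signal sum over the mask,
#' clamped to `[0,1]`. A constant region scores 0; an isolated impulse
#' scores 1. The score is invariant to multiplying the raster by any
#' positive constant, and adding a constant offset strictly decreases it
#' (the top-hat is offset-invariant while the denominator grows) — so
#' backgrounds should be subtracted first if absolute comparability matters.
#'
#' @param reporter Numeric matrix.
#' @param nucleus_mask Logical matrix (or 0/1) of the same dimensions;
#'   must contain at least one pixel.
#' @param radius Structuring-element radius, pixels (>= 1).
#' @param tophat Optional precomputed white top-hat of `reporter` (used by
#'   [measure_cells()] to share one morphological pass across cells).
#' @return Granularity fraction in `[0,1]`.
#' @export
#' @examples
#' m <- matrix(0, 32, 32); m[16, 16] <- 100
#' granularity_score(m, matrix(TRUE, 32, 32), radius = 3)  # 1
granularity_score <- function(reporter, nucleus_mask, radius = 5,
                              tophat = NULL) {
  stopifnot(radius >= 1)
  nucleus_mask <- nucleus_mask > 0
  if (!any(nucleus_mask)) stop("undefined granularity: empty mask")
  if (is.null(tophat)) tophat <- white_tophat(reporter, radius)
  denom <- sum(reporter[nucleus_mask])
  if (denom <= 0) return(0)
  min(max(sum(tophat[nucleus_mask]) / denom, 0), 1)
}

# White top-hat: raster minus its grayscale opening with a disk element.
# EBImage grayscale morphology clamps to [0,1], so scale through that range.
white_tophat <- function(img, radius) {
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  mx <- max(img)
  if (mx <= 0) return(img * 0)
  op <- EBImage::imageData(EBImage::opening(EBImage::Image(img / mx), brush))
  pmax(img - op * mx, 0)
}

#' Measure per-cell features on one field
#'
#' One record per nucleus id. Intensity means are arithmetic means over the
#' mask pixels of the reporter channel after subtraction of the field
#' background (median of pixels in neither a nucleus nor a cytoplasm,
#' floored at 0). The cytoplasm/nucleus ratio is flagged undefined
#' (`NA`) when the nuclear mean is below `ratio_eps`. Granularity is the
#' top-hat fraction of the background-subtracted reporter over the nucleus.
#' The `pyknotic` flag is left `NA`; it needs plate-level control context
#' (see [pyknosis_flag()]).
#'
#' @param field A `field_image` with at least channels `nuclear_dye` and
#'   `reporter`.
#' @param nuclei,cytoplasm Paired label maps from [segment_nuclei()] /
#'   [segment_cytoplasm()].
#' @param config Feature configuration (`default_config()$features`).
#' @return Data frame of cell records: `well_id`, `field_index`, `cell_id`,
#'   `nuc_area`, `nuc_dye_mean`, `nuc_reporter_mean`, `cyto_area`,
#'   `cyto_reporter_mean`, `cyto_nuc_ratio`, `granularity`, `pyknotic`.
#' @export
measure_cells <- function(field, nuclei, cytoplasm,
                          config = default_config()$features) {
  if (is.null(field$channels$reporter))
    stop("channel error: field has no 'reporter' channel")
  if (is.null(field$channels$nuclear_dye))
    stop("channel error: field has no 'nuclear_dye' channel")
  if (!all(dim(nuclei) == dim(field$channels$reporter)) ||
      !all(dim(cytoplasm) == dim(field$channels$reporter)))
    stop("shape error: label maps must match the field dimensions")
  K <- n_objects(nuclei)
  empty <- data.frame(well_id = character(0), field_index = integer(0),
                      cell_id = integer(0), nuc_area = numeric(0),
                      nuc_dye_mean = numeric(0), nuc_reporter_mean = numeric(0),
                      cyto_area = numeric(0), cyto_reporter_mean = numeric(0),
                      cyto_nuc_ratio = numeric(0), granularity = numeric(0),
                      pyknotic = logical(0), stringsAsFactors = FALSE)
  if (K == 0) return(empty)

  rep_ch <- field$channels$reporter
  dye_ch <- field$channels$nuclear_dye
  nuc <- unclass(nuclei); attributes(nuc) <- list(dim = dim(nuc))
  cyt <- unclass(cytoplasm); attributes(cyt) <- list(dim = dim(cyt))

  bg_px <- nuc == 0L & cyt == 0L
  bg <- if (any(bg_px)) median(rep_ch[bg_px]) else 0
  rep_sub <- pmax(rep_ch - bg, 0)
  th <- white_tophat(rep_sub, config$granularity_radius)

  # single compiled pass for all per-label pixel sums
  sums <- .label_sums_cpp(nuc, cyt, dye_ch, rep_sub, th, K)
  nuc_area <- sums$nuc[, 1]; nuc_dye <- sums$nuc[, 2]
  nuc_rep <- sums$nuc[, 3]; nuc_th <- sums$nuc[, 4]
  cyto_area <- sums$cyto[, 1]; cyto_rep <- sums$cyto[, 2]

  nuc_mean <- ifelse(nuc_area > 0, nuc_rep / nuc_area, 0)
  cyto_mean <- ifelse(cyto_area > 0, cyto_rep / cyto_area, 0)
  ratio <- ifelse(nuc_mean > config$ratio_eps, cyto_mean / nuc_mean,
                  NA_real_)
  gran <- ifelse(nuc_rep > 0, pmin(pmax(nuc_th / nuc_rep, 0), 1), 0)

  data.frame(well_id = field$well_id, field_index = field$field_index,
             cell_id = seq_len(K), nuc_area = nuc_area,
             nuc_dye_mean = ifelse(nuc_area > 0, nuc_dye / nuc_area, 0),
             nuc_reporter_mean = nuc_mean, cyto_area = cyto_area,
             cyto_reporter_mean = cyto_mean, cyto_nuc_ratio = ratio,
             granularity = gran, pyknotic = NA, stringsAsFactors = FALSE)
}

#' Plate-level control context for pyknosis calls
#'
#' Median nuclear area and nuclear-dye mean over cells from the plate's
#' negative-control wells (at least 4 per condition by the layout contract).
#'
#' @param control_records Cell records (from [measure_cells()]) of the
#'   plate's negative-control wells.
#' @return List with `median_area` and `median_dye`.
#' @export
control_context <- function(control_records) {
  if (is.null(control_records) || nrow(control_records) == 0)
    stop("context error: no negative-control cell records")
  list(median_area = median(control_records$nuc_area),
       median_dye = median(control_records$nuc_dye_mean))
}

#' Flag pyknotic (condensed, brightly staining) nuclei
#'
#' A nucleus is called pyknotic iff its area is below `alpha` times the
#' control median area AND its nuclear-dye mean exceeds `beta` times the
#' control median dye mean — the conjunction of the two condensation
#' features visible in a DNA stain.
#'
#' @param records Cell records from [measure_cells()].
#' @param context Control context from [control_context()].
#' @param alpha,beta Thresholds (defaults 0.5 and 1.3).
#' @return Logical vector, one flag per record.
#' @export
pyknosis_flag <- function(records, context, alpha = 0.5, beta = 1.3) {
  if (is.null(context$median_area) || is.null(context$median_dye))
    stop("context error: need median_area and median_dye")
  records$nuc_area < alpha * context$median_area &
    records$nuc_dye_mean > beta * context$median_dye
}

#' Summarize the cells of one well
#'
#' Unweighted means over all cells pooled across the well's fields;
#' `pyknotic_fraction` is the flagged fraction. Wells with fewer than
#' `min_cells` cells are flagged `low_count` (carried through the matrix
#' stages but excluded from normalization populations and hit calling). A
#' well with zero cells yields `n_cells = 0` and `NA` means.
#'
#' @param records Cell records of a single well (pyknotic flags filled).
#' @param layout_row One-row data frame with `well_id`, `plate_id`,
#'   `compound_id`, `concentration_uM`, `biotin`, `role`.
#' @param min_cells Low-count threshold (default 20).
#' @return One-row data frame (a `WellSummary`).
#' @export
summarize_well <- function(records, layout_row, min_cells = 20) {
  if (nrow(records) > 0 &&
      length(unique(records$well_id)) > 1)
    stop("records from multiple wells: ",
         paste(unique(records$well_id), collapse = ", "))
  n <- nrow(records)
  mean_or_na <- function(x) if (n > 0) mean(x, na.rm = TRUE) else NA_real_
  data.frame(
    plate_id = layout_row$plate_id, well_id = layout_row$well_id,
    compound_id = layout_row$compound_id,
    concentration_uM = layout_row$concentration_uM,
    biotin = layout_row$biotin, role = layout_row$role,
    n_cells = n,
    mean_nuc_reporter = mean_or_na(records$nuc_reporter_mean),
    mean_cyto_reporter = mean_or_na(records$cyto_reporter_mean),
    mean_ratio = mean_or_na(records$cyto_nuc_ratio),
    mean_granularity = mean_or_na(records$granularity),
    pyknotic_fraction = if (n > 0) sum(records$pyknotic, na.rm = TRUE) / n
                        else NA_real_,
    low_count = n < min_cells,
    stringsAsFactors = FALSE
  )
}
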