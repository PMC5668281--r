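#' Segmentation parameters
#'
#' @param smoothing_sigma Gaussian smoothing sigma, pixels.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold Intensity threshold when `threshold_method =
#'   "fixed"`.
#' @param min_nucleus_area,max_nucleus_area Object area bounds, px^2.
#' @param split_touching Split merged objects by distance-transform
#'   watershed?
#' @param cyto_max_radius Maximum distance (px) a cytoplasm pixel may lie
#'   from its nucleus.
#' @param annulus_fallback_px Width of the fallback annulus assigned to a
#'   nucleus whose cytoplasm threshold yields no pixels; 0 disables the
#'   fallback.
#' @param keep_border_objects Keep objects touching the field border?
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(smoothing_sigma = 1,
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NA_real_,
                                min_nucleus_area = 120,
                                max_nucleus_area = 1400,
                                split_touching = TRUE,
                                cyto_max_radius = 32,
                                annulus_fallback_px = 6,
                                keep_border_objects = TRUE) {
  threshold_method <- match.arg(threshold_method)
  if (!(min_nucleus_area > 0 && min_nucleus_area < max_nucleus_area))
    stop("require 0 < min_nucleus_area < max_nucleus_area")
  if (cyto_max_radius <= 0) stop("cyto_max_radius must be > 0")
  structure(list(smoothing_sigma = smoothing_sigma,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_nucleus_area = min_nucleus_area,
                 max_nucleus_area = max_nucleus_area,
                 split_touching = split_touching,
                 cyto_max_radius = cyto_max_radius,
                 annulus_fallback_px = annulus_fallback_px,
                 keep_border_objects = keep_border_objects),
            class = "segmentation_params")
}

as_seg_params <- function(x) {
  if (inherits(x, "segmentation_params")) return(x)
  do.call(segmentation_params, x)
}

# Gaussian smoothing (compiled separable kernel).
smooth_raster <- function(img, sigma) {
  if (sigma <= 0) return(img)
  .gauss_blur_cpp(img, sigma)
}

# Global threshold of a smoothed raster. Otsu runs on a 3x3-subsampled
# copy: the histogram is statistically identical and the call 9x cheaper.
threshold_raster <- function(img, params) {
  if (params$threshold_method == "fixed") {
    if (is.na(params$fixed_threshold))
      stop("fixed_threshold required for threshold_method = 'fixed'")
    return(img > params$fixed_threshold)
  }
  mx <- max(img)
  if (mx <= 0) return(matrix(FALSE, nrow(img), ncol(img)))
  sub <- img[seq(1, nrow(img), by = 3), seq(1, ncol(img), by = 3)]
  th <- EBImage::otsu(EBImage::Image(sub / mx), range = c(0, 1))
  img > th * mx
}

#' Identify nuclei from the nuclear-dye channel
#'
#' Standard high-content nucleus pipeline: Gaussian smoothing, global
#' threshold (Otsu by default), hole filling, distance-transform watershed
#' splitting of merged objects (optional; components whose area is
#' incompatible with a single convex nucleus are re-labelled on their
#' bounding boxes), and removal of objects outside the `[min, max]` area
#' window. Labels are
#' contiguous `1..K`, ordered by object centroid (row, then column); the
#' procedure is fully deterministic.
#'
#' @param nuclear_dye Numeric matrix (finite, nonnegative).
#' @param params [segmentation_params()] (or a plain list of the same
#'   fields, e.g. `default_config()$segmentation`).
#' @return A `label_map`: integer matrix (0 = background) with attributes
#'   `kind = "nucleus"`.
#' @export
segment_nuclei <- function(nuclear_dye, params = segmentation_params()) {
  params <- as_seg_params(params)
  if (any(!is.finite(nuclear_dye)) || any(nuclear_dye < 0))
    stop("nuclear_dye raster must be finite and nonnegative")
  sm <- smooth_raster(nuclear_dye, params$smoothing_sigma)
  bin <- threshold_raster(sm, params)
  if (!any(bin)) return(label_map(matrix(0L, nrow(bin), ncol(bin)), "nucleus"))
  filled <- EBImage::fillHull(EBImage::Image(bin))
  lab <- EBImage::imageData(EBImage::bwlabel(filled))
  storage.mode(lab) <- "integer"
  K <- max(lab)

  if (params$split_touching && K > 0) {
    # Split touching nuclei by distance-transform watershed. Only
    # components whose area is incompatible with a single convex nucleus
    # (area > 1.2 x pi x maxdist^2, or over the area cap) are re-labelled,
    # each on its own bounding box — same result as a full-field watershed
    # at a fraction of the cost, since isolated disks never split.
    bg_seed <- matrix(0L, nrow(lab), ncol(lab))
    bg_seed[lab == 0L] <- 1L
    dm <- .nearest_seed_cpp(bg_seed)$dist   # distance into the mask
    st <- .label_stats_cpp(lab, dm, K)
    suspicious <- which(st[, 1] > 1.2 * pi * st[, 2]^2 |
                          st[, 1] > params$max_nucleus_area)
    next_id <- K
    for (id in suspicious) {
      ri <- st[id, 3]:st[id, 4]; ci <- st[id, 5]:st[id, 6]
      sub <- lab[ri, ci, drop = FALSE] == id
      dmc <- dm[ri, ci, drop = FALSE]
      dmc[!sub] <- 0
      ws <- EBImage::imageData(EBImage::watershed(EBImage::Image(dmc),
                                                  tolerance = 1.5))
      nsub <- max(ws)
      if (nsub > 1) {
        piece <- lab[ri, ci, drop = FALSE]
        w <- ws[sub]
        piece[sub] <- ifelse(w == 0L, 0L,
                             ifelse(w == 1L, id, next_id + w - 1L))
        lab[ri, ci] <- piece
        next_id <- as.integer(next_id + nsub - 1L)
      }
    }
    K <- max(lab)
  }

  if (!params$keep_border_objects) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    lab[lab %in% setdiff(border, 0L)] <- 0L
    K <- max(lab)
  }

  if (K == 0) return(label_map(lab, "nucleus"))

  # area filter + contiguous relabel in raster order of object centroids
  st <- .label_stats_cpp(lab, matrix(0), K)
  keep <- st[, 1] >= params$min_nucleus_area &
    st[, 1] <= params$max_nucleus_area
  cy <- st[, 7] / st[, 1]
  cx <- st[, 8] / st[, 1]
  ord <- order(cy, cx)
  ord <- ord[keep[ord]]
  map <- integer(K)
  map[ord] <- seq_along(ord)
  label_map(.remap_labels_cpp(lab, map), "nucleus")
}

#' Identify cytoplasmic regions from the cytoplasmic-dye channel
#'
#' Cell bodies are grown from the nucleus seeds over the thresholded
#' cytoplasmic-dye mask by distance-based assignment (each mask pixel joins
#' the nearest nucleus — the standard distance-constrained secondary-object
#' method), clipped to `cyto_max_radius` around the nuclei; the cytoplasm
#' of cell `k` is its body minus every nucleus, so cytoplasm and nucleus
#' maps are pixel-disjoint and share ids. The cytoplasmic dye is
#' thresholded without smoothing (the body mask is contrast-limited, not
#' noise-limited). A nucleus whose thresholded mask contributes no pixels
#' still receives a fallback annulus of width `annulus_fallback_px` (set 0
#' to disable), so intensity features are always defined.
#'
#' @param cyto_dye Numeric matrix, same dimensions as the nucleus map.
#' @param nuclei Nucleus `label_map` from [segment_nuclei()].
#' @param params [segmentation_params()].
#' @return A `label_map` with `kind = "cytoplasm"`; ids match the nucleus
#'   map (regions may be empty).
#' @export
segment_cytoplasm <- function(cyto_dye, nuclei,
                              params = segmentation_params()) {
  params <- as_seg_params(params)
  if (!all(dim(cyto_dye) == dim(nuclei)))
    stop("shape error: cyto_dye ", paste(dim(cyto_dye), collapse = "x"),
         " vs nuclei ", paste(dim(nuclei), collapse = "x"))
  K <- max(nuclei)
  if (K == 0) return(label_map(matrix(0L, nrow(nuclei), ncol(nuclei)),
                               "cytoplasm"))
  bin <- threshold_raster(cyto_dye, params)

  nuc <- unclass(nuclei)
  attributes(nuc) <- list(dim = dim(nuc))
  ft <- .nearest_seed_cpp(nuc)       # distance + id of nearest nucleus
  body <- ft$label
  keep <- (bin | ft$dist <= params$annulus_fallback_px) &
    ft$dist <= params$cyto_max_radius & ft$dist > 0
  body[!keep] <- 0L
  label_map(body, "cytoplasm")
}

label_map <- function(labels, kind) {
  storage.mode(labels) <- "integer"
  structure(labels, kind = kind, class = c("label_map", "matrix", "array"))
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map> kind =", attr(x, "kind"), "-",
      nrow(x), "x", ncol(x), "px,", max(x), "object(s)\n")
  invisible(x)
}

#' Number of objects in a label map
#' @param labels A `label_map`.
#' @return Integer count.
#' @export
n_objects <- function(labels) max(0L, max(unclass(labels)))
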