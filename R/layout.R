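#' All well identifiers of a 384-well plate
#'
#' Row-major order: A01..A24, B01..B24, ..., P01..P24.
#'
#' @return Character vector of length 384.
#' @export
well_ids_384 <- function() {
  as.vector(t(outer(LETTERS[1:16], sprintf("%02d", 1:24), paste0)))
}

#' Build seeded 384-well screen layouts
#'
#' Lays out a compound library for a two-condition differential screen:
#' every compound x dose appears exactly once with the release cue
#' (`biotin = TRUE`) and once without, and every plate carries
#' `controls_per_condition` negative-control wells per cue condition (plus
#' optional positive controls). Compounds are packed onto as many 384-well
#' plates as needed; well positions are shuffled deterministically from
#' `seed`, so a given call always yields the same plate maps.
#'
#' @param n_compounds Number of library compounds.
#' @param controls_per_condition Negative-control wells per biotin condition
#'   on each plate (>= 4 per the plate contract).
#' @param doses Numeric vector of concentrations (micromolar).
#' @param seed Integer seed controlling well placement.
#' @param classes Optional character vector (length `n_compounds`) of ground
#'   truth compound classes: `"inactive"`, `"specific_releaser"`,
#'   `"nonspecific_loss"`, `"toxic"`. Default all inactive.
#' @param effects Optional numeric vector of per-compound effect sizes in
#'   `[0,1]`; defaults per class (releaser/toxic: the generator defaults,
#'   inactive: 0).
#' @param pos_controls_per_condition Positive-control wells per condition per
#'   plate (a known releaser at the default effect size). Default 0.
#' @param plate_prefix Prefix for plate identifiers.
#' @param config Configuration list, for default effect sizes.
#' @return A `plate_layout` data frame with columns `plate_id`, `well_id`,
#'   `compound_id`, `concentration_uM`, `biotin` (logical), `role`, `class`,
#'   `effect`.
#' @export
#' @examples
#' lay <- build_layout(8, controls_per_condition = 4, doses = 10, seed = 1)
#' table(lay$role)
build_layout <- function(n_compounds, controls_per_condition = 4, doses = 10,
                         seed = 1, classes = NULL, effects = NULL,
                         pos_controls_per_condition = 0,
                         plate_prefix = "PL", config = default_config()) {
  stopifnot(n_compounds >= 1, controls_per_condition >= 4, length(doses) >= 1)
  g <- config$generator
  if (is.null(classes)) classes <- rep("inactive", n_compounds)
  stopifnot(length(classes) == n_compounds)
  ok_classes <- c("inactive", "specific_releaser", "nonspecific_loss", "toxic")
  if (!all(classes %in% ok_classes))
    stop("classes must be one of: ", paste(ok_classes, collapse = ", "))
  default_eff <- c(inactive = 0,
                   specific_releaser = g$releaser_effect,
                   nonspecific_loss = g$loss_effect,
                   toxic = g$toxic_effect)
  if (is.null(effects)) effects <- unname(default_eff[classes])
  stopifnot(length(effects) == n_compounds, all(effects >= 0 & effects <= 1))

  n_ctrl <- 2L * (controls_per_condition + pos_controls_per_condition)
  capacity <- 384L - n_ctrl          # sample wells per plate
  if (capacity < 2L)
    stop("sizing error: controls alone (", n_ctrl,
         " wells) leave fewer than 2 sample wells of 384")
  n_pairs_per_plate <- capacity %/% 2L   # a compound x dose needs 2 wells
  n_pairs <- n_compounds * length(doses)
  n_plates <- ceiling(n_pairs / n_pairs_per_plate)
  if (n_pairs * 2L + n_ctrl > n_plates * 384L)
    stop("sizing error: need ", n_pairs * 2L + n_ctrl,
         " wells but only ", n_plates * 384L, " available")

  # one row per compound x dose pair
  pairs <- data.frame(
    compound_id = rep(sprintf("CMP%04d", seq_len(n_compounds)),
                      each = length(doses)),
    concentration_uM = rep(doses, times = n_compounds),
    class = rep(classes, each = length(doses)),
    effect = rep(effects, each = length(doses)),
    stringsAsFactors = FALSE
  )
  pairs$plate <- rep(seq_len(n_plates),
                     each = n_pairs_per_plate)[seq_len(nrow(pairs))]

  out <- vector("list", n_plates)
  for (p in seq_len(n_plates)) {
    pp <- pairs[pairs$plate == p, , drop = FALSE]
    ctrl <- data.frame(
      compound_id = c(rep("DMSO", 2L * controls_per_condition),
                      if (pos_controls_per_condition > 0)
                        rep("POSCTRL", 2L * pos_controls_per_condition)),
      concentration_uM = 0,
      class = c(rep("inactive", 2L * controls_per_condition),
                if (pos_controls_per_condition > 0)
                  rep("specific_releaser", 2L * pos_controls_per_condition)),
      effect = c(rep(0, 2L * controls_per_condition),
                 if (pos_controls_per_condition > 0)
                   rep(g$releaser_effect, 2L * pos_controls_per_condition)),
      stringsAsFactors = FALSE
    )
    ctrl$concentration_uM[ctrl$compound_id == "POSCTRL"] <- 10
    n_c <- nrow(ctrl)
    plate <- data.frame(
      compound_id = c(rep(pp$compound_id, each = 2L), ctrl$compound_id),
      concentration_uM = c(rep(pp$concentration_uM, each = 2L),
                           ctrl$concentration_uM),
      biotin = c(rep(c(TRUE, FALSE), times = nrow(pp)),
                 rep(c(TRUE, FALSE), times = n_c / 2L)),
      role = c(rep("sample", 2L * nrow(pp)),
               rep("negative_control", 2L * controls_per_condition),
               if (pos_controls_per_condition > 0)
                 rep("positive_control", 2L * pos_controls_per_condition)),
      class = c(rep(pp$class, each = 2L), ctrl$class),
      effect = c(rep(pp$effect, each = 2L), ctrl$effect),
      stringsAsFactors = FALSE
    )
    ids <- withr::with_seed(seed + p, sample(well_ids_384(), nrow(plate)))
    plate <- cbind(plate_id = sprintf("%s%02d", plate_prefix, p),
                   well_id = ids, plate, stringsAsFactors = FALSE)
    plate <- plate[order(plate$well_id), ]
    out[[p]] <- plate
  }
  layout <- do.call(rbind, out)
  rownames(layout) <- NULL
  layout <- layout[, c("plate_id", "well_id", "compound_id",
                       "concentration_uM", "biotin", "role", "class",
                       "effect")]
  class(layout) <- c("plate_layout", "data.frame")
  validate_layout(layout)
  layout
}

validate_layout <- function(layout) {
  need <- c("plate_id", "well_id", "compound_id", "concentration_uM",
            "biotin", "role")
  miss <- setdiff(need, names(layout))
  if (length(miss) > 0)
    stop("layout missing column(s): ", paste(miss, collapse = ", "))
  for (p in unique(layout$plate_id)) {
    pl <- layout[layout$plate_id == p, ]
    if (anyDuplicated(pl$well_id))
      stop("duplicate well_id on plate ", p)
    if (!all(pl$well_id %in% well_ids_384()))
      stop("well_id outside A01..P24 on plate ", p)
    for (b in c(TRUE, FALSE)) {
      n_neg <- sum(pl$role == "negative_control" & pl$biotin == b)
      if (n_neg < 4)
        stop("plate ", p, " has ", n_neg,
             " negative controls with biotin=", b, " (need >= 4)")
    }
  }
  invisible(layout)
}

#' Write / read a plate map CSV
#'
#' The interchange format has columns
#' `plate_id,well_id,compound_id,concentration_uM,biotin,role` with `biotin`
#' coded 0/1. Ground-truth columns (`class`, `effect`), when present, are
#' written to / read from the same file after the standard six.
#'
#' @param layout A `plate_layout` data frame.
#' @param path CSV path.
#' @return `write_plate_map()`: `path`, invisibly. `read_plate_map()`: a
#'   `plate_layout` data frame.
#' @export
write_plate_map <- function(layout, path) {
  out <- as.data.frame(layout)
  out$biotin <- as.integer(out$biotin)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate_map
#' @export
read_plate_map <- function(path) {
  layout <- read.csv(path, stringsAsFactors = FALSE)
  layout$biotin <- as.logical(layout$biotin)
  if (is.null(layout$class)) layout$class <- "inactive"
  if (is.null(layout$effect)) layout$effect <- 0
  class(layout) <- c("plate_layout", "data.frame")
  validate_layout(layout)
  layout
}
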