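# Shared fixtures and independent oracles for the suite.

# Small, fast generator configuration (noise on unless stated).
small_config <- function(field = 256L, cells = 20L, fields_per_well = 2L,
                         noise = TRUE) {
  cfg <- default_config()
  cfg$generator$field_shape <- c(field, field)
  cfg$generator$cells_per_field <- as.integer(cells)
  cfg$generator$fields_per_well <- as.integer(fields_per_well)
  cfg$generator$noise_enabled <- noise
  cfg
}

noiseless_gen <- function(field = 256L, background = 0, cv = 0) {
  g <- default_config()$generator
  g$field_shape <- c(field, field)
  g$noise_enabled <- FALSE
  g$background <- background
  g$reporter_cv <- cv
  g
}

# Hard-disk ground-truth mask for a planted nucleus.
disk_mask <- function(field, cx, cy, r) {
  sqrt(outer((seq_len(field) - cy)^2, (seq_len(field) - cx)^2, "+")) <= r
}

# Independent brute-force average-linkage clustering on a distance matrix:
# keeps explicit cluster member lists and recomputes every pairwise
# cluster distance as the plain mean of member-to-member distances.
brute_average_linkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_len(length(clusters) - 1)) {
      for (b in (a + 1):length(clusters)) {
        dd <- mean(d[clusters[[a]], clusters[[b]]])
        if (dd < best_d) { best_d <- dd; best <- c(a, b) }
      }
    }
    heights[step] <- best_d
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Independent coding of the biotin-differential classification rule, written
# as a plain truth table over the five z-scores.
oracle_classify <- function(zc_p, zc_m, zn_p, zn_m, zp, t_hit = 2,
                            t_null = 1, t_tox = 2) {
  if (zp >= t_tox) "toxic"
  else if (zn_p <= -t_hit & zn_m <= -t_hit) "nonspecific_loss"
  else if (zc_p >= t_hit & abs(zc_m) < t_null) "specific_releaser"
  else "inactive"
}

# Count strict local maxima (8-neighbourhood) above a floor, within a mask.
count_local_maxima <- function(img, mask, floor = 1) {
  nr <- nrow(img); nc <- ncol(img)
  cnt <- 0L
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    if (!mask[i, j]) next
    v <- img[i, j]
    if (v < floor) next
    nb <- img[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (v > max(nb[-5])) cnt <- cnt + 1L
  }
  cnt
}

# Layout helper: n compounds with planted classes, one dose.
planted_layout <- function(n_rel, n_loss, n_tox, n_inactive, seed = 5,
                           doses = 10) {
  classes <- c(rep("specific_releaser", n_rel),
               rep("nonspecific_loss", n_loss),
               rep("toxic", n_tox), rep("inactive", n_inactive))
  build_layout(length(classes), controls_per_condition = 4, doses = doses,
               seed = seed, classes = classes)
}
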