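#' Build a screen matrix from well summaries
#'
#' A `screen_matrix` holds a wells x features value matrix plus per-well
#' metadata and a normalization stage tag (`"raw"`, `"plate_ratio"` or
#' `"zscore"`).
#'
#' @param well_summaries Data frame of well summaries (rows from
#'   [summarize_well()], pooled over plates).
#' @param features Character vector of feature columns to carry.
#' @return A `screen_matrix` object.
#' @export
screen_matrix <- function(well_summaries,
                          features = default_config()$analysis$features) {
  miss <- setdiff(features, names(well_summaries))
  if (length(miss) > 0)
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  values <- as.matrix(well_summaries[, features, drop = FALSE])
  rownames(values) <- paste(well_summaries$plate_id, well_summaries$well_id,
                            sep = ":")
  meta <- well_summaries[, c("plate_id", "well_id", "compound_id",
                             "concentration_uM", "biotin", "role")]
  meta$low_count <- if (!is.null(well_summaries$low_count))
    well_summaries$low_count else FALSE
  structure(list(values = values, meta = meta, stage = "raw"),
            class = "screen_matrix")
}

#' @export
print.screen_matrix <- function(x, ...) {
  cat("<screen_matrix> stage =", x$stage, "-", nrow(x$values), "wells x",
      ncol(x$values), "features\n")
  invisible(x)
}

included_wells <- function(sm) !sm$meta$low_count & !is.na(sm$values[, 1])

#' Intra-plate ratio normalization
#'
#' Each feature value is divided by the mean of that feature over the
#' plate's included wells of the same assay (biotin) condition, so each
#' plate x condition group has mean exactly 1 afterwards and global
#' intensity offsets between plates cancel. Included wells are all
#' non-low-count wells; low-count wells are still transformed (using the
#' included-well mean) but never contribute to it.
#'
#' @param sm A `screen_matrix` at stage `"raw"`.
#' @return A `screen_matrix` at stage `"plate_ratio"`.
#' @export
normalize_intraplate <- function(sm) {
  stopifnot(inherits(sm, "screen_matrix"))
  if (sm$stage != "raw")
    stop("normalize_intraplate expects a stage='raw' matrix, got ", sm$stage)
  inc <- included_wells(sm)
  grp <- paste(sm$meta$plate_id, sm$meta$biotin)
  for (g in unique(grp)) {
    rows <- grp == g
    base <- rows & inc
    if (sum(base) < 2)
      stop("degenerate plate group ", g, ": fewer than 2 included wells")
    mu <- colMeans(sm$values[base, , drop = FALSE])
    if (any(mu == 0))
      stop("degenerate plate ", g, ": zero mean for feature(s) ",
           paste(colnames(sm$values)[mu == 0], collapse = ", "))
    sm$values[rows, ] <- sweep(sm$values[rows, , drop = FALSE], 2, mu, "/")
  }
  sm$stage <- "plate_ratio"
  sm
}

#' Standardize a vector (population convention)
#'
#' The inter-plate normalization formula: `Z = (Xi - mean(Xall)) /
#' std(Xall)` with the population (divide-by-N) standard deviation.
#'
#' @param x Values to transform.
#' @param population Values defining `Xall` (defaults to `x`).
#' @return Standardized values.
#' @export
#' @examples
#' zscore_values(c(1, 2, 3))  # -1.2247 0 1.2247
zscore_values <- function(x, population = x) {
  if (length(population) < 2) stop("population size must be >= 2")
  mu <- mean(population)
  sdev <- sqrt(mean((population - mu)^2))
  if (sdev == 0) stop("degenerate feature: zero standard deviation")
  (x - mu) / sdev
}

#' Inter-plate Z-scoring
#'
#' Applies [zscore_values()] to every feature column, separately within
#' each assay (biotin) condition. The normalization population is the
#' included sample wells (`population = "samples_only"`, the default) or
#' all included wells; every well (controls and low-count wells included)
#' is transformed with the population's mean and standard deviation.
#'
#' @param sm A `screen_matrix` at stage `"plate_ratio"` (a `"zscore"`
#'   matrix is passed through idempotently when re-scored with the same
#'   population).
#' @param population `"samples_only"` or `"all_wells"`.
#' @return A `screen_matrix` at stage `"zscore"`.
#' @export
zscore <- function(sm, population = c("samples_only", "all_wells")) {
  stopifnot(inherits(sm, "screen_matrix"))
  population <- match.arg(population)
  if (!sm$stage %in% c("plate_ratio", "zscore"))
    stop("zscore expects a stage='plate_ratio' matrix, got ", sm$stage)
  inc <- included_wells(sm)
  for (b in unique(sm$meta$biotin)) {
    rows <- sm$meta$biotin == b
    pop <- rows & inc
    if (population == "samples_only") pop <- pop & sm$meta$role == "sample"
    if (sum(pop) < 2)
      stop("normalization population for biotin=", b, " has < 2 wells")
    for (j in seq_len(ncol(sm$values))) {
      sm$values[rows, j] <- zscore_values(sm$values[rows, j],
                                          sm$values[pop, j])
    }
  }
  sm$stage <- "zscore"
  sm
}

#' Classify compounds by the two-condition differential logic
#'
#' For every compound x concentration with wells in both assay conditions,
#' extracts the Z-scores of the cytoplasmic reporter, nuclear reporter and
#' pyknotic fraction and applies, in order of precedence (first match
#' wins):
#'
#' 1. `toxic` — pyknosis Z (with cue) >= `t_tox`; a dying cell can show
#'    cytoplasmic signal, so toxicity outranks translocation;
#' 2. `nonspecific_loss` — nuclear reporter Z <= `-t_hit` in *both*
#'    conditions (signal lost whether or not the reporter was released:
#'    destruction or quenching, not translocation);
#' 3. `specific_releaser` — cytoplasmic reporter Z >= `t_hit` with the cue
#'    and |Z| < `t_null` without it;
#' 4. `inactive` otherwise.
#'
#' The ranking score, defined only for specific releasers, is
#' `z_cyto_plus - max(z_cyto_minus, 0)`.
#'
#' @param sm A `screen_matrix` at stage `"zscore"` containing features
#'   `mean_cyto_reporter`, `mean_nuc_reporter`, `pyknotic_fraction`.
#' @param thresholds List with `t_hit`, `t_null`, `t_tox`.
#' @return A `hit_call` data frame: one row per compound x concentration
#'   with all five Z-scores, `class`, `rank_score`.
#' @export
call_hits <- function(sm, thresholds = list(t_hit = 2.0, t_null = 1.0,
                                            t_tox = 2.0)) {
  stopifnot(inherits(sm, "screen_matrix"))
  if (sm$stage != "zscore")
    stop("call_hits expects a stage='zscore' matrix, got ", sm$stage)
  need <- c("mean_cyto_reporter", "mean_nuc_reporter", "pyknotic_fraction")
  miss <- setdiff(need, colnames(sm$values))
  if (length(miss) > 0)
    stop("zscore matrix lacks feature(s): ", paste(miss, collapse = ", "))

  meta <- sm$meta
  samp <- meta$role == "sample"
  if (any(samp & meta$low_count)) {
    drop_ids <- unique(meta$compound_id[samp & meta$low_count])
    warning("dropping compound(s) with low-count wells from hit calling: ",
            paste(drop_ids, collapse = ", "))
    samp <- samp & !(meta$compound_id %in% drop_ids)
  }
  key <- paste(meta$compound_id, meta$concentration_uM, sep = "@")
  out <- list()
  for (k in unique(key[samp])) {
    rows <- which(samp & key == k)
    plus <- rows[meta$biotin[rows]]
    minus <- rows[!meta$biotin[rows]]
    if (length(plus) == 0 || length(minus) == 0)
      stop("pairing error: compound ", sub("@.*", "", k),
           " lacks one assay condition")
    z <- function(r, f) mean(sm$values[r, f])
    zc_p <- z(plus, "mean_cyto_reporter")
    zc_m <- z(minus, "mean_cyto_reporter")
    zn_p <- z(plus, "mean_nuc_reporter")
    zn_m <- z(minus, "mean_nuc_reporter")
    zp_p <- z(plus, "pyknotic_fraction")
    cls <- classify_zs(zc_p, zc_m, zn_p, zn_m, zp_p, thresholds)
    out[[k]] <- data.frame(
      compound_id = meta$compound_id[plus[1]],
      concentration_uM = meta$concentration_uM[plus[1]],
      z_cyto_plus = zc_p, z_cyto_minus = zc_m,
      z_nuc_plus = zn_p, z_nuc_minus = zn_m,
      pyknosis_z_plus = zp_p, class = cls,
      rank_score = if (cls == "specific_releaser") zc_p - max(zc_m, 0)
                   else NA_real_,
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, out)
  rownames(hits) <- NULL
  class(hits) <- c("hit_call", "data.frame")
  hits
}

# The classification rule on plain numbers (first match wins).
classify_zs <- function(z_cyto_plus, z_cyto_minus, z_nuc_plus, z_nuc_minus,
                        pyknosis_z_plus, thresholds) {
  t_hit <- thresholds$t_hit; t_null <- thresholds$t_null
  t_tox <- thresholds$t_tox
  if (pyknosis_z_plus >= t_tox) return("toxic")
  if (z_nuc_plus <= -t_hit && z_nuc_minus <= -t_hit)
    return("nonspecific_loss")
  if (z_cyto_plus >= t_hit && abs(z_cyto_minus) < t_null)
    return("specific_releaser")
  "inactive"
}

#' Rank the top-k specific releasers
#'
#' Specific releasers sorted by `rank_score` descending, ties broken by
#' `compound_id` lexicographically; returns at most `k` rows.
#'
#' @param hits A `hit_call` data frame from [call_hits()].
#' @param k Maximum entries (>= 1).
#' @return The top `min(k, n_releasers)` rows.
#' @export
rank_top_k <- function(hits, k = 20) {
  stopifnot(k >= 1)
  rel <- hits[hits$class == "specific_releaser", , drop = FALSE]
  if (nrow(rel) == 0) return(rel)
  rel <- rel[order(-rel$rank_score, rel$compound_id), , drop = FALSE]
  head(rel, k)
}

#' Hierarchical clustering of response profiles
#'
#' Agglomerative clustering of compound profiles with average linkage on
#' Pearson distance `d = 1 - r` (profiles centered per compound by the
#' correlation itself). Zero-variance or short profiles are errors naming
#' the offending profile, not silent drops.
#'
#' @param profiles Numeric matrix, one row per compound (rownames used as
#'   labels), columns are features and/or doses.
#' @param linkage Only `"average"` is offered (the method of the screen).
#' @param metric Only `"pearson"` is offered.
#' @return A `cluster_result`: list with `hclust` (the merge tree), `order`
#'   (leaf permutation), `labels`, `dist` (the distance matrix).
#' @export
cluster_profiles <- function(profiles, linkage = "average",
                             metric = "pearson") {
  linkage <- match.arg(linkage, "average")
  metric <- match.arg(metric, "pearson")
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) stop("need >= 2 profiles to cluster")
  if (ncol(profiles) < 3) stop("profiles need >= 3 entries")
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("profile", seq_len(nrow(profiles)))
  bad <- rownames(profiles)[apply(profiles, 1, function(x)
    any(!is.finite(x)) || sd(x) == 0)]
  if (length(bad) > 0)
    stop("zero-variance or non-finite profile(s): ",
         paste(bad, collapse = ", "))
  d <- 1 - cor(t(profiles))
  hc <- hclust(as.dist(d), method = "average")
  structure(list(hclust = hc, order = hc$order,
                 labels = rownames(profiles), dist = d),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result>", length(x$labels),
      "profiles, average linkage on Pearson distance\n")
  invisible(x)
}

#' Export a dendrogram as Newick text
#'
#' @param cl A `cluster_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(cl, path) {
  phy <- ape::as.phylo(cl$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Render a clustered heat map to PNG
#'
#' Rows follow the clustering leaf order; the color scale is symmetric
#' around 0 (blue negative, red positive), matching the usual Z-score
#' display.
#'
#' @param values Numeric matrix (e.g. Z-scores), rows = compounds/wells.
#' @param cl Optional `cluster_result` supplying the row order.
#' @param path PNG output path.
#' @return `path`, invisibly.
#' @export
plot_heatmap <- function(values, cl = NULL, path) {
  ord <- if (!is.null(cl)) cl$order else seq_len(nrow(values))
  v <- values[ord, , drop = FALSE]
  lim <- max(abs(v[is.finite(v)]), 1e-9)
  png(path, width = 900, height = max(300, 12 * nrow(v) + 120))
  op <- par(mar = c(8, 10, 2, 2))
  image(t(v[rev(seq_len(nrow(v))), , drop = FALSE]),
        col = hcl.colors(101, "Blue-Red 3"), zlim = c(-lim, lim),
        axes = FALSE)
  axis(1, at = seq(0, 1, length.out = ncol(v)), labels = colnames(v),
       las = 2, cex.axis = 0.8)
  axis(2, at = seq(0, 1, length.out = nrow(v)),
       labels = rev(rownames(v)), las = 2, cex.axis = 0.6)
  par(op)
  dev.off()
  invisible(path)
}

#' Replicate summary with Student's t test
#'
#' Mean, standard error of the mean (sample convention) and a two-sample
#' two-tailed equal-variance Student's t test against the control group,
#' with the conventional significance stars (`*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001).
#'
#' @param values Treated replicate values (n >= 2).
#' @param control_values Control replicate values (n >= 2).
#' @param welch Use the Welch (unequal-variance) test instead.
#' @return List with `mean`, `sem`, `p_two_tailed`, `stars`.
#' @export
#' @examples
#' dose_time_summary(c(5, 6, 7, 8), c(1, 2, 3, 4))
dose_time_summary <- function(values, control_values, welch = FALSE) {
  if (length(values) < 2 || length(control_values) < 2)
    stop("sample-size error: each group needs >= 2 values")
  p <- t.test(values, control_values, var.equal = !welch)$p.value
  list(mean = mean(values),
       sem = sd(values) / sqrt(length(values)),
       p_two_tailed = p,
       stars = if (p < 0.001) "***" else if (p < 0.01) "**"
               else if (p < 0.05) "*" else "")
}
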