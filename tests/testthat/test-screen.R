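mk_wells <- function(values, plate = "PL01", biotin = TRUE,
                     role = "sample", feature = "mean_cyto_reporter") {
  n <- length(values)
  df <- data.frame(
    plate_id = plate, well_id = sprintf("A%02d", seq_len(n)),
    compound_id = sprintf("CMP%04d", seq_len(n)), concentration_uM = 10,
    biotin = biotin, role = role, n_cells = 100, stringsAsFactors = FALSE)
  df[[feature]] <- values
  df$low_count <- FALSE
  df
}

test_that("intra-plate ratio normalization matches the arithmetic contract", {
  sm <- screen_matrix(mk_wells(c(2, 4)), features = "mean_cyto_reporter")
  pr <- normalize_intraplate(sm)
  expect_equal(unname(pr$values[, 1]), c(2 / 3, 4 / 3))
  expect_equal(mean(pr$values[, 1]), 1, tolerance = 1e-12)
  expect_equal(pr$stage, "plate_ratio")

  # identity plate: constant wells all map to 1
  sm2 <- screen_matrix(mk_wells(rep(7.5, 6)), features = "mean_cyto_reporter")
  expect_true(all(normalize_intraplate(sm2)$values == 1))

  # degenerate zero-mean plate errors by name
  sm3 <- screen_matrix(mk_wells(c(0, 0, 0)), features = "mean_cyto_reporter")
  expect_error(normalize_intraplate(sm3), "degenerate plate")
})

test_that("a global intensity offset between plates is removed exactly", {
  pattern <- c(1, 2, 3, 4, 8)
  w1 <- mk_wells(pattern, plate = "PL01")
  w2 <- mk_wells(pattern * 2, plate = "PL02")   # 2x brighter plate
  sm <- screen_matrix(rbind(w1, w2), features = "mean_cyto_reporter")
  pr <- normalize_intraplate(sm)
  expect_equal(unname(pr$values[1:5, 1]), unname(pr$values[6:10, 1]),
               tolerance = 1e-9)
  for (p in c("PL01", "PL02"))
    expect_equal(mean(pr$values[pr$meta$plate_id == p, 1]), 1,
                 tolerance = 1e-12)
})

test_that("Z-scores follow the population-convention formula", {
  expect_equal(zscore_values(c(1, 2, 3)),
               c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_error(zscore_values(c(5, 5, 5)), "zero standard deviation")
  expect_error(zscore_values(3), "population size")

  set.seed(42)
  w <- mk_wells(runif(24, 0.5, 2))
  sm <- zscore(normalize_intraplate(screen_matrix(
    w, features = "mean_cyto_reporter")))
  expect_equal(mean(sm$values[, 1]), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean((sm$values[, 1])^2)), 1, tolerance = 1e-9)
  expect_equal(sm$stage, "zscore")

  # idempotent on re-application with the same population
  sm2 <- zscore(sm)
  expect_equal(sm2$values, sm$values, tolerance = 1e-9)
})

test_that("z-scoring is stratified by assay condition and population", {
  set.seed(7)
  w <- rbind(mk_wells(runif(12, 1, 2), biotin = TRUE),
             mk_wells(runif(12, 5, 9), biotin = FALSE))
  w$well_id <- sprintf("A%02d", 1:24)
  ctrl <- mk_wells(c(100, 200), biotin = TRUE, role = "negative_control")
  ctrl$well_id <- c("P23", "P24")
  sm <- screen_matrix(rbind(w, ctrl), features = "mean_cyto_reporter")
  sm$stage <- "plate_ratio"   # inject directly to isolate the z step
  z <- zscore(sm, population = "samples_only")
  for (b in c(TRUE, FALSE)) {
    pop <- z$meta$biotin == b & z$meta$role == "sample"
    expect_equal(mean(z$values[pop, 1]), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean(z$values[pop, 1]^2)), 1, tolerance = 1e-9)
  }
  # controls are transformed but not part of the population
  expect_gt(max(abs(z$values[z$meta$role == "negative_control", 1])), 3)
})

mk_zmatrix <- function(zc_p, zc_m, zn_p, zn_m, zp_p) {
  n <- length(zc_p)
  meta <- data.frame(
    plate_id = "PL01",
    well_id = sprintf("%s%02d", rep(LETTERS[1:16], each = 24),
                      rep(1:24, 16))[seq_len(2 * n)],
    compound_id = rep(sprintf("CMP%04d", seq_len(n)), each = 2),
    concentration_uM = 10,
    biotin = rep(c(TRUE, FALSE), n), role = "sample", low_count = FALSE,
    stringsAsFactors = FALSE)
  vals <- matrix(0, 2 * n, 3,
                 dimnames = list(NULL, c("mean_cyto_reporter",
                                         "mean_nuc_reporter",
                                         "pyknotic_fraction")))
  vals[seq(1, 2 * n, 2), ] <- cbind(zc_p, zn_p, zp_p)
  vals[seq(2, 2 * n, 2), ] <- cbind(zc_m, zn_m, 0)
  structure(list(values = vals, meta = meta, stage = "zscore"),
            class = "screen_matrix")
}

test_that("hit classification matches the documented rule on worked cases", {
  sm <- mk_zmatrix(zc_p = c(5.0, 0.1, 0, 4.0),
                   zc_m = c(0.2, 0.0, 0, 0.1),
                   zn_p = c(0.0, -4.0, 0, 0.0),
                   zn_m = c(0.1, -4.0, 0, 0.0),
                   zp_p = c(0.0, 1.0, 0, 3.0))
  hits <- call_hits(sm)
  expect_equal(hits$class,
               c("specific_releaser", "nonspecific_loss", "inactive",
                 "toxic"))  # toxicity outranks translocation in row 4
  expect_equal(hits$rank_score[1], 5.0 - 0.2)
  expect_true(all(is.na(hits$rank_score[2:4])))
})

test_that("hit classification agrees with the truth-table oracle", {
  eps <- 1e-6
  zc_p <- c(-3, 0, 2 - eps, 2, 2 + eps, 3, 5)
  zc_m <- c(-3, -1 - eps, -1 + eps, 0, 1 - eps, 1, 2.5)
  zn <- c(-4, -2 - eps, -2, -2 + eps, 0, 2)
  zp <- c(-1, 0, 2 - eps, 2, 2 + eps, 4)
  grid <- expand.grid(zc_p = zc_p, zc_m = zc_m, zn_p = zn, zn_m = zn,
                      zp = zp[c(1, 4)])
  got <- mapply(rushscreen:::classify_zs, grid$zc_p, grid$zc_m, grid$zn_p,
                grid$zn_m, grid$zp,
                MoreArgs = list(thresholds = list(t_hit = 2, t_null = 1,
                                                  t_tox = 2)))
  want <- mapply(oracle_classify, grid$zc_p, grid$zc_m, grid$zn_p,
                 grid$zn_m, grid$zp)
  expect_identical(unname(got), unname(want))
})

test_that("hit calling requires both assay conditions", {
  sm <- mk_zmatrix(1, 0, 0, 0, 0)
  sm$meta <- sm$meta[1, , drop = FALSE]
  sm$values <- sm$values[1, , drop = FALSE]
  expect_error(call_hits(sm), "pairing error")
})

test_that("top-k ranking sorts by score with lexicographic ties", {
  hits <- data.frame(
    compound_id = c("CMP0003", "CMP0001", "CMP0002", "CMP0004"),
    concentration_uM = 10,
    z_cyto_plus = c(5, 2, 9, 1), z_cyto_minus = 0, z_nuc_plus = 0,
    z_nuc_minus = 0, pyknosis_z_plus = 0,
    class = c("specific_releaser", "specific_releaser",
              "specific_releaser", "inactive"),
    rank_score = c(5, 2, 9, NA), stringsAsFactors = FALSE)
  top <- rank_top_k(hits, 2)
  expect_equal(top$rank_score, c(9, 5))
  expect_equal(nrow(rank_top_k(hits, 20)), 3)
  none <- hits[hits$class == "inactive", ]
  expect_equal(nrow(rank_top_k(none, 5)), 0)
  tie <- hits[1:2, ]; tie$rank_score <- 4
  expect_equal(rank_top_k(tie, 2)$compound_id, c("CMP0001", "CMP0003"))
})

test_that("profile clustering matches a brute-force average-linkage oracle", {
  # identical profiles merge first at distance 0
  prof <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 1, 0, 2))
  cl <- cluster_profiles(prof)
  expect_equal(cl$dist["a", "b"], 0, tolerance = 1e-12)
  expect_equal(cl$hclust$height[1], 0, tolerance = 1e-12)
  # a profile and its negation sit at distance 2
  prof2 <- rbind(a = c(1, 2, 3), b = -c(1, 2, 3), c = c(1, 0, 2))
  expect_equal(cluster_profiles(prof2)$dist["a", "b"], 2, tolerance = 1e-12)

  # merge heights equal the exhaustive computation on random instances
  set.seed(11)
  for (n in 3:5) {
    prof <- matrix(rnorm(n * 6), n)
    rownames(prof) <- letters[seq_len(n)]
    cl <- cluster_profiles(prof)
    expect_equal(sort(cl$hclust$height),
                 sort(brute_average_linkage(1 - cor(t(prof)))),
                 tolerance = 1e-9)
  }
  expect_error(cluster_profiles(rbind(a = c(1, 1, 1), b = c(1, 2, 3))),
               "zero-variance")
  expect_error(cluster_profiles(matrix(1:3, 1)), ">= 2 profiles")
})

test_that("dendrograms export to Newick with all leaves", {
  set.seed(2)
  prof <- matrix(rnorm(24), 4, dimnames = list(paste0("c", 1:4), NULL))
  cl <- cluster_profiles(prof)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(cl, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, rownames(prof))
})

test_that("replicate summaries reproduce hand-computed values", {
  s <- dose_time_summary(c(1, 2, 3, 4), c(0, 1, 3, 2))
  expect_equal(s$mean, 2.5)
  expect_equal(s$sem, sd(c(1, 2, 3, 4)) / 2)
  expect_equal(s$sem, 0.6455, tolerance = 1e-4)

  # equal means and variances by symmetry: t = 0, p = 1
  s2 <- dose_time_summary(c(1, 3), c(3, 1))
  expect_equal(s2$p_two_tailed, 1)
  expect_equal(s2$stars, "")

  # equal-variance Student's t: matches the closed form
  x <- c(5, 6, 7, 8); y <- c(1, 2, 3, 4)
  sp2 <- (3 * var(x) + 3 * var(y)) / 6
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(dose_time_summary(x, y)$p_two_tailed,
               2 * pt(-abs(tstat), 6), tolerance = 1e-12)
  expect_equal(dose_time_summary(x, y)$stars, "**")

  expect_error(dose_time_summary(1, c(1, 2)), "sample-size error")
  # Welch flag switches the test
  expect_false(isTRUE(all.equal(
    dose_time_summary(c(1, 2, 3, 9), y, welch = TRUE)$p_two_tailed,
    dose_time_summary(c(1, 2, 3, 9), y)$p_two_tailed)))
})
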