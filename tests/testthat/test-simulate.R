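test_that("phenotype specifications enforce their invariants", {
  expect_error(phenotype_spec("diffuse_nuclear",
                              cytoplasmic_reporter_fraction = 0.2),
               "< 0.1")
  expect_error(phenotype_spec("translocated",
                              cytoplasmic_reporter_fraction = 0.1),
               ">= 0.3")
  expect_error(phenotype_spec("diffuse_nuclear", n_puncta = 3),
               "punctate_retained")
  expect_error(phenotype_spec("diffuse_nuclear",
                              pyknotic_shrink_factor = 0.5),
               "pyknotic")
  ph <- default_phenotypes()
  expect_setequal(names(ph), c("punctate_retained", "diffuse_nuclear",
                               "translocated", "pyknotic"))
})

test_that("cell populations honour size, mixture and overlap constraints", {
  expect_equal(nrow(sample_cell_population(c(diffuse_nuclear = 1), 0,
                                           c(512L, 512L), seed = 0)), 0)
  cells <- sample_cell_population(c(punctate_retained = 1), 50,
                                  c(1024L, 1024L), seed = 3)
  expect_equal(nrow(cells), 50)
  expect_true(all(cells$phenotype == "punctate_retained"))

  # mixture counts fall in the exact binomial 99% interval
  mix <- c(translocated = 0.5, pyknotic = 0.5)
  cells <- sample_cell_population(mix, 400, c(1024L, 1024L), seed = 9)
  n_tr <- sum(cells$phenotype == "translocated")
  expect_gte(n_tr, qbinom(0.005, 400, 0.5))
  expect_lte(n_tr, qbinom(0.995, 400, 0.5))

  # pairwise nucleus separation respects the tolerance
  cells <- sample_cell_population(c(diffuse_nuclear = 1), 60,
                                  c(512L, 512L), seed = 4)
  d <- as.matrix(dist(cells[, c("x", "y")]))
  rsum <- outer(cells$nucleus_radius, cells$nucleus_radius, "+")
  expect_true(all(d[upper.tri(d)] >= rsum[upper.tri(rsum)] - 1e-9))

  # identical inputs and seed reproduce identical populations
  expect_identical(cells,
                   sample_cell_population(c(diffuse_nuclear = 1), 60,
                                          c(512L, 512L), seed = 4))
  expect_error(sample_cell_population(c(diffuse_nuclear = 1), 200,
                                      c(64L, 64L), seed = 1),
               "placement error")
  expect_error(sample_cell_population(c(diffuse_nuclear = 0.5), 10,
                                      c(256L, 256L), seed = 1),
               "sum to 1")
})

test_that("an empty field renders to background plus noise only", {
  g <- noiseless_gen(128, background = 40)
  fld <- render_field(data.frame(), g, seed = 1)
  expect_setequal(names(fld$channels), c("nuclear_dye", "cyto_dye",
                                         "reporter"))
  expect_true(all(fld$channels$reporter == 40))
  expect_equal(sum(fld$channels$reporter), 40 * 128^2)
  g$noise_enabled <- TRUE
  fld2 <- render_field(data.frame(), g, seed = 1)
  expect_equal(mean(fld2$channels$reporter), 40, tolerance = 0.05)
})

test_that("rendering conserves the configured per-cell reporter total", {
  g <- noiseless_gen(256, background = 0, cv = 0)
  for (ph in c("diffuse_nuclear", "punctate_retained", "translocated")) {
    cells <- data.frame(x = 128, y = 128, phenotype = ph,
                        nucleus_radius = 14)
    fld <- render_field(cells, g, seed = 2)
    expected <- default_phenotypes()[[ph]]$nuclear_reporter_mean * pi * 14^2
    expect_equal(sum(fld$channels$reporter), expected,
                 tolerance = 0.01)
  }
})

test_that("the cytoplasmic reporter fraction is rendered as configured", {
  g <- noiseless_gen(256, background = 0, cv = 0)
  cells <- data.frame(x = 128, y = 128, phenotype = "translocated",
                      nucleus_radius = 14)
  fld <- render_field(cells, g, seed = 1)
  rep_ch <- fld$channels$reporter
  # independent pixel-level expectation from the soft-disk coverage model:
  # 60% of the total spread over the nucleus, 40% over the annulus
  d <- sqrt(outer((1:256 - 128)^2, (1:256 - 128)^2, "+"))
  nw <- pmin(pmax(14 + 0.5 - d, 0), 1)
  bw <- pmin(pmax(14 * 1.9 + 0.5 - d, 0), 1)
  ann <- pmax(bw - nw, 0)
  total <- 400 * pi * 14^2
  expected <- 0.6 * total * nw / sum(nw) + 0.4 * total * ann / sum(ann)
  expect_equal(sum(rep_ch), total, tolerance = 0.01)
  # cytoplasmic share integrated over the pure-annulus region
  pure <- nw == 0
  expect_equal(sum(rep_ch[pure]) / sum(rep_ch),
               sum(expected[pure]) / total, tolerance = 0.01)
  # pixelwise agreement with the model, 16-bit quantization aside
  expect_lt(max(abs(rep_ch - expected)), 1)
})

test_that("puncta are rendered as countable local maxima", {
  g <- noiseless_gen(256, background = 0, cv = 0)
  ph <- default_phenotypes()
  ph$punctate_retained <- phenotype_spec("punctate_retained",
                                         nuclear_reporter_mean = 400,
                                         cytoplasmic_reporter_fraction = 0.02,
                                         n_puncta = 5L)
  cells <- data.frame(x = 128, y = 128, phenotype = "punctate_retained",
                      nucleus_radius = 14)
  fld <- render_field(cells, g, seed = 7, phenotypes = ph)
  nuc <- disk_mask(256, 128, 128, 15)
  n_peaks <- count_local_maxima(fld$channels$reporter, nuc, floor = 50)
  expect_equal(n_peaks, 5)
})

test_that("rendering is deterministic and validates channel names", {
  g <- small_config(128, 5)$generator
  cells <- sample_cell_population(c(diffuse_nuclear = 1), 5,
                                  c(128L, 128L), seed = 2)
  a <- render_field(cells, g, seed = 3)
  b <- render_field(cells, g, seed = 3)
  expect_identical(a$channels, b$channels)
  g$channels <- c("nuclear_dye", "cyto_dye", "reporter", "bogus")
  expect_error(render_field(cells, g, seed = 3), "unknown channel")
})

test_that("well mixtures follow compound class and release-cue logic", {
  # no compound class yields translocated cells without the cue
  for (cl in c("inactive", "specific_releaser", "nonspecific_loss",
               "toxic")) {
    mix <- phenotype_mixture(cl, biotin = FALSE, effect = 0.6)
    expect_false("translocated" %in% names(mix))
    expect_false("diffuse_nuclear" %in% names(mix))
  }
  expect_equal(phenotype_mixture("inactive", FALSE),
               c(punctate_retained = 1))
  m <- phenotype_mixture("specific_releaser", TRUE, 0.6)
  expect_equal(unname(m[c("diffuse_nuclear", "translocated")]), c(0.4, 0.6))
  m <- phenotype_mixture("toxic", FALSE, 0.5)
  expect_equal(unname(m["pyknotic"]), 0.5)
})

test_that("simulated plates carry faithful ground truth", {
  cfg <- small_config(192, 25, 2)
  lay <- build_layout(2, 4, 10, seed = 2,
                      classes = c("specific_releaser", "inactive"),
                      config = cfg)
  sim <- simulate_plate(lay, fields_per_well = 2, config = cfg, seed = 6)
  expect_equal(nrow(sim$cells), nrow(lay) * 2 * 25)
  expect_equal(nrow(sim$well_classes), nrow(lay))

  rel_minus <- lay$well_id[lay$class == "specific_releaser" & !lay$biotin]
  gt <- sim$cells[sim$cells$well_id %in% rel_minus, ]
  expect_gt(nrow(gt), 0)
  expect_equal(sum(gt$phenotype == "translocated"), 0)

  rel_plus <- lay$well_id[lay$class == "specific_releaser" & lay$biotin]
  gt <- sim$cells[sim$cells$well_id %in% rel_plus, ]
  frac <- mean(gt$phenotype == "translocated")
  n <- nrow(gt)
  expect_gte(frac, qbinom(0.005, n, 0.6) / n)
  expect_lte(frac, qbinom(0.995, n, 0.6) / n)
})

test_that("per-field seeds are unique within a run and reproducible", {
  wells <- well_ids_384()
  seeds <- unlist(lapply(1:2, function(p)
    lapply(wells, function(w) sapply(0:3, function(f)
      field_seed(11, p, w, f)))))
  expect_equal(anyDuplicated(seeds), 0)
  expect_identical(field_seed(11, 1, "B07", 2), field_seed(11, 1, "B07", 2))
})
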