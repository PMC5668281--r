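#' Construct a cell phenotype specification
#'
#' A `phenotype_spec` describes how one class of cell renders in the reporter
#' channel: how much total reporter it carries, what fraction of it sits in
#' the cytoplasm, whether the nuclear pool is concentrated in hook-bound
#' puncta or diffuse, and how the nucleus is drawn. The four canonical
#' phenotypes of a retention-hook translocation assay are:
#'
#' * `punctate_retained` — reporter hook-bound in nuclear puncta (no release
#'   cue, or drug without cue);
#' * `diffuse_nuclear` — reporter released from the hook but retained in the
#'   nucleus (cue without drug);
#' * `translocated` — a substantial reporter fraction moved to the cytoplasm
#'   (drug plus cue);
#' * `pyknotic` — condensed, brightly staining nucleus with most reporter
#'   lost (cell death).
#'
#' @param name One of `"punctate_retained"`, `"diffuse_nuclear"`,
#'   `"translocated"`, `"pyknotic"`.
#' @param nuclear_reporter_mean Mean per-pixel reporter intensity over the
#'   nucleus (arbitrary camera units) before the cytoplasmic fraction is
#'   diverted.
#' @param cytoplasmic_reporter_fraction Fraction in `[0,1]` of the cell's
#'   total reporter placed in the cytoplasmic annulus. Must be < 0.1 for the
#'   two nuclear-retained phenotypes and >= 0.3 for `translocated`.
#' @param n_puncta Number of nuclear puncta; > 0 iff `punctate_retained`.
#' @param punctum_sigma Gaussian sigma of a punctum, pixels.
#' @param nucleus_radius_mean Mean nucleus radius, pixels.
#' @param nucleus_radius_cv Coefficient of variation of the nucleus radius.
#' @param pyknotic_shrink_factor Radius shrink factor in `(0,1]`; < 1 iff
#'   `pyknotic`.
#' @return An object of class `phenotype_spec`.
#' @export
#' @examples
#' phenotype_spec("translocated", nuclear_reporter_mean = 400,
#'                cytoplasmic_reporter_fraction = 0.4)
phenotype_spec <- function(name,
                           nuclear_reporter_mean = 400,
                           cytoplasmic_reporter_fraction = 0.05,
                           n_puncta = 0L,
                           punctum_sigma = 2.0,
                           nucleus_radius_mean = 14,
                           nucleus_radius_cv = 0.15,
                           pyknotic_shrink_factor = 1.0) {
  name <- match.arg(name, c("punctate_retained", "diffuse_nuclear",
                            "translocated", "pyknotic"))
  f <- cytoplasmic_reporter_fraction
  if (f < 0 || f > 1)
    stop("cytoplasmic_reporter_fraction must lie in [0,1]")
  if (name %in% c("punctate_retained", "diffuse_nuclear") && f >= 0.1)
    stop("nuclear-retained phenotypes require cytoplasmic_reporter_fraction < 0.1")
  if (name == "translocated" && f < 0.3)
    stop("translocated requires cytoplasmic_reporter_fraction >= 0.3")
  if ((n_puncta > 0) != (name == "punctate_retained"))
    stop("n_puncta > 0 iff name = punctate_retained")
  if ((pyknotic_shrink_factor < 1) != (name == "pyknotic"))
    stop("pyknotic_shrink_factor < 1 iff name = pyknotic")
  if (pyknotic_shrink_factor <= 0 || pyknotic_shrink_factor > 1)
    stop("pyknotic_shrink_factor must lie in (0,1]")
  structure(list(
    name = name,
    nuclear_reporter_mean = nuclear_reporter_mean,
    cytoplasmic_reporter_fraction = f,
    n_puncta = as.integer(n_puncta),
    punctum_sigma = punctum_sigma,
    nucleus_radius_mean = nucleus_radius_mean,
    nucleus_radius_cv = nucleus_radius_cv,
    pyknotic_shrink_factor = pyknotic_shrink_factor
  ), class = "phenotype_spec")
}

#' Default phenotype set
#'
#' The four canonical phenotypes with generator defaults: equal reporter
#' load for the three live phenotypes, 8 puncta (sigma 2 px) for the
#' hook-bound state, 40% cytoplasmic reporter for translocated cells, and
#' the condensed pyknotic nucleus (radius x0.55, reporter x0.2; the nuclear
#' dye brightening is applied at render time).
#'
#' @param nuclear_reporter_mean Baseline mean nuclear reporter intensity.
#' @return Named list of [phenotype_spec()] objects.
#' @export
default_phenotypes <- function(nuclear_reporter_mean = 400) {
  m <- nuclear_reporter_mean
  list(
    punctate_retained = phenotype_spec("punctate_retained",
      nuclear_reporter_mean = m, cytoplasmic_reporter_fraction = 0.02,
      n_puncta = 8L),
    diffuse_nuclear = phenotype_spec("diffuse_nuclear",
      nuclear_reporter_mean = m, cytoplasmic_reporter_fraction = 0.05),
    translocated = phenotype_spec("translocated",
      nuclear_reporter_mean = m, cytoplasmic_reporter_fraction = 0.4),
    pyknotic = phenotype_spec("pyknotic",
      nuclear_reporter_mean = 0.2 * m, cytoplasmic_reporter_fraction = 0.05,
      pyknotic_shrink_factor = 0.55)
  )
}

#' Phenotype mixture implied by a compound class and assay condition
#'
#' Encodes the two-condition logic of the assay. Without the release cue the
#' reporter stays hook-bound, so no compound class yields translocated cells
#' (`biotin = FALSE` implies 0 translocated weight). With the cue, an
#' inactive compound gives diffuse-nuclear cells; a specific releaser
#' converts a fraction `effect` of them to translocated; a toxic compound
#' makes a fraction `effect` pyknotic in both conditions; a nonspecific-loss
#' compound keeps the mixture of an inactive well (its signal reduction is
#' an intensity scaling applied at render time, see [simulate_plate()]).
#'
#' @param class One of `"inactive"`, `"specific_releaser"`,
#'   `"nonspecific_loss"`, `"toxic"`.
#' @param biotin Logical; is the release cue present?
#' @param effect Effect size in `[0,1]`.
#' @return Named numeric vector of mixture weights summing to 1.
#' @export
#' @examples
#' phenotype_mixture("specific_releaser", biotin = TRUE, effect = 0.6)
#' phenotype_mixture("specific_releaser", biotin = FALSE, effect = 0.6)
phenotype_mixture <- function(class, biotin, effect = 0) {
  class <- match.arg(class, c("inactive", "specific_releaser",
                              "nonspecific_loss", "toxic"))
  stopifnot(effect >= 0, effect <= 1)
  base <- if (biotin) "diffuse_nuclear" else "punctate_retained"
  w <- switch(class,
    inactive = ,
    nonspecific_loss = setNames(1, base),
    specific_releaser = if (biotin && effect > 0)
      setNames(c(1 - effect, effect), c(base, "translocated"))
    else setNames(1, base),
    toxic = if (effect > 0)
      setNames(c(1 - effect, effect), c(base, "pyknotic"))
    else setNames(1, base)
  )
  w[w > 0]
}
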