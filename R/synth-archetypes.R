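#' Baseline trajectories for the sixteen morphological traits
#'
#' Per-trait starting values (at the first imaging day) and daily growth
#' rates, in pixels (or trait units) per day, used by the synthetic
#' trajectory model. Values are chosen to resemble a young maize seedling
#' photographed at desk scale: an 8-day-old shoot of roughly 300 px area
#' and 40 px height that roughly quadruples in area over the nine-day
#' imaging window.
#'
#' @return A tibble with columns `trait`, `start` and `rate`.
#' @export
trait_baselines <- function() {
  tibble::tribble(
    ~trait,                 ~start, ~rate,
    "area_px",               300,   100,
    "height_px",              40,     8,
    "width_px",               30,     6,
    "perimeter_px",          120,    25,
    "hull_area_px",          450,   140,
    "hull_vertices",           8,     0.8,
    "longest_axis_px",        45,     8,
    "solidity",                0.60,  0.004,
    "ellipse_center_x_px",    45,     0.5,
    "ellipse_center_y_px",   100,     2,
    "ellipse_major_px",       50,     9,
    "ellipse_minor_px",       18,     3,
    "ellipse_angle_deg",      85,     0.5,
    "eccentricity",            0.90,  0.002,
    "center_of_mass_x_px",    45,     0.5,
    "center_of_mass_y_px",    95,     2
  )
}

#' Cold-response archetypes
#'
#' Three canonical seedling responses to a transient cold stress, used to
#' populate synthetic genotype panels:
#'
#' * `tolerant` — growth resumes at the pre-stress rate and necrosis
#'   never departs from the misclassified-stem baseline;
#' * `sensitive` — markedly slowed post-stress growth and strong leaf
#'   necrosis;
#' * `intermediate` — moderate necrosis and a specifically reduced height
#'   recovery relative to its other traits.
#'
#' `recovery_multiplier` scales every trait's growth rate after the plant
#' returns to warm conditions; `height_recovery_multiplier` and
#' `width_recovery_multiplier` override it for shoot height and width
#' (the set of traits most affected by the stress differs between
#' response types); `necrosis_effect_px` is the necrotic pixel mass a
#' cold-treated plant accumulates after the stress ends.
#'
#' @return A tibble with one row per archetype.
#' @export
cold_archetypes <- function() {
  tibble::tribble(
    ~archetype,     ~recovery_multiplier, ~height_recovery_multiplier,
      ~width_recovery_multiplier, ~necrosis_effect_px,
    "tolerant",      1.0,                  1.0,   1.0,           0,
    "sensitive",     0.6,                  0.6,   0.6,         150,
    "intermediate",  0.8,                  0.5,   1.0,          50
  )
}

#' Draw a synthetic genotype panel
#'
#' Assigns `n_genotypes` inbred lines to the cold-response archetypes and
#' jitters each line's parameters around its archetype so that lines are
#' distinct but clusterable. By default 7 of 40 lines are `sensitive`
#' (strong necrosis responders), mirroring the fraction of strong necrosis
#' responders the assay is designed around; the remainder split between
#' `tolerant` and `intermediate`.
#'
#' Every line also receives a misclassified-stem rate (the fraction of its
#' tissue whose colour reads as necrosis in *all* treatments, drawn
#' uniformly on \[0, 0.1\]), a latitude of origin (uniform 32–48 degrees N,
#' independent of cold response), and a genotype-level growth scale.
#'
#' @param n_genotypes Number of lines (default 40).
#' @param archetypes Archetype table, see [cold_archetypes()].
#' @param n_sensitive Number of lines assigned to the `sensitive`
#'   archetype (default scales as 7/40).
#' @param seed Integer seed; the panel is deterministic given it.
#' @return A tibble with one row per genotype: `genotype`, `archetype`,
#'   `growth_scale`, `recovery_multiplier`, `height_recovery_multiplier`,
#'   `necrosis_effect_px`, `stem_misclass_rate`, `latitude_deg`.
#' @export
genotype_panel <- function(n_genotypes = 40,
                           archetypes = cold_archetypes(),
                           n_sensitive = max(1L, round(n_genotypes * 7 / 40)),
                           seed = 1) {
  assert_count(n_genotypes, "n_genotypes")
  if (n_sensitive > n_genotypes) abort("`n_sensitive` exceeds `n_genotypes`")
  n_tol <- round((n_genotypes - n_sensitive) * 16 / 33)
  counts <- c(tolerant = n_tol, sensitive = n_sensitive,
              intermediate = n_genotypes - n_sensitive - n_tol)
  assign <- rep(c("tolerant", "sensitive", "intermediate"), counts)

  withr::with_seed(seed, {
    arch <- archetypes[match(assign, archetypes$archetype), ]
    tibble(
      genotype = sprintf("G%02d", seq_len(n_genotypes)),
      archetype = assign,
      growth_scale = pmax(0.5, rnorm(n_genotypes, 1, 0.05)),
      recovery_multiplier = pmin(1.5, pmax(
        0, arch$recovery_multiplier + rnorm(n_genotypes, 0, 0.02))),
      height_recovery_multiplier = pmin(1.5, pmax(
        0, arch$height_recovery_multiplier + rnorm(n_genotypes, 0, 0.02))),
      width_recovery_multiplier = pmin(1.5, pmax(
        0, arch$width_recovery_multiplier + rnorm(n_genotypes, 0, 0.02))),
      necrosis_effect_px = arch$necrosis_effect_px *
        exp(rnorm(n_genotypes, 0, 0.15)),
      stem_misclass_rate = runif(n_genotypes, 0, 0.1),
      latitude_deg = runif(n_genotypes, 32, 48)
    )
  })
}
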