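# piecewise-linear growth model shared by the table-only and image modes

# effective growth days for a size trait at day `das`:
# control grows linearly from the first imaging day; cold plants grow
# identically up to stress onset, arrest completely during the stress,
# then resume at `multiplier` times the base rate.
effective_growth <- function(das, treatment, design, multiplier) {
  d0 <- min(design$das)
  if (treatment == design$treatments[1]) return(das - d0)
  (pmin(das, design$stress_start) - d0) +
    pmax(0, das - design$stress_end) * multiplier
}

# necrotic pixel mass accumulated after the stress ends (cold only)
accumulated_necrosis <- function(das, treatment, design, effect_px) {
  if (treatment == design$treatments[1]) return(rep(0, length(das)))
  frac <- pmin(1, pmax(0, (das - design$stress_end) / design$necrosis_lag))
  effect_px * frac
}

#' Simulate the true trait trajectory of one plant
#'
#' Evaluates the noiseless piecewise-linear growth model for a single
#' genotype under one treatment: every morphological trait grows linearly
#' at its genotype-scaled base rate, arrests completely during the cold
#' window, and resumes at the genotype's recovery multiplier afterwards.
#' Necrotic pixels are the misclassified-stem baseline (a fixed fraction
#' of area) plus, for cold-treated plants, a mass that accumulates
#' linearly over `necrosis_lag` days after the stress ends.
#'
#' @param genotype A single genotype row from the design's panel, or a
#'   genotype name to look up.
#' @param treatment One of the design's treatment labels.
#' @param design A [experiment_design()] object.
#' @return A tibble with one row per DAS and one column per trait, plus
#'   `healthy_px`, `necrotic_px` and `percent_necrosis`.
#' @export
simulate_trajectory <- function(genotype, treatment, design) {
  if (is.character(genotype)) {
    genotype <- design$genotypes[design$genotypes$genotype == genotype, ]
  }
  if (nrow(genotype) != 1L) abort("`genotype` must identify a single line")
  if (!treatment %in% design$treatments) {
    abort(sprintf("unknown treatment label '%s'", treatment),
          class = "coldpheno_unknown_treatment")
  }
  base <- trait_baselines()
  out <- tibble(das = design$das)
  for (i in seq_len(nrow(base))) {
    tr <- base$trait[i]
    mult <- switch(tr,
                   height_px = genotype$height_recovery_multiplier,
                   width_px = genotype$width_recovery_multiplier,
                   genotype$recovery_multiplier)
    g <- effective_growth(out$das, treatment, design, mult)
    out[[tr]] <- (base$start[i] + base$rate[i] * g) * genotype$growth_scale
  }
  nec <- accumulated_necrosis(out$das, treatment, design,
                              genotype$necrosis_effect_px)
  out$necrotic_px <- genotype$stem_misclass_rate * out$area_px + nec
  out$healthy_px <- out$area_px - out$necrotic_px
  out$percent_necrosis <- 100 * out$necrotic_px / out$area_px
  out
}

# enumerate the individual plants of a design (identity persists over days)
plant_registry <- function(design) {
  g <- design$genotypes
  grid <- tidyr::expand_grid(
    genotype = g$genotype,
    treatment = design$treatments,
    replicate = seq_len(design$replicates),
    plot_idx = seq_len(design$plots_per_treatment),
    pot = seq_len(design$plants_per_plot)
  )
  grid$plot <- sprintf("%s_%s_r%d_p%d", grid$genotype, grid$treatment,
                       grid$replicate, grid$plot_idx)
  grid$plant <- sprintf("%s_pot%d", grid$plot, grid$pot)
  grid
}

#' Simulate a full experiment in table-only mode
#'
#' Generates observed trait values for every plant and day of a design
#' without rendering any images: the true piecewise-linear trajectories
#' are scaled by a persistent per-plant size factor and perturbed with
#' per-observation Gaussian noise of sd `noise_frac` times the true
#' value. Necrotic counts follow the expected-fraction model (see
#' [experiment_design()]), so `percent_necrosis` of an unstressed plant
#' equals its genotype's misclassified-stem baseline.
#'
#' @param design A [experiment_design()] object.
#' @param noise If `FALSE`, emit the exact noiseless trajectories
#'   (equivalent to `noise_frac = 0`, `plant_scale_sd = 0`).
#' @return A wide tibble with one row per plant per day (columns
#'   `plant`, `plot`, `pot`, `genotype`, `archetype`, `treatment`,
#'   `replicate`, `das`, the 16 traits, `healthy_px`, `necrotic_px`,
#'   `percent_necrosis`). Pivot with [trait_observations()] for the
#'   long format used by the growth statistics.
#' @export
simulate_experiment <- function(design, noise = TRUE) {
  reg <- plant_registry(design)
  base <- trait_baselines()
  traits <- base$trait
  noise_frac <- if (isTRUE(noise)) design$noise_frac else 0
  scale_sd <- if (isTRUE(noise)) design$plant_scale_sd else 0
  nec_sd <- if (isTRUE(noise)) design$necrosis_noise_sd else 0

  withr::with_seed(design$seed, {
    reg$plant_scale <- pmax(0.3, rnorm(nrow(reg), 1, scale_sd))
    rows <- vector("list", nrow(reg))
    for (i in seq_len(nrow(reg))) {
      gt <- design$genotypes[design$genotypes$genotype == reg$genotype[i], ]
      true <- simulate_trajectory(gt, reg$treatment[i], design)
      nd <- nrow(true)
      obs <- tibble(
        plant = reg$plant[i], plot = reg$plot[i], pot = reg$pot[i],
        genotype = reg$genotype[i], archetype = gt$archetype,
        treatment = reg$treatment[i], replicate = reg$replicate[i],
        das = true$das
      )
      for (tr in traits) {
        v <- true[[tr]] * reg$plant_scale[i]
        obs[[tr]] <- v * (1 + rnorm(nd, 0, noise_frac))
      }
      # necrotic count derived from the *measured* area so the stem
      # baseline is an exact fraction; optional independent noise on top
      nec_true_frac <- true$necrotic_px / true$area_px
      nec <- nec_true_frac * obs$area_px
      if (nec_sd > 0) nec <- pmax(0, nec * (1 + rnorm(nd, 0, nec_sd)))
      nec <- pmin(nec, obs$area_px)
      obs$necrotic_px <- nec
      obs$healthy_px <- obs$area_px - nec
      obs$percent_necrosis <- 100 * nec / obs$area_px
      rows[[i]] <- obs
    }
  })
  dplyr::bind_rows(rows)
}

#' Pivot a wide plant-day table to long trait observations
#'
#' @param df Wide output of [simulate_experiment()] or
#'   [measure_experiment()].
#' @param traits Which value columns to keep (default: all trait columns
#'   present).
#' @return Long tibble with columns `trait` and `value`, one row per
#'   plant, day and trait.
#' @export
trait_observations <- function(df, traits = NULL) {
  known <- c(trait_baselines()$trait,
             "healthy_px", "necrotic_px", "percent_necrosis")
  traits <- traits %||% intersect(known, names(df))
  tidyr::pivot_longer(df, dplyr::all_of(traits),
                      names_to = "trait", values_to = "value")
}
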