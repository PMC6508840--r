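#' Define a synthetic cold-stress experiment
#'
#' Bundles the genotype panel with the assay schedule and the rendering /
#' noise configuration. The default schedule matches the assay the package
#' models: daily side-view imaging at 8–16 days after sowing (DAS, nine
#' time points), a 2-day cold stress starting at DAS 9 (so plants return
#' to warm conditions at DAS 11), necrotic tissue accumulating over the
#' 2 days following the stress, three biological replicates of two plots
#' (three plants each) per genotype and treatment (18 plants/group).
#'
#' Observation noise is Gaussian with sd `noise_frac` times the true
#' value, on top of a persistent per-plant size scale
#' (`plant_scale_sd`). Necrotic pixel counts follow the expected-fraction
#' model (misclassified stem tissue is a fixed genotype-specific fraction
#' of plant area); `necrosis_noise_sd` adds optional independent relative
#' noise to the necrotic count for calibration studies.
#'
#' @param genotypes Genotype tibble, see [genotype_panel()].
#' @param treatments Treatment labels; the second is the stressed group.
#' @param das_range Inclusive imaging window in days after sowing.
#' @param stress_start DAS at which stressed plants enter the cold.
#' @param stress_duration Days of cold (integer 1–4).
#' @param necrosis_lag Days over which necrotic pixels accumulate after
#'   the stress ends.
#' @param replicates Biological replicates (grow-outs).
#' @param plots_per_treatment Plots (images) per genotype, treatment and
#'   replicate.
#' @param plants_per_plot Seedlings per plot image (default 3).
#' @param noise_frac Relative sd of per-observation measurement noise.
#' @param plant_scale_sd sd of the per-plant size scale factor.
#' @param necrosis_noise_sd Independent relative sd on necrotic counts
#'   (default 0: counts are the expected fraction of measured area).
#' @param image Rendering configuration: width/height in px, the top row
#'   of the dark rack band, mean RGB of background, healthy and necrotic
#'   tissue, and their noise sds.
#' @param seed Integer master seed for all downstream randomness.
#' @return An object of class `cold_design`.
#' @export
experiment_design <- function(genotypes = genotype_panel(),
                              treatments = c("control", "cold"),
                              das_range = c(8L, 16L),
                              stress_start = 9L,
                              stress_duration = 2L,
                              necrosis_lag = 2L,
                              replicates = 3L,
                              plots_per_treatment = 2L,
                              plants_per_plot = 3L,
                              noise_frac = 0.1,
                              plant_scale_sd = 0.05,
                              necrosis_noise_sd = 0,
                              image = list(),
                              seed = 1L) {
  stopifnot(is.data.frame(genotypes), nrow(genotypes) >= 1)
  if (length(treatments) != 2L) abort("exactly two treatments are required")
  assert_count(stress_duration, "stress_duration")
  if (stress_duration > 4) abort("`stress_duration` must be 1-4 days")
  assert_count(replicates, "replicates")
  assert_count(plants_per_plot, "plants_per_plot")
  assert_count(plots_per_treatment, "plots_per_treatment")
  das <- seq(das_range[1], das_range[2])
  stress_end <- stress_start + stress_duration
  if (stress_start < das_range[1] || stress_end > das_range[2]) {
    abort("stress window must lie within `das_range`",
          class = "coldpheno_invalid_parameter")
  }

  img <- utils::modifyList(list(
    width = 270L, height = 180L, rack_top = 150L,
    background_mean = c(40, 70, 160), background_sd = 8,
    rack_mean = c(60, 60, 60), rack_sd = 3,
    healthy_mean = c(60, 140, 60), healthy_sd = 12,
    necrotic_mean = c(120, 90, 50), necrotic_sd = 12
  ), image)

  structure(list(
    genotypes = genotypes, treatments = treatments,
    das = das, stress_start = stress_start, stress_end = stress_end,
    stress_duration = stress_duration, necrosis_lag = necrosis_lag,
    replicates = replicates, plots_per_treatment = plots_per_treatment,
    plants_per_plot = plants_per_plot,
    noise_frac = noise_frac, plant_scale_sd = plant_scale_sd,
    necrosis_noise_sd = necrosis_noise_sd,
    image = img, seed = as.integer(seed)
  ), class = "cold_design")
}

#' @export
print.cold_design <- function(x, ...) {
  cat("<cold_design>\n")
  cat(sprintf("  genotypes: %d (%s)\n", nrow(x$genotypes),
              paste(unique(x$genotypes$archetype), collapse = ", ")))
  cat(sprintf("  DAS %d-%d; cold stress DAS %d-%d; necrosis lag %d d\n",
              min(x$das), max(x$das), x$stress_start, x$stress_end,
              x$necrosis_lag))
  cat(sprintf("  %d replicate(s) x %d plot(s) x %d plants per treatment\n",
              x$replicates, x$plots_per_treatment, x$plants_per_plot))
  cat(sprintf("  noise_frac %.3g, plant_scale_sd %.3g, seed %d\n",
              x$noise_frac, x$plant_scale_sd, x$seed))
  invisible(x)
}
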