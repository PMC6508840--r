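# growth-rate statistics: time-shift alignment, per-plant regression
# slopes, group rate aggregation and log2 fold changes between treatments

#' Default growth-rate intervals on the time-shifted axis
#'
#' Early recovery spans aligned DAS 9–11 (cold-treated plants' DAS
#' 11–13) and late recovery aligned DAS 11–14 (cold DAS 13–16).
#'
#' @return Tibble with columns `interval`, `start`, `end`.
#' @export
default_intervals <- function() {
  tibble(interval = c("early_recovery", "late_recovery"),
         start = c(9, 11), end = c(11, 14))
}

#' Align cold-treated observations to control time
#'
#' Because stressed plants do not grow during the cold window, a
#' cold-treated plant is developmentally comparable to a control plant
#' imaged `shift_days` earlier. Cold observations get
#' `aligned_das = das - shift_days`; control observations keep their
#' day. Records whose aligned day falls outside the control day range
#' are dropped (their count is reported via a message).
#'
#' @param df Long observation table with columns `treatment` and `das`
#'   (e.g. from [trait_observations()]).
#' @param shift_days Non-negative shift (default 2, the stress length).
#' @param cold_label Treatment label to shift (default `"cold"`).
#' @return The table with an `aligned_das` column, shifted rows
#'   outside the control range removed.
#' @export
time_shift <- function(df, shift_days = 2, cold_label = "cold") {
  if (shift_days < 0) abort("`shift_days` must be >= 0")
  df$aligned_das <- ifelse(df$treatment == cold_label,
                           df$das - shift_days, df$das)
  ctrl <- df$das[df$treatment != cold_label]
  rng <- if (length(ctrl)) range(ctrl) else range(df$aligned_das)
  keep <- df$aligned_das >= rng[1] & df$aligned_das <= rng[2]
  if (any(!keep)) {
    inform(sprintf("time_shift: dropped %d record(s) outside aligned range %d-%d",
                   sum(!keep), rng[1], rng[2]))
  }
  df[keep, , drop = FALSE]
}

# OLS slope by QR; two or more distinct x required (checked by caller)
ols_slope <- function(x, y) {
  stats::.lm.fit(cbind(1, x), y)$coefficients[2]
}

#' Per-plant regression slopes within intervals
#'
#' For every plant, trait and interval, the ordinary least-squares slope
#' of value on aligned day. Plants with fewer than two distinct days in
#' an interval are excluded from that interval (a message reports how
#' many).
#'
#' @param df Long observation table with `aligned_das` (see
#'   [time_shift()]; plain `das` is used with a message if the column is
#'   absent), `plant`, `genotype`, `treatment`, `replicate`, `trait`,
#'   `value`.
#' @param intervals Interval table, see [default_intervals()]. Windows
#'   are inclusive.
#' @return Tibble of slopes: one row per plant, trait and interval.
#' @export
plant_slopes <- function(df, intervals = default_intervals()) {
  if (!"aligned_das" %in% names(df)) {
    inform("plant_slopes: no `aligned_das` column; using `das` unshifted")
    df$aligned_das <- df$das
  }
  out <- purrr::map_dfr(seq_len(nrow(intervals)), function(i) {
    win <- df[df$aligned_das >= intervals$start[i] &
                df$aligned_das <= intervals$end[i], ]
    win$interval <- intervals$interval[i]
    win
  })
  grouped <- dplyr::group_by(out, .data$plant, .data$genotype,
                             .data$treatment, .data$replicate,
                             .data$trait, .data$interval)
  slopes <- dplyr::summarise(
    grouped,
    n_obs = dplyr::n_distinct(.data$aligned_das),
    slope = if (dplyr::n_distinct(.data$aligned_das) >= 2) {
      ols_slope(.data$aligned_das, .data$value)
    } else NA_real_,
    .groups = "drop")
  n_missing <- sum(is.na(slopes$slope))
  if (n_missing > 0) {
    inform(sprintf(
      "plant_slopes: %d plant-interval(s) with < 2 time points excluded",
      n_missing))
  }
  slopes[!is.na(slopes$slope), , drop = FALSE]
}

#' Aggregate plant slopes into group growth rates
#'
#' Arithmetic mean and standard error of the per-plant slopes for every
#' genotype, treatment, trait and interval. Empty groups are absent,
#' never zero; single-plant groups report a missing standard error.
#'
#' @param slopes Output of [plant_slopes()].
#' @return Tibble with `mean_slope`, `se`, `n_plants` per group.
#' @export
aggregate_rates <- function(slopes) {
  grouped <- dplyr::group_by(slopes, .data$genotype, .data$treatment,
                             .data$trait, .data$interval)
  dplyr::summarise(grouped,
                   mean_slope = mean(.data$slope),
                   se = if (dplyr::n() > 1) {
                     sd(.data$slope) / sqrt(dplyr::n())
                   } else NA_real_,
                   n_plants = dplyr::n(),
                   .groups = "drop")
}

#' Log2 fold change in growth rate between treatments
#'
#' `log2(max(cold, epsilon) / max(control, epsilon))` per genotype,
#' trait and interval. Clipping at `epsilon` keeps zero or negative
#' rates (growth arrest, shrinkage artifacts) in the matrix; such
#' records carry `clipped = TRUE`.
#'
#' @param rates Output of [aggregate_rates()].
#' @param epsilon Positive clipping constant in trait units per day
#'   (default 0.01).
#' @param cold_label,control_label Treatment labels.
#' @return Tibble with `log2fc`, `clipped`, and both group rates.
#' @export
log2_fold_change <- function(rates, epsilon = 0.01, cold_label = "cold",
                             control_label = "control") {
  if (epsilon <= 0) abort("`epsilon` must be positive",
                          class = "coldpheno_invalid_parameter")
  wide <- tidyr::pivot_wider(
    rates[c("genotype", "treatment", "trait", "interval", "mean_slope")],
    names_from = "treatment", values_from = "mean_slope")
  wide <- wide[!is.na(wide[[cold_label]]) & !is.na(wide[[control_label]]), ]
  tibble(
    genotype = wide$genotype, trait = wide$trait, interval = wide$interval,
    cold_rate = wide[[cold_label]], control_rate = wide[[control_label]],
    log2fc = log2(pmax(wide[[cold_label]], epsilon) /
                    pmax(wide[[control_label]], epsilon)),
    clipped = wide[[cold_label]] < epsilon | wide[[control_label]] < epsilon
  )
}

#' Correlation structure of fold-change features
#'
#' Pearson correlation, across genotypes, between every pair of
#' trait-by-interval fold-change vectors. Zero-variance features yield
#' missing correlations.
#'
#' @param folds Output of [log2_fold_change()] (>= 3 genotypes).
#' @return A symmetric correlation matrix with unit diagonal, features
#'   as `trait.interval`.
#' @export
trait_interval_correlation <- function(folds) {
  wide <- tidyr::pivot_wider(
    dplyr::mutate(folds,
                  feature = paste(.data$trait, .data$interval, sep = ".")),
    id_cols = "genotype", names_from = "feature", values_from = "log2fc")
  if (nrow(wide) < 3) abort("at least 3 genotypes are required")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$genotype
  cc <- suppressWarnings(cor(m))
  diag(cc) <- 1
  cc
}
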