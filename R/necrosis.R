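# single-day necrosis comparison between treatments within genotype

#' Per-genotype necrosis ANOVA with Tukey HSD
#'
#' For each genotype, a one-way ANOVA of percent necrosis across
#' treatment groups at a single day, followed by a post-hoc Tukey HSD
#' adjusted p-value for the cold-vs-control contrast. A genotype is
#' called significant only for an *increase*: adjusted p <= `alpha` and
#' cold mean above control mean. Because necrosis peaks and then
#' declines predictably, a single assessment day (default 13 DAS, two
#' days after the default stress ends) stands in for the full time
#' course.
#'
#' Genotypes with fewer than two plants in a treatment group are skipped
#' with a warning. Groups that are identical (zero variance overall) are
#' never significant.
#'
#' @param df Long observation table containing `percent_necrosis` rows.
#' @param day Assessment day (DAS).
#' @param alpha Significance level for the adjusted p-value.
#' @param trait Trait name carrying percent necrosis.
#' @param cold_label,control_label Treatment labels.
#' @return Tibble with one row per tested genotype: group sizes and
#'   means, `p_adj`, `significant`.
#' @export
necrosis_test <- function(df, day = 13, alpha = 0.05,
                          trait = "percent_necrosis",
                          cold_label = "cold", control_label = "control") {
  sub <- df[df$das == day & df$trait == trait, ]
  if (!nrow(sub)) abort(sprintf("no '%s' records at day %s", trait, day))
  purrr::map_dfr(split(sub, sub$genotype), function(g) {
    n_ctrl <- sum(g$treatment == control_label)
    n_cold <- sum(g$treatment == cold_label)
    if (n_ctrl < 2 || n_cold < 2) {
      warn(sprintf("genotype %s skipped: < 2 plants in a treatment group",
                   g$genotype[1]))
      return(NULL)
    }
    ctrl_mean <- mean(g$value[g$treatment == control_label])
    cold_mean <- mean(g$value[g$treatment == cold_label])
    tot_var <- var(g$value)
    scale <- mean(g$value)^2 + 1
    if (tot_var < 1e-12 * scale) {
      p_adj <- 1                                   # identical groups
    } else {
      fit <- aov(value ~ treatment, data = transform(g,
        treatment = factor(treatment, levels = c(control_label, cold_label))))
      resid_var <- sum(fit$residuals^2)
      if (resid_var < 1e-12 * scale * nrow(g)) {
        p_adj <- 0                 # groups constant but means differ
      } else {
        tk <- TukeyHSD(fit)$treatment
        p_adj <- tk[1, "p adj"]
      }
    }
    tibble(genotype = g$genotype[1], n_control = n_ctrl, n_cold = n_cold,
           control_mean = ctrl_mean, cold_mean = cold_mean, p_adj = p_adj,
           significant = p_adj <= alpha & cold_mean > ctrl_mean)
  })
}

#' Necrosis feature for the phingerprint matrix
#'
#' Cold-minus-control mean percent necrosis at the assessment day, one
#' value per genotype. A difference (not a log ratio) because control
#' necrosis can be arbitrarily close to zero.
#'
#' @inheritParams necrosis_test
#' @return Tibble with columns `genotype`, `feature`, `value`.
#' @export
necrosis_summary <- function(df, day = 13, trait = "percent_necrosis",
                             cold_label = "cold",
                             control_label = "control") {
  sub <- df[df$das == day & df$trait == trait, ]
  grouped <- dplyr::group_by(sub, .data$genotype)
  dplyr::summarise(grouped,
                   feature = sprintf("necrosis_d%d", as.integer(day)),
                   value = mean(.data$value[.data$treatment == cold_label]) -
                     mean(.data$value[.data$treatment == control_label]),
                   .groups = "drop")
}
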