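#' Feature-selection recovery experiment
#'
#' Generates a synthetic 153-feature panel in which exactly 109 features
#' carry component-dependent mean shifts of 2 standard deviations (the
#' remaining 44 are pure noise) for six conditions (control, two
#' chemotherapies, three perturbations) with a fixed, well-separated
#' subpopulation mixing-weight design — each condition is dominated by a
#' distinct pair of the nine components, so the between-condition signal is
#' a property of the experiment rather than of the run seed. The
#' permutation-filtered SVM selection is then run on the live cells and the
#' number of retained features is reported.
#'
#' @param seed integer seed for all random draws.
#' @param cells_per_condition cells simulated per condition (default 500).
#' @param alpha selection significance level.
#' @param B number of label permutations.
#' @return list: `n_retained`, `n_true_informative` (109), `n_cells`,
#'   `selection` (the full `feature_selection` object), `truth`.
#' @export
selection_recovery_experiment <- function(seed = 1L, cells_per_condition = 500,
                                          alpha = 0.05, B = 200) {
  design <- panel_design(
    chemotherapies = c("EPI", "CIS"),
    perturbations = c("RAP", "ACI", "PDMP"),
    include_doubles = FALSE,
    time_points_h = 48,
    cells_per_condition = cells_per_condition,
    n_features = 153, n_informative = 109, n_subpopulations = 9,
    seed = seed
  )
  conds <- panel_conditions(design)
  k <- design$n_subpopulations
  weights <- t(vapply(seq_along(conds), function(c) {
    w <- rep(0.05, k)
    w[((c - 1) %% k) + 1] <- w[((c - 1) %% k) + 1] + 0.30
    w[((c + 2) %% k) + 1] <- w[((c + 2) %% k) + 1] + 0.25
    w / sum(w)
  }, numeric(k)))
  rownames(weights) <- conds
  panel <- generate_feature_panel(design, weights = weights)
  live <- filter(panel$cells, .data$alive)
  std <- standardize_features(live)
  ranking <- rank_features_svm(std)
  sel <- select_features(ranking, std, alpha = alpha, B = B, seed = seed)
  list(
    n_retained = length(attr(sel, "selected")),
    n_true_informative = design$n_informative,
    n_cells = nrow(live),
    selection = sel,
    truth = panel$truth
  )
}

#' Subpopulation-number recovery experiment
#'
#' Generates the default perturbation panel (3 chemotherapies, 12
#' perturbations, all doubles, control) at the 48 h snapshot with nine
#' planted, well-separated live-cell subpopulations, and runs the MANOVA +
#' likelihood component-number selection over `k_range` on the standardized
#' live-cell features.
#'
#' @param seed integer seed.
#' @param cells_per_condition cells per condition (default 100; with the 52
#'   default conditions this yields a merged set of roughly 3500-4000 live
#'   cells).
#' @param k_range candidate component numbers.
#' @return list: `k_chosen`, `k_planted` (9), `n_cells`, `selection` (the
#'   full `sl_gmm_selection`), `truth`.
#' @export
component_recovery_experiment <- function(seed = 1L, cells_per_condition = 100,
                                          k_range = 1:12) {
  design <- panel_design(
    time_points_h = 48,
    cells_per_condition = cells_per_condition,
    n_subpopulations = 9,
    seed = seed
  )
  panel <- generate_feature_panel(design)
  live <- filter(panel$cells, .data$alive)
  std <- standardize_features(live)
  sel <- select_component_number(std, k_range = k_range, seed = seed)
  list(
    k_chosen = sel$k,
    k_planted = design$n_subpopulations,
    n_cells = nrow(live),
    selection = sel,
    truth = panel$truth
  )
}
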