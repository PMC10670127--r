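#' Experimental cytotoxicity percentage
#'
#' Cytotoxicity is the percentage of dead cells among all cells:
#' `100 * dead / total`.
#'
#' @param dead,total non-negative integer counts with `0 <= dead <= total`,
#'   `total > 0`. Vectorized.
#' @return cytotoxicity percentage in `[0, 100]`.
#' @export
compute_cytotoxicity <- function(dead, total) {
  if (any(total <= 0)) abort("total cell count must be positive")
  if (any(dead < 0) || any(dead > total)) {
    abort("dead cell count must satisfy 0 <= dead <= total")
  }
  100 * dead / total
}

#' Experimental viability percentage
#'
#' The complement of cytotoxicity: `100 - cytotoxicity`.
#'
#' @param cytotoxicity_pct percentage in `[0, 100]`. Vectorized.
#' @return viability percentage in `[0, 100]`.
#' @export
compute_viability <- function(cytotoxicity_pct) {
  if (any(cytotoxicity_pct < 0 | cytotoxicity_pct > 100)) {
    abort("cytotoxicity percentage must lie in [0, 100]")
  }
  100 - cytotoxicity_pct
}

#' Expected viability of a double treatment under independence
#'
#' Bliss-style expectation: the product of the single-treatment viability
#' percentages divided by 100. Always bounded above by the smaller single
#' viability, with equality only when the other is 100.
#'
#' @param v1_pct,v2_pct single-treatment viability percentages in `[0, 100]`.
#' @return expected combined viability percentage. Vectorized.
#' @export
expected_viability <- function(v1_pct, v2_pct) {
  if (any(v1_pct < 0 | v1_pct > 100) || any(v2_pct < 0 | v2_pct > 100)) {
    abort("viability percentages must lie in [0, 100]")
  }
  v1_pct * v2_pct / 100
}

#' Score a double treatment against its Bliss expectation
#'
#' The double interaction is the expected minus the experimental viability
#' (percentage points); the interaction ratio is that difference divided by
#' 100 (fold scale). The reported ratio is rounded half-up to one decimal
#' and classified: positive = synergism, negative = antagonism, zero = no
#' interaction.
#'
#' @param expected_pct,experimental_pct viability percentages in `[0, 100]`.
#' @return tibble with `double_interaction_pct`, `interaction_ratio` (raw),
#'   `interaction_ratio_rounded` and `interaction_class`. Vectorized.
#' @export
interaction_score <- function(expected_pct, experimental_pct) {
  if (any(expected_pct < 0 | expected_pct > 100) ||
      any(experimental_pct < 0 | experimental_pct > 100)) {
    abort("viability percentages must lie in [0, 100]")
  }
  double_pct <- expected_pct - experimental_pct
  ratio <- double_pct / 100
  rounded <- round_half_up(ratio, 1)
  tibble(
    double_interaction_pct = double_pct,
    interaction_ratio = ratio,
    interaction_ratio_rounded = rounded,
    interaction_class = dplyr::case_when(
      rounded > 0 ~ "synergism",
      rounded < 0 ~ "antagonism",
      TRUE ~ "no_interaction"
    )
  )
}

#' Per-condition viability estimates from single-cell records
#'
#' Counts dead and total cells per condition at one imaging time point
#' (viability is computed from nuclei counts, i.e. one row per cell record)
#' and applies the cytotoxicity/viability equations.
#'
#' @param cells data frame with columns `condition`, `time_h` and logical
#'   `alive` (one row per cell), e.g. from [generate_feature_panel()] or
#'   [extract_features()] joined to conditions.
#' @param time_h snapshot time in hours (default 48).
#' @return tibble: `condition`, `time_h`, `dead_cells`, `total_cells`,
#'   `cytotoxicity_pct`, `viability_pct`.
#' @export
viability_table <- function(cells, time_h = 48) {
  if (!all(c("condition", "alive") %in% names(cells))) {
    abort("cells must have `condition` and `alive` columns")
  }
  if ("time_h" %in% names(cells)) {
    cells <- cells %>% filter(.data$time_h == !!time_h)
    if (nrow(cells) == 0) abort(sprintf("no cells at time point %s h", time_h))
  }
  cells %>%
    group_by(.data$condition) %>%
    summarise(dead_cells = sum(!.data$alive), total_cells = n(),
              .groups = "drop") %>%
    mutate(
      time_h = time_h,
      cytotoxicity_pct = compute_cytotoxicity(.data$dead_cells, .data$total_cells),
      viability_pct = compute_viability(.data$cytotoxicity_pct)
    ) %>%
    select("condition", "time_h", "dead_cells", "total_cells",
           "cytotoxicity_pct", "viability_pct")
}

#' Chemotherapy x perturbation interaction matrix
#'
#' For every double condition `"CHEMO-PERT"` present in the viability table,
#' computes the Bliss expected viability from the two single conditions and
#' scores the interaction. Both singles must be present; a missing single is
#' an explicit error naming the missing control.
#'
#' @param viability tibble from [viability_table()] (or with at least
#'   `condition` and `viability_pct` columns).
#' @param chemotherapies,perturbations optional label vectors restricting
#'   which doubles are scored; defaults to every double found in the table.
#' @return object of class `interaction_scores`: a tibble with one row per
#'   (chemo, perturbation) pair carrying single viabilities, expected and
#'   experimental viability, double interaction, raw and rounded ratio, and
#'   the interaction class.
#' @export
build_interaction_matrix <- function(viability, chemotherapies = NULL,
                                     perturbations = NULL) {
  v <- setNames(viability$viability_pct, viability$condition)
  doubles <- grep("-", viability$condition, value = TRUE, fixed = TRUE)
  parts <- strsplit(doubles, "-", fixed = TRUE)
  pairs <- tibble(
    chemo = vapply(parts, `[`, character(1), 1),
    perturbation = vapply(parts, `[`, character(1), 2),
    condition = doubles
  )
  if (!is.null(chemotherapies)) pairs <- filter(pairs, .data$chemo %in% chemotherapies)
  if (!is.null(perturbations)) pairs <- filter(pairs, .data$perturbation %in% perturbations)
  if (nrow(pairs) == 0) abort("no double conditions to score")
  missing <- setdiff(unique(c(pairs$chemo, pairs$perturbation)), names(v))
  if (length(missing)) {
    abort(sprintf("missing single-treatment control(s): %s",
                  paste(missing, collapse = ", ")),
          class = "slsynergy_missing_control")
  }
  scores <- interaction_score(
    expected_viability(v[pairs$chemo], v[pairs$perturbation]),
    v[pairs$condition]
  )
  out <- dplyr::bind_cols(
    pairs %>% select("chemo", "perturbation"),
    tibble(
      single_viability_1_pct = unname(v[pairs$chemo]),
      single_viability_2_pct = unname(v[pairs$perturbation]),
      expected_viability_pct = expected_viability(v[pairs$chemo], v[pairs$perturbation]),
      experimental_viability_pct = unname(v[pairs$condition])
    ),
    scores
  )
  structure(out, class = c("interaction_scores", class(out)))
}

#' Wide interaction-ratio matrix (chemotherapies x perturbations)
#'
#' @param scores an `interaction_scores` tibble.
#' @return numeric matrix of rounded interaction ratios, rows =
#'   chemotherapies, columns = perturbations.
#' @export
interaction_matrix_wide <- function(scores) {
  w <- scores %>%
    select("chemo", "perturbation", "interaction_ratio_rounded") %>%
    tidyr::pivot_wider(names_from = "perturbation",
                       values_from = "interaction_ratio_rounded")
  m <- as.matrix(w[, -1])
  rownames(m) <- w$chemo
  m
}

#' Write interaction results to CSV
#'
#' Writes the wide rounded-ratio matrix and the long table with class labels.
#'
#' @param scores an `interaction_scores` tibble.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_interaction_matrix <- function(scores, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wide <- file.path(dir, "interaction_matrix.csv")
  long <- file.path(dir, "interaction_scores.csv")
  utils::write.csv(interaction_matrix_wide(scores), wide)
  utils::write.csv(as.data.frame(scores), long, row.names = FALSE)
  invisible(c(wide, long))
}
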