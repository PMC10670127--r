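#' Default drug labels of the perturbation panel
#'
#' Three chemotherapies (EPI epirubicin, CIS cisplatin, PAC paclitaxel),
#' eight sphingolipid-pathway enzyme inhibitors (SKI sphingosine kinase,
#' PDMP glucosylceramide synthase, DES desipramine (acid sphingomyelinase and
#' acid ceramidase), NCI neutral/alkaline ceramidase, D609 sphingomyelin
#' synthase, ACI acid ceramidase, GW neutral sphingomyelinase, MYR myriocin
#' (serine palmitoyltransferase)) and four autophagy modulators (RAP
#' rapamycin, HCQ hydroxychloroquine, SPA spautin, TOR torin).
#'
#' @return named list with elements `chemotherapies`, `sl_inhibitors`,
#'   `autophagy_modulators`, `perturbations` (inhibitors + modulators).
#' @export
default_drug_panel <- function() {
  chemo <- c("EPI", "CIS", "PAC")
  sl <- c("SKI", "PDMP", "DES", "NCI", "D609", "ACI", "GW", "MYR")
  auto <- c("RAP", "HCQ", "SPA", "TOR")
  list(
    chemotherapies = chemo,
    sl_inhibitors = sl,
    autophagy_modulators = auto,
    perturbations = c(sl, auto)
  )
}

#' Design of a synthetic perturbation panel
#'
#' Describes the experimental layout the synthetic generator emulates: an
#' A549-like monolayer treated with chemotherapies, sphingolipid-pathway
#' inhibitors and autophagy modulators (all singles, optionally all
#' chemotherapy x perturbation doubles, plus an untreated control), imaged at
#' regular intervals, with a latent Gaussian subpopulation structure shared
#' across conditions.
#'
#' @param chemotherapies character vector of chemotherapy labels.
#' @param perturbations character vector of perturbation labels (inhibitors
#'   and autophagy modulators).
#' @param include_doubles add every chemotherapy-perturbation double?
#' @param time_points_h strictly increasing non-negative imaging times (hours).
#' @param cells_per_condition cells simulated per condition and time point.
#' @param n_features number of per-cell features (default 153).
#' @param n_informative number of features carrying between-subpopulation
#'   signal (default 109); the remainder are pure noise.
#' @param n_subpopulations number of latent live-cell subpopulations (k).
#' @param effect_size scale (in within-component standard deviations) of
#'   component-dependent mean shifts on informative features.
#' @param seed integer seed controlling every random draw.
#' @return object of class `panel_design`.
#' @export
panel_design <- function(chemotherapies = default_drug_panel()$chemotherapies,
                         perturbations = default_drug_panel()$perturbations,
                         include_doubles = TRUE,
                         time_points_h = seq(0, 72, by = 6),
                         cells_per_condition = 100,
                         n_features = 153,
                         n_informative = min(109L, n_features),
                         n_subpopulations = 9,
                         effect_size = 2,
                         seed = 1L) {
  labels <- c(chemotherapies, perturbations)
  if (anyDuplicated(labels)) abort("drug labels must be unique")
  if (any(diff(time_points_h) <= 0)) abort("time points must be strictly increasing")
  if (any(time_points_h < 0)) abort("time points must be non-negative")
  if (n_subpopulations < 1) abort("n_subpopulations must be >= 1")
  if (cells_per_condition < 1) abort("cells_per_condition must be positive")
  if (n_informative > n_features) {
    abort("number of informative features cannot exceed n_features")
  }
  structure(
    list(
      chemotherapies = chemotherapies,
      perturbations = perturbations,
      include_doubles = isTRUE(include_doubles),
      time_points_h = as.numeric(time_points_h),
      cells_per_condition = as.integer(cells_per_condition),
      n_features = as.integer(n_features),
      n_informative = as.integer(n_informative),
      n_subpopulations = as.integer(n_subpopulations),
      effect_size = effect_size,
      seed = as.integer(seed)
    ),
    class = "panel_design"
  )
}

#' @export
print.panel_design <- function(x, ...) {
  cat("<panel_design>\n")
  cat("  chemotherapies:", paste(x$chemotherapies, collapse = ", "), "\n")
  cat("  perturbations: ", paste(x$perturbations, collapse = ", "), "\n")
  cat("  conditions:    ", length(panel_conditions(x)),
      if (x$include_doubles) "(with doubles)" else "(singles only)", "\n")
  cat("  time points:   ", paste(x$time_points_h, collapse = ", "), "h\n")
  cat(sprintf("  %d cells/condition, %d features (%d informative), k = %d, seed = %d\n",
              x$cells_per_condition, x$n_features, x$n_informative,
              x$n_subpopulations, x$seed))
  invisible(x)
}

#' Condition labels of a panel design
#'
#' The control condition, every single treatment, and (if enabled) every
#' chemotherapy-perturbation double written as `"CHEMO-PERT"`.
#'
#' @param design a [panel_design()].
#' @param control label used for the untreated control.
#' @return character vector of condition labels.
#' @export
panel_conditions <- function(design, control = "CTRL") {
  singles <- c(design$chemotherapies, design$perturbations)
  doubles <- character(0)
  if (design$include_doubles) {
    doubles <- as.vector(outer(design$chemotherapies, design$perturbations,
                               paste, sep = "-"))
  }
  c(control, singles, doubles)
}

#' Split a condition label into its constituent treatments
#'
#' @param condition character vector of condition labels (`"EPI"`,
#'   `"EPI-RAP"`, `"CTRL"`).
#' @return list of character vectors of treatment labels (empty for control).
#' @export
condition_parts <- function(condition) {
  lapply(strsplit(condition, "-", fixed = TRUE), function(p) p[p != "CTRL"])
}

#' Canonical per-cell feature names
#'
#' The default 153-feature taxonomy spans intensity (4 channels x 2 regions x
#' 9 statistics = 72), texture (4 channels x 13 Haralick co-occurrence
#' statistics + 2 granularity scales = 60) and morphology (nucleus and cell
#' shape, 10 each, plus the nucleus/cell area ratio = 21). Names are stable
#' across the generator and the image feature extractor.
#'
#' @param n_features how many names to return; the canonical list holds 153,
#'   shorter requests truncate it and longer ones append generic noise
#'   feature names.
#' @return character vector of length `n_features`.
#' @export
feature_names <- function(n_features = 153) {
  channels <- c("hoechst", "pi", "gfp", "mcherry")
  regions <- c("nuc", "cell")
  int_stats <- c("mean", "sd", "median", "mad", "q10", "q90", "min", "max", "integrated")
  intensity <- as.vector(outer(
    as.vector(outer(channels, regions, paste, sep = "_")),
    int_stats, paste, sep = "_"
  ))
  intensity <- paste0("int_", intensity)
  haralick <- c("asm", "con", "cor", "var", "idm", "sav", "sva", "sen",
                "ent", "dva", "den", "f12", "f13")
  texture <- c(
    paste0("tex_", as.vector(outer(channels, haralick, paste, sep = "_"))),
    paste0("tex_", as.vector(outer(channels, c("gran_s", "gran_l"), paste, sep = "_")))
  )
  shape_stats <- c("area", "perimeter", "form_factor", "eccentricity",
                   "major_axis", "minor_axis", "aspect_ratio",
                   "equiv_diameter", "extent", "radius_mean")
  morphology <- c(
    paste0("mor_", as.vector(outer(c("nuc", "cell"), shape_stats, paste, sep = "_"))),
    "mor_nuc_cell_area_ratio"
  )
  canonical <- c(intensity, texture, morphology)
  stopifnot(length(canonical) == 153L)
  if (n_features <= length(canonical)) {
    canonical[seq_len(n_features)]
  } else {
    c(canonical, sprintf("feature_%04d", seq_len(n_features - length(canonical)) + 153L))
  }
}
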