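#' Planted interaction ratios of the default synthetic panel
#'
#' The synthetic generator plants a chemotherapy x perturbation interaction
#' structure emulating the pattern observed in the A549 study system:
#' epirubicin synergizes strongly with the autophagy inducers (RAP 0.5,
#' TOR 0.4) and the ceramidase inhibitors (ACI 0.4, NCI 0.3), weakly with the
#' remaining perturbations, and shows no interaction with PDMP; cisplatin's
#' main synergy is with NCI (0.3) and it shows no interaction with D609;
#' paclitaxel is mostly antagonistic (strongest -0.4 with SPA) with weak
#' synergies only with DES (0.2) and GW (0.1).
#'
#' @return tibble with columns `chemo`, `perturbation`, `ratio` (planted
#'   interaction ratio on the fold scale of (expected - experimental)/100).
#' @export
default_interaction_ratios <- function() {
  p <- default_drug_panel()
  ratio <- rbind(
    EPI = c(SKI = 0.1, PDMP = 0.0, DES = 0.1, NCI = 0.3, D609 = 0.1,
            ACI = 0.4, GW = 0.1, MYR = 0.1, RAP = 0.5, HCQ = 0.2,
            SPA = 0.2, TOR = 0.4),
    CIS = c(SKI = 0.1, PDMP = 0.1, DES = 0.1, NCI = 0.3, D609 = 0.0,
            ACI = 0.1, GW = 0.1, MYR = 0.1, RAP = 0.1, HCQ = 0.1,
            SPA = 0.1, TOR = 0.1),
    PAC = c(SKI = -0.1, PDMP = -0.2, DES = 0.2, NCI = -0.1, D609 = -0.2,
            ACI = -0.1, GW = 0.1, MYR = -0.1, RAP = -0.2, HCQ = -0.1,
            SPA = -0.4, TOR = -0.2)
  )
  tidyr::expand_grid(chemo = p$chemotherapies, perturbation = p$perturbations) %>%
    mutate(ratio = ratio[cbind(.data$chemo, .data$perturbation)])
}

#' Planted single-treatment viabilities (percent, at the 48 h reference time)
#'
#' Chemotherapies reduce viability substantially; inhibitors and modulators
#' are mildly toxic on their own. EPI (74) and RAP (90) give an expected
#' Bliss viability of 66.6 percent for the double.
#'
#' Single viabilities are chosen so every planted double stays inside
#' `[0, 100]`: in particular PAC (70) and SPA (80) leave headroom for their
#' planted -0.4 antagonism (expected 56% + 40 points = 96%).
#'
#' @return named numeric vector of viability percentages, including `CTRL`.
#' @export
default_single_viability <- function() {
  c(CTRL = 95, EPI = 74, CIS = 70, PAC = 70,
    SKI = 90, PDMP = 90, DES = 88, NCI = 85, D609 = 90, ACI = 87,
    GW = 90, MYR = 90, RAP = 90, HCQ = 88, SPA = 80, TOR = 90)
}

# viability (%) planted for a condition at the 48 h reference time
planted_viability_48 <- function(condition) {
  singles <- default_single_viability()
  ratios <- default_interaction_ratios()
  vapply(condition, function(cond) {
    parts <- condition_parts(cond)[[1]]
    if (length(parts) == 0) return(unname(singles["CTRL"]))
    if (length(parts) == 1) {
      if (!parts %in% names(singles)) return(90)
      return(unname(singles[parts]))
    }
    v1 <- if (parts[1] %in% names(singles)) singles[parts[1]] else 90
    v2 <- if (parts[2] %in% names(singles)) singles[parts[2]] else 90
    expected <- v1 * v2 / 100
    r <- ratios$ratio[ratios$chemo == parts[1] & ratios$perturbation == parts[2]]
    if (length(r) == 0) r <- 0
    max(min(expected - 100 * r, 100), 1)
  }, numeric(1))
}

# death fraction in [0, 0.95]; accrues linearly to the planted 48 h value and
# keeps growing at the same rate afterwards
planted_death_fraction <- function(condition, time_h, reference_h = 48) {
  df48 <- 1 - planted_viability_48(condition) / 100
  pmin(pmax(df48 * time_h / reference_h, 0), 0.95)
}

#' Planted mean puncta (vesicle) counts per cell
#'
#' Emulates autophagosome accumulation: baseline ~2 puncta/cell, autophagy
#' inducers (RAP, TOR) ~6, chemotherapy doubles with an inducer ~12.
#'
#' @param condition character vector of condition labels.
#' @return numeric vector of per-cell mean puncta counts.
#' @export
planted_puncta_mean <- function(condition) {
  inducers <- c("RAP", "TOR")
  vapply(condition, function(cond) {
    parts <- condition_parts(cond)[[1]]
    if (length(parts) == 0) return(2)
    if (length(parts) == 1) return(if (parts %in% inducers) 6 else 2)
    if (any(parts %in% inducers)) 12 else 2.5
  }, numeric(1))
}

# profile archetype id for a condition; conditions sharing an archetype get
# near-identical subpopulation mixing weights (emulates the co-clustering of
# EPI/ACI/NCI, CIS/PDMP, RAP/TOR and HCQ/SPA heterogeneity profiles)
profile_archetype <- function(condition) {
  groups <- list(
    grpA = c("EPI", "ACI", "NCI"),
    grpB = c("CIS", "PDMP"),
    grpC = c("RAP", "TOR"),
    grpD = c("HCQ", "SPA")
  )
  vapply(condition, function(cond) {
    for (g in names(groups)) if (cond %in% groups[[g]]) return(g)
    cond
  }, character(1))
}

rdirichlet1 <- function(k) {
  g <- stats::rgamma(k, shape = 1)
  g / sum(g)
}
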