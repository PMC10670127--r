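# small shared fixtures; everything generated in code at test time

small_design <- function(k = 3, cells = 60, n_features = 12, n_informative = 8,
                         seed = 42, ...) {
  panel_design(
    chemotherapies = c("EPI", "CIS"),
    perturbations = c("RAP", "ACI"),
    include_doubles = FALSE,
    time_points_h = 48,
    cells_per_condition = cells,
    n_features = n_features,
    n_informative = n_informative,
    n_subpopulations = k,
    seed = seed,
    ...
  )
}

# planted profile matrix emulating the co-clustering groups: within-group
# distance <= 0.05, between-group >= 0.4
planted_group_profiles <- function() {
  base <- rbind(
    A = c(0.55, 0.20, 0.05, 0.05, 0.05, 0.10),
    B = c(0.05, 0.05, 0.55, 0.20, 0.05, 0.10),
    C = c(0.10, 0.05, 0.05, 0.55, 0.20, 0.05),
    D = c(0.20, 0.55, 0.05, 0.05, 0.10, 0.05),
    E = c(0.05, 0.10, 0.20, 0.05, 0.55, 0.05)
  )
  assign <- c(EPI = "A", ACI = "A", NCI = "A",
              CIS = "B", PDMP = "B",
              RAP = "C", TOR = "C",
              HCQ = "D", SPA = "D",
              PAC = "E")
  jit <- rbind(
    EPI = c(0.01, -0.01, 0, 0, 0, 0), ACI = c(-0.01, 0.01, 0, 0, 0, 0),
    NCI = c(0, 0, 0.01, -0.01, 0, 0), CIS = c(0.01, 0, -0.01, 0, 0, 0),
    PDMP = c(0, 0.01, 0, -0.01, 0, 0), RAP = c(0, 0, 0.01, 0, -0.01, 0),
    TOR = c(0, 0, -0.01, 0, 0.01, 0), HCQ = c(0.01, 0, 0, 0, -0.01, 0),
    SPA = c(-0.01, 0, 0, 0, 0.01, 0), PAC = c(0, 0.01, 0, -0.01, 0, 0)
  )
  m <- base[assign, ] + jit[names(assign), ]
  rownames(m) <- names(assign)
  m / rowSums(m)
}
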