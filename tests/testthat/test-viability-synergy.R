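test_that("cytotoxicity and viability arithmetic", {
  expect_equal(compute_cytotoxicity(0, 100), 0)
  expect_equal(compute_cytotoxicity(120, 120), 100)
  expect_equal(compute_cytotoxicity(30, 120), 25)
  expect_error(compute_cytotoxicity(1, 0), "positive")
  expect_error(compute_cytotoxicity(5, 4), "dead")
  expect_equal(compute_viability(0), 100)
  expect_equal(compute_viability(100), 0)
  expect_equal(compute_viability(25), 75)
  expect_error(compute_viability(120), "\\[0, 100\\]")
})

test_that("Bliss expected viability and its bound", {
  expect_equal(expected_viability(100, 100), 100)
  expect_equal(expected_viability(50, 50), 25)
  expect_equal(expected_viability(80, 84), 67.2)
  expect_error(expected_viability(-1, 50), "\\[0, 100\\]")
  # property: expected <= min(singles), equality iff one single is 100
  set.seed(2)
  v1 <- runif(200, 0, 100); v2 <- runif(200, 0, 100)
  ev <- expected_viability(v1, v2)
  expect_true(all(ev <= pmin(v1, v2) + 1e-12))
  expect_equal(expected_viability(100, 73.2), 73.2)
})

test_that("interaction scoring reproduces the worked example and sign conventions", {
  s <- interaction_score(67, 14)
  expect_equal(s$double_interaction_pct, 53)
  expect_equal(s$interaction_ratio, 0.53)
  expect_equal(s$interaction_ratio_rounded, 0.5)
  expect_equal(s$interaction_class, "synergism")
  s0 <- interaction_score(40, 40)
  expect_equal(s0$double_interaction_pct, 0)
  expect_equal(s0$interaction_class, "no_interaction")
  sa <- interaction_score(30, 70)
  expect_equal(sa$double_interaction_pct, -40)
  expect_equal(sa$interaction_ratio_rounded, -0.4)
  expect_equal(sa$interaction_class, "antagonism")
})

test_that("class antisymmetry: negating the double interaction flips the call", {
  set.seed(3)
  e <- runif(50, 10, 90); x <- runif(50, 10, 90)
  s_fwd <- interaction_score(e, x)
  s_rev <- interaction_score(x, e)
  flip <- c(synergism = "antagonism", antagonism = "synergism",
            no_interaction = "no_interaction")
  expect_equal(unname(flip[s_fwd$interaction_class]), s_rev$interaction_class)
})

test_that("rounding is half away from zero at one decimal", {
  expect_equal(round_half_up(0.45, 1), 0.5)
  expect_equal(round_half_up(-0.45, 1), -0.5)
  expect_equal(round_half_up(0.44, 1), 0.4)
  expect_equal(round_half_up(0.05, 1), 0.1)
})

test_that("interaction matrix covers the panel and errors on missing singles", {
  d <- panel_design(cells_per_condition = 40, time_points_h = 48, seed = 5,
                    n_features = 10, n_informative = 5, n_subpopulations = 2)
  p <- generate_feature_panel(d)
  vt <- viability_table(p$cells, time_h = 48)
  scores <- build_interaction_matrix(vt)
  expect_equal(nrow(scores), 3 * 12)
  expect_setequal(unique(scores$chemo), c("EPI", "CIS", "PAC"))
  m <- interaction_matrix_wide(scores)
  expect_equal(dim(m), c(3, 12))
  # removing the RAP single breaks every EPI-RAP style double explicitly
  vt2 <- dplyr::filter(vt, condition != "RAP")
  expect_error(build_interaction_matrix(vt2), "RAP",
               class = "slsynergy_missing_control")
  expect_error(viability_table(p$cells, time_h = 999), "time point")
})

test_that("null calibration: planted independent deaths give near-zero ratios", {
  # simulate Bliss-independent cytotoxicity at n = 2000 cells/condition
  set.seed(11)
  singles <- c(EPI = 0.7, CIS = 0.65, PAC = 0.75,
               RAP = 0.9, ACI = 0.85, PDMP = 0.88, SKI = 0.9)
  chemo <- c("EPI", "CIS", "PAC"); pert <- c("RAP", "ACI", "PDMP", "SKI")
  n <- 2000
  rows <- list()
  for (cond in names(singles)) {
    alive <- rbinom(1, n, singles[cond])
    rows[[cond]] <- tibble::tibble(condition = cond, dead = n - alive, total = n)
  }
  for (ch in chemo) for (pe in pert) {
    v <- singles[ch] * singles[pe]
    alive <- rbinom(1, n, v)
    cond <- paste(ch, pe, sep = "-")
    rows[[cond]] <- tibble::tibble(condition = cond, dead = n - alive, total = n)
  }
  tbl <- dplyr::bind_rows(rows) %>%
    dplyr::mutate(
      viability_pct = compute_viability(compute_cytotoxicity(dead, total))
    )
  scores <- build_interaction_matrix(tbl)
  expect_lt(abs(mean(scores$interaction_ratio)), 0.03)
  expect_true(all(abs(scores$interaction_ratio_rounded) <= 0.1))
  expect_gte(mean(scores$interaction_ratio_rounded == 0), 0.5)
})

test_that("planted panel interactions are recovered at scale", {
  # with many cells per condition the planted ratios round to their targets
  d <- panel_design(cells_per_condition = 3000, time_points_h = 48, seed = 13,
                    n_features = 4, n_informative = 2, n_subpopulations = 2)
  p <- generate_feature_panel(d)
  vt <- viability_table(p$cells, time_h = 48)
  scores <- build_interaction_matrix(vt)
  planted <- default_interaction_ratios()
  j <- dplyr::left_join(scores, planted, by = c("chemo", "perturbation"))
  expect_true(all(abs(j$interaction_ratio_rounded - j$ratio) <= 0.1))
  # headline calls reproduced exactly
  key <- function(ch, pe) unname(j$interaction_ratio_rounded[j$chemo == ch & j$perturbation == pe])
  expect_equal(key("EPI", "RAP"), 0.5)
  expect_equal(key("PAC", "SPA"), -0.4)
  expect_equal(j$interaction_class[j$chemo == "EPI" & j$perturbation == "RAP"],
               "synergism")
})
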