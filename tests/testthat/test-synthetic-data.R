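test_that("panel generation is deterministic and conserves counts", {
  d <- small_design()
  p1 <- generate_feature_panel(d)
  p2 <- generate_feature_panel(d)
  expect_identical(p1$cells, p2$cells)
  expect_identical(p1$truth$weights, p2$truth$weights)
  n_cond <- length(panel_conditions(d))
  expect_equal(nrow(p1$cells), n_cond * d$cells_per_condition)
  expect_equal(nrow(p1$truth$cell_truth), nrow(p1$cells))
  # alive/dead partition per condition
  tallies <- dplyr::count(p1$cells, condition)
  expect_true(all(tallies$n == d$cells_per_condition))
})

test_that("mixing weights are simplex vectors and invalid inputs error", {
  d <- small_design()
  p <- generate_feature_panel(d)
  expect_true(all(abs(rowSums(p$truth$weights) - 1) < 1e-9))
  badw <- matrix(1, nrow = length(panel_conditions(d)), ncol = d$n_subpopulations)
  expect_error(generate_feature_panel(d, weights = badw), "simplex")
  expect_error(panel_design(n_informative = 40, n_features = 12), "informative")
  expect_error(panel_design(time_points_h = c(6, 6)), "increasing")
  expect_error(panel_design(chemotherapies = c("EPI", "EPI")), "unique")
})

test_that("planted component frequencies are recovered within 3 binomial errors", {
  d <- small_design(k = 3, cells = 200, seed = 7)
  p <- generate_feature_panel(d)
  truth <- p$truth
  live <- dplyr::filter(truth$cell_truth, alive)
  for (cond in unique(live$condition)) {
    cl <- live[live$condition == cond, ]
    n <- nrow(cl)
    emp <- tabulate(cl$component, nbins = 3) / n
    w <- truth$weights[cond, ]
    se <- sqrt(w * (1 - w) / n)
    expect_true(all(abs(emp - w) <= 3 * pmax(se, 1e-3)), label = cond)
  }
})

test_that("single-component panels give all conditions the same expected profile", {
  d <- small_design(k = 1, cells = 30)
  p <- generate_feature_panel(d)
  expect_true(all(p$truth$weights == 1))
  expect_true(all(p$truth$cell_truth$component[p$truth$cell_truth$alive] == 1))
})

test_that("well-separated planted components are recoverable by nearest-mean", {
  d <- small_design(k = 3, cells = 150, n_features = 12, n_informative = 10,
                    seed = 3)
  p <- generate_feature_panel(d)
  mu <- p$truth$component_means
  # precondition: pairwise Mahalanobis separation >= 6 (unit variances)
  seps <- as.matrix(dist(mu))
  expect_true(all(seps[upper.tri(seps)] >= 6))
  live <- dplyr::filter(p$cells, alive)
  x <- as.matrix(live[, p$truth$informative_features])
  truth_comp <- dplyr::filter(p$truth$cell_truth, alive)$component
  # brute-force nearest ground-truth mean classifier
  d2 <- sapply(seq_len(nrow(mu)), function(cc) {
    rowSums(sweep(x, 2, mu[cc, p$truth$informative_features])^2)
  })
  pred <- max.col(-d2)
  expect_gte(mean(pred == truth_comp), 0.99)
})

test_that("planted death fractions are matched over replicate fields", {
  set.seed(1)
  dead <- 0; total <- 0
  for (s in 1:50) {
    f <- generate_field("X", n_cells = 8, death_fraction = 0.3,
                        puncta_mean = 0, width = 192, height = 192, seed = s)
    dead <- dead + sum(!f$registry$alive)
    total <- total + nrow(f$registry)
  }
  se <- sqrt(0.3 * 0.7 / total)
  expect_lt(abs(dead / total - 0.3), 3 * se)
})

test_that("field generation handles edge cases and errors", {
  f0 <- generate_field("CTRL", n_cells = 0, seed = 1)
  expect_equal(nrow(f0$registry), 0)
  expect_true(all(vapply(f0$channels, function(m) all(dim(m) == c(256, 256)),
                         logical(1))))
  # no dead cells -> PI channel is background only
  f <- generate_field("CTRL", n_cells = 5, death_fraction = 0,
                      puncta_mean = 0, seed = 2)
  expect_false(any(f$channels$pi > f$meta$bg_mean + 7 * f$meta$bg_sd))
  # impossible placement -> explicit error
  expect_error(
    generate_field("CTRL", n_cells = 40, width = 96, height = 96, seed = 3),
    class = "slsynergy_placement_error"
  )
})

test_that("planted puncta means differ between induced and control conditions", {
  f_hi <- generate_field("EPI-RAP", n_cells = 25, death_fraction = 0,
                         puncta_mean = 12, seed = 5, width = 384, height = 384)
  f_lo <- generate_field("CTRL", n_cells = 25, death_fraction = 0,
                         puncta_mean = 2, seed = 5, width = 384, height = 384)
  m_hi <- mean(f_hi$registry$n_puncta)
  m_lo <- mean(f_lo$registry$n_puncta)
  expect_gt(m_hi, 3 * m_lo)
  expect_equal(sum(f_hi$registry$n_puncta), nrow(f_hi$puncta))
})

test_that("field determinism: identical parameters and seed give identical rasters", {
  f1 <- generate_field("EPI", n_cells = 6, seed = 9)
  f2 <- generate_field("EPI", n_cells = 6, seed = 9)
  expect_identical(f1$channels, f2$channels)
  expect_identical(f1$registry, f2$registry)
})

test_that("field TIFF export round-trips intensities", {
  f <- generate_field("CTRL", n_cells = 3, seed = 4, width = 128, height = 128)
  dir <- withr::local_tempdir()
  paths <- write_field(f, dir)
  g <- read_channel(file.path(dir, "CTRL_hoechst.tif"))
  expect_equal(dim(g), c(128, 128))
  # 16-bit quantization: agreement within one grey level
  expect_lt(max(abs(g - pmin(f$channels$hoechst, 65535))), 1.01)
})
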