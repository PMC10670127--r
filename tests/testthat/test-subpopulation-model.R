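test_that("standardization centers, scales, drops constants and inverts", {
  set.seed(1)
  tb <- tibble::tibble(
    cell_id = 1:50, condition = rep(c("A", "B"), 25),
    f1 = rnorm(50, 5, 2), f2 = rnorm(50, -3, 0.5), f3 = rep(7, 50)
  )
  expect_message(std <- standardize_features(tb), "constant")
  expect_false("f3" %in% names(std))
  expect_equal(colMeans(as.matrix(std[, c("f1", "f2")])), c(f1 = 0, f2 = 0),
               tolerance = 1e-12)
  expect_equal(apply(as.matrix(std[, c("f1", "f2")]), 2, sd),
               c(f1 = 1, f2 = 1), tolerance = 1e-12)
  # standardizing an already standardized table changes nothing
  std2 <- standardize_features(std)
  expect_equal(as.matrix(std2[, c("f1", "f2")]),
               as.matrix(std[, c("f1", "f2")]), tolerance = 1e-12)
  # round trip recovers the input
  back <- unstandardize_features(std)
  expect_equal(back$f1, tb$f1, tolerance = 1e-9)
  expect_error(standardize_features(tb[1, ]), "2 rows")
  expect_error(standardize_features(tibble::tibble(f = rep(1, 5))), "constant")
})

test_that("SVM ranking puts a perfectly separating feature first", {
  set.seed(2)
  n <- 120
  lab <- rep(c("A", "B"), each = n / 2)
  x <- as.data.frame(matrix(rnorm(n * 10), n, 10))
  names(x) <- paste0("noise", 1:10)
  x$signal <- ifelse(lab == "A", 3, -3) + rnorm(n, sd = 0.2)
  tb <- standardize_features(tibble::as_tibble(cbind(condition = lab, x)) %>%
                               dplyr::mutate(dplyr::across(-condition, as.numeric)))
  # brute-force oracle: the signal column separates the labels univariately
  expect_true(min(x$signal[lab == "A"]) > max(x$signal[lab == "B"]))
  rk <- rank_features_svm(tb)
  expect_equal(rk$feature[1], "signal")
  expect_error(rank_features_svm(tb, labels = rep("A", n)), "distinct")
})

test_that("duplicated feature columns get tied scores", {
  set.seed(3)
  n <- 80
  lab <- rep(c("A", "B"), each = n / 2)
  f <- rnorm(n) + ifelse(lab == "A", 1, -1)
  tb <- tibble::tibble(condition = lab, fa = f, fb = f, noise = rnorm(n))
  std <- standardize_features(tb)
  rk <- rank_features_svm(std)
  expect_lt(abs(rk$score[rk$feature == "fa"] - rk$score[rk$feature == "fb"]),
            1e-6)
})

test_that("permutation filter controls false positives on pure noise", {
  set.seed(4)
  n <- 150; d <- 20
  tb <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * d), n, d)))
  names(tb) <- paste0("f", 1:d)
  tb$condition <- sample(rep(c("A", "B", "C"), each = n / 3))
  std <- standardize_features(tb)
  rk <- rank_features_svm(std)
  sel <- select_features(rk, std, alpha = 0.05, B = 100, seed = 4)
  # 99% binomial bound on false positives at alpha = 0.05
  expect_lte(length(attr(sel, "selected")), qbinom(0.99, d, 0.05) + 1)
  # alpha = 1 retains everything
  sel_all <- select_features(rk, std, alpha = 1, B = 20, seed = 4)
  expect_equal(sort(attr(sel_all, "selected")), sort(names(tb)[1:d]))
  expect_error(select_features(rk, std, B = 10), "20 permutations")
})

test_that("merging condition tables preserves rows and checks schemas", {
  a <- tibble::tibble(f1 = rnorm(100), f2 = rnorm(100))
  b <- tibble::tibble(f1 = rnorm(100), f2 = rnorm(100))
  m <- merge_conditions(list(A = a, B = b))
  expect_equal(nrow(m), 200)
  expect_setequal(unique(m$condition), c("A", "B"))
  # order independence up to sorting
  m2 <- merge_conditions(list(B = b, A = a))
  expect_equal(dplyr::arrange(m, condition, f1), dplyr::arrange(m2, condition, f1))
  expect_error(merge_conditions(list()), "no tables")
  expect_error(
    merge_conditions(list(A = a, B = dplyr::rename(b, g2 = f2))), "g2"
  )
})

test_that("EM fits recover planted structure and behave monotonically", {
  # k = 1 closed form
  set.seed(5)
  x <- matrix(rnorm(200 * 3, mean = 2), 200, 3)
  colnames(x) <- paste0("f", 1:3)
  m1 <- fit_gmm(x, k = 1)
  expect_equal(m1$weights, 1)
  expect_equal(as.numeric(m1$means), unname(colMeans(x)), tolerance = 1e-9)
  # planted two components 6 sd apart
  set.seed(6)
  mu <- rbind(rep(0, 4), rep(3, 4))   # Euclidean separation 6
  z <- sample(1:2, 1000, replace = TRUE, prob = c(0.4, 0.6))
  x2 <- matrix(rnorm(4000), 1000, 4) + mu[z, ]
  colnames(x2) <- paste0("f", 1:4)
  m2 <- fit_gmm(x2, k = 2, seed = 2)
  ord <- order(m2$means[, 1])
  expect_lt(max(abs(m2$means[ord, ] - mu)), 0.1)
  expect_equal(sort(m2$weights), c(0.4, 0.6), tolerance = 0.05)
  # -log likelihood non-increasing along EM iterations
  expect_true(all(diff(m2$nll_trace) <= 1e-6))
  expect_error(fit_gmm(x2, k = 0), "k must be")
  expect_error(fit_gmm(x2[1:15, ], k = 2), "10\\*k")
})

test_that("mixture fit agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(7)
  mu <- rbind(c(0, 0), c(4, 4), c(-4, 4))
  z <- sample(1:3, 600, replace = TRUE)
  x <- matrix(rnorm(1200), 600, 2) + mu[z, ]
  colnames(x) <- c("f1", "f2")
  ours <- fit_gmm(x, k = 3, seed = 1)
  ref <- mclust::Mclust(x, G = 3, modelNames = "VVI", verbose = FALSE)
  expect_equal(ours$logLik, ref$loglik, tolerance = 0.01 * abs(ref$loglik))
  ord_o <- order(ours$means[, 1]); ord_r <- order(t(ref$parameters$mean)[, 1])
  expect_equal(unname(ours$means[ord_o, ]),
               unname(t(ref$parameters$mean)[ord_r, ]), tolerance = 0.1)
})

test_that("posterior assignment is a proper soft partition", {
  set.seed(8)
  mu <- rbind(rep(-3, 3), rep(3, 3))
  z <- sample(1:2, 500, replace = TRUE)
  x <- matrix(rnorm(1500), 500, 3) + mu[z, ]
  colnames(x) <- paste0("f", 1:3)
  m <- fit_gmm(x, k = 2, seed = 3)
  a <- assign_cells(m, x)
  expect_equal(rowSums(a$posterior), rep(1, 500), tolerance = 1e-9)
  # a point at a component mean is assigned to it
  at_mean <- assign_cells(m, m$means)
  expect_equal(at_mean$component, 1:2)
  # >= 99% agreement with planted labels (up to label permutation)
  agree <- max(mean(a$component == z), mean(a$component == 3 - z))
  expect_gte(agree, 0.99)
  expect_error(assign_cells(m, x[, 1:2]), "dimension|match the fitted model")
})

test_that("component-number selection recovers planted k", {
  # planted k = 1: a single Gaussian stays a single component
  set.seed(9)
  x1 <- matrix(rnorm(600 * 4), 600, 4)
  colnames(x1) <- paste0("f", 1:4)
  s1 <- select_component_number(x1, k_range = 1:4, seed = 1)
  expect_equal(s1$k, 1)
  expect_true(all(s1$curve$k == 1:4))
  # planted k = 3 recovered across reseeded runs
  hits <- 0
  for (s in 1:6) {
    set.seed(100 + s)
    mu <- rbind(rep(0, 5), rep(4, 5), c(rep(-4, 3), rep(4, 2)))
    z <- sample(1:3, 1000, replace = TRUE)
    x <- matrix(rnorm(5000), 1000, 5) + mu[z, ]
    colnames(x) <- paste0("f", 1:5)
    sel <- select_component_number(x, k_range = 1:5, seed = s)
    hits <- hits + (sel$k == 3)
  }
  expect_gte(hits, 5)
})

test_that("heterogeneity profiles are simplex frequency vectors", {
  p <- heterogeneity_profile(c(1, 1, 2, 2), rep("A", 4), k = 3)
  expect_equal(p$frequency, c(0.5, 0.5, 0))
  p2 <- heterogeneity_profile(rep(2, 10), rep("B", 10), k = 3)
  expect_equal(p2$frequency, c(0, 1, 0))
  expect_error(heterogeneity_profile(c(1, 4), c("A", "A"), k = 3), "1..k")
  expect_error(heterogeneity_profile(integer(0), character(0), k = 3), "empty")
  # two conditions with identical planted weights have close profiles
  set.seed(10)
  a1 <- sample(1:4, 2000, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  a2 <- sample(1:4, 2000, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  pp <- heterogeneity_profile(c(a1, a2), rep(c("C1", "C2"), each = 2000), k = 4)
  m <- profile_matrix(pp)
  expect_lt(profile_distance(m[1, ], m[2, ]), 0.05)
  expect_true(all(abs(rowSums(m) - 1) < 1e-9))
})

test_that("tidy, glance and augment expose the fitted mixture", {
  set.seed(11)
  x <- matrix(rnorm(300 * 2), 300, 2) + 2
  colnames(x) <- c("f1", "f2")
  tb <- tibble::as_tibble(x)
  m <- fit_gmm(tb, k = 2, seed = 1)
  td <- generics::tidy(m)
  expect_equal(nrow(td), 2 * 2)
  expect_setequal(names(td), c("component", "weight", "feature", "mean", "variance"))
  gl <- generics::glance(m)
  expect_equal(gl$k, 2)
  aug <- generics::augment(m, tb)
  expect_true(all(aug$.component %in% 1:2))
  expect_true(all(aug$.posterior >= 0.5 - 1e-9))
})

test_that("whole-model determinism under a fixed seed", {
  d <- small_design(cells = 40)
  p <- generate_feature_panel(d)
  std <- standardize_features(dplyr::filter(p$cells, alive))
  m1 <- fit_gmm(std, k = 3, seed = 17)
  m2 <- fit_gmm(std, k = 3, seed = 17)
  expect_identical(m1$means, m2$means)
  expect_identical(m1$nll, m2$nll)
})
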