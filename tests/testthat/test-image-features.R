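test_that("nuclei are segmented from the summed channels", {
  # blank rasters: zero objects
  z <- matrix(0, 64, 64)
  expect_equal(max(segment_nuclei(z, z)), 0)
  # synthetic field with well-separated nuclei: one object per cell,
  # centroids within 2 px of the registry
  f <- generate_field("CTRL", n_cells = 5, death_fraction = 0.4,
                      puncta_mean = 0, seed = 21)
  mask <- segment_nuclei(f$channels$hoechst, f$channels$pi)
  expect_equal(max(mask), 5)
  cent <- slsynergy:::mask_centroids(mask)
  for (i in seq_len(nrow(f$registry))) {
    dmin <- min(sqrt((cent$row - f$registry$row[i])^2 +
                     (cent$col - f$registry$col[i])^2))
    expect_lt(dmin, 2)
  }
  expect_error(segment_nuclei(z, matrix(0, 32, 32)), "shape")
})

test_that("PI-only nuclei (dead cells with no Hoechst) are still segmented", {
  h <- matrix(0, 96, 96)
  p <- matrix(0, 96, 96)
  add_spot <- function(img, r0, c0, amp = 1000, sigma = 3) {
    for (r in 1:96) for (cc in 1:96) {
      img[r, cc] <- img[r, cc] +
        amp * exp(-(((r - 1) - r0)^2 + ((cc - 1) - c0)^2) / (2 * sigma^2))
    }
    img
  }
  h <- add_spot(h, 30, 30)          # live cell: Hoechst only
  p <- add_spot(p, 65, 65)          # dead cell: PI only
  p2 <- add_spot(p, 30, 70)         # second dead cell, PI only
  mask <- segment_nuclei(h, p2)
  expect_equal(max(mask), 3)
  dead <- flag_dead_cells(mask, p2)
  expect_equal(sum(dead), 2)
})

test_that("dead-cell flagging matches planted viability", {
  f <- generate_field("EPI", n_cells = 10, death_fraction = 0.3,
                      puncta_mean = 0, seed = 31)
  mask <- segment_nuclei(f$channels$hoechst, f$channels$pi)
  expect_equal(max(mask), 10)
  dead <- flag_dead_cells(mask, f$channels$pi)
  cent <- slsynergy:::mask_centroids(mask)
  # match each segmented object to its registry cell
  match_obj <- vapply(seq_len(nrow(cent)), function(i) {
    which.min((f$registry$row - cent$row[i])^2 + (f$registry$col - cent$col[i])^2)
  }, integer(1))
  expect_equal(unname(dead), !f$registry$alive[match_obj])
  # PI background only -> all live
  bg <- matrix(100 + rnorm(prod(dim(mask)), sd = 5), nrow(mask), ncol(mask))
  expect_false(any(flag_dead_cells(mask, bg)))
  # all objects PI-bright -> all dead
  bright <- bg + 2000 * (mask > 0)
  expect_true(all(flag_dead_cells(mask, bright)))
  # empty mask -> empty flags, not an error
  expect_length(flag_dead_cells(matrix(0L, 32, 32), matrix(0, 32, 32)), 0)
})

test_that("whole cells grow from nuclear seeds over the GFP footprint", {
  f <- generate_field("CTRL", n_cells = 1, death_fraction = 0,
                      puncta_mean = 0, seed = 41, width = 128, height = 128)
  mask <- segment_nuclei(f$channels$hoechst, f$channels$pi)
  cells <- segment_cells(f$channels$gfp, mask)
  # coverage of the true cytoplasmic disk
  rr <- f$registry
  grid <- expand.grid(r = 0:127, c = 0:127)
  in_disk <- with(grid, (r - rr$row)^2 + (c - rr$col)^2 <= rr$cell_radius^2)
  covered <- cells$cell_mask[cbind(grid$r + 1, grid$c + 1)] > 0
  expect_gte(sum(covered & in_disk) / sum(in_disk), 0.9)
  expect_equal(cells$map$nucleus, cells$map$cell)
  # zero nuclei -> zero cells
  empty <- segment_cells(f$channels$gfp, matrix(0L, 128, 128))
  expect_equal(max(empty$cell_mask), 0)
  # adjacent cells: both recovered, pixels split between them
  f2 <- generate_field("CTRL", n_cells = 2, death_fraction = 0,
                       puncta_mean = 0, seed = 43, width = 160, height = 160)
  m2 <- segment_nuclei(f2$channels$hoechst, f2$channels$pi)
  c2 <- segment_cells(f2$channels$gfp, m2)
  expect_equal(sort(unique(as.integer(c2$cell_mask[c2$cell_mask > 0]))), 1:2)
})

test_that("segmentation satisfies the count arithmetic and recall/precision contract", {
  f <- generate_field("EPI", n_cells = 12, death_fraction = 0.25,
                      puncta_mean = 0, seed = 51, width = 320, height = 320)
  seg <- segment_field(f)
  expect_equal(seg$n_live + seg$n_dead, seg$n_total)
  cent <- slsynergy:::mask_centroids(seg$nucleus_mask)
  hits <- vapply(seq_len(nrow(f$registry)), function(i) {
    any(sqrt((cent$row - f$registry$row[i])^2 +
             (cent$col - f$registry$col[i])^2) < f$registry$nucleus_radius[i])
  }, logical(1))
  recall <- mean(hits)
  precision <- sum(hits) / nrow(cent)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("extracted features have the stable canonical schema", {
  f <- generate_field("CTRL", n_cells = 4, death_fraction = 0.5,
                      puncta_mean = 3, seed = 61)
  seg <- segment_field(f)
  feats <- extract_features(seg$cell_mask, seg$nucleus_mask, f$channels,
                            dead = seg$dead)
  expect_equal(names(feats), c("cell_id", "alive", feature_names(153)))
  expect_true(all(is.finite(as.matrix(feats[, -(1:2)]))))
  expect_equal(nrow(feats), 4)
  # a second image yields the identical column set
  f2 <- generate_field("EPI", n_cells = 3, seed = 62)
  seg2 <- segment_field(f2)
  feats2 <- extract_features(seg2$cell_mask, seg2$nucleus_mask, f2$channels)
  expect_identical(names(feats), names(feats2))
})

test_that("feature values reflect geometry and intensity ground truth", {
  # uniform disk: intensity sd inside the nucleus is 0; circular form factor ~ 1
  mask <- matrix(0L, 64, 64)
  for (r in 1:64) for (cc in 1:64) {
    if ((r - 32)^2 + (cc - 32)^2 <= 14^2) mask[r, cc] <- 1L
  }
  flat <- matrix(500, 64, 64)
  feats <- extract_features(mask, mask, list(gfp = flat))
  expect_equal(feats$int_gfp_nuc_sd, 0)
  expect_equal(feats$mor_nuc_form_factor, 1, tolerance = 0.05)
  expect_equal(feats$mor_cell_eccentricity, 0, tolerance = 0.15)
  # a brighter-GFP cell ranks higher on mean GFP
  f <- generate_field("CTRL", n_cells = 2, death_fraction = 0,
                      puncta_mean = 0, seed = 71, width = 160, height = 160)
  ch <- f$channels
  reg <- f$registry
  # brighten cell 2's cytoplasm
  sel <- outer(0:(nrow(ch$gfp) - 1), 0:(ncol(ch$gfp) - 1), function(r, c) {
    (r - reg$row[2])^2 + (c - reg$col[2])^2 <= reg$cell_radius[2]^2
  })
  ch$gfp[sel] <- ch$gfp[sel] * 3
  seg <- segment_field(ch)
  feats2 <- extract_features(seg$cell_mask, seg$nucleus_mask, ch)
  cent <- slsynergy:::mask_centroids(seg$nucleus_mask)
  bright_obj <- which.min((cent$row - reg$row[2])^2 + (cent$col - reg$col[2])^2)
  expect_equal(which.max(feats2$int_gfp_cell_mean), bright_obj)
})

test_that("degenerate objects are dropped with a message", {
  mask <- matrix(0L, 32, 32)
  mask[5:14, 5:14] <- 1L     # 100 px object
  mask[20, 20] <- 2L         # single-pixel degenerate object
  expect_message(
    feats <- extract_features(mask, mask, list(gfp = matrix(1, 32, 32))),
    "degenerate"
  )
  expect_equal(feats$cell_id, 1)
})

test_that("puncta counting matches planted spots", {
  flat <- matrix(0, 64, 64)
  mask <- matrix(1L, 64, 64)
  expect_equal(sum(count_puncta(mask, flat)$count), 0)
  # k planted spots at 10x noise sd
  set.seed(8)
  img <- matrix(rnorm(96 * 96, 100, 8), 96, 96)
  pts <- cbind(r = c(20, 20, 48, 70, 80), c = c(20, 60, 48, 30, 75))
  for (i in seq_len(nrow(pts))) {
    for (r in 1:96) for (cc in 1:96) {
      d2 <- ((r - 1) - pts[i, 1])^2 + ((cc - 1) - pts[i, 2])^2
      if (d2 < 25) img[r, cc] <- img[r, cc] + 80 * exp(-d2 / (2 * 1.5^2))
    }
  }
  mask96 <- matrix(1L, 96, 96)
  expect_equal(sum(count_puncta(mask96, img)$count), nrow(pts))
})

test_that("detected puncta means track planted means within 20%", {
  n_det <- 0; n_pl <- 0; c_det <- 0; c_pl <- 0
  for (s in 1:7) {
    f <- generate_field("EPI-RAP", n_cells = 8, death_fraction = 0,
                        puncta_mean = 12, cell_radius = 26,
                        width = 512, height = 512, seed = s)
    seg <- segment_field(f)
    n_det <- n_det + sum(count_puncta(seg$cell_mask, f$channels$mcherry)$count)
    n_pl <- n_pl + sum(f$registry$n_puncta)
    g <- generate_field("CTRL", n_cells = 8, death_fraction = 0,
                        puncta_mean = 2, cell_radius = 26,
                        width = 512, height = 512, seed = s + 50)
    sg <- segment_field(g)
    c_det <- c_det + sum(count_puncta(sg$cell_mask, g$channels$mcherry)$count)
    c_pl <- c_pl + sum(g$registry$n_puncta)
  }
  expect_lt(abs(n_det - n_pl) / n_pl, 0.2)
  expect_lt(abs(c_det - c_pl) / max(c_pl, 1), 0.2)
})

test_that("puncta classification follows tandem-reporter semantics", {
  # identical centroid lists: all dual, colocalization 1
  a <- tibble::tibble(row = c(5, 10, 20), col = c(5, 10, 20))
  rep1 <- classify_puncta(a, a, radius = 3)
  expect_equal(rep1$dual, 3)
  expect_equal(rep1$coloc, 1)
  # far-apart lists: no dual
  b <- tibble::tibble(row = c(50, 60), col = c(50, 60))
  rep2 <- classify_puncta(a, b, radius = 3)
  expect_equal(rep2$dual, 0)
  expect_equal(rep2$mcherry_only, 2)
  # 5 gfp vs 8 mcherry with 3 planted coincidences
  gfp <- tibble::tibble(row = c(1, 10, 20, 30, 40), col = c(1, 10, 20, 30, 40))
  mch <- tibble::tibble(
    row = c(1.5, 10.5, 20.5, 70, 80, 90, 100, 110),
    col = c(1, 10, 20, 70, 80, 90, 100, 110)
  )
  # brute-force oracle: pairs within radius 3
  d <- sqrt(outer(gfp$row, mch$row, `-`)^2 + outer(gfp$col, mch$col, `-`)^2)
  expect_equal(sum(apply(d <= 3, 2, any)), 3)
  rep3 <- classify_puncta(gfp, mch, radius = 3)
  expect_equal(rep3$dual, 3)
  expect_equal(rep3$mcherry_only, 5)
  expect_equal(rep3$coloc, 3 / 5)
  # invariants
  expect_lte(rep3$dual + rep3$mcherry_only, rep3$mcherry_total)
  # swapping channels preserves the matched-pair set
  rep4 <- classify_puncta(mch, gfp, radius = 3)
  expect_equal(rep4$dual, rep3$dual)
  expect_error(classify_puncta(a, a, radius = -1), "non-negative")
  # zero gfp puncta: colocalization undefined and flagged
  rep5 <- classify_puncta(a[0, ], b, radius = 3)
  expect_true(is.na(rep5$coloc))
  expect_false(rep5$coloc_defined)
})
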