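#' Extract per-cell intensity, texture and morphology features
#'
#' Computes the canonical feature taxonomy of [feature_names()] for every
#' segmented cell: intensity statistics per channel over the nuclear and
#' whole-cell regions, Haralick co-occurrence texture statistics plus
#' top-hat granularity per channel over the cell region, and nucleus/cell
#' shape descriptors. Objects whose nucleus is smaller than `min_area`
#' pixels are dropped (their ids are reported in a message) so every
#' returned value is finite.
#'
#' @param cell_mask,nucleus_mask integer label matrices with matching labels.
#' @param channels named list of intensity matrices (`hoechst`, `pi`, `gfp`,
#'   `mcherry`); missing channels are treated as all-zero.
#' @param dead optional named logical vector from [flag_dead_cells()].
#' @param min_area minimum nucleus area (px) below which an object is
#'   considered degenerate and dropped.
#' @return tibble: `cell_id` (label), `alive`, and one column per canonical
#'   feature name, in fixed order, identical across images.
#' @export
extract_features <- function(cell_mask, nucleus_mask, channels, dead = NULL,
                             min_area = 9) {
  if (!all(dim(cell_mask) == dim(nucleus_mask))) {
    abort("cell and nucleus masks must have identical shape")
  }
  want <- c("hoechst", "pi", "gfp", "mcherry")
  for (ch in want) {
    if (is.null(channels[[ch]])) {
      channels[[ch]] <- matrix(0, nrow(cell_mask), ncol(cell_mask))
    }
  }
  labs <- sort(unique(as.integer(nucleus_mask[nucleus_mask > 0])))
  if (length(labs) == 0) {
    out <- as_tibble(setNames(
      as.list(rep(list(numeric(0)), 153 + 2)),
      c("cell_id", "alive", feature_names(153))
    ))
    out$cell_id <- integer(0); out$alive <- logical(0)
    return(out)
  }
  areas <- tabulate(nucleus_mask[nucleus_mask > 0])
  degenerate <- labs[areas[labs] < min_area]
  if (length(degenerate)) {
    message("dropping degenerate objects (nucleus area < ", min_area, " px): ",
            paste(degenerate, collapse = ", "))
    labs <- setdiff(labs, degenerate)
  }
  if (length(labs) == 0) {
    return(extract_features(cell_mask * 0L, nucleus_mask * 0L, channels))
  }

  int_stats <- function(v) {
    if (length(v) == 0) v <- 0
    q <- unname(quantile(v, c(0.1, 0.9), names = FALSE))
    c(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
      median = median(v), mad = mad(v), q10 = q[1], q90 = q[2],
      min = min(v), max = max(v), integrated = sum(v))
  }

  # Haralick texture per channel over cell bodies (EBImage co-occurrence)
  haralick_names <- c("asm", "con", "cor", "var", "idm", "sav", "sva", "sen",
                      "ent", "dva", "den", "f12", "f13")
  haralick_for <- function(raster) {
    g <- norm01(raster)
    if (is.null(g)) {
      return(matrix(0, length(labs), 13,
                    dimnames = list(labs, haralick_names)))
    }
    h <- tryCatch(
      EBImage::computeFeatures.haralick(
        EBImage::Image(cell_mask), EBImage::Image(g),
        haralick.nbins = 16, haralick.scales = 1
      ),
      error = function(e) NULL
    )
    out <- matrix(0, length(labs), 13, dimnames = list(labs, haralick_names))
    if (!is.null(h) && nrow(h) > 0) {
      rows <- intersect(seq_len(nrow(h)), labs)
      out[as.character(rows), ] <- h[rows, seq_len(13), drop = FALSE]
    }
    out[!is.finite(out)] <- 0
    out
  }

  # granularity: mean top-hat residual at small/large structuring radii
  gran_for <- function(raster) {
    g <- norm01(raster)
    if (is.null(g)) g <- matrix(0, nrow(raster), ncol(raster))
    vapply(c(2, 4), function(r) {
      th <- EBImage::imageData(EBImage::whiteTopHat(
        EBImage::Image(g), EBImage::makeBrush(2 * r + 1, "disc")
      ))
      vapply(labs, function(l) mean(th[cell_mask == l]), numeric(1))
    }, numeric(length(labs)))
  }

  # Crofton-style perimeter: transition counts in 4 directions
  crofton_perimeter <- function(bin) {
    mp <- rbind(0, cbind(0, bin, 0), 0)
    nr <- nrow(mp); nc <- ncol(mp)
    ch <- sum(mp[, -1] != mp[, -nc])
    cv <- sum(mp[-1, ] != mp[-nr, ])
    d1 <- sum(mp[-1, -1] != mp[-nr, -nc])
    d2 <- sum(mp[-1, -nc] != mp[-nr, -1])
    pi / 4 * (ch + cv + (d1 + d2) / sqrt(2)) / 2
  }

  shape_stats <- function(mask) {
    t(vapply(labs, function(l) {
      px <- which(mask == l, arr.ind = TRUE)
      a <- nrow(px)
      if (a == 0) return(rep(0, 10))
      r <- px[, 1]; c <- px[, 2]
      sub <- mask[min(r):max(r), min(c):max(c), drop = FALSE] == l
      perim <- max(crofton_perimeter(sub * 1), 1)
      # second moments -> ellipse axes and eccentricity
      mu_rr <- var(r) * (a - 1) / a + 1 / 12
      mu_cc <- var(c) * (a - 1) / a + 1 / 12
      mu_rc <- if (a > 1) stats::cov(r, c) * (a - 1) / a else 0
      tr <- mu_rr + mu_cc
      det_ <- mu_rr * mu_cc - mu_rc^2
      l1 <- tr / 2 + sqrt(max(tr^2 / 4 - det_, 0))
      l2 <- tr / 2 - sqrt(max(tr^2 / 4 - det_, 0))
      major <- 4 * sqrt(max(l1, 0)); minor <- 4 * sqrt(max(l2, 0))
      ecc <- if (l1 > 0) sqrt(max(1 - l2 / l1, 0)) else 0
      form <- 4 * pi * a / perim^2
      bbox <- (diff(range(r)) + 1) * (diff(range(c)) + 1)
      cent <- c(mean(r), mean(c))
      c(area = a, perimeter = perim, form_factor = form,
        eccentricity = ecc, major_axis = major, minor_axis = minor,
        aspect_ratio = if (minor > 0) major / minor else 1,
        equiv_diameter = 2 * sqrt(a / pi), extent = a / bbox,
        radius_mean = mean(sqrt((r - cent[1])^2 + (c - cent[2])^2)))
    }, numeric(10)))
  }

  fmat <- matrix(0, nrow = length(labs), ncol = 153,
                 dimnames = list(labs, feature_names(153)))
  for (ch in want) {
    raster <- channels[[ch]]
    for (reg in c("nuc", "cell")) {
      mask <- if (reg == "nuc") nucleus_mask else cell_mask
      stats_m <- t(vapply(labs, function(l) int_stats(raster[mask == l]),
                          numeric(9)))
      cols <- paste0("int_", ch, "_", reg, "_",
                     c("mean", "sd", "median", "mad", "q10", "q90",
                       "min", "max", "integrated"))
      fmat[, cols] <- stats_m
    }
    fmat[, paste0("tex_", ch, "_", haralick_names)] <- haralick_for(raster)
    fmat[, paste0("tex_", ch, "_", c("gran_s", "gran_l"))] <- gran_for(raster)
  }
  nuc_shape <- shape_stats(nucleus_mask)
  cell_shape <- shape_stats(cell_mask)
  shape_cols <- c("area", "perimeter", "form_factor", "eccentricity",
                  "major_axis", "minor_axis", "aspect_ratio",
                  "equiv_diameter", "extent", "radius_mean")
  fmat[, paste0("mor_nuc_", shape_cols)] <- nuc_shape
  fmat[, paste0("mor_cell_", shape_cols)] <- cell_shape
  fmat[, "mor_nuc_cell_area_ratio"] <-
    nuc_shape[, 1] / pmax(cell_shape[, 1], 1)
  fmat[!is.finite(fmat)] <- 0

  alive <- if (is.null(dead)) rep(TRUE, length(labs)) else
    !dead[as.character(labs)]
  dplyr::bind_cols(
    tibble(cell_id = labs, alive = unname(alive)),
    as_tibble(fmat)
  )
}
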