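# Internal: scale a raster to [0,1]; returns NULL if constant
norm01 <- function(x) {
  r <- range(x, finite = TRUE)
  if (!is.finite(r[1]) || diff(r) < 1e-12) return(NULL)
  (x - r[1]) / diff(r)
}

# foreground mask by Otsu thresholding on log intensities; the log compresses
# the bright-object range so a very bright subpopulation (e.g. PI-loaded dead
# nuclei) does not push the threshold above the dimmer objects
otsu_foreground <- function(x) {
  lx <- norm01(log1p(x))
  if (is.null(lx)) return(matrix(FALSE, nrow(x), ncol(x)))
  thr <- EBImage::otsu(EBImage::Image(lx), range = c(0, 1))
  lx > thr
}

relabel <- function(mask) {
  labs <- sort(unique(as.integer(mask[mask > 0])))
  if (length(labs) == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (i in seq_along(labs)) out[mask == labs[i]] <- i
  out
}

#' Segment nuclei from the summed Hoechst + PI signal
#'
#' Nuclei of all cells — live and dead — are segmented on the pixel-wise sum
#' of the Hoechst (DAPI) and PI (Texas Red) channels, so that dead nuclei
#' whose Hoechst signal is weak but whose PI signal is strong are not missed.
#' The summed image is Otsu-thresholded, holes are filled, touching objects
#' are split by a distance-transform watershed, and objects below the
#' minimum area are removed.
#'
#' @param hoechst,pi numeric intensity matrices of identical shape.
#' @param min_area minimum object area in pixels (smaller objects dropped).
#' @param watershed_tolerance minimum object-separating depth of the distance
#'   map used when splitting touching nuclei.
#' @return integer label matrix (0 = background, 1..n = nuclei).
#' @export
segment_nuclei <- function(hoechst, pi, min_area = 40, watershed_tolerance = 1) {
  if (!all(dim(hoechst) == dim(pi))) abort("channel rasters must have identical shape")
  bw <- otsu_foreground(hoechst + pi)
  if (!any(bw)) return(matrix(0L, nrow(hoechst), ncol(hoechst)))
  bw <- EBImage::fillHull(EBImage::Image(bw * 1))
  dm <- EBImage::distmap(bw)
  ws <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  mask <- matrix(as.integer(EBImage::imageData(ws)), nrow(hoechst), ncol(hoechst))
  sizes <- tabulate(mask[mask > 0])
  small <- which(sizes > 0 & sizes < min_area)
  if (length(small)) mask[mask %in% small] <- 0L
  relabel(mask)
}

#' Flag dead cells from per-nucleus PI intensity
#'
#' Each nucleus is called dead when its mean PI intensity exceeds a decision
#' threshold: the midpoint between the two modes of the per-object PI means
#' (2-means clustering) when the modes straddle the background level, and a
#' robust background threshold (median + 5 MAD of PI outside nuclei)
#' otherwise, which handles the all-live and all-dead edge cases.
#'
#' @param nucleus_mask integer label matrix from [segment_nuclei()].
#' @param pi PI-channel intensity matrix.
#' @return named logical vector, `TRUE` = dead, one entry per nucleus label.
#' @export
flag_dead_cells <- function(nucleus_mask, pi) {
  if (!all(dim(nucleus_mask) == dim(pi))) abort("mask and raster shapes differ")
  labs <- sort(unique(as.integer(nucleus_mask[nucleus_mask > 0])))
  if (length(labs) == 0) return(setNames(logical(0), character(0)))
  means <- vapply(labs, function(l) mean(pi[nucleus_mask == l]), numeric(1))
  bg <- pi[nucleus_mask == 0]
  bg_thr <- median(bg) + 5 * mad(bg)
  thr <- bg_thr
  if (length(labs) >= 2 && length(unique(round(means, 8))) >= 2) {
    km <- tryCatch(kmeans(means, centers = 2, nstart = 5),
                   error = function(e) NULL)
    if (!is.null(km)) {
      cs <- sort(km$centers[, 1])
      if (cs[1] < bg_thr && cs[2] > bg_thr) thr <- mean(cs)
    }
  }
  setNames(means > thr, labs)
}

#' Grow whole-cell regions from nuclear seeds on the GFP channel
#'
#' Seeded region growing (Voronoi propagation) from the nucleus mask,
#' constrained to above-background GFP signal (Otsu threshold on the GFP
#' channel, with nuclear pixels always included). Each resulting cell
#' carries the label of — and therefore maps to — exactly one nucleus.
#'
#' @param gfp GFP-channel intensity matrix.
#' @param nucleus_mask integer label matrix from [segment_nuclei()].
#' @param lambda regularization of the propagation metric (0 = pure
#'   geodesic distance on intensity, large = Euclidean Voronoi).
#' @return list with `cell_mask` (integer label matrix, labels matching the
#'   nucleus labels) and `map` (tibble nucleus -> cell).
#' @export
segment_cells <- function(gfp, nucleus_mask, lambda = 1e-4) {
  if (!all(dim(gfp) == dim(nucleus_mask))) abort("mask and raster shapes differ")
  labs <- sort(unique(as.integer(nucleus_mask[nucleus_mask > 0])))
  if (length(labs) == 0) {
    return(list(cell_mask = matrix(0L, nrow(gfp), ncol(gfp)),
                map = tibble(nucleus = integer(0), cell = integer(0))))
  }
  g <- norm01(gfp)
  if (is.null(g)) g <- matrix(0, nrow(gfp), ncol(gfp))
  fg <- otsu_foreground(gfp) | nucleus_mask > 0
  cm <- EBImage::propagate(EBImage::Image(g), EBImage::Image(nucleus_mask),
                           mask = EBImage::Image(fg), lambda = lambda)
  cell_mask <- matrix(as.integer(EBImage::imageData(cm)), nrow(gfp), ncol(gfp))
  list(cell_mask = cell_mask,
       map = tibble(nucleus = labs, cell = labs))
}

#' Segment a field end to end
#'
#' Convenience wrapper running [segment_nuclei()], [flag_dead_cells()] and
#' [segment_cells()] on the channels of a field, returning the full
#' segmentation result. Live cells are the complete cells minus the
#' dead-flagged ones.
#'
#' @param field a [generate_field()] result or a named list of channel
#'   matrices (`hoechst`, `pi`, `gfp`, optionally `mcherry`).
#' @param min_area minimum nucleus area (px).
#' @return object of class `segmentation_result`: nucleus mask, cell mask,
#'   nucleus-to-cell map, per-object `dead` flags, and counts.
#' @export
segment_field <- function(field, min_area = 40) {
  ch <- if (inherits(field, "synthetic_field")) field$channels else field
  nuc <- segment_nuclei(ch$hoechst, ch$pi, min_area = min_area)
  dead <- flag_dead_cells(nuc, ch$pi)
  cells <- segment_cells(ch$gfp, nuc)
  structure(
    list(nucleus_mask = nuc, cell_mask = cells$cell_mask, map = cells$map,
         dead = dead, n_total = length(dead), n_dead = sum(dead),
         n_live = sum(!dead)),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d nuclei: %d live + %d dead\n",
              x$n_total, x$n_live, x$n_dead))
  invisible(x)
}

# centroids of labelled objects, 0-based row/col
mask_centroids <- function(mask) {
  labs <- sort(unique(as.integer(mask[mask > 0])))
  if (length(labs) == 0) return(tibble(object = integer(0), row = numeric(0), col = numeric(0)))
  idx <- which(mask > 0, arr.ind = TRUE)
  l <- mask[mask > 0]
  tibble(
    object = labs,
    row = as.numeric(tapply(idx[, 1] - 1, l, mean)[as.character(labs)]),
    col = as.numeric(tapply(idx[, 2] - 1, l, mean)[as.character(labs)])
  )
}
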