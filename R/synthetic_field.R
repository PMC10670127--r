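#' Generate a synthetic multi-channel fluorescence field
#'
#' Renders a field of disk-like cells with Gaussian-profile nuclei in the
#' Hoechst channel, PI signal only over dead nuclei, a larger cytoplasmic
#' disk in the GFP channel, and optional puncta (small bright Gaussian spots,
#' Poisson-distributed per cell) in the mCherry and GFP channels emulating a
#' tandem mCherry-EGFP-LC3B reporter. Background is Gaussian noise on a
#' constant offset. A registry of every rendered object (centroid, radii,
#' amplitudes, alive flag, puncta) is returned as ground truth.
#'
#' @param condition condition label (used to look up planted defaults).
#' @param n_cells number of cells to place (>= 0).
#' @param width,height raster size in pixels.
#' @param death_fraction probability a cell is dead; default the planted
#'   48 h value for `condition`.
#' @param puncta_mean mean puncta per cell; default the planted value for
#'   `condition`.
#' @param dual_fraction fraction of puncta rendered in both GFP and mCherry
#'   (autophagosomes); the remainder are mCherry-only (autophagolysosomes).
#' @param nucleus_radius,cell_radius object radii in pixels.
#' @param bg_mean,bg_sd background offset and noise level (intensity units).
#' @param amp_hoechst,amp_pi,amp_gfp,amp_puncta peak amplitudes above
#'   background; puncta default to 10 x `bg_sd` so spot detection is
#'   well-posed.
#' @param with_mcherry render the mCherry channel (and puncta)?
#' @param max_tries placement attempts per cell before giving up.
#' @param seed integer seed.
#' @return object of class `synthetic_field`: list with `channels` (named
#'   list of numeric matrices), `registry` (one row per cell), `puncta`
#'   (one row per rendered punctum) and `meta`.
#' @export
generate_field <- function(condition = "CTRL", n_cells = 20,
                           width = 256, height = 256,
                           death_fraction = NULL, puncta_mean = NULL,
                           dual_fraction = 0.7,
                           nucleus_radius = 6, cell_radius = 12,
                           bg_mean = 100, bg_sd = 8,
                           amp_hoechst = 1200, amp_pi = 1500, amp_gfp = 800,
                           amp_puncta = 10 * bg_sd,
                           with_mcherry = TRUE,
                           max_tries = 500L, seed = 1L) {
  if (n_cells < 0) abort("n_cells must be >= 0")
  if (is.null(death_fraction)) {
    death_fraction <- planted_death_fraction(condition, 48)[[1]]
  }
  if (is.null(puncta_mean)) puncta_mean <- planted_puncta_mean(condition)[[1]]

  with_seed(derive_seed(seed, paste0("field_", condition)), {
    margin <- cell_radius + 2
    min_sep <- 2 * cell_radius + 2
    if (n_cells > 0 &&
        (width < 2 * margin + 1 || height < 2 * margin + 1)) {
      abort("raster too small for requested cell placement")
    }
    centers <- matrix(numeric(0), ncol = 2)
    tries <- 0L
    while (nrow(centers) < n_cells) {
      cand <- c(runif(1, margin, height - 1 - margin),
                runif(1, margin, width - 1 - margin))
      ok <- nrow(centers) == 0 ||
        all(sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) >= min_sep)
      if (ok) centers <- rbind(centers, cand)
      tries <- tries + 1L
      if (tries > max_tries * max(n_cells, 1)) {
        abort(sprintf(
          "could not place %d non-overlapping cells in a %dx%d raster",
          n_cells, height, width
        ), class = "slsynergy_placement_error")
      }
    }

    blank <- function() {
      matrix(pmax(bg_mean + rnorm(height * width, sd = bg_sd), 0),
             nrow = height, ncol = width)
    }
    hoechst <- blank(); pi_ch <- blank(); gfp <- blank()
    mcherry <- if (with_mcherry) blank() else matrix(0, height, width)

    alive <- if (n_cells > 0) runif(n_cells) >= death_fraction else logical(0)
    nuc_sigma <- nucleus_radius / 2

    add_disk <- function(img, r0, c0, radius, amp, gaussian = FALSE, sigma = 1) {
      rr <- max(0, floor(r0 - radius - 4)):min(height - 1, ceiling(r0 + radius + 4))
      cc <- max(0, floor(c0 - radius - 4)):min(width - 1, ceiling(c0 + radius + 4))
      d2 <- outer((rr - r0)^2, (cc - c0)^2, `+`)
      patch <- if (gaussian) {
        amp * exp(-d2 / (2 * sigma^2)) * (d2 <= (radius + 3)^2)
      } else {
        # logistic edge keeps the disk compact but not aliased
        amp / (1 + exp((sqrt(d2) - radius)))
      }
      img[rr + 1, cc + 1] <- img[rr + 1, cc + 1] + patch
      img
    }

    puncta <- list()
    for (i in seq_len(n_cells)) {
      r0 <- centers[i, 1]; c0 <- centers[i, 2]
      hoechst <- add_disk(hoechst, r0, c0, nucleus_radius, amp_hoechst,
                          gaussian = TRUE, sigma = nuc_sigma)
      if (!alive[i]) {
        pi_ch <- add_disk(pi_ch, r0, c0, nucleus_radius, amp_pi,
                          gaussian = TRUE, sigma = nuc_sigma)
      }
      gfp <- add_disk(gfp, r0, c0, cell_radius, amp_gfp)
      n_p <- rpois(1, puncta_mean)
      if (n_p > 0) {
        theta <- runif(n_p, 0, 2 * pi)
        rad <- sqrt(runif(n_p)) * 0.8 * cell_radius
        pr <- r0 + rad * sin(theta); pc <- c0 + rad * cos(theta)
        sig <- runif(n_p, 1.2, 1.8)
        dual <- runif(n_p) < dual_fraction
        for (j in seq_len(n_p)) {
          if (with_mcherry) {
            mcherry <- add_disk(mcherry, pr[j], pc[j], 3, amp_puncta,
                                gaussian = TRUE, sigma = sig[j])
          }
          if (dual[j]) {
            gfp <- add_disk(gfp, pr[j], pc[j], 3, amp_puncta,
                            gaussian = TRUE, sigma = sig[j])
          }
        }
        puncta[[length(puncta) + 1]] <- tibble(
          object = i, row = pr, col = pc, sigma = sig, dual = dual
        )
      }
    }

    registry <- tibble(
      object = seq_len(n_cells),
      row = if (n_cells > 0) centers[, 1] else numeric(0),
      col = if (n_cells > 0) centers[, 2] else numeric(0),
      nucleus_radius = rep(nucleus_radius, n_cells),
      cell_radius = rep(cell_radius, n_cells),
      amp_hoechst = rep(amp_hoechst, n_cells),
      amp_pi = ifelse(alive, 0, amp_pi),
      amp_gfp = rep(amp_gfp, n_cells),
      alive = alive,
      n_puncta = vapply(seq_len(n_cells), function(i) {
        sum(vapply(puncta, function(p) sum(p$object == i), numeric(1)))
      }, numeric(1))
    )

    structure(
      list(
        channels = list(hoechst = hoechst, pi = pi_ch, gfp = gfp,
                        mcherry = mcherry),
        registry = registry,
        puncta = if (length(puncta)) bind_rows(puncta) else
          tibble(object = integer(0), row = numeric(0), col = numeric(0),
                 sigma = numeric(0), dual = logical(0)),
        meta = list(condition = condition, pixel_size_um = 0.65,
                    bg_mean = bg_mean, bg_sd = bg_sd, seed = seed,
                    death_fraction = death_fraction,
                    puncta_mean = puncta_mean)
      ),
      class = "synthetic_field"
    )
  })
}

#' @export
print.synthetic_field <- function(x, ...) {
  cat(sprintf("<synthetic_field> %s: %d cells (%d dead), %dx%d px, %d puncta\n",
              x$meta$condition, nrow(x$registry), sum(!x$registry$alive),
              nrow(x$channels$hoechst), ncol(x$channels$hoechst),
              nrow(x$puncta)))
  invisible(x)
}

#' Write a synthetic field as one 16-bit TIFF per channel plus a JSON registry
#'
#' @param field a [generate_field()] result.
#' @param dir output directory (created if missing).
#' @param prefix filename prefix.
#' @return invisibly, the written file paths.
#' @export
write_field <- function(field, dir, prefix = field$meta$condition) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ch in names(field$channels)) {
    p <- file.path(dir, sprintf("%s_%s.tif", prefix, ch))
    img <- t(pmin(field$channels[[ch]], 65535) / 65535)
    EBImage::writeImage(EBImage::Image(img), p, type = "tiff",
                        bits.per.sample = 16L)
    paths <- c(paths, p)
  }
  rj <- file.path(dir, sprintf("%s_registry.json", prefix))
  jsonlite::write_json(
    list(registry = field$registry, puncta = field$puncta, meta = field$meta),
    rj, auto_unbox = TRUE, digits = NA
  )
  invisible(c(paths, rj))
}

#' Read a channel raster from a TIFF or PNG file
#'
#' @param path image path.
#' @return numeric matrix of intensities (original bit-depth scale).
#' @export
read_channel <- function(path) {
  img <- EBImage::readImage(path)
  m <- EBImage::imageData(img)
  if (length(dim(m)) > 2) m <- m[, , 1]
  t(m) * 65535
}
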