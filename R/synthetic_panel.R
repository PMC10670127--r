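#' Generate a synthetic single-cell feature panel with ground truth
#'
#' Draws, for every condition and time point of the design,
#' `cells_per_condition` per-cell feature vectors from a shared mixture of
#' Gaussian subpopulations with condition-specific mixing weights. A planted
#' subset of features (default 109 of 153) carries component-dependent mean
#' shifts; the remaining features are standard-normal noise. Dead cells (flag
#' drawn Bernoulli from the planted per-condition, per-time death fraction)
#' are drawn from one additional, distinctly shifted component so that
#' PI-independent viability checks are possible; the alive flag remains the
#' ground truth. All draws are reproducible from `design$seed`.
#'
#' @param design a [panel_design()].
#' @param weights optional condition x k matrix of mixing weights (rows must
#'   be simplex vectors, rownames = condition labels); by default weights are
#'   drawn per profile archetype so that the planted co-clustering groups
#'   (EPI/ACI/NCI, CIS/PDMP, RAP/TOR, HCQ/SPA) share near-identical profiles.
#' @return list with `cells` (tibble: cell_id, condition, time_h, alive and
#'   one column per feature) and `truth` (class `sl_ground_truth`: planted
#'   death fractions, mixing weights, component means/sds, dead-component
#'   mean, per-cell true component labels, puncta means).
#' @export
generate_feature_panel <- function(design, weights = NULL) {
  stopifnot(inherits(design, "panel_design"))
  k <- design$n_subpopulations
  d <- design$n_features
  conds <- panel_conditions(design)
  fnames <- feature_names(d)
  informative <- seq_len(design$n_informative)

  with_seed(derive_seed(design$seed, "panel"), {
    # shared component structure: informative features get component-dependent
    # means at the design effect size; noise features stay at zero
    mu <- matrix(0, nrow = k, ncol = d, dimnames = list(NULL, fnames))
    if (length(informative) > 0) {
      mu[, informative] <- design$effect_size * rnorm(k * length(informative))
    }
    dead_mean <- numeric(d)
    if (length(informative) > 0) {
      dead_mean[informative] <- design$effect_size * rnorm(length(informative)) + 1
    }

    if (is.null(weights)) {
      arch <- profile_archetype(conds)
      arch_w <- lapply(unique(arch), function(a) rdirichlet1(k))
      names(arch_w) <- unique(arch)
      jitter <- 0.05
      weights <- do.call(rbind, lapply(seq_along(conds), function(i) {
        w <- (1 - jitter) * arch_w[[arch[i]]] + jitter * rdirichlet1(k)
        w / sum(w)
      }))
      rownames(weights) <- conds
    } else {
      weights <- as.matrix(weights)
      if (ncol(weights) != k) abort("weights must have n_subpopulations columns")
      if (is.null(rownames(weights))) rownames(weights) <- conds
      apply(weights, 1, stopifnot_simplex, what = "mixing weights")
    }

    grid <- tidyr::expand_grid(condition = conds, time_h = design$time_points_h)
    n_cell <- design$cells_per_condition
    blocks <- purrr::pmap(grid, function(condition, time_h) {
      df <- planted_death_fraction(condition, time_h)
      alive <- runif(n_cell) >= df
      comp <- integer(n_cell)
      n_live <- sum(alive)
      if (n_live > 0) {
        comp[alive] <- sample.int(k, n_live, replace = TRUE,
                                  prob = weights[condition, ])
      }
      x <- matrix(rnorm(n_cell * d), nrow = n_cell, ncol = d,
                  dimnames = list(NULL, fnames))
      x[alive, ] <- x[alive, , drop = FALSE] + mu[comp[alive], , drop = FALSE]
      if (any(!alive)) {
        x[!alive, ] <- sweep(x[!alive, , drop = FALSE], 2, dead_mean, `+`)
      }
      list(
        meta = tibble(
          cell_id = sprintf("%s_t%02.0f_%04d", condition, time_h, seq_len(n_cell)),
          condition = condition, time_h = time_h, alive = alive,
          component = comp
        ),
        x = x
      )
    })

    meta <- bind_rows(purrr::map(blocks, "meta"))
    x <- do.call(rbind, purrr::map(blocks, "x"))
    cells <- dplyr::bind_cols(
      meta %>% select(-"component"),
      as_tibble(x)
    )
    truth <- structure(
      list(
        design = design,
        conditions = conds,
        death_fraction = grid %>%
          mutate(death_fraction = planted_death_fraction(.data$condition, .data$time_h)),
        weights = weights,
        component_means = mu,
        component_sd = rep(1, d),
        dead_mean = dead_mean,
        informative_features = fnames[informative],
        puncta_mean = tibble(condition = conds,
                             puncta_mean = planted_puncta_mean(conds)),
        cell_truth = meta
      ),
      class = "sl_ground_truth"
    )
    list(cells = cells, truth = truth)
  })
}

#' @export
print.sl_ground_truth <- function(x, ...) {
  cat("<sl_ground_truth>\n")
  cat(sprintf("  %d conditions, k = %d live subpopulations + 1 dead component\n",
              length(x$conditions), ncol(x$weights)))
  cat(sprintf("  %d features (%d informative), %d cells registered\n",
              ncol(x$component_means), length(x$informative_features),
              nrow(x$cell_truth)))
  invisible(x)
}

#' Write a feature panel to per-condition CSV files
#'
#' @param cells feature table from [generate_feature_panel()].
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
write_feature_panel <- function(cells, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(unique(cells$condition), function(cond) {
    path <- file.path(dir, paste0("features_", gsub("[^A-Za-z0-9_-]", "_", cond), ".csv"))
    utils::write.csv(cells[cells$condition == cond, , drop = FALSE], path,
                     row.names = FALSE)
    path
  }, character(1))
  invisible(paths)
}
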