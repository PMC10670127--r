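#' Tidy a fitted Gaussian mixture
#'
#' One row per component-feature pair with the fitted mean and variance,
#' plus the component weight.
#'
#' @param x an `sl_gmm`.
#' @param ... unused.
#' @return tibble: `component`, `weight`, `feature`, `mean`, `variance`.
#' @export
tidy.sl_gmm <- function(x, ...) {
  fn <- x$feature_names %||% paste0("x", seq_len(x$d))
  tidyr::expand_grid(component = seq_len(x$k), feature = fn) %>%
    mutate(
      weight = x$weights[.data$component],
      mean = x$means[cbind(.data$component, match(.data$feature, fn))],
      variance = x$variances[cbind(.data$component, match(.data$feature, fn))]
    ) %>%
    select("component", "weight", "feature", "mean", "variance")
}

#' Model-level summary of a fitted Gaussian mixture
#'
#' @param x an `sl_gmm`.
#' @param ... unused.
#' @return one-row tibble: `k`, `n`, `d`, `logLik`, `nll`, `iterations`,
#'   `converged`.
#' @export
glance.sl_gmm <- function(x, ...) {
  tibble(k = x$k, n = x$n, d = x$d, logLik = x$logLik, nll = x$nll,
         iterations = x$iterations, converged = x$converged)
}

#' Augment a feature table with mixture assignments
#'
#' @param x an `sl_gmm`.
#' @param data feature table the model dimension matches.
#' @param ... unused.
#' @return `data` with `.component` (hard label) and `.posterior` (posterior
#'   probability of that label) columns appended.
#' @export
augment.sl_gmm <- function(x, data, ...) {
  a <- assign_cells(x, data)
  data %>%
    mutate(.component = a$component,
           .posterior = a$posterior[cbind(seq_len(nrow(data)), a$component)])
}

#' Tidy a component-number selection curve
#'
#' @param x an `sl_gmm_selection`.
#' @param ... unused.
#' @return the selection curve tibble (one row per candidate k).
#' @export
tidy.sl_gmm_selection <- function(x, ...) x$curve

#' Summary of a component-number selection
#'
#' @param x an `sl_gmm_selection`.
#' @param ... unused.
#' @return one-row tibble: chosen `k`, `status`, `alpha`, `min_frac`.
#' @export
glance.sl_gmm_selection <- function(x, ...) {
  tibble(k = x$k, status = x$status, alpha = x$alpha, min_frac = x$min_frac)
}

#' Heatmap of the interaction matrix
#'
#' Tile plot of rounded interaction ratios (red = synergism, blue =
#' antagonism), one row per chemotherapy and one column per perturbation.
#'
#' @param object an `interaction_scores` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.interaction_scores <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$perturbation, y = .data$chemo,
    fill = .data$interaction_ratio_rounded
  )) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f", .data$interaction_ratio_rounded)
    ), size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "indianred", midpoint = 0,
                                  name = "interaction\nratio") +
    ggplot2::labs(x = "perturbation", y = "chemotherapy") +
    ggplot2::theme_minimal()
}

#' Stacked-bar plot of heterogeneity profiles
#'
#' @param object a `heterogeneity_profiles` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.heterogeneity_profiles <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$condition, y = .data$frequency,
    fill = factor(.data$subpopulation)
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_viridis_d(name = "subpopulation") +
    ggplot2::labs(x = NULL, y = "cell frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Selection-curve plot (MANOVA p-value and -log-likelihood against k)
#'
#' @param object an `sl_gmm_selection`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sl_gmm_selection <- function(object, ...) {
  long <- object$curve %>%
    select("k", "nll", "manova_p") %>%
    tidyr::pivot_longer(c("nll", "manova_p"), names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = 2, color = "indianred") +
    ggplot2::facet_wrap(~metric, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(nll = "-log likelihood", manova_p = "MANOVA p-value")
                        )) +
    ggplot2::labs(x = "number of subpopulations k", y = NULL) +
    ggplot2::theme_minimal()
}

#' Dendrogram plot of clustered perturbation profiles
#'
#' @param object a `perturbation_dendrogram`.
#' @param threshold optional cut height drawn as a dashed line.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.perturbation_dendrogram <- function(object, threshold = NULL, ...) {
  hc <- object$hclust
  n <- length(hc$labels)
  xpos <- numeric(n)
  xpos[hc$order] <- seq_len(n)
  node_x <- numeric(nrow(hc$merge)); node_y <- hc$height
  seg <- list()
  pos_of <- function(id) {
    if (id < 0) c(xpos[-id], 0) else c(node_x[id], node_y[id])
  }
  for (i in seq_len(nrow(hc$merge))) {
    a <- pos_of(hc$merge[i, 1]); b <- pos_of(hc$merge[i, 2])
    node_x[i] <- (a[1] + b[1]) / 2
    seg[[length(seg) + 1]] <- tibble(
      x = c(a[1], a[1], b[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], hc$height[i], hc$height[i]),
      yend = c(hc$height[i], hc$height[i], b[2])
    )
  }
  labs_df <- tibble(x = seq_len(n), label = hc$labels[hc$order])
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = bind_rows(seg), ggplot2::aes(
      x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend
    )) +
    ggplot2::geom_text(data = labs_df, ggplot2::aes(
      x = .data$x, y = -0.02 * max(hc$height), label = .data$label
    ), angle = 90, hjust = 1, size = 3) +
    ggplot2::labs(x = NULL, y = sprintf("%s distance (%s linkage)",
                                        object$metric, object$linkage)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                                 color = "indianred")
  }
  p
}
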