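#' Per-condition heterogeneity profiles
#'
#' The heterogeneity profile of a condition is the frequency vector of its
#' cells over the k mixture subpopulations — the fingerprint used to compare
#' perturbations.
#'
#' @param assignments integer vector of hard component labels (1..k).
#' @param conditions condition label per cell (same length).
#' @param k number of subpopulations.
#' @return object of class `heterogeneity_profiles`: tibble `condition`,
#'   `subpopulation`, `frequency`, `n_cells`; per-condition frequencies sum
#'   to 1.
#' @export
heterogeneity_profile <- function(assignments, conditions, k) {
  if (length(assignments) != length(conditions)) {
    abort("assignments and conditions must have the same length")
  }
  if (length(assignments) == 0) abort("empty assignment vector")
  if (any(assignments < 1 | assignments > k)) {
    abort("every assignment must lie in 1..k")
  }
  out <- purrr::map_dfr(sort(unique(conditions)), function(cond) {
    a <- assignments[conditions == cond]
    if (length(a) == 0) abort(sprintf("condition %s has no cells", cond))
    tibble(condition = cond, subpopulation = seq_len(k),
           frequency = tabulate(a, nbins = k) / length(a),
           n_cells = length(a))
  })
  structure(out, class = c("heterogeneity_profiles", class(out)))
}

#' Profiles as a condition x subpopulation matrix
#'
#' @param profiles a `heterogeneity_profiles` tibble.
#' @return numeric matrix, rows = conditions (lexicographic), columns =
#'   subpopulations.
#' @export
profile_matrix <- function(profiles) {
  w <- profiles %>%
    select("condition", "subpopulation", "frequency") %>%
    tidyr::pivot_wider(names_from = "subpopulation", values_from = "frequency",
                       values_fill = 0)
  m <- as.matrix(w[, -1])
  rownames(m) <- w$condition
  m[order(rownames(m)), , drop = FALSE]
}

#' Distance between two heterogeneity profiles
#'
#' Euclidean distance on the frequency vectors (default), or the square root
#' of the Jensen-Shannon divergence (a metric on probability vectors) as an
#' alternative.
#'
#' @param p,q frequency vectors of equal length (or single-condition rows of
#'   [profile_matrix()]).
#' @param method `"euclidean"` (default) or `"jsd"`.
#' @return non-negative scalar distance.
#' @export
profile_distance <- function(p, q, method = c("euclidean", "jsd")) {
  method <- match.arg(method)
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != length(q)) abort("profiles must have equal length")
  if (method == "euclidean") {
    sqrt(sum((p - q)^2))
  } else {
    m <- (p + q) / 2
    kl <- function(a, b) {
      i <- a > 0
      sum(a[i] * log(a[i] / b[i]))
    }
    sqrt(pmax((kl(p, m) + kl(q, m)) / 2, 0))
  }
}

#' Cluster perturbation profiles into a dendrogram
#'
#' Agglomerative clustering (average linkage / UPGMA by default) on
#' pairwise profile distances. Input profiles are ordered lexicographically
#' by label before clustering so the result is deterministic regardless of
#' input order (distance ties are then broken by label order).
#'
#' @param profiles a `heterogeneity_profiles` tibble or a numeric matrix of
#'   profiles with condition rownames.
#' @param method distance: `"euclidean"` (default) or `"jsd"`.
#' @param linkage hclust agglomeration method (default `"average"`).
#' @return object of class `perturbation_dendrogram`: the `hclust` tree,
#'   leaf labels, metric and linkage names, and the merge-height table.
#' @export
cluster_perturbations <- function(profiles, method = c("euclidean", "jsd"),
                                  linkage = "average") {
  method <- match.arg(method)
  m <- if (is.matrix(profiles)) {
    profiles[order(rownames(profiles)), , drop = FALSE]
  } else {
    profile_matrix(profiles)
  }
  if (nrow(m) < 2) abort("at least 2 profiles required")
  d <- if (method == "euclidean") {
    dist(m)
  } else {
    n <- nrow(m)
    dd <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      dd[i, j] <- dd[j, i] <- profile_distance(m[i, ], m[j, ], method = "jsd")
    }
    stats::as.dist(dd)
  }
  hc <- hclust(d, method = linkage)
  structure(
    list(hclust = hc, labels = rownames(m), metric = method,
         linkage = linkage,
         merges = tibble(step = seq_along(hc$height), height = hc$height)),
    class = "perturbation_dendrogram"
  )
}

#' @export
print.perturbation_dendrogram <- function(x, ...) {
  cat(sprintf("<perturbation_dendrogram> %d leaves, %s distance, %s linkage\n",
              length(x$labels), x$metric, x$linkage))
  invisible(x)
}

#' Extract tight co-clustering groups from a dendrogram
#'
#' Cuts the tree at `height` and returns the maximal groups whose internal
#' merge heights are all below the threshold; singletons are excluded.
#' These are the "enclosed pairs" of interest: perturbations whose
#' heterogeneity profiles are nearly identical.
#'
#' @param dendrogram a [cluster_perturbations()] result.
#' @param height cut height; default 25% of the maximum merge height.
#' @return list of character vectors (each a group of >= 2 leaf labels),
#'   sorted; each group carries its maximal internal merge height in
#'   attribute `"height"`, and the threshold used is in attribute
#'   `"threshold"`.
#' @export
extract_pairs <- function(dendrogram, height = NULL) {
  hc <- dendrogram$hclust
  if (is.null(height)) height <- 0.25 * max(hc$height)
  if (height < 0) abort("height threshold must be >= 0")
  ct <- cutree(hc, h = height)
  groups <- split(names(ct), ct)
  groups <- purrr::keep(groups, ~ length(.x) >= 2)
  groups <- purrr::map(groups, sort)
  groups <- unname(groups[order(vapply(groups, `[`, character(1), 1))])
  coph <- as.matrix(stats::cophenetic(hc))
  groups <- purrr::map(groups, function(g) {
    # height at which the last members of the group merge
    structure(g, height = max(coph[g, g]))
  })
  structure(groups, threshold = height)
}

#' Write a dendrogram in Newick format
#'
#' @param dendrogram a [cluster_perturbations()] result.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_dendrogram_newick <- function(dendrogram, path) {
  phy <- ape::as.phylo(dendrogram$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Write heterogeneity profiles to CSV (conditions x subpopulations)
#'
#' @param profiles a `heterogeneity_profiles` tibble.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_profiles_csv <- function(profiles, path) {
  utils::write.csv(profile_matrix(profiles), path)
  invisible(path)
}
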