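#' Standardize a feature table
#'
#' Centers and scales every feature column to zero mean and unit standard
#' deviation. Constant features carry no information for mixture modelling or
#' classification and are dropped with a message. The means and sds used are
#' stored as attributes so the transform can be inverted.
#'
#' @param cells feature table (metadata columns `cell_id`, `condition`,
#'   `time_h`, `alive` are passed through untouched).
#' @return standardized tibble with attributes `feature_center` and
#'   `feature_scale`.
#' @export
standardize_features <- function(cells) {
  if (nrow(cells) < 2) abort("at least 2 rows required to standardize")
  fc <- feature_cols(cells)
  x <- feature_matrix(cells)
  if (any(!is.finite(x))) abort("feature values must be finite")
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  constant <- scl < 1e-12
  if (all(constant)) abort("all features are constant")
  if (any(constant)) {
    message("dropping constant feature(s): ",
            paste(fc[constant], collapse = ", "))
    x <- x[, !constant, drop = FALSE]
    ctr <- ctr[!constant]; scl <- scl[!constant]
    fc <- fc[!constant]
  }
  z <- sweep(sweep(x, 2, ctr), 2, scl, `/`)
  out <- dplyr::bind_cols(
    cells[, setdiff(names(cells), feature_cols(cells)), drop = FALSE],
    as_tibble(z)
  )
  attr(out, "feature_center") <- ctr
  attr(out, "feature_scale") <- scl
  out
}

#' Invert [standardize_features()]
#'
#' @param std a standardized table carrying the `feature_center` /
#'   `feature_scale` attributes.
#' @return tibble on the original feature scale.
#' @export
unstandardize_features <- function(std) {
  ctr <- attr(std, "feature_center"); scl <- attr(std, "feature_scale")
  if (is.null(ctr) || is.null(scl)) abort("not a standardized table")
  fc <- feature_cols(std)
  x <- sweep(sweep(feature_matrix(std), 2, scl[fc], `*`), 2, ctr[fc], `+`)
  dplyr::bind_cols(
    std[, setdiff(names(std), fc), drop = FALSE],
    as_tibble(x)
  )
}

# linear soft-margin SVM weight vector (dual coordinate descent; class-
# balanced per-class C so the rarer class is not swamped)
svm_linear_weights <- function(x, y01, cost = 1, xt = NULL) {
  n <- length(y01)
  n_pos <- sum(y01); n_neg <- n - n_pos
  if (is.null(xt)) xt <- t(x)
  .svm_dcd_weights(xt, ifelse(y01, 1, -1),
                   c_pos = cost * n / (2 * n_pos),
                   c_neg = cost * n / (2 * n_neg))
}

# one-vs-rest linear SVM feature scores: max |weight| over the per-label
# classifiers (linear kernel, C = cost, class-balanced weights)
svm_feature_scores <- function(x, labels, cost = 1, xt = NULL) {
  if (is.null(xt)) xt <- t(x)
  lv <- sort(unique(labels))
  scores <- matrix(0, nrow = length(lv), ncol = nrow(xt))
  for (i in seq_along(lv)) {
    scores[i, ] <- abs(svm_linear_weights(NULL, labels == lv[i], cost = cost,
                                          xt = xt))
  }
  apply(scores, 2, max)
}

#' Rank features by linear SVM weight magnitude
#'
#' Trains one soft-margin linear SVM per label (one-vs-rest, class-balanced
#' weighting) on the standardized features and scores each feature by the
#' maximum absolute weight it receives across the classifiers. Features are
#' returned in descending score order.
#'
#' @param cells standardized feature table.
#' @param labels per-cell class labels; defaults to `cells$condition`.
#' @param cost SVM regularization constant C; defaults to `0.05 / n`, which
#'   places the soft-margin solution in its small-C regime where the weight
#'   vector is proportional to the class-balanced centroid difference — the
#'   scaling that gives the permutation filter of [select_features()]
#'   calibrated power on features whose class signal is a modest mean shift.
#' @return object of class `feature_ranking`: tibble `feature`, `score`,
#'   `rank`, with the training labels and cost stored as attributes.
#' @export
rank_features_svm <- function(cells, labels = NULL, cost = NULL) {
  if (is.null(labels)) labels <- cells$condition
  if (length(unique(labels)) < 2) abort("at least 2 distinct labels required")
  x <- feature_matrix(cells)
  if (length(labels) != nrow(x)) abort("labels must match rows")
  if (is.null(cost)) cost <- 0.05 / nrow(x)
  sc <- svm_feature_scores(x, labels, cost = cost)
  out <- tibble(feature = feature_cols(cells), score = sc) %>%
    arrange(dplyr::desc(.data$score)) %>%
    mutate(rank = dplyr::row_number())
  structure(out, class = c("feature_ranking", class(out)),
            cost = cost)
}

#' Select significant features by a label-permutation filter
#'
#' A feature is retained when its SVM score exceeds the `(1 - alpha)`
#' quantile of its own permutation null: the scores it receives when the
#' class labels are randomly permuted `B` times (which destroys any real
#' association while preserving the feature's marginal distribution).
#'
#' @param ranking a [rank_features_svm()] result computed on `cells`.
#' @param cells the same standardized feature table.
#' @param labels the labels used for the ranking (default `cells$condition`).
#' @param alpha significance level (default 0.05).
#' @param B number of label permutations (default 200; at least 20).
#' @param seed integer seed for the permutations.
#' @return object of class `feature_selection`: tibble `feature`, `score`,
#'   `rank`, `null_quantile`, `significant`; selected features in attribute
#'   `"selected"`, plus `alpha` and `B`.
#' @export
select_features <- function(ranking, cells, labels = NULL, alpha = 0.05,
                            B = 200, seed = 1L) {
  if (B < 20) abort("at least 20 permutations required")
  if (is.null(labels)) labels <- cells$condition
  x <- feature_matrix(cells)
  fc <- feature_cols(cells)
  if (!setequal(ranking$feature, fc)) {
    abort("ranking was not computed on this feature table")
  }
  cost <- attr(ranking, "cost") %||% (0.05 / nrow(x))
  xt <- t(x)
  null_scores <- with_seed(derive_seed(seed, "permfilter"), {
    vapply(seq_len(B), function(b) {
      svm_feature_scores(NULL, sample(labels), cost = cost, xt = xt)
    }, numeric(nrow(xt)))
  })
  thr <- apply(null_scores, 1, quantile, probs = 1 - alpha, names = FALSE)
  thr <- setNames(thr, fc)
  out <- ranking %>%
    mutate(
      null_quantile = unname(thr[.data$feature]),
      significant = if (alpha >= 1) TRUE else .data$score > .data$null_quantile
    )
  structure(out,
            class = c("feature_selection", setdiff(class(ranking), "feature_ranking")),
            selected = out$feature[out$significant],
            alpha = alpha, B = B, cost = cost)
}

#' Merge per-condition feature tables into one dataset
#'
#' Row-binds tables with identical schemas, adding (or keeping) a
#' `condition` provenance column.
#'
#' @param tables named list of feature tables (names used as condition
#'   labels when the tables lack a `condition` column).
#' @return single merged tibble.
#' @export
merge_conditions <- function(tables) {
  if (length(tables) == 0) abort("no tables to merge")
  schemas <- lapply(tables, names)
  ref <- schemas[[1]]
  for (i in seq_along(schemas)) {
    bad <- c(setdiff(schemas[[i]], ref), setdiff(ref, schemas[[i]]))
    if (length(bad)) {
      abort(sprintf("schema mismatch in table %s: %s",
                    names(tables)[i] %||% i, paste(bad, collapse = ", ")))
    }
  }
  out <- purrr::imap(tables, function(tb, nm) {
    tb <- as_tibble(tb)
    if (!"condition" %in% names(tb)) {
      tb$condition <- if (is.character(nm) && nzchar(nm)) nm else as.character(nm)
    }
    tb
  })
  bind_rows(out)
}
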