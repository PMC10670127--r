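# log densities (n x k) for a diagonal-covariance Gaussian mixture
gmm_log_dens <- function(x, means, vars, weights) {
  k <- nrow(means); d <- ncol(means)
  inv <- 1 / vars
  a <- (x^2) %*% t(inv)
  b <- x %*% t(means * inv)
  cst <- rowSums(means^2 * inv) + rowSums(log(vars)) + d * log(2 * pi)
  sweep(-0.5 * (a - 2 * b + matrix(cst, nrow(x), k, byrow = TRUE)),
        2, log(weights), `+`)
}

log_row_sum_exp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

gmm_em_once <- function(x, k, reg, tol, max_iter, init_assign) {
  n <- nrow(x); d <- ncol(x)
  resp <- matrix(0, n, k)
  resp[cbind(seq_len(n), init_assign)] <- 1
  nll_trace <- numeric(0)
  nll_prev <- Inf
  means <- vars <- NULL; weights <- NULL
  for (iter in seq_len(max_iter)) {
    nc <- pmax(colSums(resp), 1e-10)
    weights <- nc / n
    means <- sweep(crossprod(resp, x), 1, nc, `/`)
    ex2 <- sweep(crossprod(resp, x^2), 1, nc, `/`)
    vars <- pmax(ex2 - means^2, 0) + reg
    ld <- gmm_log_dens(x, means, vars, weights)
    lse <- log_row_sum_exp(ld)
    nll <- -sum(lse)
    nll_trace <- c(nll_trace, nll)
    resp <- exp(ld - lse)
    if (is.finite(nll_prev) && abs(nll_prev - nll) < tol) break
    nll_prev <- nll
  }
  list(weights = weights, means = means, vars = vars, nll = nll_trace[length(nll_trace)],
       nll_trace = nll_trace, iterations = length(nll_trace),
       converged = length(nll_trace) < max_iter)
}

# Ward agglomeration on a subsample, then nearest-centroid assignment of all
# rows; subsample capped for the O(m^2) distance matrix
ward_init_assign <- function(x, k, m_max = 2000) {
  n <- nrow(x)
  idx <- if (n > m_max) sample.int(n, m_max) else seq_len(n)
  hc <- hclust(dist(x[idx, , drop = FALSE]), method = "ward.D2")
  cl <- cutree(hc, k = k)
  centers <- t(vapply(seq_len(k), function(j) {
    colMeans(x[idx[cl == j], , drop = FALSE])
  }, numeric(ncol(x))))
  cross <- x %*% t(centers)
  d2 <- outer(rep(1, n), rowSums(centers^2)) - 2 * cross
  max.col(-d2, ties.method = "first")
}

# kmeans++ seeding: spread initial centers with probability proportional to
# squared distance from the nearest already-chosen center
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in 2:k) {
    prob <- d2 / sum(d2)
    centers[j, ] <- x[sample.int(n, 1, prob = prob), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

#' Fit a diagonal-covariance Gaussian mixture by EM
#'
#' Expectation-maximization with diagonal covariances and a small ridge
#' (`reg`) added to every variance for numerical stability; the best of
#' `n_restarts` seeded k-means initializations (by final negative
#' log-likelihood) is returned. The negative log-likelihood is
#' non-increasing across EM iterations.
#'
#' @param cells feature table (or plain numeric matrix) of standardized
#'   features; metadata columns are ignored.
#' @param k number of mixture components (>= 1).
#' @param seed integer seed for the restarts.
#' @param n_restarts number of initializations (default 5).
#' @param tol convergence tolerance on the negative log-likelihood.
#' @param max_iter maximum EM iterations per restart.
#' @param reg variance ridge (default 1e-6).
#' @return object of class `sl_gmm` with weights, means (k x d), variances
#'   (k x d), the negative log-likelihood, its per-iteration trace, and fit
#'   metadata.
#' @export
fit_gmm <- function(cells, k, seed = 1L, n_restarts = 5, tol = 1e-6,
                    max_iter = 500, reg = 1e-6) {
  if (k < 1) abort("k must be >= 1")
  x <- if (is.matrix(cells)) cells else feature_matrix(cells)
  if (nrow(x) < 10 * k) {
    abort(sprintf("need at least 10*k = %d rows to fit k = %d components", 10 * k, k))
  }
  fits <- lapply(seq_len(n_restarts), function(r) {
    with_seed(derive_seed(seed, paste0("gmm_k", k, "_r", r)), {
      init <- if (k == 1) {
        rep(1L, nrow(x))
      } else if (r == 1) {
        # Ward-linkage agglomerative init on a subsample: robust to the
        # seeding failures of random restarts on well-separated clusters
        ward_init_assign(x, k)
      } else {
        centers <- kmeanspp_centers(x, k)
        km <- tryCatch(
          suppressWarnings(kmeans(x, centers = centers, iter.max = 50)),
          error = function(e) NULL
        )
        if (is.null(km)) sample.int(k, nrow(x), replace = TRUE) else km$cluster
      }
      gmm_em_once(x, k, reg = reg, tol = tol, max_iter = max_iter,
                  init_assign = init)
    })
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "nll"))]]
  structure(
    list(k = k, weights = best$weights, means = best$means,
         variances = best$vars, nll = best$nll, logLik = -best$nll,
         nll_trace = best$nll_trace, n = nrow(x), d = ncol(x),
         feature_names = colnames(x), iterations = best$iterations,
         converged = best$converged, seed = seed, n_restarts = n_restarts,
         reg = reg),
    class = "sl_gmm"
  )
}

#' @export
print.sl_gmm <- function(x, ...) {
  cat(sprintf("<sl_gmm> k = %d, n = %d, d = %d, -logLik = %.2f (%s in %d iter)\n",
              x$k, x$n, x$d, x$nll,
              if (x$converged) "converged" else "max iterations", x$iterations))
  invisible(x)
}

#' Posterior assignment of cells to mixture components
#'
#' @param model an `sl_gmm` fit.
#' @param cells feature table or matrix with the model's feature columns.
#' @return list with `component` (hard argmax labels, 1..k) and `posterior`
#'   (n x k matrix; rows sum to 1).
#' @export
assign_cells <- function(model, cells) {
  x <- if (is.matrix(cells)) cells else feature_matrix(cells)
  if (!is.null(model$feature_names) && !is.null(colnames(x))) {
    if (!all(model$feature_names %in% colnames(x))) {
      abort("feature columns do not match the fitted model")
    }
    x <- x[, model$feature_names, drop = FALSE]
  }
  if (ncol(x) != model$d) abort("feature dimension does not match the fitted model")
  ld <- gmm_log_dens(x, model$means, model$variances, model$weights)
  lse <- log_row_sum_exp(ld)
  post <- exp(ld - lse)
  list(component = max.col(post, ties.method = "first"), posterior = post)
}

# Wilks-lambda MANOVA p-value for multivariate group separation; on
# high-dimensional data the test is computed on the top principal components
# explaining `var_explained` of the variance
manova_pvalue <- function(x, groups, var_explained = 0.95, max_dim = 50) {
  g <- factor(groups)
  if (nlevels(g) < 2 || any(table(g) < 2)) return(NA_real_)
  if (ncol(x) > max_dim) {
    pc <- prcomp(x, center = TRUE, scale. = FALSE)
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    keep <- max(2, min(which(cum >= var_explained)))
    keep <- min(keep, nrow(x) - nlevels(g) - 2, max_dim)
    x <- pc$x[, seq_len(keep), drop = FALSE]
  }
  tryCatch({
    fit <- manova(x ~ g)
    s <- summary(fit, test = "Wilks")$stats
    unname(s[1, "Pr(>F)"])
  }, error = function(e) NA_real_)
}

#' Choose the number of subpopulations by MANOVA and likelihood improvement
#'
#' For each candidate k the mixture is fitted, cells are hard-assigned, and
#' three criteria are evaluated: (a) a one-way MANOVA (Wilks' lambda, F
#' approximation) of the features against the assignment must be significant
#' at `alpha`; (b) every component must hold at least `min_frac` of the
#' cells; (c) the negative log-likelihood improvement over the previous
#' candidate must exceed a BIC-style tolerance (added parameters / 2 x
#' log n), so that splits which merely overfit a genuinely Gaussian
#' component do not count. The chosen k is the largest candidate meeting all
#' three (k = 1 is the always-eligible baseline); if no candidate is
#' eligible the smallest candidate is returned with a warning status.
#'
#' @param cells standardized feature table or matrix.
#' @param k_range candidate component numbers (default 1:15).
#' @param seed integer seed.
#' @param alpha MANOVA significance level (default 0.05).
#' @param min_frac minimum fraction of cells per component (default 0.01).
#' @param ... passed to [fit_gmm()].
#' @return object of class `sl_gmm_selection`: the chosen `sl_gmm` in
#'   `$model`, the chosen `$k`, the full selection `$curve` (k, nll,
#'   manova_p, min component fraction, delta nll, tolerance, eligible) and a
#'   `$status` of `"ok"` or `"no_eligible_k"`.
#' @export
select_component_number <- function(cells, k_range = 1:15, seed = 1L,
                                    alpha = 0.05, min_frac = 0.01, ...) {
  x <- if (is.matrix(cells)) cells else feature_matrix(cells)
  k_range <- sort(unique(as.integer(k_range)))
  fits <- list()
  rows <- list()
  nll_prev <- NA_real_
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- fit_gmm(x, k, seed = seed, ...)
    fits[[i]] <- fit
    hard <- assign_cells(fit, x)$component
    frac <- min(tabulate(hard, nbins = k)) / nrow(x)
    p <- if (k >= 2) manova_pvalue(x, hard) else NA_real_
    delta <- if (i == 1) NA_real_ else nll_prev - fit$nll
    bic_tol <- if (i == 1) NA_real_ else
      (k - k_range[i - 1]) * (2 * ncol(x) + 1) / 2 * log(nrow(x))
    eligible <- if (k == 1) TRUE else {
      !is.na(p) && p < alpha && frac >= min_frac &&
        !is.na(delta) && delta > bic_tol
    }
    rows[[i]] <- tibble(
      k = k, nll = fit$nll, manova_p = p, min_component_frac = frac,
      delta_nll = delta, delta_tolerance = bic_tol, eligible = eligible
    )
    nll_prev <- fit$nll
  }
  curve <- bind_rows(rows)
  eligible_k <- curve$k[curve$eligible]
  if (length(eligible_k) == 0) {
    warn("no candidate k satisfied the selection criteria; returning the smallest")
    chosen <- k_range[1]
    status <- "no_eligible_k"
  } else {
    chosen <- max(eligible_k)
    status <- "ok"
  }
  structure(
    list(model = fits[[match(chosen, k_range)]], k = chosen, curve = curve,
         alpha = alpha, min_frac = min_frac, status = status),
    class = "sl_gmm_selection"
  )
}

#' @export
print.sl_gmm_selection <- function(x, ...) {
  cat(sprintf("<sl_gmm_selection> chosen k = %d (%s) over candidates %s\n",
              x$k, x$status, paste(range(x$curve$k), collapse = "..")))
  invisible(x)
}

#' Write a fitted mixture model to JSON
#'
#' @param model an `sl_gmm` or `sl_gmm_selection`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gmm_json <- function(model, path) {
  sel <- NULL
  if (inherits(model, "sl_gmm_selection")) {
    sel <- model$curve; model <- model$model
  }
  jsonlite::write_json(
    list(k = model$k, weights = model$weights,
         means = model$means, variances = model$variances,
         nll = model$nll, n = model$n, d = model$d,
         feature_names = model$feature_names,
         selection_curve = sel),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
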