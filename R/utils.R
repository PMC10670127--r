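#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported interaction ratios use
#' conventional half-up rounding (0.45 -> 0.5, -0.45 -> -0.5).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

# local RNG scope: runs code with a private seed, restores global RNG state
with_seed <- function(seed, code) {
  if (!is.null(old <- globalenv()$.Random.seed)) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# derive a stream-specific 31-bit seed from a master seed and a tag
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483562) + 1L
}

stopifnot_simplex <- function(w, tol = 1e-9, what = "weights") {
  if (any(w < -tol) || abs(sum(w) - 1) > tol) {
    abort(sprintf("%s must be a simplex vector (non-negative, summing to 1)", what))
  }
  invisible(TRUE)
}

# columns of a feature table that are feature measurements
feature_cols <- function(df) {
  meta <- c("cell_id", "condition", "time_h", "alive", ".component")
  setdiff(names(df), meta)
}

feature_matrix <- function(df) {
  as.matrix(df[, feature_cols(df), drop = FALSE])
}
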