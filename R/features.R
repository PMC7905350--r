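# Per-epoch PCA feature extraction and feature-matrix assembly.

#' Per-epoch PCA scores
#'
#' Principal component analysis fitted on a single epoch, treating channels
#' as observations and time points as variables: the epoch matrix is
#' column-mean-centered and projected onto its top `n_components` principal
#' directions (ordered by decreasing variance). Component signs are fixed by
#' making each score column's largest-magnitude entry positive: the score
#' columns are spatial (across-channel) patterns, which are stable from epoch
#' to epoch, so this convention makes features comparable across epochs (and
#' reproducible across SVD implementations); fixing signs on the time-domain
#' directions instead would leave each epoch's feature signs effectively
#' random.
#'
#' @param epoch Channels x points numeric matrix.
#' @param n_components Number of components to keep,
#'   `1 <= n_components <= channels - 1`.
#' @return List with `scores` (channels x n_components matrix) and
#'   `variance_ratio` (cumulative explained-variance fraction of the kept
#'   components). A constant epoch yields zero scores and ratio 1 with a
#'   warning.
#' @export
pca_epoch_features <- function(epoch, n_components) {
  stopifnot(is.matrix(epoch), is.numeric(epoch))
  ch <- nrow(epoch)
  if (n_components < 1L || n_components > ch - 1L) {
    stop("`n_components` must be between 1 and channels - 1")
  }
  xc <- sweep(epoch, 2L, colMeans(epoch), `-`)
  total_var <- sum(xc^2)
  if (total_var < .Machine$double.eps * length(xc)) {
    warning("constant epoch: zero variance; returning zero scores")
    return(list(scores = matrix(0, ch, n_components), variance_ratio = 1))
  }
  sv <- svd(xc, nu = 0, nv = n_components)
  scores <- xc %*% sv$v
  # sign convention: largest-|entry| of each score column (a spatial pattern)
  # made positive, so signs are anchored to the stable across-channel
  # structure rather than to an epoch-specific time course
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  ratio <- sum(sv$d[seq_len(n_components)]^2) / sum(sv$d^2)
  list(scores = scores, variance_ratio = ratio)
}

fit_norm_stats <- function(X, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  if (method == "minmax") {
    mn <- apply(X, 2L, min)
    mx <- apply(X, 2L, max)
    center <- (mx + mn) / 2
    scale <- (mx - mn) / 2
  } else {
    center <- colMeans(X)
    scale <- apply(X, 2L, stats::sd)
  }
  scale[scale < .Machine$double.eps] <- 1
  list(method = method, center = center, scale = scale)
}

apply_norm_stats <- function(X, norm_stats) {
  if (length(norm_stats$center) != ncol(X)) {
    stop("norm_stats dimensionality does not match the feature matrix")
  }
  sweep(sweep(X, 2L, norm_stats$center, `-`), 2L, norm_stats$scale, `/`)
}

#' Build a feature set from an epoch set
#'
#' Maps every epoch to a row-major (channel-major) flattened vector of its
#' per-epoch PCA scores, yielding an epochs x (channels * n_components)
#' matrix. With `normalize = TRUE` and no `norm_stats`, per-feature
#' normalization statistics are fitted on these rows (training mode, min-max
#' to \[-1, 1\] by default); with `norm_stats` supplied they are applied
#' without refitting (inference mode).
#'
#' @param epoch_set An [epoch_set()].
#' @param n_components PCA components kept per epoch (default 10).
#' @param normalize Normalize features (default `TRUE`).
#' @param norm_stats Previously fitted statistics, or `NULL` to fit.
#' @param method Normalization flavor, `"minmax"` (to \[-1, 1\]) or
#'   `"zscore"`.
#' @return A `FeatureSet`: list with `X` (feature matrix), `y` (labels),
#'   `variance_ratios`, `norm_stats`, and `params` describing the pipeline.
#' @export
build_features <- function(epoch_set, n_components = 10L, normalize = TRUE,
                           norm_stats = NULL, method = "minmax") {
  stopifnot(inherits(epoch_set, "EpochSet"))
  n <- length(epoch_set$epochs)
  if (n == 0L) stop("empty epoch set")
  ch <- nrow(epoch_set$epochs[[1L]])
  d <- ch * n_components
  X <- matrix(0, n, d)
  ratios <- numeric(n)
  for (i in seq_len(n)) {
    pf <- pca_epoch_features(epoch_set$epochs[[i]], n_components)
    X[i, ] <- as.vector(t(pf$scores))     # row-major: ch1 pc1..pcr, ch2 ...
    ratios[i] <- pf$variance_ratio
  }
  if (normalize) {
    if (is.null(norm_stats)) norm_stats <- fit_norm_stats(X, method)
    X <- apply_norm_stats(X, norm_stats)
  } else {
    norm_stats <- NULL
  }
  structure(
    list(X = X, y = epoch_set$labels, variance_ratios = ratios,
         norm_stats = norm_stats,
         params = list(channels = ch, n_components = as.integer(n_components),
                       rate = epoch_set$rate,
                       points_per_epoch = epoch_set$points_per_epoch)),
    class = "FeatureSet"
  )
}

#' @export
print.FeatureSet <- function(x, ...) {
  cat(sprintf("FeatureSet: %d epochs x %d features (%d fatigue / %d alert)%s\n",
              nrow(x$X), ncol(x$X),
              sum(x$y == 1L, na.rm = TRUE), sum(x$y == 0L, na.rm = TRUE),
              if (is.null(x$norm_stats)) ", unnormalized" else ""))
  invisible(x)
}

#' Subset a feature set by row indices
#'
#' @param fs A `FeatureSet`.
#' @param idx Integer row indices to keep.
#' @return A `FeatureSet` with the selected rows (normalization statistics
#'   and pipeline parameters carried over unchanged).
#' @export
subset_features <- function(fs, idx) {
  stopifnot(inherits(fs, "FeatureSet"))
  structure(
    list(X = fs$X[idx, , drop = FALSE], y = fs$y[idx],
         variance_ratios = fs$variance_ratios[idx],
         norm_stats = fs$norm_stats, params = fs$params),
    class = "FeatureSet"
  )
}
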