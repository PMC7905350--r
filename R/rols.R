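# Lower-level learner: Gaussian candidate construction and regularized
# orthogonal forward selection with a D-optimality selection cost.
#
# Model: y(k) = sum_i theta_i exp(-||x(k) - c_i||^2 / rho) + e(k), with every
# training input a candidate center. Selection works in an orthogonalized
# regressor space Phi = W A (W orthogonal columns, A unit upper triangular,
# g = A theta), greedily maximizing the combined error reduction ratio
#   crerr_i = ((w_i'w_i + lambda) g_i^2 + beta * log(w_i'w_i)) / (y'y),
# which is the decrease of the cost e'e + lambda g'g + beta * sum(-log w'w)
# obtained by admitting regressor i. Selection stops when no remaining
# candidate has positive crerr, when max_terms is reached, or when all
# usable candidates are selected.

# Cross squared Euclidean distances between rows of A and rows of B.
cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' Build the full Gaussian candidate model
#'
#' Every training input is a candidate center: `Phi[k, i] =
#' exp(-||x(k) - x(i)||^2 / rho)`, a symmetric matrix with unit diagonal.
#'
#' @param X N x d numeric feature matrix (N >= 2).
#' @param y Numeric target vector of length N (class labels coded 0/1).
#' @param rho Gaussian width rho > 0.
#' @return A `CandidateModel`: list with `Phi`, `centers`, `rho`, `y` and a
#'   `duplicates` flag set when identical inputs produce identical candidate
#'   columns.
#' @export
build_candidates <- function(X, y, rho) {
  if (!is.matrix(X)) X <- as.matrix(X)
  N <- nrow(X)
  stopifnot(N >= 2L, length(y) == N)
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0) {
    stop("`rho` must be a single positive number")
  }
  d2 <- cross_dist2(X, X)
  dup <- any(d2[upper.tri(d2)] < 1e-24)
  if (dup) warning("duplicate rows in X: identical candidate columns present")
  Phi <- exp(-d2 / rho)
  diag(Phi) <- 1
  structure(list(Phi = Phi, centers = X, rho = rho, y = as.numeric(y),
                 duplicates = dup),
            class = "CandidateModel")
}

#' Greedy regularized orthogonal forward selection
#'
#' Modified Gram-Schmidt forward selection over the candidate columns of
#' `model$Phi`. At every step each unselected column (already orthogonalized
#' against the chosen ones) competes on its combined error reduction ratio;
#' the maximizer is admitted (ties broken by lowest candidate index) and the
#' remaining columns are orthogonalized against it. Numerically collinear
#' candidates (squared norm below `1e-12 * trace(Phi'Phi)/N`) sit out the
#' step. A re-orthogonalization pass is applied to the winning column when
#' loss of orthogonality against the selected block exceeds `1e-10`.
#'
#' @param model A [build_candidates()] result.
#' @param lambda Ridge penalty on the orthogonal weights, lambda >= 0.
#' @param beta D-optimality weighting, beta >= 0.
#' @param max_terms Cap on the number of selected centers (default N).
#' @return A `SelectionTrace`: list with `selected` (ordered candidate
#'   indices), `W` (orthogonal columns), `A` (unit upper-triangular), `g`
#'   (orthogonal-space weights), `crerr` (per-step ratios), `lambda`, `beta`,
#'   `rho`, `n_s` and `stop_reason` (one of `"no_positive_crerr"`,
#'   `"max_terms"`, `"all_selected"`).
#' @export
forward_select <- function(model, lambda, beta, max_terms = NULL) {
  stopifnot(inherits(model, "CandidateModel"))
  if (lambda < 0 || beta < 0) stop("`lambda` and `beta` must be non-negative")
  Phi <- model$Phi
  y <- model$y
  N <- ncol(Phi)
  if (is.null(max_terms)) max_terms <- N
  if (max_terms < 1L || max_terms > N) stop("`max_terms` must be in [1, N]")
  yty <- sum(y^2)
  if (yty <= 0) stop("targets are all zero; crerr is undefined")

  R <- Phi                      # working columns, orthogonalized in place
  coef <- matrix(0, N, N)       # coef[j, i]: weight of w_j inside candidate i
  avail <- rep(TRUE, N)
  selected <- integer(0)
  g_sel <- numeric(0)
  crerr_sel <- numeric(0)
  col_tol <- 1e-12 * sum(Phi^2) / N
  stop_reason <- "all_selected"

  while (TRUE) {
    ns <- length(selected)
    if (ns >= max_terms) {
      stop_reason <- if (any(avail)) "max_terms" else "all_selected"
      break
    }
    idx <- which(avail)
    if (length(idx) == 0L) { stop_reason <- "all_selected"; break }
    ww <- colSums(R[, idx, drop = FALSE]^2)
    ok <- ww > col_tol
    if (!any(ok)) { stop_reason <- "all_selected"; break }
    idx <- idx[ok]; ww <- ww[ok]
    wy <- as.vector(crossprod(R[, idx, drop = FALSE], y))
    g <- wy / (ww + lambda)
    crerr <- ((ww + lambda) * g^2 + beta * log(ww)) / yty
    best <- which.max(crerr)    # first max <=> lowest candidate index on ties
    if (crerr[best] <= 0) { stop_reason <- "no_positive_crerr"; break }
    j <- idx[best]
    w <- R[, j]

    if (ns > 0L) {
      # unconditional re-orthogonalization pass on the winner: recovers the
      # orthogonality lost by accumulated MGS roundoff at negligible cost
      Wsel <- R_sel(R, selected)          # selected orthogonal columns
      corr <- as.vector(crossprod(Wsel, w)) / colSums(Wsel^2)
      w <- as.vector(w - Wsel %*% corr)
      coef[selected, j] <- coef[selected, j] + corr
      R[, j] <- w
    }
    ww_j <- sum(w^2)
    if (ww_j <= col_tol) { avail[j] <- FALSE; next }
    g_j <- sum(w * y) / (ww_j + lambda)

    selected <- c(selected, j)
    g_sel <- c(g_sel, g_j)
    crerr_sel <- c(crerr_sel, ((ww_j + lambda) * g_j^2 + beta * log(ww_j)) / yty)
    avail[j] <- FALSE
    rem <- which(avail)
    if (length(rem)) {
      prj <- as.vector(crossprod(R[, rem, drop = FALSE], w)) / ww_j
      R[, rem] <- R[, rem, drop = FALSE] - outer(as.vector(w), prj)
      coef[j, rem] <- prj
    }
  }

  ns <- length(selected)
  W <- if (ns) R_sel(R, selected) else matrix(0, N, 0)
  A <- diag(1, ns)
  if (ns > 1L) {
    for (l in 2:ns) A[1:(l - 1L), l] <- coef[selected[1:(l - 1L)], selected[l]]
  }
  structure(
    list(selected = selected, W = W, A = A, g = g_sel, crerr = crerr_sel,
         lambda = lambda, beta = beta, rho = model$rho, n_s = ns,
         stop_reason = stop_reason),
    class = "SelectionTrace"
  )
}

R_sel <- function(R, selected) R[, selected, drop = FALSE]

#' Recover network weights from a selection trace
#'
#' Solves the unit-upper-triangular system `A theta = g` by
#' back-substitution.
#'
#' @param trace A [forward_select()] result with at least one selected term.
#' @return Numeric weight vector theta (one entry per selected center).
#' @export
recover_weights <- function(trace) {
  stopifnot(inherits(trace, "SelectionTrace"))
  if (trace$n_s < 1L) stop("empty selection: no weights to recover")
  as.vector(backsolve(trace$A, trace$g))
}

#' Construct an RBF network object
#'
#' @param centers n_s x d matrix of selected centers.
#' @param rho Gaussian width.
#' @param theta Output weights (length n_s).
#' @param selected_indices Training-row indices of the centers (optional).
#' @param lambda,beta Hyperparameters the network was trained with.
#' @param pipeline_params Frozen feature-pipeline description (PCA components,
#'   normalization statistics, window, band), or `NULL`.
#' @return An object of class `RBFNetwork`.
#' @export
rbf_network <- function(centers, rho, theta, selected_indices = NULL,
                        lambda = NA_real_, beta = NA_real_,
                        pipeline_params = NULL) {
  centers <- as.matrix(centers)
  stopifnot(nrow(centers) >= 1L, length(theta) == nrow(centers),
            all(is.finite(theta)), rho > 0)
  structure(
    list(centers = centers, rho = as.numeric(rho), theta = as.numeric(theta),
         selected_indices = selected_indices, lambda = lambda, beta = beta,
         pipeline_params = pipeline_params, format_version = 1L),
    class = "RBFNetwork"
  )
}

#' @export
print.RBFNetwork <- function(x, ...) {
  cat(sprintf("RBFNetwork: %d centers in %d dims, rho = %g, lambda = %g, beta = %g\n",
              nrow(x$centers), ncol(x$centers), x$rho, x$lambda, x$beta))
  invisible(x)
}

#' Fit a sparse RBF network by regularized orthogonal forward selection
#'
#' Composition of [build_candidates()], [forward_select()] and
#' [recover_weights()]; the network's centers are the training inputs at the
#' selected indices.
#'
#' @inheritParams build_candidates
#' @inheritParams forward_select
#' @param pipeline_params Optional frozen feature-pipeline description to
#'   embed in the returned network.
#' @return List with `network` (an `RBFNetwork`) and `trace` (the
#'   `SelectionTrace`).
#' @export
rbf_fit <- function(X, y, lambda, rho, beta, max_terms = NULL,
                    pipeline_params = NULL) {
  model <- build_candidates(X, y, rho)
  trace <- forward_select(model, lambda, beta, max_terms)
  if (trace$n_s == 0L) {
    stop("forward selection chose no terms (all crerr <= 0): ",
         "lower `beta` or raise `max_terms`")
  }
  theta <- recover_weights(trace)
  net <- rbf_network(model$centers[trace$selected, , drop = FALSE],
                     rho, theta, trace$selected, lambda, beta,
                     pipeline_params)
  list(network = net, trace = trace)
}
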