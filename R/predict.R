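# Network evaluation and the binary decision rule.

#' Continuous network output
#'
#' Evaluates `y(x) = sum_i theta_i exp(-||x - c_i||^2 / rho)` for each row of
#' the feature matrix.
#'
#' @param object An `RBFNetwork`.
#' @param newdata m x d feature matrix (d must match the centers).
#' @param ... Unused.
#' @return Numeric vector of m continuous outputs.
#' @export
predict.RBFNetwork <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != ncol(object$centers)) {
    stop(sprintf("feature dimension %d does not match network dimension %d",
                 ncol(X), ncol(object$centers)))
  }
  K <- exp(-cross_dist2(X, object$centers) / object$rho)
  as.vector(K %*% object$theta)
}

#' Binary classification at the 0.5 threshold
#'
#' Label 1 (fatigue) iff the continuous network output is strictly greater
#' than 0.5; the boundary value 0.5 itself maps to 0 (alert).
#'
#' @param net An `RBFNetwork`.
#' @param X m x d feature matrix.
#' @return Integer vector of 0/1 labels.
#' @export
classify <- function(net, X) {
  as.integer(predict(net, X) > 0.5)
}
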