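# Two-level learning hierarchy: particle swarm search over the three learner
# hyperparameters at the upper level; each candidate triple is scored by
# training the orthogonal-forward-selection RBF learner on the training set
# and measuring mean squared error of the continuous outputs on the
# validation set (the lower level).

#' Build a fitness context for the two-level trainer
#'
#' @param train_fs Training `FeatureSet` (N rows).
#' @param val_fs Validation `FeatureSet` (n_c rows, n_c >= 1).
#' @param max_terms Cap on selected centers at the lower level
#'   (default N, the training-set size).
#' @return A `FitnessContext` with an internal evaluation counter.
#' @export
fitness_context <- function(train_fs, val_fs, max_terms = NULL) {
  stopifnot(inherits(train_fs, "FeatureSet"), inherits(val_fs, "FeatureSet"))
  if (ncol(train_fs$X) != ncol(val_fs$X)) {
    stop("training and validation feature dimensions differ")
  }
  if (nrow(val_fs$X) < 1L) stop("validation set is empty")
  if (is.null(max_terms)) max_terms <- nrow(train_fs$X)
  ctx <- new.env(parent = emptyenv())
  ctx$train <- train_fs
  ctx$val <- val_fs
  ctx$max_terms <- as.integer(max_terms)
  ctx$evaluations <- 0L
  class(ctx) <- "FitnessContext"
  ctx
}

#' Validation-MSE fitness of one hyperparameter triple
#'
#' Trains the lower-level learner on the context's training set with
#' `K = c(lambda, rho, beta)` and returns the mean squared error of the
#' continuous network outputs against the 0/1 validation labels. An empty
#' selection (no positive crerr) is penalized with `+Inf` rather than
#' aborting the search.
#'
#' @param K Numeric vector `c(lambda, rho, beta)` (names optional).
#' @param ctx A [fitness_context()].
#' @return Validation MSE (scalar), or `+Inf` when the learner selects no
#'   terms.
#' @export
tllh_fitness <- function(K, ctx) {
  stopifnot(inherits(ctx, "FitnessContext"), length(K) == 3L)
  ctx$evaluations <- ctx$evaluations + 1L
  fitted <- tryCatch(
    rbf_fit(ctx$train$X, ctx$train$y, lambda = K[[1L]], rho = K[[2L]],
            beta = K[[3L]], max_terms = ctx$max_terms),
    error = function(e) NULL
  )
  if (is.null(fitted)) return(Inf)
  out <- predict(fitted$network, ctx$val$X)
  mean((ctx$val$y - out)^2)
}

#' Train an RBF classifier with the two-level learning hierarchy
#'
#' Runs [pso_optimize()] over [tllh_fitness()], then refits the lower-level
#' learner on the training set at the best hyperparameters and returns that
#' network with the feature pipeline parameters frozen inside it. Supplying
#' `fixed` (a list with `lambda`, `rho`, `beta`) bypasses the swarm search
#' entirely and trains a single network at those values — the
#' fixed-hyperparameter baseline pathway (e.g. `rho = 110`, `beta = 1e-4`
#' with a user-chosen `lambda`).
#'
#' @param train_fs,val_fs Training and validation `FeatureSet`s (disjoint
#'   rows).
#' @param space Hyperparameter [search_space()]
#'   (default [default_hyper_space()]).
#' @param swarm_size,iterations Swarm size p and iteration count T
#'   (defaults 15 and 30).
#' @param max_terms Cap on selected centers (default: training-set size).
#' @param seed Integer RNG seed for the swarm.
#' @param fixed Optional list `list(lambda=, rho=, beta=)` to skip the search.
#' @param ... Further arguments passed to [pso_optimize()].
#' @return List with `network` (an `RBFNetwork`), `best_K` (named vector),
#'   `best_fitness` (validation MSE at `best_K`), `history` (swarm
#'   global-best trace, `NULL` in fixed mode), `evaluations` (lower-level
#'   fits performed) and `trace` (the final network's `SelectionTrace`).
#' @export
tllh_train <- function(train_fs, val_fs, space = default_hyper_space(),
                       swarm_size = 15L, iterations = 30L, max_terms = NULL,
                       seed = 1L, fixed = NULL, ...) {
  ctx <- fitness_context(train_fs, val_fs, max_terms)
  pipeline_params <- c(train_fs$params,
                       list(norm_stats = train_fs$norm_stats))

  if (!is.null(fixed)) {
    stopifnot(all(c("lambda", "rho", "beta") %in% names(fixed)))
    best_K <- c(lambda = fixed$lambda, rho = fixed$rho, beta = fixed$beta)
    history <- NULL
    best_fitness <- tllh_fitness(best_K, ctx)
    if (!is.finite(best_fitness)) {
      stop("fixed hyperparameters yield an empty selection")
    }
  } else {
    res <- pso_optimize(function(K) tllh_fitness(K, ctx), space,
                        p = swarm_size, iterations = iterations,
                        seed = seed, ...)
    if (!is.finite(res$value)) {
      stop("every particle in every iteration was penalized; ",
           "no trainable hyperparameters found in the search space")
    }
    best_K <- res$par
    history <- res$history
    best_fitness <- res$value
  }

  fitted <- rbf_fit(train_fs$X, train_fs$y,
                    lambda = best_K[["lambda"]], rho = best_K[["rho"]],
                    beta = best_K[["beta"]], max_terms = ctx$max_terms,
                    pipeline_params = pipeline_params)
  list(network = fitted$network, best_K = best_K,
       best_fitness = best_fitness, history = history,
       evaluations = ctx$evaluations, trace = fitted$trace)
}
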