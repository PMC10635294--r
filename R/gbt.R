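#' Gradient-boosted-tree classifier
#'
#' Multinomial deviance boosting with depth-limited least-squares regression
#' trees: per iteration and per class a tree is fitted to the softmax
#' residual on a row subsample, and leaves carry the one-step Newton update
#' scaled by the learning rate.  Defaults follow the production setting
#' (n_estimators = 20000, learning_rate = 0.05, max_depth = 7,
#' subsample = 0.4, min_samples_split = 3, max_features = "sqrt"); reduce
#' `n_estimators` for interactive work.
#'
#' @param x feature matrix (samples x components), no missing values
#' @param y class labels (>= 2 classes present)
#' @param n_estimators boosting iterations
#' @param learning_rate shrinkage per iteration
#' @param max_depth maximum tree depth
#' @param subsample row fraction drawn (without replacement) per tree
#' @param min_samples_split minimum node size eligible for splitting
#' @param max_features `"sqrt"` or an integer count of features examined
#'   per node
#' @param seed RNG seed (subsampling and per-node feature draws)
#' @return object of class `toplap_gbt`
#' @export
gbt_train <- function(x, y, n_estimators = 20000, learning_rate = 0.05,
                      max_depth = 7, subsample = 0.4,
                      min_samples_split = 3, max_features = "sqrt",
                      seed = 1) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("features contain missing values")
  y <- as.character(y)
  classes <- sort(unique(y))
  ord <- match(y, classes)
  k <- length(classes)
  if (k < 2) stop("training set has a single class")
  n <- nrow(x)
  p <- ncol(x)
  mf <- if (identical(max_features, "sqrt")) {
    max(1L, floor(sqrt(p)))
  } else as.integer(max_features)
  Y <- matrix(0, n, k)
  Y[cbind(seq_len(n), ord)] <- 1
  prior <- pmax(colMeans(Y), 1e-12)
  F0 <- log(prior)
  F <- matrix(F0, n, k, byrow = TRUE)
  leaf_scale <- if (k == 2) 1 else (k - 1) / k
  set.seed(seed)
  trees <- vector("list", n_estimators)
  nsub <- max(2L, round(subsample * n))
  for (m in seq_len(n_estimators)) {
    P <- exp(F - apply(F, 1, max))
    P <- P / rowSums(P)
    rows <- sort(sample.int(n, nsub))
    iter_trees <- vector("list", k)
    for (cl in seq_len(k)) {
      g <- Y[, cl] - P[, cl]
      h <- pmax(P[, cl] * (1 - P[, cl]), 1e-12)
      tr <- fit_tree_cpp(x, g, h, rows, as.integer(max_depth),
                         as.integer(min_samples_split), mf, leaf_scale,
                         sample.int(.Machine$integer.max, 1))
      F[, cl] <- F[, cl] + learning_rate * predict_tree_cpp(tr, x)
      iter_trees[[cl]] <- tr
    }
    trees[[m]] <- iter_trees
  }
  structure(list(classes = classes, F0 = F0, trees = trees,
                 learning_rate = learning_rate, n_features = p,
                 n_estimators = n_estimators,
                 version = "toplap_gbt/1"),
            class = "toplap_gbt")
}

#' @export
print.toplap_gbt <- function(x, ...) {
  cat(sprintf("gradient-boosted trees: %d iterations x %d classes, %d features\n",
              x$n_estimators, length(x$classes), x$n_features))
  invisible(x)
}

gbt_decision <- function(object, x) {
  x <- as.matrix(x)
  if (ncol(x) != object$n_features) stop("feature width mismatch")
  k <- length(object$classes)
  F <- matrix(object$F0, nrow(x), k, byrow = TRUE)
  for (iter in object$trees) {
    for (cl in seq_len(k)) {
      F[, cl] <- F[, cl] + object$learning_rate *
        predict_tree_cpp(iter[[cl]], x)
    }
  }
  F
}

#' Predict classes or class probabilities
#'
#' @param object fitted `toplap_gbt`
#' @param newdata feature matrix
#' @param type `"class"` or `"prob"`
#' @param ... unused
#' @export
predict.toplap_gbt <- function(object, newdata, type = c("class", "prob"),
                               ...) {
  type <- match.arg(type)
  F <- gbt_decision(object, newdata)
  P <- exp(F - apply(F, 1, max))
  P <- P / rowSums(P)
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  object$classes[max.col(P, ties.method = "first")]
}

#' Serialize a fitted model to a single artifact with a version stamp
#' @param model fitted `toplap_gbt`
#' @param path output file
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "toplap_gbt"))
  saveRDS(list(format = "toplap-model", version = model$version,
               model = model), path)
  invisible(path)
}

#' Load a model written by [save_model()]
#' @param path input file
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "toplap-model")) stop("not a toplap model file")
  obj$model
}

#' Train the solubility-change classifier on a labeled dataset
#'
#' Thin wrapper over [gbt_train()] with the production hyperparameters,
#' kept as the module-level entry point.
#'
#' @param x feature matrix
#' @param y labels in \{-, N, +\} (or any >= 2 classes)
#' @param hyperparameters list of overrides for [gbt_train()]
#' @param seed RNG seed
#' @export
train_classifier <- function(x, y, hyperparameters = list(), seed = 1) {
  do.call(gbt_train, c(list(x = x, y = y, seed = seed), hyperparameters))
}
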