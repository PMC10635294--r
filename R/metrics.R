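SOL_CLASSES <- c("-", "N", "+")

#' Confusion matrix of true vs predicted solubility classes
#'
#' Entry (i, j) counts samples of true class i predicted as class j.
#'
#' @param truth,pred vectors of class labels
#' @param classes label set fixing the row/column order (default the three
#'   solubility classes: decrease, no change, increase)
#' @return K x K matrix
#' @export
confusion_matrix <- function(truth, pred, classes = SOL_CLASSES) {
  truth <- factor(truth, levels = classes)
  pred <- factor(pred, levels = classes)
  if (anyNA(truth) || anyNA(pred)) stop("labels outside the class set")
  unclass(table(truth = truth, pred = pred))
}

#' One-vs-rest counts for a class
#'
#' @param cm K x K confusion matrix (true rows, predicted columns)
#' @param class_index row/column index of the class
#' @return named vector (TP, TN, FP, FN)
#' @export
per_class_counts <- function(cm, class_index) {
  i <- class_index
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

#' Rescale confusion-matrix rows to equal class mass
#'
#' Row i is multiplied by (N/K)/x_i where x_i is the class-i sample count,
#' so every true class carries the same weight; the total is preserved.
#' Row-internal ratios (sensitivity, specificity) are unchanged, which is
#' what makes this the normalization consistent with paired raw/normalized
#' reporting.
#'
#' @param cm K x K confusion matrix with positive row sums
#' @export
normalize_confusion <- function(cm) {
  x <- rowSums(cm)
  if (any(x == 0)) stop("cannot normalize: empty class row")
  n <- sum(cm)
  k <- nrow(cm)
  sweep(cm, 1, (n / k) / x, "*")
}

safe_ratio <- function(num, den) {
  if (den == 0) structure(0, undefined = TRUE) else num / den
}

metrics_one <- function(cm) {
  n <- sum(cm)
  k <- nrow(cm)
  per_class <- t(vapply(seq_len(k), function(i) {
    ct <- per_class_counts(cm, i)
    c(PPV = as.numeric(safe_ratio(ct["TP"], ct["TP"] + ct["FP"])),
      NPV = as.numeric(safe_ratio(ct["TN"], ct["TN"] + ct["FN"])),
      sensitivity = as.numeric(safe_ratio(ct["TP"], ct["TP"] + ct["FN"])),
      specificity = as.numeric(safe_ratio(ct["TN"], ct["TN"] + ct["FP"])))
  }, numeric(4)))
  rownames(per_class) <- rownames(cm) %||% as.character(seq_len(k))
  x <- rowSums(cm)
  y <- colSums(cm)
  e <- outer(x, y) / n
  nz <- e > 0
  chi2 <- sum((cm[nz] - e[nz])^2 / e[nz])
  list(per_class = per_class,
       CPR = sum(diag(cm)) / n,
       GC2 = chi2 / (n * (k - 1)))
}

#' Raw and normalized multiclass performance metrics
#'
#' Per-class positive/negative predictive value, sensitivity and
#' specificity, plus the overall correct prediction ratio
#' CPR = tr(z)/N and the generalized squared correlation
#' GC2 = chi^2 / (N (K - 1)) with expected counts e_ij = x_i y_j / N.
#' Every metric is reported twice: on the raw matrix and on the
#' row-normalized matrix of [normalize_confusion()].  0/0 ratios are
#' reported as 0.
#'
#' @param cm K x K confusion matrix
#' @return object of class `metrics_report`
#' @export
metrics <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix")
  raw <- metrics_one(cm)
  norm <- metrics_one(normalize_confusion(cm))
  structure(list(raw = raw, normalized = norm, confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("multiclass metrics (raw/normalized)\n")
  pc <- x$raw$per_class
  pn <- x$normalized$per_class
  for (m in colnames(pc)) {
    cat(sprintf("%-12s", m))
    for (i in seq_len(nrow(pc))) {
      cat(sprintf("  %s %.3f/%.3f", rownames(pc)[i], pc[i, m], pn[i, m]))
    }
    cat("\n")
  }
  cat(sprintf("CPR         %.3f/%.3f\n", x$raw$CPR, x$normalized$CPR))
  cat(sprintf("GC2         %.3f/%.3f\n", x$raw$GC2, x$normalized$GC2))
  invisible(x)
}

stratified_folds <- function(y, folds) {
  idx <- integer(length(y))
  for (cl in unique(y)) {
    members <- which(y == cl)
    if (length(members) < folds) {
      stop("class '", cl, "' has fewer members than folds")
    }
    idx[members] <- sample(rep_len(seq_len(folds), length(members)))
  }
  idx
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repeat the data are partitioned into stratified folds, a
#' classifier is trained on each training split, and the per-fold test
#' predictions are pooled into one confusion matrix per repeat (pooling,
#' not per-fold metric averaging, keeps GC2 unbiased at small fold sizes).
#' Reported metrics are means over repeats; per-repeat reports are
#' retained.
#'
#' @param x feature matrix (samples x components)
#' @param y class labels
#' @param folds,repeats cross-validation shape (default 10 x 10)
#' @param seed RNG seed governing folds and model fits
#' @param hyperparameters list passed to [gbt_train()] (use a reduced
#'   `n_estimators` for exploratory runs)
#' @return list with `mean` (CPR/GC2 raw and normalized), `per_repeat`
#'   (list of `metrics_report`), and `fold_assignments`
#' @export
cross_validate <- function(x, y, folds = 10, repeats = 10, seed = 1,
                           hyperparameters = list()) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- intersect(SOL_CLASSES, unique(y))
  if (length(classes) == 0) classes <- sort(unique(y))
  set.seed(seed)
  reports <- vector("list", repeats)
  assignments <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold_id <- stratified_folds(y, folds)
    assignments[[r]] <- fold_id
    pred <- character(length(y))
    for (f in seq_len(folds)) {
      test <- fold_id == f
      fit <- do.call(gbt_train, c(list(x = x[!test, , drop = FALSE],
                                       y = y[!test],
                                       seed = seed * 1000L + r * 100L + f),
                                  hyperparameters))
      pred[test] <- predict(fit, x[test, , drop = FALSE])
    }
    reports[[r]] <- metrics(confusion_matrix(y, pred, classes = classes))
  }
  mean_of <- function(fun) mean(vapply(reports, fun, 0))
  list(
    mean = list(
      CPR_raw = mean_of(function(r) r$raw$CPR),
      CPR_normalized = mean_of(function(r) r$normalized$CPR),
      GC2_raw = mean_of(function(r) r$raw$GC2),
      GC2_normalized = mean_of(function(r) r$normalized$GC2)
    ),
    per_repeat = reports,
    fold_assignments = assignments
  )
}
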