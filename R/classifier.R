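# rank-based AUC: probability that a positive score outranks a negative one,
# ties counted half (equivalent to the Mann-Whitney statistic)
rank_auc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

fit_minmax <- function(x) {
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  list(lo = lo, rng = rng)
}

apply_minmax <- function(x, scaler) {
  sweep(sweep(x, 2L, scaler$lo, "-"), 2L, scaler$rng, "/")
}

impute_median <- function(train, test) {
  med <- apply(train, 2L, stats::median, na.rm = TRUE)
  for (j in seq_len(ncol(train))) {
    train[is.na(train[, j]), j] <- med[j]
    test[is.na(test[, j]), j] <- med[j]
  }
  list(train = train, test = test)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lev in unique(y)) {
    ix <- sample(which(y == lev))
    fold[ix] <- rep_len(sample(k), length(ix))
  }
  fold
}

# oriented decision scores: higher = more evidence for `positive`
decision_scores <- function(model, newdata, positive) {
  pred <- stats::predict(model, newdata, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  first <- strsplit(colnames(dv), "/", fixed = TRUE)[[1L]][1L]
  s <- as.numeric(dv[, 1L])
  if (first != positive) s <- -s
  list(class = pred, score = s)
}

binary_metrics <- function(truth, pred, positive) {
  pos <- truth == positive
  tp <- sum(pred == positive & pos)
  fp <- sum(pred == positive & !pos)
  fn <- sum(pred != positive & pos)
  tn <- sum(pred != positive & !pos)
  precision <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
  recall <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  f1 <- if (is.na(precision) || precision + recall == 0) NA_real_ else
    2 * precision * recall / (precision + recall)
  c(accuracy = (tp + tn) / length(truth), precision = precision,
    recall = recall, f1 = f1, uar = (recall + spec) / 2)
}

#' Repeated stratified cross-validated linear SVM
#'
#' Discriminates patients from controls with a linear-kernel support vector
#' machine over repeated stratified k-fold cross-validation. In every fold
#' the min-max scaler (and the median imputation of missing values) is fit
#' on the training folds only and applied to the test fold, so no test
#' information leaks into preprocessing. Per iteration the out-of-fold
#' decision scores are pooled for the AUC and the out-of-fold class
#' predictions give accuracy, precision, recall, F1 and UAR (macro recall);
#' the report carries the mean and SD of each metric across iterations plus
#' the coefficient-based feature importance.
#'
#' @param x numeric feature matrix (rows = participants).
#' @param y factor or character label vector.
#' @param positive label of the positive (patient) class; default
#'   `"patient"` if present, else the first label.
#' @param k number of folds (default 5).
#' @param iterations number of re-randomized fold splits (default 1000).
#' @param cost SVM regularization parameter C (default 1).
#' @param seed RNG seed for the fold splits; reports are byte-identical
#'   under the same seed.
#' @return an object of class `svm_cv_report`: list with `metrics` (mean/SD
#'   per metric), `importance` (ranked mean absolute coefficients),
#'   `auc_per_iteration`, `iterations`, `k`, `seed`.
#' @export
run_repeated_cv <- function(x, y, positive = NULL, k = 5L,
                            iterations = 1000L, cost = 1, seed = NULL) {
  x <- as.matrix(x)
  y <- as.character(y)
  levs <- unique(y)
  if (length(levs) < 2L) stop("single-class input", call. = FALSE)
  if (length(levs) > 2L) stop("binary classification only", call. = FALSE)
  if (is.null(positive)) {
    positive <- if ("patient" %in% levs) "patient" else levs[1L]
  }
  if (min(table(y)) < k) {
    stop("fold count k exceeds the size of the smallest class",
         call. = FALSE)
  }
  if (any(is.na(x))) {
    message("missing feature values present; imputing by training-fold median")
  }
  if (!is.null(seed)) set.seed(seed)
  metric_names <- c("auc", "accuracy", "precision", "recall", "f1", "uar")
  per_iter <- matrix(NA_real_, iterations, length(metric_names),
                     dimnames = list(NULL, metric_names))
  W <- matrix(0, iterations * k, ncol(x))
  colnames(W) <- colnames(x)
  wrow <- 0L
  for (it in seq_len(iterations)) {
    fold <- stratified_folds(y, k)
    scores <- numeric(length(y))
    preds <- character(length(y))
    for (f in seq_len(k)) {
      tr <- fold != f
      imp <- impute_median(x[tr, , drop = FALSE], x[!tr, , drop = FALSE])
      scaler <- fit_minmax(imp$train)
      xtr <- apply_minmax(imp$train, scaler)
      xte <- apply_minmax(imp$test, scaler)
      model <- e1071::svm(xtr, factor(y[tr]), kernel = "linear",
                          cost = cost, scale = FALSE)
      ds <- decision_scores(model, xte, positive)
      scores[!tr] <- ds$score
      preds[!tr] <- as.character(ds$class)
      wrow <- wrow + 1L
      W[wrow, ] <- crossprod(model$coefs, model$SV)
    }
    per_iter[it, "auc"] <- rank_auc(scores, y == positive)
    per_iter[it, -1L] <- binary_metrics(y, preds, positive)
  }
  metrics <- data.frame(
    metric = metric_names,
    mean = colMeans(per_iter, na.rm = TRUE),
    sd = apply(per_iter, 2L, stats::sd, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(metrics = metrics, importance = feature_importance(W),
         auc_per_iteration = per_iter[, "auc"], iterations = iterations,
         k = k, seed = seed, positive = positive),
    class = "svm_cv_report"
  )
}

#' @export
print.svm_cv_report <- function(x, ...) {
  cat(sprintf("<svm_cv_report> %d iterations x %d folds (positive = %s)\n",
              x$iterations, x$k, x$positive))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-9s %.3f", m$metric[i], m$mean[i]))
    if (is.finite(m$sd[i])) cat(sprintf(" ± %.3f", m$sd[i]))
    cat("\n")
  }
  cat("  top features:",
      paste(utils::head(x$importance$feature, 4L), collapse = ", "), "\n")
  invisible(x)
}

#' Coefficient-based feature importance of linear SVMs
#'
#' Importance of a feature is the mean absolute value of its weight across
#' all fitted linear models (folds times iterations); the preceding min-max
#' scaling makes the weights comparable across features.
#'
#' @param W matrix of linear SVM weight vectors, one row per fitted model.
#' @return a `data.frame` with `feature`, `importance`, `rank`, sorted by
#'   decreasing importance.
#' @export
feature_importance <- function(W) {
  W <- as.matrix(W)
  imp <- colMeans(abs(W))
  nm <- colnames(W)
  if (is.null(nm)) nm <- paste0("f", seq_along(imp))
  out <- data.frame(feature = nm, importance = unname(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Hold-out generalizability evaluation
#'
#' Trains the scaler and the linear SVM once on the full training split and
#' evaluates once on the hold-out participants — no cross-validation, no
#' refitting. Training and test participants must be disjoint.
#'
#' @param train_x,train_y training features and labels (the main sample).
#' @param test_x,test_y hold-out features and labels.
#' @param train_ids,test_ids optional participant ids, checked for overlap.
#' @param positive positive-class label (see [run_repeated_cv()]).
#' @param cost SVM regularization parameter.
#' @return an `svm_cv_report` with a single evaluation (SDs are `NA`).
#' @export
generalizability_eval <- function(train_x, train_y, test_x, test_y,
                                  train_ids = NULL, test_ids = NULL,
                                  positive = NULL, cost = 1) {
  if (!is.null(train_ids) && !is.null(test_ids) &&
      length(intersect(train_ids, test_ids))) {
    stop("leakage: participant ids overlap between train and test splits",
         call. = FALSE)
  }
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  train_y <- as.character(train_y); test_y <- as.character(test_y)
  levs <- unique(train_y)
  if (length(levs) != 2L) stop("binary classification only", call. = FALSE)
  if (is.null(positive)) {
    positive <- if ("patient" %in% levs) "patient" else levs[1L]
  }
  imp <- impute_median(train_x, test_x)
  scaler <- fit_minmax(imp$train)
  xtr <- apply_minmax(imp$train, scaler)
  xte <- apply_minmax(imp$test, scaler)
  model <- e1071::svm(xtr, factor(train_y), kernel = "linear",
                      cost = cost, scale = FALSE)
  ds <- decision_scores(model, xte, positive)
  met <- c(auc = rank_auc(ds$score, test_y == positive),
           binary_metrics(test_y, as.character(ds$class), positive))
  W <- crossprod(model$coefs, model$SV)
  colnames(W) <- colnames(train_x)
  structure(
    list(metrics = data.frame(metric = names(met), mean = unname(met),
                              sd = NA_real_, stringsAsFactors = FALSE),
         importance = feature_importance(W),
         auc_per_iteration = met[["auc"]], iterations = 1L, k = NA_integer_,
         seed = NULL, positive = positive),
    class = "svm_cv_report"
  )
}

#' Build a binary patient-vs-control task from a feature table
#'
#' @param features feature `data.frame` with a `group` column.
#' @param patient_group which patient group to contrast with `"HC"`.
#' @param feature_cols feature columns (default the eight speech features).
#' @return list with matrix `x`, label vector `y` (`"patient"` / `"HC"`),
#'   and `ids`.
#' @export
build_task <- function(features, patient_group = c("AD", "bvFTD"),
                       feature_cols = FEATURE_COLS) {
  patient_group <- match.arg(patient_group)
  keep <- features$group %in% c(patient_group, "HC")
  sub <- features[keep, , drop = FALSE]
  list(
    x = as.matrix(sub[, feature_cols, drop = FALSE]),
    y = ifelse(sub$group == "HC", "HC", "patient"),
    ids = sub$participant_id
  )
}
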