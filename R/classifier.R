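#' Stratified train/test split
#'
#' Splits the feature table per density class, reproducibly by seed; the
#' remainder row of a fractional split goes to the training set
#' (`n_train = ceiling(train_frac * n_class)`).
#'
#' @param table feature table with a `density` column.
#' @param train_frac training fraction in (0, 1) (default 0.7).
#' @param seed integer seed.
#' @return list with data frames `train` and `test`.
#' @export
split_stratified <- function(table, train_frac = 0.7, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  g <- factor(table$density)
  if (any(tabulate(g) < 2)) stop("every class needs at least 2 rows")
  set.seed(as.integer(seed))
  train_idx <- integer(0)
  for (cl in levels(g)) {
    idx <- which(g == cl)
    n_train <- ceiling(train_frac * length(idx))
    train_idx <- c(train_idx, sample(idx, n_train))
  }
  list(train = table[sort(train_idx), , drop = FALSE],
       test = table[setdiff(seq_len(nrow(table)), train_idx), , drop = FALSE])
}

#' Fit a multinomial logistic-regression density model
#'
#' Features are standardized on training statistics (constant features are
#' dropped with a warning); class probabilities use a softmax link with
#' reference class `a`, maximum-likelihood fitting with a small L2 ridge
#' (`nnet::multinom` with `decay = ridge`) for separable-data stability.
#'
#' @param train training feature table.
#' @param features feature column names to use.
#' @param ridge L2 penalty (default 1e-4).
#' @param maxit iteration cap (default 500).
#' @return object of class `density_mlr`: `coefficients` ((K-1) x (features+1)
#'   matrix), `features`, `classes`, `reference`, `center`/`scale`
#'   standardization vectors, `ridge`, `converged`.
#' @export
fit_multinomial_lr <- function(train, features, ridge = 1e-4, maxit = 500L) {
  g <- droplevels(factor(train$density))
  if (nlevels(g) < 2) stop("need at least 2 classes in the training set")
  X <- as.matrix(train[features])
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  keep <- scl > 0
  if (!all(keep)) {
    warning("dropping constant feature(s): ",
            paste(features[!keep], collapse = ", "))
    features <- features[keep]
    X <- X[, keep, drop = FALSE]
    ctr <- ctr[keep]; scl <- scl[keep]
  }
  Z <- scale(X, center = ctr, scale = scl)
  df <- data.frame(.y = g, Z, check.names = FALSE)
  fit <- nnet::multinom(.y ~ ., data = df, decay = ridge, maxit = maxit,
                        trace = FALSE, reltol = 1e-12, abstol = 1e-10)
  B <- stats::coef(fit)
  if (is.null(dim(B))) B <- matrix(B, nrow = 1,
                                   dimnames = list(levels(g)[2], names(B)))
  structure(
    list(coefficients = B, features = features, classes = levels(g),
         reference = levels(g)[1], center = ctr, scale = scl, ridge = ridge,
         converged = fit$convergence == 0),
    class = "density_mlr")
}

#' Predict class probabilities and labels
#'
#' Softmax over the linear scores of the standardized features; the predicted
#' label is the argmax with ties broken by class order a < b < c < d.
#'
#' @param model a [fit_multinomial_lr()] result.
#' @param newdata feature table containing the model's feature columns.
#' @return list: `prob` (rows x classes matrix, rows summing to 1) and
#'   `class` (factor of predicted labels).
#' @export
predict_proba <- function(model, newdata) {
  missing <- setdiff(model$features, colnames(newdata))
  if (length(missing) > 0)
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  Z <- scale(as.matrix(newdata[model$features]),
             center = model$center, scale = model$scale)
  eta <- cbind(0, Z %*% t(model$coefficients[, -1, drop = FALSE])) +
    rep(c(0, model$coefficients[, 1]), each = nrow(Z))
  eta <- eta - apply(eta, 1, max)
  prob <- exp(eta) / rowSums(exp(eta))
  colnames(prob) <- model$classes
  cls <- factor(model$classes[apply(prob, 1, which.max)],
                levels = model$classes)
  list(prob = prob, class = cls)
}

#' Confusion matrix (rows = true class, columns = predicted)
#'
#' @param true,predicted equal-length label vectors.
#' @param labels class order (default a-d).
#' @return integer K x K matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(true, predicted,
                             labels = density_classes()) {
  if (length(true) != length(predicted)) stop("length mismatch")
  if (!all(c(as.character(true), as.character(predicted)) %in% labels))
    stop("unknown class label")
  tt <- table(factor(true, levels = labels),
              factor(predicted, levels = labels))
  m <- matrix(as.integer(tt), nrow = length(labels),
              dimnames = list(true = labels, predicted = labels))
  structure(m, class = c("confusion_matrix", "matrix"))
}

as_confusion <- function(m) {
  structure(as.matrix(m), class = c("confusion_matrix", "matrix"))
}

#' Per-class recall and overall accuracy of a confusion matrix
#'
#' `recall(k) = 100 * cm[k, k] / rowsum(k)` (reported additionally rounded to
#' one decimal); `overall = 100 * trace / total`. An empty true-class row
#' yields `NA` recall.
#'
#' @param cm a K x K confusion matrix (rows = true class).
#' @return list: `recall` (named, percent), `recall_rounded`, `overall`
#'   (percent), `n` (grand total).
#' @export
classification_metrics <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  rs <- rowSums(cm)
  recall <- ifelse(rs > 0, 100 * diag(cm) / rs, NA_real_)
  names(recall) <- rownames(cm)
  list(recall = recall, recall_rounded = round(recall, 1),
       overall = 100 * sum(diag(cm)) / total, n = total)
}

#' Fit and evaluate the density classifier on a feature table
#'
#' Convenience wrapper: stratified split, fit on the training part, confusion
#' matrices and metrics on both parts (training accuracy and test-set
#' confusion are reported separately, clearly labelled).
#'
#' @inheritParams split_stratified
#' @inheritParams fit_multinomial_lr
#' @return list: `model`, `split`, `train_metrics`, `test_metrics`,
#'   `train_confusion`, `test_confusion`.
#' @export
evaluate_classifier <- function(table, features, train_frac = 0.7, seed = 1L,
                                ridge = 1e-4) {
  sp <- split_stratified(table, train_frac, seed)
  model <- fit_multinomial_lr(sp$train, features, ridge = ridge)
  cm_tr <- confusion_matrix(sp$train$density,
                            predict_proba(model, sp$train)$class,
                            labels = model$classes)
  cm_te <- confusion_matrix(sp$test$density,
                            predict_proba(model, sp$test)$class,
                            labels = model$classes)
  list(model = model, split = sp,
       train_confusion = cm_tr, test_confusion = cm_te,
       train_metrics = classification_metrics(cm_tr),
       test_metrics = classification_metrics(cm_te))
}

#' Save a fitted density model as JSON
#'
#' Stores coefficients, standardization parameters and configuration so a run
#' is self-describing.
#'
#' @param model a [fit_multinomial_lr()] result.
#' @param path JSON path.
#' @export
write_density_model <- function(model, path) {
  jsonlite::write_json(
    list(coefficients = model$coefficients, features = model$features,
         classes = model$classes, reference = model$reference,
         center = model$center, scale = model$scale, ridge = model$ridge,
         converged = model$converged),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
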