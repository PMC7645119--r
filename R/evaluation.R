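#' Confusion matrix
#'
#' @param truth,predicted Class labels (coerced to the union of levels when
#'   `classes` is not given).
#' @param classes Optional ordered class names.
#' @return Integer g x g matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (is.null(classes))
    classes <- union(levels(as.factor(truth)), levels(as.factor(predicted)))
  t <- factor(truth, levels = classes)
  p <- factor(predicted, levels = classes)
  m <- table(truth = t, predicted = p)
  matrix(as.integer(m), nrow = length(classes),
         dimnames = list(truth = classes, predicted = classes))
}

#' Accuracy and macro-averaged recall, precision and F1
#'
#' Accuracy is the trace over the total.  Per class (one-vs-rest):
#' recall `TP / (TP + FN)`, precision `TP / (TP + FP)`, F1 their harmonic
#' mean; macro scores are unweighted means over classes.  A class never
#' predicted gets precision 0 (and F1 0); a class absent from the truth
#' gets recall 0.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @return Named list: `accuracy`, `macro_recall`, `macro_precision`,
#'   `macro_f1`.
#' @export
macro_metrics <- function(cm) {
  total <- sum(cm)
  if (total == 0L) stop("empty confusion matrix")
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  list(accuracy = sum(tp) / total, macro_recall = mean(recall),
       macro_precision = mean(precision), macro_f1 = mean(f1))
}

# Stratified fold assignment: within each class, shuffled ids are dealt
# round-robin across folds (fold order rotated per class so sizes balance).
stratified_folds <- function(labels, folds) {
  labels <- as.factor(labels)
  counts <- table(labels)
  if (any(counts < folds))
    stop("class(es) smaller than the fold count: ",
         paste(names(counts)[counts < folds], collapse = ", "))
  assign <- integer(length(labels))
  offset <- 0L
  for (cl in levels(labels)) {
    rows <- sample(which(labels == cl))
    assign[rows] <- ((seq_along(rows) - 1L + offset) %% folds) + 1L
    offset <- offset + length(rows)
  }
  assign
}

unstratified_folds <- function(n, folds) {
  rows <- sample(n)
  assign <- integer(n)
  assign[rows] <- ((seq_len(n) - 1L) %% folds) + 1L
  assign
}

# One leakage-safe fold: every data-dependent state (duplicate-column
# removal, scaler, selection, SMOTE) is fitted on the training rows only.
fit_fold <- function(fm_all, labels, train_rows, test_rows, selection_k,
                     alpha, smote_k, ens_config, seed) {
  train <- new_feature_matrix(fm_all$data[train_rows, , drop = FALSE])
  train <- drop_duplicate_columns(train)
  scaler <- fit_scaler(train)
  train <- apply_scaler(scaler, train)
  sel <- select_k_best(train, labels[train_rows], K = selection_k,
                       alpha = alpha)
  train <- apply_selection(sel, train)
  sm <- smote_resample(train, labels[train_rows], k = smote_k, seed = seed)
  ens <- fit_ensemble(sm$features$data, sm$labels, ens_config, seed = seed)

  test <- new_feature_matrix(fm_all$data[test_rows, , drop = FALSE])
  test <- project_columns(test, scaler$columns)
  test <- apply_scaler(scaler, test)
  test <- apply_selection(sel, test)
  vote <- predict(ens, test$data)
  list(predicted = ens$classes[vote$class], K = sel$K)
}

#' Repeated stratified k-fold cross-validation of the full pipeline
#'
#' Per iteration the data are shuffled with an iteration-specific seed and
#' split into stratified folds; per fold, duplicate-column removal, min-max
#' scaling, ANOVA/BH feature selection, SMOTE and the three-model ensemble
#' are fitted on the training part only and evaluated on the held-out part.
#'
#' @param records `data.frame` with `id`, `seq` (cleaned).
#' @param labels Class labels, one per record.
#' @param descriptor_config A [descriptor_config()].
#' @param ens_config An [ensemble_config()].
#' @param folds Number of folds (default 6).
#' @param iterations Number of repetitions (default 100).
#' @param base_seed Integer; iteration i uses `base_seed + i`.
#' @param selection_k,alpha Passed to [select_k_best()].
#' @param smote_k SMOTE neighbour count.
#' @param stratified Use stratified folds (default TRUE; the published
#'   splits were random, but tiny classes can then vanish from folds).
#' @return A `cv_report`: per-fold `data.frame` (`iteration`, `fold`,
#'   `accuracy`, `macro_recall`, `macro_precision`, `macro_f1`, `auto_K`),
#'   plus `aggregate` (mean and sd per metric) and the seeds used.
#' @export
repeated_cv <- function(records, labels,
                        descriptor_config = cellopt::descriptor_config(),
                        ens_config = ensemble_config(), folds = 6L,
                        iterations = 100L, base_seed = 1L,
                        selection_k = "auto", alpha = 0.05, smote_k = 5L,
                        stratified = TRUE) {
  labels <- droplevels(as.factor(labels))
  stopifnot(nrow(records) == length(labels))
  fm_all <- featurize(records, descriptor_config)
  rows_out <- vector("list", iterations * folds)
  k <- 1L
  for (iter in seq_len(iterations)) {
    seed <- base_seed + iter
    assign <- with_seed(seed, {
      if (stratified) stratified_folds(labels, folds)
      else unstratified_folds(length(labels), folds)
    })
    for (f in seq_len(folds)) {
      test_rows <- which(assign == f)
      train_rows <- which(assign != f)
      fit <- fit_fold(fm_all, labels, train_rows, test_rows, selection_k,
                      alpha, smote_k, ens_config, seed = seed * folds + f)
      cm <- confusion_matrix(labels[test_rows], fit$predicted,
                             classes = levels(labels))
      met <- macro_metrics(cm)
      rows_out[[k]] <- data.frame(iteration = iter, fold = f,
                                  accuracy = met$accuracy,
                                  macro_recall = met$macro_recall,
                                  macro_precision = met$macro_precision,
                                  macro_f1 = met$macro_f1, auto_K = fit$K)
      k <- k + 1L
    }
  }
  per_fold <- do.call(rbind, rows_out)
  metrics <- c("accuracy", "macro_recall", "macro_precision", "macro_f1")
  aggregate <- data.frame(metric = metrics,
                          mean = vapply(per_fold[metrics], mean, 0),
                          sd = vapply(per_fold[metrics], sd, 0),
                          row.names = NULL)
  structure(list(per_fold = per_fold, aggregate = aggregate,
                 folds = folds, iterations = iterations,
                 base_seed = base_seed, stratified = stratified),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d iterations x %d folds (base seed %d)\n",
              x$iterations, x$folds, x$base_seed))
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}

#' Write a CV report (per-fold TSV plus JSON aggregate)
#'
#' @param report A `cv_report`.
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return The two paths, invisibly.
#' @export
write_cv_report <- function(report, prefix) {
  tsv <- paste0(prefix, ".tsv"); js <- paste0(prefix, ".json")
  write.table(report$per_fold, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(aggregate = report$aggregate,
                            folds = report$folds,
                            iterations = report$iterations,
                            base_seed = report$base_seed),
                       js, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(tsv, js))
}
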