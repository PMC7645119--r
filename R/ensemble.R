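#' Ensemble configuration
#'
#' Defaults are the published base-learner settings: MLP with two hidden
#' layers of 200 ReLU units trained with Adam; random forest with 200 trees
#' and information gain; RBF-kernel SVM with probability calibration.
#' Voting weights default to equal (the published weights are not stated).
#'
#' @param mlp,rf,svm Named lists of overrides for [fit_mlp()], [fit_rf()],
#'   [fit_svm()] arguments.
#' @param vote_weights Three non-negative reals (MLP, RF, SVM).
#' @return An `ensemble_config` list.
#' @export
ensemble_config <- function(mlp = list(), rf = list(), svm = list(),
                            vote_weights = c(1, 1, 1)) {
  stopifnot(length(vote_weights) == 3L, all(vote_weights >= 0),
            sum(vote_weights) > 0)
  mlp_def <- list(hidden = c(200L, 200L), epochs = 500L,
                  learning_rate = 1e-3, l2 = 1e-4, val_fraction = 0.1,
                  patience = 25L)
  rf_def <- list(ntree = 200L, mtry = NULL, min_node = 1L)
  svm_def <- list(C = 1, gamma = "scale")
  structure(list(mlp = modifyList(mlp_def, mlp),
                 rf = modifyList(rf_def, rf),
                 svm = modifyList(svm_def, svm),
                 vote_weights = vote_weights),
            class = "ensemble_config")
}

#' Fit the soft-voting ensemble on a prepared feature matrix
#'
#' Fits the MLP, random forest and SVM on identical (scaled, selected,
#' resampled) data.  Deterministic given `seed`: each learner gets a fixed
#' offset of it.
#'
#' @param x Numeric matrix (scaled, selected, resampled training rows).
#' @param y Class labels.
#' @param config An [ensemble_config()].
#' @param seed Integer seed.
#' @return A `cellopt_ensemble` with the three fitted models and weights.
#' @export
fit_ensemble <- function(x, y, config = ensemble_config(), seed = NULL) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("ensemble needs at least 2 classes")
  if (any(!is.finite(x))) stop("non-finite feature values")
  if (nrow(x) < 6L) stop("ensemble needs at least 6 training rows")
  seeds <- if (is.null(seed)) list(NULL, NULL, NULL)
           else as.list(seed + 1:3)
  mlp <- do.call(fit_mlp, c(list(x = x, y = y, seed = seeds[[1]]),
                            config$mlp))
  rf <- do.call(fit_rf, c(list(x = x, y = y, seed = seeds[[2]]), config$rf))
  svm <- do.call(fit_svm, c(list(x = x, y = y, seed = seeds[[3]]),
                            config$svm))
  structure(list(models = list(mlp = mlp, rf = rf, svm = svm),
                 classes = levels(y), weights = config$vote_weights),
            class = "cellopt_ensemble")
}

#' Weighted soft vote over per-model class probabilities
#'
#' Combines probability vectors (or matrices, one row per record) as
#' `sum(w_m * p_m) / sum(w)` and takes the argmax, ties resolved toward the
#' lowest class index.
#'
#' @param probas List of probability vectors/matrices over the same classes.
#' @param weights Non-negative weights, one per model.
#' @return `list(class = integer index/vector, proba = combined vector or
#'   matrix)`.
#' @export
soft_vote <- function(probas, weights = rep(1, length(probas))) {
  stopifnot(length(probas) == length(weights), all(weights >= 0))
  if (sum(weights) <= 0) stop("weight sum must be positive")
  mats <- lapply(probas, function(p)
    if (is.matrix(p)) p else matrix(p, nrow = 1))
  dims <- vapply(mats, ncol, 0L)
  if (length(unique(dims)) != 1L) stop("probability length mismatch")
  bad <- vapply(mats, function(p) any(abs(rowSums(p) - 1) > 1e-6), TRUE)
  if (any(bad)) stop("input probabilities must sum to 1")
  comb <- Reduce(`+`, Map(function(p, w) p * w, mats, weights)) /
    sum(weights)
  cls <- apply(comb, 1, which.max)  # which.max takes the first maximum
  if (!is.matrix(probas[[1]])) comb <- comb[1, ]
  list(class = cls, proba = comb)
}

ensemble_proba <- function(ensemble, x) {
  lapply(ensemble$models, function(m) predict(m, x))
}

#' @export
predict.cellopt_ensemble <- function(object, newdata, ...) {
  probas <- ensemble_proba(object, newdata)
  soft_vote(probas, object$weights)
}

# ---- model bundle --------------------------------------------------------

#' Assemble a prediction-ready model bundle
#'
#' A bundle carries everything needed to predict from raw sequences:
#' descriptor configuration, post-dedup training column set, fitted scaler
#' and selection states, the three classifiers, voting weights and seeds.
#'
#' @param task `"temperature"` or `"pH"`.
#' @param ensemble A fitted `cellopt_ensemble`.
#' @param scaler A `scaler_state`.
#' @param selection A `selection_state`.
#' @param columns Training column names after duplicate removal.
#' @param descriptor_config The [descriptor_config()] used for training.
#' @param config Echo of the [ensemble_config()].
#' @param seed Training seed.
#' @return A `model_bundle`.
#' @export
model_bundle <- function(task, ensemble, scaler, selection, columns,
                         descriptor_config, config, seed = NULL) {
  stopifnot(task %in% c("temperature", "pH"),
            inherits(ensemble, "cellopt_ensemble"))
  structure(list(task = task, classes = ensemble$classes,
                 ensemble = ensemble, scaler = scaler,
                 selection = selection, columns = columns,
                 descriptor_config = descriptor_config, config = config,
                 seed = seed, version = "1"),
            class = "model_bundle")
}

#' Predict optimum-temperature or pH classes for protein records
#'
#' Featurizes, projects to the training columns, scales, selects, computes
#' per-model probabilities and soft-votes.  Records too short for the
#' descriptor configuration get an error note instead of a prediction;
#' the others are still processed.  Output order equals input order.
#'
#' @param object A `model_bundle`.
#' @param newdata `data.frame` with `id`, `seq` (cleaned amino-acid
#'   sequences).
#' @param ... Unused.
#' @return `data.frame` with `id`, `label`, `note` and one probability
#'   column per class; attribute `"per_model"` holds each model's matrix.
#' @export
predict.model_bundle <- function(object, newdata, ...) {
  n <- nrow(newdata)
  need <- config_min_length(object$descriptor_config)
  ok <- nchar(newdata$seq) >= need
  out <- data.frame(id = newdata$id, label = NA_character_,
                    note = ifelse(ok, "", sprintf(
                      "sequence shorter than descriptor minimum (%d)", need)),
                    stringsAsFactors = FALSE)
  pcols <- matrix(NA_real_, n, length(object$classes),
                  dimnames = list(NULL, paste0("p_", object$classes)))
  per_model <- NULL
  if (any(ok)) {
    fm <- featurize(newdata[ok, , drop = FALSE], object$descriptor_config)
    fm <- project_columns(fm, object$columns)
    fm <- apply_scaler(object$scaler, fm)
    fm <- apply_selection(object$selection, fm)
    probas <- ensemble_proba(object$ensemble, fm$data)
    vote <- soft_vote(probas, object$ensemble$weights)
    out$label[ok] <- object$classes[vote$class]
    pcols[ok, ] <- vote$proba
    per_model <- probas
  }
  out <- cbind(out, as.data.frame(pcols))
  attr(out, "per_model") <- per_model
  out
}

#' Save / load a model bundle
#'
#' Bundles are serialized with R's native format plus a JSON metadata
#' sidecar (task, classes, column counts, seeds) for provenance.
#'
#' @param bundle A `model_bundle`.
#' @param path Output `.rds` path.
#' @return `path` (`save_bundle`) or the restored bundle (`load_bundle`).
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  saveRDS(bundle, path)
  meta <- list(task = bundle$task, classes = bundle$classes,
               n_columns = length(bundle$columns),
               K = bundle$selection$K, seed = bundle$seed,
               version = bundle$version)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  bundle <- readRDS(path)
  if (!inherits(bundle, "model_bundle")) stop("not a model bundle: ", path)
  bundle
}
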