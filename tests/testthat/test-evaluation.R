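test_that("macro metrics follow the one-vs-rest formulas", {
  cm <- confusion_matrix(rep(c("a", "b", "c"), each = 4),
                         rep(c("a", "b", "c"), each = 4))
  m <- macro_metrics(cm)
  expect_equal(unlist(m), c(accuracy = 1, macro_recall = 1,
                            macro_precision = 1, macro_f1 = 1))

  # hand computation: cm [[5,0],[5,0]]
  cm <- matrix(c(5L, 5L, 0L, 0L), 2, 2,
               dimnames = list(truth = c("x", "y"),
                               predicted = c("x", "y")))
  m <- macro_metrics(cm)
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$macro_recall, 0.5)        # recall 1.0 and 0.0
  expect_equal(m$macro_precision, 0.25)    # precision 0.5, class y never predicted -> 0
  expect_equal(m$macro_f1, 1 / 3)          # f1 2/3 and 0

  expect_error(macro_metrics(matrix(0L, 2, 2)), "empty")
})

test_that("macro metrics are invariant to class relabeling", {
  set.seed(40)
  truth <- sample(c("a", "b", "c"), 60, replace = TRUE)
  pred <- sample(c("a", "b", "c"), 60, replace = TRUE)
  m1 <- macro_metrics(confusion_matrix(truth, pred, c("a", "b", "c")))
  swap <- c(a = "c", b = "a", c = "b")
  m2 <- macro_metrics(confusion_matrix(swap[truth], swap[pred],
                                       c("a", "b", "c")))
  expect_equal(m1, m2)
})

test_that("uniform random predictions score near chance", {
  set.seed(41)
  truth <- rep(c("a", "b", "c"), each = 1000)
  pred <- sample(c("a", "b", "c"), 3000, replace = TRUE)
  m <- macro_metrics(confusion_matrix(truth, pred, c("a", "b", "c")))
  expect_lt(abs(m$accuracy - 1 / 3), 0.03)
})

test_that("stratified folds partition records and respect class balance", {
  set.seed(42)
  labels <- factor(rep(c("a", "b", "c"), c(18, 12, 6)))
  assign <- cellopt:::stratified_folds(labels, 6)
  expect_equal(length(assign), 36)
  expect_true(all(assign %in% 1:6))
  for (f in 1:6) {
    expect_equal(sum(assign == f), 6)
    expect_equal(sum(assign == f & labels == "c"), 1)  # smallest class spread
  }
  expect_error(cellopt:::stratified_folds(factor(rep(c("a", "b"), c(10, 3))),
                                          6), "b")
})

test_that("repeated_cv is deterministic and leakage-safe", {
  ds <- generate_labeled_dataset(synthetic_spec(n_per_class = 12,
                                                length_range = c(60L, 120L),
                                                seed = 27))
  cfg <- light_ensemble()

  seen_scaler <- list(); seen_select <- list(); seen_smote <- list()
  real_fit_scaler <- fit_scaler
  real_select <- select_k_best
  real_smote <- smote_resample
  testthat::local_mocked_bindings(
    fit_scaler = function(train) {
      seen_scaler[[length(seen_scaler) + 1]] <<- rownames(train$data)
      real_fit_scaler(train)
    },
    select_k_best = function(train, labels, K = "auto", alpha = 0.05) {
      seen_select[[length(seen_select) + 1]] <<- rownames(train$data)
      real_select(train, labels, K, alpha)
    },
    smote_resample = function(features, labels, k = 5L, seed = NULL) {
      seen_smote[[length(seen_smote) + 1]] <<- rownames(features$data)
      real_smote(features, labels, k, seed)
    },
    .package = "cellopt")

  rep1 <- repeated_cv(ds$records, ds$labels, ens_config = cfg, folds = 3,
                      iterations = 2, base_seed = 7)
  expect_equal(nrow(rep1$per_fold), 6)
  expect_true(all(rep1$per_fold$accuracy >= 0 & rep1$per_fold$accuracy <= 1))

  # leakage check: per iteration, the rows hidden from every fitted state
  # partition the dataset (each record tested exactly once), and all three
  # states saw identical training rows
  all_ids <- ds$records$id
  expect_length(seen_scaler, 6)
  for (i in seq_along(seen_scaler)) {
    expect_identical(seen_scaler[[i]], seen_select[[i]])
    expect_identical(seen_scaler[[i]], seen_smote[[i]])
  }
  for (iter in 1:2) {
    held_out <- lapply(seen_scaler[(iter - 1) * 3 + 1:3],
                       function(tr) setdiff(all_ids, tr))
    expect_setequal(unlist(held_out), all_ids)
    expect_equal(sum(lengths(held_out)), length(all_ids))
  }
})

test_that("repeated_cv runs are reproducible under the same base seed", {
  ds <- generate_labeled_dataset(synthetic_spec(n_per_class = 9,
                                                length_range = c(60L, 100L),
                                                seed = 29))
  cfg <- ensemble_config(mlp = list(hidden = c(8L), epochs = 40L),
                         rf = list(ntree = 20L))
  r1 <- repeated_cv(ds$records, ds$labels, ens_config = cfg, folds = 3,
                    iterations = 1, base_seed = 13)
  r2 <- repeated_cv(ds$records, ds$labels, ens_config = cfg, folds = 3,
                    iterations = 1, base_seed = 13)
  expect_identical(r1$per_fold, r2$per_fold)

  expect_error(repeated_cv(ds$records, ds$labels, ens_config = cfg,
                           folds = 10, iterations = 1), "smaller than")
})
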