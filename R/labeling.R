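TEMP_CLASSES <- c("mesophilic", "thermophilic", "hyperthermophilic")
PH_CLASSES <- c("acidic", "neutral", "alkaline")

#' Classify an optimum temperature
#'
#' `t < 50` is mesophilic, `50 <= t < 75` thermophilic, `t >= 75`
#' hyper-thermophilic.  The published inequalities are strict on both sides;
#' this package closes the lower bound of each upper class so every value
#' gets a label.
#'
#' @param t_opt Numeric vector of optimum temperatures in degrees Celsius.
#' @return Factor with levels mesophilic, thermophilic, hyperthermophilic.
#' @export
label_temperature <- function(t_opt) {
  stopifnot(all(is.finite(t_opt)))
  cut(t_opt, breaks = c(-Inf, 50, 75, Inf), labels = TEMP_CLASSES,
      right = FALSE)
}

#' Classify an optimum pH
#'
#' `ph < 5` is acidic, `5 <= ph < 8` neutral, `ph >= 8` alkaline
#' (same boundary convention as [label_temperature()]).
#'
#' @param ph_opt Numeric vector of optimum pH values in `[0, 14]`.
#' @return Factor with levels acidic, neutral, alkaline.
#' @export
label_ph <- function(ph_opt) {
  if (any(!is.finite(ph_opt)) || any(ph_opt < 0 | ph_opt > 14))
    stop("pH optima must lie in [0, 14]")
  cut(ph_opt, breaks = c(-Inf, 5, 8, Inf), labels = PH_CLASSES, right = FALSE)
}

#' Balance classes with SMOTE oversampling
#'
#' For each minority class, synthetic rows are generated until every class
#' reaches the majority-class count.  Each synthetic row is
#' `x + u * (nn - x)` where `x` is a uniformly chosen minority row, `nn` one
#' of its `k` nearest same-class neighbours (Euclidean distance, `k`
#' reduced to class size - 1 when needed) and `u ~ Uniform(0, 1)`.  Original
#' rows are preserved, in order; synthetic rows are appended with generated
#' ids `SMOTE_<class>_<i>`.
#'
#' @param features A `feature_matrix`.
#' @param labels Factor (or coercible) of class labels, one per row.
#' @param k Neighbour count (default 5).
#' @param seed Integer seed; same seed gives identical output.
#' @return `list(features = feature_matrix, labels = factor)` plus a
#'   `"report"` attribute with per-class before/after counts.
#' @export
smote_resample <- function(features, labels, k = 5L, seed = NULL) {
  stopifnot(inherits(features, "feature_matrix"), k >= 1L)
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  x <- features$data
  stopifnot(nrow(x) == length(labels))
  counts <- table(labels)
  if (any(counts < 2L))
    stop("class(es) with a single member cannot be oversampled (untrainable): ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  target <- max(counts)
  with_seed(seed, {
    syn_rows <- list(); syn_labels <- character(0)
    for (cl in names(counts)) {
      need <- target - counts[[cl]]
      if (need == 0L) next
      rows <- which(labels == cl)
      xc <- x[rows, , drop = FALSE]
      d <- as.matrix(dist(xc))
      diag(d) <- Inf
      keff <- min(k, length(rows) - 1L)
      nn <- vapply(seq_len(nrow(d)),
                   function(i) order(d[i, ])[seq_len(keff)], integer(keff))
      nn <- matrix(nn, nrow = keff)  # keff x class-size
      for (s in seq_len(need)) {
        i <- sample.int(length(rows), 1L)
        j <- nn[sample.int(keff, 1L), i]
        u <- runif(1)
        syn_rows[[length(syn_rows) + 1L]] <- xc[i, ] + u * (xc[j, ] - xc[i, ])
        syn_labels <- c(syn_labels, cl)
      }
    }
    if (length(syn_rows)) {
      syn <- do.call(rbind, syn_rows)
      rownames(syn) <- paste0("SMOTE_", syn_labels, "_",
                              seq_along(syn_labels))
      out_x <- rbind(x, syn)
      out_labels <- factor(c(as.character(labels), syn_labels),
                           levels = levels(labels))
    } else {
      out_x <- x
      out_labels <- labels
    }
    fm <- new_feature_matrix(out_x, c(features$provenance, sprintf(
      "smote:k=%d,added %d rows", k, length(syn_labels))))
    out <- list(features = fm, labels = out_labels)
    attr(out, "report") <- data.frame(class = names(counts),
                                      before = as.integer(counts),
                                      after = as.integer(table(out_labels)))
    out
  })
}
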