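#' One-way ANOVA F statistic of columns against class labels
#'
#' For each column, `F = (SSB / (g - 1)) / (SSW / (n - g))` with the p-value
#' from the upper tail of `F(g - 1, n - g)`.  Degenerate cases follow the
#' contract: zero between-group sum of squares gives `F = 0, p = 1`; zero
#' within-group sum of squares with signal gives `F = Inf, p = 0`.
#'
#' @param x Numeric vector or matrix (columns scored independently).
#' @param labels Class labels, one per observation.
#' @return For a vector, `c(f_stat, p_value)`; for a matrix, a `data.frame`
#'   with `name`, `f_stat`, `p_value`.
#' @export
anova_f <- function(x, labels) {
  labels <- as.factor(droplevels(as.factor(labels)))
  g <- nlevels(labels)
  vec <- !is.matrix(x)
  m <- if (vec) matrix(x, ncol = 1, dimnames = list(NULL, "x")) else x
  n <- nrow(m)
  if (g < 2L) stop("anova_f needs at least 2 classes")
  if (n <= g) stop("anova_f needs more observations than classes")
  stopifnot(length(labels) == n)
  counts <- as.vector(table(labels))
  gsum <- rowsum(m, labels)                      # g x p group sums
  gmean <- gsum / counts
  grand <- colMeans(m)
  ssb <- colSums(counts * (gmean - rep(grand, each = g))^2)
  ssw <- colSums((m - gmean[as.integer(labels), , drop = FALSE])^2)
  sst <- ssb + ssw
  f <- numeric(ncol(m)); p <- numeric(ncol(m))
  tol <- .Machine$double.eps^0.5 * pmax(sst, 1)
  null_col <- ssb <= tol
  sep_col <- !null_col & ssw <= tol
  ok <- !null_col & !sep_col
  f[null_col] <- 0; p[null_col] <- 1
  f[sep_col] <- Inf; p[sep_col] <- 0
  f[ok] <- (ssb[ok] / (g - 1)) / (ssw[ok] / (n - g))
  p[ok] <- pf(f[ok], g - 1, n - g, lower.tail = FALSE)
  if (vec) c(f_stat = f, p_value = p)
  else data.frame(name = colnames(m), f_stat = f, p_value = p,
                  row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min over j >= i of m * p_(j) / j`, capped at 1, returned in the
#' original order.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Vector of adjusted q-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  o <- order(p_values)
  q_sorted <- pmin(1, rev(cummin(rev(m * p_values[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Select the K best descriptors by ANOVA F score
#'
#' Scores every column with [anova_f()], BH-adjusts the p-values, and keeps
#' the `K` columns with the largest F (ties broken by column order).  With
#' `K = "auto"`, `K` is the number of columns with `q < alpha`, floored at
#' 10 (or the column count, if smaller) so the model never goes empty.
#'
#' @param train A `feature_matrix`.
#' @param labels Class labels, one per row.
#' @param K Integer or `"auto"`.
#' @param alpha FDR level for the `"auto"` rule (default 0.05).
#' @return A `selection_state`: kept column names (ordered by the original
#'   column order), `K`, `alpha`, and the full score table.
#' @export
select_k_best <- function(train, labels, K = "auto", alpha = 0.05) {
  stopifnot(inherits(train, "feature_matrix"))
  if (nrow(train$data) != length(labels))
    stop("label/row mismatch: ", nrow(train$data), " rows vs ",
         length(labels), " labels")
  scores <- anova_f(train$data, labels)
  scores$q_value <- bh_adjust(scores$p_value)
  scores$rank <- rank(-scores$f_stat, ties.method = "first")
  if (identical(K, "auto")) {
    K <- sum(scores$q_value < alpha)
    K <- max(K, min(10L, ncol(train$data)))
  }
  K <- as.integer(K)
  if (K < 1L || K > ncol(train$data))
    stop("K must be in [1, ", ncol(train$data), "]")
  keep_idx <- order(-scores$f_stat, seq_len(nrow(scores)))[seq_len(K)]
  keep <- scores$name[sort(keep_idx)]
  scores$kept <- scores$name %in% keep
  structure(list(keep = keep, K = K, alpha = alpha, scores = scores),
            class = "selection_state")
}

#' Project a feature matrix onto selected columns
#'
#' @param state A `selection_state` from [select_k_best()].
#' @param m A `feature_matrix` containing at least the selected columns.
#' @return The reduced `feature_matrix`.
#' @export
apply_selection <- function(state, m) {
  stopifnot(inherits(state, "selection_state"))
  project_columns(m, state$keep)
}

#' Write a feature-score table as TSV
#'
#' @param state A `selection_state`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(state, path) {
  write.table(state$scores, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
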