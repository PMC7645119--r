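
# ---- embedded constant tables -------------------------------------------
# 5-group amino-acid classification used by GAAC/GDPC.
AA_GROUPS5 <- list(
  aliphatic = c("G", "A", "V", "L", "M", "I"),
  aromatic  = c("F", "Y", "W"),
  positive  = c("K", "R", "H"),
  negative  = c("D", "E"),
  uncharged = c("S", "T", "C", "P", "N", "Q"))

# Classic 7-attribute, 3-group partitions of the alphabet for CTD
# (hydrophobicity; normalized van der Waals volume; polarity;
# polarizability; charge; secondary structure; solvent accessibility).
CTD_GROUPS <- list(
  hydrophobicity = c(g1 = "RKEDQN", g2 = "GASTPHY", g3 = "CLVIMFW"),
  vdwvolume      = c(g1 = "GASTPDC", g2 = "NVEQIL", g3 = "MHKFRYW"),
  polarity       = c(g1 = "LIFWCMVY", g2 = "PATGS", g3 = "HQRKNED"),
  polarizability = c(g1 = "GASDT", g2 = "CPNVEQIL", g3 = "KMHFRYW"),
  charge         = c(g1 = "KR", g2 = "ANCQGHILMFPSTWYV", g3 = "DE"),
  secondarystruct = c(g1 = "EALMQKRH", g2 = "VIYCWFT", g3 = "GNPSD"),
  solventaccess  = c(g1 = "ALFCGIVW", g2 = "RKQEND", g3 = "MSPTHY"))

# Conjoint-triad 7-class grouping (dipole / side-chain volume classes).
CT_CLASSES <- list(c("A", "G", "V"), c("I", "L", "F", "P"),
                   c("Y", "M", "T", "S"), c("H", "N", "Q", "W"),
                   c("R", "K"), c("D", "E"), c("C"))

# Pseudo amino-acid composition property scales: hydrophobicity (Tanford),
# hydrophilicity (Hopp-Woods) and side-chain mass, in AA20 order.
PAAC_SCALES <- list(
  hydrophobicity = c(A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19,
                     G = 0.48, H = -0.40, I = 1.38, K = -1.50, L = 1.06,
                     M = 0.64, N = -0.78, P = 0.12, Q = -0.85, R = -2.53,
                     S = -0.18, T = -0.05, V = 1.08, W = 0.81, Y = 0.26),
  hydrophilicity = c(A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5,
                     G = 0.0, H = -0.5, I = -1.8, K = 3.0, L = -1.8,
                     M = -1.3, N = 0.2, P = 0.0, Q = 0.2, R = 3.0,
                     S = 0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3),
  sidechainmass  = c(A = 15, C = 47, D = 59, E = 73, F = 91, G = 1,
                     H = 82, I = 57, K = 73, L = 57, M = 75, N = 58,
                     P = 42, Q = 72, R = 101, S = 31, T = 45, V = 43,
                     W = 130, Y = 107))

# Atom counts (C, H, N, O, S) of the free amino acids, from their molecular
# formulas (e.g. glycine C2H5NO2).
ATOM_COUNTS <- rbind(
  A = c(3, 7, 1, 2, 0),  C = c(3, 7, 1, 2, 1),  D = c(4, 7, 1, 4, 0),
  E = c(5, 9, 1, 4, 0),  F = c(9, 11, 1, 2, 0), G = c(2, 5, 1, 2, 0),
  H = c(6, 9, 3, 2, 0),  I = c(6, 13, 1, 2, 0), K = c(6, 14, 2, 2, 0),
  L = c(6, 13, 1, 2, 0), M = c(5, 11, 1, 2, 1), N = c(4, 8, 2, 3, 0),
  P = c(5, 9, 1, 2, 0),  Q = c(5, 10, 2, 3, 0), R = c(6, 14, 4, 2, 0),
  S = c(3, 7, 1, 3, 0),  T = c(4, 9, 1, 3, 0),  V = c(5, 11, 1, 2, 0),
  W = c(11, 12, 2, 2, 0), Y = c(9, 11, 1, 3, 0))
colnames(ATOM_COUNTS) <- c("C", "H", "N", "O", "S")

# Bond convention (documented package choice): rings per residue (proline
# plus the aromatics), total bonds = atoms - 1 + rings for a connected
# molecule, localized double bonds = backbone carboxyl C=O plus side-chain
# C=O / C=N (D, E, N, Q, R), aromatic ring count F/Y/H = 1, W = 2 (aromatic
# ring edges are counted with the single bonds).
RING_COUNTS <- c(A = 0, C = 0, D = 0, E = 0, F = 1, G = 0, H = 1, I = 0,
                 K = 0, L = 0, M = 0, N = 0, P = 1, Q = 0, R = 0, S = 0,
                 T = 0, V = 0, W = 2, Y = 1)
DOUBLE_BONDS <- c(A = 1, C = 1, D = 2, E = 2, F = 1, G = 1, H = 1, I = 1,
                  K = 1, L = 1, M = 1, N = 2, P = 1, Q = 2, R = 2, S = 1,
                  T = 1, V = 1, W = 1, Y = 1)
AROMATIC_RINGS <- c(A = 0, C = 0, D = 0, E = 0, F = 1, G = 0, H = 1, I = 0,
                    K = 0, L = 0, M = 0, N = 0, P = 0, Q = 0, R = 0, S = 0,
                    T = 0, V = 0, W = 2, Y = 1)

seq_index <- function(seq) {
  ix <- match(strsplit(seq, "")[[1]], AA20)
  if (anyNA(ix)) stop("sequence contains non-standard residues; clean first")
  ix
}

# ---- descriptor blocks ---------------------------------------------------

#' Amino-acid composition (20 descriptors)
#'
#' Frequency of each of the 20 standard residues, `count / length`.
#'
#' @param seq Cleaned amino-acid sequence (single string).
#' @return Named numeric vector of length 20 summing to 1.
#' @export
aac <- function(seq) {
  ix <- seq_index(seq)
  if (length(ix) < 1L) stop("aac: empty sequence")
  setNames(tabulate(ix, 20L) / length(ix), paste0("AAC_", AA20))
}

#' Dipeptide composition (400 descriptors)
#'
#' Frequency of each ordered residue pair, `count / (length - 1)`.
#'
#' @inheritParams aac
#' @return Named numeric vector of length 400 summing to 1.
#' @export
dpc <- function(seq) {
  ix <- seq_index(seq)
  n <- length(ix)
  if (n < 2L) stop("dpc: sequence shorter than 2")
  pair <- (ix[-n] - 1L) * 20L + ix[-1L]
  nm <- paste0("DPC_", rep(AA20, each = 20L), rep(AA20, 20L))
  setNames(tabulate(pair, 400L) / (n - 1L), nm)
}

group5_index <- function(ix) {
  map <- integer(20L)
  for (g in seq_along(AA_GROUPS5)) map[match(AA_GROUPS5[[g]], AA20)] <- g
  map[ix]
}

#' Grouped amino-acid and grouped dipeptide composition (5 + 25 descriptors)
#'
#' Residues are mapped to five physicochemical groups (aliphatic, aromatic,
#' positively charged, negatively charged, uncharged polar) and AAC/DPC are
#' computed over group symbols.
#'
#' @inheritParams aac
#' @return Named numeric vector of length 30 (two blocks each summing to 1).
#' @export
gaac_gdpc <- function(seq) {
  ix <- seq_index(seq)
  n <- length(ix)
  if (n < 2L) stop("gaac_gdpc: sequence shorter than 2")
  gi <- group5_index(ix)
  gn <- names(AA_GROUPS5)
  ga <- setNames(tabulate(gi, 5L) / n, paste0("GAAC_", gn))
  pair <- (gi[-n] - 1L) * 5L + gi[-1L]
  nm <- paste0("GDPC_", rep(gn, each = 5L), ".", rep(gn, 5L))
  gd <- setNames(tabulate(pair, 25L) / (n - 1L), nm)
  c(ga, gd)
}

ctd_group_index <- function(ix, attr_groups) {
  map <- integer(20L)
  for (g in 1:3) {
    letters_g <- strsplit(attr_groups[[g]], "")[[1]]
    map[match(letters_g, AA20)] <- g
  }
  map[ix]
}

#' Composition/Transition/Distribution descriptors (21 + 21 + 105)
#'
#' Seven physicochemical attributes each partition the alphabet into three
#' groups.  Composition: group frequencies.  Transition: frequency of
#' adjacent positions changing between each unordered group pair, over
#' `length - 1`.  Distribution: positions (percent of length, 1-based) of
#' the 1st, 25\%, 50\%, 75\% and 100\% occurrence of each group, where the
#' q-quantile occurrence index is `max(1, ceiling(q * count))`; absent
#' groups give 0.
#'
#' @inheritParams aac
#' @return Named numeric vector of length 147.
#' @export
ctd <- function(seq) {
  ix <- seq_index(seq)
  n <- length(ix)
  if (n < 2L) stop("ctd: sequence shorter than 2")
  comp <- numeric(0); tran <- numeric(0); dist <- numeric(0)
  for (a in names(CTD_GROUPS)) {
    gi <- ctd_group_index(ix, CTD_GROUPS[[a]])
    cc <- tabulate(gi, 3L)
    comp <- c(comp, setNames(cc / n, paste0("CTDC_", a, "_g", 1:3)))
    pa <- gi[-n]; pb <- gi[-1L]
    pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
    tv <- vapply(1:3, function(k) {
      sum((pa == pairs[k, 1] & pb == pairs[k, 2]) |
          (pa == pairs[k, 2] & pb == pairs[k, 1])) / (n - 1L)
    }, 0)
    tran <- c(tran, setNames(tv, paste0(
      "CTDT_", a, "_g", pairs[, 1], "g", pairs[, 2])))
    for (g in 1:3) {
      pos <- which(gi == g)
      v <- if (length(pos) == 0L) rep(0, 5) else {
        cnt <- length(pos)
        idx <- c(1L, pmax(1L, ceiling(c(0.25, 0.5, 0.75) * cnt)), cnt)
        pos[idx] / n * 100
      }
      dist <- c(dist, setNames(v, paste0(
        "CTDD_", a, "_g", g, "_p", c(1, 25, 50, 75, 100))))
    }
  }
  c(comp, tran, dist)
}

#' Conjoint-triad descriptors (343)
#'
#' Residues are mapped to seven classes; the frequency of each ordered class
#' triple over `length - 2` is reported.
#'
#' @inheritParams aac
#' @return Named numeric vector of length 343 summing to 1.
#' @export
conjoint_triad <- function(seq) {
  ix <- seq_index(seq)
  n <- length(ix)
  if (n < 3L) stop("conjoint_triad: sequence shorter than 3")
  map <- integer(20L)
  for (g in seq_along(CT_CLASSES)) map[match(CT_CLASSES[[g]], AA20)] <- g
  ci <- map[ix]
  tri <- (ci[1:(n - 2L)] - 1L) * 49L + (ci[2:(n - 1L)] - 1L) * 7L + ci[3:n]
  nm <- paste0("CT_", rep(1:7, each = 49L), rep(rep(1:7, each = 7L), 7L),
               rep(1:7, 49L))
  setNames(tabulate(tri, 343L) / (n - 2L), nm)
}

#' Pseudo amino-acid composition (20 + lambda descriptors)
#'
#' Chou's type-1 PAAC with three standardized property scales
#' (hydrophobicity, hydrophilicity, side-chain mass).  The correlation
#' factor at separation k is the mean over positions of the mean squared
#' standardized property difference.  First 20 entries are
#' `f_i / (1 + w * sum(theta))`, the rest `w * theta_k / (1 + w * sum(theta))`.
#'
#' @inheritParams aac
#' @param lambda Maximum sequence separation (default 4); requires
#'   `length(seq) > lambda`.
#' @param w Weight of the sequence-order terms (default 0.05).
#' @return Named numeric vector of length `20 + lambda`.
#' @export
paac <- function(seq, lambda = 4L, w = 0.05) {
  ix <- seq_index(seq)
  n <- length(ix)
  if (lambda < 1L) stop("paac: lambda must be >= 1")
  if (n <= lambda)
    stop("paac: sequence length ", n, " <= lambda ", lambda,
         "; drop the PAAC block or lower lambda")
  scales <- vapply(PAAC_SCALES, function(h) {
    h <- h[AA20]
    (h - mean(h)) / sqrt(sum((h - mean(h))^2) / 20)
  }, numeric(20L))
  theta <- vapply(seq_len(lambda), function(k) {
    a <- ix[1:(n - k)]; b <- ix[(1 + k):n]
    mean(rowMeans((scales[a, , drop = FALSE] - scales[b, , drop = FALSE])^2))
  }, 0)
  f <- tabulate(ix, 20L) / n
  denom <- sum(f) + w * sum(theta)
  c(setNames(f / denom, paste0("PAAC_", AA20)),
    setNames(w * theta / denom, paste0("PAAC_lambda", seq_len(lambda))))
}

#' Atom and bond composition (5 + 4 descriptors)
#'
#' Atom features: counts of C, H, N, O, S atoms of the free amino acids
#' summed over the sequence and divided by the total atom count.  Bond
#' features: total bonds, single bonds, double bonds and aromatic rings per
#' residue (see the embedded convention tables), each divided by the
#' residue count.
#'
#' @inheritParams aac
#' @return Named numeric vector of length 9; atom fractions sum to 1.
#' @export
atom_bond <- function(seq) {
  ix <- seq_index(seq)
  n <- length(ix)
  if (n < 1L) stop("atom_bond: empty sequence")
  atoms <- colSums(ATOM_COUNTS[ix, , drop = FALSE])
  atom_frac <- atoms / sum(atoms)
  total_atoms <- rowSums(ATOM_COUNTS)[AA20]
  total_bonds <- total_atoms - 1 + RING_COUNTS[AA20]
  dbl <- DOUBLE_BONDS[AA20]
  arom <- AROMATIC_RINGS[AA20]
  bonds <- c(total = sum(total_bonds[ix]),
             single = sum((total_bonds - dbl)[ix]),
             double = sum(dbl[ix]),
             aromatic = sum(arom[ix])) / n
  c(setNames(atom_frac, paste0("ATOM_", colnames(ATOM_COUNTS))),
    setNames(bonds, paste0("BOND_", names(bonds))))
}

# ---- feature matrix ------------------------------------------------------

#' Descriptor configuration
#'
#' @param blocks Character vector of enabled blocks, a subset of
#'   `c("aac","dpc","gaac_gdpc","ctd","conjoint_triad","paac","atom_bond")`,
#'   concatenated in this fixed order.
#' @param paac_lambda,paac_w PAAC parameters.
#' @return A `descriptor_config` list.
#' @export
descriptor_config <- function(blocks = c("aac", "dpc", "gaac_gdpc", "ctd",
                                         "conjoint_triad", "paac",
                                         "atom_bond"),
                              paac_lambda = 4L, paac_w = 0.05) {
  known <- c("aac", "dpc", "gaac_gdpc", "ctd", "conjoint_triad", "paac",
             "atom_bond")
  bad <- setdiff(blocks, known)
  if (length(bad)) stop("unknown descriptor block(s): ",
                        paste(bad, collapse = ", "))
  structure(list(blocks = known[known %in% blocks],
                 paac_lambda = as.integer(paac_lambda), paac_w = paac_w),
            class = "descriptor_config")
}

config_min_length <- function(config) {
  mins <- c(aac = 1L, dpc = 2L, gaac_gdpc = 2L, ctd = 2L, conjoint_triad = 3L,
            paac = config$paac_lambda + 1L, atom_bond = 1L)
  max(mins[config$blocks])
}

descriptor_row <- function(seq, config) {
  parts <- lapply(config$blocks, function(b) switch(
    b,
    aac = aac(seq), dpc = dpc(seq), gaac_gdpc = gaac_gdpc(seq),
    ctd = ctd(seq), conjoint_triad = conjoint_triad(seq),
    paac = paac(seq, config$paac_lambda, config$paac_w),
    atom_bond = atom_bond(seq)))
  unlist(parts)
}

#' Build a feature matrix from protein records
#'
#' Concatenates the enabled descriptor blocks in fixed order; rows follow
#' the input record order and each row depends only on its own sequence.
#'
#' @param records `data.frame` with `id`, `seq` (cleaned sequences).
#' @param config A [descriptor_config()].
#' @return A `feature_matrix`: list with `data` (numeric matrix, row names =
#'   ids) and `provenance` (character log of applied transforms).
#' @export
featurize <- function(records, config = descriptor_config()) {
  need <- config_min_length(config)
  if (nrow(records) > 0L) {
    short <- nchar(records$seq) < need
    if (any(short))
      stop("sequence(s) shorter than the configured minimum (", need, "): ",
           paste(records$id[short], collapse = ", "))
  }
  cols <- names(descriptor_row(strrep("ACDEFGHIKLMNPQRSTVWY", 2), config))
  data <- matrix(0, nrow(records), length(cols),
                 dimnames = list(records$id, cols))
  for (i in seq_len(nrow(records)))
    data[i, ] <- descriptor_row(records$seq[i], config)
  new_feature_matrix(data, sprintf("featurize:%d blocks,%d columns",
                                   length(config$blocks), length(cols)))
}

new_feature_matrix <- function(data, provenance = character()) {
  stopifnot(is.matrix(data), !anyDuplicated(colnames(data)))
  structure(list(data = data, provenance = provenance),
            class = "feature_matrix")
}

#' @export
dim.feature_matrix <- function(x) dim(x$data)

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d sequences x %d descriptors\n",
              nrow(x$data), ncol(x$data)))
  for (p in x$provenance) cat(" -", p, "\n")
  invisible(x)
}

#' Drop exactly-duplicated descriptor columns
#'
#' Removes columns whose value vector equals an earlier column's, keeping
#' the first occurrence; dropped names are recorded in provenance.
#'
#' @param m A `feature_matrix` with at least one row.
#' @return The deduplicated `feature_matrix`.
#' @export
drop_duplicate_columns <- function(m) {
  stopifnot(inherits(m, "feature_matrix"), nrow(m$data) >= 1L)
  dup <- duplicated(t(m$data))
  out <- m$data[, !dup, drop = FALSE]
  new_feature_matrix(out, c(m$provenance, sprintf(
    "dedup:dropped %d of %d columns", sum(dup), ncol(m$data))))
}

#' Fit a min-max scaler on a training feature matrix
#'
#' @param train A `feature_matrix` with >= 2 rows.
#' @return A `scaler_state` with per-column `min` and `max`.
#' @export
fit_scaler <- function(train) {
  stopifnot(inherits(train, "feature_matrix"), nrow(train$data) >= 2L)
  structure(list(min = apply(train$data, 2, min),
                 max = apply(train$data, 2, max),
                 columns = colnames(train$data)),
            class = "scaler_state")
}

#' Apply a fitted min-max scaler
#'
#' Transforms each column to `(x - min) / (max - min)`.  Columns constant in
#' training map to 0; values outside the training range are not clipped and
#' may fall outside `[0, 1]`.
#'
#' @param state A `scaler_state` from [fit_scaler()].
#' @param m A `feature_matrix` with exactly the training columns.
#' @return The rescaled `feature_matrix`.
#' @export
apply_scaler <- function(state, m) {
  if (!inherits(state, "scaler_state")) stop("scaler state is not fitted")
  stopifnot(inherits(m, "feature_matrix"))
  if (!identical(colnames(m$data), state$columns))
    stop("column names do not match the fitted scaler")
  rng <- state$max - state$min
  out <- sweep(m$data, 2, state$min, "-")
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, rng[nz], "/")
  out[, !nz] <- 0
  new_feature_matrix(out, c(m$provenance, "minmax-scale"))
}

# Project a feature matrix onto a reference column set (training columns);
# errors if any reference column is missing.
project_columns <- function(m, columns) {
  stopifnot(inherits(m, "feature_matrix"))
  missing_cols <- setdiff(columns, colnames(m$data))
  if (length(missing_cols))
    stop("feature matrix lacks training column(s): ",
         paste(head(missing_cols, 5), collapse = ", "))
  new_feature_matrix(m$data[, columns, drop = FALSE],
                     c(m$provenance, sprintf("project:%d columns",
                                             length(columns))))
}
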