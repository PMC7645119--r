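# Independent brute-force oracles.  Everything here is written loop-first
# from the definitions, deliberately sharing no code with the package
# implementations it checks.

AAS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n) paste(sample(AAS, n, replace = TRUE),
                                    collapse = "")

oracle_aac <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  vapply(AAS, function(a) sum(ch == a) / length(ch), 0)
}

oracle_dpc <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  out <- numeric(0)
  for (a in AAS) for (b in AAS) {
    cnt <- 0L
    for (i in seq_len(length(ch) - 1L))
      if (ch[i] == a && ch[i + 1L] == b) cnt <- cnt + 1L
    out <- c(out, cnt / (length(ch) - 1L))
  }
  out
}

GROUPS5 <- list(aliphatic = c("G","A","V","L","M","I"),
                aromatic = c("F","Y","W"), positive = c("K","R","H"),
                negative = c("D","E"), uncharged = c("S","T","C","P","N","Q"))

map_group5 <- function(ch)
  vapply(ch, function(c) which(vapply(GROUPS5, function(g) c %in% g, TRUE)), 0L)

oracle_gaac_gdpc <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  gi <- map_group5(ch)
  ga <- vapply(1:5, function(g) sum(gi == g) / length(gi), 0)
  gd <- numeric(0)
  for (a in 1:5) for (b in 1:5) {
    cnt <- 0L
    for (i in seq_len(length(gi) - 1L))
      if (gi[i] == a && gi[i + 1L] == b) cnt <- cnt + 1L
    gd <- c(gd, cnt / (length(gi) - 1L))
  }
  c(ga, gd)
}

CTDG <- list(
  hydrophobicity = c("RKEDQN", "GASTPHY", "CLVIMFW"),
  vdwvolume = c("GASTPDC", "NVEQIL", "MHKFRYW"),
  polarity = c("LIFWCMVY", "PATGS", "HQRKNED"),
  polarizability = c("GASDT", "CPNVEQIL", "KMHFRYW"),
  charge = c("KR", "ANCQGHILMFPSTWYV", "DE"),
  secondarystruct = c("EALMQKRH", "VIYCWFT", "GNPSD"),
  solventaccess = c("ALFCGIVW", "RKQEND", "MSPTHY"))

oracle_ctd <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  comp <- numeric(0); tran <- numeric(0); dst <- numeric(0)
  for (attr in names(CTDG)) {
    gi <- vapply(ch, function(c)
      which(vapply(CTDG[[attr]], function(g)
        c %in% strsplit(g, "")[[1]], TRUE)), 0L)
    for (g in 1:3) comp <- c(comp, sum(gi == g) / n)
    for (pr in list(c(1, 2), c(1, 3), c(2, 3))) {
      cnt <- 0L
      for (i in seq_len(n - 1L))
        if ((gi[i] == pr[1] && gi[i + 1] == pr[2]) ||
            (gi[i] == pr[2] && gi[i + 1] == pr[1])) cnt <- cnt + 1L
      tran <- c(tran, cnt / (n - 1L))
    }
    for (g in 1:3) {
      pos <- which(gi == g)
      if (length(pos) == 0L) { dst <- c(dst, rep(0, 5)); next }
      cnt <- length(pos)
      for (q in c(0, 0.25, 0.5, 0.75, 1)) {
        k <- if (q == 0) 1L else max(1L, ceiling(q * cnt))
        dst <- c(dst, pos[k] / n * 100)
      }
    }
  }
  unname(c(comp, tran, dst))
}

CT7 <- list(c("A","G","V"), c("I","L","F","P"), c("Y","M","T","S"),
            c("H","N","Q","W"), c("R","K"), c("D","E"), c("C"))

oracle_ct <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  ci <- vapply(ch, function(c)
    which(vapply(CT7, function(g) c %in% g, TRUE)), 0L)
  out <- numeric(0)
  n <- length(ci)
  for (a in 1:7) for (b in 1:7) for (d in 1:7) {
    cnt <- 0L
    for (i in seq_len(n - 2L))
      if (ci[i] == a && ci[i + 1] == b && ci[i + 2] == d) cnt <- cnt + 1L
    out <- c(out, cnt / (n - 2L))
  }
  out
}

# independent type-1 pseudo-AAC (scales typed in again from the published
# tables, population-SD standardization, plain loops)
oracle_paac <- function(seq, lam, w) {
  h1 <- c(0.62, 0.29, -0.9, -0.74, 1.19, 0.48, -0.4, 1.38, -1.5, 1.06,
          0.64, -0.78, 0.12, -0.85, -2.53, -0.18, -0.05, 1.08, 0.81, 0.26)
  h2 <- c(-0.5, -1, 3, 3, -2.5, 0, -0.5, -1.8, 3, -1.8, -1.3, 0.2, 0, 0.2,
          3, 0.3, -0.4, -1.5, -3.4, -2.3)
  mm <- c(15, 47, 59, 73, 91, 1, 82, 57, 73, 57, 75, 58, 42, 72, 101, 31,
          45, 43, 130, 107)
  std <- function(h) (h - mean(h)) / sqrt(mean((h - mean(h))^2))
  sc <- cbind(std(h1), std(h2), std(mm))
  ix <- match(strsplit(seq, "")[[1]], AAS)
  n <- length(ix)
  theta <- numeric(lam)
  for (k in 1:lam) {
    acc <- 0
    for (i in 1:(n - k)) {
      d <- sc[ix[i], ] - sc[ix[i + k], ]
      acc <- acc + mean(d^2)
    }
    theta[k] <- acc / (n - k)
  }
  f <- vapply(1:20, function(a) sum(ix == a) / n, 0)
  den <- 1 + w * sum(theta)
  c(f / den, w * theta / den)
}

# plain-R Gotoh local alignment (same gap convention, independent code)
oracle_sw <- function(a, b, sub, open, ext) {
  ai <- strsplit(a, "")[[1]]; bi <- strsplit(b, "")[[1]]
  m <- length(ai); n <- length(bi)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) for (j in 2:(n + 1)) {
    E[i, j] <- max(H[i, j - 1] - open, E[i, j - 1] - ext)
    F[i, j] <- max(H[i - 1, j] - open, F[i - 1, j] - ext)
    H[i, j] <- max(0, H[i - 1, j - 1] + sub[ai[i - 1], bi[j - 1]],
                   E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# exhaustive local-alignment enumeration for tiny sequences: every pair of
# substrings, every monotone alignment, recursively
oracle_sw_exhaustive <- function(a, b, sub, open, ext) {
  ai <- strsplit(a, "")[[1]]; bi <- strsplit(b, "")[[1]]
  score_align <- function(i1, i2, j1, j2) {
    # best global alignment score of a[i1..i2] vs b[j1..j2]
    rec <- function(i, j, gap_state) {
      if (i > i2 && j > j2) return(0)
      opts <- -Inf
      if (i <= i2 && j <= j2)
        opts <- max(opts, sub[ai[i], bi[j]] + rec(i + 1, j + 1, 0L))
      if (i <= i2)
        opts <- max(opts, (if (gap_state == 1L) -ext else -open) +
                      rec(i + 1, j, 1L))
      if (j <= j2)
        opts <- max(opts, (if (gap_state == 2L) -ext else -open) +
                      rec(i, j + 1, 2L))
      opts
    }
    rec(i1, j1, 0L)
  }
  best <- 0
  for (i1 in seq_along(ai)) for (i2 in i1:length(ai))
    for (j1 in seq_along(bi)) for (j2 in j1:length(bi))
      best <- max(best, score_align(i1, i2, j1, j2))
  best
}

# all-pairs identity matrix via Biostrings, for the clustering oracle
oracle_identity_matrix <- function(seqs) {
  n <- length(seqs)
  out <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    mat <- diag(1, 20); dimnames(mat) <- list(AAS, AAS)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::BString(seqs[i]), Biostrings::BString(seqs[j]),
      type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 1)
    out[i, j] <- Biostrings::nmatch(aln) / min(nchar(seqs[i]),
                                               nchar(seqs[j]))
  }
  out
}

revcomp <- function(dna)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))

# light ensemble configuration used by slow pipeline-level tests; package
# defaults stay at the published hyperparameters
light_ensemble <- function()
  ensemble_config(mlp = list(epochs = 150L, hidden = c(64L, 64L)),
                  rf = list(ntree = 100L))

fm_from_matrix <- function(m) {
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- paste0("r", seq_len(nrow(m)))
  cellopt:::new_feature_matrix(m)
}
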