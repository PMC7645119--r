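# Seeded synthetic data so every pipeline stage is testable offline.  The
# class signal is a class-conditional residue-composition bias: thermophily
# tracks enrichment in the IVYWREL set (the standard biophysical
# heuristic), acidity/alkalinity track D/E and K/R enrichment.

IVYWREL <- c("I", "V", "Y", "W", "R", "E", "L")

#' Sample a random protein sequence
#'
#' Residues are drawn i.i.d. from the normalized weight distribution.
#'
#' @param length Sequence length (>= 1).
#' @param bias Named non-negative weights over the 20 residues (unnamed
#'   residues get weight 1).
#' @param seed Optional integer seed.
#' @return A protein string.
#' @export
sample_protein <- function(length, bias = NULL, seed = NULL) {
  stopifnot(length >= 1L)
  w <- setNames(rep(1, 20), AA20)
  if (!is.null(bias)) {
    if (any(bias <= 0)) stop("bias weights must be positive")
    w[names(bias)] <- bias
  }
  with_seed(seed,
            paste(sample(AA20, length, replace = TRUE, prob = w / sum(w)),
                  collapse = ""))
}

class_bias <- function(task, class, strength) {
  if (task == "temperature") {
    switch(class,
           mesophilic = NULL,
           thermophilic = setNames(rep(strength, length(IVYWREL)), IVYWREL),
           hyperthermophilic = setNames(rep(strength^2, length(IVYWREL)),
                                        IVYWREL))
  } else {
    switch(class,
           acidic = c(D = strength^2, E = strength^2),
           neutral = NULL,
           alkaline = c(K = strength^2, R = strength^2))
  }
}

# Optimum ranges strictly inside the class intervals, so fixture labels are
# never boundary-ambiguous.
class_optimum_range <- function(task, class) {
  if (task == "temperature")
    switch(class, mesophilic = c(20, 45), thermophilic = c(52, 72),
           hyperthermophilic = c(78, 110))
  else
    switch(class, acidic = c(3, 4.5), neutral = c(5.5, 7.5),
           alkaline = c(8.5, 11))
}

#' Specification of a synthetic labeled dataset
#'
#' @param task `"temperature"` or `"pH"`.
#' @param n_per_class Sequences per class (default 60).
#' @param length_range Sequence length range in residues (default 120-400,
#'   typical catalytic-domain scale).
#' @param bias_strength Multiplicative residue-bias weight controlling task
#'   difficulty (default 2, a strongly separable compositional signal;
#'   1 = no signal).
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(task = "temperature", n_per_class = 60L,
                           length_range = c(120L, 400L),
                           bias_strength = 2, seed = 1L) {
  stopifnot(task %in% c("temperature", "pH"), n_per_class >= 1L,
            bias_strength > 0, length_range[1] >= 5L)
  structure(list(task = task, n_per_class = n_per_class,
                 length_range = length_range,
                 bias_strength = bias_strength, seed = seed),
            class = "synthetic_spec")
}

#' Generate a labeled synthetic protein dataset
#'
#' Draws `n_per_class` sequences per class under that class's residue bias
#' and assigns each a uniform optimum from the class's interior range.
#' Labels are recomputed from the optima with [label_temperature()] /
#' [label_ph()] and asserted equal to the generating class.
#'
#' @param spec A [synthetic_spec()].
#' @return List: `records` (`id`, `seq`), `optima` (`id`, `t_opt` or
#'   `ph_opt`), `labels` (factor), `task`.
#' @export
generate_labeled_dataset <- function(spec) {
  classes <- if (spec$task == "temperature") TEMP_CLASSES else PH_CLASSES
  with_seed(spec$seed, {
    ids <- character(0); seqs <- character(0); optima <- numeric(0)
    gen_class <- character(0)
    for (cl in classes) {
      bias <- class_bias(spec$task, cl, spec$bias_strength)
      rng <- class_optimum_range(spec$task, cl)
      for (i in seq_len(spec$n_per_class)) {
        len <- sample(spec$length_range[1]:spec$length_range[2], 1L)
        ids <- c(ids, sprintf("syn_%s_%03d", cl, i))
        seqs <- c(seqs, sample_protein(len, bias))
        optima <- c(optima, runif(1, rng[1], rng[2]))
        gen_class <- c(gen_class, cl)
      }
    }
    labels <- if (spec$task == "temperature") label_temperature(optima)
              else label_ph(optima)
    stopifnot(identical(as.character(labels), gen_class))
    optima_df <- data.frame(id = ids, stringsAsFactors = FALSE)
    optima_df[[if (spec$task == "temperature") "t_opt" else "ph_opt"]] <-
      optima
    list(records = data.frame(id = ids, seq = seqs,
                              stringsAsFactors = FALSE),
         optima = optima_df, labels = labels, task = spec$task)
  })
}

# codon table inverted once: amino acid -> synonymous codons
CODONS_BY_AA <- split(names(Biostrings::GENETIC_CODE),
                      unname(Biostrings::GENETIC_CODE))

#' Reverse-translate a protein into DNA
#'
#' Each residue gets a uniformly chosen synonymous codon; a uniformly
#' chosen stop codon is appended, so the result has length
#' `3 * (nchar(protein) + 1)`.
#'
#' @param protein Cleaned amino-acid string.
#' @param seed Optional integer seed.
#' @return A DNA string.
#' @export
reverse_translate <- function(protein, seed = NULL) {
  aa <- strsplit(protein, "")[[1]]
  stopifnot(all(aa %in% AA20))
  with_seed(seed, {
    codons <- vapply(aa, function(a) {
      opts <- CODONS_BY_AA[[a]]
      opts[sample.int(length(opts), 1L)]
    }, "")
    stop_codon <- CODONS_BY_AA[["*"]][sample.int(3L, 1L)]
    paste(c(codons, stop_codon), collapse = "")
  })
}

#' Specification of a synthetic contig set
#'
#' @param n_contigs Number of contigs (default 20).
#' @param length_range Contig length range in nt (default 5000-10000).
#' @param planted_fraction Fraction of contigs carrying a planted reference
#'   gene (default 0.6).
#' @param reverse_fraction Fraction of planted genes embedded on the
#'   reverse strand (default 1/3).
#' @param seed Integer seed.
#' @return A `contig_spec` list.
#' @export
contig_spec <- function(n_contigs = 20L, length_range = c(5000L, 10000L),
                        planted_fraction = 0.6, reverse_fraction = 1 / 3,
                        seed = 1L) {
  stopifnot(n_contigs >= 1L, planted_fraction >= 0, planted_fraction <= 1,
            reverse_fraction >= 0, reverse_fraction <= 1)
  structure(list(n_contigs = n_contigs, length_range = length_range,
                 planted_fraction = planted_fraction,
                 reverse_fraction = reverse_fraction, seed = seed),
            class = "contig_spec")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

#' Generate synthetic contigs with planted reference genes
#'
#' The planted fraction of contigs carries the reverse translation of a
#' randomly chosen reference protein embedded at a random offset in uniform
#' background DNA (reverse-complemented for the reverse-strand fraction);
#' the rest are pure background.
#'
#' @param spec A [contig_spec()].
#' @param reference_proteins `data.frame` with `id`, `seq`.
#' @return List: `contigs` (`id`, `seq`) and `truth` (`contig_id`,
#'   `reference_id` or NA, `strand` (+/-/NA), `offset` 1-based or NA).
#' @export
generate_contigs <- function(spec, reference_proteins) {
  stopifnot(nrow(reference_proteins) >= 1L)
  with_seed(spec$seed, {
    n_planted <- round(spec$n_contigs * spec$planted_fraction)
    n_reverse <- round(n_planted * spec$reverse_fraction)
    contigs <- vector("list", spec$n_contigs)
    truth <- vector("list", spec$n_contigs)
    for (i in seq_len(spec$n_contigs)) {
      id <- sprintf("contig_%03d", i)
      len <- sample(spec$length_range[1]:spec$length_range[2], 1L)
      if (i <= n_planted) {
        ri <- sample.int(nrow(reference_proteins), 1L)
        gene <- reverse_translate(reference_proteins$seq[ri])
        if (nchar(gene) + 200L > len)
          stop("planted gene longer than contig minus flanks: ",
               reference_proteins$id[ri])
        strand <- if (i <= n_reverse) "-" else "+"
        insert <- if (strand == "-")
          as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(gene))) else gene
        offset <- sample.int(len - nchar(insert) + 1L, 1L)
        seq <- paste0(substr(random_dna(len), 1L, offset - 1L), insert,
                      random_dna(len - offset + 1L - nchar(insert)))
        contigs[[i]] <- data.frame(id = id, seq = seq,
                                   stringsAsFactors = FALSE)
        truth[[i]] <- data.frame(contig_id = id,
                                 reference_id = reference_proteins$id[ri],
                                 strand = strand, offset = offset,
                                 stringsAsFactors = FALSE)
      } else {
        contigs[[i]] <- data.frame(id = id, seq = random_dna(len),
                                   stringsAsFactors = FALSE)
        truth[[i]] <- data.frame(contig_id = id, reference_id = NA_character_,
                                 strand = NA_character_, offset = NA_integer_,
                                 stringsAsFactors = FALSE)
      }
    }
    list(contigs = do.call(rbind, contigs), truth = do.call(rbind, truth))
  })
}
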