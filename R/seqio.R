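#' Read a FASTA file of protein or nucleotide sequences
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that enforces the
#' package's record contract: one record per header, sequences uppercased,
#' input order preserved, and a hard error naming any record with an empty
#' sequence.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @param alphabet `"protein"` or `"nucleotide"`; controls validation only.
#'   Nucleotide sequences must use A, C, G, T, N.  Protein sequences are not
#'   restricted here (see [clean_sequence()] for alphabet reduction).
#' @return A `data.frame` with columns `id` and `seq`.
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  empty <- nchar(seqs) == 0L
  if (any(empty))
    stop("record(s) with empty sequence: ", paste(ids[empty], collapse = ", "))
  if (alphabet == "nucleotide") {
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad))
      stop("non-ACGTN characters in nucleotide record(s): ",
           paste(ids[bad], collapse = ", "))
  }
  data.frame(id = ids, seq = unname(seqs), stringsAsFactors = FALSE)
}

#' Write records to a FASTA file
#'
#' @param records `data.frame` with columns `id`, `seq`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  set <- Biostrings::BStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reduce a raw sequence to the 20-letter amino-acid alphabet
#'
#' Uppercases the input and removes every character that is not one of the
#' 20 standard amino-acid letters: ambiguity codes (B, J, O, U, X, Z), gap
#' and stop symbols, whitespace and digits all go.  Idempotent.
#'
#' @param raw Character vector of raw sequences.
#' @return Character vector of cleaned sequences.  Errors if any cleaned
#'   sequence is empty (names the offending element).
#' @export
clean_sequence <- function(raw) {
  out <- gsub("[^ACDEFGHIKLMNPQRSTVWY]", "", toupper(raw))
  if (any(nchar(out) == 0L)) {
    who <- which(nchar(out) == 0L)
    lab <- if (!is.null(names(raw))) names(raw)[who] else as.character(who)
    stop("sequence(s) empty after cleaning: ", paste(lab, collapse = ", "))
  }
  out
}

# codon -> amino acid under the standard genetic code; any codon containing
# an ambiguous base translates to "X" (treated as a segment break).
translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

#' Translate a contig in all six reading frames
#'
#' Frames +1..+3 read the forward strand, -1..-3 the reverse complement.
#' Each frame's translation is split at stop codons into peptides; codons
#' containing N translate to X and likewise break the peptide.  Offsets are
#' 0-based nucleotide positions of the first codon of each peptide on the
#' strand read by that frame.
#'
#' @param contig A `data.frame` row (or list) with `id` and `seq`, sequence
#'   over A, C, G, T, N.
#' @return List of six elements, each
#'   `list(contig_id, frame, peptides, offsets)`; frames shorter than one
#'   codon yield empty peptide lists.
#' @export
six_frame_translate <- function(contig) {
  seq <- toupper(contig$seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    chartr("N", "N", seq))))
  out <- vector("list", 6L)
  k <- 1L
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) seq else rc
    n <- nchar(s)
    for (f in 1:3) {
      if (n - f + 1L < 3L) {
        out[[k]] <- list(contig_id = contig$id, frame = strand * f,
                         peptides = character(0), offsets = integer(0))
        k <- k + 1L
        next
      }
      starts <- seq.int(f, n - 2L, by = 3L)
      if (length(starts) == 0L) {
        out[[k]] <- list(contig_id = contig$id, frame = strand * f,
                         peptides = character(0), offsets = integer(0))
        k <- k + 1L
        next
      }
      codons <- substring(s, starts, starts + 2L)
      aa <- translate_codons(codons)
      brk <- aa %in% c("*", "X")
      grp <- cumsum(brk)
      keep <- !brk
      peptides <- character(0); offsets <- integer(0)
      if (any(keep)) {
        pieces <- split(seq_along(aa)[keep], grp[keep])
        peptides <- vapply(pieces, function(ix) paste(aa[ix], collapse = ""), "")
        offsets <- vapply(pieces, function(ix) starts[ix[1L]] - 1L, 0L)
        names(peptides) <- NULL
      }
      out[[k]] <- list(contig_id = contig$id, frame = strand * f,
                       peptides = peptides, offsets = unname(offsets))
      k <- k + 1L
    }
  }
  out
}

# Pairwise identity used by the clustering step: identical positions in the
# optimal global alignment (match +1, mismatch 0, linear gap -1), divided by
# the length of the shorter sequence -- the CD-Hit convention.
# Vectorized over `others` (one alignment call, many patterns).
pair_identity <- function(a, others) {
  letters_ab <- unique(unlist(strsplit(c(a, others), "")))
  mat <- diag(1, length(letters_ab))
  dimnames(mat) <- list(letters_ab, letters_ab)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BStringSet(others), Biostrings::BString(a), type = "global",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 1)
  Biostrings::nmatch(aln) / pmin(nchar(a), nchar(others))
}

#' Greedy incremental identity clustering (CD-Hit style)
#'
#' Sequences are sorted by decreasing length; each joins the first existing
#' cluster whose representative it matches at `>= identity_threshold`
#' (see `pair_identity`: global-alignment matches over the shorter length),
#' otherwise it founds a new cluster.  The representative is the longest
#' member (the founder, by construction).
#'
#' @param records `data.frame` with `id`, `seq`.
#' @param identity_threshold Fraction in (0, 1].
#' @return `data.frame` of representatives, with a `"clusters"` attribute:
#'   a `data.frame` of `representative_id`, `member_id`, `identity`.
#' @export
greedy_cluster <- function(records, identity_threshold = 0.9) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (nrow(records) == 0L) {
    out <- records
    attr(out, "clusters") <- data.frame(representative_id = character(0),
                                        member_id = character(0),
                                        identity = numeric(0))
    return(out)
  }
  ord <- order(-nchar(records$seq), seq_len(nrow(records)))
  rec <- records[ord, , drop = FALSE]
  rep_idx <- integer(0)
  rows <- list()
  for (i in seq_len(nrow(rec))) {
    placed <- FALSE
    if (length(rep_idx)) {
      idts <- pair_identity(rec$seq[i], rec$seq[rep_idx])
      hit <- which(idts >= identity_threshold)
      if (length(hit)) {
        r <- rep_idx[hit[1L]]  # first existing cluster wins
        rows[[length(rows) + 1L]] <- data.frame(
          representative_id = rec$id[r], member_id = rec$id[i],
          identity = idts[hit[1L]], stringsAsFactors = FALSE)
        placed <- TRUE
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, i)
      rows[[length(rows) + 1L]] <- data.frame(
        representative_id = rec$id[i], member_id = rec$id[i],
        identity = 1, stringsAsFactors = FALSE)
    }
  }
  reps <- rec[rep_idx, , drop = FALSE]
  # return representatives in original input order
  reps <- reps[order(match(reps$id, records$id)), , drop = FALSE]
  rownames(reps) <- NULL
  attr(reps, "clusters") <- do.call(rbind, rows)
  reps
}

#' Write a cluster report as TSV
#'
#' @param representatives Output of [greedy_cluster()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(representatives, path) {
  write.table(attr(representatives, "clusters"), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
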