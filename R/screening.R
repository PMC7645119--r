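#' Alignment parameters for translated homology screening
#'
#' Defaults: BLOSUM62, affine gaps 11/1 (a length-L gap costs
#' `open + (L - 1) * extend`), and the gapped Karlin-Altschul constants
#' `lambda = 0.267`, `K = 0.041` for bit-score conversion.
#'
#' @param matrix Substitution matrix name (only `"BLOSUM62"` is shipped) or
#'   a numeric matrix with amino-acid dimnames.
#' @param gap_open,gap_extend Positive gap penalties.
#' @param lambda,K Karlin-Altschul parameters.
#' @return An `alignment_params` list with the resolved matrix.
#' @export
alignment_params <- function(matrix = "BLOSUM62", gap_open = 11,
                             gap_extend = 1, lambda = 0.267, K = 0.041) {
  stopifnot(gap_open > 0, gap_extend > 0, lambda > 0, K > 0)
  sub <- if (is.matrix(matrix)) matrix else {
    if (!identical(matrix, "BLOSUM62"))
      stop("only BLOSUM62 is shipped; pass a numeric matrix otherwise")
    data_env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
    data_env$BLOSUM62
  }
  sub <- sub[AA20, AA20]
  structure(list(sub = sub, gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K),
            class = "alignment_params")
}

#' Exact local alignment score (Smith-Waterman, affine gaps)
#'
#' @param query,target Amino-acid strings over the 20-letter alphabet.
#' @param params An [alignment_params()].
#' @return List: `score` (raw S), 1-based `q_start`, `q_end`, `t_start`,
#'   `t_end`, and `length` (alignment columns).
#' @export
smith_waterman <- function(query, target, params = alignment_params()) {
  if (nchar(query) == 0L || nchar(target) == 0L)
    stop("smith_waterman: empty sequence")
  q <- seq_index(query) - 1L
  t <- seq_index(target) - 1L
  sw_align_cpp(q, t, params$sub, params$gap_open, params$gap_extend)
}

#' Convert a raw alignment score to bits
#'
#' `S' = (lambda * S - ln K) / ln 2`.
#'
#' @param S Raw score(s).
#' @param params An [alignment_params()].
#' @return Bit score(s).
#' @export
bit_score <- function(S, params = alignment_params()) {
  (params$lambda * S - log(params$K)) / log(2)
}

#' Screen contigs for cellulase-like genes by translated local alignment
#'
#' Each contig is translated in six frames; every stop-split peptide of at
#' least `min_peptide` residues is aligned against every reference protein
#' and the best-scoring (peptide, reference) pair per contig is kept.  A
#' hit is emitted iff its bit score reaches `cutoff_bits`.
#'
#' @param contigs `data.frame` with `id`, `seq` (A/C/G/T/N).
#' @param references `data.frame` with `id`, `seq` (cleaned proteins).
#' @param params An [alignment_params()].
#' @param cutoff_bits Minimum bit score to report (default 50).
#' @param min_contig Minimum contig length in nt (default 300, the usual
#'   assembly minimum).
#' @param min_peptide Minimum translated peptide length in aa (default 20).
#' @return `data.frame` of hits sorted by descending bit score:
#'   `contig_id`, `frame`, `peptide_start`, `peptide_end` (1-based residue
#'   positions on the frame translation), `reference_id`, `raw_score`,
#'   `bit_score`, `align_length`, `peptide` (the aligned stop-split
#'   peptide's sequence).
#' @export
screen_contigs <- function(contigs, references, params = alignment_params(),
                           cutoff_bits = 50, min_contig = 300L,
                           min_peptide = 20L) {
  if (nrow(references) == 0L) stop("empty reference set")
  ref_idx <- lapply(references$seq, function(s) seq_index(s) - 1L)
  hits <- list()
  for (ci in seq_len(nrow(contigs))) {
    contig <- contigs[ci, ]
    if (nchar(contig$seq) < min_contig) next
    frames <- six_frame_translate(contig)
    best <- NULL
    for (fr in frames) {
      keep <- nchar(fr$peptides) >= min_peptide
      if (!any(keep)) next
      peps <- fr$peptides[keep]
      offs <- fr$offsets[keep]
      for (pi in seq_along(peps)) {
        q <- seq_index(peps[pi]) - 1L
        scores <- sw_score_many_cpp(q, ref_idx, params$sub,
                                    params$gap_open, params$gap_extend)
        ri <- which.max(scores)
        if (is.null(best) || scores[ri] > best$score) {
          best <- list(score = scores[ri], frame = fr$frame,
                       peptide = peps[pi], offset = offs[pi],
                       reference = references$id[ri])
        }
      }
    }
    if (is.null(best)) next
    bits <- bit_score(best$score, params)
    if (bits < cutoff_bits) next
    aln <- smith_waterman(best$peptide,
                          references$seq[references$id == best$reference],
                          params)
    # residue position of the peptide's first aa on the frame translation
    pep_codon_start <- (best$offset - (abs(best$frame) - 1L)) %/% 3L
    hits[[length(hits) + 1L]] <- data.frame(
      contig_id = contig$id, frame = best$frame,
      peptide_start = pep_codon_start + aln$q_start,
      peptide_end = pep_codon_start + aln$q_end,
      reference_id = best$reference, raw_score = best$score,
      bit_score = bits, align_length = aln$length,
      peptide = best$peptide, stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L)
    return(data.frame(contig_id = character(0), frame = integer(0),
                      peptide_start = integer(0), peptide_end = integer(0),
                      reference_id = character(0), raw_score = numeric(0),
                      bit_score = numeric(0), align_length = integer(0),
                      peptide = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(-out$bit_score, out$contig_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Shortlist screening hits by read coverage and bit score
#'
#' Keeps hits whose contig coverage reaches the empirical
#' `coverage_quantile` of the supplied coverages AND whose bit score is at
#' least `bit_floor`.  The quantile uses the upper nearest-rank convention
#' `k = floor(q * n) + 1` (capped at `n`), so with coverages 10/20/30/40
#' the 75th percentile is 40.
#'
#' @param hits Output of [screen_contigs()].
#' @param coverage `data.frame` with `contig_id` and `mapped_reads`.
#' @param bit_floor Minimum bit score (default 300).
#' @param coverage_quantile Coverage quantile (default 0.75, i.e. the top
#'   25 percent).
#' @return `data.frame`: one row per hit contig with its best hit fields,
#'   `mapped_reads`, and a logical `shortlisted`.
#' @export
shortlist_candidates <- function(hits, coverage, bit_floor = 300,
                                 coverage_quantile = 0.75) {
  if (nrow(hits) == 0L)
    return(cbind(hits, data.frame(mapped_reads = numeric(0),
                                  shortlisted = logical(0))))
  missing_cov <- setdiff(hits$contig_id, coverage$contig_id)
  if (length(missing_cov))
    stop("coverage missing for contig(s): ",
         paste(missing_cov, collapse = ", "))
  covs <- sort(coverage$mapped_reads)
  k <- min(length(covs), floor(coverage_quantile * length(covs)) + 1L)
  threshold <- covs[k]
  out <- hits
  out$mapped_reads <- coverage$mapped_reads[
    match(out$contig_id, coverage$contig_id)]
  out$shortlisted <- out$mapped_reads >= threshold &
    out$bit_score >= bit_floor
  attr(out, "coverage_threshold") <- threshold
  out
}

#' Screen contigs and characterize the hits with trained bundles
#'
#' Runs [screen_contigs()], takes the best peptide of each passing contig,
#' and predicts its optimum-temperature and optimum-pH classes with the two
#' bundles.  Peptides too short for the bundles' descriptor configuration
#' are kept in the table with a note instead of failing the run.
#'
#' @param contigs,references,params,cutoff_bits As in [screen_contigs()].
#' @param bundle_T,bundle_pH Trained `model_bundle`s for the temperature
#'   and pH tasks.
#' @return Annotated `data.frame`: screening fields plus predicted labels
#'   and class probabilities for both tasks.
#' @export
characterize <- function(contigs, references, bundle_T, bundle_pH,
                         params = alignment_params(), cutoff_bits = 50) {
  hits <- screen_contigs(contigs, references, params, cutoff_bits)
  if (nrow(hits) == 0L) return(hits)
  records <- data.frame(id = hits$contig_id, seq = hits$peptide,
                        stringsAsFactors = FALSE)
  pt <- predict(bundle_T, records)
  pp <- predict(bundle_pH, records)
  out <- hits[, c("contig_id", "reference_id", "frame", "bit_score")]
  out$temperature_class <- ifelse(is.na(pt$label), "unpredictable", pt$label)
  out$pH_class <- ifelse(is.na(pp$label), "unpredictable", pp$label)
  pt_prob <- pt[, grep("^p_", names(pt)), drop = FALSE]
  names(pt_prob) <- paste0("T_", names(pt_prob))
  pp_prob <- pp[, grep("^p_", names(pp)), drop = FALSE]
  names(pp_prob) <- paste0("pH_", names(pp_prob))
  cbind(out, pt_prob, pp_prob)
}
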