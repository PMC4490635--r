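# Protein similarity search: Smith-Waterman local alignment with affine
# gaps under BLOSUM62, and Karlin-Altschul E-value statistics.

# Gapped Karlin-Altschul constants for BLOSUM62 with gap open 11 / extend 1.
KA_LAMBDA <- 0.267
KA_K <- 0.041

blosum62_matrix <- function() {
  if (is.null(the$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    the$blosum62 <- e$BLOSUM62[ALPHABET, ALPHABET]
    storage.mode(the$blosum62) <- "integer"
  }
  the$blosum62
}

#' Bit score and E-value of a raw alignment score
#'
#' Uses fixed gapped Karlin-Altschul constants (lambda = 0.267, K = 0.041,
#' the BLOSUM62 11/1 regime): `bit = (lambda * S - ln K) / ln 2` and
#' `E = K * m * n * exp(-lambda * S)` for sequence lengths m, n.
#'
#' @param raw_score integer Smith-Waterman score.
#' @param m,n lengths of the two sequences.
#' @return list with `bit_score` and `evalue`.
#' @export
alignment_statistics <- function(raw_score, m, n) {
  list(bit_score = (KA_LAMBDA * raw_score - log(KA_K)) / log(2),
       evalue = KA_K * m * n * exp(-KA_LAMBDA * raw_score))
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman with affine gaps (a gap of length L costs
#' `gap_open + L * gap_extend`). Identity is the fraction of identical
#' residue pairs over all alignment columns, gap columns included in the
#' denominator. A best score of 0 (all-negative scoring) is reported as
#' no hit (NULL).
#'
#' @param a,b residue strings (or lists with a `residues` field).
#' @param query_id,subject_id labels carried into the hit.
#' @param gap_open,gap_extend affine gap penalties.
#' @return an `alignment_hit` list (`query_id`, `subject_id`, `raw_score`,
#'   `bit_score`, `evalue`, `identity`, `aln_cols`, `q_cover`, `s_cover`,
#'   `cover_short`) or NULL when no positive-scoring alignment exists.
#' @export
local_align <- function(a, b, query_id = "query", subject_id = "subject",
                        gap_open = 11L, gap_extend = 1L) {
  sa <- if (is.list(a)) a$residues else a
  sb <- if (is.list(b)) b$residues else b
  sa <- normalize_residues(sa); sb <- normalize_residues(sb)
  if (nchar(sa) < 1 || nchar(sb) < 1) stop("empty sequence")
  ea <- encode_residues(sa); eb <- encode_residues(sb)
  tb <- cpp_sw_traceback(ea, eb, blosum62_matrix(),
                         as.integer(gap_open), as.integer(gap_extend))
  if (tb$score <= 0) return(NULL)
  ai <- tb$a_idx; bi <- tb$b_idx
  cols <- length(ai)
  both <- ai > 0 & bi > 0
  ident <- sum(ea[ai[both]] == eb[bi[both]])
  st <- alignment_statistics(tb$score, nchar(sa), nchar(sb))
  structure(list(query_id = query_id, subject_id = subject_id,
                 raw_score = tb$score, bit_score = st$bit_score,
                 evalue = st$evalue, identity = ident / cols,
                 aln_cols = cols,
                 q_cover = sum(ai > 0) / nchar(sa),
                 s_cover = sum(bi > 0) / nchar(sb),
                 cover_short = cols / min(nchar(sa), nchar(sb))),
            class = "alignment_hit")
}

# Score-only all-vs-all Smith-Waterman between two protein sets.
# seqs are character vectors; returns integer score matrix.
sw_score_block <- function(seqs_a, seqs_b, gap_open = 11L, gap_extend = 1L) {
  la <- lapply(seqs_a, encode_residues)
  lb <- lapply(seqs_b, encode_residues)
  cpp_sw_score_matrix(la, lb, blosum62_matrix(),
                      as.integer(gap_open), as.integer(gap_extend))
}
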