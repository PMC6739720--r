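#' Karlin-Altschul lambda for an ungapped nucleotide scoring pair
#'
#' Solves `sum_ij p_i p_j exp(lambda * s(i, j)) = 1` for lambda under uniform
#' base frequencies (p = 1/4), i.e.
#' `(1/4) exp(lambda * match) + (3/4) exp(lambda * mismatch) = 1`.
#'
#' @param match positive match score.
#' @param mismatch negative mismatch score.
#' @return lambda (> 0).
#' @export
karlin_lambda <- function(match = 1, mismatch = -2) {
  stopifnot(match > 0, mismatch < 0)
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-6, 10), tol = 1e-12)$root
}

#' Smith-Waterman local alignment with a Karlin-Altschul E-value
#'
#' Thin, contract-stable wrapper around [Biostrings::pairwiseAlignment()]
#' (`type = "local"`, affine gaps: a gap of length L costs
#' `gap_open + L * gap_extend`). Identity is `matches / aligned_length`
#' where the aligned length includes gap columns. The E-value is
#' `K * m * n * exp(-lambda * score)` with lambda solved exactly for the
#' ungapped scoring pair ([karlin_lambda()]) and K a documented stand-in
#' constant (the lattice computation of K is not attempted): E-values are
#' strictly decreasing in score and linear in `m * n`, which is all the
#' downstream gates rely on.
#'
#' @param query,subject nucleotide strings or `DNAString`s (non-empty; for
#'   complementarity screens pass the reverse complement of the target as
#'   `subject`).
#' @param match,mismatch,gap_open,gap_extend scoring parameters; gap costs
#'   are positive.
#' @param k_const Karlin-Altschul K stand-in.
#' @return list with `score`, `identity`, `aligned_length`, `query_start`,
#'   `query_end`, `subject_start`, `subject_end`, `evalue`.
#' @export
local_align <- function(query, subject, match = 1, mismatch = -2,
                        gap_open = 5, gap_extend = 2, k_const = 0.333) {
  q <- toupper(as.character(query)); s <- toupper(as.character(subject))
  if (nchar(q) == 0 || nchar(s) == 0) stop("empty sequence")
  if (grepl("[^ACGTUN]", q) || grepl("[^ACGTUN]", s))
    stop("non-nucleotide characters in input")
  q <- chartr("U", "T", q); s <- chartr("U", "T", s)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(q, s, substitutionMatrix = sm,
                                       gapOpening = gap_open,
                                       gapExtension = gap_extend,
                                       type = "local")
  sc <- Biostrings::score(aln)
  alen <- Biostrings::nchar(aln)
  nm <- Biostrings::nmatch(aln)
  lam <- karlin_lambda(match, mismatch)
  ev <- k_const * nchar(q) * nchar(s) * exp(-lam * sc)
  pr <- aln@pattern@range
  sr <- aln@subject@range
  list(score = sc,
       identity = if (alen > 0) nm / alen else 0,
       aligned_length = alen,
       query_start = IRanges::start(pr), query_end = IRanges::end(pr),
       subject_start = IRanges::start(sr), subject_end = IRanges::end(sr),
       evalue = ev)
}

#' All-vs-all local alignment scores
#'
#' Score-only Smith-Waterman of every sequence in `a` against every sequence
#' in `b`; used by the homolog search. The scoring scheme is symmetric, so
#' `align_score_matrix(a, b) == t(align_score_matrix(b, a))`.
#'
#' @param a,b named `DNAStringSet`s (or named character vectors).
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return numeric matrix `length(a)` x `length(b)`.
#' @export
align_score_matrix <- function(a, b, match = 1, mismatch = -2,
                               gap_open = 5, gap_extend = 2) {
  if (is.character(a)) a <- Biostrings::DNAStringSet(a)
  if (is.character(b)) b <- Biostrings::DNAStringSet(b)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  out <- matrix(NA_real_, length(a), length(b),
                dimnames = list(names(a), names(b)))
  for (i in seq_along(a)) {
    out[i, ] <- Biostrings::pairwiseAlignment(
      rep(a[i], length(b)), b, substitutionMatrix = sm,
      gapOpening = gap_open, gapExtension = gap_extend,
      type = "local", scoreOnly = TRUE)
  }
  out
}

#' Reverse complement helper
#'
#' @param x nucleotide string.
#' @return reverse complement as a character string (DNA alphabet).
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("U", "T", toupper(as.character(x))))))
}
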