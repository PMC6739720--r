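#' Homologous lncRNAs between two species by reciprocal best hits
#'
#' Sense-strand local alignment of the two lncRNA sequence sets (these are
#' transcripts, not genomic loci), seeded the way word-based aligners are:
#' only sequence pairs sharing at least `min_seed_kmers` exact k-mers
#' (default: 3 shared 12-mers -- chance sharing between unrelated
#' transcripts is negligible at this word size) are aligned in full, which
#' keeps all-vs-all search tractable without changing which pairs can pass
#' the E-value gate (unseeded pairs cannot reach gate-worthy scores).
#' Candidate hits are gated at `evalue < trans_max_evalue`; a pair is
#' emitted when each member is the other's best-scoring hit (reciprocal
#' best hit, ties broken by sequence name so results are deterministic).
#' Each id appears in at most one pair; ids without a pair are reported as
#' species-specific.
#'
#' In addition to the E-value gate, the reciprocal best alignment must span
#' at least `min_align_nt` nucleotides: Karlin-Altschul E-values are
#' asymptotic and a bare ~20-nt exact word between kilobase transcripts can
#' reach E < 1e-5 by chance without being homology evidence, so a minimum
#' alignment span is the standard guard (any true homolog pair in this
#' problem is supported by hundreds of aligned nucleotides).
#'
#' @param seqs_a,seqs_b named `DNAStringSet`s (or named character vectors) of
#'   lncRNA sequences for species A and B.
#' @param config an `lnc_config`.
#' @param seed_k k-mer size of the seeding prefilter.
#' @param min_seed_kmers minimum shared k-mers to trigger a full alignment.
#' @param min_align_nt minimum aligned length supporting a pair.
#' @return list with `pairs` (data.frame `id_a`, `id_b`, `score`, `identity`,
#'   `evalue`), `specific_a` and `specific_b` (character vectors).
#' @export
find_homologs <- function(seqs_a, seqs_b, config = lnc_config(),
                          seed_k = 12L, min_seed_kmers = 3L,
                          min_align_nt = 50L) {
  validate_config(config)
  if (is.character(seqs_a)) seqs_a <- Biostrings::DNAStringSet(seqs_a)
  if (is.character(seqs_b)) seqs_b <- Biostrings::DNAStringSet(seqs_b)
  empty <- list(pairs = data.frame(id_a = character(0), id_b = character(0),
                                   score = numeric(0), identity = numeric(0),
                                   evalue = numeric(0),
                                   stringsAsFactors = FALSE),
                specific_a = sort(names(seqs_a)),
                specific_b = sort(names(seqs_b)))
  if (length(seqs_a) == 0 || length(seqs_b) == 0) return(empty)
  cand <- seeded_candidates(seqs_a, seqs_b, seed_k, min_seed_kmers)
  sc <- matrix(-Inf, length(seqs_a), length(seqs_b),
               dimnames = list(names(seqs_a), names(seqs_b)))
  if (nrow(cand) > 0) {
    sm <- Biostrings::nucleotideSubstitutionMatrix(
      match = config$align_match, mismatch = config$align_mismatch,
      baseOnly = FALSE)
    sc[cbind(cand$ia, cand$ib)] <- Biostrings::pairwiseAlignment(
      seqs_a[cand$ia], seqs_b[cand$ib], substitutionMatrix = sm,
      gapOpening = config$align_gap_open,
      gapExtension = config$align_gap_extend,
      type = "local", scoreOnly = TRUE)
  }
  lam <- karlin_lambda(config$align_match, config$align_mismatch)
  wa <- Biostrings::width(seqs_a); wb <- Biostrings::width(seqs_b)
  ev <- 0.333 * outer(wa, wb) * exp(-lam * sc)
  ok <- ev < config$trans_max_evalue
  # best hit of each A in B and vice versa (ties -> first name order)
  ord_a <- order(colnames(sc))
  ord_b <- order(rownames(sc))
  best_ab <- apply(sc[, ord_a, drop = FALSE], 1, function(r)
    if (all(!is.finite(r))) NA_character_
    else colnames(sc)[ord_a][which.max(r)])
  best_ba <- apply(sc[ord_b, , drop = FALSE], 2, function(cl)
    if (all(!is.finite(cl))) NA_character_
    else rownames(sc)[ord_b][which.max(cl)])
  pairs <- list()
  for (ia in rownames(sc)) {
    ib <- best_ab[[ia]]
    if (is.na(ib)) next
    if (!identical(best_ba[[ib]], ia)) next
    if (!ok[ia, ib]) next
    hit <- local_align(as.character(seqs_a[[ia]]),
                       as.character(seqs_b[[ib]]),
                       match = config$align_match,
                       mismatch = config$align_mismatch,
                       gap_open = config$align_gap_open,
                       gap_extend = config$align_gap_extend)
    if (hit$aligned_length < min_align_nt) next
    pairs[[ia]] <- data.frame(id_a = ia, id_b = ib, score = sc[ia, ib],
                              identity = hit$identity, evalue = ev[ia, ib],
                              stringsAsFactors = FALSE)
  }
  if (length(pairs) == 0) return(empty)
  pr <- do.call(rbind, pairs)
  rownames(pr) <- NULL
  pr <- pr[order(pr$id_a), , drop = FALSE]
  list(pairs = pr,
       specific_a = sort(setdiff(names(seqs_a), pr$id_a)),
       specific_b = sort(setdiff(names(seqs_b), pr$id_b)))
}

# sequence pairs sharing >= min_n exact k-mers (indices into a and b)
seeded_candidates <- function(seqs_a, seqs_b, k, min_n) {
  kmers <- function(seqs) {
    out <- lapply(seq_along(seqs), function(i) {
      s <- as.character(seqs[[i]])
      L <- nchar(s)
      if (L < k) return(data.frame(kmer = character(0), idx = integer(0)))
      data.frame(kmer = unique(substring(s, 1:(L - k + 1), k:L)),
                 idx = i, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  ka <- kmers(seqs_a); kb <- kmers(seqs_b)
  if (nrow(ka) == 0 || nrow(kb) == 0)
    return(data.frame(ia = integer(0), ib = integer(0)))
  mg <- merge(ka, kb, by = "kmer")
  if (nrow(mg) == 0) return(data.frame(ia = integer(0), ib = integer(0)))
  cnt <- stats::aggregate(kmer ~ idx.x + idx.y, data = mg, FUN = length)
  cnt <- cnt[cnt$kmer >= min_n, , drop = FALSE]
  data.frame(ia = cnt$idx.x, ib = cnt$idx.y)
}

#' Expression concordance of homolog pairs
#'
#' Spearman rho over the control-condition (0 mM) tissue means of the two
#' members; `similar_pattern` iff `rho > concordance_rho` (strict). FPKM is
#' compared across species without additional normalization (none is
#' applied in the emulated protocol); rho is rank-based and insensitive to
#' scale. A constant profile on either side leaves rho unset and
#' `similar_pattern` FALSE, with a warning.
#'
#' @param pairs data.frame with `id_a`, `id_b` (from [find_homologs()]).
#' @param se_a,se_b expression matrices of the two species sharing the
#'   tissue vocabulary.
#' @param config an `lnc_config`.
#' @return `pairs` with added `rho` and `similar_pattern` columns.
#' @export
homolog_concordance <- function(pairs, se_a, se_b, config = lnc_config()) {
  if (nrow(pairs) == 0) {
    pairs$rho <- numeric(0); pairs$similar_pattern <- logical(0)
    return(pairs)
  }
  tma <- tissue_means(se_a, 0)
  tmb <- tissue_means(se_b, 0)
  shared <- intersect(colnames(tma), colnames(tmb))
  if (length(shared) < 2) stop("species share fewer than 2 tissues")
  rho <- rep(NA_real_, nrow(pairs))
  n_const <- 0L
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$id_a[i]; b <- pairs$id_b[i]
    if (!a %in% rownames(tma) || !b %in% rownames(tmb)) next
    x <- tma[a, shared]; y <- tmb[b, shared]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) { n_const <- n_const + 1L; next }
    rho[i] <- stats::cor(x, y, method = "spearman")
  }
  if (n_const > 0)
    warning(n_const, " pair(s) with a constant tissue profile: rho unset")
  pairs$rho <- rho
  pairs$similar_pattern <- !is.na(rho) & rho > config$concordance_rho
  pairs
}

#' Species-specific salt-responsive lncRNAs
#'
#' Ids of species A that have no homolog pair and are salt-responsive in at
#' least one (tissue, contrast). A per-tissue breakdown (number of
#' species-specific DE lncRNAs with a DE call in each tissue) is attached as
#' the `"per_tissue"` attribute.
#'
#' @param ids_a all lncRNA ids of species A.
#' @param pairs homolog pairs data.frame (`id_a` column).
#' @param de_a DE table of species A from [call_de()].
#' @return character vector of ids (sorted), with attribute `per_tissue`.
#' @export
species_specific_de <- function(ids_a, pairs, de_a) {
  unpaired <- setdiff(ids_a, pairs$id_a)
  responsive <- salt_responsive(de_a)
  out <- sort(intersect(unpaired, responsive))
  det <- unique(de_a[de_a$is_de & de_a$transcript_id %in% out,
                     c("transcript_id", "tissue")])
  attr(out, "per_tissue") <- table(det$tissue)
  out
}

#' Homolog pairs highly expressed in species A
#'
#' For each tissue, a pair is flagged when the control-condition (0 mM) mean
#' of the A member strictly exceeds `fc` times the B member's mean. A pair
#' can be flagged in several tissues. A zero B mean flags the tissue iff the
#' A mean is positive (noted in a message rather than regularized with a
#' pseudocount).
#'
#' @param pairs homolog pairs data.frame (`id_a`, `id_b`).
#' @param se_a,se_b expression matrices.
#' @param fc fold-change threshold (> 1), default the published 4.
#' @return `pairs` with added `high_in_a_tissues` (comma-separated tissue
#'   names, `""` when none) and `n_high_tissues` columns.
#' @export
high_expression_pairs <- function(pairs, se_a, se_b, fc = 4) {
  stopifnot(fc > 1)
  if (nrow(pairs) == 0) {
    pairs$high_in_a_tissues <- character(0)
    pairs$n_high_tissues <- integer(0)
    return(pairs)
  }
  tma <- tissue_means(se_a, 0)
  tmb <- tissue_means(se_b, 0)
  shared <- intersect(colnames(tma), colnames(tmb))
  n_zero <- 0L
  flags <- character(nrow(pairs))
  nh <- integer(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$id_a[i]; b <- pairs$id_b[i]
    if (!a %in% rownames(tma) || !b %in% rownames(tmb)) next
    xa <- tma[a, shared]; xb <- tmb[b, shared]
    hi <- ifelse(xb == 0, xa > 0, xa > fc * xb)
    n_zero <- n_zero + sum(xb == 0)
    flags[i] <- paste(shared[hi], collapse = ",")
    nh[i] <- sum(hi)
  }
  if (n_zero > 0)
    message(n_zero, " zero denominator(s): flagged iff A mean > 0")
  pairs$high_in_a_tissues <- flags
  pairs$n_high_tissues <- nh
  pairs
}

#' Tissue-specific homolog comparison
#'
#' Restricts homolog pairs to those whose two members are both
#' tissue-specific and partitions them by whether the maximal tissue
#' matches.
#'
#' @param pairs homolog pairs data.frame.
#' @param spec_a,spec_b `tissue_specific` data.frames from
#'   [specificity_sets()] for the two species.
#' @return data.frame `id_a`, `id_b`, `tissue_a`, `tissue_b`, `same_tissue`.
#' @export
tissue_specific_homologs <- function(pairs, spec_a, spec_b) {
  ia <- match(pairs$id_a, spec_a$transcript_id)
  ib <- match(pairs$id_b, spec_b$transcript_id)
  keep <- !is.na(ia) & !is.na(ib)
  data.frame(id_a = pairs$id_a[keep], id_b = pairs$id_b[keep],
             tissue_a = spec_a$max_tissue[ia[keep]],
             tissue_b = spec_b$max_tissue[ib[keep]],
             same_tissue = spec_a$max_tissue[ia[keep]] ==
               spec_b$max_tissue[ib[keep]],
             stringsAsFactors = FALSE)
}
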