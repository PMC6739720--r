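#' Cis target genes by genomic proximity
#'
#' Pairs every lncRNA with each gene whose span overlaps it or lies within
#' `window_bp` of it (gap measured span-to-span, inclusive at the window;
#' a gene at gap `window_bp + 1` is not paired). The relation is resolved
#' from the lncRNA's strand: a gene entirely 5' of the lncRNA is `upstream`,
#' 3' is `downstream`; overlapping genes get `overlapping`; lncRNAs
#' classified as intronic always pair with their host gene as `intron_host`
#' (distance 0).
#'
#' @param lnc `transcript_set` of lncRNAs.
#' @param genes `transcript_set` of gene models.
#' @param window_bp window in bp (default the published 10 kb).
#' @param classification optional data.frame from [classify_transcripts()];
#'   used to tag intron hosts.
#' @return data.frame with `lncrna_id`, `gene_id`, `mode` (`"cis"`),
#'   `relation`, `distance_bp`.
#' @export
cis_targets <- function(lnc, genes, window_bp = 10000L,
                        classification = NULL) {
  lspan <- tx_spans(lnc)
  gspan <- tx_spans(genes)
  empty <- data.frame(lncrna_id = character(0), gene_id = character(0),
                      mode = character(0), relation = character(0),
                      distance_bp = numeric(0), stringsAsFactors = FALSE)
  if (length(lspan) == 0 || length(gspan) == 0) return(empty)
  hits <- GenomicRanges::findOverlaps(lspan, gspan, maxgap = window_bp,
                                      ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ls <- GenomicRanges::start(lspan)[qh]; le <- GenomicRanges::end(lspan)[qh]
  gs <- GenomicRanges::start(gspan)[sh]; ge <- GenomicRanges::end(gspan)[sh]
  lstrand <- as.character(GenomicRanges::strand(lspan))[qh]
  gap <- pmax(0L, pmax(gs - le, ls - ge) - 1L)
  # side of the gene relative to the lncRNA in genomic coordinates
  before <- ge < ls
  after <- gs > le
  relation <- ifelse(!before & !after, "overlapping",
                     ifelse(xor(before, lstrand == "-"),
                            "upstream", "downstream"))
  out <- data.frame(
    lncrna_id = S4Vectors::mcols(lspan)$transcript_id[qh],
    gene_id = S4Vectors::mcols(gspan)$gene_id[sh],
    mode = "cis", relation = relation, distance_bp = as.numeric(gap),
    stringsAsFactors = FALSE)
  if (!is.null(classification)) {
    intr <- classification[classification$class == "intronic", , drop = FALSE]
    key <- paste(out$lncrna_id, out$gene_id)
    host <- paste(intr$transcript_id, intr$host_gene)
    out$relation[key %in% host] <- "intron_host"
    out$distance_bp[key %in% host] <- 0
  }
  out <- out[out$distance_bp <= window_bp, , drop = FALSE]
  out <- out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trans target genes by complementarity and duplex energy
#'
#' Two conjunctive gates applied in order, mirroring the published screen:
#'
#' 1. alignment gate -- Smith-Waterman of the lncRNA against the reverse
#'    complement of each mRNA; keep hits with identity >=
#'    `trans_min_identity` and E-value < `trans_max_evalue`;
#' 2. energy gate -- duplex free energy ([duplex_energy()]) of the pair must
#'    be <= `duplex_energy_cut`.
#'
#' The energy is only computed for pairs passing the alignment gate.
#'
#' @param lnc `transcript_set` of lncRNAs with sequences.
#' @param mrna `transcript_set` of mRNAs with sequences (its `gene_id` is
#'   reported).
#' @param config an `lnc_config`.
#' @return data.frame with `lncrna_id`, `gene_id`, `mode` (`"trans"`),
#'   `identity`, `evalue`, `energy_kcal_mol`.
#' @export
trans_targets <- function(lnc, mrna, config = lnc_config()) {
  validate_config(config)
  lseq <- tx_sequences(lnc)
  mseq <- tx_sequences(mrna)
  if (is.null(lseq) || is.null(mseq))
    stop("both transcript sets need sequences for trans prediction")
  mspan <- tx_spans(mrna)
  gene_of <- stats::setNames(S4Vectors::mcols(mspan)$gene_id,
                             S4Vectors::mcols(mspan)$transcript_id)
  out <- list()
  for (li in names(lseq)) {
    q <- as.character(lseq[[li]])
    for (mi in names(mseq)) {
      subj <- reverse_complement(as.character(mseq[[mi]]))
      hit <- local_align(q, subj,
                         match = config$align_match,
                         mismatch = config$align_mismatch,
                         gap_open = config$align_gap_open,
                         gap_extend = config$align_gap_extend)
      if (hit$identity < config$trans_min_identity ||
          hit$evalue >= config$trans_max_evalue) next
      en <- duplex_energy(q, as.character(mseq[[mi]]))
      if (en > config$duplex_energy_cut) next
      out[[paste(li, mi)]] <- data.frame(
        lncrna_id = li, gene_id = unname(gene_of[mi]), mode = "trans",
        identity = hit$identity, evalue = hit$evalue,
        energy_kcal_mol = en, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(lncrna_id = character(0), gene_id = character(0),
                      mode = character(0), identity = numeric(0),
                      evalue = numeric(0), energy_kcal_mol = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$lncrna_id, res$gene_id), , drop = FALSE]
}

#' Expression concordance of lncRNA-target pairs
#'
#' Spearman correlation between the per-(tissue, salt) mean expression
#' profiles of the two members of each pair. Trend is `"same"` when
#' `rho > concordance_rho` (strict), `"opposite"` when
#' `rho < -concordance_rho`, else `"none"`. Constant profiles leave rho
#' unset (`NA`) and the trend `"none"`.
#'
#' @param pairs data.frame with `lncrna_id` and `gene_id` columns; the gene
#'   is looked up in `se` by `gene_map` when transcript and gene ids differ.
#' @param se expression matrix containing both members of each pair.
#' @param config an `lnc_config`.
#' @param gene_map optional named vector translating `gene_id` to the
#'   expression row id (default: identity).
#' @return `pairs` with added `rho` and `trend` columns.
#' @export
pair_concordance <- function(pairs, se, config = lnc_config(),
                             gene_map = NULL) {
  if (nrow(pairs) == 0) {
    pairs$rho <- numeric(0); pairs$trend <- character(0)
    return(pairs)
  }
  cm <- condition_means(se)
  tid <- pairs$gene_id
  if (!is.null(gene_map)) tid <- unname(gene_map[tid])
  rho <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$lncrna_id[i]; g <- tid[i]
    if (!a %in% rownames(cm) || !g %in% rownames(cm)) next
    x <- cm[a, ]; y <- cm[g, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    rho[i] <- stats::cor(x, y, method = "spearman")
  }
  pairs$rho <- rho
  pairs$trend <- ifelse(is.na(rho), "none",
                        ifelse(rho > config$concordance_rho, "same",
                               ifelse(rho < -config$concordance_rho,
                                      "opposite", "none")))
  pairs
}
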