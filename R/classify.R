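#' Positional classification of lncRNAs
#'
#' Classifies each lncRNA against protein-coding gene models into the four
#' positional classes, with the fixed priority cascade:
#'
#' 1. `sense_overlap` -- at least one exon-exon overlap with a same-strand
#'    gene;
#' 2. `antisense` -- otherwise, at least one exon-exon overlap with an
#'    opposite-strand gene (a lncNAT);
#' 3. `intronic` -- otherwise, the transcript span lies wholly inside a
#'    single intron of some gene (either strand);
#' 4. `lincRNA` -- otherwise; the gap to the nearest gene span is recorded.
#'
#' Overlap queries use the interval-tree machinery of GenomicRanges; tests
#' check exact agreement with a brute-force all-pairs oracle. When several
#' genes satisfy a rule the host is the one with the largest overlap (ties
#' broken by gene id) so results are deterministic.
#'
#' @param lnc `transcript_set` of lncRNAs.
#' @param genes `transcript_set` of protein-coding gene models (transcript
#'   resolution; `gene_id` is reported as the host).
#' @return data.frame with columns `transcript_id`, `class`, `host_gene`,
#'   `distance_bp` (0 for overlapping/intronic classes; gap in bp for
#'   lincRNAs, `Inf` when the chromosome has no gene at all, with a warning).
#' @export
classify_transcripts <- function(lnc, genes) {
  ids <- tx_ids(lnc)
  n <- length(ids)
  out <- data.frame(transcript_id = ids,
                    class = rep(NA_character_, n),
                    host_gene = rep(NA_character_, n),
                    distance_bp = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  if (n == 0) return(out)

  lex <- tx_exons(lnc)
  gex <- tx_exons(genes)
  lspan <- tx_spans(lnc)
  gspan <- tx_spans(genes)
  gmc <- S4Vectors::mcols(gex)

  # rules 1-2: exon-exon overlap, split by relative strand (disjoint
  # seqlevels between the two sets are legitimate, hence the suppress)
  if (length(gex) > 0) {
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(lex, gex, ignore.strand = TRUE))
    if (length(ov) > 0) {
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      same <- as.character(GenomicRanges::strand(lex))[qh] ==
        as.character(GenomicRanges::strand(gex))[sh]
      w <- GenomicRanges::width(IRanges::pintersect(
        IRanges::ranges(lex)[qh], IRanges::ranges(gex)[sh]))
      hits <- data.frame(
        tid = S4Vectors::mcols(lex)$transcript_id[qh],
        gid = gmc$gene_id[sh], same = same, w = w,
        stringsAsFactors = FALSE)
      assign_overlap <- function(h, cls) {
        if (nrow(h) == 0) return()
        agg <- stats::aggregate(w ~ tid + gid, data = h, FUN = sum)
        agg <- agg[order(agg$tid, -agg$w, agg$gid), ]
        best <- agg[!duplicated(agg$tid), ]
        i <- match(best$tid, out$transcript_id)
        todo <- is.na(out$class[i])
        out$class[i[todo]] <<- cls
        out$host_gene[i[todo]] <<- best$gid[todo]
        out$distance_bp[i[todo]] <<- 0
      }
      assign_overlap(hits[hits$same, , drop = FALSE], "sense_overlap")
      assign_overlap(hits[!hits$same, , drop = FALSE], "antisense")
    }
  }

  # rule 3: span wholly inside a single intron
  open <- which(is.na(out$class))
  if (length(open) > 0 && length(gex) > 0) {
    introns <- gene_introns(genes)
    if (length(introns) > 0) {
      iv <- suppressWarnings(
        GenomicRanges::findOverlaps(lspan[match(out$transcript_id[open],
                                                S4Vectors::mcols(lspan)$transcript_id)],
                                    introns, type = "within",
                                    ignore.strand = TRUE))
      if (length(iv) > 0) {
        qh <- open[S4Vectors::queryHits(iv)]
        gid <- S4Vectors::mcols(introns)$gene_id[S4Vectors::subjectHits(iv)]
        df <- data.frame(i = qh, gid = gid, stringsAsFactors = FALSE)
        df <- df[order(df$i, df$gid), ]
        df <- df[!duplicated(df$i), ]
        out$class[df$i] <- "intronic"
        out$host_gene[df$i] <- df$gid
        out$distance_bp[df$i] <- 0
      }
    }
  }

  # rule 4: lincRNA, gap to nearest gene span
  open <- which(is.na(out$class))
  if (length(open) > 0) {
    out$class[open] <- "lincRNA"
    if (length(gspan) == 0) {
      warning("no gene models; all lincRNA distances set to Inf")
      out$distance_bp[open] <- Inf
    } else {
      sub <- lspan[match(out$transcript_id[open],
                         S4Vectors::mcols(lspan)$transcript_id)]
      # disjoint seqlevels between query and genes are expected (handled via
      # the Inf sentinel below), so silence the combine warning
      nr <- suppressWarnings(
        GenomicRanges::distanceToNearest(sub, gspan, ignore.strand = TRUE))
      hit <- S4Vectors::queryHits(nr)
      out$distance_bp[open[hit]] <- S4Vectors::mcols(nr)$distance
      out$host_gene[open[hit]] <-
        S4Vectors::mcols(gspan)$gene_id[S4Vectors::subjectHits(nr)]
      nohit <- setdiff(seq_along(open), hit)
      if (length(nohit) > 0) {
        warning(length(nohit), " lncRNA(s) on chromosomes without genes; ",
                "distance set to Inf")
        out$distance_bp[open[nohit]] <- Inf
      }
    }
  }
  out
}

#' Introns of gene models
#'
#' Gaps between consecutive exons of each gene transcript, annotated with the
#' owning `gene_id`.
#'
#' @param genes `transcript_set`.
#' @return `GRanges` of introns (possibly empty).
#' @export
gene_introns <- function(genes) {
  ex <- tx_exons(genes)
  if (length(ex) == 0)
    return(GenomicRanges::GRanges(gene_id = character(0)))
  mc <- S4Vectors::mcols(ex)
  res <- list()
  for (id in unique(mc$transcript_id)) {
    i <- which(mc$transcript_id == id)
    if (length(i) < 2) next
    s <- GenomicRanges::start(ex)[i]; e <- GenomicRanges::end(ex)[i]
    o <- order(s)
    s <- s[o]; e <- e[o]
    ist <- e[-length(e)] + 1L
    ien <- s[-1] - 1L
    keep <- ien >= ist
    if (!any(keep)) next
    res[[id]] <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(ex)[i[1]],
      IRanges::IRanges(ist[keep], ien[keep]),
      strand = GenomicRanges::strand(ex)[i[1]],
      gene_id = mc$gene_id[i[1]])
  }
  if (length(res) == 0)
    return(GenomicRanges::GRanges(gene_id = character(0)))
  out <- suppressWarnings(do.call(c, unname(res)))
  out
}

#' Classify all lncRNAs and tabulate class counts
#'
#' @param lnc,genes as in [classify_transcripts()].
#' @return list with `results` (the per-transcript data.frame) and `counts`
#'   (named integer vector over the four classes; always sums to the number
#'   of lncRNAs).
#' @export
classify_all <- function(lnc, genes) {
  res <- classify_transcripts(lnc, genes)
  classes <- c("lincRNA", "intronic", "antisense", "sense_overlap")
  counts <- stats::setNames(integer(4), classes)
  tb <- table(factor(res$class, levels = classes))
  counts[names(tb)] <- as.integer(tb)
  list(results = res, counts = counts)
}
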