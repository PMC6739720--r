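#' Read transcript models from GTF/GFF
#'
#' Parses a GTF (GFF2) or GFF3 annotation into a [transcript_set()]. Only
#' `exon` features are used; transcripts are grouped by `transcript_id`
#' (GTF) or `Parent` (GFF3). A `gene_biotype`/`transcript_biotype` attribute
#' of `"protein_coding"` or `"coding"` marks a transcript as coding.
#'
#' @param path annotation file; format inferred from the extension
#'   (`.gff3`/`.gff` = GFF3, anything else GTF) unless `format` is given.
#' @param format `NULL`, `"gtf"` or `"gff3"`.
#' @return A `transcript_set` (without sequences). An empty file yields an
#'   empty set with a warning.
#' @export
read_annotation <- function(path, format = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^\\s*(#|$)", lines)
  if (!any(body)) {
    warning("annotation file ", path, " contains no records")
    return(transcript_set(GenomicRanges::GRanges(
      transcript_id = character(0), gene_id = character(0),
      biotype = character(0))))
  }
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 8)) {
    bad <- which(body)[which(nf < 8)[1]]
    stop("malformed annotation line ", bad, " in ", path,
         " (expected 9 tab-separated fields, got ", nf[which(nf < 8)[1]], ")")
  }
  if (is.null(format))
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "gtf"
  gr <- rtracklayer::import(path, format = format)
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0) {
    warning("annotation file ", path, " has no exon records")
    return(transcript_set(GenomicRanges::GRanges(
      transcript_id = character(0), gene_id = character(0),
      biotype = character(0))))
  }
  mc <- S4Vectors::mcols(gr)
  tid <- if (!is.null(mc$transcript_id)) as.character(mc$transcript_id)
         else if (!is.null(mc$Parent)) as.character(unlist(mc$Parent))
         else stop("no transcript_id/Parent attribute in ", path)
  gid <- if (!is.null(mc$gene_id)) as.character(mc$gene_id) else tid
  bt <- rep("unknown", length(gr))
  for (col in c("gene_biotype", "transcript_biotype", "biotype")) {
    if (!is.null(mc[[col]])) {
      bt <- ifelse(as.character(mc[[col]]) %in% c("coding", "protein_coding"),
                   "coding", "unknown")
      break
    }
  }
  out <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(gr), IRanges::ranges(gr),
    strand = GenomicRanges::strand(gr),
    transcript_id = tid, gene_id = gid, biotype = bt)
  transcript_set(out)
}

#' Write transcript models as GTF
#'
#' Inverse of [read_annotation()]: emits one `exon` feature per exon with
#' `transcript_id`, `gene_id` and `gene_biotype` attributes. Round trips
#' preserve transcript ids, spans and exon counts.
#'
#' @param ts a `transcript_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ts, path) {
  ex <- ts$exons
  mc <- S4Vectors::mcols(ex)
  out <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(ex), IRanges::ranges(ex),
    strand = GenomicRanges::strand(ex),
    type = "exon",
    transcript_id = mc$transcript_id, gene_id = mc$gene_id,
    gene_biotype = mc$biotype)
  rtracklayer::export(out, path, format = "gtf")
  invisible(path)
}

#' Read / write spliced transcript sequences (FASTA)
#'
#' @param path FASTA file.
#' @return A named `DNAStringSet`.
#' @export
read_transcript_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' @param seqs named `DNAStringSet` or character vector.
#' @rdname read_transcript_fasta
#' @export
write_transcript_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read a replicated FPKM matrix and its sample sheet
#'
#' The matrix TSV has transcript ids in the first column and one column per
#' sample; the sample sheet TSV has columns `sample_id`, `tissue`, `salt_mM`,
#' `replicate`. Missing cells, negative values, duplicated transcript ids and
#' samples absent from the sheet are hard errors, never imputed.
#'
#' @param path matrix TSV.
#' @param meta_path sample sheet TSV.
#' @return A `SummarizedExperiment` (see [expr_matrix()]).
#' @export
read_expression <- function(path, meta_path) {
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression table needs id column plus samples")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicate transcript id in ", path, ": ", ids[duplicated(ids)][1])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    suppressWarnings(mn <- matrix(as.numeric(m), nrow(m), ncol(m),
                                  dimnames = dimnames(m)))
    if (anyNA(mn) && !anyNA(m)) {
      idx <- which(is.na(mn), arr.ind = TRUE)[1, ]
      stop("non-numeric FPKM at transcript '", ids[idx[1]], "', sample '",
           colnames(m)[idx[2]], "'")
    }
    m <- mn
  }
  rownames(m) <- ids
  meta <- utils::read.delim(meta_path, comment.char = "#",
                            stringsAsFactors = FALSE)
  expr_matrix(m, meta)
}

#' Write an expression matrix and sample sheet
#'
#' @param se a `SummarizedExperiment`.
#' @param path matrix TSV output.
#' @param meta_path sample sheet TSV output.
#' @param config optional `lnc_config`; when given, its hash is recorded in a
#'   header comment.
#' @return `path`, invisibly.
#' @export
write_expression <- function(se, path, meta_path, config = NULL) {
  m <- fpkm(se)
  df <- data.frame(transcript_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path, config)
  write_tsv(sample_info(se), meta_path, config)
  invisible(path)
}

#' Read precomputed external coding-potential scores
#'
#' Side input honoured by [identify_lncrnas()]: a TSV with columns
#' `transcript_id`, `cpc`, `cnci`. Transcripts listed here are discarded as
#' coding iff `cpc > 0` or `cnci > 0`, overriding the built-in scorer.
#'
#' @param path TSV file.
#' @return data.frame with the three columns.
#' @export
read_external_scores <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("transcript_id", "cpc", "cnci")
  if (!all(need %in% names(df)))
    stop("external score table needs columns: ", paste(need, collapse = ", "))
  df[, need]
}

#' Read tabular alignment hits (BLAST outfmt 6)
#'
#' Side input for users who ran an external aligner: standard 12-column
#' tabular output. Identity is rescaled to [0, 1].
#'
#' @param path tabular file.
#' @return data.frame with columns `query`, `subject`, `identity`,
#'   `aligned_length`, `evalue`, `bitscore`.
#' @export
read_blast_hits <- function(path) {
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 12) stop("expected 12 tab-separated columns in ", path)
  names(df)[1:12] <- cols
  data.frame(query = df$query, subject = df$subject,
             identity = df$pident / 100, aligned_length = df$length,
             evalue = df$evalue, bitscore = df$bitscore,
             stringsAsFactors = FALSE)
}

# Shared TSV writer: fixed formatting so identical inputs give identical bytes.
write_tsv <- function(df, path, config = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(config))
    writeLines(paste0("# lncsalt config_hash=", config_hash(config)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Read a TSV written by write_tsv (skipping header comments).
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
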