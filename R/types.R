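#' Transcript models
#'
#' A `transcript_set` bundles exon-structured, stranded transcript models and
#' (optionally) their spliced sequences. Exons live in a
#' [GenomicRanges::GRanges] with metadata columns `transcript_id`, `gene_id`
#' and `biotype` (`"coding"` or `"unknown"`); sequences are a
#' [Biostrings::DNAStringSet] named by transcript id whose widths must equal
#' the summed exon widths.
#'
#' Invariants enforced here: every transcript sits on a single chromosome and
#' strand; its exons, after sorting by start, are pairwise non-overlapping;
#' the transcript span runs from the first exon start to the last exon end.
#'
#' @param exons a `GRanges` of exons with at least a `transcript_id` metadata
#'   column. `gene_id` defaults to the transcript id and `biotype` to
#'   `"unknown"`.
#' @param sequences optional named `DNAStringSet` (or named character vector)
#'   of spliced transcript sequences.
#' @return An object of class `transcript_set` with elements `exons`, `spans`
#'   (one range per transcript, metadata `transcript_id`, `gene_id`,
#'   `biotype`, `n_exons`, `tx_length`) and `seq`.
#' @examples
#' ex <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(1001, 1601), c(1500, 2000)),
#'   strand = "+", transcript_id = "t1")
#' ts <- transcript_set(ex)
#' tx_lengths(ts)
#' @export
transcript_set <- function(exons, sequences = NULL) {
  stopifnot(methods::is(exons, "GRanges"))
  mc <- S4Vectors::mcols(exons)
  if (is.null(mc$transcript_id))
    stop("exons need a 'transcript_id' metadata column")
  if (is.null(mc$gene_id)) mc$gene_id <- mc$transcript_id
  if (is.null(mc$biotype)) mc$biotype <- "unknown"
  if (!all(mc$biotype %in% c("coding", "unknown")))
    stop("biotype must be 'coding' or 'unknown'")
  S4Vectors::mcols(exons) <- mc[, c("transcript_id", "gene_id", "biotype")]

  o <- order(mc$transcript_id, GenomicRanges::start(exons))
  exons <- exons[o]
  mc <- S4Vectors::mcols(exons)
  ids <- mc$transcript_id

  # per-transcript invariants
  byid <- split(seq_along(exons), ids)
  for (id in names(byid)) {
    i <- byid[[id]]
    if (length(unique(as.character(GenomicRanges::seqnames(exons)[i]))) != 1L)
      stop("transcript ", id, " has exons on multiple chromosomes")
    str <- unique(as.character(GenomicRanges::strand(exons)[i]))
    if (length(str) != 1L)
      stop("transcript ", id, " has exons on mixed strands")
    if (!str %in% c("+", "-"))
      stop("transcript ", id, " must be stranded (+ or -)")
    if (length(i) > 1L) {
      s <- GenomicRanges::start(exons)[i]; e <- GenomicRanges::end(exons)[i]
      if (any(s[-1] <= e[-length(e)]))
        stop("transcript ", id, " has overlapping exons")
    }
    gid <- unique(mc$gene_id[i]); bt <- unique(mc$biotype[i])
    if (length(gid) != 1L || length(bt) != 1L)
      stop("transcript ", id, " has inconsistent gene_id/biotype")
  }

  spans <- unlist(range(GenomicRanges::split(exons, ids)))
  sid <- names(spans)
  first <- match(sid, ids)
  S4Vectors::mcols(spans) <- S4Vectors::DataFrame(
    transcript_id = sid,
    gene_id = mc$gene_id[first],
    biotype = mc$biotype[first],
    n_exons = as.integer(lengths(byid)[sid]),
    tx_length = as.integer(vapply(byid[sid], function(i)
      sum(GenomicRanges::width(exons)[i]), numeric(1)))
  )
  names(spans) <- NULL

  if (!is.null(sequences)) {
    if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
    stopifnot(methods::is(sequences, "DNAStringSet"))
    if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
      stop("sequences must be uniquely named by transcript id")
    known <- intersect(names(sequences), sid)
    if (length(known) < length(sequences))
      stop("sequences present for unknown transcripts: ",
           paste(setdiff(names(sequences), sid), collapse = ", "))
    lens <- S4Vectors::mcols(spans)$tx_length[match(known, sid)]
    bad <- known[Biostrings::width(sequences[known]) != lens]
    if (length(bad) > 0)
      stop("sequence length != summed exon length for: ",
           paste(bad, collapse = ", "))
  }

  structure(list(exons = exons, spans = spans, seq = sequences),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  bt <- table(S4Vectors::mcols(x$spans)$biotype)
  cat("transcript_set:", length(x$spans), "transcripts (",
      paste(names(bt), bt, sep = "=", collapse = ", "), "),",
      length(x$exons), "exons,",
      if (is.null(x$seq)) "no sequences" else
        paste(length(x$seq), "sequences"), "\n")
  invisible(x)
}

#' @export
length.transcript_set <- function(x) length(x$spans)

#' Accessors for transcript sets
#'
#' @param ts a `transcript_set`.
#' @return `tx_ids`: character vector of transcript ids; `tx_spans`: `GRanges`
#'   of transcript spans; `tx_lengths`: named integer vector of spliced
#'   lengths; `tx_sequences`: named `DNAStringSet` or `NULL`;
#'   `tx_exons`: the exon `GRanges`.
#' @export
tx_ids <- function(ts) S4Vectors::mcols(ts$spans)$transcript_id

#' @rdname tx_ids
#' @export
tx_spans <- function(ts) ts$spans

#' @rdname tx_ids
#' @export
tx_exons <- function(ts) ts$exons

#' @rdname tx_ids
#' @export
tx_lengths <- function(ts) {
  stats::setNames(S4Vectors::mcols(ts$spans)$tx_length, tx_ids(ts))
}

#' @rdname tx_ids
#' @export
tx_sequences <- function(ts) ts$seq

#' Subset a transcript set by transcript id
#'
#' @param ts a `transcript_set`.
#' @param ids transcript ids to keep (or drop).
#' @param negate if `TRUE`, drop `ids` instead of keeping them.
#' @return A `transcript_set`. Order of retained transcripts follows `ids`
#'   where possible.
#' @export
subset_transcripts <- function(ts, ids, negate = FALSE) {
  all_ids <- tx_ids(ts)
  keep <- if (negate) setdiff(all_ids, ids) else intersect(ids, all_ids)
  if (!negate && length(missing <- setdiff(ids, all_ids)) > 0)
    stop("unknown transcript ids: ", paste(utils::head(missing, 5), collapse = ", "))
  ex <- ts$exons[S4Vectors::mcols(ts$exons)$transcript_id %in% keep]
  sq <- if (is.null(ts$seq)) NULL else ts$seq[intersect(names(ts$seq), keep)]
  transcript_set(ex, sq)
}

#' Split a transcript set into coding reference and candidates
#'
#' @param ts a `transcript_set`.
#' @return `coding_transcripts`: the subset annotated `biotype == "coding"`;
#'   `candidate_transcripts`: the rest.
#' @export
coding_transcripts <- function(ts) {
  subset_transcripts(ts, tx_ids(ts)[S4Vectors::mcols(ts$spans)$biotype == "coding"])
}

#' @rdname coding_transcripts
#' @export
candidate_transcripts <- function(ts) {
  subset_transcripts(ts, tx_ids(ts)[S4Vectors::mcols(ts$spans)$biotype != "coding"])
}

# ---- expression matrix -----------------------------------------------------

#' Build a replicated FPKM expression matrix
#'
#' Wraps a transcripts x samples FPKM matrix and its sample sheet into a
#' [SummarizedExperiment::SummarizedExperiment] (assay `"fpkm"`, colData
#' columns `tissue`, `salt_mM`, `replicate`). Values must be complete and
#' non-negative; sample ids must match between matrix and sheet.
#'
#' @param values numeric matrix, rownames = transcript ids, colnames = sample
#'   ids.
#' @param samples data.frame with columns `sample_id`, `tissue`, `salt_mM`,
#'   `replicate` covering every column of `values`.
#' @return A `SummarizedExperiment`.
#' @export
expr_matrix <- function(values, samples) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values needs transcript rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate transcript id: ",
         rownames(values)[duplicated(rownames(values))][1])
  need <- c("sample_id", "tissue", "salt_mM", "replicate")
  if (!all(need %in% names(samples)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  missing_meta <- setdiff(colnames(values), samples$sample_id)
  if (length(missing_meta) > 0)
    stop("samples absent from metadata: ", paste(missing_meta, collapse = ", "))
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop("missing FPKM value at transcript '", rownames(values)[idx[1]],
         "', sample '", colnames(values)[idx[2]], "'")
  }
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    stop("negative FPKM at transcript '", rownames(values)[idx[1]],
         "', sample '", colnames(values)[idx[2]], "'")
  }
  cd <- S4Vectors::DataFrame(tissue = as.character(samples$tissue),
                             salt_mM = as.numeric(samples$salt_mM),
                             replicate = as.integer(samples$replicate),
                             row.names = samples$sample_id)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = values), colData = cd)
}

#' FPKM assay and sample sheet of an expression matrix
#'
#' @param se a `SummarizedExperiment` built by [expr_matrix()].
#' @return `fpkm`: the numeric matrix; `sample_info`: the sample sheet as a
#'   `data.frame` with a `sample_id` column.
#' @export
fpkm <- function(se) SummarizedExperiment::assay(se, "fpkm")

#' @rdname fpkm
#' @export
sample_info <- function(se) {
  df <- as.data.frame(SummarizedExperiment::colData(se))
  df$sample_id <- rownames(df)
  rownames(df) <- NULL
  df[, c("sample_id", "tissue", "salt_mM", "replicate")]
}

#' Per-tissue mean expression
#'
#' Mean FPKM per transcript and tissue, optionally restricted to one salt
#' level (the usual input to the tau index is the control, 0 mM).
#'
#' @param se expression matrix.
#' @param salt_mM `NULL` (all samples) or one salt level.
#' @return numeric matrix transcripts x tissues (tissue order = order of
#'   first appearance in the sample sheet).
#' @export
tissue_means <- function(se, salt_mM = NULL) {
  info <- sample_info(se)
  keep <- if (is.null(salt_mM)) rep(TRUE, nrow(info)) else info$salt_mM == salt_mM
  if (!any(keep)) stop("no samples at salt level ", salt_mM)
  m <- fpkm(se)[, keep, drop = FALSE]
  tis <- info$tissue[keep]
  lev <- unique(info$tissue)
  out <- vapply(lev, function(tt)
    rowMeans(m[, tis == tt, drop = FALSE]), numeric(nrow(m)))
  if (nrow(m) == 1L) out <- matrix(out, nrow = 1,
                                   dimnames = list(rownames(m), lev))
  out
}

#' Per-condition mean expression
#'
#' Mean FPKM per transcript for every (tissue, salt) combination; columns are
#' named `tissue@salt` and ordered by tissue appearance then salt level.
#'
#' @param se expression matrix.
#' @return numeric matrix transcripts x conditions.
#' @export
condition_means <- function(se) {
  info <- sample_info(se)
  grp <- interaction(info$tissue, info$salt_mM, sep = "@", drop = TRUE)
  lev <- unique(info$tissue)
  salts <- sort(unique(info$salt_mM))
  want <- as.vector(t(outer(lev, salts, paste, sep = "@")))
  want <- want[want %in% levels(grp)]
  m <- fpkm(se)
  out <- vapply(want, function(g)
    rowMeans(m[, grp == g, drop = FALSE]), numeric(nrow(m)))
  if (nrow(m) == 1L) out <- matrix(out, nrow = 1,
                                   dimnames = list(rownames(m), want))
  out
}

#' Validate that a design contains the full tissue x salt x replicate grid
#'
#' @param samples sample sheet data.frame.
#' @return invisibly `TRUE`, or an error naming the missing cell.
#' @export
validate_design <- function(samples) {
  if (!0 %in% samples$salt_mM)
    stop("design is missing the control level (0 mM); contrasts are undefined")
  tab <- table(samples$tissue, samples$salt_mM)
  if (any(tab == 0)) {
    idx <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop("design cell without samples: tissue '", rownames(tab)[idx[1]],
         "' at ", colnames(tab)[idx[2]], " mM")
  }
  invisible(TRUE)
}
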