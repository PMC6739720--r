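#' @name fickett_tables
#' @title Fickett TESTCODE lookup tables
#' @description The published position/composition lookup tables of the
#'   Fickett TESTCODE statistic, exported so tests can walk them by hand.
#'   `position` and `content` hold, per base, the probability assigned to
#'   each parameter bin; `position_cut` / `content_cut` are the descending
#'   bin thresholds (a value falls in the first bin whose threshold it
#'   reaches); `position_weight` / `content_weight` are the per-base weights.
#' @format Named lists of numeric vectors (bases A, C, G, T).
NULL

#' @rdname fickett_tables
#' @export
fickett_position_prob <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))

#' @rdname fickett_tables
#' @export
fickett_position_cut <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)

#' @rdname fickett_tables
#' @export
fickett_position_weight <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)

#' @rdname fickett_tables
#' @export
fickett_content_prob <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))

#' @rdname fickett_tables
#' @export
fickett_content_cut <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19,
                         0.17, 0.0)

#' @rdname fickett_tables
#' @export
fickett_content_weight <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)

clean_seq <- function(sequence) {
  s <- toupper(as.character(sequence))
  chartr("U", "T", s)
}

#' Longest open reading frame
#'
#' Scans the three sense-strand frames for the longest ATG-to-stop open
#' reading frame (the sequencing protocol emulated here is strand-specific,
#' so the antisense strand is never scanned). ORF length includes the stop
#' codon; ties are broken by the 5'-most start.
#'
#' @param sequence nucleotide string over A/C/G/T/U/N (case-insensitive).
#' @return list with `length_nt` (0 if no complete ORF), `frame` (0, 1 or 2;
#'   `NA` when no ORF) and `start` (1-based position of the ATG; `NA` when
#'   no ORF).
#' @examples
#' longest_orf("ATGAAATAA")$length_nt  # 9
#' @export
longest_orf <- function(sequence) {
  s <- clean_seq(sequence)
  L <- nchar(s)
  best <- list(length_nt = 0L, frame = NA_integer_, start = NA_integer_)
  if (L < 6) return(best)
  stops <- c("TAA", "TAG", "TGA")
  for (f in 0:2) {
    st <- seq.int(1L + f, L - 2L, by = 3L)
    if (length(st) == 0) next
    cod <- substring(s, st, st + 2L)
    atg_i <- which(cod == "ATG")
    stop_i <- which(cod %in% stops)
    if (length(atg_i) == 0 || length(stop_i) == 0) next
    # first stop at or after each ATG
    nxt <- stop_i[findInterval(atg_i - 1L, stop_i) + 1L]
    ok <- !is.na(nxt)
    if (!any(ok)) next
    len <- (nxt[ok] - atg_i[ok] + 1L) * 3L
    pos <- st[atg_i[ok]]
    j <- which(len > best$length_nt |
                 (len == best$length_nt & pos < best$start))
    if (length(j) > 0) {
      j <- j[order(-len[j], pos[j])][1]
      if (len[j] > best$length_nt ||
          (len[j] == best$length_nt &&
           (is.na(best$start) || pos[j] < best$start)))
        best <- list(length_nt = as.integer(len[j]), frame = f,
                     start = as.integer(pos[j]))
    }
  }
  best
}

lookup_bin <- function(value, cuts) which(value >= cuts)[1]

#' Fickett TESTCODE statistic
#'
#' Classic codon-position asymmetry + composition score. For each base the
#' position parameter is `max(count in codon positions 1..3) /
#' (min(count) + 1)` and the content parameter its overall fraction; both are
#' binned through the published lookup tables and combined with the published
#' weights. Ns are ignored in the counts (with a warning when they exceed 10%
#' of the sequence). T and U are equivalent.
#'
#' @param sequence nucleotide string, length >= 2 recommended (the pipeline
#'   applies it after the 200-nt filter).
#' @return numeric score (higher = more coding-like).
#' @export
fickett_score <- function(sequence) {
  s <- clean_seq(sequence)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n_n <- sum(ch == "N")
  if (n_n / max(1L, length(ch)) > 0.1)
    warning("more than 10% N bases; Ns are ignored in Fickett counts")
  keep <- ch %in% c("A", "C", "G", "T")
  pos <- ((seq_along(ch) - 1L) %% 3L) + 1L
  ch <- ch[keep]; pos <- pos[keep]
  if (length(ch) == 0) return(0)
  score <- 0
  total <- length(ch)
  for (b in c("A", "C", "G", "T")) {
    cnt <- tabulate(pos[ch == b], nbins = 3L)
    posval <- max(cnt) / (min(cnt) + 1)
    pbin <- lookup_bin(posval, fickett_position_cut)
    score <- score + fickett_position_prob[[b]][pbin] * fickett_position_weight[[b]]
    content <- sum(cnt) / total
    cbin <- lookup_bin(content, fickett_content_cut)
    score <- score + fickett_content_prob[[b]][cbin] * fickett_content_weight[[b]]
  }
  score
}

#' Built-in coding-potential assessment
#'
#' Stand-in for external coding-potential programs, keeping their sign
#' convention: `score > 0` means coding (discard as lncRNA candidate).
#' A transcript with a complete ORF of at least `orf_coding_nt` (default
#' 300 nt = 100 codons, the classic heuristic) scores 1 outright; otherwise
#' `score = w_orf * (orf_fraction - 0.5) + w_fickett * (fickett - 0.95)`,
#' where `orf_fraction` is the longest ORF length divided by the sequence
#' length. Exactly 0 is retained (the discard rule is strict).
#'
#' @param sequence nucleotide string.
#' @param orf_coding_nt hard ORF cutoff in nt.
#' @param w_orf,w_fickett weights of the two soft terms.
#' @return list with `longest_orf_nt`, `orf_fraction`, `fickett`, `score`,
#'   `coding` (logical).
#' @export
coding_potential <- function(sequence, orf_coding_nt = 300L,
                             w_orf = 1, w_fickett = 1) {
  orf <- longest_orf(sequence)
  len <- nchar(clean_seq(sequence))
  frac <- if (len > 0) orf$length_nt / len else 0
  fick <- fickett_score(sequence)
  score <- if (orf$length_nt >= orf_coding_nt) 1
           else w_orf * (frac - 0.5) + w_fickett * (fick - 0.95)
  list(longest_orf_nt = orf$length_nt, orf_fraction = frac,
       fickett = fick, score = score, coding = score > 0)
}

#' Expression filter
#'
#' Keeps transcripts whose FPKM reaches `min_fpkm` in at least one sample
#' (inclusive); the published funnel removed transcripts below 1 FPKM in
#' every library. Input order is preserved.
#'
#' @param ts a `transcript_set`.
#' @param se expression matrix covering every transcript in `ts`.
#' @param min_fpkm threshold.
#' @return Filtered `transcript_set`.
#' @export
filter_expression <- function(ts, se, min_fpkm = 1) {
  ids <- tx_ids(ts)
  m <- fpkm(se)
  missing <- setdiff(ids, rownames(m))
  if (length(missing) > 0)
    stop("no expression row for transcript(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  mx <- apply(m[ids, , drop = FALSE], 1, max)
  subset_transcripts(ts, ids[mx >= min_fpkm])
}

#' Length filter
#'
#' Keeps transcripts whose spliced (summed exon) length is at least
#' `min_length_nt`.
#'
#' @param ts a `transcript_set`.
#' @param min_length_nt threshold in nt (inclusive).
#' @return Filtered `transcript_set`.
#' @export
filter_length <- function(ts, min_length_nt = 200L) {
  lens <- tx_lengths(ts)
  subset_transcripts(ts, names(lens)[lens >= min_length_nt])
}

#' Identify lncRNAs by the filtering cascade
#'
#' Applies, in order: removal of transcripts annotated as coding in the
#' reference; the expression filter; the length filter; and the
#' coding-potential filter (built-in scorer, or precomputed external scores
#' where provided -- a transcript listed in `external_scores` is discarded
#' iff `cpc > 0` or `cnci > 0`). Survivor counts per stage are reported via
#' `message()` and returned as the `funnel` element.
#'
#' @param ts assembled transcripts (`transcript_set` with sequences for any
#'   transcript reaching the coding-potential stage).
#' @param se expression matrix.
#' @param config an `lnc_config`.
#' @param external_scores optional data.frame from [read_external_scores()].
#' @return list with `transcripts` (surviving `transcript_set`), `records`
#'   (data.frame: transcript_id, tx_length, longest_orf_nt, orf_fraction,
#'   fickett, score, coding) and `funnel` (named integer vector of survivor
#'   counts per stage).
#' @export
identify_lncrnas <- function(ts, se, config = lnc_config(),
                             external_scores = NULL) {
  validate_config(config)
  funnel <- c(input = length(ts))
  ts1 <- candidate_transcripts(ts)
  funnel["not_annotated_coding"] <- length(ts1)
  ts2 <- filter_expression(ts1, se, config$min_fpkm)
  funnel["expressed"] <- length(ts2)
  ts3 <- filter_length(ts2, config$min_length_nt)
  funnel["long_enough"] <- length(ts3)

  ids <- tx_ids(ts3)
  seqs <- tx_sequences(ts3)
  if (length(ids) > 0 && (is.null(seqs) || !all(ids %in% names(seqs))))
    stop("sequences required for coding-potential scoring; missing for ",
         sum(!ids %in% names(seqs)), " transcript(s)")
  recs <- lapply(ids, function(id)
    coding_potential(as.character(seqs[[id]]), config$orf_coding_nt,
                     config$coding_w_orf, config$coding_w_fickett))
  records <- data.frame(
    transcript_id = ids,
    tx_length = unname(tx_lengths(ts3)[ids]),
    longest_orf_nt = vapply(recs, `[[`, integer(1), "longest_orf_nt"),
    orf_fraction = vapply(recs, `[[`, numeric(1), "orf_fraction"),
    fickett = vapply(recs, `[[`, numeric(1), "fickett"),
    score = vapply(recs, `[[`, numeric(1), "score"),
    stringsAsFactors = FALSE)
  records$coding <- records$score > 0
  if (!is.null(external_scores)) {
    i <- match(records$transcript_id, external_scores$transcript_id)
    has <- !is.na(i)
    records$coding[has] <- external_scores$cpc[i[has]] > 0 |
      external_scores$cnci[i[has]] > 0
  }
  keep <- records$transcript_id[!records$coding]
  funnel["noncoding"] <- length(keep)
  message("lncRNA identification funnel: ",
          paste(names(funnel), funnel, sep = "=", collapse = ", "))
  list(transcripts = subset_transcripts(ts3, keep),
       records = records[!records$coding, , drop = FALSE],
       funnel = funnel)
}
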