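# Independent oracles: deliberately naive implementations used only to
# check the package's optimised code paths.

# brute-force all-pairs positional classifier (no interval trees)
oracle_classify <- function(lnc, genes) {
  chr_df <- function(x) {
    df <- as.data.frame(x)
    df$seqnames <- as.character(df$seqnames)
    df$strand <- as.character(df$strand)
    df
  }
  lex <- chr_df(tx_exons(lnc))
  gex <- chr_df(tx_exons(genes))
  lsp <- chr_df(tx_spans(lnc))
  gsp <- chr_df(tx_spans(genes))
  ov <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1
  out <- character(nrow(lsp))
  for (i in seq_len(nrow(lsp))) {
    tid <- lsp$transcript_id[i]
    le <- lex[lex$transcript_id == tid, ]
    same <- FALSE; anti <- FALSE
    for (r in seq_len(nrow(le))) for (q in seq_len(nrow(gex))) {
      if (le$seqnames[r] != gex$seqnames[q]) next
      if (ov(le$start[r], le$end[r], gex$start[q], gex$end[q])) {
        if (as.character(le$strand[r]) == as.character(gex$strand[q]))
          same <- TRUE else anti <- TRUE
      }
    }
    if (same) { out[i] <- "sense_overlap"; next }
    if (anti) { out[i] <- "antisense"; next }
    intr <- FALSE
    for (g in unique(gex$transcript_id)) {
      ge <- gex[gex$transcript_id == g, ]
      ge <- ge[order(ge$start), ]
      if (nrow(ge) < 2 || ge$seqnames[1] != lsp$seqnames[i]) next
      for (r in seq_len(nrow(ge) - 1)) {
        is_ <- ge$end[r] + 1; ie_ <- ge$start[r + 1] - 1
        if (lsp$start[i] >= is_ && lsp$end[i] <= ie_) intr <- TRUE
      }
    }
    out[i] <- if (intr) "intronic" else "lincRNA"
  }
  data.frame(transcript_id = lsp$transcript_id, class = out,
             stringsAsFactors = FALSE)
}

# naive O(n*m) all-pairs cis-window oracle (span-to-span gap)
oracle_cis <- function(lnc, genes, window) {
  lsp <- as.data.frame(tx_spans(lnc))
  gsp <- as.data.frame(tx_spans(genes))
  lsp$seqnames <- as.character(lsp$seqnames)
  gsp$seqnames <- as.character(gsp$seqnames)
  res <- list()
  for (i in seq_len(nrow(lsp))) for (j in seq_len(nrow(gsp))) {
    if (lsp$seqnames[i] != gsp$seqnames[j]) next
    gap <- max(0, max(gsp$start[j] - lsp$end[i],
                      lsp$start[i] - gsp$end[j]) - 1)
    if (gap <= window)
      res[[length(res) + 1]] <- data.frame(
        lncrna_id = lsp$transcript_id[i], gene_id = gsp$gene_id[j],
        distance_bp = gap, stringsAsFactors = FALSE)
  }
  if (length(res) == 0)
    return(data.frame(lncrna_id = character(0), gene_id = character(0),
                      distance_bp = numeric(0)))
  df <- do.call(rbind, res)
  df[order(df$lncrna_id, df$gene_id), , drop = FALSE]
}

# hand dynamic program: affine-gap local alignment score
# (gap of length L costs open + L * extend, both positive)
oracle_sw_score <- function(a, b, match = 1, mismatch = -2,
                            open = 5, extend = 2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)  # best ending in a match/mismatch
  E <- matrix(-Inf, n + 1, m + 1)  # gap in b (vertical)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in a (horizontal)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i - 1, j] - open - extend, E[i - 1, j] - extend)
    F[i, j] <- max(H[i, j - 1] - open - extend, F[i, j - 1] - extend)
    s <- if (a[i - 1] == b[j - 1]) match else mismatch
    H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# exhaustive enumeration of all duplex pairings (for short sequences)
oracle_duplex <- function(a, b, par = duplex_parameters()) {
  code <- function(x)
    match(strsplit(chartr("Uu", "Tt", toupper(x)), "")[[1]],
          c("A", "C", "G", "T"))
  PC <- matrix(0L, 4, 4)
  PC[1, 4] <- 1L; PC[4, 1] <- 2L; PC[2, 3] <- 3L
  PC[3, 2] <- 4L; PC[3, 4] <- 5L; PC[4, 3] <- 6L
  xa <- code(a); yb <- rev(code(b))
  n <- length(xa); m <- length(yb)
  pair <- function(i, j)
    if (is.na(xa[i]) || is.na(yb[j])) 0L else PC[xa[i], yb[j]]
  best <- 0
  rec <- function(i0, j0, p0, acc) {
    if (i0 + 1 > n || j0 + 1 > m) return(invisible())
    for (i in (i0 + 1):n) for (j in (j0 + 1):m) {
      p <- pair(i, j)
      if (p == 0L) next
      gi <- i - i0 - 1; gj <- j - j0 - 1
      cost <- if (p0 == 0L) par$init
        else if (gi == 0 && gj == 0) par$stack[p0, p]
        else if (gi == 0 || gj == 0) par$bulge_open + par$bulge_nt * (gi + gj)
        else par$interior_open + par$interior_nt * (gi + gj)
      e <- acc + cost
      if (e < best) best <<- e
      rec(i, j, p, e)
    }
    invisible()
  }
  rec(0, 0, 0L, 0)
  best
}

# Spearman rho via explicit average ranks + Pearson formula
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# exact hypergeometric upper tail by direct enumeration with choose()
oracle_hyper <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# pooled-variance two-sided t-test on log2(x + pc), by the textbook formula
oracle_pooled_t <- function(a, b, pc = 0.01) {
  la <- log2(a + pc); lb <- log2(b + pc)
  na <- length(la); nb <- length(lb)
  sp2 <- ((na - 1) * var(la) + (nb - 1) * var(lb)) / (na + nb - 2)
  tt <- (mean(lb) - mean(la)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * pt(-abs(tt), na + nb - 2)
}

rand_seq <- function(n, alpha = c("A", "C", "G", "T")) {
  paste(sample(alpha, n, replace = TRUE), collapse = "")
}
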