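#' @name synthetic_data
#' @title Synthetic paired-species lncRNA datasets with planted truth
#' @description The generator emulates the study design this package
#'   reimplements -- two closely related tree species, four tissues (leaf,
#'   phloem, xylem, root), three salt doses (0, 150, 300 mM) with three
#'   replicates -- and plants unambiguous members of all four lncRNA
#'   positional classes, differential and tissue-specific expression
#'   effects, cis/trans target pairs and a known homolog map, so every
#'   downstream stage can be tested against known truth. See the methods
#'   vignette for what the generator does and does not emulate.
NULL

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# per-site substitutions at the given rate, uniform over the 3 other bases
mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  }
  paste(ch, collapse = "")
}

# interrupt every ORF longer than max_orf_nt by destroying its start codon
# (ATG -> ATC). The ATG count strictly decreases and a C can never be part
# of a new ATG, so the loop provably terminates; writing a stop codon into
# the ORF instead can create a fresh ATG at the junction and cycle forever.
break_orfs <- function(s, max_orf_nt) {
  max_orf_nt <- max(9L, max_orf_nt)
  repeat {
    orf <- longest_orf(s)
    if (orf$length_nt <= max_orf_nt) return(s)
    substr(s, orf$start + 2L, orf$start + 2L) <- "C"
  }
}

# coding sequence of total length len with a planted ORF >= 120 codons and a
# 3' UTR long enough (>= 200 nt) to host embedded trans-target windows
make_coding_seq <- function(len) {
  stopifnot(len >= 800)
  u5 <- 60L
  n_cod <- min(sample(140:200, 1), (len - u5 - 200L) %/% 3L - 2L)
  codons <- c(t(outer(c("A", "C", "G", "T"),
                      c(t(outer(c("A", "C", "G", "T"),
                                c("A", "C", "G", "T"), paste0))), paste0)))
  codons <- setdiff(codons, c("TAA", "TAG", "TGA", "ATG"))
  cds <- paste0("ATG", paste(sample(codons, n_cod, replace = TRUE),
                             collapse = ""), "TAA")
  u3 <- len - u5 - nchar(cds)
  paste0(break_orfs(rand_dna(u5), 57L), cds, break_orfs(rand_dna(u3), 57L))
}

#' Simulate an annotated single-chromosome genome
#'
#' Lays out `n_genes` three-exon protein-coding genes with >= 25 kb spacing
#' and, per class, `n_lnc_per_class` lncRNAs constructed to be unambiguous:
#' lincRNAs alternate between "near" placements (2-8 kb from a gene, to
#' exercise cis pairing) and "far" placements (> 10 kb from every gene);
#' intronic lncRNAs sit wholly inside the first intron with no exon
#' overlap; antisense lncRNAs overlap an exon on the opposite strand;
#' sense-overlapping lncRNAs partially overlap the last exon on the same
#' strand. lncRNA sequences are 200-2000 nt with every ORF broken below 60
#' codons (and below 35% of the length, so the coding-potential score is
#' safely negative); coding sequences carry a planted ORF of at least 140
#' codons. A fraction of the far lincRNAs carries an embedded 150-nt reverse
#' complement of its host gene's 3' UTR, planting a trans target pair.
#'
#' @param n_genes number of coding genes (>= 2; also an upper bound on
#'   `n_lnc_per_class`, one host gene per class member).
#' @param n_lnc_per_class planted lncRNAs per positional class (0 allowed).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param trans_fraction fraction of far lincRNAs receiving an embedded
#'   trans-target window.
#' @return list with `transcripts` (all assembled transcripts, biotype
#'   `"unknown"`, with sequences -- what an assembler would emit), `genes`
#'   (the coding subset as the reference annotation, biotype `"coding"`)
#'   and `truth` (a `sim_truth` list: `classes`, `cis_pairs`, `trans_pairs`,
#'   `gene_of_transcript`).
#' @export
simulate_genome <- function(n_genes = 10L, n_lnc_per_class = 5L, seed = 1L,
                            trans_fraction = 0.5) {
  stopifnot(n_genes >= 2, n_lnc_per_class >= 0)
  classes <- c("lincRNA", "intronic", "antisense", "sense_overlap")
  if (n_lnc_per_class > n_genes)
    stop("class ", classes[1], " (and others) geometrically impossible: ",
         "n_lnc_per_class (", n_lnc_per_class, ") exceeds the number of ",
         "host genes (", n_genes, ")")
  set.seed(seed)
  chrom <- "chr1"
  exon_rows <- list()
  seqs <- character(0)
  truth_class <- list()
  cis_pairs <- list()
  trans_pairs <- list()
  gene_of <- character(0)

  add_tx <- function(id, gid, strand, starts, ends, biotype, seq) {
    exon_rows[[id]] <<- data.frame(start = starts, end = ends,
                                   strand = strand, transcript_id = id,
                                   gene_id = gid, biotype = biotype,
                                   stringsAsFactors = FALSE)
    seqs[id] <<- seq
  }

  genes <- vector("list", n_genes)
  cursor <- 10000L
  for (g in seq_len(n_genes)) {
    w <- sample(300:700, 3, replace = TRUE)
    i1 <- sample(2600:5000, 1)
    i2 <- sample(500:1500, 1)
    strand <- sample(c("+", "-"), 1)
    s1 <- cursor
    e1 <- s1 + w[1] - 1L
    s2 <- e1 + i1 + 1L
    e2 <- s2 + w[2] - 1L
    s3 <- e2 + i2 + 1L
    e3 <- s3 + w[3] - 1L
    gid <- sprintf("gA%04d", g)
    tid <- sprintf("mA%04d", g)
    seq <- make_coding_seq(sum(w))
    add_tx(tid, gid, strand, c(s1, s2, s3), c(e1, e2, e3), "unknown", seq)
    gene_of[tid] <- gid
    genes[[g]] <- list(gid = gid, tid = tid, strand = strand,
                       s = c(s1, s2, s3), e = c(e1, e2, e3),
                       start = s1, end = e3, i1 = i1, seq = seq)
    cursor <- e3 + 26000L
  }

  lnc_i <- 0L
  for (cl in classes) {
    for (k in seq_len(n_lnc_per_class)) {
      h <- genes[[k]]
      lnc_i <- lnc_i + 1L
      id <- sprintf("lA%04d", lnc_i)
      if (cl == "intronic") {
        len <- sample(200:min(2000L, h$i1 - 100L), 1)
        st <- h$e[1] + 50L
        strand <- sample(c("+", "-"), 1)
        seq <- break_orfs(rand_dna(len), min(180L, floor(0.35 * len)))
        add_tx(id, id, strand, st, st + len - 1L, "unknown", seq)
      } else if (cl == "antisense") {
        len <- sample(400:1200, 1)
        st <- h$s[2] + 100L
        strand <- if (h$strand == "+") "-" else "+"
        seq <- break_orfs(rand_dna(len), min(180L, floor(0.35 * len)))
        add_tx(id, id, strand, st, st + len - 1L, "unknown", seq)
      } else if (cl == "sense_overlap") {
        w3 <- h$e[3] - h$s[3] + 1L
        st <- h$s[3] + w3 %/% 2L
        en <- h$end + sample(200:800, 1)
        len <- en - st + 1L
        seq <- break_orfs(rand_dna(len), min(180L, floor(0.35 * len)))
        add_tx(id, id, h$strand, st, en, "unknown", seq)
      } else {  # lincRNA
        len <- sample(400:2000, 1)
        near <- k %% 2L == 1L
        if (near) {
          gap <- sample(2000:8000, 1)
          st <- h$end + gap
          strand <- sample(c("+", "-"), 1)
          seq <- break_orfs(rand_dna(len), min(180L, floor(0.35 * len)))
          # the host gene sits 5' of the lncRNA in genomic coordinates
          cis_pairs[[id]] <- data.frame(
            lncrna_id = id, gene_id = h$gid,
            relation = if (strand == "+") "upstream" else "downstream",
            stringsAsFactors = FALSE)
        } else {
          st <- h$end + 11200L + sample(0:800, 1)
          strand <- sample(c("+", "-"), 1)
          seq <- rand_dna(len)
          # plant a trans target in the first ceiling(fraction * n_far)
          # far lincRNAs (deterministic count, not a coin flip)
          n_far <- n_lnc_per_class %/% 2L
          if (k %/% 2L <= ceiling(trans_fraction * n_far) && len >= 300L) {
            L <- nchar(h$seq)
            win <- reverse_complement(substr(h$seq, L - 170L, L - 21L))
            at <- max(1L, (len - 150L) %/% 2L)
            substr(seq, at, at + 149L) <- win
            trans_pairs[[id]] <- data.frame(lncrna_id = id, gene_id = h$gid,
                                            stringsAsFactors = FALSE)
          }
          seq <- break_orfs(seq, min(180L, floor(0.35 * len)))
        }
        add_tx(id, id, strand, st, st + len - 1L, "unknown", seq)
      }
      truth_class[[id]] <- data.frame(transcript_id = id, class = cl,
                                      host_gene = h$gid,
                                      stringsAsFactors = FALSE)
    }
  }

  exdf <- do.call(rbind, exon_rows)
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(exdf$start, exdf$end),
                               strand = exdf$strand,
                               transcript_id = exdf$transcript_id,
                               gene_id = exdf$gene_id,
                               biotype = exdf$biotype)
  ts_all <- transcript_set(gr, Biostrings::DNAStringSet(seqs))

  mids <- names(gene_of)
  gex <- gr[S4Vectors::mcols(gr)$transcript_id %in% mids]
  S4Vectors::mcols(gex)$biotype <- "coding"
  ts_genes <- transcript_set(gex, Biostrings::DNAStringSet(seqs[mids]))

  truth <- structure(list(
    species = "A",
    classes = if (length(truth_class) > 0) do.call(rbind, truth_class)
              else data.frame(transcript_id = character(0),
                              class = character(0),
                              host_gene = character(0)),
    cis_pairs = if (length(cis_pairs) > 0) do.call(rbind, cis_pairs)
                else data.frame(lncrna_id = character(0),
                                gene_id = character(0),
                                relation = character(0)),
    trans_pairs = if (length(trans_pairs) > 0) do.call(rbind, trans_pairs)
                  else data.frame(lncrna_id = character(0),
                                  gene_id = character(0)),
    gene_of_transcript = gene_of),
    class = "sim_truth")
  rownames(truth$classes) <- rownames(truth$cis_pairs) <-
    rownames(truth$trans_pairs) <- NULL
  list(transcripts = ts_all, genes = ts_genes, truth = truth)
}

#' The default 4-tissue x 3-dose x 3-replicate design
#'
#' @param tissues,salt_mM,replicates design factors.
#' @return sample sheet data.frame (`sample_id`, `tissue`, `salt_mM`,
#'   `replicate`).
#' @export
default_design <- function(tissues = c("leaf", "phloem", "xylem", "root"),
                           salt_mM = c(0, 150, 300), replicates = 3L) {
  g <- expand.grid(replicate = seq_len(replicates), salt_mM = salt_mM,
                   tissue = tissues, stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("%s_%g_r%d", g$tissue, g$salt_mM,
                                 g$replicate),
             tissue = g$tissue, salt_mM = g$salt_mM,
             replicate = g$replicate, stringsAsFactors = FALSE)
}

#' Simulate replicated FPKM expression with planted effects
#'
#' One log2-FPKM baseline per transcript (truncated Gaussian; lncRNAs lower
#' than mRNAs, as observed in real data); planted differential transcripts
#' receive a dose-dependent effect in one assigned tissue (default +/-1
#' log2 units at 150 mM and +/-2 at 300 mM); planted tissue-specific
#' transcripts are silenced (FPKM ~0.02) outside their target tissue;
#' planted housekeeping transcripts stay flat. Replicate noise is Gaussian
#' on the log2 scale (log-normal FPKM). Roles are drawn disjointly from the
#' lncRNA ids in `truth$classes`; a fraction of mRNAs is also made
#' differential. `truth$preset_roles` / `truth$preset_baseline` (set by
#' [simulate_sister_species()]) override the draw for listed transcripts.
#'
#' @param ts `transcript_set` to express.
#' @param truth `sim_truth` from [simulate_genome()].
#' @param design sample sheet (must contain the 0 mM control level).
#' @param noise_sd replicate standard deviation on the log2 scale (>= 0).
#' @param seed integer seed.
#' @param frac_de,frac_tissue_specific,frac_housekeeping fractions of
#'   lncRNAs given each role (disjoint).
#' @param effect_high,effect_mid absolute log2 effects at the high/mid dose.
#' @param mrna_frac_de fraction of mRNAs made differential.
#' @return list with `matrix` (a `SummarizedExperiment`) and `truth`
#'   (augmented with `de`, `tissue_specific`, `housekeeping`, `baseline`).
#' @export
simulate_expression <- function(ts, truth, design = default_design(),
                                noise_sd = 0.2, seed = 1L,
                                frac_de = 0.4, frac_tissue_specific = 0.1,
                                frac_housekeeping = 0.05,
                                effect_high = 2, effect_mid = 1,
                                mrna_frac_de = 0.2) {
  stopifnot(noise_sd >= 0)
  validate_design(design)
  set.seed(seed)
  ids <- tx_ids(ts)
  lnc_ids <- intersect(truth$classes$transcript_id, ids)
  mrna_ids <- intersect(names(truth$gene_of_transcript), ids)
  tissues <- unique(design$tissue)
  salts <- sort(unique(design$salt_mM))
  mid_salt <- if (length(salts) >= 3) salts[2] else NA_real_
  high_salt <- salts[length(salts)]

  preset <- truth$preset_roles
  preset_ids <- if (is.null(preset)) character(0) else preset$transcript_id

  draw_roles <- function(pool, n_de, n_ts, n_hk) {
    pool <- setdiff(pool, preset_ids)
    pool <- sample(pool)
    n_de <- min(n_de, length(pool))
    de <- utils::head(pool, n_de); pool <- setdiff(pool, de)
    n_ts <- min(n_ts, length(pool))
    tsd <- utils::head(pool, n_ts); pool <- setdiff(pool, tsd)
    n_hk <- min(n_hk, length(pool))
    hk <- utils::head(pool, n_hk)
    list(de = de, ts = tsd, hk = hk)
  }
  rl <- draw_roles(lnc_ids, round(frac_de * length(lnc_ids)),
                   round(frac_tissue_specific * length(lnc_ids)),
                   round(frac_housekeeping * length(lnc_ids)))
  rm_ <- draw_roles(mrna_ids, round(mrna_frac_de * length(mrna_ids)), 0L, 0L)

  roles <- data.frame(transcript_id = c(rl$de, rm_$de, rl$ts, rl$hk),
                      role = c(rep("de", length(rl$de) + length(rm_$de)),
                               rep("tissue_specific", length(rl$ts)),
                               rep("housekeeping", length(rl$hk))),
                      stringsAsFactors = FALSE)
  roles$tissue <- NA_character_
  roles$direction <- NA_real_
  is_de <- roles$role == "de"
  roles$tissue[is_de] <- sample(tissues, sum(is_de), replace = TRUE)
  roles$direction[is_de] <- sample(c(1, -1), sum(is_de), replace = TRUE)
  is_ts <- roles$role == "tissue_specific"
  roles$tissue[is_ts] <- sample(tissues, sum(is_ts), replace = TRUE)
  if (!is.null(preset)) roles <- rbind(roles, preset)

  base <- stats::setNames(ifelse(seq_along(ids) %in% match(mrna_ids, ids),
                                 pmax(stats::rnorm(length(ids), 4.5, 1), 1.5),
                                 pmax(stats::rnorm(length(ids), 2.5, 1), 1)),
                          ids)
  if (!is.null(truth$preset_baseline)) {
    pb <- truth$preset_baseline
    keep <- intersect(names(pb), ids)
    base[keep] <- pb[keep]
  }

  mu <- matrix(rep(base, times = nrow(design)), nrow = length(ids),
               dimnames = list(ids, design$sample_id))
  for (r in seq_len(nrow(roles))) {
    id <- roles$transcript_id[r]
    if (!id %in% ids) next
    if (roles$role[r] == "tissue_specific") {
      off <- design$tissue != roles$tissue[r]
      mu[id, off] <- log2(0.02)
    } else if (roles$role[r] == "de") {
      tt <- design$tissue == roles$tissue[r]
      if (!is.na(mid_salt))
        mu[id, tt & design$salt_mM == mid_salt] <-
          mu[id, tt & design$salt_mM == mid_salt] +
          roles$direction[r] * effect_mid
      mu[id, tt & design$salt_mM == high_salt] <-
        mu[id, tt & design$salt_mM == high_salt] +
        roles$direction[r] * effect_high
    }
  }
  noise <- matrix(stats::rnorm(length(mu), 0, noise_sd), nrow = nrow(mu))
  vals <- 2^(mu + noise)
  se <- expr_matrix(vals, design)

  truth$de <- roles[roles$role == "de",
                    c("transcript_id", "tissue", "direction")]
  truth$de$lfc_mid <- truth$de$direction * effect_mid
  truth$de$lfc_high <- truth$de$direction * effect_high
  rownames(truth$de) <- NULL
  truth$tissue_specific <- roles[roles$role == "tissue_specific",
                                 c("transcript_id", "tissue")]
  rownames(truth$tissue_specific) <- NULL
  truth$housekeeping <-
    roles$transcript_id[roles$role == "housekeeping"]
  truth$baseline <- base
  list(matrix = se, truth = truth)
}

#' Simulate a sister species by sequence divergence
#'
#' Copies the base genome's layout (syntenic order, identical coordinates,
#' renamed ids): all coding genes are retained as point-mutated copies at
#' the given per-site substitution rate; a fraction of the lncRNAs is
#' shared (point-mutated copies, identity ~ 1 - divergence) and the rest
#' replaced by fresh random sequences of the same length. Only shared pairs
#' enter the homolog map. When the base truth already carries expression
#' roles and baselines (i.e. [simulate_expression()] ran on species A),
#' shared lncRNAs inherit their roles and baselines in B, and a fraction of
#' the shared pairs can be planted as "highly expressed in A" by shifting
#' the B baseline down by `log2(high_expr_fold)`.
#'
#' @param base list from [simulate_genome()] (with `truth` optionally
#'   augmented by [simulate_expression()]).
#' @param divergence per-site substitution rate in `[0, 0.3]`.
#' @param fraction_shared_lnc fraction of lncRNAs shared between species.
#' @param seed integer seed.
#' @param high_expr_fraction fraction of shared pairs planted as highly
#'   expressed in A (needs baselines in `base$truth`).
#' @param high_expr_fold planted expression ratio A/B.
#' @return list with `transcripts`, `genes` (species-B `transcript_set`s)
#'   and `truth` (species-B `sim_truth` with `homolog_map`,
#'   `gene_homolog_map`, `high_expr_pairs`, `preset_roles`,
#'   `preset_baseline`).
#' @export
simulate_sister_species <- function(base, divergence = 0.02,
                                    fraction_shared_lnc = 0.2, seed = 1L,
                                    high_expr_fraction = 0,
                                    high_expr_fold = 5) {
  stopifnot(divergence >= 0, divergence <= 0.3,
            fraction_shared_lnc >= 0, fraction_shared_lnc <= 1)
  set.seed(seed)
  if (fraction_shared_lnc > 0 && divergence > 0.05)
    warning("divergence ", divergence, " implies identity below a typical ",
            "0.95 homology gate; recall will drop by construction")
  truth_a <- base$truth
  b_of <- function(id) sub("^([lmg])A", "\\1B", id)
  lnc_a <- truth_a$classes$transcript_id
  n_shared <- round(fraction_shared_lnc * length(lnc_a))
  shared <- sort(sample(lnc_a, n_shared))

  ex <- tx_exons(base$transcripts)
  mc <- S4Vectors::mcols(ex)
  exb <- GenomicRanges::GRanges(GenomicRanges::seqnames(ex),
                                IRanges::ranges(ex),
                                strand = GenomicRanges::strand(ex),
                                transcript_id = b_of(mc$transcript_id),
                                gene_id = b_of(mc$gene_id),
                                biotype = mc$biotype)
  seqs_a <- tx_sequences(base$transcripts)
  seqs_b <- character(length(seqs_a))
  names(seqs_b) <- b_of(names(seqs_a))
  for (id in names(seqs_a)) {
    s <- as.character(seqs_a[[id]])
    bid <- b_of(id)
    if (id %in% names(truth_a$gene_of_transcript)) {
      seqs_b[bid] <- mutate_seq(s, divergence)
    } else if (id %in% shared) {
      len <- nchar(s)
      seqs_b[bid] <- break_orfs(mutate_seq(s, divergence),
                                min(180L, floor(0.35 * len)))
    } else {
      len <- nchar(s)
      seqs_b[bid] <- break_orfs(rand_dna(len),
                                min(180L, floor(0.35 * len)))
    }
  }
  ts_b <- transcript_set(exb, Biostrings::DNAStringSet(seqs_b))
  mids_b <- b_of(names(truth_a$gene_of_transcript))
  gexb <- exb[S4Vectors::mcols(exb)$transcript_id %in% mids_b]
  S4Vectors::mcols(gexb)$biotype <- "coding"
  genes_b <- transcript_set(gexb, Biostrings::DNAStringSet(seqs_b[mids_b]))

  truth_b <- structure(list(
    species = "B",
    classes = transform(truth_a$classes,
                        transcript_id = b_of(transcript_id),
                        host_gene = b_of(host_gene)),
    cis_pairs = transform(truth_a$cis_pairs,
                          lncrna_id = b_of(lncrna_id),
                          gene_id = b_of(gene_id)),
    trans_pairs = transform(truth_a$trans_pairs,
                            lncrna_id = b_of(lncrna_id),
                            gene_id = b_of(gene_id)),
    gene_of_transcript = stats::setNames(
      b_of(truth_a$gene_of_transcript),
      b_of(names(truth_a$gene_of_transcript))),
    homolog_map = data.frame(id_a = shared, id_b = b_of(shared),
                             stringsAsFactors = FALSE),
    gene_homolog_map = data.frame(
      id_a = names(truth_a$gene_of_transcript),
      id_b = mids_b, stringsAsFactors = FALSE)),
    class = "sim_truth")

  # inherit expression roles/baselines for shared lncRNAs, if available
  if (!is.null(truth_a$baseline)) {
    roles_a <- rbind(
      if (nrow(truth_a$de) > 0)
        data.frame(transcript_id = truth_a$de$transcript_id, role = "de",
                   tissue = truth_a$de$tissue,
                   direction = truth_a$de$direction,
                   stringsAsFactors = FALSE),
      data.frame(transcript_id = truth_a$tissue_specific$transcript_id,
                 role = "tissue_specific",
                 tissue = truth_a$tissue_specific$tissue,
                 direction = NA_real_, stringsAsFactors = FALSE),
      if (length(truth_a$housekeeping) > 0)
        data.frame(transcript_id = truth_a$housekeeping,
                   role = "housekeeping", tissue = NA_character_,
                   direction = NA_real_, stringsAsFactors = FALSE))
    pre <- roles_a[roles_a$transcript_id %in% shared, , drop = FALSE]
    # shared lncRNAs inherit their A role *including* the null role, so a
    # lncRNA flat in A cannot be silenced or induced in B by the fresh draw
    null_ids <- setdiff(shared, pre$transcript_id)
    if (length(null_ids) > 0)
      pre <- rbind(pre, data.frame(transcript_id = null_ids, role = "null",
                                   tissue = NA_character_,
                                   direction = NA_real_,
                                   stringsAsFactors = FALSE))
    pre$transcript_id <- b_of(pre$transcript_id)
    truth_b$preset_roles <- pre
    pb <- truth_a$baseline[shared]
    names(pb) <- b_of(names(pb))
    ts_ids_b <- b_of(truth_a$tissue_specific$transcript_id)
    if (high_expr_fraction > 0) {
      cand <- setdiff(names(pb), ts_ids_b)
      n_high <- min(round(high_expr_fraction * n_shared), length(cand))
      high_b <- sort(sample(cand, n_high))
      pb[high_b] <- pb[high_b] - log2(high_expr_fold)
      truth_b$high_expr_pairs <- data.frame(
        id_a = shared[match(high_b, b_of(shared))], id_b = high_b,
        stringsAsFactors = FALSE)
    } else {
      truth_b$high_expr_pairs <- data.frame(id_a = character(0),
                                            id_b = character(0),
                                            stringsAsFactors = FALSE)
    }
    truth_b$preset_baseline <- pb
  } else if (high_expr_fraction > 0) {
    stop("high_expr_fraction > 0 requires baselines in base$truth; ",
         "run simulate_expression() on the base species first")
  }
  rownames(truth_b$classes) <- rownames(truth_b$cis_pairs) <-
    rownames(truth_b$trans_pairs) <- NULL
  list(transcripts = ts_b, genes = genes_b, truth = truth_b)
}

#' Simulate a toy GO annotation
#'
#' Assigns each gene 1-4 terms drawn from a small flat ontology (no graph
#' structure), enough to exercise the enrichment stage.
#'
#' @param gene_ids character vector of gene ids.
#' @param n_terms number of distinct terms.
#' @param seed integer seed.
#' @return data.frame with `gene_id`, `term_id`.
#' @export
simulate_go_annotation <- function(gene_ids, n_terms = 20L, seed = 1L) {
  set.seed(seed)
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  out <- lapply(gene_ids, function(g)
    data.frame(gene_id = g,
               term_id = sample(terms, sample(1:4, 1)),
               stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write / read planted truth as JSON
#'
#' @param truth a `sim_truth` list.
#' @param path JSON file.
#' @return `read_truth` returns the `sim_truth`; `write_truth` returns
#'   `path` invisibly.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  # named atomic vectors must become JSON objects, not bare arrays
  for (nm in c("gene_of_transcript", "baseline", "preset_baseline"))
    if (!is.null(x[[nm]])) x[[nm]] <- as.list(x[[nm]])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  for (nm in c("gene_of_transcript", "baseline", "preset_baseline"))
    if (!is.null(x[[nm]])) x[[nm]] <- unlist(x[[nm]])
  structure(x, class = "sim_truth")
}

#' Generate a complete two-species fixture on disk
#'
#' Runs [simulate_genome()], [simulate_expression()],
#' [simulate_sister_species()] (plus B expression) and
#' [simulate_go_annotation()] with sub-seeds derived from `seed`, and writes
#' every file the pipeline reads: GTF annotation and reference gene models,
#' transcript FASTA, expression matrix + sample sheet per species, a GO
#' table for species A genes, and the planted truth as JSON.
#'
#' @param dir output directory (created if needed).
#' @param n_genes,n_lnc_per_class,seed,noise_sd,divergence,fraction_shared_lnc,high_expr_fraction,high_expr_fold
#'   generator parameters, passed through.
#' @return named list of file paths plus `truth_a`/`truth_b` in memory.
#' @export
simulate_dataset <- function(dir, n_genes = 12L, n_lnc_per_class = 5L,
                             seed = 7L, noise_sd = 0.2, divergence = 0.02,
                             fraction_shared_lnc = 0.4,
                             high_expr_fraction = 0.2, high_expr_fold = 5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- simulate_genome(n_genes, n_lnc_per_class, seed = seed)
  ea <- simulate_expression(gen$transcripts, gen$truth, seed = seed + 1L,
                            noise_sd = noise_sd)
  gen$truth <- ea$truth
  sis <- simulate_sister_species(gen, divergence = divergence,
                                 fraction_shared_lnc = fraction_shared_lnc,
                                 seed = seed + 2L,
                                 high_expr_fraction = high_expr_fraction,
                                 high_expr_fold = high_expr_fold)
  eb <- simulate_expression(sis$transcripts, sis$truth, seed = seed + 3L,
                            noise_sd = noise_sd)
  sis$truth <- eb$truth
  go <- simulate_go_annotation(unique(gen$truth$gene_of_transcript),
                               seed = seed + 4L)
  p <- list(
    annotation_a = file.path(dir, "transcripts_a.gtf"),
    genes_a = file.path(dir, "genes_a.gtf"),
    fasta_a = file.path(dir, "transcripts_a.fa"),
    expression_a = file.path(dir, "expression_a.tsv"),
    samples_a = file.path(dir, "samples_a.tsv"),
    annotation_b = file.path(dir, "transcripts_b.gtf"),
    genes_b = file.path(dir, "genes_b.gtf"),
    fasta_b = file.path(dir, "transcripts_b.fa"),
    expression_b = file.path(dir, "expression_b.tsv"),
    samples_b = file.path(dir, "samples_b.tsv"),
    go = file.path(dir, "go_annotation.tsv"),
    truth_a = file.path(dir, "truth_a.json"),
    truth_b = file.path(dir, "truth_b.json"))
  write_annotation(gen$transcripts, p$annotation_a)
  write_annotation(gen$genes, p$genes_a)
  write_transcript_fasta(tx_sequences(gen$transcripts), p$fasta_a)
  write_expression(ea$matrix, p$expression_a, p$samples_a)
  write_annotation(sis$transcripts, p$annotation_b)
  write_annotation(sis$genes, p$genes_b)
  write_transcript_fasta(tx_sequences(sis$transcripts), p$fasta_b)
  write_expression(eb$matrix, p$expression_b, p$samples_b)
  write_tsv(go, p$go)
  write_truth(gen$truth, p$truth_a)
  write_truth(sis$truth, p$truth_b)
  c(p, list(truth_a_obj = gen$truth, truth_b_obj = sis$truth))
}
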