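test_that("cis pairing follows window, strand and relation rules", {
  lnc <- make_ts(make_exons(5000, 6000, id = "l1"))
  genes <- make_ts(make_exons(12000, 15000, id = "g1t", gene = "g1",
                              biotype = "coding"))
  p <- cis_targets(lnc, genes, 10000)
  expect_equal(nrow(p), 1L)
  expect_identical(p$relation, "downstream")  # gene 3' of a + lncRNA
  expect_equal(p$distance_bp, 12000 - 6000 - 1)

  # on the minus strand the same geometry is upstream
  lnc_m <- make_ts(make_exons(5000, 6000, strand = "-", id = "l1"))
  expect_identical(cis_targets(lnc_m, genes, 10000)$relation, "upstream")

  # strict window boundary: gap of window_bp pairs, window_bp + 1 does not
  gene_far <- function(gap) make_ts(make_exons(6000 + gap + 1, 20000 + gap,
                                               id = "g1t", gene = "g1",
                                               biotype = "coding"))
  expect_equal(nrow(cis_targets(lnc, gene_far(10000), 10000)), 1L)
  expect_equal(nrow(cis_targets(lnc, gene_far(10001), 10000)), 0L)

  # overlap -> distance 0; intronic host tagged when classification given
  genes2 <- make_ts(make_exons(c(1000, 9000), c(2000, 9500), id = "g2t",
                               gene = "g2", biotype = "coding"))
  lnc2 <- make_ts(make_exons(5000, 6000, id = "l2"))
  cls <- classify_transcripts(lnc2, genes2)
  expect_identical(cls$class, "intronic")
  p2 <- cis_targets(lnc2, genes2, 10000, cls)
  expect_identical(p2$relation, "intron_host")
  expect_equal(p2$distance_bp, 0)
})

test_that("cis pairing equals the all-pairs oracle and is shift-invariant", {
  gen <- fixture_genome(n_genes = 8, n_lnc = 8, seed = 23)
  lnc <- subset_transcripts(gen$transcripts,
                            gen$truth$classes$transcript_id)
  fast <- cis_targets(lnc, gen$genes, 10000)
  slow <- oracle_cis(lnc, gen$genes, 10000)
  expect_equal(paste(fast$lncrna_id, fast$gene_id, fast$distance_bp),
               paste(slow$lncrna_id, slow$gene_id, slow$distance_bp))
  # planted near-lincRNA cis pairs are all present
  truth_keys <- paste(gen$truth$cis_pairs$lncrna_id,
                      gen$truth$cis_pairs$gene_id)
  expect_true(all(truth_keys %in% paste(fast$lncrna_id, fast$gene_id)))
  rel <- fast[match(truth_keys, paste(fast$lncrna_id, fast$gene_id)), ]
  expect_identical(rel$relation, gen$truth$cis_pairs$relation)

  shift <- function(ts, d) transcript_set(
    GenomicRanges::shift(tx_exons(ts), d), tx_sequences(ts))
  moved <- cis_targets(shift(lnc, 12345L), shift(gen$genes, 12345L), 10000)
  expect_equal(moved[c("lncrna_id", "gene_id", "relation", "distance_bp")],
               fast[c("lncrna_id", "gene_id", "relation", "distance_bp")])
})

test_that("local alignment matches forced examples and the DP oracle", {
  set.seed(60)
  # complementarity screen: the query equals the reverse complement of the
  # subject, so aligning it against the reverse-complemented subject (the
  # convention trans_targets uses) gives a perfect full-length hit
  s <- rand_seq(50)
  q <- reverse_complement(s)
  hit <- local_align(q, reverse_complement(s))
  expect_equal(hit$identity, 1)
  expect_equal(hit$aligned_length, 50L)
  expect_equal(hit$score, 50)

  # duplicating a perfect match doubles the gap-free optimal score
  q <- rand_seq(30)
  one <- local_align(q, q)$score
  expect_equal(local_align(strrep(q, 2), strrep(q, 2))$score, 2 * one)

  for (r in 1:25) {
    a <- rand_seq(20); b <- rand_seq(20)
    expect_equal(local_align(a, b)$score, oracle_sw_score(a, b), info = r)
  }
  expect_error(local_align("ACGT", "AC-GT"), "non-nucleotide")
})

test_that("E-values decrease in score and scale with the search space", {
  lam <- karlin_lambda(1, -2)
  expect_equal(0.25 * exp(lam) + 0.75 * exp(-2 * lam), 1, tolerance = 1e-9)
  set.seed(61)
  a <- rand_seq(80)
  weak <- local_align(rand_seq(80), rand_seq(80))
  strong <- local_align(a, a)
  expect_gt(strong$score, weak$score)
  expect_lt(strong$evalue, weak$evalue)
  # doubling subject length doubles m*n, doubling the E-value at equal score
  e1 <- 0.333 * 80 * 80 * exp(-lam * 25)
  e2 <- 0.333 * 80 * 160 * exp(-lam * 25)
  expect_equal(e2 / e1, 2)
})

test_that("duplex energy reproduces trivial cases and the stack-sum helix", {
  expect_equal(duplex_energy("AAAA", "AAAA"), 0)
  expect_equal(duplex_energy("A", "UUUU"), 0)    # < 2 nt

  # perfectly complementary 8-mer: initiation + the 7 stack terms
  par <- duplex_parameters()
  a <- "GCGCAUGC"
  b <- as.character(Biostrings::reverseComplement(Biostrings::RNAString(a)))
  pairs <- c("GC", "CG", "GC", "CG", "AU", "UA", "GC", "CG")[1:8]
  pr <- vapply(strsplit(a, "")[[1]], function(x)
    switch(x, A = "AU", U = "UA", G = "GC", C = "CG"), character(1))
  stacks <- sum(vapply(seq_len(7), function(i)
    par$stack[pr[i], pr[i + 1]], numeric(1)))
  expect_equal(duplex_energy(a, b), par$init + stacks)

  # T is read as U
  expect_equal(duplex_energy(chartr("U", "T", a), chartr("U", "T", b)),
               duplex_energy(a, b))
})

test_that("duplex DP equals exhaustive enumeration on short sequences", {
  set.seed(62)
  for (r in 1:40) {
    a <- rand_seq(sample(2:8, 1), c("A", "C", "G", "U"))
    b <- rand_seq(sample(2:8, 1), c("A", "C", "G", "U"))
    expect_equal(duplex_energy(a, b), oracle_duplex(a, b),
                 info = paste(a, b))
  }
})

test_that("duplex energy is symmetric under strand exchange", {
  set.seed(63)
  for (r in 1:20) {
    a <- rand_seq(sample(5:15, 1), c("A", "C", "G", "U"))
    b <- rand_seq(sample(5:15, 1), c("A", "C", "G", "U"))
    expect_equal(duplex_energy(a, b), duplex_energy(b, a))
  }
  # the stack table itself satisfies the strand-flip identity
  par <- duplex_parameters()
  flip <- c(AU = "UA", UA = "AU", CG = "GC", GC = "CG", GU = "UG", UG = "GU")
  for (p1 in rownames(par$stack)) for (p2 in colnames(par$stack))
    expect_equal(par$stack[p1, p2], par$stack[flip[p2], flip[p1]])
})

test_that("trans gates are conjunctive and ordered", {
  gen <- fixture_genome()
  truth <- gen$truth
  expect_gt(nrow(truth$trans_pairs), 0)
  lnc <- subset_transcripts(gen$transcripts, truth$trans_pairs$lncrna_id)
  tp <- trans_targets(lnc, gen$genes, lnc_config())
  expect_true(all(paste(truth$trans_pairs$lncrna_id,
                        truth$trans_pairs$gene_id) %in%
                    paste(tp$lncrna_id, tp$gene_id)))
  expect_true(all(tp$identity >= 0.95))
  expect_true(all(tp$evalue < 1e-5))
  expect_true(all(tp$energy_kcal_mol <= -60))

  # stage-1 rejection: identity below the gate stops the pair even though
  # the duplex energy would pass
  cfg_strict <- lnc_config(trans_min_identity = 0.999)
  mutated <- subset_transcripts(lnc, tx_ids(lnc)[1])
  sq <- as.character(tx_sequences(mutated)[[1]])
  n <- nchar(sq)
  for (pos in seq(5, n, by = 40))        # ~2.5% scattered mismatches
    substr(sq, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                    substr(sq, pos, pos))[1]
  mutated$seq[[1]] <- Biostrings::DNAString(sq)
  tp2 <- trans_targets(mutated, gen$genes, cfg_strict)
  expect_equal(nrow(tp2), 0L)
})

test_that("shuffled sequences yield no trans targets", {
  set.seed(64)
  mk <- function(prefix, n, len) {
    ids <- paste0(prefix, seq_len(n))
    exs <- lapply(seq_len(n), function(i)
      make_exons(1 + (i - 1) * 50000, (i - 1) * 50000 + len, id = ids[i],
                 biotype = if (prefix == "m") "coding" else "unknown"))
    sq <- setNames(vapply(seq_len(n), function(i) rand_seq(len),
                          character(1)), ids)
    do.call(make_ts, c(exs, list(sequences = sq)))
  }
  for (s in 1:3) {
    lnc <- mk("l", 8, 600)
    mrna <- mk("m", 5, 900)
    expect_equal(nrow(trans_targets(lnc, mrna, lnc_config())), 0L)
  }
})

test_that("pair concordance classifies trends with a strict boundary", {
  ids <- c("l1", "g1", "g2", "g3")
  se <- flat_se(ids)
  m <- fpkm(se)
  prof <- seq(1, 12, length.out = 12)
  cm_cols <- split(seq_len(ncol(m)),
                   paste(sample_info(se)$tissue, sample_info(se)$salt_mM))
  # build per-condition values: l1 and g1 identical, g2 reversed
  base <- rep(prof, each = 3)
  m["l1", ] <- base; m["g1", ] <- base
  m["g2", ] <- rev(base)
  m["g3", ] <- 5
  se <- expr_matrix(m, sample_info(se))
  pairs <- data.frame(lncrna_id = "l1", gene_id = c("g1", "g2", "g3"),
                      stringsAsFactors = FALSE)
  out <- pair_concordance(pairs, se, lnc_config())
  expect_equal(out$rho, c(1, -1, NA))
  expect_identical(out$trend, c("same", "opposite", "none"))

  # rho equal to the threshold is "none" (strict >)
  rho12 <- out$rho[1]
  cfg_edge <- lnc_config(concordance_rho = 1)
  expect_identical(pair_concordance(pairs[1, ], se, cfg_edge)$trend, "none")
})
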