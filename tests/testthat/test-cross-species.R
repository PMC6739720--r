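test_that("identical sets pair with themselves; disjoint sets do not", {
  set.seed(70)
  seqs <- setNames(vapply(1:6, function(i) rand_seq(400), character(1)),
                   paste0("x", 1:6))
  hom <- find_homologs(seqs, seqs)
  expect_equal(nrow(hom$pairs), 6L)
  expect_identical(hom$pairs$id_a, hom$pairs$id_b)
  expect_true(all(hom$pairs$identity == 1))
  expect_length(hom$specific_a, 0)

  other <- setNames(vapply(1:6, function(i) rand_seq(400), character(1)),
                    paste0("y", 1:6))
  hom2 <- find_homologs(seqs, other)
  expect_equal(nrow(hom2$pairs), 0L)
  expect_setequal(hom2$specific_a, names(seqs))
  expect_setequal(hom2$specific_b, names(other))
})

test_that("reciprocal best hits are symmetric in the species order", {
  gen <- fixture_genome()
  ea <- simulate_expression(gen$transcripts, gen$truth, seed = 8)
  gen$truth <- ea$truth
  sis <- simulate_sister_species(gen, divergence = 0.02, seed = 9,
                                 fraction_shared_lnc = 0.5)
  sa <- tx_sequences(gen$transcripts)[gen$truth$classes$transcript_id]
  sb <- tx_sequences(sis$transcripts)[sis$truth$classes$transcript_id]
  ab <- find_homologs(sa, sb)
  ba <- find_homologs(sb, sa)
  expect_identical(paste(ab$pairs$id_a, ab$pairs$id_b),
                   paste(ba$pairs$id_b[order(ba$pairs$id_b)],
                         ba$pairs$id_a[order(ba$pairs$id_b)]))
  # planted pairs recovered with no false positives
  truth_keys <- paste(sis$truth$homolog_map$id_a, sis$truth$homolog_map$id_b)
  got <- paste(ab$pairs$id_a, ab$pairs$id_b)
  expect_setequal(got, truth_keys)
})

test_that("homolog recall does not increase with divergence", {
  gen <- fixture_genome(n_genes = 6, n_lnc = 6, seed = 25)
  ea <- simulate_expression(gen$transcripts, gen$truth, seed = 26)
  gen$truth <- ea$truth
  recall <- vapply(c(0, 0.02, 0.1), function(d) {
    sis <- suppressWarnings(
      simulate_sister_species(gen, divergence = d, seed = 27,
                              fraction_shared_lnc = 0.5))
    sa <- tx_sequences(gen$transcripts)[gen$truth$classes$transcript_id]
    sb <- tx_sequences(sis$transcripts)[sis$truth$classes$transcript_id]
    hom <- find_homologs(sa, sb)
    keys <- paste(sis$truth$homolog_map$id_a, sis$truth$homolog_map$id_b)
    mean(keys %in% paste(hom$pairs$id_a, hom$pairs$id_b))
  }, numeric(1))
  expect_true(all(diff(recall) <= 0))
  expect_equal(recall[1], 1)
})

test_that("homolog concordance follows the strict Spearman rule", {
  design4 <- data.frame(sample_id = paste0(c("leaf", "phloem", "xylem",
                                             "root"), "_0_r1"),
                        tissue = c("leaf", "phloem", "xylem", "root"),
                        salt_mM = 0, replicate = 1L)
  mk <- function(vals, ids) expr_matrix(
    matrix(vals, nrow = length(ids), byrow = TRUE,
           dimnames = list(ids, design4$sample_id)), design4)
  se_a <- mk(c(1, 2, 3, 4,
               1, 2, 3, 4,
               2, 2, 2, 2), c("a1", "a2", "a3"))
  se_b <- mk(c(10, 20, 30, 40,
               4, 3, 2, 1,
               1, 5, 2, 8), c("b1", "b2", "b3"))
  pairs <- data.frame(id_a = c("a1", "a2", "a3"),
                      id_b = c("b1", "b2", "b3"),
                      stringsAsFactors = FALSE)
  expect_warning(out <- homolog_concordance(pairs, se_a, se_b, lnc_config()),
                 "constant")
  expect_equal(out$rho[1], 1)          # same rank order
  expect_equal(out$rho[2], -1)         # reversed
  expect_true(is.na(out$rho[3]))       # constant profile
  expect_identical(out$similar_pattern, c(TRUE, FALSE, FALSE))

  # tied ranks agree with the average-rank oracle
  se_t <- mk(c(1, 1, 3, 4), "a1")
  se_u <- mk(c(2, 2, 5, 9), "b1")
  out_t <- homolog_concordance(pairs[1, ], se_t, se_u, lnc_config())
  expect_equal(out_t$rho, oracle_spearman(c(1, 1, 3, 4), c(2, 2, 5, 9)))
})

test_that("species-specific DE requires no homolog and a DE call", {
  de <- data.frame(transcript_id = c("u1", "h1"), tissue = "leaf",
                   contrast = "0_vs_300", log2fc = 2, p = 1e-4,
                   is_de = TRUE, stringsAsFactors = FALSE)
  pairs <- data.frame(id_a = "h1", id_b = "hB", stringsAsFactors = FALSE)
  ids <- c("u1", "u2", "h1")
  out <- species_specific_de(ids, pairs, de)
  expect_identical(as.character(out), "u1")  # u2 not DE, h1 homologous
  expect_equal(as.integer(attr(out, "per_tissue")["leaf"]), 1L)
  # no DE anywhere -> empty
  de0 <- de[de$is_de == FALSE, ]
  expect_length(species_specific_de(ids, pairs, de0), 0)
  # subset property
  expect_true(all(out %in% setdiff(ids, pairs$id_a)))
})

test_that("high-expression flags use a strict per-tissue fold rule", {
  design4 <- data.frame(sample_id = paste0(c("leaf", "root"), "_0_r1"),
                        tissue = c("leaf", "root"), salt_mM = 0,
                        replicate = 1L)
  mk <- function(vals, ids) expr_matrix(
    matrix(vals, nrow = length(ids), byrow = TRUE,
           dimnames = list(ids, design4$sample_id)), design4)
  se_a <- mk(c(10, 8), "a1")
  se_b <- mk(c(2, 2), "b1")
  pairs <- data.frame(id_a = "a1", id_b = "b1", stringsAsFactors = FALSE)
  out <- high_expression_pairs(pairs, se_a, se_b, fc = 4)
  # leaf: 10 > 8 flagged; root: 8 > 8 is false (strict >)
  expect_identical(out$high_in_a_tissues, "leaf")
  expect_equal(out$n_high_tissues, 1L)
  # zero denominator: flagged iff A mean > 0
  se_b0 <- mk(c(0, 0), "b1")
  expect_message(out0 <- high_expression_pairs(pairs, se_a, se_b0, fc = 4),
                 "zero denominator")
  expect_equal(out0$n_high_tissues, 2L)
})

test_that("planted fivefold pairs are flagged at fc 4 and not at fc 6", {
  gen <- fixture_genome()
  ea <- simulate_expression(gen$transcripts, gen$truth, seed = 8,
                            noise_sd = 0.05)
  gen$truth <- ea$truth
  sis <- simulate_sister_species(gen, divergence = 0.02, seed = 9,
                                 fraction_shared_lnc = 0.5,
                                 high_expr_fraction = 0.4,
                                 high_expr_fold = 5)
  eb <- simulate_expression(sis$transcripts, sis$truth, seed = 10,
                            noise_sd = 0.05)
  pairs <- sis$truth$homolog_map
  planted <- paste(sis$truth$high_expr_pairs$id_a,
                   sis$truth$high_expr_pairs$id_b)
  expect_gt(length(planted), 0)
  h4 <- high_expression_pairs(pairs, ea$matrix, eb$matrix, fc = 4)
  flagged4 <- paste(h4$id_a, h4$id_b)[h4$n_high_tissues > 0]
  expect_setequal(flagged4, planted)
  h6 <- high_expression_pairs(pairs, ea$matrix, eb$matrix, fc = 6)
  expect_equal(sum(h6$n_high_tissues > 0), 0L)
})

test_that("tissue-specific homolog partition matches max tissues", {
  spec_a <- data.frame(transcript_id = c("a1", "a2"),
                       max_tissue = c("leaf", "root"))
  spec_b <- data.frame(transcript_id = c("b1", "b2"),
                       max_tissue = c("leaf", "xylem"))
  pairs <- data.frame(id_a = c("a1", "a2", "a3"),
                      id_b = c("b1", "b2", "b3"),
                      stringsAsFactors = FALSE)
  out <- tissue_specific_homologs(pairs, spec_a, spec_b)
  expect_equal(nrow(out), 2L)
  expect_identical(out$same_tissue, c(TRUE, FALSE))
})
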