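test_that("log2 fold change follows the pseudocount formula", {
  expect_equal(log2_fold_change(4, 1, 0), 2)
  expect_equal(log2_fold_change(7, 7, 0.01), 0)
  expect_equal(log2_fold_change(3, 6, 0.01), log2(3.01 / 6.01))
  expect_error(log2_fold_change(0, 0, 0), "undefined")
})

test_that("contrast test matches the hand-computed statistic", {
  expect_equal(contrast_test(c(2, 2, 2), c(2, 2, 2)), 1)
  a <- c(1, 1.1, 0.9); b <- c(8, 8.2, 7.9)
  expect_equal(contrast_test(a, b), oracle_pooled_t(a, b), tolerance = 1e-12)
  expect_lt(contrast_test(a, b), 0.001)
  set.seed(40)
  for (r in 1:20) {
    a <- 2^rnorm(3, 2); b <- 2^rnorm(4, 2.5)
    expect_equal(contrast_test(a, b), oracle_pooled_t(a, b),
                 tolerance = 1e-12)
  }
  # degenerate: both groups constant
  expect_equal(contrast_test(c(1, 1), c(1, 1)), 1)
  p <- contrast_test(c(1, 1), c(4, 4))
  expect_gt(p, 0)
  expect_lt(p, 1e-10)
  expect_error(contrast_test(1, c(2, 3)), "replicates")
})

test_that("type-I error of the contrast test is near nominal", {
  set.seed(41)
  p <- replicate(2000, contrast_test(2^rnorm(3, 2, 0.5),
                                     2^rnorm(3, 2, 0.5)))
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.07)
})

test_that("DE flag applies the inclusive-FC strict-p rule", {
  design <- default_design(tissues = "leaf")
  # transcript 'hit': means 0.99 -> 1.99 with pseudocount 0.01 gives
  # log2fc exactly 1; zero within-group variance gives minimal p
  vals <- rbind(
    hit = ifelse(design$salt_mM == 0, 0.99,
                 ifelse(design$salt_mM == 150, 0.99, 1.99)),
    under = ifelse(design$salt_mM == 0, 0.99,
                   ifelse(design$salt_mM == 150, 0.99, 1.97)),
    flat = rep(5, nrow(design)))
  colnames(vals) <- design$sample_id
  se <- expr_matrix(vals, design)
  de <- suppressWarnings(call_de(se, lnc_config()))
  hit <- de[de$transcript_id == "hit" & de$contrast == "0_vs_300", ]
  expect_equal(hit$log2fc, 1)
  expect_true(hit$is_de)
  under <- de[de$transcript_id == "under" & de$contrast == "0_vs_300", ]
  expect_lt(under$log2fc, 1)
  expect_false(under$is_de)        # tiny p but |lfc| < 1
  expect_false(any(de$is_de[de$transcript_id == "flat"]))
  expect_identical(salt_responsive(de), "hit")
})

test_that("DE calling is monotone in its thresholds", {
  fx <- fixture_expressed()
  lnc <- intersect(fx$gen$truth$classes$transcript_id,
                   rownames(fpkm(fx$se)))
  de1 <- call_de(fx$se[lnc, ], lnc_config())
  de2 <- call_de(fx$se[lnc, ], lnc_config(log2fc_cut = 0.5))
  de3 <- call_de(fx$se[lnc, ], lnc_config(p_cut = 0.2))
  expect_true(all(salt_responsive(de1) %in% salt_responsive(de2)))
  expect_true(all(salt_responsive(de1) %in% salt_responsive(de3)))
})

test_that("planted DE recovery at stated noise levels", {
  gen <- fixture_genome()
  rec <- c(); fpr <- c()
  for (s in 1:3) {
    e <- simulate_expression(gen$transcripts, gen$truth, seed = 300 + s,
                             noise_sd = 0.2)
    lnc <- e$truth$classes$transcript_id
    de <- call_de(e$matrix[lnc, ], lnc_config())
    resp <- salt_responsive(de)
    planted <- intersect(e$truth$de$transcript_id, lnc)
    nulls <- setdiff(lnc, c(planted, e$truth$tissue_specific$transcript_id))
    rec <- c(rec, mean(planted %in% resp))
    fpr <- c(fpr, mean(nulls %in% resp))
  }
  expect_gte(mean(rec), 0.9)
  expect_lte(mean(fpr), 0.05)
})

test_that("tau reproduces its closed-form values and properties", {
  expect_equal(tau_index(c(0, 0, 10, 0))$tau, 1)
  expect_equal(tau_index(c(5, 5, 5, 5))$tau, 0)
  expect_equal(tau_index(c(8, 2, 4, 1))$tau, 17 / 24)
  expect_identical(tau_index(c(leaf = 1, root = 9))$max_tissue, "root")
  expect_error(tau_index(c(0, 0, 0)), "undefined")

  set.seed(50)
  for (r in 1:20) {
    x <- runif(4, 0, 20)
    # scale invariance
    expect_equal(tau_index(x)$tau, tau_index(x * 7.3)$tau)
    # raising a zero tissue toward the max strictly lowers tau
    y <- c(0, x[-1] + 1)
    expect_gt(tau_index(y)$tau, tau_index(replace(y, 1, max(y) / 2))$tau)
  }
})

test_that("tau_table excludes all-zero transcripts with a warning", {
  se <- make_se(rbind(a = c(4, 4, 4, 4), z = c(0, 0, 0, 0)),
                tissues = c("leaf", "phloem", "xylem", "root"),
                salts = rep(0, 4))
  expect_warning(tt <- tau_table(se, lnc_config()), "all-zero")
  expect_identical(tt$transcript_id, "a")
  expect_equal(tt$tau, 0)
})

test_that("specificity sets apply their strict boundaries", {
  # profile (10, 1, 1, 1) has tau = 0.9 exactly
  se <- make_se(rbind(edge = c(10, 1, 1, 1),
                      spec = c(10, 0, 0, 0),
                      flat = c(5, 5.01, 5, 5)),
                tissues = c("leaf", "phloem", "xylem", "root"),
                salts = rep(0, 4))
  tt <- tau_table(se, lnc_config())
  expect_equal(tt$tau[tt$transcript_id == "edge"], 0.9)
  de <- data.frame(transcript_id = character(0), tissue = character(0),
                   contrast = character(0), log2fc = numeric(0),
                   p = numeric(0), is_de = logical(0))
  sets <- specificity_sets(tt, de, lnc_config())
  expect_false("edge" %in% sets$tissue_specific$transcript_id)  # strict >
  expect_true("spec" %in% sets$tissue_specific$transcript_id)
  expect_true("flat" %in% sets$housekeeping)

  # a salt-responsive transcript cannot be housekeeping
  de2 <- data.frame(transcript_id = "flat", tissue = "leaf",
                    contrast = "0_vs_300", log2fc = 2, p = 1e-6,
                    is_de = TRUE)
  expect_false("flat" %in% specificity_sets(tt, de2,
                                            lnc_config())$housekeeping)

  # tissue-specific DE = responsive in exactly one tissue
  de3 <- rbind(de2,
               data.frame(transcript_id = "spec", tissue = c("leaf", "root"),
                          contrast = "0_vs_300", log2fc = 2, p = 1e-6,
                          is_de = TRUE))
  sets3 <- specificity_sets(tt, de3, lnc_config())
  expect_identical(sets3$tissue_specific_de, "flat")
})

test_that("lncRNAs show weaker inter-tissue correlation than mRNAs", {
  fx <- fixture_expressed()
  truth <- fx$gen$truth
  lnc <- truth$classes$transcript_id
  mrna <- names(truth$gene_of_transcript)
  rho <- class_correlation_contrast(fx$se, lnc, mrna)
  expect_lt(rho["mean_rho_a"], rho["mean_rho_b"])
  # uniform-profile set gives rho 1 for every tissue pair
  ids <- mrna[1:5]
  se_u <- flat_se(ids)
  m <- fpkm(se_u)
  m[] <- rep(seq(2, 10, length.out = 5), ncol(m))  # distinct baselines
  se_u <- expr_matrix(m, sample_info(se_u))
  expect_equal(unname(class_correlation_contrast(se_u, ids, ids)[1]), 1)
  # cross-check one tissue pair against the rank-formula oracle
  tm <- tissue_means(fx$se, 0)[lnc, ]
  expect_equal(stats::cor(tm[, 1], tm[, 2], method = "spearman"),
               oracle_spearman(tm[, 1], tm[, 2]))
})
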