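test_that("expression filter keeps max-over-samples >= threshold", {
  ids <- c("lo", "edge", "zeroish")
  ts <- make_ts(make_exons(1, 300, id = "lo"),
                make_exons(1001, 1300, id = "edge"),
                make_exons(2001, 2300, id = "zeroish"))
  vals <- rbind(lo = rep(0.5, 4),
                edge = c(1, 0, 0, 0),
                zeroish = rep(0, 4))
  se <- make_se(vals, tissues = c("leaf", "phloem", "xylem", "root"),
                salts = rep(0, 4))
  kept <- tx_ids(filter_expression(ts, se, 1))
  expect_identical(kept, "edge")            # >= is inclusive
  expect_identical(sort(tx_ids(filter_expression(ts, se, 0))), sort(ids))
  expect_error(filter_expression(make_ts(make_exons(1, 9, id = "ghost")),
                                 se, 1),
               "ghost")
})

test_that("length filter uses spliced length with inclusive boundary", {
  ts <- make_ts(make_exons(c(1, 200), c(99, 299), id = "spliced199"),
                make_exons(c(1001, 1200), c(1100, 1299), id = "spliced200"),
                make_exons(5000, 5349, id = "single350"))
  kept <- tx_ids(filter_length(ts, 200))
  expect_setequal(kept, c("spliced200", "single350"))
  expect_equal(length(filter_length(ts, 0)), 3L)
})

test_that("longest_orf agrees with forced examples and a brute-force scan", {
  expect_equal(longest_orf("ATGAAATAA"),
               list(length_nt = 9L, frame = 0L, start = 1L))
  expect_equal(longest_orf("CCCGGGCCC")$length_nt, 0L)
  expect_equal(longest_orf("")$length_nt, 0L)
  # length includes the stop codon; 5'-most start wins ties
  expect_equal(longest_orf("ATGATGAAATAA")$start, 1L)
  expect_equal(longest_orf("ATGATGAAATAA")$length_nt, 12L)
  # U is read as T
  expect_equal(longest_orf("AUGAAAUAA")$length_nt, 9L)

  brute <- function(s) {
    best <- 0L
    for (f in 0:2) {
      st <- seq(1 + f, nchar(s) - 2, by = 3)
      cods <- substring(s, st, st + 2)
      for (i in seq_along(cods)) {
        if (cods[i] != "ATG") next
        for (j in i:length(cods)) {
          if (cods[j] %in% c("TAA", "TAG", "TGA")) {
            best <- max(best, (j - i + 1) * 3L)
            break
          }
        }
      }
    }
    best
  }
  set.seed(20)
  for (r in 1:25) {
    s <- rand_seq(300)
    expect_equal(longest_orf(s)$length_nt, brute(s), info = s)
  }
})

test_that("fickett score matches a hand walk through the packaged tables", {
  s <- strrep("ACG", 100)
  # per base: codon-position counts and content fraction, binned by hand
  expected <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- if (b == "A") c(100, 0, 0) else if (b == "C") c(0, 100, 0)
           else if (b == "G") c(0, 0, 100) else c(0, 0, 0)
    posval <- max(cnt) / (min(cnt) + 1)
    pbin <- which(posval >= fickett_position_cut)[1]
    expected <- expected +
      fickett_position_prob[[b]][pbin] * fickett_position_weight[[b]]
    cbin <- which(sum(cnt) / 300 >= fickett_content_cut)[1]
    expected <- expected +
      fickett_content_prob[[b]][cbin] * fickett_content_weight[[b]]
  }
  expect_equal(fickett_score(s), expected)

  # T <-> U invariance; reversal permutes the three codon-phase count
  # classes, so the max/(min+1) position parameter -- and the score -- is
  # exactly reversal-invariant
  set.seed(31)
  s2 <- rand_seq(300)
  expect_identical(fickett_score(s2), fickett_score(chartr("T", "U", s2)))
  s3 <- paste(rev(strsplit(s2, "")[[1]]), collapse = "")
  expect_equal(fickett_score(s3), fickett_score(s2))

  expect_warning(fickett_score(paste0(strrep("N", 60), rand_seq(100))),
                 "10%")
})

test_that("coding potential follows the rule branches and sign convention", {
  gen <- fixture_genome()
  mrna <- names(gen$truth$gene_of_transcript)[1]
  cp <- coding_potential(as.character(tx_sequences(gen$transcripts)[[mrna]]))
  expect_identical(cp$score, 1)
  expect_true(cp$coding)

  # score exactly 0 is retained: strict > for discard.
  # orf_fraction 0.5 and fickett forced to 0.95 via weight 0
  s <- paste0("ATG", strrep("GCA", 64), "TAA", strrep("C", 198))
  # 198-nt ORF in 396 nt -> fraction exactly 0.5
  cp0 <- coding_potential(s, orf_coding_nt = 300, w_fickett = 0)
  expect_equal(cp0$orf_fraction, 0.5)
  expect_equal(cp0$score, 0)
  expect_false(cp0$coding)

  # simulated lncRNAs score negative in nearly all cases
  set.seed(12)
  scores <- replicate(100, {
    s <- break_orfs_for_test(rand_seq(sample(300:1500, 1)))
    coding_potential(s)$score
  })
  expect_gte(mean(scores < 0), 0.95)
})

test_that("the identification funnel recovers planted truth exactly", {
  fx <- fixture_expressed()
  idr <- suppressMessages(identify_lncrnas(fx$gen$transcripts, fx$se,
                                           lnc_config()))
  planted <- fx$gen$truth$classes$transcript_id
  got <- tx_ids(idr$transcripts)
  expect_setequal(got, planted)   # precision = recall = 1
  expect_equal(unname(idr$funnel["input"]), length(fx$gen$transcripts))
  expect_equal(unname(idr$funnel["noncoding"]), length(planted))

  # empty input set
  empty <- subset_transcripts(fx$gen$transcripts, character(0))
  out <- suppressMessages(identify_lncrnas(empty, fx$se, lnc_config()))
  expect_equal(length(out$transcripts), 0L)
})

test_that("filters commute, are idempotent and monotone", {
  fx <- fixture_expressed()
  ts <- fx$gen$transcripts
  cfg <- lnc_config()
  a <- filter_length(filter_expression(ts, fx$se, cfg$min_fpkm),
                     cfg$min_length_nt)
  b <- filter_expression(filter_length(ts, cfg$min_length_nt), fx$se,
                         cfg$min_fpkm)
  expect_setequal(tx_ids(a), tx_ids(b))
  expect_setequal(tx_ids(filter_length(a, cfg$min_length_nt)), tx_ids(a))
  # raising a threshold never grows the surviving set
  for (thr in c(0, 1, 5, 50)) {
    s1 <- tx_ids(filter_expression(ts, fx$se, thr))
    s2 <- tx_ids(filter_expression(ts, fx$se, thr + 1))
    expect_true(all(s2 %in% s1))
  }
  for (thr in c(0, 200, 500, 1000)) {
    s1 <- tx_ids(filter_length(ts, thr))
    s2 <- tx_ids(filter_length(ts, thr + 100))
    expect_true(all(s2 %in% s1))
  }
})

test_that("external score side-input overrides the built-in scorer", {
  fx <- fixture_expressed()
  planted <- fx$gen$truth$classes$transcript_id
  ext <- data.frame(transcript_id = planted[1:2],
                    cpc = c(1.5, -1), cnci = c(-2, 0.2))
  idr <- suppressMessages(identify_lncrnas(fx$gen$transcripts, fx$se,
                                           lnc_config(), ext))
  # both listed transcripts have a positive external score -> discarded
  expect_false(any(planted[1:2] %in% tx_ids(idr$transcripts)))
  expect_setequal(tx_ids(idr$transcripts), planted[-(1:2)])
})
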