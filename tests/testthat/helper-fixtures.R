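# Small builders used across test files; heavier simulated fixtures are
# memoised so the suite pays for them once.

make_exons <- function(starts, ends, strand = "+", id = "t1", gene = id,
                       biotype = "unknown", chrom = "chr1") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                         strand = strand, transcript_id = id,
                         gene_id = gene, biotype = biotype)
}

# transcript_set from parallel per-transcript lists
make_ts <- function(..., sequences = NULL) {
  transcript_set(do.call(c, unname(list(...))), sequences)
}

# tiny expression matrix with an explicit design
make_se <- function(values, tissues, salts, reps = NULL) {
  n <- length(tissues)
  if (is.null(reps)) reps <- rep(1L, n)
  samples <- data.frame(
    sample_id = sprintf("%s_%g_r%d", tissues, salts, reps),
    tissue = tissues, salt_mM = salts, replicate = reps,
    stringsAsFactors = FALSE)
  colnames(values) <- samples$sample_id
  expr_matrix(values, samples)
}

# full 4x3x3 design matrix for a set of transcripts, constant value
flat_se <- function(ids, value = 5) {
  design <- default_design()
  m <- matrix(value, length(ids), nrow(design),
              dimnames = list(ids, design$sample_id))
  expr_matrix(m, design)
}

# same ORF-breaking rule the generator applies, for building lncRNA-like
# random sequences in tests
break_orfs_for_test <- function(s) {
  repeat {
    orf <- longest_orf(s)
    cap <- min(180L, floor(0.35 * nchar(s)))
    if (orf$length_nt <= max(9L, cap)) return(s)
    substr(s, orf$start + 2L, orf$start + 2L) <- "C"
  }
}

local({
  cache <- new.env(parent = emptyenv())
  fixture_genome <<- function(n_genes = 10, n_lnc = 5, seed = 7) {
    key <- paste("g", n_genes, n_lnc, seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- simulate_genome(n_genes, n_lnc, seed = seed)
    cache[[key]]
  }
  fixture_expressed <<- function(seed = 7) {
    key <- paste("e", seed)
    if (is.null(cache[[key]])) {
      gen <- fixture_genome(seed = seed)
      ea <- simulate_expression(gen$transcripts, gen$truth, seed = seed + 1)
      gen$truth <- ea$truth
      cache[[key]] <- list(gen = gen, se = ea$matrix)
    }
    cache[[key]]
  }
})
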