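#' Run the full lncRNA pipeline on files
#'
#' Orchestrates the method end to end in the published order: identify
#' (filter cascade) -> classify (positional classes) -> differential
#' expression across salt contrasts -> tau / specificity sets -> cis and
#' trans target prediction with expression concordance -> optional
#' cross-species comparison (homologs, concordance, species-specific DE,
#' high-expression pairs) -> optional GO enrichment of the DE lncRNAs'
#' target genes. Every output table is TSV with a header comment recording
#' the configuration hash; a JSON run summary collects the counts per
#' stage. The run is a pure function of (inputs, config): repeated runs
#' produce byte-identical outputs.
#'
#' @param config an `lnc_config`.
#' @param species_a named list of paths: `annotation` (assembled
#'   transcripts, GTF/GFF), `fasta` (transcript sequences), `genes`
#'   (reference protein-coding models, GTF/GFF), `expression` and `samples`
#'   (TSVs), optional `external_scores`.
#' @param out_dir output directory (created if needed).
#' @param species_b optional list like `species_a` for the sister species.
#' @param go_annotation optional TSV path (`gene_id`, `term_id`) for
#'   species A.
#' @return named list of output paths, invisibly; the run summary is
#'   `summary.json`.
#' @export
run_pipeline <- function(config, species_a, out_dir, species_b = NULL,
                         go_annotation = NULL) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  summary <- list(config = unclass(config), config_hash = config_hash(config))
  outputs <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  analyse_species <- function(sp, tag) {
    res <- list()
    res$ts <- stage(paste0("read_annotation_", tag), {
      ts <- read_annotation(sp$annotation)
      seqs <- read_transcript_fasta(sp$fasta)
      transcript_set(tx_exons(ts), seqs[intersect(names(seqs), tx_ids(ts))])
    })
    res$genes <- stage(paste0("read_genes_", tag), read_annotation(sp$genes))
    if (is.null(tx_sequences(res$genes))) {
      seqs <- read_transcript_fasta(sp$fasta)
      res$genes <- transcript_set(tx_exons(res$genes),
                                  seqs[intersect(names(seqs),
                                                 tx_ids(res$genes))])
    }
    res$se <- stage(paste0("read_expression_", tag),
                    read_expression(sp$expression, sp$samples))
    ext <- if (!is.null(sp$external_scores))
      read_external_scores(sp$external_scores) else NULL

    idres <- stage(paste0("identify_", tag),
                   identify_lncrnas(res$ts, res$se, config, ext))
    res$lnc <- idres$transcripts
    res$funnel <- idres$funnel

    cls <- stage(paste0("classify_", tag), classify_all(res$lnc, res$genes))
    res$classes <- cls$results
    res$class_counts <- cls$counts

    lnc_se <- res$se[intersect(tx_ids(res$lnc), rownames(fpkm(res$se))), ]
    res$de <- stage(paste0("de_", tag), call_de(lnc_se, config))
    res$responsive <- salt_responsive(res$de)

    res$tau <- stage(paste0("tau_", tag), tau_table(lnc_se, config))
    res$sets <- stage(paste0("specificity_", tag),
                      specificity_sets(res$tau, res$de, config))

    resp_lnc <- subset_transcripts(res$lnc,
                                   intersect(tx_ids(res$lnc), res$responsive))
    res$cis <- stage(paste0("cis_targets_", tag),
                     cis_targets(resp_lnc, res$genes, config$cis_window_bp,
                                 res$classes))
    res$trans <- stage(paste0("trans_targets_", tag),
                       trans_targets(resp_lnc, res$genes, config))

    gene_map <- stats::setNames(
      S4Vectors::mcols(tx_spans(res$genes))$transcript_id,
      S4Vectors::mcols(tx_spans(res$genes))$gene_id)
    both <- merge_target_tables(res$cis, res$trans)
    res$targets <- stage(paste0("concordance_", tag),
                         pair_concordance(both, res$se, config, gene_map))
    res
  }

  write_species <- function(res, tag) {
    rec <- res$classes
    ti <- match(rec$transcript_id, res$tau$transcript_id)
    rec$tau <- res$tau$tau[ti]
    rec$max_tissue <- res$tau$max_tissue[ti]
    rec$salt_responsive <- rec$transcript_id %in% res$responsive
    rec$tissue_specific <- rec$transcript_id %in%
      res$sets$tissue_specific$transcript_id
    rec$housekeeping <- rec$transcript_id %in% res$sets$housekeeping
    f <- file.path(out_dir, paste0("lncrna_records_", tag, ".tsv"))
    write_tsv(rec, f, config)
    outputs[[paste0("records_", tag)]] <<- f
    f <- file.path(out_dir, paste0("de_", tag, ".tsv"))
    write_tsv(res$de, f, config)
    outputs[[paste0("de_", tag)]] <<- f
    f <- file.path(out_dir, paste0("targets_", tag, ".tsv"))
    write_tsv(res$targets, f, config)
    outputs[[paste0("targets_", tag)]] <<- f
    summary[[paste0("species_", tag)]] <<- list(
      funnel = as.list(res$funnel),
      class_counts = as.list(res$class_counts),
      n_lncrna = length(res$lnc),
      n_salt_responsive = length(res$responsive),
      de_per_contrast = de_contrast_counts(res$de),
      n_tissue_specific = nrow(res$sets$tissue_specific),
      n_housekeeping = length(res$sets$housekeeping),
      n_tissue_specific_de = length(res$sets$tissue_specific_de),
      n_cis_pairs = nrow(res$cis),
      n_trans_pairs = nrow(res$trans),
      n_concordant_pairs = sum(res$targets$trend != "none"))
  }

  a <- analyse_species(species_a, "a")
  write_species(a, "a")

  if (!is.null(species_b)) {
    b <- analyse_species(species_b, "b")
    write_species(b, "b")

    hom <- stage("homologs", find_homologs(
      tx_sequences(a$lnc), tx_sequences(b$lnc), config))
    pairs <- stage("homolog_concordance",
                   homolog_concordance(hom$pairs, a$se, b$se, config))
    pairs <- stage("high_expression", high_expression_pairs(
      pairs, a$se, b$se, config$homolog_expression_fc))
    f <- file.path(out_dir, "homologs.tsv")
    write_tsv(pairs, f, config)
    outputs$homologs <- f

    ssde <- stage("species_specific_de",
                  species_specific_de(tx_ids(a$lnc), hom$pairs, a$de))
    f <- file.path(out_dir, "species_specific_a.tsv")
    write_tsv(data.frame(transcript_id = ssde, stringsAsFactors = FALSE),
              f, config)
    outputs$species_specific_a <- f

    tsh <- tissue_specific_homologs(pairs, a$sets$tissue_specific,
                                    b$sets$tissue_specific)
    summary$comparison <- list(
      n_homolog_pairs = nrow(pairs),
      n_specific_a = length(hom$specific_a),
      n_specific_b = length(hom$specific_b),
      n_similar_pattern = sum(pairs$similar_pattern),
      n_high_expression_pairs = sum(pairs$n_high_tissues > 0),
      high_pairs_per_tissue = high_pairs_per_tissue(pairs),
      n_species_specific_de_a = length(ssde),
      species_specific_de_per_tissue = as.list(attr(ssde, "per_tissue")),
      n_tissue_specific_homologs = nrow(tsh),
      n_same_tissue = sum(tsh$same_tissue))
  }

  if (!is.null(go_annotation)) {
    ann <- read_tsv(go_annotation)
    background <- sort(unique(S4Vectors::mcols(tx_spans(a$genes))$gene_id))
    tgt <- sort(intersect(unique(a$targets$gene_id), background))
    enr <- stage("enrichment", go_enrichment(tgt, ann, background, config))
    f <- file.path(out_dir, "enrichment_a.tsv")
    write_tsv(enr, f, config)
    outputs$enrichment_a <- f
    summary$enrichment <- list(n_terms_tested = nrow(enr),
                               n_enriched = sum(enr$enriched))
  }

  f <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, na = "null")
  outputs$summary <- f
  invisible(outputs)
}

merge_target_tables <- function(cis, trans) {
  cols <- c("lncrna_id", "gene_id", "mode", "relation", "distance_bp",
            "identity", "evalue", "energy_kcal_mol")
  fill <- function(df) {
    for (cc in setdiff(cols, names(df)))
      df[[cc]] <- rep(if (cc == "relation") NA_character_ else NA_real_,
                      nrow(df))
    df[, cols, drop = FALSE]
  }
  out <- rbind(fill(cis), fill(trans))
  rownames(out) <- NULL
  out
}

de_contrast_counts <- function(de) {
  d <- unique(de[de$is_de, c("transcript_id", "contrast")])
  as.list(table(d$contrast))
}

high_pairs_per_tissue <- function(pairs) {
  tis <- unlist(strsplit(pairs$high_in_a_tissues[pairs$n_high_tissues > 0],
                         ",", fixed = TRUE))
  as.list(table(tis))
}
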