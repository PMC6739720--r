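#' Pipeline configuration
#'
#' Builds the configuration object holding every threshold the pipeline uses.
#' Defaults correspond to the published analysis this package reimplements:
#' transcripts are kept when FPKM >= 1 in at least one library and spliced
#' length >= 200 nt; salt response requires |log2 FC| >= 1 at p < 0.05;
#' tissue-specific means tau > 0.9 and housekeeping tau < 0.1; cis targets
#' lie within a 10-kb window; trans candidates need alignment identity >= 0.95
#' at E-value < 1e-5 and a duplex free energy <= -60 kcal/mol; homolog
#' expression concordance requires Spearman rho > 0.9 and "highly expressed"
#' pairs a fold change > 4; GO terms are called enriched at raw p < 0.05.
#'
#' @param min_fpkm minimum FPKM that must be reached in at least one sample.
#' @param min_length_nt minimum spliced transcript length in nucleotides.
#' @param log2fc_cut absolute log2 fold-change cutoff for differential calls
#'   (inclusive).
#' @param p_cut p-value cutoff for differential calls (strict).
#' @param tau_specific tau above which (strictly) a transcript is
#'   tissue-specific.
#' @param tau_housekeeping tau below which (strictly) a transcript is a
#'   housekeeping candidate. Must be smaller than `tau_specific`.
#' @param cis_window_bp maximum genomic gap (bp) between a lncRNA and a gene
#'   for a cis pairing (inclusive).
#' @param trans_min_identity minimum alignment identity for trans candidates
#'   (inclusive).
#' @param trans_max_evalue maximum alignment E-value for trans candidates
#'   (strict).
#' @param duplex_energy_cut duplex free-energy cutoff in kcal/mol; pairs are
#'   kept when energy <= this value. The published screen passed "-60" to the
#'   duplex program without units; treat this default with care and tune for
#'   your own energy model if needed.
#' @param concordance_rho Spearman rho above which (strictly) two expression
#'   profiles count as concordant ("same"; below `-concordance_rho` is
#'   "opposite").
#' @param homolog_expression_fc fold change above which (strictly) a homolog
#'   pair counts as highly expressed in species A relative to B.
#' @param go_p_cut raw p-value cutoff for GO enrichment (strict).
#' @param pseudocount value added to FPKM before log2 in fold changes and
#'   tests.
#' @param orf_coding_nt ORF length (nt, including stop) at and above which a
#'   transcript is called coding outright by the built-in scorer.
#' @param coding_w_orf,coding_w_fickett weights of the ORF-fraction and
#'   Fickett terms in the built-in coding-potential score.
#' @param align_match,align_mismatch match/mismatch scores of the local
#'   aligner.
#' @param align_gap_open,align_gap_extend positive gap costs; a gap of length
#'   L costs `align_gap_open + L * align_gap_extend`.
#' @param tau_salt_mM salt level (mM) whose samples feed the tau index;
#'   `NULL` averages over all salt levels. Default 0 (control).
#' @param seed integer seed from which all randomness in a run flows.
#' @return An object of class `lnc_config` (a validated named list).
#' @examples
#' cfg <- lnc_config()
#' cfg$min_fpkm
#' @export
lnc_config <- function(min_fpkm = 1,
                       min_length_nt = 200L,
                       log2fc_cut = 1,
                       p_cut = 0.05,
                       tau_specific = 0.9,
                       tau_housekeeping = 0.1,
                       cis_window_bp = 10000L,
                       trans_min_identity = 0.95,
                       trans_max_evalue = 1e-5,
                       duplex_energy_cut = -60,
                       concordance_rho = 0.9,
                       homolog_expression_fc = 4,
                       go_p_cut = 0.05,
                       pseudocount = 0.01,
                       orf_coding_nt = 300L,
                       coding_w_orf = 1,
                       coding_w_fickett = 1,
                       align_match = 1,
                       align_mismatch = -2,
                       align_gap_open = 5,
                       align_gap_extend = 2,
                       tau_salt_mM = 0,
                       seed = 1L) {
  cfg <- list(
    min_fpkm = min_fpkm, min_length_nt = as.integer(min_length_nt),
    log2fc_cut = log2fc_cut, p_cut = p_cut,
    tau_specific = tau_specific, tau_housekeeping = tau_housekeeping,
    cis_window_bp = as.integer(cis_window_bp),
    trans_min_identity = trans_min_identity,
    trans_max_evalue = trans_max_evalue,
    duplex_energy_cut = duplex_energy_cut,
    concordance_rho = concordance_rho,
    homolog_expression_fc = homolog_expression_fc,
    go_p_cut = go_p_cut, pseudocount = pseudocount,
    orf_coding_nt = as.integer(orf_coding_nt),
    coding_w_orf = coding_w_orf, coding_w_fickett = coding_w_fickett,
    align_match = align_match, align_mismatch = align_mismatch,
    align_gap_open = align_gap_open, align_gap_extend = align_gap_extend,
    tau_salt_mM = tau_salt_mM,
    seed = as.integer(seed)
  )
  class(cfg) <- "lnc_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg an `lnc_config` object.
#' @return `cfg`, invisibly, or an error describing the violated constraint.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "lnc_config"))
  num <- cfg[setdiff(names(cfg), "tau_salt_mM")]
  bad <- names(num)[!vapply(num, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))]
  if (length(bad) > 0)
    stop("config fields must be finite scalars: ", paste(bad, collapse = ", "))
  if (cfg$tau_housekeeping >= cfg$tau_specific)
    stop("tau_housekeeping (", cfg$tau_housekeeping,
         ") must be < tau_specific (", cfg$tau_specific, ")")
  if (cfg$p_cut <= 0 || cfg$p_cut > 1) stop("p_cut must be in (0, 1]")
  if (cfg$go_p_cut <= 0 || cfg$go_p_cut > 1) stop("go_p_cut must be in (0, 1]")
  if (cfg$min_length_nt < 0) stop("min_length_nt must be >= 0")
  if (cfg$cis_window_bp < 0) stop("cis_window_bp must be >= 0")
  if (cfg$trans_min_identity < 0 || cfg$trans_min_identity > 1)
    stop("trans_min_identity must be in [0, 1]")
  if (cfg$homolog_expression_fc <= 1)
    stop("homolog_expression_fc must be > 1")
  if (cfg$pseudocount < 0) stop("pseudocount must be >= 0")
  if (cfg$align_gap_open < 0 || cfg$align_gap_extend < 0)
    stop("gap costs are positive penalties")
  invisible(cfg)
}

#' @export
print.lnc_config <- function(x, ...) {
  cat("lncsalt pipeline configuration (hash ", config_hash(x), ")\n", sep = "")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Stable hash of a configuration
#'
#' MD5 of the deparsed configuration; recorded in the header comment of every
#' output table so results can be traced back to the thresholds that made
#' them.
#'
#' @param cfg an `lnc_config` object.
#' @return A character scalar (32 hex digits).
#' @export
config_hash <- function(cfg) {
  # normalize storage types so a JSON round trip (integer <-> double)
  # cannot change the hash
  vals <- lapply(unclass(cfg), function(x)
    if (is.numeric(x)) as.numeric(x) else x)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(vals, control = "all"), f)
  unname(tools::md5sum(f))
}

#' Read / write a configuration as JSON
#'
#' Unknown keys are rejected so typos in threshold names fail loudly.
#'
#' @param path JSON file path.
#' @return `read_config` returns an `lnc_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- jsonlite::fromJSON(path)
  unknown <- setdiff(names(vals), names(formals(lnc_config)))
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(lnc_config, vals)
}

#' @param cfg an `lnc_config` object.
#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
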