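#' Log2 fold change between two group means
#'
#' `log2((mean_b + pseudocount) / (mean_a + pseudocount))`, with means taken
#' over replicate FPKM per group. The pseudocount regularizes zero means;
#' with both means zero and no pseudocount the ratio is undefined and an
#' error is raised rather than silently returning NaN.
#'
#' @param mean_b,mean_a non-negative group means (b = treated, a = control).
#' @param pseudocount added to both means; must be > 0 unless both means are
#'   positive.
#' @return numeric log2 fold change.
#' @examples
#' log2_fold_change(4, 1, 0)   # 2
#' @export
log2_fold_change <- function(mean_b, mean_a, pseudocount = 0.01) {
  stopifnot(mean_a >= 0, mean_b >= 0, pseudocount >= 0)
  if (pseudocount == 0 && (mean_a == 0 || mean_b == 0)) {
    if (mean_a == 0 && mean_b == 0)
      stop("both means are zero and pseudocount is 0: fold change undefined")
  }
  log2((mean_b + pseudocount) / (mean_a + pseudocount))
}

#' Two-group test on log-scale expression
#'
#' Two-sided pooled-variance Student t-test on `log2(FPKM + pseudocount)`.
#' With three replicates per group a replicate-aware location test is the
#' smallest defensible choice; the pooled (equal-variance) form is used
#' rather than Welch because at n = 3 per group the Welch-Satterthwaite
#' approximation is markedly conservative (empirical size ~0.03 at nominal
#' 0.05), while the pooled test is exact under the equal-variance Gaussian
#' null. When both groups have zero variance the p-value is 1 for equal
#' means and the smallest positive double otherwise (p must stay in (0, 1]).
#'
#' @param group_a,group_b numeric vectors of replicate FPKM (>= 2 each).
#' @param pseudocount added before the log2 transform.
#' @return p-value in (0, 1].
#' @export
contrast_test <- function(group_a, group_b, pseudocount = 0.01) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("need >= 2 replicates per group")
  a <- log2(group_a + pseudocount)
  b <- log2(group_b + pseudocount)
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  if (se == 0) {
    return(if (mean(a) == mean(b)) 1 else .Machine$double.xmin)
  }
  tstat <- (mean(b) - mean(a)) / se
  p <- 2 * stats::pt(-abs(tstat), df = na + nb - 2)
  max(p, .Machine$double.xmin)
}

#' Differential-expression calls across salt contrasts
#'
#' For every transcript, tissue and ordered salt contrast (low vs high among
#' the levels present, e.g. 0 vs 150, 0 vs 300, 150 vs 300 mM) computes the
#' replicate-mean log2 fold change (high relative to low) and the p-value of
#' [contrast_test()], and flags `is_de` iff `|log2fc| >= log2fc_cut` (the
#' published rule is inclusive at 1) and `p < p_cut` (strict at 0.05).
#' A Benjamini-Hochberg adjusted column is reported alongside but does not
#' feed the flag, mirroring the published raw-p rule. A transcript is "salt
#' responsive" when `is_de` holds in at least one (tissue, contrast).
#'
#' @param se expression matrix; its design must contain every salt level in
#'   every tissue (a missing replicate group skips that contrast with a
#'   warning).
#' @param config an `lnc_config`.
#' @return data.frame with columns `transcript_id`, `tissue`, `contrast`
#'   (e.g. `"0_vs_150"`), `log2fc`, `p`, `p_adj_BH`, `is_de`.
#' @export
call_de <- function(se, config = lnc_config()) {
  validate_config(config)
  info <- sample_info(se)
  validate_design(info)
  m <- fpkm(se)
  tissues <- unique(info$tissue)
  salts <- sort(unique(info$salt_mM))
  pairs <- utils::combn(salts, 2, simplify = FALSE)
  out <- list()
  for (tt in tissues) {
    for (pr in pairs) {
      ia <- which(info$tissue == tt & info$salt_mM == pr[1])
      ib <- which(info$tissue == tt & info$salt_mM == pr[2])
      lab <- paste0(pr[1], "_vs_", pr[2])
      if (length(ia) < 2 || length(ib) < 2) {
        warning("skipping contrast ", lab, " in ", tt,
                ": missing replicate group")
        next
      }
      ga <- m[, ia, drop = FALSE]; gb <- m[, ib, drop = FALSE]
      lfc <- log2_fold_change(rowMeans(gb), rowMeans(ga), config$pseudocount)
      pv <- vapply(seq_len(nrow(m)), function(r)
        contrast_test(ga[r, ], gb[r, ], config$pseudocount), numeric(1))
      out[[paste(tt, lab)]] <- data.frame(
        transcript_id = rownames(m), tissue = tt, contrast = lab,
        log2fc = lfc, p = pv, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$p_adj_BH <- stats::p.adjust(res$p, method = "BH")
  res$is_de <- abs(res$log2fc) >= config$log2fc_cut & res$p < config$p_cut
  res
}

#' Salt-responsive transcript ids
#'
#' @param de data.frame from [call_de()].
#' @return character vector of transcripts with `is_de` in >= 1 contrast.
#' @export
salt_responsive <- function(de) {
  sort(unique(de$transcript_id[de$is_de]))
}

#' Tissue-specificity index (tau)
#'
#' `tau = sum_i (1 - Exp_i / Exp_max) / (n - 1)` over the n tissue means:
#' 0 for a perfectly uniform (housekeeping-like) profile, 1 for expression
#' restricted to a single tissue. Undefined (error) for an all-zero profile.
#'
#' @param tissue_means named non-negative numeric vector, length >= 2.
#' @return list with `tau` and `max_tissue` (name, or index when unnamed, of
#'   the maximal tissue; first maximum on ties).
#' @examples
#' tau_index(c(leaf = 0, phloem = 0, xylem = 10, root = 0))$tau  # 1
#' tau_index(c(5, 5, 5, 5))$tau                                  # 0
#' @export
tau_index <- function(tissue_means) {
  stopifnot(is.numeric(tissue_means), length(tissue_means) >= 2,
            all(tissue_means >= 0))
  mx <- max(tissue_means)
  if (mx == 0) stop("all-zero profile: tau undefined")
  tau <- sum(1 - tissue_means / mx) / (length(tissue_means) - 1)
  imax <- which.max(tissue_means)
  list(tau = tau,
       max_tissue = if (!is.null(names(tissue_means)))
         names(tissue_means)[imax] else imax)
}

#' Tau for every transcript of an expression matrix
#'
#' Tissue means are taken at the configured salt level (default the 0 mM
#' control; set `tau_salt_mM = NULL` in the config to average over all salt
#' levels). All-zero transcripts are excluded with a warning.
#'
#' @param se expression matrix.
#' @param config an `lnc_config`.
#' @return data.frame with `transcript_id`, `tau`, `max_tissue`.
#' @export
tau_table <- function(se, config = lnc_config()) {
  tm <- tissue_means(se, config$tau_salt_mM)
  if (ncol(tm) < 2) stop("tau needs >= 2 tissues")
  zero <- rowSums(tm) == 0
  if (any(zero))
    warning(sum(zero), " all-zero transcript(s) excluded from tau")
  tm <- tm[!zero, , drop = FALSE]
  res <- lapply(seq_len(nrow(tm)), function(i) tau_index(tm[i, ]))
  data.frame(transcript_id = rownames(tm),
             tau = vapply(res, `[[`, numeric(1), "tau"),
             max_tissue = vapply(res, `[[`, character(1), "max_tissue"),
             stringsAsFactors = FALSE)
}

#' Tissue-specific, housekeeping and tissue-specific-DE sets
#'
#' * tissue-specific: `tau > tau_specific` (strict);
#' * housekeeping: `tau < tau_housekeeping` (strict) and salt-responsive in
#'   no contrast;
#' * tissue-specific DE: salt-responsive in exactly one tissue.
#'
#' @param tau_df data.frame from [tau_table()].
#' @param de data.frame from [call_de()] over the same transcript universe.
#' @param config an `lnc_config`.
#' @return list with `tissue_specific` (data.frame `transcript_id`,
#'   `max_tissue`), `housekeeping` (ids) and `tissue_specific_de` (ids).
#' @export
specificity_sets <- function(tau_df, de, config = lnc_config()) {
  validate_config(config)
  ts <- tau_df[tau_df$tau > config$tau_specific,
               c("transcript_id", "max_tissue")]
  rownames(ts) <- NULL
  responsive <- salt_responsive(de)
  hk <- setdiff(tau_df$transcript_id[tau_df$tau < config$tau_housekeeping],
                responsive)
  de_t <- unique(de[de$is_de, c("transcript_id", "tissue")])
  ntis <- table(de_t$transcript_id)
  tsde <- sort(names(ntis)[ntis == 1])
  list(tissue_specific = ts, housekeeping = sort(hk),
       tissue_specific_de = tsde)
}

#' Inter-tissue correlation contrast between two transcript sets
#'
#' For each set, restricts the tissue-mean matrix to the set's transcripts
#' and computes the Spearman correlation between every pair of tissue
#' columns; returns the mean over tissue pairs for both sets. lncRNAs are
#' expected to show the lower value (weaker inter-tissue relationship) than
#' mRNAs. Constant columns make a pair's rho undefined; such pairs are
#' excluded with a warning.
#'
#' @param se expression matrix.
#' @param set_a,set_b non-empty character vectors of transcript ids.
#' @param salt_mM salt level for the tissue means (default 0 = control).
#' @return named numeric vector `c(mean_rho_a, mean_rho_b)`.
#' @export
class_correlation_contrast <- function(se, set_a, set_b, salt_mM = 0) {
  tm <- tissue_means(se, salt_mM)
  if (ncol(tm) < 2) stop("need >= 2 tissues")
  mean_rho <- function(ids) {
    stopifnot(length(ids) > 0)
    sub <- tm[intersect(ids, rownames(tm)), , drop = FALSE]
    prs <- utils::combn(ncol(sub), 2, simplify = FALSE)
    rhos <- vapply(prs, function(pr) {
      x <- sub[, pr[1]]; y <- sub[, pr[2]]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
      stats::cor(x, y, method = "spearman")
    }, numeric(1))
    if (anyNA(rhos))
      warning("excluded ", sum(is.na(rhos)), " tissue pair(s) with constant profile")
    mean(rhos, na.rm = TRUE)
  }
  c(mean_rho_a = mean_rho(set_a), mean_rho_b = mean_rho(set_b))
}
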