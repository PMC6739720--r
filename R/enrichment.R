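#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` (a set of size `n` drawn
#' from a background of `N` with `K` marked), computed in log space
#' (`lchoose` + log-sum-exp) for stability at large counts. Infeasible
#' count combinations are errors.
#'
#' @param k observed hits in the set.
#' @param K hits in the background.
#' @param n set size.
#' @param N background size.
#' @return p-value in (0, 1].
#' @examples
#' hypergeometric_tail(3, 5, 6, 20)  # 5090/38760
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (K > N || n > N || k > min(K, n) || k < 0 || K < 0 || n < 0)
    stop("infeasible hypergeometric counts: k=", k, " K=", K,
         " n=", n, " N=", N)
  if (k <= max(0, n + K - N)) return(1)
  i <- seq.int(k, min(K, n))
  lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  mx <- max(lt)
  p <- exp(mx + log(sum(exp(lt - mx))))
  min(1, p)
}

#' GO-term over-representation by the hypergeometric test
#'
#' One test per term with at least one annotated background gene. Genes
#' absent from the annotation table count as term-free background. The
#' `enriched` flag uses the raw p-value against `go_p_cut` (the published
#' rule); a Benjamini-Hochberg column over the tested terms is reported
#' alongside.
#'
#' @param target_genes character vector of gene ids (must be a subset of
#'   `background`).
#' @param annotation data.frame with columns `gene_id`, `term_id`.
#' @param background character vector of gene ids (default: all genes in the
#'   annotation).
#' @param config an `lnc_config`.
#' @return data.frame ordered by p then term id, with columns `term_id`,
#'   `k`, `K`, `n`, `N`, `p_value`, `p_adj_BH`, `enriched`.
#' @export
go_enrichment <- function(target_genes, annotation,
                          background = unique(annotation$gene_id),
                          config = lnc_config()) {
  validate_config(config)
  stopifnot(all(c("gene_id", "term_id") %in% names(annotation)))
  target_genes <- unique(target_genes)
  background <- unique(background)
  extra <- setdiff(target_genes, background)
  if (length(extra) > 0)
    stop("target genes outside the background: ",
         paste(utils::head(extra, 5), collapse = ", "))
  empty <- data.frame(term_id = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      p_adj_BH = numeric(0), enriched = logical(0),
                      stringsAsFactors = FALSE)
  if (length(target_genes) == 0) {
    warning("empty target set: no enrichment computed")
    return(empty)
  }
  ann <- unique(annotation[annotation$gene_id %in% background,
                           c("gene_id", "term_id")])
  if (nrow(ann) == 0) return(empty)
  N <- length(background)
  n <- length(target_genes)
  Ktab <- table(ann$term_id)
  ktab <- table(ann$term_id[ann$gene_id %in% target_genes])
  terms <- names(Ktab)
  k <- as.integer(ktab[terms]); k[is.na(k)] <- 0L
  K <- as.integer(Ktab[terms])
  p <- vapply(seq_along(terms), function(i)
    hypergeometric_tail(k[i], K[i], n, N), numeric(1))
  out <- data.frame(term_id = terms, k = k, K = K, n = n, N = N,
                    p_value = p,
                    p_adj_BH = stats::p.adjust(p, method = "BH"),
                    enriched = p < config$go_p_cut,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
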