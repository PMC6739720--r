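#' Parameters of the intermolecular RNA-RNA duplex energy model
#'
#' A deliberately reduced nearest-neighbor hybridization model: Watson-Crick
#' and GU wobble pairs; stacking free energies for adjacent pairs from the
#' standard Watson-Crick nearest-neighbor set (kcal/mol at 37 C), with a
#' uniform mild value for wobble-containing stacks; linear penalties for
#' bulges and interior loops; one duplex-initiation constant; no dangling
#' ends and no intramolecular structure. It is a documented stand-in for a
#' full duplex folder, validated against its own brute-force enumeration
#' oracle, not against external programs.
#'
#' The stack table is indexed by (5' pair, 3' pair) along the first strand
#' and satisfies `S[p1, p2] == S[flip(p2), flip(p1)]` (reading the helix
#' from the other strand), which makes [duplex_energy()] invariant under
#' `(a, b) -> (reverse(b), reverse(a))`.
#'
#' @return list with `stack` (6 x 6 matrix, pairs AU, UA, CG, GC, GU, UG),
#'   `init`, `bulge_open`, `bulge_nt`, `interior_open`, `interior_nt` (all
#'   kcal/mol; penalties positive).
#' @export
duplex_parameters <- function() {
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  S <- matrix(NA_real_, 6, 6, dimnames = list(pairs, pairs))
  S["AU", "AU"] <- -0.93   # 5'AA3'/3'UU5'
  S["AU", "UA"] <- -1.10   # AU/UA
  S["UA", "AU"] <- -1.33   # UA/AU
  S["CG", "UA"] <- -2.08   # CU/GA
  S["CG", "AU"] <- -2.11   # CA/GU
  S["GC", "UA"] <- -2.24   # GU/CA
  S["GC", "AU"] <- -2.35   # GA/CU
  S["CG", "GC"] <- -2.36   # CG/GC
  S["GC", "GC"] <- -3.26   # GG/CC
  S["GC", "CG"] <- -3.42   # GC/CG
  flip <- c(AU = "UA", UA = "AU", CG = "GC", GC = "CG", GU = "UG", UG = "GU")
  # wobble-containing stacks: uniform mild stabilization, except the
  # destabilizing UG-after-GU motif
  for (p1 in pairs) for (p2 in pairs)
    if (is.na(S[p1, p2]) && (p1 %in% c("GU", "UG") || p2 %in% c("GU", "UG")))
      S[p1, p2] <- -0.5
  S["GU", "UG"] <- 0.3
  S["UG", "GU"] <- 0.3
  # complete by strand-flip symmetry
  for (p1 in pairs) for (p2 in pairs)
    if (is.na(S[p1, p2])) S[p1, p2] <- S[flip[p2], flip[p1]]
  list(stack = S, init = 4.09,
       bulge_open = 3.8, bulge_nt = 0.5,
       interior_open = 2.6, interior_nt = 0.5)
}

# map a nucleotide string to integers A=1 C=2 G=3 U/T=4 (others NA)
rna_ints <- function(x) {
  s <- chartr("Uu", "Tt", toupper(as.character(x)))
  v <- match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  v
}

# 4x4 lookup: pair code for (base of a, base of b), 0 = unpairable
pair_code_matrix <- function() {
  P <- matrix(0L, 4, 4)
  P[1, 4] <- 1L  # A-U
  P[4, 1] <- 2L  # U-A
  P[2, 3] <- 3L  # C-G
  P[3, 2] <- 4L  # G-C
  P[3, 4] <- 5L  # G-U
  P[4, 3] <- 6L  # U-G
  P
}

#' Minimum free energy of an intermolecular RNA-RNA duplex
#'
#' Dynamic program over base pairings between `a` (5'->3') and `b` (read
#' 3'->5', i.e. antiparallel hybridization), minimizing
#' `init + sum(stack terms) + sum(bulge/interior penalties)` under the model
#' of [duplex_parameters()]. No intramolecular pairs are considered. Returns
#' 0 when no duplex with negative free energy exists. T is read as U;
#' positions with other characters never pair.
#'
#' @param a,b nucleotide strings (RNA or DNA alphabet).
#' @param params model parameters, see [duplex_parameters()].
#' @return duplex free energy in kcal/mol (<= 0).
#' @examples
#' duplex_energy("AAAA", "AAAA")        # 0, nothing can pair
#' duplex_energy("GGGGGGGG", "CCCCCCCC") < -15
#' @export
duplex_energy <- function(a, b, params = duplex_parameters()) {
  xa <- rna_ints(a)
  yb <- rev(rna_ints(b))
  n <- length(xa); m <- length(yb)
  if (n < 2 || m < 2) return(0)
  PC <- pair_code_matrix()
  # pair-type matrix P[i, j]
  P <- matrix(0L, n, m)
  okx <- !is.na(xa); oky <- !is.na(yb)
  if (any(okx) && any(oky))
    P[okx, oky] <- PC[cbind(rep(xa[okx], sum(oky)),
                            rep(yb[oky], each = sum(okx)))]
  if (!any(P > 0)) return(0)
  S <- params$stack
  init <- params$init
  bo <- params$bulge_open; bn <- params$bulge_nt
  io <- params$interior_open; inn <- params$interior_nt
  jj <- seq_len(m)
  H <- matrix(Inf, n, m)
  # BA[j]: min over k <= i-2 of H[k, j] - bn*k   (bulge in a)
  # CI[j]: min over k <= i-2 of H[k, j] - inn*k  (interior, a side)
  BA <- rep(Inf, m); CI <- rep(Inf, m)
  best <- Inf
  for (i in seq_len(n)) {
    if (i >= 3) {
      BA <- pmin(BA, H[i - 2, ] - bn * (i - 2))
      CI <- pmin(CI, H[i - 2, ] - inn * (i - 2))
    }
    pi_row <- P[i, ]
    can <- pi_row > 0L
    if (!any(can)) next
    cand <- rep(init, m)           # open a new duplex at this pair
    if (i >= 2) {
      # stack on the immediately preceding pair
      prevP <- c(0L, P[i - 1, -m])
      prevH <- c(Inf, H[i - 1, -m])
      stackable <- can & prevP > 0L & is.finite(prevH)
      if (any(stackable)) {
        sval <- prevH[stackable] +
          S[cbind(prevP[stackable], pi_row[stackable])]
        cand[stackable] <- pmin(cand[stackable], sval)
      }
      # bulge in b: previous pair in row i-1, skipping l..j-2 of b
      cb <- cummin(H[i - 1, ] - bn * jj)
      jbig <- jj >= 3
      vb <- c(Inf, Inf, cb[seq_len(m - 2)])[jj] + bo + bn * (jj - 1)
      cand[jbig] <- pmin(cand[jbig], vb[jbig])
    }
    if (i >= 3) {
      # bulge in a: same b column j-1, skipping k..i-2 of a
      va <- c(Inf, BA[-m])[jj] + bo + bn * (i - 1)
      cand <- pmin(cand, va)
      # interior loop: skip on both sides
      di <- cummin(CI - inn * jj)
      vi <- c(Inf, Inf, di[seq_len(m - 2)])[jj] + io + inn * ((i - 1) + (jj - 1))
      cand <- pmin(cand, vi)
    }
    row <- rep(Inf, m)
    row[can] <- cand[can]
    H[i, ] <- row
    bi <- min(row)
    if (bi < best) best <- bi
  }
  min(0, best)
}
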