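---
title: "lncsalt: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncsalt: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lncsalt` reimplements, as a self-contained and fully testable pipeline, a
comparative lncRNA analysis of the kind performed on paired halophyte /
glycophyte tree species under salt stress: four tissues (leaf, phloem,
xylem, root), three NaCl doses (0, 150, 300 mM), three biological
replicates, two closely related species. The pipeline starts from what an
assembler emits — transcript models (GTF), spliced sequences (FASTA) and an
FPKM matrix — and ends with classified lncRNA catalogues, salt-response
calls, target predictions, cross-species comparisons and GO enrichment.
This vignette records the models, every tunable that matters, and the
decisions taken where the underlying protocol left the design open.

## 1. Identification: the filtering cascade

Assembled transcripts become lncRNA candidates by surviving, in order:

1. **Reference exclusion** — transcripts annotated `biotype = "coding"` in
   the reference are dropped.
2. **Expression filter** — keep transcripts with FPKM ≥ `min_fpkm`
   (default 1) in *at least one* library. The two natural readings of the
   published rule ("removed if below 1 in each sample" vs "kept if above 1
   in at least one") differ only at exactly FPKM = 1; the inclusive
   at-least-one reading is implemented.
3. **Length filter** — spliced (summed-exon) length ≥ `min_length_nt`
   (default 200, the definitional lncRNA minimum; inclusive).
4. **Coding-potential filter** — the original protocol used two external
   coding-potential programs and discarded transcripts scoring > 0 in
   either. Those programs are not redistributable inside a package, so a
   built-in scorer keeps the *sign convention* (score > 0 ⇒ coding ⇒
   discard): a transcript with a complete ORF ≥ `orf_coding_nt` (300 nt =
   100 codons, the classic heuristic) scores 1 outright; otherwise
   `score = w_orf·(orf_fraction − 0.5) + w_fickett·(fickett − 0.95)` with
   both weights defaulting to 1. `orf_fraction` is the longest ORF over
   the transcript length; `fickett` is the classic TESTCODE statistic
   computed from the published position/composition lookup tables, which
   ship with the package (`fickett_position_prob` etc.) so tests can walk
   them by hand. The ORF scan covers the three sense-strand frames only,
   because the emulated library protocol is strand-specific. Users who did
   run the external programs can pass their scores as a side table, which
   then overrides the built-in scorer verbatim.

The centre values 0.5 and 0.95 make the two soft terms vanish for a
transcript that is half ORF with a mid-range composition score; anything
clearly noncoding (short, broken ORFs; unskewed composition) lands well
below zero. A score of exactly 0 is retained — the discard rule is strict.

## 2. Positional classification

lncRNAs are classified against protein-coding gene models with a fixed
priority cascade: same-strand exon–exon overlap ⇒ *sense-overlapping*;
otherwise opposite-strand exon–exon overlap ⇒ *antisense* (lncNAT);
otherwise span wholly inside a single intron (either strand) ⇒ *intronic*;
otherwise *lincRNA*, with the gap to the nearest gene span recorded. The
priority order mirrors the class-code precedence of the standard
transcript-comparison tool; the underlying study does not state a
tie-break. "Intronic" deliberately admits either strand: same-strand
intron residents with exon overlap were already captured by rule 1.
Overlap queries run on GenomicRanges interval trees; the test suite checks
exact agreement with a brute-force all-pairs oracle, and the acceptance
suite repeats that check on 200 simulated features.

## 3. Salt response and tissue specificity

For every transcript, tissue, and ordered salt contrast (0 vs 150, 0 vs
300, 150 vs 300 mM), the pipeline computes the replicate-mean log2 fold
change `log2((mean_high + pc)/(mean_low + pc))` (pseudocount `pc = 0.01`)
and a two-sided location test on `log2(FPKM + pc)`. A transcript is
differential in a contrast iff |log2FC| ≥ 1 (inclusive) **and** p < 0.05
(strict), and *salt responsive* if differential in at least one
(tissue, contrast). Raw p-values feed the flag to mirror the published
rule; a Benjamini–Hochberg column is emitted alongside for users who want
it.

**Choice of test.** The protocol names no test. With three replicates per
group a replicate-aware location test is the minimal defensible choice.
The pooled-variance Student t (df = 4) is used rather than Welch: at
n = 3 per group the Welch–Satterthwaite approximation is markedly
conservative (empirical size ≈ 0.03 at nominal 0.05 in a 20,000-rep
simulation), whereas the pooled test is exact under the equal-variance
log-normal null — and the acceptance suite verifies calibration
(type-I error within 0.05 ± 0.01 over 10,000 null transcripts). When both
groups have zero variance the p-value is defined as 1 for equal means and
the smallest positive double otherwise.

**Tissue specificity** uses the standard tau index over n tissue means,
`tau = sum(1 − Exp_i/Exp_max)/(n − 1)`: 0 for perfectly uniform profiles,
1 for single-tissue expression. Which samples feed the tissue means is not
specified by the protocol; control (0 mM) samples are used by default
(`tau_salt_mM = 0`), configurable to all-sample means. Derived sets:
tissue-specific (tau > 0.9, strict), housekeeping (tau < 0.1 and not salt
responsive — condition-insensitive by definition), and tissue-specific DE
(salt responsive in exactly one tissue).

## 4. Target prediction

**cis** — every gene whose span overlaps or lies within `cis_window_bp`
(default 10 kb, inclusive; a gene at 10,001 bp does not pair) of a lncRNA
span. Distances are measured span-to-span (the protocol does not say
TSS-to-TSS; span-to-span is the weaker, safer reading), and
upstream/downstream is resolved relative to the lncRNA's strand. Intronic
lncRNAs always pair with their host gene (`intron_host`, distance 0). No
expression-correlation gate is applied at pairing time; concordance is
reported separately.

**trans** — two conjunctive gates in the published order. First an
alignment gate: Smith–Waterman of the lncRNA against the reverse
complement of each mRNA, requiring identity ≥ 0.95 and E-value < 1e-5.
The aligner is Biostrings' C implementation behind a stable contract
(affine gaps: a gap of length L costs `open + L·extend`; defaults +1/−2,
5/2); the E-value is Karlin–Altschul `K·m·n·exp(−λ·score)` with λ solved
exactly from the ungapped scoring distribution under uniform base
frequencies and K a documented stand-in constant (0.333) — downstream
logic relies only on E-values being monotone in score and linear in the
search space. Second, an energy gate: the duplex free energy of the pair
must be ≤ `duplex_energy_cut`. The published screen passed "−60" to an
external duplex program without stating units; −60 kcal/mol is therefore a
config default with this caveat documented, not a physical constant.

**The duplex energy model** is a deliberately reduced hybridization DP:
Watson–Crick plus GU wobble pairs; nearest-neighbour stacking free
energies (standard Watson–Crick values, kcal/mol at 37°C, with a uniform
mild value for wobble-containing stacks); linear penalties for bulges
(3.8 + 0.5/nt) and interior loops (2.6 + 0.5/nt); one duplex-initiation
term (+4.09); no dangling ends, no intramolecular structure. It is a
stand-in for a full duplex folder and is validated against its own
brute-force enumeration oracle (exhaustive over all pairings for ≤ 8-nt
inputs), *not* against external programs. One property deserves a note:
the specification of this artifact expected energies invariant under
reversing both sequences, but with physically correct stacking tables
that identity is false (it would force the AU/UA and UA/AU stacks to be
equal; published values differ). The symmetry the model does satisfy — and
the tests assert — is strand exchange, `E(a,b) = E(b,a)`.

## 5. Cross-species comparison

Homologs are reciprocal best hits between the two species' lncRNA
sequence sets (sense strand — these are transcripts), gated at
E-value < 1e-5; the published description ("BLAST results of individual
lncRNAs to themselves") is ambiguous, and RBH is the standard
operationalization. The all-vs-all search is seeded the way word-based
aligners are: only pairs sharing ≥ 3 exact 12-mers get a full alignment.
At word size 12, chance sharing between unrelated ~1-kb transcripts is
negligible while 2%-diverged copies share hundreds of words, so seeding
changes nothing about which pairs can pass the gate — it only makes the
search tractable. A reciprocal best hit must additionally rest on an
alignment spanning at least 50 nt: Karlin–Altschul E-values are
asymptotic, and a bare ~20-nt exact word between kilobase transcripts can
reach E < 1e-5 by chance without being homology evidence, so a minimum
span is the standard RBH guard (true homolog pairs here align over
hundreds of nucleotides).

Homolog expression concordance is the Spearman correlation over the four
control-condition tissue means, with "similar pattern" meaning rho > 0.9
(strict). FPKM is compared across species without further normalization
(the emulated protocol applies none; rank-based rho is insensitive to
scale). "Highly expressed in A" pairs require the A member's
control-condition tissue mean to exceed `fc` (default 4) times the B
member's, per tissue, strictly; whether the published "FC > 4" used
control or stressed samples is unstated, so control means are the default
and configurable. Species-specific salt-responsive sets are the unpaired
ids with at least one DE call, with a per-tissue breakdown.

## 6. GO enrichment

Hypergeometric upper-tail over-representation per term, computed in log
space (`lchoose` + log-sum-exp); the background defaults to all annotated
protein-coding genes of the species. Whether the published 0.05 cutoff was
raw or adjusted is unstated: raw p < 0.05 drives the `enriched` flag (to
mirror the publication) and a BH-adjusted column is always emitted.
Annotation arrives as a plain gene→term table; no ontology-graph
propagation is performed.

## 7. The synthetic world

The generator emits what the real pipeline would consume, with known
truth: a single chromosome carrying three-exon coding genes (≥ 25 kb
apart, planted ORFs ≥ 140 codons), and per class unambiguous lncRNAs —
lincRNAs alternating between near (2–8 kb, exercising cis calls) and far
(> 10 kb) placements, intron residents, antisense and sense-overlapping
transcripts. lncRNA sequences are 200–2000 nt with every ORF broken below
60 codons *and* below 35% of the transcript length; the second cap is a
design choice that keeps the coding score decisively negative for short
transcripts (a 200-nt transcript carrying a 180-nt ORF would otherwise sit
near the decision boundary). A deterministic count of far lincRNAs
carries an embedded 150-nt reverse-complement window of its host gene's
3' UTR, planting trans pairs.

Expression is log-normal: one truncated-Gaussian log2 baseline per
transcript (lncRNAs centred lower than mRNAs, matching the observation
that lncRNAs are more weakly expressed), Gaussian replicate noise on the
log2 scale (`noise_sd`, default 0.2), planted differential effects of ±1
log2 units at 150 mM and ±2 at 300 mM in one assigned tissue
(dose-dependent, tissue-restricted — the pattern the real data show), and
tissue-specific transcripts silenced to ~0.02 FPKM off-tissue. Planted
roles (differential / tissue-specific / housekeeping) are disjoint.

The sister species reuses the base layout verbatim (syntenic order), with
all coding genes and a configurable fraction of lncRNAs carried over as
point-mutated copies (identity ≈ 1 − divergence) and the remaining
lncRNAs replaced by fresh random sequences. Shared lncRNAs inherit their
expression roles and baselines — including the null role, so a lncRNA flat
in A cannot be spuriously silenced in B — and a chosen fraction of shared
pairs is planted "highly expressed in A" by shifting the B baseline down
by log2(fold).

**What the generator does not emulate** — and hence what a green test does
not establish: read-level sampling noise and length-dependent FPKM
variance; multi-isoform loci and assembly artifacts; indels and
rearrangements (divergence is substitution-only); GC-content biases;
ontology structure. Tests against this world establish the *internal
correctness* of each stage (filters, geometry, statistics, search) and
calibrated error rates under a plausible noise model, not concordance with
any particular real dataset.

## 8. Numerical and determinism notes

All thresholds live in one validated configuration object whose hash is
written into every output table. Boundary semantics follow the published
wording wherever it is explicit: FC cut inclusive, p cut strict, tau cuts
strict, cis window inclusive, identity gate inclusive, E-value gate
strict, high-expression fold strict. Ties in classification and homolog
search break lexicographically so runs are reproducible; the pipeline is a
pure function of (inputs, config) and repeated runs are byte-identical.
All randomness flows from the single `seed` field; the generator derives
sub-seeds from it. Degenerate inputs are errors, not guesses: all-zero
tau profiles are excluded with a warning, both-zero fold changes without a
pseudocount raise, infeasible hypergeometric counts raise, and missing
expression rows name the transcript.

## 9. Known limitations

The coding-potential scorer is a two-feature stand-in — adequate for the
clearly separated synthetic world and for the sign-convention contract,
but not a replacement for modern classifiers on borderline real
transcripts. The duplex model omits dangling ends, terminal AU penalties
and accessibility, so its absolute energies are not comparable with
published duplex folders; only its ordering is meaningful, and the −60
cutoff should be recalibrated if the model changes. The Karlin–Altschul K
is a constant, so absolute E-values are order-of-magnitude. Cross-species
FPKM comparison assumes comparable library normalization between species.
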