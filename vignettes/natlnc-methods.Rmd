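---
title: "Methods: lncRNA identification, NAT classification, and neighbor co-expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA identification, NAT classification, and neighbor co-expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
decision rules, the tunable parameters and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and the
numerical and design choices made where the problem left them open.

# The identification cascade

The cascade turns an assembled transcriptome (GTF with per-transcript
assembler class codes) into an annotated lncRNA set in four stages, each a
partition of its input with a per-transcript removal reason:

1. **Class codes.** Only `u` (intergenic), `x` (antisense exonic overlap)
   and `i` (sense-intronic) transcripts are retained. Unknown codes are
   preserved verbatim and treated as "not u/x/i", i.e. removed; the
   retained vocabulary is a closed list, everything else is by definition
   already explained by the reference.
2. **Length and abundance.** Removal when exonic length < 150 nt *or*
   FPKM_max < 1, both strict, so a 150-nt transcript and an FPKM_max of
   exactly 1.0 survive. FPKM_max is the maximum over *all* samples —
   a transcript expressed anywhere is kept. Transcripts absent from the
   expression matrix have no defined FPKM_max and are removed with their
   own reason code (`absent_from_expression`) rather than silently treated
   as zero.
3. **Coding potential.** A transcript is coding if it has a qualifying
   homology hit *or* a positive signed coding-potential score.
   Hit criteria are inclusive (≥ 40 aa, ≥ 35 % identity,
   coverage ≥ 35 %) with a strict e-value gate (< 1e-4). "Coverage of the
   alignment region in either query or subject" is read literally as
   `max(query_cov, subject_cov) ≥ 35`. The score contract is sign-only:
   positive ⇒ coding, with `> 0` strict, so a score of exactly zero is
   non-coding. External coding-potential calculators can be plugged in via
   `scorer =`; the built-in default is
   `score = (orf_max_aa/100 − 1) + (orf_coverage/0.5 − 1)`,
   a monotone function of the longest-ORF length and its fractional
   coverage of the transcript (stop codon included). It is calibrated only
   at its sign: any transcript whose longest ORF is under 100 aa *and*
   covers less than half the transcript is negative; a transcript that is
   essentially one long ORF is strongly positive. No attempt is made to
   reproduce the absolute values of any external tool.
4. **Sense overlap.** Transcripts whose span overlaps a coding-gene span
   by ≥ 1 bp on the same strand are removed — *except* transcripts fully
   contained within a single intron of that gene. The exemption is
   deliberate: stage 1 explicitly retains sense-intronic (`i`)
   transcripts, which by definition lie inside a gene span; removing all
   same-strand span overlap would contradict that retention and empty the
   incRNA class. An intron-contained transcript has no exonic sense
   overlap, which is what this stage is meant to police. A transcript that
   merely brushes a gene edge (even by 1 bp) is never intron-contained and
   is removed.

ORF scanning covers the three forward frames of the already-stranded
transcript sequence (`ATG` to the next in-frame stop, length in aa
excluding the stop, `N` never matches). Whether antisense transcripts
should additionally be scanned on the reverse complement is left out by
design: the transcript's own strand is the transcribed product.

# NAT classification

Each lncRNA is classified against the coding annotation by a strict
priority order: **overlapping NAT** (≥ 1 bp antisense span overlap) >
**incRNA** (entirely inside a same-strand intron) > **divergent NAT**
(head-to-head: both 5′ ends flank the gap) > **convergent NAT**
(tail-to-tail) > **lincRNA**. Physical overlap is stronger evidence than
any proximity relation, and a total order is required for disjoint class
counts. Ties among candidate partners break by smallest gap, then smallest
`gene_id` lexicographically — deterministic and implementation-neutral.

Decisions taken where the taxonomy was open:

* **Pairing window.** Divergent/convergent pairing needs a distance
  cutoff to be decidable; `window_bp = 1000` (promoter-proximal scale) is
  the default and is configurable. Membership of the divergent+convergent
  classes is monotone in the window.
* **Span vs exon overlap.** Overlapping-NAT status is decided on genomic
  spans; exon-level overlap is recorded as a flag (`exonic_overlap`)
  rather than required, because intron-only antisense transcripts are
  still physically antisense.
* **incRNA reporting.** `fold_incrna_into = "keep"` reports incRNA as its
  own class; `"lincRNA"` and `"drop"` fold or discard it for taxonomies
  that only recognise NATs and lincRNAs.
* **Strand-flip symmetry.** A global strand flip reverses every
  transcription arrow, so it preserves overlapping/incRNA/lincRNA labels
  while exchanging divergent and convergent — head-to-head geometry
  becomes tail-to-tail. The property suite asserts exactly this invariant.

The production classifier is vectorised; `brute_force_classify()` is a
deliberately index-free scalar re-implementation of the same contract, and
the test suite requires exact record-level agreement between the two on
thousands of random planted lncRNAs and on adversarial nested-gene
fixtures.

# Expression statistics

Two-group calls use a Welch t-test on `log2(FPKM + eps)` with `eps = 1`
pseudo-FPKM, and a fold-change computed on pseudo-count-stabilised means,
`log2fc = log2((mean_a + eps)/(mean_b + eps))`. A feature is called
enriched only when *P* < 0.05 *and* fold-change ≥ 2 on the called side;
both gates are sharp: fold-change 1.99 with any p-value is `ns`.
The pseudo-count keeps zero-FPKM features finite; it attenuates
fold-changes of very lowly expressed features, which is the standard
trade-off. p-values are raw by default — the calling criterion is a plain
*P* < 0.05 — with an optional Benjamini–Hochberg flag (`fdr = TRUE`) for
users who want FDR control.

Two numerical notes. First, degenerate rows (zero variance in both groups)
get *p* = 1 when the means agree and *p* = 0 otherwise, rather than NaN.
Second, the Welch test at 3 replicates per group is conservative: with
Welch–Satterthwaite df estimated from n = 3 + 3, the true size at
α = 0.05 is ≈ 0.035 rather than 0.050 (directly verifiable by simulating
iid normal groups). The calibration property in the test suite measures
the realised false-positive rate on 2000 planted-null features and it sits
at the conservative end of the nominal band; the test never becomes
anticonservative.

Heatmap ordering scales each row to fractional density (row / row max) and
runs `stats::kmeans` with 10 random restarts under a mandatory seed,
keeping the restart with the best total within-cluster sum of squares.
Clusters are ordered by the center of mass of their centroid profile and
features within a cluster by their own center of mass, so the display
order is a pure function of (matrix, k, seed).

# Neighbor pairs and co-expression

Pairs come in seven categories: coding–coding overlapped / divergent /
convergent (CCO/CCD/CCC, immediately adjacent genes typed by the same
geometry rules as the NAT classes), NAT–gene pairs (NCO/NCD/NCC, taken
directly from the classification partner), and lincRNA–closest-gene (LC)
pairs. "Closest" is span-gap distance (0 if touching), ties again by
smaller `gene_id`; coding–coding pairing is restricted to immediate
neighbors in coordinate order rather than all pairs within a window.

Correlation is Pearson's r between the two FPKM profiles. Coding members
are quantified at gene level (isoform FPKM summed — the standard
gene-level convention), lncRNAs at transcript level. By default all
samples enter; the pipeline restricts to the condition-profiling samples
(fraction label `"total"`) so that the two-fraction assay does not dilute
the condition signal. Exclusions are explicit and partition-preserving:
pairs with a member at FPKM_max < 1 (strict) are excluded as
low-abundance, and pairs with a constant member are excluded as undefined
rather than scored 0, which would distort category distributions.

Category comparisons use a one-tailed Mann–Whitney *U* test of
"category A stochastically greater than category B". For group sizes ≤ 8
the p-value is exhaustive enumeration over all C(n₁+n₂, n₁) assignments of
the pooled values — exact under ties, observed assignment included — and
otherwise a normal approximation with tie correction and a 0.5 continuity
correction. The enumeration path is the package's own because the exact
small-sample contract (ties included) is part of the interface; the test
suite cross-checks both paths against `stats::wilcox.test` where the two
definitions coincide. The concordant set applies a strict `pcc > 0.6` to
one pair category (NCO by default).

# sRNA checks

Region abundance is RPM = reads / total mapped × 10⁶, linear in read
count. Secondary-siRNA detection asks whether the transcript carries
appreciable sRNA signal *outside* the amiRNA target site ± 50 bp flank;
the detection threshold defaults to 1 RPM, a deliberately permissive
presence/absence rule — the claim it supports is "no reads beyond the
site", not a phasing analysis. amiRNA\* specificity takes the best
ungapped antisense alignment of the star strand in the sense mRNA
(Watson–Crick matches; G:U wobble only when `allow_gu = TRUE`), reports
mismatch positions from the star 5′ end, flags mismatches in the
cleavage-critical window (positions 9–11 by default — the canonical
small-RNA cleavage geometry; configurable because the biologically
critical window is a modeling choice), and records whether the star
begins with the 5′ uridine that favors effector loading.

# The synthetic-data generator

The generator is the package's ground truth. It lays units (a coding gene
with or without a planted partner lncRNA, a coding–coding pair, a lincRNA,
a decoy) left to right on one chromosome with an inter-unit clearance of
`window + margin + 100` bp. Margins guarantee unambiguous geometry: planted
divergent/convergent gaps are at least `class_margin_bp` inside the
pairing window, planted lincRNAs at least `window + margin` away from
every gene, so no classification decision rides on a boundary tie.
Placement is rejection-free and deterministic given the seed; infeasible
configurations (chromosome too short) fail loudly.

Expression follows a log-normal model: per-feature baseline
log2 FPKM ~ N(4, 1), additive condition effects of sd 1 log2 unit shared
within replicates, replicate noise of sd 0.2 log2 units, and a fraction
effect of ±`enrichment_log2fc`/2 for planted enriched features. The
planted pair correlation is specified *on the FPKM scale* — the scale on
which the pipeline computes p.c.c. — by inverting the bivariate log-normal
correlation formula to obtain the latent condition-effect correlation;
naive latent planting would be attenuated by the exponential transform
(for variance ~1 log2 unit², a latent 0.8 measures near 0.7). With
`rho = 1` and zero noise the pair profiles are exactly proportional and
the sample correlation is exactly 1. Targets unreachable in the presence
of replicate noise (rho near 1 with noise > 0) are capped at the latent
maximum.

Sequences are generated to make the coding filter decidable by
construction: coding genes and decoys carry an ORF covering ~80 % of the
transcript, while planted lncRNAs are `ATG`-free in every frame (so the
ORF scanner provably returns zero). Homology hits follow the same logic —
decoys get one hit passing all criteria, lncRNAs get either nothing or a
hit failing exactly one criterion.

What the generator does **not** emulate: read-level noise or alignment
artifacts (inputs are finished annotations and FPKM tables), isoform
diversity beyond 1–2 exons per lncRNA, overdispersed count noise (the
noise is log-normal, not NB), chained correlation structure among
overlapping neighbor pairs (each feature belongs to at most one planted
pair; with `rho_other > 0` shared members would make planting
approximate), genome-scale gene density, or any chromatin-level signal.
Passing the recovery tests therefore demonstrates the correctness of the
decision rules and statistics under their stated assumptions — not
robustness to assembler errors or biological confounders in real data.

# Problem sizes and determinism

The shipped analyses and tests use desk-scale configurations chosen once:
the standard study (50 coding genes, 10 lncRNAs per class, 10 decoys,
5 coding–coding pairs per geometry, 9 conditions × 3 replicates), a
2000-feature null study for calibration, a 30-feature planted-effect study
for power, a 150-pair study (50 NCO + 50 per CC geometry) for the
concordance comparison, and 3 × 1000 random lncRNAs for oracle
equivalence. All randomness flows through explicit seeds; re-running any
stage with the same configuration is bit-identical, which the test suite
asserts on file checksums.

# Known limitations

* The built-in coding-potential scorer is a sign-contract stand-in, not a
  trained classifier; transcripts with unusual ORF structure (long ORF,
  tiny coverage) sit near its zero crossing.
* The Welch-based enrichment caller is conservative at 2–3 replicates (see
  above) and tests FPKM, not counts; there is no dispersion moderation.
* Classification is single-isoform: each transcript is classified
  independently, and isoform-level disagreement within a gene is resolved
  only by the documented priority rule.
* Mann–Whitney enumeration is exponential in group size and is capped at
  n ≤ 8 per group by design.
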