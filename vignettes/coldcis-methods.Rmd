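---
title: "Methods behind the coldcis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the coldcis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

coldcis turns a multi-tissue, multi-temperature RNA-seq count matrix into a
set of candidate cold-responsive *cis*-regulatory elements and a
transcription-factor interaction network.  This vignette records the models,
the tunable parameters, and the design decisions that were genuinely open —
in enough detail that a maintainer can judge every numerical choice.

## The experimental design the package assumes

The pipeline addresses a pooled, replicate-free design: eight tissues, each
sequenced once at a control temperature (28 °C) and at two cold treatments
(18 °C and 10 °C), giving 24 libraries and, per tissue, three pairwise
comparisons (28v18, 18v10, 28v10).  All statistics downstream are chosen to
work with exactly one library per condition; nothing in the package models
biological replicates.

## Differential expression without replicates

Counts are normalised as RPKM: `count / (gene length in kb × library total
in millions)`, with library totals recomputed after the low-count filter.
A gene enters a pairwise comparison if it has ≥ 5 reads in at least one of
the two libraries compared (the filter's placement is ambiguous in
replicate-free designs; per-comparison filtering retains a gene exactly
where it is testable, and a gene survives overall if it survives anywhere).

The test for one gene between two libraries is Fisher's exact test on the
2×2 table `[[a, A−a], [b, B−b]]` — the gene's reads against the rest of each
library.  The two-sided P is the sum of all table probabilities not
exceeding the observed one, the same convention as `stats::fisher.test`
(verified against it in the tests; the implementation is a vectorised
hypergeometric-support summation).  The test is two-sided because genes are
called in both directions.  Benjamini–Hochberg adjustment is applied within
each (tissue, comparison) family, since results are reported per tissue and
pair.

Two tiers are kept, both with *strict* inequalities exactly as printed in
the thresholds they come from: **loose** requires a pseudocounted RPKM fold
change > 2; **strict** additionally requires adjusted P < 0.001.  A
pseudocount of 1 RPKM (configurable) bounds fold changes when a count is
zero.  The strict union — genes strict in at least one comparison — is the
compact DEG set used for clustering; the loose union's complement among
expressed genes is the negative set for motif discovery.  The published
negative-set description ("< 2-fold in any one of the three comparisons")
is ambiguous between *any* and *every*; we require < 2-fold in **every**
comparison, because the published negative-set size (20 474) is close to
expressed genes minus DEGs, not to a union of per-comparison stable sets.

A caveat stated plainly: with only counting noise this test is exact, but
any extra-Poisson variation between conditions is attributed to the
treatment.  Overdispersion therefore inflates calls — this is a property of
the replicate-free design itself, and the reason the synthetic generator's
calibration experiments run in the near-Poisson regime (below).

## Expression profiles and MDS

Profiles are `log2((rpkm_cold + 1) / (rpkm_28 + 1))` over the 16
(tissue, cold temperature) conditions, rows restricted to the strict DEG
union.  Sample-level structure is summarised by classical (Torgerson) MDS:
Euclidean distances on log2(RPKM + 1) with each tissue's 28 °C column
subtracted (all controls map to the origin, so distance means cold
response), double-centering, top-k eigenvectors scaled by √eigenvalue.
Each axis is reflected so its largest-magnitude loading is positive, making
embeddings reproducible; planar configurations are recovered to 1e-9.

## Fuzzy k-means with correlation memberships

Distance between a gene profile and a centroid is `1 − r` (Pearson).  Raw
membership is `max(r, 0)²`, row-normalised; centroids are
membership-weighted means.  The squared-positive-correlation form follows
the fuzzy-clustering tradition for expression data: it gives smooth,
scale-free memberships and zeroes out anti-correlated clusters.  Genes with
constant profiles have no defined correlation and are excluded with a
warning.  If a gene correlates positively with no centroid, its membership
is set uniform — it will sit below any sensible assignment cutoff.

Initialisation is farthest-point seeding on correlation distance from a
seeded RNG, applied after sorting genes by id, so the result depends on the
seed but not on input row order.  Iteration stops when no centroid moves
more than 1e-4, or after 200 sweeps; empty centroids (total membership
< 1e-6) are dropped.  The membership-weighted objective is checked to be
non-increasing in the tests.

An intentionally generous k (default 60) is then collapsed by merging:
while any centroid pair correlates above 0.9 (configurable), the pair is
replaced by its membership-weighted mean, and memberships are recomputed at
the end.  Both routes from "many seeds" to "few patterns" — emptying and
merging — are therefore active.  Assignment uses a strict membership cutoff
(> 0.12 by default, with 0.4 as the tight variant); a gene may be assigned
to several clusters, or none.  Memberships are normalised over the final
merged centroids; with C clusters the uniform level is 1/C, and the default
cutoff sits a factor of ~4–5 above it for typical C ≈ 30–40.

## Length-aware GO enrichment

Long genes collect more reads, hence more DE calls at fixed thresholds.
The probability weighting function (PWF) captures P(DE | length): the DE
indicator is smoothed by a 200-gene moving average along the length
ranking (constant-width windows, shifted inward at the extremes so
variance stays uniform), then isotonic (monotone non-decreasing)
regression is applied to the smoothed rate, floored at 1e-6 and rescaled
to mean 1.  Smoothing before isotonizing matters: isotonic regression of
the raw 0/1 indicator lets a handful of extreme-length genes set the
monotone fit's edge blocks, which distorts the weights precisely when DE
status is independent of length and the function should be flat.
Moving-average-then-isotonic was chosen over a monotone spline because it
has the same contract — a monotone P(DE | length) — and is directly
verifiable.

Enrichment of a term in a cluster is tested against the Wallenius
noncentral hypergeometric distribution: drawing the cluster from the
expressed background, with category genes given odds equal to the mean PWF
weight inside the category over the mean weight outside.  The density is
integrated numerically in log space (the integrand is shifted by its mode,
so urns far beyond double-precision binomials remain computable); at
odds = 1 the tail reproduces the central hypergeometric to 1e-8, and at
odds ≠ 1 it matches a 1e5-draw biased-urn sampler within Monte-Carlo error.
BH adjustment runs across terms within each cluster (enrichment is
reported per cluster), flagged at FDR < 0.05.  Annotations are taken as
given — no GO-graph propagation is performed, so inputs should be
pre-propagated if ancestor credit is wanted.

## Discriminative motif discovery

Positive sets are cluster promoters (1 kb upstream of the TSS,
strand-aware, truncated at contig ends) at each membership cutoff; the
negative set is the stable-gene promoters.  Containment is per sequence,
not per occurrence: a promoter either bears a match (on either strand, by
default) or it does not.  Letters outside A/C/G/T — including the N used
for masking — match no IUPAC code.  The enrichment statistic for a word is
the one-sided Fisher exact P (hypergeometric upper tail) on containment
counts, positives versus negatives.

The search is seed-and-generalize, fully deterministic (ties broken
lexicographically; a word and its reverse complement are one canonical
candidate).  Each round:

1. every exact word of length 3–8 present in ≥ 2 positive promoters is
   scored (singletons cannot be meaningfully enriched);
2. the best `beam` seeds are generalized by hill climbing, where a step
   replaces one position's code by a *wider* ambiguity code (a strict
   superset of its base set, N excluded) and the single best
   strictly-P-improving step is accepted;
3. the best motif's E-value is its P times the size of the round's
   candidate space — all exact seeds scored plus the whole generalization
   space of every climbed seed (7^len − 1 words each);
4. below E < 0.05 the motif is reported, its matches are masked to N in
   both sets, and the search repeats (up to `max_motifs`).

Two choices here deserve their rationale.  *Generalization-only moves*:
allowing arbitrary single-position substitutions turns the climb into an
unbounded local search that can drift far from its seed and overfit the
split — on seed-split null data it manufactures words at 6+ SD imbalance.
Restricting moves to supersets keeps the search inside each seed's
generalization cone.  *The E multiplier counts the reachable space, not the
words actually scored*: a greedy climb is a selection over everything it
could have chosen, not just what it evaluated, and correcting only for
scored words is demonstrably anti-conservative under the null.  The
resulting E-value is a Bonferroni bound over the search's entire decision
space; with it, seed-split null promoter sets (200 vs 2000 × 1 kb) stay
clean of E < 0.05 calls in ≈ 95 % of runs while a 7-mer planted in 30 % of
positives against a 5 % background is recovered in ≥ 90 %.  Because the
multiplier grows linearly in the beam, the default beam is 10: for
discriminative signals the planted word essentially always ranks first
among seeds, so wide beams buy little power and tax significance (and
cost proportionally more time).

## Matching discovered motifs to known databases

Database PFMs (MEME minimal or JASPAR text) are reduced to IUPAC consensi
by keeping every base at frequency ≥ 0.25 per column.  Similarity is the
*consensus distance*: over all ungapped offsets with overlap ≥ min(len) − 1
and both strands, the minimum number of overlapping positions with
disjoint base sets.  A match must have fewer than 2 mismatching positions
and an empirical P < 5e-3, where P is the fraction of shuffles of the
query's own codes that do as well against the same target (add-one
corrected so it is never zero).  Everything else is reported as Novel.

Two consequences are worth knowing.  Wide ambiguity codes make chance
similarity more likely, so heavily generalized consensi can fail the
empirical P even at distance 0 — the filter is honest about how surprising
the similarity actually is.  And near-palindromic AP-1-like words partially
match their own shuffles, so even an identical query can sit near the
cutoff.  Both behaviours are deliberate: the alternative (always retaining
distance-0 matches) would silently over-annotate.

## The network stage

Nodes are the TFs mapped from annotated motifs plus their motif-bearing
genes.  Interaction edges (typed physical / colocalization / genetic) come
from an input edge list — the package performs no interaction inference —
restricted to pairs inside the node set, deduplicated per type, with
self-loops dropped.  Motif-implied TF→target binding edges are kept
separate, and TF connectivity counts interaction edges only by default
(`include_binding = TRUE` adds them), so both numbers are available rather
than guessed.

## The synthetic-data generator

The generator emulates the study's *structure*, not its biology: pooled
single libraries over 8 tissues × {28, 18, 10} °C; cluster-structured log2
fold-change patterns over the 16 cold conditions; 1-kb i.i.d. promoters at
40 % GC with IUPAC motifs planted at configured in-cluster and background
frequencies (ambiguity codes resolved uniformly, or deterministically for
exact tests); GO terms of set sizes with optional length bias (sampling
weight ∝ length-rank²) and planted cluster overlap; a motif database of
the planted consensi plus decoys at consensus distance ≥ 3; and typed
interaction edges with planted TF degrees.  Counts are negative binomial
(variance μ + φμ²) with expected counts proportional to gene length ×
expression, so RPKM cancels length by construction; expected column sums
equal the configured library size.

Defaults and why:

* **dispersion φ = 0.02.**  With independent per-library noise at φ = 0.1,
  the log2 ratio of two stable-gene libraries has SD ≈ 0.65 and ~95 % of
  stable genes cross 2-fold somewhere among 24 comparisons — the
  replicate-free workflow would call nearly everything.  The study's own
  outcome (~9 % of genes) implies far less between-condition variation;
  φ = 0.02 reproduces that regime (≈ 1–2 % false loose calls).
* **Patterns are condition-structured** (severe-cold up, severe-cold down,
  two-tissue up) rather than flat across all 16 conditions: a flat pattern
  is a constant profile, invisible to correlation-based clustering.
* **i.i.d. background sequence.**  No higher-order Markov structure; real
  promoters have composition the i.i.d. model lacks (CpG islands,
  repeats), so null calibration on synthetic data is necessary, not
  sufficient, evidence about real promoters.
* **One library per condition, no replicates** — the design under study.

Scales used by the test-suite experiments (chosen once, as desk-scale
stand-ins for the study): motif recovery and null control at 200/2000
promoters × 1 kb; clustering recovery on 3 × 100 genes × 16 conditions at
noise SD 0.2; DEG recovery with 150 genes planted at |log2fc| = 2.5 in a
6000-gene transcriptome with 2e6-read libraries at φ = 0.001; GO recovery
with a 50-gene term overlapping a 100-gene cluster 4× above expectation in
a 1000-gene background; the generator's own planted-ratio check uses 50
genes at +2 in a 3000-gene Poisson transcriptome at 5e6 reads, since its
±0.18-log2 acceptance band verifies the planting arithmetic, not noise
robustness.  The DEG conditions reflect two structural facts:
planted genes inflate cold library totals (a composition effect that
shifts every stable gene by log2 of the mass change, so the planted share
must be small), and precision degrades with overdispersion that the exact
test does not model, so the caller-correctness experiment belongs in the
near-Poisson regime.  Null-calibration runs use φ = 0 for the same reason.

## Numerical and policy details

* Pseudocount 1 RPKM in every ratio; configurable.
* All published thresholds are strict inequalities as printed: fold > 2,
  adjusted P < 0.001, membership > 0.12 / 0.4, E < 0.05, FDR < 0.05,
  database match P < 5e-3, mismatches < 2.
* Fuzzy k-means: convergence at max centroid movement < 1e-4, ≤ 200
  iterations; merge threshold r > 0.9.
* Ties everywhere break lexicographically (motif search) or toward the
  smallest index (farthest-point seeding), so identical inputs give
  byte-identical outputs.
* The pipeline fans one global seed out to stages by fixed offsets; a run
  directory contains its resolved configuration and is reproducible from
  it byte-for-byte (generated inputs included).

## Known limitations

* The Fisher DEG test treats all extra-Poisson variation as signal; with
  real (overdispersed) data the strict tier is anti-conservative.  This is
  inherent to the replicate-free design, not fixable in-package.
* The i.i.d. promoter background understates real-sequence null rates for
  motif discovery.
* Database matching by consensus distance discards within-column
  frequency information a full PFM alignment would use; its empirical
  null is conservative for degenerate queries.
* The study-scale headline numbers (1943 DEGs, 34 clusters, 17 motifs, 31
  GO terms, a 61-edge network) require the original sequencing data and
  external databases; desk-scale synthetic runs report their own counts
  and the tests assert recovery of planted structure, never those totals.
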