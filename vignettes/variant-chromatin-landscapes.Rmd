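---
title: "Quantifying histone-variant nucleosomes and directional regulatory regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying histone-variant nucleosomes and directional regulatory regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(variantscape)
```

# Scope and model

Nucleosomes carry two copies of each core histone, and the non-canonical
variants H3.3, H2A.Z and macroH2A can replace their canonical
counterparts in one or both slots of a family's slot pair. A nucleosome
with one variant copy and one canonical copy is *heterotypic*; with two
variant copies, *homotypic*. This package quantifies that composition
from bottom-up MS of purified mononucleosomes, and then asks what the
same variants look like genome-wide at promoter-distal regulatory
regions: which combinations co-occur, whether their occupancy profiles
are symmetric or skewed around the regulatory site, and whether the skew
lines up with RNA polymerase II and with the strand bias of nascent
enhancer transcription.

# The ChIP-MS arm

## Quantification model

All quantities are ratios of peptide intensities, so they are invariant
to the overall intensity scale of a sample (asserted in the tests).

*PTM relative abundance.* A peptide family is the set of all modified and
unmodified forms sharing one backbone `(sample, histone, span,
sequence)`. The abundance of a mark is the summed intensity of the forms
carrying it divided by the family total; every backbone family covering
the marked residue is pooled (for H3K27me3 that is both 27–40 variant
peptides, so the figure is "fraction of total H3"). Combinatorial queries
(`"H4:K5acK8ac"`) match one exact form instead.

*Variant stoichiometry.* Four reference peptides derived from canonical
H2A (4–11, 12–17, 21–29, 82–88) track the total H2A-family amount. Each
variant-specific peptide total is divided by each reference, giving four
ratios per variant; the summary is their arithmetic mean (the per-reference
ratios are kept for QC, and the mean can be swapped for a median without
changing any noise-free result). The three summaries are renormalized to
sum to one. Renormalization removes the common scale left by
ratio-to-reference and expresses each variant as its share of H2A-family
copies. The H3 family uses the direct 27–40 peptide pair instead; H3.1 and
H3.2 share every tryptic peptide and are reported merged as canonical H3.

Two modeling commitments deserve justification:

* *References are family-shared.* The reference peptides are treated as
  reporting canonical + H2A.Z + macroH2A copies together. A separate
  canonical-specific peptide (`KGNYAER`, 36–42) exists precisely because
  the references are not canonical-specific; under this reading a fully
  heterotypic pool quantifies to exactly 50% canonical, which matches the
  expected arithmetic of one-variant-one-canonical nucleosomes.
* *No ionization-response correction.* Peptides ionize with different
  efficiencies; the quantifier applies no correction, as is standard for
  histone ratio work with propionylation. The generator exposes
  `response_factors` so the induced bias can be demonstrated: with
  non-unit factors the recovered fractions shift by exactly the factor
  ratios, which is the uncorrectable part of the method.

`log2_enrichment` compares IP against input abundances with a pseudocount
(default 1e-4 absolute fraction, recorded in the output); equal
abundances give exactly 0 for any pseudocount.

## The peptide forward model

`generate_peptide_table` computes expected intensities (copies x response
factor), splits each family across modified forms deterministically by
the per-site mark fractions (independent sites, so co-modified forms get
the product of marginals), and multiplies mean-preserving log-normal
noise with the requested CV. The deterministic split is what makes
noise-free tables invert exactly (< 1e-9) under the quantifiers — the
round-trip the test suite asserts. What this does *not* emulate: missed
cleavages, isotope interference, retention-time drift, site-specific
ionization shifts within a family. Passing tests therefore certify the
quantification arithmetic, not robustness to those instrument effects.

At the noise level used for the recovery suite (CV 0.1, 1e4 nucleosomes,
100 seeds) each recovered quantity lands within 0.05 of truth in at least
95% of replicates; the error is dominated by the variant-peptide noise
because the shared reference denominators cancel in the renormalized
fractions.

# The ChIP-seq arm

## Anchors and profiles

Coordinates are 0-based half-open throughout (BED convention). Signal is
binned coverage (default 100 bp); RPKM normalization is
`count x 1e9 / (bin_width x library_size)` times a global display
constant (default 1; 10 reproduces tracks scaled to 10-RPKM units).
Every downstream statistic — correlation clustering, asymmetry,
orientations, strand bias, rank tests — is invariant to that constant,
which the suite tests explicitly.

Distal anchors are DHS intervals whose midpoint lies more than 2 kb from
every annotated TSS and TTS (mRNA and lncRNA) and whose interval overlaps
no gene body by even one bp — the stricter any-overlap reading, chosen
because a DHS partially inside a gene body is not credibly intergenic.
Profile matrices cover ±2 kb in 100-bp bins by default; the window is
configurable because published heat maps of this kind rarely state their
exact flank.

## Clustering, mirror pairs, orientation

Anchors are clustered on the concatenation of their four variant
profiles with Lloyd-style K-means under `d = 1 − |r|` (Pearson
correlation; plain `1 − r` by flag). Correlation distance is
scale-free per row, so rows are not standardized. The implementation is
in-package because Euclidean K-means cannot express this metric:
centroids are member means, iteration runs to label convergence, empty
clusters are re-seeded from the point farthest from its centroid,
initialization is seeded kmeans++ with multiple restarts (best total
within-cluster distance wins), and zero-variance rows — for which
correlation is undefined — are assigned afterwards to the
Euclidean-nearest centroid and flagged. One caveat of the metric: the
mean centroid is not the exact minimizer of summed correlation
distances, so on barely-separable data a globally optimal partition need
not be a fixed point of the iteration; the enumeration oracle in the
tests therefore uses separable data, where it is.

K defaults to 16. The cluster-count arithmetic that motivates this
default is 4 singleton classes plus 6 mirrored pairs: merging each pair
leaves 10 final clusters. The mirror score of two groups is the Pearson
correlation between one concatenated centroid and the other's
per-track bin-reversed concatenated centroid. An earlier formulation —
averaging per-track correlations — was rejected: a track with no signal
in a given class is flat up to noise, its correlation is meaningless,
and averaging it in drags true mirrors far below any usable threshold.
On the concatenated vectors a flat track contributes almost no variance,
so the score is driven by the signal-bearing tracks and an exact mirror
still scores 1. Pairing is greedy on descending score with a 0.8 floor,
ties toward lower group ids, self-pairing forbidden; greedy (rather than
optimal assignment) is sufficient because true mirror scores sit near 1
while spurious candidates sit well below the floor.

Asymmetry of a profile is `A = (R − L)/(R + L + ε)` with L and R the
sums strictly left and right of the center bin and `ε = 1e-12`; an
all-zero profile scores 0, and reversal negates A exactly. The statistic
and its 0.2 asymmetry threshold are package inventions (no closed form
exists in the literature for this exact task); both are exposed in the
API and the suite carries sensitivity checks through the mirror-pair
property (partners show opposite orientations with equal |A|). A group
is called asymmetric on the first track of the priority list (H3.3, then
H2A.Z — the variants that delineate orientation) that carries signal in
its centroid; members of a positive-A group are oriented "right", the
mirror partner "left", symmetric groups "none".

## Directionality and enrichment

PolII rows of left-oriented anchors are bin-reversed before scoring, so
positive skew means "toward the variant orientation"; concordance is the
fraction of asymmetric-cluster anchors with positive aligned skew.
Strand bias at an anchor is `B = (P − M)/(P + M + ε)` over the profile
window, sign-flipped at left-oriented anchors; cluster means carry a
seeded percentile bootstrap CI (1,000 resamples). Swapping the stranded
tracks negates every B exactly.

Between-cluster eRNA comparisons use the one-sided Mann–Whitney test on
per-anchor totals (P + M): eRNA totals are heavy-tailed, which makes the
rank test the defensible default over a t-test (Welch is available by
flag through `stats`). The exact null distribution is used when the
smaller cluster has at most 20 anchors and there are no ties; otherwise
the normal approximation with continuity correction. Identical constant
samples return p = 0.5 with a tie warning.

TF enrichment is the upper-tail hypergeometric probability of observing
k overlapping anchors among a cluster's n, given K overlapping among all
N distal anchors. The universe is deliberately the distal anchor set
itself — the same universe the clustering partitions — not the genome;
a genomic universe would confound open-chromatin enrichment with
cluster-specific enrichment. Overlap means any peak intersecting the
half-open ±500 bp window around the anchor center (flank configurable).
Raw p reproduces the classical criterion; BH q-values are reported
alongside for honest multiplicity handling.

# The genome fixture

One synthetic chromosome (8 Mb default) carries 60 genes, 640 anchors
(16 archetypes x 40) and 30 promoter-proximal decoy DHSs, laid out
left-to-right with gaps of at least 2.5 kb between bounding boxes — a
construction that guarantees the distal rule rather than enforcing it by
rejection. Each archetype plants Gaussian bumps (sigma = width/2,
default width 300 bp) into 100-bp bins; counts are Poisson (or exact
expectations with `noise = "none"`). The default panel holds four
symmetric classes — macroH2A-only, H3.1-only, centered H2A.Z + H3.3, and
an NFR-flanking double-bump H2A.Z + H3.3 class — and six mirrored
asymmetric classes in which H3.3 (variously with H2A.Z, H3.1 or
macroH2A) sits 400 bp off-center, PolII is offset the same way (half the
magnitude), and eRNA carries a 0.3 strand bias toward the skew. The
double-bump class exists because class identity under a correlation
metric is a matter of profile *shape*: a panel whose symmetric classes
differ only in amplitude mixes of the same centered bump does not
actually implement distinguishable classes. eRNA amplitudes grade from
weak at the macroH2A class (repressive) to strongest at H2A.Z/H3.3
classes, so cluster-level eRNA comparisons have planted order. eRNA
background defaults to zero — intergenic nascent-RNA signal is near
zero in practice, and any background shrinks the measured strand bias
below the planted value, which would make the planted number the wrong
expectation to test against. TF peaks land on target-archetype anchors
with `odds x background_rate` probability (default background 0.1).

What the fixture does not emulate: read-level artifacts (mappability,
duplicates, fragment-length effects), signal autocorrelation beyond the
bump shape, copy-number variation, overlapping regulatory elements, and
gene-derived nascent transcription in the eRNA tracks. Recovery results
on the fixture certify the statistical machinery, not robustness to
those properties of real data.

# Problem sizes and numerical choices

The test and acceptance workloads use the defaults above: 640 anchors,
16 clusters, 10 kmeans++ restarts, 1e4-nucleosome pools, 100-seed
recovery loops, 1,000-replicate null calibration of the rank test. These
sizes give stable statistics (binomial error on a 95% pass criterion at
100 seeds is about 2 points) while a full pipeline run stays in the tens
of seconds on one core.

Tolerances: exact arithmetic identities (noise-free inversion, scale
invariance, antisymmetry, strand-swap negation) are asserted at 1e-9 or
tighter; stochastic recoveries at the band the study conditions imply
(0.05 absolute, 95% of seeds). Bootstrap CIs are 95% percentile
intervals, so any single fixed-seed CI check fails 5% of the time for a
correct estimator; panel-level CI assertions therefore require coverage
in at least 4 of 6 clusters (99.7% pass probability under correctness)
together with an absolute 0.05 band on every cluster mean.

Degenerate inputs: zero-variance profile rows are flagged and assigned
by Euclidean fallback; anchors whose window leaves the chromosome are
dropped and counted; zero-signal eRNA anchors score B = 0 and are
flagged; a missing mark is reported as missing (NA), never as zero.

# Known limitations

* H3.1 and H3.2 are indistinguishable by construction; "canonical H3"
  is always their sum.
* The asymmetry statistic and its threshold are package conventions;
  rankings are robust to the threshold but the symmetric/asymmetric
  boundary is not canonical.
* With the absolute-correlation metric, a profile and its negation are
  equidistant from any centroid; this is harmless for non-negative
  coverage but matters if the package is fed signed signal.
* The Mann–Whitney exact branch requires tie-free data; heavily
  discretized totals at small n silently shift to the corrected normal
  approximation (reported in the result's `exact` field).
* The pipeline consumes DHS peaks as given; peak calling itself is out
  of scope, as are read alignment and raw spectral processing.
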