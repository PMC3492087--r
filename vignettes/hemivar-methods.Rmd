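---
title: "Methods: variant discovery and prioritization for hemizygous targeted resequencing"
author: "hemivar authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant discovery and prioritization for hemizygous targeted resequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemivar)
```

# Overview

`hemivar` re-implements, as one tested pipeline, the analysis used in deep
targeted resequencing studies of X-linked candidate loci in males: because
males are hemizygous on X, every sample carries exactly one allele per site,
and a deep pileup over a PCR-amplified target gives a near-binary signal for
genotype calling. The pipeline covers read mapping, pileup genotype calling,
functional and conservation annotation, prioritization of rare variants at
evolutionarily conserved sites, population-genetic summaries, PWM-based
scanning of regulatory sites, and the closing statistics used to interpret
the findings (a Poisson frequency bound, Welch's t-test on reporter assays,
and family segregation patterns).

Everything runs end-to-end on synthetic cohorts with known ground truth, so
each stage can be validated against what was planted.

# The synthetic cohort generator

`simulationConfig()` fixes the study conditions the generator emulates:

* a target of ~65 kb tiled without gaps by long-PCR amplicons (13 by
  default), with 144 hemizygous male samples at very deep coverage (median
  452x) — the published study design;
* a site-frequency spectrum dominated by rare alleles: `rare_fraction`
  (default 0.65) of planted variants are singletons, the rest are common
  with carrier fractions drawn above 5%;
* a known-variant catalog holding common alleles with probability
  `catalog_fraction` (default 0.9) and *never* holding the rare ones — this
  reproduces the observed pattern that almost all common variation is
  already cataloged while most rare variation is novel;
* `conserved_fraction` of the rare variants placed at perfectly conserved
  sites (PhastCons 1.0, elevated PhyloP), the remaining background drawn
  from low PhastCons (uniform on [0, 0.5]) so the conservation filter has a
  clean separation to find;
* a small indel fraction (32/208 by default, the study's indel share).

Fragments are placed uniformly along each haplotype so per-base depth is
Poisson; mates read the two fragment ends in forward/reverse orientation;
errors are uniform substitutions at `error_rate` (default 0.003). Base
qualities are written as constant Q30 because no stage of this pipeline
uses them. There is no GC bias, no PCR duplication, and no quality-profiled
error model — those are wet-lab phenomena outside the scope of what the
synthetic data needs to exercise. Variants are kept `edge_margin` bases
(default one read length) away from the target ends, where primer-proximal
coverage is unreliable in real amplicon data; positions are drawn at least
10 bases apart so indel events can never collide or silently overwrite one
another.

A passing end-to-end test on these cohorts shows that the mapper, caller
and filters are internally consistent and recover exactly what was planted
under realistic depth and error; it does not show robustness to mapping
ambiguity in repetitive sequence, batch effects, or contamination, none of
which the generator emulates.

# Read mapping

Mapping follows the four-stage architecture of hash-based paired-end
mappers: (1) a hashed index of all target k-mers (k = 16 by default, seeds
sampled every k/2 bases on both strands), (2) candidate location voting
from seed hits, (3) a local Smith–Waterman alignment at every candidate,
(4) concordant pair selection maximizing the summed score subject to
opposite strands and a fragment length inside configurable bounds, with a
discordant fallback to the best single placements.

The alignment uses affine gaps with defaults match +1, mismatch −3, gap
open −5, gap extend −2 (a gap of length g costs open + (g−1)·extend). The
published analysis does not state its scoring parameters, so these are
package defaults chosen from the common practice of penalizing a mismatch
several times the match reward; they are configurable via
`scoringScheme()`. Ties are resolved deterministically: the first maximal
cell in row-major order ends the alignment, and traceback prefers diagonal
moves, which yields the leftmost start with the fewest gaps. The
implementation evaluates a full dynamic program on a padded window around
each candidate (±20 bases), which is equivalent to a banded alignment
around the seed diagonal; the test suite checks it against an independent,
unbanded full-matrix implementation.

# Pileup calling

Each aligned base increments one pileup column; deleted reference bases
increment per-column deletion counts; insertions are tallied at the column
immediately preceding the inserted bases. Calling is hemizygous: one
allele per sample, no heterozygous calls. A column is callable at depth
≥ 8 (the published callability threshold); a variant is called when the
most frequent non-reference event (alternate base, deletion, or anchored
insertion) reaches a fraction of 0.75 of depth. The study reports that
validated variant sites showed the non-reference allele in more than 92%
of reads but never states the decision threshold of its (unpublished)
caller; 0.75 tolerates sequencing error and modest mismapping while
excluding noise, and is configurable. A tie between two non-reference
events at the threshold is a flagged no-call. Indel alleles are
reconstructed from grouped insertion/deletion events and left-normalized
against the reference (one shared leading base, VCF convention) before
cohort merging, so equivalent representations always merge. Internally
all coordinates are 0-based half-open; everything emitted is 1-based.

One systematic effect worth knowing: local alignment soft-clips
mismatching read ends, so reads whose last bases span an indel lose that
indel from their alignment. Planted SNVs consequently show non-reference
fractions near 1.0 while indel fractions sit around 0.8–0.9 at 50x. This
mirrors the published observation (> 92% non-reference reads), which
concerned SNVs.

# Annotation and prioritization

Gene models are single-gene exon/CDS structures; functional class is
assigned with precedence coding > UTR > intron > intergenic, with UTR
sidedness respecting strand. Amino-acid changes are translated with the
standard genetic code (reverse-complemented for minus-strand genes).
Catalog membership is allele-aware — position, ref and alt must all match
after left-normalization — which is stricter than position-only lookup
and prevents a novel allele at a known position from being labelled known.
Conservation is looked up per base; multi-base variants carry the maximum
per-base PhastCons (the published conserved-indel row carries a single
PhastCons despite two per-base PhyloP values, which is what the maximum
reproduces) and a `/`-joined per-base PhyloP list. Feature BED tracks are
0-based half-open on disk and converted at the I/O layer.

The prioritization filter keeps variants with PhastCons ≥ 0.7, case
frequency ≤ 1% and no catalog entry. The comparison is inclusive (≥)
with a configurable threshold: the study states a strict "> 0.7" rule yet
its result table contains a 0.69 row, so the effective rule is ambiguous;
the default 0.7 with ≥ does not admit that row, and lowering
`phastcons_min` to 0.69 reproduces the alternative reading. The frequency
cutoff is stated for a 144-sample cohort where a singleton sits at 1/144
< 1%; on smaller test cohorts the cutoff must be set just above
1/n_samples for "rare" to mean "singleton" (the end-to-end benchmark at
40 samples uses 0.026).

# Population genetics

From the cohort table the package computes Watterson's
θ_w = S/(a₁·L) per site with a₁ the (n−1)-th harmonic number, total
pairwise diversity π = Σ 2(k/n)(1−k/n)·n/(n−1) from per-site carrier
counts (equal to the mean pairwise Hamming distance over all C(n,2)
haplotype pairs), and Tajima's D = (π − S/a₁)/√(e₁S + e₂S(S−1)) with the
usual constants in n. D is computed from SNVs only by default, with a
flag to include indels, since the published analysis does not state which
it used. The surveyed length L is taken as the callable length (bases at
depth ≥ 8 in at least one sample) rather than the nominal target length:
θ_w per site needs the denominator actually surveyed, which the published
analysis leaves implicit; the study's total target length itself is never
stated and the ~65 kb default is back-solved from its reported S = 208,
n = 144 and θ_w = 5.8×10⁻⁴.

Under a neutral frequency spectrum (site frequencies ∝ 1/k at fixed S)
the expected π equals S/a₁ exactly, so D is centered at zero — the test
suite verifies this by simulation — while all-singleton cohorts force
D < 0 for any n ≥ 4, the signature of an excess of rare alleles.

# Regulatory scanning

PWMs are column-frequency matrices scored as log₂ odds against a uniform
background with an additive pseudocount (0.01). Because no raw-score
convention is standard across matrix databases, raw scores are calibrated:
for each background region the maximum score over both strands is taken,
and a scanned window's z is its raw score expressed in standard deviations
above the mean of those per-region maxima. This makes downstream z and p
values invariant to any affine change of the raw-score convention. The
one-sided p is the upper normal tail at z. A calibration needs at least 30
background regions and positive variance across them; note that a
background in which every region contains the exact consensus is
degenerate by construction (the consensus is the maximal achievable score,
so every per-region maximum coincides and the variance is zero — such
calibrations are rejected). Variant effects on a hit are reported as the
difference between the alt-substituted and reference window scores, with
a 10⁻⁹ neutrality tolerance; indels overlapping a hit are reported
unsupported rather than scored.

# Closing statistics

*Frequency bound.* With zero carriers of a disease-class mutation among n
sequenced individuals, the largest Poisson rate consistent with seeing
none at confidence c gives the frequency bound p = −ln(1−c)/n (the
gamma-quantile generalization covers k > 0). At n = 144, c = 0.99 the
bound is 0.032 — "less than 3%" to the nearest percent. The binomial
alternative 1−(1−c)^(1/n) is provided behind a flag; both round to 3%
here.

*Reporter assays.* Firefly luminescence is normalized per replicate to the
co-transfected Renilla signal; constructs are compared with Welch's
two-sided t-test (Satterthwaite degrees of freedom), the published choice
for unequal variances. Replicates are the three within-transfection wells
per construct, matching the published design; whether those should be
treated as independent is not stated there, and n = 3 per group is
assumed. A power simulation in the test suite shows that a true 10%
expression shift at n = 3 with ~10% assay noise rarely reaches p < 0.05 —
the package reproduces the study's inability to resolve effects of that
size, not a defect of the test.

*Segregation.* For an X-linked variant ascertained in a male proband: de
novo iff the mother is typed non-carrier; segregates iff every affected
sibling carries it and every unaffected male sibling does not; unknown
genotypes among those relatives, or no typed relatives, render the family
uninformative. Unaffected female siblings are always uninformative
because they can carry the variant heterozygously without phenotype.

# Problem sizes and determinism

The test suite and the acceptance script run the full pipeline on a 10 kb
target with 40 samples at 50x and error 0.003 (~100,000 read pairs), a
size at which all stage guarantees (≥ 99% SNV recovery, ≤ 1 false
positive per 10 kb, prioritized set equal to the planted
rare-conserved-novel truth) hold with margin; the package defaults
describe the full study scale and are exercised structurally rather than
at full depth. Every stochastic step draws from R's RNG seeded from the
configuration, so a repeated run with the same configuration produces
byte-identical outputs, including FASTQ files.

# Known limitations

* Single-target, single-chromosome coordinates; no liftover, no
  multi-gene overlap resolution beyond first-gene-wins.
* The caller has no base-quality model and no diploid mode; it is built
  for the hemizygous deep-coverage regime.
* Indel support fractions are depressed by end-clipping (see above);
  deletions longer than a few bases were not a design target.
* PWM hits are calibrated against user-supplied background regions; the
  package does not fetch genome-wide promoter sets.
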