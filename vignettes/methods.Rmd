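---
title: "Methods: germline and somatic SNV calling from sparse single-cell data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germline and somatic SNV calling from sparse single-cell data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellsnv)
library(dplyr)
```

# The problem

Single-cell sequencing (scRNA-seq, snRNA-seq, scATAC-seq, scDNA-seq) yields
extremely uneven coverage: most cell-site combinations have zero reads, a
heterozygous site in one cell usually shows only one of its two alleles
(allelic dropout), and per-read error rates are non-negligible. cellsnv
calls single-nucleotide variants (SNVs) from this kind of evidence at two
levels:

1. **Germline SNVs**, by borrowing linkage disequilibrium (LD) from a
   phased population reference panel: even a single read at a site, placed
   in its haplotype context, can be resolved into a confident genotype.
2. **Putative somatic SNVs**, by moving the same LD logic to the *cell
   population* within one sample: a germline allele cosegregates with its
   haplotype neighbours in essentially every cell, while an allele gained
   somatically cosegregates in only the subpopulation of cells descended
   from the mutated clone.

Everything is testable without external downloads because the package
ships a synthetic-data generator that emulates the statistical structure
the method relies on.

# Germline calling

## Read filtering and candidate scanning

Reads with more than `max_mismatch = 4` alignment mismatches or mapping
quality below `min_mapq = 20` are removed (both thresholds inclusive on
the keep side: exactly 4 mismatches or mapping quality exactly 20 is
kept). `mismatch_count` counts substituted plus inserted/deleted bases;
whether an upstream aligner's mismatch tag includes indel bases varies, so
the count definition is documented here rather than assumed. Candidate
SNVs are every pooled-pileup site where at least one read shows a
non-reference base; the most frequent non-reference base becomes the
alternative allele and rarer third alleles are ignored, keeping every
site bi-allelic (the entire downstream model is defined for two alleles).

## Genotype likelihoods

For genotype $g \in \{0, 1, 2\}$ (copies of the alternative allele) and a
read with error probability
$e = 10^{-\min(\mathrm{BQ}, \mathrm{MAPQ})/10}$, a read supports the
reference with probability $1-e$, $1/2$, $e$ under $g = 0, 1, 2$; the
site's genotype likelihood $GL(g \mid d)$ is the product over retained
reads. Sites without informative reads get a flat triplet. This is the
classical symmetric bi-allelic model; it is simple enough to verify by
hand enumeration, which the test suite does.

## Panel refinement

At sites present in the phased reference panel the likelihoods are
refined into posteriors $GP(g \mid H, d)$ with a diploid haplotype-copying
hidden Markov model over ordered pairs of panel haplotypes. Each of two
chains copies one panel haplotype; between adjacent sites a chain switches
donors with probability $1 - \exp(-d/\rho)$ (distance $d$ in bp,
`rho_scale` $\rho = 10^5$ bp by default, i.e. one expected switch per
100 kb) and lands uniformly on any donor; an emitted allele differs from
its donor with probability `theta` $= 10^{-3}$ (copying fidelity, which
absorbs both mutation since the panel's coalescent and residual
genotyping error). The observation likelihood $GL$ couples the chains at
the genotype level; because the transitions factorize, the
forward–backward pass is $O(nK^2)$ and is verified against exhaustive
summation over all pairs of donor paths on small instances
(relative error below $10^{-8}$). The defaults for `theta` and
`rho_scale` are conventional haplotype-copying values, chosen once; the
model is an explicit, testable stand-in for the clustered-haplotype
imputation engines used on cohort data, not a re-implementation of any of
them.

A Viterbi pass over the same state space supplies the phase orientation
of heterozygous calls (which haplotype carries the alternative allele),
which the somatic module consumes. When the Viterbi donor pair is
uninformative about the orientation (both donors carry the same allele),
the orientation is assigned deterministically and flagged by nothing more
than its own inconsistency — on sparse data such sites are a small
minority and only dilute, never bias, the cosegregation scores
(both orientations of a wrongly phased site are mirrored equally).

Argmax ties (flat likelihoods) break toward the smaller genotype, so an
uncovered site is called homozygous reference by the data-only argmax —
this is what makes the GL-vs-GP accuracy comparison meaningful on sparse
data.

## Consensus and the sequencing-error model

The final genotype keeps only loci where the data-only argmax
$G_{m|d}$ and the refined argmax $G_{m|H,d}$ agree. Loci called
non-reference from the data but imputed homozygous-reference by the panel
are treated as sequencing-error exemplars: they are binned by allele pair
and collapse direction into the 12 categories
(AT→AA, AT→TT, CT→CC, …, CG→GG), and the median pooled B-allele fraction
(BAF) per category becomes that category's error threshold. Categories
with no exemplars fall back to the global median (so small runs never
leave thresholds undefined). All discordant loci are excluded from the
germline call set; only the het-to-hom-reference discordances feed the
error model.

## De novo filters

Candidates absent from the panel pass two filters: pooled depth at least
`min_depth = 100` (inclusive — the default names the minimum acceptable
depth) and pooled BAF not below the maximum of the two error-model
thresholds for the site's allele pair (an A/T candidate is removed when
its BAF is below $\max\{\mathrm{BAF}_{AT \to AA},
\mathrm{BAF}_{AT \to TT}\}$; equality passes).

## SVM artifact filter

Surviving candidates are scored by a radial-kernel support-vector
classifier on seven per-site features: `qs` (phred-scaled probability the
site is non-reference), `vdb` (variant distance bias: the variance of
alt-read positions within the read relative to the uniform-placement
expectation $(L^2-1)/12$ — splice-site artifacts concentrate alt calls at
one read position), `rpb` and `bqb` (Mann–Whitney rank-sum z statistics
comparing ref- against alt-supporting reads on read position and base
quality, tie-corrected), `mqsb` (the average of the mapping-quality
rank-sum z and a z-transformed Fisher exact test of the strand-by-allele
table), `sgb` (segregation: one minus the fraction of distinct cells
among alt reads, so amplification artifacts concentrated in one cell
score high) and `baf`. `vdb` and `sgb` have no published closed form in
the variant-calling literature we follow; the formulas above are this
package's own, documented definitions and the features are pluggable.
One-sided sites impute neutral values (z = 0), since the absence of alt
reads carries no bias information.

Positives are panel-overlapping germline calls; negatives are de novo
candidates in fixed 50-kb genomic chunks containing no germline call and
more than two candidates (clusters of "somatic" SNVs in germline-free
regions are implausible at realistic somatic mutation rates). Probability
calibration uses Platt scaling — a logistic fit on the SVM decision
values — rather than the cross-validated calibration built into common
SVM implementations, because the latter randomizes fold assignment
outside the R random-number stream and would break run-for-run
reproducibility. Candidates with positive-class probability below
`svm_prob = 0.5` are discarded (exactly 0.5 is retained). On synthetic
runs whose error structure produces no negative chunks the pipeline's
`svm = "auto"` mode skips this stage rather than fabricate labels.

# Somatic calling by cell-population LD

## The cell-level allele matrix

Phased germline heterozygous SNVs (homozygous sites carry no phase
information) form a matrix of per-cell read counts $c^1_{ij} | c^2_{ij}$
supporting the haplotype-1 and haplotype-2 alleles. De novo SNVs enter
with unphased labels $A^1_s / A^2_s$ (reference / alternative).

## Distance-binned cosegregation profiles

Within a cell, two covered sites are *two-locus neighbours* when no
germline site between them is covered; a neighbourhood *cosegregates*
when the same-haplotype allele is observed at both sites
($c^1 c^1 > 0$ or $c^2 c^2 > 0$). Chains of two adjacent neighbourhoods
whose outer sites show the same haplotype's allele form *three-locus
neighbourhoods*, cosegregating when the middle site shows that allele
too; flanks agreeing on haplotype 1 and, mirrored, on haplotype 2 are
pooled, which doubles the data at no bias by phase symmetry. The score
per physical-distance bin is one minus the cosegregating fraction —
near 0 where loci share sequencing fragments, near 0.5 where allele
draws are independent. Distances use 13 bins (<100 bp up to >500 kb,
log-like spacing); two-locus neighbourhoods bin by the pair distance,
three-locus ones by the upstream-flank-to-middle distance. Empty bins
are flagged undefined, never 0/0.

## Phasing de novo SNVs and the score $p_s$

For each de novo SNV $s$ and each cell with reads at $s$, the evidence is
compared against the hypothesis "$A^1_s$ lies on haplotype 1":

* **two-locus term** — the nearest covered germline neighbour within
  `cap2` bp: the term is $1 - p(\mathrm{bin})$ if the cell's alleles are
  cosegregation-consistent with the hypothesis and $p(\mathrm{bin})$
  otherwise, with $p(\mathrm{bin})$ the profile score at the realized
  distance (an empty bin falls back to the nearest non-empty wider bin,
  then narrower ones, so cells are not dropped by binning accidents);
* **three-locus term** — the nearest covered flanks on both sides within
  `cap3`, when they agree on exactly one haplotype, judged by the allele
  observed at $s$;
* the two terms are averaged when both are defined, otherwise the defined
  one is used alone (the printed equal-weight mix presumes both exist).

Observations in which both alleles are seen at $s$ or at its neighbour
satisfy the consistency condition of *both* orientations and are dropped
as phase-uninformative. This is a deliberate choice: the obvious
alternative — letting the first-listed branch claim such cells — makes
the result depend on the arbitrary order of allele labels, and the
symmetric alternative of scoring them $0.5$ biases every site toward the
middle of the scale at moderate depth. Both orientations are evaluated
independently through mirrored conditions, which makes the final score
*exactly* invariant under exchanging the branch assignments (the test
suite checks bitwise equality); only the orientation label flips.

The population-level probability $p(A^1_s | A^2_s)$ is the mean of the
per-cell terms over informative cells, $p(A^2_s|A^1_s)$ its mirror-image
(their sum is 1 to numerical precision), the reported orientation is the
argmax, and the LD refinement score is
$p_s = \min\{p(A^1|A^2),\ p(A^2|A^1)\} \in [0, 0.5]$. A call with no
informative cells is classified `unknown`. SNVs with $p_s$ strictly
greater than `ps_threshold = 0.25` are putative somatic; $p_s$ exactly
0.25 stays germline-like.

## What $p_s$ estimates

For a germline heterozygote every cell cosegregates and $p_s \to 0$. For
a somatic SNV carried on one haplotype by a cell fraction $f$, carriers
are always consistent with the true orientation, while non-carrier cells
are homozygous reference and split evenly between the two haplotypes of
their fragments, so the expected support for the true orientation is
$f + (1-f)/2$ and

$$p_s \;\longrightarrow\; \frac{1-f}{2},$$

the fraction of cells whose alleles do not cosegregate under the best
orientation. $p_s$ therefore *decreases* from 0.5 toward 0.25 as the
clone grows from rare toward half the population; the 0.25 threshold
corresponds to clones below half of the cells, and any subclonal $f<1$
keeps $p_s$ above a germline call's near-zero score. The sparse-regime
test in the suite verifies the medians against $(1-f)/2$ within 0.05.
This analytic behaviour is worth stating because the score is sometimes
read informally as "the clone fraction"; it is the non-cosegregating
fraction, which is a monotone transform of the clone fraction, not the
fraction itself.

## Distance caps as informativeness gates

The caps restrict each model to distances where cosegregation reflects
phase rather than sampling noise: `cap2 = 100` bp and `cap3` = 10 kb
suit DNA-like data whose physical phasing comes from short reads (and
whose longer-range signal comes from amplification fragments), while
1 kb / 50 kb suit RNA-like data where transcript-length fragments phase
further. In the packaged synthetic experiments the caps are set to
about half the simulated fragment length: terms taken at distances where
the profile score approaches 0.5 contribute $\approx 0.5$ regardless of
the truth and only dilute the cell average, so gating them out sharpens
both the germline baseline and the somatic signal without biasing
either.

## Per-cluster genotyping

Putative somatic SNVs are genotyped per cell cluster by pooling the
cluster's reads and taking the argmax of the count-based genotype
likelihood under a constant error rate; clusters without reads get a
missing genotype. This simple pooled genotyper replaces a full
single-cell joint genotyping model deliberately — at cluster-level read
depths the pooled likelihood is already decisive, and it keeps the stage
dependency-free and exactly testable.

# Evaluation metrics

Call sets are compared on bi-allelic, non-reference loci keyed by
(chromosome, position, ref, alt): sensitivity $|N \cap W|/|W|$, precision
$|N \cap W|/|N|$, genotype accuracy (identical genotypes over the
intersection) and overall accuracy (precision × genotype accuracy).
Array concordance counts matching alleles per shared locus (0–2),
subtracts the minimum possible match (1 whenever either genotype is
heterozygous) and, by default, normalizes by the attainable excess
$\sum (2 - \text{min possible})$, giving a scale-free score in $[0,1]$;
"normalized against the number of loci" is ambiguous between this and a
raw per-locus mean, so both are implemented behind the `normalization`
flag and the attainable-range variant is the default because it is 1
exactly for identical informative genotypes. Clone concordance matches
each reference clone (e.g. an mtDNA clone) to its best-Jaccard somatic
SNV group — optionally pre-filtered by a rank-test enrichment criterion
at p < 0.01 — and averages $|A \cap B| / |A|$ over clones.

# Ancestry projection

The genetic relationship matrix is $R_c R_c^\top$ over samples with
column-centered genotypes (without centering, allele-frequency offsets
dominate the first eigenvector; a flag disables centering, and an
optional standardization matches pipelines that scale genotype columns —
the choice is exposed because reference implementations differ). Missing
genotypes are mean-imputed, which is unavoidable for sparse single-cell
call sets. PCA coordinates are the top-K eigenvectors scaled by the
square roots of their eigenvalues, sign-fixed so each coordinate's
largest-magnitude entry is positive.

Projection Procrustes finds an orthonormal $A_{K' \times K}$ and scale
$\rho$ minimizing $\lVert \rho \tilde{Y} A - Y \rVert_F^2$. With
$K' > K$ this has no closed form, so the package uses a
majorization–minimization iteration: the quadratic term
$\rho^2\,\mathrm{tr}(A^\top S A)$ is majorized at the current iterate,
leaving a linear Stiefel problem solved exactly by the polar factor
(SVD) of the surrogate gradient, alternated with the closed-form update
of $\rho$; the objective decreases monotonically and the fixed point is
verified against a general-purpose numeric minimizer to $10^{-6}$ in the
tests. The new sample's coordinates are $\rho \tilde{y} A$.

# The synthetic-data generator

The generator is first-class, tested code, and its defaults are the
study conditions of the packaged experiments:

* **Panel** — a copying process: each new haplotype copies a previous
  one, switching donors at `recomb_intensity` per bp and miscopying at
  2%, which produces block-wise LD decaying with distance (checked
  against direct $r^2$ computation). A minimum minor-allele count
  enforces `maf_min`. This is a desk-scale stand-in for a coalescent
  panel: it produces the LD *decay* the refinement HMM needs, not a
  calibrated human site-frequency spectrum.
* **Diploid sample** — two mosaics of panel haplotypes with
  Poisson-style donor switching (`expected_breakpoints` per haplotype).
* **Cells** — a clone tree with deterministic largest-remainder cell
  assignment; somatic alleles are gain-of-heterozygosity only, placed on
  one haplotype of homozygous-reference loci and carried by exactly the
  originating clone and its descendants (placing one on a heterozygous
  site errors out, matching the two-alleles-per-population assumption).
* **Reads** — per cell, fragment start positions form a Poisson process;
  each fragment of length `read_len` copies one haplotype, so loci
  covered by a common fragment share its haplotype draw (short-range
  physical phasing) while distant loci are sampled independently. A
  per-cell-site capture mask supplies zero inflation (`zero_inflation`,
  default 0.3, a mid-range expression sparsity; the fragment intensity
  is rescaled so the marginal per-cell-site depth mean stays
  `mean_depth`). Whole-allele dropout (default 10%) removes one
  haplotype's reads per affected cell-site; each read's allele flips
  with `error_rate` (default 0.1%). The defaults follow the packaged
  clonal experiment: 500 cells, clone fractions up to 0.4, 0.1% errors,
  10% dropout.

What the generator does **not** emulate: read-level artifacts (mapping
bias, strand bias, position-in-read error profiles beyond what the SVM
features see in simulation), copy-number events, multi-allelic sites,
bursty transcriptional kinetics beyond zero inflation, and doublets.
Passing tests therefore demonstrate the statistical mechanisms — LD
borrowing, cosegregation scoring, score calibration — not robustness to
every failure mode of real libraries.

# Problem sizes and numerical choices

The test suite and acceptance script run at desk scale, chosen so the
full suite completes in a few minutes on one CPU: panels of 24–40
haplotypes over 300–600 sites spanning 10–500 kb, 120–5000 cells, and
exhaustive-enumeration oracles at up to 4 cells × 5 loci (LD profile),
4 haplotypes × 4 sites (HMM), and $n = 20, K' = 4, K = 2$ (Procrustes).
Degenerate inputs are handled explicitly: zero-read sites get flat
likelihoods; an empty error-locus set warns and uses a configured
fallback threshold; empty profile bins are undefined and looked up by
fallback; a de novo SNV with no informative cell is `unknown`; argmax
ties break toward the smaller genotype; chunked execution attributes
each neighbourhood to the chunk containing its upstream site (exactly
once) and cannot recover neighbourhoods spanning more than the overlap
margin (default 500 kb, the largest finite bin edge).

# Known limitations

* The refinement HMM is a Li–Stephens-type approximation; it preserves
  the LD-borrowing behaviour but is not numerically identical to
  clustered-haplotype imputation engines.
* $p_s$ saturates toward 0.5 for rare clones and compresses near 0.25
  as clones approach half the population; with fewer than a handful of
  informative cells the score is noisy, and the per-cell terms assume
  mostly single-allele observations — at high per-cell-site depth both
  alleles are captured routinely, such observations carry no phase
  information, and the score degrades toward 0.5 for germline and
  somatic sites alike.
* Loss-of-heterozygosity and copy-number-aware somatic calling are out
  of scope, as are models over more than three loci.
* Ancestry projection assumes the study sample's missingness is
  uninformative after mean imputation.
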