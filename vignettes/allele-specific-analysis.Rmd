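---
title: "Allele-specific copy number, ploidy, purity and clonality from matched tumor/normal sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific copy number, ploidy, purity and clonality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascnclone)
```

## The problem

Bulk DNA sequencing of a tumor biopsy observes a mixture of cell
populations: non-tumor cells (stroma, immune infiltrate), and one or more
tumor subclones that may differ in their copy-number profile. Two sample
parameters confound every downstream quantitative analysis:

* **DNA admixture** `G`: the fraction of non-tumor DNA (purity is `1 - G`).
  Normal DNA dilutes every somatic signal, both segment coverage ratios and
  variant allele fractions.
* **Ploidy**: the average number of genome copies per cell. Coverage
  ratios are normalized by mean coverage, so a genome that has gained DNA
  overall displaces the coverage ratio of even its unaltered segments.

`ascnclone` estimates both from segmented coverage log-ratios (logR) and
pileups of germline heterozygous SNPs, then uses them to compute
allele-specific copy numbers and the clonality of copy-number aberrations
and point mutations.

## Beta: the fraction of allelically neutral reads

SNPs that are heterozygous in the matched normal ("informative SNPs") let
us partition reads by parental allele. For a genomic segment we summarize
the allelic signal by **beta**, the fraction of reads that are allelically
neutral — drawn evenly from both alleles. A balanced segment has beta 1; a
pure clonal one-copy deletion has beta 0; intermediate mixtures interpolate.
Unlike the raw allelic fraction, beta does not depend on *which* allele is
lost, which makes it the natural per-segment statistic.

At an informative SNP inside a segment with beta `b`, the alternative base
sits on the depleted or the retained allele with equal probability, so its
allelic fraction concentrates at `b/2` or `1 - b/2`. `estimate_beta()`
therefore maximizes the folded two-component binomial mixture likelihood

```
sum_i log( 1/2 Binom(k_i; n_i, b/2) + 1/2 Binom(k_i; n_i, 1 - b/2) )
```

with `k_i = round(af_i * cov_i)` (pileups store fractions, not counts).
The search is an exhaustive grid at step 0.001 — the likelihood can be
multimodal, so a local optimizer alone is unsafe — followed by a
golden-section refinement inside the best cell. The estimator is invariant
under mirroring `af -> 1 - af` by construction, and reference mapping bias
is deliberately ignored (its effect is small relative to the binomial
noise at the depths this model targets).

`compute_beta_table()` applies the estimator per segment, to the tumor
pileup (`beta`) and to the matched normal (`n_beta`). `n_beta` is expected
to be 1; values clearly below 1 indicate germline copy-number variation or
systematic pileup artifacts, and such segments are excluded from the
sample-level estimators.

### Estimation error and the error table

The precision of a beta estimate depends on the number of informative SNPs
and their coverage. `build_error_table()` calibrates, by Monte-Carlo
simulation, a symmetric error half-width per (SNP count, coverage) pair:
the 0.9-quantile of `|estimate - truth|`, maximized over a grid of true
beta values so that one number covers any underlying state. The bundled
table (grids 10–200 SNPs, 20–200x coverage, 1000 replicates per cell,
fixed seed; regeneration script in `inst/extdata/`) is looked up with
nearest-neighbor matching per dimension. Experiments far outside that grid
— ultra-deep targeted panels, very low-pass whole genomes — should rebuild
an ad hoc table. The half-widths propagate into admixture bounds
(`adm.min`/`adm.max`) and clonality bounds.

## Ploidy from the logR shift

logR is normalized by the tumor/normal mean-coverage ratio. If the tumor
genome averages `P` copies per cell, that normalization shifts wild-type
segments to `logR = shift` with `ploidy = 2 * 2^(-shift)`. A shift of 0
means ploidy 2; a shift of -0.34 means ploidy 2.53.

`compute_logR_shift()` anchors the wild-type mode using only allelically
*balanced* segments (beta at or above `beta_limit_for_neutral_reads`,
default 0.90), because an unbalanced segment near logR 0 cannot be wild
type. The lowest-logR 5% of eligible segments (`max_homo_dels_fraction`)
is discarded first: homozygous deletions are rare and extreme, and
over-trimming is harmless because the trimmed tail cannot contain the
dominant balanced mode. The remaining logR values are smoothed with a
segment-length-weighted Gaussian kernel density (Silverman's bandwidth on
the sample), and the shift is the **leftmost** local maximum whose mass is
at least 20% of the dominant mode's — balanced states are CN 2, 4, ... and
CN 2 sits at the smallest logR; the mass qualification (our calibration)
suppresses spurious noise modes. Note what this estimates: the displacement
of the observed wild-type mode, i.e. the average copy number of the
*sample* relative to a diploid reference. That is exactly the quantity the
admixture and allele-specific steps need to re-zero the logR axis.

Some profiles admit two internally consistent (ploidy, admixture)
readings — e.g. a diploid genome with pervasive subclonal losses versus an
aneuploid genome with CN-LOH. The data alone cannot break that tie, so the
package never switches interpretation silently: `check_ploidy_and_admixture()`
plots the expected lattice for inspection, and `compute_ploidy(force_shift=)`
lets the analyst impose the alternative solution.

## Admixture from the most clonal deletions

A clonal hemizygous deletion at admixture `G` has `beta = 2G / (1 + G)`
(each tumor active read is matched by two neutral reads from admixed
diploid DNA) and ploidy-adjusted `logRp = log2((1 + G) / 2)`. Inverting the
beta relation gives the *apparent* admixture of each deletion,
`G' = beta / (2 - beta)`. A subclonal deletion inflates `G'` — tumor cells
that lack the deletion are indistinguishable from normal cells — so
the sample admixture is read from the **lowest** cluster of apparent
values, not the biggest: this local, most-clonal-deletion logic keeps
heavily subclonal genomes from inflating the estimate.

`compute_dna_admixture()` screens candidates (defined beta below 0.9,
`logRp` in `[-1.2, 0)`, SNP/coverage filters, `n_beta >= 0.9`), retains
those whose `logRp` is within 0.25 of the value implied by their own `G'`
(both windows are our calibration, validated by the simulation recovery
tests), and takes the leftmost qualifying density mode of the retained
`G'` values. Bounds re-evaluate `G'` at `beta -/+` the error-table
half-width of the supporting segments. CN-LOH segments are not used: their
logRp is 0 and they carry no deletion signal.

A genome with no usable deletion — all beta near 1, logR near 0 — raises a
classed error on purpose. Such a profile is either a copy-number-quiet
tumor or an almost fully admixed sample, and nothing in (beta, logR) space
distinguishes the two; silently returning a number would be wrong either
way.

## Allele-specific copy number

Given `G` and the shift, each `(beta, logRp)` pair maps to fractional
copies of the two alleles:

```
cn_minor = (beta * 2^logRp - G) / (1 - G)
cn_major = ((2 - beta)(beta * 2^logRp - G) + 2G(1 - beta)) / ((1 - G) beta)
```

The major-allele expression simplifies algebraically to
`((2 - beta) * 2^logRp - G) / (1 - G)`; the package uses the full form and
falls back to the simplification at `beta = 0`, and the test suite verifies
their equality on a dense grid. Parental assignment is arbitrary, so the
output is ordered `(cnA, cnB) = (max, min)`. The corrected log-ratio
`log2.corr = log2((2 * 2^logRp - 2G) / (2(1 - G)))` is the logR the segment
would show in a pure diploid sample, and `cnA + cnB = 2 * 2^log2.corr`
always holds; it is reported even for segments without a beta estimate,
since total copy number needs no allelic signal.

Integer calls round half away from zero and are reported only when the
fractional value is strictly within `allelic_imbalance_th` (default 0.5)
of the integer; exact halves therefore stay uncalled. Fractional minor
alleles slightly below zero (above -0.2) are axis noise and are clamped
only inside the calling step.

## Clonality

The forward cell-mixture model gives, for an integer state `(a, b)`
present in a fraction `c` of tumor cells at admixture `G`, per-allele read
contributions `r = G + (1 - G)(c * cn + 1 - c)`, from which
`beta = 2 min(rA, rB) / (rA + rB)` and `logR = log2((rA + rB)/2) + shift`.
`scna_clonality_fit()` inverts this by enumerating states
`0 <= b <= a <= 8` (excluding (1, 1), which is wild type at any
clonality) and minimizing over `c` the squared signal distance with the
logR axis down-weighted (`w = 0.25`; logR noise exceeds beta noise at the
depths and SNP counts this model targets, and the weight was validated by
the simulation recovery suite). For the hemizygous-deletion state the
optimum has the closed form `c = (1 - G') / (1 - G)`.

Gains deserve a caveat: the signal of a state family with `(a - 1) * c`
constant is *exactly* degenerate — a clonal single-copy gain emits the
same (beta, logR) as a half-clonal two-copy gain. Noise would otherwise
break such ties arbitrarily in favor of extravagant high-copy, low-
clonality states, so state selection adds a small parsimony penalty
(`2e-3` per total copy, calibrated on the simulation recovery suite) to
the squared residual, and exact ties resolve to the smallest total, then
the smallest major allele. Fits whose unpenalized residual exceeds 0.05
are reported `not.analysed` rather than forced into the model.

Clonality bounds come from refitting at the pessimistic corners
`(beta.min, adm.max)` and `(beta.max, adm.min)`, and the status
discretization at threshold 0.85 is: `clonal` when the whole interval is
at or above the threshold, `subclonal` when it is entirely below, and an
`uncertain.` prefix when the interval straddles it, with the point
estimate choosing the suffix. The exact straddle rule is our
reconstruction of the usual practice: unprefixed calls are the reliable
ones.

For SNVs, `VAF = cl * m * (1 - G) / (2G + (1 - G) cnT)` with `m` the
multiplicity (mutated copies per mutated cell) and `cnT = cnA + cnB` the
fractional total copy number of the containing segment. The multiplicity
is chosen as the smallest integer in `1..max(1, cnA.int)` whose implied
clonality does not exceed 1.05 — the most conservative reading of a VAF
that is too high for a single copy; when no integer call is available the
multiplicity defaults to 1. `t_af_corr` rescales the VAF to a pure sample.
The top `error_rate` (default 5%) of the adjusted-VAF distribution is
flagged in the `excluded` column — systematically high adjusted VAFs
indicate copy-state mismatches or caller artifacts — but their rows are
still reported.

## The simulator

`tumor_model()`/`simulate_tumor()` generate matched inputs with known
truth, by construction from the same mixture model the estimators invert:

* informative SNPs placed uniformly at 0.33/kb, the genome-wide density of
  common heterozygous polymorphisms;
* per-SNP depths Poisson around the mean coverage (the simplest model
  consistent with the binomial read-sampling assumption);
* normal allelic fractions `Binom(cov, 1/2)/cov`; tumor fractions binomial
  around `rX / (rA + rB)` with the alternative base assigned to either
  allele with probability 1/2;
* per-segment tumor coverage scaled by `(rA + rB)/2` relative to its
  genome-wide length-weighted mean, which reproduces the mean-coverage
  normalization of logR — aneuploid models therefore show the wild-type
  shift organically rather than by injection;
* per-segment logR Gaussian noise (default sd 0.05);
* SNV read counts binomial around the VAF implied by the variant's
  clonality and multiplicity.

What it does **not** emulate: GC/mappability coverage waves, reference
mapping bias, segmentation errors (segment boundaries are taken as true),
overdispersed depths, and sequencing error in read counts. Passing
recovery tests therefore demonstrate correctness of the inference given
the model's assumptions, not robustness to upstream artifacts; profiles
with uneven coverage should be excluded upstream, as such data cannot be
disentangled downstream.

`scenario_model()` bundles four reference genomes (diploid-clean,
aneuploid with shift -0.34 / ploidy 2.53, mixed clonal+subclonal, and
copy-number-quiet) used across the test suite.

## Numerical choices and problem sizes

* Beta grid step 0.001 with golden-section refinement; ties on the grid
  resolve to the smaller beta.
* Density modes: `stats::density`, Silverman bandwidth, 512 grid points;
  mode mass by valley partition; three or fewer candidate deletions skip
  the density and use the minimum apparent admixture.
* Degenerate inputs are contracts, not crashes: zero informative SNPs give
  `beta = NA`; no balanced segment, or no candidate deletion, raises a
  classed error; `G = 1` is refused wherever division by purity occurs.
* The simulation test suite uses genomes of 24 x 0.8 Mb segments at
  coverage 150 (about 260 informative SNPs per segment), 50 genomes for
  sample-level recovery, 10 smaller-segment genomes (about 50 SNPs per
  segment) for integer-call recovery and 20 genomes with SNVs for class
  recovery; simulated admixtures span 0.1-0.7 and sample ploidies roughly
  1.8-3.3. These sizes keep the full suite comfortably within a normal
  check run while leaving the binomial-noise regime realistic.

## Known limitations

* Identifiability: profiles where every segment is aberrant admit multiple
  (ploidy, admixture) readings; the package surfaces the diagnostic
  lattice and an override instead of guessing.
* Admixture requires at least one near-clonal hemizygous deletion;
  quiet genomes refuse by design.
* Clonality assumes one aberrant subpopulation per segment against a
  wild-type background; nested or sibling subclones sharing a segment are
  averaged.
* The beta estimator treats SNPs as independent; linked haplotype blocks
  at very low SNP counts understate the error slightly, which is why the
  error table, not the likelihood curvature, supplies the bounds.
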