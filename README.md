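# ascnclone

Allele-specific copy number, tumor ploidy, DNA admixture and clonality
from matched tumor/normal DNA sequencing.

`ascnclone` is for cancer-genomics analysts who already have (i) a
segmented copy-number profile of a tumor (chromosome, start, end, logR —
the output shape of Circular Binary Segmentation or any comparable
segmenter) and (ii) pileups of candidate SNP positions for the tumor and
its matched normal, and who need the sample-level quantities that make
copy-number and mutation data comparable across samples: tumor ploidy,
DNA admixture (1 − purity), per-segment allele-specific copy numbers, and
the fraction of tumor cells carrying each aberration or point mutation.
It works on preprocessed tables, not BAM/FASTQ files, and is agnostic to
the upstream segmenter, aligner and mutation caller.

## The model in brief

* **beta** — for each segment, the fraction of reads that are allelically
  *neutral* (drawn evenly from both parental alleles), estimated from
  SNPs heterozygous in the matched normal ("informative SNPs"). At such a
  SNP the tumor allelic fraction concentrates at `β/2` or `1 − β/2`, so
  beta is the maximizer of the folded binomial-mixture likelihood
  `Σᵢ log[ ½·Binom(kᵢ; nᵢ, β/2) + ½·Binom(kᵢ; nᵢ, 1 − β/2) ]`.
* **ploidy** — logR is normalized by mean coverage, so the wild-type mode
  of allelically balanced segments sits at a shift `s` with
  `ploidy = 2·2^(−s)` (shift 0 → ploidy 2; shift −0.34 → ploidy 2.53).
* **admixture** — a clonal hemizygous deletion at admixture `G` shows
  `β = 2G/(1+G)`; inverting gives each deletion's apparent admixture
  `G' = β/(2−β)`, and the sample admixture is the lowest cluster of
  apparent values (subclonal deletions only inflate `G'`).
* **allele-specific copy number** — with `L` the ploidy-adjusted logR,
  `cn_minor = (β·2^L − G)/(1 − G)` and
  `cn_major = ((2 − β)(β·2^L − G) + 2G(1 − β)) / ((1 − G)·β)`,
  plus integer calls and the purity/ploidy-corrected `log2.corr`.
* **clonality** — a cell-mixture forward model maps any integer state
  `(a, b)` at clonality `c` to expected (beta, logR); inverting it scores
  each aberrant segment, and
  `VAF = cl·m·(1 − G)/(2G + (1 − G)·cnT)` does the same for SNVs.

A simulator (`tumor_model()` / `simulate_tumor()`) generates matched
inputs from the same generative model with full ground truth, and a
Monte-Carlo error table propagates beta uncertainty into admixture and
clonality bounds.

## Worked example

```r
library(ascnclone)

# a diploid tumor with 30% admixture, clonal deletions and gains
sim <- simulate_tumor(scenario_model("diploid_clean"), seed = 42)

bt <- compute_beta_table(sim$seg_tb, sim$pileup_tumor, sim$pileup_normal)
summarize_beta_table(bt)
#> Computed beta table of sample "sim1"
#> Number of processed segments: 30
#> Number of segments with valid beta: 30 (100%)
#> ...
#> Quantiles of number of informative SNPs per input segment:
#>   0%: 629  ...  100%: 695

pl <- compute_ploidy(bt)
#> ploidy 1.96 (logR shift 0.026)       # truth: 2

adm <- compute_dna_admixture(bt, pl)
#> adm 0.299, bounds [0.270, 0.330]     # truth: 0.30

ascn <- compute_allele_specific_scna_table(bt, pl, adm)
head(ascn[, c("chrom", "start", "logR", "beta", "log2.corr",
              "cnA", "cnB", "cnA.int", "cnB.int")], 5)
#>   chrom start    logR  beta log2.corr  cnA    cnB cnA.int cnB.int
#> 1  chr1 1e+00  0.0487 0.981    0.0320 1.05 0.9952       1       1
#> ...
#> 4  chr1 6e+06 -0.5529 0.463   -0.9198 1.04 0.0162       1       0
#> 5  chr1 8e+06  0.4507 0.741    0.5732 1.98 0.9916       2       1

cl <- compute_scna_clonality_table(bt, pl, adm)
table(cl$clonality.status)
#>  clonal  not.analysed  subclonal  uncertain.clonal
#>       8            18          1                 3
```

Reading the output: row 4 is a hemizygous deletion — beta 0.46 instead of
0 because 30% of the DNA is normal, corrected logR ≈ −0.92 ≈ log2(1/2),
called (1, 0). Row 5 is a single-copy gain called (2, 1). Wild-type
segments are `not.analysed` by the clonality step (there is nothing to
score); the aberrant segments are called clonal, as simulated.

`check_ploidy_and_admixture(bt, pl, adm)` overlays the expected lattice of
integer states on the observed beta-vs-logR cloud — the standard visual
check that the (ploidy, admixture) solution explains the profile — and
can write both the plot and the lattice table to files.

A command-line front end mirrors the R surface
(`inst/cli/ascnclone beta|ploidy|admixture|ascn|clonality-scna|clonality-snv|check-plot|simulate|error-table`).

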