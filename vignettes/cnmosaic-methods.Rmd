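---
title: "Allele-specific copy number and mosaicism from paired SNP arrays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific copy number and mosaicism from paired SNP arrays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnmosaic)
library(dplyr)
```

## The problem

A tumor biopsy is a mixture: chromosomally aberrant cancer cells admixed
with stromal and other diploid cells, and often more than one clone. SNP
genotyping arrays report two signals per marker that together resolve this
mixture where pure copy-number platforms (CGH) cannot:

* **Log R ratio (LRR)** — total intensity, a proxy for total copy number;
* **B-allele frequency (BAF)** — the relative contribution of the B allele,
  sitting at 0, 0.5 and 1 for AA, AB and BB genotypes in pure diploid tissue.

`cnmosaic` implements the paired tumor/normal analysis of these signals:
copy number relative to the matched normal, segmentation, detection of
heterozygote-band splitting in BAF, classification of the underlying
mechanism, estimation of the aberrant-cell fraction, cohort-level recurrent
regions, phenotype association, and drug-target matching.

## The two-population admixture model

For a SNP in a mixture of an aberrant population (fraction $P_1$, $b_1$ B
alleles out of $n_1$ copies) and a normal population ($P_2 = 1 - P_1$,
$b_2$ of $n_2$), the expected BAF and copy number are

$$
B_{exp} = \frac{b_1 P_1 + b_2 P_2}{n_1 P_1 + n_2 P_2},
\qquad
CN_{exp} = n_1 P_1 + n_2 P_2 .
$$

Only markers heterozygous in the matched normal ($b_2 = 1$, $n_2 = 2$) are
informative for band splitting: homozygous markers stay at BAF 0 or 1 under
every mechanism, which is why the package fixes the normal population at the
heterozygous diploid and reads splits only in the "heterozygote pane". The
paired design supplies the normal genotypes directly.

Worked through for a mono-allelic gain (`b1 = 1 or 2, n1 = 3`) present in
90% of cells: $CN_{exp} = 2.9$ and the heterozygote band splits to
$1/2.9 \approx 0.34$ and $1.9/2.9 \approx 0.66$ — at 100% the values would
be the textbook trisomy 0.33/0.67 at CN 3. A bi-allelic gain (`2 of 4`)
raises CN without splitting the band at all, and copy-neutral LOH (`0 of 2`)
splits the band at unchanged CN; these signatures are what make the joint
CN + BAF analysis strictly more informative than CN alone.

## Back-calculation of the mosaic fraction

`enumerate_mosaicism()` inverts the model by exhaustive search: all
karyotypes $0 \le b_1 \le n_1 \le 4$ and all fractions $P_1$ on a 1% grid,
scored against the observed upper band position and segment CN by

$$ r = w\,|B_{exp} - \mathrm{band}| + |CN_{exp} - CN_{obs}|, \quad w = 2. $$

Decisions behind this, where the design was genuinely open:

* **Grid, not optimizer.** The parameter space is tiny (1,515 points) and
  the surface has exact ties; exhaustive evaluation is instant, exact and
  deterministic. Reported fractions in this field are read to the nearest
  5%, so the 1% grid is conservative.
* **Residual weight.** BAF is measured far more precisely than CN (band
  position error shrinks with the square root of the heterozygote count,
  while CN carries array-wide intensity noise), so the BAF term is weighted
  twice the CN term. No quantitative fit metric is conventional here; the
  weight is configurable and results are insensitive to it in all worked
  examples.
* **Ties and parsimony.** Mirrored karyotypes ($b_1 \leftrightarrow n_1 -
  b_1$) predict identical folded bands — A/B labels are arbitrary — and some
  distinct karyotypes coincide algebraically (a `3 of 4` clone at $P$
  matches a `2 of 3` clone at $2P/(1+P)$... exactly on band and CN). Ties are
  broken toward the smaller $|n_1 - 2|$ (the least aberrant karyotype), then
  the smaller $P_1$. Residuals are compared after rounding at 1e-10 so the
  tie-break is immune to floating-point noise.
* **$P_1 = 0$ collapses to normal.** Any karyotype at zero admixture
  predicts a normal heterozygote, so such candidates are labelled `NORMAL`.
* **Mosaic monosomy.** A one-copy clone at observed CN $\le$ 1.05 (at least
  ~95% of cells monosomic) is labelled `MOSAIC_MONOSOMY`; at CN 1.2 (an 80%
  deletion) the call remains a mono-allelic deletion.

## Band detection

`detect_baf_bands()` folds heterozygote BAFs about 0.5 and compares their
10%-trimmed mean against the half-normal expectation
$\sigma\sqrt{2/\pi}$ under no split, declaring a split beyond 3 analytic
standard errors. The trimmed mean of the folded values then estimates the
split deviation $d$ directly. A symmetric-mixture likelihood scan (the test
suite's oracle) agrees within 0.01 across $d \in [0.05, 0.45]$ at noise
$\sigma \le 0.05$; the trimmed mean was chosen over mixture EM because it is
robust, deterministic and sufficient for the mirrored two-band structure.
BAF noise $\sigma$ is estimated per sample from the matched normal's
heterozygote spread. Fewer than 10 informative markers flags the profile
indeterminate rather than guessing.

The qualitative split classes mirror the descriptive interpretation grid
(`table2_label()`): no split below $d = 0.04$ (comfortably above the noise
floor of a ~0.02-0.03 sd array at realistic marker counts), moderate up to
$d = 0.22$, large beyond. These boundaries are conventions chosen so the
canonical worked examples classify to their printed rows (90% mono-allelic
gain, $d = 0.16$, moderate; 80% deletion, $d = 0.33$, large); the grid fit,
not the label, is authoritative — notably cnLOH at 50% mosaicism
($d = 0.25$) would sit beyond the moderate boundary even though its
descriptive row says moderate.

## Paired copy number and segmentation

Per marker, $CN = 2 \cdot 2^{LRR_t - LRR_n}$ against the matched normal,
cancelling shared array effects. Whether to difference LRRs or ratio raw
intensities is equivalent up to normalization; the LRR difference is used.
Segmentation is recursive binary splitting on $\log_2 CN$: the candidate cut
maximizing the Welch t statistic is accepted when both sides keep the
minimum marker count (25 by default, 10 for sparser maps) and the two-sided
p-value clears 0.001, then both sides recurse. This reimplements the
contract of commercial mean-difference genomic segmentation — the original
tool's internals are proprietary, so results are equivalent in behavior, not
bit-identical. Zero-variance sides (noise-free steps) are treated as
infinitely significant when means differ, making noise-free breakpoints
exact. Segment summaries use the geometric mean CN, $\exp(\mathrm{mean}(\log
CN))$.

State calls: amplified at mean CN $\ge 2.5$, deleted at $\le 1.5$, and
copy-neutral only within the conservative band $[1.9, 2.1]$; the gaps are
`INDETERMINATE`. Event segments must span at least 500 kb. A copy-neutral
segment with an unsplit band is `NORMAL` by definition; the grid fit is
interpreted only for abnormal segments, which prevents a 1-2% CN drift from
being "explained" as a tiny admixture.

## Recurrence, association, drug matching

Recurrent regions are maximal intervals where the per-base count of samples
carrying the event (after per-sample merging and the 500 kb filter) stays at
or above $\lceil 0.10 \cdot N \rceil$ — 9 of 86 at the canonical cohort
size. Pointwise coverage was chosen over any-overlap clustering, which is
ill-defined for chains of partially overlapping segments; the reported
support is the coverage at the region's weakest base. cnLOH regions stack
copy-neutral segments with at least a moderate split.

Association tests cross-tabulate per-region sample states (a sample is
amplified/deleted in a region when qualifying segments cover at least half
of it) against phenotypes, stratified by MSI status. Contingency tables are
tested with the Pearson chi-square after dropping all-zero rows and columns
— required so that degrees of freedom reflect the observable table when an
event class never occurs. Region tables use no continuity correction while
2x2 patient-characteristic tables use the Yates correction; this convention
is reverse-engineered from the published p-values, which it reproduces to
their printed precision, and both variants are exposed. Raw p-values are
reported (matching the source analyses); a Benjamini-Hochberg column is
emitted for convenience only. Continuous phenotypes use the equal-variance
one-way F test.

Drug matching applies the therapeutic-mode rules — amplified-region genes
vs. antagonists/antibodies/inhibitors, deleted-region genes vs.
agonists/activators/inducers — with discontinued/unknown-status records
excluded from the default report. Gene lists use full containment
(`min_frac = 1`) by default, with 0.9 exposed for the relaxed aneuploidy
convention.

## The synthetic cohort generator

`simulate_pair()` runs the admixture model forwards: germline genotypes from
the population allele frequency (default 0.5, maximizing informative
heterozygotes), BAF as genotype dosage plus truncated-normal noise (sd 0.03,
clipped to [0,1]), LRR as normal noise (sd 0.15, log2 scale), and within
events the expected BAF/CN conditioned on each marker's germline genotype.
The default map — two 100 Mb chromosomes at a few hundred to a few thousand
evenly spaced markers — is a deliberately scaled-down genome so a full
cohort analysis runs in seconds; tests use 150-2,500 markers per chromosome
and cohorts of up to 30 samples, sizes at which every stage's behavior is
already well exercised.

What the generator does **not** emulate: GC-wave and wave-correction
artifacts, genotyping error, marker-density variation, subclonal mixtures of
more than two populations, and sex chromosomes (autosomes only, as in the
source design). Passing tests therefore demonstrate correctness of the
inference given the stated noise model, not robustness to every artifact of
real array data.

Seeds are mandatory; every cohort is byte-reproducible from its
configuration, and each sample pair draws from a deterministic sub-seed.

## Numerical and degenerate-input conventions

* Marker positions are 1-based inclusive internally (as in array
  manifests); all BED output converts to 0-based half-open.
* Readers reject malformed input (bad numbers, unsorted or duplicated
  positions, unknown categorical levels) with the offending line rather
  than coercing; non-autosomal rows are dropped with a logged count.
* Bands are accepted pre-folded (a single value below 0.5) or as a
  symmetric pair; an empty band list yields `INDETERMINATE`, a CN outside
  $(0, 4]$ is an input error (segment means above 4 are clipped into the
  grid by the pipeline).
* Tables reducing below 2x2 are flagged untestable, with no p-value; the
  Yates correction refuses non-2x2 input.
* ANOVA with zero within-group variance everywhere is flagged degenerate
  (p = 0 if means differ, 1 otherwise).

## Known limitations

Translocations are invisible to this platform and out of scope. The
segmentation p-value applies to the best split per level, not a
scan-corrected family-wide error, matching the emulated tool's contract;
with p < 0.001 and the minimum-marker rules, spurious segments are rare at
the simulated noise levels but not impossible. cnLOH boundaries are found
only where CN segmentation places breakpoints or where the whole segment is
affected, since segmentation runs on CN alone. Mosaic fractions below ~5%
are not reliably distinguishable from normal at default noise.
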