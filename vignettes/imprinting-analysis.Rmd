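---
title: "Methods: allele-specific imprinting analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific imprinting analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintcall)
```

## Scope and data model

`imprintcall` analyses haplotype-resolved gene counts from mouse crosses in
which the parental strains differ at enough SNPs to assign reads to the
maternal or paternal allele. The central container, `allele_counts`, keeps
three matrices (maternal, paternal, total non-haplotyped counts) plus a
logical informativeness mask. The mask is the load-bearing design choice:
every allelic computation treats a non-informative cell as missing while the
total count is always retained, which is exactly the situation in
first-generation backcross (N1) samples where roughly half the genome is
homozygous and carries no allelic signal. Coordinates are 0-based and
half-open throughout; BED-like inputs are read as such. All counts are
validated on construction — a cell where maternal + paternal exceeds the
total is an integrity error naming the cell, because such a file indicates
broken upstream haplotyping rather than noise.

## Calling imprinting in wild type

For each candidate gene (known-imprinted, autosomal, expressed, not
excluded), the wild-type maternal/paternal counts across samples are pooled
and fitted with an intercept-only binomial model with logit link. We use
the closed form of its MLE,

$$\hat\beta = \log\frac{\sum_s m_s}{\sum_s p_s},$$

rather than an iterative fit: the two coincide exactly for an
intercept-only model (the package's tests verify agreement with `glm` to
below 1e-8 over random fixtures), and the closed form is deterministic and
fast. This pooled estimator weights samples by their haplotyped depth; a
depth-unweighted average of per-sample ratios would be an alternative, but
the pooled MLE is the literal optimum of the stated model, so it is what we
implement. When exactly one pooled sum is zero, a Haldane–Anscombe
pseudocount of 0.5 is added to both sums to keep the ratio finite; when
both are zero the gene has no usable signal and the ratio is NA.

A gene is imprinted when $|\hat\beta| \ge \log 1.5$; the boundary is
included. The silent allele is fixed from wild type (paternal when the
ratio is positive) and reused for all genotypes, so that "expression of the
silent allele" always refers to the allele that is silent under intact
imprinting. The per-gene, per-sample silent-allele proportion is
`silent / (maternal + paternal)`, NA at zero depth.

Two filters precede testing. Expression: at least 1 count per million in at
least a third of libraries, computed on the total (non-haplotyped) counts
with library size = column sum; the fraction is compared as a real number,
so 2 of 6 libraries passes. Coverage: a gene must average at least 10
haplotyped counts per sample within every genotype (mean over informative
samples), otherwise allelic proportions are too unstable to test. `Gatm` is
excluded by default because its apparent maternal bias in placenta reflects
maternal decidua contamination, not imprinting; the exclusion list is a
config field.

## Differential imprinting: two engines

**Paired negative-binomial GLM.** Each sample contributes two NB
observations, its maternal and its paternal count. The full design contains
one indicator per sample (the pairing factor), an allele main effect, and
allele × genotype interactions; the null drops the interactions, and the
genotype effect is assessed by likelihood-ratio test against χ² with one
degree of freedom per dropped column. The pairing factor absorbs total
expression and library depth, making the totals ancillary: in the
dispersion → 0 limit the test provably reduces to a binomial logistic
regression on the allelic proportions, and the test suite checks this
reduction to 1e-6. For the same reason all 2n allelic libraries are given
equal effective library sizes — depth belongs to the pairing factor, and
per-library offsets would leak depth into the allele effect. When two Cre
lines are present, an allele × Cre term is included by default
(`cre_in_model`), dropped automatically if it would make the design
rank-deficient. Fitting and dispersion estimation use edgeR's GLM
machinery; dispersion is tagwise for bulk data and common for sparse
single-embryo data, where per-gene estimates are unreliable.

**Fixed-dispersion beta-binomial.** The engine for mosaic informativeness,
where the paired design cannot be assembled. The maternal count given
informative depth $n$ is beta-binomial with mean $\pi$ on the logit scale
(intercept + genotype) and intraclass correlation fixed at
$\phi = 0.01$, so $\mathrm{Var}(y \mid n) = n\pi(1-\pi)(1+(n-1)\phi)$.
Because the genotype groups are disjoint, the full-model MLE separates into
independent one-dimensional problems, solved deterministically by golden
search on the logit in $[-12, 12]$ (tolerance 1e-9, no random restarts);
the same applies to the null. The dispersion is fixed, never re-estimated
per gene: with half the cells missing there is not enough information per
gene, and 0.01 matches both the value estimable from complete-data
experiments and the generator's simulating value, making simulated and
fitted dispersions commensurable. Samples with zero informative depth are
dropped; a genotype left empty yields NA with a reason rather than a
p-value.

**Dual calling rule.** Within one experiment the engine p-values are
Benjamini–Hochberg adjusted across tested genes, and a gene is called when
`p_adj < 0.05` *and* the mean silent-allele proportion shifts by more than
5 percentage points between wild type and the tested genotype. The shift is
the unweighted mean of per-sample proportions (matching how such data are
plotted, one dot per sample), not a ratio of pooled counts. With two Cre
lines the shift is computed per Cre stratum against the matching wild-type
stratum, and the criterion may be met by either — deletion timing in
oogenesis differs between lines, so requiring both would mask real effects.
The effect-size guard exists because at high depth the LRT detects shifts
far too small to be biologically meaningful.

## Informativeness segmentation (N1 backcrosses)

Per sample and chromosome, the CAST read proportion in 100 kb bins is fitted
with an rpart regression tree on bin position, `minsplit = 4`, `cp = 0.05`,
other controls at their defaults. Leaves of a tree on an ordered coordinate
are intervals, so they map directly to segments; the fitted value of a
segment is the mean proportion of its bins. Two points deserve emphasis:

- `cp` acts as in standard CART cost-complexity pruning: the tree is grown
  and then weakest-link pruned at `cp` × root SSE. A split whose own gain is
  below the threshold survives when its descendants jointly earn the
  complexity cost. The package's oracle tests implement exhaustive
  grow-then-prune independently and require exact agreement on every
  fixture up to 64 bins.
- the mapping from leaves to zygosity is not part of the tree: a segment is
  called heterozygous when its fitted proportion is ≥ 0.25, the midpoint
  between the expected 0.5 (heterozygous) and ≈ 0 (homozygous reference).
  The threshold is a config field (`zygosity_threshold`) since it is a
  judgment call, as is the depth guard that sets bins with fewer than 5
  allelic reads to NA (`min_bin_depth`); NA bins are skipped but their
  positions preserved.

Equally optimal splits are broken toward the leftmost index so results are
deterministic. A gene is informative in a sample when the segment
containing its midpoint is heterozygous; genes on chromosomes without
segments are non-informative with a warning. F1 samples are heterozygous
genome-wide and bypass segmentation entirely.

## Methylation analysis

Per-CpG methylated/unmethylated calls are summed over regions (half-open;
overlapping regions each receive a CpG). Imprinted DMRs are testable when
they average ≥ 10 allelic counts per sample in both compared genotypes and
show a ≥ 10 % wild-type methylation difference between the parental
alleles; the wild-type-higher allele is the hypermethylated allele. That
allele's methylated/unmethylated counts then enter the same paired NB
design used for expression — methylation state plays the role of the
allele, the state × genotype interaction is the test — at common dispersion
across regions, BH-adjusted, called at FDR 0.05. The paired interpretation
(meth/unmeth within sample) mirrors the allelic design; the mean wild-type
allelic difference is computed as the mean of per-sample differences.

Genome-wide tests (CpG islands, promoters, 10 kb bins) use the total
non-split counts: per region a binomial logistic regression of genotype,
LRT, BH, and a ≥ 10 percentage-point effect-size requirement, with regions
under 10 total counts excluded. Regions are annotated with the closest gene
within 2 kb (interval distance, 0 when overlapping or book-ended; ties by
distance then by gene start). Single embryos are sexed by the paternal-X
fraction of X-linked bisulfite reads (female ≥ 0.25, a generous margin
under the expectation of ≈ 0.5 for females and ≈ 0 for males) and excluded
when the genome-wide maternal-allele fraction reaches 0.65, indicating
maternal tissue contamination; both thresholds are config fields because
they are operational choices, not published constants.

## The synthetic-data generator

`simulation_scenario()` fixes the study conditions; the generators are pure
functions of (scenario, seed). Totals are negative-binomial (log-normal
gene means, default mean ≈ 100, NB dispersion 0.1 — typical bulk RNA-seq);
an allele-assignable depth is a binomial thinning at haplotyping efficiency
0.8, which reproduces maternal + paternal < total; maternal counts are
beta-binomial with intraclass correlation 0.01 around the
archetype-determined proportion. Imprinted archetypes express the silent
allele at 2 % at baseline; loss of imprinting raises that by
`loi_delta` (default 0.3, i.e. a strong partial loss) in a fraction of
genes in non-wild-type genotypes. Default group sizes (8/8) match bulk
experiments of this design. N1 tracks draw alternating heterozygous /
homozygous segments with a minimum of 20 bins and mean ≈ 150 bins (15 Mb) —
first-generation backcrosses experience only one or two crossovers per
chromosome, so zygosity blocks are tens of megabases — with bin depth
Poisson(50) and a 1 % residual CAST proportion in homozygous segments from
mismapping. Methylation counts are beta-binomial (intraclass correlation
0.05, typical RRBS region-level overdispersion) around class archetypes:
germline DMRs 95 %/5 % across alleles, secondary DMRs 75 %/25 %, CpG
islands unmethylated, with optional genotype shifts on the hypermethylated
allele. By default no methylation shift is simulated, matching the
expectation that germline imprints are maintained.

What the generator does *not* emulate: read-level errors and mapping bias,
reference bias in allelic assignment, gene length and GC effects,
correlated genes within clusters, cell-type mixtures, and chromosomal
abnormalities. Passing tests therefore demonstrate statistical correctness
of the pipeline under its own model assumptions, not robustness to every
artifact of real sequencing data.

## Numerical choices and degenerate inputs

- Beta-binomial likelihoods use `lbeta`/`lchoose` throughout; boundary
  means (0 or 1) are handled analytically.
- LRT statistics are clamped at 0 before the χ² tail, so numerically
  negative differences of converged likelihoods report p = 1.
- The BH adjustment wraps `stats::p.adjust`; NA p-values pass through
  without counting toward the number of tests.
- Zero-variance segmentation inputs return a single segment without
  invoking the tree; chromosomes with no usable bins produce an empty
  segment list and a warning.
- All simulators call `set.seed` internally with stage-specific offsets of
  the scenario seed, so each stage is reproducible in isolation and the
  full pipeline is byte-identical across reruns at the same seed (the
  manifest records MD5 digests to verify this).

## Problem sizes

The test and acceptance suites run the engines on 2000-gene /
2000-region null simulations for calibration, 200 genes for bias, 1000
genes for the calling rule, 25 random fixtures (≤ 64 bins) plus four
whole-genome backcross tracks for segmentation, and the 2000-gene default
scenario end-to-end, sizes at which the whole suite completes in well under
a minute per stage.

## Known limitations

- The paired NB engine requires complete informativeness per gene across
  the analysed samples; genes with missing cells are delegated to the
  beta-binomial engine rather than partially imputed.
- The tagwise dispersion route inherits edgeR's empirical-Bayes moderation;
  `mode = "common"` is available when strict reproducibility across edgeR
  versions matters.
- The genome-wide binomial logistic test carries no overdispersion term;
  with strongly overdispersed methylation its raw p-values are
  anti-conservative, which is why the ≥ 10 % effect-size rule is part of
  the call and why DMRs use the NB engine instead.
- The shipped gene and DMR lists in `inst/extdata/` are synthetic
  placeholders for interface demonstration; real analyses must supply a
  curated annotation.
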