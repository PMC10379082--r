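---
title: "Methods: diversity, differentiation and sweep scans in radsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, differentiation and sweep scans in radsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsweep)
```

radsweep implements the analysis layer that sits between a jointly called
multi-sample VCF and population-genomic conclusions: hard filtering of SNPs,
per-population diversity, sliding-window differentiation, a joint
Z(F~ST~)/log2(π-ratio) selective-sweep scan, linkage-disequilibrium decay and
LD-based effective population size, and structure inference by PCA and
admixture. It is aimed at reduced-representation (RAD-seq) studies of a few
diverged populations — for example wild versus farmed stocks of a marine
fish — where the questions are "how diverse is each population", "how
differentiated are they", and "which genomic regions were swept during
domestication or local adaptation".

Everything operates on one data model: a `variant_table` of per-site
metadata (chromosome, position, alleles, the GATK annotations QD and FS) and
a `genotype_matrix` of allele dosages in {0, 1, 2, NA} with optional
per-genotype read depths. All coordinates are 1-based; all sliding windows
are half-open `[start, start + window)` with starts at 1, 1 + step, …,
matching VCFtools' conventions so results are comparable with the tools
practitioners already use.

## The hard-filter cascade

Filters run in a fixed order, each consuming the survivors of the previous
stage, and each emitting a report row (`n_input = n_removed + n_retained`):

1. **Site annotations.** A site is removed iff `QD < 2` or `FS > 30`
   (strict inequalities, so boundary values survive). Sites lacking both
   annotations are kept and counted: a missing annotation is not evidence
   of a bad site.
2. **SNP clusters.** A site is removed iff it lies in any 35-bp window
   containing more than 3 SNPs. All members of a violating window are
   removed (GATK SnpCluster semantics); the implementation slides over
   sorted positions and flags every run of 4 sites spanning ≤ 34 bp.
3. **Depth masking.** Individual genotype calls with depth ≤ 10 or ≥ 60
   become missing; only the open interval (10, 60) survives. This runs
   *before* the missingness filter, deliberately, so that depth-masked
   calls count as missing downstream. Calls with no recorded depth are
   left alone.
4. **Missingness and MAF.** A site is removed iff its missing-call fraction
   exceeds 0.1 (the complement of `--max-missing 0.9`) or its minor-allele
   frequency among called alleles falls below 0.05; MAF exactly 0.05 is
   retained, which is VCFtools' `--maf` reading. Sites with no called
   genotypes are removed and counted separately.
5. **Hardy–Weinberg.** Sites with an exact-test p below 0.001 are removed.
   The test pools all samples by default — with structured samples that is
   anticonservative (the Wahlund effect depresses heterozygosity), so a
   `per_population` flag tests within populations and removes a site that
   deviates in any of them. Pooled is the default because it is the common
   published practice; which one a study wants is a scientific choice, not
   a numerical one.

The HWE p-value is an exact conditional test: given the observed allele
counts, every attainable heterozygote count h has probability proportional
to `n! / (n_AA! n_Aa! n_aa!) · 2^h`, and the two-sided p sums the
probabilities of all configurations no more likely than the observed one.
The implementation walks the distribution by an upward recurrence from the
minimal h; the test suite checks it against a direct factorial enumeration
for every genotype triple with total ≤ 20, and checks conservativeness on
simulated null data (the test's rejection rate at α = 0.05 stays below
0.05, as expected for a discrete exact test).

## Diversity statistics

Per-site observed heterozygosity is the het fraction among called
genotypes; expected heterozygosity is `2p(1−p)` with an optional
`n/(n−1)` small-sample correction (Nei's unbiased gene diversity, used in
the summary table). The inbreeding coefficient F~IS~ defaults to the
per-individual method-of-moments form (as in PLINK `--het`):
`F = (O_hom − E_hom) / (L − E_hom)` over the individual's called sites,
with `E_hom = Σ (1 − 2p(1−p)·n/(n−1))` at the population's allele
frequencies, averaged over individuals. The population-level `1 − HO/HE`
ratio is available as an alternative estimator (`method = "ratio"`); the
two disagree in general, which is why the choice is explicit.

Windowed nucleotide diversity sums the per-site mean pairwise difference
`2·c_ref·c_alt / (n(n−1))` over the SNPs in each window and divides by the
*window length in bp* (VCFtools `--window-pi` convention). Dividing by the
full window rather than by callable sites makes π a per-base genome-scale
quantity but underestimates diversity where callable density is low; a
`denominator = "snps"` flag gives the per-SNP variant. On explicit
haplotypes the window value equals the classic mean pairwise Hamming
distance per base, which the tests verify exactly (to 1e-12) against an
all-pairs oracle.

## The sweep scan

Differentiation uses the Weir & Cockerham (1984) two-population variance
components: per site, the among-population component `a` and the total
`a + b + c` are computed from sample sizes, allele frequencies and observed
heterozygosities, and a window's F~ST~ is `Σa / Σ(a+b+c)` over its sites —
the "ratio of averages" (VCFtools weighted) estimator, which is less biased
at low per-site information than averaging per-site ratios. Per-site
estimates may be negative; windows with no informative site are excluded.
Sites monomorphic across both populations carry components (0, 0) and drop
out of the ratio.

The scan for one population pair, windows of 100 kb stepping 10 kb:

- `z_fst`: the windowed F~ST~ distribution standardized by its own mean and
  *sample* standard deviation (the field's "Z(F~ST~)"; which sd variant the
  convention intends is never stated, and at thousands of windows the
  difference is negligible).
- `log2_pi_ratio`: `log2(π_reference / π_focal)`, oriented so that large
  positive values mean diversity *loss* in the focal (e.g. farmed)
  population. Windows where either π is 0 are undefined; they are excluded
  from quantile computation and can never be outliers.
- Outliers: a window is flagged iff it sits at or above the empirical 95th
  percentile (type-7 quantile) of *both* statistics simultaneously —
  the marginal-AND reading of a joint top-5% rule, which is the
  conventional one. Both thresholds are returned so that a run on real
  data can be compared against published cutoffs.
- Regions: overlapping or adjacent outlier windows merge into maximal
  regions (GenomicRanges `reduce`); genes overlapping a region by ≥ 1 bp
  are attached and deduplicated.

By construction the flagged fraction is at most 5% of jointly defined
windows. The end-to-end test plants five 100-kb sweeps (focal-population
frequencies pushed 98% of the way to fixation, diversity reduced about
tenfold) in a 100-region two-population genome at background drift
F = 0.05 and requires the scan to recover at least 4 of 5 planted regions
with at most 2 regions called farther than one window from any sweep.

## LD decay and effective population size

Pairwise LD is the squared Pearson correlation of dosages over individuals
called at both sites — composite genotypic r², the estimator PopLDdecay
applies to unphased genotype data. Sites are screened (MAF ≥ 0.05, missing
≤ 0.1) before pairing; only intra-chromosomal pairs within `max_dist` are
formed, and chromosomes exceeding `max_snps_per_chrom` (default 10,000)
are thinned by seeded uniform subsampling. Decay curves average r² in one
0–1 kb bin plus logarithmic bins.

Effective population size per distance bin follows the Sved-type relation
used by SNeP: with recombination fraction `c` at the bin midpoint under a
constant map (default 1 cM/Mb, configurable — no genetic map exists for
the synthetic genome, and 1 cM/Mb is the conventional assumption),
`Ne = (1/(4c)) · (1/r²_adj − α)` dated to `t = 1/(2c)` generations ago,
with the sample-size adjustment `r²_adj = mean r² − 1/(2n)` and the
mutation adjustment α ∈ {1, 2.2} (default 1). The adjustment constants are
documented defaults of this implementation, not claims from any particular
dataset; Ne is monotone decreasing in the bin's mean r², which the tests
assert directly.

A caution the tests make explicit: the rule-of-thumb expectation
`E[r²] ≈ 1/(1 + 4Nc) + 1/n` is reliable only at moderate-to-large `4Nc`.
As `4Nc → 0` it predicts r² → 1, but the neutral-coalescent expectation
for segregating, MAF-filtered SNP pairs plateaus around 0.3–0.45
(Ohta–Kimura-style behaviour, ≈ 1/(3 + 4Nc)). The test suite asserts the
factor-of-two agreement across all bins and therefore documents this
divergence at tightly linked bins: the monotone-decay property and the
Ne recovery hold, while the tight-linkage bins sit below Sved's
prediction — a property of the approximation, not of the estimator.

## PCA and admixture

PCA mean-imputes missing dosages per site, centers by `2p̂`, scales by
`sqrt(2p̂(1−p̂))` (Patterson normalization) and eigendecomposes via SVD.
Monomorphic and all-missing sites are dropped; the sign of each component
is arbitrary, so tests compare up to sign.

Admixture maximizes the standard binomial likelihood
`g_ij ~ Binomial(2, Σ_k q_ik p_kj)` by EM block updates (frappe-style)
from a seeded random initialization (Dirichlet rows for Q, uniform P).
EM rather than quasi-Newton acceleration is a deliberate simplicity
choice: the likelihood target is identical and convergence speed is
acceptable at the scale this package targets. Missing dosages contribute
nothing to the likelihood; P is clamped to `[1e-6, 1 − 1e-6]` for
numerical stability; Q rows remain stochastic by construction of the
update. The log-likelihood is non-decreasing across iterations (verified
per iteration in the tests, up to 1e-6 floating-point slack); K = 1 has
the closed-form solution (pooled frequencies).

`choose_k` keeps the published protocol's defaults — 20 seeded restarts
per K over K = 2…10 — and estimates a cross-validation error by masking a
random 1/`cv_folds` of called genotype cells per fold (5 folds by
default), refitting, and scoring held-out dosages by mean binomial
deviance, the genotype-masking CV that ADMIXTURE popularized. Whether the
published 20 runs varied seeds within or across K is unstated; here each
K gets its own 20 seeded restarts, with run seeds derived from K so that
a best-of-n fit is always at least as good as a best-of-one under the
same master seed.

## The synthetic-data generators

Two generators, deliberately not one:

- **Balding–Nichols (site-independent).** Ancestral frequencies uniform on
  (0.05, 0.95); each population's frequency Beta-distributed around the
  ancestral value with its drift parameter F (E[W&C F~ST~] ≈ F between two
  populations of equal drift); genotypes binomial; missingness Bernoulli;
  depths negative-binomial with mean 30 and size 8 — the mean sits inside
  the (10, 60) retention band so depth masking removes a realistic few
  percent of calls instead of gutting the data; QD/FS drawn from benign
  ranges with optional planted violations. Truth (drift, frequencies,
  planted sites and sweep coordinates) is carried alongside and serialized
  with every written VCF. Defaults are 2 populations × 50 diploids and
  20,000 SNPs — the scale of a small RAD-seq cohort. `plant_sweeps`
  creates the signal class the scan detects: focal-population frequencies
  moved 98% of the way to fixation and about a tenfold heterozygosity
  reduction, other populations untouched.
- **Forward Wright–Fisher (linked variants).** 2N haplotypes per
  population evolve by random union of gametes with Poisson crossovers,
  infinite-sites mutation and purging of fixed sites, burnt in for 10N
  generations from a monomorphic state (≈ 5 coalescent units, ample for
  diversity and LD to equilibrate), with an optional split into replicate
  populations. Defaults: N = 100, 1 Mb, μ = 1e-6/bp (tuned so a 50-diploid
  sample segregates on the order of 2,000 SNPs via Watterson's formula),
  recombination 1e-7/bp. The recombination default is 10 cM/Mb — the upper
  end of biological maps — chosen so the single desk-scale 1 Mb chromosome
  spans ≈ 0.1 Morgans: LD then decays visibly across the simulated window
  and the Ne time axis `t = 1/(2c)` reaches recent generations (t ≤ 50
  needs c ≥ 0.01 M, i.e. pairs ≥ 100 kb apart at this map). When the map
  is known, as here, Ne conversion should use it (`bp_per_cM = 1e5`)
  rather than the 1 cM/Mb fallback.

What the generators deliberately do *not* emulate: linkage in the
Balding–Nichols model (sites are independent, so it cannot test LD), locus
dropout and allele-specific biases of real RAD libraries, indels and
multiallelic sites beyond what the reader drops, reference bias, and
selection other than the planted frequency shifts. Tests passing on these
generators therefore validate the *estimators and their wiring*, not the
upstream genotyping process.

## Problem sizes, determinism, degenerate inputs

The test suite and the acceptance script run at fixed desk scales chosen
as the package's own study conditions: 2 × 50 diploids and 20k SNPs for
F~ST~ recovery; a 10 × 1 Mb genome with five planted sweeps for the scan;
one N = 100, 1 Mb Wright–Fisher population for LD and Ne; 2 × 30 samples
and 2,000 SNPs with K ∈ 1…4, 3 restarts and 3 folds for structure
(function defaults keep the published 20-restart protocol). Every source
of randomness flows from an explicit seed; fixed-seed reruns produce
byte-identical VCFs and identical pipeline manifests, which the pipeline
stage hashes (MD5 per output file) make checkable.

Degenerate inputs are defined, not accidental: windows with no SNPs carry
π = 0 and are flagged `n_snps = 0`; windows with no informative F~ST~ site
are excluded; z-transformation refuses fewer than 2 finite values or zero
spread; π-ratios with a zero numerator or denominator are undefined and
excluded from quantiles; LD pairs with zero dosage variance are skipped;
Ne bins with non-positive adjusted r² yield no estimate; individuals with
no usable sites are excluded from F~IS~ with a warning.

## Limitations

Haplotype-based statistics (XP-EHH, iHS), co-ancestry clustering,
multi-population (> 2) F~ST~, GO/pathway enrichment and model-based
genotype recalibration are out of scope. The π denominator convention,
pooled-HWE default, marginal-AND outlier rule and the Sved-formula caveat
above are the main interpretive choices a user should be aware of; each
has a documented switch or a reported threshold so results remain
comparable across conventions.
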