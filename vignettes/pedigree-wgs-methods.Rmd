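---
title: "Methods: pedigree-aware WGS variant interpretation with pedwgs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree-aware WGS variant interpretation with pedwgs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedwgs)
```

# Scope and model

`pedwgs` re-implements, as tested reusable operations, the bespoke
computations that arise when a multi-generation family is whole-genome
sequenced and a contiguous-gene deletion syndrome, a recessive founder
variant, and a dominant-model phenotype are all segregating at once:

1. **Depth-based deletion detection.** Read depth in fixed-width bins is
   modelled as Poisson with mean $\lambda = \bar{c}\,\cdot\,\mathrm{CN}/2$,
   where $\bar{c}$ is the diploid genome-wide mean coverage and
   $\mathrm{CN}$ the local copy number. A heterozygous deletion
   ($\mathrm{CN}=1$) halves the expected depth; detection flags maximal
   runs of bins whose depth ratio falls at or below a threshold.
2. **Parent-of-origin inference.** Inside a hemizygous region, the observed
   diploid genotype of the carrier collapses to homozygosity for the allele
   of the non-deleted parent. When the suspected-deleted parent is
   homozygous and an unaffected full sibling is heterozygous (an
   *informative site*), the carrier's expected genotype is a Mendelian
   violation: hom-alt when the father is hom-ref (class A), hom-ref when
   the father is hom-alt (class B). The combined consistency fraction over
   informative sites decides `paternal_deleted` versus `no_call`; the
   mirrored test requires maternal genotypes.
3. **Inheritance-model filtering.** Variants are partitioned into
   autosomal dominant, autosomal recessive, de novo, compound heterozygous
   and X-linked dominant tracks, then filtered on population allele
   frequency (cut-off 0.01, relaxed to 0.05 for the recessive-type
   models), caller concordance (≥ 2 pipelines), adjusted p < 0.05, impact
   class (medium/high or loss-of-function), and deleteriousness score
   > 15, with a parallel clinical-significance rescue report and an
   assembly-caller INDEL QC rule (alt coverage < 5 AND chi-square > 10.8).
4. **Phenotype-driven prioritization.** Candidate genes and CNV intervals
   are scored against a patient's HPO term set through a weighted
   knowledge base; scores are normalized to [0, 1] by the maximum, banded
   into confidence tiers (high ≥ 0.5, medium [0.1, 0.5), low < 0.1), and
   stress-tested by exact enumeration of term subsets.

# Synthetic data: what it emulates, what it does not

The generator (`simulation_spec()`, `generate_pedigree_genotypes()`) states
the world the downstream analysis assumes:

* a three-generation pedigree with nine sequenced members and two
  unsequenced connectors, sequenced at a mean coverage of 40X in 100-bp
  bins — the configuration in which the carrier's mother contributes
  alleles but no genotype column, so only the paternal-deletion test is
  decidable;
* founder allele frequencies drawn from Beta(0.5, 0.5), a
  site-frequency-spectrum-like skew toward rare and near-fixed alleles;
* whole-haplotype transmission by default (`recomb_rate = 0`), because the
  origin analysis needs haplotype-scale signal; per-site recombination is
  available for stress tests;
* genotype errors as symmetric swaps to a uniformly chosen different
  genotype at a default rate of 0.005 per genotype. No per-genome error
  rate is published for the study this emulates; 0.005 is a free parameter
  chosen as a realistic order of magnitude for joint-called WGS genotypes,
  and every injected error is logged so tests can recount exactly;
* a deletion plan with the published hg19 breakpoints of the three-segment
  15q11.2–q13.1 event (total 5,501,800 bp), planted on the paternal
  haplotype of the proband as ordinary diploid genotype codes —
  hemizygosity is hidden, exactly as a small-variant caller would report
  it.

It does **not** emulate linkage disequilibrium, demography, GC bias,
read-level artifacts, mappability, or microarray LRR/BAF signal. A green
test therefore establishes that the *operations* are correct under the
stated statistical model, not that the thresholds are optimal for any real
cohort.

## Shared maternal haplotype in the demo

With `recomb_rate = 0`, whether the proband and his brother receive the
same maternal haplotype is a single coin flip per chromosome. If they
differ, class-A/B consistency collapses to the allele-frequency baseline
(~0.4 under Beta(0.5, 0.5)) and no method could call the origin — the
information is genuinely absent. The real family's 92–94% consistency
shows the shared configuration; `pws_demo` therefore pins
`force_transmission` so both brothers carry maternal haplotype 1 across
the region. This is a statement about the scenario, not a tuning knob: the
inference code never sees it.

# Numerical and threshold choices

* **`ratio_threshold = 0.65`, `min_bins = 5`** separate the copy-1
  expectation (0.5) from diploid (1.0): at 40X and 100-bp bins,
  $P(\mathrm{Pois}(40) \le 26) \approx 0.012$ per diploid bin while
  $P(\mathrm{Pois}(20) \le 26) \approx 0.92$ per deleted bin.
* **`max_merge_gap_bins = 5`** (our choice; not externally fixed): ~8% of
  copy-1 bins exceed the cutoff, so unmerged runs would fragment a
  multi-megabase event into dozens of calls. Five bins reunite them while
  keeping diploid noise apart. `min_bins` counts *qualifying* bins in a
  merged run, never the gap bins, so loosely clustered noise cannot form a
  call. Residual behavior at defaults: roughly 1 in 100 simulated genomes
  splits one long segment at an unlucky ≥ 6-bin noise break, and false
  minimal calls in 300,000 diploid bins are of order 0.1 per genome.
  Both rates fall quickly with longer `min_bins`.
* **Edge bins are excluded from `depth_ratio`** to avoid partial-overlap
  bias; a region covering no full bin returns `NA` rather than a value.
* **Origin thresholds `min_frac = 0.8`, `min_sites = 50`**: the worked
  fractions in the motivating data are 92% over thousands of sites, but no
  threshold is published. 0.8 tolerates a few percent genotyping error
  while rejecting deletion-free regions, where the fraction sits far below
  0.6; 50 sites bound the binomial noise of the fraction at about ±0.14.
  Heterozygous proband genotypes inside the region are counted as
  *inconsistent*, not dropped: hemizygosity admits no heterozygote, so
  they are evidence against the call. Missing genotypes drop a site;
  nothing is imputed.
* **Boundary semantics** follow the printed wording strictly: AF > 0.01
  excluded (0.01 kept), CADD > 15 required (15.0 fails), adjusted
  p < 0.05 required, read support kept in [4, 50], deletion size kept at
  ≥ 10 kb, segmental-duplication overlap ≥ 0.5 removed, tier bounds 0.5
  and 0.1 inclusive below.
* **Missing population AF is treated as 0** (never observed in the
  reference panel = novel = rare); missing annotation values otherwise
  make a rule unevaluable and the record is kept with a logged warning,
  never silently removed.
* **`n_combinations()`** evaluates the multiplicative formula with exact
  integer intermediates and errors beyond $2^{53}$ instead of returning a
  rounded value.

# Prioritization scoring is a stand-in

The gene score — a weighted bipartite sum over gene–disease and
disease–term links, plus **one** damped propagation round over gene–gene
links (`damping = 0.5`) — is this package's own transparent surrogate for
proprietary phenotype-prioritization scoring. The published workflow fixes
only the inputs, the [0, 1] normalization, the tier bands and the
downsampling protocol; absolute per-term scores are therefore not
reproduction targets here. One propagation round (not a fixed point) keeps
scores bounded and every contribution auditable. Intervals score as the
maximum over contained genes so that long CNVs cannot win on gene count;
`interval_agg = "sum"` restores the additive variant. Normalization
divides by the maximum raw score across candidates — our reading of
"normalized to a range from 0 to 1", which guarantees the top candidate
scores exactly 1 whenever any signal exists.

Because the raw score is additive over input terms, the subset analysis
(`downsample_analysis()`) evaluates all $\binom{n}{k}$ subsets through a
precomputed per-term contribution matrix; the equivalence of this fast
path with direct `score_entities()` calls is itself a test. Beyond the
cap, subsets are sampled without replacement under a fixed seed (the
original protocol stops at $k = 6$ of 21 terms, i.e. 54,264 exhaustive
combinations).

# Known limitations

* Sex chromosomes: `"X"`/`"chrX"` labels drive the X-linked model; there
  is no pseudo-autosomal-region handling.
* The maternal-deletion mirrored test is undecidable without maternal
  genotypes; such regions return `no_call`, never a guess.
* Uniparental disomy and imprinting defects are out of scope — depth and
  Mendelian-inconsistency signals cannot see them.
* Phased VCF genotypes are carried but phase is not used; compound-het
  phasing relies on transmission only and reports `unphased` pairs rather
  than dropping them.
* The worked consistency figure 1944/2112 = 92% is reproduced exactly;
  the companion printed figure "861/875 (94%)" is arithmetically 98.4%
  and is deliberately not encoded as an expectation.

# A worked run

```{r, eval = FALSE}
b <- run_scenario("pws_demo", seed = 1)
scenario_report(b)
ca <- downsample_analysis(b$terms, 1:6, b$target, b$candidates, b$kb,
                          cap = 60000, seed = 1)
```

Every number the report prints is recomputed from the bundle, and the
acceptance script (`scripts/acceptance.R`) regenerates its reported
quantities from scratch at run time; the vignette intentionally states no
empirical result that the tests or that script do not themselves compute.
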