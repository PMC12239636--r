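---
title: "Models and methods behind neoxmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neoxmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoxmap)
```

# The cross and its genetics

neoxmap analyses F2 intercross genotype data in a species with
neo-sex chromosomes, modelled on the mountain pine beetle
(*Dendroctonus ponderosae*): an X formed by fusion of the ancestral X with
an autosome, paired in males with a large, partly degenerate neo-Y. The
design is a P0 cross between a UT female and an AZ male, an F1 intercross,
and a panel of F2 offspring. Its X-linked transmission rules drive most of
what is special in this package:

* The F1 male carries a single, maternally inherited UT-type X and transmits
  it to his daughters **without crossing over**; his sons receive the neo-Y.
* Every F2 therefore carries exactly **one maternally recombined X**:
  females are AZ/UT or UT/UT, males are hemizygous AZ or UT.
* Consequently F2 males cannot be heterozygous on the X, and F2 females
  cannot be AZ/AZ. Calls violating these rules are artifacts — in the
  motivating data they concentrate where neo-Y reads still map onto the
  neo-X (the "similar" region at the start of the chromosome).

Phase on the X is fully resolved by the design: a female AB call implies a
maternal AZ allele (her paternal X is constitutively UT), a BB call a
maternal UT allele. The package exploits this everywhere rather than
treating the X as a generic chromosome.

# The simulator

`simulate_cross()` generates complete synthetic datasets (genotypes,
phenotypes, and full gamete-level truth) so every downstream stage is
testable without any data download.

**Meiosis.** Crossover counts per gamete are Poisson with mean equal to the
chromosome's map length in Morgans — no interference, which is exactly the
assumption behind the Haldane map function used downstream. Crossover
positions are drawn uniformly in genetic (cM) coordinates and mapped to
physical positions by inverting a per-chromosome monotone piecewise-linear
Marey curve. Recombination suppression therefore emerges from the curve
itself: a flat stretch receives few crossovers no matter how long it is
physically.

**The default genome** (`default_genome()`) has 11 autosomes and one
64.7 Mb X totalling 1069.2 cM (mean linkage group 89.1 cM), with relative
map lengths proportioned after the per-chromosome crossover means of the
motivating cross. Autosomes are acro/telocentric (a pericentromeric 35% of
the chromosome carries 3% of its map). The X is metacentric with its
26–48 Mb interior carrying 12% of the X map (a relative rate of roughly
0.35x): suppressed enough to produce the characteristic Marey plateau, while
retaining enough interior map length that region-restricted processes (for
example viability selection against recombinant male gametes) remain
statistically visible at simulation scale. The X also carries, by default,
a segregating 18 Mb inversion (40–58 Mb in reference coordinates) plus
smaller ones on chromosomes 2 (3.7 Mb) and 3 (5.5 Mb): marker *reference*
positions inside an inversion are reflected about the interval, so the
reference order disagrees with the true meiotic order, as it would after a
real inversion or a mis-scaffolded reference.

**Phenotypes.** Generation time follows an X-linked single-QTL model with
class means by sex and maternal-gamete origin; defaults are the population
means of the motivating system (hemizygous AZ males 149 d, UT males 76 d),
heterozygous females shifted toward the UT mean (95 d, partial dominance of
the short-generation haplotype), residual SD 10 d. Body size is
deliberately polygenic — 20 autosomal loci of equal small effect (totalling
the ~0.09 mm AZ–UT pronotum difference) plus noise — giving the scan a
"no detectable QTL" negative-control regime.

**Observation model.** Per call, independently: missingness (default 5%),
genotyping error (default 0.001, a uniformly chosen different code), and —
for male X calls inside the similar region — neo-Y contamination that turns
hemizygous calls heterozygous. The contamination default is 0.01 per call:
large enough that the artifact class is clearly present, small enough that
the marker-level cleanup (below) does not delete the whole region. At 0.05,
with ~100 males, essentially every similar-region marker accrues two or
more flagged individuals and the region would vanish from the map, which
contradicts how such data behave in practice. DP and GQ fields are Poisson
draws so the quality filters have something to act on.

**Viability selection.** An optional model removes (by rejection sampling)
male F2s whose maternal X gamete recombined inside a region — default
26.9–49.0 Mb with survival 0 — reproducing a crossover-free male region
while leaving females untouched.

Every dataset uses a single RNG stream from one recorded seed, so fixtures
are bit-reproducible. What the simulator does *not* emulate: read-level
errors, linked-read artifacts, family structure effects beyond exchangeable
F2s, segregation distortion of biological origin, and neo-Y gene content.
Passing tests on simulated data show the estimators are correct under the
stated model, not that real data meet the model.

# QC cascade

`run_qc()` applies, in fixed order: call-quality filtering (GQ > 30,
DP > 20, strict; non-biallelic/indel sites dropped) → parental-informative
site selection (both P0s called, homozygous, different) with polarization of
alleles into AZ/UT origins and restriction to the named chromosomes →
marker missingness (≥ 68% missing removed) → individual missingness (≥ 99%)
→ greedy 1-per-100 kb thinning (keep-first) → X impossible-genotype
flagging and resolution → autosomal segregation-distortion filter
(chi-square against 1:2:1, 2 df, P < 0.01; the X is exempt because male
hemizygosity skews its genotype table by design).

Markers are filtered before individuals because the source protocol
describes marker-level cleanup first; both missingness filters also have an
absolute-count mode (< 75 genotypes per marker, < 100 calls per individual)
since protocols are sometimes stated that way. X flags from both reasons
(male heterozygous, female AZ/AZ) share one resolution rule: a marker
flagged in two or more individuals would require double crossovers and is
dropped whole; single flags are set missing.

# Linkage maps

**Pairwise rf.** Autosomal pairs are estimated by EM over the phase-known F2
transmission model; the E-step has a closed form on the 9-cell joint count
table, which lets the implementation run vectorized over all pairs at once.
X–X pairs reduce to direct recombinant counting on resolved maternal-gamete
origins (the complete-data MLE is the EM fixed point). LOD is the log10
likelihood ratio against r = 0.5.

**Order validation.** Linkage groups follow the reference chromosome
assignment. Within each group, markers whose strongest inter-chromosome LOD
exceeds their strongest intra-chromosome LOD are removed as probable mapping
errors; then hill-climbing minimizes the chained two-point Haldane length
with two move classes, both accepted only on strict improvement:
single-marker relocation (left-to-right scan, ties keep position) and
contiguous-block reversal. Block reversals are essential in practice:
a segregating inversion presents as a perfectly reversed block, which
relocation alone unwinds only through a long sequence of moves and tends to
stall near (but not at) the true order — on simulated data the residual
misordering inflated the X map by ~45%. With reversals the recovered order
matches the true-order estimate exactly. No "rippling" (windowed exhaustive
permutation) is performed. Moves must shorten the map by more than
`min_improve_cm` (default 1 cM): in recombination-suppressed stretches all
orders are nearly likelihood-equivalent, and chasing sub-cM noise
improvements scrambles marker order there — occasionally into spurious
>10-marker reversed runs at telocentric chromosome starts — whereas genuine
misplacements save many cM per move. Markers separated by no recombinant
remain order-unidentifiable in principle; their relative order is handled
at the Marey stage (below).

**Multipoint estimation.** `estimate_map()` is EM on a hidden Markov model
whose hidden states are true genotypes: autosomes use a 4-state phase-known
chain (each gamete's origin; collapsing to the usual 3 genotype classes in
the likelihood but giving the M-step a closed form — expected recombinant
gamete transitions), the X a 2-state maternal-origin chain with sex-specific
emissions. Emissions allow mis-genotyping with probability `error_prob`
(default 0.001); cross-impossible X codes carry no signal rather than
crashing. The E-step is scaled forward–backward vectorized over
individuals; convergence is |Δ log-lik| < 1e-6 (capped at 1000 iterations,
with a convergence flag); the likelihood trace is stored so monotonicity is
testable. Adjacent recombination fractions convert to cM by Haldane
(default) or Kosambi. With an `error_lod_cutoff` (log10 posterior error
odds, default 4 in the pipeline), calls the fitted model considers almost
certainly wrong are set missing and the map re-estimated once.

Two systematic effects are worth knowing. First, a map spans its terminal
markers, not the chromosome ends, so sparse panels under-estimate length by
roughly the uncovered end fraction. Second, a nonzero error model absorbs
isolated true double-crossovers as "errors", shrinking maps by a few cM;
the same happens in any error-aware mapper. Both effects are well inside
the 10% recovery tolerance at study scale (181 F2, 822 markers).

**Sex-specific maps** re-run the final estimation on male-only and
female-only submatrices under the same order. No normalization is needed —
both sexes inherit exactly one maternally recombined X — so X map lengths
are directly comparable between sexes.

# QTL scans

`scan_em()` is EM interval mapping: QTL genotype probabilities on a 1 cM
grid (markers always included) come from the same HMM with pseudomarkers as
data-free positions; at each position a normal mixture over QTL genotype
classes is fitted by EM with those probabilities as mixing proportions, and
LOD compares the mixture to the null single normal. On the X the classes
are maternal-gamete origins, the null includes sex as a mean covariate, and
class means are fitted within sex — sex and X genotype are confounded in
this design, and the sex-aware null prevents a spurious X-wide signal. The
implementation is vectorized across grid positions, which is what makes
permutations affordable.

`permutation_thresholds()` permutes phenotypes (freely for the autosomal
null, within sex for the X null), records separate max-LOD null
distributions for autosomes and X, and partitions the genome-wide alpha by
map length: `alpha_A = 1 - (1-alpha)^(L_A/L_T)`, `alpha_X =
1 - (1-alpha)^(L_X/L_T)`. This is the standard X-aware threshold
construction for an F2 X chromosome. With a strongly bimodal trait the
mixture can fit bimodality wherever genotype probabilities are soft, so
null X LODs are heavy-tailed when the marker order is wrong — one more
reason order repair precedes scanning.

`bayes_interval()` normalizes 10^LOD over one chromosome's grid and expands
greedily from the peak, always adding the heavier neighbouring position,
until 95% of the mass is covered; bp bounds come from interpolated marker
positions. For body size, scans can optionally regress sex out of the
phenotype first (`adjust_sex`), since the sexes differ in size.

# Marey analysis

`marey_table()` pairs each marker's reference bp with its map cM, in map
order. Markers tied in cM (no recombinant between them) have no
identifiable internal order, so tie blocks are oriented along the physical
trend of their flanking markers — the most parsimonious choice, and the one
that lets genuinely reversed runs surface instead of being chopped up by
arbitrary tie order. Ties are grouped with a 1e-3 cM tolerance because
estimated recombination fractions are floored just above zero.

`detect_inversions()` reports maximal runs of **strictly decreasing**
physical position of length ≥ 11 (i.e. more than 10 markers), with
endpoints at the run's min/max bp. Calls are labelled putative: a run is
equally consistent with a segregating inversion or a reference
mis-scaffold, and the package takes no position on which.
`reverse_within_inversions()` re-assigns bp within each call in reversed
order so local rates are not forced negative; on single-inversion data a
second detection pass finds nothing (fixed point).

`local_recomb_rate()` fits, at each marker, a tricube-weighted local
polynomial (degree 2, span 0.7 — the span the field's Marey tooling uses)
of cM on Mb, and takes the analytic first derivative as the rate; this is
hand-written because `stats::loess` does not expose derivatives. Negative
rates are retained. `gene_density()` counts protein-coding genes per
half-open 500 kb window by start coordinate (deterministic, and window
counts conserve the total). `rate_density_regression()` pairs each marker
with its window's density and fits OLS after excluding markers whose rate
is negative *and* deviates from the chromosome's median rate by more than
3 MADs — an operationalization of "markers that do not follow the pattern
of surrounding markers and skew rates negative"; the rule and threshold are
exposed as arguments.

# Crossover analysis

`count_crossovers()` is minimal (obligate) counting: origin transitions on
the X; on autosomes the per-step obligate cost (hom↔opposite-hom 2,
hom↔het 1, equal 0), which provably equals the exhaustive minimum over
gamete assignments (tested against full enumeration to length 8).
`compare_sexes()` runs two-sided Wilcoxon rank-sum tests per chromosome
(normal approximation with tie correction; W is the female sample's
Mann–Whitney statistic — conventions differ across software, so this is
fixed and stated) with Bonferroni correction over 12 linkage groups.
Region-restricted variants (exclude the first 25 Mb; ancestral-X only from
48 Mb; arbitrary windows) and the AZ/UT tally among non-recombinant males
(with an exact binomial test against equal transmission) mirror the
descriptive analyses of the motivating study.

# Coverage stratification

`window_coverage()` averages depth in 50 kb half-open windows and
normalizes by the sample's **autosomal** windowed mean (the X ratio then
reads directly as copy number; the alternative genome-wide denominator
would fold the X's own deficit into the normalizer).
`classify_strata()` labels windows by the male:female ratio — hemizygous
≤ 0.6, similar ≥ 0.85, intermediate between — smooths runs shorter than 5
windows into the longer flanking run, and merges labels into segments. The
motivating analysis classified these strata visually; the thresholds here
are an explicit, configurable operationalization, and on simulated step
data they recover breakpoints to within one window.

# Pipeline, seeds, and problem sizes

`run_pipeline()` chains simulate (optional) → QC → ordering → maps (+
sex-specific) → scan + thresholds + credible interval → Marey → crossovers
→ coverage, writing per-stage artifacts (VCF, TSVs, JSON summary; VCF/GFF
coordinates 1-based inclusive, BED and window outputs 0-based half-open).
One top-level seed fans out to stages by fixed offsets, so a run is
reproducible from its config and seed. The R functions themselves are the
interface; `scripts/acceptance.R` is the one scripted entry point, and it
reruns the package end to end.

Problem sizes used by the shipped checks, chosen as this package's own
testing design: map recovery at the study scale (181 F2, 822 markers);
QTL threshold estimation with 500 permutations and credible-interval
coverage over 50 noise-free replicates on an X-plus-one-autosome genome
without the X inversion (with an inversion, "the" true reference position
of a QTL inside it is ambiguous), with 200 kb X markers and a 0.1 cM scan
grid — under the 149-vs-76-day effect the posterior collapses to the
breakpoint-free span around the QTL, so coverage of a continuous true
position requires a grid fine enough to represent between-marker locations; null calibration from 200 phenotype redraws against one
simulated genotype panel (permutation thresholds condition on genotypes, so
redrawing phenotypes is the matching null) and 200 null X chromosomes for
the sex comparison; the viability signature from 50 X-only replicates of
2000 F2s each, noise-free — the region's detectable map length is ~16 cM
against a between-sex sampling SD of ~5 cM at that size, so the direction
of the male–female difference is essentially always identifiable.

# Known limitations

* Marker ordering is a local search; pathological rf noise can leave
  residual misorder, and order within zero-recombination blocks is
  unidentifiable in principle.
* The scan fits a single QTL with at most a sex covariate; no multiple-QTL
  or epistasis models.
* The inversion detector requires strict monotone decrease; inversions
  hidden entirely inside a zero-recombination block are undetectable from
  linkage, as they are for any method.
* Linkage groups are taken from the reference chromosome assignment; de
  novo group formation is out of scope.
* Real-data effects outside the observation model (allele-specific mapping
  bias, family structure, biological segregation distortion) are not
  simulated, and the calibration results should be read with that in mind.
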