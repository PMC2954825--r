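---
title: "Scanning a locus for long-term balancing selection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning a locus for long-term balancing selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(balsel)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the tunable parameters and why their defaults are what
they are, what the synthetic-data generators do and do not emulate, and the
design choices made where the underlying procedures were open to
interpretation. It states no empirical result that the test suite does not
itself compute.

## 1. The scan model

The scan asks whether a candidate locus departs from neutrality in the
direction expected under **long-term balancing selection**: an excess of
intermediate-frequency variants and an excess of polymorphism relative to
divergence, assessed against a panel of neutral control regions sequenced in
the same samples.

### Data model and QC

Input is a rectangular matrix of **phased haplotypes** (two rows per
diploid) over 1-based locus coordinates, with per-position region classes
(coding / non-coding) and optional amplicon spans. Variants within the
first and last 50 bp of an amplicon are discarded (`edge_bp = 50`,
boundary-inclusive: offsets 1..50 from either end), reflecting the elevated
error rate at amplicon edges in Sanger resequencing. Singletons and
triallelic sites are **flagged, never silently dropped** — the original QC
protocol *reviewed* such sites rather than removing them — with an opt-in
strict mode that drops triallelic sites. Sites with missing calls keep a
per-site called-chromosome count `m`; nothing downstream assumes complete
data.

Ancestral states come from a single aligned outgroup sequence: a site is
polarized only when the outgroup base matches one of its two segregating
alleles; otherwise it stays unpolarized and contributes to folded (but not
unfolded) spectra. Polarization never changes which sites count as
segregating.

### Site-frequency spectra and projection

Missing data make per-site sample sizes unequal, so all sites are projected
to a common size `n` (default **15 chromosomes**, small enough that sites
with moderate missingness survive the `m >= n` requirement) using the
hypergeometric weights `w(j) = C(d,j) C(m−d, n−j) / C(m,n)`. We take the
**expectation** over the projection distribution rather than sampling one
outcome: the per-site statistic fed to the rank test is the expected folded
minor count, a real number. This is deterministic, reproducible, and
matches the expectation-based spectra used for display; the alternative
(sampling a projected outcome per site) adds noise without adding
information. Mass projected to monomorphism (`j = 0` or `j = n`) is
reported as `discarded_mass`, never silently dropped.

### The three tests

**Tajima's D** with the 1989 constants. Positive D means the pairwise
estimator (weighted towards intermediate frequencies) exceeds the
segregating-sites estimator — long internal branches.

**MWUhigh** is a one-sided Mann–Whitney U comparing the candidate's
per-site expected folded frequencies against the pooled control sites,
significant only for a shift towards *higher* folded frequencies. Ties get
midranks. For combined sizes up to 12 the p-value is computed by exact
enumeration of all `C(N, n1)` assignments; beyond that, a normal
approximation with tie correction and continuity correction 0.5. The two
paths agree to about 0.01 on tie-free data at the crossover sizes; with
heavy ties at those tiny sizes the discrete U distribution is lumpy and the
normal approximation can be off by several percent — which is exactly why
the exact path exists and is the default there.

**HKA** in its classic two-locus form, with the pooled controls as the
neutral partner locus (a multi-locus extension is deferred; pooling matches
how the control panel is used by the other tests). Moment equations
`θ_i (a1_i + T + 1) = S_i + FD_i` and `Σ θ_i a1_i = Σ S_i` are solved by
bracketed root-finding on `T`; the variances include the `θ²` terms from
coalescent noise. The `χ²(1)` p-value is reported as a secondary
*analytic* diagnostic; the primary p-value is simulation-based.

### The coalescent null

Significance is assessed against an event-driven **structured-coalescent
simulator** written for this package: demes with piecewise-exponential
sizes, joins, migration-rate changes; recombination via ancestral-segment
tracking (tskit-style edge tables record every marginal tree);
exchangeable samples. The demographic null is the widely used
three-population African/European/Asian model with its published point
estimates embedded as overridable defaults (ancestral N 7310; African
expansion to 12300 at 8800 generations; out-of-Africa bottleneck 2100 at
5600 generations; European/Asian split 848 generations ago at sizes
1000/510 growing at 0.004/0.0055 per generation; the published symmetric
migration rates). Since the null has three demes, the six sampled
populations map onto them: the two African samples to the African deme,
the East Asian sample to the Asian deme, and the European, Middle Eastern
and South Asian samples to the European deme by default (configurable) —
the coarsest defensible assignment given the model.

Design choices in the simulator:

- **Time units** are `2N_ref` generations, so a sample pair in a
  constant-size population coalesces at mean 1 (the unit closed form the
  tests verify).
- **Recombination**: the quoted rate of 10⁻⁶ per bp is interpreted as the
  population-scaled `ρ = 4Nr` per bp (it is quoted in an ms-simulation
  context); a config switch (`rho_unit = "per_gen"`) gives the
  per-generation reading instead.
- **Fixed-S conditioning** ("conditioned on the total number of
  informative sites") is implemented by placing exactly `S` mutations on
  branches with probability proportional to branch length × span — direct
  placement, not rejection sampling. "Informative sites" is read as total
  segregating sites for the SFS tests; for HKA the divergence side is
  matched through calibration (below). A θ-driven Poisson mode exists for
  parametric uses.
- **Outgroup divergence** is a stem branch of scaled length
  `outgroup_scale`; with fixed-S conditioning the implied mutation rate is
  `S / total_tree_length`, so fixed differences are Poisson with mean
  `outgroup_scale × S / total_length` (linear in the scale).
  `calibrate_divergence()` root-finds the scale so that simulated data hit
  a target SNP-per-fixed-difference ratio (the control regions' observed
  0.82) within 5% relative tolerance — any misfit between the demographic
  point estimates and the true divergence is absorbed here rather than by
  re-fitting demography.
- **Empirical p-values** use the add-one estimator
  `(1 + #extreme)/(1 + N)`, so `p = 0` is never reported; displays render
  values below `1/N` as `< 1/N`.

### Haplogroups and dating

The two deep clades are recovered by **complete-linkage** agglomerative
clustering on Hamming distances — complete linkage because single linkage
chains through recombinant haplotypes; reticulation-aware network layout is
out of scope. Diagnostic sites are those whose alleles separate the two
groups perfectly (with a reported "nearly diagnostic" tier allowing one
crossover haplotype by default). The TMRCA estimator replaces a
network-internal rooting with a deterministic, testable one: the root is
the outgroup-inferred ancestral allele vector, `rho` is the mean mutational
distance of haplotypes to that root, and its dispersion uses the branch
decomposition `σ² = Σ_s c_s² / n²` (each segregating site is one mutation
on a branch with `c_s` sampled descendants). Calibration takes the locus
mutation rate from the fixed differences accumulated along *both* lineages
since outgroup divergence: `μ = FD / (2 T_div)` with `T_div` = 6 Myr by
default. Because a published dating depends on unstated options of the
original network software, the package's estimator is validated by
parameter recovery on fixtures with known coalescent ages — not by
matching any published point estimate.

## 2. Splicing and NMD

Donor (5′) sites are scored over the 9-mer spanning positions −3..+6. Two
models plug into the same interface: a **table-driven maximum-entropy
model** that reproduces the published scorer exactly (consensus GT factor ×
a 16384-entry table indexed by the seven non-GT positions, log2 scale) —
the table is an external download, deliberately not shipped — and a
built-in **toy PWM** assembled from canonical human donor base frequencies
so that everything runs offline. The toy PWM's +3 column was given a
stronger A/G contrast than raw marginal frequencies would imply, because a
single-position PWM cannot otherwise express the A-versus-G strength
difference that the maximum-entropy model derives from positional
dependencies; its absolute scores are not comparable to published ones.

Donor choice is an operationalization (the source analyses only report the
per-allele outcome): the highest-scoring candidate at or above a threshold
wins, exact ties go upstream, and if nothing reaches the threshold the
nearest candidate downstream of the canonical site is activated. The NMD
boundary is 50 nt (the cited requirement spans 50–55 nt): a stop codon
whose last base lies at least 50 nt upstream of the final exon–exon
junction flags the transcript, with the distance convention pinned down by
boundary tests (49 nt is spared). Coordinates are 1-based inclusive in
gene space, 0-based half-open internally for mRNA arithmetic, 1-based in
reports.

## 3. Assay statistics

**Allele-specific expression.** The standard curve regresses
`log2(B:A ratio)` on `ΔCt = Ct_A − Ct_B` — the standard
allelic-discrimination practice; the source describes the procedure but
prints no equation. Fits with `R² < 0.9` are refused. Unknowns map
through `ratio = 2^(slope·ΔCt + intercept)`, averaged over replicate wells
with an SEM. A heterozygous genomic-DNA control must recover ratio ≈ 1,
which is both a validity check on real plates and the reportable quantity
on synthetic ones.

**Flow cytometry.** Surface-marker MFI is standardized by dividing by the
constitutive marker's MFI per sample. Outliers are fenced per
experiment × genotype group at quartiles ± 1.5 IQR with
linear-interpolation quartiles (type 7) — the convention is documented
because the fenced set depends on it; groups smaller than 4 pass through
flagged. With the default generator (6 samples per cell) a fence can
remove 2 of 6 samples (33%) in an unlucky group, so the sanity bound the
tests assert is dataset-wide (≤ 25% overall, never more than 2 per cell)
rather than per-group. Inference is a per-experiment **Welch** t-test
between the homozygote genotypes (the source says only "T-test"; unequal
variances is the conservative default) and an additive two-factor ANOVA
with experiment entered before genotype, so the genotype F-test is
adjusted for between-experiment differences; no interaction term, matching
the stated two-factor design.

## 4. What the synthetic data emulate — and what they do not

The generators restate the study's design as defaults: 30 diploids from
each of six populations (360 haplotypes), an 8,794-bp locus with 2,883 bp
coding, 79 segregating sites at the candidate, 47 control regions with ~6
SNPs each (≈ 287 pooled), a 6-Myr outgroup, a clade split age of ≈ 1.4 Myr
(generation time 25 years), and clade frequencies 0.5.

Balancing selection is emulated **structurally**: the two allelic classes
are simulated as demes of relative size 0.5 with no exchange that merge at
the split time. This reproduces the signatures the tests consume — deep
clades at intermediate frequency, excess intermediate-frequency variants,
high polymorphism — at desk scale, without forward simulation of selection
coefficients. Consequences a user should keep in mind:

- class frequencies are hit exactly by construction (deterministic
  rounding), not maintained by a dynamic equilibrium;
- population structure *within* allelic classes is ignored in balancing
  mode (labels are dealt out evenly), so F_ST-like signals are absent;
- there is no sequencing-error model, no recurrent mutation (infinite
  sites), and fixed differences are generated from the implied per-locus
  rate, so divergence is exchangeable with the dating calibration but not
  an independent mutational clock.

A green test on these fixtures therefore establishes that the estimators
recover the parameters of this stated world at the stated sample sizes —
not that any particular real locus would reach significance.

The toy gene fixture mirrors the splice biology: a five-exon gene whose
intron-3 donor carries the allele-dependent base at intronic position +3
(9-mers ATGGTAAGG / ATGGTGAGG), a cryptic donor 56 nt downstream whose use
extends the exon, and two in-frame stops in the extension placed so the PTC
sits 197 nt upstream of the final junction (NMD-positive), while the
canonical stop lies in the last exon. Under the toy PWM the two allele
9-mers score 9.07 and 8.10 with the gene's threshold at 8.6 — chosen once,
between the two scores, when the fixture was designed.

## 5. Numerical choices and degenerate inputs

- Projection requires `m ≥ n`; sites below the target are dropped and
  counted, not imputed.
- `S = 0` makes Tajima's D undefined (error; report a null result
  upstream), and an all-zero S or FD total is a degenerate HKA input
  (error).
- The HKA root-finder brackets `T + 1` in `(0, ∞)`; the bracket is grown
  geometrically before `uniroot`.
- Monte-Carlo test tolerances are 3 standard errors unless a criterion
  states otherwise; simulation sizes in the test suite are scaled to a
  single-CPU budget and noted where they matter.
- The divergence calibration refuses to run without fixed-S conditioning
  and errors after a bounded number of batches instead of looping.
- Haplogroup partition of identical haplotypes is an error (no structure),
  and star-like data are flagged `low_support` (between/within diameter
  ratio < 2) rather than silently returning an arbitrary split.

## 6. Known limitations

- The simulator is single-locus; linkage between the candidate and other
  scanned loci is out of scope (only a basic pairwise r² utility is
  provided).
- The HKA implementation is strictly two-locus (candidate vs pooled
  controls); a multi-locus version would weight control regions
  individually.
- rho-based dating ignores uncertainty in the calibration rate `μ` and
  assumes the outgroup stem carries `2 T_div` worth of mutations exactly;
  both are acceptable at the precision the dispersion `σ` conveys, and the
  parameter-recovery test quantifies the net effect.
- The maximum-entropy splice model is exact only with the published
  tables installed; the toy PWM is a stand-in for offline operation, not a
  scientific substitute.
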