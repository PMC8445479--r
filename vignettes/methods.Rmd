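---
title: "Methods: mainland-island genome scans for local adaptation"
author: "adaptscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mainland-island genome scans for local adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

adaptscan reimplements, as a tested pipeline, a complete genome scan for
local adaptation contrasting two diverged sheep populations (mainland vs
island) genotyped on a 50k SNP array: quality control, population structure,
F_ST and FLK differentiation scans with empirical outlier calling, LD-score
and LD-decay comparison, a mixed-model association scan of origin, spatial
autocorrelation of genetic structure, and a loess-based diagnostic of the
selective process. Because the original genotypes are not publicly
deposited, every statistical property of the pipeline is established on
synthetic data with known truth; the generator is a first-class, tested
module. This vignette records the models, the numerical choices, and what
the passing tests do and do not establish about real data.

## The data model

Genotypes live in a `GenotypeData` container (a `SummarizedExperiment` with
one `dosage` assay): markers x samples, integer counts (0/1/2) of the B
allele, `NA` for missing. The counted B allele is the second allele column
of a BIM record. Positions are 1-based inclusive at all I/O boundaries;
internal window arithmetic is half-open. Markers are stored sorted by
(chromosome, position), and only the ovine autosome labels "1".."26" are
retained by the readers. MAF, F_ST, r2 and the LD statistics are invariant
to the A/B labelling; association effect signs are not, which is why the
convention is fixed and documented.

One text-format caveat: a PED file cannot say which allele a monomorphic
marker is fixed for, so the text reader assigns a single observed allele to
allele A (dosage 0). Round-trips are exact for polymorphic markers in
PED/MAP and for all markers in BED/BIM/FAM.

## The synthetic-data generator

The generator defines the study conditions; its defaults mirror the sampled
design: 90 mainland and 147 island animals, 26 autosomes of 100 Mb, 1500
markers per autosome (about 39,000 genome-wide, the post-QC marker density
of a 50k array), background differentiation `c = 0.05`, LD decline rate
0.11 per kb, 0.5% missing genotypes.

**Allele frequencies.** Per marker an ancestral frequency
`p0 ~ Uniform(0.05, 0.95)` is drawn and each population's frequency follows
the Balding-Nichols model, `p_i ~ Beta(p0(1-c)/c, (1-p0)(1-c)/c)`, whose
mean is `p0` and variance `c p0 (1 - p0)`. Under this model the
Weir-Cockerham multi-locus estimator recovers `c` (tested at
c = 0.02, 0.05, 0.1). Degenerate Beta draws (numerically 0 or 1) are
redrawn.

**Linkage disequilibrium.** Haplotypes are generated per population by a
first-order latent-Gaussian process along each chromosome: a standard AR(1)
latent variable with autocorrelation `exp(-lambda d)` over `d` kb,
thresholded at `qnorm(p_j)` to produce the allele. A direct binary Markov
chain cannot hold a target correlation under heterogeneous marker
frequencies (conditional probabilities clip, and the attenuation compounds
along the chain), which is why the latent-variable form is used; it is
still Markov of order one. The decay constant is calibrated as
`lambda = 4 beta / 33.7`, the constant fixed by fitting the Sved curve
`r2 = 1/(1 + 4 beta d)` to the model's population-level r2 profile with
marker frequencies uniform on the simulated range. The calibration is
approximate by construction — an AR(1) correlation is exponential in
distance while the Sved curve is hyperbolic — and the generator's recovery
tolerance (25% relative error on the fitted beta) reflects that
approximation. Measured recovery at 2 x 200 samples is within about 10%.

**Planted selected loci.** A locus "under selection" is planted in the
geometry that long-term local adaptation produces and that the diagnostic
module is designed to recognise: the selected allele near fixation in
population 1 (`p1 = 1 - min(0.005, (1 - t)/20)` for target differentiation
`t`) and at the intermediate frequency `p2` solving
`theta(p1, p2) = (p1-p2)^2 / ((p1-p2)^2 + p1 q1 + p2 q2) = t` in population
2. Planting realizes the requested differentiation exactly rather than as a
high-variance Beta redraw, emulating strong divergent selection.
Hitchhiking is modelled explicitly: for each linked neighbour the allele
riding the swept haplotype (B with probability `p1_j`) is dragged toward
fixation in population 1 with a weight Gaussian in distance, halving at
`sweep_halfwidth_kb` (default 150 kb — a compact footprint of a few hundred
kb; an exponential tail was rejected because it boosts the entire +-1 Mb
diagnostic window and erases the within-window contrast the classifier
relies on). This regional footprint is what gives the loess profiles
something to detect; a single planted SNP alone carries no regional
pattern.

**Relatives, missingness, coordinates.** Parent-offspring-like pairs are
planted by copying one haplotype of a sample from its partner (expected
pi-hat near 0.5); they are added after the frequency draws so they perturb
HWE and the GRM the way real cryptic relatedness does. Genotypes are masked
missing uniformly at `missing_rate`. Samples receive planar coordinates
from two Gaussian clusters (centres 10 units apart, jitter 0.5), the
spatially separated sampling the Moran's I stage expects.

**What the generator does not emulate:** coalescent genealogies,
recombination hotspots, mutation, ascertainment bias of array SNPs,
cross-population LD (each population's haplotypes are generated
independently, sufficient because no cross-population LD statistic is
computed), and genotyping error beyond missingness. Passing tests therefore
establish calibration and power under a clean two-population drift model,
not under every artefact of real array data.

## Quality control

Sample level: call-rate filter (strictly below 0.95 excluded), then
identity-by-descent pruning. Pi-hat is the PLINK `--genome`-style
method-of-moments estimator: IBS counts per pair against their expectations
under IBD state 0/1/2 computed from sample allele frequencies, solved
sequentially for P(IBD=0), P(IBD=1), P(IBD=2), clipped and normalised,
`pihat = P(IBD=1)/2 + P(IBD=2)`. The small-sample frequency corrections of
the original implementation are omitted; at the sample sizes used here the
bias is well inside the +-0.05 and +-0.1 test tolerances. Related samples
are removed greedily: while any pair exceeds 0.25, drop the sample with the
most offending pairs, ties broken by lower call rate then lexicographically
smaller id — deterministic and maximally retentive (the hub of a star of
relatives is removed, not its leaves).

Marker level, in fixed precedence (each marker attributed to the first
criterion it fails, so the report breakdown is reproducible): non-autosomal,
call rate < 0.95, MAF < 0.05 (strict: a marker at exactly 0.05 is kept),
exact HWE p < 1e-5, then LD pruning with PLINK `indep-pairwise` semantics
(50-SNP windows, step 5, r2 > 0.5 resolved by removing the lower-MAF
member, ties to the later position). The HWE test is the standard exact
conditional test — all heterozygote counts enumerated given the allele
counts, summing probabilities no larger than the observed configuration's.

One interaction deserves emphasis: HWE is tested on the pooled two-origin
sample, so strongly differentiated loci show a Wahlund heterozygote deficit
and are removed by QC. At 200+ samples a locus with pairwise theta of 0.5
or more fails the 1e-5 bound almost surely. The end-to-end test asserts
this behaviour explicitly: it is a property of the published protocol, and
one reason extreme outliers can vanish between raw and QC'd scans.

## Population structure

The GRM is VanRaden method 1: per-marker mean imputation, centring at
`2p`, `K = Z'Z / sum(2 p (1-p))` (an IBS-similarity matrix is available
behind a flag). PCA scales the top eigenvectors by the square roots of
their eigenvalues, reports percent variance as `100 lambda_i / trace(K)`,
and fixes signs by making the largest-magnitude loading positive.

Reynolds distances use a frequency-only moment estimator with a
ratio-of-sums over markers: per marker the squared contrast is debiased by
the binomial sampling terms (`p q / (2n - 1)` per population) and the
denominator adds the finite-sample-corrected gene diversities, so that
under Balding-Nichols drift `theta` estimates `c`; `D = -ln(1 - theta)`.
The implemented formula is pinned here and validated against simulation
truth rather than against any external program.

The population tree is Saitou-Nei neighbour joining with negative branch
lengths clipped to zero, midpoint-rooted for three or more populations. For
two populations the root is unidentifiable without an outgroup; the single
edge is split equally by default (`root_split` overrides). The drift matrix
`F` consumed by FLK is the shared-branch-length matrix of the rooted tree,
so the equal-split choice directly scales the FLK null — it is logged in
the `PopTree` object for that reason.

## Selection scans

Per-SNP F_ST is the Weir-Cockerham (1984) theta-hat from genotype counts
(variance components a, b, c with observed heterozygosity). Negative
estimates are truncated to zero for ranking and windowing, the signed value
kept for diagnostics. The multi-locus estimate is the standard ratio of
summed components, which is unbiased for the drift parameter where the mean
of per-marker ratios is not.

Outlier calling follows the published empirical rule: the 99.999th
percentile of the per-SNP distribution, order statistics interpolated
linearly (`h = (n-1)p + 1`, the R type-7 convention; the interpolation
choice is not recoverable from the source and is pinned here), with strict
exceedance. Windowed F_ST averages truncated values in non-overlapping
500-kb windows tiled from position 1, discarding windows with fewer than
4 SNPs; window outliers use the same percentile rule over window means.

A caution the acceptance suite itself computes: under Balding-Nichols drift
with c = 0.05, roughly 1.5 in 1000 neutral markers exceed theta-hat 0.4 at
2 x 60 samples, so the 99.999th-percentile bound of a 10,000-marker scan
sits near the genome-wide maximum (about 0.53) and a planted locus at
theta = 0.4 is essentially never called by that rule (measured power about
0/20 seeds; it ranks top-10 in roughly a third of seeds). The percentile
rule is a rank filter, not a calibrated test; its power depends entirely on
the heaviness of the neutral tail, which this generator makes explicit.

FLK whitens population frequencies by the drift covariance: per marker the
ancestral frequency is the GLS estimate `p0 = (1'F^-1 p)/(1'F^-1 1)` and
`T = (p - p0 1)' F^-1 (p - p0 1) / (p0(1-p0))` is referred to chi-squared
with npop - 1 degrees of freedom; markers whose estimated ancestral
frequency leaves (0,1) are flagged rather than forced. Observed sample
frequencies are used. With two populations and matched drift the p-values
are uniform to KS distance < 0.02 at 10,000 markers. FDR control is
Benjamini-Hochberg, significance declared at adjusted p <= 0.1 (the
boundary is inclusive). The separate Bayesian confirmation scan of the
original workflow is out of scope; its corroborating role is played by the
intersection of the F_ST-percentile and FLK-FDR calls in the outlier
report.

## LD structure

r2 is the composite (genotype-correlation) estimator: squared Pearson
correlation of dosages over pairwise-complete samples — deterministic and
phase-free; EM haplotype-frequency r2 is deliberately not implemented. LD
scores sum r2 over markers within a half-window each side of the scored
marker (window centred, truncated at chromosome ends) plus the self term,
so scores are >= 1; score distributions between origins are compared with
the two-sided Wilcoxon rank-sum test (exact for combined n <= 20 without
ties, normal approximation with tie and continuity correction otherwise).

The decay curve is `y = 1/(1 + 4 beta d) + e` fitted to Hill-Robertson
corrected values `r'2 = (r2 - 1/N)/(1 - 1/N)`, `N` twice the sampled
individuals, on pairs within 2500 kb. Fitting is Levenberg-Marquardt with
the start value inverting the model at the distance-weighted mean point,
relative-change tolerance 1e-10, at most 200 iterations; the standard error
is Gauss-Newton, the CI Wald. The published protocol drops pairs with
non-positive corrected r2 before fitting; that selection is the
`positive_only` flag (default TRUE). Applied to symmetric noise around a
truth near zero it biases beta downward by design, so the estimator's
calibration study in the acceptance suite runs with `positive_only = FALSE`
— unbiased to 1e-4 with 95% CI coverage near nominal — while the empirical
path keeps the published behaviour.

## Association scan

The EMMAX approximation: variance components of `y = mu + u + e`,
`u ~ (0, sigma_g^2 K)`, are estimated once by REML on the null model — the
profiled likelihood in `delta = sigma_e^2/sigma_g^2` evaluated on a
log-spaced grid over [1e-5, 1e5] and refined by golden-section search in
the best bracket — then held fixed while each SNP is tested by generalized
least squares on data rotated through the eigendecomposition of `K`:
intercept plus SNP, Wald t on n - 2 degrees of freedom. The binary origin
phenotype is treated as quantitative, as in the source workflow, and no
other covariates enter (herd is confounded with origin). Missing dosages
are mean-imputed; monomorphic SNPs are skipped with a flag. With `K = I`
the scan reduces exactly to ordinary least squares (tested to 1e-8). FDR is
Benjamini-Hochberg with genome-wide significance at adjusted p < 0.05;
`lambda = median(chi2_obs)/0.4549` and a Q-Q table accompany the results.
PVE is reported as the proportion `beta^2 var(g)/var(y)`; published PVE
figures for this design are ambiguous between a percentage and a
proportion reading, so the proportion is reported and no attempt is made
to match a particular printed value. The GRM includes the tested SNP
(no leave-one-chromosome-out), matching the described workflow; LOCO would
be a straightforward extension but is not offered silently.

## Spatial statistics and the selective-process diagnostic

Moran's I uses row-standardised inverse-distance weights by default
(k-nearest-neighbour optional), expectation `-1/(n-1)`, Z and p from the
randomization-moment variance, and an optional seeded permutation p. The
original analysis came from a variogram procedure with unstated weights, so
agreement is structural (sign, strength), not numeric. The kernel intensity
surface is a Gaussian-kernel point intensity plus a Nadaraya-Watson
weighted surface on a 10%-margin grid (both are emitted because the source
is ambiguous about value weighting); bandwidth defaults to Silverman's
rule.

The diagnostic profile around a focal outlier collects, within +-1 Mb,
truncated F_ST, `avHo` (mean observed heterozygosity of the two
populations) and `dHo` (their difference), and smooths each with a local
regression pinned to: tricube weights, degree 1, neighbourhood
`ceiling(0.21 n)`, no robustness iterations — the smoothing parameter 0.21
is the published choice; other implementation details of the original
procedure are unknowable, so agreement is again structural. The published
classification of the selective process was visual; it is operationalized
as explicit, config-exposed thresholds: local adaptation iff the smoothed
F_ST peak and the smoothed |dHo| peak both fall within 100 kb of the focal
marker and the smoothed avHo at the focus is below the window median. At
the study design (90/147 samples, about 65-kb marker spacing, a planted
theta-0.4 sweep) the classifier labels 80-95% of planted windows local
adaptation and 90-100% of neutral windows not-local-adaptation; the
residual misses are peak-localisation jitter inherent to a span-0.21 loess
at array density, not classifier bugs.

## Candidate annotation

Features (genes, QTLs) within 500 kb of a significant marker are reported
with the edge-gap distance: 0 inside the interval, otherwise the distance
to the nearest interval edge, inclusive at the flank bound. Distances in
published candidate-gene tables for this design do not follow any single
reconstructible convention, so reproduction is structural — the same gene
set within the flank — with the edge-gap convention pinned here.

## Pipeline, seeds, and problem sizes

`runPipeline()` executes simulate -> QC -> structure -> scan -> LD -> GWAS
-> spatial -> diagnose -> annotate, writes per-stage TSVs and a summary
JSON, and is byte-identical for identical config and seed. All randomness
derives from the single config seed through fixed per-stage offsets; no
stage draws from global state. The YAML config mirrors every threshold with
the published defaults.

Test and acceptance problem sizes are chosen to estimate each property
precisely while keeping the whole suite comfortably interactive: 10,000
markers for calibration checks (KS distances resolve 0.02 at that size),
2 x 200 samples for recovery studies, 20 fixed seeds for power and
classification rates, and a 10,401-marker, 237-sample end-to-end scenario
in the acceptance script. These sizes are the package's choices and are
fixed in the scripts.

## Known limitations

- The empirical-percentile outlier rule has essentially no power against
  moderate (theta = 0.4) planted loci under a Balding-Nichols background
  with c = 0.05, as quantified above; detection at that effect size rides
  on FLK and the association scan.
- Pooled-sample HWE filtering removes extremely differentiated loci
  (Wahlund effect) before any scan sees them.
- The LD calibration maps an exponential latent correlation onto a
  hyperbolic target; recovered decay rates carry a few percent of
  structural bias inside the stated 25% band.
- Two-population trees are rooted by assumption (equal split), which
  scales the FLK statistic; with more populations midpoint rooting is
  used.
- pi-hat omits small-sample frequency corrections; with fewer than ~50
  samples the IBD estimates drift upward.
- The text PED format cannot round-trip monomorphic markers' allele
  identity.
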