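---
title: "Methods: ROH detection, classification, inbreeding and hotspot inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROH detection, classification, inbreeding and hotspot inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscan)
```

## Scope and coordinate conventions

`rohscan` implements an ROH-centric population-genomics workflow for diploid
SNP panels: detection of runs of homozygosity (ROH), classification of their
lengths by a Gaussian mixture, genomic inbreeding coefficients, ROH-based
population structure, and permutation-calibrated ROH hotspot identification
cross-checked against windowed selection statistics. Upstream steps (read
alignment, variant calling, imputation) and external selection-scan engines
(iHS, CLR, XP-EHH, F~ST~ computation) are out of scope: genotypes enter as
VCF and selection statistics enter as per-site tables.

All internal coordinates are 0-based half-open. A SNP at external 1-based
position $p$ occupies internal base $[p-1, p)$; a segment's `end` is the
internal position of its last SNP plus one, so abutting intervals never
overlap and interval arithmetic needs no $\pm 1$ corrections. Conversion to
the `.hom` convention (1-based inclusive) and BED (0-based half-open)
happens only in readers and writers. Missing genotypes are a distinct code
(`NA`) and are never imputed; every estimator documents how it treats them.

## ROH detection

A run of homozygosity is a stretch of consecutive SNPs that is effectively
homozygous. The default parameters are the common WGS setting: at least 50
SNPs and 500 kb per run, no inter-SNP gap of 1 Mb or more, at most 3
heterozygous and 5 missing calls, and at most 50 kb per SNP. Two modes are
provided.

**Exact mode** (default) treats the allowances per segment: a reported
segment is a maximal SNP-index interval satisfying every constraint, where
maximal means that adding one SNP on either side violates some constraint
or leaves the chromosome. Overlapping maximal intervals are resolved
greedily — earliest start first, longer preferred — so each individual's
segments are disjoint. This definition is deliberately enumeration-
checkable: the test suite verifies the compiled scan against brute-force
enumeration of all $O(m^2)$ intervals on hundreds of randomized instances.

**Window mode** reproduces the PLINK-style scan, where het/missing
allowances apply per 50-SNP scanning window: each SNP scores the fraction
of acceptable windows covering it, SNPs at or above the hit threshold
(default 0.05) form candidate runs split at large gaps, and segment-level
size/length/density filters are applied last. The two modes agree on clean
planted tracts but may differ on noisy data; exact mode is the default
because its semantics are fully specified and oracle-verifiable.

The density rule is evaluated as $(\mathrm{length\ bp}/1000)/n_\mathrm{SNP}
\le 50$ kb/SNP, matching the kb-per-SNP semantics of the reference tool.
Whether the original workflow changed the scanning-window hit threshold or
density defaults is not documented; the defaults above are used and all are
exposed as parameters.

`sensitivity_grid()` supports one-factor-at-a-time robustness analysis,
reporting total count, mean length, mean count per individual and mean
F~ROH~ (overall and per class) as one parameter sweeps. Class boundaries
for the per-class columns are fit once on the baseline run and reused
across the grid, so the sweep isolates the detection parameter rather than
confounding it with re-fit class limits.

## Length classification

ROH lengths are trimodal in practice: short runs reflect ancient LD and
background relatedness, long runs recent inbreeding. `fit_length_mixture()`
fits a three-component univariate Gaussian mixture with unequal variances
by EM on raw kb lengths (a log-scale option exists for robustness checks;
raw kb is the default because class limits are conventionally reported on
that scale). Initialization is deterministic: quantile-based means first,
then nine seeded random restarts, keeping the best log-likelihood. The EM
log-likelihood is asserted non-decreasing at every iteration; convergence
tolerance is $10^{-6}$ with at most 500 iterations; component standard
deviations are floored at $10^{-6}$ of the data range to avoid variance
collapse onto single points.

Class boundaries are where the posterior-argmax component switches: the
root of $w_i\,\mathcal N(x;\mu_i,\sigma_i) = w_j\,\mathcal N(x;\mu_j,
\sigma_j)$ (a quadratic in $x$) lying between the two sorted means, with a
fine-grid argmax scan as fallback when no root lies there (possible when a
wide component envelops a narrow one). Boundary ties classify upward:
`short` is strictly below the first boundary, mirroring the conventional
"short (< b1)" statement of class limits. Degenerate input (all lengths
equal, or fewer than 30 segments) is an explicit error rather than a
spurious fit.

## Genomic inbreeding and diversity

Four standard estimators are computed per individual:

* **F~ROH~** — total ROH length over total autosome length, optionally per
  length class. Invariant to splitting segments into abutting pieces;
  overlapping segments within an individual are rejected.
* **F~HOM~** — method-of-moments excess homozygosity,
  $(O_\mathrm{hom} - E_\mathrm{hom})/(m - E_\mathrm{hom})$ with the
  sample-size-corrected expectation
  $E_\mathrm{hom}=\sum_i (1 - 2p_i(1-p_i)\,n_i/(n_i-1))$ over the
  individual's non-missing sites.
* **F~GRM~** — the variance-standardized genomic-relationship diagonal
  minus one, $\mathrm{mean}_i[(x-2p_i)^2/(2p_i(1-p_i)) - 1]$.
* **F~UNI~** — the correlation of uniting gametes,
  $\mathrm{mean}_i[(x^2-(1+2p_i)x+2p_i^2)/(2p_i(1-p_i))]$.

Allele frequencies come from the analysis panel itself, as the reference
implementations do. This matters: frequency misspecification across
heterogeneous panels is exactly what produces implausible negative
F~HOM~/F~GRM~ values in admixed groups, so the estimators are documented as
panel-relative. Sites monomorphic in-panel are excluded from the
F~GRM~/F~UNI~ denominators (they are uninformative and would divide by
zero) but still count in the plain heterozygosity proportion Ho. He per
group is $\mathrm{mean}_\mathrm{SNP}\,2\hat p(1-\hat p)$ from group allele
counts. Under Hardy–Weinberg simulation F~GRM~ and F~UNI~ center at zero
within Monte-Carlo error, which the tests assert.

Spearman correlations (`spearman_cor()`) use average ranks with the
two-sided t-approximation on $n-2$ degrees of freedom. At the panel sizes
this package targets (dozens to hundreds of individuals) the approximation
is indistinguishable from exact permutation; the test suite checks rho
against the standard implementation exactly and the p-value on the log
scale.

## ROH-based structure

`build_binary_matrix()` recodes segments as an individuals × regions 0/1
matrix. The column set is the atomic partition of the union of all
in-scope segments at every distinct segment breakpoint. Because regions
are atomic, "presence" is unambiguous: an individual's segment either
covers a region entirely or not at all, and the matrix is independent of
any arbitrary windowing choice. (Whether the original recoding pooled
overlapping runs or used fixed windows is unspecified; the atomic
partition is the one choice with no free parameter, and is flagged as a
possible divergence.) Columns constant across individuals are retained but
reported.

PCA mean-centers columns without variance scaling — entries are segment
indicators, not allele counts, so allele-frequency normalization has no
meaning here; a scaling flag exists for comparison. Component signs are
fixed (largest-magnitude loading positive) for reproducibility.
`export_structure_inputs()` writes a documented transposed marker-like
coding for external clustering tools.

## Hotspot inference by max-statistic permutation

The coverage track counts, at every SNP, the individuals whose ROH covers
it; the denominator is the whole group including ROH-free individuals, so
frequencies are comparable across groups of different ROH prevalence. The
null model redistributes every segment independently to a uniform start on
$[0, L-\ell]$ within its own chromosome for its own individual, preserving
all lengths and per-individual counts — a segment-level permutation that
retains the panel's burden structure while destroying positional sharing.
Displaced segments of one individual may overlap; coverage counts an
individual once per SNP (a sequential non-overlapping placement variant
was considered and rejected as the default because independent placement
matches the stated null and is what the simulator implements, keeping
calibration tests coherent).

Each permutation records the genome-wide maximum SNP-wise frequency. The
significance threshold is the empirical $1-\alpha$ quantile of those
maxima (order statistic at $\lceil(1-\alpha)n_\mathrm{perm}\rceil$), and a
SNP is significant only if its observed frequency **strictly exceeds** the
threshold — conservative under the heavy ties that discrete frequencies
produce, and degenerate cases (e.g. a single individual whose segment
spans the chromosome) correctly yield no calls. Per-SNP FWER-adjusted
empirical P values use the $(1+k)/(n_\mathrm{perm}+1)$ estimator so P is
never zero. Runs of consecutive significant SNPs merge into hotspots;
"adjacent" is not quantified in the field, so the default is strict index
adjacency with an optional bp bridging distance.

Calibration is the package's central claim and is measured, not assumed:
on 500 null-simulated panels (25 individuals, 50 Mb, 5,000 SNPs, 20
segments each of log-normal length, 1,000 permutations per panel) the
fraction of panels with any called hotspot is well below the nominal
$\alpha = 0.01$ (`scripts/acceptance.R` recomputes this end to end). Power
and localization are tested separately: an island carried by 90% of 30
individuals is recovered in at least 95% of replicates with no calls
outside the island beyond one SNP spacing. The permutation threshold also
falls with group size at fixed per-individual burden — the qualitative
counterpart of the inverse threshold–sample-size relationship seen in real
panels — which the suite asserts as a rank correlation without pinning a
data-dependent value.

## Windowed selection statistics and overlap

`make_windows()` tiles each chromosome with 50 kb windows stepped by 20 kb
(defaults), truncating at chromosome ends. `window_summarize()` aggregates
externally computed per-site statistics: the proportion of sites with
$|iHS|\ge2$ (windows with fewer than 10 sites dropped, for that statistic
only), the window maximum for CLR, the mean for XP-EHH/F~ST~. Nucleotide
diversity is computed natively from genotypes:
$\pi_\mathrm{site}=\frac{n}{n-1}2\hat p(1-\hat p)$ (the unbiased per-site
mean pairwise difference, verified in tests against explicit pairwise
allele comparison), summed per window and divided by window length.

Window retention z-standardizes one statistic across its windows and keeps
windows with one-sided normal $p < 0.01$ — upper tail for sweep-enriched
statistics, lower tail for diversity, both configurable. The phrase
"Z-tests with empirical P" is ambiguous in the field's usage; z-based
normal tails are the default here, with rank-based empirical quantiles
available by using the z column's ranks directly. Retained windows merge
into maximal intervals. `overlap_report()` counts, per hotspot, the
supporting methods (non-empty half-open intersection; touching intervals
do not overlap) and reports the percentage of significant hotspot SNPs
inside at least one and at least two methods' retained intervals.

## The simulator: what it emulates, and what it does not

`simulate_panel()` generates the study conditions every test runs under:

* uniform random SNP maps (default mean spacing 2 kb on 10 Mb
  chromosomes — dense enough that segment ends track tract ends to within
  a few kb);
* Hardy–Weinberg background genotypes at per-site frequencies uniform on
  [0.05, 0.5];
* planted autozygous tracts per class with Poisson counts (defaults
  2/1/0.4 per individual) and log-normal lengths (median 600/1,200/3,000
  kb, log-sd 0.2/0.25/0.35), giving a realized autozygous fraction around
  0.15–0.2 — a realistic livestock inbreeding level — and the three-modal
  length structure the classifier expects;
* uniform tract placement on $[0, L-\ell]$, matching the permutation
  null's placement model so calibration tests are coherent;
* optional hotspot islands (carriers receive a tract fully covering the
  interval, flank configurable), genotyping error inside tracts, uniform
  missingness, a per-individual target autozygous fraction for inbreeding
  gradients, and covariate-linked SNPs with a logistic frequency link for
  frequency–climate analyses.

Tract lengths drawn beyond every chromosome are redrawn and finally
clamped rather than erroring, so heavy-tailed length laws remain usable.

The simulator does **not** model linkage disequilibrium, recombination or
coalescent history: short-ROH-from-LD phenomena appear only as planted
short tracts, and background genotypes are independent across sites.
Passing tests therefore demonstrate correctness of the algorithms under
their stated models — detection recovers planted tracts, the caller's FWER
is controlled under its own null — not that real LD-driven short ROH are
classified the way array-based studies classify them.

## Numerical and design choices

* Problem sizes: validation uses panels of 20–50 individuals on 20–50 Mb
  toy genomes with 5,000–25,000 SNPs, 500 calibration replicates × 1,000
  permutations, and 100 power replicates; these sizes give binomial
  resolution well below the thresholds they check.
* All randomness flows through explicit integer seeds; `permute_null()`
  and `simulate_panel()` set the RNG themselves, and the mixture fit
  restores the caller's RNG state.
* The compiled permutation core and detection scan use R's RNG stream, so
  results are identical across platforms given a seed, and single-threaded
  by design.
* Hotspot carrier counts round `carrier_fraction × n` to the nearest
  integer with a message when rounding occurs.
* `read_vcf()` keeps the first record at duplicated positions and logs the
  drop; multi-allelic and indel records are skipped (lenient, default) or
  rejected (strict).

## Known limitations

* No LD in the simulator (above); no sex chromosomes, CNV-aware ROH, or
  phased IBD calling.
* F estimators are panel-relative; comparing F~HOM~/F~GRM~/F~UNI~ across
  differently composed panels inherits frequency-reference bias.
* Window-mode detection approximates, but does not byte-match, the
  reference tool's scan (end trimming differs).
* The z-based retention assumes approximate normality of window summaries;
  heavy-tailed statistics should use the rank-based alternative.
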