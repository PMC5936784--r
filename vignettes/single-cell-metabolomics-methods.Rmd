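---
title: "Methods: single-cell metabolomics processing and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell metabolomics processing and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and numerical
choices behind each stage. The README shows the surface; here we explain
what is computed, why the defaults are what they are, and where genuinely
open design decisions were settled.

# The data and its assumptions

The unit of observation is one living cell sampled by direct-infusion
electrospray MS: a centroided peak list of (m/z, intensity) pairs.
Experiments compare exactly two conditions with roughly 10–15 cells per
group. The pipeline assumes:

* **positive-mode, singly charged ions.** Small metabolites ionize as
  [M+H]⁺, [M+NH₄]⁺, [M+Na]⁺ or [M+K]⁺; multiply charged species are not
  modelled. Adduct mass shifts subtract one electron mass (0.000549 Da)
  because the observed m/z is that of a +1 cation; at 0.01 Da matching
  tolerances a half-millidalton bias would be a third of the error budget,
  so the correction matters.
* **intensities are relative.** Absolute ion counts vary cell to cell
  (probe positioning, matrix effects), so all statistics operate on
  TIC-normalized abundances. Missing values are true zeros — a feature
  absent from a cell contributes 0, and no imputation is performed.
* **¹³C dominates isotope structure.** Envelopes are collapsed assuming
  replicas spaced by the ¹³C–¹²C mass difference (1.00336 Da) at charge 1.
  Fine structure from ¹⁵N, ¹⁸O, ³⁴S is far below the 0.05 Da joining
  tolerance and is ignored.

# Preprocessing chain

Stage order is fixed: **filter → TIC-normalize → deisotope → align**.
Normalization precedes alignment so that cross-cell intensity weighting in
the consensus m/z is not dominated by high-TIC cells; filtering precedes
normalization because the discarded background (by design a few percent of
total signal) should not deflate the denominator.

**Filtering** keeps peaks with intensity strictly greater than the
threshold (default 10³ counts, the usual conservative export floor for
Orbitrap background) and reports both the fraction of peaks removed and
the fraction of total signal retained, so a run can document statements
like "x% of low-signal peaks excluded while retaining y% of intensity".

**Deisotoping** scans peaks in ascending m/z. An open envelope with
monoisotopic m/z m₀ holding k peaks (k < 5 by default) expects its next
replica at m₀ + k·1.00336; a peak within 0.05 Da of that position may
join. Two tie-breaks make the assignment well defined:

* a peak within tolerance of several envelopes joins the one with the
  smallest |observed − expected| (exact ties go to the lower m₀);
* symmetrically, a peak *yields* an envelope slot when a later peak lies
  strictly closer to the expected position — that later peak is almost
  surely the envelope's true replica. Without this look-ahead, a foreign
  ion sitting just below a replica position is silently absorbed and its
  feature vanishes; with it, the assignment is a nearest-position matching
  and only collisions closer than the m/z noise itself remain ambiguous.

Envelope intensity policy: the collapsed feature carries the **sum** of
its replicas, so total signal is conserved (the alternative — keeping only
the monoisotopic height — discards a carbon-count-dependent fraction and
would bias abundance comparisons between small and large molecules).
Deisotoping is idempotent: re-running it on its own output is a no-op.

**Alignment** pools all cells' peaks inside 100–1500 m/z, sorts them, and
cuts wherever the gap between consecutive pooled peaks exceeds 0.01 Da.
This greedy gap-cut is deterministic and independent of cell order, and
guarantees that adjacent consensus m/z (intensity-weighted means) differ
by more than 0.01 Da. A cell contributing several peaks to one cluster is
summed and counted in a diagnostic attribute rather than treated as an
error.

# Statistics

**Per-feature tests** are Welch (unequal-variance) *t*-tests by default.
The choice is deliberate: single-cell intensity variance scales with the
mean, so pooled-variance Student tests are anti-conservative whenever a
feature's abundance differs between groups — exactly the case of
interest. Student's variant is available via `var_equal = TRUE`.
Significance is flagged at raw *p* < 0.05 (the conventional per-feature
screen for this data type); a Benjamini–Hochberg column is emitted
alongside for users who want FDR control, but it does not drive the
default flags. Degenerate features follow explicit conventions: constant
everywhere → *p* = 1; zero variance in both groups but different means →
*p* = 0, flagged. Because "up under condition A" and "up under condition
B" are different biological statements, the result table reports the
direction (higher-mean group) per feature and the summary counts both
directions separately.

**PLS-DA** is a NIPALS partial least squares regression of column-mean-
centred intensities on a +1/−1 coded response, with deflation of both
blocks between components. For a univariate response the NIPALS iteration
converges in a single pass, so the implementation is exact and
reproducible to machine precision; scores have zero column means, and
successive weight vectors are orthogonal. No unit-variance scaling is
applied by default — TIC-normalized intensities share a scale, and
autoscaling would inflate the influence of near-zero noise features
(`autoscale = TRUE` is available). Condition labels are mapped to ±1 in
byte order of the labels so results do not depend on input row order.

**Permutation significance**: the observed statistic is the between- to
within-group sum-of-squares ratio of the first two score dimensions; the
model is refit under `n` random label permutations and
p = (1 + #{perm ≥ observed}) / (1 + n). The attainable floor is therefore
1/(n+1): 5×10⁻⁴ at the default 1999 permutations, 10⁻³ at 999. Reported
p-values at the floor mean "stronger separation than every permutation",
not a density estimate.

**Q²** is estimated by stratified k-fold cross-validation (default 10
folds, folds drawn within each group): Q² = 1 − PRESS/TSS over held-out
±1 responses, with each fold's TSS taken about its training-set mean. Q²
near 1 indicates a predictive model; values ≤ 0 mean the model predicts
held-out labels no better than the training mean, the expected outcome
under label shuffling. The conventional "good predictability" reading is
Q² > 0.5.

**Heat-map matrices** z-score each selected feature across *all* cells
(so colour encodes deviation from the overall mean, making the two
condition blocks directly comparable), then cluster rows and columns
agglomeratively (Euclidean distance, Ward linkage). Leaf order within the
dendrogram is canonicalised by label rank, so the output is invariant to
input row/column order; constant features become all-zero rows placed
last.

# Annotation and pathways

Features are matched against a library of (name, formula, class, adduct,
pathways) records over all four counter-ions at a 0.01 Da tolerance
(ppm mode available). The tolerance default mirrors the 0.01 Da alignment
delta: there is no point matching tighter than features are resolved.
All candidates within tolerance are kept, ranked by |mass error| with a
deterministic name/adduct tie-break. True isomers (identical formula,
identical adduct) are all retained; the "best" flag goes to the
lexicographically smallest name, and since isomers share a formula, the
choice cannot affect elemental counting downstream. m/z-only
identification is inherently tentative — most features of a real cell
remain unannotated, and the pathway layer therefore requires **two**
distinct annotated metabolites before a pathway is reported
(`min_hits = 2`), counting metabolite names rather than features so that
one compound observed twice cannot promote a pathway.

# Elemental stoichiometry

For a scope of annotated features, each cell's weighted element sum is
Σᵢ count(element, formulaᵢ)·abundanceᵢ, and C:N = weighted C / weighted N
(likewise C:P). Ratios are computed **per cell** and compared between
groups with a Welch test — the per-cell reading is what makes a
between-group test well defined. Two scope choices exist: the default
`"significant-annotated"` (features both significantly regulated and
annotated — the regulated-metabolome reading, which is the sharper
question under nutrient manipulation) and `"all-annotated"`. Zero
denominators (an all-N-free scope) yield flagged undefined ratios,
excluded from comparisons with an explicit count — never coerced to
infinity. Ratios are exactly invariant to rescaling a cell's abundance
vector, so they are unaffected by TIC normalization choices.

These metabolome ratios are not whole-cell Redfield ratios: proteins and
nucleic acids are invisible to small-molecule MS, so absolute values sit
far from canonical biomass stoichiometry; only the between-condition
contrast is interpretable.

# The synthetic-data generator

`simulate_experiment()` emulates: log-normal metabolite baselines
(natural-log mean ln 5×10⁴, sd 1 — centring peaks well above the 10³
export floor); per-cell biological variation (`cell_log2_sd`, default 0.6
log2 units); log-normal per-cell TIC scales (sd 0.3); Gaussian m/z jitter
(sd 0.002 Da, a realistic high-resolution calibration error); binomial
¹³C isotope envelopes on the carbon count (abundance 0.0107, so
I(M+1)/I(M) ≈ 0.0107·nC); and Poisson-count noise peaks (mean 50/cell)
uniform in m/z with intensities straddling the export floor, never placed
within 0.05 Da of a true envelope so recovery tests have unambiguous
truth. Scenario `light_dark` (15 cells/group) draws differential effects
with random sign; `n_limitation` (10 cells/group) draws them from N-free
compound classes, all up-regulated under depletion, so the true weighted
C:N rises. Differential counts follow
round(fraction_differential × library_size) exactly. All randomness flows
from one integer seed; identical configurations reproduce byte-identical
spectra.

`cell_log2_sd` is the one knob beyond the experiment's design parameters:
it sets within-group variation, hence statistical power. It has no
measured counterpart (per-metabolite biological variance of single cells
is not separately published for this kind of data), so 0.6 log2 units was
chosen once as a realistic middle ground — large enough that null
features are genuinely noisy, small enough that 2-fold effects are
detectable at n = 15 — and all calibration tests inherit it.

The built-in library (344 records) spans amino acids, sugars, organic
acids, nucleotides, pigments, sterols, free fatty acids, sphingolipids,
lyso-phospholipids and glycerolipids of the classes PA, PE, PG, PS, PI,
PC, MG, DG, TG, plus tetrapyrrole, macrolide, polyketide and terpenoid
natural products, each with a preferred counter-ion placing its ion in
100–1500 m/z. `thin_library()` extracts an unambiguous subset for
ground-truth tests: no candidate within 0.025 Da of another record's
preferred ion (0.02 Da is the identification-ambiguity bound; 0.025 also
exceeds the alignment merge bound of 0.01 Da + 6 jitter sd), and no
preferred ion within 0.01 Da (≈ 5 jitter sd) of another's isotope-replica
positions — collisions tighter than that are physically unresolvable by
any assignment rule.

What the generator does **not** emulate: chromatography or retention
time; profile-mode peak shape; ion suppression and matrix effects
(noise is additive and placement-independent); adduct competition (each
metabolite appears only as its preferred ion); charge states beyond +1;
and peptides. Passing recovery tests therefore demonstrates correctness
of the algorithms under the stated noise model, not performance on any
particular instrument's data.

# Problem sizes used by the test-suite

Unit and property tests run on 2–6 cells and 20–80 metabolites; the
recovery, calibration and power checks use the full study shapes (15 or
10 cells per group, 200 expressed metabolites), a 10,000-feature null
matrix for type-I calibration, 50 label shuffles for the null-Q² check,
and 1999 permutations for the significance floor. The whole suite
completes in about a minute on one CPU.

# Known limitations

* Greedy gap-cut alignment can merge ions closer than ~0.02 Da once
  30 cells' jitter clouds overlap; such pairs are reported as one
  feature. Real libraries contain such pairs; the unambiguous-subset
  helper exists precisely to separate algorithm verification from this
  physical limit.
* The permutation and CV statistics refit the full PLS model; with
  thousands of permutations on much larger matrices the quadratic cost
  would warrant a compiled path, which has not been needed at the study
  sizes targeted here.
* Annotation is m/z-only and therefore tentative by construction;
  isomers are never distinguished, and identification confidence beyond
  the two-hit pathway criterion is out of scope.
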