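---
title: "Mapping suppressors of a Pol I growth defect and quantifying their phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping suppressors of a Pol I growth defect and quantifying their phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgrmap)
```

## The problem

RNA polymerase I (Pol I) transcribes the ribosomal RNA genes of budding
yeast. Deleting the Pol I subunit gene *RPA49* causes a strong growth
defect, and spontaneous or UV-induced extragenic suppressors (SGR
mutants, for Suppressor of the Growth defect of the *RPA49* deletion)
restore growth. Identifying where such a suppressor lies in the genome,
and then quantifying how completely it restores growth, Pol I loading on
the rRNA genes, and rRNA synthesis, is the analytic pipeline this
package implements.

The mapping strategy is barcode-based genetic linkage. The
suppressor-bearing query strain is crossed to the genome-wide barcoded
deletion collection; after sporulation, marker selection and pooled
competitive growth, each deletion strain's barcode abundance is read on
a two-channel array (query pool vs an unselected control pool). A
deletion locus genetically *linked* to the suppressor is
counter-selected: spores carrying the collection's deletion allele at a
linked position usually inherited the region from the collection
parent, so they lack the suppressor and grow slowly, and that barcode
is depleted in the query channel. The depletion footprint along the
chromosome is the mapping signal.

## Generative model of the screen

`simulate_gim_cross()` reproduces this structure. For a barcode at
position $x$, the fraction of marker-selected spores carrying the
suppressor allele is the recombination fraction between $x$ and the
suppressor locus, mapped from physical distance with a uniform rate
(default 0.35 cM/kb, a standard genome-wide average for
*S. cerevisiae*; the original screen publishes no genetic map) through
the Haldane map function, which assumes no crossover interference:

$$r(d) = \tfrac12\left(1 - e^{-2d}\right), \qquad d \text{ in Morgans}.$$

Unlinked barcodes (other chromosomes) have $p = 1/2$. After pooled
growth for time $T$ the query-channel abundance of barcode $i$ is the
two-component exponential mixture

$$a_i \propto p_i\,2^{T/\tau_s} + (1 - p_i)\,2^{T/\tau_u},$$

with $\tau_s$ and $\tau_u$ the doubling times of suppressed and
unsuppressed spores (defaults 135 and 180 min, the doubling times
measured for the suppressed double mutant and the deletion mutant).
The control pool has no fitness differential. The pooled-growth
duration is not published; the default `competition_time = 1350` min is
ten generations of the faster grower, a typical competitive-growth
scale, and is exposed as a parameter. Intensities are the channel
abundances times multiplicative lognormal noise (default CV 0.2,
microarray-like; multiplicative noise keeps intensities positive,
unlike additive Gaussian noise). Optionally, linkage to the query
deletion marker itself depletes its own chromosome (the
positive-control peak a real screen shows at the query gene); the
depletion factor is twice the recombination fraction to the marker,
i.e. the double-recombinant retention relative to unlinked loci.

Every generator in the package takes an explicit `seed` and touches the
global RNG only through a save/restore wrapper, so pipelines are
bit-reproducible.

## Mapping procedure

```{r map, eval = FALSE}
cfg <- gim_sim_config(suppressor_locus = list(chrom = "chrXVI",
                                              pos = 500000))
bt <- simulate_gim_cross(cfg, seed = 3)
res <- map_suppressor(bt, W = 20, n_perm = 1000, seed = 3)
res$calls[1, c("chrom", "peak_pos", "score", "p_value")]
```

Four steps, each exposed separately:

1. **`normalize_arrays()`** — each channel is scaled to median 1;
   zero intensities first become half the smallest positive value in
   their channel (a pseudocount so log ratios stay finite). The
   original analysis normalized in MATLAB without publishing the
   dialect; median scaling is scale-invariant and robust, which is all
   the downstream log-ratio needs.
2. **`compute_scores()`** — score $=\log_2(\text{control}/\text{query})$.
   The orientation is deliberate: counter-selected (depleted) barcodes
   score *high*, so the linked locus is a local *maximum* of the
   smoothed curve, matching how such screens are read.
3. **`sliding_window_profile()`** — per chromosome, a plain mean over
   every run of `W = 20` consecutive barcodes (step 1, full windows
   only). Edge windows are not shrunk: a shrunk window averages fewer
   barcodes and has inflated variance, which would fabricate edge
   peaks. Window centers are the median barcode position (mean of the
   two middle positions for even `W`). Smoothing is per chromosome, not
   across chromosome boundaries, since linkage does not cross them.
4. **`call_loci()`** — local maxima (ties collapse to the leftmost
   window of a plateau, keeping output deterministic) are kept when
   they rise more than `min_prominence` above the chromosome's median
   window score; the default prominence is one median absolute
   deviation of that chromosome's window scores. Significance comes
   from a permutation null: scores are shuffled genome-wide with
   positions fixed, the profile recomputed, and the genome-wide maximum
   window score recorded per permutation;
   $p = (1 + \#\{\text{perm max} \ge \text{peak}\})/(n_{\text{perm}}+1)$.
   Shuffling (rather than circular rotation) preserves the score
   distribution exactly and is the simplest exchangeable null; the
   genome-wide maximum statistic controls the family-wise error of
   scanning all windows. The original analysis read the local maximum
   by eye; the permutation test is this package's addition.

Degenerate inputs are handled explicitly: chromosomes with fewer than
`W` barcodes yield no windows (with a warning), all-equal scores yield
no calls, and an empty profile yields an empty call table.

### What the simulation does and does not establish

With the default study conditions (4,500 barcodes on the 16 yeast
chromosomes, $\tau$ = 135/180 min, noise CV 0.2, `W` = 20) the
acceptance suite shows the top-ranked call lands on the correct
chromosome within 25 kb of the truth in well over 90% of seeded
screens, and that under a null with no fitness differential the
fraction of screens producing a $p < 0.05$ call stays within binomial
bounds of the nominal 5%. The generator draws i.i.d. lognormal noise
per channel and equal barcode spacing per chromosome; real arrays have
probe-specific biases, spatial artifacts, and uneven gene spacing, and
real crosses have interference and selection at loci other than the
suppressor. Passing these tests therefore validates the *procedure*
under its own model, not array-specific robustness.

## Growth phenotypes

`fit_doubling_time()` regresses $\log_2$ OD600 on time and returns
$\hat\tau = 1/\text{slope}$ in minutes. The exponential window is
selected automatically: the full series is used when its $R^2 \ge
0.99$; otherwise every contiguous run of at least 4 points is scanned
and the highest-$R^2$ run wins, ties going to the longer then earlier
run. This keeps lag and saturation phases out of the fit without manual
intervention (a manual `window` override exists). The method is exact
on noiseless exponentials for any sampling grid, and invariant to
rescaling OD.

`suppression_index(tau_wt, tau_mut, tau_double)` summarizes rescue as
$(\tau_{mut} - \tau_{double})/(\tau_{mut} - \tau_{wt})$: 1 is full
rescue, 0 none. For the measured 102/180/135 min triple it evaluates
to 0.577 — the suppressor recovers about 58% of the growth defect.

`estimate_frequency()` converts colony counts to per-viable-cell
suppressor frequencies (dividing by plated cells × survival fraction,
so UV killing does not deflate the rate) with a closed-form
Clopper–Pearson 95% CI, and `uv_fold()` forms the frequency ratio with
a log-scale delta-method CI. Plain frequencies, not Luria–Delbrück
rates, are estimated, because frequencies are what the colony counts
report.

## Occupancy and transcription quantification

`summarize_counts()` gives mean, median, a method-of-moments
negative-binomial dispersion and a seeded percentile-bootstrap CI
(default 2000 resamples) for Miller-spread per-gene polymerase counts;
counts arrive as integers (they are produced by visual inspection of
micrographs, not by this package). `compare_counts()` applies Welch's
t-test (two-sided) by default, with Mann–Whitney as the
distribution-free alternative; two identical constant samples return
p = 1 with a warning rather than an error. At the observed effect size
(means 91 vs 21, n = 30 genes) the Welch test has essentially full
power at $\alpha = 0.01$, the significance level used for occupancy
comparisons here. `chip_relative_occupancy()` divides each replicate's
percent-input by the reference strain's per-amplicon median and reports
medians and SDs of normalized values, with per-amplicon Welch tests
against the reference.

For signal tables (run-on slot blots, northerns, pulse labelling),
`normalize_to_control()` divides every probe's signal by the same
replicate's internal-control signal (5S for run-on, SCR1 or PGK1 for
northerns, or an explicit "loading" pseudo-probe for gels without a
stated control), which cancels replicate loading exactly by
construction. `probe_group_mean()` averages a probe group — e.g. the
Pol I group {5'ETS, 18S.2, 25S.1, 3'ETS} of a run-on blot — per
replicate. `fold_change()` uses the ratio of per-strain medians rather
than the mean of ratios: with 2–3 replicates a single outlying
replicate would dominate a mean. CIs are percentile bootstraps over
replicates; with 3 replicates they are coarse and should be read as
order-of-magnitude guides.

## Problem sizes and numerical choices

The test suite simulates at the scale the analyses describe — 4,500
barcodes, 100 mapping screens plus 200 null screens (100–199
permutations each), 200 growth curves per strain, 100 count screens of
200 genes, 300 signal-table seeds per assay, 500 fluctuation seeds —
which keeps the full suite around two minutes on a laptop-class core.
Permutation counts are the main runtime dial; `n_perm = 1000` (the
`map_suppressor()` default) is recommended for a single real screen.
All tolerances asserted in tests derive from the generative model
(binomial/bootstrap standard errors), not from fitted constants.

## Known limitations

* The map rate is uniform; real recombination hot/cold spots distort
  cM–kb conversion locally, which mostly affects peak width, not
  chromosome assignment.
* Barcode positions are the deletion collection's gene positions;
  essential genes simply have no barcode, so a suppressor inside an
  essential gene is mapped only by flanking deletions.
* The permutation null assumes exchangeable scores genome-wide; strong
  chromosome-scale trends (aneuploidy in the pool) would violate it.
* Array normalization is median-based only; no within-array spatial
  correction is attempted.
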