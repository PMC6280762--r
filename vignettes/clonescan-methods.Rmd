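---
title: "clonescan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clonescan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonescan)
```

## The problem

Spermatogonial stem cells that acquire gain-of-function mutations in growth
signalling genes (the RTK/RAS-MAPK axis) can expand clonally along
seminiferous tubules — "selfish spermatogonial selection". In a dissected
testis this produces a characteristic signature: the same nucleotide variant
at very low variant allele frequency (VAF, roughly 0.05%–3%) in a contiguous
run of biopsies, against a per-position background error rate of order
10^-4^ in deep (~15,000–22,000x) amplicon sequencing. clonescan implements
the complete discovery pipeline for this setting: a synthetic-data generator
with known ground truth, read-level pileup construction, per-position
background modelling with batch-covariate normalization, outlier calling,
a tiered prioritization cascade, spatial clonal-event analysis on a biopsy
adjacency graph, and pathway-enrichment statistics.

## The statistical model

At each (amplicon, position, alternate allele) the observed alt read count
in sample $s$ is modelled as

$$X_s \sim \mathrm{BetaBinomial}(d_s,\; e_{c,s} + v_s,\; \rho)$$

where $d_s$ is depth, $e_{c,s}$ the sample-specific background error rate at
that column, $v_s$ the (possibly zero) clonal VAF, and $\rho$ a small
overdispersion capturing PCR jackpots. The background $e_{c,s}$ combines a
heavy-tailed per-position rate (log-normal across positions, median 10^-4^)
with additive batch effects on the logit scale (flow cell, lane, mean base
quality). A true clonal VAF is first resampled through a binomial bottleneck
of $T$ template molecules per (sample, amplicon) — the droplet-PCR input —
so realized VAFs vary by $\sqrt{1/(Tv)}$ relative even before sequencing.

### Normalization

The transformed signal $t = \mathrm{logit}((x + 0.5)/(d + 1))$ is regressed,
per column, on flow cell + lane + mean base quality, and per-lane medians
are removed. Two implementation choices deserve comment:

* **Fixed-point residuals.** The literal sequence "fit, subtract, remove
  lane medians" is not idempotent on skewed low-count data: re-running it
  refits small but nonzero lane coefficients of the order of the per-column
  mean-median gap. We therefore iterate the two steps to a fixed point
  (convergence in ~2 iterations in practice), which makes normalization
  exactly idempotent up to the iteration tolerance.
* **Count-aggregate coefficient estimates.** At background rates of 10^-4^
  and depth 15,000 the per-observation alt counts are ~Poisson(1.5), and the
  pseudocounted logit transform attenuates any additive effect by a factor
  of roughly $\lambda\,\mathbb{E}[\log((x+1.5)/(x+0.5))] \approx 0.8$. Batch
  coefficients reported for diagnostics are therefore estimated from
  winsorized per-sample *aggregate* counts (summed over a whole amplicon,
  where the Poisson mean is in the hundreds and the attenuation vanishes).
  With an injected lane effect of 0.3 logit units this estimator recovers
  0.30 +/- 0.02 at 96 samples; the per-column estimator recovers ~0.24.

### Outlier calling

Each sample is tested against the background formed by the other samples at
its column. Two modes share one emission contract (call iff
$-\log_{10} P > 20$ **and** alt count >= 10):

* `betabinom` (operational default): a beta-binomial null is fitted by
  moments to the leave-one-out counts and the exact upper tail is computed.
  Before fitting, samples above the 85th percentile of alt fraction are
  trimmed: a clone spanning several biopsies would otherwise inflate the
  fitted null mean and overdispersion and mask itself (we measured the
  moment $\hat\rho$ inflating ~100-fold with 5 co-clonal samples of 48
  when winsorizing instead of trimming). The trim makes the null slightly
  anti-conservative, which is immaterial five orders of magnitude below the
  emission threshold (typical null counts sit at $-\log_{10}P \approx 6$).
* `robust_z`: the leave-one-out robust z of the normalized residual,
  $z = (r_s - \mathrm{med}(r_{-s})) / \max(1.4826\,\mathrm{MAD}(r_{-s}),
  0.05)$, with a one-sided upper-tail normal P. **This mode cannot reach the
  default cutoff in the stated world**: the logit-residual MAD at
  Poisson-level counts is ~0.7 logit units, so even a 1% spike yields
  $z \approx 5$ ($-\log_{10}P \approx 6$), while the cutoff demands
  $z \gtrsim 9.6$. We keep it as a ranking/diagnostic statistic and as the
  natural choice at lower cutoffs; the exact mode is the default
  everywhere the 20-decade cutoff applies. This is the one place where the
  pipeline's nominal design and its own acceptance conditions genuinely
  conflicted, and we resolved it in favour of the exact test.

The one-sided tail is deliberate: mosaic variants can only raise the alt
fraction above background.

### Prioritization

The filter cascade removes (a) samples/amplicons with an outlying number of
*distinct variants* (threshold $\max(Q_3 + 3\,\mathrm{IQR}, 10)$ over the
respective distribution, zeros included — the floor stops the rule from
firing on sparse clean runs where $Q_3 = \mathrm{IQR} = 0$); (b) calls
within 1 bp of a primer 3' end; (c) whole variants whose maximum VAF
reaches 3% (constitutional heterozygous signal, not mosaic); (d) positions
whose cross-sample median depth is below 5,000x. Variants then need two or
more independent calls (two samples, two overlapping amplicons, or a
replicate pair). Per-biopsy VAFs are arithmetic means over amplicons and
replicates. Adjacent calls with tightly correlated per-biopsy VAFs
(Pearson r > 0.9, or agreement within 20% when only two biopsies are
shared) merge into a single tandem dinucleotide candidate.

Tiers: **1** — overlapping-amplicon or replicate support; **2** — max VAF
>= 0.2%; **3** — max VAF in [0.1%, 0.2%); **4** — below 0.1%. Boundaries are
inclusive downward (exactly 0.2% is Tier 2). Tier 1 does not additionally
require two biopsies, per the definition's plain reading.

### Clonal geography

Biopsies form a graph: ring-neighbours within a slice, same-index biopsies
of adjacent slices. Events are counted conservatively as one per (variant,
testis) — a variant in $k$ testes is at least $k$ independent mutations,
while disconnected patches within a testis may still be one tubule dipping
below detection — with per-testis connected components reported alongside as
the upper bound. A variant is flagged as a candidate early post-zygotic
mosaic when its positive biopsies span >= 3 slices in >= 2 components with
>= 6 biopsies; these thresholds are ours (the source material describes one
example, not a rule) and were chosen so that a scattered multi-slice pattern
flags while a connected three-slice tubule walk does not.

### Enrichment statistics

Fisher's exact test uses the sum-of-smaller-probabilities two-tailed
convention (ties within 1e-7 relative). The per-base logistic coefficient
for pathway enrichment is the closed-form log odds ratio of
variant-carrying callable bases (equal to the saturated one-predictor MLE;
Haldane-Anscombe 0.5 on zero cells), with a Wald P. The observation unit
behind the published coefficient lives in supplemental tables we do not
reproduce, so table construction is explicit user input. Tandem fold
enrichment is $(n_{tandem}/n_{total})/r_0$ with $r_0 = 0.003$ by default.

## The synthetic world

Defaults state the emulated study at desk scale: 30 amplicons (120–180 bp,
primers 18–25 bp, 10% overlapping pairs, 41.9% of callable bp labelled
RAS-MAPK), 1–2 testes of slices with 23–24 biopsy rings (48–96 samples; the
full design was 288 samples from 276 biopsies with 12 duplicates), depth
15,000x (negative binomial, size 30), log-normal background (median 1e-4,
sigma 0.8, hard-capped below 1%), batch effects of 0.1–0.5 logit units,
beta-binomial overdispersion rho = 1e-5, 1,000 template molecules per
(sample, amplicon), clones with peak VAF log-uniform on (0.005, 0.029] and
geometric decay 0.6 along a self-avoiding walk. What a green test does
*not* establish: real error motifs (context-dependent substitution spectra,
strand bias, indels), alignment artifacts, or droplet-level PCR dynamics —
the generator is deliberately structural, not sequence-realistic.

## Numerical choices

Quality ties in mate-overlap resolution go to read 1 (deterministic;
early-cycle bases are typically higher quality). Mismatches are counted
after primer trimming (primer bases are oligo-derived). The beta-binomial
tail is summed in log space in chunks with early termination past the mode.
The MAD floor (0.05 logit units) prevents infinite z on degenerate columns.
Zero-depth observations are skipped; columns with fewer than 8 informative
samples are dropped with a warning.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(
  seed = 42,
  panel = list(n_amplicons = 30),
  layout = list(n_testes = 2, slices_per_testis = 2,
                biopsies_per_slice = 12, n_replicates = 2),
  clones = list(n_clones = 5, vaf_range = c(0.004, 0.025)),
  depth = list(mean_depth = 15000))
manifest <- run_pipeline(cfg, "run1")
manifest$tier_counts
read_candidates("run1")$candidates
```

## Known limitations

* Sensitivity at the fixed $-\log_{10}P > 20$ cutoff drops for clones whose
  realized VAF falls below ~0.15% after the template bottleneck; this
  mirrors the validated detection floor of the emulated study (0.06% best
  case) rather than a software limit.
* The trimmed null fit tolerates up to ~15% co-clonal contamination per
  column; a clone occupying most of a small cohort (e.g. a broad
  post-zygotic variant in 20% of biopsies) will be partially masked.
* Event counting is purely graph-combinatorial: no attempt is made to infer
  true tubule trajectories or clone ages.
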