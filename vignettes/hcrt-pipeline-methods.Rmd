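---
title: "Methods: enrichment calling, promoter motif analysis and larval sleep scoring"
author: "hcrtseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enrichment calling, promoter motif analysis and larval sleep scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

Hypocretin (orexin, Hcrt) neurons are a small hypothalamic population that
regulates sleep and wake. Profiling them requires sorting a few hundred
fluorescent cells out of a whole larval zebrafish head, sequencing heavily
amplified low-input RNA, and then separating genuine cell-type-specific
expression from amplification noise and contamination. `hcrtseq` implements
the three computational stages of such a study — enrichment calling from
count matrices, prediction of shared transcription-factor (TF) regulators
from conserved promoter binding sites, and sleep-architecture scoring of
larval locomotor traces — together with synthetic-data generators that make
every stage testable against known ground truth.

## Enrichment calling

### Normalization

Raw counts $c_g$ with transcript lengths $l_g$ are normalized per sample to
transcripts per million:

$$\mathrm{TPM}_g = 10^6 \,\frac{c_g/l_g}{\sum_j c_j/l_j},$$

so every column sums to $10^6$. Abundance and fold thresholds are stated on
the TPM scale. Between-sample scaling uses a trimmed-mean-of-M-values
factor: per-gene $M_g = \log_2(c_{gs}/c_{gr})$ against a reference sample,
over genes non-zero in both, with the extreme 30% of $M$ and 5% of the
average log-abundance $A$ trimmed two-sidedly and the remainder averaged
with inverse asymptotic-variance weights; the factor is $2^{\bar M_w}$. Our
factor is kept on the raw-count scale (a sample with every count doubled
gets factor 2), so dividing by library size yields the usual
composition-bias correction. The exact trim fractions of the published
variant are not recoverable; 30%/5% with precision weights are the
method's canonical defaults and are exposed as arguments.

TPM feeds the abundance/fold filters; the TMM factors feed the count test
as effective library sizes. This split follows from the thresholds being
quoted in TPM while the significance test operates on raw counts.

### The overdispersion-corrected exact test

Replicates are pooled within each group (sorted EGFP+, sorted EGFP-, whole
head), increasing per-gene coverage and averaging amplification bias.
Low-input libraries are overdispersed relative to Poisson; the inflation
factor $\varphi$ is estimated as the median over well-expressed genes
(mean count $\ge 10$) of the within-group variance/mean ratio averaged
across the replicate groups, floored at 1. With three replicates this
ratio is itself noisy (its median sits near $0.89\,\varphi$), which is
accurate enough for the variance correction it feeds; the estimator's
recovery bands are exercised in the tests.

For one gene, counts $a$ and $b$ from two groups with effective library
sizes $L_a$, $L_b$ are first deflated by $\varphi$ (quasi-Poisson
variance-inflation correction), then tested conditionally: given
$n = a' + b'$, under the null $a' \sim \mathrm{Binomial}(n, L_a/(L_a+L_b))$;
the two-sided p doubles the smaller tail and is capped at 1. Deflation
keeps an exact, enumerable small-count oracle — the reason we did not move
to a negative-binomial likelihood. Enrichment must hold against *both*
controls, encoded as $p = \max(p_{\mathrm{EGFP-}}, p_{\mathrm{head}})$ (the
combination rule is a design choice; the requirement itself is not).

Bonferroni correction multiplies by the number of genes whose mean raw
read count in the sorted replicates exceeds 15 — only those genes are
analyzed at all. Two tiers classify significant genes: strict
($\ge 100$ TPM in sorted cells and $\ge 7\times$ the larger control) and
relaxed ($\ge 10$ TPM, $\ge 3.6\times$), both at Bonferroni-adjusted
$p < 0.01$; the output lists genes above the relaxed fold, sorted by fold
with ties broken by gene id. A pseudocount (default 1 TPM) guards fold
changes against zero controls.

The methods narrative is tense about replicate handling (groups are pooled
for the thresholds, yet the test is described per replicate); both modes
exist behind `pooling`, with `pooled` the default because the reported
abundance thresholds operate on unified groups. The per-replicate mode
combines by taking the largest p, which is never less conservative.

## TF binding-site analysis

Position weight matrices are regularized with a background-proportional
pseudocount and scored as $\sum_j \log_2(f_{j,b}/q_b)$ over a window.
Matrix databases ship per-matrix thresholds that we cannot reproduce; the
default threshold is 85% of the maximal attainable score, per matrix and
configurable. Both strands of every promoter are scanned; windows
containing `N` are skipped.

Conservation is approximated positionally: a reference-species hit is kept
only if every other species has a threshold-passing hit for the same
matrix within 10 bp of the same offset on equal-length promoter windows
(default 2 kb upstream in real use; the simulators use shorter windows).
True multiple alignments are out of scope; the tolerance window absorbs
small indel shifts. With one species the filter is the identity.

Per gene and TF, the combined score sums each conserved hit's excess over
the matrix threshold, so over-represented sites raise the score and an
added hit can never lower it; `max` and `count` aggregations are available
because the published description fixes the intent, not the formula.
TF-set enrichment of a foreground gene set (e.g. the 48 most-enriched
transcripts) against a background is a one-sided hypergeometric tail on
genes carrying at least one conserved hit, Benjamini–Hochberg adjusted
across TFs at 0.05. The default background is all genes in the promoter
set — the annotation-service background the study used is not portable.

## Sleep scoring

Sleep in larval zebrafish is behaviorally defined as one or more minutes
of immobility. A minute is immobile iff activity $\le \epsilon$ (default
exactly 0; $\epsilon$ exists for noisy trackers); bouts are maximal
immobile runs. Per clock hour we report sleep minutes, wake-to-sleep
transitions (bout onsets — so the transition count equals the bout count
and is consistent with the bout-length summary; published transition
counts appear to tally both directions, roughly doubling ours), and the
mean length of bouts *starting* in that hour. A bout spanning an hour or
light-phase boundary counts toward its onset hour, keeping counts
additive. Day/night aggregates are per-hour means over the 14 h light /
10 h dark phases, lights-on at minute 0.

Genotype contrasts use a two-group permutation test on per-larva phase
aggregates (difference of group means; exhaustive enumeration when the
number of assignments is at most 20,000, otherwise 999 sampled
relabelings with the +1 correction). This deliberately replaces the
mixed-model repeated-measures ANOVA used with commercial software: it is
distribution-free, has no convergence failures at small n, and is
verifiable against exact enumeration. Sleep-deprivation rebound compares
post-deprivation sleep between deprived and control larvae over matched
windows with the same machinery.

## Synthetic data: what it emulates, and what it does not

**Counts.** True per-gene abundances are log-normal on the TPM simplex;
expected counts follow each group's library depth (defaults 24, 22 and
175 million reads per replicate) weighted by abundance × length; replicate
counts are negative-binomial with variance $\varphi\,\mu$ (a single global
$\varphi$, default 2 — the simplest structure consistent with
amplification noise; $\varphi = 1$ is exactly Poisson). Planted genes get
their sorted-cell abundance raised `planted_fold`-fold (default 10) over
both controls with at least `planted_min_tpm` (default 150) in the sorted
cells. Not emulated: gene-specific dispersions, GC/length bias,
contamination of the sorted fraction by neighboring cells, or novel
transcript assembly — so passing recovery tests shows the caller's
statistics are sound, not that real FACS contamination is handled.

**Promoters.** Uniform-random sequence with motif instances implanted at a
shared offset across all species for planted genes and in one species only
for background carriers (rate 0.05). Instances are sampled from the PWM
with rejection until they pass the matrix threshold (consensus fallback),
so planted sites are detectable by construction. Real promoters have
composition bias, repeats and true alignments with indels; none are
modeled.

**Traces.** Each larva is a two-state (wake/sleep) Markov chain at minute
resolution — an alternating renewal process with geometric bout lengths —
parameterized per genotype and phase by stationary sleep time (min/h) and
mean bout length; the wake-to-sleep rate is implied ($f\,p_{sw}/(1-f)$
with sleep fraction $f$ and $p_{sw} = 1/L$). Defaults are calibrated to
the published genotype means: night sleep 13.08 / 14.78 / 15.46 min/h
(hom/het/wt), day 2.76 / 2.80 / 2.87, night bout lengths 2.21 / 2.32 /
2.43 min. Day bout length is not separately recoverable (published day
sleep and transition counts would imply sub-minute bouts, impossible at
minute resolution), so it is fixed once at 1.2 min for all genotypes; the
night contrasts are the effects of interest. Individual larvae differ
beyond the chain's own sampling noise: per-larva sleep levels are
gamma-distributed around the genotype mean with between-larva SD 2.0
(day) and 1.5 (night) min/h, chosen so the total per-larva dispersion
matches published cohort SEMs ($\approx$ 2.0–2.1 day, 2.5 night min/h at
$n \approx 85$–98). Without this heterogeneity the day-phase variance
would be several-fold too small and trivial day differences would appear
significant. Wake-minute activity is gamma with mean 10 in arbitrary
units — published figures give no activity units, so none are modeled.
The chain relaxes to the new stationary level within a few minutes of a
phase switch; the resulting bias on phase means is two orders of
magnitude below the between-larva SE.

## Numerical choices and degenerate inputs

* All-zero count columns map to all-zero TPM with a warning; zero or
  negative lengths are errors.
* A pair of zero counts gives p = 1; deflated counts are rounded to keep
  the conditional test exact.
* Quantile-based trimming keeps ties (identical $M$ values are never
  split), which makes the doubled-counts case exact.
* Scan hits are reported in ascending offset, `+` before `-` at equal
  offset; output ordering everywhere breaks ties by identifier so results
  are byte-reproducible.
* Every generator takes an explicit integer seed; there is no hidden
  global random state, and equal seeds give identical output.

## Problem sizes used by the test-suite studies

The statistical studies in the tests use: 100 null datasets of 10,000
genes (family-wise error calibration), 20 planted datasets of 10,000
genes with 50 planted genes at $\varphi = 2$ (recovery), the full
$a, b \le 50$ × library-ratio grid against an enumeration oracle, 100
random 500-bp promoters × 20 matrices against a brute-force scorer, 100
planted-promoter sets (30/48 foreground, 5% background, 3 species), and
100 cohorts of 90 larvae per genotype with 999-permutation contrasts.
These sizes make Monte-Carlo bounds tight enough to be meaningful while
keeping the default test run to minutes.

## Known limitations

* The enrichment caller starts from a gene-level count matrix; alignment,
  assembly and novel-transcript discovery are upstream and out of scope.
* The conservation filter assumes positionally comparable promoter
  windows; it cannot recover sites displaced by large indels.
* Published TF counts from proprietary matrix collections are not
  reproducible and are not targets; the module's claims are about its
  statistics, demonstrated on planted ground truth.
* The sleep module consumes minute-binned activity exported by tracking
  software; arousal thresholds and sub-minute behavior are invisible at
  this resolution.
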