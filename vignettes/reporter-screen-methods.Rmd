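---
title: "Models and methods behind mutscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mutscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutscreen)
```

`mutscreen` analyses mutagenesis screens in which a population of yeast
cells carrying a promoter–YFP reporter is chemically mutagenized (EMS,
which causes predominantly G/C→A/T transitions), scored per cell by flow
cytometry, and mined for mutants with altered reporter activity. This
vignette documents the underlying models, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical and design choices a careful reader should know about.

## The measurement model

Flow cytometry reports, per cell ("event"), forward scatter (FSC, a proxy
for cell size) and fluorescence, both on arbitrary log scales. Within a
genotype, log10 YFP is close to linear in log10 FSC, so reporter *activity*
is summarized per cell as the ratio of log10 fluorescence to log10 FSC, and
per culture as the **median ratio over events inside an FSC gate** (default
window 5.30–5.55 log10 units; a percentile-based gate at the 20th–80th FSC
percentiles is available for instruments where fixed values are not
meaningful, via `gate_window_percentiles()`).

The phrase "median YFP/FSC ratio after log transformation" admits two
readings: the median of per-event ratios of the log10 values (our default,
`ratio_mode = "ratio_of_logs"`) or the median log of the linear ratio,
i.e. the median difference of log10 values (`ratio_mode = "log_of_ratio"`).
Both are implemented; they differ only by a smooth monotone reparametrization
in the relevant range and lead to identical mutant calls in practice, but the
switch keeps the choice explicit.

Culture-level effects are standardized as a Z-score against at least 10
replicate control cultures, using the sample (n−1) standard deviation —
control replicate counts are small (10–143), so the n−1 convention matters.
A genotype is a **mutant** iff |Z| > 2.58, the two-sided normal critical
value at α = 0.01 (`z_threshold(0.01)`); the inequality is strict, and the
recessivity call in diploids (|Z| < 2.58) is its strict complement, so the
boundary belongs to neither. Control cultures themselves are standardized
leave-one-out, making their Z-scores valid null draws (≈1% exceed the
threshold by construction).

Variance Z-scores apply the same standardization to the per-culture
variance of the event-level ratio, catching mutants that broaden the
fluorescence distribution without shifting its median.

## Mutation-rate inference

The treated and control per-cell phenotype distributions are compared on
common equal-width bins (default 256 spanning the pooled range; the count
difference is insensitive to bin counts in the 128–512 range). Control
counts are scaled to the treated total. A cubic smoothing spline
(`stats::smooth.spline`, smoothness by generalized cross-validation unless
`spline_df` is fixed) is fitted to the per-bin difference; for a well-formed
screen it is negative across the central mass (treated cells depleted) and
positive in both tails (mutants accumulated).

**Crossing location.** Zero crossings are sign changes of the spline on a
1,000-point grid, refined by bisection. A lightly-smoothed spline can wiggle
through zero many times, so among all crossings we select the *dominant
pair*: the downward crossing at which the cumulative integral of the spline
is maximal and the upward crossing at which it is minimal. Because the
cumulative integral rises over the low-tail excess, falls through the
central deficit, and rises again over the high-tail excess, this pair
brackets the central mass by construction and is robust to spline ringing.
If no such pair exists (e.g. treated and control are identical), the
comparison is **degenerate**: the function warns, sets `f = 0`, and flags
the result rather than failing, so that pipelines on null data run to
completion.

**The frequency.** `f` is the net sum of the *raw* (unsmoothed) bin
differences outside the crossings, divided by the treated total; the spline
only locates the crossings. Summing the net difference rather than only
positive per-bin parts avoids the upward bias that half-normal counting
noise would add (a `positive_part = TRUE` option exposes the alternative).

Under a Poisson model for the per-cell number of activity-affecting
mutations, `poisson_mutation_load()` converts `f` to
λ = −ln(1 − f), P₁ = λe^(−λ), P₍>1₎ = 1 − P₀ − P₁. Dividing λ by the
mutagen's fold-elevation — the ratio of the marker-mutant frequency in the
treated population to the marker's known spontaneous rate
(`calibration_fold()`) — yields a spontaneous rate for the reporter-activity
phenotype (`spontaneous_rate()`).

The tail-excess estimator identifies the planted load only when mutant
cells actually leave the control bulk: cell-to-cell spread is much larger
than culture-to-culture noise, so effects detectable at the culture level
(|Z| slightly above 2.58) can be invisible at the cell level. Parameter
recovery therefore holds in the large-effect regime (validated at
λ ∈ {0.01, 0.03, 0.1} with ~2-fold effects, <10% relative bias at 10⁶
cells), and the default small-effect trans class is partially missed — a
property of the method, faithfully reproduced, not a bug.

Sorting arithmetic is desk-scale: if thresholds capture `s_c` of the
control and `s_t` of the treated population, the expected mutant purity of
the sorted tail is `(s_t − s_c)/s_t`, and the expected direction
composition of the recovered collection weights each tail by
events × colony rate × purity (`expected_direction_fraction()` reports both
tails' shares rather than privileging either).

## Functional classification

Reporter-gene mutation records live in TSS-relative coordinates (+1 at the
transcription start, no position 0). The bundled default annotation places
the promoter at −680..−1, the CDS at +25..+741 and the terminator at
+742..+990; the TSS→ATG offset is an explicit annotation field, not a
constant, because it is a property of the construct. The bundled CDS
(`inst/extdata/yfp_cds_synthetic.fa`) is a **synthetic stand-in**: 717 nt
(238 codons + stop) with GC content 35.56% and a third-position CTG at the
codon covering position +348, so that the documented landmark calls (a
silent G→A at +348, promoter mutations at −255/−240/−140) behave as
expected. It is generated, not the real Venus sequence.

Coding consequences are called by translating the affected codon before and
after substitution (standard nuclear code, via Biostrings); a reference-base
mismatch against the annotation is a data-integrity error, not a silent
re-call.

Copy number comes from pyrosequencing allele fractions: with n reporter
(YFP) copies against one reference (CFP) copy, the expected YFP fraction is
n/(n+1) — 1/2 and 2/3 clusters for one and two copies. The caller splits at
their midpoint 7/12 with an indeterminate buffer of ±2 binomial standard
errors at the observed depth (the data show clusters, not thresholds, so
the decision rule is a package choice; at 1,000 reads it essentially never
crosses over, and assays under 100 reads are flagged `low_depth`).

Class assignment is a total function over the evidence lattice with
precedence coding > cis > CNV > trans (multiple evidence lines were never
observed in practice, but totality needs a rule). A *synonymous* CDS change
is class-uninformative: it falls through to the copy-number evidence, which
matches how such a genotype is counted in the trans class when its assay
shows one copy. With no informative reporter-gene change and no usable
assay the genotype is `ambiguous` — it could be CNV or trans — and is
excluded from class comparisons rather than guessed.

## Dominance analysis

Each mutant haploid is crossed to a CFP-marked reference; diploid YFP reads
out the mutant allele and CFP the reference allele. Z-scores are computed
against diploid-specific controls (haploid and diploid Z-scores are not
directly comparable — the control spreads differ).

"Model II regression" of diploid on haploid effects does not name its
variant, so both common ones are implemented: **major axis** (default;
slope from the leading eigenvector of the 2×2 covariance matrix, computed
in closed form) and **standardized major axis** (`method = "sma"`). MA is
invariant to a common rescaling of both axes but *not* to rescaling one
axis; SMA is the right choice if the two Z-scales are not considered
commensurate. With a fully recessive class (diploid Z pure noise,
covariance ≈ 0 and x-variance ≫ y-variance) the MA slope is ≈ 0, as
expected; note the reverse regression (CFP on YFP within such a class) is
near-degenerate and its slope should not be over-read.

Rank comparisons of |Z| between classes use a Mann–Whitney–Wilcoxon test
authored in the package: exact by complete enumeration (midranks for ties)
up to combined n = 12 — ties are why `stats::wilcox.test` cannot serve, as
it abandons exactness when ties occur — and a normal approximation with tie
and continuity correction beyond. Sidedness is a parameter (one of the
standard class contrasts is one-sided). Colony-formation rates are compared
with `stats::fisher.test`, whose two-sided rule is exactly the
point-probability convention required. **No multiple-testing correction is
applied anywhere**, deliberately, matching the analysis style the package
reproduces; the handful of planned contrasts does not warrant one, but
users running many contrasts should adjust externally.

`build_summary_table()` assembles the per-class summary (counts and
fractions, haploid and diploid median |Z|, direction fractions, MA slopes,
recessive fractions, CFP cross-effects). Genotypes without diploid data are
excluded from diploid statistics only; empty classes yield zero-count rows.

## The synthetic-data generator

`sim_config()` defaults encode the screen conditions the package models;
they are defaults, not truths:

| parameter | default | meaning |
|---|---|---|
| `mean_load` | 0.0303 | Poisson mutations per genome after mutagenesis |
| `class_weights` | 7/10/2/81% | coding/CNV/cis/trans mutation classes |
| `effect_params` | per class | magnitude of the log10-activity shift, lognormal; calibrated so culture-level median \|Z\| lands near 48/8/8/5 |
| direction (`p_positive`) | 0, 21/22, 1/2, 131/179 | fraction of effects increasing activity |
| `dominance` | 1/1/1/0 | fraction of the haploid effect expressed in heterozygotes |
| `fsc_mean`, `fsc_sd` | 5.42, 0.10 | log10 FSC distribution |
| `yfp_slope`, `yfp_intercept`, `yfp_resid_sd` | 1, −0.70, 0.012 | log-linear FSC→YFP model (implying FSC–YFP correlation ≈ 0.99) |
| `culture_noise_sd` | 0.0010 (haploid), 0.0008 (diploid) | between-replicate sd of the phenotype |
| `events_per_culture` | 5,000 haploid / 9,000 diploid | screen floor per clonal culture |
| `pyro_reads` | 1,000 | reads per copy-number assay |
| `cnv_cfp_effect` | 0.96 | multiplicative CNV effect on the diploid CFP channel |

Design choices worth stating:

- **Effects are multiplicative on linear activity** — additive shifts of
  log10 fluorescence — because the measurement is log-scale and effects are
  reported as standardized shifts. Multiple mutations in one cell combine
  multiplicatively; under the default load such cells are ~1% of mutants,
  so the choice is rarely exercised.
- **A CNV genotype carries a planted activity effect, not a hard 2×.**
  Doubling the template does not empirically double fluorescence (two-copy
  mutants show intermediate effects, well below the largest coding
  effects), so the generator treats the net activity consequence of a
  duplication as a calibrated draw (default median |Z| ≈ 8, 95%
  increases), carries `copies_yfp = 2` for the pyrosequencing layer, and
  reproduces the reference-allele repression pattern in diploids
  (YFP up, CFP down) through `cnv_cfp_effect < 1`. Only whole-reporter
  duplications to two copies are modelled.
- **Dominance** scales the haploid log-effect in the heterozygote: coding,
  cis and CNV alleles act allele-specifically on the YFP channel (the
  diploid's YFP comes only from the mutant allele, hence near-additive
  behaviour and haploid→diploid slopes above 1, since diploid controls are
  slightly tighter); trans mutations act through diffusible factors on
  *both* channels, scaled by their dominance coefficient, default 0 (fully
  recessive). The distribution family of trans effects is not asserted
  anywhere as a fact — it is exposed as configuration.
- **Randomness** derives from a single master seed; per-genotype sub-seeds
  are drawn deterministically from it, simulations restore the caller's
  RNG state, and identical configurations give bit-identical datasets.

What the generator does **not** emulate: FCS binary files, spectral
overlap/compensation, doublets, cell-cycle or growth-rate structure,
non-normal FSC distributions, clonal relatedness among recovered mutants,
position effects within the promoter, or genome-scale sequence mutagenesis
(reporter-gene mutation records are drawn directly at EMS-compatible
sites). Passing tests on synthetic screens therefore validate the
*arithmetic and inference chain*, not instrument- or biology-level
idiosyncrasies of real cytometry data.

## Problem sizes and numerical conventions

Validation uses: 10⁶-cell populations for load recovery (three loads,
<10% relative bias with ~2-fold planted effects); 1,137 control cultures of
5,000 events for the false-positive rate (expected inside the exact
binomial 95% band around 1%); a 221-genotype panel (16/22/4/179) with
9,000-event diploid cultures for the dominance contrasts; 10,000-replicate
binomial simulations at 1,000 reads for the copy-number caller
(misclassification < 0.1%); and complete enumeration up to combined n = 10
for the exact tests. Percentages are reported at full precision and rounded
only for display. Exact-test comparisons use a relative tolerance at
machine-precision scale; boundary cases (|Z| exactly at threshold, tied
observations, zero-variance controls, empty gates, zero-read assays) are
all defined behaviour — strict inequality, midranks, and typed errors
respectively — rather than accidents of floating point.

## Known limitations

- The tail-excess frequency under-counts small-effect mutants (see above);
  the package reports what the method measures.
- The expected-direction arithmetic depends on which purity is paired with
  which tail's colony rate; both shares are reported.
- MA slopes for classes with essentially uncorrelated haploid/diploid
  effects are near 0 but their *reverse* fits are unstable; interpret
  per-class CFP slopes only where the class shows real CFP effects.
- The bundled CDS is a synthetic stand-in; users analysing a real construct
  should supply their own `reporter_annotation()` with the true sequence
  and spans.
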