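---
title: "Sexing cattle samples from RNA-seq or in-silico PCR: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sexing cattle samples from RNA-seq or in-silico PCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chrysexer)
```

## The sexing model

Female cattle carry no chromosome Y, so any robust ChrY signal — RNA or
DNA — identifies a male. Both arms of this package reduce to that single
biological fact.

**RNA-seq arm.** For a marker panel $P$ of ChrY genes and sample $s$, the
statistic is the cumulative normalized abundance

$$T_s = \sum_{g \in P} \mathrm{CPM}(g, s), \qquad
\mathrm{CPM}(g,s) = \frac{y_{gs}}{N_s f_s} \times 10^6,$$

with $y_{gs}$ the raw count, $N_s$ the library size and $f_s$ the TMM
normalization factor. The decision rule is a double threshold:
female if $T_s \le \tau_F$, male if $T_s \ge \tau_M$, ambiguous in
between. The underlying signal is zero-versus-large: in the reference
tissue cohorts the female cumulative CPM tops out at 0.37 while the male
minimum is 30.92, and in blastocysts the extremes are 0.0592 (one female
leak) versus 22.02. No explicit numeric thresholds accompany those
published calls — they were made by inspection of zero versus large
values — so the defaults here, $\tau_F = 1$ and $\tau_M = 10$ CPM, are an
artifact decision: each sits roughly an order of magnitude from the
nearest observed extreme of the wrong class, and the band between them
exists so that borderline contamination degrades to *ambiguous* (which
exits with a distinct status for routing to the PCR assay) instead of
silently flipping a call.

**PCR arm.** A multiplex reaction combines a male-specific (MSY) primer
pair with an autosomal control pair (CDK1, chromosome 28). The band
pattern is read as: male iff at least one MSY band *and* at least one
control band; female iff control band(s) only; indeterminate iff no
control band (a failed reaction must never be read as female). The
in-silico twin predicts bands purely from sequence matching — no melting
temperatures, dimers or hairpins, which is deliberate: the assay's value
is primer uniqueness in non-repeated MSY sequence, a property of sequence
identity, not thermodynamics.

## TMM normalization, from its definition

The package re-implements the trimmed mean of M-values rather than calling
an existing implementation, because the normalization is part of the
procedure under test; the established implementation (edgeR) serves as an
independent oracle in the test suite, where both must agree to $10^{-6}$
on random negative-binomial matrices. The definition followed, with all
defaults as documented for the cited function:

* reference sample: the one whose 75th-percentile count fraction is
  closest to the mean of those fractions (ties: first in input order);
* per gene, on library-size-scaled counts against the reference:
  $M_g = \log_2\frac{y_{gs}/N_s}{y_{gr}/N_r}$ and
  $A_g = \tfrac12\left(\log_2 \tfrac{y_{gs}}{N_s} + \log_2
  \tfrac{y_{gr}}{N_r}\right)$, with genes zero in either sample dropped
  pairwise;
* double trimming: 30% each side by rank of $M$, 5% each side by rank of
  $A$ (ranks via midranks for ties; boundary kept when
  $\mathrm{rank} \ge \lfloor n\,t\rfloor + 1$);
* weighted mean of the surviving $M_g$ with inverse delta-method binomial
  variances $v_g = \frac{N_s - y_{gs}}{N_s y_{gs}} +
  \frac{N_r - y_{gr}}{N_r y_{gr}}$ (weighting can be disabled);
* $f_s = 2^{\bar M}$, then all factors rescaled to geometric mean 1. A
  sample sharing no expressed gene with the reference gets factor 1 with a
  warning; if all $|M| < 10^{-6}$ the factor is exactly 1.

CPM adds **no** prior count. The classifier depends on females being
*exactly* zero; a pseudo-count would destroy the $T_s = 0$ signature.

## The differential score

The published screen ranked ChrY genes with a quasi-likelihood NB GLM
F-test. Re-implementing that empirical-Bayes machinery would reproduce a
large general-purpose package inside a single-purpose tool, so the ranking
statistic here is a defined simplification, documented as such: a per-gene
NB likelihood-ratio test with

* group means as quasi-ML proportions, $\hat p_k = \sum_{s\in k} y_s \big/
  \sum_{s \in k} N_s f_s$, on the effective-library-size offset scale;
* one pooled within-group method-of-moments dispersion per gene,
  $\hat d = \sum_s \left[(y_s-\hat\mu_s)^2 - \hat\mu_s\right] \big/
  \sum_s \hat\mu_s^2$, floored at $10^{-8}$ so Poisson-exact fits cannot
  yield infinite statistics;
* score $= 2(\ell_{\text{two-group}} - \ell_{\text{pooled}})$, clipped at
  zero, with $p$ from $\chi^2_1$.

This is a *ranking* device, not genome-wide inference — hence no FDR
machinery. Its fidelity is established behaviorally: planted 32-fold
markers are recovered, estimated log-fold-changes center on the truth
(median within 0.25 of planted effects of 2, 4 and 8 log2 units at 15
samples per group), and the statistic is label-symmetric and
order-invariant. The displayed `logFC` uses a prior abundance of 0.25 CPM
purely to keep zero-count groups finite; the prior never enters the
statistic. Panel selection then applies the male-specificity filter (max
female CPM ≤ 1, min male CPM ≥ 10 by default) to the score ranking —
the rank alone is insufficient, since strongly *female*-enriched genes
also rank highly.

Two published conventions are kept configurable because the source leaves
them open. The abundance filter "more than 600 reads" is implemented as a
strict inequality on the raw-count total; whether 600 was meant relative
to the original 64-sample design (≈ 9.4 reads/sample) is not stated, so a
per-sample-scaled mode exists behind `scale_min_reads_per_sample`. The
coordinate window keeps genes *fully contained* in
[6,953,027, 15,591,347] — consistent with the top marker starting exactly
at the window start — with an overlap mode behind a flag.

## In-silico PCR conventions

A primer site is a placement on either strand with at most `max_mismatch`
mismatches whose 3′-terminal `anchor_3prime` bases (default 3) match
exactly; `N` in a template never matches. The default is exact matching
(`max_mismatch = 0`): the assay was designed for uniqueness in
non-repeated MSY sequence, so strict matching is the faithful default and
mismatch tolerance (up to 2) exists for robustness exploration. Product
length counts both primers, on 1-based inclusive coordinates, capped at
5,000 bp (no plausible band under a 30-second extension); these
conventions make declared product lengths directly checkable against
sequence. Declared expected lengths are *claims under test*: the published
MSY product is stated as 279 nt but its printed coordinate spans imply 179
or 287 nt, and the CDK1 product as 590 nt against a 570 nt span.
`verify_published_amplicons()` therefore reports the empirically computed
length next to the declared one and flags disagreement; it never coerces
either number to the other. The real ChrY (CM011803.1) and chromosome-28
sequences are far too large to bundle, so that confrontation runs only
when the user supplies the downloaded FASTAs; the package's tests exercise
the identical code path on synthetic templates (labelled `syn_*`) with
planted products at, and deliberately off, the declared lengths.

Amplicon identity verification mirrors the wet-lab Sanger check with a
local alignment (match +1, mismatch −1, gap −2 per base) via
`pairwiseAlignment`, reporting percent identity and placement.

## What the synthetic generator emulates

`synthetic_spec()` fixes the simulated study conditions:

| parameter | default | rationale |
|---|---|---|
| samples | 10 + 10 | small-cohort scale of a blastocyst experiment |
| genes | 996 background + 4 markers | 1,000-gene matrix; 4-gene panel as published |
| library sizes | log-uniform 1e7–4e7 | the reported mean depths (≈ 17.8M and 48.7M fragments) bracket this range; log-uniform exercises TMM non-trivially |
| marker male CPM | 40 per gene | cumulative ≈ 160, near the reported male blastocyst average of 161.38 |
| female leak | prob 0.05, ≈ 0.05 CPM | zero-inflation, not a small NB mean: observed females are exactly zero except rare tiny values (0.0592, 0.37) |
| dispersion | 0.1 | typical bulk RNA-seq (variance $\mu + d\mu^2$) |

Background genes share one log-normal abundance profile across sexes and
sit on autosomes; markers are annotated inside the ChrY window. Leak
counts are drawn as $\max(1, \mathrm{Pois}(\lambda))$ so a leak is always
visible but stays far below $\tau_F$ at these depths. Genomes for the PCR
arm are 20 kb random ACGT sequences with the control construct planted in
both sexes and the MSY construct in males only; after planting, every
primer is re-scanned and the genome redrawn if any site appears other than
exactly the expected number of times (accidental 19–20-mer matches in
20 kb are vanishingly rare, so redraws almost never trigger).

What passing on this generator does **not** show: real data add
multi-mapping of X/Y-homologous reads (the reason females show *any* ChrY
signal at all), tissue-specific expression, batch structure, and
library-prep artifacts. The simulation validates the statistical machinery
and decision logic, not read alignment — which is out of scope along with
BAM processing and actual PCR chemistry.

## Numerical choices and degenerate inputs

All randomized routines are pure functions of an integer seed, and the
simulator restores the caller's RNG state. Ties in TMM reference selection
fall to the first sample; trimming uses midranks so tied M/A values are
kept or dropped symmetrically. Counts must be nonnegative integers with
unique gene and sample ids; all-zero samples, missing normalization
factors and missing panel genes are hard errors (a silently missing ChrY
row would sex every sample female). Empty amplicon sets are valid results
(no band), as are empty gene sets after filtering; an assay without a
control pair is invalid by construction.

## Problem sizes

The bundled checks run at desk scale by design: TMM oracle agreement on
50 random 20–100 × 2–6 matrices, marker recovery on 100 simulated
1,000 × 20 cohorts, end-to-end calling on 50 cohorts, and 100-instance
brute-force agreement for the primer scanner — a few tens of seconds in
total. These sizes were chosen as the smallest at which the binomial
pass/fail criteria (e.g. ≥ 95/100 recovery) are meaningful.

## Known limitations

* The RNA-seq arm presumes counts quantified against a ChrY-aware
  annotation; with no ChrY rows at all it refuses to call rather than
  returning all-female.
* The NB score is per-gene with a common dispersion across groups; it is
  not a substitute for genome-wide differential-expression inference.
* The PCR arm models annealing as string matching; primers that fail for
  thermodynamic reasons will still "amplify" in silico.
* Thresholds $\tau_F, \tau_M$ are calibrated to bulk/low-input RNA-seq
  depths; single-cell depths (far fewer reads) compress cumulative CPM
  toward the ambiguous band, which is the safe failure mode.
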