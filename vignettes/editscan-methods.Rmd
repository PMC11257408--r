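---
title: "Methods: edit-site discovery, motif profiling and screen statistics"
author: "editscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: edit-site discovery, motif profiling and screen statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editscan)
```

`editscan` discovers depletion-sensitive C-to-U RNA editing sites from
replicated RNA-seq pileups and quantifies the nucleolar phenotypes used in
high-content screens for ribosome biogenesis factors. This vignette explains
the statistical model behind each stage, the parameters that matter, the
design decisions taken where the problem was genuinely open, and what the
synthetic-data generator does and does not emulate.

## The variant-calling model

A pileup site is a vector of base counts $(n_A, n_C, n_G, n_U)$ with depth
$D = \sum_b n_b$. Under the null hypothesis of no editing, a non-reference
base at a site arises only from sequencing error. We model error as a uniform
per-base substitution rate $e$ (default $10^{-3}$) split equally among the
three non-reference bases, so the alternative count at a reference-C site is
$X \sim \mathrm{Binomial}(D,\, e/3)$ in the absence of editing. A site is
called when

* $D > 10$ (strict inequality: depth 10 is excluded, 11 is the minimum), and
* the one-sided upper tail $p = P(X \ge n_U)$ is below $\alpha = 0.05$.

The test is one-sided because only an excess of the edited base is evidence
of editing. No base-quality weighting is applied — the pileup dialect carries
no qualities — and the caller is a deliberately simple binomial model, not a
reconstruction of quality-aware callers such as LoFreq. No multiple-testing
correction is applied at the calling stage; the replicate-concordance filter
downstream is the de facto error control, which mirrors how such pipelines
are run in practice. A Benjamini–Hochberg option exists in the enrichment
stage only.

On the minus strand a C-to-U edit is read as G-to-A; in strand-aware mode the
caller also tests reference-G/alternative-A sites, and `orient_strand()`
relabels minus-strand G>A calls as canonical C>U, flags
orientation-inconsistent calls as dropped with a reason, and routes
unknown-strand calls to an "unoriented" bucket rather than discarding them
silently.

**Numerical notes.** The tail is computed with `pbinom(k - 1, D, e/3,
lower.tail = FALSE)`; the test suite verifies agreement with direct summation
of binomial point masses to $10^{-12}$ for depths up to 200, monotonicity of
$p$ in the alternative count, and calibration (called fraction $\le \alpha$)
on error-only pileups of ~10^4 C sites.

## Replicate concordance and tiering

Calls are first intersected: a site must be called at the same (reference,
position, edit) in *every replicate of every condition*. Two concordance
rules then select depletion-sensitive sites, because small curated site sets
and transcriptome-wide sets warrant different stringency:

* `all_replicates_decrease` — every knockdown replicate's frequency lies
  below the control mean (per-replicate rule; appropriate for a handful of
  sites examined closely, e.g. on the pre-rRNA);
* `mean_decrease` — each knockdown condition's mean lies below the control
  mean (the transcriptome-wide rule).

Retained sites are scored by percent difference
$100\,(\bar f_{ctl} - \bar f_{kd}) / \bar f_{ctl}$, where $\bar f_{kd}$ is
the unweighted mean of the knockdown condition means, so conditions with
equal replicate counts contribute equally. Tier labels use strict
inequalities (>33%, >66%), so a site at exactly 66% is `gt33` but not
`gt66`, and the tiers nest by construction. Region labels resolve overlap by
the fixed precedence UTR > coding exon > non-coding exon > intron >
intergenic, which makes annotation deterministic when feature intervals
touch.

## Motif density and context

UC dinucleotide density is profiled in consecutive non-overlapping windows of
$L = 100$ nt. The random baseline uses the *window-length convention*
$E = L \cdot P(U)P(C)$, i.e. 6.25 per 100 nt for equiprobable bases. The
alternative start-position convention $(L - 1)\,P(U)P(C)$ differs by an edge
term of one part in a hundred; the window-length form is the convention used
for the published 6.25 baseline and is applied uniformly. Motif occurrences
are assigned to the window containing their *start* index, which makes window
counts sum exactly to the whole-sequence count; the final partial window is
reported with its true length and a pro-rated expectation (a choice — the
handling of partial windows is not standardised).

Edit-site contexts (±10 nt, padded with `-` at sequence ends) are summarised
as a position frequency matrix whose centre column is all C; gap characters
are counted in their own row so column sums stay constant. Enrichment of a
preceding base uses an exact binomial test with the two-sided p-value formed
by *doubling the smaller tail* (capped at 1). This convention is simple and
closed-form — e.g. 10 of 10 sites preceded by U at $p_0 = 0.25$ gives
$p = 2 \times 0.25^{10}$ — and is documented in preference to the
minimum-likelihood two-sided rule, which has no closed form.

## Gene-set enrichment

Enrichment of site-bearing transcripts is a two-sided Fisher exact test on
the 2×2 table (hit / not) × (set member / not), with fold enrichment
$(k/n)/(K/N)$ and the baseline percentage $100\,K/N$ (reported to one
decimal: 3,490 nucleolar proteins of 19,670 → 17.7%; 343 TP53 targets of
43,768 genes → 0.8%). Over-representation reporting applies the common
STRING-style rule: fold > 2 (strict) and p < 0.05, with all results retained
and only a `reported` flag toggled. The universe defaults to the genes
annotated in the run and is configurable, because published baselines mix
universes (proteome vs all approved genes) and both must be expressible.
Transcript→gene→protein mapping is 1:1 in synthetic data; isoform collapsing
is out of scope.

## Screen statistics

**Percent effect.** A treatment's one-nucleolus fraction is rescaled so the
negative control is 0% and the positive control 100%. Effects are computed
per replicate and then averaged, matching the mean ± SD error structure such
screens report; pooling cells before normalising is a different estimator
and is not the default.

**Hit calling.** Within each replicate the SD of the negative-control
well-level effects defines a cutoff $3\,\mathrm{SD}_r$; per-replicate pass
flags are reported, and the overall hit flag compares the treatment's mean
effect to the mean of the per-replicate cutoffs with an inclusive $\ge$.
Whether the original assays used well-level or replicate-level SD is not
stated in the sources this design follows; well-level SD within replicate
was chosen as the more conservative, plate-aware option. A plate whose
negative wells are identical (SD = 0) makes any non-negative effect a hit —
a documented degenerate edge rather than an error.

**Percent inhibition.** Median nucleolar 5-EU signal rescaled between the
negative (0%) and transcription-blocked positive (100%) controls. The class
boundaries are >80% (transcription), 50–80% inclusive
(processing/maturation), <50% (not required).

**Cell-cycle binning.** Control intensities are log2-transformed and the G1
and G2 peaks are located as local maxima of a Gaussian-kernel density
(bandwidth 0.05 on the log2 scale, configurable) with the G2 candidate
constrained to G1 + 1 ± 0.3; among valid pairs the one with the greatest
summed density wins. An affine map sends the peaks to 1.0 and 2.0 and is
applied to all samples. Bins are half-open and left-closed — sub-G1 < 0.75,
G1 [0.75, 1.25), S [1.25, 1.75), G2/M [1.75, 2.5], >4n > 2.5 — so every cell
lands in exactly one phase and fractions sum to 1. Where published interval
lists overlap at their boundaries (and one source prints 1.26 where another
prints 1.25), the procedural Methods values with left-closed convention are
used.

**RAMP.** Given a declared pathway of precursor→product edges (e.g.
47S → 45S → 32S → 12S), each edge's statistic is
$\log_2\!\big[(d_t/u_t)\,/\,(d_c/u_c)\big]$ for downstream $d$ and upstream
$u$ in treatment $t$ versus control $c$. A processing block shows as a
positive value on the edge into the accumulating species and a negative
value on the edge leaving it; swapping treatment and control negates every
edge. Zero intensities are an error naming the species, not a silent
`-Inf`.

## The synthetic-data generator

The generator produces data with exactly the statistical structure the
pipeline assumes, which makes recovery tests sharp but also bounds what they
demonstrate:

* **References** are i.i.d. draws from a configurable base composition —
  no secondary structure, no coverage heterogeneity along the transcript.
* **Planted sites** sit on C positions (optionally UC contexts) spaced ≥ 2 nt
  apart so motif contexts don't overlap; control frequencies default to the
  0.3–25% range reported for deaminase editing, and knockdown frequencies are
  deterministic fractions of control (`f_kd = f_ctl (1 − r)`).
* **Pileups** draw a multinomial base vector per site at fixed depth; at a
  planted site the expected alt fraction is $f + e/3$. There is no read-level
  structure: no quality scores, no PCR duplicates, no alignment artefacts,
  no strand bias. A caller that passes the recovery tests here may still need
  those filters on real data.
* **Seed hierarchy**: every (condition, replicate) stream derives its own
  sub-seed from the master seed, so libraries are independent yet the whole
  dataset is bit-reproducible.
* **Screen wells** draw per-cell nucleolus counts from a two-component model
  (1 vs 2–3 nucleoli) at the well's true one-nucleolus fraction; control
  defaults (19.2% negative, 29.2% positive, 16 wells each) follow the
  published control behaviour of such screens.
* **DNA intensities** place G1 at $2^{x_0}$, G2/M at $2^{x_0+1}$, sub-G1 and
  >4n outside them, with log-normal noise of coefficient of variation `cv`
  (default 0.05). S-phase cells are drawn uniformly over the *interior* of
  the S bin (normalized log2 1.3–1.7) rather than uniformly between the G1
  and G2 peaks: a literal uniform spread between the peaks places ~25% of
  S-phase cells into each neighbouring bin and makes phase fractions
  unrecoverable by binning, defeating the round-trip the generator exists to
  support. Real S-phase populations do span the full inter-peak range; the
  narrowed draw is a deliberate idealisation.

## Problem sizes used in the tests

The shipped suite runs the caller-vs-enumeration check at depths up to 200,
null calibration on ~10⁴ C sites at depth 100, planted-site recovery on a
3,000-nt reference with 20 sites at depth 1,000 (duplicate replicates, two
knockdown conditions), the filter/tier brute-force comparison on 200 random
frequency matrices, Fisher-vs-enumeration on random tables with N ≤ 60, and
the cell-cycle round-trip at 10⁴ cells. These sizes were chosen so every
distributional claim is tested with at least ~3-SD headroom while the whole
suite stays comfortably interactive.

## Known limitations

* The caller ignores base qualities and strand bias; it is a clean binomial
  model, not a drop-in replacement for quality-aware callers on real BAMs.
* Percent-difference is undefined at zero control frequency (such sites are
  errors, not silent zeros).
* Published aggregate percent effects computed from pooled summaries are not
  generally recoverable from the per-replicate formula; both computation
  orders exist in the field and only the per-replicate one is implemented as
  a default.
* Amino-acid consequence annotation (missense/nonsense) and secondary
  structure mapping are out of scope; region labels stop at the
  UTR/exon/intron level.
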