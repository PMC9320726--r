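---
title: "Methods: differential RNA-seq TSS mapping with tssmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential RNA-seq TSS mapping with tssmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tssmapr)
```

## The measurement and the model

dRNA-seq maps bacterial transcription start sites by sequencing 5′ ends of
transcripts in two banks prepared from the same RNA. Primary transcripts
carry 5′-triphosphates; in the "+" bank a polyphosphatase converts these to
ligatable monophosphates, so primary 5′ ends enter the library, while the
untreated "−" bank captures mostly residual processed (5′-monophosphate)
ends. A true TSS therefore shows a read-count excess in "+"; a processing
or cleavage site shows similar counts in both banks.

`tssmapr` tests each genomic position with the Skellam model: counts
`k⁺ ~ Poisson(λ⁺)` and `k⁻ ~ Poisson(λ⁻)` are independent, so their
difference follows a Skellam distribution, and the one-sided p-value for
an observed excess `d = k⁺ − k⁻` is `P(Skellam(λ⁺, λ⁻) ≥ d)`. The test is
one-sided by design — the library chemistry enriches primary ends only in
"+" — and uses raw p-values at `α = 0.01` with no multiple-testing
correction, which is the operating point of the caller this package
reimplements. Counts are never normalised for library size: depth
differences are absorbed into the separate `λ⁺` and `λ⁻`, which keeps the
counts integer as the Skellam model requires.

Rates are estimated per replicon and strand as the mean count over the
union of positions with at least one read in either bank (`global_nonzero`
policy). Excluding all-zero positions handles the zero inflation of
untranscribed regions: the Poisson rate is meant to describe transcribed
background, not the genomic majority of empty positions. A `windowed`
policy computes the same statistic within tiling windows (default 10 kb)
for genomes with strong regional expression gradients; `global_nonzero`
remains the default because the window estimator is noisier on sparse
5′-end profiles and neither variant changes the behaviour at the strong
sites that dominate TSS maps.

## Calling parameters

| parameter | default | meaning |
|---|---|---|
| `noise` | 10 reads | minimum `k⁺` at a candidate position |
| `merge` | 1 nt | adjacent significant positions fused into one TSS |
| `alpha` | 0.01 | raw one-sided p-value threshold |
| `cluster_window` | 10 nt | nearby-call resolution window in curation |
| `similar_fold` | 2 | max `k⁺` ratio for "similar read numbers" |
| `trna_upstream_window` | 250 nt | tRNA-associated call removal |
| `primary_window` | 250 nt | upstream window for primary (P) TSSs |
| `antisense_margin` | 30 nt | margin for downstream-antisense (Ad) |
| `leaderless_max` | 9 nt | maximum 5′UTR of a leaderless mRNA |

Merging retains the position with the largest count difference; ties
resolve to the 5′-most position (smallest coordinate on "+", largest on
"−"), a deterministic and biologically conservative rule. Replicates are
combined as a union with support bookkeeping (`any`), because the analysis
this package models reports one TSS set per condition and uses the other
condition as confirmation rather than as a filter; a stricter `both` mode
is available. In cross-condition curation, clusters of same-strand calls
within 10 nt whose `k⁺` are within 2-fold are resolved to one call,
preferring the member nearest to a call in the other condition, then the
highest `k⁺`, then the 5′-most. The 2-fold quantification of "similar read
numbers" separates sequencing jitter from genuine alternative TSSs at
typical depths; the rule is applied repeatedly until the call set is a
fixed point, which makes the operation idempotent. The tRNA filter uses
the same 250-nt upstream association rule as primary classification.

## Positional classification

A TSS is primary (`P`) when a same-strand gene start lies 0–250 nt
downstream; offset 0 is the gene start itself, i.e. a leaderless
transcript, which keeps leaderless mRNAs inside the primary class. It is
internal (`I`) inside a same-strand gene, internal-antisense (`Ai`) inside
an opposite-strand gene, and downstream-antisense (`Ad`) within 30 nt
beyond either end of an opposite-strand gene (the margin is applied on
both sides; the distinguishing feature of `Ad` is non-internal antisense
proximity). Labels accumulate — a TSS inside gene A and ≤ 250 nt upstream
of gene B is `{I, P}` — and `O` (orphan) is exclusive. When several gene
starts qualify, the nearest is linked, the standard dRNA-seq convention.
Summaries report both the multi-label tallies and an exclusive count under
the precedence `P > I > Ai > Ad > O`, since published class breakdowns are
usually exclusive.

The 5′UTR of a primary TSS is the distance to the start codon:
`gene_start − position` on "+", `position − gene_end` on "−"; length 0
flags a leaderless transcript.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, at
the scale of the motivating organism:

* **Genome**: i.i.d. sequence with P(G) = P(C) = GC/2 at GC = 0.68;
  non-overlapping genes with geometric lengths (mean 887 nt) alternating
  with geometric intergenic gaps (mean 183 nt) to a target gene density of
  0.833; ~2% of features are tRNAs (70–90 nt).
* **TSS landscape**: default class mix P 0.33, I 0.19, A 0.31 (split 80/20
  into Ai/Ad), O 0.17. Planted positions are verified with the package's
  own classifier so each record's exclusive class equals its planted
  class, and no two truth records lie within 25 nt on the same strand —
  twice the curation window — so merge/curation behaviour on truth sites
  is unambiguous.
* **5′UTRs**: a leaderless fraction (default 0.07) is planted at UTR 0;
  the rest draw from a discretized gamma truncated to [10, 250] whose
  shape and scale are solved numerically so that the mixture reproduces
  both summary statistics the distribution is designed around: mean 84 nt
  and median ≈ 64 nt. Each record's UTR is drawn once and only the
  placement is re-sampled on collision, so placement rejection cannot
  distort the length distribution.
* **Libraries**: at a truth TSS, `k⁺ ~ Poisson(depth × enrichment)` and
  `k⁻ ~ Poisson(depth)` (defaults 50 and 10×); at planted processed sites
  both banks share one rate (default `depth`); every transcribed position
  (gene bodies plus planted 5′UTRs, on the feature strand) receives
  background `Poisson(0.02)` noise in both banks. The background default
  follows 5′-end library arithmetic: an enriched bank of well under a
  million aligned reads spread over a multi-megabase, two-strand genome
  averages a few hundredths of a read per position *including* its signal
  peaks, so off-peak background must sit well below that. Confining
  background to transcribed regions reproduces the zero inflation that
  rate estimation must handle.
* **Determinism**: one seed drives everything; identical configurations
  give byte-identical outputs.

What the generator does **not** model: read-level artefacts (no FASTQ, no
poly(A) carry-over or alignment errors), condition-dependent expression
(a condition-specificity parameter exists but defaults to fully shared
TSSs, since the modelled study gives no condition-specific fractions), and
correlated biological replicate structure. Passing recovery tests
therefore demonstrate that the inference chain is correct under its own
statistical assumptions, not that those assumptions capture every artefact
of real libraries.

## Promoter motif discovery

For primary (and internal-primary) TSSs on the largest replicon, two
20-nt window sets are cut per TSS, strand-aware: offsets −20…−1 for the
−10 region and −35…−16 for the −35 region (the latter reading "20-nt
window ending 15 nt upstream of the TSS", which centres the window where
the −35 box sits given the canonical ~17-nt spacer); the negative set is
the window at +100…+119, transcribed sequence that shares composition but
not promoter signal. A single-motif OOPS EM fits a PWM: each sequence is
assumed to contain exactly one occurrence, the background is the negative
set's base composition, the M-step uses a pseudocount of 0.25 per cell,
and iteration stops at ΔLL < 1e−6 or 200 iterations. Initialization is
discriminative — the exact k-mers most enriched in the positive set
relative to the negative set (ties towards the word least likely under
the background) seed up to five EM runs, and the best final likelihood
wins — which makes the fit deterministic. The recorded likelihood trace
is the penalized (MAP) objective including the Dirichlet pseudocount
term; that quantity is guaranteed non-decreasing, whereas the raw
observed-data likelihood need not be under a MAP M-step. Differential
enrichment is scored as the mean best-window log-odds in the positive
minus the negative set with a label-permutation p-value. This is a
compact, testable stand-in for a full motif suite: no multi-motif search,
no ZOOPS/ANR models, no E-value calibration; both window sets are
exportable as FASTA so a full finder can be run externally.

## Numerical choices

* The Skellam pmf is evaluated in log space via the exponentially scaled
  Bessel function `I_ν(x)·e^−x`, stable to rates ≥ 1e4; underflow far in
  the tails is truncated to zero (these terms are < 1e−300). The survival
  function accumulates pmf over an integer grid extended 40 standard
  deviations past the mean — truncation error far below the 1e−9
  tolerance the implementation is tested to against an independent
  double-Poisson convolution oracle. Degenerate rates reduce exactly to
  Poisson tails and point masses.
* `λ = 0` on both sides is reported as a flagged zero-rate estimate, not
  an error, so empty tracks pass through cleanly.
* Classification is implemented with interval overlap machinery and is
  tested for exact agreement against an independent brute-force scan that
  applies the interval rules literally, plus strand-mirror invariance
  (reverse-complementing the genome and flipping all coordinates must not
  change any label).

## Problem sizes in the test-suite

The suite exercises the study's stated operating point at desk scale:
planted-TSS recovery on a 100-kb genome with 200 TSSs at depth 50 and
enrichment 10; type-I error on 1e5 null positions; classification oracle
agreement on 1000 random instances; parameter recovery with 1000 planted
TSSs (class mix) and 2000 primary TSSs (UTR statistics); motif recovery
from 200 corrupted 20-mers with 1000 permutations. These sizes give the
binomial test margins stated with each check while keeping the whole
suite fast.

## Known limitations

* A cleavage site that is as strong in the "+" bank as a true TSS is
  statistically indistinguishable from one by the position-wise Skellam
  test alone: with equal rates `r` in both banks the count difference
  fluctuates with standard deviation `√(2r)`, and for large `r` a
  fraction of such sites exceeds the calling threshold set by the global
  rates. In the modelled study this false-positive class was removed by
  *manual* curation; `tssmapr` deliberately ships no fixed removal list
  and no heuristic beyond the documented rules, so strong balanced sites
  can survive into the final table. The synthetic truth table records
  processed sites precisely so users can quantify this on their own
  parameter choices.
* The attained size of the discrete Skellam test sits below the nominal
  `α` (at moderate rates, around 0.007 at `α = 0.01`); the test is
  conservative, never anti-conservative.
* Published-reference comparison relies on a small hand-curated table;
  two of its numeric cells are ambiguous in the source and are marked in
  the table's comment column.
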