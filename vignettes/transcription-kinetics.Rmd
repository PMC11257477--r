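---
title: "Modelling RNAPII transcription kinetics from region-level occupancy"
author: "polkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling RNAPII transcription kinetics from region-level occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polkin)
```

## The model and its assumptions

`polkin` models the transcription cycle of a single yeast gene as a
continuous-time Markov jump process on a discretized gene. Every step is a
Poisson process; the gene is a row of equal 120 bp compartments (UAS for
STM-class genes, promoter, ten transcript bins, terminator), and no
compartment ever holds more than one polymerase. A transition whose
destination compartment is occupied is *disabled* — propensity zero — not
attempted and rejected. This is the standard convention for exclusion
processes (TASEP) and keeps every enabled transition exponential, which is
what makes the Gillespie simulation exact.

The promoter is a two-substate machine. Arrival (by transfer from the UAS,
`k2`, or direct recruitment, `k3`) puts the polymerase in an
"awaiting-TFIIH" substate, from which it can dissociate (`k_minus3`) or,
for STM genes with a free UAS, step back to the UAS (`k_minus2`). TFIIH
arrival (`k4`) completes the PIC; from there the only exit is initiation
(`k5`), waiting if the first transcript bin is occupied. We forbid
dissociation and reversal after TFIIH arrival because the downstream steps
(`k4`–`k7`) are irreversible in the model; whether the original
implementation allowed late dissociation is not documented, and we chose
the reading consistent with the stated irreversibility. Initiation blocked
by an occupied first bin *waits* rather than aborting — the alternative
would silently turn exclusion into extra promoter dissociation.

Elongation is stored as a speed (bp/min) and converted once to a per-bin
hop rate, `(speed/60)/bin_length`; at the default 1000 bp/min and 120 bp
bins a polymerase spends 7.2 s per bin on average. Each gene starts empty
at `t = 0`; the 1000 s simulated per gene is burn-in enough that the final
60 s recording window (chosen to match the timescale of the cleavage
reaction in the source assay) samples steady state — the exact stationary
solver below confirms this to within Monte-Carlo error.

## Parameters

| rate | meaning | default | origin |
|------|---------|---------|--------|
| `k1` | UAS association (STM) | 0.002/s | published single-molecule range 0.0019–0.0027/s |
| `k_minus1` | UAS dissociation | 0.003/s | published range 0.001–0.005/s |
| `k2` | UAS→promoter transfer | free | fitted range 0.03–0.2/s |
| `k_minus2` | promoter→UAS reversal | free | fitted range 0–0.15/s |
| `k3` | direct promoter recruitment (TFO) | 0.002/s | no independent estimate; set equal to `k1` |
| `k_minus3` | promoter dissociation | free | fitted range 0–0.03/s |
| `k4` | TFIIH recruitment | free | fitted range 0.0075–0.09/s |
| `k5` | initiation | 0.1/s | TFIIH residency time |
| `k6` | elongation | 1000 bp/min | live-imaging estimates, 1–3 kb/min |
| `k7` | terminator release | 0.037/s | terminator pause 56 ± 20 s / 70 ± 41 s |

Where a *point* default is needed for a free rate (e.g. as the baseline of
a perturbation), `default_rates()` uses the midpoint of its fitted
functional range — geometric for ranges bounded away from zero, arithmetic
for ranges that start at 0. A separate `"gcn4"` context carries the
re-fitted constants of the amino-acid-starvation experiments (`k7` =
0.0614/s and narrower `k_minus2`/wider `k4` ranges). One source-internal
inconsistency is worth recording: the narrative quotes a terminator rate of
0.0325/s while the parameter table prints 0.037/s; we follow the table.

## Ensemble fitting

`fit_transcription()` evaluates every grid point of the free rates with
the same master seed (common random numbers), so neighbouring models
differ by parameters rather than by simulation noise, and scores each
model's 3/4-region vector against the data by cosine similarity. All
models above the 0.995 threshold form the ensemble; per-rate functional
ranges are their elementwise min–max. When nothing passes the threshold —
as happens for crosslinking-style, transcript-dominated shapes — the best
`fallback_n` models are reported instead, flagged `selection_mode =
"best_n"`.

Grid spacing and resolution are not documented in the source work, so they
are package choices: log-uniform for strictly positive ranges, linear
including 0 for `k_minus2` and `k_minus3` (whose ranges start at 0.0), 12
points per dimension by default (6 for desk-scale runs). Because the
published ensemble counts (789 STM / 371 TFO models) depend on that
undocumented resolution and on sequencing-derived input vectors, the
package does not attempt to reproduce them.

Cosine similarity is invariant to positive rescaling of either argument,
so the L2 scaling step (`l2_scale()`, which gives the model vector the
Euclidean norm of the data to mimic the conversion into CPM-like units)
affects only reporting and plotting. We apply it to the aggregated region
vector, not the 13-compartment vector; the transcript region value is the
arithmetic mean of the ten equal-length bins, which equals per-bp
occupancy.

## The exact oracle

The full exclusion gene is a finite CTMC (promoter substates × occupancy
pattern: 12,288 states for the default STM architecture), so its
stationary distribution can be solved exactly as a sparse linear system.
`analytic_steady_state()` grounds the empty state rather than appending a
dense normalisation row (which would destroy sparsity in the LU factors)
and falls back to uniformised power iteration from the empty state when
the chain is reducible — e.g. `k7 = 0` with inflow, where the gene jams
and the function flags the result as absorbing. Every Monte-Carlo result
in the test suite is checked against this oracle; the oracle itself is
validated against closed forms (the two-state promoter toy gives occupancy
`k3/(k3 + k_minus3)` exactly).

## Perturbation analysis

`ensemble_delta()` simulates each ensemble member at baseline and under a
perturbed rate set with *paired seeds* — the same per-gene random
substreams — so the identity perturbation yields exactly zero change and
Monte-Carlo noise largely cancels in the difference. Both vectors are
converted to the empirical scale with the single factor
`||E||/||M_baseline||` fixed by the member's baseline; rescaling the
perturbed vector independently would normalise away amplitude changes
(e.g. a recruitment knock-down that lowers all occupancies
proportionally would map to zero change), contradicting the directional
behaviour the model is meant to capture.

The source work judged perturbation fits visually; to *rank* candidate
mechanisms we needed a number, and we use cosine similarity on the signed
change vectors (`score_delta()`), an extension of the fitting metric.
Candidates whose kinetic effects are near-degenerate — increasing a
dissociation rate versus decreasing the corresponding recruitment rate
produces almost the same occupancy change — cannot be separated by any
shape metric; the published analysis likewise lists such pairs as
alternative explanations rather than choosing between them. The published
perturbation parameter sets ship as `inst/extdata/perturbations.tsv`; cells
published as re-fitted ranges are collapsed to midpoints when a runnable
point value is required.

## Minimal dwell-time model

`minimal_occupancy_analytic()` is the back-of-envelope predictor: one
polymerase cycling promoter → transcript → terminator with mean dwells
`T_p`, `L/(v/60)`, `T_t`. By renewal-reward, long-run compartment
occupancies are dwell fractions of the cycle, summing to one; the
stochastic twin converges to them and the promoter exceeds the per-bin
transcript occupancy exactly when `T_p · v/60 > bin_length`. The published
"21 of 24 combinations" counts cannot be targeted because the exact grid
was not stated; the default grid here ({5, 10, 15, 20} s × {1000, 2000,
3000} bp/min × {5, 70} s, spanning the stated ranges) reports its own
counts, currently 22 and 20.

## Genomic binning conventions

Internal coordinates are 0-based half-open; BED is read/written as such
and bedGraph through `rtracklayer`. The analysis regions are offsets in
transcription direction — UAS −500…−151 and promoter −150…+25 relative to
the TSS, transcript +26 (TSS) … −76 (TES), terminator −75…+150 relative to
the TES — treated as inclusive positions with the anchor at offset 0, so
an offset pair `(lo, hi)` becomes the half-open interval
`[anchor + lo, anchor + hi + 1)` on the plus strand and its mirror image
on the minus strand. A worked example: TSS = 1000, TES = 3000 (plus
strand) gives UAS [500, 850), promoter [850, 1026), transcript
[1026, 2925), terminator [2925, 3151) — widths 350/176/226 bp always.
Whether the original offsets were 0- or 1-based is not decidable from the
text; this convention is fixed and documented, and a one-base shift does
not affect model fitting. Metasite smoothing emits only windows fully
inside the flank (no partial edge windows): ±250 bp with window 10/step 5
gives 99 points. Metagene profiles fix the order of operations —
replicate-average per bp, bin each segment to 100 bins per gene, then
average across genes — which makes profiles invariant to gene length.

## What the synthetic generator does and does not emulate

`synth_empirical_occupancy()` produces region vectors from known rates
with multiplicative lognormal noise (σ = 0.1 by default; positive,
scale-proportional dispersion, the qualitative behaviour of
CPM-normalised region means) and rescales to an L2 norm of 100 so numbers
resemble plotted CPM-like ranges — both package conventions, not source
values. `synth_coverage()` places reads multinomially across gene regions
in proportion to weight × length, uniformly within a region. Neither
emulates nucleosome structure, background-nuclease sequence bias,
fragment-length effects or replicate structure; a green closed-loop test
therefore establishes that the *inference machinery* recovers generating
parameters under honest noise, not that the model fits any particular
sequencing dataset. The published fitted quantities that depend on the
deposited sequencing data (functional-range endpoints, ensemble counts,
per-experiment change magnitudes) are for that reason not test targets.

## Numerical choices and limitations

* Per-gene random substreams are derived deterministically from the master
  seed and gene index (splitmix64), so ensemble results are independent of
  execution order and reproducible bit-for-bit.
* Standard errors of occupancies are across genes; within-trace
  autocorrelation is not corrected for, which is fine for means but would
  understate the error of within-gene time averages.
* `best_n` ties are broken lexicographically by free-rate values in the
  order `k2, k_minus2, k_minus3, k4` (then `k3`), ascending, making
  selection deterministic.
* The exact solver is limited to architectures with ≲ 2^12 transcript-bin
  patterns (it refuses > 5 × 10^5 states); the default gene is well within
  range.
* Blocking in the stochastic engine is rare at realistic recruitment rates
  (occupancies ~0.01–0.05), so the exclusion rule matters mostly under
  strong perturbations (e.g. `k7 → 0`), where the analytic fallback and
  the absorbing flag document the behaviour.
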