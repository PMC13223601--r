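---
title: "Identifying coexisting peptide isoforms: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying coexisting peptide isoforms: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hommtm)
```

## The problem

Bottom-up phosphoproteomics search engines report one peptide isoform per
spectrum. When a peptide carries several candidate modification sites, two
isoforms differing only in site placement can co-elute and co-fragment, so a
single MS/MS spectrum — a *HomMTM* (homogeneous multiplexed tandem mass)
spectrum — contains fragment peaks of both. `hommtm` identifies up to two
coexisting isoforms from one peptide-spectrum match and estimates their
relative abundances from peak intensities.

## Mass graphs

Everything happens on integer masses: a mass in Da is multiplied by `scale`
(ticks per Da, default 100, i.e. 0.01 Da ticks) and rounded half-up. The
package's documentation examples use `scale = 1` so that the graphs carry
small, readable integers.

The **peptide isoform mass graph** (PMG) of an `n`-residue peptide has nodes
`x_0..x_n`; each residue contributes a black edge with its monoisotopic
residue mass, and every applicable variable modification adds a red edge with
the modified residue mass. A source-to-sink path is one isoform. One numerical
choice matters here: the modification delta is rounded to ticks once and added
to the rounded residue mass (rather than rounding residue + delta per
residue). This guarantees that all placements of the same modification
multiset have exactly the same integer total mass, so two coexisting isoforms
always share one corrected precursor mass; with per-residue rounding, one-tick
discrepancies between placements would make a true isoform pair end at two
different terminal corrections and be rejected as a pair.

The **spectrum mass graph** (SMG) is the peak list in neutral prefix-mass
space, with a virtual origin peak at mass 0 (intensity 0) and a terminal peak
at `M_prec - mass(H2O)`. If no observed peak lies within the tolerance of the
terminal mass, a virtual terminal with intensity 0 is created, because every
alignment is required to span the whole spectrum from origin to terminal. An
observed peak within tolerance is snapped onto the terminal node; the
sub-tolerance mass residual is absorbed by the alignment's per-peak
correction. Observed m/z peaks are converted with both their b-ion and their
y-ion interpretation (fragment charge 1 by default); peaks that collide on the
same tick are merged keeping the maximum intensity. Only b/y ions are
considered: a/c/z ions are rare under CID/HCD for the target data and every
extra interpretation doubles the peak list.

## Peak-error-correction alignment

An alignment matches PMG nodes to peaks as triples `(x_i, y_j, k)`, where the
integer correction `k` (|k| ≤ δ, default δ = 0.1 Da in ticks) shifts the
observed peak onto its theoretical position: consecutive corrected masses must
differ by an exact PMG path mass. Correcting each peak independently prevents
the error accumulation that a per-step tolerance would allow. We use the
convention that `k` is additive (corrected mass = observed + `k`); the sign
follows the worked six-peak example, where the peak at 418 receives `k = -1`
to sit at the theoretical 417.

The predecessor sets `E(i, j, k)` are grown backwards from the terminal set
(all `k` with `m_m + k` equal to a realizable isoform mass — optionally
restricted to the modification counts reported by the upstream search) and
assembled into the **backtracking graph** `B`, whose terminal-to-origin paths
are exactly the candidate isoform-spectrum matches.

Steps that skip PMG nodes model missing peaks (red edges). A skip is admitted
only when some concrete path realizing the step mass has *all* intermediate
theoretical positions unmatched in the spectrum: a "missing" peak that is in
fact present is no justification for a skip. Without this admissibility rule
the E-sets acquire skip entries that bypass observed peaks, and the graph
no longer matches the worked examples (nor the intuition that red edges stand
for genuinely absent fragments). Skips are capped at `max_missing = 2`
consecutive nodes per step; the cap bounds the otherwise combinatorial growth
of skip edges on sparse spectra, and two consecutive absent fragments is
already a weakly supported region.

## Choosing the isoform pair

Given theoretical (flat) peak intensities `q1`, `q2` for the two isoforms,
each peak used by exactly one path contributes `|I - q_c|`, a peak shared by
both paths — same peak, same correction — contributes `|I - q1 - q2|` once,
and each missing peak contributes its full theoretical intensity (a peak of
intensity 0 at the theoretical position). A pair in which the same peak would
be used with two different corrections is invalid: a peak has one correct
position. A dynamic program over *pairs* of frontier nodes in `B` minimizes
the total error: when both frontiers sit on the same peak they advance
together (this is what makes the shared-peak error countable exactly once);
otherwise only the earlier-peak side advances. Pairs are scheduled by a
frontier expansion from the origin pair with deduplication, and the table is
evaluated terminal-ward first, ordered by decreasing sum of peak indices — a
topological order of the pair dependencies (plain reverse insertion order is
not guaranteed topological when path depths are uneven). Missing-peak
penalties on a step shared by both paths are charged per path, i.e. twice —
consistent with treating the missing peak as a shared peak of intensity 0.
A schedule cap (2 × 10⁶ pairs) aborts with a diagnostic rather than
truncating silently, and grid evaluation is chunked so the table stays within
a bounded memory footprint.

`q1` and `q2` are unknown; they are searched on the grid `I_max × x%`,
`x = 1..100`, with `I_max` the largest intensity among peaks used by `B`.
Because swapping `(P1, q1)` and `(P2, q2)` leaves the objective unchanged,
the grid is restricted to `q1 ≤ q2`. An explicit `q_values` override exists
because worked examples (e.g. the optimum at `(70, 30)` with `I_max = 110`)
need not lie on the percent grid. Ties are broken by (i) more matched peaks,
(ii) lexicographically smallest modification positions, (iii) smaller
`|q1 - q2|` — in that order, chosen to prefer better-supported and more
N-terminal assignments, then the more balanced split. Two isoforms are
reported exactly when the optimal pair's placements differ; no significance
margin is applied on top (the error minimum already arbitrates), though the
grid can be overridden to probe sensitivity.

An alignment fixes the step masses but not always the edges realizing them;
when several placements realize the same masses, the lexicographically
smallest positions consistent with the reported modification counts are
reported.

## The simulator

`simulate_spectrum()` emulates a HomMTM spectrum from a ground-truth isoform
pair. Theoretical prefix-mass lists of both isoforms are generated; each mass
is dropped independently with the missing-peak probability; a mass surviving
in both lists yields one shared peak of intensity `(q1' + q2')(1 + e)`, an
exclusive mass yields `q_c'(1 + e)`, with a fresh relative error
`e ~ N(μ, σ²)` per peak. The intensities `q1'`, `q2'` preserve the total of a
seed pair while following the desired abundance ratio. Noise peaks have
Gaussian masses centred at `M_prec / 2` with s.d. `M_prec / 4`, truncated by
rejection to the valid mass range, and Gaussian intensities truncated at 0.

Defaults are stated once and used throughout: missing-peak probability 0.05,
relative-error law `N(0, 0.1²)`, 10 noise peaks per spectrum with mean
intensity `0.2 (q1' + q2')` and s.d. half the mean. The corresponding
quantities in the original study are estimated from thousands of real
spectra; these defaults are documented surrogates of realistic magnitude, not
estimates. Simulated sound peaks carry *no mass error* (only intensity error
and dropout), so passing recovery tests demonstrates correctness of the
identification logic under intensity corruption, dropout, and background
noise — not robustness to fragment-mass miscalibration, isotope envelopes,
co-isolated foreign peptides, or intensity structure (real fragment
intensities are far from flat). Benchmarks on this simulator are therefore
upper bounds on real-data behaviour.

`run_benchmark()` mirrors the accuracy-versus-abundance-ratio design at desk
scale: the test suite uses hundreds of spectra per condition (e.g. 200 at
50:50, 100 per ratio when contrasting a 2:98 split against 47:53) with random
8–11-residue peptides carrying one phosphorylation on two candidate sites.
These sizes keep the full suite within minutes on one CPU while leaving the
Monte-Carlo error of the reported fractions a few percent.

## Degenerate inputs and edge cases

* Empty peak list: the SMG still has its two virtual endpoints; no alignment
  can match a modified peptide unless the precursor matches, and the result
  status is `"no_isoform"`.
* No realizable isoform mass within δ of the terminal: empty backtracking
  graph, status `"no_isoform"` (never an error).
* Duplicate scaled masses merge to the maximum intensity; the merge happens
  after b/y expansion, so complementary interpretations landing on one tick
  behave as one peak.
* δ = 0 forces all corrections to zero, and the correction table collapses to
  the classical exact-mass case.
* Single-residue peptides have no bonds; the peak-support rate is undefined
  and raises an error.

## Known limitations

* At most two coexisting isoforms; mixtures of three or more are out of
  scope.
* Fragment charge is fixed (default 1); no isotope-envelope deconvolution.
* The flat-intensity model (`q` per isoform) is the quantification model of
  the method, not a claim about fragment physics; abundances inherit its
  bias.
* FDR / false-localization-rate control is not provided; the tool consumes
  already-filtered PSMs.
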