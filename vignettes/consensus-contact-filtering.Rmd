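---
title: "Consensus filtering of predicted contacts by structural self-consistency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus filtering of predicted contacts by structural self-consistency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevfilter)
```

## The problem

Coevolution-based contact predictors rank residue pairs by coupling strength,
but the ranking gives no natural cutoff for how many pairs to trust, and even
conservative choices carry a substantial false-positive load — increasingly so
as the alignment gets shallow. `coevfilter` addresses both problems at once:
it fixes the number of input contacts at `floor(1.2 * N_AA)` long-range pairs
(pairs whose residues are not both inside one predicted secondary-structure
segment) and then removes the pairs that are *structurally self-inconsistent*,
i.e. that cannot be satisfied by any plausible backbone geometry compatible
with the rest of the contacts.

## The model

Each selected contact `i` becomes a distance restraint on the Cβ–Cβ distance
(Cα for glycine) with a sampled weight $\lambda_i \in [0, 1]$:

$$E_\mathrm{rest} = \sum_{i=1}^{N}
\begin{cases}
\lambda_i (d_i - d^0)^2 + D^2 (1 - \lambda_i^2), & d_i > d^0\\
0, & d_i \le d^0
\end{cases}$$

with $d^0 = 7$ Å the violation onset. Switching a restraint off
($\lambda_i = 0$) removes its distance penalty at cost $D^2$; it is favorable
exactly when $(d_i - d^0)^2 > D^2$. The total energy adds a purely repulsive
soft-core clash term over backbone (N, Cα, C) and Cβ atoms, harmonic below
$r_\mathrm{min} = 3$ Å. There is deliberately no attractive force field: the
point is to isolate what the contacts themselves imply about the geometry.

The structure is a torsion-space chain: residues inside predicted helices are
fixed at $(\phi, \psi) = (-60, -45)$, strands at $(-135, 135)$, and only the
remaining dihedrals move. During a simulated-annealing run the weights follow
a Brownian-motion-like update

$$\lambda_i(t + \Delta t) = \lambda_i(t) + \gamma F_i \Delta t +
\delta \sqrt{T \Delta t}\, \varphi_i^{norm},$$

clamped to $[0, 1]$, with $\gamma = 0.00025$, $\delta = 0.6666$, and
$F_i = -\partial E_{\mathrm{rest},i} / \partial \lambda_i$, i.e. gradient
descent on the switching energy plus thermal noise. $D$ is annealed from
150 Å (switching anything off is prohibitive, so every restraint initially
pulls) down to 3 Å (systematically violated restraints switch off cheaply).

Two properties of this update are worth stating explicitly because they shape
everything downstream:

* For a restraint that is currently satisfied ($d \le d^0$) the energy does
  not depend on $\lambda$ at all, so its weight performs a bounded random
  walk rather than drifting to 1. A single run therefore reads out a
  *random* weight for every satisfied contact; discrimination comes from the
  consensus over many runs, not from a single trajectory.
* For a violated restraint the noiseless update is bistable: the stationary
  weight $\lambda^* = (d - d^0)^2 / (2 D^2)$ is the unstable boundary between
  the basins of 0 and 1. Once $\lambda^* > 1$ (violation beyond $d^0 +
  \sqrt{2} D$, roughly) the weight can only fall.

## The protocol

One protocol run (1) anneals structure and weights jointly, (2) keeps the
contacts whose final weight is at least 0.5 (the midpoint of the enforced
range; the read-out rule is a design choice), (3) re-anneals with only those
contacts as fixed full-weight restraints, and (4) marks a contact *on* iff it
survived step 2 and its distance in the final structure does not violate
$d^0$ by more than the final $D$ (10 Å with defaults). The run is repeated
`n_repeats = 64` times with independent seeds, and the consensus keeps the
contacts that are on in strictly more than 30% of the runs. Satisfied
contacts land near an on-fraction of ~0.5 and are kept; systematically
violated contacts collapse toward 0 and are discarded. The filter can only
remove contacts, never add them.

## Calibration choices

The published description fixes $d^0$, the $D$ schedule endpoints, $\gamma$,
$\delta$, the repeat count and the consensus threshold; the sampling engine
itself is this package's own calibration:

* **Monte Carlo instead of torsion-angle dynamics.** Free dihedrals are
  sampled with Metropolis moves (uniform perturbations up to 30°); the
  contract — sample the unfixed dihedrals under the same energy — is
  preserved, the integrator is not.
* **Temperature schedule.** `T_start = 10`, `T_end = 1e-3`, geometric, shared
  between the Metropolis moves and the weight noise. The end point matters:
  the weight update behaves like Langevin dynamics at an effective
  temperature $\delta^2 T / (2\gamma) \approx 888\,T$, so the final $T$ must
  satisfy $888\,T \ll D_\mathrm{end}^2 = 9$ for the switching decision to
  freeze out; `T_end = 1e-3` puts the effective temperature near 0.9. A
  warmer end point leaves every weight an unread coin flip.
* **Schedule length.** 300 steps with `20 × (number of free dihedrals)` moves
  per step and one weight update per step, $\Delta t = 1$. The heavier test
  scenarios use 200–300 steps with a factor of 10, which the results below
  tolerate; these are problem sizes chosen for the synthetic fixtures, and
  all of them are exposed in `protocol_config()`.

## Synthetic fixtures and what they do (and do not) show

`make_toy_sheet()` builds an idealized flat antiparallel sheet (4.8 Å strand
spacing, 3.5 Å rise, Cβ proxies alternating across the sheet plane) with
Gly/Ser alternation, returning ground-truth coordinates, true contacts (all
long-range pairs at ≤ 9 Å) and a decoy pool (> 12 Å by default, avoiding the
borderline band just outside the contact cutoff). `make_prediction()` mixes
true contacts and decoys at an exact target precision. These fixtures have
no curved or bent secondary structure, no side chains beyond the Cβ proxy,
and no correlated errors of real predictors, so passing tests demonstrate
the *mechanism* — violated restraints switch off, consensus removes them —
not performance on real proteins.

The five-contact rejection fixture (`gsgs_fixture()`) emulates the topology
of the classic three-stranded-sheet experiment: four true contacts pinning
the two strand pairings and one erroneous corner contact between the outer
strands. Its strands are 8 residues long rather than the peptide's 5. The
reason is geometric: a restraint is only removable when it stays violated by
more than $D$, and each true restraint grants about
$\sqrt{(d^0)^2 - t^2} \approx 5.7$ Å of free inter-strand sliding ($t$ the
transverse spacing). With 5-residue strands the ~14 Å corner separation is
smaller than the combined slack, so a nearly strain-free conformation
satisfies all five restraints and the erroneous contact degenerates into a
borderline error — a class the method explicitly tolerates. With 8-residue
strands the corner separation (24.5 Å) exceeds the slack budget and the
erroneous restraint stays violated in every conformation satisfying the true
ones, which is the defining property of the original experiment.

## Numerical and degenerate-input choices

* Ideal backbone geometry (N–Cα 1.458, Cα–C 1.525, C–N 1.329 Å; standard
  bond angles), ω fixed at 180°, Cβ placed tetrahedrally from the local
  frame; glycine has no Cβ and falls back to Cα everywhere.
* The quota uses `floor(factor * N_AA)`; exhausting the ranked list keeps
  what exists and warns.
* Duplicate contact pairs collapse to the maximum score; ranking ties break
  by ascending `(i, j)`.
* The violation-energy guard is `d > 9` (squared excess beyond the contact
  cutoff, averaged over contacts).
* GDT uses iterative trimmed superpositions seeded from the global fit and
  from every 5-residue fragment — a deterministic approximation to the
  exhaustive search of reference implementations; it recovers intact cores
  that a single global seed misses.
* Precision and recall exclude contacts touching unresolved reference
  residues from both denominators.
* Reference structures map onto the query by sequence (exact match first,
  global alignment otherwise, requiring 90% identity); backbone dihedrals
  are only extracted within contiguous residue numbering.

## Problem sizes used in the shipped tests

The rejection scenario runs 20 full protocol executions (64 runs each) on
the 28-residue fixture with 300 schedule steps and a moves factor of 10; the
precision-improvement scenario uses a 60-residue four-strand sheet, 72 input
contacts at target precisions 0.6–0.8, 10 replicates of 16 runs each with
200 steps. On the fixtures these finish in a few minutes; the defaults
(64 runs, 300 steps, factor 20) are what a user should run on real input.

## Known limitations

* Straight idealized segments: curved or bent helices and sheets are not
  representable, which in the original work already limited structural
  accuracy with predicted secondary structure.
* Borderline false positives — pairs just outside the contact cutoff, or
  within the slack budget of the true contacts — are retained by design;
  they are cheap to satisfy and the energy model cannot distinguish them.
* The weight read-out threshold (0.5) and the per-run on/off rule are
  design choices where the published description is silent; both are
  exposed in `protocol_config()`.
* No attempt is made to reproduce benchmark-scale results on real protein
  datasets; those require external predictors and reference sets.
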