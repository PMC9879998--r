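---
title: "Designing and analysing protein fold switches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analysing protein fold switches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldswitch)
```

## The problem

A *fold switch* (or metamorphic) design embeds the complete amino acid
sequence of a small fold — a 3α helix bundle or a β-grasp domain of about
56 residues — as a contiguous window inside a roughly 50% larger
α/β-plait scaffold.  One chemical sequence must then satisfy two sets of
native interactions: the long chain folds into the plait topology, while
the excised window alone folds into the small domain.  When both folded
forms are stable relative to the unfolded state, the sequence sits near a
*critical point*: truncations, tail grafts or single substitutions flip the
fold and, with it, the function (protease inhibition for the plait scaffold
versus albumin- or immunoglobulin-binding for the small domains).

`foldswitch` implements this workflow end to end: coarse fold templates,
embedding enumeration and ranking, conflict-driven sequence design under
the shared-window constraint, thermodynamic linkage and three-state
populations, models of the functional assays, and synthetic-data
generators so every stage is testable without external inputs.

## Coarse fold templates

A `fold_template()` is deliberately minimal: ordered secondary elements
(helices/strands; loops are the implicit gaps), a residue–residue contact
map, per-residue burial classes and a reference sequence.  Contacts are
defined on representative atoms — Cβ, Cα for glycine — with an 8.0 Å cutoff
and a minimum sequence separation of 3, the standard coarse-grained
convention; both are arguments of `contacts_from_coordinates()`.  Burial is
classified from contact numbers under `burial_policy()`: core at ≥ 6
contacts, surface at ≤ 2, boundary between.  Structural papers rarely state
how "core" membership in their figures was decided, so these thresholds are
a declared convention, validated only against an independent recount of the
contact list, never against any published core listing.  Residue numbering
is 1-based and inclusive throughout, matching the "positions 11–66" style
of the structural literature.

## Embedding enumeration and conflict scoring

`enumerate_embeddings()` scans every contiguous offset at which the short
fold fits inside the long one and keeps those where a chosen *anchor*
element pair overlaps by at least 4 residues (about one helical turn;
configurable).  Embeddings are contiguous by design — the documented cases
of loop-length remodelling are represented by supplying a different long
template rather than by gapped alignment.

`score_conflicts()` evaluates a candidate sequence in *both* fold contexts:
the long fold everywhere, the short fold inside the window mapped through
the offset.  The conflict taxonomy is a declared stand-in for the
qualitative notion of a "catastrophic interaction":

| kind | trigger | default severity |
|---|---|---|
| `buried_polar` | D/E/K/R/N/Q/H at a core position | 2.0 |
| `helix_breaker` | P inside a helix beyond the first turn | 3.0 |
| `strand_breaker` | P inside a strand | 3.0 |
| `overpacked_pair` | contacting core pair > 1.25 × reference volume sum | 1.0 |
| `underpacked_core` | G/A below 0.5 × reference volume at a core position | 0.5 |

Volumes come from a standard mean-residue-volume table (Å³).  A residue
incompatible with both contexts produces one conflict per context, which is
what makes positions that are core in only one fold the informative ones.
`rank_embeddings()` sorts by conflict count, then total severity, then
(descending) the number of kind-matched element correspondences, then
offset — a total, deterministic order.  Because count is the primary key,
rankings are robust to the severity weights, which are ordinal only.

## Dual-sequence design

The governing constraint is the **embedded-identity invariant**: the window
of the long sequence *is* the short construct, at all times.  All design
operations (`resolve_cluster()`, `optimize_nonoverlap()`,
`apply_variant()`, `graft_cterminal_tail()`) preserve it, and
`truncate_to_short()` merely extracts the window.  Whether transient
violations should be allowed during design is genuinely open; we enforce
the invariant unconditionally because it keeps the mutation log replayable
and the short construct well-defined after every step.

Conflict positions plus their contact partners are grouped into clusters of
at most 6 residues (connected components of the union contact graph, split
greedily by sequence position).  Each cluster is resolved by exhaustive
search over a candidate alphabet with the lexicographic objective

1. fewest mutations from the current sequence,
2. lowest summed coarse energy of the two folds,
3. alphabetical (a pure tie-break for determinism),

encoding conservation of original residues as the *first* objective rather
than a soft penalty.  The default design alphabet omits C (disulfides),
P (breakers), W, M and H.  When the full grid would exceed
`max_assignments` (default 60 000) the search proceeds in stages of
increasing mutation count and stops at the first feasible stage — exact for
the leading objective, and the exact grid is always used for the cluster
sizes exercised in tests.  Infeasible clusters return the minimal-conflict
assignment under the same tie-break chain with a warning.

Scaffold positions outside the window are then optimised by greedy
single-position sweeps (`optimize_nonoverlap()`, default 20 sweeps with
convergence logging): a substitution is accepted only if it strictly lowers
the long-fold energy *and* introduces no new conflict.  The iteration count
of the published design loops is unstated, so this convergence rule is the
package's own declared stopping criterion.

### The coarse energy

`coarse_energy()` is an additive surrogate for an all-atom scorer:
a contact-potential term, a burial term and a secondary-structure
propensity term with weights (1, 1, 0.5).  The contact table shipped in
code is derived from Kyte–Doolittle hydropathies (attraction as the product
of shifted hydropathies, with a like-charge penalty and a salt-bridge
bonus) rather than a reproduction of a published knowledge-based matrix:
we preferred a potential whose provenance is fully auditable in three lines
of code, given that the design logic only consumes *orderings* of its
values and tests assert nothing about magnitudes.  Any external scorer with
signature `(sequence, template) → score` can be substituted via the
`model`/`scorer` arguments; no binding to an all-atom package is shipped.

## Thermodynamic linkage

Each construct is treated as two-state with Gibbs–Helmholtz stability
`ΔG_unf(T) = ΔH_m(1 − T/T_m) − ΔC_p[(T_m − T) + T·ln(T/T_m)]`; the package
reports *folding* free energies (negative = stable), uses kcal/mol,
R = 1.9872 × 10⁻³ kcal·mol⁻¹·K⁻¹, and accepts °C at every interface
(Kelvin internally).  The fold-switch free energy is composed by linkage —
`switch_free_energy(dg_short, dg_long) = dg_short − dg_long` — rather than
fit directly to any single curve, mirroring how such quantities are derived
from melts of the two constructs separately.  `three_state_populations()`
evaluates the S/G/U Boltzmann weights in log space (log-sum-exp), so
extreme stabilities cannot overflow; populations sum to 1 within 1e−9 by
construction.

`fit_melt()` fits (T_m, ΔH_m) plus linear folded/unfolded baselines to an
ellipticity-versus-temperature curve with ΔC_p fixed by policy.  The
default policy is the common empirical estimate of 0.014 kcal·mol⁻¹·K⁻¹
per residue; a numeric value or a borrowed unfolded baseline from a
low-stability reference variant may be supplied instead, and the policy is
recorded in the fit output.  Numerically the baselines are profiled out
(linear least squares inside the objective), and the two nonlinear
parameters are optimised by Nelder–Mead (relative tolerance 1e−14) from
five midpoint starts across the grid — deterministic given the curve.
Degenerate inputs are first-class: a flat curve raises a fit error; a
midpoint outside the grid, an amplitude under five residual standard
deviations, or strongly autocorrelated residuals (lag-1 > 0.6, the
signature of a biphasic melt forced through a two-state model) raise
warnings.  Biphasic melts are explicitly out of the fitting model's scope.

## Functional assay models

*Kinetics.*  Competitive inhibition is fit on the standard assay design
(substrate 0.1–10 µM, inhibitor 0/50/100 nM): stage one fits
Michaelis–Menten per inhibitor level, stage two regresses K_M,app on [I]
with inverse-variance weights, giving K_I = intercept/slope; a global
one-stage fit of `v = V_max·S/(K_M(1 + I/K_I) + S)` is reported alongside.
A slope that is zero, negative, or smaller than 10⁻⁶ of the intercept over
the inhibitor range yields the explicit "no inhibition detected" outcome.
Enzyme depletion is ignored (valid while [E] ≪ K_I); a tight-binding
correction is deliberately out of scope and the estimate should not be
trusted when [I] approaches 10·[E].

*Retention.*  The affinity-column readout uses the fast-equilibrium form
`elution_cv = 1 + [sites]/K_D`.  The published operational rule —
complete retention past 20 column volumes at 100 µM immobilized sites is
called K_D ≤ 1 µM — is an order-of-magnitude call, conservative relative to
the model's strict bound; `retention_classify()` reproduces the operational
call and scales it with the site concentration.

*CSP.*  `csp()` combines amide shift changes as
`√((W_H·Δδ_H)² + (W_N·Δδ_N)²)` with W_H = 1, W_N = 0.2, the standard
down-weighting of the wider ¹⁵N range.

## What the synthetic generator emulates — and what it does not

`make_fold_pair()` builds both templates from an idealized 3D layout:
strands as a pleated sheet (5.6 Å apart), helices as 100°-per-residue
spirals (radius 2.3 Å, 1.5 Å rise) in a layer above, chain directions
alternating, element midpoints staggered, and loops bulging outward toward
solvent.  Contacts and burial follow from the same Cβ-style rules applied
to real structures, so conflict planting is geometrically interpretable:
the short fold's reference sequence is made conflict-free against both
contexts at the planted offset, then exactly `n_planted_conflicts`
buried-polar conflicts are introduced at positions core in exactly one
fold.  Layouts are resampled (up to 100 attempts, attempt count returned)
until every decoy offset scores at least `decoy_conflict_floor`, so rank-1
recovery of the plant is a construction guarantee that the test suite then
verifies independently.  Default sizes (90/56 residues, 16-residue helix
anchor, offset 10, 3 planted conflicts, floor 6) mirror the embedded-domain
setting the package addresses.

The generator does **not** emulate real packing heterogeneity, loop
conformational diversity, side-chain rotamers, or sequences resembling any
natural fold family beyond topology-level analogy.  Passing the recovery
tests therefore demonstrates that the threading/ranking/resolution
machinery is self-consistent and recovers planted structure under the
stated noise and conflict models — not that the coarse energy would rank
designs of real proteins the way an all-atom calculation would.
Likewise, melt and kinetics recovery studies show estimator correctness
under the generative model (Gaussian CD noise, mean-one lognormal rate
noise), not robustness to instrument drift or substrate depletion.

Simulation sizes used by the test suite and the acceptance script — 100
melt seeds at 2% amplitude noise, 200 kinetics seeds at 5% rate noise, 50
planted fold pairs — were chosen as the smallest studies that give stable
medians for these estimators.

## Pipeline and reproducibility

`run_pipeline()` chains fold-pair generation → embedding ranking → design →
linkage, writing each stage's outputs (`long/short.json`, `ranks.tsv`,
`design.json`, `design.fasta`, `populations.json`) before the next starts,
and finishes with a manifest echoing the fully resolved configuration and
package version.  Unknown configuration keys are rejected before any stage
runs; a rerun with the same configuration and seed is byte-identical, and a
run can be repeated from its manifest alone.  All randomness in the package
flows through explicit seeds and restores the caller's RNG state
(`withr::with_seed`).

## Known limitations

* No backbone remodelling, loop rebuilding or structure prediction; the
  package designs sequences onto *given* coarse templates.
* No gapped or partial embeddings; loop-length variants are separate
  templates.
* The coarse energy is a ranking device, not a stability predictor; its
  absolute values are meaningless.
* Two-state melts only; no chemical-denaturant (m-value) or kinetic
  unfolding analysis; no global multi-curve fitting.
* Kinetics assume no enzyme depletion and pure competitive inhibition; no
  IC₅₀ or tight-binding analysis.
* mmCIF input and secondary-structure assignment from coordinates are out
  of scope (element boundaries are supplied, not computed).
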