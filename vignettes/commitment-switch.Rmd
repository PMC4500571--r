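---
title: "Modelling the B-lymphoid commitment switch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the B-lymphoid commitment switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bswitch)
```

## The biological system and the model family

Lymphoid-primed multipotent progenitors (LMPPs) commit to the B-lymphoid
lineage through a regulatory program in which the zinc-finger co-factor
ZNF521 antagonizes the B-cell specification axis E2A → EBF1 → PAX5. The
package models this decision as a deterministic dynamical system over ten
species: the cytokine receptors FLT3 and IL-7R, the transcription factors
IKAROS, GFI1, PU.1, E2A, ZNF521, EBF1 and PAX5, and the surface marker
CD19 that reports commitment. Two dimensionless environmental inputs,
`T_EBF1` and `T_ZNF521`, represent exogenous transcriptional activation of
EBF1 and ZNF521 and serve as the bifurcation parameters.

Every equation in the family has the same phenomenological shape

$$\frac{dx_i}{dt} \;=\; \frac{N_i(x, T)}{1 + D_i(x, T)} \;-\; \mu_i x_i,$$

a saturating production ratio minus first-order degradation, where $N_i$
and $D_i$ are sums of terms $k \cdot v_1 \cdot v_2$ with $k$ a kinetic
constant and $v_1, v_2$ states or inputs. Only heterodimeric (pairwise)
interactions appear — never higher-order cooperativity — because with
arbitrary Hill exponents bistability could be engineered trivially and the
analysis would lose its discriminating power between network topologies.
Activators appear in numerator and denominator (saturating activation);
repressors appear in the denominator only. Because every non-basal
numerator term recurs in the denominator, each production ratio is bounded
by $\max(\text{basal}, 1)$, so state $i$ is eventually confined to
$[0, \max(\text{basal}_i,1)/\mu_i]$; this invariant box sizes all
equilibrium searches.

The catalogue (`list_models()`) contains eleven members: the full network
`full_A` with the PAX5 ⊣ ZNF521 repression (strength `b4`); its ablation
`full_no_pax5_znf521` (`b4` removed); two alternative-topology variants in
which that repression is replaced by a heterodimeric EBF1:E2A term
(`full_B`) or by direct IKAROS repression (`full_C`); and the seven core
feedback sub-modules, from the two-node EBF1/ZNF521 mutual inhibition to
the three-node EBF1/PAX5/ZNF521 loop that is sufficient for the
irreversible switch.

Three printed-form decisions are worth recording. The two-node module's
ZNF521 equation is implemented with degradation acting on ZNF521 itself
(an equation's degradation term must act on its own state). The EBF1
equations of the two five-species ZNF521 modules are implemented with the
saturating *division* form used by every other equation (not a literal
product). The repression terms of `full_B` and `full_C` are structural
reconstructions — the interactions are named but their kinetic form is
not printed — built on the same heterodimeric pattern as the nominal
PAX5 arm, reusing the symbol `b4` as the variant's repression strength.
In the full model the ZNF521 repression of EBF1 enters as `a4*ZNF521`
while several sub-modules print the heterodimeric `a4*EBF1*ZNF521`; each
model is implemented exactly as written, and the sub-module consistency
tests compare only where the printed forms coincide.

## The nominal parameter set

The package ships a complete 53-symbol kinetic set
(`nominal_parameters()`, stored as
`inst/extdata/params_synthetic_nominal.txt`). The set is *synthetic*: it
was produced with the package's own bifurcation-search tooling, calibrated
once against the qualitative constraints that define the published switch
and then frozen:

* at `T_ZNF521 = 0` the full network is an irreversible bistable switch in
  `T_EBF1`: two stable branches, the lower limit point on the negative
  (inaccessible) semiaxis, the upper at positive activation;
* the two attractors carry the canonical programs — FLT3 and ZNF521 high
  with EBF1/PAX5/CD19 low (LMPP), and the reverse (pro-B);
* `T_ZNF521 = 0.12` renders the switch reversible (both folds admissible),
  and `T_ZNF521 = 0.3` shifts the transition to higher `T_EBF1`;
* the sub-module ladder reproduces its published progression (single
  steady state with an inaccessible fold for the two-node module;
  monostability for the intermediate modules; irreversible bistability
  once the PAX5-mediated repression closes the second loop).

All degradation rates are 0.1 s⁻¹, placing saturated expression levels
near 10 dimensionless units and giving relaxation times of order 10 s;
basal production rates are 1–2 orders of magnitude below saturation, a
standard regime for transcription-factor circuits. Because the set is a
calibrated stand-in rather than a transcription of the original
supplementary values, *quantities tied to specific parameter values* —
fold coordinates, sensitivity boundaries such as the printed `b4` range,
and the per-parameter sensitivity group memberships — are properties of
this set, not reproductions of the printed numbers. The structural results
(switch classes, attractor programs, ladder ordering, screen verdicts) are
the package's claims.

## Numerical methods

**Integration.** `simulate_model()` uses a stiff-capable solver (`lsoda`)
with the analytic Jacobian, relative tolerance 1e-8 and absolute 1e-10;
the rational kinetics are mildly stiff near saturation. Convergence of a
trajectory to steady state is reported as the infinity norm of the
right-hand side at the final time.

**Equilibria.** `find_equilibria()` launches damped Newton iterations from
a seeded Latin-hypercube sample of the invariant box scaled by 1.5 (plus
its corners and centre), deduplicates roots at 1e-5 in the infinity norm,
and classifies stability from the eigenvalues of the analytic Jacobian.
Roots with negative coordinates are retained but flagged inadmissible;
they are excluded from bistability counting and are not used as branch
seeds. Eigenvalue real parts within 1e-7 of zero are labelled *marginal*
and treated as unstable for branch bookkeeping (fold neighbourhoods).

**Continuation.** `continue_curve()` implements pseudo-arclength
predictor–corrector continuation: unit tangents from the null space of
the extended Jacobian, a Newton corrector constrained orthogonally to the
tangent, and adaptive steps in [1e-6, 1e-1] (initial 1e-2). Model branches
are continued in *scaled* coordinates (states divided by their
invariant-box magnitudes) so that one arclength unit is commensurate
across species whose levels differ by orders of magnitude; stability is
always classified from the unscaled Jacobian. Folds are detected by a sign
change of the tangent's parameter component and refined by bisection on
the step length; refined folds satisfy rank deficiency of the state
Jacobian (smallest singular value below 1e-6) and the two traversal
directions reproduce fold locations to 1e-6. The free parameter may run
negative — that is mathematical branch tracing; points below the
admissible bound (default 0) are flagged, matching the convention that
activating inputs cannot be negative.

**Classification.** `classify_switch()` works from stable branch
segments: bistable intervals are pairwise overlaps of distinct stable
segments (segment bounds snapped to refined fold parameters), with
segments restricted to physically admissible (non-negative) states. A
diagram is *monostable* if no admissible parameter value carries two
stable equilibria, *reversible bistable* if a bistable interval exists
with both bounding folds admissible, and *irreversible bistable* if
bistability extends below the admissible bound, disconnecting the two
stable branches on the physical domain. `hopf_scan()` tracks
complex-pair real-part sign changes along branches; for this model family
only folds are expected, so any crossing is surfaced as a warning.

**Sensitivity sweeps.** `bistability_interval()` scans 33 log-spaced
values over nominal/64 … nominal×64 — wide enough to bracket multi-fold
changes in either direction — evaluates the bistability predicate (the
`T_EBF1` diagram at `T_ZNF521 = 0` classifying non-monostable), and
refines the boundaries of the bistable run containing the nominal value by
bisection to a relative tolerance of 1e-3. Runs touching the scan edge are
reported *censored*: the switch survives beyond the scanned window and the
printed boundary is the window edge, not a fold of the system. With this
nominal set the PAX5 ⊣ ZNF521 strength `b4` has finite, uncensored
boundaries (log2 fold changes ≈ −1.31 and +3.70 around the nominal
value); parameters of the peripheral species (PU.1, GFI1, IKAROS, CD19
arms) preserve the switch across the entire window.

**Discovery.** `search_bistable_parameters()` is a seeded genetic
algorithm (tournament selection, BLX-α blend crossover in log space,
log-uniform mutation) over user-chosen parameter ranges, scored by a
graded distance-to-bistability fitness: counts of admissible stable
equilibria at probe activation values, with diagram-level rewards for the
requested objective. Every reported hit is re-verified by a full diagram
build and classification; identical seeds yield identical results.

## Synthetic data

`make_expression_fixture()` draws two-condition (LMPP, proB) expression
tables around means that encode the canonical program, with multiplicative
log-normal noise (sd 0.05 on the log scale by default) — intensities are
positive and right-skewed, as in microarray summaries. The intermediate
factors are set equal across conditions to exercise the *flat* pathway of
`concordance()`, which excludes factors whose normalized difference is
below 0.1 from the scored denominator (only factors whose expression
varies materially are compared). `make_de_table()` plants a known set of
differentially expressed rows (|fold| ≥ 2.5, p ≤ 0.01) in a null
background constructed to fail the ±2 fold-change / p < 0.05 filter, so
the filter's recovery can be checked against ground truth.

What the generators deliberately do not emulate: probe-level microarray
artifacts (background, cross-hybridization), biological replicate
structure, and p-value computation from intensities (p-values are inputs
to the filter, never computed here). Passing the concordance and filter
tests therefore demonstrates that the *model attractors* carry the
expected programs and that the *filter logic* is correct — not that the
pipeline would denoise real microarray data.

## Normalization and comparison conventions

`normalize_max()` divides each factor by its maximum across the two
conditions, so each factor reaches 1 in exactly one condition — the
per-factor reading of "normalized with respect to the given maximum",
which matches paired-bar comparisons of attractors versus measured
profiles. The operation is idempotent and scale-invariant, and direction
concordance is invariant under a consistent relabelling of the condition
columns.

## Problem sizes and runtime choices

The default analyses are desk-scale on one CPU: diagrams use 3–5 probe
values with a few dozen Newton starts each; the sensitivity sweep needs
roughly 50 predicate evaluations per parameter (about 1.5 s each for the
ten-species network); the test-suite GA runs populations of 4–10 for a
handful of generations on the three-node core module. These sizes were
chosen so that every headline analysis re-runs from scratch in minutes
while leaving the algorithms' accuracy limits (1e-6 folds, 1e-8 branch
residuals) intact.

## Known limitations

* The nominal set is one calibrated point in a 53-dimensional space;
  quantitative fold coordinates and sensitivity boundaries are specific to
  it. Re-deriving a set under the same constraints with
  `search_bistable_parameters()` will land elsewhere in the bistable
  region.
* At `T_ZNF521 = 0.3` this set sits essentially at the cusp where the two
  limit points merge: the diagram is classified at the boundary between a
  hair-thin bistable window and a steep monotone (ultrasensitive)
  response. The robust, tested statement at that level is the *delay* of
  the commitment transition, not a switch class.
* The classification machinery assumes fold-type bifurcations only (which
  is what this family exhibits); Hopf crossings are detected and warned
  about but not continued.
* No stochastic dynamics: the models are deterministic ODEs, so questions
  of noise-induced switching are out of scope.
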