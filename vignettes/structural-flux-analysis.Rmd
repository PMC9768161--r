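---
title: "Elementary-mode structural flux analysis: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elementary-mode structural flux analysis: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(struflux)
```

## The model

`struflux` predicts the flux distribution of an organ's metabolic network
from stoichiometry alone, under the assumption that the tissue has evolved to
serve identifiable biological objectives. The pipeline has four stages.

**1. Elementary modes.** An elementary mode (EM) is a flux vector `v` with
`N_int v = 0` (internal metabolites exactly balanced), `v_k >= 0` for every
irreversible reaction, and minimal support: no other steady-state vector uses
a strict subset of its reactions. The set of EMs is the unique minimal
generating set of all steady-state behaviours, so scoring EMs scores every
route the network can take — including non-optimal ones, which distinguishes
this approach from flux balance analysis, where a single optimal route
absorbs everything.

**2. Yields and efficiency.** Organ networks take up chemically incomparable
substrates (glucose, lactate, amino acids, whole protein, free fatty acids),
so a mode's coefficients are normalized by the mass it imports:
`e_i^k = c_i^k / sum_s c_{s,i} MW_s`, summing over the substrate uptake
reactions with molecular weights from a sidecar configuration. The efficiency
of mode *i* toward an objective reaction is
`eps_i = e_i^objective / sum_k |e_i^k|`: objective output per unit of total
pathway activity. Two consequences are worth stating plainly. First, because
the normalizing denominator is shared by all yields of a mode, it cancels
inside `eps_i`; molecular weights influence the analysis through the
participation terms `|e_i^k|` entering the structural flux, not through the
efficiency ranking of modes. Second, `eps_i` is homogeneous of degree zero,
so the arbitrary scaling of an EM never matters; the package still fixes a
canonical scaling (smallest nonzero |coefficient| = 1) for deterministic
equality testing and serialization.

**3. Structural fluxes.** `aSF_k = sum_i eps_i |e_i^k| / sum_i eps_i` is the
efficiency-weighted mean participation of reaction *k*;
`aStruF_k = aSF_k / aSF_TotalSub` (total substrate uptake flux) makes values
comparable across networks and, critically, across *restricted* mode sets —
the gene-constrained scenarios below compare mode subsets of very different
sizes.

**4. Evaluation.** Predicted exchange values (sign-adjusted to the
release-positive convention of arteriovenous measurements) are compared with
measured organ exchange fluxes by Pearson correlation across metabolites.
Correlation is the right comparison metric here because `aStruF` is unitless
while measurements are in nmol (100 g bw)⁻¹ min⁻¹: `r` is invariant under
positive affine rescaling of either vector, so the unknown proportionality
between structural flux and absolute rate drops out. Objectives (or per-gene
scenarios) are ranked by `r`, ties broken alphabetically for determinism,
with a two-tier significance flag (`*` for P < 0.05, `**` for
0.05 ≤ P < 0.1).

### Conventions and edge rules

Several places in the formulas need a convention the equations themselves do
not fix:

* A mode that takes up no substrate (an internal futile cycle) has a zero
  denominator in the yield normalization. Such modes are flagged
  `no_substrate` and given efficiency 0 — they are kept in the mode set so
  the same `ModeSet` serves every objective unchanged.
* A substrate carried in the producing direction contributes zero to the
  denominator (it is not an investment in that mode).
* The objective yield is read as a production ratio: modes with zero or
  negative objective yield get efficiency 0.
* If every mode has efficiency 0 the objective is *unreachable*; the direct
  computation raises an error naming the objective, and the scan/scenario
  wrappers flag the entry rather than dropping it.
* Relative changes between a constrained and a baseline prediction are
  percentages; a reaction with zero baseline and positive constrained flux
  has no finite percentage and is flagged `new flux` instead.

## Exact arithmetic

Support minimality is a combinatorial property: whether a coefficient is
exactly zero decides whether a candidate is elementary. The enumerator
therefore runs entirely in exact integer arithmetic — stoichiometric
coefficients are stored as reduced rationals (decimal input is expanded by
powers of ten), each internal-metabolite row is scaled integer by its
denominator lcm, and tableau rows are gcd-reduced after every combination.
Integers are held in doubles, which are exact up to 2^53; any operation that
would exceed that bound aborts with an explicit error rather than rounding.
Floats enter only downstream, in the structural-flux stage, where every
quantity is a ratio and round-off is benign (the scale-invariance suite
checks 1e-12 agreement under mode rescalings spanning six orders of
magnitude).

The algorithm is the nullspace-style double description: starting from the
tableau `[I | N^T]` over the reversible-split (all-irreversible) network, one
internal metabolite is eliminated per step by nonnegative combination of
sign-opposed row pairs, keeping a combination only if the pair is adjacent
(no third row's zero set contains the pair's common zero set). The column
with the fewest sign-opposed pairs is eliminated first. Spurious
forward+backward two-cycles introduced by splitting are removed, and a mode
whose support is entirely reversible is identified with its negation (first
nonzero coefficient made positive). A configurable cap (default 1e7 modes)
turns combinatorial explosion into an explicit capacity error instead of an
unbounded run; published organ models reach millions of modes, so users must
opt into larger caps consciously.

Correctness is established against `brute_force_modes()`, a definition-level
oracle: every candidate support of the split network is tested for a
one-dimensional, sign-feasible exact nullspace of the restricted internal
stoichiometry. The oracle is limited to 14 reactions post-split and is pure
verification — the test suite checks set-identical output on 50+ seeded
random networks, plus steady state, sign feasibility and mutual
non-inclusion of supports on every enumerator output.

## Gene-constrained scenarios

In a perturbed condition, the package restricts the active mode set to the
pathways containing a significantly upregulated gene — positive log2 fold
change and adjusted P below α (default 0.05) — one gene at a time, and
recomputes structural fluxes per scenario. The restriction keeps a mode if
its support intersects the gene's reaction set (the "pathway contains the
gene" reading; requiring the gene's reaction in *every* mode would instead
model an essential step, a stricter interpretation not adopted here). Gene
symbols match case-insensitively, since capitalization conventions differ
between rodent and human symbol sources. Genes mapped to identical reaction
sets provably yield identical scenarios, which the tests assert. Multi-gene
simultaneous constraints are out of scope by design; the per-gene scan keeps
scenarios interpretable and mirrors how differential-expression hits are
inspected one pathway at a time.

## Measured organ fluxes

The arteriovenous balance is deliberately elementary: flux =
(venous − arterial) × plasma flow × 100 / body weight, release-positive,
normalized per 100 g body weight. Renal plasma flow comes from PAH indicator
dilution in its classical Fick form — urinary PAH excretion rate over the
arteriovenous PAH difference — which requires net extraction
(arterial > venous) and errors otherwise. Plasma (not whole-blood) flow and
plasma concentrations are used throughout; hematocrit is carried in the data
model for completeness but enters no default formula, since a whole-blood
correction is a study-specific choice. Total ammoniagenesis is the renal
venous flux plus urinary excretion; the urinary percentage is undefined
(flagged `NA`) when the total is not positive. Group summaries report both
mean ± SEM and median/range, with a Wilcoxon rank-sum comparison per
metabolite and a Stouffer combination across metabolites (one-sided P values
signed by the group-mean difference).

## What the synthetic generator emulates — and what it does not

`make_toy_network()` produces families with analytically known mode counts
(chain: 1, diamond: 2, k-fan: k, double diamond: 4, chain+cycle: 2 including
one substrate-free cycle) and a random-sparse family whose mode set only the
oracle knows. Every generated model carries the annotations the pipeline
needs: a substrate molecular weight (100 g/mol on the uptake, for clean hand
arithmetic), an exchange map, and a one-gene-per-reaction gene map.

`make_synthetic_measurements()` inverts the organ-balance arithmetic: venous
concentrations are constructed so that `exchange_flux()` recovers a
prescribed release-positive pattern, with Gaussian noise added to the venous
concentration — on concentrations, not on fluxes, so noise propagates through
the same arithmetic real measurements would. The concentration noise SD is
chosen to realize a requested flux-scale SD exactly. Defaults encode the
study conditions of the motivating system: 8 animals per group, 300 g body
weight, 3.0 ml min⁻¹ renal plasma flow.

What passing tests on these data do **not** show about real organs: the
generator has no inter-animal variability in flow or body weight, no
measurement error on the arterial side, no hematocrit dynamics, no acid-base
physiology, and its networks are orders of magnitude smaller than a curated
organ model. The parameter-recovery guarantee (the generating objective ranks
first in ≥ 95% of noisy replicates) validates the *machinery* — enumeration,
scoring, alignment, correlation, ranking — not the biological claim that any
particular organ optimizes any particular objective; that question needs real
measured fluxes.

## Problem sizes and numerical choices

The test suite and the acceptance script run on deliberately small problems:
random networks are kept at ≤ 12 reactions after reversible splitting (the
brute-force oracle's comfort zone; its cost is exponential by construction),
the recovery simulation uses 100 replicates of an 8-animal, 3-branch design,
and the law-of-large-numbers check uses 200 animals. These sizes make the
whole suite run in well under a minute while exercising every code path;
they are choices of the package's test design, and the enumerator itself has
no such limits beyond its capacity cap and the 2^53 exactness guard.

Other numerical decisions: P values of exactly 0 or 1 entering Stouffer's
formula are clamped to a configurable epsilon (1e-15) with a warning;
correlations require n ≥ 3 and non-constant vectors (a constant vector is a
`degenerate correlation` error, not an `NA`); mode output order is sorted by
support signature then coefficients, so every run of every function is
deterministic given its inputs and seed.

## Known limitations

* Enumeration in interpreted R with exact arithmetic is intended for small
  and medium networks; a multi-million-mode organ model is beyond a desktop R
  session's patience even though the algorithm is the standard exact one.
* METATOOL is the only model format (by design); there is no SBML import and
  no Boolean gene–protein–reaction logic — the gene map is a flat
  many-to-many table.
* Substrate molecular weights and the exchange map live in a sidecar file
  because the METATOOL format cannot carry them; results depend on that
  configuration, and the package validates but cannot infer it.
* The per-gene restriction treats each upregulated gene independently;
  combinatorial interactions between simultaneous expression changes are not
  modeled.
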