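---
title: "Constraint-based modelling of mitochondrial metabolism with mitofba"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based modelling of mitochondrial metabolism with mitofba}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitofba)
```

## The model and its assumptions

mitofba works with compartmentalised constraint-based metabolic models: a
set of metabolites assigned to the mitochondrial matrix, the cytosol, or
the system boundary, and a set of reactions with signed stoichiometries
and flux bounds in µmol/min/gDW. Ids follow the common compartment-suffix
convention ("MM" matrix, "Cyto" cytosol, "_b" boundary). The central
assumption is the quasi steady state: for the stoichiometric matrix $S$
(rows: non-boundary metabolites; columns: reactions) every admissible flux
distribution $v$ satisfies

$$ S\,v = 0, \qquad v_{\min} \le v \le v_{\max}. $$

Directionality is expressed through the bounds (an irreversible reaction
has a zero lower or upper bound). Because this system is almost always
underdetermined, a flux distribution is selected by maximising (or
minimising) the flux of one *objective pseudo-reaction* — a drain encoding
a physiological demand. Six such objectives are registered per model:
cytosolic ATP demand, amino-acid availability, RNA and DNA nucleotide
synthesis, inner-membrane lipid synthesis, and haem synthesis. ATP demand
is the headline objective; the others mainly certify that the network can
produce what a mitochondrion must.

Three modelling conventions matter for everything downstream:

* **Boundary species carry no steady-state row.** Exchanges are ordinary
  columns written as explicit one-way pairs (uptake `boundary -> cytosol`,
  efflux `cytosol -> boundary`, both with non-negative flux), which
  removes any sign ambiguity in uptake/efflux judgements.
* **Unbounded means ±1000.** LP solvers dislike infinities; the sentinel
  is documented, far above any physiological flux in this domain, and
  applied uniformly (`FLUX_BOUND_SENTINEL`).
* **One objective per solve.** The objective's sense (maximise/minimise)
  is registered with it.

## The solver

No linear-programming package is available in the target R environment,
so the package carries its own bounded-variable, two-phase revised
simplex (`mitofba:::lp_solve`). Design points:

* explicit dense basis inverse with product-form updates and periodic
  refactorisation (every 64 pivots) for numerical hygiene;
* Dantzig pricing with an automatic fall-back to Bland's rule once a
  degenerate stall is detected, guaranteeing termination;
* bound flips handled in the ratio test (a nonbasic variable may move to
  its opposite bound without a basis change);
* feasibility/optimality tolerance $10^{-9}$; every optimal solution is
  re-checked against $|S v| \le 10^{-9}$ before being returned, and a
  violation is an error, never a silent return.

The solver is validated in the test suite against hand-solved programmes,
an exhaustive vertex-enumeration oracle, and `scipy.optimize.linprog`
as an independent implementation.

Columns are fed to the solver in a fixed order (category, then
lexicographic id), so identical inputs produce the identical vertex —
reproducibility of the *distribution*, not just the optimum.

## Alternate optima: the reference distribution and FVA

Steady-state LPs of realistic networks have massively degenerate optima,
so "the flux of reaction X under normal conditions" is ill-defined for a
bare LP solve. The package therefore distinguishes:

* `fba_optimize()` — one optimal vertex, deterministic but arbitrary
  among the optima;
* `reference_fluxes()` — the parsimonious optimum: among all flux
  distributions achieving the optimal objective value, the one minimising
  total absolute flux through non-boundary, non-objective reactions
  (two-stage LP). All knockdown fractions and "flux under normal
  conditions" statements in this package use this reference;
* `flux_variability()` — per-reaction min/max flux at a fixed objective
  fraction. A reported flux is only comparable with an external figure
  when its variability range at fraction 1 is narrow; scans report it
  alongside.

The flux-zero threshold for every qualitative judgement (efflux present,
pathway active, loop present, reaction blocked) is $10^{-6}$
µmol/min/gDW (`FLUX_ZERO_TOL`): three orders of magnitude below the
smallest physiologically printed fluxes, three above solver noise.

## The miniMito fixture: a stated world

`build_minimito()` generates a miniature two-compartment model of
cardiomyocyte mitochondrial physiology in code. It exists so that every
operation in the package is testable against quantities that can be
computed by hand, with no external file. It contains: glycolysis (lumped
to glucose → 2 pyruvate + 2 ATP + 2 NADH + 2 H⁺), reversible lactate
dehydrogenase, pyruvate/H⁺ import, pyruvate dehydrogenase, the full
eight-step TCA cycle under its KEGG reaction ids (so the disease presets
address `R01082MM`, `R02164MM`, `R01700MM` directly), pyruvate
carboxylase as the anaplerotic entry, lumped octanoate β-oxidation
(4 acetyl-CoA, 3 NADH, 3 QH₂, 2 ATP activation cost) and ketone-body
degradation (via succinyl-CoA:acetoacetate transfer, which forfeits one
substrate-level ATP), complexes I–IV with explicit proton pumping
(4/4/2 H⁺ per electron pair), a fixed reactive-oxygen branch carrying
0.1 % of complex I electron pairs to superoxide (dismutated and effluxed
as H₂O₂), ATP synthase translocating exactly 8/3 H⁺ per ATP, the
phosphate/H⁺ symporter contributing the remaining 1 H⁺ per exported ATP,
the malate–aspartate shuttle with an electrogenic aspartate/glutamate
carrier, the GABA shunt (`R00261MM`, `R01648MM`, `R00713MM`), and a
glutamate/H⁺ importer.

### Stated bounds

The fixture's defaults are the stated world and are not tuned:

| boundary | value (µmol/min/gDW) | rationale |
|---|---|---|
| oxygen uptake | 19.8 | measured maximum for resting heart |
| glucose uptake | 0.9 | measured maximum |
| lactate uptake | 0.5 | heart is a net lactate consumer; chosen once as a realistic uptake |
| 3-hydroxybutyrate uptake | 0.35 | ketone bodies are a minor heart fuel |
| fatty-acid uptake | sentinel | deliberately oxygen-limited, as in vivo |
| aspartate, malate, oxaloacetate, citrate | 0.01 each | the standard "arbitrarily small" probing ceiling for unmeasured boundaries |
| ammonia, glycine, bicarbonate | 0.1 each | small ceilings for nitrogen, haem and anaplerotic chemistry |

The inner-membrane lipid demand uses the literature class ratio
(phosphatidylcholine 40 %, phosphatidylethanolamine 34 %,
phosphatidylserine 3 %, cardiolipin 18 %), which sums to 95 %; the
fixture normalises the four coefficients to 1 and records the discrepancy
here.

### Protons: pumping only

Free protons are modelled per compartment, but the lumped chemistry
reactions are written proton-neutral: only proton-motive bookkeeping
(pumping at complexes I/III/IV, the synthase rotor, H⁺-coupled transport,
the one-way leak) plus the two genuinely load-bearing scalar terms
(glycolysis releases 2 H⁺, lactate dehydrogenase consumes 1) appear in
the proton rows. This keeps the matrix proton row a strict conservation
law: **every proton returned to the matrix must be re-pumped by the
respiratory chain, whose capacity is fixed by the oxygen bound.** A
useful consequence, visible in the solved model: cytosolic scalar protons
from glycolysis cannot be harvested by the ATP synthase — the optimum
vents them through the proton boundary instead, because using them would
overdraw the matrix proton row. The general microspecies-based
rebalancing the full-scale workflow needs (`rebalance_protons()`)
is implemented and tested separately; proton counts per major
microspecies at matrix pH 8.05 / cytosolic pH 7.3 are an input table, not
something this package computes.

### The pre-registered maximum-ATP yield

With ATP demand as objective, the active set is fixed by the
ATP-per-oxygen ranking of the fuels (glucose > lactate > ketone >
fatty acid, with the citrate-to-oxoglutarate shortcut ranking highest);
all bounded fuels run at their ceilings and octanoate fills the remaining
oxygen. Writing $F$ for octanoate uptake, $T = 4F + 2.3 + 0.7$ for TCA
turns and $N$ for total matrix NADH, the oxygen row and the matrix proton
row give two linear equations:

$$\Big(\tfrac{1-f}{2} + f\Big) N + \tfrac{T + 3F}{2} = 19.8,
\qquad
4(1-f)N + 6\,Q_{III} = \tfrac{8}{3} P + E + 2.3 + 2.3,$$

with $f = 0.001$ the reactive-oxygen fraction, $Q_{III}$ the quinol flux
through complex III, $P$ the synthase flux and $E = P + (T - 0.35) - 2F$
the ANT/phosphate-carrier traffic. Solving exactly in rationals gives

$$ F = \tfrac{565651}{550375}, \quad
   T = \tfrac{3913729}{550375} \approx 7.111, \quad
   Z_{\mathrm{ATP}} = \tfrac{609567852}{6054125} \approx 100.6863671, $$

with an acetyl-CoA source split of 57.8 % fatty acid, 32.3 % pyruvate,
9.8 % ketone. These rationals were frozen before the solver was connected
and the acceptance suite requires the LP to reproduce them to $10^{-9}$.
The derivation deliberately mirrors heart physiology: oxygen and glucose
uptake at their maxima, a TCA flux near 7, β-oxidation oxygen-limited,
NADH produced by the cycle in preference to fat and ketones with all
three active.

### What miniMito does not capture

No kinetics, concentrations or regulation — like all FBA, feasibility
and optimality only. β-oxidation and ketone degradation are single lumped
steps; there is no glycerol-phosphate or carnitine shuttle as separate
machinery; cytochrome c and the quinone pool live formally in the matrix
compartment; membrane potential is folded into proton counts; nitrogen
chemistry is reduced to four amino acids, ammonia and glutamine export. A
green test on miniMito certifies the *operations* (solver, audits, scans)
and the *qualitative physiology* encoded above — it does not certify any
full-scale reconstruction.

## Disease simulation semantics

`disease_preset()` ships the three TCA-cycle disorders: fumarase
deficiency (`R01082MM`, plus an added fumarate efflux path, since the
unmodified network has no exit for fumarate), succinate dehydrogenase
deficiency (`R02164MM`), and α-ketoglutarate dehydrogenase deficiency
(`R01700MM`; the E3-subunit variant adds the shared dihydrolipoamide
dehydrogenase reaction `R07618MM` where a model contains it).

* **Knockdown denominator.** A residual fraction $\varphi$ clamps the
  reaction to $[\min(0, \varphi r_0), \max(0, \varphi r_0)]$ where $r_0$
  is its *parsimonious reference* flux — preserving the direction of the
  reference (residual enzyme activity cannot reverse a physiologically
  one-way step), and making percentages reproducible where an arbitrary
  optimal vertex would not be.
* **Threshold searches** scan a 1 % fraction grid and refine the event
  boundary by bisection to 0.1 %. Events (efflux onset of a metabolite,
  inactivation of a named pathway) are assumed monotone in the fraction;
  monotonicity is checked over the grid and violations warn rather than
  silently returning a boundary.
* **Uptake relief** releases one boundary at a time (to the sentinel or
  to an explicit trial value such as 5 µmol/min/gDW), re-optimises, and
  restores the model between trials.
* **Efflux direction** is read from each exchange's stoichiometry (flux
  towards the boundary species), never from its id.

On the fixture these semantics reproduce the expected clinical
biochemistry: near-total loss of ATP production with fumarate and lactate
efflux under fumarase knockout; succinate rather than fumarate efflux,
and a slightly deeper ATP loss, under succinate dehydrogenase knockout
(complex II no longer feeds the quinone pool); and only a ~5 % ATP loss
under α-ketoglutarate dehydrogenase knockout, because the GABA shunt
bypasses the lesion at the cost of the succinyl-CoA synthetase ATP.

## Loop audits

A thermodynamically infeasible internal loop is a circulation carrying
flux with no boundary exchange. Two audits are provided:

* `find_internal_loops()` emulates the classic objective-driven audit:
  all boundary conditions *and objective drains* are constrained to zero
  (an open drain would act as a boundary — this resolves a genuine
  ambiguity in the classic description) and each objective is solved.
  Because a vertex returned under a zero-valued objective is arbitrary,
  the audit as literally described is solver-luck; this implementation
  makes it adversarial by maximising total internal flux at the fixed
  objective value, so any forward-orientable circulation is surfaced
  deterministically.
* `probe_loop_capacity()` is the orientation-complete check: each
  internal reaction's flux is maximised and minimised under the zeroed
  boundaries. An empty probe implies an empty objective-driven audit for
  every objective (and the suite property-tests this implication).

The audits report; they never auto-fix. Directionality repairs are
user-supplied constraint tables, because automatic direction flipping
silently changes biology. Audits also never mutate their input, and
`verify_flux_capability()` re-runs the blocked-reaction partition under
normal bounds so that loop-removing directionality edits can be shown not
to have silenced parts of the network.

## Design decisions in genuinely open areas

* **Anaplerosis.** The first fixture draft had every C4/C5 carrier as a
  counter-exchange, which closes the cycle-intermediate pool and silently
  makes any succinyl-CoA drain (the haem objective) infeasible. Pyruvate
  carboxylase with a small bicarbonate ceiling was added as the
  anaplerotic entry — the same route the disease analyses highlight.
* **Efflux-path neutrality.** "The added fumarate path carries no flux
  under normal conditions" is formalised as: every objective optimum is
  unchanged, the path's FVA minimum is zero at every objective (it is
  never *forced*), and the maximum-ATP reference routes nothing through
  it. The blunt form — zero in every optimal vertex — is false in any
  network where C4 venting ties between exits, for reasons that have
  nothing to do with the edit.
* **Duplicate efflux-path calls** are idempotent no-ops with a warning,
  so disease presets can be scripted safely.
* **SBML dialects.** Level 2 kinetic-law bound parameters (the 2011-era
  convention) and Level 3 FBC bound references are both read and
  normalised to plain lb/ub; the writer emits Level 2. Transport steps
  are classified by conserved chemistry across compartments — by
  stoichiometry shape, never by id. Reported model inventories
  distinguish raw and per-category counts rather than enforcing a single
  printed total.
* **Degenerate inputs.** An empty model builds a 0×0 matrix; a model
  with all-zero bounds optimises to zero rather than erroring;
  infeasibility and unboundedness are statuses, not exceptions; a forced
  nonzero bound under closed boundaries is reported as a structural
  error by the audits, not mislabelled a loop.

## Known limitations

The simplex is dense and single-threaded: adequate for models of a few
hundred reactions (a full-scale mitochondrial reconstruction solves in
well under a second), not for genome-scale networks. pFBA is implemented
by variable splitting, doubling the column count of the second stage.
`find_internal_loops()` can in principle miss a circulation whose only
feasible orientations have negative total internal flux; the capacity
probe closes that gap and is the audit of record. The package consumes a
reconstruction (SBML plus constraint tables); it does not curate one —
localisation evidence, pKa/microspecies computation and ΔG-based
directionality assignment are upstream of its scope.
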