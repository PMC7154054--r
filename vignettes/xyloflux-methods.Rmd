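---
title: "Modeling glucose/xylose co-utilization and NADPH design in E. coli"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling glucose/xylose co-utilization and NADPH design in E. coli}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xyloflux)
```

## Scope and model structure

`xyloflux` is a regulated kinetic model of *E. coli* central carbon
metabolism aimed at one design question: how the glucose/xylose ratio and a
small set of genetic interventions (Δ*pgi*, Δ*ptsG*, ArcA overexpression, a
heterologous mevalonate pathway) shape NADPH availability, NADPH
productivity and mevalonate titer in batch culture.

The state comprises intracellular metabolite pools (mM) from glucose and
xylose uptake down to the TCA cycle, plus cofactors, extracellular
substrates/products (g/l) and biomass (gDCW/l). Cofactors use moiety
reduction: ATP, NADH and NADPH are integrated and their partners follow
from conserved totals (`A_total`, `N_total`, `NP_total`), so conservation
holds to machine precision by construction; AMP is carried as a constant
pool member. Each intracellular species obeys

d[i]/dt = (production − consumption − growth demand) / V_cyto − μ·[i],

with V_cyto = 2.47 ml/gDCW converting specific rates (mmol/gDCW/h) to
concentration changes. Cofactors are not diluted: their moiety totals per
cell are maintained by synthesis during growth. Extracellular balances
scale specific rates by biomass; chemostat mode adds dilution terms
D·(feed − c) and −D·X.

## Growth coupling

Growth is not a stoichiometric biomass reaction but an energetic coupling:
μ = k_ATP · v_ATP, where v_ATP sums substrate-level phosphorylation,
oxidative phosphorylation (OP = P/O × respiration rate) and the ATP costs
of uptake and gluconeogenic reactions. At high substrate concentrations
acetate accumulates and growth is inhibited non-competitively,
μ = k_ATP·v_ATP·k_ACE/(k_ACE + [ACE]); the plain linear coupling is
recovered at zero acetate. k_ATP (0.0105 gDCW/mmol, a Y_ATP-type constant
chosen so the aerobic wild type on glucose grows at ≈0.65 h⁻¹) and k_ACE
(5 g/l, the concentration range where acetate inhibition of growth is
reported to become serious) are calibration constants, flagged `fallback`
in the parameter set.

Carbon is closed by growth-proportional precursor drains (G6P, F6P, R5P,
E4P, GAP, PEP, PYR, AcCoA, OAA, αKG) with standard *E. coli* biomass
demands (mmol/gDCW), plus anabolic ATP and NADPH (k_Anabolism = 14.849
mmol/gDCW) demands. Each drain is saturable in its pool
(c/(c + 0.05 mM)) so that an exhausted precursor throttles its demand
instead of driving the pool negative — a numerical guard that only acts
near empty pools.

## Regulation

**PTS phosphorelay and CCR.** The phosphorylated-EIIA fraction is a
quasi-steady-state, saturating function of the PEP/PYR ratio; glucose
transport keeps the ratio low (EIIA unphosphorylated), which (i) excludes
xylose via the (1 + [EIIA]/K_I) term of the transporter rate law and (ii)
keeps cAMP-Crp inactive. The ratio is regularized as
(PEP + 0.01)/(PYR + 0.01) so a starving cell with empty pools reads as
"hungry" (phosphorylated EIIA, high cAMP-Crp) rather than as
glucose-replete — the physiologically correct limit.

**Transcription factors.** cAMP-Crp follows the EIIA-P fraction (Hill),
Cra is repressed by FBP, XylR is induced by intracellular xylose, and ArcA
follows the NADH/NAD redox ratio aerobically and is pinned near 1
anaerobically. Genotype overrides (e.g. ArcA overexpression at activity
0.95) take precedence exactly and are constant across states.

**f(TF) normalization.** Regulated capacities are v'max · f(TF) with
linear edges. Repression edges are normalized to the wild-type reference
activity (f(ref) = 1, f(1) = c0), so a fully active repressor leaves the
basal fraction c0 and full derepression slightly exceeds the reference
capacity. Activation edges are normalized to full induction (f(1) = 1,
f(0) = c0): for genes that are essentially off in the glucose-grown wild
type (the xylose operons), normalizing to the near-zero reference activity
would make v'max the *repressed* capacity and inflate induced rates far
above it, so v'max is defined as the fully induced capacity instead. Multiple
regulators multiply.

The regulation map contains the edges with direct mechanistic support:
cAMP-Crp and XylR activate XT/XylA/XylB, cAMP-Crp activates non-PTS
glucose transport and Acs, Cra represses *pykF* and the OPP genes
(*zwf*, *gnd* — this is what lets xylose-driven FBP accumulation, via
lower Cra, raise the OPP flux in the Δ*pgi* mutant), ArcA represses the
TCA-cycle genes and the respiratory chain and activates *pfl*.

## Rate laws and numerical choices

Irreversible reactions use Michaelis–Menten forms with documented
effectors; reversible steps (Pgi, the non-oxidative PP interconversions)
use net reversible forms and may carry negative flux; all rate laws clamp
negative concentrations to zero. Beyond the canonical effectors, a small
set of feedbacks proved necessary to keep every culture condition inside a
physical basin (without them, transients can lock the cell into absorbing
states with a full cofactor pool and empty substrate pools):

- G6P product inhibition of the lumped non-PTS-uptake/glucokinase step and
  of the PTS (the latter standing in for *ptsG*-mRNA destabilization) —
  this is also what produces the G6P-accumulation growth defect of the
  Δ*pgi* mutant on glucose;
- OAA feedback on Ppc, which otherwise accumulates OAA without bound;
- NADH inhibition of GAPDH (inside L_Emp) and PDH, which lets anaerobic
  glycolysis balance against the fermentative NAD-regenerating sinks
  (LDH, ADH with cooperative NADH dependence) instead of overshooting;
- a soluble transhydrogenase (UdhA, NADPH→NADH) and a small, steep
  high-NADH relief valve (`NOX`, lumping non-respiratory NADH turnover)
  that make the "NADPH pool full" and "NADH pool full" states leaky;
- CoA-pool product inhibition within the mevalonate cascade (AcAcCoA on
  AtoB, HMG-CoA on HMGS) and a two-NADPH cooperative HMGR, so mevalonate
  flux genuinely reflects NADPH availability rather than an unbounded
  HMG-CoA buffer.

The xylose ABC transporter carries an ATP dependence (K = 0.1 mM,
saturated at any physiological ATP level) so import stops when the cell is
energy-exhausted; the canonical inducer-exclusion form is recovered
exactly in the ATP-saturated regime used by the rate-law limit tests.

Integration uses deSolve's stiff lsoda family (lsodar in batch mode, with
a terminal root when both sugars fall below the 0.01 g/l depletion
threshold), rtol 1e-8 / atol 1e-10 by default. The right-hand side exists
twice: a reference R implementation and a compiled C mirror (~100× faster)
that the simulators use by default; the test suite asserts their
equivalence, and `compute_fluxes()` is additionally checked against an
independent re-evaluation of every rate law.

## Batch, chemostat, and the design workflow

`simulate_batch()` integrates to depletion or horizon and records dense
states, fluxes, TF activities and growth rate; `cultivation_time()` is the
first time both sugars are below threshold. `simulate_chemostat()`
integrates to steady state, verifies |μ − D|/D < 1e-3, and reports washout
as an outcome rather than an error. NADPH accounting integrates
v_NADPH·X by trapezoid on the dense grid (the default 400–600 output
points keep the quadrature error well below 0.1%, verified as a property);
productivity is (total − anabolic demand)/T and is deliberately not
clamped: negative values mean growth demand exceeded production and would
have to be covered by transhydrogenase.

`xylose_scan()` sweeps the xylose content c (percent of a fixed total
substrate), running one batch per grid point with glucose (1−c/100)·total
and xylose (c/100)·total. The default grid is 0–100% in 1% steps with ties
broken toward the lower content; exponential-phase rates are read at the
time of maximum μ (after a 2% burn-in of the horizon, to skip the
adaptation transient of the initial pools). Initial biomass defaults to
0.01 gDCW/l — the source conditions do not state one; this value gives
realistic 6–12 h wild-type batches, and the scan optima are insensitive to
halving/doubling it (a tested property).

## What the defaults reproduce — and what they do not

The full literature parameterization of this model family is not
transcribable here, so all kinetic constants except k_Anabolism are
calibrated fallbacks (`provenance()` marks each entry). Under the default
set the model reproduces the established qualitative structure: wild-type
diauxie on 5 + 5 g/l (<2% of xylose consumed before glucose depletion);
co-consumption in Δ*pgi* and Δ*ptsG*; a Δ*pgi* growth defect on glucose of
≈82% relative to wild type, largely rescued by xylose; OPP-dominated NADPH
production in Δ*pgi* versus ICDH-dominated in Δ*ptsG*; an interior NADPH
productivity optimum for Δ*pgi* near 13–16% xylose content at 10 g/l total
substrate; wild-type NADPH availability negative and decreasing at high
xylose content; chemostat steady states with μ = D across 0.1–0.5 h⁻¹;
and, for the mevalonate designs, reduced acetate overflow, interior
content optima and a clear titer gain from pinning ArcA at 0.95 in the
Δ*pgi* background.

Quantitative magnitudes — peak productivity values, the exact mevalonate
optima and the size of the ArcA improvement — depend on the original
kinetic constants and should not be read as predictions of this fallback
calibration. Further known simplifications: GAP/DHAP, CIT/ICIT and the
Pta–Ack pair are lumped; anaerobic growth is slower than observed because
xylose-uptake energetics and anaerobic respiration (nitrate/fumarate) are
not resolved; FNR regulation is replaced by a scenario flag that zeroes
the electron-acceptor capacity and raises ArcA; and the `NOX`/UdhA relief
reactions, while small, are phenomenological. The synthetic measured-flux
fixture used to exercise the correlation utility is simulation-derived
noise, not experimental data, and is labelled synthetic accordingly.
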