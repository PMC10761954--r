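---
title: "Modeling amine-racemase behavior of transaminases with racekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling amine-racemase behavior of transaminases with racekin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(racekin)
```

## The model

Amine transaminases (ATAs) carry an amino group between an amine donor
and a ketone acceptor by shuttling between two cofactor states: E-PLP
(the internal aldimine with pyridoxal 5'-phosphate) and E-PMP (the
pyridoxamine form). `racekin` decomposes any such reaction mixture into
*elemental reactions*: one amine enantiomer interconverting with its
cognate ketone,

* oxidative deamination (OD): amine + E-PLP → ketone + E-PMP, with rate
  $v_\mathrm{OD} = k_\mathrm{OD}\,[\mathrm{D}]\,[\text{E-PLP}]$,
* reductive amination (RA): ketone + E-PMP → amine + E-PLP, with rate
  $v_\mathrm{RA} = k_\mathrm{RA}\,[\mathrm{A}]\,[\text{E-PMP}]$.

Both steps are approximated as second order — no Michaelis–Menten or
ping-pong bi-bi saturation terms, no substrate or product inhibition.
That approximation is the central modeling assumption: it holds when
substrates stay below their $K_M$ values, it makes every rate constant a
single number ($\mathrm{mM^{-1}\,h^{-1}}$), and it lets the equilibrium
constant of an elemental reaction be read off directly as
$K_\mathrm{eq} = k_\mathrm{OD}/k_\mathrm{RA}$ (detailed balance:
$v_\mathrm{OD} = v_\mathrm{RA}$ at equilibrium).

Imperfect stereoselectivity is expressed *kinetically*: a compound's S-
and R-amine each get their own elemental reaction, and the enantiomeric
ratio $E^S = k^S/k^R$ (same direction, two enantiomers) quantifies the
enzyme's stereocontrol. Strict selectivity is an explicit $k = 0$, never
a missing reaction, so the same network topology describes wild-type and
engineered enzymes. Two enantiomer-specific reactions sharing one ketone
form a *futile cycle* whose only net chemistry is a change of chiral
composition: its coupled equilibrium constant is
$K_{\mathrm{eq},S}/K_{\mathrm{eq},R}$, and because chemical equilibrium
cannot depend on chirality this ratio is 1, so the cycle racemizes the
amine pool completely — regardless of how large $E^S$ is. $E^S$ only
sets the speed. That is the mechanism by which a stereoselective
transaminase can act as an amine racemase.

The state vector stacks every chemical species plus the two enzyme
states. Three linear invariants hold exactly in the model and are
asserted (to $10^{-6}$ mM) on every simulated trajectory:

1. each compound's skeleton total $[S] + [R] + [\mathrm{ketone}]$,
2. the enzyme total $[\text{E-PLP}] + [\text{E-PMP}]$,
3. the amino-group balance $\sum[\text{amines}] + [\text{E-PMP}]$.

## Units, integration and numerical choices

Internal units are fixed at mM and hours; `read_system_config()`
converts declared µM/minute inputs on load (rate constants scale by
$1/(\text{conc} \times \text{time})$). Integration uses deSolve's
`lsoda` with `rtol` $10^{-8}$ and `atol` $10^{-10}$ — tolerances chosen
so that conservation drift stays well under the $10^{-6}$ mM assertion
over hundreds of simulated hours. A deliberately simple fixed-step RK4
integrator (`rk4_integrate()`, default $dt = 10^{-3}$ h) ships as the
independent cross-check; the test suite requires the two to agree to a
relative $10^{-4}$ on three-reaction systems.

Two degenerate-input rules: `enzyme_total` must be positive to simulate
(a zero-enzyme state vector is still accepted by `derivatives()`, which
then returns all zeros), and the enantiomeric excess
$ee = 100\,(S-R)/(S+R)$ is an error — not 0 — when both enantiomers are
absent, since that means "no analyte", not "racemic".

The initial cofactor state is a free parameter
(`initial_E_PLP_fraction`, default 1). Assay protocols typically
pre-form the E-PLP holoenzyme, and the default encodes that; the
fraction is exposed because mixtures equilibrate within minutes and the
choice is invisible at the hour scale of racemization experiments.

## Event detection

Two observables summarize a stereoinversion experiment:

* **Onset** (`detect_stereoinversion_onset()`): the first strict maximum
  of a species' concentration after $t = 0$ — located as a sign change
  of its *analytic* time derivative (evaluated from the state, not by
  finite differences) on the output grid, then refined by bisection with
  short re-integrations to ±0.001 h, an order tighter than the ±0.01 h
  the detectors promise. The equivalent net-rate detector
  (`detect_net_rate_sign_change()`) finds the sign change of
  $v = v_\mathrm{OD} - v_\mathrm{RA}$ of a chosen reaction; for the
  product-forming reaction of a futile cycle the two coincide, and both
  are exposed because either reading is defensible.
* **Completion** (`detect_racemization_completion()`): the first time
  $|ee|$ falls below a threshold (default 1%) *and stays below it to the
  end of the trajectory* — the stay-below clause guards against
  transient crossings. Refined the same way.

`equilibrium_state()` integrates with a root-stopping rule
($\max_i |\dot y_i| < 10^{-9}$ mM/h, `lsodar`) and reports the
detailed-balance residuals $v_\mathrm{OD} - v_\mathrm{RA}$ per reaction
as a cross-check; tests also verify it against an algebraic
(conservation-reduced root-finding) oracle on single-reaction systems.

## The selectivity scan

`selectivity_scan()` asks: how fast can an enzyme with enantiomeric
ratio $E$ racemize? It scales *both* constants of the disfavored
enantiomer, $k^R_\mathrm{OD} = k^S_\mathrm{OD}/E$ and
$k^R_\mathrm{RA} = k^S_\mathrm{RA}/E$ — scaling only one would change
$K_{\mathrm{eq},R}$ and violate chirality-independence of the chemical
equilibrium. Completion time is non-decreasing in $E$; at $E = 1$ the
S-start and R-start $|ee|$ trajectories coincide pointwise (the enzyme
cannot tell the enantiomers apart); at very large $E$ the cycle is a
kinetic trap and completion never arrives. A related asymmetry holds at
fixed $E$: whichever inversion direction is limited by the smallest rate
constant on its path is slower, which is why racemizing the *favored*
enantiomer can take longer than racemizing the disfavored one.

## Rate-constant estimation

`initial_rate()` implements the standard initial-rate protocol: an
ordinary least-squares line (with intercept — tolerating a baseline
offset in HPLC-derived product series) through the points below a 20%
conversion cutoff, requiring at least three admissible points. The
constant follows as $k = v_i/([E][S_0])$ per replicate
(`second_order_constant()`), aggregated as mean ± sample standard
deviation over replicates (three replicates recommended).
`stereochemistry_table()` assembles per-reaction $K_\mathrm{eq}$ and
per-compound $E^S$ for both directions, flagging strict selectivity
($k^R = 0$) as `Inf` with a `strict` marker instead of dividing by zero.

The pseudo-one-substrate limiting conditions (substrate below $K_M$,
cosubstrate above) that justify $k \approx v_i/([E][S])$ in a saturating
world are not representable in a strictly second-order model; they are
carried as assay metadata (`cosubstrate`), not enforced.

One caveat is quantified in the tests rather than hidden: with three
replicates, the interval *mean ± 3·(sample sd)* has an exact coverage
ceiling of $P(|t_2| \le 3\sqrt{3}) \approx 96.5\%$ for the true
constant, and the ~1% curvature bias of a secant slope through an
exponential progress curve (sampled to ~2% conversion by the default
generator schedule) lowers the observed coverage to roughly 94%. Error
bars from triplicates are honest about scatter but their tails are
t-distributed, not Gaussian.

## NAT geometry for docking-pose triage

Whether a docked amine can actually react is decided by the geometry of
the nucleophilic attack trajectory (NAT) of its nitrogen onto C4' of the
internal aldimine, measured from six atoms (substrate Nα and Hα,
cofactor C4' and C4, Schiff-base nitrogen, catalytic-lysine Nε):

| metric | definition | optimum / default gate |
|---|---|---|
| `d_NAT` | distance Nα–C4' | ≤ 3.5 Å (reactive poses sit near 3.0–3.1 Å) |
| `theta_BD` | angle Nα–C4'–N_sb | 105° ± 30° (Bürgi–Dunitz) |
| `theta_DH` | torsion magnitude Nα–C4'–N_sb–C4 | 90° ± 30° |
| `d_Halpha_Neps` | distance Hα–Nε | ≤ 4.5 Å |
| `halpha_same_face` | Hα and Nε on the same side of the Nα/C4'/N_sb plane | required |

The Bürgi–Dunitz angle is computed against the C4'=N_sb imine bond (the
canonical construction for attack on an sp² center); the dihedral
quadruple is configurable through the atom map because conventions for
the fourth atom differ between studies. The face test is the decisive
criterion: after attack, the lysine's ε-amino group must abstract Hα
(the rate-determining proton transfer), so a pose whose α-proton points
away from Nε is non-productive no matter how good its angles are — this
is exactly how mirror-image substrates with near-identical NAT lengths
and plausible angles are rejected. Numeric thresholds are explicit,
configurable stand-ins calibrated to exemplar productive
(3.1 Å, 91°, 78°, accessible Hα) and non-productive (3.1 Å, 79°, 70°,
opposite-face Hα) poses; classification is monotone (tightening a gate
never flips a pose to productive). All metrics are invariant under
rigid-body motion to $10^{-9}$, and dihedrals are reported as magnitudes
in [0°, 180°].

## Synthetic data: what it emulates, what it does not

Every input the package consumes can be generated in code, seeded and
reproducible:

* `generate_timecourse()` — simulator truth at chiral-HPLC-like sampling
  times (default 0.5, 1, 2, 3, 6, 12, 24 h) with multiplicative Gaussian
  noise (default cv 3%) and a 0.01 mM detection floor. This emulates
  peak-area scatter only: no retention-time drift, no co-elution, no
  calibration bias. The enzyme states are excluded — HPLC cannot see
  them.
* `generate_initial_rate_dataset()` — replicate progress points from the
  closed form $P(t) = S_0(1 - e^{-kEt})$ (enzyme held constant by
  cosubstrate recycling, as in the real assay), sampled to ~2%
  conversion so the regression slope carries at most ~1% curvature bias;
  replicate noise streams derive deterministically from the master seed.
* `impure_stock()` — splits a total into enantiomers at a prescribed
  signed ee, for modeling commercial stocks that are not enantiopure
  (e.g. a 99.1% ee R-stock is 0.225 mM S in 50 mM). Simulating strictly
  selective OD of such a stock plateaus the ketone exactly at the
  impurity concentration — a useful sanity check that the "impurity
  burn-off" signature is reproduced.
* `generate_pose()` — six-atom PDB fixtures built by internal-coordinate
  (NeRF) placement so the measured metrics equal the prescription
  exactly; the seed only randomizes the rigid-body frame. PDB
  quantization (0.001 Å) limits file round-trips to ~2×10⁻³ Å on
  distances and ~0.1° on angles.

Passing tests on these generators therefore demonstrate correctness of
the kinetic and geometric machinery under the stated error model — they
do not certify behavior under real HPLC artifacts, saturation kinetics,
or real docking ensembles.

## Problem sizes used in the shipped tests

The test suite runs three- and two-reaction systems (seven and five
state variables), horizons up to 4000 h for slow futile cycles (the
adaptive solver makes these cheap), fixed-step RK4 cross-checks at
$dt = 10^{-3}$ h over 6–30 h windows, a 1000-repeat Monte-Carlo for
estimator coverage, and 400 seeds for the noise-level check. These sizes
keep the full suite in the low minutes while leaving the oracle
comparisons statistically meaningful.

## Known limitations

* Strictly second-order kinetics: no saturation, no inhibition, no
  cofactor dissociation or apoenzyme states; constants are inputs, never
  predicted from structure.
* The onset/completion detectors assume a single turnover event;
  oscillatory chemistry (not possible in this network class) would
  confuse the "first maximum" reading.
* Docking poses are consumed, never produced; no energetics, protonation
  or mutant model building.
* The dihedral convention must match whatever produced reference values
  before comparing numbers across studies.
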