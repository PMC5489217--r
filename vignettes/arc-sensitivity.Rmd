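---
title: "Redox sensitivity analysis of a core metabolic model, from phase planes to batch cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Redox sensitivity analysis of a core metabolic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcfba)
```

## The question the package answers

Xylose-fermenting yeasts such as *Scheffersomyces stipitis* only make
ethanol in a narrow window of oxygen supply: too much oxygen and all
carbon is respired, too little and both growth and fermentation stall.
A useful way to reason about this window is through the redox couple
NAD(H/+).  Xylose assimilation through the NADPH-consuming xylose
reductase and the NADH-producing xylitol dehydrogenase leaves the
cytosol with a net NADH surplus, and whether that surplus is an asset
or a burden for ethanol production depends on the metabolic state.

`arcfba` quantifies this with shadow prices.  For a flux balance
analysis (FBA) problem — maximise an objective flux $Z$ subject to the
steady state $S\,v = 0$ and flux bounds — every metabolite $i$ carries
a dual value

$$\lambda_i^Z \;=\; -\,\frac{\partial Z}{\partial b_i^r},$$

the response of the optimal objective to a relaxation of metabolite
$i$'s mass balance (an increase in its availability).  $\lambda_i < 0$
means the metabolite is limiting, $\lambda_i > 0$ in excess,
$\lambda_i = 0$ without effect.  The sensitivity to the *available
reducing capacity* (ARC) of the redox pair is the net effect of adding
NADH while removing NAD+:

$$\lambda_{ARC}^Z \;=\; \lambda_{NADH}^Z - \lambda_{NAD}^Z.$$

The identity is exact arithmetic on stored duals;
`arc_sensitivity_fd()` validates it independently by re-solving the LP
with a joint NADH-source/NAD-sink perturbation.

## The LP engine and its validation

The FBA problems here are dense and small (tens of rows), so the
package carries its own bounded-variable two-phase simplex with dual
extraction (`solve_fba()`).  Two properties are enforced by tests
rather than assumed: (i) optimality certificates — on every solve the
bounded-LP dual objective reproduces the primal objective to $10^{-6}$;
(ii) dual correctness — `dual_sensitivity_fd()` compares each
$\lambda_i$ against two-sided finite differences of the re-solved
optimum.  Metabolites whose left and right derivatives differ sit at
degenerate vertices where the dual is a set, not a point; they are
flagged as such and reported, never silently passed.  Pivoting rules
and variable order are fixed, so repeated solves are bit-identical.

Thermodynamically infeasible internal cycles are removed by
post-processing (`enforce_loopless()`): holding every exchange flux and
the objective at their solved values, the total absolute internal flux
is minimised subject to each internal reaction keeping its sign.  At
the minimum no sign-consistent internal cycle can remain, because
subtracting it would stay feasible and reduce the total.  We chose this
over a mixed-integer loop-law formulation deliberately: on networks of
this size the post-processing is exact for the quantities the analysis
consumes (objective, exchanges, cycle-free fluxes), it needs no integer
solver, and duals are taken from the plain LP — duals of a
mixed-integer program would be undefined anyway.

## The synthetic core network

`make_core_network()` builds a ~34-reaction lumped model rather than a
genome-scale one: the analysis probes redox and respiratory topology,
not pathway completeness, and at this size every optimum can be checked
by hand.  The lumps preserve exactly the features under study:

* **Xylose assimilation** (XR/XDH/XK): XR consumes NADPH by default,
  XDH produces cytosolic NADH — one xylose yields 8/3 cytosolic NADH
  before cofactor regeneration and 5/3 net ATP, the redox asymmetry
  that widens the ARC-limited region on xylose.  The `xr_cofactor`
  option switches XR to NADH, removing the imbalance.
* **NADPH supply**: on xylose via an ATP-coupled NADH kinase; on
  glucose via an oxidative pentose-phosphate lump whose pentose
  product re-enters glycolysis.  This difference is physiological and
  is what makes the ARC-limited region larger on xylose than on
  glucose per scanned grid cell.
* **Fermentation** (PDC/ADH) reoxidises cytosolic NADH at a carbon
  cost; a **glycerol shunt** provides the overflow NADH sink that
  yeasts actually use, at carbon plus ATP cost.
* **Respiration**: a lumped TCA produces matrix NADH; CINADH (complex
  I) is the only NADH-to-quinone entry and pumps; COX pumps, AOX does
  not.  Default P/O ratios are 1.5 through CINADH+COX and 0.5 through
  CINADH+AOX (`p_o_ratio_*` options).
* **The redox shuttle** moving cytosolic NADH into the matrix is
  irreversible and electrogenic (`shuttle_pmf_cost`, default 0.5
  charge per NADH), as the physiological carriers are.  This cost is
  load-bearing: with a free reversible shuttle, spare pyruvate can be
  swapped between TCA and fermentation at no cost and the marginal
  value of a reducing equivalent collapses to zero at every
  oxygen-limited state, erasing the sign structure the analysis is
  about.
* **Biomass** consumes 40/3 pyruvate (40 mmol C), 60 ATP and 8 NADPH
  per gram dry weight; every metabolite carries a declared carbon
  count and `carbon_balance()` verifies each lumped reaction closes.

With these defaults the fully aerobic optimum has a closed form (the
test suite derives it by hand): $\mu = (37/3)/156 \approx 0.0791$ per
mmol xylose, with an oxygen demand of $1.742$ mmol per mmol xylose —
the slope of the biomass line of optimality.  At zero oxygen, growth
collapses to about a tenth of the aerobic rate (the NADPH demand must
then be paid through the NADH kinase out of fermentative ATP),
mirroring the near-arrest of anaerobic growth on xylose, while ethanol
remains bounded by the carbon left after redox bookkeeping.

## Phase planes and the bi-level ethanol sensitivity

`compute_phpp()` scans a grid of carbon and oxygen uptake bounds
(defaults 41 points over 0–20 and 0–25 mmol gDW$^{-1}$ h$^{-1}$; the
checks in this package use 21&times;21 and 11&times;11 versions of the same
ranges).  At each point it solves biomass-maximising FBA, then a second
LP maximising the ethanol exchange with the biomass flux pinned at its
step-1 optimum — the bi-level procedure that gives each grid point both
an attainable ethanol productivity and the ARC sensitivity of ethanol
production at a state with biological sense.

Two numerical choices matter here:

* **The pin keeps a sliver of slack** ($10^{-9}$ relative by default,
  widened stepwise to $10^{-4}$ only if the solver reports
  infeasibility).  Pinning the biomass flux exactly (equal bounds)
  makes the step-2 feasible set lower-dimensional and collapses much of
  its dual information; the slack formulation keeps the duals equal to
  the state's marginal values.  The slack buys a spurious ethanol
  sliver of order $10^{-9} q_c$, far below every threshold used.
* **Phase detection** uses quantised shadow-price signatures of the two
  scanned substrates (duals rounded at $10^{-6}$), flood-filled over
  grid neighbours — phases are regions of constant marginal behaviour,
  and duals measure exactly that.  Numerical gradients of $\mu$ serve
  as a test oracle (inside a detected phase the second difference of
  $\mu$ vanishes), not as the classifier, which would be fragile on
  coarse grids.

Lines of optimality are read per carbon column: the cheapest oxygen
achieving the maximal biomass yield (ties resolved toward smaller
oxygen — the "exact stoichiometric proportion" reading), and the oxygen
maximising ethanol yield.  On the toy network the biomass line is a ray
through the origin and the ethanol-yield line lies strictly below it.

Scanning any fixed-carbon row from the biomass line toward zero oxygen,
the ethanol ARC sensitivity passes through the orderings limiting
(&lt;0), optionally no-effect, then excess (&gt;0) — on this network the
middle band is essentially empty and the excess region appears at the
anaerobic edge, where the only remaining sink for a marginal reducing
equivalent is the glycerol shunt, whose carbon and ATP cost makes extra
NADH strictly harmful.

## Knockouts, partial inhibition, and one claim we cannot reproduce

Deleting both terminal oxidases (`knockout(net, c("COX", "AOX"))`)
kills the quinone cycle, so metabolism is fermentative at every grid
point and ethanol becomes growth-coupled: the grid points of maximal
growth are exactly the points of maximal ethanol productivity, and the
ARC index turns positive (reducing capacity in excess) — eliminating
respiration overshoots.

Partial inhibition (`inhibit()`) caps a reaction's flux magnitude at
$(1-f)$ times a reference flux, by default its flux in the uninhibited
optimum under the same uptakes, recomputed per grid or trajectory
point.  A bound cap is the minimal faithful model of an inhibitor when
no kinetic information is available.

One qualitative expectation does **not** reproduce under this
package's bi-level scheme, and we document it rather than engineer
around it: that with both terminal oxidases
inhibited by 80% the ethanol ARC sensitivity vanishes across the whole
plane.  Under the scheme implemented here (pin only the biomass flux),
a COX/AOX-capped state and an oxygen-limited uninhibited state are
economically isomorphic LPs — both are throughput caps on the same
respiratory funnel — so the marginal value of a reducing equivalent
must be the same in both, and it is strictly negative wherever the
uninhibited fermentative region shows ARC limitation.  The package
measures $\lambda_{ARC}^{etoh} = -1/7$ across the inhibited plane.  A
plane-wide zero does emerge under the alternative reading in which
*every* flux of the step-1 state is used as a constraint
(`fix_scope = "state"`): with the state pinned to a point the second
objective cannot respond to anything and all duals vanish — but then
they vanish for every scenario, including the uninhibited planes whose
three-region structure is plainly non-zero.  The two behaviours cannot
come from one constraint scheme; we implement the scheme that
reproduces the richer structure and expose the other as an option.

## The batch-culture model

`simulate_culture()` integrates

$$\frac{dx}{dt} = \mu x,\qquad \frac{dS}{dt} = -q_S x,\qquad
\frac{dP}{dt} = q_P x,\qquad
\frac{dC_L}{dt} = k_La\,(C^* - C_L) - q_{O_2} x$$

with Monod growth damped by a logistic lag factor,
$\mu = \mu_{max}\,S/(S+K_s)\, \cdot q_1/(q_1+e^{-v_1 t})$,
Luedeking–Piret production with its own lag,
$q_P = (\alpha \mu + \beta)\,q_2/(q_2+e^{-v_2 t})$, and the substrate
balance $q_S = \mu/Y_o + m + q_P/Y_P$.  Under oxygen limitation all
transferred oxygen is consumed, so $C_L$ is held at its quasi-steady
zero and $q_{O_2} = k_La\,C^*/x$; the full $C_L$ balance is available
for non-limited scenarios.  Two kinetic conventions are worth stating:
the growth expression includes $\mu_{max}$ (the delay factor multiplies
the Monod term, it does not replace its scale), and the growth-delay
parameter $q_1$ is fitted directly, with the derived ratio
$k = q_1/\mu_{max}$ reported afterwards.

Numerical choices: integration uses `deSolve`'s lsoda with a smooth
substrate-exhaustion gate $S/(S+10^{-3}\,\mathrm{g/L})$ on all
substrate-driven rates — a hard switch stalls the step-size controller
at depletion; the gate constant is 0.007% of the initial xylose, far
below observation noise.  Ethanol yield is capped at its theoretical
$Y_P = 0.511$ g/g, which is held fixed during fitting.

`fit_parameters()` minimises range-normalised least squares over the
ten free parameters ($\mu_{max}, K_s, Y_o, m, \alpha, \beta, q_1, q_2,
v_1, v_2$) with box-bounded Levenberg–Marquardt and seeded multi-start
(default 20 starts; the checks use 2–3).  Per-variable normalisation by
the observed range keeps the 15 g/L xylose curve from dominating the
4 g/L biomass and ethanol curves; no error model beyond additive noise
is assumed.  Individual parameters are only weakly identifiable
($\mu_{max}$ trades against the lag parameters early in the culture),
so the contract is trajectory recovery: noiseless data are refit to
below $10^{-3}$ of each signal's range, and across repeated noisy
synthetic cultures the median $\mu_{max}$ error stays under 10%.

### What the synthetic data do and do not emulate

`make_culture_dataset()` draws additive, independent Gaussian noise per
variable (defaults: 2% of the typical signal ranges at a 15 g/L xylose,
0.5 g/L inoculum culture over 48 h, the conditions of the oxygen-limited
fermentations at $k_La$ 15 and 25 h$^{-1}$ it stands in for), clipped
at zero, deterministic per seed.  Real fermentation data have
heteroscedastic, partly systematic errors (drift in turbidity
calibration, HPLC carry-over), replicate correlation, and irregular
sampling; none of that is modelled.  Passing the recovery checks
therefore shows the estimator is correct and well-conditioned under the
stated noise model — not that the model is identifiable on any given
real culture.

## Closing the loop: trajectories on the phase plane

`culture_rate_points()` converts the fitted mass-specific rates to
mmol gDW$^{-1}$ h$^{-1}$ (molar masses 150.13, 32.00, 46.07 g/mol) and
the trajectory is coupled to the network quasi-statically: each time
point bounds an independent steady-state FBA, exactly the "successive
metabolic states" construction — no dynamic feedback of biomass on the
bounds.  Early in the culture the per-cell oxygen supply
$k_La C^*/x$ is high (few cells share the transfer), so trajectories
start on the aerobic side of the biomass line and cross into the
fermentative region as biomass accumulates.

`sensitivity_trajectory()` records, per point, the single-level
biomass ARC sensitivity and the bi-level ethanol ARC sensitivity, with
an optional complex I cap from a start time onward (the rotenone
simulation; default fraction 0.8 of the per-point uninhibited flux).
The reproduced signature: before inhibition the biomass sensitivity is
negative (a marginal reducing equivalent buys respiratory ATP and
spares carbon), after the cap it turns positive (the equivalent can no
longer reach the chain and its disposal costs carbon and ATP), while
the ethanol sensitivity stays negative throughout — the state in which
inhibiting complex I favours ethanol at the expense of growth.
`inhibition_flux_report()` contrasts the matched flux-carrying sets at
a representative point (default: maximal observed specific ethanol
productivity), and ranks complex I among the largest flux reductions
with glycolytic/fermentative lumps among the increases.  (In this
lumped network the ATP synthase shift tracks the chain shift closely —
there is no alternative ATP source to compensate, as a genome-scale
model would have — so complex I need not sit strictly first.)

## Sizes, tolerances, defaults

| Quantity | Default | Note |
|---|---|---|
| LP feasibility / optimality tolerance | $10^{-9}$ | dense simplex, exact refactorisation each pivot |
| duality-gap check in tests | $10^{-6}$ | primal vs bounded-dual objective |
| flux-carrying threshold | $10^{-6}$ mmol gDW$^{-1}$ h$^{-1}$ | `flux_carrying_set()`, `compare_fcs()` |
| ARC zero band | $10^{-6}$ | classification only, configurable |
| biomass pin slack | $10^{-9}$ relative | ladder $10^{-6}$, $10^{-4}$ on infeasibility |
| phase-signature quantum | $10^{-6}$ | dual rounding for phase detection |
| default grid | 41&times;41 over 0–20 &times; 0–25 | checks use 21&times;21 and 11&times;11 |
| ODE tolerances | rtol $10^{-8}$, atol $10^{-10}$ | $10^{-6}/10^{-8}$ inside the fitter |
| multi-start fits | 20 starts | 2–3 in the packaged checks |

## Known limitations

* The core network is a caricature by design: no polyol branches, no
  acetate or xylitol secretion, no gene–protein–reaction rules, lumped
  glycolysis/TCA.  Quantities tied to a genome-scale reconstruction
  (absolute flux-shift magnitudes, absolute growth-rate readings along
  culture trajectories) are out of reach and out of scope.
* Duals at degenerate vertices are basis-dependent.  The engine is
  deterministic, so results are reproducible, but a different pivot
  order could legitimately report a different member of the dual set at
  such points; the finite-difference helpers flag exactly where this
  matters.
* The trajectory coupling is quasi-static; cultures with fast
  transients relative to metabolic relaxation would need dynamic FBA,
  which this package intentionally does not implement.
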