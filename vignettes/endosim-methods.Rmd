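---
title: "Methods: a stochastic lattice model of postsynaptic receptor trafficking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a stochastic lattice model of postsynaptic receptor trafficking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`endosim` simulates the constitutive recycling of AMPA-type glutamate
receptors (AMPARs) at a single postsynapse and the disruption of that
recycling during cerebellar long-term depression (LTD). Two compartments
are represented as 50 x 50 lattices of homogeneous sites:

* the **surface** membrane, holding the mobile postsynaptic receptor
  pool `S_m` (an immobile pool `S_im = 40` is added when the
  postsynaptic count is read out), and
* the **early endosome** (EE), whose Rab5-positive sites constitute the
  vacuolar, sorting-competent subcompartment.

Receptors diffuse on both lattices as independent random walkers
(per-direction hop probability `d*dt/dx^2`; `d = 0.05 um^2/s`,
`dx = 0.2 um`, `dt = 0.1 s`). Every surface site nucleates a
clathrin-coated pit with rate `k_endo(t) = k0 + k_ep(t)` (basal
`k0 = 1.2 /min`); a pit matures for `tau_pit ~ U(1, 2) s` and then
internalizes whatever occupies its site — *including nothing*: empty
vesicles traffic and still recruit Rab5. Endocytic vesicles reach the EE
after `tau_endo ~ N(4, 1) min`, fuse at a uniformly random EE site, and
recruit one Rab5 molecule there if the site has none. Rab5-free EE
sites bud with rate `k_exo = 1 /min` (lag `tau_bud ~ U(1.5, 2.5) s`) and
their cargo returns to a random surface site after
`tau_exo ~ N(2, 0.5) min`. Gaussian delays are truncated below at one
time step. The system is closed except for the late-endosome (LE) sink.

Rab5 residence is state dependent:

    tau_Rab5(D) = K * D * (C - D) / (1 + exp(-(D - a) / b))

with `D` the fraction of Rab5-positive EE sites, `a = 0.2`, `b = 0.02`,
`C = 1.1`, `K = 20`. The numerator is autocatalysis with a limiting
factor; the steep sigmoid suppresses lifetimes below the ignition point
`a`. A lifetime is evaluated at the moment of recruitment (at the
pre-placement `D`) and frozen.

Sorting uses a soft threshold: a per-trial reference
`h ~ N(0.4, 0.02)` (truncated to (0, 1)), the first crossing time
`t_exc` of `D >= h`, the cumulative time `T_above` spent at or above `h`
after `t_exc` (time below `h` is excluded), and

    p_sort = 0                       before the crossing
    p_sort = 1 - exp(-T_above/tau_s) after it,  tau_s = 0.38 min.

One uniform draw per 0.1-s step triggers the event; all receptors then
co-resident with Rab5 move to the LE tally, every Rab5 is cleared, and
at most one sorting event occurs per trial. Because `p_sort` grows on
the `tau_s` time scale, sorting follows within roughly a minute of a
sustained crossing; the variability of sorting times is therefore
dominated by the variability of `t_exc`.

## Why the Rab5 switch is a near-critical cascade

The steep sigmoid makes lifetimes effectively zero below the ignition
point: at `D = 0.05`, `tau_Rab5 ~ 6e-4` time units. Whatever unit `K`
carries, a freshly recruited Rab5 below `D ~ 0.066` survives only the
step it is placed in. Meanwhile the one-pit-per-site rule caps the
endocytic arrival flux at `L^2 / mean(tau_pit) ~ 1667 vesicles/s`
(about 167 per step). The highest Rab5 fraction sustainable by
single-step survivors is therefore `~167/2500 ~ 0.067` — right at the
point where lifetimes start exceeding one step. Ignition of the
autocatalytic loop is consequently a *knife-edge cascade*: it requires
stimulated endocytosis rates close to the saturation flux (plateau
amplitudes of order `2e3 /min` with the default calibration), and the
waiting time for the fluctuation that tips the lattice over the edge is
stochastic and minutes long. This mechanism is what makes sorting
probabilistic (not every repetition ignites before the stimulus wanes)
and what spreads sorting times over tens of minutes. It is also
consistent with the observation that Rab5 accumulation saturates: near
the cap, profiles of different amplitude deliver nearly the same flux,
which compresses differences in sorting occurrence between stimulus
shapes.

Once ignited, `D` runs up to near 1 within seconds and the high-Rab5
state is *marginally* self-sustained even at the basal rate
(`k0 * (1-D) * tau_Rab5(D) ~ D` around `D ~ 0.85`), so after sorting
clears the lattice the vacuolar state re-forms while the stimulus
remains near saturation and then decays slowly and stochastically back
toward the recycling state. During this period budding (allowed only
from Rab5-free sites) is throttled, the EE holds an enlarged receptor
pool, and the postsynaptic count settles at a depressed level. The
maintained depression therefore has two components: the receptors
removed to the LE at the sorting instant, and the slow-relaxing shift
of the recycling distribution toward the EE.

### The unit of `K`

The model states every other delay in minutes but leaves the unit of
`K` open. We examined both readings by simulation. With `K` in hours,
ignition is easy (amplitudes of a few `/min`) but the high-Rab5 state
becomes absolutely permanent at basal rates: every trial converges to
the same maximal depression (the entire mobile share of the
postsynaptic pool) with virtually no trial-to-trial variability —
inconsistent with partial, variable LTD maintenance and with recovery
after mild stimulation. With `K` in minutes the switch lives in the
near-critical regime described above, which reproduces probabilistic
occurrence, variable sorting times, and partial depression. The package
therefore evaluates `tau_Rab5` in minutes (`tau_rab5_unit = "min"`,
with `"hour"` retained as an option for exploration).

## Stimulus profiles

LTD-inducing stimulation is a piecewise pulse added to `k0`: a Gaussian
rise on `[0, t_peak - 3)` that meets the plateau continuously, a
6-minute plateau, and an exponential tail (decay constant 4 min). Peak
times for EP1..EP5 default to 5, 8.5, 12, 15.5 and 19 min — staggered,
earliest first, spanning early-to-late expression speeds. The rise
width defaults to `sigma = (t_peak - 3)/2` so the rise occupies its
support; note a Gaussian flank is convex more than one sigma from its
centre, so the rise is concave only over its final sigma. Amplitudes
are solved exactly (the pulse is linear in its amplitude) so that all
five profiles share one time integral; the mild profile EPm uses EP3's
timing with 25% of that integral, which keeps it far below the ignition
flux.

The common integral is the one deliberately calibrated constant
(`ep_target_integral`, default 25500 min^-1 x min). The model fixes the
profiles' integral equality but not its value; we chose the value by
scanning ensembles for the point where (i) every profile ignites in at
least ~2/3 of repetitions within the recording window and (ii) the
ensemble-mean maintained depression of the focused profiles falls in
the 20-35% range. No other constant was adjusted; in particular the
Table of model constants is used verbatim.

## Simulation protocol

A trial runs from t = -10 to +50 min in 0.1-s steps, with the stimulus
starting at t = 0 and records taken once per second. Phase order within
a step is fixed for reproducibility: Rab5 expiry; vesicle fusions
(endocytic, then exocytic); pit scission and bud release; nucleation
(pits, then buds); diffusion (surface, then EE); switch update and
sorting draw; recording. Rate-to-probability conversion uses the exact
Poisson form `1 - exp(-k dt)`. Both lattices are toroidal: the sites
are homogeneous and no boundary rule is given, and periodic boundaries
avoid edge artifacts. Receptors keep diffusing across pit and bud sites
during their lags; cargo is whatever occupies the site at the scission
or release instant. A bud whose site acquires Rab5 during its lag still
releases (the nucleation gate is Rab5-free; no abort rule is
specified). `N_syn` and `N_EE_Rab5` are normalized per trial by the
mean postsynaptic count over the 10-minute pre-stimulus baseline.

Initial compartment counts come from a stimulus-free equilibration:
from 150 surface / 100 EE receptors the basal dynamics run in 5-minute
windows until two successive windows agree, then a further 5-minute
average is rounded and used to seed all trials of an ensemble (per-trial
randomness enters through trial seeds derived from the ensemble base
seed by a counter scheme, so trials are order-independent). The
stationarity criterion uses an *absolute* scale — successive window
means within 2% of the total mobile census (250 receptors, i.e. 5
receptors) — because the stationary surface and EE compartments hold
only ~25-35 receptors whose 5-minute means fluctuate by 5-15%
indefinitely; a relative criterion on the compartment mean would never
be met. In-transit receptors are re-seeded as single-cargo vesicles
with arrival times spread over one mean transit time; the 10-minute
pre-stimulus window relaxes this approximation before anything is
measured against baseline.

The compiled engine batches per-site Bernoulli draws into binomial
draws and buckets the vesicle queue by arrival step; the pure-R
kernels implement the same semantics site by site. The two paths are
statistically equivalent (asserted by two-sample tests in the suite)
but not bit-identical; within one engine, a trial is a deterministic
function of (parameters, profile, seed). Receptor conservation is
audited at every recorded sample and any violation aborts the trial.

## What the generator emulates — and what it does not

The simulation *is* the study object here (there is no external data):
ensembles of trials play the role of repeated LTD inductions at a
single synapse. The generator reproduces fluctuating constitutive
recycling, stimulus-driven endocytic load, autocatalytic vacuole
formation, probabilistic sorting, and maintained depression. It does
not model the PKC-MAPK induction cascade (abstracted into the stimulus
profile), multi-synapse or multi-endosome arrangements, receptor
synthesis/degradation, or any molecular Rab7 species — conversion is
the sorting event itself. A green ensemble test therefore establishes
internal consistency with the stated mechanism at the stated
parameters, not a fit to electrophysiological recordings.

## Numerical choices and conventions

* Analysis windows are half-open `[t0, t1)`; a sorting time of exactly
  13 min falls in the intermediate (13-20 min) histogram window.
* The coefficient of variation uses the sample SD (n - 1).
* LTD amounts are computed on sorted trials only (LE sorting is
  required for maintenance); the amount is the baseline-window mean of
  `N_syn` minus the 40-50-min window mean.
* The low-variability comparison set shrinks each ensemble's sorted
  times toward its mean (`t' = m + s*(t - m)`, default `s = 0.1`),
  preserving per-ensemble means while collapsing variance.
* Gaussian delay draws are clamped below at one time step; the
  threshold `h` is redrawn until it falls in (0, 1).
* `tau_Rab5` evaluates at the pre-placement Rab5 fraction; vesicles
  fusing in the same step see one another sequentially.
* Whether an endocytic vesicle may fuse onto a site with a pending bud
  is unspecified; it is allowed (cargo merges, Rab5 recruited).

## Known limitations

* Because ignition requires near-saturating endocytosis, the surface
  pool is almost completely internalized during every LTD-inducing
  stimulus; the early (5-15 min) depression is therefore nearly
  identical across profiles and repetitions, and its coefficient of
  variation is small. Mechanisms that would differentiate early
  depression (sub-saturating amplitudes) cannot ignite the printed
  lifetime curve under the one-pit-per-site flux cap.
* The maintained depression of the late, dispersed profiles can exceed
  35% because their post-sorting vacuolar state has had less time to
  relax by the 40-50-min window; the focused profiles land inside the
  20-35% band. Relatedly, depression grows with peak lateness rather
  than with stimulus focus.
* The marginal stability of the basal high-Rab5 state makes maintained
  depression sensitive to the trap's stochastic relaxation; ensemble
  means are stable but individual trials vary substantially.
* With the default staggered peak times (5..19 min) the pooled
  sorting-time histogram leans toward the early (6-13 min) window:
  near-critical ignition fires a few minutes after each profile first
  approaches the saturation flux, which places the pooled mass slightly
  left of the intermediate window.
* Even the mild profile EPm transiently displaces most receptors
  through the EE at the calibrated stimulus scale; the redistribution
  tail (roughly an 8-minute e-fold) leaves the 40-50-min postsynaptic
  mean a few percent below baseline, slightly outside a 3-SE
  stationarity band, although the transient depression itself recovers
  and no EPm trial ever sorts.
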