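# endosim

Stochastic lattice simulation of postsynaptic AMPA receptor endosomal
trafficking and cerebellar long-term depression (LTD).

## The problem

A postsynapse keeps its AMPA-type glutamate receptor (AMPAR) count
remarkably stable even though every underlying trafficking process —
lateral diffusion, clathrin-mediated endocytosis, endosomal recycling,
exocytic reinsertion — fluctuates strongly. During cerebellar LTD the
same machinery must do something irreversible: commit part of the
early-endosomal (EE) receptor pool to the late endosome (LE) via the
Rab5-Rab7 conversion switch, at a time that varies widely between
inductions yet concentrates in an intermediate window. `endosim` is a
single-synapse stochastic model of this system for computational
neuroscientists who want to study how stability, variability and
reliable plasticity coexist.

## The model in brief

Two 50 x 50 lattices (surface, EE) exchange receptors through delayed
endocytic and exocytic vesicles:

* per-site pit nucleation at `k_endo(t) = k0 + k_ep(t)`, pit lag
  `U(1,2) s`, vesicle transit `N(4,1) min`; empty vesicles traffic too;
* every endocytic fusion recruits Rab5 with state-dependent lifetime
  `tau_Rab5(D) = K D (C - D) / (1 + exp(-(D - a)/b))` — autocatalytic
  accumulation with a limiting factor, evaluated at the current
  Rab5-positive site fraction `D` and frozen at recruitment;
* Rab5-free EE sites bud at `k_exo = 1/min` (lag `U(1.5,2.5) s`,
  return transit `N(2,0.5) min`);
* a soft sorting threshold: per-trial reference `h ~ N(0.4, 0.02)`;
  after `D` first reaches `h`, the sorting probability grows as
  `p_sort = 1 - exp(-T_above/tau_s)` with `T_above` the cumulative time
  at or above `h`; one uniform draw per 0.1-s step fires the EE-to-LE
  sorting event, which removes every receptor co-resident with Rab5.

Stimuli are endocytosis-rate pulses (Gaussian rise, 6-min plateau,
exponential tail). EP1..EP5 share one calibrated time integral with
staggered peaks (5..19 min) modelling different LTD expression speeds;
EPm is a mild stimulus at a quarter of that integral which never
ignites the switch.

## Worked example

```r
library(endosim)
p    <- default_parameters()
init <- equilibrate(p, seed = 7)
init
#> <endosim_init> surface 27, EE 34, endo transit 125, exo transit 64 (35 sim min)

tr <- run_trial(p, make_profile("EP3", p), seed = 43, init = init)
tr
#> <endosim_trial EP3 seed 43> baseline 67.3 receptors, t_sort 11.31 min, h 0.399
window_mean(tr, "N_syn", 40, 50)
#> [1] 0.6641933
```

The equilibrated basal state distributes the 250 mobile receptors over
surface (~27), EE (~34) and the two vesicle streams (~190, most of them
in the slow endocytic leg). In the EP3 trial the switch fired at ~11.3
minutes: the 40-50-min postsynaptic mean of 0.66 means a maintained
depression of ~34% of baseline. Ensemble statistics:

```r
ens <- run_ensemble(p, make_profile("EP3", p), n_reps = 100,
                    base_seed = 1, init = init)
sorting_occurrence(ens)   # fraction of trials whose switch fired
ltd_amounts(ens)$mean     # mean maintained depression, sorted trials
sorting_histogram(ens)    # early / intermediate / late sorting counts
```

## Package layout

* `R/parameters.R` — model constants, validation, JSON
  config round trip
* `R/state.R`, `R/trafficking.R`, `R/rab5.R` — state containers and
  pure-R reference kernels for every per-step process
* `src/engine.cpp` — compiled engine (binomial-batched events,
  bucketed vesicle queues) used for full trials
* `R/stimulus.R` — endocytosis profiles EP1..EP5 / EPm
* `R/simulator.R` — equilibration, trials, seeded ensembles
* `R/analysis.R` — windowed statistics, LTD amounts, occurrence,
  sorting-time histograms, low-variability control
* `vignettes/endosim-methods.Rmd` — model assumptions, numerical
  choices, calibration rationale, limitations
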