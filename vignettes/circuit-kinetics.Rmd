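---
title: "Kinetic modeling of biosensor strand-displacement circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modeling of biosensor strand-displacement circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandlogic)
```

## The system being modeled

A cell-free biosensor of this family couples three molecular layers in one
tube:

1. **Sensing.** An allosteric transcription factor (aTF: TetR, SmtB, TtgR)
   represses T7 transcription by binding an operator placed just downstream
   of the T7 promoter. The cognate ligand (aTc/tetracycline for TetR, zinc
   for SmtB) binds the aTF and releases the operator.
2. **Transcription.** Free template produces a short single-stranded RNA
   invader ("InvadeR") at a rate proportional to free template.
3. **Strand displacement (TMSD).** The invader displaces strands from DNA
   gates through short single-stranded toeholds. A *signal gate* is a
   fluorophore/quencher duplex whose displacement releases free fluorophore;
   *translator (OR) gates* convert one invader into another output strand;
   *AND gates* need two invaders in sequence; transcribed *RNA NOT gates*
   sequester an invader; unlabeled *threshold gates* consume invader before
   the reporter can see it.

`strandlogic` compiles declarative descriptions of such circuits into
mass-action reaction networks, integrates them, and layers readout, logic
evaluation, threshold design and parameter estimation on top.

## The kinetic model

All concentrations are uM, time is minutes, bimolecular rate constants are
uM^-1 min^-1 (templates are entered in nM and converted). For each circuit
the compiler emits:

* **TF--operator binding** `TF + template <-> template:TF` with
  `k_on_op`/`k_off_op`. A TF-bound template does not transcribe.
* **TF--ligand binding** as one lumped cooperative step
  `TF + s * ligand <-> TF:ligand_s` of mass-action order `s` (the ligand
  stoichiometry). Ligand-bound TF cannot bind the operator.
* **Transcription** `template -> template + transcript` at
  `k_tx * tx_efficiency_factor`, pseudo-first-order in free template. T7
  RNAP (nanograms per reaction) and NTPs (>10 mM) are in vast excess over
  nM templates during a 2 h run, so no resource depletion is modeled.
* **TMSD** at `toehold_rate(n) = k_tmsd_max * 10^(-decade_per_nt *
  max(0, n_sat - n))`: displacement gains about a decade per toehold
  nucleotide and saturates at `n_sat` (default 6 nt). Engineered mismatches
  multiply a path's rate by `mismatch_penalty`; inhibitory secondary
  structure of a transcript multiplies all of its displacement rates by its
  `structure_penalty` (transcription efficiency and invader structure are
  deliberately separate knobs: the first scales production, the second
  scales TMSD speed).
* **AND gates** expand to a *reversible* toehold-exchange capture of the
  first invader (`k_rev_toehold_exchange` backward), an irreversible
  output release by the second invader at the saturated rate, and a leak
  `invader1 + gate -> output` at
  `clamp_leak0 * 10^(-clamp_decay_per_bp * clamp_bp)` -- the clamp
  suppresses partial displacement by decades per base pair.
* Signal/OR/threshold displacement is irreversible (the products expose no
  toehold), and no RNA or DNA degradation is modeled: the cell-free system
  contains no added nucleases, and measured signals plateau rather than
  decay.

Initial conditions are the experimental mixing conditions: templates,
gates, TF dimers and ligands at their nominal concentrations, every
complex and product species at zero.

Species carry a bookkeeping of conserved moieties (each template, TF,
ligand, gate scaffold, output strand and the fluorophore strand), so
conservation laws are constructed symbolically and verified to be exact
left-null vectors of the stoichiometry matrix; the integrator is then
audited against them (`check_conservation()`, drift below 1e-8 under the
default tolerances `rtol = 1e-8`, `atol = 1e-10`, stiff-capable `lsoda`,
dense 1-min output mirroring plate reads). Sub-tolerance negative
excursions are clipped to zero; anything larger is reported as an
integration failure with the species and time.

## Calibrated default parameters

The fitted constants behind the original experiments are not published in
the main text, so the shipped defaults are the package's own calibration:
literature-scale magnitudes refined so that the simulated TetR sensor under
its standard conditions (50 nM template, 5 uM TetR dimer, 5 uM signal
gate) reproduces the qualitative behaviors reported for the platform --
near-baseline repression without ligand, visible activation of the induced
sensor within ten minutes, and a half-maximal aTc response between 2.5 and
5 uM at the 1 h read.

```{r params}
kinetic_params()
```

Notable choices:

* `k_tmsd_max = 60` uM^-1 min^-1 is the classic ~1e6 M^-1 s^-1
  diffusion-limited strand-displacement rate at saturating toehold length;
  `k_tx = 2` min^-1 gives 0.1 uM/min production from a 50 nM template,
  which crosses the 0.5-MEF visibility threshold in about five minutes.
* **TetR ligand stoichiometry is 1 per dimer.** Although the TetR dimer has
  two ligand sites, occupancy of a single site is sufficient to release the
  operator, and with 5 uM dimer a 2:1 consumption model would pin the
  titration corner near 10 uM ligand -- twice the upper edge of the
  observed half-maximal window. Single-site induction with effectively
  irreversible binding (Kd 0.1 nM) places the corner just below the dimer
  concentration, and the standard log-spaced titration then interpolates
  the half-maximum near 3.7 uM.
* **Per-TF ligand affinities.** TetR uses the global (tight) constants.
  SmtB carries an override (Kd 1 uM) because the zinc ADC must resolve
  2--10 uM zinc as an *analog* gradation: a tight zinc binder would make
  the response a step at the repressor concentration and leave nothing for
  the thermometer code to encode. One global affinity cannot serve both
  sensors.
* The zinc sensor uses 1.2 uM SmtB dimer (not the 5 uM used for logic)
  for the same reason: with 5 uM repressor the simulated sensor is still
  fully repressed at the lowest ADC breakpoint (2 uM zinc), and no
  threshold-gate concentration could make the first tube respond there.
* The AND gate's first toehold is 5 nt rather than saturated. In the
  NIMPLY architecture the RNA NOT gate and the AND gate compete for the
  same invader; a saturated capture step would win that race for the first
  ten minutes and leak output in the both-inputs condition. Slowing only
  the capture step preserves AND function (capture still takes seconds at
  5 uM gate) while letting sequestration dominate.
* NOT-gate templates are used at 350 nM, versus 25 nM for the unregulated
  invader templates they silence: an inverter must produce sequestering
  RNA faster than the invader it absorbs, with enough excess that the
  residual leak through the mismatch-penalized reporter path
  (`mismatch_penalty = 0.05`) integrates to well under the 0.5-MEF ON
  threshold over 2 h.

## Logic circuits

The packaged library holds the twelve two-ligand logic circuits
(tetracycline via TetR, zinc via SmtB): two NOT, OR, AND, NOR, NAND, four
IMPLY variants (both directions, with and without the translator gate) and
both NIMPLY directions. `evaluate_truth_table()` simulates every input
condition (ligands at 0 or 100 uM), reads MEF at 120 min and calls ON
strictly above 0.5 MEF:

```{r truth-table}
evaluate_truth_table(library_circuit("NIMPLY_tet_zn"),
                     settings = solver_settings(t_grid = seq(0, 120, 2)))
```

IMPLY circuits route two different strands into one signal gate (the
mismatch-carrying constitutive invader and the clean ligand-induced
strand), so signal gates accept one or two invaders with per-invader
mismatch flags.

## Kinetic comparator and ADC design

A threshold gate shares the reporter's invader but carries an 8-nt toehold
against the ADC reporter's 4 nt -- a 100-fold rate advantage -- so invader
fills the threshold pool before signal appears. In that quasi-static
regime the activation delay is the threshold amount divided by the
production rate, and `design_thresholds()` exploits it: for breakpoints
`c_1 < ... < c_J` it bisects, at each geometric midpoint of adjacent
breakpoints, the threshold concentration that puts the 100-min endpoint
exactly at the ON level. Geometric (not arithmetic) midpoints are used
because the dose--response is graded on a log scale, which lands each
breakpoint safely inside its ON/OFF region. The ON call uses raw MEF at
the read time (normalization is reserved for model--data comparison of
kinetic traces). Every design is audited by simulation at its breakpoints
before being returned; a sensor whose response is not graded over the
requested range yields a diagnostic error rather than a design.

```{r adc, eval = FALSE}
design <- design_thresholds(library_circuit("zinc_sensor"),
                            breakpoints = c(2, 3.5, 5, 10),
                            read_time = 100)
simulate_adc(design, 4)   # -> ON ON OFF OFF, decoded [3.5, 5) uM
```

Between breakpoints each tube flips at its calibration midpoint, so inputs
strictly inside a bin but above the next midpoint decode one bin high;
this quantization is inherent to thresholding at a fixed read time.

## Readout and normalization

`fit_mef_calibration()` reproduces the MEF standardization protocol:
two-fold fluorescein dilutions plus blank (12 samples, nine replicates),
replicate averaging, blank subtraction, exclusion of any concentration
with a saturated replicate, and a least-squares slope restricted to the
0--3.125 uM linear range. `normalize_trace()` applies the
baseline-and-maximum formula `(MEF_t - MEF_0) / (MaxMEF - MEF_0)` used
for comparing kinetic traces with simulations. ON calls are strictly
greater than 0.5 MEF; the same 0.5-MEF level operationalizes "visible"
fluorescence for time-to-detection, an interpretation this package makes
explicit rather than one fixed by eye.

## Parameter estimation

`fit_parameters()` minimizes the mean per-trace mean-squared MEF residual
(each trace weighted equally, so short and long runs count the same) over
log10-transformed parameters with box constraints, using seeded multistart
`nlminb` (8 log-uniform starts by default). The default identifiability
suite (`generate_fit_bundle()`) holds four conditions: uninduced, 5 uM
aTc (the corner of the titration, which pins the ligand off-rate),
saturating aTc, and saturating aTc behind a 2 uM threshold gate with a
kinetically limited reporter (4-nt toehold, 1 uM). The slow reporter is
essential: with the saturated 8-nt reporter, displacement is never
rate-limiting and `k_tmsd_max` is invisible in the data. With it, the
three-parameter fit (`k_tx`, `k_tmsd_max`, `k_off_lig`) recovers truth
within 20 percent at the stylized noise level (0.05 MEF additive, 2
percent proportional). Uncertainty beyond residual-based spread, global
samplers and model selection are out of scope.

## Synthetic data

The generators emulate the instrument protocol -- 1-min kinetic reads for
2 h at 37 C, three replicates, fluorescein standard plates, endpoint
dose--response series -- with a stylized noise model (additive s.d. 0.05
MEF, 2 percent proportional, optional saturation ceiling in raw units)
chosen to visually match replicate scatter in such data, not fitted to
any instrument. All generators are pure functions of their inputs and a
seed. What passing tests on these fixtures demonstrate is internal
consistency of model, design procedure and estimators; they do not
capture real-data features such as pipetting offsets between replicates,
drift, evaporation late in a run, or matrix effects of environmental
samples.

## Problem sizes and numerical choices

Library networks have roughly 10--25 species and 10--25 reactions;
truth-table sweeps integrate 48 such systems (12 circuits x 4
conditions) in seconds. ADC design performs ~15 bisection simulations per
tube at 1-min output resolution. Test and example sweeps use 2-min output
grids where only endpoints matter; endpoint changes from halving solver
steps are below 0.1 percent. Bisection in `critical_threshold()` stops at
a relative width of 1e-3 and verifies the fixed point to 5e-3 MEF.
Tie-breaks worth knowing: ON calls are strictly greater-than; a tube
exactly at threshold is OFF, so inputs exactly at a calibration midpoint
decode into the lower bin.

## Known limitations

* No nucleotide-level thermodynamics: toehold length, mismatches, clamps
  and secondary structure enter as lumped rate modifiers, not predictions
  from sequence; cross-talk between gate sequences is not modeled.
* Deterministic ODEs only -- concentrations are uM-scale, so stochastic
  effects are negligible.
* No resource competition (RNAP, NTPs) and no degradation; runs beyond a
  few hours or heavily loaded circuits would need both.
* The TF--ligand step is a lumped cooperative reaction; sequential-site
  kinetics are not identifiable from fluorescence endpoints and are not
  attempted.
* Temperature is fixed (37 C); lyophilization and real water matrices are
  outside the model.
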