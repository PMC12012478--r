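---
title: "Models and methods: from force traces to folding energetics and binding kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otfold)
```

This vignette is the package's own account of the science it implements:
the mechanical and kinetic models, the estimators built on them, the
synthetic-data generator that every estimator is validated against, and
the numerical and design choices a maintainer would want to know about.

## The dumbbell assay

A dual-trap optical-tweezers experiment tethers a single RNA molecule
between two beads through double-stranded DNA handles. The measured force
reflects the series elasticity of the whole construct: two traps
(harmonic, collapsed into one effective stiffness
$k_\mathrm{eff} = k_1 k_2/(k_1+k_2)$), the dsDNA handles, any released
single-stranded RNA, and the roughly rigid ~2 nm span of a closed hairpin
stem. Two measurement modes matter:

* **Constant velocity**: the trap separation is ramped; unfolding events
  appear as rips in the force–extension curve.
* **Passive mode**: the trap separation is fixed; folding transitions
  exchange ssRNA contour for the rigid stem span, so each conformational
  state sits at its own force level and the trace hops between discrete
  levels — more folded states at higher force.

### Elastic model and parameters

All mechanics run through `elastic_model()`. Units are pN, nm and pN·nm
(1 kcal/mol = 6.948 pN·nm; kT = 4.114 pN·nm at 25 °C). Defaults, all
overridable:

| parameter | default | why |
|---|---|---|
| ssRNA contour per nucleotide | 0.65 nm/nt | conventional ssRNA value; with the stem span below, a 15-nt hairpin yields a 7.75 nm net gain |
| ssRNA persistence length | 1.0 nm | conventional ssRNA value at moderate salt |
| folded stem span | 2.0 nm | end-to-end distance bridged by one closed helix (≈ A-form diameter) |
| handle contour | 600 nm | two ~900-bp dsDNA handles; a fixture convention, not a measured claim |
| handle persistence / stretch modulus | 40 nm / 1000 pN | standard dsDNA values; the enthalpic term matters above ~10 pN |
| effective trap stiffness | 0.15 pN/nm | two traps of 0.25–0.40 pN/nm in series |

The Marko–Siggia relation is inverted by solving the equivalent cubic in
$u = 1-z$ with a vectorized bisection (48 halvings, i.e. machine-level
precision); `wlc_force()` and `wlc_extension()` are mutual inverses to
better than $10^{-6}$ pN over (0, 60] pN. The passive-mode force balance
$F = k_\mathrm{eff}\,(D - x_\mathrm{total}(F))$ has a unique root because
$x_\mathrm{total}$ is strictly increasing; it is solved by the same
vectorized bisection.

**Accounting convention.** Each fully closed stem contributes one rigid
2.0-nm span that is *replaced* by ssRNA contour when it opens; partial
openings only add ssRNA contour. Contour-length gains are therefore
reported *net* of the stem span for full hairpin openings, which is the
quantity that converts to released nucleotides as
$n = (\Delta L + 2.0)/0.65$.

### Contour-length gains from constant-velocity cycles

`fit_contour_gain()` locates the rip on each stretch branch as the single
change point of the residual between the measured force and the
folded-branch prediction — a cumulative-sum split that is robust even when
the rip amplitude (≈0.5 pN for a 15-nt hairpin on 600-nm handles) is
comparable to the noise. Each branch is then WLC-fitted with the ssRNA
contour as the single free parameter. The pre-rip contour is allowed to go
(slightly) negative as a signed nuisance parameter: its true value lies
exactly at zero, and constraining it to be non-negative would bias the
fitted gain low by half a standard error (~0.1 nm).

## Kinetic schemes and the synthetic-data generator

`kinetic_scheme()` describes the folding network: states (name, released
nucleotides, zero-force folding free energy) and transitions with
Bell-model rates $k(F) = k_0 e^{\pm F \Delta x^\ddagger / kT}$. The
generator (`simulate_state_path()`, exact Gillespie sampling) evaluates
each transition at the force level of its departure state, samples the
path onto the stored time grid (raw rate / downsampling factor, default
78.125 kHz / 3) and adds i.i.d. Gaussian force noise *after*
downsampling (default 0.35 pN per stored sample). Truth labels — the
per-sample state, the per-sample bound flag, and the exact dwell sequence
including sub-sample events — ride along on every synthetic trace so
dead-time biases of the estimators can be quantified.

What the generator deliberately does **not** emulate: bead-relaxation
(Ornstein–Uhlenbeck-correlated) noise, instrument drift, camera/QPD
artifacts, or hydrodynamic coupling. Passing recovery tests therefore
demonstrates correctness of the estimators under idealized noise, not
robustness to every instrumental pathology of real data; the Gaussian
i.i.d. choice is declared, not inferred from the source experiments.

### Equilibrium fixtures as an analytic oracle

For energetics validation the rates must be exactly consistent with the
injected free energies. `equilibrium_scheme()` builds Metropolis rates
$k_{ij} = k_\mathrm{base} e^{-\max(0, E_j - E_i)/kT}$ on a given edge set,
where $E_s$ is the *total* system energy of state $s$ at the reference
trap separation: folding free energy plus the stretching free energy of
its released ssRNA and the handles plus the trap potential $F_s^2/2k$. The
stationary occupancies are then Boltzmann in $E_s$ by construction — the
key end-to-end oracle: population inversion plus mechanical-energy
subtraction must return the injected $\Delta G_0$ values at any trap
separation.

### The shipped fixtures

* **CDE_two_state** — a 15-nt triloop hairpin with hysteretic Bell rates
  ($\Delta x^\ddagger = 6$ nm both ways, equilibrium near 11.5 pN):
  unfolds at ~12.5–13.5 pN on stretch, refolds near 10 pN on relax, so
  constant-velocity cycles show one clean rip per branch.
* **ADE_six_state** — F, I1, I2, I3 on the sequential-unzipping pathway
  (14/26/38/52 released nt, matching the helix boundaries of the
  52-nt fixture hairpin `ade_hairpin()`), the unfolded state U, and an
  off-pathway misfold M (7 nt) reachable only from I2. The injected truth
  is a total-energy stagger of −0.2 … +0.5 kcal/mol around the folded
  state at the reference separation (folded state at 13 pN), which keeps
  all six levels populated; the corresponding $\Delta G_0$ values follow
  from the mechanical energies and are reported by the preset. Noise is
  0.15 pN per stored sample for this fixture so that the six levels
  (0.37–0.75 pN apart) are discernible, as they visibly are in this class
  of experiment.
* **ADE_extROQ_binding** — a reduced I1/I3/U network with
  conformational-selection binding to the folded I3: unfolding I3→U is
  blocked and refolding I3→I1 slowed $e^{\Delta\Delta G/kT}$-fold while
  bound. Binding *only* from the already-folded state encodes the
  conformational-selection (not induced-fit) mechanism directly in the
  generator.

Per-edge transition-state distances and attempt rates of real molecules
are not public at this level of detail; the fixtures use plausible values
(Δx‡ up to 6 nm, rates 1–100 s⁻¹) and are documented as synthetic.

## Hidden-Markov state assignment

`fit_hmm()` fits a Gaussian-emission HMM to the force signal:
quantile-seeded k-means initialization of the levels, Baum–Welch EM
(scaled forward–backward in compiled code) to a relative log-likelihood
tolerance of $10^{-6}$ or 500 iterations, per-state emission standard
deviations floored at 0.05 pN to prevent collapse, and Viterbi decoding
with ties broken toward the lower state index. States are canonically
ordered by descending mean force (state 1 = most folded). When the state
count is unknown, models with 2–8 states are compared by BIC — the
reproducible surrogate for choosing the level count by inspection.
Emissions are on force, not extension: in passive mode the state lives in
the force level.

`extract_dwells()` run-length-encodes the Viterbi path; dwells shorter
than a dead-time floor (default 3 samples) are merged into their
predecessor. Dwell tables carry per-dwell mean forces from the raw
samples.

## Bound/unbound segmentation and binding kinetics

Protein binding does not change the force level — it changes the
*kinetics*: the competent state is strongly stabilized. A bound phase is
therefore detected as a maximal run of dwells within the allowed state
set that contains at least one competent-state dwell exceeding a
threshold (`segment_bound_phases()`, default thresholds 0.5 s for
two-state and 1.2 s for three-state fixtures — an order of magnitude
above the unbound competent-state dwell).

The rate estimators carry three standard small-sample/detection
corrections, each derived from exact distributional results rather than
tuning:

1. **Truncation**: detected bound phases exceed the threshold $t_d$, so
   the lifetime MLE is $1/(\overline{\tau} - t_d)$.
2. **Gamma bias**: $E[1/\overline{\tau}] = k\,n/(n-1)$ for $n$
   exponential dwells, so per-group off-rate points use
   $(n-1)/(n\,(\overline{\tau}-t_d))$.
3. **Flanks and missed events** (on-rates): a detected bound phase is
   delimited by state dwells and therefore absorbs the pre-binding and
   post-unbinding portions of the flanking competent-state dwells (one
   mean unbound competent-state dwell each, by memorylessness), which is
   restored to the unbound exposure; bound events shorter than the
   threshold are missed with probability $1-e^{-k_\mathrm{off} t_d}$,
   which deflates the event count. The constant (force-independent)
   on-rate fit is the pooled Poisson MLE — events over corrected,
   occupancy-weighted exposure — which avoids the $1/n$ bias of averaging
   per-trace rates.

The off-rate force dependence is fitted as
$k_\mathrm{off}(F) = k_\mathrm{ind} + k_0 e^{F\Delta x/kT}$ (a
force-independent plus a Bell contribution) by weighted least squares
with inverse-variance weights $n/k^2$, multi-started over $\Delta x$; if
that fails to converge the pure-Bell form is tried, and as a last resort
the force-independent weighted mean is used (each fallback is flagged on
the returned object). Zero-force extrapolation of an exponential is
intrinsically ill-conditioned; the delta-method CI on
$k_\mathrm{off}(0) = k_\mathrm{ind} + k_0$ is reported and honest — wide
when the data cannot pin the intercept.

$K_D = k_\mathrm{off}(0)/k_\mathrm{on}$ with relative errors of the two
rates propagated in quadrature.

### Design of the K_D recovery experiments

`kd_recovery_experiment()` mirrors a real measurement campaign: two
passive-mode steps at each of three trap separations (bound-state forces
4, 8 and 12 pN), durations sized from the condition's own rates to give
≈5–6 bound events per trace — ≈30 events per condition. The effective
sampling rate for these experiments is 1 kHz so that the fast unbound
hopping (U dwells ~12 ms) stays resolvable; at coarser sampling, missed
unfolded-state visits chain unbound competent-state dwells together and
create false bound anchors. Association rates (2×10⁷ M⁻¹s⁻¹ for the ADE
conditions, 1×10⁷ for the CDE conditions) and the 30 nM working
concentration are the package's own choices of plausible study
conditions; the injected zero-force $K_D$ sets the off-rate as
$k_\mathrm{off}(0) = K_D k_\mathrm{on}$, split 70/30 between the
force-independent and Bell contributions with $\Delta x = 0.5$ nm.

### Design of the population-shift (ΔΔG) experiment

`ddG_recovery_experiment()` compares the I1:I3 population ratio between
bound and unbound phases,
$\Delta\Delta G = kT\,\ln[(T_{I1}/T_{I3})_\mathrm{unbound} /
(T_{I1}/T_{I3})_\mathrm{bound}]$, positive when the protein destabilizes
the more-folded state. It runs at 2 nM protein — roughly half the trace
in each phase, which maximizes the number of I1 excursions observed per
simulated second in *both* phases (at 10 nM the trace is >90% bound and
the unbound ratio is starved of data). The confidence interval is a
seeded bootstrap over dwells (1000 resamples). Both phases live at the
same trap separation; a mean force difference above 0.5 pN between the
compared phases raises a warning because it would confound the
comparison.

## Energetics

Populations are defined by occupancy *time*, not dwell counts — robust to
missed events. `zero_force_dG()` subtracts
$G_\mathrm{mech}(s) = G_\mathrm{stretch}^{ssRNA}(F_s) +
G_\mathrm{stretch}^{handles}(F_s) + F_s^2/(2k_\mathrm{eff})$ evaluated at
each state's force level. No deconvolution of bead fluctuations is
attempted — a declared limitation; the recovery tolerance of the
validation suite (0.3 kcal/mol per state pair) is set accordingly.
Stretching free energies are computed as $F x(F) - \int_0^F x\,dF'$ by
adaptive quadrature, cross-checked in the tests against an independent
trapezoid integration.

Note that passive-mode occupancies shift steeply with trap separation
(moving the reference force by 1 pN moves the folded↔unfolded energy
balance by several kcal/mol), so recovery across trap separations is
validated within the narrow window where all states remain populated —
exactly as in a real experiment.

## Folding networks and structures

`build_transition_graph()` counts consecutive dwell pairs;
`classify_off_pathway()` labels a non-terminal state connected (above a
trust threshold of 3 pooled counts) to exactly one partner as an
off-pathway dead end, errors on disconnected graphs, and reports
sub-threshold "near-miss" partners for sensitivity.

`enumerate_unzipping_intermediates()` assumes strictly outside-in
unzipping of a single hairpin: each step opens one helix together with
the interior bulge/loop nucleotides immediately inward of it (the final
step releases the terminal loop). This ordering is an assumption of the
model, stated as such. Pseudoknots and multi-branched structures are
rejected. `match_intermediates()` maps observed contour gains to the
nearest enumerated intermediate within 1.5 nm (≈2–3 nt; overridable),
flags ambiguous matches, and reports unmatched observations as misfold
candidates; `compare_structures()` ranks competing candidate structures
by total absolute residual.

## Bulk assays

* **Hill fits** (`hill_fit()`):
  $f(c) = f_\mathrm{min} + (f_\mathrm{max}-f_\mathrm{min})
  \,c^n/(K_D^n + c^n)$, Levenberg–Marquardt with multi-start over $K_D$
  decades spanning the concentration series; a fitted $K_D$ outside
  [min(c)/10, 10 max(c)] is flagged as out of range. Triplicates are
  fitted individually and summarized as mean ± SD.
* **Melting curves** (`melt_fit()`): a sum of two descending Boltzmann
  sigmoids plus baseline. The initializer comes from the extrema of a
  Savitzky–Golay smoothed derivative (window 9 points, cubic); if the
  second transition is degenerate (amplitude < 2% of the total, or
  midpoints closer than 1 °C, or no second derivative extremum) the fit
  falls back to a single Boltzmann and says so.
* **HNN-COSY couplings** (`hnn_cosy_coupling()`): the cross/diagonal
  intensity ratio of the donor and acceptor ¹⁵N resonances inverts to
  $|{}^{h2}J_{NN}| = \arctan\!\sqrt{|I_{Na}/I_{Nd}|}\,/(2\pi\Delta)$ with
  $2\Delta$ the COSY transfer time (30 ms by default). This is the
  standard quantitative-HNN-COSY inversion of
  $I_{Na}/I_{Nd} = -\tan^2(2\pi J \Delta)$, implemented from that
  relation directly; printed renderings of the formula vary between
  sources, so the package documents the form it uses rather than
  transcribing any one of them. The coupling saturates at $1/(4\Delta)$
  as the ratio grows.

## Problem sizes used in the validation suite

The test and acceptance experiments are desk-scale by design: 20
stretch–relax cycles for the contour-gain recovery; 60–150 s of
passive-mode trace (at a stored rate of 500 Hz) for HMM and energetics
recovery; ≈30 bound events per binding condition across three forces
(1 kHz stored rate); 1200 s for the population-shift experiment; 500
synthetic rate estimates for the CI-coverage check. These sizes were
chosen so each estimator's sampling error is comfortably inside the
tolerance it is tested against.

## Known limitations

* Gaussian i.i.d. noise only; correlated-noise emissions for the HMM are
  a documented extension hook, not implemented.
* No drift correction and no change-point (step-detection) alternative to
  the HMM.
* The unzipping-intermediate model is single-hairpin, strictly
  outside-in; tertiary contacts and pseudoknots are out of scope.
* Zero-force extrapolation of off-rates inherits the usual
  ill-conditioning of exponential extrapolation: trust the CI, not the
  point estimate, when the measured force range is far from zero.
* EMSA fraction-bound values are consumed as numeric tables; gel
  densitometry is out of scope.
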