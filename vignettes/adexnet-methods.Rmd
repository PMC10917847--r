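---
title: "adexnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{adexnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`adexnet` simulates a whole-brain network in which every cortical region is
a *mean-field* description of a local network of 10^4 adaptive exponential
integrate-and-fire (AdEx) neurons, 80% excitatory and 20% inhibitory with
5% connectivity (so each neuron receives `K_e = 400` excitatory and
`K_i = 100` inhibitory recurrent synapses). The mean-field state of node
$k$ has seven variables: the population rates $\nu_e^k, \nu_i^k$, the
second-order rate covariances $c_{ee}^k, c_{ei}^k, c_{ii}^k$, and the
adaptation currents $W_e^k, W_i^k$ (the inhibitory population carries no
spike-triggered or subthreshold adaptation, so $W_i$ relaxes to zero and
is retained only for symmetry of the state layout).

The rates relax with timescale $T$ towards the population *transfer
function* $\mathcal{F}_\mu(\nu_e^{tot}, \nu_i, W)$, corrected by the
covariances times the transfer function's input Hessian; the covariances
obey the standard second-order moment equations with a finite-size source
term scaled by the population sizes; and the adaptation integrates
$\tau_w \dot W = -W + b_e \tau_w \nu_e + a(\mu_V - E_{L,e})$ with $a = 0$
throughout (the paper-level convention for this model family).

The transfer function is the semi-analytic first-passage form
$$\nu_{out} = \frac{1}{2\tau_V}\,
  \mathrm{erfc}\!\left(\frac{V^{e\!f\!f}_{thre}-\mu_V}
                            {\sqrt{2}\,\sigma_V}\right),$$
where $(\mu_V, \sigma_V, \tau_V)$ are the mean, standard deviation and
autocorrelation time of the membrane potential under Poissonian
conductance bombardment, and the effective threshold is a fitted
second-order polynomial in the normalised moments. The ten polynomial
coefficients per population are *data*, not code: they are shipped in
`inst/extdata/tf_coefficients.json` (transcribed at full precision from
the public reference implementation of this mean-field in The Virtual
Brain) and can be replaced via `read_tf_coefficients()` /
`tf_params()`. Output rates are clipped to the refractory-limited maximum
`1/T_refrac` (200 Hz at the default 5 ms refractory period); the
self-consistent pathological fixed point sits slightly below the clip, at
about 193 Hz.

Nodes are coupled through a structural connectome: node $k$ receives
$$\nu_e^{k,tot} = \nu_{aff} + \nu_{drive}^k(t) +
  S \sum_{j\neq k} C_{jk}\,\nu_e^j(t - d_{jk}/v_c),$$
added to its own excitatory rate at the transfer-function input. The
drive is an Ornstein-Uhlenbeck process
$\nu_{drive}(t) = \nu_{drive} + \sigma \xi(t)$,
$d\xi = -\xi\,dt/\tau_{OU} + dW_t$, independent per node and floored at
0 Hz. Integration is a stochastic Heun (predictor-corrector) scheme at
`dt = 0.1` ms, with the drive and the delayed inputs held over each step.

## Numerical conventions that are part of the model

Three numerical choices deserve emphasis because the dynamical landscape
depends on them; all three follow the public reference implementation,
against which this package's right-hand side agrees to ~1e-13
(see `tests/testthat/fixtures-meanfield-oracle.json`).

1. **Derivative scaling.** The transfer-function derivatives entering the
   covariance equations and the Hessian correction are central difference
   quotients over a step of 1e-4 expressed in Hz, while the state is
   integrated in kHz. Relative to a dimensionally uniform reading of the
   printed equations this scales the first derivatives by 1e-3 and the
   second derivatives by 1e-6. The uniform reading makes the covariance
   subsystem linearly unstable wherever the transfer function is steep
   (covariances diverge within seconds of simulated time); the reference
   convention is the model that actually produces the published regime
   repertoire, so it is the one implemented.

2. **Cross-covariance pairing.** The $\dot c_{ei}$ equation pairs the
   derivative and covariance factors as
   $c_{ee}\partial_e\mathcal{F}_e + c_{ei}(\partial_e\mathcal{F}_i +
   \partial_i\mathcal{F}_e) + c_{ii}\partial_i\mathcal{F}_i$, the
   reference implementation's realisation of the symmetrised moment
   equation.

3. **Domain guards.** After each integrator stage, rates are clamped to
   $[0, 1/T_{refrac}]$ and covariances to the largest variance a rate
   bounded by $1/T_{refrac}$ can have, $(1/2T_{refrac})^2$. The truncated
   moment expansion is not guaranteed to stay in its validity region
   during violent transients; the guards bound such excursions and never
   bind at the model's fixed points.

## Why the coupling sum excludes the diagonal

The connectome container enforces $C_{kk} = 1$: the diagonal stands for
the node's own recurrence. That recurrence is *already* inside the
mean-field - the node's own $\nu_e$ enters its transfer function
unscaled - so the coupling operator sums over $j \neq k$ only. Feeding
the diagonal through the $S$-scaled sum as well would add a zero-lag
positive self-loop on top of the internal recurrence. Measured
consequence: with the double-counted self-term every Up-state ignition
at $b_e \ge 60$ pA runs away to the paroxysmal fixed point and the
Up/Down regime disappears from the entire depolarized region, which
contradicts the regime structure this model family is known for.

## Initial conditions: deterministic spin-up

The model is multistable: a near-silent Down state, a low-rate
asynchronous-irregular (AI) state and the ~193 Hz paroxysmal state can
coexist. An arbitrary initial condition therefore does not "wash out"
with the transient - it *selects an attractor*. Starting every node at,
say, 1 Hz with no adaptation collapses the network into a synchronized
silent phase whose collective re-ignition overshoots into the paroxysmal
state even at couplings where the AI state is perfectly stable.

`simulate_network()` therefore seeds every node (and the delay history)
with the stationary state of a single uncoupled node under the
self-consistent mean input $\nu_{aff} + \nu_{drive} + S\,\bar{c}\,\nu_e$
(three noiseless relaxation runs of 1.5 s iterate the self-consistency;
$\bar{c}$ is the mean in-strength). The spin-up is deterministic, so
simulations remain bit-reproducible. Any explicit `init_state` overrides
it - the paroxysm acceptance check, for instance, starts at 190 Hz on
purpose.

## The synthetic connectome

The generator emulates what downstream stages need from tractography
data: region centres uniform in a 100 mm cube (delays of a few ms to a
few tens of ms at `v_c` = 3 mm/ms), tract lengths as Euclidean
distances, symmetric heavy-tailed (log-normal, `meanlog` -2, `sdlog` 1)
weights with a configurable fraction of absent connections, and **unit
mean in-strength**: off-diagonal column sums are rescaled to average 1.
The rescaling matters: the sweep range $S \in [0, 0.5]$ spans "isolated"
to "paroxysm-prone" only if afferent sums are of order 1, as they are
for region-sum-scaled empirical connectomes. What the generator does
*not* emulate: hemispheric/modular block structure, distance-dependent
connection probability, and the specific weight-distance correlations of
real tractography. A green regime test therefore establishes that the
dynamics behave correctly on a *generic* connectome of realistic scale,
not that any subject-specific connectivity feature is reproduced.

Default stated world, chosen once: `n_regions = 68` (the cortical
parcellation size this model family uses), `density = 0.4`,
`nu_drive = 0.315` Hz and `sigma = 0.105` Hz (the reference
implementation's external-input and noise-weight values),
`tau_OU = 5` ms, `S = 0.3`, `T = 19` ms, `E_L = -64` mV at the safe
diagonal. Under these defaults the package reproduces the documented
regime repertoire: sustained AI at the depolarized diagonal for all
$S \le 0.5$ (~4-6 Hz), Up/Down alternation when $b_e$ rises to 60-120 pA
(mean rate falls, rate SD rises, Up durations shorten), slow-wave/silent
dynamics at hyperpolarized leaks even for $b_e = 0$, and paroxysmal
capture when excitatory leaks are depolarized while inhibitory leaks are
hyperpolarized (including at $S = 0$, the "disconnected corner").

## Feature conventions (where the source is silent)

* **Up states**: per-node threshold at 20% of that node's maximum rate,
  epochs shorter than 20 ms discarded; both are exposed arguments. The
  detection rule is a stated convention, not a reconstruction.
* **PSD peak**: rectangular-window periodogram of mean-subtracted rates,
  averaged over nodes; the highest-power non-DC local maximum with at
  least 5% of the spectrum maximum; 0 when no peak qualifies.
* **FC with silent nodes**: a zero-variance node has no defined Pearson
  correlation; its off-diagonal entries are set to 0 (self-correlation
  1) so constant networks yield finite features instead of NaNs. A
  consequence worth knowing: a perfectly constant network has
  `mean_FC = 1/n`, not 1.
* **corrFCSC**: `corr_fc_sc()` flattens both matrices *including* the
  diagonal by default (the literal flattened-array definition), but the
  feature pipeline (`extract_features()`) excludes the diagonals. Both
  FC and SC carry unit diagonals, and with sparse structural weights the
  diagonal match dominates the flattened correlation and *inverts* its
  dependence on adaptation; on the off-diagonal entries the correlation
  rises with $b_e$ (from about -0.09 to about +0.12 at the depolarized
  exemplar), which is the structure-function phenomenon this statistic
  exists to measure.
* **K-means**: traces are clustered on raw values (FC and corrFCSC are
  bounded and commensurate) with k-means++ seeding, 10 restarts, best
  inertia kept, and classes relabelled by ascending centroid value at
  the lowest $b_e$ so reports are reproducible. `k = 6` is a
  presentation choice, not a model claim.

## Sweep orchestration

`generate_grid()` builds evenly spaced values including both endpoints
(this reproduces the printed -78.667 mV as the second inhibitory-leak
value) and filters the cartesian product by the strict constraint
$E_{L,i} < E_{L,e} + 4$ mV, applied with a 1e-9 mV guard so that
on-grid equality is excluded despite floating-point spacing error. At
16 values per parameter this leaves 675,840 of the 1,048,576
combinations. `run_sweep()` derives one seed per combination from the
master seed and the combination id, so results are independent of the
worker count; per-worker append-only CSVs plus completed-id index files
make the sweep resumable after a kill. One stochastic realisation per
combination is simulated, matching the source protocol.

## Known limitations

* The full 675,840-combination census, the exact published census
  histogram and the class geographies of the published clustering are
  cluster-scale results; this package reproduces their counting
  identities exactly and their sign patterns / regime structure at desk
  scale, not the histograms themselves.
* Small networks (n of order 10) after unit-in-strength normalisation
  concentrate coupling in few strong links and are noticeably more
  paroxysm-prone during Up/Down cycling than the 68-region default;
  desk-scale sweep tests use n = 40 where trace statistics are needed.
* The hyperpolarized region at high $S$ can sustain a low-rate AI state
  rather than pure slow waves; the hyperpolarized regime checks use the
  moderate coupling ($S = 0.3$) where silent epochs dominate.
* Exact waveform agreement with the published figures would require the
  original tractography matrix and the original noise realisations;
  neither is bundled.
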