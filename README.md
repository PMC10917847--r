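# adexnet

Whole-brain networks of adaptive exponential (AdEx) mean-field models, in R.

## The scientific problem

Transitions between conscious-like and unconscious-like brain states are
accompanied by characteristic changes in large-scale cortical dynamics:
wakefulness shows sustained, low-amplitude, desynchronized
*asynchronous-irregular* (AI) activity, while deep sleep and anesthesia
show high-amplitude slow waves in which populations alternate between
silent (Down) and active (Up) epochs, and functional connectivity (FC)
collapses onto the underlying structural connectome (SC). A biologically
grounded way to study these transitions is a network of *mean-field
models*: each of 68 cortical regions is the second-order mean-field of a
10^4-neuron AdEx spiking network (seven state variables per region: two
population rates, three rate covariances, two adaptation currents),
coupled through a structural connectome with axonal conduction delays and
driven by an Ornstein-Uhlenbeck noise process, integrated with a
stochastic Heun scheme at dt = 0.1 ms.

Spike-frequency adaptation `b_e` (pA) plays the role of the
neuromodulatory knob: low adaptation produces AI states, high adaptation
produces Up/Down alternation. The model also harbours a *paroxysmal*
(epileptic-like) stable state at ~190 Hz, reached when excitation
dominates; a simulation is flagged paroxysmal when any region's
excitatory rate exceeds 175 Hz. The package implements the full
exploration pipeline around this model:

* a synthetic structural connectome generator (and a reader/writer for
  TVB-style `weights.txt` / `tract_lengths.txt` / `centres.txt` bundles),
* the node dynamics: membrane-moment formulas, erfc transfer functions
  with shipped coefficient tables, the seven-equation right-hand side,
  and a fixed-point finder (Down / Up / paroxysmal branches),
* the delayed, noise-driven network integrator (compiled core plus a
  pure-R reference engine),
* the feature pipeline: rate statistics, Up-state durations, PSD peak
  frequency, functional connectivity, FC-SC correlation, paroxysm flag,
* constrained parameter-grid sweeps (`E_L_i < E_L_e + 4` mV; 675,840 of
  16^5 combinations at default resolution) with checkpoint/resume and a
  3-D paroxysm census over (S, E_L_i, E_L_e),
* K-means classification of adaptation-indexed `FC(b_e)` and
  `corrFCSC(b_e)` traces (42,240 traces per feature at full resolution).

## Worked example

```r
library(adexnet)

conn   <- generate_synthetic_connectome(68, density = 0.4, seed = 7)
params <- adex_params(E_L_e = -64, E_L_i = -64, b_e = 0, T = 19)
cfg    <- sim_config(duration = 5000, transient = 2000, S = 0.3, seed = 1)

ts <- simulate_network(conn, cfg, params)
extract_features(ts, conn)
```

```
features:
  max nu_e           6.178 Hz
  mean nu_e          4.760 Hz
  mean SD nu_e       0.296 Hz
  mean Up dur.      3000.0 ms
  PSD peak          13.667 Hz
  mean FC           0.0106
  corrFCSC          0.7893
  paroxysmal         FALSE
```

Sustained ~5 Hz firing, a single Up state spanning the whole 3-second
post-transient window, low inter-regional correlation: the AI regime.
Raising adaptation to `b_e = 120` pA in the same configuration yields

```
features:
  max nu_e          12.622 Hz
  mean nu_e          0.368 Hz
  mean SD nu_e       0.962 Hz
  mean Up dur.        58.2 ms
  PSD peak           1.333 Hz
  mean FC           0.4899
  paroxysmal         FALSE
```

the Up/Down regime: the mean rate collapses, fluctuations and
inter-regional synchrony grow, Up states shorten to tens of ms and the
spectrum peaks at slow-wave frequencies. The paroxysmal branch is
visible directly in the fixed-point structure of an excitation-dominated
node (`E_L_e = -60`, `E_L_i = -80` mV):

```r
find_fixed_points(0, adex_params(E_L_e = -60, E_L_i = -80, b_e = 0),
                  default_tf_params())
#> nu_e =   0.00 Hz  (stable)   - Down
#> nu_e =   0.62 Hz  (unstable)
#> nu_e =  13.75 Hz  (stable)   - Up
#> nu_e = 192.79 Hz  (stable)   - paroxysmal
```

Sweeps and trace classification at desk scale:

```r
grid <- generate_grid(n_values = 4)                  # coarse: 640 combos
res  <- run_sweep(grid, conn, sim_config(duration = 1000, transient = 500),
                  workers = 2, checkpoint_dir = "ckpt")
census <- paroxysm_census(res)                       # counts over (S, E_L_i, E_L_e)
traces <- build_traces(res, "corrFCSC")
model  <- cluster_traces(traces, k = 6, seed = 1)
```

A command-line interface wrapping these stages is installed at
`system.file("cli", "adexnet", package = "adexnet")` with subcommands
`simulate`, `features`, `sweep` and `classify`.

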