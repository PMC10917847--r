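# Delayed, noise-driven network of AdEx mean-field nodes, integrated with
# the stochastic Heun scheme.

#' Simulation configuration
#'
#' @param dt Integration step (ms).
#' @param duration Total simulated time (ms).
#' @param transient Initial window discarded from the output (ms); absorbs
#'   the arbitrary initial condition.
#' @param S Dimensionless inter-region coupling strength (swept in
#'   `[0, 0.5]`).
#' @param v_c Axonal propagation speed (mm/ms); tract length / `v_c` gives
#'   the inter-region delay.
#' @param nu_aff Afferent (stimulus) input rate (Hz); 0 for spontaneous
#'   activity.
#' @param nu_drive Baseline of the external noise drive (Hz).
#' @param sigma Amplitude of the Ornstein-Uhlenbeck noise drive (Hz).
#' @param tau_OU Time constant of the OU process (ms).
#' @param seed Master seed; expands deterministically into one noise
#'   stream per node, so trajectories are reproducible and node `k`'s
#'   stream does not depend on how many nodes follow it.
#' @param init_state Optional full initial state: a length-7 named vector
#'   or `n x 7` matrix (columns `nu_e`, `nu_i` in Hz, `c_ee`, `c_ei`,
#'   `c_ii` in Hz^2, `W_e`, `W_i` in pA). When `NULL` (the default) every
#'   node starts at the stationary state of a single uncoupled node under
#'   the self-consistent mean input (a deterministic noiseless spin-up);
#'   the model is multistable, and this seeds the simulation on the
#'   attractor the configuration actually supports.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.1, duration = 5000, transient = 2000,
                       S = 0.3, v_c = 3, nu_aff = 0,
                       nu_drive = 0.315, sigma = 0.105, tau_OU = 5,
                       seed = 42L, init_state = NULL) {
  if (dt <= 0) stop("`dt` must be positive")
  if (transient >= duration) stop("`transient` must be smaller than `duration`")
  if (S < 0) stop("`S` must be nonnegative")
  if (sigma < 0) stop("`sigma` must be nonnegative")
  if (v_c <= 0) stop("`v_c` must be positive")
  if (tau_OU <= 0) stop("`tau_OU` must be positive")
  cfg <- list(dt = dt, duration = duration, transient = transient, S = S,
              v_c = v_c, nu_aff = nu_aff, nu_drive = nu_drive, sigma = sigma,
              tau_OU = tau_OU, seed = as.integer(seed),
              init_state = init_state)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("simulation config: %g ms at dt = %g ms ",
                     "(transient %g ms), S = %g, v_c = %g mm/ms\n"),
              x$duration, x$dt, x$transient, x$S, x$v_c))
  cat(sprintf("  drive: nu_aff = %g Hz, nu_drive = %g Hz, sigma = %g Hz,",
              x$nu_aff, x$nu_drive, x$sigma))
  cat(sprintf(" tau_OU = %g ms, seed = %d\n", x$tau_OU, x$seed))
  invisible(x)
}

#' One Euler-Maruyama update of the Ornstein-Uhlenbeck drive process
#'
#' The dimensionless OU state evolves as
#' \eqn{d\xi = -\xi\, dt/\tau_{OU} + dW_t} with a unit-amplitude Wiener
#' process, so its stationary variance is \eqn{\tau_{OU}/2} (with time in
#' ms). The drive delivered to a node is `nu_drive + sigma * xi`, floored
#' at 0 Hz (the flooring happens where the drive is consumed, see
#' [delayed_coupling()]).
#'
#' @param xi Current OU state(s), dimensionless.
#' @param dt Time step (ms).
#' @param tau_OU OU time constant (ms).
#' @param noise_increment Wiener increment(s) over the step: normal with
#'   standard deviation `sqrt(dt)` (pass 0 for the noiseless limit).
#' @return Updated `xi`, same shape as the input.
#' @export
ou_step <- function(xi, dt, tau_OU, noise_increment) {
  if (tau_OU <= 0) stop("`tau_OU` must be positive")
  xi - xi * dt / tau_OU + noise_increment
}

.delay_steps <- function(conn, cfg) {
  matrix(as.integer(round(conn$tract_lengths / (cfg$v_c * cfg$dt))),
         conn$n_regions, conn$n_regions)
}

# weights as used by the coupling operator: the unit diagonal of the
# connectome stands for the node's own recurrence, which already enters
# the transfer function as the (unscaled, undelayed) local rate. Feeding
# it again through the S-scaled coupling sum would double-count local
# recurrence with a zero-lag positive loop and makes every Up-state
# ignition run away to the paroxysmal fixed point; the long-range coupling
# therefore uses the off-diagonal weights only.
.coupling_weights <- function(conn) {
  w <- conn$weights
  diag(w) <- 0
  w
}

#' Total delayed excitatory input to network nodes
#'
#' Implements the coupling term of the network equations: the total
#' excitatory input of node \eqn{k} is
#' \deqn{\nu_e^{k,tot} = \nu_{aff} + \nu_{drive}^k +
#'   S \sum_{j \ne k} C_{jk}\, \nu_e^j(t - d_{jk}/v_c)}
#' with delays rounded to the nearest integer step. The connectome's unit
#' diagonal represents the node's own recurrence, which enters the
#' transfer function directly as the local rate rather than through the
#' coupling sum (see the methods vignette on why the self-term must not
#' be double-counted).
#'
#' @param history `n x depth` matrix of past excitatory rates (Hz):
#'   column 1 is the current time, column `m` is `m - 1` steps back.
#' @param conn A [connectome] object.
#' @param k Node index, or `NULL` for all nodes.
#' @param cfg A [sim_config()] (provides `S`, `v_c`, `dt`, `nu_aff`).
#' @param drive Current value(s) of the OU drive `nu_drive + sigma * xi`
#'   (Hz), floored at 0 internally; defaults to the configured baseline.
#' @return `nu_e_tot` (Hz) for node `k`, or a vector over all nodes.
#' @export
delayed_coupling <- function(history, conn, k = NULL, cfg, drive = cfg$nu_drive) {
  history <- as.matrix(history)
  n <- conn$n_regions
  if (nrow(history) != n)
    stop("`history` must have one row per region")
  d <- .delay_steps(conn, cfg)
  if (ncol(history) < max(d) + 1L)
    stop(sprintf(paste0("history depth %d is shorter than the maximum ",
                        "delay of %d steps"), ncol(history), max(d)))
  drive <- pmax(drive, 0)
  w <- .coupling_weights(conn)
  ks <- if (is.null(k)) seq_len(n) else k
  vals <- vapply(ks, function(kk) {
    sum(w[, kk] * history[cbind(seq_len(n), 1L + d[, kk])])
  }, numeric(1))
  out <- cfg$nu_aff + drive + cfg$S * vals
  if (is.null(k)) out else out[[1L]]
}

# domain guards applied after each integrator stage: rates in
# [0, 1/T_refrac]; variances in [0, (1/(2 T_refrac))^2] and the
# cross-covariance within +/- that cap. The truncated moment expansion is
# linearly unstable where the transfer function is steep; the caps keep
# pathological excursions bounded and never bind at the model's fixed
# points. Mirrors the compiled core exactly.
.clamp_khz <- function(s, p) {
  rmax <- 1 / p$T_refrac
  cmax <- (0.5 / p$T_refrac)^2
  s[, 1:2][s[, 1:2] < 0] <- 0
  s[, 1:2][s[, 1:2] > rmax] <- rmax
  s[, c(3, 5)][s[, c(3, 5)] < 0] <- 0
  s[, 3:5][s[, 3:5] > cmax] <- cmax
  s[, 4][s[, 4] < -cmax] <- -cmax
  s
}

# one Heun step in internal kHz units; ext held over the step.
.heun_khz <- function(state, ext, dt, p, P_e, P_i) {
  d1 <- .derivs(state, ext, p, P_e, P_i)
  pred <- .clamp_khz(state + dt * d1, p)
  d2 <- .derivs(pred, ext, p, P_e, P_i)
  .clamp_khz(state + dt / 2 * (d1 + d2), p)
}

#' One stochastic Heun step of the node dynamics
#'
#' Predictor-corrector update: an Euler predictor followed by a corrector
#' that averages the drift at the current and predicted states. The
#' external input (which carries the stochastic drive) is held constant
#' over the step, so the same noise increment enters both stages.
#' Population rates are clamped at 0 from below after each stage.
#'
#' @param state Length-7 named vector or `n x 7` matrix (Hz / Hz^2 / pA),
#'   see [meanfield_derivatives()].
#' @param nu_e_tot_ext External excitatory input (Hz), scalar or per node.
#' @param dt Time step (ms).
#' @param p [adex_params()] object.
#' @param tfs List with transfer functions `e` and `i`
#'   ([default_tf_params()]).
#' @return Updated state, same shape as the input.
#' @export
heun_step <- function(state, nu_e_tot_ext = 0, dt, p, tfs) {
  vec <- is.null(dim(state))
  s <- .state_to_internal(.as_state_matrix(state))
  out <- .heun_khz(s, rep(nu_e_tot_ext / 1e3, length.out = nrow(s)),
                   dt, p, tfs$e$P, tfs$i$P)
  if (any(!is.finite(out)))
    stop("integration blow-up in heun_step")
  out <- .state_to_public(out)
  colnames(out) <- .STATE_VARS
  if (vec) out[1L, ] else out
}

#' Deterministic Heun integration of an arbitrary ODE
#'
#' The same predictor-corrector scheme used by the network integrator,
#' exposed on a user-supplied drift so its second-order convergence can be
#' verified on systems with known solutions.
#'
#' @param deriv Function of the state returning its time-derivative.
#' @param x0 Initial state (numeric vector).
#' @param dt Time step.
#' @param n_steps Number of steps.
#' @return The state after `n_steps` steps.
#' @export
heun_ode <- function(deriv, x0, dt, n_steps) {
  x <- x0
  for (i in seq_len(n_steps)) {
    d1 <- deriv(x)
    d2 <- deriv(x + dt * d1)
    x <- x + dt / 2 * (d1 + d2)
  }
  x
}

# pure-R twin of the compiled core; identical algorithm, used as the
# independent reference in the tests and selectable via engine = "r".
# All arguments in internal kHz units.
.sim_core_r <- function(init, weights, delay_steps, noise, p, P_e, P_i,
                        dt, n_steps, transient_steps, S, nu_aff, nu_drive,
                        sigma, tau_OU) {
  n <- nrow(init)
  L <- max(delay_steps) + 1L
  hist <- matrix(init[, 1L], n, L)
  state <- init
  xi <- numeric(n)
  have_noise <- nrow(noise) > 0L
  n_keep <- n_steps - transient_steps
  rec <- lapply(1:7, function(v) matrix(NA_real_, n_keep, n))
  jj <- rep(seq_len(n), n)
  sqdt <- sqrt(dt)
  for (t in seq_len(n_steps) - 1L) {
    if (have_noise)
      xi <- ou_step(xi, dt, tau_OU, sqdt * noise[t + 1L, ])
    ext <- nu_aff + pmax(nu_drive + sigma * xi, 0)
    if (S > 0) {
      cols <- (t - delay_steps) %% L
      vals <- hist[jj + n * as.vector(cols)]
      ext <- ext + S * colSums(matrix(vals * weights, n, n))
    }
    state <- .heun_khz(state, ext, dt, p, P_e, P_i)
    if (any(!is.finite(state))) {
      node <- which(!is.finite(state), arr.ind = TRUE)[1L, 1L]
      stop(sprintf("integration blow-up at t = %.2f ms (node %d)",
                   (t + 1L) * dt, node))
    }
    hist[, (t + 1L) %% L + 1L] <- state[, 1L]
    if (t + 1L > transient_steps) {
      r <- t + 1L - transient_steps
      for (v in 1:7) rec[[v]][r, ] <- state[, v]
    }
  }
  names(rec) <- .STATE_VARS
  rec
}

# expand the master seed into per-node standard-normal increment streams
.noise_matrix <- function(seed, n_steps, n) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  node_seeds <- sample.int(2147483646L, n)
  noise <- matrix(0, n_steps, n)
  for (k in seq_len(n)) {
    set.seed(node_seeds[k])
    noise[, k] <- stats::rnorm(n_steps)
  }
  noise
}

.init_state_matrix <- function(cfg, n) {
  s <- cfg$init_state
  if (is.null(dim(s))) s <- matrix(s, n, 7L, byrow = TRUE,
                                   dimnames = list(NULL, names(s)))
  .as_state_matrix(s)
}

# deterministic spin-up of the initial condition: the stationary state of a
# single uncoupled node under the self-consistent mean input
# ext = nu_aff + nu_drive + S * <in-strength> * nu_e. The network is seeded
# at (and its delay history filled with) this state, so simulations start
# on the attractor the configuration actually supports instead of being
# thrown across basin boundaries by an arbitrary initial condition (the
# model is multistable: Down, Up/AI and paroxysmal states coexist).
# Noiseless and therefore reproducible; a few relaxation runs iterate the
# self-consistency.
.spinup_state <- function(conn, cfg, params, tfs, iters = 3L,
                          relax_ms = 1500) {
  instr <- mean(colSums(.coupling_weights(conn)))
  par <- c(unclass(params), list(P_e = tfs$e$P, P_i = tfs$i$P))
  # start from a strongly inhibition-dominated state so that runaway
  # excitation cannot precede the build-up of inhibition
  state <- matrix(c(1e-3, 0.1, 0, 0, 0,
                    params$b_e * params$tau_w * 1e-3, 0), 1L, 7L)
  nu <- state[1L, 1L]
  n_steps <- as.integer(round(relax_ms / cfg$dt))
  for (it in seq_len(iters)) {
    ext <- (cfg$nu_aff + max(cfg$nu_drive, 0)) / 1e3 + cfg$S * instr * nu
    rec <- .sim_core_cpp(state, matrix(0, 1L, 1L),
                         matrix(0L, 1L, 1L), matrix(0, 0L, 0L), par,
                         cfg$dt, n_steps, n_steps - 1L, 0,
                         ext, 0, 0, cfg$tau_OU)
    state <- matrix(vapply(rec, function(m) m[1L, 1L], 0), 1L, 7L)
    nu <- state[1L, 1L]
  }
  state
}

#' Simulate a whole-brain network of AdEx mean-field nodes
#'
#' Integrates `duration/dt` stochastic Heun steps of the coupled
#' seven-variable node dynamics over a structural connectome, with
#' delayed excitatory interactions and an independent Ornstein-Uhlenbeck
#' drive per node, then discards the first `transient` ms.
#'
#' Reaching the paroxysmal (pathologically high activity) fixed point is
#' not an error: it is data, detectable with [detect_paroxysm()].
#'
#' @param conn A [connectome] object.
#' @param cfg A [sim_config()] object.
#' @param params An [adex_params()] object (node-level constants; the
#'   swept parameters `T`, `b_e`, `E_L_e`, `E_L_i` live here).
#' @param tfs Transfer-function pair from [default_tf_params()].
#' @param engine `"cpp"` (compiled core, default) or `"r"` (the pure-R
#'   reference implementation; identical algorithm, much slower).
#' @return A `rate_timeseries` object: post-transient trajectories of all
#'   seven state variables (`nu_e`, `nu_i` in Hz; `c_ee`, `c_ei`, `c_ii`
#'   in Hz^2; `W_e`, `W_i` in pA) as `n_samples x n_regions` matrices,
#'   plus `times` (ms), `dt`, the configuration and the model parameters
#'   (provenance metadata).
#' @examples
#' \donttest{
#' conn <- generate_synthetic_connectome(8, density = 0.5, seed = 1)
#' ts <- simulate_network(conn, sim_config(duration = 400, transient = 200))
#' dim(ts$nu_e)
#' }
#' @export
simulate_network <- function(conn, cfg = sim_config(),
                             params = adex_params(),
                             tfs = default_tf_params(),
                             engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(conn, "connectome"), inherits(cfg, "sim_config"),
            inherits(params, "adex_params"))
  n <- conn$n_regions
  n_steps <- as.integer(round(cfg$duration / cfg$dt))
  transient_steps <- as.integer(round(cfg$transient / cfg$dt))
  if (transient_steps >= n_steps)
    stop("`transient` leaves no samples to record")
  delay_steps <- .delay_steps(conn, cfg)

  init <- if (is.null(cfg$init_state)) {
    matrix(.spinup_state(conn, cfg, params, tfs), n, 7L, byrow = TRUE)
  } else {
    .state_to_internal(.init_state_matrix(cfg, n))
  }
  noise <- if (cfg$sigma > 0) .noise_matrix(cfg$seed, n_steps, n)
           else matrix(0, 0L, 0L)

  w_coup <- .coupling_weights(conn)
  kHz <- function(x) x / 1e3
  if (engine == "cpp") {
    par <- c(unclass(params), list(P_e = tfs$e$P, P_i = tfs$i$P))
    rec <- .sim_core_cpp(init, w_coup, delay_steps, noise, par,
                         cfg$dt, n_steps, transient_steps, cfg$S,
                         kHz(cfg$nu_aff), kHz(cfg$nu_drive),
                         kHz(cfg$sigma), cfg$tau_OU)
  } else {
    rec <- .sim_core_r(init, w_coup, delay_steps, noise, params,
                       tfs$e$P, tfs$i$P, cfg$dt, n_steps, transient_steps,
                       cfg$S, kHz(cfg$nu_aff), kHz(cfg$nu_drive),
                       kHz(cfg$sigma), cfg$tau_OU)
  }
  for (v in c("nu_e", "nu_i")) rec[[v]] <- rec[[v]] * 1e3
  for (v in c("c_ee", "c_ei", "c_ii")) rec[[v]] <- rec[[v]] * 1e6

  ts <- c(rec,
          list(times = (seq_len(n_steps - transient_steps) +
                          transient_steps) * cfg$dt,
               dt = cfg$dt, n_steps = n_steps, n_regions = n,
               labels = conn$labels, config = cfg, params = params))
  class(ts) <- "rate_timeseries"
  ts
}

#' @export
print.rate_timeseries <- function(x, ...) {
  cat(sprintf(paste0("rate time series: %d regions, %d samples at ",
                     "dt = %g ms (t in [%g, %g] ms)\n"),
              x$n_regions, nrow(x$nu_e), x$dt, min(x$times), max(x$times)))
  cat(sprintf("  nu_e: mean %.2f Hz, max %.2f Hz\n",
              mean(x$nu_e), max(x$nu_e)))
  invisible(x)
}

#' Save / load a simulated time series
#'
#' The container is R's native serialisation (one object holding every
#' state-variable array with the configuration attached).
#'
#' @param ts A `rate_timeseries` object.
#' @param path Output / input file path (conventionally `.rds`).
#' @return `read_timeseries` returns the `rate_timeseries`;
#'   `write_timeseries` returns `path` invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "rate_timeseries"))
  saveRDS(ts, path)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  ts <- readRDS(path)
  if (!inherits(ts, "rate_timeseries")) stop("not a rate_timeseries file")
  ts
}

#' Export excitatory rates as CSV
#'
#' One row per time sample: `time_ms` then one column per region.
#'
#' @inheritParams write_timeseries
#' @export
write_rates_csv <- function(ts, path) {
  stopifnot(inherits(ts, "rate_timeseries"))
  df <- data.frame(time_ms = ts$times, ts$nu_e)
  names(df) <- c("time_ms", ts$labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
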