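# Second-order AdEx mean-field node dynamics.
#
# Internal convention: rates in kHz, time in ms, potentials in mV,
# conductances in nS, capacitance in pF, currents in pA. All public
# interfaces express rates in Hz (and covariances in Hz^2); conversion
# happens only at the boundary.

# state-variable layout shared by the whole package
.STATE_VARS <- c("nu_e", "nu_i", "c_ee", "c_ei", "c_ii", "W_e", "W_i")

# tiny rate floor (kHz) keeping the fluctuation formulas defined at zero
# input (spontaneous synaptic release / intrinsic currents)
.RATE_FLOOR <- 1e-6

# finite-difference step for transfer-function derivatives: 1e-7 in the
# internal kHz state units. Following the public reference implementation
# of this mean-field, the difference quotients are formed over the step
# expressed in Hz (1e-4), i.e. the covariance-feedback and Hessian terms
# carry per-Hz derivative scalings. This numerical convention is part of
# the model as used in practice; restating the quotients per-kHz makes the
# second-order feedback ~1e3 stronger and destabilises the moment system.
.TF_DF <- 1e-7
.TF_DF_HZ <- .TF_DF * 1e3

.erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

# membrane-potential moments from shot-noise conductance fluctuations.
# fe_tot, fi: population rates (kHz); W: adaptation current (pA); E_L: the
# population's leakage reversal (mV). Vectorised over all arguments.
.moments <- function(fe_tot, fi, W, p, E_L) {
  # aggregated synaptic rates (kHz); clamped so that finite-difference
  # excursions just below zero stay in the formulas' domain
  fe_a <- pmax((fe_tot + .RATE_FLOOR) * p$K_e, 0)
  fi_a <- pmax((fi + .RATE_FLOOR) * p$K_i, 0)
  mu_Ge <- p$Q_e * p$tau_syn_e * fe_a        # mean conductances (nS)
  mu_Gi <- p$Q_i * p$tau_syn_i * fi_a
  mu_G <- p$g_L + mu_Ge + mu_Gi
  tau_m <- p$C_m / mu_G                      # effective membrane time (ms)
  mu_V <- (mu_Ge * p$E_exc + mu_Gi * p$E_inh + p$g_L * E_L - W) / mu_G
  U_e <- p$Q_e / mu_G * (p$E_exc - mu_V)     # single-event PSP amplitudes (mV)
  U_i <- p$Q_i / mu_G * (p$E_inh - mu_V)
  s_e <- fe_a * (U_e * p$tau_syn_e)^2
  s_i <- fi_a * (U_i * p$tau_syn_i)^2
  sigma_V <- sqrt(s_e / (2 * (p$tau_syn_e + tau_m)) +
                  s_i / (2 * (p$tau_syn_i + tau_m)))
  den <- s_e / (p$tau_syn_e + tau_m) + s_i / (p$tau_syn_i + tau_m)
  zero <- den <= 0
  tau_V <- (s_e + s_i + zero * tau_m) / (den + zero)
  list(mu_V = mu_V, sigma_V = sigma_V, tau_V = tau_V)
}

# effective threshold (mV): second-order polynomial in normalised moments.
# P is in Volts (as fitted); converted to mV at the end.
.eff_threshold <- function(mu_V, sigma_V, tau_VN, P) {
  V <- (mu_V + 60) / 10
  S <- (sigma_V - 4) / 6
  Tn <- (tau_VN - 0.5) / 1
  1000 * (P[1] + P[2] * V + P[3] * S + P[4] * Tn +
          P[5] * V^2 + P[6] * S^2 + P[7] * Tn^2 +
          P[8] * V * S + P[9] * V * Tn + P[10] * S * Tn)
}

# transfer function (kHz): first-passage erfc form with fitted threshold,
# clipped to the refractory-limited maximum.
.tf <- function(fe_tot, fi, W, p, P, E_L) {
  m <- .moments(fe_tot, fi, W, p, E_L)
  vthr <- .eff_threshold(m$mu_V, m$sigma_V, m$tau_V * p$g_L / p$C_m, P)
  rate <- .erfc((vthr - m$mu_V) / (sqrt(2) * m$sigma_V)) / (2 * m$tau_V)
  pmin(pmax(rate, 0), 1 / p$T_refrac)
}

# transfer function plus first/second input-derivatives by central finite
# differences on a 9-point stencil, batched across nodes.
# fe_tot, fi, W: vectors length n. Returns list of length-n vectors.
.tf_with_derivs <- function(fe_tot, fi, W, p, P, E_L) {
  n <- length(fe_tot)
  h <- .TF_DF
  off_e <- c(0, h, -h, 0, 0, h, h, -h, -h)
  off_i <- c(0, 0, 0, h, -h, h, -h, h, -h)
  fe <- rep(fe_tot, times = 9L) + rep(off_e, each = n)
  fi9 <- rep(fi, times = 9L) + rep(off_i, each = n)
  r <- .tf(fe, fi9, rep(W, times = 9L), p, P, E_L)
  dim(r) <- c(n, 9L)
  hz <- .TF_DF_HZ
  list(F = r[, 1L],
       d_e = (r[, 2L] - r[, 3L]) / (2 * hz),
       d_i = (r[, 4L] - r[, 5L]) / (2 * hz),
       d2_ee = (r[, 2L] - 2 * r[, 1L] + r[, 3L]) / hz^2,
       d2_ii = (r[, 4L] - 2 * r[, 1L] + r[, 5L]) / hz^2,
       d2_ei = (r[, 6L] - r[, 7L] - r[, 8L] + r[, 9L]) / (4 * hz^2))
}

# right-hand side of the seven mean-field equations, vectorised over nodes.
# state: n x 7 matrix (kHz / kHz^2 / pA); ext: external excitatory input
# per node (kHz). Returns n x 7 matrix of time-derivatives (per ms).
.derivs <- function(state, ext, p, P_e, P_i) {
  nu_e <- state[, 1L]; nu_i <- state[, 2L]
  c_ee <- state[, 3L]; c_ei <- state[, 4L]; c_ii <- state[, 5L]
  W_e <- state[, 6L]; W_i <- state[, 7L]
  fe_tot <- nu_e + ext

  e <- .tf_with_derivs(fe_tot, nu_i, W_e, p, P_e, p$E_L_e)
  i <- .tf_with_derivs(fe_tot, nu_i, W_i, p, P_i, p$E_L_i)

  # rate equations with second-order (covariance x Hessian) correction
  dnu_e <- ((e$F - nu_e) +
            0.5 * (c_ee * e$d2_ee + 2 * c_ei * e$d2_ei + c_ii * e$d2_ii)) / p$T
  dnu_i <- ((i$F - nu_i) +
            0.5 * (c_ee * i$d2_ee + 2 * c_ei * i$d2_ei + c_ii * i$d2_ii)) / p$T

  # covariance equations
  invT <- 1 / p$T
  fe_gap <- e$F - nu_e
  fi_gap <- i$F - nu_i
  dc_ee <- (e$F * (invT - e$F) / p$N_e + fe_gap^2 +
            2 * (e$d_e * c_ee + e$d_i * c_ei) - 2 * c_ee) / p$T
  # cross-covariance: derivative-times-covariance pairing as realised in
  # the reference implementation
  dc_ei <- (fe_gap * fi_gap +
            e$d_e * c_ee + (i$d_e + e$d_i) * c_ei +
            i$d_i * c_ii - 2 * c_ei) / p$T
  dc_ii <- (i$F * (invT - i$F) / p$N_i + fi_gap^2 +
            2 * (i$d_e * c_ei + i$d_i * c_ii) - 2 * c_ii) / p$T

  # adaptation: excitatory population carries b_e and a; the inhibitory
  # mirror has b_i = a_i = 0 and therefore decays to zero.
  if (p$a != 0) {
    mu_V_e <- .moments(fe_tot, nu_i, W_e, p, p$E_L_e)$mu_V
    dW_e <- -W_e / p$tau_w + p$b_e * nu_e + p$a * (mu_V_e - p$E_L_e) / p$tau_w
  } else {
    dW_e <- -W_e / p$tau_w + p$b_e * nu_e
  }
  dW_i <- -W_i / p$tau_w

  cbind(dnu_e, dnu_i, dc_ee, dc_ei, dc_ii, dW_e, dW_i, deparse.level = 0)
}

.as_state_matrix <- function(state) {
  if (is.null(dim(state))) {
    if (length(state) != 7L)
      stop("a node state needs the 7 components: ",
           paste(.STATE_VARS, collapse = ", "))
    state <- matrix(state, nrow = 1L,
                    dimnames = list(NULL, names(state)))
  }
  state <- as.matrix(state)
  if (ncol(state) != 7L) stop("state must have 7 columns")
  if (!is.null(colnames(state))) state <- state[, .STATE_VARS, drop = FALSE]
  colnames(state) <- .STATE_VARS
  if (any(!is.finite(state))) stop("state contains non-finite values")
  if (any(state[, 1:2] < 0)) stop("rates must be nonnegative")
  state
}

# Hz-facing <-> kHz-facing conversion for full state matrices
.state_to_internal <- function(s) {
  s[, 1:2] <- s[, 1:2] / 1e3
  s[, 3:5] <- s[, 3:5] / 1e6
  s
}
.state_to_public <- function(s) {
  s[, 1:2] <- s[, 1:2] * 1e3
  s[, 3:5] <- s[, 3:5] * 1e6
  s
}

#' Membrane-potential moments of an AdEx population
#'
#' Computes the mean, standard deviation and autocorrelation time of the
#' membrane potential of one population receiving Poissonian synaptic
#' bombardment at the given presynaptic rates, under the shot-noise
#' conductance formalism. These moments are the inputs of the
#' [transfer_function()].
#'
#' @param nu_e_tot Total excitatory presynaptic rate (Hz, per synapse).
#' @param nu_i Inhibitory presynaptic rate (Hz).
#' @param W Adaptation current (pA), subtracted from the input current.
#' @param p [adex_params()] object.
#' @param population Which population's leakage reversal potential to use.
#' @return A list with `mu_V` (mV), `sigma_V` (mV) and `tau_V` (ms);
#'   vectorised over the rate inputs.
#' @examples
#' p <- adex_params()
#' membrane_moments(0, 0, 0, p)$mu_V   # leak-only limit: ~E_L_e
#' @export
membrane_moments <- function(nu_e_tot, nu_i, W, p,
                             population = c("excitatory", "inhibitory")) {
  population <- match.arg(population)
  if (any(nu_e_tot < 0) || any(nu_i < 0))
    stop("presynaptic rates must be nonnegative")
  E_L <- if (population == "excitatory") p$E_L_e else p$E_L_i
  .moments(nu_e_tot / 1e3, nu_i / 1e3, W, p, E_L)
}

#' Population transfer function
#'
#' Output firing rate of an AdEx population receiving excitatory and
#' inhibitory input rates and carrying an adaptation current. The rate is
#' the first-passage complementary-error-function form
#' \deqn{\nu_{out} = \frac{1}{2\tau_V}\,
#'   \mathrm{erfc}\!\left(\frac{V_{thr}^{eff}-\mu_V}{\sqrt{2}\sigma_V}\right)}
#' with the effective threshold a fitted second-order polynomial in the
#' normalised membrane moments, clipped to the refractory-limited maximum
#' `1000/T_refrac` Hz.
#'
#' @inheritParams membrane_moments
#' @param tf [tf_params()] object selecting the population coefficient set.
#' @return Firing rate (Hz), vectorised over the inputs.
#' @examples
#' p <- adex_params()
#' tfs <- default_tf_params()
#' transfer_function(10, 10, 0, p, tfs$e)
#' @export
transfer_function <- function(nu_e_tot, nu_i, W, p, tf) {
  stopifnot(inherits(tf, "tf_params"))
  if (any(nu_e_tot < 0) || any(nu_i < 0))
    stop("presynaptic rates must be nonnegative")
  E_L <- if (tf$population == "excitatory") p$E_L_e else p$E_L_i
  m <- .moments(nu_e_tot / 1e3, nu_i / 1e3, W, p, E_L)
  bad <- !is.finite(m$mu_V) | !is.finite(m$sigma_V) | !is.finite(m$tau_V)
  if (any(bad))
    stop(sprintf(paste0("non-finite membrane moments at nu_e_tot = %g Hz, ",
                        "nu_i = %g Hz, W = %g pA"),
                 nu_e_tot[which(bad)[1]], nu_i[which(bad)[1]],
                 W[which(bad)[1]]))
  1e3 * .tf(nu_e_tot / 1e3, nu_i / 1e3, W, p, tf$P, E_L)
}

#' Right-hand side of the seven mean-field equations
#'
#' Time-derivatives of one node's state: the two population rates (with the
#' second-order covariance-times-Hessian correction, Hessian by central
#' finite differences), the three rate covariances (including the
#' finite-size source term scaled by the population sizes), and the two
#' adaptation currents (the inhibitory one carries no spike-triggered or
#' subthreshold adaptation and decays to zero).
#'
#' @param state Named numeric vector of length 7, or an `n x 7` matrix with
#'   columns `nu_e`, `nu_i` (Hz), `c_ee`, `c_ei`, `c_ii` (Hz^2), `W_e`,
#'   `W_i` (pA).
#' @param nu_e_tot_ext External excitatory input rate added to the node's
#'   own excitatory rate at the transfer-function input (Hz); scalar or
#'   one value per node.
#' @param p [adex_params()] object.
#' @param tf_e,tf_i Excitatory / inhibitory [tf_params()].
#' @return Derivatives in the same layout as `state`, per millisecond.
#' @export
meanfield_derivatives <- function(state, nu_e_tot_ext = 0, p,
                                  tf_e, tf_i) {
  stopifnot(inherits(tf_e, "tf_params"), inherits(tf_i, "tf_params"))
  vec <- is.null(dim(state))
  s <- .state_to_internal(.as_state_matrix(state))
  d <- .derivs(s, rep(nu_e_tot_ext / 1e3, length.out = nrow(s)),
               p, tf_e$P, tf_i$P)
  d <- .state_to_public(d)
  colnames(d) <- .STATE_VARS
  if (vec) d[1L, ] else d
}

# numerical Jacobian of f at x (central differences, scale-aware step)
.num_jac <- function(f, x) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- 1e-6 * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# damped Newton on f(x) = 0 with componentwise residual weights w
.newton <- function(f, x0, w, tol = 1e-9, max_iter = 100L) {
  x <- x0
  fx <- f(x)
  if (any(!is.finite(fx))) return(NULL)
  for (it in seq_len(max_iter)) {
    if (max(abs(fx * w)) < tol) break
    J <- .num_jac(f, x)
    step <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lam <- 1
    repeat {
      xn <- x - lam * step
      xn[1:2] <- pmax(xn[1:2], 0)       # rates stay nonnegative
      fn <- f(xn)
      ok <- all(is.finite(fn)) &&
        sum((fn * w)^2) <= sum((fx * w)^2) * (1 - 1e-4 * lam)
      if (ok || lam < 1e-6) break
      lam <- lam / 2
    }
    if (lam < 1e-6 && sum((fn * w)^2) >= sum((fx * w)^2)) return(NULL)
    x <- xn; fx <- fn
  }
  if (max(abs(fx * w)) >= tol) return(NULL)
  list(x = x, J = .num_jac(f, x))
}

#' Fixed points of a single noiseless mean-field node
#'
#' Root-finds the noiseless seven-equation node dynamics from a grid of
#' initial rate guesses spanning the physiological range up to the
#' refractory-limited maximum, deduplicates the roots, and classifies each
#' root's stability by the sign of the leading eigenvalue of the numerical
#' Jacobian. Typical outcomes are a low-rate Down fixed point, an Up fixed
#' point in the tens of Hz, and - for excitation-dominated parameters - a
#' pathological paroxysmal fixed point near the refractory-limited rate.
#'
#' @param nu_e_tot_external Constant external excitatory drive (Hz).
#' @param p [adex_params()] object.
#' @param tfs List with components `e` and `i` ([default_tf_params()]).
#' @param nu_guesses Initial excitatory-rate guesses (Hz).
#' @param dedup_tol Roots closer than this (Hz, on both rates) are merged.
#' @return A list of fixed points, each a list with `state` (named
#'   length-7 vector, Hz / Hz^2 / pA), `stable` (logical) and
#'   `eigenvalues`. Empty (with a warning) if no root converged.
#' @examples
#' \donttest{
#' p <- adex_params(E_L_e = -64, E_L_i = -64, b_e = 0)
#' fps <- find_fixed_points(0.315, p, default_tf_params())
#' }
#' @export
find_fixed_points <- function(nu_e_tot_external = 0, p, tfs,
                              nu_guesses = c(0.01, 1, 5, 10, 25, 50,
                                             100, 150, 175, 195),
                              dedup_tol = 1e-3) {
  stopifnot(inherits(tfs$e, "tf_params"), inherits(tfs$i, "tf_params"))
  ext <- nu_e_tot_external / 1e3
  f <- function(x) {
    as.vector(.derivs(matrix(x, 1L, 7L), ext, p, tfs$e$P, tfs$i$P))
  }
  # residual weights: rates (kHz/ms), covariances (kHz^2/ms, tiny),
  # adaptation (pA/ms, large scale)
  w <- c(1, 1, 1e4, 1e4, 1e4, 1e-3, 1e-3)
  roots <- list()
  for (g in nu_guesses) {
    nu <- g / 1e3
    x0 <- c(nu, nu, 0, 0, 0, p$b_e * p$tau_w * nu, 0)
    sol <- .newton(f, x0, w)
    if (is.null(sol)) next
    nu_e_hz <- sol$x[1] * 1e3
    nu_i_hz <- sol$x[2] * 1e3
    dup <- any(vapply(roots, function(r)
      abs(r$state[["nu_e"]] - nu_e_hz) < dedup_tol &&
      abs(r$state[["nu_i"]] - nu_i_hz) < dedup_tol, logical(1)))
    if (dup) next
    ev <- eigen(sol$J, only.values = TRUE)$values
    st <- .state_to_public(matrix(sol$x, 1L, 7L))[1L, ]
    names(st) <- .STATE_VARS
    roots[[length(roots) + 1L]] <- list(state = st,
                                        stable = max(Re(ev)) < 0,
                                        eigenvalues = ev)
  }
  if (length(roots) == 0L)
    warning("no fixed point converged from any initial guess")
  roots
}
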