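#' Model parameters for one AdEx mean-field node
#'
#' Bundles every node-level constant of the second-order AdEx mean-field
#' model: the mean-field timescale `T`, the adaptation parameters (`b_e`,
#' `a`, `tau_w`), the leakage reversal potentials of the excitatory and
#' inhibitory populations, the population sizes, and the single-neuron /
#' synaptic constants of the underlying spiking network.
#'
#' Defaults follow the standard AdEx mean-field parameterisation of a
#' 10^4-neuron cortical network (80% excitatory, 20% inhibitory, 5%
#' connection probability, hence `K_e = 400` excitatory and `K_i = 100`
#' inhibitory inputs per neuron).
#'
#' @param T Mean-field timescale (ms). Sets how fast population rates relax
#'   towards the transfer function.
#' @param b_e Spike-triggered adaptation increment of excitatory neurons (pA).
#' @param a Subthreshold adaptation conductance (nS); 0 by default.
#' @param E_L_e,E_L_i Leakage reversal potentials of excitatory and
#'   inhibitory neurons (mV).
#' @param tau_w Adaptation time constant (ms).
#' @param N_e,N_i Number of excitatory / inhibitory neurons in the modelled
#'   population.
#' @param C_m Membrane capacitance (pF).
#' @param g_L Leak conductance (nS).
#' @param E_exc,E_inh Excitatory / inhibitory synaptic reversal potentials (mV).
#' @param Q_e,Q_i Excitatory / inhibitory synaptic quantal conductances (nS).
#' @param tau_syn_e,tau_syn_i Synaptic decay time constants (ms).
#' @param T_refrac Refractory period (ms); caps rates at `1000/T_refrac` Hz.
#' @param K_e,K_i Number of recurrent excitatory / inhibitory synapses per
#'   neuron.
#'
#' @return An object of class `adex_params` (a named list).
#' @examples
#' p <- adex_params(b_e = 60, E_L_e = -64, E_L_i = -64)
#' p$T
#' @export
adex_params <- function(T = 19, b_e = 60, a = 0,
                        E_L_e = -64, E_L_i = -64,
                        tau_w = 500,
                        N_e = 8000, N_i = 2000,
                        C_m = 200, g_L = 10,
                        E_exc = 0, E_inh = -80,
                        Q_e = 1.5, Q_i = 5,
                        tau_syn_e = 5, tau_syn_i = 5,
                        T_refrac = 5,
                        K_e = 400, K_i = 100) {
  stopifnot(T > 0, tau_w > 0, N_e > 0, N_i > 0, C_m > 0, g_L > 0,
            Q_e > 0, Q_i > 0, tau_syn_e > 0, tau_syn_i > 0, T_refrac > 0,
            K_e > 0, K_i > 0, b_e >= 0, a >= 0)
  p <- list(T = T, b_e = b_e, a = a, E_L_e = E_L_e, E_L_i = E_L_i,
            tau_w = tau_w, N_e = N_e, N_i = N_i, C_m = C_m, g_L = g_L,
            E_exc = E_exc, E_inh = E_inh, Q_e = Q_e, Q_i = Q_i,
            tau_syn_e = tau_syn_e, tau_syn_i = tau_syn_i,
            T_refrac = T_refrac, K_e = K_e, K_i = K_i)
  class(p) <- "adex_params"
  p
}

#' @export
print.adex_params <- function(x, ...) {
  cat("AdEx mean-field parameters\n")
  cat(sprintf("  T = %g ms, b_e = %g pA, a = %g nS, tau_w = %g ms\n",
              x$T, x$b_e, x$a, x$tau_w))
  cat(sprintf("  E_L_e = %g mV, E_L_i = %g mV\n", x$E_L_e, x$E_L_i))
  cat(sprintf("  N_e = %d, N_i = %d (K_e = %d, K_i = %d)\n",
              x$N_e, x$N_i, x$K_e, x$K_i))
  invisible(x)
}

#' Transfer-function coefficients for one population
#'
#' The mean-field transfer function maps presynaptic excitatory and
#' inhibitory rates (and the adaptation current) to an output firing rate
#' through the first two membrane-potential moments and a fitted
#' *effective threshold*: a second-order polynomial in the normalised
#' moments \eqn{(\mu_V, \sigma_V, \tau_V^N)}. The ten polynomial
#' coefficients are population-specific data obtained semi-analytically
#' from single-neuron simulations; they are shipped as a coefficient table
#' (see [read_tf_coefficients()]) and can be overridden.
#'
#' @param population `"excitatory"` or `"inhibitory"`: selects which
#'   coefficient set and which leakage reversal potential the transfer
#'   function uses.
#' @param P Numeric vector of 10 polynomial coefficients in Volts
#'   (order: constant, the three linear terms in \eqn{\mu_V, \sigma_V,
#'   \tau_V^N}, the three quadratic terms, the three cross terms). Defaults
#'   to the shipped table.
#' @return An object of class `tf_params`.
#' @examples
#' tfs <- default_tf_params()
#' tfs$e$P
#' @export
tf_params <- function(population = c("excitatory", "inhibitory"), P = NULL) {
  population <- match.arg(population)
  if (is.null(P)) P <- read_tf_coefficients()[[population]]
  P <- as.numeric(P)
  if (length(P) != 10 || any(!is.finite(P)))
    stop("`P` must be 10 finite polynomial coefficients")
  structure(list(population = population, P = P), class = "tf_params")
}

#' Read a transfer-function coefficient table
#'
#' @param path Path to a JSON file with numeric fields `excitatory` and
#'   `inhibitory` (10 coefficients each, in Volts). Defaults to the table
#'   shipped with the package.
#' @return A list with elements `excitatory` and `inhibitory`.
#' @export
read_tf_coefficients <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "tf_coefficients.json", package = "adexnet",
                        mustWork = TRUE)
  tab <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (pop in c("excitatory", "inhibitory")) {
    if (is.null(tab[[pop]]) || length(tab[[pop]]) != 10 ||
        any(!is.finite(tab[[pop]])))
      stop("coefficient table must contain 10 finite values for '", pop, "'")
  }
  tab[c("excitatory", "inhibitory")]
}

#' Default excitatory/inhibitory transfer-function pair
#'
#' @param path Optional path to an alternative coefficient table
#'   (see [read_tf_coefficients()]).
#' @return A list with components `e` and `i`, each a [tf_params()] object.
#' @export
default_tf_params <- function(path = NULL) {
  tab <- read_tf_coefficients(path)
  list(e = tf_params("excitatory", tab$excitatory),
       i = tf_params("inhibitory", tab$inhibitory))
}
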