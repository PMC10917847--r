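# shared fixtures, all built in code

TFS <- default_tf_params()

depol_params <- function(b_e = 0, T = 19) {
  adex_params(E_L_e = -64, E_L_i = -64, b_e = b_e, T = T)
}

hyper_params <- function(b_e = 0, T = 19) {
  adex_params(E_L_e = -80, E_L_i = -78.667, b_e = b_e, T = T)
}

toy_conn <- function(n = 8, density = 0.5, seed = 2) {
  generate_synthetic_connectome(n, density, seed)
}

# two disconnected nodes: lets the compiled network core run "single node"
# scenarios (the generator requires n >= 2)
pair_conn <- function() connectome(diag(2), matrix(0, 2, 2))

# wrap a samples-by-nodes matrix as a minimal rate time series
mat_ts <- function(mat, dt = 1) {
  structure(list(nu_e = mat, times = seq_len(nrow(mat)) * dt, dt = dt,
                 n_regions = ncol(mat),
                 labels = sprintf("R%03d", seq_len(ncol(mat)) - 1L)),
            class = "rate_timeseries")
}

# longest run of nu_e < thr per node, in ms
zero_epoch_ms <- function(ts, thr = 1) {
  apply(ts$nu_e < thr, 2L, function(v) {
    r <- rle(v)
    m <- r$lengths[r$values]
    if (length(m)) max(m) * ts$dt else 0
  })
}
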