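# Feature extraction on spontaneous activity: firing-rate statistics,
# Up-state durations, node-averaged power spectrum, functional
# connectivity, and the paroxysm flag. All features are computed from the
# excitatory rates nu_e of the post-transient window.

.nu_e_matrix <- function(ts) {
  if (inherits(ts, "rate_timeseries")) ts$nu_e
  else as.matrix(ts)
}

#' Detect paroxysmal activity
#'
#' A simulation exhibits a paroxysmal fixed point when any node's
#' excitatory rate strictly exceeds the threshold: physiological activity
#' stays well below it, and only the pathological high-activity fixed
#' point (near the refractory-limited rate) reaches such values.
#'
#' @param ts A `rate_timeseries` (or a samples-by-nodes matrix of `nu_e`,
#'   Hz).
#' @param threshold Detection threshold (Hz).
#' @return `TRUE` iff `max(nu_e) > threshold` (strict).
#' @export
detect_paroxysm <- function(ts, threshold = 175) {
  x <- .nu_e_matrix(ts)
  if (length(x) == 0L) stop("empty series")
  max(x) > threshold
}

#' Basic firing-rate statistics
#'
#' @inheritParams detect_paroxysm
#' @return A list with `max_nu_e` (max over nodes and time), `mean_nu_e`
#'   (grand mean) and `mean_sd_nu_e` (per-node SD over time, averaged over
#'   nodes), all in Hz. SDs use the population (1/n) normalisation, so a
#'   deterministic square wave has exactly its amplitude-based SD.
#' @export
basic_stats <- function(ts) {
  x <- .nu_e_matrix(ts)
  if (length(x) == 0L) stop("empty series")
  n <- nrow(x)
  sds <- sqrt(colMeans(x^2) - colMeans(x)^2)
  sds[sds < 0 | is.na(sds)] <- 0
  list(max_nu_e = max(x), mean_nu_e = mean(x), mean_sd_nu_e = mean(sds))
}

# contiguous supra-threshold epochs of one node's rate trace
.up_epochs_ms <- function(v, threshold, dt) {
  r <- rle(v > threshold)
  r$lengths[r$values] * dt
}

#' Mean Up-state duration
#'
#' Per node, contiguous epochs where `nu_e` exceeds a threshold count as
#' Up states; epochs shorter than `min_ms` are discarded. The mean Up
#' duration of each node is then averaged over nodes, nodes without Up
#' states contributing 0. The threshold is a fraction of each node's
#' maximum rate (the detection rule is a stated convention,
#' config-exposed).
#'
#' @inheritParams detect_paroxysm
#' @param threshold_frac Per-node threshold as a fraction of that node's
#'   maximum rate.
#' @param min_ms Minimum epoch duration (ms) to count as an Up state.
#' @param dt Sample spacing (ms); taken from the series when available.
#' @return Node-averaged mean Up-state duration (ms).
#' @export
mean_up_duration <- function(ts, threshold_frac = 0.2, min_ms = 20,
                             dt = NULL) {
  x <- .nu_e_matrix(ts)
  if (length(x) == 0L) stop("empty series")
  if (is.null(dt))
    dt <- if (inherits(ts, "rate_timeseries")) ts$dt else 1
  per_node <- apply(x, 2L, function(v) {
    ep <- .up_epochs_ms(v, threshold_frac * max(v), dt)
    ep <- ep[ep >= min_ms]
    if (length(ep) == 0L) 0 else mean(ep)
  })
  mean(per_node)
}

#' Frequency at the peak of the node-averaged power spectrum
#'
#' Each node's mean-subtracted `nu_e` trace is Fourier transformed with a
#' rectangular window; the squared magnitudes are averaged over nodes into
#' one PSD curve. The returned frequency is that of the highest-power
#' non-DC local maximum whose power reaches `prominence` times the
#' spectrum maximum; 0 when no such peak exists (e.g. flat spectra).
#' Mean subtraction makes the result invariant to constant offsets.
#'
#' @inheritParams detect_paroxysm
#' @param prominence Minimum peak power as a fraction of the spectrum
#'   maximum.
#' @param dt Sample spacing (ms); taken from the series when available.
#' @return Peak frequency (Hz); 0 if no peak passes the threshold.
#' @export
psd_peak_frequency <- function(ts, prominence = 0.05, dt = NULL) {
  x <- .nu_e_matrix(ts)
  if (nrow(x) < 2L) stop("need at least 2 samples")
  if (is.null(dt))
    dt <- if (inherits(ts, "rate_timeseries")) ts$dt else 1
  n <- nrow(x)
  xc <- sweep(x, 2L, colMeans(x))
  psd <- rowMeans(abs(stats::mvfft(xc))^2)
  nf <- floor(n / 2)                       # positive-frequency bins 2..nf+1
  if (nf < 2L) return(0)
  s <- psd[2:(nf + 1L)]
  if (max(s) <= 0) return(0)
  freqs <- (1:nf) / (n * dt * 1e-3)        # Hz
  left <- c(0, s[-length(s)])              # DC excluded from comparison
  right <- c(s[-1L], 0)
  is_peak <- s > left & s >= right & s >= prominence * max(s)
  if (!any(is_peak)) return(0)
  freqs[which(is_peak)[which.max(s[is_peak])]]
}

#' Functional connectivity matrix
#'
#' Pearson correlation of `nu_e` between every pair of nodes. A node with
#' zero rate variance has no defined correlation; by convention its
#' correlations with other nodes are 0 and its self-correlation 1, so
#' that a constant network yields a well-defined matrix instead of NaNs.
#'
#' @inheritParams detect_paroxysm
#' @return Symmetric `n x n` matrix with unit diagonal, entries clipped
#'   to `[-1, 1]`.
#' @export
functional_connectivity <- function(ts) {
  x <- .nu_e_matrix(ts)
  if (nrow(x) < 2L) stop("need at least 2 samples")
  sds <- apply(x, 2L, stats::sd)
  fc <- suppressWarnings(stats::cor(x))
  fc[!is.finite(fc)] <- 0
  zero <- sds == 0
  fc[zero, ] <- 0
  fc[, zero] <- 0
  diag(fc) <- 1
  fc <- (fc + t(fc)) / 2
  pmin(pmax(fc, -1), 1)
}

#' Correlation between functional and structural connectivity
#'
#' Pearson correlation of the flattened FC matrix against the flattened
#' structural weights (diagonal included by default, matching the
#' flattened-array definition). Returns 0 by convention when either
#' flattened array has zero variance.
#'
#' @param fc `n x n` functional-connectivity matrix.
#' @param c A [connectome] object (or an `n x n` weights matrix).
#' @param include_diag Keep the diagonals in the flattened vectors.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
corr_fc_sc <- function(fc, c, include_diag = TRUE) {
  w <- if (inherits(c, "connectome")) c$weights else as.matrix(c)
  fc <- as.matrix(fc)
  if (!all(dim(fc) == dim(w)))
    stop(sprintf("FC is %d x %d but SC is %d x %d", nrow(fc), ncol(fc),
                 nrow(w), ncol(w)))
  a <- as.vector(fc)
  b <- as.vector(w)
  if (!include_diag) {
    keep <- as.vector(row(fc) != col(fc))
    a <- a[keep]
    b <- b[keep]
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  min(max(stats::cor(a, b), -1), 1)
}

#' Extract the full feature set of a simulation
#'
#' Composes all feature operations on the post-transient window: maximum,
#' mean and node-averaged SD of `nu_e`, mean Up-state duration, frequency
#' at the PSD peak, mean functional connectivity (all matrix entries,
#' diagonal included), its correlation with the structural weights, and
#' the paroxysm flag.
#'
#' @param ts A `rate_timeseries`.
#' @param conn The [connectome] the simulation ran on.
#' @param up_threshold_frac,up_min_ms Up-state detection settings
#'   (see [mean_up_duration()]).
#' @param psd_prominence Peak-detection setting
#'   (see [psd_peak_frequency()]).
#' @param fc_include_diag Include the diagonal in `mean_FC` (the mean of
#'   the full matrix, as the feature is defined).
#' @param fcsc_include_diag Include the diagonals in the FC-SC
#'   flattening. Off by default: both matrices carry a unit diagonal, and
#'   with sparse structural weights the diagonal match dominates the
#'   correlation and inverts its dependence on adaptation; the
#'   off-diagonal statistic isolates the inter-regional structure the
#'   comparison is about.
#' @param paroxysm_threshold Threshold (Hz) for [detect_paroxysm()].
#' @return An object of class `feature_set`: a named list with
#'   `max_nu_e`, `mean_nu_e`, `mean_sd_nu_e` (Hz), `mean_up_duration`
#'   (ms), `psd_peak_freq` (Hz), `mean_FC`, `corrFCSC` (dimensionless)
#'   and `is_paroxysmal` (logical).
#' @export
extract_features <- function(ts, conn, up_threshold_frac = 0.2,
                             up_min_ms = 20, psd_prominence = 0.05,
                             fc_include_diag = TRUE,
                             fcsc_include_diag = FALSE,
                             paroxysm_threshold = 175) {
  st <- basic_stats(ts)
  fc <- functional_connectivity(ts)
  mean_fc <- if (fc_include_diag) mean(fc)
             else mean(fc[row(fc) != col(fc)])
  out <- list(
    max_nu_e = st$max_nu_e,
    mean_nu_e = st$mean_nu_e,
    mean_sd_nu_e = st$mean_sd_nu_e,
    mean_up_duration = mean_up_duration(ts, up_threshold_frac, up_min_ms),
    psd_peak_freq = psd_peak_frequency(ts, psd_prominence),
    mean_FC = mean_fc,
    corrFCSC = corr_fc_sc(fc, conn, include_diag = fcsc_include_diag),
    is_paroxysmal = detect_paroxysm(ts, paroxysm_threshold))
  class(out) <- "feature_set"
  out
}

#' @export
print.feature_set <- function(x, ...) {
  cat("features:\n")
  cat(sprintf("  max nu_e      %10.3f Hz\n", x$max_nu_e))
  cat(sprintf("  mean nu_e     %10.3f Hz\n", x$mean_nu_e))
  cat(sprintf("  mean SD nu_e  %10.3f Hz\n", x$mean_sd_nu_e))
  cat(sprintf("  mean Up dur.  %10.1f ms\n", x$mean_up_duration))
  cat(sprintf("  PSD peak      %10.3f Hz\n", x$psd_peak_freq))
  cat(sprintf("  mean FC       %10.4f\n", x$mean_FC))
  cat(sprintf("  corrFCSC      %10.4f\n", x$corrFCSC))
  cat(sprintf("  paroxysmal    %10s\n", x$is_paroxysmal))
  invisible(x)
}

#' @export
as.data.frame.feature_set <- function(x, ...) {
  data.frame(max_nu_e = x$max_nu_e, mean_nu_e = x$mean_nu_e,
             mean_sd_nu_e = x$mean_sd_nu_e,
             mean_up_duration = x$mean_up_duration,
             psd_peak_freq = x$psd_peak_freq, mean_FC = x$mean_FC,
             corrFCSC = x$corrFCSC, is_paroxysmal = x$is_paroxysmal)
}
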