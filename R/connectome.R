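# Structural connectomes: validated container, synthetic generator, and
# TVB-style plain-text reader/writer (weights.txt, tract_lengths.txt,
# centres.txt in a directory or zip).

#' Structural connectome container
#'
#' Holds the inter-regional coupling-strength matrix \eqn{C_{jk}}
#' (dimensionless, unit diagonal \eqn{C_{kk} = 1}), the tract-length
#' matrix (mm, symmetric, zero diagonal), region labels and, optionally,
#' region centres (mm).
#'
#' @param weights `n x n` nonnegative matrix of coupling strengths.
#' @param tract_lengths `n x n` nonnegative symmetric matrix (mm).
#' @param labels Character vector of `n` region names; autogenerated
#'   (`R000`, `R001`, ...) when empty or `NULL`.
#' @param centres Optional `n x 3` matrix of region centres (mm).
#' @return An object of class `connectome`.
#' @export
connectome <- function(weights, tract_lengths, labels = NULL,
                       centres = NULL) {
  weights <- as.matrix(weights)
  tract_lengths <- as.matrix(tract_lengths)
  n <- nrow(weights)
  if (ncol(weights) != n)
    stop("`weights` must be square")
  if (!all(dim(tract_lengths) == c(n, n)))
    stop(sprintf("`tract_lengths` is %d x %d but `weights` is %d x %d",
                 nrow(tract_lengths), ncol(tract_lengths), n, n))
  if (any(!is.finite(weights)) || any(!is.finite(tract_lengths)))
    stop("connectome matrices must be finite")
  if (any(weights < 0) || any(tract_lengths < 0))
    stop("connectome matrices must be nonnegative")
  if (any(abs(diag(weights) - 1) > 1e-12)) {
    warning("weights diagonal coerced to 1 (C_kk = 1 convention)")
    diag(weights) <- 1
  }
  if (max(abs(tract_lengths - t(tract_lengths))) > 1e-8) {
    warning("tract_lengths symmetrised (averaged with its transpose)")
    tract_lengths <- (tract_lengths + t(tract_lengths)) / 2
  }
  diag(tract_lengths) <- 0
  if (is.null(labels) || length(labels) == 0L)
    labels <- sprintf("R%03d", seq_len(n) - 1L)
  if (length(labels) != n)
    stop("`labels` must have one entry per region")
  if (!is.null(centres)) {
    centres <- as.matrix(centres)
    if (!all(dim(centres) == c(n, 3L)))
      stop("`centres` must be an n x 3 matrix")
  }
  dimnames(weights) <- dimnames(tract_lengths) <- NULL
  structure(list(n_regions = n, weights = weights,
                 tract_lengths = tract_lengths,
                 labels = as.character(labels), centres = centres),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  offd <- x$weights[row(x$weights) != col(x$weights)]
  cat(sprintf("connectome: %d regions, %.1f%% nonzero off-diagonal weights\n",
              x$n_regions, 100 * mean(offd > 0)))
  cat(sprintf("  tract lengths: %.1f-%.1f mm\n",
              min(x$tract_lengths[x$tract_lengths > 0]),
              max(x$tract_lengths)))
  invisible(x)
}

#' Generate a synthetic structural connectome
#'
#' Stand-in for tractography data so that the whole pipeline runs without
#' external downloads. Region centres are sampled uniformly in a cube of
#' side `box` mm (so conduction delays land in the few-ms range at
#' physiological axonal speeds); tract lengths are the pairwise Euclidean
#' distances; off-diagonal weights are symmetric log-normal draws
#' (heavy-tailed, like empirical tractography strengths) rescaled to a
#' maximum off-diagonal weight of 1, with a `1 - density` fraction of
#' region pairs zeroed symmetrically; the diagonal is set to 1
#' (\eqn{C_{kk} = 1}).
#'
#' @param n_regions Number of regions (>= 2); 68 matches the cortical
#'   parcellation used for whole-brain work.
#' @param density Fraction of off-diagonal region pairs with a nonzero
#'   connection, in `(0, 1]`.
#' @param seed Integer seed; the result is a deterministic function of
#'   `(n_regions, density, seed)`.
#' @param meanlog,sdlog Log-scale location and spread of the weight
#'   distribution before rescaling.
#' @param box Side of the sampling cube for region centres (mm).
#' @return A [connectome] object (with `centres` filled in).
#' @examples
#' conn <- generate_synthetic_connectome(68, density = 0.4, seed = 7)
#' all(diag(conn$weights) == 1)
#' @export
generate_synthetic_connectome <- function(n_regions, density = 0.4,
                                          seed = 1L, meanlog = -2,
                                          sdlog = 1, box = 100) {
  if (length(n_regions) != 1L || n_regions < 2 ||
      n_regions != round(n_regions))
    stop("`n_regions` must be an integer >= 2")
  if (density <= 0 || density > 1)
    stop("`density` must be in (0, 1]")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  n <- as.integer(n_regions)
  centres <- matrix(stats::runif(3L * n, 0, box), n, 3L)
  tract <- as.matrix(stats::dist(centres))
  dimnames(tract) <- NULL

  w <- matrix(0, n, n)
  upper <- which(upper.tri(w))
  w[upper] <- stats::rlnorm(length(upper), meanlog, sdlog)
  n_zero <- floor((1 - density) * length(upper))
  if (n_zero > 0)
    w[sample(upper, n_zero)] <- 0
  w <- w + t(w)                       # symmetric, zero diagonal so far
  # normalise to unit mean in-strength: empirical whole-brain couplings are
  # used after region-sum scaling, and the network's dynamical landscape
  # (where coupling strengths S in [0, 0.5] put the model between isolated
  # and paroxysm-prone regimes) presumes afferent sums of order 1
  ms <- mean(colSums(w))
  if (ms > 0) w <- w / ms
  diag(w) <- 1
  connectome(w, tract, centres = centres)
}

.read_table_file <- function(path) {
  m <- tryCatch(as.matrix(utils::read.table(path, header = FALSE)),
                error = function(e)
                  stop(sprintf("cannot read '%s': %s", path,
                               conditionMessage(e)), call. = FALSE))
  if (!is.numeric(m))
    stop(sprintf("'%s' contains non-numeric entries", path), call. = FALSE)
  dimnames(m) <- NULL
  m
}

#' Read a connectome from a TVB-style text bundle
#'
#' Accepts a directory or zip archive containing whitespace-delimited
#' `weights.txt` and `tract_lengths.txt` (equal square shapes) and
#' optionally `centres.txt` (label, x, y, z per row). A weights diagonal
#' differing from 1 is coerced to 1 with a warning; no other
#' normalisation is applied (the matrix is recorded as given).
#'
#' @param path Directory or `.zip` file.
#' @return A [connectome] object.
#' @export
read_connectome <- function(path) {
  if (length(path) != 1L || !file.exists(path))
    stop(sprintf("'%s' does not exist", path))
  dir <- path
  if (!dir.exists(path)) {
    dir <- tempfile("connectome_")
    utils::unzip(path, exdir = dir)
    # tolerate a single top-level folder inside the archive
    entries <- list.files(dir, full.names = TRUE)
    if (length(entries) == 1L && dir.exists(entries))
      dir <- entries
  }
  wfile <- file.path(dir, "weights.txt")
  lfile <- file.path(dir, "tract_lengths.txt")
  for (f in c(wfile, lfile))
    if (!file.exists(f))
      stop(sprintf("required file '%s' is missing", f))
  w <- .read_table_file(wfile)
  l <- .read_table_file(lfile)
  if (nrow(w) != ncol(w))
    stop(sprintf("'%s' is not square (%d x %d)", wfile, nrow(w), ncol(w)))
  if (!all(dim(l) == dim(w)))
    stop(sprintf("'%s' is %d x %d but '%s' is %d x %d", lfile, nrow(l),
                 ncol(l), wfile, nrow(w), ncol(w)))
  if (any(w < 0)) stop(sprintf("'%s' has negative entries", wfile))
  if (any(l < 0)) stop(sprintf("'%s' has negative entries", lfile))
  labels <- NULL
  centres <- NULL
  cfile <- file.path(dir, "centres.txt")
  if (file.exists(cfile)) {
    cc <- utils::read.table(cfile, header = FALSE,
                            colClasses = c("character", rep("numeric", 3L)))
    if (nrow(cc) != nrow(w))
      stop(sprintf("'%s' has %d rows but the matrices are %d x %d", cfile,
                   nrow(cc), nrow(w), nrow(w)))
    labels <- cc[[1L]]
    centres <- as.matrix(cc[, 2:4])
  }
  connectome(w, l, labels = labels, centres = centres)
}

#' Write a connectome as a TVB-style text bundle
#'
#' Emits `weights.txt`, `tract_lengths.txt` and `centres.txt` (label plus
#' 3-D position; zeros when the connectome has no centres) into a
#' directory, in the same layout [read_connectome()] accepts.
#'
#' @param c A [connectome] object.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_connectome <- function(c, path) {
  stopifnot(inherits(c, "connectome"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path))
    stop(sprintf("cannot create directory '%s'", path))
  fmt <- function(m) apply(m, 1L, function(r)
    paste(format(r, digits = 17, scientific = TRUE, trim = TRUE),
          collapse = " "))
  writeLines(fmt(c$weights), file.path(path, "weights.txt"))
  writeLines(fmt(c$tract_lengths), file.path(path, "tract_lengths.txt"))
  centres <- if (is.null(c$centres)) matrix(0, c$n_regions, 3L) else c$centres
  writeLines(paste(c$labels,
                   fmt(centres)),
             file.path(path, "centres.txt"))
  invisible(path)
}
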