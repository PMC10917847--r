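# Adaptation-indexed feature traces and their K-means classification:
# for each fixed (S, E_L_i, E_L_e, T) tuple, how mean FC or corrFCSC
# evolves as spike-frequency adaptation b_e increases, and which classes
# of behaviour those traces fall into.

#' Assemble adaptation-indexed feature traces
#'
#' Fixes `(S, E_L_i, E_L_e, T)` and collects the chosen feature as a
#' function of increasing `b_e`, one trace per tuple. Traces containing
#' any paroxysmal constituent simulation (or missing feature values from
#' failed runs) are marked invalid and excluded from clustering.
#'
#' @param table A `sweep_result` (or equivalent data.frame) complete over
#'   the grid: every `(S, E_L_i, E_L_e, T)` tuple present must cover the
#'   same set of `b_e` values.
#' @param feature_name `"mean_FC"` or `"corrFCSC"` (any numeric feature
#'   column works).
#' @return An object of class `feature_traces`: `keys` (one row per
#'   tuple), `b_e` (the adaptation values), `values` (traces as a
#'   `n_traces x n_b_e` matrix), `valid` (logical), `feature`.
#' @export
build_traces <- function(table, feature_name = c("mean_FC", "corrFCSC")) {
  feature_name <- feature_name[1L]
  need <- c("S", "E_L_i", "E_L_e", "T", "b_e", feature_name,
            "is_paroxysmal")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0L)
    stop("table lacks columns: ", paste(miss, collapse = ", "))
  b_e_values <- sort(unique(table$b_e))
  n_be <- length(b_e_values)
  o <- order(table$S, table$E_L_i, table$E_L_e, table$T, table$b_e)
  tab <- table[o, , drop = FALSE]
  if (nrow(tab) %% n_be != 0L ||
      !all(tab$b_e == rep(b_e_values, nrow(tab) / n_be))) {
    key <- paste(tab$S, tab$E_L_i, tab$E_L_e, tab$T, sep = "/")
    cnt <- table(key)
    bad <- names(cnt)[cnt != n_be]
    stop(sprintf(paste0("incomplete grid: %d (S/E_L_i/E_L_e/T) tuples do ",
                        "not cover all %d b_e values, e.g. %s"),
                 length(bad), n_be, paste(utils::head(bad, 3L),
                                          collapse = ", ")))
  }
  n_traces <- nrow(tab) / n_be
  first <- seq(1L, nrow(tab), by = n_be)
  keys <- tab[first, c("S", "E_L_i", "E_L_e", "T"), drop = FALSE]
  rownames(keys) <- NULL
  values <- matrix(tab[[feature_name]], n_traces, n_be, byrow = TRUE)
  parox <- matrix(tab$is_paroxysmal %in% TRUE, n_traces, n_be,
                  byrow = TRUE)
  incomplete <- matrix(!is.finite(tab[[feature_name]]), n_traces, n_be,
                       byrow = TRUE)
  valid <- rowSums(parox | incomplete) == 0L
  structure(list(keys = keys, b_e = b_e_values, values = values,
                 valid = valid, feature = feature_name),
            class = "feature_traces")
}

#' @export
print.feature_traces <- function(x, ...) {
  cat(sprintf("%d %s(b_e) traces over %d b_e values (%d valid)\n",
              nrow(x$values), x$feature, length(x$b_e), sum(x$valid)))
  invisible(x)
}

# k-means++ seeding: spread the initial centroids with probability
# proportional to squared distance from the chosen set
.kmeanspp_init <- function(X, k) {
  m <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1L, ] <- X[sample.int(m, 1L), ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  for (j in seq_len(k)[-1L]) {
    if (max(d2) <= 0) return(centers[seq_len(j - 1L), , drop = FALSE])
    centers[j, ] <- X[sample.int(m, 1L, prob = d2), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
  }
  centers
}

#' Cluster feature traces with K-means
#'
#' K-means on the valid traces viewed as points in `n_b_e` dimensions,
#' k-means++-style seeding with `nstart` restarts, best inertia kept.
#' Traces are clustered on raw values (FC and corrFCSC are already
#' bounded and commensurate). Classes are relabelled canonically by
#' ascending centroid value at the lowest `b_e`, so labels are
#' reproducible across runs.
#'
#' @param traces A [build_traces()] object.
#' @param k Number of classes (a plotting-resolution choice; default 6).
#' @param seed Integer seed for the restarts.
#' @param nstart Number of k-means++ restarts.
#' @return An object of class `trace_class_model`: `k`, `centroids`
#'   (`k x n_b_e`, rows in canonical order), `labels` (per trace, `NA`
#'   for invalid traces), `inertia`, `sizes`, `seed`, plus the trace
#'   `keys`, `b_e` and `feature` for downstream joins.
#' @export
cluster_traces <- function(traces, k = 6L, seed = 1L, nstart = 10L) {
  stopifnot(inherits(traces, "feature_traces"))
  X <- traces$values[traces$valid, , drop = FALSE]
  if (nrow(X) < k)
    stop(sprintf("only %d valid traces for k = %d clusters", nrow(X), k))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  best <- NULL
  for (r in seq_len(nstart)) {
    init <- .kmeanspp_init(X, k)
    fit <- suppressWarnings(
      stats::kmeans(X, centers = init, iter.max = 100L))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss)
      best <- fit
  }
  # canonical ordering: ascending centroid value at the lowest b_e
  ord <- order(best$centers[, 1L])
  relabel <- match(seq_len(nrow(best$centers)), ord)
  labels <- rep(NA_integer_, nrow(traces$values))
  labels[traces$valid] <- relabel[best$cluster]
  structure(list(k = nrow(best$centers),
                 centroids = best$centers[ord, , drop = FALSE],
                 labels = labels, inertia = best$tot.withinss,
                 sizes = as.integer(best$size[ord]), seed = seed,
                 keys = traces$keys, b_e = traces$b_e,
                 feature = traces$feature),
            class = "trace_class_model")
}

#' @export
print.trace_class_model <- function(x, ...) {
  cat(sprintf("%s(b_e) classes: k = %d, inertia = %.4g\n", x$feature,
              x$k, x$inertia))
  for (j in seq_len(x$k))
    cat(sprintf("  class %d (n = %d): starts at %.3f, ends at %.3f\n", j,
                x$sizes[j], x$centroids[j, 1L],
                x$centroids[j, ncol(x$centroids)]))
  invisible(x)
}

#' Predicate for the depolarized region of parameter space
#'
#' Excitatory leakage reversal potentials between -65 and -60 mV, where
#' the adaptation-driven transition from asynchronous-irregular to
#' Up/Down dynamics is most robust.
#'
#' @return A function mapping a trace `keys` data.frame to a logical
#'   vector.
#' @export
depolarized_region <- function() {
  function(keys) keys$E_L_e >= -65 & keys$E_L_e <= -60
}

#' Predicate for the hyperpolarized region of parameter space
#'
#' Excitatory leakage reversal potentials between -80 and -75 mV, where
#' slow-wave Up/Down dynamics dominate even without adaptation.
#'
#' @return A function mapping a trace `keys` data.frame to a logical
#'   vector.
#' @export
hyperpolarized_region <- function() {
  function(keys) keys$E_L_e >= -80 & keys$E_L_e <= -75
}

#' Joint class distribution of FC and corrFCSC traces
#'
#' For the traces selected by the region filter (and valid in both
#' models), the fraction assigned to FC class `i` and corrFCSC class `j`,
#' plus the per-tuple class map.
#'
#' @param model_fc,model_corr [cluster_traces()] models fitted on the
#'   same trace index (same sweep table).
#' @param region_filter Predicate on the trace `keys` data.frame
#'   ([depolarized_region()], [hyperpolarized_region()]) or `NULL` for
#'   the whole space.
#' @return A list with `joint` (`k_fc x k_corr` fraction matrix, summing
#'   to 1 over the selected traces; all zeros when the filter selects
#'   none), `map` (data.frame: the key columns plus `fc_class` and
#'   `corr_class`), and `n` (number of traces counted).
#' @export
class_distribution <- function(model_fc, model_corr,
                               region_filter = NULL) {
  stopifnot(inherits(model_fc, "trace_class_model"),
            inherits(model_corr, "trace_class_model"))
  if (!isTRUE(all.equal(model_fc$keys, model_corr$keys)))
    stop("the two models were not fitted on the same trace index")
  sel <- !is.na(model_fc$labels) & !is.na(model_corr$labels)
  if (!is.null(region_filter))
    sel <- sel & region_filter(model_fc$keys)
  joint <- matrix(0, model_fc$k, model_corr$k,
                  dimnames = list(fc_class = seq_len(model_fc$k),
                                  corr_class = seq_len(model_corr$k)))
  map <- cbind(model_fc$keys[sel, , drop = FALSE],
               fc_class = model_fc$labels[sel],
               corr_class = model_corr$labels[sel])
  rownames(map) <- NULL
  if (any(sel)) {
    tab <- table(factor(model_fc$labels[sel], seq_len(model_fc$k)),
                 factor(model_corr$labels[sel], seq_len(model_corr$k)))
    joint[] <- tab / sum(tab)
  }
  list(joint = joint, map = map, n = sum(sel))
}

#' Save a trace-class model as JSON
#'
#' Centroids, labels, sizes and inertia in a structured text file.
#'
#' @param model A [cluster_traces()] model.
#' @param path Output path.
#' @export
write_class_model <- function(model, path) {
  stopifnot(inherits(model, "trace_class_model"))
  out <- list(feature = model$feature, k = model$k, b_e = model$b_e,
              centroids = model$centroids, sizes = model$sizes,
              inertia = model$inertia, seed = model$seed,
              labels = model$labels)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
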