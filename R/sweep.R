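# Constrained parameter-grid sweeps: grid construction, checkpointed
# (resumable) execution, and the paroxysmal-fixed-point census.

#' Default sweep ranges
#'
#' The five swept parameters and their physiological ranges: coupling
#' strength `S` (dimensionless), inhibitory and excitatory leakage
#' reversal potentials (mV), mean-field timescale `T` (ms) and
#' spike-triggered adaptation `b_e` (pA).
#'
#' @return Named list of `c(min, max)` ranges.
#' @export
default_sweep_ranges <- function() {
  list(S = c(0, 0.5), E_L_i = c(-80, -60), E_L_e = c(-80, -60),
       T = c(5, 40), b_e = c(0, 120))
}

#' Build the constrained parameter grid
#'
#' For each parameter, `n_values` evenly spaced values including both
#' endpoints (spacing `range/(n_values - 1)`); the cartesian product is
#' then filtered by the strict constraint `E_L_i < E_L_e + 4` mV, which
#' removes the combinations where inhibition silences the network. At
#' defaults (16 values per parameter) this leaves 675,840 of the 16^5 =
#' 1,048,576 combinations.
#'
#' Enumeration order is deterministic: lexicographic over parameter value
#' indices in the order `S`, `E_L_i`, `E_L_e`, `T`, `b_e` with `b_e`
#' varying fastest (so the adaptation traces of one `(S, E_L_i, E_L_e,
#' T)` tuple are contiguous).
#'
#' @param ranges Named list of `c(min, max)` per parameter
#'   ([default_sweep_ranges()]).
#' @param n_values Number of evenly spaced values per parameter (>= 2).
#'   Scalar or named vector per parameter.
#' @param constrain Apply the `E_L_i < E_L_e + 4` mV filter.
#' @return An object of class `sweep_grid` with the per-parameter value
#'   lists and the enumerated combination table (`$combos`, one row per
#'   combination with an `id` column).
#' @examples
#' g <- generate_grid(n_values = 4)
#' nrow(g$combos)
#' @export
generate_grid <- function(ranges = default_sweep_ranges(), n_values = 16,
                          constrain = TRUE) {
  pars <- c("S", "E_L_i", "E_L_e", "T", "b_e")
  stopifnot(all(pars %in% names(ranges)))
  if (length(n_values) == 1L)
    n_values <- stats::setNames(rep(n_values, 5L), pars)
  if (any(n_values < 2)) stop("`n_values` must be at least 2")
  for (pp in pars)
    if (ranges[[pp]][1] >= ranges[[pp]][2])
      stop(sprintf("invalid range for %s", pp))
  values <- lapply(pars, function(pp)
    seq(ranges[[pp]][1], ranges[[pp]][2], length.out = n_values[[pp]]))
  names(values) <- pars
  # expand.grid varies the first factor fastest; build reversed, then
  # reorder the columns
  combos <- expand.grid(b_e = values$b_e, T = values$T,
                        E_L_e = values$E_L_e, E_L_i = values$E_L_i,
                        S = values$S, KEEP.OUT.ATTRS = FALSE)
  combos <- combos[, rev(seq_along(combos))]
  if (constrain) {
    # strict inequality, robust to the floating-point error of the evenly
    # spaced values (on-grid equality E_L_i = E_L_e + 4 must be excluded)
    keep <- combos$E_L_i - combos$E_L_e < 4 - 1e-9
    combos <- combos[keep, , drop = FALSE]
  }
  rownames(combos) <- NULL
  combos <- cbind(id = seq_len(nrow(combos)), combos)
  structure(list(values = values, combos = combos,
                 n_values = n_values, constrained = constrain),
            class = "sweep_grid")
}

#' @export
print.sweep_grid <- function(x, ...) {
  cat(sprintf("sweep grid: %s combinations (%sconstrained)\n",
              format(nrow(x$combos), big.mark = ","),
              if (x$constrained) "" else "un"))
  for (pp in names(x$values))
    cat(sprintf("  %-6s %d values in [%g, %g]\n", pp,
                length(x$values[[pp]]), min(x$values[[pp]]),
                max(x$values[[pp]])))
  invisible(x)
}

# deterministic per-combination seed, independent of worker layout
.combo_seed <- function(master_seed, id) {
  as.integer((as.numeric(master_seed) + 7919 * as.numeric(id)) %%
               2147483629) + 1L
}

.feature_na <- function() {
  list(max_nu_e = NA_real_, mean_nu_e = NA_real_, mean_sd_nu_e = NA_real_,
       mean_up_duration = NA_real_, psd_peak_freq = NA_real_,
       mean_FC = NA_real_, corrFCSC = NA_real_, is_paroxysmal = NA)
}

# simulate + featurise one grid row
.run_combo <- function(row, conn, base_cfg, params, tfs, master_seed) {
  cfg <- base_cfg
  cfg$S <- row$S
  cfg$seed <- .combo_seed(master_seed, row$id)
  feats <- tryCatch({
    # rebuild through the constructor so parameter validation applies
    p <- do.call(adex_params,
                 utils::modifyList(unclass(params),
                                   list(T = row$T, b_e = row$b_e,
                                        E_L_e = row$E_L_e,
                                        E_L_i = row$E_L_i)))
    ts <- simulate_network(conn, cfg, p, tfs)
    f <- extract_features(ts, conn)
    c(unclass(f), list(status = "ok"))
  }, error = function(e)
    c(.feature_na(), list(status = paste0("error: ",
                                          conditionMessage(e)))))
  cbind(row[c("id", "S", "E_L_i", "E_L_e", "T", "b_e")],
        seed = cfg$seed, as.data.frame(feats, stringsAsFactors = FALSE))
}

#' Run a parameter sweep with checkpointing
#'
#' Simulates and featurises every grid combination independently. Each
#' combination's seed derives deterministically from the master seed and
#' the combination id, so results do not depend on the number of workers.
#' Results append to per-worker CSV files in `checkpoint_dir` (with a
#' completed-id index updated after each row), so a killed sweep resumes
#' where it stopped, skipping completed combinations. Per-combination
#' failures are recorded in the `status` column and never abort the
#' sweep.
#'
#' @param grid A [generate_grid()] object.
#' @param conn A [connectome] object.
#' @param base_cfg A [sim_config()]; its `S` and `seed` are overridden per
#'   combination (the master seed is `base_cfg$seed`).
#' @param params Base [adex_params()]; `T`, `b_e`, `E_L_e`, `E_L_i` are
#'   overridden per combination.
#' @param tfs Transfer-function pair.
#' @param workers Number of parallel workers (forked processes).
#' @param checkpoint_dir Writable directory for the crash-safe store.
#' @return A `sweep_result` data.frame: one row per combination with the
#'   five parameter values, the seed, the feature set, and a status flag;
#'   ordered by combination id. Attributes `grid_values` (the axis
#'   values) and `n_computed` (rows computed in this call).
#' @export
run_sweep <- function(grid, conn, base_cfg = sim_config(),
                      params = adex_params(), tfs = default_tf_params(),
                      workers = 1L, checkpoint_dir) {
  stopifnot(inherits(grid, "sweep_grid"))
  dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(checkpoint_dir) ||
      file.access(checkpoint_dir, 2L) != 0L)
    stop(sprintf("checkpoint dir '%s' is not writable", checkpoint_dir))
  master_seed <- base_cfg$seed

  done <- integer(0)
  for (f in list.files(checkpoint_dir, pattern = "^done_.*\\.idx$",
                       full.names = TRUE))
    done <- c(done, as.integer(readLines(f)))
  todo <- grid$combos[!(grid$combos$id %in% done), , drop = FALSE]

  run_chunk <- function(w, ids) {
    csv <- file.path(checkpoint_dir, sprintf("worker_%03d.csv", w))
    idx <- file.path(checkpoint_dir, sprintf("done_%03d.idx", w))
    for (i in ids) {
      row <- todo[i, , drop = FALSE]
      rec <- .run_combo(row, conn, base_cfg, params, tfs, master_seed)
      first <- !file.exists(csv)
      utils::write.table(rec, csv, sep = ",", row.names = FALSE,
                         col.names = first, append = !first)
      cat(row$id, "\n", file = idx, append = TRUE)
    }
    NULL
  }

  if (nrow(todo) > 0L) {
    chunks <- split(seq_len(nrow(todo)),
                    (seq_len(nrow(todo)) - 1L) %% workers)
    if (workers > 1L) {
      res <- parallel::mclapply(seq_along(chunks), function(w)
        tryCatch(run_chunk(w, chunks[[w]]), error = function(e) e),
        mc.cores = workers)
      errs <- Filter(function(x) inherits(x, "error"), res)
      if (length(errs) > 0L)
        stop("worker failed: ", conditionMessage(errs[[1L]]))
    } else {
      run_chunk(1L, chunks[[1L]])
    }
  }

  files <- list.files(checkpoint_dir, pattern = "^worker_.*\\.csv$",
                      full.names = TRUE)
  tab <- do.call(rbind, lapply(files, function(f)
    utils::read.csv(f, stringsAsFactors = FALSE)))
  tab <- tab[tab$id %in% grid$combos$id, , drop = FALSE]
  tab <- tab[!duplicated(tab$id), , drop = FALSE]
  tab <- tab[order(tab$id), , drop = FALSE]
  rownames(tab) <- NULL
  if (nrow(tab) != nrow(grid$combos))
    warning(sprintf("sweep incomplete: %d of %d combinations stored",
                    nrow(tab), nrow(grid$combos)))
  attr(tab, "grid_values") <- grid$values
  attr(tab, "n_computed") <- nrow(todo)
  class(tab) <- c("sweep_result", class(tab))
  tab
}

#' Census of paroxysmal fixed points over (S, E_L_i, E_L_e)
#'
#' Fixes the values of `S`, `E_L_i` and `E_L_e` and counts how many of
#' the combinations of the remaining parameters (`T` and `b_e`) exhibited
#' paroxysmal dynamics; each cell is therefore bounded by
#' `n_T * n_b_e`. Records whose features are missing (failed
#' simulations) do not count.
#'
#' @param table A `sweep_result` (from [run_sweep()]) or equivalent
#'   data.frame with columns `S`, `E_L_i`, `E_L_e` and `is_paroxysmal`.
#' @param grid_values Optional named list of axis values (taken from the
#'   table's `grid_values` attribute, or from the observed unique values,
#'   when omitted).
#' @return 3-D integer array with `dim = c(n_S, n_E_L_i, n_E_L_e)` and
#'   the axis values as dimnames.
#' @export
paroxysm_census <- function(table, grid_values = NULL) {
  if (is.null(grid_values))
    grid_values <- attr(table, "grid_values")
  ax <- function(pp) {
    if (!is.null(grid_values[[pp]])) sort(unique(grid_values[[pp]]))
    else sort(unique(table[[pp]]))
  }
  S_v <- ax("S"); eli_v <- ax("E_L_i"); ele_v <- ax("E_L_e")
  fx <- function(x, v) factor(match(x, v), levels = seq_along(v))
  flag <- table$is_paroxysmal %in% TRUE
  cnt <- tapply(flag,
                list(fx(table$S, S_v), fx(table$E_L_i, eli_v),
                     fx(table$E_L_e, ele_v)),
                sum)
  cnt[is.na(cnt)] <- 0L
  array(as.integer(cnt), dim = c(length(S_v), length(eli_v),
                                 length(ele_v)),
        dimnames = list(S = format(S_v), E_L_i = format(eli_v),
                        E_L_e = format(ele_v)))
}

#' Export a paroxysm census as plain text
#'
#' Writes the 3-D census as a long-format CSV (`S`, `E_L_i`, `E_L_e`,
#' `count`), a layout that round-trips the array exactly.
#'
#' @param census Array from [paroxysm_census()].
#' @param path Output CSV path.
#' @export
write_census_csv <- function(census, path) {
  dn <- dimnames(census)
  df <- expand.grid(S = as.numeric(dn$S), E_L_i = as.numeric(dn$E_L_i),
                    E_L_e = as.numeric(dn$E_L_e), KEEP.OUT.ATTRS = FALSE)
  df$count <- as.vector(census)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
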