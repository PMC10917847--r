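test_that("grid combinatorics match the constrained counts", {
  g <- generate_grid(n_values = 16)
  expect_identical(nrow(g$combos), 675840L)
  g_un <- generate_grid(n_values = 16, constrain = FALSE)
  expect_identical(nrow(g_un$combos), 1048576L)

  # admissible leak pairs by exhaustive enumeration in exact (integer)
  # arithmetic: v_m = -80 + m * (4/3), so v_i < v_e + 4  <=>  m_i < m_e + 3
  cnt <- 0L
  for (mi in 0:15) for (me in 0:15) if (3 * mi < 3 * me + 9) cnt <- cnt + 1L
  expect_identical(cnt, 165L)
  expect_identical(nrow(unique(g$combos[, c("E_L_i", "E_L_e")])), 165L)

  expect_error(generate_grid(n_values = 1), "at least 2")
})

test_that("grid spacing includes endpoints and the printed value -78.667", {
  g <- generate_grid(n_values = 16)
  eli <- g$values$E_L_i
  expect_identical(range(eli), c(-80, -60))
  expect_equal(eli[2], -80 + 4 / 3, tolerance = 1e-12)   # -78.667 mV
  expect_equal(diff(eli), rep(20 / 15, 15))
  # deterministic lexicographic enumeration, b_e fastest
  expect_identical(g$combos$id, seq_len(nrow(g$combos)))
  expect_identical(g$combos$b_e[1:16], g$values$b_e)
  expect_identical(g$combos$S[1:16], rep(0, 16))
})

# a desk-scale grid + config shared by the sweep tests: 24 combinations,
# deliberately short simulations
tiny_grid <- function() {
  generate_grid(ranges = list(S = c(0.1, 0.3), E_L_i = c(-80, -60),
                              E_L_e = c(-80, -60), T = c(19, 40),
                              b_e = c(0, 120)),
                n_values = 2)
}
tiny_cfg <- function(seed = 31L) {
  sim_config(duration = 300, transient = 100, dt = 0.2, seed = seed)
}

test_that("sweep runs, checkpoints, resumes, and matches manual composition", {
  grid <- tiny_grid()
  expect_identical(nrow(grid$combos), 24L)   # 3 admissible leak pairs x 8
  conn <- toy_conn(6, 0.6, 4)
  cfg <- tiny_cfg()

  dir1 <- withr::local_tempdir()
  res <- run_sweep(grid, conn, cfg, workers = 1L, checkpoint_dir = dir1)
  expect_identical(nrow(res), 24L)
  expect_identical(res$id, grid$combos$id)
  expect_false(any(duplicated(res[, c("S", "E_L_i", "E_L_e", "T", "b_e")])))
  expect_true(all(res$status == "ok"))

  # parallel execution gives the identical table
  dir2 <- withr::local_tempdir()
  res4 <- run_sweep(grid, conn, cfg, workers = 4L, checkpoint_dir = dir2)
  expect_equal(as.data.frame(res4), as.data.frame(res), ignore_attr = TRUE)

  # kill-and-resume: seed a fresh checkpoint with the first 10 completed
  # combinations, rerun, and require the full, identical table
  dir3 <- withr::local_tempdir()
  full_csv <- readLines(file.path(dir1, "worker_001.csv"))
  writeLines(full_csv[1:11], file.path(dir3, "worker_001.csv"))  # header + 10
  writeLines(as.character(res$id[1:10]), file.path(dir3, "done_001.idx"))
  res_resumed <- run_sweep(grid, conn, cfg, workers = 1L,
                           checkpoint_dir = dir3)
  expect_identical(attr(res_resumed, "n_computed"), 14L)
  expect_identical(nrow(res_resumed), 24L)
  expect_equal(as.data.frame(res_resumed), as.data.frame(res),
               tolerance = 1e-12, ignore_attr = TRUE)

  # per-combination records equal manual simulate + extract_features with
  # the same derived seed
  for (i in c(3L, 17L)) {
    row <- grid$combos[i, ]
    p <- adex_params(T = row$T, b_e = row$b_e, E_L_e = row$E_L_e,
                     E_L_i = row$E_L_i)
    cfg_i <- cfg
    cfg_i$S <- row$S
    cfg_i$seed <- adexnet:::.combo_seed(cfg$seed, row$id)
    f <- extract_features(simulate_network(conn, cfg_i, p), conn)
    expect_equal(res$mean_nu_e[i], f$mean_nu_e, tolerance = 1e-9)
    expect_equal(res$corrFCSC[i], f$corrFCSC, tolerance = 1e-9)
    expect_identical(res$is_paroxysmal[i], f$is_paroxysmal)
  }
})

test_that("paroxysm census counts match an independent tally", {
  grid <- tiny_grid()
  set.seed(55)
  tab <- grid$combos
  tab$is_paroxysmal <- runif(nrow(tab)) < 0.4
  cen <- paroxysm_census(tab, grid$values)

  # independent group-by oracle
  for (S in grid$values$S) for (eli in grid$values$E_L_i)
    for (ele in grid$values$E_L_e) {
      want <- sum(tab$is_paroxysmal[tab$S == S & tab$E_L_i == eli &
                                      tab$E_L_e == ele])
      expect_identical(cen[format(S), format(eli), format(ele)],
                       as.integer(want))
    }
  expect_identical(sum(cen), sum(tab$is_paroxysmal))

  # saturation: every record flagged
  tab$is_paroxysmal <- TRUE
  cen_all <- paroxysm_census(tab, grid$values)
  n_T_be <- length(grid$values$T) * length(grid$values$b_e)
  admissible <- unique(tab[, c("S", "E_L_i", "E_L_e")])
  for (r in seq_len(nrow(admissible)))
    expect_identical(cen_all[format(admissible$S[r]),
                             format(admissible$E_L_i[r]),
                             format(admissible$E_L_e[r])],
                     as.integer(n_T_be))

  # no paroxysmal records: an all-zero array
  tab$is_paroxysmal <- FALSE
  expect_true(all(paroxysm_census(tab, grid$values) == 0L))

  # census round-trips through the CSV export
  f <- withr::local_tempfile(fileext = ".csv")
  write_census_csv(cen, f)
  back <- utils::read.csv(f)
  expect_identical(sum(back$count), sum(cen))
})

test_that("coarse-sweep census reproduces the paroxysm sign pattern", {
  # desk-scale stand-in for the full census: 4 values per parameter,
  # short simulations, three master seeds pooled. Paroxysm probability
  # grows with E_L_e, shrinks with E_L_i, grows with S over S > 0, and the
  # disconnected (S = 0) corner is itself paroxysm-prone.
  grid <- generate_grid(n_values = 4)
  conn <- toy_conn(8, 0.5, 3)
  pooled <- NULL
  for (seed in c(11L, 22L, 33L)) {
    cfg <- sim_config(duration = 250, transient = 100, dt = 0.25,
                      seed = seed)
    dir <- withr::local_tempdir()
    res <- run_sweep(grid, conn, cfg, workers = 1L, checkpoint_dir = dir)
    cen <- paroxysm_census(res, grid$values)
    pooled <- if (is.null(pooled)) cen else pooled + cen
  }
  expect_gt(sum(pooled), 0)
  m_S <- apply(pooled, 1, mean)
  m_Ei <- apply(pooled, 2, mean)
  m_Ee <- apply(pooled, 3, mean)
  expect_gt(cor(seq_along(m_Ee), m_Ee, method = "spearman"), 0)
  expect_lt(cor(seq_along(m_Ei), m_Ei, method = "spearman"), 0)
  expect_gte(cor(seq_along(m_S[-1]), m_S[-1], method = "spearman"), 0)
  expect_gt(m_S[1], min(m_S[-1]))   # the disconnected corner is elevated
})

test_that("per-combination failures are recorded without aborting", {
  grid <- generate_grid(ranges = list(S = c(0.1, 0.2), E_L_i = c(-70, -66),
                                      E_L_e = c(-70, -66), T = c(0, 19),
                                      b_e = c(0, 60)),
                        n_values = 2)
  conn <- toy_conn(4, 0.6, 8)
  dir <- withr::local_tempdir()
  res <- run_sweep(grid, conn, tiny_cfg(), workers = 1L,
                   checkpoint_dir = dir)
  bad <- res$T == 0
  expect_true(any(bad))
  expect_true(all(grepl("^error", res$status[bad])))
  expect_true(all(is.na(res$mean_nu_e[bad])))
  expect_true(all(res$status[!bad] == "ok"))
})
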