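# synthetic sweep tables (no simulations needed to test trace assembly)
fake_table <- function(n_values = 3, feature = function(n) runif(n)) {
  g <- generate_grid(ranges = list(S = c(0, 0.5), E_L_i = c(-80, -60),
                                   E_L_e = c(-80, -60), T = c(5, 40),
                                   b_e = c(0, 120)),
                     n_values = n_values)
  tab <- g$combos
  tab$mean_FC <- feature(nrow(tab))
  tab$corrFCSC <- feature(nrow(tab))
  tab$is_paroxysmal <- FALSE
  tab
}

test_that("trace assembly obeys the count identity and validity rule", {
  set.seed(21)
  tab <- fake_table(3)
  tr <- build_traces(tab, "mean_FC")
  expect_identical(nrow(tr$values), nrow(tab) %/% 3L)   # |grid| / n_be
  expect_identical(ncol(tr$values), 3L)
  expect_identical(length(tr$b_e), 3L)
  expect_true(all(tr$valid))

  # traces reassemble the feature values in b_e order per tuple
  key <- paste(tab$S, tab$E_L_i, tab$E_L_e, tab$T)
  i <- which(key == key[1])
  expect_equal(tr$values[which(paste(tr$keys$S, tr$keys$E_L_i,
                                     tr$keys$E_L_e, tr$keys$T) == key[1]), ],
               tab$mean_FC[i][order(tab$b_e[i])])

  # one paroxysmal record invalidates exactly one trace
  tab2 <- tab
  tab2$is_paroxysmal[7] <- TRUE
  tr2 <- build_traces(tab2, "mean_FC")
  expect_identical(sum(!tr2$valid), 1L)

  # missing combinations are a completeness error listing gaps
  expect_error(build_traces(tab[-5, ], "mean_FC"), "incomplete grid")
})

test_that("k-means recovers planted trace families perfectly", {
  set.seed(33)
  n_be <- 16
  flat <- matrix(0.1 + rnorm(200 * n_be, 0, 0.005), 200, n_be)
  rising <- matrix(rep(seq(0.1, 0.9, length.out = n_be), each = 200) +
                     rnorm(200 * n_be, 0, 0.005), 200, n_be)
  tr <- structure(list(keys = data.frame(S = seq_len(400), E_L_i = 0,
                                         E_L_e = 0, T = 0),
                       b_e = seq(0, 120, length.out = n_be),
                       values = rbind(flat, rising),
                       valid = rep(TRUE, 400), feature = "mean_FC"),
                  class = "feature_traces")
  m <- cluster_traces(tr, k = 2, seed = 4)
  expect_identical(m$k, 2L)
  expect_identical(length(unique(m$labels[1:200])), 1L)
  expect_identical(length(unique(m$labels[201:400])), 1L)
  expect_false(m$labels[1] == m$labels[201])
  # canonical ordering: class 1 starts lower at b_e = 0... both start at
  # 0.1, so order by the first b_e column mean
  expect_true(m$centroids[1, 1] <= m$centroids[2, 1])
  expect_equal(m$centroids[m$labels[1], ], colMeans(flat), tolerance = 1e-6)

  # deterministic for a fixed seed
  m2 <- cluster_traces(tr, k = 2, seed = 4)
  expect_identical(m$labels, m2$labels)
  expect_identical(m$centroids, m2$centroids)
})

test_that("degenerate clustering: identical traces collapse to one class", {
  tr <- structure(list(keys = data.frame(S = 1:50, E_L_i = 0, E_L_e = 0,
                                         T = 0),
                       b_e = 1:4,
                       values = matrix(0.25, 50, 4),
                       valid = rep(TRUE, 50), feature = "mean_FC"),
                  class = "feature_traces")
  m <- cluster_traces(tr, k = 6, seed = 1)
  expect_identical(m$k, 1L)
  expect_equal(unname(m$centroids[1, ]), rep(0.25, 4))
  expect_equal(m$inertia, 0)
  expect_true(all(m$labels == 1L))
})

test_that("requested k is honoured and validated", {
  set.seed(8)
  tr <- structure(list(keys = data.frame(S = 1:300, E_L_i = 0, E_L_e = 0,
                                         T = 0),
                       b_e = seq_len(16),
                       values = matrix(runif(300 * 16), 300, 16),
                       valid = rep(TRUE, 300), feature = "corrFCSC"),
                  class = "feature_traces")
  m <- cluster_traces(tr, k = 6, seed = 2)
  expect_identical(dim(m$centroids), c(6L, 16L))
  expect_true(all(m$labels %in% 1:6))
  expect_true(all(diff(m$centroids[, 1]) >= 0))   # canonical ordering

  tr$valid[6:300] <- FALSE
  expect_error(cluster_traces(tr, k = 6, seed = 2), "5 valid traces")
})

test_that("joint class distributions normalise, filter and degenerate", {
  set.seed(12)
  n <- 6000L
  keys <- data.frame(S = runif(n), E_L_i = -70, E_L_e = runif(n, -80, -60),
                     T = 19)
  mk_model <- function(k, labels) {
    structure(list(k = k, centroids = matrix(0, k, 4),
                   labels = labels, inertia = 0, sizes = tabulate(labels, k),
                   seed = 1, keys = keys, b_e = 1:4, feature = "mean_FC"),
              class = "trace_class_model")
  }
  la <- sample.int(3, n, replace = TRUE)
  lb <- sample.int(4, n, replace = TRUE)
  cd <- class_distribution(mk_model(3, la), mk_model(4, lb))
  expect_equal(sum(cd$joint), 1, tolerance = 1e-12)
  expect_true(all(cd$joint >= 0))
  expect_identical(cd$n, n)
  # independent labels: joint ~ outer product of marginals
  marg <- outer(tabulate(la, 3) / n, tabulate(lb, 4) / n)
  expect_lt(max(abs(cd$joint - marg)), 0.02)

  # region filtering and the one-trace degenerate case
  one <- class_distribution(mk_model(3, la), mk_model(4, lb),
                            region_filter = function(k) seq_len(n) == 17)
  expect_identical(one$n, 1L)
  expect_identical(sum(one$joint == 1), 1L)

  empty <- class_distribution(mk_model(3, la), mk_model(4, lb),
                              region_filter = function(k) rep(FALSE, n))
  expect_identical(empty$n, 0L)
  expect_true(all(empty$joint == 0))
  expect_identical(nrow(empty$map), 0L)

  # models fitted on different trace indices are rejected
  other <- mk_model(4, lb)
  other$keys <- keys[seq_len(n - 1), ]
  expect_error(class_distribution(mk_model(3, la), other), "same trace")
})

test_that("region predicates select the documented leak ranges", {
  keys <- data.frame(S = 0, E_L_i = -70,
                     E_L_e = c(-60, -63, -65, -70, -75, -80), T = 19)
  expect_identical(depolarized_region()(keys),
                   c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(hyperpolarized_region()(keys),
                   c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
})

test_that("depolarized corrFCSC traces rise with adaptation (desk scale)", {
  # coarse sweep restricted to the depolarized region at T = 19 ms: the
  # median corrFCSC(b_e) trace is nondecreasing from b_e = 0 to b_e = max,
  # the structure-function coupling signature of the descent into
  # slow-wave states
  grid <- generate_grid(ranges = list(S = c(0.1, 0.25), E_L_i = c(-65, -64),
                                      E_L_e = c(-65, -64), T = c(19, 40),
                                      b_e = c(0, 120)),
                        n_values = c(S = 2, E_L_i = 2, E_L_e = 2, T = 2,
                                     b_e = 4))
  conn <- toy_conn(40, 0.5, 3)
  cfg <- sim_config(duration = 1200, transient = 400, dt = 0.2, seed = 19)
  dir <- withr::local_tempdir()
  res <- run_sweep(grid, conn, cfg, workers = 1L, checkpoint_dir = dir)
  tr <- build_traces(res, "corrFCSC")
  sel <- tr$valid & tr$keys$T == 19 & depolarized_region()(tr$keys)
  expect_gt(sum(sel), 3)
  med <- apply(tr$values[sel, , drop = FALSE], 2, median)
  expect_gt(med[length(med)], med[1])   # endpoint rise from b_e = 0 to max
})
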