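test_that("membrane moments match limits and an independent transcription", {
  p <- depol_params()
  m0 <- membrane_moments(0, 0, 0, p)
  expect_equal(m0$mu_V, p$E_L_e, tolerance = 1e-3)  # leak-only limit
  expect_gt(membrane_moments(0, 0, 0, p)$tau_V, 0)

  # hyperpolarizing adaptation current pulls mu_V below the leak reversal
  expect_lt(membrane_moments(0, 0, 100, p)$mu_V, p$E_L_e)

  # independent one-shot transcription of the shot-noise formulas,
  # written as a single scalar expression chain (second route)
  oracle <- function(nu_e, nu_i, W, EL) {
    fe <- (nu_e / 1e3 + 1e-6) * 400
    fi <- (nu_i / 1e3 + 1e-6) * 100
    ge <- 1.5 * 5 * fe; gi <- 5 * 5 * fi
    g <- 10 + ge + gi
    tm <- 200 / g
    muv <- (ge * 0 + gi * (-80) + 10 * EL - W) / g
    ue <- 1.5 / g * (0 - muv); ui <- 5 / g * (-80 - muv)
    se <- fe * (ue * 5)^2; si <- fi * (ui * 5)^2
    list(mu_V = muv,
         sigma_V = sqrt(se / (2 * (5 + tm)) + si / (2 * (5 + tm))),
         tau_V = (se + si) / (se / (5 + tm) + si / (5 + tm)))
  }
  for (case in list(c(10, 10, 0), c(3, 20, 120), c(150, 80, 500))) {
    got <- membrane_moments(case[1], case[2], case[3], p)
    want <- oracle(case[1], case[2], case[3], p$E_L_e)
    expect_equal(got$mu_V, want$mu_V, tolerance = 1e-12)
    expect_equal(got$sigma_V, want$sigma_V, tolerance = 1e-12)
    expect_equal(got$tau_V, want$tau_V, tolerance = 1e-12)
  }
  expect_error(membrane_moments(-1, 0, 0, p), "nonnegative")
})

test_that("transfer function: midpoint identity, saturation, silencing", {
  p <- depol_params()
  # construct a coefficient set whose effective threshold equals mu_V at a
  # chosen input: the rate there must be exactly 1/(2 tau_V)  (erfc(0) = 1)
  m <- membrane_moments(10, 10, 0, p)
  tf_mid <- tf_params("excitatory", P = c(m$mu_V / 1000, rep(0, 9)))
  expect_equal(transfer_function(10, 10, 0, p, tf_mid),
               1000 / (2 * m$tau_V), tolerance = 1e-12)

  # saturating drive approaches the refractory-limited maximum (~190 Hz)
  sat <- transfer_function(500, 0, 0, p, TFS$e)
  expect_gt(sat, 170)
  expect_lte(sat, 1000 / p$T_refrac)

  # strong inhibition silences the population
  expect_lt(transfer_function(0, 50, 0, p, TFS$i), 0.1)
  expect_lt(transfer_function(0, 50, 0, p, TFS$e), 0.1)
})

test_that("transfer function is monotone and bounded on a scanned grid", {
  p <- depol_params()
  nu_grid <- seq(0, 200, length.out = 200)
  r_e <- transfer_function(nu_grid, 10, 0, p, TFS$e)
  expect_true(all(diff(r_e) >= -1e-9))           # nondecreasing in nu_e_tot
  W_grid <- seq(0, 500, length.out = 200)
  r_w <- transfer_function(20, 10, W_grid, p, TFS$e)
  expect_true(all(diff(r_w) <= 1e-9))            # nonincreasing in W
  all_r <- c(r_e, r_w)
  expect_true(all(all_r >= 0 & all_r <= 1000 / p$T_refrac))
})

test_that("derivatives match the frozen reference-implementation fixture", {
  fix <- jsonlite::read_json(test_path("fixtures-meanfield-oracle.json"),
                             simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  for (case in fix) {
    p <- adex_params(T = case$params$T, b_e = case$params$b_e,
                     E_L_e = case$params$E_L_e, E_L_i = case$params$E_L_i)
    st <- as.matrix(case$states_khz)
    st_pub <- cbind(st[, 1:2] * 1e3, st[, 3:5] * 1e6, st[, 6:7])
    colnames(st_pub) <- c("nu_e", "nu_i", "c_ee", "c_ei", "c_ii",
                          "W_e", "W_i")
    got <- meanfield_derivatives(st_pub, case$coupling_khz * 1e3, p,
                                 TFS$e, TFS$i)
    got_khz <- cbind(got[, 1:2] / 1e3, got[, 3:5] / 1e6, got[, 6:7])
    expect_equal(unname(got_khz), unname(as.matrix(case$derivs_khz)),
                 tolerance = 1e-9)
  }
})

test_that("adaptation stationarity: closed form and clamped integration", {
  p <- depol_params(b_e = 60)
  # stationary Eq: W* = b_e * tau_w * nu_e = 60 pA * 500 ms * 10 Hz = 300 pA
  st <- c(nu_e = 10, nu_i = 10, c_ee = 0, c_ei = 0, c_ii = 0,
          W_e = 300, W_i = 0)
  d <- meanfield_derivatives(st, 0, p, TFS$e, TFS$i)
  expect_equal(unname(d["W_e"]), 0, tolerance = 1e-12)

  # clamped-rate integration over 10 tau_w recovers the closed form to 1%
  wf <- heun_ode(function(w) -w / p$tau_w + p$b_e * (10 / 1e3),
                 0, dt = 1, n_steps = 10 * p$tau_w)
  expect_equal(wf, 300, tolerance = 0.01)
})

test_that("second-order correction vanishes when covariances are zero", {
  p <- depol_params()
  st <- c(nu_e = 5, nu_i = 12, c_ee = 0, c_ei = 0, c_ii = 0,
          W_e = 0, W_i = 0)
  d <- meanfield_derivatives(st, 2, p, TFS$e, TFS$i)
  f_e <- transfer_function(5 + 2, 12, 0, p, TFS$e)
  f_i <- transfer_function(5 + 2, 12, 0, p, TFS$i)
  expect_equal(unname(d["nu_e"]), (f_e - 5) / p$T, tolerance = 1e-9)
  expect_equal(unname(d["nu_i"]), (f_i - 12) / p$T, tolerance = 1e-9)
})

test_that("fixed points: Down, Up and paroxysmal branches", {
  # hyperpolarized leaks, zero drive: a stable Down point below 1 Hz
  fps <- find_fixed_points(0, adex_params(E_L_e = -80, E_L_i = -80,
                                          b_e = 0), TFS)
  stable <- Filter(function(r) r$stable, fps)
  expect_true(any(vapply(stable, function(r) r$state[["nu_e"]] < 1,
                         logical(1))))

  # depolarized leaks, moderate drive: a stable Up point in (0, 50] Hz
  fps <- find_fixed_points(2, depol_params(), TFS)
  up <- Filter(function(r) r$stable && r$state[["nu_e"]] > 0.5 &&
                 r$state[["nu_e"]] <= 50, fps)
  expect_gte(length(up), 1L)

  # excitation-dominated leaks: a stable root above 175 Hz
  fps <- find_fixed_points(0, adex_params(E_L_e = -60, E_L_i = -80,
                                          b_e = 0), TFS)
  pfp <- Filter(function(r) r$stable && r$state[["nu_e"]] > 175, fps)
  expect_gte(length(pfp), 1L)
})

test_that("derivatives vanish at a reported fixed point", {
  fps <- find_fixed_points(2, depol_params(), TFS)
  for (r in Filter(function(r) r$stable, fps)) {
    d <- meanfield_derivatives(r$state, 2, depol_params(), TFS$e, TFS$i)
    expect_lt(max(abs(d[c("nu_e", "nu_i")])), 1e-5)   # Hz per ms
    expect_lt(max(abs(d[c("W_e", "W_i")])), 1e-5)
  }
})

test_that("integrating a noiseless node from a stable fixed point is inert", {
  p <- depol_params()
  fps <- find_fixed_points(2, p, TFS)
  up <- Filter(function(r) r$stable & r$state[["nu_e"]] <= 50, fps)[[1]]
  cfg <- sim_config(duration = 2000, transient = 0, S = 0, nu_drive = 2,
                    sigma = 0, seed = 1, init_state = up$state)
  ts <- simulate_network(pair_conn(), cfg, p)
  drift <- abs(ts$nu_e[nrow(ts$nu_e), 1] - up$state[["nu_e"]])
  expect_lt(drift, 0.1)
})
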