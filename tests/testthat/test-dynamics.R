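test_that("order parameter handles coherent, balanced and two-phase states", {
  expect_equal(order_parameter(rep(1.3, 50)), 1)
  expect_equal(order_parameter(2 * pi * (0:7) / 8), 0, tolerance = 1e-12)
  expect_equal(order_parameter(c(0, pi / 2)), sqrt(2) / 2)
})

test_that("sampling times follow the geometric schedule", {
  ts <- sampling_times(1000, 1.08)
  expect_equal(ts[1], 2)           # 1 + 1.08^0
  expect_equal(ts[11], 1 + 1.08^10)
  expect_equal(ts[11], 3.158925, tolerance = 1e-6)
  expect_true(all(diff(ts) > 0))
  expect_true(max(ts) <= 1000)
  # next index would exceed t_max
  expect_gt(1 + 1.08^length(ts), 1000)
  expect_error(sampling_times(1.5), "t_max")
})

test_that("kuramoto_rhs matches hand-computed cases", {
  # isolated node: empty coupling sum
  W <- Matrix::sparseMatrix(i = 1, j = 2, x = 0, dims = c(2, 2))
  iso <- oscillator_network(Matrix::drop0(W), kind = "toy")
  expect_equal(kuramoto_rhs(c(0.3, 0.7), c(1.5, -2), iso, 5), c(1.5, -2))

  # equal phases: sin(0) = 0
  net <- ring_network(6)
  om <- rnorm(6)
  expect_equal(kuramoto_rhs(rep(0.4, 6), om, net, 2.5), om)

  # N = 2 analytic: sin(+-pi/2)
  pairW <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 1,
                                dims = c(2, 2))
  pair <- oscillator_network(pairW, kind = "pair")
  expect_equal(kuramoto_rhs(c(0, pi / 2), c(0, 0), pair, 1), c(1, -1))

  expect_error(kuramoto_rhs(1:3, 1:2, pair, 1), "length")
})

test_that("RK4 is exact for K = 0 and reversible", {
  net <- ring_network(10)
  om <- draw_frequencies(10, seed = 3)
  set.seed(4); th0 <- runif(10, 0, 2 * pi)
  th_t <- rk4_integrate(th0, om, net, K = 0, dt = 0.1, t_target = 7.3)
  expect_equal(th_t, th0 + om$omega * 7.3, tolerance = 1e-12)
  # time reversal with negated frequencies returns to the start
  back <- rk4_integrate(th_t, -om$omega, net, K = 0, dt = 0.1,
                        t_target = 7.3)
  expect_equal(back, th0, tolerance = 1e-12)
})

test_that("compiled and reference integrators agree", {
  net <- make_2dll(4, seed = 2)
  om <- draw_frequencies(16, seed = 5)
  set.seed(6); th0 <- runif(16, 0, 2 * pi)
  a <- rk4_integrate(th0, om, net, 0.8, 0.1, 5, engine = "cpp")
  b <- rk4_integrate(th0, om, net, 0.8, 0.1, 5, engine = "r")
  expect_equal(a, b, tolerance = 1e-10)
  # mean-field fast path equals the generic sparse path on the full graph
  full <- make_full_graph(40)
  omf <- draw_frequencies(40, seed = 7)
  set.seed(8); thf <- runif(40, 0, 2 * pi)
  cf <- rk4_integrate(thf, omf, full, 2, 0.1, 5, engine = "cpp")
  rf <- rk4_integrate(thf, omf, full, 2, 0.1, 5, engine = "r")
  expect_equal(cf, rf, tolerance = 1e-10)
})

test_that("halving dt changes a smooth trajectory only at RK4 order", {
  net <- ring_network(10)
  om <- draw_frequencies(10, seed = 9)
  set.seed(10); th0 <- runif(10, 0, 2 * pi)
  coarse <- rk4_integrate(th0, om, net, 0.5, 0.1, 10)
  fine <- rk4_integrate(th0, om, net, 0.5, 0.05, 10)
  # global error O(dt^4): difference well below dt^3
  expect_lt(max(abs(coarse - fine)), 1e-5)
})

test_that("rotational symmetry: a global phase shift leaves R(t) invariant", {
  net <- make_2dll(7, seed = 11)  # N = 49
  om <- draw_frequencies(49, seed = 12)
  set.seed(13); th0 <- runif(49, 0, 2 * pi)
  t_end <- 10
  a <- rk4_integrate(th0, om, net, 0.6, 0.1, t_end)
  b <- rk4_integrate(th0 + 1.234, om, net, 0.6, 0.1, t_end)
  expect_equal(order_parameter(a), order_parameter(b), tolerance = 1e-9)
  expect_equal(b - a, rep(1.234, 49), tolerance = 1e-9)
})

test_that("identical oscillators on the full graph synchronize", {
  net <- make_full_graph(100)
  cfg <- sim_config(coupling_K = 2, t_max = 50, omega_seed = 14,
                    phase_seed = 15)
  # all omega = 0: override by running the integrator directly
  set.seed(15); th0 <- runif(100, 0, 2 * pi)
  th <- rk4_integrate(th0, rep(0, 100), net, 2, 0.1, 50)
  expect_gt(order_parameter(th), 0.99)
})

test_that("R stays within [0, 1] along trajectories", {
  net <- make_2dll(6, seed = 16)
  cfg <- sim_config(coupling_K = 0.5, t_max = 100, omega_seed = 17,
                    phase_seed = 18)
  tr <- run_realization(net, cfg)
  expect_true(all(tr$R >= 0 & tr$R <= 1))
})

test_that("first-passage bookkeeping follows the midpoint rule", {
  net <- make_2dll(6, seed = 19)
  ts <- sampling_times(100, 1.08)
  # coherent start: R(t_0) ~ 1 > threshold, so t_x > t_0 if it crosses
  cfg <- sim_config(coupling_K = 0.1, t_max = 100, init_kind = "coherent",
                    omega_seed = 20, phase_seed = 21)
  tr <- run_realization(net, cfg, early_exit = TRUE)
  expect_gt(tr$R[1], tr$threshold)
  if (tr$crossed) {
    k <- which(!is.na(tr$R))
    k <- k[length(k)]
    expect_equal(tr$t_x, (ts[k] + ts[k - 1]) / 2)
  }
  # an immediate sub-threshold sample maps to t_x = t_0 / 2
  cfg2 <- sim_config(coupling_K = 0, t_max = 100, threshold = 0.999,
                     omega_seed = 22, phase_seed = 23)
  tr2 <- run_realization(net, cfg2, early_exit = TRUE)
  expect_true(tr2$crossed)
  expect_equal(tr2$t_x, ts[1] / 2)
})

test_that("strong coupling locks an incoherent start above threshold", {
  # dt must resolve the fast locking rate ~ K at this coupling
  net <- make_full_graph(200)
  cfg <- sim_config(coupling_K = 100 * kc_mean_field(), dt = 0.005,
                    t_max = 50, omega_seed = 24, phase_seed = 25)
  tr <- run_realization(net, cfg, early_exit = TRUE)
  expect_false(tr$crossed)
  expect_gt(min(tr$R), 0.9)
})

test_that("zero coupling crosses the noise threshold almost immediately", {
  net <- make_2dll(10, seed = 26)  # N = 100
  crossed_early <- vapply(1:8, function(r) {
    cfg <- sim_config(coupling_K = 0, t_max = 50,
                      omega_seed = 100 + r, phase_seed = 200 + r)
    tr <- run_realization(net, cfg, early_exit = TRUE)
    tr$crossed && tr$t_x < 10
  }, logical(1))
  expect_gt(mean(crossed_early), 0.5)
})

test_that("ensembles are deterministic and average correctly", {
  net <- make_2dll(5, seed = 27)
  cfg <- sim_config(coupling_K = 0.4, t_max = 50)
  e1 <- run_ensemble(net, cfg, 5, base_seed = 28, mode = "duration")
  e2 <- run_ensemble(net, cfg, 5, base_seed = 28, mode = "duration")
  expect_identical(e1$durations, e2$durations)
  expect_identical(e1$mean_R, e2$mean_R)

  # n = 1 curve-mode mean equals the single trajectory
  e3 <- run_ensemble(net, cfg, 1, base_seed = 29, mode = "curve")
  cfg1 <- cfg
  cfg1$omega_seed <- kuranet:::derive_seed(29, 1, 0L)
  cfg1$phase_seed <- kuranet:::derive_seed(29, 1, 1L)
  tr <- run_realization(net, cfg1)
  expect_equal(e3$mean_R$mean_R, tr$R)
  expect_true(all(e3$mean_R$mean_R >= 0 & e3$mean_R$mean_R <= 1))
})

test_that("supercritical full graph settles on the mean-field fixed point", {
  # independent oracle: the self-consistency condition
  # 1 = K * int cos^2(th) g(K r sin(th)) dth for the locked fraction
  K <- 3
  oracle <- uniroot(function(r) {
    K * integrate(function(th) cos(th)^2 * dnorm(K * r * sin(th)),
                  -pi / 2, pi / 2)$value - 1
  }, c(0.2, 0.999))$root
  net <- make_full_graph(500)
  cfg <- sim_config(coupling_K = K, t_max = 80)
  tbl <- steady_state_R(net, K, cfg, n_realizations = 6, base_seed = 33)
  expect_equal(tbl$R_inf, oracle, tolerance = 0.05)
})

test_that("ensemble outputs round-trip through CSV", {
  net <- make_2dll(4, seed = 30)
  cfg <- sim_config(coupling_K = 0.4, t_max = 30)
  ens <- run_ensemble(net, cfg, 4, base_seed = 31, mode = "duration")
  dir <- withr::local_tempdir()
  write_ensemble(ens, dir)
  expect_true(all(file.exists(file.path(dir, c("durations.csv", "mean_R.csv",
                                               "config.json")))))
  back <- read_ensemble(dir)
  expect_equal(back$durations$t_x, ens$durations$t_x)
  expect_equal(back$mean_R$mean_R, ens$mean_R$mean_R)
  expect_equal(back$config$coupling_K, cfg$coupling_K)
})
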