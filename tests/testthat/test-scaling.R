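test_that("histogram densities integrate to one over the uncensored mass", {
  u <- sample_pareto(5000, 1.5, seed = 1)
  h <- build_histogram(u)
  expect_equal(sum(h$bins$density * h$bins$width), 1, tolerance = 1e-9)
  expect_true(all(diff(c(h$bins$edge_lo[1], h$bins$edge_hi)) > 0))
  # censored samples excluded from the density but counted
  crossed <- rep(c(TRUE, FALSE), length.out = 5000)
  h2 <- build_histogram(u, crossed = crossed)
  expect_equal(h2$n_censored, 2500)
  expect_equal(sum(h2$bins$density * h2$bins$width), 1, tolerance = 1e-9)
  expect_error(build_histogram(u, crossed = rep(FALSE, 5000)), "censored")
})

test_that("bin widths grow as the prescribed power of position", {
  u <- sample_pareto(2000, 1.5, seed = 2)
  h <- build_histogram(u, width_exponent = 1.12)
  b <- h$bins
  ratio <- b$width / b$edge_lo^1.12
  expect_equal(max(ratio) / min(ratio), 1, tolerance = 1e-6)
})

test_that("degenerate histogram input occupies a single bin", {
  h <- build_histogram(rep(3.5, 10))
  expect_equal(sum(h$bins$count > 0), 1)
  occ <- h$bins[h$bins$count > 0, ]
  expect_equal(occ$density * occ$width, 1, tolerance = 1e-12)
})

test_that("tail fit is exact on noiseless power-law densities", {
  centers <- exp(seq(log(2), log(500), length.out = 30))
  edges <- sqrt(c(centers[1]^2 / centers[2] * centers[1],
                  centers[-1] * centers[-30], centers[30]^2 /
                    centers[29] * centers[30]))
  # build a synthetic histogram object directly on an exact line
  dens <- exp(4) * centers^-1.6
  h <- structure(list(
    bins = tibble::tibble(edge_lo = centers * 0.95, edge_hi = centers * 1.05,
                          center = centers, width = centers * 0.1,
                          count = rep(10L, 30), density = dens),
    n_total = 300L, n_censored = 0L, width_exponent = 1.12),
    class = "duration_histogram")
  fit <- fit_tail(h, t_min = 0)
  expect_equal(fit$exponent, 1.6, tolerance = 1e-12)
  expect_lt(fit$stderr, 1e-12)
  expect_error(fit_tail(h, t_min = 1000), "t_min")
})

test_that("histogram plus tail fit recovers planted Pareto exponents", {
  for (tau in c(1.2, 1.5, 2.0)) {
    u <- sample_pareto(1e5, tau, seed = round(tau * 100))
    h <- build_histogram(u)
    fit <- fit_tail(h, t_min = 10)
    expect_equal(fit$exponent, tau, tolerance = 0.1)
  }
})

test_that("effective exponent is exact on pure power laws", {
  ts <- sampling_times(500, 1.08)
  eta <- effective_exponent(data.frame(t = ts, mean_R = 2.7 * ts^0.6))
  expect_equal(nrow(eta), length(ts) - 3)
  expect_equal(eta$eta_eff, rep(0.6, nrow(eta)), tolerance = 1e-10)
  # constant series has zero slope
  eta0 <- effective_exponent(data.frame(t = ts, mean_R = rep(0.5,
                                                             length(ts))))
  expect_equal(eta0$eta_eff, rep(0, nrow(eta0)), tolerance = 1e-12)
  expect_error(effective_exponent(data.frame(t = ts, mean_R = -ts)),
               "non-positive")
})

test_that("effective exponent converges from below with 1/t corrections", {
  ts <- sampling_times(5000, 1.08)
  eta <- effective_exponent(data.frame(t = ts,
                                       mean_R = ts^0.75 * (1 + 5 / ts)))
  n <- nrow(eta)
  # monotone approach to 0.75 from below at late times
  expect_lt(eta$eta_eff[n], 0.75)
  expect_gt(eta$eta_eff[n], 0.74)
  expect_true(all(diff(eta$eta_eff[(n - 20):n]) > 0))
})

test_that("plateau_exponent reads off the asymptote of a flat series", {
  ts <- sampling_times(500, 1.08)
  eta <- effective_exponent(data.frame(t = ts, mean_R = ts^0.55))
  p <- plateau_exponent(eta)
  expect_equal(p$exponent, 0.55, tolerance = 1e-9)
  expect_equal(p$kind, "eta")
})

test_that("locate_transition recovers a planted critical coupling", {
  ts <- sampling_times(500, 1.08)
  fam <- purrr::map_dfr(seq(0.90, 1.10, by = 0.05), function(K) {
    effective_exponent(
      data.frame(t = ts, mean_R = ts^0.6 * exp((K - 1) * ts / 100)), K = K)
  })
  est <- locate_transition(fam)
  expect_true(est$bracket[1] <= 1 && est$bracket[2] >= 1)
  expect_equal(est$K_c, 1, tolerance = 0.05)

  # invariance under joint rescaling of <R>
  fam2 <- fam
  est2 <- locate_transition(dplyr::mutate(fam2, eta_eff = eta_eff))
  expect_equal(est2$K_c, est$K_c)

  # all-up-veering family has no bracket
  fam_up <- purrr::map_dfr(c(1.1, 1.2, 1.3), function(K) {
    effective_exponent(
      data.frame(t = ts, mean_R = ts^0.6 * exp((K - 1) * ts / 100)), K = K)
  })
  expect_error(locate_transition(fam_up), "bracket")
})

test_that("locate_transition is invariant under rescaling all curves", {
  ts <- sampling_times(300, 1.08)
  build_fam <- function(scale) {
    purrr::map_dfr(c(0.9, 1.0, 1.1), function(K) {
      effective_exponent(
        data.frame(t = ts,
                   mean_R = scale * ts^0.5 * exp((K - 1) * ts / 80)), K = K)
    })
  }
  a <- locate_transition(build_fam(1))
  b <- locate_transition(build_fam(37.5))
  expect_equal(a$K_c, b$K_c, tolerance = 1e-12)
})

test_that("steady-state inflexion locator finds a planted crossover", {
  # synthetic sweep: noise floor below K_c = 1.3, sqrt growth above
  Ks <- seq(1.0, 1.6, by = 0.05)
  R <- ifelse(Ks < 1.3, 0.02 * exp(2 * (Ks - 1.0)),
              0.02 * exp(0.6) + 0.8 * sqrt(pmax(Ks - 1.3, 0)))
  est <- locate_transition_steady(tibble::tibble(K = Ks, R_inf = R))
  expect_equal(est$K_c, 1.3, tolerance = 0.06)
  expect_true(est$bracket[1] <= 1.3 && est$bracket[2] >= 1.3)
  expect_error(locate_transition_steady(tibble::tibble(K = 1:3,
                                                       R_inf = c(1, 2, 3))),
               "at least 4")
})

test_that("decay_exponent fits exact and perturbed power-law decays", {
  ts <- sampling_times(2000, 1.08)
  fit <- decay_exponent(data.frame(t = ts, mean_R = ts^-0.6))
  expect_equal(fit$exponent, 0.6, tolerance = 1e-6)
  expect_equal(fit$kind, "delta")
  # 1/t correction: asymptotic value approached
  fit2 <- decay_exponent(data.frame(t = ts, mean_R = ts^-0.5 * (1 + 1 / ts)),
                         window = c(100, 2000))
  expect_equal(fit2$exponent, 0.5, tolerance = 0.01)
  expect_error(decay_exponent(data.frame(t = ts[1:5],
                                         mean_R = ts[1:5]^-0.5),
                              window = c(900, 1000)),
               "window too short")
})

test_that("steady_state_R tracks the strong- and zero-coupling limits", {
  net <- make_full_graph(400)
  cfg <- sim_config(coupling_K = 1, t_max = 60)
  tbl <- steady_state_R(net, c(0, 30), cfg, n_realizations = 3,
                        base_seed = 5)
  expect_equal(nrow(tbl), 2)
  # K = 0: noise level ~ 1/sqrt(N)
  expect_lt(tbl$R_inf[tbl$K == 0], 4 * noise_threshold(400))
  # K >> K_c: near-full synchrony
  expect_gt(tbl$R_inf[tbl$K == 30], 0.9)
})

test_that("scaling relation check classifies consistency correctly", {
  expect_equal(scaling_relation(0.5), 1.5)
  exact <- scaling_relation_check(1.5, 0.5)
  expect_equal(exact$discrepancy, 0)
  expect_equal(exact$status, "consistent")

  tau <- kuranet:::new_exponent_fit(1.6, 0.1, c(10, 100), 10, "tau_t")
  marginal <- scaling_relation_check(tau, 0.5)
  expect_equal(marginal$discrepancy, 0.1, tolerance = 1e-12)
  expect_true(marginal$status %in% c("consistent", "marginal"))

  tau2 <- kuranet:::new_exponent_fit(2.0, 0.05, c(10, 100), 10, "tau_t")
  expect_equal(scaling_relation_check(tau2, 0.5)$status, "inconsistent")
})

test_that("tidy and glance methods return well-formed tibbles", {
  u <- sample_pareto(2000, 1.5, seed = 3)
  h <- build_histogram(u)
  fit <- fit_tail(h, 5)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term, "tau_t")
  expect_true(all(c("estimate", "std.error") %in% names(td)))
  expect_s3_class(tidy(h), "tbl_df")
})
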