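#' Simulation configuration
#'
#' Collects the parameters of one Kuramoto integration protocol.
#'
#' @param coupling_K global coupling constant `K`.
#' @param dt fixed RK4 step size; 0.1 is sufficient for these networks
#'   (smaller steps change individual chaotic trajectories but not ensemble
#'   statistics).
#' @param t_max integration horizon.
#' @param sample_base geometric base `b` of the sampling schedule
#'   `t_k = 1 + b^k`.
#' @param init_kind `"incoherent"` (phases uniform on `(0, 2*pi]`) or
#'   `"coherent"` (all phases zero).
#' @param threshold first-passage threshold `R_T`; `NULL` means the
#'   incoherent noise level `1/sqrt(N)` of the network the config is run on.
#' @param omega_seed,phase_seed seeds of the two independent RNG streams for
#'   intrinsic frequencies and initial phases.
#' @return a `sim_config` list.
#' @export
sim_config <- function(coupling_K, dt = 0.1, t_max = 1000,
                       sample_base = 1.08,
                       init_kind = c("incoherent", "coherent"),
                       threshold = NULL,
                       omega_seed = 1L, phase_seed = 2L) {
  init_kind <- match.arg(init_kind)
  if (dt <= 0) abort("dt must be positive")
  if (t_max <= dt) abort("t_max must exceed dt")
  if (sample_base <= 1) abort("sample_base must exceed 1")
  if (!is.null(threshold) && (threshold <= 0 || threshold >= 1))
    abort("threshold must lie in (0, 1)")
  structure(list(coupling_K = coupling_K, dt = dt, t_max = t_max,
                 sample_base = sample_base, init_kind = init_kind,
                 threshold = threshold,
                 omega_seed = omega_seed, phase_seed = phase_seed),
            class = "sim_config")
}

#' Exponentially spaced sampling times
#'
#' The order parameter is sampled at `t_k = 1 + base^k`, `k = 0, 1, 2, ...`,
#' the standard schedule for power-law asymptotics: samples are equidistant
#' in `log(t - 1)` so late times are not over-resolved.
#'
#' @param t_max horizon; all returned times satisfy `t_k <= t_max`.
#' @param base geometric base (`> 1`).
#' @return increasing numeric vector of sampling times.
#' @export
sampling_times <- function(t_max, base = 1.08) {
  if (t_max <= 2) abort("t_max must exceed 2 (the first sampling time)")
  if (base <= 1) abort("base must exceed 1")
  kmax <- floor(log(t_max - 1) / log(base))
  1 + base^(0:kmax)
}

#' Kuramoto order parameter
#'
#' `R = |mean(exp(1i * theta))|`: 0 for incoherent phases, 1 for full
#' synchrony.
#'
#' @param theta numeric vector of phases (radians).
#' @return a real number in `[0, 1]`.
#' @export
order_parameter <- function(theta) {
  Mod(mean(exp(1i * theta)))
}

#' Kuramoto phase velocities (reference implementation)
#'
#' Evaluates `dtheta_i = omega_i + K * sum_j W[i, j] * sin(theta_j -
#' theta_i)` through two sparse matrix-vector products (cost proportional to
#' the stored links, never dense `N^2` work).  This R implementation is the
#' readable reference; the integrator uses an equivalent compiled kernel.
#'
#' @param theta phase vector.
#' @param omega a `frequency_set` or numeric vector of intrinsic frequencies.
#' @param net an [oscillator_network()].
#' @param K global coupling.
#' @return the phase-velocity vector.
#' @export
kuramoto_rhs <- function(theta, omega, net, K) {
  n <- net$n_nodes
  if (length(theta) != n) abort("theta length does not match the network")
  omega <- as_omega(omega, n)
  s <- sin(theta); cth <- cos(theta)
  omega + K * (cth * as.numeric(net$W %*% s) - s * as.numeric(net$W %*% cth))
}

# Decide whether the compiled mean-field fast path applies and return its
# uniform weight, or NA for the generic sparse path.
mf_weight_of <- function(net) {
  w <- net$meta$uniform_weight
  if (is.null(w)) NA_real_ else as.numeric(w)
}

cpp_args <- function(net) {
  w <- mf_weight_of(net)
  if (is.na(w)) {
    list(p = net$W@p, i = net$W@i, x = net$W@x, mf = FALSE, w = 0)
  } else {
    list(p = integer(1), i = integer(0), x = numeric(0), mf = TRUE, w = w)
  }
}

#' Fixed-step RK4 integration of the Kuramoto equation
#'
#' Advances the phases from `t0` to `t_target` with classical fourth-order
#' Runge-Kutta steps of size `dt`, the final partial step shortened to land
#' exactly on `t_target`.  `engine = "r"` runs a plain R loop over
#' [kuramoto_rhs()] (reference path used in cross-checks); `engine = "cpp"`
#' runs the compiled kernel.
#'
#' @inheritParams kuramoto_rhs
#' @param dt step size.
#' @param t_target end time.
#' @param t0 start time.
#' @param engine `"cpp"` (default) or `"r"`.
#' @return the phase vector at `t_target`.
#' @export
rk4_integrate <- function(theta, omega, net, K, dt, t_target, t0 = 0,
                          engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (dt <= 0) abort("dt must be positive")
  omega_v <- as_omega(omega, net$n_nodes)
  if (engine == "cpp") {
    a <- cpp_args(net)
    return(kuramoto_rk4_cpp(net$n_nodes, a$p, a$i, a$x, a$mf, a$w,
                            omega_v, theta, K, dt, t0, t_target))
  }
  t <- t0
  eps <- 1e-12
  while (t_target - t > eps) {
    h <- min(dt, t_target - t)
    k1 <- kuramoto_rhs(theta, omega_v, net, K)
    k2 <- kuramoto_rhs(theta + 0.5 * h * k1, omega_v, net, K)
    k3 <- kuramoto_rhs(theta + 0.5 * h * k2, omega_v, net, K)
    k4 <- kuramoto_rhs(theta + h * k3, omega_v, net, K)
    theta <- theta + (h / 6) * (k1 + 2 * (k2 + k3) + k4)
    t <- t + h
  }
  if (!all(is.finite(theta))) abort("integration blow-up: non-finite state")
  theta
}

#' Run one Kuramoto realization
#'
#' Draws intrinsic frequencies (from `config$omega_seed`) and initial phases
#' (uniform on `(0, 2*pi]` from `config$phase_seed`, or all zero for a
#' coherent start), integrates to `t_max`, samples `R(t)` on the
#' [sampling_times()] schedule, and records the first-passage time `t_x` at
#' which `R` first falls below the threshold.  Following the midpoint
#' convention, `t_x = (t_k + t_(k-1)) / 2` where `t_k` is the first sampled
#' instant with `R < R_T` (with `t_(-1) = 0`, so a first sample already
#' below threshold gives `t_x = t_0 / 2`).
#'
#' @param net an [oscillator_network()].
#' @param config a [sim_config()].
#' @param early_exit stop integrating at the first threshold crossing
#'   (duration-statistics mode); if `FALSE` the full `R(t)` curve is sampled
#'   regardless of crossings (growth/decay-curve mode).
#' @return a `kuramoto_trajectory`: list with `times`, `R` (NA after an
#'   early exit), `t_x`, `crossed`, `threshold` and the config.
#' @export
run_realization <- function(net, config, early_exit = FALSE) {
  times <- sampling_times(config$t_max, config$sample_base)
  n <- net$n_nodes
  threshold <- if (is.null(config$threshold)) noise_threshold(n)
               else config$threshold
  set.seed(config$omega_seed)
  omega <- rnorm(n)
  if (config$init_kind == "incoherent") {
    set.seed(config$phase_seed)
    theta0 <- runif(n, 0, 2 * pi)
  } else {
    theta0 <- numeric(n)
  }
  a <- cpp_args(net)
  res <- kuramoto_run_cpp(n, a$p, a$i, a$x, a$mf, a$w, omega, theta0,
                          config$coupling_K, config$dt, times, threshold,
                          early_exit, FALSE)
  fb <- res$first_below
  crossed <- !is.na(fb)
  t_x <- if (!crossed) config$t_max
         else if (fb == 1) times[1] / 2
         else (times[fb] + times[fb - 1]) / 2
  structure(list(times = times, R = res$R, t_x = t_x, crossed = crossed,
                 threshold = threshold, config = config),
            class = "kuramoto_trajectory")
}

#' @export
print.kuramoto_trajectory <- function(x, ...) {
  cat(sprintf("<kuramoto_trajectory> %d samples to t=%.4g; %s\n",
              length(x$times), max(x$times),
              if (x$crossed) sprintf("crossed R_T=%.4g at t_x=%.4g",
                                     x$threshold, x$t_x)
              else "never crossed (censored)"))
  invisible(x)
}

#' @rdname run_realization
#' @param x a `kuramoto_trajectory`.
#' @param ... unused.
#' @return for `tidy()`: a tibble with columns `t` and `R`.
#' @export
tidy.kuramoto_trajectory <- function(x, ...) {
  tibble(t = x$times, R = x$R)
}

#' Run an ensemble of Kuramoto realizations
#'
#' Repeats [run_realization()] `n_realizations` times with fresh intrinsic
#' frequencies and initial phases per realization (seeds derived
#' deterministically from `base_seed` on two independent streams), and
#' aggregates the ensemble mean `<R(t_k)>` and the first-passage sample.
#'
#' Two run modes mirror the two measurements: `mode = "duration"` terminates
#' each realization at its first threshold crossing (the cheap protocol for
#' first-passage statistics; `<R>` is then averaged over still-running
#' realizations only), while `mode = "curve"` integrates every realization to
#' `t_max` so `<R(t)>` is an unconditional ensemble mean.
#'
#' @inheritParams run_realization
#' @param n_realizations ensemble size.
#' @param base_seed master seed; realization `r` uses seeds derived from
#'   `(base_seed, r)`.
#' @param mode `"curve"` or `"duration"`.
#' @param progress print a progress line every `progress` realizations
#'   (0 = silent).
#' @return a `kuramoto_ensemble`: list with tibbles `durations`
#'   (`realization`, `t_x`, `crossed`) and `mean_R` (`t`, `mean_R`, `n_live`,
#'   `n`), plus `config`, `mode`, `threshold`, `n_realizations`, `base_seed`.
#' @export
run_ensemble <- function(net, config, n_realizations, base_seed = 1L,
                         mode = c("curve", "duration"), progress = 0L) {
  mode <- match.arg(mode)
  if (n_realizations < 1) abort("n_realizations must be >= 1")
  times <- sampling_times(config$t_max, config$sample_base)
  ns <- length(times)
  Rsum <- numeric(ns)
  Rcnt <- integer(ns)
  t_x <- numeric(n_realizations)
  crossed <- logical(n_realizations)
  threshold <- if (is.null(config$threshold)) noise_threshold(net$n_nodes)
               else config$threshold
  for (r in seq_len(n_realizations)) {
    cfg <- config
    cfg$omega_seed <- derive_seed(base_seed, r, 0L)
    cfg$phase_seed <- derive_seed(base_seed, r, 1L)
    traj <- run_realization(net, cfg, early_exit = (mode == "duration"))
    ok <- !is.na(traj$R)
    Rsum[ok] <- Rsum[ok] + traj$R[ok]
    Rcnt[ok] <- Rcnt[ok] + 1L
    t_x[r] <- traj$t_x
    crossed[r] <- traj$crossed
    if (progress > 0 && r %% progress == 0)
      message(sprintf("realization %d / %d", r, n_realizations))
  }
  n_live <- vapply(seq_along(times), function(k) {
    sum(!crossed | t_x > times[k])
  }, integer(1))
  structure(
    list(durations = tibble(realization = seq_len(n_realizations),
                            t_x = t_x, crossed = crossed),
         mean_R = tibble(t = times,
                         mean_R = ifelse(Rcnt > 0, Rsum / Rcnt, NA_real_),
                         n_live = n_live, n = Rcnt),
         config = config, mode = mode, threshold = threshold,
         n_realizations = n_realizations, base_seed = base_seed),
    class = "kuramoto_ensemble")
}

#' @export
print.kuramoto_ensemble <- function(x, ...) {
  cat(sprintf(
    "<kuramoto_ensemble> K=%.4g  n=%d  mode=%s  censored=%d (%.1f%%)\n",
    x$config$coupling_K, x$n_realizations, x$mode,
    sum(!x$durations$crossed),
    100 * mean(!x$durations$crossed)))
  invisible(x)
}

#' @rdname run_ensemble
#' @param x a `kuramoto_ensemble`.
#' @param ... unused.
#' @return for `tidy()`: the `mean_R` tibble; for `glance()`: a one-row
#'   summary tibble.
#' @export
tidy.kuramoto_ensemble <- function(x, ...) x$mean_R

#' @rdname run_ensemble
#' @export
glance.kuramoto_ensemble <- function(x, ...) {
  tibble(coupling_K = x$config$coupling_K,
         n_realizations = x$n_realizations,
         mode = x$mode,
         threshold = x$threshold,
         n_censored = sum(!x$durations$crossed),
         censoring_fraction = mean(!x$durations$crossed),
         final_mean_R = utils::tail(x$mean_R$mean_R, 1))
}

#' Write ensemble outputs as plain-text files
#'
#' Emits `durations.csv` (`realization`, `t_x`, `crossed`), `mean_R.csv`
#' (`t`, `mean_R`, `n_live`, `n`) and a `config.json` sidecar echoing all
#' parameters and seeds.
#'
#' @param ens a `kuramoto_ensemble`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ens, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(ens$durations, file.path(dir, "durations.csv"),
                   row.names = FALSE)
  utils::write.csv(ens$mean_R, file.path(dir, "mean_R.csv"),
                   row.names = FALSE)
  sidecar <- c(ens$config, list(mode = ens$mode, threshold = ens$threshold,
                                n_realizations = ens$n_realizations,
                                base_seed = ens$base_seed))
  jsonlite::write_json(sidecar, file.path(dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}

#' Read ensemble outputs written by [write_ensemble()]
#'
#' @param dir directory containing `durations.csv` and `mean_R.csv`.
#' @return a `kuramoto_ensemble` (config restored from the sidecar).
#' @export
read_ensemble <- function(dir) {
  f1 <- file.path(dir, "durations.csv")
  f2 <- file.path(dir, "mean_R.csv")
  f3 <- file.path(dir, "config.json")
  missing <- c(f1, f2, f3)[!file.exists(c(f1, f2, f3))]
  if (length(missing))
    abort(paste0("missing ensemble files: ",
                 paste(missing, collapse = ", ")))
  side <- jsonlite::read_json(f3, simplifyVector = TRUE)
  config <- sim_config(coupling_K = side$coupling_K, dt = side$dt,
                       t_max = side$t_max, sample_base = side$sample_base,
                       init_kind = side$init_kind,
                       threshold = side$threshold,
                       omega_seed = side$omega_seed,
                       phase_seed = side$phase_seed)
  durations <- as_tibble(utils::read.csv(f1))
  mean_R <- as_tibble(utils::read.csv(f2))
  structure(list(durations = durations, mean_R = mean_R, config = config,
                 mode = side$mode, threshold = side$threshold,
                 n_realizations = side$n_realizations,
                 base_seed = side$base_seed),
            class = "kuramoto_ensemble")
}
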