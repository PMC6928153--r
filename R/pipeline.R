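#' Experiment configuration
#'
#' A fully serializable description of one experiment campaign: how to build
#' (or load) the graph, which couplings to sweep, the ensemble and sampling
#' parameters, and the analysis settings.  A config plus its `base_seed`
#' determines every output.
#'
#' @param graph named list: `kind` (`"2dll"`, `"full"`,
#'   `"synthetic-connectome"` or `"edgelist"`), construction parameters
#'   (`L`, `n`, `path`, ...), and preparation flags `normalize`,
#'   `flip_fraction`, `flip_mode`, `node_flip_fraction`, `node_flip_direction`.
#' @param K_values couplings to simulate.
#' @param n_realizations ensemble size per coupling.
#' @param dt,t_max,sample_base,init_kind,threshold see [sim_config()].
#' @param mode `"curve"` or `"duration"` (see [run_ensemble()]).
#' @param t_min_tail tail-fit threshold for [fit_tail()].
#' @param target_bins histogram bin-count target.
#' @param out_dir output directory.
#' @param base_seed master seed.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(graph, K_values, n_realizations = 100L,
                              dt = 0.1, t_max = 1000, sample_base = 1.08,
                              init_kind = "incoherent", threshold = NULL,
                              mode = "duration", t_min_tail = 10,
                              target_bins = 40L, out_dir = "kuranet-out",
                              base_seed = 1L) {
  stopifnot(is.list(graph), !is.null(graph$kind))
  structure(list(graph = graph, K_values = K_values,
                 n_realizations = as.integer(n_realizations), dt = dt,
                 t_max = t_max, sample_base = sample_base,
                 init_kind = init_kind, threshold = threshold, mode = mode,
                 t_min_tail = t_min_tail,
                 target_bins = as.integer(target_bins),
                 out_dir = out_dir, base_seed = as.integer(base_seed)),
            class = "experiment_config")
}

fmt_value <- function(v) {
  if (is.null(v)) return("null")
  if (is.logical(v)) return(paste(ifelse(v, "true", "false"), collapse = ", "))
  if (is.numeric(v)) return(paste(format(v, digits = 15, scientific = FALSE,
                                         trim = TRUE), collapse = ", "))
  paste(as.character(v), collapse = ", ")
}

parse_value <- function(s) {
  s <- trimws(s)
  if (identical(s, "null")) return(NULL)
  parts <- trimws(strsplit(s, ",")[[1]])
  if (all(parts %in% c("true", "false"))) return(parts == "true")
  num <- suppressWarnings(as.numeric(parts))
  if (!anyNA(num)) return(num)
  parts
}

#' Write an experiment config as flat key-value text
#'
#' Human-diffable format: `[section]` headers with `key = value` lines;
#' lists are comma-separated.  [read_experiment_config()] inverts it.
#'
#' @param cfg an [experiment_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(cfg, path) {
  lines <- c("[graph]",
             vapply(names(cfg$graph),
                    function(k) paste(k, "=", fmt_value(cfg$graph[[k]])),
                    character(1)),
             "", "[experiment]")
  for (k in setdiff(names(cfg), "graph"))
    lines <- c(lines, paste(k, "=", fmt_value(cfg[[k]])))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config not found: ", path))
  lines <- readLines(path)
  section <- ""
  graph <- list()
  rest <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- parse_value(paste(kv[-1], collapse = "="))
    if (section == "graph") graph[[key]] <- val else rest[[key]] <- val
  }
  experiment_config(graph = graph,
                    K_values = rest$K_values,
                    n_realizations = rest$n_realizations,
                    dt = rest$dt, t_max = rest$t_max,
                    sample_base = rest$sample_base,
                    init_kind = rest$init_kind,
                    threshold = rest$threshold,
                    mode = rest$mode, t_min_tail = rest$t_min_tail,
                    target_bins = rest$target_bins,
                    out_dir = rest$out_dir, base_seed = rest$base_seed)
}

#' Build (or load) and prepare the experiment graph
#'
#' Dispatches on `cfg$graph$kind`, then applies the standard preparation
#' pipeline in fixed order: largest component, optional incoming-weight
#' normalization, optional link/node sign flips.  Writes the prepared graph
#' as `graph.tsv` under the output directory.
#'
#' @param cfg an [experiment_config()].
#' @param write write `graph.tsv` under `cfg$out_dir`.
#' @return the prepared [oscillator_network()].
#' @export
pipeline_generate <- function(cfg, write = TRUE) {
  g <- cfg$graph
  seed <- if (!is.null(g$seed)) g$seed else cfg$base_seed
  net <- switch(g$kind,
    "2dll" = make_2dll(g$L, seed = seed),
    "full" = make_full_graph(g$n,
                             normalized = isTRUE(g$normalized) ||
                               is.null(g$normalized)),
    "synthetic-connectome" = make_synthetic_connectome(
      g$n, n_modules = g$n_modules %||% 32L,
      intra_density = g$intra_density %||% 0.05,
      inter_density = g$inter_density %||% 0.002,
      weight_tail_exponent = g$weight_tail_exponent %||% 3,
      seed = seed),
    "edgelist" = load_edge_list(g$path),
    abort(paste0("unknown graph kind: ", g$kind)))
  net <- largest_component(net)
  if (isTRUE(g$normalize)) net <- normalize_incoming(net)
  if (!is.null(g$flip_fraction) && g$flip_fraction > 0)
    net <- flip_links(net, g$flip_fraction,
                      mode = g$flip_mode %||% "symmetric",
                      seed = derive_seed(seed, 1L, 3L))
  if (!is.null(g$node_flip_fraction) && g$node_flip_fraction > 0)
    net <- flip_nodes(net, g$node_flip_fraction,
                      direction = g$node_flip_direction %||% "out",
                      seed = derive_seed(seed, 2L, 3L))
  if (write) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_edge_list(net, file.path(cfg$out_dir, "graph.tsv"))
  }
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

k_dir <- function(cfg, K) file.path(cfg$out_dir, sprintf("K_%g", K))

#' Run the simulation stage of an experiment
#'
#' One ensemble per coupling in `cfg$K_values`, each written to its own
#' subdirectory (`K_<value>/`) with duration and mean-R CSVs and a config
#' sidecar.  Completed couplings are recorded in a `manifest` file and
#' skipped on re-run, so interrupted campaigns resume where they stopped.
#'
#' @param cfg an [experiment_config()].
#' @param net optionally a pre-built network (otherwise [pipeline_generate()]
#'   is called).
#' @param progress passed to [run_ensemble()].
#' @return invisibly, the vector of per-coupling output directories.
#' @export
pipeline_simulate <- function(cfg, net = NULL, progress = 0L) {
  if (is.null(net)) net <- pipeline_generate(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- file.path(cfg$out_dir, "manifest")
  done <- if (file.exists(manifest)) readLines(manifest) else character(0)
  dirs <- character(0)
  for (ik in seq_along(cfg$K_values)) {
    K <- cfg$K_values[ik]
    dk <- k_dir(cfg, K)
    dirs <- c(dirs, dk)
    tag <- sprintf("K_%g", K)
    if (tag %in% done && file.exists(file.path(dk, "durations.csv"))) {
      message(sprintf("[simulate] %s already done, skipping", tag))
      next
    }
    config <- sim_config(coupling_K = K, dt = cfg$dt, t_max = cfg$t_max,
                         sample_base = cfg$sample_base,
                         init_kind = cfg$init_kind,
                         threshold = cfg$threshold)
    ens <- run_ensemble(net, config, cfg$n_realizations,
                        base_seed = derive_seed(cfg$base_seed, ik, 11L),
                        mode = cfg$mode, progress = progress)
    write_ensemble(ens, dk)
    cat(tag, "\n", file = manifest, append = TRUE)
    message(sprintf("[simulate] %s: %d runs, %.1f%% censored", tag,
                    cfg$n_realizations,
                    100 * mean(!ens$durations$crossed)))
  }
  invisible(dirs)
}

#' Run the analysis stage of an experiment
#'
#' For each simulated coupling: a power-law-binned duration histogram and
#' tail fit (where enough crossings exist) and the late-time effective
#' exponent; across couplings, the transition location where the grid
#' brackets it.  Writes per-coupling `fit_report.json`, a campaign-level
#' `transition.json` and `summary.csv`.
#'
#' @param cfg an [experiment_config()].
#' @return a summary tibble with one row per coupling: `K`, `tau_t`,
#'   `tau_se`, `eta_late`, `censoring_fraction`, `n_realizations`.
#' @export
pipeline_analyze <- function(cfg) {
  dirs <- k_dir(cfg, cfg$K_values)
  missing <- dirs[!dir.exists(dirs)]
  if (length(missing))
    abort(paste0("missing simulation outputs: ",
                 paste(missing, collapse = ", ")))
  eta_all <- list()
  rows <- list()
  for (ik in seq_along(cfg$K_values)) {
    K <- cfg$K_values[ik]
    ens <- read_ensemble(dirs[ik])
    tau <- NA_real_; tau_se <- NA_real_
    fitj <- NULL
    if (sum(ens$durations$crossed) >= 10) {
      h <- build_histogram(ens, target_bins = cfg$target_bins)
      fit <- tryCatch(suppressWarnings(fit_tail(h, cfg$t_min_tail)),
                      error = function(e) NULL)
      if (!is.null(fit)) {
        tau <- fit$exponent; tau_se <- fit$stderr
        fitj <- list(exponent = fit$exponent, stderr = fit$stderr,
                     window = fit$fit_window, n_points = fit$n_points,
                     censoring = mean(!ens$durations$crossed))
      }
    }
    eta <- tryCatch(effective_exponent(ens), error = function(e) NULL)
    eta_late <- NA_real_
    if (!is.null(eta)) {
      eta_all[[ik]] <- eta
      tail_part <- utils::tail(eta$eta_eff[is.finite(eta$eta_eff)], 10)
      if (length(tail_part)) eta_late <- mean(tail_part)
    }
    if (!is.null(fitj))
      jsonlite::write_json(fitj, file.path(dirs[ik], "fit_report.json"),
                           auto_unbox = TRUE, digits = NA)
    rows[[ik]] <- tibble(K = K, tau_t = tau, tau_se = tau_se,
                         eta_late = eta_late,
                         censoring_fraction = mean(!ens$durations$crossed),
                         n_realizations = nrow(ens$durations))
  }
  summary_tbl <- dplyr::bind_rows(rows)
  utils::write.csv(summary_tbl, file.path(cfg$out_dir, "summary.csv"),
                   row.names = FALSE)
  eta_family <- dplyr::bind_rows(eta_all)
  trans <- tryCatch(locate_transition(eta_family), error = function(e) NULL)
  if (!is.null(trans))
    jsonlite::write_json(
      list(K_grid = cfg$K_values, trends = trans$trends,
           bracket = trans$bracket, estimate = trans$K_c),
      file.path(cfg$out_dir, "transition.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "columns")
  summary_tbl
}

#' Canned experiment recipes
#'
#' Reduced-scale versions of the three experiment families: growth duration
#' statistics on the 2dll lattice at its critical coupling
#' (`"2dll-critical"`), a coupling sweep of growth curves on the 2dll
#' lattice (`"2dll-growth"`), growth on the synthetic modular connectome
#' surrogate (`"connectome-growth"`), and the inhibitory-link variant
#' (`"inhibitory"`).
#'
#' @param name recipe name.
#' @param out_dir output directory.
#' @param base_seed master seed.
#' @return an [experiment_config()].
#' @export
recipe_config <- function(name = c("2dll-critical", "2dll-growth",
                                   "connectome-growth", "inhibitory"),
                          out_dir = file.path("kuranet-out", name),
                          base_seed = 1L) {
  name <- match.arg(name)
  switch(name,
    "2dll-critical" = experiment_config(
      graph = list(kind = "2dll", L = 32, seed = base_seed),
      K_values = 0.4775, n_realizations = 400L, t_max = 300,
      mode = "duration", t_min_tail = 10,
      out_dir = out_dir, base_seed = base_seed),
    "2dll-growth" = experiment_config(
      graph = list(kind = "2dll", L = 32, seed = base_seed),
      K_values = c(0.46, 0.47, 0.4775, 0.485, 0.50),
      n_realizations = 100L, t_max = 200, mode = "curve",
      out_dir = out_dir, base_seed = base_seed),
    "connectome-growth" = experiment_config(
      graph = list(kind = "synthetic-connectome", n = 800, seed = base_seed,
                   normalize = TRUE),
      K_values = c(1.2, 1.5, 1.7, 2.0), n_realizations = 100L,
      t_max = 200, mode = "duration", t_min_tail = 20,
      out_dir = out_dir, base_seed = base_seed),
    "inhibitory" = experiment_config(
      graph = list(kind = "synthetic-connectome", n = 800, seed = base_seed,
                   normalize = TRUE, flip_fraction = 0.05,
                   flip_mode = "symmetric"),
      K_values = c(1.4, 1.6, 1.8), n_realizations = 100L,
      t_max = 200, mode = "duration", t_min_tail = 20,
      out_dir = out_dir, base_seed = base_seed))
}
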