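#' Oscillator network objects
#'
#' An `oscillator_network` bundles the weighted coupling matrix of a Kuramoto
#' system with provenance metadata.  The matrix `W` is stored sparse
#' (`Matrix::dgCMatrix`); row `i` is the *receiving* node, column `j` the
#' *sending* node, so the coupling term of node `i` is
#' `K * sum_j W[i, j] * sin(theta_j - theta_i)`.
#'
#' @param W square sparse (or coercible) numeric matrix with zero diagonal.
#' @param kind label describing the construction (`"2dll"`, `"full"`,
#'   `"synthetic-connectome"`, `"loaded"`, ...).
#' @param is_symmetric logical; if `NULL` it is determined from `W`.
#' @param meta named list of free-form provenance (seeds, sizes, fractions).
#'
#' @return an object of class `oscillator_network` with elements `W`,
#'   `n_nodes`, `is_symmetric`, `kind` and `meta`.
#' @export
oscillator_network <- function(W, kind = "custom", is_symmetric = NULL,
                               meta = list()) {
  W <- methods::as(methods::as(methods::as(W, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  if (nrow(W) != ncol(W)) abort("coupling matrix must be square")
  if (is.null(is_symmetric)) is_symmetric <- Matrix::isSymmetric(W)
  net <- structure(
    list(W = W, n_nodes = nrow(W), is_symmetric = is_symmetric,
         kind = kind, meta = meta),
    class = "oscillator_network")
  validate_network(net)
  net
}

#' Validate the invariants of an oscillator network
#'
#' Checks that the diagonal is zero (no self-coupling), that all stored
#' weights are finite, and that the symmetry flag matches the matrix.
#'
#' @param net an [oscillator_network()].
#' @return `net`, invisibly; an error if an invariant is violated.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "oscillator_network"))
  W <- net$W
  if (any(Matrix::diag(W) != 0)) abort("self-coupling: nonzero diagonal in W")
  if (length(W@x) && !all(is.finite(W@x))) abort("non-finite weights in W")
  if (net$is_symmetric && !Matrix::isSymmetric(W))
    abort("network flagged symmetric but W is not")
  invisible(net)
}

#' @export
print.oscillator_network <- function(x, ...) {
  m <- Matrix::nnzero(x$W)
  cat(sprintf("<oscillator_network> kind=%s  N=%d  stored links=%d  %s\n",
              x$kind, x$n_nodes, m,
              if (x$is_symmetric) "symmetric" else "directed"))
  invisible(x)
}

#' Edge table of a network
#'
#' @param x an [oscillator_network()].
#' @param ... unused.
#' @return a tibble with one row per stored directed entry: `from` (sending),
#'   `to` (receiving), `weight`; node ids are 1-based.
#' @export
as_tibble.oscillator_network <- function(x, ...) {
  s <- Matrix::summary(x$W)
  tibble(from = s$j, to = s$i, weight = s$x)
}

# Undirected link positions (i < j) present in W or t(W), as a two-column
# matrix of 1-based indices.
undirected_links <- function(net) {
  s <- Matrix::summary(net$W)
  i <- pmin(s$i, s$j)
  j <- pmax(s$i, s$j)
  keep <- !duplicated(i + (j - 1) * as.numeric(net$n_nodes))
  cbind(i = i[keep], j = j[keep])
}

#' Two-dimensional lattice with random long-range links (2dll)
#'
#' Builds the small-world substrate used for the mean-field-like reference
#' runs: an `L x L` periodic square lattice (each node coupled to its four
#' nearest neighbours with weight 1) plus `floor(L^2 / 2)` additional distinct
#' long-range edges between uniformly random node pairs, giving mean degree
#' `4 + 2*floor(N/2)/N ~ 5`.
#'
#' @param L lattice side length (`L >= 3`); the network has `N = L^2` nodes.
#' @param seed RNG seed for the long-range links.
#' @return a symmetric [oscillator_network()] of kind `"2dll"`.
#' @export
make_2dll <- function(L, seed = 1L) {
  if (!is.numeric(L) || length(L) != 1 || L < 3 || L != round(L))
    abort("L must be a single integer >= 3")
  L <- as.integer(L)
  N <- L * L
  idx <- 0:(N - 1)
  px <- idx %% L
  py <- idx %/% L
  right <- ((px + 1L) %% L) + py * L
  down <- px + ((py + 1L) %% L) * L
  ei <- c(idx, idx)
  ej <- c(right, down)
  pair_key <- function(a, b) pmin(a, b) * as.numeric(N) + pmax(a, b)
  have <- pair_key(ei, ej)

  m <- N %/% 2L
  set.seed(seed)
  li <- integer(0); lj <- integer(0)
  while (length(li) < m) {
    need <- m - length(li)
    a <- sample.int(N, 2L * need + 16L, replace = TRUE) - 1L
    b <- sample.int(N, 2L * need + 16L, replace = TRUE) - 1L
    k <- pair_key(a, b)
    ok <- a != b & !(k %in% have) & !duplicated(k)
    li <- c(li, a[ok]); lj <- c(lj, b[ok])
    have <- c(have, k[ok])
    if (length(li) > m) { li <- li[seq_len(m)]; lj <- lj[seq_len(m)] }
  }

  ii <- c(ei, li); jj <- c(ej, lj)
  W <- sparseMatrix(i = c(ii, jj) + 1L, j = c(jj, ii) + 1L, x = 1,
                    dims = c(N, N))
  oscillator_network(W, kind = "2dll", is_symmetric = TRUE,
                     meta = list(L = L, seed = seed,
                                 n_lattice_edges = 2L * N,
                                 n_long_range = m))
}

#' Complete (all-to-all) coupling graph
#'
#' Mean-field reference fixture.  With `normalized = TRUE` every off-diagonal
#' weight is `1/(N-1)` so each row sums to 1 and the classical mean-field
#' critical coupling `K_c = 2*sqrt(2*pi)/pi ~ 1.596` applies for standard
#' normal intrinsic frequencies.
#'
#' @param n number of nodes (`n >= 2`).
#' @param normalized logical; divide weights by `n - 1`.
#' @return a symmetric [oscillator_network()] of kind `"full"`.
#' @export
make_full_graph <- function(n, normalized = TRUE) {
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n))
    abort("n must be a single integer >= 2")
  n <- as.integer(n)
  w <- if (normalized) 1 / (n - 1) else 1
  W <- Matrix::Matrix(w, n, n, sparse = TRUE)
  Matrix::diag(W) <- 0
  W <- drop0(W)
  oscillator_network(W, kind = "full", is_symmetric = TRUE,
                     meta = list(normalized = normalized, uniform_weight = w))
}

#' Synthetic hierarchical-modular connectome surrogate
#'
#' Generates a symmetric weighted graph emulating the statistical structure of
#' large DTI connectomes: two hierarchy levels (modules nested inside
#' module groups), dense intra-module and sparse inter-module wiring, and
#' Pareto-tailed positive weights standing in for fiber-tract counts.  A
#' spanning backbone (within and between modules) forces a single connected
#' component.  Module sizes are log-normally dispersed, mimicking the wide
#' size range of anatomical parcellations.
#'
#' @param n_nodes total number of nodes.
#' @param n_modules number of bottom-level modules (`>= 2`).
#' @param intra_density edge density inside a module, in `(0, 1]`.
#' @param inter_density edge density between modules in different groups, in
#'   `(0, 1]`; pairs of modules in the same group use the geometric mean of
#'   the two densities (the intermediate hierarchy level).
#' @param weight_tail_exponent Pareto tail exponent `alpha > 1` of the weight
#'   density `p(w) ~ w^-alpha`, `w >= 1`.
#' @param seed RNG seed.
#' @return a symmetric [oscillator_network()] of kind
#'   `"synthetic-connectome"`; the planted module membership is in
#'   `meta$membership`.
#' @export
make_synthetic_connectome <- function(n_nodes, n_modules = 32L,
                                      intra_density = 0.05,
                                      inter_density = 0.002,
                                      weight_tail_exponent = 3,
                                      seed = 1L) {
  if (n_modules < 2) abort("n_modules must be >= 2")
  if (intra_density <= 0 || intra_density > 1 ||
      inter_density <= 0 || inter_density > 1)
    abort("densities must lie in (0, 1]")
  if (weight_tail_exponent <= 1) abort("weight_tail_exponent must be > 1")
  if (n_nodes < 2 * n_modules) abort("n_nodes too small for n_modules")
  set.seed(seed)

  # log-normally dispersed module sizes, minimum 2 nodes
  raw <- exp(rnorm(n_modules, 0, 1))
  sizes <- pmax(2L, as.integer(round(raw / sum(raw) * n_nodes)))
  while (sum(sizes) != n_nodes) {
    k <- sample.int(n_modules, 1)
    if (sum(sizes) > n_nodes && sizes[k] > 2L) sizes[k] <- sizes[k] - 1L
    if (sum(sizes) < n_nodes) sizes[k] <- sizes[k] + 1L
  }
  membership <- rep(seq_len(n_modules), times = sizes)
  nodes_of <- split(seq_len(n_nodes), membership)

  # two hierarchy levels: modules belong to ~sqrt(n_modules) groups
  n_groups <- max(2L, as.integer(round(sqrt(n_modules))))
  group_of <- rep(seq_len(n_groups), length.out = n_modules)
  mid_density <- sqrt(intra_density * inter_density)

  ei <- integer(0); ej <- integer(0)
  add_pairs <- function(va, vb, dens) {
    npairs <- as.numeric(length(va)) * length(vb)
    cnt <- stats::rbinom(1, npairs, dens)
    if (cnt == 0) return(NULL)
    k <- sample.int(npairs, cnt)
    cbind(va[((k - 1) %% length(va)) + 1], vb[((k - 1) %/% length(va)) + 1])
  }
  for (m in seq_len(n_modules)) {
    v <- nodes_of[[m]]
    nv <- length(v)
    npairs <- nv * (nv - 1) / 2
    cnt <- stats::rbinom(1, npairs, intra_density)
    if (cnt > 0) {
      k <- sample.int(npairs, cnt)
      # unrank upper-triangle pairs
      a <- ceiling((2 * nv - 1 - sqrt((2 * nv - 1)^2 - 8 * k)) / 2)
      b <- k - (a - 1) * nv + (a - 1) * a / 2 + a
      ei <- c(ei, v[a]); ej <- c(ej, v[b])
    }
    # intra-module spanning chain: module internally connected
    perm <- sample(v)
    ei <- c(ei, perm[-nv]); ej <- c(ej, perm[-1])
  }
  for (m1 in seq_len(n_modules - 1)) for (m2 in (m1 + 1):n_modules) {
    dens <- if (group_of[m1] == group_of[m2]) mid_density else inter_density
    pr <- add_pairs(nodes_of[[m1]], nodes_of[[m2]], dens)
    if (!is.null(pr)) { ei <- c(ei, pr[, 1]); ej <- c(ej, pr[, 2]) }
  }
  # inter-module backbone: random spanning tree over modules
  for (m in 2:n_modules) {
    tgt <- sample.int(m - 1, 1)
    ei <- c(ei, sample(nodes_of[[m]], 1))
    ej <- c(ej, sample(nodes_of[[tgt]], 1))
  }

  # dedupe undirected pairs, drop accidental self-loops
  a <- pmin(ei, ej); b <- pmax(ei, ej)
  keep <- a != b & !duplicated(a + (b - 1) * as.numeric(n_nodes))
  a <- a[keep]; b <- b[keep]
  alpha <- weight_tail_exponent
  w <- runif(length(a))^(-1 / (alpha - 1))  # Pareto(1, alpha - 1)

  W <- sparseMatrix(i = c(a, b), j = c(b, a), x = c(w, w),
                    dims = c(n_nodes, n_nodes))
  oscillator_network(W, kind = "synthetic-connectome", is_symmetric = TRUE,
                     meta = list(seed = seed, n_modules = n_modules,
                                 n_groups = n_groups,
                                 membership = membership,
                                 intra_density = intra_density,
                                 inter_density = inter_density,
                                 weight_tail_exponent = alpha))
}

#' Draw intrinsic oscillator frequencies
#'
#' Intrinsic frequencies are i.i.d. standard normal, the conventional
#' frequency distribution for Kuramoto criticality studies.
#'
#' @param n number of oscillators.
#' @param seed RNG seed; the draw is bit-reproducible given the seed.
#' @return a `frequency_set`: list with `omega` (length-`n` numeric), `n`,
#'   and `seed`.
#' @export
draw_frequencies <- function(n, seed = 1L) {
  if (n < 1) abort("n must be >= 1")
  set.seed(seed)
  structure(list(omega = rnorm(n), n = as.integer(n), seed = seed),
            class = "frequency_set")
}

#' @export
print.frequency_set <- function(x, ...) {
  cat(sprintf("<frequency_set> n=%d seed=%s mean=%.4f sd=%.4f\n",
              x$n, format(x$seed), mean(x$omega), sd(x$omega)))
  invisible(x)
}

# Coerce a frequency_set or bare numeric vector to the omega vector.
as_omega <- function(omega, n) {
  if (inherits(omega, "frequency_set")) omega <- omega$omega
  if (length(omega) != n)
    abort(sprintf("omega has length %d but the network has %d nodes",
                  length(omega), n))
  as.numeric(omega)
}

#' Mean-field critical coupling for standard normal frequencies
#'
#' For all-to-all coupling with row-normalized weights and frequency density
#' `g`, the synchronization threshold is `K_c = 2 / (pi * g(0))`; with
#' standard normal `g` this is `2*sqrt(2*pi)/pi ~ 1.5958`.
#'
#' @param g0 frequency density at zero; defaults to the standard normal value
#'   `1/sqrt(2*pi)`.
#' @return the critical coupling.
#' @export
kc_mean_field <- function(g0 = 1 / sqrt(2 * pi)) 2 / (pi * g0)

#' First-passage noise threshold
#'
#' The desynchronization threshold used for first-passage times: the
#' incoherent-phase noise level of the order parameter, `R_T = 1/sqrt(N)`.
#'
#' @param n number of oscillators.
#' @return the threshold value.
#' @export
noise_threshold <- function(n) 1 / sqrt(n)
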