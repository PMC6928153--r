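# Small deterministic graph fixtures built in code.

ring_network <- function(n) {
  i <- seq_len(n)
  j <- c(2:n, 1L)
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1, dims = c(n, n))
  oscillator_network(W, kind = "ring")
}

path_network <- function(n) {
  i <- seq_len(n - 1)
  j <- i + 1L
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1, dims = c(n, n))
  oscillator_network(W, kind = "path")
}

# periodic square lattice without long-range links
lattice_network <- function(L) {
  N <- L * L
  idx <- 0:(N - 1)
  px <- idx %% L
  py <- idx %/% L
  right <- ((px + 1L) %% L) + py * L
  down <- px + ((py + 1L) %% L) * L
  i <- c(idx, idx) + 1L
  j <- c(right, down) + 1L
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1, dims = c(N, N))
  oscillator_network(W, kind = "lattice")
}

# hub = node 1, spokes 2..(k+1), unit weights
star_network <- function(k) {
  i <- rep(1L, k)
  j <- 2:(k + 1)
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                            dims = c(k + 1, k + 1))
  oscillator_network(W, kind = "star")
}

# Pareto tail samples with density p(t) ~ t^-tau on [1, Inf)
sample_pareto <- function(n, tau, seed) {
  set.seed(seed)
  runif(n)^(-1 / (tau - 1))
}
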