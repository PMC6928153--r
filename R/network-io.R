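#' Write a network as a plain-text edge list
#'
#' The dialect is a tab-separated file `source<TAB>target<TAB>weight` with
#' 0-based integer node ids and a `#`-prefixed header line carrying kind and
#' seed metadata.  Symmetric networks are written with one line per
#' undirected edge; directed networks with one line per stored entry and a
#' `directed=1` marker in the header.
#'
#' @param net an [oscillator_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  validate_network(net)
  meta_bits <- c(kind = net$kind,
                 n_nodes = net$n_nodes,
                 directed = as.integer(!net$is_symmetric))
  if (!is.null(net$meta$seed)) meta_bits["seed"] <- net$meta$seed
  header <- paste0("# kuranet ",
                   paste(names(meta_bits), meta_bits, sep = "=",
                         collapse = " "))
  if (net$is_symmetric) {
    s <- Matrix::summary(net$W)
    keep <- s$i < s$j
    df <- data.frame(src = s$i[keep] - 1L, dst = s$j[keep] - 1L,
                     w = s$x[keep])
  } else {
    s <- Matrix::summary(net$W)
    # line "src dst w" means: dst receives from src with weight w
    df <- data.frame(src = s$j - 1L, dst = s$i - 1L, w = s$x)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a weighted edge list as an oscillator network
#'
#' Reads the three-column whitespace/tab-separated dialect written by
#' [write_edge_list()] (and the common raw connectome edge-list format):
#' `source target weight`, arbitrary non-negative integer ids, `#` comment
#' lines.  Edges are treated as undirected; duplicate edges are merged by
#' summing their weights (weights represent fiber counts, and counts add).
#' Node ids are remapped to a dense `0..N-1` range; the mapping is kept in
#' `meta$node_map`.
#'
#' @param path input file path.
#' @return a symmetric [oscillator_network()] of kind `"loaded"`.
#' @export
load_edge_list <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  body_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(body_idx) == 0) abort("empty edge list")
  parts <- strsplit(trimws(lines[body_idx]), "[ \t]+")
  nf <- lengths(parts)
  bad <- which(nf != 3)
  if (length(bad))
    abort(sprintf("malformed line %d: expected 3 fields, got %d",
                  body_idx[bad[1]], nf[bad[1]]))
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              ncol = 3, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    abort(sprintf("malformed line %d: non-numeric field", body_idx[bad]))
  }
  if (any(m[, 3] <= 0)) {
    bad <- which(m[, 3] <= 0)[1]
    abort(sprintf("non-positive weight on line %d", body_idx[bad]))
  }
  ids <- sort(unique(c(m[, 1], m[, 2])))
  src <- match(m[, 1], ids)
  dst <- match(m[, 2], ids)
  if (any(src == dst)) abort("self-loop in edge list")
  n <- length(ids)
  # merge duplicates by weight summation; symmetrize
  W <- sparseMatrix(i = c(dst, src), j = c(src, dst), x = c(m[, 3], m[, 3]),
                    dims = c(n, n))  # sparseMatrix sums duplicate triplets
  oscillator_network(W, kind = "loaded", is_symmetric = TRUE,
                     meta = list(path = path,
                                 node_map = tibble(original_id = ids,
                                                   new_id = seq_len(n) - 1L)))
}

# igraph view of the connectivity pattern (undirected, on |W|).
as_igraph_pattern <- function(net) {
  A <- abs(net$W)
  A <- A + Matrix::t(A)
  igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Restrict a network to its largest connected component
#'
#' Connectivity is assessed on the undirected pattern of `|W|`.  Ties between
#' equally large components are broken deterministically in favour of the
#' component containing the smallest original node index.  The index mapping
#' is appended to `meta$component_nodes`.
#'
#' @param net an [oscillator_network()].
#' @return an [oscillator_network()] on the component's nodes.
#' @export
largest_component <- function(net) {
  if (net$n_nodes == 0) abort("empty graph")
  g <- as_igraph_pattern(net)
  comp <- igraph::components(g)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    first_member <- vapply(best, function(b) min(which(comp$membership == b)),
                           numeric(1))
    best <- best[which.min(first_member)]
  }
  keep <- which(comp$membership == best)
  if (length(keep) == net$n_nodes) return(net)
  W <- net$W[keep, keep, drop = FALSE]
  meta <- net$meta
  meta$component_nodes <- keep
  oscillator_network(W, kind = net$kind, meta = meta)
}

#' Normalize incoming weights
#'
#' Divides each node's received weights by their sum, `W'[i, j] = W[i, j] /
#' sum_j W[i, j]`, so every row of `W'` sums to one.  This enforces a
#' homeostatic input balance: every node receives the same total drive.  The
#' result is generally asymmetric even when the input is symmetric.
#'
#' @param net an [oscillator_network()] with positive weights.
#' @return the row-normalized [oscillator_network()].
#' @export
normalize_incoming <- function(net) {
  rs <- rowSums(net$W)
  bad <- which(rs <= 0)
  if (length(bad))
    abort(sprintf("node %d has no positive incoming weight; %s", bad[1],
                  "remove isolated nodes (largest_component) first"))
  W <- Diagonal(x = 1 / rs) %*% net$W
  meta <- net$meta
  meta$normalized <- TRUE
  if (identical(net$kind, "full"))
    meta$uniform_weight <- 1 / (net$n_nodes - 1)
  else meta$uniform_weight <- NULL
  oscillator_network(W, kind = net$kind,
                     is_symmetric = Matrix::isSymmetric(W), meta = meta)
}

# rebuild a network from a directed triplet table
net_from_triplets <- function(i, j, x, n, kind, meta) {
  keep <- x != 0
  W <- sparseMatrix(i = i[keep], j = j[keep], x = x[keep], dims = c(n, n))
  oscillator_network(W, kind = kind, meta = meta)
}

#' Flip link weights to inhibitory
#'
#' Selects `round(fraction * M)` undirected link positions (`M` = number of
#' undirected links) without replacement and negates their weights, mimicking
#' inhibitory interactions.  In `"symmetric"` mode both directions are
#' negated (`W[i,j]` and `W[j,i]`); in `"anisotropic"` mode one direction
#' (chosen uniformly at random) is negated and the reverse direction is
#' removed.
#'
#' @param net an [oscillator_network()], typically after
#'   [normalize_incoming()].
#' @param fraction fraction of undirected links to flip, in `[0, 1]`.
#' @param mode `"symmetric"` or `"anisotropic"`.
#' @param seed RNG seed for the link selection (kept independent of the
#'   frequency/phase streams).
#' @return the modified [oscillator_network()].
#' @export
flip_links <- function(net, fraction, mode = c("symmetric", "anisotropic"),
                       seed = 1L) {
  mode <- match.arg(mode)
  if (fraction < 0 || fraction > 1) abort("fraction must lie in [0, 1]")
  if (fraction == 0) return(net)
  links <- undirected_links(net)
  M <- nrow(links)
  m <- round(fraction * M)
  set.seed(seed)
  sel <- links[sample.int(M, m), , drop = FALSE]
  n <- net$n_nodes
  key <- function(i, j) i + (j - 1) * as.numeric(n)
  s <- Matrix::summary(net$W)
  i <- s$i; j <- s$j; x <- s$x
  pair_of <- key(pmin(i, j), pmax(i, j))
  sel_keys <- key(sel[, 1], sel[, 2])
  hit <- pair_of %in% sel_keys
  meta <- net$meta
  meta$flip <- list(fraction = fraction, mode = mode, seed = seed,
                    n_flipped = m)
  meta$uniform_weight <- NULL
  if (mode == "symmetric") {
    x[hit] <- -x[hit]
    out <- net_from_triplets(i, j, x, n, net$kind, meta)
    out$is_symmetric <- net$is_symmetric
    validate_network(out)
  } else {
    # per selected pair: keep direction a <- b (row a), negate; drop reverse
    flip_row <- ifelse(runif(m) < 0.5, sel[, 1], sel[, 2])
    keep_dir <- key(flip_row, sel[, 1] + sel[, 2] - flip_row)
    dir_key <- key(i, j)
    negate <- dir_key %in% keep_dir
    dropit <- hit & !negate
    x[negate] <- -x[negate]
    x[dropit] <- 0
    out <- net_from_triplets(i, j, x, n, net$kind, meta)
    out$is_symmetric <- FALSE
    out
  }
}

#' Flip all links of randomly selected nodes
#'
#' Selects `round(fraction * N)` nodes and negates all the link weights they
#' send (`direction = "out"`: column entries) or receive (`direction =
#' "in"`: row entries), modelling fully inhibitory nodes.
#'
#' @param net an [oscillator_network()].
#' @param fraction fraction of nodes to make inhibitory, in `[0, 1]`.
#' @param direction `"out"` or `"in"`.
#' @param seed RNG seed.
#' @return the modified [oscillator_network()].
#' @export
flip_nodes <- function(net, fraction, direction = c("out", "in"),
                       seed = 1L) {
  direction <- match.arg(direction)
  if (fraction < 0 || fraction > 1) abort("fraction must lie in [0, 1]")
  if (fraction == 0) return(net)
  n <- net$n_nodes
  k <- round(fraction * n)
  set.seed(seed)
  sel <- sample.int(n, k)
  s <- Matrix::summary(net$W)
  i <- s$i; j <- s$j; x <- s$x
  hit <- if (direction == "out") j %in% sel else i %in% sel
  x[hit] <- -x[hit]
  meta <- net$meta
  meta$node_flip <- list(fraction = fraction, direction = direction,
                         seed = seed, nodes = sel)
  meta$uniform_weight <- NULL
  net_from_triplets(i, j, x, n, net$kind, meta)
}

#' Delete a fraction of links uniformly at random
#'
#' Robustness probe: removes `round(fraction * M)` undirected link positions
#' (both stored directions) chosen uniformly without replacement.
#'
#' @inheritParams flip_links
#' @return the thinned [oscillator_network()].
#' @export
delete_links <- function(net, fraction, seed = 1L) {
  if (fraction < 0 || fraction > 1) abort("fraction must lie in [0, 1]")
  if (fraction == 0) return(net)
  links <- undirected_links(net)
  M <- nrow(links)
  set.seed(seed)
  sel <- links[sample.int(M, round(fraction * M)), , drop = FALSE]
  n <- net$n_nodes
  key <- function(i, j) i + (j - 1) * as.numeric(n)
  s <- Matrix::summary(net$W)
  hit <- key(pmin(s$i, s$j), pmax(s$i, s$j)) %in% key(sel[, 1], sel[, 2])
  meta <- net$meta
  meta$deleted_fraction <- fraction
  meta$uniform_weight <- NULL
  net_from_triplets(s$i[!hit], s$j[!hit], s$x[!hit], n, net$kind, meta)
}

#' Topological (chemical) dimension of a network
#'
#' Estimates the dimension `d` from the growth of the mean number of node
#' pairs within topological distance `r`, `<N_r> ~ r^d`, using breadth-first
#' shells from randomly sampled source nodes.  By default the *cumulative*
#' pair-count convention is fitted (shell counts grow as `r^(d-1)`, their
#' cumulative sum as `r^d`); `convention = "shell"` fits the shell counts and
#' reports `slope + 1`.
#'
#' The default fit window runs from `r = 2` up to the radius where the
#' cumulative count first reaches half the reachable nodes, i.e. before
#' finite-size saturation bends the curve.
#'
#' @param net a connected [oscillator_network()].
#' @param n_sources number of BFS source nodes to average over.
#' @param r_max optional cap on the shell radius.
#' @param seed RNG seed for source sampling.
#' @param convention `"cumulative"` (default) or `"shell"`.
#' @param fit_window optional `c(r_min, r_max)` override for the fit.
#' @return a `dimension_fit`: list with `shells` (tibble of `r`,
#'   `mean_shell`, `mean_cumulative`), `d_estimate`, `stderr`, `fit_window`,
#'   `convention`.
#' @export
topological_dimension <- function(net, n_sources = 10L, r_max = NULL,
                                  seed = 1L,
                                  convention = c("cumulative", "shell"),
                                  fit_window = NULL) {
  convention <- match.arg(convention)
  if (n_sources < 1) abort("n_sources must be >= 1")
  g <- as_igraph_pattern(net)
  if (igraph::components(g)$no > 1)
    abort("network is disconnected; apply largest_component() first")
  n <- net$n_nodes
  set.seed(seed)
  src <- sample.int(n, min(n_sources, n))
  d <- igraph::distances(g, v = src, weights = NA)
  dmax <- max(d[is.finite(d)])
  if (!is.null(r_max)) dmax <- min(dmax, r_max)
  radii <- seq_len(dmax)
  counts <- vapply(seq_along(src), function(k) {
    tabulate(d[k, ][d[k, ] >= 1 & d[k, ] <= dmax], nbins = dmax)
  }, numeric(dmax))
  mean_shell <- rowMeans(matrix(counts, nrow = dmax))
  mean_cum <- cumsum(mean_shell)

  if (is.null(fit_window)) {
    r_half <- radii[which(mean_cum >= max(mean_cum) / 2)[1]]
    lo <- 2L
    hi <- max(r_half, lo + 2L)
    fit_window <- c(lo, min(hi, dmax))
  }
  inwin <- radii >= fit_window[1] & radii <= fit_window[2]
  if (sum(inwin) < 3) {  # tiny graphs: fall back to the full range
    fit_window <- c(1L, dmax)
    inwin <- radii >= 1
  }
  if (convention == "cumulative") {
    yy <- mean_cum[inwin]
  } else {
    yy <- mean_shell[inwin]
  }
  xx <- radii[inwin]
  pos <- yy > 0
  if (sum(pos) < 3) abort("fit window contains fewer than 3 usable radii")
  fit <- lm(log(yy[pos]) ~ log(xx[pos]))
  # suppress the "essentially perfect fit" warning on exact lattices
  fit_summary <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[2])
  d_est <- if (convention == "cumulative") slope else slope + 1
  structure(
    list(shells = tibble(r = radii, mean_shell = mean_shell,
                         mean_cumulative = mean_cum),
         d_estimate = d_est,
         stderr = fit_summary$coefficients[2, 2],
         fit_window = fit_window,
         convention = convention,
         n_sources = length(src)),
    class = "dimension_fit")
}

#' @export
print.dimension_fit <- function(x, ...) {
  cat(sprintf("<dimension_fit> d = %.3f (se %.3f), %s convention, r in [%d, %d]\n",
              x$d_estimate, x$stderr, x$convention,
              x$fit_window[1], x$fit_window[2]))
  invisible(x)
}

#' @rdname topological_dimension
#' @param x a `dimension_fit`.
#' @param ... unused.
#' @export
tidy.dimension_fit <- function(x, ...) {
  tibble(term = "d", estimate = x$d_estimate, std.error = x$stderr,
         convention = x$convention,
         r_min = x$fit_window[1], r_max = x$fit_window[2])
}
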