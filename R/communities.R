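#' Resolution parameters for multilayer modularity
#'
#' The structural resolution `gamma` scales the intralayer
#' Newman-Girvan null (larger values favor smaller, denser communities);
#' the temporal resolution `omega` is the ordinal interlayer coupling
#' weight linking each node to its own copy in adjacent layers (larger
#' values favor labels that persist in time). Defaults are the scale at
#' which a shuffled-edge null most under-performs observed peri-stimulus
#' EEG connectivity, `gamma = 1.025`, `omega = 9`; run a [q_surface()]
#' sweep to recalibrate for other data.
#'
#' @param gamma Structural resolution, > 0.
#' @param omega Temporal resolution, >= 0.
#' @param negative_edge_rule How negative dwPLI weights are handled before
#'   modularity; only `"clip"` (set to zero) is provided, as the
#'   Newman-Girvan null assumes nonnegative weights.
#' @return A `modularity_params` list.
#' @export
modularity_params <- function(gamma = 1.025, omega = 9,
                              negative_edge_rule = c("clip")) {
  negative_edge_rule <- match.arg(negative_edge_rule)
  if (!is.numeric(gamma) || gamma <= 0) stopf("`gamma` must be > 0")
  if (!is.numeric(omega) || omega < 0) stopf("`omega` must be >= 0")
  structure(list(gamma = gamma, omega = omega,
                 negative_edge_rule = negative_edge_rule),
            class = "modularity_params")
}

#' Assemble a multilayer modularity problem
#'
#' Builds the multilayer network behind the quality function
#' \deqn{Q = \frac{1}{2\mu} \sum_{ijs} \left[ A_{ijs} - \gamma
#'   \frac{k_{is} k_{js}}{2 m_s} \right] \delta(g_{is}, g_{js})
#'   + \frac{1}{2\mu} \sum_{is} 2\,\omega\, \delta(g_{is}, g_{i,s\pm1})}
#' with one layer per retained time window, the Newman-Girvan null per
#' layer, and ordinal (adjacent-layer) interlayer coupling of weight
#' `omega`. `2mu` normalizes by the total intra- plus interlayer weight.
#' Negative edge weights are clipped to zero first; the number of clipped
#' edges is recorded.
#'
#' @param conn A `connectivity_series` (or any list with a `layers`
#'   `n x n x L` array).
#' @param params A [modularity_params()].
#' @return A `multilayer_network` with clipped `layers`, `gamma`, `omega`,
#'   per-layer strengths, `twomu`, and `n_clipped`.
#' @export
build_multilayer <- function(conn, params = modularity_params()) {
  stopifnot(inherits(params, "modularity_params"))
  layers <- conn$layers
  stopifnot(length(dim(layers)) == 3L, dim(layers)[1] == dim(layers)[2])
  n <- dim(layers)[1]; L <- dim(layers)[3]
  if (n < 2) stopf("at least 2 nodes are required")
  n_clipped <- sum(layers < 0 & !is.na(layers))
  layers[layers < 0] <- 0
  for (s in seq_len(L)) diag(layers[, , s]) <- 0
  twom <- numeric(L)
  for (s in seq_len(L)) {
    twom[s] <- sum(layers[, , s])
    if (twom[s] <= 0) stopf("layer %d has zero total weight (degenerate)", s)
  }
  twomu <- sum(twom) + 2 * params$omega * n * max(L - 1, 0)
  structure(
    list(layers = layers, n = n, L = L, gamma = params$gamma,
         omega = params$omega, twom = twom, twomu = twomu,
         n_clipped = n_clipped,
         manifest = conn$manifest %||% NULL),
    class = "multilayer_network"
  )
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat(sprintf("<multilayer_network> %d nodes x %d layers, gamma %g, omega %g (%d negative edges clipped)\n",
              x$n, x$L, x$gamma, x$omega, x$n_clipped))
  invisible(x)
}

# Dense supra-modularity matrix over node-layer tuples, column-major by
# layer: tuple (i, s) -> (s - 1) * n + i. Includes the diagonal null
# terms so that the all-in-one partition of a single layer has Q = 0.
supra_modularity_matrix <- function(net) {
  n <- net$n; L <- net$L
  B <- matrix(0, n * L, n * L)
  for (s in seq_len(L)) {
    A <- net$layers[, , s]
    k <- rowSums(A)
    idx <- (s - 1L) * n + seq_len(n)
    B[idx, idx] <- A - net$gamma * outer(k, k) / net$twom[s]
    if (s > 1L) {
      prev <- (s - 2L) * n + seq_len(n)
      B[cbind(idx, prev)] <- B[cbind(idx, prev)] + net$omega
      B[cbind(prev, idx)] <- B[cbind(prev, idx)] + net$omega
    }
  }
  B
}

#' Multilayer modularity of a given partition
#'
#' Evaluates the quality function of [build_multilayer()] for an explicit
#' label assignment; useful for oracles and for scoring partitions from
#' other sources. Invariant under community relabeling.
#'
#' @param net A `multilayer_network`.
#' @param labels `L x n` matrix (or length `n*L` vector, layer-major) of
#'   community labels.
#' @return Scalar Q.
#' @export
modularity_q <- function(net, labels) {
  lab <- as.integer(t_labels(net, labels))
  B <- supra_modularity_matrix(net)
  same <- outer(lab, lab, "==")
  sum(B[same]) / net$twomu
}

# Accept either an L x n label matrix or a flat layer-major vector and
# return the flat layer-major form.
t_labels <- function(net, labels) {
  if (is.matrix(labels)) {
    stopifnot(nrow(labels) == net$L, ncol(labels) == net$n)
    as.vector(t(labels))
  } else {
    stopifnot(length(labels) == net$n * net$L)
    as.vector(labels)
  }
}

#' Greedy multilayer community detection (one run)
#'
#' A Louvain-style optimizer of the multilayer quality function: seeded
#' random sweeps over node-layer tuples moving each to the community of
#' maximal strictly positive gain, followed by aggregation into
#' super-nodes, iterated to a local maximum. Nondeterministic across
#' seeds, bit-reproducible for a fixed seed.
#'
#' @param net A [build_multilayer()] network.
#' @param seed Integer seed for the sweep order.
#' @return A `multilayer_partition`: `labels` (`L x n` integer matrix in
#'   canonical first-appearance numbering), `Q`, `seed`, `gamma`, `omega`.
#' @export
louvain_multilayer <- function(net, seed = 1L) {
  stopifnot(inherits(net, "multilayer_network"))
  B <- supra_modularity_matrix(net)
  res <- louvain_dense(B, net$twomu, as.integer(seed))
  lab <- canonical_labels(res$labels)
  new_multilayer_partition(
    labels = matrix(lab, nrow = net$L, ncol = net$n, byrow = TRUE),
    Q = res$Q, seed = as.integer(seed), gamma = net$gamma, omega = net$omega
  )
}

new_multilayer_partition <- function(labels, Q, seed, gamma = NA_real_,
                                     omega = NA_real_) {
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, Q = Q, seed = seed, gamma = gamma,
                 omega = omega),
            class = "multilayer_partition")
}

#' @export
print.multilayer_partition <- function(x, ...) {
  cat(sprintf("<multilayer_partition> %d layers x %d nodes, %d communities, Q = %.4f (seed %s)\n",
              nrow(x$labels), ncol(x$labels),
              length(unique(as.vector(x$labels))), x$Q,
              format(x$seed)))
  invisible(x)
}

#' Ensemble of independent optimizer runs
#'
#' The greedy optimizer is nondeterministic, so the final community
#' structure is taken from an ensemble of runs (100 by default). Run `k`
#' uses seed `base_seed + k`, recorded in each member for exact replay.
#' `agreement` is the fraction of run pairs whose partitions are
#' identical up to relabeling.
#'
#' @param net A `multilayer_network`.
#' @param n_iter Number of runs.
#' @param base_seed Integer; run `k` uses `base_seed + k`.
#' @return A `partition_ensemble`: list of partitions plus `agreement`.
#' @export
partition_ensemble <- function(net, n_iter = 100L, base_seed = 0L) {
  stopifnot(is_count(n_iter), n_iter >= 1)
  runs <- lapply(seq_len(n_iter), function(k) {
    louvain_multilayer(net, seed = base_seed + k)
  })
  keys <- vapply(runs, function(p) paste(as.vector(t(p$labels)),
                                         collapse = ","), character(1))
  agreement <- if (n_iter == 1L) 1.0 else {
    tab <- table(keys)
    sum(choose(tab, 2)) / choose(n_iter, 2)
  }
  structure(list(partitions = runs, agreement = agreement,
                 base_seed = base_seed, keys = keys),
            class = "partition_ensemble")
}

#' @export
print.partition_ensemble <- function(x, ...) {
  qs <- vapply(x$partitions, `[[`, numeric(1), "Q")
  cat(sprintf("<partition_ensemble> %d runs, agreement %.3f, Q in [%.4f, %.4f]\n",
              length(x$partitions), x$agreement, min(qs), max(qs)))
  invisible(x)
}

#' Pairwise z-scored Rand similarity of two partitions
#'
#' The Rand pair-counting statistic standardized under the permutation
#' (hypergeometric) null, following the standard z-Rand formulation; when
#' the null variance is degenerate (tiny problems or single-community
#' marginals) the adjusted Rand index is returned instead so that the
#' similarity is always defined.
#'
#' @param a,b Label vectors (or `L x n` matrices) over the same items.
#' @return Scalar similarity.
#' @export
zrand <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  stopifnot(length(a) == length(b))
  n <- length(a)
  tab <- table(a, b)
  ni <- rowSums(tab); mj <- colSums(tab)
  M <- choose(n, 2)
  M1 <- sum(choose(ni, 2)); M2 <- sum(choose(mj, 2))
  w <- sum(choose(tab, 2))
  if (n < 4 || M1 == 0 || M2 == 0 || M1 == M || M2 == M) {
    return(fallback_ari(a, b))
  }
  C1 <- n * (n^2 - 3 * n - 2) - 8 * (n + 1) * M1 + 4 * sum(ni^3)
  C2 <- n * (n^2 - 3 * n - 2) - 8 * (n + 1) * M2 + 4 * sum(mj^3)
  a1 <- 4 * M1 - 2 * M
  a2 <- 4 * M2 - 2 * M
  var_w <- M / 16 -
    (a1^2 * a2^2) / (256 * M^2) +
    C1 * C2 / (16 * n * (n - 1) * (n - 2)) +
    (a1^2 - 4 * C1 - 4 * M) * (a2^2 - 4 * C2 - 4 * M) /
      (64 * n * (n - 1) * (n - 2) * (n - 3))
  if (!is.finite(var_w) || var_w <= 0) return(fallback_ari(a, b))
  (w - M1 * M2 / M) / sqrt(var_w)
}

fallback_ari <- function(a, b) {
  out <- suppressWarnings(mclust::adjustedRandIndex(a, b))
  if (!is.finite(out)) out <- as.numeric(all(canonical_labels(a) ==
                                               canonical_labels(b)))
  out
}

#' Most representative ensemble member (consensus partition)
#'
#' The final community structure is the ensemble medoid: the member
#' partition with the largest mean pairwise z-Rand similarity to all
#' other members. Ties are broken toward higher Q, then toward the lowest
#' seed. With the high run-to-run agreement typical of these networks the
#' choice of consensus rule is inconsequential.
#'
#' @param ens A [partition_ensemble()].
#' @return The selected `multilayer_partition`.
#' @export
consensus_partition <- function(ens) {
  stopifnot(inherits(ens, "partition_ensemble"))
  runs <- ens$partitions
  K <- length(runs)
  if (K == 1L) return(runs[[1L]])
  keys <- ens$keys %||% vapply(runs, function(p)
    paste(as.vector(t(p$labels)), collapse = ","), character(1))
  uk <- unique(keys)
  cls <- match(keys, uk)
  counts <- tabulate(cls, nbins = length(uk))
  reps <- match(seq_along(uk), cls)
  U <- length(uk)
  sim <- matrix(0, U, U)
  for (i in seq_len(U)) {
    for (j in i:U) {
      s <- zrand(runs[[reps[i]]]$labels, runs[[reps[j]]]$labels)
      sim[i, j] <- s; sim[j, i] <- s
    }
  }
  # mean similarity of a member in class a to the K-1 other members
  mean_sim <- vapply(seq_len(K), function(m) {
    a <- cls[m]
    (sum(counts * sim[a, ]) - sim[a, a]) / (K - 1)
  }, numeric(1))
  qs <- vapply(runs, `[[`, numeric(1), "Q")
  seeds <- vapply(runs, `[[`, numeric(1), "seed")
  ord <- order(-mean_sim, -qs, seeds)
  runs[[ord[1L]]]
}

#' Static band communities from the pre-stimulation interval
#'
#' Defines each band's community membership from the resting (pre-pulse)
#' connectivity alone, unbiased by the stimulation: a consensus multilayer
#' partition of the pre-interval layers, collapsed to one label per node
#' by taking the modal label across layers.
#'
#' @param conn A whole-epoch `connectivity_series`.
#' @param params [modularity_params()].
#' @param interval Which manifest tag defines the layer set (default
#'   `"pre"`).
#' @param n_iter,base_seed Ensemble settings (see [partition_ensemble()]).
#' @return Integer label vector (canonical numbering), with the consensus
#'   partition in attribute `"partition"`.
#' @export
static_communities <- function(conn, params = modularity_params(),
                               interval = "pre", n_iter = 100L,
                               base_seed = 0L) {
  sub <- conn_interval(conn, interval)
  net <- build_multilayer(sub, params)
  cons <- consensus_partition(partition_ensemble(net, n_iter, base_seed))
  modal <- apply(cons$labels, 2L, function(v) {
    tv <- table(v)
    as.integer(names(tv)[which.max(tv)])
  })
  out <- canonical_labels(modal)
  attr(out, "partition") <- cons
  out
}
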