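# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity.

# Textbook DFT of one real vector at bin k (0-based), O(n) per bin.
naive_dft_bin <- function(x, k) {
  n <- length(x)
  sum(x * exp(-2i * pi * k * (0:(n - 1)) / n))
}

# dwPLI by explicit summation over all ordered trial pairs.
brute_dwpli <- function(I) {
  n <- length(I)
  num <- den <- 0
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (j != k) {
        num <- num + I[j] * I[k]
        den <- den + abs(I[j] * I[k])
      }
    }
  }
  if (den == 0) 0 else num / den
}

# Exhaustive modularity maximization by enumeration of restricted-growth
# labelings (all set partitions, optionally capped at max_comm blocks).
# Q evaluated incrementally; B includes diagonal null terms.
exhaustive_modularity <- function(B, twomu, max_comm = Inf) {
  n <- nrow(B)
  best <- -Inf
  best_lab <- NULL
  lab <- integer(n)
  rec <- function(t, k, qacc) {
    if (t > n) {
      if (qacc > best) {
        best <<- qacc
        best_lab <<- lab[seq_len(n)]
      }
      return(invisible(NULL))
    }
    for (c in seq_len(min(k + 1, max_comm))) {
      members <- which(lab[seq_len(t - 1)] == c)
      dq <- B[t, t] + 2 * sum(B[t, members])
      lab[t] <<- c
      rec(t + 1L, max(k, c), qacc + dq)
    }
    lab[t] <<- 0L
  }
  rec(1L, 0L, 0)
  list(Q = best / twomu, labels = best_lab)
}

# Verify a partition is a local maximum: no single node-layer tuple move
# to any other (or new) community increases the quality.
is_local_maximum <- function(B, labels_flat) {
  n <- length(labels_flat)
  for (v in seq_len(n)) {
    cur <- labels_flat[v]
    conn <- tapply(B[v, -v], labels_flat[-v], sum)
    cur_gain <- if (as.character(cur) %in% names(conn)) {
      conn[[as.character(cur)]]
    } else 0
    if (any(conn > cur_gain + 1e-9)) return(FALSE)
    if (0 > cur_gain + 1e-9) return(FALSE) # move to a fresh community
  }
  TRUE
}

# Two disjoint unit-weight triangles as a one-layer connectivity stack.
triangles_layers <- function() {
  A <- matrix(0, 6, 6)
  edges <- list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))
  for (e in edges) {
    A[e[1], e[2]] <- 1
    A[e[2], e[1]] <- 1
  }
  list(layers = array(A, c(6, 6, 1)))
}

# Random symmetric nonnegative layer stack with planted two-block
# structure of given strength (0 = i.i.d. weights).
planted_layers <- function(n, L, strength = 0.6, seed = 1) {
  stopifnot(n %% 2 == 0)
  half <- n / 2
  blocks <- c(rep(1, half), rep(2, half))
  set.seed(seed)
  layers <- array(0, c(n, n, L))
  for (s in seq_len(L)) {
    A <- matrix(stats::runif(n * n, 0.05, 0.4), n, n)
    A <- (A + t(A)) / 2
    within <- outer(blocks, blocks, "==")
    A[within] <- A[within] + strength
    diag(A) <- 0
    layers[, , s] <- A
  }
  list(layers = layers, truth = blocks)
}

# Small manifest for hand-built connectivity series.
toy_manifest <- function(n_pre, n_post) {
  L <- n_pre + 1L + n_post
  tibble::tibble(
    index = seq_len(L),
    offset_samples = seq_len(L) - n_pre - 1L,
    center_s = (seq_len(L) - n_pre - 1L) / 128,
    tag = c(rep("pre", n_pre), "pulse", rep("post", n_post))
  )
}

toy_conn <- function(layers, n_pre, n_post, band = c(8, 12)) {
  netreconf:::new_connectivity_series(layers, band = band,
                                      manifest = toy_manifest(n_pre, n_post),
                                      label = "toy")
}

# Hand-built multilayer partition object.
toy_partition <- function(labels, Q = NA_real_, seed = 0L) {
  netreconf:::new_multilayer_partition(labels, Q = Q, seed = seed)
}
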