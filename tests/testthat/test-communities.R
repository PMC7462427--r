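test_that("two disjoint triangles reproduce the closed-form modularity", {
  net <- build_multilayer(triangles_layers(), modularity_params(gamma = 1, omega = 0))
  truth <- c(1, 1, 1, 2, 2, 2)
  # closed form: per triangle, e_in/2m - (k_tot/2m)^2 with 2m = 12
  q_expected <- 2 * (6 / 12 - (6 / 12)^2)
  expect_equal(modularity_q(net, matrix(truth, 1)), q_expected)
  expect_equal(q_expected, 0.5)

  p <- louvain_multilayer(net, seed = 1)
  expect_equal(as.vector(p$labels), canonical_labels(truth))
  expect_equal(p$Q, q_expected)

  # exhaustive search over all 203 partitions of 6 nodes agrees
  B <- netreconf:::supra_modularity_matrix(net)
  ex <- exhaustive_modularity(B, net$twomu)
  expect_equal(ex$Q, q_expected)
  expect_equal(canonical_labels(ex$labels), canonical_labels(truth))
})

test_that("the all-in-one partition of a single layer has Q = 0", {
  net <- build_multilayer(triangles_layers(), modularity_params(gamma = 1, omega = 0))
  expect_equal(modularity_q(net, matrix(1L, 1, 6)), 0)
})

test_that("Q is invariant under relabeling and node reordering", {
  pl <- planted_layers(6, 3, strength = 0.4, seed = 2)
  net <- build_multilayer(pl, modularity_params(gamma = 1.1, omega = 0.7))
  set.seed(8)
  labels <- matrix(sample(1:3, 18, replace = TRUE), 3, 6)
  q0 <- modularity_q(net, labels)
  for (rep in 1:5) {
    perm <- sample(3)
    expect_equal(modularity_q(net, matrix(perm[labels], 3, 6)), q0)
  }
  # node reordering applied consistently to layers and labels
  ord <- sample(6)
  net2 <- build_multilayer(list(layers = pl$layers[ord, ord, , drop = FALSE]),
                           modularity_params(gamma = 1.1, omega = 0.7))
  expect_equal(modularity_q(net2, labels[, ord, drop = FALSE]), q0)
})

test_that("omega = 0 decomposes Q into weighted single-layer modularities", {
  pl <- planted_layers(6, 3, strength = 0.4, seed = 4)
  net <- build_multilayer(pl, modularity_params(gamma = 1.2, omega = 1e-9))
  net$omega <- 0
  net$twomu <- sum(net$twom)
  labels <- matrix(rep(pl$truth, each = 3), 3, 6)
  q_multi <- modularity_q(net, labels)
  q_layers <- vapply(1:3, function(s) {
    single <- build_multilayer(list(layers = pl$layers[, , s, drop = FALSE]),
                               modularity_params(gamma = 1.2, omega = 0))
    modularity_q(single, matrix(pl$truth, 1))
  }, numeric(1))
  expect_equal(q_multi, sum(net$twom / sum(net$twom) * q_layers))
})

test_that("degenerate all-zero layers are rejected and negatives clipped", {
  layers <- array(0, c(3, 3, 2))
  layers[1, 2, 1] <- layers[2, 1, 1] <- 1
  expect_error(build_multilayer(list(layers = layers)), "degenerate")

  layers[, , 2] <- matrix(c(0, -0.5, 1, -0.5, 0, 1, 1, 1, 0), 3, 3)
  net <- build_multilayer(list(layers = layers))
  expect_equal(net$n_clipped, 2L)
  expect_true(all(net$layers >= 0))
})

test_that("the optimizer attains the exhaustive optimum on planted instances", {
  # multilayer plant: 4 nodes x 3 layers, two stable communities
  A <- matrix(0.05, 4, 4)
  A[1, 2] <- A[2, 1] <- 1
  A[3, 4] <- A[4, 3] <- 1
  diag(A) <- 0
  net <- build_multilayer(list(layers = array(A, c(4, 4, 3))),
                          modularity_params(gamma = 1, omega = 1))
  p <- louvain_multilayer(net, seed = 2)
  expect_equal(p$labels, matrix(rep(c(1L, 1L, 2L, 2L), each = 3), 3, 4))

  B <- netreconf:::supra_modularity_matrix(net)
  ex <- exhaustive_modularity(B, net$twomu, max_comm = 4)
  expect_equal(p$Q, ex$Q, tolerance = 1e-12)
  expect_true(is_local_maximum(B, as.vector(t(p$labels))))

  # louvain never exceeds the exhaustive optimum on random small nets
  for (seed in 1:6) {
    pl <- planted_layers(6, 1, strength = stats::runif(1, 0, 0.5), seed = seed)
    net_r <- build_multilayer(pl, modularity_params(gamma = 1, omega = 0))
    p_r <- louvain_multilayer(net_r, seed = seed)
    B_r <- netreconf:::supra_modularity_matrix(net_r)
    ex_r <- exhaustive_modularity(B_r, net_r$twomu)
    expect_lte(p_r$Q, ex_r$Q + 1e-12)
    expect_true(is_local_maximum(B_r, as.vector(t(p_r$labels))))
  }
})

test_that("a dominant null (large gamma) yields the all-singleton partition", {
  layers <- array(matrix(1, 5, 5) - diag(5), c(5, 5, 1))
  net <- build_multilayer(list(layers = layers),
                          modularity_params(gamma = 50, omega = 0))
  p <- louvain_multilayer(net, seed = 10)
  expect_equal(length(unique(as.vector(p$labels))), 5L)
})

test_that("runs are deterministic by seed and ensembles track agreement", {
  pl <- planted_layers(8, 2, strength = 0.6, seed = 12)
  net <- build_multilayer(pl, modularity_params(gamma = 1, omega = 1))
  expect_identical(louvain_multilayer(net, seed = 42),
                   louvain_multilayer(net, seed = 42))

  ens1 <- partition_ensemble(net, n_iter = 1, base_seed = 5)
  expect_equal(ens1$agreement, 1.0)

  ens <- partition_ensemble(net, n_iter = 100, base_seed = 0)
  expect_gte(ens$agreement, 0.98)
  expect_equal(vapply(ens$partitions, `[[`, numeric(1), "seed"), 1:100)
})

test_that("the consensus is the medoid by mean pairwise similarity", {
  pl <- planted_layers(8, 2, strength = 0.6, seed = 12)
  net <- build_multilayer(pl, modularity_params(gamma = 1, omega = 1))
  ens <- partition_ensemble(net, n_iter = 10, base_seed = 0)
  cons <- consensus_partition(ens)
  expect_equal(canonical_labels(cons$labels[1, ]), canonical_labels(pl$truth))

  # 9 identical + 1 deviant -> majority wins
  maj <- toy_partition(matrix(rep(c(1L, 1L, 2L, 2L), each = 2), 2, 4), Q = 0.4)
  dev <- toy_partition(matrix(c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L), 2, 4), Q = 0.9)
  fake <- structure(list(partitions = c(rep(list(maj), 9), list(dev)),
                         agreement = NA, base_seed = 0),
                    class = "partition_ensemble")
  expect_identical(consensus_partition(fake)$labels, maj$labels)

  # mixed ensemble equals a brute-force mean-similarity argmax
  set.seed(77)
  parts <- lapply(1:8, function(k)
    toy_partition(matrix(sample(1:3, 12, replace = TRUE), 3, 4),
                  Q = stats::runif(1), seed = k))
  fake2 <- structure(list(partitions = parts, agreement = NA, base_seed = 0),
                     class = "partition_ensemble")
  sims <- sapply(1:8, function(i) {
    mean(sapply(setdiff(1:8, i), function(j)
      zrand(parts[[i]]$labels, parts[[j]]$labels)))
  })
  got <- consensus_partition(fake2)
  expect_equal(got$labels, parts[[which.max(sims)]]$labels)
})

test_that("static pre-interval communities collapse modal labels", {
  labels <- matrix(c(1L, 1L, 2L,
                     1L, 1L, 2L,
                     1L, 2L, 2L), 3, 3, byrow = TRUE)
  modal <- apply(labels, 2, function(v) as.integer(names(which.max(table(v)))))
  expect_equal(modal, c(1L, 1L, 2L))

  # on planted data the pre-interval communities recover the plant
  pl <- planted_layers(8, 5, strength = 0.6, seed = 30)
  manifest <- toy_manifest(2, 2)
  conn <- toy_conn(pl$layers, 2, 2)
  static <- static_communities(conn, modularity_params(gamma = 1, omega = 1),
                               n_iter = 10, base_seed = 3)
  expect_equal(canonical_labels(static), canonical_labels(pl$truth))
})

test_that("more structural resolution never merges consensus communities", {
  pl <- planted_layers(8, 3, strength = 0.5, seed = 19)
  counts <- vapply(c(0.8, 1.2, 1.6, 2.4), function(g) {
    net <- build_multilayer(pl, modularity_params(gamma = g, omega = 1))
    cons <- consensus_partition(partition_ensemble(net, 10, base_seed = 1))
    length(unique(as.vector(cons$labels)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
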