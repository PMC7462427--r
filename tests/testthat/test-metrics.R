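test_that("flexibility counts affiliation changes per possible transition", {
  expect_equal(flexibility(matrix(c(1, 1, 2, 2, 3), ncol = 1))$flexibility, 0.5)
  const <- matrix(rep(c(1L, 2L), each = 4), 4, 2)
  expect_equal(flexibility(const)$flexibility, c(0, 0))
  alt <- matrix(rep(c(1L, 2L), times = 3), 6, 1)
  expect_equal(flexibility(alt)$flexibility, 1)
  expect_error(flexibility(matrix(1L, 1, 3)), "single layer")

  # brute-force transition count oracle on random partitions
  set.seed(41)
  for (rep in 1:10) {
    labels <- matrix(sample(1:4, 7 * 5, replace = TRUE), 7, 5)
    fx <- flexibility(labels)
    for (i in 1:5) {
      g <- 0
      for (l in 2:7) g <- g + (labels[l, i] != labels[l - 1, i])
      expect_equal(fx$changes[i], g)
      expect_equal(fx$flexibility[i], g / 6)
    }
  }
})

test_that("allegiance is the co-assignment fraction with unit diagonal", {
  # identical layers, communities {1,2} and {3}
  labels <- matrix(rep(c(1L, 1L, 2L), each = 4), 4, 3)
  P <- allegiance(labels)
  expect_equal(P, rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)))

  # all-singleton labels in every layer -> identity
  singles <- matrix(rep(1:5, each = 3), 3, 5)
  expect_equal(allegiance(singles), diag(5))

  # co-assigned in 3 of 5 layers -> 0.6
  two <- matrix(c(1L, 1L, 1L, 1L, 2L,
                  1L, 1L, 1L, 2L, 1L), 5, 2)
  expect_equal(allegiance(two)[1, 2], 0.6)

  # layer-by-layer counting oracle + relabeling invariance
  set.seed(43)
  labels <- matrix(sample(1:3, 6 * 4, replace = TRUE), 6, 4)
  P <- allegiance(labels)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(P[i, j], mean(labels[, i] == labels[, j]))
  }
  perm <- c(3L, 1L, 2L)
  expect_equal(allegiance(matrix(perm[labels], 6, 4)), P)
  expect_equal(diag(P), rep(1, 4))
  expect_equal(P, t(P))

  # literal transitions normalization divides by L - 1 instead
  expect_equal(allegiance(two, normalization = "transitions")[1, 2],
               3 / 4)
})

test_that("ensemble-mean allegiance equals the mean of member allegiances", {
  set.seed(47)
  parts <- lapply(1:6, function(k)
    matrix(sample(1:3, 5 * 4, replace = TRUE), 5, 4))
  mean_of <- Reduce(`+`, lapply(parts, allegiance)) / 6
  stacked <- allegiance(do.call(rbind, parts))
  expect_equal(stacked, mean_of)
})

test_that("pre/post differencing works on blocks of one partition", {
  tags <- c(rep("pre", 3), "pulse", rep("post", 3))
  same <- matrix(rep(c(1L, 1L, 2L, 2L), each = 7), 7, 4)
  pp <- prepost_diff(same, tags)
  expect_true(all(pp$nodes$d_flex == 0))
  expect_true(all(pp$d_alleg == 0))

  # pre constant, post alternating -> node flexibility difference 1
  labels <- same
  labels[5:7, ] <- rbind(c(1L, 2L, 1L, 2L), c(2L, 1L, 2L, 1L),
                         c(1L, 2L, 1L, 2L))
  pp2 <- prepost_diff(labels, tags)
  expect_equal(pp2$nodes$d_flex, rep(1, 4))

  # a split community elevates |dP| exactly for the split pairs
  split <- same
  split[5:7, 2] <- 3L   # node 2 leaves community 1 after the pulse
  pp3 <- prepost_diff(split, tags)
  expect_equal(pp3$d_alleg[1, 2], -1)
  expect_equal(pp3$d_alleg[3, 4], 0)
  expect_equal(pp3$d_alleg[1, 3], 0)
})

test_that("community distances are centroid-to-site Euclidean distances", {
  cfg <- sim_config(n_regions = 4, n_trials = 4, bands = list(),
                    stim_node = 2L, seed = 7)
  coords <- rbind(c(0.05, 0, 0), c(0, 0, 0), c(-0.05, 0, 0), c(0, 0.1, 0))
  geom <- generate_geometry(cfg, coordinates = coords)

  # community of the site-nearest node only -> distance 0
  d <- stim_distance(geom, c(2L, 1L, 2L, 3L))
  expect_equal(d$community$centroid_dist_m[d$community$community == 1], 0)
  # two members symmetric about the site -> centroid at the site
  expect_equal(d$community$centroid_dist_m[d$community$community == 2], 0)
  expect_equal(d$community$centroid_dist_m[d$community$community == 3], 0.1)

  # random geometry equals a direct coordinate-arithmetic oracle
  cfg2 <- sim_config(n_regions = 7, n_trials = 4, bands = list(),
                     stim_node = 3L, seed = 8)
  geom2 <- generate_geometry(cfg2)
  comm <- c(1L, 1L, 2L, 2L, 3L, 3L, 3L)
  d2 <- stim_distance(geom2, comm)
  for (cc in 1:3) {
    centroid <- colMeans(geom2$coordinates[comm == cc, , drop = FALSE])
    oracle <- sqrt(sum((centroid - geom2$coordinates[3, ])^2))
    expect_equal(d2$community$centroid_dist_m[d2$community$community == cc],
                 oracle)
  }
  expect_equal(d2$node$dist_m[3], 0)
})

test_that("site allegiance change averages |dP| to the site per community", {
  cfg <- sim_config(n_regions = 5, n_trials = 4, bands = list(),
                    stim_node = 1L, seed = 9)
  geom <- generate_geometry(cfg)
  comm <- c(1L, 1L, 1L, 2L, 2L)

  zero <- matrix(0, 5, 5)
  sa0 <- stim_allegiance(zero, geom, comm)
  expect_true(all(sa0$mean_abs_d_alleg_stim == 0))

  const <- matrix(-0.3, 5, 5)
  sa1 <- stim_allegiance(const, geom, comm)
  expect_equal(sa1$mean_abs_d_alleg_stim, c(0.3, 0.3))

  set.seed(50)
  dP <- matrix(stats::rnorm(25), 5, 5); dP <- (dP + t(dP)) / 2
  sa2 <- stim_allegiance(dP, geom, comm)
  # explicit-loop oracle; the site node is excluded from its community
  expect_equal(sa2$mean_abs_d_alleg_stim[1], mean(abs(dP[c(2, 3), 1])))
  expect_equal(sa2$mean_abs_d_alleg_stim[2], mean(abs(dP[c(4, 5), 1])))

  expect_warning(stim_allegiance(dP, geom, c(1L, 2L, 2L, 2L, 2L)),
                 "no members besides the site")
})

test_that("percentile node selection uses interpolated order statistics", {
  sel <- top_percentile_nodes(1:100, pct = 85)
  expect_equal(sel, 86:100, ignore_attr = TRUE)   # the top 15 by sort-and-count
  expect_equal(attr(sel, "threshold"),
               unname(stats::quantile(1:100, 0.85)))

  all_equal <- top_percentile_nodes(rep(0.4, 7))
  expect_equal(all_equal, 1:7, ignore_attr = TRUE)

  expect_equal(top_percentile_nodes(3.2), 1L, ignore_attr = TRUE)
})

test_that("left/right averaging is the elementwise mean of matched results", {
  expect_equal(average_lr(0, 1), 0.5)
  m <- matrix(1:4, 2)
  expect_equal(average_lr(m, m), m)
  set.seed(53)
  a <- matrix(stats::rnorm(9), 3); b <- matrix(stats::rnorm(9), 3)
  expect_equal(average_lr(a, b), (a + b) / 2)
  expect_error(average_lr(a, matrix(0, 2, 2)), "mismatched")

  ta <- tibble::tibble(community = c("a", "b", "c"), value = c(1, 2, 3))
  tb <- tibble::tibble(community = c("a", "b", "c"), value = c(3, 2, 1))
  expect_equal(average_lr(ta, tb)$value, c(2, 2, 2))
  tc <- tibble::tibble(community = c("a", "b", "d"), value = c(1, 2, 3))
  expect_error(average_lr(ta, tc), "key columns")
})
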