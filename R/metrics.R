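#' Node flexibility of a multilayer partition
#'
#' Flexibility of node `i` is the number of changes of community
#' affiliation between consecutive layers, `g_i`, normalized by the
#' `L - 1` possible changes: `xi_i = g_i / (L - 1)`. 0 means the node
#' never changes community; 1 means it changes at every transition.
#' Invariant under community relabeling.
#'
#' @param p A `multilayer_partition`, or an `L x n` label matrix.
#' @return Tibble with `node`, `changes`, `flexibility`.
#' @examples
#' p <- matrix(c(1, 1, 2, 2, 3), ncol = 1) # one node over 5 layers
#' flexibility(p)$flexibility # 0.5
#' @export
flexibility <- function(p) {
  labels <- partition_labels(p)
  L <- nrow(labels)
  if (L < 2) stopf("flexibility is undefined for a single layer")
  changes <- colSums(labels[-1L, , drop = FALSE] !=
                       labels[-L, , drop = FALSE])
  tibble::tibble(node = seq_len(ncol(labels)),
                 changes = as.integer(changes),
                 flexibility = changes / (L - 1))
}

partition_labels <- function(p) {
  if (inherits(p, "multilayer_partition")) return(p$labels)
  if (is.matrix(p)) return(p)
  stopf("expected a multilayer_partition or an L x n label matrix")
}

#' Module allegiance of a multilayer partition
#'
#' `P_ij` is the fraction of layers in which nodes `i` and `j` carry the
#' same community label; the diagonal is 1 by definition. Allegiance
#' captures how consistently each node pair co-inhabits a community over
#' time. The default normalizes the co-assignment count by the number of
#' layers `L`, which keeps `P` in `[0, 1]`; `normalization =
#' "transitions"` divides by `L - 1` instead (the count is then not
#' bounded by 1).
#'
#' @param p A `multilayer_partition` or `L x n` label matrix.
#' @param normalization `"layers"` (default) or `"transitions"`.
#' @return Symmetric `n x n` matrix.
#' @export
allegiance <- function(p, normalization = c("layers", "transitions")) {
  normalization <- match.arg(normalization)
  labels <- partition_labels(p)
  L <- nrow(labels); n <- ncol(labels)
  P <- matrix(0, n, n)
  for (s in seq_len(L)) {
    g <- labels[s, ]
    P <- P + outer(g, g, "==")
  }
  P / if (normalization == "layers") L else (L - 1)
}

#' Pre- versus post-pulse reconfiguration of one partition
#'
#' Computes flexibility and allegiance twice on the same whole-epoch
#' multilayer partition -- once on the block of pre-pulse layers and once
#' on the post-pulse block, the pulse-centered layer excluded -- and
#' returns their signed (post minus pre) and absolute differences. Using
#' blocks of one partition keeps community label identity consistent
#' across the pulse.
#'
#' @param p A `multilayer_partition` covering the whole epoch.
#' @param tags Character vector of layer tags (`"pre"`, `"pulse"`,
#'   `"post"`), typically the `tag` column of the window manifest.
#' @return List with `nodes` (tibble: `node`, `flex_pre`, `flex_post`,
#'   `d_flex`, `abs_d_flex`) and the allegiance matrices `alleg_pre`,
#'   `alleg_post`, `d_alleg` (signed, post - pre).
#' @export
prepost_diff <- function(p, tags) {
  labels <- partition_labels(p)
  stopifnot(length(tags) == nrow(labels))
  pre <- labels[tags == "pre", , drop = FALSE]
  post <- labels[tags == "post", , drop = FALSE]
  if (nrow(pre) < 2 || nrow(post) < 2) {
    stopf("both intervals need at least 2 layers")
  }
  fx_pre <- flexibility(pre)
  fx_post <- flexibility(post)
  P_pre <- allegiance(pre)
  P_post <- allegiance(post)
  nodes <- tibble::tibble(
    node = fx_pre$node,
    flex_pre = fx_pre$flexibility,
    flex_post = fx_post$flexibility,
    d_flex = fx_post$flexibility - fx_pre$flexibility,
    abs_d_flex = abs(fx_post$flexibility - fx_pre$flexibility)
  )
  list(nodes = nodes, alleg_pre = P_pre, alleg_post = P_post,
       d_alleg = P_post - P_pre)
}

#' Community distance from the stimulation site
#'
#' For every community, the Euclidean distance between the centroid (mean
#' coordinate) of its member nodes and the coordinate of the stimulation
#' site node; per-node distances to the site are also returned for
#' node-level scatter summaries.
#'
#' @param geom A [generate_geometry()] geometry.
#' @param communities Integer label per node (e.g. from
#'   [static_communities()]).
#' @return List with `community` (tibble: `community`, `n_nodes`,
#'   `centroid_dist_m`) and `node` (tibble: `node`, `community`,
#'   `dist_m`).
#' @export
stim_distance <- function(geom, communities) {
  stopifnot(inherits(geom, "geometry"))
  xyz <- geom$coordinates
  stopifnot(length(communities) == nrow(xyz))
  stim <- xyz[geom$stim_node, ]
  node_d <- sqrt(colSums((t(xyz) - stim)^2))
  comm <- sort(unique(communities))
  cent <- t(vapply(comm, function(cc) {
    colMeans(xyz[communities == cc, , drop = FALSE])
  }, numeric(3)))
  comm_d <- sqrt(colSums((t(cent) - stim)^2))
  list(
    community = tibble::tibble(
      community = comm,
      n_nodes = as.integer(tabulate(match(communities, comm))),
      centroid_dist_m = comm_d),
    node = tibble::tibble(node = seq_len(nrow(xyz)),
                          community = communities, dist_m = node_d)
  )
}

#' Community-mean allegiance change with the stimulation site
#'
#' For each community, the mean over member nodes of the absolute
#' allegiance change between that node and the stimulation-site node.
#' The site node is excluded from its own community's average.
#'
#' @param d_alleg Signed allegiance-difference matrix (post - pre).
#' @param geom A geometry (supplies the site node).
#' @param communities Integer label per node.
#' @return Tibble with `community`, `n_nodes`, `mean_abs_d_alleg_stim`.
#' @export
stim_allegiance <- function(d_alleg, geom, communities) {
  stopifnot(inherits(geom, "geometry"))
  n <- nrow(d_alleg)
  stopifnot(length(communities) == n)
  stim <- geom$stim_node
  vals <- abs(d_alleg[, stim])
  comm <- sort(unique(communities))
  rows <- lapply(comm, function(cc) {
    members <- setdiff(which(communities == cc), stim)
    if (length(members) == 0L) {
      warning(sprintf("community %d has no members besides the site; skipped", cc),
              call. = FALSE)
      return(NULL)
    }
    tibble::tibble(community = cc, n_nodes = length(members),
                   mean_abs_d_alleg_stim = mean(vals[members]))
  })
  dplyr::bind_rows(rows)
}

#' Within-community mean absolute allegiance change
#'
#' For each community, the mean of `|dP_ij|` over unordered node pairs
#' with both members in the community -- a summary of how strongly the
#' pulse restructured that community's internal co-assignment.
#'
#' @param d_alleg Signed allegiance-difference matrix.
#' @param communities Integer label per node.
#' @return Tibble with `community`, `n_pairs`, `mean_abs_d_alleg`.
#' @export
community_allegiance_change <- function(d_alleg, communities) {
  n <- nrow(d_alleg)
  stopifnot(length(communities) == n)
  comm <- sort(unique(communities))
  rows <- lapply(comm, function(cc) {
    members <- which(communities == cc)
    if (length(members) < 2L) return(NULL)
    sub <- d_alleg[members, members, drop = FALSE]
    vals <- abs(sub[upper.tri(sub)])
    tibble::tibble(community = cc, n_pairs = length(vals),
                   mean_abs_d_alleg = mean(vals))
  })
  dplyr::bind_rows(rows)
}

#' Nodes at or above a percentile of a change score
#'
#' Selects the nodes whose score reaches the given percentile of all
#' node scores; the threshold (linear interpolation between order
#' statistics) is returned for plotting as a reference line.
#'
#' @param node_diffs Numeric score per node.
#' @param pct Percentile in (0, 100]; default 85.
#' @return Integer vector of selected node indices, with the threshold in
#'   attribute `"threshold"`.
#' @export
top_percentile_nodes <- function(node_diffs, pct = 85) {
  stopifnot(length(node_diffs) >= 1, is.numeric(node_diffs))
  thr <- unname(stats::quantile(node_diffs, pct / 100, type = 7))
  out <- which(node_diffs >= thr)
  attr(out, "threshold") <- thr
  out
}

#' Average homologous stimulation-site results
#'
#' Elementwise mean of matched per-node or per-community results from two
#' homologous (left/right) stimulation conditions.
#'
#' @param left,right Numeric vectors/matrices of identical shape, or data
#'   frames with identical non-numeric key columns.
#' @return The elementwise mean, same shape as the inputs.
#' @export
average_lr <- function(left, right) {
  if (is.data.frame(left) && is.data.frame(right)) {
    if (!identical(dim(left), dim(right)) ||
        !identical(names(left), names(right))) {
      stopf("left and right tables have mismatched structure")
    }
    num <- vapply(left, is.numeric, logical(1))
    if (!identical(left[!num], right[!num])) {
      stopf("left and right key columns disagree")
    }
    out <- left
    out[num] <- (left[num] + right[num]) / 2
    return(out)
  }
  if (!identical(dim(left), dim(right)) ||
      length(left) != length(right)) {
    stopf("left and right results have mismatched shape")
  }
  (left + right) / 2
}
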