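# broom-style tidiers: tidy() returns the per-element table, glance() a
# one-row model summary.

#' Tidy a multilayer partition into a layer/node/community table
#'
#' @param x A `multilayer_partition`.
#' @param ... Unused.
#' @return Tibble with `layer`, `node`, `community`.
#' @export
tidy.multilayer_partition <- function(x, ...) {
  tibble::tibble(
    layer = rep(seq_len(nrow(x$labels)), times = ncol(x$labels)),
    node = rep(seq_len(ncol(x$labels)), each = nrow(x$labels)),
    community = as.integer(x$labels[cbind(
      rep(seq_len(nrow(x$labels)), times = ncol(x$labels)),
      rep(seq_len(ncol(x$labels)), each = nrow(x$labels)))])
  )
}

#' @rdname tidy.multilayer_partition
#' @export
glance.multilayer_partition <- function(x, ...) {
  tibble::tibble(Q = x$Q, n_layers = nrow(x$labels),
                 n_nodes = ncol(x$labels),
                 n_communities = length(unique(as.vector(x$labels))),
                 gamma = x$gamma, omega = x$omega, seed = x$seed)
}

#' Tidy an optimizer ensemble into one row per run
#'
#' @param x A `partition_ensemble`.
#' @param ... Unused.
#' @return Tibble with `run`, `seed`, `Q`, `n_communities`.
#' @export
tidy.partition_ensemble <- function(x, ...) {
  tibble::tibble(
    run = seq_along(x$partitions),
    seed = vapply(x$partitions, `[[`, numeric(1), "seed"),
    Q = vapply(x$partitions, `[[`, numeric(1), "Q"),
    n_communities = vapply(x$partitions, function(p)
      length(unique(as.vector(p$labels))), integer(1))
  )
}

#' @rdname tidy.partition_ensemble
#' @export
glance.partition_ensemble <- function(x, ...) {
  qs <- vapply(x$partitions, `[[`, numeric(1), "Q")
  tibble::tibble(n_runs = length(x$partitions), agreement = x$agreement,
                 mean_q = mean(qs), max_q = max(qs))
}

#' Tidy a connectivity series into a long edge table
#'
#' @param x A `connectivity_series`.
#' @param ... Unused.
#' @return Tibble with `layer`, `center_s`, `tag`, `node_a`, `node_b`,
#'   `weight` (upper-triangle edges only).
#' @export
tidy.connectivity_series <- function(x, ...) {
  n <- dim(x$layers)[1]
  pairs <- upper_pairs(n)
  purrr::map_dfr(seq_len(dim(x$layers)[3]), function(l) {
    tibble::tibble(layer = l,
                   center_s = x$manifest$center_s[l],
                   tag = x$manifest$tag[l],
                   node_a = pairs[, 1L], node_b = pairs[, 2L],
                   weight = x$layers[, , l][pairs])
  })
}

#' Tidy a resolution-parameter sweep
#'
#' @param x A `q_surface`.
#' @param ... Unused.
#' @return The long gamma/omega table with observed, null and difference
#'   modularity.
#' @export
tidy.q_surface <- function(x, ...) x$table

#' @rdname tidy.q_surface
#' @export
glance.q_surface <- function(x, ...) {
  sel <- select_scale(x, quiet = TRUE)
  tibble::tibble(gamma = sel$gamma, omega = sel$omega,
                 q_diff_max = sel$q_diff,
                 n_cells = nrow(x$table))
}

#' Tidy a pipeline report into the node-level metric table
#'
#' @param x A `reconfig_report`.
#' @param table Which table to return: `"nodes"`, `"communities"`,
#'   `"community_summary"`, `"edge_tests"`, `"community_tests"`,
#'   `"recovery"`.
#' @param ... Unused.
#' @return The requested tibble.
#' @export
tidy.reconfig_report <- function(x, table = c("nodes", "communities",
                                              "community_summary",
                                              "edge_tests",
                                              "community_tests",
                                              "recovery"), ...) {
  table <- match.arg(table)
  switch(table,
         nodes = x$node_metrics,
         communities = x$community_metrics,
         community_summary = x$community_summary,
         edge_tests = x$edge_tests,
         community_tests = x$community_tests,
         recovery = x$recovery)
}

#' @rdname tidy.reconfig_report
#' @export
glance.reconfig_report <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$config$n_subjects,
    n_bands = length(x$config$bands),
    gamma = x$params$gamma, omega = x$params$omega,
    n_louvain = x$n_louvain,
    recovery_hits = if (nrow(x$recovery)) sum(x$recovery$hit) else NA_integer_,
    mean_agreement = if (nrow(x$recovery)) mean(x$recovery$agreement) else NA_real_,
    percentile_threshold = x$percentile_threshold,
    n_selected_nodes = sum(x$selected_nodes$selected)
  )
}
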