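#' Edge-shuffled null connectivity
#'
#' Destroys the correlational (community) structure of a connectivity
#' series while exactly preserving each layer's edge-weight multiset:
#' within every layer independently, the upper-triangle weights are
#' uniformly permuted and mirrored to keep symmetry; diagonals are
#' untouched. This is the null model against which observed modularity is
#' calibrated during scale selection.
#'
#' @param conn A `connectivity_series`.
#' @param seed Integer RNG seed.
#' @return A `connectivity_series` of identical shape with shuffled
#'   layers.
#' @export
shuffle_null <- function(conn, seed = 1L) {
  layers <- conn$layers
  n <- dim(layers)[1]; L <- dim(layers)[3]
  pairs <- upper_pairs(n)
  with_seed(seed, {
    for (s in seq_len(L)) {
      A <- layers[, , s]
      w <- A[pairs]
      w <- w[sample.int(length(w))]
      A[pairs] <- w
      A[pairs[, c(2, 1), drop = FALSE]] <- w
      layers[, , s] <- A
    }
  })
  out <- conn
  out$layers <- layers
  out$label <- paste0(conn$label %||% "", " (shuffled null)")
  out
}

#' Sweep the (gamma, omega) grid against the shuffled null
#'
#' For every cell of the resolution-parameter grid and every subject,
#' runs the multilayer optimizer on the observed connectivity and on one
#' edge-shuffled null realization of it, and records the mean Q of each
#' over subjects (each subject's Q itself a mean over optimizer runs).
#' The surface of differences `Qdiff = Qobs - Qnull` locates the scale at
#' which the data are most unlike the null.
#'
#' @param conn_by_subject List of `connectivity_series`, one per subject.
#' @param gamma_grid,omega_grid Strictly increasing numeric grids.
#' @param n_iter_per_cell Optimizer runs per subject per cell.
#' @param base_seed Integer; all per-cell and shuffle seeds derive from it.
#' @param null_repeats Shuffled realizations per subject per cell
#'   (default 1; more allow null-variance estimation).
#' @return A `q_surface`: tibble with `gamma`, `omega`, `q_obs`, `q_null`,
#'   `q_diff` plus grid metadata.
#' @export
q_surface <- function(conn_by_subject, gamma_grid = seq(0.8, 1.6, by = 0.2),
                      omega_grid = c(0.5, 2, 9, 35),
                      n_iter_per_cell = 5L, base_seed = 0L,
                      null_repeats = 1L) {
  stopifnot(length(conn_by_subject) >= 1,
            all(diff(gamma_grid) > 0) || length(gamma_grid) == 1L,
            all(diff(omega_grid) > 0) || length(omega_grid) == 1L)
  grid <- tidyr::expand_grid(gamma = gamma_grid, omega = omega_grid)
  grid$cell_id <- seq_len(nrow(grid))
  n_subj <- length(conn_by_subject)
  res <- purrr::pmap_dfr(grid, function(gamma, omega, cell_id) {
    params <- modularity_params(gamma = gamma, omega = omega)
    qo <- qn <- rep(NA_real_, n_subj)
    for (s in seq_len(n_subj)) {
      conn <- conn_by_subject[[s]]
      seed0 <- base_seed + 10000L * cell_id + 100L * s
      qo[s] <- tryCatch(
        mean_ensemble_q(conn, params, n_iter_per_cell, seed0),
        error = function(e) {
          warning(sprintf("subject %d skipped at (%g, %g): %s",
                          s, gamma, omega, conditionMessage(e)),
                  call. = FALSE)
          NA_real_
        })
      if (is.na(qo[s])) next
      nulls <- vapply(seq_len(null_repeats), function(r) {
        nc <- shuffle_null(conn, seed = seed0 + r)
        mean_ensemble_q(nc, params, n_iter_per_cell, seed0 + 50L * r)
      }, numeric(1))
      qn[s] <- mean(nulls)
    }
    tibble::tibble(gamma = gamma, omega = omega,
                   q_obs = mean(qo, na.rm = TRUE),
                   q_null = mean(qn, na.rm = TRUE),
                   q_diff = mean(qo - qn, na.rm = TRUE),
                   n_subjects = sum(!is.na(qo)))
  })
  structure(list(table = res, gamma_grid = gamma_grid,
                 omega_grid = omega_grid),
            class = "q_surface")
}

mean_ensemble_q <- function(conn, params, n_iter, base_seed) {
  net <- build_multilayer(conn, params)
  mean(vapply(seq_len(n_iter), function(k) {
    louvain_multilayer(net, seed = base_seed + k)$Q
  }, numeric(1)))
}

#' @export
print.q_surface <- function(x, ...) {
  sel <- select_scale(x, quiet = TRUE)
  cat(sprintf("<q_surface> %d x %d grid; max Qdiff %.4f at gamma = %g, omega = %g\n",
              length(x$gamma_grid), length(x$omega_grid),
              max(x$table$q_diff), sel$gamma, sel$omega))
  invisible(x)
}

#' Select the resolution scale maximizing the null-calibrated Q
#'
#' The "difference" heuristic: pick the grid cell with the largest
#' `Qdiff = Qobs - Qnull`. Ties are broken toward smaller `omega`, then
#' smaller `gamma`; an all-equal surface triggers an ambiguous-selection
#' warning. When no sweep has been run, [modularity_params()] documents
#' the shipped default scale (`gamma = 1.025`, `omega = 9`).
#'
#' @param surface A [q_surface()].
#' @param quiet Suppress the ambiguity warning.
#' @return One-row tibble with `gamma`, `omega`, `q_diff`.
#' @export
select_scale <- function(surface, quiet = FALSE) {
  stopifnot(inherits(surface, "q_surface"))
  tab <- surface$table
  if (!all(is.finite(tab$q_diff))) stopf("non-finite Qdiff values in surface")
  if (!quiet && length(unique(tab$q_diff)) == 1L && nrow(tab) > 1L) {
    warning("flat Qdiff surface: scale selection is ambiguous; returning the tie-break",
            call. = FALSE)
  }
  ord <- order(-tab$q_diff, tab$omega, tab$gamma)
  tab[ord[1L], c("gamma", "omega", "q_diff")]
}
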