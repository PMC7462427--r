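# Plain-text serialization of the main result objects. Partitions travel
# as delimited integer tables (rows = layers, columns = nodes) under a
# commented header carrying Q, gamma, omega and the seed; geometry as a
# 4-column table in meters; surfaces as long-format CSV.

#' Write / read a multilayer partition as delimited text
#'
#' @param p A `multilayer_partition`.
#' @param path Output file.
#' @return `write_partition` returns `path` invisibly; `read_partition`
#'   returns the partition.
#' @export
write_partition <- function(p, path) {
  stopifnot(inherits(p, "multilayer_partition"))
  header <- sprintf("# Q=%.15g gamma=%.15g omega=%.15g seed=%d",
                    p$Q, p$gamma, p$omega, p$seed)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(p$labels, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  header <- readLines(path, n = 1L)
  fields <- regmatches(header,
                       gregexpr("[a-zA-Z]+=[-0-9.eE+]+", header))[[1]]
  kv <- stats::setNames(
    as.numeric(sub(".*=", "", fields)),
    sub("=.*", "", fields))
  labels <- as.matrix(utils::read.table(path, skip = 1L, sep = "\t"))
  dimnames(labels) <- NULL
  new_multilayer_partition(labels, Q = kv[["Q"]],
                           seed = as.integer(kv[["seed"]]),
                           gamma = kv[["gamma"]], omega = kv[["omega"]])
}

#' Write / read node geometry as delimited text
#'
#' Four columns: node index and x, y, z in meters; the stimulation node
#' index is carried in a comment header.
#'
#' @param geom A `geometry`.
#' @param path File path.
#' @return `write_geometry` returns `path` invisibly; `read_geometry`
#'   returns the geometry.
#' @export
write_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "geometry"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stim_node=%d", geom$stim_node), con)
  writeLines("node\tx\ty\tz", con)
  utils::write.table(
    cbind(seq_len(nrow(geom$coordinates)), geom$coordinates),
    con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  header <- readLines(path, n = 1L)
  stim <- as.integer(sub(".*stim_node=", "", header))
  tab <- utils::read.table(path, skip = 1L, header = TRUE, sep = "\t")
  coords <- as.matrix(tab[, c("x", "y", "z")])
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(coordinates = coords, stim_node = stim),
            class = "geometry")
}

#' Write a resolution sweep as long-format CSV
#'
#' @param surface A `q_surface`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_q_surface <- function(surface, path) {
  stopifnot(inherits(surface, "q_surface"))
  sel <- select_scale(surface, quiet = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# selected gamma=%g omega=%g q_diff=%.15g",
                     sel$gamma, sel$omega, sel$q_diff), con)
  utils::write.csv(surface$table, con, row.names = FALSE)
  invisible(path)
}
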