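# File I/O: delimited readers/writers for records and networks, GraphML and
# JSON node-link exports, and run manifests.

#' Read a multichannel record from a delimited file
#'
#' One column per channel; a header row supplies channel labels (generated
#' when absent). The delimiter is inferred from the file extension (`.tsv` /
#' `.txt` = tab, otherwise comma) unless given.
#'
#' @param path File path.
#' @param fs Sampling rate in Hz.
#' @param delim Field delimiter; `NULL` to infer from the extension.
#' @param col_names Whether the first row holds channel labels.
#' @return An [mc_record()].
#' @export
read_record <- function(path, fs = 1, delim = NULL, col_names = TRUE) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- readr::read_delim(path, delim = delim, col_names = col_names,
                          show_col_types = FALSE, progress = FALSE)
  mc_record(df, fs = fs)
}

#' Write a multichannel record to a delimited file
#'
#' @inheritParams read_record
#' @param record An [mc_record()].
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  readr::write_delim(as.data.frame(record$data), path, delim = delim)
  invisible(path)
}

write_labelled_matrix <- function(m, path) {
  df <- data.frame(node = rownames(m), m, check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

read_labelled_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write a network's strength and delay matrices as TSV
#'
#' Produces `<stem>_strength.tsv` and `<stem>_delay.tsv`, each a node-by-node
#' matrix with a leading label column and labelled header.
#'
#' @param network A `ctds_network`.
#' @param stem Output path stem (directory must exist).
#' @return Character vector of the two paths, invisibly.
#' @export
write_network_tsv <- function(network, stem) {
  p1 <- paste0(stem, "_strength.tsv")
  p2 <- paste0(stem, "_delay.tsv")
  write_labelled_matrix(network$strength, p1)
  write_labelled_matrix(network$delay, p2)
  invisible(c(p1, p2))
}

#' Read a strength matrix written by [write_network_tsv()]
#'
#' @param path Path to a `*_strength.tsv` (or `*_delay.tsv`) file.
#' @return A labelled numeric matrix.
#' @export
read_network_tsv <- function(path) read_labelled_matrix(path)

#' Convert a network to an igraph graph
#'
#' Edges are all directed links with strength above `min_strength`; `strength`
#' and `delay` become edge attributes. For the symmetric original estimator
#' both directions are exported.
#'
#' @param network A `ctds_network`.
#' @param min_strength Smallest strength kept as an edge (default 0,
#'   i.e. keep all links with positive strength).
#' @return An [igraph::graph] object.
#' @export
as_igraph_network <- function(network, min_strength = 0) {
  df <- tidy(network)
  df <- df[!is.na(df$strength) & df$strength > min_strength, ]
  igraph::graph_from_data_frame(
    df[, c("source", "target", "strength", "delay")],
    directed = TRUE,
    vertices = data.frame(name = network$nodes))
}

#' Write a network as GraphML
#'
#' @inheritParams as_igraph_network
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path, min_strength = 0) {
  g <- as_igraph_network(network, min_strength = min_strength)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a network as JSON node-link data
#'
#' A dependency-light export: `nodes` (labels), `links` (source, target,
#' strength, delay), `method` and analysis parameters.
#'
#' @inheritParams as_igraph_network
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(network, path, min_strength = 0) {
  df <- tidy(network)
  df <- df[!is.na(df$strength) & df$strength > min_strength, ]
  obj <- list(method = network$method,
              nodes = network$nodes,
              links = df[, c("source", "target", "strength", "delay")],
              params = network$params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration, seed, package version and exclusion counts of a
#' run so outputs can be reproduced.
#'
#' @param config Named list (typically a [ctds_config()]).
#' @param path Output path.
#' @param extra Optional named list of additional fields (e.g. exclusion
#'   counts).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, extra = list()) {
  obj <- c(list(package = "ctdsnet",
                version = as.character(utils::packageVersion("ctdsnet")),
                timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)),
           list(config = config), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
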