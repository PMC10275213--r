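# Standard-format I/O: Matrix Market for matrices, CSV for tables,
# GraphML plus edge lists for circuits.

#' Read / write a strength matrix in Matrix Market coordinate format
#'
#' Coordinate files use 1-based indices; a file with a 0 index is
#' rejected with an explicit dialect error.
#'
#' @param path File path.
#' @return `read_strength_matrix()` returns a validated sparse
#'   `dgCMatrix`.
#' @export
read_strength_matrix <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  A <- tryCatch(Matrix::readMM(path), error = function(e)
    stopf(paste("failed to parse %s as 1-based Matrix Market coordinate",
                "format (0-based indices are not a valid dialect): %s"),
          path, conditionMessage(e)))
  as_strength_matrix(A, name = path)
}

#' @rdname read_strength_matrix
#' @param strengths Matrix to write.
#' @export
write_strength_matrix <- function(strengths, path) {
  A <- as_strength_matrix(strengths)
  Matrix::writeMM(A, path)
  invisible(path)
}

#' Read / write a consensus partition as CSV
#'
#' Columns `neuron_id` and `class_id` (the string `"unassigned"` for
#' neurons outside every class).
#'
#' @param partition A `consensus_partition`.
#' @param path File path.
#' @param neuron_ids Optional neuron identifiers (default `n1..nN`).
#' @export
write_partition_csv <- function(partition, path, neuron_ids = NULL) {
  labels <- partition$labels
  if (is.null(neuron_ids)) neuron_ids <- paste0("n", seq_along(labels))
  df <- data.frame(neuron_id = neuron_ids,
                   class_id = ifelse(is.na(labels), "unassigned",
                                     as.character(labels)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_partition_csv
#' @export
read_partition_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("neuron_id", "class_id") %in% names(df)))
    stopf("%s lacks neuron_id/class_id columns", path)
  labels <- suppressWarnings(as.integer(df$class_id))
  kappa <- if (all(is.na(labels))) 0L else max(labels, na.rm = TRUE)
  structure(list(labels = labels, kappa = kappa,
                 class_sizes = if (kappa) as.integer(table(labels))
                               else integer(0),
                 unassigned = which(is.na(labels)),
                 c_size = NA_integer_, tau = NA_real_,
                 assigned_fraction = mean(!is.na(labels))),
            class = "consensus_partition")
}

circuit_to_igraph <- function(circuit) {
  g <- igraph::graph_from_data_frame(
    circuit$edges, directed = TRUE,
    vertices = data.frame(name = as.character(seq_len(circuit$kappa)),
                          size = circuit$class_sizes))
  igraph::E(g)$weight <- circuit$edges$p
  g
}

#' Write a circuit as GraphML and as a 3-column edge list
#'
#' @param circuit A `circuit`.
#' @param graphml_path,edgelist_path Output paths (either may be `NULL`
#'   to skip).
#' @export
write_circuit <- function(circuit, graphml_path = NULL, edgelist_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(circuit_to_igraph(circuit), graphml_path,
                        format = "graphml")
  if (!is.null(edgelist_path)) {
    df <- circuit$edges
    names(df) <- c("source_class", "target_class", "probability")
    write.csv(df, edgelist_path, row.names = FALSE, quote = FALSE)
  }
  invisible(circuit)
}

#' Read a circuit back from GraphML
#'
#' @param path GraphML file written by [write_circuit()].
#' @return A `circuit` (floor threshold unknown, recorded as `NA`).
#' @export
read_circuit_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  ord <- order(as.integer(igraph::V(g)$name))
  kappa <- igraph::vcount(g)
  sizes <- igraph::V(g)$size[ord]
  el <- igraph::as_data_frame(g, what = "edges")
  p <- matrix(0, kappa, kappa)
  p[cbind(as.integer(el$from), as.integer(el$to))] <- el$weight
  structure(list(p = p, class_sizes = sizes, kappa = kappa,
                 floor_threshold = NA_real_, edges = circuit_edges(p)),
            class = "circuit")
}

#' Write a synthetic dataset to disk
#'
#' Strengths as Matrix Market, metadata and true labels as CSV with a
#' header row.
#'
#' @param dataset A `synthetic_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_strength_matrix(dataset$strengths, file.path(dir, "strengths.mtx"))
  write.csv(dataset$metadata, file.path(dir, "metadata.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(data.frame(neuron_id = dataset$metadata$neuron_id,
                       true_label = dataset$labels),
            file.path(dir, "true_labels.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(dir)
}
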