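#' Read a count matrix from TSV or MatrixMarket
#'
#' TSV: first column = feature ids, remaining columns = samples. MatrixMarket
#' (`.mtx`): sidecar files `<path>.rownames` and `<path>.colnames` (one id
#' per line) supply the dimnames.
#'
#' @param path input file.
#' @param level `"gene"` or `"transcript"`.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path, level = c("gene", "transcript")) {
  level <- match.arg(level)
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(paste0(path, ".rownames"))
    cn <- readLines(paste0(path, ".colnames"))
    dimnames(m) <- list(rn, cn)
  } else {
    df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  }
  storage.mode(m) <- "integer"
  count_matrix(m, level)
}

#' Read a sample metadata table (TSV)
#'
#' @param path TSV with at least `sample_id` and `group` columns.
#' @return validated data.frame.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  validate_sample_table(df)
  df
}

#' Read a transcript-to-gene map (TSV)
#'
#' @param path TSV with `transcript_id` and `gene_id` columns.
#' @return validated data.frame.
#' @export
read_feature_map <- function(path) {
  if (!file.exists(path)) stop("feature map file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  validate_feature_map(df)
  df
}

#' Export a network to GraphML or TSV
#'
#' GraphML carries node attributes `modality` and `gene_id` and the edge
#' attribute `mi`; TSV writes the edge list (`node_a`, `node_b`, `mi`,
#' `edge_type`) plus a `<path>.nodes.tsv` sidecar with the node table, so a
#' read-back reproduces the network exactly (including isolated nodes).
#'
#' @param net an [mi_network()].
#' @param path output file.
#' @param format `"graphml"` or `"tsv"`.
#' @return the path, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "tsv")) {
  stopifnot(inherits(net, "mi_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      net$edges[, c("node_a", "node_b", "mi", "edge_type")],
      directed = FALSE, vertices = net$nodes)
    g <- igraph::set_graph_attr(g, "thresholded", as.character(net$thresholded))
    g <- igraph::set_graph_attr(g, "group_label", net$group_label)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    utils::write.table(format(net$edges, digits = 17, scientific = FALSE,
                              trim = TRUE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(net$nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    meta <- data.frame(key = c("thresholded", "group_label"),
                       value = c(as.character(net$thresholded), net$group_label))
    utils::write.table(meta, paste0(path, ".meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a network written by [export_network()]
#'
#' @param path file written by [export_network()].
#' @param format `"graphml"` or `"tsv"`.
#' @return an [mi_network()].
#' @export
read_network <- function(path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(node_id = igraph::V(g)$name,
                        modality = igraph::V(g)$modality,
                        gene_id = igraph::V(g)$gene_id,
                        stringsAsFactors = FALSE)
    el <- igraph::as_data_frame(g, what = "edges")
    edges <- data.frame(node_a = el$from, node_b = el$to, mi = el$mi,
                        stringsAsFactors = FALSE)
    thr <- identical(igraph::graph_attr(g, "thresholded"), "TRUE")
    lab <- igraph::graph_attr(g, "group_label") %||% ""
  } else {
    edges <- utils::read.delim(path, stringsAsFactors = FALSE)
    nodes <- utils::read.delim(paste0(path, ".nodes.tsv"),
                               stringsAsFactors = FALSE)
    meta <- utils::read.delim(paste0(path, ".meta.tsv"),
                              stringsAsFactors = FALSE)
    thr <- identical(meta$value[meta$key == "thresholded"], "TRUE")
    lab <- meta$value[meta$key == "group_label"]
    if (!length(lab) || is.na(lab)) lab <- ""
  }
  mi_network(nodes, edges, thresholded = thr, group_label = lab)
}

#' Join user annotations onto a hub or master-hub table
#'
#' Left join on `node_id`: every input row is kept; nodes absent from the
#' annotation table get the explicit value `"unknown"` in every flag column.
#'
#' @param table data.frame with a `node_id` column (e.g. [identify_hubs()] or
#'   [master_hubs()] output).
#' @param annotations data.frame (or TSV path) with a `node_id` column plus
#'   flag columns; duplicate node ids are an error.
#' @return the annotated table.
#' @export
annotate_nodes <- function(table, annotations) {
  if (is.character(annotations))
    annotations <- utils::read.delim(annotations, stringsAsFactors = FALSE)
  if (!"node_id" %in% names(annotations))
    stop("annotation table needs a 'node_id' column")
  if (anyDuplicated(annotations$node_id))
    stop("duplicate node_id in annotation table")
  flags <- setdiff(names(annotations), "node_id")
  idx <- match(table$node_id, annotations$node_id)
  for (f in flags) {
    v <- as.character(annotations[[f]])[idx]
    v[is.na(v)] <- "unknown"
    table[[f]] <- v
  }
  table
}
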