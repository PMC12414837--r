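#' Mutual-information co-expression network
#'
#' Undirected weighted graph whose nodes are either total-expression (TE)
#' features identified by gene id, or isoform-ratio (IR) features identified
#' by transcript id and mapped to a parent gene. Edges carry a positive
#' mutual information and an edge type derived from the endpoint modalities.
#'
#' @param nodes data.frame with columns `node_id`, `modality` (`"TE"` or
#'   `"IR"`), `gene_id`.
#' @param edges data.frame with columns `node_a`, `node_b`, `mi`; the
#'   `edge_type` column is derived if absent. Each unordered pair at most
#'   once, no self loops, `mi > 0`.
#' @param thresholded logical; has per-edge-type MI thresholding been applied?
#' @param group_label free-text label (e.g. `"affected"`).
#' @param allow_same_gene permit edges whose endpoints share a gene (only
#'   before [strip_same_gene_edges()]).
#' @return An object of class `mi_network`.
#' @export
mi_network <- function(nodes, edges, thresholded = FALSE, group_label = "",
                       allow_same_gene = FALSE) {
  stopifnot(all(c("node_id", "modality", "gene_id") %in% names(nodes)))
  if (anyDuplicated(nodes$node_id)) stop("duplicated node ids")
  if (!all(nodes$modality %in% c("TE", "IR"))) stop("modality must be TE or IR")
  if (any(is.na(nodes$gene_id))) stop("every node needs a gene_id")
  if (nrow(edges)) {
    stopifnot(all(c("node_a", "node_b", "mi") %in% names(edges)))
    if (!all(c(edges$node_a, edges$node_b) %in% nodes$node_id))
      stop("edge endpoints missing from the node table")
    if (any(edges$node_a == edges$node_b)) stop("self loops are not allowed")
    if (any(edges$mi <= 0)) stop("edge MI must be positive")
    a <- pmin(edges$node_a, edges$node_b)
    b <- pmax(edges$node_a, edges$node_b)
    edges$node_a <- a
    edges$node_b <- b
    if (anyDuplicated(paste(a, b, sep = "\r"))) stop("duplicated edges")
    mod <- structure(nodes$modality, names = nodes$node_id)
    gid <- structure(nodes$gene_id, names = nodes$node_id)
    if (!allow_same_gene && any(gid[a] == gid[b]))
      stop("edges connecting features of the same gene are not allowed; ",
           "use strip_same_gene_edges() first")
    edges$edge_type <- edge_type_of(mod[a], mod[b])
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(node_a = character(0), node_b = character(0),
                        mi = numeric(0), edge_type = character(0),
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes[, c("node_id", "modality", "gene_id")],
                 edges = edges[, c("node_a", "node_b", "mi", "edge_type")],
                 thresholded = isTRUE(thresholded),
                 group_label = group_label),
            class = "mi_network")
}

edge_type_of <- function(mod_a, mod_b) {
  ifelse(mod_a == "TE" & mod_b == "TE", "TE-TE",
         ifelse(mod_a == "IR" & mod_b == "IR", "IR-IR", "TE-IR"))
}

#' @export
print.mi_network <- function(x, ...) {
  cat(sprintf("mi_network '%s' (%s): %d nodes (%d TE, %d IR), %d edges\n",
              x$group_label, if (x$thresholded) "thresholded" else "unthresholded",
              nrow(x$nodes), sum(x$nodes$modality == "TE"),
              sum(x$nodes$modality == "IR"), nrow(x$edges)))
  if (nrow(x$edges)) {
    tab <- table(x$edges$edge_type)
    cat("  edge types: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# canonical "a\rb" edge keys for set operations
edge_keys <- function(edges) {
  if (!nrow(edges)) return(character(0))
  paste(pmin(edges$node_a, edges$node_b), pmax(edges$node_a, edges$node_b),
        sep = "\r")
}

#' Node degrees of a network
#'
#' @param net an [mi_network()].
#' @return named integer vector over all nodes (isolated nodes have degree 0).
#' @export
node_degrees <- function(net) {
  stopifnot(inherits(net, "mi_network"))
  deg <- structure(integer(nrow(net$nodes)), names = net$nodes$node_id)
  if (nrow(net$edges)) {
    tab <- table(c(net$edges$node_a, net$edges$node_b))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}
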