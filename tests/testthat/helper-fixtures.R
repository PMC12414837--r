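# Small builders shared across the test files. Everything is generated in
# code; no fixture files.

# A tiny simulation configuration that keeps unit tests fast.
tiny_config <- function(...) {
  args <- list(n_genes = 60, n_modules = 4, hubs_per_module = 1,
               n_affected = 30, n_unaffected = 20,
               n_planted_master_hubs = 2, n_switch_genes = 5, n_de_genes = 4,
               seed = 42L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# Construct an mi_network from a compact edge spec. Node ids ending in
# "-t<k>" are IR nodes (parent gene = prefix); everything else is a TE node.
make_net <- function(edges = NULL, extra_nodes = character(0),
                     thresholded = TRUE, group_label = "test") {
  ids <- unique(c(extra_nodes,
                  if (!is.null(edges)) c(edges$node_a, edges$node_b)))
  is_ir <- grepl("-t[0-9]+$", ids)
  nodes <- data.frame(node_id = ids,
                      modality = ifelse(is_ir, "IR", "TE"),
                      gene_id = sub("-t[0-9]+$", "", ids),
                      stringsAsFactors = FALSE)
  if (is.null(edges))
    edges <- data.frame(node_a = character(0), node_b = character(0),
                        mi = numeric(0))
  if (is.null(edges$mi)) edges$mi <- 1
  mi_network(nodes, edges, thresholded = thresholded,
             group_label = group_label)
}

edge_df <- function(a, b, mi = NULL) {
  d <- data.frame(node_a = a, node_b = b, stringsAsFactors = FALSE)
  d$mi <- if (is.null(mi)) rep(1, nrow(d)) else mi
  d
}

# Independent brute-force DPI oracle: enumerate every triangle and mark the
# dominated edge; simultaneous removal.
dpi_oracle <- function(edges, eps = 0) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  w <- structure(edges$mi, names = key(edges$node_a, edges$node_b))
  ids <- sort(unique(c(edges$node_a, edges$node_b)))
  drop <- character(0)
  if (length(ids) >= 3) {
    combs <- utils::combn(ids, 3)
    for (c3 in seq_len(ncol(combs))) {
      tri <- combs[, c3]
      k12 <- key(tri[1], tri[2]); k13 <- key(tri[1], tri[3])
      k23 <- key(tri[2], tri[3])
      if (all(c(k12, k13, k23) %in% names(w))) {
        ws <- c(w[k12], w[k13], w[k23])
        ks <- c(k12, k13, k23)
        for (i in 1:3)
          if (ws[i] < min(ws[-i]) - eps) drop <- c(drop, ks[i])
      }
    }
  }
  edges[!(key(edges$node_a, edges$node_b) %in% drop), , drop = FALSE]
}

# Random simple weighted graph on n nodes.
random_graph <- function(n, p_edge = 0.3, seed = 1) {
  set.seed(seed)
  pairs <- t(utils::combn(sprintf("n%02d", seq_len(n)), 2))
  sel <- stats::runif(nrow(pairs)) < p_edge
  data.frame(node_a = pairs[sel, 1], node_b = pairs[sel, 2],
             mi = stats::runif(sum(sel), 0.01, 1),
             stringsAsFactors = FALSE)
}

# Minimal count matrix fixture with explicit values.
counts_fixture <- function(values, level = "gene", prefix = "f") {
  m <- matrix(as.integer(values), nrow = nrow(values), ncol = ncol(values))
  rownames(m) <- rownames(values) %||% sprintf("%s%d", prefix, seq_len(nrow(m)))
  colnames(m) <- colnames(values) %||% sprintf("s%d", seq_len(ncol(m)))
  count_matrix(m, level)
}

expr_fixture <- function(values, level = "gene", stage = "corrected",
                         prefix = "f") {
  m <- as.matrix(values)
  if (is.null(rownames(m))) rownames(m) <- sprintf("%s%d", prefix, seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  expression_matrix(m, level, stage)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sample_fixture <- function(n_affected, n_unaffected, seed = 1) {
  set.seed(seed)
  n <- n_affected + n_unaffected
  data.frame(sample_id = sprintf("s%d", seq_len(n)),
             group = rep(c("affected", "unaffected"),
                         c(n_affected, n_unaffected)),
             batch = sample(rep_len(c("b1", "b2"), n)),
             age = rnorm(n, 35, 10),
             stringsAsFactors = FALSE)
}
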