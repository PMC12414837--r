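#' Mutual-information estimator parameters
#'
#' @param estimator `"gaussian-copula"` (rank-transform each feature to normal
#'   scores and use the closed form `-0.5 * ln(1 - rho^2)` in nats) or
#'   `"binned"` (equal-frequency bins, plug-in MI with a Miller-Madow bias
#'   correction, clamped at zero).
#' @param dpi_tolerance DPI tolerance epsilon in `[0, 1)`.
#' @param n_bins number of bins for the binned estimator (default the
#'   cube-root rule `floor(n_samples^(1/3))`, at least 2; few enough bins
#'   that the Miller-Madow correction can absorb the plug-in bias).
#' @return list of class `mi_params`.
#' @export
mi_params <- function(estimator = c("gaussian-copula", "binned"),
                      dpi_tolerance = 0, n_bins = NULL) {
  estimator <- match.arg(estimator)
  if (dpi_tolerance < 0 || dpi_tolerance >= 1)
    stop("dpi_tolerance must be in [0, 1)")
  if (!is.null(n_bins) && n_bins < 2) stop("n_bins must be at least 2")
  structure(list(estimator = estimator, dpi_tolerance = dpi_tolerance,
                 n_bins = n_bins), class = "mi_params")
}

#' Pairwise mutual information between features
#'
#' Returns the symmetric, non-negative MI matrix (nats) for every feature
#' pair of a features x samples matrix. The Gaussian-copula estimator maps
#' each feature to normal scores `qnorm((rank - 0.5) / n)` and applies the
#' bivariate-normal closed form; the binned estimator uses equal-frequency
#' bins and plug-in MI with a Miller-Madow correction.
#'
#' @param expr numeric features x samples matrix (>= 3 samples; every feature
#'   must have non-zero variance).
#' @param params an [mi_params()].
#' @return symmetric numeric matrix with zero diagonal.
#' @export
estimate_mi <- function(expr, params = mi_params()) {
  stopifnot(inherits(params, "mi_params"))
  if (!is.matrix(expr)) expr <- as.matrix(expr)
  n <- ncol(expr)
  if (n < 3) stop("need at least 3 samples")
  v <- apply(expr, 1, stats::var)
  if (any(v == 0))
    stop("constant feature(s): ",
         paste(utils::head(rownames(expr)[v == 0], 5), collapse = ", "))
  if (params$estimator == "gaussian-copula") {
    scores <- t(apply(expr, 1, function(x) stats::qnorm((rank(x) - 0.5) / n)))
    rho <- stats::cor(t(scores))
    rho[rho > 0.99999] <- 0.99999
    rho[rho < -0.99999] <- -0.99999
    mi <- -0.5 * log(1 - rho^2)
  } else {
    nb <- params$n_bins %||% max(2L, floor(n^(1 / 3)))
    binned <- t(apply(expr, 1, function(x)
      as.integer(cut(rank(x, ties.method = "first"),
                     breaks = seq(0.5, n + 0.5, length.out = nb + 1)))))
    p <- nrow(expr)
    mi <- matrix(0, p, p)
    marg <- lapply(seq_len(p), function(i) tabulate(binned[i, ], nb))
    h_marg <- vapply(marg, function(cnt) {
      f <- cnt[cnt > 0] / n
      -sum(f * log(f))
    }, 0)
    k_marg <- vapply(marg, function(cnt) sum(cnt > 0), 0L)
    for (i in seq_len(p - 1)) {
      bi <- binned[i, ]
      for (j in (i + 1):p) {
        joint <- tabulate((bi - 1L) * nb + binned[j, ], nb * nb)
        f <- joint[joint > 0] / n
        h_joint <- -sum(f * log(f))
        est <- h_marg[i] + h_marg[j] - h_joint
        # Miller-Madow: subtract the plug-in bias difference
        est <- est - (sum(joint > 0) - k_marg[i] - k_marg[j] + 1) / (2 * n)
        mi[i, j] <- mi[j, i] <- max(0, est)
      }
    }
  }
  diag(mi) <- 0
  dimnames(mi) <- list(rownames(expr), rownames(expr))
  mi
}

#' Prune indirect edges with the data processing inequality
#'
#' For every triangle (i, j, k) the edge (i, j) is marked for removal when
#' `mi(i,j) < min(mi(i,k), mi(j,k)) - eps`. All marks are computed on the
#' input graph and applied simultaneously, so the result is independent of
#' edge order and the strict maximum edge of a triangle is never removed.
#'
#' @param edges data.frame with `node_a`, `node_b`, `mi` (a simple weighted
#'   graph) or a symmetric weighted adjacency matrix with zeros for absent
#'   edges.
#' @param eps DPI tolerance (>= 0).
#' @return The surviving edges in the same form as the input.
#' @export
prune_dpi <- function(edges, eps = 0) {
  if (eps < 0) stop("eps must be non-negative")
  if (is.matrix(edges)) {
    drop <- dpi_marks(edges, eps)
    out <- edges
    out[drop] <- 0
    return(out)
  }
  stopifnot(all(c("node_a", "node_b", "mi") %in% names(edges)))
  if (!nrow(edges)) return(edges)
  ids <- sort(unique(c(edges$node_a, edges$node_b)))
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  ia <- match(edges$node_a, ids)
  ib <- match(edges$node_b, ids)
  if (anyDuplicated(cbind(pmin(ia, ib), pmax(ia, ib))))
    stop("duplicated edges in input graph")
  M[cbind(ia, ib)] <- edges$mi
  M[cbind(ib, ia)] <- edges$mi
  drop <- dpi_marks(M, eps)
  edges[!drop[cbind(ia, ib)], , drop = FALSE]
}

#' Remove edges connecting features of the same gene
#'
#' TE-IR edges between a gene and its own transcripts, and IR-IR edges
#' between sibling transcripts, are removed to avoid trivially coupled
#' features; all other edges are untouched.
#'
#' @param net an [mi_network()] (possibly created with
#'   `allow_same_gene = TRUE`).
#' @param map optional transcript-to-gene table used to fill in missing
#'   parent-gene assignments for IR nodes.
#' @return The stripped `mi_network`.
#' @export
strip_same_gene_edges <- function(net, map = NULL) {
  stopifnot(inherits(net, "mi_network"))
  nodes <- net$nodes
  if (!is.null(map)) {
    validate_feature_map(map)
    ir <- nodes$modality == "IR"
    fill <- is.na(nodes$gene_id) & ir
    nodes$gene_id[fill] <-
      structure(map$gene_id, names = map$transcript_id)[nodes$node_id[fill]]
  }
  if (any(is.na(nodes$gene_id))) stop("nodes with missing gene_id")
  gid <- structure(nodes$gene_id, names = nodes$node_id)
  edges <- net$edges
  keep <- gid[edges$node_a] != gid[edges$node_b]
  mi_network(nodes, edges[keep, , drop = FALSE],
             thresholded = net$thresholded, group_label = net$group_label)
}

#' Infer an MI network from TE and IR features of one group
#'
#' Stacks the gene-level expression matrix (TE nodes, identified by gene id)
#' and the isoform-ratio matrix (IR nodes, identified by transcript id),
#' estimates pairwise MI, keeps positive-MI pairs, prunes indirect edges with
#' the DPI, and removes same-gene edges. Isolated nodes are retained so node
#' counts stay reportable.
#'
#' @param te corrected gene-level [expression_matrix()].
#' @param ir an [ir_matrix()] on the same samples.
#' @param sample_ids samples to use (restrict to one group); default all.
#' @param params [mi_params()].
#' @param group_label label stored on the network.
#' @param min_samples below this many samples a warning about reduced
#'   inference power is emitted (default 20).
#' @return An unthresholded [mi_network()].
#' @export
infer_network <- function(te, ir, sample_ids = NULL, params = mi_params(),
                          group_label = "", min_samples = 20) {
  stopifnot(inherits(te, "expression_matrix"), inherits(ir, "ir_matrix"))
  if (is.null(sample_ids)) sample_ids <- colnames(te)
  if (!all(sample_ids %in% colnames(te)) || !all(sample_ids %in% colnames(ir)))
    stop("sample_ids missing from the TE or IR matrix")
  if (length(sample_ids) < min_samples)
    warning("only ", length(sample_ids), " samples: reduced inference power ",
            "caused by the smaller sample size")
  tev <- unclass(te)[, sample_ids, drop = FALSE]
  irv <- unclass(ir)[, sample_ids, drop = FALSE]
  shared_ids <- intersect(rownames(tev), rownames(irv))
  if (length(shared_ids))
    stop("TE and IR feature ids overlap: ",
         paste(utils::head(shared_ids, 3), collapse = ", "))
  nodes <- data.frame(
    node_id = c(rownames(tev), rownames(irv)),
    modality = rep(c("TE", "IR"), c(nrow(tev), nrow(irv))),
    gene_id = c(rownames(tev), unname(attr(ir, "gene_of")[rownames(irv)])),
    stringsAsFactors = FALSE)
  combined <- rbind(tev, irv)
  mi <- estimate_mi(combined, params)
  mi <- prune_dpi(mi, eps = params$dpi_tolerance)
  up <- which(upper.tri(mi) & mi > 0, arr.ind = TRUE)
  edges <- data.frame(node_a = rownames(mi)[up[, 1]],
                      node_b = rownames(mi)[up[, 2]],
                      mi = mi[up],
                      stringsAsFactors = FALSE)
  net <- mi_network(nodes, edges, thresholded = FALSE,
                    group_label = group_label, allow_same_gene = TRUE)
  strip_same_gene_edges(net)
}

#' Threshold a network pair at the reference network's median MI per edge type
#'
#' For each edge type the threshold is the median MI of the reference
#' (affected) network's edges of that type; both networks keep edges with
#' `mi >= threshold` of their type (inclusive, so ties are retained and the
#' reference network keeps about half its edges per type).
#'
#' @param net_a reference (affected) unthresholded [mi_network()].
#' @param net_b unthresholded comparison network.
#' @return list with `net_a_thr`, `net_b_thr`, and the named `thresholds`
#'   vector.
#' @export
threshold_pair <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "mi_network"), inherits(net_b, "mi_network"))
  if (net_a$thresholded || net_b$thresholded)
    stop("both networks must be unthresholded")
  types_needed <- union(unique(net_a$edges$edge_type),
                        unique(net_b$edges$edge_type))
  missing_t <- setdiff(types_needed, unique(net_a$edges$edge_type))
  if (length(missing_t))
    stop("edge type(s) absent from the reference network, threshold ",
         "undefined: ", paste(missing_t, collapse = ", "))
  thr <- vapply(split(net_a$edges$mi, net_a$edges$edge_type), stats::median, 0)
  apply_thr <- function(net) {
    e <- net$edges
    keep <- e$mi >= thr[e$edge_type]
    mi_network(net$nodes, e[keep, , drop = FALSE], thresholded = TRUE,
               group_label = net$group_label)
  }
  list(net_a_thr = apply_thr(net_a),
       net_b_thr = apply_thr(net_b),
       thresholds = thr)
}
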