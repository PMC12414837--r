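#' Identify hub nodes
#'
#' @param net a thresholded [mi_network()].
#' @param k hub degree threshold (inclusive, default 10).
#' @return data.frame `node_id`, `modality`, `gene_id`, `degree`, `is_hub`.
#' @export
identify_hubs <- function(net, k = 10) {
  stopifnot(inherits(net, "mi_network"))
  if (k < 1) stop("k must be at least 1")
  deg <- node_degrees(net)
  out <- net$nodes
  out$degree <- as.integer(deg[out$node_id])
  out$is_hub <- out$degree >= k
  out
}

#' Hubs common to two networks
#'
#' @param hubs_a,hubs_b [identify_hubs()] tables.
#' @return character vector of node ids that are hubs in both.
#' @export
common_hubs <- function(hubs_a, hubs_b) {
  intersect(hubs_a$node_id[hubs_a$is_hub], hubs_b$node_id[hubs_b$is_hub])
}

#' Partition common-hub edges into unique, shared and attenuated sets
#'
#' Over the edges of each thresholded network that touch at least one common
#' hub: an edge is *unique* to a network if it is absent from the
#' unthresholded version of the other network, *shared* if present in both
#' thresholded networks, and *attenuated* if present in the other network
#' only before thresholding. The three sets partition each network's
#' common-hub-incident edges.
#'
#' @param a_thr,b_thr thresholded networks.
#' @param a_raw,b_raw their unthresholded parents.
#' @param hubs character vector of common-hub node ids.
#' @return list with edge data.frames `unique_a`, `unique_b`, `shared`,
#'   `attenuated_a`, `attenuated_b` and a `summary` data.frame with counts
#'   and the percentage of unique edges per network
#'   (`100 * unique / (unique + shared + attenuated)`).
#' @export
partition_common_hub_edges <- function(a_thr, b_thr, a_raw, b_raw, hubs) {
  for (net in list(a_thr, b_thr, a_raw, b_raw)) {
    stopifnot(inherits(net, "mi_network"))
    if (!all(hubs %in% net$nodes$node_id))
      stop("hub node(s) missing from a network's node set: ",
           paste(utils::head(setdiff(hubs, net$nodes$node_id), 5), collapse = ", "))
  }
  incident <- function(net) {
    e <- net$edges
    e[e$node_a %in% hubs | e$node_b %in% hubs, , drop = FALSE]
  }
  ea <- incident(a_thr)
  eb <- incident(b_thr)
  ka <- edge_keys(ea); kb <- edge_keys(eb)
  ka_raw <- edge_keys(a_raw$edges); kb_raw <- edge_keys(b_raw$edges)
  classify <- function(e, keys, thr_other, raw_other) {
    list(unique = e[!(keys %in% raw_other), , drop = FALSE],
         shared = e[keys %in% thr_other, , drop = FALSE],
         attenuated = e[(keys %in% raw_other) & !(keys %in% thr_other), ,
                        drop = FALSE])
  }
  ca <- classify(ea, ka, kb, kb_raw)
  cb <- classify(eb, kb, ka, ka_raw)
  pct <- function(u, s, a) if (u + s + a == 0) NA_real_ else 100 * u / (u + s + a)
  summary <- data.frame(
    network = c("a", "b"),
    unique = c(nrow(ca$unique), nrow(cb$unique)),
    shared = c(nrow(ca$shared), nrow(cb$shared)),
    attenuated = c(nrow(ca$attenuated), nrow(cb$attenuated)),
    pct_unique = c(pct(nrow(ca$unique), nrow(ca$shared), nrow(ca$attenuated)),
                   pct(nrow(cb$unique), nrow(cb$shared), nrow(cb$attenuated))),
    stringsAsFactors = FALSE)
  list(unique_a = ca$unique, unique_b = cb$unique,
       shared = ca$shared,
       attenuated_a = ca$attenuated, attenuated_b = cb$attenuated,
       summary = summary)
}

#' Unique-edge percentage from partition counts
#'
#' Helper reproducing the percentage convention of
#' [partition_common_hub_edges()] from raw counts.
#'
#' @param unique,shared,attenuated edge counts.
#' @param digits decimal places (default 1).
#' @return percentage of unique edges.
#' @export
unique_edge_percentage <- function(unique, shared, attenuated = 0, digits = 1) {
  round(100 * unique / (unique + shared + attenuated), digits)
}

#' Master hub nodes
#'
#' Nodes with degree at least `k` in the thresholded focal network whose
#' degree is at least `min_fold` times their degree in the *unthresholded*
#' other network. A node absent (degree 0) from the other network has
#' infinite fold and qualifies whenever its focal degree reaches `k`. The
#' table is sorted by focal degree (descending, ties by node id) so the "top"
#' master hubs are well defined; folds exactly at the threshold are flagged
#' in `boundary`.
#'
#' @param focal_thr thresholded focal network.
#' @param other_raw unthresholded network of the other group.
#' @param k degree threshold (default 10).
#' @param min_fold minimum fold increase (inclusive, default 2).
#' @return data.frame `node_id`, `modality`, `gene_id`, `degree_focal`,
#'   `degree_other_unthresh`, `fold`, `boundary`.
#' @export
master_hubs <- function(focal_thr, other_raw, k = 10, min_fold = 2) {
  stopifnot(inherits(focal_thr, "mi_network"), inherits(other_raw, "mi_network"))
  if (min_fold < 1) stop("min_fold must be at least 1")
  if (other_raw$thresholded)
    stop("the comparison network must be unthresholded")
  deg_f <- node_degrees(focal_thr)
  deg_o <- node_degrees(other_raw)
  nodes <- focal_thr$nodes
  df <- as.integer(deg_f[nodes$node_id])
  do <- as.integer(deg_o[nodes$node_id])
  do[is.na(do)] <- 0L
  fold <- ifelse(do == 0, Inf, df / do)
  sel <- df >= k & fold >= min_fold
  out <- data.frame(node_id = nodes$node_id[sel],
                    modality = nodes$modality[sel],
                    gene_id = nodes$gene_id[sel],
                    degree_focal = df[sel],
                    degree_other_unthresh = do[sel],
                    fold = fold[sel],
                    boundary = fold[sel] == min_fold,
                    stringsAsFactors = FALSE)
  out[order(-out$degree_focal, out$node_id), , drop = FALSE]
}

#' Nodes within a hop radius of a seed set
#'
#' @param net an [mi_network()].
#' @param seeds node ids (must be in the network).
#' @param hops 1 (first-order neighbors) or 2 (two-hop neighborhood).
#' @param include_seeds include the seeds themselves (default `TRUE`).
#' @return character vector of node ids.
#' @export
neighborhood <- function(net, seeds, hops = 1, include_seeds = TRUE) {
  stopifnot(inherits(net, "mi_network"))
  if (!hops %in% c(1, 2)) stop("hops must be 1 or 2")
  if (!all(seeds %in% net$nodes$node_id))
    stop("seed node(s) not in the network")
  frontier <- seeds
  reached <- seeds
  for (h in seq_len(hops)) {
    e <- net$edges
    nb <- c(e$node_b[e$node_a %in% frontier], e$node_a[e$node_b %in% frontier])
    frontier <- setdiff(unique(nb), reached)
    reached <- union(reached, frontier)
  }
  if (!include_seeds) reached <- setdiff(reached, seeds)
  sort(reached)
}

#' Modality (TE-TE vs IR-IR) subnetwork comparison
#'
#' For each network, extracts the TE-TE subnetwork (edges as gene pairs) and
#' the IR-IR subnetwork (edges as transcript pairs, additionally mapped to
#' unordered parent-gene pairs). A TE-TE edge is *unique* when its gene pair
#' is absent from the gene-mapped IR-IR set of the same network, and vice
#' versa.
#'
#' @param a_thr,b_thr thresholded networks.
#' @param map optional transcript-to-gene table used to fill missing IR
#'   parent genes.
#' @param percent_mode `"round"` (round half to even, default) or `"floor"`
#'   for the integer percentages.
#' @return list with per-network `ModalitySplit` entries (`te_te_edges`,
#'   `ir_ir_edges`, `ir_ir_gene_pairs`, counts and integer percentages of
#'   unique edges) and a combined `summary` data.frame.
#' @export
modality_subnetworks <- function(a_thr, b_thr, map = NULL,
                                 percent_mode = c("round", "floor")) {
  percent_mode <- match.arg(percent_mode)
  pc <- function(x) if (percent_mode == "round") round(x) else floor(x)
  split_one <- function(net, label) {
    stopifnot(inherits(net, "mi_network"))
    if (!net$thresholded) stop("networks must be thresholded")
    nodes <- net$nodes
    if (!is.null(map)) {
      validate_feature_map(map)
      fill <- is.na(nodes$gene_id) & nodes$modality == "IR"
      nodes$gene_id[fill] <-
        structure(map$gene_id, names = map$transcript_id)[nodes$node_id[fill]]
    }
    if (any(is.na(nodes$gene_id))) stop("unmapped transcript node(s)")
    gid <- structure(nodes$gene_id, names = nodes$node_id)
    e <- net$edges
    tete <- e[e$edge_type == "TE-TE", , drop = FALSE]
    irir <- e[e$edge_type == "IR-IR", , drop = FALSE]
    te_pairs <- paste(pmin(tete$node_a, tete$node_b),
                      pmax(tete$node_a, tete$node_b), sep = "\r")
    ir_gene_pairs <- unique(paste(pmin(gid[irir$node_a], gid[irir$node_b]),
                                  pmax(gid[irir$node_a], gid[irir$node_b]),
                                  sep = "\r"))
    uniq_te <- sum(!(te_pairs %in% ir_gene_pairs))
    irir_gp <- paste(pmin(gid[irir$node_a], gid[irir$node_b]),
                     pmax(gid[irir$node_a], gid[irir$node_b]), sep = "\r")
    uniq_ir <- sum(!(irir_gp %in% te_pairs))
    list(network = label,
         te_te_edges = tete, ir_ir_edges = irir,
         ir_ir_gene_pairs = ir_gene_pairs,
         n_te_te = nrow(tete), n_ir_ir = nrow(irir),
         unique_te_te = uniq_te, unique_ir_ir = uniq_ir,
         pct_unique_te_te = if (nrow(tete)) pc(100 * uniq_te / nrow(tete)) else NA,
         pct_unique_ir_ir = if (nrow(irir)) pc(100 * uniq_ir / nrow(irir)) else NA)
  }
  sa <- split_one(a_thr, "a")
  sb <- split_one(b_thr, "b")
  summary <- data.frame(
    network = c("a", "b"),
    n_te_te = c(sa$n_te_te, sb$n_te_te),
    unique_te_te = c(sa$unique_te_te, sb$unique_te_te),
    pct_unique_te_te = c(sa$pct_unique_te_te, sb$pct_unique_te_te),
    n_ir_ir = c(sa$n_ir_ir, sb$n_ir_ir),
    unique_ir_ir = c(sa$unique_ir_ir, sb$unique_ir_ir),
    pct_unique_ir_ir = c(sa$pct_unique_ir_ir, sb$pct_unique_ir_ir),
    stringsAsFactors = FALSE)
  list(a = sa, b = sb, summary = summary)
}

#' Hub modality composition across degree thresholds
#'
#' For each degree threshold, counts TE and IR nodes with at least that
#' degree and reports the IR proportion.
#'
#' @param net a thresholded [mi_network()].
#' @param thresholds integer degree thresholds (default `c(10, 15, 20)`).
#' @return data.frame `threshold`, `n_te`, `n_ir`, `prop_ir`.
#' @export
hub_modality_composition <- function(net, thresholds = c(10, 15, 20)) {
  stopifnot(inherits(net, "mi_network"))
  if (length(thresholds) == 0) stop("threshold list must not be empty")
  deg <- node_degrees(net)
  mod <- structure(net$nodes$modality, names = net$nodes$node_id)
  do.call(rbind, lapply(thresholds, function(k) {
    hub <- names(deg)[deg >= k]
    n_te <- sum(mod[hub] == "TE")
    n_ir <- sum(mod[hub] == "IR")
    data.frame(threshold = k, n_te = n_te, n_ir = n_ir,
               prop_ir = if (n_te + n_ir > 0) n_ir / (n_te + n_ir) else NA_real_)
  }))
}
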