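#' Perturbation configuration for surrogate-graph generation
#'
#' @param n_graphs surrogate graphs per network (default 100, at least 2).
#' @param retention probability of keeping each edge, in (0, 1].
#' @param seed base seed for the surrogate ensemble.
#' @return list of class `perturb_config`.
#' @export
perturb_config <- function(n_graphs = 100, retention = 0.9, seed = 1L) {
  if (n_graphs < 2) stop("n_graphs must be at least 2")
  if (retention <= 0 || retention > 1) stop("retention must be in (0, 1]")
  structure(list(n_graphs = as.integer(n_graphs), retention = retention,
                 seed = as.integer(seed)), class = "perturb_config")
}

#' Degree-biased edge-resampling perturbation of a network
#'
#' Keeps each edge independently with probability `retention` and replaces
#' the removed edges (same expected count) with new edges whose endpoints
#' are sampled with probability proportional to the original node degrees,
#' rejecting self loops, duplicates, and same-gene pairs. The node set is
#' unchanged and the output is deterministic for a fixed seed. With
#' `retention = 1` the input is returned unchanged.
#'
#' @param net an [mi_network()].
#' @param retention edge retention probability in (0, 1].
#' @param seed integer seed.
#' @return A perturbed `mi_network` with the same node set.
#' @export
perturb_graph <- function(net, retention, seed) {
  stopifnot(inherits(net, "mi_network"))
  if (retention <= 0 || retention > 1) stop("retention must be in (0, 1]")
  if (retention == 1 || nrow(net$edges) == 0) return(net)
  set.seed(seed)
  e <- net$edges
  keep <- stats::runif(nrow(e)) < retention
  kept <- e[keep, , drop = FALSE]
  n_new <- nrow(e) - nrow(kept)
  if (n_new > 0) {
    deg <- node_degrees(net)
    active <- names(deg)[deg > 0]
    w <- deg[active]
    gid <- structure(net$nodes$gene_id, names = net$nodes$node_id)
    existing <- edge_keys(kept)
    fill_mi <- mean(e$mi)
    new_a <- character(0); new_b <- character(0)
    tries <- 0
    while (length(new_a) < n_new && tries < 200) {
      tries <- tries + 1
      m <- 2 * (n_new - length(new_a)) + 8
      a <- sample(active, m, replace = TRUE, prob = w)
      b <- sample(active, m, replace = TRUE, prob = w)
      lo <- pmin(a, b); hi <- pmax(a, b)
      key <- paste(lo, hi, sep = "\r")
      ok <- lo != hi & gid[lo] != gid[hi] & !(key %in% existing) &
        !duplicated(key)
      lo <- lo[ok]; hi <- hi[ok]; key <- key[ok]
      take <- seq_len(min(length(lo), n_new - length(new_a)))
      new_a <- c(new_a, lo[take]); new_b <- c(new_b, hi[take])
      existing <- c(existing, key[take])
    }
    if (length(new_a)) {
      add <- data.frame(node_a = new_a, node_b = new_b, mi = fill_mi,
                        edge_type = NA_character_, stringsAsFactors = FALSE)
      kept <- rbind(kept[, c("node_a", "node_b", "mi")],
                    add[, c("node_a", "node_b", "mi")])
    }
  }
  mi_network(net$nodes, kept, thresholded = net$thresholded,
             group_label = net$group_label)
}

# Deterministic, seed-independent 31-bit polynomial rolling hash of strings.
hash_strings <- function(x) {
  mod <- 2147483647
  vapply(x, function(s) {
    h <- 0
    for (b in utf8ToInt(s)) h <- (h * 31 + b) %% mod
    h
  }, 0, USE.NAMES = FALSE)
}

# One graph -> dim-length WL subtree feature vector (term frequencies of
# hashed refinement labels over iterations 0..iterations).
wl_features_one <- function(net, iterations, dim) {
  ids <- net$nodes$node_id
  n <- length(ids)
  lab <- net$nodes$modality
  ia <- match(net$edges$node_a, ids)
  ib <- match(net$edges$node_b, ids)
  adj <- vector("list", n)
  if (length(ia)) {
    ninc <- split(c(ib, ia), c(ia, ib))
    adj[as.integer(names(ninc))] <- ninc
  }
  counts <- numeric(dim)
  add_labels <- function(lab) {
    ul <- unique(lab)
    bucket <- hash_strings(ul) %% dim + 1
    tab <- tabulate(bucket[match(lab, ul)], dim)
    counts <<- counts + tab
  }
  add_labels(lab)
  for (it in seq_len(iterations)) {
    new_lab <- vapply(seq_len(n), function(i) {
      nb <- adj[[i]]
      if (is.null(nb) || !length(nb)) return(paste0(lab[i], "()"))
      paste0(lab[i], "(", paste(sort(lab[nb]), collapse = ","), ")")
    }, "")
    # compress long labels to their hash so strings stay bounded
    ul <- unique(new_lab)
    comp <- as.character(hash_strings(ul))
    lab <- comp[match(new_lab, ul)]
    add_labels(lab)
  }
  counts / sum(counts)
}

#' Weisfeiler-Lehman whole-graph embedding
#'
#' Each graph is mapped to a `dim`-length vector: starting from node modality
#' labels, WL label refinement runs for `iterations` rounds; every label seen
#' (across all rounds) is hashed into one of `dim` buckets with a fixed,
#' seed-independent hash, and bucket counts are scaled by the total count
#' (term frequency). Isomorphic graphs with matching modality labels receive
#' identical vectors.
#'
#' @param graphs list of [mi_network()] objects.
#' @param iterations WL refinement rounds (default 3).
#' @param dim embedding dimension (default 128, at least 2).
#' @param labels optional vector of group labels stored alongside the rows.
#' @return matrix with one row per graph; attribute `labels` carries the
#'   group labels.
#' @export
wl_embed <- function(graphs, iterations = 3, dim = 128, labels = NULL) {
  if (!length(graphs)) stop("need at least one graph")
  if (dim < 2) stop("dim must be at least 2")
  emb <- t(vapply(graphs, wl_features_one, numeric(dim),
                  iterations = iterations, dim = dim))
  rownames(emb) <- names(graphs)
  if (!is.null(labels)) attr(emb, "labels") <- labels
  emb
}

#' Separability of two networks from surrogate-graph embeddings
#'
#' Generates `n_graphs` perturbed surrogates per network, embeds all graphs
#' with [wl_embed()], reduces to `n_components` principal components, and
#' classifies network identity with an L2-penalized logistic regression on
#' repeated stratified train/test splits. Returns the mean test accuracy and
#' 2-D PCA coordinates for plotting.
#'
#' @param net_a,net_b thresholded [mi_network()] objects.
#' @param config a [perturb_config()].
#' @param n_components principal components kept (default 10).
#' @param train_frac training fraction per split (default 0.8).
#' @param n_repeats number of stratified splits (default 10).
#' @param seed integer seed driving surrogate generation and splits.
#' @param iterations,dim WL embedding parameters.
#' @return list with `accuracy` (mean test accuracy), `accuracies` (per
#'   repeat), `pca` (data.frame PC1, PC2, label), and `embedding`.
#' @export
separation_score <- function(net_a, net_b, config = perturb_config(),
                             n_components = 10, train_frac = 0.8,
                             n_repeats = 10, seed = 1,
                             iterations = 3, dim = 128) {
  stopifnot(inherits(config, "perturb_config"))
  n <- config$n_graphs
  if (2 * n < 10) stop("too few surrogate graphs for a train/test split")
  seeds <- seed + seq_len(2 * n)
  graphs <- c(lapply(seeds[seq_len(n)], function(s)
    perturb_graph(net_a, config$retention, s)),
    lapply(seeds[n + seq_len(n)], function(s)
      perturb_graph(net_b, config$retention, s)))
  labels <- rep(c(1, 0), each = n)   # 1 = group A (affected)
  emb <- wl_embed(graphs, iterations = iterations, dim = dim)
  keep <- apply(emb, 2, stats::sd) > 0
  n_components <- min(n_components, sum(keep), 2 * n - 1)
  pc <- stats::prcomp(emb[, keep, drop = FALSE], center = TRUE, scale. = FALSE,
                      rank. = max(2, n_components))
  X <- pc$x[, seq_len(n_components), drop = FALSE]

  set.seed(seed)
  acc <- vapply(seq_len(n_repeats), function(r) {
    tr <- c(sample(which(labels == 1), round(train_frac * n)),
            sample(which(labels == 0), round(train_frac * n)))
    te <- setdiff(seq_len(2 * n), tr)
    fit <- ridge_logistic(X[tr, , drop = FALSE], labels[tr])
    pred <- as.numeric(cbind(1, X[te, , drop = FALSE]) %*% fit) > 0
    mean(pred == (labels[te] == 1))
  }, 0)
  list(accuracy = mean(acc),
       accuracies = acc,
       pca = data.frame(PC1 = pc$x[, 1], PC2 = pc$x[, 2],
                        label = ifelse(labels == 1, "a", "b")),
       embedding = emb)
}

# L2-penalized logistic regression (fixed lambda = 1, intercept unpenalized)
# fitted by Newton iterations; small and deterministic, immune to the
# perfect-separation divergence of plain glm.
ridge_logistic <- function(X, y, lambda = 1, max_iter = 50) {
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1)))
  for (i in seq_len(max_iter)) {
    eta <- as.numeric(Xd %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-8)
    grad <- crossprod(Xd, y - mu) - pen %*% beta
    hess <- crossprod(Xd * w, Xd) + pen
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  beta
}
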