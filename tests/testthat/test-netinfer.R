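test_that("Gaussian-copula MI matches the bivariate-normal closed form", {
  set.seed(11)
  n <- 2000
  for (rho in c(0, 0.5, 0.9)) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    mi <- estimate_mi(rbind(a = x, b = y))
    expect_lt(abs(mi["a", "b"] - (-0.5 * log(1 - rho^2))), 0.05)
  }
})

test_that("MI of independent features is near zero and symmetric", {
  set.seed(12)
  m <- matrix(rnorm(6 * 1000), 6, 1000,
              dimnames = list(paste0("f", 1:6), NULL))
  mi <- estimate_mi(m)
  expect_true(all(mi[upper.tri(mi)] <= 0.01))
  expect_true(all(mi >= 0))
  expect_equal(mi, t(mi))
  mib <- estimate_mi(m, mi_params("binned"))
  expect_true(all(mib >= 0))
  expect_equal(mib, t(mib))
  expect_true(mean(mib[upper.tri(mib)]) <= 0.05)
})

test_that("the binned estimator tracks dependence strength", {
  set.seed(13)
  n <- 2000
  x <- rnorm(n)
  y <- 0.9 * x + sqrt(1 - 0.81) * rnorm(n)
  z <- rnorm(n)
  mi <- estimate_mi(rbind(x = x, y = y, z = z), mi_params("binned"))
  expect_gt(mi["x", "y"], 0.3)
  expect_gt(mi["x", "y"], 10 * mi["x", "z"])
})

test_that("constant features are rejected by name", {
  m <- rbind(a = rnorm(10), b = rep(1, 10))
  expect_error(estimate_mi(m), "constant feature.*b")
  expect_error(estimate_mi(m[, 1:2, drop = FALSE]), "3 samples")
})

test_that("DPI removes the weakest edge of a dominating triangle", {
  tri <- edge_df(c("A", "B", "A"), c("B", "C", "C"), c(0.5, 0.4, 0.1))
  out <- prune_dpi(tri, eps = 0)
  expect_setequal(paste(out$node_a, out$node_b), c("A B", "B C"))
  # tolerance keeps a nearly-tied edge: 0.39 >= 0.4 - 0.02
  tri2 <- edge_df(c("A", "B", "A"), c("B", "C", "C"), c(0.5, 0.4, 0.39))
  expect_equal(nrow(prune_dpi(tri2, eps = 0.02)), 3)
  expect_equal(nrow(prune_dpi(tri2, eps = 0)), 2)
  expect_error(prune_dpi(tri, eps = -0.1), "non-negative")
})

test_that("DPI equals the exhaustive brute-force oracle on random graphs", {
  for (seed in 1:30) {
    g <- random_graph(n = sample(5:30, 1), p_edge = runif(1, 0.2, 0.8),
                      seed = seed)
    for (eps in c(0, 0.05)) {
      got <- prune_dpi(g, eps)
      want <- dpi_oracle(g, eps)
      expect_equal(got[order(got$node_a, got$node_b), ],
                   want[order(want$node_a, want$node_b), ],
                   ignore_attr = TRUE)
    }
  }
})

test_that("every DPI-removed edge is dominated by some triangle", {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  for (i in 1:10) {
    g <- random_graph(n = 15, p_edge = 0.6, seed = i)
    out <- prune_dpi(g, 0)
    w <- structure(g$mi, names = key(g$node_a, g$node_b))
    removed <- setdiff(names(w), key(out$node_a, out$node_b))
    ids <- sort(unique(c(g$node_a, g$node_b)))
    for (r in removed) {
      ends <- strsplit(r, "\r", fixed = TRUE)[[1]]
      dominated <- FALSE
      for (k in setdiff(ids, ends)) {
        k1 <- key(ends[1], k); k2 <- key(ends[2], k)
        if (k1 %in% names(w) && k2 %in% names(w) &&
            min(w[k1], w[k2]) > w[r]) { dominated <- TRUE; break }
      }
      expect_true(dominated)
    }
  }
})

test_that("same-gene edges are stripped and others untouched", {
  ids <- c("G1", "G2", "G3", "G1-t1", "G2-t1", "G2-t2")
  nodes <- data.frame(node_id = ids,
                      modality = ifelse(grepl("-t", ids), "IR", "TE"),
                      gene_id = sub("-t[0-9]+$", "", ids))
  raw <- mi_network(nodes,
                    edge_df(c("G1", "G1", "G1-t1", "G2-t1", "G2"),
                            c("G1-t1", "G2-t1", "G2-t2", "G2-t2", "G3"),
                            c(0.5, 0.4, 0.3, 0.2, 0.1)),
                    allow_same_gene = TRUE, thresholded = FALSE)
  out <- strip_same_gene_edges(raw)
  # G1~G1-t1 (own transcript) and G2-t1~G2-t2 (siblings) removed; 3 remain
  expect_equal(nrow(out$edges), 3)
  expect_false(any(paste(out$edges$node_a, out$edges$node_b) %in%
                     c("G1 G1-t1", "G2-t1 G2-t2")))
})

test_that("make_net rejects same-gene fixture edges", {
  expect_error(make_net(edge_df("G1", "G1-t1")), "same gene")
})

test_that("an indirect chain edge is removed by DPI at scale", {
  set.seed(14)
  n <- 500
  x <- rnorm(n)
  y <- 0.9 * x + 0.45 * rnorm(n)
  z <- 0.9 * y + 0.45 * rnorm(n)
  m <- rbind(X = x, Y = y, Z = z)
  colnames(m) <- sprintf("s%d", 1:n)
  te <- expression_matrix(m, level = "gene", stage = "corrected")
  irv <- matrix(rnorm(n), 1, n,
                dimnames = list("Q-t1", colnames(te)))
  ir <- ir_matrix(irv, c(`Q-t1` = "Q"))
  net <- infer_network(te, ir, params = mi_params(), group_label = "test")
  keys <- paste(net$edges$node_a, net$edges$node_b)
  expect_true(all(c("X Y", "Y Z") %in% keys))
  expect_false("X Z" %in% keys)
})

test_that("network inference is deterministic and types edges correctly", {
  set.seed(15)
  n <- 60
  x <- rnorm(n)
  te <- expression_matrix(
    matrix(x + 0.2 * rnorm(n), 1, n, dimnames = list("G1", sprintf("s%d", 1:n))),
    level = "gene", stage = "corrected")
  irv <- matrix(x + 0.2 * rnorm(n), 1, n,
                dimnames = list("G2-t1", colnames(te)))
  ir <- ir_matrix(irv, c(`G2-t1` = "G2"))
  n1 <- infer_network(te, ir, group_label = "g")
  n2 <- infer_network(te, ir, group_label = "g")
  expect_identical(n1, n2)
  expect_equal(nrow(n1$edges), 1)
  expect_equal(n1$edges$edge_type, "TE-IR")
  expect_false(n1$thresholded)
  expect_warning(infer_network(te, ir, colnames(te)[1:10], min_samples = 20),
                 "smaller sample size")
})

test_that("median thresholding keeps about half the reference edges, inclusively", {
  net_a <- make_net(edge_df(paste0("A", 1:4), paste0("B", 1:4),
                            c(0.1, 0.2, 0.3, 0.4)), thresholded = FALSE)
  net_b <- make_net(edge_df(c("A1", "A2"), c("B2", "B3"), c(0.05, 0.9)),
                    thresholded = FALSE)
  thr <- threshold_pair(net_a, net_b)
  expect_equal(unname(thr$thresholds["TE-TE"]), 0.25)
  expect_equal(nrow(thr$net_a_thr$edges), 2)
  # the low-MI edge of net_b is gone, the high one kept
  expect_equal(nrow(thr$net_b_thr$edges), 1)
  expect_true(thr$net_a_thr$thresholded)
  # thresholded edges are a subset of the unthresholded ones
  expect_true(all(paste(thr$net_b_thr$edges$node_a, thr$net_b_thr$edges$node_b)
                  %in% paste(net_b$edges$node_a, net_b$edges$node_b)))
  # missing edge type in the reference network is an error
  net_c <- make_net(edge_df("G1", "G2-t1", 0.5), thresholded = FALSE)
  expect_error(threshold_pair(net_a, net_c), "TE-IR")
})

test_that("random-weight thresholding retains 45-55% of reference edges per type", {
  set.seed(16)
  for (rep in 1:5) {
    m <- sample(40:200, 1)
    net_a <- make_net(edge_df(paste0("L", seq_len(m)), paste0("R", seq_len(m)),
                              runif(m)), thresholded = FALSE)
    thr <- threshold_pair(net_a, net_a)
    frac <- nrow(thr$net_a_thr$edges) / m
    expect_gte(frac, 0.45)
    expect_lte(frac, 0.55)
  }
})

test_that("no thresholded network contains a same-gene edge end to end", {
  cfg <- tiny_config()
  tr <- build_ground_truth(cfg)
  sim <- simulate_counts(tr, cfg)
  g <- preprocess_counts(sim$gene_counts, sim$samples, c("batch", "sex"))
  tx <- preprocess_counts(sim$tx_counts, sim$samples, c("batch", "sex"))
  ir <- compute_isoform_ratios(tx, g, sim$feature_map)
  v <- apply(unclass(ir), 1, stats::var)
  ir <- ir[v > 1e-12, , drop = FALSE]
  suppressWarnings({
    net <- infer_network(g, ir, sim$samples$sample_id[sim$samples$group == "affected"])
  })
  gid <- structure(net$nodes$gene_id, names = net$nodes$node_id)
  expect_false(any(gid[net$edges$node_a] == gid[net$edges$node_b]))
})
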