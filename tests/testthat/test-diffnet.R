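test_that("hub identification uses an inclusive degree threshold", {
  star <- make_net(edge_df(rep("C", 10), paste0("L", 1:10)))
  hubs <- identify_hubs(star, k = 10)
  expect_true(hubs$is_hub[hubs$node_id == "C"])
  expect_equal(hubs$degree[hubs$node_id == "C"], 10)
  expect_false(any(hubs$is_hub[hubs$node_id != "C"]))
  empty <- make_net(extra_nodes = c("A", "B"))
  expect_equal(sum(identify_hubs(empty)$is_hub), 0)
  expect_error(identify_hubs(star, k = 0), "k must")
  # degrees {12, 10, 9, 3} -> 2 hubs
  e <- edge_df(c(rep("A", 12), rep("B", 10), rep("D", 3)),
               c(paste0("x", 1:12), paste0("y", 1:10), paste0("z", 1:3)))
  e2 <- rbind(e, edge_df(rep("E", 9), paste0("w", 1:9)))
  h <- identify_hubs(make_net(e2))
  expect_equal(sum(h$is_hub), 2)
})

test_that("common hubs are the node-id intersection", {
  ha <- data.frame(node_id = c("a", "b", "c"), is_hub = TRUE)
  hb <- data.frame(node_id = c("b", "c", "d"), is_hub = TRUE)
  expect_setequal(common_hubs(ha, hb), c("b", "c"))
  hb$is_hub <- FALSE
  expect_length(common_hubs(ha, hb), 0)
  expect_length(common_hubs(ha, ha), 3)
})

test_that("common-hub edge partition is disjoint, exhaustive and matches counts", {
  # A-thresholded star around hub H plus raw/thresholded B variants
  nodes <- c("H", paste0("n", 1:6))
  a_thr <- make_net(edge_df(rep("H", 4), paste0("n", 1:4)),
                    extra_nodes = nodes)
  a_raw <- make_net(edge_df(rep("H", 5), paste0("n", 1:5)),
                    extra_nodes = nodes, thresholded = FALSE)
  # n1: shared; n2: only raw in B (attenuated); n3, n4: absent in B (unique)
  b_thr <- make_net(edge_df(rep("H", 2), c("n1", "n6")), extra_nodes = nodes)
  b_raw <- make_net(edge_df(rep("H", 3), c("n1", "n2", "n6")),
                    extra_nodes = nodes, thresholded = FALSE)
  part <- partition_common_hub_edges(a_thr, b_thr, a_raw, b_raw, "H")
  expect_equal(nrow(part$unique_a), 2)
  expect_equal(nrow(part$shared), 1)
  expect_equal(nrow(part$attenuated_a), 1)
  # b-side: H~n6 unique (absent from a_raw), H~n1 shared
  expect_equal(nrow(part$unique_b), 1)
  expect_equal(nrow(part$attenuated_b), 0)
  # disjoint and exhaustive over a_thr's hub-incident edges
  all_keys <- c(paste(part$unique_a$node_a, part$unique_a$node_b),
                paste(part$shared$node_a, part$shared$node_b),
                paste(part$attenuated_a$node_a, part$attenuated_a$node_b))
  expect_equal(sort(all_keys), sort(paste(a_thr$edges$node_a, a_thr$edges$node_b)))
  expect_equal(anyDuplicated(all_keys), 0)
  # unique edges never appear in the other network's raw edge set
  expect_false(any(paste(part$unique_a$node_a, part$unique_a$node_b) %in%
                     paste(b_raw$edges$node_a, b_raw$edges$node_b)))
  expect_equal(part$summary$pct_unique[1], 100 * 2 / 4)
  expect_error(partition_common_hub_edges(a_thr, b_thr, a_raw, b_raw, "zz"),
               "missing")
})

test_that("identical thresholded networks share every common-hub edge", {
  net <- make_net(edge_df(rep("H", 11), paste0("n", 1:11)))
  raw <- make_net(edge_df(rep("H", 11), paste0("n", 1:11)), thresholded = FALSE)
  part <- partition_common_hub_edges(net, net, raw, raw, "H")
  expect_equal(nrow(part$unique_a), 0)
  expect_equal(nrow(part$unique_b), 0)
  expect_equal(nrow(part$shared), 11)
})

test_that("master hubs satisfy the degree and inclusive fold rules", {
  mk_star <- function(hub, n, extra = character(0), thr = TRUE)
    make_net(edge_df(rep(hub, n), paste0(hub, "x", seq_len(n))),
             extra_nodes = extra, thresholded = thr)
  # degree 24 vs 8 -> fold 3.0: master hub
  focal <- mk_star("H", 24)
  other <- make_net(edge_df(rep("H", 8), paste0("Hx", 1:8)),
                    extra_nodes = focal$nodes$node_id, thresholded = FALSE)
  mh <- master_hubs(focal, other)
  expect_equal(mh$node_id, "H")
  expect_equal(mh$fold, 3)
  expect_false(mh$boundary)
  # degree 12 vs 7 -> fold 1.71: excluded
  focal2 <- mk_star("H", 12)
  other2 <- make_net(edge_df(rep("H", 7), paste0("Hx", 1:7)),
                     extra_nodes = focal2$nodes$node_id, thresholded = FALSE)
  expect_equal(nrow(master_hubs(focal2, other2)), 0)
  # degree 34 vs 12 -> fold 2.83: master hub
  focal3 <- mk_star("H", 34)
  other3 <- make_net(edge_df(rep("H", 12), paste0("Hx", 1:12)),
                     extra_nodes = focal3$nodes$node_id, thresholded = FALSE)
  mh3 <- master_hubs(focal3, other3)
  expect_equal(mh3$degree_focal, 34)
  expect_equal(mh3$fold, 34 / 12, tolerance = 1e-12)
  # absent from the other network: infinite fold still qualifies
  other4 <- make_net(extra_nodes = focal$nodes$node_id, thresholded = FALSE)
  mh4 <- master_hubs(focal, other4)
  expect_equal(mh4$fold, Inf)
  expect_error(master_hubs(focal, other, min_fold = 0.5), "min_fold")
  expect_error(master_hubs(focal, mk_star("H", 8)), "unthresholded")
})

test_that("identical networks yield no master hubs at fold 2", {
  thr <- make_net(edge_df(rep("H", 15), paste0("n", 1:15)))
  raw <- make_net(edge_df(rep("H", 15), paste0("n", 1:15)), thresholded = FALSE)
  expect_equal(nrow(master_hubs(thr, raw)), 0)
})

test_that("master hubs are sorted by focal degree with deterministic ties", {
  e <- rbind(edge_df(rep("B", 12), paste0("x", 1:12)),
             edge_df(rep("A", 12), paste0("y", 1:12)),
             edge_df(rep("C", 14), paste0("z", 1:14)))
  focal <- make_net(e)
  other <- make_net(extra_nodes = focal$nodes$node_id, thresholded = FALSE)
  mh <- master_hubs(focal, other)
  expect_equal(mh$node_id, c("C", "A", "B"))
})

test_that("neighborhoods respect hop counts and seed inclusion", {
  path <- make_net(edge_df(c("a", "b"), c("b", "c")))
  expect_equal(neighborhood(path, "a", hops = 1), c("a", "b"))
  expect_equal(neighborhood(path, "a", hops = 2), c("a", "b", "c"))
  expect_equal(neighborhood(path, "a", hops = 1, include_seeds = FALSE), "b")
  iso <- make_net(edge_df("a", "b"), extra_nodes = "z")
  expect_equal(neighborhood(iso, "z", hops = 1), "z")
  expect_error(neighborhood(path, "a", hops = 3), "hops")
  expect_error(neighborhood(path, "missing", hops = 1), "not in the network")
})

test_that("modality subnetworks report overlap on the gene-pair level", {
  # TE-TE edge (G1, G2) overlaps IR-IR edge between transcripts of G1 and G2
  e <- edge_df(c("G1", "G1-t1", "G3", "G5-t1"),
               c("G2", "G2-t1", "G4", "G6-t1"))
  net <- make_net(e)
  ms <- modality_subnetworks(net, net)
  a <- ms$a
  expect_equal(a$n_te_te, 2)
  expect_equal(a$n_ir_ir, 2)
  expect_equal(a$unique_te_te, 1)   # (G3,G4) only
  expect_equal(a$unique_ir_ir, 1)   # (G5,G6) only
  expect_equal(a$pct_unique_te_te, 50)
  # a network with no IR-IR edges has 100% unique TE-TE
  net2 <- make_net(edge_df("G1", "G2"))
  ms2 <- modality_subnetworks(net2, net2)
  expect_equal(ms2$a$pct_unique_te_te, 100)
  expect_equal(unique_edge_percentage(5897, 5997 - 5897, 0, digits = 0), 98)
  # floor mode is available for truncating reports
  ms3 <- modality_subnetworks(net, net, percent_mode = "floor")
  expect_equal(ms3$a$pct_unique_te_te, 50)
})

test_that("hub modality composition tracks IR share across thresholds", {
  e <- rbind(edge_df(rep("G1", 12), paste0("a", 1:12)),
             edge_df(rep("G2-t1", 16), paste0("b", 1:16)),
             edge_df(rep("G3-t1", 21), paste0("c", 1:21)))
  net <- make_net(e)
  comp <- hub_modality_composition(net, thresholds = c(10, 15, 20))
  expect_equal(comp$n_te, c(1, 0, 0))
  expect_equal(comp$n_ir, c(2, 2, 1))
  expect_equal(comp$prop_ir, c(2 / 3, 1, 1))
  # IR proportion non-decreasing when the top-degree nodes are IR
  expect_true(all(diff(comp$prop_ir) >= 0))
  expect_error(hub_modality_composition(net, thresholds = integer(0)), "empty")
  all_te <- make_net(edge_df(rep("G1", 10), paste0("g", 1:10)))
  expect_equal(hub_modality_composition(all_te, 10)$prop_ir, 0)
})
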