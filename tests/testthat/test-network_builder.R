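test_that("typed networks enforce simple-graph invariants", {
  expect_error(typed_network(data.frame(id = "a", class = "protein"),
                             data.frame(from = "a", to = "a")), "self-loop")
  expect_error(typed_network(data.frame(id = "a", class = "protein"),
                             data.frame(from = "a", to = "b")), "endpoint")
  expect_error(typed_network(data.frame(id = c("a", "a"), class = "protein")),
               "duplicate")
  # duplicate unordered edges collapse
  net <- typed_network(data.frame(id = c("a", "b"), class = "protein"),
                       data.frame(from = c("a", "b"), to = c("b", "a")))
  expect_equal(n_edges(net), 1)
})

test_that("C-T construction is bipartite with restriction and isolate dropping", {
  map <- data.frame(compound_id = c("c1", "c1"), target = c("T1", "T2"))
  net <- build_ct_network(map)
  expect_equal(n_nodes(net), 3)
  expect_equal(n_edges(net), 2)
  # restriction to a disjoint target set empties the network
  expect_equal(n_nodes(build_ct_network(map, restrict_targets = "Z1")), 0)
  # compound losing all targets is dropped
  map2 <- rbind(map, data.frame(compound_id = "c2", target = "T9"))
  net2 <- build_ct_network(map2, restrict_targets = c("T1", "T2"))
  expect_false("c2" %in% net2$nodes$id)
  # bipartite identity: edges = sum of compound degrees = sum of target degrees
  d <- degree_centrality(net2)
  expect_equal(sum(d$dc[d$class == "compound"]), n_edges(net2))
  expect_equal(sum(d$dc[d$class == "target"]), n_edges(net2))
})

test_that("PPI construction applies the confidence cutoff and isolate policy", {
  edges <- data.frame(node_a = c("A", "B"), node_b = c("B", "C"),
                      score = c(0.71, 0.69))
  net <- build_ppi(edges, c("A", "B", "C"))
  expect_setequal(net$nodes$id, c("A", "B"))
  expect_equal(n_edges(net), 1)
  # keep_isolates retains the full member set
  net_iso <- build_ppi(edges, c("A", "B", "C"), keep_isolates = TRUE)
  expect_equal(n_nodes(net_iso), 3)
  # min_score = 0 keeps everything among members; 1.0 keeps nothing here
  expect_equal(n_edges(build_ppi(edges, c("A", "B", "C"), min_score = 0)), 2)
  expect_equal(n_edges(build_ppi(edges, c("A", "B", "C"), min_score = 1)), 0)
  # non-member endpoints are excluded
  expect_equal(n_edges(build_ppi(edges, c("A", "B"), min_score = 0)), 1)
})

test_that("PPI filtering composes: filter at 0 then s equals filter at s", {
  set.seed(11)
  for (rep in 1:10) {
    m <- sample(5:10, 1)
    members <- paste0("P", seq_len(m))
    pairs <- t(combn(members, 2))
    keep <- sample(nrow(pairs), sample(3:nrow(pairs), 1))
    edges <- data.frame(node_a = pairs[keep, 1], node_b = pairs[keep, 2],
                        score = runif(length(keep)))
    s <- runif(1)
    direct <- build_ppi(edges, members, min_score = s)
    loose <- build_ppi(edges, members, min_score = 0)
    refiltered <- build_ppi(edges[edges$node_a %in% loose$nodes$id &
                                    edges$node_b %in% loose$nodes$id, ],
                            loose$nodes$id, min_score = s)
    expect_equal(direct$edges, refiltered$edges)
  }
})

test_that("C-T-P construction is tripartite and prunes unannotated targets", {
  map <- data.frame(compound_id = c("c1", "c1", "c2"),
                    target = c("T1", "T2", "T2"))
  cot <- build_ct_network(map)
  coll <- structure(list(
    PW1 = list(name = "pw one", genes = c("T1")),
    PW2 = list(name = "pw two", genes = c("T9"))
  ), class = "gene_set_collection")
  # T1 in one selected pathway -> compound + target + pathway, 2 edges
  net <- build_ctp_network(cot, coll, "PW1")
  expect_equal(n_nodes(net), 3)
  expect_equal(n_edges(net), 2)
  expect_setequal(net$nodes$class, c("compound", "target", "pathway"))
  # T2 in no selected pathway: T2, c2 and their edges dropped
  expect_false(any(c("T2", "c2") %in% net$nodes$id))
  # never compound-pathway edges: every edge has exactly one target endpoint
  cls <- setNames(net$nodes$class, net$nodes$id)
  n_target_ends <- rowSums(cbind(cls[net$edges$from] == "target",
                                 cls[net$edges$to] == "target"))
  expect_true(all(n_target_ends == 1))
  # tripartite identity: edge count = sum of target degrees
  d <- degree_centrality(net)
  expect_equal(sum(d$dc[d$class == "target"]), n_edges(net))
  expect_error(build_ctp_network(cot, coll, "PW9"), "unknown pathway")
})

test_that("simulated C-T-P networks keep the tripartite edge identity", {
  cfg <- sim_config(seed = 3, n_drug_targets = 40, n_disease_targets = 60,
                    n_overlap = 30, n_pathways = 10,
                    pathway_size_range = c(5, 15),
                    degree_spec = c(20, 12, 10, 8, 6, 5, 4, 3, 2, 2, 2))
  uni <- simulate_target_universe(cfg)
  overlap <- intersect_targets(uni$drug, uni$disease)
  cot <- suppressWarnings(build_ct_network(uni$map, overlap))
  gmt <- simulate_gene_sets(cfg, unique(c(uni$drug, uni$disease)), overlap)
  net <- build_ctp_network(cot, gmt, names(gmt)[1:5])
  d <- degree_centrality(net)
  expect_equal(sum(d$dc[d$class == "target"]), n_edges(net))
  expect_equal(sum(d$dc[d$class == "compound"]) + sum(d$dc[d$class == "pathway"]),
               n_edges(net))
})
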