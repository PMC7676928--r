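test_that("degree centrality counts incident edges", {
  star <- typed_network(data.frame(id = c("hub", paste0("l", 1:4)), class = "protein"),
                        data.frame(from = "hub", to = paste0("l", 1:4)))
  d <- degree_centrality(star)
  expect_equal(d$dc[d$node_id == "hub"], 4L)
  expect_true(all(d$dc[d$node_id != "hub"] == 1L))
  iso <- typed_network(data.frame(id = c("a", "b", "c"), class = "protein"),
                       data.frame(from = "a", to = "b"))
  expect_equal(degree_centrality(iso)$dc[3], 0L)
})

test_that("betweenness matches hand-computable cases and normalization", {
  path3 <- typed_network(data.frame(id = c("A", "B", "C"), class = "protein"),
                         data.frame(from = c("A", "B"), to = c("B", "C")))
  bc <- betweenness_centrality(path3)
  expect_equal(bc$bc[bc$node_id == "B"], 1.0)
  expect_equal(betweenness_centrality(path3, normalized = FALSE)$bc[
    bc$node_id == "B"], 1.0)
  star <- typed_network(data.frame(id = c("hub", paste0("l", 1:4)), class = "protein"),
                        data.frame(from = "hub", to = paste0("l", 1:4)))
  b <- betweenness_centrality(star)
  expect_equal(b$bc[b$node_id == "hub"], 1.0)
  expect_true(all(b$bc[b$node_id != "hub"] == 0))
  # n < 3: normalized BC defined as 0
  duo <- typed_network(data.frame(id = c("a", "b"), class = "protein"),
                       data.frame(from = "a", to = "b"))
  expect_equal(betweenness_centrality(duo)$bc, c(0, 0))
})

test_that("Brandes agrees with the brute-force path-enumeration oracle", {
  set.seed(2024)
  for (i in 1:40) {
    n <- sample(3:8, 1)
    g <- random_graph(n, runif(1, 0.2, 0.8))
    mine <- betweenness_centrality(g$net, normalized = FALSE)
    oracle <- bf_betweenness(g$adj)
    expect_equal(mine$bc[match(g$ids, mine$node_id)], oracle, tolerance = 1e-12)
    # and with igraph as a second, independent implementation
    ig <- as_igraph(g$net)
    ref <- igraph::betweenness(ig, directed = FALSE)
    expect_equal(mine$bc[match(names(ref), mine$node_id)], unname(ref),
                 tolerance = 1e-10)
  }
})

test_that("betweenness total is conserved under node relabeling", {
  set.seed(77)
  g <- random_graph(8, 0.5)
  raw <- betweenness_centrality(g$net, normalized = FALSE)
  perm <- sample(g$ids)
  relab <- setNames(perm, g$ids)
  net2 <- typed_network(
    data.frame(id = relab[g$net$nodes$id], class = g$net$nodes$class),
    data.frame(from = relab[g$net$edges$from], to = relab[g$net$edges$to])
  )
  raw2 <- betweenness_centrality(net2, normalized = FALSE)
  expect_equal(sum(raw$bc), sum(raw2$bc), tolerance = 1e-12)
  expect_equal(raw2$bc[match(relab[raw$node_id], raw2$node_id)], raw$bc,
               tolerance = 1e-12)
})

test_that("class summaries compute medians and means per class", {
  tab <- data.frame(node_id = c("a", "b", "c", "d"),
                    class = c("target", "target", "target", "compound"),
                    dc = c(1, 2, 3, 10), bc = c(0.1, 0.2, 0.3, 0.5))
  s <- class_summary(tab, "median")
  expect_equal(s$dc_stat[s$class == "target"], 2)
  s2 <- class_summary(tab, "mean")
  expect_equal(s2$dc_stat[s2$class == "target"], 2)
  # even-count median = midpoint of central order statistics
  tab2 <- rbind(tab, data.frame(node_id = "e", class = "target", dc = 8, bc = 0.4))
  expect_equal(class_summary(tab2, "median")$dc_stat[2], 2.5)
  expect_error(class_summary(tab, classes = c("target", "pathway")),
               "pathway")
  expect_error(class_summary(tab[0, ]), "empty")
})

test_that("select_nodes matches an exhaustive row filter under every rule", {
  set.seed(31)
  for (i in 1:15) {
    tab <- data.frame(
      node_id = sprintf("n%02d", 1:12),
      class = sample(c("target", "compound"), 12, replace = TRUE),
      dc = sample(0:20, 12, replace = TRUE),
      bc = round(runif(12), 4)
    )
    if (length(unique(tab$class)) < 2) tab$class[1] <- "compound"
    for (comb in c("AND", "OR", "DC_ONLY")) {
      for (stat in c("median", "mean")) {
        for (strict in c(TRUE, FALSE)) {
          mult <- sample(c(1, 1.5, 2), 1)
          got <- select_nodes(tab, selection_rule(stat, mult, comb, strict))
          want <- bf_select(tab, stat, mult, comb, strict)
          expect_setequal(as.character(got), want)
        }
      }
    }
  }
})

test_that("selection output is ordered and monotone in the multiplier", {
  tab <- data.frame(node_id = c("x", "y", "z", "w"), class = "target",
                    dc = c(5, 9, 9, 2), bc = c(0.3, 0.1, 0.4, 0.05))
  sel <- select_nodes(tab, selection_rule("median", 0.5, "OR"))
  expect_equal(as.character(sel), c("z", "y", "x", "w")[seq_along(sel)])
  # identical values + strict mean rule: nothing strictly exceeds the mean
  flat <- data.frame(node_id = letters[1:4], class = "target", dc = 3, bc = 0.2)
  expect_length(select_nodes(flat, selection_rule("mean", 1, "AND")), 0)
  # raising the multiplier never adds a node
  set.seed(8)
  tab2 <- data.frame(node_id = sprintf("n%02d", 1:15), class = "protein",
                     dc = sample(0:30, 15), bc = runif(15))
  prev <- NULL
  for (mult in c(0.5, 1, 1.5, 2, 3)) {
    cur <- as.character(select_nodes(tab2, selection_rule("median", mult, "AND")))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("hub selection on a synthetic PPI reports thresholds", {
  cfg <- sim_config(seed = 9, n_drug_targets = 40, n_disease_targets = 50,
                    n_overlap = 30, ppi_edge_count = 120, ppi_frac_high = 1,
                    degree_spec = c(20, 12, 10, 8, 6, 5, 4, 3, 2, 2, 2))
  ppi <- build_ppi(simulate_ppi(cfg, sprintf("G%06d", 1:30)),
                   sprintf("G%06d", 1:30))
  tab <- centrality_table(ppi)
  hubs <- select_nodes(tab, selection_rule("median", 2, "AND"))
  thr <- attr(hubs, "thresholds")
  expect_equal(thr$dc_stat, median(tab$dc))
  expect_true(all(tab$dc[match(hubs, tab$node_id)] > 2 * thr$dc_stat))
})
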