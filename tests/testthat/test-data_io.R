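test_that("symbol normalization unifies case, hyphens, Greek letters and aliases", {
  expect_equal(normalize_symbol(c(" tp53 ", "TP53")), c("TP53", "TP53"))
  expect_equal(normalize_symbol("IL-6"), "IL6")
  expect_equal(normalize_symbol("IL-1β"), "IL1B")
  expect_equal(normalize_symbol("TNF-α"), "TNF")     # alias TNFA -> TNF
  expect_equal(normalize_symbol("COX-2"), "PTGS2")
  expect_equal(normalize_symbol("BRCA1", aliases = NULL), "BRCA1")
})

test_that("compound tables are read with validation", {
  f <- write_lines_tmp(c("compound_id\tname\tob\tdl",
                         "MOL000098\tQuercetin\t46.43\t0.28",
                         "MOL000006\tLuteolin\t36.16\t0.25"))
  df <- read_compound_table(f)
  expect_equal(df$ob, c(46.43, 36.16))
  expect_equal(df$dl[1], 0.28)

  # header only -> empty table
  f2 <- write_lines_tmp("compound_id\tname\tob\tdl")
  expect_equal(nrow(read_compound_table(f2)), 0)

  # malformed dl reported with its file line
  f3 <- write_lines_tmp(c("# a comment", "compound_id\tname\tob\tdl",
                          "M1\tx\t50\t0.3", "M2\ty\t40\tabc"))
  expect_error(read_compound_table(f3), "line 4.*dl")

  # missing column named in the error
  f4 <- write_lines_tmp(c("compound_id\tname\tob", "M1\tx\t50"))
  expect_error(read_compound_table(f4), "dl")

  # duplicate ids rejected
  f5 <- write_lines_tmp(c("compound_id\tname\tob\tdl",
                          "M1\tx\t50\t0.3", "M1\ty\t40\t0.2"))
  expect_error(read_compound_table(f5), "duplicate")
})

test_that("gene lists deduplicate after normalization", {
  f <- write_lines_tmp(c("tp53", "TP53", "", "IL-6"), ext = ".txt")
  expect_equal(read_gene_list(f), c("IL6", "TP53"))
  f2 <- write_lines_tmp(character(0), ext = ".txt")
  expect_equal(read_gene_list(f2), character(0))
  f3 <- write_lines_tmp(c("gene\tscore", "IL6\t1", "TNF\t2", "PTGS2\t3"))
  expect_equal(read_gene_list(f3, column = "gene"), c("IL6", "PTGS2", "TNF"))
  expect_error(read_gene_list(tempfile()), "no such file")
})

test_that("scored edges are rescaled, deduplicated and loop-free", {
  f <- write_lines_tmp(c("node_a\tnode_b\tscore",
                         "TP53\tMDM2\t905",
                         "TP53\tTP53\t900",
                         "EGFR\tEGF\t710",
                         "EGF\tEGFR\t680"))
  expect_message(e <- read_scored_edges(f, "thousand"), "1 self-loop")
  expect_equal(nrow(e), 2)
  expect_equal(e$score[e$node_a == "MDM2"], 0.905)
  # duplicate unordered pair keeps the max
  expect_equal(e$score[e$node_a == "EGF"], 0.71)
  # out-of-scale score rejected
  f2 <- write_lines_tmp(c("node_a\tnode_b\tscore", "A\tB\t1.2"))
  expect_error(read_scored_edges(f2, "unit"), "score")
})

test_that("reading scored edges is idempotent through write/read", {
  f <- write_lines_tmp(c("node_a\tnode_b\tscore", "A\tB\t0.9", "B\tC\t0.4",
                         "A\tC\t0.75", "C\tA\t0.6"))
  e1 <- read_scored_edges(f, "unit")
  f2 <- tempfile(fileext = ".tsv")
  write_scored_edges(e1, f2)
  e2 <- read_scored_edges(f2, "unit")
  expect_equal(e1, e2)
})

test_that("GMT collections parse, normalize and enforce unique non-empty sets", {
  f <- write_lines_tmp(c("hsa04151\tPI3K-Akt signaling pathway\tAKT1\tPIK3CG",
                         "hsa04668\tTNF signaling pathway\ttnf\tTNF\tIL-6"),
                       ext = ".gmt")
  g <- read_gmt(f)
  expect_s3_class(g, "gene_set_collection")
  expect_equal(length(g[["hsa04151"]]$genes), 2)
  expect_equal(sort(g[["hsa04668"]]$genes), c("IL6", "TNF"))  # dedup + normalize
  f2 <- write_lines_tmp(c("t1\tdesc\tA", "t2\tdesc"), ext = ".gmt")
  expect_error(read_gmt(f2), "line 2")
  f3 <- write_lines_tmp(c("t1\tdesc\tA", "t1\tdesc\tB"), ext = ".gmt")
  expect_error(read_gmt(f3), "duplicate term id")
})

test_that("network writes round-trip across formats", {
  net <- tiny_cot()
  ct <- centrality_table(net)
  net$nodes$dc <- ct$dc[match(net$nodes$id, ct$node_id)]
  net$nodes$bc <- ct$bc[match(net$nodes$id, ct$node_id)]

  # GraphML: full fidelity (classes + numeric attributes)
  f <- tempfile(fileext = ".graphml")
  write_network(net, f, "graphml")
  back <- read_network(f, "graphml")
  expect_setequal(back$nodes$id, net$nodes$id)
  expect_equal(back$nodes$class[match(net$nodes$id, back$nodes$id)],
               net$nodes$class)
  expect_equal(signif(back$nodes$bc[match(net$nodes$id, back$nodes$id)], 6),
               signif(net$nodes$bc, 6))
  expect_equal(back$edges, net$edges)

  # edge-TSV: classes preserved
  f2 <- tempfile(fileext = ".tsv")
  write_network(net, f2, "tsv")
  back2 <- read_network(f2, "tsv")
  expect_equal(back2$edges, net$edges)
  expect_equal(back2$nodes$class[match(net$nodes$id, back2$nodes$id)],
               net$nodes$class)

  # SIF: 3-node path -> 2 interaction lines; structure round-trips
  path3 <- typed_network(data.frame(id = c("A", "B", "C"), class = "protein"),
                         data.frame(from = c("A", "B"), to = c("B", "C")))
  f3 <- tempfile(fileext = ".sif")
  write_network(path3, f3, "sif")
  expect_length(readLines(f3), 2)
  expect_equal(read_network(f3, "sif")$edges, path3$edges)

  # empty network -> valid zero-edge file
  empty <- typed_network(data.frame(id = character(0), class = character(0)))
  f4 <- tempfile(fileext = ".sif")
  write_network(empty, f4, "sif")
  expect_equal(n_edges(read_network(f4, "sif")), 0)

  expect_error(write_network(net, tempfile(), "xyz"), "supported")
})
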