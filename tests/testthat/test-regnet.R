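fixture_net <- function() regulatory_network(example_regulatory_edges())

test_that("merging edge sets unions edges and keeps provenance", {
  e1 <- data.frame(source = c("L1", "L1", "T1"),
                   target = c("T1", "G1", "G2"),
                   source_class = c("lncRNA", "lncRNA", "TF"),
                   target_class = c("TF", "coding", "coding"),
                   provenance = "curated", stringsAsFactors = FALSE)
  e2 <- data.frame(source = c("L2", "T2", "T1"),
                   target = c("T2", "G3", "G4"),
                   source_class = c("lncRNA", "TF", "TF"),
                   target_class = c("TF", "coding", "coding"),
                   provenance = "ChIP", stringsAsFactors = FALSE)
  g <- merge_networks(list(e1, e2))
  expect_equal(igraph::ecount(g), 6L)
  # identical edge in both sets collapses, carrying both tags
  e3 <- e1[1, ]; e3$provenance <- "text-mined"
  g2 <- merge_networks(list(e1, e3))
  expect_equal(igraph::ecount(g2), 3L)
  eid <- igraph::get_edge_ids(g2, c("L1", "T1"))
  expect_equal(igraph::E(g2)$provenance[eid], "curated,text-mined")
  # class conflict is an error
  e4 <- e1; e4$source_class[1] <- "TF"
  expect_error(merge_networks(list(e1, e4)), "conflicting node class")
  # self-loops rejected
  e5 <- e1; e5$target[1] <- "L1"; e5$target_class[1] <- "lncRNA"
  expect_error(regulatory_network(e5), "self-loops")
})

test_that("worked-example out-degrees match the published table", {
  net <- fixture_net()
  od <- out_degree(net)
  expect_equal(unname(od["MALAT1"]), 8L)
  expect_equal(unname(od["EGR1"]), 4L)
  expect_equal(unname(od["YBX1"]), 4L)
  expect_equal(unname(od["HOTAIR"]), 3L)
  # coding driver genes are sinks
  expect_true(all(od[c("FN1", "CD44", "TIMP1", "SNAI2", "SPARC")] == 0L))
  # sum of out-degrees equals the edge count
  expect_equal(sum(od), igraph::ecount(net))
})

test_that("betweenness matches brute force and igraph on random digraphs", {
  # canonical cases
  path <- regulatory_network(data.frame(
    source = c("a", "b"), target = c("b", "c"),
    source_class = c("lncRNA", "TF"), target_class = c("TF", "coding")))
  expect_equal(unname(betweenness_centrality(path)),
               c(0, 0.5, 0))
  star <- regulatory_network(data.frame(
    source = "hub", target = c("x", "y", "z"),
    source_class = "lncRNA", target_class = "coding"))
  expect_true(all(betweenness_centrality(star) == 0))
  set.seed(41)
  for (i in 1:20) {
    n <- sample(3:6, 1)
    adj <- random_digraph(n)
    g <- digraph_to_igraph(adj)
    mine <- betweenness_centrality(g)
    expect_equal(unname(mine), brute_betweenness(adj), tolerance = 1e-12)
    ig <- igraph::betweenness(g, directed = TRUE) / ((n - 1) * (n - 2))
    expect_equal(unname(mine), unname(ig), tolerance = 1e-12)
  }
})

test_that("regulator ranking is by out-degree, betweenness, then name", {
  net <- fixture_net()
  lnc <- rank_regulators(net, "lncRNA")
  expect_equal(lnc$node[1], "MALAT1")
  expect_true("HOTAIR" %in% head(lnc$node, 3))
  tf <- rank_regulators(net, "TF")
  # EGR1 and YBX1 tie on out-degree 4; EGR1 wins on betweenness
  expect_equal(tf$node[1], "EGR1")
  # all-equal degrees fall back to lexicographic order
  eq <- regulatory_network(data.frame(
    source = c("b_lnc", "a_lnc"), target = c("g1", "g2"),
    source_class = "lncRNA", target_class = "coding"))
  expect_equal(rank_regulators(eq, "lncRNA")$node, c("a_lnc", "b_lnc"))
  expect_error(rank_regulators(net, "nonexistent"), "no nodes")
})

test_that("two-hop indirect targets are certified by explicit paths", {
  net <- fixture_net()
  ind <- two_hop_indirect_targets(net, "MALAT1")
  expect_setequal(ind$target, c("FN1", "CD44", "TIMP1"))
  expect_true(all(ind$via == "EGR1"))
  # every reported pair has its certifying 2-edge path
  for (i in seq_len(nrow(ind))) {
    expect_true(igraph::are_adjacent(net, "MALAT1", ind$via[i]))
    expect_true(igraph::are_adjacent(net, ind$via[i], ind$target[i]))
  }
  # SLNCR's only TF target (TF_F) has no coding out-edges
  expect_equal(nrow(two_hop_indirect_targets(net, "SLNCR")), 0L)
  # a node with no out-edges at all yields nothing
  expect_equal(nrow(two_hop_indirect_targets(net, "FN1")), 0L)
  expect_error(two_hop_indirect_targets(net, "ghost"), "not in network")
})

test_that("a diamond reports one row per distinct mediator", {
  dia <- regulatory_network(data.frame(
    source = c("L", "L", "T1", "T2"),
    target = c("T1", "T2", "G", "G"),
    source_class = c("lncRNA", "lncRNA", "TF", "TF"),
    target_class = c("TF", "TF", "coding", "coding")))
  ind <- two_hop_indirect_targets(dia, "L")
  expect_equal(nrow(ind), 2L)
  expect_setequal(ind$via, c("T1", "T2"))
  expect_true(all(ind$target == "G"))
})

test_that("mutual edges are reciprocal pairs only", {
  net <- fixture_net()
  mut <- find_mutual_edges(net)
  expect_equal(nrow(mut), 1L)
  expect_equal(sort(unlist(mut[1, ], use.names = FALSE)),
               c("EGR1", "MALAT1"))
  # a pure DAG has none
  dag <- regulatory_network(data.frame(
    source = c("a", "a", "b"), target = c("b", "c", "c"),
    source_class = c("lncRNA", "lncRNA", "TF"),
    target_class = c("TF", "coding", "coding")))
  expect_equal(nrow(find_mutual_edges(dag)), 0L)
  # a directed 3-cycle has no mutual pair
  cyc <- igraph::graph_from_literal(a -+ b, b -+ c, c -+ a)
  expect_equal(nrow(find_mutual_edges(cyc)), 0L)
})

test_that("cis/trans calls follow chromosome co-location", {
  annot <- example_transcript_annotation()
  expect_equal(classify_cis_trans("MALAT1", "CD44", annot), "cis")
  for (g in c("FN1", "TIMP1", "SNAI2", "SPARC"))
    expect_equal(classify_cis_trans("MALAT1", g, annot), "trans")
  # symmetric in its arguments
  expect_equal(classify_cis_trans("CD44", "MALAT1", annot), "cis")
  expect_equal(classify_cis_trans("FN1", "MALAT1", annot), "trans")
  # a gene is cis to itself
  expect_equal(classify_cis_trans("FN1", "FN1", annot), "cis")
  expect_error(classify_cis_trans("MALAT1", "ghost", annot),
               "not annotated")
})

test_that("interaction sites map to transcript regions by midpoint", {
  annot <- example_transcript_annotation()
  # FN1 5'UTR is 1-250
  expect_equal(annotate_interaction_region(10, 20, "FN1", annot)$region,
               "5'UTR")
  # site spanning a boundary: midpoint decides
  a <- data.frame(gene = "toy", chrom = "chr1", utr5_start = 1L,
                  utr5_end = 50L, cds_start = 51L, cds_end = 250L,
                  utr3_start = 251L, utr3_end = 300L,
                  stringsAsFactors = FALSE)
  r <- annotate_interaction_region(45, 60, "toy", a)
  expect_equal(r$region, "CDS")  # midpoint floor((45+60)/2) = 52
  expect_equal(sum(r$overlap_fractions), 1)
  expect_gt(r$overlap_fractions[["5'UTR"]], 0)
  # a site that is exactly the whole 3'UTR
  expect_equal(annotate_interaction_region(251, 300, "toy", a)$region,
               "3'UTR")
  expect_error(annotate_interaction_region(290, 310, "toy", a),
               "outside")
  expect_error(annotate_interaction_region(20, 10, "toy", a), "start")
})

test_that("the axis report reproduces the worked example end to end", {
  net <- fixture_net()
  rep <- build_axis_report(net, annot = example_transcript_annotation(),
                           sites = example_interaction_sites())
  expect_equal(rep$regulator, "MALAT1")
  expect_setequal(rep$direct_targets$coding, c("SPARC", "SNAI2"))
  expect_true("EGR1" %in% rep$direct_targets$TF)
  expect_setequal(rep$indirect_targets$target, c("FN1", "CD44", "TIMP1"))
  expect_equal(rep$mutual_partners, "EGR1")
  cis <- names(rep$cis_trans)[rep$cis_trans == "cis"]
  expect_equal(cis, "CD44")
  regions <- setNames(rep$interaction_regions$region,
                      rep$interaction_regions$target)
  expect_equal(unname(regions[c("FN1", "TIMP1", "SNAI2", "CD44", "SPARC")]),
               c("5'UTR", "CDS", "CDS", "3'UTR", "3'UTR"))
  out <- capture.output(print(rep))
  expect_true(any(grepl("MALAT1", out)))
})

test_that("planted synthetic networks nominate the planted regulator", {
  s <- simulate_regulatory_network(sim_config(rng_seed = 42))
  rep <- build_axis_report(s$network)
  expect_equal(rep$regulator, s$planted_regulator)
  expect_setequal(rep$mutual_partners, s$feedback_pair[1])
  # an empty network yields an explicit no-regulator report
  empty <- igraph::make_empty_graph(directed = TRUE)
  rep0 <- build_axis_report(empty)
  expect_true(rep0$no_regulator)
  out <- capture.output(print(rep0))
  expect_true(any(grepl("no regulator", out)))
})
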