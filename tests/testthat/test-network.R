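test_that("co-expression edges follow the similarity threshold", {
  set.seed(31)
  m <- matrix(rnorm(10 * 6, mean = 5), 10, 6,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:6)))
  m[2, ] <- 2 * m[1, ]            # duplicated direction: cosine exactly 1
  g <- build_coexpression_network(m, tau = 0.999999)
  expect_true(igraph::are_adjacent(g, "g01", "g02"))
  w <- igraph::E(g)$weight[igraph::get_edge_ids(g, c("g01", "g02"))]
  expect_equal(w, 1.0, tolerance = 1e-12)
  expect_error(build_coexpression_network(m[, 1:2]), "3 samples")
  expect_error(build_coexpression_network(m, tau = 0), "tau")
})

test_that("a planted co-regulated block is recovered as a component", {
  set.seed(32)
  n_s <- 20
  latent <- rnorm(n_s)
  block <- t(sapply(1:6, function(i) 5 + latent + rnorm(n_s, sd = 0.2)))
  bg <- matrix(rnorm(8 * n_s, mean = 5), 8, n_s)
  m <- rbind(block, bg)
  rownames(m) <- c(sprintf("blk%d", 1:6), sprintf("bg%d", 1:8))
  # mean-center so similarity reflects co-variation, not the shared baseline
  g <- build_coexpression_network(m - rowMeans(m), tau = 0.8)
  comp <- igraph::components(g)$membership
  expect_equal(length(unique(comp[sprintf("blk%d", 1:6)])), 1L)
  # no background gene joins the block component
  expect_false(any(comp[sprintf("bg%d", 1:8)] == comp[["blk1"]]))
})

test_that("pearson mode excludes constant rows with a warning", {
  m <- matrix(rnorm(5 * 6), 5, 6,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  m[3, ] <- 7
  expect_warning(g <- build_coexpression_network(m, tau = 0.5,
                                                 method = "pearson"),
                 "constant")
  expect_false("g3" %in% igraph::V(g)$name)
})

test_that("edge-list import applies the strict confidence cut", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t0.3", "a\tc\t0.4", "b\tc\t0.41"), path)
  g <- import_edge_list(path, min_confidence = 0.400)
  expect_equal(igraph::ecount(g), 1L)
  expect_true(igraph::are_adjacent(g, "b", "c"))
  # empty file gives an empty network
  empty <- tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_equal(igraph::ecount(import_edge_list(empty)), 0L)
  # duplicate undirected edge collapses to one, keeping max confidence
  dup <- tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t0.5", "b\ta\t0.9"), dup)
  gd <- import_edge_list(dup, min_confidence = 0.400)
  expect_equal(igraph::ecount(gd), 1L)
  expect_equal(igraph::E(gd)$confidence, 0.9)
  # malformed line reported with its number
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t0.5", "a\tc\toops"), bad)
  expect_error(import_edge_list(bad), "line 2")
  # header row tolerated
  hdr <- tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\tconfidence", "a\tb\t0.7"), hdr)
  expect_equal(igraph::ecount(import_edge_list(hdr)), 1L)
})

test_that("SIF import carries no scores and obeys the unscored rule", {
  path <- tempfile(fileext = ".sif")
  writeLines(c("a\tpp\tb", "b\tpp\tc"), path)
  g <- import_edge_list(path, min_confidence = NULL)
  expect_equal(igraph::ecount(g), 2L)
  # unscored edges are dropped when a confidence cut is requested
  g2 <- import_edge_list(path, min_confidence = 0.400)
  expect_equal(igraph::ecount(g2), 0L)
  bad <- tempfile(fileext = ".sif")
  writeLines("a\tb", bad)
  expect_error(import_edge_list(bad), "SIF line 1")
})

test_that("node degrees match a brute-force incidence count", {
  tri <- igraph::make_ring(3)
  igraph::V(tri)$name <- c("x", "y", "z")
  expect_true(all(node_degrees(tri) == 2))
  star <- igraph::make_star(7, mode = "undirected")
  igraph::V(star)$name <- paste0("n", 1:7)
  d <- node_degrees(star)
  expect_equal(unname(d["n1"]), 6L)
  expect_true(all(d[-1] == 1L))
  set.seed(33)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    g <- igraph::sample_gnp(n, 0.3)
    igraph::V(g)$name <- paste0("v", seq_len(n))
    el <- igraph::as_edgelist(g)
    brute <- vapply(igraph::V(g)$name,
                    function(v) sum(el[, 1] == v) + sum(el[, 2] == v),
                    numeric(1))
    expect_equal(node_degrees(g), setNames(as.integer(brute), names(brute)))
    # handshake lemma
    expect_equal(sum(node_degrees(g)), 2L * igraph::ecount(g))
  }
})

test_that("hub selection by threshold and by top fraction", {
  # degree-sequence fixture shaped like a published hub table row:
  # 34 high-degree nodes (a clique, degree >= 33) among 152 total
  cl <- igraph::make_full_graph(34)
  rest <- igraph::make_ring(118)
  g <- igraph::disjoint_union(cl, rest)
  igraph::V(g)$name <- sprintf("n%03d", 1:152)
  hubs <- select_hubs(g, min_degree = 30)
  expect_equal(length(hubs$hubs), 34L)
  expect_gte(hubs$lowest_degree, 30)
  expect_equal(igraph::vcount(g), 152)
  # min_degree = 0 selects every node
  expect_equal(length(select_hubs(g, min_degree = 0)$hubs), 152L)
  # top fraction includes ties at the cut
  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- paste0("n", 1:5)
  top <- select_hubs(star, top_fraction = 0.4)
  expect_equal(top$hubs[1], "n1")
  expect_equal(length(top$hubs), 5L)  # leaves tie at degree 1
  expect_error(select_hubs(g, top_fraction = 1.5), "top_fraction")
  expect_error(select_hubs(g), "exactly one")
  expect_error(select_hubs(g, min_degree = 1, top_fraction = 0.5),
               "exactly one")
})

test_that("community detection separates disjoint dense modules", {
  t1 <- igraph::make_full_graph(3)
  t2 <- igraph::make_full_graph(3)
  g <- igraph::disjoint_union(t1, t2)
  igraph::V(g)$name <- paste0("v", 1:6)
  part <- detect_communities(g)
  expect_equal(part$n_communities, 2L)
  expect_equal(part$membership[["v1"]], part$membership[["v2"]])
  expect_false(part$membership[["v1"]] == part$membership[["v4"]])
  # a single clique is one community
  clique <- igraph::make_full_graph(5)
  igraph::V(clique)$name <- paste0("c", 1:5)
  expect_equal(detect_communities(clique)$n_communities, 1L)
  # modularity of the returned partition is >= 0 (the trivial partition)
  expect_gte(part$modularity, 0)
  # partition covers all nodes
  expect_setequal(names(part$membership), igraph::V(g)$name)
})

test_that("community labels are stable under node permutation", {
  set.seed(34)
  pb <- planted_two_block(10, 0.9, 0.05)
  part1 <- detect_communities(pb$graph)
  perm <- sample(igraph::vcount(pb$graph))
  g2 <- igraph::permute(pb$graph, perm)
  part2 <- detect_communities(g2)
  m1 <- part1$membership[sort(names(part1$membership))]
  m2 <- part2$membership[sort(names(part2$membership))]
  # same partition up to label renaming
  expect_equal(length(unique(paste(m1, m2))), length(unique(m1)))
  expect_equal(part1$modularity, part2$modularity, tolerance = 1e-12)
})

test_that("hub intersection per cluster, with NA for empty clusters", {
  coexp <- c("FN1", "CD44", "X")
  ppi <- list(cluster1 = c("Q", "R"),
              cluster2 = c("FN1", "CD44", "Y"),
              cluster3 = c("FN1", "CD44"))
  r <- intersect_hubs(coexp, ppi)
  expect_true(is.na(r$cluster1))
  expect_equal(r$cluster2, c("CD44", "FN1"))
  # PPI hubs that are a subset of the co-expression hubs come back unchanged
  expect_setequal(r$cluster3, ppi$cluster3)
  # intersection is contained in both inputs
  expect_true(all(r$cluster2 %in% coexp))
  expect_true(all(r$cluster2 %in% ppi$cluster2))
})

test_that("common hubs across drugs reproduce the published counts", {
  r <- common_across_drugs(example_common_hub_sets())
  lookup <- function(g) r$n_drugs[r$gene == g]
  expect_equal(lookup("FN1"), 4L)
  expect_equal(lookup("CD44"), 4L)
  expect_equal(lookup("TIMP1"), 3L)
  expect_equal(lookup("SPARC"), 2L)
  expect_equal(lookup("SNAI2"), 2L)
  expect_equal(lookup("TYR"), 1L)
  expect_error(common_across_drugs(list(a = "X")), "two drugs")
})
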