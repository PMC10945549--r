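# Reference-network loading, bounded minimum-weight path extraction and
# weight-threshold pruning.

test_that("edge lists load with collapsing, validation and line numbers", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t0.5", "B\tC\t0.2", "A\tC\t1.5"), f)
  net <- load_reference_network(f)
  expect_equal(igraph::vcount(net), 3)
  expect_equal(igraph::ecount(net), 3)
  # duplicate edge collapses to the minimum weight
  writeLines(c("A\tB\t0.5", "B\tA\t0.2"), f)
  net2 <- load_reference_network(f)
  expect_equal(igraph::ecount(net2), 1)
  expect_equal(igraph::E(net2)$weight, 0.2)
  # non-positive weight is a parse error naming the line
  writeLines(c("A\tB\t0.5", "B\tC\t-1"), f)
  expect_error(load_reference_network(f), "line 2")
  # self loops are dropped with a warning
  writeLines(c("A\tA\t0.5", "A\tB\t0.3"), f)
  expect_warning(net3 <- load_reference_network(f), "self-loop")
  expect_equal(igraph::ecount(net3), 1)
  # SIF format with a weight column, plus a header row in TSV
  fs <- tempfile(fileext = ".sif")
  writeLines(c("A pp B 0.4", "B pp C 0.9"), fs)
  nets <- load_reference_network(fs)
  expect_equal(sort(igraph::E(nets)$weight), c(0.4, 0.9))
  writeLines(c("node1\tnode2\tweight", "A\tB\t0.7"), f)
  neth <- load_reference_network(f)
  expect_equal(igraph::ecount(neth), 1)
  # confidence scores can be inverted to the weight convention
  writeLines(c("A\tB\t2", "B\tC\t4"), f)
  neti <- load_reference_network(f, invert_confidence = TRUE)
  expect_equal(sort(igraph::E(neti)$weight), c(0.25, 0.5))
})

test_that("edge lists round-trip through write_edge_list", {
  edges <- rand_graph(12, 20, seed = 801)
  f <- write_edges_tsv(edges, tempfile(fileext = ".tsv"))
  net <- load_reference_network(f)
  f2 <- tempfile(fileext = ".tsv")
  write_edge_list(net, f2)
  net2 <- load_reference_network(f2)
  expect_setequal(igraph::V(net2)$name, igraph::V(net)$name)
  key <- function(g) {
    el <- igraph::as_data_frame(g, "edges")
    sort(paste(pmin(el$from, el$to), pmax(el$from, el$to), el$weight))
  }
  expect_equal(key(net2), key(net))
})

test_that("adjacent kinases and star graphs extract the forced topology", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("CYT\tK1\t0.3"), f)
  net <- load_reference_network(f)
  sub <- extract_cytokine_network(net, "CYT", "K1")
  expect_equal(igraph::vcount(sub$graph), 2)
  expect_equal(igraph::ecount(sub$graph), 1)
  expect_equal(sub$kinases, "K1")
  expect_equal(unname(sub$path_weight["K1"]), 0.3)
  # star: five kinases each adjacent to the anchor
  writeLines(sprintf("CYT\tK%d\t0.%d", 1:5, 1:5), f)
  star <- load_reference_network(f)
  sub5 <- extract_cytokine_network(star, "CYT", paste0("K", 1:5))
  expect_equal(igraph::vcount(sub5$graph), 6)
  expect_equal(igraph::ecount(sub5$graph), 5)
  expect_error(extract_cytokine_network(star, "NOPE", "K1"), "NOPE")
})

test_that("absent and unreachable kinases are reported, not silently dropped", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("CYT\tA\t0.5", "A\tK1\t0.5", "X\tK2\t0.2",
               "A\tB\t0.1", "B\tC\t0.1", "C\tK3\t0.1"), f)
  net <- load_reference_network(f)
  expect_message(
    sub <- extract_cytokine_network(net, "CYT", c("K1", "K2", "K3", "K9"),
                                    max_hops = 2),
    "K9")
  expect_equal(sub$kinases, "K1")          # within 2 hops
  expect_setequal(sub$disconnected, c("K2", "K3"))  # K2 off-component, K3 too deep
  expect_equal(sub$missing, "K9")
  # with a larger hop budget K3 becomes reachable
  sub4 <- extract_cytokine_network(net, "CYT", "K3", max_hops = 4)
  expect_equal(sub4$kinases, "K3")
  expect_equal(unname(sub4$path_weight["K3"]), 0.8)
})

test_that("extracted path weights equal exhaustive enumeration", {
  for (seed in 802:806) {
    edges <- rand_graph(25, 60, seed = seed)
    net <- load_reference_network(write_edges_tsv(edges,
                                                  tempfile(fileext = ".tsv")))
    vn <- igraph::V(net)$name
    set.seed(seed)
    anchor <- sample(vn, 1)
    kinases <- sample(setdiff(vn, anchor), 4)
    sub <- extract_cytokine_network(net, anchor, kinases, max_hops = 2)
    for (k in kinases) {
      brute <- min_path_bruteforce(edges, k, anchor, max_hops = 2)
      if (is.finite(brute)) {
        expect_equal(unname(sub$path_weight[k]), brute)
      } else {
        expect_true(k %in% sub$disconnected)
      }
    }
  }
})

test_that("every tied minimal path is retained", {
  f <- tempfile(fileext = ".tsv")
  # two distinct 2-hop paths from K to CYT, both of weight 0.4
  writeLines(c("K\tA\t0.2", "A\tCYT\t0.2", "K\tB\t0.1", "B\tCYT\t0.3",
               "K\tC\t0.3", "C\tCYT\t0.3"), f)
  net <- load_reference_network(f)
  sub <- extract_cytokine_network(net, "CYT", "K", max_hops = 2)
  expect_setequal(igraph::V(sub$graph)$name, c("K", "A", "B", "CYT"))
  expect_equal(igraph::ecount(sub$graph), 4)
})

test_that("pruning is threshold-monotone, idempotent and anchor-connected", {
  edges <- rand_graph(20, 45, seed = 807)
  net <- load_reference_network(write_edges_tsv(edges,
                                                tempfile(fileext = ".tsv")))
  vn <- igraph::V(net)$name
  sub <- extract_cytokine_network(net, vn[1], vn[5:10], max_hops = 3)
  w <- igraph::E(sub$graph)$weight
  # threshold at or above the max weight changes nothing
  same <- prune_by_weight(sub, max(w) + 1)
  expect_equal(igraph::ecount(same$graph), igraph::ecount(sub$graph))
  # threshold below the min weight leaves the anchor alone
  bare <- prune_by_weight(sub, min(w) / 2)
  expect_equal(igraph::V(bare$graph)$name, sub$anchor)
  expect_length(bare$kinases, 0)
  prev_edges <- -1
  for (th in sort(unique(w))) {
    pr <- prune_by_weight(sub, th)
    # idempotence
    pr2 <- prune_by_weight(pr, th)
    expect_equal(igraph::ecount(pr2$graph), igraph::ecount(pr$graph))
    # monotone growth with the threshold
    expect_gte(igraph::ecount(pr$graph), prev_edges)
    prev_edges <- igraph::ecount(pr$graph)
    # connectivity: every retained node reaches the anchor
    if (igraph::vcount(pr$graph) > 1) {
      d <- igraph::distances(pr$graph, v = pr$anchor)
      expect_true(all(is.finite(d)))
    }
  }
  expect_error(prune_by_weight(sub, 0), "threshold")
})

test_that("subnetworks export to GraphML and JSON for rendering", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("CYT\tK1\t0.3", "K1\tK2\t0.2"), f)
  net <- load_reference_network(f)
  sub <- extract_cytokine_network(net, "CYT", c("K1", "K2"))
  gml <- tempfile(fileext = ".graphml")
  write_network_graphml(sub, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(back)$name, igraph::V(sub$graph)$name)
  expect_equal(igraph::ecount(back), igraph::ecount(sub$graph))
  js <- network_to_json(sub)
  expect_equal(sort(js$nodes$id), c("CYT", "K1", "K2"))
  expect_equal(js$nodes$role[js$nodes$id == "CYT"], "anchor")
  expect_equal(nrow(js$edges), 2)
  jf <- tempfile(fileext = ".json")
  network_to_json(sub, jf)
  expect_true(jsonlite::validate(paste(readLines(jf), collapse = "\n")))
})
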