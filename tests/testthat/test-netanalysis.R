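triangle <- gene_network(tibble::tibble(
  source = c("A", "B", "C"), target = c("B", "C", "A")))

complete_net <- function(n) {
  nodes <- LETTERS[seq_len(n)]
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  gene_network(pairs[pairs$source != pairs$target, ])
}

test_that("edge lists load with self-loops and duplicates handled", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\tsign",
               "A\tB\t+", "B\tC\t-", "C\tA\t+"), path)
  net <- read_edgelist(path)
  expect_equal(nrow(net), 3)

  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget", "A\tB", "A\tB", "A\tA", "B\tC"), path2)
  expect_warning(expect_warning(net2 <- read_edgelist(path2),
                                "self-loop"), "duplicate")
  expect_equal(nrow(net2), 2)

  gen <- generate_network(9, m_edges = 29, seed = 8)
  path3 <- withr::local_tempfile(fileext = ".tsv")
  write_edgelist(gen, path3)
  back <- read_edgelist(path3)
  expect_equal(back, gen, ignore_attr = TRUE)
  expect_equal(attr(back, "nodes"), attr(gen, "nodes"))
})

test_that("density is m over n(n-1)", {
  net <- generate_network(9, m_edges = 29, seed = 1)
  expect_equal(network_density(net), 29 / 72)
  expect_equal(round(network_density(net), 2), 0.40)
  expect_equal(network_density(complete_net(5)), 1.0)
  empty9 <- gene_network(tibble::tibble(source = character(),
                                        target = character()),
                         nodes = sprintf("G%d", 1:9))
  expect_equal(network_density(empty9), 0.0)
  expect_error(network_density(gene_network(
    tibble::tibble(source = character(), target = character()),
    nodes = "A")), "at least 2")
})

test_that("path metrics cover cycles, chains, and complete digraphs", {
  pm_cycle <- path_metrics(triangle)
  expect_equal(pm_cycle$average_path_length, 1.5)
  expect_equal(pm_cycle$diameter, 2L)
  pm_k <- path_metrics(complete_net(4))
  expect_equal(pm_k$average_path_length, 1.0)
  expect_equal(pm_k$diameter, 1L)
  chain <- gene_network(tibble::tibble(source = c("a", "b"),
                                       target = c("b", "c")))
  pm_chain <- path_metrics(chain)
  expect_equal(pm_chain$average_path_length, 4 / 3)
  expect_equal(pm_chain$diameter, 2L)
  isolated <- gene_network(tibble::tibble(source = character(),
                                          target = character()),
                           nodes = c("A", "B"))
  expect_error(path_metrics(isolated), "no reachable")
})

test_that("clustering uses the undirected triad definition", {
  tri_und <- gene_network(tibble::tibble(
    source = c("A", "B", "C"), target = c("B", "C", "A")))
  expect_equal(clustering_coefficient(tri_und), 1.0)
  star <- gene_network(tibble::tibble(
    source = "H", target = c("L1", "L2", "L3")))
  expect_equal(clustering_coefficient(star), 0.0)
  # 4-clique minus one edge: two nodes see 2/3, two see 1
  k4m <- gene_network(tibble::tibble(
    source = c("A", "A", "B", "B", "C"),
    target = c("B", "C", "C", "D", "D")))
  expect_equal(clustering_coefficient(k4m), (2 * (2 / 3) + 2 * 1) / 4)
})

test_that("degree centralities use the n-1 normalization", {
  # one node receiving 7 of 8 possible in-edges in a 9-node network
  edges <- tibble::tibble(source = sprintf("G%d", 2:8), target = "G1")
  net <- gene_network(edges, nodes = sprintf("G%d", 1:9))
  prof <- centralities(net)
  expect_equal(prof$in_degree[prof$gene == "G1"], 7 / 8)
  expect_equal(round(7 / 8, 2), 0.88)
  k <- complete_net(5)
  profk <- centralities(k)
  expect_true(all(profk$betweenness == 0))
  expect_true(all(profk$in_degree == 1))
  dstar <- gene_network(tibble::tibble(source = "C",
                                       target = c("L1", "L2", "L3")))
  profs <- centralities(dstar)
  expect_equal(profs$out_degree[profs$gene == "C"], 1)
  expect_true(all(profs$out_degree[profs$gene != "C"] == 0))
})

test_that("betweenness and path metrics match exhaustive enumeration", {
  for (seed in 1:25) {
    n <- 3 + (seed %% 6)
    m <- min(n * (n - 1), max(2, round(n * (n - 1) * 0.4)))
    net <- generate_network(n, m_edges = m, seed = seed)
    want <- oracle_path_and_betweenness(net)
    if (want$n_reachable > 0) {
      pm <- path_metrics(net)
      expect_equal(pm$average_path_length, want$average_path_length)
      expect_equal(pm$diameter, want$diameter)
    }
    prof <- centralities(net)
    expect_equal(
      stats::setNames(prof$betweenness, prof$gene)[names(want$betweenness)],
      want$betweenness, tolerance = 1e-12)
  }
})

test_that("metrics are invariant under node relabeling", {
  net <- generate_network(8, m_edges = 20, seed = 12)
  nodes <- attr(net, "nodes")
  relabel <- withr::with_seed(5, stats::setNames(sample(nodes), nodes))
  renamed <- gene_network(tibble::tibble(
    source = unname(relabel[net$source]),
    target = unname(relabel[net$target])),
    nodes = unname(relabel))
  expect_equal(network_density(net), network_density(renamed))
  expect_equal(clustering_coefficient(net),
               clustering_coefficient(renamed))
  expect_equal(path_metrics(net), path_metrics(renamed))
  p1 <- centralities(net); p2 <- centralities(renamed)
  m1 <- stats::setNames(p1$betweenness, relabel[p1$gene])
  m2 <- stats::setNames(p2$betweenness, p2$gene)
  expect_equal(m1[sort(names(m1))], m2[sort(names(m2))])
})

test_that("removing an edge never increases density or degree centralities", {
  net <- generate_network(7, m_edges = 18, seed = 30)
  prof <- centralities(net)
  for (drop in c(1, 9, 18)) {
    sub <- gene_network(tibble::as_tibble(net)[-drop, ],
                        nodes = attr(net, "nodes"))
    expect_lt(network_density(sub), network_density(net))
    sp <- centralities(sub)
    expect_true(all(sp$in_degree[match(prof$gene, sp$gene)] <=
                      prof$in_degree))
    expect_true(all(sp$out_degree[match(prof$gene, sp$gene)] <=
                      prof$out_degree))
  }
})

test_that("hub designation follows the composite mean rank", {
  # G1 dominates every metric: receives and sends most edges
  edges <- tibble::tibble(
    source = c("G1", "G1", "G1", "G2", "G3", "G4", "G2"),
    target = c("G2", "G3", "G4", "G1", "G1", "G1", "G3"))
  prof <- centralities(gene_network(edges))
  expect_equal(hub_genes(prof, k = 1), "G1")
  # two symmetric nodes tie; lexicographic order breaks it
  sym <- gene_network(tibble::tibble(source = c("A", "B"),
                                     target = c("B", "A")))
  expect_equal(hub_genes(centralities(sym), k = 2), c("A", "B"))
  expect_error(hub_genes(prof, k = 10))
})

test_that("an engineered network yields its designated hubs", {
  # 4 designated hubs wired densely among themselves and to all others;
  # 5 peripheral nodes with a single outgoing edge each
  hubs <- c("CASP3", "GPX4", "APP", "SRC")
  periph <- c("P1", "P2", "P3", "P4", "P5")
  hub_edges <- expand.grid(source = hubs, target = hubs,
                           stringsAsFactors = FALSE)
  hub_edges <- hub_edges[hub_edges$source != hub_edges$target, ]
  spoke <- tibble::tibble(source = periph, target = hubs[c(1:4, 1)])
  back <- tibble::tibble(source = hubs[c(1, 2)], target = c("P1", "P2"))
  net <- gene_network(dplyr::bind_rows(hub_edges, spoke, back))
  got <- hub_genes(centralities(net), k = 4)
  expect_setequal(got, hubs)
})
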