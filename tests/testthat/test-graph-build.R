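clip_sig <- function(pos, kind = "CLIP_RIGHT", id = NULL, contig = "c1") {
  n <- length(pos)
  data.frame(kind = kind, contig = contig, pos = as.integer(pos),
             mate_contig = NA_character_, mate_pos = NA_integer_,
             read_id = id %||% sprintf("r%d", seq_len(n)),
             mapq = 60L, role = NA_character_, mate_inner = NA_integer_,
             stringsAsFactors = FALSE)
}

arp_sig <- function(left, right, kind = "ARP_LARGE_INSERT", id, contig = "c1") {
  rbind(
    data.frame(kind = kind, contig = contig, pos = as.integer(left),
               mate_contig = contig, mate_pos = as.integer(right),
               read_id = id, mapq = 60L, role = "left",
               mate_inner = as.integer(right), stringsAsFactors = FALSE),
    data.frame(kind = kind, contig = contig, pos = as.integer(right),
               mate_contig = contig, mate_pos = as.integer(left),
               read_id = id, mapq = 60L, role = "right",
               mate_inner = as.integer(left), stringsAsFactors = FALSE))
}

test_that("clip signals at nearby positions merge into one weighted node", {
  s <- clip_sig(c(5000, 5001, 5000))
  nodes <- cluster_breakpoint_signals(s, NULL, csv_params(min_weight = 1))
  expect_identical(nrow(nodes), 1L)
  expect_identical(nodes$weight, 3L)
  expect_identical(nodes$start, 5000L)
  expect_identical(nodes$end, 5001L)
})

test_that("weight and weight/coverage filters discard weak nodes", {
  one <- clip_sig(7000, kind = "CLIP_LEFT")
  cov30 <- function(contig, pos) rep(30L, length(pos))
  expect_identical(nrow(cluster_breakpoint_signals(one, cov30,
                                                   csv_params(min_weight = 2))),
                   0L)
  three <- clip_sig(c(7000, 7000, 7001))
  cov60 <- function(contig, pos) rep(60L, length(pos))
  # 3 / 60 = 0.05 < 0.1
  expect_identical(nrow(cluster_breakpoint_signals(three, cov60,
                                                   csv_params(min_weight = 2))),
                   0L)
  cov20 <- function(contig, pos) rep(20L, length(pos))
  expect_identical(nrow(cluster_breakpoint_signals(three, cov20,
                                                   csv_params(min_weight = 2))),
                   1L)
})

test_that("discordant clustering distance is mean insert minus two read lengths", {
  expect_equal(discordant_cluster_distance(test_profile(500, 50, 100)), 300)
  expect_equal(discordant_cluster_distance(test_profile(300, 30, 100)), 100)
  # clamped negative case returns the floor, not zero
  expect_equal(discordant_cluster_distance(test_profile(500, 50, 250)), 50)
})

test_that("discordant pairs cluster into two nodes and one pairing record", {
  set.seed(1)
  s <- do.call(rbind, lapply(1:6, function(i) {
    arp_sig(10000 + (i - 1) * 24, 12300 + (i - 1) * 28, id = sprintf("p%d", i))
  }))
  res <- cluster_discordant_signals(s, test_profile(), csv_params())
  expect_identical(nrow(res$nodes), 2L)
  expect_setequal(res$nodes$weight, 6L)
  expect_identical(nrow(res$pairings), 1L)
  expect_identical(res$pairings$rp, 6L)
})

test_that("left ends beyond the clustering distance split into two nodes", {
  s <- rbind(arp_sig(10000, 12000, id = "p1"),
             arp_sig(10001, 12001, id = "p2"),
             arp_sig(10400, 12400, id = "p3"),
             arp_sig(10401, 12401, id = "p4"))
  res <- cluster_discordant_signals(s, test_profile(), csv_params())
  left_nodes <- res$nodes[res$nodes$start < 11000, ]
  expect_identical(nrow(left_nodes), 2L)
})

test_that("an isolated pair is removed by the pair-support control", {
  s <- arp_sig(10000, 12000, id = "lonely")
  res <- cluster_discordant_signals(s, test_profile(),
                                    csv_params(min_pair_support = 2))
  expect_identical(nrow(res$nodes), 0L)
  expect_identical(nrow(res$pairings), 0L)
})

test_that("paired-edge connection types follow the signal-kind table", {
  nodes <- mk_nodes(c(1000, 3000), c("ARP_RF", "ARP_RF"))
  pairings <- data.frame(left_uid = "u001", right_uid = "u002", rp = 4L,
                         kind = "ARP_RF", stringsAsFactors = FALSE)
  g <- build_graph(nodes, pairings, NULL, csv_params())
  expect_identical(g$epe$link_type, "DUP")
  expect_identical(g$epe$rp, 4L)
})

test_that("adjacency edges measure the clamped gap between spans", {
  nodes <- mk_nodes(c(900, 1800), c("CLIP_LEFT", "CLIP_RIGHT"))
  nodes$end[1] <- 1000L
  g <- build_graph(nodes, NULL, NULL, csv_params())
  expect_identical(g$eae$dist, 800L)
  # single node: no edges of either type
  g1 <- build_graph(mk_nodes(500, "SPLIT"), NULL, NULL, csv_params())
  expect_identical(nrow(g1$epe), 0L)
  expect_identical(nrow(g1$eae), 0L)
})

test_that("dangling pairing records are dropped with a message, not an error", {
  nodes <- mk_nodes(c(1000, 3000), c("ARP_RF", "ARP_RF"))
  pairings <- data.frame(left_uid = "u001", right_uid = "zz999", rp = 2L,
                         kind = "ARP_RF", stringsAsFactors = FALSE)
  expect_message(g <- build_graph(nodes, pairings, NULL, csv_params()),
                 "dropped")
  expect_identical(nrow(g$epe), 0L)
})

test_that("graph invariants hold on randomized clustering inputs", {
  for (seed in 1:20) {
    set.seed(seed)
    npair <- sample(3:12, 1)
    s <- do.call(rbind, lapply(seq_len(npair), function(i) {
      l <- sample.int(50000, 1)
      arp_sig(l, l + sample(800:3000, 1), id = sprintf("s%d_%d", seed, i),
              kind = sample(c("ARP_LARGE_INSERT", "ARP_FF"), 1))
    }))
    cl <- clip_sig(sample.int(50000, 8),
                   id = sprintf("c%d_%d", seed, 1:8))
    res <- cluster_discordant_signals(s, test_profile(),
                                      csv_params(min_pair_support = 1))
    bk <- cluster_breakpoint_signals(cl, NULL, csv_params(min_weight = 1))
    # clustering never inflates support
    expect_lte(sum(res$nodes$weight), nrow(s))
    expect_lte(sum(bk$weight), nrow(cl))
    g <- build_graph(rbind(bk, res$nodes), res$pairings, NULL, csv_params())
    expect_true(validate_signal_graph(g))
  }
})

test_that("graph JSON and GraphML dumps round-trip", {
  g <- toy_graph()
  dir <- withr::local_tempdir()
  jp <- file.path(dir, "g.json")
  write_signal_graph_json(g, jp)
  g2 <- read_signal_graph_json(jp)
  expect_identical(g$nodes$start, g2$nodes$start)
  expect_identical(g$nodes$kind, g2$nodes$kind)
  expect_identical(lapply(g$nodes$read_ids, as.character),
                   lapply(g2$nodes$read_ids, as.character))
  expect_identical(g$epe, g2$epe)
  expect_identical(g$eae, g2$eae)
  skip_if_not_installed("igraph")
  gml <- file.path(dir, "g.graphml")
  write_signal_graph_graphml(g, gml)
  ig <- igraph::read_graph(gml, format = "graphml")
  expect_identical(as.integer(igraph::vcount(ig)), nrow(g$nodes))
  expect_identical(as.integer(igraph::ecount(ig)), nrow(g$epe) + nrow(g$eae))
  va <- igraph::vertex_attr(ig)
  expect_setequal(va$start, g$nodes$start)
})
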