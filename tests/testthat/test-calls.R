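test_that("CXS is distinct node types times paired edges", {
  # four distinct kinds, two paired edges: the worked example, CXS 8
  g <- toy_graph()
  call <- call_from_subgraph(1:4, g)
  expect_identical(call$cxs, 8L)
  expect_identical(call$n_node_types, 4L)
  expect_identical(call$n_epe, 2L)
  # single node, no paired edge: CXS 0
  expect_identical(call_from_subgraph(5L, g)$cxs, 0L)
  # 5 nodes of 3 distinct kinds with 3 paired edges: CXS 9
  g2 <- mk_graph(pos = c(1000, 1200, 1400, 1600, 1800),
                 kinds = c("CLIP_LEFT", "CLIP_LEFT", "SPLIT", "ARP_FF",
                           "SPLIT"),
                 epe = data.frame(i = c(1, 2, 3), j = c(3, 4, 5), rp = 2L,
                                  kind = "ARP_LARGE_INSERT"))
  expect_identical(call_from_subgraph(1:5, g2)$cxs, 9L)
})

test_that("call boundary spans leftmost node start to rightmost node end", {
  g <- toy_graph()
  call <- call_from_subgraph(1:4, g)
  expect_identical(call$start, 1000L)
  expect_identical(call$end, 2100L)
})

test_that("CXS is monotone under adding a paired edge", {
  pos <- c(1000, 1300, 1700, 2100)
  kinds <- c("CLIP_RIGHT", "ARP_LARGE_INSERT", "ARP_FF", "CLIP_LEFT")
  for (ne in 1:3) {
    epe <- data.frame(i = 1:ne, j = 1:ne + 1, rp = 2L,
                      kind = "ARP_LARGE_INSERT")
    g <- mk_graph(pos, kinds, epe)
    cx <- call_from_subgraph(1:4, g)$cxs
    if (ne > 1) expect_gte(cx, prev)
    prev <- cx
  }
})

test_that("orientation-kind adjacency edges contribute their implied type", {
  g <- mk_graph(pos = c(1000, 1400), kinds = c("ARP_FF", "ARP_FF"),
                epe = data.frame(i = 1, j = 2, rp = 3L,
                                 kind = "ARP_LARGE_INSERT"))
  call <- call_from_subgraph(1:2, g)
  expect_setequal(call$link_types, c("DEL", "INV"))
  # RF pair joined by adjacency implies a duplication connection
  g2 <- mk_graph(pos = c(1000, 1400), kinds = c("ARP_RF", "ARP_RF"))
  expect_identical(call_from_subgraph(1:2, g2)$link_types, "DUP")
})

test_that("type labels use the canonical sorted vocabulary", {
  expect_identical(label_type(c("DEL", "DUP")), "Del,Dup")
  expect_identical(label_type(c("DUP", "INS")), "Dup,Ins")
  expect_identical(label_type(c("INS", "DUP")), "Dup,Ins")
  expect_identical(label_type("INV"), "Inv")
})

test_that("the connection-type filter retains complex calls and is idempotent", {
  g <- mk_graph(pos = c(1000, 1400), kinds = c("ARP_FF", "ARP_FF"),
                epe = data.frame(i = 1, j = 2, rp = 3L,
                                 kind = "ARP_LARGE_INSERT"))
  multi <- call_from_subgraph(1:2, g)            # {DEL, INV}
  g2 <- mk_graph(pos = c(5000, 7000), kinds = c("ARP_LARGE_INSERT",
                                                "ARP_LARGE_INSERT"),
                 epe = data.frame(i = 1, j = 2, rp = 3L,
                                  kind = "ARP_LARGE_INSERT"))
  single <- call_from_subgraph(1:2, g2)          # {DEL}
  calls <- list(multi, single)
  kept <- filter_csv(calls)
  expect_length(kept, 1L)
  expect_identical(kept[[1]]$link_types, c("DEL", "INV"))
  expect_identical(filter_csv(kept), kept)
  expect_identical(filter_csv(calls, min_link_types = 1), calls)
})

test_that("callset writing produces consistent VCF, BED and JSON", {
  g <- toy_graph()
  calls <- calls_from_graph(g, find_maximal_subgraphs(g, growth_params(1, 1000)))
  dir <- withr::local_tempdir()
  paths <- write_calls(calls, file.path(dir, "out"), c(c1 = 100000L))
  vcf <- readLines(paths["vcf"])
  body <- vcf[!grepl("^#", vcf)]
  expect_length(body, length(calls))
  f <- strsplit(body[1], "\t")[[1]]
  # 1-based VCF POS from the 0-based internal start
  expect_identical(as.integer(f[2]), calls[[1]]$start + 1L)
  expect_match(f[8], sprintf("END=%d;", calls[[1]]$end))
  expect_match(f[8], "CXS=8")
  expect_identical(f[5], "<CSV>")
  bed <- read.table(paths["bed"], sep = "\t", stringsAsFactors = FALSE)
  expect_identical(bed$V2, vapply(calls, `[[`, integer(1), "start"))
  expect_identical(bed$V3, vapply(calls, `[[`, integer(1), "end"))
  # JSON round-trip reproduces the callset exactly
  back <- read_calls_json(paths["json"])
  expect_length(back, length(calls))
  for (i in seq_along(calls)) {
    for (fld in c("contig", "start", "end", "cxs", "link_types",
                  "n_node_types", "n_epe", "node_ids", "node_kinds")) {
      expect_identical(back[[i]][[fld]], calls[[i]][[fld]],
                       info = paste("field", fld))
    }
  }
  # empty callset still yields a valid header-only VCF
  p0 <- write_calls(list(), file.path(dir, "empty"), c(c1 = 100000L))
  v0 <- readLines(p0["vcf"])
  expect_true(all(grepl("^#", v0)))
  expect_identical(sum(grepl("^#CHROM", v0)), 1L)
})

test_that("emitted VCF parses with a standard VCF reader", {
  skip_if_not_installed("VariantAnnotation")
  g <- toy_graph()
  calls <- calls_from_graph(g, find_maximal_subgraphs(g, growth_params(1, 1000)))
  dir <- withr::local_tempdir()
  paths <- write_calls(calls, file.path(dir, "vv"), c(c1 = 100000L))
  v <- VariantAnnotation::readVcf(paths[["vcf"]])
  expect_identical(nrow(v), length(calls))
  expect_identical(unname(VariantAnnotation::info(v)$CXS[1]), 8L)
  expect_identical(unname(VariantAnnotation::info(v)$END[1]),
                   calls[[1]]$end)
})

test_that("calls on several contigs are emitted in dictionary order", {
  mk1 <- function(contig) {
    nodes <- mk_nodes(c(1000, 1400), c("ARP_FF", "ARP_FF"), contig = contig)
    pairings <- data.frame(left_uid = "u001", right_uid = "u002", rp = 2L,
                           kind = "ARP_FF", stringsAsFactors = FALSE)
    g <- build_graph(nodes, pairings, NULL, csv_params())
    call_from_subgraph(1:2, g)
  }
  calls <- list(mk1("beta"), mk1("alpha"))
  dir <- withr::local_tempdir()
  paths <- write_calls(calls, file.path(dir, "ord"),
                       c(beta = 50000L, alpha = 50000L))
  body <- readLines(paths["vcf"])
  body <- body[!grepl("^#", body)]
  ctgs <- vapply(strsplit(body, "\t"), `[`, character(1), 1)
  expect_identical(ctgs, c("beta", "alpha"))
})
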