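# shared fixtures: toy graphs, random graphs, oracles, tiny BAMs

test_profile <- function(mean = 500, sd = 50, rl = 100) {
  insert_profile(mean, sd, rl, 10000L)
}

# node table on one contig from positions/kinds; zero-width spans
mk_nodes <- function(pos, kinds, weight = 5L, contig = "c1") {
  n <- length(pos)
  data.frame(kind = rep_len(kinds, n), contig = contig,
             start = as.integer(pos), end = as.integer(pos),
             weight = rep_len(as.integer(weight), n),
             read_ids = I(lapply(seq_len(n), function(i)
               sprintf("r%d_%d", i, seq_len(rep_len(weight, n)[i])))),
             uid = sprintf("u%03d", seq_len(n)),
             stringsAsFactors = FALSE)
}

# graph from node positions and explicit paired edges (by position index);
# bypasses clustering, uses build_graph for ordering + Eae
mk_graph <- function(pos, kinds, epe = NULL, weight = 5L) {
  nodes <- mk_nodes(pos, kinds, weight)
  pairings <- NULL
  if (!is.null(epe) && nrow(epe)) {
    pairings <- data.frame(left_uid = nodes$uid[epe$i],
                           right_uid = nodes$uid[epe$j],
                           rp = epe$rp %||% rep(2L, nrow(epe)),
                           kind = epe$kind %||% rep("ARP_LARGE_INSERT",
                                                    nrow(epe)),
                           stringsAsFactors = FALSE)
  }
  suppressMessages(build_graph(nodes, pairings, NULL, csv_params()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# the Figure-style toy: four chained nodes of distinct kinds joined by two
# paired edges, plus distant nodes E/F with no paired edge
toy_graph <- function(min_dist = 1000) {
  # A(1000) C(1300) B(1700) D(2100) then E(9000) F(20000)
  mk_graph(pos = c(1000, 1300, 1700, 2100, 9000, 20000),
           kinds = c("CLIP_RIGHT", "ARP_LARGE_INSERT", "ARP_FF",
                     "CLIP_LEFT", "ARP_RR", "ARP_RF"),
           epe = data.frame(i = c(1, 2), j = c(3, 4),
                            rp = c(3L, 3L),
                            kind = c("ARP_LARGE_INSERT", "ARP_LARGE_INSERT")))
}

# random single-contig graph with <= max_nodes nodes
random_graph <- function(seed, max_nodes = 12, span = 20000) {
  set.seed(seed)
  n <- sample(2:max_nodes, 1)
  pos <- sort(sample.int(span, n))
  kinds <- sample(c("CLIP_LEFT", "CLIP_RIGHT", "SPLIT", "ARP_LARGE_INSERT",
                    "ARP_FF", "ARP_RF"), n, replace = TRUE)
  ne <- sample(0:min(4, n %/% 2), 1)
  epe <- NULL
  if (ne > 0) {
    prs <- matrix(replicate(ne, sort(sample.int(n, 2))), nrow = 2)
    epe <- data.frame(i = prs[1, ], j = prs[2, ], rp = 2L,
                      kind = sample(c("ARP_LARGE_INSERT", "ARP_FF", "ARP_RF"),
                                    ne, replace = TRUE))
  }
  mk_graph(pos, kinds, epe)
}

# --- independent oracles -------------------------------------------------

# direct acceptance semantics, re-stated from the definition
oracle_accepts <- function(g, v, graph, min_dist) {
  n <- graph$nodes
  last <- g[length(g)]
  if (n$contig[v] == n$contig[last] &&
      max(n$start[v] - n$end[last], 0) < min_dist) {
    return(TRUE)
  }
  e <- graph$epe
  any((e$node_i %in% g & e$node_j == v) | (e$node_j %in% g & e$node_i == v))
}

# enumerate every growth-reachable set considering ALL later nodes as
# candidates (stronger than the algorithm's edge-reachable candidate set),
# then keep maximal sets only
oracle_maximal <- function(graph, min_dist) {
  nn <- nrow(graph$nodes)
  sets <- list()
  recurse <- function(g) {
    sets[[length(sets) + 1L]] <<- g
    last <- g[length(g)]
    if (last < nn) {
      for (v in (last + 1L):nn) {
        if (oracle_accepts(g, v, graph, min_dist)) recurse(c(g, v))
      }
    }
  }
  for (s in seq_len(nn)) recurse(s)
  keys <- vapply(sets, paste, character(1), collapse = ",")
  sets <- sets[!duplicated(keys)]
  is_sub <- function(a, b) length(a) < length(b) && all(a %in% b)
  keep <- vapply(seq_along(sets), function(i) {
    !any(vapply(seq_along(sets), function(j)
      i != j && is_sub(sets[[i]], sets[[j]]), logical(1)))
  }, logical(1))
  sets[keep]
}

# enumerate the grown set with the algorithm's candidate rule (successor
# or paired-edge neighbour after the frontier), iteratively with an
# explicit stack rather than recursion/projection
oracle_grown <- function(graph, min_dist) {
  nn <- nrow(graph$nodes)
  n <- graph$nodes
  e <- graph$epe
  cand_of <- function(g) {
    last <- g[length(g)]
    cands <- integer()
    if (last < nn && n$contig[last + 1L] == n$contig[last]) {
      cands <- last + 1L
    }
    if (nrow(e)) {
      hit <- c(e$node_j[e$node_i %in% g], e$node_i[e$node_j %in% g])
      cands <- c(cands, hit[hit > last])
    }
    sort(unique(cands))
  }
  out <- list()
  stack <- lapply(seq_len(nn), identity)
  while (length(stack)) {
    g <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    out[[length(out) + 1L]] <- g
    for (v in cand_of(g)) {
      if (!(v %in% g) && oracle_accepts(g, v, graph, min_dist)) {
        stack[[length(stack) + 1L]] <- c(g, v)
      }
    }
  }
  keys <- vapply(out, paste, character(1), collapse = ",")
  out[!duplicated(keys)]
}

set_keys <- function(sets) {
  sort(vapply(sets, function(s) paste(sort(s), collapse = ","), character(1)))
}

# write a small SAM + BAM from a record table
write_test_bam <- function(records, prefix,
                           contigs = c(c1 = 100000L)) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
  lines <- vapply(records, function(r) {
    base <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t*\t*",
                    r$qname, r$flag, r$rname, r$pos, r$mapq %||% 60L,
                    r$cigar, r$rnext %||% "=", r$pnext %||% 0L,
                    r$tlen %||% 0L)
    if (!is.null(r$sa)) base <- paste0(base, "\tSA:Z:", r$sa)
    base
  }, character(1))
  sam <- paste0(prefix, ".sam")
  writeLines(c(hdr, lines), sam)
  bam <- Rsamtools::asBam(sam, prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

# records for a proper FR pair (both primary ends)
proper_pair_records <- function(qname, pos1, tlen, rl = 100,
                                rname = "c1") {
  cigar <- sprintf("%dM", rl)
  pos2 <- pos1 + tlen - rl
  list(list(qname = qname, flag = 99L, rname = rname, pos = pos1,
            cigar = cigar, pnext = pos2, tlen = tlen),
       list(qname = qname, flag = 147L, rname = rname, pos = pos2,
            cigar = cigar, pnext = pos1, tlen = -tlen))
}
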