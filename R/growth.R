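#' Can a node extend a growing subgraph?
#'
#' A candidate node `v` positioned after the subgraph's last node `v'` is
#' accepted when (a) the genomic gap between `v'` and `v` is below
#' `min_dist` (adjacency branch), or (b) a paired (Epe) edge connects `v`
#' to any node already in the subgraph, scanned from the last member
#' backwards (backtracking branch). The node must also pass the pattern
#' frequency check (`freq(v) >= minFreq`, always true at the default
#' `minFreq = 1`).
#'
#' @param g Integer vector of node ids of the current subgraph, increasing
#'   in position order.
#' @param v Candidate node id, positioned at or after the last member.
#' @param graph A `signal_graph`.
#' @param params A [growth_params()].
#' @return `TRUE` or `FALSE`; growing by an existing member is an error.
#' @export
node_in_range <- function(g, v, graph, params) {
  if (v %in% g) stop("candidate node is already part of the subgraph")
  ctx <- growth_context(graph, params)
  node_in_range_impl(g, v, ctx)
}

# precomputed structures shared across a growth run
growth_context <- function(graph, params) {
  n <- graph$nodes
  nn <- nrow(n)
  epe_adj <- rep(list(integer()), nn)
  if (nrow(graph$epe)) {
    for (k in seq_len(nrow(graph$epe))) {
      i <- graph$epe$node_i[k]; j <- graph$epe$node_j[k]
      epe_adj[[i]] <- c(epe_adj[[i]], j)
      epe_adj[[j]] <- c(epe_adj[[j]], i)
    }
    epe_adj <- lapply(epe_adj, function(x) sort(unique(x)))
  }
  succ <- rep(NA_integer_, nn)
  if (nn > 1) {
    same <- n$contig[-1] == n$contig[-nn]
    succ[which(same)] <- which(same) + 1L
  }
  type_freq <- table(n$kind)
  list(nodes = n, epe_adj = epe_adj, succ = succ,
       type_freq = type_freq,
       min_freq = params$min_freq, min_dist = params$min_dist,
       counter = new.env(parent = emptyenv()))
}

node_in_range_impl <- function(g, v, ctx) {
  n <- ctx$nodes
  if (ctx$type_freq[[n$kind[v]]] < ctx$min_freq) return(FALSE)
  last <- g[length(g)]
  if (n$contig[v] == n$contig[last]) {
    gap <- max(n$start[v] - n$end[last], 0L)
    if (gap < ctx$min_dist) return(TRUE)
  }
  # backtracking: scan members from last to first for a paired edge to v
  adj <- ctx$epe_adj[[v]]
  if (length(adj)) {
    for (m in rev(g)) {
      if (m %in% adj) return(TRUE)
    }
  }
  FALSE
}

# candidate nodes reachable from subgraph g via any edge, after its last node
growth_candidates <- function(g, ctx) {
  last <- g[length(g)]
  cand <- integer()
  s <- ctx$succ[last]
  if (!is.na(s)) cand <- s
  for (m in g) {
    a <- ctx$epe_adj[[m]]
    if (length(a)) cand <- c(cand, a[a > last])
  }
  sort(unique(cand))
}

grow_recursive <- function(g, ctx, acc) {
  acc$sets[[length(acc$sets) + 1L]] <- g
  cand <- growth_candidates(g, ctx)
  for (v in cand) {
    acc$visited <- acc$visited + 1L
    if (v %in% g) next
    if (node_in_range_impl(g, v, ctx)) {
      grow_recursive(c(g, v), ctx, acc)
    }
  }
  invisible(NULL)
}

#' Grow all subgraphs reachable from a seed
#'
#' Depth-first pattern growth: candidates are nodes reachable from the
#' current subgraph via any edge and positioned after its last node; each
#' accepted extension is recorded and recursed on, so growth proceeds in
#' increasing position order and terminates. Every intermediate subgraph
#' (including the seed) is appended to the accumulator.
#'
#' @param seed Integer vector of node ids (position-increasing), usually a
#'   single seed node.
#' @param graph A `signal_graph`.
#' @param params A [growth_params()].
#' @param out Optional existing accumulator (a list of integer vectors) to
#'   append to.
#' @return List of integer node-id vectors, with attribute
#'   `candidates_visited`.
#' @export
multi_loc_pattern_growth <- function(seed, graph, params, out = NULL) {
  stopifnot(length(seed) >= 1)
  ctx <- growth_context(graph, params)
  acc <- new.env(parent = emptyenv())
  acc$sets <- out %||% list()
  acc$visited <- 0L
  grow_recursive(as.integer(seed), ctx, acc)
  structure(acc$sets, candidates_visited = acc$visited)
}

#' Detect maximal subgraphs by pattern growth
#'
#' Seed-and-extension search: every node whose signal type reaches the
#' `minFreq` frequency threshold seeds a growth; the accumulated subgraphs
#' are reduced to maximal ones (a subgraph is dropped when its node set is
#' contained in another grown subgraph). Output is sorted by leftmost
#' position and is invariant to input permutation because nodes are held
#' in canonical `(contig, start, kind)` order.
#'
#' @param graph A `signal_graph`.
#' @param params A [growth_params()].
#' @return A list of subgraphs, each `list(node_ids, freq)` of class
#'   `csv_subgraph`, with attribute `candidates_visited`.
#' @export
find_maximal_subgraphs <- function(graph, params) {
  n <- graph$nodes
  if (nrow(n) == 0) return(structure(list(), candidates_visited = 0L))
  ctx <- growth_context(graph, params)
  eligible_types <- names(ctx$type_freq)[ctx$type_freq >= ctx$min_freq]
  seeds <- n$node_id[n$kind %in% eligible_types]
  acc <- new.env(parent = emptyenv())
  acc$sets <- list(); acc$visited <- 0L
  for (s in seeds) grow_recursive(s, ctx, acc)
  maximal <- maximal_sets(acc$sets)
  # pattern frequency: number of genomic instances sharing the ordered
  # signal-type signature
  sig <- vapply(maximal, function(ids) paste(n$kind[ids], collapse = ">"),
                character(1))
  freq <- table(sig)
  keep <- as.integer(freq[sig]) >= ctx$min_freq
  maximal <- maximal[keep]; sig <- sig[keep]
  ord <- order(vapply(maximal, function(ids) n$start[ids[1]], numeric(1)),
               vapply(maximal, function(ids) ids[1], integer(1)))
  out <- lapply(maximal[ord], function(ids) {
    structure(list(node_ids = ids,
                   freq = as.integer(freq[[paste(n$kind[ids], collapse = ">")]])),
              class = "csv_subgraph")
  })
  structure(out, candidates_visited = acc$visited)
}

# drop node sets contained in another set; input sets are sorted increasing
maximal_sets <- function(sets) {
  if (length(sets) <= 1) return(sets)
  keys <- vapply(sets, paste, character(1), collapse = ",")
  dup <- duplicated(keys)
  sets <- sets[!dup]
  m <- length(sets)
  sizes <- lengths(sets)
  # index: node -> set indices containing it
  by_node <- new.env(parent = emptyenv())
  for (i in seq_len(m)) {
    for (v in sets[[i]]) {
      key <- as.character(v)
      by_node[[key]] <- c(by_node[[key]], i)
    }
  }
  contained <- logical(m)
  for (i in seq_len(m)) {
    holders <- by_node[[as.character(sets[[i]][1])]]
    for (v in sets[[i]][-1]) {
      if (length(holders) <= 1) break
      holders <- intersect(holders, by_node[[as.character(v)]])
    }
    if (any(sizes[holders] > sizes[i])) contained[i] <- TRUE
  }
  sets[!contained]
}

#' @export
print.csv_subgraph <- function(x, ...) {
  cat(sprintf("subgraph: %d nodes (ids %s), pattern freq %d\n",
              length(x$node_ids), paste(x$node_ids, collapse = ","), x$freq))
  invisible(x)
}
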