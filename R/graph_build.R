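#' Cluster clip/split signals into weighted breakpoint nodes
#'
#' Signals of the same kind within `clip_merge_window` bp merge into one
#' node whose weight is the number of distinct supporting reads. Nodes with
#' weight below `min_weight`, or whose weight/coverage ratio at the node
#' midpoint falls below `min_weight_ratio`, are discarded.
#'
#' @param signals Signal data frame (CLIP_LEFT/CLIP_RIGHT/SPLIT rows),
#'   position-sorted.
#' @param coverage_fn `function(contig, pos) -> depth`, e.g.
#'   [coverage_lookup()]; `NULL` disables the ratio filter.
#' @param params A [csv_params()].
#' @return A node data frame: `uid`, `kind`, `contig`, `start`, `end`,
#'   `weight` and a `read_ids` list column.
#' @export
cluster_breakpoint_signals <- function(signals, coverage_fn = NULL,
                                       params = csv_params()) {
  signals <- signals[signals$kind %in% c("CLIP_LEFT", "CLIP_RIGHT", "SPLIT"), ,
                     drop = FALSE]
  if (nrow(signals) == 0) return(empty_nodes())
  grp <- interaction(signals$contig, signals$kind, drop = TRUE)
  nodes <- do.call(rbind, lapply(split(seq_len(nrow(signals)), grp), function(ii) {
    s <- signals[ii, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    cid <- cumsum(c(1L, diff(s$pos) > params$clip_merge_window))
    do.call(rbind, lapply(split(seq_len(nrow(s)), cid), function(jj) {
      ids <- unique(s$read_id[jj])
      data.frame(kind = s$kind[1], contig = s$contig[1],
                 start = min(s$pos[jj]), end = max(s$pos[jj]),
                 weight = length(ids),
                 read_ids = I(list(ids)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(nodes) <- NULL
  nodes <- filter_nodes(nodes, coverage_fn, params$min_weight,
                        params$min_weight_ratio)
  if (nrow(nodes)) nodes$uid <- sprintf("bk%06d", seq_len(nrow(nodes)))
  nodes
}

filter_nodes <- function(nodes, coverage_fn, min_weight, min_ratio) {
  if (nrow(nodes) == 0) return(nodes)
  keep <- nodes$weight >= min_weight
  if (!is.null(coverage_fn) && min_ratio > 0) {
    mid <- (nodes$start + nodes$end) %/% 2L
    cov <- mapply(function(ctg, p) coverage_fn(ctg, p), nodes$contig, mid)
    ratio <- ifelse(cov > 0, nodes$weight / cov, 1)
    keep <- keep & ratio >= min_ratio
  }
  nodes[keep, , drop = FALSE]
}

empty_nodes <- function() {
  data.frame(kind = character(), contig = character(),
             start = integer(), end = integer(), weight = integer(),
             read_ids = I(list()), uid = character(),
             stringsAsFactors = FALSE)
}

#' Discordant-pair clustering distance
#'
#' The clustering distance for discordant read-pair signals: the estimated
#' mean insert size minus twice the read length, floored at
#' `min_cluster_distance_floor`.
#'
#' @param profile An [insert_profile()].
#' @param params A [csv_params()].
#' @return Distance in bp.
#' @export
discordant_cluster_distance <- function(profile, params = csv_params()) {
  max(profile$mean_insert - 2 * profile$read_length,
      params$min_cluster_distance_floor)
}

#' Cluster discordant read-pair signals into paired nodes
#'
#' Each abnormal read-pair (ARP) kind is clustered independently by
#' single linkage with a gap threshold of [discordant_cluster_distance()].
#' Every pair contributes its left end to one node and its right end to
#' another; pairing records preserve which left node connects to which
#' right node and with how many shared pairs. Side clusters supported by
#' fewer than `min_pair_support` pairs, or failing the weight/coverage
#' ratio filter, are discarded.
#'
#' @param signals ARP signal rows from [extract_signals()].
#' @param profile An [insert_profile()].
#' @param params A [csv_params()].
#' @param coverage_fn Optional coverage lookup for the ratio filter.
#' @return `list(nodes = <node data frame>, pairings = <data frame with
#'   left_uid, right_uid, rp, kind>)`.
#' @export
cluster_discordant_signals <- function(signals, profile,
                                       params = csv_params(),
                                       coverage_fn = NULL) {
  signals <- signals[signals$kind %in% ARP_KINDS, , drop = FALSE]
  empty <- list(nodes = empty_nodes(),
                pairings = data.frame(left_uid = character(),
                                      right_uid = character(),
                                      rp = integer(), kind = character(),
                                      stringsAsFactors = FALSE))
  if (nrow(signals) == 0) return(empty)
  d <- discordant_cluster_distance(profile, params)

  # one record per pair: prefer the left-end signal (its own inner
  # coordinate and its mate's start are both exact)
  key <- paste(signals$read_id, signals$kind, signals$contig, sep = "\r")
  left <- signals$role == "left"
  ord <- order(key, !left)           # left rows first within a pair
  s <- signals[ord, , drop = FALSE]
  first <- !duplicated(key[ord])
  s <- s[first, , drop = FALSE]
  left_inner <- ifelse(s$role == "left", s$pos, s$mate_inner)
  right_inner <- ifelse(s$role == "left", s$mate_inner, s$pos)
  pairs <- data.frame(read_id = s$read_id, kind = s$kind, contig = s$contig,
                      left = as.integer(left_inner),
                      right = as.integer(right_inner),
                      stringsAsFactors = FALSE)

  all_nodes <- list(); all_pairings <- list(); uid_n <- 0L
  for (grp in split(seq_len(nrow(pairs)),
                    interaction(pairs$contig, pairs$kind, drop = TRUE))) {
    p <- pairs[grp, , drop = FALSE]
    lcl <- linkage_clusters(p$left, d)
    rcl <- linkage_clusters(p$right, d)
    # side-cluster support filter
    lsz <- table(lcl); rsz <- table(rcl)
    ok <- lsz[as.character(lcl)] >= params$min_pair_support &
      rsz[as.character(rcl)] >= params$min_pair_support
    p <- p[ok, , drop = FALSE]; lcl <- lcl[ok]; rcl <- rcl[ok]
    if (nrow(p) == 0) next
    side_nodes <- function(cl, coord) {
      do.call(rbind, lapply(split(seq_along(cl), cl), function(jj) {
        data.frame(kind = p$kind[1], contig = p$contig[1],
                   start = min(coord[jj]), end = max(coord[jj]),
                   weight = length(unique(p$read_id[jj])),
                   read_ids = I(list(unique(p$read_id[jj]))),
                   cl = cl[jj[1]], stringsAsFactors = FALSE)
      }))
    }
    ln <- side_nodes(lcl, p$left); rn <- side_nodes(rcl, p$right)
    ln <- filter_nodes(ln, coverage_fn, 1L, params$min_weight_ratio)
    rn <- filter_nodes(rn, coverage_fn, 1L, params$min_weight_ratio)
    if (nrow(ln) == 0 || nrow(rn) == 0) next
    ln$uid <- sprintf("dp%06d", uid_n + seq_len(nrow(ln)))
    uid_n <- uid_n + nrow(ln)
    rn$uid <- sprintf("dp%06d", uid_n + seq_len(nrow(rn)))
    uid_n <- uid_n + nrow(rn)
    lmap <- stats::setNames(ln$uid, ln$cl)
    rmap <- stats::setNames(rn$uid, rn$cl)
    combo <- paste(lcl, rcl)
    pr <- do.call(rbind, lapply(split(seq_along(combo), combo), function(jj) {
      lu <- lmap[as.character(lcl[jj[1]])]
      ru <- rmap[as.character(rcl[jj[1]])]
      if (is.na(lu) || is.na(ru)) return(NULL)
      data.frame(left_uid = unname(lu), right_uid = unname(ru),
                 rp = length(unique(p$read_id[jj])), kind = p$kind[1],
                 stringsAsFactors = FALSE)
    }))
    ln$cl <- NULL; rn$cl <- NULL
    all_nodes[[length(all_nodes) + 1L]] <- rbind(ln, rn)
    if (!is.null(pr)) all_pairings[[length(all_pairings) + 1L]] <- pr
  }
  if (length(all_nodes) == 0) return(empty)
  nodes <- do.call(rbind, all_nodes)
  pairings <- if (length(all_pairings)) do.call(rbind, all_pairings)
              else empty$pairings
  # drop pairing records below the pair-support threshold
  pairings <- pairings[pairings$rp >= params$min_pair_support, , drop = FALSE]
  rownames(nodes) <- NULL; rownames(pairings) <- NULL
  list(nodes = nodes, pairings = pairings)
}

# single-linkage 1-d clustering: cluster id per element, gaps > d split
linkage_clusters <- function(x, d) {
  o <- order(x)
  cid <- cumsum(c(1L, diff(x[o]) > d))
  cid[order(o)]
}

#' Paired links between split-junction nodes
#'
#' Split-read nodes sharing supporting reads are linked: a split read marks
#' two junction coordinates, so its signals fall into two nodes.
#'
#' @param split_nodes SPLIT-kind node rows (with `read_ids`).
#' @return Data frame `uid_i`, `uid_j`, `rp`.
#' @export
split_junction_links <- function(split_nodes) {
  empty <- data.frame(uid_i = character(), uid_j = character(),
                      rp = integer(), stringsAsFactors = FALSE)
  split_nodes <- split_nodes[split_nodes$kind == "SPLIT", , drop = FALSE]
  n <- nrow(split_nodes)
  if (n < 2) return(empty)
  id2nodes <- list()
  for (i in seq_len(n)) {
    for (rid in split_nodes$read_ids[[i]]) {
      id2nodes[[rid]] <- c(id2nodes[[rid]], i)
    }
  }
  cnt <- list()
  for (nodes_of_read in id2nodes) {
    nodes_of_read <- unique(nodes_of_read)
    if (length(nodes_of_read) < 2) next
    prs <- utils::combn(sort(nodes_of_read), 2)
    for (k in seq_len(ncol(prs))) {
      key <- paste(prs[1, k], prs[2, k])
      cnt[[key]] <- (cnt[[key]] %||% 0L) + 1L
    }
  }
  if (length(cnt) == 0) return(empty)
  ij <- do.call(rbind, strsplit(names(cnt), " "))
  data.frame(uid_i = split_nodes$uid[as.integer(ij[, 1])],
             uid_j = split_nodes$uid[as.integer(ij[, 2])],
             rp = unlist(cnt, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Assemble the signal graph
#'
#' Orders all nodes by `(contig, start, kind)`, creates paired (Epe) edges
#' from discordant pairing records and split-junction links, and one
#' adjacency (Eae) edge between every pair of consecutive same-contig
#' nodes. Parallel paired edges of different connection types between the
#' same node pair are all retained; pairing records whose endpoint was
#' filtered out are dropped (counted, not an error).
#'
#' @param nodes Node data frame (clip/split and discordant nodes, with
#'   `uid`).
#' @param pairings Pairing records from [cluster_discordant_signals()].
#' @param split_links Links from [split_junction_links()].
#' @param params A [csv_params()].
#' @return A `signal_graph`: `list(nodes, epe, eae)` with integer
#'   `node_id`s in position order.
#' @export
build_graph <- function(nodes, pairings = NULL, split_links = NULL,
                        params = csv_params()) {
  if (is.null(nodes) || nrow(nodes) == 0) {
    g <- list(nodes = cbind(node_id = integer(), empty_nodes()),
              epe = empty_epe(), eae = empty_eae(), dropped_edges = 0L)
    class(g) <- "signal_graph"
    return(g)
  }
  o <- order(nodes$contig, nodes$start, nodes$kind)
  nodes <- nodes[o, , drop = FALSE]
  nodes$node_id <- seq_len(nrow(nodes))
  rownames(nodes) <- NULL
  idmap <- stats::setNames(nodes$node_id, nodes$uid)

  edges <- list(); dropped <- 0L
  if (!is.null(pairings) && nrow(pairings)) {
    i <- idmap[pairings$left_uid]; j <- idmap[pairings$right_uid]
    ok <- !is.na(i) & !is.na(j) & i != j
    dropped <- dropped + sum(!ok)
    if (any(ok)) {
      edges[[1]] <- data.frame(
        node_i = pmin(i[ok], j[ok]), node_j = pmax(i[ok], j[ok]),
        rp = pairings$rp[ok],
        link_type = unname(LINK_TYPE_OF_KIND[pairings$kind[ok]]),
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(split_links) && nrow(split_links)) {
    i <- idmap[split_links$uid_i]; j <- idmap[split_links$uid_j]
    ok <- !is.na(i) & !is.na(j) & i != j
    dropped <- dropped + sum(!ok)
    if (any(ok)) {
      edges[[2]] <- data.frame(
        node_i = pmin(i[ok], j[ok]), node_j = pmax(i[ok], j[ok]),
        rp = split_links$rp[ok], link_type = "SPLIT",
        stringsAsFactors = FALSE)
    }
  }
  epe <- if (length(edges)) do.call(rbind, edges) else empty_epe()
  if (nrow(epe)) {
    # merge duplicates of the same connection type; keep parallel types
    key <- paste(epe$node_i, epe$node_j, epe$link_type)
    agg <- tapply(epe$rp, key, sum)
    first <- !duplicated(key)
    epe <- epe[first, , drop = FALSE]
    epe$rp <- as.integer(agg[paste(epe$node_i, epe$node_j, epe$link_type)])
    epe <- epe[order(epe$node_i, epe$node_j, epe$link_type), , drop = FALSE]
    rownames(epe) <- NULL
  }

  eae <- do.call(rbind, lapply(split(nodes$node_id, nodes$contig), function(ids) {
    if (length(ids) < 2) return(NULL)
    ids <- sort(ids)
    i <- ids[-length(ids)]; j <- ids[-1]
    data.frame(node_i = i, node_j = j,
               dist = pmax(nodes$start[j] - nodes$end[i], 0L))
  }))
  if (is.null(eae)) eae <- empty_eae()
  rownames(eae) <- NULL
  if (dropped > 0) {
    message(sprintf("build_graph: dropped %d edge record(s) with filtered endpoints",
                    dropped))
  }
  g <- list(nodes = nodes, epe = epe, eae = eae, dropped_edges = dropped)
  class(g) <- "signal_graph"
  g
}

empty_epe <- function() {
  data.frame(node_i = integer(), node_j = integer(), rp = integer(),
             link_type = character(), stringsAsFactors = FALSE)
}
empty_eae <- function() {
  data.frame(node_i = integer(), node_j = integer(), dist = integer())
}

#' @export
print.signal_graph <- function(x, ...) {
  cat(sprintf("signal graph: %d nodes, %d paired (Epe) edges, %d adjacent (Eae) edges\n",
              nrow(x$nodes), nrow(x$epe), nrow(x$eae)))
  if (nrow(x$nodes)) {
    tab <- table(x$nodes$kind)
    cat("  node kinds:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Validate signal-graph invariants
#'
#' Checks node ordering, edge endpoint resolution, the per-contig
#' adjacency path, and that paired-edge support never exceeds endpoint
#' weights. Used by tests; errors on violation.
#'
#' @param g A `signal_graph`.
#' @return `TRUE` invisibly.
#' @export
validate_signal_graph <- function(g) {
  n <- g$nodes
  stopifnot(identical(n$node_id, seq_len(nrow(n))))
  o <- order(n$contig, n$start, n$kind)
  stopifnot(identical(o, seq_len(nrow(n))))
  stopifnot(all(n$start <= n$end), all(n$weight >= 1))
  stopifnot(all(g$epe$node_i %in% n$node_id), all(g$epe$node_j %in% n$node_id))
  stopifnot(all(g$epe$rp >= 1))
  stopifnot(all(g$epe$rp <= pmin(n$weight[g$epe$node_i], n$weight[g$epe$node_j])))
  # Eae forms a simple path per contig
  for (ctg in unique(n$contig)) {
    ids <- n$node_id[n$contig == ctg]
    sub <- g$eae[g$eae$node_i %in% ids, , drop = FALSE]
    stopifnot(nrow(sub) == length(ids) - 1)
    if (nrow(sub)) {
      stopifnot(identical(sort(sub$node_i), ids[-length(ids)]),
                identical(sort(sub$node_j), ids[-1]),
                all(sub$dist >= 0))
    }
  }
  invisible(TRUE)
}

#' Serialize / restore a signal graph
#'
#' JSON dump (lossless round trip) and GraphML export for external
#' inspection. GraphML export requires the `igraph` package.
#'
#' @param g A `signal_graph`.
#' @param path Output file.
#' @return `path` invisibly; `read_signal_graph_json()` returns the graph.
#' @export
write_signal_graph_json <- function(g, path) {
  obj <- list(
    nodes = data.frame(node_id = g$nodes$node_id, kind = g$nodes$kind,
                       contig = g$nodes$contig, start = g$nodes$start,
                       end = g$nodes$end, weight = g$nodes$weight,
                       uid = g$nodes$uid, stringsAsFactors = FALSE),
    node_read_ids = lapply(g$nodes$read_ids, as.character),
    epe = g$epe, eae = g$eae, dropped_edges = g$dropped_edges)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_signal_graph_json
#' @export
read_signal_graph_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = FALSE)
  nodes <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
  rid <- obj$node_read_ids
  if (is.null(rid) || length(rid) == 0) rid <- rep(list(character()), nrow(nodes))
  nodes$read_ids <- I(lapply(rid, as.character))
  nodes <- nodes[, c("kind", "contig", "start", "end", "weight",
                     "read_ids", "uid", "node_id")]
  nodes$start <- as.integer(nodes$start); nodes$end <- as.integer(nodes$end)
  nodes$weight <- as.integer(nodes$weight)
  nodes$node_id <- as.integer(nodes$node_id)
  epe <- as.data.frame(obj$epe, stringsAsFactors = FALSE)
  eae <- as.data.frame(obj$eae, stringsAsFactors = FALSE)
  if (nrow(epe)) {
    epe$node_i <- as.integer(epe$node_i); epe$node_j <- as.integer(epe$node_j)
    epe$rp <- as.integer(epe$rp)
  } else epe <- empty_epe()
  if (nrow(eae)) {
    eae$node_i <- as.integer(eae$node_i); eae$node_j <- as.integer(eae$node_j)
    eae$dist <- as.integer(eae$dist)
  } else eae <- empty_eae()
  g <- list(nodes = nodes, epe = epe, eae = eae,
            dropped_edges = as.integer(obj$dropped_edges %||% 0L))
  class(g) <- "signal_graph"
  g
}

#' @rdname write_signal_graph_json
#' @export
write_signal_graph_graphml <- function(g, path) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("GraphML export requires the igraph package")
  }
  n <- g$nodes
  ed <- rbind(
    if (nrow(g$epe)) data.frame(from = g$epe$node_i, to = g$epe$node_j,
                                edge_class = "epe", rp = g$epe$rp,
                                link_type = g$epe$link_type, dist = NA_integer_),
    if (nrow(g$eae)) data.frame(from = g$eae$node_i, to = g$eae$node_j,
                                edge_class = "eae", rp = NA_integer_,
                                link_type = NA_character_, dist = g$eae$dist))
  vert <- data.frame(name = as.character(n$node_id), kind = n$kind,
                     contig = n$contig, start = n$start, end = n$end,
                     weight = n$weight, stringsAsFactors = FALSE)
  if (is.null(ed)) {
    ig <- igraph::graph_from_data_frame(
      data.frame(from = character(), to = character()),
      directed = FALSE, vertices = vert)
  } else {
    ed$from <- as.character(ed$from); ed$to <- as.character(ed$to)
    ig <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = vert)
  }
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}
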