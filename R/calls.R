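#' Convert a maximal subgraph into a CSV call
#'
#' The call boundary is the leftmost node start and rightmost node end of
#' the subgraph. The complexity score (CXS) is the number of distinct node
#' types multiplied by the number of induced paired (Epe) edges. The
#' connection-type set is the union of the induced Epe edge types plus the
#' node-kind-implied type of any adjacency (Eae) edge whose two endpoints
#' share an orientation-class kind (e.g. two same-orientation nodes joined
#' by an Eae edge contribute an Inv connection).
#'
#' @param g A `csv_subgraph` (or an integer vector of node ids).
#' @param graph The `signal_graph` the subgraph was mined from.
#' @return A list of class `csv_call` with fields `contig`, `start`,
#'   `end`, `cxs`, `link_types`, `n_node_types`, `n_epe`, `node_ids`,
#'   `node_kinds`, `epe`, `eae`.
#' @export
call_from_subgraph <- function(g, graph) {
  ids <- if (inherits(g, "csv_subgraph")) g$node_ids else as.integer(g)
  stopifnot(length(ids) >= 1)
  n <- graph$nodes
  epe <- graph$epe[graph$epe$node_i %in% ids & graph$epe$node_j %in% ids, ,
                   drop = FALSE]
  eae <- graph$eae[graph$eae$node_i %in% ids & graph$eae$node_j %in% ids, ,
                   drop = FALSE]
  kinds <- n$kind[ids]
  n_types <- length(unique(kinds))
  n_epe <- nrow(epe)
  lt <- unique(epe$link_type)
  if (nrow(eae)) {
    ki <- n$kind[eae$node_i]; kj <- n$kind[eae$node_j]
    orient <- c("ARP_RF", "ARP_FF", "ARP_RR")
    implied <- ki == kj & ki %in% orient
    lt <- unique(c(lt, unname(LINK_TYPE_OF_KIND[ki[implied]])))
  }
  structure(list(
    contig = n$contig[ids[1]],
    start = min(n$start[ids]),
    end = max(n$end[ids]),
    cxs = n_types * n_epe,
    link_types = sort(lt),
    n_node_types = n_types,
    n_epe = n_epe,
    node_ids = ids,
    node_kinds = kinds,
    node_pos_start = n$start[ids],
    node_pos_end = n$end[ids],
    epe = epe,
    eae = eae
  ), class = "csv_call")
}

#' @export
print.csv_call <- function(x, ...) {
  cat(sprintf("CSV call %s:%d-%d  CXS=%d  type=%s  (%d nodes, %d Epe)\n",
              x$contig, x$start, x$end, x$cxs, label_type(x),
              length(x$node_ids), x$n_epe))
  invisible(x)
}

#' Canonical type label of a CSV call
#'
#' Comma-joined, alphabetically sorted connection-type vocabulary, e.g.
#' `"Del,Inv"` or `"Dup,Ins"`.
#'
#' @param call A `csv_call` (or a character vector of connection types).
#' @return A single string.
#' @export
label_type <- function(call) {
  lt <- if (inherits(call, "csv_call")) call$link_types else call
  if (length(lt) == 0) return("")
  paste(sort(unname(LINK_LABELS[lt])), collapse = ",")
}

#' Filter calls by the number of distinct connection types
#'
#' Retains calls whose subgraph shows at least `min_link_types` distinct
#' edge connection types (default 2: the complex-only selection). Stable
#' order; idempotent.
#'
#' @param calls A list of `csv_call` objects.
#' @param min_link_types Minimum distinct connection types.
#' @return The filtered list.
#' @export
filter_csv <- function(calls, min_link_types = 2) {
  calls[vapply(calls, function(cl) length(cl$link_types) >= min_link_types,
               logical(1))]
}

#' Build the callset from a graph and its maximal subgraphs
#'
#' Subgraphs with no induced edge (isolated singletons) carry no
#' connection evidence and are skipped.
#'
#' @param graph A `signal_graph`.
#' @param subgraphs Output of [find_maximal_subgraphs()].
#' @param min_link_types Passed to [filter_csv()]; 1 keeps everything.
#' @return A list of `csv_call` objects sorted by `(contig, start)`.
#' @export
calls_from_graph <- function(graph, subgraphs, min_link_types = 1) {
  calls <- lapply(subgraphs, call_from_subgraph, graph = graph)
  calls <- calls[vapply(calls, function(cl) length(cl$link_types) > 0,
                        logical(1))]
  calls <- filter_csv(calls, min_link_types)
  ord <- order(vapply(calls, `[[`, character(1), "contig"),
               vapply(calls, `[[`, numeric(1), "start"))
  calls[ord]
}

#' Calls as a data frame
#'
#' @param calls A list of `csv_call` objects.
#' @return One row per call: `contig`, `start`, `end`, `cxs`, `label`,
#'   `n_node_types`, `n_epe`, `n_nodes`.
#' @export
calls_table <- function(calls) {
  if (length(calls) == 0) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), cxs = integer(), label = character(),
                      n_node_types = integer(), n_epe = integer(),
                      n_nodes = integer(), stringsAsFactors = FALSE))
  }
  data.frame(
    contig = vapply(calls, `[[`, character(1), "contig"),
    start = vapply(calls, `[[`, numeric(1), "start"),
    end = vapply(calls, `[[`, numeric(1), "end"),
    cxs = vapply(calls, `[[`, numeric(1), "cxs"),
    label = vapply(calls, label_type, character(1)),
    n_node_types = vapply(calls, `[[`, numeric(1), "n_node_types"),
    n_epe = vapply(calls, `[[`, numeric(1), "n_epe"),
    n_nodes = vapply(calls, function(cl) length(cl$node_ids), numeric(1)),
    stringsAsFactors = FALSE)
}

#' Component-level breakpoint intervals of a callset
#'
#' Every paired (Epe) edge of a call is a predicted breakpoint pair; its
#' genomic span (inner end of the left node to start of the right node) is
#' emitted as a component-level interval, alongside orientation-typed
#' adjacency edges and the call's outer interval. These intervals are the
#' prediction set for all-breakpoint evaluation.
#'
#' @param calls A list of `csv_call` objects.
#' @return Data frame `contig`, `start`, `end`, `call_id`, `source`.
#' @export
breakpoint_intervals <- function(calls) {
  out <- list()
  for (k in seq_along(calls)) {
    cl <- calls[[k]]
    out[[length(out) + 1L]] <- data.frame(
      contig = cl$contig, start = cl$start, end = cl$end,
      call_id = k, source = "outer", stringsAsFactors = FALSE)
    add_edge_spans <- function(ei, ej, src, graph_nodes = NULL) {
      lo <- pmin(ei, ej); hi <- pmax(ei, ej)
      data.frame(contig = cl$contig, start = lo, end = hi, call_id = k,
                 source = src, stringsAsFactors = FALSE)
    }
    if (nrow(cl$epe)) {
      # per-node breakpoint estimate is carried in the stored edge table
      ni <- cl$epe$node_i; nj <- cl$epe$node_j
      pos_i <- cl$node_pos_end[match(ni, cl$node_ids)]
      pos_j <- cl$node_pos_start[match(nj, cl$node_ids)]
      out[[length(out) + 1L]] <- add_edge_spans(pos_i, pos_j, "epe")
    }
    if (nrow(cl$eae)) {
      ki <- cl$node_kinds[match(cl$eae$node_i, cl$node_ids)]
      kj <- cl$node_kinds[match(cl$eae$node_j, cl$node_ids)]
      orient <- ki == kj & ki %in% c("ARP_RF", "ARP_FF", "ARP_RR")
      if (any(orient)) {
        pos_i <- cl$node_pos_end[match(cl$eae$node_i[orient], cl$node_ids)]
        pos_j <- cl$node_pos_start[match(cl$eae$node_j[orient], cl$node_ids)]
        out[[length(out) + 1L]] <- add_edge_spans(pos_i, pos_j, "eae")
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), call_id = integer(),
                      source = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a callset as VCF + BED + JSON sidecars
#'
#' The VCF (4.2) uses a symbolic `<CSV>` ALT with INFO keys `END`, `CXS`,
#' `LINKTYPES`, `NNODES`, `NEPE` and 1-based inclusive coordinates; the
#' BED sidecar keeps the internal 0-based half-open convention for
#' evaluation; the JSON sidecar stores the full per-call subgraph and
#' round-trips the callset exactly.
#'
#' @param calls A list of `csv_call` objects.
#' @param out_prefix Output prefix; writes `<prefix>.vcf`, `<prefix>.bed`,
#'   `<prefix>.json`.
#' @param contig_lengths Named integer vector of reference contig lengths
#'   (reference dictionary order).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_calls <- function(calls, out_prefix, contig_lengths) {
  stopifnot(length(contig_lengths) >= 1, !is.null(names(contig_lengths)))
  vcf <- paste0(out_prefix, ".vcf")
  bed <- paste0(out_prefix, ".bed")
  json <- paste0(out_prefix, ".json")

  tab <- calls_table(calls)
  # reference-dictionary order
  ord <- order(match(tab$contig, names(contig_lengths)), tab$start)
  calls <- calls[ord]; tab <- tab[ord, , drop = FALSE]

  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=graphsv",
    sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
            as.integer(contig_lengths)),
    "##ALT=<ID=CSV,Description=\"Complex structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=CXS,Number=1,Type=Integer,Description=\"Complexity score: distinct node types x paired edges\">",
    "##INFO=<ID=LINKTYPES,Number=.,Type=String,Description=\"Edge connection types of the subgraph\">",
    "##INFO=<ID=NNODES,Number=1,Type=Integer,Description=\"Number of signal nodes in the subgraph\">",
    "##INFO=<ID=NEPE,Number=1,Type=Integer,Description=\"Number of paired edges in the subgraph\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(0)
  if (nrow(tab)) {
    info <- sprintf("END=%d;SVTYPE=CSV;CXS=%d;LINKTYPES=%s;NNODES=%d;NEPE=%d",
                    as.integer(tab$end), as.integer(tab$cxs),
                    vapply(calls, function(cl)
                      paste(cl$link_types, collapse = ","), character(1)),
                    as.integer(tab$n_nodes), as.integer(tab$n_epe))
    rows <- sprintf("%s\t%d\t%s\tN\t<CSV>\t.\tPASS\t%s",
                    tab$contig, as.integer(tab$start) + 1L,
                    sprintf("csv_%d", seq_len(nrow(tab))), info)
  }
  writeLines(c(hdr, rows), vcf)

  bed_rows <- if (nrow(tab)) {
    sprintf("%s\t%d\t%d\tcsv_%d\t%d\t%s", tab$contig, as.integer(tab$start),
            as.integer(tab$end), seq_len(nrow(tab)), as.integer(tab$cxs),
            tab$label)
  } else character(0)
  writeLines(bed_rows, bed)

  jcalls <- lapply(seq_along(calls), function(k) {
    cl <- calls[[k]]
    list(id = sprintf("csv_%d", k), contig = cl$contig,
         start = cl$start, end = cl$end, cxs = cl$cxs,
         link_types = as.list(cl$link_types),
         n_node_types = cl$n_node_types, n_epe = cl$n_epe,
         node_ids = cl$node_ids, node_kinds = as.list(cl$node_kinds),
         node_pos_start = cl$node_pos_start,
         node_pos_end = cl$node_pos_end,
         epe = cl$epe, eae = cl$eae)
  })
  jsonlite::write_json(jcalls, json, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(vcf = vcf, bed = bed, json = json))
}

#' Read a callset back from its JSON sidecar
#'
#' @param path Path written by [write_calls()].
#' @return A list of `csv_call` objects.
#' @export
read_calls_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  edge_df <- function(x, cols, types) {
    if (length(x) == 0 || length(x[[1]]) == 0) {
      return(if ("rp" %in% cols) empty_epe() else empty_eae())
    }
    out <- lapply(seq_along(cols), function(k)
      types[[k]](unlist(x[[cols[k]]])))
    names(out) <- cols
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  lapply(obj, function(rec) {
    structure(list(
      contig = rec$contig, start = as.integer(rec$start),
      end = as.integer(rec$end), cxs = as.integer(rec$cxs),
      link_types = sort(as.character(unlist(rec$link_types))),
      n_node_types = as.integer(rec$n_node_types),
      n_epe = as.integer(rec$n_epe),
      node_ids = as.integer(unlist(rec$node_ids)),
      node_kinds = as.character(unlist(rec$node_kinds)),
      node_pos_start = as.integer(unlist(rec$node_pos_start)),
      node_pos_end = as.integer(unlist(rec$node_pos_end)),
      epe = edge_df(rec$epe, c("node_i", "node_j", "rp", "link_type"),
                    list(as.integer, as.integer, as.integer, as.character)),
      eae = edge_df(rec$eae, c("node_i", "node_j", "dist"),
                    list(as.integer, as.integer, as.integer))),
      class = "csv_call")
  })
}
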