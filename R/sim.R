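#' Simulation configuration
#'
#' Study conditions for the bundled rearrangement simulator: a synthetic
#' reference, implanted basic operations and their compositions on two
#' haplotypes, and paired-end reads.
#'
#' @param genome_length Reference length in bp (>= 100 kb).
#' @param gc_fraction Target GC content of the synthetic reference.
#' @param n_events Number of implanted CSV events.
#' @param coverage Total (diploid) fold coverage.
#' @param read_length Read length in bp.
#' @param insert_mean,insert_sd Fragment-length distribution (bp); the mean
#'   must exceed twice the read length.
#' @param base_error_rate Per-base substitution error rate of simulated
#'   reads.
#' @param seed Integer seed fixing all randomness.
#' @param mode `"reported"` draws event types from the built-in catalog of
#'   published CSV classes; `"randomized"` composes 2-4 random basic
#'   operations per locus.
#' @param zygosity `"het"` implants each event on one random haplotype,
#'   `"hom"` on both.
#' @param align_mode `"truth_guided"` places reads by inverting the
#'   variant map; `"external_aligner"` shells out to a user-provided
#'   aligner command.
#' @param contig Name of the simulated contig.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 2e6, gc_fraction = 0.5,
                       n_events = 50, coverage = 30, read_length = 100,
                       insert_mean = 500, insert_sd = 50,
                       base_error_rate = 0.01, seed = 1,
                       mode = c("reported", "randomized"),
                       zygosity = c("het", "hom"),
                       align_mode = c("truth_guided", "external_aligner"),
                       contig = "simchr") {
  mode <- match.arg(mode)
  zygosity <- match.arg(zygosity)
  align_mode <- match.arg(align_mode)
  stopifnot(coverage > 0, read_length > 0,
            insert_mean > 2 * read_length, insert_sd >= 0,
            base_error_rate >= 0, base_error_rate < 1,
            n_events >= 1, gc_fraction > 0, gc_fraction < 1)
  structure(list(genome_length = as.integer(genome_length),
                 gc_fraction = gc_fraction, n_events = as.integer(n_events),
                 coverage = coverage, read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 base_error_rate = base_error_rate, seed = as.integer(seed),
                 mode = mode, zygosity = zygosity, align_mode = align_mode,
                 contig = contig), class = "sim_config")
}

#' Generate a synthetic reference sequence
#'
#' I.i.d. bases at the configured GC fraction, fully determined by the
#' configuration seed. Optionally written as FASTA with a `.fai` index.
#'
#' @param config A [sim_config()].
#' @param fasta_path Optional output FASTA path.
#' @return A [Biostrings::DNAStringSet] with one contig; the path is
#'   attached as attribute `path` when written.
#' @export
make_reference <- function(config, fasta_path = NULL) {
  if (config$genome_length < 1e5) {
    stop("genome_length must be at least 100 kb")
  }
  set.seed(config$seed + 11L)
  gc <- config$gc_fraction
  codes <- sample.int(4L, config$genome_length, replace = TRUE,
                      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  ref <- Biostrings::DNAStringSet(intToUtf8(c(65L, 67L, 71L, 84L)[codes]))
  names(ref) <- config$contig
  if (!is.null(fasta_path)) {
    Biostrings::writeXStringSet(ref, fasta_path)
    Rsamtools::indexFa(fasta_path)
    attr(ref, "path") <- fasta_path
  }
  ref
}

# log-uniform draw
runif_log <- function(n, lo, hi) round(exp(stats::runif(n, log(lo), log(hi))))

# ---- catalog of reported CSV classes -------------------------------------
#
# Each builder returns, in window-relative coordinates:
#   pieces:     data.frame(ref_start, ref_end, strand, novel_len) replacing
#               the window [0, W)
#   components: data.frame(type, start, end) - the breakpoint pairs each
#               basic operation creates on the reference
#   width:      W
# Dispersed operations contribute their source-edge-to-insertion-site
# junction spans; interval operations contribute their reference interval.

piece <- function(s, e, strand = "+", novel = 0L) {
  data.frame(ref_start = s, ref_end = e, strand = strand,
             novel_len = as.integer(novel), stringsAsFactors = FALSE)
}
novel_piece <- function(len) piece(NA_integer_, NA_integer_, "+", len)
comp <- function(type, s, e) {
  data.frame(type = type, start = as.integer(s), end = as.integer(e),
             stringsAsFactors = FALSE)
}

# the reported-CSV vocabulary drawn from in `mode = "reported"`; the
# catalog additionally offers the basic operations for targeted implants
REPORTED_CSV_TYPES <- c("Disdup", "Invdup", "DelInv", "DelDisdup",
                        "DelInvdup", "DisdupInvdup", "InsInv", "Tantrans",
                        "DelSpaDel", "TanDisdup")

csv_catalog <- function() {
  list(
    Del = function() {
      l <- runif_log(1, 300, 3000)
      list(pieces = piece(0, 0), components = comp("Del", 0, l), width = l)
    },
    Inv = function() {
      l <- runif_log(1, 300, 3000)
      list(pieces = piece(0, l, "-"), components = comp("Inv", 0, l),
           width = l)
    },
    Tandup = function() {
      l <- runif_log(1, 300, 3000)
      list(pieces = rbind(piece(0, l), piece(0, l)),
           components = comp("Tandup", 0, l), width = l)
    },
    Disdup = function() {
      s <- runif_log(1, 200, 1500); d <- runif_log(1, 500, 4000); p <- s + d
      list(pieces = rbind(piece(0, p), piece(0, s)),
           components = rbind(comp("Disdup", 0, p), comp("Disdup", s, p)),
           width = p)
    },
    Invdup = function() {
      s <- runif_log(1, 200, 1500); d <- runif_log(1, 500, 4000); p <- s + d
      list(pieces = rbind(piece(0, p), piece(0, s, "-")),
           components = rbind(comp("Invdup", s, p), comp("Invdup", 0, p)),
           width = p)
    },
    DelInv = function() {
      d <- runif_log(1, 200, 2000); v <- runif_log(1, 200, 2000)
      list(pieces = piece(d, d + v, "-"),
           components = rbind(comp("Del", 0, d), comp("Inv", d, d + v)),
           width = d + v)
    },
    DelDisdup = function() {   # cut-and-paste: segment excised, copy at p
      d <- runif_log(1, 200, 2000); dd <- runif_log(1, 500, 4000); p <- d + dd
      list(pieces = rbind(piece(d, p), piece(0, d)),
           components = rbind(comp("Del", 0, d), comp("Disdup", 0, p),
                              comp("Disdup", d, p)),
           width = p)
    },
    DelInvdup = function() {   # cut-and-paste with inverted reinsertion
      d <- runif_log(1, 200, 2000); dd <- runif_log(1, 500, 4000); p <- d + dd
      list(pieces = rbind(piece(d, p), piece(0, d, "-")),
           components = rbind(comp("Del", 0, d), comp("Invdup", 0, p),
                              comp("Invdup", d, p)),
           width = p)
    },
    DisdupInvdup = function() {
      s <- runif_log(1, 200, 1500); d <- runif_log(1, 500, 4000); p <- s + d
      list(pieces = rbind(piece(0, p), piece(0, s), piece(0, s, "-")),
           components = rbind(comp("Disdup", 0, p), comp("Invdup", s, s),
                              comp("Invdup", 0, p)),
           width = p)
    },
    InsInv = function() {      # novel insertion, short spacer, inversion
      l <- runif_log(1, 100, 300); g <- runif_log(1, 150, 400)
      v <- runif_log(1, 200, 2000)
      list(pieces = rbind(novel_piece(l), piece(0, g), piece(g, g + v, "-")),
           components = rbind(comp("Ins", 0, 0), comp("Inv", g, g + v)),
           width = g + v)
    },
    Tantrans = function() {    # adjacent segment swap: AB -> BA
      a <- runif_log(1, 200, 1500); b <- runif_log(1, 200, 1500)
      list(pieces = rbind(piece(a, a + b), piece(0, a)),
           components = rbind(comp("Tantrans", 0, a),
                              comp("Tantrans", a, a + b),
                              comp("Tantrans", 0, a + b)),
           width = a + b)
    },
    DelSpaDel = function() {   # two deletions around an inverted spacer
      d1 <- runif_log(1, 200, 2000); sp <- runif_log(1, 50, 500)
      d2 <- runif_log(1, 200, 2000)
      list(pieces = piece(d1, d1 + sp, "-"),
           components = rbind(comp("Del", 0, d1),
                              comp("spacer", d1, d1 + sp),
                              comp("Del", d1 + sp, d1 + sp + d2)),
           width = d1 + sp + d2)
    },
    TanDisdup = function() {   # two tandem copies at a dispersed site
      s <- runif_log(1, 200, 1500); d <- runif_log(1, 500, 4000); p <- s + d
      list(pieces = rbind(piece(0, p), piece(0, s), piece(0, s)),
           components = rbind(comp("Disdup", 0, p), comp("Tandup", 0, s),
                              comp("Disdup", s, p)),
           width = p)
    }
  )
}

# randomized mode: compose 2-4 basic operations left to right in a window
random_csv_plan <- function() {
  ops <- sample(c("Del", "Inv", "Invdup", "Tandup", "Disdup"),
                sample(2:4, 1), replace = TRUE)
  cur <- 0L; pieces <- list(); comps <- list(); pending <- list()
  for (op in ops) {
    l <- runif_log(1, 100, 5000)
    if (op == "Del") {
      comps[[length(comps) + 1L]] <- comp("Del", cur, cur + l)
    } else if (op == "Inv") {
      pieces[[length(pieces) + 1L]] <- piece(cur, cur + l, "-")
      comps[[length(comps) + 1L]] <- comp("Inv", cur, cur + l)
    } else if (op == "Tandup") {
      pieces[[length(pieces) + 1L]] <- piece(cur, cur + l)
      pieces[[length(pieces) + 1L]] <- piece(cur, cur + l)
      comps[[length(comps) + 1L]] <- comp("Tandup", cur, cur + l)
    } else if (op == "Invdup") {
      pieces[[length(pieces) + 1L]] <- piece(cur, cur + l)
      pieces[[length(pieces) + 1L]] <- piece(cur, cur + l, "-")
      comps[[length(comps) + 1L]] <- comp("Invdup", cur, cur + l)
    } else {                   # Disdup: copy reinserted at the window end
      pieces[[length(pieces) + 1L]] <- piece(cur, cur + l)
      pending[[length(pending) + 1L]] <- c(cur, cur + l)
      cur <- cur + l
      next
    }
    cur <- cur + l
    g <- runif_log(1, 50, 300)   # retained spacer between operations
    pieces[[length(pieces) + 1L]] <- piece(cur, cur + g)
    cur <- cur + g
  }
  w <- cur
  for (src in pending) {
    pieces[[length(pieces) + 1L]] <- piece(src[1], src[2])
    comps[[length(comps) + 1L]] <- comp("Disdup", src[1], w)
    comps[[length(comps) + 1L]] <- comp("Disdup", src[2], w)
  }
  list(pieces = do.call(rbind, pieces), components = do.call(rbind, comps),
       width = w, type = paste(ops, collapse = "+"))
}

#' Implant CSVs on two haplotypes
#'
#' Draws event types (uniformly from the reported catalog, or random
#' compositions in randomized mode), places them with at least 10 kb
#' spacing, and applies each to one (het) or both (hom) haplotypes. Each
#' haplotype is represented by a variant map: an ordered segment table
#' mapping haplotype intervals back to reference intervals (with strand)
#' or to novel sequence.
#'
#' @param reference A [Biostrings::DNAStringSet] from [make_reference()].
#' @param config A [sim_config()].
#' @param types Optional character vector overriding the drawn catalog
#'   types (recycled to `n_events`).
#' @return `list(hap_maps, novel_seqs, truth, plans, config)`; `truth` is
#'   the benchmark table with a `components` list column.
#' @export
implant_csvs <- function(reference, config, types = NULL) {
  set.seed(config$seed + 22L)
  glen <- config$genome_length
  n <- config$n_events
  catalog <- csv_catalog()
  if (config$mode == "reported") {
    type_names <- if (is.null(types)) {
      sample(REPORTED_CSV_TYPES, n, replace = TRUE)
    } else rep_len(types, n)
    stopifnot(all(type_names %in% names(catalog)))
  }
  plans <- vector("list", n)
  slot_w <- glen %/% n
  novel_seqs <- list()
  for (i in seq_len(n)) {
    if (config$mode == "reported") {
      pl <- catalog[[type_names[i]]]()
      pl$type <- type_names[i]
    } else {
      pl <- random_csv_plan()
    }
    room <- slot_w - pl$width - 10000L
    if (room < 1) {
      stop(sprintf(paste0("event %d (%s, width %d bp) does not fit: ",
                          "slots of %d bp cannot hold it with 10 kb spacing"),
                   i, pl$type, pl$width, slot_w))
    }
    anchor <- (i - 1L) * slot_w + 5000L + floor(stats::runif(1) * (room - 1))
    pl$anchor <- as.integer(anchor)
    pl$window <- c(anchor, anchor + pl$width)
    pl$components$start <- pl$components$start + pl$anchor
    pl$components$end <- pl$components$end + pl$anchor
    abs_pieces <- pl$pieces
    mapped <- !is.na(abs_pieces$ref_start)
    abs_pieces$ref_start[mapped] <- abs_pieces$ref_start[mapped] + pl$anchor
    abs_pieces$ref_end[mapped] <- abs_pieces$ref_end[mapped] + pl$anchor
    abs_pieces$novel_id <- NA_integer_
    for (k in which(!mapped)) {
      novel_seqs[[length(novel_seqs) + 1L]] <-
        paste(sample(c("A", "C", "G", "T"), abs_pieces$novel_len[k],
                     replace = TRUE), collapse = "")
      abs_pieces$novel_id[k] <- length(novel_seqs)
    }
    pl$pieces <- abs_pieces
    pl$haps <- if (config$zygosity == "hom") c(1L, 2L) else sample(1:2, 1)
    plans[[i]] <- pl
  }

  hap_maps <- lapply(1:2, function(h) {
    build_hap_map(plans[vapply(plans, function(p) h %in% p$haps, logical(1))],
                  glen)
  })
  truth <- data.frame(
    contig = config$contig,
    start = vapply(plans, function(p) min(p$components$start), integer(1)),
    end = vapply(plans, function(p) max(p$components$end), integer(1)),
    name = sprintf("ev%03d_%s", seq_len(n),
                   vapply(plans, `[[`, character(1), "type")),
    zygosity = config$zygosity,
    stringsAsFactors = FALSE)
  truth$components <- I(lapply(plans, `[[`, "components"))
  list(hap_maps = hap_maps, novel_seqs = novel_seqs, truth = truth,
       plans = plans, config = config)
}

# ordered segment table for one haplotype
build_hap_map <- function(plans, glen) {
  rows <- list(); cursor <- 0L
  for (pl in plans) {
    w0 <- pl$window[1]; w1 <- pl$window[2]
    if (w0 > cursor) rows[[length(rows) + 1L]] <- cbind(piece(cursor, w0),
                                                        novel_id = NA_integer_)
    rows[[length(rows) + 1L]] <- pl$pieces
    cursor <- w1
  }
  if (cursor < glen) rows[[length(rows) + 1L]] <- cbind(piece(cursor, glen),
                                                        novel_id = NA_integer_)
  seg <- do.call(rbind, rows)
  wid <- ifelse(is.na(seg$ref_start), seg$novel_len,
                seg$ref_end - seg$ref_start)
  seg <- seg[wid > 0, , drop = FALSE]
  # merge reference-contiguous forward neighbours so that segment borders
  # correspond to actual breakpoints only
  if (nrow(seg) > 1) {
    keep <- rep(TRUE, nrow(seg))
    for (i in 2:nrow(seg)) {
      j <- max(which(keep[1:(i - 1)]))
      if (!is.na(seg$ref_start[i]) && !is.na(seg$ref_start[j]) &&
          seg$strand[i] == "+" && seg$strand[j] == "+" &&
          seg$ref_end[j] == seg$ref_start[i]) {
        seg$ref_end[j] <- seg$ref_end[i]
        keep[i] <- FALSE
      }
    }
    seg <- seg[keep, , drop = FALSE]
  }
  wid <- ifelse(is.na(seg$ref_start), seg$novel_len,
                seg$ref_end - seg$ref_start)
  seg$hap_end <- cumsum(as.numeric(wid))
  seg$hap_start <- seg$hap_end - wid
  rownames(seg) <- NULL
  seg
}

#' Haplotype sequence from a variant map
#'
#' @param reference Reference [Biostrings::DNAStringSet].
#' @param map A segment table from [implant_csvs()].
#' @param novel_seqs Novel-sequence list from [implant_csvs()].
#' @return A character string with the haplotype sequence.
#' @export
haplotype_seq <- function(reference, map, novel_seqs) {
  refchar <- as.character(reference[[1]])
  chunks <- character(nrow(map))
  for (i in seq_len(nrow(map))) {
    if (!is.na(map$novel_id[i])) {
      chunks[i] <- novel_seqs[[map$novel_id[i]]]
    } else {
      s <- substr(refchar, map$ref_start[i] + 1L, map$ref_end[i])
      if (map$strand[i] == "-") {
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      }
      chunks[i] <- s
    }
  }
  paste(chunks, collapse = "")
}
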