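#' Simulate paired-end reads from the implanted haplotypes
#'
#' wgsim-style sampling: fragment starts are uniform per haplotype,
#' fragment lengths normal with the configured mean/sd (truncated at twice
#' the read length plus 10 bp), and both fragment ends yield a read. The
#' pair count is `coverage * total haplotype length / (2 * 2 *
#' read_length)`, split across haplotypes by length. Sequences (with
#' i.i.d. substitution errors at `base_error_rate`) are materialized only
#' when FASTQ output is requested; the fragment table alone drives
#' [truth_guided_align()].
#'
#' @param implant Output of [implant_csvs()].
#' @param config A [sim_config()] (defaults to the one in `implant`).
#' @param fastq_prefix Optional path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @param reference Reference sequence, required only for FASTQ output.
#' @return `list(fragments, n_pairs, fastq)`; `fragments` has columns
#'   `id`, `hap`, `start`, `len` (0-based haplotype coordinates).
#' @export
simulate_reads <- function(implant, config = implant$config,
                           fastq_prefix = NULL, reference = NULL) {
  rl <- config$read_length
  if (config$insert_mean < 2 * rl) {
    stop("insert_mean must be at least twice the read length")
  }
  set.seed(config$seed + 33L)
  hap_len <- vapply(implant$hap_maps, function(m) max(m$hap_end), numeric(1))
  total <- sum(hap_len)
  n_pairs <- round(config$coverage * total / (4 * rl))
  n1 <- round(n_pairs * hap_len[1] / total)
  n_h <- c(n1, n_pairs - n1)
  frags <- do.call(rbind, lapply(1:2, function(h) {
    n <- n_h[h]
    if (n == 0) return(NULL)
    len <- round(stats::rnorm(n, config$insert_mean, config$insert_sd))
    len <- pmax(len, 2 * rl + 10)
    len <- pmin(len, hap_len[h])
    start <- floor(stats::runif(n) * (hap_len[h] - len + 1))
    data.frame(hap = h, start = start, len = as.integer(len))
  }))
  frags$id <- sprintf("f%07d", seq_len(nrow(frags)))
  rownames(frags) <- NULL
  fastq <- NULL
  if (!is.null(fastq_prefix)) {
    if (is.null(reference)) stop("FASTQ output requires the reference")
    fastq <- write_sim_fastq(frags, implant, config, reference, fastq_prefix)
  }
  list(fragments = frags[, c("id", "hap", "start", "len")],
       n_pairs = nrow(frags), fastq = fastq)
}

write_sim_fastq <- function(frags, implant, config, reference, prefix) {
  rl <- config$read_length
  hseq <- lapply(1:2, function(h)
    haplotype_seq(reference, implant$hap_maps[[h]], implant$novel_seqs))
  r1 <- character(nrow(frags)); r2 <- character(nrow(frags))
  for (h in 1:2) {
    ii <- which(frags$hap == h)
    if (!length(ii)) next
    s <- frags$start[ii]
    r1[ii] <- substring(hseq[[h]], s + 1, s + rl)
    r2raw <- substring(hseq[[h]], s + frags$len[ii] - rl + 1, s + frags$len[ii])
    r2[ii] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(r2raw)))
  }
  r1 <- inject_errors(r1, rl, config$base_error_rate)
  r2 <- inject_errors(r2, rl, config$base_error_rate)
  qual <- strrep("I", rl)
  names1 <- sprintf("@%s_%d_%.0f_%d/1", frags$id, frags$hap, frags$start,
                    frags$len)
  names2 <- sub("/1$", "/2", names1)
  f1 <- paste0(prefix, "_1.fastq"); f2 <- paste0(prefix, "_2.fastq")
  writeLines(as.vector(rbind(names1, r1, "+", qual)), f1)
  writeLines(as.vector(rbind(names2, r2, "+", qual)), f2)
  c(f1, f2)
}

# i.i.d. substitution errors; per read the error count is binomial and
# positions are drawn uniformly (rare within-read position collisions
# merge, marginally lowering the realized rate)
inject_errors <- function(reads, rl, rate) {
  if (rate <= 0 || length(reads) == 0) return(reads)
  nerr <- stats::rbinom(length(reads), rl, rate)
  tot <- sum(nerr)
  if (tot == 0) return(reads)
  idx <- rep.int(seq_along(reads), nerr)
  pos <- ceiling(stats::runif(tot) * rl)
  alt <- c("A" = "CGT", "C" = "AGT", "G" = "ACT", "T" = "ACG")
  cur <- substring(reads[idx], pos, pos)
  pick <- ceiling(stats::runif(tot) * 3)
  newb <- substring(alt[cur], pick, pick)
  newb[is.na(newb) | newb == ""] <- "N"
  for (p in sort(unique(pos))) {
    sel <- pos == p
    ri <- idx[sel]
    x <- reads[ri]
    substr(x, p, p) <- newb[sel]
    reads[ri] <- x
  }
  reads
}

# parse wgsim-style simulated read names back into a fragment table
parse_fastq_fragments <- function(fq1) {
  con <- file(fq1, "r"); on.exit(close(con))
  names <- character(0); chunk <- 400000L
  repeat {
    lines <- readLines(con, n = chunk)
    if (length(lines) == 0) break
    names <- c(names, lines[seq(1, length(lines), by = 4)])
  }
  m <- regmatches(names,
                  regexec("^@(f[0-9]+)_([12])_([0-9]+)_([0-9]+)(/[12])?$",
                          names))
  bad <- vapply(m, length, integer(1)) == 0
  if (any(bad)) stop("unparsable simulated read name: ", names[which(bad)[1]])
  data.frame(id = vapply(m, `[`, character(1), 2),
             hap = as.integer(vapply(m, `[`, character(1), 3)),
             start = as.numeric(vapply(m, `[`, character(1), 4)),
             len = as.integer(vapply(m, `[`, character(1), 5)),
             stringsAsFactors = FALSE)
}
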