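#' Place simulated reads on the reference through the variant map
#'
#' Maps every read from haplotype coordinates back to the reference using
#' the implant's segment table: reads inside one segment become full-length
#' alignments; reads spanning a breakpoint are emitted as soft-clipped
#' records, with a supplementary (split) alignment and `SA` tags when the
#' secondary piece is at least `min_split_len` bp; pairs straddling
#' rearranged segments acquire the discordant orientations and template
#' lengths the rearrangement implies. Reads falling wholly inside novel
#' sequence are emitted unmapped (or dropped when both mates are). Output
#' is a coordinate-sorted, indexed BAM.
#'
#' In `external_aligner` mode use the FASTQ output of [simulate_reads()]
#' with your own aligner instead; this function implements the
#' dependency-free route.
#'
#' @param x A fragment table from [simulate_reads()], or a character
#'   vector of the two FASTQ paths (read names are parsed back into
#'   fragments).
#' @param implant Output of [implant_csvs()].
#' @param bam_prefix Output prefix; creates `<prefix>.bam` and its index.
#' @param config A [sim_config()].
#' @param min_split_len Minimum secondary-piece length (bp) for a
#'   supplementary alignment.
#' @return Path to the sorted BAM file.
#' @export
truth_guided_align <- function(x, implant, bam_prefix,
                               config = implant$config,
                               min_split_len = 30L) {
  frags <- if (is.character(x)) parse_fastq_fragments(x[1]) else x
  rl <- config$read_length
  n <- nrow(frags)
  stopifnot(n > 0)

  # two reads per fragment; `rev` marks reverse-complement of haplotype
  reads <- data.frame(
    fi = rep(seq_len(n), 2),
    readno = rep(c(1L, 2L), each = n),
    hap = rep(frags$hap, 2),
    a = c(frags$start, frags$start + frags$len - rl),
    rev = rep(c(FALSE, TRUE), each = n))
  reads$b <- reads$a + rl

  m <- nrow(reads)
  mapped <- logical(m)
  pos0 <- rep(NA_real_, m); refrev <- logical(m)
  cigar <- rep(NA_character_, m); refw <- rep(NA_integer_, m)
  spos0 <- rep(NA_real_, m); srefrev <- logical(m)
  scigar <- rep(NA_character_, m); srefw <- rep(NA_integer_, m)

  for (h in 1:2) {
    segs <- implant$hap_maps[[h]]
    ii <- which(reads$hap == h)
    if (!length(ii)) next
    hs <- segs$hap_start
    i1 <- findInterval(reads$a[ii], hs)
    i2 <- findInterval(reads$b[ii] - 1, hs)
    plain <- i1 == i2 & is.na(segs$novel_id[i1])
    pi <- ii[plain]; k <- i1[plain]
    if (length(pi)) {
      off <- reads$a[pi] - segs$hap_start[k]
      plus <- segs$strand[k] == "+"
      pos0[pi] <- ifelse(plus, segs$ref_start[k] + off,
                         segs$ref_end[k] - off - rl)
      refrev[pi] <- xor(reads$rev[pi], !plus)
      cigar[pi] <- sprintf("%dM", rl)
      refw[pi] <- rl
      mapped[pi] <- TRUE
    }
    for (t in which(!plain)) {
      jj <- ii[t]
      res <- map_read_pieces(reads$a[jj], reads$b[jj], reads$rev[jj],
                             i1[t], i2[t],
                             segs, rl, min_split_len)
      if (is.null(res)) next
      mapped[jj] <- TRUE
      pos0[jj] <- res$pos0; refrev[jj] <- res$refrev
      cigar[jj] <- res$cigar; refw[jj] <- res$refw
      if (!is.null(res$supp)) {
        spos0[jj] <- res$supp$pos0; srefrev[jj] <- res$supp$refrev
        scigar[jj] <- res$supp$cigar; srefw[jj] <- res$supp$refw
      }
    }
  }

  # pair bookkeeping on primary alignments
  i1v <- seq_len(n); i2v <- n + seq_len(n)
  m1 <- mapped[i1v]; m2 <- mapped[i2v]
  keep_pair <- m1 | m2
  p1 <- pos0[i1v]; p2 <- pos0[i2v]
  e1 <- p1 + refw[i1v]; e2 <- p2 + refw[i2v]
  both <- m1 & m2
  tl <- ifelse(both, pmax(e1, e2, na.rm = FALSE) - pmin(p1, p2), 0)
  r1_left <- both & (p1 < p2 | (p1 == p2 & !refrev[i1v]))
  fr <- both & ifelse(r1_left,
                      !refrev[i1v] & refrev[i2v],
                      !refrev[i2v] & refrev[i1v])
  proper <- both & fr & tl >= 2 * rl &
    tl <= config$insert_mean + 4 * config$insert_sd
  # unmapped mate is placed at its mate's coordinate
  p1[!m1] <- p2[!m1]; p2[!m2] <- p1[!m2]

  flag_of <- function(self, mate, me_m, mate_m, first) {
    fl <- 1L + if (first) 64L else 128L
    fl <- fl + ifelse(proper, 2L, 0L)
    fl <- fl + ifelse(me_m, 0L, 4L) + ifelse(mate_m, 0L, 8L)
    fl <- fl + ifelse(me_m & refrev[self], 16L, 0L)
    fl <- fl + ifelse(mate_m & refrev[mate], 32L, 0L)
    fl
  }
  f1 <- flag_of(i1v, i2v, m1, m2, TRUE)
  f2 <- flag_of(i2v, i1v, m2, m1, FALSE)
  t1 <- ifelse(both, ifelse(r1_left, tl, -tl), 0)
  t2 <- ifelse(both, -t1, 0)

  ctg <- config$contig
  sa_str <- function(idx, pos, rev, cig) {
    sprintf("\tSA:Z:%s,%.0f,%s,%s,60,0;", ctg, pos[idx] + 1,
            ifelse(rev[idx], "-", "+"), cig[idx])
  }
  has_supp <- !is.na(scigar)
  opt1 <- ifelse(has_supp[i1v], sa_str(i1v, spos0, srefrev, scigar), "")
  opt2 <- ifelse(has_supp[i2v], sa_str(i2v, spos0, srefrev, scigar), "")

  qn <- frags$id
  mk_line <- function(idx, fl, tlen, opt) {
    sprintf("%s\t%d\t%s\t%.0f\t%d\t%s\t=\t%.0f\t%.0f\t*\t*%s",
            qn, fl, ctg, pos0[idx] + 1,
            ifelse(mapped[idx], 60L, 0L),
            ifelse(mapped[idx], cigar[idx], "*"),
            pos0[if (identical(idx, i1v)) i2v else i1v] + 1,
            tlen, opt)
  }
  # rewrite unmapped coordinates before formatting
  pos0[i1v] <- p1; pos0[i2v] <- p2
  l1 <- mk_line(i1v, f1, t1, opt1)[keep_pair]
  l2 <- mk_line(i2v, f2, t2, opt2)[keep_pair]

  sup_idx <- which(has_supp & mapped & keep_pair[reads$fi])
  sup_lines <- character(0)
  if (length(sup_idx)) {
    first <- sup_idx <= n
    mate_idx <- ifelse(first, sup_idx + n, sup_idx - n)
    sfl <- 1L + 2048L + ifelse(first, 64L, 128L) +
      ifelse(proper[reads$fi[sup_idx]], 2L, 0L) +
      ifelse(srefrev[sup_idx], 16L, 0L) +
      ifelse(mapped[mate_idx], ifelse(refrev[mate_idx], 32L, 0L), 8L)
    sup_lines <- sprintf(
      "%s\t%d\t%s\t%.0f\t60\t%s\t=\t%.0f\t0\t*\t*%s",
      qn[reads$fi[sup_idx]], sfl, ctg,
      spos0[sup_idx] + 1, scigar[sup_idx], pos0[mate_idx] + 1,
      sa_str(sup_idx, pos0, refrev, cigar))
  }

  sam <- paste0(bam_prefix, ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", ctg, config$genome_length))
  writeLines(c(hdr, l1, l2, sup_lines), sam)
  bam <- Rsamtools::asBam(sam, bam_prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

# map a breakpoint-spanning (or novel-overlapping) read; returns primary
# and optional supplementary placement, or NULL when nothing maps
map_read_pieces <- function(a, b, rev, k1, k2, segs, rl, min_split_len) {
  ks <- k1:k2
  plen <- q1 <- r1 <- r2 <- integer(0); prev <- logical(0)
  lc <- rc <- integer(0)
  for (k in ks) {
    if (is.na(segs$novel_id[k])) ok <- TRUE else ok <- FALSE
    hs <- max(a, segs$hap_start[k]); he <- min(b, segs$hap_end[k])
    pl <- he - hs
    if (pl <= 0 || !ok) next
    qa <- hs - a; qb <- he - a
    if (segs$strand[k] == "+") {
      rs <- segs$ref_start[k] + (hs - segs$hap_start[k]); re <- rs + pl
      lcl <- qa; rcl <- rl - qb
    } else {
      re <- segs$ref_end[k] - (hs - segs$hap_start[k]); rs <- re - pl
      lcl <- rl - qb; rcl <- qa
    }
    plen <- c(plen, pl); r1 <- c(r1, rs); r2 <- c(r2, re)
    prev <- c(prev, xor(rev, segs$strand[k] == "-"))
    lc <- c(lc, lcl); rc <- c(rc, rcl)
  }
  if (!length(plen)) return(NULL)
  o <- order(-plen)
  mk <- function(i) {
    cg <- paste0(if (lc[i] > 0) sprintf("%dS", lc[i]) else "",
                 sprintf("%dM", plen[i]),
                 if (rc[i] > 0) sprintf("%dS", rc[i]) else "")
    list(pos0 = as.numeric(r1[i]), refrev = prev[i], cigar = cg,
         refw = plen[i])
  }
  out <- mk(o[1])
  if (length(o) > 1 && plen[o[2]] >= min_split_len) {
    out$supp <- mk(o[2])
  }
  out
}
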