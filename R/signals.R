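#' Insert-size profile of a sequencing library
#'
#' @param mean_insert Mean absolute template length (bp).
#' @param sd_insert Standard deviation of the template length (bp).
#' @param read_length Modal read length (bp).
#' @param sample_size Number of proper pairs the estimate is based on.
#' @return An object of class `insert_profile`.
#' @export
insert_profile <- function(mean_insert, sd_insert, read_length, sample_size) {
  stopifnot(mean_insert > 0, sd_insert >= 0, read_length > 0, sample_size >= 1)
  structure(list(mean_insert = mean_insert, sd_insert = sd_insert,
                 read_length = as.integer(read_length),
                 sample_size = as.integer(sample_size)),
            class = "insert_profile")
}

#' @export
print.insert_profile <- function(x, ...) {
  cat(sprintf("insert profile: mean %.1f bp, sd %.1f bp, read length %d bp (n = %d)\n",
              x$mean_insert, x$sd_insert, x$read_length, x$sample_size))
  invisible(x)
}

#' Estimate the insert-size profile
#'
#' Computes robust library statistics from proper read pairs: absolute
#' template lengths are trimmed at the 1st/99th percentile before taking
#' moments, and the read length is the modal query length. These statistics
#' drive the discordance thresholds and the discordant clustering distance.
#'
#' @param x A path to a coordinate-sorted BAM file, or a numeric vector of
#'   template lengths (useful for testing and for pre-collected streams).
#' @param min_sample Minimum number of usable pairs; fewer is an error.
#' @param ... Passed to methods.
#' @return An [insert_profile()].
#' @export
estimate_insert_profile <- function(x, min_sample = 500, ...) {
  UseMethod("estimate_insert_profile")
}

#' @rdname estimate_insert_profile
#' @param read_length Read length (bp) accompanying a raw template-length
#'   vector.
#' @export
estimate_insert_profile.numeric <- function(x, min_sample = 500,
                                            read_length = 100L, ...) {
  tl <- abs(x[!is.na(x) & x != 0])
  profile_from_lengths(tl, read_length, min_sample)
}

#' @rdname estimate_insert_profile
#' @param region Optional region string `"contig"` or `"contig:start-end"`
#'   restricting the scan (requires a BAM index).
#' @param max_pairs Cap on the number of pairs scanned.
#' @export
estimate_insert_profile.character <- function(x, min_sample = 500,
                                              region = NULL,
                                              max_pairs = 1e6, ...) {
  flag <- Rsamtools::scanBamFlag(
    isPaired = TRUE, isProperPair = TRUE, isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
    isDuplicate = FALSE, isNotPassingQualityControls = FALSE,
    isFirstMateRead = TRUE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = c("isize", "cigar"),
                                   which = region_to_which(x, region))
  res <- scan_bam_flat(x, param)
  tl <- abs(res$isize[!is.na(res$isize) & res$isize != 0])
  qw <- cigar_query_length(res$cigar[!is.na(res$isize) & res$isize != 0])
  if (length(tl) > max_pairs) {
    tl <- tl[seq_len(max_pairs)]
    qw <- qw[seq_len(max_pairs)]
  }
  rl <- if (length(qw)) modal_value(qw) else 0L
  profile_from_lengths(tl, rl, min_sample)
}

profile_from_lengths <- function(tl, read_length, min_sample) {
  if (length(tl) < min_sample) {
    stop(sprintf("insert profile needs >= %d proper pairs, found %d",
                 min_sample, length(tl)), call. = FALSE)
  }
  q <- stats::quantile(tl, c(0.01, 0.99), names = FALSE, type = 7)
  keep <- tl >= q[1] & tl <= q[2]
  tl <- tl[keep]
  insert_profile(mean(tl), stats::sd(tl) %|NA|% 0,
                 read_length, length(tl))
}

`%|NA|%` <- function(a, b) if (is.na(a)) b else a

modal_value <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}

# ---- CIGAR helpers (thin wrappers over GenomicAlignments) ----

cigar_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

# full query length including soft AND hard clips: both count toward the
# clipped fraction
cigar_query_length <- function(cigar) {
  qw <- GenomicAlignments::cigarWidthAlongQuerySpace(cigar,
                                                     after.soft.clipping = FALSE)
  qw + cigar_clip(cigar, "lead", "H") + cigar_clip(cigar, "trail", "H")
}

# length of the leading/trailing clip (S and/or H), vectorized
cigar_clip <- function(cigar, side = c("lead", "trail"), ops = c("S", "H")) {
  side <- match.arg(side)
  pat <- if (side == "lead") "^(?:([0-9]+)H)?(?:([0-9]+)S)?"
         else "(?:([0-9]+)S)?(?:([0-9]+)H)?$"
  snip <- regmatches(cigar, regexpr(pat, cigar, perl = TRUE))
  num_of <- function(op) {
    hit <- grepl(op, snip, fixed = TRUE)
    out <- integer(length(snip))
    out[hit] <- as.integer(sub(paste0("^(?:.*?[HS])?0*([0-9]+)", op, ".*$"),
                               "\\1", snip[hit], perl = TRUE))
    out
  }
  tot <- integer(length(cigar))
  if ("H" %in% ops) tot <- tot + num_of("H")
  if ("S" %in% ops) tot <- tot + num_of("S")
  tot
}

# ---- classification ----

empty_signals <- function() {
  data.frame(kind = character(), contig = character(), pos = integer(),
             mate_contig = character(), mate_pos = integer(),
             read_id = character(), mapq = integer(),
             role = character(), mate_inner = integer(),
             stringsAsFactors = FALSE)
}

#' Classify one alignment record into abnormal-alignment signals
#'
#' Applies the three signal criteria: (1) a soft/hard clip of at least
#' `min_clip_frac` of the read length marks a clip signal at the clip
#' boundary (the last aligned reference base of the clipped side); (2) a
#' read with a split companion (`SA` tag) and sufficient mapping quality
#' marks a split-junction signal; (3) a discordant pair (template length
#' outside `mean +/- k*sd`, or non-FR orientation) marks one abnormal
#' read-pair (ARP) signal per read end. A record may emit several signals;
#' unmapped, secondary, duplicate and interchromosomal records emit none.
#'
#' @param record A named list with fields `qname`, `flag`, `contig`, `pos`
#'   (0-based), `mapq`, `cigar`, `mate_contig`, `mate_pos` (0-based),
#'   `tlen`, `has_sa`.
#' @param profile An [insert_profile()].
#' @param params A [csv_params()].
#' @return A data frame of signals (possibly 0 rows) with columns `kind`,
#'   `contig`, `pos`, `mate_contig`, `mate_pos`, `read_id`, `mapq`.
#' @export
classify_alignment <- function(record, profile, params = csv_params()) {
  df <- data.frame(qname = record$qname, flag = as.integer(record$flag),
                   contig = record$contig, pos = as.integer(record$pos),
                   mapq = as.integer(record$mapq), cigar = record$cigar,
                   mate_contig = record$mate_contig %||% NA_character_,
                   mate_pos = as.integer(record$mate_pos %||% NA_integer_),
                   tlen = as.integer(record$tlen %||% NA_integer_),
                   has_sa = isTRUE(record$has_sa),
                   stringsAsFactors = FALSE)
  classify_records(df, profile, params)
}

# vectorized classifier over a flat record table; `pos`/`mate_pos` 0-based
classify_records <- function(df, profile, params = csv_params()) {
  if (nrow(df) == 0) return(empty_signals())
  flag <- df$flag
  unmapped  <- bitwAnd(flag, 4L) > 0L
  secondary <- bitwAnd(flag, 256L) > 0L
  dupqc     <- bitwAnd(flag, 1024L) > 0L | bitwAnd(flag, 512L) > 0L
  suppl     <- bitwAnd(flag, 2048L) > 0L
  paired    <- bitwAnd(flag, 1L) > 0L
  mate_unm  <- bitwAnd(flag, 8L) > 0L
  interchrom <- paired & !mate_unm & !is.na(df$mate_contig) &
    df$mate_contig != df$contig
  usable <- !unmapped & !secondary & !dupqc & !is.na(df$cigar) & !interchrom
  df <- df[usable, , drop = FALSE]
  if (nrow(df) == 0) return(empty_signals())
  flag <- df$flag
  suppl <- bitwAnd(flag, 2048L) > 0L

  rw <- cigar_ref_width(df$cigar)
  qlen <- cigar_query_length(df$cigar)
  lead_clip <- cigar_clip(df$cigar, "lead")
  trail_clip <- cigar_clip(df$cigar, "trail")
  start0 <- df$pos
  end0 <- start0 + rw
  min_clip <- params$min_clip_frac * qlen

  split_ok <- df$has_sa & df$mapq >= params$min_split_mapq
  out <- vector("list", 5)

  # clip / split signals at the clip boundaries
  li <- which(lead_clip >= min_clip & lead_clip > 0 & (!suppl | split_ok))
  if (length(li)) {
    out[[1]] <- data.frame(
      kind = ifelse(split_ok[li], "SPLIT", "CLIP_LEFT"),
      contig = df$contig[li], pos = start0[li],
      mate_contig = NA_character_, mate_pos = NA_integer_,
      read_id = df$qname[li], mapq = df$mapq[li],
      role = NA_character_, mate_inner = NA_integer_,
      stringsAsFactors = FALSE)
  }
  ti <- which(trail_clip >= min_clip & trail_clip > 0 & (!suppl | split_ok))
  if (length(ti)) {
    out[[2]] <- data.frame(
      kind = ifelse(split_ok[ti], "SPLIT", "CLIP_RIGHT"),
      contig = df$contig[ti], pos = end0[ti],
      mate_contig = NA_character_, mate_pos = NA_integer_,
      read_id = df$qname[ti], mapq = df$mapq[ti],
      role = NA_character_, mate_inner = NA_integer_,
      stringsAsFactors = FALSE)
  }
  # drop supplementary records (only used for SPLIT) and CLIP from supp
  drop_clip_supp <- which(suppl & !split_ok)

  # discordant read-pair signals: primary, both mates mapped, same contig
  paired <- bitwAnd(flag, 1L) > 0L
  mate_unm <- bitwAnd(flag, 8L) > 0L
  arp_cand <- paired & !mate_unm & !suppl & !is.na(df$mate_pos) &
    !is.na(df$tlen)
  idx <- which(arp_cand)
  if (length(idx)) {
    self_rev <- bitwAnd(flag[idx], 16L) > 0L
    mate_rev <- bitwAnd(flag[idx], 32L) > 0L
    second <- bitwAnd(flag[idx], 128L) > 0L
    pos_i <- start0[idx]; mpos_i <- df$mate_pos[idx]
    is_left <- pos_i < mpos_i | (pos_i == mpos_i & !second)
    ls <- ifelse(is_left, self_rev, mate_rev)   # TRUE = reverse strand
    rs <- ifelse(is_left, mate_rev, self_rev)
    atl <- abs(df$tlen[idx])
    hi <- profile$mean_insert + params$insert_sd_mult * profile$sd_insert
    lo <- max(profile$mean_insert - params$insert_sd_mult * profile$sd_insert, 0)
    kind <- rep(NA_character_, length(idx))
    fr <- !ls & rs
    kind[fr & atl > hi] <- "ARP_LARGE_INSERT"
    kind[fr & atl < lo] <- "ARP_SMALL_INSERT"
    kind[ls & !rs] <- "ARP_RF"
    kind[!ls & !rs] <- "ARP_FF"
    kind[ls & rs] <- "ARP_RR"
    keep <- !is.na(kind)
    if (any(keep)) {
      ii <- idx[keep]
      out[[3]] <- data.frame(
        kind = kind[keep], contig = df$contig[ii],
        pos = ifelse(is_left[keep], end0[ii], start0[ii]),
        mate_contig = df$mate_contig[ii], mate_pos = df$mate_pos[ii],
        read_id = df$qname[ii], mapq = df$mapq[ii],
        role = ifelse(is_left[keep], "left", "right"),
        # inner coordinate of the mate: exact for left ends (mate start),
        # approximated by mate start + own aligned width for right ends
        mate_inner = ifelse(is_left[keep], df$mate_pos[ii],
                            df$mate_pos[ii] + rw[ii]),
        stringsAsFactors = FALSE)
    }
  }
  sig <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(sig)) return(empty_signals())
  rownames(sig) <- NULL
  sig
}

region_to_which <- function(bam, region) {
  if (is.null(region)) return(Rsamtools::ScanBamParam()@which)
  m <- regmatches(region,
                  regexec("^([^:]+)(?::([0-9]+)-([0-9]+))?$", region))[[1]]
  if (length(m) == 0) stop("cannot parse region: ", region)
  ctg <- m[2]
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!ctg %in% names(hdr)) stop("contig not in BAM header: ", ctg)
  s <- if (m[3] == "") 1L else as.integer(m[3])
  e <- if (m[4] == "") hdr[[ctg]] else as.integer(m[4])
  w <- IRanges::IRangesList(IRanges::IRanges(start = s, end = e))
  names(w) <- ctg
  w
}

scan_bam_flat <- function(bam, param) {
  res <- Rsamtools::scanBam(bam, param = param)
  # concatenate chunks (one per `which` range, or a single unrestricted one)
  fields <- names(res[[1]])
  out <- lapply(fields, function(f) {
    if (f == "tag") {
      tags <- names(res[[1]]$tag)
      tl <- lapply(tags, function(tg)
        do.call(c, lapply(res, function(ch) ch$tag[[tg]])))
      names(tl) <- tags
      tl
    } else {
      do.call(c, lapply(res, `[[`, f))
    }
  })
  names(out) <- fields
  out
}

#' Extract abnormal-alignment signals from a BAM file
#'
#' Scans a coordinate-sorted, indexed BAM file (primary and supplementary
#' records; secondary, duplicate and QC-fail records are skipped) and
#' returns the position-sorted stream of [classify_alignment()] signals.
#'
#' @param bam Path to the BAM file.
#' @param region Optional `"contig"` or `"contig:start-end"` restriction.
#' @param profile An [insert_profile()].
#' @param params A [csv_params()].
#' @return A data frame of signals sorted by `(contig, pos, kind, read_id)`.
#' @export
extract_signals <- function(bam, region = NULL, profile, params = csv_params()) {
  if (!is.null(region) && !file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam))) {
    stop("BAM index (.bai) required for region queries: ", bam)
  }
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isDuplicate = FALSE, isNotPassingQualityControls = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar",
             "mrnm", "mpos", "isize"),
    tag = "SA",
    which = region_to_which(bam, region))
  res <- scan_bam_flat(bam, param)
  if (length(res$pos) == 0) return(empty_signals())
  df <- data.frame(qname = res$qname, flag = res$flag,
                   contig = as.character(res$rname),
                   pos = res$pos - 1L, mapq = res$mapq, cigar = res$cigar,
                   mate_contig = as.character(res$mrnm),
                   mate_pos = res$mpos - 1L, tlen = res$isize,
                   has_sa = !is.na(res$tag$SA %||% rep(NA, length(res$pos))),
                   stringsAsFactors = FALSE)
  sig <- classify_records(df, profile, params)
  sig[order(sig$contig, sig$pos, sig$kind, sig$read_id), , drop = FALSE]
}

#' Primary-alignment read depth
#'
#' Per-contig coverage of primary, non-duplicate alignments, used by the
#' node weight/coverage ratio filter.
#'
#' @inheritParams extract_signals
#' @return A named list of [S4Vectors::Rle] coverage vectors (one per
#'   contig, 0-based positions shifted by +1 for indexing).
#' @export
alignment_coverage <- function(bam, region = NULL) {
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE, isDuplicate = FALSE,
    isNotPassingQualityControls = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   what = c("rname", "pos", "cigar"),
                                   which = region_to_which(bam, region))
  res <- scan_bam_flat(bam, param)
  if (length(res$pos) == 0) return(list())
  ctg <- as.character(res$rname)
  rw <- cigar_ref_width(res$cigar)
  lens <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  out <- lapply(split(seq_along(ctg), ctg), function(ii) {
    IRanges::coverage(IRanges::IRanges(start = res$pos[ii], width = rw[ii]),
                      width = lens[[ctg[ii[1]]]] + 1L)
  })
  out
}

#' Turn a coverage list into a lookup function
#'
#' @param cov Output of [alignment_coverage()].
#' @return `function(contig, pos)` returning depth at a 0-based position.
#' @export
coverage_lookup <- function(cov) {
  function(contig, pos) {
    r <- cov[[contig]]
    if (is.null(r)) return(rep(0L, length(pos)))
    p <- pmin(pmax(pos, 0L) + 1L, length(r))
    as.integer(r[p])
  }
}
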