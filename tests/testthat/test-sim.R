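# manual variant map: rows of (ref_start, ref_end, strand, novel pieces)
mk_map <- function(...) {
  rows <- list(...)
  seg <- do.call(rbind, lapply(rows, function(r) {
    data.frame(ref_start = r[["s"]] %||% NA_integer_,
               ref_end = r[["e"]] %||% NA_integer_,
               strand = r[["strand"]] %||% "+",
               novel_len = r[["novel"]] %||% 0L,
               novel_id = r[["novel_id"]] %||% NA_integer_,
               stringsAsFactors = FALSE)
  }))
  wid <- ifelse(is.na(seg$ref_start), seg$novel_len, seg$ref_end - seg$ref_start)
  seg$hap_end <- cumsum(as.numeric(wid))
  seg$hap_start <- seg$hap_end - wid
  seg
}

mini_cfg <- function(...) {
  a <- list(...)
  if (is.null(a$coverage)) a$coverage <- 10
  do.call(sim_config, c(list(genome_length = 1e5, n_events = 2, seed = 5), a))
}

del_implant <- function(cfg = mini_cfg()) {
  m <- mk_map(list(s = 0L, e = 30000L), list(s = 32000L, e = 100000L))
  list(hap_maps = list(m, m), novel_seqs = list(), config = cfg)
}

scan_all <- function(bam) {
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "pos", "cigar",
                                        "isize", "mpos"),
                               tag = "SA")
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  res
}

test_that("reference generation is seeded, GC-targeted, and guarded", {
  cfg <- sim_config(genome_length = 1e6, seed = 9)
  dir <- withr::local_tempdir()
  r1 <- make_reference(cfg, file.path(dir, "a.fa"))
  r2 <- make_reference(cfg, file.path(dir, "b.fa"))
  expect_identical(as.character(r1[[1]]), as.character(r2[[1]]))
  expect_identical(unname(tools::md5sum(file.path(dir, "a.fa"))),
                   unname(tools::md5sum(file.path(dir, "b.fa"))))
  gc <- Biostrings::letterFrequency(r1[[1]], "GC", as.prob = TRUE)
  expect_lt(abs(gc - 0.5), 0.01)
  expect_error(make_reference(sim_config(genome_length = 10)), "100 kb")
})

test_that("deletions shorten both haplotypes by the deleted length", {
  cfg <- mini_cfg(zygosity = "hom")
  ref <- make_reference(cfg)
  imp <- implant_csvs(ref, cfg, types = "Del")
  del_len <- sum(vapply(imp$plans, function(p)
    p$components$end[1] - p$components$start[1], numeric(1)))
  for (h in 1:2) {
    expect_equal(max(imp$hap_maps[[h]]$hap_end),
                 cfg$genome_length - del_len)
  }
  expect_identical(imp$truth$components[[1]]$type, "Del")
})

test_that("haplotype lengths equal reference plus signed length changes", {
  for (seed in c(2, 3)) {
    cfg <- sim_config(genome_length = 3e5, n_events = 6, seed = seed,
                      zygosity = "het")
    ref <- make_reference(cfg)
    imp <- implant_csvs(ref, cfg)
    for (h in 1:2) {
      delta <- sum(vapply(imp$plans, function(p) {
        if (!(h %in% p$haps)) return(0)
        wid <- ifelse(is.na(p$pieces$ref_start), p$pieces$novel_len,
                      p$pieces$ref_end - p$pieces$ref_start)
        sum(wid) - (p$window[2] - p$window[1])
      }, numeric(1)))
      expect_equal(max(imp$hap_maps[[h]]$hap_end),
                   cfg$genome_length + delta)
    }
  }
})

test_that("catalog compositions carry their expected component structure", {
  cfg <- sim_config(genome_length = 4e5, n_events = 4, seed = 21)
  ref <- make_reference(cfg)
  imp <- implant_csvs(ref, cfg,
                      types = c("DelSpaDel", "Tantrans", "Disdup", "InsInv"))
  cc <- imp$truth$components
  expect_identical(cc[[1]]$type, c("Del", "spacer", "Del"))
  expect_identical(cc[[2]]$type, rep("Tantrans", 3))
  expect_identical(cc[[3]]$type, rep("Disdup", 2))
  expect_true("Ins" %in% cc[[4]]$type)
  # adjacent segment swap: haplotype holds B then A
  pl <- imp$plans[[2]]
  hap <- haplotype_seq(ref, imp$hap_maps[[pl$haps[1]]], imp$novel_seqs)
  refc <- as.character(ref[[1]])
  a1 <- pl$anchor
  a <- substr(refc, pl$pieces$ref_start[2] + 1, pl$pieces$ref_end[2])
  b <- substr(refc, pl$pieces$ref_start[1] + 1, pl$pieces$ref_end[1])
  idx <- regexpr(paste0(b, a), hap, fixed = TRUE)
  expect_gt(idx, 0)
})

test_that("events that cannot fit with spacing raise a listing error", {
  cfg <- sim_config(genome_length = 1e5, n_events = 50, seed = 1)
  ref_small <- make_reference(sim_config(genome_length = 1e5, seed = 1))
  expect_error(implant_csvs(ref_small, cfg), "10 kb spacing")
})

test_that("pair count follows the coverage formula within 1%", {
  cfg <- sim_config(genome_length = 1e6, n_events = 2, coverage = 30,
                    seed = 3)
  ref <- make_reference(cfg)
  imp <- implant_csvs(ref, cfg, types = "Inv")
  rd <- simulate_reads(imp, cfg)
  total <- sum(vapply(imp$hap_maps, function(m) max(m$hap_end), numeric(1)))
  expected <- 30 * total / (2 * 2 * 100)
  expect_lt(abs(rd$n_pairs - expected) / expected, 0.01)
})

test_that("error-free reads are exact haplotype substrings and FASTQ is seeded", {
  dir <- withr::local_tempdir()
  cfg <- mini_cfg(base_error_rate = 0, coverage = 2)
  ref <- make_reference(cfg)
  imp <- implant_csvs(ref, cfg, types = c("DelInv", "Tandup"))
  rd1 <- simulate_reads(imp, cfg, fastq_prefix = file.path(dir, "x"),
                        reference = ref)
  rd2 <- simulate_reads(imp, cfg, fastq_prefix = file.path(dir, "y"),
                        reference = ref)
  expect_identical(readLines(rd1$fastq[1]), readLines(rd2$fastq[1]))
  expect_identical(readLines(rd1$fastq[2]), readLines(rd2$fastq[2]))
  haps <- vapply(1:2, function(h)
    haplotype_seq(ref, imp$hap_maps[[h]], imp$novel_seqs), character(1))
  l1 <- readLines(rd1$fastq[1])
  reads <- l1[seq(2, length(l1), by = 4)]
  names <- l1[seq(1, length(l1), by = 4)]
  pick <- sample(length(reads), 40)
  for (i in pick) {
    h <- as.integer(sub("^@f[0-9]+_([12])_.*", "\\1", names[i]))
    expect_true(grepl(reads[i], haps[h], fixed = TRUE),
                info = names[i])
  }
})

test_that("pairs straddling a deletion become long-insert FR pairs", {
  dir <- withr::local_tempdir()
  imp <- del_implant()
  # fragments bracketing the 2 kb deletion at reference [30000, 32000)
  frags <- data.frame(id = sprintf("f%07d", 1:20), hap = 1L,
                      start = 29600 - (1:20), len = 500L)
  bam <- truth_guided_align(frags, imp, file.path(dir, "del"))
  res <- scan_all(bam)
  prim <- bitwAnd(res$flag, 2048L) == 0L
  first <- bitwAnd(res$flag, 64L) > 0L & prim
  expect_equal(sum(first), 20L)
  expect_true(all(res$isize[first] %in% (2500 - (0:40))))
  expect_true(all(abs(res$isize[first] - 2500) <= 40))
  # FR orientation: first mate forward, second reverse
  expect_true(all(bitwAnd(res$flag[first], 16L) == 0L))
  expect_true(all(bitwAnd(res$flag[first], 32L) > 0L))
  # no proper-pair flag at this template length
  expect_true(all(bitwAnd(res$flag[first], 2L) == 0L))
})

test_that("reads crossing a junction are clipped/split at the breakpoint", {
  dir <- withr::local_tempdir()
  imp <- del_implant()
  frags <- data.frame(id = "f0000001", hap = 1L, start = 29950, len = 500L)
  bam <- truth_guided_align(frags, imp, file.path(dir, "split"))
  res <- scan_all(bam)
  r1 <- which(bitwAnd(res$flag, 64L) > 0 & bitwAnd(res$flag, 2048L) == 0)
  expect_identical(res$cigar[r1], "50M50S")
  expect_identical(res$pos[r1], 29951L)        # 1-based
  expect_match(res$tag$SA[r1], "^simchr,32001,\\+,50S50M")
  supp <- which(bitwAnd(res$flag, 2048L) > 0)
  expect_identical(res$pos[supp], 32001L)
})

test_that("reads crossing an inversion breakpoint split with strand flip", {
  dir <- withr::local_tempdir()
  cfg <- mini_cfg()
  m <- mk_map(list(s = 0L, e = 30000L),
              list(s = 30000L, e = 32000L, strand = "-"),
              list(s = 32000L, e = 100000L))
  imp <- list(hap_maps = list(m, m), novel_seqs = list(), config = cfg)
  frags <- data.frame(id = "f0000001", hap = 1L, start = 29940, len = 480L)
  bam <- truth_guided_align(frags, imp, file.path(dir, "inv"))
  res <- scan_all(bam)
  r1 <- which(bitwAnd(res$flag, 64L) > 0 & bitwAnd(res$flag, 2048L) == 0)
  # 60 bases before the junction, 40 inside the inverted segment
  expect_identical(res$cigar[r1], "60M40S")
  supp <- which(bitwAnd(res$flag, 2048L) > 0)
  # supplementary maps at the far side of the inversion, reverse strand
  expect_identical(res$pos[supp], 31961L)
  expect_true(bitwAnd(res$flag[supp], 16L) > 0)
  # junction coordinate on the far side is the inversion end (within 1 bp)
  expect_lte(abs((res$pos[supp] + 40L) - 32001L), 1L)
})

test_that("variant-free regions give proper pairs in the insert distribution", {
  dir <- withr::local_tempdir()
  imp <- del_implant()
  frags <- data.frame(id = sprintf("f%07d", 1:10), hap = 1L,
                      start = 5000 + (1:10) * 37, len = 480L + (1:10))
  bam <- truth_guided_align(frags, imp, file.path(dir, "calm"))
  res <- scan_all(bam)
  prim1 <- bitwAnd(res$flag, 64L) > 0 & bitwAnd(res$flag, 2048L) == 0
  expect_true(all(bitwAnd(res$flag[prim1], 2L) > 0))
  expect_identical(res$isize[prim1], 480L + (1:10))
})

test_that("reads wholly inside novel sequence come out unmapped", {
  dir <- withr::local_tempdir()
  cfg <- mini_cfg()
  m <- mk_map(list(s = 0L, e = 50000L),
              list(novel = 400L, novel_id = 1L),
              list(s = 50000L, e = 100000L))
  imp <- list(hap_maps = list(m, m),
              novel_seqs = list(strrep("ACGT", 100)), config = cfg)
  frags <- data.frame(id = "f0000001", hap = 1L, start = 50100, len = 480L)
  # R1 sits fully inside the 400 bp novel insertion at hap [50000, 50400)
  bam <- truth_guided_align(frags, imp, file.path(dir, "nov"))
  res <- scan_all(bam)
  r1 <- which(bitwAnd(res$flag, 64L) > 0)
  expect_true(bitwAnd(res$flag[r1], 4L) > 0)
  r2 <- which(bitwAnd(res$flag, 128L) > 0)
  expect_true(bitwAnd(res$flag[r2], 8L) > 0)
})

test_that("deletion-spanning template lengths recover insert plus deletion size", {
  dir <- withr::local_tempdir()
  cfg <- mini_cfg(coverage = 20)
  ref <- make_reference(cfg)
  m <- mk_map(list(s = 0L, e = 30000L), list(s = 32000L, e = 100000L))
  imp <- list(hap_maps = list(m, m), novel_seqs = list(), config = cfg)
  rd <- simulate_reads(imp, cfg)
  bam <- truth_guided_align(rd$fragments, imp, file.path(dir, "par"))
  prof <- test_profile(cfg$insert_mean, cfg$insert_sd, cfg$read_length)
  sig <- extract_signals(bam, profile = prof)
  arp <- sig[sig$kind == "ARP_LARGE_INSERT" & sig$role == "left", ]
  expect_gt(nrow(arp), 5)
  tlen <- arp$mate_inner + cfg$read_length - (arp$pos - cfg$read_length)
  med <- median(arp$mate_inner - arp$pos) # inner gap ~ deletion length
  expect_lt(abs(med - 2000), 2 * cfg$insert_sd + 300)
})

test_that("a whole simulated dataset is byte-deterministic in the seed", {
  dirs <- c(withr::local_tempdir(), withr::local_tempdir())
  cfg <- sim_config(genome_length = 2e5, n_events = 4, coverage = 8,
                    seed = 77)
  out <- lapply(dirs, function(d)
    simulate_csv_dataset(cfg, d, write_fastq = TRUE))
  expect_identical(readLines(file.path(dirs[1], "reads_1.fastq")),
                   readLines(file.path(dirs[2], "reads_1.fastq")))
  expect_identical(readLines(out[[1]]$truth_path),
                   readLines(out[[2]]$truth_path))
  s1 <- scan_all(out[[1]]$bam); s2 <- scan_all(out[[2]]$bam)
  expect_identical(s1$pos, s2$pos)
  expect_identical(s1$flag, s2$flag)
  expect_identical(s1$cigar, s2$cigar)
})
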