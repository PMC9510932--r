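#' Caller parameters
#'
#' Bundles every tunable threshold of the caller. Defaults follow the
#' method's stated rules where quantified (10% minimum clip fraction, the
#' insert-size discordance multiplier) and conservative, configurable
#' choices elsewhere.
#'
#' @param min_clip_frac Minimum clipped fraction of the read length for a
#'   clip signal (default 0.1).
#' @param min_split_mapq Minimum mapping quality for split-read signals.
#' @param insert_sd_mult Discordance multiplier `k`: a pair is insert-size
#'   discordant when its template length falls outside `mean +/- k*sd`.
#' @param clip_merge_window Merge window (bp) for clip/split signal
#'   clustering.
#' @param min_weight Minimum supporting-read weight for a clip/split node.
#' @param min_weight_ratio Minimum weight / local-coverage ratio for a node.
#' @param min_pair_support Minimum read pairs for a discordant cluster
#'   (random-discordance control).
#' @param min_cluster_distance_floor Lower bound (bp) on the discordant
#'   clustering distance.
#' @param min_dist Pattern-growth adjacency distance cap (bp); `NULL` means
#'   `max(2 * mean insert, 1000)` once the insert profile is known.
#' @param min_freq Minimum subgraph pattern frequency (`minFreq`); 1 keeps
#'   every instance so rare CSVs are not lost.
#' @param min_link_types Minimum number of distinct edge connection types a
#'   reported call must carry (1 keeps the full callset; 2 reproduces the
#'   complex-only selection).
#' @param min_sample Minimum proper pairs required to estimate the insert
#'   profile.
#' @return A list of class `csv_params`.
#' @export
csv_params <- function(min_clip_frac = 0.1,
                       min_split_mapq = 20,
                       insert_sd_mult = 3,
                       clip_merge_window = 5,
                       min_weight = 2,
                       min_weight_ratio = 0.1,
                       min_pair_support = 2,
                       min_cluster_distance_floor = 50,
                       min_dist = NULL,
                       min_freq = 1,
                       min_link_types = 1,
                       min_sample = 500) {
  stopifnot(min_clip_frac > 0, min_clip_frac < 1,
            min_split_mapq >= 0, insert_sd_mult > 0,
            clip_merge_window >= 0, min_weight >= 1,
            min_weight_ratio >= 0, min_weight_ratio <= 1,
            min_pair_support >= 1, min_cluster_distance_floor >= 0,
            is.null(min_dist) || min_dist > 0,
            min_freq >= 1, min_link_types >= 1, min_sample >= 1)
  structure(list(
    min_clip_frac = min_clip_frac,
    min_split_mapq = min_split_mapq,
    insert_sd_mult = insert_sd_mult,
    clip_merge_window = clip_merge_window,
    min_weight = min_weight,
    min_weight_ratio = min_weight_ratio,
    min_pair_support = min_pair_support,
    min_cluster_distance_floor = min_cluster_distance_floor,
    min_dist = min_dist,
    min_freq = min_freq,
    min_link_types = min_link_types,
    min_sample = min_sample
  ), class = "csv_params")
}

#' Pattern-growth parameters
#'
#' @param min_freq Minimum pattern frequency (`minFreq`), at least 1.
#' @param min_dist Maximum genomic gap (bp, `minDist`) across which the
#'   subgraph may grow along a reference-adjacency edge.
#' @return A list of class `growth_params`.
#' @export
growth_params <- function(min_freq = 1, min_dist = 1000) {
  stopifnot(min_freq >= 1, min_dist > 0)
  structure(list(min_freq = as.integer(min_freq), min_dist = min_dist),
            class = "growth_params")
}

# signal kind vocabulary
SIGNAL_KINDS <- c("CLIP_LEFT", "CLIP_RIGHT", "SPLIT",
                  "ARP_LARGE_INSERT", "ARP_SMALL_INSERT",
                  "ARP_RF", "ARP_FF", "ARP_RR")

ARP_KINDS <- c("ARP_LARGE_INSERT", "ARP_SMALL_INSERT",
               "ARP_RF", "ARP_FF", "ARP_RR")

# ARP kind -> paired-edge connection type
LINK_TYPE_OF_KIND <- c(ARP_LARGE_INSERT = "DEL",
                       ARP_SMALL_INSERT = "INS",
                       ARP_RF = "DUP",
                       ARP_FF = "INV",
                       ARP_RR = "INV")

LINK_TYPES <- c("DEL", "DUP", "INV", "INS", "SPLIT")

# connection type -> callset label vocabulary
LINK_LABELS <- c(DEL = "Del", DUP = "Dup", INV = "Inv",
                 INS = "Ins", SPLIT = "Split")

`%||%` <- function(a, b) if (is.null(a)) b else a
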