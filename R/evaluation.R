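#' Truth-set I/O
#'
#' Benchmark CSVs are BED-like TSV records: `contig  start  end  name
#' zygosity  components`, 0-based half-open outer interval, components
#' encoded `"type:start-end;type:start-end;..."` in reference coordinates.
#'
#' @param truth Truth data frame with a `components` list column of data
#'   frames (`type`, `start`, `end`).
#' @param path File path.
#' @return `read_truth_tsv()` returns the truth data frame;
#'   `write_truth_tsv()` returns `path` invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  comp <- vapply(truth$components, function(cc) {
    paste(sprintf("%s:%d-%d", cc$type, as.integer(cc$start),
                  as.integer(cc$end)), collapse = ";")
  }, character(1))
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", truth$contig,
                   as.integer(truth$start), as.integer(truth$end),
                   truth$name, truth$zygosity, comp)
  writeLines(c("#contig\tstart\tend\tname\tzygosity\tcomponents", lines), path)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), name = character(),
                      zygosity = character(),
                      components = I(list()), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  comps <- lapply(f, function(x) {
    parts <- strsplit(x[6], ";", fixed = TRUE)[[1]]
    m <- regmatches(parts, regexec("^([^:]+):([0-9]+)-([0-9]+)$", parts))
    data.frame(type = vapply(m, `[`, character(1), 2),
               start = as.integer(vapply(m, `[`, character(1), 3)),
               end = as.integer(vapply(m, `[`, character(1), 4)),
               stringsAsFactors = FALSE)
  })
  data.frame(contig = vapply(f, `[`, character(1), 1),
             start = as.integer(vapply(f, `[`, character(1), 2)),
             end = as.integer(vapply(f, `[`, character(1), 3)),
             name = vapply(f, `[`, character(1), 4),
             zygosity = vapply(f, `[`, character(1), 5),
             components = I(comps), stringsAsFactors = FALSE)
}

#' Unique-interval match
#'
#' A prediction matches a benchmark CSV at the unique-interval tier when
#' both of its breakpoints fall within `slop` bp (inclusive) of the
#' benchmark's leftmost and rightmost breakpoints, on the same contig.
#'
#' @param pred A list/row with `contig`, `start`, `end`.
#' @param truth One truth record (list/row with `contig`, `start`, `end`).
#' @param slop Breakpoint tolerance in bp (default 500).
#' @return `TRUE` or `FALSE`.
#' @export
unique_interval_match <- function(pred, truth, slop = 500) {
  if (!identical(as.character(pred$contig), as.character(truth$contig))) {
    return(FALSE)
  }
  abs(pred$start - truth$start) <= slop && abs(pred$end - truth$end) <= slop
}

#' All-breakpoint match
#'
#' A benchmark CSV is fully detected when every one of its subcomponents
#' has at least one prediction whose start and end are each within `slop`
#' bp of the component's; predictions may be reused across components.
#'
#' @param preds Prediction data frame (`contig`, `start`, `end`), e.g.
#'   [breakpoint_intervals()] output or any BED-like table.
#' @param truth One truth record with a `components` data frame.
#' @param slop Breakpoint tolerance in bp.
#' @return `TRUE` or `FALSE`.
#' @export
all_breakpoint_match <- function(preds, truth, slop = 500) {
  cc <- truth$components
  if (is.list(cc) && !is.data.frame(cc)) cc <- cc[[1]]
  stopifnot(nrow(cc) >= 1)
  p <- preds[as.character(preds$contig) == as.character(truth$contig), ,
             drop = FALSE]
  if (nrow(p) == 0) return(FALSE)
  for (k in seq_len(nrow(cc))) {
    hit <- abs(p$start - cc$start[k]) <= slop & abs(p$end - cc$end[k]) <= slop
    if (!any(hit)) return(FALSE)
  }
  TRUE
}

#' Score predictions against a benchmark
#'
#' Under the unique-interval criterion, matching is a greedy one-to-one
#' assignment (smallest summed breakpoint shift first) between predictions
#' and truth records; unmatched predictions are false positives and
#' unmatched truths false negatives. Under the all-breakpoint criterion a
#' truth record is a true positive when all its components are matched
#' (predictions reusable); predictions matching neither any component nor
#' any outer interval count as false positives.
#'
#' @param preds Prediction data frame (`contig`, `start`, `end`).
#' @param truths Truth data frame as from [read_truth_tsv()].
#' @param criterion `"unique_interval"` or `"all_breakpoint"`.
#' @param slop Breakpoint tolerance in bp.
#' @param recall_only Suppress FP-based metrics (real-data style scoring
#'   without a curated FP set).
#' @return A list of class `match_report`: `tp`, `fp`, `fn`, `recall`,
#'   `precision`, `f1`, and `tier` (per-truth match tier).
#' @export
score <- function(preds, truths,
                  criterion = c("unique_interval", "all_breakpoint"),
                  slop = 500, recall_only = FALSE) {
  criterion <- match.arg(criterion)
  nt <- nrow(truths); np <- nrow(preds)
  tier <- rep("none", nt)
  if (criterion == "unique_interval") {
    cand <- list()
    for (t in seq_len(nt)) {
      for (p in seq_len(np)) {
        if (unique_interval_match(preds[p, ], truths[t, ], slop)) {
          cand[[length(cand) + 1L]] <- c(
            t, p, abs(preds$start[p] - truths$start[t]) +
              abs(preds$end[p] - truths$end[t]))
        }
      }
    }
    used_t <- logical(nt); used_p <- logical(np)
    if (length(cand)) {
      cm <- do.call(rbind, cand)
      cm <- cm[order(cm[, 3], cm[, 1], cm[, 2]), , drop = FALSE]
      for (r in seq_len(nrow(cm))) {
        t <- cm[r, 1]; p <- cm[r, 2]
        if (!used_t[t] && !used_p[p]) {
          used_t[t] <- TRUE; used_p[p] <- TRUE
          tier[t] <- "unique_interval"
        }
      }
    }
    tp <- sum(used_t); fp <- np - sum(used_p); fn <- nt - tp
  } else {
    matched <- vapply(seq_len(nt), function(t)
      all_breakpoint_match(preds, truths[t, ], slop), logical(1))
    tier[matched] <- "all_breakpoint"
    tp <- sum(matched); fn <- nt - tp
    # FP: predictions relating to nothing in the benchmark
    useful <- rep(FALSE, np)
    for (p in seq_len(np)) {
      for (t in seq_len(nt)) {
        if (as.character(preds$contig[p]) != as.character(truths$contig[t]))
          next
        cc <- truths$components[[t]]
        hit <- any(abs(preds$start[p] - cc$start) <= slop &
                     abs(preds$end[p] - cc$end) <= slop)
        if (hit || unique_interval_match(preds[p, ], truths[t, ], slop)) {
          useful[p] <- TRUE
          break
        }
      }
    }
    fp <- sum(!useful)
  }
  recall <- if (nt > 0) tp / nt else NA_real_
  precision <- if (recall_only) NA_real_
               else if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (recall_only || is.na(precision)) NA_real_
        else if (recall + precision > 0) {
          2 * recall * precision / (recall + precision)
        } else 0
  structure(list(tp = tp, fp = if (recall_only) NA_integer_ else fp,
                 fn = fn, recall = recall, precision = precision, f1 = f1,
                 criterion = criterion, slop = slop, tier = tier),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("%s match (slop %d bp): TP %d, FP %s, FN %d | recall %.3f, precision %s, F1 %s\n",
              x$criterion, x$slop, x$tp,
              ifelse(is.na(x$fp), "-", x$fp), x$fn, x$recall,
              ifelse(is.na(x$precision), "-", sprintf("%.3f", x$precision)),
              ifelse(is.na(x$f1), "-", sprintf("%.3f", x$f1))))
  invisible(x)
}
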