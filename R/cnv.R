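#' Call heterozygous deletions from a binned depth track
#'
#' Flags maximal runs of at least `min_bins` consecutive bins whose depth
#' ratio (bin depth / genome-wide mean) is at or below `ratio_threshold`;
#' runs separated by at most `max_merge_gap_bins` non-qualifying bins are
#' merged. The default threshold 0.65 sits between the copy-1 expectation
#' (0.5) and diploid (1.0), far enough from both to separate them under
#' Poisson noise at ~40X coverage and 100-bp bins. Breakpoints are reported
#' at the outer edges of the first and last qualifying bin, in 1-based
#' inclusive coordinates.
#'
#' @param track a [depth_track()].
#' @param genome_mean genome-wide mean depth of diploid regions (> 0).
#' @param ratio_threshold maximum depth ratio for a deletion bin.
#' @param min_bins minimum number of qualifying bins in a (merged) run.
#' @param max_merge_gap_bins merge runs separated by at most this many
#'   non-qualifying bins. The default 5 bridges the short runs of
#'   at-threshold bins that Poisson noise opens inside a genuine copy-1
#'   segment while keeping isolated diploid noise bins apart.
#' @return a `CnvCalls` data frame (possibly empty) with `chrom`, `start`,
#'   `end`, `svtype = "DEL"`, `caller = "depth"`, `n_bins`, `mean_ratio`.
#' @export
call_deletions <- function(track, genome_mean, ratio_threshold = 0.65,
                           min_bins = 5L, max_merge_gap_bins = 5L) {
  if (genome_mean <= 0) stop("genome_mean must be > 0")
  empty <- cnv_calls(data.frame(chrom = character(0), start = numeric(0),
                                end = numeric(0), svtype = character(0),
                                caller = character(0), n_bins = integer(0),
                                mean_ratio = numeric(0),
                                stringsAsFactors = FALSE))
  if (!length(track$depth)) return(empty)
  low <- track$depth / genome_mean <= ratio_threshold
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  runs$n_low <- runs$end - runs$start + 1L
  if (!nrow(runs)) return(empty)
  # merge runs separated by small gaps; min_bins counts qualifying bins only
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
    if (gap <= max_merge_gap_bins) {
      merged$end[nrow(merged)] <- runs$end[i]
      merged$n_low[nrow(merged)] <- merged$n_low[nrow(merged)] + runs$n_low[i]
    } else {
      merged <- rbind(merged, runs[i, ])
    }
  }
  merged <- merged[merged$n_low >= min_bins, , drop = FALSE]
  if (!nrow(merged)) return(empty)
  bs <- track$bin_size
  out <- data.frame(
    chrom = track$chrom,
    start = (merged$start - 1) * bs + 1,
    end = merged$end * bs,
    svtype = "DEL", caller = "depth",
    n_bins = merged$end - merged$start + 1L,
    mean_ratio = vapply(seq_len(nrow(merged)), function(i)
      mean(track$depth[merged$start[i]:merged$end[i]]) / genome_mean,
      numeric(1)),
    stringsAsFactors = FALSE)
  cnv_calls(out)
}

#' Segment and gap arithmetic for a multi-segment deletion event
#'
#' All coordinates are 1-based inclusive, so segment size is
#' `end - start + 1` and the gap between consecutive segments is the
#' breakpoint-to-breakpoint distance `start[i+1] - end[i]`.
#'
#' @param calls non-overlapping `CnvCalls` on a single chromosome.
#' @return a `DeletionSegmentSet` list: sorted `segments` (with `size`),
#'   `gaps` (length n-1), `total_size`.
#' @export
segment_arithmetic <- function(calls) {
  if (length(unique(calls$chrom)) > 1L)
    stop("segments must be on a single chromosome")
  calls <- calls[order(calls$start), , drop = FALSE]
  n <- nrow(calls)
  if (n > 1L && any(calls$start[-1] <= calls$end[-n]))
    stop("segments overlap")
  calls$size <- calls$end - calls$start + 1
  gaps <- if (n > 1L) calls$start[-1] - calls$end[-n] else numeric(0)
  structure(list(segments = calls, gaps = gaps,
                 total_size = sum(calls$size)),
            class = "DeletionSegmentSet")
}

#' @export
print.DeletionSegmentSet <- function(x, ...) {
  cat(sprintf("DeletionSegmentSet: %d segment(s), total %s bp\n",
              nrow(x$segments),
              format(x$total_size, big.mark = ",")))
  for (i in seq_len(nrow(x$segments))) {
    s <- x$segments[i, ]
    cat(sprintf("  %s:%s-%s  size %s bp\n", s$chrom,
                format(s$start, big.mark = ",", scientific = FALSE),
                format(s$end, big.mark = ",", scientific = FALSE),
                format(s$size, big.mark = ",", scientific = FALSE)))
  }
  if (length(x$gaps))
    cat("  gaps:", paste(format(x$gaps, big.mark = ",", trim = TRUE),
                         collapse = ", "), "bp\n")
  invisible(x)
}

#' Mean depth ratio of a region
#'
#' Mean depth over the bins fully contained in the region, divided by the
#' genome-wide mean. Partial edge bins are excluded to avoid
#' partial-overlap bias. A heterozygous deletion is expected near 0.5,
#' diploid near 1.0.
#'
#' @param region a one-row call (or list) with `start`, `end`, 1-based
#'   inclusive.
#' @param track a [depth_track()].
#' @param genome_mean genome-wide diploid mean depth.
#' @return the ratio, or `NA` if the region covers no full bin.
#' @export
depth_ratio <- function(region, track, genome_mean) {
  bs <- track$bin_size
  first <- ceiling((region$start - 1) / bs) + 1   # first fully-inside bin
  last <- floor(region$end / bs)                  # last fully-inside bin
  if (last < first || first < 1 || last > length(track$depth))
    return(NA_real_)
  mean(track$depth[first:last]) / genome_mean
}

#' Estimate the diploid genome-wide mean depth
#'
#' Mean over bins fully outside a set of excluded regions (e.g. called or
#' known deletions).
#'
#' @param track a [depth_track()].
#' @param exclude `CnvCalls`-like data frame of regions to mask, or `NULL`.
#' @return mean depth over unmasked bins.
#' @export
estimate_genome_mean <- function(track, exclude = NULL) {
  keep <- rep(TRUE, length(track$depth))
  if (!is.null(exclude) && nrow(exclude)) {
    bs <- track$bin_size
    bin_start <- (seq_along(track$depth) - 1) * bs + 1
    bin_end <- bin_start + bs - 1
    for (i in seq_len(nrow(exclude)))
      keep[bin_end >= exclude$start[i] & bin_start <= exclude$end[i]] <- FALSE
  }
  mean(track$depth[keep])
}

# post-call SV/CNV filter rules; "class" maps caller labels to rule families
default_sv_ruleset <- function() {
  list(caller_class = c(lumpy = "read_support", erds = "erds",
                        penncnv = "array"),
       read_support_min = 4, read_support_max = 50,
       erds_confidence_min = 300,      # strict: keep > 300
       erds_dup_min_size = 200000,     # keep DUP >= 200 Kb
       erds_del_min_size = 10000,      # keep DEL >= 10 Kb
       array_min_markers = 10,
       array_max_gap = 50000,
       segdup_max_frac = 0.5)          # remove overlap >= 0.5
}

#' Filter SV/CNV calls by caller-specific post-call rules
#'
#' Applies, per call, the rule family its caller label maps to:
#' read-support callers keep `4 <= read_support <= 50`; depth/CNV callers
#' keep `confidence > 300` and size at least 200 Kb for duplications or
#' 10 Kb for deletions; array callers keep at least 10 markers with a
#' maximum inter-marker gap of 50 Kb. Independently of caller, calls whose
#' segmental-duplication overlap fraction is 0.5 or more are removed. Every
#' removal carries a rule id. A call whose applicable rule needs a missing
#' field is flagged unevaluable, kept, and a warning is raised.
#'
#' @param calls a `CnvCalls` data frame.
#' @param ruleset rule parameters; see `pedwgs:::default_sv_ruleset()`.
#' @return list with `kept`, `removed` (with a `reason` column) and the
#'   logical `unevaluable` flag vector aligned with `kept`.
#' @export
filter_calls <- function(calls, ruleset = default_sv_ruleset()) {
  n <- nrow(calls)
  reason <- rep(NA_character_, n)
  uneval <- rep(FALSE, n)
  size <- calls$end - calls$start + 1
  get <- function(col) if (is.null(calls[[col]])) rep(NA_real_, n) else calls[[col]]
  rs <- get("read_support"); conf <- get("confidence")
  nm <- get("n_markers"); gap <- get("max_intermarker_gap")
  sd <- get("segdup_overlap_frac")
  cls <- ruleset$caller_class[tolower(calls$caller)]
  for (i in seq_len(n)) {
    if (!is.na(sd[i]) && sd[i] >= ruleset$segdup_max_frac) {
      reason[i] <- "segdup_overlap"; next
    }
    if (is.na(cls[i])) next   # caller without post-call rules
    if (cls[i] == "read_support") {
      if (is.na(rs[i])) { uneval[i] <- TRUE; next }
      if (rs[i] < ruleset$read_support_min) reason[i] <- "read_support_low"
      else if (rs[i] > ruleset$read_support_max) reason[i] <- "read_support_high"
    } else if (cls[i] == "erds") {
      if (is.na(conf[i])) { uneval[i] <- TRUE; next }
      if (conf[i] <= ruleset$erds_confidence_min) { reason[i] <- "confidence"; next }
      if (calls$svtype[i] == "DUP" && size[i] < ruleset$erds_dup_min_size)
        reason[i] <- "dup_size"
      if (calls$svtype[i] == "DEL" && size[i] < ruleset$erds_del_min_size)
        reason[i] <- "del_size"
    } else if (cls[i] == "array") {
      if (is.na(nm[i]) || is.na(gap[i])) { uneval[i] <- TRUE; next }
      if (nm[i] < ruleset$array_min_markers) reason[i] <- "marker_count"
      else if (gap[i] > ruleset$array_max_gap) reason[i] <- "marker_gap"
    }
  }
  if (any(uneval))
    warning(sum(uneval), " call(s) unevaluable (missing rule fields); kept")
  removed <- calls[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  list(kept = calls[is.na(reason), , drop = FALSE],
       removed = removed,
       unevaluable = uneval[is.na(reason)])
}
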