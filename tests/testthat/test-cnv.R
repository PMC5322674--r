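printed_breakpoints <- function() {
  cnv_calls_df <- data.frame(
    chrom = "chr15",
    start = c(22749401, 23608601, 28897601),
    end = c(23198800, 28566000, 28992600),
    svtype = "DEL", caller = "depth", stringsAsFactors = FALSE)
  cnv_calls_df
}

test_that("segment arithmetic reproduces the published 15q11.2-q13.1 figures", {
  segs <- segment_arithmetic(printed_breakpoints())
  expect_equal(segs$segments$size, c(449400, 4957400, 95000))
  expect_equal(segs$total_size, 5501800)
  expect_equal(segs$gaps, c(409801, 331601))
  # rounded as printed: ~449 Kb, ~4.96 Mb, ~95 Kb, ~5.5 Mb, ~410/332 Kb
  expect_equal(round(segs$segments$size[1] / 1e3), 449)
  expect_equal(round(segs$segments$size[2] / 1e4) / 100, 4.96)
  expect_equal(round(segs$segments$size[3] / 1e3), 95)
  expect_equal(round(segs$total_size / 1e5) / 10, 5.5)
  expect_equal(round(segs$gaps / 1e3), c(410, 332))
})

test_that("segment arithmetic handles degenerate and invalid input", {
  one <- data.frame(chrom = "chr1", start = 5, end = 5)
  segs <- segment_arithmetic(one)
  expect_equal(segs$segments$size, 1)
  expect_length(segs$gaps, 0)
  overlapping <- data.frame(chrom = "chr1", start = c(1, 50), end = c(100, 200))
  expect_error(segment_arithmetic(overlapping), "overlap")
  two_chrom <- data.frame(chrom = c("chr1", "chr2"), start = 1, end = 10)
  expect_error(segment_arithmetic(two_chrom), "single chromosome")
})

test_that("deletion calling on noiseless tracks is exact", {
  # 40X diploid with one 20X stretch of 50 bins (bins 101-150)
  depth <- rep(40, 300)
  depth[101:150] <- 20
  tr <- depth_track("chr1", 100L, depth)
  calls <- call_deletions(tr, 40)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 100 * 100 + 1)
  expect_equal(calls$end, 150 * 100)
  # flat diploid track: no calls; empty track: empty result, not error
  expect_equal(nrow(call_deletions(depth_track("chr1", 100L, rep(40, 300)), 40)), 0L)
  expect_equal(nrow(call_deletions(depth_track("chr1", 100L, numeric(0)), 40)), 0L)
  # a sub-min_bins dip is ignored
  depth2 <- rep(40, 300); depth2[10:12] <- 20
  expect_equal(nrow(call_deletions(depth_track("chr1", 100L, depth2), 40)), 0L)
  # two qualifying runs within the merge gap join; beyond it they stay apart
  depth3 <- rep(40, 300)
  depth3[101:110] <- 20; depth3[114:123] <- 20   # 3-bin gap
  depth3[200:209] <- 20                           # far away
  calls3 <- call_deletions(tr3 <- depth_track("chr1", 100L, depth3), 40)
  expect_equal(nrow(calls3), 2L)
  expect_equal(calls3$start[1], 100 * 100 + 1)
  expect_equal(calls3$end[1], 123 * 100)
})

test_that("three planted segments separated beyond the merge gap give three calls", {
  del <- data.frame(start = c(100001, 200001, 400001),
                    end = c(150000, 330000, 420000),
                    carrier = "child", origin = "paternal", de_novo = TRUE,
                    copies = 1L)
  spec <- simulation_spec(seed = 17, n_sites = 10, chrom_length = 5e5,
                          mean_coverage = 40, bin_size = 100, deletions = del)
  tr <- simulate_depth(spec)
  calls <- call_deletions(tr, 40)
  expect_equal(nrow(calls), 3L)
  expect_true(all(abs(calls$start - del$start) <= 100))
  expect_true(all(abs(calls$end - del$end) <= 100))
})

test_that("breakpoint recovery: median error at most one bin over 50 replicates", {
  del <- data.frame(start = 300001, end = 700000, carrier = "child",
                    origin = "paternal", de_novo = TRUE, copies = 1L)
  errs <- vapply(1:50, function(s) {
    spec <- simulation_spec(seed = 1000 + s, n_sites = 10,
                            chrom_length = 1e6, mean_coverage = 40,
                            bin_size = 100, deletions = del)
    tr <- simulate_depth(spec)
    calls <- call_deletions(tr, 40)
    big <- calls[which.max(calls$end - calls$start), ]
    max(abs(big$start - del$start), abs(big$end - del$end)) / 100
  }, numeric(1))
  expect_lte(median(errs), 1)
})

test_that("depth ratio matches expectation and recombines over sub-regions", {
  del <- data.frame(start = 200001, end = 500000, carrier = "child",
                    origin = "paternal", de_novo = TRUE, copies = 1L)
  spec <- simulation_spec(seed = 23, n_sites = 10, chrom_length = 1e6,
                          mean_coverage = 40, bin_size = 100, deletions = del)
  tr <- simulate_depth(spec)
  r_del <- depth_ratio(list(start = 200001, end = 500000), tr, 40)
  n_bins <- 3000
  se <- sqrt(20 / n_bins) / 40
  expect_lt(abs(r_del - 0.5), 3 * se)
  r_dip <- depth_ratio(list(start = 600001, end = 900000), tr, 40)
  expect_lt(abs(r_dip - 1.0), 3 * sqrt(40 / 3000) / 40)
  # whole-region ratio is the bin-weighted mean of half-region ratios
  r1 <- depth_ratio(list(start = 200001, end = 350000), tr, 40)
  r2 <- depth_ratio(list(start = 350001, end = 500000), tr, 40)
  expect_equal(r_del, (r1 * 1500 + r2 * 1500) / 3000)
  # partial edge bins are excluded; a region with no full bin yields NA
  expect_true(is.na(depth_ratio(list(start = 150, end = 220), tr, 40)))
})

test_that("SV/CNV post-call filters apply the published thresholds", {
  calls <- cnv_calls(data.frame(
    chrom = "chr1",
    start = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    end = c(1e4, 1e4, 1e4, 9999, 3e5, 1e5, 1e4, 1e4, 1e4, 1e4),
    svtype = c("DEL", "DEL", "DEL", "DEL", "DUP", "DUP", "DEL", "DEL",
               "DEL", "DEL"),
    caller = c("lumpy", "lumpy", "lumpy", "erds", "erds", "erds",
               "penncnv", "penncnv", "cnvnator", "cnvnator"),
    read_support = c(51, 4, 3, NA, NA, NA, NA, NA, NA, NA),
    confidence = c(NA, NA, NA, 400, 400, 400, NA, NA, NA, NA),
    n_markers = c(NA, NA, NA, NA, NA, NA, 10, 9, NA, NA),
    max_intermarker_gap = c(NA, NA, NA, NA, NA, NA, 50000, 1000, NA, NA),
    segdup_overlap_frac = c(0, 0, 0, 0, 0, 0, 0, 0, 0.49, 0.5),
    stringsAsFactors = FALSE))
  res <- filter_calls(calls)
  reasons <- setNames(res$removed$reason, res$removed$caller)
  # >50 reads excluded, >=4 kept, <4 excluded
  expect_true("read_support_high" %in% res$removed$reason)
  expect_true("read_support_low" %in% res$removed$reason)
  expect_true(any(res$kept$caller == "lumpy" & res$kept$read_support == 4))
  # deletion under 10 Kb excluded despite passing confidence
  expect_true("del_size" %in% res$removed$reason)
  # duplication under 200 Kb excluded, 300 Kb kept
  expect_true("dup_size" %in% res$removed$reason)
  expect_true(any(res$kept$caller == "erds" & res$kept$svtype == "DUP"))
  # array rules: 10 markers with 50 Kb gap kept, 9 markers removed
  expect_true(any(res$kept$caller == "penncnv"))
  expect_true("marker_count" %in% res$removed$reason)
  # segdup boundary: 0.49 kept, 0.50 removed
  expect_true(any(res$kept$segdup_overlap_frac == 0.49))
  expect_true("segdup_overlap" %in% res$removed$reason)
  # partition and idempotence
  expect_equal(nrow(res$kept) + nrow(res$removed), nrow(calls))
  again <- filter_calls(res$kept)
  expect_equal(nrow(again$removed), 0L)
})

test_that("calls missing a needed rule field are kept, flagged, and warned about", {
  calls <- cnv_calls(data.frame(
    chrom = "chr1", start = 1, end = 1e4, svtype = "DEL", caller = "lumpy",
    read_support = NA_real_, segdup_overlap_frac = 0,
    stringsAsFactors = FALSE))
  expect_warning(res <- filter_calls(calls), "unevaluable")
  expect_equal(nrow(res$kept), 1L)
  expect_true(res$unevaluable[1])
})
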