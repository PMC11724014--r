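arms3 <- mini_genome_arms()

prof <- function(...) {
  segs <- list(...)
  segment_profile(do.call(rbind, lapply(segs, function(s)
    data.frame(chrom = s[[1]], start = s[[2]], end = s[[3]],
               total_cn = s[[4]], minor_cn = s[[5]],
               stringsAsFactors = FALSE))), sample_id = "T",
    genome_build = "mini")
}

test_that("segment smoothing merges sub-threshold segments into the longer
           neighbour and coalesces equal states", {
  # 2 Mb fragment between two equal-state 20 Mb segments collapses entirely
  p1 <- prof(list("chr1", 1, 20e6, 2, 1),
             list("chr1", 20e6 + 1, 22e6, 1, 0),
             list("chr1", 22e6 + 1, 42e6, 2, 1))
  sm <- smooth_segments(p1)
  expect_equal(nrow(sm$segments), 1)
  expect_equal(sm$segments$end, 42e6)
  expect_equal(sm$segments$total_cn, 2)

  # all segments >= 3 Mb with distinct states: fixpoint
  p2 <- prof(list("chr1", 1, 20e6, 2, 1), list("chr1", 20e6 + 1, 42e6, 3, 1))
  expect_equal(smooth_segments(p2)$segments, p2$segments)

  # 2 Mb between unequal 10 Mb and 30 Mb neighbours adopts the 30 Mb state
  p3 <- prof(list("chr1", 1, 10e6, 2, 1),
             list("chr1", 10e6 + 1, 12e6, 1, 0),
             list("chr1", 12e6 + 1, 42e6, 3, 1))
  sm3 <- smooth_segments(p3)
  expect_equal(nrow(sm3$segments), 2)
  expect_equal(sm3$segments$total_cn, c(2, 3))
  expect_equal(sm3$segments$start[2], 10e6 + 1)

  # idempotence
  expect_equal(smooth_segments(sm3)$segments, sm3$segments)
})

test_that("HRD-LOH counts interstitial losses strictly longer than 15 Mb", {
  expect_equal(count_hrd_loh(prof(list("chr1", 30e6, 50e6 - 1, 1, 0)),
                             arms3), 1L)
  # whole-chromosome LOH is excluded
  expect_equal(count_hrd_loh(prof(list("chr1", 1, 100e6, 1, 0)), arms3), 0L)
  # exactly 15 Mb does not count (strictly greater required)
  expect_equal(count_hrd_loh(prof(list("chr1", 30e6 + 1, 45e6, 1, 0)),
                             arms3), 0L)
  expect_equal(count_hrd_loh(prof(list("chr1", 30e6, 45e6, 1, 0)),
                             arms3), 1L)
  # balanced segments never count
  expect_equal(count_hrd_loh(prof(list("chr1", 30e6, 60e6, 2, 1)),
                             arms3), 0L)
})

test_that("TAI counts imbalanced telomeric single-arm segments of at least
           11 Mb", {
  # 15 Mb imbalanced segment reaching the q telomere
  expect_equal(count_tai(prof(list("chr1", 85e6 + 1, 100e6, 3, 1)),
                         arms3), 1L)
  # crossing the centromere disqualifies
  expect_equal(count_tai(prof(list("chr1", 30e6, 100e6, 3, 1)), arms3), 0L)
  # balanced telomeric segment does not count
  expect_equal(count_tai(prof(list("chr1", 85e6 + 1, 100e6, 2, 1)),
                         arms3), 0L)
  # interstitial imbalance does not count
  expect_equal(count_tai(prof(list("chr1", 50e6, 70e6, 3, 1)), arms3), 0L)
  # too short
  expect_equal(count_tai(prof(list("chr1", 95e6 + 1, 100e6, 3, 1)),
                         arms3), 0L)
})

test_that("LST counts state transitions between long segments with small
           gaps", {
  # two adjacent 12 Mb segments in different states
  expect_equal(count_lst(prof(list("chr1", 50e6 + 1, 62e6, 2, 1),
                              list("chr1", 62e6 + 1, 74e6, 3, 1)),
                         arms3), 1L)
  # a short flank disqualifies the breakpoint
  expect_equal(count_lst(prof(list("chr1", 50e6 + 1, 62e6, 2, 1),
                              list("chr1", 62e6 + 1, 70e6, 3, 1)),
                         arms3), 0L)
  # a gap above 3 Mb disqualifies
  expect_equal(count_lst(prof(list("chr1", 46e6 + 1, 58e6, 2, 1),
                              list("chr1", 62e6 + 1, 74e6, 3, 1)),
                         arms3), 0L)
  # three consecutive 15 Mb segments with distinct states yield 2
  expect_equal(count_lst(prof(list("chr1", 43e6 + 1, 58e6, 2, 1),
                              list("chr1", 58e6 + 1, 73e6, 3, 1),
                              list("chr1", 73e6 + 1, 88e6, 4, 2)),
                         arms3), 2L)
})

test_that("planted scar events are recovered exactly and the score is
           invariant to relabelling", {
  tm <- gen_tumor(0.7, 90, "HETEROZYGOUS", c(loh = 2, tai = 1, lst = 3),
                  n_somatic = 0, seed = 31)
  h <- hrd_score(tm$sample$profile, tm$sample$arms)
  expect_equal(c(h$loh_count, h$tai_count, h$lst_count), c(2L, 1L, 3L))
  expect_equal(h$total, 6L)
  expect_false(h$hrd_high)

  # relabel chromosomes and permute rows: total unchanged
  seg <- tm$sample$profile$segments
  arms <- tm$sample$arms
  relab <- setNames(sample(arms$chrom), arms$chrom)
  seg$chrom <- unname(relab[seg$chrom])
  arms$chrom <- unname(relab[arms$chrom])
  seg <- seg[sample(nrow(seg)), ]
  h2 <- hrd_score(segment_profile(seg, "T", "mini"), arms)
  expect_equal(h2$total, h$total)
})

test_that("sex chromosomes are excluded from scar counting by default", {
  p <- segment_profile(data.frame(chrom = "chrX", start = 30e6, end = 60e6,
                                  total_cn = 1, minor_cn = 0),
                       genome_build = "mini")
  armsX <- rbind(arms3,
                 data.frame(chrom = "chrX", chrom_start = 1,
                            cen_start = 40e6, cen_end = 42e6,
                            chrom_end = 100e6))
  expect_equal(count_hrd_loh(p, armsX), 0L)
  expect_equal(count_hrd_loh(p, armsX, exclude_sex = FALSE), 1L)
})

test_that("the HRD total is the unweighted sum with threshold behaviour on
           an empty profile", {
  empty <- segment_profile(
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               total_cn = numeric(), minor_cn = numeric()),
    genome_build = "mini")
  h <- hrd_score(empty, arms3)
  expect_equal(h$total, 0L)
  expect_false(h$hrd_high)
})
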