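# handy constructor: chrom segments from (start, end, major, minor) rows
seg_prof <- function(..., sample_id = "s") {
  rows <- list(...)
  seg <- do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = r[[1]], start = r[[2]], end = r[[3]],
               major_cn = r[[4]], minor_cn = r[[5]], cell_frac = 1)))
  segment_profile(sample_id, seg)
}

asm <- toy_assembly()  # 100/80/60 Mb chromosomes, 1 Mb centromeres

test_that("merge_segments merges identical neighbours and is idempotent", {
  p <- seg_prof(list("chr1", 1, 10e6, 2, 1), list("chr1", 10e6 + 1, 30e6, 2, 1),
                list("chr1", 30e6 + 1, 45e6, 2, 0))
  m <- merge_segments(p)
  expect_equal(nrow(m$segments), 2L)
  expect_equal(m$segments$end[1], 30e6)
  expect_equal(merge_segments(m)$segments, m$segments)

  # different CN neighbours stay distinct
  p2 <- seg_prof(list("chr1", 1, 10e6, 2, 1), list("chr1", 10e6 + 1, 30e6, 2, 0))
  expect_equal(nrow(merge_segments(p2)$segments), 2L)

  # same CN across a gap >= 3 Mb stays distinct
  p3 <- seg_prof(list("chr1", 1, 10e6, 2, 1), list("chr1", 13e6 + 1, 30e6, 2, 1))
  expect_equal(nrow(merge_segments(p3)$segments), 2L)

  # idempotence on random profiles
  for (seed in 1:25) {
    p <- random_profile(oracle_assembly(), seed)
    if (is.null(p)) next
    m1 <- merge_segments(p)
    expect_equal(merge_segments(m1)$segments, m1$segments)
  }
})

test_that("hrd_loh counts large interstitial LOH events only", {
  # 20 Mb (1,0) on a 100 Mb chromosome: one event
  p <- seg_prof(list("chr1", 1, 20e6, 1, 1), list("chr1", 20e6 + 1, 40e6, 1, 0),
                list("chr1", 40e6 + 1, 100e6, 1, 1))
  expect_equal(hrd_loh(p, asm), 1L)
  # (1,0) spanning the whole chromosome: zero
  p <- seg_prof(list("chr1", 1, 100e6, 1, 0))
  expect_equal(hrd_loh(p, asm), 0L)
  # 14 Mb is below the threshold
  p <- seg_prof(list("chr1", 1, 20e6, 1, 1), list("chr1", 20e6 + 1, 34e6, 1, 0),
                list("chr1", 34e6 + 1, 100e6, 1, 1))
  expect_equal(hrd_loh(p, asm), 0L)
  # homozygous deletion is not LOH
  p <- seg_prof(list("chr1", 1, 20e6, 1, 1), list("chr1", 20e6 + 1, 40e6, 0, 0),
                list("chr1", 40e6 + 1, 100e6, 1, 1))
  expect_equal(hrd_loh(p, asm), 0L)
})

test_that("tai counts telomeric imbalance not crossing the centromere", {
  # (2,1) abutting the p telomere, ending before the centromere
  p <- seg_prof(list("chr1", 1, 20e6, 2, 1), list("chr1", 20e6 + 1, 100e6, 1, 1))
  expect_equal(tai(p, asm), 1L)
  # run crossing the centromere (49.5-50.5 Mb): zero
  p <- seg_prof(list("chr1", 1, 60e6, 2, 1), list("chr1", 60e6 + 1, 100e6, 1, 1))
  expect_equal(tai(p, asm), 0L)
  # interstitial imbalance: zero
  p <- seg_prof(list("chr1", 1, 10e6, 1, 1), list("chr1", 10e6 + 1, 30e6, 2, 1),
                list("chr1", 30e6 + 1, 100e6, 1, 1))
  expect_equal(tai(p, asm), 0L)
  # both telomeres imbalanced by separate runs: two events
  p <- seg_prof(list("chr1", 1, 20e6, 2, 1), list("chr1", 20e6 + 1, 80e6, 1, 1),
                list("chr1", 80e6 + 1, 100e6, 3, 1))
  expect_equal(tai(p, asm), 2L)
})

test_that("lst counts breakpoints between two large regions on one arm", {
  # 12 Mb (1,1) abutting 15 Mb (2,1) on the p arm
  p <- seg_prof(list("chr1", 1e6 + 1, 13e6, 1, 1),
                list("chr1", 13e6 + 1, 28e6, 2, 1),
                list("chr1", 28e6 + 1, 33e6, 3, 1))
  expect_equal(lst(p, asm), 1L)
  # second region too small (8 Mb)
  p <- seg_prof(list("chr1", 1e6 + 1, 13e6, 1, 1),
                list("chr1", 13e6 + 1, 21e6, 2, 1))
  expect_equal(lst(p, asm), 0L)
  # breakpoint across the centromere is not counted (arm-wise scoring)
  p <- seg_prof(list("chr1", 1, 49.5e6 - 1, 1, 1),
                list("chr1", 49.5e6, 100e6, 2, 1))
  expect_equal(lst(p, asm), 0L)
})

test_that("scar scores match the bin-scale oracle on random profiles", {
  oasm <- oracle_assembly()
  checked <- 0L
  for (seed in 1:150) {
    p <- random_profile(oasm, seed)
    if (is.null(p)) next
    checked <- checked + 1L
    expect_equal(hrd_loh(p, oasm), oracle_hrd_loh(p, oasm), info = seed)
    expect_equal(tai(p, oasm), oracle_tai(p, oasm), info = seed)
    expect_equal(lst(p, oasm), oracle_lst(p, oasm), info = seed)
  }
  expect_gt(checked, 100L)
})

test_that("scores are invariant to pre-merging and additive over chromosomes", {
  oasm <- oracle_assembly()
  for (seed in c(3, 17, 41)) {
    p <- random_profile(oasm, seed)
    m <- merge_segments(p)
    expect_equal(score_profile(p, oasm)[3:6], score_profile(m, oasm)[3:6])
    # additivity across disjoint chromosomes
    total <- score_profile(p, oasm)
    per_chrom <- lapply(unique(p$segments$chrom), function(ch) {
      q <- p; q$segments <- q$segments[q$segments$chrom == ch, ]
      score_profile(q, oasm)
    })
    expect_equal(total$hrd_score,
                 sum(vapply(per_chrom, `[[`, numeric(1), "hrd_score")))
  }
})

test_that("cin_fraction is the non-diploid covered fraction", {
  p <- seg_prof(list("chr1", 1, 100e6, 1, 1))
  expect_equal(cin_fraction(p, asm), 0)
  p <- seg_prof(list("chr1", 1, 100e6, 2, 2))
  expect_equal(cin_fraction(p, asm), 1)
  p <- seg_prof(list("chr1", 1, 50e6, 2, 1), list("chr1", 50e6 + 1, 100e6, 1, 1))
  expect_equal(cin_fraction(p, asm), 0.5)
  expect_error(cin_fraction(seg_prof(list("chrZ", 1, 10, 1, 1)), asm),
               "unknown chromosome")
})

test_that("detect_wgd uses a strict majority of major CN >= 2", {
  expect_true(detect_wgd(seg_prof(list("chr1", 1, 100e6, 2, 2)), asm))
  expect_false(detect_wgd(seg_prof(list("chr1", 1, 100e6, 1, 1)), asm))
  # exactly 50%: strictly greater is required
  p <- seg_prof(list("chr1", 1, 50e6, 2, 1), list("chr1", 50e6 + 1, 100e6, 1, 1))
  expect_false(detect_wgd(p, asm))
  p <- seg_prof(list("chr1", 1, 50e6 + 2, 2, 1),
                list("chr1", 50e6 + 3, 100e6, 1, 1))
  expect_true(detect_wgd(p, asm))
})

test_that("hrd phenotype combines score threshold and BRCA status", {
  expect_true(classify_hrd_phenotype(42, FALSE))
  expect_true(classify_hrd_phenotype(41, TRUE))
  expect_false(classify_hrd_phenotype(41, FALSE))
})

test_that("sex chromosomes are accepted on input and excluded from scores", {
  hg <- default_assembly()
  p <- seg_prof(list("chrX", 1, 100e6, 1, 0), list("chr1", 1, 249e6, 1, 1))
  expect_equal(hrd_loh(p, hg), 0L)
  expect_equal(cin_fraction(p, hg), 0)
})
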