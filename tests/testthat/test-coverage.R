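toy_design <- function() {
  target_design(data.frame(chrom = "chr1",
                           start = c(0, 200, 500, 700, 900),
                           end = c(100, 320, 560, 850, 1000)))
}

test_that("depth is zero with no reads and one per base under one read", {
  d <- target_design(data.frame(chrom = "chr1", start = 0, end = 100))
  p0 <- compute_depth(make_aln("chr1", integer(), integer()), d)
  expect_equal(unlist(p0$depth), integer(100), ignore_attr = TRUE)
  p1 <- compute_depth(make_aln("chr1", 0, 100), d)
  expect_equal(unlist(p1$depth), rep(1L, 100), ignore_attr = TRUE)
  # partial overlap touches only the overlapped bases
  p2 <- compute_depth(make_aln("chr1", 90, 140), d)
  expect_equal(sum(unlist(p2$depth)), 10)
  expect_equal(p2$depth[[1]][91:100], rep(1L, 10))
})

test_that("depth matches the naive per-position oracle on random reads", {
  d <- toy_design()
  set.seed(55)
  for (i in 1:40) {
    reads <- rand_reads(200)
    p <- compute_depth(reads, d)
    for (j in seq_len(d$n_regions))
      expect_equal(p$depth[[j]],
                   as.integer(oracle_region_depth(reads, d$regions[j, ])))
  }
})

test_that("depth conserves total read overlap and respects exclusion flags", {
  d <- toy_design()
  set.seed(66)
  reads <- rand_reads(300)
  reads$is_duplicate[sample(300, 40)] <- TRUE
  reads$is_mapped[sample(300, 20)] <- FALSE
  reads$start[!reads$is_mapped] <- NA
  reads$end[!reads$is_mapped] <- NA
  reads$chrom[!reads$is_mapped] <- NA
  reads$is_duplicate <- reads$is_duplicate & reads$is_mapped

  p <- compute_depth(reads, d)
  kept <- reads[reads$is_mapped & !reads$is_duplicate, ]
  mask <- mask_from_intervals(d$regions, 1000)
  overlap <- vapply(seq_len(nrow(kept)), function(i)
    sum(mask[(kept$start[i] + 1):kept$end[i]]), numeric(1))
  expect_equal(sum(unlist(p$depth)), sum(overlap))

  # keeping duplicates never lowers any base depth
  p_all <- compute_depth(reads, d, exclude_duplicates = FALSE)
  expect_true(all(unlist(p_all$depth) >= unlist(p$depth)))
})

test_that("reads on unknown chromosomes are skipped with a warning and counted", {
  d <- toy_design()
  reads <- rbind(make_aln("chr1", 0, 50), make_aln("chrMT", 0, 50))
  expect_warning(p <- compute_depth(reads, d), "chrMT")
  expect_equal(p$n_skipped, 1L)
  expect_equal(sum(unlist(p$depth)), 50)
})

test_that("region summaries report min/max/mean and threshold fractions", {
  d <- target_design(data.frame(chrom = "chr1", start = 0, end = 5))
  # depths 5,5,5,5,4: four reads over the region plus one stopping early
  reads <- make_aln("chr1", rep(0, 5), c(rep(5, 4), 4))
  s <- summarize_regions(compute_depth(reads, d), thresholds = c(1, 5))
  expect_equal(s$min_depth, 4L)
  expect_equal(s$max_depth, 5L)
  expect_equal(s$frac_cov_5, 0.8)
  expect_equal(s$frac_cov_1, 1)

  # all-zero region
  d10 <- target_design(data.frame(chrom = "chr1", start = 0, end = 10))
  s0 <- summarize_regions(compute_depth(make_aln("chr1", integer(),
                                                 integer()), d10))
  expect_equal(s0$min_depth, 0L)
  expect_equal(s0$max_depth, 0L)
  expect_equal(s0$frac_cov_1, 0)

  # fractions never increase with the threshold; mean between min and max
  set.seed(77)
  p <- compute_depth(rand_reads(150), toy_design())
  sr <- summarize_regions(p, thresholds = c(1, 3, 5, 8))
  expect_true(all(sr$frac_cov_1 >= sr$frac_cov_3 &
                    sr$frac_cov_3 >= sr$frac_cov_5 &
                    sr$frac_cov_5 >= sr$frac_cov_8))
  expect_true(all(sr$min_depth <= sr$mean_depth + 1e-9 &
                    sr$mean_depth <= sr$max_depth + 1e-9))
})

test_that("summarize_region addresses one design region and rejects others", {
  d <- toy_design()
  set.seed(88)
  p <- compute_depth(rand_reads(100), d)
  one <- summarize_region(p, 3)
  expect_equal(one$start, 500)
  by_coord <- summarize_region(p, data.frame(chrom = "chr1", start = 500,
                                             end = 560))
  expect_equal(one, by_coord)
  expect_error(summarize_region(p, data.frame(chrom = "chr1", start = 501,
                                              end = 560)), "not in the design")
  expect_error(summarize_region(p, 99), "out of range")
})

test_that("completeness curve follows its defining recount", {
  d <- toy_design()
  # fully covered everywhere -> flat 100%
  full <- make_aln("chr1", d$regions$start, d$regions$end)
  s_full <- summarize_regions(compute_depth(full, d), thresholds = 1)
  cc <- completeness_curve(s_full, t = 1)
  expect_true(all(cc$pct_regions == 100))

  # one region 50% covered, one fully covered
  d2 <- target_design(data.frame(chrom = "chr1", start = c(0, 100),
                                 end = c(10, 110)))
  reads2 <- make_aln("chr1", c(0, 100), c(5, 110))
  s2 <- summarize_regions(compute_depth(reads2, d2), thresholds = 1)
  cc2 <- completeness_curve(s2, t = 1, grid = c(0, 0.3, 0.5, 0.7, 1))
  expect_equal(cc2$pct_regions, c(100, 100, 100, 50, 50))

  # random case: brute-force recount at every grid point + shape invariants
  set.seed(99)
  s3 <- summarize_regions(compute_depth(rand_reads(120), d), thresholds = 5)
  grid <- seq(0, 1, 0.1)
  cc3 <- completeness_curve(s3, t = 5, grid = grid)
  brute <- vapply(grid, function(x)
    100 * sum(s3$frac_cov_5 >= x) / nrow(s3), numeric(1))
  expect_equal(cc3$pct_regions, brute)
  expect_true(all(diff(cc3$pct_regions) <= 0))
  expect_equal(cc3$pct_regions[1], 100)
  expect_error(completeness_curve(s3[0, ], t = 5), "non-empty")
})
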