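test_that("read accounting arithmetic and edge cases", {
  r <- read_accounting(list(total = 1000, mapped = 900, duplicate = 100))
  expect_equal(r$remaining, 800)
  expect_equal(r$remaining_pct, 80.0)
  # all mapped, none duplicate
  r2 <- read_accounting(make_aln("chr1", 0:9, 10:19))
  expect_equal(r2$remaining, 10)
  expect_equal(r2$remaining_pct, 100.0)
  expect_error(read_accounting(make_aln("chr1", integer(), integer())),
               "total is zero")
  expect_error(read_accounting(list(total = 10, mapped = 20, duplicate = 0)),
               "inconsistent")
})

test_that("mean depth is the sum over target bases divided by design size", {
  d <- target_design(data.frame(chrom = "chr1", start = 0, end = 50))
  p0 <- compute_depth(make_aln("chr1", integer(), integer()), d)
  expect_equal(mean_sequencing_depth(p0), 0)
  p7 <- compute_depth(make_aln("chr1", rep(0, 7), rep(50, 7)), d)
  expect_equal(mean_sequencing_depth(p7), 7)
  set.seed(12)
  reads <- rand_reads(80, chrom_len = 100, read_len = 20)
  p <- compute_depth(reads, d)
  expect_equal(mean_sequencing_depth(p), sum(unlist(p$depth)) / 50)
  expect_error(mean_sequencing_depth(
    compute_depth(make_aln("chr1", integer(), integer()),
                  target_design(list()))), "empty design")
})

test_that("region threshold counts and base coverage match brute force", {
  d <- target_design(data.frame(chrom = "chr1",
                                start = seq(0, 900, 100), end = seq(50, 950, 100)))
  set.seed(13)
  for (i in 1:20) {
    reads <- rand_reads(120)
    p <- compute_depth(reads, d)
    s <- summarize_regions(p, thresholds = c(1, 5))
    for (t in c(1, 5)) {
      rc <- region_threshold_counts(s, t)
      mins <- vapply(p$depth, min, numeric(1))
      maxs <- vapply(p$depth, max, numeric(1))
      expect_equal(rc$n_min_below, sum(mins < t))
      expect_equal(rc$n_max_below, sum(maxs < t))
      expect_lte(rc$n_max_below, rc$n_min_below)
      bc <- target_bp_covered(p, t)
      expect_equal(bc$n_covered, sum(unlist(p$depth) >= t))
    }
  }
  # fully covered at t -> zero counts
  full <- make_aln("chr1", rep(d$regions$start, 5), rep(d$regions$end, 5))
  sf <- summarize_regions(compute_depth(full, d), thresholds = 5)
  rcf <- region_threshold_counts(sf, 5)
  expect_equal(c(rcf$n_min_below, rcf$n_max_below), c(0, 0))
})

test_that("specificity counts retained reads overlapping the design", {
  d <- target_design(data.frame(chrom = c("chr1", "chr2"),
                                start = c(100, 0), end = c(200, 50)))
  on <- make_aln("chr1", c(150, 90, 199), c(250, 110, 299))  # >=1 bp overlap
  off <- make_aln("chr1", c(0, 300), c(90, 400))
  expect_equal(specificity(on, d)$pct, 100)
  expect_equal(specificity(off, d)$pct, 0)

  aln <- rbind(on, off)
  s <- specificity(aln, d)
  expect_equal(s$pct, 100 * 3 / 5)
  # permutation of record order changes nothing
  expect_equal(specificity(aln[sample(nrow(aln)), ], d)$pct, s$pct)

  # duplicates and unmapped are never on target; denominators differ
  aln$is_duplicate[1] <- TRUE
  aln <- rbind(aln, make_aln("chr1", NA, NA, is_mapped = FALSE))
  expect_equal(specificity(aln, d, "remaining")$pct, 100 * 2 / 4)
  expect_equal(specificity(aln, d, "mapped")$pct, 100 * 2 / 5)
  expect_equal(specificity(aln, d, "total")$pct, 100 * 2 / 6)

  # per-chromosome: chr2 has no reads -> NA, not 0
  sc <- specificity(aln, d, by_chrom = TRUE)
  expect_true(is.na(sc$by_chrom[["chr2"]]))
  expect_false(is.na(sc$by_chrom[["chr1"]]))

  # min_overlap is configurable
  one_bp <- make_aln("chr1", 199, 299)
  expect_equal(specificity(one_bp, d, min_overlap = 1)$pct, 100)
  expect_equal(specificity(one_bp, d, min_overlap = 2)$pct, 0)
})

test_that("sample_report assembles a consistent per-sample summary", {
  cfg <- sim_config(chrom_sizes = c(chr1 = 400000L), n_target_regions = 40,
                    n_samples = 1, reads_per_sample = 6000, seed = 21)
  e <- simulate_experiment(cfg)
  m <- sample_report(e$alignments$S1, e$design)
  expect_s3_class(m, "sample_metrics")
  expect_equal(m$reads$remaining, m$reads$mapped - m$reads$duplicate)
  expect_true(all(m$regions$pct_max_below <= m$regions$pct_min_below))
  expect_equal(m$regions$pct_fully_covered + m$regions$pct_min_below,
               rep(100, 2), tolerance = 0.011)
  # monotonicity in t
  expect_lte(m$regions$pct_fully_covered[m$regions$threshold == 5],
             m$regions$pct_fully_covered[m$regions$threshold == 1])
  expect_lte(m$bases$pct_covered[m$bases$threshold == 5],
             m$bases$pct_covered[m$bases$threshold == 1])
  row <- as.data.frame(m)
  pc <- unlist(row[grep("pct|specificity", names(row))])
  expect_true(all(pc >= 0 & pc <= 100))
})

test_that("metrics agree between SAM and TSV renderings of the same reads", {
  cfg <- sim_config(chrom_sizes = c(chr1 = 300000L), n_target_regions = 30,
                    n_samples = 1, reads_per_sample = 3000, seed = 31)
  e <- simulate_experiment(cfg)
  a <- e$alignments$S1
  tsv <- tempfile(fileext = ".tsv"); sam <- tempfile(fileext = ".sam")
  write_alignments_tsv(a, tsv)
  write_sam(a, sam, cfg$chrom_sizes)
  m_tsv <- sample_report(read_alignments(tsv), e$design)
  m_sam <- sample_report(read_alignments(sam, sample_id = "S1"), e$design)
  expect_equal(m_tsv$reads, m_sam$reads)
  expect_equal(m_tsv$mean_depth, m_sam$mean_depth)
  expect_equal(m_tsv$regions, m_sam$regions)
  expect_equal(m_tsv$bases, m_sam$bases)
  expect_equal(m_tsv$specificity$pct, m_sam$specificity$pct)
})
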