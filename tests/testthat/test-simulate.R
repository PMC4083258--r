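small_cfg <- function(...) {
  sim_config(chrom_sizes = c(chr1 = 500000L, chr2 = 300000L),
             n_target_regions = 50, n_samples = 2,
             reads_per_sample = 8000, seed = 7, ...)
}

test_that("config validation rejects bad parameters", {
  expect_error(sim_config(on_target_fraction = 1.2), "probability")
  expect_error(sim_config(reads_per_sample = 10001), "even")
  expect_error(sim_config(n_samples = 0), "positive")
  expect_error(sim_config(target_region_length_range = c(300, 100)),
               "min, max")
  expect_error(sim_config(chrom_sizes = c(chr1 = 1000),
                          n_target_regions = 100,
                          target_region_length_range = c(50, 50)),
               "exceeds genome")
})

test_that("simulated designs respect the configured constraints", {
  cfg <- sim_config(chrom_sizes = c(chr1 = 1000000L), n_target_regions = 100,
                    target_region_length_range = c(100, 300), seed = 3)
  d <- simulate_design(cfg)
  expect_equal(d$n_regions, 100L)
  expect_gte(d$total_bp, 10000)
  expect_lte(d$total_bp, 30000)
  len <- d$regions$end - d$regions$start
  expect_true(all(len >= 100 & len <= 300))
  # empty design
  cfg0 <- sim_config(n_target_regions = 0)
  expect_equal(simulate_design(cfg0)$n_regions, 0L)
  # infeasible packing
  cfg_bad <- sim_config(chrom_sizes = c(chr1 = 150L, chr2 = 150L),
                        n_target_regions = 2,
                        target_region_length_range = c(100, 100), seed = 1)
  # each chromosome fits one 100 bp region; both on one chromosome cannot
  expect_error(
    for (s in 1:30) {
      cfg_bad$seed <- s
      simulate_design(cfg_bad)
    }, "infeasible packing")
})

test_that("simulation is deterministic given the seed, byte for byte", {
  cfg <- small_cfg()
  e1 <- simulate_experiment(cfg)
  e2 <- simulate_experiment(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_bed(e1$design, f1); write_bed(e2$design, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(e1$alignments, e2$alignments)
  # different seed, different reads
  cfg2 <- small_cfg(); cfg2$seed <- 8L
  expect_false(identical(simulate_experiment(cfg2)$alignments,
                         e1$alignments))
})

test_that("on_target_fraction=1 with no dropout puts every retained read on target", {
  cfg <- small_cfg(on_target_fraction = 1, dropout_region_fraction = 0,
                   duplicate_rate = 0, unmapped_rate = 0)
  e <- simulate_experiment(cfg)
  s <- specificity(e$alignments$S1, e$design)
  expect_equal(s$pct, 100)
  expect_equal(sum(e$alignments$S1$is_duplicate), 0L)
})

test_that("duplicate flags and unmapped rates behave as configured", {
  cfg <- small_cfg(duplicate_rate = 0)
  e <- simulate_experiment(cfg)
  expect_equal(sum(e$alignments$S1$is_duplicate), 0L)

  cfg2 <- small_cfg(unmapped_rate = 0)
  e2 <- simulate_experiment(cfg2)
  expect_true(all(e2$alignments$S1$is_mapped))
  # duplicates are exact coordinate copies of another fragment
  a <- e2$alignments$S1
  dup_keys <- unique(paste(a$chrom, a$start, a$end)[a$is_duplicate])
  orig_keys <- paste(a$chrom, a$start, a$end)[!a$is_duplicate]
  expect_true(all(dup_keys %in% orig_keys))
})

test_that("fragment-level on-target proportion concentrates on the configured value", {
  cfg <- sim_config(n_samples = 1, reads_per_sample = 100000,
                    duplicate_rate = 0, unmapped_rate = 0, seed = 19)
  e <- simulate_experiment(cfg)
  s <- specificity(e$alignments$S1, e$design)
  n_frag <- 50000
  tol <- 3 * sqrt(0.9 * 0.1 / n_frag)          # ~0.004
  expect_lt(abs(s$pct / 100 - 0.9), tol)
})

test_that("dropout regions get no fragments and are recovered as zero-coverage", {
  # geometry chosen so reads cannot bleed across the inter-region gaps:
  # fragment = read = 100 bp, few big regions on a large genome
  cfg <- sim_config(chrom_sizes = c(chr1 = 2000000L), n_target_regions = 10,
                    target_region_length_range = c(200, 400),
                    n_samples = 2, reads_per_sample = 4000,
                    read_length = 100, fragment_length_mean = 100,
                    fragment_length_sd = 0,
                    on_target_fraction = 1, duplicate_rate = 0,
                    unmapped_rate = 0, dropout_region_fraction = 0.2,
                    seed = 11)
  e <- simulate_experiment(cfg)
  dropout <- attr(e$alignments, "dropout_regions")
  expect_length(dropout, 2L)
  # generative guarantee: no fragment midpoint inside a dropout region
  for (a in e$alignments) {
    mid <- (a$start + a$end) / 2
    for (i in dropout) {
      r <- e$design$regions[i, ]
      expect_false(any(a$chrom == r$chrom & mid >= r$start & mid < r$end))
    }
  }
  # and the coverage engine sees exactly those regions as never covered
  profiles <- lapply(names(e$alignments), function(s)
    compute_depth(e$alignments[[s]], e$design, s))
  zero_everywhere <- which(Reduce(`&`, lapply(profiles, function(p)
    vapply(p$depth, function(v) all(v == 0), logical(1)))))
  expect_identical(zero_everywhere, dropout)
})

test_that("coordinate-based duplicate marking matches the rule on a crafted case", {
  aln <- rbind(
    make_aln("chr1", c(0, 0), c(100, 100),
             read_id = c("S1.f1/1", "S1.f1/2")),       # fragment A
    make_aln("chr1", c(0, 0), c(100, 100),
             read_id = c("S1.f2/1", "S1.f2/2")),       # copy of A -> dup
    make_aln("chr1", c(50, 50), c(150, 150),
             read_id = c("S1.f3/1", "S1.f3/2")),       # distinct
    make_aln("chr1", c(0, 0), c(100, 100), sample_id = "S2",
             read_id = c("S2.f1/1", "S2.f1/2")))       # other sample: kept
  m <- mark_duplicates(aln)
  expect_equal(m$is_duplicate,
               c(FALSE, FALSE, TRUE, TRUE, rep(FALSE, 4)))
  # unmapped reads never flagged
  aln$is_mapped[5:6] <- FALSE
  aln$start[5:6] <- NA; aln$end[5:6] <- NA; aln$chrom[5:6] <- NA
  expect_false(any(mark_duplicates(aln)$is_duplicate[5:6]))
})
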