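# Brute-force per-position oracles and tiny fixture builders. These stay
# deliberately naive (boolean masks, O(reads x bases) counting) so they are
# independent of the IRanges-based implementation paths they check.

# boolean occupancy mask of a set of 0-based half-open intervals
mask_from_intervals <- function(df, len) {
  mask <- logical(len)
  for (i in seq_len(nrow(df)))
    if (df$end[i] > df$start[i])
      mask[(df$start[i] + 1):df$end[i]] <- TRUE
  mask
}

# union size and maximal-run count from the mask (single chromosome)
oracle_union_stats <- function(df, len) {
  mask <- mask_from_intervals(df, len)
  runs <- rle(mask)
  list(total_bp = sum(mask), n_regions = sum(runs$values))
}

# per-position depth of a region by counting overlapping reads one base at
# a time
oracle_region_depth <- function(reads, region) {
  vapply((region$start + 1):region$end, function(p1) {
    p <- p1 - 1  # 0-based position
    sum(reads$start <= p & p < reads$end)
  }, numeric(1))
}

rand_intervals <- function(n, chrom = "chr1", chrom_len = 1000,
                           max_len = 100) {
  start <- sample.int(chrom_len, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = chrom, start = start,
             end = pmin(start + len, chrom_len))
}

# quick alignment table builder; reads default to mapped, non-duplicate
make_aln <- function(chrom, start, end, sample_id = "S1",
                     is_mapped = TRUE, is_duplicate = FALSE,
                     read_id = NULL) {
  n <- length(start)
  if (is.null(read_id)) read_id <- sprintf("%s.f%06d/1", sample_id, seq_len(n))
  data.frame(read_id = read_id,
             sample_id = rep_len(sample_id, n),
             chrom = rep_len(chrom, n),
             start = as.integer(start), end = as.integer(end),
             is_mapped = rep_len(is_mapped, n),
             is_duplicate = rep_len(is_duplicate, n),
             stringsAsFactors = FALSE)
}

# random reads over a toy chromosome
rand_reads <- function(n, chrom = "chr1", chrom_len = 1000, read_len = 50,
                       sample_id = "S1") {
  start <- sample.int(chrom_len - read_len, n, replace = TRUE) - 1L
  make_aln(chrom, start, start + read_len, sample_id = sample_id)
}

# naive per-read overlap with the design, via per-chromosome masks
per_read_design_overlap <- function(reads, design) {
  masks <- lapply(split(design$regions, design$regions$chrom), function(d)
    mask_from_intervals(d, max(d$end) + 1000L))
  vapply(seq_len(nrow(reads)), function(i) {
    m <- masks[[reads$chrom[i]]]
    if (is.null(m)) return(0)
    lo <- max(reads$start[i] + 1, 1)
    hi <- min(reads$end[i], length(m))
    if (lo > hi) return(0)
    sum(m[lo:hi])
  }, numeric(1))
}

# depth profile built directly from given per-region depth vectors, for
# tests that specify depths rather than reads
profile_from_depths <- function(design, depths, sample_id = "S") {
  structure(list(sample_id = sample_id, design = design, depth = depths,
                 n_skipped = 0L),
            class = "depth_profile")
}
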