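#' Per-target-base depth of coverage
#'
#' Computes the depth profile of one sample over every base of a target
#' design: each retained read adds one to every design base it overlaps
#' (reads partially overlapping a region contribute only to the overlapped
#' bases). By default duplicates and unmapped reads are excluded, matching
#' the convention of computing depth after duplicate removal. Depth is
#' per-read: overlapping mates of a pair double-count, as in a naive pileup.
#'
#' Reads on chromosomes unknown to the design (and its `chrom_sizes`, when
#' present) are skipped with a warning and counted in the result.
#'
#' @param aln alignment data.frame (columns as in [simulate_reads])
#' @param design a [target_design]
#' @param sample_id label for the profile; defaults to the single sample id
#'   present in `aln`
#' @param exclude_duplicates,exclude_unmapped drop flagged reads before
#'   counting (defaults `TRUE`)
#' @return object of class `depth_profile`: list with `sample_id`, `design`,
#'   `depth` (list of integer vectors, one per design region, in design
#'   order) and `n_skipped`
#' @export
compute_depth <- function(aln, design, sample_id = NULL,
                          exclude_duplicates = TRUE,
                          exclude_unmapped = TRUE) {
  stopifnot(inherits(design, "target_design"))
  validate_alignments(aln)
  if (is.null(sample_id)) {
    ids <- unique(aln$sample_id)
    sample_id <- if (length(ids) == 1L) ids else "combined"
  }
  keep <- rep(TRUE, nrow(aln))
  if (exclude_unmapped) keep <- keep & aln$is_mapped
  if (exclude_duplicates) keep <- keep & !aln$is_duplicate
  aln <- aln[keep & aln$is_mapped, , drop = FALSE]  # unmapped have no span

  known <- union(design$regions$chrom, names(design$chrom_sizes))
  skip <- !(aln$chrom %in% known)
  if (any(skip)) {
    warning(sum(skip), " read(s) on unknown chromosome(s) skipped: ",
            paste(unique(aln$chrom[skip]), collapse = ", "), call. = FALSE)
    aln <- aln[!skip, , drop = FALSE]
  }

  r <- design$regions
  depth <- vector("list", nrow(r))
  for (cn in unique(r$chrom)) {
    ri <- which(r$chrom == cn)
    a <- aln[aln$chrom == cn, , drop = FALSE]
    width <- max(r$end[ri], if (nrow(a)) max(a$end) else 0L)
    cov <- if (nrow(a))
      as.integer(IRanges::coverage(
        IRanges::IRanges(start = a$start + 1L, end = a$end), width = width))
    else integer(width)
    depth[ri] <- lapply(ri, function(i) cov[(r$start[i] + 1L):r$end[i]])
  }
  structure(list(sample_id = sample_id, design = design, depth = depth,
                 n_skipped = sum(skip)),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  d <- unlist(x$depth)
  cat(sprintf("Depth profile for %s: %d regions, %s target bp\n",
              x$sample_id, x$design$n_regions,
              format(x$design$total_bp, big.mark = ",")))
  if (length(d))
    cat(sprintf("  mean depth %.1fx (min %d, max %d), %.1f%% of bases >= 1x\n",
                mean(d), min(d), max(d), 100 * mean(d >= 1)))
  if (x$n_skipped) cat("  ", x$n_skipped, "read(s) skipped\n")
  invisible(x)
}

#' Summarise coverage of every design region
#'
#' Per-region minimum, maximum and mean depth, plus the fraction of region
#' bases at or above each threshold (`frac_cov_<t>` columns). A region is
#' "completely covered at t" when `min >= t`, i.e. `frac_cov_<t> == 1`.
#'
#' @param profile a [compute_depth] result
#' @param thresholds integer depth thresholds (default `c(1, 5)`)
#' @return data.frame with one row per region: `chrom`, `start`, `end`,
#'   `length`, `min_depth`, `max_depth`, `mean_depth`, `frac_cov_<t>` ...
#' @export
summarize_regions <- function(profile, thresholds = c(1, 5)) {
  stopifnot(inherits(profile, "depth_profile"))
  thresholds <- validate_thresholds(thresholds)
  r <- profile$design$regions
  d <- profile$depth
  out <- data.frame(
    chrom = r$chrom, start = r$start, end = r$end,
    length = r$end - r$start,
    min_depth = vapply(d, function(v) if (length(v)) min(v) else NA_integer_,
                       integer(1)),
    max_depth = vapply(d, function(v) if (length(v)) max(v) else NA_integer_,
                       integer(1)),
    mean_depth = vapply(d, function(v) if (length(v)) mean(v) else NA_real_,
                        numeric(1)))
  for (t in thresholds)
    out[[sprintf("frac_cov_%d", t)]] <-
      vapply(d, function(v) mean(v >= t), numeric(1))
  attr(out, "thresholds") <- thresholds
  attr(out, "sample_id") <- profile$sample_id
  out
}

#' Summarise one region of a depth profile
#'
#' @param profile a [compute_depth] result
#' @param region single-row data.frame (`chrom`,`start`,`end`) or an index
#'   into the design's region list; the region must be part of the design
#' @param thresholds integer depth thresholds
#' @return one-row data.frame as in [summarize_regions]
#' @export
summarize_region <- function(profile, region, thresholds = c(1, 5)) {
  stopifnot(inherits(profile, "depth_profile"))
  r <- profile$design$regions
  if (is.numeric(region)) {
    i <- as.integer(region)
    if (length(i) != 1L || is.na(i) || i < 1L || i > nrow(r))
      qc_stop("region index out of range")
  } else {
    i <- which(r$chrom == region$chrom & r$start == region$start &
                 r$end == region$end)
    if (length(i) != 1L)
      qc_stop("region ", region$chrom, ":", region$start, "-", region$end,
              " is not in the design")
  }
  summarize_regions(profile, thresholds)[i, , drop = FALSE]
}

validate_thresholds <- function(thresholds) {
  if (!is.numeric(thresholds) || !length(thresholds) ||
      any(is.na(thresholds)) || any(thresholds < 1) ||
      any(thresholds != as.integer(thresholds)))
    qc_stop("'thresholds' must be integers >= 1")
  sort(unique(as.integer(thresholds)))
}

#' Region completeness curve
#'
#' For a grid of completeness fractions x in \[0, 1\], the percentage of
#' regions whose fraction of bases covered at depth >= `t` is at least x:
#' the relation between how much of each region is sequenced and how many
#' regions reach that completeness. The curve is non-increasing, starts at
#' 100% (every region has >= 0 of its bases covered) and ends, at x = 1, at
#' the percentage of completely covered regions.
#'
#' @param summaries a [summarize_regions] table containing `frac_cov_<t>`
#' @param t depth threshold (default 5)
#' @param grid completeness fractions (default `seq(0, 1, 0.05)`)
#' @return data.frame with columns `x` and `pct_regions`
#' @export
completeness_curve <- function(summaries, t = 5, grid = seq(0, 1, 0.05)) {
  if (!is.data.frame(summaries) || nrow(summaries) == 0L)
    qc_stop("'summaries' must be a non-empty region summary table")
  col <- sprintf("frac_cov_%d", as.integer(t))
  if (!col %in% names(summaries))
    qc_stop("no ", col, " column; recompute summaries with threshold ", t)
  if (any(grid < 0 | grid > 1)) qc_stop("'grid' fractions must be in [0,1]")
  frac <- summaries[[col]]
  data.frame(x = grid,
             pct_regions = vapply(grid, function(x) 100 * mean(frac >= x),
                                  numeric(1)))
}
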