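#' Read accounting for one sample
#'
#' The standard read bookkeeping of a capture experiment: total reads,
#' mapped reads, duplicate reads, the remaining (mapped, non-duplicate)
#' reads used for coverage, and the percentage of total reads remaining
#' (reported to 1 decimal, half-up).
#'
#' @param aln alignment data.frame, or a list of pre-computed counts with
#'   elements `total`, `mapped`, `duplicate` (for recomputing published
#'   table rows)
#' @return list with `total`, `mapped`, `duplicate`, `remaining`,
#'   `remaining_pct` (1 dp) and `remaining_pct_raw`
#' @examples
#' read_accounting(list(total = 82574410, mapped = 77392469,
#'                      duplicate = 4820648))
#' @export
read_accounting <- function(aln) {
  if (is.data.frame(aln)) {
    validate_alignments(aln)
    counts <- list(total = nrow(aln), mapped = sum(aln$is_mapped),
                   duplicate = sum(aln$is_duplicate))
  } else if (is.list(aln) &&
             all(c("total", "mapped", "duplicate") %in% names(aln))) {
    counts <- lapply(aln[c("total", "mapped", "duplicate")], as.numeric)
  } else qc_stop("'aln' must be an alignment data.frame or a count list")
  if (counts$total == 0) qc_stop("no reads: total is zero")
  if (counts$mapped > counts$total || counts$duplicate > counts$mapped)
    qc_stop("inconsistent counts: need duplicate <= mapped <= total")
  remaining <- counts$mapped - counts$duplicate
  raw <- 100 * remaining / counts$total
  c(counts, list(remaining = remaining,
                 remaining_pct = round_half_up(raw, 1),
                 remaining_pct_raw = raw))
}

#' Mean sequencing depth over the target
#'
#' Sum of depth over all target bases divided by the design size, zero-depth
#' target bases included.
#'
#' @param profile a [compute_depth] result
#' @return mean depth (x)
#' @export
mean_sequencing_depth <- function(profile) {
  stopifnot(inherits(profile, "depth_profile"))
  if (profile$design$total_bp == 0L) qc_stop("empty design: no target bases")
  sum(as.numeric(unlist(profile$depth))) / profile$design$total_bp
}

#' Regions below a depth threshold
#'
#' Counts design regions whose minimum depth is below `t` (not completely
#' covered at `t`) and whose maximum depth is below `t` (never reaching `t`
#' anywhere), with percentages of all regions to 2 decimals.
#'
#' @param summaries a [summarize_regions] table covering all design regions
#' @param t depth threshold
#' @return list with `n_min_below`, `n_max_below`, `pct_min_below`,
#'   `pct_max_below` (2 dp) and the `_raw` percentages
#' @export
region_threshold_counts <- function(summaries, t) {
  if (!is.data.frame(summaries) || nrow(summaries) == 0L)
    qc_stop("'summaries' must be a non-empty region summary table")
  n <- nrow(summaries)
  n_min <- sum(summaries$min_depth < t)
  n_max <- sum(summaries$max_depth < t)
  list(n_min_below = n_min, n_max_below = n_max,
       pct_min_below = round_half_up(100 * n_min / n, 2),
       pct_max_below = round_half_up(100 * n_max / n, 2),
       pct_min_below_raw = 100 * n_min / n,
       pct_max_below_raw = 100 * n_max / n)
}

#' Target bases covered at a depth threshold
#'
#' @param profile a [compute_depth] result
#' @param t depth threshold
#' @return list with `n_covered`, `pct_covered` (2 dp) and
#'   `pct_covered_raw`: percentage of design bases with depth >= `t`
#' @export
target_bp_covered <- function(profile, t) {
  stopifnot(inherits(profile, "depth_profile"))
  if (profile$design$total_bp == 0L) qc_stop("empty design: no target bases")
  n <- sum(vapply(profile$depth, function(v) sum(v >= t), numeric(1)))
  raw <- 100 * n / profile$design$total_bp
  list(n_covered = n, pct_covered = round_half_up(raw, 2),
       pct_covered_raw = raw)
}

#' On-target specificity
#'
#' The fraction of reads overlapping the target design by at least
#' `min_overlap` bases, as a percentage. A read is counted on-target only if
#' it is retained (mapped and not a duplicate). The denominator is
#' selectable: `"remaining"` (retained reads, the default), `"mapped"`, or
#' `"total"` (all reads including unmapped).
#'
#' With `by_chrom = TRUE` a per-chromosome breakdown is returned, each
#' chromosome using only the reads mapped to it and the design regions on
#' it; chromosomes with a zero denominator get `NA`.
#'
#' @param aln alignment data.frame
#' @param design a [target_design]
#' @param denominator which read count to divide by
#' @param by_chrom also compute per-chromosome specificity
#' @param min_overlap minimum overlap in bases to call a read on-target
#' @return list with `pct` (percentage), `n_on_target`, `denominator`,
#'   `denominator_n`, and `by_chrom` (named vector of percentages) when
#'   requested
#' @export
specificity <- function(aln, design,
                        denominator = c("remaining", "mapped", "total"),
                        by_chrom = FALSE, min_overlap = 1) {
  stopifnot(inherits(design, "target_design"))
  validate_alignments(aln)
  denominator <- match.arg(denominator)
  retained <- aln$is_mapped & !aln$is_duplicate
  on <- logical(nrow(aln))
  r <- design$regions
  for (cn in unique(r$chrom)) {
    i <- which(retained & aln$chrom == cn)
    if (!length(i)) next
    ir <- IRanges::IRanges(start = aln$start[i] + 1L, end = aln$end[i])
    dr <- IRanges::IRanges(start = r$start[r$chrom == cn] + 1L,
                           end = r$end[r$chrom == cn])
    ov <- IRanges::findOverlaps(ir, dr, minoverlap = as.integer(min_overlap))
    on[i[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  denom_mask <- switch(denominator,
                       total = rep(TRUE, nrow(aln)),
                       mapped = aln$is_mapped,
                       remaining = retained)
  denom_n <- sum(denom_mask)
  if (denom_n == 0) qc_stop("zero reads in the '", denominator,
                            "' denominator")
  out <- list(pct = 100 * sum(on) / denom_n, n_on_target = sum(on),
              denominator = denominator, denominator_n = denom_n)
  if (by_chrom) {
    chroms <- sort(unique(r$chrom))
    out$by_chrom <- vapply(chroms, function(cn) {
      d <- sum(denom_mask & !is.na(aln$chrom) & aln$chrom == cn)
      if (d == 0) NA_real_ else 100 * sum(on & aln$chrom == cn) / d
    }, numeric(1))
  }
  out
}

#' Per-sample capture performance report
#'
#' Assembles the full per-sample summary: read accounting, mean target
#' depth, region completeness and base coverage at each depth threshold,
#' and on-target specificity (overall and per chromosome). Depth is
#' computed from retained (mapped, non-duplicate) reads.
#'
#' @param aln alignment data.frame for one sample (or pooled reads)
#' @param design a [target_design]
#' @param thresholds depth thresholds (default `c(1, 5)`)
#' @param denominator specificity denominator, see [specificity]
#' @param profile optional pre-computed [compute_depth] result for `aln`
#' @return object of class `sample_metrics`
#' @export
sample_report <- function(aln, design, thresholds = c(1, 5),
                          denominator = "remaining", profile = NULL) {
  thresholds <- validate_thresholds(thresholds)
  reads <- read_accounting(aln)
  if (is.null(profile)) profile <- compute_depth(aln, design)
  summaries <- summarize_regions(profile, thresholds)
  n_reg <- design$n_regions

  regions <- do.call(rbind, lapply(thresholds, function(t) {
    rc <- region_threshold_counts(summaries, t)
    data.frame(threshold = t,
               n_min_below = rc$n_min_below, n_max_below = rc$n_max_below,
               pct_min_below = rc$pct_min_below,
               pct_max_below = rc$pct_max_below,
               n_fully_covered = n_reg - rc$n_min_below,
               pct_fully_covered =
                 round_half_up(100 - rc$pct_min_below_raw, 2),
               pct_min_below_raw = rc$pct_min_below_raw,
               pct_max_below_raw = rc$pct_max_below_raw)
  }))
  bases <- do.call(rbind, lapply(thresholds, function(t) {
    bc <- target_bp_covered(profile, t)
    data.frame(threshold = t, n_covered = bc$n_covered,
               pct_covered = bc$pct_covered,
               pct_covered_raw = bc$pct_covered_raw)
  }))
  spec <- specificity(aln, design, denominator = denominator,
                      by_chrom = TRUE)
  out <- structure(list(sample_id = profile$sample_id,
                        reads = reads,
                        mean_depth = mean_sequencing_depth(profile),
                        thresholds = thresholds,
                        regions = regions,
                        bases = bases,
                        specificity = spec,
                        n_regions = n_reg,
                        total_bp = design$total_bp),
                   class = "sample_metrics")
  validate_sample_metrics(out)
  out
}

# internal consistency: partition/monotonicity identities of the summary
validate_sample_metrics <- function(m) {
  r <- m$reads
  stopifnot(r$remaining == r$mapped - r$duplicate,
            all(m$regions$pct_min_below_raw >= m$regions$pct_max_below_raw),
            all(abs(m$regions$pct_fully_covered +
                      m$regions$pct_min_below_raw - 100) < 0.01 +
                  1e-9))
  pcts <- c(r$remaining_pct, m$regions$pct_min_below, m$regions$pct_max_below,
            m$regions$pct_fully_covered, m$bases$pct_covered,
            m$specificity$pct)
  stopifnot(all(pcts >= 0 & pcts <= 100))
  if (length(m$thresholds) > 1L) {
    stopifnot(!is.unsorted(m$regions$pct_min_below_raw),   # rising with t
              !is.unsorted(rev(m$bases$pct_covered_raw)))  # falling with t
  }
  invisible(m)
}

#' @export
print.sample_metrics <- function(x, ...) {
  r <- x$reads
  cat(sprintf("Sample %s\n", x$sample_id))
  cat(sprintf("  reads: %s total, %s mapped, %s duplicate, %s remaining (%.1f%%)\n",
              format(r$total, big.mark = ","), format(r$mapped, big.mark = ","),
              format(r$duplicate, big.mark = ","),
              format(r$remaining, big.mark = ","), r$remaining_pct))
  cat(sprintf("  mean target depth: %.1fx over %s bp (%d regions)\n",
              x$mean_depth, format(x$total_bp, big.mark = ","), x$n_regions))
  for (i in seq_len(nrow(x$regions)))
    cat(sprintf("  t=%d: %.2f%% regions fully covered, %.2f%% regions never reach t, %.2f%% target bp covered\n",
                x$regions$threshold[i], x$regions$pct_fully_covered[i],
                x$regions$pct_max_below[i], x$bases$pct_covered[i]))
  cat(sprintf("  specificity: %.2f%% (denominator: %s reads)\n",
              x$specificity$pct, x$specificity$denominator))
  invisible(x)
}

#' @export
as.data.frame.sample_metrics <- function(x, ...) {
  row <- data.frame(sample_id = x$sample_id,
                    total = x$reads$total, mapped = x$reads$mapped,
                    duplicate = x$reads$duplicate,
                    remaining = x$reads$remaining,
                    remaining_pct = x$reads$remaining_pct,
                    mean_depth = x$mean_depth)
  for (i in seq_len(nrow(x$regions))) {
    t <- x$regions$threshold[i]
    row[[sprintf("pct_regions_fully_covered_%d", t)]] <-
      x$regions$pct_fully_covered[i]
    row[[sprintf("pct_regions_min_below_%d", t)]] <- x$regions$pct_min_below[i]
    row[[sprintf("pct_regions_max_below_%d", t)]] <- x$regions$pct_max_below[i]
    row[[sprintf("pct_target_bp_covered_%d", t)]] <- x$bases$pct_covered[i]
  }
  row$specificity <- x$specificity$pct
  row
}
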