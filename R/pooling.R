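#' Combine samples into one pool
#'
#' Multiset union of the samples' alignment records; every record is kept
#' and the original `sample_id` column is preserved, so filtering by sample
#' recovers the inputs exactly. Read ids clashing across samples are
#' disambiguated with a sample prefix.
#'
#' @param aln_list list of alignment data.frames (>= 2 samples)
#' @return one alignment data.frame
#' @export
combine_pool <- function(aln_list) {
  if (!is.list(aln_list) || length(aln_list) < 2L)
    qc_stop("a pool needs at least 2 samples")
  for (a in aln_list) validate_alignments(a)
  pool <- do.call(rbind, c(aln_list, list(make.row.names = FALSE)))
  if (anyDuplicated(pool$read_id)) {
    clash <- pool$read_id %in% pool$read_id[duplicated(pool$read_id)]
    pool$read_id[clash] <- paste0(pool$sample_id[clash], ":",
                                  pool$read_id[clash])
    if (anyDuplicated(pool$read_id))
      qc_stop("duplicate read ids within a single sample")
  }
  pool
}

#' Seeded fragment subsampling
#'
#' Draws `n_replicates` random subsets of an alignment collection, each a
#' uniform sample without replacement of `floor(fraction * N)` of the `N`
#' fragments. Mates stay together: the sampling unit is the fragment (read
#' pair), identified by the read id prefix before the mate suffix, combined
#' with the sample id. Replicate seeds are derived from the master `seed`
#' via [derive_seeds], so every replicate is reproducible from
#' `(seed, replicate index)`.
#'
#' @param aln alignment data.frame (typically a [combine_pool] result)
#' @param fraction fraction of fragments to keep, in (0, 1]
#' @param n_replicates number of independent subsets
#' @param seed master seed
#' @return list of `n_replicates` alignment data.frames (input row order
#'   preserved within each)
#' @export
subsample_fragments <- function(aln, fraction, n_replicates = 1, seed = 1) {
  validate_alignments(aln)
  if (!is_prob(fraction) || fraction <= 0)
    qc_stop("'fraction' must be in (0, 1]")
  if (!is_count(n_replicates) || n_replicates < 1)
    qc_stop("'n_replicates' must be a positive integer")
  frag <- paste(aln$sample_id, fragment_ids(aln$read_id))
  keys <- unique(frag)
  m <- floor(fraction * length(keys))
  if (m < 1L) qc_stop("fraction ", fraction, " of ", length(keys),
                      " fragments is less than one fragment")
  seeds <- derive_seeds(seed, n_replicates)
  lapply(seq_len(n_replicates), function(r) {
    chosen <- with_seed(seeds[r], sample(keys, m))
    aln[frag %in% chosen, , drop = FALSE]
  })
}

#' Pooling effect report
#'
#' Compares subset metrics (capture of a combined, unbarcoded pool,
#' informatically emulated by fractional subsampling) against the
#' individual member samples. For each depth threshold the report gives the
#' mean over replicates of the number of completely covered regions and of
#' covered target bases, minus the mean of the same count over members
#' (positive deltas mean the subsets do better), plus the specificity
#' change, with percentages of the design totals to 1 decimal.
#'
#' @param member_metrics list of [sample_report] results, one per pool
#'   member
#' @param subset_metrics list of [sample_report] results, one per replicate
#' @param thresholds depth thresholds; must be present in all metrics
#' @return object of class `pooling_delta`
#' @export
pooling_report <- function(member_metrics, subset_metrics,
                           thresholds = c(1, 5)) {
  thresholds <- validate_thresholds(thresholds)
  all_m <- c(member_metrics, subset_metrics)
  if (!length(member_metrics) || !length(subset_metrics))
    qc_stop("need at least one member and one subset metrics object")
  for (m in all_m) {
    stopifnot(inherits(m, "sample_metrics"))
    if (!all(thresholds %in% m$thresholds))
      qc_stop("metrics were not computed at threshold(s) ",
              paste(setdiff(thresholds, m$thresholds), collapse = ", "))
  }
  tot_bp <- member_metrics[[1L]]$total_bp
  n_reg <- member_metrics[[1L]]$n_regions

  pull <- function(metrics, t, what)
    vapply(metrics, function(m) {
      switch(what,
             regions = m$regions$n_fully_covered[m$regions$threshold == t],
             bp = m$bases$n_covered[m$bases$threshold == t])
    }, numeric(1))
  deltas <- do.call(rbind, lapply(thresholds, function(t) {
    dr <- mean(pull(subset_metrics, t, "regions")) -
      mean(pull(member_metrics, t, "regions"))
    db <- mean(pull(subset_metrics, t, "bp")) -
      mean(pull(member_metrics, t, "bp"))
    data.frame(threshold = t,
               additional_regions = dr,
               additional_regions_pct = round_half_up(100 * dr / n_reg, 1),
               additional_bp = db,
               additional_bp_pct = round_half_up(100 * db / tot_bp, 1))
  }))
  spec_members <- vapply(member_metrics, function(m) m$specificity$pct,
                         numeric(1))
  spec_subsets <- vapply(subset_metrics, function(m) m$specificity$pct,
                         numeric(1))
  structure(list(
    thresholds = thresholds,
    n_members = length(member_metrics),
    n_replicates = length(subset_metrics),
    deltas = deltas,
    specificity_members = mean(spec_members),
    specificity_subsets = mean(spec_subsets),
    specificity_change = mean(spec_subsets) - mean(spec_members),
    replicate_table = do.call(rbind, lapply(subset_metrics, as.data.frame)),
    member_table = do.call(rbind, lapply(member_metrics, as.data.frame)),
    total_bp = tot_bp, n_regions = n_reg),
    class = "pooling_delta")
}

#' @export
print.pooling_delta <- function(x, ...) {
  cat(sprintf("Pooling simulation: %d members vs %d subset replicate(s)\n",
              x$n_members, x$n_replicates))
  for (i in seq_len(nrow(x$deltas)))
    cat(sprintf("  t=%d: %+0.1f regions (%+.1f%%), %+0.1f target bp (%+.1f%%) vs member average\n",
                x$deltas$threshold[i], x$deltas$additional_regions[i],
                x$deltas$additional_regions_pct[i], x$deltas$additional_bp[i],
                x$deltas$additional_bp_pct[i]))
  cat(sprintf("  specificity: %.2f%% -> %.2f%% (%+.2f)\n",
              x$specificity_members, x$specificity_subsets,
              x$specificity_change))
  invisible(x)
}

#' Run the pre-capture pooling simulation
#'
#' End-to-end informatic analog of pre-capture pooling: combine the member
#' samples into one pool, draw seeded fractional subsets (defaults: 25%,
#' ten replicates, emulating four barcoded libraries pooled in one
#' capture), recompute the full per-sample metrics on every member and
#' every subset, and report the deltas.
#'
#' @param aln_list list of member alignment data.frames
#' @param design a [target_design]
#' @param fraction subset fraction (default 0.25)
#' @param n_replicates number of subsets (default 10)
#' @param seed master seed for subsampling
#' @param thresholds depth thresholds
#' @param denominator specificity denominator, see [specificity]
#' @return a [pooling_report] result with the member and subset metrics
#'   attached as attributes `member_metrics` / `subset_metrics`
#' @export
pool_simulation <- function(aln_list, design, fraction = 0.25,
                            n_replicates = 10, seed = 1,
                            thresholds = c(1, 5),
                            denominator = "remaining") {
  pool <- combine_pool(aln_list)
  subsets <- subsample_fragments(pool, fraction, n_replicates, seed)
  member_metrics <- lapply(aln_list, sample_report, design = design,
                           thresholds = thresholds,
                           denominator = denominator)
  subset_metrics <- lapply(seq_along(subsets), function(r) {
    m <- sample_report(subsets[[r]], design, thresholds = thresholds,
                       denominator = denominator)
    m$sample_id <- sprintf("subset%02d", r)
    m
  })
  rep <- pooling_report(member_metrics, subset_metrics, thresholds)
  attr(rep, "member_metrics") <- member_metrics
  attr(rep, "subset_metrics") <- subset_metrics
  rep
}
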