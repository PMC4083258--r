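#' Cross-sample base-level consistency
#'
#' Classifies every target base at depth threshold `t`: *consistent* if its
#' depth is >= `t` in every sample, *never* if it is below `t` in every
#' sample, *variable* otherwise. The three categories partition the target
#' bases exactly.
#'
#' @param profiles list of [compute_depth] results over the same design
#' @param t depth threshold
#' @return list with `n_consistent`, `n_never`, `n_variable`, `total_bp`
#' @export
base_consistency <- function(profiles, t) {
  design <- check_same_design(profiles)
  total_bp <- design$total_bp
  tally <- integer(total_bp)
  for (p in profiles) tally <- tally + (unlist(p$depth) >= t)
  n <- length(profiles)
  out <- list(n_consistent = sum(tally == n), n_never = sum(tally == 0L),
              n_variable = sum(tally > 0L & tally < n), total_bp = total_bp)
  stopifnot(out$n_consistent + out$n_never + out$n_variable == total_bp)
  out
}

#' Cross-sample region-level consistency
#'
#' Each region gets a per-sample predicate, then is classified as with
#' [base_consistency]: *consistent* if the predicate holds in every sample,
#' *never* if it holds in none, *variable* otherwise. The default predicate,
#' `mode = "complete"`, is "completely covered at `t`" (every base of the
#' region has depth >= `t`); `mode = "any"` relaxes it to "any base reaches
#' `t`".
#'
#' @param profiles list of [compute_depth] results over the same design
#' @param t depth threshold
#' @param mode region coverage predicate, `"complete"` or `"any"`
#' @return list with `n_consistent`, `n_never`, `n_variable`, `n_regions`
#' @export
region_consistency <- function(profiles, t, mode = c("complete", "any")) {
  design <- check_same_design(profiles)
  mode <- match.arg(mode)
  pred <- vapply(profiles, function(p) {
    s <- summarize_regions(p, thresholds = t)
    if (mode == "complete") s$min_depth >= t else s$max_depth >= t
  }, logical(design$n_regions))
  pred <- matrix(pred, nrow = design$n_regions)
  hits <- rowSums(pred)
  n <- length(profiles)
  out <- list(n_consistent = sum(hits == n), n_never = sum(hits == 0L),
              n_variable = sum(hits > 0L & hits < n),
              n_regions = design$n_regions)
  stopifnot(out$n_consistent + out$n_never + out$n_variable ==
              design$n_regions)
  out
}

check_same_design <- function(profiles) {
  if (!is.list(profiles) || !length(profiles) ||
      !all(vapply(profiles, inherits, logical(1), "depth_profile")))
    qc_stop("'profiles' must be a list of depth profiles")
  if (length(profiles) < 2L)
    warning("single-sample consistency is degenerate: ",
            "every base/region is either consistent or never covered",
            call. = FALSE)
  design <- profiles[[1L]]$design
  for (p in profiles[-1L])
    if (!identical(p$design$regions, design$regions))
      qc_stop("profiles were computed over different designs")
  design
}

#' Multi-sample reproducibility report
#'
#' Combines [base_consistency] and [region_consistency] into the standard
#' reproducibility summary, with percentages of the design size and region
#' count to 1 decimal (half-up). Can also be assembled directly from
#' published counts via the `counts` argument, to recompute reported
#' percentages.
#'
#' @param profiles list of [compute_depth] results (ignored when `counts`
#'   is given)
#' @param t depth threshold
#' @param mode region predicate, see [region_consistency]
#' @param counts optional list with `bases_consistent`, `bases_never`,
#'   `total_bp`, `regions_consistent`, `regions_never`, `n_regions`; the
#'   variable categories are completed by subtraction
#' @return object of class `consistency_report`
#' @export
consistency_report <- function(profiles = NULL, t = 5, mode = "complete",
                               counts = NULL) {
  if (is.null(counts)) {
    b <- base_consistency(profiles, t)
    r <- region_consistency(profiles, t, mode)
    sample_ids <- vapply(profiles, function(p) p$sample_id, character(1))
    counts <- list(bases_consistent = b$n_consistent,
                   bases_never = b$n_never, total_bp = b$total_bp,
                   regions_consistent = r$n_consistent,
                   regions_never = r$n_never, n_regions = r$n_regions)
  } else {
    need <- c("bases_consistent", "bases_never", "total_bp",
              "regions_consistent", "regions_never", "n_regions")
    if (!all(need %in% names(counts)))
      qc_stop("'counts' needs elements ", paste(need, collapse = ", "))
    sample_ids <- character()
  }
  bv <- counts$total_bp - counts$bases_consistent - counts$bases_never
  rv <- counts$n_regions - counts$regions_consistent - counts$regions_never
  if (bv < 0 || rv < 0) qc_stop("counts exceed totals")
  pct <- function(x, tot) round_half_up(100 * x / tot, 1)
  structure(list(
    threshold = t, mode = mode, sample_ids = sample_ids,
    bases = data.frame(
      category = c("consistent", "never", "variable"),
      n = c(counts$bases_consistent, counts$bases_never, bv),
      pct = pct(c(counts$bases_consistent, counts$bases_never, bv),
                counts$total_bp)),
    regions = data.frame(
      category = c("consistent", "never", "variable"),
      n = c(counts$regions_consistent, counts$regions_never, rv),
      pct = pct(c(counts$regions_consistent, counts$regions_never, rv),
                counts$n_regions)),
    total_bp = counts$total_bp, n_regions = counts$n_regions),
    class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("Reproducibility at minimum coverage %d (%d samples, region mode: %s)\n",
              x$threshold, length(x$sample_ids), x$mode))
  cat(sprintf("  target bases (of %s):\n", format(x$total_bp, big.mark = ",")))
  for (i in 1:3)
    cat(sprintf("    %-10s %s (%.1f%%)\n", x$bases$category[i],
                format(x$bases$n[i], big.mark = ","), x$bases$pct[i]))
  cat(sprintf("  regions (of %s):\n", format(x$n_regions, big.mark = ",")))
  for (i in 1:3)
    cat(sprintf("    %-10s %s (%.1f%%)\n", x$regions$category[i],
                format(x$regions$n[i], big.mark = ","), x$regions$pct[i]))
  invisible(x)
}

#' Regions never sufficiently covered in any sample
#'
#' The region list behind the "never" category of [consistency_report]:
#' regions where no sample satisfies the coverage predicate at `t`.
#'
#' @inheritParams region_consistency
#' @return data.frame of regions (`chrom`, `start`, `end`), BED-ready
#' @export
never_covered_regions <- function(profiles, t, mode = c("complete", "any")) {
  design <- check_same_design(profiles)
  mode <- match.arg(mode)
  pred <- vapply(profiles, function(p) {
    s <- summarize_regions(p, thresholds = t)
    if (mode == "complete") s$min_depth >= t else s$max_depth >= t
  }, logical(design$n_regions))
  pred <- matrix(pred, nrow = design$n_regions)
  design$regions[rowSums(pred) == 0L, , drop = FALSE]
}
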