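#' Fit a qPCR standard curve
#'
#' Least-squares fit of threshold cycle (Ct) against log10 of template
#' quantity over a dilution series. Replicate measurements at the same
#' quantity are averaged to one Ct before fitting. The amplification
#' efficiency is `E = 10^(-1/slope)`: the per-cycle amplification factor,
#' with E = 2 for a perfect assay (slope -3.3219 cycles per tenfold
#' dilution).
#'
#' @param quantity template quantities (e.g. ng), all positive, or a
#'   data.frame with columns `quantity` and `ct`
#' @param ct threshold cycles matching `quantity` (ignored when `quantity`
#'   is a data.frame)
#' @return object of class `standard_curve` with elements `points`
#'   (averaged), `slope`, `intercept`, `r_squared`, `efficiency`
#' @examples
#' q <- rep(c(20, 10, 5, 2.5, 1.25), each = 3)
#' fit_standard_curve(q, 30 - 3.321928 * log10(q))$efficiency  # 2
#' @export
fit_standard_curve <- function(quantity, ct = NULL) {
  if (is.data.frame(quantity)) {
    if (!all(c("quantity", "ct") %in% names(quantity)))
      qc_stop("standard-curve table needs columns 'quantity' and 'ct'")
    ct <- quantity$ct
    quantity <- quantity$quantity
  }
  if (length(quantity) != length(ct))
    qc_stop("'quantity' and 'ct' lengths differ")
  if (any(is.na(quantity)) || any(is.na(ct)) || any(quantity <= 0))
    qc_stop("quantities must be positive and Ct values non-missing")
  pts <- stats::aggregate(list(ct = ct), list(quantity = quantity), mean)
  if (nrow(pts) < 3L)
    qc_stop("need at least 3 distinct quantities, got ", nrow(pts))
  fit <- stats::lm(ct ~ log10(quantity), data = pts)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0)
    qc_stop("non-physical standard curve: slope must be negative ",
            "(Ct falls as template rises); got ", format(slope))
  structure(list(points = pts[order(-pts$quantity), ],
                 slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 # computed directly: summary.lm warns on noise-free curves
                 r_squared = 1 - sum(stats::residuals(fit)^2) /
                   sum((pts$ct - mean(pts$ct))^2),
                 efficiency = 10^(-1 / slope)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve (%d dilutions)\n", nrow(x$points)))
  cat(sprintf("  Ct = %.3f %+.4f * log10(quantity), R^2 = %.4f\n",
              x$intercept, x$slope, x$r_squared))
  cat(sprintf("  amplification efficiency E = %.4f (perfect doubling: 2)\n",
              x$efficiency))
  invisible(x)
}

#' Capture fold enrichment from pre/post-capture Ct values
#'
#' The enrichment of a locus after capture is `E^dCt` with
#' `dCt = Ct_pre - Ct_post`: a locus whose template concentration increased
#' crosses the qPCR threshold earlier after capture, and each cycle gained
#' corresponds to an E-fold concentration increase. A locus passes the
#' quality rule when its fold enrichment reaches `threshold` (default 10).
#'
#' @param curve a [fit_standard_curve] result, or a plain efficiency value
#'   E > 0
#' @param ct_pre,ct_post threshold cycles before / after capture
#'   (vectorised)
#' @param locus optional locus labels
#' @param threshold pass threshold in fold (default 10)
#' @return data.frame with columns `locus`, `ct_pre`, `ct_post`, `delta_ct`,
#'   `fold_enrichment`, `passes_threshold`; the efficiency used is attached
#'   as `attr(, "efficiency")`
#' @export
fold_enrichment <- function(curve, ct_pre, ct_post, locus = NULL,
                            threshold = 10) {
  E <- if (inherits(curve, "standard_curve")) curve$efficiency
  else as.numeric(curve)
  if (!is.finite(E) || E <= 0) qc_stop("efficiency must be positive")
  if (length(ct_pre) != length(ct_post))
    qc_stop("'ct_pre' and 'ct_post' lengths differ")
  if (is.null(locus)) locus <- sprintf("locus%d", seq_along(ct_pre))
  delta <- ct_pre - ct_post
  fold <- E^delta
  out <- data.frame(locus = locus, ct_pre = ct_pre, ct_post = ct_post,
                    delta_ct = delta, fold_enrichment = fold,
                    passes_threshold = fold >= threshold)
  attr(out, "efficiency") <- E
  attr(out, "mean_fold_enrichment") <- mean(fold)
  out
}
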