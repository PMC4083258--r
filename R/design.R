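#' Target designs: merged capture interval sets
#'
#' A capture target design is the set of genomic intervals (exons, mRNAs,
#' miRNAs, ...) an enrichment kit aims to sequence. `target_design()` builds
#' one from one or more annotation interval tracks by taking the base-level
#' union: overlapping *and* bookended (abutting) intervals are merged into a
#' single region, matching the default behaviour of `bedtools merge`.
#'
#' All coordinates follow the BED convention: 0-based, half-open
#' `[start, end)`. Strand is ignored; target space is strandless.
#'
#' @param tracks a data.frame with columns `chrom`, `start`, `end` (extra
#'   columns are ignored), or a list of such data.frames (one per annotation
#'   track).
#' @param chrom_sizes optional named integer vector of chromosome lengths,
#'   used for clipping when padding and for genome-aware simulation.
#' @return an object of class `target_design`: a list with elements
#'   `regions` (sorted, disjoint, non-bookended data.frame of
#'   `chrom`,`start`,`end`), `total_bp`, `n_regions` and `chrom_sizes`.
#' @examples
#' d <- target_design(data.frame(chrom = "chr1",
#'                               start = c(0, 5), end = c(10, 15)))
#' d$total_bp   # 15: the union of [0,10) and [5,15)
#' @export
target_design <- function(tracks, chrom_sizes = NULL) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  if (!is.list(tracks) || !all(vapply(tracks, is.data.frame, logical(1))))
    qc_stop("'tracks' must be a data.frame or a list of data.frames")
  for (i in seq_along(tracks)) validate_intervals(tracks[[i]], track = i)
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)

  all <- do.call(rbind, lapply(tracks, function(t)
    data.frame(chrom = as.character(t$chrom),
               start = as.integer(t$start),
               end   = as.integer(t$end))))
  if (is.null(all) || nrow(all) == 0L) {
    regions <- data.frame(chrom = character(), start = integer(),
                          end = integer())
  } else {
    if (!is.null(chrom_sizes)) {
      bad <- setdiff(unique(all$chrom), names(chrom_sizes))
      if (length(bad))
        qc_stop("interval chromosome(s) absent from chrom_sizes: ",
                paste(bad, collapse = ", "))
      over <- all$end > chrom_sizes[all$chrom]
      if (any(over))
        qc_stop("interval extends past chromosome end: ",
                all$chrom[which(over)[1]], ":", all$start[which(over)[1]],
                "-", all$end[which(over)[1]])
    }
    regions <- merge_intervals(all)
  }
  structure(list(regions    = regions,
                 total_bp   = sum(regions$end - regions$start),
                 n_regions  = nrow(regions),
                 chrom_sizes = chrom_sizes),
            class = "target_design")
}

# base-level union per chromosome; IRanges::reduce with its default
# min.gapwidth = 1 merges overlapping and abutting intervals (bedtools
# `merge` distance-0 semantics). 1-based closed internally, BED outside.
merge_intervals <- function(df) {
  out <- lapply(split(df, df$chrom), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    data.frame(chrom = d$chrom[1L],
               start = IRanges::start(r) - 1L,
               end   = IRanges::end(r))
  })
  out <- do.call(rbind, out[order(names(out))])
  rownames(out) <- NULL
  out
}

validate_intervals <- function(df, track = NULL) {
  where <- if (is.null(track)) "" else paste0(" (track ", track, ")")
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    qc_stop("interval table", where, " must have columns chrom, start, end")
  if (nrow(df) == 0L) return(invisible(df))
  if (!is.numeric(df$start) || !is.numeric(df$end))
    qc_stop("interval coordinates", where, " must be numeric")
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 0 |
                 df$end <= df$start)
  if (length(bad))
    qc_stop("malformed interval", where, " at row ", bad[1L], ": ",
            df$chrom[bad[1L]], ":", df$start[bad[1L]], "-", df$end[bad[1L]],
            " (need 0 <= start < end)")
  invisible(df)
}

validate_chrom_sizes <- function(chrom_sizes) {
  if (is.null(chrom_sizes)) return(NULL)
  if (is.null(names(chrom_sizes)) || any(names(chrom_sizes) == "") ||
      anyDuplicated(names(chrom_sizes)))
    qc_stop("'chrom_sizes' must be a uniquely named vector of lengths")
  if (!is.numeric(chrom_sizes) || any(is.na(chrom_sizes)) ||
      any(chrom_sizes < 1))
    qc_stop("'chrom_sizes' must be positive lengths")
  stats::setNames(as.integer(chrom_sizes), names(chrom_sizes))
}

#' Pad short target regions to a minimum length
#'
#' Capture chemistry performs poorly on very short regions, so designs pad
#' them: every region shorter than `min_len` is grown to `min_len`. Padding
#' is centered — the deficit is split equally between the two sides, with an
#' odd leftover base going to the end (right) side. Padded windows that
#' stick out past position 0 or the chromosome end (when `chrom_sizes` is
#' known) are shifted back inside before clipping, so every region reaches
#' `min(min_len, chromosome length)`; the result is re-merged so the design
#' invariants (sorted, disjoint, non-bookended) still hold. Regions already
#' at least `min_len` long are untouched.
#'
#' @param design a [target_design]
#' @param min_len minimum region length in bp (default 100)
#' @return a new `target_design`
#' @export
pad_short_regions <- function(design, min_len = 100) {
  stopifnot(inherits(design, "target_design"))
  if (!is_count(min_len) || min_len < 1)
    qc_stop("'min_len' must be a positive integer")
  r <- design$regions
  if (nrow(r) == 0L) return(design)
  len <- r$end - r$start
  deficit <- pmax(0L, as.integer(min_len) - len)
  left  <- deficit %/% 2L
  right <- deficit - left                 # odd base goes right
  start <- r$start - left
  end   <- r$end + right
  # shift the padded window inside the chromosome before clipping, so
  # regions keep length min(min_len, chrom length) even at the ends
  shift <- pmax(0L, -start)
  start <- start + shift; end <- end + shift
  if (!is.null(design$chrom_sizes)) {
    shift <- pmax(0L, end - design$chrom_sizes[r$chrom])
    start <- start - shift; end <- end - shift
    end <- pmin(end, design$chrom_sizes[r$chrom])
  }
  start <- pmax(0L, start)
  target_design(data.frame(chrom = r$chrom, start = start, end = end),
                chrom_sizes = design$chrom_sizes)
}

#' Design summary statistics
#'
#' @param design a [target_design]
#' @return list with `total_bp`, `n_regions` and `per_chrom`, a data.frame
#'   with one row per chromosome (`chrom`, `n_regions`, `total_bp`).
#' @export
design_stats <- function(design) {
  stopifnot(inherits(design, "target_design"))
  r <- design$regions
  if (nrow(r) == 0L) {
    per <- data.frame(chrom = character(), n_regions = integer(),
                      total_bp = integer())
  } else {
    len <- r$end - r$start
    per <- do.call(rbind, lapply(split(len, r$chrom), function(l)
      data.frame(n_regions = length(l), total_bp = sum(l))))
    per <- data.frame(chrom = rownames(per), per, row.names = NULL)
  }
  list(total_bp = design$total_bp, n_regions = design$n_regions,
       per_chrom = per)
}

#' @export
print.target_design <- function(x, ...) {
  cat("Target design:", x$n_regions, "regions,",
      format(x$total_bp, big.mark = ","), "bp")
  if (!is.null(x$chrom_sizes))
    cat(sprintf(" (%.2f%% of %s bp genome)",
                100 * x$total_bp / sum(x$chrom_sizes),
                format(sum(x$chrom_sizes), big.mark = ",")))
  cat("\n")
  if (x$n_regions > 0L) {
    s <- design_stats(x)$per_chrom
    for (i in seq_len(nrow(s)))
      cat(sprintf("  %s: %d regions, %s bp\n", s$chrom[i], s$n_regions[i],
                  format(s$total_bp[i], big.mark = ",")))
  }
  invisible(x)
}

#' @export
as.data.frame.target_design <- function(x, ...) x$regions
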