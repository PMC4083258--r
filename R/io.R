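#' Read a BED3+ file
#'
#' Parses a BED file in the 0-based half-open convention. `track`, `browser`
#' and `#` comment lines are skipped; columns beyond the third are kept
#' verbatim as character payload columns (`V4`, `V5`, ...). Malformed
#' records are rejected with their line number.
#'
#' @param path BED file
#' @return data.frame with `chrom`, `start`, `end` and any extra columns
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) qc_stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  if (!length(lineno))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncol <- vapply(parts, length, integer(1))
  if (any(ncol < 3L))
    qc_stop(path, " line ", lineno[which(ncol < 3L)[1L]],
            ": fewer than 3 tab-separated fields")
  start <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    qc_stop(path, " line ", lineno[bad[1L]], ": non-numeric coordinates")
  bad <- which(start < 0 | end <= start | start != floor(start) |
                 end != floor(end))
  if (length(bad))
    qc_stop(path, " line ", lineno[bad[1L]], ": invalid interval [",
            start[bad[1L]], ", ", end[bad[1L]], ")")
  out <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                    start = as.integer(start), end = as.integer(end))
  if (max(ncol) >= 4L)
    for (j in 4L:max(ncol))
      out[[paste0("V", j)]] <- vapply(parts, function(p)
        if (length(p) >= j) p[j] else NA_character_, "")
  out
}

#' Write intervals as BED3
#'
#' @param x a [target_design] or a data.frame with `chrom`,`start`,`end`
#' @param path output file
#' @export
write_bed <- function(x, path) {
  df <- if (inherits(x, "target_design")) x$regions else x
  validate_intervals(df)
  utils::write.table(df[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column chrom.sizes file
#'
#' @param path tab-separated file: chromosome name, length
#' @return named integer vector
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "integer"))
  validate_chrom_sizes(stats::setNames(df$size, df$chrom))
}

aln_tsv_cols <- c("read_id", "sample_id", "chrom", "start", "end",
                  "is_mapped", "is_duplicate")

#' Read alignments from SAM/BAM or the plain 7-column table
#'
#' The plain table is tab-separated with a header row and columns
#' `read_id`, `sample_id`, `chrom`, `start`, `end` (0-based half-open),
#' `is_mapped`, `is_duplicate`. SAM/BAM files are read through Rsamtools:
#' the mapped flag comes from FLAG bit 0x4, the duplicate flag from 0x400,
#' and secondary (0x100) / supplementary (0x800) alignments are dropped.
#' Reference spans of BAM/SAM records are the reference-consuming extent of
#' the CIGAR string.
#'
#' @param path input file
#' @param format `"auto"` (by extension), `"sam"`, `"bam"` or `"tsv"`
#' @param sample_id sample label for SAM/BAM input (defaults to the file
#'   name without extension); the TSV carries its own
#' @return alignment data.frame (see [simulate_reads])
#' @export
read_alignments <- function(path, format = c("auto", "sam", "bam", "tsv"),
                            sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) qc_stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext, sam = "sam", bam = "bam", "tsv")
  }
  if (format == "tsv") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, na.strings = c("NA", "."))
    if (!all(aln_tsv_cols %in% names(df)))
      qc_stop(path, ": alignment table must have columns ",
              paste(aln_tsv_cols, collapse = ", "))
    df <- df[, aln_tsv_cols]
    df$is_mapped <- as.logical(df$is_mapped)
    df$is_duplicate <- as.logical(df$is_duplicate)
    validate_alignments(df)
    return(df)
  }
  if (is.null(sample_id))
    sample_id <- sub("\\.(sam|bam)$", "", basename(path), ignore.case = TRUE)
  bam <- if (format == "sam") {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  } else path
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(flag = flags,
                               what = c("qname", "flag", "rname", "pos",
                                        "cigar"))
  b <- Rsamtools::scanBam(bam, param = p)[[1L]]
  mapped <- !bitwAnd(b$flag, 4L)
  dup <- bitwAnd(b$flag, 1024L) > 0L
  width <- rep(NA_integer_, length(b$qname))
  width[mapped] <- GenomicAlignments::cigarWidthAlongReferenceSpace(
    b$cigar[mapped])
  df <- data.frame(read_id = b$qname,
                   sample_id = sample_id,
                   chrom = ifelse(mapped, as.character(b$rname), NA),
                   start = ifelse(mapped, b$pos - 1L, NA),
                   end = ifelse(mapped, b$pos - 1L + width, NA),
                   is_mapped = mapped,
                   is_duplicate = dup & mapped,
                   stringsAsFactors = FALSE)
  validate_alignments(df)
  df
}

#' Write alignments as the plain 7-column table
#'
#' @param aln alignment data.frame
#' @param path output file
#' @export
write_alignments_tsv <- function(aln, path) {
  validate_alignments(aln)
  utils::write.table(aln[, aln_tsv_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write alignments as SAM
#'
#' Minimal SAM emission for the simulator's records: `@SQ` headers from
#' `chrom_sizes`, 1-based POS, an ungapped `<len>M` CIGAR, `*` sequence and
#' qualities. FLAG carries paired/mate bits (0x1, 0x40/0x80), 0x4 for
#' unmapped and 0x400 for duplicates. Mate suffixes (`/1`, `/2`) are
#' stripped from QNAME per SAM convention.
#'
#' @param aln alignment data.frame
#' @param path output file
#' @param chrom_sizes named vector of chromosome lengths for `@SQ` lines
#' @export
write_sam <- function(aln, path, chrom_sizes) {
  validate_alignments(aln)
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  if (is.null(chrom_sizes)) qc_stop("'chrom_sizes' is required for @SQ lines")
  used <- unique(aln$chrom[aln$is_mapped])
  if (!all(used %in% names(chrom_sizes)))
    qc_stop("chrom_sizes is missing: ",
            paste(setdiff(used, names(chrom_sizes)), collapse = ", "))
  mate <- ifelse(grepl("/2$", aln$read_id), 2L, 1L)
  flag <- 1L + ifelse(mate == 2L, 128L, 64L) +
    ifelse(aln$is_mapped, 0L, 4L) + ifelse(aln$is_duplicate, 1024L, 0L)
  lines <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes), chrom_sizes),
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
            fragment_ids(aln$read_id), flag,
            ifelse(aln$is_mapped, aln$chrom, "*"),
            ifelse(aln$is_mapped, aln$start + 1L, 0L),
            ifelse(aln$is_mapped, 60L, 0L),
            ifelse(aln$is_mapped,
                   sprintf("%dM", aln$end - aln$start), "*")))
  writeLines(lines, path)
  invisible(path)
}

#' Write a depth profile as BedGraph
#'
#' Emits one `chrom start end depth` row per run of constant depth within
#' each design region (0-based half-open, zero-depth runs included so the
#' profile round-trips).
#'
#' @param profile a [compute_depth] result
#' @param path output file
#' @export
write_bedgraph <- function(profile, path) {
  stopifnot(inherits(profile, "depth_profile"))
  r <- profile$design$regions
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", profile$sample_id),
             con)
  for (i in seq_len(nrow(r))) {
    v <- profile$depth[[i]]
    if (!length(v)) next
    rl <- rle(v)
    end <- r$start[i] + cumsum(rl$lengths)
    start <- end - rl$lengths
    writeLines(sprintf("%s\t%d\t%d\t%d", r$chrom[i], start, end, rl$values),
               con)
  }
  invisible(path)
}

#' Read a BedGraph back into a depth profile
#'
#' Reconstructs per-target-base depth over `design` from a BedGraph track;
#' design bases not covered by any BedGraph row get depth 0.
#'
#' @param path BedGraph file
#' @param design the [target_design] the profile is over
#' @param sample_id profile label (defaults to the file name)
#' @return a `depth_profile`
#' @export
read_bedgraph <- function(path, design, sample_id = NULL) {
  stopifnot(inherits(design, "target_design"))
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  df <- read_bed(path)          # same skip/validation rules
  depth_col <- if ("V4" %in% names(df)) as.numeric(df$V4) else
    qc_stop(path, ": BedGraph needs a 4th (depth) column")
  r <- design$regions
  depth <- vector("list", nrow(r))
  for (cn in unique(r$chrom)) {
    ri <- which(r$chrom == cn)
    g <- df[df$chrom == cn, , drop = FALSE]
    width <- max(r$end[ri], if (nrow(g)) max(g$end) else 0L)
    cov <- integer(width)
    gi <- which(df$chrom == cn)
    for (k in gi)
      cov[(df$start[k] + 1L):df$end[k]] <-
        cov[(df$start[k] + 1L):df$end[k]] + as.integer(depth_col[k])
    depth[ri] <- lapply(ri, function(i) cov[(r$start[i] + 1L):r$end[i]])
  }
  structure(list(sample_id = sample_id, design = design, depth = depth,
                 n_skipped = 0L),
            class = "depth_profile")
}

#' Read a qPCR standard-curve table
#'
#' Comma- or tab-separated with a header; needs columns `quantity` (or
#' `quantity_ng`) and `ct`, optionally `locus`.
#'
#' @param path input file
#' @return data.frame with `quantity`, `ct` (and `locus` if present)
#' @export
read_qpcr_standard <- function(path) {
  df <- read_delim_auto(path)
  if ("quantity_ng" %in% names(df) && !"quantity" %in% names(df))
    df$quantity <- df$quantity_ng
  if (!all(c("quantity", "ct") %in% names(df)))
    qc_stop(path, ": needs columns 'quantity' (or 'quantity_ng') and 'ct'")
  df
}

#' Read a pre/post-capture Ct table
#'
#' Long format: columns `locus`, `stage` (`pre` or `post`) and `ct`;
#' replicate rows per (locus, stage) are averaged. Returns one row per
#' locus with `ct_pre` and `ct_post`.
#'
#' @param path input file
#' @return data.frame with `locus`, `ct_pre`, `ct_post`
#' @export
read_qpcr_ct <- function(path) {
  df <- read_delim_auto(path)
  if (!all(c("locus", "stage", "ct") %in% names(df)))
    qc_stop(path, ": needs columns 'locus', 'stage', 'ct'")
  if (!all(df$stage %in% c("pre", "post")))
    qc_stop(path, ": 'stage' must be 'pre' or 'post'")
  agg <- stats::aggregate(list(ct = df$ct),
                          list(locus = df$locus, stage = df$stage), mean)
  wide <- stats::reshape(agg, direction = "wide", idvar = "locus",
                         timevar = "stage")
  names(wide) <- sub("^ct\\.", "ct_", names(wide))
  if (!all(c("ct_pre", "ct_post") %in% names(wide)))
    qc_stop(path, ": every locus needs both a 'pre' and a 'post' Ct")
  wide[order(wide$locus), c("locus", "ct_pre", "ct_post")]
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) qc_stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
}
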