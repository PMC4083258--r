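#' Simulation configuration
#'
#' Describes the synthetic capture experiment: a toy genome, a target design
#' occupying a small fraction of it, and per-sample paired reads with a
#' controlled on-target fraction, duplicate rate, mapping rate and
#' region dropout. The defaults emulate the regime of a well-performing
#' exome capture: a design covering ~2% of the genome split into many short
#' regions, ~90% of reads on target, 5–10% duplicates, ~94% of reads mapped,
#' a few percent of regions never captured, and a per-sample mean target
#' depth on the order of 100x.
#'
#' @param chrom_sizes named vector of chromosome lengths (bp)
#' @param n_target_regions number of target regions to place
#' @param target_region_length_range length-2 vector, min/max region length
#' @param n_samples number of barcoded samples
#' @param reads_per_sample total reads per sample; reads are paired, so the
#'   number of fragments per sample is `reads_per_sample / 2`
#' @param read_length read length in bp
#' @param fragment_length_mean,fragment_length_sd fragment (insert) length
#'   distribution in bp (normal, rounded, floored at `read_length`)
#' @param on_target_fraction probability that a fragment is captured
#'   on target
#' @param duplicate_rate probability that a mapped fragment is a duplicate
#'   copy of another fragment from the same sample
#' @param dropout_region_fraction fraction of target regions that receive no
#'   on-target fragments in any sample (capture dropout)
#' @param unmapped_rate probability that a fragment fails to map
#' @param seed master seed; all per-sample and per-stage streams are derived
#'   from it (see [derive_seeds])
#' @return object of class `sim_config`
#' @export
sim_config <- function(chrom_sizes = c(chr1 = 1200000L, chr2 = 800000L),
                       n_target_regions = 200,
                       target_region_length_range = c(100, 300),
                       n_samples = 4,
                       reads_per_sample = 60000,
                       read_length = 100,
                       fragment_length_mean = 300,
                       fragment_length_sd = 50,
                       on_target_fraction = 0.9,
                       duplicate_rate = 0.07,
                       dropout_region_fraction = 0.025,
                       unmapped_rate = 0.06,
                       seed = 1) {
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  if (is.null(chrom_sizes)) qc_stop("'chrom_sizes' is required")
  cfg <- list(chrom_sizes = chrom_sizes,
              n_target_regions = as.integer(n_target_regions),
              target_region_length_range =
                as.integer(target_region_length_range),
              n_samples = as.integer(n_samples),
              reads_per_sample = as.integer(reads_per_sample),
              read_length = as.integer(read_length),
              fragment_length_mean = fragment_length_mean,
              fragment_length_sd = fragment_length_sd,
              on_target_fraction = on_target_fraction,
              duplicate_rate = duplicate_rate,
              dropout_region_fraction = dropout_region_fraction,
              unmapped_rate = unmapped_rate,
              seed = as.integer(seed))
  for (p in c("on_target_fraction", "duplicate_rate",
              "dropout_region_fraction", "unmapped_rate"))
    if (!is_prob(cfg[[p]])) qc_stop("'", p, "' must be a probability in [0,1]")
  for (p in c("n_samples", "reads_per_sample", "read_length"))
    if (!is_count(cfg[[p]]) || cfg[[p]] < 1)
      qc_stop("'", p, "' must be a positive integer")
  if (!is_count(cfg$n_target_regions))
    qc_stop("'n_target_regions' must be a non-negative integer")
  rng <- cfg$target_region_length_range
  if (length(rng) != 2L || any(rng < 1) || rng[2] < rng[1])
    qc_stop("'target_region_length_range' must be (min, max) with 1 <= min <= max")
  if (cfg$reads_per_sample %% 2L != 0L)
    qc_stop("'reads_per_sample' must be even (reads are paired)")
  if (cfg$fragment_length_mean < cfg$read_length)
    qc_stop("'fragment_length_mean' must be >= read_length")
  if (cfg$fragment_length_sd < 0) qc_stop("'fragment_length_sd' must be >= 0")
  if (cfg$n_target_regions * rng[2] > sum(chrom_sizes))
    qc_stop("total target length exceeds genome length")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Capture simulation config:\n")
  cat(sprintf("  genome: %s bp over %d chromosome(s)\n",
              format(sum(x$chrom_sizes), big.mark = ","),
              length(x$chrom_sizes)))
  cat(sprintf("  design: %d regions of %d-%d bp\n", x$n_target_regions,
              x$target_region_length_range[1], x$target_region_length_range[2]))
  cat(sprintf("  %d sample(s) x %s paired reads of %d bp\n", x$n_samples,
              format(x$reads_per_sample, big.mark = ","), x$read_length))
  cat(sprintf("  on-target %.2f, duplicates %.2f, unmapped %.2f, dropout %.3f, seed %d\n",
              x$on_target_fraction, x$duplicate_rate, x$unmapped_rate,
              x$dropout_region_fraction, x$seed))
  invisible(x)
}

#' Simulate a target design
#'
#' Places `n_target_regions` non-overlapping regions on the toy genome.
#' Region lengths are uniform over `target_region_length_range`; regions are
#' assigned to chromosomes with probability proportional to chromosome
#' length and placed uniformly at random with at least 1 bp between
#' neighbours, so the merged design keeps exactly `n_target_regions`
#' regions. Deterministic given `config$seed`.
#'
#' @param config a [sim_config]
#' @return a [target_design] carrying the config's `chrom_sizes`
#' @export
simulate_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed, 2L + config$n_samples)
  with_seed(seeds[1L], simulate_design_impl(config))
}

simulate_design_impl <- function(config) {
  n <- config$n_target_regions
  if (n == 0L)
    return(target_design(list(), chrom_sizes = config$chrom_sizes))
  sizes <- config$chrom_sizes
  rng <- config$target_region_length_range
  chrom <- sample(names(sizes), n, replace = TRUE,
                  prob = sizes / sum(sizes))
  lens <- sample(seq.int(rng[1], rng[2]), n, replace = TRUE)
  parts <- lapply(split(lens, chrom), sort)        # placement per chromosome
  rows <- lapply(names(parts), function(cn) {
    l <- sample(parts[[cn]])                        # shuffle lengths again
    k <- length(l)
    free <- sizes[[cn]] - sum(l) - (k - 1L)
    if (free < 0L)
      qc_stop("infeasible packing: ", k, " regions totalling ", sum(l),
              " bp (+gaps) do not fit on ", cn, " (", sizes[[cn]], " bp)")
    # stars-and-bars: sorted slack offsets + mandatory 1 bp inter-region gap
    u <- sort(sample.int(free + 1L, k, replace = TRUE) - 1L)
    start <- u + cumsum(c(0L, l[-k] + 1L))
    data.frame(chrom = cn, start = start, end = start + l)
  })
  target_design(do.call(rbind, rows), chrom_sizes = sizes)
}

#' Simulate aligned paired reads for a capture experiment
#'
#' For each sample, fragments are generated independently. A fragment is
#' unmapped with probability `unmapped_rate`; a mapped fragment is a
#' duplicate copy of a random earlier fragment from the same sample with
#' probability `duplicate_rate` (its two reads are flagged as duplicates);
#' otherwise it is a fresh fragment that is on-target with probability
#' `on_target_fraction`. On-target fragments draw their midpoint uniformly
#' over the bases of non-dropout target regions and are re-drawn (midpoint
#' and fragment length together) until both mate reads overlap the design,
#' so the on-target state of a retained
#' (mapped, non-duplicate) read is exactly Bernoulli(`on_target_fraction`)
#' at the fragment level. Off-target fragments are uniform over the genome
#' conditioned on neither read touching the design. A fixed fraction of
#' regions (`dropout_region_fraction`, drawn once per run from the master
#' seed) receives no on-target fragments in any sample.
#'
#' Each fragment yields two reads covering its first and last `read_length`
#' bases; read ids are `<sample>.f<i>/1` and `/2`, so mates share the id
#' prefix. Everything is deterministic given `config$seed`.
#'
#' @param design a [target_design], typically from [simulate_design]
#' @param config a [sim_config]
#' @return named list (one element per sample) of alignment data.frames with
#'   columns `read_id`, `sample_id`, `chrom`, `start`, `end`, `is_mapped`,
#'   `is_duplicate`. The dropout region indices are attached as
#'   `attr(, "dropout_regions")`.
#' @export
simulate_reads <- function(design, config) {
  stopifnot(inherits(design, "target_design"), inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed, 2L + config$n_samples)
  n_regions <- design$n_regions
  n_drop <- as.integer(round(config$dropout_region_fraction * n_regions))
  dropout <- if (n_drop > 0L)
    with_seed(seeds[2L], sort(sample.int(n_regions, n_drop))) else integer()
  out <- lapply(seq_len(config$n_samples), function(s) {
    sid <- sprintf("S%d", s)
    with_seed(seeds[2L + s],
              simulate_sample_reads(design, config, sid, dropout))
  })
  names(out) <- sprintf("S%d", seq_len(config$n_samples))
  attr(out, "dropout_regions") <- dropout
  out
}

simulate_sample_reads <- function(design, config, sample_id, dropout) {
  n_frag <- config$reads_per_sample %/% 2L
  rl <- config$read_length
  sizes <- config$chrom_sizes
  keep <- setdiff(seq_len(design$n_regions), dropout)
  r <- design$regions[keep, , drop = FALSE]
  if (nrow(r) == 0L && config$on_target_fraction > 0)
    qc_stop("no non-dropout target regions to place on-target fragments in")
  design_ir <- lapply(split(design$regions, design$regions$chrom), function(d)
    IRanges::IRanges(start = d$start + 1L, end = d$end))

  status <- runif(n_frag)
  unmapped <- status < config$unmapped_rate
  dup <- !unmapped & (runif(n_frag) < config$duplicate_rate)
  fresh <- which(!unmapped & !dup)
  on <- logical(n_frag)
  on[fresh] <- runif(length(fresh)) < config$on_target_fraction

  frag_len <- pmax(rl, as.integer(round(stats::rnorm(
    n_frag, config$fragment_length_mean, config$fragment_length_sd))))
  chrom <- rep(NA_character_, n_frag)
  fstart <- rep(NA_integer_, n_frag)

  place_on <- function(idx) {
    # fragment midpoint uniform over non-dropout target bases, re-drawn
    # until both mate reads overlap the design and the fragment is inside
    # its chromosome
    act <- idx
    for (iter in 1:1000) {
      if (!length(act)) return(invisible())
      if (iter > 1L)  # extreme fragment lengths can be unplaceable; redraw
        frag_len[act] <<- pmax(rl, as.integer(round(stats::rnorm(
          length(act), config$fragment_length_mean,
          config$fragment_length_sd))))
      w <- r$end - r$start
      reg <- sample.int(nrow(r), length(act), replace = TRUE,
                        prob = w / sum(w))
      mid <- r$start[reg] + floor(runif(length(act)) * w[reg])
      fs <- mid - frag_len[act] %/% 2L
      fe <- fs + frag_len[act]
      cn <- r$chrom[reg]
      ok <- fs >= 0L & fe <= sizes[cn] &
        reads_touch_design(cn, fs, fe, rl, design_ir, both = TRUE)
      chrom[act[ok]] <<- cn[ok]
      fstart[act[ok]] <<- fs[ok]
      act <- act[!ok]
    }
    qc_stop("on-target placement failed to converge; regions may be far ",
            "shorter than the read length")
  }
  place_off <- function(idx) {
    act <- idx
    for (iter in 1:1000) {
      if (!length(act)) return(invisible())
      cn <- sample(names(sizes), length(act), replace = TRUE,
                   prob = sizes / sum(sizes))
      room <- sizes[cn] - frag_len[act]
      ok0 <- room >= 0L
      fs <- ifelse(ok0, floor(runif(length(act)) * (room + 1L)), NA_integer_)
      fe <- fs + frag_len[act]
      ok <- ok0 & !reads_touch_design(cn, fs, fe, rl, design_ir, both = FALSE)
      chrom[act[ok]] <<- cn[ok]
      fstart[act[ok]] <<- as.integer(fs[ok])
      act <- act[!ok]
    }
    qc_stop("off-target placement failed to converge; the design may cover ",
            "nearly the whole genome")
  }
  place_on(fresh[on[fresh]])
  place_off(fresh[!on[fresh]])

  dup_idx <- which(dup)
  if (length(dup_idx)) {
    if (!length(fresh)) {           # degenerate: nothing to copy
      on[dup_idx[1L]] <- runif(1) < config$on_target_fraction
      dup[dup_idx[1L]] <- FALSE
      if (on[dup_idx[1L]]) place_on(dup_idx[1L]) else place_off(dup_idx[1L])
      fresh <- dup_idx[1L]
      dup_idx <- dup_idx[-1L]
    }
    src <- fresh[sample.int(length(fresh), length(dup_idx), replace = TRUE)]
    chrom[dup_idx] <- chrom[src]
    fstart[dup_idx] <- fstart[src]
    frag_len[dup_idx] <- frag_len[src]
  }

  fend <- fstart + frag_len
  mapped <- !unmapped
  idx <- rep(seq_len(n_frag), each = 2L)
  mate <- rep(1:2, n_frag)
  data.frame(
    read_id = sprintf("%s.f%06d/%d", sample_id, idx, mate),
    sample_id = sample_id,
    chrom = ifelse(mapped[idx], chrom[idx], NA_character_),
    start = ifelse(mapped[idx],
                   ifelse(mate == 1L, fstart[idx], fend[idx] - rl),
                   NA_integer_),
    end = ifelse(mapped[idx],
                 ifelse(mate == 1L, fstart[idx] + rl, fend[idx]),
                 NA_integer_),
    is_mapped = mapped[idx],
    is_duplicate = dup[idx],
    stringsAsFactors = FALSE)
}

# do reads [fs,fs+rl) and [fe-rl,fe) overlap the design?  both=TRUE demands
# both mates, both=FALSE flags any touch
reads_touch_design <- function(cn, fs, fe, rl, design_ir, both) {
  res <- if (both) rep(FALSE, length(cn)) else rep(FALSE, length(cn))
  for (c1 in unique(cn)) {
    i <- which(cn == c1 & !is.na(fs))
    if (!length(i)) next
    ir <- design_ir[[c1]]
    if (is.null(ir)) next
    h1 <- IRanges::overlapsAny(
      IRanges::IRanges(start = fs[i] + 1L, end = fs[i] + rl), ir)
    h2 <- IRanges::overlapsAny(
      IRanges::IRanges(start = fe[i] - rl + 1L, end = fe[i]), ir)
    res[i] <- if (both) h1 & h2 else h1 | h2
  }
  res
}

#' Mark duplicate fragments by coordinates
#'
#' Coordinate-based duplicate marking for plain alignment tables that carry
#' no duplicate flags: all reads of fragments sharing
#' (sample, chromosome, fragment start, fragment end) beyond the first
#' occurrence are flagged as duplicates. The fragment span is the hull of
#' its mates' spans; mates are identified by the read id prefix before the
#' `/1` / `/2` suffix. Unmapped reads are never flagged.
#'
#' @param aln alignment data.frame (see [simulate_reads] for columns)
#' @return `aln` with `is_duplicate` recomputed
#' @export
mark_duplicates <- function(aln) {
  validate_alignments(aln)
  aln$is_duplicate <- FALSE
  m <- which(aln$is_mapped)
  if (!length(m)) return(aln)
  fid <- fragment_ids(aln$read_id[m])
  key <- paste(aln$sample_id[m], fid)
  fstart <- stats::ave(aln$start[m], key, FUN = min)
  fend <- stats::ave(aln$end[m], key, FUN = max)
  fkey <- paste(aln$sample_id[m], aln$chrom[m], fstart, fend)
  first_frag <- !duplicated(key)
  dup_frags <- unique(key[first_frag][duplicated(fkey[first_frag])])
  aln$is_duplicate[m] <- key %in% dup_frags
  aln
}

fragment_ids <- function(read_id) sub("/[12]$", "", read_id)

validate_alignments <- function(aln) {
  need <- c("read_id", "sample_id", "chrom", "start", "end", "is_mapped",
            "is_duplicate")
  if (!is.data.frame(aln) || !all(need %in% names(aln)))
    qc_stop("alignments must be a data.frame with columns ",
            paste(need, collapse = ", "))
  m <- aln$is_mapped
  bad <- which(m & (is.na(aln$start) | is.na(aln$end) | is.na(aln$chrom) |
                      aln$end <= aln$start | aln$start < 0))
  if (length(bad))
    qc_stop("mapped alignment with invalid span at row ", bad[1L])
  if (any(aln$is_duplicate & !m))
    qc_stop("unmapped reads cannot be duplicates")
  invisible(aln)
}

#' Simulate a full capture experiment
#'
#' Convenience wrapper: [simulate_design] then [simulate_reads].
#'
#' @param config a [sim_config]
#' @return list with `design`, `alignments` (per-sample list) and `config`
#' @export
simulate_experiment <- function(config = sim_config()) {
  design <- simulate_design(config)
  list(design = design,
       alignments = simulate_reads(design, config),
       config = config)
}
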