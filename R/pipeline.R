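#' Run the full capture QC pipeline
#'
#' Umbrella driver: per-sample depth profiles and performance metrics,
#' multi-sample reproducibility at each threshold (overall and within
#' optional sample groups/pools), and — when `pooling` is given — the
#' pre-capture pooling simulation. With `out_dir` set, writes the report
#' bundle to disk: a per-sample metrics TSV, a JSON report (including
#' per-chromosome specificity), per-threshold consistency TSV/JSON, the
#' never-sufficiently-covered region BED, and the pooling summary.
#' Emitted percentages are re-validated (range and partition identities)
#' at write time.
#'
#' @param design a [target_design], or a path to a BED file
#' @param alignments named list of alignment data.frames, or a character
#'   vector of file paths (names become sample ids)
#' @param thresholds depth thresholds (default `c(1, 5)`)
#' @param groups optional named list of sample-id vectors defining pools
#'   for within-pool consistency reports
#' @param pooling optional list with elements `fraction`, `n_replicates`
#'   to run [pool_simulation] over all samples
#' @param denominator specificity denominator, see [specificity]
#' @param out_dir optional output directory
#' @param seed master seed (pooling subsampling)
#' @return object of class `capqc_report`: list with `metrics` (per-sample
#'   [sample_report]s), `metrics_table`, `consistency` (per threshold),
#'   `pooling`, `parameters`
#' @export
capture_pipeline <- function(design, alignments, thresholds = c(1, 5),
                             groups = NULL, pooling = NULL,
                             denominator = "remaining", out_dir = NULL,
                             seed = 1) {
  if (is.character(design)) design <- target_design(read_bed(design))
  stopifnot(inherits(design, "target_design"))
  if (is.character(alignments)) {
    paths <- alignments
    alignments <- lapply(paths, read_alignments)
    names(alignments) <- if (!is.null(names(paths))) names(paths) else
      vapply(alignments, function(a) a$sample_id[1L], "")
  }
  if (is.null(names(alignments)) || anyDuplicated(names(alignments)))
    qc_stop("'alignments' must be a uniquely named list of samples")
  thresholds <- validate_thresholds(thresholds)

  profiles <- lapply(names(alignments), function(s)
    compute_depth(alignments[[s]], design, sample_id = s))
  names(profiles) <- names(alignments)
  metrics <- lapply(names(alignments), function(s)
    sample_report(alignments[[s]], design, thresholds = thresholds,
                  denominator = denominator, profile = profiles[[s]]))
  names(metrics) <- names(alignments)
  metrics_table <- do.call(rbind, lapply(metrics, as.data.frame))
  rownames(metrics_table) <- NULL

  consistency <- list()
  if (length(alignments) >= 2L) {
    for (t in thresholds) {
      cons <- list(all = consistency_report(profiles, t = t))
      for (g in names(groups)) {
        ids <- groups[[g]]
        if (!all(ids %in% names(profiles)))
          qc_stop("group '", g, "' names unknown sample(s): ",
                  paste(setdiff(ids, names(profiles)), collapse = ", "))
        if (length(ids) >= 2L)
          cons[[g]] <- consistency_report(profiles[ids], t = t)
      }
      consistency[[as.character(t)]] <- cons
    }
  }

  pooling_res <- NULL
  if (!is.null(pooling)) {
    if (length(alignments) < 2L)
      qc_stop("pooling simulation needs at least 2 samples")
    pooling_res <- pool_simulation(
      alignments, design,
      fraction = if (is.null(pooling$fraction)) 0.25 else pooling$fraction,
      n_replicates = if (is.null(pooling$n_replicates)) 10 else
        pooling$n_replicates,
      seed = seed, thresholds = thresholds, denominator = denominator)
  }

  report <- structure(list(
    design = design, profiles = profiles, metrics = metrics,
    metrics_table = metrics_table, consistency = consistency,
    pooling = pooling_res,
    parameters = list(thresholds = thresholds, denominator = denominator,
                      seed = seed, groups = groups,
                      pooling = pooling,
                      package_version =
                        as.character(utils::packageVersion("capqc")))),
    class = "capqc_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.capqc_report <- function(x, ...) {
  cat("Capture QC report:", length(x$metrics), "sample(s),",
      x$design$n_regions, "target regions,",
      format(x$design$total_bp, big.mark = ","), "target bp\n\n")
  for (m in x$metrics) { print(m); cat("\n") }
  for (t in names(x$consistency)) print(x$consistency[[t]]$all)
  if (!is.null(x$pooling)) { cat("\n"); print(x$pooling) }
  invisible(x)
}

# serialise the bundle; re-validates ranges/partitions before writing
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mt <- report$metrics_table
  pct_cols <- grep("pct|specificity", names(mt), value = TRUE)
  stopifnot(all(unlist(mt[pct_cols]) >= 0, na.rm = TRUE),
            all(unlist(mt[pct_cols]) <= 100, na.rm = TRUE))
  utils::write.table(mt, file.path(out_dir, "sample_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cons_rows <- list()
  for (t in names(report$consistency))
    for (g in names(report$consistency[[t]])) {
      cr <- report$consistency[[t]][[g]]
      stopifnot(sum(cr$bases$n) == cr$total_bp,
                sum(cr$regions$n) == cr$n_regions)
      cons_rows[[paste(t, g)]] <- data.frame(
        threshold = cr$threshold, group = g,
        level = rep(c("bases", "regions"), each = 3L),
        category = c(cr$bases$category, cr$regions$category),
        n = c(cr$bases$n, cr$regions$n),
        pct = c(cr$bases$pct, cr$regions$pct))
    }
  if (length(cons_rows))
    utils::write.table(do.call(rbind, cons_rows),
                       file.path(out_dir, "consistency.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (length(report$profiles) >= 2L && length(report$parameters$thresholds)) {
    t_max <- max(report$parameters$thresholds)
    nb <- never_covered_regions(report$profiles, t_max)
    if (nrow(nb)) write_bed(nb, file.path(out_dir, "never_covered.bed"))
  }
  if (!is.null(report$pooling)) {
    utils::write.table(report$pooling$replicate_table,
                       file.path(out_dir, "pooling_replicates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  json <- list(
    schema_version = "1.0",
    parameters = report$parameters,
    design = design_stats(report$design)[c("total_bp", "n_regions")],
    samples = lapply(report$metrics, function(m)
      list(sample_id = m$sample_id, reads = m$reads,
           mean_depth = m$mean_depth, regions = m$regions,
           bases = m$bases,
           specificity = m$specificity[c("pct", "denominator")],
           specificity_by_chrom = as.list(m$specificity$by_chrom))),
    consistency = lapply(report$consistency, function(by_group)
      lapply(by_group, function(cr)
        list(threshold = cr$threshold, bases = cr$bases,
             regions = cr$regions))),
    pooling = if (!is.null(report$pooling))
      list(deltas = report$pooling$deltas,
           specificity_members = report$pooling$specificity_members,
           specificity_subsets = report$pooling$specificity_subsets,
           n_replicates = report$pooling$n_replicates))
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(out_dir)
}
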