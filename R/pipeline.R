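#' Configuration for a full pipeline run
#'
#' @param cohort a [cohort_spec()]; defaults to the full study-shaped cohort
#'   from [table1_cohort_spec()].
#' @param grid_shape phantom grid (slices, rows, columns).
#' @param noise_sigma additive noise level of the simulated volumes.
#' @param k noise-threshold multiplier for enhanced-FGT segmentation.
#' @param c_min,c_max fuzzy c-means cluster-number range.
#' @param phase_times post-contrast acquisition times in seconds.
#' @param seed integer master seed; reseeds the cohort spec so one value
#'   controls the whole run.
#' @param out_dir optional output directory for CSV tables, the JSON
#'   manifest and (optionally) NIfTI volumes.
#' @param write_volumes write per-subject NIfTI volumes and masks under
#'   `out_dir/volumes` (off by default: the tables are the endpoint).
#' @param verbose emit one log line per subject and stage.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort = table1_cohort_spec(),
                       grid_shape = c(96L, 96L, 96L),
                       noise_sigma = 5, k = 3, c_min = 2L, c_max = 5L,
                       phase_times = c(60, 180, 300),
                       seed = 1L, out_dir = NULL,
                       write_volumes = FALSE, verbose = FALSE) {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (k <= 0) stop("k must be positive")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, grid_shape = as.integer(grid_shape),
                 noise_sigma = noise_sigma, k = k,
                 c_min = c_min, c_max = c_max, phase_times = phase_times,
                 seed = as.integer(seed), out_dir = out_dir,
                 write_volumes = isTRUE(write_volumes),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys: `seed`, `grid_shape`, `noise_sigma`, `k`, `c_min`,
#' `c_max`, `out_dir`, `write_volumes`, and a `cohort` block with `n_pre`,
#' `weeks`, `n_post`.  Missing keys take the [run_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  ck <- y$cohort %||% list()
  cohort <- table1_cohort_spec(
    seed = y$seed %||% 1L,
    n_pre = as.integer(ck$n_pre %||% 62L),
    weeks = as.integer(ck$weeks %||% c(13L, 16L, 15L, 18L)),
    n_post = as.integer(ck$n_post %||% 70L))
  run_config(cohort = cohort,
             grid_shape = as.integer(y$grid_shape %||% c(96L, 96L, 96L)),
             noise_sigma = y$noise_sigma %||% 5,
             k = y$k %||% 3,
             c_min = as.integer(y$c_min %||% 2L),
             c_max = as.integer(y$c_max %||% 5L),
             seed = as.integer(y$seed %||% 1L),
             out_dir = y$out_dir,
             write_volumes = isTRUE(y$write_volumes),
             verbose = isTRUE(y$verbose))
}

#' Run the full simulation-to-statistics pipeline
#'
#' Generates (or re-generates, deterministically) the phantom cohort, runs
#' the three segmentation steps and the metric computation per subject,
#' applies the laterality rule, and produces the per-subject results table
#' plus the group-comparison tables (cancer vs control and cancer vs benign,
#' per menopausal stratum, FGT plus the two BPE metrics at three phases).
#' Per-subject failures are caught, logged and summarized; the run continues
#' for the remaining subjects.
#'
#' @param config a [run_config()].
#' @return Object of class `bpe_run`: `results` (per-subject data frame),
#'   `comparisons` (stacked [compare_groups()] rows), `cohort`, `failures`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- make_cohort(config$cohort)
  rows <- list(); failures <- list()
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  for (i in seq_len(nrow(cohort))) {
    rec <- cohort[i, ]
    t0 <- Sys.time()
    res <- tryCatch({
      spec <- phantom_spec_for_record(rec, grid_shape = config$grid_shape,
                                      noise_sigma = config$noise_sigma)
      ph <- make_phantom(spec)
      if (config$write_volumes && !is.null(out_dir)) {
        vd <- file.path(out_dir, "volumes", rec$subject_id)
        dir.create(vd, recursive = TRUE, showWarnings = FALSE)
        write_volume(ph$series$pre, file.path(vd, "pre.nii.gz"), ph$series$spacing)
        for (p in 1:3)
          write_volume(ph$series$post[[p]],
                       file.path(vd, sprintf("post%d.nii.gz", p)), ph$series$spacing)
        write_mask(ph$gt$breast_mask, file.path(vd, "breast_truth.nii.gz"),
                   ph$series$spacing)
      }
      q <- quantify_series(ph$series, k = config$k,
                           c_min = config$c_min, c_max = config$c_max)
      sel <- select_measurement(rec$group, q$left, q$right, rec$lesion_side)
      data.frame(subject_id = rec$subject_id, group = rec$group,
                 menopause = rec$menopause, week = rec$week,
                 lesion_side = rec$lesion_side, side = sel$side,
                 fgt = sel$fgt,
                 bpe_v_1 = sel$bpe_v[1], bpe_v_2 = sel$bpe_v[2],
                 bpe_v_3 = sel$bpe_v[3],
                 bpe_i_1 = sel$bpe_i[1], bpe_i_2 = sel$bpe_i[2],
                 bpe_i_3 = sel$bpe_i[3],
                 flags = paste(sel$flags, collapse = ";"),
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- data.frame(
        subject_id = rec$subject_id, stage = "quantify",
        message = conditionMessage(res), stringsAsFactors = FALSE)
      if (config$verbose)
        message(sprintf("[%s] FAILED: %s", rec$subject_id, conditionMessage(res)))
      next
    }
    rows[[length(rows) + 1L]] <- res
    if (config$verbose)
      message(sprintf("[%s] ok (%.1fs)", rec$subject_id,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  results <- if (length(rows)) do.call(rbind, rows) else data.frame()

  comparisons <- NULL
  if (nrow(results) > 0) {
    cmp_rows <- list()
    for (stratum in intersect(c("pre", "post"), unique(results$menopause))) {
      add <- function(metric, phase = NULL) {
        r <- tryCatch(compare_groups(results, metric, stratum, phase),
                      error = function(e) NULL)
        if (!is.null(r)) cmp_rows[[length(cmp_rows) + 1L]] <<- r
      }
      add("fgt")
      for (p in 1:3) { add("bpe_v", p); add("bpe_i", p) }
    }
    if (length(cmp_rows)) comparisons <- do.call(rbind, cmp_rows)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("bpequant")),
    seed = config$seed,
    n_subjects = nrow(cohort), n_quantified = nrow(results),
    n_failed = length(failures),
    config = list(grid_shape = config$grid_shape,
                  noise_sigma = config$noise_sigma, k = config$k,
                  c_min = config$c_min, c_max = config$c_max))

  if (!is.null(out_dir)) {
    utils::write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
    utils::write.csv(results, file.path(out_dir, "results.csv"), row.names = FALSE)
    if (!is.null(comparisons))
      utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                       row.names = FALSE)
    manifest$checksums <- as.list(tools::md5sum(
      list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)))
    names(manifest$checksums) <- basename(names(manifest$checksums))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  structure(list(results = results, comparisons = comparisons,
                 cohort = cohort,
                 failures = if (length(failures)) do.call(rbind, failures)
                            else NULL,
                 manifest = manifest),
            class = "bpe_run")
}

#' @export
print.bpe_run <- function(x, ...) {
  cat("Breast DCE-MRI quantification run\n")
  cat(sprintf("  subjects: %d quantified, %d failed (seed %d)\n",
              x$manifest$n_quantified, x$manifest$n_failed, x$manifest$seed))
  if (!is.null(x$comparisons)) {
    cat("  group comparisons (cancer vs control/benign):\n")
    print(format(x$comparisons[, c("metric", "stratum", "phase", "contrast",
                                   "cancer_pct", "comparator_pct", "p", "auc")],
                 digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.bpe_run <- function(object, ...) {
  print(object)
  if (nrow(object$results)) {
    cat("\n  per-group metric medians (%):\n")
    agg <- stats::aggregate(
      object$results[, c("fgt", "bpe_v_1", "bpe_v_2", "bpe_v_3")],
      by = list(group = object$results$group,
                menopause = object$results$menopause),
      FUN = function(v) round(100 * stats::median(v, na.rm = TRUE), 1))
    print(agg, row.names = FALSE)
  }
  invisible(object)
}
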