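## File formats and end-to-end orchestration. Canonical tabular interchange
## is tab-separated text: one timeseries TSV per subject (rows = timepoints,
## header = region names), long-format TSVs for metrics and results, JSON
## for ground truth, concordance reports and the run manifest.

#' Write / read a BOLD panel as per-subject TSV files
#'
#' Each subject is written as `<subject>.tsv` with a region-name header.
#' Reading validates every file against the atlas: the header must contain
#' exactly the atlas regions (any order; columns are reordered to atlas
#' order), rows must be rectangular, and empty files are rejected.
#'
#' @param panel A `bold_panel`.
#' @param dir Directory for the per-subject files (created if needed).
#' @param atlas An `atlas_table` (fixes region order on read).
#' @param tr Repetition time of the stored data (read side).
#' @return `write_bold_panel` returns the written paths invisibly;
#'   `read_bold_panel` returns a `bold_panel`.
#' @export
write_bold_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "bold_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(panel$subjects), function(s) {
    p <- file.path(dir, paste0(s, ".tsv"))
    utils::write.table(panel$subjects[[s]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' @rdname write_bold_panel
#' @export
read_bold_panel <- function(dir, atlas, tr) {
  validate_atlas(atlas)
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(files)) stop("no .tsv timeseries files found in ", dir)
  subjects <- lapply(files, function(f) {
    if (file.size(f) == 0) stop("empty timeseries file: ", f)
    x <- utils::read.delim(f, check.names = FALSE)
    if (!nrow(x)) stop("timeseries file has a header but no data rows: ", f)
    unknown <- setdiff(colnames(x), atlas$name)
    if (length(unknown))
      stop("file ", basename(f), " contains regions absent from the atlas: ",
           paste(unknown, collapse = ", "))
    missing <- setdiff(atlas$name, colnames(x))
    if (length(missing))
      stop("file ", basename(f), " is missing atlas regions: ",
           paste(missing, collapse = ", "))
    if (!all(vapply(x, is.numeric, logical(1))))
      stop("non-numeric or ragged rows in ", f)
    as.matrix(x[, atlas$name, drop = FALSE])
  })
  names(subjects) <- sub("\\.tsv$", "", basename(files))
  bold_panel(subjects, tr = tr)
}

#' Write long-format tables (metrics, laterality, test results) as TSV
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Pipeline run configuration
#'
#' A single declarative configuration for [run_pipeline()]. Every default
#' matches the analysis conventions used throughout the package (outlier
#' thresholds 0.9 mm / 5 SD, 0.008-0.09 Hz band, graph cost 0.15, 25 mm
#' LCOR kernel, 64 SVD components, alpha 0.05, Bonferroni divisor = number
#' of atlas regions). Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults listed above.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    out_dir = NULL,
    # simulation stage (set cohorts to a list of sim_config to enable)
    cohorts = NULL,
    # preprocessing
    preprocess = FALSE, fd_thresh = 0.9, gs_thresh = 5,
    band = c(0.008, 0.09), filter_method = "fft",
    # graph stage
    cost_target = 0.15,
    metrics = c("GE", "LE", "BC", "APL", "CC", "degree", "cost", "fALFF"),
    # voxel stage
    voxel = FALSE, grid_shape = c(8, 8, 2), voxel_size_mm = 3,
    n_components = 64, fwhm_mm = 25,
    # statistics
    alpha = 0.05, bonferroni_m = NULL,
    corrected_concordance = TRUE,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over, keep.null = TRUE)
  structure(cfg, class = "run_config")
}

#' Read a YAML run configuration
#'
#' @param path YAML file whose top-level keys are [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the full laterality pipeline
#'
#' Orchestrates simulation (when `cohorts` holds simulation configurations),
#' optional timeseries denoising, graph/spectral node metrics, optional
#' voxel metrics, laterality tests for each cohort, and - when two cohorts
#' are configured - the between-cohort concordance report. All tables are
#' written under `out_dir` and listed, with md5 checksums, in a JSON run
#' manifest; identical configurations reproduce identical checksums.
#'
#' @param config A [run_config()] with at least `out_dir` and `cohorts` set.
#' @return The run manifest (list), invisibly; written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  if (is.null(config$cohorts) || !length(config$cohorts))
    stop("config$cohorts must hold at least one simulation configuration ",
         "or cohort object")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_seen <- character(0)
  note <- function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  cohort_names <- names(config$cohorts)
  if (is.null(cohort_names))
    cohort_names <- paste0("cohort", LETTERS[seq_along(config$cohorts)])
  results <- list()
  files <- character(0)

  withCallingHandlers(for (ci in seq_along(config$cohorts)) {
    nm <- cohort_names[ci]
    spec <- config$cohorts[[ci]]
    cohort <- if (inherits(spec, "sim_config")) simulate_cohort(spec)
              else spec
    stopifnot(inherits(cohort, "cohort"))
    cdir <- file.path(out_dir, nm)
    dir.create(cdir, showWarnings = FALSE, recursive = TRUE)

    panel <- cohort$panel
    if (isTRUE(config$preprocess)) {
      motion <- simulate_motion(cohort$config)
      panel$subjects <- lapply(seq_along(panel$subjects), function(s)
        preprocess_subject(panel$subjects[[s]], panel$tr,
                           motion = motion[[s]],
                           fd_thresh = config$fd_thresh,
                           gs_thresh = config$gs_thresh,
                           band = config$band,
                           filter_method = config$filter_method)$bold)
      names(panel$subjects) <- names(cohort$panel$subjects)
    }

    metrics <- compute_node_metrics(panel, cohort$atlas,
                                    cost_target = config$cost_target,
                                    metrics = config$metrics,
                                    band = config$band)
    if (isTRUE(config$voxel)) {
      parc <- block_parcellation(config$grid_shape, cohort$atlas)
      vox <- do.call(rbind, lapply(seq_along(panel$subjects), function(s) {
        vp <- simulate_voxel_session(cohort$config, cohort$atlas,
                                     config$grid_shape,
                                     config$voxel_size_mm, parc, subject = s)
        compute_voxel_metrics(vp, cohort$atlas,
                              n_components = config$n_components,
                              fwhm_mm = config$fwhm_mm, band = config$band,
                              subject = names(panel$subjects)[s])
      }))
      metrics <- rbind(metrics, vox)
    }

    m_div <- if (is.null(config$bonferroni_m)) nrow(cohort$atlas)
             else config$bonferroni_m
    li <- build_laterality_table(metrics, cohort$atlas)
    paired <- paired_lr_tests(metrics, cohort$atlas, alpha = config$alpha,
                              m = m_div)
    one_sample <- li_one_sample_tests(li, cohort$atlas,
                                      alpha = config$alpha, m = m_div)

    f <- c(metrics = file.path(cdir, "node_metrics.tsv"),
           laterality = file.path(cdir, "laterality.tsv"),
           paired = file.path(cdir, "paired_tests.tsv"),
           one_sample = file.path(cdir, "li_tests.tsv"),
           demographics = file.path(cdir, "demographics.tsv"))
    write_results_tsv(metrics, f[["metrics"]])
    write_results_tsv(li, f[["laterality"]])
    write_results_tsv(paired, f[["paired"]])
    write_results_tsv(one_sample, f[["one_sample"]])
    write_results_tsv(cohort$demographics, f[["demographics"]])
    if (!is.null(cohort$ground_truth$effects) ||
        !is.null(cohort$ground_truth$outlier_frames)) {
      f[["ground_truth"]] <- file.path(cdir, "ground_truth.json")
      write_ground_truth(cohort, f[["ground_truth"]])
    }
    files <- c(files, f)
    results[[nm]] <- list(paired = paired, one_sample = one_sample,
                          demographics = cohort$demographics)
  }, warning = note)

  if (length(results) >= 2) {
    conc <- concordance(results[[1]]$paired, results[[2]]$paired,
                        corrected = config$corrected_concordance,
                        alpha = config$alpha)
    cpath <- file.path(out_dir, "concordance.json")
    write_concordance(conc, cpath)
    files <- c(files, concordance = cpath)
    demo_path <- file.path(out_dir, "demographic_comparison.tsv")
    write_results_tsv(compare_demographics(results[[1]]$demographics,
                                           results[[2]]$demographics),
                      demo_path)
    files <- c(files, demographic_comparison = demo_path)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("hemilat")),
    config = serializable_config(config),
    files = lapply(files, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    warnings = warnings_seen
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}

serializable_config <- function(config) {
  cfg <- unclass(config)
  cfg$cohorts <- lapply(cfg$cohorts, function(x) {
    if (inherits(x, "sim_config")) unclass(x)[c("n_subjects", "n_timepoints",
                                                "tr", "n_pairs", "n_unpaired",
                                                "noise_sd", "seed")]
    else "pre-built cohort"
  })
  cfg
}

#' Block parcellation of a voxel grid
#'
#' Assigns contiguous, equally sized blocks of the flattened grid to the
#' atlas regions in `roi_id` order (leftover voxels become background).
#' Used to pair the synthetic voxel sessions with the toy atlas.
#'
#' @param grid_shape Integer 3-vector.
#' @param atlas An `atlas_table`.
#' @return Integer array of `grid_shape` with ROI labels (0 = background).
#' @export
block_parcellation <- function(grid_shape, atlas) {
  n_vox <- prod(grid_shape)
  n_roi <- nrow(atlas)
  per <- floor(n_vox / n_roi)
  if (per < 2)
    stop("grid too small: fewer than 2 voxels per region")
  labs <- rep(0L, n_vox)
  labs[seq_len(per * n_roi)] <- rep(atlas$roi_id, each = per)
  array(labs, dim = grid_shape)
}
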