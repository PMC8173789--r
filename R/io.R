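metrics_csv_header <- c("patient_id", "oar", "dsc", "cmd_cm", "dv_pct",
                        "mhd_cm", "ahd_cm")

#' Read and write metric tables
#'
#' Metric CSVs carry one row per reference/test pair with the header exactly
#' `patient_id, oar, dsc, cmd_cm, dv_pct, mhd_cm, ahd_cm`. By default values
#' round-trip at full double precision; `display = TRUE` writes the
#' reporting precision instead (DSC 4 decimals, distances 2, volume
#' difference 1).
#'
#' @param x data frame of metrics (or list of [metric_set()] objects).
#' @param path CSV file path.
#' @param display write display-rounded values instead of full precision.
#' @return `read_metrics_csv` returns the data frame; writers return `path`
#'   invisibly.
#' @export
write_metrics_csv <- function(x, path, display = FALSE) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- do.call(rbind, lapply(x, as.data.frame))
  }
  stopifnot(all(metrics_csv_header %in% names(x)))
  x <- x[metrics_csv_header]
  if (display) {
    x$dsc <- sprintf("%.4f", x$dsc)
    x$cmd_cm <- sprintf("%.2f", x$cmd_cm)
    x$dv_pct <- sprintf("%.1f", x$dv_pct)
    x$mhd_cm <- sprintf("%.2f", x$mhd_cm)
    x$ahd_cm <- sprintf("%.2f", x$ahd_cm)
  } else {
    for (nm in metrics_csv_header[-(1:2)]) {
      x[[nm]] <- formatC(x[[nm]], digits = 17, format = "g")
    }
  }
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(metrics_csv_header, names(df))
  if (length(miss)) {
    stop("metrics CSV lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read a cohort CSV for SOC derivation
#'
#' Expects the metric columns plus `subjective_level` (1-4) and an optional
#' 0/1 `exclude` flag honoured by [soc_standard()].
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("oar", "dsc", "subjective_level")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("cohort CSV lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read per-organ slice-modification records
#'
#' Columns: `oar`, `total_slices`, `modified_slices`, optionally
#' `pct_modified` (used, unrounded, in preference to the count ratio when
#' present — e.g. cohort-average percentages reported next to averaged
#' counts).
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_slices_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("oar", "total_slices"), names(df))
  if (length(miss)) {
    stop("slices CSV lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Subjectively grade a table of slice records
#'
#' Applies [subjective_grade()] row by row.
#'
#' @param df data frame as from [read_slices_csv()].
#' @return Named integer vector of levels, named by organ.
#' @export
grade_subjective_table <- function(df) {
  lv <- vapply(seq_len(nrow(df)), function(i) {
    subjective_grade(
      total_slices = df$total_slices[i],
      modified_slices = if (!is.null(df$modified_slices) &&
                            !is.na(df$modified_slices[i]))
        df$modified_slices[i] else NULL,
      pct_modified = if (!is.null(df$pct_modified) &&
                         !is.na(df$pct_modified[i]))
        df$pct_modified[i] else NULL)
  }, integer(1))
  stats::setNames(lv, df$oar)
}

#' Grade a table of metric rows under a scheme
#'
#' Applies [grade_metric_set()] row by row; one column of levels per index
#' the scheme defines.
#'
#' @param df data frame with the metric columns.
#' @param scheme scheme object or name.
#' @return Data frame: `oar` (and `patient_id` if present) plus
#'   `level_<index>` columns.
#' @export
grade_metrics_table <- function(df, scheme = "our_center") {
  if (is.character(scheme)) scheme <- load_scheme(scheme)
  lv <- do.call(rbind, lapply(seq_len(nrow(df)), function(i)
    grade_metric_set(df[i, , drop = FALSE], scheme)))
  colnames(lv) <- paste0("level_", names(scheme$indexes))
  id_cols <- intersect(c("patient_id", "oar"), names(df))
  cbind(df[id_cols], as.data.frame(lv))
}

#' Write a derived SOC standard as machine-readable JSON
#'
#' Serialises per-organ, per-index, per-level entries with their mode tags
#' (`range` / `mean` / `undefined`) and the distribution kind.
#'
#' @param fit a [soc_standard()] object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_standard_json <- function(fit, path) {
  stopifnot(inherits(fit, "soc_standard"))
  payload <- list(
    indexes = fit$indexes,
    oars = lapply(fit$oars, function(f) {
      list(oar = f$oar, distribution_kind = f$distribution_kind,
           n_cases = f$n_cases,
           indexes = lapply(f$indexes, function(e) {
             lv <- e$levels
             lv$hi[is.infinite(lv$hi)] <- "Inf"
             list(levels = lv, pairs = e$pairs)
           }))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Batch metric computation over paired NIfTI directories
#'
#' Pairs reference and test masks either by identical relative filename
#' under two directories, or by an explicit manifest (data frame or CSV with
#' columns `patient_id`, `oar`, `reference`, `test`). Failures on individual
#' pairs are collected, not fatal to the batch.
#'
#' @param ref_dir,test_dir directories of NIfTI masks paired by filename;
#'   ignored when `manifest` is given.
#' @param manifest optional manifest data frame or CSV path.
#' @param out optional path to write the metrics CSV.
#' @return List with `metrics` (data frame of successful pairs) and `errors`
#'   (data frame `pair`, `message`, zero rows when all pairs succeeded).
#' @export
run_metrics <- function(ref_dir = NULL, test_dir = NULL, manifest = NULL,
                        out = NULL) {
  if (!is.null(manifest)) {
    if (is.character(manifest)) {
      manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    }
    stopifnot(all(c("reference", "test") %in% names(manifest)))
    if (is.null(manifest$patient_id)) manifest$patient_id <- basename(manifest$reference)
    if (is.null(manifest$oar)) manifest$oar <- NA_character_
  } else {
    stopifnot(!is.null(ref_dir), !is.null(test_dir))
    files <- list.files(ref_dir, pattern = "\\.nii(\\.gz)?$", recursive = TRUE)
    files <- files[file.exists(file.path(test_dir, files))]
    if (!length(files)) {
      stop("no reference/test mask pairs found", call. = FALSE)
    }
    manifest <- data.frame(patient_id = files, oar = NA_character_,
                           reference = file.path(ref_dir, files),
                           test = file.path(test_dir, files),
                           stringsAsFactors = FALSE)
  }
  rows <- list(); errs <- list()
  for (i in seq_len(nrow(manifest))) {
    res <- tryCatch(suppressWarnings({
      r <- read_mask_nifti(manifest$reference[i])
      t <- read_mask_nifti(manifest$test[i])
      as.data.frame(compute_metric_set(r, t,
                                       patient_id = manifest$patient_id[i],
                                       oar = manifest$oar[i]))
    }), error = function(e) e)
    if (inherits(res, "error")) {
      errs[[length(errs) + 1]] <- data.frame(
        pair = manifest$patient_id[i], message = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  metrics <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 7)), metrics_csv_header)
  errors <- if (length(errs)) do.call(rbind, errs) else
    data.frame(pair = character(0), message = character(0))
  if (!is.null(out) && nrow(metrics)) write_metrics_csv(metrics, out)
  list(metrics = metrics, errors = errors)
}

#' Full grading pipeline on a cohort
#'
#' From a per-case cohort (metrics + subjective level) this computes, in
#' one deterministic pass: per-organ mean metrics, their objective levels
#' under a grading scheme, per-organ subjective levels (from slice records
#' when supplied, else the per-organ median case level, ties to the worse
#' level), the subjective-vs-DSC consistency report, and the derived SOC
#' standard. With `out_dir` set, all artifacts plus a manifest JSON are
#' written; reruns on the same inputs are byte-identical.
#'
#' @param cohort data frame (or CSV path) of per-case records: `oar`, the
#'   metric columns, `subjective_level`, optional `patient_id`/`exclude`.
#' @param slices optional data frame or CSV of per-organ slice records for
#'   the subjective path (see [read_slices_csv()]).
#' @param scheme grading scheme or name for the objective path.
#' @param indexes indexes for which to derive the SOC standard.
#' @param out_dir optional output directory.
#' @return List: `mean_metrics`, `objective_levels`, `subjective_levels`,
#'   `consistency`, `standard` (a [soc_standard()]), `standard_table`.
#' @export
run_pipeline <- function(cohort, slices = NULL, scheme = "our_center",
                         indexes = "dsc", out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  if (is.character(slices)) slices <- read_slices_csv(slices)
  if (is.character(scheme)) scheme <- load_scheme(scheme)
  if (!is.null(cohort$exclude)) {
    cohort <- cohort[!(as.numeric(cohort$exclude) > 0), , drop = FALSE]
  }
  idx_cols <- intersect(metric_names(), names(cohort))
  mean_metrics <- stats::aggregate(cohort[idx_cols],
                                   by = list(oar = cohort$oar), FUN = mean)
  mean_metrics <- mean_metrics[order(mean_metrics$oar), , drop = FALSE]
  objective <- grade_metrics_table(mean_metrics, scheme)

  subjective <- if (!is.null(slices)) {
    grade_subjective_table(slices)
  } else {
    v <- vapply(split(cohort$subjective_level, cohort$oar), function(l) {
      as.integer(floor(stats::median(l)))
    }, integer(1))
    v
  }

  consistency <- if ("level_dsc" %in% names(objective)) {
    obj_dsc <- stats::setNames(objective$level_dsc, objective$oar)
    common <- intersect(names(subjective), names(obj_dsc))
    consistency_report(subjective[common], obj_dsc[common])
  } else NULL

  standard <- soc_standard(cohort, indexes = indexes)
  standard_table <- format_standard_table(standard)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(objective, file.path(out_dir, "objective_levels.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(oar = names(subjective),
                                subjective_level = as.integer(subjective)),
                     file.path(out_dir, "subjective_levels.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(consistency)) {
      utils::write.csv(as.data.frame(consistency),
                       file.path(out_dir, "consistency.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    write_standard_json(standard, file.path(out_dir, "standard.json"))
    utils::write.csv(standard_table, file.path(out_dir, "standard_table.csv"),
                     row.names = FALSE, quote = FALSE)
    manifest <- list(
      artifacts = c("objective_levels.csv", "subjective_levels.csv",
                    if (!is.null(consistency)) "consistency.csv",
                    "standard.json", "standard_table.csv"),
      scheme = scheme$name, indexes = indexes,
      n_cases = nrow(cohort), n_oars = length(unique(cohort$oar)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(mean_metrics = mean_metrics, objective_levels = objective,
       subjective_levels = subjective, consistency = consistency,
       standard = standard, standard_table = standard_table)
}

#' Published thoracic worked-example tables
#'
#' Per-organ summary tables from a 20-patient atlas-based auto-segmentation
#' evaluation of the 13 RTOG thoracic organs at risk, shipped as plain-CSV
#' fixtures: the per-organ mean (and SD) of the five geometric indexes, the
#' published level assignments under the three built-in schemes, and the
#' per-organ slice-modification records with their subjective scores. They
#' serve as the package's worked example: regrading the printed means and
#' slice records reproduces the printed level assignments.
#'
#' @return Data frames (see the CSVs under `inst/extdata/thorax/`).
#' @name thorax_tables
NULL

thorax_file <- function(name) {
  system.file("extdata", "thorax", name, package = "socgrade", mustWork = TRUE)
}

#' @rdname thorax_tables
#' @export
thorax_index_means <- function() {
  utils::read.csv(thorax_file("thorax_index_means.csv"),
                  stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname thorax_tables
#' @export
thorax_published_levels <- function() {
  utils::read.csv(thorax_file("thorax_published_levels.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname thorax_tables
#' @export
thorax_subjective <- function() {
  utils::read.csv(thorax_file("thorax_subjective.csv"),
                  stringsAsFactors = FALSE)
}
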