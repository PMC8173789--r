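#' Threshold-based grading schemes
#'
#' A grading scheme maps each geometric index value to an accuracy level.
#' Levels 1-3 partition the index's legal range via ordered cutpoints
#' (1 = auto-segmentation not recommended, 2 = many manual modifications
#' required, 3 = some manual modifications required); an optional Level 4
#' is awarded only at the exact perfect value (DSC 1, distance 0, within
#' 1e-9), meaning the auto-contour can replace manual delineation outright.
#'
#' Three built-in schemes ship with the package as versioned JSON configs:
#'
#' * `our_center` — all five indexes. DSC cutpoints (0.7, 0.8); dCMD
#'   (0.5, 1.0) cm; dV (10, 20) %; MHD (1.0, 2.2) cm; AHD (0.2, 0.4) cm;
#'   Level 4 at the perfect value.
#' * `velker` — DSC only, cutpoints (0.6, 0.8), levels 1-3.
#' * `ciardo` — DSC (0.6, 0.8), dCMD (0.2, 0.5) cm, AHD (0.15, 0.40) cm,
#'   levels 1-3.
#'
#' **Boundary convention:** a value lying exactly on a cutpoint is assigned
#' the *better* level (the partition is closed on the better side), e.g.
#' DSC 0.8 is level 3 and dCMD 1.0 cm is level 2 under `our_center`.
#'
#' @param name one of `"our_center"`, `"velker"`, `"ciardo"`, or the path
#'   of a custom scheme JSON file.
#' @return A `grading_scheme` object: list with `name` and `indexes`, the
#'   latter keyed by index name (`dsc`, `cmd`, `dv`, `mhd`, `ahd`), each a
#'   list with `direction` (`"higher"`/`"lower"`), ascending `cutpoints`,
#'   and optional `perfect` value.
#' @examples
#' sch <- load_scheme("our_center")
#' grade_value(0.96, sch$indexes$dsc)  # level 3
#' @export
load_scheme <- function(name) {
  builtin <- c("our_center", "velker", "ciardo")
  path <- if (name %in% builtin) {
    system.file("extdata", "schemes", paste0(name, ".json"),
                package = "socgrade", mustWork = TRUE)
  } else if (file.exists(name)) {
    name
  } else {
    stop("unknown scheme '", name, "': not a built-in (",
         paste(builtin, collapse = ", "), ") nor an existing file",
         call. = FALSE)
  }
  read_scheme_json(path)
}

#' Read and validate a grading-scheme JSON config
#'
#' @param path a JSON file as written by the built-in configs:
#'   `{"name": ..., "indexes": {"dsc": {"direction", "cutpoints", "perfect"}, ...}}`.
#' @return A validated `grading_scheme`.
#' @export
read_scheme_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$name) || is.null(raw$indexes) || !length(raw$indexes)) {
    stop("scheme config must have `name` and a nonempty `indexes` map: ",
         path, call. = FALSE)
  }
  idx <- lapply(names(raw$indexes), function(nm) {
    spec <- raw$indexes[[nm]]
    if (!nm %in% c("dsc", "cmd", "dv", "mhd", "ahd")) {
      stop("unknown index '", nm, "' in scheme config", call. = FALSE)
    }
    dir <- match.arg(spec$direction, c("higher", "lower"))
    cp <- as.numeric(spec$cutpoints)
    if (length(cp) < 1 || is.unsorted(cp, strictly = TRUE)) {
      stop("cutpoints for '", nm, "' must be strictly increasing", call. = FALSE)
    }
    expected_dir <- if (nm == "dsc") "higher" else "lower"
    if (dir != expected_dir) {
      stop("index '", nm, "' must have direction '", expected_dir, "'",
           call. = FALSE)
    }
    list(index = nm, direction = dir, cutpoints = cp,
         perfect = if (is.null(spec$perfect)) NULL else as.numeric(spec$perfect))
  })
  names(idx) <- names(raw$indexes)
  structure(list(name = raw$name, indexes = idx), class = "grading_scheme")
}

#' @export
print.grading_scheme <- function(x, ...) {
  cat(sprintf("<grading_scheme '%s'> indexes: %s\n", x$name,
              paste(names(x$indexes), collapse = ", ")))
  invisible(x)
}

#' Grade one index value
#'
#' Maps a value to a level under one index's thresholds. Higher-is-better
#' indexes (DSC) with ascending cutpoints `(c1, ..., ck)` yield level
#' `1 + #\{ci <= value\}`; lower-is-better indexes yield
#' `1 + #\{value <= ci\}` so that small distances grade well. A value
#' exactly on a cutpoint takes the better level. If the thresholds define a
#' `perfect` value, matching it within 1e-9 yields the extra top level
#' (level 4 for the two-cutpoint built-ins).
#'
#' @param value the index value (DSC in \[0,1\]; distances/percentages >= 0).
#' @param thresholds one entry of a [load_scheme()] object's `indexes`.
#' @return Integer level.
#' @export
grade_value <- function(value, thresholds) {
  if (is.na(value)) stop("cannot grade NA", call. = FALSE)
  eps <- 1e-9
  if (thresholds$index == "dsc") {
    if (value < -eps || value > 1 + eps) {
      stop("dsc value out of range [0, 1]: ", value, call. = FALSE)
    }
  } else if (value < -eps) {
    stop("'", thresholds$index, "' value must be >= 0: ", value, call. = FALSE)
  }
  if (!is.null(thresholds$perfect) &&
      abs(value - thresholds$perfect) <= eps) {
    return(length(thresholds$cutpoints) + 2L)
  }
  if (thresholds$direction == "higher") {
    1L + sum(value >= thresholds$cutpoints - eps)
  } else {
    1L + sum(value <= thresholds$cutpoints + eps)
  }
}

#' Grade a metric set under a scheme
#'
#' One level per index the scheme defines; indexes absent from the scheme
#' (e.g. dV under `ciardo`) are omitted from the result, not defaulted.
#'
#' @param metrics a [metric_set()], or a named list/one-row data frame with
#'   fields `dsc`, `cmd_cm`, `dv_pct`, `mhd_cm`, `ahd_cm`.
#' @param scheme a `grading_scheme` or a scheme name for [load_scheme()].
#' @return Named integer vector of levels, names being the scheme's indexes.
#' @examples
#' m <- metric_set(dsc = 0.9, cmd_cm = 0.4, dv_pct = 7,
#'                 mhd_cm = 1.85, ahd_cm = 0.24)
#' grade_metric_set(m, "our_center")
#' @export
grade_metric_set <- function(metrics, scheme = "our_center") {
  if (is.character(scheme)) scheme <- load_scheme(scheme)
  stopifnot(inherits(scheme, "grading_scheme"))
  field <- c(dsc = "dsc", cmd = "cmd_cm", dv = "dv_pct",
             mhd = "mhd_cm", ahd = "ahd_cm")
  vapply(scheme$indexes, function(th) {
    v <- metrics[[field[[th$index]]]]
    if (is.null(v)) {
      stop("metrics lack field '", field[[th$index]], "' required by scheme '",
           scheme$name, "'", call. = FALSE)
    }
    grade_value(as.numeric(v), th)
  }, integer(1))
}

#' Subjective slice-modification grading
#'
#' Grades an auto-segmentation contour from how many of its CT slices an
#' expert had to modify, on a 1-4 scale (4 = nothing to modify, the
#' auto-contour replaces manual delineation; 1 = auto-segmentation not
#' recommended). The rule depends on the organ's length in slices:
#'
#' * more than 10 slices — by percentage modified: level 3 for (0, 10\],
#'   level 2 for (10, 20\], level 1 for (20, 100\];
#' * 3-10 slices — by count: level 3 for 1 slice, 2 for 2-3, 1 for more
#'   than 3;
#' * fewer than 3 slices — by count: level 3 for 1, 2 for 2, 1 for 3 or
#'   more (with at most 2 slices this last class is vacuous; it is kept as
#'   written in the standard).
#'
#' A percentage exactly on a boundary takes the better level (10% is
#' level 3). When `pct_modified` is not supplied it is computed as
#' `100 * modified_slices / total_slices` and used unrounded.
#'
#' @param total_slices number of CT slices the organ spans.
#' @param modified_slices number of slices requiring manual modification.
#'   May be omitted for organs over 10 slices if `pct_modified` is given
#'   and nonzero.
#' @param pct_modified percentage of slices modified; optional override
#'   (e.g. a cohort-average percentage reported alongside averaged counts).
#' @return Integer level in 1-4.
#' @examples
#' subjective_grade(71, 5)            # level 3
#' subjective_grade(9, 7)             # level 1
#' subjective_grade(319, pct_modified = 14)  # level 2
#' @export
subjective_grade <- function(total_slices, modified_slices = NULL,
                             pct_modified = NULL) {
  if (is.na(total_slices) || total_slices < 0) {
    stop("`total_slices` must be a nonnegative count", call. = FALSE)
  }
  if (!is.null(modified_slices)) {
    if (is.na(modified_slices) || modified_slices < 0) {
      stop("`modified_slices` must be a nonnegative count", call. = FALSE)
    }
    if (modified_slices > total_slices) {
      stop("inconsistent-record error: modified_slices (", modified_slices,
           ") exceeds total_slices (", total_slices, ")", call. = FALSE)
    }
  }
  none_modified <- (!is.null(modified_slices) && modified_slices == 0) ||
    (is.null(modified_slices) && !is.null(pct_modified) && pct_modified == 0)
  if (none_modified) return(4L)
  if (total_slices == 0) {
    stop("inconsistent-record error: total_slices is 0 but modifications were recorded",
         call. = FALSE)
  }
  eps <- 1e-9
  if (total_slices > 10) {
    pct <- if (!is.null(pct_modified)) pct_modified else
      100 * modified_slices / total_slices
    if (is.na(pct) || pct < 0 || pct > 100 + eps) {
      stop("percentage modified out of [0, 100]: ", pct, call. = FALSE)
    }
    if (pct <= 10 + eps) 3L else if (pct <= 20 + eps) 2L else 1L
  } else {
    if (is.null(modified_slices)) {
      stop("`modified_slices` is required for organs of 10 slices or fewer",
           call. = FALSE)
    }
    if (total_slices >= 3) {
      if (modified_slices == 1) 3L else if (modified_slices <= 3) 2L else 1L
    } else {
      if (modified_slices == 1) 3L else if (modified_slices == 2) 2L else 1L
    }
  }
}

#' Display-rounded modification percentage
#'
#' Round-half-up to the nearest integer percent, for table display only;
#' grading always uses the unrounded percentage.
#'
#' @param modified_slices,total_slices slice counts.
#' @return Integer percent.
#' @export
pct_modified_display <- function(modified_slices, total_slices) {
  floor(100 * modified_slices / total_slices + 0.5)
}

#' Compare subjective and objective level assignments
#'
#' Tabulates, organ by organ, how a subjective level assignment relates to
#' an objective (index-based) one, and summarises how often the subjective
#' grade is exactly one level lower — the signature of geometric indexes
#' missing clinically relevant modification burden.
#'
#' @param subjective,objective named integer vectors of levels with the same
#'   organ names (order may differ).
#' @return A `consistency_report`: data frame with columns `oar`,
#'   `subjective`, `objective`, `delta`, `category` (one of
#'   `"one_level_lower"`, `"equal"`, `"other"`), with a `summary` attribute
#'   giving counts and percentages (one decimal).
#' @export
consistency_report <- function(subjective, objective) {
  if (is.null(names(subjective)) || is.null(names(objective))) {
    stop("both level vectors must be named by organ", call. = FALSE)
  }
  miss_o <- setdiff(names(subjective), names(objective))
  miss_s <- setdiff(names(objective), names(subjective))
  if (length(miss_o) || length(miss_s)) {
    stop("organ key mismatch; missing from objective: [",
         paste(miss_o, collapse = ", "), "], missing from subjective: [",
         paste(miss_s, collapse = ", "), "]", call. = FALSE)
  }
  objective <- objective[names(subjective)]
  delta <- as.integer(subjective) - as.integer(objective)
  category <- ifelse(delta == -1L, "one_level_lower",
                     ifelse(delta == 0L, "equal", "other"))
  out <- data.frame(oar = names(subjective),
                    subjective = as.integer(subjective),
                    objective = as.integer(objective),
                    delta = delta, category = category,
                    stringsAsFactors = FALSE, row.names = NULL)
  n <- nrow(out)
  counts <- c(one_level_lower = sum(category == "one_level_lower"),
              equal = sum(category == "equal"),
              other = sum(category == "other"))
  summary <- data.frame(category = names(counts),
                        count = as.integer(counts),
                        pct = round(100 * counts / n, 1),
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(out, summary = summary, class = c("consistency_report",
                                              "data.frame"))
}

#' @export
print.consistency_report <- function(x, ...) {
  print.data.frame(x, ...)
  s <- attr(x, "summary")
  cat("\n")
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-16s %2d (%.1f%%)\n", s$category[i], s$count[i], s$pct[i]))
  }
  invisible(x)
}
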