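#' Per-level summaries of geometric indexes for one organ
#'
#' Groups one organ's cases by subjective level and returns, per observed
#' level and index, the exact minimum, maximum and mean — the raw material
#' from which a combined grading standard is derived.
#'
#' @param cases data frame of cases for a single organ, with a
#'   `subjective_level` column (integer 1-4) and one column per index.
#' @param indexes index columns to summarise; defaults to all of
#'   `dsc`, `cmd_cm`, `dv_pct`, `mhd_cm`, `ahd_cm` that are present.
#' @return A data frame with columns `level`, `n_cases`, `index`, `min`,
#'   `max`, `mean`, one row per observed level x index.
#' @examples
#' cases <- data.frame(subjective_level = c(3, 3, 3),
#'                     dsc = c(0.93, 0.95, 0.99))
#' summarize_levels(cases)
#' @export
summarize_levels <- function(cases, indexes = intersect(metric_names(),
                                                        names(cases))) {
  if (!is.data.frame(cases) || nrow(cases) == 0) {
    stop("`cases` must be a nonempty data frame", call. = FALSE)
  }
  if (!is.null(cases$oar) && length(unique(cases$oar)) > 1) {
    stop("`cases` mixes several organs: ",
         paste(unique(cases$oar), collapse = ", "), call. = FALSE)
  }
  if (is.null(cases$subjective_level) ||
      !all(cases$subjective_level %in% 1:4)) {
    stop("`subjective_level` must be present with values in 1-4", call. = FALSE)
  }
  if (!length(indexes)) stop("no index columns found", call. = FALSE)
  lv <- sort(unique(as.integer(cases$subjective_level)))
  out <- do.call(rbind, lapply(lv, function(l) {
    sub <- cases[cases$subjective_level == l, , drop = FALSE]
    do.call(rbind, lapply(indexes, function(ix) {
      v <- as.numeric(sub[[ix]])
      data.frame(level = l, n_cases = nrow(sub), index = ix,
                 min = min(v), max = max(v), mean = mean(v),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Do two closed intervals intersect?
#'
#' @param a,b numeric length-2 `c(lo, hi)` closed intervals.
#' @return `TRUE` iff the intervals share at least one point (a shared
#'   endpoint counts as overlap).
#' @export
ranges_overlap <- function(a, b) {
  stopifnot(length(a) == 2, length(b) == 2, a[1] <= a[2], b[1] <= b[2])
  a[1] <= b[2] && b[1] <= a[2]
}

index_direction <- function(index) {
  if (index == "dsc") "higher" else "lower"
}

# Derive per-level entries for one organ and one index from its level
# summaries. Returns list(levels = data.frame(level, n, min, max, mean,
# mode, lo, hi), pairs = data.frame(lower, upper, relation)).
derive_index_entries <- function(stats, index) {
  s <- stats[stats$index == index, , drop = FALSE]
  s <- s[order(s$level), , drop = FALSE]
  dir <- index_direction(index)
  k <- nrow(s)

  relation <- character(0)
  if (k > 1) {
    relation <- vapply(seq_len(k - 1), function(i) {
      lo_lv <- c(s$min[i], s$max[i])
      hi_lv <- c(s$min[i + 1], s$max[i + 1])
      if (!ranges_overlap(lo_lv, hi_lv)) return("disjoint")
      mono <- if (dir == "higher") s$mean[i + 1] > s$mean[i]
              else s$mean[i + 1] < s$mean[i]
      if (mono) "overlap_monotone" else "overlap_nonmonotone"
    }, character(1))
  }

  mode <- character(k)
  for (i in seq_len(k)) {
    adj <- relation[c(if (i > 1) i - 1, if (i < k) i)]
    mode[i] <- if (any(adj == "overlap_nonmonotone")) "undefined"
               else if (any(adj == "overlap_monotone")) "mean"
               else "range"
  }

  # Interval bounds for range-mode entries: the bound facing an adjacent
  # level (observed or reachable) is the observed extreme; the bound on a
  # side with nothing beyond it is extended to the theoretical limit
  # (level 1 on the poor side; level >= 3 on the quality side, where the
  # limit is the perfect value itself).
  lo <- hi <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    if (mode[i] != "range") next
    if (dir == "higher") {
      lo[i] <- if (s$level[i] == 1L) 0 else s$min[i]
      hi[i] <- if (s$level[i] >= 3L) 1 else s$max[i]
    } else {
      lo[i] <- if (s$level[i] >= 3L) 0 else s$min[i]
      hi[i] <- if (s$level[i] == 1L) Inf else s$max[i]
    }
  }

  levels <- data.frame(level = s$level, n = s$n_cases, min = s$min,
                       max = s$max, mean = s$mean, mode = mode,
                       lo = lo, hi = hi, stringsAsFactors = FALSE)
  pairs <- if (k > 1) {
    data.frame(lower = s$level[-k], upper = s$level[-1],
               relation = relation, stringsAsFactors = FALSE)
  } else {
    data.frame(lower = integer(0), upper = integer(0),
               relation = character(0), stringsAsFactors = FALSE)
  }
  list(levels = levels, pairs = pairs)
}

#' Derive a subjective-objective-combined (SOC) grading standard
#'
#' Fits an organ-specific grading standard from a cohort of cases, each
#' carrying geometric index values for an auto-segmentation/manual contour
#' pair plus the expert's subjective level (1-4). Per organ and index, the
#' cases are grouped by subjective level:
#'
#' * If an organ shows a **single** subjective level, its observed index
#'   range defines a half-bounded interval for that level (anchored at the
#'   observed extreme facing the unobserved adjacent levels and extended to
#'   the theoretical limit on the level's own quality side, e.g. DSC
#'   `min-1` for level 3, `0-max` for level 1).
#' * If it shows **several** levels, adjacent observed levels are compared:
#'   when their observed index ranges do not overlap, the ranges themselves
#'   become the standard (range-based); when they overlap but the per-level
#'   means are still monotone in the index's direction of improvement, the
#'   means become the standard (mean-based); non-monotone means yield an
#'   explicit `"undefined"` entry rather than a silent standard.
#'
#' A mixed standard (ranges between one adjacent pair, means at another) is
#' possible and preserved. Cases flagged in an `exclude` column (nonzero)
#' are dropped before derivation.
#'
#' @param data data frame with columns `oar`, `subjective_level`, the index
#'   columns in `indexes`, and optionally `patient_id` and `exclude`.
#' @param indexes which index columns to derive standards for. The headline
#'   SOC standard uses DSC only (the index whose per-level correspondence
#'   proved strongest); pass more of `cmd_cm`, `dv_pct`, `mhd_cm`, `ahd_cm`
#'   to derive the others.
#' @return An object of class `soc_standard` with `print`, `summary`,
#'   `predict`, `plot`, and `as.data.frame` methods. Per organ it records
#'   the distribution kind (`"single-level"`/`"multi-level"`), per-level
#'   case counts, and per index the per-level entries with mode tags
#'   (`"range"`, `"mean"`, `"undefined"`).
#' @examples
#' set.seed(1)
#' coh <- simulate_cohort(data.frame(
#'   oar = "LungX", level = c(2, 3), n = c(20, 20),
#'   dsc_lo = c(0.70, 0.82), dsc_hi = c(0.78, 0.95)))
#' fit <- soc_standard(coh)
#' fit
#' predict(fit, data.frame(oar = "LungX", dsc = c(0.75, 0.90)))
#' @export
soc_standard <- function(data, indexes = "dsc") {
  if (!is.data.frame(data) || nrow(data) == 0) {
    stop("`data` must be a nonempty data frame of cases", call. = FALSE)
  }
  need <- c("oar", "subjective_level", indexes)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("`data` lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(indexes, metric_names())
  if (length(bad)) {
    stop("unknown index column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(data$exclude)) {
    data <- data[!(as.numeric(data$exclude) > 0), , drop = FALSE]
    if (nrow(data) == 0) stop("all cases excluded", call. = FALSE)
  }
  oars <- unique(as.character(data$oar))
  fits <- lapply(oars, function(o) {
    cases <- data[data$oar == o, , drop = FALSE]
    stats <- summarize_levels(cases, indexes)
    entries <- lapply(indexes, function(ix) derive_index_entries(stats, ix))
    names(entries) <- indexes
    nlev <- length(unique(cases$subjective_level))
    list(oar = o,
         distribution_kind = if (nlev == 1) "single-level" else "multi-level",
         n_cases = nrow(cases),
         mean_index = vapply(indexes, function(ix)
           mean(as.numeric(cases[[ix]])), numeric(1)),
         indexes = entries)
  })
  names(fits) <- oars
  structure(list(oars = fits, indexes = indexes, data = data,
                 call = match.call()),
            class = "soc_standard")
}

#' @export
print.soc_standard <- function(x, ...) {
  cat("SOC grading standard —", length(x$oars), "organ(s), indexes:",
      paste(x$indexes, collapse = ", "), "\n\n")
  print(format_standard_table(x), right = FALSE, row.names = FALSE)
  invisible(x)
}

#' @export
summary.soc_standard <- function(object, ...) {
  rows <- do.call(rbind, lapply(object$oars, function(f) {
    do.call(rbind, lapply(names(f$indexes), function(ix) {
      lv <- f$indexes[[ix]]$levels
      data.frame(oar = f$oar, index = ix, kind = f$distribution_kind,
                 level = lv$level, n = lv$n, min = lv$min, max = lv$max,
                 mean = lv$mean, mode = lv$mode,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  structure(rows, class = c("summary.soc_standard", "data.frame"))
}

#' @export
print.summary.soc_standard <- function(x, ...) {
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.soc_standard <- function(x, ...) {
  as.data.frame(unclass(summary(x)), stringsAsFactors = FALSE)
}

fmt_num <- function(x) {
  format(round(x, 4), trim = TRUE, scientific = FALSE)
}

render_entry <- function(row) {
  if (row$mode == "mean") return(fmt_num(row$mean))
  if (row$mode == "undefined") return("undefined")
  if (is.infinite(row$hi)) return(paste0(">= ", fmt_num(row$lo)))
  paste0(fmt_num(row$lo), "-", fmt_num(row$hi))
}

#' Render SOC standards as a per-organ table
#'
#' One row per organ, one column per index x level; intervals rendered as
#' `"a-b"`, half-bounded intervals as `">= a"`, mean-based entries as bare
#' numbers, levels with no cases as `"-"`. Organs are ordered by descending
#' mean value of the first index (descending mean DSC in the default fit),
#' ties broken by name.
#'
#' @param x a [soc_standard()] fit.
#' @param levels which level columns to render; defaults to 1 up to the
#'   highest observed level (at least 3).
#' @return A character data frame.
#' @export
format_standard_table <- function(x, levels = NULL) {
  stopifnot(inherits(x, "soc_standard"))
  max_obs <- max(vapply(x$oars, function(f)
    max(f$indexes[[1]]$levels$level), numeric(1)))
  if (is.null(levels)) levels <- seq_len(max(3, max_obs))
  ord <- order(-vapply(x$oars, function(f) f$mean_index[[1]], numeric(1)),
               vapply(x$oars, function(f) f$oar, character(1)))
  rows <- lapply(x$oars[ord], function(f) {
    cells <- lapply(x$indexes, function(ix) {
      lv <- f$indexes[[ix]]$levels
      vapply(levels, function(l) {
        i <- which(lv$level == l)
        if (!length(i)) "-" else render_entry(lv[i, , drop = FALSE])
      }, character(1))
    })
    c(oar = f$oar, unlist(cells))
  })
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("oar", unlist(lapply(x$indexes, function(ix)
    paste0(ix, "_L", levels))))
  rownames(out) <- NULL
  out
}

#' Grade new cases by a derived SOC standard
#'
#' For organs whose standard is range-based, a value inside a level's
#' interval takes that level; a value in the unobserved gap between two
#' adjacent intervals takes the worse level (conservative: it triggers more
#' review, not less), and a value beyond the observed extremes takes the
#' nearest observed level on that side. For mean-based (or mixed) standards
#' the value takes the level of the nearest level representative (the mean
#' for mean-based entries, the interval for range-based ones), ties going
#' to the better level.
#'
#' @param object a [soc_standard()] fit.
#' @param newdata data frame with columns `oar` and the index named in
#'   `index`.
#' @param index which index to grade by (default `"dsc"`, the headline SOC
#'   index).
#' @param ... unused.
#' @return Integer vector of levels; `NA` where the organ has no derived
#'   standard or the entry is undefined.
#' @export
predict.soc_standard <- function(object, newdata, index = "dsc", ...) {
  stopifnot(is.data.frame(newdata), index %in% object$indexes,
            all(c("oar", index) %in% names(newdata)))
  eps <- 1e-12
  vapply(seq_len(nrow(newdata)), function(i) {
    o <- as.character(newdata$oar[i])
    v <- as.numeric(newdata[[index]][i])
    f <- object$oars[[o]]
    if (is.null(f)) return(NA_integer_)
    lv <- f$indexes[[index]]$levels
    if (any(lv$mode == "undefined")) return(NA_integer_)
    dir <- index_direction(index)
    if (all(lv$mode == "range")) {
      if (dir == "higher") {
        ok <- lv$level[lv$lo <= v + eps]
      } else {
        ok <- lv$level[lv$hi >= v - eps]
      }
      if (length(ok)) max(ok) else min(lv$level)
    } else {
      rep_dist <- vapply(seq_len(nrow(lv)), function(j) {
        if (lv$mode[j] == "mean") abs(v - lv$mean[j])
        else max(0, lv$lo[j] - v, v - lv$hi[j])
      }, numeric(1))
      best <- which(rep_dist <= min(rep_dist) + eps)
      max(lv$level[best])
    }
  }, integer(1))
}

#' Plot per-level index values behind a SOC standard
#'
#' Strip plot of the training cases' index values against their subjective
#' level for one organ, with the per-level means marked — the visual check
#' that adjacent levels separate (range-based) or at least order their
#' means (mean-based).
#'
#' @param x a [soc_standard()] fit.
#' @param oar organ to plot (default: the first).
#' @param index index to plot (default `"dsc"`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.soc_standard <- function(x, oar = names(x$oars)[1], index = "dsc", ...) {
  stopifnot(index %in% x$indexes, oar %in% names(x$oars))
  cases <- x$data[x$data$oar == oar, , drop = FALSE]
  v <- as.numeric(cases[[index]])
  l <- as.integer(cases$subjective_level)
  graphics::plot(jitter(l, amount = 0.08), v, xlab = "subjective level",
                 ylab = index, main = oar, xaxt = "n", pch = 16,
                 col = "steelblue", ...)
  graphics::axis(1, at = sort(unique(l)))
  lv <- x$oars[[oar]]$indexes[[index]]$levels
  graphics::points(lv$level, lv$mean, pch = 18, cex = 1.6, col = "darkorange")
  invisible(x)
}
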