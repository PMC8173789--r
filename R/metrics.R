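#' Geometric contour-comparison indexes
#'
#' Five indexes quantify the agreement between a manual reference contour
#' and an auto-segmented test contour, both given as voxel masks on a
#' common grid:
#'
#' * **DSC** — Dice similarity coefficient, `2|A n B| / (|A| + |B|)` by
#'   voxel counts, in \[0, 1\]; 1 for perfectly coincident contours.
#' * **dCMD** — Euclidean distance between the two centres of mass, cm.
#' * **dV** — absolute relative volume difference,
#'   `100 |V_test - V_ref| / V_ref`, percent. The manual reference volume is
#'   the denominator (it is the declared gold standard), so unlike the other
#'   indexes this one is not symmetric in its arguments.
#' * **MHD** — maximum Hausdorff distance between the surface point sets of
#'   the two masks, symmetrised over both directions, cm.
#' * **AHD** — average Hausdorff distance: the mean of the two directed mean
#'   nearest-neighbour surface distances, cm. Note other symmetrisations
#'   (max-of-means, pooled mean) exist in the literature; this package uses
#'   the average of the two directed means.
#'
#' Distances are computed in physical space (mm internally) between voxel
#' centres, honouring anisotropic spacing, and reported in cm.
#'
#' @param reference,test [voxel_mask()] objects on the same grid, both
#'   nonempty (see [validate_pair()]).
#' @return `dice()` a number in \[0,1\]; `centroid_distance()` cm;
#'   `volume_difference_pct()` percent; `hausdorff()` a named numeric
#'   `c(mhd_cm=, ahd_cm=)`.
#' @examples
#' p <- make_box_pair(size = 10, shift = c(5, 0, 0))
#' dice(p$reference, p$test)        # 0.5
#' centroid_distance(p$reference, p$test)  # 0.5 cm
#' @name geometry_metrics
NULL

#' @rdname geometry_metrics
#' @export
dice <- function(reference, test) {
  validate_pair(reference, test)
  a <- reference$grid
  b <- test$grid
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' @rdname geometry_metrics
#' @export
centroid_distance <- function(reference, test) {
  validate_pair(reference, test)
  d_mm <- sqrt(sum((center_of_mass(reference) - center_of_mass(test))^2))
  d_mm / 10
}

#' @rdname geometry_metrics
#' @export
volume_difference_pct <- function(reference, test) {
  validate_pair(reference, test)
  100 * abs(mask_volume(test) - mask_volume(reference)) / mask_volume(reference)
}

# Directed nearest-neighbour distances from each row of `a` to the point set
# `b` (both n x 3 matrices, mm). Squared distances are assembled blockwise
# from the BLAS identity |a-b|^2 = |a|^2 - 2 a.b + |b|^2; max.col picks the
# row minimum. Block size caps memory at ~8 MB per block.
directed_nn_dist <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  nb <- nrow(b)
  b2 <- rowSums(b * b)
  out <- numeric(nrow(a))
  block <- max(1L, as.integer(1e6 / nb))
  for (start in seq(1L, nrow(a), by = block)) {
    i <- start:min(start + block - 1L, nrow(a))
    d2 <- -2 * tcrossprod(a[i, , drop = FALSE], b)
    d2 <- sweep(d2, 2, b2, "+") + rowSums(a[i, , drop = FALSE]^2)
    j <- max.col(-d2, ties.method = "first")
    out[i] <- pmax(d2[cbind(seq_along(i), j)], 0)
  }
  sqrt(out)
}

#' @rdname geometry_metrics
#' @export
hausdorff <- function(reference, test) {
  validate_pair(reference, test)
  sa <- extract_surface(reference)
  sb <- extract_surface(test)
  dab <- directed_nn_dist(sa, sb)
  dba <- directed_nn_dist(sb, sa)
  c(mhd_cm = max(max(dab), max(dba)) / 10,
    ahd_cm = (mean(dab) + mean(dba)) / 2 / 10)
}

#' Compute the full index set for a mask pair
#'
#' Populates a `metric_set` with the five indexes of [geometry_metrics].
#'
#' @inheritParams geometry_metrics
#' @param patient_id,oar optional identifiers carried into tabular output.
#' @return A `metric_set` object (named list with `dsc`, `cmd_cm`, `dv_pct`,
#'   `mhd_cm`, `ahd_cm`, plus any identifiers).
#' @export
compute_metric_set <- function(reference, test, patient_id = NA_character_,
                               oar = NA_character_) {
  validate_pair(reference, test)
  hd <- hausdorff(reference, test)
  metric_set(dsc = dice(reference, test),
             cmd_cm = centroid_distance(reference, test),
             dv_pct = volume_difference_pct(reference, test),
             mhd_cm = unname(hd["mhd_cm"]),
             ahd_cm = unname(hd["ahd_cm"]),
             patient_id = patient_id, oar = oar)
}

#' Construct a metric set
#'
#' Container for the five geometric indexes of one reference/test pair.
#' Enforces the defining invariants: DSC in \[0,1\], all distances
#' nonnegative, AHD <= MHD.
#'
#' @param dsc Dice similarity coefficient.
#' @param cmd_cm centre-of-mass distance, cm.
#' @param dv_pct absolute relative volume difference, percent.
#' @param mhd_cm maximum Hausdorff distance, cm.
#' @param ahd_cm average Hausdorff distance, cm.
#' @param patient_id,oar optional identifiers.
#' @return A `metric_set` object.
#' @export
metric_set <- function(dsc, cmd_cm, dv_pct, mhd_cm, ahd_cm,
                       patient_id = NA_character_, oar = NA_character_) {
  vals <- c(dsc = dsc, cmd_cm = cmd_cm, dv_pct = dv_pct,
            mhd_cm = mhd_cm, ahd_cm = ahd_cm)
  if (anyNA(vals)) stop("metric values must not be NA", call. = FALSE)
  if (dsc < 0 || dsc > 1) stop("dsc must be in [0, 1]", call. = FALSE)
  if (any(vals[-1] < 0)) stop("distance/volume indexes must be >= 0", call. = FALSE)
  if (ahd_cm > mhd_cm + 1e-12) {
    stop("ahd_cm must not exceed mhd_cm", call. = FALSE)
  }
  structure(list(dsc = dsc, cmd_cm = cmd_cm, dv_pct = dv_pct,
                 mhd_cm = mhd_cm, ahd_cm = ahd_cm,
                 patient_id = patient_id, oar = oar),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  hdr <- if (!is.na(x$oar)) paste0(" ", x$oar) else ""
  cat(sprintf("<metric_set%s> DSC %.4f | dCMD %.2f cm | dV %.1f%% | MHD %.2f cm | AHD %.2f cm\n",
              hdr, x$dsc, x$cmd_cm, x$dv_pct, x$mhd_cm, x$ahd_cm))
  invisible(x)
}

#' @export
as.data.frame.metric_set <- function(x, ...) {
  data.frame(patient_id = x$patient_id, oar = x$oar, dsc = x$dsc,
             cmd_cm = x$cmd_cm, dv_pct = x$dv_pct, mhd_cm = x$mhd_cm,
             ahd_cm = x$ahd_cm, stringsAsFactors = FALSE)
}

metric_names <- function() c("dsc", "cmd_cm", "dv_pct", "mhd_cm", "ahd_cm")
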