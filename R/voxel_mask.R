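#' Construct a 3D voxel mask
#'
#' A `voxel_mask` is the elementary unit all contour-comparison metrics
#' consume: a 3D logical occupancy grid together with the physical voxel
#' size per axis and the physical coordinate of the centre of voxel
#' `(1,1,1)`. Axes are ordered x, y, z; the third axis is conventionally
#' the cranio-caudal (axial slice) direction. All physical quantities are
#' millimetres; distances are converted to centimetres only at reporting
#' boundaries.
#'
#' @param grid logical (or coercible 0/1 numeric) 3D array.
#' @param spacing numeric length-3, physical voxel size in mm per axis;
#'   strictly positive.
#' @param origin numeric length-3, physical coordinate (mm) of the centre
#'   of the first voxel. Default `c(0, 0, 0)`.
#' @param id optional character identifier carried into surface point sets.
#'
#' @return An object of class `voxel_mask`: a list with elements `grid`,
#'   `spacing`, `origin`, `id`.
#' @examples
#' g <- array(FALSE, c(8, 8, 8)); g[3:6, 3:6, 3:6] <- TRUE
#' m <- voxel_mask(g, spacing = c(1, 1, 3))
#' mask_volume(m)  # 64 voxels x 3 mm^3
#' @export
voxel_mask <- function(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       id = NULL) {
  if (is.numeric(grid)) {
    grid <- grid > 0.5
  }
  if (!is.logical(grid) || length(dim(grid)) != 3L) {
    stop("`grid` must be a 3D logical array", call. = FALSE)
  }
  if (anyNA(grid)) stop("`grid` contains NA", call. = FALSE)
  if (any(dim(grid) < 1L)) stop("all grid dimensions must be >= 1", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0)) {
    stop("`spacing` must be three strictly positive values (mm)", call. = FALSE)
  }
  if (length(origin) != 3L || anyNA(origin)) {
    stop("`origin` must be three finite values (mm)", call. = FALSE)
  }
  structure(list(grid = grid, spacing = spacing, origin = origin, id = id),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<voxel_mask%s> %dx%dx%d voxels, spacing %s mm, %d foreground (%.1f mm^3)\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              d[1], d[2], d[3],
              paste(format(x$spacing, trim = TRUE), collapse = "x"),
              sum(x$grid), mask_volume(x)))
  invisible(x)
}

is_voxel_mask <- function(x) inherits(x, "voxel_mask")

#' Number of foreground voxels and physical volume
#'
#' @param mask a [voxel_mask()].
#' @return `mask_volume` returns the physical volume in mm^3 (0 iff the mask
#'   is empty); `mask_count` the number of foreground voxels.
#' @export
mask_volume <- function(mask) {
  stopifnot(is_voxel_mask(mask))
  sum(mask$grid) * prod(mask$spacing)
}

#' @rdname mask_volume
#' @export
mask_count <- function(mask) {
  stopifnot(is_voxel_mask(mask))
  sum(mask$grid)
}

is_empty_mask <- function(mask) !any(mask$grid)

stop_empty <- function(which = "mask") {
  stop(sprintf("empty-mask error: %s has no foreground voxels; metrics on empty masks are undefined",
               which), call. = FALSE)
}

#' Validate a reference/test mask pair
#'
#' Contour-comparison metrics are only meaningful between masks living on
#' the same voxel grid. This checks that the two masks have identical grid
#' shape, voxel spacing (relative tolerance 1e-6) and origin, and that both
#' are nonempty.
#'
#' @param reference,test [voxel_mask()] objects; `reference` is the manual
#'   (gold standard) contour, `test` the auto-segmentation.
#' @return Invisibly, `list(reference=, test=)` if the pair is valid;
#'   otherwise an error naming the offending field.
#' @export
validate_pair <- function(reference, test) {
  stopifnot(is_voxel_mask(reference), is_voxel_mask(test))
  if (!identical(dim(reference$grid), dim(test$grid))) {
    stop(sprintf("geometry-mismatch error: grid shapes differ (%s vs %s)",
                 paste(dim(reference$grid), collapse = "x"),
                 paste(dim(test$grid), collapse = "x")), call. = FALSE)
  }
  rel <- abs(reference$spacing - test$spacing) /
    pmax(abs(reference$spacing), abs(test$spacing))
  if (any(rel > 1e-6)) {
    stop("geometry-mismatch error: voxel spacing differs between the masks",
         call. = FALSE)
  }
  tol <- 1e-6 * max(1, max(abs(reference$origin)), max(abs(test$origin)))
  if (any(abs(reference$origin - test$origin) > tol)) {
    stop("geometry-mismatch error: origin differs between the masks",
         call. = FALSE)
  }
  if (is_empty_mask(reference)) stop_empty("reference mask")
  if (is_empty_mask(test)) stop_empty("test mask")
  invisible(list(reference = reference, test = test))
}

# Voxel indices (1-based, n x 3 integer matrix) of foreground voxels.
mask_indices <- function(mask) {
  which(mask$grid, arr.ind = TRUE)
}

# Physical coordinates (mm) of voxel centres given 1-based indices.
index_to_mm <- function(idx, mask) {
  sweep(sweep(idx - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")
}

#' Extract the surface point set of a mask
#'
#' Surface voxels are foreground voxels with at least one background
#' 6-connected (face) neighbour; voxels on the grid boundary count as
#' surface (outside the grid is background). The returned points are the
#' physical centres of the surface voxels, in mm — the "point set of the
#' contour" that the Hausdorff distances operate on.
#'
#' @param mask a nonempty [voxel_mask()].
#' @return A `surface_points` object: a numeric matrix (n x 3, mm) with
#'   attribute `source_mask_id`.
#' @export
extract_surface <- function(mask) {
  stopifnot(is_voxel_mask(mask))
  if (is_empty_mask(mask)) stop_empty()
  g <- mask$grid
  d <- dim(g)
  surf <- array(FALSE, d)
  for (ax in 1:3) {
    n <- d[ax]
    # neighbour occupancy in the -ax and +ax directions, FALSE beyond the grid
    lo <- array(FALSE, d)
    hi <- array(FALSE, d)
    idx_all <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    if (n > 1) {
      src <- idx_all; src[[ax]] <- 1:(n - 1)
      dst <- idx_all; dst[[ax]] <- 2:n
      lo[dst[[1]], dst[[2]], dst[[3]]] <- g[src[[1]], src[[2]], src[[3]]]
      hi[src[[1]], src[[2]], src[[3]]] <- g[dst[[1]], dst[[2]], dst[[3]]]
    }
    surf <- surf | (g & !lo) | (g & !hi)
  }
  idx <- which(surf, arr.ind = TRUE)
  pts <- index_to_mm(idx, mask)
  structure(pts, source_mask_id = mask$id, class = c("surface_points", class(pts)))
}

#' Centre of mass of a mask
#'
#' Unweighted mean of foreground voxel centre coordinates in physical space.
#'
#' @param mask a nonempty [voxel_mask()].
#' @return Numeric length-3, mm.
#' @export
center_of_mass <- function(mask) {
  stopifnot(is_voxel_mask(mask))
  if (is_empty_mask(mask)) stop_empty()
  unname(colMeans(index_to_mm(mask_indices(mask), mask)))
}

#' Count occupied slices along an axis
#'
#' Number of planes along `axis` containing at least one foreground voxel.
#' Defaults to the third (axial) axis, the CT slice direction. Supports the
#' subjective grading path when masks rather than slice counts are supplied.
#'
#' @param mask a [voxel_mask()] (may be empty; an empty mask has 0 slices).
#' @param axis 1, 2 or 3, or one of `"x"`, `"y"`, `"z"`.
#' @return Integer slice count.
#' @export
slice_count <- function(mask, axis = 3L) {
  stopifnot(is_voxel_mask(mask))
  if (is.character(axis)) {
    axis <- match(tolower(axis), c("x", "y", "z"))
  }
  if (is.na(axis) || !axis %in% 1:3) {
    stop("`axis` must be 1, 2, 3 or one of \"x\", \"y\", \"z\"", call. = FALSE)
  }
  sum(apply(mask$grid, axis, any))
}

#' Read a binary mask from a NIfTI file
#'
#' Voxels with value > 0.5 are foreground. Spacing is taken from the header
#' pixdim; the origin from the translation column of the xform. Affines with
#' rotation or shear beyond axis permutations and flips are rejected: the
#' mask model has no oblique-grid support, and silently dropping an oblique
#' rotation would corrupt all physical distances.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param id optional identifier (defaults to the file name).
#' @return A [voxel_mask()].
#' @export
read_mask_nifti <- function(path, id = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) {
    arr <- arr[, , , 1, drop = TRUE]
  }
  if (length(dim(arr)) != 3L) {
    stop("NIfTI image is not a 3D volume: ", path, call. = FALSE)
  }
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  # each row/column must contain exactly one nonzero entry (permutation + flip)
  tolr <- 1e-4 * max(abs(rot))
  nz <- abs(rot) > tolr
  if (any(rowSums(nz) != 1L) || any(colSums(nz) != 1L)) {
    stop("NIfTI affine has rotation/shear beyond axis permutation and flips; ",
         "resample the mask to an axis-aligned grid first: ", path,
         call. = FALSE)
  }
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- xf[1:3, 4]
  voxel_mask(arr > 0.5, spacing = spacing, origin = origin,
             id = if (is.null(id)) basename(path) else id)
}

#' Write a mask to a NIfTI file
#'
#' Writes the occupancy grid as uint8 with the mask's spacing in the header.
#'
#' @param mask a [voxel_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(mask, path) {
  stopifnot(is_voxel_mask(mask))
  arr <- array(as.integer(mask$grid), dim(mask$grid))
  img <- RNifti::asNifti(arr, datatype = "uint8",
                         reference = list(pixdim = c(-1, mask$spacing, 0, 0, 0, 0)))
  RNifti::writeNifti(img, path)
  invisible(path)
}
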