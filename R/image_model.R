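#' @importFrom stats rnorm runif sd var setNames dnorm pt qt
#' @importFrom utils read.csv write.csv
NULL

#' Construct a 2-D scalar image slice
#'
#' A `scalar_slice` is the working canvas of the pipeline: a single 2-D
#' scalar field (an SUV map, dimensionless, or an ADC map in mm^2/s) on a
#' physical voxel grid. Voxel indices are 0-based in the physical-coordinate
#' convention: the center of voxel `(i, j)` sits at
#' `origin + (i * spacing[1], j * spacing[2])` mm.
#'
#' @param values Numeric matrix (rows x cols). Non-finite entries are
#'   permitted and treated as invalid voxels by downstream consumers.
#' @param spacing Numeric length-2, (row, col) voxel size in mm; both > 0.
#' @param origin Numeric length-2, physical coordinate (mm) of the center of
#'   voxel (0, 0).
#' @return An object of class `scalar_slice`.
#' @export
scalar_slice <- function(values, spacing = c(2, 2), origin = c(0, 0)) {
  values <- as.matrix(values)
  if (length(values) == 0L) stop("values must be a non-empty matrix")
  if (!is.numeric(values)) stop("values must be numeric")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be two positive finite numbers (mm)")
  if (length(origin) != 2L || any(!is.finite(origin)))
    stop("origin must be two finite numbers (mm)")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "scalar_slice")
}

#' @export
print.scalar_slice <- function(x, ...) {
  cat(sprintf("<scalar_slice> %d x %d voxels, spacing %g x %g mm, origin (%g, %g) mm\n",
              nrow(x$values), ncol(x$values), x$spacing[1], x$spacing[2],
              x$origin[1], x$origin[2]))
  rng <- range(x$values[is.finite(x$values)])
  cat(sprintf("  value range: [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Construct a 2-D binary mask
#'
#' Boolean lesion mask on the same grid convention as [scalar_slice()].
#' Masks may be empty (all `FALSE`), which happens in practice when a fixed
#' SUV threshold exceeds every voxel of a treated lesion.
#'
#' @param mask Logical matrix (or coercible 0/1 numeric matrix).
#' @inheritParams scalar_slice
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(mask, spacing = c(2, 2), origin = c(0, 0)) {
  mask <- as.matrix(mask)
  if (length(mask) == 0L) stop("mask must be non-empty")
  if (is.numeric(mask)) {
    if (!all(mask %in% c(0, 1))) stop("numeric mask must contain only 0/1")
    mask <- array(mask == 1, dim = dim(mask))
  }
  if (!is.logical(mask)) stop("mask must be logical or 0/1 numeric")
  if (anyNA(mask)) stop("mask must not contain NA")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 2L || any(spacing <= 0)) stop("spacing must be positive")
  structure(list(mask = mask, spacing = spacing, origin = origin),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d voxels, %d in mask, spacing %g x %g mm\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              x$spacing[1], x$spacing[2]))
  invisible(x)
}

#' Construct a multi-b-value DWI signal stack
#'
#' Aligned 2-D diffusion-weighted signal slices indexed by b-value
#' (s/mm^2), the input to ADC fitting. The acquisition this models uses
#' b = 0, 50, 120, 200, 400, 700 s/mm^2.
#'
#' @param signals List of numeric matrices, one per b-value, all the same
#'   shape, signals >= 0.
#' @param bvalues Numeric vector of non-negative b-values (s/mm^2), strictly
#'   increasing, same length as `signals`.
#' @inheritParams scalar_slice
#' @return An object of class `dwi_stack`.
#' @export
dwi_stack <- function(signals, bvalues, spacing = c(2, 2), origin = c(0, 0)) {
  if (!is.list(signals) || length(signals) == 0L)
    stop("signals must be a non-empty list of matrices")
  bvalues <- as.numeric(bvalues)
  if (length(signals) != length(bvalues))
    stop("signals and bvalues must have equal length")
  if (any(bvalues < 0) || any(diff(bvalues) <= 0))
    stop("bvalues must be non-negative and strictly increasing")
  signals <- lapply(signals, as.matrix)
  d <- dim(signals[[1]])
  for (s in signals) {
    if (!identical(dim(s), d)) stop("all signal slices must share one shape")
    if (any(s[is.finite(s)] < 0)) stop("signals must be non-negative")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(spacing <= 0)) stop("spacing must be positive")
  structure(list(signals = signals, bvalues = bvalues,
                 spacing = spacing, origin = as.numeric(origin)),
            class = "dwi_stack")
}

#' Construct a rectangular crop box
#'
#' Half-open voxel-index box `[row_min, row_max) x [col_min, col_max)`,
#' 0-based, delimiting the manually identified lesion region on the SUV map.
#'
#' @param row_min,row_max,col_min,col_max Integer voxel indices with
#'   `0 <= min < max`.
#' @return An object of class `crop_box`.
#' @export
crop_box <- function(row_min, row_max, col_min, col_max) {
  b <- c(row_min = row_min, row_max = row_max,
         col_min = col_min, col_max = col_max)
  if (any(b != round(b))) stop("crop box indices must be integers")
  b <- setNames(as.integer(round(b)), names(b))
  if (b[1] < 0L || b[3] < 0L) stop("crop box indices must be >= 0")
  if (b[1] >= b[2] || b[3] >= b[4])
    stop("crop box must satisfy min < max on both axes (half-open)")
  structure(as.list(b), class = "crop_box")
}

grid_compatible <- function(a, b, tol = 1e-6) {
  da <- if (!is.null(a$values)) dim(a$values) else dim(a$mask)
  db <- if (!is.null(b$values)) dim(b$values) else dim(b$mask)
  identical(da, db) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

stop_if_grid_mismatch <- function(a, b) {
  if (!grid_compatible(a, b))
    stop("inputs are not on the same voxel grid (shape/spacing/origin)")
  invisible(TRUE)
}

#' Physical coordinates of voxel centers
#'
#' @param x A `scalar_slice` or `binary_mask`.
#' @param i,j 0-based row and column voxel indices (vectorized).
#' @return A two-column matrix of (x, y) physical positions in mm.
#' @export
voxel_coords <- function(x, i, j) {
  cbind(x = x$origin[1] + i * x$spacing[1],
        y = x$origin[2] + j * x$spacing[2])
}

#' Crop a slice to a rectangular lesion region
#'
#' Returns the sub-image covered by the half-open box, with the origin
#' shifted so physical coordinates of retained voxels are unchanged.
#'
#' @param slice A [scalar_slice()].
#' @param box A [crop_box()], fully inside the slice extent.
#' @return A `scalar_slice` of shape
#'   `(row_max - row_min) x (col_max - col_min)`.
#' @export
crop_slice <- function(slice, box) {
  stopifnot(inherits(slice, "scalar_slice"), inherits(box, "crop_box"))
  d <- dim(slice$values)
  if (box$row_max > d[1] || box$col_max > d[2])
    stop("crop box extends outside the slice")
  vals <- slice$values[(box$row_min + 1L):box$row_max,
                       (box$col_min + 1L):box$col_max, drop = FALSE]
  scalar_slice(vals, spacing = slice$spacing,
               origin = slice$origin +
                 c(box$row_min, box$col_min) * slice$spacing)
}

#' Embed a cropped mask back into full-grid coordinates
#'
#' @param mask A `binary_mask` defined on the cropped grid.
#' @param box The [crop_box()] used to produce the crop.
#' @param shape Integer length-2, full-grid (rows, cols).
#' @param origin Physical origin of the full grid (mm).
#' @return A `binary_mask` on the full grid, `FALSE` outside the box.
#' @export
uncrop_mask <- function(mask, box, shape, origin = c(0, 0)) {
  stopifnot(inherits(mask, "binary_mask"), inherits(box, "crop_box"))
  d <- dim(mask$mask)
  if (d[1] != box$row_max - box$row_min || d[2] != box$col_max - box$col_min)
    stop("mask shape does not match crop box")
  full <- matrix(FALSE, shape[1], shape[2])
  full[(box$row_min + 1L):box$row_max, (box$col_min + 1L):box$col_max] <-
    mask$mask
  binary_mask(full, spacing = mask$spacing, origin = origin)
}

slice_to_nifti <- function(values, spacing, origin) {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- spacing
  m <- diag(4)
  m[1, 1] <- spacing[1]
  m[2, 2] <- spacing[2]
  m[1:2, 4] <- origin
  RNifti::`sform<-`(img, structure(m, code = 2L))
}

nifti_geometry <- function(img) {
  pd <- RNifti::pixdim(img)[1:2]
  if (any(!is.finite(pd)) || any(pd <= 0))
    stop("NIfTI header has non-positive voxel spacing")
  x <- RNifti::xform(img)
  list(spacing = pd, origin = as.numeric(x[1:2, 4]))
}

#' Read a scalar slice from a NIfTI file
#'
#' @param path Path to a `.nii`/`.nii.gz` file containing a 2-D image, or a
#'   3-D image together with `slice_index`.
#' @param slice_index 0-based index of the slice to extract from a 3-D
#'   image; must be `NULL` for 2-D images.
#' @return A [scalar_slice()] with spacing and origin from the header.
#' @export
read_slice <- function(path, slice_index = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI image: ", path))
  a <- as.array(img)
  nd <- length(dim(a))
  if (nd == 3L) {
    if (is.null(slice_index))
      stop("3-D image requires slice_index")
    if (slice_index < 0 || slice_index >= dim(a)[3])
      stop("slice_index out of range")
    a <- a[, , slice_index + 1L, drop = TRUE]
  } else if (nd != 2L) {
    stop("expected a 2-D or 3-D image, got ", nd, " dimensions")
  }
  a <- matrix(as.numeric(a), nrow(a))  # drop NIfTI attributes
  g <- nifti_geometry(img)
  scalar_slice(a, spacing = g$spacing, origin = g$origin)
}

#' Write a scalar slice to a NIfTI file
#'
#' @param slice A [scalar_slice()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_slice <- function(slice, path) {
  stopifnot(inherits(slice, "scalar_slice"))
  img <- slice_to_nifti(slice$values, slice$spacing, slice$origin)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from a 0/1 NIfTI file
#'
#' @inheritParams read_slice
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, slice_index = NULL) {
  sl <- read_slice(path, slice_index)
  binary_mask(sl$values != 0, spacing = sl$spacing, origin = sl$origin)
}

#' Write a binary mask as an unsigned 8-bit 0/1 NIfTI file
#'
#' @param mask A [binary_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  img <- slice_to_nifti(array(as.integer(mask$mask), dim = dim(mask$mask)),
                        mask$spacing, mask$origin)
  img <- RNifti::asNifti(img, datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read b-values from a one-column CSV
#'
#' @param path CSV with a single column of b-values (s/mm^2).
#' @return Numeric vector of b-values.
#' @export
read_bvalues <- function(path) {
  tab <- read.csv(path)
  as.numeric(tab[[1]])
}

#' Read a crop box from CSV
#'
#' Expects one row with columns `row_min,row_max,col_min,col_max`.
#'
#' @param path CSV path.
#' @return A [crop_box()].
#' @export
read_crop_box <- function(path) {
  tab <- read.csv(path)
  need <- c("row_min", "row_max", "col_min", "col_max")
  if (!all(need %in% names(tab))) stop("crop CSV must have columns ",
                                       paste(need, collapse = ","))
  crop_box(tab$row_min[1], tab$row_max[1], tab$col_min[1], tab$col_max[1])
}

#' Write a crop box to CSV
#' @param box A [crop_box()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_crop_box <- function(box, path) {
  stopifnot(inherits(box, "crop_box"))
  write.csv(data.frame(row_min = box$row_min, row_max = box$row_max,
                       col_min = box$col_min, col_max = box$col_max),
            path, row.names = FALSE)
  invisible(path)
}
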