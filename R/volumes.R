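#' 3D image volume
#'
#' Lightweight carrier for a 3D scalar grid with isotropic-or-not voxel
#' spacing, used for synthetic MPRage-like and FLAIR-like channels.
#' World coordinates are \code{voxel_size * (index - 1) + origin} (mm).
#'
#' @param data numeric 3D array.
#' @param voxel_size length-3 numeric, mm per axis.
#' @param origin length-3 numeric, mm position of voxel (1,1,1).
#' @return an object of class \code{image_volume}.
#' @export
image_volume <- function(data, voxel_size = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            length(voxel_size) == 3L, all(voxel_size > 0),
            length(origin) == 3L)
  structure(list(data = data,
                 voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = "x"),
      " voxels @ ", paste(signif(x$voxel_size, 4), collapse = "x"), " mm\n",
      sep = "")
  invisible(x)
}

#' Binary segmentation mask
#'
#' A 3D boolean grid aligned to an \code{\link{image_volume}}, representing
#' one tumor compartment: \code{"CV"} (contrast-enhancing volume) or
#' \code{"FV"} (FLAIR-hyperintense volume).
#'
#' @param grid logical 3D array.
#' @param voxel_size length-3 numeric, mm per axis.
#' @param compartment \code{"CV"}, \code{"FV"} or \code{"other"}.
#' @param origin length-3 numeric, mm position of voxel (1,1,1).
#' @return an object of class \code{binary_mask}.
#' @export
binary_mask <- function(grid, voxel_size = c(1, 1, 1),
                        compartment = c("CV", "FV", "other"),
                        origin = c(0, 0, 0)) {
  compartment <- match.arg(compartment)
  stopifnot(is.array(grid), length(dim(grid)) == 3L,
            length(voxel_size) == 3L, all(voxel_size > 0))
  storage.mode(grid) <- "logical"
  grid[is.na(grid)] <- FALSE
  structure(list(grid = grid,
                 voxel_size = as.numeric(voxel_size),
                 compartment = compartment,
                 origin = as.numeric(origin)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask:", x$compartment, "> ",
      paste(dim(x$grid), collapse = "x"), " voxels, ",
      format(mask_volume_ml(x), digits = 4), " ml\n", sep = "")
  invisible(x)
}

#' Mask volume in millilitres
#'
#' Volume readout behind every cohort table: exact voxel count times the
#' voxel volume in mm^3, divided by 1000.
#'
#' @param mask a \code{\link{binary_mask}}.
#' @return volume in ml (numeric scalar).
#' @examples
#' m <- binary_mask(array(TRUE, c(10, 10, 10)))
#' mask_volume_ml(m)  # 1 ml
#' @export
mask_volume_ml <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  n <- sum(mask$grid)
  n * prod(mask$voxel_size) / 1000
}

#' Manual mask correction
#'
#' Emulates rater correction of a semi-automated segmentation by adding and
#' erasing voxel sets: result is (mask U add) \\ erase. Identity when both
#' sets are empty; erasure wins where the sets overlap.
#'
#' @param mask a \code{\link{binary_mask}}.
#' @param add,erase logical arrays of the mask's shape, or integer matrices
#'   of voxel indices (one row per voxel), or NULL.
#' @return the corrected \code{binary_mask}.
#' @export
manual_edit <- function(mask, add = NULL, erase = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  g <- mask$grid
  g <- g | .voxel_set(add, dim(g))
  g <- g & !.voxel_set(erase, dim(g))
  binary_mask(g, mask$voxel_size, mask$compartment, mask$origin)
}

.voxel_set <- function(x, dims) {
  if (is.null(x)) return(array(FALSE, dims))
  if (is.array(x) && is.logical(x)) {
    if (!identical(dim(x), as.integer(dims)))
      stop("voxel set shape does not match the mask grid")
    return(x)
  }
  if (is.matrix(x) && ncol(x) == 3L) {
    if (any(x < 1) || any(x[, 1] > dims[1]) || any(x[, 2] > dims[2]) ||
        any(x[, 3] > dims[3]))
      stop("voxel indices outside the mask grid")
    out <- array(FALSE, dims)
    out[x] <- TRUE
    return(out)
  }
  stop("voxel sets must be logical arrays or n x 3 index matrices")
}

#' Write a volume or mask to NIfTI
#'
#' @param x an \code{image_volume} or \code{binary_mask}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return the path, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  dat <- if (inherits(x, "binary_mask")) x$grid + 0L else x$data
  attr(dat, "pixdim") <- x$voxel_size
  attr(dat, "pixunits") <- "mm"
  img <- RNifti::asNifti(dat, datatype = if (inherits(x, "binary_mask")) "uint8" else "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as an image volume or binary mask
#'
#' @param path NIfTI file path.
#' @param as \code{"image"} or \code{"mask"}; masks are thresholded at > 0.
#' @param compartment compartment label when reading a mask.
#' @return an \code{image_volume} or \code{binary_mask}.
#' @export
read_nifti_volume <- function(path, as = c("image", "mask"),
                              compartment = "other") {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  if (as == "image") image_volume(arr, vs)
  else binary_mask(arr > 0, vs, compartment)
}
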