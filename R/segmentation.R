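#' Seed contour for semi-automated segmentation
#'
#' The semi-automated workflow mirrors a two-plane brush tool: the rater
#' draws one 2D region on an axial slice and one on a coronal slice; the two
#' contours seed a 3D region-growing interpolation.
#'
#' @param plane \code{"axial"} (fixed z index) or \code{"coronal"} (fixed y).
#' @param slice_index 1-based voxel index of the slice.
#' @param region logical 2D matrix: the drawn region on that slice
#'   (axial: x by y; coronal: x by z).
#' @return an object of class \code{seed_contour}.
#' @export
seed_contour <- function(plane = c("axial", "coronal"), slice_index, region) {
  plane <- match.arg(plane)
  stopifnot(is.matrix(region), is.logical(region))
  if (!any(region)) stop("seed contour region is empty")
  if (slice_index < 1) stop("slice_index out of bounds")
  structure(list(plane = plane, slice_index = as.integer(slice_index),
                 region = region),
            class = "seed_contour")
}

# Embed a seed contour into a 3D logical array of the image's shape.
.seed_to_grid <- function(seed, dims) {
  g <- array(FALSE, dims)
  if (seed$plane == "axial") {
    if (seed$slice_index > dims[3]) stop("axial slice_index out of bounds")
    if (!identical(dim(seed$region), as.integer(dims[1:2])))
      stop("axial seed region must be nx x ny")
    g[, , seed$slice_index] <- seed$region
  } else {
    if (seed$slice_index > dims[2]) stop("coronal slice_index out of bounds")
    if (!identical(dim(seed$region), as.integer(dims[c(1, 3)])))
      stop("coronal seed region must be nx x nz")
    g[, seed$slice_index, ] <- seed$region
  }
  g
}

#' Semi-automated 3D segmentation from two seed contours
#'
#' Grows a 3D mask from two orthogonal 2D seed regions: the intensity band
#' is estimated from the seed voxels (mean +/- \code{tolerance_k} standard
#' deviations, inclusive bounds), the band is flooded by 6-connected
#' (face-adjacent) region growing from the union of the seeds, and fully
#' enclosed cavities are filled, approximating the "rough 3D
#' interpolation" step of commercial brush tools. The commercial
#' algorithm itself is proprietary; this is a documented, transparent
#' stand-in reproducing the workflow (two planes in, one 3D mask out), not
#' its voxel-for-voxel output.
#'
#' @param image an \code{\link{image_volume}}.
#' @param axial_seed,coronal_seed \code{\link{seed_contour}} objects.
#' @param tolerance_k band half-width in seed-intensity standard deviations.
#' @param max_iter cap on growth sweeps (safety; each sweep adds one voxel
#'   shell).
#' @param volume_cap_ml growth beyond this volume aborts with an error,
#'   signalling that the tolerance band leaked into background.
#' @param fill_holes fill fully enclosed cavities after growth (repairs
#'   interior voxels dropped by intensity noise without ever moving the
#'   outer boundary).
#' @param compartment compartment label for the returned mask.
#' @return a \code{\link{binary_mask}}.
#' @export
segment_semiauto <- function(image, axial_seed, coronal_seed,
                             tolerance_k = 2.5, max_iter = 500L,
                             volume_cap_ml = 500,
                             fill_holes = TRUE,
                             compartment = c("other", "CV", "FV")) {
  stopifnot(inherits(image, "image_volume"),
            inherits(axial_seed, "seed_contour"),
            inherits(coronal_seed, "seed_contour"))
  compartment <- match.arg(compartment)
  dims <- dim(image$data)
  seeds <- .seed_to_grid(axial_seed, dims) | .seed_to_grid(coronal_seed, dims)
  if (!any(seeds)) stop("seed contours are empty on this grid")
  vals <- image$data[seeds]
  m <- mean(vals)
  s <- stats::sd(vals)
  if (!is.finite(s) || s == 0) s <- 0  # uniform seed: exact-intensity band
  lo <- m - tolerance_k * s
  hi <- m + tolerance_k * s
  band <- image$data >= lo & image$data <= hi
  if (!all(band[seeds]))
    seeds <- seeds & band  # grow only from in-band seed voxels
  if (!any(seeds)) stop("no seed voxel lies inside its own intensity band")
  cap_vox <- volume_cap_ml * 1000 / prod(image$voxel_size)
  grown <- .flood6(seeds, band, max_iter = max_iter, cap = cap_vox)
  if (fill_holes) grown <- .fill_holes3d(grown)
  binary_mask(grown, image$voxel_size, compartment, image$origin)
}

# 6-connected flood fill by iterative frontier dilation, vectorised over the
# whole grid; each iteration advances the front by one voxel shell.
.flood6 <- function(seeds, band, max_iter = 500L, cap = Inf) {
  acc <- seeds & band
  frontier <- acc
  it <- 0L
  while (any(frontier) && it < max_iter) {
    cand <- .dilate6(frontier) & band & !acc
    if (!any(cand)) break
    acc <- acc | cand
    if (sum(acc) > cap)
      stop("region growing exceeded the volume cap; tolerance too loose")
    frontier <- cand
    it <- it + 1L
  }
  acc
}

# One-voxel 6-neighbourhood dilation via array shifts (no wraparound).
.dilate6 <- function(g) {
  d <- dim(g)
  out <- g
  out[-1, , ] <- out[-1, , ] | g[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | g[-1, , ]
  out[, -1, ] <- out[, -1, ] | g[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | g[, -1, ]
  out[, , -1] <- out[, , -1] | g[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | g[, , -1]
  out
}

.erode6 <- function(g) {
  !.dilate6(!g)
}

# Fill fully enclosed cavities: background components reachable from the
# grid border stay background, everything else becomes foreground.
.fill_holes3d <- function(g) {
  d <- dim(g)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  outside <- .flood6(border & !g, !g, max_iter = sum(d))
  g | !(g | outside)
}

#' Build seed contours from a reference mask
#'
#' Convenience emulation of the rater's two-plane input on phantoms: the
#' axial seed is the mask's slice through its centroid z (eroded in-plane by
#' one voxel where possible), the coronal seed its centroid-y slice.
#'
#' @param mask a \code{\link{binary_mask}} (e.g. phantom ground truth).
#' @return list with elements \code{axial} and \code{coronal}.
#' @export
seeds_from_mask <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"), any(mask$grid))
  idx <- which(mask$grid, arr.ind = TRUE)
  cz <- round(mean(idx[, 3]))
  cy <- round(mean(idx[, 2]))
  # snap to the nearest non-empty slice
  zs <- sort(unique(idx[, 3]))
  ys <- sort(unique(idx[, 2]))
  cz <- zs[which.min(abs(zs - cz))]
  cy <- ys[which.min(abs(ys - cy))]
  ax <- .erode2(mask$grid[, , cz])
  if (!any(ax)) ax <- mask$grid[, , cz]
  co <- .erode2(mask$grid[, cy, ])
  if (!any(co)) co <- mask$grid[, cy, ]
  list(axial = seed_contour("axial", cz, ax),
       coronal = seed_contour("coronal", cy, co))
}

.erode2 <- function(m) {
  d <- dim(m)
  out <- m
  sh <- function(g) {
    r <- g
    r[-1, ] <- r[-1, ] & g[-d[1], ]; r[-d[1], ] <- r[-d[1], ] & g[-1, ]
    r[, -1] <- r[, -1] & g[, -d[2]]; r[, -d[2]] <- r[, -d[2]] & g[, -1]
    r
  }
  sh(out)
}
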