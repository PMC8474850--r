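#' Binary bone occupancy volume
#'
#' The canonical bone representation used by the corridor search: a 3D
#' binary occupancy grid with isotropic-or-not voxel spacing and a scanner
#' space origin. Meshes and label volumes are converted into this form by
#' [read_bone_model()]. The grid is axis-aligned in scanner space; the
#' origin is the centre of voxel (1,1,1) (0-based index (0,0,0)).
#'
#' @param occupancy 3D array, nonzero/`TRUE` = bone.
#' @param spacing voxel spacing in mm: scalar or length-3 vector.
#' @param origin scanner coordinates (mm) of the first voxel centre.
#' @return an object of class `bone_model`.
#' @export
bone_model <- function(occupancy, spacing, origin = c(0, 0, 0)) {
  if (length(dim(occupancy)) != 3)
    stop("occupancy must be a 3D array")
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(length(spacing) == 3, all(spacing > 0), length(origin) == 3)
  occ <- array(as.integer(occupancy != 0), dim = dim(occupancy))
  if (!any(occ == 1L)) stop("bone model has no occupied voxel")
  structure(list(occupancy = occ,
                 spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "bone_model")
}

#' @export
print.bone_model <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf("Bone model: %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (mm): %.2f %.2f %.2f | occupied: %d (%.1f%%)\n",
              x$origin[1], x$origin[2], x$origin[3],
              sum(x$occupancy), 100 * mean(x$occupancy)))
  invisible(x)
}

# Scanner-space bounding box of the voxel grid (voxel centres).
model_bbox <- function(model) {
  d <- dim(model$occupancy)
  list(min = model$origin,
       max = model$origin + (d - 1) * model$spacing)
}

#' Occupied volume of a bone model
#'
#' @param model a [bone_model()].
#' @return occupied volume in mm^3 (voxel count times voxel volume).
#' @export
model_volume <- function(model) {
  sum(model$occupancy) * prod(model$spacing)
}
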