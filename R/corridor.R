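#' Ray-safety projection of a bone model
#'
#' Virtual-fluoroscopy projection: casts a bundle of parallel rays through
#' the occupancy grid along `direction` and classifies each projection
#' pixel as safe or unsafe. A ray is safe iff its bone intersection is a
#' single contiguous interval (no internal air gap longer than `gap_tol`)
#' of length at least `min_len` — the discrete analogue of the bright
#' "U-shaped" corridor cross-section seen when the pelvis is rendered
#' semi-transparent, whose dark rim is superimposed cortex.
#'
#' Occupancy is sampled along each ray at half the smallest voxel spacing
#' (nearest-voxel lookup); the projection-plane pixel pitch defaults to
#' the same value.
#'
#' @param model a [bone_model()].
#' @param direction ray direction (normalised internally).
#' @param roi optional `list(min =, max =)` scanner-space box restricting
#'   the projection; default the model's bounding box.
#' @param pixel_pitch projection pixel pitch, mm.
#' @param min_len minimum contiguous intra-osseous length, mm.
#' @param gap_tol largest tolerated internal gap, mm.
#' @return an object of class `safety_map`: logical matrix `safe`, depth
#'   matrices `entry`/`exit` (mm along `direction` from the plane through
#'   the box centre), the plane basis (`u`, `v`, `center`), pixel-centre
#'   offsets `us`/`vs`, and `pixel_pitch`.
#' @export
ray_safety_map <- function(model, direction, roi = NULL,
                           pixel_pitch = min(model$spacing) / 2,
                           min_len = 40, gap_tol = 0) {
  stopifnot(inherits(model, "bone_model"))
  d <- unitv(direction)
  bb <- model_bbox(model)
  if (!is.null(roi)) {
    lo <- pmax(roi$min, bb$min); hi <- pmin(roi$max, bb$max)
    if (any(lo > hi)) stop("roi does not intersect the bone model")
  } else {
    lo <- bb$min; hi <- bb$max
  }
  ctr <- (lo + hi) / 2
  bas <- plane_basis(d)
  corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                                   c(lo[3], hi[3])))
  rel <- sweep(corners, 2, ctr)
  pu <- rel %*% bas$u; pv <- rel %*% bas$v; pt <- rel %*% d
  step <- min(model$spacing) / 2
  half_u <- max(abs(pu)) + pixel_pitch
  half_v <- max(abs(pv)) + pixel_pitch
  us <- seq(-half_u, half_u, by = pixel_pitch)
  vs <- seq(-half_v, half_v, by = pixel_pitch)
  starts <- cbind(
    as.vector(ctr[1] + outer(us * bas$u[1], vs * bas$v[1], `+`)),
    as.vector(ctr[2] + outer(us * bas$u[2], vs * bas$v[2], `+`)),
    as.vector(ctr[3] + outer(us * bas$u[3], vs * bas$v[3], `+`))
  )
  prof <- ray_profiles_cpp(model$occupancy, dim(model$occupancy),
                           model$origin, model$spacing,
                           starts, d,
                           min(pt) - step, max(pt) + step, step,
                           min_len, gap_tol)
  n_u <- length(us)
  structure(list(safe = matrix(prof[, 1] > 0.5, n_u),
                 entry = matrix(prof[, 2], n_u),
                 exit = matrix(prof[, 3], n_u),
                 u = bas$u, v = bas$v, direction = d, center = ctr,
                 us = us, vs = vs, pixel_pitch = pixel_pitch,
                 min_len = min_len, gap_tol = gap_tol, step = step),
            class = "safety_map")
}

#' @export
print.safety_map <- function(x, ...) {
  cat(sprintf("Safety map: %d x %d px @ %.3g mm, %d safe (%.1f%%)\n",
              nrow(x$safe), ncol(x$safe), x$pixel_pitch, sum(x$safe),
              100 * mean(x$safe)))
  invisible(x)
}

#' Largest disc inscribed in the safe region of a safety map
#'
#' Finds the centre and radius of the largest disc fully contained in one
#' connected safe component — the projected cross-section of the maximal
#' corridor cylinder. Uses an exact Euclidean distance transform
#' (`EBImage::distmap`) on the safe mask padded with an unsafe border;
#' components come from `EBImage::bwlabel`. With a `seed_hint`, the search
#' is restricted to the component containing (or nearest to) the hint;
#' otherwise the component holding the globally maximal disc wins. Ties
#' are broken by proximity to the component centroid, then by row-major
#' pixel order.
#'
#' @param map a [ray_safety_map()].
#' @param seed_hint optional scanner-space point (mm) whose projection
#'   selects the safe component to search.
#' @return list: `center` (scanner point on the depth-0 plane), `center_uv`
#'   and `center_px` (in-plane coordinates), `radius` (mm; 0 with flag
#'   `"no_corridor"` when no safe pixel exists), `dist_px` (the raw
#'   distance-transform value at the centre, pixels; the continuous
#'   radius is `(dist_px - 0.5) * pixel_pitch`), `component`, `flag`.
#' @export
max_inscribed_disc <- function(map, seed_hint = NULL) {
  stopifnot(inherits(map, "safety_map"))
  if (!any(map$safe))
    return(list(center = NULL, center_uv = NULL, center_px = NULL,
                radius = 0, component = NA_integer_, flag = "no_corridor"))
  m <- map$safe * 1
  pad <- matrix(0, nrow(m) + 2, ncol(m) + 2)
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  dt <- EBImage::distmap(pad, metric = "euclidean")
  dt <- dt[2:(nrow(m) + 1), 2:(ncol(m) + 1), drop = FALSE]
  lab <- EBImage::bwlabel(m)

  comp <- NULL
  if (!is.null(seed_hint)) {
    rel <- seed_hint - map$center
    hu <- dot3(rel, map$u); hv <- dot3(rel, map$v)
    safe_idx <- which(map$safe, arr.ind = TRUE)
    du <- map$us[safe_idx[, 1]] - hu
    dv <- map$vs[safe_idx[, 2]] - hv
    nearest <- safe_idx[which.min(du^2 + dv^2), , drop = FALSE]
    comp <- lab[nearest[1, 1], nearest[1, 2]]
  } else {
    comp <- lab[which.max(dt * (lab > 0))]
  }
  in_comp <- lab == comp
  r_px <- max(dt[in_comp])
  cand <- which(in_comp & abs(dt - r_px) < 1e-9, arr.ind = TRUE)
  if (nrow(cand) > 1) {
    ci <- which(in_comp, arr.ind = TRUE)
    centroid <- colMeans(ci)
    d2 <- (cand[, 1] - centroid[1])^2 + (cand[, 2] - centroid[2])^2
    cand <- cand[order(d2, cand[, 1], cand[, 2]), , drop = FALSE]
  }
  px <- cand[1, ]
  uv <- c(map$us[px[1]], map$vs[px[2]])
  # dt is the distance to the nearest unsafe pixel *centre*; the
  # continuous inscribed radius inside the safe pixel region is half a
  # pixel less (a single safe pixel admits a half-pitch disc)
  list(center = map$center + uv[1] * map$u + uv[2] * map$v,
       center_uv = uv, center_px = as.integer(px),
       radius = max(0, r_px - 0.5) * map$pixel_pitch,
       dist_px = r_px,
       component = as.integer(comp), flag = "ok")
}

# Depth profile of the single ray through `point` along `direction`.
central_ray_profile <- function(model, point, direction, min_len = 40,
                                gap_tol = 0) {
  d <- unitv(direction)
  bb <- model_bbox(model)
  corners <- as.matrix(expand.grid(c(bb$min[1], bb$max[1]),
                                   c(bb$min[2], bb$max[2]),
                                   c(bb$min[3], bb$max[3])))
  pt <- sweep(corners, 2, point) %*% d
  step <- min(model$spacing) / 2
  prof <- ray_profiles_cpp(model$occupancy, dim(model$occupancy),
                           model$origin, model$spacing,
                           matrix(point, 1), d,
                           min(pt) - step, max(pt) + step, step,
                           min_len, gap_tol)
  list(safe = prof[1, 1] > 0.5, entry = prof[1, 2], exit = prof[1, 3],
       max_gap = prof[1, 4])
}

#' Verify that a cylinder lies entirely in bone
#'
#' The acceptance oracle of the corridor search: samples the full cylinder
#' (interior and boundary surface) at sub-voxel pitch and returns `TRUE`
#' iff every sample lies in bone. Emulates the manual check that a virtual
#' screw "does not break through the cortex" anywhere between its entry
#' and exit faces.
#'
#' @param model a [bone_model()].
#' @param axis cylinder axis (normalised internally).
#' @param center point on the axis (mm).
#' @param diameter cylinder diameter, mm.
#' @param length_span numeric length-2: depths (mm, along `axis`, relative
#'   to `center`) of the entry and exit faces.
#' @param oversample sampling-density multiplier (1 = half-voxel pitch).
#' @return logical.
#' @export
verify_cylinder <- function(model, axis, center, diameter, length_span,
                            oversample = 1) {
  stopifnot(inherits(model, "bone_model"), diameter >= 0,
            length(length_span) == 2, length_span[2] > length_span[1])
  a <- unitv(axis)
  bas <- plane_basis(a)
  h <- min(model$spacing) / 2 / oversample
  as.logical(cylinder_ok_cpp(model$occupancy, dim(model$occupancy),
                             model$origin, model$spacing,
                             center, a, bas$u, bas$v,
                             diameter / 2, length_span[1], length_span[2],
                             h, h))
}

#' Grow a virtual screw until it breaches the cortex
#'
#' The literal bedside procedure: place a 1 mm virtual screw on `axis`
#' through `center` and increase its diameter in increments of `step`
#' while [verify_cylinder()] still passes; the last passing diameter is
#' returned. Serves as an independent cross-check of the
#' distance-transform route in [max_inscribed_disc()].
#'
#' @param model a [bone_model()].
#' @param axis screw axis.
#' @param center point on the axis.
#' @param step diameter increment, mm.
#' @param start starting diameter, mm.
#' @param length_span optional entry/exit depths; default the central
#'   ray's intra-osseous interval (error if that ray is unsafe).
#' @param max_diameter search cap, mm.
#' @param min_len,gap_tol ray-safety parameters for the central ray.
#' @return largest verified diameter in mm (0 if even `start` fails).
#' @export
grow_cylinder <- function(model, axis, center, step = 0.1, start = 1,
                          length_span = NULL, max_diameter = 50,
                          min_len = 40, gap_tol = 0) {
  a <- unitv(axis)
  if (is.null(length_span)) {
    prof <- central_ray_profile(model, center, a, min_len, gap_tol)
    if (!prof$safe)
      stop("central ray is unsafe: no contiguous intra-osseous interval ",
           "of the required length through this centre")
    # inset covers the entry/exit depth uncertainty of nearest-voxel ray
    # marching (half a marching step plus half a voxel)
    inset <- 0.75 * min(model$spacing)
    length_span <- c(prof$entry + inset, prof$exit - inset)
  }
  if (!verify_cylinder(model, a, center, start, length_span)) return(0)
  d <- start
  while (d + step <= max_diameter &&
         verify_cylinder(model, a, center, d + step, length_span))
    d <- d + step
  d
}

#' Corridor result container
#' @keywords internal
corridor_result <- function(iad, ial, aip, axis, center_entry, center_exit,
                            azimuth_at_max, alpha, side, flag = "ok") {
  structure(list(iad = iad, ial = ial, aip = aip, axis = axis,
                 center_entry = center_entry, center_exit = center_exit,
                 azimuth_at_max = azimuth_at_max, alpha = alpha,
                 side = side, flag = flag),
            class = "corridor_result")
}

#' @export
print.corridor_result <- function(x, ...) {
  cat(sprintf("Corridor @ alpha=%g deg (%s): IAD %.2f mm, IAL %.2f mm, AIP %+.2f deg",
              x$alpha, x$side, x$iad, x$ial, x$aip))
  cat(sprintf(" | azimuth %.1f deg [%s]\n", x$azimuth_at_max, x$flag))
  invisible(x)
}

#' @export
as.data.frame.corridor_result <- function(x, ...) {
  data.frame(side = x$side, alpha = x$alpha, iad = x$iad, ial = x$ial,
             aip = x$aip, azimuth = x$azimuth_at_max, flag = x$flag,
             stringsAsFactors = FALSE)
}

# Projected corridor volume at one azimuth: the sum of intra-osseous
# lengths over all safe rays (safe-area weighted by depth). This is the
# quantitative form of the manual rule "turn the beam until the largest
# bright U-shaped area appears": it is maximal, and exactly symmetric for
# a symmetric channel, about the azimuth aligning the beam with the
# channel axis — whereas the inscribed-disc diameter is flat to first
# order within the channel's opening cone and cannot localize azimuth.
scan_objective <- function(model, frame, cfg, azimuth, pitch, roi) {
  dir <- fluoro_direction(frame, cfg$alpha, azimuth)
  map <- ray_safety_map(model, dir, roi = roi, pixel_pitch = pitch,
                        min_len = cfg$min_len, gap_tol = cfg$gap_tol)
  if (!any(map$safe)) return(0)
  sum((map$exit - map$entry)[map$safe])
}

# Full corridor measurement at one azimuth. The inscribed disc of the
# safety map is only an upper bound on the screw diameter: its rays are
# individually safe but need not share a common depth interval (e.g.
# bundles threading opposite ends of a biconical channel), so the disc
# estimate is confirmed against the cortical-breach oracle and backed off
# in half-pixel steps until it verifies.
azimuth_objective <- function(model, frame, cfg, azimuth, pitch, roi,
                              seed_hint) {
  dir <- fluoro_direction(frame, cfg$alpha, azimuth)
  map <- ray_safety_map(model, dir, roi = roi, pixel_pitch = pitch,
                        min_len = cfg$min_len, gap_tol = cfg$gap_tol)
  disc <- max_inscribed_disc(map, seed_hint = seed_hint)
  if (disc$radius <= 0)
    return(list(iad = 0, ial = 0, map = map, disc = disc, direction = dir,
                entry = NA_real_, exit = NA_real_, center_mid = NULL))
  px <- disc$center_px
  entry <- map$entry[px[1], px[2]]
  exit <- map$exit[px[1], px[2]]
  center_mid <- disc$center + (entry + exit) / 2 * dir
  # inset covers the entry/exit depth uncertainty of nearest-voxel ray
  # marching (half a marching step plus half a voxel)
  inset <- 0.75 * min(model$spacing)
  span <- c(entry + inset, exit - inset) - (entry + exit) / 2
  iad <- 2 * disc$radius
  while (iad > 0 && !verify_cylinder(model, dir, center_mid, iad, span))
    iad <- max(0, iad - map$pixel_pitch / 2)
  list(iad = iad, ial = exit - entry, map = map, disc = disc,
       direction = dir, entry = entry, exit = exit,
       center_mid = center_mid)
}

#' Find the maximal intra-osseous screw corridor at one fluoroscopic angle
#'
#' The measurement core. For one bone model, anatomical frame, side and
#' fluoroscopic angle `alpha`, scans the azimuth about the pelvis'
#' vertical axis over `+/- azimuth_range` in steps of `azimuth_step`,
#' builds the ray-safety projection at each azimuth, and takes the largest
#' inscribed safe disc — i.e. it turns the beam until the largest bright
#' corridor cross-section appears, then places the largest screw that
#' fits. The azimuth grid optimum is refined by golden-section search to
#' 0.1 degree. The reported diameter is the largest one that passes the
#' [verify_cylinder()] cortical-breach oracle (the disc estimate is
#' shrunk in half-pixel steps if discretization put it marginally over);
#' IAL is the intra-osseous length of the central ray, and AIP comes from
#' [axis_smp_angle()].
#'
#' With `restarts > 1` the whole search is repeated with a uniformly
#' jittered azimuth-grid origin and the largest diameter kept, emulating
#' repeated manual measurements that retain the maximum; requires a prior
#' `set.seed()` for reproducibility.
#'
#' @param model a [bone_model()].
#' @param frame an [app_from_landmarks()] frame.
#' @param cfg a [fluoro_config()].
#' @param roi optional scanner-space box restricting the projection.
#' @param seed_hint optional scanner point selecting the safe component.
#' @param restarts number of jittered repeats (default 1, deterministic).
#' @param refine_tol azimuth refinement tolerance, degrees.
#' @return a `corridor_result`: `iad`, `ial`, `aip`, `axis`,
#'   `center_entry`, `center_exit`, `azimuth_at_max`, `alpha`, `side`,
#'   `flag` (`"ok"` or `"no_corridor"` with `iad = 0`).
#' @export
optimize_corridor <- function(model, frame, cfg, roi = NULL,
                              seed_hint = NULL, restarts = 1,
                              refine_tol = 0.1) {
  stopifnot(inherits(cfg, "fluoro_config"))
  best <- NULL
  for (k in seq_len(restarts)) {
    off <- if (k == 1) 0 else runif(1, -cfg$azimuth_step / 2,
                                    cfg$azimuth_step / 2)
    res <- optimize_corridor_once(model, frame, cfg, roi, seed_hint,
                                  refine_tol, grid_offset = off)
    if (is.null(best) || res$iad > best$iad) best <- res
  }
  best
}

optimize_corridor_once <- function(model, frame, cfg, roi, seed_hint,
                                   refine_tol, grid_offset = 0) {
  pitch <- if (is.null(cfg$pixel_pitch)) min(model$spacing) / 2 else
    cfg$pixel_pitch
  azs <- seq(-cfg$azimuth_range, cfg$azimuth_range,
             by = cfg$azimuth_step) + grid_offset
  azs <- azs[abs(azs) <= cfg$azimuth_range + 1e-9]
  vol <- vapply(azs, function(az)
    scan_objective(model, frame, cfg, az, pitch, roi), numeric(1))
  if (all(vol == 0))
    return(corridor_result(0, 0, NA_real_, NULL, NULL, NULL, NA_real_,
                           cfg$alpha, cfg$side, flag = "no_corridor"))
  i_best <- which.max(vol)

  # contiguous near-maximal plateau containing the grid optimum
  keep <- vol >= cfg$plateau_frac * vol[i_best]
  lo_i <- i_best; while (lo_i > 1 && keep[lo_i - 1]) lo_i <- lo_i - 1
  hi_i <- i_best; while (hi_i < length(azs) && keep[hi_i + 1]) hi_i <- hi_i + 1

  if (azs[hi_i] - azs[lo_i] <= 2 * cfg$azimuth_step) {
    # sharp peak: golden-section refinement on the bracketing interval
    lo <- azs[max(1, i_best - 1)]; hi <- azs[min(length(azs), i_best + 1)]
    gr <- (sqrt(5) - 1) / 2
    x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
    f1 <- scan_objective(model, frame, cfg, x1, pitch, roi)
    f2 <- scan_objective(model, frame, cfg, x2, pitch, roi)
    while (hi - lo > refine_tol) {
      if (f1 >= f2) {
        hi <- x2; x2 <- x1; f2 <- f1
        x1 <- hi - gr * (hi - lo)
        f1 <- scan_objective(model, frame, cfg, x1, pitch, roi)
      } else {
        lo <- x1; x1 <- x2; f1 <- f2
        x2 <- lo + gr * (hi - lo)
        f2 <- scan_objective(model, frame, cfg, x2, pitch, roi)
      }
    }
    az_best <- (lo + hi) / 2
  } else {
    # flat-topped objective (beam inside the channel's opening cone): the
    # symmetric estimate of the channel azimuth is the plateau centre,
    # with the plateau edges located by linear interpolation of the
    # objective's threshold crossings for sub-grid resolution
    thr <- cfg$plateau_frac * vol[i_best]
    az_lo <- azs[lo_i]
    if (lo_i > 1 && vol[lo_i] > vol[lo_i - 1])
      az_lo <- azs[lo_i - 1] + (thr - vol[lo_i - 1]) /
        (vol[lo_i] - vol[lo_i - 1]) * (azs[lo_i] - azs[lo_i - 1])
    az_hi <- azs[hi_i]
    if (hi_i < length(azs) && vol[hi_i] > vol[hi_i + 1])
      az_hi <- azs[hi_i] + (vol[hi_i] - thr) /
        (vol[hi_i] - vol[hi_i + 1]) * (azs[hi_i + 1] - azs[hi_i])
    az_best <- (az_lo + az_hi) / 2
  }

  fin <- azimuth_objective(model, frame, cfg, az_best, pitch, roi,
                           seed_hint)
  if (fin$iad <= 0)
    return(corridor_result(0, 0, NA_real_, fin$direction, NULL, NULL,
                           az_best, cfg$alpha, cfg$side,
                           flag = "no_corridor"))
  dir <- fin$direction
  corridor_result(iad = fin$iad, ial = fin$ial,
                  aip = axis_smp_angle(dir, frame, cfg$side),
                  axis = dir,
                  center_entry = fin$disc$center + fin$entry * dir,
                  center_exit = fin$disc$center + fin$exit * dir,
                  azimuth_at_max = az_best, alpha = cfg$alpha,
                  side = cfg$side)
}
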