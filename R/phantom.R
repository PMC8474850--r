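#' Specification of a synthetic channel phantom
#'
#' Describes a synthetic bone solid containing a single intra-osseous
#' channel with analytically known maximal-cylinder geometry. The channel
#' emulates the infra-acetabular corridor's biconical pattern: a solid of
#' revolution whose radius is smallest at mid-length (the waist) and grows
#' linearly towards both ends. The channel is embedded in a surrounding
#' body (circular or square cross-section) from which it is separated by
#' an air moat; a transverse air notch cut through the body at mid-length
#' guarantees the channel is the only bony through-passage of corridor
#' length.
#'
#' For a bicone the maximal inscribed cylinder spanning the full length
#' has diameter equal to the waist diameter; for a cylinder it is the
#' channel itself.
#'
#' @param shape `"bicone"`, `"cylinder"` or `"slab_with_channel"` (square
#'   outer cross-section, same channel profile).
#' @param channel_waist_diameter waist diameter, mm.
#' @param channel_end_diameter diameter at both channel ends, mm
#'   (>= waist; forced equal to the waist for `"cylinder"`).
#' @param channel_length channel length along its axis, mm.
#' @param channel_elevation degrees; the fluoroscopic angle that aligns the
#'   viewing direction with the channel axis (the ground-truth ideal alpha).
#' @param channel_azimuth degrees; azimuth of the channel axis about the
#'   pelvis' vertical axis (the ground-truth ideal azimuth).
#' @param voxel_spacing isotropic voxel spacing, mm.
#' @param body_margin radial thickness of solid bone outside the moat, mm.
#' @param moat radial air gap between channel surface and body, mm.
#' @param notch_half_width axial half-width of the transverse air notch cut
#'   through the body at mid-length, mm.
#' @param breach optional `list(position_fraction =, depth =)`: carves a
#'   spherical cortical defect of radius `depth` centred on the channel
#'   surface at `position_fraction` (0-1) along the axis.
#' @param side hip the phantom stands in for (`"left"`/`"right"`), used
#'   only for the ground-truth AIP sign.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c("bicone", "cylinder", "slab_with_channel"),
                         channel_waist_diameter = 4,
                         channel_end_diameter = 12,
                         channel_length = 80,
                         channel_elevation = 15,
                         channel_azimuth = 0,
                         voxel_spacing = 0.5,
                         body_margin = 2.5,
                         moat = 3,
                         notch_half_width = 1.5,
                         breach = NULL,
                         side = c("left", "right")) {
  shape <- match.arg(shape)
  side <- match.arg(side)
  if (shape == "cylinder") channel_end_diameter <- channel_waist_diameter
  if (channel_end_diameter < channel_waist_diameter)
    stop("channel_end_diameter must be >= channel_waist_diameter")
  stopifnot(channel_waist_diameter > 0, channel_length > 0,
            voxel_spacing > 0, body_margin > 0, moat > 0,
            notch_half_width > 0)
  if (channel_waist_diameter < 3 * voxel_spacing)
    stop(sprintf(paste0("voxel spacing %.3g mm too coarse to resolve the ",
                        "%.3g mm waist (< 3 voxels across); refine the grid"),
                 voxel_spacing, channel_waist_diameter))
  if (!is.null(breach)) {
    stopifnot(is.list(breach),
              breach$position_fraction >= 0, breach$position_fraction <= 1,
              breach$depth > 0)
  }
  structure(list(shape = shape,
                 channel_waist_diameter = channel_waist_diameter,
                 channel_end_diameter = channel_end_diameter,
                 channel_length = channel_length,
                 channel_elevation = channel_elevation,
                 channel_azimuth = channel_azimuth,
                 voxel_spacing = voxel_spacing,
                 body_margin = body_margin,
                 moat = moat,
                 notch_half_width = notch_half_width,
                 breach = breach,
                 side = side),
            class = "phantom_spec")
}

# Channel radius profile at axial offset t (mm from mid-length).
channel_radius_at <- function(spec, t) {
  w <- spec$channel_waist_diameter / 2
  e <- spec$channel_end_diameter / 2
  w + abs(t) * (e - w) / (spec$channel_length / 2)
}

# Canonical phantom landmarks: scanner x = patient left-to-right,
# z = vertical (table up), y = anterior. The APP coincides with the x-z
# plane, so the APP-vs-table angle of the untransformed phantom is 0.
phantom_landmarks <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  tr <- function(p) as.numeric(rotation %*% p + translation)
  landmark_set(asis_left = tr(c(-120, 0, 150)),
               asis_right = tr(c(120, 0, 150)),
               pubic_symphysis = tr(c(0, 0, 0)),
               table_up = c(0, 0, 1))
}

#' Generate a channel phantom with analytic ground truth
#'
#' Voxelizes the solid described by a [phantom_spec()] together with a
#' synthetic landmark set (placed at known offsets so the APP and SMP are
#' exact by construction) and the analytic ground truth that the corridor
#' engine should recover.
#'
#' An optional rigid transform (applied jointly to solid and landmarks)
#' re-poses the whole scene; all frame-relative ground-truth quantities
#' are invariant under it.
#'
#' @param spec a [phantom_spec()].
#' @param rotation 3x3 rotation matrix applied to the scene.
#' @param translation length-3 translation (mm) applied to the scene.
#' @param pad extra empty margin around the solid, voxels.
#' @return list with components `model` ([bone_model()]), `landmarks`
#'   ([landmark_set()]) and `truth` (class `phantom_truth`: `true_axis`,
#'   `true_center`, `true_max_diameter`, `true_length`, `true_aip`,
#'   `true_elevation`, `true_azimuth`).
#' @examples
#' ph <- make_channel_phantom(phantom_spec(voxel_spacing = 1))
#' ph$truth$true_max_diameter
#' @export
make_channel_phantom <- function(spec, rotation = diag(3),
                                 translation = c(0, 0, 0), pad = 2) {
  stopifnot(inherits(spec, "phantom_spec"))
  lm <- phantom_landmarks(rotation, translation)
  frame <- app_from_landmarks(lm)

  # channel axis and centre in the (possibly re-posed) scanner frame
  axis <- fluoro_direction(frame, spec$channel_elevation, spec$channel_azimuth)
  center <- frame$origin + 30 * frame$ml_axis + 40 * frame$si_axis -
    10 * frame$ap_axis
  bas <- plane_basis(axis)
  u <- bas$u; v <- bas$v

  L <- spec$channel_length
  r_end <- spec$channel_end_diameter / 2
  r_out <- r_end + spec$moat + spec$body_margin
  sp <- spec$voxel_spacing

  # grid covering the body
  half <- c(L / 2, r_out, r_out)
  corners <- as.matrix(expand.grid(c(-1, 1) * half[1], c(-1, 1) * half[2],
                                   c(-1, 1) * half[3]))
  M <- cbind(axis, u, v)
  world <- t(M %*% t(corners)) + rep(center, each = 8)
  lo <- apply(world, 2, min) - pad * sp
  hi <- apply(world, 2, max) + pad * sp
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / sp)) + 1L)

  xs <- lo[1] + (seq_len(dims[1]) - 1) * sp
  ys <- lo[2] + (seq_len(dims[2]) - 1) * sp
  zs <- lo[3] + (seq_len(dims[3]) - 1) * sp
  px <- array(xs, dims)
  py <- array(rep(ys, each = dims[1]), dims)
  pz <- array(rep(zs, each = dims[1] * dims[2]), dims)

  rx <- px - center[1]; ry <- py - center[2]; rz <- pz - center[3]
  t_ax <- rx * axis[1] + ry * axis[2] + rz * axis[3]
  pu <- rx * u[1] + ry * u[2] + rz * u[3]
  pv <- rx * v[1] + ry * v[2] + rz * v[3]
  rm(px, py, pz, rx, ry, rz)
  rho2 <- pu^2 + pv^2

  rc <- channel_radius_at(spec, t_ax)
  in_span <- abs(t_ax) <= L / 2
  outer_ok <- if (spec$shape == "slab_with_channel") {
    pmax(abs(pu), abs(pv)) <= r_out
  } else {
    rho2 <= r_out^2
  }
  in_channel <- rho2 <= rc^2
  in_shell <- rho2 >= (rc + spec$moat)^2 &
    abs(t_ax) > spec$notch_half_width
  occ <- in_span & outer_ok & (in_channel | in_shell)

  if (!is.null(spec$breach)) {
    tb <- (spec$breach$position_fraction - 0.5) * L
    rb <- channel_radius_at(spec, tb)
    bc <- center + tb * axis + rb * u
    px <- array(xs, dims)
    py <- array(rep(ys, each = dims[1]), dims)
    pz <- array(rep(zs, each = dims[1] * dims[2]), dims)
    d2 <- (px - bc[1])^2 + (py - bc[2])^2 + (pz - bc[3])^2
    occ <- occ & (d2 > spec$breach$depth^2)
    rm(px, py, pz, d2)
  }

  model <- bone_model(occ, spacing = sp, origin = lo)
  truth <- structure(list(true_axis = axis,
                          true_center = center,
                          true_max_diameter = spec$channel_waist_diameter,
                          true_length = L,
                          true_aip = axis_smp_angle(axis, frame, spec$side),
                          true_elevation = spec$channel_elevation,
                          true_azimuth = spec$channel_azimuth),
                     class = "phantom_truth")
  list(model = model, landmarks = lm, truth = truth, spec = spec)
}

#' Analytic bone volume of an unbreached phantom
#'
#' Closed-form occupied volume of the solid described by a
#' [phantom_spec()] (ignoring any breach), used to check voxelization
#' convergence.
#'
#' @param spec a [phantom_spec()].
#' @return volume in mm^3.
#' @export
phantom_analytic_volume <- function(spec) {
  w <- spec$channel_waist_diameter / 2
  e <- spec$channel_end_diameter / 2
  L <- spec$channel_length
  m <- spec$moat
  r_out <- e + m + spec$body_margin
  q <- (e - w) / (L / 2)

  # channel: two frustums from waist to end radius
  v_channel <- 2 * pi * (L / 2) / 3 * (w^2 + w * e + e^2)

  # shell: outer area minus moat-boundary disc, integrated over |t| > notch
  a_out <- if (spec$shape == "slab_with_channel") (2 * r_out)^2 else pi * r_out^2
  int_rc_moat2 <- function(t0, t1) {
    # integral of (w + m + q t)^2 dt on [t0, t1], t >= 0
    c0 <- w + m
    if (q == 0) return(c0^2 * (t1 - t0))
    ((c0 + q * t1)^3 - (c0 + q * t0)^3) / (3 * q)
  }
  nh <- spec$notch_half_width
  v_shell <- 2 * (a_out * (L / 2 - nh) - pi * int_rc_moat2(nh, L / 2))
  v_channel + v_shell
}
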