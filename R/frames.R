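#' Landmark set defining the anterior pelvic plane
#'
#' Bundles the three bony landmarks that define the anterior pelvic plane
#' (APP): the left and right anterior superior iliac spines (ASIS) and the
#' pubic symphysis (PS), all in scanner coordinates (mm). An optional
#' `table_up` vector gives the normal of the CT table's horizontal plane
#' (scanner vertical by default) and is only used by [app_table_angle()].
#'
#' @param asis_left,asis_right,pubic_symphysis numeric 3-vectors, mm.
#' @param table_up unit normal of the table's horizontal plane.
#' @return an object of class `landmark_set`.
#' @examples
#' lm <- landmark_set(c(-120, 0, 150), c(120, 0, 150), c(0, 0, 0))
#' app_from_landmarks(lm)
#' @export
landmark_set <- function(asis_left, asis_right, pubic_symphysis,
                         table_up = c(0, 0, 1)) {
  pts <- list(asis_left = asis_left, asis_right = asis_right,
              pubic_symphysis = pubic_symphysis)
  for (nm in names(pts)) {
    p <- pts[[nm]]
    if (!is.numeric(p) || length(p) != 3 || any(!is.finite(p)))
      stop("landmark '", nm, "' must be a finite numeric 3-vector")
  }
  if (vnorm(asis_right - asis_left) < 1e-6)
    stop("degenerate landmarks: asis_left and asis_right coincide")
  if (vnorm(cross3(asis_right - asis_left, pubic_symphysis - asis_left)) < 1e-6)
    stop("degenerate landmarks: asis_left, asis_right and pubic_symphysis ",
         "are collinear")
  structure(list(asis_left = as.numeric(asis_left),
                 asis_right = as.numeric(asis_right),
                 pubic_symphysis = as.numeric(pubic_symphysis),
                 table_up = unitv(as.numeric(table_up))),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("Pelvic landmark set (mm, scanner frame)\n")
  for (nm in c("asis_left", "asis_right", "pubic_symphysis"))
    cat(sprintf("  %-16s %8.2f %8.2f %8.2f\n", nm,
                x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  invisible(x)
}

#' Anatomical frame from the APP landmarks
#'
#' Builds the anatomical reference frame used throughout the corridor
#' measurement. The anterior pelvic plane (APP) is the plane through both
#' ASIS and the pubic symphysis; the sagittal midline plane (SMP) passes
#' through the pubic symphysis and the ASIS midpoint and is perpendicular
#' to the APP.
#'
#' Axes (orthonormal, right-handed):
#' * `ml_axis` — medial-lateral, from left ASIS towards right ASIS
#'   (projected into the APP, where it already lies);
#' * `si_axis` — superior-inferior, the in-plane direction from the pubic
#'   symphysis towards the ASIS midpoint;
#' * `ap_axis` — anterior-posterior, `si x ml`, the APP normal pointing
#'   anteriorly; it is also the SMP's in-plane vertical complement.
#'
#' `smp_normal` equals `ml_axis`; `app_normal` equals `ap_axis`.
#'
#' @param lm a [landmark_set()].
#' @return an object of class `anatomical_frame` with fields `origin`
#'   (the pubic symphysis), `ml_axis`, `si_axis`, `ap_axis`, `app_normal`,
#'   `smp_normal`.
#' @export
app_from_landmarks <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  ml <- unitv(lm$asis_right - lm$asis_left)
  mid <- (lm$asis_left + lm$asis_right) / 2
  si_raw <- mid - lm$pubic_symphysis
  si <- unitv(si_raw - dot3(si_raw, ml) * ml)
  ap <- cross3(si, ml)
  structure(list(origin = lm$pubic_symphysis,
                 ml_axis = ml, si_axis = si, ap_axis = ap,
                 app_normal = ap, smp_normal = ml,
                 table_up = lm$table_up),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("Anatomical frame (APP/SMP)\n")
  cat(sprintf("  origin  %8.2f %8.2f %8.2f\n",
              x$origin[1], x$origin[2], x$origin[3]))
  for (nm in c("ml_axis", "si_axis", "ap_axis"))
    cat(sprintf("  %-7s %8.4f %8.4f %8.4f\n", nm,
                x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  invisible(x)
}

#' Tilt of the anterior pelvic plane relative to the CT table
#'
#' Returns the signed angle (degrees) between the APP and the table's
#' horizontal plane, the quantity used to judge whether the APP is a valid
#' supine reference plane. The convention is: 0 degrees when the APP is
#' perpendicular to the table plane (the neutral supine pose, where the
#' APP contains the table normal), positive when the pelvis is tilted
#' forward (the pubic symphysis carried anteriorly relative to the ASIS).
#' Numerically the angle is `asin(ap_axis . table_up)`.
#'
#' Published cohorts do not state the sign convention they report under, so
#' it is exposed: `sign_convention = "forward_negative"` flips the sign.
#'
#' @param lm a [landmark_set()] with a `table_up` vector.
#' @param sign_convention `"forward_positive"` (default) or
#'   `"forward_negative"`.
#' @return signed angle in degrees.
#' @export
app_table_angle <- function(lm, sign_convention = c("forward_positive",
                                                    "forward_negative")) {
  sign_convention <- match.arg(sign_convention)
  fr <- app_from_landmarks(lm)
  s <- dot3(fr$ap_axis, lm$table_up)
  ang <- rad2deg(asin(max(-1, min(1, s))))
  if (sign_convention == "forward_negative") ang <- -ang
  ang
}

#' Fluoroscopy configuration
#'
#' Parameters of one virtual-fluoroscopy measurement: the fluoroscopic
#' angle `alpha` (forward tilt of the viewing direction from the plain AP
#' view towards an inlet view, degrees), the azimuth scan about the
#' pelvis' vertical axis, and the measured side.
#'
#' @param alpha fluoroscopic angle, degrees, `0 <= alpha < 90`.
#' @param azimuth_range half-width of the azimuth scan, degrees.
#' @param azimuth_step azimuth grid step, degrees (> 0).
#' @param side `"left"` or `"right"` hip.
#' @param min_len minimum contiguous intra-osseous length (mm) for a ray to
#'   count as part of the corridor; excludes grazing trajectories.
#' @param gap_tol largest tolerated internal air gap along a ray, mm
#'   (0 = any cortical exit-and-re-entry disqualifies the ray).
#' @param pixel_pitch safety-map pixel pitch, mm; default half the smallest
#'   voxel spacing of the model being measured.
#' @param plateau_frac fraction of the maximal azimuth-scan objective that
#'   still counts as "on the plateau"; when the objective is flat around
#'   its optimum (a beam anywhere inside the channel's opening cone sees
#'   nearly the same corridor) the azimuth is taken as the plateau centre.
#' @return an object of class `fluoro_config`.
#' @export
fluoro_config <- function(alpha, azimuth_range = 30, azimuth_step = 1,
                          side = c("left", "right"), min_len = 40,
                          gap_tol = 0, pixel_pitch = NULL,
                          plateau_frac = 0.9) {
  side <- match.arg(side)
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha >= 0, alpha < 90,
            azimuth_step > 0, azimuth_range >= 0, min_len > 0, gap_tol >= 0,
            plateau_frac > 0, plateau_frac <= 1)
  structure(list(alpha = alpha, azimuth_range = azimuth_range,
                 azimuth_step = azimuth_step, side = side,
                 min_len = min_len, gap_tol = gap_tol,
                 pixel_pitch = pixel_pitch, plateau_frac = plateau_frac),
            class = "fluoro_config")
}

#' Virtual-fluoroscopy viewing direction
#'
#' The beam direction for a fluoroscopic angle `alpha` and azimuth: start
#' from the AP viewing direction `-ap_axis`, rotate by `alpha` about
#' `ml_axis` (caudal inlet tilt — equivalent to tilting the pelvis forward
#' by `alpha`), then rotate by `azimuth` about `si_axis` (the pelvis'
#' vertical axis). For `azimuth = 0` the result makes exactly `alpha`
#' degrees with the AP view, i.e. with the APP normal.
#'
#' @param frame an [app_from_landmarks()] frame.
#' @param alpha fluoroscopic angle, degrees.
#' @param azimuth rotation about the vertical axis, degrees.
#' @return unit 3-vector (beam travel direction, anterior to posterior).
#' @export
fluoro_direction <- function(frame, alpha, azimuth = 0) {
  stopifnot(inherits(frame, "anatomical_frame"))
  d <- rotate_about(-frame$ap_axis, frame$ml_axis, alpha)
  unitv(rotate_about(d, frame$si_axis, azimuth))
}

#' Signed angle between a corridor axis and the sagittal midline plane
#'
#' The AIP of a corridor: the angle between the screw axis and the SMP,
#' in degrees. The axis is first oriented anterior-to-posterior (flipped if
#' needed). The sign is side-aware so left and right hips are directly
#' comparable: positive when the axis runs anteromedial to posterolateral
#' (the posterior end farther from the SMP on the measured side), negative
#' when anterolateral to posteromedial.
#'
#' @param axis numeric 3-vector, the corridor/screw axis.
#' @param frame an [app_from_landmarks()] frame.
#' @param side `"left"` or `"right"`, the measured hip.
#' @return signed angle in degrees, in (-90, 90).
#' @export
axis_smp_angle <- function(axis, frame, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(inherits(frame, "anatomical_frame"))
  if (vnorm(axis) < 1e-12) stop("corridor axis is a zero vector")
  a <- unitv(axis)
  if (dot3(a, frame$ap_axis) > 0) a <- -a  # orient anterior-to-posterior
  m <- dot3(a, frame$ml_axis)              # lateral drift towards patient right
  s <- if (side == "right") 1 else -1
  s * rad2deg(asin(max(-1, min(1, m))))
}
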