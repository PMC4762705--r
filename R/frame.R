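# Natural-head-position anatomical frame and the clinical decomposition
# of rigid transforms into AP/LR/UD translations and pitch/roll/yaw.

# Canonical landmark vocabulary. Bilateral landmarks are stored with a
# _left/_right suffix.
LANDMARK_NAMES <- c(
  "nasion", "sella",
  "porion_left", "porion_right", "orbitale_left", "orbitale_right",
  "upper_incisor", "mesial_cusp_16", "mesial_cusp_26",
  "lower_incisor", "mesial_cusp_36", "mesial_cusp_46",
  "condor_left", "condor_right", "c_point_left", "c_point_right",
  "gonion_left", "gonion_right"
)

# Accepted synonyms (case-insensitive; spaces and hyphens map to "_").
LANDMARK_SYNONYMS <- c(
  n = "nasion", s = "sella", por = "porion", or = "orbitale",
  ui = "upper_incisor", li = "lower_incisor",
  con = "condor", c = "c_point", cpoint = "c_point", go = "gonion",
  cusp_16 = "mesial_cusp_16", cusp_26 = "mesial_cusp_26",
  cusp_36 = "mesial_cusp_36", cusp_46 = "mesial_cusp_46"
)

BILATERAL_LANDMARKS <- c("porion", "orbitale", "condor", "c_point", "gonion")

# Normalize a (name, side) pair to a canonical landmark key; errors on
# unknown names so typos cannot silently drop a landmark.
normalize_landmark_name <- function(name, side = "") {
  key <- gsub("[ -]+", "_", tolower(trimws(name)))
  if (key %in% names(LANDMARK_SYNONYMS)) key <- LANDMARK_SYNONYMS[[key]]
  side <- tolower(trimws(side))
  side <- switch(side, l = "left", r = "right", side)
  if (key %in% BILATERAL_LANDMARKS) {
    if (!side %in% c("left", "right"))
      stop("landmark '", name, "' is bilateral; side must be left or right")
    key <- paste0(key, "_", side)
  }
  if (!key %in% LANDMARK_NAMES)
    stop("unknown landmark name '", name, "'. Known landmarks: ",
         paste(LANDMARK_NAMES, collapse = ", "))
  key
}

#' Cephalometric landmark set
#'
#' Named collection of 3D landmark positions (mm). Names are validated
#' against the cephalometric vocabulary (nasion, sella, porion, orbitale,
#' upper/lower incisor, mesial cusps 16/26/36/46, condor, C-point,
#' gonion); bilateral landmarks carry a \code{_left}/\code{_right}
#' suffix.
#'
#' @param ... named length-3 numeric vectors, or a single named list of
#'   them.
#' @return Object of class \code{landmark_set} (named list of length-3
#'   points).
#' @export
landmark_set <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && is.null(names(args)[1]))
    args <- args[[1]]
  if (is.null(names(args)) || any(names(args) == ""))
    stop("landmark_set: all landmarks must be named")
  out <- list()
  for (i in seq_along(args)) {
    key <- normalize_landmark_name(names(args)[i])
    p <- as.numeric(args[[i]])
    if (length(p) != 3L || !all(is.finite(p)))
      stop("landmark '", names(args)[i], "': expected 3 finite coordinates")
    if (!is.null(out[[key]]))
      stop("duplicate landmark '", key, "'")
    out[[key]] <- p
  }
  structure(out, class = "landmark_set")
}

#' Build the anatomical coordinate frame
#'
#' Constructs the natural-head-position frame from the reference
#' landmarks: the up/down axis is the unit normal of the Frankfort plane
#' (least-squares fit through both porions and all available orbitale
#' points), oriented cranially; the left/right axis runs from the left to
#' the right porion, projected into the Frankfort plane; the
#' anterior/posterior axis completes the right-handed set and points
#' anteriorly (toward nasion). Origin is sella. Orthonormality is
#' enforced by Gram-Schmidt.
#'
#' @param landmarks a \code{landmark_set} containing at least nasion,
#'   sella, both porions and one orbitale.
#' @return Object of class \code{anatomical_frame}: list with
#'   \code{origin} and unit axes \code{axis_lr}, \code{axis_ap},
#'   \code{axis_ud} (also bundled as the 3x3 basis matrix \code{basis}
#'   with axes in columns lr, ap, ud).
#' @export
build_frame <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  need <- c("nasion", "sella", "porion_left", "porion_right")
  for (nm in need)
    if (is.null(landmarks[[nm]]))
      stop("build_frame: missing required landmark '", nm, "'")
  orb <- landmarks[intersect(c("orbitale_left", "orbitale_right"),
                             names(landmarks))]
  if (length(orb) == 0L)
    stop("build_frame: missing required landmark 'orbitale' (either side)")

  pl <- landmarks$porion_left
  pr <- landmarks$porion_right
  if (sqrt(sum((pr - pl)^2)) < 1e-6)
    stop("build_frame: degenerate frame, porions coincide")

  # Frankfort plane through both porions and the orbitale point(s).
  pts <- rbind(pl, pr, do.call(rbind, orb))
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  normal <- sv$v[, 3]
  if (sv$d[2] < 1e-6)
    stop("build_frame: degenerate frame, Frankfort landmarks are collinear")
  # Orient cranially: nasion lies above the Frankfort plane.
  if (sum(normal * (landmarks$nasion - ctr)) < 0) normal <- -normal
  ud <- normal / sqrt(sum(normal^2))

  lr <- pr - pl
  lr <- lr - sum(lr * ud) * ud
  nlr <- sqrt(sum(lr^2))
  if (nlr < 1e-6)
    stop("build_frame: degenerate frame, porion axis parallel to plane normal")
  lr <- lr / nlr
  ap <- c(ud[2] * lr[3] - ud[3] * lr[2],
          ud[3] * lr[1] - ud[1] * lr[3],
          ud[1] * lr[2] - ud[2] * lr[1])  # ud x lr, unit by construction
  if (sum(ap * (landmarks$nasion - ctr)) < 0)
    stop("build_frame: inconsistent landmark configuration ",
         "(anterior axis points away from nasion; check porion sides)")
  structure(list(origin = landmarks$sella,
                 axis_lr = lr, axis_ap = ap, axis_ud = ud,
                 basis = cbind(lr = lr, ap = ap, ud = ud)),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("Anatomical frame (origin = sella)\n")
  m <- rbind(origin = x$origin, lr = x$axis_lr, ap = x$axis_ap, ud = x$axis_ud)
  colnames(m) <- c("x", "y", "z")
  print(round(m, 6))
  invisible(x)
}

#' Movement report
#'
#' The six clinically reported quantities for one segment. Sign
#' conventions: \code{d_ap} positive = anterior; \code{d_lr} positive =
#' toward the patient's right; \code{d_ud} positive = cranial; rotations
#' are right-handed about the respective anatomical axes, i.e. positive
#' pitch appears anti-clockwise viewed from the patient's right, positive
#' roll anti-clockwise viewed from anterior, positive yaw anti-clockwise
#' viewed from above.
#'
#' @param d_ap,d_lr,d_ud translations in mm.
#' @param pitch,roll,yaw rotations in degrees, each in (-180, 180].
#' @param segment_id segment identifier.
#' @return Object of class \code{movement_report}.
#' @export
movement_report <- function(d_ap = 0, d_lr = 0, d_ud = 0,
                            pitch = 0, roll = 0, yaw = 0,
                            segment_id = "maxilla") {
  vals <- c(d_ap = d_ap, d_lr = d_lr, d_ud = d_ud,
            pitch = pitch, roll = roll, yaw = yaw)
  if (!all(is.finite(vals))) stop("movement_report: non-finite component")
  ang <- vals[c("pitch", "roll", "yaw")]
  if (any(ang <= -180 | ang > 180))
    stop("movement_report: angles must lie in (-180, 180]")
  structure(c(as.list(vals), list(segment_id = segment_id)),
            class = "movement_report")
}

#' @export
print.movement_report <- function(x, ...) {
  cat(sprintf("%s: AP %+0.2f  LR %+0.2f  UD %+0.2f mm | pitch %+0.2f  roll %+0.2f  yaw %+0.2f deg\n",
              x$segment_id, x$d_ap, x$d_lr, x$d_ud, x$pitch, x$roll, x$yaw))
  invisible(x)
}

REPORT_COMPONENTS <- c("d_ap", "d_lr", "d_ud", "pitch", "roll", "yaw")

#' Decompose a rigid transform into clinical components
#'
#' Expresses the transform in the anatomical frame and factors it into
#' the three translations and three rotations that are reported
#' clinically. The rotation is factored by the fixed intrinsic sequence
#' yaw (about UD), then roll (about AP), then pitch (about LR); at the
#' small angles seen in surgical-accuracy data the sequence choice is
#' immaterial (see the package vignette for the measured order
#' sensitivity). The reported translation is the displacement of
#' \code{center} under the transform (default: the frame origin); for a
#' segment transform obtained from a triangle fit, pass the triangle
#' centroid so the translation is the centroid displacement.
#'
#' @param t a \code{rigid_transform}.
#' @param frame an \code{anatomical_frame}.
#' @param center point (mm) whose displacement is reported; default the
#'   frame origin.
#' @param segment_id passed through to the report.
#' @return A \code{movement_report}.
#' @export
decompose_transform <- function(t, frame, center = frame$origin,
                                segment_id = "maxilla") {
  stopifnot(inherits(t, "rigid_transform"), inherits(frame, "anatomical_frame"))
  b <- frame$basis
  d_world <- apply_transform(t, center) - center
  d <- as.numeric(crossprod(b, d_world))  # (lr, ap, ud) components

  # Rotation in frame coordinates (x = LR, y = AP, z = UD):
  # R_f = Rz(yaw) %*% Ry(roll) %*% Rx(pitch)
  rf <- crossprod(b, t$rotation %*% b)
  s_roll <- -rf[3, 1]
  s_roll <- max(-1, min(1, s_roll))
  if (1 - abs(s_roll) < 1e-12 ||
      abs(abs(asin(s_roll)) * 180 / pi - 90) < 1e-6)
    stop("decompose_transform: gimbal lock (roll within 1e-6 deg of 90); ",
         "Euler factorization is singular here")
  roll <- asin(s_roll) * 180 / pi
  pitch <- atan2(rf[3, 2], rf[3, 3]) * 180 / pi
  yaw <- atan2(rf[2, 1], rf[1, 1]) * 180 / pi
  movement_report(d_ap = d[2], d_lr = d[1], d_ud = d[3],
                  pitch = wrap_angle(pitch), roll = wrap_angle(roll),
                  yaw = wrap_angle(yaw), segment_id = segment_id)
}

#' Recompose a movement report into a rigid transform
#'
#' Inverse of \code{\link{decompose_transform}} under the same fixed
#' Euler sequence and the same \code{center}.
#'
#' @param report a \code{movement_report}.
#' @param frame an \code{anatomical_frame}.
#' @param center the reference point used at decomposition.
#' @return A \code{rigid_transform}.
#' @export
recompose_transform <- function(report, frame, center = frame$origin) {
  stopifnot(inherits(report, "movement_report"),
            inherits(frame, "anatomical_frame"))
  b <- frame$basis
  rf <- rot_z(report$yaw) %*% rot_y(report$roll) %*% rot_x(report$pitch)
  r <- b %*% rf %*% t(b)
  d_world <- report$d_lr * frame$axis_lr + report$d_ap * frame$axis_ap +
    report$d_ud * frame$axis_ud
  tr <- d_world + center - as.numeric(r %*% center)
  rigid_transform(r, tr)
}

#' Proximal-segment rotational measures
#'
#' The proximal (condyle-bearing) mandibular segments are not planned in
#' 3D, so only two rotational measures are reported for them:
#' autorotation, the pitch-like rotation about the left/right axis, and
#' flare, the yaw-like rotation about the up/down axis. Same Euler
#' sequence and sign conventions as \code{\link{decompose_transform}}.
#'
#' @param t a \code{rigid_transform} (preop to postop motion of the
#'   proximal segment).
#' @param frame an \code{anatomical_frame}.
#' @param side \code{"left"} or \code{"right"}.
#' @param center reference point for the (unreported) translation part.
#' @return Object of class \code{proximal_report}: list with \code{side},
#'   \code{autorotation}, \code{flare} (degrees).
#' @export
proximal_measures <- function(t, frame, side, center = frame$origin) {
  side <- match.arg(side, c("left", "right"))
  rep <- decompose_transform(t, frame, center = center,
                             segment_id = paste0("proximal_", side))
  structure(list(side = side, autorotation = rep$pitch, flare = rep$yaw),
            class = "proximal_report")
}

#' @export
print.proximal_report <- function(x, ...) {
  cat(sprintf("proximal_%s: autorotation %+0.2f deg, flare %+0.2f deg\n",
              x$side, x$autorotation, x$flare))
  invisible(x)
}
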