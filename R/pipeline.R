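# Per-patient analysis and cohort summaries.
#
# For each osteotomized segment the preoperative triangle is carried to
# the planned position by the planning transform; the planned-to-postop
# motion (surgical accuracy) and preop-to-postop motion (surgical
# displacement) are then obtained by rigid Procrustes fits of the
# corresponding triangles and decomposed in the anatomical frame.

PLANNED_SEGMENTS <- c("maxilla", "mandible_distal")
PROXIMAL_SEGMENTS <- c("proximal_left", "proximal_right")

#' Patient case
#'
#' Inputs for one patient. In direct mode the postoperative triangles
#' are supplied; in registration mode per-segment volumes (maxilla,
#' distal mandible) and/or meshes (proximal segments) in planned and
#' postoperative state are supplied instead and the planned-to-postop
#' transform is recovered by image or surface registration.
#'
#' @param case_id identifier.
#' @param landmarks_preop a \code{landmark_set} with the reference
#'   landmarks and the triangle landmarks of every analyzed segment.
#' @param planning_transforms named list (by segment) of
#'   \code{rigid_transform}, preop to planned. Proximal segments are not
#'   planned; omit them (identity is assumed).
#' @param postop_triangles named list (by segment) of
#'   \code{segment_triangle} in the postop state (direct mode).
#' @param volumes named list (by segment) of lists with elements
#'   \code{planned}, \code{postop} (\code{volume_image}) and optionally
#'   \code{mask} (\code{region_mask}) (registration mode).
#' @param meshes named list (by segment) of lists with elements
#'   \code{planned}, \code{postop} (\code{surface_mesh}) (registration
#'   mode).
#' @return Object of class \code{patient_case}.
#' @export
patient_case <- function(case_id, landmarks_preop,
                         planning_transforms = list(),
                         postop_triangles = NULL,
                         volumes = NULL, meshes = NULL) {
  stopifnot(inherits(landmarks_preop, "landmark_set"))
  for (tf in planning_transforms)
    stopifnot(inherits(tf, "rigid_transform"))
  structure(list(case_id = case_id, landmarks_preop = landmarks_preop,
                 planning_transforms = planning_transforms,
                 postop_triangles = postop_triangles,
                 volumes = volumes, meshes = meshes),
            class = "patient_case")
}

#' Build a segment triangle from a landmark set
#'
#' Uses the fixed per-segment vertex-order convention (maxilla: mesial
#' cusp 16, upper incisor, mesial cusp 26; distal mandible: mesial cusp
#' 46, lower incisor, mesial cusp 36; proximal: condor, C-point, gonion
#' per side).
#'
#' @param landmarks a \code{landmark_set}.
#' @param segment_id segment identifier.
#' @param state state label for the resulting triangle.
#' @return A \code{segment_triangle}.
#' @export
triangle_from_landmarks <- function(landmarks, segment_id, state = "preop") {
  segment_id <- match.arg(segment_id, SEGMENT_IDS)
  names_needed <- SEGMENT_VERTEX_ORDER[[segment_id]]
  missing <- setdiff(names_needed, names(landmarks))
  if (length(missing) > 0)
    stop("triangle_from_landmarks: missing landmark(s) ",
         paste(missing, collapse = ", "), " for segment ", segment_id)
  v <- do.call(rbind, landmarks[names_needed])
  segment_triangle(segment_id, v, state)
}

#' Transfer a triangle through a planning transform
#'
#' Applies the preop-to-planned transform of the virtual plan to every
#' vertex of the preoperative triangle, yielding the planned triangle.
#'
#' @param tri_preop a \code{segment_triangle} in state \code{preop}.
#' @param plan a \code{rigid_transform} (preop to planned).
#' @return A \code{segment_triangle} in state \code{planned}.
#' @export
transfer_triangle <- function(tri_preop, plan) {
  stopifnot(inherits(tri_preop, "segment_triangle"),
            inherits(plan, "rigid_transform"))
  segment_triangle(tri_preop$segment_id,
                   apply_transform(plan, tri_preop$vertices), "planned")
}

#' Analyze one patient case
#'
#' Computes, per segment, the surgical displacement (preop to postop)
#' and the surgical accuracy (planned to postop) movement reports, and
#' the autorotation/flare measures for the proximal segments (which are
#' not planned, so only their preop-to-postop motion is reported).
#' Translations are reported as displacements of the source-triangle
#' centroid.
#'
#' @param case a \code{patient_case}.
#' @param mode \code{"direct"} (postop triangles supplied) or
#'   \code{"registration"} (planned-to-postop transform recovered from
#'   per-segment volumes/meshes and applied to the planned triangle).
#' @return Object of class \code{case_result}: list with \code{case_id},
#'   \code{accuracy} and \code{displacement} (named lists of
#'   \code{movement_report}) and \code{proximal} (named list of
#'   \code{proximal_report}).
#' @export
compute_case <- function(case, mode = c("direct", "registration")) {
  stopifnot(inherits(case, "patient_case"))
  mode <- match.arg(mode)
  frame <- build_frame(case$landmarks_preop)

  segments_with_data <- if (mode == "direct") names(case$postop_triangles)
                        else union(names(case$volumes), names(case$meshes))
  accuracy <- list(); displacement <- list(); proximal <- list()

  for (seg in intersect(SEGMENT_IDS, segments_with_data)) {
    tri_pre <- tryCatch(
      triangle_from_landmarks(case$landmarks_preop, seg, "preop"),
      error = function(e) {
        warning("case ", case$case_id, ": segment ", seg, " skipped (",
                conditionMessage(e), ")")
        NULL
      })
    if (is.null(tri_pre)) next
    plan <- case$planning_transforms[[seg]] %||% rt_identity()
    tri_plan <- transfer_triangle(tri_pre, plan)

    tri_post <- if (mode == "direct") {
      case$postop_triangles[[seg]]
    } else {
      tf <- if (!is.null(case$volumes[[seg]])) {
        register_volumes_rigid(case$volumes[[seg]]$planned,
                               case$volumes[[seg]]$postop,
                               mask = case$volumes[[seg]]$mask)$transform
      } else {
        register_surfaces_icp(case$meshes[[seg]]$planned,
                              case$meshes[[seg]]$postop)$transform
      }
      segment_triangle(seg, apply_transform(tf, tri_plan$vertices), "postop")
    }
    if (is.null(tri_post)) next

    disp_fit <- procrustes_rigid(tri_pre, tri_post)
    if (seg %in% PROXIMAL_SEGMENTS) {
      side <- sub("proximal_", "", seg)
      proximal[[side]] <- proximal_measures(
        disp_fit$transform, frame, side,
        center = triangle_centroid(tri_pre))
    } else {
      acc_fit <- procrustes_rigid(tri_plan, tri_post)
      accuracy[[seg]] <- decompose_transform(
        acc_fit$transform, frame,
        center = triangle_centroid(tri_plan), segment_id = seg)
      displacement[[seg]] <- decompose_transform(
        disp_fit$transform, frame,
        center = triangle_centroid(tri_pre), segment_id = seg)
    }
  }
  structure(list(case_id = case$case_id, accuracy = accuracy,
                 displacement = displacement, proximal = proximal),
            class = "case_result")
}

#' @export
print.case_result <- function(x, ...) {
  cat("Case", x$case_id, "\n accuracy (planned -> postop):\n")
  for (r in x$accuracy) { cat("  "); print(r) }
  cat(" displacement (preop -> postop):\n")
  for (r in x$displacement) { cat("  "); print(r) }
  for (p in x$proximal) { cat(" "); print(p) }
  invisible(x)
}

#' Summarize a cohort of movement reports
#'
#' Per component: arithmetic mean of the signed values, mean of the
#' absolute values, and the counts of strictly negative and strictly
#' positive values (zeros count as neither, so e.g. the number of
#' maxillae positioned more posteriorly than planned is
#' \code{n_negative} of the AP component).
#'
#' @param reports list of \code{movement_report} for a single segment,
#'   or a data frame with columns \code{d_ap, d_lr, d_ud, pitch, roll,
#'   yaw}.
#' @return Object of class \code{cohort_summary}: data frame with one
#'   row per component and columns \code{component, mean, abs_mean,
#'   n_negative, n_positive, n}.
#' @export
summarize_cohort <- function(reports) {
  if (is.data.frame(reports)) {
    stopifnot(all(REPORT_COMPONENTS %in% names(reports)))
    m <- as.matrix(reports[, REPORT_COMPONENTS])
  } else {
    if (length(reports) == 0) stop("summarize_cohort: empty report list")
    for (r in reports) stopifnot(inherits(r, "movement_report"))
    segs <- unique(vapply(reports, `[[`, "", "segment_id"))
    if (length(segs) != 1)
      stop("summarize_cohort: reports mix segments (",
           paste(segs, collapse = ", "), ")")
    m <- do.call(rbind, lapply(reports, function(r)
      unlist(r[REPORT_COMPONENTS])))
  }
  if (nrow(m) == 0) stop("summarize_cohort: empty report list")
  out <- data.frame(
    component = REPORT_COMPONENTS,
    mean = colMeans(m),
    abs_mean = colMeans(abs(m)),
    n_negative = colSums(m < 0),
    n_positive = colSums(m > 0),
    n = nrow(m),
    row.names = NULL)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Round half away from zero
#'
#' Table-printing convention: 0.005 rounds to 0.01 (base \code{round}
#' uses round-half-even and would print 1.035 as 1.03).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
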