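# Synthetic study generator: skull-like landmark constellations, a
# geometric desk-scale phantom volume, per-segment blob meshes, planned
# movements, execution errors, and observer landmark-identification
# noise. Everything is deterministic under a fixed seed, and every
# ground-truth transform is stored so recovery can be tested exactly.

# Canonical landmark constellation (mm). World axes of the canonical
# pose: +x = patient's right, +y = anterior, +z = cranial; the Frankfort
# landmarks lie in the z = 0 plane so the canonical anatomical frame is
# the world frame with origin at sella.
canonical_landmarks <- function() {
  landmark_set(
    nasion = c(0, 80, 25), sella = c(0, 10, 20),
    porion_left = c(-58, 0, 0), porion_right = c(58, 0, 0),
    orbitale_left = c(-30, 65, 0), orbitale_right = c(30, 65, 0),
    upper_incisor = c(0, 85, -35),
    mesial_cusp_16 = c(25, 55, -33), mesial_cusp_26 = c(-25, 55, -33),
    lower_incisor = c(0, 83, -48),
    mesial_cusp_36 = c(-26, 53, -45), mesial_cusp_46 = c(26, 53, -45),
    condor_left = c(-55, -5, -5), condor_right = c(55, -5, -5),
    c_point_left = c(-52, 3, -20), c_point_right = c(52, 3, -20),
    gonion_left = c(-50, 0, -70), gonion_right = c(50, 0, -70))
}

#' Execution-error model
#'
#' Distribution of the per-segment discrepancy between the planned and
#' achieved position (the surgical execution error), expressed in
#' anatomical-frame components, plus the landmark-identification noise.
#' Defaults emulate the dispersion seen in ten-patient
#' bimaxillary-surgery accuracy cohorts (AP absolute error around
#' 1.4 mm with a posterior bias, vertical error around 1.9 mm, pitch
#' around 2.7 degrees; see the package vignette).
#'
#' @param translation_mean,translation_sd mm, named (ap, lr, ud).
#' @param rotation_mean,rotation_sd degrees, named (pitch, roll, yaw).
#' @param landmark_noise_sd mm, SD of isotropic landmark-identification
#'   noise per coordinate.
#' @return Object of class \code{error_model}.
#' @export
error_model <- function(translation_mean = c(ap = -0.46, lr = 0.29, ud = -0.45),
                        translation_sd = c(ap = 1.8, lr = 0.7, ud = 2.2),
                        rotation_mean = c(pitch = 1.37, roll = -0.54, yaw = 0.51),
                        rotation_sd = c(pitch = 3.0, roll = 1.1, yaw = 1.3),
                        landmark_noise_sd = 0.1) {
  stopifnot(all(translation_sd >= 0), all(rotation_sd >= 0),
            landmark_noise_sd >= 0)
  structure(list(translation_mean = translation_mean,
                 translation_sd = translation_sd,
                 rotation_mean = rotation_mean,
                 rotation_sd = rotation_sd,
                 landmark_noise_sd = landmark_noise_sd),
            class = "error_model")
}

# UV-sphere blob mesh with angular radius modulation (asymmetric, so
# surface registration has a unique optimum).
blob_mesh <- function(center, radii, n_lat = 15L, n_lon = 20L,
                      bump = 0.2) {
  th <- seq(0, pi, length.out = n_lat)          # polar
  ph <- seq(0, 2 * pi, length.out = n_lon + 1L)[-(n_lon + 1L)]
  verts <- matrix(0, 0, 3)
  for (i in seq_len(n_lat)) {
    if (i == 1L || i == n_lat) {
      verts <- rbind(verts, c(0, 0, cos(th[i])))
    } else {
      for (j in seq_len(n_lon)) {
        r <- 1 + bump * sin(3 * ph[j]) * sin(th[i]) +
          0.6 * bump * cos(2 * th[i]) * cos(ph[j])
        verts <- rbind(verts, r * c(sin(th[i]) * cos(ph[j]),
                                    sin(th[i]) * sin(ph[j]), cos(th[i])))
      }
    }
  }
  verts <- sweep(sweep(verts, 2, radii, "*"), 2, center, "+")
  ring <- function(i) 1L + (i - 2L) * n_lon + seq_len(n_lon)  # i in 2..n_lat-1
  faces <- matrix(0L, 0, 3)
  r2 <- ring(2L)
  for (j in seq_len(n_lon))
    faces <- rbind(faces, c(1L, r2[j], r2[j %% n_lon + 1L]))
  for (i in 2L:(n_lat - 2L)) {
    a <- ring(i); b <- ring(i + 1L)
    for (j in seq_len(n_lon)) {
      jn <- j %% n_lon + 1L
      faces <- rbind(faces, c(a[j], b[j], b[jn]), c(a[j], b[jn], a[jn]))
    }
  }
  last <- nrow(verts)
  rl <- ring(n_lat - 1L)
  for (j in seq_len(n_lon))
    faces <- rbind(faces, c(last, rl[j %% n_lon + 1L], rl[j]))
  surface_mesh(verts, faces)
}

# Analytic phantom density: smooth-edged ellipsoidal components with a
# low-amplitude cosine texture. Evaluated in world coordinates, so a
# segment at a different pose is just the density composed with the
# inverse pose.
phantom_density <- function(shape, pts) {
  val <- rep(0, nrow(pts))
  tex <- rep(1, nrow(pts))
  for (m in seq_len(nrow(shape$tex_k))) {
    tex <- tex + shape$tex_amp *
      cos(pts %*% shape$tex_k[m, ] + shape$tex_phase[m])
  }
  for (comp in shape$components) {
    u <- sweep(pts, 2, comp$center)
    q <- (u[, 1] / comp$radii[1])^2 + (u[, 2] / comp$radii[2])^2 +
      (u[, 3] / comp$radii[3])^2
    s <- (sqrt(q) - 1) * min(comp$radii)   # approx signed distance, mm
    val <- val + comp$intensity * stats::plogis(-s / 0.5)
  }
  as.vector(val * tex)
}

voxelize_density <- function(shape, dim, spacing, origin, pose = NULL) {
  vol <- volume_image(array(0, dim = dim), spacing = spacing, origin = origin)
  pts <- voxel_grid_world(vol)
  if (!is.null(pose)) pts <- apply_transform(invert(pose), pts)
  vol$data <- array(phantom_density(shape, pts), dim = dim)
  vol
}

#' Generate a synthetic skull phantom
#'
#' Produces (i) an anatomically plausible cephalometric landmark
#' constellation (canonical natural head position plus a small
#' per-seed asymmetry perturbation), (ii) one irregular blob mesh per
#' jaw segment, (iii) a desk-scale textured phantom volume containing
#' distinct cranial-base, maxilla and mandible intensity structures in
#' a small field of view around the jaws, and (iv) the cranial-base
#' region mask used for registration. Deterministic per seed.
#'
#' @param seed RNG seed.
#' @param spacing voxel spacing in mm (default 0.4).
#' @param dim voxel grid dimensions (default 64^3, i.e. a 25.6 mm field
#'   of view at the default spacing).
#' @param asymmetry_sd mm, SD of the landmark perturbation (default 0.5).
#' @return Object of class \code{skull_phantom}: list with
#'   \code{landmarks}, \code{meshes} (per segment), \code{volume},
#'   \code{cranial_mask}, \code{shape} (analytic density parameters) and
#'   \code{seed}.
#' @export
generate_phantom <- function(seed = 1L, spacing = 0.4, dim = c(64L, 64L, 64L),
                             asymmetry_sd = 0.5) {
  set.seed(seed)
  lm <- canonical_landmarks()
  for (nm in names(lm)) lm[[nm]] <- lm[[nm]] + stats::rnorm(3, 0, asymmetry_sd)
  lm <- landmark_set(unclass(lm))

  meshes <- list(
    maxilla = blob_mesh(c(0, 65, -33), c(24, 20, 9)),
    mandible_distal = blob_mesh(c(0, 63, -46), c(25, 20, 10)),
    proximal_left = blob_mesh(c(-52, -1, -32), c(9, 11, 34), bump = 0.15),
    proximal_right = blob_mesh(c(52, -1, -32), c(9, 11, 34), bump = 0.15))

  # Miniature intensity phantom centred on the jaw region.
  c0 <- c(0, 60, -40)
  fov <- dim * spacing
  origin <- c0 - (dim - 1) / 2 * spacing
  shape <- list(
    components = list(
      cranial = list(center = c0 + c(0, 0, 0.36 * fov[3]),
                     radii = 0.36 * fov * c(1, 0.8, 0.35), intensity = 0.9),
      maxilla = list(center = c0 + c(0, 0.06 * fov[2], 0.04 * fov[3]),
                     radii = 0.25 * fov * c(1, 0.75, 0.4), intensity = 0.7),
      mandible = list(center = c0 + c(0, 0.02 * fov[2], -0.28 * fov[3]),
                      radii = 0.28 * fov * c(1, 0.75, 0.4), intensity = 0.55),
      proximal_left = list(center = c0 + c(-0.33 * fov[1], -0.1 * fov[2], -0.16 * fov[3]),
                           radii = 0.1 * fov * c(0.9, 1.2, 1.8), intensity = 0.45),
      proximal_right = list(center = c0 + c(0.33 * fov[1], -0.1 * fov[2], -0.16 * fov[3]),
                            radii = 0.1 * fov * c(0.9, 1.2, 1.8), intensity = 0.45)),
    tex_amp = 0.08,
    tex_k = matrix(stats::runif(9, -1, 1) * 2 * pi / (0.18 * min(fov)), 3, 3),
    tex_phase = stats::runif(3, 0, 2 * pi))

  vol <- voxelize_density(shape, dim, spacing, origin)
  crn <- shape$components$cranial
  pts <- voxel_grid_world(vol)
  u <- sweep(pts, 2, crn$center)
  q <- (u[, 1] / crn$radii[1])^2 + (u[, 2] / crn$radii[2])^2 +
    (u[, 3] / crn$radii[3])^2
  mask <- region_mask(array(q < 1.2, dim = dim))

  structure(list(landmarks = lm, meshes = meshes, volume = vol,
                 cranial_mask = mask, shape = shape, seed = seed,
                 spacing = spacing, dim = dim, origin = origin),
            class = "skull_phantom")
}

# Draw one execution-error movement report from an error model.
draw_error_report <- function(em, segment_id) {
  tr <- stats::rnorm(3, em$translation_mean, em$translation_sd)
  ro <- stats::rnorm(3, em$rotation_mean, em$rotation_sd)
  movement_report(d_ap = tr[1], d_lr = tr[2], d_ud = tr[3],
                  pitch = ro[1], roll = ro[2], yaw = ro[3],
                  segment_id = segment_id)
}

noisy_landmarks <- function(lm, sd) {
  if (sd <= 0) return(lm)
  for (nm in names(lm)) lm[[nm]] <- lm[[nm]] + stats::rnorm(3, 0, sd)
  landmark_set(unclass(lm))
}

noisy_triangle <- function(tri, sd) {
  if (sd <= 0) return(tri)
  segment_triangle(tri$segment_id,
                   tri$vertices + matrix(stats::rnorm(9, 0, sd), 3, 3),
                   tri$state)
}

#' Simulate a planned surgery with execution error
#'
#' Applies the per-segment planning transforms to the phantom's preop
#' segments, composes each with an execution-error transform drawn from
#' the error model (rotations taken about the planned-triangle
#' centroid, error components expressed in the phantom's anatomical
#' frame), perturbs the landmarks of every state with independent
#' identification noise, and records all ground-truth transforms. The
#' proximal segments are not planned: their "plan" is the identity and
#' the drawn error plays the role of the passive intra-operative
#' proximal-segment motion.
#'
#' @param phantom a \code{skull_phantom}.
#' @param plans named list (by segment) of \code{rigid_transform}
#'   preop-to-planned transforms; segments not named get the identity.
#' @param em an \code{error_model}.
#' @param seed RNG seed.
#' @param segments segments to simulate (default all four).
#' @param volumes if TRUE, also voxelize planned/postop per-segment
#'   volumes for the maxilla and distal mandible (registration mode).
#' @param meshes if TRUE, also emit planned/postop meshes for the
#'   proximal segments (registration mode).
#' @return Object of class \code{synthetic_case}: a
#'   \code{\link{patient_case}} plus \code{ground_truth} (per segment:
#'   \code{plan}, \code{error}, \code{error_report}, and clean
#'   triangles), the clean landmark set, the error model and the seed.
#' @export
simulate_surgery <- function(phantom, plans = list(), em = error_model(),
                             seed = 1L, segments = SEGMENT_IDS,
                             volumes = FALSE, meshes = FALSE) {
  stopifnot(inherits(phantom, "skull_phantom"), inherits(em, "error_model"))
  set.seed(seed)
  lm_clean <- phantom$landmarks
  frame <- build_frame(lm_clean)
  gt <- list()
  postop_tris <- list()
  vol_data <- list(); mesh_data <- list()

  for (seg in segments) {
    plan <- plans[[seg]] %||% rt_identity()
    tri_pre <- triangle_from_landmarks(lm_clean, seg, "preop")
    tri_plan <- transfer_triangle(tri_pre, plan)
    err_rep <- draw_error_report(em, seg)
    err <- recompose_transform(err_rep, frame,
                               center = triangle_centroid(tri_plan))
    tri_post <- segment_triangle(seg, apply_transform(err, tri_plan$vertices),
                                 "postop")
    gt[[seg]] <- list(plan = plan, error = err, error_report = err_rep,
                      triangle_preop = tri_pre, triangle_planned = tri_plan,
                      triangle_postop = tri_post)
    postop_tris[[seg]] <- tri_post

    if (volumes && seg %in% PLANNED_SEGMENTS) {
      comp_name <- if (seg == "maxilla") "maxilla" else "mandible"
      sub <- phantom$shape
      sub$components <- sub$components[comp_name]
      vol_data[[seg]] <- list(
        planned = voxelize_density(sub, phantom$dim, phantom$spacing,
                                   phantom$origin, pose = plan),
        postop = voxelize_density(sub, phantom$dim, phantom$spacing,
                                  phantom$origin, pose = compose(err, plan)))
    }
    if (meshes && seg %in% PROXIMAL_SEGMENTS) {
      m <- phantom$meshes[[seg]]
      mesh_data[[seg]] <- list(
        planned = transform_mesh(m, plan),
        postop = transform_mesh(m, compose(err, plan)))
    }
  }

  nsd <- em$landmark_noise_sd
  case <- patient_case(
    case_id = paste0("synthetic_", seed),
    landmarks_preop = noisy_landmarks(lm_clean, nsd),
    planning_transforms = lapply(
      stats::setNames(segments, segments), function(s) gt[[s]]$plan),
    postop_triangles = lapply(postop_tris, noisy_triangle, sd = nsd),
    volumes = if (volumes) vol_data else NULL,
    meshes = if (meshes) mesh_data else NULL)
  structure(c(case, list(ground_truth = gt, landmarks_clean = lm_clean,
                         error_model = em, seed = seed)),
            class = c("synthetic_case", "patient_case"))
}

#' Per-session registration alignment noise
#'
#' Observer-dependent error of the per-segment rigid registration that
#' carries a triangle from the planned to the postoperative position.
#' In the workflow being emulated the landmarks are identified once per
#' session and then transferred, so landmark-identification error
#' largely cancels out of the planned-to-postop comparison; what
#' remains between sessions is the small alignment error of the
#' voxel/surface registration itself (sub-voxel translations, fractions
#' of a degree). Defaults are of the magnitude reported for
#' voxel-based matching at 0.4 mm voxels.
#'
#' @param translation_sd mm, named (ap, lr, ud).
#' @param rotation_sd degrees, named (pitch, roll, yaw).
#' @return A list with the two SD vectors.
#' @export
alignment_noise <- function(translation_sd = c(ap = 0.06, lr = 0.03, ud = 0.12),
                            rotation_sd = c(pitch = 0.35, roll = 0.12,
                                            yaw = 0.05)) {
  stopifnot(all(translation_sd >= 0), all(rotation_sd >= 0))
  list(translation_sd = translation_sd, rotation_sd = rotation_sd)
}

#' Simulate repeated observer sessions
#'
#' Emulates the reliability study design: in each session the observer
#' re-identifies every landmark on the preoperative model (independent
#' identification noise), the triangles are transferred to the planned
#' position, and the planned-to-postop motion of each segment is the
#' true execution transform perturbed by that session's registration
#' alignment error. The full per-case analysis is rerun per session and
#' the movement components are assembled into a patients x sessions x
#' components grid.
#'
#' @param cases a \code{synthetic_case} or list of them.
#' @param landmark_noise_sd mm, per-coordinate identification noise.
#' @param reg_noise an \code{\link{alignment_noise}} specification; use
#'   \code{alignment_noise(c(0, 0, 0), c(0, 0, 0))} for noise-free
#'   registration.
#' @param n_sessions number of sessions (>= 2; with 3 the sessions are
#'   labelled observer1_t1, observer1_t2, observer2).
#' @param seed RNG seed.
#' @return A \code{\link{measurement_grid}} whose components are named
#'   \code{<segment>.<component>} for the planned segments' accuracy
#'   reports and \code{proximal_<side>.autorotation/.flare} for the
#'   proximal segments.
#' @export
simulate_observer_sessions <- function(cases, landmark_noise_sd = 0.1,
                                       reg_noise = alignment_noise(),
                                       n_sessions = 3L, seed = 1L) {
  if (inherits(cases, "synthetic_case")) cases <- list(cases)
  stopifnot(length(cases) >= 1L, n_sessions >= 2L)
  set.seed(seed)
  sess_names <- if (n_sessions == 3L)
    c("observer1_t1", "observer1_t2", "observer2")
  else paste0("session", seq_len(n_sessions))

  rows <- list()
  for (case in cases) {
    stopifnot(inherits(case, "synthetic_case"))
    segs <- names(case$ground_truth)
    frame_clean <- build_frame(case$landmarks_clean)
    for (s in seq_len(n_sessions)) {
      lm_s <- noisy_landmarks(case$landmarks_clean, landmark_noise_sd)
      post_s <- list()
      for (seg in segs) {
        gt <- case$ground_truth[[seg]]
        tri_pre_s <- triangle_from_landmarks(lm_s, seg, "preop")
        tri_plan_s <- transfer_triangle(tri_pre_s, gt$plan)
        nrep <- movement_report(
          d_ap = stats::rnorm(1, 0, reg_noise$translation_sd[1]),
          d_lr = stats::rnorm(1, 0, reg_noise$translation_sd[2]),
          d_ud = stats::rnorm(1, 0, reg_noise$translation_sd[3]),
          pitch = stats::rnorm(1, 0, reg_noise$rotation_sd[1]),
          roll = stats::rnorm(1, 0, reg_noise$rotation_sd[2]),
          yaw = stats::rnorm(1, 0, reg_noise$rotation_sd[3]),
          segment_id = seg)
        reg_err <- recompose_transform(
          nrep, frame_clean, center = triangle_centroid(gt$triangle_planned))
        post_s[[seg]] <- segment_triangle(
          seg,
          apply_transform(compose(reg_err, gt$error), tri_plan_s$vertices),
          "postop")
      }
      pc <- patient_case(case$case_id, lm_s,
                         planning_transforms = lapply(
                           stats::setNames(segs, segs),
                           function(g) case$ground_truth[[g]]$plan),
                         postop_triangles = post_s)
      res <- compute_case(pc, mode = "direct")
      for (seg in names(res$accuracy)) {
        r <- res$accuracy[[seg]]
        for (comp in REPORT_COMPONENTS)
          rows[[length(rows) + 1L]] <- data.frame(
            case_id = case$case_id, session = sess_names[s],
            component = paste0(seg, ".", comp), value = r[[comp]])
      }
      for (side in names(res$proximal)) {
        p <- res$proximal[[side]]
        rows[[length(rows) + 1L]] <- data.frame(
          case_id = case$case_id, session = sess_names[s],
          component = paste0("proximal_", side, ".autorotation"),
          value = p$autorotation)
        rows[[length(rows) + 1L]] <- data.frame(
          case_id = case$case_id, session = sess_names[s],
          component = paste0("proximal_", side, ".flare"), value = p$flare)
      }
    }
  }
  measurement_grid(do.call(rbind, rows))
}
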