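# Segment triangles and the rigid Procrustes (Kabsch) fit.
#
# Three cephalometric landmarks per osteotomized segment encode its 3D
# position and orientation as an ordered triangle; matching the same
# triangle between two states yields the segment's rigid motion.

SEGMENT_IDS <- c("maxilla", "mandible_distal", "proximal_left", "proximal_right")
STATE_LABELS <- c("preop", "planned", "postop")

# Fixed vertex-order conventions per segment. The order follows the
# landmark listing used when the triangles are defined on each bone
# segment; keeping it fixed makes the point correspondence in the
# Procrustes fit unambiguous.
SEGMENT_VERTEX_ORDER <- list(
  maxilla         = c("mesial_cusp_16", "upper_incisor", "mesial_cusp_26"),
  mandible_distal = c("mesial_cusp_46", "lower_incisor", "mesial_cusp_36"),
  proximal_left   = c("condor_left",  "c_point_left",  "gonion_left"),
  proximal_right  = c("condor_right", "c_point_right", "gonion_right")
)

#' Segment triangle
#'
#' Ordered triple of landmark positions encoding the position and
#' orientation of one jaw segment in one state. The vertex order is a
#' fixed convention per segment (see \code{SEGMENT_VERTEX_ORDER} in the
#' package source) so that vertices correspond one-to-one between states.
#'
#' @param segment_id one of \code{"maxilla"}, \code{"mandible_distal"},
#'   \code{"proximal_left"}, \code{"proximal_right"}.
#' @param vertices 3 x 3 numeric matrix, one vertex per row, mm.
#' @param state one of \code{"preop"}, \code{"planned"}, \code{"postop"}.
#' @return An object of class \code{segment_triangle}.
#' @export
segment_triangle <- function(segment_id, vertices, state = "preop") {
  segment_id <- match.arg(segment_id, SEGMENT_IDS)
  state <- match.arg(state, STATE_LABELS)
  vertices <- as.matrix(vertices)
  stopifnot(identical(dim(vertices), c(3L, 3L)))
  if (!all(is.finite(vertices))) stop("segment_triangle: non-finite vertex")
  area <- triangle_area(vertices)
  if (area <= 1e-6)
    stop("segment_triangle: degenerate (collinear) landmark configuration ",
         "for segment '", segment_id, "' (area ", format(area), " mm^2)")
  structure(list(segment_id = segment_id, vertices = vertices, state = state),
            class = "segment_triangle")
}

#' Triangle area
#' @param x a \code{segment_triangle} or a 3 x 3 vertex matrix.
#' @return Area in mm^2.
#' @export
triangle_area <- function(x) {
  v <- if (inherits(x, "segment_triangle")) x$vertices else as.matrix(x)
  e1 <- v[2, ] - v[1, ]
  e2 <- v[3, ] - v[1, ]
  cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  0.5 * sqrt(sum(cr^2))
}

#' Triangle centroid
#' @param x a \code{segment_triangle} or a 3 x 3 vertex matrix.
#' @return Length-3 centroid (mm).
#' @export
triangle_centroid <- function(x) {
  v <- if (inherits(x, "segment_triangle")) x$vertices else as.matrix(x)
  colMeans(v)
}

#' Rigid Procrustes fit between two segment triangles
#'
#' Least-squares rigid match (Kabsch/SVD): finds the proper rigid
#' transform (rotation + translation, no scaling, no reflection)
#' minimizing the sum of squared distances between corresponding
#' vertices. If the singular system would yield a reflection, the sign of
#' the smallest singular direction is corrected so the returned rotation
#' always has determinant +1.
#'
#' @param source,target \code{segment_triangle} objects with the same
#'   \code{segment_id} (and hence the same vertex-order convention).
#' @return A \code{fit_result}: list with \code{transform}
#'   (\code{rigid_transform} mapping source vertices onto target) and
#'   \code{rmsd} (root-mean-square vertex residual, mm).
#' @examples
#' v <- rbind(c(25, 55, -33), c(0, 85, -35), c(-25, 55, -33))
#' a <- segment_triangle("maxilla", v)
#' b <- segment_triangle("maxilla", v + rep(c(1, 2, 3), each = 3), "planned")
#' procrustes_rigid(a, b)$transform$translation
#' @export
procrustes_rigid <- function(source, target) {
  stopifnot(inherits(source, "segment_triangle"),
            inherits(target, "segment_triangle"))
  if (!identical(source$segment_id, target$segment_id))
    stop("procrustes_rigid: mismatched segment_id ('", source$segment_id,
         "' vs '", target$segment_id, "')")
  fit <- kabsch(source$vertices, target$vertices)
  fit_result(fit$transform, fit$rmsd)
}

# Kabsch rigid fit on corresponding row-point matrices (n >= 3).
kabsch <- function(src, tgt) {
  src <- as.matrix(src); tgt <- as.matrix(tgt)
  stopifnot(nrow(src) == nrow(tgt), ncol(src) == 3L, ncol(tgt) == 3L)
  cs <- colMeans(src); ct <- colMeans(tgt)
  h <- crossprod(sweep(src, 2, cs), sweep(tgt, 2, ct))
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- ct - as.numeric(r %*% cs)
  tf <- rigid_transform(r, tr)
  res <- apply_transform(tf, src) - tgt
  list(transform = tf, rmsd = sqrt(mean(rowSums(res^2))))
}

#' Fit result
#' @param transform a \code{rigid_transform}.
#' @param rmsd non-negative root-mean-square residual (mm).
#' @return Object of class \code{fit_result}.
#' @export
fit_result <- function(transform, rmsd) {
  stopifnot(inherits(transform, "rigid_transform"), rmsd >= 0)
  structure(list(transform = transform, rmsd = rmsd), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Rigid fit, rmsd =", format(x$rmsd), "mm\n")
  print(x$transform)
  invisible(x)
}
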