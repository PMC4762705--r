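# Rigid-body transforms: proper rotation + translation, in millimetres.

#' Rigid transform
#'
#' A proper rigid-body transform mapping a point \code{p} to
#' \code{rotation \%*\% p + translation}. Rotations must be proper
#' (orthonormal, determinant +1): reflections and scaling are rejected
#' because segment motion between two states of the same bone is a
#' physical rigid motion.
#'
#' @param rotation 3x3 numeric matrix, orthonormal with determinant +1
#'   (checked to 1e-9).
#' @param translation numeric length-3, millimetres.
#' @return An object of class \code{rigid_transform} with elements
#'   \code{rotation} and \code{translation}.
#' @examples
#' t1 <- rigid_transform(diag(3), c(1, 2, 3))
#' apply_transform(t1, c(0, 0, 0))
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3L)
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    stop("rigid_transform: non-finite components")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rigid_transform: rotation is not orthonormal within 1e-9")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rigid_transform: rotation determinant is not +1 within 1e-9 ",
         "(reflection or scaling rejected)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation (mm):", format(round(x$translation, 6)), "\n")
  invisible(x)
}

#' Identity rigid transform
#' @return A \code{rigid_transform} that leaves every point unchanged.
#' @export
rt_identity <- function() rigid_transform(diag(3), c(0, 0, 0))

#' Compose two rigid transforms
#'
#' @param a,b \code{rigid_transform} objects.
#' @return The \code{rigid_transform} mapping \code{x} to \code{a(b(x))}.
#' @export
compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#'
#' @param t a \code{rigid_transform}.
#' @return The \code{rigid_transform} such that \code{compose(t, invert(t))}
#'   is the identity.
#' @export
invert <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  rt <- t(t$rotation)
  rigid_transform(rt, -as.numeric(rt %*% t$translation))
}

#' Apply a rigid transform to points
#'
#' @param t a \code{rigid_transform}.
#' @param p numeric length-3 point, or an n x 3 matrix of row points (mm).
#' @return Transformed point(s), same shape as the input.
#' @export
apply_transform <- function(t, p) {
  stopifnot(inherits(t, "rigid_transform"))
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3L)
    sweep(p %*% t(t$rotation), 2, t$translation, "+")
  } else {
    stopifnot(length(p) == 3L)
    as.numeric(t$rotation %*% p) + t$translation
  }
}

#' Rotation about an arbitrary axis
#'
#' Right-handed rotation matrix (Rodrigues formula).
#'
#' @param axis numeric length-3, need not be unit length.
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation_about_axis: zero axis")
  a <- axis / n
  th <- angle_deg * pi / 180
  k <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

# Elementary rotations about world axes (degrees), right-handed.
rot_x <- function(a) rotation_about_axis(c(1, 0, 0), a)
rot_y <- function(a) rotation_about_axis(c(0, 1, 0), a)
rot_z <- function(a) rotation_about_axis(c(0, 0, 1), a)

#' Draw a random proper rigid transform
#'
#' Rotation uniform over SO(3) up to a bounded angle (uniform random unit
#' axis, uniform angle), translation uniform per axis. Uses the current RNG
#' state; seed outside for reproducibility.
#'
#' @param max_angle_deg upper bound on the rotation angle magnitude.
#' @param max_translation_mm upper bound on each translation component
#'   magnitude.
#' @return A \code{rigid_transform}.
#' @export
random_rigid <- function(max_angle_deg = 180, max_translation_mm = 10) {
  ax <- stats::rnorm(3)
  while (sqrt(sum(ax^2)) < 1e-6) ax <- stats::rnorm(3)
  ang <- stats::runif(1, -max_angle_deg, max_angle_deg)
  tr <- stats::runif(3, -max_translation_mm, max_translation_mm)
  rigid_transform(rotation_about_axis(ax, ang), tr)
}

# Map an angle in degrees to (-180, 180].
wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  ifelse(a == -180, 180, a)
}
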