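# Surface meshes and trimmed iterative-closest-point rigid registration
# (surface-based matching stand-in for the proximal segments).

#' Surface mesh
#'
#' Triangle mesh with vertices in mm.
#'
#' @param vertices n x 3 numeric matrix.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return Object of class \code{surface_mesh}.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  stopifnot(ncol(vertices) == 3L)
  if (nrow(vertices) < 4L) stop("surface_mesh: need >= 4 vertices")
  if (!all(is.finite(vertices))) stop("surface_mesh: non-finite vertex")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("surface_mesh: face index out of range")
  if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
          faces[, 2] == faces[, 3]))
    stop("surface_mesh: degenerate face (repeated vertex index)")
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("Surface mesh:", nrow(x$vertices), "vertices,",
      nrow(x$faces), "faces\n")
  invisible(x)
}

#' Transform a surface mesh
#' @param mesh a \code{surface_mesh}.
#' @param t a \code{rigid_transform}.
#' @return The transformed \code{surface_mesh}.
#' @export
transform_mesh <- function(mesh, t) {
  stopifnot(inherits(mesh, "surface_mesh"))
  surface_mesh(apply_transform(t, mesh$vertices), mesh$faces)
}

# Nearest fixed vertex for each query point; brute force in chunks
# (meshes here are phantom scale, a few thousand vertices at most).
nearest_vertex <- function(query, ref) {
  n <- nrow(query)
  idx <- integer(n); d2 <- numeric(n)
  ref2 <- rowSums(ref^2)
  chunk <- max(1L, floor(2e6 / nrow(ref)))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    q <- query[s:e, , drop = FALSE]
    dd <- outer(rowSums(q^2), ref2, "+") - 2 * tcrossprod(q, ref)
    j <- max.col(-dd, ties.method = "first")
    idx[s:e] <- j
    d2[s:e] <- dd[cbind(seq_len(e - s + 1L), j)]
  }
  list(index = idx, dist2 = pmax(d2, 0))
}

#' Rigid surface registration by trimmed ICP
#'
#' Point-to-point iterative closest point with worst-pair trimming:
#' at each iteration every moving vertex is paired with its nearest
#' fixed vertex, the worst 10\% of pairs (by distance) are discarded,
#' and the rigid Kabsch fit of the remaining pairs updates the pose.
#' Trimming makes the fit robust to partial overlap (e.g. incompletely
#' segmented condyles). Deterministic given identical inputs.
#'
#' @param moving,fixed \code{surface_mesh} objects that overlap
#'   substantially under \code{init}.
#' @param init optional \code{rigid_transform} initial guess.
#' @param trim fraction of worst pairs discarded (default 0.1).
#' @param max_iter iteration cap (default 200).
#' @param tol convergence threshold on the rmsd change (mm, default 1e-6).
#' @return A \code{fit_result}: transform mapping moving onto fixed, and
#'   the final rms point-to-correspondence distance (mm) over kept pairs.
#' @export
register_surfaces_icp <- function(moving, fixed, init = NULL, trim = 0.1,
                                  max_iter = 200L, tol = 1e-6) {
  stopifnot(inherits(moving, "surface_mesh"), inherits(fixed, "surface_mesh"))
  src <- moving$vertices
  ref <- fixed$vertices
  # default initialization: align centroids (standard ICP practice;
  # removes any gross translation offset before iterating)
  tf <- if (is.null(init))
    rigid_transform(diag(3), colMeans(ref) - colMeans(src))
  else init
  stopifnot(inherits(tf, "rigid_transform"))
  n_keep <- max(4L, floor((1 - trim) * nrow(src)))
  if (n_keep < 4L || nrow(ref) < 4L)
    stop("register_surfaces_icp: fewer than 4 usable correspondences")
  prev <- Inf
  rmsd <- Inf
  for (it in seq_len(max_iter)) {
    cur <- apply_transform(tf, src)
    nn <- nearest_vertex(cur, ref)
    keep <- order(nn$dist2)[seq_len(n_keep)]
    fit <- kabsch(src[keep, , drop = FALSE],
                  ref[nn$index[keep], , drop = FALSE])
    tf <- fit$transform
    rmsd <- fit$rmsd
    if (abs(prev - rmsd) < tol) break
    prev <- rmsd
  }
  fit_result(tf, rmsd)
}
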