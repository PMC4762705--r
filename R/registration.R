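# Rigid intensity-based volume registration (voxel-based matching
# stand-in): multi-resolution normalized cross-correlation with
# trilinear resampling, optimized by Nelder-Mead. Fully deterministic.

#' Volume image
#'
#' A 3D scalar image with isotropic or per-axis voxel spacing. World
#' coordinates of voxel (i, j, k) (1-based) are
#' \code{origin + (c(i, j, k) - 1) * spacing}.
#'
#' @param data 3D numeric array of intensities (NA marks excluded voxels).
#' @param spacing voxel spacing in mm, scalar or length 3 (default 0.4).
#' @param origin world position of voxel (1,1,1), mm.
#' @return Object of class \code{volume_image}.
#' @export
volume_image <- function(data, spacing = 0.4, origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (any(dim(data) < 8L))
    stop("volume_image: dimensions must be >= 8 per axis")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("volume_image: spacing must be > 0")
  structure(list(data = data, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat("Volume image", paste(dim(x$data), collapse = " x "),
      "voxels, spacing", paste(format(x$spacing), collapse = "/"),
      "mm\n")
  invisible(x)
}

#' Region mask
#'
#' Boolean mask congruent with a \code{volume_image}; used to restrict a
#' registration metric to a subvolume unaffected by surgery (cranial
#' base).
#'
#' @param data 3D logical array.
#' @return Object of class \code{region_mask}.
#' @export
region_mask <- function(data) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  data <- array(as.logical(data), dim = dim(data))
  if (!any(data, na.rm = TRUE)) stop("region_mask: empty mask")
  structure(list(data = data), class = "region_mask")
}

#' Crop a volume to the bounding box of a mask
#'
#' Voxels inside the bounding box but outside the mask are set to NA so
#' that downstream metrics exclude them.
#'
#' @param volume a \code{volume_image}.
#' @param mask a \code{region_mask} of identical shape.
#' @return A \code{volume_image} covering the mask bounding box.
#' @export
crop_to_mask <- function(volume, mask) {
  stopifnot(inherits(volume, "volume_image"), inherits(mask, "region_mask"))
  if (!identical(dim(volume$data), dim(mask$data)))
    stop("crop_to_mask: mask shape does not match volume")
  idx <- which(mask$data, arr.ind = TRUE)
  lo <- unname(apply(idx, 2, min)); hi <- unname(apply(idx, 2, max))
  d <- volume$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  m <- mask$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  d[!m] <- NA_real_
  d <- array(d, dim = hi - lo + 1L)
  # note: crops below the 8-voxel floor are legitimate here
  out <- structure(list(data = d, spacing = volume$spacing,
                        origin = volume$origin + (lo - 1) * volume$spacing),
                   class = "volume_image")
  out
}

# World coordinates of every voxel center, n x 3 matrix (column-major
# voxel order, matching as.vector of the data array).
voxel_grid_world <- function(volume) {
  d <- dim(volume$data)
  i <- (seq_len(d[1]) - 1) * volume$spacing[1] + volume$origin[1]
  j <- (seq_len(d[2]) - 1) * volume$spacing[2] + volume$origin[2]
  k <- (seq_len(d[3]) - 1) * volume$spacing[3] + volume$origin[3]
  cbind(rep(i, times = d[2] * d[3]),
        rep(rep(j, each = d[1]), times = d[3]),
        rep(k, each = d[1] * d[2]))
}

# Trilinear interpolation of a volume at world points (n x 3). Points
# outside the volume (or touching NA voxels) return NA.
interp_trilinear <- function(volume, pts) {
  d <- dim(volume$data)
  x <- (pts[, 1] - volume$origin[1]) / volume$spacing[1] + 1
  y <- (pts[, 2] - volume$origin[2]) / volume$spacing[2] + 1
  z <- (pts[, 3] - volume$origin[3]) / volume$spacing[3] + 1
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  ok <- x0 >= 1 & x0 <= d[1] - 1 & y0 >= 1 & y0 <= d[2] - 1 &
    z0 >= 1 & z0 <= d[3] - 1
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  x0 <- x0[ok]; y0 <- y0[ok]; z0 <- z0[ok]
  fx <- x[ok] - x0; fy <- y[ok] - y0; fz <- z[ok] - z0
  v <- volume$data
  n1 <- d[1]; n12 <- d[1] * d[2]
  base <- (x0) + (y0 - 1) * n1 + (z0 - 1) * n12  # linear index of (x0,y0,z0)
  c000 <- v[base];            c100 <- v[base + 1]
  c010 <- v[base + n1];       c110 <- v[base + n1 + 1]
  c001 <- v[base + n12];      c101 <- v[base + n12 + 1]
  c011 <- v[base + n1 + n12]; c111 <- v[base + n1 + n12 + 1]
  out[ok] <-
    c000 * (1 - fx) * (1 - fy) * (1 - fz) + c100 * fx * (1 - fy) * (1 - fz) +
    c010 * (1 - fx) * fy * (1 - fz)       + c110 * fx * fy * (1 - fz) +
    c001 * (1 - fx) * (1 - fy) * fz       + c101 * fx * (1 - fy) * fz +
    c011 * (1 - fx) * fy * fz             + c111 * fx * fy * fz
  out
}

# Block-mean downsample by integer factor (1 = identity). NA-aware.
downsample_volume <- function(volume, factor) {
  if (factor == 1L) return(volume)
  d <- dim(volume$data)
  nd <- d %/% factor
  if (any(nd < 2L)) return(volume)
  crop <- volume$data[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                      seq_len(nd[3] * factor), drop = FALSE]
  a <- array(crop, dim = c(factor, nd[1], factor, nd[2], factor, nd[3]))
  m <- apply(a, c(2, 4, 6), mean)  # NA propagates: excluded blocks stay NA
  structure(list(data = m, spacing = volume$spacing * factor,
                 origin = volume$origin + (factor - 1) / 2 * volume$spacing),
            class = "volume_image")
}

downsample_mask <- function(mask, factor) {
  if (factor == 1L) return(mask)
  d <- dim(mask$data)
  nd <- d %/% factor
  if (any(nd < 2L)) return(mask)
  crop <- mask$data[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                    seq_len(nd[3] * factor), drop = FALSE]
  a <- array(crop, dim = c(factor, nd[1], factor, nd[2], factor, nd[3]))
  # inclusive at coarse levels: a block counts if any voxel is masked
  region_mask(apply(a, c(2, 4, 6), mean) > 0)
}

# Transform parameter vector (rx, ry, rz degrees, tx, ty, tz mm) to a
# rigid transform rotating about `center`.
params_to_transform <- function(p, center) {
  r <- rot_z(p[3]) %*% rot_y(p[2]) %*% rot_x(p[1])
  rigid_transform(r, as.numeric(p[4:6]) + center - as.numeric(r %*% center))
}

#' Rigid intensity-based volume registration
#'
#' Multi-resolution (3 levels, downsampling factors 4/2/1) rigid
#' registration maximizing normalized cross-correlation (or minimizing
#' mean squared intensity difference) between the transformed moving
#' volume and the fixed volume, with trilinear interpolation and a
#' deterministic Nelder-Mead optimizer. The returned transform maps
#' moving-volume world coordinates onto fixed-volume world coordinates
#' (i.e. it is the rigid motion of the imaged object from the moving to
#' the fixed state).
#'
#' @param moving,fixed \code{volume_image} objects.
#' @param mask optional \code{region_mask} congruent with \code{fixed};
#'   restricts the metric to that subvolume.
#' @param init optional \code{rigid_transform} initial guess (default
#'   identity).
#' @param metric \code{"ncc"} (default) or \code{"mse"}.
#' @param levels downsampling factors, coarse to fine.
#' @param maxit Nelder-Mead iteration caps per level (recycled).
#' @return A \code{fit_result}; \code{rmsd} is the root-mean-square
#'   residual of z-normalized intensities over the evaluated region (a
#'   unitless fit-quality figure).
#' @export
register_volumes_rigid <- function(moving, fixed, mask = NULL, init = NULL,
                                   metric = c("ncc", "mse"),
                                   levels = c(4L, 2L, 1L),
                                   maxit = c(400L, 300L, 300L)) {
  stopifnot(inherits(moving, "volume_image"), inherits(fixed, "volume_image"))
  metric <- match.arg(metric)
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "region_mask"))
    if (!identical(dim(mask$data), dim(fixed$data)))
      stop("register_volumes_rigid: mask shape does not match fixed volume")
  }
  maxit <- rep_len(as.integer(maxit), length(levels))

  center <- fixed$origin + (dim(fixed$data) - 1) / 2 * fixed$spacing
  # initial parameters from init (decompose about `center`)
  p <- c(0, 0, 0, 0, 0, 0)
  if (!is.null(init)) {
    stopifnot(inherits(init, "rigid_transform"))
    rf <- init$rotation
    roll <- asin(max(-1, min(1, -rf[3, 1]))) * 180 / pi
    p <- c(atan2(rf[3, 2], rf[3, 3]) * 180 / pi, roll,
           atan2(rf[2, 1], rf[1, 1]) * 180 / pi,
           apply_transform(init, center) - center)
  }

  for (li in seq_along(levels)) {
    f <- as.integer(levels[li])
    fx <- downsample_volume(fixed, f)
    mv <- downsample_volume(moving, f)
    mk <- if (!is.null(mask)) downsample_mask(mask, f) else NULL
    grid <- voxel_grid_world(fx)
    fvals <- as.vector(fx$data)
    keep <- is.finite(fvals)
    if (!is.null(mk)) keep <- keep & as.vector(mk$data)
    if (sum(keep) < 32L)
      stop("register_volumes_rigid: too few usable voxels in metric region")
    grid <- grid[keep, , drop = FALSE]
    fvals <- fvals[keep]

    cost <- function(q) {
      tf <- params_to_transform(q, center)
      mvals <- interp_trilinear(mv, apply_transform(invert(tf), grid))
      ok <- is.finite(mvals)
      if (sum(ok) < max(32, 0.25 * length(mvals))) return(1e6)
      if (metric == "ncc") {
        s <- stats::sd(mvals[ok])
        if (s < 1e-12) return(1e6)
        1 - stats::cor(mvals[ok], fvals[ok])
      } else {
        a <- mvals[ok]; b <- fvals[ok]
        mean(((a - mean(a)) / max(stats::sd(a), 1e-12) -
              (b - mean(b)) / max(stats::sd(b), 1e-12))^2)
      }
    }
    if (li == 1L) {
      # capture-range initializer: deterministic grid search over
      # translations at the coarsest level
      offsets <- as.matrix(expand.grid(tx = seq(-6, 6, by = 2),
                                       ty = seq(-6, 6, by = 2),
                                       tz = seq(-6, 6, by = 2)))
      vals <- apply(offsets, 1, function(o) cost(p + c(0, 0, 0, o)))
      best <- which.min(vals)
      if (vals[best] < cost(p)) p <- p + c(0, 0, 0, offsets[best, ])
    }
    # Nelder-Mead with a restart to rebuild a fresh simplex
    ctrl <- list(maxit = maxit[li], reltol = 1e-10,
                 parscale = c(4, 4, 4, 2, 2, 2))
    opt <- stats::optim(p, cost, method = "Nelder-Mead", control = ctrl)
    opt <- stats::optim(opt$par, cost, method = "Nelder-Mead", control = ctrl)
    p <- opt$par
    if (f == 1L && opt$value >= 1e6)
      stop("register_volumes_rigid: no usable overlap between volumes ",
           "(metric undefined at optimum; check initialization)")
  }

  tf <- params_to_transform(p, center)
  # fit quality at full resolution
  grid <- voxel_grid_world(fixed)
  fvals <- as.vector(fixed$data)
  keep <- is.finite(fvals)
  if (!is.null(mask)) keep <- keep & as.vector(mask$data)
  grid <- grid[keep, , drop = FALSE]; fvals <- fvals[keep]
  mvals <- interp_trilinear(moving, apply_transform(invert(tf), grid))
  ok <- is.finite(mvals)
  zs <- function(v) (v - mean(v)) / max(stats::sd(v), 1e-12)
  rmsd <- sqrt(mean((zs(mvals[ok]) - zs(fvals[ok]))^2))
  fit_result(tf, rmsd)
}
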