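# Observer-reliability statistics: intra/inter-observer variation with
# bootstrap CIs, and two-way random-effects absolute-agreement
# single-measures ICC with F-distribution CIs.

#' Measurement grid
#'
#' Values indexed by (patient, session, component). Sessions are
#' repeated analyses of the same patients (e.g. observer1_t1,
#' observer1_t2, observer2); components are the reported movement
#' quantities.
#'
#' @param values 3D numeric array (patients x sessions x components),
#'   with dimnames, or a long data frame with columns \code{case_id,
#'   session, component, value}.
#' @return Object of class \code{measurement_grid} (the named array).
#' @export
measurement_grid <- function(values) {
  if (is.data.frame(values)) {
    need <- c("case_id", "session", "component", "value")
    stopifnot(all(need %in% names(values)))
    pats <- unique(as.character(values$case_id))
    sess <- unique(as.character(values$session))
    comp <- unique(as.character(values$component))
    arr <- array(NA_real_, dim = c(length(pats), length(sess), length(comp)),
                 dimnames = list(patient = pats, session = sess,
                                 component = comp))
    idx <- cbind(match(as.character(values$case_id), pats),
                 match(as.character(values$session), sess),
                 match(as.character(values$component), comp))
    if (anyDuplicated(idx))
      stop("measurement_grid: duplicate (patient, session, component) cell")
    arr[idx] <- values$value
    values <- arr
  }
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (dim(values)[1] < 2L) stop("measurement_grid: need >= 2 patients")
  if (dim(values)[2] < 2L) stop("measurement_grid: need >= 2 sessions")
  if (is.null(dimnames(values)))
    dimnames(values) <- list(patient = paste0("p", seq_len(dim(values)[1])),
                             session = paste0("s", seq_len(dim(values)[2])),
                             component = paste0("c", seq_len(dim(values)[3])))
  structure(values, class = "measurement_grid")
}

grid_sessions <- function(grid) dimnames(grid)[[2]]

#' Observer variation between two sessions
#'
#' Per component, the mean over patients of the absolute difference
#' between the two sessions' values, with a percentile-bootstrap 95\%
#' confidence interval over patients (the CI method for these
#' repeated-measure variations is a package choice; it is
#' assumption-light at small n).
#'
#' @param grid a \code{measurement_grid} with complete cells for both
#'   sessions.
#' @param session_a,session_b session names.
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed RNG seed for the bootstrap (default 1).
#' @param conf confidence level (default 0.95).
#' @return Data frame (class \code{reliability_result}) with columns
#'   \code{component, value, ci_low, ci_high}; units are those of the
#'   component (mm or degrees).
#' @export
observer_variation <- function(grid, session_a, session_b,
                               n_boot = 10000L, seed = 1L, conf = 0.95) {
  stopifnot(inherits(grid, "measurement_grid"))
  sess <- grid_sessions(grid)
  if (!all(c(session_a, session_b) %in% sess))
    stop("observer_variation: unknown session; available: ",
         paste(sess, collapse = ", "))
  a <- grid[, session_a, , drop = FALSE]
  b <- grid[, session_b, , drop = FALSE]
  n <- dim(grid)[1]
  if (n < 2L) stop("observer_variation: need >= 2 patients")
  d <- abs(a - b)[, 1, , drop = TRUE]  # patients x components
  d <- matrix(d, nrow = n)
  if (anyNA(d)) stop("observer_variation: missing cells (no imputation)")
  set.seed(seed)
  bidx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  alpha <- (1 - conf) / 2
  out <- data.frame(component = dimnames(grid)[[3]],
                    value = colMeans(d), ci_low = NA_real_,
                    ci_high = NA_real_, row.names = NULL)
  for (j in seq_len(ncol(d))) {
    bm <- rowMeans(matrix(d[bidx, j], nrow = n_boot))
    q <- stats::quantile(bm, c(alpha, 1 - alpha), names = FALSE, type = 7)
    out$ci_low[j] <- q[1]; out$ci_high[j] <- q[2]
  }
  class(out) <- c("reliability_result", "data.frame")
  out
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measures ICC
#' computed from the ANOVA mean squares, with the 95\% confidence
#' interval from the F-distribution (McGraw-Wong). The absolute-
#' agreement form is used because sessions measure the same physical
#' quantity and systematic between-session offsets must count as
#' disagreement.
#'
#' @param grid a \code{measurement_grid}.
#' @param sessions session names to include (default: all; >= 2
#'   required, >= 3 patients).
#' @param conf confidence level (default 0.95).
#' @return Data frame (class \code{reliability_result}) with columns
#'   \code{component, value, ci_low, ci_high}.
#' @export
icc <- function(grid, sessions = NULL, conf = 0.95) {
  stopifnot(inherits(grid, "measurement_grid"))
  if (is.null(sessions)) sessions <- grid_sessions(grid)
  if (!all(sessions %in% grid_sessions(grid)))
    stop("icc: unknown session name")
  if (length(sessions) < 2L) stop("icc: need >= 2 sessions")
  n <- dim(grid)[1]
  if (n < 3L) stop("icc: need >= 3 patients")
  comps <- dimnames(grid)[[3]]
  out <- data.frame(component = comps, value = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_, row.names = NULL)
  for (ci in seq_along(comps)) {
    y <- matrix(grid[, sessions, ci], nrow = n)  # patients x raters
    if (anyNA(y)) stop("icc: missing cells (no imputation)")
    ms <- icc_mean_squares(y)
    scale2 <- max(mean((y - mean(y))^2), .Machine$double.eps)
    if (stats::var(rowMeans(y)) <= 1e-12 * scale2)
      stop("icc: zero between-patient variance for component '",
           comps[ci], "'; ICC undefined")
    k <- length(sessions)
    val <- (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
    if (!is.finite(val))
      stop("icc: ICC undefined for component '", comps[ci],
           "' (zero total variance)")
    cint <- icc_a1_ci(ms, n, k, val, conf)
    out$value[ci] <- val
    out$ci_low[ci] <- cint[1]; out$ci_high[ci] <- cint[2]
  }
  class(out) <- c("reliability_result", "data.frame")
  out
}

# Two-way ANOVA mean squares for an n x k complete grid.
icc_mean_squares <- function(y) {
  n <- nrow(y); k <- ncol(y)
  gm <- mean(y)
  rm_ <- rowMeans(y); cm <- colMeans(y)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sst <- sum((y - gm)^2)
  sse <- sst - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)))
}

# McGraw-Wong confidence interval for ICC(A,1).
icc_a1_ci <- function(ms, n, k, icc_val, conf) {
  alpha <- 1 - conf
  a <- k * icc_val / (n * (1 - icc_val))
  b <- 1 + k * icc_val * (n - 1) / (n * (1 - icc_val))
  v <- (a * ms$msc + b * ms$mse)^2 /
    ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (ms$msr - f_l * ms$mse) /
    (f_l * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
  hi <- n * (f_u * ms$msr - ms$mse) /
    (k * ms$msc + (k * n - k - n) * ms$mse + n * f_u * ms$msr)
  c(max(-1, lo), min(1, hi))
}
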