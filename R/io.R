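# Delimited-text I/O for landmarks, planning transforms, measurement
# grids and result reports.

# Parse numbers accepting decimal commas ("0,26"); warns once per call.
parse_numeric_field <- function(x, what = "value") {
  x <- as.character(x)
  has_comma <- grepl(",", x, fixed = TRUE)
  if (any(has_comma)) {
    warning("decimal comma normalized to dot in ", sum(has_comma), " ",
            what, " field(s)", call. = FALSE)
    x <- gsub(",", ".", x, fixed = TRUE)
  }
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out) & !anyNA(x)) stop("non-numeric ", what, " field")
  out
}

#' Read landmark files
#'
#' Tab- or comma-delimited text with header columns \code{case_id,
#' state, name, side, x, y, z} (side empty for midline landmarks).
#' Landmark names are validated against the cephalometric vocabulary
#' (case-insensitive; short synonyms such as "UI" or "Go" are
#' accepted). Decimal commas in coordinates are normalized to dots with
#' a warning. Units are mm.
#'
#' @param path input file.
#' @return Named list: per case, per state, a
#'   \code{\link{landmark_set}}.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("read_landmarks: no such file: ", path)
  sep <- if (grepl("\\.csv$", tolower(path))) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", strip.white = TRUE)
  need <- c("case_id", "state", "name", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("read_landmarks: missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$side)) df$side <- ""
  df$key <- mapply(normalize_landmark_name, df$name, df$side)
  df$state <- tolower(df$state)
  bad <- setdiff(unique(df$state), STATE_LABELS)
  if (length(bad) > 0)
    stop("read_landmarks: unknown state label(s): ",
         paste(bad, collapse = ", "))
  dup <- duplicated(df[, c("case_id", "state", "key")])
  if (any(dup))
    stop("read_landmarks: duplicate (name, side, state) entries: ",
         paste(unique(df$key[dup]), collapse = ", "))
  for (v in c("x", "y", "z"))
    df[[v]] <- parse_numeric_field(df[[v]], paste("coordinate", v))
  out <- list()
  for (cid in unique(df$case_id)) {
    out[[cid]] <- list()
    for (st in unique(df$state[df$case_id == cid])) {
      sub <- df[df$case_id == cid & df$state == st, ]
      pts <- lapply(seq_len(nrow(sub)), function(i)
        c(sub$x[i], sub$y[i], sub$z[i]))
      names(pts) <- sub$key
      out[[cid]][[st]] <- landmark_set(pts)
    }
  }
  out
}

#' Write landmark sets to delimited text
#'
#' @param landmarks a \code{landmark_set}, or nested list as returned by
#'   \code{\link{read_landmarks}} (per case, per state).
#' @param path output path (.tsv or .csv).
#' @param case_id,state used when a bare \code{landmark_set} is given.
#' @export
write_landmarks <- function(landmarks, path, case_id = "case1",
                            state = "preop") {
  if (inherits(landmarks, "landmark_set"))
    landmarks <- stats::setNames(list(stats::setNames(list(landmarks), state)),
                                 case_id)
  rows <- list()
  for (cid in names(landmarks)) for (st in names(landmarks[[cid]])) {
    lm <- landmarks[[cid]][[st]]
    for (nm in names(lm)) {
      side <- ""
      base <- nm
      if (grepl("_(left|right)$", nm) &&
          sub("_(left|right)$", "", nm) %in% BILATERAL_LANDMARKS) {
        side <- sub("^.*_", "", nm)
        base <- sub("_(left|right)$", "", nm)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = cid, state = st, name = base, side = side,
        x = lm[[nm]][1], y = lm[[nm]][2], z = lm[[nm]][3])
    }
  }
  df <- do.call(rbind, rows)
  sep <- if (grepl("\\.csv$", tolower(path))) "," else "\t"
  utils::write.table(format(df, digits = 12, trim = TRUE), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read planning transforms
#'
#' Structured text: blocks of \code{segment: <id>} followed by four
#' lines of four numbers (a row-major 4x4 homogeneous matrix). The
#' upper-left 3x3 block must be a proper rotation.
#'
#' @param path input file.
#' @return Named list of \code{rigid_transform} by segment.
#' @export
read_planning_transforms <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^segment\\s*:", lines[i]))
      stop("read_planning_transforms: expected 'segment: <id>' at line ", i)
    seg <- match.arg(trimws(sub("^segment\\s*:", "", lines[i])), SEGMENT_IDS)
    if (i + 4L > length(lines))
      stop("read_planning_transforms: truncated matrix for ", seg)
    m <- do.call(rbind, lapply(lines[(i + 1L):(i + 4L)], function(l)
      parse_numeric_field(strsplit(l, "[\\s,;]+", perl = TRUE)[[1]],
                          "matrix")))
    if (!identical(dim(m), c(4L, 4L)) ||
        max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-9)
      stop("read_planning_transforms: invalid 4x4 matrix for ", seg)
    out[[seg]] <- rigid_transform(m[1:3, 1:3], m[1:3, 4])
    i <- i + 5L
  }
  out
}

#' Write planning transforms
#' @param transforms named list of \code{rigid_transform} by segment.
#' @param path output file.
#' @export
write_planning_transforms <- function(transforms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (seg in names(transforms)) {
    tf <- transforms[[seg]]
    m <- rbind(cbind(tf$rotation, tf$translation), c(0, 0, 0, 1))
    writeLines(paste0("segment: ", seg), con)
    for (r in 1:4)
      writeLines(paste(sprintf("%.15g", m[r, ]), collapse = " "), con)
  }
  invisible(path)
}

#' Read a measurement grid from delimited text
#'
#' Columns: \code{case_id, session, component, value}.
#'
#' @param path input file (.tsv or .csv).
#' @return A \code{\link{measurement_grid}}.
#' @export
read_measurement_grid <- function(path) {
  sep <- if (grepl("\\.csv$", tolower(path))) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", strip.white = TRUE)
  df$value <- parse_numeric_field(df$value, "value")
  measurement_grid(df)
}

#' Analysis configuration
#'
#' Bundles the run parameters that are recorded in every report for
#' reproducibility.
#'
#' @param mode \code{"direct"} or \code{"registration"}.
#' @param decimals printed decimals for mm/degree tables.
#' @param metric volume-registration similarity metric.
#' @param icc_variant label of the ICC form computed.
#' @param n_boot bootstrap resamples for variation CIs.
#' @param seed RNG seed recorded in outputs.
#' @return Object of class \code{analysis_config}.
#' @export
analysis_config <- function(mode = "direct", decimals = 2L, metric = "ncc",
                            icc_variant = "ICC(2,1) absolute agreement",
                            n_boot = 10000L, seed = 1L) {
  structure(list(mode = match.arg(mode, c("direct", "registration")),
                 decimals = as.integer(decimals), metric = metric,
                 icc_variant = icc_variant, n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "analysis_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(unclass(config), file = tmp)
  unname(tools::md5sum(tmp))
}

#' Write an analysis report
#'
#' Writes per-case movement tables and the cohort summary as delimited
#' text in the clinical column order (Translation AP, LR, UD, Pitch,
#' Roll, Yaw), values rounded half-up to the configured number of
#' decimals, preceded by a run-metadata block (package version, config
#' hash, seed). Two runs on identical inputs produce byte-identical
#' files.
#'
#' @param results list of \code{case_result}.
#' @param path output file.
#' @param config an \code{\link{analysis_config}}.
#' @return The path, invisibly.
#' @export
write_report <- function(results, path, config = analysis_config()) {
  if (length(results) == 0) stop("write_report: empty results")
  for (r in results) stopifnot(inherits(r, "case_result"))
  dec <- config$decimals
  fmt <- function(x) sprintf(paste0("%.", dec, "f"), round_half_up(x, dec))
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("gnathometry"))
  writeLines(c("# gnathometry report",
               paste0("# package_version: ", ver),
               paste0("# mode: ", config$mode),
               paste0("# seed: ", config$seed),
               paste0("# config_md5: ", config_hash(config)),
               ""), con)
  header <- paste(c("case_id", "segment", "kind", "Translation AP",
                    "Translation LR", "Translation UD", "Pitch", "Roll",
                    "Yaw"), collapse = "\t")
  writeLines(header, con)
  per_seg <- list()
  for (res in results) {
    for (kind in c("accuracy", "displacement")) {
      for (seg in names(res[[kind]])) {
        r <- res[[kind]][[seg]]
        writeLines(paste(c(res$case_id, seg, kind,
                           fmt(c(r$d_ap, r$d_lr, r$d_ud,
                                 r$pitch, r$roll, r$yaw))),
                         collapse = "\t"), con)
        if (kind == "accuracy")
          per_seg[[seg]] <- c(per_seg[[seg]], list(r))
      }
    }
    for (side in names(res$proximal)) {
      p <- res$proximal[[side]]
      writeLines(paste(c(res$case_id, paste0("proximal_", side), "proximal",
                         "", "", "", fmt(p$autorotation), "",
                         fmt(p$flare)), collapse = "\t"), con)
    }
  }
  writeLines(c("", "# cohort summary (accuracy, planned -> postop)"), con)
  writeLines(paste(c("segment", "statistic", "Translation AP",
                     "Translation LR", "Translation UD", "Pitch", "Roll",
                     "Yaw"), collapse = "\t"), con)
  for (seg in names(per_seg)) {
    s <- summarize_cohort(per_seg[[seg]])
    writeLines(paste(c(seg, "mean", fmt(s$mean)), collapse = "\t"), con)
    writeLines(paste(c(seg, "absolute_mean", fmt(s$abs_mean)),
                     collapse = "\t"), con)
  }
  invisible(path)
}
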