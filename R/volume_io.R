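# Volume I/O: NIfTI through RNifti; MetaImage (.mhd/.mha) implemented
# directly (ASCII header + little-endian raw block).

#' Write a volume image (NIfTI or MetaImage, by extension)
#'
#' \code{.nii}/\code{.nii.gz} go through RNifti; \code{.mhd} writes an
#' ASCII header plus a sibling \code{.raw} file; \code{.mha} writes a
#' single file with the raw block appended after the header.
#'
#' @param volume a \code{volume_image}.
#' @param path output path.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_image"))
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    img <- RNifti::asNifti(volume$data)
    img <- RNifti::`pixdim<-`(img, volume$spacing)
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  if (grepl("\\.mhd$", lp) || grepl("\\.mha$", lp)) {
    local_data <- grepl("\\.mha$", lp)
    d <- dim(volume$data)
    raw_name <- if (local_data) "LOCAL"
                else paste0(tools::file_path_sans_ext(basename(path)), ".raw")
    hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
             "BinaryDataByteOrderMSB = False", "CompressedData = False",
             "TransformMatrix = 1 0 0 0 1 0 0 0 1",
             paste("Offset =", paste(format(volume$origin), collapse = " ")),
             "CenterOfRotation = 0 0 0",
             paste("ElementSpacing =",
                   paste(format(volume$spacing), collapse = " ")),
             paste("DimSize =", paste(d, collapse = " ")),
             "ElementType = MET_DOUBLE",
             paste("ElementDataFile =", raw_name))
    con <- file(path, "wb")
    writeLines(hdr, con)
    if (local_data) {
      writeBin(as.vector(volume$data), con, size = 8, endian = "little")
      close(con)
    } else {
      close(con)
      rcon <- file(file.path(dirname(path), raw_name), "wb")
      writeBin(as.vector(volume$data), rcon, size = 8, endian = "little")
      close(rcon)
    }
    return(invisible(path))
  }
  stop("write_volume: unsupported extension for '", path, "'")
}

#' Read a volume image (NIfTI or MetaImage, by extension)
#' @param path a \code{.nii}, \code{.nii.gz}, \code{.mhd} or \code{.mha}
#'   file.
#' @return A \code{volume_image}.
#' @export
read_volume <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    img <- RNifti::readNifti(path)
    sp <- attr(img, "pixdim")
    if (is.null(sp)) sp <- RNifti::pixdim(img)
    return(volume_image(array(as.numeric(img), dim = dim(img)),
                        spacing = sp[seq_len(3)]))
  }
  if (grepl("\\.mhd$", lp) || grepl("\\.mha$", lp)) {
    return(read_metaimage(path))
  }
  stop("read_volume: unsupported extension for '", path, "'")
}

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- character()
  repeat {
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (length(ln) == 0) stop("read_metaimage: missing ElementDataFile")
    hdr <- c(hdr, ln)
    if (grepl("^ElementDataFile", ln)) break
  }
  get <- function(key) {
    v <- grep(paste0("^", key, "\\s*="), hdr, value = TRUE)
    if (length(v) == 0) return(NULL)
    trimws(sub("^[^=]*=", "", v[1]))
  }
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing") %||% "1 1 1",
                                 "\\s+")[[1]])
  origin <- as.numeric(strsplit(get("Offset") %||% "0 0 0", "\\s+")[[1]])
  etype <- get("ElementType") %||% "MET_DOUBLE"
  datafile <- get("ElementDataFile")
  msb <- identical(toupper(get("BinaryDataByteOrderMSB") %||% "FALSE"), "TRUE")
  endian <- if (msb) "big" else "little"
  n <- prod(dims)
  spec <- switch(etype,
                 MET_DOUBLE = list(what = numeric(), size = 8),
                 MET_FLOAT = list(what = numeric(), size = 4),
                 MET_SHORT = list(what = integer(), size = 2),
                 MET_USHORT = list(what = integer(), size = 2),
                 MET_UCHAR = list(what = integer(), size = 1),
                 MET_CHAR = list(what = integer(), size = 1),
                 stop("read_metaimage: unsupported ElementType ", etype))
  signed <- !etype %in% c("MET_USHORT", "MET_UCHAR")
  if (identical(datafile, "LOCAL")) {
    vals <- readBin(con, spec$what, n = n, size = spec$size,
                    endian = endian, signed = signed)
  } else {
    rcon <- file(file.path(dirname(path), datafile), "rb")
    on.exit(close(rcon), add = TRUE)
    vals <- readBin(rcon, spec$what, n = n, size = spec$size,
                    endian = endian, signed = signed)
  }
  if (length(vals) != n) stop("read_metaimage: truncated data block")
  volume_image(array(as.numeric(vals), dim = dims),
               spacing = spacing, origin = origin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
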