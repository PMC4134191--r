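#' Read and write 3D volumes (NIfTI-1 and NRRD)
#'
#' `write_volume()` stores an [image_volume()] to disk; `read_volume()` loads
#' it back. Format is chosen from the file extension: `.nii` / `.nii.gz` for
#' NIfTI-1 (via the RNifti library; voxel spacing goes in `pixdim`, the
#' origin into the qform translation) and `.nrrd` for NRRD0004 (scalar 3D
#' payloads, `raw` or `ascii` encodings). Round trips preserve voxel values
#' bit-exactly (data are written as 64-bit floats) and spacing/origin to
#' better than 1e-6 mm. The intensity unit label is not representable in
#' either header, so `read_volume()` takes it as an argument.
#'
#' @param volume An `image_volume`.
#' @param path File path ending in `.nii`, `.nii.gz`, or `.nrrd`.
#' @param units Intensity unit label to attach on read.
#' @param encoding NRRD payload encoding, `"raw"` or `"ascii"`; ignored for
#'   NIfTI.
#' @return `read_volume()` returns an `image_volume`; `write_volume()`
#'   returns `path` invisibly.
#' @examples
#' vol <- image_volume(array(rnorm(4^3), c(4, 4, 4)), c(1, 1, 1))
#' f <- tempfile(fileext = ".nii.gz")
#' write_volume(vol, f)
#' identical(read_volume(f)$values, vol$values)
#' @export
write_volume <- function(volume, path, encoding = "raw") {
  stopifnot(inherits(volume, "image_volume") || inherits(volume, "roi_mask"))
  fmt <- guess_format(path)
  vals <- volume$values
  if (is.logical(vals)) vals <- array(as.numeric(vals), dim(vals))
  switch(fmt,
    nifti = {
      img <- RNifti::asNifti(vals)
      RNifti::`pixdim<-`(img, volume$spacing_mm) -> img
      aff <- diag(c(volume$spacing_mm, 1))
      aff[1:3, 4] <- volume$origin_mm
      RNifti::`qform<-`(img, structure(aff, code = 2L)) -> img
      dt <- if (inherits(volume, "roi_mask")) "uint8" else "double"
      RNifti::writeNifti(img, path, datatype = dt)
    },
    nrrd = write_nrrd(vals, volume$spacing_mm, volume$origin_mm, path,
                      encoding = encoding,
                      type = if (inherits(volume, "roi_mask")) "uint8"
                             else "double")
  )
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, units = "arbitrary") {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  fmt <- guess_format(path)
  parsed <- switch(fmt,
    nifti = {
      img <- RNifti::readNifti(path)
      vals <- as.array(img)
      if (length(dim(vals)) != 3L) {
        abort(sprintf("Expected a 3D payload, got %dD: %s",
                      length(dim(vals)), path))
      }
      xf <- RNifti::xform(img)
      list(values = array(as.numeric(vals), dim(vals)),
           spacing_mm = RNifti::pixdim(img)[1:3],
           origin_mm = as.numeric(xf[1:3, 4]))
    },
    nrrd = read_nrrd(path)
  )
  image_volume(parsed$values, parsed$spacing_mm, parsed$origin_mm,
               units = units)
}

#' Read and write ROI masks
#'
#' Masks are stored as unsigned 8-bit 0/1 volumes in the same formats as
#' [write_volume()]. On read, any nonzero voxel is treated as in-mask (with a
#' warning if values other than 0/1 occur).
#'
#' @param mask An `roi_mask`.
#' @param path File path (`.nii`, `.nii.gz`, or `.nrrd`).
#' @param role Role tag to attach on read; see [roi_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  write_volume(mask, path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, role = "ground_truth") {
  vol <- read_volume(path)
  roi_mask(vol$values, vol$spacing_mm, vol$origin_mm, role = role)
}

guess_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return("nrrd")
  abort(sprintf(
    "Unrecognized volume format for '%s' (supported: .nii, .nii.gz, .nrrd).",
    path))
}

# --- minimal NRRD0004 support (3D scalar, raw/ascii, little-endian) --------
# No NRRD reader exists on CRAN/Bioconductor for plain R; the format's header
# is line-oriented text, so a focused implementation is small and auditable.

nrrd_types <- c(double = "double", float = "float", uint8 = "uchar")

write_nrrd <- function(values, spacing_mm, origin_mm, path,
                       encoding = c("raw", "ascii"), type = "double") {
  encoding <- match.arg(encoding)
  stopifnot(type %in% names(nrrd_types))
  header <- c(
    "NRRD0004",
    "# 3D scalar volume",
    sprintf("type: %s", nrrd_types[[type]]),
    "dimension: 3",
    sprintf("sizes: %s", paste(dim(values), collapse = " ")),
    sprintf("encoding: %s", encoding),
    "endian: little",
    "space dimension: 3",
    sprintf("space origin: (%s)", paste(format(origin_mm, digits = 17),
                                        collapse = ",")),
    sprintf("spacings: %s", paste(format(spacing_mm, digits = 17),
                                  collapse = " ")),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  flat <- as.vector(values)
  if (encoding == "ascii") {
    writeLines(paste(format(flat, digits = 17), collapse = " "), con)
  } else if (type == "uint8") {
    writeBin(as.integer(flat), con, size = 1L, endian = "little")
  } else if (type == "float") {
    writeBin(as.numeric(flat), con, size = 4L, endian = "little")
  } else {
    writeBin(as.numeric(flat), con, size = 8L, endian = "little")
  }
  invisible(path)
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000[1-5]$", magic)) {
    abort(sprintf("Not an NRRD file (bad magic '%s'): %s", magic, path))
  }
  fields <- list()
  repeat {
    line <- read_header_line(con)
    if (is.null(line)) abort(sprintf("Truncated NRRD header: %s", path))
    if (line == "") break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) abort(sprintf("Malformed NRRD header line: '%s'", line))
    fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  dims <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (is.null(fields[["dimension"]]) || fields[["dimension"]] != "3" ||
      length(dims) != 3L) {
    abort(sprintf("Only 3D NRRD payloads are supported: %s", path))
  }
  type <- fields[["type"]] %||% "double"
  encoding <- fields[["encoding"]] %||% "raw"
  n <- prod(dims)
  flat <- if (encoding == "ascii") {
    as.numeric(scan(con, what = double(), n = n, quiet = TRUE))
  } else if (encoding == "raw") {
    endian <- fields[["endian"]] %||% "little"
    switch(type,
      uchar = as.numeric(readBin(con, "integer", n = n, size = 1L,
                                 signed = FALSE, endian = endian)),
      float = readBin(con, "numeric", n = n, size = 4L, endian = endian),
      double = readBin(con, "numeric", n = n, size = 8L, endian = endian),
      abort(sprintf("Unsupported NRRD type '%s'.", type)))
  } else {
    abort(sprintf("Unsupported NRRD encoding '%s'.", encoding))
  }
  if (length(flat) != n) abort(sprintf("Truncated NRRD payload: %s", path))
  spacing <- if (!is.null(fields[["spacings"]])) {
    as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    dirs <- fields[["space directions"]]
    vecs <- regmatches(dirs, gregexpr("\\(([^)]*)\\)", dirs))[[1]]
    vapply(seq_along(vecs), function(i) {
      v <- as.numeric(strsplit(gsub("[()]", "", vecs[i]), ",")[[1]])
      sqrt(sum(v^2))
    }, numeric(1))
  } else {
    c(1, 1, 1)
  }
  origin <- if (!is.null(fields[["space origin"]])) {
    as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]), ",")[[1]])
  } else {
    c(0, 0, 0)
  }
  list(values = array(flat, dims), spacing_mm = spacing, origin_mm = origin)
}

# readLines on a binary connection stops at \n; keep header reading byte-safe.
read_header_line <- function(con) {
  bytes <- raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L) return(if (length(bytes)) rawToChar(bytes) else NULL)
    if (b == as.raw(10L)) return(rawToChar(bytes))
    if (b != as.raw(13L)) bytes <- c(bytes, b)
  }
}
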