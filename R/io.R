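#' Diffusion-weighted dataset container
#'
#' A 4D signal array with its gradient table and voxel mask. Gradient
#' directions of diffusion-weighted volumes must be unit vectors; vectors
#' whose norm deviates by more than 1e-3 are re-normalized with a warning,
#' larger deviations are rejected.
#'
#' @param data 4D array (x, y, z, volume) of magnitude signals.
#' @param bvals numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs 3 x n matrix of gradient directions (FSL convention);
#'   an n x 3 matrix is transposed automatically.
#' @param mask logical 3D array; default: voxels with any positive signal.
#' @param b0_max b-values at or below this count as b=0.
#' @return a `dwi_dataset` object.
#' @export
dwi_dataset <- function(data, bvals, bvecs, mask = NULL, b0_max = 50) {
  dm <- dim(data)
  if (length(dm) != 4L) stop("data must be a 4D array", call. = FALSE)
  if (length(bvals) != dm[4])
    stop("number of volumes (", dm[4], ") does not match bvals (",
         length(bvals), ")", call. = FALSE)
  if (any(bvals < 0)) stop("b-values must be >= 0", call. = FALSE)
  if (!is.matrix(bvecs)) bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) {
    message("bvecs given as n x 3; transposing to FSL 3 x n layout")
    bvecs <- t(bvecs)
  }
  if (nrow(bvecs) != 3L || ncol(bvecs) != dm[4])
    stop("bvecs must be 3 x n_volumes", call. = FALSE)
  dwv <- bvals > b0_max
  nrm <- sqrt(colSums(bvecs^2))
  bad <- dwv & abs(nrm - 1) > 1e-3
  if (any(nrm[dwv] < 0.5))
    stop("diffusion-weighted volumes must have non-zero unit gradient vectors",
         call. = FALSE)
  if (any(bad)) {
    warning(sum(bad), " gradient vector(s) re-normalized (|g| off by > 1e-3)")
    bvecs[, bad] <- sweep(bvecs[, bad, drop = FALSE], 2, nrm[bad], "/")
  } else if (any(dwv)) {
    bvecs[, dwv] <- sweep(bvecs[, dwv, drop = FALSE], 2, nrm[dwv], "/")
  }
  if (is.null(mask)) {
    mask <- array(rowSums(matrix(data, prod(dm[1:3]), dm[4])) > 0, dm[1:3])
  }
  structure(list(data = data, bvals = as.numeric(bvals), bvecs = bvecs,
                 mask = mask), class = "dwi_dataset")
}

# ---- minimal NIfTI-1 reader/writer -----------------------------------------
# Single-file .nii (optionally gzipped on read), little-endian, no extensions.
# No R NIfTI package is available in the target environment, so the fixed
# 348-byte NIfTI-1 header is read and written directly.

nifti_datatypes <- c("uint8" = 2L, "int16" = 4L, "int32" = 8L,
                     "float32" = 16L, "float64" = 64L)

#' Write a 3D/4D array as a NIfTI-1 file
#'
#' @param img numeric/integer array, 3 or 4 dimensions.
#' @param path output file name (`.nii`).
#' @param pixdim voxel sizes (mm), length 3.
#' @param datatype `"float32"` (default) or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, pixdim = c(1, 1, 1),
                        datatype = c("float32", "float64")) {
  datatype <- match.arg(datatype)
  dm <- dim(img)
  if (is.null(dm) || !length(dm) %in% c(3L, 4L))
    stop("img must be a 3D or 4D array", call. = FALSE)
  code <- nifti_datatypes[[datatype]]
  bitpix <- if (datatype == "float64") 64L else 32L
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wc <- function(s, n) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(n - length(raw))), con)
  }
  wi(348L, 4)                       # sizeof_hdr
  wc("", 10); wc("", 18)            # data_type, db_name (unused)
  wi(0L, 4); wi(0L, 2); wc("", 1); wc("", 1)  # extents, session_error, regular, dim_info
  dims <- c(length(dm), dm, rep(1L, 7 - length(dm)))
  wi(dims, 2)                       # dim[8]
  wf(c(0, 0, 0))                    # intent_p1-3
  wi(0L, 2)                         # intent_code
  wi(code, 2)                       # datatype
  wi(bitpix, 2)                     # bitpix
  wi(0L, 2)                         # slice_start
  wf(c(1, pixdim, rep(1, 7 - length(pixdim))))  # pixdim[8], qfac = 1
  wf(352)                           # vox_offset
  wf(1); wf(0)                      # scl_slope, scl_inter
  wi(0L, 2); wc("", 1); wc("", 1)   # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                 # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                  # glmax, glmin
  wc("t1aniso", 80)                 # descrip
  wc("", 24)                        # aux_file
  wi(0L, 2); wi(1L, 2)              # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0))           # quaternions b,c,d + offsets
  wf(c(pixdim[1], 0, 0, 0))         # srow_x
  wf(c(0, pixdim[2], 0, 0))         # srow_y
  wf(c(0, 0, pixdim[3], 0))         # srow_z
  wc("", 16)                        # intent_name
  wc("n+1", 4)                      # magic
  writeBin(raw(4), con)             # extension flag
  writeBin(as.double(img), con, size = if (datatype == "float64") 8 else 4,
           endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 file written by [write_nifti()] or compatible tools
#'
#' Supports single-file little-endian `.nii` (optionally gzip-compressed)
#' with common datatypes; applies the scaling slope/intercept. Attribute
#' `pixdim` carries the voxel sizes.
#'
#' @param path file name.
#' @return numeric array (3D or 4D) with attribute `pixdim`.
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size) readBin(con, "integer", n = n, size = size, endian = "little")
  rf <- function(n) readBin(con, "double", n = n, size = 4, endian = "little")
  hdr_size <- ri(1, 4)
  if (!identical(hdr_size, 348L))
    stop("unsupported NIfTI file (expected little-endian NIfTI-1)", call. = FALSE)
  readBin(con, "raw", n = 36)       # skip to dim
  dims <- ri(8, 2)
  rf(3); ri(1, 2)                   # intent_p1-3, intent_code
  dtype <- ri(1, 2)
  ri(1, 2); ri(1, 2)                # bitpix, slice_start
  pixdim <- rf(8)
  vox_offset <- rf(1)
  scl_slope <- rf(1); scl_inter <- rf(1)
  readBin(con, "raw", n = 348 - 120)
  ndim <- dims[1]
  dm <- dims[2:(1 + ndim)]
  n <- prod(dm)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  dat <- switch(as.character(dtype),
                "2" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE)),
                "4" = as.numeric(readBin(con, "integer", n = n, size = 2, endian = "little")),
                "8" = as.numeric(readBin(con, "integer", n = n, size = 4, endian = "little")),
                "16" = readBin(con, "double", n = n, size = 4, endian = "little"),
                "64" = readBin(con, "double", n = n, size = 8, endian = "little"),
                stop("unsupported NIfTI datatype code ", dtype, call. = FALSE))
  if (is.na(scl_slope) || scl_slope == 0) scl_slope <- 1
  if (is.na(scl_inter)) scl_inter <- 0
  dat <- dat * scl_slope + scl_inter
  out <- array(dat, dm)
  attr(out, "pixdim") <- pixdim[2:(1 + min(ndim, 3))]
  out
}

#' Read/write FSL-style bvals and bvecs tables
#'
#' `bvals` is one row of b-values; `bvecs` is three rows (x, y, z) of unit
#' direction components. A transposed n x 3 `bvecs` file is auto-detected
#' and transposed with a message.
#'
#' @param path file name.
#' @return `read_bvals`: numeric vector. `read_bvecs`: 3 x n matrix.
#' @export
read_bvals <- function(path) as.numeric(scan(path, quiet = TRUE))

#' @rdname read_bvals
#' @export
read_bvecs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1L) stop("ragged bvecs file", call. = FALSE)
  m <- do.call(rbind, rows)
  if (nrow(m) != 3L && ncol(m) == 3L) {
    message("bvecs stored as n x 3; transposing to FSL 3 x n layout")
    m <- t(m)
  }
  if (nrow(m) != 3L) stop("bvecs must have 3 rows (or 3 columns)", call. = FALSE)
  m
}

#' @rdname read_bvals
#' @param bvals,bvecs gradient table to write.
#' @export
write_bvals_bvecs <- function(bvals, bvecs, path) {
  writeLines(paste(format(bvals, trim = TRUE), collapse = " "),
             paste0(path, ".bval"))
  con <- file(paste0(path, ".bvec"), "w")
  on.exit(close(con))
  for (r in 1:3)
    writeLines(paste(format(bvecs[r, ], trim = TRUE, digits = 10),
                     collapse = " "), con)
  invisible(path)
}

#' Write / read a diffusion dataset as NIfTI + bval/bvec files
#' @param dwi a `dwi_dataset`.
#' @param prefix path prefix; writes `<prefix>.nii`, `<prefix>.bval`,
#'   `<prefix>.bvec`.
#' @return `read_dwi` returns a `dwi_dataset`.
#' @export
write_dwi <- function(dwi, prefix) {
  stopifnot(inherits(dwi, "dwi_dataset"))
  write_nifti(dwi$data, paste0(prefix, ".nii"))
  write_bvals_bvecs(dwi$bvals, dwi$bvecs, prefix)
  invisible(prefix)
}

#' @rdname write_dwi
#' @export
read_dwi <- function(prefix) {
  dat <- read_nifti(paste0(prefix, ".nii"))
  dwi_dataset(dat, read_bvals(paste0(prefix, ".bval")),
              read_bvecs(paste0(prefix, ".bvec")))
}
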