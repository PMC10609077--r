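# MRC2014 stack I/O, gain/dark correction, file-size prediction, and the
# JSON ground-truth sidecar. The writer emits little-endian files with a
# 1024-byte header and no extended header; the reader honours the machine
# stamp and tolerates extended headers.

.mrc_modes <- c(`0` = 1L, `1` = 2L, `2` = 4L, `6` = 2L)  # bytes per pixel

mrc_bytes_per_pixel <- function(mode) {
  b <- .mrc_modes[as.character(mode)]
  if (is.na(b)) stop(sprintf("unsupported MRC mode %s", mode))
  unname(b)
}

#' Predicted MRC file size
#'
#' `1024 + nx * ny * nz * bytes_per_pixel(mode)` bytes: the standard header
#' plus the raw data block (no extended header). A 32-bit float stack of
#' 11520 x 8184 x 70 comes to 24.58 GiB, the storage footprint of one
#' super-resolution K3 movie.
#'
#' @param nx,ny,nz stack dimensions (>= 1).
#' @param mode MRC data mode: 0 (int8), 1 (int16), 2 (float32), 6 (uint16).
#' @return file size in bytes.
#' @export
#' @examples
#' expected_file_size(11520, 8184, 70, mode = 2) / 2^30  # ~24.58 GiB
expected_file_size <- function(nx, ny, nz, mode = 2) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1)
  1024 + as.numeric(nx) * ny * nz * mrc_bytes_per_pixel(mode)
}

#' Write a frame stack as an MRC2014 file
#'
#' Standard MRC2014 layout: 1024-byte header, little-endian with machine
#' stamp, frames stored as z-slices with x the fast axis, pixel size
#' recorded in the cell dimensions. Integer modes reject values outside
#' their representable range.
#'
#' @param frames a [frame_stack()] or a numeric matrix/3-D array.
#' @param path output file path.
#' @param mode MRC data mode (default 2, 32-bit float).
#' @param pixel_size Angstrom per pixel; defaults to the stack's.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(frames, path, mode = 2, pixel_size = NULL) {
  if (inherits(frames, "frame_stack")) {
    if (is.null(pixel_size)) pixel_size <- frames$pixel_size
    data <- frames$data
  } else {
    if (is.null(pixel_size)) pixel_size <- 1
    data <- frames
  }
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3)
  bpp <- mrc_bytes_per_pixel(mode)
  d <- dim(data)
  v <- as.vector(data)
  range_ok <- switch(as.character(mode),
    `0` = all(v >= -128 & v <= 127),
    `1` = all(v >= -32768 & v <= 32767),
    `6` = all(v >= 0 & v <= 65535),
    TRUE)
  if (!isTRUE(range_ok)) {
    stop(sprintf("values outside the representable range of MRC mode %d", mode))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                                  # nx ny nz
  wi(mode)                               # mode
  wi(c(0, 0, 0))                         # nxstart nystart nzstart
  wi(d)                                  # mx my mz
  wf(d * pixel_size)                     # cella
  wf(c(90, 90, 90))                      # cellb
  wi(c(1, 2, 3))                         # mapc mapr maps
  wf(c(min(v), max(v), mean(v)))         # dmin dmax dmean
  wi(0)                                  # ispg
  wi(0)                                  # nsymbt (no extended header)
  wi(rep(0, 3))                          # extra words 25-27 (exttyp blank)
  wi(20140)                              # nversion (word 28)
  wi(rep(0, 21))                         # extra words 29-49
  wf(c(0, 0, 0))                         # origin x y z
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machine stamp (LE)
  wf(sd(v))                              # rms
  wi(1)                                  # nlabl
  lab <- formatC("cryophantom phantom movie stack", width = -80)
  writeChar(lab, con, nchars = 80, eos = NULL)
  writeBin(raw(9 * 80), con)             # remaining labels
  switch(as.character(mode),
    `0` = writeBin(as.integer(v), con, size = 1),
    `1` = writeBin(as.integer(v), con, size = 2, endian = "little"),
    `2` = writeBin(as.numeric(v), con, size = 4, endian = "little"),
    `6` = {
      # R's writeBin has no unsigned 16-bit type; wrap to the signed range.
      u <- as.integer(v)
      u[u > 32767] <- u[u > 32767] - 65536L
      writeBin(u, con, size = 2, endian = "little")
    })
  invisible(path)
}

#' Read an MRC file
#'
#' Parses the MRC2014 header (honouring the machine-stamp endianness),
#' validates it, and loads the data, promoting integer modes losslessly to
#' numeric.
#'
#' @param path path to an MRC file.
#' @return a [frame_stack()] with attribute `info`: a list with `nx`, `ny`,
#'   `nz`, `mode`, `pixel_size`, `header_bytes`.
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  fsize <- file.info(path)$size
  if (fsize < 1024) stop("malformed MRC: file shorter than the 1024-byte header")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 1024)

  machst <- hdr[213:216]
  endian <- if (machst[1] == as.raw(0x11)) "big" else "little"
  ri <- function(off, n = 1) {
    readBin(hdr[(off + 1):(off + 4 * n)], "integer", n = n, size = 4,
            endian = endian)
  }
  rf <- function(off, n = 1) {
    readBin(hdr[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4,
            endian = endian)
  }
  nx <- ri(0); ny <- ri(4); nz <- ri(8); mode <- ri(12)
  nsymbt <- ri(92)
  cella <- rf(40, 3)
  map_tag <- rawToChar(hdr[209:212])
  if (map_tag != "MAP ") stop("malformed MRC: bad MAP signature in header")
  if (!(as.character(mode) %in% names(.mrc_modes))) {
    stop(sprintf("malformed MRC: unsupported mode %d", mode))
  }
  if (nx < 1 || ny < 1 || nz < 1) {
    stop("malformed MRC: non-positive dimensions (nx/ny/nz)")
  }
  bpp <- mrc_bytes_per_pixel(mode)
  need <- 1024 + nsymbt + as.numeric(nx) * ny * nz * bpp
  if (fsize < need) {
    stop(sprintf("malformed MRC: file truncated (%d bytes, expected %.0f)",
                 fsize, need))
  }
  if (nsymbt > 0) readBin(con, "raw", n = nsymbt)
  n <- nx * ny * nz
  v <- switch(as.character(mode),
    `0` = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE)),
    `1` = as.numeric(readBin(con, "integer", n = n, size = 2, signed = TRUE,
                             endian = endian)),
    `2` = readBin(con, "numeric", n = n, size = 4, endian = endian),
    `6` = {
      u <- readBin(con, "integer", n = n, size = 2, signed = FALSE,
                   endian = endian)
      as.numeric(u)
    })
  pixel_size <- if (nx > 0 && cella[1] > 0) cella[1] / nx else 1
  fs <- frame_stack(array(v, c(nx, ny, nz)), pixel_size = pixel_size)
  attr(fs, "info") <- list(nx = nx, ny = ny, nz = nz, mode = mode,
                           pixel_size = pixel_size,
                           header_bytes = 1024 + nsymbt)
  fs
}

#' Gain/dark correction
#'
#' Per pixel and per frame: `corrected = (raw - dark) * gain`, the common
#' camera convention of multiplicative gain after dark subtraction.
#'
#' @param frames a [frame_stack()] or 3-D array.
#' @param gain,dark matrices at frame dimensions.
#' @return corrected frames (same class as the input).
#' @export
apply_gain_dark <- function(frames, gain, dark) {
  data <- if (inherits(frames, "frame_stack")) frames$data else frames
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  d <- dim(data)
  if (!all(dim(gain) == d[1:2]) || !all(dim(dark) == d[1:2])) {
    stop("gain/dark dimensions must equal frame dimensions")
  }
  out <- sweep(sweep(data, 1:2, dark, "-"), 1:2, gain, "*")
  if (inherits(frames, "frame_stack")) {
    frame_stack(out, pixel_size = frames$pixel_size)
  } else {
    out
  }
}

#' Write the ground-truth sidecar
#'
#' JSON sidecar with one record per frame (`frame_index`, `shift_x_px`,
#' `shift_y_px`, `k1`, `k2`), the frame `dims`, and the radius
#' `normalization` tag; written next to the MRC movie.
#'
#' @param truth a [motion_ground_truth()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "motion_ground_truth"))
  recs <- data.frame(frame_index = 0:(truth$n_frames - 1),
                     shift_x_px = truth$shifts[, 1],
                     shift_y_px = truth$shifts[, 2],
                     k1 = truth$k[, 1], k2 = truth$k[, 2])
  jsonlite::write_json(list(dims = truth$dims,
                            normalization = truth$normalization,
                            frames = recs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ground-truth sidecar
#'
#' @param path path to a JSON sidecar written by [write_ground_truth()].
#' @return a [motion_ground_truth()].
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("dims", "normalization", "frames")) {
    if (is.null(obj[[f]])) stop(sprintf("ground-truth sidecar missing field '%s'", f))
  }
  fr <- obj$frames
  for (f in c("frame_index", "shift_x_px", "shift_y_px", "k1", "k2")) {
    if (is.null(fr[[f]])) stop(sprintf("ground-truth sidecar missing field '%s'", f))
  }
  fr <- fr[order(fr$frame_index), ]
  tr <- motion_ground_truth(nrow(fr), obj$dims)
  tr$shifts <- cbind(x = fr$shift_x_px, y = fr$shift_y_px)
  tr$k <- cbind(k1 = fr$k1, k2 = fr$k2)
  tr$normalization <- obj$normalization
  tr
}
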