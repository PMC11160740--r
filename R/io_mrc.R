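# Minimal MRC/MRCS reader and writer (mode 2, float32, little-endian).
# Covers the subset of the format the tool touches: single 3D maps and
# image stacks with a correct voxel size in the header.

#' Write a volume or image stack to an MRC file
#'
#' @param map D x D x D real array (volume) or D x D x N (stack; set
#'   `is_stack = TRUE` to mark NZ as the stack axis).
#' @param pixel_size voxel size in Angstrom, written to the cell header.
#' @param path output file.
#' @param is_stack whether the third axis counts images, not z.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(map, pixel_size, path, is_stack = FALSE) {
  d <- dim(map)
  if (length(d) == 2L) { map <- array(map, dim = c(d, 1L)); d <- dim(map) }
  if (length(d) != 3L) stop("write_mrc expects a 3D array")
  if (!is_stack && length(unique(d)) != 1L)
    stop("write_mrc: volume must be cubic (use is_stack = TRUE for stacks)")
  if (any(!is.finite(map))) stop("write_mrc: refusing to write NaN/Inf voxels")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                                   # nx ny nz
  wi(2L)                                  # mode 2 = float32
  wi(c(0L, 0L, 0L))                       # nxstart
  wi(d)                                   # mx my mz
  wf(d * pixel_size)                      # cella
  wf(c(90, 90, 90))                       # cellb
  wi(c(1L, 2L, 3L))                       # mapc mapr maps
  wf(c(min(map), max(map), mean(map)))    # dmin dmax dmean
  wi(c(if (is_stack) 0L else 1L, 0L))     # ispg, nsymbt
  writeBin(raw(100), con)                 # extra
  wf(c(0, 0, 0))                          # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst (LE)
  wf(stats::sd(map))                      # rms
  wi(0L)                                  # nlabl
  writeBin(raw(800), con)                 # labels
  writeBin(as.numeric(map), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC/MRCS file
#'
#' @param path file path.
#' @return list with `data` (array, singleton third axis dropped for
#'   single images), `pixel_size`, `dims`, `is_stack`.
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("MRC file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2L) stop("read_mrc: only mode 2 (float32) is supported, got ",
                       mode)
  ri(3)               # nxstart
  mx <- ri(3)
  cella <- rf(3)
  rf(3)               # cellb
  ri(3)               # mapc/r/s
  rf(3)               # dmin dmax dmean
  ispg <- ri(1)
  nsymbt <- ri(1)
  seek(con, 1024 + nsymbt)
  vals <- readBin(con, "numeric", prod(d), size = 4, endian = "little")
  if (length(vals) != prod(d))
    stop("read_mrc: header promises ", prod(d), " voxels but file holds ",
         length(vals))
  px <- if (mx[1] > 0) cella[1] / mx[1] else 1
  list(data = array(vals, dim = d), pixel_size = px, dims = d,
       is_stack = ispg == 0L && d[3] > 1L && d[1] == d[2])
}

#' @rdname write_mrc
#' @param vol D^3 array.
#' @export
write_volume <- function(vol, pixel_size, path) {
  write_mrc(vol, pixel_size, path, is_stack = FALSE)
}
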