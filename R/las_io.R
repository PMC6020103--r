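#' Read an ASPRS LAS point cloud
#'
#' Minimal binary reader for uncompressed LAS (versions 1.1-1.4) with
#' point record formats 0-3: coordinates, the return-number / number-of-
#' returns bit field and the classification byte are decoded. Compressed
#' LAZ is not supported and raises an error (decompress externally first).
#'
#' @param path path to a `.las` file.
#' @return A [point_cloud()] with columns `x`, `y`, `z`,
#'   `number_of_returns`, `return_number`, `classification`.
#' @export
read_las <- function(path) {
  if (!file.exists(path)) stop("read_las: file not found: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 227) stop("read_las: truncated LAS header")
  if (rawToChar(raw[1:4]) != "LASF")
    stop("read_las: not a LAS file (bad signature)")

  u16 <- function(off) readBin(raw[off + 1:2], "integer", size = 2,
                               endian = "little", signed = FALSE)
  u32 <- function(off) {
    v <- readBin(raw[off + 1:4], "integer", size = 4, endian = "little")
    if (v < 0) v <- v + 2^32
    v
  }
  f64 <- function(off, n = 1) readBin(raw[off + 1:(8 * n)], "double",
                                      n = n, size = 8, endian = "little")

  ver_major <- as.integer(raw[25]); ver_minor <- as.integer(raw[26])
  offset_to_points <- u32(96)
  pdrf <- as.integer(raw[105])
  if (pdrf >= 128)
    stop("read_las: compressed LAZ data is not supported; ",
         "decompress to .las first")
  if (!pdrf %in% 0:3)
    stop("read_las: unsupported point data record format ", pdrf)
  rec_len <- u16(105)
  npts <- u32(107)
  if (ver_major == 1 && ver_minor == 4 && npts == 0) {
    # LAS 1.4 moves the count to a 64-bit header field
    npts <- sum(readBin(raw[247 + 1:8], "integer", size = 4,
                        endian = "little") * c(1, 2^32))
  }
  scale <- f64(131, 3)
  offs <- f64(155, 3)

  if (npts == 0)
    return(point_cloud(data.frame(x = numeric(0), y = numeric(0),
                                  z = numeric(0),
                                  number_of_returns = integer(0),
                                  return_number = integer(0),
                                  classification = integer(0))))

  need <- offset_to_points + npts * rec_len
  if (length(raw) < need) stop("read_las: truncated point data block")

  base <- offset_to_points + rec_len * (seq_len(npts) - 1)
  pull_i32 <- function(field_off) {
    idx <- rep(base, each = 4) + rep(field_off + 1:4, times = npts)
    readBin(raw[idx], "integer", n = npts, size = 4, endian = "little")
  }
  x <- pull_i32(0) * scale[1] + offs[1]
  y <- pull_i32(4) * scale[2] + offs[2]
  z <- pull_i32(8) * scale[3] + offs[3]
  flag <- as.integer(raw[base + 15])      # byte 14 (0-based): return bits
  cls <- as.integer(raw[base + 16])
  rn <- bitwAnd(flag, 7L)
  nr <- bitwAnd(bitwShiftR(flag, 3L), 7L)
  if (any(nr < 1))
    stop("read_las: NumberOfReturns field missing or zero for some points")

  point_cloud(data.frame(x = x, y = y, z = z,
                         number_of_returns = nr,
                         return_number = rn,
                         classification = cls))
}

#' Write a point cloud to LAS 1.2
#'
#' Writes point record format 0. Coordinates are quantized at `scale`
#' (default 0.01 m, i.e. centimetre resolution), so a write/read round
#' trip reproduces coordinates at that stored precision exactly.
#'
#' @param cloud a [point_cloud()]; `number_of_returns` must be populated.
#' @param path output path.
#' @param scale coordinate resolution in metres.
#' @return `path`, invisibly.
#' @export
write_las <- function(cloud, path, scale = 0.01) {
  n <- nrow(cloud)
  nr <- cloud$number_of_returns
  if (n && anyNA(nr))
    stop("write_las: number_of_returns must be populated")
  rn <- if ("return_number" %in% names(cloud) &&
            !anyNA(cloud$return_number)) cloud$return_number else pmin(nr, 1L)
  cls <- if ("classification" %in% names(cloud) &&
             !anyNA(cloud$classification)) cloud$classification else
    integer(n)

  offs <- if (n) c(floor(min(cloud$x)), floor(min(cloud$y)),
                   floor(min(cloud$z))) else c(0, 0, 0)
  mins <- if (n) c(min(cloud$x), min(cloud$y), min(cloud$z)) else c(0, 0, 0)
  maxs <- if (n) c(max(cloud$x), max(cloud$y), max(cloud$z)) else c(0, 0, 0)

  con <- file(path, "wb")
  on.exit(close(con))
  w8 <- function(v) writeBin(as.integer(v), con, size = 1)
  w16 <- function(v) writeBin(as.integer(v), con, size = 2,
                              endian = "little")
  w32 <- function(v) writeBin(as.integer(v), con, size = 4,
                              endian = "little")
  wf64 <- function(v) writeBin(as.double(v), con, size = 8,
                               endian = "little")
  pad <- function(s, width) {
    b <- charToRaw(s)
    writeBin(c(b, raw(width - length(b))), con)
  }

  writeChar("LASF", con, 4, eos = NULL)
  w16(0); w16(0)                      # source id, global encoding
  writeBin(raw(16), con)              # GUID
  w8(1); w8(2)                        # version 1.2
  pad("urbancanopy", 32)
  pad("urbancanopy R package", 32)
  w16(1); w16(2026)                   # day/year of creation
  w16(227)                            # header size
  w32(227)                            # offset to point data
  w32(0)                              # number of VLRs
  w8(0)                               # point data record format 0
  w16(20)                             # record length
  w32(n)
  by_return <- tabulate(pmin(rn, 5L), nbins = 5)
  w32(by_return)
  wf64(c(scale, scale, scale))
  wf64(offs)
  wf64(c(maxs[1], mins[1], maxs[2], mins[2], maxs[3], mins[3]))

  if (n) {
    xi <- as.integer(round((cloud$x - offs[1]) / scale))
    yi <- as.integer(round((cloud$y - offs[2]) / scale))
    zi <- as.integer(round((cloud$z - offs[3]) / scale))
    flag <- bitwOr(bitwAnd(as.integer(rn), 7L),
                   bitwShiftL(bitwAnd(as.integer(nr), 7L), 3L))
    rec <- matrix(as.raw(0), nrow = 20, ncol = n)
    rec[1:4, ] <- matrix(writeBin(xi, raw(), size = 4, endian = "little"), 4)
    rec[5:8, ] <- matrix(writeBin(yi, raw(), size = 4, endian = "little"), 4)
    rec[9:12, ] <- matrix(writeBin(zi, raw(), size = 4, endian = "little"), 4)
    rec[15, ] <- as.raw(flag)
    rec[16, ] <- as.raw(as.integer(cls))
    writeBin(as.vector(rec), con)
  }
  invisible(path)
}
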