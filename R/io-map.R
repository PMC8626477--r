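# MRC/CCP4 2014 map reading and writing (modes 0, 1, 2; orthogonal cells).
# On read, the grid is permuted from the stored column/row/section axis order
# to the canonical [x, y, z] order. The physical origin is taken from the
# ORIGIN header fields; when those are all zero but the start indices are not,
# origin = start indices x voxel size. The rule that fired is recorded.

.MACHST_LE <- as.raw(c(0x44, 0x44, 0x00, 0x00))

#' Read an MRC/CCP4 density map
#'
#' @param path file path.
#' @return a [DensityMap-class]; `mapOrigin()` gives the physical position of
#'   grid index (1,1,1) and the object records which origin dialect fired.
#' @export
readDensityMap <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  con <- file(path, "rb")
  on.exit(close(con))
  hdrInt <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdrFlt <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  nc <- hdrInt[1]; nr <- hdrInt[2]; ns <- hdrInt[3]
  mode <- hdrInt[4]
  if (!mode %in% c(0L, 1L, 2L))
    stop("unsupported MRC mode ", mode, " (modes 0, 1, 2 are supported)")
  starts <- hdrInt[5:7]                      # along column/row/section axes
  mxyz <- hdrInt[8:10]                       # sampling along cell x, y, z
  cellLen <- hdrFlt[11:13]
  cellAng <- hdrFlt[14:16]
  if (any(abs(cellAng - 90) > 1e-3))
    stop("unsupported geometry: non-orthogonal cell (angles ",
         paste(sprintf("%.2f", cellAng), collapse = ", "), ")")
  mapcrs <- hdrInt[17:19]
  if (!identical(sort(mapcrs), 1:3))
    stop("invalid MRC axis-order fields (MAPC/MAPR/MAPS = ",
         paste(mapcrs, collapse = ","), ")")
  nsymbt <- hdrInt[24]
  originXyz <- hdrFlt[50:52]
  voxel <- cellLen / mxyz
  if (any(!is.finite(voxel)) || any(voxel <= 0))
    stop("invalid voxel size derived from header (cell ",
         paste(cellLen, collapse = ","), ", sampling ",
         paste(mxyz, collapse = ","), ")")
  seek(con, 1024 + nsymbt)
  nvox <- as.numeric(nc) * nr * ns
  data <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = nvox, size = 1, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n = nvox, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = nvox, size = 4, endian = "little"))
  if (length(data) != nvox)
    stop("truncated MRC data block: expected ", nvox, " voxels, read ",
         length(data))
  arr <- array(as.numeric(data), dim = c(nc, nr, ns))
  # permute axes: stored dim i is physical axis mapcrs[i]
  perm <- match(1:3, mapcrs)
  arr <- aperm(arr, perm)
  if (any(abs(originXyz) > 1e-6)) {
    origin <- originXyz
    rule <- "origin-field"
  } else if (any(starts != 0L)) {
    startsXyz <- starts[perm]
    origin <- startsXyz * voxel
    rule <- "start-indices"
  } else {
    origin <- c(0, 0, 0)
    rule <- "origin-field"
  }
  densityMap(arr, voxel = voxel, origin = origin, originRule = rule)
}

#' Write a density map as MRC/CCP4 2014 (mode 2)
#'
#' Writes in the canonical axis order (columns = x), with the physical origin
#' in the ORIGIN header fields and header statistics (min/max/mean/rms)
#' recomputed from the data.
#'
#' @param map a [DensityMap-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDensityMap <- function(map, path) {
  g <- mapGrid(map)
  d <- dim(g)
  voxel <- voxelSize(map)
  stats <- mapStatistics(map)
  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wFlt <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wInt(d)                        # nx ny nz (columns/rows/sections)
  wInt(2L)                       # mode 2: float32
  wInt(c(0L, 0L, 0L))            # start indices
  wInt(d)                        # mx my mz
  wFlt(d * voxel)                # cell lengths
  wFlt(c(90, 90, 90))            # cell angles
  wInt(1:3)                      # mapc mapr maps: canonical
  wFlt(stats[c("min", "max", "mean")])
  wInt(1L)                       # ispg
  wInt(0L)                       # nsymbt
  wInt(rep(0L, 25))              # extra (words 25-49)
  wFlt(mapOrigin(map))           # origin x y z (words 50-52)
  writeBin(charToRaw("MAP "), con)
  writeBin(.MACHST_LE, con)
  wFlt(stats["rms"])
  wInt(0L)                       # nlabl
  writeBin(raw(800), con)        # labels
  writeBin(as.vector(g), con, size = 4, endian = "little")
  invisible(path)
}
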