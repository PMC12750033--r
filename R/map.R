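#' Density grids
#'
#' A `density_grid` holds a 3D scalar field in canonical axis order:
#' `data[ix, iy, iz]` with x the fastest-varying (first) array index,
#' whatever axis permutation the source file used.  `voxel` is the voxel
#' edge length per axis in Angstroms and `origin` the position of the
#' centre of voxel `(1, 1, 1)` in the model coordinate frame.  All
#' real-space/voxel conversions in the package go through
#' `world_to_index()` / `index_to_world()` below.
#'
#' @param data 3D numeric array, dim `c(nx, ny, nz)`.
#' @param voxel Voxel size, scalar or length-3, Angstroms.
#' @param origin Length-3 position of voxel (1,1,1) centre, Angstroms.
#' @param label One of `"map"`, `"locres"`, `"simulated"`.
#' @return A `density_grid`.
#' @export
density_grid <- function(data, voxel, origin = c(0, 0, 0), label = "map") {
  if (length(dim(data)) != 3L) abort("density_grid: data must be a 3D array")
  voxel <- rep(as.numeric(voxel), length.out = 3)
  if (any(voxel <= 0)) abort("density_grid: voxel size must be positive")
  if (!all(is.finite(data))) abort("density_grid: non-finite voxel values")
  structure(list(data = data, voxel = voxel,
                 origin = as.numeric(origin), label = label),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf(
    "<density_grid [%s]: %s voxels @ %.3g x %.3g x %.3g A, origin (%.3g, %.3g, %.3g)>\n",
    x$label, paste(dim(x$data), collapse = " x "),
    x$voxel[1], x$voxel[2], x$voxel[3],
    x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
dim.density_grid <- function(x) dim(x$data)

# Fractional (1-based) voxel index of world positions; xyz is n x 3.
world_to_index <- function(grid, xyz) {
  sweep(sweep(xyz, 2, grid$origin, "-"), 2, grid$voxel, "/") + 1
}

index_to_world <- function(grid, ijk) {
  sweep(sweep(ijk - 1, 2, grid$voxel, "*"), 2, grid$origin, "+")
}

# Nearest voxel index with ties broken toward the lower index on each axis.
nearest_index <- function(frac) ceiling(frac - 0.5)

#' Value of the voxel nearest a position
#'
#' Returns the value of the voxel whose centre is closest to `position`;
#' ties at the exact midpoint between voxel centres break toward the lower
#' index on each axis.  Positions outside the grid give `NA`, not an error.
#'
#' @param grid A [density_grid()].
#' @param position Length-3 vector or n x 3 matrix of positions, Angstroms.
#' @return Numeric vector of voxel values (`NA` outside the grid).
#' @export
nearest_voxel_value <- function(grid, position) {
  if (is.null(dim(position))) position <- matrix(position, ncol = 3)
  idx <- nearest_index(world_to_index(grid, position))
  d <- dim(grid$data)
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
        idx[, 2] >= 1 & idx[, 2] <= d[2] &
        idx[, 3] >= 1 & idx[, 3] <= d[3]
  out <- rep(NA_real_, nrow(idx))
  if (any(ok)) out[ok] <- grid$data[idx[ok, , drop = FALSE]]
  out
}

# ---- MRC/CCP4 2014 I/O ------------------------------------------------
#
# 1024-byte header, little-endian.  Word layout (1-based 4-byte words):
#  1-3 NC NR NS, 4 MODE, 5-7 NCSTART NRSTART NSSTART, 8-10 MX MY MZ,
#  11-13 CELLA, 14-16 CELLB, 17-19 MAPC MAPR MAPS, 20-22 DMIN DMAX DMEAN,
#  23 ISPG, 24 NSYMBT, 25-49 extra, 50-52 ORIGIN, 53 'MAP ', 54 MACHST,
#  55 RMS, 56 NLABL, 57-256 labels.

#' Read an MRC/CCP4 2014 density map
#'
#' The on-disk axis order (MAPC/MAPR/MAPS) is normalised to the canonical
#' x-fastest order.  The origin is taken from the ORIGIN record when any
#' component is non-zero, otherwise from the start indices times the voxel
#' size.  Voxel size comes from the cell dimensions over the grid sampling.
#' Only orthogonal cells (all angles 90 degrees) and scalar modes 0, 1, 2
#' are supported.
#'
#' @param path File path.
#' @param label Label for the returned grid.
#' @return A [density_grid()].
#' @export
read_map <- function(path, label = "map") {
  if (!file.exists(path)) abort(paste0("read_map: no such file: ", path),
                                class = "cryofit_input_missing")
  con <- file(path, "rb")
  on.exit(close(con))
  ints1 <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  dstats <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  readBin(con, "integer", n = 2, size = 4, endian = "little")  # ISPG NSYMBT
  readBin(con, "integer", n = 25, size = 4, endian = "little") # extra
  orig <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  magic_ok <- identical(readBin(con, "raw", n = 4)[1:3], charToRaw("MAP"))
  readBin(con, "integer", n = 1, size = 4, endian = "little")  # MACHST
  readBin(con, "numeric", n = 1, size = 4, endian = "little")  # RMS
  readBin(con, "integer", n = 1, size = 4, endian = "little")  # NLABL
  readBin(con, "raw", n = 800)                                 # labels
  nc <- ints1[1]; nr <- ints1[2]; ns <- ints1[3]; mode <- ints1[4]
  ncrs_start <- ints1[5:7]; m <- ints1[8:10]
  if (!magic_ok) {
    abort(paste0("read_map: '", path, "' lacks the MAP magic word"),
          class = "cryofit_parse_error")
  }
  if (any(abs(cellb - 90) > 1e-3)) {
    abort("read_map: non-orthogonal cell not supported",
          class = "cryofit_parse_error")
  }
  n_vox <- as.double(nc) * nr * ns
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n_vox, size = 1,
                             signed = TRUE, endian = "little")),
    "1" = as.numeric(readBin(con, "integer", n = n_vox, size = 2,
                             signed = TRUE, endian = "little")),
    "2" = readBin(con, "numeric", n = n_vox, size = 4, endian = "little"),
    abort(paste0("read_map: unsupported mode ", mode),
          class = "cryofit_parse_error"))
  if (length(vals) != n_vox) {
    abort("read_map: truncated data section", class = "cryofit_parse_error")
  }
  arr <- array(vals, dim = c(nc, nr, ns))      # column/row/section order
  if (any(sort(mapcrs) != 1:3)) {
    abort("read_map: invalid MAPC/MAPR/MAPS words",
          class = "cryofit_parse_error")
  }
  # aperm so that output index 1 is x, 2 is y, 3 is z
  perm <- match(1:3, mapcrs)  # which file axis carries x, y, z
  arr <- aperm(arr, perm)
  voxel <- cella / m
  start_xyz <- ncrs_start[perm]
  origin <- if (any(orig != 0)) orig else start_xyz * voxel
  density_grid(arr, voxel = voxel, origin = origin, label = label)
}

#' Write a density grid as MRC 2014
#'
#' Canonical axis order (MAPC/MAPR/MAPS = 1,2,3), mode 2 (float32), ORIGIN
#' set from the grid origin, density statistics filled in.
#'
#' @param grid A [density_grid()].
#' @param path Output path.
#' @export
write_map <- function(grid, path) {
  con <- tryCatch(file(path, "wb"),
                  error = function(e) abort(paste0("write_map: cannot open ",
                                                   path), class = "cryofit_io_error"))
  on.exit(close(con))
  d <- dim(grid$data)
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d); wi(2); wi(c(0, 0, 0)); wi(d)
  wf(d * grid$voxel); wf(c(90, 90, 90))
  wi(1:3)
  v <- grid$data
  wf(c(min(v), max(v), mean(v)))
  wi(c(1, 0)); wi(rep(0L, 25))
  wf(grid$origin)
  writeChar("MAP ", con, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)   # MACHST little-endian
  wf(sd(as.vector(v)) * sqrt((length(v) - 1) / length(v)))
  wi(0); writeBin(raw(800), con)
  writeBin(as.numeric(v), con, size = 4, endian = "little")
  invisible(path)
}
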