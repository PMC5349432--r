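## Density-grid file I/O: CCP4/MRC binary maps (mode 2, orthogonal cell,
## axis order X,Y,Z) and a plain-text dump for small grids.

#' Write a density grid as a CCP4/MRC map
#'
#' Mode-2 (32-bit float) map with an orthogonal cell; the grid origin is
#' encoded in the ORIGIN header words (MRC-2014 convention).
#'
#' @param g A [density_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ccp4_map <- function(g, path) {
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  v <- g$values
  wi(g$dims)                    # NX NY NZ
  wi(2)                         # MODE 2 = float32
  wi(c(0, 0, 0))                # NXSTART..
  wi(g$dims)                    # MX MY MZ
  wf(g$dims * g$spacing)        # cell a b c
  wf(c(90, 90, 90))             # alpha beta gamma
  wi(c(1, 2, 3))                # MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v)))
  wi(c(1, 0))                   # ISPG, NSYMBT
  wi(rep(0, 12))                # EXTRA (words 26-37)
  wf(g$origin)                  # ORIGIN (words 50-52 in MRC-2014)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.numeric(v)))
  wi(0)                         # NLABL
  writeBin(raw(800), con)       # labels
  wf(as.numeric(v))             # X fastest
  invisible(path)
}

#' Read a CCP4/MRC map into a density grid
#'
#' Only orthogonal cells with axis order X,Y,Z and isotropic spacing are
#' supported.
#'
#' @param path Map file path.
#' @return A [density_grid()].
#' @export
read_ccp4_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  dims <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("unsupported MRC mode: ", mode)
  ri(3)                         # NXSTART
  m <- ri(3)
  cell <- rf(3)
  ang <- rf(3)
  if (any(abs(ang - 90) > 1e-3)) stop("non-orthogonal cell not supported")
  axes <- ri(3)
  if (!all(axes == c(1, 2, 3))) stop("axis order must be X,Y,Z")
  rf(3); ri(2); ri(12)
  origin <- rf(3)
  readBin(con, "raw", 4 + 4)    # MAP + machine stamp
  rf(1); nlabl <- ri(1)
  readBin(con, "raw", 800)
  sp <- cell / m
  if (max(sp) - min(sp) > 1e-5) stop("anisotropic spacing not supported")
  vals <- rf(prod(dims))
  density_grid(origin, sp[1], dims, array(vals, dim = dims))
}

#' Write a density grid as plain text
#'
#' Header line with origin, spacing and dims, then one value per line in
#' X-fastest order. Intended for small fixture grids.
#'
#' @param g A [density_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_text <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(paste("# density_grid",
                   paste(sprintf("%.6f", g$origin), collapse = " "),
                   sprintf("%.6f", g$spacing),
                   paste(g$dims, collapse = " ")), con)
  writeLines(sprintf("%.9g", as.numeric(g$values)), con)
  invisible(path)
}

#' Read a plain-text density grid
#'
#' @param path File written by [write_grid_text()].
#' @return A [density_grid()].
#' @export
read_grid_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hd <- strsplit(lines[1], "\\s+")[[1]]
  if (hd[2] != "density_grid") stop("not a density_grid text file")
  origin <- as.numeric(hd[3:5])
  spacing <- as.numeric(hd[6])
  dims <- as.integer(hd[7:9])
  vals <- as.numeric(lines[-1])
  density_grid(origin, spacing, dims, array(vals, dim = dims))
}
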