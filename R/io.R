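## ---- site tables (CSV / PDB / mmCIF) ----------------------------------

#' Write a monomer site table to CSV
#'
#' Columns \code{pf}, \code{repeat_index}, \code{chain}, \code{x,y,z}
#' (nm).
#'
#' @param x an \code{mt_lattice} or site data frame.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_sites_csv <- function(x, path) {
  sites <- lattice_sites(x)
  utils::write.csv(sites, path, row.names = FALSE)
  invisible(path)
}

#' Read a monomer site table from CSV
#'
#' Expects \code{x,y,z} (nm); \code{pf}, \code{repeat_index} and
#' \code{chain} are used when present. A missing chain column loads with
#' \code{chain = "unknown"} and a warning.
#'
#' @param path CSV file.
#' @return site data frame.
#' @export
read_sites_csv <- function(path) {
  sites <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y", "z") %in% names(sites)))
    stop("site CSV needs x, y, z columns")
  if (!"chain" %in% names(sites)) {
    warning("no chain column: loading with chain = 'unknown'")
    sites$chain <- "unknown"
  }
  sites
}

#' Export a lattice as a PDB coordinate model
#'
#' One chain per protofilament, residue numbering by axial repeat,
#' alpha/beta tubulin encoded in the residue name (\code{TBA} /
#' \code{TBB}); one pseudo-atom (CA) per monomer. Coordinates are
#' converted from nm to Angstrom.
#'
#' @param lattice an \code{mt_lattice} (or site data frame with labels).
#' @param path output PDB file.
#' @return \code{path}, invisibly.
#' @export
write_lattice_pdb <- function(lattice, path) {
  sites <- lattice_sites(lattice)
  if (!all(c("pf", "repeat_index", "chain") %in% names(sites)))
    stop("PDB export needs pf, repeat_index and chain labels")
  chains <- c(LETTERS, letters, 0:9)
  if (max(sites$pf) > length(chains)) stop("too many protofilaments for chain ids")
  xyz <- as.numeric(t(as.matrix(sites[, c("x", "y", "z")]) * 10))
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    type = rep("ATOM", nrow(sites)),
    resno = sites$repeat_index + 1L,
    resid = ifelse(sites$chain == "alpha", "TBA", "TBB"),
    chain = chains[sites$pf],
    elety = rep("CA", nrow(sites))
  )
  invisible(path)
}

#' Read labelled coordinates from PDB or mmCIF
#'
#' Chain identities are mapped back from residue names (\code{TBA} ->
#' alpha, \code{TBB} -> beta; unknown residue names load as
#' \code{chain = "unknown"} with a warning), protofilament labels from
#' the chain grouping (in file order) and repeat indices from residue
#' numbers. Coordinates are converted from Angstrom to nm.
#'
#' @param path a \code{.pdb} or \code{.cif} file.
#' @param format \code{"auto"} (by extension), \code{"pdb"} or
#'   \code{"cif"}.
#' @return site data frame (nm).
#' @export
read_coordinates <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  mdl <- if (format == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path)
  at <- mdl$atom
  if (is.null(at) || nrow(at) == 0L || anyNA(at$x))
    stop("parse error: no usable atom records in ", path)
  chain_map <- c(TBA = "alpha", TBB = "beta")
  chain <- unname(chain_map[at$resid])
  if (anyNA(chain)) {
    warning("unrecognized residue naming: loading affected sites with chain = 'unknown'")
    chain[is.na(chain)] <- "unknown"
  }
  data.frame(
    pf = as.integer(factor(at$chain, levels = unique(at$chain))),
    repeat_index = at$resno - 1L,
    chain = chain,
    x = at$x / 10, y = at$y / 10, z = at$z / 10,
    stringsAsFactors = FALSE
  )
}

## ---- MRC volumes -------------------------------------------------------

#' Write a density volume as MRC (mode 2, little-endian)
#'
#' The 1024-byte header records the grid, the voxel size through the
#' cell dimensions, and the origin; densities are 32-bit floats.
#'
#' @param vol an \code{mt_volume}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_mrc <- function(vol, path) {
  stopifnot(inherits(vol, "mt_volume"))
  if (any(!is.finite(vol$data))) stop("volume contains non-finite densities")
  d <- dim(vol$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(d)                                    # nx ny nz
  wi(2L)                                   # mode 2: float32
  wi(c(0L, 0L, 0L))                        # nxstart nystart nzstart
  wi(d)                                    # mx my mz
  wf(d * vol$voxel_size)                   # cella (A)
  wf(c(90, 90, 90))                        # cellb
  wi(c(1L, 2L, 3L))                        # mapc mapr maps
  wf(c(min(vol$data), max(vol$data), mean(vol$data)))
  wi(1L)                                   # ispg: volume
  wi(0L)                                   # nsymbt
  wi(rep(0L, 25L))                         # extra
  wf(vol$origin)                           # origin (A), words 50-52
  writeChar("MAP ", con, 4L, eos = NULL)   # word 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.numeric(vol$data)))      # rms
  wi(0L)                                   # nlabl
  writeBin(raw(800L), con)                 # labels
  wf(as.numeric(vol$data))
  invisible(path)
}

#' Read a mode-2 MRC density volume
#'
#' @param path MRC file written by \code{\link{write_mrc}} or another
#'   tool using mode 2 (32-bit float) and the standard header.
#' @return an \code{mt_volume}.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4L, endian = "little")
  d <- ri(3L)
  mode <- ri(1L)
  ri(3L)                                   # nxstart..
  mx <- ri(3L)
  cella <- rf(3L)
  rf(3L)                                   # cellb
  ri(3L)                                   # mapc..
  rf(3L)                                   # dmin dmax dmean
  ri(2L)                                   # ispg nsymbt
  ri(25L)                                  # extra
  origin <- rf(3L)
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(magic, "MAP ")) stop("not an MRC file (missing MAP magic)")
  if (mode != 2L) stop(sprintf("unsupported MRC mode %d (only mode 2)", mode))
  seek(con, 1024L)
  a <- array(rf(prod(d)), dim = d)
  vx <- cella / ifelse(mx > 0, mx, d)
  if (max(abs(vx - vx[1L])) > 1e-4) warning("anisotropic voxel size; using x")
  mt_volume(a, vx[1L], origin)
}

## ---- kymographs (TIFF + JSON sidecar) and traces ----------------------

#' Write a kymograph as TIFF with a JSON calibration sidecar
#'
#' The image is written as 32-bit float TIFF, linearly rescaled to
#' [0, 1]; the sidecar (\code{<path>.json}) records the intensity range
#' and the pixel/frame calibration so that
#' \code{\link{read_kymograph}} restores the object losslessly.
#'
#' @param kymo a \code{kymograph}.
#' @param path output TIFF file.
#' @return \code{path}, invisibly.
#' @export
write_kymograph <- function(kymo, path) {
  stopifnot(inherits(kymo, "kymograph"))
  rng <- range(kymo$image)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  tiff::writeTIFF((kymo$image - rng[1L]) / scale, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(pixel_size_um = kymo$pixel_size,
         frame_interval_s = kymo$frame_interval,
         seed_extent_px = kymo$seed_extent,
         intensity_min = rng[1L], intensity_range = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a kymograph TIFF with its JSON sidecar
#'
#' @param path TIFF file written by \code{\link{write_kymograph}} (the
#'   \code{<path>.json} sidecar must sit next to it).
#' @return a \code{kymograph}.
#' @export
read_kymograph <- function(path) {
  img <- tiff::readTIFF(path)
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing calibration sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  structure(list(
    image = img * meta$intensity_range + meta$intensity_min,
    pixel_size = meta$pixel_size_um,
    frame_interval = meta$frame_interval_s,
    seed_extent = meta$seed_extent_px
  ), class = "kymograph")
}

#' Write / read tip traces as CSV
#'
#' Columns \code{frame}, \code{tip_px}; calibration columns
#' \code{pixel_size_um} and \code{frame_interval_s} are carried when
#' known.
#'
#' @param trace a \code{tip_trace}.
#' @param path CSV file.
#' @return \code{path} (write) or a \code{tip_trace} (read).
#' @export
write_tip_trace <- function(trace, path) {
  stopifnot(inherits(trace, "tip_trace"))
  df <- as.data.frame(trace)
  df$pixel_size_um <- attr(trace, "pixel_size")
  df$frame_interval_s <- attr(trace, "frame_interval")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tip_trace
#' @export
read_tip_trace <- function(path) {
  df <- utils::read.csv(path)
  if (!"tip_px" %in% names(df)) stop("trace CSV needs a tip_px column")
  tip_trace(df$tip_px,
            pixel_size = if ("pixel_size_um" %in% names(df)) df$pixel_size_um[1L] else NA_real_,
            frame_interval = if ("frame_interval_s" %in% names(df)) df$frame_interval_s[1L] else NA_real_,
            provenance = "manual_csv")
}

#' Read an IMOD ASCII point export as a filament trace
#'
#' Accepts \code{model2point} style output: whitespace-separated rows of
#' either \code{x y z} or \code{object contour x y z} (the first
#' contour is returned unless \code{contour} is given). Coordinates are
#' interpreted as Angstrom unless \code{scale} converts them.
#'
#' @param path text file of points.
#' @param contour contour number to extract (5-column exports).
#' @param scale multiplicative factor applied to coordinates (e.g. the
#'   pixel size, to go from pixels to Angstrom).
#' @return matrix of trace points (columns \code{x,y,z}, Angstrom).
#' @export
read_imod_points <- function(path, contour = NULL, scale = 1) {
  tb <- utils::read.table(path)
  if (ncol(tb) == 3L) {
    pts <- as.matrix(tb)
  } else if (ncol(tb) >= 5L) {
    cont <- tb[[2L]]
    if (is.null(contour)) contour <- cont[1L]
    pts <- as.matrix(tb[cont == contour, 3:5])
  } else {
    stop("expected 3 (x y z) or 5 (object contour x y z) columns")
  }
  colnames(pts) <- c("x", "y", "z")
  pts * scale
}
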