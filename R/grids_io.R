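# Volumetric map I/O.  MRC/CCP4 (binary mode-2 float) and OpenDX (text) are
# written from scratch: no installed R package reads either format.  Only the
# orthogonal-axis subset of each format is supported, which is all the package
# produces.  Infinite sentinel values are clamped on write.

.clamp_finite <- function(v, clamp = 1e30) {
  v[v > clamp] <- clamp
  v[v < -clamp] <- -clamp
  v
}

#' Write a grid as an MRC/CCP4 density map (mode 2, 32-bit float)
#'
#' @param grid a [scalar_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(grid, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- grid$dim
  vals <- .clamp_finite(as.numeric(grid$values), 3e38)
  cella <- d * grid$spacing
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                       # NX NY NZ
  wi(2)                       # MODE 2 = float32
  wi(c(0, 0, 0))              # NXSTART..
  wi(d)                       # MX MY MZ
  wf(cella)                   # CELLA
  wf(c(90, 90, 90))           # CELLB
  wi(c(1, 2, 3))              # MAPC MAPR MAPS
  wf(c(min(vals), max(vals), mean(vals)))  # DMIN DMAX DMEAN
  wi(1)                       # ISPG
  wi(0)                       # NSYMBT
  # EXTRA (100 bytes): words 26-34, stash the true origin in words 50-52 slot
  wi(rep(0, 25))
  # ORIGIN (words 50-52 in the 2014 convention)
  wf(grid$origin)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian machine stamp
  wf(stats::sd(vals))         # RMS
  wi(1)                       # NLABL
  lab <- sprintf("npcvoid scalar grid, unit=%s", grid$unit)
  lab <- substr(paste0(lab, strrep(" ", 80)), 1, 80)
  writeChar(lab, con, nchars = 80, eos = NULL)
  writeChar(strrep(" ", 80 * 9), con, nchars = 720, eos = NULL)
  writeBin(as.numeric(vals), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC/CCP4 density map written in the orthogonal-axis convention
#'
#' @param path input file path.
#' @param unit unit tag to attach (MRC has no unit metadata); defaults to the
#'   label written by [write_mrc()] when present.
#' @return A [scalar_grid()].
#' @export
read_mrc <- function(path, unit = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("only mode-2 (float32) MRC maps are supported")
  ri(3)               # NXSTART
  ri(3)               # MX
  cella <- rf(3)
  rf(3)               # CELLB
  mapcrs <- ri(3)
  if (!all(mapcrs == c(1, 2, 3)))
    stop("only MAPC,MAPR,MAPS = 1,2,3 axis order is supported")
  rf(3)               # DMIN DMAX DMEAN
  ri(1); nsymbt <- ri(1)
  ri(25)              # EXTRA
  origin <- rf(3)
  readChar(con, 4, useBytes = TRUE)  # MAP
  readBin(con, "raw", 4)             # machine stamp
  rf(1)                              # RMS
  nlabl <- ri(1)
  labels <- readChar(con, 80 * 10, useBytes = TRUE)
  if (nsymbt > 0) readBin(con, "raw", nsymbt)
  vals <- rf(prod(d))
  if (is.null(unit)) {
    m <- regmatches(labels, regexpr("unit=[^ ]+", labels))
    unit <- if (length(m)) sub("unit=", "", m) else "dimensionless"
  }
  scalar_grid(origin = origin, spacing = cella / d, dim = d,
              values = array(vals, d), unit = unit)
}

#' Write a grid as an OpenDX regular-grid scalar field
#'
#' The DX `origin` keyword refers to the first data point, i.e. the first
#' voxel centre.
#'
#' @inheritParams write_mrc
#' @export
write_dx <- function(grid, path) {
  d <- grid$dim
  first <- grid$origin + grid$spacing / 2
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("# npcvoid scalar grid, unit=%s", grid$unit),
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.10g %.10g %.10g", first[1], first[2], first[3]),
    sprintf("delta %.10g 0 0", grid$spacing[1]),
    sprintf("delta 0 %.10g 0", grid$spacing[2]),
    sprintf("delta 0 0 %.10g", grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # DX stores with the LAST index fastest: permute x<->z
  vals <- .clamp_finite(as.numeric(aperm(grid$values, c(3, 2, 1))))
  n <- length(vals)
  nfull <- (n %/% 3) * 3
  if (nfull > 0) {
    m <- matrix(vals[seq_len(nfull)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.10g %.10g %.10g", m[, 1], m[, 2], m[, 3]), con)
  }
  if (n > nfull)
    writeLines(paste(sprintf("%.10g", vals[(nfull + 1):n]), collapse = " "), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

#' Read an OpenDX regular-grid scalar field
#' @inheritParams read_mrc
#' @return A [scalar_grid()].
#' @export
read_dx <- function(path, unit = NULL) {
  lines <- readLines(path)
  if (is.null(unit)) {
    m <- regmatches(lines[1], regexpr("unit=[^ ]+", lines[1]))
    unit <- if (length(m)) sub("unit=", "", m) else "dimensionless"
  }
  lines <- lines[!grepl("^#", lines)]
  cnt <- lines[grepl("gridpositions counts", lines)][1]
  d <- as.integer(strsplit(sub(".*counts +", "", cnt), " +")[[1]])
  org <- as.numeric(strsplit(sub("^origin +", "",
                                 lines[grepl("^origin", lines)][1]), " +")[[1]])
  deltas <- lines[grepl("^delta", lines)]
  dm <- t(vapply(deltas, function(l)
    as.numeric(strsplit(sub("^delta +", "", l), " +")[[1]]),
    numeric(3)))
  spacing <- diag(dm)
  if (any(abs(dm - diag(spacing)) > 1e-12))
    stop("only axis-aligned DX grids are supported")
  i0 <- which(grepl("data follows", lines))[1]
  iend <- which(grepl("^attribute", lines))
  iend <- if (length(iend)) min(iend[iend > i0]) - 1 else length(lines)
  vals <- as.numeric(unlist(strsplit(trimws(lines[(i0 + 1):iend]), "[ \t]+")))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(d)) stop("DX data length does not match counts")
  arr <- aperm(array(vals, rev(d)), c(3, 2, 1))   # last index fastest on disk
  scalar_grid(origin = org - spacing / 2, spacing = spacing, dim = d,
              values = arr, unit = unit)
}

#' Write a 1D profile as a TSV file
#' @param df data frame.
#' @param path output path.
#' @param meta optional named list written to a JSON sidecar `<path>.json`.
#' @export
write_profile_tsv <- function(df, path, meta = NULL) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a TSV profile written by [write_profile_tsv()]
#' @param path input path.
#' @export
read_profile_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t")
}
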