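#' Read a vessel from the canonical plain-text format
#'
#' The canonical format is plain text: comment lines start with `#`, then
#' one cross-section per line, whitespace-separated:
#' `s_mm  x_mm  y_mm  z_mm  radius_mm`, with s strictly increasing from 0.
#' Malformed lines, non-positive radii and non-monotone arc lengths are
#' rejected with the offending line number.
#'
#' @param path path to a vessel file.
#' @return a `vessel_geometry`.
#' @export
read_vessel <- function(path) {
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  lineno <- which(keep)
  rows <- raw[keep]
  if (length(rows) < 2L) stop("vessel file must contain at least 2 sections")
  vals <- matrix(NA_real_, length(rows), 5)
  for (i in seq_along(rows)) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(rows[i]), "\\s+")[[1]]))
    if (length(f) != 5L || anyNA(f))
      stop(sprintf("malformed vessel line %d: expected 's x y z r'", lineno[i]))
    if (f[5] <= 0)
      stop(sprintf("non-positive radius at line %d", lineno[i]))
    vals[i, ] <- f
  }
  if (any(diff(vals[, 1]) <= 0)) {
    bad <- lineno[which(diff(vals[, 1]) <= 0)[1] + 1L]
    stop(sprintf("arc length not increasing at line %d", bad))
  }
  vessel_geometry(vals[, 1], vals[, 2:4], vals[, 5],
                  name = basename(path))
}

#' Write a vessel in the canonical plain-text format
#'
#' Values are written with 12 significant digits so a write/read round trip
#' reproduces the geometry to text precision.
#'
#' @param vessel a `vessel_geometry`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vessel <- function(vessel, path) {
  validate_vessel(vessel)
  sec <- vessel$sections
  hdr <- c(sprintf("# vessel: %s", vessel$name),
           "# columns: s_mm x_mm y_mm z_mm radius_mm")
  body <- sprintf("%.12g %.12g %.12g %.12g %.12g",
                  sec$s, sec$x, sec$y, sec$z, sec$r)
  writeLines(c(hdr, body), path)
  invisible(path)
}
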