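# Multi-frame geometry input: plain multi-frame XYZ ensembles.

#' Read a multi-frame XYZ file
#'
#' Reads a concatenated-XYZ trajectory (the frame index is the record order):
#' each frame is `n`, a comment line, then `n` lines of `element x y z` in
#' Angstrom.  A `time_ps=<value>` token in the comment line is parsed into
#' the frame time; otherwise frames are stamped `(index - 1) * stride_ps`.
#'
#' @param path file path.
#' @param stride_ps fallback time spacing between frames in ps (default 50).
#' @return A list of frames; each frame is a list with `elements`, `coords`
#'   (n x 3, Angstrom) and `time_ps`.
#' @seealso [write_xyz_frames()]
#' @export
read_xyz_frames <- function(path, stride_ps = 50) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  idx <- 0L
  while (i <= length(lines)) {
    if (grepl("^\\s*$", lines[i])) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1) {
      stop("malformed XYZ at line ", i, " of ", path,
           ": expected an atom count")
    }
    if (i + 1L + n > length(lines)) {
      stop("truncated XYZ frame starting at line ", i, " of ", path)
    }
    comment <- lines[i + 1L]
    idx <- idx + 1L
    tm <- regmatches(comment, regexec("time_ps=([-0-9.eE+]+)", comment))[[1]]
    time_ps <- if (length(tm) == 2) as.numeric(tm[2]) else (idx - 1L) * stride_ps
    el <- character(n)
    xyz <- matrix(NA_real_, n, 3)
    for (k in seq_len(n)) {
      tok <- strsplit(trimws(lines[i + 1L + k]), "[[:space:]]+")[[1]]
      if (length(tok) < 4) {
        stop("malformed atom record at line ", i + 1L + k, " of ", path)
      }
      el[k] <- tok[1]
      xyz[k, ] <- as.numeric(tok[2:4])
    }
    if (anyNA(xyz)) stop("non-numeric coordinates in frame ", idx, " of ", path)
    frames[[idx]] <- geometry_frame(el, xyz, time_ps)
    i <- i + 2L + n
  }
  if (idx == 0L) stop("no frames found in ", path)
  frames
}

#' Construct a geometry frame
#'
#' @param elements character vector of element symbols.
#' @param coords n x 3 coordinate matrix, Angstrom.
#' @param time_ps frame time stamp in ps.
#' @return A list of class `geometry_frame`.
#' @export
geometry_frame <- function(elements, coords, time_ps = 0) {
  coords <- as_coord_matrix(coords)
  stopifnot(length(elements) == nrow(coords))
  structure(list(elements = as.character(elements), coords = coords,
                 time_ps = as.numeric(time_ps)),
            class = "geometry_frame")
}

#' Write frames to a multi-frame XYZ file
#'
#' @param frames list of `geometry_frame` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz_frames <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    writeLines(as.character(nrow(fr$coords)), con)
    writeLines(sprintf("time_ps=%s", format_full(fr$time_ps)), con)
    writeLines(sprintf("%-3s %s %s %s", fr$elements,
                       format_full(fr$coords[, 1]),
                       format_full(fr$coords[, 2]),
                       format_full(fr$coords[, 3])), con)
  }
  invisible(path)
}
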