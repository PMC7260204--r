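#' Read an OOMMF Vector Field (OVF) file
#'
#' Parses text OVF 1.0 or 2.0 files with a rectangular mesh and 3-component
#' vector data, the de-facto exchange format of micromagnetic solvers
#' (OOMMF, mumax3).  Binary OVF segments are not supported.  Values are
#' scaled to A/m using the file's `valuemultiplier` (OVF 1.0); OVF 2.0 data
#' are taken to already be in the declared `valueunits`.
#'
#' @param path path to a text OVF file.
#' @param Ms optional saturation magnetization in A/m; defaults to the
#'   maximum cell magnitude found in the file (OVF carries no Ms of its own).
#' @return a [mag_grid()].
#' @export
read_ovf <- function(path, Ms = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^#\\s*OOMMF", lines[1], ignore.case = TRUE))
    stop("not an OVF file (missing '# OOMMF' signature): ", path)
  header <- list()
  data_start <- NA_integer_
  data_end <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^#\\s*Begin:\\s*Data", ln, ignore.case = TRUE)) {
      if (!grepl("Text", ln, ignore.case = TRUE))
        stop("unsupported OVF data encoding (text only): line ", i, ": ", ln)
      data_start <- i + 1L
      next
    }
    if (grepl("^#\\s*End:\\s*Data", ln, ignore.case = TRUE)) {
      data_end <- i - 1L
      break
    }
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) header[[tolower(m[2])]] <- trimws(m[3])
  }
  if (is.na(data_start)) stop("no 'Begin: Data Text' section found in ", path)
  if (is.na(data_end)) data_end <- length(lines)

  hnum <- function(key, required = TRUE, default = NA_real_) {
    v <- header[[key]]
    if (is.null(v)) {
      if (required) stop("malformed OVF header: missing '", key, ":'")
      return(default)
    }
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) stop("malformed OVF header line '", key, ": ", v, "'")
    x
  }
  meshtype <- header[["meshtype"]]
  if (!is.null(meshtype) && tolower(meshtype) != "rectangular")
    stop("unsupported OVF mesh: header line 'meshtype: ", meshtype,
         "' (rectangular only)")
  valuedim <- hnum("valuedim", required = FALSE, default = 3)
  if (valuedim != 3)
    stop("unsupported OVF data: header line 'valuedim: ", valuedim,
         "' (3-component vectors only)")
  n <- c(hnum("xnodes"), hnum("ynodes"), hnum("znodes"))
  cell <- c(hnum("xstepsize"), hnum("ystepsize"), hnum("zstepsize"))
  base <- c(hnum("xbase", required = FALSE, default = cell[1] / 2),
            hnum("ybase", required = FALSE, default = cell[2] / 2),
            hnum("zbase", required = FALSE, default = cell[3] / 2))
  mult <- hnum("valuemultiplier", required = FALSE, default = 1)

  txt <- lines[data_start:data_end]
  txt <- txt[!grepl("^#", txt) & nzchar(trimws(txt))]
  vals <- scan(text = paste(txt, collapse = "\n"), quiet = TRUE)
  if (length(vals) != prod(n) * 3)
    stop(sprintf("OVF data size mismatch: expected %d values, found %d",
                 prod(n) * 3, length(vals)))
  # OVF data order: component fastest, then x, then y, then z
  arr <- aperm(array(vals, dim = c(3, n)), c(2, 3, 4, 1)) * mult
  if (is.null(Ms))
    Ms <- sqrt(max(arr[, , , 1]^2 + arr[, , , 2]^2 + arr[, , , 3]^2))
  mag_grid(arr, cell, origin = base, Ms = Ms)
}

#' Write a magnetization grid as a text OVF 2.0 file
#'
#' @param grid a [mag_grid()].
#' @param path output file path.
#' @param title segment title string.
#' @return `path`, invisibly.
#' @export
write_ovf <- function(grid, path, title = "beadscape magnetization state") {
  n <- grid$n
  cell <- grid$cell_size
  base <- grid$origin
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# OOMMF OVF 2.0")
  w("# Segment count: 1")
  w("# Begin: Segment")
  w("# Begin: Header")
  w("# Title: %s", title)
  w("# meshtype: rectangular")
  w("# meshunit: m")
  w("# valueunits: A/m A/m A/m")
  w("# valuedim: 3")
  w("# xbase: %.17g", base[1]); w("# ybase: %.17g", base[2])
  w("# zbase: %.17g", base[3])
  w("# xstepsize: %.17g", cell[1]); w("# ystepsize: %.17g", cell[2])
  w("# zstepsize: %.17g", cell[3])
  w("# xnodes: %d", n[1]); w("# ynodes: %d", n[2]); w("# znodes: %d", n[3])
  w("# xmin: %.17g", base[1] - cell[1] / 2)
  w("# ymin: %.17g", base[2] - cell[2] / 2)
  w("# zmin: %.17g", base[3] - cell[3] / 2)
  w("# xmax: %.17g", base[1] + (n[1] - 0.5) * cell[1])
  w("# ymax: %.17g", base[2] + (n[2] - 0.5) * cell[2])
  w("# zmax: %.17g", base[3] + (n[3] - 0.5) * cell[3])
  w("# End: Header")
  w("# Begin: Data Text")
  # component fastest, then x, then y, then z
  vals <- aperm(grid$M, c(4, 1, 2, 3))
  mat <- matrix(vals, nrow = 3)
  writeLines(sprintf("%.17g %.17g %.17g", mat[1, ], mat[2, ], mat[3, ]), con)
  w("# End: Data Text")
  w("# End: Segment")
  invisible(path)
}
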