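#' Matrix-backed rasters
#'
#' Rasters are stored north-up as plain matrices (row 1 = northernmost row)
#' together with the cell size in meters, the coordinates of the lower-left
#' corner, a nodata sentinel, and an opaque CRS tag. This mirrors the ESRI
#' ASCII grid model, the package's interchange format.
#'
#' @param values numeric/integer matrix, row 1 northernmost.
#' @param cell_size cell side length in meters (> 0).
#' @param xll,yll coordinates of the lower-left corner of the grid, meters.
#' @param nodata sentinel value marking cells outside the data.
#' @param crs_tag opaque identifier carried through I/O.
#' @return An object of class `park_raster`.
#' @export
park_raster <- function(values, cell_size, xll = 0, yll = 0,
                        nodata = -9999, crs_tag = "local-metric") {
  stopifnot(is.matrix(values), cell_size > 0)
  structure(
    list(values = values, cell_size = cell_size, xll = xll, yll = yll,
         nodata = nodata, crs_tag = crs_tag),
    class = "park_raster"
  )
}

#' @export
print.park_raster <- function(x, ...) {
  v <- x$values[x$values != x$nodata]
  cat(sprintf("<park_raster> %d x %d cells @ %g m, %d nodata cells\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              sum(x$values == x$nodata)))
  if (length(v)) {
    if (is.integer(x$values)) {
      tab <- table(v)
      cat("codes:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
    } else {
      cat(sprintf("range: [%g, %g]\n", min(v), max(v)))
    }
  }
  invisible(x)
}

#' Cell area in km^2
#' @param raster a `park_raster`.
#' @return Scalar area of one cell in km^2.
#' @export
cell_area_km2 <- function(raster) (raster$cell_size / 1000)^2

# zone mask codes
ZONE_CODES <- c(OUTSIDE = 0L, CORE = 1L, GENERAL = 2L)

#' Build a zone mask raster
#'
#' @param values integer matrix of codes 0 (outside), 1 (core), 2 (general);
#'   georeferencing is taken from `template`.
#' @param template a `park_raster` sharing the grid.
#' @return A `park_raster` whose values are zone codes (nodata = -9999 unused;
#'   outside cells carry code 0).
#' @export
zone_mask <- function(values, template) {
  stopifnot(all(values %in% ZONE_CODES))
  park_raster(matrix(as.integer(values), nrow(values), ncol(values)),
              cell_size = template$cell_size, xll = template$xll,
              yll = template$yll, nodata = -9999L, crs_tag = template$crs_tag)
}

.check_aligned <- function(a, b, what = "rasters") {
  if (!identical(dim(a$values), dim(b$values)) ||
      a$cell_size != b$cell_size || a$xll != b$xll || a$yll != b$yll) {
    stop(what, " are not aligned (shape, cell size and origin must match)")
  }
  invisible(TRUE)
}

#' Read a categorical land-use raster
#'
#' Reads an ESRI ASCII grid and validates every non-nodata code against the
#' catalog legend. Unknown codes are tolerated up to `max_unknown_fraction`
#' of the data cells (reported with counts); beyond that, reading fails.
#'
#' @param path an ESRI ASCII grid (`.asc`).
#' @param catalog a `park_catalog` giving the legal codes.
#' @param max_unknown_fraction tolerated fraction of unknown-code cells.
#' @return A `park_raster` of integer codes.
#' @export
read_landuse <- function(path, catalog, max_unknown_fraction = 0) {
  r <- read_ascii_grid(path, integer = TRUE)
  v <- r$values[r$values != r$nodata]
  unknown <- setdiff(unique(v), catalog$classes$code)
  if (length(unknown)) {
    counts <- table(v[v %in% unknown])
    msg <- paste(sprintf("%s: %d", names(counts), as.integer(counts)), collapse = ", ")
    if (sum(counts) > max_unknown_fraction * length(v)) {
      stop("unknown land-use codes {", msg, "} exceed tolerance")
    }
    warning("unknown land-use codes treated as nodata {", msg, "}")
    r$values[r$values %in% unknown] <- r$nodata
  }
  r
}

#' Read / write ESRI ASCII grids
#'
#' The text grid dialect with `NCOLS`/`NROWS`/`XLLCORNER`/`YLLCORNER`/
#' `CELLSIZE`/`NODATA_VALUE` header and north-to-south rows. Values round-trip
#' bit-exactly for integer grids and to full double precision for float grids.
#'
#' @param path file path.
#' @param integer read values as integers (class codes) rather than doubles.
#' @param raster a `park_raster` to write.
#' @return `read_ascii_grid` returns a `park_raster`; `write_ascii_grid`
#'   returns `path` invisibly.
#' @export
read_ascii_grid <- function(path, integer = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[toupper(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("NCOLS", "NROWS", "XLLCORNER", "YLLCORNER", "CELLSIZE")
  if (!all(need %in% names(hdr))) {
    stop("ASCII grid header incomplete; missing ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  }
  nodata <- if (!is.null(hdr$NODATA_VALUE)) hdr$NODATA_VALUE else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$NCOLS * hdr$NROWS) {
    stop("ASCII grid body has ", length(vals), " values; expected ",
         hdr$NCOLS * hdr$NROWS)
  }
  m <- matrix(vals, nrow = hdr$NROWS, ncol = hdr$NCOLS, byrow = TRUE)
  if (integer) {
    m <- matrix(as.integer(m), nrow(m), ncol(m))
    nodata <- as.integer(nodata)
  }
  park_raster(m, cell_size = hdr$CELLSIZE, xll = hdr$XLLCORNER,
              yll = hdr$YLLCORNER, nodata = nodata)
}

#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(raster, path) {
  stopifnot(inherits(raster, "park_raster"), length(raster$values) > 0)
  m <- raster$values
  fmt <- function(x) {
    if (is.integer(x)) as.character(x) else sprintf("%.17g", x)
  }
  hdr <- c(
    sprintf("NCOLS %d", ncol(m)),
    sprintf("NROWS %d", nrow(m)),
    sprintf("XLLCORNER %.17g", raster$xll),
    sprintf("YLLCORNER %.17g", raster$yll),
    sprintf("CELLSIZE %.17g", raster$cell_size),
    sprintf("NODATA_VALUE %s", fmt(raster$nodata))
  )
  body <- apply(m, 1, function(row) paste(fmt(row), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write any pipeline raster
#'
#' Thin dispatcher kept for a stable I/O surface: grade maps and zoning maps
#' are integer grids, kriged surfaces are float grids; all serialize to the
#' ASCII grid dialect.
#'
#' @param raster a `park_raster`.
#' @param path output path.
#' @param format only `"ascii"` is supported.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path, format = c("ascii")) {
  format <- match.arg(format)
  write_ascii_grid(raster, path)
}

#' Coordinates of cell centers
#'
#' @param raster a `park_raster`.
#' @param rows,cols cell indices (row 1 = north).
#' @return Two-column matrix of x/y center coordinates in meters.
#' @export
cell_centers <- function(raster, rows, cols) {
  cs <- raster$cell_size
  nr <- nrow(raster$values)
  x <- raster$xll + (cols - 0.5) * cs
  y <- raster$yll + (nr - rows + 0.5) * cs
  cbind(x = x, y = y)
}
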