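#' Construct a binary forest map
#'
#' A `forest_map` is an integer matrix of 1 (forest), 0 (non-forest) and `NA`
#' (nodata) with the minimal georeferencing needed for gridded landscape
#' analysis: a square pixel size in metres, the projected coordinates of the
#' upper-left raster corner, a CRS identifier and an epoch label. All
#' coordinates are assumed to be in a projected equal-area system; the package
#' never reprojects.
#'
#' @param values Matrix of 0/1/`NA`. Numeric input is binarized
#'   (values >= 0.5 become 1).
#' @param pixel_size Side length of one (square) pixel, metres. Must be > 0.
#' @param origin Numeric length-2: projected x/y of the upper-left corner.
#' @param crs Character identifier of the projected CRS (free-form; used only
#'   for co-registration checks and sidecar files).
#' @param epoch Year label of the map (e.g. `2000`).
#' @return An object of class `forest_map`.
#' @examples
#' m <- forest_map(matrix(c(1, 0, 0, 1), 2), pixel_size = 30, epoch = 2000)
#' forest_pixels(m)
#' @export
forest_map <- function(values, pixel_size, origin = c(0, 0),
                       crs = "local_equal_area", epoch = NA) {
  if (!is.matrix(values) || nrow(values) < 1 || ncol(values) < 1) {
    abort("`values` must be a matrix with at least one row and one column.")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    abort("`pixel_size` must be a single positive number (metres).")
  }
  v <- values
  storage.mode(v) <- "double"
  bad <- !is.na(v) & !(v %in% c(0, 1))
  if (any(bad)) {
    # tolerate continuous input (e.g. cover fractions): binarize at 0.5
    v[!is.na(v)] <- as.numeric(v[!is.na(v)] >= 0.5)
  }
  storage.mode(v) <- "integer"
  structure(
    list(
      values = v,
      pixel_size = as.numeric(pixel_size),
      origin = as.numeric(origin),
      crs = as.character(crs),
      epoch = epoch
    ),
    class = "forest_map"
  )
}

#' @export
print.forest_map <- function(x, ...) {
  cat(sprintf(
    "<forest_map> %d x %d pixels of %g m, epoch %s\n  forest: %d px (FC = %.3f), nodata: %d px\n  origin (%g, %g), crs: %s\n",
    nrow(x$values), ncol(x$values), x$pixel_size, format(x$epoch),
    forest_pixels(x), mean(x$values == 1L, na.rm = TRUE),
    sum(is.na(x$values)), x$origin[1], x$origin[2], x$crs
  ))
  invisible(x)
}

#' @export
dim.forest_map <- function(x) dim(x$values)

#' Count forest pixels of a map
#' @param map A [forest_map()].
#' @return Integer count of pixels equal to 1.
#' @export
forest_pixels <- function(map) {
  stopifnot(inherits(map, "forest_map"))
  sum(map$values == 1L, na.rm = TRUE)
}

#' Read a binary forest map from an Esri AAIGrid (.asc) file
#'
#' Reads the plain-text Arc/Info ASCII grid format, binarizes the band
#' (values >= 0.5 and not equal to the nodata sentinel become forest) and
#' masks nodata. If a `.prj` sidecar exists it is used as the CRS string; a
#' sidecar describing a geographic (degree-unit) system is rejected because
#' all metrics are computed in metres on an equal-area projection.
#'
#' GeoTIFF input is not supported by this build (no GDAL-backed reader is
#' used); convert to AAIGrid (e.g. `gdal_translate -of AAIGrid`) first.
#'
#' @param path Path to a `.asc`/`.agr`/`.grd` AAIGrid file.
#' @param epoch Year label to attach to the map.
#' @return A [forest_map()].
#' @export
read_forest_map <- function(path, epoch = NA) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    abort(paste0(
      "GeoTIFF input is not supported; convert '", basename(path),
      "' to Esri AAIGrid (.asc) with square pixels in a projected ",
      "equal-area CRS and retry."
    ))
  }
  hdr <- parse_aaigrid_header(path)
  if (!is.null(hdr$dx) && !isTRUE(all.equal(hdr$dx, hdr$dy))) {
    abort(sprintf(
      "Non-square pixels (dx = %g, dy = %g); resample to square pixels first.",
      hdr$dx, hdr$dy
    ))
  }
  crs <- "unknown"
  prj <- sub("\\.[^.]+$", ".prj", path)
  if (file.exists(prj)) {
    crs <- paste(trimws(readLines(prj, warn = FALSE)), collapse = " ")
    if (grepl("^\\s*GEOGCS", crs, ignore.case = TRUE)) {
      abort(paste0(
        "Map is in a geographic (degree-unit) CRS; reproject to a projected ",
        "equal-area system with metre units before analysis."
      ))
    }
  }
  vals <- scan(path, what = double(), skip = hdr$n_header, quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols) {
    abort(sprintf(
      "AAIGrid body has %d values, expected %d (%d rows x %d cols).",
      length(vals), hdr$nrows * hdr$ncols, hdr$nrows, hdr$ncols
    ))
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.na(hdr$nodata)) m[m == hdr$nodata] <- NA
  m[!is.na(m)] <- as.numeric(m[!is.na(m)] >= 0.5)
  origin <- c(hdr$xll, hdr$yll + hdr$nrows * hdr$cellsize)
  forest_map(m, pixel_size = hdr$cellsize, origin = origin, crs = crs,
             epoch = epoch)
}

parse_aaigrid_header <- function(path) {
  lines <- readLines(path, n = 8, warn = FALSE)
  hdr <- list(nodata = NA_real_, dx = NULL, dy = NULL)
  n_header <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2 || is.na(suppressWarnings(as.numeric(parts[2])))) break
    key <- tolower(parts[1])
    val <- as.numeric(parts[2])
    n_header <- n_header + 1
    hdr[[switch(key,
      ncols = "ncols", nrows = "nrows",
      xllcorner = "xll", yllcorner = "yll",
      xllcenter = "xllc", yllcenter = "yllc",
      cellsize = "cellsize", dx = "dx", dy = "dy",
      nodata_value = "nodata", key
    )]] <- val
  }
  if (is.null(hdr$cellsize) && !is.null(hdr$dx)) hdr$cellsize <- hdr$dx
  if (is.null(hdr$ncols) || is.null(hdr$nrows) || is.null(hdr$cellsize)) {
    abort(sprintf("'%s' is not a readable Esri AAIGrid (missing header keys).",
                  basename(path)))
  }
  # cell-centre registered headers: shift to the corner convention
  if (is.null(hdr$xll) && !is.null(hdr$xllc)) hdr$xll <- hdr$xllc - hdr$cellsize / 2
  if (is.null(hdr$yll) && !is.null(hdr$yllc)) hdr$yll <- hdr$yllc - hdr$cellsize / 2
  if (is.null(hdr$xll)) hdr$xll <- 0
  if (is.null(hdr$yll)) hdr$yll <- 0
  hdr$nrows <- as.integer(hdr$nrows)
  hdr$ncols <- as.integer(hdr$ncols)
  hdr$n_header <- n_header
  hdr
}

#' Write a forest map as Esri AAIGrid
#'
#' Writes the lattice as plain-text AAIGrid with nodata sentinel -9999 and,
#' when the CRS is known, a `.prj` sidecar. A write/read round trip
#' reproduces values and metadata exactly.
#'
#' @param map A [forest_map()].
#' @param path Output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_forest_map <- function(map, path) {
  stopifnot(inherits(map, "forest_map"))
  v <- map$values
  v[is.na(v)] <- -9999L
  hdr <- c(
    sprintf("ncols %d", ncol(map$values)),
    sprintf("nrows %d", nrow(map$values)),
    sprintf("xllcorner %.10g", map$origin[1]),
    sprintf("yllcorner %.10g", map$origin[2] - nrow(map$values) * map$pixel_size),
    sprintf("cellsize %.10g", map$pixel_size),
    "NODATA_value -9999"
  )
  body <- apply(v, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  if (!map$crs %in% c("unknown", "", NA)) {
    writeLines(map$crs, sub("\\.[^.]+$", ".prj", path))
  }
  invisible(path)
}

#' Check that two maps are co-registered
#'
#' Two maps can be compared cell-by-cell only if they share shape, pixel
#' size, origin and CRS; the epoch label is deliberately not compared.
#'
#' @param map_a,map_b [forest_map()] objects.
#' @return A list of class `coregistration` with elements `ok` (logical) and
#'   `mismatches` (tibble with one row per differing field).
#' @export
check_coregistration <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "forest_map"), inherits(map_b, "forest_map"))
  mk <- function(field, a, b) tibble::tibble(field = field, map_a = a, map_b = b)
  bad <- list()
  if (!identical(dim(map_a$values), dim(map_b$values))) {
    bad <- c(bad, list(mk("shape", paste(dim(map_a$values), collapse = "x"),
                          paste(dim(map_b$values), collapse = "x"))))
  }
  if (!isTRUE(all.equal(map_a$pixel_size, map_b$pixel_size))) {
    bad <- c(bad, list(mk("pixel_size", format(map_a$pixel_size),
                          format(map_b$pixel_size))))
  }
  if (!isTRUE(all.equal(map_a$origin, map_b$origin))) {
    bad <- c(bad, list(mk("origin", paste(map_a$origin, collapse = ", "),
                          paste(map_b$origin, collapse = ", "))))
  }
  if (!identical(map_a$crs, map_b$crs)) {
    bad <- c(bad, list(mk("crs", map_a$crs, map_b$crs)))
  }
  mism <- if (length(bad)) dplyr::bind_rows(bad) else
    tibble::tibble(field = character(), map_a = character(), map_b = character())
  structure(list(ok = nrow(mism) == 0, mismatches = mism),
            class = "coregistration")
}

#' @export
print.coregistration <- function(x, ...) {
  if (x$ok) {
    cat("<coregistration> OK: maps share shape, pixel size, origin and CRS\n")
  } else {
    cat("<coregistration> MISMATCH in:", paste(x$mismatches$field, collapse = ", "), "\n")
    print(x$mismatches)
  }
  invisible(x)
}
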