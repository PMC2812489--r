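# Landscape file I/O: ESRI ASCII grid for the patch-identifier raster plus a
# CSV patch attribute table. Written and read bit-stably; areas and centroids
# are always recomputed on read.

#' Write a landscape to an ESRI ASCII grid and a patch table CSV
#'
#' The grid file carries the standard six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by one line per
#' raster row (top row first). The CSV has columns `id,type_code,barrier`.
#'
#' @param landscape a `landscape` object.
#' @param grid_path path for the `.asc` raster.
#' @param table_path path for the patch attribute CSV.
#' @return invisibly, the two paths.
#' @export
write_landscape <- function(landscape, grid_path, table_path) {
  validate_landscape(landscape)
  g <- landscape$grid
  con <- file(grid_path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(g)),
    paste("nrows", nrow(g)),
    paste("xllcorner", 0),
    paste("yllcorner", 0),
    paste("cellsize", format(landscape$cell_size)),
    paste("NODATA_value", -9999)
  ), con)
  writeLines(apply(g, 1L, paste, collapse = " "), con)
  p <- landscape$patches[, c("id", "type_code", "barrier")]
  utils::write.csv(p, table_path, row.names = FALSE, quote = FALSE)
  invisible(c(grid_path, table_path))
}

#' Read a landscape from an ESRI ASCII grid and a patch table CSV
#'
#' Every identifier present in the grid must appear in the table (the error
#' names any that are missing); the table's barrier flags must agree with its
#' type codes. Areas and centroids are recomputed from the grid.
#'
#' @param grid_path path to the `.asc` raster of integer patch identifiers.
#' @param table_path path to the CSV with header `id,type_code,barrier`.
#' @return a `landscape` object.
#' @export
read_landscape <- function(grid_path, table_path) {
  lines <- readLines(grid_path)
  if (length(lines) < 7L) stop("malformed ESRI ASCII grid: too few lines")
  hdr <- lines[1:6]
  keys <- tolower(vapply(strsplit(hdr, "\\s+"), `[`, "", 1L))
  vals <- as.numeric(vapply(strsplit(hdr, "\\s+"), `[`, "", 2L))
  expected <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!identical(keys, expected) || anyNA(vals))
    stop("malformed ESRI ASCII grid header: expected keys ",
         paste(expected, collapse = ", "))
  nc <- as.integer(vals[1L]); nr <- as.integer(vals[2L])
  body <- lines[-(1:6)]
  if (length(body) != nr) stop("malformed ESRI ASCII grid: expected ", nr,
                               " data rows, found ", length(body))
  cells <- scan(text = body, what = integer(), quiet = TRUE)
  if (length(cells) != nr * nc)
    stop("malformed ESRI ASCII grid: expected ", nr * nc, " cells")
  grid <- matrix(cells, nrow = nr, ncol = nc, byrow = TRUE)

  tab <- utils::read.csv(table_path, stringsAsFactors = FALSE)
  if (!all(c("id", "type_code", "barrier") %in% names(tab)))
    stop("malformed patch table header: need columns id, type_code, barrier")
  ids_grid <- unique(as.integer(grid))
  missing <- setdiff(ids_grid, tab$id)
  if (length(missing))
    stop("patch table is missing grid identifier(s): ",
         paste(sort(missing), collapse = ", "))
  types <- stats::setNames(tab$type_code, as.character(tab$id))
  flag <- unname(types[as.character(tab$id)]) %in% BARRIER_TYPES
  if (!all(as.logical(tab$barrier) == flag))
    stop("patch table barrier flags disagree with type codes")
  new_landscape(grid, types, cell_size = vals[5L])
}
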