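# Landscape data model: raster patch mosaics with a patch attribute table.

#' Barrier type codes
#'
#' The fixed set of immovable landscape elements that act as dispersal
#' barriers and are never altered by any landscape transform.
#' @export
BARRIER_TYPES <- c("road", "river", "building", "lake", "railway")

#' Default habitat vocabulary
#'
#' A reduced controlled vocabulary of habitat types for synthetic
#' agricultural mosaics: per-type target cover fraction (of the non-barrier
#' area, summing to 1), whether patches of the type grow as elongated,
#' corridor-like features (field boundaries, hedgerows, roadside verges) or
#' as compact blocks (fields, grassland, forest), and the type's patch-size
#' range as log10 area relative to the landscape mean patch area. Sizes are
#' strongly type-stratified, as in real agricultural mosaics: fields span
#' the largest patches, linear elements the smallest, with the overall
#' spread above two orders of magnitude.
#'
#' @return data.frame with columns `type_code`, `cover`, `elongated`,
#'   `size_lo`, `size_hi` (decades).
#' @export
default_vocabulary <- function() {
  data.frame(
    type_code = c("rotational_field", "grassland", "forest",
                  "field_boundary", "hedgerow", "roadside_verge"),
    cover     = c(0.50, 0.14, 0.12, 0.10, 0.08, 0.06),
    elongated = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    size_lo   = c(1.0, 0.7, 0.7, 1.1, 1.1, 0.9),
    size_hi   = c(2.5, 2.0, 2.2, 1.9, 1.9, 1.7),
    stringsAsFactors = FALSE
  )
}

check_vocabulary <- function(vocabulary) {
  stopifnot(is.data.frame(vocabulary),
            all(c("type_code", "cover") %in% names(vocabulary)))
  if (any(vocabulary$cover < 0)) stop("vocabulary cover fractions must be >= 0")
  if (any(vocabulary$type_code %in% BARRIER_TYPES))
    stop("vocabulary must not contain barrier types")
  if (abs(sum(vocabulary$cover) - 1) > 1e-8)
    stop("habitat cover fractions must sum to 1 (they are fractions of the non-barrier area)")
  if (is.null(vocabulary$elongated)) vocabulary$elongated <- FALSE
  if (is.null(vocabulary$size_lo)) vocabulary$size_lo <- 0
  if (is.null(vocabulary$size_hi)) vocabulary$size_hi <- 2.5
  if (any(vocabulary$size_hi < vocabulary$size_lo))
    stop("size_hi must be >= size_lo")
  vocabulary
}

#' Patch size class
#'
#' Patches are binned on a quarter-decade log scale:
#' `class_index = floor(4 * log10(area_m2))`, so a 10,000 m2 patch falls in
#' class 16 and a 1 m2 patch in class 0. Monotone in area; equal areas share
#' a class.
#'
#' @param area_m2 numeric vector of patch areas in square metres.
#' @return integer vector of class indices.
#' @export
size_class <- function(area_m2) {
  stopifnot(all(area_m2 > 0))
  as.integer(floor(4 * log10(area_m2)))
}

# Build the patch attribute table from a grid and an id -> (type, barrier)
# map; areas and centroids are always recomputed from the grid.
build_patches <- function(grid, type_of, barrier_of) {
  ids <- sort(unique(as.integer(grid)))
  tab <- tabulate(grid, nbins = max(ids))
  rows <- as.integer(row(grid))
  cols <- as.integer(col(grid))
  g <- as.integer(grid)
  cr <- vapply(split(rows, g), mean, 0)
  ccol <- vapply(split(cols, g), mean, 0)
  data.frame(
    id = ids,
    type_code = unname(type_of[as.character(ids)]),
    barrier = unname(barrier_of[as.character(ids)]),
    area_cells = tab[ids],
    centroid_row = unname(cr[as.character(ids)]),
    centroid_col = unname(ccol[as.character(ids)]),
    stringsAsFactors = FALSE
  )
}

#' Construct a landscape object
#'
#' A landscape is a raster `grid` of integer patch identifiers plus a patch
#' attribute table. Areas and centroids are recomputed from the grid, never
#' trusted from the caller.
#'
#' @param grid integer matrix of patch identifiers (every cell owned).
#' @param types named character vector mapping patch id to type code.
#' @param cell_size cell edge length in metres (default 50, the desk-scale
#'   stand-in where a 200 x 200 grid spans 10 x 10 km).
#' @return object of class `landscape` with fields `grid`, `patches`,
#'   `cell_size`.
#' @export
new_landscape <- function(grid, types, cell_size = 50) {
  stopifnot(is.matrix(grid), is.numeric(grid), cell_size > 0)
  storage.mode(grid) <- "integer"
  ids <- sort(unique(as.integer(grid)))
  if (any(ids < 1L)) stop("patch identifiers must be positive integers")
  if (is.null(names(types))) stop("`types` must be a named vector (id -> type_code)")
  missing <- setdiff(as.character(ids), names(types))
  if (length(missing))
    stop("grid identifiers missing from the patch table: ", paste(missing, collapse = ", "))
  barrier_of <- stats::setNames(unname(types) %in% BARRIER_TYPES, names(types))
  patches <- build_patches(grid, types, barrier_of)
  structure(list(grid = grid, patches = patches, cell_size = cell_size),
            class = "landscape")
}

validate_landscape <- function(x) {
  stopifnot(inherits(x, "landscape"))
  g <- x$grid; p <- x$patches
  ids <- sort(unique(as.integer(g)))
  if (!setequal(ids, p$id)) stop("grid ids and patch table ids disagree")
  areas <- tabulate(g, nbins = max(ids))[p$id]
  if (!all(areas == p$area_cells)) stop("patch areas inconsistent with grid")
  if (!all(p$barrier == (p$type_code %in% BARRIER_TYPES)))
    stop("barrier flags inconsistent with type codes")
  invisible(x)
}

#' @export
print.landscape <- function(x, ...) {
  p <- x$patches
  cat("landscape:", nrow(x$grid), "x", ncol(x$grid), "cells,",
      "cell size", x$cell_size, "m\n")
  cat("  patches:", nrow(p), " (", sum(p$barrier), "barrier )\n")
  cov <- sort(relative_cover(x), decreasing = TRUE)
  cat("  cover:", paste(sprintf("%s %.2f", names(cov), cov), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.landscape <- function(x, ...) {
  p <- x$patches
  tt <- sort(unique(p$type_code))
  tmap <- stats::setNames(match(p$type_code, tt), as.character(p$id))
  img <- matrix(tmap[as.character(x$grid)], nrow(x$grid), ncol(x$grid))
  graphics::image(t(img)[, nrow(img):1], col = grDevices::hcl.colors(length(tt), "Spectral"),
                  axes = FALSE, ...)
  invisible(x)
}

#' Patch attribute table with size classes
#'
#' One row per patch: id, type code, barrier flag, area in cells, centroid
#' (row, col), and the quarter-decade size class computed from area in m2
#' (`area_cells * cell_size^2`).
#'
#' @param landscape a `landscape` object.
#' @return data.frame.
#' @export
patch_table <- function(landscape) {
  validate_landscape(landscape)
  p <- landscape$patches
  p$size_class <- size_class(p$area_cells * landscape$cell_size^2)
  p
}

#' Relative cover of each patch type
#'
#' Fraction of all grid cells (barriers included) occupied by each type;
#' fractions sum to 1.
#'
#' @param landscape a `landscape` object.
#' @return named numeric vector.
#' @export
relative_cover <- function(landscape) {
  p <- landscape$patches
  tot <- sum(p$area_cells)
  out <- tapply(p$area_cells, p$type_code, sum) / tot
  stats::setNames(as.numeric(out), names(out))
}

#' Mean nearest-neighbour separation among same-type patches
#'
#' For each type, the mean over its patches of the Euclidean centroid
#' distance (in cells) to the nearest other patch of the same type. Types
#' with a single patch report `NA` (no neighbour exists). Quantifies the
#' fragmentation induced by the landscape transforms.
#'
#' @param landscape a `landscape` object.
#' @return named numeric vector (NA where undefined).
#' @export
same_type_separation <- function(landscape) {
  p <- landscape$patches
  out <- vapply(split(seq_len(nrow(p)), p$type_code), function(idx) {
    if (length(idx) < 2L) return(NA_real_)
    xy <- cbind(p$centroid_row[idx], p$centroid_col[idx])
    d <- as.matrix(stats::dist(xy))
    diag(d) <- Inf
    mean(apply(d, 1L, min))
  }, 0)
  out
}
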