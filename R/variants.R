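# The three complexity-reduction transforms producing landscape variants
# B (homogenized patch shapes), C (within-size-class arrangement
# randomization) and D (unconstrained size randomization) from a variant-A
# mosaic. Barrier elements are left untouched by every transform.

#' Homogenize patch shapes (variant B)
#'
#' Re-tiles the non-barrier area with compact patches that keep their
#' original identifier, type and (up to the deadlock rule) area. Each patch
#' is seeded at its original centroid (snapped to the nearest member cell
#' when the centroid falls outside a concave patch) and the mosaic is
#' regrown one cell at a time: at each step a patch is drawn with
#' probability proportional to the fraction of its original area it has
#' left to grow and claims one unclaimed adjacent cell, so nearly-complete
#' patches grow slowly. A patch that runs out of free adjacent cells is
#' frozen; leftover cells are assigned to the adjacent patch with the
#' largest remaining deficit (ties to the lowest identifier), keeping the
#' tiling total while bounding the area error. Barrier cells are
#' bit-identical to the input. Deterministic given `seed`.
#'
#' @param landscape a `landscape` object (variant A).
#' @param seed integer seed.
#' @return a `landscape` object (variant B).
#' @export
homogenize_shapes <- function(landscape, seed = NULL) {
  validate_landscape(landscape)
  g <- landscape$grid
  nr <- nrow(g); nc <- ncol(g)
  p <- landscape$patches
  hab <- p[!p$barrier, ]
  if (!nrow(hab)) stop("landscape has no non-barrier patches")
  barrier_ids <- p$id[p$barrier]
  free <- !(matrix(g %in% barrier_ids, nr, nc))
  local_seed(seed, {
    # seed each patch at its centroid, snapped to its nearest member cell
    seeds <- integer(nrow(hab))
    for (i in seq_len(nrow(hab))) {
      cells <- which(g == hab$id[i])
      rr <- (cells - 1L) %% nr + 1L
      cc <- (cells - 1L) %/% nr + 1L
      d2 <- (rr - hab$centroid_row[i])^2 + (cc - hab$centroid_col[i])^2
      seeds[i] <- cells[which.min(d2)]
    }
    if (anyDuplicated(seeds)) {
      dup <- hab$id[duplicated(seeds)]
      stop("seed cell unclaimable for patch ", dup[1L])
    }
    gr <- grow_patches(free, seeds, hab$area_cells, rep(FALSE, nrow(hab)))
    gr <- mop_up(gr$claim, gr$sizes, hab$area_cells)
    gr <- balance_areas(gr$claim, gr$sizes, hab$area_cells)
    new_grid <- g                       # barrier cells keep their ids
    sel <- gr$claim > 0L
    new_grid[sel] <- hab$id[gr$claim[sel]]
    types <- stats::setNames(p$type_code, as.character(p$id))
    out <- new_landscape(new_grid, types, cell_size = landscape$cell_size)
    attr(out, "variant") <- "B"
    out
  })
}

#' Randomize patch arrangement within size classes (variant C)
#'
#' Type labels are permuted uniformly at random among non-barrier patches
#' within each quarter-decade size class; geometry (identifiers, outlines)
#' is untouched and per-type patch counts are conserved exactly. Because
#' areas within a class differ slightly, per-type cover is conserved only
#' approximately; a relative change above `cover_tol` triggers a warning.
#' Size classes holding a single patch keep their type (a no-op, recorded
#' in the `notes` attribute).
#'
#' @param landscape a `landscape` object (variant B).
#' @param seed integer seed.
#' @param cover_tol maximum tolerated relative change in per-type cover.
#' @return a `landscape` object (variant C).
#' @export
randomize_arrangement <- function(landscape, seed = NULL, cover_tol = 0.05) {
  validate_landscape(landscape)
  p <- landscape$patches
  hab <- which(!p$barrier)
  cls <- size_class(p$area_cells[hab] * landscape$cell_size^2)
  before <- relative_cover(landscape)
  notes <- character(0)
  local_seed(seed, {
    for (k in unique(cls)) {
      idx <- hab[cls == k]
      if (length(idx) < 2L) {
        notes <- c(notes, paste0("size class ", k, " holds a single patch; type kept"))
        next
      }
      p$type_code[idx] <- p$type_code[idx][sample.int(length(idx))]
    }
  })
  types <- stats::setNames(p$type_code, as.character(p$id))
  out <- new_landscape(landscape$grid, types, cell_size = landscape$cell_size)
  after <- relative_cover(out)
  common <- intersect(names(before), names(after))
  rel <- abs(after[common] - before[common]) / pmax(before[common], 1e-12)
  if (any(rel > cover_tol))
    warning("per-type cover changed by more than ", cover_tol * 100,
            "% for: ", paste(common[rel > cover_tol], collapse = ", "))
  attr(out, "variant") <- "C"
  attr(out, "notes") <- notes
  out
}

#' Randomize patch sizes (variant D)
#'
#' Type labels are permuted uniformly at random over all non-barrier
#' patches irrespective of size class, so the expected cover of a type
#' becomes its patch-count frequency times the total non-barrier area.
#' Geometry and per-type patch counts are conserved.
#'
#' @param landscape a `landscape` object (variant C or B).
#' @param seed integer seed.
#' @return a `landscape` object (variant D).
#' @export
randomize_sizes <- function(landscape, seed = NULL) {
  validate_landscape(landscape)
  p <- landscape$patches
  hab <- which(!p$barrier)
  local_seed(seed, {
    p$type_code[hab] <- p$type_code[hab][sample.int(length(hab))]
  })
  types <- stats::setNames(p$type_code, as.character(p$id))
  out <- new_landscape(landscape$grid, types, cell_size = landscape$cell_size)
  attr(out, "variant") <- "D"
  out
}

#' Build the full variant set A-D
#'
#' B = [homogenize_shapes()] applied to A; C = [randomize_arrangement()]
#' applied to B; D = [randomize_sizes()] applied to C. Each stage uses an
#' independent sub-seed derived from `seed` by stage name, so the set is
#' reproducible stage by stage.
#'
#' @param landscape_A a `landscape` object.
#' @param seed integer master seed.
#' @return named list of `landscape` objects (A, B, C, D).
#' @export
make_variants <- function(landscape_A, seed = NULL) {
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1L)
  A <- landscape_A
  attr(A, "variant") <- "A"
  B <- homogenize_shapes(A, derive_seed(seed, "B"))
  C <- randomize_arrangement(B, derive_seed(seed, "C"))
  D <- randomize_sizes(C, derive_seed(seed, "D"))
  list(A = A, B = B, C = C, D = D)
}

#' Replicate landscapes of one variant type
#'
#' Applies the transform chain to `landscape_A` `n_replicates` times with
#' independent sub-seeds (replicate i uses the full chain under
#' `derive_seed(seed, "rep<i>")`, so n = 1 reproduces the matching
#' [make_variants()] output for that sub-seed). Variant A has no stochastic
#' stage and cannot be replicated.
#'
#' @param landscape_A a `landscape` object.
#' @param variant one of "B", "C", "D".
#' @param n_replicates number of replicates.
#' @param seed integer master seed.
#' @return list of `landscape` objects.
#' @export
replicate_landscapes <- function(landscape_A, variant, n_replicates, seed = NULL) {
  variant <- match.arg(variant, c("B", "C", "D"))
  stopifnot(n_replicates >= 1L)
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1L)
  lapply(seq_len(n_replicates), function(i) {
    s <- derive_seed(seed, paste0("rep", i))
    # same seed derivation as make_variants(landscape_A, s)[[variant]],
    # without computing stages past the one requested
    B <- homogenize_shapes(landscape_A, derive_seed(s, "B"))
    if (variant == "B") return(B)
    C <- randomize_arrangement(B, derive_seed(s, "C"))
    if (variant == "C") return(C)
    randomize_sizes(C, derive_seed(s, "D"))
  })
}
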