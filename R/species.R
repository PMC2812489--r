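# Desk-scale spatially explicit individual-based population engine.
#
# The annual cycle is breed -> disperse -> overwinter, with the census taken
# at the start of the year (1 January, i.e. after the previous overwinter).
# Density dependence is emergent: per-adult fecundity falls linearly with the
# patch's current count relative to its carrying capacity.

#' Construct a species parameter set
#'
#' @param name species label.
#' @param r_max maximum per-capita offspring rate per year (> 0).
#' @param fecundity named vector, habitat type -> multiplier in [0, 1];
#'   omitted types are 0.
#' @param overwinter_survival named vector, habitat type -> survival
#'   probability in [0, 1]; omitted types are 0.
#' @param capacity named vector, habitat type -> carrying-capacity density
#'   (individuals per cell); omitted types are 0.
#' @param d_max maximum dispersal distance in cells (>= 0).
#' @param dispersal_mortality probability a disperser dies in transit.
#' @param barriers_block TRUE for ground-bound dispersers stopped by barrier
#'   cells; FALSE for fliers/ballooners that cross them at no extra cost.
#' @param semelparous TRUE if adults die after breeding (short-lived,
#'   fast-reproducing species); FALSE if adults also overwinter.
#' @param complementation_types habitat types required within `d_w` cells of
#'   an individual's cell for overwinter survival (empty = unused).
#' @param d_w complementation neighbourhood radius in cells (4-neighbourhood
#'   dilation steps).
#' @param avoidance_types habitat types avoided for breeding: adults within
#'   `d_t` cells of these types do not breed (empty = unused).
#' @param d_t avoidance neighbourhood radius in cells.
#' @return object of class `species_params`.
#' @export
species_params <- function(name, r_max, fecundity, overwinter_survival,
                           capacity, d_max, dispersal_mortality,
                           barriers_block, semelparous,
                           complementation_types = character(0), d_w = 0L,
                           avoidance_types = character(0), d_t = 0L) {
  stopifnot(r_max > 0, d_max >= 0, d_w >= 0, d_t >= 0,
            dispersal_mortality >= 0, dispersal_mortality <= 1,
            all(fecundity >= 0), all(fecundity <= 1),
            all(overwinter_survival >= 0), all(overwinter_survival <= 1),
            all(capacity >= 0))
  structure(list(
    name = name, r_max = r_max, fecundity = fecundity,
    overwinter_survival = overwinter_survival, capacity = capacity,
    d_max = d_max, dispersal_mortality = dispersal_mortality,
    barriers_block = barriers_block, semelparous = semelparous,
    complementation_types = complementation_types, d_w = as.integer(d_w),
    avoidance_types = avoidance_types, d_t = as.integer(d_t)
  ), class = "species_params")
}

#' @export
print.species_params <- function(x, ...) {
  cat("species archetype:", x$name, "\n")
  cat("  r_max", x$r_max,
      if (x$semelparous) "(semelparous)" else "(iteroparous)", "\n")
  cat("  dispersal: d_max", x$d_max, "cells, mortality", x$dispersal_mortality,
      if (x$barriers_block) "(blocked by barriers)" else "(crosses barriers)", "\n")
  if (length(x$complementation_types))
    cat("  complementation:", paste(x$complementation_types, collapse = ", "),
        "within", x$d_w, "cells\n")
  if (length(x$avoidance_types))
    cat("  avoidance:", paste(x$avoidance_types, collapse = ", "),
        "within", x$d_t, "cells\n")
  invisible(x)
}

#' Packaged life-history archetypes
#'
#' Four contrasting archetypes. The defaults are this package's own; only
#' the ordinal relations between them reflect the modelled species:
#' \describe{
#'   \item{beetle}{fast-reproducing, short-dispersing ground beetle of
#'     arable fields, blocked by barriers; overwinter survival requires
#'     vegetated field boundaries or hedgerows within `d_w` cells
#'     (landscape complementation).}
#'   \item{vole}{slower-reproducing, short-dispersing grassland specialist
#'     with elevated mortality in the surrounding matrix.}
#'   \item{skylark}{slow-reproducing, long-dispersing open-field breeder
#'     that does not nest within `d_t` cells of forest or hedgerows.}
#'   \item{spider}{fast-reproducing linyphiid able to disperse far by
#'     ballooning at the cost of high in-transit mortality; insensitive to
#'     the surrounding patch types.}
#' }
#'
#' @param name one of "beetle", "vole", "skylark", "spider".
#' @return a `species_params` object.
#' @export
make_archetype <- function(name) {
  valid <- c("beetle", "vole", "skylark", "spider")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid))
    stop("unknown archetype; valid archetypes are: ",
         paste(valid, collapse = ", "))
  switch(name,
    beetle = species_params(
      name = "beetle", r_max = 6, semelparous = TRUE,
      fecundity = c(rotational_field = 1.0, field_boundary = 0.5,
                    hedgerow = 0.5, roadside_verge = 0.3, grassland = 0.2),
      overwinter_survival = c(rotational_field = 0.55, field_boundary = 0.65,
                              hedgerow = 0.65, roadside_verge = 0.55,
                              grassland = 0.45, forest = 0.10),
      capacity = c(rotational_field = 0.30, field_boundary = 0.20,
                   hedgerow = 0.20, roadside_verge = 0.15, grassland = 0.10),
      d_max = 3, dispersal_mortality = 0.10, barriers_block = TRUE,
      complementation_types = c("field_boundary", "hedgerow"), d_w = 2L),
    vole = species_params(
      name = "vole", r_max = 4, semelparous = FALSE,
      fecundity = c(grassland = 1.0, roadside_verge = 0.5,
                    field_boundary = 0.4, hedgerow = 0.4,
                    rotational_field = 0.10, forest = 0.05),
      overwinter_survival = c(grassland = 0.60, roadside_verge = 0.35,
                              field_boundary = 0.30, hedgerow = 0.30,
                              rotational_field = 0.15, forest = 0.15),
      capacity = c(grassland = 0.40, roadside_verge = 0.15,
                   field_boundary = 0.10, hedgerow = 0.10,
                   rotational_field = 0.05),
      d_max = 4, dispersal_mortality = 0.15, barriers_block = TRUE),
    skylark = species_params(
      name = "skylark", r_max = 2.2, semelparous = FALSE,
      fecundity = c(rotational_field = 1.0, grassland = 0.6,
                    roadside_verge = 0.3),
      overwinter_survival = c(rotational_field = 0.75, grassland = 0.75,
                              roadside_verge = 0.60, field_boundary = 0.50,
                              hedgerow = 0.50, forest = 0.50),
      capacity = c(rotational_field = 0.06, grassland = 0.04,
                   roadside_verge = 0.02),
      d_max = 40, dispersal_mortality = 0.05, barriers_block = FALSE,
      avoidance_types = c("forest", "hedgerow"), d_t = 2L),
    spider = species_params(
      name = "spider", r_max = 8, semelparous = TRUE,
      fecundity = c(rotational_field = 1.0, grassland = 0.8,
                    field_boundary = 0.8, roadside_verge = 0.8,
                    hedgerow = 0.8, forest = 0.8),
      overwinter_survival = c(rotational_field = 0.50, grassland = 0.50,
                              field_boundary = 0.50, roadside_verge = 0.50,
                              hedgerow = 0.50, forest = 0.50),
      capacity = c(rotational_field = 0.25, grassland = 0.25,
                   field_boundary = 0.25, roadside_verge = 0.25,
                   hedgerow = 0.25, forest = 0.25),
      d_max = 50, dispersal_mortality = 0.50, barriers_block = FALSE)
  )
}

#' Weather-year multipliers
#'
#' A cycle of exactly 10 labelled fecundity multipliers, applied
#' sequentially by calendar year (label of year y is `(y - 1) mod 10 + 1`).
#' Multipliers are log-normal with unit mean and fixed per label, so weather
#' years form reproducible groups for the random-asymptote fit.
#'
#' @param sigma log-scale standard deviation of the multipliers.
#' @param seed integer seed.
#' @param n_labels cycle length (default and study condition: 10).
#' @return named numeric vector of class `weather_sequence`.
#' @export
weather_sequence <- function(sigma = 0.15, seed = NULL, n_labels = 10L) {
  stopifnot(sigma >= 0, n_labels >= 1L)
  w <- local_seed(seed, exp(stats::rnorm(n_labels, 0, sigma) - sigma^2 / 2))
  structure(stats::setNames(w, sprintf("w%02d", seq_len(n_labels))),
            class = "weather_sequence")
}

#' Weather label of a calendar year
#' @param year calendar year index (1-based).
#' @param n_labels cycle length.
#' @return integer label index in `1..n_labels`.
#' @export
weather_label <- function(year, n_labels = 10L) (year - 1L) %% n_labels + 1L

# Precompute the per-cell lookups one simulation needs: type index, patch
# id, barrier mask, per-patch capacity, fecundity/survival per cell, and the
# complementation / avoidance neighbourhood masks.
species_context <- function(landscape, species) {
  validate_landscape(landscape)
  g <- landscape$grid
  p <- landscape$patches
  nr <- nrow(g); nc <- ncol(g)
  type_of <- stats::setNames(p$type_code, as.character(p$id))
  maxid <- max(p$id)
  type_by_id <- character(maxid)
  type_by_id[p$id] <- p$type_code
  barrier_by_id <- logical(maxid)
  barrier_by_id[p$id] <- p$barrier
  area_by_id <- integer(maxid)
  area_by_id[p$id] <- p$area_cells

  lookup <- function(map) {
    v <- numeric(maxid)
    hit <- type_by_id %in% names(map)
    v[hit] <- map[type_by_id[hit]]
    v
  }
  fec_by_id <- lookup(species$fecundity)
  surv_by_id <- lookup(species$overwinter_survival)
  kappa_by_id <- lookup(species$capacity)
  fec_by_id[barrier_by_id] <- 0
  surv_by_id[barrier_by_id] <- 0

  barrier_mask <- matrix(barrier_by_id[g], nr, nc)
  comp_ok <- NULL
  if (length(species$complementation_types)) {
    src <- matrix(type_by_id[g] %in% species$complementation_types, nr, nc)
    comp_ok <- dilate4(src, species$d_w)
  }
  avoid <- NULL
  if (length(species$avoidance_types)) {
    src <- matrix(type_by_id[g] %in% species$avoidance_types, nr, nc)
    avoid <- dilate4(src, species$d_t)
  }
  habitable <- which(fec_by_id[g] > 0 & !barrier_mask)
  list(nr = nr, nc = nc, grid = g,
       fec_cell = fec_by_id[g], surv_cell = surv_by_id[g],
       kappa_patch = kappa_by_id * area_by_id,   # capacity per patch
       barrier_mask = barrier_mask, comp_ok = comp_ok, avoid = avoid,
       habitable = habitable)
}

new_population <- function(row, col) {
  structure(list(row = as.integer(row), col = as.integer(col),
                 age = rep("adult", length(row))),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat("population of", length(x$row), "individuals\n")
  invisible(x)
}

#' Initialize a population
#'
#' Places `round(initial_density * n_habitable)` adults uniformly at random
#' on habitable cells (non-barrier cells whose type has positive fecundity).
#'
#' @param landscape a `landscape` object.
#' @param species a `species_params` object.
#' @param initial_density individuals per habitable cell (>= 0).
#' @param seed integer seed.
#' @param ctx optional precomputed context from an earlier call (internal).
#' @return a `population` object.
#' @export
init_population <- function(landscape, species, initial_density, seed = NULL,
                            ctx = NULL) {
  stopifnot(initial_density >= 0)
  if (is.null(ctx)) ctx <- species_context(landscape, species)
  if (!length(ctx$habitable)) stop("no habitable cell for species ", species$name)
  n <- round(initial_density * length(ctx$habitable))
  if (n == 0) return(new_population(integer(0), integer(0)))
  cells <- local_seed(seed, sample(ctx$habitable, n, replace = TRUE))
  new_population((cells - 1L) %% ctx$nr + 1L, (cells - 1L) %/% ctx$nr + 1L)
}

#' Census: total population size
#'
#' Taken at the start of the year (1 January), i.e. after the previous
#' overwinter and before breeding.
#'
#' @param population a `population` object.
#' @return non-negative integer count.
#' @export
census <- function(population) length(population$row)

# Per-patch counts (named by patch id).
patch_counts <- function(population, landscape) {
  g <- landscape$grid
  lin <- (population$col - 1L) * nrow(g) + population$row
  tab <- tabulate(g[lin], nbins = max(landscape$patches$id))
  stats::setNames(tab[landscape$patches$id],
                  as.character(landscape$patches$id))
}

#' Advance the population by one year
#'
#' Applies, in order: (1) breeding -- each adult on a cell of type h
#' produces `Poisson(r_max * fecundity[h] * w_y * max(0, 1 - n/K_patch))`
#' offspring, where n is the patch's current adult count and K_patch its
#' carrying capacity (capacity density times patch area); adults of
#' avoidance archetypes within `d_t` of avoided types do not breed; adults
#' of semelparous archetypes then die. (2) dispersal -- every juvenile
#' draws a uniform direction and a uniform distance on `[0, d_max]`;
#' ground-bound dispersers stop at the cell before the first barrier cell on
#' the straight (cell-centre rasterized) path, fliers settle on the last
#' non-barrier cell of the path; the grid edge halts movement; each
#' disperser dies in transit with probability `dispersal_mortality`.
#' (3) overwinter -- each individual survives with the survival probability
#' of its cell's type; complementation archetypes survive only if some cell
#' within `d_w` holds a complementation type. Survivors enter the next year
#' as adults.
#'
#' @param population a `population` object.
#' @param landscape a `landscape` object.
#' @param species a `species_params` object.
#' @param w_y weather multiplier for the year (> 0).
#' @param seed optional integer seed (NULL = continue the current stream).
#' @param ctx optional precomputed context (reused across years by
#'   [run_experiment()]).
#' @return a `population` object.
#' @export
step_year <- function(population, landscape, species, w_y = 1, seed = NULL,
                      ctx = NULL) {
  stopifnot(w_y > 0)
  if (is.null(ctx)) ctx <- species_context(landscape, species)
  local_seed(seed, {
    nr <- ctx$nr; nc <- ctx$nc
    n0 <- length(population$row)
    if (n0 == 0L) return(new_population(integer(0), integer(0)))
    lin <- (population$col - 1L) * nr + population$row

    ## 1) breeding
    pid <- ctx$grid[lin]
    n_patch <- tabulate(pid, nbins = length(ctx$kappa_patch))
    dens <- pmax(0, 1 - n_patch[pid] / pmax(ctx$kappa_patch[pid], 1e-12))
    lambda <- species$r_max * ctx$fec_cell[lin] * w_y * dens
    if (!is.null(ctx$avoid)) lambda[ctx$avoid[lin]] <- 0
    off <- stats::rpois(n0, lambda)
    jrow <- rep.int(population$row, off)
    jcol <- rep.int(population$col, off)

    ## 2) juvenile dispersal
    nj <- length(jrow)
    if (nj && species$d_max > 0) {
      theta <- stats::runif(nj, 0, 2 * pi)
      dist <- stats::runif(nj, 0, species$d_max)
      dr <- sin(theta); dc <- cos(theta)
      cur_r <- jrow; cur_c <- jcol          # last valid (settleable) cell
      active <- rep(TRUE, nj)
      maxstep <- ceiling(species$d_max)
      for (s in seq_len(maxstep)) {
        active <- active & (dist >= s - 0.5)
        if (!any(active)) break
        idx <- which(active)
        rr <- jrow[idx] + as.integer(round(s * dr[idx]))
        cc <- jcol[idx] + as.integer(round(s * dc[idx]))
        inside <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        active[idx[!inside]] <- FALSE       # the grid edge halts movement
        ok <- idx[inside]
        if (!length(ok)) next
        rr <- rr[inside]; cc <- cc[inside]
        bar <- ctx$barrier_mask[(cc - 1L) * nr + rr]
        if (species$barriers_block) {
          active[ok[bar]] <- FALSE          # stop at the cell before it
          keep <- !bar
        } else {
          keep <- !bar                      # cross, but only settle off-barrier
        }
        cur_r[ok[keep]] <- rr[keep]
        cur_c[ok[keep]] <- cc[keep]
      }
      jrow <- cur_r; jcol <- cur_c
    }
    if (nj && species$dispersal_mortality > 0) {
      live <- stats::runif(nj) >= species$dispersal_mortality
      jrow <- jrow[live]; jcol <- jcol[live]
    }

    ## adults die after breeding in semelparous archetypes
    if (species$semelparous) {
      arow <- integer(0); acol <- integer(0)
    } else {
      arow <- population$row; acol <- population$col
    }
    row_all <- c(arow, jrow); col_all <- c(acol, jcol)
    n_all <- length(row_all)
    if (n_all == 0L) return(new_population(integer(0), integer(0)))

    ## 3) overwinter
    lin_all <- (col_all - 1L) * nr + row_all
    sv <- ctx$surv_cell[lin_all]
    if (!is.null(ctx$comp_ok)) sv[!ctx$comp_ok[lin_all]] <- 0
    keep <- stats::runif(n_all) < sv
    new_population(row_all[keep], col_all[keep])
  })
}
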