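# Stochastic region-growing engine shared by the synthetic generator and the
# shape-homogenization transform.
#
# Patches grow one cell at a time from fixed seed cells. At every step one
# growing patch is drawn with probability proportional to the fraction of its
# target area it has left to grow, and claims one unclaimed growable cell
# adjacent (4-neighbourhood) to its current extent; patches close to their
# target therefore grow slowly. A patch whose frontier is exhausted is frozen.

# free: logical matrix (TRUE = growable); seeds: linear index per patch;
# targets: integer target areas; elongated: per-patch flag -- elongated
# patches grow preferentially along a random axis through their seed (a
# narrow strip), compact patches claim uniformly at random among frontier
# cells. Returns list(claim = integer matrix (0 unclaimed, -1 blocked, else
# patch index), sizes).
grow_patches <- function(free, seeds, targets, elongated) {
  nr <- nrow(free); nc <- ncol(free)
  n <- length(seeds)
  stopifnot(length(targets) == n, length(elongated) == n)
  if (anyDuplicated(seeds)) stop("duplicate seed cells")
  if (!all(free[seeds])) stop("seed cell not growable for patch ",
                              which(!free[seeds])[1L])
  claim <- matrix(0L, nr, nc)
  claim[!free] <- -1L
  claim[seeds] <- seq_len(n)
  sizes <- rep(1L, n)
  seed_r <- (seeds - 1L) %% nr + 1L
  seed_c <- (seeds - 1L) %/% nr + 1L
  axis <- stats::runif(n, 0, pi)          # elongation axis per patch
  frontier <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- neighbors4(seeds[i], nr, nc)
    frontier[[i]] <- nb[claim[nb] == 0L]
  }
  active <- which(sizes < targets)
  dead <- rep(FALSE, n)
  while (length(active)) {
    rem <- (targets[active] - sizes[active]) / targets[active]
    i <- if (length(active) == 1L) active else
      active[sample.int(length(active), 1L, prob = rem)]
    fr <- frontier[[i]]
    fr <- fr[claim[fr] == 0L]
    if (!length(fr)) {              # deadlocked: freeze this patch
      frontier[[i]] <- integer(0)
      dead[i] <- TRUE
      active <- active[active != i]
      next
    }
    if (elongated[i]) {
      # prefer cells near the axis line through the seed, extending along it
      cand <- if (length(fr) > 12L) fr[sample.int(length(fr), 12L)] else fr
      dr <- (cand - 1L) %% nr + 1L - seed_r[i]
      dc <- (cand - 1L) %/% nr + 1L - seed_c[i]
      along <- dr * sin(axis[i]) + dc * cos(axis[i])
      perp <- -dr * cos(axis[i]) + dc * sin(axis[i])
      score <- 4 * perp^2 - 0.2 * abs(along) + stats::runif(length(cand))
      cell <- cand[which.min(score)]
    } else {
      cell <- if (length(fr) == 1L) fr else fr[sample.int(length(fr), 1L)]
    }
    claim[cell] <- i
    sizes[i] <- sizes[i] + 1L
    nb <- neighbors4(cell, nr, nc)
    frontier[[i]] <- c(fr[fr != cell], nb[claim[nb] == 0L])
    if (sizes[i] >= targets[i]) active <- active[active != i]
  }
  list(claim = claim, sizes = sizes)
}

# Assign remaining unclaimed growable cells to the adjacent patch with the
# largest remaining deficit (target - size), ties broken by lowest patch
# index; swept repeatedly until the tiling is total. Errors if unreachable
# cells remain (growable area not adjacent to any patch).
mop_up <- function(claim, sizes, targets) {
  nr <- nrow(claim); nc <- ncol(claim)
  repeat {
    un <- which(claim == 0L)
    if (!length(un)) break
    assigned <- FALSE
    for (L in un) {
      nb <- neighbors4(L, nr, nc)
      pn <- unique(claim[nb])
      pn <- pn[pn > 0L]
      if (!length(pn)) next
      defic <- targets[pn] - sizes[pn]
      p <- pn[order(-defic, pn)][1L]
      claim[L] <- p
      sizes[p] <- sizes[p] + 1L
      assigned <- TRUE
    }
    if (!assigned)
      stop("unreachable growable cells remain: ", sum(claim == 0L),
           " cells are not adjacent to any patch")
  }
  list(claim = claim, sizes = sizes)
}

# Snap target areas to the quarter-decade class-centre ladder
# (round(10^((j + 0.5) / 4)) cells) and adjust rung assignments so they sum
# to `total`: patches are promoted/demoted one rung at a time, preferring
# the largest admissible step, so all areas stay on the ladder and patches
# within a size class are interchangeable without altering cover. Any
# residual smaller than the finest step lands on the largest patch.
snap_ladder <- function(raw, total) {
  jmax <- max(30L, ceiling(4 * log10(total)) + 2L)
  ladder <- as.integer(round(10^((seq_len(jmax) - 1L + 0.5) / 4)))
  j <- pmin(pmax(as.integer(round(4 * log10(raw) - 0.5)) + 1L, 1L), jmax)
  delta <- total - sum(ladder[j])
  for (iter in seq_len(8L * length(raw))) {
    if (delta == 0L) break
    if (delta > 0L) {
      up <- which(j < jmax)
      if (!length(up)) break
      steps <- ladder[j[up] + 1L] - ladder[j[up]]
      ok <- steps <= delta
      pick <- if (any(ok)) up[ok][which.max(steps[ok])] else up[which.min(steps)]
      delta <- delta - (ladder[j[pick] + 1L] - ladder[j[pick]])
      j[pick] <- j[pick] + 1L
    } else {
      dn <- which(j > 1L)
      if (!length(dn)) break
      steps <- ladder[j[dn]] - ladder[j[dn] - 1L]
      ok <- steps <= -delta
      pick <- if (any(ok)) dn[ok][which.max(steps[ok])] else dn[which.min(steps)]
      delta <- delta + (ladder[j[pick]] - ladder[j[pick] - 1L])
      j[pick] <- j[pick] - 1L
    }
  }
  out <- ladder[j]
  if (delta != 0L) {
    big <- which.max(out)
    out[big] <- max(1L, out[big] + delta)
  }
  out
}

# TRUE when removing cell L from patch p keeps the patch 4-connected
# locally (standard simple-point test for 4-connectivity): the member
# 4-neighbours must form a single arc, where consecutive 4-neighbours are
# linked through the shared corner cell.
is_simple4 <- function(claim, L, p, nr, nc) {
  r <- (L - 1L) %% nr + 1L
  cc <- (L - 1L) %/% nr + 1L
  mem <- function(rr, ccc)
    rr >= 1L && rr <= nr && ccc >= 1L && ccc <= nc && claim[rr, ccc] == p
  pres <- c(mem(r - 1L, cc), mem(r, cc + 1L), mem(r + 1L, cc), mem(r, cc - 1L))
  k <- sum(pres)
  if (k == 0L) return(FALSE)
  if (k == 1L) return(TRUE)
  link <- c(mem(r - 1L, cc + 1L), mem(r + 1L, cc + 1L),
            mem(r + 1L, cc - 1L), mem(r - 1L, cc - 1L))
  comps <- 0L
  for (i in 1:4) {
    j <- i %% 4L + 1L
    if (pres[i] && !(pres[j] && link[i])) comps <- comps + 1L
  }
  comps == 1L
}

# Area-balancing diffusion after growth and mop-up: surplus patches donate
# boundary cells to adjacent patches, moving each patch's area toward its
# target while preserving 4-connectivity (only simple cells are donated).
# A transfer is allowed when it moves surplus directly into deficit, down a
# surplus gradient, or laterally toward the nearest deficit patch in the
# patch-adjacency graph (directed routing through intermediate patches).
# Terminates at a sweep cap or when no admissible move remains.
balance_areas <- function(claim, sizes, targets, max_sweeps = 500L) {
  nr <- nrow(claim); nc <- ncol(claim)
  np <- length(targets)
  pot <- sizes - targets
  for (sweep in seq_len(max_sweeps)) {
    if (all(pot == 0L)) break
    # candidate transfers: boundary cells with a different positive owner
    idx <- which(claim > 0L)
    cand_cell <- integer(0); cand_to <- integer(0)
    for (shift in c(-1L, 1L, -nr, nr)) {
      nb <- idx + shift
      ok <- nb >= 1L & nb <= nr * nc
      if (shift == -1L) ok <- ok & (idx - 1L) %% nr != 0L
      if (shift == 1L)  ok <- ok & idx %% nr != 0L
      own <- claim[idx[ok]]
      oth <- claim[nb[ok]]
      sel <- oth > 0L & oth != own
      cand_cell <- c(cand_cell, idx[ok][sel])
      cand_to <- c(cand_to, oth[sel])
    }
    if (!length(cand_cell)) break
    # BFS distance to the nearest deficit patch over patch adjacency
    adj_from <- c(claim[cand_cell], cand_to)
    adj_to <- c(cand_to, claim[cand_cell])
    dist <- rep(NA_integer_, np)
    frontier <- which(pot < 0L)
    dist[frontier] <- 0L
    dd <- 0L
    while (length(frontier)) {
      dd <- dd + 1L
      nxt <- unique(adj_to[adj_from %in% frontier])
      nxt <- nxt[is.na(dist[nxt])]
      dist[nxt] <- dd
      frontier <- nxt
    }
    ord <- sample.int(length(cand_cell))
    moved <- FALSE
    for (j in ord) {
      L <- cand_cell[j]
      p <- claim[L]
      q <- cand_to[j]
      if (p <= 0L || claim[L] != p) next
      dp <- pot[p]; dq <- pot[q]
      admissible <- (dp >= 1L && dq <= -1L) || (dp - dq >= 2L) ||
        (dp >= 1L && dq <= 0L && !is.na(dist[p]) && !is.na(dist[q]) &&
           dist[q] < dist[p])
      if (!admissible) next
      if (sizes[p] <= 1L) next
      # the candidate list predates earlier moves in this sweep: the cell
      # must still touch the receiver or the transfer would disconnect q
      r <- (L - 1L) %% nr + 1L; cc <- (L - 1L) %/% nr + 1L
      touches_q <- (r > 1L && claim[r - 1L, cc] == q) ||
        (r < nr && claim[r + 1L, cc] == q) ||
        (cc > 1L && claim[r, cc - 1L] == q) ||
        (cc < nc && claim[r, cc + 1L] == q)
      if (!touches_q) next
      if (!is_simple4(claim, L, p, nr, nc)) next
      claim[L] <- q
      sizes[p] <- sizes[p] - 1L; sizes[q] <- sizes[q] + 1L
      pot[p] <- pot[p] - 1L; pot[q] <- pot[q] + 1L
      moved <- TRUE
    }
    if (!moved) break
  }
  list(claim = claim, sizes = sizes)
}

#' Stamp a simple barrier layout
#'
#' Builds a character matrix of barrier type codes (NA = free) with a road
#' grid, an optional meandering river, scattered 2 x 2 buildings and circular
#' lakes. Stamp order is lake, river, road, building, so roads stay
#' continuous where they cross the river.
#'
#' @param extent_cells integer (square) or length-2 (rows, cols) grid extent.
#' @param road_spacing spacing in cells between grid roads (NULL = no roads).
#' @param river logical, add one meandering top-to-bottom river.
#' @param n_buildings number of scattered 2 x 2 building blocks.
#' @param n_lakes number of circular lakes (radius 3 cells).
#' @param seed integer seed.
#' @return character matrix (NA where no barrier).
#' @export
make_barrier_layout <- function(extent_cells, road_spacing = NULL,
                                river = FALSE, n_buildings = 0L,
                                n_lakes = 0L, seed = NULL) {
  if (length(extent_cells) == 1L) extent_cells <- rep(extent_cells, 2L)
  nr <- extent_cells[1L]; nc <- extent_cells[2L]
  m <- matrix(NA_character_, nr, nc)
  local_seed(seed, {
    for (k in seq_len(n_lakes)) {
      cr <- sample.int(nr, 1L); cc <- sample.int(nc, 1L)
      sel <- outer(seq_len(nr), seq_len(nc),
                   function(r, c) (r - cr)^2 + (c - cc)^2 <= 9)
      m[sel] <- "lake"
    }
    if (isTRUE(river)) {
      cc <- sample.int(nc, 1L)
      for (r in seq_len(nr)) {
        m[r, cc] <- "river"
        cc <- min(nc, max(1L, cc + sample(c(-1L, 0L, 0L, 1L), 1L)))
      }
    }
    if (!is.null(road_spacing)) {
      rs <- seq(road_spacing, nr - 1L, by = road_spacing)
      cs <- seq(road_spacing, nc - 1L, by = road_spacing)
      m[rs, ] <- "road"
      m[, cs] <- "road"
    }
    if (n_buildings > 0L) {
      for (k in seq_len(n_buildings)) {
        r <- sample.int(nr - 1L, 1L); cc <- sample.int(nc - 1L, 1L)
        blk <- m[r:(r + 1L), cc:(cc + 1L)]
        if (all(is.na(blk))) m[r:(r + 1L), cc:(cc + 1L)] <- "building"
      }
    }
  })
  m
}

#' Generate a synthetic patch-mosaic landscape
#'
#' Emulates the statistical structure of an agricultural patch mosaic:
#' immovable barrier elements are stamped first and never overwritten, then
#' `n_patches` contiguous habitat patches are grown from random seed points
#' until the non-barrier area is completely tiled. Patch counts per type
#' follow the vocabulary's cover targets; target areas are drawn
#' log-uniformly within each type's size range (type-stratified and
#' right-skewed, spanning more than two orders of magnitude overall) and
#' rescaled per type so realized cover tracks the target fractions.
#' Corridor-like types (vocabulary's `elongated` flag) grow with an
#' elongation preference. Deterministic given `seed`.
#'
#' @param extent_cells integer (square) or length-2 (rows, cols) extent.
#' @param n_patches number of habitat patches to grow.
#' @param vocabulary habitat vocabulary (see [default_vocabulary()]).
#' @param barrier_layout character matrix from [make_barrier_layout()], or
#'   NULL for no barriers.
#' @param seed integer seed.
#' @param cell_size cell edge length in metres.
#' @return a `landscape` object.
#' @export
generate_landscape <- function(extent_cells, n_patches,
                               vocabulary = default_vocabulary(),
                               barrier_layout = NULL, seed = NULL,
                               cell_size = 50) {
  if (length(extent_cells) == 1L) extent_cells <- rep(extent_cells, 2L)
  nr <- extent_cells[1L]; nc <- extent_cells[2L]
  vocabulary <- check_vocabulary(vocabulary)
  stopifnot(n_patches >= 1L)
  if (!is.null(barrier_layout))
    stopifnot(is.matrix(barrier_layout), nrow(barrier_layout) == nr,
              ncol(barrier_layout) == nc,
              all(barrier_layout[!is.na(barrier_layout)] %in% BARRIER_TYPES))
  free <- if (is.null(barrier_layout)) matrix(TRUE, nr, nc) else is.na(barrier_layout)
  n_free <- sum(free)
  if (n_patches > n_free)
    stop("infeasible tiling: ", n_patches, " patches requested for ",
         n_free, " free cells")
  comp <- label_components(free)
  n_comp <- max(comp)
  if (n_comp == 0L) stop("no free cells to tile")
  comp_sizes <- tabulate(comp, nbins = n_comp)
  if (n_patches < n_comp)
    stop("infeasible tiling: the barrier layout splits the free area into ",
         n_comp, " components but only ", n_patches, " patches were requested")

  local_seed(seed, {
    per_comp <- apportion(comp_sizes, n_patches, minimum = 1L)
    total_free <- sum(comp_sizes)
    ntypes <- nrow(vocabulary)
    span <- pmax(vocabulary$size_hi - vocabulary$size_lo, 1e-9)
    mean_area <- (10^vocabulary$size_hi - 10^vocabulary$size_lo) /
      (span * log(10))                      # E[10^U(lo, hi)]
    if (n_patches >= ntypes) {
      # patch counts per type from cover targets and mean patch size
      n_type <- apportion(vocabulary$cover / mean_area, n_patches, minimum = 1L)
      type_i <- sample(rep(seq_len(ntypes), n_type))
    } else {
      type_i <- sample.int(ntypes, n_patches, replace = TRUE,
                           prob = vocabulary$cover)
    }
    # raw target areas: log-uniform within the type's size range, then
    # rescaled per type so realized cover matches the target fractions
    raw <- 10^stats::runif(n_patches, vocabulary$size_lo[type_i],
                           vocabulary$size_hi[type_i])
    for (ti in unique(type_i)) {
      sel <- type_i == ti
      share <- vocabulary$cover[ti] /
        sum(vocabulary$cover[unique(type_i)])
      raw[sel] <- raw[sel] * (share * total_free / sum(raw[sel]))
    }
    types <- vocabulary$type_code[type_i]
    elong <- vocabulary$elongated[type_i]
    # distribute patches over free-space components and integerize targets,
    # snapping areas to quarter-decade class-centre rungs so patches within
    # a size class are interchangeable without altering cover; each
    # component's residual is absorbed by its largest patch
    targets <- integer(n_patches)
    seeds <- integer(n_patches)
    slot <- split(sample.int(n_patches), rep(seq_len(n_comp), per_comp))
    for (k in seq_len(n_comp)) {
      idx <- slot[[k]]
      targets[idx] <- snap_ladder(pmax(raw[idx], 1), comp_sizes[k])
      cells_k <- which(comp == k)
      seeds[idx] <- if (length(cells_k) == 1L) cells_k else
        sample(cells_k, length(idx))
    }
    gr <- grow_patches(free, seeds, targets, elong)
    gr <- mop_up(gr$claim, gr$sizes, targets)
    gr <- balance_areas(gr$claim, gr$sizes, targets)
    balance_gap <- sum(abs(gr$sizes - targets))
    grid <- gr$claim
    type_of <- stats::setNames(types, as.character(seq_len(n_patches)))
    # barrier features become patches: connected same-type regions
    if (!is.null(barrier_layout) && any(!is.na(barrier_layout))) {
      next_id <- n_patches
      for (bt in unique(barrier_layout[!is.na(barrier_layout)])) {
        bcomp <- label_components(!is.na(barrier_layout) & barrier_layout == bt)
        nb <- max(bcomp)
        sel <- bcomp > 0L
        grid[sel] <- next_id + bcomp[sel]
        type_of <- c(type_of, stats::setNames(rep(bt, nb),
                                              as.character(next_id + seq_len(nb))))
        next_id <- next_id + nb
      }
    }
    out <- new_landscape(grid, type_of, cell_size = cell_size)
    attr(out, "balance_gap") <- balance_gap
    out
  })
}
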