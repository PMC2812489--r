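# Shared fixtures: hand-built landscapes, custom species, and the
# independently coded scalar stochastic-logistic oracle used to check the
# spatial engine.

# A landscape that is a single habitat patch covering an n x n grid.
single_patch_landscape <- function(n = 40, type = "rotational_field",
                                   cell_size = 50) {
  new_landscape(matrix(1L, n, n), stats::setNames(type, "1"),
                cell_size = cell_size)
}

# Two-patch landscape: left half type_a (id 1), right half type_b (id 2).
two_patch_landscape <- function(n = 10, type_a = "rotational_field",
                                type_b = "grassland") {
  g <- matrix(1L, n, n)
  g[, (n %/% 2 + 1):n] <- 2L
  new_landscape(g, stats::setNames(c(type_a, type_b), c("1", "2")))
}

# Minimal semelparous field specialist without complementation or barriers:
# its single-patch dynamics match the scalar oracle exactly. The default
# growth rate r * f * s = 2 keeps the discrete logistic in the stable
# regime (no overshoot past the capacity, which would zero fecundity).
oracle_species <- function(r_max = 4, fec = 1, surv = 0.5, kappa = 0.5,
                           d_max = 3) {
  species_params(
    name = "oracle", r_max = r_max, semelparous = TRUE,
    fecundity = c(rotational_field = fec),
    overwinter_survival = c(rotational_field = surv),
    capacity = c(rotational_field = kappa),
    d_max = d_max, dispersal_mortality = 0, barriers_block = FALSE)
}

# Independently coded scalar stochastic-logistic oracle: the same
# Poisson-breeding / binomial-survival annual scheme as the spatial engine,
# collapsed to one number. Census first, then breed -> survive.
oracle_run <- function(N0, years, r, f, surv, kA, w = 1, semelparous = TRUE,
                       adult_surv = surv) {
  N <- integer(years)
  cur <- N0
  for (y in seq_len(years)) {
    N[y] <- cur
    dens <- max(0, 1 - cur / kA)
    off <- stats::rpois(1L, cur * r * f * w * dens)
    juv <- stats::rbinom(1L, off, surv)
    cur <- if (semelparous) juv else juv + stats::rbinom(1L, cur, adult_surv)
  }
  N
}

# Deterministic fixed point of the matched semelparous map
# N' = N * r * f * s * (1 - N / kA).
oracle_fixed_point <- function(r, f, surv, kA) kA * (1 - 1 / (r * f * surv))

# Small generated landscape shared across tests (built once per run).
cached_landscape <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_landscape(100, 120, seed = 42,
        barrier_layout = make_barrier_layout(100, road_spacing = 50,
                                             n_buildings = 4, seed = 7))
    cache
  }
})
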