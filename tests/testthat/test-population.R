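test_that("archetypes encode the intended ordinal life-history contrasts", {
  b <- make_archetype("beetle"); v <- make_archetype("vole")
  sk <- make_archetype("skylark"); sp <- make_archetype("spider")
  expect_gt(length(b$complementation_types), 0)
  expect_lt(b$d_max, sk$d_max)
  expect_gt(sp$dispersal_mortality, b$dispersal_mortality)
  expect_gt(b$r_max, v$r_max)
  expect_gt(sp$r_max, sk$r_max)
  expect_true(b$barriers_block && v$barriers_block)
  expect_false(sk$barriers_block || sp$barriers_block)
  expect_setequal(sk$avoidance_types, c("forest", "hedgerow"))
  expect_error(make_archetype("badger"), "beetle, vole, skylark, spider")
})

test_that("initial placement is uniform over habitable cells", {
  L <- single_patch_landscape(10)
  sp <- oracle_species()
  expect_equal(census(init_population(L, sp, 0, seed = 1)), 0)
  expect_equal(census(init_population(L, sp, 0.1, seed = 1)), 10)

  counts <- numeric(100)
  for (s in 1:500) {
    p <- init_population(L, sp, 0.05, seed = s)   # 5 individuals per draw
    counts <- counts + tabulate((p$col - 1) * 10 + p$row, 100)
  }
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("annual cycle handles the degenerate cases", {
  L <- single_patch_landscape(10)
  dead <- oracle_species(surv = 0)
  p <- init_population(L, dead, 0.5, seed = 1)
  expect_equal(census(step_year(p, L, dead, seed = 2)), 0)
  empty <- init_population(L, dead, 0, seed = 1)
  out <- step_year(empty, L, oracle_species(), seed = 3)
  expect_equal(census(out), 0)
  expect_error(step_year(p, L, oracle_species(), w_y = 0))
})

test_that("census equals the per-patch recount", {
  L <- two_patch_landscape(10)
  sp <- species_params("gen", r_max = 3, semelparous = FALSE,
                       fecundity = c(rotational_field = 1, grassland = 1),
                       overwinter_survival = c(rotational_field = .5, grassland = .5),
                       capacity = c(rotational_field = .5, grassland = .5),
                       d_max = 2, dispersal_mortality = 0, barriers_block = FALSE)
  p <- init_population(L, sp, 0.3, seed = 4)
  expect_equal(census(p), sum(landrec:::patch_counts(p, L)))
  expect_equal(census(p), 30)
})

test_that("no individual ever occupies a barrier cell", {
  bl <- make_barrier_layout(40, road_spacing = 13, n_buildings = 3, seed = 1)
  L <- generate_landscape(40, 30, barrier_layout = bl, seed = 2)
  bids <- L$patches$id[L$patches$barrier]
  for (nm in c("beetle", "spider")) {
    sp <- make_archetype(nm)
    p <- init_population(L, sp, 0.3, seed = 3)
    set.seed(9)
    for (i in 1:5) {
      p <- step_year(p, L, sp)
      if (census(p) == 0) break
      lin <- (p$col - 1L) * nrow(L$grid) + p$row
      expect_false(any(L$grid[lin] %in% bids))
    }
  }
})

test_that("low-density growth factor matches 1 + r*f*w for iteroparous species", {
  L <- single_patch_landscape(60, cell_size = 50)
  sp <- species_params("it", r_max = 2, semelparous = FALSE,
                       fecundity = c(rotational_field = 0.8),
                       overwinter_survival = c(rotational_field = 1),
                       capacity = c(rotational_field = 10),
                       d_max = 2, dispersal_mortality = 0, barriers_block = FALSE)
  p <- init_population(L, sp, 0.05, seed = 1)   # n << kappa * area
  n0 <- census(p)
  set.seed(11)
  g <- replicate(300, census(step_year(p, L, sp, w_y = 1.1)) / n0)
  expected <- 1 + 2 * 0.8 * 1.1
  expect_lt(abs(mean(g) - expected) / expected, 0.02)
})

test_that("with zero fecundity the population is non-increasing", {
  L <- single_patch_landscape(20)
  sp <- oracle_species(fec = 1, surv = 0.8)
  p <- init_population(L, sp, 0.5, seed = 2)
  sp$fecundity["rotational_field"] <- 0
  set.seed(3)
  n <- census(p)
  for (i in 1:5) {
    p <- step_year(p, L, sp)
    expect_lte(census(p), n)
    n <- census(p)
  }
})

test_that("single-patch equilibrium sits near the deterministic fixed point", {
  # kappa * area = 0.5 * 2500 = 1250 individuals
  L <- single_patch_landscape(50)
  sp <- oracle_species(r_max = 3.5, fec = 1, surv = 0.5, kappa = 0.5)
  fp <- oracle_fixed_point(3.5, 1, 0.5, 0.5 * 2500)
  p <- init_population(L, sp, 0.3, seed = 6)
  set.seed(7)
  n <- numeric(40)
  for (y in 1:40) { p <- step_year(p, L, sp); n[y] <- census(p) }
  expect_lt(abs(mean(n[21:40]) - fp) / fp, 0.10)
})

test_that("ground-bound dispersers are stopped by barriers, fliers are not", {
  # habitat split by a vertical road at column 11
  g <- matrix(1L, 21, 21); g[, 11] <- 2L; g[, 12:21] <- 3L
  L <- new_landscape(g, stats::setNames(c("rotational_field", "road",
                                          "rotational_field"), 1:3))
  base <- list(r_max = 4, fecundity = c(rotational_field = 1),
               overwinter_survival = c(rotational_field = 1),
               capacity = c(rotational_field = 100),
               d_max = 8, dispersal_mortality = 0, semelparous = TRUE)
  walker <- do.call(species_params, c(name = "walker", barriers_block = TRUE, base))
  flier <- do.call(species_params, c(name = "flier", barriers_block = FALSE, base))
  start <- new_landscape(g, stats::setNames(c("rotational_field", "road",
                                              "rotational_field"), 1:3))
  p0 <- structure(list(row = rep(11L, 200), col = rep(5L, 200),
                       age = rep("adult", 200)), class = "population")
  set.seed(5)
  pw <- step_year(p0, L, walker)
  pf <- step_year(p0, L, flier)
  expect_equal(sum(pw$col > 11), 0)        # nobody crosses the road
  expect_gt(sum(pf$col > 11), 0)           # fliers do
})
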