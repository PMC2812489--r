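test_that("shape homogenization conserves identity, type and area", {
  L1 <- single_patch_landscape(12)
  B1 <- homogenize_shapes(L1, seed = 1)
  expect_identical(sort(unique(as.integer(B1$grid))), 1L)
  expect_equal(B1$patches$area_cells, 144L)

  L <- cached_landscape()
  B <- homogenize_shapes(L, seed = 5)
  pa <- L$patches; pb <- B$patches
  expect_identical(pb$type_code[match(pa$id, pb$id)], pa$type_code)
  # barrier cells bit-identical
  bids <- pa$id[pa$barrier]
  expect_identical(matrix(B$grid %in% bids, nrow(B$grid)),
                   matrix(L$grid %in% bids, nrow(L$grid)))
  expect_identical(B$grid[L$grid %in% bids], L$grid[L$grid %in% bids])
  expect_equal(sum(pb$area_cells), sum(pa$area_cells))
  # deterministic given seed
  expect_identical(B$grid, homogenize_shapes(L, seed = 5)$grid)
})

test_that("homogenized patches are 4-connected", {
  L <- generate_landscape(60, 40, seed = 8)
  B <- homogenize_shapes(L, seed = 9)
  for (id in B$patches$id) {
    comp <- landrec:::label_components(B$grid == id)
    expect_equal(max(comp), 1L)
  }
})

test_that("arrangement randomization permutes types only within size classes", {
  # patches in distinct size classes: no legal swap, type map unchanged
  g <- matrix(3L, 12, 12)
  g[1, 1] <- 1L; g[1:2, 2:3] <- 2L
  L <- new_landscape(g, stats::setNames(c("forest", "grassland",
                                          "rotational_field"), 1:3))
  C <- randomize_arrangement(L, seed = 1)
  expect_identical(C$patches$type_code, L$patches$type_code)

  # two same-class patches: both orders occur across seeds
  L2 <- two_patch_landscape(10, "forest", "grassland")
  flips <- sapply(1:100, function(s)
    randomize_arrangement(L2, seed = s)$patches$type_code[1])
  expect_setequal(unique(flips), c("forest", "grassland"))

  # (size_class, type) multiset is a permutation invariant
  B <- homogenize_shapes(cached_landscape(), seed = 5)
  C2 <- suppressWarnings(randomize_arrangement(B, seed = 3))
  pb <- patch_table(B); pc <- patch_table(C2)
  expect_identical(pc$id, pb$id)
  expect_identical(pc$area_cells, pb$area_cells)   # geometry untouched
  expect_identical(C2$grid, B$grid)
  expect_equal(table(pc$size_class, pc$type_code),
               table(pb$size_class, pb$type_code))
})

test_that("size randomization follows the patch-count frequency cover law", {
  # equal areas: cover invariant under any permutation
  L2 <- two_patch_landscape(10, "forest", "grassland")
  D2 <- randomize_sizes(L2, seed = 4)
  expect_equal(relative_cover(D2)[c("forest", "grassland")],
               relative_cover(L2)[c("forest", "grassland")])

  L <- cached_landscape()
  D <- randomize_sizes(L, seed = 4)
  expect_equal(table(D$patches$type_code), table(L$patches$type_code))
  expect_identical(D$grid, L$grid)

  # mean cover over seeds ~ count frequency x non-barrier area
  hab <- L$patches[!L$patches$barrier, ]
  freq <- table(hab$type_code) / nrow(hab)
  free_frac <- sum(hab$area_cells) / length(L$grid)
  covs <- rowMeans(sapply(1:60, function(s)
    relative_cover(randomize_sizes(L, seed = s))[names(freq)]))
  expect_lt(max(abs(covs - c(freq) * free_frac)), 0.02)
})

test_that("the variant chain is reproducible and conserves cover through C", {
  L <- cached_landscape()
  v1 <- make_variants(L, seed = 11)
  v2 <- make_variants(L, seed = 11)
  for (nm in c("A", "B", "C", "D")) {
    expect_identical(v1[[nm]]$grid, v2[[nm]]$grid)
    expect_identical(v1[[nm]]$patches$type_code, v2[[nm]]$patches$type_code)
  }
  ca <- relative_cover(v1$A)
  cb <- relative_cover(v1$B)[names(ca)]
  expect_lt(max(abs(cb - ca) / ca), 0.02)   # conserved up to the deadlock rule
  cc <- relative_cover(v1$C)[names(ca)]
  expect_lt(max(abs(cc - ca) / ca), 0.05)
  # total area conserved exactly across all variants
  for (nm in c("B", "C", "D"))
    expect_equal(sum(v1[[nm]]$patches$area_cells), sum(L$patches$area_cells))
})

test_that("homogenization plus rearrangement increases same-type separation", {
  deltas <- sapply(1:5, function(r) {
    L <- generate_landscape(100, 120, seed = 20 + r)
    v <- suppressWarnings(make_variants(L, seed = 30 + r))
    hab <- unique(L$patches$type_code[!L$patches$barrier])
    sA <- same_type_separation(v$A)[hab]
    sC <- same_type_separation(v$C)[hab]
    median(sC - sA, na.rm = TRUE)
  })
  expect_gte(mean(deltas), 0)
})

test_that("replicate landscapes are independent and consistent", {
  L <- cached_landscape()
  reps <- suppressWarnings(replicate_landscapes(L, "C", 10, seed = 77))
  expect_length(reps, 10)
  tm <- sapply(reps, function(x) paste(x$patches$type_code, collapse = ""))
  expect_gt(length(unique(tm)), 1)
  # n = 1 equals the matching make_variants output for the same sub-seed
  one <- suppressWarnings(replicate_landscapes(L, "C", 1, seed = 77))[[1]]
  full <- suppressWarnings(
    make_variants(L, derive_seed(77, "rep1")))$C
  expect_identical(one$grid, full$grid)
  expect_identical(one$patches$type_code, full$patches$type_code)
  expect_error(replicate_landscapes(L, "A", 2, seed = 1))
  # cover conservation holds on every B replicate
  ca <- relative_cover(L)
  for (x in suppressWarnings(replicate_landscapes(L, "B", 3, seed = 5)))
    expect_lt(max(abs(relative_cover(x)[names(ca)] - ca) / ca), 0.02)
})
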