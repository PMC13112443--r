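test_that("seeded watershed recovers single and multiple discs", {
  # one disc on dark background
  s1 <- image_spec(image_shape = c(96L, 96L), n_cells = 1L,
                   per_cell_gp = 0.3, seed = 101)
  im <- make_cell_image(s1)
  tot <- im$image$blue + im$image$red
  lab <- seeded_watershed(tot, truth_seeds(im$truth))
  truth_px <- which(im$truth$cell_label_map == 1L)
  expect_gte(jaccard(which(lab$labels == 1L), truth_px), 0.95)
  # two well-separated discs, one seed each
  s2 <- image_spec(image_shape = c(128L, 128L), n_cells = 2L,
                   per_cell_gp = c(0.2, 0.5), seed = 102)
  im2 <- make_cell_image(s2)
  tot2 <- im2$image$blue + im2$image$red
  lab2 <- seeded_watershed(tot2, truth_seeds(im2$truth))
  expect_equal(lab2$n_cells, 2L)
  cellpx <- im2$truth$cell_label_map > 0L
  agree <- lab2$labels[cellpx] == im2$truth$cell_label_map[cellpx]
  expect_gte(mean(agree), 0.99)
})

test_that("watershed partition is complete, seed-containing, deterministic", {
  s <- image_spec(image_shape = c(128L, 128L), n_cells = 6L, seed = 103)
  im <- make_cell_image(s)
  tot <- im$image$blue + im$image$red
  seeds <- truth_seeds(im$truth)
  lab <- seeded_watershed(tot, seeds)
  # every pixel labeled, labels exactly {0} U {1..N}
  expect_false(anyNA(lab$labels))
  expect_setequal(unique(as.vector(lab$labels)), 0:6)
  # each cell seed inside its own final label
  sc <- seeds$cell_seeds + 1L
  expect_equal(lab$labels[sc], 1:6)
  # deterministic
  expect_identical(seeded_watershed(tot, seeds), lab)
  # constant image: deterministic partition under the tie-break rule
  const <- matrix(1, 32, 32)
  cs <- seed_set(cell_seeds = matrix(c(8, 8), 1),
                 background_seeds = matrix(c(30, 30), 1))
  p1 <- seeded_watershed(const, cs, sigma = 0)
  p2 <- seeded_watershed(const, cs, sigma = 0)
  expect_identical(p1, p2)
  expect_setequal(unique(as.vector(p1$labels)), 0:1)
})

test_that("watershed input contracts are enforced", {
  img <- matrix(1, 16, 16)
  expect_error(
    seeded_watershed(img, seed_set(matrix(c(2, 20), 1), matrix(c(1, 1), 1))),
    "bounds")
  img[3, 3] <- NA
  expect_error(
    seeded_watershed(img, seed_set(matrix(c(5, 5), 1), matrix(c(1, 1), 1))),
    "finite")
  expect_error(seed_set(matrix(c(2, 2, 2, 2), 2, byrow = TRUE),
                        matrix(c(1, 1), 1)),
               "distinct")
  # two cell seeds inside the same basin: both labels kept, warning raised
  s <- image_spec(image_shape = c(96L, 96L), n_cells = 1L, seed = 104)
  im <- make_cell_image(s)
  tot <- im$image$blue + im$image$red
  ctr <- round(im$truth$centers[1, ])
  seeds2 <- seed_set(cell_seeds = rbind(ctr, ctr + c(2, 0)),
                     background_seeds = matrix(c(0, 0), 1))
  expect_warning(lab <- seeded_watershed(tot, seeds2), "catchment")
  expect_setequal(unique(as.vector(lab$labels)), 0:2)
})

test_that("rank-based gradient makes segmentation monotone invariant", {
  s <- image_spec(image_shape = c(96L, 96L), n_cells = 3L, seed = 105)
  im <- make_cell_image(s)
  tot <- im$image$blue + im$image$red
  seeds <- truth_seeds(im$truth)
  a <- seeded_watershed(tot, seeds, gradient = "rank")
  b <- seeded_watershed(sqrt(tot) + 3, seeds, gradient = "rank")
  expect_identical(a$labels, b$labels)
})

test_that("membrane band extraction follows its closed conventions", {
  # filled square, band_width 1, quantile 0 -> inner morphological boundary
  labs <- matrix(0L, 20, 20)
  labs[5:14, 6:15] <- 1L
  lm <- structure(list(labels = labs, n_cells = 1L), class = "CellLabelMap")
  mem <- extract_membrane(lm, matrix(1, 20, 20), band_width = 1,
                          refinement_quantile = 0)
  inner <- which(labs == 1L &
                   !(row(labs) %in% 6:13 & col(labs) %in% 7:14))
  expect_setequal(mem$masks[[1]], inner)
  # quantile 0.99 on a uniform band keeps everything (closed >= rule)
  mem99 <- extract_membrane(lm, matrix(7, 20, 20), band_width = 1,
                            refinement_quantile = 0.99)
  expect_setequal(mem99$masks[[1]], inner)
  expect_error(extract_membrane(lm, matrix(1, 20, 20), band_width = 0),
               "band_width")
  expect_error(extract_membrane(lm, matrix(1, 20, 20),
                                refinement_quantile = 1),
               "refinement_quantile")
})

test_that("extracted membranes overlap the true rings", {
  s <- image_spec(image_shape = c(128L, 128L), n_cells = 4L,
                  per_cell_gp = 0.4, seed = 106)
  im <- make_cell_image(s)
  tot <- im$image$blue + im$image$red
  lab <- seeded_watershed(tot, truth_seeds(im$truth))
  mem <- extract_membrane(lab, tot)
  js <- vapply(1:4, function(k)
    jaccard(mem$masks[[k]], im$truth$membrane_masks[[k]]), numeric(1))
  expect_true(all(js >= 0.8))
  # masks disjoint across cells
  expect_equal(anyDuplicated(unlist(mem$masks)), 0L)
})

test_that("per-cell median GP follows median conventions and filters", {
  gp <- structure(list(gp = matrix(0.25, 10, 10),
                       valid = matrix(TRUE, 10, 10),
                       intensity_threshold = 0), class = "GPMap")
  mem <- structure(list(masks = list(1:30, 31:34, 35:60),
                        band_width = 1, refinement_quantile = 0,
                        dim = c(10L, 10L), excluded = integer(0)),
                   class = "MembraneMask")
  rec <- per_cell_median_gp(gp, mem, min_pixels = 20)
  # constant GP -> median is that constant; small cell 2 excluded
  expect_equal(rec$cell_id, c(1L, 3L))
  expect_equal(rec$median_gp, c(0.25, 0.25))
  expect_equal(attr(rec, "excluded"), 2L)
  # even pixel count: midpoint of the two central order statistics
  gp2 <- gp
  gp2$gp[1:4] <- c(0.1, 0.2, 0.6, 0.9)
  mem2 <- mem; mem2$masks <- list(1:4)
  rec2 <- per_cell_median_gp(gp2, mem2, min_pixels = 2)
  expect_equal(rec2$median_gp, (0.2 + 0.6) / 2)
  # no surviving cells -> explicit empty signal
  expect_warning(empty <- per_cell_median_gp(gp, mem, min_pixels = 1000),
                 "no cell")
  expect_equal(nrow(empty), 0L)
})

test_that("the full segmentation stack recovers per-cell GP", {
  set.seed(107)
  s <- image_spec(image_shape = c(512L, 512L), n_cells = 40L,
                  per_cell_gp = runif(40, 0.1, 0.6), seed = 107)
  im <- make_cell_image(s)
  tot <- im$image$blue + im$image$red
  lab <- seeded_watershed(tot, truth_seeds(im$truth))
  mem <- extract_membrane(lab, tot)
  rec <- per_cell_median_gp(gp_map(im$image), mem)
  err <- rec$median_gp - im$truth$per_cell_gp[rec$cell_id]
  expect_gte(nrow(rec), 38)
  expect_lt(mean(abs(err)), 0.05)
})

test_that("per-cell GP estimates are unbiased over many cells", {
  errs <- unlist(lapply(1:3, function(i) {
    set.seed(200 + i)
    s <- image_spec(image_shape = c(512L, 512L), n_cells = 40L,
                    per_cell_gp = runif(40, 0.1, 0.6), seed = 200 + i)
    im <- make_cell_image(s)
    tot <- im$image$blue + im$image$red
    lab <- seeded_watershed(tot, truth_seeds(im$truth))
    mem <- extract_membrane(lab, tot)
    rec <- per_cell_median_gp(gp_map(im$image), mem)
    rec$median_gp - im$truth$per_cell_gp[rec$cell_id]
  }))
  expect_gte(length(errs), 100)
  expect_lt(abs(mean(errs)), 0.02)
})
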