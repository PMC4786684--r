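random_histogram <- function(seed) {
  set.seed(seed)
  nb <- sample(16:64, 1)
  h <- numeric(nb)
  # dominant peak plus a decaying tail, randomly mirrored
  pk <- sample(seq_len(nb), 1)
  h[pk] <- sample(200:2000, 1)
  tail_len <- sample(3:(nb - 1), 1)
  idx <- unique(pmin(pmax(pk + sample(-tail_len:tail_len, tail_len), 1), nb))
  h[idx] <- h[idx] + sample(0:80, length(idx), replace = TRUE)
  extra <- sample(seq_len(nb), sample(2:8, 1))
  h[extra] <- h[extra] + sample(0:40, length(extra), replace = TRUE)
  h
}

test_that("triangle threshold equals the point-line-distance oracle", {
  # two-spike histogram: threshold strictly between the spikes
  h2 <- numeric(64); h2[4] <- 1000; h2[50] <- 60
  thr <- triangle_threshold(h2)
  expect_gt(as.numeric(thr), 3)
  expect_lt(as.numeric(thr), 49)
  expect_equal(as.numeric(thr), oracle_triangle(h2))

  # mirrored tail: peak on the right, tail on the left
  hm <- rev(h2)
  expect_equal(as.numeric(triangle_threshold(hm)), oracle_triangle(hm))
  expect_identical(attr(triangle_threshold(hm), "side"), "left")

  for (s in 1:120) {
    h <- random_histogram(s)
    if (sum(h > 0) < 2) next
    expect_equal(as.numeric(triangle_threshold(h)), oracle_triangle(h),
                 info = paste("histogram seed", s))
  }
  expect_error(triangle_threshold(c(0, 5, 0)), "2 non-empty")
})

test_that("colocalize counts planted internal puncta and applies the >1 px rule", {
  sp <- generate_puncta_image(5, 3, puncta_size_px = 4, seed = 3)
  res <- colocalize(sp$channel_cell, sp$channel_puncta)
  expect_identical(res$n_internal_puncta, 5L)
  expect_equal(res$density_per_um2,
               res$n_internal_puncta / res$microglia_area_um2)

  none <- generate_puncta_image(0, 4, puncta_size_px = 4, seed = 4)
  expect_identical(colocalize(none$channel_cell,
                              none$channel_puncta)$n_internal_puncta, 0L)

  # single-pixel overlaps only: all fail the "larger than 1 pixel" rule
  cell <- matrix(0, 32, 32); cell[8:24, 8:24] <- 255
  pun <- matrix(0, 32, 32)
  pun[cbind(c(10, 14, 20), c(10, 18, 12))] <- 255
  res1 <- colocalize(cell, pun, min_punctum_px = 1, smooth_sigma = 0)
  expect_identical(res1$n_internal_puncta, 0L)
  # the same spots count once the rule floor is dropped to 0
  res0 <- colocalize(cell, pun, min_punctum_px = 0, smooth_sigma = 0)
  expect_identical(res0$n_internal_puncta, 3L)

  disjoint_pun <- matrix(0, 32, 32); disjoint_pun[1:3, 1:3] <- 255
  expect_identical(colocalize(cell, disjoint_pun,
                              smooth_sigma = 0)$n_internal_puncta, 0L)
  # a featureless cell channel cannot provide the area normalizer
  expect_error(colocalize(matrix(0, 16, 16), disjoint_pun[1:16, 1:16],
                          smooth_sigma = 0), "constant")
})

test_that("density halves when microglial area doubles with counts fixed", {
  pun <- matrix(0, 40, 60)
  pun[10:11, 10:11] <- 255; pun[20:21, 15:16] <- 255   # two 4-px puncta
  cellA <- matrix(0, 40, 60); cellA[5:24, 5:24] <- 255     # 400 px
  cellB <- matrix(0, 40, 60); cellB[5:24, 5:44] <- 255     # 800 px
  a <- colocalize(cellA, pun, smooth_sigma = 0)
  b <- colocalize(cellB, pun, smooth_sigma = 0)
  expect_identical(a$n_internal_puncta, b$n_internal_puncta)
  expect_equal(b$microglia_area_um2, 2 * a$microglia_area_um2)
  expect_equal(b$density_per_um2, a$density_per_um2 / 2)
})

test_that("product mask is symmetric and min_punctum_px is monotone", {
  sp <- generate_puncta_image(4, 2, puncta_size_px = 5, seed = 9)
  ab <- colocalize(sp$channel_cell, sp$channel_puncta)
  ba_mask <- colocalize(sp$channel_puncta, sp$channel_cell)$product_mask
  expect_identical(ab$product_mask, ba_mask)
  counts <- vapply(0:6, function(k)
    colocalize(sp$channel_cell, sp$channel_puncta,
               min_punctum_px = k)$n_internal_puncta, integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("3D puncta span planes under 26-connectivity", {
  cell <- array(0, c(4, 24, 24)); cell[, 4:20, 4:20] <- 255
  pun <- array(0, c(4, 24, 24))
  pun[1, 10, 10] <- 255; pun[2, 11, 11] <- 255   # diagonal across planes
  res <- colocalize(cell, pun, smooth_sigma = 0)
  expect_identical(res$n_internal_puncta, 1L)     # one 2-voxel component
  res2d <- colocalize(cell[1, , , drop = TRUE], pun[1, , , drop = TRUE],
                      smooth_sigma = 0)
  expect_identical(res2d$n_internal_puncta, 0L)   # single voxel fails the rule
})

test_that("group density comparison reports means, sems and planted ratios", {
  mk <- function(n_int, seed) {
    sp <- generate_puncta_image(n_int, 2, puncta_size_px = 4, seed = seed)
    colocalize(sp$channel_cell, sp$channel_puncta)
  }
  a <- lapply(1:4, function(s) mk(8, s))
  b <- lapply(1:4, function(s) mk(4, s + 50))
  cmp <- compare_density(a, b)
  expect_equal(cmp$ratio, 2, tolerance = 0.05)
  same <- compare_density(a, a)
  expect_equal(same$difference, 0)
  one <- compare_density(a[1], b[1])
  expect_equal(one$sem_a, 0)
})
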