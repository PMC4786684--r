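test_that("binarize thresholds strictly above and filters artefacts", {
  img <- matrix(10, 20, 20)
  expect_false(any(binarize(img, "fixed", value = 10)$mask))  # strict >
  img[img > 0] <- 10
  img[2, 2] <- 50
  expect_true(binarize(img, "fixed", value = 10, min_size = 1)$mask[2, 2])

  # artefact filter: 3-px speck removed, 10-px branch kept at min_size 5
  img2 <- matrix(0, 20, 20)
  img2[5, 3:5] <- 100            # 3-px speck
  img2[12, 4:13] <- 100          # 10-px branch
  b <- binarize(img2, "fixed", value = 50, min_size = 5)
  expect_equal(sum(b$mask), 10)
  expect_true(all(b$mask[12, 4:13]))

  # triangle picks out a small bright population from a dark majority
  set.seed(3)
  img3 <- matrix(0, 32, 32)
  bright <- sample(length(img3), 40)
  img3[bright] <- 200
  b3 <- binarize(img3, "triangle", min_size = 1)
  expect_identical(sort(which(b3$mask)), sort(bright))

  expect_warning(b0 <- binarize(matrix(5, 8, 8), "triangle"), "constant")
  expect_false(any(b0$mask))
})

test_that("sholl matches analytic profiles for a ray and a Y-arbor", {
  arb <- generate_arbor(1, c(5, 10, 15, 20), seed = 1, lengths_um = 25)
  prof <- sholl(arb$mask, arb$soma_center, radius_step = 5, max_radius = 20)
  expect_identical(prof$crossings, c(1L, 1L, 1L, 1L))

  y <- build_y_arbor(side = 65, fork_um = 12)
  profy <- sholl(y$mask, y$center, radius_step = 5, max_radius = 20)
  expect_identical(profy$crossings, c(1L, 1L, 2L, 2L))

  empty <- matrix(FALSE, 33, 33)
  expect_warning(p0 <- sholl(empty, c(16, 16), 5, 15), "background")
  expect_identical(p0$crossings, c(0L, 0L, 0L))
})

test_that("ring-run crossings equal the circle-walk oracle on random arbors and masks", {
  for (s in 1:30) {
    n <- (s %% 6)
    arb <- generate_arbor(n, seq(10, 30, 5), seed = s)
    for (r_um in seq(10, 30, 5)) {
      got <- gliaquant:::ring_run_crossings(arb$mask, arb$soma_center, r_um)
      expect_identical(got, oracle_circle_walk(arb$mask, arb$soma_center, r_um),
                       info = sprintf("arbor seed %d radius %d", s, r_um))
      expect_identical(got,
                       arb$ground_truth_crossings$crossings[
                         arb$ground_truth_crossings$radius_um == r_um])
    }
  }
  # dense random masks stress the run/seam logic far beyond real arbors
  set.seed(99)
  for (i in 1:30) {
    m <- matrix(stats::runif(41 * 41) < 0.35, 41)
    ctr <- c(sample(10:30, 1), sample(10:30, 1))
    r <- sample(3:12, 1)
    expect_identical(gliaquant:::ring_run_crossings(m, ctr, r),
                     oracle_circle_walk(m, ctr, r),
                     info = sprintf("random mask %d", i))
  }
})

test_that("sholl profiles are invariant under translation and 90-degree rotation", {
  arb <- generate_arbor(5, seq(10, 25, 5), seed = 4)
  base <- sholl(arb$mask, arb$soma_center, 5, 25)
  # translate by padding
  pad <- matrix(FALSE, nrow(arb$mask) + 6, ncol(arb$mask) + 9)
  pad[6 + seq_len(nrow(arb$mask)) - 0, 9 + seq_len(ncol(arb$mask))] <-
    arb$mask
  shifted <- sholl(pad, arb$soma_center + c(6, 9), 5, 25)
  expect_identical(shifted$crossings, base$crossings)
  # rotate 90 degrees: new[r, c] = old[n - 1 - c, r] (0-based)
  rot <- t(arb$mask)[, rev(seq_len(nrow(arb$mask)))]
  ctr_rot <- c(arb$soma_center[2L], nrow(arb$mask) - 1L - arb$soma_center[1L])
  rotated <- sholl(rot, ctr_rot, 5, 25)
  expect_identical(rotated$crossings, base$crossings)
})

test_that("removing whole branches never increases total crossings", {
  for (s in 1:5) {
    full <- generate_arbor(6, seq(10, 30, 5), seed = s)
    fewer <- generate_arbor(4, seq(10, 30, 5), seed = s,
                            lengths_um = full$lengths_um[1:4])
    tot_full <- sum(sholl(full$mask, full$soma_center, 5, 30)$crossings)
    tot_fewer <- sum(sholl(fewer$mask, fewer$soma_center, 5, 30)$crossings)
    expect_lte(tot_fewer, tot_full)
  }
})

test_that("soma metrics, cell density and density ratio follow their formulas", {
  img <- matrix(20, 30, 30)
  soma <- matrix(FALSE, 30, 30); soma[10:19, 10:19] <- TRUE
  img[soma] <- 100
  bg <- matrix(FALSE, 30, 30); bg[1:5, 1:5] <- TRUE
  m <- soma_metrics(img, soma, bg, pixel_size = 0.5)
  expect_equal(m$area_um2, 25)                       # 100 px * 0.25 um^2
  expect_equal(m$mean_intensity_bg_subtracted, 80)
  img[soma] <- 5
  expect_lt(soma_metrics(img, soma, bg, 0.5)$mean_intensity_bg_subtracted, 0)
  expect_error(soma_metrics(img, soma, matrix(FALSE, 30, 30), 0.5),
               "background")

  expect_equal(cell_density(10, c(0.05, 0.05)), 100)
  expect_equal(cell_density(0, 0.2), 0)
  expect_equal(cell_density(8, c(1, 1)), cell_density(8, c(2, 2)) * 2)
  expect_error(cell_density(3, 0), "zero total")

  expect_equal(density_ratio(4, 4), 1)
  expect_equal(density_ratio(8, 4), 2)
  expect_error(density_ratio(1, 0), "positive")
})
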