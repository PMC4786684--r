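# The generators must be pure functions of (parameters, seed) and their
# recorded ground truth must match brute-force recomputation from the
# generated arrays.

test_that("every generator is deterministic under a fixed seed", {
  a1 <- generate_arbor(5, seq(10, 30, 5), seed = 7)
  a2 <- generate_arbor(5, seq(10, 30, 5), seed = 7)
  expect_identical(a1$image, a2$image)
  expect_identical(a1$ground_truth_crossings, a2$ground_truth_crossings)

  t1 <- generate_timelapse(a1, T = 5, seed = 3)
  t2 <- generate_timelapse(a2, T = 5, seed = 3)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$planted, t2$planted)

  b1 <- generate_ablation_movie(T = 4, converge_rate = 2, seed = 9)
  b2 <- generate_ablation_movie(T = 4, converge_rate = 2, seed = 9)
  expect_identical(b1$frames, b2$frames)

  p1 <- generate_puncta_image(3, 2, seed = 5)
  p2 <- generate_puncta_image(3, 2, seed = 5)
  expect_identical(p1$channel_puncta, p2$channel_puncta)

  s1 <- generate_ios_session(matrix(1, 4, 4), matrix(1, 4, 4), 0.125, 16, 4,
                             noise_sd = 0.3, seed = 2)
  s2 <- generate_ios_session(matrix(1, 4, 4), matrix(1, 4, 4), 0.125, 16, 4,
                             noise_sd = 0.3, seed = 2)
  expect_identical(s1$sessions, s2$sessions)

  e1 <- generate_event_table(c(g = 0.5), seed = 4)
  e2 <- generate_event_table(c(g = 0.5), seed = 4)
  expect_identical(e1$table, e2$table)
})

test_that("arbor ground truth is analytic and the arbor is 4-connected", {
  # a 25-um ray crosses every circle of radius < 25 exactly once
  arb <- generate_arbor(1, c(5, 10, 15, 20), pixel_size = 1, seed = 1,
                        lengths_um = 25)
  expect_identical(arb$ground_truth_crossings$crossings, rep(1L, 4))
  arb0 <- generate_arbor(0, c(5, 10, 15), seed = 2)
  expect_identical(arb0$ground_truth_crossings$crossings, c(0L, 0L, 0L))
  # arbor pixels form one 4-connected component containing the soma
  lab <- label_components(generate_arbor(6, seq(10, 30, 5), seed = 3)$mask,
                          connectivity = 4L)
  expect_identical(max(lab), 1L)
  expect_error(generate_arbor(2, c(5, 10), pixel_size = -1),
               "pixel_size")
  expect_error(generate_arbor(2, c(10, 5)), "increasing")
})

test_that("timelapse planted sets equal the set differences of the masks", {
  arb <- generate_arbor(6, seq(10, 30, 5), seed = 2)
  tl <- generate_timelapse(arb, T = 12, extension_fraction = 0.1,
                           retraction_fraction = 0.1, seed = 5)
  for (k in seq_along(tl$planted)) {
    m1 <- tl$masks[[k]]; m2 <- tl$masks[[k + 1L]]
    expect_identical(tl$planted[[k]]$added, which(!m1 & m2))
    expect_identical(tl$planted[[k]]$removed, which(m1 & !m2))
    expect_identical(tl$planted[[k]]$stable, sum(m1 & m2))
    # planted counts track the requested fractions of the prior foreground
    expect_equal(length(tl$planted[[k]]$added), round(0.1 * sum(m1)),
                 tolerance = 0.35)
  }
  frozen <- generate_timelapse(arb, T = 3, extension_fraction = 0,
                               retraction_fraction = 0, seed = 5)
  expect_identical(frozen$masks[[1L]], frozen$masks[[3L]])
})

test_that("ablation movie ground truth matches a brute-force recount", {
  ab <- generate_ablation_movie(T = 6, converge_rate = 3, seed = 11)
  d <- gliaquant:::pixel_distances_um(dim(ab$frames[[1L]]), ab$center,
                                      ab$pixel_size)
  g <- ab$geometry
  recount <- vapply(ab$frames, function(f)
    sum(f > 0 & d > g$core_exclusion_um & d <= g$inner_radius_um), numeric(1))
  expect_identical(recount, ab$planted_Rx_counts)
  expect_true(all(diff(ab$planted_Rx_counts) >= 0))
  static <- generate_ablation_movie(T = 5, converge_rate = 0, seed = 12)
  expect_identical(diff(static$planted_Rx_counts), rep(0, 4))
  expect_gt(ab$planted_Ry0, 0)
})

test_that("planted puncta are distinct multi-pixel components wholly inside/outside the cell", {
  sp <- generate_puncta_image(4, 3, puncta_size_px = 4, seed = 8)
  lab <- label_components(sp$puncta_mask, connectivity = 8L)
  expect_identical(max(lab), sp$planted_internal + sp$planted_external)
  sizes <- tabulate(lab[lab > 0])
  expect_true(all(sizes > 1L))
  # each component is entirely inside or entirely outside the cell mask
  for (l in seq_len(max(lab))) {
    inside <- sp$cell_mask[lab == l]
    expect_true(all(inside) || all(!inside))
  }
  expect_identical(sum(vapply(seq_len(max(lab)), function(l)
    all(sp$cell_mask[lab == l]), logical(1))), sp$planted_internal)
  expect_error(generate_puncta_image(2, 2, puncta_size_px = 1), ">= 2")
})

test_that("ios sessions carry exact planted sinusoids at an exact FFT bin", {
  A <- matrix(2, 6, 6)
  s <- generate_ios_session(A, A, stim_frequency = 0.125, duration_s = 48,
                            sampling_rate = 4, noise_sd = 0, seed = 3)
  am <- amplitude_map(s$sessions$contra_up, 4, 0.125)
  expect_equal(max(abs(am$amplitude - 2)), 0, tolerance = 1e-10)
  expect_error(generate_ios_session(A, A, 0.125, 50, 4),
               "integer multiple")
  expect_error(generate_ios_session(A, A, 3, 48, 4), "Nyquist")
})

test_that("event tables draw Poisson counts around the planted densities", {
  et0 <- generate_event_table(c(g = 0), n_animals = 2, n_processes = 20,
                              seed = 1)
  expect_true(all(et0$table$events == 0))
  et <- generate_event_table(c(g = 0.5), n_animals = 1, n_processes = 1000,
                             area_range = c(1, 3), seed = 2)
  dens <- et$table$events / et$table$area_um2
  # Poisson density estimate: Var(count/area) = lambda/area
  se <- sqrt(mean(0.5 / et$table$area_um2) / 1000)
  expect_lt(abs(mean(dens) - 0.5), 3 * se)
})

test_that("synthetic objects round-trip through TIFF + JSON sidecars", {
  dir <- withr::local_tempdir()
  arb <- generate_arbor(3, seq(10, 20, 5), seed = 1)
  paths <- save_synthetic(arb, file.path(dir, "arbor"))
  expect_true(all(file.exists(paths)))
  st <- read_stack(paths[1L], pixel_size = arb$pixel_size)
  expect_equal(st$data[1L, , ], arb$image)
  truth <- jsonlite::read_json(paths[2L], simplifyVector = TRUE)
  expect_equal(truth$ground_truth_crossings$crossings,
               arb$ground_truth_crossings$crossings)
})
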