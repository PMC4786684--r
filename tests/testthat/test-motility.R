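mk <- function(v, n = 3) matrix(as.logical(v), n)

test_that("classify_changes labels and counts match the definitions", {
  m <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  cm <- classify_changes(m, m)
  expect_equal(unname(cm$counts), c(2L, 0L, 0L))

  empty <- matrix(FALSE, 2, 2)
  grow <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2)
  cm2 <- classify_changes(empty, grow)
  expect_equal(cm2$counts[["extended"]], 3L)
  expect_equal(cm2$counts[["stable"]], 0L)

  # validity mask excludes pixels from every count: (1,1) is foreground in
  # `grow` but masked out, so only 2 of the 3 retractions are counted
  val <- matrix(c(FALSE, TRUE, TRUE, TRUE), 2)
  cm3 <- classify_changes(grow, empty, validity = val)
  expect_equal(cm3$counts[["retracted"]], 2L)
  expect_error(classify_changes(m, matrix(FALSE, 3, 3)), "shapes")
})

test_that("classification equals exhaustive enumeration on random pairs", {
  set.seed(11)
  for (i in 1:60) {
    n <- sample(2:16, 1)
    m1 <- matrix(stats::runif(n * n) < 0.5, n)
    m2 <- matrix(stats::runif(n * n) < 0.5, n)
    val <- matrix(stats::runif(n * n) < 0.9, n)
    expect_identical(classify_changes(m1, m2, val)$counts,
                     oracle_classify_counts(m1, m2, val))
  }
})

test_that("label conservation and frame-swap symmetry hold", {
  set.seed(5)
  for (i in 1:20) {
    m1 <- matrix(stats::runif(64) < 0.4, 8)
    m2 <- matrix(stats::runif(64) < 0.4, 8)
    cm <- classify_changes(m1, m2)
    # stable + extended partition frame-2 foreground; stable + retracted frame-1
    expect_equal(cm$counts[["stable"]] + cm$counts[["extended"]], sum(m2))
    expect_equal(cm$counts[["stable"]] + cm$counts[["retracted"]], sum(m1))
    sw <- classify_changes(m2, m1)
    expect_equal(sw$counts[["extended"]], cm$counts[["retracted"]])
    expect_equal(sw$counts[["retracted"]], cm$counts[["extended"]])
  }
})

test_that("motility index follows (ext + ret) / stable averaged over overlays", {
  stable5 <- mk(c(1, 1, 1, 1, 1, 0, 0, 0, 0), 3)
  all_stable <- classify_changes(stable5, stable5)
  expect_equal(motility_index(list(all_stable))$motility_index, 0)

  # ext = 2, ret = 3, stable = 5 -> motility 1.0, extension 0.4, retraction 0.6
  m1 <- matrix(FALSE, 4, 4); m2 <- matrix(FALSE, 4, 4)
  m1[1, 1:4] <- TRUE; m1[2, 1] <- TRUE                 # 5 fg
  m2[1, 1:4] <- TRUE; m2[2, 1] <- TRUE                 # stable 5
  m1[3, 1:3] <- TRUE                                   # 3 retracted
  m2[4, 1:2] <- TRUE                                   # 2 extended
  res <- motility_index(list(classify_changes(m1, m2)))
  expect_equal(res$motility_index, 1.0)
  expect_equal(res$extension_index, 0.4)
  expect_equal(res$retraction_index, 0.6)

  none <- classify_changes(matrix(FALSE, 2, 2), matrix(TRUE, 2, 2))
  expect_error(motility_index(list(all_stable, none)), "interval 2")
})

test_that("stability and instability indices follow their proportions", {
  base <- matrix(FALSE, 5, 5)
  f1 <- base; f1[1, 1:5] <- TRUE
  f2 <- base; f2[1, 1:5] <- TRUE; f2[2, 1:5] <- TRUE; f2[3, 1:5] <- TRUE
  ov1 <- classify_changes(f1, f2)            # 10 extended (rows 2 and 3)
  # next frame keeps 4 of those 10 extended pixels
  f3 <- base; f3[1, 1:5] <- TRUE; f3[2, 1:4] <- TRUE
  ov2 <- classify_changes(f2, f3)
  expect_equal(stability_index(ov1, ov2), 0.4)

  persist <- classify_changes(f2, f2)
  expect_equal(stability_index(ov1, persist), 1.0)
  gone <- classify_changes(f2, f1)
  expect_equal(stability_index(ov1, gone), 0.0)

  # instability: 3 of 12 stable pixels retract
  g1 <- base; g1[1:3, 1:4] <- TRUE                      # 12 fg
  ovA <- classify_changes(g1, g1)                       # 12 stable
  g2 <- g1; g2[3, 1:3] <- FALSE
  ovB <- classify_changes(g1, g2)
  expect_equal(instability_index(ovA, ovB), 0.25)
  expect_equal(instability_index(ovA, ovA), 0.0)
  shrunkAll <- classify_changes(g1, base)
  expect_equal(instability_index(ovA, shrunkAll), 1.0)

  # undefined cases propagate NA, never 0
  no_ext <- classify_changes(g1, g1)
  expect_true(is.na(stability_index(no_ext, ovB)))
  no_stable <- classify_changes(base, g1)
  expect_true(is.na(instability_index(no_stable, ovB)))
})

test_that("stability histogram tracks newly stabilized cohorts", {
  base <- matrix(FALSE, 6, 6)
  soma <- base; soma[1, ] <- TRUE            # always-stable row, excluded
  frames <- list()
  # pixel A (3,3) appears at frame 2 and persists; pixel B (5,5) appears at
  # frame 2 and retracts at frame 4
  f1 <- soma
  f2 <- soma; f2[3, 3] <- TRUE; f2[5, 5] <- TRUE
  f3 <- f2
  f4 <- soma; f4[3, 3] <- TRUE
  f5 <- f4
  ov <- list(classify_changes(f1, f2), classify_changes(f2, f3),
             classify_changes(f3, f4), classify_changes(f4, f5))
  h <- stability_histogram(ov)
  # both pixels newly stabilize at overlay 2; A survives offsets 1 and 2,
  # B survives neither
  expect_equal(h$fraction_stable[h$offset == 0], 1.0)
  expect_equal(h$fraction_stable[h$offset == 1], 0.5)
  expect_equal(h$fraction_stable[h$offset == 2], 0.5)
  expect_equal(h$n_at_risk[h$offset == 1], 2L)

  frozen <- list(classify_changes(soma, soma), classify_changes(soma, soma),
                 classify_changes(soma, soma))
  expect_warning(h0 <- stability_histogram(frozen), "no newly stabilized")
  expect_identical(nrow(h0), 0L)
  expect_error(stability_histogram(ov[1:2]), ">= 3")
})

test_that("traced process motility is mean |dL| per minute", {
  expect_equal(traced_motility(c(12, 12, 12), 5), 0)
  expect_equal(traced_motility(c(10, 15), 5), 1.0)
  expect_equal(traced_motility(c(10, 12, 9), 5), 0.5)
  expect_error(traced_motility(10, 5), ">= 2")
  expect_error(traced_motility(c(10, 12), 0), "positive")
})

test_that("pipeline indices equal planted indices exactly on noiseless movies", {
  arb <- generate_arbor(6, seq(10, 30, 5), seed = 21)
  tl <- generate_timelapse(arb, T = 8, extension_fraction = 0.1,
                           retraction_fraction = 0.08, seed = 22)
  pl <- planted_motility(tl)
  pipe <- motility_pipeline(tl$frames, frame_interval = 4)
  expect_identical(pipe$indices$motility_index, pl$motility_index)
  expect_identical(pipe$indices$extension_index, pl$extension_index)
  expect_identical(pipe$indices$retraction_index, pl$retraction_index)
  expect_true(all(pipe$registration$shifts == 0))
  expect_true(all(pipe$stability$per_pair$stability >= 0 &
                    pipe$stability$per_pair$stability <= 1, na.rm = TRUE))
})
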