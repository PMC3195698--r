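test_that("single-pair and constant images give the expected matrices", {
  # 1x2 image [5, 9]: one symmetric pair, probs 0.5/0.5
  nuc <- nucleus_image(gray_image(matrix(c(5L, 9L), 1, 2)),
                       matrix(TRUE, 1, 2))
  m <- build_glcm(nuc)
  expect_equal(m$counts[6, 10], 1)
  expect_equal(m$counts[10, 6], 1)
  expect_equal(sum(m$counts), 2)
  expect_equal(m$probs[6, 10], 0.5)

  # constant image: all mass on one diagonal cell
  cn <- nucleus_image(gray_image(matrix(42L, 6, 6)), matrix(TRUE, 6, 6))
  mc <- build_glcm(cn)
  expect_equal(mc$probs[43, 43], 1)

  # a small blob admits no pair at a displacement larger than its extent
  mk <- matrix(FALSE, 5, 5); mk[2, 2:3] <- TRUE
  sp <- nucleus_image(gray_image(matrix(0L, 5, 5)), mk)
  expect_error(build_glcm(sp, distance = 3L), "degenerate matrix")
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_error(build_glcm(nucleus_image(gray_image(matrix(0L, 5, 5)), one)),
               "fewer than 2")
})

test_that("matrix and features match the brute-force oracle", {
  for (seed in 1:8) {
    nuc <- random_nucleus(seed, n = 8L, levels = 4L)
    m <- build_glcm(nuc, levels = 16L)
    oc <- oracle_glcm_counts(unclass(nuc$image), unclass(nuc$mask),
                             levels = 16L)
    expect_equal(m$counts, oc, label = paste("counts seed", seed))
    of <- oracle_glcm_features(oc)
    f <- glcm_features(m)
    for (nm in names(of))
      expect_equal(f[[nm]], of[[nm]], tolerance = 1e-10,
                   label = paste(nm, "seed", seed))
  }
})

test_that("masked pixels are excluded from pair counting", {
  set.seed(5)
  g <- matrix(sample(0:255, 49, TRUE), 7, 7)
  mask <- matrix(TRUE, 7, 7); mask[3:5, 3:5] <- FALSE
  mask[1, ] <- c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  nuc <- nucleus_image(gray_image(g), nucleus_mask(mask))
  m <- build_glcm(nuc, levels = 32L)
  expect_equal(m$counts,
               oracle_glcm_counts(g, mask, levels = 32L))
})

test_that("closed-form two-cell matrix features are exact", {
  # alternating 0/1 line -> p(0,1) = p(1,0) = 0.5 at distance 1, 0 degrees
  g <- matrix(c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L), 1, 8)
  nuc <- nucleus_image(gray_image(g), matrix(TRUE, 1, 8))
  f <- glcm_features(build_glcm(nuc, directions = "0"))
  expect_equal(f$entropy, 1)            # 1 bit
  expect_equal(f$inertia, 1)
  expect_equal(f$contrast, f$inertia)   # identical by definition
  expect_equal(f$local_homogeneity, 0.5)
  expect_equal(f$energy_normalized, 0.5)
  expect_equal(f$diagonal_moment, 1)

  # delta distribution: constant image
  cn <- nucleus_image(gray_image(matrix(9L, 5, 5)), matrix(TRUE, 5, 5))
  fc <- glcm_features(build_glcm(cn))
  expect_equal(fc$entropy, 0)
  expect_equal(fc$inertia, 0)
  expect_equal(fc$local_homogeneity, 1)
  expect_equal(fc$energy_normalized, 1)
  expect_equal(fc$diagonal_moment, 0)
  expect_equal(fc$cluster_prominence, 0)
})

test_that("features are invariant under transposition and rotation", {
  rot <- function(x) t(x)[, nrow(x):1, drop = FALSE]
  for (seed in c(3, 14)) {
    nuc <- random_nucleus(seed, n = 10L)
    f0 <- glcm_features(build_glcm(nuc, levels = 64L))
    tnuc <- nucleus_image(gray_image(t(unclass(nuc$image))),
                          t(unclass(nuc$mask)))
    rnuc <- nucleus_image(gray_image(rot(unclass(nuc$image))),
                          rot(unclass(nuc$mask)))
    expect_equal(glcm_features(build_glcm(tnuc, levels = 64L)), f0,
                 tolerance = 1e-12)
    expect_equal(glcm_features(build_glcm(rnuc, levels = 64L)), f0,
                 tolerance = 1e-12)
  }
})

test_that("normalisation and entropy bounds hold on random images", {
  for (seed in 1:10) {
    nuc <- random_nucleus(seed + 40L, n = 12L)
    m <- build_glcm(nuc, levels = 32L)
    expect_equal(sum(m$probs), 1, tolerance = 1e-12)
    expect_true(all(m$probs >= 0))
    expect_equal(m$counts, t(m$counts))
    f <- glcm_features(m)
    expect_gte(f$entropy, 0)
    expect_lte(f$entropy, 2 * log2(m$levels))
    expect_gt(f$energy_normalized, 0)
    expect_lte(f$energy_normalized, 1)
    expect_gte(f$cluster_prominence, 0)
  }
})

test_that("increasing noise moves the features monotonically", {
  amps <- c(0, 10, 40)
  reps <- 20
  mean_feats <- sapply(amps, function(a) {
    rowMeans(sapply(seq_len(reps), function(s) {
      set.seed(1000 + 17 * s)
      g <- pmin(pmax(round(128 + a * stats::rnorm(32 * 32)), 0), 255)
      nuc <- nucleus_image(gray_image(matrix(as.integer(g), 32, 32)),
                           matrix(TRUE, 32, 32))
      f <- glcm_features(build_glcm(nuc))
      c(entropy = f$entropy, inertia = f$inertia,
        lh = f$local_homogeneity, en = f$energy_normalized)
    }))
  })
  expect_true(all(diff(mean_feats["entropy", ]) > 0))
  expect_true(all(diff(mean_feats["inertia", ]) > 0))
  expect_true(all(diff(mean_feats["lh", ]) < 0))
  expect_true(all(diff(mean_feats["en", ]) < 0))
})
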