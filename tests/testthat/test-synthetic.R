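test_that("generated masks meet their geometric targets deterministically", {
  r0 <- nucleus_recipe(mask_area_px = 3000, boundary_irregularity = 0,
                       axis_ratio = 1)
  m <- generate_mask(r0, 1)
  expect_s3_class(m, "nucleus_mask")
  expect_lt(abs(sum(m) - 3000) / 3000, 0.1)
  nuc <- nucleus_image(gray_image(matrix(0L, nrow(m), ncol(m))), m)
  # circular mask: chain-code circularity constant (see morphometry tests)
  expect_gt(form_factor(nuc), 0.89)

  # requested second-moment axis ratio is recovered
  r5 <- nucleus_recipe(mask_area_px = 3000, boundary_irregularity = 0.03,
                       axis_ratio = 0.5)
  m5 <- generate_mask(r5, 2)
  nuc5 <- nucleus_image(gray_image(matrix(0L, nrow(m5), ncol(m5))), m5)
  expect_equal(form_factor(nuc5, "axis_ratio"), 0.5, tolerance = 0.05)

  # same seed -> identical mask; different seed -> different mask
  expect_identical(generate_mask(r0, 9), generate_mask(r0, 9))
  expect_false(identical(generate_mask(r5, 9), generate_mask(r5, 10)))
})

test_that("generated textures hit the target gray statistics", {
  r <- nucleus_recipe(mask_area_px = 3000)
  m <- generate_mask(r, 1)
  tex <- generate_texture(r, m, 3)
  v <- unclass(tex)[unclass(m)]
  expect_lt(abs(mean(v) - r$target_mean_gray), 2)
  expect_lt(abs(stats::sd(v) - r$target_sd_gray), 1)
  expect_true(all(v >= 0 & v <= 255))
  expect_identical(generate_texture(r, m, 3), tex)

  # unreachable SD after clipping is reported
  rbad <- nucleus_recipe(mask_area_px = 3000, target_mean_gray = 250,
                         target_sd_gray = 60, clump_count = 0)
  expect_warning(generate_texture(rbad, m, 4), "off target")
})

test_that("the smooth limit yields a near-constant, low-entropy image", {
  r <- nucleus_recipe(mask_area_px = 3000, hurst = 0.95, clump_count = 0,
                      target_sd_gray = 0.1)
  nuc <- generate_nucleus(r, 5)
  expect_lt(glcm_features(build_glcm(nuc))$entropy, 0.5)
})

test_that("texture roughness is recovered by the fractal pipeline", {
  # rougher recipe (low Hurst) must measure a higher FD than a smooth one
  fds <- sapply(c(0.2, 0.8), function(H) {
    mean(sapply(1:8, function(s) {
      r <- nucleus_recipe(mask_area_px = 3000, hurst = H, clump_count = 0,
                          target_sd_gray = 30)
      fractal_features(generate_nucleus(r, 200 + s))$fd_minkowski
    }))
  })
  expect_gt(fds[1], fds[2])
})

test_that("chromatin clumps raise cluster prominence", {
  d <- sapply(1:12, function(s) {
    sapply(c(0, 20), function(k) {
      r <- nucleus_recipe(mask_area_px = 3000, hurst = 0.8, clump_count = k,
                          clump_amplitude = 5, clump_sigma = 3)
      glcm_features(build_glcm(generate_nucleus(r, 300 + s)))$cluster_prominence
    })
  })
  expect_gt(mean(d[2, ] / d[1, ]), 1)
  expect_gte(mean(d[2, ] > d[1, ]), 0.75)
})

test_that("simulated cohorts recover the atypical-class ground truth", {
  reps <- 120
  run <- function(lambda, seed_base) {
    labs <- vapply(seq_len(reps), function(s) {
      rec <- cohort_recipe(lambda = lambda)  # 2-SD effect, 30 patients
      classify_all(simulate_cohort(rec, seed = seed_base + s))$label
    }, character(1))
    labs
  }
  mid <- run(0.5, 1000)
  expect_gte(mean(mid == "intermediate"), 0.8)
  pro <- run(0, 2000)
  expect_gte(mean(pro == "close_to_promyelocytes"), 0.9)
  blast <- run(1, 3000)
  expect_gte(mean(blast %in% c("close_to_blasts", "not_defined")), 0.9)

  # null: all class means equal -> almost always not defined
  null_labs <- vapply(seq_len(reps), function(s) {
    rec <- cohort_recipe(features = data.frame(feature = "f", mu_blast = 0,
                                               mu_pro = 0, sd = 1))
    classify_all(simulate_cohort(rec, seed = 4000 + s))$label
  }, character(1))
  expect_gte(mean(null_labs == "not_defined"), 0.85)
})

test_that("cohort simulation is deterministic and carries ground truth", {
  rec <- cohort_recipe()
  t1 <- simulate_cohort(rec, 7)
  t2 <- simulate_cohort(rec, 7)
  expect_equal(t1, t2)
  gt <- attr(t1, "ground_truth")
  expect_equal(gt$effect_sd, 2)
  expect_equal(gt$lambda, 0.5)
  expect_equal(nrow(t1), 90)  # 30 patients x 3 classes
})

test_that("an image-level cohort run through the whole pipeline recovers the
           maturation pattern", {
  # scaled-down study: 6 patients x 3 classes x 4 nuclei, ~3000-px masks,
  # atypical texture halfway between the blast and promyelocyte presets
  nuclei <- simulate_image_cohort(n_patients = 6, n_nuclei_per_class = 4,
                                  lambda = 0.5, seed = 11,
                                  mask_area_px = 3000)
  expect_length(nuclei, 72)
  feats <- analyze_nuclei(nuclei)
  tab <- aggregate_cohort(feats, min_nuclei = 4)
  expect_equal(nrow(tab), 18)

  cm_ent <- tapply(tab$entropy, tab$cell_class, mean)
  cm_fd <- tapply(tab$fd_minkowski, tab$cell_class, mean)
  # blast chromatin is rougher: higher entropy and fractal dimension,
  # with atypical cells in between
  expect_gt(cm_ent[["blast"]], cm_ent[["promyelocyte"]])
  expect_gt(cm_fd[["blast"]], cm_fd[["promyelocyte"]])
  expect_true(cm_fd[["atypical"]] > cm_fd[["promyelocyte"]] &&
              cm_fd[["atypical"]] < cm_fd[["blast"]])

  rep <- classify_all(tab)
  expect_s3_class(rep, "atypical_report")
  # strongly separated texture features must not look blast-like
  sep <- rep[rep$feature %in% c("entropy", "fd_minkowski", "inertia"), ]
  expect_false(any(sep$label == "close_to_blasts"))
})
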