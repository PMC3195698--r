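test_that("grayscale conversion follows BT.601 luminance", {
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  # gray-axis fixed points and extremes
  expect_equal(as.integer(to_grayscale(px(0, 0, 0))), 0L)
  expect_equal(as.integer(to_grayscale(px(255, 255, 255))), 255L)
  expect_equal(as.integer(to_grayscale(px(100, 100, 100))), 100L)
  # hand-computed luminance: round(0.299*30 + 0.587*60 + 0.114*120) = 58
  expect_equal(as.integer(to_grayscale(px(30, 60, 120))), 58L)
  # idempotent on the gray axis for every level
  v <- 0:255
  rgb <- array(c(v, v, v), dim = c(256, 1, 3))
  expect_equal(as.vector(to_grayscale(rgb)), v)
})

test_that("images round-trip through PNG bit-exactly and RGB is converted", {
  set.seed(11)
  img <- gray_image(matrix(sample(0:255, 64 * 48, TRUE), 48, 64))
  path <- withr::local_tempfile(fileext = ".png")
  write_image(img, path)
  expect_equal(unclass(load_image(path)), unclass(img))

  # constant gray PNG passes through unchanged
  path2 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(200 / 255, 8, 8), path2)
  expect_true(all(unclass(load_image(path2)) == 200L))

  # RGB white maps to 255
  path3 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(1, dim = c(4, 4, 3)), path3)
  expect_true(all(unclass(load_image(path3)) == 255L))

  expect_error(load_image(file.path(tempdir(), "absent.png")), "cannot read")
})

test_that("BMP decoding handles 24-bit files", {
  # write a 24-bit BMP by hand, read it back
  w <- 5L; h <- 3L
  set.seed(4)
  r <- matrix(sample(0:255, h * w, TRUE), h, w)
  g <- matrix(sample(0:255, h * w, TRUE), h, w)
  b <- matrix(sample(0:255, h * w, TRUE), h, w)
  row_bytes <- ((w * 3L + 3L) %/% 4L) * 4L
  px <- raw(row_bytes * h)
  for (ri in seq_len(h)) {
    base <- (ri - 1L) * row_bytes
    for (ci in seq_len(w)) {
      rr <- h - ri + 1L  # bottom-up storage
      px[base + (ci - 1L) * 3L + 1:3] <-
        as.raw(c(b[rr, ci], g[rr, ci], r[rr, ci]))
    }
  }
  le32 <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256,
                               x %/% 65536 %% 256, x %/% 16777216))
  header <- c(charToRaw("BM"), le32(54 + length(px)), le32(0), le32(54),
              le32(40), le32(w), le32(h), as.raw(c(1, 0, 24, 0)),
              le32(0), le32(length(px)), le32(2835), le32(2835),
              le32(0), le32(0))
  path <- withr::local_tempfile(fileext = ".bmp")
  writeBin(c(header, px), path)
  loaded <- load_image(path)
  expected <- to_grayscale(array(c(r, g, b), dim = c(h, w, 3)))
  expect_equal(unclass(loaded), unclass(expected))
})

test_that("mask loading enforces the connectivity invariants", {
  # one 8-connected blob passes with the right pixel count
  m <- matrix(0, 12, 12); m[4:8, 4:9] <- 1
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(m, path)
  mk <- load_mask(path)
  expect_s3_class(mk, "nucleus_mask")
  expect_equal(sum(mk), 30)

  expect_error(nucleus_mask(matrix(0, 5, 5)), "empty mask")
  two <- matrix(0, 8, 8); two[1:2, 1:2] <- 1; two[6:7, 6:7] <- 1
  expect_error(nucleus_mask(two), "multi-component mask: 2")
  # diagonal contact is 8-connected, hence a single component
  diag2 <- matrix(0, 4, 4); diag2[1, 1] <- 1; diag2[2, 2] <- 1
  expect_silent(nucleus_mask(diag2))
})

test_that("nucleus bundling validates shapes and records calibration", {
  img <- gray_image(matrix(128L, 64, 64))
  msk <- matrix(TRUE, 64, 64)
  nuc <- nucleus_image(img, msk)
  expect_equal(nuc$pixel_size, 0.1)  # default calibration, um per pixel
  expect_error(nucleus_image(img, matrix(TRUE, 32, 32)), "dimension error")
  expect_error(nucleus_image(img, msk, pixel_size = 0),
               "positive")
  expect_error(nucleus_image(img, msk, cell_class = "monocyte"),
               "blast, atypical or promyelocyte")
})

test_that("features ignore everything outside the mask", {
  set.seed(21)
  base <- matrix(sample(40:200, 32 * 32, TRUE), 32, 32)
  mask <- outer(1:32, 1:32, function(i, j) sqrt((i - 16)^2 + (j - 16)^2) <= 10)
  altered <- base
  altered[!mask] <- sample(0:255, sum(!mask), TRUE)
  n1 <- nucleus_image(gray_image(base), mask)
  n2 <- nucleus_image(gray_image(altered), mask)
  f1 <- nucleus_features(n1)
  f2 <- nucleus_features(n2)
  expect_equal(f1, f2)
})

test_that("manifest loading resolves paths and metadata", {
  dir <- withr::local_tempdir()
  img <- gray_image(matrix(100L, 16, 16))
  m <- matrix(0, 16, 16); m[5:12, 5:12] <- 1
  write_image(img, file.path(dir, "cell1.png"))
  png::writePNG(m, file.path(dir, "cell1_mask.png"))
  utils::write.csv(data.frame(image_path = "cell1.png", mask_path = "",
                              patient_id = "P01", cell_class = "blast",
                              cell_index = 1),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  nuclei <- load_manifest(file.path(dir, "manifest.csv"))
  expect_length(nuclei, 1)
  expect_equal(nuclei[[1]]$patient_id, "P01")
  expect_equal(sum(nuclei[[1]]$mask), 64)
})
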