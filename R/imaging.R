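# ---- gray image -------------------------------------------------------------

#' Construct a gray image
#'
#' A gray image is an integer matrix of gray levels in \[0, 255\], 255 being
#' the brightest, stored row-major with the origin at the top-left corner.
#'
#' @param pixels Numeric matrix of gray levels in \[0, 255\].
#' @return An integer matrix of class `gray_image`.
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (anyNA(pixels)) stop("gray image contains missing values")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("gray levels must lie in [0, 255]")
  storage.mode(pixels) <- "integer"
  structure(pixels, class = c("gray_image", "matrix"))
}

#' Convert an RGB array to a gray image
#'
#' Luminance conversion with ITU-R BT.601 weights,
#' `round(0.299 R + 0.587 G + 0.114 B)` (rounding half away from zero),
#' clipped to \[0, 255\]. Gray-axis pixels (R = G = B = v) map to v exactly.
#'
#' @param rgb Numeric array `h x w x 3` with channels in \[0, 255\].
#' @param weights Length-3 channel weights; default BT.601.
#' @return A [gray_image()].
#' @export
to_grayscale <- function(rgb, weights = c(0.299, 0.587, 0.114)) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] < 3L)
    stop("`rgb` must be an h x w x 3 array")
  if (min(rgb) < 0 || max(rgb) > 255) stop("channels must lie in [0, 255]")
  y <- weights[1] * rgb[, , 1] + weights[2] * rgb[, , 2] + weights[3] * rgb[, , 3]
  y <- matrix(floor(y + 0.5), dim(rgb)[1], dim(rgb)[2])  # round half up
  gray_image(pmin(pmax(y, 0), 255))
}

# ---- file readers -----------------------------------------------------------

# Decode an uncompressed BI_RGB Windows BMP (8-bit palette or 24/32-bit).
# No installed package reads BMP, so this is done by hand; covers the
# formats produced by routine capture systems.
read_bmp <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 54L || rawToChar(raw[1:2]) != "BM")
    stop("not a BMP file: ", path)
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * 256^(0:1))
  data_off <- u32(10L)
  header_size <- u32(14L)
  if (header_size < 40L) stop("unsupported BMP header in ", path)
  w <- u32(18L)
  h_raw <- u32(22L)
  top_down <- h_raw > 2^31
  h <- if (top_down) 2^32 - h_raw else h_raw
  bpp <- u16(28L)
  compression <- u32(30L)
  if (compression != 0L)
    stop("unsupported format: compressed BMP in ", path)
  if (!bpp %in% c(8L, 24L, 32L))
    stop("unsupported format: ", bpp, "-bit BMP in ", path)
  if (bpp == 8L) {
    n_colors <- u32(46L)
    if (n_colors == 0L) n_colors <- 256L
    pal_off <- 14L + header_size
    pal <- matrix(as.integer(raw[pal_off + seq_len(4L * n_colors)]),
                  ncol = 4L, byrow = TRUE)  # B, G, R, reserved
    row_bytes <- ((w + 3L) %/% 4L) * 4L
    idx <- matrix(0L, h, w)
    for (r in seq_len(h)) {
      off <- data_off + (r - 1L) * row_bytes
      idx[r, ] <- as.integer(raw[off + seq_len(w)])
    }
    if (!top_down) idx <- idx[h:1, , drop = FALSE]
    rgb <- array(0, dim = c(h, w, 3L))
    rgb[, , 1] <- matrix(pal[idx + 1L, 3L], h, w)
    rgb[, , 2] <- matrix(pal[idx + 1L, 2L], h, w)
    rgb[, , 3] <- matrix(pal[idx + 1L, 1L], h, w)
  } else {
    bytes_pp <- bpp %/% 8L
    row_bytes <- ((w * bytes_pp + 3L) %/% 4L) * 4L
    rgb <- array(0, dim = c(h, w, 3L))
    for (r in seq_len(h)) {
      off <- data_off + (r - 1L) * row_bytes
      px <- matrix(as.integer(raw[off + seq_len(w * bytes_pp)]),
                   nrow = bytes_pp)  # B, G, R[, A] per column
      rgb[r, , 1] <- px[3L, ]
      rgb[r, , 2] <- px[2L, ]
      rgb[r, , 3] <- px[1L, ]
    }
    if (!top_down) rgb <- rgb[h:1, , , drop = FALSE]
  }
  rgb
}

# Read any supported file into either a gray matrix or an h x w x 3 array,
# both on the 0..255 integer scale. Checks that the source is 8 bits per
# channel.
read_pixels <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = tryCatch(png::readPNG(path),
                   error = function(e) stop("cannot read image file: ", path,
                                            " (", conditionMessage(e), ")")),
    tif = ,
    tiff = tryCatch(tiff::readTIFF(path),
                    error = function(e) stop("cannot read image file: ", path,
                                             " (", conditionMessage(e), ")")),
    bmp = return(read_bmp(path)),
    stop("unsupported format: .", ext, " (", path, ")")
  )
  a <- a * 255
  if (max(abs(a - round(a))) > 1e-6)
    stop("unsupported format: ", path, " is not 8 bits per channel")
  a <- round(a)
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] == 2L) a <- a[, , 1]                        # gray + alpha
    else if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]   # drop alpha
    else if (dim(a)[3] == 1L) a <- a[, , 1]
  }
  a
}

#' Load an image file as a gray image
#'
#' Reads an 8-bit BMP, PNG or TIFF. RGB inputs are converted through
#' [to_grayscale()]; single-channel inputs pass through unchanged.
#'
#' @param path Path to the image file.
#' @return A [gray_image()].
#' @export
load_image <- function(path) {
  a <- read_pixels(path)
  if (length(dim(a)) == 3L) to_grayscale(a) else gray_image(a)
}

#' Write a gray image to a PNG file
#'
#' Round-trips bit-exactly through [load_image()].
#'
#' @param img A [gray_image()].
#' @param path Output path (.png).
#' @export
write_image <- function(img, path) {
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}

# ---- masks ------------------------------------------------------------------

# 8-connected component labels of a logical matrix, by vectorised frontier
# expansion. Returns an integer matrix (0 = background).
label_components <- function(fg) {
  h <- nrow(fg); w <- ncol(fg)
  labels <- matrix(0L, h, w)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- fg
  lab_pad <- matrix(0L, h + 2L, w + 2L)
  next_label <- 0L
  remaining <- which(pad & lab_pad == 0L)
  offs <- c(-1L, 1L, -(h + 2L), h + 2L,
            -(h + 2L) - 1L, -(h + 2L) + 1L, (h + 2L) - 1L, (h + 2L) + 1L)
  while (length(remaining) > 0L) {
    next_label <- next_label + 1L
    frontier <- remaining[1L]
    lab_pad[frontier] <- next_label
    while (length(frontier) > 0L) {
      nb <- unique(rep(frontier, each = 8L) + offs)
      nb <- nb[pad[nb] & lab_pad[nb] == 0L]
      lab_pad[nb] <- next_label
      frontier <- nb
    }
    remaining <- which(pad & lab_pad == 0L)
  }
  labels[, ] <- lab_pad[2:(h + 1L), 2:(w + 1L)]
  labels
}

#' Construct a nucleus mask
#'
#' A mask is a logical matrix whose TRUE pixels form the nucleus. It must
#' contain at least one foreground pixel and exactly one 8-connected
#' component; masks with interior holes are accepted (the holes are simply
#' not part of the nucleus pixel set).
#'
#' @param pixels Logical (or 0/1 numeric) matrix; TRUE/nonzero = nucleus.
#' @return A logical matrix of class `nucleus_mask`.
#' @export
nucleus_mask <- function(pixels) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  fg <- pixels > 0
  if (!any(fg)) stop("empty mask: no foreground pixels")
  n_comp <- max(label_components(fg))
  if (n_comp > 1L)
    stop("multi-component mask: ", n_comp, " 8-connected components found")
  structure(fg, class = c("nucleus_mask", "matrix"))
}

#' Load a mask file
#'
#' Reads a single-channel (or RGB, collapsed by luminance) image and
#' thresholds it: pixels > 0 become foreground. The single-component
#' invariant of [nucleus_mask()] is enforced.
#'
#' @param path Path to the mask image.
#' @return A `nucleus_mask`.
#' @export
load_mask <- function(path) {
  img <- load_image(path)
  nucleus_mask(unclass(img) > 0)
}

# ---- nucleus bundle ---------------------------------------------------------

#' Bundle a calibrated, masked nucleus
#'
#' The unit of measurement for all downstream features: a gray image, its
#' nucleus mask, the pixel calibration and the cohort metadata. Feature code
#' never reads pixels outside the mask.
#'
#' @param image A [gray_image()] (a plain matrix is accepted and validated).
#' @param mask A [nucleus_mask()] (a plain logical matrix is accepted).
#' @param pixel_size Side length of one pixel in micrometres; default 0.1.
#' @param patient_id,cell_class,cell_index Metadata carried through to the
#'   feature table. `cell_class` is one of `"blast"`, `"atypical"`,
#'   `"promyelocyte"` (or NA).
#' @return An object of class `nucleus_image`.
#' @export
nucleus_image <- function(image, mask, pixel_size = 0.1,
                          patient_id = NA_character_,
                          cell_class = NA_character_,
                          cell_index = NA_integer_) {
  if (!inherits(image, "gray_image")) image <- gray_image(image)
  if (!inherits(mask, "nucleus_mask")) mask <- nucleus_mask(mask)
  if (!identical(dim(image), dim(mask)))
    stop("dimension error: image is ", paste(dim(image), collapse = "x"),
         " but mask is ", paste(dim(mask), collapse = "x"))
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number")
  if (!is.na(cell_class) &&
      !cell_class %in% c("blast", "atypical", "promyelocyte"))
    stop("`cell_class` must be blast, atypical or promyelocyte")
  structure(
    list(image = image, mask = mask, pixel_size = pixel_size,
         patient_id = patient_id, cell_class = cell_class,
         cell_index = cell_index),
    class = "nucleus_image"
  )
}

#' @export
print.nucleus_image <- function(x, ...) {
  cat("<nucleus_image> ", nrow(x$image), "x", ncol(x$image),
      " px, ", sum(x$mask), " nucleus pixels, ",
      x$pixel_size, " um/px\n", sep = "")
  if (!is.na(x$patient_id) || !is.na(x$cell_class))
    cat("  patient ", x$patient_id, ", class ", x$cell_class,
        ", cell ", x$cell_index, "\n", sep = "")
  invisible(x)
}

# Gray values of the nucleus pixels only.
mask_values <- function(nucleus) {
  as.integer(nucleus$image)[as.logical(nucleus$mask)]
}

#' Load nuclei from a manifest
#'
#' Reads a manifest CSV with columns `image_path`, `mask_path`,
#' `patient_id`, `cell_class`, `cell_index`, resolving relative paths
#' against the manifest's directory. Alternatively, [load_image()] +
#' [load_mask()] + [nucleus_image()] compose the same thing by hand; mask
#' files following the `<stem>_mask.<ext>` convention can be paired with
#' `mask_path` left blank.
#'
#' @param manifest Path to the manifest CSV.
#' @param pixel_size Calibration applied to every nucleus (micrometres).
#' @return A list of [nucleus_image()] objects.
#' @export
load_manifest <- function(manifest, pixel_size = 0.1) {
  df <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("image_path", "patient_id", "cell_class", "cell_index")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(manifest)
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  lapply(seq_len(nrow(df)), function(i) {
    ip <- resolve(df$image_path[i])
    mp <- if ("mask_path" %in% names(df) && !is.na(df$mask_path[i]) &&
              nzchar(df$mask_path[i])) {
      resolve(df$mask_path[i])
    } else {
      stem <- tools::file_path_sans_ext(ip)
      ext <- tools::file_ext(ip)
      paste0(stem, "_mask.", ext)
    }
    nucleus_image(load_image(ip), load_mask(mp), pixel_size = pixel_size,
                  patient_id = as.character(df$patient_id[i]),
                  cell_class = df$cell_class[i],
                  cell_index = as.integer(df$cell_index[i]))
  })
}
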