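# Synthetic nucleus images and patient cohorts. Everything here is a pure
# function of (recipe, seed), so pipeline tests need no microscopy data.

# run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Fractional Brownian surface by spectral synthesis
#'
#' Generates an n x n stationary-increment random surface whose power
#' spectrum falls as `f^-(2H + 2)`, the spectrum of two-dimensional
#' fractional Brownian motion with Hurst exponent H. Its theoretical
#' Minkowski-Bouligand dimension is `FD = 3 - H`. The surface is
#' normalised to mean 0, standard deviation 1.
#'
#' @param n Side length (any positive integer; powers of two are fastest).
#' @param hurst Hurst exponent in (0, 1).
#' @param seed Integer seed.
#' @return An n x n numeric matrix.
#' @export
fbm_surface <- function(n, hurst, seed) {
  stopifnot(n >= 2, hurst > 0, hurst < 1)
  with_seed(seed, {
    k <- if (n == 2) c(0, -0.5) else c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
    fx <- matrix(k, n, n)
    fy <- t(fx)
    amp <- (fx^2 + fy^2)^(-(hurst + 1) / 2)
    amp[1, 1] <- 0
    spec <- amp * matrix(complex(real = stats::rnorm(n * n),
                                 imaginary = stats::rnorm(n * n)), n, n)
    field <- Re(stats::fft(spec, inverse = TRUE)) / n
    (field - mean(field)) / stats::sd(field)
  })
}

#' Recipe for one synthetic nucleus
#'
#' Parameters of the synthetic nucleus generator. The defaults, and the
#' two presets, are patterned on immature granulocytic precursors imaged
#' at 0.1 um/pixel: masks of roughly 110-120 um^2 (11000-12000 px), nearly
#' elliptical with a controllable low-order boundary perturbation, and a
#' chromatin-like interior built from a fractional Brownian texture
#' (theoretical FD = 3 - hurst) plus darker Gaussian chromatin clumps.
#'
#' `preset = "blast"` gives a rounder mask with rougher, brighter, more
#' heterogeneous chromatin (more sharp condensation spots);
#' `preset = "promyelocyte"` an indented mask with smoother, darker, more
#' homogeneous chromatin — matching the sign pattern of the maturation
#' contrast (promyelocytes: lower entropy, inertia, fractal dimension and
#' cluster prominence, higher local homogeneity).
#'
#' @param preset NULL, `"blast"` or `"promyelocyte"`.
#' @param mask_area_px Target mask area in pixels (>= 50).
#' @param axis_ratio Minor/major axis of the base ellipse, in (0, 1].
#' @param boundary_irregularity Amplitude of the low-order Fourier
#'   perturbation of the ellipse radius (0 = exact ellipse).
#' @param hurst Hurst exponent of the fBm texture, in (0, 1).
#' @param clump_count Number of Gaussian chromatin clumps.
#' @param clump_amplitude Clump depth in units of the texture SD
#'   (clumps darken, as condensed chromatin does).
#' @param clump_sigma Clump radius (pixels).
#' @param target_mean_gray,target_sd_gray In-mask gray statistics the
#'   texture is rescaled to.
#' @return A list of class `nucleus_recipe`.
#' @export
nucleus_recipe <- function(preset = NULL, mask_area_px = 11200,
                           axis_ratio = 0.9, boundary_irregularity = 0.04,
                           hurst = 0.45, clump_count = 10,
                           clump_amplitude = 4, clump_sigma = 3,
                           target_mean_gray = 122, target_sd_gray = 8.5) {
  r <- list(mask_area_px = mask_area_px, axis_ratio = axis_ratio,
            boundary_irregularity = boundary_irregularity, hurst = hurst,
            clump_count = clump_count, clump_amplitude = clump_amplitude,
            clump_sigma = clump_sigma, target_mean_gray = target_mean_gray,
            target_sd_gray = target_sd_gray)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("blast", "promyelocyte"))
    tweak <- switch(preset,
      blast = list(mask_area_px = 11800, axis_ratio = 0.95,
                   boundary_irregularity = 0.02, hurst = 0.35,
                   clump_count = 12, clump_amplitude = 4, clump_sigma = 2.5,
                   target_mean_gray = 125, target_sd_gray = 9.1),
      promyelocyte = list(mask_area_px = 12100, axis_ratio = 0.85,
                          boundary_irregularity = 0.08, hurst = 0.55,
                          clump_count = 6, clump_amplitude = 3,
                          clump_sigma = 3.5, target_mean_gray = 118.6,
                          target_sd_gray = 8.1))
    called <- names(as.list(match.call()))[-1]
    tweak <- tweak[setdiff(names(tweak), called)]  # explicit args win
    r[names(tweak)] <- tweak
  }
  stopifnot(r$mask_area_px >= 50, r$axis_ratio > 0, r$axis_ratio <= 1,
            r$boundary_irregularity >= 0, r$hurst > 0, r$hurst < 1,
            r$clump_count >= 0, r$clump_amplitude >= 0, r$clump_sigma > 0)
  structure(r, class = "nucleus_recipe")
}

#' Generate a synthetic nucleus mask
#'
#' Rasterises an ellipse of the recipe's area and axis ratio whose polar
#' radius is perturbed by a random low-order (harmonics 2-5) Fourier
#' series with amplitude `boundary_irregularity`. Regenerates (up to 10
#' draws) if the perturbation splits the region or moves the area more
#' than 10% off target.
#'
#' @param recipe A [nucleus_recipe()].
#' @param seed Integer seed.
#' @return A `nucleus_mask`.
#' @export
generate_mask <- function(recipe, seed) {
  stopifnot(inherits(recipe, "nucleus_recipe"))
  a <- sqrt(recipe$mask_area_px / (pi * recipe$axis_ratio))  # semi-major
  b <- recipe$axis_ratio * a
  half <- ceiling(a * (1 + 3 * recipe$boundary_irregularity) + 2)
  n <- 2L * half + 1L
  ctr <- half + 1L
  rows <- matrix(seq_len(n) - ctr, n, n)
  cols <- t(rows)
  theta <- atan2(rows, cols)
  rho <- sqrt(rows^2 + cols^2)
  r_ell <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  for (attempt in 1:10) {
    pert <- with_seed(seed + 1000003L * (attempt - 1L), {
      out <- matrix(0, n, n)
      for (k in 2:5) {
        ck <- stats::rnorm(1) / k; sk <- stats::rnorm(1) / k
        out <- out + ck * cos(k * theta) + sk * sin(k * theta)
      }
      out
    })
    fg <- rho <= r_ell * (1 + recipe$boundary_irregularity * pert)
    area <- sum(fg)
    if (area < 1 ||
        abs(area - recipe$mask_area_px) > 0.1 * recipe$mask_area_px) next
    if (max(label_components(fg)) != 1L) next
    return(nucleus_mask(fg))
  }
  stop("infeasible mask geometry: no valid mask in 10 attempts")
}

#' Generate a synthetic chromatin texture inside a mask
#'
#' A fractional Brownian surface with the recipe's Hurst exponent, minus
#' `clump_count` Gaussian chromatin clumps (darker, since condensed
#' chromatin absorbs more stain) at random in-mask centres, affinely
#' rescaled so the in-mask pixels match the recipe's target mean and SD,
#' then clipped to \[0, 255\] and rounded. If clipping moves the achieved
#' statistics off target (mean by > 2 or SD by > 1), a warning reports the
#' achieved values.
#'
#' @param recipe A [nucleus_recipe()].
#' @param mask A `nucleus_mask`.
#' @param seed Integer seed.
#' @return A [gray_image()] the size of the mask.
#' @export
generate_texture <- function(recipe, mask, seed) {
  stopifnot(inherits(recipe, "nucleus_recipe"))
  if (!inherits(mask, "nucleus_mask")) mask <- nucleus_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  n <- 2^ceiling(log2(max(h, w)))
  field <- fbm_surface(n, recipe$hurst, seed)[seq_len(h), seq_len(w)]
  if (recipe$clump_count > 0 && recipe$clump_amplitude > 0) {
    fg_idx <- which(unclass(mask), arr.ind = TRUE)
    centres <- with_seed(seed + 7L,
      fg_idx[sample.int(nrow(fg_idx), recipe$clump_count, replace = TRUE), ,
             drop = FALSE])
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (i in seq_len(nrow(centres))) {
      d2 <- (rows - centres[i, 1])^2 + (cols - centres[i, 2])^2
      field <- field - recipe$clump_amplitude *
        exp(-d2 / (2 * recipe$clump_sigma^2))
    }
  }
  field <- (field - mean(field[unclass(mask)])) /
    stats::sd(field[unclass(mask)])
  g <- recipe$target_mean_gray + recipe$target_sd_gray * field
  g <- round(pmin(pmax(g, 0), 255))
  got <- g[unclass(mask)]
  if (abs(mean(got) - recipe$target_mean_gray) > 2 ||
      abs(stats::sd(got) - recipe$target_sd_gray) > 1)
    warning(sprintf(
      "clipping moved in-mask statistics off target: mean %.1f (target %.1f), sd %.1f (target %.1f)",
      mean(got), recipe$target_mean_gray, stats::sd(got),
      recipe$target_sd_gray))
  gray_image(g)
}

#' Generate one complete synthetic nucleus
#'
#' @param recipe A [nucleus_recipe()].
#' @param seed Integer seed.
#' @param pixel_size,patient_id,cell_class,cell_index Passed to
#'   [nucleus_image()].
#' @return A [nucleus_image()].
#' @export
generate_nucleus <- function(recipe, seed, pixel_size = 0.1,
                             patient_id = NA_character_,
                             cell_class = NA_character_,
                             cell_index = NA_integer_) {
  mask <- generate_mask(recipe, seed)
  img <- generate_texture(recipe, mask, seed + 1L)
  nucleus_image(img, mask, pixel_size, patient_id, cell_class, cell_index)
}

#' Recipe for a simulated patient cohort
#'
#' Defines the distribution of patient-level feature means for the three
#' cell classes. Each feature has a blast mean, a promyelocyte mean and a
#' common SD; the atypical-class mean is the mixture
#' `mu_atyp = lambda * mu_blast + (1 - lambda) * mu_pro`, so `lambda = 1`
#' makes atypical cells blast-like and `lambda = 0` promyelocyte-like.
#' A patient random effect with variance `rho * sd^2` is shared by the
#' three classes of a patient (within-patient correlation), the remainder
#' `(1 - rho) * sd^2` is residual.
#'
#' The default cohort matches the usual study conditions: 30 patients,
#' 30 nuclei per class, one feature with a two-SD blast-promyelocyte
#' separation, within-patient correlation 0.3.
#'
#' @param n_patients Number of patients (default 30).
#' @param n_nuclei_per_class Nuclei behind each patient-class mean
#'   (metadata; default 30).
#' @param features Data frame with columns `feature`, `mu_blast`,
#'   `mu_pro`, `sd`.
#' @param lambda Atypical-class mixing in \[0, 1\] (default 0.5).
#' @param rho Within-patient correlation in \[0, 1) (default 0.3).
#' @return A list of class `cohort_recipe`.
#' @export
cohort_recipe <- function(n_patients = 30L, n_nuclei_per_class = 30L,
                          features = data.frame(feature = "texture",
                                                mu_blast = 1, mu_pro = -1,
                                                sd = 1),
                          lambda = 0.5, rho = 0.3) {
  stopifnot(lambda >= 0, lambda <= 1, rho >= 0, rho < 1,
            all(features$sd > 0), n_patients >= 3)
  structure(list(n_patients = as.integer(n_patients),
                 n_nuclei_per_class = as.integer(n_nuclei_per_class),
                 features = features, lambda = lambda, rho = rho),
            class = "cohort_recipe")
}

#' Simulate a patient cohort of feature means
#'
#' Draws the patient-level class means described by the recipe. The
#' ground truth (lambda, per-feature effect sizes) is attached as
#' attribute `ground_truth`.
#'
#' @param recipe A [cohort_recipe()].
#' @param seed Integer seed.
#' @return A `cohort_table` with classes blast, atypical, promyelocyte.
#' @export
simulate_cohort <- function(recipe, seed) {
  stopifnot(inherits(recipe, "cohort_recipe"))
  with_seed(seed, {
    np <- recipe$n_patients
    fs <- recipe$features
    classes <- c("blast", "atypical", "promyelocyte")
    out <- data.frame(
      patient_id = rep(sprintf("P%02d", seq_len(np)), times = 3L),
      cell_class = rep(classes, each = np),
      n_nuclei = recipe$n_nuclei_per_class,
      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(fs))) {
      mu <- c(blast = fs$mu_blast[i],
              atypical = recipe$lambda * fs$mu_blast[i] +
                (1 - recipe$lambda) * fs$mu_pro[i],
              promyelocyte = fs$mu_pro[i])
      b <- stats::rnorm(np, 0, sqrt(recipe$rho) * fs$sd[i])
      e <- matrix(stats::rnorm(3L * np, 0, sqrt(1 - recipe$rho) * fs$sd[i]),
                  np, 3L)
      out[[fs$feature[i]]] <- as.vector(
        rep(b, 3L) + e + rep(mu[classes], each = np))
    }
    gt <- data.frame(feature = fs$feature,
                     effect_sd = abs(fs$mu_blast - fs$mu_pro) / fs$sd,
                     lambda = recipe$lambda)
    structure(cohort_table(out, cohort = "MDS"), ground_truth = gt)
  })
}

#' Simulate a full image-level cohort
#'
#' Generates synthetic nucleus images for every patient, cell class and
#' cell: blasts from the blast preset, promyelocytes from the
#' promyelocyte preset, and atypical cells from a recipe whose continuous
#' parameters are interpolated between the two with weight `lambda`
#' (1 = blast-like). Patient-to-patient variation is added as small
#' random offsets on the Hurst exponent and target mean gray.
#'
#' @param n_patients,n_nuclei_per_class Cohort size (defaults 30 and 30;
#'   scale these down for quick runs).
#' @param lambda Atypical-class interpolation weight in \[0, 1\].
#' @param seed Integer seed.
#' @param mask_area_px Override of the presets' mask area (smaller masks
#'   run much faster; NULL keeps the presets' full size).
#' @param patient_sd_hurst,patient_sd_mean SDs of the per-patient offsets.
#' @return A list of [nucleus_image()] objects.
#' @export
simulate_image_cohort <- function(n_patients = 30L, n_nuclei_per_class = 30L,
                                  lambda = 0.5, seed = 1L,
                                  mask_area_px = NULL,
                                  patient_sd_hurst = 0.02,
                                  patient_sd_mean = 1.5) {
  base <- list(blast = nucleus_recipe(preset = "blast"),
               promyelocyte = nucleus_recipe(preset = "promyelocyte"))
  interp <- function(f) lambda * base$blast[[f]] +
    (1 - lambda) * base$promyelocyte[[f]]
  atyp <- nucleus_recipe(
    mask_area_px = interp("mask_area_px"),
    axis_ratio = interp("axis_ratio"),
    boundary_irregularity = interp("boundary_irregularity"),
    hurst = interp("hurst"), clump_count = round(interp("clump_count")),
    clump_amplitude = interp("clump_amplitude"),
    clump_sigma = interp("clump_sigma"),
    target_mean_gray = interp("target_mean_gray"),
    target_sd_gray = interp("target_sd_gray"))
  recipes <- list(blast = base$blast, atypical = atyp,
                  promyelocyte = base$promyelocyte)
  if (!is.null(mask_area_px))
    for (cl in names(recipes)) recipes[[cl]]$mask_area_px <- mask_area_px
  offsets <- with_seed(seed, list(
    hurst = stats::rnorm(n_patients, 0, patient_sd_hurst),
    mean = stats::rnorm(n_patients, 0, patient_sd_mean)))
  nuclei <- list()
  cell_seed <- seed
  for (p in seq_len(n_patients)) {
    for (cl in names(recipes)) {
      r <- recipes[[cl]]
      r$hurst <- min(max(r$hurst + offsets$hurst[p], 0.05), 0.95)
      r$target_mean_gray <- r$target_mean_gray + offsets$mean[p]
      for (i in seq_len(n_nuclei_per_class)) {
        cell_seed <- cell_seed + 2L
        nuclei[[length(nuclei) + 1L]] <- generate_nucleus(
          r, cell_seed, patient_id = sprintf("P%02d", p),
          cell_class = cl, cell_index = i)
      }
    }
  }
  nuclei
}
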