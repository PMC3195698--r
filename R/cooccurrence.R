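# Gray-level co-occurrence matrix over nucleus pixels and the seven
# texture features reported for chromatin analysis.

# The four standard directions at 0, 45, 90 and 135 degrees as (drow, dcol)
# displacements in matrix coordinates (row grows downwards).
glcm_directions <- function() {
  list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
       `135` = c(-1L, -1L))
}

#' Build the gray-level co-occurrence matrix of a nucleus
#'
#' Counts pairs of gray levels at displacement `distance` along the given
#' directions. A pair contributes only if both pixels lie inside the
#' nucleus mask. Pairs are accumulated over all directions and both
#' orientations, so the matrix is symmetric; `probs` is the count matrix
#' normalised to sum to 1. Gray levels 0..255 are quantised to `levels`
#' bins by `floor(g * levels / 256)`.
#'
#' @param nucleus A [nucleus_image()].
#' @param distance Displacement in pixels (default 1).
#' @param directions Character subset of `c("0", "45", "90", "135")`
#'   (degrees), default all four, pooled into one matrix.
#' @param levels Number of gray levels G after quantisation; one of
#'   16, 32, 64, 128, 256 (default 256, the full gray range).
#' @return An object of class `glcm` with elements `counts`, `probs`
#'   (G x G matrices), `levels`, `distance`, `directions`, `n_pairs`.
#' @export
build_glcm <- function(nucleus, distance = 1L,
                       directions = c("0", "45", "90", "135"),
                       levels = 256L) {
  stopifnot(inherits(nucleus, "nucleus_image"))
  if (!levels %in% c(16L, 32L, 64L, 128L, 256L))
    stop("`levels` must be one of 16, 32, 64, 128, 256")
  directions <- match.arg(directions, c("0", "45", "90", "135"),
                          several.ok = TRUE)
  if (sum(nucleus$mask) < 2L)
    stop("degenerate matrix: mask has fewer than 2 pixels")
  g <- unclass(nucleus$image) %/% as.integer(256L / levels)
  m <- unclass(nucleus$mask)
  h <- nrow(g); w <- ncol(g)
  counts <- matrix(0, levels, levels)
  for (dir in glcm_directions()[directions]) {
    dr <- dir[1L] * distance; dc <- dir[2L] * distance
    if (max(1L, 1L - dr) > min(h, h - dr) ||
        max(1L, 1L - dc) > min(w, w - dc)) next
    r1 <- max(1L, 1L - dr):min(h, h - dr)
    c1 <- max(1L, 1L - dc):min(w, w - dc)
    ok <- m[r1, c1, drop = FALSE] & m[r1 + dr, c1 + dc, drop = FALSE]
    if (!any(ok)) next
    i <- g[r1, c1, drop = FALSE][ok]
    j <- g[r1 + dr, c1 + dc, drop = FALSE][ok]
    # accumulate both orientations -> symmetric counts
    tab <- tabulate(i * levels + j + 1L, nbins = levels * levels) +
           tabulate(j * levels + i + 1L, nbins = levels * levels)
    counts <- counts + matrix(tab, levels, levels, byrow = TRUE)
  }
  n_pairs <- sum(counts)
  if (n_pairs == 0)
    stop("degenerate matrix: no valid in-mask pixel pair at distance ",
         distance)
  structure(
    list(counts = counts, probs = counts / n_pairs, levels = levels,
         distance = distance, directions = directions, n_pairs = n_pairs),
    class = "glcm"
  )
}

#' @export
print.glcm <- function(x, ...) {
  cat("<glcm> ", x$levels, " gray levels, distance ", x$distance,
      ", directions {", paste(x$directions, collapse = ", "),
      "} deg, ", x$n_pairs, " (oriented) pairs\n", sep = "")
  invisible(x)
}

#' Co-occurrence texture features
#'
#' The seven chromatin texture features computed from the normalised
#' co-occurrence matrix p(i, j), with marginal means
#' `mu_x = sum_i sum_j i p(i,j)` and `mu_y = sum_i sum_j j p(i,j)`:
#'
#' * `entropy` — Haralick's entropy, `-sum p log2 p` in bits (0 log 0 = 0);
#' * `inertia` and `contrast` — `sum (i-j)^2 p`; the two names denote the
#'   same moment and are reported as two identical columns;
#' * `local_homogeneity` — inverse difference moment, `sum p / (1+(i-j)^2)`;
#' * `energy_normalized` — angular second moment `sum p^2` (in (0, 1]);
#' * `energy_raw` — the unnormalised companion `sum counts^2`, on the
#'   pair-count scale;
#' * `diagonal_moment` — first difference moment `sum |i-j| p`
#'   (dissimilarity);
#' * `cluster_prominence` — fourth cluster moment
#'   `sum (i+j-mu_x-mu_y)^4 p` (unscaled).
#'
#' @param m A `glcm` from [build_glcm()].
#' @return One-row data.frame with the eight feature columns plus `mu_x`,
#'   `mu_y`.
#' @export
glcm_features <- function(m) {
  stopifnot(inherits(m, "glcm"))
  p <- m$probs
  G <- m$levels
  i <- matrix(0:(G - 1L), G, G)
  j <- t(i)
  d <- i - j
  mu_x <- sum(i * p)
  mu_y <- sum(j * p)
  nz <- p > 0
  data.frame(
    entropy = -sum(p[nz] * log2(p[nz])),
    inertia = sum(d^2 * p),
    local_homogeneity = sum(p / (1 + d^2)),
    energy_normalized = sum(p^2),
    energy_raw = sum(m$counts^2),
    contrast = sum(d^2 * p),
    diagonal_moment = sum(abs(d) * p),
    cluster_prominence = sum((i + j - mu_x - mu_y)^4 * p),
    mu_x = mu_x, mu_y = mu_y
  )
}
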