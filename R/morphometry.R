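# Geometric and first-order gray-level descriptors of a segmented nucleus.

#' Nuclear area
#'
#' @param nucleus A [nucleus_image()].
#' @return A list with `area_px` (foreground pixel count) and `area_um2`
#'   (`area_px * pixel_size^2`).
#' @export
nucleus_area <- function(nucleus) {
  stopifnot(inherits(nucleus, "nucleus_image"))
  n <- sum(nucleus$mask)
  list(area_px = n, area_um2 = n * nucleus$pixel_size^2)
}

# Moore boundary trace of the single 8-connected foreground component.
# Returns the closed chain of boundary pixel coordinates (rows of a 2-col
# matrix); the chain revisits pixels where the region is one pixel wide.
trace_boundary <- function(fg) {
  h <- nrow(fg); w <- ncol(fg)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- fg
  # clockwise 8-neighbourhood starting east, in (row, col) offsets
  dr <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  start <- which(pad, arr.ind = TRUE)
  start <- start[order(start[, 1L], start[, 2L]), , drop = FALSE][1L, ]
  if (sum(pad) == 1L) return(matrix(start, ncol = 2L))
  chain <- matrix(0L, 16L * sum(pad) + 2L, 2L)
  chain[1L, ] <- start
  n_chain <- 1L
  cur <- start
  # backtrack direction: we entered the top-left-most pixel from the west
  back <- 5L  # index of (0, -1)
  first_move <- NA_integer_
  repeat {
    move <- NA_integer_
    for (k in 1:8) {
      d <- ((back - 1L + k) %% 8L) + 1L  # scan clockwise from backtrack
      nr <- cur[1L] + dr[d]; nc <- cur[2L] + dc[d]
      if (pad[nr, nc]) {
        move <- d
        break
      }
    }
    if (is.na(move)) break  # cannot happen for a connected region, n > 1
    # Jacob's criterion: stop when the first directed edge out of the start
    # pixel repeats (not merely on reaching the start pixel again).
    at_start <- cur[1L] == start[1L] && cur[2L] == start[2L]
    if (at_start && !is.na(first_move) && move == first_move) break
    if (at_start && is.na(first_move)) first_move <- move
    cur <- c(cur[1L] + dr[move], cur[2L] + dc[move])
    n_chain <- n_chain + 1L
    chain[n_chain, ] <- cur
    back <- ((move + 3L) %% 8L) + 1L   # opposite direction
    if (n_chain >= nrow(chain)) break  # safety bound
  }
  chain[seq_len(n_chain), , drop = FALSE]
}

#' Nuclear perimeter
#'
#' Length of the 8-connected chain code around the outer boundary of the
#' nucleus: axial steps count 1, diagonal steps count sqrt(2). Interior
#' holes do not contribute. A single-pixel mask is assigned the unit-square
#' boundary length 4.
#'
#' @param nucleus A [nucleus_image()].
#' @return A list with `perimeter_px` and `perimeter_um`.
#' @export
nucleus_perimeter <- function(nucleus) {
  stopifnot(inherits(nucleus, "nucleus_image"))
  fg <- unclass(nucleus$mask)
  if (sum(fg) == 1L) {
    p <- 4
  } else {
    ch <- trace_boundary(fg)
    steps <- abs(diff(ch))
    p <- sum(ifelse(steps[, 1L] + steps[, 2L] == 2L, sqrt(2), 1))
  }
  list(perimeter_px = p, perimeter_um = p * nucleus$pixel_size)
}

#' Nuclear form factor
#'
#' `method = "circularity"` (default) gives `4 * pi * area_px /
#' perimeter_px^2`, clipped to at most 1 — on a discrete grid the chain-code
#' perimeter underestimates small convex shapes, so the raw ratio can exceed
#' 1. `method = "axis_ratio"` gives minor/major axis of the mask's
#' second-moment ellipse.
#'
#' @param nucleus A [nucleus_image()].
#' @param method `"circularity"` or `"axis_ratio"`.
#' @return A single number in (0, 1].
#' @export
form_factor <- function(nucleus, method = c("circularity", "axis_ratio")) {
  stopifnot(inherits(nucleus, "nucleus_image"))
  method <- match.arg(method)
  if (method == "circularity") {
    a <- nucleus_area(nucleus)$area_px
    p <- nucleus_perimeter(nucleus)$perimeter_px
    min(4 * pi * a / p^2, 1)
  } else {
    xy <- which(unclass(nucleus$mask), arr.ind = TRUE)
    if (nrow(xy) < 2L) return(1)
    ev <- eigen(stats::cov(xy), symmetric = TRUE, only.values = TRUE)$values
    if (ev[1] <= 0) return(1)
    sqrt(max(ev[2], 0) / ev[1])
  }
}

#' First-order gray statistics of the nucleus
#'
#' Mean and sample standard deviation (denominator n - 1) of the gray
#' values over foreground pixels only; background pixels never enter.
#'
#' @param nucleus A [nucleus_image()].
#' @return A list with `mean_gray` and `sd_gray`.
#' @export
gray_stats <- function(nucleus) {
  stopifnot(inherits(nucleus, "nucleus_image"))
  v <- mask_values(nucleus)
  if (length(v) == 1L) {
    warning("single-pixel mask: sd_gray reported as 0")
    return(list(mean_gray = as.numeric(v), sd_gray = 0))
  }
  list(mean_gray = mean(v), sd_gray = stats::sd(v))
}

#' All morphometry features of a nucleus
#'
#' @param nucleus A [nucleus_image()].
#' @param form_factor_method Passed to [form_factor()].
#' @return One-row data.frame: `area_px`, `area_um2`, `perimeter_px`,
#'   `perimeter_um`, `form_factor`, `mean_gray`, `sd_gray`.
#' @export
morphometry <- function(nucleus, form_factor_method = "circularity") {
  a <- nucleus_area(nucleus)
  p <- nucleus_perimeter(nucleus)
  g <- gray_stats(nucleus)
  data.frame(area_px = a$area_px, area_um2 = a$area_um2,
             perimeter_px = p$perimeter_px, perimeter_um = p$perimeter_um,
             form_factor = form_factor(nucleus, form_factor_method),
             mean_gray = g$mean_gray, sd_gray = g$sd_gray)
}
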