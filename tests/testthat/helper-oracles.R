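# Independent oracles, written against the definitions (loops, not the
# package's vectorised code paths), plus small fixture builders.

# discrete disk mask: pixel included iff centre distance <= r
disk_mask <- function(r, margin = 2L) {
  n <- 2L * (r + margin) + 1L
  ctr <- r + margin + 1L
  outer(seq_len(n), seq_len(n),
        function(i, j) sqrt((i - ctr)^2 + (j - ctr)^2) <= r)
}

# solid axis-aligned ellipse mask with semi-axes (a cols, b rows)
ellipse_mask <- function(a, b, margin = 2L) {
  h <- 2L * (b + margin) + 1L
  w <- 2L * (a + margin) + 1L
  cr <- b + margin + 1L
  cc <- a + margin + 1L
  outer(seq_len(h), seq_len(w),
        function(i, j) ((i - cr) / b)^2 + ((j - cc) / a)^2 <= 1)
}

# random seeded single-component blob: union of disks around a random walk
blob_mask <- function(seed, n = 20L, steps = 12L, r = 2.5) {
  set.seed(seed)
  pos <- matrix(round(n / 2), 1, 2)
  for (s in seq_len(steps)) {
    cand <- pmin(pmax(pos[nrow(pos), ] + sample(-2:2, 2, TRUE), 4), n - 3)
    pos <- rbind(pos, cand)
  }
  m <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(pos))) {
    d <- outer(seq_len(n), seq_len(n),
               function(i, j) sqrt((i - pos[k, 1])^2 + (j - pos[k, 2])^2))
    m <- m | (d <= r)
  }
  m
}

random_nucleus <- function(seed, n = 8L, levels = 256L, mask = NULL) {
  set.seed(seed)
  g <- matrix(sample(0:(levels - 1L), n * n, replace = TRUE), n, n)
  if (levels < 256L) g <- g * (256L %/% levels)  # spread over 0..255
  if (is.null(mask)) mask <- matrix(TRUE, n, n)
  nucleus_image(gray_image(g), mask)
}

# ---- GLCM oracle: literal pair enumeration ---------------------------------

oracle_glcm_counts <- function(gray, mask, distance = 1L,
                               directions = c("0", "45", "90", "135"),
                               levels = 256L) {
  offs <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
               `135` = c(-1L, -1L))[directions]
  q <- gray %/% (256L %/% levels)
  counts <- matrix(0, levels, levels)
  for (r in seq_len(nrow(gray))) for (c in seq_len(ncol(gray))) {
    if (!mask[r, c]) next
    for (o in offs) {
      r2 <- r + o[1L] * distance; c2 <- c + o[2L] * distance
      if (r2 < 1 || r2 > nrow(gray) || c2 < 1 || c2 > ncol(gray)) next
      if (!mask[r2, c2]) next
      i <- q[r, c] + 1L; j <- q[r2, c2] + 1L
      counts[i, j] <- counts[i, j] + 1
      counts[j, i] <- counts[j, i] + 1
    }
  }
  counts
}

oracle_glcm_features <- function(counts) {
  p <- counts / sum(counts)
  G <- nrow(p)
  ent <- iner <- lh <- en <- dm <- mux <- muy <- 0
  for (i in seq_len(G)) for (j in seq_len(G)) {
    pij <- p[i, j]
    if (pij > 0) ent <- ent - pij * log2(pij)
    iner <- iner + (i - j)^2 * pij
    lh <- lh + pij / (1 + (i - j)^2)
    en <- en + pij^2
    dm <- dm + abs(i - j) * pij
    mux <- mux + (i - 1) * pij
    muy <- muy + (j - 1) * pij
  }
  cp <- 0
  for (i in seq_len(G)) for (j in seq_len(G))
    cp <- cp + ((i - 1) + (j - 1) - mux - muy)^4 * p[i, j]
  list(entropy = ent, inertia = iner, local_homogeneity = lh,
       energy_normalized = en, energy_raw = sum(counts^2), contrast = iner,
       diagonal_moment = dm, cluster_prominence = cp)
}

# ---- blanket oracle: literal envelope recursion -----------------------------

oracle_blanket_volumes <- function(gray, mask, eps_max = 5L) {
  h <- nrow(gray); w <- ncol(gray)
  u <- matrix(as.numeric(gray), h, w); l <- u
  vols <- numeric(eps_max)
  for (e in seq_len(eps_max)) {
    un <- u; ln <- l
    for (r in seq_len(h)) for (c in seq_len(w)) {
      if (!mask[r, c]) next
      hi <- u[r, c] + 1; lo <- l[r, c] - 1
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- c + dc
        if (r2 < 1 || r2 > h || c2 < 1 || c2 > w) next
        if (!mask[r2, c2]) next
        hi <- max(hi, u[r2, c2])
        lo <- min(lo, l[r2, c2])
      }
      un[r, c] <- hi; ln[r, c] <- lo
    }
    u <- un; l <- ln
    vols[e] <- sum((u - l)[mask])
  }
  vols
}

# ---- repeated-measures ANOVA oracle: literal SS decomposition ---------------

oracle_rm_anova_f <- function(values) {
  n <- nrow(values); k <- ncol(values)
  grand <- mean(values)
  ss_class <- n * sum((colMeans(values) - grand)^2)
  ss_subj <- k * sum((rowMeans(values) - grand)^2)
  ss_tot <- sum((values - grand)^2)
  ss_err <- ss_tot - ss_class - ss_subj
  f <- (ss_class / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  list(f = f, df1 = k - 1, df2 = (k - 1) * (n - 1),
       p = stats::pf(f, k - 1, (k - 1) * (n - 1), lower.tail = FALSE))
}

# perimeter oracle: EBImage oriented contour (independent implementation)
oracle_perimeter <- function(mask) {
  oc <- EBImage::ocontour(ifelse(mask, 1L, 0L))[[1]]
  if (nrow(oc) == 1L) return(4)
  d <- abs(diff(rbind(oc, oc[1L, , drop = FALSE])))
  sum(ifelse(rowSums(d) == 2L, sqrt(2), 1))
}

# fBm surface -> full-frame gray nucleus, the package's image convention
fbm_nucleus <- function(n, hurst, seed, mean_gray = 128, sd_gray = 40) {
  f <- fbm_surface(n, hurst, seed)
  g <- gray_image(round(pmin(pmax(mean_gray + sd_gray * f, 0), 255)))
  nucleus_image(g, matrix(TRUE, n, n))
}
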