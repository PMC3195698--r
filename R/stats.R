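# The three tests used to compare cell classes, and the four-outcome
# significance-pattern rule for atypical immature myeloid precursors.

test_result <- function(statistic, df, p_value, test_kind) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), test_kind = test_kind),
            class = "karyotex_test")
}

#' @export
print.karyotex_test <- function(x, ...) {
  lab <- switch(x$test_kind, paired_t = "t (paired)",
                independent_t = "t (pooled)", rm_anova = "F (within-subject)")
  cat(lab, " = ", format(x$statistic, digits = 5),
      ", df = ", paste(round(x$df, 2), collapse = ", "),
      ", p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Paired t-test between two matched feature vectors
#'
#' Two-sided t-test on the within-patient differences; pairs with a missing
#' side are dropped.
#'
#' @param x,y Numeric vectors matched by patient, equal length.
#' @return A `karyotex_test` with statistic, df = n - 1 and p-value.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must be matched (equal length)")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x - y) == 0)
    stop("degenerate test: zero variance of the paired differences")
  tt <- stats::t.test(x, y, paired = TRUE)
  test_result(tt$statistic, tt$parameter, tt$p.value, "paired_t")
}

#' Pooled-variance (Student) t-test between two independent groups
#'
#' @param x,y Numeric vectors (missing values dropped), each of length >= 2.
#' @return A `karyotex_test` with statistic, df = n_x + n_y - 2 and p-value.
#' @export
independent_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 values per group")
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
         (length(x) + length(y) - 2)
  if (sp2 == 0) stop("degenerate test: zero pooled variance")
  tt <- stats::t.test(x, y, var.equal = TRUE)
  test_result(tt$statistic, tt$parameter, tt$p.value, "independent_t")
}

#' Welch t-test (unequal variances)
#'
#' Available as an alternative to the default pooled-variance test.
#'
#' @param x,y Numeric vectors (missing values dropped).
#' @return A `karyotex_test`.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  tt <- stats::t.test(x, y, var.equal = FALSE)
  test_result(tt$statistic, tt$parameter, tt$p.value, "independent_t")
}

#' One-way repeated-measures analysis of variance across cell classes
#'
#' Within-subject ANOVA on a patients x classes matrix of feature values:
#' the subject (patient) effect is removed and the class effect is tested
#' against the residual, `F = MS_class / MS_error` with
#' `df = (k - 1, (k - 1)(n - 1))` for n complete patients and k classes.
#' No sphericity correction is applied by default; the Greenhouse-Geisser
#' epsilon-corrected p-value is returned alongside when
#' `greenhouse_geisser = TRUE`. Patients with any missing class are dropped
#' with a warning.
#'
#' @param values Numeric matrix, rows = patients, columns = cell classes.
#' @param greenhouse_geisser If TRUE, also compute the epsilon-corrected
#'   p-value (as attribute `p_gg`).
#' @return A `karyotex_test` with the F statistic, df pair and p-value.
#' @export
rm_anova <- function(values, greenhouse_geisser = FALSE) {
  values <- as.matrix(values)
  complete <- stats::complete.cases(values)
  if (any(!complete)) {
    warning(sum(!complete), " patient(s) with incomplete classes dropped")
    values <- values[complete, , drop = FALSE]
  }
  n <- nrow(values); k <- ncol(values)
  if (n < 3L) stop("insufficient data: need >= 3 complete patients")
  df <- data.frame(
    value = as.vector(values),
    patient = factor(rep(seq_len(n), times = k)),
    class = factor(rep(seq_len(k), each = n))
  )
  fit <- stats::aov(value ~ class + patient, data = df)
  tab <- summary(fit)[[1]]
  rownames(tab) <- trimws(rownames(tab))
  ss_class <- tab["class", "Sum Sq"]
  ss_error <- tab["Residuals", "Sum Sq"]
  df1 <- tab["class", "Df"]
  df2 <- tab["Residuals", "Df"]
  ss_total <- sum(tab[, "Sum Sq"])
  if (ss_class <= 1e-12 * ss_total || ss_total == 0) {
    f <- 0
  } else {
    if (ss_error <= 1e-12 * ss_total)
      stop("degenerate test: zero within-subject error variance")
    f <- (ss_class / df1) / (ss_error / df2)
  }
  res <- test_result(f, c(df1, df2), stats::pf(f, df1, df2, lower.tail = FALSE),
                     "rm_anova")
  if (greenhouse_geisser) {
    # epsilon from the double-centred covariance of the class columns
    s <- stats::cov(values)
    sc <- sweep(sweep(s, 1, rowMeans(s)), 2, colMeans(s)) + mean(s)
    eps <- sum(diag(sc))^2 / ((k - 1) * sum(sc^2))
    eps <- min(max(eps, 1 / (k - 1)), 1)
    attr(res, "p_gg") <- stats::pf(f, eps * df1, eps * df2, lower.tail = FALSE)
    attr(res, "gg_epsilon") <- eps
  }
  res
}

#' Classify an atypical-precursor feature from its significance pattern
#'
#' Applies the four-outcome rule to a feature's three p-values: the
#' blast-vs-atypical paired test (`p_ba`), the atypical-vs-promyelocyte
#' paired test (`p_ap`) and the global repeated-measures test
#' (`p_global`). With significance at `p <= alpha`:
#'
#' * global test not significant, or neither paired test significant ->
#'   `"not_defined"`;
#' * both paired tests significant -> `"intermediate"` (the atypical cells
#'   differ from both neighbours in maturation);
#' * only blast-vs-atypical significant -> `"close_to_promyelocytes"`;
#' * only atypical-vs-promyelocyte significant -> `"close_to_blasts"`.
#'
#' The rule is total and deterministic: every p-triple in \[0, 1\]^3 maps
#' to exactly one label.
#'
#' @param p_ba,p_ap,p_global p-values in \[0, 1\] (vectorised).
#' @param alpha Significance level, default 0.05; `p = alpha` counts as
#'   significant.
#' @return Character vector of labels.
#' @export
classify_atypical <- function(p_ba, p_ap, p_global, alpha = 0.05) {
  p <- cbind(p_ba, p_ap, p_global)
  if (anyNA(p) || min(p) < 0 || max(p) > 1)
    stop("p-values must lie in [0, 1]")
  sig_ba <- p[, 1] <= alpha
  sig_ap <- p[, 2] <= alpha
  sig_g  <- p[, 3] <= alpha
  unname(ifelse(!sig_g | (!sig_ba & !sig_ap), "not_defined",
    ifelse(sig_ba & sig_ap, "intermediate",
      ifelse(sig_ba, "close_to_promyelocytes", "close_to_blasts"))))
}
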