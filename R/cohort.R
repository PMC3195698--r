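# Patient-level aggregation and the class-comparison reports.

feature_columns <- function(df) {
  meta <- c("patient_id", "cell_class", "cell_index", "cohort", "n_nuclei")
  setdiff(names(df)[vapply(df, is.numeric, logical(1))], meta)
}

#' Aggregate a per-nucleus feature table to patient level
#'
#' Computes, for every (patient, cell class) group, the arithmetic mean of
#' each numeric feature column. The patient-level mean is the statistical
#' unit of all downstream tests. Groups with fewer than `min_nuclei` nuclei
#' are excluded with a warning (or a hard error if `strict = TRUE`).
#'
#' @param per_nucleus Data frame with columns `patient_id`, `cell_class`
#'   and one numeric column per feature (e.g. from [analyze_nuclei()] or a
#'   CSV path, which is read first).
#' @param min_nuclei Minimum nuclei per (patient, class) group; default 30,
#'   the usual karyometry sampling floor.
#' @param strict If TRUE, below-minimum groups are an error.
#' @param cohort Optional cohort label ("normal" or "MDS") stored on the
#'   result.
#' @return A data.frame of class `cohort_table`: one row per (patient_id,
#'   cell_class), columns `n_nuclei` plus the feature means.
#' @export
aggregate_cohort <- function(per_nucleus, min_nuclei = 30L, strict = FALSE,
                             cohort = NA_character_) {
  if (is.character(per_nucleus) && length(per_nucleus) == 1L)
    per_nucleus <- utils::read.csv(per_nucleus, stringsAsFactors = FALSE)
  need <- c("patient_id", "cell_class")
  if (!all(need %in% names(per_nucleus)))
    stop("per-nucleus table must have columns: ", paste(need, collapse = ", "))
  feats <- feature_columns(per_nucleus)
  if (length(feats) == 0L) stop("no numeric feature columns found")
  key <- interaction(per_nucleus$patient_id, per_nucleus$cell_class,
                     drop = TRUE, sep = "\r")
  counts <- as.vector(table(key))
  groups <- do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE))
  keep <- counts >= min_nuclei
  if (any(!keep)) {
    msg <- paste0(groups[!keep, 1L], "/", groups[!keep, 2L], " (n=",
                  counts[!keep], ")", collapse = ", ")
    if (strict)
      stop("groups below the minimum of ", min_nuclei, " nuclei: ", msg)
    warning("excluding groups below the minimum of ", min_nuclei,
            " nuclei: ", msg)
  }
  means <- do.call(rbind, lapply(which(keep), function(g) {
    rows <- key == levels(key)[g]
    colMeans(per_nucleus[rows, feats, drop = FALSE])
  }))
  out <- data.frame(patient_id = groups[keep, 1L],
                    cell_class = groups[keep, 2L],
                    n_nuclei = counts[keep],
                    means, stringsAsFactors = FALSE)
  attr(out, "cohort") <- cohort
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Construct a cohort table from ready-made patient-level values
#'
#' For simulated or externally aggregated data: one row per (patient,
#' class) with feature means already computed.
#'
#' @param df Data frame with `patient_id`, `cell_class` and feature columns.
#' @param cohort Optional cohort label.
#' @return A `cohort_table`.
#' @export
cohort_table <- function(df, cohort = NA_character_) {
  need <- c("patient_id", "cell_class")
  if (!all(need %in% names(df)))
    stop("cohort table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df[, need]))
    stop("each patient may contribute at most one row per cell class")
  attr(df, "cohort") <- cohort
  class(df) <- unique(c("cohort_table", class(df)))
  df
}

# patients x classes matrix of one feature, NA where a class is missing
class_matrix <- function(tab, feature, classes) {
  patients <- unique(tab$patient_id)
  m <- matrix(NA_real_, length(patients), length(classes),
              dimnames = list(patients, classes))
  for (cl in classes) {
    rows <- tab$cell_class == cl
    m[match(tab$patient_id[rows], patients), cl] <- tab[[feature]][rows]
  }
  m
}

#' Compare two cohorts feature by feature
#'
#' For each feature: the within-cohort blast-vs-promyelocyte paired t-test
#' in the first cohort, and independent (pooled) t-tests between the
#' cohorts for blasts and for promyelocytes. Mirrors the usual layout of
#' normal-vs-MDS karyometry tables. Features whose tests cannot run
#' (missing classes, degenerate variance) are reported with NA and a
#' warning.
#'
#' @param normal,mds `cohort_table`s sharing feature columns.
#' @return Data frame: one row per feature with group means and the three
#'   p-values (`p_paired_normal`, `p_blasts`, `p_promyelocytes`).
#' @export
compare_cohorts <- function(normal, mds) {
  feats <- intersect(feature_columns(normal), feature_columns(mds))
  if (length(feats) == 0L)
    return(data.frame(feature = character(0)))
  safe_p <- function(expr) tryCatch(expr$p_value, error = function(e) {
    warning(conditionMessage(e)); NA_real_
  })
  rows <- lapply(feats, function(f) {
    nb <- class_matrix(normal, f, c("blast", "promyelocyte"))
    mb <- class_matrix(mds, f, c("blast", "promyelocyte"))
    data.frame(
      feature = f,
      mean_normal_blast = mean(nb[, "blast"], na.rm = TRUE),
      mean_normal_pro = mean(nb[, "promyelocyte"], na.rm = TRUE),
      mean_mds_blast = mean(mb[, "blast"], na.rm = TRUE),
      mean_mds_pro = mean(mb[, "promyelocyte"], na.rm = TRUE),
      p_paired_normal = safe_p(paired_t(nb[, "blast"], nb[, "promyelocyte"])),
      p_blasts = safe_p(independent_t(nb[, "blast"], mb[, "blast"])),
      p_promyelocytes = safe_p(independent_t(nb[, "promyelocyte"],
                                             mb[, "promyelocyte"]))
    )
  })
  do.call(rbind, rows)
}

#' Classify every feature's atypical-precursor pattern in an MDS cohort
#'
#' For each feature: the three class means, the blast-vs-atypical and
#' atypical-vs-promyelocyte paired t-tests, the global repeated-measures
#' ANOVA over the three classes, and the four-outcome label from
#' [classify_atypical()].
#'
#' @param mds A `cohort_table` containing the classes `blast`, `atypical`
#'   and `promyelocyte`.
#' @param alpha Significance level for the labels (default 0.05).
#' @return A data.frame of class `atypical_report`: one row per feature
#'   with means, p-values and label; label counts are available via
#'   [summary()].
#' @export
classify_all <- function(mds, alpha = 0.05) {
  classes <- c("blast", "atypical", "promyelocyte")
  feats <- feature_columns(mds)
  rows <- lapply(feats, function(f) {
    m <- class_matrix(mds, f, classes)
    complete <- stats::complete.cases(m)
    if (sum(complete) < 3L)
      stop("insufficient data: need >= 3 patients with all three classes")
    p_ba <- paired_t(m[, "blast"], m[, "atypical"])$p_value
    p_ap <- paired_t(m[, "atypical"], m[, "promyelocyte"])$p_value
    p_global <- rm_anova(m)$p_value
    data.frame(
      feature = f,
      mean_blast = mean(m[complete, "blast"]),
      mean_atypical = mean(m[complete, "atypical"]),
      mean_promyelocyte = mean(m[complete, "promyelocyte"]),
      p_blast_atypical = p_ba,
      p_atypical_promyelocyte = p_ap,
      p_global = p_global,
      label = classify_atypical(p_ba, p_ap, p_global, alpha)
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  class(out) <- c("atypical_report", "data.frame")
  out
}

#' @export
print.atypical_report <- function(x, digits = 4, ...) {
  cat("Atypical immature myeloid precursor classification (alpha = ",
      attr(x, "alpha"), ")\n\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  cat("\n")
  print(label_counts(x))
  invisible(x)
}

#' Label counts of an atypical-precursor report
#'
#' @param report An `atypical_report` (or any data.frame with a `label`
#'   column).
#' @return Named integer vector over the four labels.
#' @export
label_counts <- function(report) {
  lev <- c("intermediate", "close_to_promyelocytes", "close_to_blasts",
           "not_defined")
  table(factor(report$label, levels = lev))
}

#' @export
summary.atypical_report <- function(object, ...) {
  counts <- label_counts(object)
  structure(list(counts = counts, alpha = attr(object, "alpha"),
                 n_features = nrow(object)),
            class = "summary.atypical_report")
}

#' @export
print.summary.atypical_report <- function(x, ...) {
  cat("Classification of", x$n_features, "nuclear features (alpha =",
      x$alpha, "):\n")
  for (l in names(x$counts))
    cat(sprintf("  %-24s %d\n", l, x$counts[[l]]))
  invisible(x)
}

#' Published worked example: p-values for 14 nuclear features in MDS
#'
#' The three p-values (blast vs atypical paired test, atypical vs
#' promyelocyte paired test, global repeated-measures test) reported for
#' each of 14 nuclear morphometric and texture features in a reference
#' cohort of 30 MDS patients, together with the published classification
#' of each feature. Upper-bound entries such as "<0.0001" are recorded as
#' the bound itself, which leaves their significance at any usual alpha
#' unchanged.
#'
#' @return Data frame with columns `feature`, `p_blast_atypical`,
#'   `p_atypical_promyelocyte`, `p_global`, `published_label`.
#' @export
example_pvalues <- function() {
  path <- system.file("extdata", "mds_precursor_pvalues.csv",
                      package = "karyotex", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
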