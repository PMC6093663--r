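#' Cross-tabulate detector outcome against clinician labels
#'
#' @param si_flags Logical vector: study classified S&I (at a given window
#'   offset, or any offset).
#' @param do_labels Character or logical vector of clinician
#'   detrusor-overactivity labels; `"yes"`/`"no"` or `TRUE`/`FALSE`.
#'   `"unknown"` labels are a data error.
#' @param study_ids Optional ids used in error messages.
#' @return 2x2 integer matrix, rows `S&I`/`not S&I`, columns `DO`/`not DO`.
#' @export
confusion_counts <- function(si_flags, do_labels, study_ids = NULL) {
  if (!length(si_flags)) stop("empty cohort", call. = FALSE)
  if (length(si_flags) != length(do_labels))
    stop("si_flags and do_labels lengths differ", call. = FALSE)
  if (is.character(do_labels)) {
    unknown <- !do_labels %in% c("yes", "no")
    if (any(unknown)) {
      ids <- if (is.null(study_ids)) which(unknown) else study_ids[unknown]
      stop("unknown DO label for studies: ", paste(ids, collapse = ", "),
           call. = FALSE)
    }
    do_labels <- do_labels == "yes"
  }
  matrix(c(sum(si_flags & do_labels), sum(!si_flags & do_labels),
           sum(si_flags & !do_labels), sum(!si_flags & !do_labels)),
         nrow = 2, dimnames = list(c("S&I", "not S&I"), c("DO", "not DO")))
}

#' Sensitivity and specificity from a 2x2 table
#'
#' Sensitivity = S&I-and-DO over all DO; specificity = not-S&I-and-not-DO
#' over all not-DO (rows: detector, columns: clinician).
#'
#' @param table 2x2 numeric matrix as from [confusion_counts()].
#' @return Named numeric vector `c(sensitivity, specificity)`.
#' @export
sensitivity_specificity <- function(table) {
  if (any(colSums(table) == 0))
    stop("a label column is empty; sensitivity/specificity undefined",
         call. = FALSE)
  c(sensitivity = table[1, 1] / sum(table[, 1]),
    specificity = table[2, 2] / sum(table[, 2]))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Computed from first principles: with the margins fixed, the probability of
#' each possible table is hypergeometric (evaluated with log-factorials), and
#' the two-sided p-value sums the probabilities of all tables whose point
#' probability does not exceed the observed one (with a relative tie
#' tolerance of 1e-12, the usual point-probability two-sided convention).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value in \[0, 1\].
#' @export
fisher_exact_two_sided <- function(table) {
  x <- as.vector(table)
  if (any(x < 0) || any(abs(x - round(x)) > 1e-9))
    stop("cells must be non-negative integers", call. = FALSE)
  x <- round(x)
  a <- x[1]; c_ <- x[2]; b <- x[3]; d <- x[4]
  n <- a + b + c_ + d
  if (n == 0) stop("table total must be positive", call. = FALSE)
  r1 <- a + b           # first row margin
  k1 <- a + c_          # first column margin

  lo <- max(0L, r1 + k1 - n)
  hi <- min(r1, k1)
  support <- lo:hi
  # log P(A = i | margins) via log-factorials, over the whole support
  logp <- lfactorial(r1) + lfactorial(n - r1) + lfactorial(k1) +
    lfactorial(n - k1) - lfactorial(n) - lfactorial(support) -
    lfactorial(r1 - support) - lfactorial(k1 - support) -
    lfactorial(n - r1 - k1 + support)
  p_obs <- logp[support == a]
  min(1, sum(exp(logp[logp <= p_obs + log(1 + 1e-12)])))
}

#' Pooled-variance two-sample t-test p-value
#'
#' Two-tailed, equal-variance t-test with `n_a + n_b - 2` degrees of freedom.
#' Degenerate inputs are handled explicitly: identical constant groups give
#' p = 1; zero pooled variance with unequal means gives p = 0.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return Two-tailed p-value.
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0)
    return(if (mean(a) == mean(b)) 1 else 0)
  stats::t.test(a, b, var.equal = TRUE)$p.value
}

#' Mean and standard error of the slowest S&I frequency and amplitude
#'
#' Summarizes only the S&I studies of a result list: arithmetic mean and
#' standard error (sd/sqrt(n)) of the slowest S&I frequency (cycles/min) and
#' of the sine-model peak-to-peak amplitude (cm-H2O). With a single S&I
#' study the standard error is reported as 0 with `single_observation =
#' TRUE`; with none, an empty summary is returned.
#'
#' @param results List of `larc_result` objects.
#' @return A list: `n_si`, `frequency` (`mean`, `se`), `amplitude`
#'   (`mean`, `se`), `single_observation`.
#' @export
summarize_subgroup <- function(results) {
  si <- Filter(function(r) r$category == "significant_and_independent",
               results)
  if (!length(si))
    return(list(n_si = 0L, frequency = NULL, amplitude = NULL,
                single_observation = FALSE))
  f <- vapply(si, `[[`, numeric(1), "slowest_si_frequency")
  a <- vapply(si, function(r) r$slowest_si_model$peak_to_peak, numeric(1))
  se <- function(x) if (length(x) < 2) 0 else stats::sd(x) / sqrt(length(x))
  list(n_si = length(si),
       frequency = list(mean = mean(f), se = se(f)),
       amplitude = list(mean = mean(a), se = se(a)),
       single_observation = length(si) == 1L)
}

#' Full cohort summary for one analysis window
#'
#' @param si_flags Logical S&I flags per study.
#' @param do_labels Clinician DO labels per study.
#' @param results Optional list of `larc_result` objects for the subgroup
#'   descriptives.
#' @param roi_offset_s Window offset label (seconds, or `"any"`).
#' @param study_ids Optional study ids for error messages.
#' @return A list of class `cohort_summary`: `roi_offset_s`, `counts`,
#'   `sensitivity`, `specificity`, `fisher_p`, `subgroup_stats`.
#' @export
cohort_summary <- function(si_flags, do_labels, results = NULL,
                           roi_offset_s = "any", study_ids = NULL) {
  counts <- confusion_counts(si_flags, do_labels, study_ids)
  ss <- sensitivity_specificity(counts)
  structure(list(
    roi_offset_s = roi_offset_s, counts = counts,
    sensitivity = unname(ss["sensitivity"]),
    specificity = unname(ss["specificity"]),
    fisher_p = fisher_exact_two_sided(counts),
    subgroup_stats = if (is.null(results)) NULL else summarize_subgroup(results)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> window offset %s\n", x$roi_offset_s))
  print(x$counts)
  cat(sprintf("  sensitivity %.4f  specificity %.4f  Fisher p %.4g\n",
              x$sensitivity, x$specificity, x$fisher_p))
  s <- x$subgroup_stats
  if (!is.null(s) && s$n_si > 0)
    cat(sprintf(
      "  slowest S&I rhythm: %.2f +/- %.2f cycles/min, %.2f +/- %.2f cm-H2O (n=%d)\n",
      s$frequency$mean, s$frequency$se, s$amplitude$mean, s$amplitude$se,
      s$n_si))
  invisible(x)
}
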