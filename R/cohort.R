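#' Stratify patients by DLL3-positive CTC fraction
#'
#' Assigns each patient to the DLL3-Low or DLL3-Pos stratum by the fraction
#' of their CTCs scoring DLL3-positive, with an additional DLL3-High flag
#' for very high fractions. A fraction exactly at the cutoff is assigned
#' Pos (the published wording "fewer than 25\%" vs "more than 25\%" leaves
#' the boundary open; the >= convention is fixed here and configurable).
#'
#' @param fraction numeric vector of DLL3-positive CTC fractions in percent
#'   (0--100). \code{NA} (patient with no CTCs) propagates to \code{NA}.
#' @param cutoff Low/Pos boundary in percent, default 25.
#' @param high_cutoff High flag boundary (strict \code{>}), default 75.
#' @return data frame with \code{fraction_pct}, \code{stratum} (factor
#'   \code{Low}/\code{Pos}) and logical \code{high}.
#' @export
stratify_patient <- function(fraction, cutoff = 25, high_cutoff = 75) {
  ok <- is.na(fraction) | (fraction >= 0 & fraction <= 100)
  if (!all(ok))
    stop("DLL3 fraction must lie in [0, 100] percent")
  stratum <- ifelse(fraction >= cutoff, "Pos", "Low")
  data.frame(
    fraction_pct = fraction,
    stratum = factor(stratum, levels = c("Low", "Pos")),
    high = !is.na(fraction) & fraction > high_cutoff
  )
}

#' Build per-patient summaries from enumeration and clinical tables
#'
#' Joins the per-patient CTC enumeration with clinical response labels and
#' stratifies by DLL3 fraction. Patients with zero CTCs have an undefined
#' DLL3 fraction and are excluded from stratification with a warning (the
#' logged reason mirrors exclusion for inadequate baseline CTC assessment);
#' they are retained in the table with \code{NA} stratum.
#'
#' @param enumeration a \code{\link{enumerate_ctcs}} result (or any data
#'   frame with \code{patient_id}, \code{ctc_per_ref}, \code{ctc_dll3_per_ref},
#'   \code{dll3_fraction_pct}).
#' @param clinical data frame with \code{patient_id} and \code{response}
#'   (one of \code{"PR"}, \code{"SD"}, \code{"PD"}).
#' @param cutoff,high_cutoff passed to \code{\link{stratify_patient}}.
#' @return data frame of class \code{patient_summary}: one row per patient
#'   with counts, fraction, stratum, high flag, response and logical
#'   \code{benefit} (PR or SD).
#' @export
patient_summaries <- function(enumeration, clinical, cutoff = 25,
                              high_cutoff = 75) {
  m <- merge(as.data.frame(enumeration), clinical, by = "patient_id",
             all.x = TRUE)
  s <- stratify_patient(m$dll3_fraction_pct, cutoff, high_cutoff)
  m$stratum <- s$stratum
  m$high <- s$high
  m$response <- factor(as.character(m$response), levels = c("PR", "SD", "PD"))
  m$benefit <- m$response %in% c("PR", "SD")
  if (anyNA(m$dll3_fraction_pct))
    warning(sum(is.na(m$dll3_fraction_pct)),
            " patient(s) with no CTCs excluded from stratification ",
            "(DLL3 fraction undefined)")
  class(m) <- c("patient_summary", "data.frame")
  m
}

#' Cross-tabulate DLL3 stratum against clinical benefit
#'
#' Builds the 2x2 table of DLL3-Pos/Low stratum versus clinical benefit
#' (benefit = PR or SD): TP = Pos with benefit, FN = Low with benefit,
#' FP = Pos without benefit, TN = Low without benefit. Patients with a
#' missing response or stratum are excluded with a warning that reports
#' how many were dropped.
#'
#' @param summaries a \code{\link{patient_summaries}} result.
#' @return object of class \code{contingency_table}: list with integer
#'   \code{TP}, \code{FN}, \code{FP}, \code{TN} and \code{n_excluded}.
#' @export
build_contingency <- function(summaries) {
  usable <- !is.na(summaries$response) & !is.na(summaries$stratum)
  n_excl <- sum(!usable)
  if (n_excl > 0)
    warning(n_excl, " patient(s) excluded from contingency table ",
            "(missing response or stratum)")
  s <- summaries[usable, , drop = FALSE]
  pos <- s$stratum == "Pos"
  structure(list(
    TP = sum(pos & s$benefit), FN = sum(!pos & s$benefit),
    FP = sum(pos & !s$benefit), TN = sum(!pos & !s$benefit),
    n_excluded = n_excl
  ), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2, byrow = TRUE,
              dimnames = list(c("benefit", "no benefit"),
                              c("DLL3-Pos", "DLL3-Low")))
  print(m)
  if (x$n_excluded > 0) cat(x$n_excluded, "patient(s) excluded\n")
  invisible(x)
}

#' Exact (Clopper--Pearson) binomial confidence interval
#'
#' Computes the exact interval for a binomial proportion from Beta
#' quantiles: lower = qbeta(alpha/2; x, n-x+1), upper =
#' qbeta(1-alpha/2; x+1, n-x). When the point estimate is exactly 0 or 1
#' the one-sided (1-alpha/2) bound is reported on that side:
#' for x = n the lower bound is (alpha/2)^(1/n) with upper 1; for x = 0
#' the upper bound is 1 - (alpha/2)^(1/n) with lower 0.
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param alpha total error rate, default 0.05.
#' @return list: \code{estimate}, \code{lower}, \code{upper} (proportions
#'   in [0,1]) and \code{one_sided} (logical).
#' @export
clopper_pearson <- function(x, n, alpha = 0.05) {
  stopifnot(n >= 1, x >= 0, x <= n, alpha > 0, alpha < 1)
  est <- x / n
  if (x == n) {
    list(estimate = est, lower = (alpha / 2)^(1 / n), upper = 1,
         one_sided = TRUE)
  } else if (x == 0) {
    list(estimate = est, lower = 0, upper = 1 - (alpha / 2)^(1 / n),
         one_sided = TRUE)
  } else {
    list(estimate = est,
         lower = stats::qbeta(alpha / 2, x, n - x + 1),
         upper = stats::qbeta(1 - alpha / 2, x + 1, n - x),
         one_sided = FALSE)
  }
}

#' Predictive performance of DLL3 stratification
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP) and positive predictive
#' value TP/(TP+FP) of calling DLL3-Pos for clinical benefit, each with an
#' exact \code{\link{clopper_pearson}} interval: two-sided (1-alpha) when
#' the point estimate is interior, one-sided (1-alpha/2) at 0\% or 100\%.
#' Metrics with a zero denominator are reported as undefined (\code{NA}),
#' never as 0. Values are kept at full precision; the print method rounds
#' to the nearest integer percent for display.
#'
#' @param table a \code{\link{build_contingency}} result.
#' @param alpha total error rate, default 0.05.
#' @return object of class \code{predictive_metrics}: list with one entry
#'   per metric, each holding \code{estimate_pct}, \code{lower_pct},
#'   \code{upper_pct}, \code{one_sided}, \code{x}, \code{n}.
#' @export
predictive_metrics <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "contingency_table"))
  one <- function(x, n) {
    if (n == 0)
      return(list(estimate_pct = NA_real_, lower_pct = NA_real_,
                  upper_pct = NA_real_, one_sided = NA, x = x, n = n))
    ci <- clopper_pearson(x, n, alpha)
    list(estimate_pct = 100 * ci$estimate, lower_pct = 100 * ci$lower,
         upper_pct = 100 * ci$upper, one_sided = ci$one_sided, x = x, n = n)
  }
  structure(list(
    sensitivity = one(table$TP, table$TP + table$FN),
    specificity = one(table$TN, table$TN + table$FP),
    ppv = one(table$TP, table$TP + table$FP),
    alpha = alpha
  ), class = "predictive_metrics")
}

#' @export
print.predictive_metrics <- function(x, ...) {
  fmt <- function(m, name) {
    if (is.na(m$estimate_pct)) {
      cat(sprintf("  %-12s undefined (denominator 0)\n", name))
    } else if (isTRUE(m$one_sided)) {
      side <- if (m$x == m$n) "lower" else "upper"
      bound <- if (side == "lower") m$lower_pct else m$upper_pct
      cat(sprintf("  %-12s %d%% (one-sided %.1f%% CI %s bound: %d%%)\n",
                  name, round(m$estimate_pct), 100 * (1 - x$alpha / 2),
                  side, round(bound)))
    } else {
      cat(sprintf("  %-12s %d%% (%d%% CI: %d%%-%d%%)\n", name,
                  round(m$estimate_pct), round(100 * (1 - x$alpha)),
                  round(m$lower_pct), round(m$upper_pct)))
    }
  }
  cat("Predictive metrics (exact binomial intervals)\n")
  fmt(x$sensitivity, "sensitivity")
  fmt(x$specificity, "specificity")
  fmt(x$ppv, "PPV")
  invisible(x)
}

#' Pooled CTC and DLL3-positive counts per response group
#'
#' Sums per-patient CTC counts within each response group and reports the
#' pooled DLL3-positive percentage (100 x pooled positive / pooled total,
#' rounded to integer for the report column; full precision retained in
#' \code{pct}). The pooled percent equals the count-weighted mean of the
#' per-patient fractions. Raw (unscaled) counts are pooled when available,
#' matching how per-group totals are reported.
#'
#' @param summaries a \code{\link{patient_summaries}} result (or data frame
#'   with \code{response} and count columns).
#' @param total_col,positive_col names of the per-patient total and
#'   DLL3-positive CTC count columns; default the raw counts.
#' @return data frame: response, n_patients, ctc_total, ctc_dll3_positive,
#'   \code{pct} (full precision), \code{pct_rounded}.
#' @export
group_marker_totals <- function(summaries, total_col = "ctc_raw",
                                positive_col = "ctc_dll3_raw") {
  groups <- levels(factor(summaries$response))
  out <- do.call(rbind, lapply(groups, function(g) {
    s <- summaries[!is.na(summaries$response) & summaries$response == g, ,
                   drop = FALSE]
    tot <- sum(s[[total_col]])
    pos <- sum(s[[positive_col]])
    data.frame(response = g, n_patients = nrow(s), ctc_total = tot,
               ctc_dll3_positive = pos,
               pct = if (tot > 0) 100 * pos / tot else 0,
               stringsAsFactors = FALSE)
  }))
  out$pct_rounded <- round(out$pct)
  rownames(out) <- NULL
  out
}

#' Rank-based and parametric group comparisons
#'
#' A thin, uniform surface over the standard two-sided tests used for
#' group comparisons: Wilcoxon rank-sum (exact for combined n <= 20
#' without ties, normal approximation with tie correction otherwise),
#' Kruskal--Wallis for more than two groups, Holm-adjusted p-values,
#' Spearman correlation with average ranks on ties, and unpaired/paired
#' t-tests. Degenerate input (all values identical across the compared
#' groups) returns p = 1 with \code{degenerate = TRUE} rather than an
#' error.
#'
#' @param x,y numeric vectors (for \code{method = "spearman"} the two
#'   variables; for tests the two groups; \code{y} ignored for
#'   \code{"kruskal"}).
#' @param method one of \code{"wilcoxon"}, \code{"kruskal"},
#'   \code{"spearman"}, \code{"t"}, \code{"t_paired"}.
#' @param groups for \code{method = "kruskal"}: list of numeric vectors.
#' @return list with \code{statistic}, \code{p_value}, \code{method},
#'   \code{degenerate}, and \code{estimate} (rho) for Spearman.
#' @export
rank_stats <- function(x, y = NULL, method = c("wilcoxon", "kruskal",
                                               "spearman", "t", "t_paired"),
                       groups = NULL) {
  method <- match.arg(method)
  degen <- FALSE
  if (method == "kruskal") {
    if (is.null(groups)) stop("'groups' (list of vectors) required")
    if (any(lengths(groups) < 1L)) stop("each group needs >= 1 observation")
    vals <- unlist(groups)
    if (length(unique(vals)) == 1L)
      return(list(statistic = 0, p_value = 1, method = "kruskal",
                  degenerate = TRUE))
    g <- factor(rep(seq_along(groups), lengths(groups)))
    ht <- stats::kruskal.test(vals, g)
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                method = "kruskal", degenerate = FALSE))
  }
  if (is.null(y)) stop("'y' required for method '", method, "'")
  if (length(x) < 1L || length(y) < 1L) stop("each group needs >= 1 observation")
  if (method == "spearman") {
    ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                estimate = unname(ht$estimate), method = "spearman",
                degenerate = FALSE))
  }
  if (method == "t_paired" && length(x) != length(y))
    stop("paired test requires equal lengths")
  if (length(unique(c(x, y))) == 1L)
    return(list(statistic = 0, p_value = 1, method = method,
                degenerate = TRUE))
  ht <- switch(method,
    wilcoxon = suppressWarnings(stats::wilcox.test(
      x, y, exact = (length(x) + length(y)) <= 20, correct = TRUE)),
    t = stats::t.test(x, y),
    t_paired = stats::t.test(x, y, paired = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = method, degenerate = degen)
}

#' Holm step-down multiple-testing adjustment
#'
#' Monotone max-accumulated step-down adjustment of a vector of p-values,
#' delegated to \code{stats::p.adjust(method = "holm")}.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the original order.
#' @export
holm_adjust <- function(p) stats::p.adjust(p, method = "holm")

#' Immunohistochemistry H-score
#'
#' The H-score summarizes IHC staining on a 0--300 scale: each cell is
#' binned by staining intensity (0 absent, 1 weak, 2 medium, 3 strong) and
#' the score is the sum of intensity times the percentage of cells in that
#' bin.
#'
#' @param pct_by_intensity numeric vector of length 4 (percent of cells at
#'   intensities 0,1,2,3) or length 3 (intensities 1,2,3; the zero bin
#'   contributes nothing). Percentages must be nonnegative and sum to at
#'   most 100.
#' @return list of class \code{h_score}: \code{score} in [0,300] and the
#'   per-bin percentages.
#' @export
h_score <- function(pct_by_intensity) {
  p <- pct_by_intensity
  if (any(p < 0)) stop("percentages must be nonnegative")
  if (length(p) == 3L) {
    if (sum(p) > 100 + 1e-9) stop("percentages sum above 100")
    p <- c(100 - sum(p), p)
  }
  if (length(p) != 4L) stop("expected percentages for intensity bins 0-3")
  if (sum(p) > 100 + 1e-9) stop("percentages sum above 100")
  score <- sum((0:3) * p)
  structure(list(score = score, pct = p), class = "h_score")
}

#' @export
print.h_score <- function(x, ...) {
  cat(sprintf("H-score: %g (of 300)\n", x$score))
  invisible(x)
}
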