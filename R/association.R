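#' Count cohort carriers of a locus, stratified by copy number
#'
#' For each copy-number class (0, 1, 3, 4) counts the distinct individuals in
#' the cohort with at least one call of that class overlapping the locus by
#' at least one base. `total` is the number of distinct (individual, class)
#' pairs, so an individual carrying calls of two classes at the locus
#' contributes to both strata; `n_carriers` pools classes and counts each
#' individual once (the unit used for the association test), and `n_calls`
#' counts overlapping calls.
#'
#' @param locus One-row interval data.frame; for shared groups pass the
#'   largest encompassing region.
#' @param cohort_calls Calls data.frame for the cohort.
#' @return One-row data.frame: `cn0`, `cn1`, `cn3`, `cn4`, `total`,
#'   `n_carriers`, `n_calls`, `intersect_label` (the `"T (a|b|c|d)"` string).
#' @export
intersect_cohort <- function(locus, cohort_calls) {
  hit <- overlaps(cohort_calls, locus)
  hits <- cohort_calls[hit, , drop = FALSE]
  per_cn <- vapply(c(0, 1, 3, 4), function(cn) {
    length(unique(hits$sample_id[hits$copy_number == cn]))
  }, 0L)
  out <- data.frame(cn0 = per_cn[1], cn1 = per_cn[2], cn3 = per_cn[3],
                    cn4 = per_cn[4], total = sum(per_cn),
                    n_carriers = length(unique(hits$sample_id)),
                    n_calls = nrow(hits))
  out$intersect_label <- format_intersect(out)
  out
}

#' Build a carrier/non-carrier contingency table
#'
#' Diagnostic-test layout: TP = case carriers, FN = case non-carriers,
#' FP = control carriers, TN = control non-carriers.
#'
#' @param tp,fn,fp,tn Non-negative counts.
#' @return A named list of the four cells, class `contingency_table`.
#' @export
contingency_table <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(cells < 0) || anyNA(cells)) stop("contingency cells must be non-negative")
  structure(as.list(cells), class = "contingency_table")
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value: with margins fixed, the hypergeometric point
#' probability of every achievable table is computed and those no more
#' probable than the observed table (within relative tolerance 1e-7, to
#' absorb floating-point ties) are summed. An all-zero table returns p = 1 by
#' convention with a message.
#'
#' @param table A [contingency_table()] (or list with `tp`, `fn`, `fp`, `tn`).
#' @return The two-sided p-value in (0, 1].
#' @export
#' @examples
#' fisher_two_sided(contingency_table(5, 0, 0, 5)) # 2/252
fisher_two_sided <- function(table) {
  tp <- table$tp; fn <- table$fn; fp <- table$fp; tn <- table$tn
  if (tp + fn + fp + tn == 0) {
    message("all-zero contingency table; returning p = 1")
    return(1)
  }
  m <- tp + fn         # cases
  n <- fp + tn         # controls
  k <- tp + fp         # carriers
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  d_obs <- stats::dhyper(tp, m, n, k)
  p <- sum(d[d <= d_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Positive and negative likelihood ratios from a 2x2 table
#'
#' LR+ = sensitivity / (1 - specificity) = (TP/(TP+FN)) / (FP/(FP+TN));
#' LR- = (1 - sensitivity) / specificity = (FN/(TP+FN)) / (TN/(FP+TN)).
#' When FP = 0 with TP > 0 the LR+ is undefined and returned as `Inf`
#' (likewise LR- when TN = 0 with FN > 0); 0/0 cases return `NaN`. Reports
#' render infinite ratios as "inf" rather than dropping them.
#'
#' @param table A [contingency_table()].
#' @return List with `lr_positive` and `lr_negative`.
#' @export
#' @examples
#' likelihood_ratios(contingency_table(13, 2310, 28, 4539))
likelihood_ratios <- function(table) {
  tp <- table$tp; fn <- table$fn; fp <- table$fp; tn <- table$tn
  if (tp + fn == 0 || fp + tn == 0) {
    stop("likelihood ratios need a non-empty case and control margin")
  }
  sens <- tp / (tp + fn)
  fpr <- fp / (fp + tn)
  lr_pos <- if (fpr == 0) {
    if (sens > 0) Inf else NaN
  } else {
    sens / fpr
  }
  spec <- tn / (fp + tn)
  miss <- fn / (tp + fn)
  lr_neg <- if (spec == 0) {
    if (miss > 0) Inf else NaN
  } else {
    miss / spec
  }
  list(lr_positive = lr_pos, lr_negative = lr_neg)
}

#' Case/control association of a candidate locus
#'
#' Carriers are distinct individuals with any overlapping call, pooled across
#' copy-number classes (one significance statement per locus); per-class
#' counts are reported alongside for the printed-table layout. The 2x2 table
#' uses the full cohort sizes as denominators, Fisher's exact test (two-sided)
#' provides the p-value, and the diagnostic likelihood ratios are attached.
#' No multiple-testing correction is applied.
#'
#' @param locus One-row interval data.frame.
#' @param case_calls,control_calls Calls data.frames for the two cohorts.
#' @param n_case,n_control Cohort sizes after QC (individuals, not calls).
#' @param alpha Significance level (default 0.05).
#' @return One-row data.frame: the four cells, `fisher_p`, `significant`,
#'   `lr_positive`, `lr_negative`, `case_intersect`, `control_intersect`.
#' @export
associate <- function(locus, case_calls, control_calls, n_case, n_control,
                      alpha = 0.05) {
  stopifnot(n_case >= 1, n_control >= 1, alpha > 0, alpha < 1)
  ic_case <- intersect_cohort(locus, case_calls)
  ic_ctrl <- intersect_cohort(locus, control_calls)
  if (ic_case$n_carriers > n_case || ic_ctrl$n_carriers > n_control) {
    stop("more carriers than cohort individuals; check cohort sizes")
  }
  tab <- contingency_table(tp = ic_case$n_carriers,
                           fn = n_case - ic_case$n_carriers,
                           fp = ic_ctrl$n_carriers,
                           tn = n_control - ic_ctrl$n_carriers)
  p <- fisher_two_sided(tab)
  lr <- likelihood_ratios(tab)
  data.frame(tp = tab$tp, fn = tab$fn, fp = tab$fp, tn = tab$tn,
             fisher_p = p, significant = p < alpha,
             lr_positive = lr$lr_positive, lr_negative = lr$lr_negative,
             case_intersect = ic_case$intersect_label,
             control_intersect = ic_ctrl$intersect_label)
}
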