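# Delta-Ct / delta-delta-Ct qPCR workflow and ELISA normalization, with
# outlier removal and group-comparison statistics.

#' Normalized qPCR expression (delta-Ct)
#'
#' Target Ct minus housekeeping Ct.  Higher Ct means lower expression,
#' so the per-well relative expression is `2^-delta_ct`.
#'
#' @param ct_target,ct_housekeeping Finite cycle-threshold values.
#' @return `ct_target - ct_housekeeping` (vectorized).
#' @export
delta_ct <- function(ct_target, ct_housekeeping) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_housekeeping)))
    stop("Ct values must be finite")
  ct_target - ct_housekeeping
}

#' Per-well relative expression from delta-Ct
#' @param dct Delta-Ct values.
#' @return `2^-dct`.
#' @export
relative_expression <- function(dct) 2^(-dct)

#' Tukey outlier removal
#'
#' Removes values outside `[Q1 - k*IQR, Q3 + k*IQR]`.  With fewer than
#' 4 values the fences are not meaningful: nothing is removed and a
#' warning is issued.
#'
#' @param values Numeric vector.
#' @param k Fence multiplier (default 1.5).
#' @return List with `kept`, `removed` and `removed_idx`.
#' @export
remove_outliers <- function(values, k = 1.5) {
  if (length(values) < 4L) {
    warning("fewer than 4 values; outlier removal skipped")
    return(list(kept = values, removed = numeric(0), removed_idx = integer(0)))
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - k * iqr
  hi <- q[2] + k * iqr
  out <- values < lo | values > hi
  list(kept = values[!out], removed = values[out], removed_idx = which(out))
}

#' Delta-delta-Ct fold change between mutant and control groups
#'
#' Applies the standard transform to the group-mean delta-Ct values:
#' `ddct = 2^-(mean(delta_mut) - mean(delta_ctrl))`.  When the mutant is
#' the lower-expressed group its mean delta-Ct is larger, so `ddct < 1`;
#' the reciprocal `2^(mean(delta_mut) - mean(delta_ctrl))` is reported
#' alongside as the wildtype-over-mutant expression ratio (the "x-fold
#' higher in the wildtype" figure).  The two always multiply to 1.
#'
#' @param delta_mut,delta_ctrl Non-empty delta-Ct vectors
#'   (post-outlier-removal).
#' @return List with `ddct`, `fold_change_wt_over_mut`, `log2_ratio`
#'   (mean difference) and the two group means.
#' @export
ddct_fold_change <- function(delta_mut, delta_ctrl) {
  if (length(delta_mut) == 0L || length(delta_ctrl) == 0L)
    stop("empty group in ddct_fold_change")
  d <- mean(delta_mut) - mean(delta_ctrl)
  list(ddct = 2^(-d), fold_change_wt_over_mut = 2^d, log2_ratio = d,
       mean_delta_mut = mean(delta_mut), mean_delta_ctrl = mean(delta_ctrl))
}

#' Two-group comparison of expression values
#'
#' Welch two-sample t-test by default (unequal-variance-safe for
#' replicate designs of this size); `test = "wilcoxon"` switches to the
#' Mann-Whitney rank-sum alternative.
#'
#' @param a,b Numeric vectors, each with >= 2 values.
#' @param test `"welch"` or `"wilcoxon"`.
#' @return List with `statistic` and `p_value` (two-sided).
#' @export
compare_groups <- function(a, b, test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs >= 2 values")
  if (test == "welch") {
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      stop("degenerate variance in both groups")
    ht <- stats::t.test(a, b)
  } else {
    ht <- stats::wilcox.test(a, b, exact = FALSE)
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value, method = test)
}

#' Construct a grouped qPCR dataset
#'
#' @param group Character vector, `"WILDTYPE"` or `"MUTANT"` per row.
#' @param bio_rep,tech_rep Integer replicate labels.
#' @param ct_target,ct_housekeeping Cycle thresholds per well.
#' @return data.frame of class `qpcr_dataset`; `(group, bio_rep,
#'   tech_rep)` keys must be unique and Ct values positive finite.
#' @export
qpcr_dataset <- function(group, bio_rep, tech_rep, ct_target, ct_housekeeping) {
  group <- toupper(group)
  if (!all(group %in% c("WILDTYPE", "MUTANT")))
    stop("group must be WILDTYPE or MUTANT")
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_housekeeping)) ||
      any(ct_target <= 0) || any(ct_housekeeping <= 0))
    stop("Ct values must be positive and finite")
  key <- paste(group, bio_rep, tech_rep)
  if (anyDuplicated(key)) stop("duplicate (group, bio_rep, tech_rep) key")
  df <- data.frame(group = group, bio_rep = as.integer(bio_rep),
                   tech_rep = as.integer(tech_rep),
                   ct_target = ct_target, ct_housekeeping = ct_housekeeping,
                   stringsAsFactors = FALSE)
  class(df) <- c("qpcr_dataset", "data.frame")
  df
}

#' Read a qPCR CSV
#'
#' Columns: `group`, `bio_rep`, `tech_rep`, `ct_target`, `ct_housekeeping`.
#'
#' @param path CSV file path.
#' @return A [qpcr_dataset()].
#' @export
read_qpcr_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "bio_rep", "tech_rep", "ct_target", "ct_housekeeping")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("qPCR CSV missing column(s): ", paste(miss, collapse = ", "))
  qpcr_dataset(df$group, df$bio_rep, df$tech_rep, df$ct_target, df$ct_housekeeping)
}

#' Full delta-delta-Ct qPCR analysis
#'
#' Per-well delta-Ct and relative expression; Tukey outlier removal on
#' relative expression within each group; group means; the
#' delta-delta-Ct fold change with both orientations; and a two-group
#' test on relative expression.  Technical replicates are treated as
#' independent wells by default; `average_bio = TRUE` first averages
#' within biological replicate and compares the per-replicate means.
#'
#' @param data A [qpcr_dataset()].
#' @param outlier_k Tukey fence multiplier; `NA` disables removal.
#' @param test Passed to [compare_groups()].
#' @param average_bio Average technical replicates within biological
#'   replicate before testing and fold-change estimation.
#' @return Object of class `expression_result`.
#' @export
analyze_qpcr <- function(data, outlier_k = 1.5, test = "welch", average_bio = FALSE) {
  data$delta_ct <- delta_ct(data$ct_target, data$ct_housekeeping)
  data$rel_expr <- relative_expression(data$delta_ct)

  kept <- data
  n_removed <- c(WILDTYPE = 0L, MUTANT = 0L)
  if (!is.na(outlier_k)) {
    keep_rows <- logical(nrow(data))
    for (g in unique(data$group)) {
      idx <- which(data$group == g)
      res <- remove_outliers(data$rel_expr[idx], k = outlier_k)
      drop <- idx[res$removed_idx]
      keep_rows[setdiff(idx, drop)] <- TRUE
      n_removed[g] <- length(drop)
    }
    kept <- data[keep_rows, , drop = FALSE]
  } else {
    kept <- data
  }

  if (average_bio) {
    agg <- stats::aggregate(cbind(delta_ct, rel_expr) ~ group + bio_rep,
                            data = kept, FUN = mean)
    dmut <- agg$delta_ct[agg$group == "MUTANT"]
    dwt <- agg$delta_ct[agg$group == "WILDTYPE"]
    emut <- agg$rel_expr[agg$group == "MUTANT"]
    ewt <- agg$rel_expr[agg$group == "WILDTYPE"]
  } else {
    dmut <- kept$delta_ct[kept$group == "MUTANT"]
    dwt <- kept$delta_ct[kept$group == "WILDTYPE"]
    emut <- kept$rel_expr[kept$group == "MUTANT"]
    ewt <- kept$rel_expr[kept$group == "WILDTYPE"]
  }
  fc <- ddct_fold_change(dmut, dwt)
  cmp <- compare_groups(ewt, emut, test = test)
  structure(
    list(data = data, kept = kept, n_removed = n_removed,
         ddct = fc$ddct, fold_change_wt_over_mut = fc$fold_change_wt_over_mut,
         log2_ratio = fc$log2_ratio,
         mean_delta_wt = fc$mean_delta_ctrl, mean_delta_mut = fc$mean_delta_mut,
         statistic = cmp$statistic, p_value = cmp$p_value, test = cmp$method,
         average_bio = average_bio),
    class = "expression_result")
}

#' @export
print.expression_result <- function(x, ...) {
  cat("<expression_result> ddCt analysis (", x$test,
      if (x$average_bio) ", per-biological-replicate" else ", per-well", ")\n",
      "  mean dCt wildtype: ", format(x$mean_delta_wt, digits = 4),
      "   mutant: ", format(x$mean_delta_mut, digits = 4), "\n",
      "  ddCt = ", format(x$ddct, digits = 4),
      "; wildtype/mutant ratio = ", format(x$fold_change_wt_over_mut, digits = 5), "\n",
      "  p = ", format(x$p_value, digits = 5),
      "; outliers removed: WT ", x$n_removed[["WILDTYPE"]],
      ", MUT ", x$n_removed[["MUTANT"]], "\n", sep = "")
  invisible(x)
}

#' One-row summary of an expression result
#' @param object An `expression_result`.
#' @param ... Unused.
#' @return data.frame with means, ddCt, ratio, p and removal counts.
#' @export
summary.expression_result <- function(object, ...) {
  data.frame(
    mean_delta_wt = object$mean_delta_wt,
    mean_delta_mut = object$mean_delta_mut,
    ddct = object$ddct,
    fold_change_wt_over_mut = object$fold_change_wt_over_mut,
    p_value = object$p_value,
    n_removed_wt = object$n_removed[["WILDTYPE"]],
    n_removed_mut = object$n_removed[["MUTANT"]])
}

#' Normalize an ELISA concentration to total protein
#'
#' @param pilra_conc Target protein concentration (pg/mL), positive.
#' @param total_protein Total protein concentration (ug/mL), positive.
#' @return The ratio (vectorized); scale-invariant in the common factor.
#' @export
normalize_elisa <- function(pilra_conc, total_protein) {
  if (any(!is.finite(total_protein)) || any(total_protein <= 0))
    stop("total_protein must be positive")
  if (any(!is.finite(pilra_conc)) || any(pilra_conc <= 0))
    stop("pilra_conc must be positive")
  pilra_conc / total_protein
}

#' Read an ELISA CSV
#'
#' Columns: `group`, `replicate`, `pilra_conc`, `total_protein`.
#'
#' @param path CSV file path.
#' @return data.frame with an added `normalized` column.
#' @export
read_elisa_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "replicate", "pilra_conc", "total_protein")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("ELISA CSV missing column(s): ", paste(miss, collapse = ", "))
  df$group <- toupper(df$group)
  df$normalized <- normalize_elisa(df$pilra_conc, df$total_protein)
  df
}

#' Analyze an ELISA dataset
#'
#' Normalizes each replicate to total protein and compares groups.
#'
#' @param df Data frame from [read_elisa_csv()] (or with the same columns).
#' @param test Passed to [compare_groups()].
#' @return List with group means, wildtype/mutant ratio, statistic and p.
#' @export
analyze_elisa <- function(df, test = "welch") {
  if (is.null(df$normalized))
    df$normalized <- normalize_elisa(df$pilra_conc, df$total_protein)
  wt <- df$normalized[df$group == "WILDTYPE"]
  mut <- df$normalized[df$group == "MUTANT"]
  cmp <- compare_groups(wt, mut, test = test)
  list(mean_wt = mean(wt), mean_mut = mean(mut),
       ratio_wt_over_mut = mean(wt) / mean(mut),
       statistic = cmp$statistic, p_value = cmp$p_value, test = cmp$method)
}
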