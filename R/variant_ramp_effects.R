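# Wildtype-vs-mutant ramp sweeps across contexts and isoforms, and the
# variant-effect taxonomy (Loss of Ramp > Gain of Ramp > Ramp Size >
# Gene with Ramp > none).

PAIRWISE_OUTCOMES <- c("LOSS", "GAIN", "SIZE_CHANGE", "UNCHANGED", "NEITHER")
EFFECT_CATEGORIES <- c("LOSS_OF_RAMP", "GAIN_OF_RAMP", "RAMP_SIZE",
                       "GENE_WITH_RAMP", "NONE")

#' Compare wildtype and mutant ramp calls in one context
#'
#' @param wt,mut `ramp_call` objects on the same isoform and context
#'   (the mutant call is made on the sequence carrying the variant).
#' @return One of `"LOSS"` (wildtype ramp destroyed), `"GAIN"` (ramp
#'   created), `"SIZE_CHANGE"` (both present, different extent),
#'   `"UNCHANGED"` (both present, same extent), `"NEITHER"` (both absent).
#' @export
compare_ramp_calls <- function(wt, mut) {
  if (wt$context_id != mut$context_id || wt$seq_id != mut$seq_id)
    stop("wildtype and mutant calls are from different contexts or isoforms (",
         wt$seq_id, " x ", wt$context_id, " vs ", mut$seq_id, " x ",
         mut$context_id, ")")
  if (wt$present && !mut$present) "LOSS"
  else if (!wt$present && mut$present) "GAIN"
  else if (wt$present && mut$present) {
    if (wt$ramp_end_codon != mut$ramp_end_codon) "SIZE_CHANGE" else "UNCHANGED"
  } else "NEITHER"
}

#' Most severe ramp-effect category from a sweep
#'
#' Severity ordering: `LOSS_OF_RAMP > GAIN_OF_RAMP > RAMP_SIZE >
#' GENE_WITH_RAMP > NONE`.  `GENE_WITH_RAMP` is assigned when no
#' loss/gain/size outcome exists in any context but the wildtype gene
#' has a ramp in at least one context (the variant sits outside it);
#' `NONE` when the gene has no ramp anywhere.
#'
#' @param outcomes Character vector of pairwise outcomes from a
#'   completed sweep.
#' @param variant_in_ramp Was the variant inside the wildtype ramp
#'   extent in at least one context? (recorded, not used in ranking).
#' @param gene_has_ramp Does the wildtype have a ramp in >= 1 context?
#' @return One effect category string.
#' @export
most_severe_effect <- function(outcomes, variant_in_ramp, gene_has_ramp) {
  bad <- setdiff(outcomes, PAIRWISE_OUTCOMES)
  if (length(bad)) stop("unknown pairwise outcome(s): ", paste(bad, collapse = ", "))
  if ("LOSS" %in% outcomes) "LOSS_OF_RAMP"
  else if ("GAIN" %in% outcomes) "GAIN_OF_RAMP"
  else if ("SIZE_CHANGE" %in% outcomes) "RAMP_SIZE"
  else if (isTRUE(gene_has_ramp)) "GENE_WITH_RAMP"
  else "NONE"
}

#' Render an effect category the way report tables print it
#' @param category An effect category string.
#' @return Human-readable label; `"N/A"` for `NONE`.
#' @export
format_ramp_effect <- function(category) {
  switch(category,
         LOSS_OF_RAMP = "Loss of Ramp",
         GAIN_OF_RAMP = "Gain of Ramp",
         RAMP_SIZE = "Ramp Size",
         GENE_WITH_RAMP = "Gene with Ramp",
         NONE = "N/A",
         stop("unknown category: ", category))
}

#' Sweep a variant across isoforms and tRNA contexts
#'
#' Runs [detect_ramp()] on every (isoform, context) pair for both the
#' wildtype and the mutant sequence — `2 x isoforms x contexts` calls,
#' all counted — and aggregates the pairwise outcomes into a single
#' variant-level effect.
#'
#' @param isoforms List of [coding_sequence()] objects; the variant is
#'   applied to every isoform whose id matches `v$transcript_id`.
#' @param v A [variant_spec()].
#' @param tables Non-empty list of [efficiency_table()] objects.
#' @param p A [ramp_params()].
#' @return Object of class `ramp_effect` with fields `variant_id`,
#'   `category`, `n_contexts_affected`, `variant_in_ramp`,
#'   `gene_has_ramp`, `per_context` (data.frame of per-pair outcomes),
#'   `wt_ramp_contexts` (contexts with a wildtype ramp, split by
#'   context class), `n_isoforms_with_ramp`, `n_isoforms` and
#'   `n_detect_calls`.
#' @export
sweep_contexts <- function(isoforms, v, tables, p = ramp_params()) {
  if (length(tables) == 0L) stop("sweep over 0 efficiency tables")
  ids <- vapply(isoforms, function(s) s$id, character(1))
  affected <- which(ids == v$transcript_id)
  if (length(affected) == 0L)
    stop("variant '", v$id, "' maps to no supplied isoform (transcript ",
         v$transcript_id, ")")
  v <- annotate_consequence(isoforms[[affected[1]]], v)
  var_codon <- codon_index_of(v$cds_pos)

  rows <- list()
  n_calls <- 0L
  variant_in_ramp <- FALSE
  for (i in affected) {
    wt_seq <- isoforms[[i]]
    mut_seq <- apply_variant(wt_seq, v)
    for (t in tables) {
      wt_call <- detect_ramp(wt_seq, t, p)
      mut_call <- detect_ramp(mut_seq, t, p)
      n_calls <- n_calls + 2L
      if (wt_call$present && var_codon <= wt_call$ramp_end_codon)
        variant_in_ramp <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        isoform = wt_seq$id,
        context_id = t$context_id,
        context_class = t$context_class,
        wt_present = wt_call$present,
        wt_ramp_end = wt_call$ramp_end_codon,
        mut_present = mut_call$present,
        mut_ramp_end = mut_call$ramp_end_codon,
        outcome = compare_ramp_calls(wt_call, mut_call),
        stringsAsFactors = FALSE)
    }
  }
  per_context <- do.call(rbind, rows)
  gene_has_ramp <- any(per_context$wt_present)
  category <- most_severe_effect(per_context$outcome, variant_in_ramp, gene_has_ramp)
  affected_ctx <- unique(per_context$context_id[
    !per_context$outcome %in% c("UNCHANGED", "NEITHER")])
  wt_ctx <- per_context[per_context$wt_present, c("context_id", "context_class")]
  wt_ctx <- unique(wt_ctx)
  structure(
    list(variant_id = v$id, variant = v, category = category,
         n_contexts_affected = length(affected_ctx),
         variant_in_ramp = variant_in_ramp, gene_has_ramp = gene_has_ramp,
         per_context = per_context,
         wt_ramp_contexts = split(wt_ctx$context_id, wt_ctx$context_class),
         n_isoforms_with_ramp = length(unique(per_context$isoform[per_context$wt_present])),
         n_isoforms = length(affected),
         n_detect_calls = n_calls),
    class = "ramp_effect")
}

#' @export
print.ramp_effect <- function(x, ...) {
  cat("<ramp_effect> ", x$variant_id, ": ", format_ramp_effect(x$category),
      "\n  consequence: ", x$variant$consequence,
      "\n  contexts affected: ", x$n_contexts_affected,
      "; wildtype ramp in ",
      sum(lengths(x$wt_ramp_contexts)), " context(s)",
      "\n  isoforms with ramp: ", render_fraction(x$n_isoforms_with_ramp, x$n_isoforms),
      "; detect_ramp calls: ", x$n_detect_calls, "\n", sep = "")
  invisible(x)
}

#' @export
summary.ramp_effect <- function(object, ...) {
  tab <- table(factor(object$per_context$outcome, levels = PAIRWISE_OUTCOMES))
  cat("Pairwise outcomes across", nrow(object$per_context), "isoform x context pairs:\n")
  print(tab)
  invisible(tab)
}

#' Fraction of isoforms with a wildtype ramp in any context
#'
#' @param isoforms List of [coding_sequence()] objects.
#' @param tables List of [efficiency_table()] objects.
#' @param p A [ramp_params()].
#' @return List with `k` (isoforms carrying a ramp in >= 1 context),
#'   `n` (isoform count) and `label` rendered as `"k/n (pct%)"` with the
#'   percentage rounded to the nearest integer.
#' @export
isoform_ramp_fraction <- function(isoforms, tables, p = ramp_params()) {
  if (length(isoforms) == 0L || length(tables) == 0L)
    stop("isoform_ramp_fraction requires non-empty isoforms and tables")
  has_ramp <- vapply(isoforms, function(s) {
    any(vapply(tables, function(t) detect_ramp(s, t, p)$present, logical(1)))
  }, logical(1))
  k <- sum(has_ramp)
  n <- length(isoforms)
  list(k = k, n = n, label = render_fraction(k, n))
}

render_fraction <- function(k, n) {
  sprintf("%d/%d (%d%%)", k, n, as.integer(round(100 * k / n)))
}
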