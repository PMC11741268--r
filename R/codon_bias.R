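# Secondary codon-usage-bias metrics: GC content, identical codon
# pairing, codon aversion, within-family codon rank.

#' GC content of a coding sequence
#'
#' Nucleotide-level (#G + #C) / length; the terminal stop codon is
#' included because GC is a nucleotide property, not a translational
#' one.
#'
#' @param seq A [coding_sequence()].
#' @return Fraction in \[0, 1\].
#' @export
gc_content <- function(seq) {
  nt <- strsplit(paste(seq$codons, collapse = ""), "")[[1]]
  sum(nt %in% c("G", "C")) / length(nt)
}

#' Identical codon pairing counts
#'
#' Recurrence of the same codon within a short distance, thought to
#' speed translation through tRNA recycling.  In `WINDOW` mode
#' (default, window 9 — one ribosome footprint) each codon occurrence
#' pairs with the nearest previous occurrence of the same codon iff
#' their codon-index distance is strictly less than the window; counts
#' chain along the sequence.  In `ADJACENT` mode only consecutive
#' identical codons pair.  The terminal stop codon is excluded.
#'
#' @param seq A [coding_sequence()].
#' @param window Window in codons (>= 2), used in `WINDOW` mode.
#' @param mode `"WINDOW"` or `"ADJACENT"`.
#' @return List with `counts` (named per-codon pair counts, only codons
#'   with >= 1 pair) and `total`.
#' @export
identical_codon_pairing <- function(seq, window = 9L, mode = c("WINDOW", "ADJACENT")) {
  mode <- match.arg(mode)
  window <- as.integer(window)
  if (mode == "WINDOW" && window < 2L) stop("window must be >= 2 in WINDOW mode")
  codons <- sense_part(seq)
  counts <- integer(0)
  last_seen <- new.env(parent = emptyenv())
  for (j in seq_along(codons)) {
    cd <- codons[j]
    i <- if (exists(cd, envir = last_seen)) get(cd, envir = last_seen) else NA_integer_
    paired <- if (is.na(i)) FALSE
      else if (mode == "WINDOW") (j - i) < window
      else (j - i) == 1L
    if (paired) counts[cd] <- if (is.na(counts[cd])) 1L else counts[cd] + 1L
    assign(cd, j, envir = last_seen)
  }
  counts <- counts[!is.na(counts)]
  list(counts = counts, total = as.integer(sum(counts)))
}

#' Codon aversion set of a sequence
#'
#' The sense codons a transcript never uses (terminal stop excluded).
#'
#' @param seq A [coding_sequence()].
#' @return Character vector of averted sense codons, sorted.
#' @export
codon_aversion_set <- function(seq) {
  sort(setdiff(sense_codons(), unique(sense_part(seq))))
}

#' Rank of a codon within its synonymous family
#'
#' Rank 1 is the highest-valued (most adaptive / most used) codon of the
#' amino-acid family under the supplied usage or efficiency table; ties
#' share the smaller rank.
#'
#' @param codon A sense codon.
#' @param usage An [efficiency_table()] or a named numeric vector
#'   covering the codon's synonymous family.
#' @return List with `rank` and `family_size`.
#' @export
codon_family_rank <- function(codon, usage) {
  codon <- toupper(codon)
  if (codon %in% STOP_CODONS) stop("stop codon ", codon, " has no family rank")
  vals <- if (inherits(usage, "efficiency_table")) usage$eff else usage
  aa <- translate_codon(codon)
  fam <- names(vals)[translate_codon(names(vals)) == aa]
  if (!codon %in% fam)
    stop("usage table does not cover codon ", codon)
  fam_vals <- vals[fam]
  rank <- as.integer(rank(-fam_vals, ties.method = "min")[codon])
  list(rank = rank, family_size = length(fam))
}

#' Codon-usage-bias report for one sequence
#'
#' @param seq A [coding_sequence()].
#' @param usage Optional [efficiency_table()] for family ranks of the
#'   codons named in `rank_codons`.
#' @param pairing_window,pairing_mode Passed to [identical_codon_pairing()].
#' @param rank_codons Codons to rank within their synonymous families
#'   (e.g. the reference and alternate codons of a variant).
#' @return Object of class `bias_report` with fields `seq_id`,
#'   `gc_fraction`, `pairing_counts`, `total_pairing`, `averted_codons`
#'   and `rank_table`.
#' @export
bias_report <- function(seq, usage = NULL, pairing_window = 9L,
                        pairing_mode = "WINDOW", rank_codons = character(0)) {
  pairing <- identical_codon_pairing(seq, pairing_window, pairing_mode)
  ranks <- NULL
  if (length(rank_codons) && !is.null(usage)) {
    ranks <- do.call(rbind, lapply(rank_codons, function(cd) {
      r <- codon_family_rank(cd, usage)
      data.frame(codon = cd, rank = r$rank, family_size = r$family_size,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(
    list(seq_id = seq$id, gc_fraction = gc_content(seq),
         pairing_counts = pairing$counts, total_pairing = pairing$total,
         averted_codons = codon_aversion_set(seq), rank_table = ranks),
    class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat("<bias_report> ", x$seq_id,
      "\n  GC fraction:    ", format(x$gc_fraction, digits = 4),
      "\n  total pairing:  ", x$total_pairing,
      "\n  averted codons: ", length(x$averted_codons), "\n", sep = "")
  if (!is.null(x$rank_table)) {
    cat("  family ranks:\n")
    for (i in seq_len(nrow(x$rank_table)))
      cat("    ", x$rank_table$codon[i], ": ", x$rank_table$rank[i], "/",
          x$rank_table$family_size[i], "\n", sep = "")
  }
  invisible(x)
}

#' Wildtype-vs-mutant bias comparison table
#'
#' One row per sequence with GC fraction and total pairing, plus
#' per-codon pairing deltas (mutant minus wildtype) and averted-codon
#' set differences.
#'
#' @param wt,mut `bias_report` objects.
#' @return List with `summary` (data.frame), `pairing_delta` (named
#'   vector over codons whose counts changed) and `aversion_delta`
#'   (codons averted in exactly one of the two).
#' @export
compare_bias <- function(wt, mut) {
  all_codons <- union(names(wt$pairing_counts), names(mut$pairing_counts))
  gv <- function(cnt, cd) if (cd %in% names(cnt)) cnt[[cd]] else 0L
  delta <- vapply(all_codons, function(cd) gv(mut$pairing_counts, cd) - gv(wt$pairing_counts, cd),
                  integer(1))
  delta <- delta[delta != 0L]
  list(
    summary = data.frame(
      seq_id = c(wt$seq_id, mut$seq_id),
      gc_fraction = c(wt$gc_fraction, mut$gc_fraction),
      total_pairing = c(wt$total_pairing, mut$total_pairing),
      stringsAsFactors = FALSE),
    pairing_delta = delta,
    aversion_delta = sort(c(setdiff(wt$averted_codons, mut$averted_codons),
                            setdiff(mut$averted_codons, wt$averted_codons))))
}
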