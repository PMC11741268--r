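# Calling the presence and extent of a 5' ramp from a window speed profile.

#' Ramp-detection parameters
#'
#' @param window_size Ribosome window width in codons (default 9).
#' @param outlier_rule How low-outlier windows are identified in the
#'   gene's window-speed distribution: `"IQR"` (Tukey, below
#'   `Q1 - k * IQR`; robust for the short, skewed profiles of single
#'   genes) or `"SD"` (below `mean - k * SD`).
#' @param outlier_k Fence multiplier; defaults to 1.5 for IQR and 2.0
#'   for SD when not given.
#' @param min_ramp_windows Minimum number of outlier windows the
#'   candidate 5' run must contain to be called a ramp (default 1).
#' @return Object of class `ramp_params`.
#' @export
ramp_params <- function(window_size = 9L, outlier_rule = c("IQR", "SD"),
                        outlier_k = NULL, min_ramp_windows = 1L) {
  outlier_rule <- match.arg(outlier_rule)
  if (is.null(outlier_k)) outlier_k <- if (outlier_rule == "IQR") 1.5 else 2.0
  window_size <- as.integer(window_size)
  if (window_size < 1L) stop("window_size must be >= 1")
  if (!is.finite(outlier_k) || outlier_k <= 0) stop("outlier_k must be > 0")
  structure(
    list(window_size = window_size, outlier_rule = outlier_rule,
         outlier_k = outlier_k, min_ramp_windows = as.integer(min_ramp_windows)),
    class = "ramp_params")
}

# Low-outlier fence for a window-speed distribution.
low_fence <- function(window_speeds, rule, k) {
  if (rule == "IQR") {
    q <- stats::quantile(window_speeds, c(0.25, 0.75), names = FALSE)
    q[1] - k * (q[2] - q[1])
  } else {
    mean(window_speeds) - k * stats::sd(window_speeds)
  }
}

#' Detect a 5' ramp sequence in one sequence under one tRNA context
#'
#' A ramp is a run of slowly translated windows at the very start of the
#' gene.  The call proceeds in five steps: (1) the gene-wide speed is the
#' harmonic mean of all sense-codon efficiencies; (2) the window profile
#' is the sliding harmonic mean over `window_size` codons; (3) the
#' candidate ramp is the maximal run of consecutive windows, starting at
#' window 1, whose speed is strictly below the gene speed (a slow region
#' preceded by a fast first window is not a ramp; ties break toward "not
#' below"); (4) the candidate qualifies as a ramp iff it contains at
#' least `min_ramp_windows` windows that are low outliers of the full
#' window-speed distribution under the configured rule; (5) the ramp end
#' is the last codon covered by the last outlier window of the run.
#'
#' The initiation codon is excluded from the speed statistics: its
#' decoding is governed by initiation factors and the initiator tRNA,
#' which elongation-efficiency tables do not describe, so window `i`
#' covers codons `i + 1` through `i + window_size` and ramp extents are
#' reported in original codon coordinates.
#'
#' Sequences shorter than one window yield `present = FALSE` with a
#' `"too_short"` flag rather than an error, so genome-wide sweeps never
#' abort.
#'
#' @param seq A [coding_sequence()].
#' @param t An [efficiency_table()].
#' @param p A [ramp_params()].
#' @return Object of class `ramp_call` with fields `seq_id`,
#'   `context_id`, `context_class`, `present`, `ramp_end_codon` (0 when
#'   absent), `gene_speed`, `profile` and `flag`.
#' @export
detect_ramp <- function(seq, t, p = ramp_params()) {
  codons <- sense_part(seq)
  if (length(codons) - 1L < p$window_size) {
    speeds <- t$eff[codons]
    gene_speed <- if (length(speeds) && !anyNA(speeds) && all(speeds > 0))
      harmonic_mean(unname(speeds)) else NA_real_
    return(structure(
      list(seq_id = seq$id, context_id = t$context_id,
           context_class = t$context_class, present = FALSE,
           ramp_end_codon = 0L, gene_speed = gene_speed,
           profile = NULL, flag = "too_short"),
      class = "ramp_call"))
  }
  prof <- codon_speed_profile(seq, t, p$window_size, exclude_start = TRUE)
  gene_speed <- harmonic_mean(prof$codon_speeds)
  ws <- prof$window_speeds
  below <- ws < gene_speed
  run_len <- if (!below[1]) 0L else {
    first_not <- which(!below)[1]
    if (is.na(first_not)) length(ws) else first_not - 1L
  }
  present <- FALSE
  ramp_end <- 0L
  if (run_len >= 1L) {
    fence <- low_fence(ws, p$outlier_rule, p$outlier_k)
    qual <- which(ws[seq_len(run_len)] < fence)
    if (length(qual) >= p$min_ramp_windows) {
      present <- TRUE
      ramp_end <- max(qual) + p$window_size - 1L + prof$start_offset
    }
  }
  structure(
    list(seq_id = seq$id, context_id = t$context_id,
         context_class = t$context_class, present = present,
         ramp_end_codon = as.integer(ramp_end), gene_speed = gene_speed,
         profile = prof, flag = "ok"),
    class = "ramp_call")
}

#' @export
print.ramp_call <- function(x, ...) {
  cat("<ramp_call> ", x$seq_id, " x ", x$context_id, ": ",
      if (x$present) paste0("ramp through codon ", x$ramp_end_codon)
      else paste0("no ramp (", x$flag, ")"),
      ", gene speed ", format(x$gene_speed, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Length of a called ramp, in codons
#'
#' @param call A `ramp_call`.
#' @return `ramp_end_codon` when the ramp is present, 0 otherwise.
#' @export
ramp_length <- function(call) {
  if (isTRUE(call$present)) call$ramp_end_codon else 0L
}

#' Tabulate ramp calls as a data frame
#'
#' One row per call: `seq_id`, `context_id`, `context_class`, `present`,
#' `ramp_end_codon`, `gene_speed`, `min_window_speed` — the per-call TSV
#' layout the pipeline writes.
#'
#' @param calls List of `ramp_call` objects.
#' @return data.frame.
#' @export
ramp_calls_table <- function(calls) {
  data.frame(
    seq_id = vapply(calls, function(x) x$seq_id, character(1)),
    context_id = vapply(calls, function(x) x$context_id, character(1)),
    context_class = vapply(calls, function(x) x$context_class, character(1)),
    present = vapply(calls, function(x) x$present, logical(1)),
    ramp_end_codon = vapply(calls, function(x) x$ramp_end_codon, integer(1)),
    gene_speed = vapply(calls, function(x) x$gene_speed, numeric(1)),
    min_window_speed = vapply(calls, function(x)
      if (is.null(x$profile)) NA_real_ else min(x$profile$window_speeds), numeric(1)),
    stringsAsFactors = FALSE)
}
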