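# Per-context codon translational-efficiency tables, normalization to
# relative adaptiveness, and codon/window speed profiles.

#' Construct a per-context codon efficiency table
#'
#' One tissue's or cell type's map from each of the 61 sense codons to a
#' positive translational-efficiency value — the relative codon
#' adaptiveness fed to ramp detection.  Values are opaque positive
#' weights; only their relative order and ratios matter downstream.
#'
#' @param context_id Tissue or cell-type name.
#' @param eff Named numeric vector covering all 61 sense codons with
#'   strictly positive values.  Zero efficiencies are rejected rather
#'   than floored: the harmonic mean is undefined at zero.
#' @param context_class `"TISSUE"` or `"CELL"`.
#' @return Object of class `efficiency_table`.
#' @export
efficiency_table <- function(context_id, eff, context_class = c("TISSUE", "CELL")) {
  context_class <- match.arg(context_class)
  codons <- sense_codons()
  nm <- toupper(names(eff))
  if (anyDuplicated(nm))
    stop("context '", context_id, "': duplicate codon row ",
         nm[duplicated(nm)][1])
  miss <- setdiff(codons, nm)
  if (length(miss))
    stop("context '", context_id, "': missing codon ", miss[1])
  extra <- setdiff(nm, codons)
  if (length(extra))
    stop("context '", context_id, "': unexpected codon(s) ",
         paste(extra, collapse = ", "), " (stop codons carry no efficiency)")
  names(eff) <- nm
  eff <- eff[codons]
  if (any(!is.finite(eff)) || any(eff <= 0))
    stop("context '", context_id, "': non-positive or non-numeric efficiency for codon ",
         codons[which(!is.finite(eff) | eff <= 0)][1])
  structure(
    list(context_id = context_id, context_class = context_class,
         eff = eff),
    class = "efficiency_table")
}

#' @export
print.efficiency_table <- function(x, ...) {
  cat("<efficiency_table> ", x$context_id, " (", x$context_class, "): 61 sense codons, ",
      "range [", format(min(x$eff), digits = 4), ", ",
      format(max(x$eff), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Read per-context codon efficiency tables
#'
#' Delimited text (TSV or CSV, chosen by file extension) with a first
#' column `codon` and one numeric column per tissue/cell context.  Each
#' context column becomes one [efficiency_table()], in column order.
#'
#' @param path File path; `.csv` is comma-separated, anything else
#'   tab-separated.
#' @param context_class Class recorded on every table from this file,
#'   mirroring the two-file tissue/cell layout of per-context atlases.
#' @return List of [efficiency_table()] objects.
#' @export
read_efficiency_tables <- function(path, context_class = c("TISSUE", "CELL")) {
  context_class <- match.arg(context_class)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"codon" %in% tolower(names(df)))
    stop("efficiency file ", path, " has no 'codon' column")
  codon_col <- which(tolower(names(df)) == "codon")[1]
  contexts <- names(df)[-codon_col]
  if (length(contexts) == 0L) stop("efficiency file ", path, " has no context columns")
  codons <- toupper(df[[codon_col]])
  lapply(contexts, function(ctx) {
    vals <- df[[ctx]]
    if (!is.numeric(vals))
      stop("context '", ctx, "': non-numeric efficiency values")
    eff <- stats::setNames(vals, codons)
    efficiency_table(ctx, eff, context_class = context_class)
  })
}

#' Write efficiency tables to a TSV file
#'
#' @param tables List of [efficiency_table()] objects.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_efficiency_tables <- function(tables, path) {
  codons <- sense_codons()
  df <- data.frame(codon = codons, stringsAsFactors = FALSE)
  for (t in tables) df[[t$context_id]] <- unname(t$eff[codons])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize an efficiency table to relative adaptiveness
#'
#' Divides every value by the table maximum (tAI-style), so the best
#' codon has weight 1; codon ordering is preserved and the operation is
#' idempotent.  `style = "cai"` instead divides each codon by the
#' maximum within its synonymous family (CAI-style), for sensitivity
#' analysis.
#'
#' @param t An [efficiency_table()].
#' @param style `"tai"` (global maximum, default) or `"cai"`
#'   (per-amino-acid family maximum).
#' @return A normalized [efficiency_table()].
#' @export
relative_adaptiveness <- function(t, style = c("tai", "cai")) {
  style <- match.arg(style)
  eff <- t$eff
  if (style == "tai") {
    eff <- eff / max(eff)
  } else {
    fam <- translate_codon(names(eff))
    fam_max <- tapply(eff, fam, max)
    eff <- eff / fam_max[fam]
    names(eff) <- names(t$eff)
  }
  efficiency_table(t$context_id, eff, context_class = t$context_class)
}

#' Harmonic mean of a positive vector
#'
#' `n / sum(1/x)`; dominated by the smallest values, which is what makes
#' it suited to detecting translational bottlenecks.
#'
#' @param values Non-empty numeric vector, all values strictly positive.
#' @return The harmonic mean; always between `min(values)` and
#'   `max(values)` and never above the arithmetic mean.
#' @export
harmonic_mean <- function(values) {
  if (length(values) == 0L) stop("harmonic mean of an empty vector")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("harmonic mean requires strictly positive finite values")
  length(values) / sum(1 / values)
}

#' Codon and sliding-window speed profile of a sequence
#'
#' Looks up the efficiency of every sense codon (terminal stop
#' excluded), then slides a ribosome-sized window along the sequence at
#' stride one codon, scoring each window by the harmonic mean of the
#' codon efficiencies it covers.
#'
#' @param seq A [coding_sequence()] with at least `window_size` sense codons.
#' @param t An [efficiency_table()].
#' @param window_size Window width in codons; 9 by default, roughly the
#'   footprint of one ribosome.
#' @param exclude_start Drop the initiation codon from the profile.
#'   Initiation is kinetically distinct from elongation (the AUG is
#'   decoded by the initiator tRNA, which elongation-efficiency tables
#'   do not describe), so ramp detection profiles elongation codons
#'   only; the default keeps the full per-codon contract.  When set,
#'   `start_offset` is 1 and window `i` covers codons
#'   `(i + 1)..(i + window_size)` of the original sequence.
#' @return Object of class `speed_profile` with fields `codon_speeds`,
#'   `window_speeds` (length `n - window_size + 1`) and `start_offset`.
#' @export
codon_speed_profile <- function(seq, t, window_size = 9L, exclude_start = FALSE) {
  window_size <- as.integer(window_size)
  if (window_size < 1L) stop("window_size must be >= 1")
  codons <- sense_part(seq)
  offset <- 0L
  if (exclude_start && length(codons) > 1L) {
    codons <- codons[-1L]
    offset <- 1L
  }
  speeds <- t$eff[codons]
  if (anyNA(speeds))
    stop("sequence '", seq$id, "' contains codon(s) absent from table '",
         t$context_id, "'")
  speeds <- unname(speeds)
  n <- length(speeds)
  if (n < window_size)
    stop("gene too short for ramp analysis: ", n, " sense codons < window of ",
         window_size)
  inv <- 1 / speeds
  csum <- cumsum(c(0, inv))
  idx <- seq_len(n - window_size + 1L)
  window_speeds <- window_size / (csum[idx + window_size] - csum[idx])
  structure(
    list(seq_id = seq$id, context_id = t$context_id,
         codon_speeds = speeds, window_speeds = window_speeds,
         window_size = window_size, start_offset = offset),
    class = "speed_profile")
}

#' @export
print.speed_profile <- function(x, ...) {
  cat("<speed_profile> ", x$seq_id, " x ", x$context_id, ": ",
      length(x$codon_speeds), " codons, ", length(x$window_speeds),
      " windows of ", x$window_size, "\n", sep = "")
  invisible(x)
}

#' Plot a sliding-window speed profile
#'
#' @param x A `speed_profile`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.speed_profile <- function(x, ...) {
  graphics::plot(seq_along(x$window_speeds), x$window_speeds, type = "l",
                 xlab = "window start (codon)",
                 ylab = "harmonic-mean efficiency",
                 main = paste(x$seq_id, "x", x$context_id), ...)
  graphics::abline(h = harmonic_mean(x$codon_speeds), lty = 2, col = "grey40")
  invisible(x)
}
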