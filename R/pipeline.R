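# End-to-end orchestration: read a run configuration, sweep every
# variant across all contexts, and write report tables plus a manifest.

#' Build a run configuration
#'
#' Mirrors a flat key-value (YAML) config document 1:1; every field can
#' equally be given as a function argument, and a character path is
#' loaded as YAML first.
#'
#' @param config Named list or path to a YAML file.
#' @param ... Individual fields overriding the config document:
#'   `cds`, `tissue_efficiencies`, `cell_efficiencies`, `variants`,
#'   `exon_map`, `qpcr`, `elisa` (file paths); `out_dir`;
#'   `window_size`, `outlier_rule`, `outlier_k`, `min_ramp_windows`;
#'   `pairing_window`, `pairing_mode`; `seed`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(config = NULL, ...) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else
    if (is.null(config)) list() else config
  dots <- list(...)
  cfg[names(dots)] <- dots
  defaults <- list(window_size = 9L, outlier_rule = "IQR", outlier_k = NULL,
                   min_ramp_windows = 1L, pairing_window = 9L,
                   pairing_mode = "WINDOW", seed = 1L, out_dir = "ramp_out")
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (is.null(cfg$cds)) stop("run_config: 'cds' FASTA path is required")
  if (is.null(cfg$tissue_efficiencies) && is.null(cfg$cell_efficiencies))
    stop("run_config: at least one of 'tissue_efficiencies'/'cell_efficiencies' is required")
  structure(cfg, class = "run_config")
}

pipeline_log <- function(...) message("[rampvar] ", ...)

#' Run the variant ramp-effect pipeline
#'
#' For each variant in the variant table: annotates the coding
#' consequence, sweeps wildtype and mutant sequences across every
#' tissue/cell context, classifies the most severe ramp effect, and
#' computes codon-usage-bias reports.  When qPCR or ELISA CSVs are
#' supplied, the expression-statistics stage runs too.  Writes, under
#' `out_dir`: `ramp_calls.tsv` (every isoform x context call, wildtype
#' and mutant), `variant_effects.tsv` (one row per variant with the
#' transcripts-with-ramp fraction, consequence and most severe effect,
#' plus any pass-through annotation columns), `wt_ramp_contexts.tsv`
#' (contexts with a wildtype ramp, split by context class),
#' `bias_report.tsv`, optional `expression_summary.csv` /
#' `elisa_summary.csv`, and `manifest.json` recording the seed,
#' parameters, package version and the number of ramp-detection calls.
#' Any stage error removes partial outputs before propagating.
#'
#' @param cfg A [run_config()] (or anything accepted by it).
#' @return Report bundle (named list of tables, effects and paths),
#'   invisibly.
#' @export
run_ramp_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  out_dir <- cfg$out_dir
  created <- !dir.exists(out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  tryCatch({
    p <- ramp_params(cfg$window_size, cfg$outlier_rule, cfg$outlier_k,
                     cfg$min_ramp_windows)
    pipeline_log("stage: read inputs")
    isoforms <- read_cds_fasta(cfg$cds)
    tables <- c(
      if (!is.null(cfg$tissue_efficiencies))
        read_efficiency_tables(cfg$tissue_efficiencies, "TISSUE") else list(),
      if (!is.null(cfg$cell_efficiencies))
        read_efficiency_tables(cfg$cell_efficiencies, "CELL") else list())
    tables <- lapply(tables, relative_adaptiveness)
    exon_maps <- if (!is.null(cfg$exon_map)) read_exon_maps(cfg$exon_map) else NULL

    variants <- list(); annotations <- NULL
    if (!is.null(cfg$variants)) {
      vt <- read_variant_table(cfg$variants, exon_maps)
      variants <- vt$variants
      annotations <- vt$annotations
    }
    if (length(variants) == 0L)
      warning("empty variant table: variant-effect report will be empty")

    pipeline_log("stage: variant sweeps (", length(variants), " variant(s) x ",
                 length(tables), " context(s))")
    effects <- list()
    call_rows <- list()
    effect_rows <- list()
    n_calls_total <- 0L
    for (v in variants) {
      eff <- sweep_contexts(isoforms, v, tables, p)
      effects[[v$id]] <- eff
      n_calls_total <- n_calls_total + eff$n_detect_calls
      frac <- isoform_ramp_fraction(
        isoforms[vapply(isoforms, function(s) s$id, character(1)) == v$transcript_id],
        tables, p)
      effect_rows[[v$id]] <- data.frame(
        variant_id = eff$variant_id,
        transcript_id = v$transcript_id,
        transcripts_with_ramp = frac$label,
        consequence = eff$variant$consequence,
        most_severe_ramp_effect = format_ramp_effect(eff$category),
        n_contexts_affected = eff$n_contexts_affected,
        variant_in_ramp = eff$variant_in_ramp,
        stringsAsFactors = FALSE)
      pc <- eff$per_context
      pc$variant_id <- eff$variant_id
      call_rows[[v$id]] <- pc
      pipeline_log("  ", v$id, ": ", format_ramp_effect(eff$category),
                   " (", eff$n_detect_calls, " detect_ramp calls)")
    }

    effect_table <- if (length(effect_rows)) do.call(rbind, effect_rows) else
      data.frame(variant_id = character(0), transcript_id = character(0),
                 transcripts_with_ramp = character(0), consequence = character(0),
                 most_severe_ramp_effect = character(0),
                 n_contexts_affected = integer(0), variant_in_ramp = logical(0))
    if (!is.null(annotations) && nrow(effect_table))
      effect_table <- merge(effect_table, annotations, by = "variant_id", sort = FALSE)
    call_table <- if (length(call_rows)) do.call(rbind, call_rows) else NULL

    # contexts with a wildtype ramp, by class (per isoform union)
    pipeline_log("stage: wildtype ramp contexts")
    wt_rows <- list()
    for (s in isoforms) {
      for (t in tables) {
        cl <- detect_ramp(s, t, p)
        if (cl$present)
          wt_rows[[length(wt_rows) + 1L]] <- data.frame(
            seq_id = s$id, context_id = t$context_id,
            context_class = t$context_class, ramp_end_codon = cl$ramp_end_codon,
            stringsAsFactors = FALSE)
      }
    }
    wt_table <- if (length(wt_rows)) do.call(rbind, wt_rows) else
      data.frame(seq_id = character(0), context_id = character(0),
                 context_class = character(0), ramp_end_codon = integer(0))

    pipeline_log("stage: codon bias")
    usage <- if (length(tables)) tables[[1]] else NULL
    bias_rows <- list()
    for (s in isoforms) {
      wt_bias <- bias_report(s, usage, cfg$pairing_window, cfg$pairing_mode)
      bias_rows[[s$id]] <- data.frame(
        seq_id = s$id, variant_id = "", gc_fraction = wt_bias$gc_fraction,
        total_pairing = wt_bias$total_pairing,
        averted_codons = paste(wt_bias$averted_codons, collapse = ","),
        stringsAsFactors = FALSE)
      for (v in variants) {
        if (v$transcript_id != s$id) next
        mut <- apply_variant(s, v)
        mb <- bias_report(mut, usage, cfg$pairing_window, cfg$pairing_mode)
        bias_rows[[paste(s$id, v$id)]] <- data.frame(
          seq_id = mut$id, variant_id = v$id, gc_fraction = mb$gc_fraction,
          total_pairing = mb$total_pairing,
          averted_codons = paste(mb$averted_codons, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
    bias_table <- do.call(rbind, bias_rows)

    expr_res <- NULL
    if (!is.null(cfg$qpcr)) {
      pipeline_log("stage: qPCR ddCt analysis")
      expr_res <- analyze_qpcr(read_qpcr_csv(cfg$qpcr))
    }
    elisa_res <- NULL
    if (!is.null(cfg$elisa)) {
      pipeline_log("stage: ELISA analysis")
      elisa_res <- analyze_elisa(read_elisa_csv(cfg$elisa))
    }

    pipeline_log("stage: write outputs -> ", out_dir)
    wr <- function(df, name, csv = FALSE) {
      path <- file.path(out_dir, name)
      if (csv) utils::write.csv(df, path, row.names = FALSE)
      else utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
      written <<- c(written, path)
      path
    }
    wr(effect_table, "variant_effects.tsv")
    wr(wt_table, "wt_ramp_contexts.tsv")
    if (!is.null(call_table)) wr(call_table, "ramp_calls.tsv")
    wr(bias_table, "bias_report.tsv")
    if (!is.null(expr_res)) wr(summary(expr_res), "expression_summary.csv", csv = TRUE)
    if (!is.null(elisa_res))
      wr(as.data.frame(elisa_res[c("mean_wt", "mean_mut", "ratio_wt_over_mut",
                                   "statistic", "p_value")]),
         "elisa_summary.csv", csv = TRUE)

    manifest <- list(
      package = "rampvar",
      version = as.character(utils::packageVersion("rampvar")),
      seed = cfg$seed,
      params = list(window_size = cfg$window_size, outlier_rule = cfg$outlier_rule,
                    outlier_k = ramp_params(cfg$window_size, cfg$outlier_rule,
                                            cfg$outlier_k)$outlier_k,
                    min_ramp_windows = cfg$min_ramp_windows,
                    pairing_window = cfg$pairing_window,
                    pairing_mode = cfg$pairing_mode),
      n_isoforms = length(isoforms),
      n_contexts = length(tables),
      n_variants = length(variants),
      n_detect_calls = stats::setNames(
        lapply(effects, function(e) e$n_detect_calls), names(effects)),
      n_detect_calls_total = n_calls_total)
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
    written <- c(written, manifest_path)

    invisible(list(effects = effects, effect_table = effect_table,
                   wt_ramp_contexts = wt_table, ramp_calls = call_table,
                   bias_table = bias_table, expression = expr_res,
                   elisa = elisa_res, manifest = manifest, paths = written))
  }, error = function(e) {
    # a failed stage must not leave partial outputs behind
    unlink(written)
    if (created) unlink(out_dir, recursive = TRUE)
    stop(e)
  })
}

#' Plot wildtype vs. mutant window-speed profiles
#'
#' Draws both sliding-window adaptiveness profiles against codon index
#' with the wildtype gene-wide harmonic mean as a guide line, and writes
#' a PNG.  Both profiles must come from the same context and window
#' size.
#'
#' @param wt,mut `speed_profile` objects.
#' @param out Output PNG path.
#' @return Invisibly, the plotted data (codon index and both window
#'   speed vectors) for downstream assertions.
#' @export
render_adaptiveness_plot <- function(wt, mut, out) {
  if (wt$context_id != mut$context_id)
    stop("profiles come from different contexts: ", wt$context_id,
         " vs ", mut$context_id)
  if (wt$window_size != mut$window_size)
    stop("profiles use different window sizes")
  n <- max(length(wt$window_speeds), length(mut$window_speeds))
  grDevices::png(out, width = 900, height = 500)
  on.exit(grDevices::dev.off())
  graphics::matplot(seq_len(n),
                    cbind(wt$window_speeds[seq_len(n)], mut$window_speeds[seq_len(n)]),
                    type = "l", lty = 1, lwd = 2, col = c("grey25", "firebrick"),
                    xlab = "window start (codon index)",
                    ylab = "harmonic-mean relative adaptiveness",
                    main = paste0(wt$seq_id, " vs ", mut$seq_id, " (", wt$context_id, ")"))
  graphics::abline(h = harmonic_mean(wt$codon_speeds), lty = 2, col = "grey50")
  graphics::legend("bottomright", c("wildtype", "mutant", "wildtype gene speed"),
                   lty = c(1, 1, 2), lwd = c(2, 2, 1),
                   col = c("grey25", "firebrick", "grey50"), bty = "n")
  invisible(list(window = seq_len(n), wt = wt$window_speeds, mut = mut$window_speeds))
}
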