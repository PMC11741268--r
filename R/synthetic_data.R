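# Synthetic inputs with controllable ground truth: per-context codon
# efficiency tables, CDSs with planted 5' ramps, ramp-destroying
# synonymous variants, and replicate-structured qPCR / ELISA data.
# Every generator is a pure function of (seed, parameters).

#' Configuration for the synthetic-data generators
#'
#' Defaults encode the study conditions the pipeline is validated
#' against: a 3 biological x 8 technical replicate qPCR design, a
#' planted log2 expression effect of 7 (the scale of a ~130-fold
#' knockdown), technical Ct noise of 0.3 cycles, log-normal codon
#' efficiencies with unit dispersion, and a 15-codon slow prefix at a
#' slow/fast efficiency ratio of 0.2 inside a 200-codon CDS.
#'
#' @param seed Integer master seed; all generators derive their
#'   randomness from it.
#' @param n_contexts Number of efficiency-table contexts to emit.
#' @param efficiency_dispersion Log-scale SD of codon efficiencies (>= 0).
#' @param cds_length Total CDS length in codons, start and stop included.
#' @param ramp_length Planted slow-codon prefix length in codons.
#' @param slow_fast_ratio Required ratio of slow-pool to fast-pool mean
#'   efficiency, in (0, 1).
#' @param qpcr_log2fc Planted log2 expression difference
#'   (mutant delta-Ct minus wildtype delta-Ct).
#' @param qpcr_noise_sd Technical Ct noise SD, in cycles.
#' @param qpcr_bio_sd SD of the shared biological-replicate baseline
#'   shift, in cycles (0 by default: wells are exchangeable, matching
#'   the per-well analysis convention).
#' @param qpcr_delta0 Baseline wildtype delta-Ct (target minus
#'   housekeeping), in cycles.
#' @param n_bio,n_tech Biological and technical replicates per group.
#' @param elisa_ratio Planted wildtype/mutant normalized-concentration
#'   ratio.
#' @param elisa_cv Coefficient of variation of ELISA replicates.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_contexts = 10L, efficiency_dispersion = 1.0,
                         cds_length = 200L, ramp_length = 15L,
                         slow_fast_ratio = 0.2, qpcr_log2fc = 7.0,
                         qpcr_noise_sd = 0.3, qpcr_bio_sd = 0.0,
                         qpcr_delta0 = 5.0, n_bio = 3L, n_tech = 8L,
                         elisa_ratio = 1.1635, elisa_cv = 0.08) {
  stopifnot(n_contexts >= 1, cds_length >= 1, ramp_length >= 1,
            n_bio >= 1, n_tech >= 1,
            efficiency_dispersion >= 0, slow_fast_ratio > 0, slow_fast_ratio < 1,
            qpcr_noise_sd >= 0, qpcr_bio_sd >= 0)
  structure(
    list(seed = as.integer(seed), n_contexts = as.integer(n_contexts),
         efficiency_dispersion = efficiency_dispersion,
         cds_length = as.integer(cds_length), ramp_length = as.integer(ramp_length),
         slow_fast_ratio = slow_fast_ratio, qpcr_log2fc = qpcr_log2fc,
         qpcr_noise_sd = qpcr_noise_sd, qpcr_bio_sd = qpcr_bio_sd,
         qpcr_delta0 = qpcr_delta0, n_bio = as.integer(n_bio),
         n_tech = as.integer(n_tech), elisa_ratio = elisa_ratio,
         elisa_cv = elisa_cv),
    class = "synth_config")
}

# Small deterministic string hash (for per-context substreams).
str_hash <- function(s) {
  h <- 0L
  for (x in utf8ToInt(s)) h <- (h * 31L + x) %% 1048573L
  h
}

# Run expr under a derived seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

derive_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 7919 + str_hash(tag)) %% 2147483647)
}

#' Generate one per-context codon efficiency table
#'
#' Draws 61 strictly positive efficiencies log-normally
#' (`meanlog = 0`, `sdlog = efficiency_dispersion`) and normalizes to a
#' maximum of 1.  Deterministic given `(cfg$seed, context_id)`;
#' dispersion 0 gives the uniform table.
#'
#' @param cfg A [synth_config()].
#' @param context_id Context name (also salts the substream).
#' @param context_class `"TISSUE"` or `"CELL"`.
#' @return An [efficiency_table()].
#' @export
gen_efficiency_table <- function(cfg, context_id, context_class = "TISSUE") {
  vals <- with_seed(derive_seed(cfg$seed, paste0("efftab:", context_id)), {
    exp(stats::rnorm(61, 0, cfg$efficiency_dispersion))
  })
  eff <- stats::setNames(vals / max(vals), sense_codons())
  efficiency_table(context_id, eff, context_class = context_class)
}

# Slow/fast quartile codon pools of a table; errors when too uniform.
codon_pools <- function(table, slow_fast_ratio) {
  eff <- table$eff
  q <- stats::quantile(eff, c(0.25, 0.75), names = FALSE)
  slow <- names(eff)[eff <= q[1]]
  fast <- names(eff)[eff >= q[2]]
  if (mean(eff[slow]) > slow_fast_ratio * mean(eff[fast]))
    stop("efficiency table '", table$context_id,
         "' is too uniform to separate slow and fast codon quartiles at ratio ",
         slow_fast_ratio, "; increase the dispersion")
  list(slow = slow, fast = fast)
}

#' Generate a CDS with (or without) a planted 5' ramp
#'
#' When `plant = TRUE` the first `ramp_length` codons (after the ATG
#' start) are drawn from the slowest quartile of the table and the rest
#' of the body from the fastest quartile, giving an unambiguous
#' slow-prefix ground truth; when `FALSE` the whole body is fast — the
#' matched no-ramp control.  The sequence starts with ATG, ends with a
#' stop, and contains no internal stops (the pools hold sense codons
#' only).  Deterministic given the seed.
#'
#' @param cfg A [synth_config()]; `cds_length` must exceed
#'   `ramp_length` plus one ribosome window.
#' @param table An [efficiency_table()].
#' @param plant Plant a ramp?
#' @param id Sequence id.
#' @return List with `seq` (a [coding_sequence()]) and `truth`
#'   (`ramp_length` when planted, 0 otherwise).
#' @export
gen_cds_with_planted_ramp <- function(cfg, table, plant = TRUE,
                                      id = if (plant) "planted_ramp" else "no_ramp") {
  if (cfg$cds_length <= cfg$ramp_length + 10L)
    stop("cds_length must exceed ramp_length + one window")
  pools <- codon_pools(table, cfg$slow_fast_ratio)
  n_body <- cfg$cds_length - 2L  # minus ATG and stop
  codons <- with_seed(derive_seed(cfg$seed, paste0("cds:", id, ":", table$context_id)), {
    if (plant) {
      n_slow <- cfg$ramp_length - 1L  # ATG occupies codon 1 of the ramp
      c(sample(pools$slow, n_slow, replace = TRUE),
        sample(pools$fast, n_body - n_slow, replace = TRUE))
    } else {
      sample(pools$fast, n_body, replace = TRUE)
    }
  })
  seq <- coding_sequence(id, c("ATG", codons, "TAA"), source = "synthetic")
  list(seq = seq, truth = if (plant) cfg$ramp_length else 0L)
}

#' Generate a CDS whose ramp hinges on a single slow codon
#'
#' Emulates the marginal-ramp situation a ramp-destroying synonymous
#' SNV exploits: the body is drawn from the fastest codon quartile, and
#' one very slow codon placed near the 5' end carries the entire
#' bottleneck, so every window covering it is a low outlier.  The slow
#' codon is chosen, deterministically, as the slowest-quartile codon
#' with the largest single-nucleotide synonymous efficiency gain — so
#' [gen_synonymous_variant()] with `RAMP_DESTROYING` targets exactly
#' this codon and the resulting mutant has no ramp.
#'
#' @param cfg A [synth_config()].
#' @param table An [efficiency_table()].
#' @param slow_pos Codon index of the planted slow codon (2..window).
#' @param id Sequence id.
#' @return List with `seq`, `slow_pos` and `slow_codon`.
#' @export
gen_cds_fragile_ramp <- function(cfg, table, slow_pos = 5L, id = "fragile_ramp") {
  if (slow_pos < 2L || slow_pos > 9L) stop("slow_pos must lie in codons 2..9")
  pools <- codon_pools(table, cfg$slow_fast_ratio)
  # slow codon must admit a synonymous single-nt swap with a large gain
  best <- NULL
  for (cd in pools$slow) {
    tmp <- coding_sequence("probe", c(cd, "TAA"))
    sw <- synonymous_swaps_5prime(tmp, table, 1L)
    if (length(sw) == 0L) next
    gain <- max(vapply(sw, function(s) s$delta, numeric(1)))
    if (is.null(best) || gain > best$gain) best <- list(codon = cd, gain = gain)
  }
  if (is.null(best) || best$gain <= 0)
    stop("no slow-quartile codon admits a synonymous efficiency-raising swap; ",
         "increase the dispersion")
  # first-window body codons must not out-gain the slow codon, so the
  # maximal synonymous swap is the one that removes the bottleneck
  no_gain <- Filter(function(cd) {
    sw <- synonymous_swaps_5prime(coding_sequence("probe", c(cd, "TAA")), table, 1L)
    length(sw) == 0L || max(vapply(sw, function(s) s$delta, numeric(1))) <= 0
  }, pools$fast)
  if (length(no_gain) == 0L)
    stop("no fast-quartile codon is a local efficiency maximum; increase dispersion")
  n_body <- cfg$cds_length - 2L
  body <- with_seed(derive_seed(cfg$seed, paste0("fragile:", id)), {
    b <- sample(pools$fast, n_body, replace = TRUE)
    b[seq_len(8L)] <- sample(no_gain, 8L, replace = TRUE)
    b
  })
  body[slow_pos - 1L] <- best$codon
  list(seq = coding_sequence(id, c("ATG", body, "TAA"), source = "synthetic"),
       slow_pos = slow_pos, slow_codon = best$codon)
}

# All synonymous single-nucleotide swaps of the first `region` codons,
# with their efficiency deltas under `table`.
synonymous_swaps_5prime <- function(seq, table, region) {
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (ci in seq_len(min(region, length(sense_part(seq))))) {
    codon <- seq$codons[ci]
    for (off in 1:3) {
      ref <- substr(codon, off, off)
      for (alt in setdiff(bases, ref)) {
        alt_codon <- codon
        substr(alt_codon, off, off) <- alt
        if (alt_codon %in% STOP_CODONS) next
        if (translate_codon(alt_codon) != translate_codon(codon)) next
        out[[length(out) + 1L]] <- list(
          codon_idx = ci, cds_pos = (ci - 1L) * 3L + off,
          ref = ref, alt = alt,
          delta = unname(table$eff[alt_codon] - table$eff[codon]))
      }
    }
  }
  out
}

#' Generate a synonymous variant targeting the 5' window
#'
#' Enumerates every synonymous single-nucleotide swap among the first
#' `region` codons.  `RAMP_DESTROYING` picks the swap with the largest
#' strict increase in codon efficiency (raising the 5' window's
#' harmonic-mean speed); `NEUTRAL` picks a swap whose reference and
#' alternate codons have identical efficiency, leaving every window
#' speed unchanged.
#'
#' @param seq A [coding_sequence()].
#' @param table An [efficiency_table()].
#' @param target `"RAMP_DESTROYING"` or `"NEUTRAL"`.
#' @param region Codon span searched at the 5' end (default 9, one
#'   ribosome window).
#' @return A [variant_spec()] with consequence `SYNONYMOUS`.
#' @export
gen_synonymous_variant <- function(seq, table,
                                   target = c("RAMP_DESTROYING", "NEUTRAL"),
                                   region = 9L) {
  target <- match.arg(target)
  swaps <- synonymous_swaps_5prime(seq, table, region)
  if (target == "RAMP_DESTROYING") {
    deltas <- vapply(swaps, function(s) s$delta, numeric(1))
    if (length(swaps) == 0L || max(deltas) <= 0)
      stop("no synonymous swap in the first ", region,
           " codons increases efficiency; cannot build a ramp-destroying variant")
    pick <- swaps[[which.max(deltas)]]
  } else {
    eq <- Filter(function(s) s$delta == 0, swaps)
    if (length(eq) == 0L)
      stop("no efficiency-neutral synonymous swap in the first ", region, " codons")
    pick <- eq[[1L]]
  }
  v <- variant_spec(
    id = sprintf("syn_%s_c%d%s>%s", tolower(target), pick$cds_pos, pick$ref, pick$alt),
    transcript_id = seq$id, cds_pos = pick$cds_pos, ref = pick$ref, alt = pick$alt)
  annotate_consequence(seq, v)
}

#' Generate a replicate-structured qPCR dataset
#'
#' Two groups (wildtype, mutant) of `n_bio x n_tech` wells.  Each well's
#' housekeeping Ct is drawn from Normal(20, 0.2); the true delta-Ct is
#' the wildtype baseline (`qpcr_delta0` plus a biological-replicate
#' shift of SD `qpcr_bio_sd`) plus `qpcr_log2fc` for the mutant group;
#' the target Ct adds technical noise of SD `qpcr_noise_sd` on top, so
#' per-well delta-Ct noise equals the technical SD exactly.
#' Deterministic given the seed.
#'
#' @param cfg A [synth_config()].
#' @return A [qpcr_dataset()] with `2 * n_bio * n_tech` rows.
#' @export
gen_qpcr_dataset <- function(cfg) {
  with_seed(derive_seed(cfg$seed, "qpcr"), {
    rows <- expand.grid(tech_rep = seq_len(cfg$n_tech),
                        bio_rep = seq_len(cfg$n_bio),
                        group = c("WILDTYPE", "MUTANT"),
                        stringsAsFactors = FALSE)
    bio_shift <- stats::rnorm(2L * cfg$n_bio, 0, cfg$qpcr_bio_sd)
    names(bio_shift) <- paste(rep(c("WILDTYPE", "MUTANT"), each = cfg$n_bio),
                              rep(seq_len(cfg$n_bio), 2L))
    dtrue <- cfg$qpcr_delta0 +
      bio_shift[paste(rows$group, rows$bio_rep)] +
      ifelse(rows$group == "MUTANT", cfg$qpcr_log2fc, 0)
    ct_hk <- stats::rnorm(nrow(rows), 20, 0.2)
    ct_t <- ct_hk + dtrue + stats::rnorm(nrow(rows), 0, cfg$qpcr_noise_sd)
    qpcr_dataset(rows$group, rows$bio_rep, rows$tech_rep, ct_t, ct_hk)
  })
}

#' Generate an ELISA dataset
#'
#' `n_bio x n_tech` replicates per group; the planted wildtype/mutant
#' normalized-concentration ratio is `elisa_ratio`, with log-normal
#' replicate noise of coefficient of variation `elisa_cv` and total
#' protein around 200 ug/mL.
#'
#' @param cfg A [synth_config()].
#' @return data.frame with columns `group`, `replicate`, `pilra_conc`,
#'   `total_protein`.
#' @export
gen_elisa_dataset <- function(cfg) {
  with_seed(derive_seed(cfg$seed, "elisa"), {
    n <- cfg$n_bio * cfg$n_tech
    sdlog <- sqrt(log(1 + cfg$elisa_cv^2))
    total <- stats::rnorm(2L * n, 200, 10)
    base <- 1000  # pg/mL at a normalized value of 5
    conc <- c(base * cfg$elisa_ratio * exp(stats::rnorm(n, 0, sdlog)),
              base * exp(stats::rnorm(n, 0, sdlog)))
    data.frame(group = rep(c("WILDTYPE", "MUTANT"), each = n),
               replicate = rep(seq_len(n), 2L),
               pilra_conc = conc * total / 200,
               total_protein = total,
               stringsAsFactors = FALSE)
  })
}

#' Write a complete synthetic toy study to disk
#'
#' Emits, under one seed, every input class the pipeline reads: a
#' wildtype CDS FASTA with a planted ramp, tissue and cell efficiency
#' tables sharing the ramp-supporting rank order, a ramp-destroying
#' synonymous variant TSV, and qPCR / ELISA CSVs.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if needed).
#' @param n_tissues,n_cells Number of tissue and cell-type contexts.
#' @return Named list of written file paths, invisibly.
#' @export
write_fixture_study <- function(cfg, dir, n_tissues = 62L, n_cells = 66L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- gen_efficiency_table(cfg, "context_base")
  # contexts perturb the base table mildly so all share its rank order
  jitter_table <- function(ctx, class) {
    vals <- with_seed(derive_seed(cfg$seed, paste0("jitter:", ctx)), {
      base$eff * exp(stats::rnorm(61, 0, 0.05))
    })
    efficiency_table(ctx, vals / max(vals), context_class = class)
  }
  tissues <- lapply(sprintf("tissue_%02d", seq_len(n_tissues)), jitter_table, class = "TISSUE")
  cells <- lapply(sprintf("cell_%02d", seq_len(n_cells)), jitter_table, class = "CELL")
  gen <- gen_cds_fragile_ramp(cfg, base, id = "synthetic_tx_1")
  v <- gen_synonymous_variant(gen$seq, base, "RAMP_DESTROYING")

  paths <- list(
    cds = file.path(dir, "cds.fasta"),
    tissues = file.path(dir, "tissue_efficiencies.tsv"),
    cells = file.path(dir, "cell_efficiencies.tsv"),
    variants = file.path(dir, "variants.tsv"),
    qpcr = file.path(dir, "qpcr.csv"),
    elisa = file.path(dir, "elisa.csv"))
  write_cds_fasta(list(gen$seq), paths$cds)
  write_efficiency_tables(tissues, paths$tissues)
  write_efficiency_tables(cells, paths$cells)
  vdf <- data.frame(variant_id = v$id, transcript_id = v$transcript_id,
                    coordinate_system = "cds", position = v$cds_pos,
                    ref = v$ref, alt = v$alt, stringsAsFactors = FALSE)
  utils::write.table(vdf, paths$variants, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(gen_qpcr_dataset(cfg), paths$qpcr, row.names = FALSE)
  utils::write.csv(gen_elisa_dataset(cfg), paths$elisa, row.names = FALSE)
  invisible(paths)
}
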