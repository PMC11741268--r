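test_that("generators are pure functions of seed and parameters", {
  cfg <- synth_config(seed = 51)
  expect_identical(gen_efficiency_table(cfg, "liver")$eff,
                   gen_efficiency_table(cfg, "liver")$eff)
  expect_false(identical(gen_efficiency_table(cfg, "liver")$eff,
                         gen_efficiency_table(cfg, "brain")$eff))
  cfg2 <- synth_config(seed = 52)
  expect_false(identical(gen_efficiency_table(cfg, "liver")$eff,
                         gen_efficiency_table(cfg2, "liver")$eff))

  t <- gen_efficiency_table(cfg, "liver")
  g1 <- gen_cds_with_planted_ramp(cfg, t)
  g2 <- gen_cds_with_planted_ramp(cfg, t)
  expect_identical(g1$seq$codons, g2$seq$codons)
  expect_identical(gen_qpcr_dataset(cfg), gen_qpcr_dataset(cfg))

  # generators do not disturb the caller's RNG stream
  set.seed(99); a <- runif(3)
  set.seed(99); invisible(gen_efficiency_table(cfg, "x")); b <- runif(3)
  expect_identical(a, b)
})

test_that("dispersion zero degenerates to the uniform table", {
  cfg <- synth_config(seed = 53, efficiency_dispersion = 0)
  t <- gen_efficiency_table(cfg, "flat")
  expect_equal(unname(t$eff), rep(1, 61))
  expect_error(gen_cds_with_planted_ramp(cfg, t), "increase the dispersion")
})

test_that("log-normal efficiencies have the generator's stated moments", {
  cfg <- synth_config(seed = 54, efficiency_dispersion = 1)
  # pool raw log-values across many contexts (undo the max-normalization
  # by centering each table's logs, which removes the per-table shift)
  z <- unlist(lapply(1:40, function(i) {
    lv <- log(gen_efficiency_table(cfg, paste0("c", i))$eff)
    lv - mean(lv)
  }))
  expect_equal(stats::sd(z), 1, tolerance = 0.08)
  expect_lt(abs(mean(z)), 1e-10)
})

test_that("planted CDSs honor their construction constraints", {
  cfg <- synth_config(seed = 55)
  t <- gen_efficiency_table(cfg, "ctx")
  g <- gen_cds_with_planted_ramp(cfg, t, plant = TRUE)
  s <- g$seq
  expect_equal(s$codons[1], "ATG")
  expect_true(s$has_stop)
  expect_equal(length(s$codons), cfg$cds_length)
  expect_false(any(s$codons[-length(s$codons)] %in% c("TAA", "TAG", "TGA")))
  aa <- translate_cds(s)
  expect_false(grepl("\\*", aa))
  expect_equal(g$truth, cfg$ramp_length)
  # slow prefix really is slow relative to the body
  sp <- t$eff[s$codons[2:cfg$ramp_length]]
  body <- t$eff[s$codons[(cfg$ramp_length + 1):(cfg$cds_length - 1)]]
  expect_lt(mean(sp), cfg$slow_fast_ratio * mean(body) + 1e-9)

  g0 <- gen_cds_with_planted_ramp(cfg, t, plant = FALSE)
  expect_equal(g0$truth, 0L)
  expect_error(gen_cds_with_planted_ramp(synth_config(seed = 55, cds_length = 20),
                                         t), "must exceed")
})

test_that("generated synonymous variants do what their target says", {
  cfg <- synth_config(seed = 56)
  t <- gen_efficiency_table(cfg, "ctx")
  g <- gen_cds_with_planted_ramp(cfg, t, plant = TRUE)
  v <- gen_synonymous_variant(g$seq, t, "RAMP_DESTROYING")
  expect_equal(v$consequence, "SYNONYMOUS")
  expect_equal(classify_consequence(g$seq, v), "SYNONYMOUS")
  # first-window speed strictly increases
  w_wt <- codon_speed_profile(g$seq, t, 9)$window_speeds[1]
  w_mut <- codon_speed_profile(apply_variant(g$seq, v), t, 9)$window_speeds[1]
  expect_gt(w_mut, w_wt)

  # neutral variants leave every window speed unchanged
  eff <- t$eff
  eff[c("GCT", "GCC")] <- 0.37  # force an equal-efficiency Ala pair
  t_eq <- efficiency_table("eq", eff)
  s <- coding_sequence("tx", c("ATG", "GCT", rep("AAA", 12), "TAA"))
  vn <- gen_synonymous_variant(s, t_eq, "NEUTRAL")
  expect_equal(vn$consequence, "SYNONYMOUS")
  expect_equal(codon_speed_profile(apply_variant(s, vn), t_eq, 9)$window_speeds,
               codon_speed_profile(s, t_eq, 9)$window_speeds)

  expect_error(gen_synonymous_variant(
    coding_sequence("tx", c("ATG", "TGG", "TAA")), t, "RAMP_DESTROYING"),
    "no synonymous swap")
})

test_that("fragile-ramp sequences lose their ramp under the generated variant", {
  for (seed in c(61, 62, 63)) {
    cfg <- synth_config(seed = seed)
    t <- gen_efficiency_table(cfg, "ctx")
    fr <- gen_cds_fragile_ramp(cfg, t)
    wt_call <- detect_ramp(fr$seq, t)
    expect_true(wt_call$present)
    v <- gen_synonymous_variant(fr$seq, t, "RAMP_DESTROYING")
    expect_equal(((v$cds_pos - 1) %/% 3) + 1, fr$slow_pos)
    mut_call <- detect_ramp(apply_variant(fr$seq, v), t)
    expect_equal(compare_ramp_calls(wt_call, mut_call), "LOSS")
  }
})

test_that("qPCR datasets carry the replicate structure and planted effect", {
  cfg <- synth_config(seed = 57)
  d <- gen_qpcr_dataset(cfg)
  expect_equal(nrow(d), 2 * 3 * 8)
  expect_equal(sort(unique(d$group)), c("MUTANT", "WILDTYPE"))
  expect_equal(max(d$bio_rep), 3)
  expect_equal(max(d$tech_rep), 8)
  dct <- delta_ct(d$ct_target, d$ct_housekeeping)
  gap <- mean(dct[d$group == "MUTANT"]) - mean(dct[d$group == "WILDTYPE"])
  expect_equal(gap, cfg$qpcr_log2fc, tolerance = 0.5)
})

test_that("a written fixture study is complete and readable by the pipeline", {
  cfg <- synth_config(seed = 58)
  dir <- tempfile("fixture")
  paths <- write_fixture_study(cfg, dir, n_tissues = 3, n_cells = 2)
  expect_true(all(file.exists(unlist(paths))))
  expect_length(read_cds_fasta(paths$cds), 1)
  expect_length(read_efficiency_tables(paths$tissues), 3)
  expect_length(read_efficiency_tables(paths$cells, "CELL"), 2)
  vt <- read_variant_table(paths$variants)
  expect_length(vt$variants, 1)
  expect_s3_class(read_qpcr_csv(paths$qpcr), "qpcr_dataset")
  unlink(dir, recursive = TRUE)
})
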