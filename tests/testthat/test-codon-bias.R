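test_that("GC content is a nucleotide fraction including the stop codon", {
  expect_equal(gc_content(coding_sequence("x", "GGCCGC")), 1.0)
  expect_equal(gc_content(coding_sequence("x", "ATATAT")), 0.0)
  expect_equal(gc_content(coding_sequence("x", "ATGTAA")), 1 / 6)

  # any single T>C change raises GC by exactly 1/len
  set.seed(31)
  for (i in 1:10) {
    s <- random_cds(30)
    nt <- strsplit(paste(s$codons, collapse = ""), "")[[1]]
    tpos <- which(nt == "T")
    tpos <- tpos[tpos < length(nt) - 2]  # keep the stop codon intact
    if (length(tpos) == 0) next
    p <- sample(tpos, 1)
    v <- variant_spec("t2c", s$id, p, "T", "C")
    mut <- try(apply_variant(s, v), silent = TRUE)
    if (inherits(mut, "try-error")) next
    expect_equal(gc_content(mut) - gc_content(s), 1 / length(nt))
  }
})

test_that("identical codon pairing chains nearest-previous occurrences", {
  s3 <- coding_sequence("x", c("CTG", "CTG", "CTG"))
  p <- identical_codon_pairing(s3)
  expect_equal(unname(p$counts["CTG"]), 2L)
  expect_equal(p$total, 2L)

  far <- coding_sequence("x", c("CTG", rep("AAA", 9), "CTG"))
  p2 <- identical_codon_pairing(far, window = 9)
  expect_false("CTG" %in% names(p2$counts))  # distance 10 >= window
  expect_equal(unname(p2$counts["AAA"]), 8L)

  norep <- coding_sequence("x", c("ATG", "TTG", "GCA", "TAA"))
  expect_equal(identical_codon_pairing(norep)$total, 0L)

  # ADJACENT counts never exceed WINDOW counts; both match the naive oracle
  set.seed(32)
  for (i in 1:20) {
    s <- random_cds(sample(10:80, 1))
    w <- sample(2:12, 1)
    pw <- identical_codon_pairing(s, window = w, mode = "WINDOW")
    pa <- identical_codon_pairing(s, mode = "ADJACENT")
    expect_lte(pa$total, pw$total)
    codons <- if (s$has_stop) s$codons[-length(s$codons)] else s$codons
    expect_equal(pw$total, oracle_pairing(codons, w))
    expect_equal(pa$total, oracle_pairing(codons, w, adjacent = TRUE))
  }
  expect_error(identical_codon_pairing(s3, window = 1), "window must be >= 2")
})

test_that("a synonymous swap changes pairing only for the two codons involved", {
  set.seed(33)
  for (i in 1:10) {
    s <- random_cds(50)
    sw <- NULL
    for (ci in 2:(length(s$codons) - 1)) {
      cd <- s$codons[ci]
      for (off in 1:3) for (alt in setdiff(c("A", "C", "G", "T"), substr(cd, off, off))) {
        alt_cd <- cd; substr(alt_cd, off, off) <- alt
        if (!alt_cd %in% sense_codons() || translate_codon(alt_cd) != translate_codon(cd)) next
        sw <- list(pos = (ci - 1) * 3 + off, ref = substr(cd, off, off), alt = alt,
                   ref_cd = cd, alt_cd = alt_cd)
        break
      }
      if (!is.null(sw)) break
    }
    if (is.null(sw)) next
    mut <- apply_variant(s, variant_spec("syn", s$id, sw$pos, sw$ref, sw$alt))
    pw <- identical_codon_pairing(s)$counts
    pm <- identical_codon_pairing(mut)$counts
    all_cd <- union(names(pw), names(pm))
    changed <- all_cd[vapply(all_cd, function(cd) {
      gw <- if (cd %in% names(pw)) pw[[cd]] else 0L
      gm <- if (cd %in% names(pm)) pm[[cd]] else 0L
      gw != gm
    }, logical(1))]
    expect_true(all(changed %in% c(sw$ref_cd, sw$alt_cd)))
  }
})

test_that("codon aversion is the complement of the codons used", {
  av <- codon_aversion_set(coding_sequence("x", "ATGTAA"))
  expect_setequal(av, setdiff(sense_codons(), "ATG"))

  all61 <- coding_sequence("x", c(sense_codons(), "TAA"))
  expect_length(codon_aversion_set(all61), 0)

  # synonymous mutant whose replaced codon occurs elsewhere: identical sets
  s <- coding_sequence("x", c("ATG", "TTG", "TTG", "GCA", "TAA"))
  mut <- apply_variant(s, variant_spec("v", "x", 4, "T", "C"))  # one TTG -> CTG
  expect_false(setequal(codon_aversion_set(s), codon_aversion_set(mut)))
  s2 <- coding_sequence("x", c("ATG", "TTG", "CTG", "TTG", "TAA"))
  mut2 <- apply_variant(s2, variant_spec("v", "x", 4, "T", "C"))
  expect_setequal(codon_aversion_set(s2), codon_aversion_set(mut2))
})

test_that("family ranks order codons within their synonymous family", {
  eff <- stats::setNames(rep(0.5, 61), sense_codons())
  eff["CTG"] <- 1.0   # most common Leu codon
  eff["TTG"] <- 0.1
  eff["AAA"] <- 0.3; eff["AAG"] <- 0.7
  t <- efficiency_table("usage", eff)
  expect_equal(codon_family_rank("CTG", t), list(rank = 1L, family_size = 6L))
  expect_gt(codon_family_rank("TTG", t)$rank, 1L)
  expect_equal(codon_family_rank("ATG", t), list(rank = 1L, family_size = 1L))
  expect_equal(codon_family_rank("AAA", t), list(rank = 2L, family_size = 2L))
  expect_error(codon_family_rank("TAA", t), "stop codon")

  # ties share the smaller rank
  expect_equal(codon_family_rank("GGA", t)$rank, 1L)  # all Gly at 0.5
})

test_that("bias reports and wildtype/mutant comparisons assemble cleanly", {
  s <- coding_sequence("wt", c("ATG", "TTG", "CTG", "CTG", "GCA", "TAA"))
  mut <- apply_variant(s, variant_spec("v", "wt", 4, "T", "C"))
  eff <- stats::setNames(runif(61, 0.1, 1), sense_codons())
  t <- efficiency_table("u", eff)
  bw <- bias_report(s, t, rank_codons = c("TTG", "CTG"))
  bm <- bias_report(mut, t, rank_codons = c("TTG", "CTG"))
  expect_s3_class(bw, "bias_report")
  expect_equal(nrow(bw$rank_table), 2)
  cmp <- compare_bias(bw, bm)
  expect_equal(unname(cmp$pairing_delta["CTG"]), 1L)  # CTG CTG -> CTG CTG CTG
  expect_equal(cmp$summary$gc_fraction[2] - cmp$summary$gc_fraction[1], 1 / 18)
})
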