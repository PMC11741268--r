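test_that("FASTA records are parsed, framed and validated", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">tx1 minimal", "ATGTTGTAA",
               ">tx2", paste(rep("ATGGCA", 5), collapse = ""),
               ">tx3", "ATGGCATAA"), fa)
  seqs <- read_cds_fasta(fa)
  expect_length(seqs, 3)
  expect_equal(seqs[[1]]$codons, c("ATG", "TTG", "TAA"))
  expect_true(seqs[[1]]$has_stop)
  expect_false(seqs[[2]]$has_stop)
  expect_equal(vapply(seqs, function(s) length(s$codons), integer(1)), c(3L, 10L, 3L))
  expect_equal(vapply(seqs, function(s) s$id, character(1)), c("tx1", "tx2", "tx3"))

  bad <- tempfile(fileext = ".fasta")
  writeLines(c(">frameshift", "ATGTTGTAAA"), bad)  # 10 nt
  expect_error(read_cds_fasta(bad), "multiple of 3")
  writeLines(c(">ambiguous", "ATGNNNTAA"), bad)
  expect_error(read_cds_fasta(bad), "invalid codon")
  writeLines(c(">internalstop", "ATGTAATTGTAA"), bad)
  expect_error(read_cds_fasta(bad), "internal stop")
})

test_that("variant application swaps exactly one base and is revertible", {
  s <- coding_sequence("tx", "ATGTTGGGCAAA")
  v <- variant_spec("v1", "tx", 4, "T", "C")
  mut <- apply_variant(s, v)
  expect_equal(mut$codons, c("ATG", "CTG", "GGC", "AAA"))
  expect_equal(s$codons[2], "TTG")  # input untouched
  nt_wt <- strsplit(paste(s$codons, collapse = ""), "")[[1]]
  nt_mut <- strsplit(paste(mut$codons, collapse = ""), "")[[1]]
  expect_equal(sum(nt_wt != nt_mut), 1)
  back <- apply_variant(mut, variant_spec("v1rev", "tx", 4, "C", "T"))
  expect_identical(back$codons, s$codons)

  expect_error(variant_spec("noop", "tx", 4, "T", "T"), "identical")
  expect_error(apply_variant(s, variant_spec("wrongref", "tx", 4, "G", "C")),
               "expected ref base")
  expect_error(apply_variant(s, variant_spec("far", "tx", 999, "T", "C")),
               "beyond CDS length")
  expect_error(apply_variant(s, variant_spec("wrongtx", "other", 4, "T", "C")),
               "targets transcript")
})

test_that("consequence classification matches the standard genetic code", {
  s <- coding_sequence("tx", "ATGTTGTGGAAA")
  expect_equal(classify_consequence(s, variant_spec("leu", "tx", 4, "T", "C")),
               "SYNONYMOUS")  # TTG -> CTG, both Leu
  expect_equal(classify_consequence(s, variant_spec("stopgain", "tx", 9, "G", "A")),
               "NONSENSE")    # TGG -> TGA
  expect_equal(classify_consequence(s, variant_spec("lys", "tx", 12, "A", "G")),
               "SYNONYMOUS")  # AAA -> AAG
  expect_equal(classify_consequence(s, variant_spec("mis", "tx", 10, "A", "G")),
               "MISSENSE")    # AAA -> GAA
})

test_that("synonymous consequence coincides exactly with protein identity", {
  # fuzz: every single-nucleotide change of every codon of random CDSs
  set.seed(101)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:5) {
    s <- random_cds(25)
    nt <- strsplit(paste(s$codons, collapse = ""), "")[[1]]
    for (pos in seq_len(length(nt) - 3)) {  # spare the stop codon
      for (alt in setdiff(bases, nt[pos])) {
        v <- variant_spec("f", s$id, pos, nt[pos], alt)
        mut <- try(apply_variant(s, v), silent = TRUE)
        if (inherits(mut, "try-error")) next  # internal stop created
        cons <- classify_consequence(s, v)
        same_protein <- identical(translate_cds(mut), translate_cds(s))
        expect_equal(cons == "SYNONYMOUS", same_protein)
      }
    }
  }
})

test_that("genomic positions project onto CDS coordinates on both strands", {
  em_plus <- exon_map("tx", "+", 101, 130)
  expect_equal(project_genomic_to_cds(101, em_plus), 1)
  expect_equal(project_genomic_to_cds(130, em_plus), 30)
  em_minus <- exon_map("tx", "-", 101, 130)
  expect_equal(project_genomic_to_cds(130, em_minus), 1)
  expect_equal(project_genomic_to_cds(101, em_minus), 30)

  em2 <- exon_map("tx", "+", c(101, 201), c(110, 210))
  expect_equal(project_genomic_to_cds(203, em2), 13)
  expect_error(project_genomic_to_cds(150, em2), "non-CDS position")

  # bijection onto 1..CDS-length, brute force over random exon maps
  set.seed(7)
  for (rep in 1:20) {
    n_ex <- sample(1:4, 1)
    widths <- sample(3:12, n_ex, replace = TRUE)
    gaps <- sample(1:50, n_ex, replace = TRUE)
    starts <- sample(100:200, 1) + cumsum(gaps) + c(0, cumsum(widths))[seq_len(n_ex)]
    ends <- starts + widths - 1
    strand <- sample(c("+", "-"), 1)
    em <- exon_map("tx", strand, starts, ends)
    gpos <- unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE))
    cds <- vapply(gpos, project_genomic_to_cds, numeric(1), emap = em)
    expect_setequal(cds, seq_len(exon_map_length(em)))
  }
})

test_that("variant tables round-trip, with genomic rows projected and complemented", {
  tsv <- tempfile(fileext = ".tsv")
  df <- data.frame(variant_id = c("v_cds", "v_gen"),
                   transcript_id = "tx", coordinate_system = c("cds", "genomic"),
                   position = c(4, 127), ref = c("T", "A"), alt = c("C", "G"),
                   CADD = c(4.238, 0.578))
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  em <- exon_map("tx", "-", 101, 130)  # gpos 127 -> cds 4, minus strand
  vt <- read_variant_table(tsv, exon_maps = list(tx = em))
  expect_length(vt$variants, 2)
  expect_equal(vt$variants[[2]]$cds_pos, 4L)
  expect_equal(vt$variants[[2]]$ref, "T")  # complemented from A
  expect_equal(vt$variants[[2]]$alt, "C")
  expect_equal(vt$annotations$CADD, df$CADD)
  expect_error(read_variant_table(tsv), "no exon map")
})
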