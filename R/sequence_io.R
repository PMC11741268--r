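# Coding-sequence containers, FASTA input, variant application and
# consequence annotation, genomic -> CDS coordinate projection.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' The 61 sense codons of the standard genetic code
#'
#' @return Character vector of the 61 DNA sense codons, alphabetical.
#' @export
sense_codons <- function() {
  all64 <- names(Biostrings::GENETIC_CODE)
  sort(setdiff(all64, STOP_CODONS))
}

#' Translate a codon under the standard genetic code
#'
#' @param codon Character vector of 3-mers over ACGT.
#' @return One-letter amino acids, `"*"` for stop.
#' @export
translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  if (anyNA(aa)) stop("not a DNA codon: ", paste(codon[is.na(aa)], collapse = ", "))
  unname(aa)
}

#' Construct a coding sequence
#'
#' A `coding_sequence` is an in-frame codon list: the unit all ramp and
#' codon-bias metrics operate on.  A terminal stop codon is retained but
#' flagged, and is excluded from all speed and bias profiles downstream
#' (efficiency tables cover only the 61 sense codons).  Internal stop
#' codons and ambiguity codes are rejected: they are not a valid curated
#' CDS and make codon speed undefined.
#'
#' @param id Transcript identifier.
#' @param sequence Nucleotide string (length a multiple of 3) or a
#'   character vector of codons.
#' @param source Free-text provenance.
#' @param allow_internal_stops Accept premature stop codons.  Curated
#'   input CDSs never carry them, but a nonsense SNV legitimately
#'   creates one, so variant application relaxes this check.
#' @return An object of class `coding_sequence` with fields `id`,
#'   `codons`, `source` and `has_stop` (terminal stop flag).
#' @examples
#' coding_sequence("tx1", "ATGTTGTAA")
#' @export
coding_sequence <- function(id, sequence, source = "", allow_internal_stops = FALSE) {
  if (length(sequence) == 1L && nchar(sequence) > 3L) {
    nt <- toupper(sequence)
    if (nchar(nt) %% 3L != 0L)
      stop("CDS '", id, "': length ", nchar(nt), " is not a multiple of 3")
    codons <- substring(nt, seq(1L, nchar(nt), 3L), seq(3L, nchar(nt), 3L))
  } else {
    codons <- toupper(as.character(sequence))
  }
  bad <- !codons %in% names(Biostrings::GENETIC_CODE)
  if (any(bad))
    stop("CDS '", id, "': invalid codon(s) ", paste(unique(codons[bad]), collapse = ", "),
         " (non-ACGT characters are rejected, not imputed)")
  n <- length(codons)
  internal_stop <- codons[-n] %in% STOP_CODONS
  if (any(internal_stop) && !allow_internal_stops)
    stop("CDS '", id, "': internal stop codon at codon ", which(internal_stop)[1])
  structure(
    list(id = id, codons = codons, source = source,
         has_stop = codons[n] %in% STOP_CODONS),
    class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat("<coding_sequence> ", x$id, ": ", length(x$codons), " codons",
      if (x$has_stop) " (terminal stop)" else " (no terminal stop)",
      "\n", sep = "")
  head_n <- min(8L, length(x$codons))
  cat("  ", paste(x$codons[seq_len(head_n)], collapse = " "),
      if (length(x$codons) > head_n) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.coding_sequence <- function(x) length(x$codons)

# Sense codons of a CDS (terminal stop dropped); the profile domain.
sense_part <- function(seq) {
  if (seq$has_stop) seq$codons[-length(seq$codons)] else seq$codons
}

#' Translate a coding sequence to protein
#'
#' @param seq A [coding_sequence()].
#' @param drop_stop Drop the terminal `*` if present (default `TRUE`).
#' @return Single amino-acid string.
#' @export
translate_cds <- function(seq, drop_stop = TRUE) {
  aa <- translate_codon(seq$codons)
  if (drop_stop && seq$has_stop) aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

#' Read coding sequences from a FASTA file
#'
#' Every record is validated as an in-frame CDS: length a multiple of 3,
#' only ACGT characters, no internal stop codons.
#'
#' @param path FASTA file (wrapped or unwrapped, multi-record).
#' @return List of [coding_sequence()] objects, record order preserved.
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) {
    coding_sequence(ids[i], as.character(set[[i]]), source = path)
  })
}

#' Write coding sequences to a FASTA file
#'
#' @param seqs List of [coding_sequence()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(seqs, path) {
  nt <- vapply(seqs, function(s) paste(s$codons, collapse = ""), character(1))
  set <- Biostrings::DNAStringSet(nt)
  names(set) <- vapply(seqs, function(s) s$id, character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Specify a single-nucleotide variant on a transcript
#'
#' @param id Variant name, e.g. `"rs2405442:T>C"`.
#' @param transcript_id Transcript the CDS position refers to.
#' @param cds_pos 1-based nucleotide position within the CDS.
#' @param ref,alt Single reference/alternate bases; must differ.
#' @return Object of class `variant_spec`; the `consequence` field is
#'   `"UNASSESSED"` until [classify_consequence()] is applied.
#' @export
variant_spec <- function(id, transcript_id, cds_pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!ref %in% c("A", "C", "G", "T") || !alt %in% c("A", "C", "G", "T"))
    stop("variant '", id, "': ref/alt must be single ACGT bases")
  if (ref == alt) stop("variant '", id, "': ref and alt are identical")
  cds_pos <- as.integer(cds_pos)
  if (is.na(cds_pos) || cds_pos < 1L) stop("variant '", id, "': invalid cds_pos")
  structure(
    list(id = id, transcript_id = transcript_id, cds_pos = cds_pos,
         ref = ref, alt = alt, consequence = "UNASSESSED"),
    class = "variant_spec")
}

#' @export
print.variant_spec <- function(x, ...) {
  cat("<variant_spec> ", x$id, " on ", x$transcript_id, ": c.", x$cds_pos,
      x$ref, ">", x$alt, " [", x$consequence, "]\n", sep = "")
  invisible(x)
}

# Codon index and within-codon offset of a CDS position.
codon_index_of <- function(cds_pos) ((cds_pos - 1L) %/% 3L) + 1L

#' Apply a single-nucleotide variant to a coding sequence
#'
#' Returns a new sequence with exactly one nucleotide changed; the input
#' is unchanged.  The base observed at `cds_pos` must equal `v$ref`.
#'
#' @param seq A [coding_sequence()].
#' @param v A [variant_spec()] with `transcript_id == seq$id`.
#' @return A new `coding_sequence` carrying the alternate allele.
#' @export
apply_variant <- function(seq, v) {
  if (v$transcript_id != seq$id)
    stop("variant '", v$id, "' targets transcript '", v$transcript_id,
         "', not '", seq$id, "'")
  n_nt <- 3L * length(seq$codons)
  if (v$cds_pos > n_nt)
    stop("variant '", v$id, "': cds_pos ", v$cds_pos,
         " beyond CDS length ", n_nt)
  ci <- codon_index_of(v$cds_pos)
  off <- ((v$cds_pos - 1L) %% 3L) + 1L
  codon <- seq$codons[ci]
  obs <- substr(codon, off, off)
  if (obs != v$ref)
    stop("variant '", v$id, "': expected ref base ", v$ref, " at CDS position ",
         v$cds_pos, " but observed ", obs)
  substr(codon, off, off) <- v$alt
  codons <- seq$codons
  codons[ci] <- codon
  coding_sequence(seq$id, codons, source = paste0(seq$source, " + ", v$id),
                  allow_internal_stops = TRUE)
}

#' Classify the coding consequence of a variant
#'
#' @param seq A [coding_sequence()].
#' @param v A [variant_spec()].
#' @return `"SYNONYMOUS"` if reference and alternate codons encode the
#'   same amino acid, `"NONSENSE"` if the alternate codon is a stop,
#'   `"MISSENSE"` otherwise.
#' @export
classify_consequence <- function(seq, v) {
  mut <- apply_variant(seq, v)
  ci <- codon_index_of(v$cds_pos)
  ref_aa <- translate_codon(seq$codons[ci])
  alt_aa <- translate_codon(mut$codons[ci])
  if (alt_aa == ref_aa) "SYNONYMOUS"
  else if (alt_aa == "*") "NONSENSE"
  else "MISSENSE"
}

#' Annotate a variant with its consequence
#'
#' @inheritParams classify_consequence
#' @return The variant with its `consequence` field filled in.
#' @export
annotate_consequence <- function(seq, v) {
  v$consequence <- classify_consequence(seq, v)
  v
}

#' Exon map of a transcript's CDS
#'
#' Holds the closed 1-based genomic intervals covering the CDS, in
#' transcription order, for projecting genomic SNV coordinates onto the
#' CDS.  On the minus strand, CDS positions count from the
#' transcription-start end; complementing ref/alt alleles for
#' minus-strand variants is the caller's duty (done by the pipeline
#' layer), keeping the projection itself pure.
#'
#' @param transcript_id Transcript identifier.
#' @param strand `"+"` or `"-"`.
#' @param starts,ends Equal-length integer vectors of closed 1-based
#'   interval bounds, in transcription order, non-overlapping.
#' @return Object of class `exon_map`.
#' @export
exon_map <- function(transcript_id, strand, starts, ends) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  starts <- as.integer(starts); ends <- as.integer(ends)
  if (length(starts) != length(ends) || length(starts) == 0L)
    stop("starts/ends must be equal-length, non-empty")
  if (any(ends < starts)) stop("exon end before start")
  ord <- order(starts)
  s <- starts[ord]; e <- ends[ord]
  if (any(s[-1] <= e[-length(e)])) stop("overlapping exons")
  structure(
    list(transcript_id = transcript_id, strand = strand,
         starts = starts, ends = ends),
    class = "exon_map")
}

#' Total CDS length covered by an exon map
#' @param emap An [exon_map()].
#' @return Integer nucleotide count.
#' @export
exon_map_length <- function(emap) sum(emap$ends - emap$starts + 1L)

#' Project a genomic position onto CDS coordinates
#'
#' @param gpos 1-based genomic position; must fall in an exon.
#' @param emap An [exon_map()].
#' @return 1-based CDS position.  On the minus strand positions count
#'   from the transcription-start (highest-coordinate) end.
#' @export
project_genomic_to_cds <- function(gpos, emap) {
  # genomic-coordinate order
  ord <- order(emap$starts)
  s <- emap$starts[ord]; e <- emap$ends[ord]
  hit <- which(gpos >= s & gpos <= e)
  if (length(hit) == 0L)
    stop("non-CDS position: ", gpos, " falls outside all exons of ",
         emap$transcript_id)
  widths <- e - s + 1L
  if (emap$strand == "+") {
    before <- if (hit > 1L) sum(widths[seq_len(hit - 1L)]) else 0L
    before + (gpos - s[hit]) + 1L
  } else {
    after <- if (hit < length(s)) sum(widths[seq(hit + 1L, length(s))]) else 0L
    after + (e[hit] - gpos) + 1L
  }
}

#' Complement of a DNA base
#' @param base Character vector of ACGT bases.
#' @return Complemented bases.
#' @export
complement_base <- function(base) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- comp[toupper(base)]
  if (anyNA(out)) stop("not an ACGT base: ", paste(base[is.na(out)], collapse = ","))
  unname(out)
}

#' Read a variant table
#'
#' Expects a TSV with columns `variant_id`, `transcript_id`,
#' `coordinate_system` (`cds` or `genomic`), `position`, `ref`, `alt`.
#' Any additional columns (e.g. MAF, CADD, GERP, RegulomeDB) are carried
#' through verbatim as annotation.  Genomic coordinates require an exon
#' map per transcript; minus-strand alleles are complemented here.
#'
#' @param path TSV file path.
#' @param exon_maps Optional named list of [exon_map()] objects keyed by
#'   transcript id, required for rows with `coordinate_system == "genomic"`.
#' @return List with `variants` (list of [variant_spec()]) and
#'   `annotations` (data.frame of pass-through columns, one row per variant).
#' @export
read_variant_table <- function(path, exon_maps = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = c(ref = "character", alt = "character"))
  need <- c("variant_id", "transcript_id", "coordinate_system", "position", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("variant table missing column(s): ", paste(miss, collapse = ", "))
  variants <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    cs <- tolower(df$coordinate_system[i])
    ref <- df$ref[i]; alt <- df$alt[i]; pos <- df$position[i]
    if (cs == "genomic") {
      emap <- exon_maps[[df$transcript_id[i]]]
      if (is.null(emap))
        stop("variant '", df$variant_id[i], "' uses genomic coordinates but no exon map",
             " was supplied for transcript ", df$transcript_id[i])
      pos <- project_genomic_to_cds(pos, emap)
      if (emap$strand == "-") {
        ref <- complement_base(ref); alt <- complement_base(alt)
      }
    } else if (cs != "cds") {
      stop("variant '", df$variant_id[i], "': unknown coordinate_system '", cs, "'")
    }
    variants[[i]] <- variant_spec(df$variant_id[i], df$transcript_id[i], pos, ref, alt)
  }
  ann <- df[, setdiff(names(df), need), drop = FALSE]
  ann <- cbind(data.frame(variant_id = df$variant_id, stringsAsFactors = FALSE), ann)
  list(variants = variants, annotations = ann)
}

#' Read an exon-map table
#'
#' BED-like TSV with columns `transcript_id`, `strand`, `start`, `end`,
#' one exon interval per row (closed, 1-based), rows in transcription
#' order within each transcript.
#'
#' @param path TSV file path.
#' @return Named list of [exon_map()] objects keyed by transcript id.
#' @export
read_exon_maps <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "strand", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("exon map missing column(s): ", paste(miss, collapse = ", "))
  out <- lapply(split(df, df$transcript_id), function(d) {
    exon_map(d$transcript_id[1], d$strand[1], d$start, d$end)
  })
  out
}
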