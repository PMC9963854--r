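#' Read alignments from a SAM or BAM file
#'
#' SAM text is parsed directly; `.bam` files are read through
#' `Rsamtools::scanBam()`. Only the eleven mandatory fields are kept.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return A tibble of SAM fields (`qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `rnext`, `pnext`, `tlen`, `seq`, `qual`).
#' @export
read_alignments <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      abort("Reading BAM requires the Rsamtools package.")
    }
    b <- Rsamtools::scanBam(path)[[1]]
    return(tibble(
      qname = b$qname,
      flag = as.integer(b$flag),
      rname = as.character(b$rname),
      pos = as.integer(b$pos),
      mapq = as.integer(b$mapq),
      cigar = b$cigar,
      rnext = as.character(b$mrnm),
      pnext = as.integer(b$mpos),
      tlen = as.integer(b$isize),
      seq = as.character(b$seq),
      qual = as.character(b$qual)
    ))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(tibble(qname = character(), flag = integer(), rname = character(),
                  pos = integer(), mapq = integer(), cigar = character(),
                  rnext = character(), pnext = integer(), tlen = integer(),
                  seq = character(), qual = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  field <- function(i) vapply(parts, `[[`, character(1), i)
  tibble(
    qname = field(1), flag = as.integer(field(2)), rname = field(3),
    pos = as.integer(field(4)), mapq = as.integer(field(5)),
    cigar = field(6), rnext = field(7), pnext = as.integer(field(8)),
    tlen = as.integer(field(9)), seq = field(10), qual = field(11)
  )
}

#' Write alignments as a SAM file
#'
#' @param reads Tibble of SAM fields (as produced by [simulate_reads()]);
#'   an optional `sample_id` column is dropped.
#' @param path Output path.
#' @param reference Named character vector of reference sequences used to
#'   emit `@SQ` header lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, reference) {
  reads <- reads[setdiff(names(reads),
                         c("sample_id"))][, c("qname", "flag", "rname", "pos",
                                              "mapq", "cigar", "rnext",
                                              "pnext", "tlen", "seq", "qual")]
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(reference), nchar(reference)))
  body <- do.call(paste, c(as.list(reads), sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write reference sequences as FASTA
#'
#' @param reference Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reference), path)
  invisible(path)
}

#' Write gene models as BED6
#'
#' Standard BED6 (0-based half-open; `name` = gene id, score 0). Imprinting
#' flags and locus membership are deliberately not packed into BED columns;
#' write them with [write_gene_annotation()] instead.
#'
#' @param models Gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(models, path) {
  readr::write_tsv(
    tibble(chrom = models$chromosome, start = models$start, end = models$end,
           name = models$gene_id, score = 0L, strand = models$strand),
    path, col_names = FALSE)
  invisible(path)
}

#' Read a BED6 annotation into a gene-model tibble
#'
#' @param path BED file (0-based half-open coordinates).
#' @return Tibble with `gene_id`, `chromosome`, `start`, `end`, `strand`
#'   and `transcript_length_bp` (= span, single-exon convention).
#' @export
read_bed <- function(path) {
  b <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                           "score", "strand"),
                       col_types = "ciicic", progress = FALSE)
  tibble(gene_id = b$name, chromosome = b$chrom, start = b$start,
         end = b$end, strand = b$strand,
         transcript_length_bp = b$end - b$start)
}

#' Write / read the gene annotation sidecar (imprinting flags, loci)
#'
#' @param models Gene-model tibble.
#' @param path TSV path.
#' @return `path` (writer) or a tibble (reader).
#' @export
write_gene_annotation <- function(models, path) {
  readr::write_tsv(
    select(models, "gene_id", "imprinted", "locus_id", "transcript_length_bp"),
    path)
  invisible(path)
}

#' @rdname write_gene_annotation
#' @export
read_gene_annotation <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", imprinted = "l", locus_id = "c",
    transcript_length_bp = "i"), progress = FALSE)
}

#' Write / read a variant-call table
#'
#' Full-precision TSV round-trip of the caller output (chromosome, 1-based
#' position, ref and alt base, depth, alt-supporting reads, variant
#' frequency in percent, mean alt base quality, plus any pass-through
#' grouping columns such as `sample_id`).
#'
#' @param calls Variant-call tibble from [call_variants()].
#' @param path TSV path.
#' @return `path` (writer) or a tibble (reader).
#' @export
write_variants <- function(calls, path) {
  readr::write_tsv(calls, path)
  invisible(path)
}

#' @rdname write_variants
#' @export
read_variants <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chromosome = "c", pos = "i", ref_base = "c", alt_base = "c",
    depth = "i", alt_reads = "i", variant_frequency = "d",
    mean_alt_quality = "d", .default = "c"), progress = FALSE)
}

#' Convert between BED and pileup coordinates
#'
#' The single place where the two conventions meet: gene annotation is
#' 0-based half-open (`start`, `end`), pileup positions are 1-based
#' inclusive. A BED interval `[start, end)` covers pileup positions
#' `start + 1 .. end`.
#'
#' @param start,end BED 0-based half-open interval.
#' @return A list with `first` and `last`, the 1-based inclusive pileup
#'   positions of the interval.
#' @examples
#' bed_to_pileup(0, 100)  # positions 1..100
#' @export
bed_to_pileup <- function(start, end) {
  list(first = as.integer(start) + 1L, last = as.integer(end))
}
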