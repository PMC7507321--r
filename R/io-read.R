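# Readers for the standard formats. All coordinates are converted to the
# package's internal 0-based half-open convention at parse time (GTF is
# 1-based closed on disk, BED already half-open, SAM POS 1-based).

#' Read a genome FASTA into a named character vector
#' @param path FASTA file (gzip allowed).
#' @return Named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  setNames(as.character(dna), sub("\\s.*$", "", names(dna)))
}

#' Read FASTQ sequences
#' @param path FASTQ file (gzip allowed).
#' @return Character vector of read sequences, named by read id.
#' @export
read_fastq_seqs <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(dna), sub("\\s.*$", "", names(dna)))
}

#' Read a BED6 file of Alu elements (or any intervals)
#' @param path BED file.
#' @return Tibble: alu_id, chrom, start, end, strand (0-based half-open).
#' @export
read_bed6 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble(alu_id = gr$name %||% paste0("iv", seq_along(gr)),
         chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr),
         strand = as.character(GenomicRanges::strand(gr)))
}

#' Read gene/exon annotation from GTF
#' @param path GTF file with exon features carrying `gene_id` attributes.
#' @return List with `genes` (gene_id, chrom, strand) and `exons`
#'   (gene_id, exon_rank, chrom, start, end; 0-based half-open, ranks in
#'   genome coordinate order).
#' @export
read_gtf_exons <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  exons <- tibble(gene_id = ex$gene_id,
                  chrom = as.character(GenomicRanges::seqnames(ex)),
                  start = GenomicRanges::start(ex) - 1L,
                  end = GenomicRanges::end(ex),
                  strand = as.character(GenomicRanges::strand(ex))) |>
    arrange(.data$gene_id, .data$start) |>
    group_by(.data$gene_id) |>
    mutate(exon_rank = dplyr::row_number()) |>
    ungroup()
  genes <- distinct(exons, .data$gene_id, .data$chrom, .data$strand)
  list(genes = genes,
       exons = select(exons, "gene_id", "exon_rank", "chrom", "start", "end"))
}

#' Read sample metadata TSV
#' @param path TSV with at least sample_id; region/condition/age/sex used
#'   when present.
#' @return Tibble.
#' @export
read_sample_meta <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"sample_id" %in% names(meta)) {
    abort("metadata must contain a sample_id column.")
  }
  meta
}

#' Assemble a genome model from standard files
#'
#' Real-data entry point: genome FASTA + annotation GTF + Alu BED become the
#' same `genome_model` structure the simulator produces (without generative
#' fields: base_expression/circ_exon/circ_fraction are NA/0 and unused by
#' detection and editing analyses).
#'
#' @param fasta Genome FASTA path.
#' @param gtf Annotation GTF path.
#' @param alu_bed Optional Alu BED6 path.
#' @return A `genome_model`.
#' @export
genome_from_files <- function(fasta, gtf, alu_bed = NULL) {
  chromosomes <- read_genome_fasta(fasta)
  ann <- read_gtf_exons(gtf)
  genes <- ann$genes |>
    mutate(base_expression = 1, circ_exon = NA_integer_, circ_fraction = 0)
  alus <- if (is.null(alu_bed)) {
    tibble(alu_id = character(), chrom = character(), start = integer(),
           end = integer(), strand = character())
  } else {
    read_bed6(alu_bed)
  }
  gm <- structure(list(chromosomes = chromosomes, genes = genes,
                       exons = ann$exons, alus = alus),
                  class = "genome_model")
  validate_genome(gm)
  gm
}
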