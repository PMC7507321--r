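# Writers for the standard formats at the package edges. Coordinates are
# 0-based half-open internally; GTF and SAM serialization converts to
# 1-based at the boundary.

#' Write genome FASTA
#' @param genome A `genome_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  dna <- Biostrings::DNAStringSet(genome$chromosomes)
  Biostrings::writeXStringSet(dna, filepath = path)
  invisible(path)
}

#' Write gene annotation as GTF (gene and exon features)
#' @inheritParams write_genome_fasta
#' @export
write_gtf <- function(genome, path) {
  ex <- left_join(genome$exons,
                  select(genome$genes, "gene_id", "strand"), by = "gene_id")
  gene_rows <- ex |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    mutate(feature = "gene", exon_rank = NA_integer_)
  ex_rows <- mutate(ex, feature = "exon")
  all_rows <- bind_rows(gene_rows, ex_rows) |>
    arrange(.data$chrom, .data$start, dplyr::desc(.data$feature))
  attrs <- ifelse(
    all_rows$feature == "gene",
    sprintf('gene_id "%s";', all_rows$gene_id),
    sprintf('gene_id "%s"; exon_number "%d";', all_rows$gene_id,
            all_rows$exon_rank))
  lines <- sprintf("%s\tcircnigra\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   all_rows$chrom, all_rows$feature,
                   all_rows$start + 1L, all_rows$end,  # GTF is 1-based closed
                   all_rows$strand, attrs)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write Alu elements as BED6
#' @inheritParams write_genome_fasta
#' @export
write_alu_bed <- function(genome, path) {
  al <- genome$alus
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   al$chrom, al$start, al$end, al$alu_id, al$strand)
  readr::write_lines(lines, path)
  invisible(path)
}

#' @noRd
write_fastq <- function(seqs, ids, path, qual_char = "I") {
  n <- length(seqs)
  lines <- character(4L * n)
  lines[seq(1L, by = 4L, length.out = n)] <- paste0("@", ids)
  lines[seq(2L, by = 4L, length.out = n)] <- seqs
  lines[seq(3L, by = 4L, length.out = n)] <- "+"
  lines[seq(4L, by = 4L, length.out = n)] <- strrep(qual_char, nchar(seqs))
  readr::write_lines(lines, path)
  invisible(path)
}

# Ground-truth SAM writer. `reads` carries gene_id/class/start (template
# coordinates); `maps` is the gene_maps() list. Junction-crossing circular
# reads become a primary + supplementary soft-clipped record pair.
write_truth_sam <- function(reads, maps, chrom_lens, path, read_len) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lens),
                      unname(chrom_lens)))
  L <- read_len
  recs <- vector("list", length(maps))
  gene_ids <- vapply(maps, `[[`, character(1), "gene_id")
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    rr <- reads[reads$gene_id == m$gene_id, , drop = FALSE]
    if (nrow(rr) == 0) next
    minus <- m$strand == "-"
    out <- vector("list", 4L)

    ## linear spliced reads
    tx <- rr[rr$class == "tx", , drop = FALSE]
    if (nrow(tx) > 0) {
      splus <- if (minus) m$tx_len - tx$start - L + 2L else tx$start
      k1 <- findInterval(splus - 0.5, c(0L, m$cum))
      k2 <- findInterval(splus + L - 1L - 0.5, c(0L, m$cum))
      off <- splus - 1L - m$cb[k1]
      g0 <- m$ex_start[k1] + off
      one <- k1 == k2
      cigar <- character(nrow(tx))
      cigar[one] <- sprintf("%dM", L)
      if (any(!one)) {
        m1 <- m$cum[k1[!one]] - (splus[!one] - 1L)
        gap <- m$ex_start[k2[!one]] - m$ex_end[k1[!one]]
        cigar[!one] <- sprintf("%dM%dN%dM", m1, gap, L - m1)
      }
      out[[1]] <- tibble(qname = tx$read_id,
                         flag = if (minus) 16L else 0L,
                         pos1 = g0 + 1L, cigar = cigar,
                         seq = if (minus) revcomp(tx$seq) else tx$seq)
    }

    ## pre-mRNA reads: always a single block
    pre <- rr[rr$class == "pre", , drop = FALSE]
    if (nrow(pre) > 0) {
      splus <- if (minus) m$pre_len - pre$start - L + 2L else pre$start
      out[[2]] <- tibble(qname = pre$read_id,
                         flag = if (minus) 16L else 0L,
                         pos1 = m$span_start + splus, cigar = sprintf("%dM", L),
                         seq = if (minus) revcomp(pre$seq) else pre$seq)
    }

    ## circular reads
    cc <- rr[rr$class == "circ", , drop = FALSE]
    if (nrow(cc) > 0) {
      Lc <- m$circ$Lc; cs <- m$circ$cstart; ce <- m$circ$cend
      cross <- cc$start > Lc - (L - 1L)
      ncr <- cc[!cross, , drop = FALSE]
      if (nrow(ncr) > 0) {
        g0 <- if (minus) ce - ncr$start - L + 1L else cs + ncr$start - 1L
        out[[3]] <- tibble(qname = ncr$read_id,
                           flag = if (minus) 16L else 0L,
                           pos1 = g0 + 1L, cigar = sprintf("%dM", L),
                           seq = if (minus) revcomp(ncr$seq) else ncr$seq)
      }
      cr <- cc[cross, , drop = FALSE]
      if (nrow(cr) > 0) {
        l1 <- Lc - cr$start + 1L
        l2 <- L - l1
        sseq <- if (minus) revcomp(cr$seq) else cr$seq
        if (!minus) {
          prim <- tibble(qname = cr$read_id, flag = 0L,
                         pos1 = cs + cr$start,
                         cigar = sprintf("%dM%dS", l1, l2), seq = sseq)
          supp <- tibble(qname = cr$read_id, flag = 2048L,
                         pos1 = cs + 1L,
                         cigar = sprintf("%dS%dM", l1, l2), seq = sseq)
        } else {
          prim <- tibble(qname = cr$read_id, flag = 16L,
                         pos1 = cs + 1L,
                         cigar = sprintf("%dS%dM", l2, l1), seq = sseq)
          supp <- tibble(qname = cr$read_id, flag = 2064L,
                         pos1 = ce - l2 + 1L,
                         cigar = sprintf("%dM%dS", l2, l1), seq = sseq)
        }
        out[[4]] <- bind_rows(prim, supp)
      }
    }
    recs[[i]] <- mutate(bind_rows(out), rname = m$chrom)
  }
  recs <- bind_rows(recs)
  body <- if (nrow(recs) > 0) {
    recs <- recs[order(recs$qname, recs$flag), , drop = FALSE]
    sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s",
            recs$qname, recs$flag, recs$rname, recs$pos1, recs$cigar,
            recs$seq, strrep("I", nchar(recs$seq)))
  } else character()
  readr::write_lines(c(header, body), path)
  invisible(path)
}
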