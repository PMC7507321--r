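# Cohort-level junction calling: batch anchor mapping over whole FASTQ
# files, shared breakpoint resolution with detect_backsplice(), per-sample
# counting and the cohort-wide support filter.

#' Call back-splice junctions across a cohort
#'
#' Runs the anchor-based head-to-tail detector over one FASTQ per sample and
#' assembles a [circ_counts()] container. Per-sample counts are reads
#' supporting each junction; junctions with total support below
#' `min_support` across the whole cohort are dropped. The per-sample
#' mapped-read total is the number of reads with at least one anchor hit
#' anywhere on the genome (the detector runs no external aligner).
#'
#' @param fastq_paths Character vector of FASTQ paths, named by sample id
#'   (unnamed paths are named from the file name).
#' @param genome A `genome_model`.
#' @param params [detect_params()].
#' @param min_support Cohort-wide minimum supporting reads per junction.
#' @param meta Optional sample metadata tibble.
#' @param index Optional pre-built [build_index()] (rebuilt when `NULL`).
#' @param merge_window Junctions of identical circle length on one
#'   chromosome and strand whose boundaries differ by at most this many nt
#'   are merged into the better-supported key (0 disables). Short homology
#'   around a breakpoint can place single erroneous reads a few nt off even
#'   when both placements look canonical; clustering absorbs them.
#' @return A `circ_counts` object.
#' @export
call_junctions <- function(fastq_paths, genome, params = detect_params(),
                           min_support = 2L, meta = NULL, index = NULL,
                           merge_window = 5L) {
  if (length(fastq_paths) < 1L) abort("at least one sample is required.")
  ids <- names(fastq_paths)
  if (is.null(ids)) {
    ids <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastq_paths))
  }
  if (anyDuplicated(ids)) abort("sample ids must be unique.")
  if (is.null(index)) index <- build_index(genome, params$anchor_len)

  per_sample <- vector("list", length(fastq_paths))
  mapped_totals <- setNames(numeric(length(ids)), ids)
  for (i in seq_along(fastq_paths)) {
    seqs <- read_fastq_seqs(fastq_paths[[i]])
    if (length(seqs) == 0) {
      warn(sprintf("empty FASTQ for sample %s; keeping a zero column.", ids[i]))
      per_sample[[i]] <- tibble(junction_id = character(), chrom = character(),
                                start = integer(), end = integer(),
                                strand = character(),
                                splice_signal = character(), n = integer())
      mapped_totals[i] <- 0
      next
    }
    res <- detect_batch(seqs, index, genome, params)
    mapped_totals[i] <- res$mapped_total
    per_sample[[i]] <- res$junctions
  }

  all_j <- purrr::map2_dfr(per_sample, ids,
                           function(d, s) mutate(d, sample_id = s))
  if (nrow(all_j) == 0) {
    junctions <- tibble(junction_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), splice_signal = character(),
                        total_support = integer())
    counts <- bind_cols(tibble(junction_id = character()),
                        as_tibble(setNames(rep(list(integer()), length(ids)),
                                           ids)))
    return(circ_counts(junctions, counts, mapped_totals, meta))
  }

  if (merge_window > 0) all_j <- merge_near_junctions(all_j, merge_window)

  wide <- all_j |>
    select("junction_id", "sample_id", "n") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "n",
                       values_fill = 0L)
  for (s in setdiff(ids, names(wide))) wide[[s]] <- 0L
  wide <- wide[c("junction_id", ids)]
  total <- rowSums(as.matrix(wide[ids]))
  keep <- total >= min_support
  wide <- wide[keep, , drop = FALSE]

  junctions <- all_j |>
    distinct(.data$junction_id, .keep_all = TRUE) |>
    select("junction_id", "chrom", "start", "end", "strand",
           "splice_signal") |>
    filter(.data$junction_id %in% wide$junction_id) |>
    mutate(total_support = as.integer(total[keep])[
      match(.data$junction_id, wide$junction_id)]) |>
    arrange(.data$chrom, .data$start, .data$end)
  wide <- wide[match(junctions$junction_id, wide$junction_id), , drop = FALSE]

  circ_counts(junctions, wide, mapped_totals, meta)
}

# Greedy clustering of near-duplicate junction keys: reassign a minority
# placement to the dominant placement when chromosome, strand and circle
# length agree and the boundary offset is within `window` nt.
merge_near_junctions <- function(all_j, window) {
  totals <- all_j |>
    group_by(.data$junction_id, .data$chrom, .data$start, .data$end,
             .data$strand) |>
    summarise(total = sum(.data$n), .groups = "drop") |>
    mutate(len = .data$end - .data$start) |>
    arrange(dplyr::desc(.data$total), .data$start)
  canonical <- character(nrow(totals))
  kept <- totals[0, ]
  for (i in seq_len(nrow(totals))) {
    cnd <- totals[i, ]
    hit <- which(kept$chrom == cnd$chrom & kept$strand == cnd$strand &
                   kept$len == cnd$len &
                   abs(kept$start - cnd$start) <= window)
    if (length(hit) > 0) {
      canonical[i] <- kept$junction_id[hit[1]]
    } else {
      canonical[i] <- cnd$junction_id
      kept <- bind_rows(kept, cnd)
    }
  }
  remap <- setNames(canonical, totals$junction_id)
  canon_info <- all_j |>
    distinct(.data$junction_id, .keep_all = TRUE) |>
    select("junction_id", "chrom", "start", "end", "strand",
           "splice_signal")
  all_j |>
    mutate(junction_id = unname(remap[.data$junction_id])) |>
    group_by(.data$junction_id, .data$sample_id) |>
    summarise(n = sum(.data$n), .groups = "drop") |>
    left_join(canon_info, by = "junction_id")
}

# Vectorised batch version of detect_backsplice(): same anchor rules and the
# same resolve_breakpoint() on candidates.
detect_batch <- function(seqs, index, genome, params) {
  k <- params$anchor_len
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    warn(sprintf("%d read(s) with non-ACGT bases skipped.", sum(bad)))
    seqs <- seqs[!bad]
  }
  Lr <- nchar(seqs)
  short <- Lr < 2L * k
  if (any(short)) {
    warn(sprintf("%d read(s) shorter than two anchors skipped.", sum(short)))
    seqs <- seqs[!short]; Lr <- Lr[!short]
  }
  n <- length(seqs)
  empty <- tibble(junction_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  splice_signal = character(), n = integer())
  if (n == 0) return(list(junctions = empty, mapped_total = 0))

  a5 <- substr(seqs, 1L, k)
  a3 <- substr(seqs, Lr - k + 1L, Lr)
  agg <- index$agg
  i5p <- match(a5, agg$kmer); i5m <- match(revcomp(a5), agg$kmer)
  i3p <- match(a3, agg$kmer); i3m <- match(revcomp(a3), agg$kmer)
  cnt <- function(i) ifelse(is.na(i), 0L, agg$n[i])
  n5 <- cnt(i5p) + cnt(i5m)
  n3 <- cnt(i3p) + cnt(i3m)
  mapped_total <- sum(n5 > 0L | n3 > 0L)

  # candidates: both anchors unique, same chromosome and strand, reversed
  # genomic order (head-to-tail)
  uniq <- n5 == 1L & n3 == 1L
  s5 <- ifelse(!is.na(i5p) & cnt(i5p) == 1L, "+", "-")
  s3 <- ifelse(!is.na(i3p) & cnt(i3p) == 1L, "+", "-")
  j5 <- ifelse(s5 == "+", i5p, i5m)
  j3 <- ifelse(s3 == "+", i3p, i3m)
  keep <- which(uniq & s5 == s3 & agg$chrom[j5] == agg$chrom[j3])
  p5 <- agg$pos[j5[keep]]; p3 <- agg$pos[j3[keep]]
  st <- s5[keep]
  ht <- (st == "+" & p3 < p5) | (st == "-" & p5 < p3)
  keep <- keep[ht]
  if (length(keep) == 0) {
    return(list(junctions = empty, mapped_total = mapped_total))
  }
  nc <- length(keep)
  c_read <- keep; c_chrom <- agg$chrom[j5[keep]]; c_strand <- s5[keep]
  c_p5 <- agg$pos[j5[keep]]; c_p3 <- agg$pos[j3[keep]]
  o_start <- integer(nc); o_end <- integer(nc); o_sig <- character(nc)
  ok <- logical(nc)
  for (j in seq_len(nc)) {
    chrom_seq <- genome$chromosomes[[c_chrom[j]]]
    res <- if (c_strand[j] == "+") {
      resolve_breakpoint(seqs[c_read[j]], chrom_seq, c_p5[j], c_p3[j],
                         "+", params)
    } else {
      resolve_breakpoint(revcomp(seqs[c_read[j]]), chrom_seq, c_p3[j],
                         c_p5[j], "-", params)
    }
    if (is.null(res)) next
    ok[j] <- TRUE
    o_start[j] <- res$start; o_end[j] <- res$end
    o_sig[j] <- res$splice_signal
  }
  found <- tibble(chrom = c_chrom[ok], start = o_start[ok], end = o_end[ok],
                  strand = c_strand[ok], splice_signal = o_sig[ok])
  if (nrow(found) == 0) return(list(junctions = empty, mapped_total = mapped_total))
  junctions <- found |>
    mutate(junction_id = paste0(.data$chrom, ":", .data$start, "-",
                                .data$end, ":", .data$strand)) |>
    group_by(.data$junction_id, .data$chrom, .data$start, .data$end,
             .data$strand) |>
    summarise(splice_signal = .data$splice_signal[1], n = dplyr::n(),
              .groups = "drop")
  list(junctions = junctions, mapped_total = mapped_total)
}

#' Write a junction table as BED6-compatible TSV with per-sample counts
#'
#' First six columns are BED6 (chrom, start, end, name, score = total
#' support, strand), followed by one count column per sample.
#'
#' @param x A `circ_counts` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_junction_tsv <- function(x, path) {
  stopifnot(inherits(x, "circ_counts"))
  bed <- x$junctions |>
    dplyr::transmute(.data$chrom, .data$start, .data$end,
                     name = .data$junction_id,
                     score = .data$total_support, .data$strand) |>
    bind_cols(x$counts[sample_names(x)])
  readr::write_tsv(bed, path)
  invisible(path)
}
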