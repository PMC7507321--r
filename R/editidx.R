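# Alu editing index: per-position base counts from alignments, pooled
# numerator/denominator index per mismatch type in transcribed orientation,
# the full 12-type mismatch spectrum, and circRNA-proximal region sets.

#' The 12 ordered mismatch types
#' @return Character vector like "A>G", in transcribed orientation.
#' @export
mismatch_types <- function() {
  apply(expand.grid(alt = BASES, ref = BASES), 1L,
        function(r) if (r["ref"] == r["alt"]) NA_character_ else
          paste0(r["ref"], ">", r["alt"])) |>
    stats::na.omit() |> as.character() |> sort()
}

parse_mismatch <- function(mismatch) {
  m <- stringr::str_match(mismatch, "^([ACGT])>([ACGT])$")
  if (is.na(m[1, 1]) || m[1, 2] == m[1, 3]) {
    abort('`mismatch` must be one of the 12 ordered types, e.g. "A>G".')
  }
  c(ref = m[1, 2], alt = m[1, 3])
}

#' Per-position base counts from a SAM file
#'
#' Converts the SAM to BAM internally and counts A/C/G/T read bases at each
#' covered position, using primary mapped records only; deletions,
#' insertions and soft clips contribute nothing.
#'
#' @param sam_path SAM (or BAM) file path.
#' @param regions Optional tibble (chrom, start, end; 0-based half-open)
#'   restricting the pileup; overlapping regions are merged first. An empty
#'   tibble yields an empty pileup.
#' @param genome Optional `genome_model`; when given, the SAM header's
#'   sequence dictionary must match its chromosomes.
#' @return Tibble: chrom, pos (0-based), A, C, G, T counts.
#' @export
pileup_from_sam <- function(sam_path, regions = NULL, genome = NULL) {
  empty <- tibble(chrom = character(), pos = integer(),
                  A = integer(), C = integer(), G = integer(), T = integer())
  if (!is.null(regions) && nrow(regions) == 0) return(empty)
  bam <- if (grepl("\\.bam$", sam_path)) {
    sam_path
  } else {
    Rsamtools::asBam(sam_path, destination = tempfile("pileup_"),
                     overwrite = TRUE, indexDestination = TRUE)
  }
  if (!is.null(genome)) {
    sq <- Rsamtools::scanBamHeader(bam)[[1]]$targets
    if (!all(names(genome$chromosomes) %in% names(sq)) ||
        any(sq[names(genome$chromosomes)] != nchar(genome$chromosomes))) {
      abort("SAM @SQ lines do not match the genome's chromosomes.")
    }
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  sbp <- if (is.null(regions)) {
    Rsamtools::ScanBamParam(flag = flags)
  } else {
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end)))
    Rsamtools::ScanBamParam(flag = flags, which = gr)
  }
  pp <- Rsamtools::PileupParam(max_depth = 1000000L, min_base_quality = 0L,
                               min_mapq = 0L, min_nucleotide_depth = 1L,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = TRUE,
                               include_deletions = FALSE,
                               include_insertions = FALSE)
  pu <- Rsamtools::pileup(bam, scanBamParam = sbp, pileupParam = pp)
  if (nrow(pu) == 0) return(empty)
  pu |>
    mutate(chrom = as.character(.data$seqnames), pos = .data$pos - 1L,
           nucleotide = as.character(.data$nucleotide)) |>
    filter(.data$nucleotide %in% BASES) |>
    select("chrom", "pos", "nucleotide", "count") |>
    dplyr::distinct(.data$chrom, .data$pos, .data$nucleotide,
                    .keep_all = TRUE) |>
    tidyr::pivot_wider(names_from = "nucleotide", values_from = "count",
                       values_fill = 0L) |>
    add_missing_base_cols() |>
    select("chrom", "pos", "A", "C", "G", "T") |>
    arrange(.data$chrom, .data$pos)
}

add_missing_base_cols <- function(d) {
  for (b in BASES) if (!b %in% names(d)) d[[b]] <- 0L
  d
}

# Strand context for every Alu position (not just adenosines): containing
# gene strand wins; opposite-strand gene overlap excludes the position;
# intergenic positions use the Alu's own strand. Pure in the genome, so the
# result is memoised (keyed by a hash of the genome) to keep repeated index
# calls over one genome cheap.
.ctx_cache <- new.env(parent = emptyenv())

alu_position_context <- function(genome) {
  key <- rlang::hash(list(genome$chromosomes, genome$alus, genome$exons,
                          genome$genes$strand))
  hit <- get0(key, envir = .ctx_cache)
  if (!is.null(hit)) return(hit)
  ctx <- alu_site_context(genome)
  ref <- chrom_base(genome, ctx$chrom, ctx$pos)
  out <- mutate(ctx, ref_plus = ref,
                ref_tx = ifelse(.data$ctx_strand == "+", ref,
                                complement_base(ref)))
  if (length(ls(.ctx_cache)) > 16L) rm(list = ls(.ctx_cache),
                                       envir = .ctx_cache)
  assign(key, out, envir = .ctx_cache)
  out
}

#' Alu editing index for one mismatch type
#'
#' Pools read counts over all eligible Alu positions: positions inside an
#' Alu element whose transcribed-strand reference base equals the mismatch's
#' reference and whose coverage reaches `min_coverage`. The index is
#' `100 * sum(alt reads) / (sum(ref reads) + sum(alt reads))`; expression
#' weighting arises from pooling read counts rather than averaging per-site
#' rates. For minus-strand context the plus-strand pileup is
#' complement-mapped (A>G editing appears as T>C and is counted as A>G).
#'
#' @param pileup Tibble from [pileup_from_sam()].
#' @param genome A `genome_model` (provides Alu elements, genes and the
#'   reference bases).
#' @param mismatch Ordered mismatch type, e.g. `"A>G"`.
#' @param min_coverage Minimum total read coverage for a position to be
#'   eligible ("expressed Alu" threshold).
#' @param region_label Label stored in the result row.
#' @return One-row tibble: region_label, mismatch, numerator, denominator,
#'   index_percent (NA with `defined = FALSE` when the denominator is 0),
#'   n_positions.
#' @export
alu_editing_index <- function(pileup, genome, mismatch = "A>G",
                              min_coverage = 1L, region_label = "global") {
  mm <- parse_mismatch(mismatch)
  ctx <- alu_position_context(genome)
  d <- inner_join(pileup, ctx, by = c("chrom", "pos"))
  if (nrow(d) > 0) {
    cov <- d$A + d$C + d$G + d$T
    d <- d[cov >= min_coverage & d$ref_tx == mm["ref"], , drop = FALSE]
  }
  if (nrow(d) == 0) {
    return(tibble(region_label = region_label, mismatch = mismatch,
                  numerator = 0L, denominator = 0L,
                  index_percent = NA_real_, defined = FALSE,
                  n_positions = 0L))
  }
  plus <- d$ctx_strand == "+"
  ref_col <- ifelse(plus, mm["ref"], complement_base(mm["ref"]))
  alt_col <- ifelse(plus, mm["alt"], complement_base(mm["alt"]))
  dm <- as.matrix(d[BASES])
  ref_reads <- dm[cbind(seq_len(nrow(d)), match(ref_col, BASES))]
  alt_reads <- dm[cbind(seq_len(nrow(d)), match(alt_col, BASES))]
  num <- sum(alt_reads)
  den <- num + sum(ref_reads)
  tibble(region_label = region_label, mismatch = mismatch,
         numerator = num, denominator = den,
         index_percent = if (den > 0) 100 * num / den else NA_real_,
         defined = den > 0, n_positions = nrow(d))
}

#' Mismatch spectrum: the editing index for all 12 ordered mismatch types
#'
#' @inheritParams alu_editing_index
#' @return Tibble with one row per mismatch type.
#' @export
mismatch_spectrum <- function(pileup, genome, min_coverage = 1L,
                              region_label = "global") {
  purrr::map_dfr(mismatch_types(), function(mm) {
    alu_editing_index(pileup, genome, mismatch = mm,
                      min_coverage = min_coverage,
                      region_label = region_label)
  })
}

#' Region sets for circRNA exons and their flanking intron windows
#'
#' For each junction assignable to a host gene (by span containment), the
#' circle `[start, end)` and the two flanks `[start - w, start)` and
#' `[end, end + w)`, clipped to the host gene span and chromosome bounds.
#' With `subtract_exons = TRUE` (default) the host gene's exons are removed
#' from the flanks, leaving intronic sequence; otherwise flanks are clipped
#' to gene bounds only. Overlapping intervals are merged within each label.
#'
#' @param junctions Tibble with chrom, start, end (0-based half-open).
#' @param genome A `genome_model`.
#' @param window Flank window size in nt (customarily 1000, 5000 or 10000).
#' @param subtract_exons Remove exonic sequence from flanks.
#' @return List of two tibbles `circ_exons` and `flanks`, each with
#'   label, chrom, start, end.
#' @export
circ_flank_regions <- function(junctions, genome, window = 1000L,
                               subtract_exons = TRUE) {
  window <- assert_scalar_int(window, "window", min = 0L)
  spans <- genome$exons |>
    group_by(.data$gene_id, .data$chrom) |>
    summarise(gstart = min(.data$start), gend = max(.data$end),
              .groups = "drop")
  chrom_len <- nchar(genome$chromosomes)

  circ <- list(); flank <- list()
  for (i in seq_len(nrow(junctions))) {
    jn <- junctions[i, ]
    host <- spans |>
      filter(.data$chrom == jn$chrom, .data$gstart <= jn$start,
             .data$gend >= jn$end)
    if (nrow(host) == 0) {
      warn(sprintf("junction %s:%d-%d has no host gene; excluded.",
                   jn$chrom, jn$start, jn$end))
      next
    }
    host <- host[1, ]
    circ[[length(circ) + 1L]] <- tibble(chrom = jn$chrom, start = jn$start,
                                        end = jn$end)
    lo <- max(jn$start - window, host$gstart, 0L)
    hi <- min(jn$end + window, host$gend, chrom_len[[jn$chrom]])
    fl <- tibble(chrom = jn$chrom,
                 start = c(lo, jn$end), end = c(jn$start, hi)) |>
      filter(.data$start < .data$end)
    if (subtract_exons && nrow(fl) > 0) {
      ex <- genome$exons |>
        filter(.data$gene_id == host$gene_id) |>
        filter(!(.data$start == jn$start & .data$end == jn$end))
      fl <- subtract_intervals(fl, ex)
    }
    flank[[length(flank) + 1L]] <- fl
  }
  list(circ_exons = merge_intervals(bind_rows(circ), "circ_exons"),
       flanks = merge_intervals(bind_rows(flank),
                                paste0("flank_", window)))
}

merge_intervals <- function(d, label) {
  if (is.null(d) || nrow(d) == 0) {
    return(tibble(label = character(), chrom = character(),
                  start = integer(), end = integer()))
  }
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    d$chrom, IRanges::IRanges(d$start + 1L, d$end)))
  tibble(label = label,
         chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr))
}

subtract_intervals <- function(d, remove) {
  if (nrow(d) == 0 || nrow(remove) == 0) return(d)
  gr <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start + 1L, d$end))
  rm_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    remove$chrom, IRanges::IRanges(remove$start + 1L, remove$end)))
  left <- GenomicRanges::setdiff(gr, rm_gr)
  tibble(chrom = as.character(GenomicRanges::seqnames(left)),
         start = GenomicRanges::start(left) - 1L,
         end = GenomicRanges::end(left))
}

restrict_pileup <- function(pileup, regions) {
  if (nrow(regions) == 0 || nrow(pileup) == 0) return(pileup[0, ])
  keep <- rep(FALSE, nrow(pileup))
  for (ch in unique(regions$chrom)) {
    ri <- IRanges::IRanges(regions$start[regions$chrom == ch] + 1L,
                           regions$end[regions$chrom == ch])
    pi <- which(pileup$chrom == ch)
    if (length(pi) == 0) next
    qi <- IRanges::IRanges(pileup$pos[pi] + 1L, width = 1L)
    keep[pi] <- IRanges::overlapsAny(qi, ri)
  }
  pileup[keep, , drop = FALSE]
}

#' Regional editing report: global, circRNA exons, and flank windows
#'
#' Computes the full mismatch spectrum globally, over circRNA exons, and
#' over flanking intron windows of each requested size.
#'
#' @param sam_path Alignment SAM for one sample (or a precomputed pileup
#'   tibble passed as `pileup`).
#' @param genome A `genome_model`.
#' @param junctions Junction tibble (chrom, start, end).
#' @param windows Flank window sizes.
#' @param min_coverage Eligibility threshold per position.
#' @param pileup Optional precomputed whole-genome pileup.
#' @param subtract_exons Passed to [circ_flank_regions()].
#' @return Tibble: one row per region x mismatch with numerator,
#'   denominator, index_percent, n_positions.
#' @export
regional_editing_report <- function(sam_path = NULL, genome, junctions,
                                    windows = c(1000L, 5000L, 10000L),
                                    min_coverage = 1L, pileup = NULL,
                                    subtract_exons = TRUE) {
  if (is.null(pileup)) pileup <- pileup_from_sam(sam_path, genome = genome)
  out <- list(mismatch_spectrum(pileup, genome, min_coverage, "global"))
  if (nrow(junctions) > 0) {
    rs <- circ_flank_regions(junctions, genome, window = windows[1],
                             subtract_exons = subtract_exons)
    out[[length(out) + 1L]] <- mismatch_spectrum(
      restrict_pileup(pileup, rs$circ_exons), genome, min_coverage,
      "circ_exons")
    for (w in windows) {
      rs_w <- circ_flank_regions(junctions, genome, window = w,
                                 subtract_exons = subtract_exons)
      out[[length(out) + 1L]] <- mismatch_spectrum(
        restrict_pileup(pileup, rs_w$flanks), genome, min_coverage,
        paste0("flank_", w))
    }
  }
  bind_rows(out)
}
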