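# Per-site A-to-I editing model over Alu adenosines of the transcribed strand.

#' Strand context of Alu positions
#'
#' The transcribed strand at a position is decided position by position: the
#' strand of a covering gene wins (positions covered by genes on opposite
#' strands are excluded as ambiguous); intergenic positions fall back to the
#' Alu element's own strand (likewise excluded if two overlapping Alus
#' disagree). Duplicated positions from overlapping Alus are collapsed to
#' one entry.
#'
#' @noRd
alu_site_context <- function(genome) {
  al <- genome$alus
  empty <- tibble(chrom = character(), pos = integer(),
                  ctx_strand = character(), alu_id = character())
  if (nrow(al) == 0) return(empty)
  gene_spans <- genome$exons |>
    group_by(.data$gene_id, .data$chrom) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    left_join(select(genome$genes, "gene_id", "strand"), by = "gene_id")

  pos_tbl <- purrr::pmap_dfr(al, function(alu_id, chrom, start, end, strand) {
    tibble(chrom = chrom, pos = start:(end - 1L), alu_strand = strand,
           alu_id = alu_id)
  })
  # collapse duplicated positions from overlapping Alus; strand conflicts
  # between overlapping Alus become NA (ambiguous unless a gene decides)
  key <- paste(pos_tbl$chrom, pos_tbl$pos)
  if (anyDuplicated(key)) {
    dup_keys <- unique(key[duplicated(key)])
    in_dup <- key %in% dup_keys
    strands <- vapply(split(pos_tbl$alu_strand[in_dup], key[in_dup]),
                      function(s) if (length(unique(s)) == 1L) s[1]
                      else NA_character_, character(1))
    pos_tbl$alu_strand[in_dup] <- strands[key[in_dup]]
    pos_tbl <- pos_tbl[!duplicated(key), , drop = FALSE]
  }

  ctx <- character(nrow(pos_tbl))
  for (ch in unique(pos_tbl$chrom)) {
    pi <- which(pos_tbl$chrom == ch)
    gs <- gene_spans[gene_spans$chrom == ch, ]
    has_plus <- has_minus <- rep(FALSE, length(pi))
    for (gi in seq_len(nrow(gs))) {
      inside <- pos_tbl$pos[pi] >= gs$start[gi] & pos_tbl$pos[pi] < gs$end[gi]
      if (gs$strand[gi] == "+") has_plus <- has_plus | inside
      else has_minus <- has_minus | inside
    }
    ctx[pi] <- dplyr::case_when(
      has_plus & has_minus ~ NA_character_,   # opposite-strand gene overlap
      has_plus ~ "+",
      has_minus ~ "-",
      .default = pos_tbl$alu_strand[pi]
    )
  }
  pos_tbl |>
    mutate(ctx_strand = ctx) |>
    filter(!is.na(.data$ctx_strand)) |>
    select("chrom", "pos", "ctx_strand", "alu_id")
}

#' Define per-site A-to-I editing rates over Alu adenosines
#'
#' Assigns an editing rate to every adenosine of the transcribed strand that
#' falls inside an Alu element: reference A positions for plus-strand context,
#' reference T positions (read as A on the transcribed strand) for
#' minus-strand context. Rates are either a fixed value or drawn from a
#' Beta(alpha, beta) distribution.
#'
#' @param genome A `genome_model`.
#' @param rate Fixed per-site rate in `[0, 1]`; ignored when `alpha` and
#'   `beta` are given.
#' @param alpha,beta Optional Beta shape parameters for heterogeneous rates.
#' @param seed Integer seed used when drawing Beta rates.
#' @return A list of class `editing_model`: `sites` (tibble chrom, pos,
#'   ctx_strand, alu_id, rate) and `global_mean` (mean per-site rate).
#' @examples
#' g <- build_genome(genome_config(), seed = 1)
#' em <- editing_model(g, rate = 0.05)
#' em$global_mean
#' @export
editing_model <- function(genome, rate = 0.05, alpha = NULL, beta = NULL,
                          seed = 1L) {
  sites <- alu_site_context(genome)
  if (nrow(sites) > 0) {
    ref <- chrom_base(genome, sites$chrom, sites$pos)
    transcribed <- ifelse(sites$ctx_strand == "+", ref, complement_base(ref))
    sites <- sites[transcribed == "A", , drop = FALSE]
  }
  if (!is.null(alpha) && !is.null(beta)) {
    set.seed(assert_scalar_int(seed, "seed"))
    sites$rate <- rbeta(nrow(sites), alpha, beta)
  } else {
    assert_prob(rate, "rate")
    sites$rate <- rep(rate, nrow(sites))
  }
  structure(list(sites = sites,
                 global_mean = if (nrow(sites)) mean(sites$rate) else 0),
            class = "editing_model")
}

# Reference base at 0-based positions (plus strand).
chrom_base <- function(genome, chrom, pos) {
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    out[i] <- substring(genome$chromosomes[[ch]], pos[i] + 1L, pos[i] + 1L)
  }
  out
}

#' @export
print.editing_model <- function(x, ...) {
  cat(sprintf("<editing_model> %d Alu adenosine sites, mean rate %.4f\n",
              nrow(x$sites), x$global_mean))
  invisible(x)
}
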