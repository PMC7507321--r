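# Synthetic genome generator: multi-gene chromosomes with circularizable
# exons, canonical GT/AG splice signals and Alu-like elements.

#' Configuration for the synthetic genome generator
#'
#' Collects the sizing and composition parameters for [build_genome()].
#' Defaults describe a small but structured genome: one chromosome, a handful
#' of multi-exon genes, a single circularizable exon in a subset of genes, and
#' Alu-like elements placed inside exons and their flanking introns in both
#' orientations.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Length of each chromosome in nucleotides.
#' @param n_genes Total number of genes to place (split evenly over
#'   chromosomes).
#' @param exons_per_gene Integer range (length 2) of exon counts per gene.
#' @param exon_len Integer range of exon lengths. The lower bound must be at
#'   least the read length used downstream so that simulated reads cross at
#'   most one splice junction.
#' @param intron_len Integer range of intron lengths.
#' @param gap_len Integer range of intergenic gaps.
#' @param circ_gene_fraction Fraction of genes given a circularizable exon.
#' @param circ_fraction_range Range of the per-gene back-splice fraction
#'   (probability that a transcript is back-spliced) drawn uniformly for
#'   circularizable genes.
#' @param alu_per_gene Expected number of Alu-like elements per gene (placed
#'   in exons and flanking introns; Poisson-distributed).
#' @param alu_len Integer range of Alu element lengths (minimum 50).
#' @param alu_sense_fraction Probability that an Alu element is placed on the
#'   gene's sense strand.
#' @param minus_strand_fraction Fraction of genes on the minus strand.
#' @param expression_meanlog,expression_sdlog Log-normal parameters for the
#'   per-gene relative expression weight.
#'
#' @return A list of class `genome_config`.
#' @seealso [build_genome()]
#' @export
genome_config <- function(n_chrom = 1L,
                          chrom_len = 20000L,
                          n_genes = 5L,
                          exons_per_gene = c(2L, 3L),
                          exon_len = c(150L, 400L),
                          intron_len = c(200L, 700L),
                          gap_len = c(100L, 400L),
                          circ_gene_fraction = 0.6,
                          circ_fraction_range = c(0.05, 0.25),
                          alu_per_gene = 2,
                          alu_len = c(80L, 280L),
                          alu_sense_fraction = 0.5,
                          minus_strand_fraction = 0.4,
                          expression_meanlog = 0,
                          expression_sdlog = 0.6) {
  cfg <- list(
    n_chrom = assert_scalar_int(n_chrom, "n_chrom", min = 1L),
    chrom_len = assert_scalar_int(chrom_len, "chrom_len", min = 1000L),
    n_genes = assert_scalar_int(n_genes, "n_genes", min = 1L),
    exons_per_gene = as.integer(exons_per_gene),
    exon_len = as.integer(exon_len),
    intron_len = as.integer(intron_len),
    gap_len = as.integer(gap_len),
    circ_gene_fraction = assert_prob(circ_gene_fraction, "circ_gene_fraction"),
    circ_fraction_range = as.numeric(circ_fraction_range),
    alu_per_gene = as.numeric(alu_per_gene),
    alu_len = as.integer(alu_len),
    alu_sense_fraction = assert_prob(alu_sense_fraction, "alu_sense_fraction"),
    minus_strand_fraction = assert_prob(minus_strand_fraction,
                                        "minus_strand_fraction"),
    expression_meanlog = expression_meanlog,
    expression_sdlog = expression_sdlog
  )
  if (cfg$alu_len[1] < 50L) abort("Alu elements must be at least 50 nt long.")
  structure(cfg, class = "genome_config")
}

#' Build a seeded synthetic genome with circularizable exons
#'
#' Generates random chromosome sequences, places non-overlapping multi-exon
#' genes on both strands, installs canonical splice signals at every exon
#' boundary (GT immediately downstream of each donor and AG immediately
#' upstream of each acceptor, in transcribed orientation), marks one
#' circularizable exon in a subset of genes, and annotates Alu-like elements
#' in exons and flanking introns.
#'
#' Alu elements here are labelled intervals over the random background, not
#' repeat-consensus insertions: the editing index downstream needs only their
#' adenosine content, and a non-repetitive genome keeps anchor mapping
#' unambiguous.
#'
#' @param config A [genome_config()] object.
#' @param seed Integer seed; the same seed reproduces the same genome.
#' @return A list of class `genome_model` with elements `chromosomes` (named
#'   character vector), `genes` (tibble: gene_id, chrom, strand,
#'   base_expression, circ_exon, circ_fraction), `exons` (tibble: gene_id,
#'   exon_rank, chrom, start, end; 0-based half-open), and `alus` (tibble:
#'   alu_id, chrom, start, end, strand).
#' @examples
#' g <- build_genome(genome_config(), seed = 1)
#' g$genes
#' @export
build_genome <- function(config = genome_config(), seed = 1L) {
  stopifnot(inherits(config, "genome_config"))
  seed <- assert_scalar_int(seed, "seed")
  set.seed(seed)

  genes_per_chrom <- diff_split(config$n_genes, config$n_chrom)
  chrom_names <- pad_id("chr", seq_len(config$n_chrom), width = 1L)

  chromosomes <- setNames(
    vapply(seq_len(config$n_chrom), function(i) random_dna(config$chrom_len),
           character(1)),
    chrom_names
  )

  genes <- list(); exons <- list(); alus <- list()
  gene_counter <- 0L; alu_counter <- 0L

  for (ci in seq_len(config$n_chrom)) {
    chrom <- chrom_names[ci]
    seq_ch <- chromosomes[[chrom]]
    cursor <- sample(config$gap_len[1]:config$gap_len[2], 1L) + 10L
    for (gi in seq_len(genes_per_chrom[ci])) {
      n_ex <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1L)
      ex_lens <- sample(config$exon_len[1]:config$exon_len[2], n_ex,
                        replace = TRUE)
      in_lens <- if (n_ex > 1L) {
        sample(config$intron_len[1]:config$intron_len[2], n_ex - 1L,
               replace = TRUE)
      } else integer()
      span <- sum(ex_lens) + sum(in_lens)
      if (cursor + span + 10L > config$chrom_len) {
        abort(sprintf(
          paste0("Chromosome length %d cannot fit the requested genes ",
                 "(ran out of space at gene %d of %d on %s); increase ",
                 "`chrom_len` or reduce gene sizes."),
          config$chrom_len, gi, genes_per_chrom[ci], chrom))
      }
      gene_counter <- gene_counter + 1L
      gene_id <- pad_id("g", gene_counter)
      strand <- if (runif(1) < config$minus_strand_fraction) "-" else "+"

      starts <- integer(n_ex); ends <- integer(n_ex)
      pos <- cursor
      for (k in seq_len(n_ex)) {
        starts[k] <- pos
        ends[k] <- pos + ex_lens[k]
        pos <- ends[k] + if (k < n_ex) in_lens[k] else 0L
      }

      # Install canonical splice signals in transcribed orientation. On the
      # plus strand the two bases after each exon end read GT and the two
      # before each exon start read AG; on the minus strand the mirrored
      # complements (AC before start, CT after end on the plus strand).
      for (k in seq_len(n_ex)) {
        if (strand == "+") {
          substr(seq_ch, ends[k] + 1L, ends[k] + 2L) <- "GT"
          substr(seq_ch, starts[k] - 1L, starts[k]) <- "AG"
        } else {
          substr(seq_ch, starts[k] - 1L, starts[k]) <- "AC"
          substr(seq_ch, ends[k] + 1L, ends[k] + 2L) <- "CT"
        }
      }

      is_circ <- runif(1) < config$circ_gene_fraction
      circ_exon <- NA_integer_
      circ_fraction <- 0
      if (is_circ) {
        # Prefer an internal exon as the circularizable one, as for the
        # single-exon circles the analysis targets (e.g. a second exon).
        circ_exon <- if (n_ex >= 3L) {
          (2:(n_ex - 1L))[sample.int(n_ex - 2L, 1L)]
        } else if (n_ex == 2L) 2L else 1L
        circ_fraction <- runif(1, config$circ_fraction_range[1],
                               config$circ_fraction_range[2])
      }

      genes[[gene_counter]] <- tibble(
        gene_id = gene_id, chrom = chrom, strand = strand,
        base_expression = stats::rlnorm(1, config$expression_meanlog,
                                        config$expression_sdlog),
        circ_exon = circ_exon, circ_fraction = circ_fraction
      )
      exons[[gene_counter]] <- tibble(
        gene_id = gene_id, exon_rank = seq_len(n_ex), chrom = chrom,
        start = starts, end = ends
      )

      # Alu elements: inside exons and inside flanking introns, either
      # orientation, clear of the 2-nt splice signals.
      n_alu <- stats::rpois(1, config$alu_per_gene)
      if (n_alu > 0L) {
        targets <- rbind(
          cbind(starts + 2L, ends - 2L),
          if (n_ex > 1L) cbind(ends[-n_ex] + 4L, starts[-1L] - 4L) else NULL
        )
        placed <- matrix(integer(), ncol = 2L)
        for (a in seq_len(n_alu)) {
          alen <- sample(config$alu_len[1]:config$alu_len[2], 1L)
          ok <- which(targets[, 2] - targets[, 1] > alen + 2L)
          if (length(ok) == 0L) next
          tgt <- targets[ok[sample.int(length(ok), 1L)], , drop = TRUE]
          # rejection-sample a start that does not overlap an earlier Alu
          a_start <- NA_integer_
          for (try in 1:8) {
            cnd <- tgt[1] + sample.int(tgt[2] - alen - tgt[1] + 1L, 1L) - 1L
            if (nrow(placed) == 0L ||
                all(cnd + alen <= placed[, 1] | cnd >= placed[, 2])) {
              a_start <- cnd; break
            }
          }
          if (is.na(a_start)) next
          placed <- rbind(placed, c(a_start, a_start + alen))
          alu_counter <- alu_counter + 1L
          sense <- runif(1) < config$alu_sense_fraction
          alus[[alu_counter]] <- tibble(
            alu_id = pad_id("alu", alu_counter),
            chrom = chrom, start = a_start, end = a_start + alen,
            strand = if (sense) strand else flip_strand(strand)
          )
        }
      }
      cursor <- pos + sample(config$gap_len[1]:config$gap_len[2], 1L) + 10L
    }
    chromosomes[[chrom]] <- seq_ch
  }

  gm <- structure(list(
    chromosomes = chromosomes,
    genes = bind_rows(genes),
    exons = bind_rows(exons),
    alus = if (alu_counter > 0L) bind_rows(alus) else {
      tibble(alu_id = character(), chrom = character(),
             start = integer(), end = integer(), strand = character())
    }
  ), class = "genome_model")
  validate_genome(gm)
  gm
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

diff_split <- function(n, k) {
  base <- rep(n %/% k, k)
  if (n %% k > 0) base[seq_len(n %% k)] <- base[seq_len(n %% k)] + 1L
  base
}

#' @noRd
validate_genome <- function(gm) {
  lens <- nchar(gm$chromosomes)
  ex <- gm$exons
  bad <- ex$start < 0L | ex$end > lens[ex$chrom] | ex$start >= ex$end
  if (any(bad)) abort("Exon intervals must lie within their chromosome.")
  by_gene <- split(ex, ex$gene_id)
  for (g in by_gene) {
    o <- order(g$start)
    if (any(g$start[o][-1] < g$end[o][-nrow(g)])) {
      abort("Exons of one gene must be disjoint.")
    }
  }
  al <- gm$alus
  if (nrow(al) > 0) {
    bad <- al$start < 0L | al$end > lens[al$chrom] | al$end - al$start < 50L
    if (any(bad)) abort("Alu elements must lie within a chromosome and be >= 50 nt.")
  }
  gn <- gm$genes
  if (any(!is.na(gn$circ_exon))) {
    n_ex <- table(ex$gene_id)
    ci <- gn$circ_exon[!is.na(gn$circ_exon)]
    if (any(ci < 1L | ci > n_ex[gn$gene_id[!is.na(gn$circ_exon)]])) {
      abort("circ_exon must address an existing exon.")
    }
  }
  if (any(gn$circ_fraction < 0 | gn$circ_fraction > 1)) {
    abort("circ_fraction must lie in [0, 1].")
  }
  invisible(gm)
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf(
    "<genome_model> %d chromosome(s), %d genes (%d circularizable), %d Alu elements\n",
    length(x$chromosomes), nrow(x$genes), sum(!is.na(x$genes$circ_exon)),
    nrow(x$alus)))
  invisible(x)
}

#' True back-splice junctions implied by a genome model
#'
#' One row per circularizable exon: the genomic circle a back-splice read
#' supports. Coordinates are the exon boundaries (0-based half-open).
#'
#' @param genome A `genome_model`.
#' @return Tibble with columns junction_id, gene_id, chrom, start, end,
#'   strand, circ_fraction.
#' @export
true_junctions <- function(genome) {
  gn <- filter(genome$genes, !is.na(.data$circ_exon))
  if (nrow(gn) == 0) {
    return(tibble(junction_id = character(), gene_id = character(),
                  chrom = character(), start = integer(), end = integer(),
                  strand = character(), circ_fraction = numeric()))
  }
  ex <- genome$exons
  purrr::pmap_dfr(gn, function(gene_id, chrom, strand, base_expression,
                               circ_exon, circ_fraction) {
    e <- ex[ex$gene_id == gene_id & ex$exon_rank == circ_exon, ]
    tibble(junction_id = paste0(chrom, ":", e$start, "-", e$end, ":", strand),
           gene_id = gene_id, chrom = chrom, start = e$start, end = e$end,
           strand = strand, circ_fraction = circ_fraction)
  })
}
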