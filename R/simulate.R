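# Read simulator: per-sample FASTQ + ground-truth SAM with linear spliced,
# unspliced (pre-mRNA) and back-spliced circular reads, per-site A-to-I
# editing at Alu adenosines, and uniform substitution sequencing error.

# Precompute per-gene transcript machinery: spliced transcript, pre-mRNA and
# circular-exon templates (strand-oriented), exon block tables, and editing
# site positions in each template's coordinates.
gene_maps <- function(genome, editing = NULL) {
  sites <- if (is.null(editing)) NULL else editing$sites
  out <- vector("list", nrow(genome$genes))
  names(out) <- genome$genes$gene_id
  for (i in seq_len(nrow(genome$genes))) {
    g <- genome$genes[i, ]
    ex <- genome$exons |>
      filter(.data$gene_id == g$gene_id) |>
      arrange(.data$start)
    seq_ch <- genome$chromosomes[[g$chrom]]
    ex_lens <- ex$end - ex$start
    cum <- cumsum(ex_lens)
    cb <- c(0L, head(cum, -1L))
    tx_len <- sum(ex_lens)
    plus_cat <- paste(substring(seq_ch, ex$start + 1L, ex$end), collapse = "")
    tx_seq <- if (g$strand == "+") plus_cat else revcomp(plus_cat)
    span_start <- min(ex$start); span_end <- max(ex$end)
    pre_len <- span_end - span_start
    pre_plus <- subseq0(seq_ch, span_start, span_end)
    pre_seq <- if (g$strand == "+") pre_plus else revcomp(pre_plus)

    circ <- NULL
    if (!is.na(g$circ_exon)) {
      ce <- ex[ex$exon_rank == g$circ_exon, ]
      Lc <- ce$end - ce$start
      c_plus <- subseq0(seq_ch, ce$start, ce$end)
      cseq <- if (g$strand == "+") c_plus else revcomp(c_plus)
      circ <- list(cstart = ce$start, cend = ce$end, Lc = Lc,
                   template = paste0(cseq, substr(cseq, 1L, nchar(cseq) - 1L)))
    }

    gsite <- NULL
    if (!is.null(sites) && nrow(sites) > 0) {
      gsite <- sites |>
        filter(.data$chrom == g$chrom, .data$pos >= span_start,
               .data$pos < span_end, .data$ctx_strand == g$strand)
    }
    tx_sites <- pre_sites <- circ_sites <- tibble(tpos = integer(),
                                                  rate = numeric())
    if (!is.null(gsite) && nrow(gsite) > 0) {
      # pre-mRNA template
      p_plus <- gsite$pos - span_start + 1L
      ppos <- if (g$strand == "+") p_plus else pre_len - p_plus + 1L
      pre_sites <- tibble(tpos = ppos, rate = gsite$rate)
      # spliced transcript: positions inside an exon
      k <- findInterval(gsite$pos, ex$start)
      in_ex <- k >= 1 & gsite$pos < ex$end[pmax(k, 1L)]
      if (any(in_ex)) {
        kk <- k[in_ex]
        t_plus <- cb[kk] + (gsite$pos[in_ex] - ex$start[kk]) + 1L
        tpos <- if (g$strand == "+") t_plus else tx_len - t_plus + 1L
        tx_sites <- tibble(tpos = tpos, rate = gsite$rate[in_ex])
      }
      if (!is.null(circ)) {
        in_c <- gsite$pos >= circ$cstart & gsite$pos < circ$cend
        if (any(in_c)) {
          o <- gsite$pos[in_c] - circ$cstart + 1L
          cpos <- if (g$strand == "+") o else circ$Lc - o + 1L
          circ_sites <- tibble(tpos = cpos, rate = gsite$rate[in_c])
        }
      }
    }

    out[[i]] <- list(
      gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
      ex_start = ex$start, ex_end = ex$end, ex_lens = ex_lens,
      cum = cum, cb = cb, tx_len = tx_len, tx_seq = tx_seq,
      span_start = span_start, span_end = span_end,
      pre_len = pre_len, pre_seq = pre_seq, circ = circ,
      tx_sites = tx_sites, pre_sites = pre_sites, circ_sites = circ_sites,
      circ_fraction = g$circ_fraction, base_expression = g$base_expression
    )
  }
  out
}

# Apply per-site editing (A->G on the transcribed strand) to a batch of reads
# drawn from one template. `starts` are 1-based template starts; sites may
# include a duplicated copy at tpos + period for circular templates.
apply_editing <- function(seqs, starts, read_len, sites, edit_mult,
                          period = NULL) {
  if (nrow(sites) == 0 || length(seqs) == 0) return(seqs)
  tpos <- sites$tpos
  rate <- pmin(1, sites$rate * edit_mult)
  if (!is.null(period)) {
    tpos <- c(tpos, tpos + period)
    rate <- c(rate, rate)
  }
  for (j in seq_along(tpos)) {
    t <- tpos[j]
    idx <- which(starts <= t & starts > t - read_len)
    if (length(idx) == 0) next
    hit <- idx[rbinom(length(idx), 1L, rate[j]) == 1L]
    if (length(hit) == 0) next
    off <- t - starts[hit] + 1L
    substr(seqs[hit], off, off) <- "G"
    # NB: templates are transcribed-strand sequences, so the edited base is
    # always written as G here; minus-strand genes acquire C on the plus
    # strand at serialization through the reverse complement.
  }
  seqs
}

# Uniform substitution errors: each base independently flips to one of the
# three other bases with probability error_rate.
apply_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0) return(seqs)
  L <- nchar(seqs)
  n_err <- rbinom(length(seqs), L, error_rate)
  which_err <- which(n_err > 0)
  if (length(which_err) == 0) return(seqs)
  idx <- rep(which_err, n_err[which_err])
  pos <- unlist(lapply(which_err, function(i) {
    sample.int(L[i], n_err[i], replace = FALSE)
  }))
  cur <- substr(seqs[idx], pos, pos)
  ci <- match(cur, BASES)
  new <- BASES[((ci - 1L + sample.int(3L, length(ci), replace = TRUE)) %% 4L) + 1L]
  substr(seqs[idx], pos, pos) <- new
  seqs
}

#' Simulate one sample's reads with ground truth
#'
#' Draws single-end reads from a synthetic genome for one cohort sample.
#' Reads come from the spliced linear transcript, from unspliced pre-mRNA
#' (so flanking-intron Alu positions receive coverage, as in rRNA-depleted
#' libraries), or from the circular exon with wrap-around; circular reads
#' whose start lies within `read_len - 1` of the circle end cross the
#' back-splice junction. A-to-I editing is applied per site at the Alu
#' adenosines of the transcribed strand before uniform substitution error.
#' The ground-truth SAM records the error-free alignment of every read:
#' spliced reads as M/N-gapped records, junction-crossing circular reads as a
#' primary plus a supplementary soft-clipped record.
#'
#' @param genome A `genome_model`.
#' @param meta One row of sample metadata (must appear in `design`).
#' @param design A [cohort_design()].
#' @param editing Optional [editing_model()]; `NULL` disables editing.
#' @param n_reads Number of reads to draw.
#' @param read_len Read length; must be shorter than every circularizable
#'   exon and no longer than the shortest exon.
#' @param error_rate Per-base substitution error rate in `[0, 0.05)`.
#' @param premrna_fraction Fraction of non-circular reads drawn unspliced.
#' @param outdir Directory for the FASTQ/SAM output files.
#' @param write_files Write FASTQ and truth SAM (default) or return reads
#'   in memory only.
#' @param write_sam Set `FALSE` to skip the truth SAM (for workflows that
#'   only consume reads).
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `sample_id`, file paths `fastq` and `sam` (or `NULL`),
#'   `reads` (tibble: read_id, gene_id, class, start, seq), and `truth`
#'   (tibble of true junctions with expected and realized junction-read
#'   counts for this sample).
#' @export
simulate_sample <- function(genome, meta, design, editing = NULL,
                            n_reads = 20000L, read_len = 100L,
                            error_rate = 0.002, premrna_fraction = 0.08,
                            outdir = tempfile("sample_"),
                            write_files = TRUE, write_sam = TRUE,
                            seed = 1L) {
  n_reads <- assert_scalar_int(n_reads, "n_reads", min = 1L)
  read_len <- assert_scalar_int(read_len, "read_len", min = 20L)
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 0.05) {
    abort("`error_rate` must lie in [0, 0.05).")
  }
  if (!meta$sample_id %in% design$samples$sample_id) {
    abort(sprintf("unknown sample_id '%s' (not in the cohort design).",
                  meta$sample_id))
  }
  maps <- if (is.list(genome) && !inherits(genome, "genome_model")) {
    genome  # pre-computed gene_maps passed through by simulate_cohort
  } else {
    m <- gene_maps(genome, editing)
    attr(m, "chrom_lens") <- nchar(genome$chromosomes)
    m
  }
  min_exon <- min(unlist(lapply(maps, function(m) m$ex_lens)))
  circ_lens <- unlist(lapply(maps, function(m) if (is.null(m$circ)) NULL else m$circ$Lc))
  if (length(circ_lens) && read_len >= min(circ_lens)) {
    abort("`read_len` must be shorter than every circularizable exon.")
  }
  if (read_len > min_exon) {
    abort("`read_len` must not exceed the shortest exon (reads may cross at most one splice junction).")
  }
  set.seed(assert_scalar_int(seed, "seed"))

  mod <- design$modifiers[design$modifiers$sample_id == meta$sample_id, ]
  w <- vapply(maps, function(m) m$base_expression, numeric(1))
  w <- w / sum(w)
  gene_draw <- sample.int(length(maps), n_reads, replace = TRUE, prob = w)
  n_per_gene <- tabulate(gene_draw, nbins = length(maps))

  L <- read_len
  parts <- vector("list", length(maps))
  truth <- vector("list", length(maps))

  for (i in seq_along(maps)) {
    m <- maps[[i]]
    ng <- n_per_gene[i]
    pc <- if (is.null(m$circ)) 0 else min(1, m$circ_fraction * mod$circ_mult)
    cls <- if (ng > 0) {
      sample(c("circ", "pre", "tx"), ng, replace = TRUE,
             prob = c(pc, (1 - pc) * premrna_fraction,
                      (1 - pc) * (1 - premrna_fraction)))
    } else character()
    n_c <- sum(cls == "circ"); n_p <- sum(cls == "pre"); n_t <- sum(cls == "tx")

    if (n_t > 0) {
      s_t <- sample.int(m$tx_len - L + 1L, n_t, replace = TRUE)
      q_t <- substring(m$tx_seq, s_t, s_t + L - 1L)
      q_t <- apply_editing(q_t, s_t, L, m$tx_sites, mod$edit_mult)
    } else {
      s_t <- integer(); q_t <- character()
    }

    if (n_p > 0) {
      s_p <- sample.int(m$pre_len - L + 1L, n_p, replace = TRUE)
      q_p <- substring(m$pre_seq, s_p, s_p + L - 1L)
      q_p <- apply_editing(q_p, s_p, L, m$pre_sites, mod$edit_mult)
    } else {
      s_p <- integer(); q_p <- character()
    }

    if (n_c > 0) {
      s_c <- sample.int(m$circ$Lc, n_c, replace = TRUE)
      q_c <- substring(m$circ$template, s_c, s_c + L - 1L)
      q_c <- apply_editing(q_c, s_c, L, m$circ_sites, mod$edit_mult,
                           period = m$circ$Lc)
    } else {
      s_c <- integer(); q_c <- character()
    }

    parts[[i]] <- tibble(
      gene_id = m$gene_id,
      class = c(rep("tx", n_t), rep("pre", n_p), rep("circ", n_c)),
      start = c(s_t, s_p, s_c),
      seq = c(q_t, q_p, q_c)
    )
    if (!is.null(m$circ)) {
      realized <- sum(s_c > m$circ$Lc - (L - 1L))
      truth[[i]] <- tibble(
        junction_id = paste0(m$chrom, ":", m$circ$cstart, "-", m$circ$cend,
                             ":", m$strand),
        gene_id = m$gene_id, chrom = m$chrom,
        start = m$circ$cstart, end = m$circ$cend, strand = m$strand,
        expected_reads = n_reads * w[i] * pc * (L - 1) / m$circ$Lc,
        realized_reads = realized
      )
    }
  }

  reads <- bind_rows(parts)
  reads$seq <- apply_errors(reads$seq, error_rate)
  reads$read_id <- sprintf("r%06d", seq_len(nrow(reads)))
  reads <- select(reads, "read_id", "gene_id", "class", "start", "seq")

  fastq <- sam <- NULL
  if (write_files) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fastq <- file.path(outdir, paste0(meta$sample_id, ".fastq"))
    write_fastq(reads$seq, reads$read_id, fastq)
    if (write_sam) {
      sam <- file.path(outdir, paste0(meta$sample_id, ".sam"))
      write_truth_sam(reads, maps, genome_lengths(maps), sam, read_len = L)
    }
  }

  list(sample_id = meta$sample_id, fastq = fastq, sam = sam, reads = reads,
       truth = bind_rows(truth))
}

genome_lengths <- function(maps) {
  # chromosome lengths are carried on the maps' parent genome at write time;
  # recovered from attributes set in simulate_cohort, else from the maps'
  # spans (upper bound). Overridden by write_truth_sam callers when exact.
  attr(maps, "chrom_lens")
}

#' Simulate a full cohort with master ground truth
#'
#' Runs [simulate_sample()] for every sample in a [cohort_design()], deriving
#' each sample's seed from the design seed so the whole cohort is
#' reproducible. Condition multipliers, the age trend, and the optional
#' editing coupling enter through the design's per-sample modifiers.
#'
#' @inheritParams simulate_sample
#' @param design A [cohort_design()].
#' @param outdir Output directory (one FASTQ + SAM per sample).
#' @return A list of class `cohort_sim`: `samples` (tibble sample_id, fastq,
#'   sam), `truth_junctions` (long tibble junction x sample expected and
#'   realized junction-read counts), `truth_editing` (per-sample expected
#'   mean editing rate), `design`, and the simulation parameters.
#' @export
simulate_cohort <- function(genome, design, editing = NULL,
                            n_reads = 20000L, read_len = 100L,
                            error_rate = 0.002, premrna_fraction = 0.08,
                            outdir = tempfile("cohort_"),
                            write_files = TRUE, write_sam = TRUE) {
  stopifnot(inherits(design, "cohort_design"))
  if (nrow(design$samples) == 0) abort("empty sample list.")
  maps <- gene_maps(genome, editing)
  attr(maps, "chrom_lens") <- nchar(genome$chromosomes)
  set.seed(design$seed)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, nrow(design$samples))

  res <- vector("list", nrow(design$samples))
  for (i in seq_len(nrow(design$samples))) {
    meta <- design$samples[i, ]
    res[[i]] <- simulate_sample(
      maps, meta, design, editing = editing, n_reads = n_reads,
      read_len = read_len, error_rate = error_rate,
      premrna_fraction = premrna_fraction,
      outdir = outdir, write_files = write_files, write_sam = write_sam,
      seed = sample_seeds[i])
  }

  truth_junctions <- purrr::map2_dfr(res, design$samples$sample_id,
    function(r, sid) mutate(r$truth, sample_id = sid))
  truth_editing <- tibble(
    sample_id = design$samples$sample_id,
    edit_mult = design$modifiers$edit_mult,
    expected_mean_rate = vapply(design$modifiers$edit_mult, function(mlt) {
      if (is.null(editing) || nrow(editing$sites) == 0) 0
      else mean(pmin(1, editing$sites$rate * mlt))
    }, numeric(1))
  )
  structure(list(
    samples = tibble(
      sample_id = design$samples$sample_id,
      fastq = vapply(res, function(r) r$fastq %||% NA_character_, character(1)),
      sam = vapply(res, function(r) r$sam %||% NA_character_, character(1))
    ),
    reads = if (write_files) NULL else lapply(res, `[[`, "reads"),
    truth_junctions = truth_junctions,
    truth_editing = truth_editing,
    design = design,
    params = list(n_reads = n_reads, read_len = read_len,
                  error_rate = error_rate,
                  premrna_fraction = premrna_fraction)
  ), class = "cohort_sim")
}
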