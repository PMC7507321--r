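# Back-splice (head-to-tail) junction detection: anchor both read ends on
# the genome, call a candidate when the 3' anchor maps upstream of the 5'
# anchor on one strand, then locate the breakpoint by mismatch-budgeted
# extension and canonical GT/AG placement.

#' Detection parameters
#'
#' @param anchor_len Anchor length taken from each read end (also the k-mer
#'   size of the index).
#' @param max_span Maximum genomic span of a junction (nt).
#' @param breakpoint_ambiguity_max Maximum slide (nt) applied around the
#'   best breakpoint to find a GT/AG placement.
#' @param require_gt_ag Keep only junctions with canonical GT/AG signals in
#'   transcribed orientation.
#' @param max_mismatch_extend Mismatches allowed outside the anchors when
#'   extending to the breakpoint.
#' @return A list of class `detect_params`.
#' @export
detect_params <- function(anchor_len = 20L, max_span = 100000L,
                          breakpoint_ambiguity_max = 2L,
                          require_gt_ag = TRUE, max_mismatch_extend = 2L) {
  structure(list(
    anchor_len = assert_scalar_int(anchor_len, "anchor_len", 12L, 32L),
    max_span = assert_scalar_int(max_span, "max_span", min = 1L),
    breakpoint_ambiguity_max = assert_scalar_int(
      breakpoint_ambiguity_max, "breakpoint_ambiguity_max", min = 0L),
    require_gt_ag = isTRUE(require_gt_ag),
    max_mismatch_extend = assert_scalar_int(
      max_mismatch_extend, "max_mismatch_extend", min = 0L)
  ), class = "detect_params")
}

# Locate the breakpoint of a head-to-tail candidate. `read` is oriented so
# that it aligns the plus strand of `chrom_seq` (minus-strand candidates are
# reverse-complemented by the caller); a0/b0 are the 0-based plus-strand
# positions of its 5' and 3' anchors, with b0 < a0. Returns NULL or
# list(start, end, mismatches, splice_signal).
resolve_breakpoint <- function(read, chrom_seq, a0, b0, strand, params) {
  Lr <- nchar(read)
  k <- params$anchor_len
  n_ch <- nchar(chrom_seq)
  rch <- charToRaw(read)

  # Genome context for prefix extension (from the 5' anchor rightwards) and
  # suffix extension (leftwards into the 3' anchor); out-of-range positions
  # are padded so they never match.
  g5 <- safe_sub(chrom_seq, a0 + 1L, a0 + Lr, n_ch)
  g3 <- safe_sub(chrom_seq, b0 + k - Lr + 1L, b0 + k, n_ch)
  eq5 <- cumsum(rch == charToRaw(g5))
  eq3 <- cumsum(rch == charToRaw(g3))
  tot3 <- eq3[Lr]

  xs <- k:(Lr - k)
  mm <- (xs - eq5[xs]) + ((Lr - xs) - (tot3 - eq3[xs]))
  mm_min <- min(mm)
  if (mm_min > params$max_mismatch_extend) return(NULL)
  cand <- xs[mm == mm_min]

  sig_at <- function(x) {
    s0 <- b0 + k - (Lr - x)
    e0 <- a0 + x
    if (s0 < 2L || e0 + 2L > n_ch || s0 >= e0) return(NULL)
    if (strand == "+") {
      donor <- subseq0(chrom_seq, e0, e0 + 2L)
      acceptor <- subseq0(chrom_seq, s0 - 2L, s0)
      ok <- donor == "GT" && acceptor == "AG"
      sig <- paste0(donor, "/", acceptor)
    } else {
      # transcribed-orientation GT/AG reads AC before start and CT after end
      # on the plus strand
      donor <- revcomp(subseq0(chrom_seq, s0 - 2L, s0))
      acceptor <- revcomp(subseq0(chrom_seq, e0, e0 + 2L))
      ok <- donor == "GT" && acceptor == "AG"
      sig <- paste0(donor, "/", acceptor)
    }
    list(start = s0, end = e0, canonical = ok, splice_signal = sig)
  }

  # Prefer a canonical GT/AG placement among equally good breakpoints,
  # sliding at most breakpoint_ambiguity_max from the first optimum.
  window <- cand[abs(cand - cand[1]) <= params$breakpoint_ambiguity_max]
  pick <- NULL
  for (x in window) {
    s <- sig_at(x)
    if (is.null(s)) next
    if (s$canonical) { pick <- s; break }
    if (is.null(pick)) pick <- s
  }
  if (is.null(pick)) return(NULL)
  if (params$require_gt_ag && !pick$canonical) return(NULL)
  if (pick$end - pick$start > params$max_span) return(NULL)
  list(start = pick$start, end = pick$end, mismatches = mm_min,
       splice_signal = pick$splice_signal)
}

safe_sub <- function(seq_ch, from1, to1, n_ch) {
  left_pad <- max(0L, 1L - from1)
  right_pad <- max(0L, to1 - n_ch)
  core <- substr(seq_ch, max(1L, from1), min(n_ch, to1))
  paste0(strrep(".", left_pad), core, strrep(".", right_pad))
}

#' Detect a back-splice junction in a single read
#'
#' Takes the first and last `anchor_len` bases as anchors, maps both on the
#' k-mer index, and calls a candidate only when both anchors map uniquely to
#' the same chromosome and strand in head-to-tail order (the 3' anchor
#' upstream of the 5' anchor in transcribed orientation). The breakpoint is
#' then located by extension with at most `max_mismatch_extend` mismatches
#' and slid within `breakpoint_ambiguity_max` positions to a canonical GT/AG
#' placement.
#'
#' @param read A single read sequence (character).
#' @param index A [build_index()] result over `genome`.
#' @param genome The `genome_model` the index was built from.
#' @param params A [detect_params()] list.
#' @return A one-row tibble (chrom, start, end, strand, splice_signal,
#'   mismatches) or `NULL` when the read supports no junction.
#' @export
detect_backsplice <- function(read, index, genome, params = detect_params()) {
  k <- params$anchor_len
  if (nchar(read) < 2L * k) abort("read shorter than two anchors.")
  if (grepl("[^ACGT]", read)) {
    warn(sprintf("read with non-ACGT base skipped: %s...",
                 substr(read, 1L, 12L)))
    return(NULL)
  }
  Lr <- nchar(read)
  lk <- index_lookup(index, c(substr(read, 1L, k),
                              substr(read, Lr - k + 1L, Lr)))
  if (any(lk$class != "unique")) return(NULL)
  h5 <- lk$hits[lk$hits$query == 1L, ]
  h3 <- lk$hits[lk$hits$query == 2L, ]
  if (h5$chrom != h3$chrom || h5$strand != h3$strand) return(NULL)

  chrom_seq <- genome$chromosomes[[h5$chrom]]
  if (h5$strand == "+") {
    if (h3$pos >= h5$pos) return(NULL)            # linear order: no circle
    res <- resolve_breakpoint(read, chrom_seq, h5$pos, h3$pos, "+", params)
  } else {
    if (h5$pos >= h3$pos) return(NULL)
    # reverse-complement the read: it then aligns the plus strand, with its
    # 5' anchor at the old 3' anchor position and vice versa
    res <- resolve_breakpoint(revcomp(read), chrom_seq, h3$pos, h5$pos,
                              "-", params)
  }
  if (is.null(res)) return(NULL)
  tibble(chrom = h5$chrom, start = res$start, end = res$end,
         strand = h5$strand, splice_signal = res$splice_signal,
         mismatches = res$mismatches)
}
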