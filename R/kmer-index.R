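# Exact k-mer anchor index over the genome. Plus-strand k-mers are stored;
# minus-strand hits are found by querying the reverse complement, so every
# stored position re-reads to its k-mer on the plus strand.

#' Build an exact k-mer index of a genome
#'
#' Indexes every overlapping k-mer of every chromosome (plus strand). Both
#' strands are queryable through [index_lookup()], which also queries the
#' reverse complement of each query.
#'
#' @param genome A `genome_model` (or any list with a `chromosomes` named
#'   character vector).
#' @param k Anchor length, between 12 and 32.
#' @return A list of class `kmer_index` with `k` and `positions` (tibble:
#'   kmer, chrom, pos; pos 0-based).
#' @export
build_index <- function(genome, k = 20L) {
  k <- assert_scalar_int(k, "k", min = 12L, max = 32L)
  lens <- nchar(genome$chromosomes)
  if (any(lens < k)) {
    abort(sprintf("k = %d exceeds the shortest chromosome (%d nt).",
                  k, min(lens)))
  }
  tabs <- purrr::imap(genome$chromosomes, function(seq_ch, chrom) {
    n <- nchar(seq_ch)
    tibble(kmer = substring(seq_ch, 1:(n - k + 1L), k:n),
           chrom = chrom, pos = 0:(n - k))
  })
  positions <- bind_rows(tabs)
  # aggregated lookup table: one row per distinct k-mer with its hit count
  # and (for single-hit k-mers) the hit location -- all the batch detector
  # needs, reachable with one hash match() per query vector
  ord <- order(positions$kmer)
  km <- positions$kmer[ord]
  first <- !duplicated(km)
  n_hits <- diff(c(which(first), length(km) + 1L))
  agg <- list(kmer = km[first],
              chrom = positions$chrom[ord][first],
              pos = positions$pos[ord][first],
              n = n_hits)
  structure(list(k = k, positions = positions, agg = agg),
            class = "kmer_index")
}

#' Look up anchors in a k-mer index
#'
#' Returns all exact hits of each query on either strand: a plus-strand hit
#' means the query matches the genome forward at `pos`; a minus-strand hit
#' means the query's reverse complement matches at `pos` (the query aligns to
#' the minus strand there). Each query is also classified
#' unique / multi / none across both strands.
#'
#' @param index A `kmer_index`.
#' @param kmers Character vector of queries of length `index$k`.
#' @return List with `hits` (tibble: query (index into `kmers`), chrom, pos,
#'   strand) and `class` (character vector, one of "unique", "multi",
#'   "none" per query).
#' @export
index_lookup <- function(index, kmers) {
  stopifnot(inherits(index, "kmer_index"))
  if (any(nchar(kmers) != index$k)) {
    abort(sprintf("queries must have length k = %d.", index$k))
  }
  q <- tibble(query = seq_along(kmers), kmer = kmers, strand = "+")
  qrc <- tibble(query = seq_along(kmers), kmer = revcomp(kmers), strand = "-")
  hits <- bind_rows(q, qrc) |>
    inner_join(index$positions, by = "kmer",
               relationship = "many-to-many") |>
    select("query", "chrom", "pos", "strand") |>
    arrange(.data$query, .data$chrom, .data$pos)
  n_hits <- tabulate(hits$query, nbins = length(kmers))
  cls <- ifelse(n_hits == 0L, "none", ifelse(n_hits == 1L, "unique", "multi"))
  list(hits = hits, class = cls)
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k = %d, %d positions over %d chromosome(s)\n",
              x$k, nrow(x$positions), length(unique(x$positions$chrom))))
  invisible(x)
}
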