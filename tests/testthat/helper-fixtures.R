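# Shared fixtures (built in code) and independent oracles used across the
# test files. Heavier simulated objects are memoised for the session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  hit <- get0(key, envir = .fixture_env)
  if (!is.null(hit)) return(hit)
  val <- build()
  assign(key, val, envir = .fixture_env)
  val
}

tiny_genome <- function(seed = 1L, ...) {
  build_genome(genome_config(chrom_len = 20000L, n_genes = 5L, ...),
               seed = seed)
}

# A small simulated cohort shared by detection/editing tests.
tiny_cohort <- function() {
  memo("tiny_cohort", function() {
    g <- tiny_genome(seed = 11)
    em <- editing_model(g, rate = 0.05)
    d <- cohort_design(
      cohort_samples(1L, regions = c("SN", "MTG"), seed = 11), seed = 11)
    sim <- simulate_cohort(g, d, editing = em, n_reads = 15000L,
                           outdir = file.path(tempdir(), "tiny_cohort"))
    list(genome = g, editing = em, design = d, sim = sim)
  })
}

tiny_counts <- function() {
  memo("tiny_counts", function() {
    tc <- tiny_cohort()
    call_junctions(setNames(tc$sim$samples$fastq, tc$sim$samples$sample_id),
                   tc$genome, meta = tc$design$samples)
  })
}

# Build a circ_counts object directly from a dense count matrix.
make_counts <- function(mat, mapped = NULL, meta = NULL) {
  jid <- paste0("j", seq_len(nrow(mat)))
  junctions <- tibble::tibble(
    junction_id = jid, chrom = "chr1",
    start = seq_len(nrow(mat)) * 1000L,
    end = seq_len(nrow(mat)) * 1000L + 200L, strand = "+")
  counts <- dplyr::bind_cols(tibble::tibble(junction_id = jid),
                             tibble::as_tibble(mat))
  if (is.null(mapped)) mapped <- setNames(colSums(mat) + 1000, colnames(mat))
  circ_counts(junctions, counts, mapped, meta)
}

# --- independent oracles -------------------------------------------------

# Brute-force circular seed scan: rotate the circle through every offset,
# test each motif at the rotated origin, then apply pairwise containment
# suppression (quadratic, no shared code with scan_seed_sites()).
oracle_scan <- function(circle, mirna) {
  circle <- chartr("U", "T", toupper(circle))
  L <- nchar(circle)
  ranks <- c(`6mer` = 1L, `7mer-A1` = 2L, `7mer-m8` = 3L, `8mer` = 4L)
  found <- list()
  for (r in 0:(L - 1L)) {
    rot <- paste0(substr(circle, r + 1L, L), substr(circle, 1L, r))
    rot2 <- paste0(rot, rot)  # allow motifs longer than the remainder
    for (cl in names(sort(ranks, decreasing = TRUE))) {
      motif <- mirna$motifs[[cl]]
      if (substr(rot2, 1L, nchar(motif)) == motif) {
        found[[length(found) + 1L]] <-
          list(pos = r, class = cl, len = nchar(motif))
        break
      }
    }
  }
  if (length(found) == 0) {
    return(tibble::tibble(position = integer(), site_class = character()))
  }
  keep <- rep(TRUE, length(found))
  for (i in seq_along(found)) {
    for (j in seq_along(found)) {
      if (i == j || !keep[j]) next
      fi <- found[[i]]; fj <- found[[j]]
      if (ranks[fj$class] > ranks[fi$class] &&
          ((fi$pos - fj$pos) %% L) + fi$len <= fj$len) {
        keep[i] <- FALSE
      }
    }
  }
  kept <- found[keep]
  tibble::tibble(
    position = vapply(kept, `[[`, integer(1), "pos"),
    site_class = vapply(kept, `[[`, character(1), "class")) |>
    dplyr::arrange(position)
}

# Closed-form one-sided hypergeometric tail for a 2x2 table
# (a = DE&target), computed from binomial coefficients only.
oracle_fisher_tail <- function(a, b, c_, d) {
  K <- a + b          # DE genes
  M <- a + c_         # targets
  N <- a + b + c_ + d
  ks <- a:min(K, M)
  sum(choose(M, ks) * choose(N - M, K - ks)) / choose(N, K)
}

# Brute-force BH step-up.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# Does `read` equal some rotation of the circle [start,end) (transcribed
# orientation) up to `max_mm` mismatches? Exhaustive over rotations.
oracle_is_circle_read <- function(read, genome, chrom, start, end, strand,
                                  max_mm = 0L) {
  circ <- substr(genome$chromosomes[[chrom]], start + 1L, end)
  if (strand == "-") circ <- revcomp(circ)
  L <- nchar(circ)
  doubled <- paste0(circ, circ)
  rl <- nchar(read)
  rch <- strsplit(read, NULL)[[1]]
  for (s in 1:L) {
    win <- substr(doubled, s, s + rl - 1L)
    if (sum(strsplit(win, NULL)[[1]] != rch) <= max_mm) return(TRUE)
  }
  FALSE
}

# Parse a minimal SAM body back into records (qname, flag, rname, pos1,
# cigar, seq) without Rsamtools, for realignment checks.
parse_sam <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  if (length(body) == 0) {
    return(tibble::tibble(qname = character(), flag = integer(),
                          rname = character(), pos1 = integer(),
                          cigar = character(), seq = character()))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  tibble::tibble(qname = vapply(f, `[[`, character(1), 1),
                 flag = as.integer(vapply(f, `[[`, character(1), 2)),
                 rname = vapply(f, `[[`, character(1), 3),
                 pos1 = as.integer(vapply(f, `[[`, character(1), 4)),
                 cigar = vapply(f, `[[`, character(1), 6),
                 seq = vapply(f, `[[`, character(1), 10))
}

# Verify one SAM record's M blocks match the genome exactly.
sam_record_realigns <- function(rec, genome) {
  ops <- stringr::str_match_all(rec$cigar, "(\\d+)([MNS])")[[1]]
  gpos <- rec$pos1
  qpos <- 1L
  for (k in seq_len(nrow(ops))) {
    len <- as.integer(ops[k, 2]); op <- ops[k, 3]
    if (op == "M") {
      gseg <- substr(genome$chromosomes[[rec$rname]], gpos, gpos + len - 1L)
      qseg <- substr(rec$seq, qpos, qpos + len - 1L)
      if (gseg != qseg) return(FALSE)
      gpos <- gpos + len; qpos <- qpos + len
    } else if (op == "N") {
      gpos <- gpos + len
    } else if (op == "S") {
      qpos <- qpos + len
    }
  }
  TRUE
}
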