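# Back-splice detection: k-mer index behaviour, single-read breakpoint
# calls against an exhaustive rotation oracle, cohort-level calling against
# simulator ground truth, and the QC filters.

test_that("k-mer index classifies unique, multi and absent queries", {
  seq1 <- paste0(strrep("ACGT", 4L), "CCTAGGTTAACCGGATCCAA",
                 paste(rep(c("A", "C", "G", "T"), 250L), collapse = ""))
  dup <- "TTGACCAGTTGACGAATCGC"
  chrom <- paste0(seq1, dup, strrep("CA", 30L), dup)
  g <- list(chromosomes = c(c1 = chrom))
  idx <- build_index(g, k = 20L)
  q_first <- substr(chrom, 1L, 20L)
  lk <- index_lookup(idx, c(q_first, strrep("A", 20L), dup))
  expect_true(any(lk$hits$pos[lk$hits$query == 1] == 0L))
  expect_identical(lk$class[2], "none")
  expect_identical(lk$class[3], "multi")
  # minus-strand query: the reverse complement of a plus k-mer
  lk2 <- index_lookup(idx, revcomp(q_first))
  expect_true(any(lk2$hits$strand == "-" & lk2$hits$pos == 0L))
  expect_error(build_index(list(chromosomes = c(c1 = "ACGTACGT")), k = 20L),
               "shortest chromosome")
  expect_error(build_index(g, k = 8L), "k")
})

# A deterministic genome with one plus-strand circle [300, 400) flanked by
# canonical signals, built base by base so the coordinates are exact.
circle_genome <- function(seed = 101L) {
  set.seed(seed)
  n <- 3000L
  s <- random_dna(n)
  substr(s, 299L, 300L) <- "AG"   # acceptor upstream of start (0-based 300)
  substr(s, 401L, 402L) <- "GT"   # donor downstream of end (0-based 400)
  list(chromosomes = c(c1 = s))
}

test_that("detect_backsplice calls a constructed canonical circle and rejects linear order", {
  g <- circle_genome()
  idx <- build_index(g, 20L)
  chrom <- g$chromosomes[["c1"]]
  # head-to-tail read: the circle's 3' end then its 5' start
  read <- paste0(substr(chrom, 361L, 400L), substr(chrom, 301L, 340L))
  hit <- detect_backsplice(read, idx, g)
  expect_identical(hit$start, 300L)
  expect_identical(hit$end, 400L)
  expect_identical(hit$strand, "+")
  expect_identical(hit$splice_signal, "GT/AG")

  linear <- paste0(substr(chrom, 301L, 340L), substr(chrom, 361L, 400L))
  expect_null(detect_backsplice(linear, idx, g))
  expect_warning(out <- detect_backsplice(chartr("A", "N", read), idx, g),
                 "non-ACGT")
  expect_null(out)
})

test_that("breakpoint calls tolerate interior mismatches and agree with the rotation oracle", {
  g <- circle_genome()
  idx <- build_index(g, 20L)
  chrom <- g$chromosomes[["c1"]]
  set.seed(7)
  for (rep in 1:25) {
    s0 <- sample(301:399, 1L)   # 1-based read start within the circle
    doubled <- paste0(substr(chrom, 301L, 400L), substr(chrom, 301L, 400L))
    read <- substr(doubled, s0 - 300L, s0 - 300L + 79L)
    l1 <- 401L - s0           # bases before the wrap
    detectable <- l1 >= 20L && (80L - l1) >= 20L  # both anchors in one arm
    # plant one interior substitution (outside both anchors)
    p <- sample(25:56, 1L)
    b <- substr(read, p, p)
    substr(read, p, p) <- setdiff(c("A", "C", "G", "T"), b)[sample.int(3L, 1L)]
    hit <- detect_backsplice(read, idx, g,
                             detect_params(max_mismatch_extend = 2L))
    if (detectable) {
      expect_false(is.null(hit))
      expect_identical(c(hit$start, hit$end), c(300L, 400L))
      expect_true(oracle_is_circle_read(read, g, "c1", hit$start, hit$end,
                                        "+", max_mm = 1L))
    } else {
      # collinear, or an anchor spans the breakpoint: no call
      expect_null(hit)
    }
  }
})

test_that("all rotations of a circle yield the same junction and reverse complement flips strand", {
  tc <- tiny_cohort()
  g <- tc$genome
  idx <- build_index(g, 20L)
  tj <- true_junctions(g)
  jn <- tj[tj$strand == "+", ][1, ]
  circ <- substr(g$chromosomes[[jn$chrom]], jn$start + 1L, jn$end)
  L <- nchar(circ)
  doubled <- paste0(circ, circ)
  R <- 80L
  # junction-crossing rotations whose two arms both contain a full anchor
  starts <- seq(L - (R - 21L), L - 19L, by = 4L)
  for (s in starts) {
    read <- substr(doubled, s, s + R - 1L)
    hit <- detect_backsplice(read, idx, g)
    expect_identical(c(hit$start, hit$end, hit$strand),
                     c(jn$start, jn$end, "+"))
    # the reverse complement carries the splice signals in the opposite
    # orientation, so the flip property is checked signal-free
    flip <- detect_backsplice(revcomp(read), idx, g,
                              detect_params(require_gt_ag = FALSE))
    expect_identical(c(flip$start, flip$end, flip$strand),
                     c(jn$start, jn$end, "-"))
  }
})

test_that("cohort calling recovers the simulated truth exactly on clean data", {
  g <- build_genome(genome_config(chrom_len = 20000L, n_genes = 5L,
                                  circ_fraction_range = c(0.1, 0.3)),
                    seed = 31)
  d <- cohort_design(cohort_samples(1L, regions = "SN", seed = 31),
                     seed = 31)
  sim <- simulate_cohort(g, d, n_reads = 20000L, error_rate = 0,
                         outdir = withr::local_tempdir())
  cc <- call_junctions(setNames(sim$samples$fastq, sim$samples$sample_id),
                       g, meta = d$samples, min_support = 2L)
  exp_support <- sim$truth_junctions |>
    dplyr::group_by(junction_id) |>
    dplyr::summarise(e = sum(expected_reads))
  eligible <- exp_support$junction_id[exp_support$e >= 2]
  expect_true(all(cc$junctions$junction_id %in%
                    true_junctions(g)$junction_id))      # precision 1
  expect_true(all(eligible %in% cc$junctions$junction_id)) # recall
})

test_that("support and expression filters are strict and monotone", {
  # 10 identical junction reads -> one junction with count 10
  g <- circle_genome()
  chrom <- g$chromosomes[["c1"]]
  read <- paste0(substr(chrom, 361L, 400L), substr(chrom, 301L, 340L))
  dir <- withr::local_tempdir()
  fq1 <- file.path(dir, "s1.fastq")
  circnigra:::write_fastq(rep(read, 10L), sprintf("r%02d", 1:10), fq1)
  cc <- call_junctions(c(s1 = fq1), g, min_support = 2L)
  expect_identical(nrow(cc$junctions), 1L)
  expect_identical(cc$counts$s1, 10L)

  # a single supporting read is dropped at min_support = 2
  fq2 <- file.path(dir, "s2.fastq")
  circnigra:::write_fastq(read, "r1", fq2)
  cc1 <- call_junctions(c(s2 = fq2), g, min_support = 2L)
  expect_identical(nrow(cc1$junctions), 0L)
  expect_identical(nrow(call_junctions(c(s2 = fq2), g,
                                       min_support = 1L)$junctions), 1L)

  # empty FASTQ keeps the sample as a zero column with a warning
  fq3 <- file.path(dir, "s3.fastq")
  writeLines(character(), fq3)
  expect_warning(cc3 <- call_junctions(c(s1 = fq1, s3 = fq3), g),
                 "empty FASTQ")
  expect_identical(cc3$counts$s3, 0L)
  expect_identical(unname(cc3$mapped_totals["s3"]), 0)
})

test_that("sample QC threshold is strict and reports exclusions", {
  mat <- cbind(sA = c(3L, 2L, 0L), sB = c(5L, 5L, 5L), sC = c(1L, 0L, 0L))
  x <- make_counts(mat)
  # distinct-junction unit: sA detects 2, sB 3, sC 1
  expect_message(f <- qc_filter_samples(x, min_detected = 2L),
                 "excluded.*sC")
  expect_identical(attr(f, "excluded_samples"), "sC")
  expect_identical(sort(circnigra:::sample_names(f)), c("sA", "sB"))
  # boundary: exactly at threshold is retained (strict <)
  f2 <- qc_filter_samples(x, min_detected = 1L)
  expect_identical(length(circnigra:::sample_names(f2)), 3L)
  # reads unit, threshold 5: sA has 5 (kept), sC has 1 (dropped)
  expect_message(f3 <- qc_filter_samples(x, min_detected = 5L,
                                         unit = "reads"), "sC")
  expect_true(all(c("sA", "sB") %in% circnigra:::sample_names(f3)))
  # threshold 0 is the identity
  expect_identical(circnigra:::sample_names(qc_filter_samples(x, 0L)),
                   c("sA", "sB", "sC"))
  expect_error(qc_filter_samples(x, min_detected = 100L), "empty cohort")
})

test_that("per-tissue expression filter uses a strict > rule per tissue", {
  mat <- cbind(SN1 = c(3L, 6L, 0L), SN2 = c(3L, 0L, 0L),
               MTG1 = c(0L, 0L, 5L), MTG2 = c(0L, 0L, 0L))
  meta <- tibble::tibble(sample_id = colnames(mat),
                         region = c("SN", "SN", "MTG", "MTG"))
  x <- make_counts(mat, meta = meta)
  f <- filter_by_tissue(x, min_reads = 5L)
  expr <- attr(f, "tissue_expression")
  # junction 1: 6 reads in SN -> expressed there only (SN-unique)
  expect_identical(expr$SN[expr$junction_id == "j1"], TRUE)
  expect_identical(expr$MTG[expr$junction_id == "j1"], FALSE)
  # junction 2: 6 reads in SN -> expressed; junction 3: exactly 5 in MTG -> not
  expect_true("j2" %in% expr$junction_id)
  expect_false("j3" %in% expr$junction_id)
  # monotonicity: a higher threshold never adds junctions
  f10 <- filter_by_tissue(x, min_reads = 10L)
  expect_true(all(f10$junctions$junction_id %in% f$junctions$junction_id))
  expect_error(filter_by_tissue(make_counts(mat), min_reads = 5L),
               "metadata")
})

test_that("per-million normalization is exact and scale invariant", {
  mat <- cbind(s1 = c(50L, 0L), s2 = c(10L, 20L))
  x <- make_counts(mat, mapped = c(s1 = 1e6, s2 = 2e6))
  nm <- normalize_per_million(x)
  expect_equal(nm$s1, c(50, 0))
  expect_equal(nm$s2, c(5, 10))
  x2 <- make_counts(2L * mat, mapped = c(s1 = 2e6, s2 = 4e6))
  expect_equal(normalize_per_million(x2)$s1, nm$s1)
  x0 <- x
  x0$mapped_totals["s2"] <- 0
  expect_error(normalize_per_million(x0), "s2")
})
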