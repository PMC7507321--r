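# Synthetic genome and read simulator: splice signals, determinism, the
# circular junction-read fraction, editing application and truth alignments.

test_that("generated genomes carry canonical splice signals at every exon boundary", {
  g <- tiny_genome(seed = 1)
  ex <- dplyr::left_join(g$exons,
                         dplyr::select(g$genes, gene_id, strand),
                         by = "gene_id")
  for (i in seq_len(nrow(ex))) {
    seq_ch <- g$chromosomes[[ex$chrom[i]]]
    after_end <- substr(seq_ch, ex$end[i] + 1L, ex$end[i] + 2L)
    before_start <- substr(seq_ch, ex$start[i] - 1L, ex$start[i])
    if (ex$strand[i] == "+") {
      expect_identical(after_end, "GT")
      expect_identical(before_start, "AG")
    } else {
      # mirrored complements on the plus strand
      expect_identical(before_start, "AC")
      expect_identical(after_end, "CT")
    }
  }
})

test_that("genome generation is deterministic and respects sizing limits", {
  cfg <- genome_config(chrom_len = 20000L, n_genes = 5L)
  expect_identical(build_genome(cfg, seed = 3), build_genome(cfg, seed = 3))
  expect_false(identical(build_genome(cfg, seed = 3),
                         build_genome(cfg, seed = 4)))
  expect_error(build_genome(genome_config(chrom_len = 1500L, n_genes = 10L),
                            seed = 1),
               "cannot fit")
  g0 <- build_genome(genome_config(alu_per_gene = 0), seed = 1)
  expect_identical(nrow(g0$alus), 0L)
})

test_that("circularizable-exon invariants hold", {
  g <- tiny_genome(seed = 2)
  tj <- true_junctions(g)
  ex <- g$exons
  for (i in seq_len(nrow(tj))) {
    e <- ex[ex$gene_id == tj$gene_id[i], ]
    expect_true(any(e$start == tj$start[i] & e$end == tj$end[i]))
  }
  expect_true(all(g$genes$circ_fraction >= 0 & g$genes$circ_fraction <= 1))
})

test_that("null-model reads realign perfectly and contain no head-to-tail arrangement", {
  g <- build_genome(genome_config(chrom_len = 15000L, n_genes = 4L,
                                  circ_gene_fraction = 0),
                    seed = 5)
  d <- cohort_design(cohort_samples(1L, regions = "SN", conditions = "CT",
                                    seed = 5), seed = 5)
  out <- simulate_sample(g, d$samples[1, ], d, editing = NULL,
                         n_reads = 3000L, error_rate = 0,
                         outdir = withr::local_tempdir(), seed = 5)
  recs <- parse_sam(out$sam)
  expect_identical(nrow(recs), 3000L)
  expect_true(all(vapply(seq_len(nrow(recs)),
                         function(i) sam_record_realigns(recs[i, ], g),
                         logical(1))))
  cc <- call_junctions(setNames(out$fastq, "SN_CT_1"), g)
  expect_identical(nrow(cc$junctions), 0L)
})

test_that("simulation output is byte-identical for identical seeds", {
  g <- tiny_genome(seed = 6)
  d <- cohort_design(cohort_samples(1L, regions = "SN", conditions = "CT",
                                    seed = 6), seed = 6)
  o1 <- simulate_sample(g, d$samples[1, ], d, n_reads = 2000L,
                        outdir = withr::local_tempdir(), seed = 42)
  o2 <- simulate_sample(g, d$samples[1, ], d, n_reads = 2000L,
                        outdir = withr::local_tempdir(), seed = 42)
  expect_identical(readLines(o1$fastq), readLines(o2$fastq))
  expect_identical(readLines(o1$sam), readLines(o2$sam))
})

test_that("junction-crossing fraction matches the (R-1)/L closed form", {
  g <- build_genome(genome_config(chrom_len = 8000L, n_genes = 1L,
                                  exons_per_gene = c(3L, 3L),
                                  circ_gene_fraction = 1),
                    seed = 9)
  g$genes$circ_fraction <- 1
  d <- cohort_design(cohort_samples(1L, regions = "SN", conditions = "CT",
                                    seed = 9), seed = 9)
  R <- 100L
  out <- simulate_sample(g, d$samples[1, ], d, n_reads = 100000L,
                         read_len = R, error_rate = 0, premrna_fraction = 0,
                         write_files = FALSE, seed = 9)
  L <- out$truth$end - out$truth$start
  p <- (R - 1) / L
  frac <- out$truth$realized_reads / 100000L
  se <- sqrt(p * (1 - p) / 100000)
  expect_lt(abs(frac - p), 3 * se)
})

test_that("per-site editing rates are recovered from the pooled pileup", {
  g <- build_genome(genome_config(chrom_len = 12000L, n_genes = 4L,
                                  alu_per_gene = 3),
                    seed = 12)
  em <- editing_model(g, rate = 0.05)
  d <- cohort_design(cohort_samples(1L, regions = "SN", conditions = "CT",
                                    seed = 12), seed = 12)
  out <- simulate_sample(g, d$samples[1, ], d, editing = em,
                         n_reads = 40000L, error_rate = 0,
                         outdir = withr::local_tempdir(), seed = 12)
  pu <- pileup_from_sam(out$sam, genome = g)
  sites <- dplyr::inner_join(pu, em$sites, by = c("chrom", "pos"))
  a <- ifelse(sites$ctx_strand == "+", sites$A, sites$T)
  gg <- ifelse(sites$ctx_strand == "+", sites$G, sites$C)
  covered <- a + gg >= 50
  pooled <- sum(gg[covered]) / sum(a[covered] + gg[covered])
  expect_lt(abs(pooled - 0.05), 0.005)

  # per-site convergence at high coverage: binomial test passes at alpha
  # 0.01 for at least 95% of well-covered sites
  hi <- which(a + gg >= 200)
  pass <- vapply(hi, function(i) {
    stats::binom.test(gg[i], a[i] + gg[i], p = 0.05)$p.value > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("editing respects the transcribed strand of minus-strand genes", {
  cfg <- genome_config(chrom_len = 12000L, n_genes = 3L, alu_per_gene = 3,
                       minus_strand_fraction = 1)
  g <- build_genome(cfg, seed = 13)
  expect_true(all(g$genes$strand == "-"))
  em <- editing_model(g, rate = 0.2)
  d <- cohort_design(cohort_samples(1L, regions = "SN", conditions = "CT",
                                    seed = 13), seed = 13)
  out <- simulate_sample(g, d$samples[1, ], d, editing = em,
                         n_reads = 15000L, error_rate = 0,
                         outdir = withr::local_tempdir(), seed = 13)
  pu <- pileup_from_sam(out$sam, genome = g)
  ref <- circnigra:::chrom_base(g, pu$chrom, pu$pos)
  # edited positions appear on the plus strand as C at reference-T sites
  expect_gt(sum(pu$C[ref == "T"]), 0)
  expect_identical(sum(pu$G[ref == "A"]), 0L)
})

test_that("cohort effects propagate into the ground truth", {
  g <- tiny_genome(seed = 20)
  em <- editing_model(g, rate = 0.05)
  samples <- cohort_samples(5L, regions = "SN", conditions = "CT", seed = 20)

  flat <- cohort_design(samples, age_slope = 0, seed = 20)
  sim_flat <- simulate_cohort(g, flat, editing = em, n_reads = 500L,
                              write_files = FALSE)
  per_sample <- sim_flat$truth_junctions |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(e = sum(expected_reads))
  expect_lt(diff(range(per_sample$e)), 1e-9)

  sloped <- cohort_design(samples, age_slope = 0.03,
                          age_slope_region = "SN", seed = 20)
  sim_slope <- simulate_cohort(g, sloped, editing = em, n_reads = 500L,
                               write_files = FALSE)
  joined <- sim_slope$truth_junctions |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(e = sum(expected_reads)) |>
    dplyr::left_join(samples, by = "sample_id")
  expect_gt(stats::cor(joined$age, joined$e), 0)

  halved <- cohort_design(samples, editing_effects = c(CT = 0.5), seed = 20)
  sim_half <- simulate_cohort(g, halved, editing = em, n_reads = 500L,
                              write_files = FALSE)
  expect_equal(sim_half$truth_editing$expected_mean_rate,
               rep(0.025, 5), tolerance = 1e-12)
})

test_that("simulator rejects invalid inputs", {
  g <- tiny_genome(seed = 1)
  d <- cohort_design(cohort_samples(1L, regions = "SN", conditions = "CT",
                                    seed = 1), seed = 1)
  expect_error(simulate_sample(g, d$samples[1, ], d, read_len = 5000L,
                               write_files = FALSE, seed = 1),
               "circularizable exon|shortest exon")
  bad <- d$samples[1, ]; bad$sample_id <- "nope"
  expect_error(simulate_sample(g, bad, d, write_files = FALSE, seed = 1),
               "unknown sample_id")
  expect_error(simulate_sample(g, d$samples[1, ], d, error_rate = 0.2,
                               write_files = FALSE, seed = 1),
               "error_rate")
  expect_error(cohort_design(cohort_samples(0L, seed = 1)), "at least one")
})
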