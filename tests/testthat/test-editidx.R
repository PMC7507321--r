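# Alu editing index: pileup behaviour, the pooled numerator/denominator
# index, read-weighting vs site-averaging, strand mapping, the mismatch
# spectrum and circRNA-proximal region sets.

# A hand-built genome: one plus-strand Alu covering [100, 120) on a known
# sequence, so pileups and indices can be forced by construction.
flat_genome <- function(gene_strand = "+") {
  s <- strrep("ACGT", 500L)  # 2000 nt
  list(chromosomes = c(c1 = s),
       genes = tibble::tibble(gene_id = "gX", chrom = "c1",
                              strand = gene_strand, base_expression = 1,
                              circ_exon = NA_integer_, circ_fraction = 0),
       exons = tibble::tibble(gene_id = "gX", exon_rank = 1L, chrom = "c1",
                              start = 50L, end = 250L),
       alus = tibble::tibble(alu_id = "aluX", chrom = "c1", start = 100L,
                             end = 180L, strand = "+"))
}

make_pileup <- function(pos, A = 0L, C = 0L, G = 0L, T = 0L) {
  tibble::tibble(chrom = "c1", pos = as.integer(pos),
                 A = as.integer(A), C = as.integer(C),
                 G = as.integer(G), T = as.integer(T))
}

test_that("the pooled index follows the forced arithmetic", {
  g <- flat_genome()
  # reference A positions inside the Alu on a plus gene: pos %% 4 == 0
  pu <- make_pileup(c(100L, 104L), A = c(50L, 40L), G = c(5L, 5L))
  res <- alu_editing_index(pu, g, "A>G")
  expect_identical(res$numerator, 10L)
  expect_identical(res$denominator, 100L)
  expect_equal(res$index_percent, 10)
  expect_identical(res$n_positions, 2L)

  # no alt reads -> 0%
  res0 <- alu_editing_index(make_pileup(100L, A = 30L), g, "A>G")
  expect_equal(res0$index_percent, 0)

  # zero denominator -> undefined with flag, not 0
  resu <- alu_editing_index(make_pileup(101L, C = 30L), g, "A>G")
  expect_false(resu$defined)
  expect_true(is.na(resu$index_percent))
})

test_that("pooling weights sites by their read counts, not per-site averages", {
  g <- flat_genome()
  # sites (A=100, G=0) and (A=0, G=100): pooled 50%, site mean 50% too;
  # with coverages (100,0) and (300,100): pooled 20%, site mean 12.5%
  pu <- make_pileup(c(100L, 104L), A = c(100L, 300L), G = c(0L, 100L))
  res <- alu_editing_index(pu, g, "A>G")
  expect_equal(res$index_percent, 20)
  site_mean <- mean(c(0 / 100, 100 / 400)) * 100
  expect_equal(site_mean, 12.5)

  pu2 <- make_pileup(c(100L, 104L), A = c(100L, 0L), G = c(0L, 100L))
  expect_equal(alu_editing_index(pu2, g, "A>G")$index_percent, 50)
})

test_that("partitioning the region set and recombining sums reproduces the index exactly", {
  g <- flat_genome()
  set.seed(41)
  pos <- seq(100L, 176L, by = 4L)  # reference-A Alu positions
  pu <- make_pileup(pos, A = sample(50:200, length(pos), TRUE),
                    G = sample(0:20, length(pos), TRUE))
  whole <- alu_editing_index(pu, g, "A>G")
  half1 <- alu_editing_index(pu[1:7, ], g, "A>G")
  half2 <- alu_editing_index(pu[-(1:7), ], g, "A>G")
  num <- half1$numerator + half2$numerator
  den <- half1$denominator + half2$denominator
  expect_identical(num, whole$numerator)
  expect_identical(den, whole$denominator)
  expect_equal(100 * num / den, whole$index_percent)
})

test_that("minus-strand context complement-maps the plus-strand pileup", {
  gp <- flat_genome("+")
  gm <- flat_genome("-")
  # on a minus gene, transcribed A sits at plus-strand T (pos %% 4 == 3);
  # editing shows up as C in the plus pileup
  pu_minus <- make_pileup(c(103L, 107L), T = c(90L, 90L), C = c(10L, 10L))
  res_m <- alu_editing_index(pu_minus, gm, "A>G")
  expect_equal(res_m$index_percent, 10)
  expect_identical(res_m$n_positions, 2L)
  # the equivalent plus-strand construction gives the identical index
  pu_plus <- make_pileup(c(100L, 104L), A = c(90L, 90L), G = c(10L, 10L))
  expect_equal(alu_editing_index(pu_plus, gp, "A>G")$index_percent,
               res_m$index_percent)
  # relabeling the gene swaps the roles of A>G and T>C
  expect_equal(alu_editing_index(pu_minus, gp, "T>C")$index_percent, 10)
})

test_that("raising min_coverage only changes eligibility, never contributions", {
  g <- flat_genome()
  pu <- make_pileup(c(100L, 104L, 108L), A = c(100L, 30L, 5L),
                    G = c(10L, 3L, 1L))
  r1 <- alu_editing_index(pu, g, "A>G", min_coverage = 1L)
  r2 <- alu_editing_index(pu, g, "A>G", min_coverage = 20L)
  expect_identical(r1$n_positions, 3L)
  expect_identical(r2$n_positions, 2L)
  expect_identical(r2$numerator, 13L)
  expect_identical(r2$denominator, 143L)
})

test_that("pileup counts reference bases and isolated mismatches correctly", {
  tc <- tiny_cohort()
  g <- tc$genome
  pu <- pileup_from_sam(tc$sim$samples$sam[1], genome = g)
  expect_true(nrow(pu) > 0)
  # positions outside editing sites carry (almost) pure reference signal;
  # verify a clean error-free constructed case instead of sampling noise
  d <- cohort_design(cohort_samples(1L, regions = "SN", conditions = "CT",
                                    seed = 77), seed = 77)
  out <- simulate_sample(build_genome(genome_config(chrom_len = 12000L,
                                                    n_genes = 3L), seed = 77),
                         d$samples[1, ], d, n_reads = 2000L, error_rate = 0,
                         outdir = withr::local_tempdir(), seed = 77)
  g77 <- build_genome(genome_config(chrom_len = 12000L, n_genes = 3L),
                      seed = 77)
  pu77 <- pileup_from_sam(out$sam, genome = g77)
  ref <- circnigra:::chrom_base(g77, pu77$chrom, pu77$pos)
  m <- as.matrix(pu77[c("A", "C", "G", "T")])
  nonref <- sum(m) - sum(m[cbind(seq_len(nrow(m)), match(ref, c("A","C","G","T")))])
  expect_identical(nonref, 0L)

  # empty region set -> empty pileup
  expect_identical(nrow(pileup_from_sam(tc$sim$samples$sam[1],
                                        regions = tibble::tibble(
                                          chrom = character(),
                                          start = integer(),
                                          end = integer()))), 0L)
})

test_that("error-free, editing-free data give a flat zero mismatch spectrum", {
  g <- build_genome(genome_config(chrom_len = 12000L, n_genes = 3L,
                                  alu_per_gene = 3), seed = 55)
  d <- cohort_design(cohort_samples(1L, regions = "SN", conditions = "CT",
                                    seed = 55), seed = 55)
  out <- simulate_sample(g, d$samples[1, ], d, n_reads = 5000L,
                         error_rate = 0, outdir = withr::local_tempdir(),
                         seed = 55)
  sp <- mismatch_spectrum(pileup_from_sam(out$sam, genome = g), g)
  expect_identical(nrow(sp), 12L)
  expect_true(all(sp$index_percent[sp$defined] == 0))
})

test_that("flank regions are clipped, merged, and optionally exon-subtracted", {
  g <- flat_genome()
  g$exons <- tibble::tibble(gene_id = "gX", exon_rank = 1:2, chrom = "c1",
                            start = c(50L, 300L), end = c(250L, 400L))
  jn <- tibble::tibble(chrom = "c1", start = 300L, end = 400L)
  rs <- circ_flank_regions(jn, g, window = 1000L, subtract_exons = FALSE)
  expect_identical(rs$circ_exons$start, 300L)
  expect_identical(rs$circ_exons$end, 400L)
  # clipped to the gene span [50, 400): left flank [50,300), right empty
  expect_identical(nrow(rs$flanks), 1L)
  expect_identical(c(rs$flanks$start, rs$flanks$end), c(50L, 300L))
  # intron subtraction removes the other exon from the flank
  rs2 <- circ_flank_regions(jn, g, window = 1000L, subtract_exons = TRUE)
  expect_identical(c(rs2$flanks$start, rs2$flanks$end), c(250L, 300L))
  # a gene spanning exactly the circle has no flanks
  g2 <- flat_genome()
  g2$exons <- tibble::tibble(gene_id = "gX", exon_rank = 1L, chrom = "c1",
                             start = 300L, end = 400L)
  rs3 <- circ_flank_regions(jn, g2, window = 1000L)
  expect_identical(nrow(rs3$flanks), 0L)
  # junctions without a host gene are excluded with a warning
  expect_warning(
    out <- circ_flank_regions(tibble::tibble(chrom = "c1", start = 1500L,
                                             end = 1600L), g, 1000L),
    "no host gene")
  expect_identical(nrow(out$circ_exons), 0L)
})

test_that("overlapping flanks merge to less than their naive sum", {
  g <- flat_genome()
  g$exons <- tibble::tibble(gene_id = "gX", exon_rank = 1L, chrom = "c1",
                            start = 0L, end = 2000L)
  jn <- tibble::tibble(chrom = "c1", start = c(500L, 700L),
                       end = c(600L, 800L))
  rs <- circ_flank_regions(jn, g, window = 300L, subtract_exons = FALSE)
  merged_len <- sum(rs$flanks$end - rs$flanks$start)
  naive <- 4L * 300L
  expect_lt(merged_len, naive)
  # oracle: union of the four clipped flank intervals, position by position
  cover <- rep(FALSE, 2000L)
  for (i in 1:2) {
    cover[(jn$start[i] - 300L):(jn$start[i] - 1L) + 1L] <- TRUE
    cover[(jn$end[i]):(jn$end[i] + 300L - 1L) + 1L] <- TRUE
  }
  # positions inside either circle still count if flanked by the other circle
  expect_identical(merged_len, sum(cover))
})

test_that("the regional report is consistent with its component indices", {
  tc <- tiny_cohort()
  g <- tc$genome
  pu <- pileup_from_sam(tc$sim$samples$sam[1], genome = g)
  tj <- true_junctions(g)
  rep_tbl <- regional_editing_report(genome = g, junctions = tj,
                                     pileup = pu)
  expect_identical(nrow(rep_tbl), 12L * 5L)
  glob <- rep_tbl[rep_tbl$region_label == "global" &
                    rep_tbl$mismatch == "A>G", ]
  direct <- alu_editing_index(pu, g, "A>G")
  expect_equal(glob$index_percent, direct$index_percent)
  expect_identical(glob$numerator, direct$numerator)
})

test_that("editing confined to flanking introns dominates the flank index", {
  g <- build_genome(genome_config(chrom_len = 15000L, n_genes = 3L,
                                  exons_per_gene = c(3L, 3L),
                                  circ_gene_fraction = 1, alu_per_gene = 4),
                    seed = 66)
  em <- editing_model(g, rate = 0.3)
  tj <- true_junctions(g)
  # keep editing only at sites outside the circularizable exons
  in_circ <- rep(FALSE, nrow(em$sites))
  for (i in seq_len(nrow(tj))) {
    in_circ <- in_circ | (em$sites$chrom == tj$chrom[i] &
                            em$sites$pos >= tj$start[i] &
                            em$sites$pos < tj$end[i])
  }
  em$sites <- em$sites[!in_circ, , drop = FALSE]
  d <- cohort_design(cohort_samples(1L, regions = "SN", conditions = "CT",
                                    seed = 66), seed = 66)
  out <- simulate_sample(g, d$samples[1, ], d, editing = em,
                         n_reads = 30000L, error_rate = 0,
                         premrna_fraction = 0.3,
                         outdir = withr::local_tempdir(), seed = 66)
  rep_tbl <- regional_editing_report(out$sam, g, tj,
                                     windows = c(1000L, 5000L, 10000L))
  ag <- rep_tbl[rep_tbl$mismatch == "A>G", ]
  circ_idx <- ag$index_percent[ag$region_label == "circ_exons"]
  flank_idx <- ag$index_percent[ag$region_label == "flank_1000"]
  expect_true(is.na(circ_idx) || circ_idx < 1)
  expect_gt(flank_idx, 10)
})
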