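---
title: "Methods: circRNA detection, Alu editing and miRNA seed analysis in circnigra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circRNA detection, Alu editing and miRNA seed analysis in circnigra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circnigra)
```

circnigra is a desk-scale toolkit for cohort studies of circular RNAs
(circRNAs) in brain RNA-seq. It covers the computational chain such a study
runs: detecting and counting back-splice junctions, applying cohort QC
filters and normalization, measuring A-to-I editing over Alu elements
globally and around circRNA loci, cohort statistics (group tests, FDR,
region sharing, age and editing correlations, a simple differential test,
cell-type calls), and miRNA seed-site analysis on circular topology. A
seeded synthetic-data generator with full ground truth replaces postmortem
brain sequencing, so every stage can be verified end to end on a laptop.

All genomic coordinates inside the package are 0-based half-open (the BED
convention); GTF and SAM are converted at the file boundary (1-based closed
and 1-based, respectively).

## The synthetic cohort generator

`build_genome()` draws random chromosome sequences and places non-overlapping
multi-exon genes on both strands. At every exon boundary it installs the
canonical spliceosomal dinucleotides in transcribed orientation — GT
immediately downstream of each donor, AG immediately upstream of each
acceptor (their reverse complements on the plus strand for minus-strand
genes) — so both linear splice junctions and back-splice junctions are
canonically flanked. A configurable fraction of genes receives one
circularizable exon (an internal exon where the gene has three or more, as
for single-exon circles such as the second exon of SLC8A1) with a per-gene
back-splice fraction drawn from `circ_fraction_range`.

Alu elements are *labelled intervals* over the random background rather than
repeat-consensus insertions: the editing index only needs their adenosine
content, and a non-repetitive genome keeps anchor mapping unambiguous. This
is a deliberate simplification — real Alus are highly repetitive and
multi-mapping is a genuine complication the simulator does not model (see
Limitations).

`simulate_sample()` draws single-end reads from three templates per gene:

* the spliced transcript (probability `(1 - p_c)(1 - premrna_fraction)`),
* unspliced pre-mRNA (`(1 - p_c) * premrna_fraction`, default 0.08) — rRNA-
  depleted brain libraries carry substantial intronic signal, and this gives
  flanking-intron Alu positions read coverage,
* the circular exon with wrap-around (probability
  `p_c = circ_fraction x per-sample multiplier`). Circular start positions
  are uniform over the circle, so a read of length `R` on a circle of length
  `L` crosses the back-splice junction with probability `(R - 1)/L` — the
  closed form the detector tests use.

A-to-I editing is applied per site: every adenosine of the transcribed
strand inside an Alu element receives a rate (fixed, default 5%, or
Beta-distributed), and each covering read flips that base to G independently
with that rate. For minus-strand genes the edited base appears as C at the
reference-T position of the plus strand, which is exactly the strand rule
the editing index must undo. Sequencing error is a uniform substitution to
one of the three other bases (default 0.2%); indels are not simulated
because no downstream step consumes them.

The ground-truth SAM records the error-free alignment coordinates of every
read (bases carry the editing and sequencing-error signal, otherwise a
pileup could not see them). Spliced reads crossing an exon junction are
written as `M N M` records; junction-crossing circular reads become a
primary plus a supplementary soft-clipped record, the representation split
aligners use. Pileups count primary records only, so a junction read
contributes its primary block of coverage.

`cohort_design()` couples sample metadata to generative effects:
per-condition multipliers on the back-splice fraction and the editing mean,
a linear age trend on expected circRNA output restricted to one region
(`age_slope`, per year, relative), and an optional latent per-sample factor
`u ~ U(0.5, 1.5)` that scales circRNA output by `u` and editing by `1/u` —
the inverse coupling that produces an editing/circRNA anti-correlation of
about −0.95 in truth. All randomness derives from the design seed; identical
seeds give byte-identical FASTQ/SAM.

The generator emulates the statistical structure the analysis assumes —
per-region/condition effects, age coupling, editing-circularization
coupling, sequencing error — but not library chemistry, PCR duplicates,
quality-score profiles, paired ends, repeat-driven multi-mapping, or
SNP/editing confounding. Tests passing on synthetic cohorts therefore
demonstrate the *pipeline's* correctness and calibration, not robustness to
every artefact of real brain libraries.

## Back-splice junction detection

`detect_backsplice()` implements the anchor-based head-to-tail idea: take
the first and last `anchor_len` (default 20) bases of a read, map both with
an exact k-mer index, and call a candidate only when both anchors map
uniquely to the same chromosome and strand with the 3' anchor *upstream* of
the 5' anchor — the reverse of linear order, which is the diagnostic
signature of a circle. The breakpoint is then located by extending both
anchors toward the read interior: with cumulative match arrays the mismatch
count of every breakpoint position is available in one linear pass, the
minimum is taken subject to `max_mismatch_extend` (default 2), and the
breakpoint may slide up to `breakpoint_ambiguity_max` (default 2) positions
to a placement whose flanks read GT/AG in transcribed orientation
(`require_gt_ag`, default on). Anchors are matched exactly; mismatch
tolerance lives entirely in the extension step.

Junction identity is the tuple (chrom, start, end, strand). One clustering
step is applied at cohort level: junction keys with identical circle length
on one chromosome and strand whose boundaries differ by at most
`merge_window` (default 5) nt are merged into the better-supported key.
Short homology around a breakpoint can make two placements equally good and
even canonically flanked, and a single read error can then win the
mismatch minimum at the shifted placement; clustering absorbs these
placement minorities, which is what established circRNA callers do.

`call_junctions()` applies the same logic in vectorised batches over whole
FASTQ files, counts supporting reads per junction per sample, and drops
junctions with cohort-wide support below `min_support` (default 2). The
per-sample "mapped total" used for per-million normalization is the number
of reads with at least one anchor hit — no external aligner is run, so this
stands in for an aligner's mapped-read count.

Cohort QC follows the conventions of brain circRNA studies: samples whose
detected circRNA level falls strictly below `min_detected` are excluded
(`qc_filter_samples()`; the unit can be distinct junctions or junction
reads, since "detected circRNAs" is used in both senses in the literature —
distinct junctions is the default), and a junction counts as expressed in a
tissue only when its summed reads there strictly exceed `tissue_min_reads`
(5 or 10 are the customary choices).

On simulated cohorts at the scale used by the acceptance checks (one 100 kb
chromosome, 30 genes, ~20 circularizable exons, 200,000 reads per sample,
0.2% error), detection achieves exact-coordinate precision 1.0 and recall
at least 0.95 for true junctions with at least 2 expected supporting reads.
Reads whose junction-proximal arm is shorter than the anchor cannot be
called (about 40% of crossing reads at R = 100, anchors 20), which reduces
per-junction counts but not junction-level recall at these depths.

## The Alu editing index

A-to-I editing reads as A→G on the transcribed strand. The index pools read
counts over all eligible positions: inside an Alu element, transcribed-
strand reference base equal to the mismatch's reference, coverage at least
`min_coverage` (default 1 — the "expressed Alu" criterion, config-exposed
because no standard number exists). With numerator the summed alt-base reads
and denominator numerator plus summed ref-base reads,

index = 100 x num / den.

Pooling read counts is what makes the index *expression-weighted*: a
heavily covered site contributes proportionally to its reads, which the
package demonstrates against per-site averaging in its tests (two sites
with coverages 100/0 and 300/100 pool to 20.0% while the unweighted site
mean is 12.5%). The strand context of a position is the strand of the
covering gene (positions covered by genes on opposite strands are excluded
rather than guessed); intergenic positions fall back to the Alu's own
strand. For minus-strand context the plus-strand pileup is complement-
mapped, so A→G editing is read from T→C counts. All 12 ordered mismatch
types go through the same machinery (`mismatch_spectrum()`); under pure
editing plus uniform error ε, the A→G index recovers
`100ρ + 100ε/3` within half a percentage point at 50x coverage and every
other mismatch stays at the error floor — the dominance pattern that
distinguishes real editing signal from noise.

`circ_flank_regions()` builds the circRNA-proximal region sets: the circle
`[start, end)` of each junction and flanking windows of 1,000, 5,000 and
10,000 nt, clipped to the host gene's span and the chromosome. Whether
flanks should exclude exonic sequence is ambiguous in practice, so both
behaviours exist; the default subtracts the host gene's exons, leaving
intronic sequence. Overlapping intervals are merged per label.
`regional_editing_report()` assembles the full region x mismatch table per
sample.

## Cohort statistics

The statistics layer is deliberately plain and transparent:

* `two_group_test()`: Welch's unequal-variance two-sided t-test, or the
  Wilcoxon rank-sum test (exact null for small tie-free samples, tie-
  corrected normal approximation otherwise). Zero variance in both groups
  under t returns p = 1 with a flag rather than an error.
* `bh_adjust()`: Benjamini-Hochberg step-up, applied uniformly wherever
  multiple features are tested; raw and adjusted values are always both
  reported.
* `pearson_correlation()`: sample Pearson r with the t-distributed p-value
  on n − 2 degrees of freedom. Pearson is used for all correlations.
* `size_factors()`: the median-of-ratios construction (per sample, median
  over features of count/geometric-mean, over features positive in every
  sample). This step is implemented here on purpose — it is the part of
  count normalization the analysis depends on — and is cross-checked in the
  test suite against DESeq2's implementation on random matrices.
* `simple_de()`: counts divided by size factors, log2(x+1), per-feature
  two-group test, BH across features. This is a deliberately transparent
  replacement for a negative-binomial GLM: its null behaviour is easy to
  verify (the false-positive rate at q < 0.05 is at most 0.05 on null
  Poisson matrices in the acceptance checks) at the cost of the variance
  modelling a dedicated differential-expression package provides. It is
  labelled `simple_de` everywhere, never presented as DESeq2.
* `celltype_call()`: a gene is called expressed in a cell type when its
  value is at least 10x the mean of the *other* types and exceeds their
  mean plus 5 standard deviations (the standard deviation of a single other
  value is 0). The rule's published phrasing is grammatically ambiguous
  (whether the 10x multiplies the whole mean+5sd term, and whether the
  candidate is included in the reference set); the leave-one-out
  conjunction is the default and all four readings are selectable via
  `rule=`.
* `sharing_summary()` partitions expressed features into region-combination
  cells (which brain regions each circRNA is expressed in) from the same
  strict per-tissue expression rule as `filter_by_tissue()`.

## miRNA seed sites on circular topology

`scan_seed_sites()` matches the four canonical seed-site classes — 6mer
(reverse complement of miRNA positions 2-7), 7mer-A1 (6mer followed by A),
7mer-m8 (reverse complement of positions 2-8), 8mer (7mer-m8 followed by A)
— against a circular target by scanning the sequence extended with its own
first 7 bases, so sites spanning the back-splice junction are found; a
linear mode exists for comparison with junction-unaware scans. Each start
position is reported once with its strongest class, and a weaker site whose
interval is contained (modulo the circle length) in a stronger reported
site is suppressed: an 8mer always contains a 7mer-m8 at the same start and
a 7mer-A1 one position in, and counting those separately would double-count
one physical site. The scanner is verified against a rotation brute-force
oracle (rotate the circle through every offset, test motifs at the origin,
apply containment suppression quadratically) on a thousand random circles.

Because the real human SLC8A1 circularizable exon is not distributed with
the package, `synthetic_circslc8a1()` provides a clearly labelled synthetic
surrogate: a seeded random 1,823-nt circle carrying exactly seven canonical
miR-128 seed sites at fixed positions, one spanning the junction, with the
background rejection-sampled so no additional site occurs by chance. It
exercises the circular scanner end to end (the published count for the real
exon is also seven sites for miR-128), but it is not the real sequence and
supports no conclusion about SLC8A1 itself.

`fisher_enrichment()` tests each miRNA's validated-target set for
enrichment among differential genes with a one-sided Fisher exact test
(hypergeometric tail), BH-adjusted across miRNAs; target maps are consumed
as a two-column table, with no live database access. `fit_standard_curve()`
fits `Cq = slope x log10(copies) + intercept` to a qPCR dilution series
(at least 3 points spanning 2 decades), reporting R² and the amplification
efficiency `10^(-1/slope) - 1`, flagged outside [0.8, 1.1]; `tidy()`,
`glance()` and `autoplot()` methods are provided. `stoichiometry()` turns a
site count and two molar concentrations into the sites-per-miRNA ratio
`n_sites x [circRNA]/[miRNA]` — with seven sites and a 1:7 molar ratio the
circRNA pool offers about one binding site per miRNA molecule.

## Numerical and scale choices

Problem sizes were chosen so the full verification chain runs on one CPU in
minutes: detector fidelity on a 100 kb genome with 30 genes and 200,000
reads per sample across 4 samples; editing recovery on 40,000 reads at
~300x Alu coverage; the anti-correlation and age-trend checks on 100
independent cohorts each (5-16 samples of 3,000-5,000 reads on 12-15 kb
genomes). The age slope default used in the trend check (0.02 per year,
i.e. expected circRNA output rising ~70% across a 60-95-year cohort) and
the coupling range U(0.5, 1.5) were fixed from power reasoning — they give
at least 80% detection power at n = 8 per region and a truth-level
anti-correlation near −0.95 — before any end-to-end measurement, and are
ordinary generator defaults, not tuned quantities.

Degenerate inputs are handled explicitly: an editing index with a zero
denominator is reported as undefined with a flag rather than 0; a
correlation of a zero-variance vector is undefined-with-flag; an empty
FASTQ keeps its sample as a zero column with a warning; removing every
sample in QC is an explicit empty-cohort error; all-zero features are
excluded and flagged by `simple_de()`.

## Known limitations

* Anchors are matched exactly: reads with a sequencing error inside an
  anchor (about 8% of reads at 0.2% error and 2x20 nt anchors) are lost to
  detection. This costs per-junction counts, not junction recall, at
  realistic depths.
* The synthetic genome is non-repetitive; multi-mapping, the dominant
  real-world complication of Alu-dense loci, is unmodelled.
* SNP masking for the editing index (dbSNP) is a real-data concern the
  package does not implement.
* The simple differential test ignores count overdispersion structure a
  negative-binomial model would capture; it is calibrated under the null
  but less powerful than a dedicated DE package at small n.
* Only single-exon circles are simulated and only single-end reads; the
  detector itself is agnostic to internal circle structure (it sees only
  the junction).
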