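# Circular-topology miRNA seed-site scanning, target-set enrichment, qPCR
# standard curves and binding-site stoichiometry.

#' A miRNA record with derived seed
#'
#' @param mirna_id Identifier.
#' @param sequence 5'->3' miRNA sequence (RNA or DNA alphabet), length >= 19.
#' @return List of class `mirna_record` with the sequence and the seed
#'   (positions 2-8).
#' @export
mirna_record <- function(mirna_id, sequence) {
  seq_up <- stringr::str_to_upper(sequence)
  if (grepl("[^ACGUT]", seq_up)) abort("miRNA sequence must be over A/C/G/U (or T).")
  if (nchar(seq_up) < 19) abort("miRNA sequence must be >= 19 nt.")
  dna <- chartr("U", "T", seq_up)
  structure(list(mirna_id = mirna_id, sequence = sequence,
                 seed = substr(seq_up, 2L, 8L),
                 motifs = seed_motifs(dna)),
            class = "mirna_record")
}

# Canonical seed-match motifs on the target (DNA alphabet, 5'->3').
seed_motifs <- function(mirna_dna) {
  m8 <- revcomp(substr(mirna_dna, 2L, 8L))   # 7mer-m8
  six <- revcomp(substr(mirna_dna, 2L, 7L))  # 6mer
  list(`8mer` = paste0(m8, "A"),
       `7mer-m8` = m8,
       `7mer-A1` = paste0(six, "A"),
       `6mer` = six)
}

#' The published miR-128 record
#' @return A [mirna_record()] for miR-128 (UCACAGUGAACCGGUCUCUUU).
#' @export
mir128_record <- function() {
  mirna_record("miR-128", "UCACAGUGAACCGGUCUCUUU")
}

site_rank <- c(`6mer` = 1L, `7mer-A1` = 2L, `7mer-m8` = 3L, `8mer` = 4L)

#' Scan a circular sequence for canonical miRNA seed sites
#'
#' Matches the four canonical site classes (6mer, 7mer-A1, 7mer-m8, 8mer,
#' in increasing strength) against a circular target by scanning the
#' sequence extended with its own first 7 bases, so sites spanning the
#' back-splice junction are found. Each start position is reported at most
#' once with its strongest class, and a weaker site whose interval is
#' contained (modulo the circle length) within a stronger reported site is
#' suppressed, so nested sub-motifs of one physical site are not
#' double-counted.
#'
#' @param circle_seq Circular target sequence (RNA or DNA; T and U are
#'   equivalent), length >= 8.
#' @param mirna A [mirna_record()].
#' @param circular Set `FALSE` for a plain linear scan (for comparison with
#'   junction-unaware tools).
#' @return Tibble: mirna_id, position (0-based start on the circle),
#'   site_class, site_len, spans_junction.
#' @export
scan_seed_sites <- function(circle_seq, mirna, circular = TRUE) {
  stopifnot(inherits(mirna, "mirna_record"))
  target <- chartr("U", "T", stringr::str_to_upper(circle_seq))
  if (grepl("[^ACGT]", target)) abort("circle sequence must be over A/C/G/U/T.")
  L <- nchar(target)
  if (L < 8) abort("circle length must be >= 8.")
  ext <- if (circular) paste0(target, substr(target, 1L, 7L)) else target
  classes <- names(site_rank)[order(site_rank, decreasing = TRUE)]

  raw <- list()
  max_start <- if (circular) L - 1L else L - 6L
  for (i in 0:max_start) {
    for (cl in classes) {
      motif <- mirna$motifs[[cl]]
      len <- nchar(motif)
      if (i + len > nchar(ext)) next
      if (substr(ext, i + 1L, i + len) == motif) {
        raw[[length(raw) + 1L]] <- list(pos = i, class = cl, len = len)
        break
      }
    }
  }
  if (length(raw) == 0) {
    return(tibble(mirna_id = mirna$mirna_id, position = integer(),
                  site_class = character(), site_len = integer(),
                  spans_junction = logical()))
  }
  d <- purrr::map_dfr(raw, as_tibble) |>
    arrange(dplyr::desc(site_rank[.data$class]), .data$pos)
  kept <- d[0, ]
  for (j in seq_len(nrow(d))) {
    cnd <- d[j, ]
    contained <- FALSE
    if (nrow(kept) > 0) {
      stronger <- kept[site_rank[kept$class] > site_rank[cnd$class], ,
                       drop = FALSE]
      if (nrow(stronger) > 0) {
        off <- if (circular) (cnd$pos - stronger$pos) %% L else
          cnd$pos - stronger$pos
        contained <- any(off >= 0 & off + cnd$len <= stronger$len)
      }
    }
    if (!contained) kept <- bind_rows(kept, cnd)
  }
  kept |>
    arrange(.data$pos) |>
    dplyr::transmute(mirna_id = mirna$mirna_id, position = .data$pos,
                     site_class = .data$class, site_len = .data$len,
                     spans_junction = circular & (.data$pos + .data$len > L))
}

#' Count seed sites per miRNA on a circular sequence
#'
#' @param circle_seq Circular target sequence.
#' @param mirna_list List of [mirna_record()]s (unique ids).
#' @param min_sites Report threshold (a count of 3 or more is the customary
#'   shortlist rule); the full table is attached as
#'   `attr(, "full_table")`.
#' @param circular Passed to [scan_seed_sites()].
#' @return Tibble: mirna_id, n_sites (only miRNAs with
#'   `n_sites >= min_sites`).
#' @export
count_sites_per_mirna <- function(circle_seq, mirna_list, min_sites = 1L,
                                  circular = TRUE) {
  ids <- vapply(mirna_list, `[[`, character(1), "mirna_id")
  if (anyDuplicated(ids)) abort("duplicate mirna_id in `mirna_list`.")
  full <- purrr::map_dfr(mirna_list, function(mr) {
    tibble(mirna_id = mr$mirna_id,
           n_sites = nrow(scan_seed_sites(circle_seq, mr,
                                          circular = circular)))
  })
  out <- filter(full, .data$n_sites >= min_sites)
  attr(out, "full_table") <- full
  out
}

#' miRNA target-set enrichment among differential genes
#'
#' One-sided Fisher's exact test (enrichment) per miRNA: the 2x2 table of
#' differential vs background genes against target vs non-target, after
#' intersecting each miRNA's target set with the expressed universe. BH
#' adjustment across miRNAs. The odds ratio is `ad/bc`, with a 0.5
#' continuity correction (flagged) only when a zero cell occurs.
#'
#' @param de_genes Character vector of differential genes (subset of
#'   `universe`).
#' @param target_map Tibble with columns mirna_id, gene_id.
#' @param universe Character vector of all expressed genes.
#' @return Tibble: mirna_id, de_target, de_other, bg_target, bg_other,
#'   odds_ratio, or_flag, p_value, q_value.
#' @export
fisher_enrichment <- function(de_genes, target_map, universe) {
  if (length(universe) == 0) abort("empty universe.")
  universe <- unique(universe)
  de_genes <- unique(de_genes)
  if (!all(de_genes %in% universe)) {
    abort("`de_genes` must be a subset of `universe`.")
  }
  res <- target_map |>
    filter(.data$gene_id %in% universe) |>
    group_by(.data$mirna_id) |>
    summarise(targets = list(unique(.data$gene_id)), .groups = "drop") |>
    purrr::pmap_dfr(function(mirna_id, targets) {
      a <- sum(de_genes %in% targets)
      b <- length(de_genes) - a
      c_ <- length(targets) - a
      d <- length(universe) - a - b - c_
      p <- fisher.test(matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE),
                       alternative = "greater")$p.value
      zero <- any(c(a, b, c_, d) == 0)
      or <- if (zero) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5)) else
        (a * d) / (b * c_)
      tibble(mirna_id = mirna_id, de_target = a, de_other = b,
             bg_target = c_, bg_other = d, odds_ratio = or,
             or_flag = if (zero) "continuity_0.5" else NA_character_,
             p_value = p)
    })
  if (nrow(res) > 0) res$q_value <- bh_adjust(res$p_value)
  arrange(res, .data$p_value)
}

#' Fit a qPCR standard curve
#'
#' Least-squares line `Cq = slope * log10(copies) + intercept` over a
#' dilution series; reports R^2 and the amplification efficiency
#' `10^(-1/slope) - 1` (1.0 = perfect doubling; flagged outside
#' `[0.8, 1.1]`).
#'
#' @param points Tibble/data frame with columns `copies` (> 0) and `cq`.
#' @return An object of class `circ_std_curve`.
#' @export
fit_standard_curve <- function(points) {
  if (nrow(points) < 3) abort("at least 3 dilution points are required.")
  if (any(points$copies <= 0)) abort("copy numbers must be positive.")
  lc <- log10(points$copies)
  if (diff(range(lc)) < 2) {
    abort("the dilution series must span at least 2 log10 units.")
  }
  fit <- lm(cq ~ lc, data = tibble(cq = points$cq, lc = lc))
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  eff <- 10^(-1 / slope) - 1
  structure(list(
    model = fit, slope = slope, intercept = intercept,
    r_squared = summary(fit)$r.squared, efficiency = eff,
    n_points = nrow(points),
    flag = if (slope >= 0) "nonnegative_slope"
           else if (eff < 0.8 || eff > 1.1) "efficiency_out_of_range"
           else NA_character_
  ), class = "circ_std_curve")
}

#' @export
print.circ_std_curve <- function(x, ...) {
  cat(sprintf(
    "<circ_std_curve> Cq = %.4f * log10(copies) + %.4f  (R2 = %.4f, efficiency = %.3f)\n",
    x$slope, x$intercept, x$r_squared, x$efficiency))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Invert a standard curve: copies from Cq
#' @param curve A `circ_std_curve`.
#' @param cq Numeric vector of quantification cycles.
#' @return Numeric vector of copy numbers.
#' @export
quantify_copies <- function(curve, cq) {
  stopifnot(inherits(curve, "circ_std_curve"))
  10^((cq - curve$intercept) / curve$slope)
}

#' @export
#' @method tidy circ_std_curve
#' @rdname fit_standard_curve
#' @param x A `circ_std_curve`.
#' @param ... Unused.
tidy.circ_std_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = unname(summary(x$model)$coefficients[, "Std. Error"]))
}

#' @export
#' @method glance circ_std_curve
#' @rdname fit_standard_curve
glance.circ_std_curve <- function(x, ...) {
  tibble(r.squared = x$r_squared, efficiency = x$efficiency,
         n_points = x$n_points, flag = x$flag)
}

#' Binding-site stoichiometry
#'
#' Number of miRNA binding sites contributed per miRNA molecule:
#' `n_sites * circ_molar / mir_molar`. A value near 1 means the circRNA
#' pool offers about one site per miRNA molecule.
#'
#' @param n_sites Number of binding sites on the circRNA (>= 0).
#' @param circ_molar,mir_molar Molar concentrations (mir_molar > 0).
#' @return Sites-per-miRNA ratio.
#' @export
stoichiometry <- function(n_sites, circ_molar, mir_molar) {
  if (n_sites < 0) abort("`n_sites` must be >= 0.")
  if (mir_molar <= 0) abort("`mir_molar` must be positive.")
  if (circ_molar <= 0) abort("`circ_molar` must be positive.")
  n_sites * circ_molar / mir_molar
}

#' Synthetic circSLC8A1 surrogate sequence
#'
#' A constructed, clearly synthetic stand-in for the human SLC8A1
#' circularizable exon (which is not shipped): a seeded random circle of
#' the reported ~1.8 kb exon scale carrying exactly seven canonical miR-128
#' seed sites at fixed positions (one spanning the back-splice junction),
#' on a background rejection-sampled so that no additional seed match
#' occurs by chance. Useful for exercising the circular scanner end to end;
#' it is not the real exon and carries no other biological signal.
#'
#' @param seed Integer seed.
#' @param length Circle length.
#' @return A single character string (DNA alphabet).
#' @export
synthetic_circslc8a1 <- function(seed = 1L, length = 1823L) {
  set.seed(assert_scalar_int(seed, "seed"))
  mir <- mir128_record()
  stamps <- tibble(
    pos = c(60L, 310L, 585L, 872L, 1150L, 1480L, 1819L),
    motif = c(mir$motifs[["8mer"]], mir$motifs[["7mer-m8"]],
              mir$motifs[["7mer-A1"]], mir$motifs[["6mer"]],
              mir$motifs[["8mer"]], mir$motifs[["7mer-m8"]],
              mir$motifs[["8mer"]])  # the last one spans the junction
  )
  for (attempt in 1:200) {
    s <- random_dna(length)
    ext <- paste0(s, substr(s, 1L, 8L))
    for (i in seq_len(nrow(stamps))) {
      substr(ext, stamps$pos[i] + 1L,
             stamps$pos[i] + nchar(stamps$motif[i])) <- stamps$motif[i]
    }
    # fold the extension back onto the circle start
    s <- paste0(substr(ext, length + 1L, length + 8L),
                substr(ext, 9L, length))
    hits <- scan_seed_sites(s, mir)
    if (nrow(hits) == 7L) return(s)
  }
  abort("failed to construct the surrogate; try another seed.")  # nocov
}
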