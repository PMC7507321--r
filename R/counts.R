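# circ_counts: the junction x sample count container plus the cohort QC
# filters and per-million normalization applied to it.

#' Construct a circRNA count container
#'
#' Bundles detected junctions, the junction x sample count table, per-sample
#' mapped-read totals and sample metadata.
#'
#' @param junctions Tibble with columns junction_id, chrom, start, end,
#'   strand (and optionally splice_signal, total_support).
#' @param counts Tibble with column junction_id plus one integer column per
#'   sample.
#' @param mapped_totals Named numeric vector of per-sample mapped-read
#'   totals (names = sample ids, superset check against count columns).
#' @param meta Optional sample metadata tibble (sample_id, region,
#'   condition, age, sex).
#' @return An object of class `circ_counts`.
#' @export
circ_counts <- function(junctions, counts, mapped_totals, meta = NULL) {
  samples <- setdiff(names(counts), "junction_id")
  if (!identical(sort(junctions$junction_id), sort(counts$junction_id))) {
    abort("`junctions` and `counts` must describe the same junctions.")
  }
  if (!all(samples %in% names(mapped_totals))) {
    abort("`mapped_totals` must name every sample column.")
  }
  cs <- vapply(counts[samples], sum, numeric(1))
  if (any(mapped_totals[samples] < cs)) {
    abort("mapped_totals must be >= the column sums of counts.")
  }
  structure(list(junctions = as_tibble(junctions),
                 counts = as_tibble(counts),
                 mapped_totals = mapped_totals[samples],
                 meta = if (is.null(meta)) NULL else as_tibble(meta)),
            class = "circ_counts")
}

#' @export
print.circ_counts <- function(x, ...) {
  cat(sprintf("<circ_counts> %d junctions x %d samples\n",
              nrow(x$junctions), length(x$mapped_totals)))
  invisible(x)
}

sample_names <- function(x) setdiff(names(x$counts), "junction_id")

#' Long-format view of a circRNA count container
#'
#' @param x A `circ_counts` object.
#' @param ... Unused.
#' @return Tibble: junction_id, sample_id, count, mapped_total, plus
#'   junction coordinates and (if present) sample metadata.
#' @export
#' @method tidy circ_counts
tidy.circ_counts <- function(x, ...) {
  long <- tidyr::pivot_longer(x$counts, -"junction_id",
                              names_to = "sample_id", values_to = "count") |>
    mutate(mapped_total = unname(x$mapped_totals[.data$sample_id])) |>
    left_join(select(x$junctions, "junction_id", "chrom", "start", "end",
                     "strand"), by = "junction_id")
  if (!is.null(x$meta)) long <- left_join(long, x$meta, by = "sample_id")
  long
}

#' Exclude samples with too few detected circRNAs
#'
#' Removes samples whose detected-circRNA level falls strictly below
#' `min_detected`. The unit is configurable: `"junctions"` counts distinct
#' junctions with at least one read (the default), `"reads"` counts summed
#' junction reads; the two readings of "detected circRNAs" found in cohort
#' reports differ, so both are provided.
#'
#' @param x A `circ_counts` object.
#' @param min_detected Exclusion threshold (strict `<`).
#' @param unit `"junctions"` or `"reads"`.
#' @return A filtered `circ_counts`; excluded sample ids are reported via a
#'   message and stored in `attr(, "excluded_samples")`.
#' @export
qc_filter_samples <- function(x, min_detected = 5000L,
                              unit = c("junctions", "reads")) {
  stopifnot(inherits(x, "circ_counts"))
  unit <- match.arg(unit)
  if (min_detected < 0) abort("`min_detected` must be >= 0.")
  sm <- sample_names(x)
  level <- vapply(x$counts[sm], function(v) {
    if (unit == "junctions") sum(v > 0) else sum(v)
  }, numeric(1))
  drop <- sm[level < min_detected]
  if (length(drop) == length(sm)) {
    abort(sprintf(
      "all %d samples fall below min_detected = %d: empty cohort.",
      length(sm), min_detected))
  }
  if (length(drop) > 0) {
    inform(sprintf("qc_filter_samples: excluded %d sample(s) with < %d %s: %s",
                   length(drop), min_detected, unit,
                   paste(drop, collapse = ", ")))
  }
  keep <- setdiff(sm, drop)
  out <- circ_counts(x$junctions,
                     x$counts[c("junction_id", keep)],
                     x$mapped_totals[keep],
                     if (is.null(x$meta)) NULL else
                       filter(x$meta, .data$sample_id %in% keep))
  attr(out, "excluded_samples") <- drop
  out
}

#' Keep junctions expressed above a per-tissue read threshold
#'
#' A junction counts as expressed in a tissue when its summed reads over
#' that tissue's samples exceed `min_reads` (strict `>`). Junctions
#' expressed in no tissue are dropped; the per-tissue expression flags are
#' attached as `attr(, "tissue_expression")` for sharing analyses.
#'
#' @param x A `circ_counts` object.
#' @param meta Sample metadata with `sample_id` and `region`; defaults to
#'   the metadata stored in `x`.
#' @param min_reads Per-tissue expression threshold (customarily 5 or 10).
#' @return A filtered `circ_counts`.
#' @export
filter_by_tissue <- function(x, meta = x$meta, min_reads = 5L) {
  stopifnot(inherits(x, "circ_counts"))
  if (is.null(meta)) abort("sample metadata with a `region` column is required.")
  sm <- sample_names(x)
  missing <- setdiff(sm, meta$sample_id)
  if (length(missing) > 0) {
    abort(paste0("samples absent from metadata: ",
                 paste(missing, collapse = ", ")))
  }
  region_of <- setNames(meta$region, meta$sample_id)[sm]
  tissues <- unique(region_of)
  expr <- purrr::map_dfc(setNames(tissues, tissues), function(tis) {
    cols <- sm[region_of == tis]
    rowSums(as.matrix(x$counts[cols])) > min_reads
  })
  expr <- bind_cols(tibble(junction_id = x$counts$junction_id), expr)
  keep <- rowSums(as.matrix(expr[tissues])) > 0
  out <- circ_counts(x$junctions[keep, , drop = FALSE],
                     x$counts[keep, , drop = FALSE],
                     x$mapped_totals, x$meta)
  attr(out, "tissue_expression") <- expr[keep, , drop = FALSE]
  out
}

#' Normalize junction counts to reads per million mapped reads
#'
#' @param x A `circ_counts` object.
#' @return Tibble: junction_id plus one numeric column per sample with
#'   `count / mapped_total * 1e6`.
#' @export
normalize_per_million <- function(x) {
  stopifnot(inherits(x, "circ_counts"))
  sm <- sample_names(x)
  zero <- sm[x$mapped_totals[sm] <= 0]
  if (length(zero) > 0) {
    abort(paste0("zero mapped-read total for sample(s): ",
                 paste(zero, collapse = ", ")))
  }
  out <- x$counts
  for (s in sm) out[[s]] <- out[[s]] / x$mapped_totals[[s]] * 1e6
  out
}
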