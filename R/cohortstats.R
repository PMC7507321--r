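# Cohort-level statistics: per-sample totals, two-group tests with BH
# control, correlations, sharing across regions, median-of-ratios size
# factors, a transparent log-scale differential test, and cell-type calls.

#' Per-sample circRNA totals
#'
#' @param x A `circ_counts` object.
#' @param mode `"distinct"` (junctions with count > 0) or `"reads"`
#'   (summed junction reads).
#' @param normalized Divide by mapped reads (per million).
#' @return Tibble: sample_id, total (plus metadata columns when present).
#' @export
circ_totals_per_sample <- function(x, mode = c("distinct", "reads"),
                                   normalized = FALSE) {
  stopifnot(inherits(x, "circ_counts"))
  mode <- match.arg(mode)
  sm <- sample_names(x)
  if (length(sm) == 0) abort("no samples in the count container.")
  tot <- vapply(x$counts[sm], function(v) {
    if (mode == "distinct") sum(v > 0) else sum(v)
  }, numeric(1))
  if (normalized) tot <- tot / (x$mapped_totals[sm] / 1e6)
  out <- tibble(sample_id = sm, total = unname(tot))
  if (!is.null(x$meta)) out <- left_join(out, x$meta, by = "sample_id")
  out
}

#' Two-group comparison (Welch t or Wilcoxon rank-sum)
#'
#' The t-test is Welch's unequal-variance two-sided test; the Wilcoxon test
#' uses the exact small-sample null when possible (no ties, min group size
#' within R's exact range) and the tie-corrected normal approximation
#' otherwise.
#'
#' @param values_a,values_b Numeric vectors for the two groups.
#' @param method `"t"` or `"wilcoxon"`.
#' @param group_a,group_b Labels stored in the result.
#' @param feature Feature label stored in the result.
#' @return One-row tibble: feature, group_a, group_b, method, statistic,
#'   p_value, effect (difference of means), flag.
#' @export
two_group_test <- function(values_a, values_b,
                           method = c("t", "wilcoxon"),
                           group_a = "a", group_b = "b", feature = NA_character_) {
  method <- match.arg(method)
  flag <- NA_character_
  if (method == "t") {
    if (length(values_a) < 2 || length(values_b) < 2) {
      abort("the t-test needs n >= 2 per group.")
    }
    if (sd(values_a) == 0 && sd(values_b) == 0) {
      stat <- 0; p <- 1; flag <- "zero_variance"
    } else {
      tt <- t.test(values_a, values_b, var.equal = FALSE,
                   alternative = "two.sided")
      stat <- unname(tt$statistic); p <- tt$p.value
    }
  } else {
    if (length(values_a) < 1 || length(values_b) < 1) {
      abort("the wilcoxon test needs n >= 1 per group.")
    }
    wt <- suppressWarnings(
      wilcox.test(values_a, values_b, alternative = "two.sided",
                  exact = min(length(values_a), length(values_b)) <= 12 &&
                    !anyDuplicated(c(values_a, values_b)),
                  correct = TRUE))
    stat <- unname(wt$statistic); p <- wt$p.value
  }
  tibble(feature = feature, group_a = group_a, group_b = group_b,
         method = method, statistic = stat, p_value = p,
         effect = mean(values_a) - mean(values_b), flag = flag)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control; a thin, named wrapper so every analysis corrects the
#' same way.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values (same length; empty in, empty out).
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric())
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Pearson correlation with a t-distributed p-value
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return One-row tibble: r, p_value, n, method, defined (FALSE when either
#'   vector has zero variance).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length.")
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort("at least 3 paired observations are required.")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(r = NA_real_, p_value = NA_real_, n = n,
                  method = "pearson", defined = FALSE))
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = n,
         method = "pearson", defined = TRUE)
}

#' Sharing of expressed features across regions
#'
#' Partitions expressed features into region-combination cells (which
#' regions each feature is expressed in) and summarises unique, pairwise
#' and all-region shared counts.
#'
#' @param x A `circ_counts` object, or a tibble of logical expression flags
#'   with a `junction_id`/`feature` column plus one column per region.
#' @param meta Sample metadata (needed when `x` is a `circ_counts`).
#' @param min_reads Per-tissue expression rule threshold (strict `>`),
#'   passed to [filter_by_tissue()] for circRNA counts; use 0 for a
#'   count>0 rule as applied to mRNAs.
#' @return List: `cells` (tibble regions, n — disjoint combination cells),
#'   `per_region_unique`, `all_shared`, `pairwise` (tibble region_a,
#'   region_b, n shared), `n_expressed`.
#' @export
sharing_summary <- function(x, meta = NULL, min_reads = 5L) {
  if (inherits(x, "circ_counts")) {
    meta <- meta %||% x$meta
    if (is.null(meta)) abort("sample metadata is required.")
    if (length(unique(meta$region)) < 2) abort("need >= 2 regions.")
    if (any(table(meta$region) == 0)) abort("region with zero samples.")
    fx <- filter_by_tissue(x, meta, min_reads = min_reads)
    expr <- attr(fx, "tissue_expression")
    regions <- setdiff(names(expr), "junction_id")
  } else {
    expr <- x
    regions <- setdiff(names(expr), c("junction_id", "feature"))
    if (length(regions) < 2) abort("need >= 2 regions.")
  }
  flags <- as.matrix(expr[regions])
  expressed <- rowSums(flags) > 0
  flags <- flags[expressed, , drop = FALSE]
  combo <- apply(flags, 1L, function(r) paste(regions[r], collapse = "+"))
  cells <- tibble(regions = combo) |>
    dplyr::count(.data$regions, name = "n") |>
    arrange(dplyr::desc(.data$n))
  per_region_unique <- setNames(
    vapply(regions, function(rg) sum(combo == rg), integer(1)), regions)
  pairwise <- purrr::map_dfr(utils::combn(regions, 2, simplify = FALSE),
    function(pr) tibble(region_a = pr[1], region_b = pr[2],
                        n = sum(flags[, pr[1]] & flags[, pr[2]])))
  list(cells = cells,
       per_region_unique = per_region_unique,
       all_shared = sum(rowSums(flags) == length(regions)),
       pairwise = pairwise,
       n_expressed = nrow(flags))
}

#' Median-of-ratios size factors
#'
#' The library-size normalization used for count matrices: per sample, the
#' median over features of the ratio of the count to the feature's
#' geometric mean across samples, computed over features whose geometric
#' mean is positive.
#'
#' @param counts Matrix or tibble (features x samples; a `junction_id`
#'   column is dropped automatically).
#' @return Named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts) {
  m <- counts_matrix(counts)
  log_gm <- rowMeans(log(m))
  use <- is.finite(log_gm)
  if (!any(use)) {
    abort(paste0("no feature has positive counts in every sample; ",
                 "size factors need at least one all-positive feature ",
                 "(consider a pseudo-reference)."))
  }
  apply(m, 2L, function(col) exp(median((log(col) - log_gm)[use])))
}

counts_matrix <- function(counts) {
  if (inherits(counts, "circ_counts")) {
    m <- as.matrix(counts$counts[sample_names(counts)])
    rownames(m) <- counts$counts$junction_id
    return(m)
  }
  if (is.data.frame(counts)) {
    ids <- counts[["junction_id"]] %||% counts[["feature"]]
    m <- as.matrix(counts[setdiff(names(counts), c("junction_id", "feature"))])
    if (!is.null(ids)) rownames(m) <- ids
    return(m)
  }
  as.matrix(counts)
}

#' Simple two-group differential expression on normalized log counts
#'
#' A transparent replacement for a negative-binomial GLM: counts are
#' divided by median-of-ratios size factors, log2(x + 1) transformed, and
#' each feature is tested with [two_group_test()]; BH adjustment across
#' features. The effect size is the difference of group means on the log2
#' scale. All-zero features are excluded and flagged.
#'
#' @param x A `circ_counts` object or counts matrix/tibble.
#' @param meta Sample metadata with `sample_id` and the grouping column.
#' @param grouping Name of the metadata column defining the two groups.
#' @param method `"t"` or `"wilcoxon"`.
#' @return Tibble: feature, group_a, group_b, method, statistic, p_value,
#'   effect (log2 difference a - b), q_value, flag.
#' @export
simple_de <- function(x, meta = NULL, grouping = "condition",
                      method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  if (inherits(x, "circ_counts")) meta <- meta %||% x$meta
  if (is.null(meta)) abort("sample metadata is required.")
  m <- counts_matrix(x)
  groups <- setNames(meta[[grouping]], meta$sample_id)[colnames(m)]
  lv <- sort(unique(groups))
  if (length(lv) != 2) abort("`grouping` must define exactly two groups.")
  sf <- size_factors(m)
  lg <- log2(sweep(m, 2L, sf, "/") + 1)
  feats <- rownames(lg) %||% as.character(seq_len(nrow(lg)))
  allzero <- rowSums(m) == 0
  res <- purrr::map_dfr(which(!allzero), function(i) {
    two_group_test(lg[i, groups == lv[1]], lg[i, groups == lv[2]],
                   method = method, group_a = lv[1], group_b = lv[2],
                   feature = feats[i])
  })
  if (nrow(res) > 0) res$q_value <- bh_adjust(res$p_value)
  if (any(allzero)) {
    res <- bind_rows(res, tibble(
      feature = feats[allzero], group_a = lv[1], group_b = lv[2],
      method = method, statistic = NA_real_, p_value = NA_real_,
      effect = NA_real_, flag = "all_zero", q_value = NA_real_))
  }
  res
}

#' Cell-type expression calls
#'
#' Calls a gene expressed in a cell type when its expression stands far
#' above the remaining types. The default (leave-one-out conjunction)
#' requires `expr >= fold * mean(others)` AND
#' `expr >= mean(others) + sd_mult * sd(others)`; the standard deviation of
#' a single other value is 0. The alternative readings of the rule are
#' selectable.
#'
#' @param expression Named numeric vector (one value per cell type), or a
#'   tibble with `gene` and one column per cell type.
#' @param fold Fold threshold ("order of magnitude" = 10).
#' @param sd_mult Standard-deviation multiplier.
#' @param rule `"loo_and"` (default), `"loo_times"`
#'   (`expr >= fold * (mean(others) + sd_mult * sd(others))`), `"all_and"`,
#'   or `"all_times"` (the all-type readings include the candidate in the
#'   mean/sd).
#' @return Tibble: gene, cell_type, expression, called.
#' @export
celltype_call <- function(expression, fold = 10, sd_mult = 5,
                          rule = c("loo_and", "loo_times", "all_and",
                                   "all_times")) {
  rule <- match.arg(rule)
  if (is.data.frame(expression)) {
    genes <- expression$gene %||% as.character(seq_len(nrow(expression)))
    mat <- as.matrix(expression[setdiff(names(expression), "gene")])
  } else {
    genes <- "gene"
    mat <- matrix(expression, nrow = 1,
                  dimnames = list(NULL, names(expression)))
  }
  if (ncol(mat) < 2) abort("need expression for at least 2 cell types.")
  if (any(mat < 0)) abort("expression values must be nonnegative.")
  purrr::map_dfr(seq_len(nrow(mat)), function(g) {
    v <- mat[g, ]
    called <- vapply(seq_along(v), function(ci) {
      others <- if (startsWith(rule, "loo")) v[-ci] else v
      mu <- mean(others)
      s <- if (length(others) > 1) sd(others) else 0
      if (v[ci] == 0) return(FALSE)
      switch(rule,
        loo_and = , all_and = v[ci] >= fold * mu && v[ci] >= mu + sd_mult * s,
        loo_times = , all_times = v[ci] >= fold * (mu + sd_mult * s))
    }, logical(1))
    tibble(gene = genes[g], cell_type = colnames(mat),
           expression = unname(v), called = called)
  })
}
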