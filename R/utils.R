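# Shared low-level helpers: sequence manipulation and coordinate checks.

BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over plain character strings (A/C/G/T, with
#' N passed through). Used throughout for strand handling.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @examples
#' revcomp(c("ACGT", "GGTA"))
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTUNacgtun", "TGCAANTGCAAN", x))
}

complement_base <- function(b) chartr("ACGT", "TGCA", b)

#' @noRd
assert_scalar_int <- function(x, name, min = NULL, max = NULL) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer.", name))
  }
  x <- as.integer(x)
  if (!is.null(min) && x < min) {
    abort(sprintf("`%s` must be >= %s (got %s).", name, min, x))
  }
  if (!is.null(max) && x > max) {
    abort(sprintf("`%s` must be <= %s (got %s).", name, max, x))
  }
  x
}

#' @noRd
assert_prob <- function(x, name, lt1 = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 ||
      (lt1 && x >= 1) || (!lt1 && x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1%s].",
                  name, if (lt1) ")" else "]"))
  }
  as.numeric(x)
}

# Draw a random DNA string of length n as a single string.
random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# Substring by 0-based half-open interval.
subseq0 <- function(x, start0, end0) {
  substr(x, start0 + 1L, end0)
}

# Fixed-width integer formatting for ids.
pad_id <- function(prefix, i, width = 3L) {
  sprintf(paste0(prefix, "%0", width, "d"), i)
}

# Collapse runs of consecutive integers into (start, len) blocks.
# Used to turn per-base genome positions into alignment blocks.
int_runs <- function(pos) {
  if (length(pos) == 0L) {
    return(tibble(start = integer(), len = integer()))
  }
  brk <- c(TRUE, diff(pos) != 1L)
  grp <- cumsum(brk)
  starts <- pos[brk]
  lens <- tabulate(grp)
  tibble(start = starts, len = lens)
}
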