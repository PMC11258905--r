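#' Round half away from zero
#'
#' Printed percentages throughout the package use commercial ("half-up")
#' rounding rather than R's banker's rounding, so that e.g. 1.085 renders as
#' 1.09.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up to `digits` places.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Reverse complement of a nucleotide string
#'
#' Vectorised over `x`; accepts A/C/G/T/N (any case), returns uppercase.
#'
#' @param x Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  flipped <- chartr("ACGTNacgtn", "TGCANTGCAN", x)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

gc_fraction <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GCgc]", "", x))
  ifelse(n == 0, NA_real_, gc / n)
}

longest_homopolymer <- function(x) {
  vapply(x, function(s) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
    if (length(r$lengths) == 0) 0L else max(r$lengths)
  }, integer(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# column accessor that does not warn on absent tibble columns
col_or <- function(d, nm, default) {
  if (nm %in% names(d)) d[[nm]] else default
}

# number of mismatched characters between two equal-length strings
str_mismatches <- function(a, b) {
  xa <- charToRaw(a); xb <- charToRaw(b)
  stopifnot(length(xa) == length(xb))
  sum(xa != xb)
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
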