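#' @keywords internal
"_PACKAGE"

#' @importFrom stats qgamma rbinom runif rmultinom setNames rexp
#' @importFrom utils head tail
NULL

# Split a DNA string into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_seq <- function(x) paste(x, collapse = "")

#' Reverse complement of a DNA string
#'
#' Operates on plain uppercase character strings over \{A,C,G,T,N\};
#' gap characters (`-`) are preserved.
#'
#' @param x a single DNA string.
#' @return the reverse complement as a character string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  comp <- chartr("ACGTN-", "TGCAN-", x)
  chars_seq(rev(seq_chars(comp)))
}

#' Generate a random DNA sequence
#'
#' Bases are drawn i.i.d. with the given GC content (C and G equiprobable,
#' A and T equiprobable). Uses the current RNG state.
#'
#' @param n sequence length in bp.
#' @param gc GC content as a fraction in \[0,1\].
#' @return a DNA string of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 1, gc >= 0, gc <= 1)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars_seq(sample(names(p), n, replace = TRUE, prob = p))
}

# 0-based half-open substring of a DNA string, clamped to sequence bounds.
subseq0 <- function(seq, start, end) {
  n <- nchar(seq)
  start <- max(0L, start)
  end <- min(n, end)
  if (end <= start) return("")
  substr(seq, start + 1L, end)
}

is_base <- function(x) x %in% c("A", "C", "G", "T")

# transition partner lookup (A<->G, C<->T)
TI_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
# transversion partners
TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                    C = c("A", "G"), T = c("A", "G"))
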