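#' Reverse complement of a DNA string
#'
#' @param seq character vector of DNA strings over `A`, `C`, `G`, `T`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  vapply(seq, cpp_revcomp, character(1), USE.NAMES = FALSE)
}

#' Generate uniform random DNA
#'
#' @param n sequence length in bp.
#' @return a single DNA string of length `n`.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# round half up ("closest integer", ties away from zero for positives)
round_half_up <- function(x) floor(x + 0.5)

# rotate a string so it starts at 1-based position `at`
rotate_seq <- function(seq, at) {
  n <- nchar(seq)
  if (at == 1L) return(seq)
  paste0(substr(seq, at, n), substr(seq, 1L, at - 1L))
}

# is `b` a rotation (or reverse complement of a rotation) of `a`?
seq_rotation_equal <- function(a, b) {
  if (nchar(a) != nchar(b)) return(FALSE)
  grepl(b, paste0(a, a), fixed = TRUE) ||
    grepl(revcomp(b), paste0(a, a), fixed = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
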