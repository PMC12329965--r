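# Closed syncmer collection and the syncmer table.
#
# Reads are homopolymer compressed (hoco) and reduced to their closed
# syncmers: k-mers whose first or last s-mer carries the minimal hash among
# all s-mers of the k-mer (ties qualify). Closed syncmers overlap by
# construction (p_{i+1} - p_i < k), so a read is fully represented, between
# its first and last syncmer, by the vector of <table index, position,
# orientation> triples.

#' Syncmer parameters
#'
#' @param k syncmer length in hoco bases (odd). The default matches typical
#'   HiFi read accuracy; tests use a smaller k for speed.
#' @param s s-mer length, at most 31 so that an s-mer packs into 62 bits and
#'   the strand-canonical s-mer hash is perfect.
#' @return a `syncmer_params` list.
#' @export
syncmer_params <- function(k = 1001L, s = 31L) {
  k <- as.integer(k); s <- as.integer(s)
  stopifnot(s > 0L, s <= k, s <= 31L)
  if (k %% 2L == 0L) stop("k must be odd (odd hoco k-mers are never palindromic)")
  structure(list(k = k, s = s), class = "syncmer_params")
}

#' Homopolymer compression
#'
#' Collapses each run of identical bases to a single base and records the run
#' lengths, so the original sequence is exactly recoverable.
#'
#' @param seq DNA string over `A`, `C`, `G`, `T`.
#' @return list with `bases` (compressed string) and `runs` (integer vector).
#' @export
hoco_compress <- function(seq) {
  h <- cpp_hoco(seq)
  structure(list(bases = h$bases, runs = h$runs), class = "hoco_seq")
}

#' Expand a homopolymer-compressed sequence
#'
#' @param hseq a `hoco_seq` (or any list with `bases` and `runs`).
#' @return the expanded DNA string.
#' @export
hoco_expand <- function(hseq) {
  cpp_expand_runs(hseq$bases, as.integer(hseq$runs))
}

#' Strand-canonical s-mer hash
#'
#' A perfect (collision-free) hash on canonical s-mers for s <= 31: the 2-bit
#' packed encoding of min(x, revcomp(x)) is passed through a fixed invertible
#' 64-bit mixing function, so `hash(x) == hash(revcomp(x))` and distinct
#' canonical s-mers never collide.
#'
#' @param smer character vector of s-mers (all the same length, no `N`).
#' @return character vector of 16-digit hex hash values.
#' @export
canonical_smer_hash <- function(smer) {
  s <- unique(nchar(smer))
  if (length(s) != 1L) stop("all s-mers must have the same length")
  if (s > 31L) stop("s must be <= 31")
  cpp_smer_hash(smer, as.integer(s))
}

#' Extract closed syncmers from a hoco sequence
#'
#' A k-mer qualifies as a closed syncmer iff the hash of its first or last
#' s-mer is less than or equal to the hashes of all other s-mers it contains.
#'
#' @param hseq a hoco-compressed DNA string (character) or `hoco_seq`.
#' @param params a [syncmer_params()] object.
#' @return data.frame with 0-based `pos`, the `kmer` string, and `orient`
#'   (0 if the k-mer is its own canonical form, 1 if the reverse complement is).
#' @export
extract_closed_syncmers <- function(hseq, params) {
  if (is.list(hseq)) hseq <- hseq$bases
  pos <- cpp_extract_syncmer_positions(hseq, params$k, params$s)
  if (length(pos) == 0L)
    return(data.frame(pos = integer(), kmer = character(), orient = integer()))
  kmer <- substring(hseq, pos + 1L, pos + params$k)
  rc <- revcomp(kmer)
  hf <- cpp_kmer_hash(kmer)
  hr <- cpp_kmer_hash(rc)
  orient <- ifelse(hf < hr, 0L, ifelse(hr < hf, 1L, ifelse(rc < kmer, 1L, 0L)))
  data.frame(pos = pos, kmer = kmer, orient = orient, stringsAsFactors = FALSE)
}

#' Build the syncmer table and syncmer vectors from reads
#'
#' Constructs the k-mer table T of all distinct closed syncmers in the reads
#' (canonical orientation: the strand with the smaller 64-bit hash; hash
#' collisions are resolved by sequence comparison) and rewrites each read as
#' its syncmer vector. Reads are split at `N` into fragments processed
#' independently; positions are 0-based hoco coordinates within the fragment.
#'
#' @param reads data.frame from [read_seq_records()] or a character vector.
#' @param params a [syncmer_params()] object.
#' @return a `syncmer_table`: entries (`seq`, `freq`, `hash`, `runlen_sum`)
#'   plus the transformed read set `vectors` (data.table `read`, `frag`,
#'   `index`, `pos`, `orient`) and per-fragment hoco lengths `frags`.
#' @export
build_syncmer_table <- function(reads, params) {
  if (is.data.frame(reads)) {
    ids <- reads$id
    seqs <- reads$seq
  } else {
    seqs <- reads
    ids <- names(reads) %||% paste0("read", seq_along(seqs))
  }
  res <- cpp_build_table(toupper(seqs), params$k, params$s)
  vec <- as.data.table(res$vec)
  frags <- as.data.table(res$frags)
  tab <- list(params = params, seq = res$seq, freq = res$freq,
              hash = res$hash, runlen_sum = res$runlen_sum,
              runlen_n = res$freq,  # accumulation counts; frozen across recounts
              read_ids = ids, vectors = vec, frags = frags)
  class(tab) <- "syncmer_table"
  tab
}

#' @export
print.syncmer_table <- function(x, ...) {
  cat(sprintf("syncmer_table: %d entries (k=%d, s=%d), %d syncmer occurrences in %d reads\n",
              length(x$freq), x$params$k, x$params$s, nrow(x$vectors),
              length(x$read_ids)))
  invisible(x)
}

# per-entry rounded run-length consensus matrix (k x n); the denominator is
# the number of occurrences accumulated into runlen_sum, which is frozen
# when frequencies are later recounted from corrected vectors
consensus_runs <- function(table, index) {
  f <- (table$runlen_n %||% table$freq)[index]
  round_half_up(table$runlen_sum[, index, drop = FALSE] /
                  rep(f, each = nrow(table$runlen_sum)))
}

#' Full-length consensus sequence of a syncmer table entry
#'
#' Each hoco base of the entry is expanded to the closest integer to the
#' average of all run lengths observed at that position (ties round half up).
#'
#' @param table a `syncmer_table`.
#' @param index entry index (1-based).
#' @param orient 0 for the stored canonical orientation, 1 for its reverse
#'   complement.
#' @return uncompressed consensus DNA string.
#' @export
kmer_consensus_sequence <- function(table, index, orient = 0L) {
  runs <- as.integer(consensus_runs(table, index))
  seq <- table$seq[index]
  if (orient == 1L) {
    seq <- revcomp(seq)
    runs <- rev(runs)
  }
  cpp_expand_runs(seq, runs)
}

# oriented hoco sequence of an entry
entry_hoco <- function(table, index, orient = 0L) {
  if (orient == 0L) table$seq[index] else revcomp(table$seq[index])
}

# recompute entry frequencies from a (possibly corrected) vector set
recount_frequencies <- function(table, vectors = table$vectors) {
  n <- length(table$freq)
  tb <- tabulate(vectors$index, nbins = n)
  table$freq <- as.integer(tb)
  table
}

# signed vertex id of a vector row: +index for orient 0, -index for orient 1
signed_vertex <- function(index, orient) ifelse(orient == 0L, index, -index)
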