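# Synthetic organelle genomes, HiFi-like reads and gene hit tables.
#
# The generator emulates what matters to the pipeline: circular genomes with
# exact inverted/direct repeats and inter-organelle shared segments, strong
# coverage stratification (organelle >> nuclear), 10-25 kb reads at ~99%
# accuracy whose errors are dominated by homopolymer run-length changes, and
# significant gene hits with scores and e-values.

#' Specify a synthetic genome set
#'
#' @param components list of component specs; each is a list with `name`,
#'   `size` (bp, excluding planted repeats), `circular`, `depth`, and
#'   optionally `quadripartite = c(lsc, ir, ssc)` sizes (then `size` is
#'   ignored), `repeat_len`/`repeat_kind` (`"IR"`/`"DR"`) for a simple
#'   planted repeat.
#' @param genes optional data.frame with `gene`, `organelle`, `component`,
#'   `start`, `len`, `strand` describing a planted gene layout.
#' @param shared list of shared segments, each `list(length, donor,
#'   acceptor, divergence)`; the segment is copied from the donor into the
#'   acceptor with per-base substitutions at rate `divergence`.
#' @param seed RNG seed; generation is fully deterministic under it.
#' @return a `genome_spec` list.
#' @export
genome_spec <- function(components, genes = NULL, shared = list(), seed = 1L) {
  structure(list(components = components, genes = genes, shared = shared,
                 seed = seed), class = "genome_spec")
}

substitute_bases <- function(seq, positions) {
  if (length(positions) == 0L) return(seq)
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Generate synthetic genomes from a spec
#'
#' @param spec a [genome_spec()].
#' @return list with `records` (data.frame `id`, `seq`), `truth` (per
#'   component: depth, circularity, repeat coordinates) and `genes` (the
#'   realised gene layout, if any).
#' @export
make_genomes <- function(spec) {
  set.seed(spec$seed)
  recs <- list(); truth <- list()
  for (cs in spec$components) {
    if (!is.null(cs$quadripartite)) {
      q <- cs$quadripartite
      stopifnot(length(q) == 3L)
      lsc <- random_dna(q[1]); ir <- random_dna(q[2]); ssc <- random_dna(q[3])
      seq <- paste0(lsc, ir, ssc, revcomp(ir))
      rep_coords <- data.frame(kind = "IR",
                               start = c(q[1], q[1] + q[2] + q[3]),
                               len = q[2])
    } else if (!is.null(cs$repeat_len)) {
      body <- random_dna(cs$size)
      rp <- random_dna(cs$repeat_len)
      third <- cs$size %/% 3L
      copy2 <- if (identical(cs$repeat_kind, "IR")) revcomp(rp) else rp
      seq <- paste0(substr(body, 1, third), rp,
                    substr(body, third + 1L, 2L * third), copy2,
                    substr(body, 2L * third + 1L, cs$size))
      rep_coords <- data.frame(kind = cs$repeat_kind,
                               start = c(third, 2L * third + cs$repeat_len),
                               len = cs$repeat_len)
    } else {
      seq <- random_dna(cs$size)
      rep_coords <- NULL
    }
    recs[[cs$name]] <- seq
    truth[[cs$name]] <- list(depth = cs$depth, circular = isTRUE(cs$circular),
                             repeats = rep_coords)
  }
  for (sh in spec$shared) {
    donor <- recs[[sh$donor]]
    seg <- substr(donor, sh$at %||% 1L, (sh$at %||% 1L) + sh$length - 1L)
    div <- sh$divergence %||% 0
    if (div > 0) {
      np <- rbinom(1L, sh$length, div)
      seg <- substitute_bases(seg, sample.int(sh$length, np))
    }
    acc <- recs[[sh$acceptor]]
    at <- sh$acceptor_at %||% (nchar(acc) %/% 2L)
    recs[[sh$acceptor]] <- paste0(substr(acc, 1L, at), seg,
                                  substr(acc, at + 1L, nchar(acc)))
  }
  records <- data.frame(id = names(recs), seq = unname(unlist(recs)),
                        stringsAsFactors = FALSE)
  list(records = records, truth = truth, genes = spec$genes)
}

#' Read-simulation configuration
#'
#' Defaults reflect HiFi-like data: lognormal read lengths with mean about
#' 15 kb truncated to 5-25 kb, and a total error rate around 1% dominated by
#' homopolymer run-length changes (which homopolymer compression absorbs),
#' with a small residual substitution component.
#'
#' @param depth target per-component depth of coverage.
#' @param mean_len,sd_log,min_len,max_len read length distribution.
#' @param sub_rate per-base substitution rate.
#' @param homo_rate per-base homopolymer run-length (+/-1) error rate.
#' @param seed RNG seed.
#' @return a `readsim_config` list.
#' @export
readsim_config <- function(depth = 50, mean_len = 15000, sd_log = 0.25,
                           min_len = 5000, max_len = 25000,
                           sub_rate = 0.001, homo_rate = 0.009, seed = 1L) {
  stopifnot(sub_rate >= 0, sub_rate <= 1, homo_rate >= 0, homo_rate <= 1)
  structure(list(depth = depth, mean_len = mean_len, sd_log = sd_log,
                 min_len = min_len, max_len = max_len, sub_rate = sub_rate,
                 homo_rate = homo_rate, seed = seed),
            class = "readsim_config")
}

apply_homopolymer_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  r <- rle(strsplit(seq, "")[[1]])
  # homopolymer run-length errors: +/-1 on runs of length >= 2, with
  # probability proportional to the run length; the run never drops below 1,
  # so these errors are invisible to homopolymer compression
  p <- pmin(1, rate * r$lengths) * (r$lengths >= 2L)
  hit <- runif(length(p)) < p
  delta <- ifelse(runif(sum(hit)) < 0.5, -1L, 1L)
  r$lengths[hit] <- pmax(1L, r$lengths[hit] + delta)
  paste(rep(r$values, r$lengths), collapse = "")
}

#' Simulate HiFi-like reads from synthetic genomes
#'
#' Circular components are sampled with wraparound; strands are uniform.
#' Substitution errors and homopolymer run-length errors are applied at the
#' configured rates. Read names encode the truth:
#' `component:start:strand:length`.
#'
#' @param genomes output of [make_genomes()].
#' @param cfg a [readsim_config()]; its `depth` is used for components whose
#'   spec carries none.
#' @return data.frame of reads (`id`, `seq`, `qual = NA`).
#' @export
simulate_reads <- function(genomes, cfg = readsim_config()) {
  set.seed(cfg$seed)
  out <- list()
  for (nm in genomes$records$id) {
    seq <- genomes$records$seq[genomes$records$id == nm]
    G <- nchar(seq)
    depth <- genomes$truth[[nm]]$depth %||% cfg$depth
    circular <- genomes$truth[[nm]]$circular
    target <- depth * G
    tot <- 0; i <- 0L
    tiled <- strrep(seq, ceiling((G + cfg$max_len) / G))  # any wraparound depth
    while (tot < target) {
      len <- round(rlnorm(1, log(cfg$mean_len) - cfg$sd_log^2 / 2, cfg$sd_log))
      len <- min(max(len, cfg$min_len), cfg$max_len)
      if (!circular) len <- min(len, G)
      start <- if (circular) sample.int(G, 1L) else sample.int(max(G - len + 1L, 1L), 1L)
      raw <- substr(tiled, start, start + len - 1L)
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") raw <- revcomp(raw)
      nsub <- rbinom(1L, len, cfg$sub_rate)
      if (nsub > 0L) raw <- substitute_bases(raw, sample.int(len, nsub))
      raw <- apply_homopolymer_errors(raw, cfg$homo_rate)
      i <- i + 1L
      out[[length(out) + 1L]] <- data.frame(
        id = sprintf("%s:%d:%s:%d", nm, start, strand, len),
        seq = raw, qual = NA_character_, stringsAsFactors = FALSE)
      tot <- tot + len
    }
  }
  do.call(rbind, out)
}

#' Build a synthetic gene hit table against unitig sequences
#'
#' Locates each planted gene (a substring of the truth genome) on the
#' assembled unitigs by exact search on both strands and emits one
#' significant hit per occurrence, with scores in 300-2000 and e-values at
#' most 1e-10, plus optional sub-threshold decoy rows.
#'
#' @param g a `unitig_graph`.
#' @param genomes output of [make_genomes()] (with a `genes` layout).
#' @param n_decoys number of insignificant decoy hits to add.
#' @param seed RNG seed for scores.
#' @return data.frame of hits in the shape of [parse_nhmmscan_tbl()].
#' @export
make_hit_table <- function(g, genomes, n_decoys = 0L, seed = 1L) {
  set.seed(seed)
  genes <- genomes$genes
  stopifnot(!is.null(genes))
  rows <- list()
  for (r in seq_len(nrow(genes))) {
    comp <- genes$component[r]
    gseq <- genomes$records$seq[genomes$records$id == comp]
    sub <- substr(gseq, genes$start[r], genes$start[r] + genes$len[r] - 1L)
    if (identical(genes$strand[r], "-")) sub <- revcomp(sub)
    score <- runif(1, 300, 2000)
    for (u in seq_along(g$name)) {
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") sub else revcomp(sub)
        hits_at <- gregexpr(pat, g$seq[u], fixed = TRUE)[[1]]
        if (hits_at[1] == -1L) next
        for (at in hits_at) {
          rows[[length(rows) + 1L]] <- data.frame(
            target_id = g$name[u], gene = genes$gene[r],
            organelle = genes$organelle[r], score = score,
            evalue = 10^-runif(1, 10, 40), start = at,
            end = at + nchar(pat) - 1L, strand = strand,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target_id = character(), gene = character(),
               organelle = character(), score = numeric(), evalue = numeric(),
               start = integer(), end = integer(), strand = character())
  if (n_decoys > 0L && length(g$name)) {
    dec <- data.frame(
      target_id = sample(g$name, n_decoys, replace = TRUE),
      gene = sprintf("decoy%02d", seq_len(n_decoys)),
      organelle = sample(c("plastid", "mitochondrion"), n_decoys, replace = TRUE),
      score = runif(n_decoys, 50, 299),
      evalue = 10^-runif(n_decoys, 0, 5),
      start = 1L, end = 100L, strand = "+", stringsAsFactors = FALSE)
    hits <- rbind(hits, dec)
  }
  hits
}
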