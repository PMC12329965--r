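# End-to-end orchestration: reads -> syncmer table -> error correction ->
# cleaned k-mer graph -> unitig graph -> disentangling -> (with gene hits)
# component classification -> per-component primary sequences.

#' Assemble reads into a cleaned, disentangled unitig graph
#'
#' Runs syncmer collection, error correction (with graph reconstruction from
#' the corrected syncmers), coverage/tip/bubble cleaning, unitig
#' construction, debris removal and triplet disentangling.
#'
#' @param reads data.frame of reads (from [read_seq_records()] or
#'   [simulate_reads()]) or character vector.
#' @param params a [syncmer_params()].
#' @param correction a [correction_params()] or NULL to skip correction.
#' @param clean a [clean_params()].
#' @param min_component_bp debris threshold.
#' @param disentangle_lambda triplet domination threshold (NULL skips
#'   disentangling).
#' @return list with `graph` (`unitig_graph`), `table` (corrected
#'   `syncmer_table`), `read_paths` (mapped reads) and `stats`.
#' @export
syncmer_assemble <- function(reads, params = syncmer_params(),
                    correction = correction_params(),
                    clean = clean_params(),
                    min_component_bp = 10000L,
                    disentangle_lambda = 0.1) {
  table <- build_syncmer_table(reads, params)
  stats <- NULL
  if (!is.null(correction)) {
    cr <- correct_reads(table, correction)
    table <- cr$table
    stats <- cr$stats
  }
  graph <- build_kmer_graph(table)
  graph <- clean_graph(graph, clean)
  ug <- build_unitig_graph(graph)
  ug <- drop_debris(ug, min_component_bp)
  if (!is.null(disentangle_lambda) && length(ug$name) > 0L)
    ug <- disentangle(ug, lambda = disentangle_lambda)
  read_paths <- if (length(ug$name) > 0L) map_reads(ug) else list()
  list(graph = ug, table = table, read_paths = read_paths,
       correction_stats = stats)
}

#' Resolve one graph component into a primary sequence
#'
#' Estimates copy numbers, enumerates canonical candidate paths and selects
#' the primary one. If the first-round primary is non-circular, edge visits
#' are optimised and a second enumeration round is run with the optimised
#' visits as edge multiplicities.
#'
#' @param g a `unitig_graph`.
#' @param comp component id.
#' @param read_paths mapped read paths (for junction-support tie-breaks).
#' @param circular_preference see [select_primary_path()].
#' @param sa_seed seed for simulated annealing in the second round.
#' @param max_expanded cap on expanded nodes.
#' @return list with the selected `candidate` (path, circular, length,
#'   support), all tied `candidates`, the copy-number `model`, the built
#'   `seq`, and `round` (1 or 2).
#' @export
resolve_component <- function(g, comp, read_paths = list(),
                              circular_preference = 0.9, sa_seed = 42L,
                              max_expanded = 64L) {
  nodes <- which(g$comp == comp)
  model <- estimate_copy_numbers(g$len[nodes], g$cov[nodes])
  cands <- enumerate_candidate_paths(g, comp, model, max_expanded = max_expanded)
  best <- select_primary_path(cands, read_paths, circular_preference)
  round <- 1L
  if (!best$circular && nrow(g$edges[abs(g$edges$from) %in% nodes]) > 0L) {
    opt <- optimize_edge_visits(g, comp, model, sa_seed = sa_seed)
    caps <- setNames(opt$edges$t, opt$edges$ekey)
    copies2 <- pmax(1L, as.integer(pmax(opt$tin, opt$tout)))
    cands2 <- tryCatch(
      enumerate_candidate_paths(g, comp, model, edge_caps = caps,
                                copies = copies2, max_expanded = max_expanded),
      error = function(e) list())
    if (length(cands2)) {
      best2 <- select_primary_path(cands2, read_paths, circular_preference)
      if (best2$circular || best2$length > best$length) {
        best <- best2
        cands <- cands2
        round <- 2L
      }
    }
  }
  ps <- path_to_sequence(g, best$path, best$circular)
  list(candidate = best, candidates = cands, model = model, seq = ps$seq,
       round = round)
}

#' Assemble and resolve organelle genomes end to end
#'
#' @param reads input reads (data.frame or character vector).
#' @param hits gene hit table (data.frame as from [parse_nhmmscan_tbl()]),
#'   already computed against the unitig sequences, or NULL to skip
#'   classification (all components are resolved, unlabelled).
#' @param params,correction,clean,annotation stage parameter objects.
#' @param ... passed to [syncmer_assemble()].
#' @return list with `assembly` (the [syncmer_assemble()] result), `labels`
#'   (component organelle labels) and `solutions` (per resolved component:
#'   label, candidate, sequence).
#' @export
assemble_organelles <- function(reads, hits = NULL,
                                params = syncmer_params(),
                                correction = correction_params(),
                                clean = clean_params(),
                                annotation = annotation_params(), ...) {
  asm <- syncmer_assemble(reads, params = params, correction = correction,
                 clean = clean, ...)
  g <- asm$graph
  labels <- NULL
  comps <- sort(unique(g$comp))
  if (!is.null(hits)) {
    sig <- filter_hits(hits, annotation)
    labels <- assign_organelle_types(g, sig, annotation)
    comps <- labels$component[labels$label != "unassigned"]
  }
  solutions <- list()
  for (cid in comps) {
    sol <- resolve_component(g, cid, asm$read_paths)
    sol$component <- cid
    sol$label <- if (!is.null(labels)) labels$label[labels$component == cid] else NA_character_
    solutions[[as.character(cid)]] <- sol
  }
  list(assembly = asm, labels = labels, solutions = solutions)
}
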