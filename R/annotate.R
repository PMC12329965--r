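# Organelle-type classification of graph components from profile-HMM gene
# hits, and the gene-database sequence selection utility.

#' Annotation parameters
#'
#' @param max_evalue hits with larger e-values are insignificant.
#' @param min_score hits with smaller bit scores are insignificant.
#' @param mito_vs_plastid_ratio a plastid-labelled component is reassigned to
#'   mitochondrion when its mitochondrial score reaches this fraction of its
#'   plastid score (and a plastid component already exists). Plastid genes
#'   are strongly conserved, so a few transferred plastid genes can dominate
#'   a mitochondrial component's score; this ratio counteracts that.
#' @param min_new_best_plastid,min_new_best_mito number of genes that must
#'   beat the running best score for a new component to be accepted for the
#'   respective organelle (guards against NUMT/NUPT junk components).
#' @return an `annotation_params` list.
#' @export
annotation_params <- function(max_evalue = 1e-6, min_score = 300,
                              mito_vs_plastid_ratio = 1 / 3,
                              min_new_best_plastid = 3L,
                              min_new_best_mito = 1L) {
  structure(list(max_evalue = max_evalue, min_score = min_score,
                 mito_vs_plastid_ratio = mito_vs_plastid_ratio,
                 min_new_best_plastid = as.integer(min_new_best_plastid),
                 min_new_best_mito = as.integer(min_new_best_mito)),
            class = "annotation_params")
}

#' Filter HMM hits for significance
#'
#' @param hits data.frame of hits from [parse_nhmmscan_tbl()].
#' @param params an [annotation_params()] object.
#' @return the significant hits (evalue <= max_evalue and score >= min_score).
#' @export
filter_hits <- function(hits, params = annotation_params()) {
  hits[hits$evalue <= params$max_evalue & hits$score >= params$min_score, ,
       drop = FALSE]
}

# per-component best hit per (organelle, gene): list of gene tables
component_gene_tables <- function(g, hits) {
  comp <- g$comp[match(hits$target_id, g$name)]
  hits <- hits[!is.na(comp), , drop = FALSE]
  comp <- comp[!is.na(comp)]
  out <- list()
  for (cid in sort(unique(comp))) {
    h <- hits[comp == cid, , drop = FALSE]
    h <- h[order(h$organelle, h$gene, -h$score, h$target_id, h$start), , drop = FALSE]
    best <- h[!duplicated(paste(h$organelle, h$gene)), , drop = FALSE]
    out[[as.character(cid)]] <- list(
      component = cid, hits = best,
      plastid_score = sum(best$score[best$organelle == "plastid"]),
      mito_score = sum(best$score[best$organelle == "mitochondrion"]))
  }
  out
}

#' Assign organelle types to graph components
#'
#' Components are sorted by their stronger organelle score (sum of
#' best-per-gene hit scores) in descending order and processed progressively.
#' Each component is tentatively labelled with its stronger organelle; a
#' plastid label is flipped to mitochondrion when a plastid component already
#' exists and the component's mitochondrial score is at least one third of
#' its plastid score. The component is accepted only if enough of its genes
#' beat the running per-gene best scores (3 for plastid, 1 for mitochondrion);
#' otherwise it stays unassigned. Accepted components update the running best
#' scores for both organelles.
#'
#' @param g a `unitig_graph` with component labels.
#' @param hits significant hits (already passed through [filter_hits()]).
#' @param params an [annotation_params()] object.
#' @return data.frame with `component` and `label` (`"plastid"`,
#'   `"mitochondrion"` or `"unassigned"`), one row per component with hits;
#'   components without hits are omitted.
#' @export
assign_organelle_types <- function(g, hits, params = annotation_params()) {
  tabs <- component_gene_tables(g, hits)
  if (length(tabs) == 0L)
    return(data.frame(component = integer(), label = character()))
  score <- vapply(tabs, function(t) max(t$plastid_score, t$mito_score), numeric(1))
  cid <- vapply(tabs, `[[`, integer(1), "component")
  ord <- order(-score, cid)
  best_score <- new.env(parent = emptyenv())  # key "organelle:gene" -> score
  labels <- setNames(rep("unassigned", length(tabs)), as.character(cid))
  plastid_assigned <- FALSE
  for (t in tabs[ord]) {
    label <- if (t$plastid_score >= t$mito_score) "plastid" else "mitochondrion"
    if (label == "plastid" && plastid_assigned &&
        t$mito_score >= params$mito_vs_plastid_ratio * t$plastid_score)
      label <- "mitochondrion"
    th <- if (label == "plastid") params$min_new_best_plastid else params$min_new_best_mito
    lh <- t$hits[t$hits$organelle == label, , drop = FALSE]
    n_new_best <- 0L
    if (nrow(lh)) {
      for (r in seq_len(nrow(lh))) {
        key <- paste0(lh$organelle[r], ":", lh$gene[r])
        cur <- best_score[[key]] %||% -Inf
        if (lh$score[r] > cur) n_new_best <- n_new_best + 1L
      }
    }
    if (n_new_best < th) next
    labels[as.character(t$component)] <- label
    if (label == "plastid") plastid_assigned <- TRUE
    for (r in seq_len(nrow(t$hits))) {
      key <- paste0(t$hits$organelle[r], ":", t$hits$gene[r])
      cur <- best_score[[key]] %||% -Inf
      if (t$hits$score[r] > cur) best_score[[key]] <- t$hits$score[r]
    }
  }
  data.frame(component = cid, label = unname(labels[as.character(cid)]),
             stringsAsFactors = FALSE)
}

#' Select representative sequences for gene-database construction
#'
#' Removes sequences with invalid characters and those shorter than one third
#' or longer than three times the average length. If more than `cap` remain,
#' the most representative `cap` are kept by 12-mer completeness: a 12-mer
#' count table is built over the survivors, the 1% most and 1% least
#' frequent 12-mers are excluded, and each sequence is scored by the sum of
#' counts of its unique 12-mers.
#'
#' @param seqs data.frame with `id` and `seq`, or a named character vector.
#' @param cap maximum number of sequences to keep.
#' @return the selected subset, same shape as the input data.frame.
#' @export
select_representative_sequences <- function(seqs, cap = 10000L) {
  if (!is.data.frame(seqs))
    seqs <- data.frame(id = names(seqs) %||% as.character(seq_along(seqs)),
                       seq = unname(seqs), stringsAsFactors = FALSE)
  valid <- !grepl("[^ACGT]", seqs$seq)
  seqs <- seqs[valid, , drop = FALSE]
  if (nrow(seqs) == 0L) stop("no valid sequences left after character filter")
  avg <- mean(nchar(seqs$seq))
  keep <- nchar(seqs$seq) >= avg / 3 & nchar(seqs$seq) <= 3 * avg
  seqs <- seqs[keep, , drop = FALSE]
  if (nrow(seqs) == 0L) stop("no sequences left after length filter")
  if (nrow(seqs) <= cap) return(seqs)
  kmers_of <- function(s) {
    n <- nchar(s)
    if (n < 12L) return(character(0))
    substring(s, 1:(n - 11L), 12:n)
  }
  all_kmers <- lapply(seqs$seq, kmers_of)
  counts <- table(unlist(all_kmers))
  qs <- stats::quantile(as.numeric(counts), c(0.01, 0.99), type = 1)
  ok <- counts > qs[1] & counts < qs[2]
  # exclude the 1% most and least frequent 12-mers (ties at the cut kept out)
  usable <- counts[ok]
  score <- vapply(all_kmers, function(km) {
    u <- unique(km)
    sum(as.numeric(usable[u]), na.rm = TRUE)
  }, numeric(1))
  seqs[order(-score, seqs$id)[seq_len(cap)], , drop = FALSE]
}
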