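# The sparse de Bruijn (syncmer) graph.
#
# A vertex is a signed integer: +i is table entry i in its canonical
# orientation, -i its reverse complement; the complement of vertex v is -v.
# Edges are directed and stored with both complements present, each carrying
# a coverage (number of supporting read adjacencies) and a hoco overlap
# length. This makes the graph Watson-Crick complete by construction.

#' Build the sparse k-mer graph from a syncmer table
#'
#' Every pair of adjacent syncmers on a read contributes one unit of coverage
#' to the corresponding edge and its complement. Overlap lengths are
#' consolidated per edge; when different read distances are observed for the
#' same vertex pair, the largest distance (smallest overlap) wins.
#'
#' @param table a `syncmer_table`.
#' @param vectors syncmer vectors (defaults to `table$vectors`).
#' @return a `kmer_graph` with fields `table`, `alive` (logical per entry)
#'   and `edges` (data.table `from`, `to`, `cov`, `ovl`).
#' @export
build_kmer_graph <- function(table, vectors = table$vectors) {
  k <- table$params$k
  v <- vectors[order(vectors$read, vectors$frag, vectors$pos)]
  n <- nrow(v)
  if (n >= 2L) {
    same <- v$read[-1L] == v$read[-n] & v$frag[-1L] == v$frag[-n]
    from <- signed_vertex(v$index[-n], v$orient[-n])[same]
    to <- signed_vertex(v$index[-1L], v$orient[-1L])[same]
    dist <- (v$pos[-1L] - v$pos[-n])[same]
    if (any(dist >= k) || any(dist <= 0L))
      stop("syncmer vector violates the overlap guarantee (0 < p_{i+1}-p_i < k)")
    e <- data.table(from = c(from, -to), to = c(to, -from),
                    dist = c(dist, dist))
    edges <- e[, list(cov = .N, ovl = k - max(dist)), by = c("from", "to")]
  } else {
    edges <- data.table(from = integer(), to = integer(),
                        cov = integer(), ovl = integer())
  }
  setkeyv(edges, c("from", "to"))
  g <- list(table = table, alive = rep(TRUE, length(table$freq)), edges = edges)
  class(g) <- "kmer_graph"
  g
}

#' @export
print.kmer_graph <- function(x, ...) {
  cat(sprintf("kmer_graph: %d/%d live entries, %d directed edges\n",
              sum(x$alive), length(x$alive), nrow(x$edges)))
  invisible(x)
}

# edges restricted to live vertices
live_edges <- function(graph) {
  e <- graph$edges
  e[graph$alive[abs(e$from)] & graph$alive[abs(e$to)]]
}

#' Verify Watson-Crick completeness of a k-mer graph
#'
#' Checks that every edge has its complement present with identical coverage
#' and overlap (vertex pairing is implied by the signed representation).
#'
#' @param graph a `kmer_graph`.
#' @return `TRUE`, or `FALSE` with attribute `violation` describing the first
#'   failure.
#' @export
verify_wc_complete <- function(graph) {
  e <- live_edges(graph)
  if (nrow(e) == 0L) return(TRUE)
  m <- merge(e, data.table(from = -e$to, to = -e$from, cov2 = e$cov, ovl2 = e$ovl),
             by = c("from", "to"), all.x = TRUE)
  bad <- which(is.na(m$cov2) | m$cov2 != m$cov | m$ovl2 != m$ovl)
  if (length(bad)) {
    r <- m[bad[1]]
    out <- FALSE
    attr(out, "violation") <- sprintf("edge %d->%d lacks a matching complement",
                                      r$from, r$to)
    return(out)
  }
  TRUE
}

# remove entries (vertex pairs) from the graph
drop_entries <- function(graph, idx) {
  graph$alive[idx] <- FALSE
  graph
}
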