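# Shared fixture builders and independent oracles.

tiny_params <- function() syncmer_params(k = 31L, s = 7L)

# one random circular genome plus simulated reads
circle_fixture <- function(size = 8000, depth = 30, seed = 1,
                           sub_rate = 0, homo_rate = 0) {
  spec <- genome_spec(list(list(name = "circ", size = size, circular = TRUE,
                                depth = depth)), seed = seed)
  gen <- make_genomes(spec)
  reads <- simulate_reads(gen, readsim_config(depth = depth,
                                              sub_rate = sub_rate,
                                              homo_rate = homo_rate,
                                              seed = seed + 100))
  list(gen = gen, reads = reads, truth = gen$records$seq[1])
}

# genomes list usable by simulate_reads() from explicit sequences
manual_genomes <- function(seqs, depth = 30, circular = TRUE) {
  list(records = data.frame(id = names(seqs), seq = unname(unlist(seqs)),
                            stringsAsFactors = FALSE),
       truth = lapply(seqs, function(s) list(depth = depth, circular = circular)),
       genes = NULL)
}

# ---- independent oracles ----------------------------------------------------

# brute-force per-position closed-syncmer checker (independent of the deque
# sliding-minimum implementation)
oracle_is_syncmer <- function(hseq, pos0, k, s) {
  kmer <- substr(hseq, pos0 + 1L, pos0 + k)
  smers <- substring(kmer, 1:(k - s + 1L), s:k)
  h <- canonical_smer_hash(smers)  # fixed-width hex: lexicographic == numeric
  mn <- min(h)
  h[1] == mn || h[length(h)] == mn
}

# exhaustive maximal-walk enumeration over an expanded graph, with canonical
# dedup done from scratch (rotations / reversal on copy-erased labels)
oracle_enumerate <- function(nodes, copies, edges) {
  # edges: data.frame(from, to) signed node ids; complement edges included
  adj <- split(edges$to, edges$from)
  exp_nodes <- unlist(lapply(seq_along(nodes), function(i)
    rep(nodes[i], copies[i])))
  key_lin <- function(p) min(paste(p, collapse = ","),
                             paste(rev(-p), collapse = ","))
  key_circ <- function(p) {
    best <- NULL
    for (q in list(p, rev(-p))) {
      for (i in seq_along(q)) {
        r <- paste(c(q[i:length(q)], q[seq_len(i - 1L)]), collapse = ",")
        if (is.null(best) || r < best) best <- r
      }
    }
    best
  }
  seen <- new.env(parent = emptyenv())
  out <- new.env(parent = emptyenv()); out$res <- list()
  has_edge <- function(a, b) b %in% (adj[[as.character(a)]] %||% integer(0))
  `%||%` <- function(a, b) if (is.null(a)) b else a
  rec <- function(path, used) {
    ext <- FALSE
    for (b in adj[[as.character(path[length(path)])]] %||% integer(0)) {
      z <- abs(b)
      if (sum(used == z) >= copies[match(z, nodes)]) next
      ext <- TRUE
      rec(c(path, b), c(used, z))
    }
    if (!ext) {
      circ <- has_edge(path[length(path)], path[1])
      key <- paste0(if (circ) "c:" else "l:",
                    if (circ) key_circ(path) else key_lin(path))
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out$res[[length(out$res) + 1L]] <- list(path = path, circular = circ,
                                                key = key)
      }
    }
  }
  for (z in nodes) for (sg in c(1L, -1L)) rec(sg * z, z)
  out$res
}

# objective of an edge-visit assignment, recomputed from scratch
oracle_edge_objective <- function(t, e_from, e_to, node_ids, cz, wz) {
  tin <- setNames(numeric(length(node_ids)), node_ids)
  tout <- tin
  for (i in seq_along(t)) {
    f <- e_from[i]; d <- e_to[i]
    if (f > 0) tout[as.character(f)] <- tout[as.character(f)] + t[i]
    else tin[as.character(-f)] <- tin[as.character(-f)] + t[i]
    if (d > 0) tin[as.character(d)] <- tin[as.character(d)] + t[i]
    else tout[as.character(-d)] <- tout[as.character(-d)] + t[i]
  }
  sum((abs(cz - tin) / 2 + abs(cz - tout) / 2 + abs(tin - tout)) * wz)
}

rc <- function(x) syntig:::cpp_revcomp(x)

# maximal inverted-repeat length of a circle given the planted repeat
# coordinates (0-based starts of IRa and IRb and planted length): extends
# both boundaries while the flanks keep reverse-complement identity
oracle_max_ir <- function(seq, a0, b0, len) {
  L <- nchar(seq)
  at <- function(i) substr(seq, ((i) %% L) + 1L, ((i) %% L) + 1L)
  comp1 <- function(x) chartr("ACGT", "TGCA", x)
  ext_left <- 0L
  while (at(a0 - ext_left - 1L) == comp1(at(b0 + len + ext_left))) {
    ext_left <- ext_left + 1L
  }
  ext_right <- 0L
  while (at(a0 + len + ext_right) == comp1(at(b0 - ext_right - 1L))) {
    ext_right <- ext_right + 1L
  }
  len + ext_left + ext_right
}

# minimal unitig graph for pathfinder-level tests: given lengths and signed
# edges (complements added automatically)
mk_accept_graph <- function(lens, edges_df, covs = NULL) {
  n <- length(lens)
  e <- data.table::data.table(from = as.integer(edges_df$from),
                              to = as.integer(edges_df$to), ovl = 0L, cov = 10)
  e <- unique(rbind(e, data.table::data.table(from = -e$to, to = -e$from,
                                              ovl = 0L, cov = 10)))
  g <- list(name = sprintf("utg%06d", 1:n), seq = rep("AAA", n),
            len = as.integer(lens),
            cov = if (is.null(covs)) rep(10, n) else covs,
            circular = rep(FALSE, n), hoco = NULL, runs = NULL, vpath = NULL,
            edges = e, comp = rep(1L, n))
  class(g) <- "unitig_graph"
  g
}
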