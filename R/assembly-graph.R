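# Graph cleaning, unitig construction, k-mer-level read mapping and
# triplet-based disentangling.
#
# Unitigs are maximal unambiguous paths in the k-mer graph. A `unitig_graph`
# stores one record per complement pair (parallel vectors; the signed id +u /
# -u addresses the two orientations) plus a Watson-Crick complete edge table.

#' Graph cleaning parameters
#'
#' @param cov_threshold coverage filter c: k-mers below this frequency are
#'   removed before unitigging. Typically five times the haploid nuclear
#'   coverage, so that almost all nuclear sequence (and all but the most
#'   recent NUMT/NUPT insertions) is excluded.
#' @param tip_len dead-end chains shorter than this (uncompressed bp) are
#'   trimmed.
#' @param bubble_len two-arm bubbles with arms shorter than this are popped,
#'   keeping the higher-coverage arm.
#' @return a `clean_params` list.
#' @export
clean_params <- function(cov_threshold = 1L, tip_len = 10000L,
                         bubble_len = 100000L) {
  stopifnot(cov_threshold >= 0, tip_len > 0, bubble_len > 0)
  structure(list(cov_threshold = as.integer(cov_threshold),
                 tip_len = as.integer(tip_len),
                 bubble_len = as.integer(bubble_len)), class = "clean_params")
}

# ---- chain decomposition ----------------------------------------------------

# signed vertex -> array slot (1..2n)
vslot <- function(v, n) ifelse(v > 0L, v, n - v)

# Maximal unambiguous chains of the live k-mer graph. Returns a list with
# one canonical chain per complement pair: `path` (signed vertices), `dist`
# (inter-vertex distances, hoco bp), `circular`.
kmer_chains <- function(graph) {
  n <- length(graph$alive)
  e <- live_edges(graph)
  outdeg <- integer(2L * n)
  if (nrow(e)) {
    tb <- e[, list(nd = .N), by = "from"]
    outdeg[vslot(tb$from, n)] <- tb$nd
  }
  indeg_of <- function(v) outdeg[vslot(-v, n)]
  nxt <- integer(2L * n)
  dst <- integer(2L * n)
  if (nrow(e)) {
    k <- graph$table$params$k
    single <- e[outdeg[vslot(e$from, n)] == 1L & outdeg[vslot(-e$to, n)] == 1L]
    nxt[vslot(single$from, n)] <- single$to
    dst[vslot(single$from, n)] <- k - single$ovl
  }
  verts <- which(graph$alive)
  allv <- c(verts, -verts)
  prv <- integer(2L * n)
  has_nxt <- which(nxt != 0L)
  prv[vslot(nxt[has_nxt], n)] <- c(has_nxt)  # slot of predecessor (as slot id)
  slot_to_v <- function(s) ifelse(s <= n, s, -(s - n))

  visited <- logical(2L * n)
  chains <- list()
  add_chain <- function(path, dist, circular) {
    chains[[length(chains) + 1L]] <<- list(path = path, dist = dist,
                                           circular = circular)
  }
  # linear chains: start where no mergeable predecessor exists
  for (v in allv) {
    sv <- vslot(v, n)
    if (visited[sv]) next
    if (prv[sv] != 0L) next
    path <- v; dist <- integer(0)
    visited[sv] <- TRUE
    w <- v
    repeat {
      nx <- nxt[vslot(w, n)]
      if (nx == 0L) break
      dist <- c(dist, dst[vslot(w, n)])
      w <- nx
      visited[vslot(w, n)] <- TRUE
      path <- c(path, w)
    }
    add_chain(path, dist, FALSE)
  }
  # remaining vertices belong to cycles
  for (v in allv) {
    sv <- vslot(v, n)
    if (visited[sv]) next
    path <- v; dist <- integer(0)
    visited[sv] <- TRUE
    w <- v
    repeat {
      nx <- nxt[vslot(w, n)]
      dist <- c(dist, dst[vslot(w, n)])
      if (nx == v) break
      w <- nx
      visited[vslot(w, n)] <- TRUE
      path <- c(path, w)
    }
    add_chain(path, dist, TRUE)
  }
  # keep one chain per complement pair
  keyof <- function(ch) {
    p <- ch$path
    if (ch$circular && length(p) > 1L) {
      i <- which.min(p)
      p <- c(p[i:length(p)], p[seq_len(i - 1L)])
    }
    paste(p, collapse = ",")
  }
  canon <- vapply(chains, function(ch) {
    comp <- list(path = rev(-ch$path), dist = rev(ch$dist), circular = ch$circular)
    min(keyof(ch), keyof(comp))
  }, character(1))
  chains[!duplicated(canon)]
}

# per-entry uncompressed consensus lengths
entry_cons_len <- function(table) {
  f <- rep(table$runlen_n %||% table$freq, each = nrow(table$runlen_sum))
  colSums(floor(table$runlen_sum / f + 0.5))
}

# uncompressed bp length of a chain
chain_bp <- function(chain, table, cons_len) {
  p <- chain$path
  total <- cons_len[abs(p[1])]
  if (length(p) > 1L) {
    for (i in 2L:length(p)) {
      d <- chain$dist[i - 1L]
      runs <- consensus_runs(table, abs(p[i]))[, 1]
      if (p[i] < 0L) runs <- rev(runs)
      total <- total + sum(runs[(length(runs) - d + 1L):length(runs)])
    }
  }
  total
}

# ---- cleaning ---------------------------------------------------------------

#' Clean a k-mer graph
#'
#' Applies, iteratively to a fixed point (at most 16 rounds): removal of
#' k-mers below the coverage threshold, trimming of dead-end chains shorter
#' than `tip_len`, and popping of two-arm bubbles with arms shorter than
#' `bubble_len` (the arm with the higher coverage x length is kept; ties go
#' to the arm with the smaller first entry index).
#'
#' @param graph a `kmer_graph`.
#' @param params a [clean_params()] object.
#' @return the cleaned `kmer_graph`.
#' @export
clean_graph <- function(graph, params) {
  graph$alive <- graph$alive & graph$table$freq >= params$cov_threshold
  cons_len <- entry_cons_len(graph$table)
  n <- length(graph$alive)
  for (round in seq_len(16L)) {
    changed <- FALSE
    chains <- kmer_chains(graph)
    if (length(chains) == 0L) break
    e <- live_edges(graph)
    outdeg <- integer(2L * n)
    if (nrow(e)) {
      tb <- e[, list(nd = .N), by = "from"]
      outdeg[vslot(tb$from, n)] <- tb$nd
    }
    # tips: dead end on exactly one side, shorter than tip_len
    for (ch in chains) {
      p <- ch$path
      if (ch$circular) next
      ind <- outdeg[vslot(-p[1], n)]
      outd <- outdeg[vslot(p[length(p)], n)]
      if ((ind == 0L) == (outd == 0L)) next  # internal or isolated
      if (chain_bp(ch, graph$table, cons_len) < params$tip_len) {
        graph <- drop_entries(graph, abs(p))
        changed <- TRUE
      }
    }
    if (changed) next
    # bubbles: arms (directed chains incl. complements) grouped by endpoints
    arms <- list()
    for (ch in chains) {
      if (ch$circular) next
      arms[[length(arms) + 1L]] <- ch
      arms[[length(arms) + 1L]] <- list(path = rev(-ch$path),
                                        dist = rev(ch$dist), circular = FALSE)
    }
    if (length(arms)) {
      setkeyv(e, c("from", "to"))
      preds <- lapply(arms, function(a) e[e$to == a$path[1]]$from)
      succs <- lapply(arms, function(a) e[e$from == a$path[length(a$path)]]$to)
      key <- vapply(seq_along(arms), function(i) {
        if (length(preds[[i]]) == 1L && length(succs[[i]]) == 1L)
          paste(preds[[i]], succs[[i]]) else NA_character_
      }, character(1))
      grp <- split(seq_along(arms), key)
      for (g in grp) {
        # an arm and its own complement share (pred, succ) when flanked by an
        # inverted repeat; they are one sequence, not a bubble
        esets <- vapply(arms[g], function(a)
          paste(sort(unique(abs(a$path))), collapse = ","), character(1))
        g <- g[!duplicated(esets)]
        if (length(g) < 2L) next
        lens <- vapply(arms[g], chain_bp, numeric(1), table = graph$table,
                       cons_len = cons_len)
        covs <- vapply(arms[g], function(a) mean(graph$table$freq[abs(a$path)]),
                       numeric(1))
        if (any(lens >= params$bubble_len)) next
        # variant bubbles (errors, diverged repeat copies) have near-equal
        # arms; two unrelated through-routes sharing endpoints (e.g. two
        # genomes joined by a shared segment) do not, and must be kept for
        # read-phased disentangling
        if (min(lens) < 0.9 * max(lens)) next
        score <- covs * lens
        first_id <- vapply(arms[g], function(a) min(abs(a$path)), integer(1))
        best <- g[order(-score, first_id)][1]
        for (a in setdiff(g, best)) {
          if (any(graph$alive[abs(arms[[a]]$path)])) {
            graph <- drop_entries(graph, abs(arms[[a]]$path))
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  graph
}

# ---- unitig graph -----------------------------------------------------------

#' Build a unitig graph from a (cleaned) k-mer graph
#'
#' Every live vertex ends up in exactly one unitig (or its complement).
#' Unitig sequences are the run-length consensus expansions of their k-mers
#' with overlaps removed; edges connect unitigs whose terminal k-mers are
#' adjacent in the k-mer graph.
#'
#' @param graph a `kmer_graph`.
#' @return a `unitig_graph`.
#' @export
build_unitig_graph <- function(graph) {
  table <- graph$table
  k <- table$params$k
  chains <- kmer_chains(graph)
  nu <- length(chains)
  name <- sprintf("utg%06d", seq_len(nu))
  hoco <- character(nu); runs <- vector("list", nu)
  seqs <- character(nu); len <- integer(nu); cov <- numeric(nu)
  circ <- logical(nu); vpath <- vector("list", nu)
  for (i in seq_len(nu)) {
    ch <- chains[[i]]
    p <- ch$path
    bases <- entry_hoco(table, abs(p[1]), as.integer(p[1] < 0))
    r1 <- consensus_runs(table, abs(p[1]))[, 1]
    if (p[1] < 0L) r1 <- rev(r1)
    rr <- r1
    if (length(p) > 1L) {
      for (j in 2L:length(p)) {
        d <- ch$dist[j - 1L]
        hj <- entry_hoco(table, abs(p[j]), as.integer(p[j] < 0))
        rj <- consensus_runs(table, abs(p[j]))[, 1]
        if (p[j] < 0L) rj <- rev(rj)
        bases <- paste0(bases, substr(hj, k - d + 1L, k))
        rr <- c(rr, rj[(k - d + 1L):k])
      }
    }
    if (ch$circular) {
      # drop the wrap-around overlap (the first k - d_wrap hoco bases repeat)
      dw <- ch$dist[length(ch$dist)]
      keep <- sum(ch$dist)  # total hoco length of the cycle
      bases <- substr(bases, 1L, keep)
      rr <- rr[seq_len(keep)]
    }
    hoco[i] <- bases
    runs[[i]] <- as.integer(rr)
    seqs[i] <- cpp_expand_runs(bases, as.integer(rr))
    len[i] <- nchar(seqs[i])
    cov[i] <- mean(table$freq[abs(p)])
    circ[i] <- ch$circular
    vpath[[i]] <- p
  }
  # edges between chain terminals (internal mergeable edges excluded)
  ends <- new.env(parent = emptyenv())    # vertex -> signed utg ending there
  starts <- new.env(parent = emptyenv())  # vertex -> signed utg starting there
  addloc <- function(env, v, su) {
    key <- as.character(v)
    env[[key]] <- c(env[[key]], su)
  }
  for (i in seq_len(nu)) {
    p <- vpath[[i]]
    addloc(starts, p[1], i); addloc(ends, p[length(p)], i)
    addloc(starts, -p[length(p)], -i); addloc(ends, -p[1], -i)
  }
  e <- live_edges(graph)
  ef <- integer(0); et <- integer(0); eo <- integer(0); ec <- numeric(0)
  if (nrow(e)) {
    for (j in seq_len(nrow(e))) {
      us <- ends[[as.character(e$from[j])]]
      vs <- starts[[as.character(e$to[j])]]
      if (is.null(us) || is.null(vs)) next
      for (a in us) for (b in vs) {
        if (circ[abs(a)] || circ[abs(b)]) next  # cycle wrap edges are internal
        ef <- c(ef, a); et <- c(et, b); eo <- c(eo, e$ovl[j]); ec <- c(ec, e$cov[j])
      }
    }
  }
  edges <- unique(data.table(from = ef, to = et, ovl = eo, cov = ec),
                  by = c("from", "to"))
  # drop edges that are actually internal chain links (single-vertex case is
  # already excluded because chain terminals of a mergeable edge never both
  # remain terminals)
  g <- list(k = k, s = table$params$s, name = name, seq = seqs, len = len,
            cov = cov, circular = circ, hoco = hoco, runs = runs,
            vpath = vpath, edges = edges, comp = NULL, table = table)
  class(g) <- "unitig_graph"
  g$comp <- unitig_components(g)
  g
}

#' @export
print.unitig_graph <- function(x, ...) {
  cat(sprintf("unitig_graph: %d unitigs (%d bp), %d directed edges, %d component(s)\n",
              length(x$name), sum(x$len), nrow(x$edges),
              length(unique(x$comp))))
  invisible(x)
}

# connected component labels (undirected, ignoring orientation)
unitig_components <- function(g) {
  n <- length(g$name)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (!is.null(g$edges) && nrow(g$edges)) {
    a <- as.integer(abs(g$edges$from)); b <- as.integer(abs(g$edges$to))
    for (j in seq_along(a)) {
      ra <- find(a[j]); rb <- find(b[j])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# oriented k-mer path of a signed unitig
path_of <- function(g, su) if (su > 0L) g$vpath[[su]] else rev(-g$vpath[[-su]])

# oriented hoco/runs of a signed unitig
oriented_hoco <- function(g, su) if (su > 0L) g$hoco[su] else revcomp(g$hoco[-su])
oriented_runs <- function(g, su) if (su > 0L) g$runs[[su]] else rev(g$runs[[-su]])
oriented_seq <- function(g, su) if (su > 0L) g$seq[su] else revcomp(g$seq[-su])

# ---- read mapping -----------------------------------------------------------

# vertex -> list of (signed utg, 1-based offset) location index
build_vertex_index <- function(g) {
  env <- new.env(parent = emptyenv())
  for (u in seq_along(g$name)) {
    p <- g$vpath[[u]]
    L <- length(p)
    for (i in seq_len(L)) {
      key <- as.character(p[i])
      env[[key]] <- rbind(env[[key]], c(u, i))
      key2 <- as.character(-p[i])
      env[[key2]] <- rbind(env[[key2]], c(-u, L + 1L - i))
    }
  }
  env
}

#' Map a read's syncmer vector to the unitig graph
#'
#' Seed-and-extend at the k-mer level: the first k-mer of the read present in
#' the graph seeds the walk, which then follows the read's k-mer order
#' through unitig boundaries. A k-mer that is not where the walk expects it
#' makes the read unmapped. Ambiguous placements (after disentangling,
#' k-mers can occur in several unitig copies) are tracked as parallel states
#' and resolved by context; reads whose placement stays ambiguous are
#' unmapped.
#'
#' @param vec one read's syncmer vector rows (single fragment).
#' @param g a `unitig_graph`.
#' @param vindex prebuilt vertex index from `build_vertex_index(g)`.
#' @param max_states ambiguity cap.
#' @return integer vector of signed unitig ids, or `NULL` if unmapped.
#' @export
map_read_to_unitigs <- function(vec, g, vindex = build_vertex_index(g),
                                max_states = 16L) {
  w <- signed_vertex(vec$index, vec$orient)
  m <- length(w)
  seed <- 0L
  for (i in seq_len(m)) {
    if (!is.null(vindex[[as.character(w[i])]])) { seed <- i; break }
  }
  if (seed == 0L) return(NULL)
  locs <- vindex[[as.character(w[seed])]]
  states <- lapply(seq_len(nrow(locs)), function(r)
    list(u = locs[r, 1], off = locs[r, 2], path = locs[r, 1]))
  ulen <- function(su) length(g$vpath[[abs(su)]])
  i <- seed
  while (i < m) {
    i <- i + 1L
    nw <- w[i]
    nstates <- list()
    for (st in states) {
      if (st$off < ulen(st$u)) {
        p <- path_of(g, st$u)
        if (p[st$off + 1L] == nw) {
          st$off <- st$off + 1L
          nstates[[length(nstates) + 1L]] <- st
        }
      } else {
        outs <- g$edges[g$edges$from == st$u]
        if (nrow(outs)) for (b in outs$to) {
          pb <- path_of(g, b)
          if (pb[1] == nw)
            nstates[[length(nstates) + 1L]] <- list(u = b, off = 1L,
                                                    path = c(st$path, b))
        }
        # circular single unitig: wrap around
        if (g$circular[abs(st$u)] && ulen(st$u) >= 1L) {
          pb <- path_of(g, st$u)
          if (pb[1] == nw)
            nstates[[length(nstates) + 1L]] <- list(u = st$u, off = 1L,
                                                    path = c(st$path, st$u))
        }
      }
    }
    if (length(nstates) == 0L) return(NULL)
    if (length(nstates) > max_states) return(NULL)
    states <- nstates
  }
  paths <- unique(lapply(states, `[[`, "path"))
  if (length(paths) != 1L) return(NULL)
  paths[[1]]
}

#' Map all reads to the unitig graph
#'
#' @param g a `unitig_graph`.
#' @param table a `syncmer_table` whose vectors to map (defaults to the one
#'   the graph was built from).
#' @return list of signed unitig paths (NULL where unmapped), one entry per
#'   (read, fragment).
#' @export
map_reads <- function(g, table = g$table) {
  vindex <- build_vertex_index(g)
  v <- table$vectors
  split_keys <- paste(v$read, v$frag)
  lapply(split(v, factor(split_keys, levels = unique(split_keys))),
         map_read_to_unitigs, g = g, vindex = vindex)
}

# ---- disentangling ----------------------------------------------------------

# spanning triplet counts for every center unitig: data.table(center, a, b, n)
# where a -> center -> b is counted in the +center frame
triplet_counts <- function(paths) {
  rows <- list()
  for (p in paths) {
    if (is.null(p) || length(p) < 3L) next
    for (i in 2L:(length(p) - 1L)) {
      u <- p[i]
      if (u > 0L) rows[[length(rows) + 1L]] <- c(u, p[i - 1L], p[i + 1L])
      else rows[[length(rows) + 1L]] <- c(-u, -p[i + 1L], -p[i - 1L])
    }
  }
  if (length(rows) == 0L)
    return(data.table(center = integer(), a = integer(), b = integer(),
                      n = integer()))
  m <- do.call(rbind, rows)
  dt <- data.table(center = m[, 1], a = m[, 2], b = m[, 3])
  dt[, list(n = .N), by = c("center", "a", "b")]
}

#' Disentangle a unitig graph using read-phased spanning triplets
#'
#' For each center node, the number of reads supporting each spanning triplet
#' (incoming node, center, outgoing node) is counted. A triplet is dominated
#' if its count is below `lambda` times the maximum of both its row and its
#' column of the triplet matrix. A node with at least one dominated triplet
#' is resolved: one copy of the center is created per non-dominated triplet,
#' wired to exactly that in/out pair, and the original center removed.
#' Rounds repeat (reads are remapped each round) until the structure
#' converges or `max_rounds` is reached.
#'
#' @param g a `unitig_graph` (with `table` attached for read remapping).
#' @param lambda domination threshold in (0, 1].
#' @param max_rounds hard cap on resolution rounds.
#' @return the disentangled `unitig_graph`.
#' @export
disentangle <- function(g, lambda = 0.1, max_rounds = 16L) {
  stopifnot(lambda > 0, lambda <= 1)
  for (round in seq_len(max_rounds)) {
    paths <- map_reads(g)
    tc <- triplet_counts(paths)
    if (nrow(tc) == 0L) break
    resolved_any <- FALSE
    touched <- integer(0)
    for (u in sort(unique(tc$center))) {
      tu <- tc[tc$center == u]
      # full matrix over observed in/out neighbours plus structural ones
      ins <- g$edges[g$edges$to == u]$from
      outs <- g$edges[g$edges$from == u]$to
      if (length(ins) == 0L || length(outs) == 0L) next
      if (u %in% abs(c(ins, outs))) next  # self-adjacent centers not handled
      if (u %in% touched || any(abs(c(ins, outs)) %in% touched)) next
      x <- matrix(0, length(ins), length(outs),
                  dimnames = list(as.character(ins), as.character(outs)))
      for (r in seq_len(nrow(tu))) {
        ia <- match(tu$a[r], ins); ib <- match(tu$b[r], outs)
        if (!is.na(ia) && !is.na(ib)) x[ia, ib] <- tu$n[r]
      }
      if (all(x == 0)) next
      colmax <- apply(x, 2, max); rowmax <- apply(x, 1, max)
      dominated <- x / rep(colmax, each = nrow(x)) < lambda &
        x / rowmax < lambda
      dominated[is.na(dominated)] <- FALSE
      if (!any(dominated)) next
      nondom <- which(!dominated, arr.ind = TRUE)
      g <- resolve_center(g, u, ins[nondom[, 1]], outs[nondom[, 2]],
                          x[nondom])
      touched <- c(touched, u, abs(ins), abs(outs))
      resolved_any <- TRUE
    }
    if (!resolved_any) break
    g <- compact_unitig_graph(g)
  }
  g$comp <- unitig_components(g)
  g
}

# replace center u by one copy per (a_i, b_i) context pair; the original
# coverage is split across the copies in proportion to their read support
resolve_center <- function(g, u, as_, bs, wts = rep(1, length(as_))) {
  eu <- g$edges
  share <- if (sum(wts) > 0) wts / sum(wts) else rep(1 / length(wts), length(wts))
  for (i in seq_along(as_)) {
    a <- as_[i]; b <- bs[i]
    nid <- length(g$name) + 1L
    g$name <- c(g$name, sprintf("utg%06d", nid))
    g$seq <- c(g$seq, g$seq[u]); g$len <- c(g$len, g$len[u])
    g$cov <- c(g$cov, g$cov[u] * share[i]); g$circular <- c(g$circular, FALSE)
    g$hoco <- c(g$hoco, g$hoco[u]); g$runs <- c(g$runs, g$runs[u])
    g$vpath <- c(g$vpath, g$vpath[u])
    oa <- eu[eu$from == a & eu$to == u]
    ob <- eu[eu$from == u & eu$to == b]
    newe <- data.table(from = c(a, -nid, nid, -b),
                       to = c(nid, -a, b, -nid),
                       ovl = c(oa$ovl[1], oa$ovl[1], ob$ovl[1], ob$ovl[1]),
                       cov = c(oa$cov[1], oa$cov[1], ob$cov[1], ob$cov[1]))
    g$edges <- rbind(g$edges, newe)
  }
  g$edges <- g$edges[abs(g$edges$from) != u & abs(g$edges$to) != u]
  g$dead <- c(g$dead %||% integer(0), u)
  g
}

# drop dead unitigs and renumber
compact_unitig_graph <- function(g) {
  dead <- g$dead %||% integer(0)
  if (length(dead) == 0L) { g$comp <- unitig_components(g); return(g) }
  keep <- setdiff(seq_along(g$name), dead)
  remap <- integer(length(g$name)); remap[keep] <- seq_along(keep)
  g$name <- sprintf("utg%06d", seq_along(keep))
  g$seq <- g$seq[keep]; g$len <- g$len[keep]; g$cov <- g$cov[keep]
  g$circular <- g$circular[keep]; g$hoco <- g$hoco[keep]
  g$runs <- g$runs[keep]; g$vpath <- g$vpath[keep]
  sgn <- function(v) as.integer(sign(v) * remap[abs(v)])
  g$edges <- data.table(from = sgn(g$edges$from), to = sgn(g$edges$to),
                        ovl = g$edges$ovl, cov = g$edges$cov)
  g$dead <- NULL
  g$comp <- unitig_components(g)
  g
}

#' Discard debris components
#'
#' Removes connected components whose total sequence length is below
#' `min_bp` (default 10 kb).
#'
#' @param g a `unitig_graph`.
#' @param min_bp minimum component size in bp.
#' @return the filtered graph.
#' @export
drop_debris <- function(g, min_bp = 10000L) {
  tot <- tapply(g$len, g$comp, sum)
  bad_comps <- as.integer(names(tot)[tot < min_bp])
  if (length(bad_comps) == 0L) return(g)
  g$dead <- which(g$comp %in% bad_comps)
  compact_unitig_graph(g)
}
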