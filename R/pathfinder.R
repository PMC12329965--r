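# Resolution of an organelle graph component into a primary sequence.
#
# The stages are: EM estimation of per-unitig copy numbers from depth and
# length; exhaustive enumeration of canonical maximal walks over the
# copy-expanded graph; selection of the primary path (longest, with a 90%
# preference for circular over linear and a read-support tie-break); for
# plastomes, choice of the single-copy orientation by Spearman correlation
# of gene order against a packaged reference order, and rotation to the psbA
# start; and, when the first round is non-circular, an integer edge-visit
# optimisation (brute force or simulated annealing) feeding a second round.

#' Estimate unitig copy numbers by EM
#'
#' Alternates the average base coverage `dbar = sum(l*d)/sum(l*c)` with the
#' copy-number update `c = round(d/dbar)` (at least 1) until the copy
#' numbers are stable.
#'
#' @param lens unitig lengths (bp).
#' @param depths unitig sequence depths.
#' @param max_iter iteration cap.
#' @return list with `copy` (integer), `dbar`, `iterations`.
#' @export
estimate_copy_numbers <- function(lens, depths, max_iter = 1000L) {
  stopifnot(length(lens) == length(depths), all(lens > 0), all(depths > 0))
  dmin <- min(depths)
  cz <- pmax(1L, as.integer(round_half_up(depths / dmin)))
  for (it in seq_len(max_iter)) {
    dbar <- sum(lens * depths) / sum(lens * cz)
    cz2 <- pmax(1L, as.integer(round_half_up(depths / dbar)))
    if (all(cz2 == cz)) {
      return(list(copy = cz, dbar = sum(lens * depths) / sum(lens * cz),
                  iterations = it))
    }
    cz <- cz2
  }
  stop("copy-number EM did not converge after ", max_iter, " iterations; ",
       "depths: ", paste(round(depths, 1), collapse = ","))
}

# ---- canonical path keys ----------------------------------------------------

path_key_linear <- function(p) {
  a <- paste(p, collapse = ",")
  b <- paste(rev(-p), collapse = ",")
  min(a, b)
}

path_key_circular <- function(p) {
  best <- NULL
  for (q in list(p, rev(-p))) {
    n <- length(q)
    for (i in seq_len(n)) {
      r <- paste(c(q[i:n], q[seq_len(i - 1L)]), collapse = ",")
      if (is.null(best) || r < best) best <- r
    }
  }
  best
}

# ---- enumeration ------------------------------------------------------------

#' Enumerate candidate paths of a graph component
#'
#' Expands multi-copy nodes into copies and enumerates all maximal walks by
#' depth-first search, visiting each expanded node at most once. Equivalent
#' walks under rotation, reversal and permutation of copies are examined only
#' once (copies are consumed in order; walks are deduplicated by a canonical
#' key with copy labels erased). A walk whose last node connects back to its
#' first is recorded as circular. Only the longest circular and longest
#' linear walks are retained.
#'
#' @param g a `unitig_graph`.
#' @param comp component id to resolve.
#' @param model copy-number model from [estimate_copy_numbers()] for the
#'   component's unitigs (in component order), or NULL to estimate here.
#' @param edge_caps optional named vector of visit caps per canonical edge
#'   key (second-round constraint).
#' @param copies optional explicit per-unitig copy numbers overriding the
#'   model.
#' @param max_expanded cap on the number of expanded nodes.
#' @param max_states cap on DFS states explored.
#' @return list of candidates, each `list(path, circular, length, key)`;
#'   `path` uses signed unitig ids with copy labels erased.
#' @export
enumerate_candidate_paths <- function(g, comp, model = NULL, edge_caps = NULL,
                                      copies = NULL, max_expanded = 64L,
                                      max_states = 1e7) {
  nodes <- which(g$comp == comp)
  if (length(nodes) == 0L) stop("empty component ", comp)
  if (is.null(copies)) {
    if (is.null(model))
      model <- estimate_copy_numbers(g$len[nodes], g$cov[nodes])
    copies <- model$copy
  }
  stopifnot(length(copies) == length(nodes))
  if (sum(copies) > max_expanded)
    stop("expanded graph has ", sum(copies), " nodes (cap ", max_expanded,
         "); raise the coverage filter or the cap")
  cz <- setNames(as.integer(copies), nodes)
  edges <- g$edges[abs(g$edges$from) %in% nodes]
  ekeys <- canonical_edge_keys(edges)
  adj <- split(seq_len(nrow(edges)), edges$from)

  # single circular unitig component
  if (length(nodes) == 1L && g$circular[nodes]) {
    p <- nodes
    return(list(list(path = p, circular = TRUE, length = g$len[nodes],
                     key = path_key_circular(p))))
  }

  env <- new.env(parent = emptyenv())
  env$seen <- new.env(parent = emptyenv())
  env$cands <- list()
  env$states <- 0L

  edge_between <- function(a, b) {
    ix <- adj[[as.character(a)]]
    if (is.null(ix)) return(NA_integer_)
    ix[edges$to[ix] == b][1]
  }

  record <- function(path, used_edges) {
    # circular iff an edge from the last to the first node remains available
    n <- length(path)
    closing <- edge_between(path[n], path[1])
    circular <- !is.na(closing) && cap_ok(closing, used_edges)
    len <- sum(g$len[abs(path)])
    if (n > 1L) {
      for (i in 2L:n) {
        e <- edge_between(path[i - 1L], path[i])
        len <- len - edges$ovl[e]
      }
    }
    if (circular) len <- len - edges$ovl[closing]
    key <- if (circular) path_key_circular(path) else path_key_linear(path)
    key <- paste0(if (circular) "c:" else "l:", key)
    if (!is.null(env$seen[[key]])) return(invisible())
    env$seen[[key]] <- TRUE
    env$cands[[length(env$cands) + 1L]] <-
      list(path = path, circular = circular, length = len, key = key)
  }

  cap_ok <- function(eidx, used_edges) {
    if (is.null(edge_caps)) return(TRUE)
    k <- ekeys[eidx]
    cap <- edge_caps[k]
    if (is.na(cap)) cap <- 0L
    used <- used_edges[k]
    if (is.na(used)) used <- 0L
    used < cap
  }

  dfs <- function(cur, used_copies, path, used_edges) {
    env$states <- env$states + 1L
    if (env$states > max_states) stop("path enumeration exceeded state cap")
    ext <- FALSE
    ix <- adj[[as.character(cur)]]
    if (!is.null(ix)) {
      for (e in ix) {
        b <- edges$to[e]
        z <- abs(b)
        uc <- used_copies[as.character(z)]
        if (is.na(uc)) uc <- 0L
        if (uc >= cz[as.character(z)]) next
        if (!cap_ok(e, used_edges)) next
        ext <- TRUE
        uc2 <- used_copies
        uc2[as.character(z)] <- uc + 1L
        ue2 <- used_edges
        k <- ekeys[e]
        ue2[k] <- (if (is.na(ue2[k])) 0L else ue2[k]) + 1L
        dfs(b, uc2, c(path, b), ue2)
      }
    }
    if (!ext) record(path, used_edges)
  }

  for (sz in c(nodes, -nodes)) {
    uc <- setNames(integer(length(nodes)), nodes)
    uc[as.character(abs(sz))] <- 1L
    dfs(sz, uc, sz, setNames(integer(0), character(0)))
  }

  cands <- env$cands
  if (length(cands) == 0L) return(cands)
  circ <- vapply(cands, `[[`, logical(1), "circular")
  lens <- vapply(cands, `[[`, numeric(1), "length")
  keep <- logical(length(cands))
  if (any(circ)) keep[circ & lens == max(lens[circ])] <- TRUE
  if (any(!circ)) keep[!circ & lens == max(lens[!circ])] <- TRUE
  cands[keep]
}

# ---- selection --------------------------------------------------------------

# data.table of adjacent signed-unitig pairs across all mapped reads
read_pair_counts <- function(read_paths) {
  rows <- list()
  for (p in read_paths) {
    if (is.null(p) || length(p) < 2L) next
    rows[[length(rows) + 1L]] <- cbind(p[-length(p)], p[-1L])
  }
  if (length(rows) == 0L) {
    dt0 <- data.table(from = integer(), to = integer(), n = integer())
    setkeyv(dt0, c("from", "to"))
    return(dt0)
  }
  m <- do.call(rbind, rows)
  dt <- data.table(from = m[, 1], to = m[, 2])
  dt <- dt[, list(n = .N), by = c("from", "to")]
  setkeyv(dt, c("from", "to"))
  dt
}

# total reads spanning the junctions of a path (both directions summed)
junction_support <- function(path, circular, pair_counts) {
  if (length(path) < 2L && !circular) return(0L)
  a <- path
  b <- c(path[-1L], if (circular) path[1])
  a <- a[seq_along(b)]
  n1 <- pair_counts[list(a, b)]$n
  n2 <- pair_counts[list(-b, -a)]$n
  sum(n1, na.rm = TRUE) + sum(n2, na.rm = TRUE)
}

#' Select the primary path among candidates
#'
#' The longest path wins; a circular path is preferred over a longer linear
#' one when it covers at least `circular_preference` (default 90%) of the
#' linear length. Equal-length candidates are tie-broken by the total number
#' of reads spanning their node junctions.
#'
#' @param candidates list from [enumerate_candidate_paths()].
#' @param read_paths mapped read paths from [map_reads()] (for support).
#' @param circular_preference circular-over-linear length fraction.
#' @return the winning candidate with `support` attached.
#' @export
select_primary_path <- function(candidates, read_paths = list(),
                                circular_preference = 0.9) {
  stopifnot(length(candidates) > 0L)
  circ <- vapply(candidates, `[[`, logical(1), "circular")
  lens <- vapply(candidates, `[[`, numeric(1), "length")
  use_circ <- any(circ) &&
    (!any(!circ) || max(lens[circ]) >= circular_preference * max(lens[!circ]))
  pool <- which(circ == use_circ & lens == max(lens[circ == use_circ]))
  pc <- read_pair_counts(read_paths)
  sup <- vapply(pool, function(i)
    junction_support(candidates[[i]]$path, candidates[[i]]$circular, pc),
    numeric(1))
  keys <- vapply(pool, function(i) candidates[[i]]$key, character(1))
  win <- pool[order(-sup, keys)][1]
  out <- candidates[[win]]
  out$support <- sup[match(win, pool)]
  out
}

# ---- edge-visit optimisation ------------------------------------------------

#' Optimise integer edge-visit counts for a component
#'
#' Minimises `sum_z (|c_z - t_{z-}|/2 + |c_z - t_{z+}|/2 + |t_{z-} - t_{z+}|)
#' log(l_z)` over integer visits per (complement-deduplicated) edge, each
#' bounded by `[min(c_i,c_j)-3, max(c_i,c_j)+3]` (and at least 0). Brute
#' force when the solution space is at most `brute_limit`, otherwise
#' simulated annealing with a fixed seed.
#'
#' @param g a `unitig_graph`.
#' @param comp component id.
#' @param model copy-number model for the component.
#' @param brute_limit maximum solution-space size for brute force.
#' @param sa_seed seed for the annealing RNG.
#' @return list with `edges` (data.table `from`, `to`, `lo`, `hi`, `t`,
#'   `ekey`), `objective`, `method`, and per-node `tin`/`tout`.
#' @export
optimize_edge_visits <- function(g, comp, model = NULL, brute_limit = 1e8,
                                 sa_seed = 42L) {
  nodes <- which(g$comp == comp)
  if (is.null(model)) model <- estimate_copy_numbers(g$len[nodes], g$cov[nodes])
  cz <- setNames(model$copy, nodes)
  e <- g$edges[abs(g$edges$from) %in% nodes & abs(g$edges$to) %in% nodes]
  if (nrow(e) == 0L) stop("component ", comp, " has no edges")
  key <- canonical_edge_keys(e)
  keep <- !duplicated(key)
  e <- e[keep]; key <- key[keep]
  zidx <- function(z) match(z, nodes)
  # side ids: 2i-1 = in side, 2i = out side of the i-th component node.
  # An edge leaving +z exits z's out side; leaving -z exits z's in side.
  side_of_source <- function(v) 2L * zidx(abs(v)) - as.integer(v < 0L)
  side_of_target <- function(v) 2L * zidx(abs(v)) - as.integer(v > 0L)
  sa <- vapply(e$from, side_of_source, integer(1))
  sb <- vapply(e$to, side_of_target, integer(1))
  ci <- cz[as.character(abs(e$from))]
  cj <- cz[as.character(abs(e$to))]
  lo <- pmax(0L, pmin(ci, cj) - 3L)
  hi <- pmax(ci, cj) + 3L
  space <- prod(as.numeric(hi - lo + 1L))
  wz <- log(g$len[nodes])
  czv <- as.numeric(cz)

  objective <- function(t) {
    tin <- numeric(length(nodes)); tout <- numeric(length(nodes))
    for (i in seq_along(t)) {
      if (sa[i] %% 2L == 1L) tin[(sa[i] + 1L) %/% 2L] <- tin[(sa[i] + 1L) %/% 2L] + t[i]
      else tout[sa[i] %/% 2L] <- tout[sa[i] %/% 2L] + t[i]
      if (sb[i] %% 2L == 1L) tin[(sb[i] + 1L) %/% 2L] <- tin[(sb[i] + 1L) %/% 2L] + t[i]
      else tout[sb[i] %/% 2L] <- tout[sb[i] %/% 2L] + t[i]
    }
    sum((abs(czv - tin) / 2 + abs(czv - tout) / 2 + abs(tin - tout)) * wz)
  }

  if (space <= brute_limit) {
    res <- cpp_bf_edge_visits(as.integer(lo), as.integer(hi),
                              as.integer(sa), as.integer(sb), czv, wz)
    t <- res$t; obj <- res$objective; method <- "brute_force"
  } else {
    t <- pmin(pmax(pmin(ci, cj), lo), hi)
    obj <- objective(t)
    best_t <- t; best_obj <- obj
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(sa_seed)
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    temp <- 10
    while (temp > 0.01) {
      for (rep in seq_len(200L)) {
        i <- sample.int(length(t), 1L)
        delta <- sample(c(-1L, 1L), 1L)
        nt <- t[i] + delta
        if (nt < lo[i] || nt > hi[i]) next
        t2 <- t; t2[i] <- nt
        obj2 <- objective(t2)
        if (obj2 <= obj || runif(1) < exp((obj - obj2) / temp)) {
          t <- t2; obj <- obj2
          if (obj < best_obj) { best_obj <- obj; best_t <- t }
        }
      }
      temp <- temp * 0.95
    }
    t <- best_t; obj <- best_obj; method <- "simulated_annealing"
  }
  tin <- numeric(length(nodes)); tout <- numeric(length(nodes))
  for (i in seq_along(t)) {
    for (s in c(sa[i], sb[i])) {
      if (s %% 2L == 1L) tin[(s + 1L) %/% 2L] <- tin[(s + 1L) %/% 2L] + t[i]
      else tout[s %/% 2L] <- tout[s %/% 2L] + t[i]
    }
  }
  list(edges = data.table(from = e$from, to = e$to, lo = lo, hi = hi,
                          t = as.integer(t), ekey = key),
       objective = obj, method = method,
       nodes = nodes, tin = tin, tout = tout)
}

# ---- sequence construction --------------------------------------------------

# expanded sequence of a walk, dropping each incoming overlap (and, for a
# circular walk, the wrap-around overlap at the first node); also returns the
# uncompressed start offset of each visit
path_to_sequence <- function(g, path, circular) {
  if (length(path) == 1L && g$circular[abs(path[1])]) {
    return(list(seq = oriented_seq(g, path[1]), offsets = 0L))
  }
  e <- g$edges
  setkeyv(e, c("from", "to"))
  ovl_in <- integer(length(path))
  if (length(path) > 1L)
    for (i in 2L:length(path))
      ovl_in[i] <- e[list(path[i - 1L], path[i])]$ovl[1]
  if (circular) ovl_in[1] <- e[list(path[length(path)], path[1])]$ovl[1]
  pieces <- character(length(path))
  offsets <- integer(length(path))
  utrim <- integer(length(path))  # uncompressed bp trimmed from each visit
  off <- 0L
  for (i in seq_along(path)) {
    b <- oriented_hoco(g, path[i])
    r <- oriented_runs(g, path[i])
    o <- ovl_in[i]
    if (o > 0L) {
      utrim[i] <- sum(r[seq_len(o)])
      b <- substr(b, o + 1L, nchar(b))
      r <- r[-seq_len(o)]
    }
    pieces[i] <- cpp_expand_runs(b, r)
    offsets[i] <- off
    off <- off + nchar(pieces[i])
  }
  list(seq = paste(pieces, collapse = ""), offsets = offsets,
       trimmed = ovl_in, utrim = utrim)
}

# ---- plastome orientation and rotation --------------------------------------

#' Packaged reference plastid gene order
#'
#' The order of 71 plastid protein-coding genes around a reference
#' angiosperm plastome (LSC from psbA, then SSC, then IRb genes), used to
#' pick between the two single-copy orientations of a quadripartite
#' assembly.
#'
#' @return character vector of gene names in reference order.
#' @export
plastid_gene_order <- function() {
  readLines(system.file("extdata", "plastid_gene_order.txt",
                        package = "syntig"))
}

# gene positions along a candidate path: data.frame(gene, pos, strand)
path_gene_positions <- function(g, cand, hits) {
  ps <- path_to_sequence(g, cand$path, cand$circular)
  rows <- list()
  for (i in seq_along(cand$path)) {
    su <- cand$path[i]
    h <- hits[hits$target_id == g$name[abs(su)], , drop = FALSE]
    if (nrow(h) == 0L) next
    L <- g$len[abs(su)]
    total <- nchar(ps$seq)
    if (su > 0L) {
      pos <- ps$offsets[i] + h$start - ps$utrim[i]
      strand <- h$strand
    } else {
      pos <- ps$offsets[i] + (L - h$end + 1L) - ps$utrim[i]
      strand <- ifelse(h$strand == "+", "-", "+")
    }
    pos <- ((pos - 1L) %% total) + 1L
    rows[[length(rows) + 1L]] <- data.frame(gene = h$gene, pos = pos,
                                            strand = strand,
                                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(gene = character(), pos = numeric(), strand = character()))
  do.call(rbind, rows)
}

#' Orient and rotate a circular plastome
#'
#' Chooses, among candidate circular conformations, the one whose gene order
#' correlates best (Spearman) with the packaged reference order, then
#' rotates the sequence (flipping strand if necessary) so it begins with the
#' start of the psbA gene.
#'
#' @param g a `unitig_graph`.
#' @param candidates list of circular candidates (from enumeration /
#'   selection); typically the two quadripartite conformations.
#' @param hits significant plastid hits on the component's unitigs.
#' @param ref_genes reference gene order (default [plastid_gene_order()]).
#' @return list with `seq` (rotated DNA), `candidate`, `rho` (the winning
#'   Spearman coefficient), `rotated` (logical).
#' @export
orient_and_rotate_plastome <- function(g, candidates, hits,
                                       ref_genes = plastid_gene_order()) {
  stopifnot(length(candidates) >= 1L)
  hits <- hits[hits$organelle == "plastid", , drop = FALSE]
  # a conformation can be read on either strand; evaluate both readings
  candidates <- c(candidates, lapply(candidates, function(cc) {
    cc$path <- rev(-cc$path)
    cc
  }))
  rho <- rep(NA_real_, length(candidates))
  gps <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    gp <- path_gene_positions(g, candidates[[i]], hits)
    gp <- gp[order(gp$pos), , drop = FALSE]
    gp <- gp[!duplicated(gp$gene), , drop = FALSE]
    gps[[i]] <- gp
    shared <- gp$gene[gp$gene %in% ref_genes]
    if (length(shared) < 2L) next
    refrank <- match(shared, ref_genes)
    # rotate the circular observed order to start at the gene with the
    # smallest reference rank, so the correlation is rotation-invariant
    start <- which.min(refrank)
    obs <- c(shared[start:length(shared)], shared[seq_len(start - 1L)])
    obsrank <- match(shared, obs)
    rho[i] <- suppressWarnings(cor(refrank, obsrank, method = "spearman"))
  }
  win <- if (all(is.na(rho))) 1L else which.max(rho)
  cand <- candidates[[win]]
  ps <- path_to_sequence(g, cand$path, cand$circular)
  seq <- ps$seq
  gp <- path_gene_positions(g, cand, hits)
  psba <- gp[gp$gene == "psbA", , drop = FALSE]
  rotated <- FALSE
  if (nrow(psba)) {
    p <- psba[which.min(psba$pos), ]
    if (p$strand == "-") {
      # put psbA on the forward strand; its start becomes L - old_pos + 1
      # only approximately without the gene length, so flip first and
      # re-derive from the flipped coordinates of the hit end
      h <- hits[hits$gene == "psbA", , drop = FALSE][1, ]
      glen <- h$end - h$start + 1L
      seq <- revcomp(seq)
      newstart <- nchar(seq) - (p$pos + glen - 1L) + 1L
      seq <- rotate_seq(seq, ((newstart - 1L) %% nchar(seq)) + 1L)
    } else {
      seq <- rotate_seq(seq, ((p$pos - 1L) %% nchar(seq)) + 1L)
    }
    rotated <- TRUE
  } else {
    warning("psbA not found among hits; rotation skipped")
  }
  list(seq = seq, candidate = cand, rho = rho[win], rotated = rotated,
       rho_all = rho)
}

# ---- quadripartite structure ------------------------------------------------

#' Detect the quadripartite structure of a circular sequence
#'
#' Finds the inverted-repeat pair by exact 31-mer reverse-complement
#' self-matching with seed chaining: collinear seed matches within a
#' Manhattan distance of `merge_gap` are merged, merged segments must reach
#' `min_identity` (seed-covered fraction), and the largest segment pair
#' gives IRa/IRb. The flanking regions are labelled LSC (larger) and SSC
#' (smaller). Detection is run on two rotations of the circle so that IRs
#' straddling the origin are still found.
#'
#' @param seq circular DNA sequence.
#' @param min_identity minimum identity of a merged segment.
#' @param merge_gap maximum endpoint distance for merging alignments (bp).
#' @param min_ir minimum IR length (bp) to call a quadripartite structure.
#' @return list with `classification` (`"quadripartite"` or `"IR-lacking"`),
#'   and for quadripartite: `lsc`, `ira`, `ssc`, `irb` (0-based half-open
#'   `[start,end)` intervals on the input circle, possibly wrapping),
#'   `ir_len`, `identity`.
#' @export
detect_quadripartite <- function(seq, min_identity = 0.95, merge_gap = 50L,
                                 min_ir = 1000L) {
  L <- nchar(seq)
  best <- NULL
  for (shift in unique(c(0L, L %/% 2L))) {
    s <- if (shift == 0L) seq else rotate_seq(seq, shift + 1L)
    hit <- find_largest_ir(s, min_identity, merge_gap)
    if (is.null(hit)) next
    if (is.null(best) || hit$len > best$len) { best <- hit; best$shift <- shift }
  }
  if (is.null(best) || best$len < min_ir)
    return(list(classification = "IR-lacking"))
  un <- function(x) (x + best$shift) %% L  # back to input coordinates
  a0 <- un(best$a[1]); a1 <- a0 + best$len
  b0 <- un(best$b[1]); b1 <- b0 + best$len
  # flanks on the circle: from end of one IR to start of the other
  gap1 <- (b0 - a1) %% L
  gap2 <- (a0 - b1) %% L
  # IRa is the repeat immediately following the LSC (LSC-IRa-SSC-IRb order)
  if (gap1 >= gap2) {
    lsc <- c(a1 %% L, gap1); ssc <- c(b1 %% L, gap2)
    ira <- c(b0, best$len); irb <- c(a0, best$len)
  } else {
    lsc <- c(b1 %% L, gap2); ssc <- c(a1 %% L, gap1)
    ira <- c(a0, best$len); irb <- c(b0, best$len)
  }
  iv <- function(x) c(start = x[1], end = x[1] + x[2])
  list(classification = "quadripartite",
       lsc = iv(lsc), ira = iv(ira), ssc = iv(ssc), irb = iv(irb),
       ir_len = best$len, identity = best$identity)
}

# total length covered by the union of intervals [x, x + w)
interval_coverage <- function(starts, w) {
  s <- sort(unique(starts))
  gaps <- diff(s)
  sum(pmin(gaps, w)) + w
}

# largest merged reverse-complement self-match of a linear string; intervals
# 0-based [start,len]
find_largest_ir <- function(s, min_identity, merge_gap, w = 31L) {
  L <- nchar(s)
  if (L < 2L * w) return(NULL)
  km <- substring(s, 1:(L - w + 1L), w:L)
  rs <- revcomp(s)
  kmr <- substring(rs, 1:(L - w + 1L), w:L)
  d1 <- data.table(kmer = km, i = 0:(L - w))
  d2 <- data.table(kmer = kmr, j = 0:(L - w))
  mm <- merge(d1, d2, by = "kmer", allow.cartesian = TRUE)
  if (nrow(mm) == 0L) return(NULL)
  # match: s[i, i+w) == revcomp of s[bi, bi+w) with bi = L - j - w
  mm$bi <- L - mm$j - w
  mm <- mm[mm$i < mm$bi]  # one of the two symmetric reports; keep i < bi
  if (nrow(mm) == 0L) return(NULL)
  mm$diag <- mm$i + mm$bi
  mm <- mm[order(mm$diag, mm$i)]
  # cluster seeds on nearby antidiagonals
  cl <- integer(nrow(mm))
  ncl <- 0L
  last_diag <- -Inf; last_i <- -Inf
  for (r in seq_len(nrow(mm))) {
    if (mm$diag[r] - last_diag > merge_gap ||
        (mm$diag[r] == last_diag && mm$i[r] - last_i > merge_gap + w)) {
      ncl <- ncl + 1L
    }
    cl[r] <- ncl
    last_diag <- mm$diag[r]; last_i <- mm$i[r]
  }
  mm$cl <- cl
  agg <- mm[, list(a0 = min(i), a1 = max(i) + w, b0 = min(bi), b1 = max(bi) + w,
                   cov = interval_coverage(i, w)),
            by = "cl"]
  agg$len <- agg$a1 - agg$a0
  agg$identity <- agg$cov / agg$len
  agg <- agg[agg$identity >= min_identity & agg$b0 >= agg$a1]
  if (nrow(agg) == 0L) return(NULL)
  topr <- agg[order(-agg$len)][1]
  list(a = c(topr$a0, topr$a1), b = c(topr$b0, topr$b1), len = topr$len,
       identity = topr$identity)
}

# ---- flip-flop recombination support ----------------------------------------

# count reads whose mapped path fully covers `target` (contiguously, in
# either direction)
count_path_support <- function(read_paths, target) {
  rc <- rev(-target)
  m <- length(target)
  n <- 0L
  for (p in read_paths) {
    if (is.null(p) || length(p) < m) next
    hit <- FALSE
    for (i in seq_len(length(p) - m + 1L)) {
      seg <- p[i:(i + m - 1L)]
      if (all(seg == target) || all(seg == rc)) { hit <- TRUE; break }
    }
    if (hit) n <- n + 1L
  }
  n
}

#' Read support for the two flip-flop forms of a quadripartite genome
#'
#' Given the primary circular path of a quadripartite component (the repeat
#' node visited twice), counts reads whose mapped path fully covers the
#' IR-through triplet of each structural form, and tests the counts against
#' a binomial with probability 0.5.
#'
#' @param g a `unitig_graph`.
#' @param read_paths mapped read paths from [map_reads()].
#' @param solution the selected circular candidate (its `path` must visit
#'   one repeat unitig twice).
#' @return list with `n_form1`, `n_form2`, `p_value` (`NA` when no read
#'   spans an IR).
#' @export
flipflop_support <- function(g, read_paths, solution) {
  p <- solution$path
  z <- abs(p)
  rep_z <- unique(z[duplicated(z)])
  if (length(rep_z) != 1L)
    stop("expected exactly one repeat unitig in the path; found ",
         length(rep_z))
  n <- length(p)
  at <- which(z == rep_z)
  nb <- function(i) p[(i %% n) + 1L]        # successor (wraps)
  pv <- function(i) p[((i - 2L) %% n) + 1L] # predecessor (wraps)
  t1a <- c(pv(at[1]), p[at[1]], nb(at[1]))
  t1b <- c(pv(at[2]), p[at[2]], nb(at[2]))
  # the recombined form swaps the two IR exits
  t2a <- c(pv(at[1]), p[at[1]], -pv(at[2]))
  t2b <- c(-nb(at[1]), p[at[2]], nb(at[2]))
  n1 <- count_path_support(read_paths, t1a) + count_path_support(read_paths, t1b)
  n2 <- count_path_support(read_paths, t2a) + count_path_support(read_paths, t2b)
  if (n1 + n2 == 0L)
    return(list(n_form1 = 0L, n_form2 = 0L, p_value = NA_real_))
  list(n_form1 = n1, n_form2 = n2,
       p_value = binom.test(n1, n1 + n2, 0.5)$p.value)
}
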