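# Syncmer error correction.
#
# Syncmers with table frequency below a threshold theta are treated as likely
# sequencing errors. Maximal runs of such error syncmers on a read form error
# blocks; each block (with its flanking trusted boundary syncmers) delineates
# a hoco subsequence xi which is re-threaded through the trimmed graph G'
# (the k-mer graph with error vertices removed) by a depth-first search. Path
# prefixes are scored with a banded prefix edit distance; a correction is
# accepted when the best path's distance is within the budget eps*l and beats
# the second-best distinct path by the ambiguity factor omega.

#' Error-correction parameters
#'
#' @param theta frequency threshold below which a syncmer is a potential
#'   error.
#' @param epsilon edit budget per base; the distance limit for a block of
#'   length l is `epsilon * l`. Should reflect the base accuracy of the data.
#' @param tau maximum number of completed depth searches per block.
#' @param omega ambiguity ratio; the best path must satisfy e < omega *
#'   second-best.
#' @return a `correction_params` list.
#' @export
correction_params <- function(theta = 3L, epsilon = 0.01, tau = 10000L,
                              omega = 0.7) {
  stopifnot(theta >= 1L, epsilon > 0, epsilon < 1, omega > 0, omega <= 1)
  structure(list(theta = as.integer(theta), epsilon = epsilon,
                 tau = as.integer(tau), omega = omega),
            class = "correction_params")
}

#' Find error blocks on a read's syncmer vector
#'
#' @param vec data.table of one read's syncmer vector rows (columns `frag`,
#'   `index`, `pos`, `orient`, ordered by position).
#' @param table the `syncmer_table` (current frequencies).
#' @param params a [correction_params()] object.
#' @return list of blocks; each has `frag`, `rows` (row numbers of the error
#'   run within `vec`), `left`/`right` (boundary row numbers or `NA`) and
#'   `excluded` (no boundary at all).
#' @export
find_error_blocks <- function(vec, table, params) {
  blocks <- list()
  err <- table$freq[vec$index] < params$theta
  for (f in unique(vec$frag)) {
    rows <- which(vec$frag == f)
    e <- err[rows]
    if (!any(e)) next
    r <- rle(e)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      a <- starts[j]; b <- ends[j]
      blocks[[length(blocks) + 1L]] <- list(
        frag = f,
        rows = rows[a:b],
        left = if (a > 1L) rows[a - 1L] else NA_integer_,
        right = if (b < length(rows)) rows[b + 1L] else NA_integer_,
        excluded = (a == 1L && b == length(rows)))
    }
  }
  blocks
}

# Reconstruct the hoco subsequence spanned by vector rows `rows` (the first
# row is included in full, then each subsequent k-mer adds its last
# p_{i+1}-p_i bases).
rows_subseq <- function(vec, rows, table) {
  k <- table$params$k
  s <- entry_hoco(table, vec$index[rows[1]], vec$orient[rows[1]])
  if (length(rows) > 1L) {
    for (i in 2L:length(rows)) {
      d <- vec$pos[rows[i]] - vec$pos[rows[i - 1L]]
      s <- paste0(s, substr(entry_hoco(table, vec$index[rows[i]], vec$orient[rows[i]]),
                            k - d + 1L, k))
    }
  }
  s
}

# adjacency of the trimmed graph: named list keyed by signed vertex, each a
# data.table(to, ovl, cov) in DFS child order (descending coverage, then
# vertex id)
build_adjacency <- function(edges, alive) {
  e <- edges[alive[abs(edges$from)] & alive[abs(edges$to)]]
  if (nrow(e) == 0L) return(list())
  e <- e[order(e$from, -e$cov, e$to)]
  split(e[, c("to", "ovl", "cov")], e$from)
}

#' Banded prefix edit distance
#'
#' Computes the prefix edit distance `d` between a target `xi` and query
#' `xi_n` (the minimum Levenshtein distance between `xi_n` and any prefix of
#' `xi`, i.e. ignoring trailing target bases) together with the overhang
#' length `g` of `xi`, using a diagonal band of half-width `budget`. The sum
#' `d + g` equals the full Levenshtein distance for the alignment shape in
#' which all of `xi` is consumed.
#'
#' @param target the target string xi.
#' @param query the query string.
#' @param budget band half-width (maximum trackable distance).
#' @return list with `d`, `g` and `exceeded` (`TRUE` when d > budget, in
#'   which case `d`/`g` are unreliable sentinels).
#' @export
prefix_edit_distance <- function(target, query, budget) {
  budget <- max(1L, as.integer(budget))
  l <- nchar(target)
  st <- cpp_band_init(l, budget)
  st <- cpp_band_extend(st, target, query)
  if (st$dmin > budget) return(list(d = NA_integer_, g = NA_integer_, exceeded = TRUE))
  g <- l - st$jstar
  list(d = as.integer(st$erow - g), g = as.integer(g), exceeded = FALSE)
}

# DFS over the trimmed graph to find the minimal-distance replacement path
# for one error block. Returns status plus the winning path of signed
# vertices (starting at v0, ending at vright when given).
correct_block_dfs <- function(xi, v0, vright, adj, table, params,
                              max_depth = 1000L) {
  k <- table$params$k
  l <- nchar(xi)
  epsl <- params$epsilon * l
  B <- as.integer(max(2, ceiling(epsl) + 1))
  env <- new.env(parent = emptyenv())
  env$nsearch <- 0L
  env$ehat <- Inf
  env$etilde <- Inf
  env$best <- NULL
  env$aborted <- FALSE

  eligible <- function(v) is.na(vright) || v == vright
  consider <- function(path, e) {
    if (!is.finite(e)) return(invisible())
    if (e < env$ehat) {
      if (!is.null(env$best) && !identical(env$best, path)) env$etilde <- env$ehat
      env$ehat <- e
      env$best <- path
    } else if (e < env$etilde && !identical(path, env$best)) {
      env$etilde <- e
    }
  }

  descend <- function(v, st, path) {
    if (env$aborted) return(invisible())
    # d + g semantics: a path that overshoots the target pays for the
    # overshoot, so extending past a complete match cannot tie with it
    if (eligible(v)) consider(path, st$erow)
    terminate <- st$dmin >= epsl || st$q >= (1 + params$epsilon) * l ||
      length(path) >= max_depth
    kids <- if (!terminate) adj[[as.character(v)]] else NULL
    if (is.null(kids) || nrow(kids) == 0L) {
      env$nsearch <- env$nsearch + 1L
      if (env$nsearch > params$tau) env$aborted <- TRUE
      return(invisible())
    }
    for (i in seq_len(nrow(kids))) {
      if (env$aborted) return(invisible())
      w <- kids$to[i]
      add <- substr(entry_hoco(table, abs(w), as.integer(w < 0)),
                    kids$ovl[i] + 1L, k)
      descend(w, cpp_band_extend(st, xi, add), c(path, w))
    }
  }

  st0 <- cpp_band_extend(cpp_band_init(l, B), xi,
                         entry_hoco(table, abs(v0), as.integer(v0 < 0)))
  descend(v0, st0, v0)

  if (env$aborted) return(list(status = "failed", reason = "over_tau"))
  if (!is.finite(env$ehat) || env$ehat > epsl)
    return(list(status = "failed", reason = "over_budget"))
  if (is.finite(env$etilde) && !(env$ehat < params$omega * env$etilde))
    return(list(status = "ambiguous"))
  list(status = "corrected", path = env$best, e = env$ehat)
}

# flip a signed-vertex path to its complement reading
flip_path <- function(path) rev(-path)

#' Correct the error blocks of all reads
#'
#' Applies [find_error_blocks()] and the DFS path search to every read,
#' rewriting corrected blocks in the syncmer vectors, then recomputes the
#' table frequencies from the corrected vectors. Blocks with only a right
#' boundary are corrected on the reverse complement strand; reads that are a
#' single boundary-less block are excluded.
#'
#' @param table a `syncmer_table` (with `vectors`).
#' @param params a [correction_params()] object.
#' @param graph optional prebuilt `kmer_graph` for the same table.
#' @return list with `table` (corrected vectors, recounted frequencies) and
#'   `stats` (found, corrected, ambiguous, failed, excluded).
#' @export
correct_reads <- function(table, params = correction_params(), graph = NULL) {
  if (is.null(graph)) graph <- build_kmer_graph(table)
  k <- table$params$k
  alive <- table$freq >= params$theta
  adj <- build_adjacency(graph$edges, alive)
  ekey <- graph$edges
  stats <- c(found = 0L, corrected = 0L, ambiguous = 0L, failed = 0L,
             excluded = 0L)
  vecs <- table$vectors
  out <- vector("list", length(table$read_ids))

  edge_ovl <- function(.f, .t) {
    ekey[list(.f, .t)]$ovl
  }

  for (ri in seq_along(table$read_ids)) {
    vec <- vecs[vecs$read == ri]
    if (nrow(vec) == 0L) { out[[ri]] <- vec; next }
    blocks <- find_error_blocks(vec, table, params)
    if (length(blocks) == 0L) { out[[ri]] <- vec; next }
    stats["found"] <- stats["found"] + length(blocks)
    # per-row signed vertex and distance-to-next bookkeeping
    idx <- vec$index; ori <- vec$orient; frag <- vec$frag; pos <- vec$pos
    repl <- vector("list", length(blocks))
    spans <- vector("list", length(blocks))
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      if (b$excluded) { stats["excluded"] <- stats["excluded"] + 1L; next }
      if (!is.na(b$left)) {
        # when a right boundary exists the alignment target runs through the
        # boundary k-mer, so that the required path end coincides with the
        # target end and the length stopping rule stays consistent
        rows <- c(b$left, b$rows, if (!is.na(b$right)) b$right)
        xi <- rows_subseq(vec, rows, table)
        v0 <- signed_vertex(idx[b$left], ori[b$left])
        vr <- if (!is.na(b$right)) signed_vertex(idx[b$right], ori[b$right]) else NA
        if (is.null(adj[[as.character(v0)]])) {
          stats["failed"] <- stats["failed"] + 1L; next
        }
        res <- correct_block_dfs(xi, v0, vr, adj, table, params)
        if (res$status == "corrected") {
          path <- res$path
          span <- c(b$left, b$rows, if (!is.na(b$right)) b$right)
          if (!is.na(b$right) && path[length(path)] != signed_vertex(idx[b$right], ori[b$right])) {
            stats["failed"] <- stats["failed"] + 1L; next
          }
          repl[[bi]] <- path
          spans[[bi]] <- span
          stats["corrected"] <- stats["corrected"] + 1L
        } else if (res$status == "ambiguous") {
          stats["ambiguous"] <- stats["ambiguous"] + 1L
        } else stats["failed"] <- stats["failed"] + 1L
      } else {
        # only a right boundary: solve on the reverse complement
        rows <- rev(c(b$rows, b$right))
        xi <- {
          rvec <- data.table(frag = frag[rows], index = idx[rows],
                             pos = -pos[rows], orient = 1L - ori[rows])
          rows_subseq(rvec, seq_along(rows), table)
        }
        v0 <- -signed_vertex(idx[b$right], ori[b$right])
        if (is.null(adj[[as.character(v0)]])) {
          stats["failed"] <- stats["failed"] + 1L; next
        }
        res <- correct_block_dfs(xi, v0, NA, adj, table, params)
        if (res$status == "corrected") {
          repl[[bi]] <- flip_path(res$path)
          spans[[bi]] <- c(b$rows, b$right)
          stats["corrected"] <- stats["corrected"] + 1L
        } else if (res$status == "ambiguous") {
          stats["ambiguous"] <- stats["ambiguous"] + 1L
        } else stats["failed"] <- stats["failed"] + 1L
      }
    }
    # assemble the corrected vector per fragment, then rebuild positions
    newvec <- rebuild_vector(vec, repl, spans, k, edge_ovl, ri)
    out[[ri]] <- newvec
  }
  newvecs <- rbindlist(out)
  table$vectors <- newvecs
  table <- recount_frequencies(table)
  list(table = table, stats = stats)
}

# Splice replacement paths into a read vector and recompute positions.
# Distances inside corrected spans come from graph edge overlaps (k - ovl);
# every junction between untouched rows (or to/from the original boundary
# rows that start/end a span) keeps the original inter-syncmer distance.
# Only distances matter downstream, so each fragment is re-anchored.
rebuild_vector <- function(vec, repl, spans, k, edge_ovl, read_no) {
  keep <- !vapply(repl, is.null, logical(1))
  if (!any(keep))
    return(vec[, c("read", "frag", "index", "pos", "orient")])
  n <- nrow(vec)
  blks <- which(keep)
  bptr <- 1L
  rows_out <- list()
  i <- 1L
  while (i <= n) {
    bi <- if (bptr <= length(blks)) blks[bptr] else NA_integer_
    span <- if (!is.na(bi)) spans[[bi]] else NULL
    if (!is.na(bi) && (span[1] == i || span[1] == i - 1L)) {
      path <- repl[[bi]]
      m <- length(path)
      d <- if (m > 1L) as.integer(k - edge_ovl(path[-m], path[-1L])) else integer(0)
      dist <- c(NA_integer_, d)
      orig <- c(span[1], rep(NA_integer_, max(m - 2L, 0L)), span[length(span)])[seq_len(m)]
      if (span[1] == i - 1L) {
        # shared boundary row with the previous block already emitted: the
        # first path vertex is that boundary; splice the tail only
        path <- path[-1L]; orig <- orig[-1L]; dist <- dist[-1L]
        m <- m - 1L
      }
      if (m > 0L)
        rows_out[[length(rows_out) + 1L]] <- data.table(
          frag = vec$frag[span[1]], index = abs(path),
          orient = as.integer(path < 0), dist = dist, orig = orig)
      i <- span[length(span)] + 1L
      bptr <- bptr + 1L
    } else if (!is.na(bi) && span[1] < i - 1L) {
      bptr <- bptr + 1L  # should not happen; skip defensively
    } else {
      rows_out[[length(rows_out) + 1L]] <- data.table(
        frag = vec$frag[i], index = vec$index[i], orient = vec$orient[i],
        dist = NA_integer_, orig = i)
      i <- i + 1L
    }
  }
  rr <- rbindlist(rows_out)
  m <- nrow(rr)
  pos <- integer(m)
  for (j in seq_len(m)) {
    if (j == 1L || rr$frag[j] != rr$frag[j - 1L]) {
      pos[j] <- if (!is.na(rr$orig[j])) vec$pos[rr$orig[j]] else 0L
    } else if (!is.na(rr$dist[j])) {
      pos[j] <- pos[j - 1L] + rr$dist[j]
    } else {
      # both this row and the previous one are original rows
      pos[j] <- pos[j - 1L] + (vec$pos[rr$orig[j]] - vec$pos[rr$orig[j - 1L]])
    }
  }
  data.table(read = read_no, frag = rr$frag, index = rr$index, pos = pos,
             orient = rr$orient)
}
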