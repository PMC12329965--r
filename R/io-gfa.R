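# GFA 1 input/output for unitig graphs.
#
# One S line is written per complement pair, using the orientation whose
# sequence is lexicographically smaller. Sequence depth is carried in the
# `dc:f:` tag. L lines carry the overlap as a single-match CIGAR ("<n>M");
# one L line is written per complement edge pair.

canonical_edge_keys <- function(edges) {
  a <- paste(edges$from, edges$to)
  b <- paste(-edges$to, -edges$from)
  ifelse(a <= b, a, b)
}

#' Write a unitig graph to GFA 1
#'
#' @param graph a `unitig_graph` object.
#' @param path output path.
#' @export
write_gfa <- function(graph, path) {
  out <- "H\tVN:Z:1.0"
  n <- length(graph$name)
  flip <- logical(n)
  seqs <- graph$seq
  for (i in seq_len(n)) {
    rc <- revcomp(seqs[i])
    if (rc < seqs[i]) { seqs[i] <- rc; flip[i] <- TRUE }
  }
  out <- c(out, sprintf("S\t%s\t%s\tdc:f:%g", graph$name, seqs, graph$cov))
  e <- graph$edges
  if (!is.null(e) && nrow(e) > 0) {
    sgn <- function(v) ifelse(flip[abs(v)], -v, v)
    ef <- sgn(e$from); et <- sgn(e$to)
    key <- canonical_edge_keys(data.frame(from = ef, to = et))
    keep <- !duplicated(key)
    ef <- ef[keep]; et <- et[keep]; ovl <- e$ovl[keep]
    out <- c(out, sprintf("L\t%s\t%s\t%s\t%s\t%dM",
                          graph$name[abs(ef)], ifelse(ef > 0, "+", "-"),
                          graph$name[abs(et)], ifelse(et > 0, "+", "-"), ovl))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a unitig graph from GFA 1
#'
#' Reconstructs topology, sequences, coverages and overlaps. Syncmer-level
#' information (k-mer paths, run lengths) is not representable in GFA and is
#' absent from the result.
#'
#' @param path path to a GFA 1 file.
#' @return a `unitig_graph` object.
#' @export
read_gfa <- function(path) {
  lines <- read_text_lines(path)
  typ <- substr(lines, 1, 1)
  sl <- strsplit(lines[typ == "S"], "\t", fixed = TRUE)
  name <- vapply(sl, `[`, character(1), 2)
  seq <- vapply(sl, `[`, character(1), 3)
  cov <- rep(NA_real_, length(sl))
  for (i in seq_along(sl)) {
    tags <- sl[[i]][-(1:3)]
    dc <- grep("^(dc|DP):f:", tags, value = TRUE)
    if (length(dc)) cov[i] <- as.numeric(sub("^..:f:", "", dc[1]))
  }
  edges <- data.table(from = integer(), to = integer(), ovl = integer(), cov = numeric())
  ll <- strsplit(lines[typ == "L"], "\t", fixed = TRUE)
  if (length(ll)) {
    bad <- which(vapply(ll, length, integer(1)) < 6L)
    if (length(bad)) stop("malformed L line in ", path)
    f <- vapply(ll, `[`, character(1), 2); fo <- vapply(ll, `[`, character(1), 3)
    t <- vapply(ll, `[`, character(1), 4); to <- vapply(ll, `[`, character(1), 5)
    cg <- vapply(ll, `[`, character(1), 6)
    fi <- match(f, name); ti <- match(t, name)
    if (anyNA(fi) || anyNA(ti)) stop("GFA L line references unknown segment in ", path)
    ovl <- as.integer(sub("M$", "", cg))
    from <- ifelse(fo == "+", fi, -fi)
    tov <- ifelse(to == "+", ti, -ti)
    edges <- data.table(from = c(from, -tov), to = c(tov, -from),
                        ovl = c(ovl, ovl), cov = NA_real_)
    edges <- unique(edges, by = c("from", "to"))
  }
  g <- list(k = NA_integer_, s = NA_integer_, name = name, seq = seq,
            len = nchar(seq), cov = cov, circular = rep(FALSE, length(name)),
            hoco = NULL, runs = NULL, vpath = NULL, edges = edges,
            comp = NULL)
  class(g) <- "unitig_graph"
  g$comp <- unitig_components(g)
  g
}
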