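# Parsing of HMMER3 nhmmscan --tblout hit tables.
#
# In nhmmscan output the "target" is the profile HMM (the gene model) and the
# "query" is the scanned nucleotide sequence. Internally a hit is stored with
# `target_id` = sequence name, `gene` = gene model, 1-based inclusive
# coordinates normalised so that start <= end, and the strand kept separately.

#' Parse an nhmmscan --tblout file
#'
#' @param path path to a tabular nhmmscan output file.
#' @param gene_map optional data.frame with columns `gene` and `organelle`
#'   (`"plastid"` or `"mitochondrion"`). When absent, the organelle is taken
#'   from a `_pt` / `_mt` suffix on the gene model name.
#' @return data.frame of hits with columns `target_id`, `gene`, `organelle`,
#'   `score`, `evalue`, `start`, `end`, `strand`.
#' @export
parse_nhmmscan_tbl <- function(path, gene_map = NULL) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  empty <- data.frame(target_id = character(), gene = character(),
                      organelle = character(), score = numeric(),
                      evalue = numeric(), start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 16L))
    stop(sprintf("malformed tblout row (%d columns, expected >= 16) in %s",
                 min(nf), path))
  col <- function(i) vapply(fields, `[`, character(1), i)
  gene_raw <- col(1)
  target <- col(3)
  alifrom <- as.integer(col(7))
  alito <- as.integer(col(8))
  strand <- col(12)
  evalue <- as.numeric(col(13))
  score <- as.numeric(col(14))
  strand[!strand %in% c("+", "-")] <- ifelse(alifrom[!strand %in% c("+", "-")] <= alito[!strand %in% c("+", "-")], "+", "-")
  start <- pmin(alifrom, alito)
  end <- pmax(alifrom, alito)
  if (!is.null(gene_map)) {
    org <- gene_map$organelle[match(gene_raw, gene_map$gene)]
    gene <- gene_raw
  } else {
    suf <- sub("^.*_", "", gene_raw)
    org <- c(pt = "plastid", mt = "mitochondrion")[suf]
    gene <- sub("_(pt|mt)$", "", gene_raw)
  }
  if (anyNA(org))
    stop("cannot determine organelle for gene(s): ",
         paste(unique(gene_raw[is.na(org)]), collapse = ", "))
  data.frame(target_id = target, gene = gene, organelle = unname(org),
             score = score, evalue = evalue, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

#' Write hits in nhmmscan --tblout format
#'
#' The inverse of [parse_nhmmscan_tbl()], used by the synthetic data
#' generator. Gene model names are written with the `_pt` / `_mt` organelle
#' suffix convention.
#'
#' @param hits data.frame as returned by [parse_nhmmscan_tbl()].
#' @param path output path.
#' @export
write_tblout <- function(hits, path) {
  suf <- c(plastid = "_pt", mitochondrion = "_mt")[hits$organelle]
  alifrom <- ifelse(hits$strand == "+", hits$start, hits$end)
  alito <- ifelse(hits$strand == "+", hits$end, hits$start)
  rows <- sprintf("%s - %s - 1 100 %d %d %d %d 0 %s %.3g %.1f 0.0 -",
                  paste0(hits$gene, suf), hits$target_id, alifrom, alito,
                  pmin(hits$start, hits$end), pmax(hits$start, hits$end),
                  hits$strand, hits$evalue, hits$score)
  writeLines(c("# synthetic nhmmscan tblout", rows), path)
  invisible(path)
}
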