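# FASTA/FASTQ input and output.
#
# Records are held as a plain data.frame with columns `id`, `seq` and `qual`
# (`NA` for FASTA). Files may be plain or gzip compressed; compression is
# sniffed from the magic bytes, not the file extension.

read_text_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  magic <- readBin(path, "raw", n = 2L)
  con <- if (length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b))
    gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

validate_dna <- function(seq, line_no, path) {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("invalid sequence character in %s near line %d", path, line_no[i]))
  }
}

#' Read sequence records from a FASTA or FASTQ file
#'
#' The format is sniffed from the first character (`>` FASTA, `@` FASTQ) and
#' gzip compression from the magic bytes. Sequences are uppercased and must be
#' over the alphabet `A`, `C`, `G`, `T`, `N`.
#'
#' @param path path to a FASTA or FASTQ file, optionally gzipped.
#' @return a data.frame with columns `id`, `seq`, `qual` (`NA` for FASTA).
#' @export
read_seq_records <- function(path) {
  lines <- read_text_lines(path)
  nonempty <- which(nzchar(lines))
  if (length(nonempty) == 0L)
    return(data.frame(id = character(), seq = character(), qual = character(),
                      stringsAsFactors = FALSE))
  first <- substr(lines[nonempty[1]], 1, 1)
  if (first == ">") parse_fasta(lines, path)
  else if (first == "@") parse_fastq(lines, path)
  else stop(sprintf("cannot determine format of %s: line %d starts with '%s'",
                    path, nonempty[1], first))
}

parse_fasta <- function(lines, path) {
  keep <- nzchar(lines)
  hdr <- substr(lines, 1, 1) == ">" & keep
  if (!hdr[which(keep)[1]]) stop(sprintf("malformed FASTA in %s: line %d", path, which(keep)[1]))
  grp <- cumsum(hdr)
  ids <- sub("^>", "", sub("\\s.*$", "", lines[hdr]))
  if (any(!nzchar(ids))) {
    ln <- which(hdr)[which(!nzchar(ids))[1]]
    stop(sprintf("empty FASTA record id in %s at line %d", path, ln))
  }
  body <- !hdr & keep
  seqs <- vapply(split(toupper(lines[body]), grp[body]), paste, character(1), collapse = "")
  seqs <- as.character(seqs[match(seq_along(ids), as.integer(names(seqs)))])
  seqs[is.na(seqs)] <- ""
  ln <- which(hdr)
  validate_dna(seqs, ln, path)
  data.frame(id = ids, seq = seqs, qual = NA_character_, stringsAsFactors = FALSE)
}

parse_fastq <- function(lines, path) {
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  if (n %% 4L != 0L)
    stop(sprintf("malformed FASTQ in %s: %d lines is not a multiple of 4", path, n))
  i <- seq(1L, n, by = 4L)
  if (any(substr(lines[i], 1, 1) != "@"))
    stop(sprintf("malformed FASTQ in %s: record at line %d does not start with '@'",
                 path, i[which(substr(lines[i], 1, 1) != "@")[1]]))
  if (any(substr(lines[i + 2L], 1, 1) != "+"))
    stop(sprintf("malformed FASTQ in %s: line %d is not a '+' separator",
                 path, i[which(substr(lines[i + 2L], 1, 1) != "+")[1]] + 2L))
  ids <- sub("^@", "", sub("\\s.*$", "", lines[i]))
  seqs <- toupper(lines[i + 1L])
  quals <- lines[i + 3L]
  bad <- nchar(seqs) != nchar(quals)
  if (any(bad))
    stop(sprintf("FASTQ record at line %d in %s: sequence and quality lengths differ",
                 i[which(bad)[1]], path))
  validate_dna(seqs, i + 1L, path)
  data.frame(id = ids, seq = seqs, qual = quals, stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records data.frame with columns `id` and `seq`.
#' @param path output path.
#' @param width line wrap width; 0 disables wrapping.
#' @export
write_fasta <- function(records, path, width = 0L) {
  out <- character(0)
  for (i in seq_len(nrow(records))) {
    s <- records$seq[i]
    body <- if (width > 0L) {
      starts <- seq(1L, nchar(s), by = width)
      substring(s, starts, pmin(starts + width - 1L, nchar(s)))
    } else s
    out <- c(out, paste0(">", records$id[i]), body)
  }
  writeLines(out, path)
}

#' Write sequence records to FASTQ
#'
#' @param records data.frame with columns `id`, `seq` and optionally `qual`.
#' @param path output path.
#' @export
write_fastq <- function(records, path) {
  qual <- records$qual
  if (is.null(qual)) qual <- rep(NA_character_, nrow(records))
  qual <- ifelse(is.na(qual), strrep("I", nchar(records$seq)), qual)
  writeLines(as.vector(rbind(paste0("@", records$id), records$seq, "+", qual)), path)
}
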