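# Shared file I/O: FASTA (Biostrings), FASTQ, BED, TSV, JSON.
# Coordinates are 0-based half-open throughout (BED native convention).

#' Read a FASTA file
#'
#' @param path path to a (optionally gzipped) FASTA file.
#' @return a named character vector of upper-case sequences; names are the
#'   full FASTA description lines.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Permissive 4-line FASTQ parser that preserves the full header line
#' (including ONT-style whitespace-separated `key=value` fields). CRLF line
#' endings are tolerated, the `+` separator line is ignored, and gzipped
#' input is detected from the `.gz` extension.
#'
#' @param path path to a FASTQ or FASTQ.gz file.
#' @return data.frame with columns `read_id`, `header` (full header without
#'   the leading `@`), `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- sub("\r$", "", lines)
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) %% 4 != 0) {
    stopf("malformed FASTQ '%s': %d lines (not a multiple of 4)",
          path, length(lines))
  }
  idx <- seq(1, length(lines), by = 4)
  headers <- lines[idx]
  bad <- !startsWith(headers, "@")
  if (any(bad)) {
    stopf("malformed FASTQ '%s': record at line %d does not start with '@'",
          path, (which(bad)[1] - 1) * 4 + 1)
  }
  headers <- substring(headers, 2)
  data.frame(
    read_id = sub("\\s.*$", "", headers),
    header = headers,
    sequence = toupper(lines[idx + 1]),
    quality = lines[idx + 3],
    stringsAsFactors = FALSE
  )
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with columns `header` and `sequence` (and
#'   optionally `quality`; a constant placeholder quality is written
#'   otherwise).
#' @param path output path (gzipped when it ends in `.gz`).
#' @export
write_fastq <- function(reads, path) {
  qual <- if (!is.null(reads$quality)) reads$quality
          else strrep("I", nchar(reads$sequence))
  out <- character(4 * nrow(reads))
  out[seq(1, length(out), 4)] <- paste0("@", reads$header)
  out[seq(2, length(out), 4)] <- reads$sequence
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- qual
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path path to a 3-6 column BED file (0-based half-open intervals).
#' @return data.frame with columns `contig`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  x <- read.delim(path, header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE)
  if (ncol(x) < 3) stopf("BED file '%s' has fewer than 3 columns", path)
  out <- data.frame(
    contig = as.character(x[[1]]),
    start = as.integer(x[[2]]),
    end = as.integer(x[[3]]),
    name = if (ncol(x) >= 4) as.character(x[[4]]) else
      sprintf("%s:%d-%d", x[[1]], x[[2]], x[[3]]),
    score = if (ncol(x) >= 5) x[[5]] else 0,
    strand = if (ncol(x) >= 6) as.character(x[[6]]) else "+",
    stringsAsFactors = FALSE
  )
  bad <- which(out$end <= out$start | out$start < 0)
  if (length(bad)) {
    stopf("BED file '%s': invalid interval on line %d", path, bad[1])
  }
  out
}

#' Read / write tab-separated tables
#' @param path file path.
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @param x data.frame to write.
#' @rdname read_tsv
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an object as JSON
#' @param x object to serialise.
#' @param path output path.
#' @export
write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
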