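# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded package functions never disturb a user's
#' random stream.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

check_dna <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGTacgt]", seq)
  if (any(bad)) {
    stop(sprintf("invalid %s: non-ACGT characters in %d record(s)",
                 what, sum(bad)), call. = FALSE)
  }
  invisible(toupper(seq))
}

#' Reverse complement of character DNA sequences
#' @param x character vector of ACGT sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, cpp_revcomp, character(1), USE.NAMES = FALSE)
}

#' Maximal homopolymer run length of each sequence
#' @noRd
max_homopolymer_run <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) max(rle(ch)$lengths), integer(1))
}

gc_count <- function(x) {
  nchar(gsub("[^GCgc]", "", x))
}

# all 4^k k-mers in rolling-code order (first base most significant)
all_kmers <- function(k) {
  codes <- 0:(4^k - 1)
  cols <- lapply((k - 1):0, function(p) DNA_BASES[(codes %/% 4^p) %% 4 + 1])
  do.call(paste0, cols)
}

# integer codes (0-based) of the k-mers starting at each position of seq
kmer_codes <- function(seq, k) {
  b <- match(strsplit(seq, "", fixed = TRUE)[[1]], DNA_BASES) - 1L
  if (anyNA(b)) stop("non-ACGT character in sequence", call. = FALSE)
  if (length(b) < k) return(integer(0))
  E <- embed(b, k)  # column 1 holds the k-mer's last base
  as.integer(E %*% 4^(0:(k - 1)))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
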