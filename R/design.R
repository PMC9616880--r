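# Panel design: k-mer-complete source sequence, variable-region selection,
# homology and hairpin screens, and gene-specific control sequences.

#' Design configuration for a CAPTOR panel
#'
#' Defaults reproduce the published panel geometry: 72 adaptors of 90 nt,
#' each a 30-nt shared 5' "burn-in" constant, a 30-nt unique variable region
#' drawn from a 6-mer-complete source, and a 30-nt shared 3' constant that
#' prevents preferential ligation. Variable regions are kept at least
#' `min_pairwise_edits` apart so reads remain classifiable at nanopore error
#' rates.
#'
#' @param n_adaptors number of adaptors in the panel.
#' @param len_constant5,len_variable,len_constant3 segment lengths (nt).
#' @param k k-mer order of the variable-region source sequence.
#' @param homology_max_shared maximum tolerated exact shared substring (nt)
#'   with a screening database.
#' @param hairpin_max_stem maximum tolerated contiguous hairpin stem (nt).
#' @param min_pairwise_edits minimum edit distance between variable regions.
#' @param rng_seed integer seed; the whole design is deterministic in it.
#' @return a `captor_design_config` list.
#' @export
design_config <- function(n_adaptors = 72, len_constant5 = 30,
                          len_variable = 30, len_constant3 = 30, k = 6,
                          homology_max_shared = 20, hairpin_max_stem = 8,
                          min_pairwise_edits = 10, rng_seed = 1L) {
  cfg <- list(n_adaptors = as.integer(n_adaptors),
              len_constant5 = as.integer(len_constant5),
              len_variable = as.integer(len_variable),
              len_constant3 = as.integer(len_constant3),
              k = as.integer(k),
              homology_max_shared = as.integer(homology_max_shared),
              hairpin_max_stem = as.integer(hairpin_max_stem),
              min_pairwise_edits = as.integer(min_pairwise_edits),
              rng_seed = as.integer(rng_seed))
  if (any(unlist(cfg[2:4]) <= 0)) stopf("all segment lengths must be > 0")
  if (cfg$n_adaptors < 1) stopf("n_adaptors must be >= 1")
  if (cfg$len_variable < cfg$k) stopf("len_variable must be >= k")
  class(cfg) <- "captor_design_config"
  cfg
}

#' Generate a k-mer-complete source sequence
#'
#' Builds a linear DNA sequence of length `4^k + k - 1` in which every one of
#' the `4^k` k-mers occurs exactly once, by linearising a de Bruijn sequence
#' (Eulerian cycle over the order-(k-1) graph, lexicographic edge preference)
#' rotated to a seed-determined start.
#'
#' @param k k-mer order (1-10).
#' @param rng_seed integer seed controlling the rotation.
#' @return a DNA string.
#' @export
generate_kmer_complete_source <- function(k, rng_seed = 1L) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > 10 || k != round(k)) {
    stopf("k must be an integer in [1, 10]")
  }
  k <- as.integer(k)
  cyc <- debruijn_cycle(k)
  n <- nchar(cyc)
  rot <- with_seed(rng_seed, sample.int(n, 1L)) - 1L
  rotated <- paste0(substring(cyc, rot + 1L, n), substring(cyc, 1L, rot))
  if (k > 1) rotated <- paste0(rotated, substring(rotated, 1L, k - 1L))
  rotated
}

# lexicographically least de Bruijn sequence B(4, k) via the
# Fredricksen-Kessler-Maiorana necklace concatenation
debruijn_cycle <- function(k) {
  n <- 4L
  a <- integer(k + 1)
  acc <- vector("list", 0)
  db <- function(t, p) {
    if (t > k) {
      if (k %% p == 0) acc[[length(acc) + 1L]] <<- a[2:(p + 1)]
    } else {
      a[t + 1L] <<- a[t - p + 1L]
      db(t + 1L, p)
      j <- a[t - p + 1L] + 1L
      while (j <= n - 1L) {
        a[t + 1L] <<- j
        db(t + 1L, t)
        j <- j + 1L
      }
    }
  }
  db(1L, 1L)
  paste(DNA_BASES[unlist(acc) + 1L], collapse = "")
}

#' Longest hairpin stem of a sequence
#'
#' Returns the length of the longest contiguous substring whose reverse
#' complement also occurs downstream with at least `min_loop` intervening
#' bases (a contiguous DNA hairpin stem; no wobble pairing). A candidate
#' passes the panel screen when the result does not exceed the configured
#' `hairpin_max_stem`.
#'
#' @param seq DNA string.
#' @param min_loop minimum loop size (nt) between the stem halves.
#' @return stem length in nt (0 when no complementary pairing exists).
#' @export
max_hairpin_stem <- function(seq, min_loop = 3) {
  if (!nzchar(seq)) stopf("empty sequence")
  b <- strsplit(check_dna(seq), "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(b)
  if (n < 2) return(0L)
  cb <- comp[b]
  best <- 0L
  for (s in 3:(2L * n - 1L)) {  # anti-diagonal p + q = s (1-based, p < q)
    p <- max(1L, s - n):((s - 1L) %/% 2L)
    if (!length(p)) next
    q <- s - p
    paired <- b[p] == cb[q]
    if (!any(paired)) next
    r <- rle(paired)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      p0 <- p[starts[i]]
      q0 <- s - p0
      cand <- min(r$lengths[i], (q0 - p0 + 1L - min_loop) %/% 2L)
      if (cand > best) best <- cand
    }
  }
  as.integer(best)
}

#' Longest exact substring shared with a screening database
#'
#' Local stand-in for a BLAST homology screen: the length of the longest
#' exact substring of `seq` found anywhere in `screening_db` on either
#' strand. A candidate passes when the result does not exceed the configured
#' `homology_max_shared`.
#'
#' @param seq DNA string.
#' @param screening_db named character vector of database sequences (or a
#'   FASTA path).
#' @return shared substring length in nt.
#' @export
max_shared_substring <- function(seq, screening_db) {
  if (is.character(screening_db) && length(screening_db) == 1 &&
      file.exists(screening_db)) {
    screening_db <- read_fasta(screening_db)
  }
  if (length(screening_db) == 0) {
    warnf("empty screening database; homology screen returns 0")
    return(0L)
  }
  seq <- check_dna(seq)
  db <- toupper(as.character(screening_db))
  hay <- paste(c(db, revcomp(db)), collapse = "#")
  n <- nchar(seq)
  hi <- min(n, max(nchar(db)))
  shared_at <- function(L) {
    subs <- unique(substring(seq, 1:(n - L + 1), L:n))
    any(vapply(subs, grepl, logical(1), x = hay, fixed = TRUE))
  }
  lo <- 0L
  while (lo < hi) {
    mid <- as.integer((lo + hi + 1) %/% 2)
    if (shared_at(mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}

#' Select variable regions from a k-mer-complete source
#'
#' Greedy maximisation of distinct k-mer coverage over all windows of the
#' source: windows are picked in order of the number of not-yet-covered
#' k-mers they contribute (ties to the leftmost window), subject to a
#' pairwise edit-distance floor between selected regions and an optional
#' per-candidate screen. A panel of 72 x 30 nt regions cannot contain all
#' 4096 6-mers, so achieved coverage is reported alongside the regions.
#'
#' @param source DNA string, typically from
#'   [generate_kmer_complete_source()].
#' @param config a [design_config()].
#' @param screen optional predicate `function(region)`; candidates for which
#'   it returns `FALSE` are skipped (used by [design_panel()] to apply
#'   hairpin/homology screens to the assembled adaptor).
#' @return list with `regions` (character vector of length `n_adaptors`) and
#'   `kmer_coverage` (count of distinct k-mers covered).
#' @export
select_variable_regions <- function(source, config = design_config(),
                                    screen = NULL) {
  v <- config$len_variable
  k <- config$k
  if (nchar(source) < v) stopf("source shorter than len_variable")
  source <- check_dna(source)
  codes <- kmer_codes(source, k)
  n_wind <- nchar(source) - v + 1L
  per_win <- v - k + 1L
  W <- embed(codes[seq_len(n_wind + per_win - 1L)], per_win)[, per_win:1, drop = FALSE] + 1L
  starts <- seq_len(n_wind)
  regions <- character(0)
  covered <- logical(4^k)
  for (pick in seq_len(config$n_adaptors)) {
    gain <- rowSums(matrix(!covered[W], nrow = n_wind))
    ord <- order(-gain, starts)
    chosen <- NA_integer_
    for (cand in ord) {
      reg <- substring(source, starts[cand], starts[cand] + v - 1L)
      if (length(regions)) {
        if (reg %in% regions) next
        if (config$min_pairwise_edits > 0 &&
            any(utils::adist(reg, regions) < config$min_pairwise_edits)) next
      }
      if (!is.null(screen) && !isTRUE(screen(reg))) next
      chosen <- cand
      regions <- c(regions, reg)
      covered[W[cand, ]] <- TRUE
      break
    }
    if (is.na(chosen)) {
      stopf(paste0("design infeasible: no window satisfies the pairwise ",
                   "edit-distance floor (%d) and screens for region %d of %d"),
            config$min_pairwise_edits, pick, config$n_adaptors)
    }
  }
  list(regions = regions, kmer_coverage = sum(covered))
}

#' Design a CAPTOR panel
#'
#' Assembles `n_adaptors` adaptors of the configured constant-variable-
#' constant structure. The shared constant segments are seed-derived random
#' sequences screened with the same hairpin/homology filters; variable
#' regions are selected from a k-mer-complete de Bruijn source with greedy
#' coverage maximisation, and any candidate whose assembled adaptor fails a
#' screen is deterministically skipped in favour of the next-best window.
#'
#' @param config a [design_config()].
#' @param screening_db optional named character vector (or FASTA path) of
#'   natural sequences for the homology screen.
#' @param max_tries retry budget for constant-segment drawing.
#' @return a `captor_panel` data.frame with columns `id`, `constant5`,
#'   `variable`, `constant3`, `full_sequence`; attribute `kmer_coverage`
#'   carries the distinct k-mer count of the variable regions.
#' @export
design_panel <- function(config = design_config(), screening_db = NULL,
                         max_tries = 100L) {
  if (is.character(screening_db) && length(screening_db) == 1 &&
      !is.null(screening_db) && file.exists(screening_db)) {
    screening_db <- read_fasta(screening_db)
  }
  passes <- function(s) {
    max_hairpin_stem(s) <= config$hairpin_max_stem &&
      (is.null(screening_db) ||
         max_shared_substring(s, screening_db) <= config$homology_max_shared)
  }
  draw_constant <- function(len) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }
  constants <- with_seed(config$rng_seed, {
    for (i in seq_len(max_tries)) {
      c5 <- draw_constant(config$len_constant5)
      c3 <- draw_constant(config$len_constant3)
      if (passes(c5) && passes(c3) && passes(paste0(c5, c3))) {
        break
      }
      c5 <- NULL
    }
    if (is.null(c5)) {
      stopf("design infeasible: no constant segments passed screens in %d tries",
            max_tries)
    }
    list(c5 = c5, c3 = c3)
  })
  source <- generate_kmer_complete_source(config$k, config$rng_seed)
  sel <- select_variable_regions(
    source, config,
    screen = function(reg) passes(paste0(constants$c5, reg, constants$c3)))
  panel <- data.frame(
    id = sprintf("CAPTOR_%02d", seq_len(config$n_adaptors)),
    constant5 = constants$c5,
    variable = sel$regions,
    constant3 = constants$c3,
    stringsAsFactors = FALSE
  )
  panel$full_sequence <- paste0(panel$constant5, panel$variable, panel$constant3)
  attr(panel, "kmer_coverage") <- sel$kmer_coverage
  attr(panel, "config") <- config
  class(panel) <- c("captor_panel", "data.frame")
  panel
}

#' Write / read a panel
#'
#' The FASTA description carries the segment offsets; a TSV sidecar stores
#' the individual segments so panels round-trip exactly.
#'
#' @param panel a `captor_panel`.
#' @param fasta,tsv output paths (`tsv` defaults alongside the FASTA).
#' @export
write_panel <- function(panel, fasta, tsv = sub("\\.fa(sta)?$", ".tsv", fasta)) {
  cfg <- attr(panel, "config")
  segs <- sprintf("segments=%d,%d,%d", nchar(panel$constant5[1]),
                  nchar(panel$variable[1]), nchar(panel$constant3[1]))
  write_fasta(setNames(panel$full_sequence, paste(panel$id, segs)), fasta)
  write_tsv(panel[, c("id", "constant5", "variable", "constant3")], tsv)
  invisible(fasta)
}

#' @param tsv path of the TSV sidecar written by [write_panel()].
#' @rdname write_panel
#' @export
read_panel <- function(tsv) {
  x <- read_tsv(tsv)
  need <- c("id", "constant5", "variable", "constant3")
  if (!all(need %in% names(x))) stopf("panel TSV missing columns")
  x$full_sequence <- paste0(x$constant5, x$variable, x$constant3)
  class(x) <- c("captor_panel", "data.frame")
  x
}

#' Design gene-specific control sequences
#'
#' Extracts strand-aware slices of reference contigs (for example whole
#' clinical-gene exons) to serve as gene-specific control adaptors that
#' establish a matched background error profile for the accompanying sample.
#'
#' @param gene_fasta named character vector of contigs, or a FASTA path.
#' @param regions data.frame of intervals as returned by [read_bed()]
#'   (0-based half-open), or a BED path.
#' @return a `captor_gene_controls` data.frame with columns `id`, `sequence`,
#'   `contig`, `start`, `end`, `strand`.
#' @export
design_gene_controls <- function(gene_fasta, regions) {
  if (is.character(gene_fasta) && length(gene_fasta) == 1 &&
      file.exists(gene_fasta)) {
    gene_fasta <- read_fasta(gene_fasta)
  }
  names(gene_fasta) <- sub("\\s.*$", "", names(gene_fasta))
  if (is.character(regions)) regions <- read_bed(regions)
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    if (!r$contig %in% names(gene_fasta)) {
      stopf("region '%s': contig '%s' not found", r$name, r$contig)
    }
    contig <- gene_fasta[[r$contig]]
    if (r$start < 0 || r$end > nchar(contig)) {
      stopf("region '%s': interval %d-%d outside contig '%s' (length %d)",
            r$name, r$start, r$end, r$contig, nchar(contig))
    }
    s <- substring(contig, r$start + 1L, r$end)
    if (identical(r$strand, "-")) s <- revcomp(s)
    out[[i]] <- data.frame(id = r$name, sequence = s, contig = r$contig,
                           start = r$start, end = r$end, strand = r$strand,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("captor_gene_controls", "data.frame")
  res
}
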