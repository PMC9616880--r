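# Read parsing, clipping, semi-global alignment, adaptor classification,
# event-profile accumulation and insert-to-feature assignment.

UNCLASSIFIED <- "UNCLASSIFIED"
UNASSIGNED <- "UNASSIGNED"

#' Parse an ONT-style FASTQ header
#'
#' Extracts the read id and the whitespace-separated `ch=` and `start_time=`
#' fields when present; absent or malformed fields yield `NA` (with a
#' warning for a malformed channel), never an error.
#'
#' @param header header line (with or without the leading `@`).
#' @return list with `read_id`, `channel` (integer or NA), `start_time`
#'   (POSIXct or NA), `pass_flag` (logical or NA).
#' @export
parse_read_header <- function(header) {
  h <- sub("^@", "", header)
  parts <- strsplit(trimws(h), "\\s+")[[1]]
  if (!length(parts) || !nzchar(parts[1])) stopf("empty read header")
  kv <- grep("=", parts[-1], value = TRUE, fixed = TRUE)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  get <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
  ch_raw <- get("ch")
  channel <- suppressWarnings(as.integer(ch_raw))
  if (!is.na(ch_raw) && is.na(channel)) {
    warnf("read '%s': malformed ch value '%s'", parts[1], ch_raw)
  }
  st_raw <- get("start_time")
  start_time <- if (is.na(st_raw)) as.POSIXct(NA) else
    as.POSIXct(st_raw, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  pf_raw <- get("pass")
  pass_flag <- if (is.na(pf_raw)) NA else tolower(pf_raw) %in% c("true", "1", "pass")
  list(read_id = parts[1], channel = channel, start_time = start_time,
       pass_flag = pass_flag)
}

#' Clip a read to its first n bases
#' @param sequence character vector of read sequences.
#' @param n number of leading bases to keep (default 500, the conventional
#'   clip for adaptor analysis).
#' @export
clip_read <- function(sequence, n = 500) {
  if (n < 1) stopf("n must be >= 1")
  substring(sequence, 1, n)
}

#' Semi-global (fitting) alignment
#'
#' Minimum-unit-cost alignment of `ref` end-to-end against a window of
#' `query` with free leading/trailing query gaps. Traceback ties are broken
#' deterministically (match > mismatch > deletion > insertion) and the
#' alignment ends at the leftmost minimal-cost query position. Insertions are
#' attributed to the preceding reference position.
#'
#' @param query read sequence (free end gaps).
#' @param ref reference sequence (aligned end-to-end).
#' @return a `captor_alignment` list: `edit_distance`, `identity`, operation
#'   counts, `query_start`/`query_end` (0-based half-open span on the query)
#'   and `aligned_pairs` (data.frame of `ref_pos`, `read_pos`, `op`).
#' @export
semiglobal_align <- function(query, ref) {
  if (!nzchar(query) || !nzchar(ref)) stopf("query and ref must be non-empty")
  a <- cpp_fit_align(toupper(ref), toupper(query), TRUE)
  ops <- a$ops
  tot <- a$n_match + a$n_mismatch + a$n_insertion + a$n_deletion
  structure(list(
    edit_distance = a$dist,
    identity = if (tot > 0) a$n_match / tot else 0,
    n_match = a$n_match, n_mismatch = a$n_mismatch,
    n_insertion = a$n_insertion, n_deletion = a$n_deletion,
    query_start = a$qstart, query_end = a$qend,
    aligned_pairs = data.frame(
      ref_pos = ops[, 1], read_pos = ifelse(ops[, 2] < 0, NA_integer_, ops[, 2]),
      op = c("match", "mismatch", "insertion", "deletion")[ops[, 3]],
      stringsAsFactors = FALSE)
  ), class = "captor_alignment")
}

#' Classify reads against a CAPTOR panel
#'
#' Locates the shared 5' constant region on the clipped read (and its
#' reverse complement when `search_both_orientations`), then aligns every
#' panel variable region inside the localised window; the adaptor with the
#' minimal variable-region edit distance wins, so the decision between
#' adaptors uses only the variable region's signal - the constant segments
#' are shared across the panel. The classified/unclassified gate, however,
#' uses the identity of the full adaptor alignment (a genuine adaptor read
#' also carries the constants, which a random sequence cannot match): a read
#' is `UNCLASSIFIED` when that identity falls below `min_identity` or when
#' two distinct adaptors tie on the variable region.
#'
#' @param fastq a data.frame from [read_fastq()] / [simulate_library()] (or a
#'   FASTQ path), or a plain character vector of sequences.
#' @param panel a `captor_panel`.
#' @param clip leading bases searched for the adaptor.
#' @param min_identity minimum variable-region identity for classification.
#' @param search_both_orientations also search the reverse complement.
#' @return a `captor_classification`: list with `reads` (per-read table:
#'   `read_id`, `captor_id`, `orientation`, `identity`, `edit_distance`,
#'   `per_read_error`, adaptor span, channel/time metadata) and `profiles`
#'   (per-adaptor event profiles, see [accumulate_events()]).
#' @export
classify_reads <- function(fastq, panel, clip = 500, min_identity = 0.7,
                           search_both_orientations = TRUE) {
  if (is.character(fastq) && length(fastq) == 1 && file.exists(fastq)) {
    fastq <- read_fastq(fastq)
  }
  if (is.character(fastq)) {
    fastq <- data.frame(read_id = sprintf("read_%d", seq_along(fastq)),
                        header = sprintf("read_%d", seq_along(fastq)),
                        sequence = fastq, stringsAsFactors = FALSE)
  }
  if (!nrow(fastq)) stopf("no reads to classify")
  res <- cpp_classify_reads(toupper(fastq$sequence), panel$constant5[1],
                            panel$variable, panel$full_sequence,
                            clip = as.integer(clip),
                            min_identity = min_identity,
                            both_orientations = isTRUE(search_both_orientations))
  meta <- lapply(fastq$header, parse_read_header)
  reads <- data.frame(
    read_id = fastq$read_id,
    captor_id = ifelse(is.na(res$captor), UNCLASSIFIED, panel$id[res$captor]),
    orientation = res$orientation,
    identity = res$identity,
    edit_distance = res$edit_distance,
    per_read_error = res$per_read_error,
    var_mismatch = res$var_mismatch,
    var_insertion = res$var_insertion,
    var_deletion = res$var_deletion,
    adaptor_qstart = res$adaptor_qstart,
    adaptor_qend = res$adaptor_qend,
    channel = vapply(meta, function(m) m$channel, integer(1)),
    stringsAsFactors = FALSE)
  reads$start_time <- as.POSIXct(
    vapply(meta, function(m) as.numeric(m$start_time), numeric(1)),
    origin = "1970-01-01", tz = "UTC")
  profiles <- lapply(seq_len(nrow(panel)), function(a) {
    ev <- res$events[[a]]
    events_to_profile(ev, panel$full_sequence[a])
  })
  names(profiles) <- panel$id
  structure(list(reads = reads, profiles = profiles, panel = panel,
                 clip = clip, min_identity = min_identity),
            class = "captor_classification")
}

#' Classify a single read
#'
#' Single-read convenience wrapper around the panel classifier; returns the
#' full alignment of the winning adaptor.
#'
#' @param read a read sequence.
#' @inheritParams classify_reads
#' @return list with `captor_id` (or `"UNCLASSIFIED"`), `orientation`,
#'   `identity`, and `alignment` (a `captor_alignment` of the full winning
#'   adaptor against the searched strand, or NULL).
#' @export
classify_read <- function(read, panel, clip = 500, min_identity = 0.7,
                          search_both_orientations = TRUE) {
  cl <- classify_reads(read, panel, clip = clip, min_identity = min_identity,
                       search_both_orientations = search_both_orientations)
  row <- cl$reads[1, ]
  aln <- NULL
  if (row$captor_id != UNCLASSIFIED) {
    strand <- clip_read(toupper(read), clip)
    if (row$orientation == "-") strand <- revcomp(strand)
    aln <- semiglobal_align(strand,
                            panel$full_sequence[match(row$captor_id, panel$id)])
    aln$captor_id <- row$captor_id
  }
  list(captor_id = row$captor_id, orientation = row$orientation,
       identity = row$identity, per_read_error = row$per_read_error,
       alignment = aln)
}

events_to_profile <- function(ev, ref_seq) {
  L <- nchar(ref_seq)
  data.frame(
    position = 0:(L - 1),
    ref_base = strsplit(ref_seq, "", fixed = TRUE)[[1]],
    n_match = ev[, 1], n_mismatch = ev[, 2],
    n_insertion = ev[, 3], n_deletion = ev[, 4],
    depth = ev[, 1] + ev[, 2] + ev[, 4],
    stringsAsFactors = FALSE)
}

#' Profile reads against known references
#'
#' Aligns each read semi-globally to its designated reference and
#' accumulates per-position event counts - the profiling path for reads
#' whose reference assignment is already known (ground-truth simulator
#' output, or gene-control reads identified by their reference index).
#' Reads on the reverse strand should be supplied reverse-complemented (or
#' pass `strand`).
#'
#' @param sequences character vector of read sequences.
#' @param ref_ids character vector assigning each read to a reference name.
#' @param refs named character vector of reference sequences.
#' @param strand optional character vector of `"+"`/`"-"`; minus-strand
#'   reads are reverse-complemented before alignment.
#' @param clip optional number of leading bases (after strand correction) to
#'   align; use when the reference is known to sit at the read start.
#' @return named list of event-profile data.frames (one per reference).
#' @export
profile_reads <- function(sequences, ref_ids, refs, strand = NULL,
                          clip = NULL) {
  if (!is.null(strand)) {
    rev <- strand == "-"
    sequences[rev] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(sequences[rev])))
  }
  if (!is.null(clip)) sequences <- clip_read(sequences, clip)
  idx <- match(ref_ids, names(refs))
  if (anyNA(idx)) stopf("ref_ids contain names absent from refs")
  res <- cpp_profile_reads(toupper(sequences), idx, toupper(as.character(refs)))
  profiles <- lapply(seq_along(refs), function(i) {
    events_to_profile(res$events[[i]], toupper(refs[[i]]))
  })
  names(profiles) <- names(refs)
  profiles
}

#' Accumulate alignment events into per-adaptor profiles
#'
#' Sums per-reference-position match/mismatch/insertion/deletion events over
#' classified alignments. Insertions are attributed to the reference
#' position immediately 5' of the inserted bases; depth at a position is the
#' number of reads covering it (`n_match + n_mismatch + n_deletion`).
#'
#' @param alignments list of `captor_alignment` objects, each carrying a
#'   `captor_id` element naming a panel adaptor.
#' @param panel a `captor_panel`.
#' @return named list (one per panel adaptor) of event-profile data.frames
#'   with columns `position`, `ref_base`, `n_match`, `n_mismatch`,
#'   `n_insertion`, `n_deletion`, `depth`.
#' @export
accumulate_events <- function(alignments, panel) {
  evs <- lapply(panel$full_sequence, function(s) matrix(0L, nchar(s), 4))
  names(evs) <- panel$id
  opcode <- c(match = 1L, mismatch = 2L, insertion = 3L, deletion = 4L)
  for (aln in alignments) {
    id <- aln$captor_id
    if (is.null(id) || !(id %in% panel$id)) {
      stopf("alignment references unknown adaptor '%s'",
            if (is.null(id)) "<missing>" else id)
    }
    ap <- aln$aligned_pairs
    idx <- cbind(ap$ref_pos + 1L, opcode[ap$op])
    for (r in seq_len(nrow(idx))) {
      evs[[id]][idx[r, 1], idx[r, 2]] <- evs[[id]][idx[r, 1], idx[r, 2]] + 1L
    }
  }
  profiles <- lapply(panel$id, function(id) {
    events_to_profile(evs[[id]], panel$full_sequence[match(id, panel$id)])
  })
  names(profiles) <- panel$id
  profiles
}

#' Per-read error rate of a classified alignment
#'
#' Errors (mismatch + insertion + deletion) per aligned reference
#' nucleotide. By default restricted to the adaptor's variable region, the
#' segment carrying the classification signal; set `region = "full"` for the
#' whole adaptor.
#'
#' @param alignment a `captor_alignment` of a full adaptor (from
#'   [classify_read()]).
#' @param panel the panel the alignment refers to.
#' @param region `"variable"` (default) or `"full"`.
#' @export
per_read_error <- function(alignment, panel, region = c("variable", "full")) {
  region <- match.arg(region)
  ap <- alignment$aligned_pairs
  if (region == "variable") {
    lo <- nchar(panel$constant5[1])
    hi <- lo + nchar(panel$variable[1]) - 1L
    ap <- ap[ap$ref_pos >= lo & ap$ref_pos <= hi, ]
    len <- hi - lo + 1L
  } else {
    len <- nchar(panel$full_sequence[1])
  }
  sum(ap$op != "match") / len
}

#' Assign read inserts to sample features
#'
#' For each classified read, the insert is taken as the sub-read after the
#' 5' adaptor; a trailing adaptor (recognised by its constant segments) is
#' trimmed off. The insert is then aligned semi-globally to every feature
#' and the best identity wins if it reaches `min_identity`; ties and empty
#' inserts yield `UNASSIGNED`.
#'
#' @param fastq reads as given to [classify_reads()].
#' @param classification the matching `captor_classification`.
#' @param feature_refs named character vector of feature sequences (or FASTA
#'   path).
#' @param min_identity minimum insert-to-feature identity.
#' @return data.frame with `read_id`, `feature_id`, `identity`,
#'   `aligned_bases` (span covered on the feature).
#' @export
assign_inserts <- function(fastq, classification, feature_refs,
                           min_identity = 0.7) {
  if (is.character(feature_refs) && length(feature_refs) == 1 &&
      file.exists(feature_refs)) {
    feature_refs <- read_fasta(feature_refs)
  }
  if (length(feature_refs) == 0) stopf("feature_refs must not be empty")
  if (is.character(fastq) && length(fastq) == 1 && file.exists(fastq)) {
    fastq <- read_fastq(fastq)
  }
  if (is.character(fastq)) fastq <- data.frame(sequence = fastq)
  feats <- toupper(as.character(feature_refs))
  fnames <- names(feature_refs)
  panel <- classification$panel
  c5 <- panel$constant5[1]
  rc3 <- revcomp(panel$constant3[1])
  cl <- classification$reads
  n <- nrow(cl)
  feature_id <- rep(UNASSIGNED, n)
  identity <- rep(NA_real_, n)
  aligned <- rep(0L, n)
  strands <- clip_read(toupper(fastq$sequence), classification$clip)
  flip <- !is.na(cl$orientation) & cl$orientation == "-"
  strands[flip] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(strands[flip])))
  for (i in seq_len(n)) {
    if (cl$captor_id[i] == UNCLASSIFIED) next
    strand <- strands[i]
    after <- substring(strand, cl$adaptor_qend[i] + 1L)
    if (nchar(after) >= 10) {
      insert <- after
      if (nchar(insert) >= nchar(c5)) {
        # trim a trailing adaptor: earliest qualifying constant-segment hit
        cut <- nchar(insert) + 1L
        for (probe in c(c5, rc3)) {
          hit <- cpp_fit_align(probe, insert, FALSE)
          tot <- hit$n_match + hit$n_mismatch + hit$n_insertion + hit$n_deletion
          if (tot > 0 && hit$n_match / tot >= 0.75) cut <- min(cut, hit$qstart + 1L)
        }
        insert <- substring(insert, 1, cut - 1L)
      }
    } else {
      # matched adaptor sits at the strand's 3' end; the insert precedes it,
      # possibly behind a leading adaptor ending in the 3' constant
      insert <- substring(strand, 1, cl$adaptor_qstart[i])
      if (nchar(insert) >= nchar(c5)) {
        hit <- cpp_fit_align(panel$constant3[1], insert, FALSE)
        tot <- hit$n_match + hit$n_mismatch + hit$n_insertion + hit$n_deletion
        if (tot > 0 && hit$n_match / tot >= 0.75) {
          insert <- substring(insert, hit$qend + 1L)
        }
      }
    }
    if (nchar(insert) < 10) next
    scores <- cpp_fit_queries(insert, feats)
    best <- which(scores == min(scores))
    if (length(best) > 1) next
    approx_ident <- 1 - scores[best] / nchar(insert)
    if (approx_ident < min_identity) next
    fin <- cpp_fit_align(insert, feats[best], FALSE)
    tot <- fin$n_match + fin$n_mismatch + fin$n_insertion + fin$n_deletion
    ident <- if (tot > 0) fin$n_match / tot else 0
    if (ident < min_identity) next
    feature_id[i] <- fnames[best]
    identity[i] <- ident
    aligned[i] <- fin$qend - fin$qstart
  }
  data.frame(read_id = cl$read_id, feature_id = feature_id,
             identity = identity, aligned_bases = aligned,
             stringsAsFactors = FALSE)
}
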