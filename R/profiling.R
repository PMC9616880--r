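# Per-nucleotide error rates, per-6-mer error tables, pore/time summaries,
# replicate comparison, and per-nucleotide subtraction error correction.

#' Per-position error rates from an event profile
#'
#' Converts event counts into per-nucleotide rates (`events / depth`) at
#' positions with at least `min_depth` covering reads; shallower positions
#' are reported with `NA` rates so downstream averages never mix in
#' unreliable estimates.
#'
#' @param events an event-profile data.frame (see [accumulate_events()]).
#' @param min_depth minimum depth for a position to receive rates.
#' @return a `captor_position_profile` data.frame with `position`,
#'   `ref_base`, `depth`, `r_mismatch`, `r_insertion`, `r_deletion`,
#'   `r_total`.
#' @export
profile_rates <- function(events, min_depth = 10) {
  ok <- events$depth >= min_depth
  rate <- function(x) ifelse(ok, x / events$depth, NA_real_)
  out <- data.frame(
    position = events$position, ref_base = events$ref_base,
    depth = events$depth,
    r_mismatch = rate(events$n_mismatch),
    r_insertion = rate(events$n_insertion),
    r_deletion = rate(events$n_deletion),
    stringsAsFactors = FALSE)
  out$r_total <- out$r_mismatch + out$r_insertion + out$r_deletion
  class(out) <- c("captor_position_profile", "data.frame")
  out
}

#' Per-6-mer error table from positional profiles
#'
#' Restricts each adaptor's profile to its variable region, slides
#' overlapping 6-mer windows across it (25 windows per 30-nt region), takes
#' the unweighted mean of the per-position rates across each window's k
#' positions, and - where a 6-mer occurs in more than one adaptor - the mean
#' across all instances. Windows containing a position without a rate
#' (depth below the profile's threshold) are skipped. GC count and maximal
#' homopolymer run are attached as sequence annotations.
#'
#' @param profiles named list of `captor_position_profile`s (one per panel
#'   adaptor, as from [classify_reads()] + [profile_rates()]).
#' @param panel the `captor_panel`.
#' @param k window size (default 6).
#' @return a `captor_kmer_table` data.frame: `kmer`, per-class mean rates,
#'   `mean_r_total`, `n_instances`, `gc_count`, `max_homopolymer_run`.
#' @export
kmer_table <- function(profiles, panel, k = 6) {
  if (!all(panel$id %in% names(profiles))) {
    stopf("profiles must cover every panel adaptor")
  }
  lo <- nchar(panel$constant5[1])
  v <- nchar(panel$variable[1])
  rows <- list()
  skipped <- 0L
  for (a in seq_len(nrow(panel))) {
    pr <- profiles[[panel$id[a]]]
    var_pr <- pr[pr$position >= lo & pr$position < lo + v, ]
    vseq <- panel$variable[a]
    for (w in seq_len(v - k + 1)) {
      win <- var_pr[w:(w + k - 1), ]
      if (anyNA(win$r_total)) { skipped <- skipped + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        kmer = substring(vseq, w, w + k - 1),
        r_mismatch = mean(win$r_mismatch),
        r_insertion = mean(win$r_insertion),
        r_deletion = mean(win$r_deletion),
        r_total = mean(win$r_total),
        stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0) {
    message(sprintf("kmer_table: skipped %d window(s) with undefined positions",
                    skipped))
  }
  if (!length(rows)) stopf("no windows with defined rates")
  inst <- do.call(rbind, rows)
  agg <- aggregate(inst[, -1], by = list(kmer = inst$kmer), FUN = mean)
  cnt <- table(inst$kmer)
  out <- data.frame(
    kmer = agg$kmer,
    mean_r_mismatch = agg$r_mismatch,
    mean_r_insertion = agg$r_insertion,
    mean_r_deletion = agg$r_deletion,
    mean_r_total = agg$r_total,
    n_instances = as.integer(cnt[agg$kmer]),
    gc_count = gc_count(agg$kmer),
    max_homopolymer_run = max_homopolymer_run(agg$kmer),
    stringsAsFactors = FALSE)
  class(out) <- c("captor_kmer_table", "data.frame")
  out
}

#' Compare two per-6-mer error tables
#'
#' Per-6-mer absolute differences plus, per error class, the symmetric mean
#' relative difference over the shared 6-mers:
#' `mean(100 * |a - b| / ((a + b) / 2))`, excluding 6-mers where both rates
#' are zero. This is the package's replicate-agreement metric.
#'
#' @param table_a,table_b `captor_kmer_table`s with shared 6-mer support.
#' @return list with `per_kmer` (data.frame of differences) and
#'   `mean_relative_difference` (named vector, percent, one entry per class).
#' @export
compare_tables <- function(table_a, table_b) {
  shared <- intersect(table_a$kmer, table_b$kmer)
  if (!length(shared)) stopf("tables share no 6-mers")
  a <- table_a[match(shared, table_a$kmer), ]
  b <- table_b[match(shared, table_b$kmer), ]
  classes <- c("mean_r_mismatch", "mean_r_insertion", "mean_r_deletion",
               "mean_r_total")
  per <- data.frame(kmer = shared, stringsAsFactors = FALSE)
  mrd <- setNames(numeric(length(classes)), sub("mean_r_", "", classes))
  for (i in seq_along(classes)) {
    av <- a[[classes[i]]]; bv <- b[[classes[i]]]
    per[[paste0("delta_", sub("mean_r_", "", classes[i]))]] <- abs(av - bv)
    denom <- (av + bv) / 2
    use <- denom > 0
    mrd[i] <- if (any(use)) mean(100 * abs(av - bv)[use] / denom[use]) else NA_real_
  }
  list(per_kmer = per, mean_relative_difference = mrd)
}

#' Per-pore and per-time error summary
#'
#' Bins classified reads by channel and start-time window and reports read
#' counts and mean per-read error, plus per-channel totals (overall mean
#' error, throughput, and the max/min ratio across that channel's bins) -
#' the tabular equivalent of a flowcell accuracy map.
#'
#' @param reads the per-read table of a `captor_classification`.
#' @param time_bin bin width in seconds.
#' @param run_duration optional run length; reads past it are clamped into
#'   the final bin.
#' @return list with `bins` (channel x time-bin table) and `channels`
#'   (per-channel summary).
#' @export
pore_time_summary <- function(reads, time_bin = 3600, run_duration = NULL) {
  x <- reads[!is.na(reads$channel) & !is.na(reads$per_read_error), ]
  if (!nrow(x)) {
    warnf("no reads with channel metadata; returning empty summary")
    return(list(bins = data.frame(), channels = data.frame()))
  }
  tsec <- as.numeric(x$start_time) - min(as.numeric(x$start_time), na.rm = TRUE)
  tsec[is.na(tsec)] <- 0
  bin <- floor(tsec / time_bin)
  if (!is.null(run_duration)) {
    last <- floor((run_duration - 1e-9) / time_bin)
    over <- bin > last
    if (any(over)) {
      message(sprintf("pore_time_summary: clamped %d read(s) past run end",
                      sum(over)))
      bin[over] <- last
    }
  }
  bins <- aggregate(list(mean_error = x$per_read_error),
                    by = list(channel = x$channel, time_bin = bin), FUN = mean)
  bins$n_reads <- aggregate(list(n = rep(1L, nrow(x))),
                            by = list(channel = x$channel, time_bin = bin),
                            FUN = sum)$n
  ch <- aggregate(list(mean_error = x$per_read_error),
                  by = list(channel = x$channel), FUN = mean)
  ch$n_reads <- as.integer(table(x$channel)[as.character(ch$channel)])
  ch$bin_ratio <- vapply(ch$channel, function(c0) {
    m <- bins$mean_error[bins$channel == c0]
    if (length(m) < 2 || min(m) == 0) NA_real_ else max(m) / min(m)
  }, numeric(1))
  list(bins = bins[order(bins$channel, bins$time_bin), ], channels = ch)
}

#' Subtract a control error profile from a sample profile
#'
#' Per-nucleotide error correction: for each position and error class the
#' corrected rate is `max(0, sample - control)` (rates are probabilities, so
#' negative differences clamp at zero). Gene-specific control adaptors
#' sequenced alongside the sample share its systematic error component, so
#' subtraction removes reproducible errors while true variants - present
#' only in the sample - retain their excess rate.
#'
#' @param sample,control `captor_position_profile`s of equal length over the
#'   same reference.
#' @return a `captor_correction` list: `positions` (sample, control and
#'   corrected rates per position) and `summary` (median rates before/after
#'   per class, over positions where both profiles are defined).
#' @export
subtract_profiles <- function(sample, control) {
  if (nrow(sample) != nrow(control)) {
    stopf("profile length mismatch: sample %d vs control %d positions",
          nrow(sample), nrow(control))
  }
  classes <- c("r_mismatch", "r_insertion", "r_deletion", "r_total")
  pos <- data.frame(position = sample$position, ref_base = sample$ref_base,
                    stringsAsFactors = FALSE)
  for (cl in classes) {
    pos[[paste0("sample_", cl)]] <- sample[[cl]]
    pos[[paste0("control_", cl)]] <- control[[cl]]
    pos[[paste0("corrected_", cl)]] <- pmax(sample[[cl]] - control[[cl]], 0)
  }
  structure(list(positions = pos,
                 summary = correction_summary(pos, classes)),
            class = "captor_correction")
}

correction_summary <- function(pos, classes = c("r_mismatch", "r_insertion",
                                                "r_deletion", "r_total")) {
  out <- lapply(classes, function(cl) {
    s <- pos[[paste0("sample_", cl)]]
    co <- pos[[paste0("corrected_", cl)]]
    ok <- !is.na(s) & !is.na(pos[[paste0("control_", cl)]])
    c(median_before = median(s[ok]), median_after = median(co[ok]),
      n_positions = sum(ok))
  })
  m <- do.call(rbind, out)
  data.frame(class = sub("r_", "", classes), m, stringsAsFactors = FALSE)
}

#' Restrict a correction report to variant positions
#'
#' Recomputes the summary medians over a masked set of positions only (for
#' example annotated pathogenic variants), or over its complement with
#' `invert = TRUE`.
#'
#' @param report a `captor_correction`.
#' @param positions data.frame of intervals ([read_bed()] convention) or an
#'   integer vector of 0-based positions.
#' @param invert summarise the complement of the mask instead.
#' @export
restrict_to_variants <- function(report, positions, invert = FALSE) {
  if (is.data.frame(positions)) {
    positions <- unlist(lapply(seq_len(nrow(positions)), function(i) {
      seq(positions$start[i], positions$end[i] - 1L)
    }))
  }
  if (any(!(positions %in% report$positions$position))) {
    stopf("variant positions outside profile coordinates")
  }
  keep <- report$positions$position %in% positions
  if (invert) keep <- !keep
  masked <- report$positions[keep, ]
  if (!nrow(masked)) {
    warnf("empty position mask; no summary computed")
    report$summary <- NULL
    return(report)
  }
  report$positions_masked <- masked
  report$summary <- correction_summary(masked)
  report
}

#' Correlation between sample and control error profiles
#'
#' Pearson correlation of per-position rates for each error class over the
#' positions where both profiles are defined; classes with zero variance in
#' either profile yield `NA` with a warning.
#'
#' @param sample,control `captor_position_profile`s of equal length.
#' @return named numeric vector of correlations (mismatch, insertion,
#'   deletion, total).
#' @export
profile_correlation <- function(sample, control) {
  if (nrow(sample) != nrow(control)) stopf("profile length mismatch")
  classes <- c("r_mismatch", "r_insertion", "r_deletion", "r_total")
  out <- setNames(rep(NA_real_, length(classes)), sub("r_", "", classes))
  for (i in seq_along(classes)) {
    s <- sample[[classes[i]]]; co <- control[[classes[i]]]
    ok <- !is.na(s) & !is.na(co)
    if (sum(ok) < 3) stopf("need at least 3 shared defined positions")
    if (sd(s[ok]) == 0 || sd(co[ok]) == 0) {
      warnf("zero variance in class '%s'; correlation undefined", classes[i])
      next
    }
    out[i] <- cor(s[ok], co[ok])
  }
  out
}
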