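# Read simulator: adaptor-flanked inserts passed through a context-dependent
# systematic error channel, with per-channel (pore) metadata and exact
# ground-truth bookkeeping.

#' Build a context-dependent error model
#'
#' Assigns each of the 4096 6-mers a mismatch, insertion and deletion rate
#' per emitted nucleotide:
#' `clamp(base + gc_slope * GC + homopolymer_slope * (maxrun - 1) + e, 0, 0.5)`
#' where `GC` is the 6-mer GC fraction, `maxrun` its longest homopolymer run
#' and `e` a seed-deterministic per-6-mer offset drawn from
#' `Normal(0, systematic_sd)` per error class. The systematic offsets make
#' errors reproducible across simulated libraries, mirroring the observation
#' that nanopore errors are predominantly systematic; the positive GC and
#' homopolymer slopes reproduce the elevated error of GC-rich and
#' low-complexity 6-mers. Defaults are calibrated so class means sit near
#' reported MinION R9.4.1 rates (mismatch ~0.03, insertion+deletion ~0.06,
#' total ~0.09 errors/nt).
#'
#' @param base_mismatch,base_insertion,base_deletion per-class base rates.
#' @param gc_slope rate increase per unit GC fraction (per class).
#' @param homopolymer_slope rate increase per extra homopolymer base.
#' @param systematic_sd standard deviation of the per-6-mer offsets.
#' @param rng_seed integer seed; identical inputs give identical tables.
#' @return a `captor_error_model`: data.frame of per-6-mer rates plus a
#'   `params` attribute.
#' @export
build_context_error_model <- function(base_mismatch = 0.020,
                                      base_insertion = 0.018,
                                      base_deletion = 0.018,
                                      gc_slope = 0.015,
                                      homopolymer_slope = 0.006,
                                      systematic_sd = 0.008,
                                      rng_seed = 1L) {
  params <- list(base_mismatch = base_mismatch,
                 base_insertion = base_insertion,
                 base_deletion = base_deletion, gc_slope = gc_slope,
                 homopolymer_slope = homopolymer_slope,
                 systematic_sd = systematic_sd, rng_seed = as.integer(rng_seed))
  if (any(unlist(params[1:3]) < 0) || any(unlist(params[1:3]) > 0.5)) {
    stopf("base rates must lie in [0, 0.5]")
  }
  if (systematic_sd < 0) stopf("systematic_sd must be >= 0")
  kmer <- all_kmers(6)
  gc <- gc_count(kmer)
  run <- max_homopolymer_run(kmer)
  shape <- gc_slope * gc / 6 + homopolymer_slope * (run - 1)
  raw <- with_seed(rng_seed, {
    lapply(c(base_mismatch, base_insertion, base_deletion), function(b) {
      b + shape + rnorm(4096, 0, systematic_sd)
    })
  })
  rates <- lapply(raw, function(r) pmin(pmax(r, 0), 0.5))
  if (any(vapply(raw, function(r) mean(r < 0 | r > 0.5), numeric(1)) > 0.1)) {
    warnf("more than 10%% of 6-mer rates clamped at [0, 0.5] bounds")
  }
  model <- data.frame(kmer = kmer, gc_count = gc, max_homopolymer_run = run,
                      p_mismatch = rates[[1]], p_insertion = rates[[2]],
                      p_deletion = rates[[3]], stringsAsFactors = FALSE)
  attr(model, "params") <- params
  class(model) <- c("captor_error_model", "data.frame")
  model
}

#' Pore (channel) model for the simulator
#'
#' Each channel carries a multiplicative error scalar and a throughput
#' weight. By default multipliers are log-normal with spread chosen so the
#' max/min accuracy ratio across channels is a few-fold (pore performance is
#' observed to vary ~3-fold), and throughput weights are the reciprocal of
#' the multiplier so inaccurate pores also yield fewer reads.
#'
#' @param n_channels number of channels.
#' @param multiplier_sdlog sdlog of the log-normal error multipliers.
#' @param run_duration seconds the flowcell runs; `active_until` defaults to
#'   the full duration for every channel.
#' @param rng_seed integer seed.
#' @return a `captor_pore_model` data.frame.
#' @export
pore_model <- function(n_channels = 12, multiplier_sdlog = 0.35,
                       run_duration = 8 * 3600, rng_seed = 1L) {
  if (n_channels < 1) stopf("need at least one channel")
  mult <- with_seed(rng_seed, exp(rnorm(n_channels, 0, multiplier_sdlog)))
  pm <- data.frame(channel_id = seq_len(n_channels),
                   error_multiplier = mult,
                   throughput_weight = 1 / mult,
                   active_until = run_duration)
  class(pm) <- c("captor_pore_model", "data.frame")
  pm
}

#' Simulation configuration
#'
#' @param n_reads number of reads to emit.
#' @param insert_mean,insert_sd insert length distribution (nt).
#' @param attach_3prime also ligate an adaptor to the 3' end of each insert.
#' @param run_duration run length in seconds (start times are uniform on it).
#' @param rng_seed integer seed.
#' @export
sim_config <- function(n_reads = 1000, insert_mean = 100, insert_sd = 20,
                       attach_3prime = TRUE, run_duration = 8 * 3600,
                       rng_seed = 1L) {
  if (n_reads < 1) stopf("n_reads must be >= 1")
  if (insert_mean < 0) stopf("insert lengths must be >= 0")
  structure(list(n_reads = as.integer(n_reads), insert_mean = insert_mean,
                 insert_sd = insert_sd, attach_3prime = isTRUE(attach_3prime),
                 run_duration = run_duration, rng_seed = as.integer(rng_seed)),
            class = "captor_sim_config")
}

model_rate_vectors <- function(error_model) {
  list(pm = error_model$p_mismatch, pi = error_model$p_insertion,
       pd = error_model$p_deletion)
}

#' Simulate a sequencing library
#'
#' Each read is a 5' adaptor (drawn from the manifest's expected fractions),
#' an insert sampled uniformly from the sample references, and optionally a
#' 3' adaptor, passed base-by-base through the context error channel scaled
#' by the read's channel multiplier. Half the reads are emitted as reverse
#' complements. Headers carry ONT-style `ch=` and `start_time=` fields; the
#' truth table records both terminal adaptors and the exact injected event
#' counts.
#'
#' @param panel a `captor_panel`.
#' @param manifest a `captor_manifest` (ids must be a subset of the panel).
#' @param sample_refs named character vector of insert references (or FASTA
#'   path).
#' @param error_model a `captor_error_model`.
#' @param pores a `captor_pore_model` (default [pore_model()]).
#' @param config a [sim_config()].
#' @param adaptor_prob,ref_prob optional sampling weight overrides (used by
#'   [simulate_mixture_pair()] to plant batch effects).
#' @return a `captor_library`: list with `fastq` (data.frame of `read_id`,
#'   `header`, `sequence`) and `truth` (per-read ground truth).
#' @export
simulate_library <- function(panel, manifest, sample_refs, error_model,
                             pores = NULL, config = sim_config(),
                             adaptor_prob = NULL, ref_prob = NULL) {
  if (is.character(sample_refs) && length(sample_refs) == 1 &&
      file.exists(sample_refs)) {
    sample_refs <- read_fasta(sample_refs)
  }
  if (length(sample_refs) == 0) stopf("sample_refs must not be empty")
  if (!all(manifest$captor_id %in% panel$id)) {
    stopf("manifest ids must be a subset of panel ids")
  }
  if (is.null(pores)) {
    pores <- pore_model(run_duration = config$run_duration,
                        rng_seed = config$rng_seed)
  }
  refs <- toupper(as.character(sample_refs))
  ref_names <- names(sample_refs)
  if (is.null(ref_names)) ref_names <- sprintf("ref_%d", seq_along(refs))
  rv <- model_rate_vectors(error_model)
  n <- config$n_reads
  seqs <- panel$full_sequence[match(manifest$captor_id, panel$id)]
  ap <- if (is.null(adaptor_prob)) manifest$expected_fraction else adaptor_prob
  rp <- if (is.null(ref_prob)) rep(1, length(refs)) else ref_prob

  with_seed(config$rng_seed, {
    a5 <- sample.int(nrow(manifest), n, replace = TRUE, prob = ap)
    a3 <- if (config$attach_3prime)
      sample.int(nrow(manifest), n, replace = TRUE, prob = ap) else rep(NA_integer_, n)
    ri <- sample.int(length(refs), n, replace = TRUE, prob = rp)
    ilen <- pmin(pmax(round(rnorm(n, config$insert_mean, config$insert_sd)), 0L),
                 nchar(refs)[ri])
    istart <- floor(runif(n) * (nchar(refs)[ri] - ilen + 1)) + 1L
    insert <- substring(refs[ri], istart, istart + ilen - 1L)
    tpl <- paste0(seqs[a5], insert,
                  ifelse(is.na(a3), "", seqs[ifelse(is.na(a3), 1L, a3)]))
    tsec <- runif(n, 0, config$run_duration)
    w <- pores$throughput_weight
    if (all(pores$active_until >= config$run_duration)) {
      ch <- sample(pores$channel_id, n, replace = TRUE, prob = w)
    } else {
      active <- outer(tsec, pores$active_until, `<=`)
      ch <- integer(n)
      for (i in seq_len(n)) {
        ok <- active[i, ]
        if (!any(ok)) ok <- rep(TRUE, nrow(pores))
        ch[i] <- sample(pores$channel_id, 1, prob = w * ok)
      }
    }
    mult <- pores$error_multiplier[match(ch, pores$channel_id)]
    mut <- cpp_mutate_many(tpl, rv$pm, rv$pi, rv$pd, mult)
    rev <- runif(n) < 0.5
    emitted <- mut$sequence
    emitted[rev] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(emitted[rev])))
    read_id <- sprintf("read_%06d", seq_len(n))
    iso <- format(as.POSIXct("2022-01-01", tz = "UTC") + tsec,
                  "%Y-%m-%dT%H:%M:%SZ")
    fastq <- data.frame(
      read_id = read_id,
      header = sprintf("%s ch=%d start_time=%s", read_id, ch, iso),
      sequence = emitted, stringsAsFactors = FALSE)
    truth <- data.frame(
      read_id = read_id,
      captor_id = manifest$captor_id[a5],
      captor_id_3prime = ifelse(is.na(a3), NA_character_,
                                manifest$captor_id[ifelse(is.na(a3), 1L, a3)]),
      strand = ifelse(rev, "-", "+"),
      channel = ch, start_time = tsec,
      error_multiplier = mult,
      insert_ref = ref_names[ri], insert_length = ilen,
      n_sub = mut$n_sub, n_ins = mut$n_ins, n_del = mut$n_del,
      stringsAsFactors = FALSE)
    structure(list(fastq = fastq, truth = truth,
                   panel = panel, manifest = manifest),
              class = "captor_library")
  })
}

#' Simulate reads of a gene-specific control or its accompanying sample
#'
#' Emits full-length reads of a single reference through the context error
#' channel - the desk-scale analogue of sequencing a gene-specific control
#' adaptor (synthetic exon copy) alongside patient fragments of the same
#' exon. Optional variants make a fraction of molecules carry an alternate
#' base at given positions, as a true variant would in the sample but not in
#' the synthetic control.
#'
#' @param reference a single reference sequence (the exon).
#' @param n_reads number of reads.
#' @param error_model a `captor_error_model`.
#' @param variants optional data.frame with `position` (0-based), `alt`
#'   (base), `fraction` (allele fraction of molecules carrying it).
#' @param error_multiplier per-read error scaling (recycled).
#' @param rng_seed integer seed.
#' @return data.frame with `read_id`, `sequence`, `strand`, `n_sub`,
#'   `n_ins`, `n_del` (injected sequencing-error counts; variant bases are
#'   template changes, not errors).
#' @export
simulate_gene_control_reads <- function(reference, n_reads, error_model,
                                        variants = NULL, error_multiplier = 1,
                                        rng_seed = 1L) {
  reference <- check_dna(reference)
  rv <- model_rate_vectors(error_model)
  with_seed(rng_seed, {
    tpl <- rep(reference, n_reads)
    if (!is.null(variants)) {
      for (i in seq_len(nrow(variants))) {
        carry <- runif(n_reads) < variants$fraction[i]
        p <- variants$position[i] + 1L
        substr(tpl[carry], p, p) <- variants$alt[i]
      }
    }
    mut <- cpp_mutate_many(tpl, rv$pm, rv$pi, rv$pd,
                           rep_len(error_multiplier, n_reads))
    rev <- runif(n_reads) < 0.5
    emitted <- mut$sequence
    emitted[rev] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(emitted[rev])))
    data.frame(read_id = sprintf("read_%06d", seq_len(n_reads)),
               sequence = emitted, strand = ifelse(rev, "-", "+"),
               n_sub = mut$n_sub, n_ins = mut$n_ins, n_del = mut$n_del,
               stringsAsFactors = FALSE)
  })
}

#' Simulate paired mixtures with known fold changes
#'
#' Generates replicate libraries from two conditions (A and B) sharing one
#' adaptor master mix. Feature abundances in B equal those in A scaled by
#' `2^fold_change_spec`. Per-library unwanted variation is planted as a
#' one-factor model: each feature and adaptor receives a loading, each
#' library a factor score of magnitude `batch_sd`, and sampling weights are
#' multiplied by `exp(loading * score)`; a per-library depth scalar
#' (`depth_sdlog`) additionally perturbs the read count. Both are recorded
#' in the returned `batch` table.
#'
#' @param panel,manifest,error_model as in [simulate_library()].
#' @param feature_refs named character vector of feature sequences.
#' @param fold_change_spec named numeric of expected log2 fold changes
#'   (names must be feature names; missing features default to 0).
#' @param replicates libraries per condition.
#' @param config a [sim_config()]; `rng_seed` seeds the whole experiment.
#' @param batch_sd standard deviation of the per-library batch factor.
#' @param depth_sdlog sdlog of the per-library depth scalar.
#' @return list with `libraries` (named list of `captor_library`), `design`
#'   (sample table), `expected_log2fc`, and `batch` (planted factors).
#' @export
simulate_mixture_pair <- function(panel, manifest, feature_refs,
                                  fold_change_spec, replicates = 3,
                                  error_model, config = sim_config(),
                                  batch_sd = 0, depth_sdlog = 0) {
  if (replicates < 1) stopf("replicate count must be >= 1")
  if (!all(names(fold_change_spec) %in% names(feature_refs))) {
    stopf("fold_change_spec names features absent from feature_refs")
  }
  spec <- setNames(rep(0, length(feature_refs)), names(feature_refs))
  spec[names(fold_change_spec)] <- fold_change_spec
  nf <- length(feature_refs)
  na <- nrow(manifest)
  plan <- with_seed(config$rng_seed, {
    list(load_f = rnorm(nf), load_a = rnorm(na),
         score = rnorm(2 * replicates, 0, batch_sd),
         depth = exp(rnorm(2 * replicates, 0, depth_sdlog)),
         seeds = sample.int(2^30, 2 * replicates))
  })
  samples <- data.frame(
    sample = sprintf("%s_rep%d", rep(c("A", "B"), each = replicates),
                     rep(seq_len(replicates), 2)),
    condition = rep(c("A", "B"), each = replicates),
    replicate = rep(seq_len(replicates), 2), stringsAsFactors = FALSE)
  base_p <- rep(1, nf)
  libs <- vector("list", nrow(samples))
  names(libs) <- samples$sample
  for (i in seq_len(nrow(samples))) {
    cond_p <- base_p * if (samples$condition[i] == "B") 2^spec else 1
    rp <- cond_p * exp(plan$load_f * plan$score[i])
    ap <- manifest$expected_fraction * exp(plan$load_a * plan$score[i])
    cfg_i <- config
    cfg_i$n_reads <- max(1L, as.integer(round(config$n_reads * plan$depth[i])))
    cfg_i$rng_seed <- plan$seeds[i]
    libs[[i]] <- simulate_library(panel, manifest, feature_refs, error_model,
                                  config = cfg_i,
                                  adaptor_prob = ap / sum(ap),
                                  ref_prob = rp / sum(rp))
  }
  list(libraries = libs, design = samples, expected_log2fc = spec,
       batch = data.frame(sample = samples$sample, score = plan$score,
                          depth_scalar = plan$depth,
                          stringsAsFactors = FALSE))
}
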