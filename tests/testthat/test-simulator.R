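test_that("context error model follows its construction formula", {
  # no slopes, no systematic spread: flat tables at the base rates
  flat <- build_context_error_model(base_mismatch = 0.03,
                                    base_insertion = 0.01,
                                    base_deletion = 0.02, gc_slope = 0,
                                    homopolymer_slope = 0, systematic_sd = 0)
  expect_true(all(flat$p_mismatch == 0.03))
  expect_true(all(flat$p_insertion == 0.01))
  expect_true(all(flat$p_deletion == 0.02))

  # positive GC slope: rates increase monotonically across GC strata
  gc <- build_context_error_model(gc_slope = 0.06, systematic_sd = 0)
  strata <- tapply(gc$p_mismatch, gc$gc_count, mean)
  expect_true(all(diff(strata) > 0))
  expect_gt(gc$p_mismatch[gc$kmer == "GGGCGC"],
            gc$p_mismatch[gc$kmer == "AATATA"])

  # positive homopolymer slope: rates increase with the maximal run
  hp <- build_context_error_model(homopolymer_slope = 0.02, systematic_sd = 0)
  runs <- tapply(hp$p_deletion, hp$max_homopolymer_run, mean)
  expect_true(all(diff(runs) > 0))

  # seed determinism of the systematic component
  m1 <- build_context_error_model(rng_seed = 6)
  m2 <- build_context_error_model(rng_seed = 6)
  expect_identical(m1, m2)
  expect_false(identical(m1$p_mismatch,
                         build_context_error_model(rng_seed = 7)$p_mismatch))

  # heavy clamping is flagged
  expect_warning(build_context_error_model(base_mismatch = 0.49,
                                           systematic_sd = 0.1), "clamped")
  expect_error(build_context_error_model(base_mismatch = 0.6), "0.5")
})

test_that("error-free simulation reproduces adaptors and inserts verbatim", {
  panel <- small_panel()
  man <- build_staggered_manifest(panel$id, group_size = 2, n_levels = 4)
  zero <- build_context_error_model(base_mismatch = 0, base_insertion = 0,
                                    base_deletion = 0, gc_slope = 0,
                                    homopolymer_slope = 0, systematic_sd = 0)
  set.seed(1)
  refs <- setNames(random_dna(2, 200), c("r1", "r2"))
  lib <- simulate_library(panel, man, refs, zero,
                          config = sim_config(n_reads = 50, insert_mean = 60,
                                              insert_sd = 5,
                                              attach_3prime = FALSE,
                                              rng_seed = 2))
  tpl <- ifelse(lib$truth$strand == "-", revcomp(lib$fastq$sequence),
                lib$fastq$sequence)
  adaptor_region <- substring(tpl, 1, 90)
  expect_identical(adaptor_region,
                   panel$full_sequence[match(lib$truth$captor_id, panel$id)])
  expect_true(all(lib$truth$n_sub == 0 & lib$truth$n_ins == 0 &
                    lib$truth$n_del == 0))
})

test_that("adaptor draws follow the manifest's expected fractions", {
  panel <- small_panel()
  man <- build_staggered_manifest(panel$id, group_size = 2, n_levels = 4)
  model <- default_model()
  set.seed(1)
  refs <- setNames(random_dna(2, 200), c("r1", "r2"))
  n <- 20000
  lib <- simulate_library(panel, man, refs, model,
                          config = sim_config(n_reads = n, insert_mean = 40,
                                              insert_sd = 5, rng_seed = 3))
  draws <- table(factor(lib$truth$captor_id, levels = man$captor_id))
  p <- man$expected_fraction
  z <- abs(as.numeric(draws) - n * p) / sqrt(n * p * (1 - p))
  expect_true(all(z < 3.5))
})

test_that("per-read bookkeeping conserves emitted length", {
  panel <- small_panel()
  man <- build_staggered_manifest(panel$id, group_size = 2, n_levels = 4)
  model <- default_model()
  refs <- setNames(random_dna(2, 200), c("r1", "r2"))
  lib <- simulate_library(panel, man, refs, model,
                          config = sim_config(n_reads = 300, rng_seed = 4))
  template_len <- 2 * 90 + lib$truth$insert_length
  expect_equal(nchar(lib$fastq$sequence),
               template_len - lib$truth$n_del + lib$truth$n_ins)
})

test_that("channel multipliers scale injected error rates proportionally", {
  panel <- small_panel()
  man <- build_staggered_manifest(panel$id, group_size = 2, n_levels = 4)
  model <- default_model()
  refs <- setNames(random_dna(2, 200), c("r1", "r2"))
  pm <- data.frame(channel_id = 1:2, error_multiplier = c(1, 3),
                   throughput_weight = c(1, 1), active_until = 8 * 3600)
  class(pm) <- c("captor_pore_model", "data.frame")
  lib <- simulate_library(panel, man, refs, model, pores = pm,
                          config = sim_config(n_reads = 4000, rng_seed = 55))
  tr <- lib$truth
  err <- (tr$n_sub + tr$n_ins + tr$n_del) / (180 + tr$insert_length)
  ratio <- tapply(err, tr$channel, mean)[["2"]] / tapply(err, tr$channel, mean)[["1"]]
  expect_gt(ratio, 2.6)
  expect_lt(ratio, 3.4)
})

test_that("simulation is byte-reproducible for a fixed seed", {
  panel <- small_panel()
  man <- build_staggered_manifest(panel$id, group_size = 2, n_levels = 4)
  model <- default_model()
  refs <- setNames(random_dna(2, 200), c("r1", "r2"))
  l1 <- simulate_library(panel, man, refs, model,
                         config = sim_config(n_reads = 100, rng_seed = 9))
  l2 <- simulate_library(panel, man, refs, model,
                         config = sim_config(n_reads = 100, rng_seed = 9))
  expect_identical(l1$fastq, l2$fastq)
  expect_identical(l1$truth, l2$truth)
  l3 <- simulate_library(panel, man, refs, model,
                         config = sim_config(n_reads = 100, rng_seed = 10))
  expect_false(identical(l1$fastq$sequence, l3$fastq$sequence))
})

test_that("simulated per-6-mer error rates recover the model", {
  # truth-bypass recovery on a 4-adaptor panel at ~400 reads per adaptor
  panel <- design_panel(design_config(n_adaptors = 4, rng_seed = 6))
  model <- build_context_error_model(systematic_sd = 0, rng_seed = 6)
  man <- build_staggered_manifest(panel$id, group_size = 4, n_levels = 1,
                                  fold = 2)
  refs <- c(r1 = random_dna(1, 120))
  pm1 <- data.frame(channel_id = 1L, error_multiplier = 1,
                    throughput_weight = 1, active_until = 8 * 3600)
  class(pm1) <- c("captor_pore_model", "data.frame")
  lib <- simulate_library(panel, man, refs, model, pores = pm1,
                          config = sim_config(n_reads = 1600, insert_mean = 40,
                                              insert_sd = 5, rng_seed = 7))
  profs <- profile_reads(lib$fastq$sequence, lib$truth$captor_id,
                         setNames(panel$full_sequence, panel$id),
                         strand = lib$truth$strand, clip = 160)
  obs <- kmer_table(lapply(profs, profile_rates), panel)

  # expected table: model rates at each position's context, window-averaged
  # identically; tolerance is 3 binomial SE of the window-mean estimator
  exp_profiles <- lapply(seq_len(nrow(panel)), function(a) {
    s <- panel$full_sequence[a]
    b <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T")) - 1L
    ctx <- integer(90); acc <- 0L
    for (i in 1:90) { acc <- bitwAnd(acc * 4L + b[i], 4095L); ctx[i] <- acc + 1L }
    out <- data.frame(position = 0:89, ref_base = strsplit(s, "")[[1]],
                      depth = profs[[panel$id[a]]]$depth,
                      r_mismatch = model$p_mismatch[ctx],
                      r_insertion = model$p_insertion[ctx],
                      r_deletion = model$p_deletion[ctx])
    out$r_total <- out$r_mismatch + out$r_insertion + out$r_deletion
    out
  })
  names(exp_profiles) <- panel$id
  expd <- kmer_table(exp_profiles, panel)
  m <- merge(obs, expd, by = "kmer", suffixes = c("_obs", "_exp"))
  depth_by <- vapply(panel$id, function(id) mean(profs[[id]]$depth),
                     numeric(1))
  se <- sqrt(m$mean_r_total_exp * (1 - m$mean_r_total_exp) /
               (6 * min(depth_by)))
  z <- abs(m$mean_r_total_obs - m$mean_r_total_exp) / se
  expect_gte(mean(z <= 3), 0.95)
})

test_that("mixture pairs plant the requested fold changes", {
  panel <- small_panel()
  man <- build_staggered_manifest(panel$id, group_size = 2, n_levels = 4)
  model <- default_model()
  feats <- test_features()

  # zero spec: A and B feature draws come from one distribution
  mp0 <- simulate_mixture_pair(panel, man, feats,
                               setNames(rep(0, 8), names(feats)),
                               replicates = 1, error_model = model,
                               config = sim_config(n_reads = 3000,
                                                   rng_seed = 20))
  ta <- table(factor(mp0$libraries$A_rep1$truth$insert_ref, names(feats)))
  tb <- table(factor(mp0$libraries$B_rep1$truth$insert_ref, names(feats)))
  expect_gt(suppressWarnings(chisq.test(cbind(ta, tb))$p.value), 1e-4)

  # +/-1 log2 fold changes appear as ~2x and ~0.5x draw ratios
  mp <- simulate_mixture_pair(panel, man, feats, c(f1 = 1, f2 = -1),
                              replicates = 1, error_model = model,
                              config = sim_config(n_reads = 12000,
                                                  rng_seed = 21))
  ta <- table(factor(mp$libraries$A_rep1$truth$insert_ref, names(feats)))
  tb <- table(factor(mp$libraries$B_rep1$truth$insert_ref, names(feats)))
  fa <- ta / sum(ta); fb <- tb / sum(tb)
  expect_equal(unname(fb["f1"] / fa["f1"]), 2, tolerance = 0.25)
  expect_equal(unname(fb["f2"] / fa["f2"]), 0.5, tolerance = 0.25)

  # replicates differ in reads but share the truth spec
  mp3 <- simulate_mixture_pair(panel, man, feats, c(f1 = 1), replicates = 3,
                               error_model = model,
                               config = sim_config(n_reads = 200,
                                                   rng_seed = 22))
  expect_length(mp3$libraries, 6)
  expect_false(identical(mp3$libraries$A_rep1$fastq$sequence,
                         mp3$libraries$A_rep2$fastq$sequence))
  expect_equal(mp3$expected_log2fc[["f1"]], 1)
  expect_error(simulate_mixture_pair(panel, man, feats, c(f1 = 1),
                                     replicates = 0, error_model = model),
               "replicate")
  expect_error(simulate_mixture_pair(panel, man, feats, c(nope = 1),
                                     replicates = 2, error_model = model),
               "absent")
})

test_that("gene-control reads carry variants at the requested fraction", {
  set.seed(30)
  exon <- random_dna(1, 200)
  zero <- build_context_error_model(base_mismatch = 0, base_insertion = 0,
                                    base_deletion = 0, gc_slope = 0,
                                    homopolymer_slope = 0, systematic_sd = 0)
  ex_chars <- strsplit(exon, "")[[1]]
  alt <- setdiff(c("A", "C", "G", "T"), ex_chars[51])[1]
  reads <- simulate_gene_control_reads(exon, 2000, zero,
                                       variants = data.frame(position = 50L,
                                                             alt = alt,
                                                             fraction = 0.4),
                                       rng_seed = 31)
  tpl <- ifelse(reads$strand == "-", revcomp(reads$sequence), reads$sequence)
  carried <- substring(tpl, 51, 51) == alt
  expect_equal(mean(carried), 0.4, tolerance = 0.04)
  expect_true(all(nchar(reads$sequence) == 200))
})
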