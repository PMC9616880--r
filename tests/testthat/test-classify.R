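test_that("ONT-style headers parse permissively", {
  m <- parse_read_header("@r1 ch=505 start_time=2021-01-01T00:10:00Z")
  expect_equal(m$read_id, "r1")
  expect_equal(m$channel, 505L)
  expect_equal(as.numeric(m$start_time),
               as.numeric(as.POSIXct("2021-01-01 00:10:00", tz = "UTC")))

  bare <- parse_read_header("@r2")
  expect_equal(bare$read_id, "r2")
  expect_true(is.na(bare$channel))
  expect_true(is.na(bare$start_time))

  expect_warning(bad <- parse_read_header("@r3 ch=abc"), "malformed")
  expect_true(is.na(bad$channel))

  pf <- parse_read_header("@r4 ch=2 pass=true")
  expect_true(pf$pass_flag)
})

test_that("clip_read keeps the leading bases", {
  set.seed(1)
  long <- random_dna(1, 800)
  expect_equal(clip_read(long), substring(long, 1, 500))
  short <- random_dna(1, 90)
  expect_equal(clip_read(short), short)
  expect_equal(nchar(clip_read(long, 1)), 1)
  expect_error(clip_read(long, 0), ">= 1")
})

test_that("semi-global aligner handles exact, substituted and padded cases", {
  set.seed(2)
  ref <- random_dna(1, 20)
  query <- paste0("TTTTT", ref, "GGGGG")
  a <- semiglobal_align(query, ref)
  expect_equal(a$edit_distance, 0)
  expect_equal(a$identity, 1)
  expect_equal(a$query_start, 5)
  expect_equal(a$query_end, 25)

  # one substitution at ref position 3
  q2 <- "ACGAACGT"
  a2 <- semiglobal_align(paste0("TT", q2, "TT"), "ACGTACGT")
  expect_equal(a2$edit_distance, 1)
  mm <- a2$aligned_pairs[a2$aligned_pairs$op == "mismatch", ]
  expect_equal(mm$ref_pos, 3)

  # ref longer than the whole query: the missing bases are deletions
  a3 <- semiglobal_align("AA", "AAAA")
  expect_equal(a3$edit_distance, 2)
  expect_equal(a3$n_deletion, 2)
})

test_that("aligner matches the exhaustive substring oracle", {
  # exhaustive over a two-letter alphabet
  refs <- all_strings(c("A", "C"), 4)
  queries <- all_strings(c("A", "C"), 5)
  for (r in refs[seq(1, length(refs), 2)]) {
    for (q in queries[seq(1, length(queries), 3)]) {
      expect_equal(semiglobal_align(q, r)$edit_distance, oracle_fit_dist(r, q),
                   info = paste(r, q))
    }
  }
  # random DNA pairs at the contract sizes
  set.seed(3)
  for (i in 1:100) {
    r <- random_dna(1, sample(1:6, 1))
    q <- random_dna(1, sample(1:8, 1))
    a <- semiglobal_align(q, r)
    expect_equal(a$edit_distance, oracle_fit_dist(r, q), info = paste(r, q))
    # internal consistency of the reported alignment
    expect_equal(a$edit_distance, a$n_mismatch + a$n_insertion + a$n_deletion)
    expect_equal(a$identity, a$n_match / max(1, a$n_match + a$n_mismatch +
                                               a$n_insertion + a$n_deletion))
    rp <- a$aligned_pairs$ref_pos[a$aligned_pairs$op != "insertion"]
    expect_true(all(diff(rp) > 0) || length(rp) < 2)
  }
})

test_that("reads classify to their adaptor in either orientation", {
  panel <- small_panel()
  set.seed(4)
  insert <- random_dna(1, 60)
  read <- paste0(panel$full_sequence[7], insert)
  cr <- classify_read(read, panel)
  expect_equal(cr$captor_id, "CAPTOR_07")
  expect_equal(cr$orientation, "+")
  expect_equal(cr$identity, 1)
  expect_equal(cr$per_read_error, 0)

  rc <- classify_read(revcomp(paste0(panel$full_sequence[3], insert)), panel)
  expect_equal(rc$captor_id, "CAPTOR_03")
  expect_equal(rc$orientation, "-")

  # orientation invariance: flipping the read flips only the orientation
  r2 <- classify_read(revcomp(read), panel)
  expect_equal(r2$captor_id, "CAPTOR_07")
  expect_equal(r2$orientation, "-")
})

test_that("random reads and exact ties are unclassified", {
  panel <- small_panel()
  set.seed(42)
  rnd <- random_dna(100, 150)
  cl <- classify_reads(rnd, panel)
  expect_true(all(cl$reads$captor_id == "UNCLASSIFIED"))

  # a read whose variable region is equidistant from two adaptors
  c5 <- strrep("A", 30); c3 <- strrep("T", 30)
  vA <- paste0(strrep("C", 10), strrep("G", 20))
  vB <- paste0(strrep("C", 20), strrep("G", 10))   # distance 10 from vA
  toy <- make_panel(c5, c(vA, vB), c3)
  vmid <- paste0(strrep("C", 15), strrep("G", 15)) # distance 5 from both
  tie_read <- paste0(c5, vmid, c3, "ACGTACGTAC")
  tie <- classify_read(tie_read, toy)
  expect_equal(tie$captor_id, "UNCLASSIFIED")
})

test_that("classification recovers truth on simulated libraries", {
  panel <- default_panel()
  man <- build_staggered_manifest(panel$id)
  model <- default_model()
  set.seed(13)
  refs <- setNames(random_dna(4, 300), paste0("f", 1:4))
  pm1 <- data.frame(channel_id = 1L, error_multiplier = 1,
                    throughput_weight = 1, active_until = 8 * 3600)
  class(pm1) <- c("captor_pore_model", "data.frame")
  lib <- simulate_library(panel, man, refs, model, pores = pm1,
                          config = sim_config(n_reads = 5000, insert_mean = 80,
                                              insert_sd = 15, rng_seed = 14))
  cl <- classify_reads(lib$fastq, panel)
  cls <- cl$reads$captor_id
  # a read may legitimately classify by either of its two terminal adaptors
  ok <- cls == lib$truth$captor_id | cls == lib$truth$captor_id_3prime
  expect_gte(mean(ok), 0.99)
  expect_equal(sum(cls != "UNCLASSIFIED" & !ok), 0)
})

test_that("event accumulation attributes operations per the pileup convention", {
  panel <- small_panel()
  ref <- panel$full_sequence[1]
  insert <- strrep("ACGT", 10)

  # ten error-free reads
  alns <- lapply(1:10, function(i) {
    a <- semiglobal_align(paste0(ref, insert), ref)
    a$captor_id <- panel$id[1]
    a
  })
  prof <- accumulate_events(alns, panel)[[1]]
  expect_true(all(prof$n_match == 10))
  expect_true(all(prof$n_mismatch == 0))
  expect_true(all(prof$depth == 10))

  # one substitution at position 40 among ten reads
  mut <- ref
  substr(mut, 41, 41) <- setdiff(c("A", "C", "G", "T"),
                                 substring(ref, 41, 41))[1]
  alns[[1]] <- semiglobal_align(paste0(mut, insert), ref)
  alns[[1]]$captor_id <- panel$id[1]
  prof2 <- accumulate_events(alns, panel)[[1]]
  expect_equal(prof2$n_mismatch[prof2$position == 40], 1)
  expect_equal(prof2$depth[prof2$position == 40], 10)

  # deletion of positions 50-51 in one read
  del <- paste0(substring(ref, 1, 50), substring(ref, 53))
  alns[[2]] <- semiglobal_align(paste0(del, insert), ref)
  alns[[2]]$captor_id <- panel$id[1]
  prof3 <- accumulate_events(alns, panel)[[1]]
  expect_equal(prof3$n_deletion[prof3$position %in% c(50, 51)], c(1, 1))
  # event conservation at every position
  expect_equal(prof3$n_match + prof3$n_mismatch + prof3$n_deletion,
               prof3$depth)

  # insertion attributed to the preceding reference position (the inserted
  # base differs from both neighbours so its placement is unambiguous)
  ins_base <- setdiff(c("A", "C", "G", "T"),
                      c(substring(ref, 60, 60), substring(ref, 61, 61)))[1]
  ins <- paste0(substring(ref, 1, 60), ins_base, substring(ref, 61))
  a_ins <- semiglobal_align(paste0(ins, insert), ref)
  ips <- a_ins$aligned_pairs[a_ins$aligned_pairs$op == "insertion", ]
  expect_equal(nrow(ips), 1)
  expect_equal(ips$ref_pos, 59)

  alns_bad <- list(structure(list(captor_id = "nope",
                                  aligned_pairs = data.frame()),
                             class = "captor_alignment"))
  expect_error(accumulate_events(alns_bad, panel), "unknown adaptor")
})

test_that("batch classification and per-read accumulation agree", {
  panel <- small_panel()
  man <- build_staggered_manifest(panel$id, group_size = 2, n_levels = 4)
  model <- default_model()
  set.seed(5)
  refs <- setNames(random_dna(2, 150), c("r1", "r2"))
  lib <- simulate_library(panel, man, refs, model,
                          config = sim_config(n_reads = 60, rng_seed = 6))
  cl <- classify_reads(lib$fastq, panel)
  keep <- cl$reads$captor_id != "UNCLASSIFIED"
  alns <- lapply(which(keep), function(i) {
    classify_read(lib$fastq$sequence[i], panel)$alignment
  })
  profs <- accumulate_events(alns, panel)
  for (id in panel$id) {
    expect_equal(profs[[id]], cl$profiles[[id]], info = id)
  }
  # conservation holds on the batch profiles
  for (id in panel$id) {
    p <- cl$profiles[[id]]
    expect_equal(p$n_match + p$n_mismatch + p$n_deletion, p$depth)
  }
})

test_that("per-read error distinguishes variable region from full adaptor", {
  panel <- small_panel()
  ref <- panel$full_sequence[1]
  # plant 3 substitutions inside the variable region (positions 35, 40, 45)
  mut <- ref
  for (p in c(36, 41, 46)) {
    substr(mut, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substring(ref, p, p))[1]
  }
  aln <- semiglobal_align(paste0(mut, strrep("ACGT", 8)), ref)
  expect_equal(per_read_error(aln, panel), 3 / 30)
  expect_equal(per_read_error(aln, panel, region = "full"), 3 / 90)
  clean <- semiglobal_align(paste0(ref, "ACGTACGT"), ref)
  expect_equal(per_read_error(clean, panel), 0)
})

test_that("inserts are assigned to their source features", {
  panel <- small_panel()
  feats <- test_features()
  set.seed(7)

  # verbatim insert
  read <- paste0(panel$full_sequence[2], feats[["f2"]])
  cl <- classify_reads(read, panel)
  asn <- assign_inserts(read, cl, feats)
  expect_equal(asn$feature_id, "f2")
  expect_equal(asn$aligned_bases, 150L)

  # insert with ~5% errors still assigns (features are ~75% divergent)
  noisy <- strsplit(feats[["f2"]], "")[[1]]
  idx <- sample(150, 8)
  noisy[idx] <- vapply(noisy[idx], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  read2 <- paste0(panel$full_sequence[2], paste(noisy, collapse = ""))
  asn2 <- assign_inserts(read2, classify_reads(read2, panel), feats)
  expect_equal(asn2$feature_id, "f2")

  # an adaptor-only read has no insert
  read3 <- panel$full_sequence[3]
  asn3 <- assign_inserts(read3, classify_reads(read3, panel), feats)
  expect_equal(asn3$feature_id, "UNASSIGNED")

  # doubly-ligated read: trailing adaptor is trimmed before assignment
  read4 <- paste0(panel$full_sequence[2], feats[["f3"]],
                  panel$full_sequence[5])
  asn4 <- assign_inserts(read4, classify_reads(read4, panel), feats)
  expect_equal(asn4$feature_id, "f3")
})

test_that("profile_reads matches accumulate_events on known assignments", {
  panel <- small_panel()
  refs <- setNames(panel$full_sequence[1:2], panel$id[1:2])
  set.seed(8)
  reads <- c(paste0(refs[[1]], "ACGT"), refs[[2]], revcomp(refs[[1]]))
  profs <- profile_reads(reads, c(panel$id[1], panel$id[2], panel$id[1]),
                         refs, strand = c("+", "+", "-"))
  expect_equal(sum(profs[[1]]$depth), 2 * 90)
  expect_true(all(profs[[1]]$n_match == 2))
  expect_true(all(profs[[2]]$n_match == 1))
  expect_error(profile_reads(reads, c("x", "y", "z"), refs), "absent")
})
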