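# Umbrella pipeline: design -> mix -> simulate (or ingest) -> classify ->
# profile -> ladder, with a JSON artifact manifest.

#' Default pipeline configuration
#'
#' Every stage block mirrors that module's documented defaults; the demo
#' scale (a 16-adaptor panel, 2000 reads) completes in well under a minute
#' on one CPU.
#'
#' @param rng_seed global seed; per-stage seeds are derived from it.
#' @return nested configuration list.
#' @export
demo_run_config <- function(rng_seed = 1L) {
  list(
    rng_seed = as.integer(rng_seed),
    design = list(n_adaptors = 16, k = 6),
    mixture = list(group_size = 4, n_levels = 4, fold = 2),
    simulate = list(n_reads = 2000, insert_mean = 80, insert_sd = 15),
    classify = list(clip = 500, min_identity = 0.7),
    profile = list(min_depth = 10),
    fastq = NULL  # set to a path to analyse real reads instead of simulating
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Run the full CAPTOR pipeline
#'
#' Executes design, master-mix construction, simulation (or FASTQ
#' ingestion), classification, error profiling and the quantitative ladder,
#' writing all artifacts plus a JSON manifest to `outdir`. Identical
#' configuration and seed give identical artifacts.
#'
#' @param config configuration list (see [demo_run_config()]) or a YAML
#'   path; missing entries fall back to the demo defaults.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list of in-memory results (`panel`, `manifest`,
#'   `classification`, `kmers`, `ladder`, `files`).
#' @export
run_pipeline <- function(config = demo_run_config(), outdir = tempfile("captor_run_")) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file '%s' not found", config)
    config <- yaml::read_yaml(config)
  }
  config <- merge_config(demo_run_config(), config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$rng_seed
  path <- function(...) file.path(outdir, ...)

  cfg <- do.call(design_config, c(config$design, list(rng_seed = seed)))
  panel <- design_panel(cfg)
  write_panel(panel, path("panel.fasta"))

  manifest <- do.call(build_staggered_manifest,
                      c(list(captor_ids = panel$id), config$mixture))
  write_manifest(manifest, path("manifest.tsv"))

  if (is.null(config$fastq)) {
    refs <- with_seed(seed + 1, setNames(
      vapply(1:4, function(i) paste(sample(DNA_BASES, 400, TRUE), collapse = ""),
             character(1)),
      sprintf("feature_%d", 1:4)))
    model <- build_context_error_model(rng_seed = seed + 2)
    sim <- do.call(sim_config, c(config$simulate, list(rng_seed = seed + 3)))
    lib <- simulate_library(panel, manifest, refs, model, config = sim)
    write_fastq(lib$fastq, path("reads.fastq"))
    write_tsv(lib$truth, path("truth.tsv"))
    fastq <- lib$fastq
  } else {
    if (!file.exists(config$fastq)) {
      stopf("input FASTQ '%s' not found", config$fastq)
    }
    fastq <- read_fastq(config$fastq)
  }

  cl <- classify_reads(fastq, panel, clip = config$classify$clip,
                       min_identity = config$classify$min_identity)
  write_tsv(cl$reads, path("classification.tsv"))

  profiles <- lapply(cl$profiles, profile_rates,
                     min_depth = config$profile$min_depth)
  kmers <- kmer_table(profiles, panel)
  write_tsv(kmers, path("kmer_errors.tsv"))

  counts <- captor_counts(cl)
  ladder <- tryCatch(ladder_fit(counts, manifest), error = function(e) NULL)
  if (!is.null(ladder)) {
    write_json(ladder[c("slope", "intercept", "r_squared",
                        "slope_ci_halfwidth", "n_points")], path("ladder.json"))
  }

  write_json(list(package = "captor",
                  version = as.character(utils::packageVersion("captor")),
                  rng_seed = seed, artifacts = list.files(outdir)),
             path("run_manifest.json"))
  files <- list.files(outdir)
  invisible(list(panel = panel, manifest = manifest, classification = cl,
                 kmers = kmers, ladder = ladder, counts = counts,
                 outdir = outdir, files = files))
}
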