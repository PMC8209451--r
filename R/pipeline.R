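# End-to-end pipeline: simulate -> clean -> map -> termini -> coverage,
# with deterministic per-stage seeds derived from one global seed. The
# exported functions are the primary interface; exec/flds is a thin
# command-line wrapper over them.

#' Default end-to-end run configuration
#'
#' Stage parameters mirror the knobs of [community_config()],
#' [library_config()], [clean_reads()] and [call_completeness()]; every
#' randomised stage receives a seed derived deterministically from the
#' global `seed`.
#'
#' @param seed Global integer seed.
#' @param ... Overrides for any default entry (see the returned list).
#' @return Named list of class `run_config`.
#' @export
run_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # community
    n_viruses = 4, segments_per_virus = c(1, 3),
    genome_length = c(1000, 3000), shared_terminus_length = 20,
    abundance_span = 1,
    # library
    n_pairs = 8000, mean_fragment_bp = 300, read_length = 300,
    error_rate = 0.002, ligation_efficiency = 0.9, terminal_enrichment = 50,
    dimer_rate = 0.02, duplicate_rate = 0.05, low_quality_rate = 0.05,
    # cleaning
    window = 4, qv_threshold = 20, min_len = 50, dust_threshold = 7,
    subsample_n = NULL,
    # terminus / coverage
    tolerance_bp = 5, alpha = 0.05, breadth_threshold = 0.95)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML-compatible key/value file
#' @param path Config file.
#' @return `run_config` list.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the full pipeline on a simulated library
#'
#' Executes simulate, clean, map (internal seed-and-extend mapper),
#' terminus calling and coverage in order, writing every report into
#' `out_dir`. All randomness derives from `config$seed`, so a repeated run
#' produces an identical report bundle.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with `community`, `sim`, `clean`, `alignments`,
#'   `calls`, `coverage`, `stats`, and `files` (paths written).
#' @export
run_all <- function(config = run_config(), out_dir = tempfile("flds_run_"),
                    quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (config$n_pairs <= 0) stop("config error: n_pairs must be positive")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  ccfg <- community_config(
    n_viruses = config$n_viruses,
    segments_per_virus = config$segments_per_virus,
    genome_length = config$genome_length,
    shared_terminus_length = config$shared_terminus_length,
    abundance_span = config$abundance_span,
    seed = derive_seed(config$seed, 1))
  community <- generate_community(ccfg)
  say("community: %d segments", length(community$segments))

  lcfg <- library_config(
    n_pairs = config$n_pairs, mean_fragment_bp = config$mean_fragment_bp,
    read_length = config$read_length, error_rate = config$error_rate,
    ligation_efficiency = config$ligation_efficiency,
    terminal_enrichment = config$terminal_enrichment,
    dimer_rate = config$dimer_rate, duplicate_rate = config$duplicate_rate,
    low_quality_rate = config$low_quality_rate,
    seed = derive_seed(config$seed, 2))
  sim <- simulate_library(community, lcfg)
  say("simulated %d read pairs", nrow(sim$r1))

  clean <- clean_reads(sim$r1, sim$r2, adaptors = lcfg$adaptors,
                       window = config$window, threshold = config$qv_threshold,
                       min_len = config$min_len,
                       dust_threshold = config$dust_threshold,
                       subsample_n = config$subsample_n,
                       seed = derive_seed(config$seed, 3))
  say("clean pairs: %d of %d raw", clean$counters$clean, clean$counters$raw)

  aln <- map_clean_pairs(clean, community$segments)
  say("mapped %d of %d clean mates", nrow(aln), 2L * nrow(clean$r1))

  ref_lengths <- stats::setNames(Biostrings::width(community$segments),
                                 names(community$segments))
  calls <- call_completeness(aln, ref_lengths,
                             tolerance_bp = config$tolerance_bp,
                             alpha = config$alpha)
  say("complete segments: %d of %d",
      sum(calls$status[calls$end == "five_prime"] == "complete"),
      length(ref_lengths))

  cov <- depth_breadth(aln, ref_lengths)
  stats_tab <- assembly_stats(community$segments)

  files <- c(write_simulation(sim, community, file.path(out_dir, "sim")),
             report = file.path(out_dir, "composition.tsv"),
             report_json = file.path(out_dir, "composition.json"),
             sam = file.path(out_dir, "alignments.sam"),
             calls = file.path(out_dir, "calls.tsv"),
             coverage = file.path(out_dir, "coverage.tsv"),
             stats = file.path(out_dir, "stats.tsv"),
             config = file.path(out_dir, "config.yaml"))
  utils::write.table(clean$report, files[["report"]], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(clean$counters, files[["report_json"]],
                       auto_unbox = TRUE, digits = NA)
  write_sam(aln, ref_lengths, files[["sam"]])
  utils::write.table(calls, files[["calls"]], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(cov, files[["coverage"]], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(stats_tab, files[["stats"]], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  yaml::write_yaml(unclass(config), files[["config"]])

  invisible(list(community = community, sim = sim, clean = clean,
                 alignments = aln, calls = calls, coverage = cov,
                 stats = stats_tab, files = files))
}
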