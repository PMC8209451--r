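# Synthetic FLDS library simulator: a segmented RNA viral community, dsRNA
# fragmentation, 3'-adaptor ligation, PCR artifacts and 2x300 bp paired-end
# reads, with per-read ground truth. Stands in for real MiSeq data so every
# downstream stage is testable end to end.

#' Default cDNA-synthesis adaptor set
#'
#' `u2` is the 20-nt oligonucleotide ligated to the 3' termini of sheared
#' dsRNA; `u2_comp` is its reverse complement (the cDNA-synthesis primer);
#' `upm` is the template-switching universal primer appended at the 5' side
#' of the original strand (kit component; the default is the public SMARTer
#' 25-mer and is freely configurable — only its detectability matters).
#'
#' @param u2,upm Override adaptor sequences.
#' @return List with elements `u2`, `u2_comp`, `upm`, `upm_comp`.
#' @export
default_adaptors <- function(u2 = "GACGTAAGAACGTCGCACCA",
                             upm = "AAGCAGTGGTATCAACGCAGAGTAC") {
  list(u2 = u2, u2_comp = reverse_complement(u2),
       upm = upm, upm_comp = reverse_complement(upm))
}

#' Configuration for a synthetic RNA viral community
#'
#' @param n_viruses Number of viruses.
#' @param segments_per_virus Integer range `c(min, max)`; each virus gets a
#'   uniform draw of genome segments.
#' @param genome_length Range `c(min, max)` of segment lengths (bp).
#' @param shared_terminus_length Length (bp) of the terminal blocks shared by
#'   all segments of one virus (the FLDS signature that groups segments);
#'   must be below half the minimum segment length.
#' @param abundance_span Orders of magnitude spanned by per-segment
#'   log-uniform abundances (2 emulates a community spread over >= 2 orders).
#' @param seed Integer seed; the community is a pure function of its config.
#' @return Object of class `community_config`.
#' @export
community_config <- function(n_viruses = 6, segments_per_virus = c(1, 5),
                             genome_length = c(1000, 5000),
                             shared_terminus_length = 20,
                             abundance_span = 2, seed = 1) {
  stopifnot(n_viruses >= 1, length(segments_per_virus) == 2,
            all(segments_per_virus >= 1),
            segments_per_virus[1] <= segments_per_virus[2],
            length(genome_length) == 2, all(genome_length > 0),
            genome_length[1] <= genome_length[2],
            shared_terminus_length >= 0, abundance_span >= 0)
  if (shared_terminus_length >= genome_length[1] / 2) {
    stop("shared_terminus_length must be < min genome length / 2")
  }
  structure(list(n_viruses = as.integer(n_viruses),
                 segments_per_virus = as.integer(segments_per_virus),
                 genome_length = as.integer(genome_length),
                 shared_terminus_length = as.integer(shared_terminus_length),
                 abundance_span = abundance_span,
                 seed = as.integer(seed)),
            class = "community_config")
}

random_dna <- function(n_bases) {
  if (n_bases <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n_bases, replace = TRUE), collapse = "")
}

# Uniform integer in [lo, hi] (safe for lo == hi, unlike sample(x, 1)).
sample_range <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

#' Generate a synthetic segmented RNA viral community
#'
#' Segments of one virus share identical terminal blocks at both ends
#' (length `shared_terminus_length`); per-segment abundances are log-uniform
#' over `abundance_span` orders of magnitude and normalised to sum to 1.
#' Deterministic for a fixed config.
#'
#' @param config A [community_config()].
#' @return List with `segments` (named `DNAStringSet`), `abundance` (named,
#'   sums to 1) and `termini` (data.frame: `ref_id`, `virus`, `length`,
#'   `five_prime`, `three_prime` 0-based positions).
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "community_config"))
  with_seed(config$seed, {
    segs <- character(0); virus <- character(0)
    for (v in seq_len(config$n_viruses)) {
      nseg <- sample_range(config$segments_per_virus[1],
                           config$segments_per_virus[2])
      k <- config$shared_terminus_length
      left <- random_dna(k)
      right <- random_dna(k)
      for (s in seq_len(nseg)) {
        len <- sample_range(config$genome_length[1], config$genome_length[2])
        core <- random_dna(len - 2L * k)
        segs <- c(segs, paste0(left, core, right))
        virus <- c(virus, sprintf("v%02d", v))
      }
    }
    ids <- sprintf("%ss%02d", virus, stats::ave(seq_along(virus), virus,
                                                FUN = seq_along))
    names(segs) <- ids
    ab <- 10^stats::runif(length(segs), -config$abundance_span, 0)
    ab <- ab / sum(ab)
    names(ab) <- ids
    lens <- nchar(segs)
    list(segments = Biostrings::DNAStringSet(segs),
         abundance = ab,
         termini = data.frame(ref_id = ids, virus = virus, length = lens,
                              five_prime = 0L, three_prime = lens - 1L,
                              stringsAsFactors = FALSE))
  })
}

#' Configuration for one simulated FLDS sequencing library
#'
#' Defaults describe a well-behaved "1 ng input" library sequenced 2x300 bp.
#' PCR cycles map to a duplicate rate through the toy proxy
#' `1 - 0.5^(cycles - 25)` (25 cycles as reference) only when
#' `duplicate_rate` is not given explicitly.
#'
#' @param input_mass_pg Nominal dsRNA input mass (informational label).
#' @param mean_fragment_bp Mean sheared-fragment length; lengths are
#'   log-normal with `fragment_sd_log` sd in log space.
#' @param fragment_sd_log Log-space sd of fragment lengths.
#' @param ligation_efficiency Probability a fragment carries the ligated U2
#'   adaptor (and hence a countable junction).
#' @param terminal_enrichment Over-sampling multiplier for fragments whose
#'   3' end abuts a true genome terminus; models the terminal read pile-up
#'   that makes terminus calling possible.
#' @param pcr_cycles PCR cycle count (used only via the duplicate proxy).
#' @param duplicate_rate Probability a pair is an exact PCR copy.
#' @param dimer_rate Probability a pair is an adaptor self-ligation product.
#' @param low_quality_rate Probability a pair gets a collapsed-quality 3'
#'   tail (exercises quality trimming).
#' @param read_length Read length (bp), default 300 (2x300 chemistry).
#' @param error_rate Per-base substitution probability.
#' @param n_pairs Number of read pairs to emit.
#' @param min_fragment_bp Lower clamp on fragment length.
#' @param adaptors Adaptor set, see [default_adaptors()].
#' @param seed Integer seed.
#' @return Object of class `library_config`.
#' @export
library_config <- function(input_mass_pg = 1000, mean_fragment_bp = 300,
                           fragment_sd_log = 0.35, ligation_efficiency = 0.9,
                           terminal_enrichment = 50, pcr_cycles = 25,
                           duplicate_rate = NULL, dimer_rate = 0.01,
                           low_quality_rate = 0.05, read_length = 300,
                           error_rate = 0.002, n_pairs = 10000,
                           min_fragment_bp = 30,
                           adaptors = default_adaptors(), seed = 1) {
  if (is.null(duplicate_rate)) {
    duplicate_rate <- max(0, 1 - 0.5^(pcr_cycles - 25))
  }
  probs <- c(ligation_efficiency, duplicate_rate, dimer_rate,
             low_quality_rate, error_rate)
  stopifnot(all(probs >= 0), all(probs <= 1), read_length > 0, n_pairs >= 0,
            mean_fragment_bp > 0, terminal_enrichment >= 1,
            dimer_rate + duplicate_rate + low_quality_rate < 1)
  structure(list(input_mass_pg = input_mass_pg,
                 mean_fragment_bp = mean_fragment_bp,
                 fragment_sd_log = fragment_sd_log,
                 ligation_efficiency = ligation_efficiency,
                 terminal_enrichment = terminal_enrichment,
                 pcr_cycles = pcr_cycles, duplicate_rate = duplicate_rate,
                 dimer_rate = dimer_rate, low_quality_rate = low_quality_rate,
                 read_length = as.integer(read_length),
                 error_rate = error_rate, n_pairs = as.integer(n_pairs),
                 min_fragment_bp = as.integer(min_fragment_bp),
                 adaptors = adaptors, seed = as.integer(seed)),
            class = "library_config")
}

#' Draw sheared dsRNA fragments from one genome segment
#'
#' Fragment lengths are log-normal around `mean_fragment_bp`; each fragment
#' comes from the plus or minus strand with equal probability. A fragment
#' whose 3' end (the end that receives the U2 adaptor) coincides with the
#' strand's true 3' terminus is over-sampled by `terminal_enrichment`
#' relative to any single interior placement. The terminal decision is a
#' threshold on one uniform draw per fragment, so for a fixed seed the set
#' of terminal fragments grows monotonically with the enrichment factor.
#'
#' @param segment_length Segment length (bp).
#' @param n Number of fragments.
#' @param mean_fragment_bp,fragment_sd_log,min_fragment_bp Length model.
#' @param terminal_enrichment Enrichment multiplier (1 = uniform placement).
#' @param seed Optional seed (NULL inherits the caller's RNG stream).
#' @return data.frame with 0-based half-open `start`, `end`, `strand` and
#'   logical `terminal`.
#' @export
draw_fragments <- function(segment_length, n, mean_fragment_bp = 300,
                           fragment_sd_log = 0.35, min_fragment_bp = 30,
                           terminal_enrichment = 50, seed = NULL) {
  with_seed(seed, {
    len <- pmin(pmax(round(stats::rlnorm(n, log(mean_fragment_bp),
                                         fragment_sd_log)),
                     min_fragment_bp), segment_length)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    m <- segment_length - len + 1L          # placements per fragment
    u_term <- stats::runif(n)
    u_pos <- stats::runif(n)
    p_term <- terminal_enrichment / (terminal_enrichment + pmax(m - 1L, 0L))
    terminal <- u_term < p_term | m == 1L
    # interior placement: any start except the terminal-abutting one
    interior <- floor(u_pos * pmax(m - 1L, 1L))  # 0 .. m-2
    start <- integer(n)
    plus <- strand == "+"
    # plus-strand 3' end is the segment right end -> terminal start = L - len;
    # minus-strand 3' end is coordinate 0 -> terminal start = 0
    start[plus] <- ifelse(terminal[plus], segment_length - len[plus],
                          interior[plus])
    start[!plus] <- ifelse(terminal[!plus], 0L, interior[!plus] + 1L)
    data.frame(start = as.integer(start),
               end = as.integer(start + len),
               strand = strand, terminal = terminal,
               stringsAsFactors = FALSE)
  })
}

# Quality string models, cached per read length. Normal reads: Q37 decaying
# linearly to Q30 at the 3' end (never trimmable); low-quality reads: Q37
# collapsing to Q8 from ~10% into the read (always trimmed short).
qual_string <- function(lens, low = FALSE) {
  ulen <- sort(unique(lens))
  make <- function(l) {
    if (l == 0L) return("")
    pos <- seq_len(l) - 1L
    if (low) {
      q <- ifelse(pos < max(1L, round(0.1 * l)), 37L, 8L)
    } else {
      q <- 37L - round(7 * pos / max(1L, l - 1L))
    }
    int_to_phred(q)
  }
  tab <- vapply(ulen, make, "")
  tab[match(lens, ulen)]
}

# Inject substitution errors at rate e per base across a character vector of
# reads; operates on the concatenated byte stream for speed.
inject_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || !length(seqs)) return(seqs)
  lens <- nchar(seqs)
  total <- sum(lens)
  n_err <- stats::rbinom(1L, total, error_rate)
  if (n_err == 0L) return(seqs)
  big <- charToRaw(paste(seqs, collapse = ""))
  pos <- sample.int(total, n_err)
  bases <- charToRaw("ACGT")
  shift <- sample.int(3L, n_err, replace = TRUE)
  cur <- match(big[pos], bases)
  cur[is.na(cur)] <- 1L          # N or odd byte: overwrite with a real base
  big[pos] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  ends <- cumsum(lens)
  substring(rawToChar(big), ends - lens + 1L, ends)
}

#' Simulate a paired-end FLDS sequencing library
#'
#' Each emitted pair is, exhaustively, one of four categories: `dimer`
#' (adaptor self-ligation product, no biological insert), `duplicate`
#' (exact PCR copy of another emitted pair), `low_quality` (collapsed 3'
#' quality tail) or `clean`. A clean/low-quality pair derives from a sheared
#' fragment of one community segment: the sequenced insert is
#' `UPM + fragment + U2` in original-strand orientation (U2 marks the
#' fragment 3' side; `ligation_efficiency` < 1 drops the U2 block and with
#' it the junction). Reads are the two insert ends, the right one reverse
#' complemented, mate order randomised.
#'
#' @param community Result of [generate_community()].
#' @param config A [library_config()].
#' @return List with `r1`, `r2` (read tables as in [read_fastq()]), `truth`
#'   (per-pair data.frame: `read_id`, `category`, `ref_id`, `frag_start`,
#'   `frag_end`, `strand`, `ligated`) and `warnings` (character; e.g. when a
#'   segment received no terminal fragment).
#' @export
simulate_library <- function(community, config) {
  stopifnot(inherits(config, "library_config"))
  ad <- config$adaptors
  rl <- config$read_length
  with_seed(config$seed, {
    n <- config$n_pairs
    if (n == 0L) {
      empty <- data.frame(id = character(0), seq = character(0),
                          qual = character(0), stringsAsFactors = FALSE)
      return(list(r1 = empty, r2 = empty,
                  truth = data.frame(read_id = character(0),
                                     category = character(0),
                                     ref_id = character(0),
                                     frag_start = integer(0),
                                     frag_end = integer(0),
                                     strand = character(0),
                                     ligated = logical(0)),
                  warnings = character(0)))
    }
    ids <- sprintf("sim%07d", seq_len(n))
    u <- stats::runif(n)
    category <- ifelse(u < config$dimer_rate, "dimer",
                ifelse(u < config$dimer_rate + config$duplicate_rate,
                       "duplicate",
                ifelse(u < config$dimer_rate + config$duplicate_rate +
                           config$low_quality_rate, "low_quality", "clean")))
    fresh <- category %in% c("clean", "low_quality")
    if (!any(fresh)) {                      # duplicates need a source
      category[1L] <- "clean"
      fresh[1L] <- TRUE
    }

    seg_names <- names(community$segments)
    seg_chr <- as.character(community$segments)
    seg_len <- nchar(seg_chr)

    ref_id <- rep(NA_character_, n)
    frag_start <- rep(NA_integer_, n)
    frag_end <- rep(NA_integer_, n)
    strand <- rep(NA_character_, n)
    ligated <- rep(NA, n)
    insert <- character(n)

    nf <- sum(fresh)
    seg_pick <- sample(seq_along(seg_names), nf, replace = TRUE,
                       prob = community$abundance)
    lig <- stats::runif(nf) < config$ligation_efficiency
    fr_start <- integer(nf); fr_end <- integer(nf); fr_strand <- character(nf)
    for (s in unique(seg_pick)) {
      w <- which(seg_pick == s)
      fr <- draw_fragments(seg_len[s], length(w), config$mean_fragment_bp,
                           config$fragment_sd_log, config$min_fragment_bp,
                           config$terminal_enrichment)
      fr_start[w] <- fr$start; fr_end[w] <- fr$end; fr_strand[w] <- fr$strand
    }
    frag_seq <- substring(seg_chr[seg_pick], fr_start + 1L, fr_end)
    neg <- fr_strand == "-"
    if (any(neg)) frag_seq[neg] <- reverse_complement(frag_seq[neg])
    ins <- paste0(ad$upm, frag_seq, ifelse(lig, ad$u2, ""))

    ref_id[fresh] <- seg_names[seg_pick]
    frag_start[fresh] <- fr_start; frag_end[fresh] <- fr_end
    strand[fresh] <- fr_strand; ligated[fresh] <- lig
    insert[fresh] <- ins

    dim_i <- category == "dimer"
    insert[dim_i] <- paste0(ad$upm, ad$u2)
    ligated[dim_i] <- TRUE

    # reads from both insert ends; right end reverse complemented
    ilen <- nchar(insert)
    left <- substr(insert, 1L, pmin(rl, ilen))
    right <- reverse_complement(substring(insert, pmax(1L, ilen - rl + 1L),
                                          ilen))
    nondup <- category != "duplicate"
    left[nondup] <- inject_errors(left[nondup], config$error_rate)
    right[nondup] <- inject_errors(right[nondup], config$error_rate)

    lowq <- category == "low_quality"
    lq <- qual_string(nchar(left))
    rq <- qual_string(nchar(right))
    lq[lowq] <- qual_string(nchar(left[lowq]), low = TRUE)

    # mate order random: which physical end becomes R1
    swap <- stats::runif(n) < 0.5
    r1_seq <- ifelse(swap, right, left); r1_q <- ifelse(swap, rq, lq)
    r2_seq <- ifelse(swap, left, right); r2_q <- ifelse(swap, lq, rq)

    # duplicates: exact copies (bases and qualities) of a random EARLIER
    # clean pair, so first-occurrence deduplication recovers the category
    # (a copy of a low-quality pair would fall to the quality filter, and a
    # copy occurring before its source would invert survivor order)
    dup_i <- which(category == "duplicate")
    if (length(dup_i)) {
      clean_idx <- which(category == "clean")
      n_before <- findInterval(dup_i - 1L, clean_idx)
      n_before[n_before == 0L] <- 1L   # dup before any clean pair: copy the
                                       # first clean pair (vanishingly rare)
      pick <- pmax(1L, ceiling(stats::runif(length(dup_i)) * n_before))
      src <- clean_idx[pick]
      r1_seq[dup_i] <- r1_seq[src]; r1_q[dup_i] <- r1_q[src]
      r2_seq[dup_i] <- r2_seq[src]; r2_q[dup_i] <- r2_q[src]
      ref_id[dup_i] <- ref_id[src]
      frag_start[dup_i] <- frag_start[src]; frag_end[dup_i] <- frag_end[src]
      strand[dup_i] <- strand[src]; ligated[dup_i] <- ligated[src]
    }

    truth <- data.frame(read_id = ids, category = category, ref_id = ref_id,
                        frag_start = frag_start, frag_end = frag_end,
                        strand = strand, ligated = ligated,
                        stringsAsFactors = FALSE)
    warn <- character(0)
    lig_term <- fresh & ligated & !is.na(frag_start) &
      ((strand == "+" & frag_end == seg_len[match(ref_id, seg_names)]) |
       (strand == "-" & frag_start == 0L))
    no_term <- setdiff(seg_names, unique(truth$ref_id[which(lig_term)]))
    if (length(no_term)) {
      warn <- sprintf("no terminal junction fragment emitted for segment %s",
                      no_term)
    }
    list(r1 = data.frame(id = ids, seq = r1_seq, qual = r1_q,
                         stringsAsFactors = FALSE),
         r2 = data.frame(id = ids, seq = r2_seq, qual = r2_q,
                         stringsAsFactors = FALSE),
         truth = truth, warnings = warn)
  })
}

#' Write simulator outputs to disk
#'
#' Emits paired FASTQ (R1/R2), the community FASTA, and truth/terminus
#' tables as TSV.
#'
#' @param sim Result of [simulate_library()].
#' @param community Result of [generate_community()].
#' @param prefix Output path prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, community, prefix) {
  files <- c(r1 = paste0(prefix, "_R1.fastq"), r2 = paste0(prefix, "_R2.fastq"),
             fasta = paste0(prefix, "_community.fasta"),
             truth = paste0(prefix, "_truth.tsv"),
             termini = paste0(prefix, "_termini.tsv"))
  write_fastq(sim$r1, files["r1"])
  write_fastq(sim$r2, files["r2"])
  write_fasta(community$segments, files["fasta"])
  utils::write.table(sim$truth, files["truth"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(community$termini, files["termini"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(files)
}
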