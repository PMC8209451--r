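# Internal read mapper: exact 5'-prefix seeding (Biostrings PDict) with
# full-length substitution-only extension. Intended for simulated data,
# which contains substitutions but no indels; real libraries should be
# aligned externally and ingested via read_sam().

#' Map reads to reference sequences (seed-and-extend, no indels)
#'
#' Seeds on an exact match of the first `seed_length` read bases against
#' both reference strands, then verifies the full read with at most
#' `floor(max_mismatch_rate * length)` substitutions and no overhang. The
#' best hit per read (fewest mismatches; ties broken by reference order,
#' then strand, then position) is reported.
#'
#' @param reads Read table (`id`, `seq`) — typically clean, adaptor-trimmed
#'   reads.
#' @param refs Named `DNAStringSet` of reference sequences.
#' @param seed_length Exact seed prefix length; reads shorter than this (or
#'   with non-ACGT seed bases) are left unmapped.
#' @param max_mismatch_rate Maximum mismatch fraction over the full read.
#' @return Alignment data.frame: `read_id`, `ref_id`, `start`, `end`
#'   (0-based half-open), `strand`, `mismatches`, `seq` (read bases in read
#'   orientation). One row per mapped read.
#' @export
map_reads <- function(reads, refs, seed_length = 24L,
                      max_mismatch_rate = 0.05) {
  empty <- data.frame(read_id = character(0), ref_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      seq = character(0), stringsAsFactors = FALSE)
  if (!nrow(reads) || !length(refs)) return(empty)
  lens <- nchar(reads$seq)
  usable <- lens >= seed_length &
    !grepl("[^ACGT]", substr(reads$seq, 1L, seed_length))
  if (!any(usable)) return(empty)
  ridx <- which(usable)
  seeds <- substr(reads$seq[ridx], 1L, seed_length)
  useed <- unique(seeds)
  seed_of_read <- match(seeds, useed)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(useed))

  fwd_chr <- as.character(refs)
  rev_chr <- as.character(Biostrings::reverseComplement(refs))
  ref_len <- nchar(fwd_chr)

  hits <- list()
  for (r in seq_along(refs)) {
    for (s in c("+", "-")) {
      subj <- if (s == "+") refs[[r]] else
        Biostrings::reverseComplement(refs[[r]])
      m <- Biostrings::matchPDict(pd, subj)
      cnt <- S4Vectors::elementNROWS(m)
      if (!sum(cnt)) next
      hits[[length(hits) + 1L]] <- data.table::data.table(
        seed = rep(seq_along(cnt), cnt),
        pos = BiocGenerics::start(BiocGenerics::unlist(m)),
        ref = r, strand = s)
    }
  }
  if (!length(hits)) return(empty)
  ht <- data.table::rbindlist(hits)
  # expand seed hits to reads carrying that seed
  rd <- data.table::data.table(read = ridx, seed = seed_of_read,
                               len = lens[ridx])
  cand <- merge(rd, ht, by = "seed", allow.cartesian = TRUE)
  if (!nrow(cand)) return(empty)
  cand <- cand[cand$pos + cand$len - 1L <= ref_len[cand$ref], ]
  if (!nrow(cand)) return(empty)

  # full-length mismatch verification, grouped by read length
  cand$mm <- NA_integer_
  subj_chr <- ifelse(cand$strand == "+", fwd_chr[cand$ref],
                     rev_chr[cand$ref])
  window <- substring(subj_chr, cand$pos, cand$pos + cand$len - 1L)
  readseq <- reads$seq[cand$read]
  for (l in unique(cand$len)) {
    g <- which(cand$len == l)
    cand$mm[g] <- mismatch_count(readseq[g], window[g])
  }
  cand <- cand[cand$mm <= floor(max_mismatch_rate * cand$len), ]
  if (!nrow(cand)) return(empty)
  data.table::setorderv(cand, c("read", "mm", "ref", "strand", "pos"))
  best <- cand[!duplicated(cand$read), ]

  L <- ref_len[best$ref]
  start0 <- ifelse(best$strand == "+", best$pos - 1L,
                   L - (best$pos - 1L + best$len))
  data.frame(read_id = reads$id[best$read],
             ref_id = names(refs)[best$ref],
             start = as.integer(start0),
             end = as.integer(start0 + best$len),
             strand = best$strand,
             mismatches = best$mm,
             seq = reads$seq[best$read],
             stringsAsFactors = FALSE)
}

#' Map the mates of a cleaned pair set, carrying junction annotations
#'
#' Convenience wrapper used by the end-to-end pipeline: pools both mates of
#' an adaptor-annotated clean pair set (output of [clean_reads()]), maps
#' them with [map_reads()], and attaches `junction_adaptor`, `junction_end`
#' and `junction_pos` columns (see [junction_position()] conventions).
#'
#' @param clean Result of [clean_reads()].
#' @param refs Named `DNAStringSet`.
#' @param ... Passed to [map_reads()].
#' @return Alignment data.frame with junction columns.
#' @export
map_clean_pairs <- function(clean, refs, ...) {
  mates <- rbind(
    cbind(clean$r1, mate = 1L),
    cbind(clean$r2, mate = 2L))
  mates$uid <- paste0(mates$id, "/", mates$mate)
  aln <- map_reads(data.frame(id = mates$uid, seq = mates$seq,
                              stringsAsFactors = FALSE), refs, ...)
  i <- match(aln$read_id, mates$uid)
  aln$pair_id <- mates$id[i]
  aln$mate <- mates$mate[i]
  a5 <- mates$adaptor5[i]; a3 <- mates$adaptor3[i]
  aln$junction_adaptor <- ifelse(!is.na(a5), a5, a3)
  aln$junction_end <- ifelse(!is.na(a5), "5p",
                             ifelse(!is.na(a3), "3p", NA_character_))
  # prefer the U2 signature when both ends carry an adaptor
  both <- !is.na(a5) & !is.na(a3) & a5 != "U2" & a3 == "U2"
  aln$junction_adaptor[both] <- "U2"
  aln$junction_end[both] <- "3p"
  aln$junction_pos <- junction_position(aln)
  aln
}
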