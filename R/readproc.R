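# Clean-read workflow: cDNA-synthesis adaptor trimming and adaptor-dimer
# detection, sliding-window quality trimming, exact PCR-duplicate removal,
# DUST low-complexity filtering, optional rRNA id-list exclusion, and
# fixed-depth downsampling, with per-category library accounting.

#' Sliding-window quality trimming
#'
#' Scans each read 5' to 3' with a window of `window` bases; at the first
#' window whose mean Phred score falls below `threshold`, the read is cut
#' immediately before the first base of that window whose own score is below
#' `threshold`. Reads shorter than `min_len` after cutting are dropped.
#'
#' @param reads Read table (`id`, `seq`, `qual`).
#' @param window Window width in bases.
#' @param threshold Mean Phred threshold.
#' @param min_len Minimum surviving length; shorter reads are dropped.
#' @return List with `reads` (trimmed survivors), `kept` (logical over input
#'   rows) and `n_dropped`.
#' @export
trim_quality <- function(reads, window = 4L, threshold = 20, min_len = 50L) {
  n <- nrow(reads)
  if (n == 0L) return(list(reads = reads, kept = logical(0), n_dropped = 0L))
  lens <- nchar(reads$qual)
  keep_len <- lens
  for (l in unique(lens)) {
    rows <- which(lens == l)
    if (l == 0L) { keep_len[rows] <- 0L; next }
    w <- min(as.integer(window), l)
    qm <- matrix(utf8ToInt(paste(reads$qual[rows], collapse = "")) - 33L,
                 ncol = l, byrow = TRUE)
    cs <- qm
    if (l > 1L) for (j in 2:l) cs[, j] <- cs[, j - 1L] + qm[, j]
    nw <- l - w + 1L
    wm <- (cs[, seq(w, l), drop = FALSE] -
             cbind(0L, cs[, seq_len(nw - 1L), drop = FALSE])) / w
    fw <- row_first_true(wm < threshold)
    hit <- which(!is.na(fw))
    if (length(hit)) {
      cut <- rep(NA_integer_, length(hit))
      for (k in 0:(w - 1L)) {
        low <- qm[cbind(hit, fw[hit] + k)] < threshold
        cut[is.na(cut) & low] <- fw[hit][is.na(cut) & low] + k - 1L
      }
      # a failing window always contains a sub-threshold base
      keep_len[rows[hit]] <- cut
    }
  }
  kept <- keep_len >= min_len
  out <- reads[kept, , drop = FALSE]
  trim <- keep_len[kept] < lens[kept]
  out$seq[trim] <- substr(out$seq[trim], 1L, keep_len[kept][trim])
  out$qual[trim] <- substr(out$qual[trim], 1L, keep_len[kept][trim])
  rownames(out) <- NULL
  list(reads = out, kept = kept, n_dropped = sum(!kept))
}

# Locate and remove one adaptor occurrence at each read end.
# 5' end: a full adaptor at the very start (sequencing begins at the insert
# boundary). 3' end: a full or truncated (read-through) adaptor prefix of
# length >= min_overlap as the read suffix. Returns trimmed seq/qual plus
# per-read annotation columns.
trim_adaptor_reads <- function(seqs, quals, adaptors,
                               max_mismatch_rate = 0.1, min_overlap = 10L) {
  n <- length(seqs)
  variants <- list(
    list(label = "UPM", seq = adaptors$upm),
    list(label = "UPM", seq = adaptors$upm_comp),
    list(label = "U2", seq = adaptors$u2),
    list(label = "U2", seq = adaptors$u2_comp))
  ord <- order(-vapply(variants, function(v) nchar(v$seq), 0L))
  variants <- variants[ord]                 # prefer longest match
  a5 <- rep(NA_character_, n); a3 <- rep(NA_character_, n)
  t5 <- integer(n); t3 <- integer(n)
  lens <- nchar(seqs)
  for (v in variants) {
    la <- nchar(v$seq)
    cand <- which(is.na(a5) & lens >= la)
    if (!length(cand)) next
    mm <- mismatch_count(substr(seqs[cand], 1L, la),
                         rep(v$seq, length(cand)))
    hit <- cand[mm <= floor(max_mismatch_rate * la)]
    if (length(hit)) {
      a5[hit] <- v$label
      t5[hit] <- la
    }
  }
  rem <- lens - t5                           # remaining insert length
  for (v in variants) {
    la <- nchar(v$seq)
    if (la < min_overlap) next
    for (k in seq(la, min_overlap)) {
      cand <- which(is.na(a3) & rem >= k)
      if (!length(cand)) next
      suff <- substr(seqs[cand], lens[cand] - k + 1L, lens[cand])
      mm <- mismatch_count(suff, rep(substr(v$seq, 1L, k), length(cand)))
      hit <- cand[mm <= floor(max_mismatch_rate * k)]
      if (length(hit)) {
        a3[hit] <- v$label
        t3[hit] <- k
      }
    }
  }
  keep_from <- t5 + 1L
  keep_to <- lens - t3
  data.frame(seq = substr(seqs, keep_from, keep_to),
             qual = substr(quals, keep_from, keep_to),
             adaptor5 = a5, adaptor3 = a3, trim5 = t5, trim3 = t3,
             orig_len = lens, stringsAsFactors = FALSE)
}

#' Trim cDNA-synthesis adaptors from a read pair set
#'
#' Removes U2 / U2-complement / UPM occurrences (sense or antisense) from
#' read ends, annotating which adaptor was found at which end of each mate.
#' A pair whose post-trim inserts are both shorter than `dimer_min_insert`
#' and whose content was at least `dimer_adaptor_frac` adaptor is flagged as
#' an adaptor dimer.
#'
#' @param r1,r2 Read tables (`id`, `seq`, `qual`), row-paired.
#' @param adaptors Adaptor set from [default_adaptors()].
#' @param max_mismatch_rate Allowed mismatch fraction within a match.
#' @param min_overlap Minimum 3'-end (read-through) match length.
#' @param dimer_min_insert,dimer_adaptor_frac Adaptor-dimer flag thresholds.
#' @return List with trimmed `r1`, `r2` (annotation columns `adaptor5`,
#'   `adaptor3`, `trim5`, `trim3` added) and logical `dimer` per pair.
#' @export
trim_adaptors <- function(r1, r2, adaptors = default_adaptors(),
                          max_mismatch_rate = 0.1, min_overlap = 10L,
                          dimer_min_insert = 20L, dimer_adaptor_frac = 0.9) {
  stopifnot(nrow(r1) == nrow(r2))
  tr1 <- trim_adaptor_reads(r1$seq, r1$qual, adaptors, max_mismatch_rate,
                            min_overlap)
  tr2 <- trim_adaptor_reads(r2$seq, r2$qual, adaptors, max_mismatch_rate,
                            min_overlap)
  out1 <- cbind(data.frame(id = r1$id, stringsAsFactors = FALSE), tr1)
  out2 <- cbind(data.frame(id = r2$id, stringsAsFactors = FALSE), tr2)
  adfrac <- function(tr) ifelse(tr$orig_len > 0,
                                (tr$trim5 + tr$trim3) / tr$orig_len, 0)
  dimer <- nchar(tr1$seq) < dimer_min_insert &
    nchar(tr2$seq) < dimer_min_insert &
    adfrac(tr1) >= dimer_adaptor_frac & adfrac(tr2) >= dimer_adaptor_frac
  list(r1 = out1, r2 = out2, dimer = dimer)
}

#' Remove exact PCR duplicates from a pair stream
#'
#' Pairs identical in (mate-1 bases, mate-2 bases) collapse to their first
#' occurrence; survivor order is preserved. Qualities are ignored.
#'
#' @param r1,r2 Row-paired read tables.
#' @return List with deduplicated `r1`, `r2`, logical `kept` over input rows
#'   and `n_duplicates`.
#' @export
dedupe <- function(r1, r2) {
  stopifnot(nrow(r1) == nrow(r2))
  key <- paste(r1$seq, r2$seq, sep = "\r")
  kept <- !duplicated(key)
  list(r1 = r1[kept, , drop = FALSE], r2 = r2[kept, , drop = FALSE],
       kept = kept, n_duplicates = sum(!kept))
}

#' DUST low-complexity score
#'
#' Triplet-frequency DUST score scaled to 0..100 (a homopolymer scores 100):
#' `100 * sum(c_t * (c_t - 1) / 2) / (k * (k - 1) / 2)` over the `k = L - 2`
#' overlapping triplets of each read (triplets containing non-ACGT bases are
#' ignored). Reads with fewer than 2 scorable triplets score 0.
#'
#' @param seqs Character vector of sequences.
#' @return Numeric score per sequence.
#' @export
dust_score <- function(seqs) {
  n <- length(seqs)
  if (!n) return(numeric(0))
  lens <- nchar(seqs)
  score <- numeric(n)
  pos_ok <- lens >= 3L
  if (!any(pos_ok)) return(score)
  big <- utf8ToInt(paste(seqs, collapse = ""))
  code <- match(big, utf8ToInt("ACGT")) - 1L
  rid <- rep.int(seq_len(n), lens)
  idx <- seq_len(length(big) - 2L)
  tri_ok <- rid[idx] == rid[idx + 2L] &
    !is.na(code[idx]) & !is.na(code[idx + 1L]) & !is.na(code[idx + 2L])
  if (!any(tri_ok)) return(score)
  i <- idx[tri_ok]
  tc <- 16L * code[i] + 4L * code[i + 1L] + code[i + 2L]
  dt <- data.table::data.table(rid = rid[i], tc = tc)
  cnt <- dt[, .N, by = c("rid", "tc")]
  raw <- cnt[, list(raw = sum(N * (N - 1) / 2), k = sum(N)), by = "rid"]
  ok <- raw$k >= 2
  score[raw$rid[ok]] <- 100 * raw$raw[ok] / (raw$k[ok] * (raw$k[ok] - 1) / 2)
  score
}

#' Filter low-complexity reads
#'
#' @param reads Read table.
#' @param threshold Drop reads with DUST score strictly above this value
#'   (default 7, the convention of common preprocessing tools).
#' @return List with `reads`, logical `kept`, `n_dropped`.
#' @export
filter_low_complexity <- function(reads, threshold = 7) {
  kept <- dust_score(reads$seq) <= threshold
  list(reads = reads[kept, , drop = FALSE], kept = kept,
       n_dropped = sum(!kept))
}

#' Downsample read pairs without replacement
#'
#' @param r1,r2 Row-paired read tables.
#' @param n Number of pairs to keep (0.8 M mirrors the fixed normalisation
#'   depth used for library comparison).
#' @param seed Integer seed; the same seed always selects the same pairs.
#' @return List with subsampled `r1`, `r2` and integer `index` of kept rows
#'   (in original order).
#' @export
subsample_pairs <- function(r1, r2, n = 800000, seed = 1) {
  stopifnot(nrow(r1) == nrow(r2), n >= 0)
  total <- nrow(r1)
  idx <- if (n >= total) seq_len(total) else
    with_seed(seed, sort(sample.int(total, n)))
  list(r1 = r1[idx, , drop = FALSE], r2 = r2[idx, , drop = FALSE],
       index = idx)
}

#' Build a library composition report
#'
#' @param counters Named list/vector with counts for `raw` and the removal
#'   categories `adaptor_dimer`, `quality_trimmed_out`, `duplicates`,
#'   `low_complexity`, `rrna`; `clean` is derived as the remainder and must
#'   reconcile (categories partition the raw count).
#' @return data.frame with `category`, `count`, `fraction` (fractions sum to
#'   1 for nonzero input).
#' @export
compose_report <- function(counters) {
  counters <- as.list(counters)
  cats <- c("adaptor_dimer", "quality_trimmed_out", "duplicates",
            "low_complexity", "rrna")
  raw <- counters$raw %||% 0L
  cnt <- vapply(cats, function(k) as.numeric(counters[[k]] %||% 0), 0)
  clean <- counters$clean %||% (raw - sum(cnt))
  if (raw != sum(cnt) + clean || clean < 0) {
    stop("inconsistent counters: categories do not partition the raw count")
  }
  counts <- c(raw = raw, cnt, clean = clean)
  frac <- if (raw > 0) counts / raw else counts * 0
  frac[["raw"]] <- if (raw > 0) 1 else 0
  data.frame(category = names(counts), count = as.numeric(counts),
             fraction = as.numeric(frac), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Run the full clean-read workflow on a read pair set
#'
#' Stage order: adaptor trimming with adaptor-dimer removal, quality
#' trimming (a pair is dropped when either mate falls below `min_len`),
#' exact pair deduplication, low-complexity removal, optional rRNA id-list
#' exclusion (externally produced), and optional fixed-n downsampling.
#' Adaptor-dimer detection runs first because dimer pairs are short,
#' high-quality adaptor concatenations that a length filter would otherwise
#' absorb into the wrong category.
#'
#' @param r1,r2 Raw read tables (row-paired).
#' @param adaptors Adaptor set.
#' @param window,threshold,min_len Quality-trimming parameters.
#' @param max_mismatch_rate,min_overlap Adaptor-trimming parameters.
#' @param dust_threshold Low-complexity threshold.
#' @param rrna_ids Optional character vector of read ids to exclude as
#'   rRNA-derived (hook for an external profile search; not reimplemented).
#' @param subsample_n Optional downsampling depth (pairs).
#' @param seed Seed for downsampling.
#' @return List with clean `r1`, `r2` (annotated, trimmed), `report`
#'   (see [compose_report()]), `category` (per raw pair), and `counters`.
#' @export
clean_reads <- function(r1, r2, adaptors = default_adaptors(), window = 4L,
                        threshold = 20, min_len = 50L,
                        max_mismatch_rate = 0.1, min_overlap = 10L,
                        dust_threshold = 7, rrna_ids = NULL,
                        subsample_n = NULL, seed = 1) {
  stopifnot(nrow(r1) == nrow(r2), all(r1$id == r2$id))
  raw <- nrow(r1)
  category <- rep("clean", raw)

  tr <- trim_adaptors(r1, r2, adaptors, max_mismatch_rate, min_overlap)
  category[tr$dimer] <- "adaptor_dimer"
  keep <- !tr$dimer
  c1 <- tr$r1[keep, , drop = FALSE]
  c2 <- tr$r2[keep, , drop = FALSE]

  q1 <- trim_quality(c1, window, threshold, min_len)
  q2 <- trim_quality(c2, window, threshold, min_len)
  qkeep <- q1$kept & q2$kept
  category[which(keep)[!qkeep]] <- "quality_trimmed_out"
  c1 <- c1[qkeep, , drop = FALSE]; c2 <- c2[qkeep, , drop = FALSE]
  # apply the per-mate trims to the surviving pairs
  c1[c("seq", "qual")] <- trim_to(q1, qkeep)
  c2[c("seq", "qual")] <- trim_to(q2, qkeep)

  dd <- dedupe(c1, c2)
  category[which(category == "clean")[!dd$kept]] <- "duplicates"
  c1 <- dd$r1; c2 <- dd$r2

  lc1 <- dust_score(c1$seq) > dust_threshold
  lc2 <- dust_score(c2$seq) > dust_threshold
  lc <- lc1 | lc2
  category[which(category == "clean")[lc]] <- "low_complexity"
  c1 <- c1[!lc, , drop = FALSE]; c2 <- c2[!lc, , drop = FALSE]

  if (!is.null(rrna_ids)) {
    rr <- c1$id %in% rrna_ids
    category[which(category == "clean")[rr]] <- "rrna"
    c1 <- c1[!rr, , drop = FALSE]; c2 <- c2[!rr, , drop = FALSE]
  }

  counters <- list(raw = raw,
                   adaptor_dimer = sum(category == "adaptor_dimer"),
                   quality_trimmed_out = sum(category == "quality_trimmed_out"),
                   duplicates = sum(category == "duplicates"),
                   low_complexity = sum(category == "low_complexity"),
                   rrna = sum(category == "rrna"),
                   clean = sum(category == "clean"))
  if (!is.null(subsample_n)) {
    ss <- subsample_pairs(c1, c2, subsample_n, seed)
    c1 <- ss$r1; c2 <- ss$r2
    counters$sampled <- nrow(c1)
  }
  rownames(c1) <- rownames(c2) <- NULL
  list(r1 = c1, r2 = c2, report = compose_report(counters),
       category = category, counters = counters)
}

# Extract the trimmed seq/qual of rows kept in BOTH mates from a
# trim_quality() result for one mate.
trim_to <- function(q, pair_kept) {
  sel <- pair_kept[q$kept]
  list(seq = q$reads$seq[sel], qual = q$reads$qual[sel])
}
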