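# Terminus detection: strand assignment from adaptor signatures, per-strand
# junction-position counting, and the one-sided Smirnov-Grubbs outlier test
# that decides whether a contig end shows the terminal read pile-up of a
# complete genome or genome segment.

#' Orient a mapped adaptor-bearing read relative to the original RNA strand
#'
#' In an FLDS insert the U2 adaptor marks the 3' side of the original
#' strand. For a read whose U2 signature sits at its 5' end (the usual
#' case: the U2-side mate is sequenced back across the junction), the
#' source fragment came from the strand opposite to the mapping strand; for
#' a read-through U2 at the read 3' end, from the mapping strand itself.
#' `"sense"` means the fragment derives from the contig's plus strand.
#'
#' @param aln Alignment data.frame with `strand`, `junction_adaptor`,
#'   `junction_end` columns (see [read_sam()] / [map_clean_pairs()]).
#' @return Character vector: `"sense"`, `"antisense"`, or `NA` where no U2
#'   annotation is present.
#' @export
assign_strand <- function(aln) {
  out <- rep(NA_character_, nrow(aln))
  u2 <- !is.na(aln$junction_adaptor) & aln$junction_adaptor == "U2"
  five <- u2 & aln$junction_end == "5p"
  three <- u2 & aln$junction_end == "3p"
  frag_plus <- (five & aln$strand == "-") | (three & aln$strand == "+")
  frag_minus <- (five & aln$strand == "+") | (three & aln$strand == "-")
  out[frag_plus] <- "sense"
  out[frag_minus] <- "antisense"
  out
}

#' Count adaptor-junction positions along a reference
#'
#' For every U2-junction alignment on the given reference, increments the
#' count at the 5' aligned position of the read (reference coordinate of
#' the adaptor-adjacent aligned base) on the track of its mapping strand.
#' Junctions of minus-strand fragments accumulate at the reference 5'
#' terminus on the plus track; junctions of plus-strand fragments at the 3'
#' terminus on the minus track.
#'
#' @param aln Alignment data.frame with junction columns.
#' @param ref_id Reference to count on.
#' @param ref_length Reference length (bp).
#' @param mate_unique Count at most one junction observation per read pair
#'   (drop read-through 3' U2 hits when the pair also has a 5' U2 mate).
#' @return List with integer vectors `plus` and `minus` of length
#'   `ref_length`, and `n_used` / `n_skipped` alignment counts.
#' @export
junction_counts <- function(aln, ref_id, ref_length, mate_unique = TRUE) {
  plus <- integer(ref_length)
  minus <- integer(ref_length)
  sel <- !is.na(aln$junction_adaptor) & aln$junction_adaptor == "U2" &
    !is.na(aln$junction_pos)
  skip <- sum(sel & aln$ref_id != ref_id)
  sel <- sel & aln$ref_id == ref_id
  a <- aln[sel, , drop = FALSE]
  if (mate_unique && !is.null(a$pair_id)) {
    # one observation per pair; the 5'-U2 mate is canonical
    ord <- order(a$junction_end != "5p")
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(a$pair_id), , drop = FALSE]
  }
  if (nrow(a)) {
    bad <- a$junction_pos < 0L | a$junction_pos >= ref_length
    skip <- skip + sum(bad)
    a <- a[!bad, , drop = FALSE]
    tp <- tabulate(a$junction_pos[a$strand == "+"] + 1L, nbins = ref_length)
    tm <- tabulate(a$junction_pos[a$strand == "-"] + 1L, nbins = ref_length)
    plus <- as.integer(tp)
    minus <- as.integer(tm)
  }
  list(plus = plus, minus = minus, n_used = sum(plus) + sum(minus),
       n_skipped = skip)
}

#' Critical value of the one-sided maximum Grubbs test
#'
#' `G_crit = ((N-1)/sqrt(N)) * sqrt(t^2 / (N - 2 + t^2))` with `t` the upper
#' `alpha/N` one-sided critical value of Student's t with `N - 2` degrees of
#' freedom.
#'
#' @param n Population size (>= 3).
#' @param alpha Significance level.
#' @return Critical value for `G = (max - mean) / sd`.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  stopifnot(all(n >= 3))
  t <- stats::qt(1 - alpha / n, df = n - 2)
  ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

#' One-sided Smirnov-Grubbs test for a maximum-value outlier
#'
#' Tests whether `candidate`, a member and the maximum of `population`, is
#' an upper outlier: `G = (candidate - mean) / sd` (sample sd, N-1
#' denominator) compared against [grubbs_critical()]. Degenerate
#' populations (sd 0) and candidates that are not the population maximum
#' are never outliers.
#'
#' @param population Numeric vector of counts, candidate included.
#' @param candidate The value under test.
#' @param alpha Significance level.
#' @return List: `G`, `G_crit`, `is_outlier`, `n`, `reason` (NA when a
#'   regular test was performed).
#' @export
grubbs_max_test <- function(population, candidate, alpha = 0.05) {
  n <- length(population)
  if (n < 3) {
    return(list(G = NA_real_, G_crit = NA_real_, is_outlier = FALSE,
                n = n, reason = "too_few"))
  }
  m <- mean(population)
  s <- stats::sd(population)
  if (s == 0) {
    return(list(G = NA_real_, G_crit = grubbs_critical(n, alpha),
                is_outlier = FALSE, n = n, reason = "degenerate"))
  }
  G <- (candidate - m) / s
  gc <- grubbs_critical(n, alpha)
  if (candidate < max(population)) {
    return(list(G = G, G_crit = gc, is_outlier = FALSE, n = n,
                reason = "not_maximum"))
  }
  list(G = G, G_crit = gc, is_outlier = G > gc, n = n, reason = NA_character_)
}

#' Test both contig ends for terminal junction pile-ups
#'
#' The 5'-terminus candidate is the maximum junction count within
#' `tolerance_bp` of position 0 on the plus track (where minus-strand
#' fragments deposit their U2 junctions); the 3'-terminus candidate is
#' found analogously at the right end of the minus track. Each candidate is
#' tested with [grubbs_max_test()] against the population of nonzero
#' junction counts on its own track (candidate included; the zero majority
#' is excluded so the test is among observed junction sites). Ties for the
#' window maximum resolve to the position closest to the contig end.
#'
#' @param tracks Result of [junction_counts()].
#' @param ref_id Reference id (echoed into the output).
#' @param tolerance_bp Window at each contig end for locating the
#'   candidate; allows for ragged assembly termini.
#' @param alpha Significance level per end.
#' @return data.frame with one row per end: `ref_id`, `end`,
#'   `candidate_pos`, `candidate_count`, `n_population`, `G`, `G_crit`,
#'   `is_outlier`, `reason`.
#' @export
call_termini <- function(tracks, ref_id, tolerance_bp = 5, alpha = 0.05) {
  L <- length(tracks$plus)
  one_end <- function(track, end) {
    win <- if (end == "five_prime") seq_len(min(tolerance_bp + 1L, L)) else
      seq(max(1L, L - tolerance_bp), L)
    wc <- track[win]
    # tie-break: position closest to the contig end
    ord <- if (end == "five_prime") seq_along(win) else rev(seq_along(win))
    best <- ord[which.max(wc[ord])]
    cand_pos <- win[best] - 1L
    cand_cnt <- track[win[best]]
    nz <- track[track > 0L]
    if (!length(nz)) {
      return(data.frame(ref_id = ref_id, end = end,
                        candidate_pos = NA_integer_,
                        candidate_count = 0L, n_population = 0L,
                        G = NA_real_, G_crit = NA_real_, is_outlier = FALSE,
                        reason = "no_junctions", stringsAsFactors = FALSE))
    }
    pop <- if (cand_cnt > 0L) nz else c(nz, 0L)
    gt <- grubbs_max_test(pop, cand_cnt, alpha)
    data.frame(ref_id = ref_id, end = end, candidate_pos = cand_pos,
               candidate_count = cand_cnt, n_population = gt$n,
               G = gt$G, G_crit = gt$G_crit, is_outlier = gt$is_outlier,
               reason = gt$reason, stringsAsFactors = FALSE)
  }
  rbind(one_end(tracks$plus, "five_prime"),
        one_end(tracks$minus, "three_prime"))
}

#' Aggregate two terminus calls into a completeness status
#'
#' @param calls data.frame from [call_termini()] (two rows).
#' @return One of `"complete"` (both ends outliers), `"partial_5p"` /
#'   `"partial_3p"` (only that end), `"incomplete"`.
#' @export
classify_completeness <- function(calls) {
  five <- calls$is_outlier[calls$end == "five_prime"]
  three <- calls$is_outlier[calls$end == "three_prime"]
  five <- isTRUE(five[1]); three <- isTRUE(three[1])
  if (five && three) "complete"
  else if (five) "partial_5p"
  else if (three) "partial_3p"
  else "incomplete"
}

#' Call genome/segment completeness for every reference
#'
#' Runs [junction_counts()], [call_termini()] and
#' [classify_completeness()] per reference.
#'
#' @param aln Junction-annotated alignment data.frame (from
#'   [map_clean_pairs()] or [read_sam()]).
#' @param ref_lengths Named integer vector of reference lengths.
#' @param tolerance_bp,alpha See [call_termini()].
#' @return data.frame with the per-end call rows plus a `status` column.
#' @export
call_completeness <- function(aln, ref_lengths, tolerance_bp = 5,
                              alpha = 0.05) {
  out <- lapply(names(ref_lengths), function(rid) {
    tr <- junction_counts(aln, rid, ref_lengths[[rid]])
    calls <- call_termini(tr, rid, tolerance_bp, alpha)
    calls$status <- classify_completeness(calls)
    calls
  })
  do.call(rbind, out)
}
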