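test_that("Grubbs critical values match the brute-force t-quantile oracle", {
  for (alpha in c(0.01, 0.05)) {
    for (n in c(3, 4, 7, 10, 30, 120)) {
      expect_equal(grubbs_critical(n, alpha), oracle_grubbs_crit(n, alpha),
                   tolerance = 1e-9)
    }
  }
})

test_that("the one-sided maximum Grubbs test flags clear outliers only", {
  # a count of 100 among ones is an extreme outlier
  gt <- grubbs_max_test(c(rep(1, 9), 100), 100, alpha = 0.05)
  expect_true(gt$is_outlier)
  expect_equal(gt$n, 10L)
  expect_gt(gt$G, gt$G_crit)

  # all-equal population: degenerate, never an outlier
  gt <- grubbs_max_test(rep(5, 10), 5)
  expect_false(gt$is_outlier)
  expect_equal(gt$reason, "degenerate")

  # a candidate below the maximum cannot be a maximum outlier
  gt <- grubbs_max_test(c(1, 2, 3, 50), 3)
  expect_false(gt$is_outlier)
  expect_equal(gt$reason, "not_maximum")

  # populations below 3 cannot be tested
  expect_false(grubbs_max_test(c(1, 9), 9)$is_outlier)

  # G is invariant under positive affine maps of the counts
  pop <- c(2, 3, 1, 4, 2, 30)
  g1 <- grubbs_max_test(pop, 30)$G
  g2 <- grubbs_max_test(7 * pop + 3, 7 * 30 + 3)$G
  expect_equal(g1, g2, tolerance = 1e-12)
})

test_that("junction counting conserves alignments on per-strand tracks", {
  aln <- data.frame(
    read_id = paste0("r", 1:5),
    ref_id = c("c1", "c1", "c1", "c1", "c2"),
    start = c(0L, 0L, 57L, 10L, 3L), end = c(30L, 30L, 90L, 40L, 40L),
    strand = c("+", "+", "+", "-", "+"),
    junction_adaptor = c("U2", "U2", "U2", "U2", "U2"),
    junction_end = "5p", stringsAsFactors = FALSE)
  aln$junction_pos <- c(0L, 0L, 57L, 39L, 3L)
  tr <- junction_counts(aln, "c1", 100L)
  expect_equal(tr$plus[1], 2L)      # two reads at position 0
  expect_equal(tr$plus[58], 1L)     # one read at position 57
  expect_equal(tr$minus[40], 1L)
  expect_equal(sum(tr$plus) + sum(tr$minus), 4L)
  expect_equal(tr$n_skipped, 1L)    # the c2 alignment

  # no alignments: two all-zero tracks
  tr0 <- junction_counts(aln[0, ], "c1", 100L)
  expect_true(all(tr0$plus == 0L) && all(tr0$minus == 0L))

  # non-U2 or unannotated alignments never contribute
  aln$junction_adaptor <- c("UPM", NA, "U2", "U2", "U2")
  tr2 <- junction_counts(aln, "c1", 100L)
  expect_equal(tr2$n_used, 2L)
})

test_that("strand assignment follows the U2 adaptor orientation convention", {
  base <- data.frame(read_id = "r", ref_id = "c", start = 0L, end = 10L,
                     stringsAsFactors = FALSE)
  mk <- function(strand, adaptor, end) {
    cbind(base, data.frame(strand = strand, junction_adaptor = adaptor,
                           junction_end = end, stringsAsFactors = FALSE))
  }
  # U2 at read 5' end: fragment strand is opposite to the mapping strand
  expect_equal(assign_strand(mk("-", "U2", "5p")), "sense")
  expect_equal(assign_strand(mk("+", "U2", "5p")), "antisense")
  # read-through U2 at read 3' end: fragment strand equals mapping strand
  expect_equal(assign_strand(mk("+", "U2", "3p")), "sense")
  expect_equal(assign_strand(mk("-", "U2", "3p")), "antisense")
  # UPM-only or unannotated reads are not classifiable
  expect_true(is.na(assign_strand(mk("+", "UPM", "5p"))))
  expect_true(is.na(assign_strand(mk("+", NA, NA))))
})

test_that("strand assignment agrees with simulation truth and flips with the contig", {
  com <- small_community()
  lc <- library_config(n_pairs = 1500, error_rate = 0, dimer_rate = 0,
                       duplicate_rate = 0, low_quality_rate = 0,
                       ligation_efficiency = 1, seed = 41)
  sim <- simulate_library(com, lc)
  cl <- clean_reads(sim$r1, sim$r2, adaptors = lc$adaptors)
  aln <- map_clean_pairs(cl, com$segments)
  ja <- aln[!is.na(aln$junction_adaptor) & aln$junction_adaptor == "U2", ]
  sa <- assign_strand(ja)
  tr <- sim$truth[match(ja$pair_id, sim$truth$read_id), ]
  expect_true(all((sa == "sense") == (tr$strand == "+")))

  # mapping onto the reverse-complemented contigs flips every assignment
  rc <- Biostrings::reverseComplement(com$segments)
  names(rc) <- names(com$segments)
  aln_rc <- map_clean_pairs(cl, rc)
  ja_rc <- aln_rc[!is.na(aln_rc$junction_adaptor) &
                    aln_rc$junction_adaptor == "U2", ]
  sa_rc <- assign_strand(ja_rc)
  tr_rc <- sim$truth[match(ja_rc$pair_id, sim$truth$read_id), ]
  expect_true(all((sa_rc == "antisense") == (tr_rc$strand == "+")))
})

test_that("terminus calls respond to pile-ups and respect the tie-break", {
  # constructed tracks: background singletons plus a terminal pile-up
  L <- 500L
  plus <- integer(L); minus <- integer(L)
  set.seed(3)
  plus[sample(10:490, 60)] <- 1L
  minus[sample(10:490, 60)] <- 1L
  plus[1] <- 25L                       # strong 5' signal at position 0
  tracks <- list(plus = plus, minus = minus)
  calls <- call_termini(tracks, "c1", tolerance_bp = 5, alpha = 0.05)
  five <- calls[calls$end == "five_prime", ]
  three <- calls[calls$end == "three_prime", ]
  expect_true(five$is_outlier)
  expect_equal(five$candidate_pos, 0L)
  expect_false(three$is_outlier)
  expect_equal(classify_completeness(calls), "partial_5p")

  # tie within the window resolves to the position closest to the end
  plus[1] <- 25L; plus[4] <- 25L
  calls2 <- call_termini(list(plus = plus, minus = minus), "c1")
  expect_equal(calls2$candidate_pos[calls2$end == "five_prime"], 0L)

  # empty track: no-call
  calls3 <- call_termini(list(plus = integer(L), minus = integer(L)), "c1")
  expect_true(all(!calls3$is_outlier))
  expect_true(all(calls3$reason == "no_junctions"))
})

test_that("completeness classification covers all call combinations", {
  mk <- function(f, t) {
    data.frame(end = c("five_prime", "three_prime"), is_outlier = c(f, t))
  }
  expect_equal(classify_completeness(mk(TRUE, TRUE)), "complete")
  expect_equal(classify_completeness(mk(TRUE, FALSE)), "partial_5p")
  expect_equal(classify_completeness(mk(FALSE, TRUE)), "partial_3p")
  expect_equal(classify_completeness(mk(FALSE, FALSE)), "incomplete")
})

test_that("the internal mapper recovers exact positions on both strands", {
  set.seed(17)
  ref <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
  refs <- Biostrings::DNAStringSet(c(c1 = ref))
  fwd <- substr(ref, 101, 160)                       # [100,160) on +
  rev <- reverse_complement(substr(ref, 201, 260))   # [200,260) on -
  reads <- data.frame(id = c("f", "r"), seq = c(fwd, rev),
                      stringsAsFactors = FALSE)
  aln <- map_reads(reads, refs)
  aln <- aln[order(aln$read_id), ]
  expect_equal(aln$start, c(100L, 200L))
  expect_equal(aln$end, c(160L, 260L))
  expect_equal(aln$strand, c("+", "-"))
  expect_equal(aln$mismatches, c(0L, 0L))

  # substitutions within the budget are tolerated and counted
  mut <- fwd
  substr(mut, 30, 30) <- if (substr(mut, 30, 30) == "A") "C" else "A"
  aln2 <- map_reads(data.frame(id = "m", seq = mut), refs)
  expect_equal(aln2$mismatches, 1L)
  expect_equal(aln2$start, 100L)

  # reads absent from the reference stay unmapped
  aln3 <- map_reads(data.frame(id = "x", seq = strrep("ACGT", 15)), refs)
  expect_equal(nrow(aln3), 0L)
})

test_that("per-reference completeness calling integrates tracks and tests", {
  com <- small_community()
  lc <- library_config(n_pairs = 6000, error_rate = 0.002, seed = 43)
  sim <- simulate_library(com, lc)
  cl <- clean_reads(sim$r1, sim$r2, adaptors = lc$adaptors)
  aln <- map_clean_pairs(cl, com$segments)
  rl <- ref_lengths_of(com)
  calls <- call_completeness(aln, rl)
  expect_equal(nrow(calls), 2L * length(rl))
  cov <- depth_breadth(aln, rl)
  well <- cov$ref_id[cov$depth >= 30]
  st <- calls$status[match(well, calls$ref_id)]
  expect_true(all(st == "complete"))

  # candidate positions sit at the contig ends
  five <- calls[calls$end == "five_prime" & calls$is_outlier, ]
  expect_true(all(five$candidate_pos <= 5))
})
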