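make_reads <- function(seqs, quals = NULL) {
  if (is.null(quals)) quals <- strrep("F", nchar(seqs))  # Q37
  data.frame(id = sprintf("r%03d", seq_along(seqs)), seq = seqs,
             qual = quals, stringsAsFactors = FALSE)
}

qstr <- function(q) intToUtf8(q + 33L)

test_that("sliding-window quality trimming follows the documented cut rule", {
  # all above threshold: unchanged
  r <- make_reads("ACGTACGT", qstr(rep(30, 8)))
  out <- trim_quality(r, window = 4, threshold = 20, min_len = 1)
  expect_equal(out$reads$seq, "ACGTACGT")

  # first failing window [30,30,5,5]: cut before its first low base -> 4 kept
  r <- make_reads("ACGTACGT", qstr(c(30, 30, 30, 30, 5, 5, 5, 5)))
  out <- trim_quality(r, window = 4, threshold = 20, min_len = 1)
  expect_equal(nchar(out$reads$seq), 4L)
  expect_equal(out$reads$qual, qstr(rep(30, 4)))

  # hopeless read: dropped and counted
  r <- make_reads("ACGTACGTAC", qstr(rep(5, 10)))
  out <- trim_quality(r, window = 4, threshold = 20, min_len = 1)
  expect_equal(nrow(out$reads), 0L)
  expect_equal(out$n_dropped, 1L)

  # survivors below min_len are dropped
  r <- make_reads(strrep("A", 60), qstr(c(rep(37, 20), rep(2, 40))))
  out <- trim_quality(r, window = 4, threshold = 20, min_len = 50)
  expect_equal(nrow(out$reads), 0L)
})

test_that("quality trimming agrees with a position-by-position oracle", {
  set.seed(101)
  for (i in 1:200) {
    l <- sample(5:80, 1)
    q <- sample(2:40, l, replace = TRUE)
    r <- make_reads(strrep("A", l), qstr(q))
    out <- trim_quality(r, window = 4, threshold = 20, min_len = 0)
    got <- if (nrow(out$reads)) nchar(out$reads$seq) else 0L
    expect_equal(got, oracle_quality_cut(q, 4, 20),
                 info = paste("quals:", paste(q, collapse = ",")))
  }
})

test_that("adaptor occurrences at read ends are trimmed and annotated", {
  ad <- default_adaptors()
  set.seed(7)
  insert <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                  collapse = "")
  # U2 at the read 5' end + 40-nt insert
  r1 <- make_reads(paste0(ad$u2, insert))
  r2 <- make_reads(insert)
  tr <- trim_adaptors(r1, r2, ad)
  expect_equal(tr$r1$seq, insert)
  expect_equal(tr$r1$adaptor5, "U2")
  expect_equal(tr$r1$trim5, nchar(ad$u2))
  expect_false(tr$dimer)

  # no adaptor: unchanged, no annotation
  expect_equal(tr$r2$seq, insert)
  expect_true(is.na(tr$r2$adaptor5) && is.na(tr$r2$adaptor3))

  # pure-adaptor pair (U2 + rc(UPM) and its complement) flagged as dimer
  d1 <- make_reads(paste0(ad$u2, ad$upm_comp))
  d2 <- make_reads(paste0(ad$upm, ad$u2_comp))
  trd <- trim_adaptors(d1, d2, ad)
  expect_true(trd$dimer)
  expect_lt(nchar(trd$r1$seq), 20)

  # read-through: truncated adaptor prefix at the 3' end is removed
  rt1 <- make_reads(paste0(insert, substr(ad$u2, 1, 12)))
  rt <- trim_adaptors(rt1, make_reads(insert), ad)
  expect_equal(rt$r1$seq, insert)
  expect_equal(rt$r1$adaptor3, "U2")
  expect_equal(rt$r1$trim3, 12L)
})

test_that("deduplication keeps first occurrences and is idempotent", {
  r1 <- make_reads(c("ACGT", "ACGT", "ACGT", "TTTT"))
  r2 <- make_reads(c("GGGG", "GGGG", "GGGG", "AAAA"))
  dd <- dedupe(r1, r2)
  expect_equal(nrow(dd$r1), 2L)
  expect_equal(dd$n_duplicates, 2L)
  expect_equal(dd$r1$id[1], "r001")  # first occurrence survives

  # all distinct: identity
  r1 <- make_reads(c("ACGT", "CCCC")); r2 <- make_reads(c("AAAA", "GGGG"))
  dd <- dedupe(r1, r2)
  expect_equal(dd$r1, r1)

  # idempotence
  dd2 <- dedupe(dd$r1, dd$r2)
  expect_equal(dd2$r1, dd$r1)
  expect_equal(dd2$n_duplicates, 0L)

  # mates are considered jointly: same r1, different r2 is not a duplicate
  r1 <- make_reads(c("ACGT", "ACGT")); r2 <- make_reads(c("AAAA", "GGGG"))
  expect_equal(dedupe(r1, r2)$n_duplicates, 0L)
})

test_that("DUST low-complexity scoring matches a direct oracle", {
  expect_gt(dust_score(strrep("AC", 25)), 7)    # dinucleotide repeat
  expect_equal(dust_score(strrep("A", 50)), 100)  # homopolymer maximum
  set.seed(11)
  rnd <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
               collapse = "")
  expect_lte(dust_score(rnd), 7)
  seqs <- c(rnd, strrep("AC", 25), strrep("A", 50), "ACG", "A", "",
            "ACGTNNNACGT",
            vapply(1:20, function(i) paste(
              sample(c("A", "C", "G", "T", "N"), sample(3:60, 1),
                     replace = TRUE), collapse = ""), ""))
  expect_equal(dust_score(seqs), vapply(seqs, oracle_dust, 0,
                                        USE.NAMES = FALSE))
  lc <- filter_low_complexity(make_reads(c(rnd, strrep("A", 50))))
  expect_equal(lc$n_dropped, 1L)
})

test_that("subsampling is deterministic, capped, and seed-sensitive", {
  r1 <- make_reads(strrep(c("A", "C", "G", "T"), 10)[rep(1:4, 25)])
  r2 <- r1
  s1 <- subsample_pairs(r1, r2, n = 40, seed = 1)
  s2 <- subsample_pairs(r1, r2, n = 40, seed = 1)
  expect_identical(s1$index, s2$index)
  expect_equal(length(s1$index), 40L)

  # n >= available: identity
  s3 <- subsample_pairs(r1, r2, n = 1000, seed = 1)
  expect_identical(s3$r1, r1)

  # two seeds overlap near the hypergeometric expectation n^2/N
  sa <- subsample_pairs(r1, r2, n = 40, seed = 1)$index
  sb <- subsample_pairs(r1, r2, n = 40, seed = 2)$index
  expect_false(identical(sa, sb))
  overlap <- length(intersect(sa, sb))
  expect_gt(overlap, 40 * 40 / 100 - 3 * sqrt(40 * 0.4 * 0.6))
  expect_lt(overlap, 40 * 40 / 100 + 3 * sqrt(40 * 0.4 * 0.6))
})

test_that("composition reports partition the raw count", {
  rep1 <- compose_report(list(raw = 100, adaptor_dimer = 30,
                              duplicates = 10, clean = 60))
  expect_equal(rep1$fraction[rep1$category == "clean"], 0.6)
  expect_equal(rep1$fraction[rep1$category == "adaptor_dimer"], 0.3)
  expect_equal(rep1$fraction[rep1$category == "duplicates"], 0.1)
  expect_equal(sum(rep1$fraction[rep1$category != "raw"]), 1, tolerance = 1e-9)

  # zero-read input: all-zero report, no division error
  rep0 <- compose_report(list(raw = 0))
  expect_true(all(rep0$count == 0))
  expect_true(all(is.finite(rep0$fraction)))

  # inconsistent counters rejected
  expect_error(compose_report(list(raw = 10, adaptor_dimer = 5, clean = 9)),
               "inconsistent")
})

test_that("the clean workflow recovers simulated categories and conserves counts", {
  com <- small_community()
  lc <- library_config(n_pairs = 4000, error_rate = 0, dimer_rate = 0.1,
                       duplicate_rate = 0.1, low_quality_rate = 0.05,
                       seed = 29)
  sim <- simulate_library(com, lc)
  cl <- clean_reads(sim$r1, sim$r2, adaptors = lc$adaptors)

  # conservation: categories partition raw input
  expect_equal(sum(unlist(cl$counters[c("adaptor_dimer",
                                        "quality_trimmed_out", "duplicates",
                                        "low_complexity", "rrna",
                                        "clean")])),
               cl$counters$raw)
  expect_equal(cl$counters$raw, 4000L)

  # per-pair category agreement with truth >= 95% at zero error rate
  agree <- mean(cl$category == truth_to_report_category(sim$truth$category))
  expect_gte(agree, 0.95)

  # trimming never lengthens a read
  keep <- sim$truth$category == "clean"
  m <- match(cl$r1$id, sim$r1$id)
  expect_true(all(nchar(cl$r1$seq) <= nchar(sim$r1$seq[m])))

  # the rRNA hook diverts listed ids from the clean category
  rr <- clean_reads(sim$r1, sim$r2, adaptors = lc$adaptors,
                    rrna_ids = cl$r1$id[1:10])
  expect_equal(rr$counters$rrna, 10L)
  expect_equal(rr$counters$clean, cl$counters$clean - 10L)
})

test_that("downsampling inside the workflow returns exactly n pairs", {
  com <- small_community()
  sim <- simulate_library(com, library_config(n_pairs = 1000, seed = 37))
  cl <- clean_reads(sim$r1, sim$r2, subsample_n = 200, seed = 5)
  expect_equal(nrow(cl$r1), 200L)
  expect_equal(cl$counters$sampled, 200L)
  cl2 <- clean_reads(sim$r1, sim$r2, subsample_n = 200, seed = 5)
  expect_identical(cl$r1$id, cl2$r1$id)
})
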