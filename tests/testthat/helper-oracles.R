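# Independent brute-force oracles used to validate package computations.
# These deliberately avoid the code paths they check.

# Student's t quantile by numeric integration of the density + root finding
# (independent of stats::qt). Works on the upper-tail integral, which is
# well behaved even for df = 1 where quantiles are huge.
oracle_t_quantile <- function(p, df) {
  tail_prob <- function(x) {
    stats::integrate(function(u) stats::dt(u, df), x, Inf,
                     rel.tol = 1e-12)$value
  }
  stats::uniroot(function(x) tail_prob(x) - (1 - p),
                 interval = c(0, 10), tol = 1e-12,
                 extendInt = "downX", maxiter = 3000)$root
}

oracle_grubbs_crit <- function(n, alpha) {
  t <- oracle_t_quantile(1 - alpha / n, n - 2)
  ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

# Per-base enumeration of depth and breadth.
oracle_depth_breadth <- function(aln, L) {
  v <- integer(L)
  for (i in seq_len(nrow(aln))) {
    idx <- (aln$start[i] + 1L):aln$end[i]
    v[idx] <- v[idx] + 1L
  }
  list(depth = sum(v) / L, breadth = mean(v > 0))
}

# Definition-walk N50: length at which cumulative sorted-descending lengths
# first reach half the total.
oracle_n50 <- function(lengths) {
  ws <- sort(lengths, decreasing = TRUE)
  total <- sum(ws)
  acc <- 0
  for (w in ws) {
    acc <- acc + w
    if (acc >= total / 2) return(w)
  }
}

# Direct DUST score from a per-read triplet table.
oracle_dust <- function(seq) {
  l <- nchar(seq)
  if (l < 3) return(0)
  tri <- substring(seq, 1:(l - 2), 3:l)
  tri <- tri[!grepl("[^ACGT]", tri)]
  k <- length(tri)
  if (k < 2) return(0)
  ct <- table(tri)
  100 * sum(ct * (ct - 1) / 2) / (k * (k - 1) / 2)
}

# Position-by-position sliding-window quality cut: returns the kept length
# under the documented rule (cut before the first sub-threshold base of the
# first window whose mean falls below threshold).
oracle_quality_cut <- function(q, window = 4L, threshold = 20) {
  l <- length(q)
  if (l == 0L) return(0L)
  w <- min(window, l)
  for (s in 1:(l - w + 1L)) {
    if (mean(q[s:(s + w - 1L)]) < threshold) {
      for (p in s:(s + w - 1L)) {
        if (q[p] < threshold) return(p - 1L)
      }
    }
  }
  l
}

# Simple independent reverse complement.
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# Map simulator truth categories onto clean-read report categories.
truth_to_report_category <- function(x) {
  c(clean = "clean", dimer = "adaptor_dimer", duplicate = "duplicates",
    low_quality = "quality_trimmed_out")[x]
}

# Small shared fixture: a 3-virus community and matching config.
small_community <- function(seed = 5) {
  generate_community(community_config(
    n_viruses = 3, segments_per_virus = c(2, 3),
    genome_length = c(1000, 2000), shared_terminus_length = 20,
    abundance_span = 1, seed = seed))
}

ref_lengths_of <- function(community) {
  stats::setNames(Biostrings::width(community$segments),
                  names(community$segments))
}
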