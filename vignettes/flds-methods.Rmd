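---
title: "Identifying complete RNA viral genomes from dsRNA sequencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying complete RNA viral genomes from dsRNA sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fldsr)
```

## The problem

Long double-stranded RNA is the genome of dsRNA viruses and the replicative
intermediate of single-stranded RNA viruses, which makes purified cellular
dsRNA an efficient enrichment target for RNA virome sequencing (FLDS:
fragmented and primer-ligated dsRNA sequencing). The library construction
leaves two exploitable signatures in the reads:

1. **Orientation.** Each sequenced insert is flanked by two distinct
   adaptors: the ligated U2 oligonucleotide
   (`GACGTAAGAACGTCGCACCA`) marks the **3′ side** of the original RNA
   strand, and the template-switching universal primer (UPM) marks the
   **5′ side**. A read that contains a U2 signature therefore reveals
   which strand of an assembled contig corresponds to the original
   molecule.
2. **Termini.** Because the U2 adaptor is ligated to the 3′ ends of the
   sheared dsRNA, fragments that end exactly at a genome terminus are
   systematically over-represented: the terminal position receives reads
   from every molecule whose last fragment abuts that end, while interior
   positions receive reads only from fragments that happen to break there.
   Junction reads consequently pile up at true genome/segment termini.

`fldsr` turns these signatures into a completeness test for candidate
viral genomes and genome segments: count, per reference and strand, the 5′
aligned positions of adaptor-bearing reads (the *junction positions*), and
ask whether the count at each contig end is a statistical outlier among
the observed junction counts.

## The terminus test

For one contig end, let the population be the junction counts at all
positions with at least one junction read on the relevant strand track
(the candidate included). With `N` such counts, mean `m` and sample
standard deviation `s`, the candidate count `c` is tested with the
one-sided maximum Smirnov–Grubbs statistic

\[ G = (c - m) / s, \qquad
   G_{crit} = \frac{N-1}{\sqrt{N}}
   \sqrt{\frac{t^2_{\alpha/N,\,N-2}}{N - 2 + t^2_{\alpha/N,\,N-2}}} \]

where `t` is the upper `α/N` one-sided critical value of Student's *t*
with `N − 2` degrees of freedom. The end is called terminal when
`G > G_crit` at `α = 0.05`. A contig is **complete** when both ends are
terminal, **partial_5p/3p** when exactly one is, **incomplete** otherwise.

Design choices that the test's verbal description leaves open, and how
this package resolves them:

* **Which strand track tests which end.** U2-bearing reads of plus-strand
  fragments map to the minus strand with their junction at the fragment's
  right edge; minus-strand fragments map to the plus strand with the
  junction at the left edge. The 5′-terminus candidate is therefore taken
  near position 0 on the plus track and the 3′-terminus candidate near
  `L − 1` on the minus track.
* **Zeros are excluded from the Grubbs population.** Most reference
  positions carry no junction read; including the zero majority would
  make any covered position an "outlier". The population is the counts at
  observed junction sites. If the end candidate itself has count 0 it is
  appended as a zero (and can never be an outlier).
* **Candidate window.** Assemblies can have ragged termini, so the
  candidate is the maximum count within `tolerance_bp = 5` of the contig
  end; ties resolve deterministically to the position closest to the end.
* **Degenerate inputs.** Populations of fewer than 3 counts, zero
  standard deviation (all counts equal), and candidates that are not the
  population maximum never yield an outlier; each case is reported with a
  reason code rather than an error.
* **No cross-end multiplicity correction.** The two ends are tested
  independently at `α = 0.05` each; the `α/N` inside the critical value is
  the standard Grubbs form, not an extra correction.

## Strand assignment

`assign_strand()` reads the adaptor annotation of a mapped read: a U2
signature at the read 5′ end means the source fragment came from the
strand *opposite* to the mapping strand (the U2-side mate is sequenced
back across the junction); a read-through U2 at the read 3′ end means the
fragment came from the mapping strand itself. `"sense"` denotes a
fragment from the contig's plus strand. On error-free simulated pairs this
assignment agrees with the generator's ground truth for every read.

## The clean-read workflow

`clean_reads()` reproduces the preprocessing used for FLDS libraries with
explicit, oracle-tested conventions:

* **Adaptor trimming** (first): full-length U2/U2-complement/UPM matches
  at the read 5′ end and full or truncated (read-through) matches of at
  least `min_overlap = 10` bases at the 3′ end are removed, at up to 10%
  mismatches. A pair whose post-trim inserts are both under 20 bp and
  whose content was ≥90% adaptor is an **adaptor dimer** — the
  self-ligation product that dominates failed low-input libraries.
  Dimer detection runs *before* any length filtering because dimer reads
  are short, high-quality adaptor concatenations that a minimum-length
  rule would silently absorb into the wrong category. Adaptor remnants
  shorter than `min_overlap` can survive at a read's 3′ end, exactly as
  with conventional trimmers; they sit on the UPM side of the insert and
  never touch the junction-defining 5′ end.
* **Quality trimming**: sliding window of 4 bases, mean Phred < 20; the
  read is cut immediately before the first sub-threshold base of the
  first failing window (the exact cut point is tool-internal in common
  trimmers; this package's rule is documented and tested against a
  position-by-position oracle). Reads shorter than `min_len = 50` after
  cutting are dropped, and a pair dies with either mate.
* **Duplicate removal**: pairs identical in both mates' bases (qualities
  ignored) collapse to their first occurrence — a reproducible, pair-aware
  definition of a PCR duplicate.
* **Low-complexity removal**: triplet-frequency DUST score scaled to
  0–100 (homopolymer = 100); reads scoring above 7 are dropped, mirroring
  the common preprocessing convention.
* **rRNA removal** is a pass-through hook taking an externally produced
  id list; profile-based rRNA search is out of scope.
* **Downsampling**: optional fixed-depth subsampling without replacement
  (0.8 M pairs is the conventional normalisation depth for library
  comparison), deterministic per seed.

The per-category counts always partition the raw pair count exactly.

## The simulator

`generate_community()` + `simulate_library()` provide the ground truth
that makes every stage testable without external sequencing data. The
generator emulates:

* a community of segmented RNA viruses in which all segments of one virus
  share identical terminal blocks (default 20 nt) — the FLDS signature
  used to group segments;
* per-segment abundances log-uniform over ≥2 orders of magnitude
  (configurable), mirroring the wide abundance spread of real viromes;
* mechanical shearing as log-normal fragment lengths (mean 300 bp,
  sd 0.35 in log space — any unimodal model suffices and both knobs are
  exposed);
* 3′ adaptor ligation with configurable efficiency, and **terminal
  enrichment** modelled as preferential sampling: a fragment whose 3′ end
  abuts a true terminus is over-sampled by a single multiplier (default
  50) relative to any one interior placement. This reproduces the
  observable (junction pile-ups at termini whose expected height is the
  multiplier times the per-position interior rate) without modelling
  ligation kinetics. The terminal decision is a threshold on one uniform
  draw per fragment, so the set of terminal fragments grows monotonically
  with the multiplier under a fixed seed;
* PCR artifacts: adaptor dimers (inserts of pure `UPM + U2`) at
  `dimer_rate`, and exact duplicate pairs at `duplicate_rate`. Each pair
  is drawn once from a single multinomial over
  {dimer, duplicate, low-quality, clean}, so the observed fractions are
  unbiased estimates of the rates. Duplicates copy a random *earlier*
  clean pair — a copy of a low-quality pair would fall to the quality
  filter, and a copy preceding its source would invert first-occurrence
  deduplication. PCR cycles map to a duplicate rate through the toy proxy
  `1 − 0.5^(cycles − 25)` only when no explicit rate is given;
* 2×300 bp paired reads from both insert ends with a per-base
  substitution model (default 0.002), constant Q37 qualities with a mild
  3′ decay, and a configurable fraction of pairs with a collapsed-quality
  tail to exercise trimming.

It does **not** emulate chimeras, sequence-specific ligation bias, indel
errors, quality-dependent error rates, PhiX spike-ins, or host/rRNA
contamination. Passing tests on simulated data therefore demonstrate the
correctness of the counting, testing and accounting machinery under the
stated generative model — not robustness to every artifact of real MiSeq
runs; real libraries should be aligned with a production aligner and
ingested as SAM.

## Mapping

The built-in mapper seeds on an exact 24-nt 5′ prefix match (both
strands) and verifies the full read allowing substitutions up to 5% of
the read length, no indels. This matches the simulator's error model and
keeps the package self-contained; it is not a general-purpose aligner.
Shared terminal blocks (20 nt) are shorter than the seed, so reads
spanning a terminus into segment-specific sequence still map uniquely;
the best hit (fewest mismatches, deterministic tie-break) is reported.
For real data, any external aligner can be used: `clean_reads()`
annotations travel as read-name suffixes (`readid|U2:5p`) that
`read_sam()` decodes.

## Coverage, library comparison, and assembly statistics

Depth of coverage is the average number of times a reference base is
covered (sum of aligned bases over reference length); breadth is the
fraction of bases covered at least once. Both equal a per-base
enumeration oracle exactly. A reference counts as **retrieved complete**
in a library when its breadth reaches a threshold; the default is 1.0,
but the library-size analyses in this package use 0.95 because at strict
1.0 the count responds to single uncovered bases, which reflects sampling
noise rather than library capacity. `assembly_stats()` computes contig
count, total size, average length, N50 (cumulative-half definition) and
GC%, the standard summary row for an assembly table.

## dsRNA quantification

`fit_standard_curve()` regresses fluorescence signal on the marker
dilution series (default `{1, 2.5, 5, 10, 25, 50}` ng/µL) by ordinary
least squares and `estimate_concentration()` inverts the line (classical
calibration; inverse regression is a known alternative and deliberately
not the default). Negative estimates clamp to zero with a `below_range`
flag; estimates outside the calibrated range are flagged `extrapolated`.
A note on validation: "estimate within 3 standard errors" is itself a
statistical event — with 6 points (4 df) an ideal fit misses a 3-SE
interval about 4% of the time, and proportional (heteroscedastic) noise
inflates that to ~37% for the slope. The package therefore validates
coverage *frequency* over 200 replicates of a homoscedastic 5%-noise
design rather than asserting a single draw.

## Validation problem sizes

The shipped validation suite runs entirely on simulated data at sizes
chosen to exercise every code path at desk scale: terminus recovery on a
7-virus community (~20–25 segments, 1–5 kb) sequenced to 70 000 pairs
with enrichment 50 and error 0.002, scored on segments with achieved
depth ≥ 30×, with 200-bp-truncated contigs as negative controls; a
400-track type-I study at enrichment 1; strand assignment on 10 000
error-free pairs; accounting on 20 000-pair libraries at dimer rates 0.05
and 0.3; and a ten-seed library-size comparison of 30 000- vs 3 000-pair
libraries (10× apart, the smaller with dimer rate 0.3) over communities
spanning two orders of abundance. These sizes are the package's own
choices for a laptop-scale validation; all knobs scale up freely.

## Known limitations

* The completeness call is per-contig; grouping segments into viruses via
  shared termini is not implemented.
* The internal mapper requires a clean 24-nt 5′ prefix; heavily
  error-laden or indel-bearing reads should be aligned externally.
* Terminal enrichment is phenomenological — one multiplier, no
  end-chemistry model — so simulator-based power estimates translate to
  real libraries only through that multiplier.
* The Grubbs test assumes approximately independent junction counts;
  strongly uneven coverage (amplification hotspots) can inflate interior
  counts and cost sensitivity at weakly covered termini.
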