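# Depth/breadth of coverage per reference and contig assembly statistics.

#' Depth and breadth of coverage per reference
#'
#' Depth is the average number of times a reference base is covered by
#' aligned reads (sum of aligned bases over reference length); breadth is
#' the fraction of reference bases covered at least once. Each mate of a
#' pair counts as an independent alignment.
#'
#' @param aln Alignment data.frame with `ref_id`, `start`, `end` (0-based
#'   half-open intervals within the reference).
#' @param ref_lengths Named integer vector of reference lengths (> 0).
#' @return data.frame: `ref_id`, `length`, `n_reads`, `depth`, `breadth`.
#' @export
depth_breadth <- function(aln, ref_lengths) {
  stopifnot(all(ref_lengths > 0))
  out <- lapply(names(ref_lengths), function(rid) {
    L <- ref_lengths[[rid]]
    a <- aln[aln$ref_id == rid, , drop = FALSE]
    if (nrow(a)) {
      stopifnot(all(a$start >= 0), all(a$end <= L), all(a$start < a$end))
      ir <- IRanges::IRanges(start = a$start + 1L, end = a$end)
      covered <- sum(IRanges::width(IRanges::reduce(ir)))
      depth <- sum(a$end - a$start) / L
    } else {
      covered <- 0L
      depth <- 0
    }
    data.frame(ref_id = rid, length = L, n_reads = nrow(a), depth = depth,
               breadth = covered / L, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Assembly summary statistics for a contig set
#'
#' N50 is the length at which the cumulative length of contigs sorted in
#' descending order first reaches half of the total assembly size; GC
#' content is computed over all bases.
#'
#' @param contigs Named `DNAStringSet` (or character vector) of contigs.
#' @return data.frame: `n_contigs`, `total_size_bp`, `average_length_bp`,
#'   `n50_bp`, `gc_percent`.
#' @export
assembly_stats <- function(contigs) {
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  if (!length(contigs)) stop("empty contig set")
  w <- Biostrings::width(contigs)
  total <- sum(w)
  ws <- sort(w, decreasing = TRUE)
  n50 <- ws[which(cumsum(ws) >= total / 2)[1L]]
  gc <- sum(Biostrings::letterFrequency(contigs, c("G", "C")))
  data.frame(n_contigs = length(contigs), total_size_bp = total,
             average_length_bp = total / length(contigs),
             n50_bp = n50, gc_percent = 100 * gc / total)
}

#' Compare coverage across libraries over a shared reference set
#'
#' @param summaries Named list of [depth_breadth()] tables, one per
#'   library, all over the same references.
#' @param breadth_threshold A reference counts as "retrieved complete" in a
#'   library when its breadth reaches this value (default 1, i.e. every
#'   base covered; 0.95 is a common relaxation for ragged ends).
#' @return List with `table` (long format: `library`, `ref_id`, `depth`,
#'   `breadth`, `retrieved_complete`) and `retrieved` (named count of
#'   retrieved-complete references per library).
#' @export
compare_libraries <- function(summaries, breadth_threshold = 1.0) {
  stopifnot(length(summaries) >= 1, !is.null(names(summaries)))
  ref_sets <- lapply(summaries, function(s) sort(s$ref_id))
  for (i in seq_along(ref_sets)[-1]) {
    if (!identical(ref_sets[[1]], ref_sets[[i]])) {
      d <- c(setdiff(ref_sets[[1]], ref_sets[[i]]),
             setdiff(ref_sets[[i]], ref_sets[[1]]))
      stop("libraries cover different reference sets; differing: ",
           paste(d, collapse = ", "))
    }
  }
  tab <- do.call(rbind, lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    data.frame(library = nm, ref_id = s$ref_id, depth = s$depth,
               breadth = s$breadth,
               retrieved_complete = s$breadth >= breadth_threshold,
               stringsAsFactors = FALSE)
  }))
  retrieved <- vapply(split(tab$retrieved_complete, tab$library), sum, 0)
  list(table = tab, retrieved = retrieved[names(summaries)])
}
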