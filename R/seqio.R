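#' Reverse complement of nucleotide sequences
#'
#' Watson-Crick complement, reversed. `N` maps to `N`. Input is validated
#' against the alphabet `{A,C,G,T,N}` (lowercase accepted and uppercased).
#'
#' @param seq Character vector of nucleotide sequences.
#' @return Character vector of the same length and element widths.
#' @examples
#' reverse_complement("GACGTAAGAACGTCGCACCA")
#' @export
reverse_complement <- function(seq) {
  if (length(seq) == 0L) return(character(0))
  seq <- toupper(seq)
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop("non-nucleotide character in sequence(s): ",
         paste(utils::head(which(bad), 3L), collapse = ", "))
  }
  out <- character(length(seq))
  empty <- !nzchar(seq)
  out[empty] <- ""
  if (any(!empty)) {
    out[!empty] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seq[!empty])))
  }
  out
}

#' Read a FASTQ file into a read table
#'
#' Returns one row per record with Phred+33 quality strings kept verbatim.
#' Bases are uppercased on ingest.
#'
#' @param path FASTQ file (uncompressed or gzipped).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (file.size(path) %in% c(0L, NA_integer_) && file.exists(path)) {
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  }
  parsed <- tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    list(ids = names(x), seqs = toupper(as.character(x)),
         quals = as.character(S4Vectors::mcols(x)$qualities))
  }, error = function(e) stop("malformed FASTQ in '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  seqs <- parsed$seqs
  quals <- parsed$quals
  # structural check: the parser is lenient about truncated final records
  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines %% 4L != 0L || length(seqs) != n_lines %/% 4L) {
    stop("malformed FASTQ in '", path, "': truncated record near '",
         if (length(parsed$ids)) utils::tail(parsed$ids, 1L) else "<start>",
         "'", call. = FALSE)
  }
  if (any(nchar(seqs) != nchar(quals))) {
    i <- which(nchar(seqs) != nchar(quals))[1L]
    stop("quality/sequence length mismatch at record '", parsed$ids[i],
         "' in '", path, "'", call. = FALSE)
  }
  data.frame(id = parsed$ids, seq = unname(seqs), qual = unname(quals),
             stringsAsFactors = FALSE)
}

#' Write a read table as FASTQ
#'
#' Inverse of [read_fastq()]: emits standard 4-line records with a bare `+`
#' separator, so reading then writing a conforming file reproduces it
#' byte-identically.
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path Output file.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    stop("quality/sequence length mismatch at record '",
         reads$id[which(nchar(reads$seq) != nchar(reads$qual))[1L]], "'")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  if (nrow(reads)) {
    lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read reference sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named `DNAStringSet` (uppercased).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  names(x) <- sub("\\s.*$", "", names(x))
  Biostrings::DNAStringSet(toupper(x))
}

#' Write reference sequences to FASTA
#' @param refs Named `DNAStringSet` or named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(refs, path) {
  if (is.character(refs)) refs <- Biostrings::DNAStringSet(refs)
  Biostrings::writeXStringSet(refs, path, format = "fasta")
  invisible(path)
}

# Parse "|ADAPTOR:END" read-name suffixes (scheme written by the clean stage
# so junction annotations survive external aligners). Returns a list with the
# bare id and, preferring U2 over UPM, the junction adaptor and read end.
parse_junction_name <- function(qname) {
  parts <- strsplit(qname, "|", fixed = TRUE)
  id <- vapply(parts, `[[`, "", 1L)
  adaptor <- rep(NA_character_, length(qname))
  end <- rep(NA_character_, length(qname))
  tags <- lapply(parts, function(p) p[-1L])
  has <- lengths(tags) > 0L
  if (any(has)) {
    pick <- vapply(tags[has], function(tg) {
      u2 <- grep("^U2:", tg, value = TRUE)
      if (length(u2)) u2[1L] else tg[1L]
    }, "")
    adaptor[has] <- sub(":.*$", "", pick)
    end[has] <- sub("^.*:", "", pick)
  }
  list(id = id, adaptor = adaptor, end = end)
}

#' Read alignments from a SAM file
#'
#' Mapped records are returned with 0-based half-open reference intervals;
#' strand comes from flag bit 0x10 and soft-clipped bases are excluded from
#' the interval. Adaptor-junction annotations encoded in read names by
#' [clean_reads()] (suffix scheme `|U2:5p`, `|UPM:3p`, ...) are decoded into
#' `junction_adaptor` / `junction_end`, and `junction_pos` gives the
#' reference coordinate of the adaptor-adjacent aligned base.
#'
#' @param path SAM (or BAM) file with `@SQ` headers.
#' @return data.frame with columns `read_id`, `ref_id`, `start`, `end`,
#'   `strand`, `junction_adaptor`, `junction_end`, `junction_pos`.
#' @export
read_sam <- function(path) {
  is_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  bam <- if (is_bam) path else
    tryCatch(
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("malformed SAM in '", path, "': ",
                               conditionMessage(e), call. = FALSE))
  g <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(what = c("qname", "flag")))
  qn <- S4Vectors::mcols(g)$qname
  jn <- parse_junction_name(qn)
  strand <- as.character(BiocGenerics::strand(g))
  start0 <- BiocGenerics::start(g) - 1L
  end0 <- BiocGenerics::end(g)
  aln <- data.frame(
    read_id = jn$id,
    ref_id = as.character(GenomeInfoDb::seqnames(g)),
    start = start0, end = end0, strand = strand,
    junction_adaptor = jn$adaptor, junction_end = jn$end,
    stringsAsFactors = FALSE)
  aln$junction_pos <- junction_position(aln)
  aln
}

# Reference coordinate of the adaptor-adjacent aligned base. For an adaptor
# at the read 5' end this is the first aligned base in read orientation; for
# the 3' end, the last.
junction_position <- function(aln) {
  pos <- rep(NA_integer_, nrow(aln))
  five <- !is.na(aln$junction_end) & aln$junction_end == "5p"
  three <- !is.na(aln$junction_end) & aln$junction_end == "3p"
  plus <- aln$strand == "+"
  pos[five & plus] <- aln$start[five & plus]
  pos[five & !plus] <- aln$end[five & !plus] - 1L
  pos[three & plus] <- aln$end[three & plus] - 1L
  pos[three & !plus] <- aln$start[three & !plus]
  pos
}

#' Write alignments as SAM
#'
#' Emits ungapped alignments (`<n>M` CIGAR) with read bases stored in
#' reference orientation, as produced by [map_reads()]. Junction annotations
#' present in `aln$junction_adaptor`/`junction_end` are appended to read
#' names using the `|ADAPTOR:END` scheme consumed by [read_sam()].
#'
#' @param aln Alignment data.frame (`read_id`, `ref_id`, `start`, `end`,
#'   `strand`, optionally junction columns and `seq`).
#' @param ref_lengths Named integer vector of reference lengths.
#' @param path Output SAM path.
#' @export
write_sam <- function(aln, ref_lengths, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  writeLines(hdr, con)
  if (nrow(aln)) {
    qname <- aln$read_id
    if (!is.null(aln$junction_adaptor)) {
      tag <- !is.na(aln$junction_adaptor)
      qname[tag] <- paste0(qname[tag], "|", aln$junction_adaptor[tag], ":",
                           aln$junction_end[tag])
    }
    flag <- ifelse(aln$strand == "-", 16L, 0L)
    len <- aln$end - aln$start
    # SAM stores sequences in reference (plus-strand) orientation
    sq <- seq_read_orient(aln)
    seq_ref <- sq
    neg <- aln$strand == "-"
    if (any(neg)) seq_ref[neg] <- reverse_complement(sq[neg])
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                       qname, flag, aln$ref_id, aln$start + 1L, len, seq_ref),
               con)
  }
  invisible(path)
}

# Read bases in read orientation, or Ns when absent.
seq_read_orient <- function(aln) {
  if (!is.null(aln$seq)) aln$seq else strrep("N", aln$end - aln$start)
}
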