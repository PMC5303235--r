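#' Read a FASTA file into reference genomes
#'
#' Sequences are case-folded to upper case; `U` is rejected. An empty file
#' yields an empty list with a warning.
#'
#' @param path FASTA file.
#' @param circular logical, recycled over records.
#' @return list of [reference_genome()].
#' @export
read_fasta <- function(path, circular = TRUE) {
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("FASTA parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    return(list())
  }
  circular <- rep_len(circular, length(set))
  out <- lapply(seq_along(set), function(i) {
    reference_genome(sub("\\s.*", "", names(set)[i]),
                     as.character(set[[i]]), circular = circular[i])
  })
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Write sequences to FASTA
#'
#' @param x list of [reference_genome()] or a named character vector.
#' @param path output file.
#' @param width line wrap width.
#' @export
write_fasta <- function(x, path, width = 60) {
  if (is.list(x) && length(x) && inherits(x[[1]], "ReferenceGenome")) {
    seqs <- vapply(x, `[[`, "", "sequence")
    names(seqs) <- vapply(x, `[[`, "", "id")
    x <- seqs
  }
  set <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read single-end FASTQ (Phred+33)
#'
#' A hand-validated reader so that malformed records are reported with their
#' line number, which the assembly pipeline's provenance reports rely on.
#'
#' @param path FASTQ file.
#' @return `data.frame` with id, bases, quals.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    warning("empty FASTQ file: ", path)
    return(data.frame(id = character(), bases = character(),
                      quals = character(), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4 != 0L)
    stop("FASTQ parse error: truncated record near line ", length(lines))
  n <- length(lines) / 4L
  hdr <- lines[seq(1, length(lines), 4)]
  seqs <- toupper(lines[seq(2, length(lines), 4)])
  plus <- lines[seq(3, length(lines), 4)]
  quals <- lines[seq(4, length(lines), 4)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop("FASTQ parse error: missing '@' header at line ", (bad[1] - 1L) * 4L + 1L)
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop("FASTQ parse error: missing '+' separator at line ", (bad[1] - 1L) * 4L + 3L)
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop("FASTQ parse error: sequence/quality length mismatch at line ",
         (bad[1] - 1L) * 4L + 2L)
  bad <- which(grepl("U", seqs, fixed = TRUE))
  if (length(bad))
    stop("FASTQ parse error: RNA base 'U' at line ", (bad[1] - 1L) * 4L + 2L)
  data.frame(id = sub("\\s.*", "", substring(hdr, 2)), bases = seqs,
             quals = quals, stringsAsFactors = FALSE)
}

#' Write single-end FASTQ (Phred+33)
#'
#' @param reads `data.frame` with id, bases, quals.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$bases) == nchar(reads$quals)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$bases, "\n+\n", reads$quals), con)
  invisible(path)
}

#' Read / write tab-separated tables
#'
#' Thin wrappers fixing the dialect used across all pipeline reports
#' (tab-separated, header, no quoting, no row names).
#'
#' @param path file path.
#' @param x `data.frame`.
#' @return `read_tsv` returns a `data.frame`.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export alignments as minimal SAM
#'
#' Unsorted single-end records with 1-based POS, NM tag carrying the edit
#' distance, and the package's three-tier MAPQ.
#'
#' @param alignments alignment `data.frame` from [align_reads()].
#' @param panel the reference panel aligned against.
#' @param path output file.
#' @export
write_sam <- function(alignments, panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (g in panel)
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", g$id, nchar(g$sequence)), con)
  if (nrow(alignments)) {
    flag <- ifelse(alignments$strand == "-", 16L, 0L)
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                       alignments$read_id, flag, alignments$genome_id,
                       alignments$start + 1L, alignments$mapq,
                       alignments$cigar, alignments$oriented,
                       alignments$edit), con)
  }
  invisible(path)
}
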