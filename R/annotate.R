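#' Banded global alignment of two homologous mitogenomes
#'
#' End-to-end alignment minimizing unit-cost edit distance within a diagonal
#' band. For circular inputs the query is first rotated so that a k-mer shared
#' with the reference origin region anchors both origins; the applied rotation
#' is returned so projected coordinates can be mapped back. `N` is a wildcard.
#'
#' @param consensus sequence string (or `ConsensusState`) to annotate.
#' @param annotated_ref a [reference_genome()] carrying features.
#' @param band maximum diagonal offset (default 200).
#' @param circular rotate the consensus to the reference origin first.
#' @param anchor_k anchor k-mer length.
#' @return a `GenomeAlignment`: list with `edit`, `cigar` (M/I/D, I = base in
#'   consensus only), `rotation` (original coordinate = (rotated + rotation)
#'   mod L), `ref_to_cons` (per reference position, 0-based rotated-consensus
#'   coordinate or NA when deleted), `cons_to_ref`.
#' @export
global_align <- function(consensus, annotated_ref, band = 200,
                         circular = TRUE, anchor_k = 20) {
  if (inherits(consensus, "ConsensusState")) consensus <- consensus$sequence
  ref <- annotated_ref$sequence
  rotation <- 0L
  cons <- consensus
  L <- nchar(cons)
  if (circular && annotated_ref$circular) {
    rotation <- find_rotation(cons, ref, anchor_k)
    if (rotation != 0L)
      cons <- paste0(substr(cons, rotation + 1, L), substr(cons, 1, rotation))
  }
  al <- cpp_banded_global(cons, ref, as.integer(band))
  maps <- cigar_maps(al$cigar, nchar(cons), nchar(ref))
  structure(list(edit = al$edit, cigar = al$cigar, rotation = rotation,
                 consensus_rotated = cons, reference = ref,
                 ref_to_cons = maps$b_to_a, cons_to_ref = maps$a_to_b),
            class = "GenomeAlignment")
}

# find rotation r such that rotated consensus (orig = (rot + r) mod L) starts
# near the reference origin: locate an exact reference-start k-mer in the
# consensus, trying successive reference offsets until one hits uniquely
find_rotation <- function(cons, ref, k = 20) {
  L <- nchar(cons)
  dbl <- paste0(cons, substr(cons, 1, k))
  for (off in seq(0, min(2000, nchar(ref) - k), by = 37)) {
    kmer <- substr(ref, off + 1, off + k)
    if (grepl("N", kmer, fixed = TRUE)) next
    hit <- Biostrings::matchPattern(kmer, Biostrings::DNAString(dbl))
    if (length(hit) == 1L) {
      return(as.integer((BiocGenerics::start(hit)[1] - 1L - off) %% L))
    }
  }
  0L
}

# coordinate maps from a global cigar over a (length n) and b (length m)
cigar_maps <- function(cigar, n, m) {
  ops <- cigar_ops(cigar)
  a_to_b <- rep(NA_integer_, n)
  b_to_a <- rep(NA_integer_, m)
  i <- 0L; j <- 0L
  for (r in seq_len(nrow(ops))) {
    len <- ops$len[r]
    if (ops$op[r] == "M") {
      a_to_b[(i + 1):(i + len)] <- j + 0:(len - 1L)
      b_to_a[(j + 1):(j + len)] <- i + 0:(len - 1L)
      i <- i + len; j <- j + len
    } else if (ops$op[r] == "I") i <- i + len
    else j <- j + len
  }
  list(a_to_b = a_to_b, b_to_a = b_to_a)
}

cigar_ops <- function(cigar) {
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[MID]", cigar))[[1]]
  data.frame(len = len, op = op, stringsAsFactors = FALSE)
}

#' Project reference features onto an aligned consensus
#'
#' Each feature boundary is mapped through the global alignment; a boundary
#' falling in a deletion maps to the nearest aligned column toward the
#' feature interior and the projection is flagged. CDS projections are
#' validated under the vertebrate mitochondrial code.
#'
#' @param alignment a `GenomeAlignment` from [global_align()].
#' @param features feature `data.frame` of the annotated reference (name,
#'   kind, start, end, strand; 0-based half-open).
#' @return `data.frame` of `FeatureProjection`s: source and projected
#'   intervals (on the rotated consensus), `n_indels_within`, `flagged`, and
#'   CDS validation columns.
#' @export
project_features <- function(alignment, features) {
  map <- alignment$ref_to_cons
  m <- length(map)
  out <- features
  out$proj_start <- NA_integer_; out$proj_end <- NA_integer_
  out$n_indels_within <- NA_integer_; out$flagged <- FALSE
  out$start_ok <- NA; out$stop_ok <- NA
  out$no_internal_stop <- NA; out$length_multiple_of_3 <- NA
  for (i in seq_len(nrow(features))) {
    s <- features$start[i]; e <- features$end[i]  # half-open on reference
    ps <- map[s + 1L]
    pe <- if (e <= m) { if (e == m) NA else map[e + 1L] } else NA
    flagged <- FALSE
    if (is.na(ps)) {  # start deleted: move inward (rightwards)
      k <- s + 1L
      while (k < e && is.na(map[k + 1L])) k <- k + 1L
      ps <- if (k < e) map[k + 1L] else NA
      flagged <- TRUE
    }
    # end boundary: map the last included base, inward (leftwards) on deletion
    k <- e - 1L
    while (k > s && is.na(map[k + 1L])) { k <- k - 1L; flagged <- TRUE }
    pe_incl <- map[k + 1L]
    if (is.na(ps) || is.na(pe_incl)) {
      out$flagged[i] <- TRUE
      next
    }
    out$proj_start[i] <- ps
    out$proj_end[i] <- pe_incl + 1L
    span_ref <- e - s
    span_cons <- pe_incl + 1L - ps
    out$n_indels_within[i] <- abs(span_cons - span_ref)
    out$flagged[i] <- flagged
    if (features$kind[i] == "CDS") {
      seq <- substr(alignment$consensus_rotated, ps + 1L, pe_incl + 1L)
      if (features$strand[i] == "-") seq <- revcomp(seq)
      v <- validate_cds(seq)
      out$start_ok[i] <- v$start_ok
      out$stop_ok[i] <- v$stop_ok
      out$no_internal_stop[i] <- v$no_internal_stop
      out$length_multiple_of_3[i] <- v$length_multiple_of_3
      if (v$flagged) out$flagged[i] <- TRUE
    }
  }
  out
}

#' Validate a coding sequence under the vertebrate mitochondrial code
#'
#' Start codons ATG, ATA or GTG; stop codons TAA, TAG, AGA or AGG, or an
#' incomplete terminal `T`/`TA` (completed by polyadenylation; accepted but
#' flagged); no internal stop codon in frame.
#'
#' @param seq CDS nucleotide sequence, 5' to 3' on the coding strand.
#' @return list with `start_ok`, `stop_ok`, `no_internal_stop`,
#'   `length_multiple_of_3`, `flagged`.
#' @export
validate_cds <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  starts <- c("ATG", "ATA", "GTG")
  stops <- c("TAA", "TAG", "AGA", "AGG")
  start_ok <- n >= 3 && substr(seq, 1, 3) %in% starts
  rem <- n %% 3
  flagged <- FALSE
  if (rem == 0) {
    last <- substr(seq, n - 2, n)
    stop_ok <- last %in% stops
    body_end <- n - 3
  } else {
    tail <- substr(seq, n - rem + 1, n)
    stop_ok <- tail %in% c("T", "TA")   # incomplete stop, polyadenylated
    flagged <- stop_ok
    body_end <- n - rem
  }
  ncod <- body_end %/% 3
  internal <- if (ncod >= 2) {
    cods <- substring(seq, seq(4, by = 3, length.out = ncod - 1),
                      seq(6, by = 3, length.out = ncod - 1))
    any(cods %in% stops)
  } else FALSE
  list(start_ok = start_ok, stop_ok = stop_ok,
       no_internal_stop = !internal,
       length_multiple_of_3 = rem == 0, flagged = flagged)
}
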