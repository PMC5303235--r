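#' Read-length-dependent maximum edit distance
#'
#' The smallest non-negative integer `k` such that the upper-tail probability
#' `P(X > k)` of `X ~ Poisson(err * l)` falls below `miss_thres` — the rule
#' BWA's `-n 0.1` uses, giving 1 allowed difference for 20-26 nt reads up to
#' 4 for 88-101 nt reads at the default 2% error rate.
#'
#' @param l read length(s).
#' @param err assumed per-base error rate.
#' @param miss_thres tolerated probability of missing a true alignment.
#' @return integer vector of maximum edit distances, monotone in `l`.
#' @export
maxdiff <- function(l, err = 0.02, miss_thres = 0.1) {
  stopifnot(all(l >= 1))
  cpp_maxdiff(as.integer(l), err, miss_thres)
}

#' Aligner parameters
#'
#' @param err assumed per-base error rate (drives [maxdiff()]).
#' @param miss_thres missing-alignment probability threshold.
#' @param max_gap_opens maximum gap openings per alignment (0-2).
#' @param seed_len exact k-mer seed length; 9 guarantees a clean seed for any
#'   substitution-only placement within [maxdiff()] at every read length.
#' @return an `AlignerParams` list.
#' @export
aligner_params <- function(err = 0.02, miss_thres = 0.1, max_gap_opens = 1,
                           seed_len = 9) {
  stopifnot(err > 0, err < 1, miss_thres > 0, miss_thres < 1,
            max_gap_opens %in% 0:2, seed_len >= 4)
  structure(list(err = err, miss_thres = miss_thres,
                 max_gap_opens = as.integer(max_gap_opens),
                 seed_len = as.integer(seed_len)), class = "AlignerParams")
}

#' Align short reads against a small reference panel
#'
#' Candidate loci are found by exact k-mer seeding on both strands (circular
#' references are extended across the origin), scored by banded unit-cost edit
#' distance with a cap on gap openings, and kept when the edit distance is at
#' most [maxdiff()] of the read length. An uncalled (`N`) reference position
#' carries no evidence, so by default it scores as a mismatch — provisional
#' consensus gaps therefore neither attract nor veto reads; set
#' `n_wildcard_free = TRUE` (used for PCR fragments spanning gaps) to make `N`
#' match at zero cost instead. Per read and genome the best placement is
#' reported; mapping quality encodes placement uniqueness across the whole
#' panel in three tiers: 0 when a rival placement is at least as good, 20
#' when a rival exists exactly one edit worse, and 37 otherwise.
#'
#' @param reads `data.frame` with id, bases (quals optional).
#' @param panel list of [reference_genome()].
#' @param params an [aligner_params()].
#' @param n_wildcard_free make reference `N` match at zero cost.
#' @return `data.frame`, one row per read and genome (the best placement
#'   there): read_id, genome_id, start (0-based, modulo the genome length),
#'   strand, edit, n_wild (bases aligned against reference N), gap_opens,
#'   cigar, oriented (read as aligned to the forward reference strand), mapq,
#'   co_optimal (placements at least as good, including this one),
#'   evidential (within [maxdiff()]). Reads shorter than `seed_len` or
#'   without an acceptable placement are absent.
#' @export
align_reads <- function(reads, panel, params = aligner_params(),
                        n_wildcard_free = FALSE) {
  hits <- align_raw(reads, panel, params, n_wildcard_free)
  if (nrow(hits) == 0L) {
    return(data.frame(read_id = character(), genome_id = character(),
                      start = integer(), strand = character(),
                      edit = integer(), n_wild = integer(),
                      gap_opens = integer(), cigar = character(),
                      oriented = character(), mapq = integer(),
                      co_optimal = integer(), evidential = logical(),
                      stringsAsFactors = FALSE))
  }
  ids <- vapply(panel, `[[`, "", "id")
  # three-tier mapping quality from placement uniqueness across the panel
  n_le <- integer(nrow(hits))    # rivals at least as good as this placement
  n_plus1 <- integer(nrow(hits)) # rivals exactly one edit worse
  grp <- split(seq_len(nrow(hits)), hits$read)
  for (g in grp) {
    if (length(g) == 1L) next
    e <- hits$edit[g]
    for (t in seq_along(g)) {
      n_le[g[t]] <- sum(e[-t] <= e[t])
      n_plus1[g[t]] <- sum(e[-t] == e[t] + 1L)
    }
  }
  mapq <- ifelse(n_le > 0L, 0L, ifelse(n_plus1 > 0L, 20L, 37L))
  out <- data.frame(read_id = reads$id[hits$read], genome_id = ids[hits$genome],
                    start = hits$start,
                    strand = ifelse(hits$strand == 1, "+", "-"),
                    edit = hits$edit, n_wild = hits$n_wild,
                    gap_opens = hits$gap_opens, cigar = hits$cigar,
                    oriented = ifelse(hits$strand == 1, reads$bases[hits$read],
                                      revcomp(reads$bases[hits$read])),
                    mapq = mapq,
                    co_optimal = 1L + n_le, evidential = TRUE,
                    stringsAsFactors = FALSE)
  # keep the best placement per (read, genome); deterministic tie-break
  ord <- order(hits$read, hits$genome, hits$edit,
               hits$strand == -1, hits$start)
  out <- out[ord, , drop = FALSE]
  keep <- !duplicated(paste(hits$read[ord], hits$genome[ord]))
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname align_reads
#' @param bases single read sequence.
#' @export
align_read <- function(bases, panel, params = aligner_params()) {
  align_reads(data.frame(id = "read", bases = bases,
                         stringsAsFactors = FALSE), panel, params)
}

# all deduplicated placements (uncollapsed), with 1-based indices into
# reads/panel; internal workhorse shared by align_reads and the co-assembly
# gate
align_raw <- function(reads, panel, params, n_free = FALSE) {
  if (length(panel) == 0L) stop("panel must be non-empty")
  seqs <- vapply(panel, `[[`, "", "sequence")
  circ <- vapply(panel, `[[`, TRUE, "circular")
  res <- cpp_align_reads(reads$bases, seqs, circ, params$err,
                         params$miss_thres, params$max_gap_opens,
                         params$seed_len, n_free)
  res$hits
}
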