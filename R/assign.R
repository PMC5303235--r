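#' Competitive taxonomic assignment against a mitogenome panel
#'
#' A read is credited to a genome only when it matches that genome perfectly —
#' full length, zero mismatches, zero indels, either strand, circular wrap
#' allowed — and matches no other panel genome perfectly. Reads perfect in two
#' or more genomes fall into `n_shared` (never double-counted); reads with
#' only imperfect placements into `n_imperfect_only`; the rest are unmapped.
#'
#' @param reads `data.frame` with id, bases.
#' @param panel list of [reference_genome()].
#' @param params an [aligner_params()]; its `err`/`miss_thres` govern what
#'   counts as an imperfect (as opposed to absent) placement.
#' @return an `AssignmentTable`: list with `per_genome` (`data.frame`:
#'   genome_id, n_perfect_unique, fraction of the whole pool), `n_shared`,
#'   `n_imperfect_only`, `n_unmapped`, `n_reads`.
#' @export
assign_reads <- function(reads, panel, params = aligner_params()) {
  if (length(panel) == 0L) stop("panel must be non-empty")
  aln <- align_reads(reads, panel, params)
  ids <- vapply(panel, `[[`, "", "id")
  n <- nrow(reads)
  counts <- setNames(integer(length(ids)), ids)
  n_shared <- 0L; n_imperfect <- 0L
  if (nrow(aln)) {
    perf <- aln[aln$edit == 0L & aln$n_wild == 0L, , drop = FALSE]
    genomes_per_read <- tapply(perf$genome_id, perf$read_id,
                               function(g) unique(g), simplify = FALSE)
    npg <- lengths(genomes_per_read)
    uniq <- names(npg)[npg == 1L]
    shared <- names(npg)[npg > 1L]
    n_shared <- length(shared)
    if (length(uniq)) {
      tb <- table(vapply(genomes_per_read[uniq], `[[`, "", 1L))
      counts[names(tb)] <- as.integer(tb)
    }
    mapped_ids <- unique(aln$read_id)
    perfect_ids <- unique(perf$read_id)
    n_imperfect <- length(setdiff(mapped_ids, perfect_ids))
  }
  n_unmapped <- n - sum(counts) - n_shared - n_imperfect
  structure(list(
    per_genome = data.frame(genome_id = ids, n_perfect_unique = unname(counts),
                            fraction = unname(counts) / max(n, 1L),
                            stringsAsFactors = FALSE),
    n_shared = n_shared, n_imperfect_only = n_imperfect,
    n_unmapped = n_unmapped, n_reads = n), class = "AssignmentTable")
}

#' @export
print.AssignmentTable <- function(x, ...) {
  top <- x$per_genome[order(-x$per_genome$n_perfect_unique), ][1:min(5, nrow(x$per_genome)), ]
  cat(sprintf("<AssignmentTable: %d reads; shared %d, imperfect-only %d, unmapped %d>\n",
              x$n_reads, x$n_shared, x$n_imperfect_only, x$n_unmapped))
  print(top, row.names = FALSE)
  invisible(x)
}
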