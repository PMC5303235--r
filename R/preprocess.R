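#' Trim one read at the 3' end
#'
#' Removes the longest 3'-suffix that matches a prefix of the adapter
#' (minimum overlap 3 nt, at most 1 mismatch per 10 aligned bases), then any
#' trailing run of `N` bases or bases below the quality floor. Bases and
#' qualities are trimmed in lockstep; the worst case is an empty read.
#'
#' @param bases read sequence.
#' @param quals Phred+33 quality string of equal length.
#' @param adapter adapter sequence (non-empty).
#' @param qual_floor Phred score below which trailing bases are clipped.
#' @param min_overlap minimum adapter overlap considered.
#' @return list with `bases`, `quals`, `adapter_trimmed`, `quality_trimmed`.
#' @export
trim_read <- function(bases, quals, adapter, qual_floor = 2, min_overlap = 3) {
  if (nchar(adapter) == 0L) stop("adapter must be non-empty")
  stopifnot(nchar(bases) == nchar(quals))
  l <- nchar(bases)
  adapter_trimmed <- FALSE
  # longest suffix of read matching a prefix of the adapter
  max_ov <- min(l, nchar(adapter))
  rv <- strsplit(bases, "")[[1]]
  av <- strsplit(adapter, "")[[1]]
  if (max_ov >= min_overlap) {
    for (ov in max_ov:min_overlap) {
      mism <- sum(rv[(l - ov + 1):l] != av[1:ov])
      if (mism <= ov %/% 10) {
        bases <- substr(bases, 1, l - ov)
        quals <- substr(quals, 1, l - ov)
        l <- l - ov
        adapter_trimmed <- TRUE
        break
      }
    }
  }
  # trailing N / low-quality clipping
  quality_trimmed <- FALSE
  if (l > 0) {
    bv <- strsplit(bases, "")[[1]]
    qv <- utf8ToInt(quals) - 33L
    keep <- l
    while (keep > 0 && (bv[keep] == "N" || qv[keep] < qual_floor)) keep <- keep - 1L
    if (keep < l) {
      bases <- substr(bases, 1, keep)
      quals <- substr(quals, 1, keep)
      quality_trimmed <- TRUE
    }
  }
  list(bases = bases, quals = quals, adapter_trimmed = adapter_trimmed,
       quality_trimmed = quality_trimmed)
}

#' Trim a read pool at the 3' end
#'
#' Applies [trim_read()] to every read.
#'
#' @param reads `data.frame` with id, bases, quals.
#' @inheritParams trim_read
#' @return list with `reads` (trimmed, possibly zero-length sequences kept)
#'   and counts `n_adapter_trimmed`, `n_quality_trimmed`.
#' @export
trim_pool <- function(reads, adapter, qual_floor = 2) {
  n <- nrow(reads)
  na <- 0L; nq <- 0L
  if (n) {
    for (i in seq_len(n)) {
      tr <- trim_read(reads$bases[i], reads$quals[i], adapter, qual_floor)
      reads$bases[i] <- tr$bases
      reads$quals[i] <- tr$quals
      na <- na + tr$adapter_trimmed
      nq <- nq + tr$quality_trimmed
    }
  }
  list(reads = reads, n_adapter_trimmed = na, n_quality_trimmed = nq)
}

#' Discard reads below the minimum length
#'
#' Reads shorter than `min_len` nucleotides are discarded; order is preserved.
#'
#' @param reads `data.frame` with id, bases, quals.
#' @param min_len minimum retained length (default 20).
#' @param n_adapter_trimmed,n_quality_trimmed counts carried into the report.
#' @return list with `reads` and a `report` (`TrimReport` row: n_input,
#'   n_adapter_trimmed, n_quality_trimmed, n_discarded_short, n_output).
#' @export
filter_length <- function(reads, min_len = 20, n_adapter_trimmed = 0L,
                          n_quality_trimmed = 0L) {
  if (min_len < 1) stop("min_len must be >= 1")
  n_in <- nrow(reads)
  keep <- nchar(reads$bases) >= min_len
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  report <- data.frame(n_input = n_in,
                       n_adapter_trimmed = as.integer(n_adapter_trimmed),
                       n_quality_trimmed = as.integer(n_quality_trimmed),
                       n_discarded_short = as.integer(sum(!keep)),
                       n_output = as.integer(sum(keep)))
  list(reads = out, report = report)
}

#' Full preprocessing: 3' trimming then length filtering
#'
#' @inheritParams trim_pool
#' @inheritParams filter_length
#' @return list with `reads` and `report` as in [filter_length()].
#' @export
preprocess_reads <- function(reads, adapter, qual_floor = 2, min_len = 20) {
  tr <- trim_pool(reads, adapter, qual_floor)
  filter_length(tr$reads, min_len, tr$n_adapter_trimmed, tr$n_quality_trimmed)
}
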