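#' Reverse complement of DNA strings
#'
#' @param x character vector over A, C, G, T, N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  cpp_revcomp(as.character(x))
}

# substring with circular wrap; start 0-based, len bases
substr_circular <- function(seq, start, len, circular = TRUE) {
  L <- nchar(seq)
  start <- start %% L
  if (start + len <= L) return(substr(seq, start + 1, start + len))
  if (!circular) stop("interval exceeds a linear sequence")
  if (len > L) stop("interval longer than the genome")
  paste0(substr(seq, start + 1, L), substr(seq, 1, len - (L - start)))
}

# Hamming distance of two equal-length strings
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
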