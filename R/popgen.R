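#' Pseudo-haploid genotyping of a low-coverage sample at a SNP panel
#'
#' For each panel site, the read bases of mapping-quality-gated alignments
#' covering the site are tallied; the call is the majority base when it is one
#' of the two panel alleles, supported by at least `min_depth` ref-or-alt
#' reads, with no tie and no third allele outvoting it — otherwise missing.
#' This is the pseudo-haploid re-expression of a diploid depth>=2 / QUAL
#' caller appropriate for ancient low-coverage data.
#'
#' @param alignments alignment `data.frame` (from [align_reads()]) against the
#'   panel reference; apply the mapping-quality gate before calling.
#' @param panel `data.frame` with `chrom`, `pos` (0-based), `ref`, `alt`.
#' @param min_depth minimum ref+alt depth (default 2).
#' @param L reference length (for circular wrap), or NULL for linear.
#' @param circular logical.
#' @return character vector over sites: "ref", "alt", or NA (missing).
#' @export
genotype_sites <- function(alignments, panel, min_depth = 2, L = NULL,
                           circular = FALSE) {
  n_sites <- nrow(panel)
  out <- rep(NA_character_, n_sites)
  if (nrow(alignments) == 0L) return(out)
  if (is.null(L)) L <- max(alignments$start + nchar(alignments$oriented)) + 1L
  pu <- cpp_pileup(alignments$oriented, alignments$start,
                   ifelse(alignments$strand == "+", 1L, -1L),
                   alignments$cigar, as.integer(L), 0L, circular)
  counts <- pu$counts
  rownames(counts) <- c("A", "C", "G", "T", "-")
  for (i in seq_len(n_sites)) {
    p <- panel$pos[i] + 1L
    if (p < 1L || p > ncol(counts)) next
    cr <- counts[panel$ref[i], p]
    ca <- counts[panel$alt[i], p]
    if (cr + ca < min_depth || cr == ca) next
    maj <- if (cr > ca) cr else ca
    other <- max(counts[setdiff(rownames(counts), c(panel$ref[i], panel$alt[i])), p])
    if (other >= maj) next  # third allele outvotes (or ties) the best panel allele
    out[i] <- if (cr > ca) "ref" else "alt"
  }
  out
}

#' Allele-sharing distance between pseudo-haploid samples
#'
#' `d(i, j) = 1 - matches / shared` over sites where both samples are called.
#'
#' @param geno samples x sites matrix of "ref"/"alt"/NA (rows named).
#' @param min_shared minimum shared called sites per pair (default 100).
#' @return symmetric distance matrix.
#' @export
pairwise_allele_distance <- function(geno, min_shared = 100) {
  n <- nrow(geno)
  if (n < 2) stop("need at least 2 samples")
  labs <- rownames(geno) %||% paste0("s", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  bad <- character(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- !is.na(geno[i, ]) & !is.na(geno[j, ])
    ns <- sum(use)
    if (ns < min_shared) {
      bad <- c(bad, paste0(labs[i], "/", labs[j], " (", ns, " shared)"))
      next
    }
    d[i, j] <- d[j, i] <- 1 - sum(geno[i, use] == geno[j, use]) / ns
  }
  if (length(bad))
    stop("insufficient overlap for pair(s): ", paste(bad, collapse = ", "))
  d
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix, eigendecomposes, and returns
#' the top-`k` coordinates scaled by the square root of the eigenvalues
#' (via `stats::cmdscale`). Negative eigenvalues are truncated and reported;
#' when fewer than `k` positive eigenvalues exist a smaller embedding is
#' returned with a warning.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param k target dimensionality (default 2).
#' @return list with `points` (n x k_used), `eig` (all eigenvalues,
#'   non-increasing), `k_used`, `n_negative_eig`.
#' @export
classical_mds <- function(d, k = 2) {
  d <- as.matrix(d)
  if (any(abs(d - t(d)) > 1e-9) || any(diag(d) != 0))
    stop("distance matrix must be symmetric with zero diagonal")
  n <- nrow(d)
  fit <- cmdscale(d, k = min(k, n - 1), eig = TRUE)
  eig <- fit$eig
  npos <- sum(eig > max(eig) * 1e-9)
  k_used <- as.integer(min(k, npos))
  if (k_used < k) {
    warning("only ", k_used, " positive eigenvalue(s); returning a ",
            k_used, "-dimensional embedding")
  }
  pts <- fit$points[, seq_len(k_used), drop = FALSE]
  list(points = pts, eig = eig, k_used = k_used,
       n_negative_eig = sum(eig < 0))
}
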