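#' Substitution-rate profile by distance from read ends
#'
#' Computes, for all 12 substitution types (consensus base to read base, in
#' read-strand space), the rate at each distance 0..`maxd - 1` from the 5' and
#' the 3' read end, as mismatches over aligned consensus bases of the
#' substituted-from type at that distance. Consensus `N` columns are excluded
#' from numerator and denominator. Post-mortem deamination inflates C-to-T at
#' 5' ends and G-to-A at 3' ends; a flat profile suggests modern DNA.
#'
#' @param alignments the unique gated alignments used for the consensus.
#' @param consensus consensus sequence string (or `ConsensusState`).
#' @param circular logical.
#' @param maxd number of end distances profiled (default 25).
#' @return a `DamageProfile`: list with `rates5`/`rates3` (12 x maxd matrices,
#'   rows like "G>A"), `mism5`/`mism3`, `opp5`/`opp3`, `n_aligned_bases`,
#'   `n_mismatches`, `identity_fraction`, `length_histogram`, `median_length`.
#' @export
profile_damage <- function(alignments, consensus, circular = TRUE, maxd = 25) {
  if (inherits(consensus, "ConsensusState")) consensus <- consensus$sequence
  if (nrow(alignments) == 0L) stop("empty alignment set")
  res <- cpp_damage_counts(alignments$oriented, alignments$start,
                           ifelse(alignments$strand == "+", 1L, -1L),
                           alignments$cigar, consensus, circular,
                           as.integer(maxd))
  bases <- c("A", "C", "G", "T")
  shape <- function(m) {
    a <- array(m, dim = c(maxd, 4, 4))  # [d, to, from] given C fill order
    # cpp fills index (fi*4 + ti)*maxd + d -> fastest d, then ti, then fi
    a <- aperm(a, c(3, 2, 1))           # [from, to, d]
    a
  }
  mm5 <- shape(res$m5); mm3 <- shape(res$m3)
  op5 <- matrix(res$op5, nrow = 4, byrow = TRUE,
                dimnames = list(bases, NULL))
  op3 <- matrix(res$op3, nrow = 4, byrow = TRUE,
                dimnames = list(bases, NULL))
  types <- expand.grid(to = bases, from = bases, stringsAsFactors = FALSE)
  types <- types[types$from != types$to, c("from", "to")]
  rn <- paste0(types$from, ">", types$to)
  pick <- function(mm, op) {
    out <- matrix(0, nrow(types), maxd, dimnames = list(rn, NULL))
    msm <- out
    for (i in seq_len(nrow(types))) {
      fi <- match(types$from[i], bases); ti <- match(types$to[i], bases)
      msm[i, ] <- mm[fi, ti, ]
      denom <- op[fi, ]
      out[i, ] <- ifelse(denom > 0, mm[fi, ti, ] / denom, 0)
    }
    list(rates = out, mism = msm)
  }
  p5 <- pick(mm5, op5); p3 <- pick(mm3, op3)
  lens <- nchar(alignments$oriented)
  structure(list(
    rates5 = p5$rates, rates3 = p3$rates, mism5 = p5$mism, mism3 = p3$mism,
    opp5 = op5, opp3 = op3,
    n_aligned_bases = res$n_aligned, n_mismatches = res$n_mismatch,
    identity_fraction = 1 - res$n_mismatch / res$n_aligned,
    length_histogram = table(lens), median_length = median(lens)),
    class = "DamageProfile")
}

#' @export
print.DamageProfile <- function(x, ...) {
  cat(sprintf("<DamageProfile: %.0f aligned bases, identity %.4f, median length %g>\n",
              x$n_aligned_bases, x$identity_fraction, x$median_length))
  cat(sprintf("  G>A 3'-terminal rate %.4f; C>T 5'-terminal rate %.4f\n",
              x$rates3["G>A", 1], x$rates5["C>T", 1]))
  invisible(x)
}

#' Ancient-DNA authenticity verdict from a damage profile
#'
#' `authentic_like` when the terminal G-to-A (3') or C-to-T (5') rate is at
#' least `fold_threshold` times its interior plateau (mean rate over distances
#' 10..24) with at least `min_opportunities` aligned bases of the relevant
#' type at the terminal position; `insufficient` below that opportunity floor;
#' otherwise `flat`.
#'
#' @param profile a `DamageProfile`.
#' @param fold_threshold terminal-over-plateau fold (default 3).
#' @param min_opportunities opportunity floor at the terminal position.
#' @return one of "authentic_like", "flat", "insufficient".
#' @export
authenticity_verdict <- function(profile, fold_threshold = 3,
                                 min_opportunities = 100) {
  opp3 <- profile$opp3["G", 1]
  opp5 <- profile$opp5["C", 1]
  if (max(opp3, opp5) < min_opportunities) return("insufficient")
  plateau_idx <- 11:min(25, ncol(profile$rates3))
  eps <- 1e-6  # plateau floor so a zero-interior profile can still be exceeded
  p3 <- max(mean(profile$rates3["G>A", plateau_idx]), eps)
  p5 <- max(mean(profile$rates5["C>T", plateau_idx]), eps)
  g3 <- profile$rates3["G>A", 1]
  c5 <- profile$rates5["C>T", 1]
  if ((opp3 >= min_opportunities && g3 >= fold_threshold * p3 && g3 > 0.01) ||
      (opp5 >= min_opportunities && c5 >= fold_threshold * p5 && c5 > 0.01))
    return("authentic_like")
  "flat"
}
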