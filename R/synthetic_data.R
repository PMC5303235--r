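#' Reference genome record
#'
#' A named DNA sequence, optionally circular and annotated with features, used
#' as a panel member or assembly reference.
#'
#' @param id short label.
#' @param sequence DNA string over A, C, G, T (N allowed in provisional
#'   consensuses).
#' @param circular logical; mitogenomes are circular.
#' @param features `data.frame` with columns `name`, `kind` (one of CDS, tRNA,
#'   rRNA, D-loop), `start`, `end` (0-based half-open), `strand` (+/-), or
#'   `NULL`.
#' @return an object of class `ReferenceGenome`.
#' @export
reference_genome <- function(id, sequence, circular = TRUE, features = NULL) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("sequence must be non-empty")
  if (grepl("U", sequence, fixed = TRUE)) stop("RNA (U) not accepted")
  if (grepl("[^ACGTN]", sequence)) stop("sequence contains non-ACGTN characters")
  if (!is.null(features)) {
    stopifnot(all(c("name", "kind", "start", "end", "strand") %in% names(features)))
    L <- nchar(sequence)
    bad <- features$start < 0 | features$start >= L |
      (!circular & features$end > L)
    if (any(bad)) stop("feature interval outside the genome")
  }
  structure(list(id = id, sequence = sequence, circular = circular,
                 features = features),
            class = "ReferenceGenome")
}

#' @export
print.ReferenceGenome <- function(x, ...) {
  cat(sprintf("<ReferenceGenome %s: %d bp, %s, %d feature(s)>\n", x$id,
              nchar(x$sequence), if (x$circular) "circular" else "linear",
              if (is.null(x$features)) 0L else nrow(x$features)))
  invisible(x)
}

#' Post-mortem damage and sequencing-error model
#'
#' Terminal deamination rates decay geometrically inward from the read ends:
#' the G-to-A rate at distance `d` from the 3' end is `delta3 * decay^d`, and
#' the C-to-T rate at distance `d` from the 5' end is `delta5 * decay^d`, both
#' in read-strand space. `err` is a uniform per-base sequencing error applied
#' afterwards.
#'
#' @param delta3 G-to-A probability at the 3'-terminal base.
#' @param delta5 C-to-T probability at the 5'-terminal base.
#' @param decay geometric decay per base inward, in (0, 1).
#' @param err uniform per-base error probability.
#' @return an object of class `DamageModel`.
#' @export
damage_model <- function(delta3 = 0, delta5 = 0, decay = 0.5, err = 0) {
  for (p in c(delta3, delta5, err)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  if (decay <= 0 || decay >= 1) stop("decay must lie in (0, 1)")
  structure(list(delta3 = delta3, delta5 = delta5, decay = decay, err = err),
            class = "DamageModel")
}

#' Plant a valid coding sequence into a raw DNA string
#'
#' Overwrites `[start, start + len)` (0-based) so that it begins with ATG,
#' ends with TAA, and contains no internal stop codon of the vertebrate
#' mitochondrial code — used so synthetic genomes carry an annotatable gene
#' that survives divergence simulation when re-planted.
#'
#' @param seq DNA string.
#' @param start 0-based start of the CDS.
#' @param len CDS length, a multiple of 3 (>= 9).
#' @return the edited sequence.
#' @export
plant_cds <- function(seq, start, len) {
  stopifnot(len %% 3 == 0, len >= 9)
  body <- substr(seq, start + 1, start + len)
  codons <- substring(body, seq(1, len, 3), seq(3, len, 3))
  codons[1] <- "ATG"
  codons[length(codons)] <- "TAA"
  stops <- c("TAA", "TAG", "AGA", "AGG")
  inner <- codons[-c(1, length(codons))]
  inner[inner %in% stops] <- "CTG"
  codons[-c(1, length(codons))] <- inner
  paste0(substr(seq, 1, start), paste(codons, collapse = ""),
         substr(seq, start + len + 1, nchar(seq)))
}

#' Generate a star-diverged panel of circular reference genomes
#'
#' Genome 1 is an ancestral random sequence; every other genome differs from
#' it by independent per-site substitutions with probability `divergence`
#' (a star tree, so expected pairwise divergence between two derived genomes
#' is roughly twice the per-genome value). Each genome carries a synthetic CDS
#' with a valid start/stop and no internal stop, plus a D-loop label.
#'
#' @param seed integer seed.
#' @param n_genomes number of genomes (>= 1).
#' @param length genome length in bp (>= 1000).
#' @param divergence per-site substitution probability in [0, 0.25].
#' @param circular logical.
#' @return list of [reference_genome()] objects named `g01`, `g02`, ...
#' @export
generate_panel <- function(seed, n_genomes, length = 16000, divergence = 0.05,
                           circular = TRUE) {
  if (divergence < 0 || divergence > 0.25) stop("divergence must lie in [0, 0.25]")
  if (length < 1000) stop("length must be >= 1000")
  if (n_genomes < 1) stop("n_genomes must be >= 1")
  set.seed(seed)
  anc <- random_dna(length)
  cds_start <- 120L
  cds_len <- 300L
  bases <- c("A", "C", "G", "T")
  feats <- data.frame(
    name = c("synthCDS1", "Dloop"),
    kind = c("CDS", "D-loop"),
    start = c(cds_start, length - 600L),
    end = c(cds_start + cds_len, length - 50L),
    strand = c("+", "+"),
    stringsAsFactors = FALSE)
  out <- vector("list", n_genomes)
  for (i in seq_len(n_genomes)) {
    s <- anc
    if (i > 1L && divergence > 0) {
      v <- strsplit(anc, "")[[1]]
      hit <- which(runif(length) < divergence)
      if (base::length(hit)) {
        v[hit] <- vapply(v[hit], function(b) sample(setdiff(bases, b), 1L), "")
        s <- paste(v, collapse = "")
      }
    }
    s <- plant_cds(s, cds_start, cds_len)
    out[[i]] <- reference_genome(sprintf("g%02d", i), s, circular = circular,
                                 features = feats)
  }
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Simulate an ancient-read pool from a genome panel
#'
#' Fragments are sampled from the panel genomes at the given proportions, with
#' lognormal lengths truncated to \[20, 101\] nt, uniform start positions
#' (wrapping the origin on circular genomes), and reverse-complement
#' orientation with probability 1/2. Deamination damage is then applied in
#' read-strand space per the [damage_model()], followed by uniform sequencing
#' error. Optionally a fraction of reads are exact duplicates of earlier reads
#' (PCR duplicates).
#'
#' @param panel list of [reference_genome()].
#' @param proportions per-genome weights summing to 1.
#' @param total number of reads.
#' @param fraglen list with `meanlog` and `sdlog` of the lognormal length law;
#'   default median 48 nt.
#' @param damage a [damage_model()].
#' @param seed integer seed.
#' @param dup_rate probability that a read is an exact copy of an earlier one.
#' @return a `ReadPool`: list with `reads` (`data.frame`: id, bases, quals) and
#'   `truth` (`data.frame`: read_id, source, start, end, strand, n_damage,
#'   n_error), coordinates 0-based half-open modulo genome length.
#' @export
simulate_reads <- function(panel, proportions, total,
                           fraglen = list(meanlog = log(48), sdlog = 0.35),
                           damage = damage_model(), seed = 1, dup_rate = 0) {
  if (length(panel) == 0L) stop("panel must be non-empty")
  if (any(proportions < 0) || sum(proportions) <= 0)
    stop("proportions must be non-negative and normalizable")
  if (abs(sum(proportions) - 1) > 1e-8) proportions <- proportions / sum(proportions)
  set.seed(seed)
  ng <- length(panel)
  lens <- vapply(panel, function(g) nchar(g$sequence), 0L)
  ids <- vapply(panel, `[[`, "", "id")
  bases4 <- c("A", "C", "G", "T")

  src <- sample.int(ng, total, replace = TRUE, prob = proportions)
  fl <- round(rlnorm(total, fraglen$meanlog, fraglen$sdlog))
  while (any(bad <- fl < 20 | fl > 101)) {
    fl[bad] <- round(rlnorm(sum(bad), fraglen$meanlog, fraglen$sdlog))
  }
  starts <- integer(total); strands <- character(total)
  reads <- character(total); ndmg <- integer(total); nerr <- integer(total)
  dup_of <- rep(NA_integer_, total)
  for (i in seq_len(total)) {
    if (dup_rate > 0 && i > 1L && runif(1) < dup_rate) {
      j <- sample.int(i - 1L, 1L)
      dup_of[i] <- j
      src[i] <- src[j]; fl[i] <- fl[j]; starts[i] <- starts[j]
      strands[i] <- strands[j]; reads[i] <- reads[j]
      ndmg[i] <- ndmg[j]; nerr[i] <- nerr[j]
      next
    }
    g <- panel[[src[i]]]
    L <- lens[src[i]]
    st <- if (g$circular) sample.int(L, 1L) - 1L else sample.int(L - fl[i] + 1L, 1L) - 1L
    frag <- substr_circular(g$sequence, st, fl[i], g$circular)
    fwd <- runif(1) < 0.5
    rd <- if (fwd) frag else revcomp(frag)
    v <- strsplit(rd, "")[[1]]
    l <- length(v)
    # deamination in read-strand space
    d3 <- (l - 1):0  # distance from 3' end per position
    d5 <- 0:(l - 1)
    pGA <- damage$delta3 * damage$decay^d3
    pCT <- damage$delta5 * damage$decay^d5
    hitG <- v == "G" & runif(l) < pGA
    hitC <- v == "C" & runif(l) < pCT
    v[hitG] <- "A"; v[hitC] <- "T"
    nd <- sum(hitG) + sum(hitC)
    # uniform sequencing error
    he <- runif(l) < damage$err
    if (any(he)) {
      v[he] <- vapply(v[he], function(b) sample(setdiff(bases4, b), 1L), "")
    }
    starts[i] <- st %% L
    strands[i] <- if (fwd) "+" else "-"
    reads[i] <- paste(v, collapse = "")
    ndmg[i] <- nd
    nerr[i] <- sum(he)
  }
  id <- sprintf("read%06d", seq_len(total))
  pool <- list(
    reads = data.frame(id = id, bases = reads,
                       quals = strrep(rawToChar(as.raw(33 + 37)), fl),
                       stringsAsFactors = FALSE),
    truth = data.frame(read_id = id, source = ids[src], start = starts,
                       end = (starts + fl) %% lens[src], strand = strands,
                       n_damage = ndmg, n_error = nerr, dup_of = dup_of,
                       stringsAsFactors = FALSE))
  class(pool) <- "ReadPool"
  pool
}

#' Extract error-free PCR consensus fragments from a genome
#'
#' Emulates Sanger-sequenced PCR amplicon consensuses used to fill assembly
#' gaps: exact substrings labelled with their source interval.
#'
#' @param genome a [reference_genome()].
#' @param intervals `data.frame` or matrix with columns `start`, `end`
#'   (0-based half-open; `end < start` wraps the origin on circular genomes).
#' @return `data.frame` with id, start, end, sequence.
#' @export
simulate_pcr_fragments <- function(genome, intervals) {
  intervals <- as.data.frame(intervals)
  L <- nchar(genome$sequence)
  out <- lapply(seq_len(nrow(intervals)), function(i) {
    s <- intervals$start[i]; e <- intervals$end[i]
    if (s < 0 || s >= L || e < 0 || e > L) stop("interval outside the genome")
    len <- if (e > s) e - s else (L - s) + e
    if (e <= s && !genome$circular) stop("wrapping interval on a linear genome")
    data.frame(id = sprintf("pcr%03d", i), start = s, end = e %% L,
               sequence = substr_circular(genome$sequence, s, len,
                                          genome$circular),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
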