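#' Collapse duplicate read placements
#'
#' Alignments identical in (genome, start, strand, read bases) are PCR/optical
#' duplicates of one molecule and collapse to a single representative.
#'
#' @param alignments alignment `data.frame` from [align_reads()].
#' @return list with `alignments` (unique) and `n_collapsed`.
#' @export
dedup_unique <- function(alignments) {
  if (nrow(alignments) == 0L)
    return(list(alignments = alignments, n_collapsed = 0L))
  key <- paste(alignments$genome_id, alignments$start, alignments$strand,
               alignments$oriented, sep = "\r")
  keep <- !duplicated(key)
  list(alignments = alignments[keep, , drop = FALSE],
       n_collapsed = sum(!keep))
}

#' Exclusive-mapping filter
#'
#' Keeps alignments to the target genome whose read has no accepted placement
#' on the competitor genome and whose mapping quality passes the gate
#' (>= `mq_min`, or > when `strict`). A competitor placement only excludes a
#' read when it is evidential — its edit distance stays within [maxdiff()]
#' with uncalled (N) reference positions counted as mismatches — so uncalled
#' stretches of a provisional competitor consensus cannot veto reads.
#'
#' @param alignments alignment `data.frame` covering both genomes.
#' @param target,competitor genome ids present in the alignment panel.
#' @param mq_min mapping-quality gate (default 25).
#' @param strict use a strictly-greater gate.
#' @return the filtered alignment `data.frame`.
#' @export
exclusivity_filter <- function(alignments, target, competitor, mq_min = 25,
                               strict = FALSE) {
  comp_hits <- alignments$genome_id %in% competitor
  if (!is.null(alignments$evidential)) comp_hits <- comp_hits & alignments$evidential
  comp_reads <- unique(alignments$read_id[comp_hits])
  keep <- alignments$genome_id == target &
    !(alignments$read_id %in% comp_reads) &
    (if (strict) alignments$mapq > mq_min else alignments$mapq >= mq_min)
  out <- alignments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build pileup columns for one genome
#'
#' Tallies base support per reference column from gated unique read
#' alignments, plus separate support from PCR consensus fragments, and the
#' damage-qualifying observation counts used to explain G-to-A disputes.
#'
#' @param alignments unique, gated alignments to this genome.
#' @param L reference length.
#' @param circular logical.
#' @param pcr optional PCR fragment alignments (same columns).
#' @param damage_window bases from the read 3' end within which an A-vs-G
#'   (read-strand) observation counts as damage-explainable.
#' @return list with `counts` (5 x L: A, C, G, T, gap), `pcr_counts`,
#'   `dmgA`, `dmgT`.
#' @export
build_columns <- function(alignments, L, circular = TRUE, pcr = NULL,
                          damage_window = 10) {
  pile <- function(df) {
    if (is.null(df) || nrow(df) == 0L) {
      list(counts = matrix(0L, 5, L), dmgA = integer(L), dmgT = integer(L))
    } else {
      cpp_pileup(df$oriented, df$start, ifelse(df$strand == "+", 1L, -1L),
                 df$cigar, L, as.integer(damage_window), circular)
    }
  }
  p <- pile(alignments)
  q <- pile(pcr)
  rownames(p$counts) <- rownames(q$counts) <- c("A", "C", "G", "T", "-")
  list(counts = p$counts, pcr_counts = q$counts, dmgA = p$dmgA, dmgT = p$dmgT)
}

#' Call a majority consensus over pileup columns
#'
#' Per column: with total support (unique reads plus PCR fragments) below
#' `min_concordant` the call is `N`, flagged `no_coverage` (depth 0) or
#' `single_coverage` (depth 1). Otherwise the most frequent base is taken,
#' requiring at least `min_concordant` agreeing sequences; ties give `N`
#' flagged `disputed`. When more than `dispute_frac` of the evidence disagrees
#' with the majority the column is flagged `disputed`; if every disagreeing
#' read base is a read-strand G-to-A observation within `damage_window` of the
#' contributing read's 3' end, it is additionally flagged `damage_explained`
#' and the majority base stands. Disputed columns that are not damage
#' explained keep the majority base only when a PCR fragment concurs,
#' otherwise `N`.
#'
#' @param columns output of [build_columns()].
#' @param genome_id label carried into the state.
#' @param iteration iteration index (0 = first reference-guided pass).
#' @param min_concordant minimum concordant unique sequences (default 2).
#' @param dispute_frac disagreement fraction triggering review (default 0.25).
#' @return a `ConsensusState`: list with `genome_id`, `iteration`, `calls`
#'   (per-column character, `-` = deleted), `sequence` (calls with deletions
#'   removed), `flags` (logical matrix), `depth_unique`, `depth_pcr`,
#'   `gap_report` and `singleton_report` (0-based half-open intervals /
#'   positions on the column coordinates).
#' @export
call_consensus <- function(columns, genome_id = "genome", iteration = 0L,
                           min_concordant = 2, dispute_frac = 0.25) {
  cnt <- columns$counts
  pcr <- columns$pcr_counts
  L <- ncol(cnt)
  tot_base <- cnt + pcr
  depth_unique <- colSums(cnt)
  depth_pcr <- colSums(pcr)
  total <- depth_unique + depth_pcr
  calls <- rep("N", L)
  flags <- matrix(FALSE, L, 5,
                  dimnames = list(NULL, c("no_coverage", "single_coverage",
                                          "disputed", "damage_explained",
                                          "pcr_confirmed")))
  bases <- rownames(cnt)
  mx <- apply(tot_base, 2, max)
  n_at_max <- colSums(tot_base == rep(mx, each = 5) & tot_base > 0)
  maj_idx <- apply(tot_base, 2, which.max)

  flags[total == 0, "no_coverage"] <- TRUE
  flags[total == 1, "single_coverage"] <- TRUE

  for (j in which(total >= 2)) {
    if (n_at_max[j] > 1L) { flags[j, "disputed"] <- TRUE; next }  # tie
    maj <- bases[maj_idx[j]]
    if (mx[j] < min_concordant) { flags[j, "disputed"] <- TRUE; next }
    disagree <- total[j] - mx[j]
    if (pcr[maj, j] > 0) flags[j, "pcr_confirmed"] <- TRUE
    if (disagree / total[j] > dispute_frac) {
      flags[j, "disputed"] <- TRUE
      dmg <- FALSE
      read_disagree <- depth_unique[j] - cnt[maj, j]
      pcr_disagree <- depth_pcr[j] - pcr[maj, j]
      if (pcr_disagree == 0 && read_disagree > 0) {
        if (maj == "G" && cnt["A", j] == read_disagree &&
            columns$dmgA[j] == cnt["A", j]) dmg <- TRUE
        if (maj == "C" && cnt["T", j] == read_disagree &&
            columns$dmgT[j] == cnt["T", j]) dmg <- TRUE
      }
      if (dmg) {
        flags[j, "damage_explained"] <- TRUE
        calls[j] <- maj
      } else if (pcr[maj, j] > 0) {
        calls[j] <- maj
      } # else stays N
    } else {
      calls[j] <- maj
    }
  }
  nocov <- which(flags[, "no_coverage"])
  gap_report <- intervals_from_positions(nocov - 1L)
  state <- list(genome_id = genome_id, iteration = as.integer(iteration),
                calls = calls,
                sequence = paste(calls[calls != "-"], collapse = ""),
                flags = flags, depth_unique = depth_unique,
                depth_pcr = depth_pcr, gap_report = gap_report,
                singleton_report = which(flags[, "single_coverage"]) - 1L)
  class(state) <- "ConsensusState"
  state
}

# maximal runs of sorted 0-based positions -> data.frame(start, end) half-open
intervals_from_positions <- function(pos) {
  if (length(pos) == 0L)
    return(data.frame(start = integer(), end = integer()))
  pos <- sort(unique(as.integer(pos)))
  brk <- c(0L, which(diff(pos) > 1L), length(pos))
  data.frame(start = pos[brk[-length(brk)] + 1L],
             end = pos[brk[-1L]] + 1L)
}

#' @export
print.ConsensusState <- function(x, ...) {
  cat(sprintf("<ConsensusState %s iter %d: %d columns, %d called, %d N, %d gap run(s), %d singleton(s)>\n",
              x$genome_id, x$iteration, length(x$calls),
              sum(x$calls %in% c("A", "C", "G", "T")),
              sum(x$calls == "N"), nrow(x$gap_report),
              length(x$singleton_report)))
  invisible(x)
}

#' Propose PCR amplicon targets covering gaps and singletons
#'
#' Returns intervals covering every `no_coverage` and `single_coverage`
#' position, split so that no amplicon exceeds `max_len` once padded by the
#' primer margin.
#'
#' @param state a `ConsensusState`.
#' @param margin primer padding per side (default 25).
#' @param max_len amplicon length cap (default 150).
#' @return `data.frame` with `start`, `end` (0-based half-open, clamped to the
#'   sequence).
#' @export
propose_pcr_targets <- function(state, margin = 25, max_len = 150) {
  L <- length(state$calls)
  flagged <- sort(unique(c(which(state$flags[, "no_coverage"]),
                           which(state$flags[, "single_coverage"])))) - 1L
  runs <- intervals_from_positions(flagged)
  if (nrow(runs) == 0L) return(runs)
  core <- max(1L, max_len - 2L * margin)
  out <- list()
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]; e <- runs$end[i]
    starts <- seq(s, e - 1L, by = core)
    for (cs in starts) {
      ce <- min(cs + core, e)
      out[[length(out) + 1L]] <- c(max(0L, cs - margin), min(L, ce + margin))
    }
  }
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

# Per-round read retention for the co-assembly: align the pool simultaneously
# to the current consensuses AND the external references, then per target
# genome keep reads that (a) place on the target consensus within maxdiff,
# (b) have no accepted placement on a competitor REFERENCE genome (the
# exclusivity screen is anchored to the fixed references, so the retained
# read set cannot oscillate with the evolving consensuses), and (c) pass the
# three-tier mapping-quality gate, whose rival placements are the competitor
# reference placements plus any second placement on the target itself (an
# uncalled N charged as a mismatch there).  A read's own placement aligns
# through N freely, anchored by its called overlap, so gap-edge evidence is
# kept.
coassembly_gate <- function(reads, cons, refs, params, mq_min = 25,
                            strict = FALSE, consensus_veto = FALSE) {
  ids <- names(cons)
  ng <- length(ids)
  panel <- c(cons, setNames(refs, paste0(ids, "__ref")))
  hits <- align_raw(reads, panel, params, n_free = TRUE)
  empty <- data.frame(read_id = character(), genome_id = character(),
                      start = integer(), strand = character(),
                      edit = integer(), n_wild = integer(), cigar = character(),
                      oriented = character(), mapq = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(setNames(rep(list(empty), ng), ids))
  eff <- hits$edit + hits$n_wild
  keep_rows <- vector("list", ng)
  keep_mapq <- vector("list", ng)
  for (i in seq_len(ng)) keep_rows[[i]] <- integer(0)
  grp <- split(seq_len(nrow(hits)), hits$read)
  for (g in grp) {
    gen <- hits$genome[g]
    for (i in seq_len(ng)) {
      own_all <- g[gen == i]
      if (!length(own_all)) next
      # competitor reference placements are emitted only within maxdiff
      if (any(gen > ng & gen != ng + i)) next
      if (consensus_veto) {
        # final screen: a placement on a competitor consensus within maxdiff
        # (N charged as mismatch) also vetoes
        comp <- g[gen <= ng & gen != i]
        if (length(comp)) {
          kk <- maxdiff(nchar(reads$bases)[hits$read[comp]], params$err,
                        params$miss_thres)
          if (any(eff[comp] <= kk)) next
        }
      }
      o <- own_all[order(hits$edit[own_all], hits$strand[own_all] == -1,
                         hits$start[own_all])][1]
      rivals <- eff[setdiff(own_all, o)]
      own_edit <- hits$edit[o]
      mq <- if (any(rivals <= own_edit)) 0L
            else if (any(rivals == own_edit + 1L)) 20L else 37L
      if (if (strict) mq > mq_min else mq >= mq_min) {
        keep_rows[[i]] <- c(keep_rows[[i]], o)
        keep_mapq[[i]] <- c(keep_mapq[[i]], mq)
      }
    }
  }
  out <- vector("list", ng)
  for (i in seq_len(ng)) {
    rows <- keep_rows[[i]]
    if (!length(rows)) { out[[i]] <- empty; next }
    out[[i]] <- data.frame(
      read_id = reads$id[hits$read[rows]], genome_id = ids[i],
      start = hits$start[rows],
      strand = ifelse(hits$strand[rows] == 1, "+", "-"),
      edit = hits$edit[rows], n_wild = hits$n_wild[rows],
      cigar = hits$cigar[rows],
      oriented = ifelse(hits$strand[rows] == 1, reads$bases[hits$read[rows]],
                        revcomp(reads$bases[hits$read[rows]])),
      mapq = keep_mapq[[i]], stringsAsFactors = FALSE)
  }
  setNames(out, ids)
}

#' Simultaneous iterative co-assembly of several mitogenomes
#'
#' Round 0 aligns the full read pool simultaneously to the external reference
#' genomes; each later round realigns the full pool to the current provisional
#' consensuses (keeping the external references in the panel for the
#' exclusivity screen), applies the exclusive-mapping and mapping-quality
#' gates in both directions, collapses duplicate placements, and recalls the
#' majority consensus. Uncalled (N) consensus positions carry no evidence: a
#' competitor placement leaning on them is charged a mismatch per N, while a
#' read's own placement aligns through them freely, anchored by its called
#' overlap. PCR consensus fragments, when supplied, are aligned to their
#' genome's current consensus and counted once each as concordant evidence
#' (no mapping-quality gate). Iteration stops when every consensus is
#' unchanged between rounds, or at `max_iterations` with a warning flag in
#' the log.
#'
#' @param reads `data.frame` with id, bases.
#' @param refs list of two or more [reference_genome()] (the canonical case is a
#'   prey and a predator reference).
#' @param params an [aligner_params()].
#' @param pcr_fragments optional named list (by genome id) of PCR fragment
#'   `data.frame`s as from [simulate_pcr_fragments()].
#' @param pcr_from_iteration iteration index at which PCR evidence enters.
#' @param max_iterations iteration cap (default 5).
#' @param mq_min,strict mapping-quality gate.
#' @param min_concordant,dispute_frac,damage_window consensus-calling
#'   thresholds, see [call_consensus()].
#' @return list with `states` (final `ConsensusState` per genome), `log`
#'   (`data.frame`: iteration, genome_id, n_changed, n_gap_positions,
#'   n_singletons), `converged`, `n_iterations`.
#' @export
iterate_coassembly <- function(reads, refs, params = aligner_params(),
                               pcr_fragments = NULL, pcr_from_iteration = 1L,
                               max_iterations = 5, mq_min = 25, strict = FALSE,
                               min_concordant = 2, dispute_frac = 0.25,
                               damage_window = 10) {
  stopifnot(length(refs) >= 2)
  ids <- vapply(refs, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("reference genomes must be distinct")
  circ <- vapply(refs, `[[`, TRUE, "circular")
  current <- vapply(refs, `[[`, "", "sequence")
  log <- list()
  states <- NULL
  converged <- FALSE
  iter_done <- 0L
  for (it in 0:(max_iterations - 1L)) {
    panel <- lapply(seq_along(ids), function(i)
      reference_genome(ids[i], current[i], circular = circ[i]))
    names(panel) <- ids
    gated <- coassembly_gate(reads, panel, refs, params,
                             mq_min = mq_min, strict = strict)
    new_states <- vector("list", length(ids))
    names(new_states) <- ids
    for (i in seq_along(ids)) {
      dd <- dedup_unique(gated[[ids[i]]])
      pcr_aln <- NULL
      if (!is.null(pcr_fragments) && it >= pcr_from_iteration &&
          !is.null(pcr_fragments[[ids[i]]])) {
        frag <- pcr_fragments[[ids[i]]]
        pcr_aln <- align_reads(
          data.frame(id = frag$id, bases = frag$sequence,
                     stringsAsFactors = FALSE),
          panel[i], params, n_wildcard_free = TRUE)
      }
      cols <- build_columns(dd$alignments, nchar(current[i]),
                            circular = circ[i], pcr = pcr_aln,
                            damage_window = damage_window)
      st <- call_consensus(cols, genome_id = ids[i], iteration = it,
                           min_concordant = min_concordant,
                           dispute_frac = dispute_frac)
      st$n_unique_reads <- nrow(dd$alignments)
      st$n_collapsed_duplicates <- dd$n_collapsed
      new_states[[i]] <- st
    }
    new_seq <- vapply(new_states, `[[`, "", "sequence")
    n_changed <- vapply(seq_along(ids), function(i) {
      if (nchar(new_seq[i]) != nchar(current[i])) return(NA_integer_)
      hamming(new_seq[i], current[i])
    }, 0L)
    for (i in seq_along(ids)) {
      log[[length(log) + 1L]] <- data.frame(
        iteration = it, genome_id = ids[i], n_changed = n_changed[i],
        n_gap_positions = sum(new_states[[i]]$flags[, "no_coverage"]),
        n_singletons = length(new_states[[i]]$singleton_report),
        n_unique_reads = new_states[[i]]$n_unique_reads)
    }
    states <- new_states
    iter_done <- it + 1L
    # converged when consensuses are unchanged between successive rounds
    # (round 0 compares against the external references, so never converges)
    if (it > 0L && all(!is.na(n_changed)) && all(n_changed == 0L)) {
      converged <- TRUE
      current <- new_seq
      break
    }
    current <- new_seq
  }
  # final screening pass over the frozen consensuses: competitor-consensus
  # placements now veto too, so no retained read can match the other
  # genome's called sequence within maxdiff (one-shot, post-convergence)
  panel <- lapply(seq_along(ids), function(i)
    reference_genome(ids[i], current[i], circular = circ[i]))
  names(panel) <- ids
  gated <- coassembly_gate(reads, panel, refs, params, mq_min = mq_min,
                           strict = strict, consensus_veto = TRUE)
  for (i in seq_along(ids)) {
    dd <- dedup_unique(gated[[ids[i]]])
    pcr_aln <- NULL
    if (!is.null(pcr_fragments) && !is.null(pcr_fragments[[ids[i]]])) {
      frag <- pcr_fragments[[ids[i]]]
      pcr_aln <- align_reads(
        data.frame(id = frag$id, bases = frag$sequence,
                   stringsAsFactors = FALSE),
        panel[i], params, n_wildcard_free = TRUE)
    }
    cols <- build_columns(dd$alignments, nchar(current[i]),
                          circular = circ[i], pcr = pcr_aln,
                          damage_window = damage_window)
    st <- call_consensus(cols, genome_id = ids[i], iteration = iter_done,
                         min_concordant = min_concordant,
                         dispute_frac = dispute_frac)
    st$n_unique_reads <- nrow(dd$alignments)
    st$n_collapsed_duplicates <- dd$n_collapsed
    states[[ids[i]]] <- st
    log[[length(log) + 1L]] <- data.frame(
      iteration = iter_done, genome_id = ids[i],
      n_changed = NA_integer_,
      n_gap_positions = sum(st$flags[, "no_coverage"]),
      n_singletons = length(st$singleton_report),
      n_unique_reads = st$n_unique_reads)
  }
  log <- do.call(rbind, log)
  log$stage <- c(rep("iterate", nrow(log) - length(ids)),
                 rep("final_screen", length(ids)))
  if (!converged) {
    warning("co-assembly did not converge within ", max_iterations,
            " iterations")
    log$warning <- "not_converged"
  } else log$warning <- ""
  list(states = states, log = log, converged = converged,
       n_iterations = iter_done)
}
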