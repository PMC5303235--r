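# shared fixtures and independent oracles, all generated in code

# per-site mutated copy of a sequence (for database-reference emulation)
mutate_seq <- function(seq, rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  if (length(hit))
    v[hit] <- vapply(v[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  paste(v, collapse = "")
}

# the study-condition fixture: two 16-kb truth mitogenomes at 5% star
# divergence, database references 2% off the truths, and a damaged read pool
# at ~30x per genome
make_study <- function(seed, length = 16000, coverage = 30,
                       delta3 = 0.1, err = 0.001) {
  truths <- generate_panel(seed, 2, length, 0.05)
  refs <- lapply(truths, function(g)
    reference_genome(g$id, mutate_seq(g$sequence, 0.02, seed + 1000L),
                     circular = g$circular, features = g$features))
  total <- round(2 * length * coverage / 51)
  pool <- simulate_reads(truths, c(0.5, 0.5), total,
                         damage = damage_model(delta3 = delta3, decay = 0.5,
                                               err = err),
                         seed = seed + 2000L)
  list(truths = truths, refs = refs, pool = pool)
}

# full-Levenshtein substring distance (free genome start/end, unrestricted
# gaps), computed by an independent vectorised row DP with the running-min
# trick for horizontal gaps
lev_substring <- function(read, genome) {
  rv <- strsplit(read, "")[[1]]
  gv <- strsplit(genome, "")[[1]]
  n <- length(gv)
  prev <- rep(0L, n + 1L)
  for (i in seq_along(rv)) {
    sub <- prev[1:n] + (gv != rv[i])
    up <- prev[2:(n + 1)] + 1L
    tmp <- c(i, pmin(sub, up))
    cur <- cummin(tmp - seq_len(n + 1L)) + seq_len(n + 1L)
    prev <- cur
  }
  min(prev)
}

# read-strand source sequence of a simulated read, from the truth table
truth_source_seq <- function(pool, i, panel) {
  t1 <- pool$truth[i, ]
  r <- pool$reads$bases[i]
  g <- panel[[t1$source]]
  frag <- copromito:::substr_circular(g$sequence, t1$start, nchar(r),
                                      g$circular)
  if (t1$strand == "+") frag else revcomp(frag)
}

# mismatch count of a read against a genome window at its truth coordinates
truth_window_mismatches <- function(pool, i, genome) {
  t1 <- pool$truth[i, ]
  r <- pool$reads$bases[i]
  frag <- copromito:::substr_circular(genome$sequence, t1$start, nchar(r),
                                      genome$circular)
  src <- if (t1$strand == "+") frag else revcomp(frag)
  sum(strsplit(src, "")[[1]] != strsplit(r, "")[[1]])
}

# additive distance matrix by path sums over a fixed 4-taxon tree
# ((A:a, B:b):m, (C:c, D:d)) with internal edge m
additive4 <- function(a, b, c, d, m) {
  dm <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                        c("A", "B", "C", "D")))
  dm["A", "B"] <- dm["B", "A"] <- a + b
  dm["A", "C"] <- dm["C", "A"] <- a + m + c
  dm["A", "D"] <- dm["D", "A"] <- a + m + d
  dm["B", "C"] <- dm["C", "B"] <- b + m + c
  dm["B", "D"] <- dm["D", "B"] <- b + m + d
  dm["C", "D"] <- dm["D", "C"] <- c + d
  dm
}

# evolve aligned sequences down a given rooted tree by per-site substitution
simulate_tree_seqs <- function(tree, len, rate, seed) {
  set.seed(seed)
  root <- random_seq <- paste(sample(c("A", "C", "G", "T"), len,
                                     replace = TRUE), collapse = "")
  n_tip <- length(tree$tip.label)
  seqs <- character(n_tip + tree$Nnode)
  seqs[n_tip + 1L] <- root
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  for (r in seq_len(nrow(ord))) {
    parent <- ord[r, 1]; child <- ord[r, 2]
    seqs[child] <- mutate_seq(seqs[parent], rate)
  }
  out <- seqs[seq_len(n_tip)]
  names(out) <- tree$tip.label
  out
}
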