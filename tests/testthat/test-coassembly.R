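test_that("duplicate placements collapse to one; near-duplicates are kept", {
  base <- data.frame(read_id = c("r1", "r2", "r3"), genome_id = "g",
                     start = 100L, strand = "+",
                     oriented = c("ACGT", "ACGT", "ACGA"),
                     stringsAsFactors = FALSE)
  out <- dedup_unique(base)
  expect_identical(nrow(out$alignments), 2L)
  expect_identical(out$n_collapsed, 1L)
  # simulated duplicate rate 0.2 recovers the expected unique count
  p <- generate_panel(31, 1, 4000, 0)
  pool <- simulate_reads(p, 1, 2000, seed = 32, dup_rate = 0.2)
  aln <- align_reads(pool$reads, p)
  dd <- dedup_unique(aln)
  expn <- 2000 * 0.2
  expect_lt(abs(dd$n_collapsed - expn), 3 * sqrt(2000 * 0.2 * 0.8) + 30)
})

test_that("exclusivity keeps unique high-mapq target reads and drops cross-mappers", {
  aln <- data.frame(
    read_id = c("both", "both", "uniq", "ambig"),
    genome_id = c("A", "B", "A", "A"),
    mapq = c(37L, 37L, 37L, 0L),
    evidential = TRUE, stringsAsFactors = FALSE)
  out <- exclusivity_filter(aln, "A", "B")
  expect_identical(out$read_id, "uniq")
})

test_that("consensus calling follows the 2-concordant / 25%-dispute / damage rules", {
  L <- 6L
  counts <- matrix(0L, 5, L, dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  pcr <- counts
  dmgA <- integer(L); dmgT <- integer(L)
  counts["G", 1] <- 5L                      # clean call
  counts["G", 2] <- 1L                      # singleton -> N
  counts["G", 3] <- 6L; counts["A", 3] <- 3L; dmgA[3] <- 3L  # damage dispute
  counts["C", 4] <- 2L; counts["T", 4] <- 2L                  # tie -> N
  counts["G", 5] <- 6L; counts["A", 5] <- 3L; dmgA[5] <- 1L   # unexplained
  # col 6: no coverage
  st <- call_consensus(list(counts = counts, pcr_counts = pcr,
                            dmgA = dmgA, dmgT = dmgT))
  expect_identical(st$calls, c("G", "N", "G", "N", "N", "N"))
  expect_true(st$flags[2, "single_coverage"])
  expect_true(st$flags[3, "disputed"] && st$flags[3, "damage_explained"])
  expect_true(st$flags[4, "disputed"])
  expect_true(st$flags[5, "disputed"] && !st$flags[5, "damage_explained"])
  expect_true(st$flags[6, "no_coverage"])
  expect_identical(st$gap_report, data.frame(start = 5L, end = 6L))
})

test_that("PCR evidence rescues unexplained disputes and counts toward concordance", {
  L <- 3L
  counts <- matrix(0L, 5, L, dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  pcr <- counts
  counts["G", 1] <- 6L; counts["A", 1] <- 3L; pcr["G", 1] <- 1L  # pcr concurs
  counts["T", 2] <- 1L; pcr["T", 2] <- 1L                        # 1 read + 1 pcr
  pcr["C", 3] <- 2L                                              # pcr only
  st <- call_consensus(list(counts = counts, pcr_counts = pcr,
                            dmgA = integer(L), dmgT = integer(L)))
  expect_identical(st$calls, c("G", "T", "C"))
  expect_true(st$flags[1, "pcr_confirmed"])
})

test_that("reverse-strand terminal damage (T vs consensus C) is damage-explained", {
  L <- 1L
  counts <- matrix(0L, 5, L, dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  counts["C", 1] <- 5L; counts["T", 1] <- 3L
  st <- call_consensus(list(counts = counts, pcr_counts = counts * 0L,
                            dmgA = integer(L), dmgT = 3L))
  expect_identical(st$calls, "C")
  expect_true(st$flags[1, "damage_explained"])
})

test_that("PCR target proposal covers all gap and singleton positions", {
  L <- 2000L
  counts <- matrix(2L, 5, L, dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  counts[] <- 0L
  counts["G", ] <- 3L
  gap_pos <- c(11:13, 501)
  single_pos <- c(900:905)
  counts["G", gap_pos + 1L] <- 0L
  counts["G", single_pos + 1L] <- 1L
  st <- call_consensus(list(counts = counts, pcr_counts = counts * 0L,
                            dmgA = integer(L), dmgT = integer(L)))
  tg <- propose_pcr_targets(st)
  flagged <- c(gap_pos, single_pos)
  covered <- unlist(Map(seq, tg$start, tg$end - 1L))
  expect_true(all(flagged %in% covered))
  expect_true(all(tg$end - tg$start <= 150))
  # fully called state proposes nothing
  fc <- matrix(0L, 5, 4, dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  fc["A", ] <- 3L
  full <- call_consensus(list(counts = fc, pcr_counts = fc * 0L,
                              dmgA = integer(4), dmgT = integer(4)))
  expect_identical(nrow(propose_pcr_targets(full)), 0L)
})

test_that("a fixture with 169 gap and 144 singleton positions is fully covered", {
  L <- 16000L
  counts <- matrix(0L, 5, L, dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  counts["A", ] <- 4L
  set.seed(33)
  # 43 gap runs totalling 169 positions, plus 144 scattered singletons
  gap_pos <- as.vector(outer(0:3, seq(200L, by = 120L, length.out = 43L),
                             "+"))[1:169]
  rest <- setdiff(seq_len(L) - 1L, c(gap_pos, gap_pos + 1L, gap_pos - 1L))
  single_pos <- sample(rest, 144)
  counts["A", gap_pos + 1L] <- 0L
  counts["A", single_pos + 1L] <- 1L
  st <- call_consensus(list(counts = counts, pcr_counts = counts * 0L,
                            dmgA = integer(L), dmgT = integer(L)))
  expect_identical(sum(st$flags[, "no_coverage"]), 169L)
  expect_identical(sum(st$flags[, "single_coverage"]), 144L)
  tg <- propose_pcr_targets(st)
  covered <- unlist(Map(seq, tg$start, tg$end - 1L))
  expect_true(all(c(gap_pos, single_pos) %in% covered))
})

test_that("co-assembly of an absent taxon yields an almost entirely uncalled consensus", {
  set.seed(34)
  p <- generate_panel(34, 1, 4000, 0)
  pool <- simulate_reads(p, 1, 2400, seed = 35)
  unrelated <- reference_genome("x", random_dna(4000))
  co <- suppressWarnings(iterate_coassembly(pool$reads, list(p[[1]], unrelated),
                                            max_iterations = 3))
  frac_called_x <- mean(co$states$x$calls %in% c("A", "C", "G", "T"))
  expect_lt(frac_called_x, 0.02)
  frac_called_g <- mean(co$states$g01$calls %in% c("A", "C", "G", "T"))
  expect_gt(frac_called_g, 0.9)
})

test_that("co-assembly is deterministic across reruns", {
  st <- make_study(301, length = 4000, coverage = 20)
  a <- suppressWarnings(iterate_coassembly(st$pool$reads, st$refs,
                                           max_iterations = 3))
  b <- suppressWarnings(iterate_coassembly(st$pool$reads, st$refs,
                                           max_iterations = 3))
  expect_identical(vapply(a$states, `[[`, "", "sequence"),
                   vapply(b$states, `[[`, "", "sequence"))
})

test_that("supplying PCR fragments over gaps is monotone and completes covered spans", {
  st <- make_study(302, length = 6000, coverage = 25)
  co <- iterate_coassembly(st$pool$reads, st$refs)
  s1 <- co$states[[1]]
  tg <- propose_pcr_targets(s1)
  skip_if(nrow(tg) == 0)
  # two staggered replicate amplicon sets, as in replicated PCR experiments
  frags <- rbind(simulate_pcr_fragments(st$truths[[1]], tg),
                 simulate_pcr_fragments(st$truths[[1]],
                                        data.frame(start = pmax(tg$start - 7, 0),
                                                   end = pmin(tg$end + 7, 6000))))
  co2 <- iterate_coassembly(st$pool$reads, st$refs,
                            pcr_fragments = setNames(list(frags),
                                                     names(st$truths)[1]))
  s2 <- co2$states[[1]]
  expect_lte(sum(s2$calls == "N"), sum(s1$calls == "N"))
  covered <- unlist(Map(seq, tg$start, tg$end - 1L))
  expect_identical(sum(s2$flags[covered + 1L, "no_coverage"]), 0L)
  # PCR evidence is error-free here, so newly called bases are true
  tv <- strsplit(st$truths[[1]]$sequence, "")[[1]]
  called <- s2$calls %in% c("A", "C", "G", "T")
  expect_gt(mean(s2$calls[called] == tv[called]), 0.999)
})

test_that("no retained read in one pileup matches the competitor consensus perfectly", {
  st <- make_study(303, length = 4000, coverage = 20)
  co <- iterate_coassembly(st$pool$reads, st$refs)
  consB <- reference_genome("bcons", co$states[[2]]$sequence)
  # reconstruct A's final kept set through the gate itself
  gated <- copromito:::coassembly_gate(
    st$pool$reads,
    lapply(co$states, function(s) reference_genome(s$genome_id, s$sequence)),
    st$refs, aligner_params(), consensus_veto = TRUE)
  keptA <- gated[[1]]
  skip_if(nrow(keptA) == 0)
  sub <- data.frame(id = keptA$read_id,
                    bases = st$pool$reads$bases[match(keptA$read_id,
                                                      st$pool$reads$id)],
                    stringsAsFactors = FALSE)
  alnB <- align_reads(sub, list(consB))
  expect_identical(sum(alnB$edit == 0L & alnB$n_wild == 0L), 0L)
})
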