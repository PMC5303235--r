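test_that("maxdiff reproduces the published length-to-mismatch table", {
  expect_true(all(maxdiff(20:26) == 1L))
  expect_true(all(maxdiff(88:101) == 4L))
  expect_identical(maxdiff(87), 3L)
  expect_identical(maxdiff(27), 2L)
  # brute-force Poisson tail oracle over the full length range
  oracle <- function(l, err = 0.02, thr = 0.1) {
    lambda <- err * l
    k <- 0L
    while (ppois(k, lambda, lower.tail = FALSE) >= thr) k <- k + 1L
    k
  }
  ls <- 20:101
  expect_identical(maxdiff(ls), vapply(ls, oracle, 0L))
  # monotone in length; zero under a zero error rate
  expect_true(all(diff(maxdiff(20:150)) >= 0))
  expect_true(all(maxdiff(c(20, 101), err = 1e-12) == 0L))
})

test_that("an exact unique substring aligns at edit 0 with mapq 37", {
  set.seed(1)
  g <- reference_genome("g", random_dna(3000), circular = FALSE)
  read <- substr(g$sequence, 501, 550)
  aln <- align_read(read, list(g))
  expect_identical(nrow(aln), 1L)
  expect_identical(aln$start, 500L)
  expect_identical(aln$edit, 0L)
  expect_identical(aln$mapq, 37L)
  expect_identical(aln$cigar, "50M")
})

test_that("strand symmetry: the reverse complement maps to the same interval", {
  set.seed(2)
  g <- reference_genome("g", random_dna(3000))
  read <- substr(g$sequence, 1001, 1048)
  a <- align_read(read, list(g))
  b <- align_read(revcomp(read), list(g))
  expect_identical(a$start, b$start)
  expect_identical(a$edit, b$edit)
  expect_setequal(c(a$strand, b$strand), c("-", "+"))
})

test_that("origin-spanning reads on a circular genome get wrapped coordinates", {
  set.seed(3)
  g <- reference_genome("g", random_dna(2000), circular = TRUE)
  L <- 2000L
  read <- paste0(substr(g$sequence, L - 19, L), substr(g$sequence, 1, 20))
  aln <- align_read(read, list(g))
  expect_identical(nrow(aln), 1L)
  expect_identical(aln$start, L - 20L)
  expect_identical(aln$edit, 0L)
  # and only once: never double-reported for the wrap
  expect_identical(sum(aln$genome_id == "g"), 1L)
})

test_that("a region shared verbatim by two genomes yields co-optimal mapq-0 placements", {
  set.seed(4)
  shared <- random_dna(200)
  a <- reference_genome("a", paste0(random_dna(900), shared, random_dna(900)))
  b <- reference_genome("b", paste0(random_dna(900), shared, random_dna(900)))
  read <- substr(shared, 50, 99)
  aln <- align_read(read, list(a, b))
  expect_identical(sort(aln$genome_id), c("a", "b"))
  expect_true(all(aln$edit == 0L))
  expect_true(all(aln$mapq == 0L))
  expect_true(all(aln$co_optimal >= 2L))
})

test_that("mapq is 20 when a second-best placement exists one edit worse", {
  set.seed(5)
  seq_a <- random_dna(1500)
  seq_b <- seq_a
  substr(seq_b, 720, 720) <- if (substr(seq_a, 720, 720) == "A") "C" else "A"
  a <- reference_genome("a", seq_a)
  b <- reference_genome("b", seq_b)
  read <- substr(seq_a, 701, 748)
  aln <- align_read(read, list(a, b))
  expect_identical(aln$mapq[aln$genome_id == "a"], 20L)
  expect_identical(aln$mapq[aln$genome_id == "b"], 0L)
})

test_that("gap openings are capped and counted", {
  set.seed(6)
  g <- reference_genome("g", random_dna(2000), circular = FALSE)
  base <- substr(g$sequence, 301, 360)
  # delete one interior base of the read -> one 1-nt reference deletion
  read <- paste0(substr(base, 1, 30), substr(base, 32, 60))
  aln <- align_read(read, list(g))
  expect_identical(aln$edit, 1L)
  expect_identical(aln$gap_opens, 1L)
  expect_match(aln$cigar, "D")
  # with gaps disabled the same read needs mismatches instead
  aln0 <- align_read(read, list(g), aligner_params(max_gap_opens = 0))
  expect_true(nrow(aln0) == 0L || aln0$gap_opens == 0L)
})

test_that("best edit distance matches an exhaustive substring-distance oracle on 200 reads", {
  set.seed(7)
  g <- generate_panel(42, 1, 2000, 0)[[1]]
  pool <- simulate_reads(list(g), 1, 200,
                         fraglen = list(meanlog = log(35), sdlog = 0.3),
                         damage = damage_model(err = 0.03), seed = 43)
  aln <- align_reads(pool$reads, list(g))
  gext <- paste0(g$sequence, substr(g$sequence, 1, 101))
  for (i in seq_len(200)) {
    r <- pool$reads$bases[i]
    k <- maxdiff(nchar(r))
    o <- min(lev_substring(r, gext), lev_substring(revcomp(r), gext))
    a <- aln$edit[aln$read_id == pool$reads$id[i]]
    a <- if (length(a)) min(a) else Inf
    expect_identical(as.numeric(if (o > k) Inf else o), as.numeric(a))
  }
})

test_that("best edit distance agrees with Biostrings global-local alignment on a subset", {
  set.seed(8)
  g <- generate_panel(44, 1, 1500, 0)[[1]]
  pool <- simulate_reads(list(g), 1, 40,
                         fraglen = list(meanlog = log(40), sdlog = 0.25),
                         damage = damage_model(err = 0.04), seed = 45)
  # the library oracle allows unrestricted gap openings, so the aligner runs
  # at its maximum cap here to compare like with like
  aln <- align_reads(pool$reads, list(g), aligner_params(max_gap_opens = 2))
  gext <- Biostrings::DNAString(paste0(g$sequence, substr(g$sequence, 1, 101)))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1)
  for (i in seq_len(40)) {
    r <- pool$reads$bases[i]
    k <- maxdiff(nchar(r))
    sc <- max(
      Biostrings::score(Biostrings::pairwiseAlignment(
        r, gext, type = "global-local", substitutionMatrix = mat,
        gapOpening = 0, gapExtension = 1)),
      Biostrings::score(Biostrings::pairwiseAlignment(
        revcomp(r), gext, type = "global-local", substitutionMatrix = mat,
        gapOpening = 0, gapExtension = 1)))
    o <- -sc
    a <- aln$edit[aln$read_id == pool$reads$id[i]]
    a <- if (length(a)) min(a) else Inf
    expect_identical(as.numeric(if (o > k) Inf else o), as.numeric(a))
  }
})

test_that("reads shorter than the seed are unaligned, not an error", {
  g <- generate_panel(9, 1, 2000, 0)
  aln <- align_read("ACGTACGTAC", g)  # 10 nt < seed 12
  expect_identical(nrow(aln), 0L)
})
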