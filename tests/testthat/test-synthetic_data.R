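test_that("panel generation honours divergence: zero gives clones, 5% gives ~800/16kb", {
  p0 <- generate_panel(1, 2, 16000, 0)
  expect_identical(p0[[1]]$sequence, p0[[2]]$sequence)

  p <- generate_panel(1, 2, 16000, 0.05)
  d <- hamming(p[[1]]$sequence, p[[2]]$sequence)
  # Binomial(16000, 0.05): mean 800, sd 27.6; CDS replanting perturbs a little
  expect_gt(d, 800 - 3 * 27.6 - 20)
  expect_lt(d, 800 + 3 * 27.6 + 20)
})

test_that("a 49-genome panel is pairwise distinct and deterministic in the seed", {
  p <- generate_panel(1, 49, 16000, 0.08)
  expect_length(p, 49)
  seqs <- vapply(p, `[[`, "", "sequence")
  expect_false(anyDuplicated(seqs) > 0)
  p2 <- generate_panel(1, 49, 16000, 0.08)
  expect_identical(seqs, vapply(p2, `[[`, "", "sequence"))
})

test_that("every generated genome carries a CDS that validates under the mito code", {
  p <- generate_panel(3, 5, 4000, 0.1)
  for (g in p) {
    cds <- g$features[g$features$kind == "CDS", ][1, ]
    seq <- substr(g$sequence, cds$start + 1, cds$end)
    v <- validate_cds(seq)
    expect_true(v$start_ok && v$stop_ok && v$no_internal_stop &&
                  v$length_multiple_of_3)
  }
})

test_that("generator rejects invalid parameters", {
  expect_error(generate_panel(1, 2, 500, 0.05), "length")
  expect_error(generate_panel(1, 2, 16000, 0.5), "divergence")
  expect_error(simulate_reads(list(), 1, 10), "panel")
  expect_error(simulate_reads(generate_panel(1, 1, 2000, 0), c(-1), 10),
               "proportions")
  expect_error(damage_model(decay = 1.5), "decay")
})

test_that("noise-free reads are exact (possibly reverse-complemented, wrapped) substrings", {
  p <- generate_panel(2, 2, 3000, 0.05)
  pool <- simulate_reads(p, c(0.5, 0.5), 300, seed = 3)
  for (i in seq_len(300)) {
    src <- truth_source_seq(pool, i, p)
    expect_identical(pool$reads$bases[i], src)
  }
  expect_true(all(pool$truth$n_damage == 0L))
  expect_true(all(pool$truth$n_error == 0L))
})

test_that("read pools are deterministic, conserve counts, and match proportions", {
  p <- generate_panel(4, 3, 3000, 0.05)
  a <- simulate_reads(p, c(0.6, 0.3, 0.1), 2000, seed = 5)
  b <- simulate_reads(p, c(0.6, 0.3, 0.1), 2000, seed = 5)
  expect_identical(a, b)
  expect_identical(nrow(a$reads), 2000L)
  expect_identical(sort(a$reads$id), sort(a$truth$read_id))
  tab <- table(a$truth$source)
  for (i in 1:3) {
    expn <- 2000 * c(0.6, 0.3, 0.1)[i]
    sd3 <- 3 * sqrt(expn * (1 - c(0.6, 0.3, 0.1)[i]))
    expect_lt(abs(tab[[names(p)[i]]] - expn), sd3)
  }
  # truth length invariant: end - start (mod L) equals read length
  L <- nchar(p[[1]]$sequence)
  lens <- (a$truth$end - a$truth$start) %% L
  expect_identical(as.integer(lens), nchar(a$reads$bases))
})

test_that("fragment lengths are lognormal with median ~48 in [20, 101]", {
  p <- generate_panel(6, 1, 4000, 0)
  pool <- simulate_reads(p, 1, 10000, seed = 7)
  lens <- nchar(pool$reads$bases)
  expect_true(all(lens >= 20 & lens <= 101))
  expect_gte(median(lens), 46)
  expect_lte(median(lens), 50)
})

test_that("terminal damage rates follow delta3 * decay^d within sampling error", {
  p <- generate_panel(8, 1, 8000, 0)
  pool <- simulate_reads(list(p[[1]]), 1, 50000,
                         damage = damage_model(delta3 = 0.3, decay = 0.5),
                         seed = 9)
  g <- p[[1]]$sequence
  count_rate <- function(dist3) {
    nG <- 0L; nGA <- 0L
    for (i in seq_len(5000)) {  # subsample for speed; still thousands of G's
      src <- truth_source_seq(pool, i, p)
      l <- nchar(src)
      pos <- l - dist3
      if (pos < 1) next
      if (substr(src, pos, pos) == "G") {
        nG <- nG + 1L
        if (substr(pool$reads$bases[i], pos, pos) == "A") nGA <- nGA + 1L
      }
    }
    c(nGA, nG)
  }
  r0 <- count_rate(0)
  expect_lt(abs(r0[1] / r0[2] - 0.3), 3 * sqrt(0.3 * 0.7 / r0[2]))
  r3 <- count_rate(3)
  expect_lt(abs(r3[1] / r3[2] - 0.0375), 3 * sqrt(0.0375 * 0.9625 / r3[2]))
})

test_that("duplicate simulation yields the expected unique-read count", {
  p <- generate_panel(10, 1, 4000, 0)
  pool <- simulate_reads(p, 1, 3000, seed = 11, dup_rate = 0.2)
  n_unique <- length(unique(paste(pool$truth$start, pool$truth$end,
                                  pool$truth$strand, pool$reads$bases)))
  expn <- 1 + (3000 - 1) * 0.8
  expect_lt(abs(n_unique - expn), 3 * sqrt(3000 * 0.2 * 0.8) + 30)
})

test_that("PCR fragments are exact substrings, wrap the origin, and honour the 609-bp layout", {
  g <- generate_panel(12, 1, 4000, 0)[[1]]
  fr <- simulate_pcr_fragments(g, data.frame(start = 0, end = 100))
  expect_identical(fr$sequence, substr(g$sequence, 1, 100))
  L <- nchar(g$sequence)
  wrap <- simulate_pcr_fragments(g, data.frame(start = L - 10, end = 5))
  expect_identical(nchar(wrap$sequence), 15L)
  expect_identical(wrap$sequence,
                   paste0(substr(g$sequence, L - 9, L), substr(g$sequence, 1, 5)))
  expect_error(simulate_pcr_fragments(g, data.frame(start = -1, end = 10)),
               "interval")
  # 16 disjoint amplicons totalling 609 bp, the concatenated-fragment layout
  starts <- seq(0, by = 220, length.out = 16)
  lens <- c(rep(38, 15), 39)
  f16 <- simulate_pcr_fragments(g, data.frame(start = starts,
                                              end = starts + lens))
  expect_identical(nrow(f16), 16L)
  expect_identical(sum(nchar(f16$sequence)), 609L)
})
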