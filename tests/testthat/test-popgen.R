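make_site_alignments <- function(bases_by_read, start = 0L) {
  # helper: stack reads of equal length at the same locus
  data.frame(read_id = paste0("r", seq_along(bases_by_read)),
             genome_id = "chr", start = start, strand = "+",
             cigar = paste0(nchar(bases_by_read), "M"),
             oriented = bases_by_read, mapq = 37L, stringsAsFactors = FALSE)
}

test_that("pseudo-haploid calls follow majority, depth and third-allele rules", {
  panel <- data.frame(chrom = "chr", pos = c(2L, 5L), ref = c("A", "C"),
                      alt = c("G", "T"), stringsAsFactors = FALSE)
  aln3 <- make_site_alignments(c("TTGTTT", "TTGTTT", "TTGTTT"))
  expect_identical(genotype_sites(aln3, panel, L = 6)[1], "alt")
  # one read only -> missing under the depth >= 2 gate
  aln1 <- make_site_alignments("TTGTTT")
  expect_true(is.na(genotype_sites(aln1, panel, L = 6)[1]))
  # 1 ref vs 1 alt tie -> missing; 2 vs 1 majority -> called
  aln_tie <- make_site_alignments(c("TTATTT", "TTGTTT"))
  expect_true(is.na(genotype_sites(aln_tie, panel, L = 6)[1]))
  aln_maj <- make_site_alignments(c("TTATTT", "TTATTT", "TTGTTT"))
  expect_identical(genotype_sites(aln_maj, panel, L = 6)[1], "ref")
  # a third allele outvoting both panel alleles -> missing
  aln_third <- make_site_alignments(c("TTCTTT", "TTCTTT", "TTCTTT",
                                      "TTATTT", "TTATTT"))
  expect_true(is.na(genotype_sites(aln_third, panel, L = 6)[1]))
})

test_that("calls are invariant to read order and recover simulated truth at 4x", {
  set.seed(71)
  ref <- generate_panel(71, 1, 20000, 0)[[1]]
  ref$circular <- FALSE
  # carrier genome: alt allele at half of 500 panel sites
  sites <- sort(sample(100:19900, 500))
  refv <- strsplit(ref$sequence, "")[[1]]
  alt <- vapply(refv[sites + 1L], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  truth_geno <- sample(c("ref", "alt"), 500, replace = TRUE)
  carrier <- refv
  swap <- truth_geno == "alt"
  carrier[sites[swap] + 1L] <- alt[swap]
  carrier_g <- reference_genome("carrier", paste(carrier, collapse = ""),
                                circular = FALSE)
  pool <- simulate_reads(list(carrier_g), 1, round(20000 * 4 / 51),
                         damage = damage_model(err = 0.001), seed = 72)
  aln <- align_reads(pool$reads, list(ref))
  aln <- aln[aln$mapq >= 25, ]
  panel <- data.frame(chrom = "ref", pos = sites, ref = refv[sites + 1L],
                      alt = alt, stringsAsFactors = FALSE)
  calls <- genotype_sites(aln, panel, L = 20000)
  called <- !is.na(calls)
  expect_gt(mean(calls[called] == truth_geno[called]), 0.99)
  expect_gt(sum(called), 200)  # 4x coverage leaves most sites callable
  # read order invariance
  calls2 <- genotype_sites(aln[sample(nrow(aln)), ], panel, L = 20000)
  expect_identical(calls, calls2)
})

test_that("allele-sharing distance matches binomial expectation and errors on thin overlap", {
  set.seed(73)
  g1 <- sample(c("ref", "alt"), 1000, replace = TRUE)
  g2 <- ifelse(runif(1000) < 0.3,
               ifelse(g1 == "ref", "alt", "ref"), g1)
  m <- rbind(s1 = g1, s2 = g2)
  d <- pairwise_allele_distance(m)
  expect_identical(d["s1", "s1"], 0)
  expect_lt(abs(d["s1", "s2"] - 0.3), 3 * sqrt(0.3 * 0.7 / 1000))
  # complementary rows hit the maximum
  comp <- rbind(a = g1, b = ifelse(g1 == "ref", "alt", "ref"))
  expect_identical(pairwise_allele_distance(comp)["a", "b"], 1)
  thin <- rbind(x = c(g1[1:50], rep(NA, 950)), y = c(rep(NA, 950), g1[51:100]))
  expect_error(pairwise_allele_distance(thin), "insufficient overlap")
})

test_that("classical MDS reproduces line, square and random planar configurations", {
  # 3 collinear points
  d3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  f3 <- classical_mds(d3, 1)
  expect_lt(max(abs(as.matrix(dist(f3$points)) - d3)), 1e-9)
  # unit square up to rotation/reflection: compare distance matrices
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  Dsq <- as.matrix(dist(sq))
  fsq <- classical_mds(Dsq, 2)
  expect_lt(max(abs(as.matrix(dist(fsq$points)) - Dsq)), 1e-8)
  # Procrustes alignment onto the source configuration
  pr <- vegan::procrustes(sq, fsq$points, symmetric = FALSE)
  expect_lt(sqrt(mean(residuals(pr)^2)), 1e-8)
  # random 6-point planar configuration is Euclidean-realizable exactly
  set.seed(74)
  pts <- matrix(runif(12), 6, 2)
  D6 <- as.matrix(dist(pts))
  f6 <- classical_mds(D6, 2)
  expect_lt(max(abs(as.matrix(dist(f6$points)) - D6)), 1e-9)
  expect_true(all(diff(f6$eig) <= 1e-9))
  # k above the positive-eigenvalue count shrinks with a warning
  expect_warning(fk <- classical_mds(d3, 2), "positive eigenvalue")
  expect_identical(fk$k_used, 1L)
})

test_that("samples from two source genomes separate on MDS axis 1", {
  skip_if_not_installed("cluster")
  set.seed(75)
  nsites <- 400
  src1 <- sample(c("ref", "alt"), nsites, replace = TRUE)
  src2 <- ifelse(runif(nsites) < 0.4, ifelse(src1 == "ref", "alt", "ref"), src1)
  noisy <- function(g, miss = 0.3, err = 0.02) {
    out <- ifelse(runif(nsites) < err, ifelse(g == "ref", "alt", "ref"), g)
    out[runif(nsites) < miss] <- NA
    out
  }
  geno <- rbind(a1 = noisy(src1), a2 = noisy(src1), a3 = noisy(src1),
                b1 = noisy(src2), b2 = noisy(src2), b3 = noisy(src2))
  d <- pairwise_allele_distance(geno)
  fit <- classical_mds(d, 2)
  grp <- c(1, 1, 1, 2, 2, 2)
  sil <- cluster::silhouette(grp, dist(fit$points[, 1]))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})
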