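#!/usr/bin/env Rscript
# Nuclear-style analysis: genotype low-coverage samples at a SNP panel
# pseudo-haploidly, compute allele-sharing distances, and place the samples
# by classical multidimensional scaling.
source("analysis/00_common.R")

set.seed(SEED + 401L)
scaffold <- generate_panel(SEED + 402L, 1, 20000, 0)[[1]]
scaffold$circular <- FALSE
refv <- strsplit(scaffold$sequence, "")[[1]]
sites <- sort(sample(100:19900, 600))
alt <- vapply(refv[sites + 1L], function(b)
  sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
panel <- data.frame(chrom = scaffold$id, pos = sites,
                    ref = refv[sites + 1L], alt = alt,
                    stringsAsFactors = FALSE)
write_tsv(panel, res_dir("popgen", "snp_panel.tsv"))

# two source populations with divergent allele profiles; the "coprolite"
# sample is drawn from population A at low coverage
pop_geno <- function(p_alt) ifelse(runif(600) < p_alt, "alt", "ref")
pA <- pop_geno(0.7); pB <- pop_geno(0.3)
make_sample <- function(geno, coverage, sub_seed) {
  carrier <- refv
  swap <- geno == "alt"
  carrier[sites[swap] + 1L] <- alt[swap]
  g <- reference_genome("carrier", paste(carrier, collapse = ""),
                        circular = FALSE)
  pool <- simulate_reads(list(g), 1, round(20000 * coverage / 51),
                         damage = damage_model(delta3 = 0.1, decay = 0.5,
                                               err = 0.001),
                         seed = sub_seed)
  aln <- align_reads(pool$reads, list(scaffold))
  genotype_sites(aln[aln$mapq >= 25, ], panel, L = 20000)
}
samples <- rbind(
  coprolite = make_sample(pA, 4, SEED + 403L),
  popA_1 = make_sample(pA, 8, SEED + 404L),
  popA_2 = make_sample(pA, 8, SEED + 405L),
  popB_1 = make_sample(pB, 8, SEED + 406L),
  popB_2 = make_sample(pB, 8, SEED + 407L))
calls <- rowSums(!is.na(samples))
message(sprintf("SNPs called: %s",
                paste(sprintf("%s=%d", names(calls), calls), collapse = ", ")))
write_tsv(data.frame(sample = rownames(samples), samples, check.names = FALSE),
          res_dir("popgen", "genotypes.tsv"))

d <- pairwise_allele_distance(samples)
write_tsv(data.frame(sample = rownames(d), d, check.names = FALSE),
          res_dir("popgen", "distances.tsv"))
fit <- classical_mds(d, 2)
coords <- data.frame(sample = rownames(fit$points),
                     axis1 = fit$points[, 1], axis2 = fit$points[, 2])
write_tsv(coords, res_dir("popgen", "mds_coordinates.tsv"))
nearest <- rownames(d)[order(d["coprolite", ])][2]
message(sprintf("coprolite groups with %s on the MDS (axis-1 separation)",
                nearest))
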