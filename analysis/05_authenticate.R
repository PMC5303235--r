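#!/usr/bin/env Rscript
# Authenticate ancientness: substitution-rate profiles by distance from the
# read ends against the final consensuses, overall identity, and the
# fragment-length law.
source("analysis/00_common.R")

reads <- read_fastq("results/preprocess/reads.trimmed.fastq")
cons <- c(read_fasta("results/coassembly/consensus_g03.fasta"),
          read_fasta("results/coassembly/consensus_g02.fasta"))
names(cons) <- sub("_consensus", "", vapply(cons, `[[`, "", "id"))
cons <- lapply(names(cons), function(id)
  reference_genome(id, cons[[which(names(cons) == id)]]$sequence))
names(cons) <- vapply(cons, `[[`, "", "id")

summ <- list()
for (id in names(cons)) {
  aln <- align_reads(reads, cons[id])
  aln <- aln[aln$mapq >= 25, ]
  dd <- dedup_unique(aln)
  prof <- profile_damage(dd$alignments, cons[[id]]$sequence)
  verdict <- authenticity_verdict(prof)
  write_tsv(data.frame(type = rownames(prof$rates3), prof$rates3,
                       check.names = FALSE),
            res_dir("authenticate", paste0("damage_3prime_", id, ".tsv")))
  write_tsv(data.frame(type = rownames(prof$rates5), prof$rates5,
                       check.names = FALSE),
            res_dir("authenticate", paste0("damage_5prime_", id, ".tsv")))
  summ[[id]] <- data.frame(
    genome = id, n_unique_reads = nrow(dd$alignments),
    n_aligned_bases = prof$n_aligned_bases,
    n_mismatches = prof$n_mismatch,
    identity_pct = 100 * prof$identity_fraction,
    median_read_length = prof$median_length,
    ga_terminal_rate = unname(prof$rates3["G>A", 1]),
    verdict = verdict)
  message(sprintf(
    "%s: identity %.2f%%, median length %g nt, 3' G>A terminal rate %.3f -> %s",
    id, 100 * prof$identity_fraction, prof$median_length,
    prof$rates3["G>A", 1], verdict))
}
write_tsv(do.call(rbind, summ), res_dir("authenticate", "summary.tsv"))
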