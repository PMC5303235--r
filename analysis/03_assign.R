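#!/usr/bin/env Rscript
# Competitive assignment of the trimmed pool against the 49-genome panel:
# only reads matching perfectly and uniquely credit a genome. The top two
# counts identify the coprolite producer and its prey.
source("analysis/00_common.R")

reads <- read_fastq("results/preprocess/reads.trimmed.fastq")
panel <- read_fasta("results/data/panel49.fasta")
at <- assign_reads(reads, panel)

tab <- at$per_genome[order(-at$per_genome$n_perfect_unique), ]
write_tsv(tab, res_dir("assign", "assignment.tsv"))
write_tsv(data.frame(class = c("shared", "imperfect_only", "unmapped"),
                     n = c(at$n_shared, at$n_imperfect_only, at$n_unmapped)),
          res_dir("assign", "assignment_summary.tsv"))
message(sprintf("top taxa: %s (%d reads), %s (%d reads); shared %d",
                tab$genome_id[1], tab$n_perfect_unique[1],
                tab$genome_id[2], tab$n_perfect_unique[2], at$n_shared))
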