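#!/usr/bin/env Rscript
# Build the synthetic study: a 49-mitogenome panel, the coprolite read pool
# (producer + prey + trace taxa, ancient-DNA damage), and write the raw
# inputs every later stage reads.
source("analysis/00_common.R")

study <- build_study()

write_fasta(study$panel49, res_dir("data", "panel49.fasta"))
write_fastq(study$pool$reads, res_dir("data", "reads.fastq"))
write_tsv(study$pool$truth, res_dir("data", "truth.tsv"))
write_tsv(study$panel49$g02$features, res_dir("data", "producer_features.tsv"))
write_fasta(study$truths, res_dir("data", "sample_truth_genomes.fasta"))
write_tsv(data.frame(label = c("collagen", "gelatin"),
                     age = c(32316, 32623), sigma = c(215, 200)),
          res_dir("data", "c14.tsv"))

lens <- nchar(study$pool$reads$bases)
message(sprintf("pool: %d reads, median length %d nt (range %d-%d)",
                length(lens), median(lens), min(lens), max(lens)))
message(sprintf("sources: %s", paste(names(sort(table(study$pool$truth$source),
                                                decreasing = TRUE)[1:3]),
                                     collapse = ", ")))
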