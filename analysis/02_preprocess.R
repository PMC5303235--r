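#!/usr/bin/env Rscript
# 3'-end trimming (adapter, N, low quality) and the <20-nt length filter.
source("analysis/00_common.R")

reads <- read_fastq("results/data/reads.fastq")
cfg <- pipeline_config()
out <- preprocess_reads(reads, cfg$adapter, cfg$qual_floor, cfg$min_read_len)
write_fastq(out$reads, res_dir("preprocess", "reads.trimmed.fastq"))
write_tsv(out$report, res_dir("preprocess", "trim_report.tsv"))
message(sprintf("preprocess: %d in, %d adapter-trimmed, %d short discarded, %d out",
                out$report$n_input, out$report$n_adapter_trimmed,
                out$report$n_discarded_short, out$report$n_output))
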