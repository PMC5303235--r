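#!/usr/bin/env Rscript
# Place the assembled prey consensus among its relatives: concatenate the
# homologous called regions, count pairwise differences, build the
# neighbor-joining tree and attach 500-replicate bootstrap supports.
source("analysis/00_common.R")

study <- build_study()
cons <- read_fasta(file.path("results/coassembly",
                             paste0("consensus_", study$prey, ".fasta")))[[1]]

# relatives: the prey's database reference plus a star of derived cousins
set.seed(SEED + 301L)
ref_seq <- study$panel49[[study$prey]]$sequence
relatives <- c(
  consensus = cons$sequence,
  reference = ref_seq,
  cousin1 = mutate_seq(ref_seq, 0.01, SEED + 302L),
  cousin2 = mutate_seq(ref_seq, 0.03, SEED + 303L),
  outgroup = study$panel49$g01$sequence)
# coordinates are shared by construction (no indels), so columns align 1:1;
# complete deletion removes every column uncalled in the consensus
pd <- pairwise_differences(relatives)
write_tsv(data.frame(taxon = rownames(pd$d), pd$d, check.names = FALSE),
          res_dir("phylo", "difference_counts.tsv"))
message(sprintf("sites used after complete deletion: %d", pd$sites_used))
message(sprintf("consensus vs reference: %d differences",
                pd$d["consensus", "reference"]))

bs <- bootstrap_support(relatives, reps = 500, seed = SEED + 304L)
ape::write.tree(bs$tree, res_dir("phylo", "nj_bootstrap.nwk"))
message(sprintf("bootstrap supports (500 reps): %s",
                paste(round(stats::na.omit(bs$support), 2), collapse = ", ")))
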