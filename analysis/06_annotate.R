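#!/usr/bin/env Rscript
# Transfer the reference annotation onto the assembled prey consensus through
# a banded global alignment, and validate the coding sequence under the
# vertebrate mitochondrial code.
source("analysis/00_common.R")

study <- build_study()
cons <- read_fasta(file.path("results/coassembly",
                             paste0("consensus_", study$prey, ".fasta")))[[1]]
ref <- study$panel49[[study$prey]]  # the annotated database reference

al <- global_align(cons$sequence, ref)
proj <- project_features(al, ref$features)
write_tsv(proj, res_dir("annotate", "projected_features.tsv"))
message(sprintf("global alignment: %d edit(s), rotation %d", al$edit,
                al$rotation))
for (i in seq_len(nrow(proj))) {
  if (proj$kind[i] == "CDS")
    message(sprintf(
      "CDS %s: [%d,%d) -> [%d,%d); start_ok=%s stop_ok=%s no_internal_stop=%s",
      proj$name[i], proj$start[i], proj$end[i], proj$proj_start[i],
      proj$proj_end[i], proj$start_ok[i], proj$stop_ok[i],
      proj$no_internal_stop[i]))
}
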