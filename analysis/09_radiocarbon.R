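#!/usr/bin/env Rscript
# Combine the two replicate AMS measurements of the associated bone sample.
source("analysis/00_common.R")

dates <- read_tsv("results/data/c14.tsv")
comb <- combine_dates(dates)
iv <- combine_dates(dates, method = "inverse_variance")
out <- data.frame(
  method = c("arithmetic", "inverse_variance"),
  age_bp = c(comb$age, iv$age),
  sigma_bp = c(comb$sigma, iv$sigma),
  T_statistic = c(attr(comb, "T_statistic"), attr(iv, "T_statistic")))
write_tsv(out, res_dir("radiocarbon", "combined.tsv"))
message(sprintf("combined age: %d +/- %d BP (arithmetic); T = %.2f on 1 df",
                comb$age, comb$sigma, attr(comb, "T_statistic")))
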