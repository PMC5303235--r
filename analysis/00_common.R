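# Shared setup for the analysis drivers: one seed, one output tree, and the
# synthetic study design (who is in the panel, who produced the coprolite,
# what the assembly references are).
library(copromito)

SEED <- 1L
res_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(dirname(d), showWarnings = FALSE, recursive = TRUE)
  d
}

# per-site mutated copy (database reference vs sample genome)
mutate_seq <- function(seq, rate, sub_seed) {
  set.seed(sub_seed)
  v <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  if (length(hit))
    v[hit] <- vapply(v[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  paste(v, collapse = "")
}

# The study: a 49-mitogenome panel; the coprolite pool mixes the producer
# (g02, "the predator") at 45%, the prey (g03) at 30%, and trace taxa.
# The true sample genomes differ ~2% from their database references,
# reads carry 3' G>A damage (0.1, decay 0.5) and 0.1% error.
build_study <- function(seed = SEED) {
  panel49 <- generate_panel(seed, 49, 16000, 0.08)
  # the sample genomes diverge 2% from their database references, but their
  # CDS stays intact (selection): re-plant it after mutating
  sample_genome <- function(id, sub_seed) {
    f <- panel49[[id]]$features
    cds <- f[f$kind == "CDS", ][1, ]
    s <- mutate_seq(panel49[[id]]$sequence, 0.02, sub_seed)
    reference_genome(id, plant_cds(s, cds$start, cds$end - cds$start),
                     features = f)
  }
  truths <- list(g02 = sample_genome("g02", seed + 101L),
                 g03 = sample_genome("g03", seed + 102L))
  props <- c(0.05, 0.45, 0.30, rep(0.20 / 46, 46))
  sources <- c(panel49[1], truths, panel49[4:49])
  pool <- simulate_reads(sources, props, 20000,
                         damage = damage_model(delta3 = 0.1, decay = 0.5,
                                               err = 0.001),
                         seed = seed + 103L)
  list(panel49 = panel49, truths = truths, pool = pool,
       producer = "g02", prey = "g03")
}
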