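# copromito

Ancient-DNA workflows for mixed-source samples: a carnivore coprolite
contains mitochondrial DNA of both the animal that produced it and the prey
it digested, fragmented to ~20–100 nt and carrying the deamination damage
signature of old DNA. `copromito` implements, as a tested R package plus a
reproducible analysis workflow, the computational path from such a read
pool to two finished mitogenomes and their downstream analyses:

* **Competitive assignment** — credit a read to a panel genome only when it
  matches perfectly, without mismatch or indel, and to that genome alone;
  the two largest counts identify producer and prey.
* **Simultaneous iterative co-assembly** — align the full pool to both
  reference mitogenomes at once, keep reads mapping exclusively to one
  genome with mapping quality ≥ 25, collapse duplicates, call a majority
  consensus requiring ≥ 2 concordant unique sequences per position, flag
  columns with > 25% disagreement (retaining the majority when the
  disagreement is explained by 3'-terminal G→A damage), realign to the
  provisional consensuses, and repeat to a fixed point; PCR consensus
  fragments fill the remaining gaps and singleton-coverage positions.
* **Damage authentication** — substitution rates by distance from the read
  ends; an elevated terminal G→A (3') or C→T (5') rate authenticates the
  assembly as ancient.
* **Annotation transfer, difference-count neighbor-joining with bootstrap,
  pseudo-haploid SNP genotyping with classical MDS, and radiocarbon date
  combination** complete the workflow.

The aligner uses BWA's read-length-dependent edit-distance ceiling: the
maximum number of differences for a read of length *l* is the smallest *k*
with P(X > k) < 0.1 for X ~ Poisson(0.02 l) — one difference for 20–26-nt
reads up to four for 88–101-nt reads. A synthetic-data module (lognormal
fragment lengths with median 48 nt, geometric-decay terminal deamination,
uniform error, full truth tables) makes every stage testable offline.

## Worked example

Simulate two 4-kb circular genomes at 5% divergence, an ancient read pool
covering both at ~30×, co-assemble, and authenticate:

```r
library(copromito)

truths <- generate_panel(seed = 11, n_genomes = 2, length = 4000, divergence = 0.05)
pool <- simulate_reads(truths, proportions = c(0.5, 0.5), total = 4800,
                       damage = damage_model(delta3 = 0.1, decay = 0.5, err = 0.001),
                       seed = 12)
median(nchar(pool$reads$bases))
#> [1] 48

co <- iterate_coassembly(pool$reads, truths)
co$converged
#> [1] TRUE
co$states$g01
#> <ConsensusState g01 iter 2: 4000 columns, 3285 called, 715 N, 13 gap run(s), 221 singleton(s)>

aln <- align_reads(pool$reads, truths["g01"])
prof <- profile_damage(dedup_unique(aln[aln$mapq >= 25, ])$alignments,
                       co$states$g01$sequence)
prof
#> <DamageProfile: 148379 aligned bases, identity 0.9857, median length 47>
#>   G>A 3'-terminal rate 0.0921; C>T 5'-terminal rate 0.0042
authenticity_verdict(prof)
#> [1] "authentic_like"

combine_dates(data.frame(age = c(32316, 32623), sigma = c(215, 200)))
#> combined: 32,469 ± 147 BP
```

At 5% divergence about half of all read windows are compatible with both
genomes; the exclusivity screen removes them, so the called positions are
essentially error-free while the shared windows honestly remain N — those
are the regions `propose_pcr_targets()` designs amplicons for. The 3'
G→A terminal rate (0.092 here) recovers the simulated δ₃ = 0.1; the small
nonzero C→T background comes from cross-mapped reads of the other genome,
absent once the exclusivity gate is applied. The combined radiocarbon age
reproduces the arithmetic-mean convention exactly.

## The analysis workflow

`analysis/01_simulate.R` … `analysis/09_radiocarbon.R` are thin numbered
drivers that run the whole study on synthetic data — 49-genome panel,
20,000-read coprolite pool (producer 45%, prey 30%, trace taxa), trimming,
assignment, co-assembly with PCR fill, authentication, annotation,
phylogeny with 500-replicate bootstrap, SNP/MDS placement, and date
combination — writing their tables under `results/`:

```sh
for s in analysis/0[1-9]*.R; do Rscript "$s"; done
```

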