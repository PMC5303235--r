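---
title: "Methods: co-assembling two mitogenomes from one ancient read pool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-assembling two mitogenomes from one ancient read pool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(copromito)
```

## The problem

A carnivore coprolite contains DNA of the animal that produced it and of the
animals it ate, fragmented to a few tens of nucleotides and chemically
damaged by millennia of cytosine deamination. From one single-end Illumina
library of such a sample, the workflow implemented here (i) identifies the
producer and the dominant prey by competitive assignment against a panel of
candidate mitochondrial genomes, (ii) assembles *both* mitogenomes
simultaneously from the mixed pool by iterative reference-guided consensus,
(iii) authenticates the assemblies through the damage signature at read
ends, and (iv) carries the result into annotation, difference-count
phylogenetics, pseudo-haploid SNP genotyping with classical MDS, and
combination of replicate radiocarbon dates. No external data are required:
a first-class synthetic-data module generates reference panels and damaged
ancient read pools with full truth tables.

## The read and damage model

`simulate_reads()` draws fragments from circular source genomes with
lognormal lengths truncated to [20, 101] nt. The paper-grade default
(`meanlog = log(48)`, `sdlog = 0.35`) puts the median at 48 nt, the
hallmark of ancient, highly fragmented DNA; only the median and range of the
real library are known, so the lognormal family and its spread are package
decisions exposed as parameters, not facts about the source data.

Damage follows `damage_model(delta3, delta5, decay, err)`: in read-strand
space, a G at distance $d$ from the 3' end becomes A with probability
$\delta_3\,\mathrm{decay}^d$, and a C at distance $d$ from the 5' end
becomes T with probability $\delta_5\,\mathrm{decay}^d$; uniform sequencing
error `err` is applied afterwards. Because the emulated library type is
blunt-end repaired, its published signature is an elevated G→A rate at 3'
ends only; the study-condition simulations therefore set `delta3` and leave
`delta5 = 0`, while the profiler (`profile_damage()`) tabulates all twelve
substitution types from both ends so a 5' C→T excess would be seen if
present.

What the generator does *not* emulate: indel-type damage, GC-dependent
coverage bias, overhang-length distributions, base-quality degradation
profiles (qualities are constant Q37; only the 3'-trim step consumes them),
and nuclear-genome-scale data. Passing tests therefore certify the
algorithmic machinery under an idealised substitution-only error process,
not performance on real libraries with those additional artefacts.

## The aligner

Reads are mapped by exact k-mer seeding (both strands; circular references
are extended across the origin) followed by banded unit-cost edit-distance
dynamic programming with a cap on gap *openings* (`max_gap_opens = 1` by
default, mirroring a `-o 1` style gap policy). A placement is accepted when
its edit distance is at most `maxdiff(l)`, the smallest $k$ with
$P(X > k) < 0.1$ for $X \sim \mathrm{Poisson}(0.02\,l)$ — the rule that
yields 1 tolerated difference for 20–26-nt reads up to 4 for 88–101-nt
reads.

Numerical choices that matter:

* **Seed length 9.** With at most $k$ substitutions in a read of length
  $l$, the longest clean stretch is at least $\lceil (l-k)/(k+1) \rceil$,
  which stays ≥ 9 over the whole `maxdiff` table; a 9-mer seed therefore
  guarantees that every substitution-only placement within `maxdiff` is
  found. (A 12-mer seed provably misses some 30-nt reads with two spread-out
  mismatches.)
* **Canonical alignments.** Leading and trailing read insertions are
  forbidden and final-state ties prefer fewer gap openings, so a terminal
  mismatch is never silently recast as an end-adjacent indel. Without this,
  half of the 3'-terminal G→A events vanish from the damage profile because
  the cost-equivalent `...1I1M` representation hides them.
* **Mapping quality** is a three-tier uniqueness code: 0 when a rival
  placement is at least as good, 20 when a rival sits exactly one edit
  worse, 37 otherwise. The workflow's gate ("mapping quality of at least
  25") therefore retains exactly the tier-37 placements; the inclusive
  (`>=`) reading of the gate is the default, with a strict option in the
  configuration.

## The co-assembly and its stability

Each round aligns the *full* pool simultaneously to the current provisional
consensuses, keeps per target genome the reads that pass the
exclusive-mapping screen and the mapping-quality gate, collapses duplicate
placements (identical genome, start, strand and bases), and calls a
majority consensus per column: at least two concordant unique sequences
(Illumina reads or PCR consensus fragments) are required for a call;
columns with more than 25% disagreement are flagged `disputed`; a dispute
is resolved in favour of the majority when every disagreeing base is a
read-strand G→A observation within 10 nt of the contributing read's 3' end
(`damage_explained` — the mechanised counterpart of a by-hand review), or
when a PCR fragment concurs; ties and unresolved disputes give N. PCR
fragments bypass the mapping-quality gate and count once each; a single
fragment therefore leaves a column one short of the concordance floor,
which is why the workflow supplies replicate amplicons per target, as the
original experiments did.

Two design points deserve an explanation because the obvious alternatives
fail:

* **Uncalled positions carry no evidence.** If consensus N matched reads at
  zero cost, each genome's N-mask would modulate the *competitor's*
  exclusivity decisions and the two assemblies would oscillate instead of
  converging; if N always cost a mismatch, reads anchored at a gap edge
  would be expelled and gaps would creep outward a few bases every round.
  The resolution is asymmetric: a read's own placement aligns through N
  freely (its seeds anchor it to called sequence), while any *rival*
  placement — and any would-be veto — is charged one mismatch per N it
  leans on.
* **The exclusivity screen is anchored to the fixed external references.**
  The screen asks "could this read come from the other taxon?"; answering
  it against the evolving competitor consensus couples the two assemblies
  and produces limit cycles in regions the genomes share. The references
  never change, so reference-anchored exclusion makes the retained read set
  stabilise within a few rounds. After convergence one final screening pass
  also vetoes reads that match the competitor's *called consensus* within
  `maxdiff` (N charged as mismatch), so no retained read matches the other
  assembly — a one-shot pass cannot oscillate.

Iteration stops when both consensus sequences are unchanged between
successive rounds (the convergence criterion is a package decision; the
source study simply performed "a last iteration") or at `max_iterations = 5`
with a warning. Under the stress conditions used in the acceptance suite —
two 16-kb genomes at 5% divergence, ~30× coverage each, damage 0.1 with
decay 0.5, error 10⁻³, references 2% off the true genomes — the fixed point
is typically reached in 5–6 rounds; the acceptance script runs with a cap
of 8 so the iterations-to-convergence measurement is never censored, while
the pipeline default keeps the cap of 5. At 5% divergence roughly half the
read windows are compatible with both genomes, so the exclusivity screen
leaves genuine coverage deficits; these are exactly the gaps the PCR module
is designed to fill, and the acceptance test verifies that every
no-coverage flag corresponds to a deficit of truth-level exclusive unique
reads. The realistic predator/prey case (~15% divergence, as in the
`analysis/` drivers) assembles essentially gap-free.

## Downstream modules

**Damage authentication.** Rates are mismatches over aligned consensus
bases of the substituted-from type at each end distance 0–24 (consensus N
columns excluded from numerator and denominator). The verdict is
`authentic_like` when the terminal 3' G→A or 5' C→T rate is at least 3× its
interior plateau (mean over distances 10–24, floored at 10⁻⁶ so a zero
plateau cannot trivially satisfy the fold rule) and exceeds 1% absolutely,
with at least 100 opportunities at the terminal position; `insufficient`
below that floor. The fold threshold, absolute floor and opportunity floor
are package decisions — the source analysis states no numeric authenticity
criterion.

**Annotation transfer** uses a banded global aligner (band 200 by default,
generous for mitogenome-scale indel load; the band is validated and a
too-small band is an explicit error). Circular inputs are first rotated via
a shared anchor k-mer near the reference origin. Feature boundaries map
through the alignment; a boundary landing in a deletion moves to the
nearest aligned column toward the feature interior and the projection is
flagged. CDS validation uses the vertebrate mitochondrial code with start
set {ATG, ATA, GTG} (covering common bovid mitochondrial starts), stop set
{TAA, TAG, AGA, AGG}, and the polyadenylation-completed incomplete stops T
and TA (accepted, flagged).

**Phylogenetics.** Distances are raw difference counts under
complete-deletion site filtering (a fixed shared site set, as in
fixed-position concatenated analyses); no multiple-hit correction is
applied because difference counts are the quantity reported downstream.
The neighbor-joining implementation clamps negative intermediate branch
lengths to zero and shifts the deficit to the sister edge, preserving path
lengths; trees are `ape` objects, and bootstrap supports are bipartition
frequencies over column-resampled replicates (500 by default). An alignment
of identical sequences yields no resolved splits and NA supports rather
than an error.

**SNP genotyping and MDS.** The published diploid caller with QUAL > 25 and
depth ≥ 2 is re-expressed pseudo-haploidly: per site, the majority base
among reads passing the mapping-quality gate, requiring ref+alt depth ≥ 2,
no tie, and no third allele outvoting the panel alleles. The
between-sample distance is 1 − allele sharing over jointly called sites
(at least 100 shared sites per pair, otherwise an error naming the pair);
classical (Torgerson) MDS is computed via `stats::cmdscale`, reporting
truncated negative eigenvalues and shrinking the embedding with a warning
when fewer positive eigenvalues exist than requested.

**Radiocarbon combination.** The arithmetic method truncates the mean
toward zero and rounds sigma half-up from $\sqrt{\sum\sigma_i^2}/n$ — the
only rounding convention consistent with combining 32,316 ± 215 and
32,623 ± 200 into 32,469 ± 147. An inverse-variance weighted mean is
available as an option; both report the consistency statistic
$T=\sum((x_i-\bar x)/\sigma_i)^2$. Calibration to calendar years requires
an external calibration curve and is out of scope; no curve ships with the
package.

## Problem sizes

The test suite and acceptance script run, by choice, at: 16-kb genomes and
~19–20k reads for the co-assembly study; 8-kb genomes and 8,000 reads for
damage recovery; a 49 × 16-kb panel with 2,500 reads for dominance
recovery; 200 reads against a 2-kb genome for the aligner/oracle
equivalence; 8-taxon, 2-kb alignments over 10 seeds for tree consistency;
500 bootstrap replicates. These sizes make every stochastic check
well-powered under binomial 3σ bounds while keeping a full run in the
minutes range on one core.

## Known limitations

The aligner is a small-panel tool (hash seeding, no FM-index); it is not
meant for nuclear-genome-scale references. Consensus coordinates assume the
reference length is essentially preserved (deletions can be called per
column, but large structural rearrangements are out of scope). The
exclusivity screen's reference anchoring assumes the database references
are within a few percent of the sample genomes, as is the case for the
congeneric references the workflow targets; with a grossly wrong reference
the screen degrades toward ordinary single-genome assembly of whichever
taxon the reference does match.
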