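---
title: "Clade-exclusion benchmarking of taxonomic classifiers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clade-exclusion benchmarking of taxonomic classifiers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladebench)
```

## The problem

Read-level taxonomic classifiers perform deceptively well when the query
genomes sit in their reference database: the test is then essentially a
lookup of the training data. In real environmental samples the majority of
organisms have no sequenced representative, so honest evaluation must
remove the truth taxa from the reference first. Clade exclusion does this
at a chosen rank: under species exclusion every genome of the truth species
is removed (all its strains with it); under genus exclusion the whole
genus; and so on up to class. The lowest rank at which a correct call
remains achievable — the *best possible rank* — is one step above the
exclusion rank.

cladebench provides the scaffolding around the external classifier: ground
truth generation, reference pruning, and scoring. It never runs or
reimplements any classifier; users run their tool on the pruned reference
and feed the assignments back.

## Scoring model

All rank arithmetic uses the canonical ladder with indices counted upward
from species:

```{r}
rank_ladder()
```

Nodes with any other rank label ("no rank", strains, subspecies) take part
in path membership but are invisible to the ladder: a strain projects to
its species, an unranked clade to the first canonical ancestor above it.
This reproduces ranks-above counting on real NCBI trees, which are full of
unranked internal nodes.

Per read, with truth species $t$ and assignment $a$:

* unassigned $\rightarrow$ FN;
* $a$ on the path from $t$ to the root (after projecting $a$ below-species
  nodes to their species) $\rightarrow$ TP;
* otherwise FP — unless overpredictions are being counted as correct, in
  which case the read is TP iff the ancestor of $a$ at the best possible
  rank equals the ancestor of $t$ at that rank (wrong species, right genus
  under species exclusion). An assignment *above* the best possible rank
  has no ancestor at it and stays FP under this rescue.

Sensitivity is $TP/(TP+FN)$, precision $TP/(TP+FP)$. Taxonomic distance,
over TP reads only, is $\max(0,\; \mathrm{idx}(a) - b)$ where
$\mathrm{idx}(a)$ is the canonical index of the assignment's nearest
canonical ancestor and $b$ the best-possible index. The clamp at zero
matters: under species exclusion a tool can still emit the (now
database-absent) species taxid, and "ranks above" cannot meaningfully go
negative.

### Aggregation

The default mode computes the three metrics per genome and averages them
unweighted, so a large genome (more reads) counts no more than a small one.
Two degenerate cases are excluded from the mean rather than imputed:
precision is undefined for a genome with no assigned reads (averaging in a
zero would conflate "conservative" with "wrong"), and distance is undefined
with zero TP reads. The counts of such genomes are carried in the result so
the exclusion is visible.

Pooled mode exists for in vitro mock communities, where DNA of the members
is mixed physically and no per-read source genome can be known. There all
reads are scored jointly and an assignment is correct when it lies on the
truth path of *any* community member. The distance baseline is then the
member whose path contains the assignment; when several do, the member
giving the smallest distance is used. Because all member species sit at
index 0, this most-generous tie-break is deterministic and in practice
gives the same distance for every containing member.

Either mode can rescue overpredictions. Rank-specific classifiers — tools
that emit all reads at one fixed rank — are only meaningfully compared in
the rescued mode, since strict path scoring penalizes them at every rank
below their target.

### Rank distributions

The proportion of reads assigned at each rank is a diagnostic for how
aggressively a tool commits. Whether such proportions should be computed
over assigned reads or all reads is a genuine ambiguity, so
`rank_distribution()` reports both denominators (`frac_assigned`,
`frac_all`) plus the unassigned fraction.

## Species-overprediction tables

`species_table()` attributes each assigned read to a species by projecting
to species rank; assignments above species contribute no row. Relative
abundance is the species' share of *species-attributed* reads — not of all
reads — because the table describes the composition a user would read off
the tool's species-level predictions; the choice is recorded in the report
metadata. A species is correct iff it is a community member.
`apply_cutoffs()` keeps a species at cutoff $c$ when its abundance is at
least $c$: the boundary is inclusive ("at least"), which we prefer over a
strict reading of cutoff headers written as "> x %"; with the inclusive
rule the no-cutoff column is exactly the $c = 0$ case. Both conventions
appear in published tables, so the rule is stated in the output metadata.

Genome-size correction of abundances (larger genomes contribute more
reads) is deliberately not implemented; the tables count species, and the
read counts are reported so users can correct externally.

## Synthetic data

### Packaged communities

Two classic mock-community definitions are packaged as metadata-only
profiles with hand-built companion taxonomies: `MetaSimHC` (11 genomes, 11
species, spanning Bacteria and Archaea) and `FW` (freshwater; 13 genomes,
11 species — *Pseudomonas aeruginosa* contributes strains PAO1,
UCBPP-PA14 and PA7, and the genus holds three species so congeneric
confusion is representable). The member count of a community is its number
of distinct species; the strain genomes are all recorded and callers can
subset. Companion taxonomies use circa-2013 NCBI rank names (e.g. order
Actinomycetales, class Deltaproteobacteria), matching the era of the
reference snapshots these communities were historically evaluated against;
taxids are internal synthetic IDs with real NCBI species taxids kept as
metadata only. No genome sequences are bundled — users point the simulator
at their own FASTA files.

### Synthetic worlds

`make_synthetic_world()` generates a taxonomy in which every genus gets its
own complete phylum→genus chain under a shared Bacteria superkingdom, with
congeneric pairs adding second species to existing genera, plus i.i.d.
uniform-base genomes (default lengths 5–20 kb, drawn uniformly). Uniform
bases carry no composition signal on purpose: the harness tests evaluation
logic, not classifier biology, and no conclusion about real-sequence
performance follows from these worlds. Output is byte-deterministic per
seed.

### Read simulation

Reads are error-free and single-end, mirroring evaluation protocols that
simulate at 100/250/500/1000 bp with every organism at 1X coverage and no
error model. Per genome the read count is
$\mathrm{round}(\text{coverage} \cdot L / \ell)$ — `round`, not `floor`,
so 1X of a 10,050 bp genome at 100 bp gives 100 reads (not 100.5 truncated
to 100; the choice only matters at the ±1-read margin and is stated so
counts are reproducible). Start positions are uniform with replacement,
strands equiprobable, minus-strand reads reverse-complemented, and reads
never wrap a circular origin (negligible at these coverages). FASTA is the
native output since there are no qualities; a FASTQ mode writes constant
Q40.

### Synthetic classifier

`simulate_classifier()` draws per read, independently: unassigned with
$p_U$; correct with $p_C$, emitted at a rank drawn from a configurable
profile (species-heavy = aggressive, family/order-heavy = conservative);
otherwise misassigned to a congeneric sibling, a random species outside the
truth genus, or the LCA of the truth and a confused sibling. A sibling
request in a singleton genus falls back to the other-clade mode and logs
it. Per-read independence is a deliberate simplification — real classifier
errors correlate along genomes (e.g. rRNA operons and other conserved or
non-coding regions) — so parameter-recovery results validate the metric
pipeline, not any claim about real tools. Under strict scoring with
species-rank output the closed-form expectations are sensitivity
$p_C/(p_C+p_U)$ and precision $p_C/(p_C+p_M)$, which the test suite
recovers within 99 % binomial confidence intervals.

## Inputs, formats, degenerate cases

* Taxonomies load from NCBI taxdump `nodes.dmp`/`names.dmp` (scientific
  names only) or a 4-column TSV; validation rejects duplicate taxids,
  unresolved parents, multiple roots and cycles. Merged/deleted NCBI taxid
  remapping is out of scope: unknown taxids are hard errors, which keeps
  every contract testable.
* Classifier output is ingested as generic `read_id → taxid` TSV (0/U =
  unassigned) or Kraken's five-column format. Reads present in the truth
  but missing from the output are counted as unassigned (FN) — classifiers
  that silently drop reads should not gain precision by it; assignments for
  unknown reads are errors.
* Clade exclusion is by lineage membership of the excluded ancestor, never
  by name matching. A reference genome whose lineage has no node at the
  exclusion rank is kept, with a warning: the conservative choice, since
  removing it would silently shrink the reference for reasons unrelated to
  the excluded clade.
* A truth taxon with no ancestor at the requested exclusion rank is a
  specification error, not a silent no-op.

## Problem sizes in the test suite

The suite exercises: ~200 randomized scoring scenarios of 40–180 reads on
random taxonomies (including unranked clades and strains), checked exactly
against a brute-force per-read oracle; parameter recovery on a
10,000-read world over 20 classifier seeds; 50-seed positional-uniformity
checks of the read simulator; and 10–20-world property sweeps for exclusion
nesting and cutoff monotonicity. These sizes were chosen to give exact
oracle agreement and tight (±2–4 %) binomial checks while keeping the whole
suite under a minute on a laptop.

## Known limitations

* Synthetic genomes are composition-free and reads error-free; nothing here
  measures robustness to sequencing error or to real sequence divergence.
* Communities are small (11 species); per-genome means on such communities
  are sensitive to single abnormal genomes, which is a property of the
  design being emulated, not of the implementation.
* Only two input dialects are parsed; MEGAN/RMA, BLAST-tabular-LCA and
  similar formats must be pre-converted.
* The strict-mode treatment of an on-path assignment *below* the best
  possible rank (e.g. the correct species taxid emitted under species
  exclusion) counts it TP, reading the path rule literally; evaluations
  that instead discard such reads will differ.
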