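---
title: "Comparative plastome divergence analysis with plastdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastome divergence analysis with plastdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastdiv)
```

## What the package computes

plastdiv analyzes sets of closely related annotated chloroplast genomes
the way congeneric plastome comparisons are usually done:

1. **Quadripartite structure.** Land-plant plastomes are circular molecules
   of roughly 150 kb organized as a large and a small single-copy region
   (LSC, SSC) separated by two identical inverted repeats (IRa/IRb,
   typically ~25 kb each). `find_inverted_repeats()` locates the repeat
   pair, `junction_table()` compares the four single-copy/IR junctions
   (JLB, JSB, JSA, JLA) across genomes, and `summarize_genome()` produces
   the conventional comparison-table row (region lengths, per-region GC,
   gene counts).
2. **Stepwise-window divergence scan.** `scan_windows()` computes
   nucleotide diversity (Pi), GC content and gap proportion in sliding
   windows over a multiple whole-genome alignment; `rank_hotspots()`
   merges above-threshold windows into candidate marker regions and
   `correlate_windows()` fits the Pi-versus-composition regressions.
3. **Region-wise divergence.** `classify_regions()` projects the
   annotation (exon / intron / intergenic spacer) into alignment
   coordinates; `region_pi()` scores each named region; `count_pics()`
   counts parsimony-informative characters per gene.
4. **Supermatrix assembly.** `extract_codon_alignments()` builds per-gene
   codon alignments by protein-guided back-translation;
   `build_supermatrix()` concatenates them and strips high-gap columns,
   emitting RAxML-style partitions for downstream phylogenetics.
5. **Substitution rates.** `ng86_pair()`/`gene_rates()` estimate
   synonymous and nonsynonymous rates (dS, dN) and their ratio omega with
   the Nei–Gojobori (1986) counting method; `group_rates()` aggregates
   over the nine conventional plastid functional groups.
6. **Ground-truth simulation.** `simulate_plastomes()` generates
   plastome-like data with a replayable truth registry so that every
   statistic above can be tested against planted truth.

## Definitions and conventions

**Coordinates.** All internal intervals are 0-based half-open; every
human-facing table is 1-based inclusive. Genomes are circular; where a
region wraps the origin its interval is carried as `start + length` with
coordinates interpreted modulo the genome length.

**Nucleotide diversity.** For a window (or region), every unordered pair
of rows is compared at the columns where *both* carry an unambiguous base
(`A/C/G/T`); `N` and `-` are excluded pair by pair (pairwise deletion).
The pair distance is mismatches over compared sites, and Pi is the mean
over pairs. Pairs with no comparable site are dropped and counted; when
every pair is dropped Pi is reported missing, never zero. Pairwise
deletion (rather than complete deletion) keeps windows with partial
coverage informative and matches the per-pair definition of the
statistic.

**GC content** is `(G + C) / (A + C + G + T)` over all cells, so `N` and
gaps dilute neither numerator nor denominator. **Gap proportion** is the
fraction of `-` cells among all cells; `N` counts as a base cell.

**Windows** (default 600 bp at a 200 bp step — the conventional scale at
which congeneric plastome scans resolve spacer-sized hotspots) are laid on
*alignment* coordinates, and trailing windows shorter than the window
length are dropped, so every emitted value summarizes the same number of
columns. Both choices are recorded in the run metadata because published
scans rarely state them.

**Correlation analysis** regresses `sqrt(Pi)` on GC (untransformed) and on
`sqrt(gap)`. The square root is the standard variance-stabilizing choice
for small proportions; the transforms are labeled in the output and can be
overridden. The fit is ordinary least squares with the slope's two-sided
t-test; windows with undefined Pi are excluded and counted rather than
imputed, which would fabricate signal.

**Parsimony-informative characters.** A column is informative when at
least two distinct bases each occur in at least two rows, counting only
`A/C/G/T`; gaps and `N` are missing data and never form an informative
state pair (the standard parsimony convention). The PIC table reports
`PIC / alignment length` as a percentage with two decimals.

**Inverted-repeat detection** uses an exact-match definition: the maximal
pair of disjoint intervals on the circle whose sequences are exact reverse
complements, found by seeded matching (tiles of half the minimum length
guarantee detection) with maximal bidirectional extension. Exactness makes
the detector deterministic and checkable against a quadratic brute-force
oracle; ties go to the smallest start coordinate. The default minimum
length of 10 kb is far above chance matches and below any real plastome
IR. When a junction falls inside sequence shared by the repeat and a
single-copy region, maximal extension may disagree with a published
annotation by a base or two; this is inherent to any exact rule.

**"Gene in IR"** means at least half of the gene's exonic span lies inside
either repeat copy — genes spanning junctions (ycf1 at JSA is the
classic case) need an unambiguous rule, and published tables do not state
one.

**Supermatrix.** Genes concatenate in alphabetical order of normalized
name (determinism for the partition table); columns are removed when their
gap fraction is *strictly greater than* the threshold (default 0.2), so a
five-row column with exactly one gap survives. Partition expressions are
re-indexed to the filtered matrix.

**NG86 rates.** Potential synonymous sites per codon come from enumerating
all nine single-base changes under the standard code; changes to stop
codons count as nonsynonymous potential. Observed differences are
apportioned by averaging over all minimal mutational pathways between the
two codons, excluding pathways that pass through a stop (falling back to
all pathways when every one is blocked). Proportions receive the
Jukes–Cantor correction `d = -(3/4) log(1 - 4p/3)`; `p >= 3/4` leaves the
rate undefined rather than infinite, and genes with `dS = 0, dN > 0` are
flagged `nonsynonymous-only` with omega undefined rather than a sentinel.
Codons containing gaps, `N`, or a stop in either sequence are excluded
pair by pair, preserving signal in otherwise clean genes. Rates are
averaged over all sequence pairs (with 5 closely related taxa, pairwise
means are the standard desk-scale surrogate for tree-based branch
estimates) and omega is the ratio of the averaged rates. The counting
method will not numerically reproduce maximum-likelihood (codeml-style)
estimates; per-gene codon alignments can be exported for external ML
estimation when those are needed.

**Functional groups.** The nine conventional plastid groups (photosystems
I and II, cytochrome b6f, ATP synthase, NADH dehydrogenase, RuBisCO, RNA
polymerase, ribosomal proteins, other/unknown) ship as an editable
prefix/exact-match table in `extdata/functional_groups.tsv`; unknown names
fall into other/unknown with a logged note. Group rates are reported both
as the estimate on the concatenated member alignment and as the mean and
standard deviation of per-gene estimates, since published group tables
rarely say which of the two they print.

**Gene names** are normalized to the plastid convention (three-letter
lowercase stem, uppercase suffix letters, anticodons uppercase,
`trnfM-CAU` preserved), with a user-extensible synonym table for
annotation dialects. Normalization is idempotent; comparison-table gene
counts are defined over normalized names.

## The simulator and what it emulates

`simulation_config()` defaults describe a small congeneric study: five
taxa; a 152.4 kb quadripartite genome (LSC 83.5 kb, SSC 17.5 kb, IR
25.7 kb) carrying 114 unique genes — 80 protein-coding, 30 tRNA, 4 rRNA,
18 duplicated in the IR, 18 intron-containing (two with three exons) —
with realistic per-gene lengths from an editable plan table; genome-wide
expected pairwise divergence theta = 0.01 (low interspecific divergence,
most windows below the 0.03 hotspot threshold); region rate multipliers
0.3 / 1 / 3 for exon / intron / spacer sites, normalized so the
genome-wide expectation stays theta; six spacers boosted 2.5-fold as
planted hotspots; spacer/intron-only indels at 2e-4 events per site with
geometric lengths (mean 40 bp) plus two one-off large insertions (431 and
258 bp) planting the spacer length polymorphism seen between congeneric
plastomes; coding evolution thinned to omega = 0.2 (plastid purifying
selection); GC drawn per region (LSC 0.35, SSC 0.31, IR 0.42), with
coding sequence GC-richer than spacers so composition and conservation
are linked as they are in real plastomes.

Implementation choices that matter for interpreting tests:

* **Exact divergence calibration.** Substitutions are Bernoulli per site
  and taxon with probability `p` solving `2p - (4/3)p^2 = theta * m`
  (the coincident-hit inversion), so realized pairwise divergence matches
  the target without small-sample drift.
* **Omega control.** Coding events are thinned per site to
  `(s + omega * (3 - s)) / 3` of the base rate (`s` = synonymous targets
  among the three changes) and the target base is drawn with stop targets
  at zero weight and their share redistributed onto viable nonsynonymous
  targets. This keeps open reading frames intact while making the
  process's counting-method omega equal omega_true in expectation; the
  residual bias (sites whose every nonsynonymous neighbor is a stop, e.g.
  tyrosine third positions) is well under the Monte Carlo noise of the
  recovery tests. One estimator-side caveat: under strong thinning the
  synonymous sites carry most of the coding rate, and once their
  divergence climbs well past ~0.1 the Jukes–Cantor correction and the
  pathway averaging acquire a small (few percent) downward omega bias —
  the recovery experiments therefore pitch the synonymous-site divergence
  at the 0.05 scale the correction is comfortable with.
* **IR homogenization.** The two repeat copies evolve as one locus: IRa is
  regenerated as the reverse complement of IRb after substitution, and
  indels are confined to single-copy regions — mirroring the gene
  conversion that keeps real plastome IRs effectively identical. The
  planted repeat is made exactly maximal by breaking chance
  complementarity just outside its junctions, so the detector's
  planted-truth test can demand coordinate equality.
* **Truth alignment by registry replay.** The multiple alignment is
  induced directly from the indel registry (deletions become gap runs,
  each insertion a column block carried only by its taxon; independent
  insertions at one anchor are stacked, not aligned to each other). This
  separates statistic correctness from heuristic aligner error; it also
  means the simulator never exercises a real aligner's mistakes, which is
  a deliberate limit of what the tests show.

What the simulator does *not* emulate: IR expansion/contraction,
rearrangements and inversions (absent in the motivating study group),
recombination, rate variation within a region class beyond the planted
hotspots, base-composition bias of the substitution process (changes are
Jukes–Cantor-uniform, matching the correction used by the estimator), and
alignment error. Passing planted-truth tests therefore demonstrates the
statistics and bookkeeping, not robustness to annotation or alignment
noise in real data.

## Numerical choices and degenerate inputs

* GC percentages round half-up to one decimal (the rendering convention of
  published comparison tables); PIC percentages to two decimals.
* Ambiguity codes other than `N` map to `N` on ingest, with a count.
* Protein-coding features whose exon lengths do not sum to a multiple of
  three are flagged non-canonical and excluded from codon work, never
  silently dropped.
* An alignment region with no comparable pair reports missing Pi; a
  regression needs at least three usable windows; hotspot ranking of an
  empty profile returns an empty report.
* A genome without a detectable repeat gets a structured no-IR result and
  downstream reports simply omit quadripartite-specific columns.
* Equal-length candidate repeats tie-break to the smallest start; gene
  concatenation order and region maps are deterministic, so reruns are
  byte-identical under a fixed seed.

## Problem sizes in the shipped tests

The test suite exercises the full-scale default simulation (152.4 kb,
five taxa) for end-to-end checks and a reduced 20.2 kb plan for
replicated experiments; recovery tests use 20 replicates per theta value,
50 planted-repeat genomes, 50 long (1500-codon) genes for neutral-omega
recovery, and 200-case brute-force comparisons for the window statistic
and PIC counter. These sizes keep each property at comfortable Monte
Carlo resolution while the whole suite stays desk-scale.

## Worked example

```{r example, eval = FALSE}
library(plastdiv)

sim <- simulate_plastomes(simulation_config(seed = 1))
q <- find_inverted_repeats(sim$ancestor$genome)
summarize_genome(sim$ancestor$genome, q)

prof <- scan_windows(sim$alignment, window = 600, step = 200)
correlate_windows(prof, "gc")
correlate_windows(prof, "gap")

g1 <- sim$genomes[[1]]
map <- classify_regions(g1, sim$alignment, g1$id)
rank_hotspots(prof, map, threshold = 0.03)

set <- extract_codon_alignments(sim$genomes)
pic_table(set)
est <- gene_rates_table(set)
group_rates(est, classify_functional_groups(est$gene), set)
```

Real GenBank flat files drop into the same pipeline through
`read_genbank()`, and whole-genome alignments (e.g. from MAFFT) through
`read_alignment()`; the `plastdiv` command-line wrapper
(`inst/exec/plastdiv`) chains the stages with a flat key=value config
file and writes run metadata alongside every artifact.
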