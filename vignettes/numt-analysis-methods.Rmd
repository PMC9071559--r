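---
title: "Models and methods behind numtscope"
author: "numtscope authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind numtscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numtscope)
```

# The problem

Nuclear insertions of mitochondrial DNA (numts) can be enormous: the
*Arabidopsis thaliana* chromosome 2 numt is larger than the mitochondrial
genome it derives from, is >99.9% identical to it, and is internally
repetitive, with large regions present in three copies. numtscope provides
the analysis chain needed to characterize such an insertion against a
circular organelle reference:

1. **Synteny decomposition** — which organelle regions make up the numt,
   in what order and orientation, and how were the pieces joined
   (repeat-mediated recombination vs NHEJ-like fusion)?
2. **Variant calling and mutation spectrum** — how far has the numt
   diverged, with what substitution bias, and is the C→T excess
   concentrated at CpG/CHG cytosines as expected if the numt is
   methylated?
3. **Duplication history** — did the multi-copy regions arise at insertion
   time (a star phylogeny) or by a later tandem duplication (copies
   sharing derived alleles)?
4. **Read partitioning** — which long reads come from the numt rather than
   the mitogenome, and what do methylation profiles look like before and
   after removing organelle reads?

Every stage can be exercised without external data through a genesis
simulator that produces machine-readable ground truth.

# Synteny decomposition

Anchors are k-mers (default k = 31) that occur exactly once in the
organelle genome counting both strands. Anchors found in the numt are
chained into collinear runs: consecutive anchors on the same strand whose
diagonal drifts by at most 50 bp (an indel-slack allowance) extend a
chain; chains are then merged across anchorless gaps whenever the numt-side
and organelle-side gap lengths agree within the same tolerance. The merge
step is what carries blocks through large repeats: repeat interiors are
anchorless by construction (their k-mers occur twice), so a traversal of a
repeat copy appears as two flanking chains with matching gaps. Because the
two copies of a repeat pair are near-identical, only the flanks are
informative about which copy was traversed — block boundaries at repeats
are therefore resolved by flank connectivity, never by repeat-internal
sequence.

Junctions between adjacent blocks are classified by their organelle-side
geometry: when the left block stops at one copy of an annotated repeat
pair and the right block resumes at the other copy (within a tolerance,
default 50 bp, chosen above the k-mer boundary error and reported in the
output), the junction is the signature of recombination between the
copies (`repeat_mediated`); otherwise it is `nhej` when the two organelle
intervals are disjoint on the circle and `unknown` when they overlap. The
paper-style "four conformations of a repeat pair" (A-B, A-B&prime;,
A&prime;-B, A&prime;-B&prime;, where A/B are copy 1's flanks and
A&prime;/B&prime; copy 2's) are detected from the same geometry: a block
spanning a copy evidences its parental conformation, a junction entering
through one copy and leaving through the other evidences a recombinant
one.

Two numerical choices matter here. Chance matches of junction-spanning
k-mers can extend a chain a base or two past the true boundary, so blocks
are trimmed to tile the numt strictly; boundary error is bounded by k.
And circular coordinates are handled by unwrapping: blocks may cross the
origin, reported with `org_end` past the genome length and a `wrapped`
flag.

# Alignment and variant calling

Homologous block pairs are aligned with a banded global aligner (affine
gaps: match +1, mismatch −2, a gap of length L costs 4 + L). The band is
widened and the alignment recomputed whenever the optimal path touches the
band edge, so the result equals the unbanded optimum — a property the test
suite verifies against an independent full dynamic-programming
implementation on hundreds of random pairs. The scoring is chosen to
behave sensibly at ≥99% identity; it is not tuned to any published
substitution matrix.

Variant records follow high-identity comparison conventions:

* isolated mismatch columns are SNVs;
* maximal runs of ≥2 adjacent mismatches are multi-nucleotide variants
  (MNVs), excluded from SNV counts and identity;
* gap runs are indels, excluded from identity, with polarity recorded
  (numt shorter vs longer);
* SNVs within `adjacency_window` (default 5) columns of any gap are
  excluded as `indel_adjacent` — short unalignable stretches next to
  indels are unreliable;
* columns containing N are excluded as unalignable and never emitted.

Percent identity is `100 × (1 − SNVs / eligible columns)`, where eligible
columns are the match/mismatch columns surviving all exclusions; the
window used is stated in the outputs.

The spectrum collapses strands in the organelle→numt direction into six
categories (GC<>AT, AT<>GC, GC<>TA, AT<>CG, GC<>CG, AT<>TA); the AT-bias
ratio is GC<>AT transitions over AT<>GC transitions. Cytosine context
(CpG/CHG/CHH, H ∈ {A,C,T}) of a C→T variant is evaluated on the organelle
genome at the organelle position, on the strand where the organelle allele
is C — the ancestral state of a deamination. Context enrichment uses a
1-df chi-squared goodness of fit of the (in-context, out-of-context) split
of C→T SNVs against the genome-wide fraction of cytosines in CpG or CHG
context.

# Duplication history

Organelle regions covered by ≥3 blocks of ≥5 kb are multi-copy groups.
Instead of a heuristic multiple aligner, each copy is aligned pairwise to
the organelle homolog and projected onto homolog columns (copies are
≥99.7% identical, so the projection is lossless except at copy-specific
insertions, which are kept as side records — deterministic and testable,
with no MSA drift). SNV columns are classified by allele sharing:
`singleton`, `shared_pair(i, j)` (exactly two copies share a derived
allele, the rest match the organelle), `all_derived`, `other`; indel
columns are ignored.

The star-phylogeny null — all copies diverging independently since
insertion — is tested by Monte Carlo: each copy mutates each column
independently at its observed copy-to-organelle rate, and a homoplasic
"shared pair" requires two copies to hit the same column with the same
one of three alternative bases. The p-value is the conservative
`(1 + #{simulated ≥ observed}) / (n_sim + 1)`; because the statistic is a
small discrete count, a randomized (uniform-under-the-null) companion
p-value is also reported and is the one used for calibration checks. The
seed is a required argument; the default 10,000 replicates resolve
p < 0.001 comfortably.

A tandem duplication is inferred when one copy pairing dominates the
shared-pair patterns, the patterns spread over at least half of the
aligned region (a localized cluster is better explained by a gene
conversion tract, and is reported as conflicting evidence instead), and
consistent patterns outnumber conflicting ones at least 2:1. The inferred
duplicated interval is the tandem span of the two daughter copies, with
the central breakpoint at their junction. Nested or multiple duplications
are out of scope and yield `inconclusive` — as does pervasive gene
conversion, which genuinely cannot be distinguished from duplication by
this evidence alone.

# Read partitioning and methylation

Non-excluded SNVs double as diagnostic sites. A read's covered sites are
scored for numt vs organelle alleles; a read is assigned to a source when
it shows at least `min_sites` supporting alleles and none of the other
source ("ambiguous" reads, with both alleles, are excluded from both
partitions — the conservative choice). `min_sites` defaults to 2; the
field convention of requiring "more than two" supporting observations is
one notch stricter and available by setting `min_sites = 3` — the
strictness is a visible tunable, not a hidden constant.

Methylation profiles pool calls into tiling windows per context
(calls-weighted, not read-averaged, matching common methylation-profile
conventions; stated in output headers); windows without calls are flagged
rather than zero-filled. Because the organelle genome is essentially
unmethylated, removing organelle-derived reads can only raise the numt's
apparent methylation in contaminated windows — a monotonicity property the
tests check directly.

Long 100%-identical regions (found by maximal-exact-match scanning, both
orientations) are the candidates for assembly "overwriting" by the more
abundant organelle reads; they are validated by anchored consensus: reads
spanning the region that carry numt alleles at flanking diagnostic sites
on both sides are anchored, and their per-column majority consensus is
compared with the assembly.

# The genesis simulator

The simulator emulates the hypothesized genesis of a large plant numt:

* a circular organelle genome of configurable length and GC content with
  planted identical repeat pairs — defaults follow the Arabidopsis
  system: ~368 kb, two large pairs (6.0 and 4.2 kb) and two small pairs
  (457 and 206 bp);
* fusion of an arbitrary fragment plan (intervals, orientations, origin
  wrapping allowed) — whether duplicate content arrives as one multimeric
  molecule or separate fragments is deliberately left to the plan, since
  the biology does not determine it;
* nuclear mutation accumulation at a default rate of 6.7×10⁻⁴
  substitutions per site (the observed numt/mitogenome divergence scale)
  with category weights defaulting to the observed spectrum (235:35:58:30:42:25,
  i.e. a 6.7:1 AT bias) and C→T context multipliers (CpG = CHG = 6,
  CHH = 1, chosen to reproduce a ~75% CpG+CHG share at a one-third
  context fraction). Two normalizations keep these knobs orthogonal and
  recoverable: category weights are corrected for base composition so
  they are realized as genome-wide event proportions, and context
  multipliers are normalized to mean 1 over C/G sites so they
  redistribute C→T events across contexts without changing category
  totals;
* an optional tandem duplication at a configurable `time_fraction` of the
  divergence period — variants drawn before it are copied into both
  daughter copies (the shared-derived-variant signal), later ones are
  copy-specific; `time_fraction = 0` produces an insertion-time (star)
  duplicate;
* optional gene-conversion tracts between the duplication copies;
* a deletion-biased indel process (deletion fraction 30/44, the observed
  polarity; lengths geometric with p = 0.5 capped at 20 bp, since no
  empirical indel length model is available);
* reads with true source labels, per-site allele error, and per-context
  methylation rates (numt reads methylated, organelle reads not).

All stochastic draws flow from R's global generator, seeded once per
top-level operation from the config, so identical configs give
byte-identical output. Truth objects record source blocks, fusion points
(with seamless rejoinings marked `collinear` — they are not structural
fusions), every planted variant with its epoch, the realized duplication,
conversion tracts and indels.

What the simulator does **not** model: gene structure or selection (the
analysis never uses annotation), sequencing error beyond a per-site allele
flip, read quality, mappability, or assembly error. Passing the
simulation-recovery tests therefore demonstrates correctness of the
algorithms under the stated generative model, not robustness to every
artifact of real long-read data.

# Problem sizes and verification strategy

The test suite runs everything on scaled-down instances — genomes of
30–150 kb, copies of ~10 kb, hundreds of reads — sizes at which each
property is statistically decisive while the whole suite stays fast. The
key verifications are: the banded aligner against an independent exhaustive
dynamic-programming oracle (≥500 random pairs ≤200 bp); simulator spectrum
calibration by chi-squared goodness of fit at ≥10,000 events; breakpoint
recall and precision ≥0.95 over 20 random genesis configurations at
divergence ≤0.3%; duplication-epoch verdicts (star vs post-insertion)
correct in ≥95% of 40 runs; uniformity of the randomized star-test
p-values under the null (Kolmogorov–Smirnov); read-partition accuracy
≥99% for reads covering ≥3 diagnostic sites at 0.1% allele error; the
methylation deconvolution monotonicity; and byte-identical pipeline
reruns.

`scripts/acceptance.R` recomputes the same quantities from scratch at run
time, plus the analytics that are pure functions of the published variant
counts (the 6.7:1 AT-bias ratio, the 74.5% CpG+CHG share of C→T
transitions, and the chi-squared enrichment statistic 178.9).

# Worked example

```{r example, eval = FALSE}
cfg <- sim_config(
  genome_length = 60000L, large_repeats = 3000L, small_repeats = 457L,
  seed = 5,
  fragment_plan = list(list(start = 1000, end = 15000, strand = "+"),
                       list(start = 30000, end = 45000, strand = "+")),
  mutation_rate = 1e-3)
g <- simulate_organelle_genome(cfg)
gen <- simulate_numt_genesis(g, cfg)
blocks <- decompose_synteny(gen$numt, g)
classify_breakpoints(blocks, g)
v <- call_block_variants(gen$numt, g, blocks)
spectrum_table(v)
percent_identity(v)
```

# Known limitations

* The synteny stage is specialized to ≥99% identity comparisons; it is
  not a general whole-genome aligner.
* Repeat-mediated vs NHEJ classification near (but not at) a small repeat
  depends on the 50-bp tolerance; junctions in the gray zone are flagged
  rather than silently decided.
* Only single tandem duplications are modelled; shared variants produced
  by pervasive gene conversion cannot be distinguished from duplication
  and are reported as conflicting evidence.
* The read module consumes tabulated allele/methylation observations; BAM
  parsing and signal-level methylation calling are out of scope.
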