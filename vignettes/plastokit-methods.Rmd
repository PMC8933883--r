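---
title: "Methods: comparative plastome structure, diversity and barcode analysis"
author: "plastokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative plastome structure, diversity and barcode analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

plastokit re-implements, as one reusable pipeline, the comparative analyses
typically run on a family of complete chloroplast genomes (plastomes):
quadripartite structure detection and junction typing, repeat and SSR
scanning, region-wise nucleotide diversity, DNA-barcode candidate selection
with tree-based discrimination scoring, region-size correlations, and a
pairwise Ka/Ks screen. This vignette documents the models, parameter
choices and numerical conventions, and what the bundled synthetic generator
does and does not emulate.

## Coordinates and containers

All internal coordinates are 0-based half-open on the forward strand of one
linearization of the circular genome; external files (GFF3-like tables) use
1-based inclusive coordinates. Features that wrap the origin are split into
two sub-intervals on load, so all downstream interval code is linear. IUPAC
ambiguity codes other than N are degraded to N with a warning rather than
rejected, because public records contain occasional ambiguities.

The canonical orientation places the LSC start at coordinate 0 with region
order LSC-IRb-SSC-IRa; IRb is, by convention, the IR copy whose
clockwise (increasing-coordinate) neighbour is the SSC. Published junction
figures require such a convention but rarely state one; fixing it by SSC
adjacency makes junction coordinates comparable across taxa.

## Inverted-repeat detection

`detect_inverted_repeats()` finds the maximal pair of segments (i1, i2)
such that i2 is the reverse complement of i1 at identity >= 0.99 and length
>= 1000 bp (both user-settable). Seeds of width k = 31 are matched exactly
against the reverse complement of the logically doubled sequence (so the
detection is rotation-invariant on the circle); seed hits sharing an
anti-diagonal are chained into collinear blocks — one circular pairing can
appear twice on the same anti-diagonal in the doubled sequence, offset by
one genome length, so only nearby seeds are chained — and each block is
extended by exact match outward. Ties are broken by longer length, then
smaller start.

Two numerical choices matter. First, extension is *exact-match* beyond the
chained blocks: extending "while overall identity stays above 0.99" would
let a 25 kb repeat absorb hundreds of chance-matching bases beyond the true
boundary (about 1.3% of the repeat length at a 25% per-base chance-match
rate), which would blur every junction coordinate. With near-identical IRs
— the rule in plastomes, where the two copies homogenize by gene
conversion — exact extension recovers boundaries to the base. Second,
indel-containing IR pairs are out of scope: the detector is ungapped.

`partition_genome()` assigns the longer inter-IR arc to the LSC and errors
(rather than guessing) if the two arcs tie.

## Junction profiling and boundary types

For each of the four junctions, `profile_junctions()` reports either the
annotated gene spanning the junction point (with the bp split across it) or
the nearest annotated gene on each side with its distance; 0 means the gene
abuts the junction. "Between A and B" in the classifier means the junction
point lies in an intergenic gap whose nearest annotated flanks are A and B,
irrespective of order and strand. tRNA names with anticodon suffixes
("trnN-GUU") match their bare symbol.

`classify_junction_type()` is a pure decision table over the IRb/SSC and
SSC/IRa junctions:

* **I** — IRb/SSC between trnN and ndhF; SSC/IRa inside ycf1 *or* between
  ycf1 and trnN. Both sub-cases are accepted and recorded, because the two
  arrangements differ only in whether ycf1 reaches the junction.
* **II** — IRb/SSC inside ndhF; SSC/IRa between rps15 and ycf1, with ycf1
  fully duplicated into the IRs (large IR expansion).
* **III** — IRb/SSC between trnR and trnN (the SSC expanded to capture
  trnN); SSC/IRa between ycf1 and the IR terminus. Under exact IR symmetry
  the IRa-side flank after such a contraction is necessarily trnR — both IR
  copies lose their trnN terminus together — so the classifier accepts
  either trnN or trnR there and records which sub-case fired.
* **IV** — IRb/SSC between trnN and ycf1 and SSC/IRa between ndhF and trnN,
  i.e. a reverse-complemented SSC.

Everything else is `unclassified` with a reason, including annotations
missing all five marker genes.

## The synthetic plastome family generator

Every downstream stage is tested against genomes with known ground truth.
`synth_config()` defaults describe a realistic member of an aroid-like
plastome family: LSC 91,710 bp, SSC 22,994 bp, IRs 25,601 bp (165,906 bp
total), per-region GC of 33.8% (LSC), 28.6% (SSC) and 42.3% (IR), junction
marker genes in the type I arrangement, and ordinary loci giving named
spacers (atpH-atpI, trnS-trnG, psaC-ndhE, ...). CDS content is random
stop-free codons at the surrounding GC (so the Ka/Ks screen sees valid
ORFs), giving an overall GC near 36%.

The family is produced by Jukes-Cantor substitution along a known 8-taxon
tree as a per-site Poisson process (so multiple hits follow the JC closed
form exactly), with rate multipliers by site class: coding 1.0, intergenic
2.6, two designated hotspot spacers 8.0, and the IRs scaled by 0.3. With
the default tree depth this yields mean pairwise diversity of roughly 0.04
in coding regions, 0.10 in spacers and 0.25 in the hotspot spacers —
matching the levels reported for aroid plastome families, where the two
designated hotspots comfortably clear the pi > 0.17 barcode rule and
background spacers comfortably miss it.

Three deliberate idealizations keep the ground truth exact:

* **Concerted IR evolution.** Substitutions drawn for IRb are mirrored into
  IRa, so the copies remain exact reverse complements in every tip — the
  synthetic analogue of gene-conversion homogenization. Diversity measured
  on IR genes still reflects the reduced IR rate.
* **No indels.** Tips remain positionally aligned to the ancestor, so
  region alignments can be stacked without an aligner
  (`family_region_alignments()`) and planted coordinates hold in every tip.
  Real data must come pre-aligned (external mode).
* **Substitution-free planted repeats.** Planted SSR/repeat loci and one
  flanking base on each side are excluded from substitution (slippage
  dynamics are out of scope), so repeat truth is exact in every tip; the
  flanks are additionally chosen non-extendable so each planted run is
  maximal at its recorded coordinates, and the four bases flanking the
  IR/SC junctions are constrained so the planted IR pair is the unique
  maximal reverse-complement match.

What the generator does **not** emulate: natural SSR density (a real
plastome carries ~150 microsatellites; the default plan plants 15, enough
to exercise every counting rule but far sparser than nature), indel and
rearrangement evolution, codon-level selection (the simulator is neutral
within codons, so NG86 omegas scatter around 1 rather than showing the
strong purifying signal of real plastid genes), and rate heterogeneity
beyond the fixed site classes. Passing tests therefore demonstrate correct
computation, not robustness to alignment error or annotation noise.

Junction edits transform the canonical type I ancestor:
`typeII` expands both IRs into the SSC — the prefix up to mid-ndhF and the
suffix from just past rps15 are captured, duplicating ycf1 fully into the
IRs while keeping IRa = revcomp(IRb) exactly; `typeIII` contracts the IRs
by deleting the IRa terminus carrying trnN, leaving a single trnN copy at
the SSC edge; `typeIV` reverse-complements the SSC (an involution, which
the boundary-contrast constraint is invariant under). Truth tables are
remapped through the same piece map that builds the edited sequence, so
duplicated loci acquire truth entries for both copies.

`synth_size_panel()` emulates between-species size variation: most size
change is an IR boundary shift into or out of the SSC (drawn uniformly from
-900 to +500 bp, each bp gained by the IRs being lost by the SSC), plus
small independent LSC (sd 300 bp) and SSC (sd 80 bp) perturbations. This
mechanism reproduces the strong negative SSC~IR coupling seen across
plastome families against nearly independent LSC variation; the variance
split was fixed once from that qualitative pattern.

## Repeat scanning

`find_ssrs()` reports all maximal perfect tandem runs of primitive units of
length 1-6 at the MISA-style thresholds 10/5/4/3/3/3 copies. A run is
reported once, under its shortest primitive unit (Fine-Wilf guarantees a
span with two qualifying periods reduces to a common divisor period), at
its leftmost phase, labeled by the lexicographically smallest rotation of
the unit. N never matches. Compound SSRs are *not* merged — each simple
run counts separately, matching plain MISA totals; the alternative is a
single switch away in downstream counting if a different convention is
needed.

`find_tandem_repeats()` is a deliberately simplified tandem-array finder:
candidate periods come from self-matches at each lag (7-120 bp), runs
merged across short mismatch gaps when the continuation pays for the gap
under the +2/-7 weights, and each candidate is scored ungapped against its
per-phase majority consensus (+2 per agreeing base, -7 per disagreeing
base; arrays scoring >= 50 with unit >= 7 bp reported; overlaps reduced to
the best-scoring representative, ties to the shorter unit). There is no
indel alignment and no probabilistic period refinement.

`find_pair_repeats()` seeds exact 20-mers of the sequence against itself
(dispersed) or its reverse complement (palindromic), chains seeds per
(anti)diagonal, and extends ungapped across isolated mismatches, stopping
at two consecutive mismatches or when the running identity would fall below
0.90; trailing mismatches are trimmed. Hits >= 30 bp are reported with the
trivial self-diagonal excluded, symmetric duplicates collapsed and
overlapping hits merged to the longest representative. On a plastome the
largest palindromic hit is the IR pair itself, as in published repeat
tables.

## Nucleotide diversity

`nucleotide_diversity()` computes Nei's pi: columns containing any gap or N
are removed first (complete deletion, the default of the standard desktop
tool for this analysis; pairwise deletion is available behind a flag), then
pi is the mean over all sequence pairs of the per-site difference
proportion. An alignment with no clean columns is an error, not pi = 0.
Spacer regions are named "A-B" in canonical genome order; "trnN-trnF" is
accepted as an alias of "trnN-ndhF", a spelling variation seen in the
literature.

The internal aligner (`align_region(mode = "internal")`) is a center-star
progressive Needleman-Wunsch (match 1, mismatch -1, gap -2; guide order by
shared 3-mer counts) intended for short regions and tests; family-scale
real data should be aligned externally and ingested.

## Trees, bootstrap and discrimination

Distances are p, JC69 or K2P with pairwise deletion; saturation (log-domain
violations) is an error naming the pair. `neighbor_joining()` is the
standard Saitou-Nei agglomeration with two determinism rules: Q ties break
to the smallest (i, j) index pair, and negative branch lengths clamp to 0
with a warning. `bootstrap_support()` resamples alignment columns with
replacement (replicate r draws from a stream at offset r of the user seed,
so runs are reproducible and order-independent); support of each internal
split of the point-estimate tree is the percentage of successful replicates
containing it, with saturated replicates skipped and counted. Since
resampling only reweights columns, replicate distances are computed from
per-pair sparse site classes (differing transition/transversion/excluded
columns), which makes 200 replicates on a 30 kb concatenation take seconds.

The discrimination success ratio of a candidate barcode is defined here as
100 x (non-trivial reference-tree splits recovered by the barcode's NJ
tree) / (non-trivial reference-tree splits), with the reference tree built
from the concatenated protein-coding alignment. The underlying published
metric is not given as a formula; this reading reproduces its two anchor
properties — the reference alignment scores 100% against itself, and
combined markers reach 100% where single markers fall short. "Supported
edges" counts internal edges of the point-estimate tree with bootstrap
support strictly above 75.

Barcode selection follows the published rule exactly: pi strictly greater
than 0.17 *and* at least 3 SSRs in at least one focal taxon (the focal set
defaults to all taxa). The strict inequality is asserted at the boundary in
the tests.

## Ka/Ks screen

`ng86_kaks()` implements the Nei-Gojobori (1986) method under the plastid
(bacterial, table 11) genetic code: per-codon fractional synonymous site
counts averaged over the two sequences; difference counts averaged with
equal weight over all orderings of the differing positions. Two conventions
the method itself leaves open are fixed as: mutations creating a stop codon
count as nonsynonymous in site counting, and pathways passing through an
intermediate stop are excluded (with a fallback to all pathways if every
ordering is blocked). Proportions are corrected by d = -3/4 ln(1 - 4p/3);
p >= 3/4 is a saturation error. Codons containing a gap or N in either
sequence are excluded pairwise; an internal stop is a validation error
unless the caller opts into masking (the screen over simulated families
does, since neutral simulation can create stops). omega = ka/ks is
undefined (NA) exactly when ks = 0. The published site-model analysis
(M1a/M2a/M7/M8 likelihood ratio tests and Bayes-empirical-Bayes site
posteriors) is intentionally out of scope; this screen is the desk-scale
pairwise analogue.

## Problem sizes used by the checks

The bundled analysis scripts and the acceptance script run the full-size
default family (165,906 bp, 8 taxa) once for the structural, repeat,
diversity, selection and barcode tables, a 17-genome size panel for the
correlation analysis, and replicated loops (20 families for structure
recovery and hotspot selection, 50 for the coding/noncoding contrast and
the combined-vs-single comparison, at a compact ~32 kb geometry with the
same layout and marker genes) for the rate-style summaries. The compact
geometry keeps replicated runs fast; every property it checks also holds,
more strongly, at full size, since all the statistics concerned gain
precision with sequence length.

## Known limitations

* The IR detector assumes near-identical, indel-free IR copies; highly
  diverged or rearranged IRs are reported as structure-not-found rather
  than guessed at.
* The tandem finder's counts are not comparable to Tandem Repeats Finder
  output (no indel model, no period refinement); dispersed/palindromic
  counts likewise index a simplified detector, not Vmatch.
* The junction classifier is driven entirely by annotation; missing or
  renamed marker genes yield `unclassified`, never a guess.
* NJ + bootstrap is the only in-package tree engine; maximum-likelihood and
  Bayesian inference are out of scope, so published support values from
  those methods are not reproduced, only the discrimination *structure* of
  the marker tables.
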