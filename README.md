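# plastokit

Comparative structural and diversity analysis of complete chloroplast
genomes (plastomes), built as a reusable R package plus a numbered analysis
workflow.

Plant chloroplast genomes are circular molecules of ~150–170 kb with a
conserved quadripartite layout: a large and a small single-copy region
(LSC, SSC) separated by two inverted repeats (IRa, IRb). Their
expansion/contraction drives genome-size change, and a handful of fast
evolving intergenic spacers make good DNA barcodes for telling closely
related species apart. plastokit implements the analyses such a comparative
study runs:

* **Quadripartite structure** — IR detection by seeded reverse-complement
  matching with exact extension, LSC/IRb/SSC/IRa partitioning, per-junction
  gene profiles, and a rule-based classifier of the four boundary types
  (I–IV) defined by the genes at the IRb/SSC and SSC/IRa junctions
  (trnN, ndhF, ycf1, rps15, trnR).
* **Region-size correlations** — Pearson r / R² / p (t distribution,
  df = n − 2) across genome, LSC, SSC and IR sizes.
* **Repeats** — a MISA-style perfect microsatellite scanner (thresholds
  10/5/4/3/3/3 copies for mono- to hexanucleotide units), a simplified
  tandem-array finder (unit ≥ 7 bp, match/mismatch +2/−7, score ≥ 50), and
  dispersed/palindromic repeat pairs (≥ 30 bp at ≥ 90% identity), with
  summaries by motif class, region and genic context.
* **Nucleotide diversity** — Nei's π per shared coding region and
  intergenic spacer, complete gap/N deletion, class summaries and hotspot
  ranking.
* **DNA barcodes** — highly variable region selection (π > 0.17 and ≥ 3
  SSRs in at least one taxon), marker combination, and discrimination
  scoring of each candidate against the reference tree from the
  concatenated protein-coding alignment (NJ + seeded bootstrap; the
  discrimination success ratio is the percentage of reference-tree splits
  the barcode tree recovers).
* **Selection screen** — pairwise Ka/Ks by Nei–Gojobori (1986) under the
  plastid genetic code, with mean pairwise ω per gene.
* **Synthetic plastome families** — a generator with full ground truth
  (structure, junction type, planted repeats, rate hotspots, true tree)
  so every stage has an exact recovery test without downloads, plus a
  size-varied genome panel emulating IR-driven size variation.

GenBank flatfiles and FASTA are read directly (`read_genbank()`,
`read_fasta()`); `fetch_genbank()` downloads accessions when a network is
available.

## Worked example

The analysis workflow is a sequence of thin drivers over the package:

```sh
Rscript analysis/01_simulate_family.R
Rscript analysis/02_structure.R
Rscript analysis/03_repeats.R
Rscript analysis/04_diversity.R
Rscript analysis/05_selection.R
Rscript analysis/06_barcodes.R
```

Stage 1 simulates the default family — an aroid-like 165,906 bp ancestor
(LSC 91,710 / IRs 25,601 / SSC 22,994 bp) with two planted hotspot spacers,
evolved into 8 taxa along a known tree — and the later stages analyze it
blind to the truth, printing:

```
partition recovery vs truth (8 tips): 8/8 exact
junction types: I
size correlations (17 genomes): SSC~IR r = -0.981 (R2 = 0.962, p = 4.41e-12)
SSRs per genome: 18-23; planted-SSR recovery 100%
motif classes (mono..hexa): 50/31/11/7/0/1 %
ancestor repeats: 1 tandem, 1 dispersed, 2 palindromic (largest palindrome = the 25604 bp IR pair)
68 regions (32 coding, 36 noncoding)
mean pi: coding 0.036, noncoding 0.091
top regions: atpH-atpI 0.256, trnS-trnG 0.252, trnL-ccsA 0.114
HVR candidates (pi > 0.17 and >= 3 SSRs): atpH-atpI, trnS-trnG
reference CDS tree vs true tree: RF = 0
marker table:
  atpH-atpI                       954 bp  var  62.8%  inf  29.4%  >75:  5  disc 100.0%
  atpH-atpI + trnS-trnG          1966 bp  var  63.3%  inf  27.6%  >75:  5  disc 100.0%
  CDS (reference)               27861 bp  var  12.0%  inf   3.5%  >75:  5  disc 100.0%
  trnS-trnG                      1012 bp  var  63.8%  inf  26.0%  >75:  5  disc 100.0%
```

Reading this: the structure stage recovered every planted region boundary
to the base and classified all tips as boundary type I; the diversity stage
found intergenic spacers ~2.5× more diverse than coding regions with the
two planted hotspots on top (π ≈ 0.26 ≫ 0.17); the barcode stage selected
exactly those two spacers as candidates, and both (alone and combined)
recover 100% of the reference tree's splits, which itself matches the true
simulation tree (RF = 0). Tables land under `results/`
(`partitions.tsv`, `junctions.tsv`, `ssrs.tsv`, `pi.tsv`, `kaks.tsv`,
`barcode_table.tsv`, ...).

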