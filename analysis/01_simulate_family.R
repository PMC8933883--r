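#!/usr/bin/env Rscript
# Stage 1: simulate the study system.
#
# Generates the default synthetic plastome family: an Aroideae-like
# quadripartite ancestor (LSC 91,710 / IRs 25,601 / SSC 22,994 bp, per-region
# GC 33.8/42.3/28.6%), junction marker genes in the type I arrangement, two
# planted hotspot spacers (atpH-atpI, trnS-trnG) carrying SSRs, planted
# tandem/dispersed/palindromic repeats, and eight taxa evolved along a known
# tree under Jukes-Cantor with region-specific rates. Everything downstream
# reads these files.

suppressPackageStartupMessages(library(plastokit))

seed <- 1L
outdir <- "results/family"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- synth_config(seed = seed)
fam <- synth_family(cfg)

write_fasta(fam$tips, file.path(outdir, "tips.fasta"))
write_fasta(fam$ancestor, file.path(outdir, "ancestor.fasta"))
write_annotation_table(fam$ancestor, file.path(outdir, "annotation.gff3"))
writeLines(fam$truth$tree, file.path(outdir, "true_tree.nwk"))

part <- fam$truth$partition
write.table(
  data.frame(region = c("LSC", "IRb", "SSC", "IRa"),
             start = c(part$lsc[["start"]], part$irb[["start"]],
                       part$ssc[["start"]], part$ira[["start"]]),
             end = c(part$lsc[["end"]], part$irb[["end"]],
                     part$ssc[["end"]], part$ira[["end"]])),
  file.path(outdir, "truth_partition.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
write.table(fam$truth$ssrs, file.path(outdir, "truth_ssrs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(fam$truth$repeats, file.path(outdir, "truth_repeats.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("simulated ", length(fam$tips), " taxa of ",
        nchar(fam$ancestor$seq), " bp (seed ", seed, ")")
message("planted: ", nrow(fam$truth$ssrs), " SSR loci, ",
        nrow(fam$truth$repeats), " repeat loci, junction type ",
        fam$truth$junction_type)
message("wrote ", outdir, "/")
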