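#!/usr/bin/env Rscript
# Stage 4: nucleotide diversity.
#
# Extracts every shared coding region and intergenic spacer across the
# family, stacks them into per-region alignments (the simulator is
# indel-free, so tips are positionally aligned) and computes Nei's pi with
# complete gap/N deletion, then summarizes by class and ranks the hotspots.

suppressPackageStartupMessages(library(plastokit))

famdir <- "results/family"
if (!file.exists(file.path(famdir, "tips.fasta")))
  stop("run analysis/01_simulate_family.R first")
tips <- read_fasta(file.path(famdir, "tips.fasta"))
genes <- read_annotation_table(file.path(famdir, "annotation.gff3"))
tips <- lapply(tips, function(p) { p$genes <- genes; p })

alns <- family_region_alignments(tips)
recs <- do.call(rbind, lapply(alns, nucleotide_diversity))
sm <- diversity_summary(recs)

write.table(sm$ranked, "results/pi.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(sm$class_means, "results/pi_class_means.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cm <- sm$class_means
message(nrow(recs), " regions (", sum(recs$class == "coding"), " coding, ",
        sum(recs$class == "noncoding"), " noncoding)")
message("mean pi: coding ", round(cm$mean_pi[cm$class == "coding"], 3),
        ", noncoding ", round(cm$mean_pi[cm$class == "noncoding"], 3))
message("top regions: ",
        paste(head(sm$ranked$name, 3), round(head(sm$ranked$pi, 3), 3),
              collapse = ", "))
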