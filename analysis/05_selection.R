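#!/usr/bin/env Rscript
# Stage 5: selective-pressure screen.
#
# Pairwise NG86 Ka/Ks over every shared protein-coding gene (plastid
# genetic code, table 11), averaged across taxon pairs; genes with mean
# omega > 1 are flagged. The simulator is selectively neutral within
# codons, so omegas are expected to scatter around 1 here; on real
# families purifying selection pushes most genes well below 1.

suppressPackageStartupMessages(library(plastokit))

famdir <- "results/family"
if (!file.exists(file.path(famdir, "tips.fasta")))
  stop("run analysis/01_simulate_family.R first")
tips <- read_fasta(file.path(famdir, "tips.fasta"))
genes <- read_annotation_table(file.path(famdir, "annotation.gff3"))
tips <- lapply(tips, function(p) { p$genes <- genes; p })

regs <- extract_shared_regions(tips)
cds_names <- unique(genes$name[genes$kind == "CDS"])
cds <- lapply(regs[names(regs) %in% cds_names], `[[`, "seqs")

scr <- gene_selection_screen(cds)
scr <- scr[order(-scr$mean_omega), ]
write.table(scr, "results/kaks.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(nrow(scr), " genes screened; mean omega ",
        round(mean(scr$mean_omega, na.rm = TRUE), 3), "; ",
        sum(scr$flagged, na.rm = TRUE), " flagged with mean omega > 1")
message("highest: ", scr$gene[[1]], " (",
        round(scr$mean_omega[[1]], 3), ")")
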