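#!/usr/bin/env Rscript
# Stage 3: repeat landscape.
#
# MISA-style SSR scan of every tip (thresholds 10/5/4/3/3/3 for mono- to
# hexanucleotide units), per-genome summaries by motif class / region /
# context, and tandem + dispersed + palindromic repeat detection on the
# ancestor (30 bp minimum, 90% identity for pairs; unit >= 7 bp, match 2 /
# mismatch 7, score >= 50 for tandems).

suppressPackageStartupMessages(library(plastokit))

famdir <- "results/family"
if (!file.exists(file.path(famdir, "tips.fasta")))
  stop("run analysis/01_simulate_family.R first")
tips <- read_fasta(file.path(famdir, "tips.fasta"))
anc <- read_fasta(file.path(famdir, "ancestor.fasta"))[[1]]
genes <- read_annotation_table(file.path(famdir, "annotation.gff3"))
truth <- read.delim(file.path(famdir, "truth_partition.tsv"))
part <- new_partition(max(truth$end),
                      lsc = c(start = truth$start[[1]], end = truth$end[[1]]),
                      irb = c(start = truth$start[[2]], end = truth$end[[2]]),
                      ssc = c(start = truth$start[[3]], end = truth$end[[3]]),
                      ira = c(start = truth$start[[4]], end = truth$end[[4]]))
truth_ssrs <- read.delim(file.path(famdir, "truth_ssrs.tsv"))

all_ssrs <- list(); per_locus <- list()
for (p in tips) {
  ssrs <- find_ssrs(p$seq)
  sm <- ssr_region_summary(ssrs, part, genes)
  ssrs <- sm$ssrs; ssrs$taxon <- p$id
  all_ssrs[[p$id]] <- ssrs
  pl <- sm$per_locus; pl$taxon <- p$id
  per_locus[[p$id]] <- pl
}
ssr_tab <- do.call(rbind, all_ssrs)
write.table(ssr_tab, "results/ssrs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(do.call(rbind, per_locus), "results/ssr_per_locus.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

tkey <- paste(truth_ssrs$start, truth_ssrs$end)
rec <- vapply(split(ssr_tab, ssr_tab$taxon), function(df)
  mean(tkey %in% paste(df$start, df$end)), 0)
message("SSRs per genome: ", paste(range(table(ssr_tab$taxon)), collapse = "-"),
        "; planted-SSR recovery ", round(100 * mean(rec), 1), "%")
cls <- table(factor(ssr_tab$class, levels = 1:6))
message("motif classes (mono..hexa): ",
        paste(round(100 * cls / sum(cls)), collapse = "/"), " %")

tand <- find_tandem_repeats(anc$seq)
disp <- find_pair_repeats(anc$seq, "dispersed")
pal <- find_pair_repeats(anc$seq, "palindromic")
write.table(tand, "results/tandem_repeats.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(rbind(disp, pal), "results/pair_repeats.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("ancestor repeats: ", nrow(tand), " tandem, ", nrow(disp),
        " dispersed, ", nrow(pal), " palindromic (largest palindrome = the ",
        max(pal$length), " bp IR pair)")
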