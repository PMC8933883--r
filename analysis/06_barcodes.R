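#!/usr/bin/env Rscript
# Stage 6: DNA-barcode development.
#
# Selects highly variable regions (pi > 0.17 with >= 3 SSRs in at least one
# taxon), evaluates each candidate and their combinations against the
# reference tree built from the concatenated protein-coding alignment
# (NJ + 200 bootstrap replicates, K2P distances), and writes the ranked
# marker table: alignment length, variable/informative sites, edges with
# bootstrap support > 75, and the discrimination success ratio (% of
# reference-tree splits recovered).

suppressPackageStartupMessages(library(plastokit))

famdir <- "results/family"
if (!file.exists(file.path(famdir, "tips.fasta")))
  stop("run analysis/01_simulate_family.R first")
tips <- read_fasta(file.path(famdir, "tips.fasta"))
genes <- read_annotation_table(file.path(famdir, "annotation.gff3"))
tips <- lapply(tips, function(p) { p$genes <- genes; p })
truth <- read.delim(file.path(famdir, "truth_partition.tsv"))
part <- new_partition(max(truth$end),
                      lsc = c(start = truth$start[[1]], end = truth$end[[1]]),
                      irb = c(start = truth$start[[2]], end = truth$end[[2]]),
                      ssc = c(start = truth$start[[3]], end = truth$end[[3]]),
                      ira = c(start = truth$start[[4]], end = truth$end[[4]]))

alns <- family_region_alignments(tips)
recs <- do.call(rbind, lapply(alns, nucleotide_diversity))
cnts <- do.call(rbind, lapply(tips, function(tp) {
  ssr_region_summary(find_ssrs(tp$seq), part, genes)$per_locus
}))

sel <- select_hvrs(recs, cnts, pi_threshold = 0.17, min_ssr = 3L)
write.table(sel, "results/hvr_selection.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
hvrs <- sel$name[sel$selected]
message("HVR candidates (pi > 0.17 and >= 3 SSRs): ",
        paste(hvrs, collapse = ", "))

## reference tree from the concatenated protein-coding alignment
cds_names <- unique(genes$name[genes$kind == "CDS"])
cod <- alns[names(alns) %in% cds_names]
ref_aln <- combine_markers(unname(cod), name = "CDS")
ref_tree <- neighbor_joining(distance_matrix(ref_aln, "K2P"))
write_newick(ref_tree, "results/reference_tree.nwk")
true_tree <- read_newick(file.path(famdir, "true_tree.nwk"))
message("reference CDS tree vs true tree: RF = ",
        shared_split_fraction(ref_tree, true_tree)$rf)

evals <- list()
for (h in hvrs)
  evals[[h]] <- evaluate_barcode(alns[[h]], ref_tree, n_boot = 200, seed = 1)
if (length(hvrs) >= 2) {
  for (i in seq_len(length(hvrs) - 1L)) for (j in (i + 1L):length(hvrs)) {
    cmb <- combine_markers(alns[c(hvrs[[i]], hvrs[[j]])])
    evals[[cmb$name]] <- evaluate_barcode(cmb, ref_tree, n_boot = 200, seed = 1)
  }
}
evals[["CDS (reference)"]] <- evaluate_barcode(ref_aln, ref_tree,
                                               n_boot = 200, seed = 1)
tab <- marker_ranking_table(evals)
tab$marker[tab$marker == "CDS"] <- "CDS (reference)"
write.table(tab, "results/barcode_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("marker table:")
for (i in seq_len(nrow(tab)))
  message(sprintf("  %-28s %6d bp  var %5.1f%%  inf %5.1f%%  >75: %2d  disc %5.1f%%",
                  tab$marker[[i]], tab$aln_length[[i]], tab$variable_pct[[i]],
                  tab$informative_pct[[i]], tab$n_supported[[i]],
                  tab$discrimination[[i]]))
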