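## Candidate DNA-barcode selection (highly variable regions), marker
## combination, and tree-based discrimination scoring.

## region-name aliases seen in the literature for the same spacer
norm_region_name <- function(x) {
  x[x == "trnN-trnF"] <- "trnN-ndhF"
  x
}

#' Select highly variable regions (barcode candidates)
#'
#' A region is selected iff its nucleotide diversity is strictly greater
#' than \code{pi_threshold} and it carries at least \code{min_ssr} SSRs in
#' at least one focal taxon.
#'
#' @param diversity_records data.frame with columns name and pi
#'   (from [nucleotide_diversity()] rows).
#' @param ssr_counts data.frame with columns locus and n_ssr; one row per
#'   (taxon, locus) or per locus. The per-locus maximum across rows is used.
#' @param pi_threshold strict lower bound on pi.
#' @param min_ssr minimum SSR count.
#' @return data.frame name/pi/ssr_count_max/selected/selected_by.
#' @export
select_hvrs <- function(diversity_records, ssr_counts,
                        pi_threshold = 0.17, min_ssr = 3L) {
  dn <- norm_region_name(diversity_records$name)
  sn <- norm_region_name(ssr_counts$locus)
  if (!any(dn %in% sn)) {
    orphans <- utils::head(unique(dn), 20L)
    stop("reconciliation error: no shared region names between the ",
         "diversity and SSR tables; diversity names include ",
         paste(orphans, collapse = ", "))
  }
  ssr_max <- tapply(ssr_counts$n_ssr, sn, max)
  cnt <- as.integer(ssr_max[dn])
  cnt[is.na(cnt)] <- 0L
  sel_pi <- diversity_records$pi > pi_threshold
  sel_ssr <- cnt >= min_ssr
  trace <- paste0("pi=", signif(diversity_records$pi, 4),
                  ifelse(sel_pi, " > ", " <= "), pi_threshold,
                  "; max SSRs=", cnt, ifelse(sel_ssr, " >= ", " < "), min_ssr)
  out <- data.frame(name = diversity_records$name,
                    pi = diversity_records$pi,
                    ssr_count_max = cnt,
                    selected = sel_pi & sel_ssr,
                    selected_by = trace, stringsAsFactors = FALSE)
  out[order(-out$pi), ]
}

#' Alignment length, variable sites and parsimony-informative sites
#'
#' Variable: columns with at least two distinct non-gap, non-N states.
#' Parsimony-informative: columns with at least two states each present in
#' at least two taxa (gaps/N are not states).
#'
#' @param aln [region_alignment()].
#' @return one-row data.frame length/variable_sites/variable_pct/
#'   informative_sites/informative_pct.
#' @export
alignment_stats <- function(aln) {
  mi <- aln_int_matrix(aln)
  L <- ncol(mi)
  cnt <- vapply(1:4, function(b) colSums(mi == b), numeric(L))  # L x 4
  if (L == 1L) cnt <- matrix(cnt, nrow = 1L)
  n_states <- rowSums(cnt > 0L)
  n_dup_states <- rowSums(cnt >= 2L)
  var_s <- sum(n_states >= 2L)
  inf_s <- sum(n_states >= 2L & n_dup_states >= 2L)
  data.frame(length = L, variable_sites = var_s,
             variable_pct = 100 * var_s / L,
             informative_sites = inf_s,
             informative_pct = 100 * inf_s / L)
}

#' Concatenate marker alignments into a combined barcode
#'
#' Column-wise concatenation in the given order, restricted to the common
#' taxon set (dropped taxa are reported in a warning and recorded in the
#' \code{dropped} attribute); partition boundaries are recorded in the
#' \code{boundaries} attribute.
#'
#' @param alignments list of [region_alignment()].
#' @param name label for the combination; defaults to the part names joined
#'   by " + ".
#' @return [region_alignment()] whose length is the sum of the parts.
#' @export
combine_markers <- function(alignments, name = NULL) {
  stopifnot(length(alignments) >= 1L)
  taxa <- Reduce(intersect, lapply(alignments, function(a) names(a$seqs)))
  if (length(taxa) < 2L) stop("empty taxon intersection across markers")
  all_taxa <- unique(unlist(lapply(alignments, function(a) names(a$seqs))))
  dropped <- setdiff(all_taxa, taxa)
  if (length(dropped))
    warning("dropped taxa absent from some markers: ",
            paste(dropped, collapse = ", "))
  parts <- lapply(alignments, function(a) a$seqs[taxa])
  seqs <- setNames(do.call(paste0, parts), taxa)
  nm <- name %||% paste(vapply(alignments, `[[`, "", "name"), collapse = " + ")
  out <- region_alignment(nm, "combined", seqs)
  attr(out, "boundaries") <- cumsum(vapply(alignments, function(a)
    nchar(a$seqs[[1]]), 0))
  attr(out, "dropped") <- dropped
  out
}

#' Evaluate a candidate barcode against a reference tree
#'
#' Builds the NJ + bootstrap tree of the barcode alignment, counts internal
#' edges with support strictly above \code{support_threshold}, and scores
#' discrimination success as 100 x the fraction of the reference tree's
#' non-trivial splits recovered by the barcode tree.
#'
#' @param aln [region_alignment()]; taxa must be a subset of the reference
#'   tree's tips.
#' @param ref_tree \code{ape::phylo} reference (e.g. the tree from the
#'   concatenated protein-coding alignment).
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @param support_threshold strict support cutoff (percent).
#' @param model distance model.
#' @return one-row data.frame marker/aln_length/variable_sites/variable_pct/
#'   informative_sites/informative_pct/n_supported/discrimination.
#' @export
evaluate_barcode <- function(aln, ref_tree, n_boot = 100, seed = 1,
                             support_threshold = 75, model = "K2P") {
  if (!all(names(aln$seqs) %in% ref_tree$tip.label))
    stop("barcode taxa missing from the reference tree: ",
         paste(setdiff(names(aln$seqs), ref_tree$tip.label), collapse = ", "))
  st <- alignment_stats(aln)
  bs <- bootstrap_support(aln, n_reps = n_boot, seed = seed, model = model)
  ssf <- shared_split_fraction(bs$tree, ref_tree)
  data.frame(marker = aln$name,
             aln_length = st$length,
             variable_sites = st$variable_sites,
             variable_pct = st$variable_pct,
             informative_sites = st$informative_sites,
             informative_pct = st$informative_pct,
             n_supported = sum(bs$support > support_threshold),
             discrimination = 100 * ssf$fraction,
             stringsAsFactors = FALSE)
}

#' Rank barcode evaluations
#'
#' Rows sorted by discrimination (descending), ties broken by the number of
#' supported edges (descending).
#'
#' @param evaluations data.frame of [evaluate_barcode()] rows (or list).
#' @return sorted data.frame.
#' @export
marker_ranking_table <- function(evaluations) {
  tab <- if (is.data.frame(evaluations)) evaluations
         else do.call(rbind, evaluations)
  if (!nrow(tab)) stop("no evaluations")
  tab <- tab[order(-tab$discrimination, -tab$n_supported, tab$marker), ]
  rownames(tab) <- NULL
  tab
}
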