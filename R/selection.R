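## Pairwise Nei-Gojobori (NG86) Ka/Ks with the plastid (bacterial) genetic
## code: fractional synonymous site counting, equal-weight averaging over
## all minimal substitution pathways per codon, Jukes-Cantor correction.

codon_split <- function(s) {
  n <- nchar(s)
  if (n %% 3L != 0L) stop("frame violation: length ", n, " not divisible by 3")
  substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
}

## fractional synonymous potential per codon position; mutations creating a
## stop codon count as nonsynonymous
codon_syn_sites <- function(codon, gc) {
  aa <- gc[[codon]]
  s <- 0
  for (k in 1:3) {
    base <- substr(codon, k, k)
    for (b in setdiff(DNA_BASES, base)) {
      alt <- codon
      substr(alt, k, k) <- b
      if (gc[[alt]] != "*" && gc[[alt]] == aa) s <- s + 1 / 3
    }
  }
  s
}

## average syn/nonsyn difference counts over all orderings of the differing
## positions; pathways through intermediate stop codons are excluded (all
## blocked: fall back to every pathway)
codon_path_diffs <- function(ca, cb, gc) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  t <- length(pos)
  if (t == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (t == 1L) list(pos)
           else if (t == 2L) list(pos, rev(pos))
           else list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
                     pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)])
  walk <- function(perm) {
    cur <- ca; syn <- 0; nonsyn <- 0
    for (k in perm) {
      nxt <- cur
      substr(nxt, k, k) <- substr(cb, k, k)
      if (gc[[nxt]] == "*") return(NULL)    # intermediate stop: blocked
      if (gc[[nxt]] == gc[[cur]]) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk))
  if (!length(res)) {
    res <- lapply(perms, function(perm) {
      cur <- ca; syn <- 0; nonsyn <- 0
      for (k in perm) {
        nxt <- cur
        substr(nxt, k, k) <- substr(cb, k, k)
        if (gc[[nxt]] != "*" && gc[[nxt]] == gc[[cur]]) syn <- syn + 1
        else nonsyn <- nonsyn + 1
        cur <- nxt
      }
      c(syn = syn, nonsyn = nonsyn)
    })
  }
  colMeans(do.call(rbind, res))
}

jc_correct <- function(p) {
  if (p >= 0.75) stop("saturation error: difference proportion ", round(p, 4),
                      " >= 3/4")
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise Ka/Ks by the Nei-Gojobori (1986) method
#'
#' Site counts use the fractional synonymous potential of each codon
#' position averaged over the two sequences; differences are counted with
#' equal-weight averaging over all minimal substitution pathways per codon
#' (pathways through intermediate stops excluded); proportions are
#' Jukes-Cantor corrected, d = -3/4 ln(1 - 4p/3). Codons containing a gap
#' or N in either sequence are excluded pairwise; a trailing stop codon is
#' dropped.
#'
#' @param cds_a,cds_b in-frame aligned CDS strings of equal length.
#' @param genetic_code NCBI code id; 11 (bacterial/plastid) by default.
#' @param mask_stops if TRUE, codon pairs where either codon is a stop are
#'   excluded instead of raising a validation error (used by the screen on
#'   simulated families, where substitutions may create stops).
#' @param gene label carried into the output.
#' @param pair label of the sequence pair.
#' @return one-row data.frame gene/pair/ka/ks/omega/n_sites/s_sites/
#'   n_diffs/s_diffs/codons_used. \code{omega} is NA iff ks = 0.
#' @export
ng86_kaks <- function(cds_a, cds_b, genetic_code = "11", mask_stops = FALSE,
                      gene = NA_character_, pair = NA_character_) {
  if (nchar(cds_a) != nchar(cds_b))
    stop("aligned CDS lengths differ (", nchar(cds_a), " vs ", nchar(cds_b), ")")
  gc <- Biostrings::getGeneticCode(as.character(genetic_code))
  ca <- codon_split(toupper(cds_a))
  cb <- codon_split(toupper(cds_b))
  ncod <- length(ca)
  ## drop a trailing stop codon pair
  if (ncod > 0L && !grepl("[-N]", paste0(ca[[ncod]], cb[[ncod]])) &&
      (gc[[ca[[ncod]]]] == "*" || gc[[cb[[ncod]]]] == "*")) {
    ca <- ca[-ncod]; cb <- cb[-ncod]; ncod <- ncod - 1L
  }
  S <- 0; Sd <- 0; Nd <- 0; used <- 0L
  for (i in seq_len(ncod)) {
    if (grepl("[-N]", ca[[i]]) || grepl("[-N]", cb[[i]])) next
    stop_a <- gc[[ca[[i]]]] == "*"; stop_b <- gc[[cb[[i]]]] == "*"
    if (stop_a || stop_b) {
      if (mask_stops) next
      stop("validation error: internal stop codon at codon ", i)
    }
    used <- used + 1L
    S <- S + (codon_syn_sites(ca[[i]], gc) + codon_syn_sites(cb[[i]], gc)) / 2
    dd <- codon_path_diffs(ca[[i]], cb[[i]], gc)
    Sd <- Sd + dd[["syn"]]; Nd <- Nd + dd[["nonsyn"]]
  }
  if (used == 0L) stop("no comparable codons after masking")
  N <- 3 * used - S
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  ks <- jc_correct(ps)
  ka <- jc_correct(pn)
  data.frame(gene = gene, pair = pair, ka = ka, ks = ks,
             omega = if (ks > 0) ka / ks else NA_real_,
             n_sites = N, s_sites = S, n_diffs = Nd, s_diffs = Sd,
             codons_used = used, stringsAsFactors = FALSE)
}

#' Screen genes for elevated mean pairwise omega
#'
#' Runs [ng86_kaks()] over every sequence pair of each in-frame codon
#' alignment, averages the defined omegas, and flags genes with mean
#' omega > 1. Stop codons arising in simulated/diverged sequences are
#' masked pairwise. Genes whose omegas are all undefined (no synonymous
#' changes) are reported as NA.
#'
#' @param gene_alignments named list: gene -> named character vector of
#'   aligned in-frame CDS (or [region_alignment()]).
#' @param genetic_code NCBI code id.
#' @return data.frame gene/mean_omega/mean_ka/mean_ks/n_pairs/flagged.
#' @export
gene_selection_screen <- function(gene_alignments, genetic_code = "11") {
  rows <- lapply(names(gene_alignments), function(g) {
    seqs <- gene_alignments[[g]]
    if (inherits(seqs, "region_alignment")) seqs <- seqs$seqs
    if (nchar(seqs[[1]]) %% 3L != 0L)
      stop("frame violation in gene ", g)
    tx <- names(seqs)
    recs <- list()
    for (i in seq_along(tx)[-length(tx)]) for (j in (i + 1L):length(tx)) {
      recs[[length(recs) + 1L]] <-
        ng86_kaks(seqs[[i]], seqs[[j]], genetic_code = genetic_code,
                  mask_stops = TRUE, gene = g,
                  pair = paste0(tx[[i]], ":", tx[[j]]))
    }
    tab <- do.call(rbind, recs)
    om <- tab$omega[!is.na(tab$omega)]
    data.frame(gene = g,
               mean_omega = if (length(om)) mean(om) else NA_real_,
               mean_ka = mean(tab$ka), mean_ks = mean(tab$ks),
               n_pairs = nrow(tab),
               flagged = length(om) > 0 && mean(om) > 1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
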