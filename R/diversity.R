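## Region-wise nucleotide diversity: shared coding/intergenic region
## extraction, a small progressive aligner for toys (external alignments are
## ingested for real data), and Nei's pi with complete gap deletion.

#' Construct a region alignment
#'
#' @param name locus or spacer label (spacers use the "A-B" convention in
#'   canonical genome order).
#' @param class "coding" or "noncoding".
#' @param seqs named character vector of equal-length aligned rows (gap "-").
#' @return object of class \code{region_alignment}.
#' @export
region_alignment <- function(name, class, seqs) {
  if (length(seqs) < 2L) stop("alignment needs >= 2 taxa for '", name, "'")
  if (length(unique(nchar(seqs))) != 1L)
    stop("format error: rows of '", name, "' differ in length")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("rows must be named by taxon")
  structure(list(name = name, class = class, seqs = seqs),
            class = "region_alignment")
}

#' @export
print.region_alignment <- function(x, ...) {
  cat("<region_alignment> ", x$name, " (", x$class, "): ",
      length(x$seqs), " taxa x ", nchar(x$seqs[[1]]), " columns\n", sep = "")
  invisible(x)
}

## alignment as a character matrix, taxa in rows
aln_matrix <- function(aln) {
  seqs <- if (inherits(aln, "region_alignment")) aln$seqs else aln
  do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
}

#' Read / write aligned FASTA
#'
#' @param path FASTA file of equal-length rows.
#' @param name,class metadata for the resulting [region_alignment()].
#' @return a region_alignment.
#' @export
read_alignment <- function(path, name = basename(path), class = "noncoding") {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("format error: no records in ", path)
  seqs <- toupper(setNames(as.character(ss), sub("\\s.*$", "", names(ss))))
  region_alignment(name, class, seqs)
}

#' @rdname read_alignment
#' @param aln region_alignment to write.
#' @export
write_alignment <- function(aln, path) {
  ss <- Biostrings::BStringSet(aln$seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Extract shared coding regions and intergenic spacers from a family
#'
#' For every gene name annotated in at least two taxa, emits its
#' strand-normalized sequences; for every ordered adjacent gene pair (A, B)
#' shared by at least two taxa, emits the intergenic spacer "A-B"
#' (zero-length spacers skipped). Genes duplicated within a genome (IR
#' copies) contribute their first copy in genome order.
#'
#' @param plastomes list of annotated plastomes.
#' @return named list; each element has \code{class} ("coding"/"noncoding")
#'   and \code{seqs} (named character, one per taxon).
#' @export
extract_shared_regions <- function(plastomes) {
  for (p in plastomes)
    if (nrow(p$genes) == 0L)
      stop("plastome '", p$id, "' has no annotation")
  per_taxon <- lapply(plastomes, function(p) {
    g <- p$genes[order(p$genes$start), , drop = FALSE]
    gene_seqs <- list()
    for (i in seq_len(nrow(g))) {
      nm <- g$name[[i]]
      if (!is.null(gene_seqs[[nm]])) next        # first copy only
      s <- substr(p$seq, g$start[[i]] + 1L, g$end[[i]])
      if (g$strand[[i]] == "-") s <- seq_rc(s)
      gene_seqs[[nm]] <- s
    }
    spacer_seqs <- list()
    if (nrow(g) > 1L) {
      for (i in seq_len(nrow(g) - 1L)) {
        a <- g[i, ]; b <- g[i + 1L, ]
        if (b$start <= a$end) next               # overlapping/abutting genes
        lbl <- paste0(a$name, "-", b$name)
        if (!is.null(spacer_seqs[[lbl]])) next
        spacer_seqs[[lbl]] <- substr(p$seq, a$end + 1L, b$start)
      }
    }
    list(genes = gene_seqs, spacers = spacer_seqs)
  })
  names(per_taxon) <- vapply(plastomes, `[[`, "", "id")

  collect <- function(field, class) {
    all_names <- unique(unlist(lapply(per_taxon, function(t) names(t[[field]]))))
    out <- list()
    for (nm in all_names) {
      seqs <- unlist(lapply(names(per_taxon), function(tx) {
        s <- per_taxon[[tx]][[field]][[nm]]
        if (is.null(s)) NULL else setNames(s, tx)
      }))
      if (length(seqs) >= 2L)
        out[[nm]] <- list(class = class, seqs = seqs)
    }
    out
  }
  c(collect("genes", "coding"), collect("spacers", "noncoding"))
}

## Needleman-Wunsch global alignment (linear gap), deterministic tie-break:
## diagonal > up (gap in b) > left (gap in a)
nw_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  sc <- matrix(0, n + 1L, m + 1L)
  sc[1L, ] <- gap * (0:m)
  sc[, 1L] <- gap * (0:n)
  for (i in seq_len(n)) {
    sub <- ifelse(bv == av[[i]], match, mismatch)
    row_prev <- sc[i, ]
    row_cur <- numeric(m + 1L)
    row_cur[[1L]] <- gap * i
    for (j in seq_len(m)) {
      row_cur[[j + 1L]] <- max(row_prev[[j]] + sub[[j]],
                               row_prev[[j + 1L]] + gap,
                               row_cur[[j]] + gap)
    }
    sc[i + 1L, ] <- row_cur
  }
  ## traceback
  ra <- character(0); rb <- character(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        sc[i + 1L, j + 1L] == sc[i, j] + (if (av[[i]] == bv[[j]]) match else mismatch)) {
      ra <- c(av[[i]], ra); rb <- c(bv[[j]], rb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && sc[i + 1L, j + 1L] == sc[i, j + 1L] + gap) {
      ra <- c(av[[i]], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(bv[[j]], rb); j <- j - 1L
    }
  }
  list(a = paste(ra, collapse = ""), b = paste(rb, collapse = ""),
       score = sc[n + 1L, m + 1L])
}

kmer_profile <- function(s, k = 3L) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}

#' Align the sequences of one region
#'
#' \code{internal} mode runs a small progressive (center-star)
#' Needleman-Wunsch aligner with weights match 1 / mismatch -1 / gap -2,
#' guide order by pairwise 3-mer similarity — intended for short regions and
#' tests. \code{external} mode ingests rows that are already aligned (e.g.
#' by MAFFT) and only validates them. Degapping any output row reproduces
#' its input sequence.
#'
#' @param seqs named character vector (>= 2).
#' @param mode "internal" or "external".
#' @param name,class metadata for the result.
#' @return [region_alignment()].
#' @export
align_region <- function(seqs, mode = c("internal", "external"),
                         name = "region", class = "noncoding") {
  mode <- match.arg(mode)
  if (length(seqs) < 2L) stop("need >= 2 sequences")
  if (mode == "external") {
    if (length(unique(nchar(seqs))) != 1L)
      stop("format error: external alignment rows differ in length")
    return(region_alignment(name, class, toupper(seqs)))
  }
  seqs <- toupper(seqs)
  if (length(unique(seqs)) == 1L)
    return(region_alignment(name, class, seqs))
  ## guide order: center = sequence with highest total shared-3-mer count
  profs <- lapply(seqs, kmer_profile)
  sim <- matrix(0, length(seqs), length(seqs))
  for (i in seq_along(seqs)) for (j in seq_along(seqs)) if (i < j) {
    s <- length(intersect(profs[[i]], profs[[j]]))
    sim[i, j] <- s; sim[j, i] <- s
  }
  center <- which.max(rowSums(sim))
  order_rest <- setdiff(order(sim[center, ], decreasing = TRUE), center)

  master_center <- strsplit(seqs[[center]], "", fixed = TRUE)[[1]]
  rows <- list()
  rows[[names(seqs)[[center]]]] <- master_center
  for (idx in order_rest) {
    pw <- nw_align(paste(master_center[master_center != "-"], collapse = ""),
                   seqs[[idx]])
    ac <- strsplit(pw$a, "", fixed = TRUE)[[1]]
    as_ <- strsplit(pw$b, "", fixed = TRUE)[[1]]
    ## merge the new pairwise alignment into the master gap pattern
    new_master <- character(0)
    new_row <- character(0)
    grow <- matrix("", nrow = length(rows), ncol = 0)
    old_rows <- do.call(rbind, rows)
    i <- 1L; j <- 1L
    nm_old <- length(master_center); nm_new <- length(ac)
    cols_old <- integer(0); cols_gap_old <- integer(0)
    out_old <- list(); out_new_row <- character(0); out_center <- character(0)
    take_old <- function() {
      out_old[[length(out_old) + 1L]] <<- old_rows[, i]
      out_center <<- c(out_center, master_center[[i]])
    }
    while (i <= nm_old || j <= nm_new) {
      oc <- if (i <= nm_old) master_center[[i]] else NA
      nc <- if (j <= nm_new) ac[[j]] else NA
      if (!is.na(oc) && oc == "-" && (is.na(nc) || nc != "-")) {
        take_old(); out_new_row <- c(out_new_row, "-"); i <- i + 1L
      } else if (!is.na(nc) && nc == "-" && (is.na(oc) || oc != "-")) {
        out_old[[length(out_old) + 1L]] <- rep("-", nrow(old_rows))
        out_center <- c(out_center, "-")
        out_new_row <- c(out_new_row, as_[[j]]); j <- j + 1L
      } else {
        ## both consume (char/char or gap/gap)
        take_old(); out_new_row <- c(out_new_row, as_[[j]])
        i <- i + 1L; j <- j + 1L
      }
    }
    old_mat <- do.call(cbind, out_old)
    rows <- lapply(seq_len(nrow(old_mat)), function(r) old_mat[r, ])
    names(rows) <- rownames(old_rows)
    rows[[names(seqs)[[idx]]]] <- out_new_row
    master_center <- out_center
  }
  aligned <- vapply(rows, paste, "", collapse = "")
  region_alignment(name, class, aligned[names(seqs)])
}

#' Nucleotide diversity (Nei's pi) of a region alignment
#'
#' Columns containing any gap or N are removed (complete deletion, the
#' DnaSP default; set \code{pairwise_deletion = TRUE} for pairwise
#' deletion), then pi is the average over all sequence pairs of the
#' per-site difference proportion.
#'
#' @param aln [region_alignment()].
#' @param pairwise_deletion if TRUE, each pair uses its own gap/N-free
#'   columns.
#' @return one-row data.frame name/class/pi/n_taxa/n_sites_used.
#' @export
nucleotide_diversity <- function(aln, pairwise_deletion = FALSE) {
  m <- aln_matrix(aln)
  nt <- nrow(m)
  if (nt < 2L) stop("need >= 2 rows")
  bad <- m == "-" | m == "N"
  if (!pairwise_deletion) {
    keep <- colSums(bad) == 0L
    if (!any(keep))
      stop("no-sites error: every column of '", aln$name,
           "' contains a gap or N")
    m <- m[, keep, drop = FALSE]
    nsites <- ncol(m)
    tot <- 0
    for (i in seq_len(nt - 1L)) for (j in (i + 1L):nt)
      tot <- tot + mean(m[i, ] != m[j, ])
    pi <- tot / (nt * (nt - 1L) / 2L)
  } else {
    tot <- 0; used <- integer(0)
    for (i in seq_len(nt - 1L)) for (j in (i + 1L):nt) {
      ok <- !bad[i, ] & !bad[j, ]
      if (!any(ok))
        stop("no-sites error: pair ", i, "/", j, " of '", aln$name,
             "' shares no gap/N-free columns")
      tot <- tot + mean(m[i, ok] != m[j, ok])
      used <- c(used, sum(ok))
    }
    pi <- tot / (nt * (nt - 1L) / 2L)
    nsites <- min(used)
  }
  data.frame(name = aln$name, class = aln$class, pi = pi,
             n_taxa = nt, n_sites_used = nsites, stringsAsFactors = FALSE)
}

#' Per-class summary and ranking of diversity records
#'
#' @param records data.frame of [nucleotide_diversity()] rows.
#' @param top_k how many top regions to echo in the \code{top} element.
#' @return list with \code{class_means} (data.frame class/mean_pi/n),
#'   \code{ranked} (records sorted by pi, descending) and \code{top}.
#' @export
diversity_summary <- function(records, top_k = 10L) {
  if (!nrow(records)) stop("no diversity records")
  cm <- aggregate(pi ~ class, data = records, FUN = mean)
  names(cm) <- c("class", "mean_pi")
  cm$n <- as.integer(table(records$class)[cm$class])
  ranked <- records[order(-records$pi, records$name), ]
  rownames(ranked) <- NULL
  list(class_means = cm, ranked = ranked,
       top = head(ranked, top_k))
}

#' Build region alignments directly from a synthetic family
#'
#' The simulator is indel-free, so tips remain positionally aligned to the
#' ancestor and shared-region sequences can be stacked without running an
#' aligner. Real (indel-containing) data should go through external
#' alignments instead.
#'
#' @param tips named list of plastomes from [evolve_family()].
#' @return named list of [region_alignment()] objects.
#' @export
family_region_alignments <- function(tips) {
  regs <- extract_shared_regions(tips)
  out <- list()
  for (nm in names(regs)) {
    seqs <- regs[[nm]]$seqs
    if (length(unique(nchar(seqs))) != 1L) next
    out[[nm]] <- region_alignment(nm, regs[[nm]]$class, seqs)
  }
  out
}
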