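#' Read plastomes from a FASTA file
#'
#' One [plastome()] per record. Sequences are uppercased, U is mapped to T and
#' IUPAC ambiguity codes other than N are mapped to N with a warning giving
#' the count per record.
#'
#' @param path FASTA file (multi-record allowed).
#' @param circular logical, topology flag to set on every record.
#' @return list of plastome objects.
#' @export
read_fasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("format error: no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(ss))
  lapply(seq_along(ss), function(i) {
    plastome(ids[[i]], as.character(ss[[i]]), circular = circular)
  })
}

#' Write plastomes to a FASTA file
#'
#' @param plastomes a plastome or list of plastomes.
#' @param path output file; sequence lines wrapped at 70 columns.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(plastomes, path) {
  if (inherits(plastomes, "plastome")) plastomes <- list(plastomes)
  ss <- Biostrings::DNAStringSet(vapply(plastomes, `[[`, "", "seq"))
  names(ss) <- vapply(plastomes, `[[`, "", "id")
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

## ---- GenBank flatfile -------------------------------------------------

## parse a GenBank location string into sub-intervals (0-based half-open).
## join()/order() are split; complement() flips the strand of every part.
parse_gb_location <- function(loc) {
  loc <- gsub("\\s", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  out <- lapply(parts, function(p) {
    p2 <- p
    inner <- "+"
    if (grepl("^complement\\(", p2)) {
      inner <- "-"
      p2 <- sub("^complement\\((.*)\\)$", "\\1", p2)
    }
    p2 <- gsub("[<>]", "", p2)
    if (grepl("\\.\\.", p2)) {
      ab <- as.integer(strsplit(p2, "..", fixed = TRUE)[[1]])
    } else {
      ab <- c(as.integer(p2), as.integer(p2))
    }
    st <- if (strand == "-" || inner == "-") "-" else "+"
    c(start = ab[[1]] - 1L, end = ab[[2]], strand = st)
  })
  data.frame(start = vapply(out, function(x) as.integer(x[["start"]]), 0L),
             end = vapply(out, function(x) as.integer(x[["end"]]), 0L),
             strand = vapply(out, function(x) x[["strand"]], ""),
             stringsAsFactors = FALSE)
}

#' Read a GenBank flatfile
#'
#' Minimal parser for the fields this pipeline needs: the LOCUS line
#' (length, circular topology), gene/CDS/tRNA/rRNA features with their
#' locations and \code{/gene} qualifiers, and the ORIGIN sequence.
#' Coordinates are converted from GenBank's 1-based inclusive convention to
#' the internal 0-based half-open one; \code{join()} locations are split into
#' sub-intervals (one feature row per interval).
#'
#' @param path GenBank flatfile.
#' @return a [plastome()].
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  circular <- length(locus) > 0 && grepl("circular", locus[[1]], ignore.case = TRUE)
  acc <- if (length(locus)) strsplit(trimws(locus[[1]]), "\\s+")[[1]][2] else "unknown"

  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0L) stop("format error: missing ORIGIN in ", path)
  endrec <- grep("^//", lines)
  endrec <- if (length(endrec)) endrec[endrec > ori[[1]]][1] else length(lines) + 1L
  seqlines <- lines[(ori[[1]] + 1L):(endrec - 1L)]
  seq <- toupper(gsub("[^a-zA-Z]", "", paste(seqlines, collapse = "")))

  feat0 <- grep("^FEATURES", lines)
  genes <- gene_table()
  if (length(feat0)) {
    flines <- lines[(feat0[[1]] + 1L):(ori[[1]] - 1L)]
    ## a new feature starts with a key in columns 6-20; qualifiers start with /
    is_key <- grepl("^ {1,10}\\S", flines) & !grepl("^ *\\/", flines)
    idx <- cumsum(is_key)
    keep <- idx > 0
    recs <- split(flines[keep], idx[keep])
    rows <- list()
    for (r in recs) {
      m <- regmatches(r[[1]], regexec("^\\s*(\\S+)\\s+(\\S.*)$", r[[1]]))[[1]]
      if (length(m) < 3) next
      key <- m[[2]]
      if (!key %in% c("gene", "CDS", "tRNA", "rRNA")) next
      loc <- m[[3]]
      i <- 2L
      while (i <= length(r) && !grepl("^\\s*/", r[[i]])) {
        loc <- paste0(loc, trimws(r[[i]])); i <- i + 1L
      }
      quals <- paste(r[seq_along(r) >= i], collapse = " ")
      gname <- regmatches(quals, regexec("/gene=\"([^\"]+)\"", quals))[[1]]
      gname <- if (length(gname) >= 2) gname[[2]] else NA_character_
      iv <- parse_gb_location(loc)
      kind <- if (key == "gene") "gene" else key
      rows[[length(rows) + 1L]] <-
        data.frame(name = gname, start = iv$start, end = iv$end,
                   strand = iv$strand, kind = kind, stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      ft <- do.call(rbind, rows)
      ft <- ft[!is.na(ft$name), , drop = FALSE]
      ## prefer typed features (CDS/tRNA/rRNA); keep plain "gene" rows only
      ## for names with no typed feature
      typed <- ft[ft$kind != "gene", , drop = FALSE]
      plain <- ft[ft$kind == "gene" & !(ft$name %in% typed$name), , drop = FALSE]
      if (nrow(plain)) plain$kind <- "CDS"
      ft <- rbind(typed, plain)
      ft <- ft[order(ft$start, ft$end), , drop = FALSE]
      rownames(ft) <- NULL
      genes <- gene_table(ft$name, ft$start, ft$end, ft$strand, ft$kind)
    }
  }
  plastome(acc, seq, circular = circular, genes = genes)
}

#' Download a GenBank record from NCBI
#'
#' Fetches the flatfile (with sequence) for an accession via NCBI efetch.
#' Requires network access.
#'
#' @param accession e.g. \code{"MN972442"}.
#' @param dest destination file; defaults to a tempfile.
#' @param timeout seconds before giving up.
#' @return path to the downloaded flatfile.
#' @export
fetch_genbank <- function(accession, dest = tempfile(fileext = ".gb"),
                          timeout = 60) {
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=nuccore&id=", accession,
                "&rettype=gbwithparts&retmode=text")
  old <- options(timeout = timeout); on.exit(options(old))
  status <- tryCatch(download.file(url, dest, quiet = TRUE, mode = "wb"),
                     error = function(e) -1L, warning = function(w) -1L)
  if (!identical(status, 0L) || !file.exists(dest) || file.size(dest) < 100)
    stop("download failed for ", accession, " (no network access?)")
  dest
}

## ---- GFF3-like annotation tables --------------------------------------

#' Write a gene feature table as GFF3
#'
#' External coordinates are 1-based inclusive (GFF3 dialect); the gene symbol
#' is stored in the \code{Name} attribute and the feature kind in column 3.
#'
#' @param p plastome whose \code{genes} are written.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
write_annotation_table <- function(p, path) {
  g <- p$genes
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(g)) {
    lines <- paste(p$id, "plastokit", g$kind, g$start + 1L, g$end, ".",
                   g$strand, ".", paste0("Name=", g$name), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a GFF3-like annotation table
#'
#' Inverse of [write_annotation_table()]: a 9-column TSV with 1-based
#' inclusive coordinates and a \code{Name=} attribute. Writing then reading
#' reproduces the feature table exactly.
#'
#' @param path TSV file.
#' @return gene feature table (0-based half-open coordinates).
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) return(gene_table())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols != 9L))
    stop("parse error: expected 9 tab-separated columns at line ",
         which(ncols != 9L)[[1]])
  m <- do.call(rbind, parts)
  name <- sub("^.*Name=([^;]+).*$", "\\1", m[, 9])
  gene_table(name = name, start = as.integer(m[, 4]) - 1L,
             end = as.integer(m[, 5]), strand = m[, 7], kind = m[, 3])
}

#' Rotate a plastome so the LSC begins at position 0
#'
#' Produces the canonical linearization used throughout the pipeline: region
#' order LSC-IRb-SSC-IRa with the LSC start at coordinate 0. Gene coordinates
#' are remapped; features that would wrap the new origin are split into two
#' sub-intervals. Idempotent and length-preserving.
#'
#' @param p plastome.
#' @param part quadripartite partition of \code{p} (see
#'   [partition_genome()]).
#' @return list with elements \code{plastome} (rotated) and \code{partition}
#'   (canonical, non-wrapping).
#' @export
rotate_to_lsc_origin <- function(p, part) {
  n <- nchar(p$seq)
  if (part$genome_length != n)
    stop("consistency error: partition is for a genome of length ",
         part$genome_length, ", not ", n)
  k <- part$lsc[["start"]]
  seq2 <- seq_rotate(p$seq, k)
  g <- p$genes
  if (nrow(g)) {
    len <- g$end - g$start
    s2 <- ((g$start - k) %% n + n) %% n
    e2 <- s2 + len
    wrap <- e2 > n
    gm <- gene_table(g$name[!wrap], s2[!wrap], e2[!wrap],
                     g$strand[!wrap], g$kind[!wrap])
    if (any(wrap)) {
      gw <- rbind(
        gene_table(g$name[wrap], s2[wrap], rep(n, sum(wrap)),
                   g$strand[wrap], g$kind[wrap]),
        gene_table(g$name[wrap], rep(0L, sum(wrap)), e2[wrap] - n,
                   g$strand[wrap], g$kind[wrap]))
      gm <- rbind(gm, gw)
    }
    gm <- gm[order(gm$start, gm$end), , drop = FALSE]
    rownames(gm) <- NULL
  } else gm <- g
  p2 <- plastome(p$id, seq2, circular = p$circular, genes = gm)
  L <- region_width(part$lsc, n); I <- region_width(part$irb, n)
  S <- region_width(part$ssc, n)
  part2 <- new_partition(n,
                         lsc = c(start = 0L, end = L),
                         irb = c(start = L, end = L + I),
                         ssc = c(start = L + I, end = L + I + S),
                         ira = c(start = L + I + S, end = n),
                         identity = part$identity)
  list(plastome = p2, partition = part2)
}
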