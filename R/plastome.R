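#' @importFrom stats cor.test rpois runif setNames
#' @importFrom utils head tail download.file
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Works on plain uppercase character strings over \code{A,C,G,T,N}.
#'
#' @param s character scalar, DNA sequence.
#' @return character scalar, the reverse complement.
#' @export
seq_rc <- function(s) {
  if (nchar(s) == 0L) return(s)
  chartr("ACGTN", "TGCAN", rawToChar(rev(charToRaw(s))))
}

#' Complement (no reversal) of a DNA string
#' @param s character scalar.
#' @return character scalar.
#' @keywords internal
seq_comp <- function(s) chartr("ACGTN", "TGCAN", s)

#' Rotate a circular sequence
#'
#' Returns the sequence starting at 0-based offset \code{k}, i.e. the
#' linearization of the same circle cut \code{k} bases downstream.
#'
#' @param s character scalar.
#' @param k integer offset in \code{[0, nchar(s))}.
#' @return character scalar of the same length.
#' @export
seq_rotate <- function(s, k) {
  n <- nchar(s)
  k <- ((k %% n) + n) %% n
  if (k == 0L) return(s)
  paste0(substr(s, k + 1L, n), substr(s, 1L, k))
}

#' GC content of a sequence
#' @param s character scalar over A,C,G,T,N. N bases are excluded.
#' @return fraction in \code{[0,1]}.
#' @export
gc_content <- function(s) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  v <- v[v != "N"]
  sum(v == "G" | v == "C") / length(v)
}

## integer codes 1:4 = A,C,G,T; 0 = N. Used by the simulator and scanners.
dna_to_int <- function(s) {
  m <- integer(256)
  m[c(65L, 67L, 71L, 84L)] <- 1:4        # A C G T
  m[utf8ToInt(s)]
}

int_to_dna <- function(v) {
  intToUtf8(c(78L, 65L, 67L, 71L, 84L)[v + 1L])   # 0 -> N
}

## complement on integer codes (A<->T, C<->G), N (0) maps to 0
int_comp <- function(v) c(0L, 4L, 3L, 2L, 1L)[v + 1L]

#' Construct a gene feature table
#'
#' Internal coordinates are 0-based half-open on the forward strand of one
#' linearization of the circle; features that wrap the origin must be split
#' into two sub-intervals before construction.
#'
#' @param name character, gene symbols.
#' @param start,end integer, 0-based half-open.
#' @param strand character, "+" or "-".
#' @param kind character, one of CDS, tRNA, rRNA, intergenic.
#' @return data.frame with columns name, start, end, strand, kind.
#' @export
gene_table <- function(name = character(), start = integer(), end = integer(),
                       strand = character(), kind = character()) {
  stopifnot(length(name) == length(start), length(start) == length(end),
            length(end) == length(strand), length(strand) == length(kind))
  if (length(start) && any(start >= end))
    stop("gene features must satisfy start < end (0-based half-open)")
  if (length(strand) && !all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  data.frame(name = as.character(name), start = as.integer(start),
             end = as.integer(end), strand = as.character(strand),
             kind = as.character(kind), stringsAsFactors = FALSE)
}

#' Construct a plastome object
#'
#' The canonical in-memory representation of a chloroplast genome: an
#' uppercase DNA string over \code{A,C,G,T,N}, a circularity flag and a gene
#' feature table.
#'
#' @param id accession / taxon identifier.
#' @param seq DNA string; lowercase is uppercased, U mapped to T, IUPAC
#'   ambiguity codes other than N mapped to N (with a warning giving the count).
#' @param circular logical.
#' @param genes gene feature table from [gene_table()].
#' @return object of class \code{plastome}.
#' @export
plastome <- function(id, seq, circular = TRUE, genes = gene_table()) {
  seq <- toupper(seq)
  seq <- chartr("U", "T", seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(v) == 0L) stop("empty sequence for '", id, "'")
  bad <- !(v %in% c(DNA_BASES, "N"))
  if (any(bad)) {
    amb <- v[bad] %in% strsplit("RYSWKMBDHV", "")[[1]]
    if (!all(amb))
      stop("non-nucleotide alphabet in '", id, "': ",
           paste(unique(v[bad][!amb]), collapse = ","))
    warning(sum(bad), " ambiguity code(s) mapped to N in '", id, "'")
    v[bad] <- "N"
    seq <- paste(v, collapse = "")
  }
  n <- length(v)
  if (nrow(genes)) {
    if (any(genes$start < 0L) || any(genes$end > n))
      stop("gene coordinates outside [0, ", n, ") for '", id, "'")
  }
  structure(list(id = id, seq = seq, circular = isTRUE(circular),
                 genes = genes),
            class = "plastome")
}

#' @export
print.plastome <- function(x, ...) {
  cat("<plastome> ", x$id, ": ", nchar(x$seq), " bp, ",
      if (x$circular) "circular" else "linear", ", ",
      nrow(x$genes), " gene feature(s)\n", sep = "")
  invisible(x)
}

#' @export
length.plastome <- function(x) nchar(x$seq)

#' Extract a subsequence of a plastome (circular-aware)
#'
#' @param p plastome.
#' @param start 0-based start.
#' @param end 0-based half-open end; may exceed the genome length, in which
#'   case the slice wraps around the origin (circular genomes only).
#' @return character scalar.
#' @export
plastome_slice <- function(p, start, end) {
  n <- nchar(p$seq)
  stopifnot(start >= 0L, end > start)
  if (end <= n) return(substr(p$seq, start + 1L, end))
  if (!p$circular) stop("slice beyond the end of a linear genome")
  paste0(substr(p$seq, start + 1L, n), substr(p$seq, 1L, end - n))
}
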