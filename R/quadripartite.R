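## Quadripartite structure: IR detection, LSC/IRb/SSC/IRa partitioning,
## junction profiling and boundary-type classification.

#' Construct a quadripartite partition
#'
#' Regions are \code{c(start, end)} 0-based half-open on one linearization of
#' the circle; \code{end} may exceed the genome length, meaning the region
#' wraps through the origin. The four regions must tile the circle exactly,
#' the two IRs must have equal width and the LSC must be longer than the SSC.
#'
#' @param genome_length integer.
#' @param lsc,irb,ssc,ira named numeric vectors \code{c(start=, end=)}.
#' @param identity fraction identity between the two IR copies.
#' @return object of class \code{quadripartition}.
#' @export
new_partition <- function(genome_length, lsc, irb, ssc, ira, identity = 1) {
  w <- vapply(list(lsc = lsc, irb = irb, ssc = ssc, ira = ira),
              function(r) region_width(r, genome_length), 0)
  if (sum(w) != genome_length)
    stop("partition does not tile the genome: region widths sum to ",
         sum(w), ", genome length ", genome_length)
  if (w[["irb"]] != w[["ira"]])
    stop("IR copies differ in width (", w[["irb"]], " vs ", w[["ira"]], ")")
  if (w[["lsc"]] <= w[["ssc"]])
    stop("LSC (", w[["lsc"]], " bp) must be longer than SSC (",
         w[["ssc"]], " bp)")
  structure(list(genome_length = as.integer(genome_length),
                 lsc = lsc, irb = irb, ssc = ssc, ira = ira,
                 identity = identity),
            class = "quadripartition")
}

#' @export
print.quadripartition <- function(x, ...) {
  cat(sprintf("<quadripartition> %d bp: LSC %d, IRb %d, SSC %d, IRa %d (IR identity %.4f)\n",
              x$genome_length,
              region_width(x$lsc, x$genome_length),
              region_width(x$irb, x$genome_length),
              region_width(x$ssc, x$genome_length),
              region_width(x$ira, x$genome_length),
              x$identity))
  invisible(x)
}

#' Width of a (possibly wrapping) region
#' @param r \code{c(start, end)}, end may exceed the genome length.
#' @param n genome length (unused; kept for interface symmetry).
#' @return integer width.
#' @export
region_width <- function(r, n = NULL) as.integer(r[["end"]] - r[["start"]])

#' Region lengths of a partition as a named vector
#' @param part quadripartition.
#' @return named integer vector size/lsc/ssc/ir.
#' @export
partition_lengths <- function(part) {
  c(size = part$genome_length,
    lsc = region_width(part$lsc),
    ssc = region_width(part$ssc),
    ir = region_width(part$irb))
}

#' Detect the inverted-repeat pair of a plastome
#'
#' Finds the maximal pair of non-overlapping segments (i1, i2) on the circle
#' such that segment i2 is the reverse complement of segment i1 at identity
#' \code{>= min_identity} and length \code{>= min_len}. Seeds of width
#' \code{k} are matched against the reverse complement of the (logically
#' doubled) sequence, collinear seed hits on the same anti-diagonal are
#' chained, and the chain is extended by exact match; ties are broken by
#' longer length, then smaller start coordinate.
#'
#' @param seq DNA string or plastome.
#' @param min_len minimum IR length (bp).
#' @param min_identity minimum fraction identity between the copies.
#' @param k seed width.
#' @return list with \code{i1}, \code{i2} (each \code{c(start, end)}, 0-based
#'   half-open on the circle, \code{end} possibly past the origin),
#'   \code{length} and \code{identity}; \code{i1} has the smaller start.
#' @export
detect_inverted_repeats <- function(seq, min_len = 1000, min_identity = 0.99,
                                    k = 31) {
  if (inherits(seq, "plastome")) seq <- seq$seq
  n <- nchar(seq)
  if (n < 4 * min_len)
    stop("sequence too short (", n, " bp) for min_len ", min_len)
  s2 <- paste0(seq, seq)
  X <- dna_to_int(s2)
  XC <- int_comp(X)

  stride <- max(1L, min(487L, min_len - k + 1L))
  starts <- seq.int(1L, n, by = stride)
  kmers <- substring(s2, starts, starts + k - 1L)
  ok <- !grepl("N", kmers, fixed = TRUE)
  starts <- starts[ok]; kmers <- kmers[ok]
  if (!length(starts)) stop("structure-not-found: no usable seeds")

  rck <- vapply(kmers, seq_rc, "", USE.NAMES = FALSE)
  dict <- Biostrings::PDict(Biostrings::DNAStringSet(rck))
  hits <- Biostrings::matchPDict(dict, Biostrings::DNAString(s2))

  ## anti-diagonal constant: site u pairs with site C - u
  cons <- integer(0); useeds <- integer(0)
  for (i in seq_along(starts)) {
    js <- Biostrings::startIndex(hits)[[i]]
    if (is.null(js) || length(js) == 0L || length(js) > 64L) next
    cons <- c(cons, starts[[i]] + js + k - 1L)
    useeds <- c(useeds, rep(starts[[i]], length(js)))
  }
  if (!length(cons)) stop("structure-not-found: no reverse-complement seed matches")

  best <- NULL
  for (C in unique(cons)) {
    us <- useeds[cons == C]
    us <- us[2L * us < C]       # keep the half where u < partner
    if (!length(us)) next
    ## one circular pairing can appear twice in the doubled sequence on the
    ## same anti-diagonal (offset by +/- n): chain only collinear seeds that
    ## are close together, evaluating each block separately
    us <- sort(unique(us))
    brk <- c(0L, which(diff(us) > 2L * stride + k), length(us))
    for (bi in seq_len(length(brk) - 1L)) {
      blk <- us[(brk[[bi]] + 1L):brk[[bi + 1L]]]
      a <- min(blk); b <- max(blk) + k - 1L
      if (2 * b >= C) b <- (C - 1L) %/% 2L
      ## exact extension outward
      while (a > 1L && C - a + 1L <= 2L * n && X[a - 1L] != 0L &&
             X[a - 1L] == XC[C - a + 1L]) a <- a - 1L
      while (b + 1L < C - (b + 1L) && b + 1L <= 2L * n && C - b - 1L >= 1L &&
             X[b + 1L] != 0L && X[b + 1L] == XC[C - b - 1L]) b <- b + 1L
      len <- b - a + 1L
      if (len < min_len) next
      m <- sum(X[a:b] != 0L & X[a:b] == XC[C - (a:b)])
      idf <- m / len
      if (idf < min_identity) next
      ## partner interval
      pa <- C - b; pb <- C - a
      if (pa <= b) next                     # overlapping self-palindrome
      if ((pb - a + 1L) > n + len) next     # cannot fit one circle period
      s1 <- (a - 1L) %% n; s1b <- (pa - 1L) %% n
      key_lo <- min(s1, s1b); key_hi <- max(s1, s1b)
      cand <- list(i1 = c(start = key_lo, end = key_lo + len),
                   i2 = c(start = key_hi, end = key_hi + len),
                   length = len, identity = idf)
      if (is.null(best) || cand$length > best$length ||
          (cand$length == best$length && cand$i1[["start"]] < best$i1[["start"]]))
        best <- cand
    }
  }
  if (is.null(best))
    stop("structure-not-found: no inverted-repeat pair of length >= ",
         min_len, " at identity >= ", min_identity)
  best
}

#' Partition a plastome into LSC/IRb/SSC/IRa
#'
#' The two arcs of the circle between the detected IR copies are assigned
#' LSC (longer) and SSC (shorter); IRb is the IR copy whose clockwise
#' (increasing-coordinate) neighbour is the SSC.
#'
#' @param p plastome (or its length as integer).
#' @param irpair result of [detect_inverted_repeats()].
#' @return [new_partition()] object.
#' @export
partition_genome <- function(p, irpair) {
  n <- if (inherits(p, "plastome")) nchar(p$seq) else as.integer(p)
  s1 <- irpair$i1[["start"]]; e1 <- irpair$i1[["end"]]
  s2 <- irpair$i2[["start"]]; e2 <- irpair$i2[["end"]]
  gap1 <- (s2 - e1) %% n          # arc clockwise after copy 1
  gap2 <- (s1 - e2) %% n          # arc clockwise after copy 2
  if (gap1 == gap2)
    stop("ambiguity error: inter-IR arcs have equal length (", gap1,
         " bp); LSC/SSC assignment is undefined")
  if (gap1 < gap2) {
    ## arc after copy 1 is SSC => copy 1 is IRb
    irb <- c(start = s1 %% n, end = (s1 %% n) + (e1 - s1))
    ssc <- c(start = e1 %% n, end = (e1 %% n) + gap1)
    ira <- c(start = s2 %% n, end = (s2 %% n) + (e2 - s2))
    lsc <- c(start = e2 %% n, end = (e2 %% n) + gap2)
  } else {
    irb <- c(start = s2 %% n, end = (s2 %% n) + (e2 - s2))
    ssc <- c(start = e2 %% n, end = (e2 %% n) + gap2)
    ira <- c(start = s1 %% n, end = (s1 %% n) + (e1 - s1))
    lsc <- c(start = e1 %% n, end = (e1 %% n) + gap1)
  }
  new_partition(n, lsc = lsc, irb = irb, ssc = ssc, ira = ira,
                identity = irpair$identity)
}

#' Detect and partition in one step, returning the canonical rotation
#'
#' Convenience wrapper: detect the IR pair, partition, and rotate the genome
#' so the LSC starts at coordinate 0 (region order LSC-IRb-SSC-IRa).
#'
#' @param p plastome.
#' @inheritParams detect_inverted_repeats
#' @return list with \code{plastome} and \code{partition} (canonical).
#' @export
quadripartite_structure <- function(p, min_len = 1000, min_identity = 0.99,
                                    k = 31) {
  ir <- detect_inverted_repeats(p$seq, min_len = min_len,
                                min_identity = min_identity, k = k)
  part <- partition_genome(p, ir)
  rotate_to_lsc_origin(p, part)
}

## marker gene matching: GenBank tRNA names carry anticodons (trnN-GUU)
gene_matches <- function(names, marker) {
  names == marker | startsWith(names, paste0(marker, "-"))
}

#' Profile the genes at the four IR/SC junctions
#'
#' For each junction (LSC/IRb, IRb/SSC, SSC/IRa, IRa/LSC) reports the gene
#' overlapping the junction point (with the bp split across it), or the
#' nearest annotated gene on each side with its distance in bp. A distance of
#' 0 means the gene abuts the junction. Requires the canonical linearization
#' (LSC start at 0; see [rotate_to_lsc_origin()]).
#'
#' @param p plastome with non-empty \code{genes}.
#' @param part canonical quadripartition of \code{p}.
#' @param max_dist genes farther than this from a junction are not reported.
#' @return list of four junction records, each with \code{junction},
#'   \code{position}, \code{overlapping} (data.frame name/left_bp/right_bp),
#'   \code{left} and \code{right} (name, distance).
#' @export
profile_junctions <- function(p, part, max_dist = 10000) {
  if (nrow(p$genes) == 0L) stop("plastome '", p$id, "' has no gene features")
  if (part$lsc[["start"]] != 0L)
    stop("profile_junctions requires the canonical rotation (LSC start at 0)")
  n <- part$genome_length
  g <- p$genes
  jpos <- c("J(LSC/IRb)" = part$lsc[["end"]],
            "J(IRb/SSC)" = part$irb[["end"]],
            "J(SSC/IRa)" = part$ssc[["end"]],
            "J(IRa/LSC)" = part$ira[["end"]] %% n)
  out <- lapply(seq_along(jpos), function(i) {
    q <- jpos[[i]]
    ov <- g[g$start < q & g$end > q, , drop = FALSE]
    overlapping <- if (nrow(ov)) {
      data.frame(name = ov$name, left_bp = q - ov$start,
                 right_bp = ov$end - q, stringsAsFactors = FALSE)
    } else data.frame(name = character(), left_bp = integer(),
                      right_bp = integer())
    ## nearest gene strictly on each side, circular distances
    dl <- (q - g$end) %% n      # gene ends before junction (clockwise gap)
    dr <- (g$start - q) %% n    # gene starts after junction
    left <- right <- NULL
    cand_l <- which(dl <= max_dist & !(g$start < q & g$end > q))
    if (length(cand_l)) {
      jl <- cand_l[which.min(dl[cand_l])]
      left <- list(name = g$name[[jl]], distance = as.integer(dl[[jl]]))
    } else warning("no gene within ", max_dist, " bp left of ", names(jpos)[[i]])
    cand_r <- which(dr <= max_dist & !(g$start < q & g$end > q))
    if (length(cand_r)) {
      jr <- cand_r[which.min(dr[cand_r])]
      right <- list(name = g$name[[jr]], distance = as.integer(dr[[jr]]))
    } else warning("no gene within ", max_dist, " bp right of ", names(jpos)[[i]])
    list(junction = names(jpos)[[i]], position = as.integer(q),
         overlapping = overlapping, left = left, right = right)
  })
  names(out) <- names(jpos)
  out
}

j_within <- function(j, marker) {
  nrow(j$overlapping) > 0 && any(gene_matches(j$overlapping$name, marker))
}

j_between <- function(j, a, b) {
  if (nrow(j$overlapping) > 0) return(FALSE)
  if (is.null(j$left) || is.null(j$right)) return(FALSE)
  fl <- c(j$left$name, j$right$name)
  (any(gene_matches(fl[1], a)) && any(gene_matches(fl[2], b))) ||
    (any(gene_matches(fl[1], b)) && any(gene_matches(fl[2], a)))
}

#' Classify the IR/SC boundary type of a junction profile
#'
#' Rule-based decision table over the genes flanking or spanning the
#' IRb/SSC and SSC/IRa junctions, mirroring the four boundary
#' configurations observed across Aroideae plastomes:
#' \describe{
#'   \item{I}{IRb/SSC between trnN and ndhF; SSC/IRa inside ycf1 (split) or
#'     between ycf1 and trnN (sub-case recorded).}
#'   \item{II}{IRb/SSC within ndhF; SSC/IRa between rps15 and ycf1 (ycf1
#'     fully duplicated into the IRs).}
#'   \item{III}{IRb/SSC between trnR and trnN (SSC expansion captured trnN);
#'     SSC/IRa between ycf1 and the IR terminus (trnN or, when trnN moved
#'     into the SSC, trnR; sub-case recorded).}
#'   \item{IV}{IRb/SSC between trnN and ycf1; SSC/IRa between ndhF and trnN
#'     (reverse-complemented SSC).}
#' }
#' "Between A and B" means the junction point lies in the intergenic gap
#' whose nearest annotated flanks are A and B, irrespective of order/strand.
#'
#' @param profile result of [profile_junctions()].
#' @return character label in \code{I, II, III, IV, unclassified}, with
#'   attributes \code{subcase} and (when unclassified) \code{reason}.
#' @export
classify_junction_type <- function(profile) {
  j2 <- profile[["J(IRb/SSC)"]]
  j3 <- profile[["J(SSC/IRa)"]]
  markers <- c("trnN", "ndhF", "ycf1", "rps15", "trnR")
  seen <- unique(unlist(lapply(list(j2, j3), function(j) {
    c(j$overlapping$name, j$left$name, j$right$name)
  })))
  if (!any(vapply(markers, function(m) any(gene_matches(seen, m)), TRUE))) {
    return(structure("unclassified",
                     reason = "no junction marker genes (trnN/ndhF/ycf1/rps15/trnR) annotated near the IR/SC junctions"))
  }
  if (j_within(j2, "ndhF") && j_between(j3, "rps15", "ycf1"))
    return(structure("II", subcase = "ndhF split; ycf1 duplicated in IR"))
  if (j_between(j2, "trnN", "ndhF")) {
    if (j_within(j3, "ycf1"))
      return(structure("I", subcase = "SSC/IRa inside ycf1"))
    if (j_between(j3, "ycf1", "trnN"))
      return(structure("I", subcase = "SSC/IRa between ycf1 and trnN"))
  }
  if (j_between(j2, "trnR", "trnN")) {
    if (j_between(j3, "ycf1", "trnN"))
      return(structure("III", subcase = "SSC/IRa between ycf1 and trnN"))
    if (j_between(j3, "ycf1", "trnR"))
      return(structure("III", subcase = "SSC/IRa between ycf1 and trnR (trnN relocated to SSC)"))
  }
  if (j_between(j2, "trnN", "ycf1") && j_between(j3, "ndhF", "trnN"))
    return(structure("IV", subcase = "reverse-complemented SSC"))
  structure("unclassified",
            reason = "junction flanks match none of the four boundary configurations")
}

#' Pairwise Pearson correlations among genome and region sizes
#'
#' For a set of quadripartite partitions, computes Pearson r, R-squared and
#' the two-sided p-value (t distribution, df = n - 2) for the six pairs
#' size~LSC, size~SSC, size~IR, LSC~SSC, LSC~IR and SSC~IR.
#'
#' @param partitions list of quadripartition objects.
#' @return data.frame with columns pair, r, r2, p, n.
#' @export
region_size_correlations <- function(partitions) {
  if (length(partitions) < 3L) stop("need at least 3 partitions")
  m <- t(vapply(partitions, partition_lengths, numeric(4)))
  pairs <- list(c("size", "lsc"), c("size", "ssc"), c("size", "ir"),
                c("lsc", "ssc"), c("lsc", "ir"), c("ssc", "ir"))
  rows <- lapply(pairs, function(pr) {
    x <- m[, pr[[1]]]; y <- m[, pr[[2]]]
    lbl <- paste0(pr[[1]], "~", pr[[2]])
    if (stats::var(x) == 0 || stats::var(y) == 0) {
      warning("undefined correlation (zero variance) for ", lbl)
      return(data.frame(pair = lbl, r = NA_real_, r2 = NA_real_,
                        p = NA_real_, n = nrow(m)))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(pair = lbl, r = unname(ct$estimate),
               r2 = unname(ct$estimate)^2, p = ct$p.value, n = nrow(m))
  })
  do.call(rbind, rows)
}
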