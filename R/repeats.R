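## Repeat scanning: MISA-style perfect microsatellites, a simplified
## tandem-array finder, and seed-and-extend dispersed/palindromic repeats.

## default MISA-style minimum copy numbers by unit length 1..6
SSR_THRESHOLDS <- c(`1` = 10L, `2` = 5L, `3` = 4L, `4` = 3L, `5` = 3L, `6` = 3L)

is_primitive_unit <- function(unit) {
  m <- nchar(unit)
  if (m == 1L) return(TRUE)
  for (p in seq_len(m - 1L)) {
    if (m %% p == 0L && unit == strrep(substr(unit, 1L, p), m %/% p))
      return(FALSE)
  }
  TRUE
}

#' Canonical SSR motif
#'
#' Reduces a repeat unit to its primitive form (e.g. "ATAT" to "AT") and
#' returns the lexicographically smallest rotation, so all phases of the
#' same microsatellite share one label.
#'
#' @param unit repeat unit, length 1-6 after reduction.
#' @return canonical motif string.
#' @export
canonical_motif <- function(unit) {
  m <- nchar(unit)
  stopifnot(m >= 1L)
  for (p in seq_len(m)) {
    if (m %% p == 0L && unit == strrep(substr(unit, 1L, p), m %/% p)) {
      unit <- substr(unit, 1L, p); break
    }
  }
  p <- nchar(unit)
  if (p > 6L) stop("unit longer than 6 after primitive reduction")
  rots <- vapply(seq_len(p), function(i)
    paste0(substr(unit, i, p), substr(unit, 1L, i - 1L)), "")
  min(rots)
}

#' Scan for perfect microsatellites (SSRs)
#'
#' Finds all maximal perfect tandem runs of primitive units of length 1-6
#' meeting the per-class minimum copy number (MISA-style thresholds
#' 10/5/4/3/3/3 by default). A run is reported once, under its shortest
#' primitive unit, at its leftmost phase; N never matches.
#'
#' @param seq DNA string or plastome.
#' @param thresholds named integer vector, minimum copies for unit lengths
#'   "1".."6".
#' @return data.frame start/end (0-based half-open), motif (canonical),
#'   unit (as read at the leftmost phase), copies, class.
#' @export
find_ssrs <- function(seq, thresholds = SSR_THRESHOLDS) {
  if (inherits(seq, "plastome")) seq <- seq$seq
  x <- dna_to_int(seq)
  n <- length(x)
  out <- list()
  for (m in 1:6) {
    thr <- thresholds[[as.character(m)]]
    if (n <= m) next
    a <- x[seq_len(n - m)]
    b <- x[(m + 1L):n]
    eq <- a == b & a != 0L
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths + m >= thr * m)
    for (h in hit) {
      i <- starts[[h]]                  # first site of the run (1-based)
      span <- r$lengths[[h]] + m        # perfect period-m stretch length
      copies <- span %/% m
      if (copies < thr) next
      unit <- substr(seq, i, i + m - 1L)
      if (!is_primitive_unit(unit)) next   # reported under the shorter unit
      out[[length(out) + 1L]] <-
        data.frame(start = i - 1L, end = i - 1L + copies * m,
                   motif = canonical_motif(unit), unit = unit,
                   copies = copies, class = m, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(), motif = character(),
                      unit = character(), copies = integer(), class = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$class), ]
  rownames(res) <- NULL
  res
}

#' Detect tandem repeat arrays (simplified Tandem Repeats Finder)
#'
#' Candidate periods are proposed from self-matches at each lag; runs of
#' matching positions (allowing short mismatch gaps when the continuation
#' pays for them under the +match/-mismatch weights) define candidate
#' arrays, which are then scored ungapped against their per-phase majority
#' consensus (+match per agreeing base, -mismatch per disagreeing base).
#' Arrays with score >= \code{min_score} and unit length >= \code{min_unit}
#' are reported; overlapping arrays are reduced to the highest-scoring
#' representative (ties broken toward the shorter unit). Indels are not
#' modelled.
#'
#' @param seq DNA string or plastome.
#' @param min_unit minimum unit length (bp).
#' @param match,mismatch alignment weights (positive numbers; mismatch is
#'   subtracted).
#' @param indel unused (kept for interface compatibility; the detector is
#'   ungapped).
#' @param min_score minimum consensus alignment score.
#' @param max_period largest unit length considered.
#' @return data.frame start/end/unit_len/copies/score/identity.
#' @export
find_tandem_repeats <- function(seq, min_unit = 7, match = 2, mismatch = 7,
                                indel = 7, min_score = 50, max_period = 120) {
  if (inherits(seq, "plastome")) seq <- seq$seq
  x <- dna_to_int(seq)
  n <- length(x)
  if (n < 2 * min_unit) stop("sequence shorter than two units")
  cand <- list()
  for (d in min_unit:min(max_period, n %/% 2L)) {
    a <- x[seq_len(n - d)]
    b <- x[(d + 1L):n]
    eq <- a == b & a != 0L
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    idx <- which(r$values)
    if (!length(idx)) next
    ## merge TRUE runs across short mismatch gaps when profitable
    segs <- list()
    cur_s <- NA_integer_; cur_e <- NA_integer_
    for (h in idx) {
      if (is.na(cur_s)) { cur_s <- starts[[h]]; cur_e <- ends[[h]]; next }
      gap <- starts[[h]] - cur_e - 1L
      if (gap * mismatch < r$lengths[[h]] * match && gap <= 2L * d) {
        cur_e <- ends[[h]]
      } else {
        segs[[length(segs) + 1L]] <- c(cur_s, cur_e)
        cur_s <- starts[[h]]; cur_e <- ends[[h]]
      }
    }
    segs[[length(segs) + 1L]] <- c(cur_s, cur_e)
    for (sg in segs) {
      span <- (sg[[2]] - sg[[1]] + 1L) + d
      if (span < 2L * d) next
      pos <- sg[[1]]:(sg[[1]] + span - 1L)
      ## report each array only at its smallest period: skip the candidate
      ## if the span has a cleaner or equal period below d
      arr <- x[pos]
      agree_d <- mean(arr[seq_len(span - d)] == arr[(d + 1L):span])
      smaller <- FALSE
      for (p in seq_len(d - 1L)) {
        if (mean(arr[seq_len(span - p)] == arr[(p + 1L):span]) >= agree_d) {
          smaller <- TRUE; break
        }
      }
      if (smaller) next
      ## consensus scoring over phases
      ph <- (pos - sg[[1]]) %% d
      bases <- x[pos]
      cons <- vapply(split(bases, ph), function(v) {
        tb <- tabulate(v[v != 0L], 4L); which.max(tb)
      }, 0L)
      agree <- bases == cons[as.character(ph)]
      score <- match * sum(agree) - mismatch * sum(!agree)
      if (score < min_score) next
      cand[[length(cand) + 1L]] <-
        data.frame(start = sg[[1]] - 1L, end = sg[[1]] - 1L + span,
                   unit_len = d, copies = span / d, score = score,
                   identity = mean(agree), stringsAsFactors = FALSE)
    }
  }
  if (!length(cand))
    return(data.frame(start = integer(), end = integer(), unit_len = integer(),
                      copies = numeric(), score = numeric(), identity = numeric()))
  res <- do.call(rbind, cand)
  res <- res[order(-res$score, res$unit_len, res$start), ]
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    if (!keep[[i]]) next
    later <- which(keep & seq_len(nrow(res)) > i)
    ov <- res$start[later] < res$end[[i]] & res$end[later] > res$start[[i]]
    keep[later[ov]] <- FALSE
  }
  res <- res[keep, ]
  res <- res[order(res$start), ]
  rownames(res) <- NULL
  res
}

## greedy ungapped extension crossing isolated mismatches; stops at two
## consecutive mismatches or when overall identity would fall below the
## threshold; trailing mismatches are trimmed.
extend_pair <- function(match_at, lo, hi, core_lo, core_hi, min_identity) {
  mlen <- core_hi - core_lo + 1L
  mm <- 0L
  best_hi <- core_hi
  u <- core_hi; streak <- 0L
  while (u < hi) {
    u <- u + 1L
    if (match_at(u)) {
      if ((u - core_lo + 1L - mm) / (u - core_lo + 1L) >= min_identity) best_hi <- u
      streak <- 0L
    } else {
      mm <- mm + 1L; streak <- streak + 1L
      if (streak >= 2L) break
      if ((u - core_lo + 1L - mm) / (u - core_lo + 1L) < min_identity) break
    }
  }
  idx_hi <- if (best_hi > core_hi) (core_hi + 1L):best_hi else integer(0)
  mm_hi <- if (length(idx_hi)) sum(!vapply(idx_hi, match_at, TRUE)) else 0L
  best_lo <- core_lo
  mm <- mm_hi
  u <- core_lo; streak <- 0L
  while (u > lo) {
    u <- u - 1L
    if (match_at(u)) {
      if ((best_hi - u + 1L - mm) / (best_hi - u + 1L) >= min_identity) best_lo <- u
      streak <- 0L
    } else {
      mm <- mm + 1L; streak <- streak + 1L
      if (streak >= 2L) break
      if ((best_hi - u + 1L - mm) / (best_hi - u + 1L) < min_identity) break
    }
  }
  c(best_lo, best_hi)
}

#' Detect dispersed or palindromic repeat pairs
#'
#' Exact \code{seed_k}-mer matches between the sequence and itself
#' (dispersed, same strand) or its reverse complement (palindromic) are
#' chained along their (anti)diagonal and extended ungapped while the
#' running identity stays at or above \code{min_identity}; pairs of final
#' length \code{>= min_len} are reported. The trivial self-diagonal is
#' excluded, symmetric duplicates are collapsed, and overlapping hits are
#' merged to the longest representative.
#'
#' @param seq DNA string or plastome.
#' @param kind "dispersed" or "palindromic".
#' @param min_len minimum repeat length (bp).
#' @param min_identity minimum fraction identity between the copies.
#' @param seed_k exact seed width.
#' @param max_occ k-mers occurring more often than this are skipped
#'   (low-complexity guard).
#' @return data.frame kind/start1/end1/start2/end2/length/identity.
#' @export
find_pair_repeats <- function(seq, kind = c("dispersed", "palindromic"),
                              min_len = 30, min_identity = 0.90,
                              seed_k = 20, max_occ = 30) {
  kind <- match.arg(kind)
  if (inherits(seq, "plastome")) seq <- seq$seq
  x <- dna_to_int(seq)
  n <- length(x)
  if (n < 2L * seed_k) return(empty_pair_df())
  k <- seed_k
  kmers <- substring(seq, seq_len(n - k + 1L), k:n)
  valid <- !grepl("N", kmers, fixed = TRUE)

  acc_i <- list(); acc_j <- list()
  if (kind == "dispersed") {
    grp <- split(which(valid), kmers[valid])
    grp <- grp[lengths(grp) >= 2L & lengths(grp) <= max_occ]
    for (g in grp) {
      cmb <- utils::combn(g, 2L)
      acc_i[[length(acc_i) + 1L]] <- cmb[1L, ]
      acc_j[[length(acc_j) + 1L]] <- cmb[2L, ]
    }
    if (!length(acc_i)) return(empty_pair_df())
    pairs <- data.frame(i = unlist(acc_i), j = unlist(acc_j))
    pairs$key <- pairs$j - pairs$i               # diagonal
  } else {
    ## rc k-mer at i is the k-mer of the reverse-complemented sequence
    ## starting at n - (i + k - 1) + 1
    rcseq <- seq_rc(seq)
    rcmers <- substring(rcseq, n - k - seq_len(n - k + 1L) + 2L,
                        n - seq_len(n - k + 1L) + 1L)
    pos_by_kmer <- split(seq_len(n - k + 1L)[valid], kmers[valid])
    for (i in which(valid)) {
      js <- pos_by_kmer[[rcmers[[i]]]]
      if (is.null(js) || length(js) > max_occ) next
      ## sites i..i+k-1 pair with j+k-1..j: anti-diagonal C = i + j + k - 1
      js <- js[js > i + k - 1L]   # partner to the right; collapse (i,j)/(j,i)
      if (length(js)) {
        acc_i[[length(acc_i) + 1L]] <- rep(i, length(js))
        acc_j[[length(acc_j) + 1L]] <- js
      }
    }
    if (!length(acc_i)) return(empty_pair_df())
    pairs <- data.frame(i = unlist(acc_i), j = unlist(acc_j))
    pairs$key <- pairs$i + pairs$j + k - 1L
  }

  hits <- list()
  for (key in unique(pairs$key)) {
    sub <- pairs[pairs$key == key, , drop = FALSE]
    is <- sort(unique(sub$i))
    ## chain seeds on the same (anti)diagonal into cores
    brk <- c(0L, which(diff(is) > k), length(is))
    for (bi in seq_len(length(brk) - 1L)) {
      grp_i <- is[(brk[[bi]] + 1L):brk[[bi + 1L]]]
      core_lo <- min(grp_i); core_hi <- max(grp_i) + k - 1L
      if (kind == "dispersed") {
        dlt <- key
        match_at <- function(u) {
          v <- u + dlt
          v <= n && x[u] != 0L && x[u] == x[v]
        }
        lim_hi <- n - dlt
        ext <- extend_pair(match_at, 1L, lim_hi, core_lo, core_hi, min_identity)
        s1 <- ext[[1]]; e1 <- ext[[2]]
        s2 <- s1 + dlt; e2 <- e1 + dlt
        if (s2 <= e1) next   # overlapping copies: tandem, not dispersed
      } else {
        C <- key
        match_at <- function(u) {
          v <- C - u
          v >= 1L && v <= n && x[u] != 0L && x[u] == int_comp(x[v])
        }
        ## keep u strictly below the anti-diagonal midpoint
        ext <- extend_pair(match_at, 1L, (C - 1L) %/% 2L, core_lo,
                           min(core_hi, (C - 1L) %/% 2L), min_identity)
        s1 <- ext[[1]]; e1 <- ext[[2]]
        s2 <- C - e1; e2 <- C - s1
        if (s2 <= e1) next
      }
      len <- e1 - s1 + 1L
      if (len < min_len) next
      mvec <- vapply(s1:e1, match_at, TRUE)
      hits[[length(hits) + 1L]] <-
        data.frame(kind = kind, start1 = s1 - 1L, end1 = e1,
                   start2 = s2 - 1L, end2 = e2, length = len,
                   identity = mean(mvec), stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(empty_pair_df())
  res <- unique(do.call(rbind, hits))
  ## merge overlapping hits into one representative (longest, then best id)
  res <- res[order(-res$length, -res$identity, res$start1), ]
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    if (!keep[[i]]) next
    later <- which(keep & seq_len(nrow(res)) > i)
    ov <- res$start1[later] < res$end1[[i]] & res$end1[later] > res$start1[[i]] &
      res$start2[later] < res$end2[[i]] & res$end2[later] > res$start2[[i]]
    keep[later[ov]] <- FALSE
  }
  res <- res[keep, ]
  res <- res[order(res$start1), ]
  rownames(res) <- NULL
  res
}

empty_pair_df <- function() {
  data.frame(kind = character(), start1 = integer(), end1 = integer(),
             start2 = integer(), end2 = integer(), length = integer(),
             identity = numeric(), stringsAsFactors = FALSE)
}

## intergenic spacer label "A-B" for a position, given genes sorted by start
spacer_label <- function(start, end, genes) {
  left <- genes[genes$end <= start, ]
  right <- genes[genes$start >= end, ]
  a <- if (nrow(left)) left$name[[which.max(left$end)]] else "origin"
  b <- if (nrow(right)) right$name[[which.min(right$start)]] else "origin"
  paste0(a, "-", b)
}

#' Summarize SSRs by motif class, region and genomic context
#'
#' @param ssrs output of [find_ssrs()] on one genome.
#' @param part quadripartition of the same genome (canonical).
#' @param genes gene feature table of the same genome.
#' @param min_flag loci (genes/spacers) with at least this many SSRs are
#'   flagged (barcode co-occurrence rule).
#' @return list with \code{ssrs} (annotated), \code{by_class} (counts and
#'   percentages, unit lengths 1-6), \code{by_region} (LSC/SSC/IR),
#'   \code{by_context}, and \code{per_locus} (SSR count per gene/spacer,
#'   with \code{flagged}).
#' @export
ssr_region_summary <- function(ssrs, part, genes, min_flag = 3L) {
  if (nrow(ssrs) && max(ssrs$end) > part$genome_length)
    stop("consistency error: SSR coordinates exceed the partition's genome")
  genes <- genes[order(genes$start), , drop = FALSE]
  region <- character(nrow(ssrs))
  context <- character(nrow(ssrs))
  locus <- character(nrow(ssrs))
  for (i in seq_len(nrow(ssrs))) {
    region[[i]] <- region_of(ssrs$start[[i]], part)
    ov <- genes[genes$start < ssrs$end[[i]] & genes$end > ssrs$start[[i]], ]
    if (nrow(ov)) {
      context[[i]] <- "genic"
      locus[[i]] <- ov$name[[1L]]
    } else {
      context[[i]] <- "intergenic"
      locus[[i]] <- spacer_label(ssrs$start[[i]], ssrs$end[[i]], genes)
    }
  }
  ssrs$region <- region; ssrs$context <- context; ssrs$locus <- locus
  cls <- factor(ssrs$class, levels = 1:6)
  by_class <- data.frame(class = 1:6, count = as.integer(table(cls)))
  by_class$pct <- if (nrow(ssrs)) 100 * by_class$count / nrow(ssrs) else 0
  reg3 <- sub("IR[ab]", "IR", ssrs$region)
  by_region <- as.data.frame(table(factor(reg3, levels = c("LSC", "SSC", "IR"))),
                             stringsAsFactors = FALSE)
  names(by_region) <- c("region", "count")
  by_region$pct <- if (nrow(ssrs)) 100 * by_region$count / nrow(ssrs) else 0
  by_context <- as.data.frame(table(factor(context, levels = c("genic", "intergenic"))),
                              stringsAsFactors = FALSE)
  names(by_context) <- c("context", "count")
  per_locus <- as.data.frame(table(locus), stringsAsFactors = FALSE)
  names(per_locus) <- c("locus", "n_ssr")
  per_locus$flagged <- per_locus$n_ssr >= min_flag
  per_locus <- per_locus[order(-per_locus$n_ssr), ]
  rownames(per_locus) <- NULL
  list(ssrs = ssrs, by_class = by_class, by_region = by_region,
       by_context = by_context, per_locus = per_locus)
}
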