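test_that("canonical motifs are primitive minimal rotations", {
  expect_equal(canonical_motif("TA"), "AT")
  expect_equal(canonical_motif("ATAT"), "AT")
  expect_equal(canonical_motif("GAA"), "AAG")
  expect_equal(canonical_motif("A"), "A")
  expect_equal(canonical_motif("CGA"), "ACG")
})

test_that("SSR thresholds are exact boundaries", {
  expect_equal(nrow(find_ssrs(paste0("GC", strrep("A", 10), "GC"))), 1L)
  expect_equal(nrow(find_ssrs(paste0("GC", strrep("A", 9), "GC"))), 0L)
  r <- find_ssrs(paste0("GGG", strrep("AT", 5), "GGG"))
  expect_equal(nrow(r), 1L)
  expect_equal(r$motif, "AT")
  expect_equal(r$copies, 5L)
  expect_equal(c(r$start, r$end), c(3L, 13L))
  ## N breaks runs
  expect_equal(nrow(find_ssrs(paste0(strrep("A", 5), "N", strrep("A", 5)))), 0L)
})

test_that("SSR scanner equals the brute-force oracle on random sequences", {
  for (s in 1:25) {
    seq <- random_dna(2000, 900 + s)
    imp <- find_ssrs(seq)[, c("start", "end", "motif", "copies", "class")]
    ora <- oracle_ssrs(seq)
    rownames(imp) <- NULL; rownames(ora) <- NULL
    expect_identical(imp, ora)
  }
  ## and on repeat-dense composites
  for (s in 1:10) {
    base <- random_dna(300, 950 + s)
    seq <- paste0(base, strrep("A", 12), strrep("AT", 6), base,
                  strrep("CAG", 5), strrep("T", 10))
    imp <- find_ssrs(seq)[, c("start", "end", "motif", "copies", "class")]
    ora <- oracle_ssrs(seq)
    rownames(imp) <- NULL; rownames(ora) <- NULL
    expect_identical(imp, ora)
  }
})

test_that("reported SSR runs are maximal and same-class non-overlapping", {
  for (s in 1:5) {
    fam_seq <- build_ancestor(small_cfg(960 + s))$plastome$seq
    r <- find_ssrs(fam_seq)
    v <- strsplit(fam_seq, "", fixed = TRUE)[[1]]
    for (i in seq_len(nrow(r))) {
      m <- r$class[[i]]; st <- r$start[[i]]
      ## extending one unit left or right must fail
      if (st >= 1L) expect_false(v[st] == v[st + m])
    }
    by_class <- split(r, r$class)
    for (b in by_class) {
      if (nrow(b) < 2L) next
      b <- b[order(b$start), ]
      expect_true(all(b$start[-1L] >= b$end[-nrow(b)]))
    }
  }
})

test_that("planted SSRs are recovered exactly in ancestors and evolved tips", {
  for (s in 1:5) {
    fam <- synth_family(small_cfg(970 + s))
    truth <- fam$truth$ssrs
    tkey <- paste(truth$start, truth$end)
    tmotif <- vapply(truth$motif, canonical_motif, "")
    for (g in c(list(fam$ancestor), fam$tips[c(1, 5)])) {
      found <- find_ssrs(g$seq)
      key <- paste(found$start, found$end)
      expect_true(all(tkey %in% key))
      expect_equal(found$motif[match(tkey, key)], unname(tmotif))
    }
  }
})

test_that("tandem arrays score against their consensus as specified", {
  ## exact 7-mer x 5: 35 consensus matches x 2 = 70
  r <- find_tandem_repeats(strrep("ACGTGCA", 5))
  expect_equal(nrow(r), 1L)
  expect_equal(r$unit_len, 7L)
  expect_equal(r$score, 70)
  expect_equal(r$identity, 1)
  ## unit below min_unit is not reported
  expect_equal(nrow(find_tandem_repeats(strrep("ACGTGC", 10))), 0L)
  ## a mismatched copy is still detected, with identity < 1
  arr <- paste0(strrep("ACGTGCATTC", 2), "ACGTGGATTC", strrep("ACGTGCATTC", 2))
  r2 <- find_tandem_repeats(arr)
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$unit_len, 10L)
  expect_lt(r2$identity, 1)
  expect_gt(r2$copies, 4.9)
})

test_that("planted tandem repeats in synthetic genomes are detected", {
  anc <- build_ancestor(small_cfg(55))
  tr <- anc$truth$repeats[anc$truth$repeats$kind == "tandem", ]
  hits <- find_tandem_repeats(substr(anc$plastome$seq, tr$start - 200L, tr$end + 200L))
  expect_gte(nrow(hits), 1L)
  expect_true(any(hits$unit_len == tr$unit_len))
})

test_that("pair repeats: planted dispersed and palindromic copies are found", {
  anc <- build_ancestor(small_cfg(56))
  reps <- anc$truth$repeats
  seq <- anc$plastome$seq

  dsp <- find_pair_repeats(seq, "dispersed", min_len = 30)
  drow <- reps[reps$kind == "dispersed", ]
  hit <- dsp[dsp$start1 == drow$start & dsp$start2 == drow$start2, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$length, drow$end - drow$start)
  expect_equal(hit$identity, 1)

  pal <- find_pair_repeats(seq, "palindromic", min_len = 30)
  prow <- reps[reps$kind == "palindromic", ]
  hit2 <- pal[pal$start1 == prow$start & pal$start2 == prow$start2, ]
  expect_equal(nrow(hit2), 1L)
  expect_equal(hit2$identity, 1)
  ## the IR pair itself is the largest palindromic repeat
  expect_equal(max(pal$length), region_width(anc$truth$partition$irb))
})

test_that("pair-repeat identity threshold separates 0.92 from 0.88", {
  bg <- random_dna(5000, 77)
  seg <- random_dna(50, 78)
  mut <- function(s, pos) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
    paste(v, collapse = "")
  }
  make <- function(pos) paste0(substr(bg, 1, 1000), seg, substr(bg, 1001, 3000),
                               mut(seg, pos), substr(bg, 3001, 5000))
  ## 4 isolated mismatches in the tail (identity 0.92): full-length hit
  hits4 <- find_pair_repeats(make(c(28, 34, 40, 46)), "dispersed", min_len = 40)
  expect_true(any(hits4$start1 <= 1000 & hits4$end1 >= 1047 &
                    hits4$identity >= 0.90))
  ## 6 mismatches (identity 0.88): no qualifying full-length hit survives
  hits6 <- find_pair_repeats(make(c(26, 30, 34, 38, 42, 46)), "dispersed",
                             min_len = 40)
  expect_false(any(hits6$start1 <= 1000 & hits6$end1 >= 1046 &
                     hits6$identity >= 0.90))
})

test_that("exact-identity pair search equals brute-force duplicate detection", {
  seq <- paste0(random_dna(400, 81), substr(random_dna(400, 81), 50, 89),
                random_dna(400, 82))
  ## brute force: all exact maximal duplicate segments >= 30 bp
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(v)
  brute <- list()
  for (i in seq_len(n - 30L)) for (j in (i + 1L):(n - 29L)) {
    if (v[i] != v[j]) next
    if (i > 1L && j > i && v[i - 1L] == v[j - 1L]) next   # not leftmost
    L <- 0L
    while (j + L <= n && v[i + L] == v[j + L]) L <- L + 1L
    if (L >= 30L && j > i + L - 1L)
      brute[[length(brute) + 1L]] <- c(i - 1L, j - 1L, L)
  }
  bm <- do.call(rbind, brute)
  hits <- find_pair_repeats(seq, "dispersed", min_len = 30, min_identity = 1)
  for (r in seq_len(nrow(bm))) {
    expect_true(any(hits$start1 <= bm[r, 1] & hits$end1 >= bm[r, 1] + bm[r, 3] &
                      hits$identity == 1))
  }
})

test_that("reverse-complementing the genome preserves pair-repeat kinds", {
  anc <- build_ancestor(small_cfg(57))
  seq <- anc$plastome$seq
  rcs <- seq_rc(seq)
  n <- nchar(seq)
  for (kind in c("dispersed", "palindromic")) {
    h1 <- find_pair_repeats(seq, kind, min_len = 35)
    h2 <- find_pair_repeats(rcs, kind, min_len = 35)
    expect_equal(nrow(h1), nrow(h2))
    ## intervals map through x -> n - x
    m1 <- sort(c(n - h1$end1, n - h1$end2))
    m2 <- sort(c(h2$start1, h2$start2))
    expect_equal(m1, m2)
  }
})

test_that("SSR summaries attribute region, context and co-occurrence flags", {
  anc <- build_ancestor(small_cfg(58))
  ssrs <- find_ssrs(anc$plastome$seq)
  sm <- ssr_region_summary(ssrs, anc$truth$partition, anc$plastome$genes)
  expect_equal(sum(sm$by_class$count), nrow(ssrs))
  expect_equal(sum(sm$by_region$count), nrow(ssrs))
  expect_true(abs(sum(sm$by_class$pct) - 100) < 1e-9)
  ## the two hotspot spacers were planted with 4 SSRs each
  pl <- sm$per_locus
  expect_gte(pl$n_ssr[pl$locus == "atpH-atpI"], 4L)
  expect_true(pl$flagged[pl$locus == "atpH-atpI"])
  expect_gte(pl$n_ssr[pl$locus == "trnS-trnG"], 4L)
  ## the distractor spacer has exactly 3 planted SSRs: flagged at >= 3
  expect_true(pl$flagged[pl$locus == "ndhG-ndhI"])
  ## planted IR SSR appears in both copies
  expect_gte(sm$by_region$count[sm$by_region$region == "IR"], 2L)
})
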