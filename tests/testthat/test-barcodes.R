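test_that("HVR selection applies strict pi and SSR thresholds", {
  recs <- data.frame(name = c("r1", "r2", "r3", "r4"),
                     class = "noncoding",
                     pi = c(0.18, 0.17, 0.30, 0.10))
  cnts <- data.frame(locus = c("r1", "r2", "r3", "r4", "r4"),
                     n_ssr = c(3L, 5L, 0L, 4L, 6L))
  sel <- select_hvrs(recs, cnts)
  expect_true(sel$selected[sel$name == "r1"])       # 0.18 > 0.17, 3 SSRs
  expect_false(sel$selected[sel$name == "r2"])      # pi exactly at threshold
  expect_false(sel$selected[sel$name == "r3"])      # no SSRs
  expect_false(sel$selected[sel$name == "r4"])      # low pi despite SSRs
  expect_equal(sel$ssr_count_max[sel$name == "r4"], 6L)  # max across rows

  expect_error(select_hvrs(recs, data.frame(locus = "zzz", n_ssr = 1L)),
               "reconciliation error")
})

test_that("planted hotspot spacers are exactly the selected barcodes", {
  fam <- synth_family(small_cfg(101))
  alns <- family_region_alignments(fam$tips)
  recs <- do.call(rbind, lapply(alns, nucleotide_diversity))
  cnts <- do.call(rbind, lapply(fam$tips, function(tp) {
    ssr_region_summary(find_ssrs(tp$seq), fam$truth$partition, tp$genes)$per_locus
  }))
  sel <- select_hvrs(recs, cnts)
  expect_setequal(sel$name[sel$selected], c("atpH-atpI", "trnS-trnG"))
})

test_that("alignment stats follow the site definitions", {
  aln <- region_alignment("s", "noncoding",
                          c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA"))
  st <- alignment_stats(aln)
  expect_equal(c(st$length, st$variable_sites, st$informative_sites),
               c(4L, 0L, 0L))
  ## column {A:1, T:3}: variable but not informative;
  ## column {A:2, T:2}: variable and informative;
  ## gaps and N are not states
  aln2 <- region_alignment("s2", "noncoding",
                           c(a = "TTA-", b = "ATAN", c = "ATTA", d = "ATTA"))
  st2 <- alignment_stats(aln2)
  expect_equal(st2$variable_sites, 2L)
  expect_equal(st2$informative_sites, 1L)
  expect_equal(st2$variable_pct, 50)
})

test_that("marker combination concatenates columns and preserves distances", {
  mk <- function(nm, seqs) region_alignment(nm, "noncoding", seqs)
  A <- mk("A", c(t1 = strrep("ACGT", 10), t2 = strrep("ACGA", 10),
                 t3 = strrep("ACCT", 10), t4 = strrep("TCGT", 10)))
  B <- mk("B", c(t1 = strrep("GG", 8), t2 = strrep("GC", 8),
                 t3 = strrep("GG", 8), t4 = strrep("AG", 8)))
  cmb <- combine_markers(list(A, B))
  expect_equal(nchar(cmb$seqs[[1]]), 40L + 16L)
  expect_equal(cmb$name, "A + B")
  expect_equal(unname(attr(cmb, "boundaries")), c(40, 56))

  ## order invariance of downstream distances
  d1 <- distance_matrix(combine_markers(list(A, B)), "p")$d
  d2 <- distance_matrix(combine_markers(list(B, A)), "p")$d
  expect_equal(d1, d2[rownames(d1), colnames(d1)], tolerance = 1e-12)

  ## taxon intersection with report
  B2 <- mk("B2", c(t1 = "GGGG", t2 = "GGGG", t3 = "GGGG"))
  expect_warning(cmb2 <- combine_markers(list(A, B2)), "dropped")
  expect_setequal(names(cmb2$seqs), c("t1", "t2", "t3"))

  ## the published combination arithmetic: 1330 + 3475 = 4805 columns
  L1 <- mk("atpH-atpI", setNames(replicate(4, random_dna(1330, 105)), paste0("t", 1:4)))
  L2 <- mk("trnS-trnG", setNames(replicate(4, random_dna(3475, 106)), paste0("t", 1:4)))
  expect_equal(nchar(combine_markers(list(L1, L2))$seqs[[1]]), 4805L)
})

test_that("barcode evaluation is exact on the reference and label-invariant", {
  fam <- synth_family(small_cfg(102))
  alns <- family_region_alignments(fam$tips)
  cod <- alns[vapply(alns, function(a) a$class == "coding", TRUE)]
  ref_aln <- combine_markers(unname(cod), name = "CDS")
  ref_tree <- neighbor_joining(distance_matrix(ref_aln, "K2P"))

  ev <- evaluate_barcode(ref_aln, ref_tree, n_boot = 40, seed = 2)
  expect_equal(ev$discrimination, 100)
  expect_true(ev$informative_sites <= ev$variable_sites)
  expect_true(ev$variable_sites <= ev$aln_length)

  ## consistent relabeling of alignment and reference changes nothing
  relab <- setNames(paste0("X", seq_along(fam$tips)), names(fam$tips))
  aln2 <- ref_aln
  names(aln2$seqs) <- unname(relab[names(ref_aln$seqs)])
  tree2 <- ref_tree
  tree2$tip.label <- unname(relab[ref_tree$tip.label])
  ev2 <- evaluate_barcode(aln2, tree2, n_boot = 40, seed = 2)
  expect_equal(ev2$discrimination, ev$discrimination)
  expect_equal(ev2$n_supported, ev$n_supported)

  expect_error(evaluate_barcode(aln2, ref_tree, n_boot = 10, seed = 1),
               "missing from the reference tree")
})

test_that("hotspot barcodes discriminate better than cold spacers on average", {
  wins <- 0L; n_rep <- 12L
  for (s in seq_len(n_rep)) {
    fam <- synth_family(small_cfg(120 + s))
    alns <- family_region_alignments(fam$tips)
    cod <- alns[vapply(alns, function(a) a$class == "coding", TRUE)]
    ref_tree <- neighbor_joining(
      distance_matrix(combine_markers(unname(cod), name = "CDS"), "K2P"))
    hot <- evaluate_barcode(alns[["atpH-atpI"]], ref_tree, n_boot = 30, seed = s)
    cold <- evaluate_barcode(alns[["rps19-rpl2"]], ref_tree, n_boot = 30, seed = s)
    if (hot$discrimination >= cold$discrimination) wins <- wins + 1L
  }
  expect_gte(wins, ceiling(0.7 * n_rep))
})

test_that("rankings sort by discrimination then supported edges", {
  evs <- data.frame(marker = c("m1", "m2", "m3"),
                    aln_length = c(100L, 200L, 300L),
                    variable_sites = 1L, variable_pct = 1,
                    informative_sites = 1L, informative_pct = 1,
                    n_supported = c(2L, 5L, 3L),
                    discrimination = c(80, 80, 100))
  rk <- marker_ranking_table(evs)
  expect_equal(rk$marker, c("m3", "m2", "m1"))
  expect_setequal(rk$marker, evs$marker)
})
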