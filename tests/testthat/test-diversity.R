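test_that("shared region extraction strand-normalizes and names spacers", {
  g <- gene_table(c("gA", "gB"), c(10L, 40L), c(22L, 55L), c("+", "-"),
                  c("CDS", "CDS"))
  s <- random_dna(80, 61)
  p1 <- plastome("t1", s, genes = g)
  p2 <- plastome("t2", s, genes = g)
  regs <- extract_shared_regions(list(p1, p2))
  expect_setequal(names(regs), c("gA", "gB", "gA-gB"))
  expect_equal(regs$gA$class, "coding")
  expect_equal(regs$`gA-gB`$class, "noncoding")
  ## every region has both (identical) members
  expect_equal(unname(regs$gA$seqs[["t1"]]), unname(regs$gA$seqs[["t2"]]))
  ## minus-strand gene emitted as reverse complement of the genome slice
  expect_equal(unname(regs$gB$seqs[["t1"]]), seq_rc(substr(s, 41, 55)))
  ## spacer slice in forward orientation
  expect_equal(unname(regs$`gA-gB`$seqs[["t1"]]), substr(s, 23, 40))

  expect_error(extract_shared_regions(list(plastome("x", "ACGTACGT"))),
               "'x' has no annotation")
})

test_that("synthetic family regions match the generator layout", {
  fam <- synth_family(small_cfg(62))
  regs <- extract_shared_regions(fam$tips)
  expect_true(all(c("atpH", "ycf1", "atpH-atpI", "trnS-trnG", "psaC-ndhE") %in%
                    names(regs)))
  expect_equal(length(regs$atpH$seqs), length(fam$tips))
})

test_that("the internal aligner is score-optimal on toys and degap-faithful", {
  pw <- plastokit:::nw_align("ACGT", "AGT")
  expect_equal(pw$score, 1)            # 3 matches - 1 gap x 2
  expect_equal(nchar(pw$a), 4L)
  expect_equal(pw$b, "A-GT")

  ## exhaustive check of the DP optimum over all alignments of tiny strings
  brute_best <- function(a, b) {
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    best <- -Inf
    rec <- function(i, j, sc) {
      if (i > length(av) && j > length(bv)) {
        best <<- max(best, sc); return(invisible())
      }
      if (i <= length(av) && j <= length(bv))
        rec(i + 1, j + 1, sc + if (av[i] == bv[j]) 1 else -1)
      if (i <= length(av)) rec(i + 1, j, sc - 2)
      if (j <= length(bv)) rec(i, j + 1, sc - 2)
    }
    rec(1, 1, 0)
    best
  }
  for (s in 1:5) {
    a <- random_dna(7, 700 + s); b <- random_dna(5, 710 + s)
    expect_equal(plastokit:::nw_align(a, b)$score, brute_best(a, b))
  }

  seqs <- c(x = "ACGTACGT", y = "ACGTCGT", z = "ACCTACGT")
  aln <- align_region(seqs, "internal")
  for (nm in names(seqs))
    expect_equal(gsub("-", "", aln$seqs[[nm]]), unname(seqs[[nm]]))
  ## identical sequences align without gaps
  aln2 <- align_region(c(a = "ACGT", b = "ACGT"), "internal")
  expect_false(any(grepl("-", aln2$seqs)))
})

test_that("external mode validates row lengths", {
  expect_error(align_region(c(a = "ACGT", b = "ACG"), "external"),
               "format error")
  aln <- align_region(c(a = "AC-T", b = "ACGT"), "external")
  expect_equal(nchar(aln$seqs[["a"]]), 4L)
})

test_that("nucleotide diversity matches hand computations", {
  aln <- region_alignment("r", "coding",
                          c(a = "AAAA", b = "AAAT", c = "AAAT"))
  rec <- nucleotide_diversity(aln)
  expect_equal(rec$pi, (0.25 + 0.25 + 0) / 3, tolerance = 1e-12)
  expect_equal(rec$n_sites_used, 4L)

  ident <- region_alignment("s", "coding", c(a = "ACGT", b = "ACGT"))
  expect_equal(nucleotide_diversity(ident)$pi, 0)

  ## complete deletion removes gap/N columns
  gappy <- region_alignment("g", "coding", c(a = "A-CN", b = "ATCA"))
  expect_equal(nucleotide_diversity(gappy)$n_sites_used, 2L)
  allgap <- region_alignment("h", "coding", c(a = "-A", b = "A-"))
  expect_error(nucleotide_diversity(allgap), "no-sites")
})

test_that("pi is invariant to row/column permutations and taxon duplication", {
  set.seed(63)
  rows <- vapply(1:5, function(i) random_dna(60, 630 + i), "")
  names(rows) <- paste0("t", 1:5)
  aln <- region_alignment("p", "coding", rows)
  pi0 <- nucleotide_diversity(aln)$pi
  ## row order
  aln_r <- region_alignment("p", "coding", rows[c(3, 1, 5, 2, 4)])
  expect_equal(nucleotide_diversity(aln_r)$pi, pi0, tolerance = 1e-12)
  ## column order
  perm <- sample(60)
  rows_c <- vapply(rows, function(s)
    paste(strsplit(s, "")[[1]][perm], collapse = ""), "")
  expect_equal(nucleotide_diversity(region_alignment("p", "coding", rows_c))$pi,
               pi0, tolerance = 1e-12)
  ## duplicated taxa: explicit C(2n,2) reweighting of the pairwise sums
  rows_d <- c(rows, setNames(rows, paste0("d", 1:5)))
  pi_dup <- nucleotide_diversity(region_alignment("p", "coding", rows_d))$pi
  n <- 5
  expect_equal(pi_dup, pi0 * (4 * choose(n, 2)) / choose(2 * n, 2),
               tolerance = 1e-12)
})

test_that("class summaries rank regions and preserve the pi multiset", {
  recs <- data.frame(name = c("a", "b", "c"), class = c("coding", "noncoding", "noncoding"),
                     pi = c(0.01, 0.2, 0.05), n_taxa = 4, n_sites_used = 100)
  sm <- diversity_summary(recs)
  expect_equal(sm$class_means$mean_pi[sm$class_means$class == "coding"], 0.01)
  expect_equal(sm$class_means$mean_pi[sm$class_means$class == "noncoding"], 0.125)
  expect_equal(sort(sm$ranked$pi), sort(recs$pi))
  expect_equal(sm$ranked$name[[1]], "b")
})
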