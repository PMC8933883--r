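test_that("distance models match their closed forms", {
  ## p = 0.1 under JC69
  a <- strrep("A", 100)
  b <- paste0(strrep("C", 10), strrep("A", 90))
  cc <- a
  D <- distance_matrix(c(x = a, y = b, z = cc), model = "JC69")
  expect_equal(D$d["x", "y"], -0.75 * log(1 - 4 * 0.1 / 3), tolerance = 1e-10)
  expect_equal(D$d["x", "z"], 0)

  ## identical rows: all distances 0
  D0 <- distance_matrix(c(x = a, y = a, z = a), model = "K2P")
  expect_true(all(D0$d == 0))

  ## K2P with only transversions: P = 0, Q = p
  bt <- paste0(strrep("C", 12), strrep("A", 88))   # A->C is a transversion
  Dk <- distance_matrix(c(x = a, y = bt, z = cc), model = "K2P")
  Q <- 0.12   # P = 0: d = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q))
  expect_equal(Dk$d["x", "y"], -0.5 * log((1 - Q) * sqrt(1 - 2 * Q)),
               tolerance = 1e-10)

  ## saturation raises an error naming the pair
  sat <- chartr("A", "G", substr(a, 1, 80))
  expect_error(distance_matrix(c(x = strrep("A", 80), y = sat, z = substr(a, 1, 80)),
                               model = "JC69"),
               "saturation.*x/y")

  ## gap/N sites are pairwise-deleted
  Dg <- distance_matrix(c(x = "AC-TA", y = "ACGTN", z = "ACGTA"), model = "p")
  expect_equal(Dg$d["x", "y"], 0)
})

test_that("NJ recovers additive metrics exactly, matching ape as cross-check", {
  set.seed(91)
  for (rep in 1:10) {
    ntip <- sample(6:10, 1)
    tr <- ape::rtree(ntip)
    tr$edge.length <- tr$edge.length + 0.05
    D <- ape::cophenetic.phylo(tr)
    mine <- neighbor_joining(D)
    expect_equal(shared_split_fraction(mine, ape::unroot(tr))$rf, 0)
    expect_equal(phangorn::RF.dist(mine, ape::nj(D)), 0)
  }
})

test_that("NJ on three taxa returns the exact star lengths", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], 2)   # (5 + 9 - 10) / 2
  expect_equal(bl[["b"]], 3)
  expect_equal(bl[["c"]], 7)
  expect_error(neighbor_joining(d[1:2, 1:2]), "size error")
})

test_that("NJ is invariant to taxon order", {
  set.seed(92)
  tr <- ape::rtree(7); tr$edge.length <- tr$edge.length + 0.05
  D <- ape::cophenetic.phylo(tr)
  perm <- sample(7)
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D[perm, perm])
  expect_equal(shared_split_fraction(t1, t2)$rf, 0)
})

test_that("split sets and the shared-split fraction match hand enumeration", {
  t1 <- ape::read.tree(text = "((a,b),c,(d,e));")
  expect_setequal(tree_splits(t1), c("c,d,e", "d,e"))  # canonical side omits "a"
  expect_equal(shared_split_fraction(t1, t1)$fraction, 1)
  expect_equal(shared_split_fraction(t1, t1)$rf, 0)
  ## one NNI away: exactly one of two splits shared
  t2 <- ape::read.tree(text = "((a,c),b,(d,e));")
  ssf <- shared_split_fraction(t2, t1)
  expect_equal(ssf$fraction, 1 / 2)
  expect_equal(ssf$rf, 2)
  ## caterpillar vs balanced 6-taxon trees, cross-checked against phangorn
  t3 <- ape::read.tree(text = "(((((a,b),c),d),e),f);")
  t4 <- ape::read.tree(text = "(((a,b),(c,d)),(e,f));")
  expect_equal(shared_split_fraction(ape::unroot(t3), ape::unroot(t4))$rf,
               phangorn::RF.dist(ape::unroot(t3), ape::unroot(t4)))
  expect_error(shared_split_fraction(ape::read.tree(text = "((a,b),(c,x));"),
                                     ape::read.tree(text = "((a,b),(y,z));")),
               "undefined")
})

test_that("bootstrap supports are deterministic, bounded and high on clean clades", {
  fam <- synth_family(small_cfg(93))
  alns <- family_region_alignments(fam$tips)
  aln <- alns[["ndhF"]]
  b1 <- bootstrap_support(aln, n_reps = 60, seed = 5)
  b2 <- bootstrap_support(aln, n_reps = 60, seed = 5)
  expect_identical(b1$support, b2$support)
  expect_true(all(b1$support >= 0 & b1$support <= 100))

  ## four clearly separated clades in two superclades: every internal edge
  ## of the planted hierarchy gets support >= 95
  set.seed(94)
  clade_seq <- function(base, k) {
    v <- strsplit(base, "", fixed = TRUE)[[1]]
    pos <- sample(length(v), k)
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    paste(v, collapse = "")
  }
  anc4 <- random_dna(800, 95)
  up <- clade_seq(anc4, 150); dn <- clade_seq(anc4, 150)
  cl <- list(clade_seq(up, 80), clade_seq(up, 80),
             clade_seq(dn, 80), clade_seq(dn, 80))
  rows <- c(a1 = clade_seq(cl[[1]], 5), a2 = clade_seq(cl[[1]], 5),
            b1 = clade_seq(cl[[2]], 5), b2 = clade_seq(cl[[2]], 5),
            c1 = clade_seq(cl[[3]], 5), c2 = clade_seq(cl[[3]], 5),
            d1 = clade_seq(cl[[4]], 5), d2 = clade_seq(cl[[4]], 5))
  bs <- bootstrap_support(region_alignment("clades", "noncoding", rows),
                          n_reps = 100, seed = 6)
  expect_true(all(bs$support >= 95))
})

test_that("zero-variation alignments yield star-like replicate trees", {
  rows <- setNames(rep(strrep("ACGT", 30), 5), paste0("t", 1:5))
  bs <- bootstrap_support(region_alignment("flat", "noncoding", rows),
                          n_reps = 10, seed = 3)
  ## the point tree has no resolved internal structure to support
  expect_true(length(bs$support) == 0 || all(bs$support %in% c(0, 100)))
})

test_that("newick round trips preserve topology, lengths and supports", {
  tf <- tempfile(fileext = ".nwk")
  t1 <- ape::read.tree(text = "((A:0.1,B:0.2)75:0.05,(C:0.3,D:0.4)98:0.06);")
  write_newick(t1, tf)
  t2 <- read_newick(tf)
  expect_equal(shared_split_fraction(ape::unroot(t1), ape::unroot(t2))$rf, 0)
  expect_equal(sort(t2$edge.length), sort(t1$edge.length), tolerance = 1e-12)
  expect_setequal(t2$node.label[nzchar(t2$node.label)], c("75", "98"))

  bad <- tempfile()
  writeLines("((a,b,(c;", bad)
  expect_error(read_newick(bad), "parse error")
})
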