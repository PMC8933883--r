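test_that("IR detection recovers planted coordinates exactly and reports identity", {
  anc <- build_ancestor(small_cfg(41))
  part <- anc$truth$partition
  ir <- detect_inverted_repeats(anc$plastome$seq)
  expect_equal(ir$length, region_width(part$irb))
  expect_equal(ir$identity, 1)
  expect_equal(as.integer(ir$i1), as.integer(part$irb))
  expect_equal(as.integer(ir$i2), as.integer(part$ira))
})

test_that("random sequences without planted IRs raise structure-not-found", {
  for (s in 1:10) {
    expect_error(detect_inverted_repeats(random_dna(10000, 500 + s),
                                         min_len = 1000),
                 "structure-not-found")
  }
})

test_that("detection is rotation-invariant in region lengths", {
  anc <- build_ancestor(small_cfg(42))
  truthlen <- partition_lengths(anc$truth$partition)
  set.seed(7)
  for (k in sample(nchar(anc$plastome$seq) - 1L, 4L)) {
    rp <- plastome("r", seq_rotate(anc$plastome$seq, k))
    part <- partition_genome(rp, detect_inverted_repeats(rp$seq))
    expect_equal(partition_lengths(part), truthlen)
  }
})

test_that("partitions tile the genome and name IRb by SSC adjacency", {
  anc <- build_ancestor(small_cfg(43))
  part <- partition_genome(anc$plastome,
                           detect_inverted_repeats(anc$plastome$seq))
  pl <- partition_lengths(part)
  expect_equal(pl[["lsc"]] + pl[["ssc"]] + 2L * pl[["ir"]], pl[["size"]])
  ## IRb's clockwise neighbour must be the SSC
  expect_equal(part$irb[["end"]] %% part$genome_length,
               part$ssc[["start"]])
  expect_error(new_partition(100, c(start = 0, end = 40),
                             c(start = 40, end = 60),
                             c(start = 60, end = 70),
                             c(start = 70, end = 100)),
               "differ in width")
})

test_that("junction profiling reports splits, abutting genes and flanks", {
  toy_part <- new_partition(270,
                            lsc = c(start = 0L, end = 100L),
                            irb = c(start = 100L, end = 140L),
                            ssc = c(start = 140L, end = 230L),
                            ira = c(start = 230L, end = 270L))
  toy_seq <- substr(strrep("ACGT", 70), 1, 270)

  g <- gene_table(c("left", "span", "right"),
                  c(10L, 80L, 150L), c(50L, 120L, 180L),
                  c("+", "+", "+"), c("CDS", "CDS", "CDS"))
  prof <- profile_junctions(plastome("toy", toy_seq, genes = g), toy_part)
  j1 <- prof[["J(LSC/IRb)"]]   # position 100: inside "span" [80,120)
  expect_equal(j1$overlapping$name, "span")
  expect_equal(j1$overlapping$left_bp, 20L)
  expect_equal(j1$overlapping$right_bp, 20L)
  ## gene "left" ends at 50: distance 50 from junction 100 on the left
  expect_equal(j1$left$name, "left")
  expect_equal(j1$left$distance, 50L)
  ## J(IRb/SSC) at 140: "span" ends 20 bp before, "right" starts 10 bp after
  j2 <- prof[["J(IRb/SSC)"]]
  expect_equal(nrow(j2$overlapping), 0L)
  expect_equal(j2$left$name, "span")
  expect_equal(j2$left$distance, 20L)
  expect_equal(j2$right$name, "right")
  expect_equal(j2$right$distance, 10L)

  ## a gene abutting a junction has distance 0
  g2 <- gene_table("abut", 60L, 100L, "+", "CDS")
  prof2 <- profile_junctions(plastome("t2", toy_seq, genes = g2), toy_part)
  expect_equal(prof2[["J(LSC/IRb)"]]$left$name, "abut")
  expect_equal(prof2[["J(LSC/IRb)"]]$left$distance, 0L)
})

test_that("type I genomes show the rpl2/trnH arrangement at J(IRa/LSC)", {
  anc <- build_ancestor(small_cfg(44))
  prof <- profile_junctions(anc$plastome, anc$truth$partition)
  j4 <- prof[["J(IRa/LSC)"]]
  expect_setequal(c(j4$left$name, j4$right$name), c("rpl2", "trnH"))
  lab <- classify_junction_type(prof)
  expect_equal(as.character(lab), "I")
})

test_that("the classifier needs marker genes and ignores non-marker permutations", {
  anc <- build_ancestor(small_cfg(45))
  qs <- quadripartite_structure(anc$plastome)
  ## drop trnN (both copies): unclassified with a reason
  p2 <- qs$plastome
  p2$genes <- p2$genes[p2$genes$name != "trnN", ]
  lab <- classify_junction_type(profile_junctions(p2, qs$partition))
  expect_equal(as.character(lab), "unclassified")
  ## renaming a gene far from any junction never changes the label
  p3 <- qs$plastome
  p3$genes$name[p3$genes$name == "rbcL"] <- "zzzX"
  expect_equal(as.character(classify_junction_type(profile_junctions(p3, qs$partition))),
               "I")
})

test_that("region size correlations match the closed-form Pearson formulas", {
  mkpart <- function(size, lsc, ssc, ir) {
    new_partition(size, lsc = c(start = 0, end = lsc),
                  irb = c(start = lsc, end = lsc + ir),
                  ssc = c(start = lsc + ir, end = lsc + ir + ssc),
                  ira = c(start = lsc + ir + ssc, end = size))
  }
  ## n = 4 fixture with hand-computable sums
  lsc <- c(80000, 82000, 84000, 90000)
  ssc <- c(20000, 19000, 18500, 17000)
  ir <- c(25000, 25500, 26000, 27000)
  size <- lsc + ssc + 2 * ir
  parts <- lapply(1:4, function(i) mkpart(size[i], lsc[i], ssc[i], ir[i]))
  res <- region_size_correlations(parts)
  hand_r <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(res$r[res$pair == "lsc~ssc"], hand_r(lsc, ssc), tolerance = 1e-12)
  expect_equal(res$r[res$pair == "ssc~ir"], hand_r(ssc, ir), tolerance = 1e-12)
  expect_equal(res$r2, res$r^2, tolerance = 1e-12)
  ## p-value from the t distribution with df = n - 2
  r <- hand_r(lsc, ssc)
  tstat <- r * sqrt(2 / (1 - r^2))
  expect_equal(res$p[res$pair == "lsc~ssc"],
               2 * stats::pt(-abs(tstat), df = 2), tolerance = 1e-12)

  ## exact linear relations
  y2 <- 2 * lsc
  parts2 <- lapply(1:4, function(i) mkpart(lsc[i] + y2[i] + 2 * ir[i],
                                           y2[i], lsc[i], ir[i]))
  res2 <- region_size_correlations(parts2)
  expect_equal(res2$r[res2$pair == "lsc~ssc"], 1, tolerance = 1e-12)

  expect_error(region_size_correlations(parts[1:2]), "at least 3")
})
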