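## Distance-based tree engine: p/JC69/K2P distances, Saitou-Nei
## neighbor-joining with deterministic tie-breaks, column-resampling
## bootstrap, and bipartition-level tree comparison.

## alignment rows as an integer matrix: A,C,G,T = 1..4, gap/N/other = 0
aln_int_matrix <- function(aln) {
  seqs <- if (inherits(aln, "region_alignment")) aln$seqs else aln
  do.call(rbind, lapply(unname(seqs), dna_to_int))
}

## model-corrected distances on an integer alignment matrix
dist_int <- function(mi, taxa, model) {
  nt <- nrow(mi)
  purine <- mi == 1L | mi == 3L       # A or G
  d <- matrix(0, nt, nt, dimnames = list(taxa, taxa))
  for (i in seq_len(nt - 1L)) for (j in (i + 1L):nt) {
    ok <- mi[i, ] > 0L & mi[j, ] > 0L
    if (!any(ok)) stop("saturation error: no comparable sites for pair ",
                       taxa[[i]], "/", taxa[[j]])
    diff <- mi[i, ok] != mi[j, ok]
    p <- mean(diff)
    dij <- switch(model,
      p = p,
      JC69 = {
        if (p >= 0.75) stop("saturation error: p >= 3/4 for pair ",
                            taxa[[i]], "/", taxa[[j]])
        -0.75 * log(1 - 4 * p / 3)
      },
      K2P = {
        ts <- diff & (purine[i, ok] == purine[j, ok])   # within purines/pyrimidines
        P <- mean(ts); Q <- p - P
        a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
        if (a1 <= 0 || a2 <= 0)
          stop("saturation error: K2P log-domain violation for pair ",
               taxa[[i]], "/", taxa[[j]])
        -0.5 * log(a1 * sqrt(a2))
      })
    d[i, j] <- dij; d[j, i] <- dij
  }
  d
}

#' Pairwise distance matrix from an alignment
#'
#' Gap/N sites are pairwise-deleted. Models: \code{p} (raw proportion),
#' \code{JC69} (-3/4 ln(1 - 4p/3)) and \code{K2P} (from transition and
#' transversion proportions).
#'
#' @param aln [region_alignment()] or named character vector.
#' @param model "p", "JC69" or "K2P".
#' @return list with \code{taxa} and symmetric matrix \code{d}.
#' @export
distance_matrix <- function(aln, model = c("p", "JC69", "K2P")) {
  model <- match.arg(model)
  taxa <- names(if (inherits(aln, "region_alignment")) aln$seqs else aln)
  mi <- aln_int_matrix(aln)
  if (nrow(mi) < 3L) stop("need >= 3 taxa")
  list(taxa = taxa, d = dist_int(mi, taxa, model))
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Standard Q-matrix agglomeration. Ties in Q are broken by the smallest
#' (i, j) index pair; negative branch lengths are clamped to 0 with a
#' warning.
#'
#' @param D result of [distance_matrix()] or a symmetric matrix with
#'   dimnames.
#' @return unrooted \code{ape::phylo} tree.
#' @export
neighbor_joining <- function(D) {
  d <- if (is.list(D)) D$d else D
  labs <- rownames(d)
  m <- nrow(d)
  if (m < 3L) stop("size error: need >= 3 taxa")
  nwk <- labs
  clamp <- function(b) {
    if (b < 0) { warning("negative branch length clamped to 0"); 0 } else b
  }
  fmt <- function(b) sprintf("%.12g", b)
  while (m > 3L) {
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * abs(qmin), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    bi <- clamp(d[i, j] / 2 + (r[[i]] - r[[j]]) / (2 * (m - 2)))
    bj <- clamp(d[i, j] - (d[i, j] / 2 + (r[[i]] - r[[j]]) / (2 * (m - 2))))
    newlab <- paste0("(", nwk[[i]], ":", fmt(bi), ",", nwk[[j]], ":", fmt(bj), ")")
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    nwk <- c(nwk[keep], newlab)
    rownames(d2) <- colnames(d2) <- NULL
    d <- d2
    m <- m - 1L
  }
  b1 <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  b2 <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  b3 <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  txt <- paste0("(", nwk[[1]], ":", fmt(b1), ",", nwk[[2]], ":", fmt(b2),
                ",", nwk[[3]], ":", fmt(b3), ");")
  ape::read.tree(text = txt)
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge induces a split of the tip set; splits are
#' canonicalized by the side that does not contain a fixed reference taxon
#' (the alphabetically first tip) and returned as sorted,
#' comma-joined tip strings. Trivial splits (single tip / complement) are
#' excluded.
#'
#' @param tr \code{ape::phylo}.
#' @return character vector of split keys.
#' @export
tree_splits <- function(tr) {
  nt <- length(tr$tip.label)
  ref <- sort(tr$tip.label)[[1]]
  ## descendant tips per node via postorder accumulation
  po <- ape::reorder.phylo(tr, "postorder")
  desc <- vector("list", nt + tr$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- tr$tip.label[[i]]
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    desc[[par]] <- c(desc[[par]], desc[[ch]])
  }
  keys <- character(0)
  for (e in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[e, 2]
    if (ch <= nt) next                      # pendant edge: trivial split
    side <- desc[[ch]]
    if (length(side) <= 1L || length(side) >= nt - 1L) next
    if (ref %in% side) side <- setdiff(tr$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = ","))
  }
  unique(keys)
}

#' Fraction of reference splits shared by a test tree
#'
#' \code{fraction} = |splits(test) intersect splits(ref)| / |splits(ref)|
#' over non-trivial splits; \code{rf} is the Robinson-Foulds distance
#' (symmetric difference size). Trees with different tip sets are restricted
#' to the intersection (reported in \code{n_shared_tips}).
#'
#' @param test_tree,ref_tree \code{ape::phylo}.
#' @return list fraction/rf/n_ref/n_test/n_shared_tips.
#' @export
shared_split_fraction <- function(test_tree, ref_tree) {
  shared <- intersect(test_tree$tip.label, ref_tree$tip.label)
  if (length(shared) < 4L)
    stop("undefined error: fewer than 4 shared tips")
  if (length(shared) < length(test_tree$tip.label))
    test_tree <- ape::keep.tip(test_tree, shared)
  if (length(shared) < length(ref_tree$tip.label))
    ref_tree <- ape::keep.tip(ref_tree, shared)
  st <- tree_splits(test_tree)
  sr <- tree_splits(ref_tree)
  frac <- if (length(sr)) length(intersect(st, sr)) / length(sr) else NA_real_
  list(fraction = frac,
       rf = length(setdiff(st, sr)) + length(setdiff(sr, st)),
       n_ref = length(sr), n_test = length(st),
       n_shared_tips = length(shared))
}

#' Neighbor-joining with column-resampling bootstrap
#'
#' Builds the point-estimate NJ tree from the full alignment, then
#' \code{n_reps} bootstrap replicates (alignment columns resampled with
#' replacement, seeded; replicate r uses stream offset r). The support of
#' each internal split of the point tree is the percentage of successful
#' replicates whose NJ tree contains it. Replicates hitting distance
#' saturation are skipped and counted.
#'
#' @param aln [region_alignment()] with >= 4 taxa.
#' @param n_reps number of replicates.
#' @param seed integer seed.
#' @param model distance model (see [distance_matrix()]).
#' @return object of class \code{support_tree}: list with \code{tree}
#'   (phylo), \code{support} (named percentage vector keyed by split),
#'   \code{n_reps}, \code{n_skipped}.
#' @export
bootstrap_support <- function(aln, n_reps = 100, seed = 1, model = "K2P") {
  taxa <- names(aln$seqs)
  mi <- aln_int_matrix(aln)
  if (nrow(mi) < 4L) stop("need >= 4 taxa")
  L <- ncol(mi)
  full <- distance_matrix(aln, model = model)
  tr0 <- neighbor_joining(full)
  splits0 <- tree_splits(tr0)
  counts <- setNames(numeric(length(splits0)), splits0)
  skipped <- 0L
  ## sparse per-pair site classes: resampling only reweights columns, so the
  ## per-replicate distances need just the differing/bad column indices
  nt <- nrow(mi)
  purine <- mi == 1L | mi == 3L
  pairs <- which(upper.tri(matrix(0, nt, nt)), arr.ind = TRUE)
  pre <- lapply(seq_len(nrow(pairs)), function(pp) {
    i <- pairs[pp, 1L]; j <- pairs[pp, 2L]
    ok <- mi[i, ] > 0L & mi[j, ] > 0L
    diff <- ok & mi[i, ] != mi[j, ]
    ts <- diff & purine[i, ] == purine[j, ]
    list(i = i, j = j, bad = which(!ok), ts = which(ts), tv = which(diff & !ts))
  })
  boot_dist <- function(w) {
    d <- matrix(0, nt, nt, dimnames = list(taxa, taxa))
    for (pr in pre) {
      L_ok <- L - sum(w[pr$bad])
      if (L_ok <= 0) stop("saturation error: no comparable sites")
      P <- sum(w[pr$ts]) / L_ok
      Q <- sum(w[pr$tv]) / L_ok
      p <- P + Q
      dij <- switch(model,
        p = p,
        JC69 = {
          if (p >= 0.75) stop("saturation error: p >= 3/4")
          -0.75 * log(1 - 4 * p / 3)
        },
        K2P = {
          a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
          if (a1 <= 0 || a2 <= 0) stop("saturation error: K2P log-domain")
          -0.5 * log(a1 * sqrt(a2))
        })
      d[pr$i, pr$j] <- dij; d[pr$j, pr$i] <- dij
    }
    d
  }
  for (r in seq_len(n_reps)) {
    set.seed(stream_seed(seed, 1000L + r))
    idx <- sample.int(L, L, replace = TRUE)
    res <- tryCatch({
      db <- boot_dist(tabulate(idx, L))
      ## replicate trees routinely clamp tiny negative branches: keep quiet
      tree_splits(suppressWarnings(neighbor_joining(db)))
    }, error = function(e) {
      if (grepl("saturation", conditionMessage(e))) NULL else stop(e)
    })
    if (is.null(res)) { skipped <- skipped + 1L; next }
    hit <- splits0 %in% res
    counts[hit] <- counts[hit] + 1
  }
  ok <- n_reps - skipped
  support <- if (ok > 0) 100 * counts / ok else counts * NA_real_
  if (skipped > 0)
    warning(skipped, " bootstrap replicate(s) skipped (distance saturation)")
  structure(list(tree = tr0, support = support, n_reps = n_reps,
                 n_skipped = skipped),
            class = "support_tree")
}

#' @export
print.support_tree <- function(x, ...) {
  cat("<support_tree> ", length(x$tree$tip.label), " tips, ",
      length(x$support), " internal split(s), ", x$n_reps, " replicates",
      if (x$n_skipped) paste0(" (", x$n_skipped, " skipped)") else "", "\n",
      sep = "")
  invisible(x)
}

#' Read / write newick trees
#'
#' Thin wrappers over \pkg{ape}: topology, branch lengths and internal node
#' (support) labels survive a round trip.
#'
#' @param path newick file.
#' @return \code{ape::phylo} (read) or \code{path} invisibly (write).
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path), error = function(e)
    stop("parse error reading newick ", path, ": ", conditionMessage(e)))
  if (is.null(tr)) stop("parse error: no tree in ", path)
  tr
}

#' @rdname read_newick
#' @param tr \code{ape::phylo}.
#' @export
write_newick <- function(tr, path) {
  ape::write.tree(tr, file = path, digits = 12)
  invisible(path)
}
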