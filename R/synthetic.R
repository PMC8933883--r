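## Synthetic plastome families with known ground truth: quadripartite
## layout, junction-flanking marker genes, planted SSR/tandem/pair repeats,
## and Jukes-Cantor evolution along a known tree with region-specific rates.

## derive a deterministic sub-stream seed (< 2^31) for an operation tag
stream_seed <- function(seed, tag) {
  (as.integer(seed) %% 100000000L) * 17L + tag
}

#' Default gene layout for synthetic plastomes
#'
#' Offsets are within-region, 0-based; IRb genes are mirrored automatically
#' into IRa (reverse-complement position, flipped strand). The layout places
#' the junction marker genes (rps19, rpl2, trnH, trnN, trnR, ndhF, rps15,
#' ycf1) in the type I configuration observed across most Aroideae, plus
#' enough ordinary loci to give the diversity/barcode stages named coding
#' regions and intergenic spacers (e.g. atpH-atpI, trnS-trnG, psaC-ndhE).
#'
#' @param lsc_len,ssc_len,ir_len region lengths (bp); used to anchor the
#'   junction-adjacent genes.
#' @return data.frame gene/region/offset/length/strand/kind.
#' @export
default_gene_layout <- function(lsc_len = 91710, ssc_len = 22994,
                                ir_len = 25601) {
  rbind(
    data.frame(gene = "trnH",  region = "LSC", offset = 50L,    length = 75L,   strand = "-", kind = "tRNA"),
    data.frame(gene = "psbA",  region = "LSC", offset = 500L,   length = 1062L, strand = "-", kind = "CDS"),
    data.frame(gene = "matK",  region = "LSC", offset = 2600L,  length = 1530L, strand = "-", kind = "CDS"),
    data.frame(gene = "atpH",  region = "LSC", offset = 9000L,  length = 246L,  strand = "-", kind = "CDS"),
    data.frame(gene = "atpI",  region = "LSC", offset = 10200L, length = 744L,  strand = "-", kind = "CDS"),
    data.frame(gene = "trnS",  region = "LSC", offset = 15000L, length = 88L,   strand = "-", kind = "tRNA"),
    data.frame(gene = "trnG",  region = "LSC", offset = 16100L, length = 71L,   strand = "+", kind = "tRNA"),
    data.frame(gene = "rpoB",  region = "LSC", offset = 20000L, length = 3213L, strand = "-", kind = "CDS"),
    data.frame(gene = "atpA",  region = "LSC", offset = 30000L, length = 1524L, strand = "-", kind = "CDS"),
    data.frame(gene = "rbcL",  region = "LSC", offset = 56000L, length = 1425L, strand = "+", kind = "CDS"),
    data.frame(gene = "psaI",  region = "LSC", offset = 58500L, length = 111L,  strand = "+", kind = "CDS"),
    data.frame(gene = "petA",  region = "LSC", offset = 64000L, length = 963L,  strand = "+", kind = "CDS"),
    data.frame(gene = "psbB",  region = "LSC", offset = 70000L, length = 1527L, strand = "+", kind = "CDS"),
    data.frame(gene = "rps19", region = "LSC", offset = lsc_len - 289L, length = 279L, strand = "-", kind = "CDS"),
    data.frame(gene = "rpl2",  region = "IRb", offset = 60L,    length = 1491L, strand = "-", kind = "CDS"),
    data.frame(gene = "rrn16", region = "IRb", offset = 9000L,  length = 1491L, strand = "+", kind = "rRNA"),
    data.frame(gene = "rrn23", region = "IRb", offset = 12000L, length = 2810L, strand = "+", kind = "rRNA"),
    data.frame(gene = "trnR",  region = "IRb", offset = ir_len - 801L, length = 74L, strand = "+", kind = "tRNA"),
    data.frame(gene = "trnN",  region = "IRb", offset = ir_len - 112L, length = 72L, strand = "-", kind = "tRNA"),
    data.frame(gene = "ndhF",  region = "SSC", offset = 60L,    length = 2241L, strand = "-", kind = "CDS"),
    data.frame(gene = "rpl32", region = "SSC", offset = 3200L,  length = 174L,  strand = "+", kind = "CDS"),
    data.frame(gene = "trnL",  region = "SSC", offset = 4200L,  length = 80L,   strand = "-", kind = "tRNA"),
    data.frame(gene = "ccsA",  region = "SSC", offset = 5400L,  length = 966L,  strand = "+", kind = "CDS"),
    data.frame(gene = "ndhD",  region = "SSC", offset = 7000L,  length = 1503L, strand = "-", kind = "CDS"),
    data.frame(gene = "psaC",  region = "SSC", offset = 9000L,  length = 246L,  strand = "-", kind = "CDS"),
    data.frame(gene = "ndhE",  region = "SSC", offset = 9900L,  length = 306L,  strand = "-", kind = "CDS"),
    data.frame(gene = "ndhG",  region = "SSC", offset = 11000L, length = 531L,  strand = "-", kind = "CDS"),
    data.frame(gene = "ndhI",  region = "SSC", offset = 12200L, length = 543L,  strand = "-", kind = "CDS"),
    data.frame(gene = "ndhA",  region = "SSC", offset = 13500L, length = 1080L, strand = "-", kind = "CDS"),
    data.frame(gene = "ndhH",  region = "SSC", offset = 15200L, length = 1182L, strand = "-", kind = "CDS"),
    data.frame(gene = "rps15", region = "SSC", offset = ssc_len - 5994L, length = 273L, strand = "-", kind = "CDS"),
    data.frame(gene = "ycf1",  region = "SSC", offset = ssc_len - 4994L, length = 4701L, strand = "+", kind = "CDS")
  )
}

#' Default planted-SSR plan
#'
#' Two LSC hotspot spacers (atpH-atpI, trnS-trnG) carry four SSRs each so
#' they satisfy the barcode co-occurrence rule; a cold SSC spacer
#' (ndhG-ndhI) carries three SSRs as a distractor; the rest are background,
#' including one SSR inside IRb (mirrored into IRa by construction).
#'
#' @return data.frame motif/copies/region/offset (within-region, 0-based).
#' @export
default_ssr_plan <- function() {
  rbind(
    data.frame(motif = "A",   copies = 12L, region = "LSC", offset = 9300L),
    data.frame(motif = "AT",  copies = 7L,  region = "LSC", offset = 9400L),
    data.frame(motif = "T",   copies = 11L, region = "LSC", offset = 9500L),
    data.frame(motif = "AAG", copies = 5L,  region = "LSC", offset = 9650L),
    data.frame(motif = "A",   copies = 12L, region = "LSC", offset = 15200L),
    data.frame(motif = "TA",  copies = 7L,  region = "LSC", offset = 15320L),
    data.frame(motif = "C",   copies = 10L, region = "LSC", offset = 15450L),
    data.frame(motif = "AAT", copies = 5L,  region = "LSC", offset = 15600L),
    data.frame(motif = "A",   copies = 10L, region = "LSC", offset = 40000L),
    data.frame(motif = "GA",  copies = 6L,  region = "LSC", offset = 45000L),
    data.frame(motif = "T",   copies = 11L, region = "SSC", offset = 11600L),
    data.frame(motif = "AT",  copies = 6L,  region = "SSC", offset = 11700L),
    data.frame(motif = "A",   copies = 10L, region = "SSC", offset = 11800L),
    data.frame(motif = "A",   copies = 10L, region = "IRb", offset = 20000L)
  )
}

#' Default planted tandem/dispersed/palindromic repeat plan
#'
#' @return data.frame kind/region/offset/offset2/unit_len/copies/length.
#'   \code{offset2} is the second-copy position for pair repeats.
#' @export
default_repeat_plan <- function() {
  rbind(
    data.frame(kind = "dispersed",   region = "LSC", offset = 35000L,
               offset2 = 48000L, unit_len = NA_integer_, copies = NA_integer_, length = 40L),
    data.frame(kind = "palindromic", region = "LSC", offset = 52000L,
               offset2 = 54000L, unit_len = NA_integer_, copies = NA_integer_, length = 40L),
    data.frame(kind = "tandem",      region = "LSC", offset = 60000L,
               offset2 = NA_integer_, unit_len = 12L, copies = 5L, length = 60L)
  )
}

#' Configuration for the synthetic plastome generator
#'
#' Defaults emulate the quadripartite structure of an Aroideae plastome
#' (region lengths and per-region GC from a representative genome), a
#' type I junction layout, an 8-taxon family, and substitution-rate classes
#' chosen so that coding, intergenic and hotspot nucleotide diversity fall
#' in the ranges observed in the subfamily (about 0.04 / 0.10 / 0.25).
#'
#' @param seed RNG seed (integer).
#' @param lsc_len,ssc_len,ir_len region lengths, bp; \code{lsc_len} must
#'   exceed \code{ssc_len}.
#' @param gc named per-region GC fractions (LSC/SSC/IR).
#' @param gene_layout see [default_gene_layout()].
#' @param ssr_plan see [default_ssr_plan()]; NULL for none.
#' @param repeat_plan see [default_repeat_plan()]; NULL for none.
#' @param tree newick string with branch lengths in expected
#'   substitutions/site at rate multiplier 1.
#' @param region_rates list with elements \code{coding}, \code{noncoding},
#'   \code{ir_scale} (multiplier applied on top within the IRs),
#'   \code{hotspot} and \code{hotspot_spacers} (character, "A-B" labels).
#' @param junction_edit one of none/typeII/typeIII/typeIV.
#' @return list of class \code{synth_config}.
#' @export
synth_config <- function(seed = 1L,
                         lsc_len = 91710L, ssc_len = 22994L, ir_len = 25601L,
                         gc = c(LSC = 0.338, SSC = 0.286, IR = 0.423),
                         gene_layout = default_gene_layout(lsc_len, ssc_len, ir_len),
                         ssr_plan = default_ssr_plan(),
                         repeat_plan = default_repeat_plan(),
                         tree = "((t1:0.012,t2:0.012):0.008,((t3:0.012,t4:0.012):0.008,((t5:0.012,t6:0.012):0.008,(t7:0.012,t8:0.012):0.008):0.005):0.003);",
                         region_rates = list(coding = 1, noncoding = 2.6,
                                             ir_scale = 0.3, hotspot = 8,
                                             hotspot_spacers = c("atpH-atpI", "trnS-trnG")),
                         junction_edit = c("none", "typeII", "typeIII", "typeIV")) {
  junction_edit <- match.arg(junction_edit)
  if (lsc_len <= ssc_len) stop("config error: lsc_len must exceed ssc_len")
  for (nm in c("coding", "noncoding", "ir_scale", "hotspot"))
    if (is.null(region_rates[[nm]]) || region_rates[[nm]] < 0)
      stop("config error: region_rates$", nm, " missing or negative")
  cfg <- list(seed = as.integer(seed), lsc_len = as.integer(lsc_len),
              ssc_len = as.integer(ssc_len), ir_len = as.integer(ir_len),
              gc = gc, gene_layout = gene_layout, ssr_plan = ssr_plan,
              repeat_plan = repeat_plan, tree = tree,
              region_rates = region_rates, junction_edit = junction_edit)
  class(cfg) <- "synth_config"
  cfg
}

## sample background bases at a given GC (int codes)
sample_bases <- function(n, gc) {
  sample.int(4L, n, replace = TRUE,
             prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

## random CDS content at the surrounding GC: ATG start, TAA end, internal
## codons resampled until free of stops
random_cds_int <- function(len, gc = 0.35) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  v <- sample_bases(len, gc)
  v[1:3] <- c(1L, 4L, 3L)                        # ATG
  v[(len - 2L):len] <- c(4L, 1L, 1L)             # TAA
  ## stop codons in integer codes: TAA 4-1-1, TAG 4-1-3, TGA 4-3-1
  repeat {
    first <- v[seq(4L, len - 5L, by = 3L)]
    second <- v[seq(5L, len - 4L, by = 3L)]
    third <- v[seq(6L, len - 3L, by = 3L)]
    is_stop <- first == 4L & ((second == 1L & (third == 1L | third == 3L)) |
                                (second == 3L & third == 1L))
    if (!any(is_stop)) break
    for (ci in which(is_stop)) {
      v[(3L * ci + 1L):(3L * ci + 3L)] <- sample_bases(3L, gc)
    }
  }
  v
}

region_start <- function(cfg, region) {
  switch(region,
         LSC = 0L,
         IRb = cfg$lsc_len,
         SSC = cfg$lsc_len + cfg$ir_len,
         IRa = cfg$lsc_len + cfg$ir_len + cfg$ssc_len,
         stop("config error: unknown region ", region))
}

#' Build the synthetic ancestor genome
#'
#' Assembles LSC + IRb + SSC + IRa with IRa the exact reverse complement of
#' IRb, places the configured genes (CDS content is random stop-free codons,
#' so the selection screen has valid ORFs), inserts the planted SSRs and
#' repeats verbatim with non-extendable flanks, and constrains the four
#' junction-flanking bases so the planted IR pair is the unique maximal
#' reverse-complement match. Deterministic under the config seed.
#'
#' @param cfg [synth_config()].
#' @return list with \code{plastome} and \code{truth} (partition, planted
#'   loci, junction label, config echo).
#' @export
build_ancestor <- function(cfg) {
  set.seed(stream_seed(cfg$seed, 1L))
  L <- cfg$lsc_len; I <- cfg$ir_len; S <- cfg$ssc_len
  n <- L + 2L * I + S

  lay <- cfg$gene_layout
  if (!all(lay$region %in% c("LSC", "IRb", "SSC")))
    stop("config error: gene_layout regions must be LSC, IRb or SSC")
  rlen <- c(LSC = L, IRb = I, SSC = S)
  if (any(lay$offset < 0L | lay$offset + lay$length > rlen[lay$region]))
    stop("config error: gene outside its region")
  ## overlap check within each region
  for (rg in unique(lay$region)) {
    sub <- lay[lay$region == rg, ]
    sub <- sub[order(sub$offset), ]
    if (nrow(sub) > 1L && any(sub$offset[-1L] < (sub$offset + sub$length)[-nrow(sub)]))
      stop("config error: overlapping planned genes in ", rg)
  }

  lsc <- sample_bases(L, cfg$gc[["LSC"]])
  irb <- sample_bases(I, cfg$gc[["IR"]])
  ssc <- sample_bases(S, cfg$gc[["SSC"]])
  regs <- list(LSC = lsc, IRb = irb, SSC = ssc)

  ## place gene content
  for (i in seq_len(nrow(lay))) {
    g <- lay[i, ]
    rgc <- cfg$gc[[sub("IRb", "IR", g$region)]]
    content <- if (g$kind == "CDS") random_cds_int(g$length, rgc)
               else sample_bases(g$length, rgc)
    if (g$strand == "-") content <- rev(int_comp(content))
    regs[[g$region]][(g$offset + 1L):(g$offset + g$length)] <- content
  }

  ## planted SSRs (verbatim, with non-extendable flanks)
  ssr_truth <- NULL
  if (!is.null(cfg$ssr_plan) && nrow(cfg$ssr_plan)) {
    for (i in seq_len(nrow(cfg$ssr_plan))) {
      p <- cfg$ssr_plan[i, ]
      unit <- dna_to_int(p$motif)
      m <- length(unit); len <- m * p$copies
      off <- p$offset
      regs[[p$region]][(off + 1L):(off + len)] <- rep(unit, p$copies)
      ## break period-m extension on both flanks
      v <- regs[[p$region]]
      if (off >= 1L && v[off] == v[off + m])
        v[off] <- setdiff(1:4, c(v[off + m], v[off + m + 1L]))[1L]
      if (off + len < length(v) && v[off + len + 1L] == v[off + len + 1L - m])
        v[off + len + 1L] <- setdiff(1:4, c(v[off + len + 1L - m], v[off + len - m]))[1L]
      regs[[p$region]] <- v
      gstart <- region_start(cfg, p$region) + off
      ssr_truth <- rbind(ssr_truth,
                         data.frame(start = gstart, end = gstart + len,
                                    motif = p$motif, copies = p$copies,
                                    region = p$region, stringsAsFactors = FALSE))
    }
  }

  ## planted tandem / dispersed / palindromic repeats
  rep_truth <- NULL
  if (!is.null(cfg$repeat_plan) && nrow(cfg$repeat_plan)) {
    for (i in seq_len(nrow(cfg$repeat_plan))) {
      p <- cfg$repeat_plan[i, ]
      rs <- region_start(cfg, p$region)
      if (p$kind == "tandem") {
        unit <- sample_bases(p$unit_len, 0.45)
        arr <- rep(unit, p$copies)
        regs[[p$region]][(p$offset + 1L):(p$offset + length(arr))] <- arr
        ## break unit-phase extension at the flanks
        v <- regs[[p$region]]
        v[p$offset] <- setdiff(1:4, v[p$offset + p$unit_len])[1L]
        v[p$offset + length(arr) + 1L] <-
          setdiff(1:4, v[p$offset + length(arr) + 1L - p$unit_len])[1L]
        regs[[p$region]] <- v
        rep_truth <- rbind(rep_truth,
                           data.frame(kind = "tandem", start = rs + p$offset,
                                      end = rs + p$offset + length(arr),
                                      start2 = NA_integer_, end2 = NA_integer_,
                                      unit_len = p$unit_len, stringsAsFactors = FALSE))
      } else {
        seg <- sample_bases(p$length, 0.45)
        seg2 <- if (p$kind == "palindromic") rev(int_comp(seg)) else seg
        regs[[p$region]][(p$offset + 1L):(p$offset + p$length)] <- seg
        regs[[p$region]][(p$offset2 + 1L):(p$offset2 + p$length)] <- seg2
        ## make the copies non-extendable: two contrasting bases per flank so
        ## seed-and-extend stops exactly at the planted boundaries
        v <- regs[[p$region]]
        for (t in 0:1) {
          if (p$kind == "dispersed") {
            if (v[p$offset - t] == v[p$offset2 - t])
              v[p$offset2 - t] <- setdiff(1:4, v[p$offset - t])[1L]
            if (v[p$offset + p$length + 1L + t] == v[p$offset2 + p$length + 1L + t])
              v[p$offset2 + p$length + 1L + t] <-
                setdiff(1:4, v[p$offset + p$length + 1L + t])[1L]
          } else {
            if (v[p$offset - t] == int_comp(v[p$offset2 + p$length + 1L + t]))
              v[p$offset2 + p$length + 1L + t] <-
                setdiff(1:4, int_comp(v[p$offset - t]))[1L]
            if (v[p$offset + p$length + 1L + t] == int_comp(v[p$offset2 - t]))
              v[p$offset2 - t] <-
                setdiff(1:4, int_comp(v[p$offset + p$length + 1L + t]))[1L]
          }
        }
        regs[[p$region]] <- v
        rep_truth <- rbind(rep_truth,
                           data.frame(kind = p$kind, start = rs + p$offset,
                                      end = rs + p$offset + p$length,
                                      start2 = rs + p$offset2,
                                      end2 = rs + p$offset2 + p$length,
                                      unit_len = NA_integer_, stringsAsFactors = FALSE))
      }
    }
  }

  ## assemble: LSC + IRb + SSC + IRa, IRa = rc(IRb); mirror IRb SSRs into IRa truth
  ira <- rev(int_comp(regs$IRb))
  genome <- c(regs$LSC, regs$IRb, regs$SSC, ira)

  ## junction contrast: LSC first/last and SSC first/last must not allow the
  ## IR pair to extend by one base into the single-copy regions
  fix_contrast <- function(genome, first_i, last_i) {
    if (genome[first_i] == int_comp(genome[last_i]))
      genome[first_i] <- setdiff(1:4, int_comp(genome[last_i]))[1L]
    genome
  }
  genome <- fix_contrast(genome, 1L, L)                       # LSC ends
  genome <- fix_contrast(genome, L + I + 1L, L + I + S)       # SSC ends

  if (!is.null(ssr_truth)) {
    irb_rows <- ssr_truth[ssr_truth$region == "IRb", , drop = FALSE]
    if (nrow(irb_rows)) {
      off_in_ir <- irb_rows$start - L
      len <- irb_rows$end - irb_rows$start
      mir_start <- (L + I + S) + (I - (off_in_ir + len))
      mir <- data.frame(start = mir_start, end = mir_start + len,
                        motif = vapply(irb_rows$motif, seq_rc, ""),
                        copies = irb_rows$copies, region = "IRa",
                        stringsAsFactors = FALSE)
      rownames(mir) <- NULL
      ssr_truth <- rbind(ssr_truth, mir)
    }
  }

  ## gene table: LSC/IRb/SSC as planned, IRb genes mirrored into IRa
  gl <- lay
  gstart <- vapply(seq_len(nrow(gl)), function(i)
    region_start(cfg, gl$region[[i]]) + gl$offset[[i]], 0L)
  genes <- gene_table(gl$gene, gstart, gstart + gl$length, gl$strand, gl$kind)
  irg <- lay[lay$region == "IRb", , drop = FALSE]
  if (nrow(irg)) {
    mstart <- (L + I + S) + (I - (irg$offset + irg$length))
    genes <- rbind(genes,
                   gene_table(irg$gene, mstart, mstart + irg$length,
                              ifelse(irg$strand == "+", "-", "+"), irg$kind))
  }
  genes <- genes[order(genes$start), ]; rownames(genes) <- NULL

  part <- new_partition(n,
                        lsc = c(start = 0L, end = L),
                        irb = c(start = L, end = L + I),
                        ssc = c(start = L + I, end = L + I + S),
                        ira = c(start = L + I + S, end = n))
  p <- plastome("ancestor", int_to_dna(genome), circular = TRUE, genes = genes)
  truth <- list(partition = part, ssrs = ssr_truth, repeats = rep_truth,
                junction_type = "I", tree = cfg$tree, config = cfg)
  list(plastome = p, truth = truth)
}

## assemble a new genome from oriented pieces of an old one and remap
## annotations/planted loci. pieces: list of list(src = c(start, end), rc =
## TRUE/FALSE) in old 0-based half-open coordinates, emitted in order.
assemble_genome <- function(p, pieces, id = p$id) {
  v <- dna_to_int(p$seq)
  segs <- lapply(pieces, function(pc) {
    s <- v[(pc$src[[1]] + 1L):pc$src[[2]]]
    if (isTRUE(pc$rc)) rev(int_comp(s)) else s
  })
  new_starts <- cumsum(c(0L, head(lengths(segs), -1L)))
  newseq <- int_to_dna(unlist(segs))

  map_interval <- function(s, e) {
    out <- NULL
    for (i in seq_along(pieces)) {
      pc <- pieces[[i]]
      if (s >= pc$src[[1]] && e <= pc$src[[2]]) {
        if (isTRUE(pc$rc)) {
          ns <- new_starts[[i]] + (pc$src[[2]] - e)
          out <- rbind(out, data.frame(start = ns, end = ns + (e - s), rc = TRUE))
        } else {
          ns <- new_starts[[i]] + (s - pc$src[[1]])
          out <- rbind(out, data.frame(start = ns, end = ns + (e - s), rc = FALSE))
        }
      }
    }
    out
  }

  g <- p$genes
  rows <- list()
  for (i in seq_len(nrow(g))) {
    hits <- map_interval(g$start[[i]], g$end[[i]])
    if (is.null(hits)) next
    for (j in seq_len(nrow(hits))) {
      strand <- if (hits$rc[[j]]) (if (g$strand[[i]] == "+") "-" else "+") else g$strand[[i]]
      rows[[length(rows) + 1L]] <-
        gene_table(g$name[[i]], hits$start[[j]], hits$end[[j]], strand, g$kind[[i]])
    }
  }
  genes <- if (length(rows)) do.call(rbind, rows) else gene_table()
  genes <- genes[order(genes$start), ]; rownames(genes) <- NULL
  list(plastome = plastome(id, newseq, circular = TRUE, genes = genes),
       map_interval = map_interval)
}

#' Apply a junction-type edit to a synthetic ancestor
#'
#' Transforms a canonical type I genome into one of the other boundary
#' configurations: \code{typeII} expands both IRs into the SSC (the prefix
#' up to mid-ndhF and the suffix from just past rps15, duplicating ycf1 into
#' the IRs); \code{typeIII} contracts the IRs by deleting the IRa terminus
#' that carried trnN, leaving a single trnN copy at the SSC edge; and
#' \code{typeIV} reverse-complements the SSC segment (an involution).
#'
#' @param p canonical ancestor plastome (from [build_ancestor()]).
#' @param truth its truth record.
#' @param kind typeII, typeIII or typeIV.
#' @return list with updated \code{plastome} and \code{truth}.
#' @export
apply_junction_edit <- function(p, truth, kind = c("typeII", "typeIII", "typeIV")) {
  kind <- match.arg(kind)
  part <- truth$partition
  n <- part$genome_length
  L <- region_width(part$lsc); I <- region_width(part$irb)
  S <- region_width(part$ssc)
  sscs <- part$ssc[["start"]]
  g <- p$genes
  find_gene <- function(nm, lo, hi) {
    k <- which(gene_matches(g$name, nm) & g$start >= lo & g$end <= hi)
    if (!length(k)) stop("config error: gene ", nm, " not found in [", lo, ",", hi, ")")
    g[k[[1L]], ]
  }

  if (kind == "typeIV") {
    out <- assemble_genome(p, list(
      list(src = c(0L, sscs), rc = FALSE),
      list(src = c(sscs, sscs + S), rc = TRUE),
      list(src = c(sscs + S, n), rc = FALSE)), id = p$id)
    truth2 <- truth
    truth2$junction_type <- if (truth$junction_type == "IV") "I" else "IV"
    truth2 <- remap_truth(truth2, out$map_interval, part)
    truth2$partition <- part   # same region geometry
    return(list(plastome = out$plastome, truth = truth2))
  }

  if (kind == "typeII") {
    ndhF <- find_gene("ndhF", sscs, sscs + S)
    rps15 <- find_gene("rps15", sscs, sscs + S)
    ycf1 <- find_gene("ycf1", sscs, sscs + S)
    d2 <- (ndhF$start + (ndhF$end - ndhF$start) %/% 2L) - sscs  # cut mid-ndhF
    tt <- (rps15$end + ycf1$start) %/% 2L - sscs                # cut before ycf1
    if (tt <= d2) stop("config error: typeII cuts would empty the SSC")
    ## new genome: L | Rb rc(Q) P | S'' | rc(P) Q Ra
    out <- assemble_genome(p, list(
      list(src = c(0L, sscs), rc = FALSE),                    # LSC + IRb
      list(src = c(sscs + tt, sscs + S), rc = TRUE),          # rc(Q)
      list(src = c(sscs, sscs + tt), rc = FALSE),             # P + S''
      list(src = c(sscs, sscs + d2), rc = TRUE),              # rc(P)
      list(src = c(sscs + tt, sscs + S), rc = FALSE),         # Q
      list(src = c(sscs + S, n), rc = FALSE)), id = p$id)     # IRa
    qlen <- S - tt
    I2 <- I + qlen + d2
    S2 <- tt - d2
    n2 <- L + 2L * I2 + S2
    part2 <- new_partition(n2,
                           lsc = c(start = 0L, end = L),
                           irb = c(start = L, end = L + I2),
                           ssc = c(start = L + I2, end = L + I2 + S2),
                           ira = c(start = L + I2 + S2, end = n2))
    pl <- out$plastome
    v <- dna_to_int(pl$seq)
    if (v[L + I2 + 1L] == int_comp(v[L + I2 + S2]))
      v[L + I2 + 1L] <- setdiff(1:4, int_comp(v[L + I2 + S2]))[1L]
    pl <- plastome(pl$id, int_to_dna(v), circular = TRUE, genes = pl$genes)
    truth2 <- remap_truth(truth, out$map_interval, part2)
    truth2$junction_type <- "II"
    truth2$partition <- part2
    return(list(plastome = pl, truth = truth2))
  }

  ## typeIII: delete the IRa-initial segment containing the trnN copy
  iras <- part$ira[["start"]]
  trnNa <- find_gene("trnN", iras, n)
  trnRa <- find_gene("trnR", iras, n)
  d <- (trnNa$end + trnRa$start) %/% 2L - iras   # cut between trnN' and trnR'
  if (d <= 0L || d >= I) stop("config error: typeIII cut outside the IR")
  out <- assemble_genome(p, list(
    list(src = c(0L, iras), rc = FALSE),
    list(src = c(iras + d, n), rc = FALSE)), id = p$id)
  I3 <- I - d
  S3 <- S + d
  n3 <- n - d
  if (L <= S3) stop("config error: typeIII edit would make SSC >= LSC")
  part3 <- new_partition(n3,
                         lsc = c(start = 0L, end = L),
                         irb = c(start = L, end = L + I3),
                         ssc = c(start = L + I3, end = L + I3 + S3),
                         ira = c(start = L + I3 + S3, end = n3))
  pl <- out$plastome
  v <- dna_to_int(pl$seq)
  if (v[L + I3 + 1L] == int_comp(v[L + I3 + S3]))
    v[L + I3 + 1L] <- setdiff(1:4, int_comp(v[L + I3 + S3]))[1L]
  pl <- plastome(pl$id, int_to_dna(v), circular = TRUE, genes = pl$genes)
  truth2 <- remap_truth(truth, out$map_interval, part3)
  truth2$junction_type <- "III"
  truth2$partition <- part3
  list(plastome = pl, truth = truth2)
}

## remap planted SSR/repeat truth through an assemble_genome interval map
remap_truth <- function(truth, map_interval, new_part) {
  remap_ssrs <- function(df) {
    if (is.null(df)) return(NULL)
    rows <- list()
    for (i in seq_len(nrow(df))) {
      hits <- map_interval(df$start[[i]], df$end[[i]])
      if (is.null(hits)) next
      for (j in seq_len(nrow(hits))) {
        motif <- if (hits$rc[[j]]) seq_rc(df$motif[[i]]) else df$motif[[i]]
        rows[[length(rows) + 1L]] <-
          data.frame(start = hits$start[[j]], end = hits$end[[j]],
                     motif = motif, copies = df$copies[[i]],
                     region = region_of(hits$start[[j]], new_part),
                     stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  }
  remap_reps <- function(df) {
    if (is.null(df)) return(NULL)
    rows <- list()
    for (i in seq_len(nrow(df))) {
      h1 <- map_interval(df$start[[i]], df$end[[i]])
      if (is.null(h1)) next
      r <- df[i, ]
      r$start <- h1$start[[1L]]; r$end <- h1$end[[1L]]
      if (!is.na(df$start2[[i]])) {
        h2 <- map_interval(df$start2[[i]], df$end2[[i]])
        if (is.null(h2)) next
        r$start2 <- h2$start[[1L]]; r$end2 <- h2$end[[1L]]
      }
      rows[[length(rows) + 1L]] <- r
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  }
  truth$ssrs <- remap_ssrs(truth$ssrs)
  truth$repeats <- remap_reps(truth$repeats)
  truth
}

#' Which quadripartite region contains a position
#' @param pos 0-based position.
#' @param part quadripartition (canonical).
#' @return "LSC", "IRb", "SSC" or "IRa".
#' @export
region_of <- function(pos, part) {
  for (nm in c("lsc", "irb", "ssc", "ira")) {
    r <- part[[nm]]
    if (pos >= r[["start"]] && pos < r[["end"]])
      return(c(lsc = "LSC", irb = "IRb", ssc = "SSC", ira = "IRa")[[nm]])
  }
  stop("position ", pos, " outside the genome")
}

## per-site substitution-rate multipliers from truth (IRa zeroed: it is
## synchronized to IRb after mutation, i.e. the IRs evolve in concert)
site_rates <- function(p, truth, region_rates) {
  part <- truth$partition
  n <- part$genome_length
  r <- rep(region_rates$noncoding, n)
  g <- p$genes
  for (i in seq_len(nrow(g)))
    r[(g$start[[i]] + 1L):g$end[[i]]] <- region_rates$coding
  ## hotspot spacers: intergenic gap between the named gene pair
  for (sp in region_rates$hotspot_spacers %||% character()) {
    ab <- strsplit(sp, "-", fixed = TRUE)[[1]]
    ga <- g[gene_matches(g$name, ab[[1]]), ]
    gb <- g[gene_matches(g$name, ab[[2]]), ]
    if (!nrow(ga) || !nrow(gb)) next
    if (ga$start[[1L]] <= gb$start[[1L]]) {
      lo <- ga$end[[1L]]; hi <- gb$start[[1L]]
    } else {
      lo <- gb$end[[1L]]; hi <- ga$start[[1L]]
    }
    if (hi > lo) r[(lo + 1L):hi] <- region_rates$hotspot
  }
  ## IR scaling, then freeze IRa (concerted with IRb)
  irb <- part$irb; ira <- part$ira
  r[(irb[["start"]] + 1L):irb[["end"]]] <-
    r[(irb[["start"]] + 1L):irb[["end"]]] * region_rates$ir_scale
  r[(ira[["start"]] + 1L):min(ira[["end"]], n)] <- 0
  ## planted repeat loci are substitution-free (slippage out of scope); the
  ## flanking bases are frozen too so the planted runs stay maximal at their
  ## recorded coordinates in every tip
  freeze <- function(a, b) r[max(1L, a + 1L):min(n, b)] <<- 0
  if (!is.null(truth$ssrs))
    for (i in seq_len(nrow(truth$ssrs)))
      freeze(truth$ssrs$start[[i]] - 1L, truth$ssrs$end[[i]] + 1L)
  if (!is.null(truth$repeats))
    for (i in seq_len(nrow(truth$repeats))) {
      freeze(truth$repeats$start[[i]] - 2L, truth$repeats$end[[i]] + 2L)
      if (!is.na(truth$repeats$start2[[i]]))
        freeze(truth$repeats$start2[[i]] - 2L, truth$repeats$end2[[i]] + 2L)
    }
  ## junction-contrast guard bases stay fixed
  L <- region_width(part$lsc); I <- region_width(part$irb); S <- region_width(part$ssc)
  r[c(1L, L, L + I + 1L, L + I + S)] <- 0
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## apply Poisson(JC) substitutions to an int sequence for one branch
jc_mutate <- function(v, rates_idx, b) {
  ## rates_idx: list(rate = numeric, sites = list of integer vectors)
  for (k in seq_along(rates_idx$rate)) {
    rate <- rates_idx$rate[[k]]
    sites <- rates_idx$sites[[k]]
    mu <- b * rate
    if (mu <= 0 || !length(sites)) next
    nev <- rpois(1L, mu * length(sites))
    if (nev == 0L) next
    pos <- sample(sites, nev, replace = TRUE)
    while (length(pos)) {
      first <- !duplicated(pos)
      pp <- pos[first]
      d <- sample.int(3L, length(pp), replace = TRUE)
      v[pp] <- ((v[pp] - 1L + d) %% 4L) + 1L
      pos <- pos[!first]
    }
  }
  v
}

#' Evolve a plastome family along a tree under Jukes-Cantor
#'
#' Applies Poisson-process JC69 substitutions per site along each branch
#' with expected count = branch length x site-rate multiplier. No indels,
#' so all tips stay positionally aligned to the ancestor and the truth
#' coordinates hold in every tip. The IRs evolve in concert (IRb mutations
#' are mirrored into IRa, keeping the copies exact reverse complements) and
#' planted repeat loci are substitution-free. Deterministic under
#' \code{seed}.
#'
#' @param ancestor plastome (canonical).
#' @param truth its truth record.
#' @param tree newick string; defaults to the config tree.
#' @param region_rates rate-class list; defaults to the config's.
#' @param seed integer; defaults to the config seed.
#' @return list with \code{tips} (named list of plastomes), \code{truth}
#'   (with the tree attached) and \code{tree} (ape phylo).
#' @export
evolve_family <- function(ancestor, truth, tree = NULL, region_rates = NULL,
                          seed = NULL) {
  cfg <- truth$config
  tree <- tree %||% cfg$tree
  region_rates <- region_rates %||% cfg$region_rates
  seed <- seed %||% cfg$seed
  tr <- if (inherits(tree, "phylo")) tree else ape::read.tree(text = tree)
  if (is.null(tr)) stop("config error: unparsable tree")
  if (length(tr$tip.label) < 3L) stop("config error: tree needs >= 3 tips")
  if (is.null(tr$edge.length) || any(tr$edge.length < 0))
    stop("config error: tree needs nonnegative branch lengths")

  set.seed(stream_seed(seed, 2L))
  part <- truth$partition
  n <- part$genome_length
  r <- site_rates(ancestor, truth, region_rates)
  classes <- split(seq_len(n), r)
  rates_idx <- list(rate = as.numeric(names(classes)), sites = unname(classes))

  tr2 <- ape::reorder.phylo(tr, "cladewise")   # parents precede children
  nt <- length(tr2$tip.label)
  root <- nt + 1L
  seqs <- vector("list", nt + tr2$Nnode)
  seqs[[root]] <- dna_to_int(ancestor$seq)
  for (e in seq_len(nrow(tr2$edge))) {
    par <- tr2$edge[e, 1L]; ch <- tr2$edge[e, 2L]
    seqs[[ch]] <- jc_mutate(seqs[[par]], rates_idx, tr2$edge.length[[e]])
  }

  irb <- part$irb; ira <- part$ira
  tips <- setNames(vector("list", nt), tr2$tip.label)
  for (i in seq_len(nt)) {
    v <- seqs[[i]]
    v[(ira[["start"]] + 1L):ira[["end"]]] <-
      rev(int_comp(v[(irb[["start"]] + 1L):irb[["end"]]]))
    tips[[i]] <- plastome(tr2$tip.label[[i]], int_to_dna(v),
                          circular = TRUE, genes = ancestor$genes)
  }
  truth$tree <- tree
  list(tips = tips, truth = truth, tree = tr)
}

#' Configurations for a panel of plastomes with varied region sizes
#'
#' Emulates the between-species size variation of a plastome family: most
#' size change is driven by IR boundary shifts into or out of the SSC (an
#' IR gain is an SSC loss), with smaller independent variation of the LSC
#' and SSC. This reproduces the strong negative SSC~IR coupling observed
#' across such families, against nearly independent LSC variation.
#'
#' @param seed RNG seed.
#' @param n number of genomes.
#' @param lsc_len,ssc_len,ir_len central region lengths (bp).
#' @param ir_shift_range uniform range (bp) of the IR boundary shift; a
#'   positive shift expands the IRs at the SSC's expense.
#' @param lsc_sd,ssc_sd SDs of the independent LSC/SSC perturbations (bp).
#' @param ... passed to [synth_config()] (e.g. junction_edit, plans).
#' @return list of [synth_config()] objects.
#' @export
synth_size_panel <- function(seed, n = 17, lsc_len = 91710L,
                             ssc_len = 22994L, ir_len = 25601L,
                             ir_shift_range = c(-900L, 500L),
                             lsc_sd = 300, ssc_sd = 80, ...) {
  set.seed(stream_seed(seed, 3L))
  lapply(seq_len(n), function(i) {
    dlt <- as.integer(round(runif(1L, ir_shift_range[[1]], ir_shift_range[[2]])))
    lsc <- as.integer(round(lsc_len + stats::rnorm(1L, 0, lsc_sd)))
    ssc <- as.integer(max(ssc_len - 560L,
                          round(ssc_len - dlt + stats::rnorm(1L, 0, ssc_sd))))
    ir <- as.integer(ir_len + dlt)
    synth_config(seed = stream_seed(seed, 100L + i), lsc_len = lsc,
                 ssc_len = ssc, ir_len = ir,
                 gene_layout = default_gene_layout(lsc, ssc, ir), ...)
  })
}

#' Generate a complete synthetic family in one call
#'
#' [build_ancestor()], optional [apply_junction_edit()], then
#' [evolve_family()].
#'
#' @param cfg [synth_config()].
#' @return list with \code{ancestor}, \code{tips}, \code{truth}, \code{tree}.
#' @export
synth_family <- function(cfg) {
  anc <- build_ancestor(cfg)
  if (cfg$junction_edit != "none") {
    ed <- apply_junction_edit(anc$plastome, anc$truth,
                              kind = cfg$junction_edit)
    anc <- list(plastome = ed$plastome, truth = ed$truth)
  }
  fam <- evolve_family(anc$plastome, anc$truth)
  list(ancestor = anc$plastome, tips = fam$tips, truth = fam$truth,
       tree = fam$tree)
}
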