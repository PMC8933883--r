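# Compact synthetic configuration: same quadripartite layout, marker genes,
# hotspot spacers and planted repeats as the default, at ~32 kb so loops over
# many seeded families stay fast.
small_layout <- function(lsc_len = 16000L, ssc_len = 7000L, ir_len = 4500L) {
  rbind(
    data.frame(gene = "trnH",  region = "LSC", offset = 50L,   length = 75L,   strand = "-", kind = "tRNA"),
    data.frame(gene = "psbA",  region = "LSC", offset = 500L,  length = 501L,  strand = "-", kind = "CDS"),
    data.frame(gene = "atpH",  region = "LSC", offset = 3000L, length = 246L,  strand = "-", kind = "CDS"),
    data.frame(gene = "atpI",  region = "LSC", offset = 4200L, length = 744L,  strand = "-", kind = "CDS"),
    data.frame(gene = "trnS",  region = "LSC", offset = 6000L, length = 88L,   strand = "-", kind = "tRNA"),
    data.frame(gene = "trnG",  region = "LSC", offset = 7100L, length = 71L,   strand = "+", kind = "tRNA"),
    data.frame(gene = "rbcL",  region = "LSC", offset = 9000L, length = 1425L, strand = "+", kind = "CDS"),
    data.frame(gene = "rps19", region = "LSC", offset = lsc_len - 289L, length = 279L, strand = "-", kind = "CDS"),
    data.frame(gene = "rpl2",  region = "IRb", offset = 60L,   length = 1491L, strand = "-", kind = "CDS"),
    data.frame(gene = "rrn16", region = "IRb", offset = 1700L, length = 1491L, strand = "+", kind = "rRNA"),
    data.frame(gene = "trnR",  region = "IRb", offset = 3700L, length = 74L,   strand = "+", kind = "tRNA"),
    data.frame(gene = "trnN",  region = "IRb", offset = ir_len - 112L, length = 72L, strand = "-", kind = "tRNA"),
    data.frame(gene = "ndhF",  region = "SSC", offset = 60L,   length = 2241L, strand = "-", kind = "CDS"),
    data.frame(gene = "psaC",  region = "SSC", offset = 2500L, length = 246L,  strand = "-", kind = "CDS"),
    data.frame(gene = "ndhE",  region = "SSC", offset = 3000L, length = 306L,  strand = "-", kind = "CDS"),
    data.frame(gene = "ndhG",  region = "SSC", offset = 3500L, length = 531L,  strand = "-", kind = "CDS"),
    data.frame(gene = "ndhI",  region = "SSC", offset = 4200L, length = 543L,  strand = "-", kind = "CDS"),
    data.frame(gene = "rps15", region = "SSC", offset = 5000L, length = 273L,  strand = "-", kind = "CDS"),
    data.frame(gene = "ycf1",  region = "SSC", offset = 5900L, length = 900L,  strand = "+", kind = "CDS")
  )
}

small_ssr_plan <- function() {
  rbind(
    data.frame(motif = "A",   copies = 12L, region = "LSC", offset = 3300L),
    data.frame(motif = "AT",  copies = 7L,  region = "LSC", offset = 3400L),
    data.frame(motif = "T",   copies = 11L, region = "LSC", offset = 3500L),
    data.frame(motif = "AAG", copies = 5L,  region = "LSC", offset = 3650L),
    data.frame(motif = "A",   copies = 12L, region = "LSC", offset = 6200L),
    data.frame(motif = "TA",  copies = 7L,  region = "LSC", offset = 6320L),
    data.frame(motif = "C",   copies = 10L, region = "LSC", offset = 6450L),
    data.frame(motif = "AAT", copies = 5L,  region = "LSC", offset = 6600L),
    data.frame(motif = "A",   copies = 10L, region = "LSC", offset = 12000L),
    data.frame(motif = "GA",  copies = 6L,  region = "LSC", offset = 13000L),
    data.frame(motif = "T",   copies = 11L, region = "SSC", offset = 4050L),
    data.frame(motif = "AT",  copies = 6L,  region = "SSC", offset = 4080L),
    data.frame(motif = "A",   copies = 10L, region = "SSC", offset = 4110L),
    data.frame(motif = "A",   copies = 10L, region = "IRb", offset = 3300L)
  )
}

small_repeat_plan <- function() {
  rbind(
    data.frame(kind = "dispersed",   region = "LSC", offset = 10500L,
               offset2 = 14000L, unit_len = NA_integer_, copies = NA_integer_, length = 40L),
    data.frame(kind = "palindromic", region = "LSC", offset = 11000L,
               offset2 = 11500L, unit_len = NA_integer_, copies = NA_integer_, length = 40L),
    data.frame(kind = "tandem",      region = "LSC", offset = 12500L,
               offset2 = NA_integer_, unit_len = 12L, copies = 5L, length = 60L)
  )
}

small_cfg <- function(seed, junction_edit = "none", ...) {
  args <- list(seed = seed, lsc_len = 16000L, ssc_len = 7000L, ir_len = 4500L,
               gene_layout = small_layout(), ssr_plan = small_ssr_plan(),
               repeat_plan = small_repeat_plan(), junction_edit = junction_edit)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synth_config, args)
}

partition_coords <- function(part) {
  as.integer(unlist(part[c("lsc", "irb", "ssc", "ira")]))
}

# ---- Independent oracles ---------------------------------------------------

# brute-force SSR scanner: per-position unit extension, leftmost-phase and
# primitive-unit filters applied explicitly
oracle_ssrs <- function(seq, thresholds = c(`1` = 10L, `2` = 5L, `3` = 4L,
                                            `4` = 3L, `5` = 3L, `6` = 3L)) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(v)
  prim <- function(u) {
    m <- length(u)
    for (p in seq_len(m - 1L)) {
      if (m %% p == 0L && all(u == rep(u[seq_len(p)], m %/% p))) return(FALSE)
    }
    TRUE
  }
  canon <- function(u) {
    m <- length(u)
    min(vapply(seq_len(m), function(i)
      paste(c(u[i:m], u[seq_len(i - 1L)])[1:m], collapse = ""), ""))
  }
  out <- list()
  for (m in 1:6) {
    thr <- thresholds[[as.character(m)]]
    for (i in seq_len(n - m * thr + 1L)) {
      unit <- v[i:(i + m - 1L)]
      if (any(!unit %in% c("A", "C", "G", "T"))) next
      cp <- 1L
      while (i + (cp + 1L) * m - 1L <= n &&
             all(v[(i + cp * m):(i + (cp + 1L) * m - 1L)] == unit)) cp <- cp + 1L
      if (cp < thr) next
      if (i > 1L && v[i - 1L] == v[i + m - 1L]) next   # not leftmost phase
      if (!prim(unit)) next
      out[[length(out) + 1L]] <-
        data.frame(start = i - 1L, end = i - 1L + cp * m,
                   motif = canon(unit), copies = cp, class = m,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(), motif = character(),
                      copies = integer(), class = integer()))
  res <- unique(do.call(rbind, out))
  res <- res[order(res$start, res$class), ]
  rownames(res) <- NULL
  res
}

# exhaustive-pathway NG86: recursion over orderings of the differing codon
# positions (blocked at intermediate stops, falling back to every pathway),
# site counts by enumerating all nine single-base mutations per codon
oracle_ng86 <- function(a, b, code = "11") {
  gctab <- Biostrings::getGeneticCode(code)
  aa <- function(cod) gctab[[cod]]
  cods_a <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cods_b <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  syn_sites <- function(cod) {
    s <- 0
    for (k in 1:3) for (bb in c("A", "C", "G", "T")) {
      if (bb == substr(cod, k, k)) next
      alt <- cod; substr(alt, k, k) <- bb
      if (aa(alt) != "*" && aa(alt) == aa(cod)) s <- s + 1 / 3
    }
    s
  }
  paths <- function(cur, target, allow_stop) {
    pos <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (!length(pos)) return(list(c(syn = 0, nonsyn = 0)))
    res <- list()
    for (k in pos) {
      nxt <- cur; substr(nxt, k, k) <- substr(target, k, k)
      if (!allow_stop && aa(nxt) == "*") next
      step <- if (aa(nxt) != "*" && aa(nxt) == aa(cur)) c(syn = 1, nonsyn = 0)
              else c(syn = 0, nonsyn = 1)
      for (sb in paths(nxt, target, allow_stop))
        res[[length(res) + 1L]] <- step + sb
    }
    res
  }
  S <- 0; Sd <- 0; Nd <- 0; used <- 0
  for (i in seq_along(cods_a)) {
    ca <- cods_a[[i]]; cb <- cods_b[[i]]
    if (aa(ca) == "*" || aa(cb) == "*") next
    used <- used + 1
    S <- S + (syn_sites(ca) + syn_sites(cb)) / 2
    pw <- paths(ca, cb, allow_stop = FALSE)
    if (!length(pw)) pw <- paths(ca, cb, allow_stop = TRUE)
    avg <- colMeans(do.call(rbind, pw))
    Sd <- Sd + avg[["syn"]]; Nd <- Nd + avg[["nonsyn"]]
  }
  N <- 3 * used - S
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  list(ka = jc(if (N > 0) Nd / N else 0), ks = jc(if (S > 0) Sd / S else 0),
       S = S, N = N, Sd = Sd, Nd = Nd)
}

# random stop-free in-frame CDS for Ka/Ks tests
random_cds <- function(ncodons, seed) {
  set.seed(seed)
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  codons <- setdiff(codons, stops)
  paste(sample(codons, ncodons, replace = TRUE), collapse = "")
}

# mutate a CDS at k random positions avoiding stop codons in the result
mutate_cds <- function(cds, k, seed) {
  set.seed(seed)
  gctab <- Biostrings::getGeneticCode("11")
  v <- strsplit(cds, "", fixed = TRUE)[[1]]
  done <- 0L; guard <- 0L
  while (done < k && guard < 1000L) {
    guard <- guard + 1L
    p <- sample(length(v), 1L)
    old <- v[[p]]
    v[[p]] <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    cod_i <- (p - 1L) %/% 3L
    cod <- paste(v[(cod_i * 3L + 1L):(cod_i * 3L + 3L)], collapse = "")
    if (gctab[[cod]] == "*") v[[p]] <- old else done <- done + 1L
  }
  paste(v, collapse = "")
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
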