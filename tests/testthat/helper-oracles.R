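# Independent oracles and small fixture builders used across the suite.

# Brute-force Benjamini-Hochberg: sort, cummin from the largest p, unsort.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  run_min <- 1
  for (i in m:1) {
    run_min <- min(run_min, sorted[i] * m / i)
    adj[i] <- run_min
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exhaustive enumeration of all antiparallel miRNA/site alignments with at
# most one contiguous bulge, scored from base-pairing first principles
# (miRNA base a against target base t: Watson-Crick iff t == complement(a),
# G:U wobble iff {a=G,t=T} or {a=T,t=G}). The target is walked from its
# 3' end so that miRNA position 1 meets the site's 3' terminus.
mirna_score_oracle <- function(mirna, window, seed_start = 2, seed_end = 13,
                               mismatch = 1, wobble = 0.5, gap = 2) {
  norm <- function(x) strsplit(toupper(gsub("U", "T", x)), "")[[1]]
  m <- norm(mirna)
  tgt <- rev(norm(window))  # reversed only: antiparallel walk
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  wt <- function(pos) if (pos >= seed_start && pos <= seed_end) 2 else 1
  pen <- function(a, t) {
    if (comp[[a]] == t) 0
    else if ((a == "G" && t == "T") || (a == "T" && t == "G")) wobble
    else mismatch
  }
  M <- length(m); W <- length(tgt)
  k <- W - M
  best <- Inf
  if (k == 0) {
    best <- sum(vapply(seq_len(M), function(i) pen(m[i], tgt[i]) * wt(i),
                       numeric(1)))
  } else if (k > 0) {
    # k unpaired target bases bulge out between miRNA positions p-1 and p
    for (p in seq_len(M + 1)) {
      sc <- gap * k * wt(p)
      for (i in seq_len(M)) {
        j <- if (i < p) i else i + k
        sc <- sc + pen(m[i], tgt[j]) * wt(i)
      }
      best <- min(best, sc)
    }
  } else {
    kk <- -k
    if (kk < M) {
      # miRNA positions d..d+kk-1 bulge out unpaired
      for (d in seq_len(M - kk + 1)) {
        sc <- sum(vapply(d:(d + kk - 1), function(j) gap * wt(j), numeric(1)))
        for (i in seq_len(M)) {
          if (i >= d && i <= d + kk - 1) next
          j <- if (i < d) i else i - kk
          sc <- sc + pen(m[i], tgt[j]) * wt(i)
        }
        best <- min(best, sc)
      }
    }
  }
  best
}

revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

random_dna_chr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# regex-based both-strand IUPAC scan, the oracle for scan_motif
scan_motif_oracle <- function(promoter, consensus) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
                S = "[GC]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
                D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  to_re <- function(x) paste0(vapply(strsplit(toupper(x), "")[[1]],
                                     function(ch) iupac[[ch]], ""),
                              collapse = "")
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  rc <- paste(rev(comp[strsplit(toupper(consensus), "")[[1]]]), collapse = "")
  find_all <- function(re) {
    hits <- integer(0)
    L <- nchar(consensus)
    for (off in 0:(nchar(promoter) - L)) {
      if (grepl(paste0("^", re, "$"), substr(promoter, off + 1, off + L))) {
        hits <- c(hits, off)
      }
    }
    hits
  }
  list(fwd = find_all(to_re(consensus)), rev = find_all(to_re(rc)))
}

# small hand-built annotation exercising all lncRNA classes:
#   gA (+): [1000, 3000], exons [1000,1500] + [2500,3000] (intron 1501-2499)
#   gB (-): [20000, 22000], single exon
#   lnc_intronic (+): inside gA's intron
#   lnc_sense (+): overlaps gA exon 1
#   lnc_anti (-): overlaps gA
#   lnc_linc (+): far from everything
tiny_annotation <- function() {
  feats <- data.frame(
    id = c("gA", "gA.t", "gB", "gB.t",
           "lncI", "lncI.t", "lncS", "lncS.t",
           "lncA", "lncA.t", "lncL", "lncL.t"),
    type = rep(c("gene", "transcript"), 6),
    role = c(rep("mRNA", 4), rep("lncRNA", 8)),
    chrom = "chr1",
    strand = c("+", "+", "-", "-", "+", "+", "+", "+", "-", "-", "+", "+"),
    start = c(1000L, 1000L, 20000L, 20000L, 1600L, 1600L, 1200L, 1200L,
              1100L, 1100L, 50000L, 50000L),
    end = c(3000L, 3000L, 22000L, 22000L, 1900L, 1900L, 1700L, 1700L,
            1450L, 1450L, 50400L, 50400L),
    parent_id = c(NA, "gA", NA, "gB", NA, "lncI", NA, "lncS",
                  NA, "lncA", NA, "lncL"),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    parent_id = c("gA.t", "gA.t", "gB.t", "lncI.t", "lncS.t", "lncA.t",
                  "lncL.t"),
    start = c(1000L, 2500L, 20000L, 1600L, 1200L, 1100L, 50000L),
    end = c(1500L, 3000L, 22000L, 1900L, 1700L, 1450L, 50400L),
    stringsAsFactors = FALSE)
  genome_annotation(feats, exons)
}

# expression matrix whose log2(x+1) values equal `logvals` exactly
em_from_log2 <- function(logvals, roles, conditions, unit = "FPKM") {
  expression_matrix(2^logvals - 1, roles, conditions, unit)
}

# compact simulation config for unit tests (seconds, not minutes)
small_sim_config <- function(seed = 11, ...) {
  sim_config(n_genes = 20, n_tfs = 4, n_lncrnas = 8, n_mirnas = 6,
             planted_tf_edges = 4, planted_mirna_edges = 3,
             planted_lnc_cis_edges = 4, planted_lnc_trans_edges = 2,
             n_background_genes = 20, n_background_mirnas = 6,
             seed = seed, ...)
}
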