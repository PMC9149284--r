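# Synthetic fixture generator: annotation, sequences, promoters with
# planted binding elements, and negative-binomial counts with planted
# regulator-target co/anti-expression, plus the ground truth needed to
# score edge recovery.

.IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                    R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"),
                    W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                    B = c("C", "G", "T"), D = c("A", "G", "T"),
                    H = c("A", "C", "T"), V = c("A", "C", "G"),
                    N = c("A", "C", "G", "T"))

.iupac_regex <- function(consensus) {
  paste0(vapply(strsplit(toupper(consensus), "")[[1]], function(ch) {
    s <- .IUPAC_SETS[[ch]]
    if (is.null(s)) stop("invalid IUPAC code: ", ch)
    if (length(s) == 1) s else paste0("[", paste(s, collapse = ""), "]")
  }, ""), collapse = "")
}

.iupac_revcomp <- function(consensus) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(toupper(consensus), "")[[1]]]), collapse = "")
}

.instantiate_iupac <- function(consensus) {
  paste(vapply(strsplit(toupper(consensus), "")[[1]], function(ch) {
    s <- .IUPAC_SETS[[ch]]
    if (length(s) == 1) s else sample(s, 1)
  }, ""), collapse = "")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulation configuration
#'
#' Defines a synthetic nitrogen-response study: a 3-condition x
#' 3-replicate design by default, negative-binomial counts, and planted
#' regulatory edges of all four mechanism classes.
#'
#' @param n_genes Number of protein-coding (non-TF) genes; the first
#'   genes are used, in order, as TF targets, miRNA targets, cis-lncRNA
#'   partners and trans-lncRNA partners, the remainder are decoys.
#' @param n_tfs,n_lncrnas,n_mirnas Pool sizes for the other roles;
#'   features beyond the planted edges are decoys.
#' @param n_conditions,n_replicates Design dimensions (default 3 x 3,
#'   conditions labelled N0/N6/N18 when `n_conditions` is 3).
#' @param chrom_length Chromosome length in bp; `NULL` (default) sizes it
#'   to hold all features without forced overlap.
#' @param planted_tf_edges,planted_mirna_edges,planted_lnc_cis_edges,planted_lnc_trans_edges
#'   Numbers of planted edges per mechanism.
#' @param target_correlation Attainable sample-level Pearson correlation
#'   of a planted pair, in `[0, 1]`; 0 means the target receives no
#'   signal from its regulator at all.
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   `mu + mu^2 * dispersion`), shared by all features; must be > 0.
#' @param baseline_mean_log_range Range (log2 counts) from which baseline
#'   expression is drawn uniformly.
#' @param n_background_genes,n_background_mirnas Numbers of stable
#'   high-abundance background (housekeeping-like) features added to the
#'   RNA and small-RNA matrices. They emulate the bulk of a real library
#'   and keep per-sample totals nearly condition-invariant, so that
#'   FPKM/TPM normalization does not inject composition bias into the
#'   small simulated feature set.
#' @param background_mean_log_range Baseline range (log2 counts) for
#'   background features.
#' @param signal_amplitude Norm (log2 units) of the centered
#'   condition-trajectory of planted regulators.
#' @param decoy_amplitude Maximal trajectory norm of decoy features; the
#'   default keeps decoy fold changes below the 2-fold DE threshold.
#' @param replicate_noise_sd Replicate-level biological log2-noise (sd),
#'   centered within each condition, applied to decoy and background
#'   features. It emulates the replicate variability that keeps null
#'   genes from being called differential in real data.
#' @param motif_consensus IUPAC core of the TF binding elements; each TF
#'   receives the core plus a TF-specific flank so binding elements are
#'   distinguishable.
#' @param promoter_length Promoter length in bp (default 2000).
#' @param mirna_length Mature miRNA length in nt (default 21).
#' @param plant_motifs Implant binding elements in target promoters
#'   (default TRUE; FALSE yields the motif-free null fixture).
#' @param seed Integer master seed; identical config + seed reproduces
#'   every emitted file byte for byte.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 130, n_tfs = 30, n_lncrnas = 40,
                       n_mirnas = 40, n_conditions = 3, n_replicates = 3,
                       chrom_length = NULL,
                       planted_tf_edges = 30, planted_mirna_edges = 20,
                       planted_lnc_cis_edges = 10,
                       planted_lnc_trans_edges = 10,
                       target_correlation = 0.95, nb_dispersion = 0.05,
                       baseline_mean_log_range = c(9, 11),
                       n_background_genes = 120, n_background_mirnas = 30,
                       background_mean_log_range = c(15, 16.5),
                       signal_amplitude = 5.5, decoy_amplitude = 0.5,
                       replicate_noise_sd = 0.7,
                       motif_consensus = "TGACGT", promoter_length = 2000,
                       mirna_length = 21, plant_motifs = TRUE, seed = 1) {
  cfg <- list(n_genes = n_genes, n_tfs = n_tfs, n_lncrnas = n_lncrnas,
              n_mirnas = n_mirnas, n_conditions = n_conditions,
              n_replicates = n_replicates, chrom_length = chrom_length,
              planted_tf_edges = planted_tf_edges,
              planted_mirna_edges = planted_mirna_edges,
              planted_lnc_cis_edges = planted_lnc_cis_edges,
              planted_lnc_trans_edges = planted_lnc_trans_edges,
              target_correlation = target_correlation,
              nb_dispersion = nb_dispersion,
              baseline_mean_log_range = baseline_mean_log_range,
              n_background_genes = n_background_genes,
              n_background_mirnas = n_background_mirnas,
              background_mean_log_range = background_mean_log_range,
              signal_amplitude = signal_amplitude,
              decoy_amplitude = decoy_amplitude,
              replicate_noise_sd = replicate_noise_sd,
              motif_consensus = toupper(motif_consensus),
              promoter_length = promoter_length,
              mirna_length = mirna_length,
              plant_motifs = isTRUE(plant_motifs), seed = as.integer(seed))
  counts <- cfg[c("n_genes", "n_tfs", "n_lncrnas", "n_mirnas",
                  "n_background_genes", "n_background_mirnas",
                  "n_conditions", "n_replicates", "planted_tf_edges",
                  "planted_mirna_edges", "planted_lnc_cis_edges",
                  "planted_lnc_trans_edges")]
  if (any(unlist(counts) < 0)) stop("counts must be >= 0")
  if (cfg$n_conditions < 2 || cfg$n_replicates < 2) {
    stop("need >= 2 conditions and >= 2 replicates")
  }
  n_targets <- planted_tf_edges + planted_mirna_edges +
    planted_lnc_cis_edges + planted_lnc_trans_edges
  if (planted_tf_edges > n_tfs) {
    stop("planted_tf_edges exceeds the TF pool")
  }
  if (planted_mirna_edges > n_mirnas) {
    stop("planted_mirna_edges exceeds the miRNA pool")
  }
  if (planted_lnc_cis_edges + planted_lnc_trans_edges > n_lncrnas) {
    stop("planted lncRNA edges exceed the lncRNA pool")
  }
  if (n_targets > n_genes) {
    stop("planted edges exceed the gene pool (need ", n_targets,
         " target genes, have ", n_genes, ")")
  }
  if (target_correlation < 0 || target_correlation > 1) {
    stop("target_correlation must be in [0, 1]")
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (nchar(cfg$motif_consensus) + 4 >= promoter_length) {
    stop("motif longer than promoter")
  }
  if (mirna_length < 18 || mirna_length > 30) {
    stop("mirna_length must lie in 18..30")
  }
  structure(cfg, class = "sim_config")
}

# deterministic id/edge bookkeeping derived from a config (no RNG)
.sim_plan <- function(config) {
  g <- sprintf("G%04d", seq_len(config$n_genes))
  tf <- sprintf("TF%03d", seq_len(config$n_tfs))
  lnc <- sprintf("LNC%03d", seq_len(config$n_lncrnas))
  mir <- sprintf("MIR%03d", seq_len(config$n_mirnas))
  bg <- sprintf("BG%04d", seq_len(config$n_background_genes))
  bgm <- sprintf("BGM%03d", seq_len(config$n_background_mirnas))
  ntf <- config$planted_tf_edges
  nmi <- config$planted_mirna_edges
  nci <- config$planted_lnc_cis_edges
  ntr <- config$planted_lnc_trans_edges
  tf_targets <- g[seq_len(ntf)]
  mir_targets <- g[ntf + seq_len(nmi)]
  cis_targets <- g[ntf + nmi + seq_len(nci)]
  # trans pairs beyond the 8 that fit on well-separated trajectory axes
  # (4 axes x 2 orientations) share the target gene of their axis's
  # first pair, mirroring the many-to-one DEL-DEG targeting seen in
  # nitrogen-response data
  n_distinct_trans <- min(ntr, 8L)
  trans_gene_idx <- vapply(seq_len(ntr), function(k) {
    if (k <= 8L) k else 2L * ((k - 9L) %% 4L) + 1L
  }, integer(1))
  trans_targets <- g[ntf + nmi + nci + trans_gene_idx]
  cis_lncs <- lnc[seq_len(nci)]
  trans_lncs <- lnc[nci + seq_len(ntr)]
  edges <- rbind(
    if (ntf) data.frame(source_id = tf[seq_len(ntf)], target_id = tf_targets,
                        mechanism = "tf_binding", stringsAsFactors = FALSE),
    if (nmi) data.frame(source_id = mir[seq_len(nmi)], target_id = mir_targets,
                        mechanism = "mirna_cleavage", stringsAsFactors = FALSE),
    if (nci) data.frame(source_id = cis_lncs, target_id = cis_targets,
                        mechanism = "lnc_cis", stringsAsFactors = FALSE),
    if (ntr) data.frame(source_id = trans_lncs, target_id = trans_targets,
                        mechanism = "lnc_trans", stringsAsFactors = FALSE))
  if (is.null(edges)) {
    edges <- data.frame(source_id = character(0), target_id = character(0),
                        mechanism = character(0), stringsAsFactors = FALSE)
  }
  classes <- if (nci) rep(c("lincRNA", "intronic", "antisense", "sense"),
                          length.out = nci) else character(0)
  roles <- c(setNames(rep("mRNA", length(g)), g),
             setNames(rep("TF", length(tf)), tf),
             setNames(rep("lncRNA", length(lnc)), lnc),
             setNames(rep("miRNA", length(mir)), mir),
             setNames(rep("mRNA", length(bg)), bg),
             setNames(rep("miRNA", length(bgm)), bgm))
  list(genes = g, tfs = tf, lncs = lnc, mirs = mir,
       bg_genes = bg, bg_mirs = bgm, edges = edges,
       cis_lncs = cis_lncs, trans_lncs = trans_lncs,
       cis_hosts = cis_targets, cis_classes = classes, roles = roles)
}

#' Generate the synthetic annotation, genome and feature sequences
#'
#' Lays out genes, TFs, lncRNA loci and miRNA loci on one chromosome in
#' well-separated slots (inter-locus gaps far exceed the 10 kb cis
#' window), realising all four positional lncRNA classes among the
#' cis-planted lncRNAs: lincRNA partners sit 2.5-5 kb from their host
#' gene, intronic ones inside a host intron, antisense and sense ones
#' overlap the host on the opposite / same strand. Gene transcripts are
#' two-exon; targets of planted miRNA edges carry an exact
#' reverse-complement site of their miRNA in exon 1.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return List with `annotation` ([genome_annotation()]), `genome`
#'   (named character, one chromosome), `transcripts` (named character,
#'   spliced mRNA/TF/lncRNA sequences), `mirnas` (named character,
#'   mature sequences), `lnc_classes` (`data.frame`), `plan` (internal
#'   bookkeeping reused by the other generator stages).
#' @export
generate_annotation <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  plan <- .sim_plan(config)
  slot <- 24000L
  standalone_lncs <- setdiff(plan$lncs, plan$cis_lncs)
  n_slots <- config$n_genes + config$n_tfs + length(standalone_lncs) +
    config$n_mirnas + config$n_background_genes + config$n_background_mirnas
  need <- (n_slots + 1L) * slot
  chrom_length <- config$chrom_length
  if (is.null(chrom_length)) chrom_length <- need
  if (chrom_length < need) {
    stop("chrom_length ", chrom_length, " too small to place ", n_slots,
         " loci without forced overlap (need >= ", need, " bp)")
  }
  feat <- list(); exons <- list()
  add_feat <- function(id, type, role, strand, start, end, parent = NA) {
    feat[[length(feat) + 1L]] <<- data.frame(
      id = id, type = type, role = role, chrom = "chr1", strand = strand,
      start = as.integer(start), end = as.integer(end),
      parent_id = as.character(parent), stringsAsFactors = FALSE)
  }
  add_exon <- function(pid, start, end) {
    exons[[length(exons) + 1L]] <<- data.frame(
      parent_id = pid, start = as.integer(start), end = as.integer(end),
      stringsAsFactors = FALSE)
  }
  mir_target_of <- setNames(
    plan$edges$source_id[plan$edges$mechanism == "mirna_cleavage"],
    plan$edges$target_id[plan$edges$mechanism == "mirna_cleavage"])
  intronic_hosts <- plan$cis_hosts[plan$cis_classes == "intronic"]

  slot_i <- 0L
  gene_layout <- list()
  for (gid in c(plan$genes, plan$tfs, plan$bg_genes)) {
    slot_i <- slot_i + 1L
    base <- (slot_i - 1L) * slot
    start <- base + 12000L
    e1 <- sample(500:900, 1)
    intr <- if (gid %in% intronic_hosts) 600L else sample(450:800, 1)
    e2 <- sample(500:900, 1)
    end <- start + e1 + intr + e2 - 1L
    strand <- sample(c("+", "-"), 1)
    role <- if (startsWith(gid, "TF")) "TF" else "mRNA"
    tid <- paste0(gid, ".t1")
    add_feat(gid, "gene", role, strand, start, end)
    add_feat(tid, "transcript", role, strand, start, end, gid)
    add_exon(tid, start, start + e1 - 1L)
    add_exon(tid, start + e1 + intr, end)
    gene_layout[[gid]] <- list(start = start, end = end, strand = strand,
                               e1 = e1, intron = intr, e2 = e2)
  }
  # cis lncRNAs relative to their host genes
  lnc_layout <- list()
  if (length(plan$cis_lncs)) {
    for (i in seq_along(plan$cis_lncs)) {
      lid <- plan$cis_lncs[i]
      cls <- plan$cis_classes[i]
      host <- gene_layout[[plan$cis_hosts[i]]]
      if (cls == "lincRNA") {
        lstart <- host$end + sample(2500:5000, 1)
        lend <- lstart + sample(300:600, 1)
        lstrand <- sample(c("+", "-"), 1)
      } else if (cls == "intronic") {
        istart <- host$start + host$e1
        lstart <- istart + 50L
        lend <- lstart + 300L
        lstrand <- host$strand
      } else if (cls == "antisense") {
        lstart <- host$start + 100L
        lend <- lstart + 300L
        lstrand <- if (host$strand == "+") "-" else "+"
      } else {  # sense: overlaps exon 1 on the host strand
        lstart <- host$start + 50L
        lend <- lstart + 350L
        lstrand <- host$strand
      }
      tid <- paste0(lid, ".t1")
      add_feat(lid, "gene", "lncRNA", lstrand, lstart, lend)
      add_feat(tid, "transcript", "lncRNA", lstrand, lstart, lend, lid)
      add_exon(tid, lstart, lend)
      lnc_layout[[lid]] <- list(start = lstart, end = lend, strand = lstrand)
    }
  }
  for (lid in standalone_lncs) {
    slot_i <- slot_i + 1L
    base <- (slot_i - 1L) * slot
    lstart <- base + 12000L
    lend <- lstart + sample(300:600, 1)
    lstrand <- sample(c("+", "-"), 1)
    tid <- paste0(lid, ".t1")
    add_feat(lid, "gene", "lncRNA", lstrand, lstart, lend)
    add_feat(tid, "transcript", "lncRNA", lstrand, lstart, lend, lid)
    add_exon(tid, lstart, lend)
    lnc_layout[[lid]] <- list(start = lstart, end = lend, strand = lstrand)
  }
  mir_layout <- list()
  for (mid in c(plan$mirs, plan$bg_mirs)) {
    slot_i <- slot_i + 1L
    base <- (slot_i - 1L) * slot
    mstart <- base + 12000L
    mend <- mstart + config$mirna_length - 1L
    tid <- paste0(mid, ".t1")
    add_feat(mid, "gene", "miRNA", "+", mstart, mend)
    add_feat(tid, "transcript", "miRNA", "+", mstart, mend, mid)
    add_exon(tid, mstart, mend)
    mir_layout[[mid]] <- list(start = mstart, end = mend)
  }
  annotation <- genome_annotation(do.call(rbind, feat), do.call(rbind, exons))

  # genome background, then patch feature sequences into it
  gchars <- sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE)
  all_mirs <- c(plan$mirs, plan$bg_mirs)
  mirna_seqs <- setNames(
    vapply(all_mirs, function(m) .random_dna(config$mirna_length), ""),
    all_mirs)
  patch <- function(start, end, seqstr) {
    gchars[start:end] <<- strsplit(seqstr, "")[[1]]
  }
  transcripts <- character(0)
  for (gid in c(plan$genes, plan$tfs, plan$bg_genes)) {
    gl <- gene_layout[[gid]]
    txlen <- gl$e1 + gl$e2
    tx <- .random_dna(txlen)
    if (gid %in% names(mir_target_of)) {
      site <- .revcomp(mirna_seqs[[mir_target_of[[gid]]]])
      pos <- 101L  # inside exon 1 on the spliced transcript
      substr(tx, pos, pos + nchar(site) - 1L) <- site
    }
    ex1 <- c(gl$start, gl$start + gl$e1 - 1L)
    ex2 <- c(gl$start + gl$e1 + gl$intron, gl$end)
    if (gl$strand == "+") {
      patch(ex1[1], ex1[2], substr(tx, 1, gl$e1))
      patch(ex2[1], ex2[2], substr(tx, gl$e1 + 1L, txlen))
    } else {
      patch(ex2[1], ex2[2], .revcomp(substr(tx, 1, gl$e2)))
      patch(ex1[1], ex1[2], .revcomp(substr(tx, gl$e2 + 1L, txlen)))
    }
    transcripts[[gid]] <- tx
  }
  for (mid in c(plan$mirs, plan$bg_mirs)) {
    ml <- mir_layout[[mid]]
    patch(ml$start, ml$end, mirna_seqs[[mid]])
  }
  # lncRNA sequences read off the (patched) genome, strand-aware
  for (lid in plan$lncs) {
    ll <- lnc_layout[[lid]]
    s <- paste(gchars[ll$start:ll$end], collapse = "")
    transcripts[[lid]] <- if (ll$strand == "+") s else .revcomp(s)
  }
  genome <- setNames(paste(gchars, collapse = ""), "chr1")
  lnc_classes <- data.frame(
    lnc_id = c(plan$cis_lncs, standalone_lncs),
    class = c(plan$cis_classes, rep("lincRNA", length(standalone_lncs))),
    gene_id = c(plan$cis_hosts, rep("", length(standalone_lncs))),
    stringsAsFactors = FALSE)
  list(annotation = annotation, genome = genome, transcripts = transcripts,
       mirnas = mirna_seqs, lnc_classes = lnc_classes, plan = plan)
}

#' Plant TF binding elements in target promoters
#'
#' Assigns each TF a distinct binding element (the configured IUPAC core
#' plus a TF-specific 4-nt flank), draws motif-free background promoters
#' for every gene (rejection-sampled against all elements on both
#' strands), and implants one exact element instance at a random offset
#' and strand in the promoter of every planted TF target, so that motif
#' presence is equivalent to planted regulation. Promoter sequences are
#' patched back into the genome so that [extract_promoter()] reproduces
#' them.
#'
#' @param siminfo Result of [generate_annotation()].
#' @param config The [sim_config()].
#' @param seed RNG seed (defaults to `config$seed + 1`).
#' @return List with `promoters` (named character, oriented upstream
#'   sequences for every mRNA/TF gene), `placements` (`data.frame`
#'   `gene_id`, `offset` (0-based), `strand`, `instance`), `tf_motifs`
#'   (`data.frame` `tf_id`, `motif`), and the patched `genome`.
#' @export
plant_motifs <- function(siminfo, config, seed = config$seed + 1L) {
  set.seed(seed)
  plan <- siminfo$plan
  P <- config$promoter_length
  ann <- siminfo$annotation
  ft <- ann$features
  # distinct flanks; widen the flank if the TF pool is very large
  flank_len <- 4L
  while (4^flank_len < max(1L, config$n_tfs) * 4L) flank_len <- flank_len + 1L
  flanks <- character(0)
  while (length(flanks) < config$n_tfs) {
    f <- .random_dna(flank_len)
    if (!f %in% flanks) flanks <- c(flanks, f)
  }
  motifs <- paste0(config$motif_consensus, flanks)
  names(motifs) <- plan$tfs
  pat <- paste0("(", paste(c(vapply(motifs, .iupac_regex, ""),
                             vapply(motifs, function(m)
                               .iupac_regex(.iupac_revcomp(m)), "")),
                           collapse = ")|("), ")")
  has_any_motif <- function(s) grepl(pat, s)
  tf_of_target <- split(
    plan$edges$source_id[plan$edges$mechanism == "tf_binding"],
    plan$edges$target_id[plan$edges$mechanism == "tf_binding"])

  gene_ids <- c(plan$genes, plan$tfs, plan$bg_genes)
  gchars <- strsplit(siminfo$genome[[1]], "")[[1]]
  promoters <- character(0)
  placements <- list()
  for (gid in gene_ids) {
    bg <- NULL
    for (try in 1:50) {
      cand <- .random_dna(P)
      if (!has_any_motif(cand)) { bg <- cand; break }
    }
    if (is.null(bg)) stop("could not draw a motif-free promoter for ", gid)
    tfs_here <- if (config$plant_motifs) tf_of_target[[gid]] else NULL
    if (!is.null(tfs_here)) {
      for (tf in tfs_here) {
        placed <- FALSE
        for (try in 1:50) {
          inst <- .instantiate_iupac(motifs[[tf]])
          off <- sample(0:(P - nchar(inst)), 1)
          strand <- sample(c("+", "-"), 1)
          cand <- bg
          piece <- if (strand == "+") inst else .revcomp(inst)
          substr(cand, off + 1L, off + nchar(inst)) <- piece
          # implanting must not fabricate another TF's element
          others <- motifs[names(motifs) != tf]
          ok <- !length(others) || !any(vapply(others, function(m) {
            grepl(.iupac_regex(m), cand) ||
              grepl(.iupac_regex(.iupac_revcomp(m)), cand)
          }, logical(1)))
          if (ok) {
            bg <- cand
            placements[[length(placements) + 1L]] <- data.frame(
              gene_id = gid, tf_id = tf, offset = off, strand = strand,
              instance = inst, stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
        }
        if (!placed) stop("could not implant element of ", tf, " in ", gid)
      }
    }
    promoters[[gid]] <- bg
    g <- ft[ft$id == gid, ]
    if (g$strand == "+") {
      from <- g$start - P
      if (from < 1L) stop("no room for promoter upstream of ", gid)
      gchars[from:(g$start - 1L)] <- strsplit(bg, "")[[1]]
    } else {
      to <- g$end + P
      if (to > length(gchars)) stop("no room for promoter downstream of ", gid)
      gchars[(g$end + 1L):to] <- strsplit(.revcomp(bg), "")[[1]]
    }
  }
  placements <- if (length(placements)) do.call(rbind, placements) else
    data.frame(gene_id = character(0), tf_id = character(0),
               offset = integer(0), strand = character(0),
               instance = character(0), stringsAsFactors = FALSE)
  list(promoters = promoters,
       placements = placements,
       tf_motifs = data.frame(tf_id = plan$tfs, motif = unname(motifs),
                              stringsAsFactors = FALSE),
       genome = setNames(paste(gchars, collapse = ""), names(siminfo$genome)))
}

# orthonormal basis of the centered condition space (first two directions)
.centered_basis <- function(n_cond) {
  if (n_cond == 2) {
    return(list(e1 = c(1, -1) / sqrt(2), e2 = c(0, 0)))
  }
  b1 <- seq_len(n_cond) - mean(seq_len(n_cond))
  e1 <- b1 / sqrt(sum(b1^2))
  b2 <- (seq_len(n_cond) - mean(seq_len(n_cond)))^2
  b2 <- b2 - mean(b2) - sum(b2 * e1) * e1
  list(e1 = e1, e2 = b2 / sqrt(sum(b2^2)))
}

.traj_from_angle <- function(theta_deg, amplitude, basis) {
  th <- theta_deg * pi / 180
  amplitude * (cos(th) * basis$e1 + sin(th) * basis$e2)
}

# Angular slots for trans-lncRNA trajectories. Trans pairs are laid out
# as mirrored duos on shared axes: the two pairs of an axis run in
# opposite orientations (lnc at a / gene at a+180, and lnc at a+180 /
# gene at a), so their cross-correlations are positive and invisible to
# the anticorrelation rule. Axes are kept >= 36 degrees away from the
# main coexpression direction (0) and from each other, so only the
# planted partner of a trans lncRNA can anticorrelate beyond the trans
# threshold.
.trans_angles <- function(n) {
  if (n == 0) return(numeric(0))
  n_axes <- min(ceiling(n / 2), 4L)
  axes <- if (n_axes == 1) 90 else seq(36, 144, length.out = n_axes)
  duo <- as.vector(rbind(axes, axes + 180))
  vapply(seq_len(n), function(k) {
    if (k <= 2L * n_axes) duo[k] else axes[(k - 2L * n_axes - 1L) %% n_axes + 1L]
  }, numeric(1))
}

#' Generate planted-structure count matrices
#'
#' Every planted regulator carries a latent log2 condition trajectory
#' (norm `signal_amplitude` in centered-profile space); its target
#' receives the same trajectory (sign-flipped for `mirna_cleavage` and
#' `lnc_trans` edges) plus per-sample Gaussian log-noise calibrated so
#' the expected pair correlation matches `target_correlation`. With
#' `target_correlation = 0` the target receives no signal at all. Decoy
#' features get weak random trajectories below the 2-fold DE threshold.
#' Counts are negative-binomial around the per-sample mean.
#'
#' @param siminfo Result of [generate_annotation()].
#' @param config The [sim_config()].
#' @param seed RNG seed (defaults to `config$seed + 2`).
#' @return List with `counts_rna` (mRNA/TF/lncRNA [expression_matrix()]),
#'   `counts_mirna` (miRNA [expression_matrix()]), `expected_de`
#'   (feature ids whose latent trajectories differ >= 2-fold between
#'   condition 1 and some other condition), `trajectories` (matrix of
#'   latent centered log2 trajectories).
#' @export
generate_expression <- function(siminfo, config, seed = config$seed + 2L) {
  if (config$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  set.seed(seed)
  plan <- siminfo$plan
  nc <- config$n_conditions
  nr <- config$n_replicates
  conds <- if (nc == 3) c("N0", "N6", "N18") else paste0("C", seq_len(nc))
  samples <- paste0(rep(conds, each = nr), "_", rep(seq_len(nr), nc))
  cond_of <- setNames(rep(conds, each = nr), samples)
  basis <- .centered_basis(nc)
  A <- config$signal_amplitude
  rho <- config$target_correlation
  ids <- names(plan$roles)
  traj <- matrix(0, length(ids), nc, dimnames = list(ids, conds))
  is_regulator <- ids %in% plan$edges$source_id
  is_target <- ids %in% plan$edges$target_id
  # regulator directions
  reg_theta <- setNames(rep(NA_real_, length(ids)), ids)
  tfs_p <- plan$edges$source_id[plan$edges$mechanism == "tf_binding"]
  cis_p <- plan$edges$source_id[plan$edges$mechanism == "lnc_cis"]
  mir_p <- plan$edges$source_id[plan$edges$mechanism == "mirna_cleavage"]
  trans_p <- plan$edges$source_id[plan$edges$mechanism == "lnc_trans"]
  # the coexpressed block shares one exact direction; angular separation
  # from the trans slots is what keeps non-planted pairs below the trans
  # correlation threshold
  for (id in c(tfs_p, cis_p)) reg_theta[id] <- 0
  for (id in mir_p) reg_theta[id] <- 180
  ta <- .trans_angles(length(trans_p))
  for (i in seq_along(trans_p)) reg_theta[trans_p[i]] <- ta[i]
  for (id in ids[is_regulator]) {
    traj[id, ] <- .traj_from_angle(reg_theta[id], A, basis)
  }
  target_sign <- c(tf_binding = 1, lnc_cis = 1,
                   mirna_cleavage = -1, lnc_trans = -1)
  reg_of <- setNames(plan$edges$source_id, plan$edges$target_id)
  sign_of <- setNames(target_sign[plan$edges$mechanism], plan$edges$target_id)
  if (rho > 0) {
    for (id in ids[is_target]) {
      traj[id, ] <- sign_of[[id]] * traj[reg_of[[id]], ]
    }
  }
  # decoys: weak random trajectories
  decoys <- ids[!is_regulator & !is_target]
  for (id in decoys) {
    traj[id, ] <- .traj_from_angle(runif(1, 0, 360),
                                   runif(1, 0, config$decoy_amplitude), basis)
  }
  # per-sample log-noise for targets, calibrated to target_correlation;
  # NB counting noise (~ dispersion / ln(2)^2 in log2 units) is part of
  # the noise budget
  # Calibrate replicate-level log-noise so the expected planted-pair
  # correlation over samples is ~ rho, split evenly between regulator and
  # target. The noise is centered within each condition: it attenuates
  # the sample-level PCC (carrying the target_correlation budget) without
  # perturbing realized condition means, so planted condition-profile
  # directions stay exact. Decoys and background features get fixed
  # replicate noise for the same reason real null genes are null: their
  # drift is buried in replicate variability.
  S2 <- A^2 / nc
  nb_log_var <- config$nb_dispersion / log(2)^2
  sigma2_pair <- if (rho > 0 && rho < 1) {
    max(0, min(9, S2 * (1 / rho - 1) - nb_log_var))
  } else 0
  to_raw <- function(v) if (nr > 1) sqrt(v * nr / (nr - 1)) else sqrt(v)
  pair_raw_sd <- to_raw(sigma2_pair)
  decoy_raw_sd <- to_raw(config$replicate_noise_sd^2)
  center_within_condition <- function(e) {
    e - ave(e, cond_of)
  }
  base_range <- config$baseline_mean_log_range
  bg_range <- config$background_mean_log_range
  is_bg <- ids %in% c(plan$bg_genes, plan$bg_mirs)
  baseline <- setNames(ifelse(is_bg,
                              runif(length(ids), bg_range[1], bg_range[2]),
                              runif(length(ids), base_range[1], base_range[2])),
                       ids)
  n_s <- length(samples)
  counts <- matrix(0L, length(ids), n_s, dimnames = list(ids, samples))
  for (id in ids) {
    mu_log <- baseline[id] + traj[id, cond_of]
    i <- match(id, ids)
    if ((is_target[i] || is_regulator[i]) && rho > 0 && rho < 1) {
      mu_log <- mu_log + center_within_condition(rnorm(n_s, 0, pair_raw_sd))
    } else if ((!is_regulator[i] && !is_target[i]) ||
               (is_target[i] && rho == 0)) {
      # null features (decoys, background, and targets of a zero-strength
      # planting): replicate-level scatter, condition means flat
      mu_log <- mu_log + center_within_condition(rnorm(n_s, 0, decoy_raw_sd))
    }
    mu <- 2^mu_log
    counts[id, ] <- rnbinom(n_s, mu = mu, size = 1 / config$nb_dispersion)
  }
  expected_de <- ids[apply(traj, 1, function(t)
    max(abs(t[1] - t[-1])) >= 1)]
  rna_ids <- c(plan$genes, plan$tfs, plan$lncs, plan$bg_genes)
  mir_ids <- c(plan$mirs, plan$bg_mirs)
  counts_rna <- expression_matrix(counts[rna_ids, , drop = FALSE],
                                  plan$roles, cond_of, "raw_count")
  counts_mirna <- expression_matrix(counts[mir_ids, , drop = FALSE],
                                    plan$roles, cond_of, "raw_count")
  list(counts_rna = counts_rna, counts_mirna = counts_mirna,
       expected_de = expected_de, trajectories = traj)
}

#' Simulate a complete study fixture on disk
#'
#' Runs [generate_annotation()], [plant_motifs()] and
#' [generate_expression()] with seeds derived from `config$seed` and
#' writes the full input bundle plus ground truth: `genome.fa`,
#' `annotation.gff3`, `transcripts.fa`, `promoters.fa`, `mirnas.fa`,
#' `counts_rna.tsv`, `counts_mirna.tsv`, `samples.tsv`, `roles.tsv`,
#' `tf_motifs.tsv`, `truth_edges.tsv`, `truth_motifs.tsv`,
#' `lnc_classes.tsv`, `expected_de.tsv`. Identical config + seed gives
#' byte-identical files.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths), `truth`
#'   (a `ground_truth` object), and the in-memory pieces.
#' @export
simulate_dataset <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  siminfo <- generate_annotation(config, seed = config$seed)
  pm <- plant_motifs(siminfo, config, seed = config$seed + 1L)
  expr <- generate_expression(siminfo, config, seed = config$seed + 2L)
  p <- function(f) file.path(dir, f)
  write_fasta(pm$genome, p("genome.fa"))
  write_gff3(siminfo$annotation, p("annotation.gff3"))
  write_fasta(siminfo$transcripts, p("transcripts.fa"))
  write_fasta(pm$promoters, p("promoters.fa"))
  write_fasta(siminfo$mirnas, p("mirnas.fa"))
  write_counts(expr$counts_rna, p("counts_rna.tsv"))
  write_counts(expr$counts_mirna, p("counts_mirna.tsv"))
  write_sample_sheet(expr$counts_rna$conditions, p("samples.tsv"))
  roles <- siminfo$plan$roles
  write.table(data.frame(feature_id = names(roles), role = unname(roles)),
              p("roles.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(pm$tf_motifs, p("tf_motifs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(siminfo$plan$edges, p("truth_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(pm$placements, p("truth_motifs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(siminfo$lnc_classes, p("lnc_classes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(feature_id = expr$expected_de),
              p("expected_de.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- structure(list(edges = siminfo$plan$edges,
                          motif_placements = pm$placements,
                          expected_de_features = expr$expected_de,
                          lnc_classes = siminfo$lnc_classes,
                          tf_motifs = pm$tf_motifs),
                     class = "ground_truth")
  paths <- setNames(
    vapply(c("genome.fa", "annotation.gff3", "transcripts.fa",
             "promoters.fa", "mirnas.fa", "counts_rna.tsv",
             "counts_mirna.tsv", "samples.tsv", "roles.tsv",
             "tf_motifs.tsv", "truth_edges.tsv", "truth_motifs.tsv",
             "lnc_classes.tsv", "expected_de.tsv"), p, ""),
    c("genome", "annotation", "transcripts", "promoters", "mirnas",
      "counts_rna", "counts_mirna", "samples", "roles", "tf_motifs",
      "truth_edges", "truth_motifs", "lnc_classes", "expected_de"))
  invisible(list(paths = paths, truth = truth, config = config,
                 annotation = siminfo$annotation, genome = pm$genome,
                 transcripts = siminfo$transcripts, mirnas = siminfo$mirnas,
                 promoters = pm$promoters, counts_rna = expr$counts_rna,
                 counts_mirna = expr$counts_mirna,
                 trajectories = expr$trajectories))
}
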