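# One-command orchestration: simulate -> normalize -> DE -> lncRNA
# classification and targets -> miRNA targets -> TF pairs -> network ->
# recovery, from a single validated config, with a deterministic manifest.

.default_thresholds <- list(
  fc_threshold = 2, fdr_threshold = 0.05,
  pcc_threshold = 0.8, p_threshold = 0.05,
  trans_r_threshold = 0.9, cis_window_bp = 10000,
  mirna_cutoff = 4, promoter_length = 2000,
  small_rna_min_nt = 18, small_rna_max_nt = 30,
  pseudocount = 1)

.default_modes <- list(trans_correlation_mode = "anticorrelated",
                       require_motif = TRUE, filter_lncrna = FALSE)

#' Build and validate a pipeline configuration
#'
#' A configuration either embeds a `simulate` block (arguments to
#' [sim_config()]) or an `inputs` block with paths to `counts_rna`,
#' `counts_mirna`, `annotation`, `transcripts`, `mirnas`, `roles`,
#' `samples`, `tf_motifs`, plus either `promoters` or `genome`, and
#' optionally `truth_edges` for recovery scoring. All analysis
#' thresholds are surfaced with their canonical defaults (fold change 2,
#' FDR 0.05, |PCC| 0.8 with p 0.05 for TF pairs, trans correlation 0.9,
#' cis window 10 kb, miRNA penalty cutoff 4, 18-30 nt small RNAs).
#'
#' @param simulate Named list of [sim_config()] arguments, or `NULL`.
#' @param inputs Named list of input paths, or `NULL`.
#' @param thresholds Named list overriding the default thresholds.
#' @param modes Named list overriding `trans_correlation_mode`
#'   (`"anticorrelated"`/`"absolute"`), `require_motif`, `filter_lncrna`.
#' @param seed Integer seed forwarded to the simulator.
#' @param output_dir Output directory for [run_pipeline()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, inputs = NULL,
                            thresholds = list(), modes = list(),
                            seed = 1, output_dir = "nitronet_out") {
  if (is.null(simulate) && is.null(inputs)) {
    stop("config needs a 'simulate' block or an 'inputs' block")
  }
  th <- modifyList(.default_thresholds, thresholds)
  md <- modifyList(.default_modes, modes)
  chk <- function(cond, msg) if (!cond) stop("invalid config: ", msg)
  chk(th$fc_threshold > 0, "fc_threshold must be > 0")
  chk(th$fdr_threshold > 0 && th$fdr_threshold <= 1,
      "fdr_threshold must be in (0, 1]")
  chk(th$pcc_threshold >= 0 && th$pcc_threshold < 1,
      "pcc_threshold must be in [0, 1)")
  chk(th$p_threshold > 0 && th$p_threshold <= 1,
      "p_threshold must be in (0, 1]")
  chk(th$trans_r_threshold > 0 && th$trans_r_threshold <= 1,
      "trans_r_threshold must be in (0, 1]")
  chk(th$cis_window_bp > 0, "cis_window_bp must be > 0")
  chk(th$mirna_cutoff >= 0, "mirna_cutoff must be >= 0")
  chk(th$promoter_length > 0, "promoter_length must be > 0")
  chk(th$small_rna_min_nt >= 1 &&
        th$small_rna_max_nt >= th$small_rna_min_nt,
      "small RNA length bounds out of order")
  chk(md$trans_correlation_mode %in% c("anticorrelated", "absolute"),
      "unknown trans_correlation_mode")
  if (!is.null(inputs)) {
    need <- c("counts_rna", "counts_mirna", "annotation", "transcripts",
              "mirnas", "roles", "samples", "tf_motifs")
    miss <- setdiff(need, names(inputs))
    chk(!length(miss),
        paste("inputs missing:", paste(miss, collapse = ", ")))
    chk(!is.null(inputs$promoters) || !is.null(inputs$genome),
        "inputs need 'promoters' or 'genome'")
  }
  structure(list(simulate = simulate, inputs = inputs, thresholds = th,
                 modes = md, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with the blocks documented in
#'   [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(simulate = y$simulate, inputs = y$inputs,
                  thresholds = y$thresholds %||% list(),
                  modes = y$modes %||% list(),
                  seed = y$seed %||% 1,
                  output_dir = y$output_dir %||% "nitronet_out")
}

# exonic length per gene-level feature (sum of exons over its transcripts)
.feature_lengths <- function(annotation) {
  ft <- annotation$features
  genes <- ft[ft$type == "gene", , drop = FALSE]
  tx <- ft[ft$type == "transcript", , drop = FALSE]
  ex <- annotation$exons
  exlen <- tapply(ex$end - ex$start + 1L, ex$parent_id, sum)
  len <- setNames(genes$end - genes$start + 1L, genes$id)
  for (i in seq_len(nrow(tx))) {
    gid <- tx$parent_id[i]
    l <- exlen[[tx$id[i]]]
    if (!is.na(gid) && !is.null(l)) len[gid] <- l
  }
  len
}

.subset_em <- function(em, ids) {
  expression_matrix(em$values[ids, , drop = FALSE], em$roles,
                    em$conditions, em$unit)
}

.stage_msg <- function(...) message("[nitronet] ", ...)

#' Run the full analysis pipeline
#'
#' Executes, in fixed order: (optional) simulation, input loading,
#' FPKM/TPM normalization, differential expression per pairwise
#' contrast, lncRNA classification, cis and trans lncRNA target calling
#' restricted to DEL-DEG pairs, miRNA target prediction with coherence
#' classification restricted to DEM-DEG pairs, TF-gene pairing with
#' promoter motif gating, network assembly and export (edge TSV, SIF,
#' GraphML), and - when ground truth is available - recovery scoring.
#' Every stage writes a TSV; a JSON manifest records the config hash,
#' seed, package version and per-stage row counts (no timestamps, so
#' rerunning an identical config reproduces every output byte for
#' byte). A stage failure aborts with the stage name and leaves a
#' `FAILED` marker in the manifest.
#'
#' @param config A [pipeline_config()] or a path to a YAML config.
#' @param output_dir Overrides `config$output_dir` when non-`NULL`.
#' @return Invisibly, a list with the network, per-stage tables,
#'   recovery metrics (or `NULL`), and the manifest.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- output_dir %||% config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  md <- config$modes
  manifest <- list(
    tool = "nitronet",
    version = as.character(utils::packageVersion("nitronet")),
    seed = config$seed,
    config_md5 = .config_md5(config),
    stages = list())
  stage <- function(name, expr) {
    .stage_msg("stage: ", name)
    tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- "FAILED"
      jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  truth <- NULL
  inputs <- config$inputs
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      args <- config$simulate
      if (is.null(args$seed)) args$seed <- config$seed
      simulate_dataset(do.call(sim_config, args), file.path(out, "sim"))
    })
    truth <- sim$truth
    inputs <- as.list(sim$paths)
  }
  loaded <- stage("load", {
    ann <- read_gff3(inputs$annotation)
    roles_df <- read.delim(inputs$roles, stringsAsFactors = FALSE)
    roles <- setNames(roles_df$role, roles_df$feature_id)
    list(
      annotation = ann,
      roles = roles,
      counts_rna = read_counts(inputs$counts_rna, inputs$samples, roles),
      counts_mirna = read_counts(inputs$counts_mirna, inputs$samples, roles),
      transcripts = read_fasta(inputs$transcripts),
      mirna_seqs = read_fasta(inputs$mirnas),
      promoters = if (!is.null(inputs$promoters))
        read_fasta(inputs$promoters) else NULL,
      genome = if (!is.null(inputs$genome)) read_fasta(inputs$genome)
        else NULL,
      tf_motifs = read.delim(inputs$tf_motifs, stringsAsFactors = FALSE))
  })
  if (is.null(truth) && !is.null(inputs$truth_edges)) {
    truth <- structure(
      list(edges = read.delim(inputs$truth_edges, stringsAsFactors = FALSE)),
      class = "ground_truth")
  }
  ann <- loaded$annotation
  roles <- loaded$roles

  norm <- stage("normalize", {
    lens <- .feature_lengths(ann)
    list(fpkm = fpkm(loaded$counts_rna, lens), tpm = tpm(loaded$counts_mirna))
  })
  de_all <- stage("differential_expression", {
    de_rna <- differential_expression(
      norm$fpkm, fc_threshold = th$fc_threshold,
      fdr_threshold = th$fdr_threshold, pseudocount = th$pseudocount)
    kept_mirnas <- names(filter_small_rna(loaded$mirna_seqs,
                                          th$small_rna_min_nt,
                                          th$small_rna_max_nt))
    tpm_kept <- .subset_em(norm$tpm,
                           intersect(rownames(norm$tpm$values), kept_mirnas))
    de_mir <- differential_expression(
      tpm_kept, fc_threshold = th$fc_threshold,
      fdr_threshold = th$fdr_threshold, pseudocount = th$pseudocount)
    de <- rbind(de_rna, de_mir)
    write.table(de, file.path(out, "differential_expression.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    de
  })
  sig_ids <- unique(de_all$feature_id[de_all$call != "ns"])
  lnc_ids_all <- names(roles)[roles == "lncRNA"]
  if (md$filter_lncrna) {
    lnc_ids_all <- stage("filter_lncrna", {
      filter_lncrna_candidates(lnc_ids_all, loaded$transcripts)
    })
  }
  classes <- stage("classify_lncrna", {
    cl <- classify_lncrna(ann, lnc_ids_all)
    write.table(cl, file.path(out, "lncrna_classes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cl
  })
  dels <- intersect(lnc_ids_all, sig_ids)
  degs <- intersect(names(roles)[roles %in% c("mRNA", "TF")], sig_ids)
  dems <- intersect(names(roles)[roles == "miRNA"], sig_ids)

  cis_pairs <- stage("cis_targets", {
    rows <- lapply(dels, function(l) {
      hits <- cis_targets(ann, l, th$cis_window_bp)
      hits[hits$gene_id %in% degs, , drop = FALSE]
    })
    cp <- do.call(rbind, c(rows, list(data.frame(
      lnc_id = character(0), gene_id = character(0), gap_bp = integer(0),
      stringsAsFactors = FALSE))))
    write.table(cp, file.path(out, "lnc_cis_pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cp
  })
  trans_pairs <- stage("trans_targets", {
    lnc_em <- .subset_em(norm$fpkm, intersect(rownames(norm$fpkm$values),
                                              lnc_ids_all))
    gene_em <- .subset_em(norm$fpkm,
                          rownames(norm$fpkm$values)[
                            norm$fpkm$roles %in% c("mRNA", "TF")])
    tp <- trans_targets(lnc_em, gene_em, de_all,
                        r_threshold = th$trans_r_threshold,
                        mode = md$trans_correlation_mode)
    write.table(tp, file.path(out, "lnc_trans_pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    tp
  })
  mirna_pairs <- stage("mirna_targets", {
    mseqs <- loaded$mirna_seqs[intersect(names(loaded$mirna_seqs), dems)]
    tseqs <- loaded$transcripts[intersect(names(loaded$transcripts), degs)]
    sites <- if (length(mseqs) && length(tseqs)) {
      predict_targets(mseqs, tseqs, cutoff = th$mirna_cutoff)
    } else {
      data.frame(mirna_id = character(0), transcript_id = character(0),
                 site_start = integer(0), site_length = integer(0),
                 penalty_score = numeric(0), paired_string = character(0),
                 stringsAsFactors = FALSE)
    }
    write.table(sites, file.path(out, "mirna_sites.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    # coherence in the first shared DE contrast
    rows <- list()
    for (i in seq_len(nrow(sites))) {
      dm <- de_all[de_all$feature_id == sites$mirna_id[i], ]
      dt <- de_all[de_all$feature_id == sites$transcript_id[i], ]
      shared <- intersect(dm$contrast[dm$call != "ns"],
                          dt$contrast[dt$call != "ns"])
      if (!length(shared)) next
      coh <- classify_pair_coherence(dm, dt, shared[1])
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = sites$mirna_id[i], target_id = sites$transcript_id[i],
        penalty_score = sites$penalty_score[i], contrast = shared[1],
        coherence = coh$coherence, stringsAsFactors = FALSE)
    }
    mp <- if (length(rows)) do.call(rbind, rows) else data.frame(
      mirna_id = character(0), target_id = character(0),
      penalty_score = numeric(0), contrast = character(0),
      coherence = character(0), stringsAsFactors = FALSE)
    write.table(mp, file.path(out, "mirna_pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    mp
  })
  tf_pairs <- stage("tf_pairs", {
    tf_em <- .subset_em(norm$fpkm,
                        rownames(norm$fpkm$values)[norm$fpkm$roles == "TF"])
    gene_em <- .subset_em(norm$fpkm,
                          rownames(norm$fpkm$values)[
                            norm$fpkm$roles == "mRNA"])
    proms <- loaded$promoters
    if (is.null(proms)) {
      cand <- intersect(rownames(gene_em$values), sig_ids)
      proms <- setNames(vapply(cand, function(g)
        extract_promoter(ann, g, loaded$genome, th$promoter_length), ""),
        cand)
    }
    motifs <- setNames(as.list(loaded$tf_motifs$motif),
                       loaded$tf_motifs$tf_id)
    tp <- tf_gene_pairs(tf_em, gene_em, de_all, proms, motifs,
                        pcc_threshold = th$pcc_threshold,
                        p_threshold = th$p_threshold,
                        require_motif = md$require_motif)
    write.table(tp, file.path(out, "tf_pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    tp
  })
  network <- stage("assemble_network", {
    net <- assemble_network(
      tf_pairs = tf_pairs,
      mirna_pairs = mirna_pairs,
      lnc_cis_pairs = cis_pairs,
      lnc_trans_pairs = trans_pairs,
      role_map = roles)
    export_network(net, file.path(out, "network_edges.tsv"), "tsv")
    export_network(net, file.path(out, "network.sif"), "sif")
    export_network(net, file.path(out, "network.graphml"), "graphml")
    net
  })
  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- stage("recovery", {
      rm_ <- recovery_metrics(network, truth)
      write.table(rm_, file.path(out, "recovery_metrics.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      rm_
    })
  }
  manifest$stages <- list(
    load = list(rna_features = nrow(loaded$counts_rna$values),
                mirna_features = nrow(loaded$counts_mirna$values),
                samples = ncol(loaded$counts_rna$values)),
    differential_expression = list(
      rows = nrow(de_all),
      de_features = length(sig_ids),
      dels = length(dels), degs = length(degs), dems = length(dems)),
    classify_lncrna = list(rows = nrow(classes)),
    cis_targets = list(rows = nrow(cis_pairs)),
    trans_targets = list(rows = nrow(trans_pairs)),
    mirna_targets = list(rows = nrow(mirna_pairs)),
    tf_pairs = list(rows = nrow(tf_pairs),
                    accepted = sum(tf_pairs$accepted)),
    network = list(nodes = nrow(network$nodes),
                   edges = nrow(network$edges)),
    recovery = if (is.null(recovery)) NULL else
      list(rows = nrow(recovery)))
  manifest$stages <- Filter(Negate(is.null), manifest$stages)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(network = network, de = de_all, classes = classes,
                 cis_pairs = cis_pairs, trans_pairs = trans_pairs,
                 mirna_pairs = mirna_pairs, tf_pairs = tf_pairs,
                 recovery = recovery, manifest = manifest,
                 truth = truth, output_dir = out))
}

# md5 of the canonical JSON rendering of the analysis-relevant config
# (identical analysis config => identical hash regardless of where the
# outputs are written; no timestamps involved)
.config_md5 <- function(config) {
  x <- unclass(config)
  x$output_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
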