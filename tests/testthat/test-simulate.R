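test_that("identical config and seed reproduce the fixture byte for byte", {
  d1 <- file.path(tempdir(), "sim_det_a")
  d2 <- file.path(tempdir(), "sim_det_b")
  simulate_dataset(small_sim_config(seed = 5), d1)
  simulate_dataset(small_sim_config(seed = 5), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed changes the data
  d3 <- file.path(tempdir(), "sim_det_c")
  simulate_dataset(small_sim_config(seed = 6), d3)
  expect_false(identical(readLines(file.path(d1, "counts_rna.tsv")),
                         readLines(file.path(d3, "counts_rna.tsv"))))
})

test_that("four cis-planted lncRNAs realize exactly the four classes", {
  cfg <- sim_config(n_genes = 10, n_tfs = 2, n_lncrnas = 4, n_mirnas = 2,
                    planted_tf_edges = 2, planted_mirna_edges = 2,
                    planted_lnc_cis_edges = 4, planted_lnc_trans_edges = 0,
                    n_background_genes = 5, n_background_mirnas = 2,
                    seed = 3)
  si <- generate_annotation(cfg)
  expect_setequal(si$lnc_classes$class,
                  c("lincRNA", "intronic", "antisense", "sense"))
  # recorded classes agree with positional classification of the annotation
  cl <- classify_lncrna(si$annotation)
  merged <- merge(cl, si$lnc_classes, by = "lnc_id")
  expect_equal(merged$class.x, merged$class.y)
})

test_that("infeasible placement fails with the constraint named", {
  cfg <- small_sim_config(chrom_length = 50000)
  expect_error(generate_annotation(cfg), "too small")
  expect_error(sim_config(n_genes = 2, planted_tf_edges = 30),
               "exceed")
  expect_error(sim_config(nb_dispersion = 0), "dispersion")
  expect_error(sim_config(target_correlation = 1.5), "target_correlation")
})

test_that("motif presence is equivalent to planted TF regulation", {
  cfg <- small_sim_config(seed = 9)
  si <- generate_annotation(cfg)
  pm <- plant_motifs(si, cfg)
  edges <- si$plan$edges
  tf_edges <- edges[edges$mechanism == "tf_binding", ]
  motifs <- setNames(pm$tf_motifs$motif, pm$tf_motifs$tf_id)
  # every planted target promoter carries its TF's element
  for (i in seq_len(nrow(tf_edges))) {
    hits <- scan_motif(pm$promoters[[tf_edges$target_id[i]]],
                       motifs[[tf_edges$source_id[i]]])
    expect_gte(nrow(hits), 1)
  }
  # no non-target promoter contains any element (either strand)
  non_targets <- setdiff(names(pm$promoters), tf_edges$target_id)
  total <- sum(vapply(non_targets, function(g) {
    sum(vapply(motifs, function(mo) nrow(scan_motif(pm$promoters[[g]], mo)),
               numeric(1)))
  }, numeric(1)))
  expect_equal(total, 0)
  # recorded placements are recovered by scanning at the recorded offset
  pl <- pm$placements
  for (i in seq_len(nrow(pl))) {
    hits <- scan_motif(pm$promoters[[pl$gene_id[i]]],
                       motifs[[pl$tf_id[i]]])
    expect_true(any(hits$offset == pl$offset[i] &
                      hits$strand == pl$strand[i]))
  }
  # promoters patched into the genome match strand-aware extraction
  for (g in utils::head(names(pm$promoters), 5)) {
    expect_equal(extract_promoter(si$annotation, g, pm$genome,
                                  cfg$promoter_length),
                 unname(pm$promoters[[g]]))
  }
})

test_that("no elements are implanted when motif planting is disabled", {
  cfg <- small_sim_config(seed = 9, plant_motifs = FALSE)
  si <- generate_annotation(cfg)
  pm <- plant_motifs(si, cfg)
  expect_equal(nrow(pm$placements), 0)
  motifs <- setNames(pm$tf_motifs$motif, pm$tf_motifs$tf_id)
  total <- sum(vapply(names(pm$promoters), function(g) {
    sum(vapply(motifs, function(mo) nrow(scan_motif(pm$promoters[[g]], mo)),
               numeric(1)))
  }, numeric(1)))
  expect_equal(total, 0)
})

test_that("planted pairs approach perfect correlation in the clean limit", {
  cfg <- small_sim_config(seed = 2, target_correlation = 1,
                          nb_dispersion = 1e-4)
  si <- generate_annotation(cfg)
  ex <- generate_expression(si, cfg)
  v <- log2(rbind(ex$counts_rna$values, ex$counts_mirna$values) + 1)
  ed <- si$plan$edges
  for (i in seq_len(nrow(ed))) {
    r <- cor(v[ed$source_id[i], ], v[ed$target_id[i], ])
    if (ed$mechanism[i] %in% c("tf_binding", "lnc_cis")) {
      expect_gt(r, 0.99)
    } else {
      expect_lt(r, -0.99)
    }
  }
})

test_that("planted-pair correlations dominate decoy-pair correlations", {
  cfg <- small_sim_config(seed = 4)
  si <- generate_annotation(cfg)
  ex <- generate_expression(si, cfg)
  v <- log2(ex$counts_rna$values + 1)
  ed <- si$plan$edges
  ed <- ed[ed$mechanism != "mirna_cleavage", ]
  planted <- abs(mapply(function(s, t) cor(v[s, ], v[t, ]),
                        ed$source_id, ed$target_id))
  decoy_lncs <- setdiff(si$plan$lncs,
                        c(si$plan$cis_lncs, si$plan$trans_lncs))
  decoy_genes <- setdiff(si$plan$genes, si$plan$edges$target_id)
  grid <- expand.grid(lnc = decoy_lncs, gene = decoy_genes,
                      stringsAsFactors = FALSE)
  decoy <- abs(mapply(function(l, g) cor(v[l, ], v[g, ]),
                      grid$lnc, grid$gene))
  expect_gt(min(planted), stats::median(decoy))
  expect_gt(mean(outer(planted, decoy, ">")), 0.95)
})

test_that("planted TF pairs at the frozen reference seed stay tight", {
  # regression baseline computed once at seed 101 and frozen: every one of
  # the 20 planted TF pairs exceeded |PCC| 0.8 (minimum 0.884)
  cfg <- sim_config(n_genes = 40, n_tfs = 20, n_lncrnas = 4, n_mirnas = 4,
                    planted_tf_edges = 20, planted_mirna_edges = 2,
                    planted_lnc_cis_edges = 2, planted_lnc_trans_edges = 2,
                    n_background_genes = 30, n_background_mirnas = 8,
                    seed = 101)
  si <- generate_annotation(cfg)
  ex <- generate_expression(si, cfg)
  v <- log2(ex$counts_rna$values + 1)
  ed <- si$plan$edges
  ed <- ed[ed$mechanism == "tf_binding", ]
  pcc <- mapply(function(s, t) cor(v[s, ], v[t, ]), ed$source_id,
                ed$target_id)
  expect_equal(mean(abs(pcc) > 0.8), 1)
  expect_gt(min(pcc), 0.85)
})

test_that("expected DE bookkeeping matches the latent trajectories", {
  cfg <- small_sim_config(seed = 12)
  si <- generate_annotation(cfg)
  ex <- generate_expression(si, cfg)
  tr <- ex$trajectories
  manual <- rownames(tr)[apply(tr, 1, function(t)
    max(abs(t[1] - t[-1])) >= 1)]
  expect_setequal(ex$expected_de, manual)
  # planted features are expected-DE; background never is
  expect_true(all(si$plan$edges$source_id %in% ex$expected_de))
  expect_false(any(si$plan$bg_genes %in% ex$expected_de))
})

test_that("the emitted bundle round-trips through the package readers", {
  d <- file.path(tempdir(), "sim_rt")
  sim <- simulate_dataset(small_sim_config(seed = 8), d)
  ann <- read_gff3(sim$paths[["annotation"]])
  expect_equal(ann$features[, c("id", "type", "role", "start", "end")],
               sim$annotation$features[, c("id", "type", "role", "start",
                                           "end")])
  roles_df <- read.delim(sim$paths[["roles"]])
  roles <- setNames(roles_df$role, roles_df$feature_id)
  cr <- read_counts(sim$paths[["counts_rna"]], sim$paths[["samples"]], roles)
  expect_equal(cr$values, sim$counts_rna$values)
  expect_equal(cr$roles, sim$counts_rna$roles)
  tx <- read_fasta(sim$paths[["transcripts"]])
  expect_equal(unname(tx[names(sim$transcripts)]),
               unname(sim$transcripts))
  gen <- read_fasta(sim$paths[["genome"]])
  expect_equal(nchar(gen[["chr1"]]), nchar(sim$genome[["chr1"]]))
  # planted miRNA sites are present verbatim in their target transcripts
  ed <- sim$truth$edges
  ed <- ed[ed$mechanism == "mirna_cleavage", ]
  mir <- read_fasta(sim$paths[["mirnas"]])
  for (i in seq_len(nrow(ed))) {
    expect_true(grepl(revcomp_chr(mir[[ed$source_id[i]]]),
                      tx[[ed$target_id[i]]], fixed = TRUE))
  }
})
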