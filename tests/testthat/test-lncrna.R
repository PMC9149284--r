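test_that("positional classification assigns each class by precedence", {
  ann <- tiny_annotation()
  cl <- classify_lncrna(ann)
  got <- setNames(cl$class, cl$lnc_id)
  expect_equal(got[["lncI"]], "intronic")   # inside gA's intron, same strand
  expect_equal(got[["lncS"]], "sense")      # overlaps gA exon 1, same strand
  expect_equal(got[["lncA"]], "antisense")  # overlaps gA, opposite strand
  expect_equal(got[["lncL"]], "lincRNA")    # 28 kb from the nearest gene
  expect_equal(cl$gene_id[cl$lnc_id == "lncI"], "gA")
  expect_equal(cl$gene_id[cl$lnc_id == "lncL"], "")
  # total and single-valued: one row per input, class always one of four
  expect_equal(nrow(cl), 4)
  expect_true(all(cl$class %in% c("lincRNA", "intronic", "antisense",
                                  "sense")))
})

test_that("exonic same-strand overlap outranks opposite-strand overlap", {
  # lncX overlaps gA exon 1 on the same strand AND an opposite-strand gene
  ann <- tiny_annotation()
  extra_gene <- data.frame(
    id = c("gC", "gC.t"), type = c("gene", "transcript"), role = "mRNA",
    chrom = "chr1", strand = "-", start = 1150L, end = 1350L,
    parent_id = c(NA, "gC"), stringsAsFactors = FALSE)
  lncX <- data.frame(
    id = c("lncX", "lncX.t"), type = c("gene", "transcript"),
    role = "lncRNA", chrom = "chr1", strand = "+", start = 1200L,
    end = 1340L, parent_id = c(NA, "lncX"), stringsAsFactors = FALSE)
  feats <- rbind(ann$features, extra_gene, lncX)
  exons <- rbind(ann$exons,
                 data.frame(parent_id = c("gC.t", "lncX.t"),
                            start = c(1150L, 1200L), end = c(1350L, 1340L)))
  ann2 <- genome_annotation(feats, exons)
  cl <- classify_lncrna(ann2, "lncX")
  expect_equal(cl$class, "sense")
})

test_that("cis windows use gap distance with inclusive 10 kb boundary", {
  mk <- function(gene_start) {
    feats <- data.frame(
      id = c("lnc", "lnc.t", "g", "g.t"),
      type = rep(c("gene", "transcript"), 2),
      role = c("lncRNA", "lncRNA", "mRNA", "mRNA"),
      chrom = "chr1", strand = "+",
      start = c(5000L, 5000L, gene_start, gene_start),
      end = c(10000L, 10000L, gene_start + 999L, gene_start + 999L),
      parent_id = c(NA, "lnc", NA, "g"), stringsAsFactors = FALSE)
    exons <- data.frame(parent_id = c("lnc.t", "g.t"),
                        start = c(5000L, gene_start),
                        end = c(10000L, gene_start + 999L))
    genome_annotation(feats, exons)
  }
  # gap = gene_start - lnc_end - 1
  expect_equal(cis_targets(mk(20001L), "lnc")$gene_id, "g")   # gap 10000
  expect_equal(nrow(cis_targets(mk(20002L), "lnc")), 0)       # gap 10001
  hit <- cis_targets(mk(8000L), "lnc")                        # overlap
  expect_equal(hit$gap_bp, 0)
  expect_equal(cis_targets(mk(20001L), "lnc")$gap_bp, 10000)
})

test_that("cis target sets are invariant under coordinate reflection", {
  ref_point <- 1000000L
  base <- tiny_annotation()
  reflect <- function(ann) {
    f <- ann$features
    ns <- ref_point - f$end; ne <- ref_point - f$start
    f$start <- ns; f$end <- ne
    f$strand <- ifelse(f$strand == "+", "-", "+")
    e <- ann$exons
    es <- ref_point - e$end; ee <- ref_point - e$start
    e$start <- es; e$end <- ee
    genome_annotation(f, e)
  }
  mirrored <- reflect(base)
  for (lnc in c("lncI", "lncS", "lncA", "lncL")) {
    expect_setequal(cis_targets(base, lnc)$gene_id,
                    cis_targets(mirrored, lnc)$gene_id)
  }
})

test_that("candidate filtering applies the length and ORF rules", {
  no_orf <- function(n) strrep("C", n)  # no ATG at all
  with_orf <- function(codons) {
    # ATG + (codons-1) CCC + TAA stop, embedded in C-runs
    paste0(strrep("C", 60), "ATG", strrep("CCC", codons - 1), "TAA",
           strrep("C", 60))
  }
  seqs <- c(short = no_orf(150),
            clean = no_orf(500),
            small_orf = with_orf(40),     # 40-codon ORF, length ~250
            big_orf = with_orf(150))      # 150-codon ORF, length ~580
  expect_false(nchar(seqs[["small_orf"]]) < 200)
  kept <- filter_lncrna_candidates(names(seqs), seqs)
  expect_false("short" %in% kept)     # 150 nt < 200
  expect_true("clean" %in% kept)
  expect_true("small_orf" %in% kept)  # ORF 40 < 100 codons
  expect_false("big_orf" %in% kept)   # ORF 150 >= 100 codons
  expect_error(filter_lncrna_candidates("missing", seqs), "missing")
})

test_that("open reading frames without a stop codon still count", {
  # ATG then 120 Pro codons running off the 3' end, length > 200
  s <- c(open = paste0(strrep("C", 40), "ATG", strrep("CCC", 120)))
  expect_length(filter_lncrna_candidates("open", s), 0)
})

test_that("trans calling requires anticorrelation plus opposite DE calls", {
  samples <- paste0("s", 1:9)
  conds <- setNames(rep(c("N0", "N6", "N18"), each = 3), samples)
  x <- c(1, 1.1, 0.9, 5, 5.1, 4.9, 9, 9.1, 8.9)
  shuffled <- c(5, 9, 1, 9, 1, 5, 1, 5.2, 9)
  lv <- rbind(lnc1 = 10 - x,   # strong anticorrelation with x
              lnc2 = x,        # strong positive correlation
              lnc3 = 10 - shuffled)
  gv <- rbind(gene = x)
  colnames(lv) <- colnames(gv) <- samples
  lnc_em <- em_from_log2(lv, setNames(rep("lncRNA", 3), rownames(lv)), conds)
  gene_em <- em_from_log2(gv, c(gene = "mRNA"), conds)
  de <- data.frame(
    feature_id = c("lnc1", "lnc2", "lnc3", "gene"),
    contrast = "N0 vs N6",
    call = c("down", "up", "down", "up"), stringsAsFactors = FALSE)
  got <- trans_targets(lnc_em, gene_em, de)
  expect_equal(got$lnc_id, "lnc1")       # lnc2: +PCC; lnc3: |PCC| < 0.9
  expect_equal(got$gene_id, "gene")
  expect_lt(got$pcc, -0.9)
  expect_equal(got$contrast, "N0 vs N6")

  # absolute mode admits the positively correlated DE pair as well
  got_abs <- trans_targets(lnc_em, gene_em, de, mode = "absolute")
  expect_setequal(got_abs$lnc_id, c("lnc1", "lnc2"))

  # same-direction calls block the pair even under strong anticorrelation
  de2 <- de; de2$call <- c("up", "up", "up", "up")
  expect_equal(nrow(trans_targets(lnc_em, gene_em, de2)), 0)
})

test_that("zero-variance profiles are skipped with a warning, never NaN", {
  samples <- paste0("s", 1:9)
  conds <- setNames(rep(c("N0", "N6", "N18"), each = 3), samples)
  lv <- rbind(flat = rep(2, 9), ok = 9:1)
  gv <- rbind(gene = 1:9)
  colnames(lv) <- colnames(gv) <- samples
  lnc_em <- em_from_log2(lv, c(flat = "lncRNA", ok = "lncRNA"), conds)
  gene_em <- em_from_log2(gv, c(gene = "mRNA"), conds)
  de <- data.frame(feature_id = c("flat", "ok", "gene"),
                   contrast = "N0 vs N18",
                   call = c("down", "down", "up"), stringsAsFactors = FALSE)
  expect_warning(got <- trans_targets(lnc_em, gene_em, de), "zero-variance")
  expect_false(any(is.na(got$pcc)))
  expect_equal(got$lnc_id, "ok")
})
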