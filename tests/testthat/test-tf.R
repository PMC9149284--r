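test_that("correlation matches hand values and affine identities", {
  expect_equal(pearson_with_p(1:5, 2 * (1:5) + 3)$r, 1)
  expect_equal(pearson_with_p(1:5, -(1:5))$r, -1)
  expect_equal(pearson_with_p(1:5, 2 * (1:5))$p, 0)
  # deviation products 4 over sqrt(5 * 5)
  got <- pearson_with_p(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(got$r, 0.8)
  expect_error(pearson_with_p(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_with_p(1:2, 1:2), "n >= 3")
})

test_that("correlation p-values match the t-reference to high precision", {
  set.seed(14)
  for (i in 1:300) {
    n <- sample(c(6, 9, 12), 1)
    x <- rnorm(n)
    y <- rnorm(n) + x * runif(1, -2, 2)
    got <- pearson_with_p(x, y)
    ref <- cor.test(x, y)
    expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("promoter extraction is strand-aware and truncates at edges", {
  feats <- data.frame(
    id = c("plus", "minus", "edge"),
    type = "gene", role = "mRNA", chrom = "chr1",
    strand = c("+", "-", "+"),
    start = c(5001L, 2001L, 101L),
    end = c(6000L, 3000L, 200L),
    parent_id = NA_character_, stringsAsFactors = FALSE)
  ann <- genome_annotation(feats, data.frame(parent_id = character(0),
                                             start = integer(0),
                                             end = integer(0)))
  set.seed(8)
  chrom <- random_dna_chr(10000)
  genome <- c(chr1 = chrom)

  # plus strand: the 2000 bases immediately upstream of start
  expect_equal(extract_promoter(ann, "plus", genome),
               substr(chrom, 3001, 5000))
  # minus strand: downstream bases, reverse-complemented
  expect_equal(extract_promoter(ann, "minus", genome),
               revcomp_chr(substr(chrom, 3001, 5000)))
  # truncation at the chromosome start, with warning
  expect_warning(p <- extract_promoter(ann, "edge", genome), "truncated")
  expect_equal(p, substr(chrom, 1, 100))
  expect_equal(nchar(p), 100)
  expect_error(extract_promoter(ann, "nope", genome), "unknown gene")
})

test_that("motif scanning handles strands, IUPAC codes, and PWMs", {
  prom <- paste0(strrep("A", 50), "TGACGT", strrep("A", 30), "ACGTCA",
                 strrep("A", 20))
  hits <- scan_motif(prom, "TGACGT")
  expect_equal(hits$offset, c(50L, 86L))
  expect_equal(hits$strand, c("+", "-"))  # ACGTCA is the reverse complement

  # N matches anything
  expect_equal(nrow(scan_motif("CCTGACGTCC", "TGACNT")[
    scan_motif("CCTGACGTCC", "TGACNT")$strand == "+", ]), 1)

  # PWM mode: perfect window scores 1, threshold excludes weak windows
  pwm <- matrix(0.1, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm[cbind(match(c("T", "G", "A", "C"), c("A", "C", "G", "T")), 1:4)] <- 1
  mm <- motif_model("m", "TGAC", pwm = pwm, score_fraction_threshold = 0.9)
  ph <- scan_motif(paste0("CCCC", "TGAC", "CCCC"), mm)
  expect_true(any(ph$offset == 4 & ph$strand == "+"))
  expect_equal(max(ph$score), 1)
})

test_that("motif scanning equals regex enumeration on random promoters", {
  set.seed(77)
  for (i in 1:25) {
    prom <- random_dna_chr(300)
    consensus <- c("TGACGT", "TGACNT", "RYGACW", "TGASTCA")[[sample(4, 1)]]
    got <- scan_motif(prom, consensus)
    ref <- scan_motif_oracle(prom, consensus)
    expect_setequal(got$offset[got$strand == "+"], ref$fwd)
    expect_setequal(got$offset[got$strand == "-"], ref$rev)
  }
})

test_that("TF pairing applies coexpression, significance, and motif gates", {
  samples <- paste0("s", 1:9)
  conds <- setNames(rep(c("N0", "N6", "N18"), each = 3), samples)
  t_prof <- c(1, 1.2, 0.8, 5, 5.2, 4.8, 9, 9.2, 8.8)
  tl <- rbind(TF1 = t_prof)
  gl <- rbind(gA = t_prof + 0.05,          # near-perfect correlation
              gB = t_prof + 0.05,          # same profile, no motif
              gC = rev(t_prof))            # strong anticorrelation
  colnames(tl) <- colnames(gl) <- samples
  tf_em <- em_from_log2(tl, c(TF1 = "TF"), conds)
  gene_em <- em_from_log2(gl, setNames(rep("mRNA", 3), rownames(gl)), conds)
  de <- data.frame(feature_id = c("TF1", "gA", "gB", "gC"),
                   contrast = "N0 vs N18",
                   call = c("up", "up", "up", "down"),
                   stringsAsFactors = FALSE)
  proms <- c(gA = paste0(random_dna_chr(100), "TGACGTAAAA",
                         random_dna_chr(100)),
             gB = strrep("C", 210),
             gC = paste0("TGACGTAAAA", strrep("C", 200)))
  pairs <- tf_gene_pairs(tf_em, gene_em, de, proms,
                         motifs = list(TF1 = "TGACGTAAAA"))
  acc <- setNames(pairs$accepted, pairs$gene_id)
  expect_true(acc[["gA"]])    # correlated + motif
  expect_false(acc[["gB"]])   # correlated, no motif hit
  expect_true(acc[["gC"]])    # |PCC| gate, sign not restricted; motif present
  expect_true(all(pairs$pcc_p < 0.05))
  expect_error(tf_gene_pairs(tf_em, gene_em, de, proms, motifs = list()),
               "no motif assigned")
  # without the motif requirement, gB passes on coexpression alone
  pairs2 <- tf_gene_pairs(tf_em, gene_em, de, proms,
                          motifs = list(TF1 = "TGACGTAAAA"),
                          require_motif = FALSE)
  expect_true(all(pairs2$accepted))
})

test_that("a pair at exactly the correlation threshold is rejected", {
  samples <- paste0("s", 1:4)
  conds <- setNames(rep(c("N0", "N6"), each = 2), samples)
  tl <- rbind(TF1 = c(1, 2, 3, 4))
  gl <- rbind(gA = c(1, 3, 2, 4))  # r = 0.8 exactly
  colnames(tl) <- colnames(gl) <- samples
  tf_em <- em_from_log2(tl, c(TF1 = "TF"), conds)
  gene_em <- em_from_log2(gl, c(gA = "mRNA"), conds)
  de <- data.frame(feature_id = c("TF1", "gA"), contrast = "N0 vs N6",
                   call = "up", stringsAsFactors = FALSE)
  pairs <- tf_gene_pairs(tf_em, gene_em, de,
                         c(gA = paste0("TGACGT", strrep("A", 50))),
                         motifs = list(TF1 = "TGACGT"))
  expect_equal(pairs$pcc, 0.8)
  expect_false(pairs$accepted)  # strict > 0.8
})
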