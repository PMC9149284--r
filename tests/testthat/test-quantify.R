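make_em <- function(m, conds = NULL) {
  if (is.null(conds)) conds <- setNames(rep("A", ncol(m)), colnames(m))
  expression_matrix(m, setNames(rep("mRNA", nrow(m)), rownames(m)), conds)
}

test_that("FPKM matches its definition and guards degenerate input", {
  m <- matrix(c(10, 999990, 0, 1e6), 2, 2,
              dimnames = list(c("f1", "f2"), c("s1", "s2")))
  em <- make_em(m)
  lens <- c(f1 = 2000, f2 = 1000)
  out <- fpkm(em, lens)
  # count 10, length 2000 bp, total 1e6 -> 10 * 1e9 / (2000 * 1e6) = 5
  expect_equal(out$values["f1", "s1"], 5)
  expect_equal(out$values["f1", "s2"], 0)  # zero count -> zero FPKM
  expect_equal(out$unit, "FPKM")

  # equal lengths and equal counts -> equal FPKM within a sample
  m2 <- matrix(c(7, 7, 7), 3, 1, dimnames = list(paste0("g", 1:3), "s"))
  out2 <- fpkm(make_em(m2), setNames(rep(500, 3), paste0("g", 1:3)))
  expect_length(unique(out2$values[, 1]), 1)

  expect_error(fpkm(em, c(f1 = 0, f2 = 1000)), "length")
  m3 <- m; m3[, 1] <- 0
  expect_error(fpkm(make_em(m3), lens), "zero total")
  expect_error(fpkm(out, lens), "raw counts")
})

test_that("TPM columns are exact proportions summing to one million", {
  m <- matrix(c(1, 3, 42, 0), 2, 2,
              dimnames = list(c("f1", "f2"), c("s1", "s2")))
  out <- tpm(make_em(m))
  expect_equal(out$values[, "s1"], c(f1 = 250000, f2 = 750000))
  expect_equal(unname(colSums(out$values)), c(1e6, 1e6), tolerance = 1e-9)

  one <- matrix(5, 1, 1, dimnames = list("only", "s"))
  expect_equal(unname(tpm(make_em(one))$values[1, 1]), 1e6)

  # scale equivariance: doubling a sample's counts leaves TPM unchanged
  m2 <- m; m2[, 1] <- m2[, 1] * 2
  expect_equal(tpm(make_em(m2))$values[, "s1"], out$values[, "s1"])
})

test_that("log2 fold change is antisymmetric and handles zeros", {
  expect_equal(log2_fold_change(5, 5), 0)
  expect_equal(log2_fold_change(10, 40, pseudocount = 1e-9), 2,
               tolerance = 1e-6)
  expect_equal(log2_fold_change(3, 12), -log2_fold_change(12, 3))
  expect_equal(log2_fold_change(0, 0), 0)
  expect_error(log2_fold_change(1, 2, pseudocount = 0), "pseudocount")
})

test_that("Welch test flags separated groups and is honest under the null", {
  conds <- setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
  set.seed(42)
  sep <- rbind(x = c(1, 1, 1, 100, 100, 100) + runif(6, 0, 0.01))
  colnames(sep) <- names(conds)
  p <- de_test(make_em(sep, conds), c("A", "B"))
  expect_lt(p[["x"]], 0.01)

  flat <- rbind(y = rep(7, 6)); colnames(flat) <- names(conds)
  expect_equal(unname(de_test(make_em(flat, conds), c("A", "B"))[["y"]]), 1)

  # null simulation: both groups from one distribution -> p approx uniform
  set.seed(7)
  nullm <- matrix(rlnorm(1000 * 6, 5, 1), 1000, 6,
                  dimnames = list(paste0("f", 1:1000), names(conds)))
  pn <- de_test(make_em(nullm, conds), c("A", "B"))
  expect_gt(mean(pn < 0.05), 0.02)
  expect_lt(mean(pn < 0.05), 0.09)

  expect_error(de_test(make_em(sep, setNames(c("A", rep("B", 5)),
                                             names(conds))), c("A", "B")),
               "replicates")
})

test_that("Benjamini-Hochberg equals hand-derived step-up values", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(c(0.005, 0.1)), c(0.01, 0.1))
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_equal(benjamini_hochberg(numeric(0)), numeric(0))
})

test_that("Benjamini-Hochberg agrees with p.adjust and the brute oracle", {
  set.seed(3)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    got <- benjamini_hochberg(p)
    expect_equal(got, p.adjust(p, "BH"), tolerance = 1e-14)
    expect_equal(got, bh_oracle(p), tolerance = 1e-14)
  }
})

test_that("DE calls respect the stated boundary semantics", {
  # |FC| exactly 2 qualifies (>=), FDR exactly 0.05 does not (<)
  expect_equal(call_de(1.0, 0.049), "up")
  expect_equal(call_de(0.9, 0.001), "ns")
  expect_equal(call_de(-3.0, 0.05), "ns")
  expect_equal(call_de(-1.0, 0.049), "down")
  expect_equal(call_de(c(2, -2, 0), c(0.01, 0.01, 0.01)),
               c("up", "down", "ns"))
})

test_that("DE calling is monotone in effect size and significance", {
  set.seed(9)
  for (i in 1:200) {
    lfc <- runif(1, -4, 4); fdr <- runif(1)
    call1 <- call_de(lfc, fdr)
    if (call1 %in% c("up", "down")) {
      # stronger effect or smaller fdr never turns a call into ns
      expect_equal(call_de(lfc * 1.5, fdr), call1)
      expect_equal(call_de(lfc, fdr / 2), call1)
    }
  }
})

test_that("hypergeometric enrichment matches exact tail probabilities", {
  bg <- paste0("g", 1:20)
  de <- paste0("g", 1:5)
  res <- hypergeometric_enrichment(de, bg, list(
    all = bg,                       # whole background: no enrichment possible
    hit = paste0("g", 1:5),         # perfectly enriched
    none = paste0("g", 11:15)))     # k = 0
  expect_equal(res$p[res$term == "all"], 1)
  expect_equal(res$p[res$term == "hit"], 1 / choose(20, 5))
  expect_equal(res$p[res$term == "none"], 1)
  expect_true(all(res$fdr >= res$p - 1e-12))
  expect_error(hypergeometric_enrichment(c("g1", "zz"), bg, list(a = bg)),
               "absent")
})

test_that("2^-ddCt relative expression follows the qPCR identities", {
  expect_equal(ddct(5, 5, 7, 7), 1)          # ddCt = 0
  expect_equal(ddct(6, 5, 5, 5), 0.5)        # ddCt = 1
  expect_equal(ddct(3, 5, 5, 5), 4)          # ddCt = -2
  expect_error(ddct(Inf, 1, 1, 1))
})

test_that("differential_expression ties the pieces together per contrast", {
  set.seed(21)
  conds <- setNames(rep(c("N0", "N6", "N18"), each = 3), paste0("s", 1:9))
  base <- matrix(rnbinom(30 * 9, mu = 500, size = 50), 30, 9,
                 dimnames = list(paste0("f", 1:30), names(conds)))
  base["f1", conds == "N6"] <- rnbinom(3, mu = 8000, size = 50)
  em <- tpm(make_em(base, conds))
  de <- differential_expression(em)
  expect_setequal(unique(de$contrast),
                  c("N0 vs N6", "N0 vs N18", "N6 vs N18"))
  f1 <- de[de$feature_id == "f1" & de$contrast == "N0 vs N6", ]
  expect_equal(f1$call, "up")
  expect_gt(f1$log2fc, 1)
  # calls always respect their own fold change / fdr evidence
  called <- de[de$call != "ns", ]
  expect_true(all(abs(called$log2fc) >= 1 & called$fdr < 0.05))
})
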