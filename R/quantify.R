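# Normalization, differential calling, FDR, enrichment, qPCR arithmetic.

#' FPKM normalization
#'
#' Fragments per kilobase of exon model per million mapped fragments:
#' `count * 1e9 / (length_bp * sample_total)`. Used for mRNA, TF and
#' lncRNA abundances.
#'
#' @param em An [expression_matrix()] with unit `raw_count`.
#' @param lengths Named numeric vector of feature lengths in bp (exonic
#'   length), covering all features.
#' @return An [expression_matrix()] with unit `FPKM`.
#' @export
fpkm <- function(em, lengths) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$unit != "raw_count") stop("fpkm() expects raw counts")
  ids <- rownames(em$values)
  miss <- setdiff(ids, names(lengths))
  if (length(miss)) stop("missing length for: ", paste(head(miss, 5), collapse = ", "))
  len <- lengths[ids]
  if (any(len <= 0)) stop("zero or negative feature length")
  totals <- colSums(em$values)
  if (any(totals <= 0)) stop("sample with zero total count")
  vals <- sweep(em$values * 1e9 / len, 2, totals, "/")
  expression_matrix(vals, em$roles, em$conditions, "FPKM")
}

#' TPM normalization for small-RNA counts
#'
#' Transcripts per million without length normalization (each read is one
#' molecule): `count * 1e6 / sample_total`. Every column sums to 1e6.
#'
#' @param em An [expression_matrix()] with unit `raw_count`.
#' @return An [expression_matrix()] with unit `TPM`.
#' @export
tpm <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$unit != "raw_count") stop("tpm() expects raw counts")
  totals <- colSums(em$values)
  if (any(totals <= 0)) stop("sample with zero total count")
  vals <- sweep(em$values * 1e6, 2, totals, "/")
  expression_matrix(vals, em$roles, em$conditions, "TPM")
}

#' Log2 fold change between two group means
#'
#' `log2((mean_b + pseudocount) / (mean_a + pseudocount))`; antisymmetric
#' under swapping the groups. The pseudocount guards zero means.
#'
#' @param mean_a,mean_b Non-negative group means (vectorized).
#' @param pseudocount Positive pseudocount, default 1.
#' @return Numeric log2 fold change(s), condition B over condition A.
#' @export
log2_fold_change <- function(mean_a, mean_b, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (any(mean_a < 0) || any(mean_b < 0)) stop("means must be >= 0")
  log2((mean_b + pseudocount) / (mean_a + pseudocount))
}

# Welch two-sided t-test on one feature; constant-in-both convention.
.welch_p <- function(x, y) {
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  nx <- length(x); ny <- length(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * pt(-abs(t), df)
}

#' Per-feature two-group location test
#'
#' Welch unequal-variance t-test on `log2(normalized + 1)`, two-sided.
#' Features constant in both groups get p = 1 (no signal) unless the two
#' constants differ, which yields p = 0.
#'
#' @param em An [expression_matrix()] in a normalized unit.
#' @param contrast Character vector of two condition labels
#'   `c(condition_a, condition_b)`.
#' @return Named numeric vector of p-values, one per feature.
#' @export
de_test <- function(em, contrast) {
  stopifnot(inherits(em, "expression_matrix"), length(contrast) == 2)
  ga <- names(em$conditions)[em$conditions == contrast[1]]
  gb <- names(em$conditions)[em$conditions == contrast[2]]
  if (length(ga) < 2 || length(gb) < 2) {
    stop("each group needs >= 2 replicates (",
         contrast[1], ": ", length(ga), ", ",
         contrast[2], ": ", length(gb), ")")
  }
  lv <- log2(em$values + 1)
  a <- lv[, ga, drop = FALSE]
  b <- lv[, gb, drop = FALSE]
  p <- vapply(seq_len(nrow(lv)),
              function(i) .welch_p(a[i, ], b[i, ]), numeric(1))
  setNames(p, rownames(lv))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `fdr_i = min_{j: p_j >= p_i} (p_j * m / rank_j)`, capped at 1;
#' order-preserving in the ranked p ordering.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in the original order.
#' @export
benjamini_hochberg <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(p[o] * m / (m:1)))
  adj[ro]
}

#' Differential-expression call from effect size and FDR
#'
#' `up` when `log2fc >= log2(fc_threshold)` and `fdr < fdr_threshold`;
#' `down` for the mirrored effect; otherwise `ns`. A fold change of
#' exactly `fc_threshold` qualifies (>=); an FDR of exactly
#' `fdr_threshold` does not (<).
#'
#' @param log2fc Log2 fold change(s).
#' @param fdr Adjusted p-value(s).
#' @param fc_threshold Fold-change threshold on the linear scale, default 2.
#' @param fdr_threshold FDR threshold, default 0.05.
#' @return Character vector in `{"up", "down", "ns"}`.
#' @export
call_de <- function(log2fc, fdr, fc_threshold = 2, fdr_threshold = 0.05) {
  if (fc_threshold <= 0 || fdr_threshold <= 0) stop("thresholds must be > 0")
  lt <- log2(fc_threshold)
  out <- rep("ns", length(log2fc))
  sig <- fdr < fdr_threshold
  out[sig & log2fc >= lt] <- "up"
  out[sig & log2fc <= -lt] <- "down"
  out
}

#' Differential expression over one or more contrasts
#'
#' Runs [de_test()] per contrast on a normalized matrix, adjusts p-values
#' with [benjamini_hochberg()] within each contrast, computes group-mean
#' fold changes with a pseudocount, and applies [call_de()].
#'
#' @param em Normalized [expression_matrix()] (FPKM or TPM).
#' @param contrasts List of 2-vectors of condition labels; default all
#'   pairwise combinations in order of appearance.
#' @param fc_threshold,fdr_threshold,pseudocount Calling parameters.
#' @return A `data.frame` with columns `feature_id`, `contrast`,
#'   `condition_a`, `condition_b`, `mean_a`, `mean_b`, `log2fc`,
#'   `p_value`, `fdr`, `call`.
#' @export
differential_expression <- function(em, contrasts = NULL, fc_threshold = 2,
                                    fdr_threshold = 0.05, pseudocount = 1) {
  stopifnot(inherits(em, "expression_matrix"))
  conds <- unique(unname(em$conditions))
  if (is.null(contrasts)) {
    contrasts <- utils::combn(conds, 2, simplify = FALSE)
  }
  res <- lapply(contrasts, function(ct) {
    p <- de_test(em, ct)
    fdr <- benjamini_hochberg(p)
    sa <- names(em$conditions)[em$conditions == ct[1]]
    sb <- names(em$conditions)[em$conditions == ct[2]]
    ma <- rowMeans(em$values[, sa, drop = FALSE])
    mb <- rowMeans(em$values[, sb, drop = FALSE])
    lfc <- log2_fold_change(ma, mb, pseudocount)
    data.frame(feature_id = rownames(em$values),
               contrast = paste(ct[1], "vs", ct[2]),
               condition_a = ct[1], condition_b = ct[2],
               mean_a = ma, mean_b = mb, log2fc = lfc,
               p_value = unname(p), fdr = unname(fdr),
               call = call_de(lfc, fdr, fc_threshold, fdr_threshold),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Hypergeometric over-representation test
#'
#' One-sided upper-tail hypergeometric p per term, `P(X >= k)` for `k`
#' differentially expressed members of a `K`-member term drawn `n` from
#' `N`, followed by Benjamini-Hochberg adjustment across terms.
#'
#' @param de_set Character vector of hit features (subset of background).
#' @param background_set Character vector, the universe.
#' @param term_map Named list mapping term id to a character vector of
#'   member features (subsets of background).
#' @return `data.frame` with `term`, `k`, `K`, `n`, `N`, `p`, `fdr`.
#' @export
hypergeometric_enrichment <- function(de_set, background_set, term_map) {
  de_set <- unique(de_set)
  background_set <- unique(background_set)
  out <- setdiff(de_set, background_set)
  if (length(out)) {
    stop("feature(s) absent from background: ",
         paste(head(out, 5), collapse = ", "))
  }
  N <- length(background_set)
  n <- length(de_set)
  rows <- lapply(names(term_map), function(tm) {
    members <- intersect(unique(term_map[[tm]]), background_set)
    K <- length(members)
    k <- length(intersect(members, de_set))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- benjamini_hochberg(res$p)
  res
}

#' Relative expression by the 2^-ddCt method
#'
#' `2 ^ -((ct_target_sample - ct_ref_sample) -
#'        (ct_target_calibrator - ct_ref_calibrator))`,
#' the standard qPCR quantification relative to a reference gene and a
#' calibrator sample.
#'
#' @param ct_target_sample,ct_ref_sample Ct values in the sample of
#'   interest for the target and the reference gene.
#' @param ct_target_calibrator,ct_ref_calibrator Ct values in the
#'   calibrator sample.
#' @return Relative expression (1 when ddCt = 0).
#' @export
ddct <- function(ct_target_sample, ct_ref_sample,
                 ct_target_calibrator, ct_ref_calibrator) {
  stopifnot(is.finite(ct_target_sample), is.finite(ct_ref_sample),
            is.finite(ct_target_calibrator), is.finite(ct_ref_calibrator))
  dd <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-dd)
}
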