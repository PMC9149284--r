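# TF -> gene regulation by coexpression plus promoter binding elements.

#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson coefficient with the usual t transform,
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom,
#' two-sided. Perfect correlation (`|r| = 1`) yields p = 0.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, both non-constant.
#' @return List with elements `r` and `p`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need n >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector")
  r <- cor(x, y)
  if (abs(r) >= 1) {
    return(list(r = sign(r), p = 0))
  }
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * pt(-abs(tstat), n - 2))
}

#' Extract a promoter sequence upstream of a gene
#'
#' Strand-aware: for a plus-strand gene the `length` bases immediately
#' upstream of its start; for a minus-strand gene the `length` bases
#' downstream of its end, reverse-complemented, so the promoter always
#' reads toward the gene. Truncated (with a warning) at the chromosome
#' boundary.
#'
#' @param annotation A [genome_annotation()].
#' @param gene_id Gene feature id.
#' @param genome Named character vector of chromosome sequences.
#' @param length Promoter length in bp, default 2000.
#' @return Promoter sequence (possibly shorter than `length` at a
#'   chromosome edge).
#' @export
extract_promoter <- function(annotation, gene_id, genome, length = 2000) {
  ft <- annotation$features
  g <- ft[ft$id == gene_id, , drop = FALSE]
  if (!nrow(g)) stop("unknown gene id: ", gene_id)
  if (!g$chrom %in% names(genome)) stop("chromosome not in genome: ", g$chrom)
  chrom <- genome[[g$chrom]]
  clen <- nchar(chrom)
  if (g$strand == "+") {
    from <- g$start - length
    to <- g$start - 1L
    if (from < 1L) {
      warning("promoter of ", gene_id, " truncated at chromosome start")
      from <- 1L
    }
    if (to < 1L) return("")
    substr(chrom, from, to)
  } else {
    from <- g$end + 1L
    to <- g$end + length
    if (to > clen) {
      warning("promoter of ", gene_id, " truncated at chromosome end")
      to <- clen
    }
    if (from > clen) return("")
    .revcomp(substr(chrom, from, to))
  }
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Construct a binding-element motif model
#'
#' Either a plain IUPAC consensus, or a consensus plus a position weight
#' matrix (rows A, C, G, T) scanned at a fractional score threshold.
#'
#' @param name Motif name.
#' @param consensus IUPAC consensus string.
#' @param pwm Optional 4 x L numeric matrix with rownames A, C, G, T.
#' @param score_fraction_threshold Fraction of the maximal attainable PWM
#'   score required for a hit in weight-matrix mode, default 0.85.
#' @return An object of class `motif_model`.
#' @export
motif_model <- function(name, consensus, pwm = NULL,
                        score_fraction_threshold = 0.85) {
  if (!nzchar(consensus)) stop("consensus must be non-empty")
  ok <- grepl("^[ACGTRYSWKMBDHVN]+$", toupper(consensus))
  if (!ok) stop("consensus contains non-IUPAC characters")
  if (!is.null(pwm)) {
    if (!is.matrix(pwm) || nrow(pwm) != 4 ||
        ncol(pwm) != nchar(consensus)) {
      stop("pwm must be a 4 x nchar(consensus) matrix")
    }
    if (is.null(rownames(pwm))) rownames(pwm) <- c("A", "C", "G", "T")
    if (score_fraction_threshold <= 0 || score_fraction_threshold > 1) {
      stop("score_fraction_threshold must be in (0, 1]")
    }
  }
  structure(list(name = name, consensus = toupper(consensus), pwm = pwm,
                 score_fraction_threshold = score_fraction_threshold),
            class = "motif_model")
}

#' Scan a promoter for motif hits on both strands
#'
#' Consensus mode reports every offset where the window matches the IUPAC
#' pattern on the forward or reverse strand; weight-matrix mode reports
#' windows scoring at least `score_fraction_threshold` of the maximal
#' attainable score. Offsets are 0-based on the promoter as given.
#'
#' @param promoter_seq Promoter sequence (DNA).
#' @param motif A [motif_model()] (a bare IUPAC string is also accepted).
#' @return `data.frame` with `offset` (0-based), `strand`, `score` (1 for
#'   consensus hits; PWM score fraction in weight-matrix mode).
#' @export
scan_motif <- function(promoter_seq, motif) {
  if (is.character(motif)) motif <- motif_model(motif, motif)
  stopifnot(inherits(motif, "motif_model"))
  subj <- Biostrings::DNAString(toupper(promoter_seq))
  empty <- data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (is.null(motif$pwm)) {
    pat <- Biostrings::DNAString(motif$consensus)
    fwd <- Biostrings::matchPattern(pat, subj,
                                    fixed = c(pattern = FALSE, subject = TRUE))
    rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat), subj,
                                    fixed = c(pattern = FALSE, subject = TRUE))
    hits <- rbind(
      if (length(fwd)) data.frame(offset = Biostrings::start(fwd) - 1L,
                                  strand = "+", score = 1) else empty,
      if (length(rev)) data.frame(offset = Biostrings::start(rev) - 1L,
                                  strand = "-", score = 1) else empty)
  } else {
    pwm <- motif$pwm[c("A", "C", "G", "T"), , drop = FALSE]
    maxsc <- sum(apply(pwm, 2, max))
    thr <- motif$score_fraction_threshold
    score_hits <- function(p, strand) {
      if (length(subj) < ncol(p)) return(empty)
      h <- Biostrings::matchPWM(p, subj, min.score = thr * maxsc)
      if (!length(h)) return(empty)
      sc <- vapply(as.character(h), function(w) {
        sum(p[cbind(match(strsplit(w, "")[[1]], c("A", "C", "G", "T")),
                    seq_len(ncol(p)))])
      }, numeric(1))
      data.frame(offset = Biostrings::start(h) - 1L, strand = strand,
                 score = unname(sc) / maxsc, stringsAsFactors = FALSE)
    }
    hits <- rbind(score_hits(pwm, "+"),
                  score_hits(Biostrings::reverseComplement(pwm), "-"))
  }
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Identify TF-gene regulatory pairs
#'
#' Every differentially expressed TF is paired with every differentially
#' expressed candidate gene; a pair is accepted iff `|PCC| >
#' pcc_threshold` (strict), `p < p_threshold` (strict), and - when
#' `require_motif` - the TF's binding element has at least one hit in the
#' gene's promoter. All evaluated pairs are returned with their evidence.
#'
#' @param tf_expr [expression_matrix()] containing the TFs.
#' @param gene_expr [expression_matrix()] containing the candidate genes.
#' @param de_results DE table covering TFs and genes (only features with a
#'   non-`ns` call in some contrast are paired).
#' @param promoters Named character vector of promoter sequences keyed by
#'   gene id.
#' @param motifs Named list mapping TF id to a [motif_model()] (or IUPAC
#'   string).
#' @param pcc_threshold,p_threshold Acceptance thresholds (defaults 0.8
#'   and 0.05, strict inequalities).
#' @param require_motif Gate pairs on promoter evidence, default TRUE.
#' @return `data.frame` with `tf_id`, `gene_id`, `pcc`, `pcc_p`,
#'   `motif_hits`, `accepted`.
#' @export
tf_gene_pairs <- function(tf_expr, gene_expr, de_results, promoters, motifs,
                          pcc_threshold = 0.8, p_threshold = 0.05,
                          require_motif = TRUE) {
  sig <- unique(de_results$feature_id[de_results$call != "ns"])
  tf_ids <- intersect(rownames(tf_expr$values)[tf_expr$roles == "TF"], sig)
  gene_ids <- intersect(rownames(gene_expr$values), sig)
  gene_ids <- setdiff(gene_ids, tf_ids)
  shared <- intersect(colnames(tf_expr$values), colnames(gene_expr$values))
  if (length(shared) < 3) stop("need >= 3 shared samples")
  if (require_motif) {
    nomotif <- setdiff(tf_ids, names(motifs))
    if (length(nomotif)) {
      stop("no motif assigned for TF(s): ", paste(nomotif, collapse = ", "))
    }
  }
  tl <- log2(tf_expr$values[tf_ids, shared, drop = FALSE] + 1)
  gl <- log2(gene_expr$values[gene_ids, shared, drop = FALSE] + 1)
  # motif hits are per (TF motif, gene promoter); cache per TF
  rows <- list()
  for (tf in tf_ids) {
    if (sd(tl[tf, ]) == 0) {
      warning("skipping constant TF profile: ", tf)
      next
    }
    hit_cache <- new.env(parent = emptyenv())
    for (g in gene_ids) {
      if (sd(gl[g, ]) == 0) next
      ct <- pearson_with_p(tl[tf, ], gl[g, ])
      nhits <- NA_integer_
      if (require_motif) {
        if (is.null(hit_cache[[g]])) {
          if (!g %in% names(promoters) || is.na(promoters[[g]])) {
            stop("no promoter sequence for gene: ", g)
          }
          hit_cache[[g]] <- nrow(scan_motif(promoters[[g]], motifs[[tf]]))
        }
        nhits <- hit_cache[[g]]
      }
      acc <- abs(ct$r) > pcc_threshold && ct$p < p_threshold &&
        (!require_motif || nhits >= 1)
      rows[[length(rows) + 1L]] <- data.frame(
        tf_id = tf, gene_id = g, pcc = ct$r, pcc_p = ct$p,
        motif_hits = nhits, accepted = acc, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(tf_id = character(0), gene_id = character(0),
                      pcc = numeric(0), pcc_p = numeric(0),
                      motif_hits = integer(0), accepted = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
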