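# Plant-rule miRNA target scoring and expression-coherence pairing.
#
# Scoring scheme: the miRNA is aligned antiparallel to a candidate site;
# per aligned position (counted from the miRNA 5' end) a Watson-Crick pair
# costs 0, a G:U wobble 0.5, a mismatch 1.0, and each bulged (inserted or
# deleted) base 2.0; penalties falling at miRNA positions 2-13 are doubled;
# the site score is the minimum total penalty over alignments with at most
# one contiguous bulge.

.DNA_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)
.DNA_COMP <- c(4L, 3L, 2L, 1L)  # A<->T, C<->G on the integer code

.encode_dna <- function(seq, what = "sequence") {
  s <- toupper(seq)
  s <- gsub("U", "T", s, fixed = TRUE)
  v <- .DNA_CODE[strsplit(s, "", fixed = TRUE)[[1]]]
  if (any(is.na(v))) {
    stop(what, " contains non-ACGTU character(s)")
  }
  unname(v)
}

# 4x4 penalty lookup: rows miRNA base, cols complement(target base).
# Equal codes pair Watson-Crick; wobble pairs G:U and U:G of the original
# strands appear here as (G, A) and (T, C) because the target is stored
# as its complement.
.pair_penalty_matrix <- function(mismatch = 1, wobble = 0.5) {
  p <- matrix(mismatch, 4, 4)
  diag(p) <- 0
  p[.DNA_CODE[["G"]], .DNA_CODE[["A"]]] <- wobble
  p[.DNA_CODE[["T"]], .DNA_CODE[["C"]]] <- wobble
  p
}

.position_weights <- function(m_len, seed_start = 2L, seed_end = 13L) {
  w <- rep(1, m_len + 1L)  # +1: bulge insertion point can sit after the 3' end
  idx <- seq_len(m_len + 1L)
  w[idx >= seed_start & idx <= seed_end] <- 2
  w
}

# Best penalty per window start for all windows of length M + k on an
# encoded transcript (k = 0 ungapped, k > 0 target bulge, k < 0 miRNA
# bulge). Returns a numeric vector indexed by window start.
.scan_windows_k <- function(m, compseq, k, weights, pmat,
                            gap_open = 2) {
  M <- length(m)
  W <- M + k
  L <- length(compseq)
  n <- L - W + 1L
  if (n < 1L || W < 1L) return(numeric(0))
  wt <- weights[seq_len(M)]
  if (k == 0L) {
    sc <- numeric(n)
    for (i in seq_len(M)) {
      idx <- (W - i + 1L):(L - i + 1L)
      sc <- sc + pmat[m[i], compseq[idx]] * wt[i]
    }
    return(sc)
  }
  if (k > 0L) {
    # A_i: miRNA i aligned before the bulge; B_i: after the bulge
    A <- matrix(0, M, n); B <- matrix(0, M, n)
    for (i in seq_len(M)) {
      ia <- (M + k - i + 1L):(L - i + 1L)
      ib <- (M - i + 1L):(L - i + 1L - k)
      A[i, ] <- pmat[m[i], compseq[ia]] * wt[i]
      B[i, ] <- pmat[m[i], compseq[ib]] * wt[i]
    }
    cumA <- rbind(0, apply(A, 2, cumsum))           # (M+1) x n
    sumB <- colSums(B)
    cumB <- rbind(0, apply(B, 2, cumsum))
    best <- rep(Inf, n)
    for (p in seq_len(M + 1L)) {
      pen <- gap_open * k * weights[p]
      sc <- cumA[p, ] + (sumB - cumB[p, ]) + pen
      best <- pmin(best, sc)
    }
    return(best)
  }
  # k < 0: |k| miRNA bases bulged out at positions d..d+|k|-1
  kk <- -k
  if (kk >= M) return(numeric(0))
  C <- matrix(0, M, n); B <- matrix(0, M, n)
  for (i in seq_len(M)) {
    ic_lo <- W - i + 1L; ic_hi <- ic_lo + n - 1L
    ib_lo <- M - i + 1L; ib_hi <- ib_lo + n - 1L
    # rows falling outside the sequence can never belong to a legal
    # alignment (checked against the bulge placement below); zero them
    C[i, ] <- if (ic_lo >= 1L && ic_hi <= L)
      pmat[m[i], compseq[ic_lo:ic_hi]] * wt[i] else 0
    B[i, ] <- if (ib_lo >= 1L && ib_hi <= L)
      pmat[m[i], compseq[ib_lo:ib_hi]] * wt[i] else 0
  }
  cumC <- rbind(0, apply(C, 2, cumsum))
  sumB <- colSums(B)
  cumB <- rbind(0, apply(B, 2, cumsum))
  best <- rep(Inf, n)
  for (d in seq_len(M - kk + 1L)) {
    bulge <- gap_open * sum(weights[d:(d + kk - 1L)])
    sc <- cumC[d, ] + (sumB - cumB[d + kk, ]) + bulge
    best <- pmin(best, sc)
  }
  best
}

#' Score a miRNA against one candidate target site
#'
#' The penalty of the best antiparallel alignment of the miRNA to the
#' window under the plant complementarity rule (see the module header):
#' Watson-Crick 0, G:U wobble 0.5, mismatch 1.0, bulged base 2.0, doubled
#' at miRNA positions 2-13 (from the 5' end, 1-based), minimized over
#' alignments with at most one contiguous bulge. The window length may
#' differ from the miRNA length by the bulge length.
#'
#' @param mirna_seq miRNA sequence, 5'->3' (RNA or DNA, any case).
#' @param window_seq Candidate site on the transcript, 5'->3'.
#' @param seed_start,seed_end Bounds of the doubled-penalty region.
#' @param mismatch,wobble,gap_open Penalty weights.
#' @return The penalty score (0 for a perfect reverse complement).
#' @export
score_mirna_target <- function(mirna_seq, window_seq, seed_start = 2L,
                               seed_end = 13L, mismatch = 1, wobble = 0.5,
                               gap_open = 2) {
  m <- .encode_dna(mirna_seq, "miRNA sequence")
  w <- .encode_dna(window_seq, "window sequence")
  k <- length(w) - length(m)
  weights <- .position_weights(length(m), seed_start, seed_end)
  pmat <- .pair_penalty_matrix(mismatch, wobble)
  sc <- .scan_windows_k(m, .DNA_COMP[w], k, weights, pmat, gap_open)
  if (!length(sc)) stop("window incompatible with miRNA length")
  sc[[1]]
}

#' Predict miRNA target sites on a set of transcripts
#'
#' Slides every window of length `len(miRNA) +/- max_bulge` along each
#' transcript, scores it with the plant complementarity rule, and keeps
#' the best (lowest-penalty) site per miRNA-transcript pair when its
#' penalty is at most `cutoff`. Ties are broken by leftmost site, then by
#' shortest window.
#'
#' @param mirnas Named character vector of miRNA sequences (5'->3').
#' @param transcripts Named character vector of transcript sequences.
#' @param cutoff Maximum penalty for a reported site, default 4.0.
#' @param max_bulge Maximum bulge length in bases, default 1.
#' @param seed_start,seed_end,mismatch,wobble,gap_open Scoring parameters,
#'   as in [score_mirna_target()].
#' @return `data.frame` with `mirna_id`, `transcript_id`, `site_start`
#'   (0-based on the transcript), `site_length`, `penalty_score`,
#'   `paired_string` (site sequence 5'->3').
#' @export
predict_targets <- function(mirnas, transcripts, cutoff = 4, max_bulge = 1L,
                            seed_start = 2L, seed_end = 13L, mismatch = 1,
                            wobble = 0.5, gap_open = 2) {
  stopifnot(!is.null(names(mirnas)), !is.null(names(transcripts)))
  pmat <- .pair_penalty_matrix(mismatch, wobble)
  enc_tx <- lapply(transcripts, .encode_dna, what = "transcript")
  rows <- list()
  for (mi in names(mirnas)) {
    m <- .encode_dna(mirnas[[mi]], "miRNA sequence")
    weights <- .position_weights(length(m), seed_start, seed_end)
    for (ti in names(transcripts)) {
      compseq <- .DNA_COMP[enc_tx[[ti]]]
      best <- NULL
      for (k in seq.int(-max_bulge, max_bulge)) {
        sc <- .scan_windows_k(m, compseq, k, weights, pmat, gap_open)
        if (!length(sc)) next
        ok <- which(sc <= cutoff)
        if (!length(ok)) next
        i <- ok[which.min(sc[ok])]
        # leftmost among equal-score windows for this k
        i <- min(ok[sc[ok] == sc[i]])
        cand <- list(score = sc[i], start = i, len = length(m) + k)
        if (is.null(best) ||
            cand$score < best$score ||
            (cand$score == best$score && cand$start < best$start) ||
            (cand$score == best$score && cand$start == best$start &&
               cand$len < best$len)) {
          best <- cand
        }
      }
      if (!is.null(best)) {
        site <- substr(toupper(gsub("U", "T", transcripts[[ti]], fixed = TRUE)),
                       best$start, best$start + best$len - 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = mi, transcript_id = ti,
          site_start = best$start - 1L, site_length = best$len,
          penalty_score = best$score, paired_string = site,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      site_start = integer(0), site_length = integer(0),
                      penalty_score = numeric(0), paired_string = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Filter small-RNA sequences by length
#'
#' Retains sequences whose length lies within the inclusive bounds;
#' the defaults keep the canonical 18-30 nt size class of mature plant
#' small RNAs.
#'
#' @param seqs Named character vector of sequences.
#' @param min_nt,max_nt Inclusive length bounds, defaults 18 and 30.
#' @return The retained subset of `seqs`.
#' @export
filter_small_rna <- function(seqs, min_nt = 18L, max_nt = 30L) {
  if (!length(seqs)) stop("no sequences supplied")
  len <- nchar(seqs)
  seqs[len >= min_nt & len <= max_nt]
}

#' Classify a miRNA-target pair by expression coherence
#'
#' When both members are differentially expressed in the contrast, the
#' pair is \emph{coherent} if their directions are opposite (consistent
#' with miRNA-guided repression) and \emph{noncoherent} if they share the
#' direction. If either member is not DE in the contrast, no pair is
#' emitted.
#'
#' @param de_mirna,de_target Rows of a [differential_expression()] result
#'   for the miRNA and for the target (any rows; filtered by `contrast`).
#' @param contrast Contrast label as in the DE tables
#'   (`"<a> vs <b>"`).
#' @return One-row `data.frame` with `mirna_id`, `target_id`, `contrast`,
#'   `coherence`, or `NULL` when either member is not DE.
#' @export
classify_pair_coherence <- function(de_mirna, de_target, contrast) {
  rm_ <- de_mirna[de_mirna$contrast == contrast, , drop = FALSE]
  rt_ <- de_target[de_target$contrast == contrast, , drop = FALSE]
  if (nrow(rm_) != 1 || nrow(rt_) != 1) return(NULL)
  if (rm_$call == "ns" || rt_$call == "ns") return(NULL)
  data.frame(mirna_id = rm_$feature_id, target_id = rt_$feature_id,
             contrast = contrast,
             coherence = if (rm_$call != rt_$call) "coherent" else "noncoherent",
             stringsAsFactors = FALSE)
}
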