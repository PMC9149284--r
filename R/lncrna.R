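# Positional classification of lncRNA loci and cis/trans target calling.

# introns of protein-coding genes as GRanges (gene span minus exons of the
# gene's transcript children)
.intron_granges <- function(annotation, roles = c("mRNA", "TF")) {
  ft <- annotation$features
  genes <- ft[ft$type == "gene" & ft$role %in% roles, , drop = FALSE]
  tx <- ft[ft$type == "transcript", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    kids <- tx$id[!is.na(tx$parent_id) & tx$parent_id == g$id]
    ex <- annotation$exons[annotation$exons$parent_id %in% kids, , drop = FALSE]
    if (nrow(ex) < 2) next
    ex <- ex[order(ex$start), ]
    istart <- ex$end[-nrow(ex)] + 1L
    iend <- ex$start[-1] - 1L
    keep <- iend >= istart
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = g$chrom, strand = g$strand, start = istart[keep],
      end = iend[keep], gene_id = g$id, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(GenomicRanges::GRanges())
  }
  d <- do.call(rbind, rows)
  GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start, d$end),
                         strand = d$strand, gene_id = d$gene_id)
}

.exon_granges <- function(annotation, roles = c("mRNA", "TF")) {
  ft <- annotation$features
  genes <- ft[ft$type == "gene" & ft$role %in% roles, , drop = FALSE]
  tx <- ft[ft$type == "transcript", , drop = FALSE]
  tx <- tx[!is.na(tx$parent_id) & tx$parent_id %in% genes$id, , drop = FALSE]
  ex <- annotation$exons[annotation$exons$parent_id %in% tx$id, , drop = FALSE]
  if (!nrow(ex)) return(GenomicRanges::GRanges())
  gid <- tx$parent_id[match(ex$parent_id, tx$id)]
  g <- genes[match(gid, genes$id), ]
  GenomicRanges::GRanges(g$chrom, IRanges::IRanges(ex$start, ex$end),
                         strand = g$strand, gene_id = gid)
}

#' Classify lncRNA loci by position relative to protein-coding genes
#'
#' Assigns exactly one of four positional classes by precedence:
#' \enumerate{
#'   \item \strong{sense} - exonic overlap with a gene on the same strand;
#'   \item \strong{antisense} - any overlap with a gene on the opposite
#'     strand;
#'   \item \strong{intronic} - contained entirely within an intron of a
#'     same-strand gene;
#'   \item \strong{lincRNA} - no genic overlap (intergenic).
#' }
#'
#' @param annotation A [genome_annotation()].
#' @param lnc_ids Ids of lncRNA features to classify; default every
#'   gene-level feature with role `lncRNA`.
#' @return `data.frame` with `lnc_id`, `class`, `gene_id` (supporting
#'   gene; `""` for lincRNA).
#' @export
classify_lncrna <- function(annotation, lnc_ids = NULL) {
  ft <- annotation$features
  if (is.null(lnc_ids)) {
    lnc_ids <- ft$id[ft$type == "gene" & ft$role == "lncRNA"]
  }
  lt <- ft[match(lnc_ids, ft$id), , drop = FALSE]
  if (any(is.na(lt$id))) {
    stop("unknown lncRNA id(s): ",
         paste(lnc_ids[is.na(lt$id)], collapse = ", "))
  }
  lgr <- GenomicRanges::GRanges(lt$chrom, IRanges::IRanges(lt$start, lt$end),
                                strand = lt$strand)
  genes <- .gene_granges(annotation)
  exons <- .exon_granges(annotation)
  introns <- .intron_granges(annotation)

  pick <- function(hits, meta) {
    # deterministic supporting gene: first by position in subject
    if (!length(hits)) NA_character_ else meta[min(hits)]
  }
  res <- lapply(seq_along(lgr), function(i) {
    q <- lgr[i]
    qs <- as.character(GenomicRanges::strand(q))
    same_exon <- which(IRanges::overlapsAny(exons, q, ignore.strand = TRUE) &
                         as.character(GenomicRanges::strand(exons)) == qs)
    if (length(same_exon)) {
      return(c("sense", exons$gene_id[min(same_exon)]))
    }
    anti <- which(IRanges::overlapsAny(genes, q, ignore.strand = TRUE) &
                    as.character(GenomicRanges::strand(genes)) != qs)
    if (length(anti)) {
      return(c("antisense", genes$id[min(anti)]))
    }
    if (length(introns)) {
      within <- which(as.character(GenomicRanges::strand(introns)) == qs &
                        GenomicRanges::start(introns) <= GenomicRanges::start(q) &
                        GenomicRanges::end(introns) >= GenomicRanges::end(q) &
                        as.character(GenomicRanges::seqnames(introns)) ==
                          as.character(GenomicRanges::seqnames(q)))
      if (length(within)) {
        return(c("intronic", introns$gene_id[min(within)]))
      }
    }
    c("lincRNA", "")
  })
  data.frame(lnc_id = lt$id,
             class = vapply(res, `[[`, "", 1L),
             gene_id = vapply(res, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

# longest open reading frame (ATG..stop, forward frames only), in codons
# counting the start codon and excluding the stop; an ORF running off the
# 3' end is counted as open.
.longest_orf_codons <- function(seq) {
  n <- nchar(seq)
  if (n < 3) return(0L)
  codon_starts <- 1:(n - 2)
  codons <- substring(seq, codon_starts, codon_starts + 2)
  best <- 0L
  for (frame in 0:2) {
    idx <- seq(1 + frame, n - 2, by = 3)
    if (!length(idx)) next
    fc <- codons[idx]
    is_start <- fc == "ATG"
    is_stop <- fc %in% c("TAA", "TAG", "TGA")
    if (!any(is_start)) next
    stop_pos <- which(is_stop)
    for (s in which(is_start)) {
      nxt <- stop_pos[stop_pos > s]
      len <- if (length(nxt)) nxt[1] - s else length(fc) - s + 1L
      if (len > best) best <- len
    }
  }
  best
}

#' Filter lncRNA candidates by length and coding potential
#'
#' A transcript is retained as a credible lncRNA iff its length is at
#' least `min_length` nt and its longest forward-frame ORF (ATG to stop,
#' three frames) is shorter than `max_orf_aa` codons.
#'
#' @param ids Candidate transcript ids.
#' @param sequences Named character vector covering all candidates.
#' @param min_length Minimum transcript length in nt, default 200.
#' @param max_orf_aa ORF-length cutoff in codons, default 100; candidates
#'   with an ORF of `max_orf_aa` or more codons are removed.
#' @return Character vector of retained ids.
#' @export
filter_lncrna_candidates <- function(ids, sequences, min_length = 200,
                                     max_orf_aa = 100) {
  miss <- setdiff(ids, names(sequences))
  if (length(miss)) {
    stop("missing sequence for: ", paste(head(miss, 5), collapse = ", "))
  }
  keep <- vapply(ids, function(id) {
    s <- toupper(sequences[[id]])
    nchar(s) >= min_length && .longest_orf_codons(s) < max_orf_aa
  }, logical(1))
  ids[keep]
}

#' Cis targets of a lncRNA locus
#'
#' A gene is a cis target iff the genomic gap between the lncRNA span and
#' the gene span is at most `window_bp` (overlapping loci have gap 0);
#' both up- and downstream genes qualify, strand-agnostic, same
#' chromosome only.
#'
#' @param annotation A [genome_annotation()].
#' @param lnc_id lncRNA feature id.
#' @param window_bp Window size in bp, default 10000 (10 kb).
#' @return `data.frame` with `lnc_id`, `gene_id`, `gap_bp`.
#' @export
cis_targets <- function(annotation, lnc_id, window_bp = 10000) {
  if (window_bp <= 0) stop("window_bp must be > 0")
  ft <- annotation$features
  lt <- ft[ft$id == lnc_id, , drop = FALSE]
  if (!nrow(lt)) stop("unknown lncRNA id: ", lnc_id)
  genes <- .gene_granges(annotation)
  q <- GenomicRanges::GRanges(lt$chrom, IRanges::IRanges(lt$start, lt$end))
  same <- as.character(GenomicRanges::seqnames(genes)) == lt$chrom
  d <- rep(NA_integer_, length(genes))
  d[same] <- IRanges::distance(IRanges::ranges(genes[same]),
                               IRanges::ranges(q))
  hit <- which(!is.na(d) & d <= window_bp)
  data.frame(lnc_id = rep(lnc_id, length(hit)),
             gene_id = genes$id[hit],
             gap_bp = d[hit],
             stringsAsFactors = FALSE)
}

# signed DE calls per feature x contrast as a lookup table
.de_sign_table <- function(de) {
  sig <- de[de$call != "ns", c("feature_id", "contrast", "call")]
  sig
}

#' Trans targets of lncRNAs by expression correlation
#'
#' A (lncRNA, gene) pair is reported when the Pearson correlation of their
#' `log2(abundance + 1)` profiles across shared samples is at or beyond
#' the threshold and both members are differentially expressed in at
#' least one common contrast with directions consistent with the sign of
#' the correlation (opposite calls for anticorrelated pairs, concordant
#' calls for positively correlated pairs). The default mode
#' `"anticorrelated"` requires `PCC <= -r_threshold`, reading "opposite
#' expression with correlation >= 0.9" as strong anticorrelation; mode
#' `"absolute"` accepts `|PCC| >= r_threshold` of either sign.
#'
#' @param lnc_expr [expression_matrix()] restricted to (or containing)
#'   lncRNA features.
#' @param mrna_expr [expression_matrix()] of candidate target genes.
#' @param de_results Differential results covering both sets (from
#'   [differential_expression()]).
#' @param r_threshold Correlation magnitude threshold, default 0.9.
#' @param mode `"anticorrelated"` (default) or `"absolute"`.
#' @return `data.frame` with `lnc_id`, `gene_id`, `pcc`, `contrast` (the
#'   first contrast satisfying the DE-direction rule).
#' @export
trans_targets <- function(lnc_expr, mrna_expr, de_results, r_threshold = 0.9,
                          mode = c("anticorrelated", "absolute")) {
  mode <- match.arg(mode)
  shared <- intersect(colnames(lnc_expr$values), colnames(mrna_expr$values))
  if (length(shared) < 3) stop("need >= 3 shared samples")
  lids <- rownames(lnc_expr$values)[lnc_expr$roles == "lncRNA"]
  gids <- rownames(mrna_expr$values)
  sig <- .de_sign_table(de_results)
  de_ids <- unique(sig$feature_id)
  lids <- intersect(lids, de_ids)
  gids <- intersect(gids, de_ids)
  lv <- log2(lnc_expr$values[lids, shared, drop = FALSE] + 1)
  gv <- log2(mrna_expr$values[gids, shared, drop = FALSE] + 1)
  lvar <- apply(lv, 1, var)
  gvar <- apply(gv, 1, var)
  if (any(lvar == 0) || any(gvar == 0)) {
    drop <- c(lids[lvar == 0], gids[gvar == 0])
    warning("skipping zero-variance feature(s): ",
            paste(head(drop, 5), collapse = ", "))
    lids <- lids[lvar > 0]; lv <- lv[lids, , drop = FALSE]
    gids <- gids[gvar > 0]; gv <- gv[gids, , drop = FALSE]
  }
  if (!length(lids) || !length(gids)) {
    return(data.frame(lnc_id = character(0), gene_id = character(0),
                      pcc = numeric(0), contrast = character(0),
                      stringsAsFactors = FALSE))
  }
  cc <- cor(t(lv), t(gv))  # lnc x gene
  rows <- list()
  for (i in seq_along(lids)) {
    for (j in seq_along(gids)) {
      if (lids[i] == gids[j]) next
      r <- cc[i, j]
      pass <- if (mode == "anticorrelated") r <= -r_threshold else
        abs(r) >= r_threshold
      if (!pass) next
      sl <- sig[sig$feature_id == lids[i], ]
      sg <- sig[sig$feature_id == gids[j], ]
      common <- intersect(sl$contrast, sg$contrast)
      hit <- NA_character_
      # direction rule: an anticorrelated pair must show opposite calls,
      # a positively correlated pair (absolute mode) concordant calls
      want_opposite <- r < 0
      for (ct in common) {
        cl <- sl$call[sl$contrast == ct]
        cg <- sg$call[sg$contrast == ct]
        if (!length(cl) || !length(cg)) next
        if ((want_opposite && cl != cg) || (!want_opposite && cl == cg)) {
          hit <- ct; break
        }
      }
      if (is.na(hit)) next
      rows[[length(rows) + 1L]] <- data.frame(
        lnc_id = lids[i], gene_id = gids[j], pcc = r, contrast = hit,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(lnc_id = character(0), gene_id = character(0),
                      pcc = numeric(0), contrast = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
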