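# Assembly of typed regulatory edges, recovery scoring, graph export.

.EDGE_COLS <- c("source_id", "source_role", "target_id", "target_role",
                "mechanism", "pcc", "pcc_p", "motif_hits", "penalty_score",
                "coherence", "support")

.MECHANISM_ROLE <- c(tf_binding = "TF", mirna_cleavage = "miRNA",
                     lnc_cis = "lncRNA", lnc_trans = "lncRNA")

.empty_edges <- function() {
  data.frame(source_id = character(0), source_role = character(0),
             target_id = character(0), target_role = character(0),
             mechanism = character(0), pcc = numeric(0), pcc_p = numeric(0),
             motif_hits = integer(0), penalty_score = numeric(0),
             coherence = character(0), support = character(0),
             stringsAsFactors = FALSE)
}

.edge_row <- function(source_id, target_id, mechanism, role_map,
                      pcc = NA_real_, pcc_p = NA_real_,
                      motif_hits = NA_integer_, penalty_score = NA_real_,
                      coherence = NA_character_, support = "prediction") {
  sr <- role_map[[source_id]]
  tr <- role_map[[target_id]]
  if (is.null(sr) || is.null(tr)) {
    stop("feature missing from role map: ",
         if (is.null(sr)) source_id else target_id)
  }
  data.frame(source_id = source_id, source_role = sr,
             target_id = target_id, target_role = tr,
             mechanism = mechanism, pcc = pcc, pcc_p = pcc_p,
             motif_hits = motif_hits, penalty_score = penalty_score,
             coherence = coherence, support = support,
             stringsAsFactors = FALSE)
}

#' Assemble a typed regulatory network from accepted pairs
#'
#' Merges TF, miRNA, and lncRNA (cis/trans) pair evidence into one edge
#' set. Duplicate (source, target, mechanism) triples are collapsed
#' keeping the strongest evidence (lowest p, then lowest penalty). TF
#' targets may themselves be sources, so indirect chains
#' (lncRNA -> TF -> gene) are representable.
#'
#' @param tf_pairs Output of [tf_gene_pairs()] (only accepted rows are
#'   used), or `NULL`.
#' @param mirna_pairs `data.frame` with `mirna_id`, `target_id`, and
#'   optionally `penalty_score`, `coherence`, or `NULL`.
#' @param lnc_cis_pairs `data.frame` with `lnc_id`, `gene_id`, or `NULL`.
#' @param lnc_trans_pairs `data.frame` with `lnc_id`, `gene_id`, and
#'   optionally `pcc`, or `NULL`.
#' @param role_map Named character vector mapping feature id to role
#'   (`mRNA`, `TF`, `lncRNA`, `miRNA`).
#' @param support_map Optional named character vector mapping
#'   `"source->target"` to `"experiment"` for edges with experimental
#'   (e.g. qPCR) support; all other edges carry `"prediction"`.
#' @return Object of class `regulatory_network` with `nodes` and `edges`.
#' @export
assemble_network <- function(tf_pairs = NULL, mirna_pairs = NULL,
                             lnc_cis_pairs = NULL, lnc_trans_pairs = NULL,
                             role_map, support_map = NULL) {
  role_map <- as.list(role_map)
  rows <- list()
  add <- function(df) if (!is.null(df) && nrow(df)) rows[[length(rows) + 1L]] <<- df
  if (!is.null(tf_pairs) && nrow(tf_pairs)) {
    acc <- tf_pairs[tf_pairs$accepted %in% TRUE, , drop = FALSE]
    if (nrow(acc)) {
      add(do.call(rbind, lapply(seq_len(nrow(acc)), function(i) {
        .edge_row(acc$tf_id[i], acc$gene_id[i], "tf_binding", role_map,
                  pcc = acc$pcc[i], pcc_p = acc$pcc_p[i],
                  motif_hits = acc$motif_hits[i])
      })))
    }
  }
  if (!is.null(mirna_pairs) && nrow(mirna_pairs)) {
    add(do.call(rbind, lapply(seq_len(nrow(mirna_pairs)), function(i) {
      .edge_row(mirna_pairs$mirna_id[i], mirna_pairs$target_id[i],
                "mirna_cleavage", role_map,
                penalty_score = if ("penalty_score" %in% names(mirna_pairs))
                  mirna_pairs$penalty_score[i] else NA_real_,
                coherence = if ("coherence" %in% names(mirna_pairs))
                  mirna_pairs$coherence[i] else NA_character_)
    })))
  }
  if (!is.null(lnc_cis_pairs) && nrow(lnc_cis_pairs)) {
    add(do.call(rbind, lapply(seq_len(nrow(lnc_cis_pairs)), function(i) {
      .edge_row(lnc_cis_pairs$lnc_id[i], lnc_cis_pairs$gene_id[i],
                "lnc_cis", role_map)
    })))
  }
  if (!is.null(lnc_trans_pairs) && nrow(lnc_trans_pairs)) {
    add(do.call(rbind, lapply(seq_len(nrow(lnc_trans_pairs)), function(i) {
      .edge_row(lnc_trans_pairs$lnc_id[i], lnc_trans_pairs$gene_id[i],
                "lnc_trans", role_map,
                pcc = if ("pcc" %in% names(lnc_trans_pairs))
                  lnc_trans_pairs$pcc[i] else NA_real_)
    })))
  }
  edges <- if (length(rows)) do.call(rbind, rows) else .empty_edges()
  # mechanism/source-role consistency
  if (nrow(edges)) {
    bad <- edges$source_role != .MECHANISM_ROLE[edges$mechanism]
    if (any(bad)) {
      stop("mechanism inconsistent with source role for: ",
           paste(edges$source_id[bad], collapse = ", "))
    }
    if (!is.null(support_map)) {
      key <- paste0(edges$source_id, "->", edges$target_id)
      sup <- support_map[key]
      edges$support[!is.na(sup) & sup == "experiment"] <- "experiment"
    }
    # dedup keeping best evidence
    key <- paste(edges$source_id, edges$target_id, edges$mechanism, sep = "\r")
    ord <- order(key,
                 ifelse(is.na(edges$pcc_p), Inf, edges$pcc_p),
                 ifelse(is.na(edges$penalty_score), Inf, edges$penalty_score))
    edges <- edges[ord, , drop = FALSE]
    edges <- edges[!duplicated(key[ord]), , drop = FALSE]
    edges <- edges[order(edges$mechanism, edges$source_id, edges$target_id), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  }
  ids <- unique(c(edges$source_id, edges$target_id))
  roles <- vapply(ids, function(i) role_map[[i]], "")
  conflict <- tapply(c(edges$source_role, edges$target_role),
                     c(edges$source_id, edges$target_id),
                     function(x) length(unique(x)))
  if (length(conflict) && any(conflict > 1)) {
    stop("conflicting roles for node(s): ",
         paste(names(conflict)[conflict > 1], collapse = ", "))
  }
  nodes <- data.frame(id = ids, role = unname(roles),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("regulatory_network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  if (nrow(x$edges)) {
    tb <- table(x$edges$mechanism)
    cat("mechanisms:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Score a predicted network against planted ground truth
#'
#' Edge identity is the (source, target, mechanism) triple. Precision is
#' TP / (TP + FP) (0 when there are no predictions), recall TP / (TP +
#' FN), and F1 their harmonic mean (0 when either is 0), overall and per
#' mechanism.
#'
#' @param predicted A `regulatory_network` or an edge `data.frame` with
#'   `source_id`, `target_id`, `mechanism`.
#' @param truth `data.frame` of planted edges with the same three
#'   columns (a `ground_truth` object's `edges` element works).
#' @return `data.frame` with one row per mechanism plus an `overall` row:
#'   `mechanism`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
recovery_metrics <- function(predicted, truth) {
  if (inherits(predicted, "regulatory_network")) predicted <- predicted$edges
  if (inherits(truth, "ground_truth")) truth <- truth$edges
  pk <- unique(paste(predicted$source_id, predicted$target_id,
                     predicted$mechanism, sep = "\r"))
  tk <- unique(paste(truth$source_id, truth$target_id, truth$mechanism,
                     sep = "\r"))
  mech_of <- function(k) vapply(strsplit(k, "\r", fixed = TRUE), `[[`, "", 3L)
  mechs <- sort(unique(c(mech_of(pk), mech_of(tk))))
  one <- function(p, t, label) {
    tp <- length(intersect(p, t))
    fp <- length(setdiff(p, t))
    fn <- length(setdiff(t, p))
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec == 0 || rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(mechanism = label, tp = tp, fp = fp, fn = fn,
               precision = prec, recall = rec, f1 = f1,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(mechs, function(m) {
    one(pk[mech_of(pk) == m], tk[mech_of(tk) == m], m)
  })
  do.call(rbind, c(rows, list(one(pk, tk, "overall"))))
}

#' Export a regulatory network
#'
#' Formats: `"sif"` (`source<TAB>mechanism<TAB>target`), `"tsv"` (full
#' edge table; re-importing with [read_network_tsv()] reproduces the edge
#' set exactly), `"graphml"` (roles and evidence as attributes).
#'
#' @param network A `regulatory_network`.
#' @param path Output file path.
#' @param format One of `"sif"`, `"tsv"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("sif", "tsv", "graphml")) {
  stopifnot(inherits(network, "regulatory_network"))
  format <- match.arg(format)
  edges <- network$edges
  if (format == "sif") {
    writeLines(paste(edges$source_id, edges$mechanism, edges$target_id,
                     sep = "\t"), path)
  } else if (format == "tsv") {
    write.table(edges[, .EDGE_COLS], path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    doc <- xml2::xml_new_root("graphml",
      xmlns = "http://graphml.graphdrawing.org/xmlns")
    keys <- list(c("role", "node", "string"),
                 c("mechanism", "edge", "string"),
                 c("pcc", "edge", "double"),
                 c("pcc_p", "edge", "double"),
                 c("motif_hits", "edge", "int"),
                 c("penalty_score", "edge", "double"),
                 c("coherence", "edge", "string"),
                 c("support", "edge", "string"))
    for (k in keys) {
      xml2::xml_add_child(doc, "key", id = k[1], `for` = k[2],
                          attr.name = k[1], attr.type = k[3])
    }
    gr <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "directed")
    for (i in seq_len(nrow(network$nodes))) {
      nd <- xml2::xml_add_child(gr, "node", id = network$nodes$id[i])
      dat <- xml2::xml_add_child(nd, "data", key = "role")
      xml2::xml_text(dat) <- network$nodes$role[i]
    }
    for (i in seq_len(nrow(edges))) {
      ed <- xml2::xml_add_child(gr, "edge", source = edges$source_id[i],
                                target = edges$target_id[i])
      for (k in c("mechanism", "pcc", "pcc_p", "motif_hits",
                  "penalty_score", "coherence", "support")) {
        v <- edges[[k]][i]
        if (is.na(v)) next
        dat <- xml2::xml_add_child(ed, "data", key = k)
        xml2::xml_text(dat) <- as.character(v)
      }
    }
    xml2::write_xml(doc, path)
  }
  invisible(path)
}

#' Read an edge table written by [export_network()] (`tsv` format)
#'
#' @param path Edge TSV path.
#' @return Edge `data.frame` in the package's standard column layout.
#' @export
read_network_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("source_id", "target_id", "mechanism"), names(df))
  if (length(miss)) {
    stop("edge table missing column(s): ", paste(miss, collapse = ", "))
  }
  df
}
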