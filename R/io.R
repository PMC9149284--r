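#' @importFrom stats cor pt rnbinom runif rnorm setNames phyper sd var
#' @importFrom utils read.delim write.table head modifyList
#' @keywords internal
"_PACKAGE"

# -- FASTA ---------------------------------------------------------------

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased on read. RNA records (containing `U`) are
#' converted to DNA (`U` -> `T`) and flagged in the `"rna"` attribute, a
#' named logical vector parallel to the result.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences with attribute `rna`.
#'   An empty file yields an empty vector.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  rna <- grepl("U", seqs, fixed = TRUE)
  names(rna) <- ids
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  attr(seqs, "rna") <- rna
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n == 0L) next
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

# -- GFF3 ----------------------------------------------------------------

.parse_gff_attrs <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- vapply(kv, function(p) if (length(p) >= 2) p[[2]] else "", "")
  names(vals) <- vapply(kv, `[[`, "", 1L)
  vals
}

.attr_get <- function(at, key) {
  if (key %in% names(at)) at[[key]] else NULL
}

#' Construct a genome annotation object
#'
#' The in-memory annotation used throughout the package: a `features` table
#' (gene- and transcript-level rows) and an `exons` table keyed by
#' transcript id. Coordinates are 1-based inclusive, as in GFF3.
#'
#' @param features `data.frame` with columns `id`, `type` (`gene` or
#'   `transcript`), `role` (`mRNA`, `TF`, `lncRNA`, `miRNA`), `chrom`,
#'   `strand` (`+`/`-`), `start`, `end`, `parent_id` (`NA` for genes).
#' @param exons `data.frame` with columns `parent_id`, `start`, `end`.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(features, exons) {
  stopifnot(is.data.frame(features), is.data.frame(exons))
  need <- c("id", "type", "role", "chrom", "strand", "start", "end", "parent_id")
  if (!all(need %in% names(features))) {
    stop("features must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(features$id)) {
    stop("duplicate feature id(s): ",
         paste(unique(features$id[duplicated(features$id)]), collapse = ", "))
  }
  if (any(features$end < features$start)) {
    bad <- features$id[features$end < features$start]
    stop("end < start for feature(s): ", paste(bad, collapse = ", "))
  }
  if (nrow(exons)) {
    if (any(exons$end < exons$start)) stop("exon with end < start")
    sp <- split(exons, exons$parent_id)
    for (pid in names(sp)) {
      tx <- features[features$id == pid, ]
      if (!nrow(tx)) stop("exon parent not in features: ", pid)
      ex <- sp[[pid]][order(sp[[pid]]$start), ]
      if (any(ex$start < tx$start) || any(ex$end > tx$end)) {
        stop("exon outside transcript span for ", pid)
      }
      if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
        stop("overlapping exons for ", pid)
      }
    }
    exons <- exons[order(exons$parent_id, exons$start), , drop = FALSE]
    rownames(exons) <- NULL
  }
  rownames(features) <- NULL
  structure(list(features = features, exons = exons),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  ft <- x$features
  cat("genome_annotation:", sum(ft$type == "gene"), "genes,",
      sum(ft$type == "transcript"), "transcripts,",
      nrow(x$exons), "exons\n")
  cat("roles:", paste(names(table(ft$role[ft$type == "gene"])),
                      table(ft$role[ft$type == "gene"]),
                      sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a GFF3 file
#'
#' Recognized feature types are `gene` (gene level) and `mRNA`,
#' `transcript`, `lnc_RNA`, `miRNA` (transcript level); `exon` rows attach
#' to their `Parent` transcript. Unknown types are skipped with one summary
#' warning. `role` / `biotype` attributes are captured (biotype `lncRNA`
#' or `miRNA` implies the role). Coordinates are kept 1-based inclusive.
#'
#' @param path Path to a GFF3 file.
#' @return A [genome_annotation()] object.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  feat <- list()
  ex <- list()
  skipped <- character(0)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L) {
      stop("malformed GFF3 line ", i, ": expected 9 tab-separated fields")
    }
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end)) {
      stop("malformed GFF3 line ", i, ": non-numeric coordinates")
    }
    if (end < start) stop("GFF3 line ", i, ": end < start")
    type <- f[3]
    at <- .parse_gff_attrs(f[9])
    if (type == "exon") {
      pid <- .attr_get(at, "Parent")
      if (is.null(pid)) stop("GFF3 line ", i, ": exon without Parent")
      ex[[length(ex) + 1L]] <- data.frame(
        parent_id = pid, start = start, end = end,
        stringsAsFactors = FALSE)
      next
    }
    lvl <- switch(type,
                  gene = "gene",
                  mRNA = , transcript = , lnc_RNA = , miRNA = "transcript",
                  NA_character_)
    if (is.na(lvl)) {
      skipped <- c(skipped, type)
      next
    }
    role_at <- .attr_get(at, "role")
    biotype <- .attr_get(at, "biotype")
    role <- if (!is.null(role_at) && nzchar(role_at)) {
      role_at
    } else if (!is.null(biotype)) {
      switch(biotype,
             lncRNA = "lncRNA", miRNA = "miRNA",
             protein_coding = "mRNA", biotype)
    } else {
      NA_character_
    }
    id <- .attr_get(at, "ID")
    if (is.null(id)) stop("GFF3 line ", i, ": feature without ID")
    feat[[length(feat) + 1L]] <- data.frame(
      id = id, type = lvl, role = role %||% NA_character_,
      chrom = f[1], strand = f[7], start = start, end = end,
      parent_id = .attr_get(at, "Parent") %||% NA_character_,
      stringsAsFactors = FALSE)
  }
  if (length(skipped)) {
    warning("skipped unknown GFF3 feature type(s): ",
            paste(unique(skipped), collapse = ", "))
  }
  features <- do.call(rbind, feat)
  exons <- if (length(ex)) do.call(rbind, ex) else
    data.frame(parent_id = character(0), start = integer(0), end = integer(0))
  # inherit role from parent gene where transcripts carry none
  if (!is.null(features)) {
    miss <- which(is.na(features$role) & !is.na(features$parent_id))
    if (length(miss)) {
      pr <- features$role[match(features$parent_id[miss], features$id)]
      features$role[miss] <- pr
    }
  }
  genome_annotation(features, exons)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a genome annotation to GFF3
#'
#' Gene rows are written as `gene`, transcript rows by role (`mRNA` for
#' mRNA/TF, `lnc_RNA` for lncRNA, `miRNA` for miRNA) with `biotype` and
#' `role` attributes, exons as `exon` children.
#'
#' @param annotation A [genome_annotation()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  ft <- annotation$features
  ex <- annotation$exons
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(chrom, type, start, end, strand, attrs) {
    paste(chrom, "nitronet", type, as.character(as.integer(start)),
          as.character(as.integer(end)), ".", strand, ".", attrs, sep = "\t")
  }
  out <- character(0)
  for (i in seq_len(nrow(ft))) {
    r <- ft[i, ]
    if (r$type == "gene") {
      out <- c(out, fmt(r$chrom, "gene", r$start, r$end, r$strand,
                        sprintf("ID=%s;role=%s", r$id, r$role)))
    } else {
      gtype <- switch(r$role, mRNA = "mRNA", TF = "mRNA",
                      lncRNA = "lnc_RNA", miRNA = "miRNA", "transcript")
      bt <- switch(r$role, mRNA = "protein_coding", TF = "protein_coding",
                   lncRNA = "lncRNA", miRNA = "miRNA", "misc")
      at <- sprintf("ID=%s;Parent=%s;role=%s;biotype=%s",
                    r$id, r$parent_id, r$role, bt)
      if (is.na(r$parent_id)) at <- sprintf("ID=%s;role=%s;biotype=%s",
                                            r$id, r$role, bt)
      out <- c(out, fmt(r$chrom, gtype, r$start, r$end, r$strand, at))
      exi <- ex[ex$parent_id == r$id, , drop = FALSE]
      if (nrow(exi)) {
        for (j in seq_len(nrow(exi))) {
          out <- c(out, fmt(r$chrom, "exon", exi$start[j], exi$end[j],
                            r$strand, sprintf("Parent=%s", r$id)))
        }
      }
    }
  }
  writeLines(out, con)
  invisible(path)
}

# -- expression matrices -------------------------------------------------

#' Construct an expression matrix object
#'
#' A dense features-by-samples abundance table together with per-feature
#' role labels and per-sample condition labels.
#'
#' @param values Numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids). Must be non-negative.
#' @param roles Named character vector mapping feature id to one of
#'   `mRNA`, `TF`, `lncRNA`, `miRNA` (may cover a superset).
#' @param conditions Named character vector mapping sample id to condition.
#' @param unit One of `"raw_count"`, `"FPKM"`, `"TPM"`, `"log2"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, roles, conditions,
                              unit = c("raw_count", "FPKM", "TPM", "log2")) {
  unit <- match.arg(unit)
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(values < 0)) stop("expression values must be non-negative")
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids")
  miss <- setdiff(colnames(values), names(conditions))
  if (length(miss)) {
    stop("sample(s) missing a condition: ", paste(miss, collapse = ", "))
  }
  missr <- setdiff(rownames(values), names(roles))
  if (length(missr)) {
    stop("feature(s) missing a role: ", paste(head(missr, 5), collapse = ", "))
  }
  structure(list(values = values,
                 roles = roles[rownames(values)],
                 conditions = conditions[colnames(values)],
                 unit = unit),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "features x",
      ncol(x$values), "samples [", x$unit, "]\n")
  cat("conditions:", paste(unique(x$conditions), collapse = ", "), "\n")
  invisible(x)
}

#' Read a counts table plus sample sheet
#'
#' The counts file is TSV with a `feature_id` column followed by one column
#' per sample; the sample sheet is TSV with columns `sample` and
#' `condition` and must cover every count column.
#'
#' @param path Counts TSV path.
#' @param sample_sheet Path to a sample-sheet TSV, or a `data.frame` with
#'   columns `sample` and `condition`.
#' @param roles Named character vector of feature roles; defaults to `mRNA`
#'   for all features.
#' @param unit Unit label for the resulting matrix.
#' @return An [expression_matrix()].
#' @export
read_counts <- function(path, sample_sheet, roles = NULL, unit = "raw_count") {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "feature_id") {
    stop("counts file must start with a 'feature_id' column")
  }
  ids <- tab$feature_id
  if (anyDuplicated(ids)) {
    stop("duplicated feature id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in counts file")
  if (any(is.na(m))) stop("missing values in counts file")
  if (any(m < 0)) stop("negative value(s) in counts file")
  rownames(m) <- ids
  if (is.character(sample_sheet)) {
    sample_sheet <- read.delim(sample_sheet, stringsAsFactors = FALSE)
  }
  if (!all(c("sample", "condition") %in% names(sample_sheet))) {
    stop("sample sheet needs 'sample' and 'condition' columns")
  }
  conditions <- setNames(as.character(sample_sheet$condition),
                         sample_sheet$sample)
  miss <- setdiff(colnames(m), names(conditions))
  if (length(miss)) {
    stop("count column(s) absent from sample sheet: ",
         paste(miss, collapse = ", "))
  }
  if (is.null(roles)) {
    roles <- setNames(rep("mRNA", length(ids)), ids)
  }
  expression_matrix(m, roles, conditions, unit)
}

#' Write an expression matrix as a counts TSV
#'
#' Inverse of [read_counts()]: integer matrices round-trip exactly.
#'
#' @param em An [expression_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(em, path) {
  stopifnot(inherits(em, "expression_matrix"))
  df <- data.frame(feature_id = rownames(em$values),
                   em$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a sample sheet TSV
#' @param conditions Named character vector mapping sample to condition.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(conditions, path) {
  write.table(data.frame(sample = names(conditions),
                         condition = unname(conditions)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# internal: GRanges view of gene-level features
.gene_granges <- function(annotation, roles = c("mRNA", "TF")) {
  ft <- annotation$features
  g <- ft[ft$type == "gene" & ft$role %in% roles, , drop = FALSE]
  GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand,
    id = g$id)
}
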