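# Quantification of the tRNA gene pool from Pol III ChIP-seq read counts:
# gene-name parsing, occupancy classification, relative expression at gene /
# transcript-group / isoacceptor / isotype resolution, within-family
# composition, pool diversity, and collapsing of identical mature sequences.

#' Parse gtRNAdb-style tRNA gene names
#'
#' Accepts the dialect \code{tRNA-<Iso>-<Anticodon>-<group>-<copy>} with or
#' without the leading \code{tRNA-}, with ASCII hyphens or en-dashes, e.g.
#' \code{tRNA-Ile-TAT-2-1}. Entries with ambiguous isotype/anticodon carry
#' the \code{tRX} prefix and are flagged for exclusion.
#'
#' @param name character vector of gene names.
#' @return data.frame with columns \code{name}, \code{isotype},
#'   \code{anticodon}, \code{transcript_group}, \code{copy}, \code{is_trx}.
#' @export
#' @examples
#' parse_trna_gene_name(c("tRNA-Ile-TAT-2-1", "tRX-NNN-1-1"))
parse_trna_gene_name <- function(name) {
  fail_if(length(name) == 0L || any(!nzchar(name)), "empty gene name")
  # normalize en/em dashes to ASCII hyphen
  norm <- gsub("–|—", "-", name)

  trx_pat  <- "^tRX(?:-([A-Za-z]{3}))?-([ACGTN]{3})-([0-9]+)-([0-9]+)$"
  trna_pat <- "^(?:tRNA-)?([A-Za-z]{3,4})-([ACGT]{3})-([0-9]+)-([0-9]+)$"

  is_trx <- grepl(trx_pat, norm)
  ok <- is_trx | grepl(trna_pat, norm)
  fail_if(any(!ok), "unparseable tRNA gene name(s): %s",
          paste(unique(name[!ok]), collapse = ", "))

  iso <- anti <- character(length(norm))
  grp <- cp <- integer(length(norm))
  if (any(is_trx)) {
    m <- regmatches(norm[is_trx], regexec(trx_pat, norm[is_trx]))
    iso[is_trx] <- NA_character_
    anti[is_trx] <- vapply(m, `[`, "", 3L)
    grp[is_trx] <- as.integer(vapply(m, `[`, "", 4L))
    cp[is_trx] <- as.integer(vapply(m, `[`, "", 5L))
  }
  if (any(!is_trx)) {
    m <- regmatches(norm[!is_trx], regexec(trna_pat, norm[!is_trx]))
    iso[!is_trx] <- vapply(m, `[`, "", 2L)
    anti[!is_trx] <- vapply(m, `[`, "", 3L)
    grp[!is_trx] <- as.integer(vapply(m, `[`, "", 4L))
    cp[!is_trx] <- as.integer(vapply(m, `[`, "", 5L))
  }
  data.frame(name = name, isotype = iso, anticodon = anti,
             transcript_group = grp, copy = cp, is_trx = is_trx,
             stringsAsFactors = FALSE)
}

check_count_matrix <- function(counts, sample_sheet) {
  fail_if(!is.matrix(counts) || !is.numeric(counts),
          "counts must be a numeric matrix")
  fail_if(any(counts < 0), "counts must be non-negative")
  fail_if(is.null(rownames(counts)) || is.null(colnames(counts)),
          "counts must have gene rownames and sample colnames")
  missing <- setdiff(colnames(counts), sample_sheet$sample)
  fail_if(length(missing) > 0, "samples absent from sample sheet: %s",
          paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Classify tRNA genes as Pol III-occupied (expressed)
#'
#' A gene is expressed in a cell type iff its read count is strictly greater
#' than \code{min_reads} in every replicate of that cell type (the
#' both-replicates rule generalized to all replicates).
#'
#' @param counts genes x samples integer matrix.
#' @param sample_sheet data.frame with \code{sample} and \code{cell_type}.
#' @param min_reads strict lower read threshold per replicate (default 2,
#'   i.e. >2 reads required).
#' @return logical genes x cell-types matrix; attribute
#'   \code{"any_cell_type"} marks genes expressed in at least one cell type.
#' @export
classify_expressed <- function(counts, sample_sheet, min_reads = 2) {
  check_count_matrix(counts, sample_sheet)
  ct <- unique(sample_sheet$cell_type)
  out <- matrix(NA, nrow(counts), length(ct),
                dimnames = list(rownames(counts), ct))
  for (j in seq_along(ct)) {
    reps <- sample_sheet$sample[sample_sheet$cell_type == ct[j]]
    reps <- intersect(reps, colnames(counts))
    if (length(reps) < 2L)
      warning(sprintf(
        "cell type '%s' has a single replicate; occupancy rule degenerates to that sample",
        ct[j]), call. = FALSE)
    sub <- counts[, reps, drop = FALSE]
    out[, j] <- rowSums(sub > min_reads) == length(reps)
  }
  attr(out, "any_cell_type") <- rowSums(out) > 0
  out
}

#' Relative tRNA expression (gene resolution)
#'
#' Per sample, each gene's fraction of the total tRNA-mapped reads. Cell-type
#' values are the mean of the cell type's replicate fractions (switchable to
#' pooled raw counts). tRX and, optionally, low-confidence genes are excluded
#' before normalization, with an audit of excluded names.
#'
#' @param counts genes x samples integer matrix.
#' @param sample_sheet sample sheet with \code{sample} and \code{cell_type}.
#' @param annotation optional \code{trna_annotation} used for exclusions.
#' @param exclude_trx drop tRX genes before normalization (default TRUE).
#' @param exclude_low_confidence also drop genes not in the high-confidence
#'   set (default FALSE).
#' @param cell_type_stat how cell-type values are formed from replicates:
#'   \code{"mean_fraction"} (default) or \code{"pooled_counts"}.
#' @return object of class \code{family_expression}: list with
#'   \code{resolution}, \code{values} (fractions, genes x samples),
#'   \code{by_cell_type}, \code{sd} (replicate sd per cell type),
#'   \code{n_replicates}, \code{sample_sheet}, \code{excluded}.
#' @export
relative_expression <- function(counts, sample_sheet, annotation = NULL,
                                exclude_trx = TRUE,
                                exclude_low_confidence = FALSE,
                                cell_type_stat = c("mean_fraction",
                                                   "pooled_counts")) {
  cell_type_stat <- match.arg(cell_type_stat)
  check_count_matrix(counts, sample_sheet)

  excluded <- character(0)
  if (!is.null(annotation)) {
    drop <- rep(FALSE, nrow(annotation))
    if (exclude_trx) drop <- drop | annotation$is_trx
    if (exclude_low_confidence) drop <- drop | !annotation$is_high_confidence
    excluded <- intersect(annotation$gene_name[drop], rownames(counts))
    counts <- counts[setdiff(rownames(counts), excluded), , drop = FALSE]
  } else if (exclude_trx) {
    trx <- parse_trna_gene_name(rownames(counts))$is_trx
    excluded <- rownames(counts)[trx]
    counts <- counts[!trx, , drop = FALSE]
  }

  totals <- colSums(counts)
  fail_if(any(totals == 0), "sample(s) with zero total tRNA counts: %s",
          paste(colnames(counts)[totals == 0], collapse = ", "))
  fr <- sweep(counts, 2L, totals, "/")

  ct <- unique(sample_sheet$cell_type[sample_sheet$sample %in% colnames(fr)])
  by_ct <- sdev <- matrix(NA_real_, nrow(fr), length(ct),
                          dimnames = list(rownames(fr), ct))
  n_rep <- integer(length(ct)); names(n_rep) <- ct
  for (j in seq_along(ct)) {
    reps <- intersect(sample_sheet$sample[sample_sheet$cell_type == ct[j]],
                      colnames(fr))
    n_rep[j] <- length(reps)
    if (cell_type_stat == "mean_fraction") {
      by_ct[, j] <- rowMeans(fr[, reps, drop = FALSE])
    } else {
      pooled <- rowSums(counts[, reps, drop = FALSE])
      by_ct[, j] <- pooled / sum(pooled)
    }
    sdev[, j] <- apply(fr[, reps, drop = FALSE], 1L, sd)
  }

  structure(list(resolution = "gene", values = fr, by_cell_type = by_ct,
                 sd = sdev, n_replicates = n_rep,
                 sample_sheet = sample_sheet, excluded = excluded),
            class = "family_expression")
}

aggregation_key <- function(annotation, genes,
                            level = c("isoacceptor", "isotype",
                                      "transcript_group")) {
  level <- match.arg(level)
  idx <- match(genes, annotation$gene_name)
  fail_if(anyNA(idx), "genes absent from annotation: %s",
          paste(genes[is.na(idx)], collapse = ", "))
  a <- annotation[idx, ]
  switch(level,
         isoacceptor = paste(a$isotype, a$anticodon, sep = "-"),
         isotype = a$isotype,
         transcript_group = a$identical_group_id)
}

#' Aggregate gene-resolution expression to coarser families
#'
#' Family values are the sums of member-gene fractions: isoacceptor =
#' (isotype, anticodon); isotype = amino acid; transcript_group = identical
#' mature sequence group.
#'
#' @param expr a gene-resolution \code{family_expression}.
#' @param annotation a \code{trna_annotation} covering all genes.
#' @param level one of \code{"isoacceptor"}, \code{"isotype"},
#'   \code{"transcript_group"}.
#' @return a \code{family_expression} at the requested resolution.
#' @export
aggregate_expression <- function(expr, annotation,
                                 level = c("isoacceptor", "isotype",
                                           "transcript_group")) {
  level <- match.arg(level)
  fail_if(!inherits(expr, "family_expression"), "expr must be a family_expression")
  fail_if(expr$resolution != "gene", "aggregation starts from gene resolution")
  key <- aggregation_key(annotation, rownames(expr$values), level)
  agg <- function(m) {
    out <- rowsum(m, key, reorder = TRUE)
    out[order(rownames(out)), , drop = FALSE]
  }
  structure(list(resolution = level, values = agg(expr$values),
                 by_cell_type = agg(expr$by_cell_type), sd = NULL,
                 n_replicates = expr$n_replicates,
                 sample_sheet = expr$sample_sheet, excluded = expr$excluded),
            class = "family_expression")
}

#' Within-family composition of the tRNA pool
#'
#' For each gene, its fraction of the summed expression of its family
#' (isoacceptor by default, or identical-transcript group). Families with
#' zero total are reported as undefined (NA), never as zeros.
#'
#' @param expr a gene-resolution \code{family_expression}.
#' @param annotation a \code{trna_annotation}.
#' @param family \code{"isoacceptor"} (default) or \code{"transcript_group"}.
#' @return genes x cell-types matrix of within-family fractions with
#'   attributes \code{"family"} (per-gene family key) and
#'   \code{"undefined_families"} (per cell type, families with zero total).
#' @export
family_composition <- function(expr, annotation,
                               family = c("isoacceptor", "transcript_group")) {
  family <- match.arg(family)
  fail_if(!inherits(expr, "family_expression"), "expr must be a family_expression")
  fail_if(expr$resolution != "gene", "composition starts from gene resolution")
  key <- aggregation_key(annotation, rownames(expr$by_cell_type), family)
  m <- expr$by_cell_type
  totals <- rowsum(m, key, reorder = FALSE)
  denom <- totals[match(key, rownames(totals)), , drop = FALSE]
  comp <- m / denom
  comp[denom == 0] <- NA_real_
  undef <- apply(totals == 0, 2L, function(z) rownames(totals)[z],
                 simplify = FALSE)
  attr(comp, "family") <- key
  attr(comp, "undefined_families") <- undef
  comp
}

#' Pool diversity: fraction of genes contributing significantly to families
#'
#' A gene is a significant contributor iff its within-family fraction is
#' strictly greater than \code{threshold} (default 5\% of the isoacceptor
#' family pool).
#'
#' @param composition matrix from \code{\link{family_composition}}.
#' @param threshold strict contribution threshold in (0, 1).
#' @return list with \code{percent_contributors} (per cell type, \% of genes
#'   with defined composition that are contributors), \code{contributor}
#'   (logical genes x cell types), and \code{per_family} (data.frame of
#'   contributor counts per family and cell type).
#' @export
diversity_fraction <- function(composition, threshold = 0.05) {
  fail_if(threshold <= 0 || threshold >= 1, "threshold must be in (0, 1)")
  contrib <- composition > threshold   # NA stays NA
  pct <- 100 * colMeans(contrib, na.rm = TRUE)
  fam <- attr(composition, "family")
  per_family <- do.call(rbind, lapply(colnames(composition), function(ctn) {
    cnt <- tapply(contrib[, ctn], fam, function(z) sum(z, na.rm = TRUE))
    data.frame(family = names(cnt), cell_type = ctn,
               n_contributors = as.integer(cnt), stringsAsFactors = FALSE)
  }))
  rownames(per_family) <- NULL
  list(percent_contributors = pct, contributor = contrib,
       per_family = per_family)
}

#' Collapse genes with identical mature sequences
#'
#' Sums read counts of genes sharing (isotype, anticodon, transcript group),
#' e.g. tRNA-Ile-TAT-2-1/2-2/2-3 become one distinguishable unit. Column
#' totals are preserved exactly.
#'
#' @param counts genes x samples matrix.
#' @param annotation a \code{trna_annotation} with
#'   \code{identical_group_id}.
#' @return transcript-groups x samples matrix.
#' @export
collapse_identical <- function(counts, annotation) {
  idx <- match(rownames(counts), annotation$gene_name)
  fail_if(anyNA(idx), "counts contain genes absent from annotation: %s",
          paste(rownames(counts)[is.na(idx)], collapse = ", "))
  key <- annotation$identical_group_id[idx]
  out <- rowsum(counts, key, reorder = TRUE)
  out[order(rownames(out)), , drop = FALSE]
}
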