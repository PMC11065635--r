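# Readers and writers for the on-disk formats the pipeline touches: 6-column
# BED + TSV side table for the tRNA catalogue, TSV count/TPM matrices and
# sample sheets, FASTA CDS, tidy expression tables, and JSON ground truth.
# Coordinates follow the BED convention (0-based, half-open) on disk.

#' Read a sample sheet
#'
#' @param path TSV with columns \code{sample}, \code{cell_type},
#'   \code{replicate}, and optionally \code{group} and \code{class}.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "cell_type", "replicate")
  fail_if(!all(need %in% names(sheet)), "sample sheet missing column(s): %s",
          paste(setdiff(need, names(sheet)), collapse = ", "))
  fail_if(anyDuplicated(sheet$sample) > 0, "duplicate sample id(s): %s",
          paste(unique(sheet$sample[duplicated(sheet$sample)]), collapse = ", "))
  sheet
}

#' Write a sample sheet
#' @param sheet data.frame as read by \code{\link{read_sample_sheet}}.
#' @param path output TSV path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a tRNA gene annotation
#'
#' Accepts either a 6-column BED file (0-based half-open coordinates; name =
#' full gene name; score = high-confidence flag 0/1; strand) or the TSV side
#' table written by \code{\link{write_trna_annotation}}. Gene names are
#' parsed with \code{\link{parse_trna_gene_name}}; tRX rows are flagged.
#'
#' @param path input file.
#' @return a \code{trna_annotation} data.frame.
#' @export
read_trna_annotation <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^gene_name\t", first)) {
    ann <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_name", "isotype", "anticodon", "transcript_group", "copy",
              "identical_group_id", "is_trx", "is_high_confidence")
    fail_if(!all(need %in% names(ann)), "annotation TSV missing column(s): %s",
            paste(setdiff(need, names(ann)), collapse = ", "))
    if (!"chrom" %in% names(ann)) {
      ann$chrom <- NA_character_; ann$start <- NA_integer_
      ann$end <- NA_integer_; ann$strand <- NA_character_
    }
    ann$isotype[ann$is_trx] <- NA_character_
  } else {
    bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    fail_if(ncol(bed) < 6L, "BED file needs 6 columns")
    names(bed)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
    bad <- which(bed$start >= bed$end)
    fail_if(length(bad) > 0, "malformed coordinates (start >= end) at line %d",
            bad[1])
    parsed <- parse_trna_gene_name(bed$name)
    ann <- data.frame(
      gene_name = bed$name, isotype = parsed$isotype,
      anticodon = parsed$anticodon,
      transcript_group = parsed$transcript_group, copy = parsed$copy,
      identical_group_id = ifelse(
        parsed$is_trx, bed$name,
        sprintf("%s-%s-%d", parsed$isotype, parsed$anticodon,
                parsed$transcript_group)),
      is_trx = parsed$is_trx,
      is_high_confidence = bed$score == 1 & !parsed$is_trx,
      chrom = bed$chrom, start = bed$start, end = bed$end,
      strand = bed$strand, stringsAsFactors = FALSE)
  }
  rownames(ann) <- ann$gene_name
  class(ann) <- c("trna_annotation", "data.frame")
  ann
}

#' Write a tRNA gene annotation
#'
#' Writes the catalogue as 6-column BED (0-based half-open; score carries the
#' high-confidence flag) and/or as the full TSV side table.
#'
#' @param annotation a \code{trna_annotation}.
#' @param bed optional BED output path.
#' @param tsv optional TSV side-table output path.
#' @export
write_trna_annotation <- function(annotation, bed = NULL, tsv = NULL) {
  if (!is.null(bed)) {
    out <- data.frame(annotation$chrom, annotation$start, annotation$end,
                      annotation$gene_name,
                      as.integer(annotation$is_high_confidence),
                      annotation$strand)
    utils::write.table(out, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv)) {
    utils::write.table(as.data.frame(annotation), tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(annotation)
}

read_numeric_matrix <- function(path, what) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- df[[1]]
  fail_if(anyDuplicated(ids) > 0, "duplicate %s id(s): %s", what,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  fail_if(!is.numeric(m), "non-numeric values in %s matrix", what)
  neg <- which(m < 0, arr.ind = TRUE)
  fail_if(nrow(neg) > 0, "negative value at row '%s', column '%s'",
          ids[neg[1, 1]], colnames(m)[neg[1, 2]])
  rownames(m) <- ids
  m
}

#' Read a read-count matrix
#'
#' TSV with gene ids in the first column and sample ids in the header.
#' Validated against the sample sheet when one is given.
#'
#' @param path counts TSV.
#' @param sample_sheet optional data.frame from
#'   \code{\link{read_sample_sheet}}.
#' @return genes x samples numeric matrix.
#' @export
read_count_matrix <- function(path, sample_sheet = NULL) {
  m <- read_numeric_matrix(path, "gene")
  fail_if(any(m != round(m)), "counts must be integers")
  if (!is.null(sample_sheet)) check_count_matrix(m, sample_sheet)
  m
}

#' Read a TPM matrix
#' @param path TPM TSV (transcripts x samples).
#' @param sample_sheet optional sample sheet for validation.
#' @return transcripts x samples numeric matrix.
#' @export
read_tpm_matrix <- function(path, sample_sheet = NULL) {
  m <- read_numeric_matrix(path, "transcript")
  if (!is.null(sample_sheet)) {
    missing <- setdiff(colnames(m), sample_sheet$sample)
    fail_if(length(missing) > 0, "samples absent from sample sheet: %s",
            paste(missing, collapse = ", "))
  }
  m
}

#' Write a numeric matrix as TSV
#' @param m matrix with row and column names.
#' @param path output TSV; first column is named \code{id}.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read CDS sequences from FASTA
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write CDS sequences to FASTA
#' @param cds named character vector.
#' @param path output FASTA.
#' @export
write_cds_fasta <- function(cds, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cds), path)
  invisible(path)
}

#' Write a tidy expression table
#'
#' One row per (unit, cell type): value, number of replicates, and replicate
#' sd where available.
#'
#' @param expr a \code{family_expression}.
#' @param path output TSV.
#' @export
write_expression_table <- function(expr, path) {
  m <- expr$by_cell_type
  rows <- do.call(rbind, lapply(colnames(m), function(ctn) {
    data.frame(unit = rownames(m), resolution = expr$resolution,
               cell_type = ctn, value = m[, ctn],
               n_replicates = unname(expr$n_replicates[ctn]),
               sd = if (is.null(expr$sd)) NA_real_ else expr$sd[, ctn],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ground truth as JSON
#' @param truth ground-truth list from a simulation.
#' @param path output JSON.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read ground truth JSON
#' @param path JSON written by \code{\link{write_ground_truth}}.
#' @return list.
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a complete simulated study to a directory
#'
#' Emits the annotation (BED + TSV), ChIP counts and sample sheet, CDS FASTA,
#' TPM table, translatome sample sheet, and both ground-truth JSON files.
#'
#' @param chip a \code{chip_sim}.
#' @param translatome a \code{translatome_sim}.
#' @param annotation the \code{trna_annotation} used for the ChIP simulation.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simulated_study <- function(chip, translatome, annotation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trna_annotation(annotation,
                        bed = file.path(dir, "trna_annotation.bed"),
                        tsv = file.path(dir, "trna_annotation.tsv"))
  write_matrix_tsv(chip$counts, file.path(dir, "chip_counts.tsv"))
  write_sample_sheet(chip$sample_sheet, file.path(dir, "chip_samples.tsv"))
  write_ground_truth(chip$truth, file.path(dir, "chip_truth.json"))
  write_cds_fasta(translatome$cds, file.path(dir, "cds.fa"))
  write_matrix_tsv(translatome$tpm, file.path(dir, "tpm.tsv"))
  write_sample_sheet(translatome$sample_sheet,
                     file.path(dir, "translatome_samples.tsv"))
  write_ground_truth(translatome$truth,
                     file.path(dir, "translatome_truth.json"))
  invisible(dir)
}
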