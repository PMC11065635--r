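# Codon demand from translatomes: codon counting of CDS sequences,
# expression-weighted codon usage, 50-fold cell-type-specific gene sets,
# Watson-Crick codon-anticodon correlation with wobble-pair exclusion, the
# matched-vs-mismatched comparison, and the tRNA-supply/codon-demand ratio.

#' Count sense codons of one CDS
#'
#' Counts frame-0 triplets over the 61 sense codons. A terminal stop codon is
#' tolerated and excluded from the counts. Sequences whose length is not a
#' multiple of 3, or that contain an internal stop, are rejected under the
#' default policy.
#'
#' @param cds a single nucleotide string over \{A, C, G, T\}.
#' @param policy \code{"reject"} (default): invalid CDS yields a
#'   \code{codon_rejection}; \code{"count"}: count complete valid triplets,
#'   skipping stops and any trailing partial codon.
#' @return named integer vector over the 61 sense codons, or an object of
#'   class \code{codon_rejection} (list with \code{reason}).
#' @export
#' @examples
#' codon_counts("ATGAAATAA")  # ATG:1, AAA:1; terminal TAA excluded
codon_counts <- function(cds, policy = c("reject", "count")) {
  policy <- match.arg(policy)
  fail_if(!is.character(cds) || length(cds) != 1L, "cds must be one string")
  cds <- toupper(cds)
  fail_if(nchar(cds) < 3L, "cds shorter than one codon")
  if (grepl("[^ACGT]", cds))
    return(structure(list(reason = "non-ACGT character"),
                     class = "codon_rejection"))

  n <- nchar(cds)
  if (policy == "reject" && n %% 3L != 0L)
    return(structure(list(reason = "length not multiple of 3"),
                     class = "codon_rejection"))

  starts <- seq.int(1L, n - n %% 3L, by = 3L)
  triplets <- substring(cds, starts, starts + 2L)

  stops <- triplets %in% stop_codons()
  if (policy == "reject" && any(stops[-length(triplets)]))
    return(structure(list(reason = "internal stop codon"),
                     class = "codon_rejection"))

  codons <- sense_codons()
  counts <- tabulate(match(triplets[!stops], codons), nbins = 61L)
  names(counts) <- codons
  counts
}

#' Codon count matrix for a set of transcripts
#'
#' Applies \code{\link{codon_counts}} to each CDS; rejected transcripts are
#' dropped and logged in the \code{"rejected"} attribute.
#'
#' @param cds named character vector of CDS sequences.
#' @param policy see \code{\link{codon_counts}}.
#' @return integer matrix, transcripts x 61 sense codons, with attribute
#'   \code{"rejected"} (data.frame \code{transcript}, \code{reason}).
#' @export
codon_count_matrix <- function(cds, policy = c("reject", "count")) {
  policy <- match.arg(policy)
  fail_if(is.null(names(cds)) || anyDuplicated(names(cds)) > 0,
          "cds must be named with unique transcript ids")
  res <- lapply(cds, codon_counts, policy = policy)
  bad <- vapply(res, inherits, TRUE, "codon_rejection")
  rejected <- data.frame(
    transcript = names(cds)[bad],
    reason = vapply(res[bad], function(r) r$reason, ""),
    stringsAsFactors = FALSE)
  m <- do.call(rbind, res[!bad])
  if (is.null(m)) m <- matrix(0L, 0L, 61L, dimnames = list(NULL, sense_codons()))
  rownames(m) <- names(cds)[!bad]
  attr(m, "rejected") <- rejected
  m
}

#' Expression-weighted codon usage
#'
#' The occurrence count of each sense codon in each transcript is multiplied
#' by the transcript's expression (TPM), summed over transcripts, and
#' normalized to the total over the 61 sense codons, expressed as a
#' percentage of total use.
#'
#' @param codon_matrix transcripts x 61 codon count matrix
#'   (\code{\link{codon_count_matrix}}).
#' @param tpm numeric vector of non-negative expression values, one per row
#'   of \code{codon_matrix} (matched by name when named).
#' @param context optional label (cell type or gene-set name).
#' @return named numeric vector over the 61 sense codons summing to 100, with
#'   attributes \code{"context"} and \code{"n_transcripts"}.
#' @export
weighted_codon_usage <- function(codon_matrix, tpm, context = NULL) {
  if (!is.null(names(tpm)) && !is.null(rownames(codon_matrix))) {
    fail_if(!all(rownames(codon_matrix) %in% names(tpm)),
            "tpm missing transcripts present in codon_matrix")
    tpm <- tpm[rownames(codon_matrix)]
  }
  fail_if(length(tpm) != nrow(codon_matrix),
          "tpm length does not match codon_matrix rows")
  fail_if(any(tpm < 0), "tpm must be non-negative")
  fail_if(all(tpm == 0), "all tpm are zero")
  w <- as.vector(crossprod(codon_matrix, tpm))
  names(w) <- colnames(codon_matrix)
  usage <- 100 * w / sum(w)
  attr(usage, "context") <- context
  attr(usage, "n_transcripts") <- sum(tpm > 0)
  usage
}

#' Cell-type-specific gene sets by fold change
#'
#' A transcript belongs to the set specific to cell type A iff
#' (mean TPM_A + pseudo) / (mean TPM_B + pseudo) >= \code{fold}; symmetric
#' for B. The two sets are disjoint for \code{fold} > 1.
#'
#' @param tpm transcripts x samples matrix.
#' @param sample_sheet data.frame with \code{sample} and \code{cell_type}.
#' @param cell_a,cell_b the two cell types compared.
#' @param fold fold-change threshold (default 50).
#' @param pseudo pseudocount in TPM units (default 0.01).
#' @return list with \code{set_a}, \code{set_b} (transcript ids) and
#'   \code{ratio} (data.frame \code{transcript}, \code{mean_a},
#'   \code{mean_b}, \code{ratio_a_over_b}).
#' @export
specific_gene_sets <- function(tpm, sample_sheet, cell_a, cell_b, fold = 50,
                               pseudo = 0.01) {
  sa <- intersect(sample_sheet$sample[sample_sheet$cell_type == cell_a],
                  colnames(tpm))
  sb <- intersect(sample_sheet$sample[sample_sheet$cell_type == cell_b],
                  colnames(tpm))
  fail_if(length(sa) == 0L || length(sb) == 0L,
          "cell type without samples in the TPM table")
  ma <- rowMeans(tpm[, sa, drop = FALSE])
  mb <- rowMeans(tpm[, sb, drop = FALSE])
  ra <- (ma + pseudo) / (mb + pseudo)
  list(set_a = rownames(tpm)[ra >= fold],
       set_b = rownames(tpm)[1 / ra >= fold],
       ratio = data.frame(transcript = rownames(tpm), mean_a = ma,
                          mean_b = mb, ratio_a_over_b = ra,
                          stringsAsFactors = FALSE))
}

# Split isoacceptor keys "Iso-Anti" into isotype and anticodon.
split_isoacceptor <- function(keys) {
  parts <- strsplit(keys, "-", fixed = TRUE)
  ok <- lengths(parts) == 2L & grepl("^[ACGTN]{3}$",
                                     vapply(parts, `[`, "", 2L))
  fail_if(any(!ok), "isoacceptor keys must look like 'Ile-TAT': %s",
          paste(keys[!ok], collapse = ", "))
  data.frame(isotype = vapply(parts, `[`, "", 1L),
             anticodon = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Codon-anticodon correlation with wobble pairs excluded
#'
#' Pairs each sense codon with the isoacceptor family whose anticodon is its
#' exact Watson-Crick reverse complement. Codons whose decoding would rely
#' only on wobble pairing (no exact-cognate family expressed) are excluded
#' and recorded. The Spearman rank correlation between family tRNA levels and
#' cognate codon usage is computed over the included pairs.
#'
#' @param trna_pct named numeric vector of isoacceptor family levels
#'   (\% of the tRNA pool), names like \code{"Ile-TAT"}.
#' @param codon_pct named numeric vector over the 61 sense codons
#'   (\% of codon usage).
#' @return list with \code{rho}, \code{n_pairs}, and \code{pairs}
#'   (data.frame \code{codon}, \code{isoacceptor}, \code{anticodon},
#'   \code{trna_pct}, \code{codon_pct}, \code{included},
#'   \code{exclusion_reason}).
#' @export
codon_anticodon_correlation <- function(trna_pct, codon_pct) {
  fail_if(is.null(names(trna_pct)) || is.null(names(codon_pct)),
          "both vectors must be named")
  fams <- split_isoacceptor(names(trna_pct))
  fams <- fams[grepl("^[ACGT]{3}$", fams$anticodon), , drop = FALSE]
  cognate <- anticodon_to_codon(fams$anticodon)
  fam_of_codon <- stats::setNames(
    paste(fams$isotype, fams$anticodon, sep = "-"), cognate)

  codons <- intersect(sense_codons(), names(codon_pct))
  pairs <- data.frame(codon = codons,
                      isoacceptor = unname(fam_of_codon[codons]),
                      stringsAsFactors = FALSE)
  pairs$anticodon <- anticodon_to_codon(pairs$codon)  # revcomp of the codon
  pairs$trna_pct <- unname(trna_pct[pairs$isoacceptor])
  pairs$codon_pct <- unname(codon_pct[pairs$codon])
  no_family <- is.na(pairs$isoacceptor)
  unexpressed <- !no_family & (is.na(pairs$trna_pct) | pairs$trna_pct <= 0)
  pairs$included <- !no_family & !unexpressed
  pairs$exclusion_reason <- ifelse(no_family, "wobble-only decoding",
                                   ifelse(unexpressed, "family not expressed",
                                          NA_character_))
  inc <- pairs[pairs$included, ]
  fail_if(nrow(inc) < 3L, "fewer than 3 Watson-Crick pairs available")
  rho <- stats::cor(inc$trna_pct, inc$codon_pct, method = "spearman")
  list(rho = rho, n_pairs = nrow(inc), pairs = pairs)
}

#' Matched vs mismatched codon-anticodon correlations
#'
#' Given the matrix of Spearman correlations between every tRNA-pool cell
#' type (rows) and every translatome cell type (columns), compares the
#' matched (diagonal) values with the mismatched (off-diagonal) values by a
#' two-sided Mann-Whitney U test.
#'
#' @param rho_matrix square numeric matrix with identical row and column
#'   cell-type names.
#' @return list with \code{p}, \code{U}, \code{matched}, \code{mismatched}.
#' @export
matched_mismatched_test <- function(rho_matrix) {
  fail_if(!is.matrix(rho_matrix) || nrow(rho_matrix) < 2L ||
            nrow(rho_matrix) != ncol(rho_matrix),
          "rho_matrix must be a square matrix with >= 2 cell types")
  fail_if(!identical(rownames(rho_matrix), colnames(rho_matrix)),
          "row and column cell types must match")
  matched <- diag(rho_matrix)
  mismatched <- rho_matrix[row(rho_matrix) != col(rho_matrix)]
  if (length(unique(c(matched, mismatched))) == 1L) {
    # identical distributions: no evidence of a shift by convention
    return(list(p = 1, U = length(matched) * length(mismatched) / 2,
                matched = matched, mismatched = mismatched))
  }
  wt <- suppressWarnings(stats::wilcox.test(matched, mismatched,
                                            alternative = "two.sided"))
  list(p = wt$p.value, U = unname(wt$statistic),
       matched = matched, mismatched = mismatched)
}

#' tRNA supply / codon demand ratio
#'
#' The ratio of each isoacceptor family's relative tRNA level (\% of the
#' tRNA pool) to the expression-weighted usage of its exact cognate codon
#' (\% of total codon use) in the translatome.
#'
#' @param trna_pct named isoacceptor levels in percent (names "Iso-Anti").
#' @param codon_pct named codon usage in percent over the 61 sense codons.
#' @return data.frame with \code{isoacceptor}, \code{isotype},
#'   \code{anticodon}, \code{cognate_codon}, \code{trna_pct},
#'   \code{codon_pct}, \code{ratio}.
#' @export
supply_demand_ratio <- function(trna_pct, codon_pct) {
  fams <- split_isoacceptor(names(trna_pct))
  keep <- grepl("^[ACGT]{3}$", fams$anticodon)
  fams <- fams[keep, , drop = FALSE]
  lv <- trna_pct[keep]
  cognate <- anticodon_to_codon(fams$anticodon)
  fail_if(!all(cognate %in% names(codon_pct)),
          "codon usage missing cognate codon(s): %s",
          paste(setdiff(cognate, names(codon_pct)), collapse = ", "))
  usage <- unname(codon_pct[cognate])
  fail_if(any(usage == 0), "zero codon usage for cognate codon(s): %s",
          paste(cognate[usage == 0], collapse = ", "))
  data.frame(isoacceptor = paste(fams$isotype, fams$anticodon, sep = "-"),
             isotype = fams$isotype, anticodon = fams$anticodon,
             cognate_codon = cognate, trna_pct = unname(lv),
             codon_pct = usage, ratio = unname(lv) / usage,
             stringsAsFactors = FALSE)
}
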