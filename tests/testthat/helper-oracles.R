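# Independent brute-force oracles used to cross-check the package's
# implementations, written directly from the definitions they verify.

# Benjamini-Hochberg step-up from the definition:
# q_(i) = min_{j >= i} p_(j) * m / j, capped at 1, back in input order.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Spearman rho as rank-then-Pearson with average ranks for ties.
spearman_bruteforce <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Pearson r from first principles.
pearson_bruteforce <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Expression-weighted codon usage by an explicit transcript-by-transcript
# accumulation loop (never vectorized, never shares code with the package).
weighted_usage_bruteforce <- function(codon_matrix, tpm) {
  acc <- setNames(numeric(ncol(codon_matrix)), colnames(codon_matrix))
  for (t in seq_len(nrow(codon_matrix))) {
    for (cod in colnames(codon_matrix)) {
      acc[cod] <- acc[cod] + codon_matrix[t, cod] * tpm[t]
    }
  }
  100 * acc / sum(acc)
}

# A tiny hand-built count matrix + sample sheet: 2 cell types x 2 replicates.
toy_counts <- function() {
  counts <- matrix(
    c(50, 40, 10, 20,
      50, 60, 90, 80,
      3, 5, 0, 1),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("tRNA-Ile-TAT-2-1", "tRNA-Ile-TAT-2-2",
                      "tRNA-Arg-TCT-4-1"),
                    c("N_rep1", "N_rep2", "G_rep1", "G_rep2")))
  sheet <- data.frame(
    sample = colnames(counts),
    cell_type = c("N", "N", "G", "G"),
    replicate = c(1, 2, 1, 2),
    group = c("A", "A", "B", "B"),
    class = c("neuronal", "neuronal", "non_neuronal", "non_neuronal"),
    stringsAsFactors = FALSE)
  list(counts = counts, sheet = sheet)
}

# Annotation matching toy_counts().
toy_annotation <- function() {
  ann <- data.frame(
    gene_name = c("tRNA-Ile-TAT-2-1", "tRNA-Ile-TAT-2-2", "tRNA-Arg-TCT-4-1"),
    isotype = c("Ile", "Ile", "Arg"),
    anticodon = c("TAT", "TAT", "TCT"),
    transcript_group = c(2L, 2L, 4L),
    copy = c(1L, 2L, 1L),
    identical_group_id = c("Ile-TAT-2", "Ile-TAT-2", "Arg-TCT-4"),
    is_trx = FALSE,
    is_high_confidence = TRUE,
    chrom = "chr1", start = c(100L, 300L, 500L),
    end = c(172L, 372L, 572L), strand = "+",
    stringsAsFactors = FALSE)
  rownames(ann) <- ann$gene_name
  class(ann) <- c("trna_annotation", "data.frame")
  ann
}
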