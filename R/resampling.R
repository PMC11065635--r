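# Empirical permutation tests: a random-gene-set null for the correlation
# between codon-usage vectors of two cell types, and per-codon two-sided
# over/under-representation p-values for a gene set of interest. Both share
# one reproducible sampling engine and report plain-fraction empirical
# p-values (fraction of random sets strictly higher / strictly lower), with
# a smoothed (r+1)/(n+1) option.

#' Sample random gene sets
#'
#' Draws \code{n_perm} independent sets of \code{size} indices, each sampled
#' uniformly without replacement from \code{1:universe_size}. Fully
#' reproducible from \code{seed}; the caller's RNG state is untouched.
#'
#' @param universe_size number of transcripts in the universe.
#' @param size set size.
#' @param n_perm number of sets.
#' @param seed integer seed.
#' @return integer matrix, \code{n_perm} x \code{size}; row i is the i-th set.
#' @export
sample_gene_sets <- function(universe_size, size, n_perm, seed) {
  fail_if(!is_count(universe_size), "universe_size must be a positive integer")
  fail_if(!is_count(size), "size must be a positive integer")
  fail_if(size > universe_size, "set size (%d) exceeds universe size (%d)",
          size, universe_size)
  fail_if(!is_count(n_perm), "n_perm must be a positive integer")
  with_seed(seed, {
    m <- matrix(0L, nrow = n_perm, ncol = size)
    for (i in seq_len(n_perm)) m[i, ] <- sample.int(universe_size, size)
    m
  })
}

empirical_p <- function(null_values, observed, n_perm, smoothed) {
  n_low <- sum(null_values < observed)
  n_high <- sum(null_values > observed)
  n_equal <- n_perm - n_low - n_high
  if (smoothed) {
    list(p_low = (n_low + 1) / (n_perm + 1),
         p_high = (n_high + 1) / (n_perm + 1),
         p_equal = n_equal / n_perm,
         n_low = n_low, n_high = n_high, n_equal = n_equal)
  } else {
    list(p_low = n_low / n_perm, p_high = n_high / n_perm,
         p_equal = n_equal / n_perm,
         n_low = n_low, n_high = n_high, n_equal = n_equal)
  }
}

#' Random-gene-set null for between-cell-type codon-usage correlation
#'
#' Tests whether the Pearson correlation between the codon-usage vectors of
#' two gene sets (each weighted by its own cell type's TPM) is lower than
#' expected for random sets of the same sizes. Each of \code{n_perm}
#' permutations draws two independent random sets of the stated sizes from
#' the universe, computes each set's expression-weighted codon usage in its
#' respective cell type, and the Pearson correlation between the two usage
#' vectors. The observed correlation is compared against this null;
#' \code{p_low} (fraction of null correlations strictly below the observed)
#' is the significance measure for "lower than expected by chance".
#'
#' @param codon_matrix transcripts x 61 codon count matrix over the universe.
#' @param tpm_a,tpm_b TPM vectors for the two cell types, one value per
#'   universe transcript (matched by name when named).
#' @param set_a,set_b the observed gene sets (transcript ids or indices).
#' @param n_perm number of random set pairs (default 10000).
#' @param seed integer seed (mandatory).
#' @param smoothed use the (r+1)/(n+1) estimator (default FALSE:
#'   plain fraction).
#' @return object of class \code{empirical_test}: list with
#'   \code{statistic_name}, \code{observed}, \code{n_perm}, \code{p_low},
#'   \code{p_high}, \code{p_equal}, counts \code{n_low}/\code{n_high}/
#'   \code{n_equal}, \code{seed}, \code{set_size}, \code{universe_size},
#'   \code{null_values}.
#' @export
empirical_correlation_null <- function(codon_matrix, tpm_a, tpm_b,
                                       set_a, set_b, n_perm = 10000L, seed,
                                       smoothed = FALSE) {
  fail_if(missing(seed), "seed is mandatory")
  universe <- rownames(codon_matrix)
  fail_if(is.null(universe), "codon_matrix needs transcript rownames")
  align <- function(tpm) {
    if (!is.null(names(tpm))) {
      fail_if(!all(universe %in% names(tpm)), "tpm missing universe transcripts")
      tpm <- tpm[universe]
    }
    fail_if(length(tpm) != length(universe), "tpm length mismatch")
    tpm
  }
  tpm_a <- align(tpm_a); tpm_b <- align(tpm_b)
  to_idx <- function(s) {
    if (is.character(s)) {
      idx <- match(s, universe)
      fail_if(anyNA(idx), "gene set members absent from universe: %s",
              paste(s[is.na(idx)], collapse = ", "))
      idx
    } else as.integer(s)
  }
  ia <- to_idx(set_a); ib <- to_idx(set_b)
  fail_if(length(ia) == 0L || length(ib) == 0L, "empty gene set")
  fail_if(length(ia) > length(universe) || length(ib) > length(universe),
          "set size exceeds universe size")

  usage_of <- function(idx, tpm) {
    w <- crossprod(codon_matrix[idx, , drop = FALSE], tpm[idx])
    100 * w / sum(w)
  }
  observed <- as.vector(stats::cor(usage_of(ia, tpm_a), usage_of(ib, tpm_b)))

  sets_a <- sample_gene_sets(length(universe), length(ia), n_perm,
                             stream_seed(seed, "corr_null_a"))
  sets_b <- sample_gene_sets(length(universe), length(ib), n_perm,
                             stream_seed(seed, "corr_null_b"))
  null_values <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    null_values[i] <- stats::cor(usage_of(sets_a[i, ], tpm_a),
                                 usage_of(sets_b[i, ], tpm_b))
  }

  ep <- empirical_p(null_values, observed, n_perm, smoothed)
  structure(c(list(statistic_name = "pearson_correlation",
                   observed = as.vector(observed), n_perm = n_perm),
              ep,
              list(seed = seed, set_size = c(length(ia), length(ib)),
                   universe_size = length(universe),
                   null_values = null_values, smoothed = smoothed)),
            class = "empirical_test")
}

#' Per-codon enrichment in a gene set by random-set permutation
#'
#' Draws \code{n_perm} random gene sets of the same size as the observed set
#' from the universe and computes each set's expression-weighted codon usage;
#' every codon's p-values come from the same random sets (one pass). For each
#' of the 61 sense codons, \code{p_high} is the fraction of random sets with
#' strictly higher usage than the observed set and \code{p_low} the fraction
#' strictly lower. A codon is flagged overrepresented iff
#' \code{p_high <= alpha} (few random sets exceed the observed usage) and
#' underrepresented iff \code{p_low <= alpha}.
#'
#' @param codon_matrix transcripts x 61 codon count matrix over the universe.
#' @param tpm TPM vector for the cell type in which usage is weighted.
#' @param gene_set observed set (transcript ids or indices).
#' @param n_perm number of random sets (default 10000).
#' @param seed integer seed (mandatory).
#' @param alpha flag threshold on the empirical p (default 0.05).
#' @param smoothed use the (r+1)/(n+1) estimator (default FALSE).
#' @return data.frame with one row per sense codon: \code{codon},
#'   \code{amino_acid}, \code{observed_pct}, \code{null_mean_pct},
#'   \code{p_high}, \code{p_low}, \code{p_equal}, \code{flag_over},
#'   \code{flag_under}. Attributes: \code{"n_perm"}, \code{"seed"},
#'   \code{"set_size"}, \code{"universe_size"}, \code{"smoothed"}.
#' @export
empirical_codon_enrichment <- function(codon_matrix, tpm, gene_set,
                                       n_perm = 10000L, seed, alpha = 0.05,
                                       smoothed = FALSE) {
  fail_if(missing(seed), "seed is mandatory")
  universe <- rownames(codon_matrix)
  fail_if(is.null(universe), "codon_matrix needs transcript rownames")
  if (!is.null(names(tpm))) {
    fail_if(!all(universe %in% names(tpm)), "tpm missing universe transcripts")
    tpm <- tpm[universe]
  }
  fail_if(length(tpm) != length(universe), "tpm length mismatch")
  if (is.character(gene_set)) {
    idx <- match(gene_set, universe)
    fail_if(anyNA(idx), "gene set members absent from universe: %s",
            paste(gene_set[is.na(idx)], collapse = ", "))
  } else idx <- as.integer(gene_set)
  fail_if(length(idx) == 0L, "empty gene set")
  fail_if(length(idx) > length(universe), "set size exceeds universe size")

  usage_of <- function(i) {
    w <- crossprod(codon_matrix[i, , drop = FALSE], tpm[i])
    as.vector(100 * w / sum(w))
  }
  observed <- usage_of(idx)

  sets <- sample_gene_sets(length(universe), length(idx), n_perm,
                           stream_seed(seed, "codon_enrichment"))
  null_usage <- matrix(0, n_perm, 61L)
  for (i in seq_len(n_perm)) null_usage[i, ] <- usage_of(sets[i, ])

  n_high <- colSums(sweep(null_usage, 2L, observed, ">"))
  n_low <- colSums(sweep(null_usage, 2L, observed, "<"))
  n_equal <- n_perm - n_high - n_low
  if (smoothed) {
    p_high <- (n_high + 1) / (n_perm + 1)
    p_low <- (n_low + 1) / (n_perm + 1)
  } else {
    p_high <- n_high / n_perm
    p_low <- n_low / n_perm
  }

  tab <- codon_table()
  out <- data.frame(codon = colnames(codon_matrix),
                    amino_acid = tab$amino_acid[match(colnames(codon_matrix),
                                                      tab$codon)],
                    observed_pct = observed,
                    null_mean_pct = colMeans(null_usage),
                    p_high = p_high, p_low = p_low,
                    p_equal = n_equal / n_perm,
                    flag_over = p_high <= alpha,
                    flag_under = p_low <= alpha,
                    stringsAsFactors = FALSE)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "set_size") <- length(idx)
  attr(out, "universe_size") <- length(universe)
  attr(out, "smoothed") <- smoothed
  attr(out, "counts") <- data.frame(codon = colnames(codon_matrix),
                                    n_low = n_low, n_high = n_high,
                                    n_equal = n_equal)
  out
}
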