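# Differential expression of tRNA units between two sample groups: an F-test
# variance gate choosing Student vs Welch, Benjamini-Hochberg control, the
# q <= 0.05 & |log2FC| >= 0.5 significance rule, and the high-variance gene
# screen.

#' Variance-gated two-sample t-test
#'
#' Tests equality of variances with a two-sided F-test; if the gate rejects
#' (p < \code{gate_alpha}) a Welch t-test (Satterthwaite df) is used,
#' otherwise a Student t-test with pooled variance. Degenerate inputs with
#' zero variance in both groups return p = 1 (equal means) or p = 0 (unequal
#' means) by convention, flagged.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param gate_alpha F-test significance level for the gate (default 0.05).
#' @return list with \code{t_stat}, \code{df}, \code{p}, \code{test_used}
#'   ("student" or "welch"), \code{p_f} (gate p-value), \code{degenerate}.
#' @export
variance_gated_ttest <- function(x, y, gate_alpha = 0.05) {
  fail_if(length(x) < 2L || length(y) < 2L, "each group needs >= 2 values")
  fail_if(anyNA(x) || anyNA(y), "missing values are not allowed")
  vx <- var(x); vy <- var(y)

  if (vx == 0 && vy == 0) {
    equal <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t_stat = if (equal) 0 else sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2,
                p = if (equal) 1 else 0,
                test_used = "student", p_f = NA_real_, degenerate = TRUE))
  }

  p_f <- if (vx == 0 || vy == 0) 0 else stats::var.test(x, y)$p.value
  welch <- p_f < gate_alpha
  tt <- stats::t.test(x, y, var.equal = !welch)
  list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, test_used = if (welch) "welch" else "student",
       p_f = p_f, degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values (q-values)
#'
#' Step-up FDR adjustment: q_(i) = min over j >= i of p_(j) * m / j, capped
#' at 1 and mapped back to input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  fail_if(!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1),
          "p-values must be numbers in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

resolve_group_samples <- function(sample_sheet, group) {
  if (all(group %in% sample_sheet$cell_type)) {
    sample_sheet$sample[sample_sheet$cell_type %in% group]
  } else if (all(group %in% sample_sheet$group)) {
    sample_sheet$sample[sample_sheet$group %in% group]
  } else if (all(group %in% sample_sheet$sample)) {
    group
  } else {
    stop(sprintf("group '%s' matches no cell type, group label or sample",
                 paste(group, collapse = ",")), call. = FALSE)
  }
}

#' Differential expression table between two groups
#'
#' For every unit of a relative-expression table, tests the difference in
#' per-sample fractions between two groups with the variance-gated t-test,
#' adjusts p-values with Benjamini-Hochberg across all units at this
#' resolution, and flags units significant iff q <= \code{alpha} and
#' |log2FC| >= \code{fc_min}. Fold changes are computed on group mean
#' fractions with a pseudocount (default: half the smallest nonzero fraction
#' at this resolution) so zeros never produce infinite log2FC.
#'
#' @param expr a \code{family_expression} at any resolution.
#' @param group1,group2 cell-type names, group labels, or sample ids; the
#'   samples entering each side are all replicate-level fractions of member
#'   cell types (switch to cell-type means via \code{samples}).
#' @param alpha q-value threshold (default 0.05).
#' @param fc_min |log2FC| threshold (default 0.5).
#' @param gate_alpha F-test gate level (default 0.05).
#' @param pseudo pseudocount added to both group means; NULL for the default.
#' @param samples \code{"replicates"} (default) or \code{"cell_type_means"}.
#' @return data.frame with one row per unit: \code{unit}, \code{resolution},
#'   \code{mean1}, \code{mean2}, \code{log2fc}, \code{t_stat}, \code{df},
#'   \code{p}, \code{q}, \code{test_used}, \code{significant}. Metadata
#'   (alpha, fc_min, gate_alpha, pseudo) in attribute \code{"metadata"}.
#' @export
differential_table <- function(expr, group1, group2, alpha = 0.05,
                               fc_min = 0.5, gate_alpha = 0.05, pseudo = NULL,
                               samples = c("replicates", "cell_type_means")) {
  samples <- match.arg(samples)
  fail_if(!inherits(expr, "family_expression"), "expr must be a family_expression")

  if (samples == "replicates") {
    X <- expr$values
    s1 <- intersect(resolve_group_samples(expr$sample_sheet, group1), colnames(X))
    s2 <- intersect(resolve_group_samples(expr$sample_sheet, group2), colnames(X))
  } else {
    X <- expr$by_cell_type
    s1 <- intersect(group1, colnames(X))
    s2 <- intersect(group2, colnames(X))
  }
  fail_if(length(intersect(s1, s2)) > 0, "groups share sample(s): %s",
          paste(intersect(s1, s2), collapse = ", "))
  fail_if(length(s1) < 2L || length(s2) < 2L, "each group needs >= 2 samples")

  if (is.null(pseudo)) {
    nz <- X[X > 0]
    pseudo <- if (length(nz)) min(nz) / 2 else 0
  }

  units <- rownames(X)
  res <- lapply(units, function(u) {
    tt <- variance_gated_ttest(X[u, s1], X[u, s2], gate_alpha = gate_alpha)
    m1 <- mean(X[u, s1]); m2 <- mean(X[u, s2])
    data.frame(unit = u, resolution = expr$resolution, mean1 = m1, mean2 = m2,
               log2fc = log2((m1 + pseudo) / (m2 + pseudo)),
               t_stat = tt$t_stat, df = tt$df, p = tt$p,
               test_used = tt$test_used, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q <= alpha & abs(out$log2fc) >= fc_min
  out <- out[, c("unit", "resolution", "mean1", "mean2", "log2fc", "t_stat",
                 "df", "p", "q", "test_used", "significant")]
  attr(out, "metadata") <- list(alpha = alpha, fc_min = fc_min,
                                gate_alpha = gate_alpha, pseudo = pseudo,
                                samples = samples)
  out
}

#' High-variance tRNA units across cell types
#'
#' Computes, per unit, the population variance of cell-type mean fractions
#' across cell types and, per cell type, the variance across its replicates.
#' Units where any within-cell-type variance is strictly greater than the
#' population variance are filtered out; survivors are ranked by population
#' variance (descending, ties broken by unit name) and the top \code{k}
#' returned.
#'
#' @param expr a \code{family_expression} with >= 2 cell types.
#' @param k number of top units to return (default 25).
#' @return data.frame \code{unit}, \code{population_variance},
#'   \code{max_within_variance}, \code{rank}; attributes \code{"dropped"}
#'   (filtered units) and \code{"note"} when fewer than k survive.
#' @export
high_variance_genes <- function(expr, k = 25) {
  fail_if(!inherits(expr, "family_expression"), "expr must be a family_expression")
  M <- expr$by_cell_type
  fail_if(ncol(M) < 2L, "need >= 2 cell types")
  pop_var <- apply(M, 1L, var)

  within <- matrix(NA_real_, nrow(M), ncol(M),
                   dimnames = dimnames(M))
  for (ctn in colnames(M)) {
    reps <- intersect(expr$sample_sheet$sample[expr$sample_sheet$cell_type == ctn],
                      colnames(expr$values))
    within[, ctn] <- apply(expr$values[, reps, drop = FALSE], 1L, var)
  }
  max_within <- apply(within, 1L, max)

  keep <- !(max_within > pop_var)          # strict: ties and 0 > 0 retained
  dropped <- rownames(M)[!keep]
  surv <- data.frame(unit = rownames(M)[keep],
                     population_variance = pop_var[keep],
                     max_within_variance = max_within[keep],
                     stringsAsFactors = FALSE)
  surv <- surv[order(-surv$population_variance, surv$unit), ]
  surv$rank <- seq_len(nrow(surv))
  rownames(surv) <- NULL
  note <- NULL
  if (k > nrow(surv)) {
    note <- sprintf("k = %d exceeds the %d surviving units; returning all",
                    k, nrow(surv))
  }
  out <- utils::head(surv, k)
  attr(out, "dropped") <- dropped
  attr(out, "note") <- note
  out
}
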