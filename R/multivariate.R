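# Shared descriptive machinery: row z-scores, PCA with variance explained,
# Euclidean distance with deterministic dendrogram leaf ordering, and the
# frequency-distribution + Gaussian curve fit.

#' Row-wise z-scores
#'
#' Standardizes each row to mean 0 and (sample) sd 1. Rows with zero sd are
#' returned as all-zero and flagged.
#'
#' @param m numeric matrix with >= 2 columns.
#' @return matrix of z-scores; attribute \code{"constant_rows"} names rows
#'   with zero sd.
#' @export
zscore_rows <- function(m) {
  fail_if(!is.matrix(m) || ncol(m) < 2L, "need a matrix with >= 2 columns")
  fail_if(any(!is.finite(m)), "non-finite values in matrix")
  mu <- rowMeans(m)
  sdev <- apply(m, 1L, sd)
  z <- (m - mu) / sdev
  const <- sdev == 0
  z[const, ] <- 0
  attr(z, "constant_rows") <- rownames(m)[const]
  z
}

#' PCA of expression profiles
#'
#' Centered (unscaled by default) principal-component analysis of the
#' samples (columns) of a units x samples matrix, with the proportion of
#' variance explained per component. For determinism the sign of each
#' component is fixed so its largest-magnitude loading is positive.
#'
#' @param m units x samples numeric matrix (>= 2 of each).
#' @param scale. scale unit rows to unit variance before PCA (default FALSE).
#' @return list with \code{scores} (samples x components), \code{loadings}
#'   (units x components), \code{var_explained} (fractions, non-increasing),
#'   \code{center}, \code{scaled}.
#' @export
pca_expression <- function(m, scale. = FALSE) {
  fail_if(!is.matrix(m) || nrow(m) < 2L || ncol(m) < 2L,
          "need >= 2 units and >= 2 samples")
  p <- stats::prcomp(t(m), center = TRUE, scale. = scale.)
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  ve <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x, loadings = p$rotation, var_explained = ve,
       center = p$center, scaled = scale.)
}

# Deterministic leaf order of an hclust tree: at every internal node the
# subtree with fewer leaves comes first; ties broken by the lexicographically
# smallest leaf label.
ordered_leaves <- function(h) {
  labels <- h$labels
  walk <- function(node) {
    if (node < 0) return(list(leaves = -node, min_label = labels[-node]))
    left <- walk(h$merge[node, 1])
    right <- walk(h$merge[node, 2])
    swap <- length(left$leaves) > length(right$leaves) ||
      (length(left$leaves) == length(right$leaves) &&
         right$min_label < left$min_label)
    if (swap) { tmp <- left; left <- right; right <- tmp }
    list(leaves = c(left$leaves, right$leaves),
         min_label = min(left$min_label, right$min_label))
  }
  walk(nrow(h$merge))$leaves
}

#' Euclidean distances with deterministic dendrogram ordering
#'
#' Pairwise Euclidean distances between the columns of \code{m}, an
#' average-linkage hierarchical clustering, and a deterministic leaf order
#' (smallest-subtree-first, ties by smallest leaf label).
#'
#' @param m units x items numeric matrix with >= 2 columns.
#' @return list with \code{dist} (symmetric matrix), \code{hclust}, and
#'   \code{order} (item labels in leaf order).
#' @export
euclidean_ordering <- function(m) {
  fail_if(!is.matrix(m) || ncol(m) < 2L, "need >= 2 columns")
  d <- stats::dist(t(m), method = "euclidean")
  h <- stats::hclust(d, method = "average")
  leaf_idx <- ordered_leaves(h)
  list(dist = as.matrix(d), hclust = h, order = h$labels[leaf_idx])
}

#' Gaussian fit to a frequency distribution
#'
#' Bins the values into a histogram of counts with the given bin width and
#' fits \eqn{A exp(-(x - \mu)^2 / (2\sigma^2))} to the bin centers by
#' nonlinear least squares (Levenberg-Marquardt). Initialization:
#' \eqn{\mu_0} = sample mean, \eqn{\sigma_0} = sample sd, \eqn{A_0} = max bin
#' count; convergence tolerance 1e-8 on the relative change in the residual
#' sum of squares.
#'
#' @param values numeric vector with >= 5 distinct values.
#' @param bin_width histogram bin width (same units as \code{values}).
#' @return object of class \code{gaussian_fit}: list with \code{amplitude},
#'   \code{mean}, \code{sd}, \code{rss}, \code{bins} (data.frame
#'   \code{center}, \code{count}).
#' @export
gaussian_frequency_fit <- function(values, bin_width) {
  fail_if(!is.numeric(values) || length(unique(values)) < 5L,
          "need >= 5 distinct values")
  fail_if(!is.numeric(bin_width) || bin_width <= 0, "bin_width must be > 0")
  lo <- floor(min(values) / bin_width) * bin_width
  breaks <- seq(lo, max(values) + bin_width, by = bin_width)
  hh <- hist(values, breaks = breaks, plot = FALSE, right = FALSE)
  dat <- data.frame(x = hh$mids, y = hh$counts)
  fail_if(sum(dat$y > 0) < 2L, "degenerate histogram: a single occupied bin")

  fit <- minpack.lm::nlsLM(
    y ~ A * exp(-(x - mu)^2 / (2 * s^2)), data = dat,
    start = list(A = max(dat$y), mu = mean(values), s = sd(values)),
    control = minpack.lm::nls.lm.control(ftol = 1e-8, maxiter = 200))
  est <- coef(fit)
  structure(list(amplitude = unname(est["A"]), mean = unname(est["mu"]),
                 sd = abs(unname(est["s"])),
                 rss = sum(residuals(fit)^2),
                 bins = data.frame(center = dat$x, count = dat$y)),
            class = "gaussian_fit")
}
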